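# Seeded synthetic-data generator: site climates, pseudo-observations and
# covariates with the statistical structure the evaluation pipeline
# assumes, so the whole tool is testable with no external data.

#' Synthetic-data configuration
#'
#' Defaults emulate the published global compilation the evaluation
#' pipeline was designed for: ~200 sites, ~18 observations per site
#' (3672 / 201), climates spanning the vegetated ranges (growing-season
#' temperature 0-35 degC, vapour pressure deficit 100-3000 Pa, irradiance
#' 200-1500 umol m-2 s-1, elevation 0-4000 m), multiplicative lognormal
#' observation noise with CV 0.25 (scatter grows with magnitude, as the
#' per-site standard errors of the compilation do), leaf-temperature
#' jitter of +/- 8 degC around growth temperature (lab/field mix), and 44%
#' of records flagged as one-point-method estimates.
#'
#' The covariate model makes leaf nitrogen track true capacity
#' (`Na = na_intercept + na_slope * Vcmax_true + noise`, the
#' demand-driven view) while the six soil variables are noise, optionally
#' correlated with growth temperature through `soil_rho`. `bias_ig`
#' injects a known irradiance-dependent percent bias (percent per
#' umol m-2 s-1 of centered Ig) for parameter-recovery tests.
#'
#' @param n_sites number of sites.
#' @param obs_per_site pseudo-observations per site.
#' @param seed RNG seed used by [simulate_sites()]/[simulate_monthly()].
#' @param tg_range,dg_range,ig_range,z_range climate ranges (degC, Pa,
#'   umol m-2 s-1, m).
#' @param ca_ppm atmospheric CO2 at sea level, umol mol-1.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal observation noise.
#' @param tmeas_jitter half-width of the uniform leaf-temperature jitter,
#'   degC.
#' @param na_intercept,na_slope,na_noise_sd leaf-nitrogen model
#'   (gN m-2, gN m-2 per umol m-2 s-1, gN m-2).
#' @param soil_rho correlation in (0, 1) between soil variables and
#'   growth temperature (0 = pure noise).
#' @param frac_one_point fraction of records labelled `one_point`.
#' @param bias_ig injected bias slope on centered irradiance, percent per
#'   umol m-2 s-1 (0 = unbiased).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 200L, obs_per_site = 18L, seed = 42L,
                       tg_range = c(0, 35), dg_range = c(100, 3000),
                       ig_range = c(200, 1500), z_range = c(0, 4000),
                       ca_ppm = 400, noise_cv = 0.25, tmeas_jitter = 8,
                       na_intercept = 0.8, na_slope = 0.02,
                       na_noise_sd = 0.25, soil_rho = 0,
                       frac_one_point = 0.44, bias_ig = 0) {
  cfg <- list(n_sites = as.integer(n_sites),
              obs_per_site = as.integer(obs_per_site),
              seed = as.integer(seed),
              tg_range = tg_range, dg_range = dg_range,
              ig_range = ig_range, z_range = z_range,
              ca_ppm = ca_ppm, noise_cv = noise_cv,
              tmeas_jitter = tmeas_jitter,
              na_intercept = na_intercept, na_slope = na_slope,
              na_noise_sd = na_noise_sd, soil_rho = soil_rho,
              frac_one_point = frac_one_point, bias_ig = bias_ig)
  for (rng in c("tg_range", "dg_range", "ig_range", "z_range")) {
    r <- cfg[[rng]]
    if (length(r) != 2L || r[1] > r[2]) {
      vcx_config_error(paste0(rng, " must be an ordered pair"))
    }
  }
  if (cfg$noise_cv < 0) vcx_config_error("noise_cv must be >= 0")
  if (cfg$soil_rho < 0 || cfg$soil_rho >= 1) {
    vcx_config_error("soil_rho must be in [0, 1)")
  }
  if (cfg$frac_one_point < 0 || cfg$frac_one_point > 1) {
    vcx_config_error("frac_one_point must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# soil variable: rho-correlated blend of standardized Tg and noise,
# mapped to a realistic location/scale
soil_var <- function(zt, rho, n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rho * zt + sqrt(1 - rho^2) * stats::rnorm(n)
  pmin(pmax(mean + sd * x, lower), upper)
}

#' Simulate sites, truth and pseudo-observations
#'
#' Draws site climates uniformly within the configured ranges (seeded),
#' computes the true optimal Vcmax and Jmax with [predict_optimal()], and
#' manufactures pseudo-observations by (1) multiplying truth by lognormal
#' noise with median 1 and CV `noise_cv`, (2) optionally applying the
#' injected irradiance-dependent bias, and (3) *un*-standardizing from
#' growth temperature to a jittered leaf temperature with the inverse of
#' the peaked-Arrhenius standardization — so that
#' [standardize_to_tg()] recovers the noisy value at Tg exactly, and with
#' zero noise the full pipeline closes on truth.
#'
#' Infeasible climates (below the Jmax feasibility threshold; the
#' no-growing-season analogue) are excluded and reported via the
#' `n_excluded` attribute.
#'
#' @param cfg a [sim_config()].
#' @param params a [model_params()] list.
#' @return list with data.frames `sites` (site table in the CSV dialect of
#'   the prediction front end), `observations` (one row per
#'   pseudo-measurement with leaf temperature, method flag and
#'   covariates) and `truth` (per-site true `vcmax_opt`, `jmax_opt`,
#'   `jv_ratio`).
#' @export
simulate_sites <- function(cfg = sim_config(), params = model_params()) {
  withr_seed(cfg$seed, {
    n <- cfg$n_sites
    runif2 <- function(r, n) stats::runif(n, r[1], r[2])
    sites <- data.frame(
      site_id = sprintf("site_%03d", seq_len(n)),
      lat = stats::runif(n, -55, 70),
      lon = stats::runif(n, -180, 180),
      z_m = runif2(cfg$z_range, n),
      tg_c = runif2(cfg$tg_range, n),
      dg_pa = runif2(cfg$dg_range, n),
      ig_umol_m2_s = runif2(cfg$ig_range, n),
      ca_ppm = cfg$ca_ppm
    )
    # exclude infeasible climates site by site (rare within default ranges)
    feasible <- vapply(seq_len(n), function(i) {
      !inherits(tryCatch(
        predict_optimal(sites$ig_umol_m2_s[i], sites$tg_c[i],
                        sites$dg_pa[i], sites$z_m[i], sites$ca_ppm[i],
                        params),
        vcx_domain_error = function(e) e), "error")
    }, logical(1))
    n_excluded <- sum(!feasible)
    sites <- sites[feasible, , drop = FALSE]
    n <- nrow(sites)
    if (!n) vcx_domain_error("all simulated climates infeasible")

    truth <- cbind(sites["site_id"],
                   predict_optimal(sites$ig_umol_m2_s, sites$tg_c,
                                   sites$dg_pa, sites$z_m, sites$ca_ppm,
                                   params))

    # site-level covariates
    zt <- as.numeric(scale(sites$tg_c))
    if (all(!is.finite(zt))) zt <- rep(0, n)  # degenerate single-value Tg
    rho <- cfg$soil_rho
    covs <- data.frame(
      site_id = sites$site_id,
      na_gN_m2 = pmax(cfg$na_intercept + cfg$na_slope * truth$vcmax_opt +
                        stats::rnorm(n, 0, cfg$na_noise_sd), 0.2),
      lma_g_m2 = pmax(stats::rlnorm(n, log(100), 0.4), 20),
      cec = soil_var(zt, rho, n, 15, 8, lower = 1),
      ph = soil_var(zt, rho, n, 6, 0.8, lower = 3.5, upper = 8.5),
      cn = soil_var(zt, rho, n, 12, 3, lower = 4),
      silt_pct = soil_var(zt, rho, n, 35, 12, lower = 1, upper = 90),
      clay_pct = soil_var(zt, rho, n, 25, 10, lower = 1, upper = 80),
      alpha = pmin(pmax(soil_var(zt, rho, n, 0.8, 0.25), 0.05), 1.26)
    )

    # pseudo-observations: noisy truth at Tg, un-standardized to Tmeas
    m <- cfg$obs_per_site
    idx <- rep(seq_len(n), each = m)
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- stats::rlnorm(n * m, meanlog = 0, sdlog = sdlog)
    bias_factor <- 1 + cfg$bias_ig *
      (sites$ig_umol_m2_s[idx] - mean(cfg$ig_range)) / 100
    if (any(bias_factor <= 0)) {
      vcx_config_error("bias_ig too large: implied observation <= 0")
    }
    v_tg <- truth$vcmax_opt[idx] * noise / bias_factor
    tmeas <- pmin(pmax(sites$tg_c[idx] +
                         stats::runif(n * m, -cfg$tmeas_jitter,
                                      cfg$tmeas_jitter), 0.5), 49.5)
    tg <- sites$tg_c[idx]
    dS <- entropy_vcmax(tg, params)
    # inverse of the Tmeas -> Tg standardization
    vcmax_meas <- kattge_knorr_scale(v_tg, tg + 273.15, tmeas + 273.15,
                                     dS, params)
    # Jmax pseudo-observations share the site noise structure
    j_tg <- truth$jmax_opt[idx] * stats::rlnorm(n * m, 0, sdlog)
    dSj <- entropy_jmax(tg, params)
    jmax_meas <- kattge_knorr_scale(j_tg, tg + 273.15, tmeas + 273.15,
                                    dSj, params, Ha = params$Ha_jmax)
    method <- ifelse(stats::runif(n * m) < cfg$frac_one_point,
                     "one_point", "aci_curve")

    obs <- data.frame(
      site_id = sites$site_id[idx],
      lat = sites$lat[idx],
      lon = sites$lon[idx],
      vcmax_meas = vcmax_meas,
      t_meas_c = tmeas,
      jmax_meas = jmax_meas,
      method = method
    )
    obs <- merge(obs, covs, by = "site_id", sort = FALSE)

    out <- list(sites = sites,
                observations = obs,
                truth = truth[c("site_id", "vcmax_opt", "jmax_opt",
                                "jv_ratio")])
    attr(out, "n_excluded") <- n_excluded
    out
  })
}

#' Simulate monthly climate series
#'
#' Sinusoidal annual cycles with site-specific mean and amplitude,
#' peaking mid-year in the northern hemisphere and offset by six months in
#' the southern; vapour pressure deficit grows exponentially with
#' temperature and radiation tracks it linearly. A configurable fraction
#' of sites is polar-like (all months below 0 degC) to exercise the
#' no-growing-season path.
#'
#' @param cfg a [sim_config()]; `n_sites` and `seed` are used.
#' @param frac_polar fraction of sites with no month above 0 degC.
#' @return data.frame with columns `site_id`, `lat`, `month`, `tair_c`,
#'   `vpd_pa`, `par_umol_m2_s`.
#' @export
simulate_monthly <- function(cfg = sim_config(), frac_polar = 0.05) {
  withr_seed(cfg$seed + 1L, {
    n <- cfg$n_sites
    lat <- stats::runif(n, -70, 75)
    polar <- stats::runif(n) < frac_polar
    tmean <- ifelse(polar, stats::runif(n, -25, -12),
                    stats::runif(n, -3, 25))
    amp <- stats::runif(n, 0, 20) * (abs(lat) / 75)
    month <- 1:12
    rows <- lapply(seq_len(n), function(i) {
      phase <- if (lat[i] >= 0) 7 else 1   # warmest month
      tair <- tmean[i] + amp[i] * cos(2 * pi * (month - phase) / 12)
      vpd <- pmax(150 * exp(0.055 * tair), 10)
      par <- pmax(250 + 28 * tair, 20)
      data.frame(site_id = sprintf("site_%03d", i), lat = lat[i],
                 month = month, tair_c = tair, vpd_pa = vpd,
                 par_umol_m2_s = par)
    })
    do.call(rbind, rows)
  })
}
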