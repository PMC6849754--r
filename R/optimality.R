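# The optimality model proper: least-cost optimal chi, coordination-theory
# optimal Vcmax and Jmax, and the peaked-Arrhenius temperature scaling that
# ties them to growth temperature.

#' Optimal Ci:Ca ratio from least-cost theory
#'
#' Least-cost theory co-minimizes the carbon costs of transpiration and
#' carboxylation per unit assimilation,
#' `f(Ci) = 1.6 eta* D / (Ca - Ci) + beta (Ci + K) / (Ci - Gamma*)`,
#' whose interior minimum is attained at
#' \deqn{\chi = \Gamma^*/C_a + (1 - \Gamma^*/C_a)\,\xi/(\xi + \sqrt{D}),
#'   \qquad \xi = \sqrt{\beta (K + \Gamma^*) / (1.6\,\eta^*)}}
#' with D the vapour pressure deficit in Pa and xi in Pa^0.5.
#'
#' chi is clamped to `(Gamma*/Ca + 1e-9, 1]` with a warning if the clamp
#' fires (it cannot for valid inputs; the guard protects downstream terms
#' from rounding).
#'
#' @param ks a `kinetic_state` from [calc_kinetics()].
#' @param dg_pa vapour pressure deficit, Pa (>= 0).
#' @param params a [model_params()] list (uses `beta`).
#' @return list with `xi` (Pa^0.5), `chi` (unitless), `ci` (Pa).
#' @examples
#' ks <- calc_kinetics(25, calc_patm(0))
#' calc_chi(ks, 1000)$chi
#' @export
calc_chi <- function(ks, dg_pa, params = model_params()) {
  assert_number(dg_pa, "dg_pa", lower = 0)
  if (any(ks$ca <= ks$gammastar)) {
    vcx_domain_error("Ca <= Gamma*: no feasible CO2 drawdown at this site")
  }
  xi <- sqrt(params$beta * (ks$K + ks$gammastar) / (1.6 * ks$eta_star))
  g <- ks$gammastar / ks$ca
  chi <- g + (1 - g) * xi / (xi + sqrt(dg_pa))
  lo <- g + 1e-9
  if (any(chi <= lo) || any(chi > 1)) {
    warning("chi clamped to (Gamma*/Ca, 1]")
    chi <- pmin(pmax(chi, lo), 1)
  }
  list(xi = xi, chi = chi, ci = chi * ks$ca)
}

#' CO2 limitation terms of assimilation
#'
#' `m = (Ci - Gamma*) / (Ci + 2 Gamma*)` is the CO2 limitation of
#' electron-transport-limited assimilation; `mc = (Ci - Gamma*) / (Ci + K)`
#' that of Rubisco-limited assimilation. `m > mc` whenever `K > 2 Gamma*`,
#' which holds at physiological temperatures.
#'
#' @param ci intercellular CO2 partial pressure, Pa (> Gamma*).
#' @param ks a `kinetic_state`.
#' @return list with `m`, `mc`, both in (0, 1).
#' @export
calc_m_terms <- function(ci, ks) {
  assert_number(ci, "ci")
  if (any(ci <= ks$gammastar)) {
    vcx_domain_error("ci <= Gamma*: assimilation terms undefined")
  }
  list(m  = (ci - ks$gammastar) / (ci + 2 * ks$gammastar),
       mc = (ci - ks$gammastar) / (ci + ks$K))
}

# Smaller root of the non-rectangular hyperbola: electron-transport-limited
# assimilation as a function of Jmax at irradiance I (used by the numeric
# omega mode and by the test oracles through the same algebra).
aj_of_jmax <- function(jmax, I, m, phi, theta) {
  x <- phi * I
  m * (x + jmax - sqrt((x + jmax)^2 - 4 * theta * x * jmax)) / (8 * theta)
}

#' Optimal Jmax multiplier omega
#'
#' omega solves the marginal-benefit condition `dAj/dJmax = c` with
#' `Jmax = phi I omega`; because the condition is homogeneous in irradiance,
#' omega depends only on `theta`, `c` and `m`. The closed form
#' (default `omega_mode = "closed"`) is
#' \deqn{\omega = -(1 - 2\theta) + k \sqrt{(1-\theta) / (d (1 - \theta d))},
#'   \quad d = 4c/m,\ k = 1 - 2\theta d,}
#' algebraically equivalent to solving the squared marginal condition and
#' picking the branch consistent with the unsquared one (the sign of `k`
#' carries that choice). `omega_mode = "numeric"` root-finds the marginal
#' condition directly.
#'
#' Feasibility requires `m > 4 c` (the initial slope of Aj in Jmax is
#' `m / 4`; below that, capacity can never pay its marginal cost) — cold or
#' dark degenerate inputs fail loudly here.
#'
#' @param params a [model_params()] list (uses `theta`, `c_cost`,
#'   `omega_mode`).
#' @param m CO2 limitation term of light-limited assimilation.
#' @return omega (> 0), same length as `m`.
#' @export
calc_omega <- function(params, m) {
  assert_number(m, "m")
  theta <- params$theta; cc <- params$c_cost
  d <- 4 * cc / m
  if (any(d >= 1)) {
    vcx_domain_error(sprintf(
      "infeasible site: m = %g <= 4c = %g (too cold/dark for positive Jmax)",
      m[which(d >= 1)[1L]], 4 * cc))
  }
  disc <- (1 - theta) / (d * (1 - theta * d))
  if (any(d * (1 - theta * d) <= 0) || any(disc < 0)) {
    vcx_domain_error("negative discriminant in omega closed form")
  }
  if (params$omega_mode == "closed") {
    k <- 1 - 2 * theta * d
    omega <- -(1 - 2 * theta) + k * sqrt(disc)
  } else {
    omega <- vapply(m, function(mi) {
      f <- function(j) {
        h <- max(j * 1e-6, 1e-8)
        (aj_of_jmax(j + h, 800, mi, params$phi, theta) -
           aj_of_jmax(j - h, 800, mi, params$phi, theta)) / (2 * h) - cc
      }
      stats::uniroot(f, c(1e-8, 1e6), tol = 1e-12)$root / (params$phi * 800)
    }, numeric(1))
  }
  if (any(omega <= 0)) {
    vcx_domain_error("omega <= 0: site below Jmax feasibility threshold")
  }
  omega
}

#' omega* term of light-limited assimilation at the optimum
#'
#' `omega* = 1 + omega - sqrt((1 + omega)^2 - 4 theta omega)`, so that
#' `Aj = phi I m omega* / (8 theta)` equals the smaller-root hyperbola
#' evaluated at `Jmax = phi I omega` (algebraic identity).
#'
#' @param omega output of [calc_omega()].
#' @param theta light-response curvature.
#' @return omega*, in (0, 2).
#' @export
calc_omega_star <- function(omega, theta) {
  assert_number(omega, "omega", lower = 0)
  1 + omega - sqrt((1 + omega)^2 - 4 * theta * omega)
}

#' Intermediate optimal Vcmax at the optimum temperature
#'
#' Coordination (`Ac = Aj`) with `Ac = Vcmax mc` gives
#' `Vcmax* = phi I (m / mc) omega* / (8 theta)`. Strictly proportional to
#' irradiance.
#'
#' @param I photosynthetic photon flux density, umol m-2 s-1.
#' @param m,mc CO2 limitation terms from [calc_m_terms()].
#' @param omega_star from [calc_omega_star()].
#' @param params a [model_params()] list.
#' @return Vcmax*, umol m-2 s-1.
#' @export
calc_vcmax_star <- function(I, m, mc, omega_star, params = model_params()) {
  assert_number(I, "I", lower = 0)
  if (any(mc <= 0)) vcx_domain_error("mc must be > 0")
  params$phi * I * (m / mc) * omega_star / (8 * params$theta)
}

#' Peaked-Arrhenius (Kattge-Knorr) temperature scaling
#'
#' Scales a rate from temperature `t_from` to `t_to` (both Kelvin) with the
#' modified Arrhenius ratio
#' \deqn{r(T_2) = r(T_1)\, e^{H_a (T_2 - T_1)/(R T_1 T_2)}
#'   \frac{1 + e^{(T_1 \Delta S - H_d)/(R T_1)}}
#'        {1 + e^{(T_2 \Delta S - H_d)/(R T_2)}}}
#' This single function backs both the model's scaling from the optimum
#' temperature to growth temperature and the standardization of field
#' measurements to growth temperature — one source of truth for the
#' temperature response.
#'
#' @param rate rate at `t_from`.
#' @param t_from,t_to temperatures in Kelvin (an input below 150 is
#'   treated as accidentally-Celsius and rejected).
#' @param dS entropy term, J mol-1 K-1 (compute from growth temperature via
#'   [entropy_vcmax()]).
#' @param params a [model_params()] list.
#' @param Ha,Hd activation/deactivation energies, J mol-1; default the
#'   Vcmax constants, override with `params$Ha_jmax` for Jmax.
#' @return the rate at `t_to`; identical to `rate` when `t_to == t_from`.
#' @export
kattge_knorr_scale <- function(rate, t_from, t_to, dS,
                               params = model_params(),
                               Ha = params$Ha, Hd = params$Hd) {
  if (any(t_from < 150) || any(t_to < 150)) {
    vcx_domain_error("temperatures must be in Kelvin (got a value < 150)")
  }
  R <- params$R
  rate * exp(Ha * (t_to - t_from) / (R * t_to * t_from)) *
    (1 + exp((t_from * dS - Hd) / (R * t_from))) /
    (1 + exp((t_to * dS - Hd) / (R * t_to)))
}

#' Entropy term of the Vcmax temperature response
#'
#' Linear acclimation regression on growth temperature in degrees Celsius
#' (intercept 668.39, slope -1.07 J mol-1 K-1). The Celsius convention here
#' versus the Kelvin convention in [calc_t_opt()] follows the source
#' calibration; mixing them is the classic silent failure of this model.
#'
#' @param tg_c growth temperature, degC.
#' @param params a [model_params()] list.
#' @return dS, J mol-1 K-1.
#' @export
entropy_vcmax <- function(tg_c, params = model_params()) {
  params$dS_intercept + params$dS_slope * tg_c
}

#' @rdname entropy_vcmax
#' @export
entropy_jmax <- function(tg_c, params = model_params()) {
  params$dS_intercept_jmax + params$dS_slope_jmax * tg_c
}

#' Optimum temperature of Vcmax from growth temperature
#'
#' `To = 177.884 + 0.44 Tg`, both in Kelvin (equivalently
#' `To_degC = 24.92 + 0.44 Tg_degC`).
#'
#' @param tg_k growth temperature, Kelvin.
#' @param params a [model_params()] list.
#' @return To in Kelvin.
#' @export
calc_t_opt <- function(tg_k, params = model_params()) {
  if (any(tg_k < 150)) {
    vcx_domain_error("tg_k must be in Kelvin (got a value < 150)")
  }
  params$To_intercept + params$To_slope * tg_k
}

#' Predict optimal photosynthetic capacity from climate
#'
#' End-to-end optimality prediction for one or more sites: kinetics at
#' growth temperature and pressure, least-cost chi, CO2 limitation terms,
#' optimal Jmax multiplier, coordination Vcmax* at the optimum temperature
#' To, and peaked-Arrhenius scaling of both capacities from To to growth
#' temperature. All intermediates are returned for audit.
#'
#' `Vcmax*` is interpreted as operating at `To` (the temperature the
#' acclimated enzyme system is optimized for), so the temperature scaling
#' runs from `To` to `Tg`. The Jmax:Vcmax ratio uses Jmax-specific
#' activation energy and entropy by default
#' (`jv_ratio_mode = "scaled"`); `"at_to"` reports the unscaled ratio
#' `phi I omega / Vcmax*`.
#'
#' @param ig_umol_m2_s growing-season mean photosynthetic photon flux
#'   density, umol m-2 s-1.
#' @param tg_c growing-season mean air temperature, degC.
#' @param dg_pa growing-season mean vapour pressure deficit, Pa.
#' @param z_m elevation, m.
#' @param ca_ppm atmospheric CO2, umol mol-1 (default 400).
#' @param params a [model_params()] list.
#' @return data.frame with one row per site: inputs, `patm`, `ca`,
#'   `gammastar`, `K`, `eta_star`, `xi`, `chi`, `ci`, `m`, `mc`, `omega`,
#'   `omega_star`, `vcmax_star`, `t_opt_k`, `dS`, `vcmax_opt`, `jmax_opt`,
#'   `jv_ratio`.
#' @examples
#' predict_optimal(800, 25, 1000, 0)
#' @export
predict_optimal <- function(ig_umol_m2_s, tg_c, dg_pa, z_m, ca_ppm = 400,
                            params = model_params()) {
  n <- max(length(ig_umol_m2_s), length(tg_c), length(dg_pa), length(z_m),
           length(ca_ppm))
  ig <- rep_len(ig_umol_m2_s, n); tg <- rep_len(tg_c, n)
  dg <- rep_len(dg_pa, n); z <- rep_len(z_m, n)
  cap <- rep_len(ca_ppm, n)
  assert_number(ig, "ig_umol_m2_s", lower = 0)
  assert_number(dg, "dg_pa", lower = 0)

  patm <- calc_patm(z)
  ks <- calc_kinetics(tg, patm, cap, params)
  chi <- calc_chi(ks, dg, params)
  mm <- calc_m_terms(chi$ci, ks)
  omega <- calc_omega(params, mm$m)
  omega_star <- calc_omega_star(omega, params$theta)
  vstar <- calc_vcmax_star(ig, mm$m, mm$mc, omega_star, params)

  tg_k <- tg + 273.15
  t_opt <- calc_t_opt(tg_k, params)
  dS <- entropy_vcmax(tg, params)
  vcmax_opt <- kattge_knorr_scale(vstar, t_opt, tg_k, dS, params)

  jstar <- params$phi * ig * omega   # Jmax at To
  if (params$jv_ratio_mode == "scaled") {
    dSj <- entropy_jmax(tg, params)
    jmax_opt <- kattge_knorr_scale(jstar, t_opt, tg_k, dSj, params,
                                   Ha = params$Ha_jmax)
  } else {
    jmax_opt <- jstar
  }
  jv <- jmax_opt /
    (if (params$jv_ratio_mode == "scaled") vcmax_opt else vstar)

  data.frame(
    ig_umol_m2_s = ig, tg_c = tg, dg_pa = dg, z_m = z, ca_ppm = cap,
    patm = patm, ca = ks$ca, gammastar = ks$gammastar, K = ks$K,
    eta_star = ks$eta_star, xi = chi$xi, chi = chi$chi, ci = chi$ci,
    m = mm$m, mc = mm$mc, omega = omega, omega_star = omega_star,
    vcmax_star = vstar, t_opt_k = t_opt, dS = dS,
    vcmax_opt = vcmax_opt, jmax_opt = jmax_opt, jv_ratio = jv
  )
}

#' Predict for a site table
#'
#' Data-frame front end to [predict_optimal()]: takes a site table with
#' columns `ig_umol_m2_s`, `tg_c`, `dg_pa`, `z_m` and optionally `ca_ppm`
#' (default 400) plus identifier columns (`site_id`, `lat`, `lon`), which
#' are carried through to the output.
#'
#' @param sites data.frame of sites.
#' @param params a [model_params()] list.
#' @return data.frame: identifier columns then all [predict_optimal()]
#'   columns.
#' @export
predict_vcmax <- function(sites, params = model_params()) {
  need <- c("ig_umol_m2_s", "tg_c", "dg_pa", "z_m")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols)) {
    vcx_parse_error(paste0("site table lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  ca <- if ("ca_ppm" %in% names(sites)) sites$ca_ppm else 400
  out <- tryCatch(
    predict_optimal(sites$ig_umol_m2_s, sites$tg_c, sites$dg_pa,
                    sites$z_m, ca, params),
    vcx_domain_error = function(e) {
      ids <- if ("site_id" %in% names(sites)) {
        paste0(" [sites: ", paste(utils::head(sites$site_id, 5), collapse = ", "), "]")
      } else ""
      vcx_domain_error(paste0(conditionMessage(e), ids))
    })
  id_cols <- intersect(c("site_id", "lat", "lon", "year"), names(sites))
  if (length(id_cols)) out <- cbind(sites[id_cols], out)
  out
}
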