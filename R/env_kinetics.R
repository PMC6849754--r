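# Physical environment and temperature-dependent Rubisco kinetics.

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere barometric formula: sea-level pressure 101325 Pa,
#' lapse rate 0.0065 K m-1, base temperature 288.15 K, g = 9.80665 m s-2,
#' molar mass of air 0.028963 kg mol-1, R = 8.314 J mol-1 K-1.
#'
#' @param z elevation in metres; accepted range -430 (Dead Sea shore) to
#'   9000 m.
#' @return pressure in Pa; exactly 101325 at `z = 0`.
#' @examples
#' calc_patm(0)
#' calc_patm(c(1000, 2000))
#' @export
calc_patm <- function(z) {
  assert_number(z, "z", lower = -430, upper = 9000)
  kTo <- 288.15; kL <- 0.0065; kG <- 9.80665; kMa <- 0.028963; kR <- 8.314
  101325 * (1 - kL * z / kTo)^(kG * kMa / (kR * kL))
}

#' CO2 partial pressure from mole fraction
#'
#' @param ca_ppm CO2 mole fraction, umol mol-1.
#' @param patm atmospheric pressure, Pa.
#' @return CO2 partial pressure Ca, Pa.
#' @examples
#' calc_co2_partial_pressure(400, calc_patm(0))
#' @export
calc_co2_partial_pressure <- function(ca_ppm, patm) {
  assert_number(ca_ppm, "ca_ppm")
  assert_number(patm, "patm")
  if (any(ca_ppm <= 0)) vcx_domain_error("`ca_ppm` must be > 0")
  if (any(patm <= 0)) vcx_domain_error("`patm` must be > 0")
  ca_ppm * 1e-6 * patm
}

# --- water density & viscosity -----------------------------------------

# Tumlirz equation-of-state fit (Fisher et al. 2006): density of pure
# water as a function of temperature (degC) and pressure (Pa). Needed
# because the viscosity correlation below takes density, not pressure.
calc_density_h2o <- function(tc, p) {
  lambda <- 1788.316 + 21.55053 * tc - 0.4695911 * tc^2 +
    3.096363e-3 * tc^3 - 7.341182e-6 * tc^4
  po <- 5918.499 + 58.05267 * tc - 1.1253317 * tc^2 +
    6.6123869e-3 * tc^3 - 1.4661625e-5 * tc^4
  vinf <- 0.6980547 - 7.435626e-4 * tc + 3.704258e-5 * tc^2 -
    6.315724e-7 * tc^3 + 9.829576e-9 * tc^4 - 1.197269e-10 * tc^5 +
    1.005461e-12 * tc^6 - 5.437898e-15 * tc^7 + 1.69946e-17 * tc^8 -
    2.295063e-20 * tc^9
  pbar <- 1e-5 * p                      # Pa -> bar
  vau <- vinf + lambda / (po + pbar)    # specific volume, cm3 g-1
  1e3 / vau                             # kg m-3
}

# IAPWS 2008 / Huber et al. (2009) dynamic viscosity of water, Pa s.
# mu0 is the dilute-gas term in reduced temperature; mu1 the residual
# term in reduced temperature and density. The critical-enhancement term
# is negligible at surface conditions and omitted (as in the reference
# formulation for industrial use).
calc_viscosity_h2o <- function(tc, p) {
  tk_ast <- 647.096; rho_ast <- 322.0; mu_ast <- 1e-6
  rho <- calc_density_h2o(tc, p)
  tbar <- (tc + 273.15) / tk_ast
  rbar <- rho / rho_ast
  mu0 <- 1e2 * sqrt(tbar) /
    (1.67752 + 2.20462 / tbar + 0.6366564 / tbar^2 - 0.241605 / tbar^3)
  # H[i+1, j+1] multiplies (1/tbar - 1)^i * (rbar - 1)^j
  H <- matrix(0, 6, 7)
  H[1, 1] <- 5.20094e-1; H[2, 1] <- 8.50895e-2; H[3, 1] <- -1.08374
  H[4, 1] <- -2.89555e-1
  H[1, 2] <- 2.22531e-1; H[2, 2] <- 9.99115e-1; H[3, 2] <- 1.88797
  H[4, 2] <- 1.26613; H[6, 2] <- 1.20573e-1
  H[1, 3] <- -2.81378e-1; H[2, 3] <- -9.06851e-1; H[3, 3] <- -7.72479e-1
  H[4, 3] <- -4.89837e-1; H[5, 3] <- -2.57040e-1
  H[1, 4] <- 1.61913e-1; H[2, 4] <- 2.57399e-1
  H[1, 5] <- -3.25372e-2; H[4, 5] <- 6.98452e-2
  H[5, 6] <- 8.72102e-3
  H[4, 7] <- -4.35673e-3; H[6, 7] <- -5.93264e-4
  ct <- 1 / tbar - 1
  cr <- rbar - 1
  s <- 0
  for (i in 0:5) {
    inner <- 0
    for (j in 0:6) inner <- inner + H[i + 1, j + 1] * cr^j
    s <- s + ct^i * inner
  }
  mu1 <- exp(rbar * s)
  mu0 * mu1 * mu_ast
}

# Temperature-only fallback (Vogel equation); pressure dependence of
# liquid-water viscosity is < 0.1% over the elevation range considered.
calc_viscosity_simple <- function(tc) {
  1e-3 * exp(-3.7188 + 578.919 / (tc + 273.15 - 137.546))
}

#' Viscosity of water relative to 25 degC
#'
#' eta* scales the carbon cost of the transpiration stream in least-cost
#' theory. Computed from the Huber et al. (2009) correlation at
#' `(tc, patm)` divided by its value at 25 degC and sea-level pressure
#' (so `eta_star(25, 101325) == 1` exactly).
#'
#' @param tc temperature, degC.
#' @param patm pressure, Pa.
#' @param params `model_params`; `viscosity_mode = "simple"` switches to a
#'   temperature-only approximation.
#' @return unitless relative viscosity.
#' @export
calc_eta_star <- function(tc, patm, params = model_params()) {
  if (params$viscosity_mode == "huber") {
    calc_viscosity_h2o(tc, patm) / calc_viscosity_h2o(25, 101325)
  } else {
    calc_viscosity_simple(tc) / calc_viscosity_simple(25)
  }
}

# --- Rubisco kinetics ---------------------------------------------------

# Arrhenius response relative to 25 degC, tk in Kelvin.
arrhenius <- function(ref25, dha, tk, R = 8.314) {
  ref25 * exp(dha * (tk - 298.15) / (298.15 * R * tk))
}

#' Temperature- and pressure-dependent photosynthetic kinetics
#'
#' Evaluates the Bernacchi et al. (2001) Arrhenius responses of the
#' Michaelis constants of Rubisco for CO2 (Kc) and O2 (Ko) and of the
#' photorespiratory compensation point (Gamma*), converts them to partial
#' pressures at site atmospheric pressure, and assembles the effective
#' Michaelis-Menten coefficient `K = Kc (1 + Oi / Ko)` with
#' `Oi = 0.2095 patm`. Also computes Ca and the relative water viscosity
#' eta*.
#'
#' @param tg_c growth temperature, degC (range -30 to 60).
#' @param patm atmospheric pressure, Pa (use [calc_patm()]).
#' @param ca_ppm atmospheric CO2, umol mol-1 (default 400).
#' @param params a [model_params()] list.
#' @return list of class `"kinetic_state"` with elements `patm`, `ca`,
#'   `oi`, `kc`, `ko`, `gammastar`, `K`, `eta_star` (pressures in Pa).
#' @examples
#' ks <- calc_kinetics(25, calc_patm(0))
#' ks$K            # ~71.9 Pa
#' ks$eta_star     # 1 at the reference point
#' @export
calc_kinetics <- function(tg_c, patm, ca_ppm = 400, params = model_params()) {
  assert_number(tg_c, "tg_c", lower = -30, upper = 60)
  assert_number(patm, "patm")
  if (any(patm <= 0)) vcx_domain_error("`patm` must be > 0")
  tk <- tg_c + 273.15
  kc <- arrhenius(params$kc25 * patm, params$dha_kc, tk, params$R)
  ko <- arrhenius(params$ko25 * patm, params$dha_ko, tk, params$R)
  gammastar <- arrhenius(params$gammastar25 * patm, params$dha_gammastar,
                         tk, params$R)
  oi <- params$o2_frac * patm
  structure(list(
    patm = patm,
    ca = calc_co2_partial_pressure(ca_ppm, patm),
    oi = oi,
    kc = kc,
    ko = ko,
    gammastar = gammastar,
    K = kc * (1 + oi / ko),
    eta_star = calc_eta_star(tg_c, patm, params)
  ), class = "kinetic_state")
}

# --- growing-season climatology ----------------------------------------

#' Growing-season means from monthly climate
#'
#' The growing season is defined as calendar months whose mean air
#' temperature exceeds 0 degC (strictly; months at exactly 0 are
#' excluded). Returns unweighted means of temperature, vapour pressure
#' deficit and photosynthetically active radiation over those months.
#'
#' Sites with no month above 0 degC get `growing_season = FALSE` and NA
#' means: the caller must withhold a prediction rather than silently use
#' zeros.
#'
#' @param tair_c monthly mean air temperature, degC.
#' @param vpd_pa monthly mean vapour pressure deficit, Pa.
#' @param par_umol_m2_s monthly mean photosynthetic photon flux density,
#'   umol m-2 s-1.
#' @return list with `tg_c`, `dg_pa`, `ig_umol_m2_s`, `n_months`,
#'   `growing_season`.
#' @examples
#' growing_season_means(c(-5, 5, 15, 20), c(500, 600, 900, 1200),
#'                      c(300, 500, 900, 1100))
#' @export
growing_season_means <- function(tair_c, vpd_pa, par_umol_m2_s) {
  n <- length(tair_c)
  if (n < 1L) vcx_domain_error("need at least one month")
  if (length(vpd_pa) != n || length(par_umol_m2_s) != n) {
    vcx_domain_error("monthly series must have equal lengths")
  }
  if (anyNA(tair_c) || anyNA(vpd_pa) || anyNA(par_umol_m2_s)) {
    vcx_domain_error("monthly series contain missing values")
  }
  grow <- tair_c > 0
  if (!any(grow)) {
    return(list(tg_c = NA_real_, dg_pa = NA_real_, ig_umol_m2_s = NA_real_,
                n_months = 0L, growing_season = FALSE))
  }
  list(tg_c = mean(tair_c[grow]),
       dg_pa = mean(vpd_pa[grow]),
       ig_umol_m2_s = mean(par_umol_m2_s[grow]),
       n_months = sum(grow),
       growing_season = TRUE)
}
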