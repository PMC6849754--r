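#' Model parameters and physical constants
#'
#' Builds the full parameter set used by the optimality model and the
#' evaluation pipeline. Every constant can be overridden by name, which is
#' how sensitivity experiments and unit tests perturb the model; defaults
#' are the published calibration.
#'
#' The tunable core:
#' \describe{
#'   \item{phi}{Realized quantum yield of photosynthetic electron transport
#'     (mol electrons per mol photons), default 0.257. Product of intrinsic
#'     quantum efficiency and leaf absorptance; calibrated so the
#'     observed-vs-predicted Vcmax slope is near 1.}
#'   \item{theta}{Curvature of the non-rectangular hyperbolic light response
#'     of electron transport (unitless), default 0.85.}
#'   \item{c_cost}{Marginal carbon cost of maintaining Jmax capacity,
#'     i.e. the value of dAj/dJmax at the optimum (unitless), default 0.053
#'     (derived at standard conditions: Tg 25 degC, Dg 1 kPa, z 0).}
#'   \item{beta}{Ratio b/a of the carbon cost of maintaining carboxylation
#'     capacity to the cost of maintaining the transpiration stream
#'     (unitless), default 146, estimated from leaf carbon-isotope data.}
#' }
#'
#' Temperature-response constants (Kattge-Knorr peaked Arrhenius):
#' `Ha` (activation energy for Vcmax, 71513 J mol-1), `Hd` (deactivation
#' energy, 200000 J mol-1), entropy regression on growth temperature in
#' degC (`dS_intercept` 668.39, `dS_slope` -1.07 J mol-1 K-1), optimum
#' temperature regression on growth temperature in K (`To_intercept`
#' 177.884, `To_slope` 0.44, returning K), and the Jmax-specific variant
#' (`Ha_jmax` 49884, `dS_intercept_jmax` 659.70, `dS_slope_jmax` -0.75).
#'
#' Rubisco kinetics are the Bernacchi et al. (2001) in-vivo constants,
#' stored as 25 degC mole fractions (`kc25` 404.9 umol mol-1, `ko25` 278.4
#' mmol mol-1, `gammastar25` 42.75 umol mol-1) with activation energies
#' (`dha_kc` 79430, `dha_ko` 36380, `dha_gammastar` 37830 J mol-1);
#' partial pressures scale with site atmospheric pressure, as does the
#' O2 partial pressure (`o2_frac` 0.2095).
#'
#' Mode switches: `viscosity_mode` selects the full Huber et al. (2009)
#' water-viscosity correlation (`"huber"`, default) or a
#' temperature-only Vogel-type approximation (`"simple"`);
#' `omega_mode` selects the closed-form solution of the marginal-cost
#' condition for Jmax (`"closed"`, default) or numerical root-finding
#' (`"numeric"`); `jv_ratio_mode` reports the Jmax:Vcmax ratio with both
#' rates scaled to growth temperature (`"scaled"`, default) or unscaled at
#' the optimum temperature (`"at_to"`).
#'
#' @param ... named overrides of any listed constant.
#' @return A list of class `"model_params"`.
#' @examples
#' p <- model_params()
#' p$beta
#' model_params(phi = 0.26, beta = 240)$beta
#' @export
model_params <- function(...) {
  p <- list(
    # optimality core
    phi    = 0.257,
    theta  = 0.85,
    c_cost = 0.053,
    beta   = 146,
    # peaked Arrhenius (Vcmax)
    Ha = 71513,
    Hd = 200000,
    R  = 8.314,
    dS_slope     = -1.07,
    dS_intercept = 668.39,
    To_slope     = 0.44,     # K per K, Tg in K
    To_intercept = 177.884,  # K
    # peaked Arrhenius (Jmax variant, same source)
    Ha_jmax = 49884,
    dS_slope_jmax     = -0.75,
    dS_intercept_jmax = 659.70,
    # Rubisco kinetics at 25 degC (mole fractions) + activation energies
    kc25        = 404.9e-6,   # mol mol-1
    ko25        = 278.4e-3,   # mol mol-1
    gammastar25 = 42.75e-6,   # mol mol-1
    dha_kc        = 79430,    # J mol-1
    dha_ko        = 36380,
    dha_gammastar = 37830,
    o2_frac = 0.2095,
    # mode switches
    viscosity_mode = "huber",
    omega_mode     = "closed",
    jv_ratio_mode  = "scaled"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      vcx_config_error("parameter overrides must be named")
    }
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) {
      vcx_config_error(paste0("unknown parameter(s): ",
                              paste(unknown, collapse = ", ")))
    }
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  if (!(p$phi > 0 && p$phi < 0.5))  vcx_config_error("phi must be in (0, 0.5)")
  if (!(p$theta > 0 && p$theta < 1)) vcx_config_error("theta must be in (0, 1)")
  if (!(p$c_cost > 0)) vcx_config_error("c_cost must be > 0")
  if (!(p$beta > 0))   vcx_config_error("beta must be > 0")
  if (!(p$Hd > p$Ha && p$Ha > 0)) {
    vcx_config_error("need Hd > Ha > 0 for a peaked temperature response")
  }
  if (!p$viscosity_mode %in% c("huber", "simple")) {
    vcx_config_error("viscosity_mode must be 'huber' or 'simple'")
  }
  if (!p$omega_mode %in% c("closed", "numeric")) {
    vcx_config_error("omega_mode must be 'closed' or 'numeric'")
  }
  if (!p$jv_ratio_mode %in% c("scaled", "at_to")) {
    vcx_config_error("jv_ratio_mode must be 'scaled' or 'at_to'")
  }
  invisible(p)
}

#' Read parameter overrides from a key=value file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments,
#' keys matching [model_params()] names. Mode switches take their string
#' values; everything else is numeric.
#'
#' @param path file path.
#' @return A `model_params` object.
#' @export
read_params_file <- function(path) {
  if (!file.exists(path)) vcx_config_error(paste0("no such params file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  modes <- c("viscosity_mode", "omega_mode", "jv_ratio_mode")
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[[i]], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      vcx_parse_error(sprintf("params file line %d: expected 'key = value'", i))
    }
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key %in% modes) {
      over[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        vcx_parse_error(sprintf("params file line %d: '%s' is not numeric", i, val))
      }
      over[[key]] <- num
    }
  }
  do.call(model_params, over)
}
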