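# Observation temperature-standardization and grid-cell aggregation.

#' Standardize measured Vcmax to growth temperature
#'
#' Field measurements are taken at whatever leaf temperature prevailed;
#' model predictions are at growing-season mean temperature Tg. This
#' rescales each measurement from its leaf temperature to Tg with the same
#' peaked-Arrhenius response used by the prediction side
#' ([kattge_knorr_scale()]), with the entropy term computed from Tg — not
#' from the measurement temperature (a common implementation mistake; the
#' acclimated entropy state belongs to the growth environment).
#'
#' Records with leaf temperature outside 0-50 degC are rejected: their
#' result is NA and a warning reports how many were dropped.
#'
#' @param vcmax_meas measured Vcmax, umol m-2 s-1 (> 0).
#' @param t_meas_c leaf temperature at measurement, degC.
#' @param tg_c growing-season mean temperature, degC (scalar or per
#'   record).
#' @param params a [model_params()] list.
#' @param Ha activation energy; default the Vcmax value, pass
#'   `params$Ha_jmax` to standardize Jmax measurements (with `dS` switched
#'   via `entropy`).
#' @param entropy function of `(tg_c, params)` returning dS; default
#'   [entropy_vcmax()].
#' @return vector of Vcmax at Tg; NA where rejected.
#' @examples
#' standardize_to_tg(60, 25, 25)   # identity
#' standardize_to_tg(50, 30, 20)
#' @export
standardize_to_tg <- function(vcmax_meas, t_meas_c, tg_c,
                              params = model_params(),
                              Ha = params$Ha, entropy = entropy_vcmax) {
  assert_number(vcmax_meas, "vcmax_meas")
  if (any(vcmax_meas <= 0)) vcx_domain_error("`vcmax_meas` must be > 0")
  n <- max(length(vcmax_meas), length(t_meas_c), length(tg_c))
  v <- rep_len(vcmax_meas, n)
  tm <- rep_len(t_meas_c, n)
  tg <- rep_len(tg_c, n)
  bad <- is.na(tm) | tm < 0 | tm > 50
  if (any(bad)) {
    warning(sprintf(
      "%d record(s) rejected: leaf temperature outside [0, 50] degC",
      sum(bad)))
  }
  dS <- entropy(tg, params)
  out <- kattge_knorr_scale(v, tm + 273.15, tg + 273.15, dS, params, Ha = Ha)
  out[bad] <- NA_real_
  out
}

#' Aggregate observations and predictions to half-degree cells
#'
#' Assigns records to 0.5-degree grid cells (half-open `[x, x + 0.5)`) and
#' returns per-cell means: number of observations, mean and standard error
#' of the standardized observed Vcmax, mean prediction, and means of any
#' extra covariate columns. The standard error is NA for single-record
#' cells.
#'
#' @param records data.frame with columns `lat`, `lon`, `vcmax_obs`
#'   (standardized observations), optionally `vcmax_pred` and further
#'   numeric covariates (all numeric columns are averaged per cell).
#' @param anchor `"integer"` anchors cell edges at multiples of 0.5 degree
#'   (centers at 0.25 offsets, the CRU layout); `"offset"` shifts edges by
#'   0.25 degree (centers on integers/halves).
#' @return data.frame with `cell_lat`, `cell_lon` (cell centers), `n_obs`,
#'   `vcmax_obs_mean`, `vcmax_obs_se`, and per-cell means of the remaining
#'   numeric columns. Records with invalid coordinates or NA `vcmax_obs`
#'   are dropped with a warning.
#' @export
aggregate_to_cells <- function(records, anchor = c("integer", "offset")) {
  anchor <- match.arg(anchor)
  need <- c("lat", "lon", "vcmax_obs")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    vcx_parse_error(paste0("records lack column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  bad_coord <- is.na(records$lat) | is.na(records$lon) |
    abs(records$lat) > 90 | abs(records$lon) > 180
  bad_obs <- is.na(records$vcmax_obs)
  drop <- bad_coord | bad_obs
  if (any(drop)) {
    warning(sprintf("%d record(s) dropped (%d invalid coordinates, %d missing observation)",
                    sum(drop), sum(bad_coord), sum(bad_obs & !bad_coord)))
    records <- records[!drop, , drop = FALSE]
  }
  if (!nrow(records)) vcx_domain_error("no valid records to aggregate")

  off <- if (anchor == "integer") 0 else 0.25
  edge <- function(x) floor((x - off) * 2) / 2 + off
  cell_lat <- edge(records$lat) + 0.25
  cell_lon <- edge(records$lon) + 0.25
  key <- paste(cell_lat, cell_lon, sep = "|")

  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      c("lat", "lon", "vcmax_obs"))
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    obs <- records$vcmax_obs[idx]
    base <- data.frame(
      cell_lat = cell_lat[idx[1L]],
      cell_lon = cell_lon[idx[1L]],
      n_obs = length(idx),
      vcmax_obs_mean = mean(obs),
      vcmax_obs_se = if (length(idx) >= 2L) {
        stats::sd(obs) / sqrt(length(idx))
      } else NA_real_
    )
    for (cn in num_cols) base[[cn]] <- mean(records[[cn]][idx], na.rm = TRUE)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_lat, out$cell_lon), , drop = FALSE]
}
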