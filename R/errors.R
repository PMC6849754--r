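# Structured error conditions. Every user-facing failure mode carries a
# class so the CLI can map it to a distinct exit code and tests can assert
# on the failure kind rather than on message wording.

vcx_error <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "vcx_error"),
                      call = call))
}

#' @noRd
vcx_domain_error <- function(message, ...) {
  vcx_error(message, "vcx_domain_error", call = sys.call(-1), ...)
}

#' @noRd
vcx_parse_error <- function(message, ...) {
  vcx_error(message, "vcx_parse_error", call = sys.call(-1), ...)
}

#' @noRd
vcx_config_error <- function(message, ...) {
  vcx_error(message, "vcx_config_error", call = sys.call(-1), ...)
}

# argument check helpers ------------------------------------------------

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_vector = TRUE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    vcx_domain_error(sprintf("`%s` must be numeric", name))
  }
  if (anyNA(x)) {
    vcx_domain_error(sprintf("`%s` contains missing values", name))
  }
  bad <- x < lower | x > upper
  if (any(bad)) {
    vcx_domain_error(sprintf(
      "`%s` out of range [%g, %g]: offending value %g",
      name, lower, upper, x[which(bad)[1L]]))
  }
  invisible(x)
}
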