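# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 2) {
  # base round() ties to even; printed clinical thresholds use half-up.
  # The 1e-9 guard keeps decimal ties (e.g. 0.575, stored just below the
  # tie in binary) on the half-up side.
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
#' @noRd
clip01 <- function(x) pmin(1, pmax(0, x))

# Distance from x to the closed interval [band[1], band[2]] (0 inside).
#' @keywords internal
#' @noRd
band_dist <- function(x, band) {
  pmax(band[1] - x, 0) + pmax(x - band[2], 0)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Full-precision numeric formatting so CSV round-trips are lossless.
#' @keywords internal
#' @noRd
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
  out
}

#' @keywords internal
#' @noRd
stop_cranfis <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cranfis_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
#' @noRd
warn_cranfis <- function(msg, class, ...) {
  warning(structure(
    class = c(class, "cranfis_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
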