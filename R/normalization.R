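#' Min-max normalization parameters
#'
#' A `norm_params` object is the affine map between a clinical variable's
#' physical units and the unit interval: `u = (x - vmin) / (vmax - vmin)`.
#' All model mathematics (membership functions, rule consequents, risk
#' thresholds) live on the normalized scale; `norm_params` is the only
#' bridge back to pg/mL, mmol/L, % and mL/min/1.73 m^2.
#'
#' @param vmin,vmax Column extremes in physical units; `vmin < vmax`.
#' @param variable Variable name (one of the canonical model variables, or
#'   any label for user-supplied columns).
#' @return An object of class `norm_params`.
#' @examples
#' p <- norm_params(2.4, 7.8, "k")
#' normalize_value(3.5, p)
#' @export
norm_params <- function(vmin, vmax, variable = "x") {
  if (!is.finite(vmin) || !is.finite(vmax)) {
    stop_cranfis("normalization bounds must be finite", "cranfis_invalid_params")
  }
  if (vmin >= vmax) {
    stop_cranfis(
      sprintf("degenerate normalization for '%s': vmin (%g) >= vmax (%g)",
              variable, vmin, vmax),
      "cranfis_degenerate_column"
    )
  }
  structure(list(variable = variable, vmin = vmin, vmax = vmax),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf("<norm_params> %s: [%g, %g] -> [0, 1]\n", x$variable, x$vmin, x$vmax))
  invisible(x)
}

# Canonical model variables and the cohort CSV dialect.
MODEL_VARS <- c("ntprobnp", "na", "k", "ef", "epi_cysc")
INPUT_VARS <- c("ntprobnp", "na", "k")
CSV_COLS <- c(id = "id", ntprobnp = "ntprobnp_pg_ml", na = "na_mmol_l",
              k = "k_mmol_l", ef = "ef_pct", epi_cysc = "epi_cysc_ml_min",
              age = "age_y", sex = "sex")

#' Frozen normalization bounds from the published cohort ranges
#'
#' The study normalized every variable by its observed cohort minimum and
#' maximum. Those extremes are printed (NT-proBNP 10-5000 pg/mL,
#' Na+ 123-150 mmol/L, K+ 2.4-7.8 mmol/L, EF 12-75 %, cystatin-C GFR
#' 14-146 mL/min/1.73 m^2), so the default pipeline freezes them: the
#' normalized risk thresholds (0.20, 0.44, 0.58, ...) are then reproducible
#' regardless of which sample is in hand. Use [fit_minmax()] instead to
#' refit bounds from a cohort.
#'
#' @return Named list of [norm_params()] for the five model variables.
#' @export
default_norm_params <- function() {
  list(
    ntprobnp = norm_params(10, 5000, "ntprobnp"),
    na       = norm_params(123, 150, "na"),
    k        = norm_params(2.4, 7.8, "k"),
    ef       = norm_params(12, 75, "ef"),
    epi_cysc = norm_params(14, 146, "epi_cysc")
  )
}

#' Fit min-max bounds from a cohort column
#'
#' @param cohort A cohort table (see [read_cohort()] / [generate_cohort()]).
#' @param variable Column name (canonical: `ntprobnp`, `na`, `k`, `ef`,
#'   `epi_cysc`).
#' @return A [norm_params()] whose bounds are the column extremes.
#' @export
fit_minmax <- function(cohort, variable) {
  if (!variable %in% names(cohort)) {
    stop_cranfis(sprintf("variable '%s' not present in cohort", variable),
                 "cranfis_missing_variable")
  }
  x <- cohort[[variable]]
  x <- x[is.finite(x)]
  if (length(x) < 2L || min(x) == max(x)) {
    stop_cranfis(
      sprintf("cannot fit min-max bounds for '%s': column is degenerate (fewer than two distinct values)",
              variable),
      "cranfis_degenerate_column"
    )
  }
  norm_params(min(x), max(x), variable)
}

#' Map a physical value to the unit interval
#'
#' @param x Value(s) in physical units.
#' @param params A [norm_params()].
#' @param clamp If `TRUE` (default), out-of-range values map to 0 or 1 with
#'   a warning; if `FALSE`, they raise an error. A deployed score must not
#'   crash on a new extreme value, hence the clamping default.
#' @return Normalized value(s) in `[0, 1]`.
#' @export
normalize_value <- function(x, params, clamp = TRUE) {
  stopifnot(inherits(params, "norm_params"))
  if (any(!is.finite(x))) {
    stop_cranfis(sprintf("non-finite value passed to normalize for '%s'",
                         params$variable),
                 "cranfis_nonfinite")
  }
  u <- (x - params$vmin) / (params$vmax - params$vmin)
  oob <- u < 0 | u > 1
  if (any(oob)) {
    if (!clamp) {
      stop_cranfis(
        sprintf("%d value(s) of '%s' outside [%g, %g] and clamp = FALSE",
                sum(oob), params$variable, params$vmin, params$vmax),
        "cranfis_out_of_range"
      )
    }
    warn_cranfis(
      sprintf("clamped %d out-of-range value(s) of '%s' to [0, 1]",
              sum(oob), params$variable),
      "cranfis_clamped"
    )
    u <- clip01(u)
  }
  u
}

#' Map a normalized value back to physical units
#'
#' Exact inverse of [normalize_value()] on `[vmin, vmax]`.
#'
#' @param u Normalized value(s).
#' @inheritParams normalize_value
#' @return Value(s) in physical units.
#' @export
denormalize_value <- function(u, params) {
  stopifnot(inherits(params, "norm_params"))
  if (any(!is.finite(u))) {
    stop_cranfis("non-finite normalized value", "cranfis_nonfinite")
  }
  params$vmin + u * (params$vmax - params$vmin)
}

#' Normalized position of a clinical reference limit
#'
#' Projects a reference limit (e.g. the K+ lower reference value of
#' 3.5 mmol/L) onto the normalized scale and reports it at the 2-decimal
#' precision used for the published band edges. Rounding is half-up.
#'
#' @param ref_limit Reference limit in physical units.
#' @inheritParams normalize_value
#' @return Normalized threshold, rounded half-up to 2 decimals.
#' @export
reference_band_normalized <- function(ref_limit, params) {
  stopifnot(inherits(params, "norm_params"))
  u <- (ref_limit - params$vmin) / (params$vmax - params$vmin)
  if (u < 0 || u > 1) {
    warn_cranfis(
      sprintf("reference limit %g for '%s' outside [%g, %g]; clamped",
              ref_limit, params$variable, params$vmin, params$vmax),
      "cranfis_clamped"
    )
    u <- clip01(u)
  }
  round_half_up(u, 2)
}
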