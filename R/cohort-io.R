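#' Cohort tables
#'
#' A cohort table is a data frame with one row per subject and the
#' canonical columns `id`, `ntprobnp` (pg/mL), `na` (mmol/L), `k` (mmol/L),
#' `ef` (%), `epi_cysc` (mL/min/1.73 m^2), plus optional `age` (years) and
#' `sex` (`"male"`/`"female"`). Provenance (synthetic seed or file path) is
#' carried in attributes.
#'
#' @param df Data frame with the canonical columns.
#' @param provenance `"synthetic"` or `"file"`.
#' @param seed Generator seed (synthetic cohorts).
#' @param path Source path (file cohorts).
#' @return A `cohort_table`.
#' @export
as_cohort <- function(df, provenance = "file", seed = NULL, path = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(MODEL_VARS, names(df))
  if (length(missing_cols)) {
    stop_cranfis(sprintf("cohort lacks model variable(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "cranfis_missing_variable")
  }
  if (nrow(df) == 0L) {
    stop_cranfis("cohort is empty", "cranfis_empty_cohort")
  }
  for (v in MODEL_VARS) {
    x <- df[[v]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop_cranfis(sprintf("cohort column '%s' has missing or non-numeric values", v),
                   "cranfis_invalid_cohort")
    }
    if (any(x <= 0)) {
      stop_cranfis(sprintf("cohort column '%s' must be strictly positive", v),
                   "cranfis_invalid_cohort")
    }
  }
  if (any(df$ef > 100)) {
    stop_cranfis("ejection fraction must lie in (0, 100]", "cranfis_invalid_cohort")
  }
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  structure(df, class = c("cohort_table", "data.frame"),
            provenance = provenance, seed = seed, path = path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%s%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown",
              if (!is.null(attr(x, "seed"))) sprintf(", seed %d", attr(x, "seed")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort CSV
#'
#' Expects the header
#' `id,ntprobnp_pg_ml,na_mmol_l,k_mmol_l,ef_pct,epi_cysc_ml_min,age_y,sex`
#' (decimal point, UTF-8, one row per subject); `age_y` and `sex` may be
#' absent.
#'
#' @param path CSV path.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_cranfis(sprintf("cohort file not found: %s", path), "cranfis_missing_file")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- CSV_COLS[MODEL_VARS]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_cranfis(sprintf("cohort CSV %s lacks column(s): %s", path,
                         paste(missing_cols, collapse = ", ")),
                 "cranfis_invalid_cohort")
  }
  present <- CSV_COLS[CSV_COLS %in% names(raw)]
  df <- raw[, present, drop = FALSE]
  names(df) <- names(present)
  as_cohort(df, provenance = "file", path = path)
}

#' Write a cohort CSV
#'
#' Numeric columns are written at full double precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  cols <- CSV_COLS[names(CSV_COLS) %in% names(df)]
  out <- df[, names(cols), drop = FALSE]
  for (v in names(out)) {
    if (is.numeric(out[[v]])) out[[v]] <- fmt_full(out[[v]])
  }
  names(out) <- unname(cols)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
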