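#' Normalized risk bands and thresholds
#'
#' The published surface analysis reads clinical state off the normalized
#' scale: electrolyte stability bands (K+ 0.20-0.60, Na+ 0.44-1.00),
#' NT-proBNP band 0.30-0.60, an EF threshold of 0.5 separating serious
#' adverse events from at-risk patients, and a GFR threshold of 0.58 below
#' which renal failure is indicated. Boundary conventions: "below" is
#' strict (`<`), band membership is inclusive (`[lo, hi]`).
#'
#' @param k_band,na_band,bnp_band Length-2 normalized bands.
#' @param ef_threshold,epi_threshold Normalized output thresholds in
#'   `(0, 1)`.
#' @return An object of class `risk_bands`.
#' @export
risk_bands <- function(k_band = c(0.20, 0.60), na_band = c(0.44, 1.00),
                       bnp_band = c(0.30, 0.60),
                       ef_threshold = 0.50, epi_threshold = 0.58) {
  for (b in list(k_band, na_band, bnp_band)) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop_cranfis("each band must be an increasing pair", "cranfis_invalid_bands")
    }
  }
  for (th in c(ef_threshold, epi_threshold)) {
    if (th <= 0 || th >= 1) {
      stop_cranfis("thresholds must lie in (0, 1)", "cranfis_invalid_bands")
    }
  }
  structure(list(k_band = k_band, na_band = na_band, bnp_band = bnp_band,
                 ef_threshold = ef_threshold, epi_threshold = epi_threshold),
            class = "risk_bands")
}

#' Response surface over two predictors
#'
#' Predicted normalized output over a regular grid of two normalized
#' predictors with the third held fixed - the object behind the published
#' three-dimensional interdependence panels.
#'
#' @param model An `anfis_model`.
#' @param var_x,var_y Distinct predictor names (`ntprobnp`, `na`, `k`).
#' @param fixed_value Normalized value of the remaining predictor
#'   (default 0.5).
#' @param grid_n Grid points per axis (`>= 2`).
#' @return An object of class `surface_grid`: grids, the `z` matrix
#'   (`grid_n x grid_n`, rows follow `x`), and the fixed variable.
#' @export
response_surface <- function(model, var_x, var_y, fixed_value = 0.5, grid_n = 41L) {
  vars <- INPUT_VARS
  if (!var_x %in% vars || !var_y %in% vars) {
    stop_cranfis(sprintf("unknown predictor; choose two of: %s",
                         paste(vars, collapse = ", ")),
                 "cranfis_missing_variable")
  }
  if (var_x == var_y) stop_cranfis("var_x and var_y must differ", "cranfis_invalid_spec")
  if (grid_n < 2L) stop_cranfis("grid_n must be at least 2", "cranfis_invalid_spec")
  fixed_var <- setdiff(vars, c(var_x, var_y))
  g <- seq(0, 1, length.out = grid_n)
  nodes <- expand.grid(x = g, y = g)
  X <- matrix(fixed_value, nrow(nodes), 3L, dimnames = list(NULL, vars))
  X[, var_x] <- nodes$x; X[, var_y] <- nodes$y
  y <- anfis_forward(model, X)$y_norm
  structure(list(var_x = var_x, var_y = var_y, fixed_var = fixed_var,
                 fixed_value = fixed_value, x_grid = g, y_grid = g,
                 z = matrix(y, grid_n, grid_n),
                 output_name = model$output_name,
                 out_params = model$norm_params[[model$output_name]]),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %s over %s x %s (%s fixed at %.2f), %dx%d nodes, z in [%.3f, %.3f]\n",
              x$output_name, x$var_x, x$var_y, x$fixed_var, x$fixed_value,
              length(x$x_grid), length(x$y_grid), min(x$z), max(x$z)))
  invisible(x)
}

#' All six published surface panels
#'
#' EF and GFR each against the three predictor pairs, matching the
#' published panel layout (a)-(f).
#'
#' @param model_ef,model_epi Trained models for the two outputs.
#' @param fixed_value Normalized value for the held-out predictor.
#' @param grid_n Grid points per axis.
#' @return Named list of six [response_surface()] grids.
#' @export
surface_panels <- function(model_ef, model_epi, fixed_value = 0.5, grid_n = 41L) {
  pairs <- list(c("ntprobnp", "k"), c("ntprobnp", "na"), c("na", "k"))
  out <- list()
  for (m in list(model_ef, model_epi)) {
    for (p in pairs) {
      s <- response_surface(m, p[1], p[2], fixed_value, grid_n)
      out[[sprintf("%s_%s_%s", m$output_name, p[1], p[2])]] <- s
    }
  }
  out
}

#' Export a surface grid as long-format CSV
#'
#' Columns: `var_x,var_y,fixed_var,fixed_value,x,y,z_norm,z_physical`.
#'
#' @param surface A `surface_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  nodes <- expand.grid(x = surface$x_grid, y = surface$y_grid)
  z <- as.vector(surface$z)
  df <- data.frame(var_x = surface$var_x, var_y = surface$var_y,
                   fixed_var = surface$fixed_var,
                   fixed_value = fmt_full(surface$fixed_value),
                   x = fmt_full(nodes$x), y = fmt_full(nodes$y),
                   z_norm = fmt_full(z),
                   z_physical = fmt_full(denormalize_value(clip01(z), surface$out_params)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Heat-map of a response surface
#'
#' @param x A `surface_grid`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.surface_grid <- function(x, ...) {
  graphics::image(x$x_grid, x$y_grid, x$z, xlab = x$var_x, ylab = x$var_y,
                  main = sprintf("%s (%s = %.2f)", x$output_name, x$fixed_var,
                                 x$fixed_value), ...)
  invisible(x)
}

# One subject's classification row.
classify_one <- function(bnp_n, na_n, k_n, ef_pred, epi_pred, bands) {
  ef_n <- ef_pred$y_norm; epi_n <- epi_pred$y_norm
  list(
    ef_norm = ef_n, ef_pred = ef_pred$y_physical,
    epi_norm = epi_n, epi_pred = epi_pred$y_physical,
    cardiac_class = if (ef_n < bands$ef_threshold) "serious_adverse_event" else "at_risk",
    phenotype = if (ef_pred$y_physical < 40) "HFrEF" else "HFpEF_range",
    renal_class = if (epi_n < bands$epi_threshold) "renal_failure" else "preserved",
    k_flag = if (k_n >= bands$k_band[1] && k_n <= bands$k_band[2]) "stable" else "unstable",
    na_flag = if (na_n >= bands$na_band[1] && na_n <= bands$na_band[2]) "stable" else "unstable",
    bnp_flag = if (bnp_n >= bands$bnp_band[1] && bnp_n <= bands$bnp_band[2]) "in_band" else "out_of_band"
  )
}

#' Classify one patient against the risk bands
#'
#' Predicts EF and GFR for the record and applies the band rules: EF
#' below the threshold flags a serious adverse event (otherwise at risk);
#' a predicted EF under 40% labels the HFrEF phenotype; GFR below its
#' threshold flags renal failure; each electrolyte is stable exactly when
#' its normalized value lies inside its band (inclusive).
#'
#' @param record One-row data frame (or list) with `ntprobnp`, `na`, `k`
#'   in physical units.
#' @param model_ef,model_epi Trained models for the two outputs; they must
#'   share input normalization.
#' @param bands A [risk_bands()].
#' @return One-row data frame of predictions, classes and flags.
#' @export
classify_patient <- function(record, model_ef, model_epi, bands = risk_bands()) {
  for (v in INPUT_VARS) {
    a <- model_ef$norm_params[[v]]; b <- model_epi$norm_params[[v]]
    if (abs(a$vmin - b$vmin) > 1e-12 || abs(a$vmax - b$vmax) > 1e-12) {
      stop_cranfis(sprintf("models disagree on '%s' normalization", v),
                   "cranfis_invalid_model")
    }
  }
  x <- vapply(INPUT_VARS, function(v) {
    normalize_value(record[[v]], model_ef$norm_params[[v]], clamp = TRUE)
  }, numeric(1))
  row <- classify_one(x["ntprobnp"], x["na"], x["k"],
                      predict_norm(model_ef, x), predict_norm(model_epi, x),
                      bands)
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Risk report for a whole cohort
#'
#' One classification row per subject plus class counts per axis.
#'
#' @param cohort A `cohort_table`.
#' @param model_ef,model_epi Trained models for the two outputs.
#' @param bands A [risk_bands()].
#' @return A list of class `risk_report`: `table` (data frame, one row
#'   per subject, keyed by `id`), `counts` (list of per-axis tallies) and
#'   the `bands` used.
#' @export
batch_report <- function(cohort, model_ef, model_epi, bands = risk_bands()) {
  if (nrow(cohort) == 0L) stop_cranfis("cohort is empty", "cranfis_empty_cohort")
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    classify_patient(cohort[i, ], model_ef, model_epi, bands)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(id = cohort$id, tab)
  counts <- list(
    cardiac = table(factor(tab$cardiac_class,
                           levels = c("serious_adverse_event", "at_risk"))),
    phenotype = table(factor(tab$phenotype, levels = c("HFrEF", "HFpEF_range"))),
    renal = table(factor(tab$renal_class, levels = c("renal_failure", "preserved"))),
    k = table(factor(tab$k_flag, levels = c("stable", "unstable"))),
    na = table(factor(tab$na_flag, levels = c("stable", "unstable"))),
    bnp = table(factor(tab$bnp_flag, levels = c("in_band", "out_of_band")))
  )
  structure(list(table = tab, counts = counts, bands = bands),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> %d subjects\n", nrow(x$table)))
  for (nm in names(x$counts)) {
    tally <- paste(sprintf("%s=%d", names(x$counts[[nm]]), as.integer(x$counts[[nm]])),
                   collapse = ", ")
    cat(sprintf("  %-9s %s\n", nm, tally))
  }
  invisible(x)
}

#' Export a risk report (CSV table + JSON summary)
#'
#' @param report A `risk_report`.
#' @param csv_path Per-patient table destination.
#' @param json_path Optional destination for the class counts and bands.
#' @return `csv_path`, invisibly.
#' @export
write_risk_report <- function(report, csv_path, json_path = NULL) {
  tab <- report$table
  for (v in names(tab)) if (is.numeric(tab[[v]]) && v != "id") tab[[v]] <- fmt_full(tab[[v]])
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(counts = lapply(report$counts, function(t) as.list(stats::setNames(as.integer(t), names(t)))),
           bands = unclass(report$bands)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
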