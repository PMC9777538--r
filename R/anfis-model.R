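#' Trapezoidal membership function
#'
#' Membership is 0 left of `a`, rises linearly on `[a, b]`, is 1 on
#' `[b, c]`, falls linearly on `[c, d]` and is 0 right of `d`. Degenerate
#' edges (`a == b` or `c == d`) are legal and evaluate as step edges with
#' the plateau value at the breakpoint itself.
#'
#' @param a,b,c,d Breakpoints on the normalized scale, `a <= b <= c <= d`.
#' @param label Linguistic label, conventionally `"low"`, `"normal"`,
#'   `"high"`.
#' @return An object of class `trapezoid_mf`.
#' @export
trapezoid_mf <- function(a, b, c, d, label = "mf") {
  bp <- c(a, b, c, d)
  if (any(!is.finite(bp))) {
    stop_cranfis("trapezoid breakpoints must be finite", "cranfis_invalid_mf")
  }
  if (is.unsorted(bp)) {
    stop_cranfis(
      sprintf("trapezoid breakpoints for '%s' must satisfy a <= b <= c <= d (got %s)",
              label, paste(signif(bp, 6), collapse = ", ")),
      "cranfis_invalid_mf"
    )
  }
  structure(list(a = a, b = b, c = c, d = d, label = label),
            class = "trapezoid_mf")
}

#' Evaluate a trapezoidal membership function
#'
#' @param x Crisp value(s) on the normalized scale.
#' @param mf A [trapezoid_mf()].
#' @return Membership degree(s) in `[0, 1]`.
#' @export
trapezoid_membership <- function(x, mf) {
  stopifnot(inherits(mf, "trapezoid_mf"))
  if (any(!is.finite(x))) {
    stop_cranfis("non-finite input to membership function", "cranfis_nonfinite")
  }
  rise <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$a)
  fall <- if (mf$d > mf$c) (mf$d - x) / (mf$d - mf$c) else as.numeric(x <= mf$d)
  clip01(pmin(rise, fall))
}

#' Default normalized risk-band edges
#'
#' The published analysis reads three bands off the normalized response
#' surfaces: K+ 0.20-0.60, Na+ 0.44-1.00, NT-proBNP 0.30-0.60. The K+ and
#' Na+ lower edges coincide with the laboratory reference limits
#' (3.5 mmol/L and 135 mmol/L) mapped through the frozen cohort ranges;
#' the remaining edges do not derive exactly from any stated reference
#' value, so all six are kept as configurable constants defaulting to the
#' printed figures.
#'
#' @return Named list of length-2 numeric vectors (normalized units).
#' @export
default_band_edges <- function() {
  list(ntprobnp = c(0.30, 0.60), na = c(0.44, 1.00), k = c(0.20, 0.60))
}

# Ruspini trapezoid triple (low/normal/high) for one input: transition
# ramps of half-width `shoulder` centred on the two band edges, clipped to
# [0, 1]. Memberships sum to 1 everywhere on [0, 1] by construction.
ruspini_triple <- function(edges, shoulder) {
  if (length(edges) != 2L || edges[1] >= edges[2]) {
    stop_cranfis("band edges must be an increasing pair", "cranfis_invalid_mf")
  }
  if (edges[1] + shoulder > edges[2] - shoulder) {
    stop_cranfis("band edges overlap at this shoulder width", "cranfis_invalid_mf")
  }
  t1 <- max(edges[1] - shoulder, 0); t2 <- min(edges[1] + shoulder, 1)
  t3 <- max(edges[2] - shoulder, 0); t4 <- min(edges[2] + shoulder, 1)
  list(
    trapezoid_mf(0, 0, t1, t2, "low"),
    trapezoid_mf(t1, t2, t3, t4, "normal"),
    trapezoid_mf(t3, t4, 1, 1, "high")
  )
}

#' Build the default 27-rule Takagi-Sugeno ANFIS
#'
#' Each of the three inputs (NT-proBNP, Na+, K+) is stratified into
#' low/normal/high by a Ruspini partition of trapezoids centred on the
#' normalized reference-band edges; the rule base is the full Cartesian
#' product (3^3 = 27 rules) in lexicographic antecedent order, with
#' first-order consequents `V = c1*x1 + c2*x2 + c3*x3` initialized to
#' coefficients (1/3, 1/3, 1/3).
#'
#' @param output `"ef"` or `"epi_cysc"` - the single output variable.
#' @param bands Normalized band edges per input, see [default_band_edges()].
#' @param shoulder Transition half-width in normalized units (default
#'   0.05); adjacent membership functions share a ramp of width
#'   `2 * shoulder`.
#' @param tnorm Fuzzy "and": `"product"` (default) or `"min"`.
#' @param norm Normalization parameters per variable, see
#'   [default_norm_params()].
#' @param bias If `TRUE`, rule consequents carry an intercept `c0`
#'   (initialized to 0). The published rule form has none.
#' @return An object of class `anfis_model`.
#' @export
build_default_model <- function(output = c("ef", "epi_cysc"),
                                bands = default_band_edges(),
                                shoulder = 0.05,
                                tnorm = c("product", "min"),
                                norm = default_norm_params(),
                                bias = FALSE) {
  output <- match.arg(output)
  tnorm <- match.arg(tnorm)
  if (shoulder <= 0) {
    stop_cranfis("shoulder must be positive", "cranfis_invalid_mf")
  }
  for (v in INPUT_VARS) {
    e <- bands[[v]]
    if (is.null(e) || any(e < 0) || any(e > 1)) {
      stop_cranfis(sprintf("band edges for '%s' must lie in [0, 1]", v),
                   "cranfis_invalid_mf")
    }
  }
  mfs <- lapply(INPUT_VARS, function(v) ruspini_triple(bands[[v]], shoulder))
  names(mfs) <- INPUT_VARS
  ant <- as.matrix(expand.grid(k = 1:3, j = 1:3, i = 1:3)[, 3:1])
  colnames(ant) <- c("i", "j", "k")
  rules <- lapply(seq_len(27L), function(l) {
    list(antecedent = unname(ant[l, ]),
         coeffs = rep(1 / 3, 3),
         bias = if (bias) 0 else NULL)
  })
  model <- structure(
    list(input_mfs = mfs, rules = rules, output_name = output,
         norm_params = norm[c(INPUT_VARS, output)], tnorm = tnorm,
         bias = bias),
    class = "anfis_model"
  )
  validate_model(model)
  model
}

#' Validate an ANFIS model object
#'
#' Checks the structural invariants: exactly 27 rules covering every
#' antecedent combination once, ordered trapezoid breakpoints, finite
#' coefficients, and input coverage (every normalized value has positive
#' maximum membership).
#'
#' @param model An `anfis_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "anfis_model")) {
    stop_cranfis("not an anfis_model", "cranfis_invalid_model")
  }
  if (length(model$rules) != 27L) {
    stop_cranfis(sprintf("rule base must contain exactly 27 rules, found %d",
                         length(model$rules)),
                 "cranfis_invalid_model")
  }
  ant <- t(vapply(model$rules, function(r) as.integer(r$antecedent), integer(3)))
  if (any(ant < 1L | ant > 3L)) {
    stop_cranfis("rule antecedent indices must lie in {1, 2, 3}",
                 "cranfis_invalid_model")
  }
  key <- ant %*% c(9L, 3L, 1L)
  if (anyDuplicated(key)) {
    stop_cranfis("every antecedent combination must appear exactly once",
                 "cranfis_invalid_model")
  }
  for (r in model$rules) {
    if (any(!is.finite(r$coeffs)) || length(r$coeffs) != 3L) {
      stop_cranfis("rule coefficients must be three finite numbers",
                   "cranfis_invalid_model")
    }
    if (!is.null(r$bias) && !is.finite(r$bias)) {
      stop_cranfis("rule bias must be finite", "cranfis_invalid_model")
    }
  }
  grid <- seq(0, 1, length.out = 101L)
  for (v in INPUT_VARS) {
    triple <- model$input_mfs[[v]]
    if (length(triple) != 3L) {
      stop_cranfis(sprintf("input '%s' must carry three membership functions", v),
                   "cranfis_invalid_model")
    }
    for (mf in triple) {
      stopifnot(inherits(mf, "trapezoid_mf"))
    }
    cover <- Reduce(pmax, lapply(triple, function(mf) trapezoid_membership(grid, mf)))
    if (any(cover <= 0)) {
      stop_cranfis(sprintf("membership functions for '%s' leave part of [0, 1] uncovered", v),
                   "cranfis_invalid_model")
    }
  }
  invisible(model)
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("<anfis_model> output: %s | 27 Takagi-Sugeno rules | t-norm: %s%s\n",
              x$output_name, x$tnorm, if (x$bias) " | bias term" else ""))
  for (v in INPUT_VARS) {
    bp <- vapply(x$input_mfs[[v]], function(m) sprintf("%s(%.3g,%.3g,%.3g,%.3g)",
                                                       m$label, m$a, m$b, m$c, m$d), "")
    cat(sprintf("  %-9s %s\n", v, paste(bp, collapse = " ")))
  }
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L

#' Serialize an ANFIS model to JSON
#'
#' The file embeds the normalization parameters, so a saved model predicts
#' in physical units without any companion file.
#'
#' @param model An `anfis_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    output_name = model$output_name,
    tnorm = model$tnorm,
    bias = model$bias,
    inputs = lapply(INPUT_VARS, function(v) {
      np <- model$norm_params[[v]]
      list(name = v, vmin = np$vmin, vmax = np$vmax,
           mfs = lapply(model$input_mfs[[v]], function(m) {
             list(label = m$label, a = m$a, b = m$b, c = m$c, d = m$d)
           }))
    }),
    output = list(name = model$output_name,
                  vmin = model$norm_params[[model$output_name]]$vmin,
                  vmax = model$norm_params[[model$output_name]]$vmax),
    rules = lapply(model$rules, function(r) {
      list(antecedent = as.integer(r$antecedent), coeffs = r$coeffs,
           bias = r$bias)
    })
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly,
  # so load(save(m)) predicts bit-identically to m
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load an ANFIS model from JSON
#'
#' @param path Path to a file written by [save_model()].
#' @return An `anfis_model`; schema or invariant violations raise a
#'   descriptive error.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_cranfis(sprintf("model file not found: %s", path), "cranfis_missing_file")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("schema_version", "output_name", "tnorm", "inputs", "output", "rules")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop_cranfis(sprintf("model JSON %s lacks field(s): %s", path,
                         paste(miss, collapse = ", ")),
                 "cranfis_schema_error")
  }
  if (obj$schema_version != MODEL_SCHEMA_VERSION) {
    stop_cranfis(sprintf("unsupported model schema version %s", obj$schema_version),
                 "cranfis_schema_error")
  }
  if (length(obj$rules) != 27L) {
    stop_cranfis(sprintf("model JSON carries %d rules; 27 required", length(obj$rules)),
                 "cranfis_schema_error")
  }
  mfs <- list(); np <- list()
  for (inp in obj$inputs) {
    mfs[[inp$name]] <- lapply(inp$mfs, function(m) {
      trapezoid_mf(m$a, m$b, m$c, m$d, m$label)
    })
    np[[inp$name]] <- norm_params(inp$vmin, inp$vmax, inp$name)
  }
  np[[obj$output_name]] <- norm_params(obj$output$vmin, obj$output$vmax,
                                       obj$output_name)
  rules <- lapply(obj$rules, function(r) {
    list(antecedent = as.integer(unlist(r$antecedent)),
         coeffs = as.numeric(unlist(r$coeffs)),
         bias = if (is.null(r$bias)) NULL else as.numeric(r$bias))
  })
  model <- structure(
    list(input_mfs = mfs, rules = rules, output_name = obj$output_name,
         norm_params = np, tnorm = obj$tnorm,
         bias = isTRUE(obj$bias)),
    class = "anfis_model"
  )
  validate_model(model)
  model
}
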