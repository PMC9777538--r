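# Forward pass of the five-layer ANFIS: fuzzification, rule firing,
# strength normalization, consequent evaluation, weighted summation.

# Membership matrices per input: list of n x 3 matrices, one per variable.
membership_matrices <- function(model, X) {
  lapply(INPUT_VARS, function(v) {
    idx <- match(v, INPUT_VARS)
    m <- vapply(model$input_mfs[[v]],
                function(mf) trapezoid_membership(X[, idx], mf),
                numeric(nrow(X)))
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
    m
  })
}

rule_antecedents <- function(model) {
  t(vapply(model$rules, function(r) as.integer(r$antecedent), integer(3)))
}

rule_coefficients <- function(model) {
  t(vapply(model$rules, function(r) as.numeric(r$coeffs), numeric(3)))
}

rule_biases <- function(model) {
  vapply(model$rules, function(r) if (is.null(r$bias)) 0 else r$bias, numeric(1))
}

#' Rule firing strengths
#'
#' Layer-2 output: for each of the 27 rules, the fuzzy conjunction of the
#' three antecedent membership degrees (product t-norm by default, minimum
#' if the model says so).
#'
#' @param x_norm Length-3 vector of normalized inputs (NT-proBNP, Na+, K+),
#'   or an `n x 3` matrix.
#' @param model An `anfis_model`.
#' @return Length-27 vector (or `n x 27` matrix) of strengths `w >= 0`, in
#'   the model's rule order.
#' @export
firing_strengths <- function(x_norm, model) {
  X <- if (is.matrix(x_norm)) x_norm else matrix(x_norm, nrow = 1L)
  stopifnot(ncol(X) == 3L)
  M <- membership_matrices(model, X)
  ant <- rule_antecedents(model)
  W <- matrix(0, nrow(X), 27L)
  for (l in seq_len(27L)) {
    m1 <- M[[1]][, ant[l, 1]]; m2 <- M[[2]][, ant[l, 2]]; m3 <- M[[3]][, ant[l, 3]]
    W[, l] <- if (model$tnorm == "min") pmin(m1, m2, m3) else m1 * m2 * m3
  }
  if (is.matrix(x_norm)) W else drop(W)
}

#' Normalize firing strengths
#'
#' Layer-3 output: each rule's share of the total strength,
#' `wbar_l = w_l / sum(w)`; the shares sum to 1.
#'
#' @param w Length-27 vector (or `n x 27` matrix) of non-negative
#'   strengths.
#' @return Normalized strengths of the same shape.
#' @export
normalize_strengths <- function(w) {
  W <- if (is.matrix(w)) w else matrix(w, nrow = 1L)
  if (any(W < 0)) {
    stop_cranfis("firing strengths must be non-negative", "cranfis_invalid_strengths")
  }
  s <- rowSums(W)
  if (any(s == 0)) {
    stop_cranfis(
      "uncovered input: all 27 rule strengths are zero (membership functions do not cover this point)",
      "cranfis_uncovered_input"
    )
  }
  out <- W / s
  if (is.matrix(w)) out else drop(out)
}

#' Rule consequent value
#'
#' First-order Takagi-Sugeno consequent
#' `V = c1*x1 + c2*x2 + c3*x3 (+ c0)`, evaluated on the crisp normalized
#' inputs.
#'
#' @param x_norm Length-3 vector of normalized inputs.
#' @param rule One rule of an `anfis_model` (list with `coeffs` and
#'   optional `bias`).
#' @return Scalar consequent value.
#' @export
rule_consequent <- function(x_norm, rule) {
  stopifnot(length(x_norm) == 3L)
  v <- sum(rule$coeffs * x_norm)
  if (!is.null(rule$bias)) v <- v + rule$bias
  v
}

# Core vectorized forward pass on an n x 3 normalized matrix.
anfis_forward <- function(model, X) {
  W <- firing_strengths(X, model)
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  Wbar <- normalize_strengths(W)
  if (!is.matrix(Wbar)) Wbar <- matrix(Wbar, nrow = 1L)
  V <- X %*% t(rule_coefficients(model))
  b <- rule_biases(model)
  if (any(b != 0)) V <- sweep(V, 2L, b, `+`)
  y <- rowSums(Wbar * V)
  list(y_norm = y, wbar = Wbar, w = W, V = V)
}

#' Predict from normalized inputs
#'
#' Runs the five-layer forward pass at one normalized input triple and
#' returns the full prediction object, including the 27 normalized rule
#' activations.
#'
#' @param model An `anfis_model`.
#' @param x_norm Length-3 vector `(ntprobnp, na, k)` on the normalized
#'   scale.
#' @return A list of class `anfis_prediction`: `y_norm`, `y_physical`
#'   (via the embedded output normalization) and `rule_activations`.
#' @export
predict_norm <- function(model, x_norm) {
  stopifnot(length(x_norm) == 3L)
  fw <- anfis_forward(model, matrix(x_norm, nrow = 1L))
  out_np <- model$norm_params[[model$output_name]]
  structure(
    list(y_norm = fw$y_norm[1L],
         y_physical = denormalize_value(clip01(fw$y_norm[1L]), out_np),
         rule_activations = drop(fw$wbar)),
    class = "anfis_prediction"
  )
}

#' @export
print.anfis_prediction <- function(x, ...) {
  cat(sprintf("<anfis_prediction> y_norm = %.4f, y_physical = %.2f (top rule %d at %.2f)\n",
              x$y_norm, x$y_physical, which.max(x$rule_activations),
              max(x$rule_activations)))
  invisible(x)
}

#' Predict for a cohort in physical units
#'
#' Normalizes the predictor columns with the model's embedded parameters
#' (clamping out-of-range values with a warning), runs the forward pass
#' and denormalizes the output.
#'
#' @param object An `anfis_model`.
#' @param newdata A `cohort_table` or data frame with columns `ntprobnp`,
#'   `na`, `k` in physical units.
#' @param ... Unused.
#' @return Data frame with `y_norm` and `y_physical` (one row per
#'   subject).
#' @export
predict.anfis_model <- function(object, newdata, ...) {
  X <- normalize_inputs(object, newdata)
  fw <- anfis_forward(object, X)
  out_np <- object$norm_params[[object$output_name]]
  data.frame(y_norm = fw$y_norm,
             y_physical = denormalize_value(clip01(fw$y_norm), out_np))
}

# n x 3 normalized predictor matrix from a physical-units table.
normalize_inputs <- function(model, data) {
  miss <- setdiff(INPUT_VARS, names(data))
  if (length(miss)) {
    stop_cranfis(sprintf("data lacks predictor column(s): %s",
                         paste(miss, collapse = ", ")),
                 "cranfis_missing_variable")
  }
  X <- sapply(INPUT_VARS, function(v) {
    normalize_value(data[[v]], model$norm_params[[v]], clamp = TRUE)
  })
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L, dimnames = list(NULL, INPUT_VARS))
  X
}

# Normalized output column of a cohort, using the model's output params.
normalize_target <- function(model, cohort) {
  normalize_value(cohort[[model$output_name]],
                  model$norm_params[[model$output_name]], clamp = TRUE)
}
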