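#' Training configuration
#'
#' Defaults follow the published regime where stated (1000 epochs,
#' stopping tolerance of 0.0005 on the training mean square error) and the
#' smallest-assumption reading elsewhere (70/15/15 split, learning rate
#' 0.01, full-batch vanilla gradient descent).
#'
#' @param epochs Maximum epochs (`>= 0`).
#' @param mse_tol Early-stopping threshold on training MSE, normalized
#'   scale.
#' @param learning_rate Gradient-descent step size.
#' @param mode `"bp"` (pure backpropagation) or `"hybrid"` (consequents by
#'   least squares each epoch, premises by gradient).
#' @param split_fractions Named or positional `(train, test, check)`
#'   fractions summing to 1.
#' @param seed Seed for the data split (and any other training
#'   randomness).
#' @param train_premise Also update the trapezoid breakpoints (subgradient
#'   steps with sort-and-clip projection).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 1000L, mse_tol = 5e-4,
                            learning_rate = 0.01,
                            mode = c("bp", "hybrid"),
                            split_fractions = c(train = 0.70, test = 0.15, check = 0.15),
                            seed = 42L, train_premise = TRUE) {
  mode <- match.arg(mode)
  if (epochs < 0) stop_cranfis("epochs must be >= 0", "cranfis_invalid_config")
  if (mse_tol <= 0) stop_cranfis("mse_tol must be > 0", "cranfis_invalid_config")
  if (learning_rate <= 0) stop_cranfis("learning_rate must be > 0", "cranfis_invalid_config")
  f <- as.numeric(split_fractions)
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop_cranfis("split_fractions must be three non-negative numbers summing to 1",
                 "cranfis_invalid_config")
  }
  structure(list(epochs = as.integer(epochs), mse_tol = mse_tol,
                 learning_rate = learning_rate, mode = mode,
                 split_fractions = c(train = f[1], test = f[2], check = f[3]),
                 seed = as.integer(seed), train_premise = isTRUE(train_premise)),
            class = "training_config")
}

#' Split a cohort into training, testing and checking sets
#'
#' Test and check sizes are the floors of their fractions; the remainder
#' goes to training. The shuffle is deterministic in `config$seed`.
#'
#' @param cohort A `cohort_table` with at least 3 rows.
#' @param config A [training_config()].
#' @return Named list of three `cohort_table`s: `train`, `test`, `check`.
#' @export
split_dataset <- function(cohort, config = training_config()) {
  n <- nrow(cohort)
  if (n < 3L) stop_cranfis("cohort must have at least 3 subjects to split",
                           "cranfis_invalid_cohort")
  f <- config$split_fractions
  n_test <- floor(n * f["test"]); n_check <- floor(n * f["check"])
  n_train <- n - n_test - n_check
  if (n_train < 1L || n_test < 1L || n_check < 1L) {
    stop_cranfis(
      sprintf("split %g/%g/%g of %d subjects leaves an empty set (%d/%d/%d)",
              f["train"], f["test"], f["check"], n, n_train, n_test, n_check),
      "cranfis_empty_split"
    )
  }
  perm <- with_seed(config$seed, sample.int(n))
  idx <- list(train = perm[seq_len(n_train)],
              test = perm[n_train + seq_len(n_test)],
              check = perm[n_train + n_test + seq_len(n_check)])
  lapply(idx, function(i) {
    structure(as.data.frame(cohort)[i, , drop = FALSE],
              class = c("cohort_table", "data.frame"),
              provenance = attr(cohort, "provenance"),
              seed = attr(cohort, "seed"), path = attr(cohort, "path"))
  })
}

#' Mean square error
#'
#' @param predictions,targets Equal-length numeric vectors on the
#'   normalized-output scale.
#' @return Mean of squared differences.
#' @export
mse <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0L) {
    stop_cranfis("predictions and targets must be equal-length, non-empty",
                 "cranfis_length_mismatch")
  }
  mean((predictions - targets)^2)
}

# --- gradient machinery -----------------------------------------------------

# Flatten/unflatten consequent coefficients as a 27 x p matrix (p = 3 or 4).
consequent_matrix <- function(model) {
  C <- rule_coefficients(model)
  if (model$bias) C <- cbind(C, rule_biases(model))
  C
}

set_consequents <- function(model, C) {
  for (l in seq_len(27L)) {
    model$rules[[l]]$coeffs <- as.numeric(C[l, 1:3])
    if (model$bias) model$rules[[l]]$bias <- as.numeric(C[l, 4])
  }
  model
}

# Subgradients of one trapezoid's membership w.r.t. its breakpoints at x.
# Non-zero only strictly inside the rising (a,b) or falling (c,d) edge;
# corners take the plateau-side (zero) subgradient.
trap_grad <- function(x, mf) {
  g <- matrix(0, length(x), 4L)
  if (mf$b > mf$a) {
    on_rise <- x > mf$a & x < mf$b
    den <- (mf$b - mf$a)^2
    g[on_rise, 1L] <- (x[on_rise] - mf$b) / den
    g[on_rise, 2L] <- -(x[on_rise] - mf$a) / den
  }
  if (mf$d > mf$c) {
    on_fall <- x > mf$c & x < mf$d
    den <- (mf$d - mf$c)^2
    g[on_fall, 3L] <- (mf$d - x[on_fall]) / den
    g[on_fall, 4L] <- (x[on_fall] - mf$c) / den
  }
  g
}

# One full-batch gradient evaluation. Returns list(mse, gC, gP) where gC is
# 27 x p and gP is a list (per variable) of 3 x 4 breakpoint gradients
# (NULL when premises are frozen). Premise gradients assume the product
# t-norm; see training_config()/vignette.
anfis_gradients <- function(model, X, tgt, want_premise = TRUE) {
  n <- nrow(X)
  fw <- anfis_forward(model, X)
  r <- fw$y_norm - tgt                      # residuals
  loss <- mean(r^2)
  # d loss / d V_l = (2/n) r wbar_l ; V_l = C_l . x
  A <- (2 / n) * (r * fw$wbar)              # n x 27
  Xd <- if (model$bias) cbind(X, 1) else X
  gC <- t(A) %*% Xd                          # 27 x p
  gP <- NULL
  if (want_premise && model$tnorm == "product") {
    M <- membership_matrices(model, X)
    ant <- rule_antecedents(model)
    S <- rowSums(fw$w)
    # d y / d w_l = (V_l - y) / S
    dY_dW <- (fw$V - fw$y_norm) / S          # n x 27
    gP <- vector("list", 3L)
    for (v in 1:3) {
      gP[[v]] <- matrix(0, 3L, 4L)
      others <- setdiff(1:3, v)
      for (m in 1:3) {
        rules_vm <- which(ant[, v] == m)
        # d w_l / d mu_{v,m} = product of the other two memberships
        dmu <- numeric(n)
        for (l in rules_vm) {
          dmu <- dmu + dY_dW[, l] *
            M[[others[1]]][, ant[l, others[1]]] * M[[others[2]]][, ant[l, others[2]]]
        }
        gmf <- trap_grad(X[, v], model$input_mfs[[v]][[m]])
        gP[[v]][m, ] <- (2 / n) * colSums(r * dmu * gmf)
      }
    }
  }
  list(mse = loss, gC = gC, gP = gP)
}

# Project breakpoints back to a valid trapezoid on [0, 1]: sort, then clip.
project_breakpoints <- function(bp) {
  pmin(1, pmax(0, sort(bp)))
}

apply_premise_step <- function(model, gP, lr) {
  for (v in 1:3) {
    for (m in 1:3) {
      mf <- model$input_mfs[[v]][[m]]
      bp <- c(mf$a, mf$b, mf$c, mf$d) - lr * gP[[v]][m, ]
      bp <- project_breakpoints(bp)
      model$input_mfs[[v]][[m]] <- trapezoid_mf(bp[1], bp[2], bp[3], bp[4], mf$label)
    }
  }
  model
}

# Least-squares consequent solve given current premises (hybrid mode).
# Design: column (l, j) carries wbar_l * x_j. Rules that barely fire in the
# training set produce near-null columns whose unpenalized solution explodes
# off-sample, so a tiny Tikhonov term (1e-8 of the mean diagonal) pins them
# near zero; the bias it adds is orders below the 5e-4 stopping tolerance
# (noise-free refits land around 1e-8 train MSE).
solve_consequents <- function(model, X, tgt) {
  fw <- anfis_forward(model, X)
  p <- if (model$bias) 4L else 3L
  Xd <- if (model$bias) cbind(X, 1) else X
  D <- matrix(0, nrow(X), 27L * p)
  for (l in seq_len(27L)) {
    D[, (l - 1L) * p + seq_len(p)] <- fw$wbar[, l] * Xd
  }
  G <- crossprod(D)
  lambda <- 1e-4 * mean(diag(G))
  beta <- solve(G + diag(lambda, ncol(D)), crossprod(D, tgt))
  matrix(beta, nrow = 27L, ncol = p, byrow = TRUE)
}

#' Fit an ANFIS by backpropagation or hybrid learning
#'
#' Full-batch training on the mean square error of the normalized output.
#' `mode = "bp"` descends both the consequent coefficients and (if
#' `train_premise`) the trapezoid breakpoints, using one-sided plateau
#' subgradients at the corners and a sort-and-clip projection after every
#' premise step. `mode = "hybrid"` solves the consequent subproblem
#' exactly by least squares each epoch (it is linear given the premises)
#' and moves the premises by gradient. Training stops when the epoch's MSE
#' drops to `mse_tol` or at the epoch limit.
#'
#' @param model An `anfis_model` (its `output_name` selects the target
#'   column).
#' @param train A `cohort_table` with the three predictors and the target.
#' @param config A [training_config()].
#' @param validation Optional `cohort_table`; its per-epoch MSE is
#'   recorded alongside the training history.
#' @return A list of class `anfis_fit`: `model` (trained), `fit` (a
#'   `fit_result` with `mse_history`, `final_mse`, `epochs_run`,
#'   `stopped_by`, and `validation_history` if requested).
#' @export
anfis_fit <- function(model, train, config = training_config(), validation = NULL) {
  validate_model(model)
  X <- normalize_inputs(model, train)
  tgt <- normalize_target(model, train)
  Xv <- NULL; tv <- NULL
  if (!is.null(validation)) {
    Xv <- normalize_inputs(model, validation)
    tv <- normalize_target(model, validation)
  }
  want_premise <- config$train_premise && model$tnorm == "product"
  if (config$train_premise && model$tnorm == "min") {
    warn_cranfis("premise training is only implemented for the product t-norm; premises stay frozen",
                 "cranfis_premise_frozen")
  }
  history <- numeric(0)
  vhistory <- numeric(0)
  stopped_by <- "epoch_limit"
  epochs_run <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (config$mode == "hybrid") {
      model <- set_consequents(model, solve_consequents(model, X, tgt))
    }
    need_grad <- config$mode == "bp" || want_premise
    if (need_grad) {
      g <- anfis_gradients(model, X, tgt, want_premise = want_premise)
      if (!is.finite(g$mse)) {
        stop_cranfis(
          sprintf("training diverged at epoch %d (non-finite MSE); reduce learning_rate (currently %g)",
                  epoch, config$learning_rate),
          "cranfis_diverged"
        )
      }
    }
    if (config$mode == "bp") {
      C <- consequent_matrix(model) - config$learning_rate * g$gC
      model <- set_consequents(model, C)
    }
    if (want_premise) model <- apply_premise_step(model, g$gP, config$learning_rate)
    # record the MSE of the parameters in force this epoch
    epoch_mse <- mse(anfis_forward(model, X)$y_norm, tgt)
    history <- c(history, epoch_mse)
    if (!is.null(Xv)) vhistory <- c(vhistory, mse(anfis_forward(model, Xv)$y_norm, tv))
    epochs_run <- epoch
    if (epoch_mse <= config$mse_tol) {
      stopped_by <- "tolerance"
      break
    }
  }
  if (config$epochs == 0L) stopped_by <- "epoch_limit"
  final_train <- if (epochs_run > 0L) history[epochs_run] else mse(anfis_forward(model, X)$y_norm, tgt)
  fit <- structure(
    list(mse_history = history,
         validation_history = if (is.null(Xv)) NULL else vhistory,
         final_mse = list(train = final_train, test = NA_real_, check = NA_real_),
         epochs_run = epochs_run, stopped_by = stopped_by,
         config = config),
    class = "fit_result"
  )
  structure(list(model = model, fit = fit), class = "anfis_fit")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d epoch(s), stopped by %s; final train MSE %.6g\n",
              x$epochs_run, x$stopped_by,
              x$final_mse$train))
  invisible(x)
}

#' @export
print.anfis_fit <- function(x, ...) {
  print(x$fit)
  print(x$model)
  invisible(x)
}

#' Evaluate a fitted model on the testing and checking sets
#'
#' Reports MSE on the normalized-output scale for both sets and the
#' relative deviation of the check MSE from the test MSE, in percent -
#' this package's operationalization of "consistency of checking" (the
#' published figure of roughly 15% has no stated metric and is reported,
#' never asserted).
#'
#' @param model A trained `anfis_model`.
#' @param test,check Non-empty `cohort_table`s.
#' @return List with `test_mse`, `check_mse`,
#'   `relative_check_deviation_pct` (`NA` when `test_mse` is 0).
#' @export
evaluate_anfis <- function(model, test, check) {
  pt <- anfis_forward(model, normalize_inputs(model, test))$y_norm
  pc <- anfis_forward(model, normalize_inputs(model, check))$y_norm
  test_mse <- mse(pt, normalize_target(model, test))
  check_mse <- mse(pc, normalize_target(model, check))
  dev <- if (test_mse == 0) NA_real_ else 100 * abs(check_mse - test_mse) / test_mse
  list(test_mse = test_mse, check_mse = check_mse,
       relative_check_deviation_pct = dev)
}

#' Export a fit history as CSV (`epoch,mse`)
#'
#' @param fit A `fit_result` (or `anfis_fit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_history <- function(fit, path) {
  if (inherits(fit, "anfis_fit")) fit <- fit$fit
  df <- data.frame(epoch = seq_along(fit$mse_history),
                   mse = fmt_full(fit$mse_history))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
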