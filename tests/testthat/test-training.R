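test_that("the three-way split is exhaustive, disjoint and seed-deterministic", {
  co <- quiet_generate(cohort_spec(n = 90, seed = 21))
  cfg <- training_config(seed = 5)
  sets <- split_dataset(co, cfg)
  expect_identical(vapply(sets, nrow, 1L), c(train = 64L, test = 13L, check = 13L))
  ids <- sort(unname(unlist(lapply(sets, `[[`, "id"))))
  expect_identical(ids, sort(co$id))
  sets2 <- split_dataset(co, cfg)
  expect_identical(lapply(sets, `[[`, "id"), lapply(sets2, `[[`, "id"))
  sets3 <- split_dataset(co, training_config(seed = 6))
  expect_false(identical(sets$train$id, sets3$train$id))
  expect_error(split_dataset(co, training_config(split_fractions = c(1, 0, 0))),
               class = "cranfis_empty_split")
})

test_that("mse matches the brute-force definition", {
  expect_identical(mse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_identical(mse(c(0, 1), c(1, 0)), 1)
  p <- cranfis:::with_seed(22, stats::runif(50))
  t <- cranfis:::with_seed(23, stats::runif(50))
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - t[i])^2
  expect_equal(mse(p, t), acc / 50, tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), class = "cranfis_length_mismatch")
})

test_that("zero epochs leave the model untouched with an empty history", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 30, seed = 24)
  out <- anfis_fit(build_default_model("ef"), co, training_config(epochs = 0))
  expect_identical(out$model$rules, build_default_model("ef")$rules)
  expect_length(out$fit$mse_history, 0L)
  expect_identical(out$fit$epochs_run, 0L)
})

test_that("backprop drives a single training point to its target", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 30, seed = 25)[1, , drop = FALSE]
  cfg <- training_config(epochs = 3000, learning_rate = 0.3, mode = "bp",
                         train_premise = FALSE, mse_tol = 1e-12)
  out <- anfis_fit(build_default_model("ef"), co, cfg)
  pred <- predict(out$model, co)$y_norm
  tgt <- normalize_value(co$ef, out$model$norm_params$ef)
  expect_lt(abs(pred - tgt), 1e-3)
})

test_that("hybrid consequents solve the (regularized) normal equations exactly", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 20, seed = 26, noise_sd = 0.05)
  model <- build_default_model("ef")
  cfg <- training_config(epochs = 1, mode = "hybrid", train_premise = FALSE)
  out <- anfis_fit(model, co, cfg)
  # independent oracle: assemble the design matrix from memberships alone
  X <- cranfis:::normalize_inputs(model, co)
  tgt <- normalize_value(co$ef, model$norm_params$ef)
  ant <- t(sapply(model$rules, `[[`, "antecedent"))
  D <- matrix(0, 20, 81)
  for (r in 1:20) {
    w <- vapply(seq_len(27L), function(l) {
      prod(vapply(1:3, function(v) {
        trapezoid_membership(X[r, v], model$input_mfs[[v]][[ant[l, v]]])
      }, numeric(1)))
    }, numeric(1))
    wbar <- w / sum(w)
    for (l in seq_len(27L)) D[r, (l - 1) * 3 + 1:3] <- wbar[l] * X[r, ]
  }
  G <- crossprod(D)
  beta <- solve(G + diag(1e-4 * mean(diag(G)), 81), crossprod(D, tgt))
  C_oracle <- matrix(beta, 27, 3, byrow = TRUE)
  C_fit <- t(sapply(out$model$rules, `[[`, "coeffs"))
  expect_equal(C_fit, C_oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("frozen-premise backprop has a non-increasing loss at lr 0.01", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 60, seed = 27, noise_sd = 0.02)
  cfg <- training_config(epochs = 120, learning_rate = 0.01, mode = "bp",
                         train_premise = FALSE, mse_tol = 1e-12)
  out <- anfis_fit(build_default_model("ef"), co, cfg)
  expect_true(all(diff(out$fit$mse_history) <= 1e-12))
})

test_that("fit results are bit-identical under identical config and data", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 40, seed = 28, noise_sd = 0.05)
  cfg <- training_config(epochs = 25, mode = "bp")
  a <- anfis_fit(build_default_model("ef"), co, cfg)
  b <- anfis_fit(build_default_model("ef"), co, cfg)
  expect_identical(a$fit$mse_history, b$fit$mse_history)
  expect_identical(a$model, b$model)
})

test_that("stopping rule: tolerance reached implies last MSE below it", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 80, seed = 29)   # noise-free
  cfg <- training_config(epochs = 1000, mode = "hybrid", train_premise = FALSE)
  out <- anfis_fit(build_default_model("ef"), co, cfg)
  expect_identical(out$fit$stopped_by, "tolerance")
  expect_lte(out$fit$final_mse$train, cfg$mse_tol)
  expect_length(out$fit$mse_history, out$fit$epochs_run)
})

test_that("premise training moves breakpoints but keeps them valid", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 60, seed = 30, noise_sd = 0.02)
  start <- build_default_model("ef")
  # perturb the start so premise gradients are non-trivial
  cfg <- training_config(epochs = 40, learning_rate = 0.05, mode = "bp",
                         train_premise = TRUE, mse_tol = 1e-12)
  out <- anfis_fit(start, co, cfg)
  moved <- FALSE
  for (v in 1:3) for (m in 1:3) {
    mf0 <- start$input_mfs[[v]][[m]]; mf1 <- out$model$input_mfs[[v]][[m]]
    bp <- c(mf1$a, mf1$b, mf1$c, mf1$d)
    expect_false(is.unsorted(bp))
    expect_true(all(bp >= 0 & bp <= 1))
    if (any(abs(bp - c(mf0$a, mf0$b, mf0$c, mf0$d)) > 1e-9)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("training aborts with guidance when the loss diverges", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 30, seed = 31, noise_sd = 0.05)
  cfg <- training_config(epochs = 2000, learning_rate = 1e8, mode = "bp",
                         train_premise = FALSE, mse_tol = 1e-12)
  err <- expect_error(anfis_fit(build_default_model("ef"), co, cfg),
                      class = "cranfis_diverged")
  expect_match(conditionMessage(err), "learning_rate")
})

test_that("evaluate reports MSEs and the relative check deviation", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 40, seed = 32, noise_sd = 0.05)
  half <- co[1:20, ]
  ev_same <- evaluate_anfis(ref, half, half)
  expect_identical(ev_same$relative_check_deviation_pct, 0)
  noise_free <- make_model_cohort(ref, n = 40, seed = 33)
  ev_near <- evaluate_anfis(ref, noise_free[1:20, ], noise_free[21:40, ])
  expect_lt(ev_near$test_mse, 1e-20)
  expect_lt(ev_near$check_mse, 1e-20)
  # an exactly-zero test MSE (targets at the output minimum, all-zero
  # consequents) makes the relative deviation undefined
  zero_model <- make_constant_model(0, "ef")
  co0 <- make_model_cohort(ref, n = 10, seed = 35)
  co0$ef <- rep(12, 10)   # normalizes to exactly 0
  ev0 <- evaluate_anfis(zero_model, co0, co0)
  expect_identical(ev0$test_mse, 0)
  expect_true(is.na(ev0$relative_check_deviation_pct))
  # smoke: deviation on a realistic synthetic split is finite and recorded
  cfg <- training_config(epochs = 50, mode = "hybrid", train_premise = FALSE)
  co90 <- quiet_generate(cohort_spec(n = 90, seed = 42))
  sets <- split_dataset(co90, cfg)
  fitd <- anfis_fit(build_default_model("ef"), sets$train, cfg)
  ev <- evaluate_anfis(fitd$model, sets$test, sets$check)
  expect_true(is.finite(ev$relative_check_deviation_pct))
})

test_that("fit history exports as epoch,mse CSV", {
  ref <- make_reference_model()
  co <- make_model_cohort(ref, n = 30, seed = 34, noise_sd = 0.05)
  out <- anfis_fit(build_default_model("ef"), co,
                   training_config(epochs = 10, mode = "bp", train_premise = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_history(out, path)
  hist <- utils::read.csv(path)
  expect_identical(names(hist), c("epoch", "mse"))
  expect_equal(hist$mse, out$fit$mse_history, tolerance = 1e-15)
})
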