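# Shared fixtures: all built in code, no stored data.

# generate_cohort() warns (by design) that the printed NT-proBNP SD is not
# attainable in the truncated-lognormal family; tests that are not about
# that warning silence exactly that class.
quiet_generate <- function(spec) {
  withCallingHandlers(
    generate_cohort(spec),
    cranfis_calibration_gap = function(w) invokeRestart("muffleWarning")
  )
}

quiet_calibrate <- function(spec) {
  withCallingHandlers(
    calibrate_truncated(spec),
    cranfis_calibration_gap = function(w) invokeRestart("muffleWarning")
  )
}

# Reference ANFIS with known, in-range consequents: y_norm stays inside
# [0, 1] for any input because every coefficient lies in [0.05, 0.30].
make_reference_model <- function(output = "ef", seed = 7) {
  model <- build_default_model(output)
  cf <- cranfis:::with_seed(seed, matrix(stats::runif(81, 0.05, 0.30), 27, 3))
  for (l in seq_len(27L)) model$rules[[l]]$coeffs <- cf[l, ]
  model
}

# Cohort whose output column is generated by a reference model (+ optional
# Gaussian noise on the normalized scale), for parameter-recovery tests.
make_model_cohort <- function(ref, n = 200, seed = 11, noise_sd = 0) {
  co <- quiet_generate(cohort_spec(n = n, seed = seed))
  y <- predict(ref, co)$y_norm
  if (noise_sd > 0) {
    y <- y + cranfis:::with_seed(seed + 1L, stats::rnorm(n, 0, noise_sd))
  }
  out <- ref$output_name
  np <- ref$norm_params[[out]]
  co[[out]] <- pmin(np$vmax, pmax(np$vmin, denormalize_value(pmin(1, pmax(0, y)), np)))
  co
}

# Independent closed-form forward pass: one expression, no layers.
oracle_trap <- function(x, mf) {
  rise <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$a)
  fall <- if (mf$d > mf$c) (mf$d - x) / (mf$d - mf$c) else as.numeric(x <= mf$d)
  max(0, min(1, rise, fall))
}

oracle_predict <- function(model, x) {
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    w <- oracle_trap(x[1], model$input_mfs[[1]][[i]]) *
      oracle_trap(x[2], model$input_mfs[[2]][[j]]) *
      oracle_trap(x[3], model$input_mfs[[3]][[k]])
    rule <- Filter(function(r) all(r$antecedent == c(i, j, k)), model$rules)[[1]]
    v <- sum(rule$coeffs * x) + (if (is.null(rule$bias)) 0 else rule$bias)
    num <- num + w * v
    den <- den + w
  }
  num / den
}

# Constant-output model: every consequent returns `value` via the bias
# term, so y_norm == value everywhere.
make_constant_model <- function(value, output = "ef") {
  model <- build_default_model(output, bias = TRUE)
  for (l in seq_len(27L)) {
    model$rules[[l]]$coeffs <- c(0, 0, 0)
    model$rules[[l]]$bias <- value
  }
  model
}
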