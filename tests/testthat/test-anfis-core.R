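test_that("trapezoid membership follows the piecewise-linear definition", {
  mf <- trapezoid_mf(0.1, 0.3, 0.6, 0.9, "normal")
  expect_identical(trapezoid_membership(c(0.35, 0.6, 0.3), mf), c(1, 1, 1))
  expect_identical(trapezoid_membership(c(0, 0.1, 0.9, 1), mf), c(0, 0, 0, 0))
  expect_equal(trapezoid_membership(0.2, mf), 0.5)        # midpoint of rising edge
  expect_equal(trapezoid_membership(0.75, mf), 0.5)       # midpoint of falling edge
  # degenerate vertical edges evaluate to their plateau side
  step <- trapezoid_mf(0.4, 0.4, 0.7, 0.7, "step")
  expect_identical(trapezoid_membership(c(0.39, 0.4, 0.7, 0.71), step), c(0, 1, 1, 0))
  expect_error(trapezoid_mf(0.5, 0.4, 0.6, 0.7), class = "cranfis_invalid_mf")
  expect_error(trapezoid_membership(NA_real_, mf), class = "cranfis_nonfinite")
})

test_that("default model is a 27-rule Ruspini-partition ANFIS", {
  model <- build_default_model("ef")
  expect_length(model$rules, 27L)
  ant <- t(sapply(model$rules, `[[`, "antecedent"))
  expect_identical(nrow(unique(ant)), 27L)
  grid <- seq(0, 1, length.out = 200)
  for (v in c("ntprobnp", "na", "k")) {
    s <- Reduce(`+`, lapply(model$input_mfs[[v]],
                            function(mf) trapezoid_membership(grid, mf)))
    expect_equal(s, rep(1, 200), tolerance = 1e-12, label = v)
  }
  # normal-MF plateau sits shoulder-inside the published K+ band edges
  k_normal <- model$input_mfs$k[[2]]
  expect_equal(c(k_normal$b, k_normal$c), c(0.25, 0.55))
  expect_error(build_default_model(bands = list(ntprobnp = c(0.6, 0.3),
                                                na = c(0.44, 1), k = c(0.2, 0.6))),
               class = "cranfis_invalid_mf")
  expect_error(build_default_model(shoulder = -0.1), class = "cranfis_invalid_mf")
})

test_that("firing strengths match the brute-force t-norm", {
  model <- build_default_model("ef")
  # centre of all three "normal" plateaus: rule (2,2,2) fires alone
  x0 <- c(0.45, 0.7, 0.4)
  w <- firing_strengths(x0, model)
  ant <- t(sapply(model$rules, `[[`, "antecedent"))
  l222 <- which(apply(ant, 1, function(a) all(a == 2)))
  expect_equal(w[l222], 1)
  expect_equal(sum(w), 1)                      # Ruspini product partition
  # product t-norm equals the direct triple product on random inputs
  X <- cranfis:::with_seed(5, matrix(stats::runif(300), ncol = 3))
  W <- firing_strengths(X, model)
  for (r in c(1, 50, 100)) {
    for (l in seq_len(27L)) {
      mu <- vapply(1:3, function(v) {
        trapezoid_membership(X[r, v], model$input_mfs[[v]][[ant[l, v]]])
      }, numeric(1))
      expect_equal(W[r, l], prod(mu), tolerance = 1e-14)
    }
  }
  # min t-norm option
  mmin <- build_default_model("ef", tnorm = "min")
  Wmin <- firing_strengths(X, mmin)
  for (r in c(2, 40)) {
    for (l in seq_len(27L)) {
      mu <- vapply(1:3, function(v) {
        trapezoid_membership(X[r, v], mmin$input_mfs[[v]][[ant[l, v]]])
      }, numeric(1))
      expect_equal(Wmin[r, l], min(mu), tolerance = 1e-14)
    }
  }
})

test_that("strength normalization is element-wise division summing to one", {
  e1 <- c(1, rep(0, 26))
  expect_identical(normalize_strengths(e1), e1)
  expect_equal(normalize_strengths(rep(3, 27)), rep(1 / 27, 27))
  w <- cranfis:::with_seed(6, stats::runif(27, 0.01, 2))
  expect_equal(normalize_strengths(w), w / sum(w), tolerance = 1e-15)
  expect_error(normalize_strengths(rep(0, 27)), class = "cranfis_uncovered_input")
  expect_error(normalize_strengths(c(-1, rep(1, 26))), class = "cranfis_invalid_strengths")
})

test_that("rule consequents are dot products of the crisp inputs", {
  expect_identical(rule_consequent(c(0.2, 0.8, 0.5), list(coeffs = c(0, 0, 0))), 0)
  expect_identical(rule_consequent(c(0.3, 0.9, 0.1), list(coeffs = c(1, 0, 0))), 0.3)
  cf <- cranfis:::with_seed(8, stats::runif(3, -1, 1))
  x <- cranfis:::with_seed(9, stats::runif(3))
  expect_equal(rule_consequent(x, list(coeffs = cf)), sum(cf * x), tolerance = 1e-15)
  expect_equal(rule_consequent(x, list(coeffs = cf, bias = 0.2)),
               sum(cf * x) + 0.2, tolerance = 1e-15)
})

test_that("predict is a convex combination and matches the closed-form oracle", {
  const <- make_constant_model(0.37)
  for (x in list(c(0, 0, 0), c(1, 1, 1), c(0.2, 0.9, 0.44))) {
    expect_equal(predict_norm(const, x)$y_norm, 0.37, tolerance = 1e-12)
  }
  # one rule firing alone returns that rule's consequent
  ref <- make_reference_model()
  x0 <- c(0.45, 0.7, 0.4)
  ant <- t(sapply(ref$rules, `[[`, "antecedent"))
  l222 <- which(apply(ant, 1, function(a) all(a == 2)))
  expect_equal(predict_norm(ref, x0)$y_norm,
               sum(ref$rules[[l222]]$coeffs * x0), tolerance = 1e-12)
  # layered pass vs independent single-expression oracle
  X <- cranfis:::with_seed(10, matrix(stats::runif(750), ncol = 3))
  y <- cranfis:::anfis_forward(ref, X)$y_norm
  y_oracle <- apply(X, 1, function(x) oracle_predict(ref, x))
  expect_lt(max(abs(y - y_oracle)), 1e-10)
  # activations sum to one
  act <- predict_norm(ref, c(0.31, 0.62, 0.18))$rule_activations
  expect_equal(sum(act), 1, tolerance = 1e-9)
})

test_that("predictions are invariant to rule order and continuous in x", {
  ref <- make_reference_model()
  perm <- cranfis:::with_seed(11, sample(27))
  shuffled <- ref
  shuffled$rules <- ref$rules[perm]
  X <- cranfis:::with_seed(12, matrix(stats::runif(150), ncol = 3))
  expect_equal(cranfis:::anfis_forward(shuffled, X)$y_norm,
               cranfis:::anfis_forward(ref, X)$y_norm, tolerance = 1e-12)
  # Lipschitz bound on a fine grid along each axis
  max_slope <- 1 / (2 * 0.05)   # steepest ramp of the default partition
  L <- max(abs(unlist(lapply(ref$rules, `[[`, "coeffs")))) * (1 + max_slope) * 3
  h <- 1e-4
  for (v in 1:3) {
    x <- c(0.31, 0.62, 0.18)
    g <- seq(0, 1 - h, by = 0.01)
    for (gv in g) {
      x1 <- x; x1[v] <- gv
      x2 <- x; x2[v] <- gv + h
      dy <- abs(predict_norm(ref, x2)$y_norm - predict_norm(ref, x1)$y_norm)
      expect_lt(dy, L * h + 1e-12)
    }
  }
})

test_that("product and min t-norms agree exactly at pure plateau points", {
  prod_m <- make_reference_model()
  min_m <- prod_m
  min_m$tnorm <- "min"
  plateaus <- list(c(0.05, 0.2, 0.05), c(0.45, 0.7, 0.4), c(0.9, 0.99, 0.9))
  for (x in plateaus) {
    expect_equal(predict_norm(min_m, x)$y_norm, predict_norm(prod_m, x)$y_norm,
                 tolerance = 1e-12)
  }
})

test_that("model JSON round-trip is lossless and schema violations are caught", {
  ref <- make_reference_model("epi_cysc")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(ref, path)
  back <- load_model(path)
  X <- cranfis:::with_seed(13, matrix(stats::runif(150), ncol = 3))
  expect_identical(cranfis:::anfis_forward(back, X)$y_norm,
                   cranfis:::anfis_forward(ref, X)$y_norm)
  expect_identical(back$output_name, "epi_cysc")

  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj26 <- obj; obj26$rules <- obj$rules[-1]
  p26 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj26, p26, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(p26), class = "cranfis_schema_error")

  objbad <- obj; objbad$inputs[[1]]$mfs[[1]]$a <- 0.9   # breaks a <= b
  pbad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(objbad, pbad, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(pbad), class = "cranfis_invalid_mf")

  objmiss <- obj; objmiss$rules <- NULL
  pmiss <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(objmiss, pmiss, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(pmiss), class = "cranfis_schema_error")
})
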