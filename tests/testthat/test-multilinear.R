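# multilinear module: term enumeration, stepwise selection, survival
# filtering, CV protocol, term statistics.

test_that("enumerate_terms counts and canonical ordering", {
  expect_length(enumerate_terms(21), 1561L)
  expect_length(enumerate_terms(3), 7L)
  expect_equal(enumerate_terms(c("b", "a"), max_valency = 1), c("a", "b"))
  expect_equal(enumerate_terms(1, max_valency = 1), "m01")
  expect_error(enumerate_terms(0), class = "cv_invalid_argument")
  # canonicalisation is order-free
  expect_identical(enumerate_terms(c("x", "y", "z")),
                   enumerate_terms(c("z", "x", "y")))
  expect_equal(chromvalence:::canonical_terms("c*a*b"), "a*b*c")
})

test_that("build_design forms amplitude products", {
  A <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  X <- build_design(A, c("a", "a*b"))
  expect_equal(X[, "a"], A[, "a"], ignore_attr = TRUE)
  expect_equal(X[, "a*b"], A[, "a"] * A[, "b"], ignore_attr = TRUE)
  expect_error(build_design(A, "a*q"), class = "cv_invalid_argument")
})

test_that("stepwise_fit recovers a near-noiseless planted model exactly", {
  set.seed(5)
  A <- matrix(rlnorm(600), 200, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 3 * A[, "x1"]  # noiseless limit: RSS hits 0 after the true term
  fit <- stepwise_fit(build_design(A, c("x1", "x2")), y, c("x1", "x2"))
  expect_identical(fit$terms, "x1")
  expect_equal(unname(fit$beta["x1"]), 3, tolerance = 1e-9)
})

test_that("stepwise coefficients equal OLS when everything is forced in", {
  set.seed(6)
  A <- matrix(rlnorm(1500), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * A[, "a"] - 1.5 * A[, "c"] + rnorm(500, 0, 0.5)
  X <- build_design(A, c("a", "b", "c"))
  # alpha_remove = 1 keeps every initial term: oracle equivalence with lm
  fit <- stepwise_fit(X, y, colnames(X), initial_terms = colnames(X),
                      alpha_enter = 0, alpha_remove = 1)
  ref <- lm(y ~ A[, "a"] + A[, "b"] + A[, "c"])
  expect_equal(unname(fit$beta[c("(Intercept)", "a", "b", "c")]),
               unname(coef(ref)), tolerance = 1e-9)
  expect_equal(unname(fit$se[c("a", "b", "c")]),
               unname(summary(ref)$coefficients[2:4, 2]), tolerance = 1e-9)
})

test_that("stepwise false-inclusion rate under the null is near one term", {
  set.seed(7)
  incl <- vapply(1:40, function(i) {
    X <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, sprintf("n%02d", 1:20)))
    y <- rnorm(200)
    length(stepwise_fit(X, y, colnames(X))$terms)
  }, numeric(1))
  expect_gt(mean(incl), 0.2)  # per-term type-I error ~ 0.05 * 20 = 1
  expect_lt(mean(incl), 2.5)
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  set.seed(8)
  x <- rnorm(100)
  X <- cbind(a = x, b = 2 * x, c = rnorm(100))
  y <- x + rnorm(100, 0, 0.1)
  expect_warning(
    fit <- stepwise_fit(X, y, colnames(X), initial_terms = colnames(X),
                        alpha_remove = 1),
    "aliased")
  expect_lt(length(fit$terms), 3L)
})

test_that("round1_survival keeps dominant terms and filters null ones", {
  sc <- scenario_three_terms(n = 500, seed = 12)
  X <- build_design(sc$A, enumerate_terms(colnames(sc$A)))
  r1 <- round1_survival(X, sc$y, colnames(X), n_runs = 12, init_size = 15,
                        seed = 13)
  # always-significant terms survive every run; all planted terms survive
  expect_equal(unname(r1$rates["mk2*mk3"]), 1)
  expect_equal(unname(r1$rates["mk4*mk5*mk6"]), 1)
  expect_true(all(r1$rates[sc$planted] >= 0.9))
  expect_true(all(sc$planted %in% r1$surviving))
  expect_error(round1_survival(X, sc$y, n_runs = 1),
               class = "cv_invalid_argument")

  # survival filtering is monotone in the cutoff
  surv_hi <- names(r1$rates)[r1$rates >= 0.8]
  expect_true(all(surv_hi %in% r1$surviving))

  # null-only design: near-empty surviving set at cutoff 0.35
  set.seed(14)
  Xn <- matrix(rnorm(300 * 25), 300, 25,
               dimnames = list(NULL, sprintf("z%02d", 1:25)))
  yn <- rnorm(300)
  r1n <- round1_survival(Xn, yn, colnames(Xn), n_runs = 12, init_size = 8,
                         seed = 15)
  expect_lt(length(r1n$surviving), 3L)
})

test_that("cv_protocol: noiseless recovery, retention arithmetic, empty model", {
  set.seed(16)
  A <- matrix(rlnorm(2400), 800, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + 4 * A[, "a"] - 6 * A[, "b"] * A[, "c"] + rnorm(800, 0, 1e-7)
  terms <- enumerate_terms(colnames(A))
  X <- build_design(A, terms)
  m <- cv_protocol(X, y, terms, n_folds = 5, runs_per_fold = 2,
                   extra_random_terms = 4, retention = 3, seed = 17)
  expect_setequal(m$terms, c("a", "b*c"))
  expect_equal(unname(m$beta[c("(Intercept)", "a", "b*c")]), c(2, 4, -6),
               tolerance = 1e-5)
  # per-fold betas essentially identical in the noiseless limit
  expect_lt(max(apply(m$fold_beta, 2, sd)), 1e-5)
  # trimmed mean equals full OLS here
  ols <- coef(lm(y ~ A[, "a"] + I(A[, "b"] * A[, "c"])))
  expect_equal(unname(m$beta), unname(ols), tolerance = 1e-5)

  # impossible retention threshold -> explicit empty model
  expect_message(
    m0 <- cv_protocol(X, y, terms, n_folds = 5, runs_per_fold = 2,
                      extra_random_terms = 4, retention = 11, seed = 17),
    "empty")
  expect_true(m0$empty)
  expect_length(m0$terms, 0L)
  expect_equal(predict(m0, A), rep(mean(y), nrow(A)), tolerance = 1e-12)
})

test_that("canonicalisation: permuting mark columns leaves the fit unchanged", {
  sc <- scenario_three_terms(n = 400, seed = 18)
  terms <- enumerate_terms(colnames(sc$A))
  perm <- sc$A[, sample(ncol(sc$A))]
  X1 <- build_design(sc$A, terms)
  X2 <- build_design(perm, enumerate_terms(colnames(perm)))
  f1 <- stepwise_fit(X1, sc$y, colnames(X1))
  f2 <- stepwise_fit(X2, sc$y, colnames(X2))
  expect_setequal(f1$terms, f2$terms)
  expect_equal(f1$beta[sort(names(f1$beta))], f2$beta[sort(names(f2$beta))],
               tolerance = 1e-9)
})

test_that("term_statistics computes impact = beta x IQR and flags direction", {
  ds <- small_default_dataset(n = 1200, seed = 19)
  A <- ds$ground_truth$true_amplitudes
  y <- ds$ground_truth$expression
  terms <- enumerate_terms(colnames(A))
  X <- build_design(A, terms)
  m <- cv_protocol(X, y, terms, runs_per_fold = 3, extra_random_terms = 20,
                   seed = 20)
  st <- term_statistics(m, A)
  expect_equal(st$impact, st$beta * st$iqr, tolerance = 1e-12)
  expect_true(all(st$direction[st$beta < 0] == "repressing"))
  expect_false(is.unsorted(rev(st$impact)))
  # the confounded repressor: negative impact, strongly significant
  expect_true("repArg" %in% st$term)
  expect_lt(st$z[st$term == "repArg"], -3)
  expect_lt(st$impact[st$term == "repArg"], 0)
})
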