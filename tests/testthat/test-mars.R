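# mars module: hinge bases, forward/backward passes, GCV, reports.

test_that("hinge basics and the pair identity", {
  expect_equal(hinge(0.5, 0.3, 1), 0.2)
  expect_equal(hinge(0.3, 0.3, 1), 0)
  expect_equal(hinge(0.3, 0.3, -1), 0)
  x <- seq(-2, 2, by = 0.01)
  expect_equal(hinge(x, 0.4, 1) + hinge(x, 0.4, -1), abs(x - 0.4))
})

test_that("forward pass: constant response, exact hinge recovery, saturation", {
  set.seed(30)
  A <- cbind(x1 = runif(300), x2 = runif(300))

  m0 <- mars_forward(A, rep(3.5, 300))
  expect_length(m0$all_bases, 1L)
  expect_equal(unname(m0$coefficients[1]), 3.5)

  # exactly representable response with the knot among the data values
  xs <- sample(rep(seq(0, 1, by = 0.1), length.out = 300))
  A2 <- cbind(x1 = xs, x2 = runif(300))
  y2 <- 2 * pmax(0, A2[, "x1"] - 0.5)
  m2 <- fit_mars(A2, y2, max_knots = 50)
  expect_lt(m2$rss, 1e-10)
  knots <- unlist(lapply(m2$all_bases[lengths(m2$all_bases) > 0],
                         function(b) vapply(b, `[[`, numeric(1), "knot")))
  expect_true(0.5 %in% knots)

  # planted saturating response: fitted curve flat above the knot
  y3 <- pmin(A[, "x1"], 0.7) + rnorm(300, 0, 0.02)
  m3 <- fit_mars(A, y3, max_knots = 50)
  surf <- response_surface(m3, A, "x1", grid_size = 60)
  hi <- surf$prediction[surf$x1 > 0.8]
  expect_lt(max(hi) - min(hi), 0.1)
  expect_error(mars_forward(A, y3, max_terms = 0),
               class = "cv_invalid_argument")
})

test_that("GCV arithmetic and the backward pass", {
  expect_equal(chromvalence:::mars_gcv(100, 1000, 10),
               0.1 / 0.99^2, tolerance = 1e-12)
  expect_equal(chromvalence:::mars_gcv(1, 10, 10), Inf)

  # noiseless representable response: pruning keeps the full fit (RSS ~ 0)
  set.seed(31)
  xs <- sample(rep(seq(0, 1, by = 0.05), length.out = 200))
  A <- cbind(x1 = xs, x2 = runif(200))
  y <- 3 * pmax(0, A[, "x1"] - 0.4) - 2 * pmax(0, 0.4 - A[, "x1"])
  fwd <- mars_forward(A, y, max_knots = 50)
  prn <- mars_backward(fwd, A, y)
  expect_lt(prn$rss, 1e-9)
  expect_lte(prn$gcv, chromvalence:::mars_gcv(fwd$rss, fwd$n_obs,
    chromvalence:::mars_enp(fwd$all_bases, 3)))

  # pure noise: pruned to intercept-only in a clear majority of seeds
  intercept_only <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    An <- cbind(a = runif(150), b = runif(150), c = runif(150))
    yn <- rnorm(150)
    length(fit_mars(An, yn)$all_bases) == 1L
  }, logical(1))
  expect_gt(mean(intercept_only), 0.5)
})

test_that("hierarchy and degree constraints hold in the forward model", {
  ds <- small_default_dataset(n = 800, seed = 32)
  A <- ds$ground_truth$true_amplitudes
  # the hierarchy invariant concerns bases as created: test before pruning
  # (the reverse pass may legitimately delete a parent but keep its child)
  m <- mars_forward(A, ds$ground_truth$expression)
  bases <- m$all_bases[lengths(m$all_bases) > 0]
  sig <- function(b) paste(sort(vapply(b, function(f)
    paste(f$mark, f$knot, f$dir), "")), collapse = "|")
  # no repeated mark inside a basis; degree <= 3
  for (b in bases) {
    mks <- vapply(b, `[[`, "", "mark")
    expect_lte(length(mks), 3L)
    expect_equal(anyDuplicated(mks), 0L)
  }
  # every degree-d basis shares d-1 factors with an existing lower basis
  sigs1 <- vapply(bases, sig, "")
  for (b in bases[lengths(bases) > 1]) {
    parents <- combn(seq_along(b), length(b) - 1L,
                     function(i) sig(b[i]), simplify = TRUE)
    expect_true(any(parents %in% c("", sigs1)))
  }
})

test_that("prediction path is linear in the coefficients", {
  set.seed(33)
  A <- cbind(u = runif(100), v = runif(100))
  y <- sin(4 * A[, "u"]) + rnorm(100, 0, 0.1)
  m <- fit_mars(A, y)
  p1 <- predict(m, A)
  m2 <- m
  m2$coefficients <- 2 * m$coefficients
  expect_equal(predict(m2, A), 2 * p1)
})

test_that("mars_report: non-zero counts and percentile impacts", {
  set.seed(34)
  A <- cbind(up = runif(400), off = runif(400))
  # handcrafted model: intercept 1 + 2*h(up - 0.3); "off" appears nowhere
  m <- structure(list(
    all_bases = list(list(), list(list(mark = "up", knot = 0.3, dir = 1))),
    coefficients = c(1, 2)), class = "cv_mars")
  rep <- mars_report(m, A)
  expect_equal(rep$bases$n_nonzero, sum(A[, "up"] > 0.3))
  expect_equal(rep$bases$coefficient, 2)
  # mark absent from every basis has exactly zero impact
  expect_equal(rep$impact$impact[rep$impact$mark == "off"], 0)
  # monotone single-mark model: impact equals the curve rise between the
  # 5th and 95th percentile, and is positive
  imp <- rep$impact$impact[rep$impact$mark == "up"]
  expect_equal(imp, 2 * (pmax(0, quantile(A[, "up"], 0.95) - 0.3) -
                           pmax(0, quantile(A[, "up"], 0.05) - 0.3)),
               ignore_attr = TRUE)
  expect_gt(imp, 0)
  # basis with an unreachable knot is never active
  dead <- list(list(mark = "up", knot = -5, dir = -1))
  expect_equal(sum(chromvalence:::basis_values(dead, A) != 0), 0)
})

test_that("synergy tables and response surfaces are self-consistent", {
  set.seed(35)
  A <- cbind(p = runif(300), q = runif(300), r = runif(300))
  # additive model: no interaction -> synergy difference identical
  y_add <- 2 * A[, "p"] + 3 * A[, "q"] + rnorm(300, 0, 0.05)
  m_add <- fit_mars(A, y_add, max_degree = 1)
  syn <- synergy_table(m_add, A, c("p", "q"))
  hh <- syn$prediction[syn$p == "high" & syn$q == "high"]
  hl <- syn$prediction[syn$p == "high" & syn$q == "low"]
  lh <- syn$prediction[syn$p == "low" & syn$q == "high"]
  ll <- syn$prediction[syn$p == "low" & syn$q == "low"]
  expect_equal(hh - hl, lh - ll, tolerance = 1e-9)

  # planted positive interaction: high-high beats the additive expectation
  y_syn <- 4 * pmax(0, A[, "p"] - 0.3) * pmax(0, A[, "q"] - 0.3) +
    rnorm(300, 0, 0.02)
  m_syn <- fit_mars(A, y_syn)
  s2 <- synergy_table(m_syn, A, c("p", "q"))
  hh2 <- s2$prediction[s2$p == "high" & s2$q == "high"]
  add2 <- s2$prediction[s2$p == "high" & s2$q == "low"] +
    s2$prediction[s2$p == "low" & s2$q == "high"] -
    s2$prediction[s2$p == "low" & s2$q == "low"]
  expect_gt(hh2, add2 + 0.05)

  # surfaces agree with direct predictions; intercept-only model is flat
  surf <- response_surface(m_add, A, c("p", "q"), grid_size = 5)
  row <- matrix(apply(A, 2, median), 1, 3, dimnames = list(NULL, colnames(A)))
  row[, "p"] <- surf$p[7]; row[, "q"] <- surf$q[7]
  expect_equal(surf$prediction[7], predict(m_add, row))
  m_int <- fit_mars(A, rep(1.25, 300))
  flat <- response_surface(m_int, A, "p", grid_size = 10)
  expect_equal(flat$prediction, rep(1.25, 10))
  expect_error(response_surface(m_int, A, "p", grid_size = 1),
               class = "cv_invalid_argument")
})
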