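# synthetic_data module: gene models, templates, profiles, expression, and
# the confounded repressor's defining property.

test_that("make_gene_models validates input and honours alt_site_rate", {
  expect_error(make_gene_models(0), class = "cv_invalid_argument")

  gm <- make_gene_models(100, alt_site_rate = 0, seed = 3)
  expect_equal(nrow(gm), 100L)
  expect_true(all(lengths(gm$start_sites) == 1L))
  expect_true(all(lengths(gm$stop_sites) == 1L))
  expect_true(all(gm$end - gm$start >= 500))

  # binomial sampling check: fraction with >= 2 starts ~ 0.30 +/- 0.05
  gm2 <- make_gene_models(1000, alt_site_rate = 0.3, seed = 7)
  frac <- mean(lengths(gm2$start_sites) >= 2L)
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.35)

  # chosen sites are members of the candidate lists; bodies nonempty
  ok <- vapply(seq_len(nrow(gm2)), function(i)
    gm2$chosen_tss[i] %in% gm2$start_sites[[i]] &&
      gm2$chosen_tes[i] %in% gm2$stop_sites[[i]], logical(1))
  expect_true(all(ok))
  expect_true(all(abs(gm2$chosen_tes - gm2$chosen_tss) >= 1))

  # deterministic given seed
  expect_identical(make_gene_models(50, seed = 11)$start,
                   make_gene_models(50, seed = 11)$start)
})

test_that("make_true_template produces positive, mean-1 templates of every shape", {
  for (shape in c("tss_peak", "body_ramp_3prime", "body_uniform",
                  "bimodal_tss_tes")) {
    tpl <- make_true_template(mark_spec("m", shape), 200, 20)
    expect_length(tpl$values, 240L)
    expect_true(all(tpl$values > 0))
    expect_equal(mean(tpl$values), 1, tolerance = 1e-12)
  }
  uni <- make_true_template(mark_spec("u", "body_uniform"), 50, 0)
  expect_equal(uni$values, rep(1, 50))
  ramp <- make_true_template(mark_spec("r", "body_ramp_3prime"), 100, 10)
  body <- ramp$values[11:110]
  expect_gt(body[100], body[1])
  expect_error(mark_spec("x", "no_such_shape"))
})

test_that("simulate_profiles matches its model in both noise regimes", {
  gm <- make_gene_models(5, seed = 1)
  specs <- list(u = mark_spec("u", "body_uniform"))
  A <- matrix(2, 5, 1, dimnames = list(NULL, "u"))
  prof <- simulate_profiles(gm, specs, A, n_body_bins = 10, flank_bins = 0,
                            noise = "none", seed = 1)
  expect_equal(unname(prof$u), matrix(2, 5, 10))

  # noiseless profiles are exactly rank-1: amplitude x template
  specs2 <- default_mark_panel()
  gm2 <- make_gene_models(20, seed = 2)
  z <- chromvalence:::with_seed(5, rnorm(20))
  A2 <- true_amplitudes(specs2, z, seed = 5)
  p2 <- simulate_profiles(gm2, specs2, A2, n_body_bins = 60, flank_bins = 5,
                          noise = "none", seed = 1)
  tpl <- attr(p2, "templates")
  for (mk in names(specs2))
    expect_equal(p2[[mk]], outer(A2[, mk], tpl[[mk]]$values),
                 ignore_attr = TRUE, tolerance = 1e-12)

  # Poisson: mean near amplitude on a uniform template (3 sigma band),
  # and per-bin variance tracks the mean within 10%
  gm1 <- make_gene_models(1, seed = 1)
  A1 <- matrix(5, 1, 1, dimnames = list(NULL, "u"))
  pp <- simulate_profiles(gm1, specs, A1, n_body_bins = 8138, flank_bins = 0,
                          noise = "poisson", seed = 42)
  counts <- as.numeric(pp$u)
  expect_lt(abs(mean(counts) - 5), 0.25)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)

  # sub-1x coverage: most bins are empty
  Alow <- matrix(0.01, 1, 1, dimnames = list(NULL, "u"))
  plow <- simulate_profiles(gm1, specs, Alow, n_body_bins = 2000,
                            flank_bins = 0, noise = "poisson", seed = 3)
  expect_gt(mean(plow$u == 0), 0.95)

  # determinism + dimension validation
  expect_identical(
    simulate_profiles(gm, specs, A, 10, 0, noise = "poisson", seed = 9),
    simulate_profiles(gm, specs, A, 10, 0, noise = "poisson", seed = 9))
  expect_error(simulate_profiles(gm, specs, A[1:3, , drop = FALSE], 10, 0,
                                 seed = 1),
               class = "cv_invalid_argument")
})

test_that("simulate_expression composes planted terms as stated", {
  A <- matrix(runif(60, 0.5, 2), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y0 <- simulate_expression(A, list(), intercept = 7, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(y0), rep(7, 20))

  y1 <- simulate_expression(A, list(planted_term("a", 3)), 0, 0, seed = 1)
  expect_equal(cor(as.numeric(y1), A[, "a"]), 1)

  # hinge factor: 2 * h(a - 1)
  y2 <- simulate_expression(A, list(planted_term("a", 2, knots = 1)),
                            0, 0, seed = 1)
  expect_equal(as.numeric(y2), 2 * pmax(0, A[, "a"] - 1))

  expect_error(simulate_expression(A, list(planted_term("zz", 1)), 0, 0, 1),
               class = "cv_invalid_argument")
})

test_that("confounded repressor: invisible marginally, repressive multivariately", {
  n <- 5000
  z <- chromvalence:::with_seed(101, rnorm(n))
  R <- make_confounded_repressor(z, cancel_marginal = TRUE, seed = 102)
  a <- attr(R, "loading")
  # analytic root of rep_coef*a^2 - act_coef*a + rep_coef*noise_sd^2 = 0
  expect_equal(6 * a^2 - 4 * a + 6 * 0.3^2, 0, tolerance = 1e-12)

  A1 <- pmax(0.05, 3 + z + 0.5 * chromvalence:::with_seed(103, rnorm(n)))
  y <- 5 + 4 * A1 - 6 * as.numeric(R) +
    chromvalence:::with_seed(104, rnorm(n, 0, 2))

  # defining property: |Spearman| < 0.05 yet OLS coefficient negative, p<1e-3
  expect_lt(abs(cor(R, y, method = "spearman")), 0.05)
  fit <- summary(lm(y ~ A1 + R))$coefficients
  expect_lt(fit["R", "Estimate"], 0)
  expect_lt(fit["R", "Pr(>|t|)"], 1e-3)
  # OLS recovers the planted -6 within 15%
  expect_lt(abs(fit["R", "Estimate"] - (-6)) / 6, 0.15)

  # cancel_marginal = FALSE: no activity coupling, marginal corr tracks the
  # planted (negative) sign
  R0 <- make_confounded_repressor(z, cancel_marginal = FALSE, seed = 102)
  expect_equal(attr(R0, "loading"), 0)
  y0 <- 5 - 6 * as.numeric(R0) + chromvalence:::with_seed(105, rnorm(n, 0, 1))
  expect_lt(cor(R0, y0), -0.5)
})

test_that("simulate_dataset is reproducible and internally consistent", {
  d1 <- simulate_dataset(n_genes = 80, n_body_bins = 40, flank_bins = 4,
                         seed = 6)
  d2 <- simulate_dataset(n_genes = 80, n_body_bins = 40, flank_bins = 4,
                         seed = 6)
  expect_identical(d1$ground_truth$expression, d2$ground_truth$expression)
  expect_identical(d1$profiles, d2$profiles)

  gt <- d1$ground_truth
  # expression = signal + noise with the derived sd; counts are integers >= 0
  expect_equal(gt$expression, as.numeric(gt$signal +
    (gt$expression - gt$signal)))
  expect_true(all(vapply(d1$profiles, function(p)
    all(p >= 0 & p == round(p)), logical(1))))
  expect_true(all(gt$true_amplitudes > 0))
  # realised true R2 close to the 0.5 target
  r2 <- var(gt$signal) / var(gt$expression)
  expect_gt(r2, 0.35); expect_lt(r2, 0.65)
})

test_that("dataset writers emit readable plain-text files", {
  d <- simulate_dataset(n_genes = 15, n_body_bins = 20, flank_bins = 2,
                        seed = 9, multi_probe_rate = 0.3)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  gm <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(nrow(gm), 15L)
  expect_identical(gm$gene_id, d$gene_models$gene_id)
  profs <- read_profiles_dir(dir)
  expect_setequal(names(profs), names(d$mark_specs))
  expect_equal(unname(profs$actTSS), unname(d$profiles$actTSS))
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_true(nrow(expr) >= 15L)  # multi-probe rows included
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$rng_seed, 9L)
})

test_that("simulate_tags emits BED-consistent tag counts", {
  gm <- make_gene_models(2, length_distribution = list(meanlog = log(300),
                                                       sdlog = 0.1,
                                                       min_bp = 200),
                         alt_site_rate = 0, seed = 4)
  specs <- list(u = mark_spec("u", "body_uniform"))
  A <- matrix(c(3, 0.5), 2, 1, dimnames = list(NULL, "u"))
  tags <- simulate_tags(gm, specs, A, flank_bp = 50, seed = 8)
  expect_true(all(tags$u$end - tags$u$start == 1L))
  # expected total tags ~ A * n_positions per gene
  L <- gm$end - gm$start
  expected <- sum(A[, 1] * (L + 100))
  expect_lt(abs(nrow(tags$u) - expected) / expected, 0.15)
})
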