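#' Generate synthetic gene models
#'
#' Genes are laid end-to-end on a single synthetic chromosome with random
#' intergenic gaps, log-normal body lengths (default median ~8 kbp, matching
#' the median human gene length the scaled-bin layout is calibrated to) and
#' Bernoulli(0.5) strands. With probability `alt_site_rate` a gene receives an
#' additional internal alternative start site, and independently with the same
#' probability an alternative (body-shortening) stop site. Coordinates are
#' 0-based half-open (BED convention).
#'
#' @param n_genes number of genes (>= 1).
#' @param length_distribution list with `meanlog`, `sdlog`, `min_bp`.
#' @param alt_site_rate probability a gene carries >= 2 start (stop) sites.
#' @param seed integer seed; output is deterministic given the seed.
#' @return data.frame of class `cv_gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `chosen_tss`, `chosen_tes` and list
#'   columns `start_sites`, `stop_sites` (genomic coordinates).
#' @export
make_gene_models <- function(n_genes,
                             length_distribution = list(meanlog = log(8138),
                                                        sdlog = 0.8,
                                                        min_bp = 500),
                             alt_site_rate = 0.15,
                             seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_invalid("n_genes must be a positive count")
  ld <- length_distribution
  if ((ld$min_bp %||% 1) < 1) stop_invalid("min_bp must be >= 1")
  with_seed(seed, {
    n <- as.integer(n_genes)
    len <- pmax(ld$min_bp, round(rlnorm(n, ld$meanlog, ld$sdlog)))
    gap <- 2000L + round(runif(n, 0, 8000))
    start <- cumsum(c(1000, head(len + gap, -1L)))
    end <- start + len
    strand <- ifelse(runif(n) < 0.5, "+", "-")

    has_alt_start <- runif(n) < alt_site_rate
    has_alt_stop <- runif(n) < alt_site_rate
    # alternative TSS sits 10-50% into the body; alternative TES shortens the
    # body by 10-50% from the canonical stop
    alt_off_s <- round(len * runif(n, 0.1, 0.5))
    alt_off_e <- round(len * runif(n, 0.1, 0.5))

    tss <- ifelse(strand == "+", start, end)
    tes <- ifelse(strand == "+", end, start)
    dirn <- ifelse(strand == "+", 1L, -1L)
    start_sites <- lapply(seq_len(n), function(i) {
      s <- tss[i]
      if (has_alt_start[i]) s <- c(s, tss[i] + dirn[i] * alt_off_s[i])
      unique(s)
    })
    stop_sites <- lapply(seq_len(n), function(i) {
      s <- tes[i]
      if (has_alt_stop[i]) s <- c(s, tes[i] - dirn[i] * alt_off_e[i])
      unique(s)
    })
    gm <- data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                     chrom = "chrS", start = start, end = end,
                     strand = strand, chosen_tss = tss, chosen_tes = tes,
                     stringsAsFactors = FALSE)
    gm$start_sites <- start_sites
    gm$stop_sites <- stop_sites
    class(gm) <- c("cv_gene_models", "data.frame")
    gm
  })
}

#' @noRd
gene_body_length <- function(gm) abs(gm$chosen_tes - gm$chosen_tss)

#' Engineer a repressor whose marginal association with expression vanishes
#'
#' Returns per-gene amplitudes `R = shift + a * z + eta`,
#' `eta ~ Normal(0, noise_sd^2)`, for a mark planted in the expression model
#' with coefficient `-rep_coef` alongside an activity-coupled activator that
#' contributes `act_coef * (act_loading * z)` of activity-driven signal. With
#' `cancel_marginal = TRUE` the activity loading `a` solves
#'
#'   `rep_coef * a^2 - act_coef * act_loading * a + rep_coef * noise_sd^2 = 0`
#'
#' (larger root), which makes `Cov(R, Y) = a * act_coef * act_loading -
#' rep_coef * Var(R)` exactly zero: the mark is invisible in univariate
#' analysis yet conditionally repressive - the package's synthetic analogue of
#' an arginine-methylation mark that shows no marginal expression trend but is
#' strongly repressive multivariately.
#'
#' @param activity latent activity vector `z` (finite).
#' @param cancel_marginal if `FALSE`, `a = 0` (mark independent of drivers).
#' @param act_coef,act_loading expression coefficient and activity loading of
#'   the activator being cancelled against.
#' @param rep_coef magnitude of the mark's own (negative) planted coefficient.
#' @param noise_sd sd of the mark's idiosyncratic noise.
#' @param shift constitutive amplitude level (keeps values positive).
#' @param seed integer seed.
#' @return numeric amplitude vector (floored at 1e-3) with attribute
#'   `"loading"` = `a`.
#' @export
make_confounded_repressor <- function(activity, cancel_marginal = TRUE,
                                      act_coef = 4, act_loading = 1,
                                      rep_coef = 6, noise_sd = 0.3,
                                      shift = 2, seed = 1L) {
  if (!all(is.finite(activity))) stop_invalid("activity must be finite")
  a <- 0
  if (isTRUE(cancel_marginal)) {
    cb <- act_coef * act_loading
    disc <- cb^2 - 4 * rep_coef^2 * noise_sd^2
    if (disc < 0)
      stop_invalid("no real activity loading cancels the marginal covariance; ",
                   "decrease noise_sd or rep_coef")
    a <- (cb + sqrt(disc)) / (2 * rep_coef)
  }
  r <- with_seed(seed, shift + a * activity +
                   rnorm(length(activity), 0, noise_sd))
  r <- pmax(r, 1e-3)
  attr(r, "loading") <- a
  r
}

#' Describe a planted expression term
#'
#' A term contributes `coef * prod_f g_f(A_f)` to log2 expression, where each
#' factor is either the raw amplitude (`knot = NA`) or a hinge
#' `max(0, dir * (A - knot))`.
#'
#' @param marks character vector of 1-3 mark names.
#' @param coef scalar coefficient.
#' @param knots numeric vector aligned with `marks` (NA = raw amplitude).
#' @param dirs +1 (`h(x - k)`) or -1 (`h(k - x)`) per factor.
#' @export
planted_term <- function(marks, coef, knots = NULL, dirs = NULL) {
  if (length(marks) < 1L || length(marks) > 3L || anyDuplicated(marks))
    stop_invalid("a planted term uses 1-3 distinct marks")
  list(marks = as.character(marks), coef = coef,
       knots = knots %||% rep(NA_real_, length(marks)),
       dirs = dirs %||% rep(1, length(marks)))
}

#' Default planted expression model for the 8-mark panel
#'
#' One linear mono term on the activity-coupled activator, a saturating mono
#' response on `actBody` (linear + negative hinge, i.e. `3 * min(A, 2)`), one
#' bivalent product, one repressive trivalent product, and the `-6 * repArg`
#' term that the confounded repressor cancels against.
#' @return list of [planted_term()]s.
#' @export
default_planted_terms <- function() {
  list(
    planted_term("actTSS", 4),
    planted_term("actBody", 3),
    planted_term("actBody", -3, knots = 2, dirs = 1),
    planted_term(c("actK9", "actEnh"), 2),
    planted_term(c("repPolyA", "repPolyB", "repK20"), -1),
    planted_term("repArg", -6)
  )
}

#' Draw true per-gene amplitudes for a mark panel
#'
#' @param mark_specs named list of [mark_spec()].
#' @param activity latent activity vector `z ~ Normal(0, 1)`.
#' @param seed integer seed.
#' @return genes x marks matrix of strictly positive amplitudes, with the
#'   confounded-repressor loading (if any) stored in attribute `"loadings"`.
#' @export
true_amplitudes <- function(mark_specs, activity, seed = 1L) {
  n <- length(activity)
  amps <- matrix(NA_real_, n, length(mark_specs),
                 dimnames = list(NULL, names(mark_specs)))
  loadings <- numeric(0)
  for (j in seq_along(mark_specs)) {
    am <- mark_specs[[j]]$amplitude
    sj <- child_seed(seed, "amp", names(mark_specs)[j])
    amps[, j] <- switch(am$family %||% "lognormal",
      lognormal = (am$baseline %||% 0) + exp((am$meanlog %||% 0) +
        (am$loading %||% 0) * activity +
        (am$sdlog %||% 0.5) * with_seed(sj, rnorm(n))),
      gaussian = pmax(am$floor %||% 0.05,
        (am$center %||% 1) + (am$loading %||% 0) * activity +
        (am$sd %||% 0.5) * with_seed(sj, rnorm(n))),
      confounded = {
        r <- make_confounded_repressor(activity,
               cancel_marginal = am$cancel_marginal %||% TRUE,
               act_coef = am$act_coef %||% 4,
               act_loading = am$act_loading %||% 1,
               rep_coef = am$rep_coef %||% 6,
               noise_sd = am$noise_sd %||% 0.3,
               shift = am$shift %||% 2, seed = sj)
        loadings[names(mark_specs)[j]] <- attr(r, "loading")
        as.numeric(r)
      },
      stop_invalid("unknown amplitude family: ", am$family)
    )
  }
  attr(amps, "loadings") <- loadings
  amps
}

#' @noRd
term_contribution <- function(term, amplitudes) {
  miss <- setdiff(term$marks, colnames(amplitudes))
  if (length(miss))
    stop_invalid("planted term references unknown mark(s): ",
                 paste(miss, collapse = ", "))
  contrib <- rep(term$coef, nrow(amplitudes))
  for (f in seq_along(term$marks)) {
    x <- amplitudes[, term$marks[f]]
    k <- term$knots[f]
    contrib <- contrib * if (is.na(k)) x else pmax(0, term$dirs[f] * (x - k))
  }
  contrib
}

#' Simulate log2 expression from planted terms
#'
#' `Y_k = intercept + sum_terms coef * prod(factors) + Normal(0, noise_sd^2)`.
#'
#' @param true_amplitudes genes x marks matrix with column names.
#' @param planted_terms list of [planted_term()]s.
#' @param intercept scalar intercept (log2 units).
#' @param noise_sd residual sd.
#' @param seed integer seed.
#' @return numeric vector of per-gene log2 expression with attribute
#'   `"signal"` (the noiseless component).
#' @export
simulate_expression <- function(true_amplitudes, planted_terms,
                                intercept = 5, noise_sd = 1, seed = 1L) {
  signal <- rep(intercept, nrow(true_amplitudes))
  for (tm in planted_terms)
    signal <- signal + term_contribution(tm, true_amplitudes)
  y <- signal +
    with_seed(seed, rnorm(nrow(true_amplitudes), 0, noise_sd))
  attr(y, "signal") <- signal
  y
}

#' Simulate binned tag-count profiles
#'
#' Each gene x mark profile is `A * t` (rank-1 in the noiseless case); with
#' Poisson noise, each bin count is drawn `Poisson(A * t_i)`. Poisson is this
#' generator's choice of ChIP-Seq count noise, not a property inherited from
#' any reference data set.
#'
#' @param gene_models a `cv_gene_models` table (defines the number of genes).
#' @param mark_specs named list of [mark_spec()].
#' @param amplitudes genes x marks matrix of true amplitudes.
#' @param n_body_bins,flank_bins layout of the binned profiles.
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed.
#' @return named list (one per mark) of genes x bins matrices; attribute
#'   `"templates"` holds the true `cv_template`s used.
#' @export
simulate_profiles <- function(gene_models, mark_specs, amplitudes,
                              n_body_bins = 300L, flank_bins = 20L,
                              noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  n <- nrow(gene_models)
  if (nrow(amplitudes) != n || ncol(amplitudes) != length(mark_specs))
    stop_invalid("amplitude matrix dimensions do not match genes x marks")
  if (any(amplitudes <= 0)) stop_invalid("true amplitudes must be positive")
  templates <- lapply(mark_specs, make_true_template,
                      n_body_bins = n_body_bins, flank_bins = flank_bins)
  profiles <- vector("list", length(mark_specs))
  names(profiles) <- names(mark_specs)
  for (j in seq_along(mark_specs)) {
    lam <- outer(amplitudes[, j], templates[[j]]$values)
    profiles[[j]] <- if (noise == "none") lam else
      with_seed(child_seed(seed, "prof", names(mark_specs)[j]),
                matrix(rpois(length(lam), lam), nrow(lam), ncol(lam)))
    rownames(profiles[[j]]) <- gene_models$gene_id
  }
  attr(profiles, "templates") <- templates
  profiles
}

#' Sample tag start positions (BED mode)
#'
#' Draws per-base Poisson counts around `A * t_base` over each gene's
#' `[tss - flank_bp, tes + flank_bp)` window at 1 bp resolution and emits one
#' BED6 interval per tag 5' start. Intended for small-scale I/O tests of the
#' interval-reading path.
#'
#' @inheritParams simulate_profiles
#' @param flank_bp flank width in base pairs.
#' @return named list (one per mark) of BED6 `data.frame`s
#'   (`chrom,start,end,name,score,strand`).
#' @export
simulate_tags <- function(gene_models, mark_specs, amplitudes,
                          flank_bp = 2000L, seed = 1L) {
  out <- lapply(names(mark_specs), function(mk) {
    spec <- mark_specs[[mk]]
    rows <- vector("list", nrow(gene_models))
    for (i in seq_len(nrow(gene_models))) {
      g <- gene_models[i, ]
      L <- g$end - g$start
      tb <- make_true_template(spec, n_body_bins = L, flank_bins = flank_bp)
      lam <- amplitudes[i, mk] * tb$values  # 5'->3' orientation
      cnt <- with_seed(child_seed(seed, "tags", mk, i),
                       rpois(length(lam), lam))
      # map layout position -> genomic coordinate
      coords <- if (g$strand == "+")
        seq(g$start - flank_bp, g$end + flank_bp - 1L) else
        rev(seq(g$start - flank_bp, g$end + flank_bp - 1L))
      pos <- rep(coords, cnt)
      rows[[i]] <- if (length(pos)) data.frame(chrom = g$chrom, start = pos,
                                               end = pos + 1L, name = mk,
                                               score = 0L, strand = "+") else NULL
    }
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  })
  stats::setNames(out, names(mark_specs))
}

#' Simulate a complete synthetic dataset
#'
#' Generates gene models, the latent activity factor, true amplitudes
#' (including the confounded repressor where the panel plants one), log2
#' expression at a target true R-squared, and (optionally) binned Poisson
#' profiles. This is the stated world every downstream stage is tested
#' against.
#'
#' @param n_genes number of genes (default 2000, the demo scale).
#' @param mark_specs mark panel (default [default_mark_panel()]).
#' @param planted_terms expression model (default [default_planted_terms()]).
#' @param n_body_bins,flank_bins binned-profile layout (defaults 300 body bins
#'   and 20 aggregated flank bins - a speed-scaled stand-in for the 8138-bin,
#'   2 kbp-flank layout used on real data).
#' @param target_r2 fraction of expression variance explained by the planted
#'   signal (default 0.5); the residual sd is derived from the realised signal
#'   variance. Ignored when `noise_sd` is given.
#' @param noise_sd residual sd override.
#' @param intercept expression intercept (log2 units).
#' @param profile_noise `"poisson"`, `"none"`, or `"skip"` (no profiles).
#' @param multi_probe_rate fraction of genes carrying a second expression
#'   probe (independent residual draw around the same signal).
#' @param seed master seed.
#' @return object of class `cv_dataset`: list with `gene_models`, `mark_specs`,
#'   `profiles`, `expression` (probe table), `ground_truth`, layout and seed.
#' @export
simulate_dataset <- function(n_genes = 2000L,
                             mark_specs = default_mark_panel(),
                             planted_terms = default_planted_terms(),
                             n_body_bins = 300L, flank_bins = 20L,
                             target_r2 = 0.5, noise_sd = NULL,
                             intercept = 5,
                             profile_noise = c("poisson", "none", "skip"),
                             multi_probe_rate = 0,
                             seed = 1L) {
  profile_noise <- match.arg(profile_noise)
  gm <- make_gene_models(n_genes, seed = child_seed(seed, "genes"))
  z <- with_seed(child_seed(seed, "activity"), rnorm(n_genes))
  amps <- true_amplitudes(mark_specs, z, seed = child_seed(seed, "amps"))

  # residual sd from the realised signal variance: sd_eps = sd(signal) *
  # sqrt((1 - R2) / R2)
  signal <- rep(intercept, n_genes)
  for (tm in planted_terms) signal <- signal + term_contribution(tm, amps)
  if (is.null(noise_sd))
    noise_sd <- stats::sd(signal) * sqrt((1 - target_r2) / target_r2)
  y <- signal + with_seed(child_seed(seed, "expr"), rnorm(n_genes, 0, noise_sd))

  expression <- data.frame(probe_id = paste0(gm$gene_id, "_p1"),
                           gene_id = gm$gene_id, log2_expr = y,
                           stringsAsFactors = FALSE)
  if (multi_probe_rate > 0) {
    extra <- with_seed(child_seed(seed, "probes"),
                       which(runif(n_genes) < multi_probe_rate))
    if (length(extra)) {
      y2 <- signal[extra] + with_seed(child_seed(seed, "probe_noise"),
                                      rnorm(length(extra), 0, noise_sd))
      expression <- rbind(expression,
        data.frame(probe_id = paste0(gm$gene_id[extra], "_p2"),
                   gene_id = gm$gene_id[extra], log2_expr = y2,
                   stringsAsFactors = FALSE))
    }
  }

  profiles <- if (profile_noise == "skip") NULL else
    simulate_profiles(gm, mark_specs, amps, n_body_bins, flank_bins,
                      noise = profile_noise, seed = child_seed(seed, "prof"))

  structure(list(
    gene_models = gm, mark_specs = mark_specs, profiles = profiles,
    expression = expression,
    ground_truth = list(activity = z, true_amplitudes = amps,
                        planted_terms = planted_terms,
                        expression_noise_sd = noise_sd,
                        expression = as.numeric(y), signal = signal),
    n_body_bins = as.integer(n_body_bins), flank_bins = as.integer(flank_bins),
    rng_seed = as.integer(seed)), class = "cv_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `genes.tsv` (BED12-like: chrom, start, end, name, score, strand,
#' alt_starts, alt_ends; 0-based half-open), one `profile_<mark>.tsv` matrix
#' per mark, `expression.tsv` (probe_id, log2_expr, gene_id) and a
#' `ground_truth.json` sidecar (planted terms, noise sd, seed, amplitude file
#' pointer) plus `true_amplitudes.tsv`.
#'
#' @param dataset a `cv_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- dataset$gene_models
  genes <- data.frame(chrom = gm$chrom, start = gm$start, end = gm$end,
                      name = gm$gene_id, score = 0L, strand = gm$strand,
                      alt_starts = vapply(gm$start_sites, paste, "", collapse = ","),
                      alt_ends = vapply(gm$stop_sites, paste, "", collapse = ","))
  data.table::fwrite(genes, file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(dataset$expression[, c("probe_id", "log2_expr", "gene_id")],
                     file.path(dir, "expression.tsv"), sep = "\t")
  for (mk in names(dataset$profiles %||% list()))
    data.table::fwrite(as.data.frame(dataset$profiles[[mk]]),
                       file.path(dir, paste0("profile_", mk, ".tsv")),
                       sep = "\t", col.names = FALSE)
  amps <- as.data.frame(dataset$ground_truth$true_amplitudes)
  amps <- cbind(gene_id = gm$gene_id, amps)
  data.table::fwrite(amps, file.path(dir, "true_amplitudes.tsv"), sep = "\t")
  gt <- dataset$ground_truth
  jsonlite::write_json(list(
    planted_terms = lapply(gt$planted_terms, function(tm)
      list(marks = tm$marks, coef = tm$coef, knots = tm$knots, dirs = tm$dirs)),
    expression_noise_sd = gt$expression_noise_sd,
    rng_seed = dataset$rng_seed,
    n_body_bins = dataset$n_body_bins, flank_bins = dataset$flank_bins,
    marks = names(dataset$mark_specs)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
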