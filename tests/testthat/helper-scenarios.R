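# Shared fixture builders. Everything is generated in code at test time.

# 8 generic log-normal marks, three planted terms (one mono, one bi, one tri)
# at a chosen true R2. Used by the stepwise-recovery tests.
scenario_three_terms <- function(n = 2000L, r2 = 0.5, seed = 1L) {
  marks <- paste0("mk", 1:8)
  eps <- chromvalence:::with_seed(seed, matrix(rnorm(n * 8), n, 8))
  A <- exp(0.5 * eps)
  colnames(A) <- marks
  # coefficients chosen once so the three terms contribute comparable signal
  # variance (log-normal products are increasingly heavy-tailed with valency)
  planted <- list(planted_term("mk1", 4),
                  planted_term(c("mk2", "mk3"), 2),
                  planted_term(c("mk4", "mk5", "mk6"), -1.5))
  signal <- rep(5, n)
  for (tm in planted) signal <- signal + chromvalence:::term_contribution(tm, A)
  noise_sd <- sd(signal) * sqrt((1 - r2) / r2)
  y <- simulate_expression(A, planted, intercept = 5, noise_sd = noise_sd,
                           seed = seed + 1L)
  list(A = A, y = as.numeric(y), noise_sd = noise_sd,
       planted = c("mk1", "mk2*mk3", "mk4*mk5*mk6"),
       planted_signs = c(1, 1, -1))
}

# Small default-panel dataset without profiles (fast).
small_default_dataset <- function(n = 600L, seed = 1L) {
  simulate_dataset(n_genes = n, profile_noise = "skip", seed = seed)
}

# A gene row for binning tests.
fake_gene <- function(start, end, strand = "+", chrom = "chrT") {
  list(gene_id = "g1", chrom = chrom, strand = strand,
       chosen_tss = if (strand == "+") start else end,
       chosen_tes = if (strand == "+") end else start,
       start_sites = list(if (strand == "+") start else end),
       stop_sites = list(if (strand == "+") end else start))
}

# Tag positions giving `counts[i]` tags at base `start + i - 1`.
tags_from_counts <- function(counts, start) {
  rep(seq(start, start + length(counts) - 1L), counts)
}
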