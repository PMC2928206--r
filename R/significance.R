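# Enrichment calling against a left-tail Gaussian null, BH FDR control, and
# representative TSS/TES selection.

#' Half-sample mode estimator
#'
#' Robust, parameter-free mode: repeatedly keep the half of the sorted sample
#' with the smallest range until three or fewer points remain, then average.
#'
#' @param x numeric vector.
#' @return scalar mode estimate.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  while (length(x) > 3L) {
    n <- length(x)
    h <- ceiling(n / 2)
    ranges <- x[h:n] - x[1:(n - h + 1L)]
    i <- which.min(ranges)  # ties -> leftmost half
    x <- x[i:(i + h - 1L)]
  }
  mean(x)
}

#' @noRd
histogram_mode <- function(x) {
  # Freedman-Diaconis bin width fallback
  h <- 2 * IQR(x) / length(x)^(1 / 3)
  if (h <= 0) return(half_sample_mode(x))
  brk <- seq(min(x) - h / 2, max(x) + h, by = h)
  hs <- hist(x, breaks = brk, plot = FALSE)
  hs$mids[which.max(hs$counts)]
}

#' Fit the left-tail Gaussian null for one mark
#'
#' The mode of the amplitude distribution is the null mean; the null sd is the
#' left-tail root mean square deviation
#' `sigma = sqrt( sum_{A_k <= mu} (A_k - mu)^2 / n )` over the `n` genes at or
#' below the mode (the mode itself is included; the effect is negligible).
#'
#' @param amplitudes numeric vector of one mark's amplitudes across genes.
#' @param mode_estimator `"hsm"` (half-sample mode, default) or `"histogram"`
#'   (Freedman-Diaconis histogram mode).
#' @param mark_id optional label.
#' @return object of class `cv_null`: list with `mark_id`, `mu`, `sigma`, `n_left`.
#' @export
fit_null <- function(amplitudes, mode_estimator = c("hsm", "histogram"),
                     mark_id = "mark") {
  mode_estimator <- match.arg(mode_estimator)
  if (length(amplitudes) < 50L)
    warning("fewer than 50 genes; mode estimate may be unstable")
  mu <- switch(mode_estimator, hsm = half_sample_mode(amplitudes),
               histogram = histogram_mode(amplitudes))
  left <- amplitudes[amplitudes <= mu]
  if (length(left) == 0L)
    stop(errorCondition("degenerate null: no genes at or below the mode",
                        class = c("cv_degenerate_null", "error")))
  sigma <- sqrt(sum((left - mu)^2) / length(left))
  if (sigma <= 0)
    stop(errorCondition("degenerate null: zero left-tail spread",
                        class = c("cv_degenerate_null", "error")))
  structure(list(mark_id = mark_id, mu = mu, sigma = sigma,
                 n_left = length(left)), class = "cv_null")
}

#' Upper-tail enrichment p-values
#'
#' `p = 1 - Phi((A - mu) / sigma)`: the integral of the null Gaussian from the
#' amplitude to infinity.
#'
#' @param amplitudes numeric vector.
#' @param null a `cv_null`.
#' @export
enrichment_pvalues <- function(amplitudes, null) {
  if (!inherits(null, "cv_null")) stop_invalid("'null' must be a cv_null")
  pnorm(amplitudes, mean = null$mu, sd = null$sigma, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort ascending; `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; original
#' order restored. (Implemented directly; equivalent to
#' `p.adjust(method = "BH")`.)
#'
#' @param p vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Significance calls for an amplitude matrix
#'
#' Fits one Gaussian null per mark, computes raw p-values, applies BH within
#' each mark across genes (matching the per-mark null), and flags
#' `q <= fdr_cutoff`.
#'
#' @param amplitudes genes x marks matrix (or a `cv_amplitudes`).
#' @param fdr_cutoff FDR level (default 0.05).
#' @param mode_estimator passed to [fit_null()].
#' @return object of class `cv_significance`: list with matrices `p`, `q`,
#'   `flag`, the per-mark `nulls`, and `fdr_cutoff`.
#' @export
significance_calls <- function(amplitudes, fdr_cutoff = 0.05,
                               mode_estimator = "hsm") {
  if (inherits(amplitudes, "cv_amplitudes")) amplitudes <- amplitudes$amplitudes
  marks <- colnames(amplitudes)
  p <- q <- flag <- amplitudes * NA
  nulls <- list()
  for (mk in marks) {
    nulls[[mk]] <- fit_null(amplitudes[, mk], mode_estimator, mark_id = mk)
    p[, mk] <- enrichment_pvalues(amplitudes[, mk], nulls[[mk]])
    q[, mk] <- bh_adjust(p[, mk])
    flag[, mk] <- q[, mk] <= fdr_cutoff
  }
  structure(list(p = p, q = q, flag = flag == 1, nulls = nulls,
                 fdr_cutoff = fdr_cutoff), class = "cv_significance")
}

#' Select a gene's representative TSS/TES
#'
#' The start site with the largest number of significantly enriched marks wins;
#' ties go to the most 5'-upstream start (smallest coordinate on `+`, largest
#' on `-`). Given the chosen TSS, the stop site with the largest count wins;
#' stop ties go to the longest gene body (a deterministic stand-in for an
#' arbitrary choice).
#'
#' @param gene list/row with `strand`, `start_sites`, `stop_sites`.
#' @param start_counts significant-mark counts aligned with
#'   `gene$start_sites`.
#' @param stop_counts significant-mark counts aligned with `gene$stop_sites`
#'   (computed for the winning TSS).
#' @return list with `tss` and `tes` coordinates.
#' @export
select_sites <- function(gene, start_counts, stop_counts) {
  starts <- unlist(gene$start_sites)
  stops <- unlist(gene$stop_sites)
  if (length(starts) < 1L || length(stops) < 1L)
    stop_invalid("gene needs >= 1 start and >= 1 stop site")
  stopifnot(length(start_counts) == length(starts),
            length(stop_counts) == length(stops))
  best <- which(start_counts == max(start_counts))
  tss <- if (gene$strand == "+") min(starts[best]) else max(starts[best])
  bests <- which(stop_counts == max(stop_counts))
  body_len <- abs(stops[bests] - tss)
  tes <- stops[bests][which.max(body_len)]
  list(tss = tss, tes = tes)
}

# Largest raw p-value flagged significant for each mark; the per-mark
# threshold used when scoring candidate sites one gene at a time.
#' @noRd
raw_p_thresholds <- function(sig) {
  vapply(colnames(sig$p), function(mk) {
    flagged <- sig$p[sig$flag[, mk], mk]
    if (length(flagged)) max(flagged) else 0
  }, numeric(1))
}

#' Choose representative sites for every gene from tag data
#'
#' For each gene, each candidate (start, stop) pair (capped at
#' `max_candidates`) is re-binned and re-scored: per mark, the candidate
#' amplitude is estimated against the mark's template and compared with the
#' per-mark raw-p threshold implied by the dataset-level BH flags. The
#' candidate counts feed [select_sites()].
#'
#' @param gene_models a `cv_gene_models` table.
#' @param tag_sets named list (per mark) of BED6 data.frames or position
#'   vectors.
#' @param templates named list of `cv_template`s.
#' @param sig a `cv_significance` from the dataset-level amplitudes.
#' @param n_body_bins,flank_bp,flank_bin_bp binning layout.
#' @param max_candidates cap on (start, stop) pairs per gene (default 10).
#' @return `gene_models` with `chosen_tss`/`chosen_tes` updated.
#' @export
choose_sites <- function(gene_models, tag_sets, templates, sig,
                         n_body_bins, flank_bp = 2000L, flank_bin_bp = 1L,
                         max_candidates = 10L) {
  thr <- raw_p_thresholds(sig)
  marks <- names(templates)
  score_candidate <- function(gene, tss, tes) {
    g <- gene
    g$chosen_tss <- tss; g$chosen_tes <- tes
    sum(vapply(marks, function(mk) {
      prof <- suppressWarnings(
        bin_gene_profile(tag_sets[[mk]], g, n_body_bins, flank_bp, flank_bin_bp))
      a <- estimate_amplitude(prof, templates[[mk]])
      p <- enrichment_pvalues(a, sig$nulls[[mk]])
      p <= thr[mk]
    }, logical(1)))
  }
  for (i in seq_len(nrow(gene_models))) {
    gene <- gene_models[i, ]
    starts <- unlist(gene$start_sites)
    stops <- unlist(gene$stop_sites)
    if (length(starts) == 1L && length(stops) == 1L) {
      gene_models$chosen_tss[i] <- starts
      gene_models$chosen_tes[i] <- stops
      next
    }
    n_stop_per_start <- max(1L, min(length(stops),
                                    max_candidates %/% length(starts)))
    start_counts <- vapply(starts, function(s)
      max(vapply(stops[seq_len(n_stop_per_start)], function(e)
        score_candidate(gene, s, e), numeric(1))), numeric(1))
    # stop counts evaluated at the winning TSS
    best <- which(start_counts == max(start_counts))
    tss0 <- if (gene$strand == "+") min(starts[best]) else max(starts[best])
    stop_counts <- vapply(stops, function(e)
      score_candidate(gene, tss0, e), numeric(1))
    sel <- select_sites(gene, start_counts, stop_counts)
    gene_models$chosen_tss[i] <- sel$tss
    gene_models$chosen_tes[i] <- sel$tes
  }
  gene_models
}
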