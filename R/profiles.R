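# Gene-body scaling, metagene templates and least-squares amplitudes.
#
# Layout convention everywhere: [5' flank | N scaled body bins | 3' flank] in
# 5'->3' orientation (minus-strand genes are reversed). Coordinates are
# 0-based half-open; tags are counted at their 5' start position.

# Scale a per-base vector to N body bins.
# L >= N: bin value = mean of per-base counts between boundaries
#         round(L*b/N) (a base bisected by a boundary goes wholly to the bin
#         holding its majority; "round half up", not banker's rounding).
# L <  N: per-base values are repeated; bin b takes the base containing the
#         majority of the bin's span, i.e. the base under the bin midpoint.
#' @noRd
scale_to_bins <- function(x, n_bins) {
  L <- length(x)
  if (L >= n_bins) {
    cuts <- floor(L * (0:n_bins) / n_bins + 0.5)
    cs <- c(0, cumsum(x))
    (cs[cuts[-1] + 1L] - cs[cuts[-(n_bins + 1L)] + 1L]) / diff(cuts)
  } else {
    x[floor(L * (seq_len(n_bins) - 0.5) / n_bins) + 1L]
  }
}

# Aggregate a per-base flank into flank bins of flank_bin_bp bases (mean),
# preserving the per-base count scale.
#' @noRd
aggregate_flank <- function(x, flank_bin_bp) {
  if (flank_bin_bp <= 1L) return(x)
  n <- length(x) %/% flank_bin_bp
  colMeans(matrix(x[seq_len(n * flank_bin_bp)], nrow = flank_bin_bp))
}

# Bin a 5'->3' oriented per-base window (flank_bp | L | flank_bp) into the
# standard layout.
#' @noRd
bin_base_window <- function(x, L, n_body_bins, flank_bp, flank_bin_bp = 1L) {
  stopifnot(length(x) == L + 2L * flank_bp)
  c(aggregate_flank(x[seq_len(flank_bp)], flank_bin_bp),
    scale_to_bins(x[flank_bp + seq_len(L)], n_body_bins),
    aggregate_flank(x[flank_bp + L + seq_len(flank_bp)], flank_bin_bp))
}

#' Bin one gene's tag profile into the scaled-gene layout
#'
#' Counts tag 5' starts per base over `[tss - flank_bp, tes + flank_bp)`,
#' scales the gene body to `n_body_bins` bins (averaging within bins for long
#' genes, repeating bases for short genes, majority-rule assignment of
#' boundary-straddling bases), optionally aggregates the per-base flanks into
#' `flank_bin_bp`-wide bins, and reverses minus-strand genes so the vector
#' runs 5' to 3'.
#'
#' @param tag_intervals BED6-like data.frame (`chrom`, `start` used) or an
#'   integer vector of tag 5' start positions on the gene's chromosome.
#' @param gene one row of a `cv_gene_models` table (or any list with `chrom`,
#'   `strand`, `chosen_tss`, `chosen_tes`).
#' @param n_body_bins number of scaled body bins (>= 1).
#' @param flank_bp flank width in base pairs (default 2000).
#' @param flank_bin_bp flank aggregation width (default 1 = per-nucleotide).
#' @return numeric profile vector in the standard layout.
#' @export
bin_gene_profile <- function(tag_intervals, gene, n_body_bins,
                             flank_bp = 2000L, flank_bin_bp = 1L) {
  if (n_body_bins < 1) stop_invalid("n_body_bins must be >= 1")
  gstart <- min(gene$chosen_tss, gene$chosen_tes)
  gend <- max(gene$chosen_tss, gene$chosen_tes)
  L <- gend - gstart
  if (L < 1) stop_invalid("gene body must be >= 1 bp")
  pos <- if (is.data.frame(tag_intervals)) {
    tag_intervals$start[tag_intervals$chrom == gene$chrom]
  } else as.integer(tag_intervals)
  w0 <- gstart - flank_bp
  inwin <- pos >= w0 & pos < gend + flank_bp
  counts <- numeric(L + 2L * flank_bp)
  if (!any(inwin)) {
    warning("no tags overlap gene window; returning all-zero profile")
  } else {
    tb <- tabulate(pos[inwin] - w0 + 1L, nbins = L + 2L * flank_bp)
    counts <- as.numeric(tb)
  }
  prof <- bin_base_window(counts, L, n_body_bins, flank_bp, flank_bin_bp)
  if (gene$strand == "-") prof <- rev(prof)
  prof
}

#' Build a mark's template from binned profiles
#'
#' Position-wise mean across genes of TSS/TES-aligned scaled profiles,
#' rescaled so the mean over *all* positions (flanks included) is exactly 1.
#'
#' @param profiles genes x positions matrix (or list of equal-length vectors)
#'   of binned profiles for one mark.
#' @param mark_id template label.
#' @param n_body_bins,flank_bins layout metadata carried on the result; when
#'   `n_body_bins` is `NULL` all positions are treated as body bins.
#' @return a `cv_template`.
#' @export
build_template <- function(profiles, mark_id = "mark",
                           n_body_bins = NULL, flank_bins = 0L) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) stop_invalid("need at least one profile")
  avg <- colMeans(profiles)
  m <- mean(avg)
  if (m <= 0)
    stop(errorCondition("degenerate template: aggregate profile is all zero",
                        class = c("cv_degenerate_template", "error")))
  new_template(mark_id, avg / m,
               n_body_bins %||% ncol(profiles),
               flank_bins)
}

#' Least-squares enrichment amplitude of one profile
#'
#' Closed-form minimiser of `sum_i (y_i - A * t_i)^2`:
#' `A = sum(y * t) / sum(t^2)`. For a uniform template this reduces to the
#' simple bin average of the profile.
#'
#' @param profile numeric profile vector (same layout as the template).
#' @param template a `cv_template` or numeric vector.
#' @return scalar amplitude (nonnegative whenever profile and template are).
#' @export
estimate_amplitude <- function(profile, template) {
  t <- if (inherits(template, "cv_template")) template$values else template
  if (length(profile) != length(t))
    stop_invalid("profile and template layouts differ")
  ss <- sum(t^2)
  if (ss == 0)
    stop(errorCondition("degenerate template: sum of squares is zero",
                        class = c("cv_degenerate_template", "error")))
  sum(profile * t) / ss
}

#' Relative error of the template fit: CV(RMSD)
#'
#' `sqrt(mean((y - A t)^2)) / A`; the RMSD between profile and fitted model in
#' units of the amplitude. Undefined (returned as `NA`) for `A <= 0`.
#'
#' @inheritParams estimate_amplitude
#' @param amplitude fitted amplitude for this profile.
#' @return nonnegative scalar, or `NA_real_` when `amplitude <= 0`.
#' @export
cv_rmsd <- function(profile, template, amplitude) {
  t <- if (inherits(template, "cv_template")) template$values else template
  if (amplitude <= 0) return(NA_real_)
  sqrt(mean((profile - amplitude * t)^2)) / amplitude
}

#' Amplitudes and diagnostics for a full dataset
#'
#' Builds one template per mark from the supplied binned profiles (unless
#' templates are given) and computes the genes x marks amplitude and CV(RMSD)
#' matrices in one pass.
#'
#' @param profiles named list (per mark) of genes x positions matrices.
#' @param templates optional named list of `cv_template`s to reuse.
#' @param n_body_bins,flank_bins layout metadata (template construction).
#' @return object of class `cv_amplitudes`: list with `amplitudes`, `cv_rmsd`
#'   (genes x marks matrices), `templates`, `n_body_bins`.
#' @export
amplitude_matrix <- function(profiles, templates = NULL,
                             n_body_bins = NULL, flank_bins = 0L) {
  marks <- names(profiles)
  if (is.null(marks)) stop_invalid("'profiles' must be a named list")
  if (is.null(templates))
    templates <- lapply(marks, function(mk)
      build_template(profiles[[mk]], mk, n_body_bins, flank_bins))
  names(templates) <- marks
  n <- nrow(profiles[[1]])
  A <- matrix(NA_real_, n, length(marks), dimnames = list(rownames(profiles[[1]]), marks))
  CV <- A
  for (mk in marks) {
    P <- profiles[[mk]]
    tv <- templates[[mk]]$values
    a <- as.numeric(P %*% tv) / sum(tv^2)
    resid2 <- rowMeans((P - tcrossprod(a, tv))^2)
    A[, mk] <- a
    CV[, mk] <- ifelse(a > 0, sqrt(resid2) / a, NA_real_)
  }
  structure(list(amplitudes = A, cv_rmsd = CV, templates = templates,
                 n_body_bins = templates[[1]]$n_body_bins),
            class = "cv_amplitudes")
}

#' Fractional difference between two amplitude estimates
#'
#' `2 * (a - b) / (a + b)`; defined as 0 when both are 0.
#' @param a,b numeric vectors.
#' @export
fractional_difference <- function(a, b) {
  d <- 2 * (a - b) / (a + b)
  d[a == 0 & b == 0] <- 0
  d
}

#' Recompute amplitudes under several body-bin counts
#'
#' Streams gene-by-gene base-resolution profiles through the template/amplitude
#' machinery once per requested bin count (two passes each: template
#' accumulation, then amplitude estimation), so full base-level data never
#' needs to be held in memory.
#'
#' @param base_profile_fun `function(i)` returning gene `i`'s 5'->3' oriented
#'   per-base window matrix (`(L_i + 2*flank_bp)` rows x marks columns).
#' @param gene_lengths integer vector of gene body lengths (bp).
#' @param mark_names character vector of mark names (column order of the
#'   window matrices).
#' @param bin_counts body-bin counts to evaluate, e.g. `c(6000, 8138, 10000)`.
#' @param flank_bp,flank_bin_bp flank layout passed to the binning rule.
#' @return named list (per bin count, as character) of genes x marks
#'   amplitude matrices.
#' @export
amplitudes_at_binnings <- function(base_profile_fun, gene_lengths, mark_names,
                                   bin_counts, flank_bp = 2000L,
                                   flank_bin_bp = 10L) {
  n <- length(gene_lengths)
  out <- list()
  for (nb in bin_counts) {
    flank_bins <- flank_bp %/% flank_bin_bp
    width <- nb + 2L * flank_bins
    tsum <- matrix(0, width, length(mark_names))
    for (i in seq_len(n)) {
      W <- base_profile_fun(i)
      for (j in seq_along(mark_names))
        tsum[, j] <- tsum[, j] +
          bin_base_window(W[, j], gene_lengths[i], nb, flank_bp, flank_bin_bp)
    }
    templates <- lapply(seq_along(mark_names), function(j) {
      v <- tsum[, j] / n
      new_template(mark_names[j], v / mean(v), nb, flank_bins)
    })
    A <- matrix(NA_real_, n, length(mark_names),
                dimnames = list(NULL, mark_names))
    for (i in seq_len(n)) {
      W <- base_profile_fun(i)
      for (j in seq_along(mark_names)) {
        prof <- bin_base_window(W[, j], gene_lengths[i], nb, flank_bp,
                                flank_bin_bp)
        A[i, j] <- estimate_amplitude(prof, templates[[j]])
      }
    }
    out[[as.character(nb)]] <- A
  }
  out
}

#' Bin-size robustness report
#'
#' For each mark and each non-reference bin count: the Spearman correlation
#' against the reference amplitudes and the 0/25/50/75/100th percentiles of
#' the per-gene fractional difference `2(a - b)/(a + b)`.
#'
#' @param amplitude_sets named list of genes x marks amplitude matrices keyed
#'   by bin count (e.g. output of [amplitudes_at_binnings()]).
#' @param reference name of the reference set (default `"8138"` when present,
#'   else the first).
#' @return data.frame with columns `mark`, `bins`, `spearman`, `fd_p0`,
#'   `fd_p25`, `fd_p50`, `fd_p75`, `fd_p100`.
#' @export
robustness_report <- function(amplitude_sets, reference = NULL) {
  if (length(amplitude_sets) < 2L) stop_invalid("need >= 2 bin counts")
  reference <- reference %||%
    (if ("8138" %in% names(amplitude_sets)) "8138" else names(amplitude_sets)[1])
  ref <- amplitude_sets[[reference]]
  rows <- list()
  for (nb in setdiff(names(amplitude_sets), reference)) {
    alt <- amplitude_sets[[nb]]
    for (mk in colnames(ref)) {
      fd <- fractional_difference(ref[, mk], alt[, mk])
      qq <- quantile(fd, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mark = mk, bins = nb,
        spearman = cor(ref[, mk], alt[, mk], method = "spearman"),
        fd_p0 = qq[1], fd_p25 = qq[2], fd_p50 = qq[3], fd_p75 = qq[4],
        fd_p100 = qq[5], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Noiseless base-resolution profile provider
#'
#' Returns a closure suitable for [amplitudes_at_binnings()] that evaluates
#' each gene's exact rank-1 window `A * t_base` at 1 bp resolution (no count
#' noise), in 5'->3' orientation.
#'
#' @param gene_models a `cv_gene_models` table.
#' @param mark_specs named list of [mark_spec()].
#' @param amplitudes genes x marks matrix of true amplitudes.
#' @param flank_bp flank width in bp.
#' @export
noiseless_base_profiles <- function(gene_models, mark_specs, amplitudes,
                                    flank_bp = 2000L) {
  lens <- gene_models$end - gene_models$start
  force(mark_specs); force(amplitudes); force(flank_bp)
  function(i) {
    L <- lens[i]
    vapply(seq_along(mark_specs), function(j) {
      tb <- make_true_template(mark_specs[[j]], n_body_bins = L,
                               flank_bins = flank_bp)
      amplitudes[i, j] * tb$values
    }, numeric(L + 2L * flank_bp))
  }
}
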