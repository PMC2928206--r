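# In-silico knockouts, quintile stratification, site-proportion profiles and
# bivalent expression heat maps.

#' In-silico knockout of one or two marks
#'
#' Sets the named marks' amplitude columns to zero everywhere and re-evaluates
#' the model (terms and hinge bases containing the mark are recomputed at
#' amplitude 0, not dropped - `h(knot - 0)` can be positive). The per-gene
#' log2 fold change is `predicted_WT - predicted_KO` (predictions are already
#' log2 expression, so the difference is the log of the WT/KO ratio). A
#' positive median marks an activator; negative, a repressor.
#'
#' @param model a fitted `cv_mlmodel` or `cv_mars`.
#' @param amplitudes genes x marks matrix with named columns.
#' @param marks_to_zero 1 or 2 mark names.
#' @return object of class `cv_knockout`: list with `marks`, `fold_change`
#'   (per observation), `wt`, `ko`, and `summary` (median, quartiles, mean).
#' @export
knockout <- function(model, amplitudes, marks_to_zero) {
  if (!all(marks_to_zero %in% colnames(amplitudes)))
    stop_invalid("unknown mark(s): ",
                 paste(setdiff(marks_to_zero, colnames(amplitudes)),
                       collapse = ", "))
  if (!length(marks_to_zero) %in% 1:2)
    stop_invalid("knock out 1 or 2 marks at a time")
  wt <- predict(model, amplitudes)
  ko_amps <- amplitudes
  ko_amps[, marks_to_zero] <- 0
  ko <- predict(model, ko_amps)
  fc <- wt - ko
  structure(list(marks = marks_to_zero, fold_change = fc, wt = wt, ko = ko,
                 summary = c(median = median(fc),
                             q1 = unname(quantile(fc, 0.25)),
                             q3 = unname(quantile(fc, 0.75)),
                             mean = mean(fc))),
            class = "cv_knockout")
}

#' Knockout screen over all single (and pairwise) marks
#'
#' @param model a fitted `cv_mlmodel` or `cv_mars`.
#' @param amplitudes genes x marks matrix.
#' @param pairs also knock out all mark pairs (default `FALSE`).
#' @return data.frame (one row per knocked set, ascending median fold change)
#'   with columns `knockout`, `n_marks`, `median_fc`, `mean_fc`, `q1`, `q3`.
#' @export
knockout_screen <- function(model, amplitudes, pairs = FALSE) {
  marks <- colnames(amplitudes)
  sets <- as.list(marks)
  if (pairs && length(marks) > 1L)
    sets <- c(sets, combn(marks, 2L, simplify = FALSE))
  rows <- lapply(sets, function(s) {
    ko <- knockout(model, amplitudes, s)
    data.frame(knockout = paste(s, collapse = "-"), n_marks = length(s),
               median_fc = unname(ko$summary["median"]),
               mean_fc = unname(ko$summary["mean"]),
               q1 = unname(ko$summary["q1"]), q3 = unname(ko$summary["q3"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$median_fc), , drop = FALSE]
}

#' Stratify a knockout by fold-change quintiles
#'
#' Observations are ranked by the knockout's effect so that QU1 holds the 20%
#' of genes most up-regulated by the knockout (the largest de-repression,
#' i.e. the most negative `WT - KO` fold changes) and QU5 the genes least
#' up-regulated (or down-regulated) by it. Ties keep their original order;
#' quintile sizes differ by at most one.
#'
#' @param ko a `cv_knockout` (or numeric fold-change vector, in which case
#'   `wt_pred`/`ko_pred` must be supplied).
#' @param wt_pred,ko_pred optional prediction vectors (default from `ko`).
#' @return object of class `cv_quintiles`: list with `quintile` (per
#'   observation, 1-5), `order`, and `summary` - a data.frame of five-number
#'   summaries of WT and KO predictions per quintile.
#' @export
quintile_stratify <- function(ko, wt_pred = NULL, ko_pred = NULL) {
  if (inherits(ko, "cv_knockout")) {
    fc <- ko$fold_change
    wt_pred <- wt_pred %||% ko$wt
    ko_pred <- ko_pred %||% ko$ko
  } else fc <- as.numeric(ko)
  if (is.null(wt_pred) || is.null(ko_pred))
    stop_invalid("wt_pred and ko_pred are required when 'ko' is a plain vector")
  n <- length(fc)
  if (n < 5L) stop_invalid("need >= 5 observations for quintiles")
  o <- order(fc)   # QU1 = most negative WT-KO; ties keep observation order
  qu <- integer(n)
  qu[o] <- ceiling(5 * seq_len(n) / n)
  five_num <- function(x, prefix) {
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    stats::setNames(q, paste0(prefix, c("min", "q1", "median", "q3", "max")))
  }
  summ <- do.call(rbind, lapply(1:5, function(k) {
    idx <- qu == k
    cbind(data.frame(quintile = paste0("QU", k), n = sum(idx),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(c(five_num(wt_pred[idx], "wt_"),
                                  five_num(ko_pred[idx], "ko_")))))
  }))
  structure(list(quintile = qu, order = o, summary = summ),
            class = "cv_quintiles")
}

#' Significant-site proportions per knockout quintile
#'
#' For each mark, the proportion of genes in each fold-change quintile whose
#' enrichment is flagged significant. Rows are proportions per quintile, not a
#' distribution (they need not sum to 1). Internal significance flags stand in
#' for external peak calls.
#'
#' @param quintiles a `cv_quintiles` (or an integer vector of quintile labels
#'   1-5 per gene).
#' @param significance a `cv_significance` (or a logical genes x marks flag
#'   matrix) on the same genes, same order.
#' @return marks x 5 proportion matrix (columns `QU1`..`QU5`).
#' @export
site_proportion_profiles <- function(quintiles, significance) {
  qu <- if (inherits(quintiles, "cv_quintiles")) quintiles$quintile else
    as.integer(quintiles)
  flags <- if (inherits(significance, "cv_significance")) significance$flag else
    significance
  if (length(qu) != nrow(flags))
    stop_invalid("quintile labels and significance flags cover different gene sets")
  out <- vapply(1:5, function(k) colMeans(flags[qu == k, , drop = FALSE]),
                numeric(ncol(flags)))
  colnames(out) <- paste0("QU", 1:5)
  out
}

#' Bivalent expression heat map
#'
#' Mean observed log2 expression over a `grid x grid` lattice of
#' (monovalent amplitude `x`, bivalent product amplitude `x * partner`).
#' Equal-width bins span the observed ranges; empty cells are `NA` (distinct
#' from a 0 mean), with occupancy counts reported alongside.
#'
#' @param amplitudes genes x marks matrix.
#' @param expression per-gene log2 expression, same order.
#' @param mark_x monovalent mark on the x-axis.
#' @param mark_partner partner mark; the y-axis is `mark_x * mark_partner`.
#' @param grid bins per axis (default 100, i.e. 10,000 cells).
#' @return object of class `cv_heatmap`: list with `mean` and `count`
#'   matrices (`grid x grid`, rows = y bins), `x_breaks`, `y_breaks`.
#' @export
bivalent_heatmap <- function(amplitudes, expression, mark_x, mark_partner,
                             grid = 100L) {
  if (!all(c(mark_x, mark_partner) %in% colnames(amplitudes)))
    stop_invalid("both marks must be present in the amplitude matrix")
  x <- amplitudes[, mark_x]
  y <- x * amplitudes[, mark_partner]
  bin_index <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    i <- floor((v - rng[1]) / diff(rng) * grid) + 1L
    pmin(i, grid)
  }
  ix <- bin_index(x)
  iy <- bin_index(y)
  cell <- (iy - 1L) * grid + ix
  cnt <- tabulate(cell, nbins = grid * grid)
  sums <- numeric(grid * grid)
  agg <- rowsum(expression, cell)
  sums[as.integer(rownames(agg))] <- agg
  mean_mat <- matrix(ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_),
                     nrow = grid, byrow = TRUE)
  count_mat <- matrix(cnt, nrow = grid, byrow = TRUE)
  structure(list(mean = mean_mat, count = count_mat,
                 x_breaks = seq(min(x), max(x), length.out = grid + 1L),
                 y_breaks = seq(min(y), max(y), length.out = grid + 1L),
                 marks = c(mark_x, mark_partner)),
            class = "cv_heatmap")
}
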