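# Multivariate adaptive regression splines: paired hinge bases, hierarchy-
# constrained products up to degree 3, GCV reverse pruning.

#' Hinge function
#'
#' `max(0, x - knot)` for `direction = +1`, `max(0, knot - x)` for
#' `direction = -1`. A symmetric pair about the knot satisfies
#' `h(x - k) + h(k - x) = |x - k|`.
#'
#' @param x numeric vector.
#' @param knot scalar knot.
#' @param direction `+1` or `-1`.
#' @export
hinge <- function(x, knot, direction = 1) {
  pmax(0, direction * (x - knot))
}

# A basis is a list of up to 3 factors (mark, knot, dir); the intercept is the
# empty factor list.
#' @noRd
basis_values <- function(basis, A) {
  v <- rep(1, nrow(A))
  for (f in basis) v <- v * hinge(A[, f$mark], f$knot, f$dir)
  v
}

#' @noRd
basis_label <- function(basis) {
  if (!length(basis)) return("(Intercept)")
  paste(vapply(basis, function(f)
    if (f$dir > 0) sprintf("h(%s-%g)", f$mark, f$knot)
    else sprintf("h(%g-%s)", f$knot, f$mark), ""), collapse = "*")
}

#' @noRd
basis_marks <- function(basis) vapply(basis, `[[`, "", "mark")

# Quantile-spaced knot candidates drawn from observed values.
#' @noRd
knot_candidates <- function(x, max_knots) {
  u <- sort(unique(x))
  if (length(u) <= max_knots) return(u)
  quantile(x, probs = seq(0, 1, length.out = max_knots), type = 1L,
           names = FALSE)
}

#' MARS forward pass
#'
#' Starts from the intercept (the response mean) and greedily adds the
#' hierarchy-legal (parent basis x symmetric hinge pair) whose joint addition
#' maximally reduces the residual sum of squares. Bivalent bases must extend a
#' monovalent basis already in the model, trivalent bases a bivalent one; a
#' basis never uses the same mark twice. Both members of a pair are added
#' together (zero-norm members are skipped). Ties are broken by canonical
#' (mark, knot) order via the search order.
#'
#' @param A observations x marks amplitude matrix (named columns).
#' @param y numeric response.
#' @param max_degree maximum factors per basis (default 3).
#' @param max_terms maximum number of model terms including the intercept
#'   (default 21).
#' @param min_rss_reduction absolute RSS-reduction floor; default
#'   `1e-4 * RSS0` where `RSS0` is the intercept-only RSS.
#' @param max_knots knot candidates per mark (quantile-spaced observed
#'   values; default 20).
#' @return object of class `cv_mars` (unpruned): see [mars_backward()].
#' @export
mars_forward <- function(A, y, max_degree = 3L, max_terms = 21L,
                         min_rss_reduction = NULL, max_knots = 20L) {
  if (max_terms < 1L) stop_invalid("max_terms must be >= 1")
  if (any(apply(A, 2L, function(x) length(unique(x))) < 2L))
    stop_invalid("every mark needs >= 2 distinct amplitude values")
  n <- nrow(A)
  bases <- list(list())           # element 1 = intercept
  B <- matrix(1, n, 1L)
  rss0 <- sum((y - mean(y))^2)
  floor_red <- max(min_rss_reduction %||% (1e-4 * rss0),
                   1e-10 * max(rss0, 1))
  knots <- lapply(colnames(A), function(mk) knot_candidates(A[, mk], max_knots))
  names(knots) <- colnames(A)

  repeat {
    if (ncol(B) >= max_terms) break
    qrx <- qr(B)
    Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    r <- y - Q %*% crossprod(Q, y)
    rss <- sum(r^2)
    if (rss <= 1e-10 * max(rss0, 1)) break  # (near-)perfect fit
    best <- list(red = -Inf)
    for (pb in seq_along(bases)) {
      parent <- bases[[pb]]
      if (length(parent) >= max_degree) next
      bp <- B[, pb]
      for (mk in setdiff(colnames(A), basis_marks(parent))) {
        ks <- knots[[mk]]
        K <- length(ks)
        x <- A[, mk]
        # columns 1..K: parent * h(x - k); K+1..2K: parent * h(k - x)
        C <- cbind(bp * pmax(outer(x, ks, `-`), 0),
                   bp * pmax(outer(x, ks, function(a, b) b - a), 0))
        QtC <- crossprod(Q, C)
        Cp <- C - Q %*% QtC
        a11 <- colSums(Cp[, 1:K, drop = FALSE]^2)
        a22 <- colSums(Cp[, K + (1:K), drop = FALSE]^2)
        a12 <- colSums(Cp[, 1:K, drop = FALSE] * Cp[, K + (1:K), drop = FALSE])
        b1 <- colSums(Cp[, 1:K, drop = FALSE] * as.numeric(r))
        b2 <- colSums(Cp[, K + (1:K), drop = FALSE] * as.numeric(r))
        det <- a11 * a22 - a12^2
        scale2 <- pmax(a11 * a22, 1e-300)
        red_pair <- ifelse(det > 1e-10 * scale2,
                           (a22 * b1^2 - 2 * a12 * b1 * b2 + a11 * b2^2) / det,
                           NA_real_)
        red_single <- pmax(ifelse(a11 > 1e-12, b1^2 / a11, 0),
                           ifelse(a22 > 1e-12, b2^2 / a22, 0))
        red <- ifelse(is.na(red_pair), red_single, red_pair)
        red[!is.finite(red)] <- 0
        i <- which.max(red)
        if (red[i] > best$red + 1e-12) {
          best <- list(red = red[i], parent = pb, mark = mk, knot = ks[i])
        }
      }
    }
    if (!is.finite(best$red) || best$red < floor_red) break
    parent <- bases[[best$parent]]
    bp <- B[, best$parent]
    for (dir in c(1, -1)) {
      col <- bp * hinge(A[, best$mark], best$knot, dir)
      if (sum(col^2) <= 1e-12) next
      if (ncol(B) + 1L > max_terms) break
      bases[[length(bases) + 1L]] <-
        c(parent, list(list(mark = best$mark, knot = best$knot, dir = dir)))
      B <- cbind(B, col)
    }
  }
  finalize_mars(bases, A, y, penalty = 3)
}

# Fit coefficients for a basis set and assemble a cv_mars object.
#' @noRd
finalize_mars <- function(bases, A, y, penalty) {
  B <- vapply(bases, basis_values, numeric(nrow(A)), A = A)
  colnames(B) <- paste0("b", seq_along(bases))
  fit <- suppressWarnings(fit_ols(B, y))
  keep <- colnames(B) %in% names(fit$coef)  # aliased bases dropped in the fit
  bases <- bases[keep]
  n <- length(y)
  gcv <- mars_gcv(fit$rss, n, mars_enp(bases, penalty))
  structure(list(bases = bases[-1L], intercept_first = TRUE,
                 coefficients = stats::setNames(fit$coef,
                   vapply(bases, basis_label, "")),
                 all_bases = bases, penalty = penalty,
                 rss = fit$rss, mse = fit$rss / n,
                 r2 = 1 - fit$rss / sum((y - mean(y))^2),
                 gcv = gcv, n_obs = n,
                 enp_formula = "enp = T + penalty * n_hinge_pairs"),
            class = "cv_mars")
}

# Effective number of parameters: T terms plus penalty per distinct hinge
# pair (a pair is identified by its factor set ignoring directions).
#' @noRd
mars_enp <- function(bases, penalty) {
  nb <- bases[lengths(bases) > 0L]
  if (!length(nb)) return(1)
  sig <- vapply(nb, function(b)
    paste(sort(vapply(b, function(f) paste(f$mark, f$knot), "")),
          collapse = "|"), "")
  length(nb) + 1L + penalty * length(unique(sig))
}

#' @noRd
mars_gcv <- function(rss, n, enp) {
  if (enp >= n) return(Inf)
  (rss / n) / (1 - enp / n)^2
}

#' MARS reverse (pruning) pass
#'
#' Iteratively deletes the non-intercept basis whose removal most improves the
#' generalised cross-validation score
#' `GCV = (RSS/N) / (1 - enp/N)^2`, `enp = T + P * (number of hinge pairs)`,
#' and returns the best-GCV subset encountered (which may be the full forward
#' model). Members of a hinge pair may be deleted individually.
#'
#' @param model a `cv_mars` from [mars_forward()].
#' @param A,y the training data.
#' @param penalty GCV penalty per hinge pair (default 3).
#' @return pruned `cv_mars`; `$gcv` is the optimised score.
#' @export
mars_backward <- function(model, A, y, penalty = 3) {
  bases <- model$all_bases
  n <- length(y)
  if (mars_enp(bases, penalty) >= n)
    stop("model too large: effective parameters exceed observations")
  evaluate <- function(bs) {
    B <- vapply(bs, basis_values, numeric(n), A = A)
    fit <- suppressWarnings(fit_ols(B, y))
    mars_gcv(fit$rss, n, mars_enp(bs, penalty))
  }
  best_set <- bases
  best_gcv <- evaluate(bases)
  current <- bases
  while (length(current) > 1L) {
    gcvs <- vapply(2:length(current), function(i) evaluate(current[-i]),
                   numeric(1))
    i <- which.min(gcvs)
    current <- current[-(i + 1L)]
    if (gcvs[i] <= best_gcv) {
      best_gcv <- gcvs[i]
      best_set <- current
    }
  }
  out <- finalize_mars(best_set, A, y, penalty)
  out
}

#' Fit a MARS model (forward + reverse pass)
#'
#' @inheritParams mars_forward
#' @param penalty GCV penalty (default 3, the convention for models that allow
#'   interactions).
#' @return pruned `cv_mars`.
#' @export
fit_mars <- function(A, y, max_degree = 3L, max_terms = 21L, penalty = 3,
                     min_rss_reduction = NULL, max_knots = 20L) {
  fwd <- mars_forward(A, y, max_degree, max_terms, min_rss_reduction,
                      max_knots)
  mars_backward(fwd, A, y, penalty)
}

#' Predict from a MARS model
#'
#' @param object a `cv_mars`.
#' @param amplitudes observations x marks matrix with named columns.
#' @param ... unused.
#' @export
predict.cv_mars <- function(object, amplitudes, ...) {
  B <- vapply(object$all_bases, basis_values, numeric(nrow(amplitudes)),
              A = amplitudes)
  as.numeric(B %*% object$coefficients)
}

#' Basis table and per-mark impacts
#'
#' Per basis: hinge description, coefficient, and the number of observations
#' where the basis is non-zero. Per mark: impact = prediction with the mark at
#' its 95th amplitude percentile minus prediction at its 5th percentile, all
#' other marks held at their medians.
#'
#' @param model a `cv_mars`.
#' @param amplitudes observations x marks matrix.
#' @return list with `bases` (data.frame) and `impact` (data.frame).
#' @export
mars_report <- function(model, amplitudes) {
  nb <- model$all_bases[lengths(model$all_bases) > 0L]
  B <- if (length(nb))
    vapply(nb, basis_values, numeric(nrow(amplitudes)), A = amplitudes) else
    matrix(0, nrow(amplitudes), 0L)
  bases <- data.frame(
    basis = vapply(nb, basis_label, ""),
    degree = lengths(nb),
    coefficient = unname(model$coefficients[-1L][seq_along(nb)]),
    n_nonzero = if (length(nb)) colSums(B != 0) else integer(0),
    stringsAsFactors = FALSE)
  med <- apply(amplitudes, 2L, median)
  base_row <- matrix(med, 1L, ncol(amplitudes),
                     dimnames = list(NULL, colnames(amplitudes)))
  impact <- vapply(colnames(amplitudes), function(mk) {
    hi <- lo <- base_row
    hi[, mk] <- quantile(amplitudes[, mk], 0.95, names = FALSE)
    lo[, mk] <- quantile(amplitudes[, mk], 0.05, names = FALSE)
    predict(model, hi) - predict(model, lo)
  }, numeric(1))
  list(bases = bases,
       impact = data.frame(mark = colnames(amplitudes),
                           impact = unname(impact),
                           stringsAsFactors = FALSE))
}

#' Low/high synergy grid for a 2- or 3-mark combination
#'
#' Predictions at every combination of each listed mark at its 5th ("low") or
#' 95th ("high") amplitude percentile, all other marks at their medians.
#'
#' @param model a fitted model with a `predict` method (`cv_mars` or
#'   `cv_mlmodel`).
#' @param amplitudes observations x marks matrix.
#' @param term_marks character vector of 2 or 3 mark names.
#' @return data.frame with one row per low/high combination and a
#'   `prediction` column.
#' @export
synergy_table <- function(model, amplitudes, term_marks) {
  if (!all(term_marks %in% colnames(amplitudes)))
    stop_invalid("unknown mark in term_marks")
  if (!length(term_marks) %in% 2:3)
    stop_invalid("synergy tables are for 2- or 3-mark combinations")
  med <- apply(amplitudes, 2L, median)
  lo <- apply(amplitudes[, term_marks, drop = FALSE], 2L, quantile,
              probs = 0.05, names = FALSE)
  hi <- apply(amplitudes[, term_marks, drop = FALSE], 2L, quantile,
              probs = 0.95, names = FALSE)
  combos <- expand.grid(rep(list(c("low", "high")), length(term_marks)),
                        stringsAsFactors = FALSE)
  names(combos) <- term_marks
  preds <- vapply(seq_len(nrow(combos)), function(i) {
    row <- matrix(med, 1L, length(med), dimnames = list(NULL, names(med)))
    for (mk in term_marks)
      row[, mk] <- if (combos[i, mk] == "high") hi[mk] else lo[mk]
    predict(model, row)
  }, numeric(1))
  cbind(combos, prediction = preds)
}

#' Response curve/surface with other marks at their medians
#'
#' @param model fitted model with a `predict` method.
#' @param amplitudes observations x marks matrix.
#' @param marks 1 or 2 mark names.
#' @param grid_size points per axis (>= 2).
#' @return data.frame of grid coordinates and predictions.
#' @export
response_surface <- function(model, amplitudes, marks, grid_size = 50L) {
  if (grid_size < 2L) stop_invalid("grid_size must be >= 2")
  if (!length(marks) %in% 1:2) stop_invalid("1 or 2 marks required")
  med <- apply(amplitudes, 2L, median)
  axes <- lapply(marks, function(mk)
    seq(min(amplitudes[, mk]), max(amplitudes[, mk]), length.out = grid_size))
  names(axes) <- marks
  grid <- expand.grid(axes)
  preds <- vapply(seq_len(nrow(grid)), function(i) {
    row <- matrix(med, 1L, length(med), dimnames = list(NULL, names(med)))
    for (mk in marks) row[, mk] <- grid[i, mk]
    predict(model, row)
  }, numeric(1))
  cbind(grid, prediction = preds)
}
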