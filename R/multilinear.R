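# Multivalent multilinear model: stepwise F-test selection with the
# multi-round, survival-filtered, 10-fold cross-validated protocol.

#' Enumerate mono-, bi- and trivalent terms
#'
#' All C(n,1) + C(n,2) + C(n,3) products of distinct mark amplitudes, in a
#' canonical deterministic order (marks sorted by name within a term; terms
#' listed by valency then lexicographically), so that
#' `markA*markB == markB*markA`.
#'
#' @param marks either a character vector of mark names or a mark count (names
#'   `m01`, `m02`, ... are generated).
#' @param max_valency maximum product size (default 3).
#' @return character vector of term ids, factors joined by `"*"`.
#' @export
enumerate_terms <- function(marks, max_valency = 3L) {
  if (is.numeric(marks)) {
    if (length(marks) != 1L || marks < 1) stop_invalid("mark count must be >= 1")
    marks <- sprintf("m%02d", seq_len(marks))
  }
  if (length(marks) < 1L) stop_invalid("need at least one mark")
  if (max_valency < 1L) stop_invalid("max_valency must be >= 1")
  marks <- sort(unique(marks))
  unlist(lapply(seq_len(min(max_valency, length(marks))), function(v)
    apply(combn(marks, v), 2L, paste, collapse = "*")), use.names = FALSE)
}

#' @noRd
term_marks <- function(term_ids) strsplit(term_ids, "*", fixed = TRUE)

#' Canonicalise term ids (sort marks within each term)
#' @noRd
canonical_terms <- function(term_ids) {
  vapply(term_marks(term_ids), function(m) paste(sort(m), collapse = "*"), "")
}

#' Build the multivalent design matrix
#'
#' One column per term: the row-wise product of the named amplitude columns.
#'
#' @param amplitudes genes (or probes) x marks matrix with column names.
#' @param terms character vector of term ids (see [enumerate_terms()]).
#' @return observations x terms numeric matrix.
#' @export
build_design <- function(amplitudes, terms) {
  terms <- canonical_terms(terms)
  mk <- term_marks(terms)
  miss <- setdiff(unique(unlist(mk)), colnames(amplitudes))
  if (length(miss))
    stop_invalid("terms reference unknown marks: ", paste(miss, collapse = ", "))
  X <- vapply(mk, function(m) {
    col <- amplitudes[, m[1]]
    for (f in m[-1]) col <- col * amplitudes[, f]
    col
  }, numeric(nrow(amplitudes)))
  colnames(X) <- terms
  X
}

# OLS with coefficient t-tests via one QR decomposition.
#' @noRd
fit_ols <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    warning("dropping aliased column(s): ", paste(aliased, collapse = ", "))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    qrx <- qr(X)
  }
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se_piv <- sqrt(pmax(sigma2 * diag(chol2inv(qr.R(qrx))), 0))
  se <- numeric(ncol(X))
  se[qrx$pivot] <- se_piv  # chol2inv is in pivoted column order
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  list(coef = beta, se = se, t = tval, p = pval, rss = rss, df = df,
       sigma2 = sigma2, residuals = res,
       mse = rss / nrow(X),
       adj_r2 = 1 - (rss / max(df, 1)) / (tss / (nrow(X) - 1)))
}

# Partial-F entry p-values for every excluded column, vectorised against an
# explicit orthonormal basis Q of the current model.
#' @noRd
entry_scan <- function(Q, r, rss, df_new, Xe) {
  Xp <- Xe - Q %*% crossprod(Q, Xe)
  d <- colSums(Xp^2)
  num <- colSums(Xp * r)^2 / d
  valid <- d > 1e-9 * pmax(colSums(Xe^2), 1e-300)
  fstat <- num / ((rss - num) / df_new)
  p <- pf(fstat, 1, df_new, lower.tail = FALSE)
  p[!is.finite(p)] <- 1        # perfect fit: nothing left to explain
  p[!valid] <- 1               # aliased with current model
  list(p = p, f = fstat, Xp = Xp, d = d)
}

# Backward elimination by rank-one downdating of (X'X)^{-1}: one QR
# factorisation, then O(k^2) updates per removal. Column 1 (intercept) is
# protected. Returns the kept column names and final fit statistics.
#' @noRd
ols_backward_downdate <- function(Xc, y, alpha) {
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    aliased <- colnames(Xc)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(Xc))]]
    warning("dropping aliased column(s): ", paste(aliased, collapse = ", "))
    Xc <- Xc[, setdiff(colnames(Xc), aliased), drop = FALSE]
    qrx <- qr(Xc)
  }
  k <- ncol(Xc)
  n <- nrow(Xc)
  beta <- qr.coef(qrx, y)
  rss <- sum(qr.resid(qrx, y)^2)
  Mp <- chol2inv(qr.R(qrx))
  M <- matrix(NA_real_, k, k)
  M[qrx$pivot, qrx$pivot] <- Mp
  keep <- colnames(Xc)
  df <- n - k
  repeat {
    if (length(keep) <= 1L) break
    sigma2 <- rss / max(df, 1L)
    se2 <- sigma2 * diag(M)
    tstat2 <- beta^2 / pmax(se2, 1e-300)
    p <- pf(tstat2, 1, max(df, 1L), lower.tail = FALSE)
    p[1L] <- 0  # intercept protected
    worst <- which.max(p)
    if (p[worst] <= alpha || df < 1L) break
    mj <- M[, worst]
    mjj <- mj[worst]
    if (mjj <= 0) break
    rss <- rss + beta[worst]^2 / mjj
    beta <- beta[-worst] - mj[-worst] * beta[worst] / mjj
    M <- M[-worst, -worst, drop = FALSE] -
      tcrossprod(mj[-worst]) / mjj
    keep <- keep[-worst]
    df <- df + 1L
  }
  sigma2 <- rss / max(df, 1L)
  se <- sqrt(pmax(sigma2 * diag(M), 0))
  names(beta) <- names(se) <- keep
  tval <- beta / se
  list(keep = keep, beta = beta, se = se, t = tval,
       p = 2 * pt(abs(tval), max(df, 1L), lower.tail = FALSE),
       rss = rss, df = df, sigma2 = sigma2)
}

#' Stepwise multilinear fit
#'
#' Forward steps add the candidate with the smallest partial-F p-value while
#' any is `<= alpha_enter`; a backward pass then removes the least significant
#' included term while any has `p > alpha_remove`; the two passes alternate
#' until no change. The intercept is always included. Deterministic given its
#' inputs: entry ties are broken by larger F, then canonical term order.
#'
#' @param design observations x candidate-terms matrix (named columns; see
#'   [build_design()]).
#' @param response numeric response (log2 expression).
#' @param candidate_terms candidate pool (default: all design columns).
#' @param initial_terms starting model: a character vector of term ids, or an
#'   integer count of terms to sample at random (then `seed` matters).
#' @param alpha_enter,alpha_remove F-test thresholds (defaults 0.05).
#' @param seed used only to sample a random initial model.
#' @param max_iter safety cap on forward/backward alternations.
#' @return object of class `cv_stepwise`: list with `terms`, `beta`, `se`,
#'   `z`, `p`, `mse`, `adj_r2`, `rss`, `sigma2`, `n`.
#' @export
stepwise_fit <- function(design, response, candidate_terms = colnames(design),
                         initial_terms = character(),
                         alpha_enter = 0.05, alpha_remove = 0.05,
                         seed = 1L, max_iter = 400L) {
  n <- length(response)
  if (is.numeric(initial_terms) && length(initial_terms) == 1L) {
    k <- min(initial_terms, length(candidate_terms))
    initial_terms <- with_seed(seed, sample(candidate_terms, k))
  }
  if (n <= length(initial_terms) + 2L)
    stop_invalid("need more observations than initial terms + 2")
  # degenerate (constant / all-zero) candidate columns are unusable
  usable <- candidate_terms[apply(design[, candidate_terms, drop = FALSE], 2L,
                                  function(x) stats::var(x) > 0)]
  if (length(usable) < length(candidate_terms))
    message("dropping ", length(candidate_terms) - length(usable),
            " constant candidate column(s)")
  S <- intersect(initial_terms, usable)
  seen <- new.env(hash = TRUE)

  backward <- function(S) {
    if (!length(S)) return(S)
    fit <- ols_backward_downdate(
      cbind(`(Intercept)` = 1, design[, S, drop = FALSE]), response,
      alpha_remove)
    setdiff(fit$keep, "(Intercept)")
  }

  # orthonormal basis of the current model (intercept + S), refreshed after
  # every backward phase; forward additions extend it by Gram-Schmidt
  refresh <- function(S) {
    qrx <- qr(cbind(`(Intercept)` = 1, design[, S, drop = FALSE]))
    qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  }

  iter <- 0L
  Q <- refresh(S)
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    r <- as.numeric(response - Q %*% crossprod(Q, response))
    rss <- sum(r^2)
    # forward: add while something enters
    repeat {
      df_new <- n - ncol(Q) - 1L
      if (df_new < 1L) break
      E <- setdiff(usable, S)
      if (!length(E)) break
      sc <- entry_scan(Q, r, rss, df_new, design[, E, drop = FALSE])
      if (min(sc$p) > alpha_enter) break
      best <- which(sc$p == min(sc$p))
      if (length(best) > 1L) best <- best[which.max(sc$f[best])]
      S <- c(S, E[best])
      q <- sc$Xp[, best]
      q <- q - Q %*% crossprod(Q, q)  # second orthogonalisation pass
      q <- q / sqrt(sum(q^2))
      Q <- cbind(Q, q)
      r <- as.numeric(r - q * sum(q * r))
      rss <- sum(r^2)
      changed <- TRUE
    }
    S2 <- backward(S)
    if (!setequal(S2, S)) changed <- TRUE
    S <- S2
    Q <- refresh(S)
    key <- paste0(".", paste(sort(S), collapse = "|"))
    if (!changed || iter >= max_iter) break
    if (!is.null(seen[[key]])) break  # oscillation guard
    seen[[key]] <- TRUE
  }

  fit <- fit_ols(cbind(`(Intercept)` = 1, design[, S, drop = FALSE]), response)
  structure(list(terms = S, beta = fit$coef, se = fit$se,
                 z = fit$coef / fit$se, p = fit$p, rss = fit$rss,
                 sigma2 = fit$sigma2, mse = fit$mse, adj_r2 = fit$adj_r2,
                 n = n), class = "cv_stepwise")
}

#' Round-1 term survival filtering
#'
#' Runs the stepwise fit `n_runs` times on the full data from random initial
#' models; a term's survival rate is the fraction of converged models
#' containing it. Terms at or above `cutoff` survive to the next round.
#'
#' @inheritParams stepwise_fit
#' @param n_runs number of randomly seeded runs (default 100).
#' @param cutoff survival-rate cutoff (default 0.35).
#' @param init_size size of each random initial model (default 30).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @return list with `rates` (named vector), `surviving`, `n_runs`, `cutoff`,
#'   and `null_tail` - the Binomial(n_runs, mean model size / n candidates)
#'   tail probability of each observed rate, a diagnostic for the survival
#'   null (not a calibrated test).
#' @export
round1_survival <- function(design, response, candidate_terms = colnames(design),
                            n_runs = 100L, cutoff = 0.35, init_size = 30L,
                            seed = 1L) {
  if (n_runs < 2L) stop_invalid("n_runs must be >= 2")
  counts <- stats::setNames(numeric(length(candidate_terms)), candidate_terms)
  sizes <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- stepwise_fit(design, response, candidate_terms,
                        initial_terms = init_size,
                        seed = child_seed(seed, "round1", r))
    counts[fit$terms] <- counts[fit$terms] + 1
    sizes[r] <- length(fit$terms)
  }
  rates <- counts / n_runs
  p_incl <- mean(sizes) / length(candidate_terms)
  null_tail <- stats::pbinom(round(rates * n_runs) - 1, n_runs, p_incl,
                             lower.tail = FALSE)
  list(rates = rates, surviving = names(rates)[rates >= cutoff],
       n_runs = n_runs, cutoff = cutoff, mean_model_size = mean(sizes),
       null_tail = null_tail)
}

# Backward-only pruning of a fixed term set against held-out data.
#' @noRd
backward_prune <- function(design, response, terms, alpha = 0.05) {
  S <- terms
  if (length(response) <= length(S) + 2L)
    stop("fold too small to assess ", length(S), " terms on ",
         length(response), " held-out observations; increase fold size")
  if (!length(S)) return(S)
  fit <- ols_backward_downdate(
    cbind(`(Intercept)` = 1, design[, S, drop = FALSE]), response, alpha)
  setdiff(fit$keep, "(Intercept)")
}

#' Cross-validated stepwise protocol
#'
#' For each of `n_folds` folds: `runs_per_fold` stepwise fits on the training
#' rows, each seeded with `starting_terms` plus `extra_random_terms` randomly
#' drawn candidates; each converged model is pruned by a backward-only pass on
#' the fold's held-out rows (terms with held-out p > 0.05 removed); the
#' pruned model with the lowest held-out MSE is kept for the fold. Terms
#' appearing in at least `retention` of the kept models enter the final model,
#' whose coefficients are the per-coefficient trimmed means (single min and
#' max dropped) of refits on each fold's training rows.
#'
#' @inheritParams stepwise_fit
#' @param starting_terms terms seeding every run (e.g. round-1 survivors).
#' @param n_folds number of folds (default 10).
#' @param runs_per_fold stepwise runs per fold (default 10).
#' @param extra_random_terms random candidates added to each run's initial
#'   model (default 60).
#' @param retention minimum number of kept models containing a term
#'   (default 5).
#' @param gene_ids optional per-observation gene ids; folds are assigned by
#'   gene so probes of one gene never straddle train/test.
#' @param seed master seed.
#' @return object of class `cv_mlmodel`: `terms`, `beta` (trimmed means,
#'   intercept first), per-fold coefficient/Z/p matrices, per-fold train/test
#'   MSE and adjusted R-squared, and protocol metadata.
#' @export
cv_protocol <- function(design, response, candidate_terms = colnames(design),
                        starting_terms = character(), n_folds = 10L,
                        runs_per_fold = 10L, extra_random_terms = 60L,
                        retention = 5L, gene_ids = NULL, seed = 1L) {
  n <- length(response)
  init_size <- length(starting_terms) + extra_random_terms
  if (n / max(init_size, 1L) < 10)
    warning("fewer than 10 observations per initial term; fits may be unstable")
  ids <- gene_ids %||% seq_len(n)
  genes <- unique(ids)
  fold_of_gene <- with_seed(child_seed(seed, "folds"), {
    f <- rep(seq_len(n_folds), length.out = length(genes))
    stats::setNames(sample(f), genes)
  })
  fold <- fold_of_gene[as.character(ids)]

  kept_models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    best <- NULL
    for (r in seq_len(runs_per_fold)) {
      sd_r <- child_seed(seed, "fold", f, "run", r)
      extra <- with_seed(sd_r, sample(setdiff(candidate_terms, starting_terms),
                                      min(extra_random_terms,
                                          length(candidate_terms) -
                                            length(starting_terms))))
      m <- stepwise_fit(design[tr, , drop = FALSE], response[tr],
                        candidate_terms,
                        initial_terms = c(starting_terms, extra), seed = sd_r)
      pruned <- backward_prune(design[te, , drop = FALSE], response[te],
                               m$terms)
      refit <- suppressWarnings(fit_ols(
        cbind(`(Intercept)` = 1, design[tr, pruned, drop = FALSE]),
        response[tr]))
      pruned <- setdiff(names(refit$coef), "(Intercept)")
      pred_te <- cbind(1, design[te, pruned, drop = FALSE]) %*% refit$coef
      test_mse <- mean((response[te] - pred_te)^2)
      if (is.null(best) || test_mse < best$test_mse)
        best <- list(terms = pruned, test_mse = test_mse)
    }
    kept_models[[f]] <- best$terms
  }

  tab <- table(unlist(kept_models))
  retained <- sort(names(tab)[tab >= retention])
  meta <- list(n_folds = n_folds, runs_per_fold = runs_per_fold,
               extra_random_terms = extra_random_terms, retention = retention,
               retention_rule = "counted across the one lowest-test-MSE model kept per fold",
               trim_rule = "drop single min and max across folds", seed = seed)
  if (!length(retained)) {
    message("no term reached the retention threshold; returning the empty ",
            "(intercept-only) model")
    return(structure(list(terms = character(), beta = c(`(Intercept)` = mean(response)),
                          fold_beta = NULL, fold_z = NULL, fold_p = NULL,
                          train_mse = NA, test_mse = NA,
                          train_adj_r2 = NA, test_adj_r2 = NA,
                          kept_models = kept_models, empty = TRUE,
                          meta = meta), class = "cv_mlmodel"))
  }

  cn <- c("(Intercept)", retained)
  fold_beta <- fold_z <- fold_p <- matrix(NA_real_, n_folds, length(cn),
                                          dimnames = list(NULL, cn))
  train_mse <- test_mse <- train_r2 <- test_r2 <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    if (sum(te) <= length(retained) + 2L)
      stop("fold too small to refit the retained model; increase fold size")
    fit <- suppressWarnings(fit_ols(
      cbind(`(Intercept)` = 1, design[tr, retained, drop = FALSE]),
      response[tr]))
    fold_beta[f, names(fit$coef)] <- fit$coef
    fold_z[f, names(fit$coef)] <- fit$coef / fit$se
    fold_p[f, names(fit$coef)] <- fit$p
    pred_te <- cbind(1, design[te, retained, drop = FALSE]) %*%
      fit$coef[cn]
    train_mse[f] <- fit$mse
    train_r2[f] <- fit$adj_r2
    rss_te <- sum((response[te] - pred_te)^2)
    test_mse[f] <- rss_te / sum(te)
    df_te <- sum(te) - length(cn)
    tss_te <- sum((response[te] - mean(response[te]))^2)
    test_r2[f] <- 1 - (rss_te / max(df_te, 1)) / (tss_te / (sum(te) - 1))
  }
  beta <- apply(fold_beta, 2L, trimmed_mean)
  structure(list(terms = retained, beta = beta, fold_beta = fold_beta,
                 fold_z = fold_z, fold_p = fold_p,
                 train_mse = train_mse, test_mse = test_mse,
                 train_adj_r2 = train_r2, test_adj_r2 = test_r2,
                 kept_models = kept_models, empty = FALSE, meta = meta),
            class = "cv_mlmodel")
}

#' Predict log2 expression from a fitted multilinear model
#'
#' @param object a `cv_mlmodel`.
#' @param amplitudes genes x marks matrix with named columns.
#' @param ... unused.
#' @export
predict.cv_mlmodel <- function(object, amplitudes, ...) {
  if (!length(object$terms))
    return(rep(unname(object$beta["(Intercept)"]), nrow(amplitudes)))
  X <- cbind(`(Intercept)` = 1, build_design(amplitudes, object$terms))
  as.numeric(X %*% object$beta[colnames(X)])
}

#' Term statistics table (coefficients, Z, impact)
#'
#' Per retained term: trimmed-mean coefficient and Z-score across folds,
#' median fold p-value, and the impact factor `beta x IQR(regressor)`; rows
#' sorted by decreasing impact, with an activating/repressing label from the
#' coefficient sign.
#'
#' @param model a `cv_mlmodel`.
#' @param amplitudes genes x marks matrix used to evaluate regressor IQRs.
#' @return data.frame with columns `term`, `valency`, `beta`, `z`, `p_median`,
#'   `iqr`, `impact`, `direction`.
#' @export
term_statistics <- function(model, amplitudes) {
  if (!length(model$terms))
    return(data.frame(term = character(), valency = integer(),
                      beta = numeric(), z = numeric(), p_median = numeric(),
                      iqr = numeric(), impact = numeric(),
                      direction = character()))
  X <- build_design(amplitudes, model$terms)
  beta <- model$beta[model$terms]
  z <- apply(model$fold_z[, model$terms, drop = FALSE], 2L, trimmed_mean)
  pmed <- apply(model$fold_p[, model$terms, drop = FALSE], 2L, median)
  iqr <- apply(X, 2L, IQR)
  impact <- beta * iqr
  out <- data.frame(term = model$terms,
                    valency = lengths(term_marks(model$terms)),
                    beta = unname(beta), z = unname(z),
                    p_median = unname(pmed), iqr = unname(iqr),
                    impact = unname(impact),
                    direction = ifelse(beta >= 0, "activating", "repressing"),
                    stringsAsFactors = FALSE)
  out[order(-out$impact), , drop = FALSE]
}
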