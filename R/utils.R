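#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cv_invalid_argument", "error")))
}

#' Evaluate code with a temporary RNG state
#'
#' All stochastic operations in the package take an explicit `seed`; the
#' global RNG stream of the caller is left untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a master seed and a stage label.
# Kept below 2^31 - 1; R integers are 32-bit.
#' @noRd
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Trimmed mean across folds: drop the single smallest and single largest
# value, then average (20% total trim on 10 values).
#' @noRd
trimmed_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) <= 2L) return(mean(x))
  mean(sort(x)[-c(1L, length(x))])
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
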