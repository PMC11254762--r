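# Internal numeric and RNG helpers shared across modules.

# Largest representable R integer seed; sub-seeds stay below this.
.MAX_SEED <- 2147483646L

#' Derive a stream of reproducible sub-seeds from one master seed
#'
#' All stochastic stages draw their own seed from a single integer via this
#' splitting scheme, so that a pipeline run is fully determined by one seed
#' while stages remain independently reproducible.
#'
#' @param seed Single integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.MAX_SEED, as.integer(n))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Row-wise L2 normalization; errors on zero-norm rows.
unit_rows <- function(m, what = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) {
    stop("cannot normalize: ", what, " with zero or non-finite norm", call. = FALSE)
  }
  m / nrm
}

# Cosine similarity between rows of a and rows of b (assumed unit-norm).
cosine_sim <- function(a, b) tcrossprod(a, b)

# Full pairwise cosine distance matrix for unit-norm rows.
cosine_dist_matrix <- function(m) {
  d <- 1 - tcrossprod(m)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Lower-triangle vector of unordered pair values from a symmetric matrix.
lower_tri <- function(m) m[lower.tri(m)]

# Mean and symmetric 95% t confidence interval.
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}
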