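# Shared fixtures and independent brute-force oracles for the test suite.
# Fixtures are generated in code; sessions used by several files are cached
# per test run.

# A reduced-scale generator configuration used where study-scale sizes are
# not the point of the test.
small_cfg <- function(...) {
  cfg <- generator_config(
    words_per_domain = 12L, dim = 50L, n_sentences = 60L, n_units = 80L,
    story_blocks = 15L, homophone_pairs = 6L, homophone_occurrences = 6L,
    nonword_blocks = 3L
  )
  modifyList(cfg, list(...))
}

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key = "default", cfg = small_cfg(), seed = 7L) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- generate_session(cfg, seed = seed)
  }
  .session_cache[[key]]
}

cached_sentence_matrix <- function(key = "default", ...) {
  rkey <- paste0(key, "_rm")
  if (is.null(.session_cache[[rkey]])) {
    s <- cached_session(key, ...)
    .session_cache[[rkey]] <- select_events(
      align_responses(s$spikes, s$events), condition == "sentence")
  }
  .session_cache[[rkey]]
}

# random embedding table fixture
random_embeddings <- function(n, d, seed = 1) {
  set.seed(seed)
  embedding_tbl(sprintf("t%02d", seq_len(n)), matrix(rnorm(n * d), n))
}

# Brute-force per-point silhouette under an arbitrary distance matrix.
silhouette_brute <- function(assignment, dmat) {
  n <- length(assignment)
  vapply(seq_len(n), function(i) {
    own <- assignment[[i]]
    a <- mean(dmat[i, setdiff(which(assignment == own), i)])
    b <- min(vapply(setdiff(unique(assignment), own), function(cl) {
      mean(dmat[i, assignment == cl])
    }, numeric(1)))
    if (is.nan(a)) return(0)  # singleton cluster convention
    (b - a) / max(a, b)
  }, numeric(1))
}

# O(n^3) brute-force single-linkage agglomeration returning the full
# cophenetic distance matrix.
single_linkage_brute <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d_ij <- min(dmat[clusters[[i]], clusters[[j]]])
        if (d_ij < best[[1L]]) best <- c(d_ij, j, i)
      }
    }
    a <- clusters[[best[[2L]]]]
    b <- clusters[[best[[3L]]]]
    coph[a, b] <- best[[1L]]
    coph[b, a] <- best[[1L]]
    clusters[[best[[2L]]]] <- c(a, b)
    clusters[[best[[3L]]]] <- NULL
  }
  coph
}

# Hand step-up Benjamini-Hochberg adjustment.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Exact primal minimizer of the linear soft-margin objective on a toy
# problem (via quasi-Newton on the convex hinge loss), used as the
# independent margin-classifier oracle.
svm_primal_oracle <- function(x, y, C, w_pos = 1, w_neg = 1) {
  obj <- function(par) {
    w <- par[-length(par)]
    b <- par[[length(par)]]
    margins <- y * (x %*% w + b)
    cw <- ifelse(y > 0, w_pos, w_neg)
    0.5 * sum(w^2) + C * sum(cw * pmax(0, 1 - margins))
  }
  fit <- optim(rep(0, ncol(x) + 1L), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-12))
  list(w = fit$par[-length(fit$par)], b = fit$par[[length(fit$par)]],
       value = fit$value)
}

# A minimal language model stub with fixed conditional probability,
# exercising the pluggable model interface.
const_lm <- function(p) structure(list(p = p), class = "const_lm")
conditional_prob.const_lm <- function(lm, word, prefix = character(0)) lm$p
registerS3method("conditional_prob", "const_lm", conditional_prob.const_lm,
                 envir = asNamespace("semspike"))
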