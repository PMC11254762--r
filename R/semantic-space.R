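# The neuronal-semantic space: per-neuron ridge regressions onto word
# embeddings, PCA of the stacked weights, word projections, distance
# correlations against embedding geometry, and the cophenetic hierarchy.

#' Regress each unit's responses onto word embeddings
#'
#' Models each unit's normalized per-word firing rate as a linear function
#' of the word's embedding vector, `F_w = v_w theta + eps`, solving the
#' ridge-penalized normal equations `(V'V + lambda I) theta = V'F` per unit.
#' The per-word response is the mean z-scored rate over that word's events;
#' a non-z-scored matrix is z-scored internally. Embedding words without
#' events are dropped from the design and logged.
#'
#' @param rm A `response_matrix`.
#' @param emb An [embedding_tbl()].
#' @param lambda Ridge penalty (default `1e-4`).
#' @return `units x dim` coefficient matrix with attributes `lambda` and
#'   `words` (the design vocabulary).
#' @export
fit_embedding_regression <- function(rm, emb, lambda = 1e-4) {
  stopifnot(inherits(rm, "response_matrix"), inherits(emb, "embedding_tbl"),
            lambda >= 0)
  if (!rm$zscored) {
    message("z-scoring rates per unit before regression")
    rm <- zscore_units(rm)
  }
  tokens <- unique(rm$events$token)
  words <- intersect(emb$words, tokens)
  dropped <- setdiff(emb$words, tokens)
  if (length(dropped)) {
    message(length(dropped), " embedding word(s) without events dropped from design")
  }
  if (length(words) < 2L) stop("fewer than 2 design words", call. = FALSE)
  f <- word_mean_rates(rm, words)              # units x words
  v <- unit_rows(emb$vectors)[words, , drop = FALSE]  # words x dim
  theta <- t(solve(crossprod(v) + lambda * diag(ncol(v)), crossprod(v, t(f))))
  rownames(theta) <- rownames(rm$rates)
  attr(theta, "lambda") <- lambda
  attr(theta, "words") <- words
  theta
}

#' Principal-component reduction of the neuronal-semantic space
#'
#' Reduces the stacked `units x dim` coefficient matrix along the neuronal
#' dimension: units are observations, embedding dimensions variables, so each
#' principal component is a direction in embedding space (length `dim`).
#' Words are placed in the reduced space by projecting their embedding
#' vectors on each component.
#'
#' @param theta Coefficient matrix from [fit_embedding_regression()].
#' @param emb An [embedding_tbl()] supplying the words to project (defaults
#'   to the design words stored on `theta`).
#' @param n_pc Number of components to keep (default 5; truncated with a
#'   warning if it exceeds the rank).
#' @return An object of class `semantic_space`: `theta`, `pcs`
#'   (`dim x n_pc`), `explained_variance`, `projections`
#'   (`words x n_pc`), `lambda`.
#' @export
pca_space <- function(theta, emb, n_pc = 5L) {
  stopifnot(is.matrix(theta), inherits(emb, "embedding_tbl"))
  pc <- prcomp(theta, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_pc > rank) {
    warning("n_pc truncated to rank ", rank, call. = FALSE)
    n_pc <- rank
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  pcs <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  proj <- unit_rows(emb$vectors) %*% pcs
  structure(
    list(theta = theta, pcs = pcs, explained_variance = ev[seq_len(n_pc)],
         total_variance_explained = sum(ev[seq_len(n_pc)]),
         projections = proj, lambda = attr(theta, "lambda"), n_pc = n_pc),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space> ", nrow(x$theta), " units, ", x$n_pc,
      " PCs explaining ", sprintf("%.1f%%", 100 * x$total_variance_explained),
      " of weight variance; ", nrow(x$projections), " word projections\n",
      sep = "")
  invisible(x)
}

#' Correlation between projection-space and embedding-space word distances
#'
#' Pearson correlation over all unordered word pairs between cosine
#' distances of the neuronal word projections and cosine distances of the
#' original embedding vectors, with a permutation p-value obtained by
#' shuffling word identity of the projections.
#'
#' @param space A `semantic_space`.
#' @param emb The [embedding_tbl()] (vocabulary must cover the projections).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List: `r`, `p_value`, `n_pairs`, `null`.
#' @export
distance_correlation <- function(space, emb, n_perm = 1000L, seed = NULL,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .set_seed_if(seed)
  words <- intersect(rownames(space$projections), emb$words)
  if (length(words) < 3L) stop("need at least 3 shared words", call. = FALSE)
  dp <- cosine_dist_matrix(unit_rows(space$projections[words, , drop = FALSE]))
  de <- cosine_dist_matrix(unit_rows(emb$vectors[words, , drop = FALSE]))
  v_e <- lower_tri(de)
  r <- cor(lower_tri(dp), v_e)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(length(words))
    cor(lower_tri(dp[p, p]), v_e)
  }, numeric(1))
  p_val <- if (alternative == "greater") {
    (1 + sum(null >= r)) / (1 + n_perm)
  } else {
    (1 + sum(abs(null) >= abs(r))) / (1 + n_perm)
  }
  list(r = r, p_value = p_val, n_pairs = length(v_e), null = null)
}

# population |rate difference| per word pair from per-word mean rates
.pair_rate_diff <- function(rm, words) {
  if (!rm$zscored) rm <- zscore_units(rm)
  wr <- word_mean_rates(rm, words)       # units x words
  pop <- colMeans(wr)                    # population-average normalized rate
  abs(outer(pop, pop, `-`))
}

# percentile-bin x and average y within bins; empty/duplicate bins merge
bin_means <- function(x, y, bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 3L) stop("too few distinct values to bin", call. = FALSE)
  g <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  tibble(bin = sort(unique(g)),
         x = as.numeric(tapply(x, g, mean)),
         y = as.numeric(tapply(y, g, mean)))
}

#' Correlation of neuronal activity differences with embedding distances
#'
#' For every unordered word pair, relates the absolute difference in
#' population-averaged normalized firing rate to the cosine distance of the
#' two words' embedding vectors, after percentile-binning the pairs by
#' embedding distance. Significance is a one-sided permutation test
#' shuffling the word-to-rate mapping.
#'
#' @param rm A `response_matrix`.
#' @param emb An [embedding_tbl()].
#' @param bins Number of percentile bins (default 100).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @return List: `r`, `p_value`, `binned` tibble, `n_pairs`.
#' @export
rate_distance_correlation <- function(rm, emb, bins = 100L, n_perm = 1000L,
                                      seed = NULL) {
  stopifnot(inherits(rm, "response_matrix"), inherits(emb, "embedding_tbl"))
  .set_seed_if(seed)
  words <- intersect(emb$words, unique(rm$events$token))
  if (length(words) < 3L) stop("need at least 3 words", call. = FALSE)
  de <- cosine_dist_matrix(unit_rows(emb$vectors[words, , drop = FALSE]))
  dr <- .pair_rate_diff(rm, words)
  x <- lower_tri(de)
  y <- lower_tri(dr)
  binned <- bin_means(x, y, bins)
  r <- cor(binned$x, binned$y)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(length(words))
    cor(binned$x, bin_means(x, lower_tri(dr[p, p]), bins)$y)
  }, numeric(1))
  list(r = r, p_value = (1 + sum(null >= r)) / (1 + n_perm),
       binned = binned, n_pairs = length(x))
}

#' Cophenetic hierarchy of word meanings versus neuronal activity
#'
#' Builds a single-linkage (nearest-neighbour) dendrogram over the words'
#' embedding-space cosine distances; the cophenetic distance of a word pair
#' is the merge height at which the two words first join one cluster (always
#' an ultrametric). The analysis then correlates percentile-binned
#' cophenetic distances with the absolute difference in population-averaged
#' normalized firing rate, with a one-sided permutation p. Words are sorted
#' lexicographically before clustering so distance ties resolve
#' deterministically.
#'
#' @param emb An [embedding_tbl()].
#' @param rm A `response_matrix` (typically restricted to the semantically
#'   selective units).
#' @param bins Number of percentile bins (default 100).
#' @param n_perm Permutations for the correlation p-value (default 1000).
#' @param sessions Optional named list of per-session `response_matrix`
#'   objects; each is analysed with finer binning and 2.5 x IQR outlier-bin
#'   exclusion, yielding a per-session correlation distribution.
#' @param session_bins Bin count for per-session correlations (default 200).
#' @param seed Optional seed.
#' @return An object of class `cophenetic_hierarchy`: `hclust` tree,
#'   `cophenetic` (dist), `r`, `p_value`, `binned`, and optionally
#'   `per_session`.
#' @export
cophenetic_hierarchy <- function(emb, rm, bins = 100L, n_perm = 1000L,
                                 sessions = NULL, session_bins = 200L,
                                 seed = NULL) {
  stopifnot(inherits(emb, "embedding_tbl"), inherits(rm, "response_matrix"))
  .set_seed_if(seed)
  words <- sort(intersect(emb$words, unique(rm$events$token)))
  if (length(words) < 3L) stop("need at least 3 words", call. = FALSE)
  de <- cosine_dist_matrix(unit_rows(emb$vectors[words, , drop = FALSE]))
  hc <- hclust(stats::as.dist(de), method = "single")
  coph <- cophenetic(hc)
  cmat <- as.matrix(coph)[words, words]
  x <- lower_tri(cmat)
  corr_for <- function(rmat, nb, drop_outliers = FALSE) {
    y <- lower_tri(.pair_rate_diff(rmat, words))
    b <- bin_means(x, y, nb)
    if (drop_outliers) {
      qs <- quantile(b$y, c(0.25, 0.75))
      iqr <- diff(qs)
      b <- b[b$y >= qs[[1L]] - 2.5 * iqr & b$y <= qs[[2L]] + 2.5 * iqr, ]
    }
    list(r = cor(b$x, b$y), binned = b)
  }
  obs <- corr_for(rm, bins)
  dr <- .pair_rate_diff(rm, words)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(length(words))
    cor(obs$binned$x, bin_means(x, lower_tri(dr[p, p]), bins)$y)
  }, numeric(1))
  per_session <- NULL
  if (!is.null(sessions)) {
    per_session <- tibble(
      session = names(sessions) %||% as.character(seq_along(sessions)),
      r = vapply(sessions, function(s) {
        corr_for(s, session_bins, drop_outliers = TRUE)$r
      }, numeric(1))
    )
  }
  structure(
    list(hclust = hc, cophenetic = coph, r = obs$r,
         p_value = (1 + sum(null >= obs$r)) / (1 + n_perm),
         binned = obs$binned, per_session = per_session,
         n_words = length(words)),
    class = "cophenetic_hierarchy"
  )
}

#' @export
print.cophenetic_hierarchy <- function(x, ...) {
  cat("<cophenetic_hierarchy> ", x$n_words, " words; binned r = ",
      sprintf("%.3f", x$r), ", permutation p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Leaf labels are words; branch lengths are merge-height increments.
#'
#' @param x A `cophenetic_hierarchy` (or an `hclust`).
#' @param path Output file path.
#' @export
export_dendrogram_newick <- function(x, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  hc <- if (inherits(x, "cophenetic_hierarchy")) x$hclust else x
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
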