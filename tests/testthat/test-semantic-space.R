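rm_from_word_rates <- function(rates_by_word) {
  # one event per word, rates given as units x words
  n <- ncol(rates_by_word)
  events <- tibble::tibble(
    event_id = seq_len(n), token = colnames(rates_by_word),
    onset = seq_len(n) * 0.4, condition = "sentence",
    sentence_id = rep(seq_len(ceiling(n / 4)), each = 4L)[seq_len(n)],
    position = 1L, domain = 1L
  )
  structure(list(rates = rates_by_word, events = events,
                 window = c(0.1, 0.5), zscored = TRUE),
            class = "response_matrix")
}

test_that("the ridge solution matches hand-solved normal equations on a toy system", {
  v <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))  # 3 words x 2 dims
  emb <- embedding_tbl(c("a", "b", "c"), v, normalize = FALSE)
  f <- matrix(c(1, 2, 3), 1, dimnames = list("u1", NULL))
  colnames(f) <- c("a", "b", "c")
  rm1 <- rm_from_word_rates(f)
  lambda <- 0.1
  theta <- fit_embedding_regression(rm1, emb, lambda = lambda)
  hand <- solve(t(v) %*% v + lambda * diag(2), t(v) %*% c(1, 2, 3))
  expect_equal(unname(theta["u1", ]), drop(hand))
})

test_that("ridge recovers planted coefficients and approaches OLS as lambda -> 0", {
  set.seed(3)
  v <- matrix(rnorm(40 * 6), 40)
  v <- v / sqrt(rowSums(v^2))
  emb <- embedding_tbl(sprintf("w%02d", 1:40), v, normalize = FALSE)
  theta_star <- rnorm(6)
  f <- matrix(v %*% theta_star, 1, dimnames = list("u1", emb$words))
  rm1 <- rm_from_word_rates(f)
  theta <- fit_embedding_regression(rm1, emb, lambda = 1e-8)
  expect_lt(max(abs(theta["u1", ] - theta_star)), 1e-6)

  # continuity in lambda and the OLS limit
  ols <- solve(crossprod(v), crossprod(v, drop(f)))
  th1 <- fit_embedding_regression(rm1, emb, lambda = 1e-6)
  th2 <- fit_embedding_regression(rm1, emb, lambda = 2e-6)
  expect_lt(max(abs(th1["u1", ] - drop(ols))), 1e-4)
  expect_lt(max(abs(th1 - th2)), 1e-5)
})

test_that("PCA of the weight matrix matches an eigen-decomposition oracle", {
  set.seed(5)
  theta <- matrix(rnorm(30 * 8), 30)
  emb <- random_embeddings(12, 8, seed = 2)
  sp <- pca_space(theta, emb, n_pc = 3)
  ev_oracle <- eigen(stats::cov(theta), symmetric = TRUE)$values
  ev_oracle <- ev_oracle / sum(ev_oracle)
  expect_equal(unname(sp$explained_variance), ev_oracle[1:3],
               tolerance = 1e-10)
  expect_equal(dim(sp$pcs), c(8L, 3L))
  expect_equal(dim(sp$projections), c(12L, 3L))

  # rank-1 weights: one component carries all variance
  theta1 <- outer(rnorm(20), rnorm(8))
  expect_warning(sp1 <- pca_space(theta1, emb, n_pc = 3), "truncated")
  expect_equal(sp1$explained_variance[[1]], 1, tolerance = 1e-10)
})

test_that("projection-distance correlation is exact for identity and rotation-invariant", {
  emb <- random_embeddings(15, 4, seed = 7)
  sp <- list(projections = emb$vectors, n_pc = 4)
  class(sp) <- "semantic_space"
  dc <- distance_correlation(sp, emb, n_perm = 50, seed = 1)
  expect_equal(dc$r, 1, tolerance = 1e-12)
  expect_equal(dc$n_pairs, choose(15, 2))

  # orthogonal rotation of the projection space leaves r unchanged
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  sp_rot <- sp
  sp_rot$projections <- emb$vectors %*% q
  dc_rot <- distance_correlation(sp_rot, emb, n_perm = 50, seed = 1)
  expect_equal(dc_rot$r, dc$r, tolerance = 1e-9)

  # independent projections: small r, non-significant
  sp_rand <- sp
  set.seed(9)
  sp_rand$projections <- matrix(rnorm(60), 15,
                                dimnames = list(emb$words, NULL))
  dc0 <- distance_correlation(sp_rand, emb, n_perm = 200, seed = 2)
  expect_lt(abs(dc0$r), 0.35)
  expect_gt(dc0$p_value, 0.05)
})

test_that("pair binning matches a quantile oracle", {
  set.seed(10)
  x <- runif(200)
  y <- 2 * x + rnorm(200, sd = 0.1)
  b <- semspike:::bin_means(x, y, 10)
  br <- quantile(x, probs = seq(0, 1, 0.1))
  g <- cut(x, unique(br), include.lowest = TRUE, labels = FALSE)
  expect_equal(b$y, as.numeric(tapply(y, g, mean)))
})

test_that("cophenetic distances match a manual single-linkage trace and brute force", {
  # manual 3-point trace: d(a,b)=1, d(a,c)=4, d(b,c)=4.5
  dm <- matrix(c(0, 1, 4, 1, 0, 4.5, 4, 4.5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hclust(as.dist(dm), method = "single")
  cm <- as.matrix(cophenetic(hc))
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], 4)
  expect_equal(cm["b", "c"], 4)

  # brute-force O(n^3) agglomeration oracle on 25 random points
  set.seed(11)
  pts <- matrix(rnorm(25 * 5), 25)
  dmat <- as.matrix(dist(pts))
  brute <- single_linkage_brute(dmat)
  hc2 <- hclust(as.dist(dmat), method = "single")
  expect_equal(unname(as.matrix(cophenetic(hc2))), brute, tolerance = 1e-12)

  # ultrametric input is a fixed point
  um <- cm  # cophenetic output is ultrametric
  hc3 <- hclust(as.dist(um), method = "single")
  expect_equal(as.matrix(cophenetic(hc3)), um)

  # ultrametric inequality holds exhaustively on the package's own output
  emb <- random_embeddings(20, 6, seed = 12)
  rates <- matrix(rnorm(5 * 20), 5, dimnames = list(sprintf("u%d", 1:5),
                                                    emb$words))
  rm1 <- rm_from_word_rates(rates)
  colnames(rm1$rates) <- as.character(rm1$events$event_id)
  rm1$events$token <- emb$words
  ch <- cophenetic_hierarchy(emb, rm1, bins = 10, n_perm = 20, seed = 1)
  cmat <- as.matrix(ch$cophenetic)
  n <- nrow(cmat)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      expect_true(all(cmat[i, j] <= pmax(cmat[i, ], cmat[j, ]) + 1e-12))
    }
  }
})

test_that("geometry-coupled populations show positive rate-geometry correlations", {
  # the statistic population-averages the selective units' rates, so its
  # power varies with how the planted preferred domains balance out; test
  # over three seeds and require the effect in most
  cfg <- small_cfg(tuning_mode = "geometry", story_blocks = 0L,
                   nonword_blocks = 0L, include_word_lists = FALSE)
  res <- vapply(51:53, function(sd) {
    s <- generate_session(cfg, seed = sd)
    rm1 <- select_events(align_responses(s$spikes, s$events),
                         condition == "sentence")
    gt <- s$spikes$ground_truth
    rm_sel <- rm1
    rm_sel$rates <- rm_sel$rates[gt$unit[gt$selective], , drop = FALSE]
    rdc <- rate_distance_correlation(rm_sel, s$space$embeddings,
                                     n_perm = 100, seed = 2)
    ch <- cophenetic_hierarchy(s$space$embeddings, rm_sel, n_perm = 100,
                               seed = 3)
    c(rdc$r, rdc$p_value, ch$r, ch$p_value)
  }, numeric(4))
  expect_gt(mean(res[1, ]), 0)              # rate-distance r positive overall
  expect_gte(sum(res[2, ] < 0.05), 2)       # significant in most seeds
  expect_gt(mean(res[3, ]), 0)              # cophenetic r positive overall
  expect_gte(sum(res[4, ] < 0.05), 2)

  # untuned control: no geometry in the rates; r centers on zero across seeds
  r0 <- vapply(52:54, function(sd) {
    s0 <- generate_session(small_cfg(tuning_gain = 0, story_blocks = 0L,
                                     nonword_blocks = 0L,
                                     include_word_lists = FALSE), seed = sd)
    rm0 <- select_events(align_responses(s0$spikes, s0$events),
                         condition == "sentence")
    rate_distance_correlation(rm0, s0$space$embeddings, n_perm = 10,
                              seed = 2)$r
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.15)
})

test_that("the semantic space recovers planted geometry end to end", {
  cfg <- small_cfg(tuning_mode = "geometry", story_blocks = 0L,
                   nonword_blocks = 0L, include_word_lists = FALSE,
                   n_units = 100L)
  s <- generate_session(cfg, seed = 53)
  rm1 <- select_events(align_responses(s$spikes, s$events),
                       condition == "sentence")
  theta <- fit_embedding_regression(zscore_units(rm1), s$space$embeddings)
  sp <- pca_space(theta, s$space$embeddings, n_pc = 5)
  expect_gt(sp$total_variance_explained, 0.2)
  dc <- distance_correlation(sp, s$space$embeddings, n_perm = 200, seed = 4)
  expect_gt(dc$r, 0)
  expect_lt(dc$p_value, 0.05)
  # Newick export writes a tree over the vocabulary
  ch <- cophenetic_hierarchy(s$space$embeddings, rm1, n_perm = 20, seed = 5)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(ch, nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(sort(tree$tip.label), sort(ch$hclust$labels))
})
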