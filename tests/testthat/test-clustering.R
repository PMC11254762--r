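test_that("spherical k-means separates antipodal bundles and checks preconditions", {
  set.seed(1)
  base <- c(1, 0, 0)
  pts <- rbind(
    t(replicate(6, base + rnorm(3, sd = 0.01))),
    t(replicate(6, -base + rnorm(3, sd = 0.01)))
  )
  emb <- embedding_tbl(sprintf("p%02d", 1:12), pts)
  part <- spherical_kmeans(emb, 2, seed = 4)
  a <- part$assignment
  expect_equal(length(unique(a[1:6])), 1L)
  expect_equal(length(unique(a[7:12])), 1L)
  expect_false(a[[1]] == a[[7]])

  expect_error(spherical_kmeans(emb, 1), ">= 2")
  expect_error(spherical_kmeans(emb, 13), "exceeds")
})

test_that("spherical k-means attains the exhaustive-best objective on a tiny instance", {
  set.seed(5)
  cen <- diag(3)
  pts <- do.call(rbind, lapply(1:3, function(j) {
    t(replicate(3, cen[j, ] + rnorm(3, sd = 0.15)))
  }))
  v <- pts / sqrt(rowSums(pts^2))
  emb <- embedding_tbl(sprintf("p%d", 1:9), pts)
  # brute force over all 3^9 assignments
  objective <- function(assign) {
    sum(vapply(unique(assign), function(cl) {
      mu <- colSums(v[assign == cl, , drop = FALSE])
      sqrt(sum(mu^2))  # sum of cosines to normalized mean
    }, numeric(1)))
  }
  grid <- expand.grid(rep(list(1:3), 9))
  best <- max(apply(grid, 1L, objective))
  part <- spherical_kmeans(emb, 3, seed = 2)
  expect_equal(attr(part, "objective"), best, tolerance = 1e-8)
})

test_that("spherical k-means is deterministic for a fixed seed", {
  emb <- random_embeddings(30, 8, seed = 9)
  p1 <- spherical_kmeans(emb, 4, seed = 11)
  p2 <- spherical_kmeans(emb, 4, seed = 11)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$centroids, p2$centroids)
})

test_that("mean silhouette matches the per-point brute-force computation", {
  set.seed(6)
  pts <- rbind(t(replicate(5, c(1, 0) + rnorm(2, sd = 0.2))),
               t(replicate(4, c(0, 1) + rnorm(2, sd = 0.2))))
  emb <- embedding_tbl(sprintf("w%d", 1:9), pts)
  part <- spherical_kmeans(emb, 2, seed = 1)
  dmat <- 1 - tcrossprod(emb$vectors)
  diag(dmat) <- 0
  ours <- semspike:::mean_silhouette(unname(part$assignment), dmat)
  brute <- mean(silhouette_brute(unname(part$assignment), dmat))
  expect_equal(ours, brute, tolerance = 1e-10)
})

test_that("silhouette selection recovers a planted cluster count and flags no structure", {
  sp <- generate_embedding_space(small_cfg(words_per_domain = 8L, dim = 30L),
                                 seed = 3)
  sel <- select_cluster_count(sp$embeddings, k_range = c(5, 12),
                              n_repeats = 8, seed = 2)
  expect_equal(sel$k_star, 9L)
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(nrow(tidy(sel)), 8L)

  # isotropic cloud: weak separation flagged
  iso <- random_embeddings(40, 10, seed = 8)
  expect_message(sel0 <- select_cluster_count(iso, k_range = c(5, 8),
                                              n_repeats = 4, seed = 1),
                 "weak separation")
  expect_true(sel0$weak_separation)
  expect_lt(max(sel0$criterion$mean_silhouette), 0.25)

  # k_range above the word count is truncated with a warning
  tiny <- random_embeddings(7, 4, seed = 2)
  expect_warning(select_cluster_count(tiny, k_range = c(2, 10),
                                      n_repeats = 2, seed = 1), "truncated")
})

test_that("purity matches exhaustive overlap counting and its invariants", {
  cen <- diag(3)[1:2, ]
  p_new <- domain_partition(setNames(c(1, 1, 1, 2, 2, 2), letters[1:6]), cen)
  p_ref <- domain_partition(setNames(c(1, 1, 2, 1, 2, 2), letters[1:6]), cen)
  expect_equal(purity(p_new, p_ref), 4 / 6)
  expect_equal(purity(p_new, p_new), 1)

  # exhaustive overlap-count oracle
  oracle <- function(a, b) {
    s <- 0
    for (i in unique(a)) {
      s <- s + max(vapply(unique(b), function(j) {
        sum(a == i & b[names(a)] == j)
      }, numeric(1)))
    }
    s / length(a)
  }
  expect_equal(purity(p_new, p_ref),
               oracle(p_new$assignment, p_ref$assignment))

  # permutation invariance of labels
  p_swap <- domain_partition(setNames(c(2, 2, 2, 1, 1, 1), letters[1:6]), cen)
  expect_equal(purity(p_swap, p_ref), purity(p_new, p_ref))

  # all-in-one clustering against singleton reference: 1/n
  cen6 <- diag(6)
  singletons <- domain_partition(setNames(1:6, letters[1:6]), cen6)
  lump <- domain_partition(setNames(c(1, 1, 1, 1, 1, 2), letters[1:6]), cen)
  expect_equal(purity(singletons, lump),
               1)  # every ref word its own cluster: each max overlap is 1
  expect_equal(purity(lump, singletons), 2 / 6)

  # correcting a misassigned word never decreases purity
  p_fix <- domain_partition(setNames(c(1, 1, 2, 1, 2, 2), letters[1:6]), cen)
  expect_gte(purity(p_fix, p_ref), purity(p_new, p_ref))

  # word-set mismatch errors with the symmetric difference
  p_other <- domain_partition(setNames(c(1, 2), c("a", "zz")), cen)
  expect_error(purity(p_new, p_other), "zz")
})

test_that("d-prime separability matches direct arithmetic and sign convention", {
  set.seed(4)
  pts <- rbind(t(replicate(3, c(1, 0, 0) + rnorm(3, sd = 0.1))),
               t(replicate(3, c(0, 1, 0) + rnorm(3, sd = 0.1))))
  emb <- embedding_tbl(sprintf("w%d", 1:6), pts)
  part <- domain_partition(setNames(rep(1:2, each = 3), emb$words),
                           rbind(c(1, 0, 0), c(0, 1, 0)))
  dp <- dprime_separability(part, emb)
  # direct formula on the actual distance sets for domain 1
  d <- 1 - tcrossprod(emb$vectors)
  within <- d[1:3, 1:3][lower.tri(diag(3))]
  between <- as.vector(d[1:3, 4:6])
  expected <- (mean(between) - mean(within)) /
    sqrt((var(within) + var(between)) / 2)
  expect_equal(dp$d_prime[[1]], expected)
  expect_gt(dp$d_prime[[1]], 0)  # tighter within than between

  # planted nine-domain space: every domain separates positively
  sp <- generate_embedding_space(small_cfg(words_per_domain = 6L, dim = 20L),
                                 seed = 5)
  dp9 <- dprime_separability(sp$partition, sp$embeddings)
  expect_true(all(dp9$d_prime > 0))
})
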