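# Spherical k-means over word embeddings, silhouette model selection, and
# cluster-quality diagnostics (purity, d-prime separability).

#' Construct a domain partition
#'
#' A partition assigns every word to exactly one semantic domain and carries
#' one unit-norm centroid direction per domain.
#'
#' @param assignment Named integer vector, word -> domain in `1..k`.
#' @param centroids Numeric `k x d` matrix of domain centroids.
#' @param labels Optional character vector of human-readable domain names.
#' @return An object of class `domain_partition`.
#' @export
domain_partition <- function(assignment, centroids, labels = NULL) {
  stopifnot(!is.null(names(assignment)))
  assignment <- setNames(as.integer(assignment), tolower(names(assignment)))
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 2L) stop("a partition needs k >= 2 domains", call. = FALSE)
  if (any(assignment < 1L | assignment > k)) {
    stop("assignment labels outside 1..k", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicate words in assignment", call. = FALSE)
  }
  centroids <- unit_rows(centroids, "centroid")
  if (!is.null(labels)) stopifnot(length(labels) == k)
  structure(
    list(assignment = assignment, centroids = centroids, k = k, labels = labels),
    class = "domain_partition"
  )
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> ", length(x$assignment), " words in ", x$k,
      " domains\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.domain_partition <- function(x, ...) {
  tibble(word = names(x$assignment), domain = unname(x$assignment))
}

#' Spherical k-means clustering of word embeddings
#'
#' Lloyd-style iteration on the unit sphere: words are assigned to the
#' centroid of maximal cosine similarity and centroids are recomputed as
#' normalized means. The objective (sum of cosine similarities of words to
#' their assigned centroid) is non-decreasing across iterations. Emptied
#' clusters are re-seeded with the point farthest from its current centroid,
#' which keeps the run deterministic for a fixed seed.
#'
#' @param x An [embedding_tbl()].
#' @param k Number of clusters (`>= 2`, `<=` number of words).
#' @param seed Optional integer seed for the pseudorandom initial centroids.
#' @param max_iter Iteration cap (default 100).
#' @return A [domain_partition()] with attributes `objective` and `iterations`.
#' @export
spherical_kmeans <- function(x, k, seed = NULL, max_iter = 100L) {
  stopifnot(inherits(x, "embedding_tbl"))
  n <- n_words(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds number of words (", n, ")", call. = FALSE)
  .set_seed_if(seed)
  v <- unit_rows(x$vectors)
  centroids <- v[.kmeanspp_seeds(v, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  objective <- -Inf
  for (it in seq_len(max_iter)) {
    sim <- cosine_sim(v, centroids)
    assignment <- max.col(sim, ties.method = "first")
    # re-seed empty clusters with the globally worst-fitting point
    fit <- sim[cbind(seq_len(n), assignment)]
    for (j in setdiff(seq_len(k), unique(assignment))) {
      far <- which.min(fit)
      centroids[j, ] <- v[far, ]
      assignment[far] <- j
      fit[far] <- 1
    }
    for (j in seq_len(k)) {
      mu <- colSums(v[assignment == j, , drop = FALSE])
      nrm <- sqrt(sum(mu^2))
      if (nrm > 0) centroids[j, ] <- mu / nrm
    }
    objective <- sum(cosine_sim(v, centroids)[cbind(seq_len(n), assignment)])
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  out <- domain_partition(setNames(assignment, x$words), centroids)
  attr(out, "objective") <- objective
  attr(out, "iterations") <- it
  out
}

# k-means++-style pseudorandom seeding on the sphere: each further seed is
# drawn with probability proportional to the squared cosine distance to its
# nearest already-chosen seed.
.kmeanspp_seeds <- function(v, k) {
  n <- nrow(v)
  seeds <- sample.int(n, 1L)
  d2 <- (1 - drop(v %*% v[seeds, ]))^2
  while (length(seeds) < k) {
    d2[seeds] <- 0
    nxt <- if (sum(d2) == 0) {
      sample(setdiff(seq_len(n), seeds), 1L)
    } else {
      sample.int(n, 1L, prob = d2)
    }
    seeds <- c(seeds, nxt)
    d2 <- pmin(d2, (1 - drop(v %*% v[nxt, ]))^2)
  }
  seeds
}

# Mean silhouette width of an assignment under a precomputed distance matrix.
mean_silhouette <- function(assignment, dmat) {
  if (length(unique(assignment)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(assignment, dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' Select the number of semantic domains by silhouette criterion
#'
#' Repeats spherical k-means with pseudorandom seeding `n_repeats` times; for
#' each repeat and each candidate `k` the mean silhouette width under cosine
#' distance is computed over all words. The selected `k_star` maximizes the
#' average criterion (ties go to the smaller `k`, favouring parsimony); the
#' per-repeat argmax mode is reported alongside.
#'
#' @param x An [embedding_tbl()].
#' @param k_range Integer interval of candidate cluster counts (default
#'   `c(5, 20)`).
#' @param n_repeats Number of seeded repeats (default 100).
#' @param seed Optional master seed.
#' @param silhouette_floor Mean-silhouette level below which separation is
#'   flagged as weak (default 0.25, the conventional boundary below which a
#'   silhouette profile indicates no substantial structure).
#' @return An object of class `cluster_count_selection` with elements
#'   `k_star`, `k_modal`, `criterion` (tibble of k, mean/sd silhouette, modal
#'   count) and `weak_separation`.
#' @export
select_cluster_count <- function(x, k_range = c(5L, 20L), n_repeats = 100L,
                                 seed = NULL, silhouette_floor = 0.25) {
  stopifnot(inherits(x, "embedding_tbl"), length(k_range) == 2L)
  n <- n_words(x)
  k_hi <- min(k_range[[2L]], n - 1L)
  if (k_hi < k_range[[2L]]) {
    warning("upper k truncated to ", k_hi, " (only ", n, " words)", call. = FALSE)
  }
  ks <- seq.int(max(2L, k_range[[1L]]), k_hi)
  dmat <- cosine_dist_matrix(unit_rows(x$vectors))
  seeds <- split_seed(if (is.null(seed)) 1L else seed, n_repeats)
  sil <- matrix(NA_real_, n_repeats, length(ks),
                dimnames = list(NULL, as.character(ks)))
  for (r in seq_len(n_repeats)) {
    sub <- split_seed(seeds[[r]], length(ks))
    for (j in seq_along(ks)) {
      part <- spherical_kmeans(x, ks[[j]], seed = sub[[j]])
      sil[r, j] <- mean_silhouette(unname(part$assignment), dmat)
    }
  }
  best_per_repeat <- ks[apply(sil, 1L, which.max)]
  criterion <- tibble(
    k = ks,
    mean_silhouette = colMeans(sil),
    sd_silhouette = apply(sil, 2L, sd),
    modal_count = vapply(ks, function(k) sum(best_per_repeat == k), integer(1))
  )
  k_star <- ks[[which.max(criterion$mean_silhouette)]]  # first max = smallest k
  k_modal <- ks[[which.max(criterion$modal_count)]]
  weak <- max(criterion$mean_silhouette) < silhouette_floor
  if (weak) message("weak separation: max mean silhouette < ", silhouette_floor)
  structure(
    list(k_star = k_star, k_modal = k_modal, criterion = criterion,
         weak_separation = weak, n_repeats = n_repeats),
    class = "cluster_count_selection"
  )
}

#' @export
print.cluster_count_selection <- function(x, ...) {
  cat("<cluster_count_selection> k* = ", x$k_star, " (modal ", x$k_modal,
      ") over ", x$n_repeats, " repeats",
      if (x$weak_separation) " [weak separation]", "\n", sep = "")
  invisible(x)
}

#' Purity of a clustering against a reference partition
#'
#' The fraction of words that land in the best-matched reference cluster:
#' `(1/n) * sum_i max_j |omega_i intersect c_j|`, ranging from near 0 (bad
#' clustering) to 1 (perfect clustering). Invariant to relabelling of either
#' partition.
#'
#' @param new,ref [domain_partition()] objects over the same word set.
#' @return A number in (0, 1].
#' @export
purity <- function(new, ref) {
  a <- new$assignment
  b <- ref$assignment
  if (!setequal(names(a), names(b))) {
    dif <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("word sets differ; symmetric difference: ",
         paste(dif, collapse = ", "), call. = FALSE)
  }
  b <- b[names(a)]
  sum(apply(table(a, b), 1L, max)) / length(a)
}

#' d-prime separability of semantic domains
#'
#' For each domain, compares within-domain to between-domain cosine distances
#' using `d' = (mu_between - mu_within) / sqrt((var_within + var_between)/2)`.
#' Positive values mean words in the domain sit closer to one another than to
#' words outside it.
#'
#' @param partition A [domain_partition()].
#' @param x The [embedding_tbl()] the partition was built from.
#' @return Tibble with columns `domain`, `n_words`, `d_prime`.
#' @export
dprime_separability <- function(partition, x) {
  stopifnot(inherits(partition, "domain_partition"), inherits(x, "embedding_tbl"))
  words <- names(partition$assignment)
  emb <- subset_embeddings(x, words)
  dmat <- cosine_dist_matrix(unit_rows(emb$vectors))
  lab <- partition$assignment[emb$words]
  res <- purrr::map_dfr(sort(unique(lab)), function(dom) {
    inside <- which(lab == dom)
    if (length(inside) < 2L) {
      warning("domain ", dom, " has < 2 words; d' undefined", call. = FALSE)
      return(tibble(domain = dom, n_words = length(inside), d_prime = NA_real_))
    }
    within <- lower_tri(dmat[inside, inside, drop = FALSE])
    between <- as.vector(dmat[inside, -inside, drop = FALSE])
    pooled <- (var(within) + var(between)) / 2
    dp <- if (!is.finite(pooled) || pooled == 0) {
      warning("zero pooled variance for domain ", dom, call. = FALSE)
      NaN
    } else {
      (mean(between) - mean(within)) / sqrt(pooled)
    }
    tibble(domain = dom, n_words = length(inside), d_prime = dp)
  })
  res
}

#' @importFrom stats var
NULL
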