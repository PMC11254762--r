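# Population decoding of semantic domains: linear max-margin classifiers with
# balanced class weights, sentence-level train/validation splits, permutation
# nulls, cross-material generalization, and the domain-by-unit improvement
# surface.

#' Decoder configuration
#'
#' @param C Soft-margin regularization parameter of the linear support vector
#'   classifier (default 1).
#' @param train_fraction Fraction of sentences used for training (default 0.6).
#' @param n_iterations Train/validation split repetitions (default 1000).
#' @param n_permutations Label permutations for the null (default 1000).
#' @param standardize Standardize features using training-split statistics
#'   only (default `TRUE`).
#' @param multiclass `"ovr"` one-vs-rest (default) or `"ovo"` one-vs-one.
#' @param bootstrap_validation Resample validation words with replacement to
#'   equal counts per domain before scoring (default `TRUE`); with `FALSE`
#'   balanced accuracy (mean per-domain recall) is computed directly. Both
#'   have chance level `1/k`.
#' @param seed Optional seed.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(C = 1, train_fraction = 0.6, n_iterations = 1000L,
                           n_permutations = 1000L, standardize = TRUE,
                           multiclass = c("ovr", "ovo"),
                           bootstrap_validation = TRUE, seed = NULL) {
  stopifnot(C > 0, train_fraction > 0, train_fraction < 1)
  structure(
    list(C = C, train_fraction = train_fraction,
         n_iterations = as.integer(n_iterations),
         n_permutations = as.integer(n_permutations),
         standardize = isTRUE(standardize),
         multiclass = match.arg(multiclass),
         bootstrap_validation = isTRUE(bootstrap_validation),
         seed = seed),
    class = "decoder_config"
  )
}

# Balanced class weights: n / (k * n_class), the standard reweighting that
# equalizes each class's contribution to the margin objective.
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

# Fit a linear SVC (one-vs-rest by default) and return a predict closure.
fit_svc <- function(x, y, cfg) {
  y <- factor(y)
  lev <- levels(y)
  center <- scl <- NULL
  if (cfg$standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0] <- 1
    x <- scale(x, center, scl)
  }
  if (cfg$multiclass == "ovo" || length(lev) == 2L) {
    fit <- e1071::svm(x, y, kernel = "linear", cost = cfg$C, scale = FALSE,
                      class.weights = balanced_weights(y))
    predictor <- function(newx) as.character(predict(fit, newx))
  } else {
    fits <- lapply(lev, function(cl) {
      yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
      e1071::svm(x, yb, kernel = "linear", cost = cfg$C, scale = FALSE,
                 class.weights = balanced_weights(yb))
    })
    predictor <- function(newx) {
      dec <- vapply(fits, function(f) {
        d <- attr(predict(f, newx, decision.values = TRUE), "decision.values")
        # orient so that larger means more "pos"
        if (colnames(d)[[1L]] == "pos/neg") d[, 1L] else -d[, 1L]
      }, numeric(nrow(newx)))
      dec <- matrix(dec, nrow = nrow(newx))
      lev[max.col(dec, ties.method = "first")]
    }
  }
  function(newx) {
    if (cfg$standardize) newx <- scale(newx, center, scl)
    predictor(newx)
  }
}

# Mean per-class recall ("balanced accuracy"); chance = 1/k.
balanced_accuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# Score one fitted model on validation data; optionally bootstrap-resamples
# validation events to equal per-class counts.
score_validation <- function(predictor, x_val, y_val, cfg) {
  pred <- predictor(x_val)
  correct <- pred == y_val
  if (cfg$bootstrap_validation) {
    cls <- unique(y_val)
    m <- max(1L, round(mean(table(y_val))))
    idx <- unlist(lapply(cls, function(cl) {
      sample(which(y_val == cl), m, replace = TRUE)
    }))
    acc <- mean(correct[idx])
  } else {
    acc <- balanced_accuracy(y_val, pred)
  }
  list(accuracy = acc, raw_accuracy = mean(correct), correct = correct,
       pred = pred)
}

# Shared iteration engine over sentence-level splits.
run_decoding_iterations <- function(rates, labels, sentences, cfg, n_iter,
                                    track_words = TRUE) {
  sids <- unique(sentences)
  n_train <- max(1L, round(cfg$train_fraction * length(sids)))
  k <- length(unique(labels))
  n_ev <- length(labels)
  acc <- raw_acc <- numeric(n_iter)
  n_eval <- n_correct <- integer(n_ev)
  confusion <- matrix(0L, k, k,
                      dimnames = list(sort(unique(labels)), sort(unique(labels))))
  resampled <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      train_s <- sample(sids, n_train)
      tr <- sentences %in% train_s
      if (length(unique(labels[tr])) == k && any(!tr)) break
      resampled <- resampled + 1L
      if (resampled > 50L * n_iter) {
        stop("cannot draw a split containing every domain", call. = FALSE)
      }
    }
    predictor <- fit_svc(rates[tr, , drop = FALSE], labels[tr], cfg)
    sc <- score_validation(predictor, rates[!tr, , drop = FALSE], labels[!tr], cfg)
    acc[[i]] <- sc$accuracy
    raw_acc[[i]] <- sc$raw_accuracy
    if (track_words) {
      vi <- which(!tr)
      n_eval[vi] <- n_eval[vi] + 1L
      n_correct[vi] <- n_correct[vi] + sc$correct
      tt <- table(factor(labels[!tr], rownames(confusion)),
                  factor(sc$pred, rownames(confusion)))
      confusion <- confusion + tt
    }
  }
  if (resampled > 0L) {
    warning(resampled, " split(s) redrawn to keep every domain in training",
            call. = FALSE)
  }
  list(accuracy = acc, raw_accuracy = raw_acc, n_eval = n_eval,
       n_correct = n_correct, confusion = confusion)
}

# Extract the (rates, labels, sentences) triple used by the decoders.
decoding_data <- function(rm, units = NULL) {
  keep <- !is.na(rm$events$domain)
  rates <- t(rm$rates[, keep, drop = FALSE])
  if (!is.null(units)) rates <- rates[, units, drop = FALSE]
  list(rates = rates,
       labels = as.character(rm$events$domain[keep]),
       sentences = rm$events$sentence_id[keep],
       event_id = rm$events$event_id[keep])
}

#' Decode semantic domains from population activity
#'
#' Repeatedly splits sentences into train/validation sets, fits a linear
#' support vector classifier (soft margin `1/2 w'w + C sum(zeta)`, balanced
#' class weights) on the training words' population rates, and scores
#' class-balanced accuracy on held-out words. Chance level is `1/k`.
#'
#' @param rm A `response_matrix` with domain-labelled events.
#' @param units Optional character vector of unit ids to use (typically the
#'   semantically selective units); default all units.
#' @param cfg A [decoder_config()].
#' @return An object of class `decoding_result`: `accuracy` /`raw_accuracy`
#'   vectors over iterations, their means and sds, summed `confusion`
#'   matrix, and `per_word` correctness tibble for downstream conditioning.
#' @export
decode_domains <- function(rm, units = NULL, cfg = decoder_config()) {
  stopifnot(inherits(rm, "response_matrix"))
  .set_seed_if(cfg$seed)
  dat <- decoding_data(rm, units)
  res <- run_decoding_iterations(dat$rates, dat$labels, dat$sentences, cfg,
                                 cfg$n_iterations)
  structure(
    list(accuracy = res$accuracy, raw_accuracy = res$raw_accuracy,
         mean_accuracy = mean(res$accuracy), sd_accuracy = sd(res$accuracy),
         confusion = res$confusion,
         per_word = tibble(event_id = dat$event_id, n_eval = res$n_eval,
                           n_correct = res$n_correct),
         n_units = ncol(dat$rates), units = colnames(dat$rates), cfg = cfg),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> balanced accuracy ",
      sprintf("%.1f%% +/- %.1f%%", 100 * x$mean_accuracy, 100 * x$sd_accuracy),
      " (", x$n_units, " units, ", length(x$accuracy), " iterations)\n",
      sep = "")
  if (!is.null(x$null)) {
    cat("  permutation null mean ", sprintf("%.1f%%", 100 * mean(x$null)),
        ", empirical p = ", format(x$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

# Shuffle domain labels for the permutation null. The default event-level
# shuffle breaks any word-rate association, so class-balanced accuracy has
# expectation exactly 1/k under the null. The word-level variant keeps labels
# consistent within a word (permuting the word -> domain map); because words
# recur across train and validation sentences it leaves word-identity
# information in place and its null sits slightly above 1/k.
permute_labels <- function(tokens, labels, scope = c("event", "word")) {
  scope <- match.arg(scope)
  if (scope == "event") return(sample(labels))
  words <- unique(tokens)
  word_lab <- labels[match(words, tokens)]
  new_lab <- setNames(sample(word_lab), words)
  unname(new_lab[tokens])
}

#' Permutation null for domain decoding
#'
#' Reruns the decoding pipeline with the word-to-domain labels shuffled
#' before splitting, once per permutation, building the empirical null of
#' decoding accuracies. The empirical p-value is the add-one-smoothed
#' fraction of permutations whose accuracy reaches the observed mean
#' (guaranteed in `(0, 1]`); the raw fraction is also reported.
#'
#' @param rm A `response_matrix` with domain-labelled events.
#' @param units Optional unit subset.
#' @param cfg A [decoder_config()]; `n_permutations` controls the null size
#'   (values below 100 trigger a resolution warning).
#' @param observed Observed mean accuracy. If `NULL`, [decode_domains()] is
#'   run first and its result returned with the null attached.
#' @return If `observed` is given: list `null`, `p_value`, `p_raw`.
#'   Otherwise a `decoding_result` with `null`, `p_value`, `p_raw` fields.
#' @export
permutation_null <- function(rm, units = NULL, cfg = decoder_config(),
                             observed = NULL,
                             scope = c("event", "word")) {
  scope <- match.arg(scope)
  stopifnot(inherits(rm, "response_matrix"))
  if (cfg$n_permutations < 100L) {
    warning("fewer than 100 permutations limits p-value resolution",
            call. = FALSE)
  }
  result <- NULL
  if (is.null(observed)) {
    result <- decode_domains(rm, units, cfg)
    observed <- result$mean_accuracy
  }
  .set_seed_if(if (is.null(cfg$seed)) NULL else cfg$seed + 1L)
  dat <- decoding_data(rm, units)
  tokens <- rm$events$token[!is.na(rm$events$domain)]
  null <- vapply(seq_len(cfg$n_permutations), function(p) {
    lab_p <- permute_labels(tokens, dat$labels, scope)
    run_decoding_iterations(dat$rates, lab_p, dat$sentences, cfg, 1L,
                            track_words = FALSE)$accuracy
  }, numeric(1))
  p_raw <- mean(null >= observed)
  p_val <- (1 + sum(null >= observed)) / (1 + cfg$n_permutations)
  if (is.null(result)) {
    list(null = null, p_value = p_val, p_raw = p_raw)
  } else {
    result$null <- null
    result$p_value <- p_val
    result$p_raw <- p_raw
    result
  }
}

#' Cross-material generalization: train on sentences, test on the story
#'
#' Fits one classifier on all domain-labelled training events (sentences)
#' and evaluates balanced accuracy on the test material (story narrative),
#' whose vocabulary may be partially novel. Significance is assessed against
#' a label-shuffled null refit per permutation.
#'
#' @param rm_train,rm_test `response_matrix` objects for the two materials.
#' @param units Optional unit subset.
#' @param cfg A [decoder_config()].
#' @return List: `accuracy`, `raw_accuracy`, `null`, `p_value`, `p_raw`.
#' @export
generalize_across_materials <- function(rm_train, rm_test, units = NULL,
                                        cfg = decoder_config(),
                                        scope = c("event", "word")) {
  scope <- match.arg(scope)
  stopifnot(inherits(rm_train, "response_matrix"),
            inherits(rm_test, "response_matrix"))
  if (nrow(rm_test$events) == 0L) stop("empty test material", call. = FALSE)
  .set_seed_if(cfg$seed)
  tr <- decoding_data(rm_train, units)
  te <- decoding_data(rm_test, units)
  predictor <- fit_svc(tr$rates, tr$labels, cfg)
  sc <- score_validation(predictor, te$rates, te$labels, cfg)
  tokens <- rm_train$events$token[!is.na(rm_train$events$domain)]
  null <- vapply(seq_len(cfg$n_permutations), function(p) {
    lab_p <- permute_labels(tokens, tr$labels, scope)
    pr <- fit_svc(tr$rates, lab_p, cfg)
    score_validation(pr, te$rates, te$labels, cfg)$accuracy
  }, numeric(1))
  p_raw <- mean(null >= sc$accuracy)
  list(accuracy = sc$accuracy, raw_accuracy = sc$raw_accuracy, null = null,
       p_value = (1 + sum(null >= sc$accuracy)) / (1 + cfg$n_permutations),
       p_raw = p_raw)
}

#' Decoding improvement over domain count and population size
#'
#' Re-clusters the vocabulary at each domain count `d`, subsamples `n` units,
#' and measures `improvement(d, n) = 100 * (PA_actual - PA_shuffle) /
#' PA_actual`, the percentage of decoding accuracy attributable to the true
#' word-domain relation.
#'
#' @param rm A `response_matrix`.
#' @param emb The [embedding_tbl()] for re-clustering.
#' @param d_range Integer vector of domain counts (e.g. `2:20`).
#' @param n_units_range Integer vector of population sizes.
#' @param cfg A [decoder_config()]; `n_iterations` splits are averaged per
#'   cell and the same number of shuffled-label splits forms the control.
#' @param seed Optional seed.
#' @return Tibble: `d`, `n_units`, `pa_actual`, `pa_shuffle`, `improvement`.
#' @export
improvement_surface <- function(rm, emb, d_range = 2:20, n_units_range,
                                cfg = decoder_config(), seed = NULL) {
  stopifnot(inherits(rm, "response_matrix"), inherits(emb, "embedding_tbl"))
  .set_seed_if(seed)
  all_units <- rownames(rm$rates)
  purrr::map_dfr(d_range, function(d) {
    part_d <- spherical_kmeans(emb, d, seed = sample.int(.MAX_SEED, 1L))
    rm_d <- rm
    rm_d$events$domain <- unname(part_d$assignment[rm_d$events$token])
    dat <- decoding_data(rm_d)
    tokens <- rm_d$events$token[!is.na(rm_d$events$domain)]
    purrr::map_dfr(n_units_range, function(n) {
      u <- sample(all_units, min(n, length(all_units)))
      x <- dat$rates[, u, drop = FALSE]
      pa_a <- mean(run_decoding_iterations(x, dat$labels, dat$sentences, cfg,
                                           cfg$n_iterations,
                                           track_words = FALSE)$accuracy)
      lab_s <- permute_labels(tokens, dat$labels)
      pa_s <- mean(run_decoding_iterations(x, lab_s, dat$sentences, cfg,
                                           cfg$n_iterations,
                                           track_words = FALSE)$accuracy)
      imp <- if (pa_a == 0) {
        warning("PA_actual = 0 at d = ", d, ", n = ", n,
                "; improvement undefined", call. = FALSE)
        NA_real_
      } else {
        100 * (pa_a - pa_s) / pa_a
      }
      tibble(d = d, n_units = length(u), pa_actual = pa_a, pa_shuffle = pa_s,
             improvement = imp)
    })
  })
}
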