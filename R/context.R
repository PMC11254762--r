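# Context-dependence analyses: a backoff bigram language model and surprisal,
# surprisal-conditioned decoding, the homophone permutation contrast, the
# sentence vs word-list selectivity comparison, and participant dropping.

#' Train a backoff bigram language model
#'
#' A Katz-style absolutely discounted bigram model over a sentence corpus:
#' seen bigrams receive `(count - discount)/count(prev)` and the discounted
#' mass backs off to an add-one-smoothed unigram distribution (with an
#' unknown-word cell), so conditional probabilities over the vocabulary sum
#' to at most 1. A sentence-start symbol conditions the first word. Any
#' language model exposing `conditional_prob(lm, word, prefix)` can stand in
#' for it (e.g. a neural model for real data); this count-based default is
#' trained on the stimulus corpus itself.
#'
#' @param events Word-event tibble; rows with `condition == "sentence"` are
#'   used, grouped by `sentence_id` and ordered by `position`.
#' @param discount Absolute discount in `(0, 1)` (default 0.5).
#' @return An object of class `ngram_lm`.
#' @export
ngram_lm <- function(events, discount = 0.5) {
  stopifnot(discount > 0, discount < 1)
  ev <- dplyr::arrange(dplyr::filter(events, .data$condition == "sentence"),
                       .data$sentence_id, .data$position)
  if (nrow(ev) == 0L) stop("no sentence events to train on", call. = FALSE)
  sents <- split(ev$token, ev$sentence_id)
  prev <- unlist(lapply(sents, function(s) c("<s>", s[-length(s)])))
  cur <- unlist(sents, use.names = FALSE)
  bigram <- table(paste(prev, cur))
  ctx <- table(prev)
  ctx_types <- table(prev[!duplicated(paste(prev, cur))])
  uni <- table(cur)
  vocab <- names(uni)
  n_tok <- length(cur)
  structure(
    list(bigram = bigram, ctx = ctx, ctx_types = ctx_types, uni = uni,
         vocab = vocab, n_tokens = n_tok, discount = discount),
    class = "ngram_lm"
  )
}

# add-one unigram probability with an unknown-word cell
.unigram_prob <- function(lm, word) {
  c_w <- if (word %in% lm$vocab) lm$uni[[word]] else 0L
  (c_w + 1) / (lm$n_tokens + length(lm$vocab) + 1)
}

#' Conditional word probability under a language model
#'
#' @param lm An `ngram_lm`.
#' @param word Current token.
#' @param prefix Character vector of preceding tokens in the sentence (empty
#'   for the first word).
#' @return Probability in `(0, 1]`.
#' @export
conditional_prob <- function(lm, word, prefix = character(0)) {
  UseMethod("conditional_prob")
}

#' @export
conditional_prob.ngram_lm <- function(lm, word, prefix = character(0)) {
  prev <- if (length(prefix) == 0L) "<s>" else prefix[[length(prefix)]]
  c_prev <- if (prev %in% names(lm$ctx)) lm$ctx[[prev]] else 0L
  if (c_prev == 0L) return(.unigram_prob(lm, word))
  key <- paste(prev, word)
  c_bi <- if (key %in% names(lm$bigram)) lm$bigram[[key]] else 0L
  alpha <- lm$discount * lm$ctx_types[[prev]] / c_prev
  max(c_bi - lm$discount, 0) / c_prev + alpha * .unigram_prob(lm, word)
}

#' Per-word surprisal over sentence events
#'
#' `surprisal(w_i) = -log P(w_i | w_1 ... w_(i-1))` in natural-log units
#' (configurable base), computed per sentence with the first word conditioned
#' on the empty prefix. Zero probabilities are capped at `max_surprisal`
#' with a warning.
#'
#' @param events Word-event tibble (sentence-condition rows are scored).
#' @param lm A language model for [conditional_prob()].
#' @param base Logarithm base; `exp(1)` (default) gives nats.
#' @param max_surprisal Cap for impossible words (default 30).
#' @return Tibble: `event_id`, `token`, `sentence_id`, `position`,
#'   `surprisal`.
#' @export
surprisal <- function(events, lm, base = exp(1), max_surprisal = 30) {
  ev <- dplyr::arrange(dplyr::filter(events, .data$condition == "sentence"),
                       .data$sentence_id, .data$position)
  if (nrow(ev) == 0L) stop("no sentence events to score", call. = FALSE)
  capped <- FALSE
  out <- ev |>
    dplyr::group_by(.data$sentence_id) |>
    dplyr::mutate(surprisal = {
      toks <- .data$token
      vapply(seq_along(toks), function(i) {
        p <- conditional_prob(lm, toks[[i]], toks[seq_len(i - 1L)])
        if (p <= 0) {
          capped <<- TRUE
          max_surprisal
        } else {
          min(-log(p, base = base), max_surprisal)
        }
      }, numeric(1))
    }) |>
    dplyr::ungroup()
  if (capped) warning("zero-probability word(s) capped at ", max_surprisal,
                      call. = FALSE)
  out[, c("event_id", "token", "sentence_id", "position", "surprisal")]
}

#' Decoding accuracy conditioned on word surprisal
#'
#' Runs domain decoding while tracking per-word correctness, then compares
#' per-iteration accuracy for validation words in the bottom (most
#' predictable) versus top (least predictable) surprisal decile with a
#' rank-sum test. When a decile holds fewer than 10 words the split widens
#' to quintiles with a warning.
#'
#' @param rm A `response_matrix` (sentence events).
#' @param surprisals Output of [surprisal()] covering the decoded events.
#' @param units Optional unit subset.
#' @param cfg A [decoder_config()].
#' @return List: `acc_low`, `acc_high` (mean/sd each), `z`, `p`,
#'   `per_iteration` tibble, and the `breaks` used.
#' @export
surprisal_decile_decoding <- function(rm, surprisals, units = NULL,
                                      cfg = decoder_config()) {
  stopifnot(inherits(rm, "response_matrix"))
  s <- surprisals$surprisal[match(rm$events$event_id, surprisals$event_id)]
  scored <- !is.na(s) & !is.na(rm$events$domain)
  q <- 10L
  qs <- quantile(s[scored], probs = seq(0, 1, length.out = q + 1L))
  grp <- cut(s[scored], breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  if (min(table(grp)) < 10L) {
    warning("fewer than 10 words in a decile; widening to quintiles",
            call. = FALSE)
    q <- 5L
    qs <- quantile(s[scored], probs = seq(0, 1, length.out = q + 1L))
    grp <- cut(s[scored], breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
  }
  low_ids <- rm$events$event_id[scored][grp == 1L]
  high_ids <- rm$events$event_id[scored][grp == max(grp)]
  .set_seed_if(cfg$seed)
  dat <- decoding_data(rm, units)
  sids <- unique(dat$sentences)
  n_train <- max(1L, round(cfg$train_fraction * length(sids)))
  k <- length(unique(dat$labels))
  acc_low <- acc_high <- rep(NA_real_, cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    repeat {
      tr <- dat$sentences %in% sample(sids, n_train)
      if (length(unique(dat$labels[tr])) == k && any(!tr)) break
    }
    predictor <- fit_svc(dat$rates[tr, , drop = FALSE], dat$labels[tr], cfg)
    pred <- predictor(dat$rates[!tr, , drop = FALSE])
    correct <- pred == dat$labels[!tr]
    ids_val <- dat$event_id[!tr]
    in_low <- ids_val %in% low_ids
    in_high <- ids_val %in% high_ids
    if (any(in_low)) acc_low[[i]] <- mean(correct[in_low])
    if (any(in_high)) acc_high[[i]] <- mean(correct[in_high])
  }
  wt <- wilcox.test(acc_low, acc_high, exact = FALSE)
  z <- unname(qnorm(wt$p.value / 2, lower.tail = FALSE)) *
    sign(mean(acc_low, na.rm = TRUE) - mean(acc_high, na.rm = TRUE))
  list(
    acc_low = c(mean = mean(acc_low, na.rm = TRUE), sd = sd(acc_low, na.rm = TRUE)),
    acc_high = c(mean = mean(acc_high, na.rm = TRUE), sd = sd(acc_high, na.rm = TRUE)),
    z = z, p = wt$p.value,
    per_iteration = tibble(iteration = seq_len(cfg$n_iterations),
                           acc_low = acc_low, acc_high = acc_high),
    breaks = qs, n_quantiles = q
  )
}

#' @importFrom stats qnorm
NULL

#' Homophone versus non-homophone response contrast
#'
#' Tests whether units encode meaning rather than phonetic form: for each
#' unit, the absolute difference in mean rate is computed for homophone
#' pairs (identical sound, different domains) and for sampled same-domain
#' non-homophone pairs (different sound, similar meaning), matched in count.
#' The pooled measurements are compared with a two-sided permutation test
#' (mean difference statistic), plus a one-tailed paired t-test on the
#' per-unit scatter. Units with no response over the tested words, or lying
#' beyond 2.5 times the interquartile range, are excluded and logged.
#'
#' @param rm A `response_matrix` whose events carry `phonetic_id`.
#' @param units Optional unit subset (typically the semantically selective
#'   units).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return An object of class `homophone_contrast`: observed means, the
#'   permutation p, per-unit tibble, excluded units, and the t-test.
#' @export
homophone_contrast <- function(rm, units = NULL, n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  .set_seed_if(seed)
  ev <- rm$events
  word_info <- dplyr::distinct(ev[!is.na(ev$domain), ],
                               .data$token, .data$phonetic_id, .data$domain)
  hom <- word_info |>
    dplyr::group_by(.data$phonetic_id) |>
    dplyr::filter(dplyr::n() == 2L, dplyr::n_distinct(.data$domain) == 2L) |>
    dplyr::summarise(w1 = dplyr::first(.data$token),
                     w2 = dplyr::last(.data$token)) |>
    dplyr::ungroup()
  if (nrow(hom) == 0L) stop("no homophone pairs in events", call. = FALSE)
  # same-domain, different-sound comparison pairs, matched in count and --
  # where possible -- in occurrence number, so estimator noise is comparable
  counts <- table(ev$token[!is.na(ev$domain)])
  n_hom_occ <- min(counts[c(hom$w1, hom$w2)])
  nonhom <- purrr::map_dfr(seq_len(nrow(hom)), function(i) {
    doms <- word_info$domain[word_info$token %in% c(hom$w1[[i]], hom$w2[[i]])]
    pools <- lapply(doms, function(d) {
      cand <- setdiff(word_info$token[word_info$domain == d],
                      c(hom$w1, hom$w2))
      rich <- cand[counts[cand] >= n_hom_occ]
      if (length(rich) >= 2L) rich else cand
    })
    # prefer the mate domain whose candidates have the most occurrences
    pool <- pools[[which.max(vapply(pools, function(p) {
      if (length(p) < 2L) -Inf else min(sort(counts[p], decreasing = TRUE)[1:2])
    }, numeric(1)))]]
    if (length(pool) < 2L) return(NULL)
    pick <- sample(pool, 2L, prob = counts[pool] / sum(counts[pool]))
    tibble(w1 = pick[[1L]], w2 = pick[[2L]])
  })
  if (nrow(nonhom) == 0L) stop("no same-domain comparison pairs available",
                               call. = FALSE)
  units <- units %||% rownames(rm$rates)
  # per-word mean rates over an equal number of subsampled occurrences
  involved <- unique(c(hom$w1, hom$w2, nonhom$w1, nonhom$w2))
  n_eq <- min(counts[involved])
  wr <- vapply(involved, function(w) {
    idx <- which(rm$events$token == w)
    if (length(idx) > n_eq) idx <- sample(idx, n_eq)
    rowMeans(rm$rates[, idx, drop = FALSE])
  }, numeric(nrow(rm$rates)))
  wr <- matrix(wr, nrow = nrow(rm$rates),
               dimnames = list(rownames(rm$rates), involved))
  wr <- wr[units, , drop = FALSE]
  pair_delta <- function(pairs) {
    abs(wr[, pairs$w1, drop = FALSE] - wr[, pairs$w2, drop = FALSE])
  }
  dx <- pair_delta(hom)     # units x homophone pairs
  dy <- pair_delta(nonhom)  # units x non-homophone pairs
  # exclusions: no response at all, then 2.5 x IQR outliers on per-unit means
  responded <- rowSums(wr) > 0
  per_unit_mean <- rowMeans(cbind(dx, dy))
  qs <- quantile(per_unit_mean[responded], c(0.25, 0.75))
  iqr <- diff(qs)
  inlier <- per_unit_mean >= qs[[1L]] - 2.5 * iqr &
    per_unit_mean <= qs[[2L]] + 2.5 * iqr
  keep <- responded & inlier
  excluded <- tibble(unit = units[!keep],
                     reason = ifelse(!responded[!keep], "no response",
                                     "outside 2.5 x IQR"))
  if (nrow(excluded)) {
    message(nrow(excluded), " unit(s) excluded: ",
            paste(unique(excluded$reason), collapse = ", "))
  }
  x <- as.vector(dx[keep, , drop = FALSE])
  y <- as.vector(dy[keep, , drop = FALSE])
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  n_x <- length(x)
  perm <- vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(length(pooled), n_x)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  p_perm <- mean(abs(perm) >= abs(obs))
  per_unit <- tibble(unit = units[keep],
                     delta_homophone = rowMeans(dx[keep, , drop = FALSE]),
                     delta_nonhomophone = rowMeans(dy[keep, , drop = FALSE]))
  tt <- t.test(per_unit$delta_homophone, per_unit$delta_nonhomophone,
               paired = TRUE, alternative = "greater")
  structure(
    list(delta_homophone = mean(x), delta_nonhomophone = mean(y),
         statistic = obs, p_perm = p_perm, n_perm = n_perm,
         per_unit = per_unit, excluded = excluded,
         t_statistic = unname(tt$statistic), p_t = tt$p.value,
         n_pairs = nrow(hom)),
    class = "homophone_contrast"
  )
}

#' @export
print.homophone_contrast <- function(x, ...) {
  cat("<homophone_contrast> |dFR| homophone ",
      sprintf("%.3f", x$delta_homophone), " vs non-homophone ",
      sprintf("%.3f", x$delta_nonhomophone), " Hz; permutation p = ",
      format(x$p_perm, digits = 3), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Selectivity attenuation from sentences to word lists
#'
#' Computes each unit's preferred-domain SI separately in the sentence and
#' word-list conditions and compares them with a paired signed-rank test; a
#' companion rank-sum test on per-unit mean rates checks that overall firing
#' does not differ between conditions (the expected null when only tuning,
#' not engagement, changes).
#'
#' @param rm A `response_matrix` containing both conditions.
#' @param units_tbl Tibble with `unit` and `preferred_domain` (the selective
#'   units as determined in the sentence condition).
#' @return List: `per_unit` tibble, `mean_si_sentence`, `mean_si_wordlist`,
#'   `signed_rank_p`, `rate_rank_sum_p`, `n_units`.
#' @export
sentence_vs_wordlist_si <- function(rm, units_tbl) {
  stopifnot(inherits(rm, "response_matrix"), nrow(units_tbl) > 0L)
  if (!any(rm$events$condition == "word_list")) {
    stop("no word-list events present", call. = FALSE)
  }
  rm_s <- select_events(rm, .data$condition == "sentence")
  rm_w <- select_events(rm, .data$condition == "word_list")
  per_unit <- purrr::map_dfr(seq_len(nrow(units_tbl)), function(i) {
    u <- units_tbl$unit[[i]]
    d <- units_tbl$preferred_domain[[i]]
    tibble(unit = u, preferred_domain = d,
           si_sentence = selectivity_index(rm_s, u, d),
           si_wordlist = selectivity_index(rm_w, u, d),
           rate_sentence = mean(rm_s$rates[u, ]),
           rate_wordlist = mean(rm_w$rates[u, ]))
  })
  dropped <- per_unit[!is.finite(per_unit$si_wordlist) |
                        !is.finite(per_unit$si_sentence), ]
  if (nrow(dropped)) {
    message(nrow(dropped), " unit(s) without defined SI in both conditions excluded")
  }
  ok <- per_unit[is.finite(per_unit$si_wordlist) &
                   is.finite(per_unit$si_sentence), ]
  sr <- wilcox.test(ok$si_sentence, ok$si_wordlist, paired = TRUE,
                    exact = FALSE)
  rs <- wilcox.test(per_unit$rate_sentence, per_unit$rate_wordlist,
                    exact = FALSE)
  list(per_unit = per_unit,
       mean_si_sentence = mean(ok$si_sentence),
       mean_si_wordlist = mean(ok$si_wordlist),
       signed_rank_p = sr$p.value,
       rate_rank_sum_p = rs$p.value,
       n_units = nrow(ok))
}

#' Leave-one-out session-dropping robustness check
#'
#' Reruns an analysis with each session removed in turn and flags the result
#' when removal of any single session changes it significantly (one-way
#' ANOVA of the iteration-level values across dropout groups).
#'
#' @param sessions List of session data objects (length >= 3).
#' @param analysis A function taking a list of sessions and returning a
#'   numeric vector of iteration-level result values.
#' @param alpha Significance level for the ANOVA flag (default 0.05).
#' @return List: `per_dropout` tibble (`dropped`, `mean`, `sd`, `n`),
#'   `anova_p`, `flagged`.
#' @export
participant_dropout <- function(sessions, analysis, alpha = 0.05) {
  if (!is.function(analysis)) {
    stop("`analysis` must be a rerunnable function of the session list",
         call. = FALSE)
  }
  if (length(sessions) < 3L) stop("need at least 3 sessions", call. = FALSE)
  runs <- lapply(seq_along(sessions), function(i) {
    v <- analysis(sessions[-i])
    stopifnot(is.numeric(v), length(v) >= 1L)
    v
  })
  per_dropout <- tibble(
    dropped = seq_along(sessions),
    mean = vapply(runs, mean, numeric(1)),
    sd = vapply(runs, sd, numeric(1)),
    n = lengths(runs)
  )
  df <- tibble(value = unlist(runs),
               group = factor(rep(seq_along(runs), lengths(runs))))
  anova_p <- if (all(lengths(runs) >= 2L)) {
    summary(aov(value ~ group, data = df))[[1L]][["Pr(>F)"]][[1L]]
  } else {
    NA_real_
  }
  list(per_dropout = per_dropout, anova_p = anova_p,
       flagged = isTRUE(anova_p < alpha))
}
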