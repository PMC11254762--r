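# Synthetic study generator: planted semantic embedding spaces, naturalistic
# stimulus streams (sentences, word lists, nonwords, homophones, story), and
# Poisson spiking populations with controllable semantic tuning.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate one recorded session at the scale of the study this
#' pipeline targets: ~459 unique words over 131 eight-word sentences, 133
#' units of which ~15% are semantically selective, nine planted domains, a
#' word-list condition that attenuates semantic tuning, homophone pairs
#' crossing domains, nonword blocks, and a story with a partially novel
#' vocabulary (70 unique words, 28 shared with the sentences).
#'
#' @param n_domains Number of planted semantic domains.
#' @param words_per_domain Sentence-vocabulary words per domain (51 x 9 = 459).
#' @param dim Embedding dimension.
#' @param concentration Spread of word vectors around their domain centroid;
#'   per-coordinate noise sd is `1/(concentration*sqrt(dim))`, so the expected
#'   off-centroid displacement norm is `1/concentration` at any dimension.
#' @param n_sentences,sentence_length Sentence-condition block shape.
#' @param n_units Number of simulated units.
#' @param frac_selective Fraction of units with planted domain tuning.
#' @param baseline_rate Baseline firing rate (Hz).
#' @param tuning_gain Rate added for preferred-domain words (Hz). The default
#'   pair (4, 3.6) places the planted selectivity index near 0.3:
#'   `SI = g/(2b + g)`.
#' @param context_attenuation Multiplier `gamma` in `[0,1]` on `tuning_gain`
#'   during the word-list condition (1 = no context dependence).
#' @param include_word_lists Whether to present token-shuffled copies of the
#'   sentences as word lists.
#' @param homophone_pairs Number of cross-domain homophone pairs.
#' @param homophone_occurrences Minimum sentence-condition occurrences per
#'   homophone word (oversampled so pairwise rate contrasts are estimable).
#' @param nonword_blocks Number of eight-item nonword blocks.
#' @param story_unique,story_shared Story vocabulary: total unique words and
#'   how many are shared with the sentence vocabulary.
#' @param story_blocks Number of eight-word story segments.
#' @param word_interval,onset_jitter_sd Mean inter-onset interval (s) and the
#'   truncated-Gaussian jitter sd around it (0.341 +/- 0.005 s).
#' @param response_lag,response_dur Response window relative to word onset:
#'   spikes are generated in `[onset+lag, onset+lag+dur)` (0.1 s + 0.4 s).
#' @param nonword_discriminability In `[0,1]`; all units respond to nonwords
#'   at `baseline_rate * (1 - nonword_discriminability)` (0 = no word/nonword
#'   difference).
#' @param tuning_mode `"domain"` (gain for preferred-domain words),
#'   `"geometry"` (gain scales with the positive part of the cosine between a
#'   word's vector and the unit's preferred direction, for every unit), or
#'   `"phonetic"` (control: units respond to phonetic form, not meaning).
#' @param seed Master seed used when per-call seeds are not given.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_domains = 9L,
                             words_per_domain = 51L,
                             dim = 300L,
                             concentration = 2.5,
                             n_sentences = 131L,
                             sentence_length = 8L,
                             n_units = 133L,
                             frac_selective = 0.15,
                             baseline_rate = 4,
                             tuning_gain = 3.6,
                             context_attenuation = 0.5,
                             include_word_lists = TRUE,
                             homophone_pairs = 10L,
                             homophone_occurrences = 8L,
                             nonword_blocks = 5L,
                             story_unique = 70L,
                             story_shared = 28L,
                             story_blocks = 20L,
                             word_interval = 0.341,
                             onset_jitter_sd = 0.005,
                             response_lag = 0.1,
                             response_dur = 0.4,
                             nonword_discriminability = 0.4,
                             tuning_mode = c("domain", "geometry", "phonetic"),
                             seed = 1L) {
  cfg <- list(
    n_domains = as.integer(n_domains),
    words_per_domain = as.integer(words_per_domain),
    dim = as.integer(dim),
    concentration = concentration,
    n_sentences = as.integer(n_sentences),
    sentence_length = as.integer(sentence_length),
    n_units = as.integer(n_units),
    frac_selective = frac_selective,
    baseline_rate = baseline_rate,
    tuning_gain = tuning_gain,
    context_attenuation = context_attenuation,
    include_word_lists = isTRUE(include_word_lists),
    homophone_pairs = as.integer(homophone_pairs),
    homophone_occurrences = as.integer(homophone_occurrences),
    nonword_blocks = as.integer(nonword_blocks),
    story_unique = as.integer(story_unique),
    story_shared = as.integer(story_shared),
    story_blocks = as.integer(story_blocks),
    word_interval = word_interval,
    onset_jitter_sd = onset_jitter_sd,
    response_lag = response_lag,
    response_dur = response_dur,
    nonword_discriminability = nonword_discriminability,
    tuning_mode = match.arg(tuning_mode),
    seed = as.integer(seed)
  )
  stopifnot(cfg$baseline_rate >= 0, cfg$tuning_gain >= 0,
            cfg$context_attenuation >= 0, cfg$context_attenuation <= 1,
            cfg$sentence_length >= 2L,
            cfg$nonword_discriminability >= 0, cfg$nonword_discriminability <= 1,
            cfg$story_shared <= cfg$story_unique,
            cfg$response_dur > 0, cfg$response_lag >= 0)
  structure(cfg, class = "generator_config")
}

#' Generate a planted semantic embedding space
#'
#' Places `n_domains` near-orthogonal unit centroids (rows of a random
#' orthonormal basis) and draws each word vector as the normalized sum of its
#' domain centroid plus isotropic Gaussian noise scaled by
#' `1/concentration`. Story-only words (the non-shared part of the story
#' vocabulary) are generated alongside and flagged, so cross-material
#' analyses can use novel words with known domain geometry.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `embeddings` ([embedding_tbl()]), `partition`
#'   ([domain_partition()] over all words, sentence and story alike), and
#'   `story_only_words`.
#' @export
generate_embedding_space <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$dim < cfg$n_domains) {
    stop("dim < n_domains: cannot place separated centroids", call. = FALSE)
  }
  if (cfg$words_per_domain * cfg$n_domains < 2L) {
    stop("need at least 2 words", call. = FALSE)
  }
  .set_seed_if(if (is.null(seed)) cfg$seed else seed)
  # random orthonormal directions via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(cfg$dim * cfg$n_domains), cfg$dim)))
  centroids <- t(q)[seq_len(cfg$n_domains), , drop = FALSE]
  n_story_new <- cfg$story_unique - cfg$story_shared
  new_per_dom <- diff(round(seq(0, n_story_new, length.out = cfg$n_domains + 1L)))
  words <- character(0)
  domains <- integer(0)
  story_only <- character(0)
  vecs <- NULL
  sdv <- 1 / (cfg$concentration * sqrt(cfg$dim))
  for (j in seq_len(cfg$n_domains)) {
    n_j <- cfg$words_per_domain + new_per_dom[[j]]
    w_j <- c(sprintf("w%d_%02d", j, seq_len(cfg$words_per_domain)),
             if (new_per_dom[[j]] > 0) sprintf("s%d_%02d", j, seq_len(new_per_dom[[j]])))
    noise <- matrix(rnorm(n_j * cfg$dim, sd = sdv), n_j)
    v_j <- sweep(noise, 2L, centroids[j, ], `+`)
    words <- c(words, w_j)
    domains <- c(domains, rep(j, n_j))
    story_only <- c(story_only, w_j[startsWith(w_j, "s")])
    vecs <- rbind(vecs, v_j)
  }
  emb <- embedding_tbl(words, vecs)
  part <- domain_partition(setNames(domains, words), centroids)
  list(embeddings = emb, partition = part, story_only_words = story_only)
}

#' Generate a naturalistic stimulus stream
#'
#' Builds the four presentation conditions in sequence: eight-word sentences
#' sampling words across all domains (every sentence-vocabulary word occurs at
#' least once), word lists that are token-shuffled copies of the sentences,
#' nonword blocks, and a story reusing the configured shared/new vocabulary
#' split. Homophone mates are pairs of words from different domains that share
#' a `phonetic_id`; all other words sound like themselves. Onsets increase
#' strictly, with inter-onset intervals jittered around `word_interval`.
#'
#' @param cfg A [generator_config()].
#' @param space Output of [generate_embedding_space()] (or a compatible list
#'   with `partition` and `story_only_words`).
#' @param seed Optional seed.
#' @return Tibble of word events: `event_id`, `token`, `phonetic_id`,
#'   `onset`, `condition`, `sentence_id`, `position`, `domain`.
#' @export
generate_stimuli <- function(cfg, space, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  part <- space$partition
  story_only <- space$story_only_words %||% character(0)
  vocab <- setdiff(names(part$assignment), story_only)
  if (length(vocab) < cfg$sentence_length) {
    stop("vocabulary smaller than sentence_length", call. = FALSE)
  }
  .set_seed_if(if (is.null(seed)) cfg$seed + 1L else seed)

  # homophone mates: cross-domain word pairs sharing a phonetic id
  phonetic_id <- setNames(names(part$assignment), names(part$assignment))
  if (cfg$homophone_pairs > 0L) {
    doms <- part$assignment[vocab]
    capacity <- length(vocab) %/% 2L
    if (cfg$homophone_pairs > capacity || part$k < 2L) {
      stop("homophone request exceeds cross-domain capacity", call. = FALSE)
    }
    pool <- sample(vocab)
    mates <- character(0)
    used <- character(0)
    for (h in seq_len(cfg$homophone_pairs)) {
      w1 <- setdiff(pool, used)[[1L]]
      w2 <- setdiff(pool[part$assignment[pool] != part$assignment[[w1]]], used)[[1L]]
      phonetic_id[[w2]] <- paste0("h", h)
      phonetic_id[[w1]] <- paste0("h", h)
      used <- c(used, w1, w2)
    }
    homophone_words <- used
    # frequency-matched same-domain control words for the non-homophone
    # comparison pairs, oversampled to the same occurrence count
    controls <- character(0)
    for (w1 in homophone_words[c(TRUE, FALSE)]) {
      cand <- setdiff(vocab[part$assignment[vocab] == part$assignment[[w1]]],
                      c(homophone_words, controls))
      controls <- c(controls, head(sample(cand), 2L))
    }
    homophone_words <- c(homophone_words, controls)
  } else {
    homophone_words <- character(0)
  }

  # sentence tokens: full vocabulary coverage, homophones oversampled, the
  # remainder drawn uniformly
  n_tok <- cfg$n_sentences * cfg$sentence_length
  base <- vocab
  extra_hom <- rep(homophone_words,
                   max(0L, cfg$homophone_occurrences - 1L))
  n_fill <- n_tok - length(base) - length(extra_hom)
  if (n_fill < 0L) stop("sentence budget too small for vocabulary", call. = FALSE)
  fill <- sample(vocab, n_fill, replace = TRUE)
  tokens <- sample(c(base, extra_hom, fill))
  sent <- tibble(
    token = tokens,
    condition = "sentence",
    sentence_id = rep(seq_len(cfg$n_sentences), each = cfg$sentence_length),
    position = rep(seq_len(cfg$sentence_length), cfg$n_sentences)
  )

  blocks <- list(sent)
  next_id <- cfg$n_sentences

  if (cfg$include_word_lists) {
    wl_tokens <- sample(sent$token)  # same multiset, shuffled order
    blocks <- c(blocks, list(tibble(
      token = wl_tokens,
      condition = "word_list",
      sentence_id = next_id + rep(seq_len(cfg$n_sentences), each = cfg$sentence_length),
      position = rep(seq_len(cfg$sentence_length), cfg$n_sentences)
    )))
    next_id <- next_id + cfg$n_sentences
  }

  if (cfg$nonword_blocks > 0L) {
    n_nw <- cfg$nonword_blocks * cfg$sentence_length
    blocks <- c(blocks, list(tibble(
      token = sprintf("nw_%02d", seq_len(n_nw)),
      condition = "nonword",
      sentence_id = next_id + rep(seq_len(cfg$nonword_blocks), each = cfg$sentence_length),
      position = rep(seq_len(cfg$sentence_length), cfg$nonword_blocks)
    )))
    next_id <- next_id + cfg$nonword_blocks
  }

  if (cfg$story_blocks > 0L) {
    shared <- sample(vocab, min(cfg$story_shared, length(vocab)))
    story_vocab <- c(shared, story_only)
    n_st <- cfg$story_blocks * cfg$sentence_length
    if (n_st < length(story_vocab)) {
      stop("story_blocks too small to cover story vocabulary", call. = FALSE)
    }
    st_tokens <- sample(c(story_vocab,
                          sample(story_vocab, n_st - length(story_vocab),
                                 replace = TRUE)))
    blocks <- c(blocks, list(tibble(
      token = st_tokens,
      condition = "story",
      sentence_id = next_id + rep(seq_len(cfg$story_blocks), each = cfg$sentence_length),
      position = rep(seq_len(cfg$sentence_length), cfg$story_blocks)
    )))
  }

  ev <- dplyr::bind_rows(blocks)
  gaps <- pmax(rnorm(nrow(ev), cfg$word_interval, cfg$onset_jitter_sd), 1e-3)
  # a 2 s pause between condition blocks
  block_start <- c(FALSE, ev$condition[-1L] != ev$condition[-nrow(ev)])
  gaps[block_start] <- gaps[block_start] + 2
  ev$onset <- cumsum(gaps)
  ev$phonetic_id <- unname(phonetic_id[ev$token])
  ev$phonetic_id[is.na(ev$phonetic_id)] <- ev$token[is.na(ev$phonetic_id)]
  ev$domain <- unname(part$assignment[ev$token])
  ev$event_id <- seq_len(nrow(ev))
  ev[, c("event_id", "token", "phonetic_id", "onset", "condition",
         "sentence_id", "position", "domain")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a semantically tuned Poisson spiking population
#'
#' Each unit emits Poisson spikes within each word's response window
#' `[onset+lag, onset+lag+dur)` at a rate of `baseline + tuning term`, where
#' the tuning term depends on `cfg$tuning_mode`:
#' \describe{
#'   \item{domain}{`gain` for words of the unit's preferred domain (selective
#'     units only).}
#'   \item{geometry}{`gain * max(0, cos(v_w, u_i))` for every unit, where
#'     `u_i` is the unit's preferred direction (its preferred domain centroid
#'     for selective units, a random unit vector otherwise).}
#'   \item{phonetic}{control mode: units respond to a random grouping of
#'     phonetic ids rather than meaning, so homophone mates elicit identical
#'     expected rates.}
#' }
#' The tuning term is multiplied by `context_attenuation` for word-list
#' events and by the optional per-event `gain_scale`. Nonword events elicit
#' `baseline * (1 - nonword_discriminability)` in all units.
#'
#' @param cfg A [generator_config()].
#' @param events Tibble from [generate_stimuli()].
#' @param space Output of [generate_embedding_space()] (needed for geometry
#'   mode and ground-truth bookkeeping).
#' @param gain_scale Optional numeric vector (length `nrow(events)`) scaling
#'   the tuning term per event, e.g. by word predictability.
#' @param seed Optional seed.
#' @return An object of class `spike_data`: list of per-unit sorted spike-time
#'   vectors, a `ground_truth` tibble (`unit`, `selective`,
#'   `preferred_domain`), and the window convention used.
#' @export
simulate_population <- function(cfg, events, space, gain_scale = NULL,
                                seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"), nrow(events) > 0L)
  if (cfg$baseline_rate < 0 || cfg$tuning_gain < 0) {
    stop("negative configured rate", call. = FALSE)
  }
  if (!is.null(gain_scale)) stopifnot(length(gain_scale) == nrow(events))
  .set_seed_if(if (is.null(seed)) cfg$seed + 2L else seed)
  part <- space$partition
  n_sel <- round(cfg$frac_selective * cfg$n_units)
  selective <- seq_len(cfg$n_units) %in% sample.int(cfg$n_units, n_sel)
  preferred <- ifelse(selective,
                      sample.int(part$k, cfg$n_units, replace = TRUE), NA_integer_)
  scale_ev <- if (is.null(gain_scale)) rep(1, nrow(events)) else gain_scale
  atten <- ifelse(events$condition == "word_list", cfg$context_attenuation, 1)
  is_nonword <- events$condition == "nonword"

  if (cfg$tuning_mode == "geometry") {
    dirs <- matrix(rnorm(cfg$n_units * cfg$dim), cfg$n_units)
    dirs <- unit_rows(dirs)
    sel_rows <- which(selective)
    dirs[sel_rows, ] <- part$centroids[preferred[sel_rows], , drop = FALSE]
    v <- space$embeddings$vectors[events$token[!is_nonword], , drop = FALSE]
    tune_wd <- pmax(cosine_sim(dirs, v), 0)  # units x word events
  } else if (cfg$tuning_mode == "phonetic") {
    pid <- unique(events$phonetic_id[!is_nonword])
    pid_group <- setNames(sample(rep_len(seq_len(part$k), length(pid))), pid)
    ev_group <- pid_group[events$phonetic_id[!is_nonword]]
    tune_wd <- outer(preferred, ev_group, function(p, g) as.numeric(!is.na(p) & p == g))
  } else {
    ev_dom <- events$domain[!is_nonword]
    tune_wd <- outer(preferred, ev_dom, function(p, d) as.numeric(!is.na(p) & p == d))
  }

  n_ev <- nrow(events)
  rates <- matrix(cfg$baseline_rate, cfg$n_units, n_ev)
  rates[, is_nonword] <- cfg$baseline_rate * (1 - cfg$nonword_discriminability)
  word_cols <- which(!is_nonword)
  gain_term <- cfg$tuning_gain * tune_wd
  gain_term <- sweep(gain_term, 2L, (atten * scale_ev)[word_cols], `*`)
  # word-list attenuation redistributes the lost tuning drive as an
  # unselective rate increase, so overall engagement (mean rate) is
  # preserved while word-specific modulation shrinks
  is_wl <- events$condition[word_cols] == "word_list"
  if (any(is_wl) && cfg$context_attenuation < 1) {
    avg_tune <- rowMeans(tune_wd[, !is_wl, drop = FALSE])
    gain_term[, is_wl] <- gain_term[, is_wl] +
      cfg$tuning_gain * (1 - cfg$context_attenuation) * avg_tune
  }
  rates[, word_cols] <- rates[, word_cols] + gain_term
  stopifnot(all(rates >= 0))

  w_start <- events$onset + cfg$response_lag
  counts <- matrix(rpois(length(rates), rates * cfg$response_dur),
                   cfg$n_units, n_ev)
  spikes <- vector("list", cfg$n_units)
  for (u in seq_len(cfg$n_units)) {
    cnt <- counts[u, ]
    tot <- sum(cnt)
    if (tot == 0L) {
      spikes[[u]] <- numeric(0)
      next
    }
    t0 <- rep(w_start, cnt)
    spikes[[u]] <- sort(t0 + runif(tot, 0, cfg$response_dur))
  }
  names(spikes) <- sprintf("u%03d", seq_len(cfg$n_units))
  structure(
    list(
      spikes = spikes,
      ground_truth = tibble(unit = names(spikes), selective = selective,
                            preferred_domain = preferred),
      window = c(lag = cfg$response_lag, end = cfg$response_lag + cfg$response_dur)
    ),
    class = "spike_data"
  )
}

#' @export
print.spike_data <- function(x, ...) {
  cat("<spike_data> ", length(x$spikes), " units, ",
      sum(lengths(x$spikes)), " spikes; ",
      sum(x$ground_truth$selective), " selective units\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper chaining [generate_embedding_space()],
#' [generate_stimuli()] and [simulate_population()] under one seed.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional master seed overriding `cfg$seed`.
#' @param gain_scale Optional per-event tuning scale (see
#'   [simulate_population()]); may also be a function of the events tibble.
#' @return List with `space`, `events`, `spikes` and the `cfg` used.
#' @export
generate_session <- function(cfg = generator_config(), seed = NULL,
                             gain_scale = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  seeds <- split_seed(cfg$seed, 3L)
  space <- generate_embedding_space(cfg, seed = seeds[[1L]])
  events <- generate_stimuli(cfg, space, seed = seeds[[2L]])
  gs <- if (is.function(gain_scale)) gain_scale(events) else gain_scale
  spikes <- simulate_population(cfg, events, space, gain_scale = gs,
                                seed = seeds[[3L]])
  list(space = space, events = events, spikes = spikes, cfg = cfg)
}
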