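toy_events <- function(sentences) {
  tibble::tibble(
    event_id = seq_along(unlist(sentences)),
    token = unlist(sentences),
    onset = seq_along(unlist(sentences)) * 0.4,
    condition = "sentence",
    sentence_id = rep(seq_along(sentences), lengths(sentences)),
    position = unlist(lapply(sentences, seq_along)),
    domain = 1L
  )
}

test_that("surprisal follows its closed form under the model interface", {
  ev <- toy_events(list(c("a", "b")))
  expect_equal(surprisal(ev, const_lm(1))$surprisal, c(0, 0))
  expect_equal(surprisal(ev, const_lm(exp(-2)))$surprisal, c(2, 2))
  # base-2 option
  expect_equal(surprisal(ev, const_lm(0.5), base = 2)$surprisal, c(1, 1))
  # zero probability capped with a warning
  expect_warning(sp0 <- surprisal(ev, const_lm(0)), "capped")
  expect_equal(sp0$surprisal, c(30, 30))
})

test_that("the backoff bigram model matches hand-computed counts on a toy corpus", {
  sents <- list(c("the", "dog", "ran"), c("the", "cat", "ran"),
                c("the", "dog", "sat"))
  ev <- toy_events(sents)
  lm <- ngram_lm(ev, discount = 0.5)
  # counts: c(the)=3 as context (all sentence-initial via <s>), c(the dog)=2
  # unigram: P(dog) = (2+1)/(9+6+1); vocabulary = {the,dog,cat,ran,sat} +
  # "the" appears... 5 types among tokens; N = 9
  v <- length(unique(unlist(sents)))
  p_uni_dog <- (2 + 1) / (9 + v + 1)
  # P(dog | the): (2 - 0.5)/3 + 0.5*2/3 * P_uni(dog)  [2 continuation types]
  expect_equal(conditional_prob(lm, "dog", "the"),
               1.5 / 3 + (0.5 * 2 / 3) * p_uni_dog)
  # P(ran | dog): (1 - 0.5)/2 + 0.5*2/2 * P_uni(ran)
  p_uni_ran <- (2 + 1) / (9 + v + 1)
  expect_equal(conditional_prob(lm, "ran", c("the", "dog")),
               0.5 / 2 + 0.5 * p_uni_ran)
  # sentence-initial word conditions on the start symbol: P(the | <s>)
  expect_equal(conditional_prob(lm, "the", character(0)),
               (3 - 0.5) / 3 + (0.5 * 1 / 3) * (3 + 1) / (9 + v + 1))
  # unseen context backs off to the unigram
  expect_equal(conditional_prob(lm, "dog", "zebra"), p_uni_dog)
})

test_that("conditional probabilities are proper and surprisal is additive", {
  ev <- toy_events(list(c("a", "b", "c"), c("a", "c", "b"), c("b", "a", "c")))
  lm <- ngram_lm(ev)
  vocab <- unique(ev$token)
  for (prev in c(character(0), "a", "b")) {
    total <- sum(vapply(vocab, function(w) {
      conditional_prob(lm, w, prev)
    }, numeric(1)))
    expect_lte(total, 1 + 1e-9)
  }
  sp <- surprisal(ev, lm)
  expect_true(all(sp$surprisal >= 0))
  # chain rule: per-sentence sum equals -log of the product of conditionals
  s1 <- c("a", "b", "c")
  logp <- sum(vapply(seq_along(s1), function(i) {
    log(conditional_prob(lm, s1[[i]], s1[seq_len(i - 1L)]))
  }, numeric(1)))
  expect_equal(sum(sp$surprisal[sp$sentence_id == 1]), -logp)
})

test_that("surprisal deciles split at the quantile boundaries", {
  s <- cached_session()
  lm <- ngram_lm(s$events)
  sp <- surprisal(s$events, lm)
  rm1 <- cached_sentence_matrix()
  res <- surprisal_decile_decoding(
    rm1, sp, units = rownames(rm1$rates)[1:10],
    cfg = decoder_config(n_iterations = 3, seed = 2))
  qs <- quantile(sp$surprisal[match(rm1$events$event_id, sp$event_id)],
                 probs = seq(0, 1, length.out = res$n_quantiles + 1L))
  expect_equal(unname(res$breaks), unname(qs))
})

test_that("predictability-coupled tuning raises low-surprisal decoding accuracy", {
  cfg <- small_cfg(story_blocks = 0L, nonword_blocks = 0L,
                   include_word_lists = FALSE)
  seeds <- split_seed(41L, 3L)
  space <- generate_embedding_space(cfg, seed = seeds[[1]])
  events <- generate_stimuli(cfg, space, seed = seeds[[2]])
  lm <- ngram_lm(events)
  sp <- surprisal(events, lm)
  pred <- 1 - (rank(sp$surprisal) - 1) / (nrow(sp) - 1)
  gs <- rep(1, nrow(events))
  gs[match(sp$event_id, events$event_id)] <- 2 * pred
  spikes <- simulate_population(cfg, events, space, gain_scale = gs,
                                seed = seeds[[3]])
  rm1 <- align_responses(spikes, events)
  sel <- domain_selectivity(rm1, space$partition)
  res <- surprisal_decile_decoding(
    rm1, sp, units = selective_units(sel),
    cfg = decoder_config(n_iterations = 25, seed = 5))
  expect_gt(res$acc_low[["mean"]], res$acc_high[["mean"]])
  expect_lt(res$p, 0.05)

  # without coupling the deciles are indistinguishable
  spikes0 <- simulate_population(cfg, events, space, seed = seeds[[3]])
  rm0 <- align_responses(spikes0, events)
  sel0 <- domain_selectivity(rm0, space$partition)
  res0 <- surprisal_decile_decoding(
    rm0, sp, units = selective_units(sel0),
    cfg = decoder_config(n_iterations = 25, seed = 5))
  expect_gt(res0$p, 0.05)
})

test_that("identical responses give a null homophone contrast", {
  s <- cached_session()
  rm1 <- cached_sentence_matrix()
  rm_const <- rm1
  rm_const$rates[] <- 5
  hc <- homophone_contrast(rm_const, n_perm = 300, seed = 1)
  expect_equal(hc$statistic, 0)
  expect_gt(hc$p_perm, 0.9)
})

test_that("meaning-coding populations show the homophone effect and phonetic ones reverse it", {
  # pool selective units across three sessions, as a multi-participant
  # analysis would, before testing the per-unit scatter
  per_unit <- purrr::map_dfr(1:3, function(i) {
    s <- generate_session(generator_config(), seed = 300 + i)
    rm1 <- select_events(align_responses(s$spikes, s$events),
                         condition == "sentence")
    sel <- domain_selectivity(rm1, s$space$partition)
    hc <- homophone_contrast(rm1, units = selective_units(sel),
                             n_perm = 600, seed = i)
    hc$per_unit
  })
  expect_gt(mean(per_unit$delta_homophone), mean(per_unit$delta_nonhomophone))
  tt <- t.test(per_unit$delta_homophone, per_unit$delta_nonhomophone,
               paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.05)

  cfgp <- generator_config(tuning_mode = "phonetic")
  sp <- generate_session(cfgp, seed = 311)
  rmp <- select_events(align_responses(sp$spikes, sp$events),
                       condition == "sentence")
  gtp <- sp$spikes$ground_truth
  hcp <- homophone_contrast(rmp, units = gtp$unit[gtp$selective],
                            n_perm = 600, seed = 4)
  expect_lt(hcp$delta_homophone, hcp$delta_nonhomophone)
})

test_that("word-list attenuation shrinks SI without changing mean rates", {
  s <- generate_session(generator_config(), seed = 401)  # gamma = 0.5
  rm_all <- align_responses(s$spikes, s$events)
  rm_s <- select_events(rm_all, condition == "sentence")
  sel <- domain_selectivity(rm_s, s$space$partition)
  sel_tbl <- sel$units[sel$units$selective, ]
  rm_sw <- select_events(rm_all, condition %in% c("sentence", "word_list"))
  res <- sentence_vs_wordlist_si(rm_sw, sel_tbl)
  expect_lt(res$mean_si_wordlist, res$mean_si_sentence)
  expect_lt(res$signed_rank_p, 0.05)
  expect_gt(res$rate_rank_sum_p, 0.05)  # engagement (mean rate) unchanged

  # gamma = 1: same generative law in both conditions
  s1 <- generate_session(generator_config(context_attenuation = 1),
                         seed = 402)
  rm1 <- align_responses(s1$spikes, s1$events)
  sel1 <- domain_selectivity(select_events(rm1, condition == "sentence"),
                             s1$space$partition)
  res1 <- sentence_vs_wordlist_si(
    select_events(rm1, condition %in% c("sentence", "word_list")),
    sel1$units[sel1$units$selective, ])
  expect_gt(res1$signed_rank_p, 0.05)
})

test_that("session dropping counts runs and flags a planted outlier", {
  sessions <- lapply(1:4, function(i) rnorm(20, mean = 1, sd = 0.2))
  analysis <- function(ss) unlist(ss)
  res <- participant_dropout(sessions, analysis)
  expect_equal(nrow(res$per_dropout), 4L)
  expect_false(res$flagged)

  outlier <- c(sessions[1:3], list(rnorm(20, mean = 5, sd = 0.2)))
  res_o <- participant_dropout(outlier, analysis)
  expect_true(res_o$flagged)

  expect_error(participant_dropout(sessions[1:2], analysis), "3 sessions")
  expect_error(participant_dropout(sessions, "not a function"), "rerunnable")
})
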