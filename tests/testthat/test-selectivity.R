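# direct construction of a response matrix from a rate table
rm_from_rates <- function(rates, domains, sentence_id = NULL) {
  n <- length(domains)
  events <- tibble::tibble(
    event_id = seq_len(n), token = sprintf("w%d", seq_len(n)),
    onset = seq_len(n) * 0.4, condition = "sentence",
    sentence_id = sentence_id %||% rep(seq_len(ceiling(n / 4)), each = 4L)[seq_len(n)],
    position = 1L, domain = domains
  )
  structure(list(rates = rates, events = events, window = c(0.1, 0.5),
                 zscored = FALSE), class = "response_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the selectivity index matches its closed form", {
  doms <- rep(1:3, each = 4)
  rates <- rbind(
    exclusive = ifelse(doms == 1, 6, 0),   # fires only for domain 1
    uniform = rep(5, 12),                   # no modulation
    graded = ifelse(doms == 1, 10, 5),      # |10-5|/15 = 1/3
    silent = rep(0, 12)
  )
  rm1 <- rm_from_rates(rates, doms)
  expect_equal(selectivity_index(rm1, "exclusive", 1), 1)
  expect_equal(selectivity_index(rm1, "uniform", 1), 0)
  expect_equal(selectivity_index(rm1, "graded", 1), 1 / 3)
  # both means zero: undefined, flagged as NA
  expect_true(is.na(selectivity_index(rm1, "silent", 1)))
  expect_error(selectivity_index(rm1, "graded", 99), "unknown domain")
  # the formula is symmetric in which side is "domain"
  fr_a <- mean(rates["graded", doms == 1])
  fr_b <- mean(rates["graded", doms != 1])
  expect_equal(abs(fr_a - fr_b) / (fr_a + fr_b),
               abs(fr_b - fr_a) / (fr_b + fr_a))
})

test_that("per-unit BH adjustment matches hand step-up arithmetic", {
  s <- cached_session()
  rm1 <- cached_sentence_matrix()
  sel <- domain_selectivity(rm1, s$space$partition)
  one <- sel$tests[sel$tests$unit == sel$tests$unit[[1]], ]
  expect_equal(one$p_adj, bh_brute(one$p_raw))
  # and on the documented example sequence
  p <- seq(0.01, 0.09, by = 0.01)
  expect_equal(p.adjust(p, "BH"), bh_brute(p))
})

test_that("constant-rate units are never called selective", {
  doms <- rep(1:3, each = 10)
  rm1 <- rm_from_rates(rbind(flat = rep(4, 30)), doms)
  cen <- diag(3)
  part <- domain_partition(setNames(1:3, c("a", "b", "c")), cen)
  sel <- domain_selectivity(rm1, part)
  expect_false(any(sel$units$selective))
})

test_that("a planted selective unit is recovered with its own domain", {
  s <- cached_session()
  rm1 <- cached_sentence_matrix()
  sel <- domain_selectivity(rm1, s$space$partition)
  gt <- s$spikes$ground_truth
  planted <- gt[gt$selective, ]
  found <- sel$units[match(planted$unit, sel$units$unit), ]
  expect_gt(mean(found$selective), 0.8)
  ok <- found$selective
  expect_true(all(found$preferred_domain[ok] == planted$preferred_domain[ok]))
})

test_that("Welch's t statistic matches hand computation on a 3+3 toy sample", {
  x <- c(4, 5, 6)
  y <- c(1, 2, 9)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  rates <- rbind(u1 = c(x, y))
  events <- tibble::tibble(event_id = 1:6, token = sprintf("w%d", 1:6),
                           onset = (1:6) * 0.4,
                           condition = rep(c("sentence", "nonword"), each = 3),
                           sentence_id = 1L, position = 1L,
                           domain = c(1L, 1L, 1L, NA, NA, NA))
  rm1 <- structure(list(rates = rates, events = events, window = c(0.1, 0.5),
                        zscored = FALSE), class = "response_matrix")
  res <- word_nonword_test(rm1)
  expect_equal(res$t[[1]], t_hand)
})

test_that("word/nonword discrimination detects the planted difference and calibrates under the null", {
  s <- generate_session(small_cfg(nonword_blocks = 8L), seed = 19)
  rm_all <- align_responses(s$spikes, s$events)
  res <- word_nonword_test(rm_all)
  expect_gt(mean(res$discriminating), 0.9)  # planted discriminability 0.4

  # identical generative rates everywhere: rejections calibrate to alpha.
  # word spacing is widened past the window so adjacent-event rates are
  # independent (overlapping windows share spikes and induce dependence).
  cfg0 <- small_cfg(nonword_discriminability = 0, tuning_gain = 0,
                    n_units = 200L, story_blocks = 0L, nonword_blocks = 6L,
                    word_interval = 0.6)
  s0 <- generate_session(cfg0, seed = 31)
  res0 <- word_nonword_test(align_responses(s0$spikes, s0$events))
  # rejection fraction near alpha (3 binomial s.e. slack)
  expect_lt(mean(res0$discriminating), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))

  rm_s <- cached_sentence_matrix()
  expect_error(word_nonword_test(rm_s), "nonword")
})

test_that("bootstrap SI has zero variance for deterministic rates and tracks the full-data SI", {
  doms <- rep(1:3, times = 20)
  rates <- rbind(det = ifelse(doms == 2, 8, 2))
  rm1 <- rm_from_rates(rates, doms, sentence_id = rep(1:15, each = 4))
  bs <- bootstrap_si(rm1, "det", 2, n_iter = 30, seed = 5)
  expect_equal(sd(bs$si), 0)
  expect_equal(bs$si[[1]], selectivity_index(rm1, "det", 2))

  # a planted unit: subsample mean within the CI of an independent run
  s <- cached_session()
  rm2 <- cached_sentence_matrix()
  gt <- s$spikes$ground_truth
  u <- gt$unit[gt$selective][[1]]
  d <- gt$preferred_domain[gt$selective][[1]]
  b1 <- bootstrap_si(rm2, u, d, n_iter = 60, seed = 101)
  b2 <- bootstrap_si(rm2, u, d, n_iter = 60, seed = 202)
  ci <- mean(b2$si) + c(-4, 4) * sd(b2$si) / sqrt(length(b2$si))
  expect_gt(mean(b1$si), ci[[1]])
  expect_lt(mean(b1$si), ci[[2]])
  # cross-domain significance stays rare for a cleanly tuned unit
  expect_lt(b1$cross_domain_rate, 0.2)
})

test_that("specificity restriction reproduces baseline at fraction 1 and uses nearest words", {
  s <- cached_session()
  rm1 <- cached_sentence_matrix()
  sel <- domain_selectivity(rm1, s$space$partition)
  sel_tbl <- sel$units[sel$units$selective, ]
  sc <- specificity_curve(rm1, s$space$partition, s$space$embeddings, sel_tbl,
                          fractions = c(1, 0.5))
  base <- sc$per_unit[sc$per_unit$fraction == 1, ]
  expect_equal(base$si, sel_tbl$si[match(base$unit, sel_tbl$unit)])

  # sorting oracle: fraction-0.5 SIs equal SIs on the brute-force
  # nearest-to-centroid word subset
  emb <- s$space$embeddings
  part <- s$space$partition
  nearest <- unlist(lapply(1:part$k, function(d) {
    w <- intersect(names(part$assignment)[part$assignment == d], emb$words)
    dist <- 1 - drop(emb$vectors[w, ] %*% part$centroids[d, ])
    w[order(dist)][seq_len(ceiling(0.5 * length(w)))]
  }))
  rm_half <- select_events(rm1, token %in% nearest)
  expected <- vapply(seq_len(nrow(sel_tbl)), function(i) {
    selectivity_index(rm_half, sel_tbl$unit[[i]], sel_tbl$preferred_domain[[i]])
  }, numeric(1))
  half <- sc$per_unit[sc$per_unit$fraction == 0.5, ]
  expect_equal(half$si, expected[match(half$unit, sel_tbl$unit)])
})
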