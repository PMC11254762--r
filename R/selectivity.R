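# Per-neuron semantic selectivity: rank-sum domain tests with BH false
# discovery control, the selectivity index, bootstrap robustness, specificity
# curves, and the word/nonword contrast.

# SI = |a - b| / (a + b); undefined (NA) when both means are zero.
si_from_means <- function(fr_domain, fr_other) {
  tot <- fr_domain + fr_other
  ifelse(tot == 0, NA_real_, abs(fr_domain - fr_other) / abs(tot))
}

#' Test each unit's selectivity for each semantic domain
#'
#' For every unit and every domain, compares firing rates for in-domain
#' events against all out-of-domain events with a two-sided rank-sum
#' (Wilcoxon) test, then adjusts the per-unit p-values across the `k`
#' domains with the Benjamini-Hochberg step-up procedure. A unit is called
#' selective when any adjusted p-value falls below `alpha`; its preferred
#' domain is the one with the smallest adjusted p (ties broken by the larger
#' rate modulation, then the lower domain index).
#'
#' @param rm A `response_matrix` whose events carry domain labels (unlabelled
#'   events, e.g. nonwords, are ignored).
#' @param partition A [domain_partition()] (used for the domain universe).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param bh_scope `"unit"` adjusts across the `k` domains within each unit
#'   (default); `"pooled"` adjusts one family of all unit-by-domain tests.
#' @return An object of class `selectivity_result` with `tests` (tibble:
#'   unit, domain, n_domain, fr_domain, fr_other, si, p_raw, p_adj) and
#'   `units` (tibble: unit, selective, preferred_domain, n_sig, si).
#' @export
domain_selectivity <- function(rm, partition, alpha = 0.05,
                               bh_scope = c("unit", "pooled")) {
  stopifnot(inherits(rm, "response_matrix"))
  bh_scope <- match.arg(bh_scope)
  lab <- rm$events$domain
  keep <- !is.na(lab)
  rates <- rm$rates[, keep, drop = FALSE]
  lab <- lab[keep]
  doms <- sort(unique(lab))
  counts <- table(lab)
  usable <- doms[counts[as.character(doms)] >= 2L]
  if (length(usable) < length(doms)) {
    warning("domain(s) with < 2 events skipped: ",
            paste(setdiff(doms, usable), collapse = ", "), call. = FALSE)
  }
  units <- rownames(rates)
  tests <- purrr::map_dfr(seq_along(units), function(u) {
    x <- rates[u, ]
    purrr::map_dfr(usable, function(d) {
      inside <- x[lab == d]
      outside <- x[lab != d]
      p <- if (length(unique(c(inside, outside))) == 1L) {
        1  # constant rates carry no evidence
      } else {
        wilcox.test(inside, outside, exact = FALSE)$p.value
      }
      tibble(unit = units[[u]], domain = d, n_domain = length(inside),
             fr_domain = mean(inside), fr_other = mean(outside),
             si = si_from_means(mean(inside), mean(outside)), p_raw = p)
    })
  })
  tests <- if (bh_scope == "unit") {
    dplyr::mutate(dplyr::group_by(tests, .data$unit),
                  p_adj = p.adjust(.data$p_raw, "BH")) |> dplyr::ungroup()
  } else {
    dplyr::mutate(tests, p_adj = p.adjust(.data$p_raw, "BH"))
  }
  unit_tbl <- tests |>
    dplyr::group_by(.data$unit) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(abs(.data$fr_domain - .data$fr_other)),
                   .data$domain, .by_group = TRUE) |>
    dplyr::summarise(
      selective = any(.data$p_adj < alpha),
      preferred_domain = dplyr::if_else(any(.data$p_adj < alpha),
                                        dplyr::first(.data$domain), NA_integer_),
      n_sig = sum(.data$p_adj < alpha),
      si = dplyr::first(.data$si)
    ) |>
    dplyr::ungroup()
  unit_tbl <- unit_tbl[match(units, unit_tbl$unit), ]
  structure(
    list(tests = tests, units = unit_tbl, alpha = alpha, bh_scope = bh_scope),
    class = "selectivity_result"
  )
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("<selectivity_result> ", sum(x$units$selective), "/", nrow(x$units),
      " selective units (alpha = ", x$alpha, ", BH per ", x$bh_scope, ")\n",
      sep = "")
  invisible(x)
}

#' Selective units of a selectivity result
#' @param x A `selectivity_result`.
#' @return Character vector of selective unit ids.
#' @export
selective_units <- function(x) x$units$unit[x$units$selective]

#' Selectivity index of one unit for one domain
#'
#' `SI = |FR_domain - FR_other| / |FR_domain + FR_other|`, where the FRs are
#' the unit's mean rates over in-domain and out-of-domain events. Bounded in
#' `[0, 1]`: 0 means no rate difference across domains, 1 means the unit
#' fires only for the considered domain. Undefined (`NA`) when both means
#' are zero.
#'
#' @param rm A `response_matrix` with domain-labelled events.
#' @param unit Unit id (row name).
#' @param domain Domain label.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
selectivity_index <- function(rm, unit, domain) {
  stopifnot(inherits(rm, "response_matrix"))
  lab <- rm$events$domain
  if (!domain %in% lab) stop("unknown domain: ", domain, call. = FALSE)
  if (!unit %in% rownames(rm$rates)) stop("unknown unit: ", unit, call. = FALSE)
  x <- rm$rates[unit, !is.na(lab)]
  lab <- lab[!is.na(lab)]
  si_from_means(mean(x[lab == domain]), mean(x[lab != domain]))
}

#' Bootstrap robustness of a unit's selectivity index
#'
#' Recomputes the SI on random sentence-level subsamples: each iteration
#' keeps the events of a random `split` fraction of sentences and recomputes
#' the preferred-domain SI. The cross-domain rate is the fraction of
#' iterations in which some non-preferred domain reaches (BH-adjusted)
#' significance, a measure of how often selectivity wanders off the preferred
#' domain under resampling.
#'
#' @param rm A `response_matrix` with domain labels and sentence ids.
#' @param unit Unit id.
#' @param domain The unit's preferred domain.
#' @param n_iter Number of subsamples (default 100).
#' @param split Fraction of sentences kept per iteration (default 0.6).
#' @param alpha Significance level for the cross-domain check.
#' @param seed Optional seed.
#' @return List: `si` (vector of per-iteration SIs), `cross_domain_rate`,
#'   `n_resampled` (iterations redrawn because a domain vanished).
#' @export
bootstrap_si <- function(rm, unit, domain, n_iter = 100L, split = 0.6,
                         alpha = 0.05, seed = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  .set_seed_if(seed)
  lab_all <- rm$events$domain
  keep <- !is.na(lab_all)
  x <- rm$rates[unit, keep]
  lab <- lab_all[keep]
  sent <- rm$events$sentence_id[keep]
  doms <- sort(unique(lab))
  sids <- unique(sent)
  n_take <- max(1L, round(split * length(sids)))
  si <- numeric(n_iter)
  cross <- logical(n_iter)
  n_resampled <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      sel <- sent %in% sample(sids, n_take)
      if (all(doms %in% lab[sel])) break
      n_resampled <- n_resampled + 1L
    }
    xi <- x[sel]
    li <- lab[sel]
    si[[i]] <- si_from_means(mean(xi[li == domain]), mean(xi[li != domain]))
    p <- vapply(doms, function(d) {
      if (length(unique(xi)) == 1L) return(1)
      wilcox.test(xi[li == d], xi[li != d], exact = FALSE)$p.value
    }, numeric(1))
    p_adj <- p.adjust(p, "BH")
    cross[[i]] <- any(p_adj[doms != domain] < alpha)
  }
  if (n_resampled > 0.1 * n_iter) {
    warning(n_resampled, " subsamples redrawn for losing a domain", call. = FALSE)
  }
  list(si = si, cross_domain_rate = mean(cross), n_resampled = n_resampled)
}

#' Selectivity as domains become more specific
#'
#' Restricts each domain to the words nearest its centroid (by cosine
#' distance) at each retention fraction and recomputes the preferred-domain
#' SI of the given units, measuring whether tighter meaning increases
#' selectivity.
#'
#' @param rm A `response_matrix` with domain labels.
#' @param partition A [domain_partition()].
#' @param emb The [embedding_tbl()] behind the partition.
#' @param units_tbl Tibble with `unit` and `preferred_domain` columns (e.g.
#'   the selective rows of a [domain_selectivity()] result).
#' @param fractions Retention fractions in `(0, 1]`
#'   (default `c(1, 0.75, 0.5, 0.25)`).
#' @return List with `summary` (tibble: fraction, n_units, mean_si, ci_lo,
#'   ci_hi) and `per_unit` (tibble: fraction, unit, si).
#' @export
specificity_curve <- function(rm, partition, emb, units_tbl,
                              fractions = c(1, 0.75, 0.5, 0.25)) {
  stopifnot(all(fractions > 0), all(fractions <= 1), nrow(units_tbl) > 0L)
  assignment <- partition$assignment
  cen_sim <- cosine_sim(unit_rows(emb$vectors),
                        partition$centroids)  # words x domains
  per_unit <- purrr::map_dfr(fractions, function(f) {
    kept_words <- unlist(lapply(seq_len(partition$k), function(d) {
      w <- names(assignment)[assignment == d]
      w <- intersect(w, emb$words)
      n_keep <- ceiling(f * length(w))
      if (n_keep < 2L) {
        warning("fraction ", f, " leaves < 2 words in domain ", d,
                "; domain skipped", call. = FALSE)
        return(character(0))
      }
      # nearest to centroid = largest cosine similarity
      w[order(cen_sim[w, d], decreasing = TRUE)][seq_len(n_keep)]
    }))
    rm_f <- select_events(rm, .data$token %in% kept_words)
    purrr::map_dfr(seq_len(nrow(units_tbl)), function(i) {
      tibble(fraction = f, unit = units_tbl$unit[[i]],
             si = selectivity_index(rm_f, units_tbl$unit[[i]],
                                    units_tbl$preferred_domain[[i]]))
    })
  })
  summary <- per_unit |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(n_units = sum(is.finite(.data$si)),
                     mean_si = mean_ci(.data$si)[["mean"]],
                     ci_lo = mean_ci(.data$si)[["lo"]],
                     ci_hi = mean_ci(.data$si)[["hi"]]) |>
    dplyr::ungroup()
  list(summary = summary, per_unit = per_unit)
}

#' Word versus nonword discrimination per unit
#'
#' Welch's two-tailed t-test of each unit's rates for word events against
#' nonword events.
#'
#' @param rm A `response_matrix` containing both word and nonword events.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `unit`, `t`, `df`, `p`, `discriminating`.
#' @export
word_nonword_test <- function(rm, alpha = 0.05) {
  stopifnot(inherits(rm, "response_matrix"))
  is_nw <- rm$events$condition == "nonword"
  if (!any(is_nw)) {
    stop("no nonword events; enable nonword blocks in the generator",
         call. = FALSE)
  }
  if (all(is_nw)) stop("no word events", call. = FALSE)
  purrr::map_dfr(rownames(rm$rates), function(u) {
    x <- rm$rates[u, !is_nw]
    y <- rm$rates[u, is_nw]
    if (sd(x) == 0 && sd(y) == 0) {
      return(tibble(unit = u, t = 0, df = NA_real_, p = 1,
                    discriminating = FALSE))
    }
    tt <- t.test(x, y)
    tibble(unit = u, t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, discriminating = tt$p.value < alpha)
  })
}
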