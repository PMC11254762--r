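# End-to-end orchestration: simulate -> cluster -> align -> selectivity ->
# decode -> context -> space, with stage toggles and a JSON run report.

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Stage toggles switch whole
#' analysis blocks off; every stochastic stage draws its seed from the single
#' `seed` via [split_seed()], so a run is fully reproducible from the
#' configuration alone.
#'
#' @param generator A [generator_config()].
#' @param window Analysis window `(lag, end)` seconds relative to word onset.
#' @param alpha Significance level for selectivity calls.
#' @param decoder A [decoder_config()]; iteration counts here size the
#'   decoding and permutation work.
#' @param k_range,n_repeats Cluster-count sweep settings.
#' @param lambda Ridge penalty for the embedding regression.
#' @param n_pc Number of principal components for the semantic space.
#' @param stages Character vector of stages to run (subset of the default).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            window = c(0.1, 0.5),
                            alpha = 0.05,
                            decoder = decoder_config(n_iterations = 100L,
                                                     n_permutations = 100L),
                            k_range = c(5L, 20L),
                            n_repeats = 20L,
                            lambda = 1e-4,
                            n_pc = 5L,
                            stages = c("simulate", "cluster", "align",
                                       "selectivity", "decode", "context",
                                       "space"),
                            seed = 1L) {
  structure(
    list(generator = generator, window = window, alpha = alpha,
         decoder = decoder, k_range = k_range,
         n_repeats = as.integer(n_repeats), lambda = lambda,
         n_pc = as.integer(n_pc), stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the toggled stages in order and collects every statistic into a
#' nested report list; with `out_dir` set, intermediate artifacts (events,
#' partition, response matrix) and the JSON report are written to disk.
#' Identical configuration and seed yield byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return The run report (invisibly a list; also written as
#'   `report.json` when `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 10L)
  report <- list(
    provenance = list(
      package = "semspike",
      version = as.character(utils::packageVersion("semspike")),
      seed = config$seed,
      stages = config$stages
    )
  )
  stage_on <- function(s) s %in% config$stages
  run_stage <- function(name, fun) {
    if (!stage_on(name)) return(list(status = "skipped"))
    tryCatch(c(list(status = "ok"), fun()),
             error = function(e) {
               stop("stage '", name, "' failed: ", conditionMessage(e),
                    call. = FALSE)
             })
  }

  session <- NULL
  report$simulate <- run_stage("simulate", function() {
    session <<- generate_session(config$generator, seed = seeds[[1L]])
    list(n_units = config$generator$n_units,
         n_events = nrow(session$events),
         n_words = n_words(session$space$embeddings),
         n_selective_planted = sum(session$spikes$ground_truth$selective))
  })
  if (is.null(session)) {
    stop("the simulate stage is required for downstream stages", call. = FALSE)
  }

  partition <- session$space$partition
  report$cluster <- run_stage("cluster", function() {
    sel <- select_cluster_count(session$space$embeddings,
                                k_range = config$k_range,
                                n_repeats = config$n_repeats,
                                seed = seeds[[2L]])
    fitted <- spherical_kmeans(session$space$embeddings, sel$k_star,
                               seed = seeds[[3L]])
    list(k_star = sel$k_star, k_modal = sel$k_modal,
         weak_separation = sel$weak_separation,
         purity_vs_planted = purity(fitted, partition),
         mean_dprime = mean(dprime_separability(partition,
                                                session$space$embeddings)$d_prime))
  })

  rm_all <- NULL
  report$align <- run_stage("align", function() {
    rm_all <<- align_responses(session$spikes, session$events,
                               window = config$window)
    list(window = config$window, n_units = nrow(rm_all$rates),
         n_events = ncol(rm_all$rates))
  })
  if (is.null(rm_all)) return(.finish_report(report, out_dir, session, NULL))

  rm_sent <- select_events(rm_all, .data$condition == "sentence")
  sel_res <- NULL
  report$selectivity <- run_stage("selectivity", function() {
    sel_res <<- domain_selectivity(rm_sent, partition, alpha = config$alpha)
    gt <- session$spikes$ground_truth
    hits <- sel_res$units$selective & gt$selective
    nonword <- if (any(rm_all$events$condition == "nonword")) {
      wn <- word_nonword_test(rm_all, alpha = config$alpha)
      list(n_discriminating = sum(wn$discriminating))
    } else {
      NULL
    }
    list(n_selective = sum(sel_res$units$selective),
         frac_selective = mean(sel_res$units$selective),
         sensitivity = sum(hits) / max(1L, sum(gt$selective)),
         mean_si = mean(sel_res$units$si[sel_res$units$selective], na.rm = TRUE),
         word_nonword = nonword)
  })

  sel_units <- if (!is.null(sel_res)) selective_units(sel_res) else units_of(rm_all)
  report$decode <- run_stage("decode", function() {
    cfg <- config$decoder
    cfg$seed <- seeds[[4L]]
    dec <- permutation_null(rm_sent, units = sel_units, cfg = cfg)
    out <- list(mean_accuracy = dec$mean_accuracy,
                sd_accuracy = dec$sd_accuracy,
                chance = 1 / partition$k,
                null_mean = mean(dec$null), p_value = dec$p_value,
                n_units = dec$n_units)
    if (any(rm_all$events$condition == "story")) {
      rm_story <- select_events(rm_all, .data$condition == "story")
      cfg$seed <- seeds[[5L]]
      gen <- generalize_across_materials(rm_sent, rm_story,
                                         units = sel_units, cfg = cfg)
      out$story <- list(accuracy = gen$accuracy, p_value = gen$p_value)
    }
    out
  })

  report$context <- run_stage("context", function() {
    out <- list()
    if (!is.null(sel_res) && any(rm_all$events$condition == "word_list")) {
      sel_tbl <- sel_res$units[sel_res$units$selective, ]
      if (nrow(sel_tbl) > 0L) {
        rm_sw <- select_events(rm_all,
                               .data$condition %in% c("sentence", "word_list"))
        swl <- sentence_vs_wordlist_si(rm_sw, sel_tbl)
        out$wordlist <- list(mean_si_sentence = swl$mean_si_sentence,
                             mean_si_wordlist = swl$mean_si_wordlist,
                             signed_rank_p = swl$signed_rank_p,
                             rate_rank_sum_p = swl$rate_rank_sum_p)
      }
    }
    hc <- tryCatch(
      homophone_contrast(rm_sent, units = sel_units,
                         n_perm = config$decoder$n_permutations,
                         seed = seeds[[6L]]),
      error = function(e) NULL
    )
    if (!is.null(hc)) {
      out$homophone <- list(delta_homophone = hc$delta_homophone,
                            delta_nonhomophone = hc$delta_nonhomophone,
                            p_perm = hc$p_perm)
    }
    lm <- ngram_lm(session$events)
    sp <- surprisal(session$events, lm)
    out$surprisal <- list(mean = mean(sp$surprisal), sd = sd(sp$surprisal))
    out
  })

  report$space <- run_stage("space", function() {
    theta <- fit_embedding_regression(zscore_units(rm_sent),
                                      session$space$embeddings,
                                      lambda = config$lambda)
    sp <- pca_space(theta, session$space$embeddings, n_pc = config$n_pc)
    dc <- distance_correlation(sp, session$space$embeddings,
                               n_perm = config$decoder$n_permutations,
                               seed = seeds[[7L]])
    rm_sel <- rm_sent
    rm_sel$rates <- rm_sel$rates[sel_units, , drop = FALSE]
    ch <- cophenetic_hierarchy(session$space$embeddings, rm_sel,
                               n_perm = config$decoder$n_permutations,
                               seed = seeds[[8L]])
    list(variance_explained = sp$total_variance_explained,
         projection_distance_r = dc$r, projection_distance_p = dc$p_value,
         cophenetic_r = ch$r, cophenetic_p = ch$p_value)
  })

  .finish_report(report, out_dir, session, rm_all)
}

.finish_report <- function(report, out_dir, session, rm_all) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_tsv(session$events, file.path(out_dir, "events.tsv"))
    write_partition_tsv(session$space$partition,
                        file.path(out_dir, "domains.tsv"))
    if (!is.null(rm_all)) {
      write_response_matrix_tsv(rm_all, file.path(out_dir, "responses.tsv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
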