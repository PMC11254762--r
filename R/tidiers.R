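# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' Tidy a cluster-count selection
#'
#' @param x A `cluster_count_selection`.
#' @param ... Unused.
#' @return The per-k criterion tibble.
#' @export
tidy.cluster_count_selection <- function(x, ...) x$criterion

#' @rdname tidy.cluster_count_selection
#' @export
glance.cluster_count_selection <- function(x, ...) {
  tibble(k_star = x$k_star, k_modal = x$k_modal,
         max_mean_silhouette = max(x$criterion$mean_silhouette),
         weak_separation = x$weak_separation, n_repeats = x$n_repeats)
}

#' Tidy a selectivity result
#'
#' @param x A `selectivity_result`.
#' @param ... Unused.
#' @return The per-unit-per-domain test tibble.
#' @export
tidy.selectivity_result <- function(x, ...) x$tests

#' @rdname tidy.selectivity_result
#' @export
glance.selectivity_result <- function(x, ...) {
  sel <- x$units$selective
  tibble(n_units = nrow(x$units), n_selective = sum(sel),
         frac_selective = mean(sel),
         mean_si = mean(x$units$si[sel], na.rm = TRUE),
         alpha = x$alpha)
}

#' Tidy a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble of per-iteration accuracies.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble(iteration = seq_along(x$accuracy), accuracy = x$accuracy,
         raw_accuracy = x$raw_accuracy)
}

#' @rdname tidy.decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
         n_units = x$n_units, n_iterations = length(x$accuracy),
         p_value = if (is.null(x$p_value)) NA_real_ else x$p_value)
}

#' Tidy a semantic space
#'
#' @param x A `semantic_space`.
#' @param ... Unused.
#' @return Tibble of word projections, one column per principal component.
#' @export
tidy.semantic_space <- function(x, ...) {
  as_tibble(x$projections, rownames = "word")
}

#' @rdname tidy.semantic_space
#' @export
glance.semantic_space <- function(x, ...) {
  tibble(n_units = nrow(x$theta), n_pc = x$n_pc,
         variance_explained = x$total_variance_explained,
         lambda = if (is.null(x$lambda)) NA_real_ else x$lambda)
}

#' Plot the silhouette criterion across cluster counts
#'
#' @param object A `cluster_count_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_count_selection <- function(object, ...) {
  ggplot2::ggplot(object$criterion,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_silhouette - .data$sd_silhouette,
      ymax = .data$mean_silhouette + .data$sd_silhouette)) +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of domains (k)", y = "mean silhouette width",
                  title = sprintf("Silhouette criterion (k* = %d)", object$k_star)) +
    ggplot2::theme_minimal()
}

#' Plot per-unit selectivity indices
#'
#' @param object A `selectivity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selectivity_result <- function(object, ...) {
  dat <- dplyr::filter(object$units, is.finite(.data$si))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$si, fill = .data$selective)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = "selectivity index", y = "units", fill = "selective") +
    ggplot2::theme_minimal()
}

#' Plot decoding accuracy against its permutation null
#'
#' @param object A `decoding_result` (with a null attached, if available).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble(accuracy = object$accuracy, which = "observed"),
    if (!is.null(object$null)) tibble(accuracy = object$null, which = "null")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$accuracy, fill = .data$which)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::labs(x = "balanced accuracy", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot word projections in the first two principal components
#'
#' @param object A `semantic_space`.
#' @param partition Optional [domain_partition()] for colouring words.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.semantic_space <- function(object, partition = NULL, ...) {
  dat <- tidy.semantic_space(object)
  if (!is.null(partition)) {
    dat$domain <- factor(partition$assignment[dat$word])
  }
  aes <- if (is.null(partition)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$domain)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "PC1 projection", y = "PC2 projection") +
    ggplot2::theme_minimal()
}
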