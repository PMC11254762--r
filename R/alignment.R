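# Word-aligned firing-rate matrices: the container every downstream analysis
# consumes.

#' Align spike times to word events
#'
#' Counts spikes in a half-open window `[onset + lag, onset + end)` around
#' each word onset and converts to rates (spikes/s). Windows may overlap
#' adjacent words (they do at ~341 ms word spacing with the default 100-500 ms
#' window); a spike landing exactly on the window end is excluded, so no spike
#' is double-counted at a boundary.
#'
#' @param spikes A `spike_data` object or a named list of sorted spike-time
#'   vectors (seconds).
#' @param events Word-event tibble (needs `onset`; other columns carried
#'   through as metadata).
#' @param window Numeric `(lag, end)` in seconds relative to onset, `0 <= lag
#'   < end`. Default `c(0.1, 0.5)`: a 400-ms window with a 100-ms lag.
#' @param zscore Z-score each unit's rates across events (default `FALSE`).
#' @return An object of class `response_matrix`: `rates` (units x events),
#'   `events` metadata tibble, `window`, `zscored`.
#' @export
align_responses <- function(spikes, events, window = c(0.1, 0.5),
                            zscore = FALSE) {
  spk <- if (inherits(spikes, "spike_data")) spikes$spikes else spikes
  stopifnot(is.list(spk), !is.null(names(spk)), nrow(events) > 0L)
  if (length(window) != 2L || window[[1L]] < 0 || diff(window) <= 0) {
    stop("window must satisfy end > lag >= 0", call. = FALSE)
  }
  starts <- events$onset + window[[1L]]
  ends <- events$onset + window[[2L]]
  dur <- diff(window)
  rates <- vapply(spk, function(s) {
    s <- sort(s)
    (count_lt(s, ends) - count_lt(s, starts)) / dur
  }, numeric(length(starts)))
  rates <- matrix(rates, nrow = length(starts))
  rates <- t(rates)
  dimnames(rates) <- list(names(spk),
                          as.character(events$event_id %||% seq_len(nrow(events))))
  out <- structure(
    list(rates = rates, events = as_tibble(events), window = window,
         zscored = FALSE),
    class = "response_matrix"
  )
  if (zscore) zscore_units(out) else out
}

# number of sorted values strictly below each x (vectorized)
count_lt <- function(sorted, x) findInterval(x, sorted, left.open = TRUE)

#' Z-score a response matrix per unit
#'
#' Centers and scales each unit's rates across the included events. Units
#' with zero rate variance become all-zero rows.
#'
#' @param rm A `response_matrix`.
#' @return The z-scored `response_matrix`.
#' @export
zscore_units <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  mu <- rowMeans(rm$rates)
  sdv <- apply(rm$rates, 1L, sd)
  sdv[sdv == 0] <- Inf  # constant units -> 0 after scaling
  rm$rates <- (rm$rates - mu) / sdv
  rm$zscored <- TRUE
  rm
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$rates), " units x ", ncol(x$rates),
      " events; window [", x$window[[1L]], ", ", x$window[[2L]], ") s",
      if (x$zscored) "; z-scored", "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.response_matrix <- function(x, ...) {
  long <- as_tibble(x$rates, rownames = "unit") |>
    tidyr::pivot_longer(-"unit", names_to = "event_id", values_to = "rate") |>
    dplyr::mutate(event_id = as.integer(.data$event_id))
  dplyr::left_join(long, x$events, by = "event_id")
}

#' Subset a response matrix by event predicates
#'
#' Filters the event columns with dplyr-style predicates over the event
#' metadata (condition, position, domain, sentence id, ...). Supports, e.g.,
#' the every-other-word control via `position %% 2 == 1`.
#'
#' @param rm A `response_matrix`.
#' @param ... Logical predicates evaluated in the events tibble.
#' @return The column-subset `response_matrix`.
#' @export
select_events <- function(rm, ...) {
  stopifnot(inherits(rm, "response_matrix"))
  keep_tbl <- dplyr::filter(dplyr::mutate(rm$events,
                                          .row = dplyr::row_number()), ...)
  if (nrow(keep_tbl) == 0L) stop("empty event selection", call. = FALSE)
  idx <- keep_tbl$.row
  rm$rates <- rm$rates[, idx, drop = FALSE]
  rm$events <- dplyr::select(keep_tbl, -".row")
  rm
}

#' Units of a response matrix
#' @param rm A `response_matrix`.
#' @export
units_of <- function(rm) rownames(rm$rates)

# Mean rate per word (units x words) over the events of each token.
word_mean_rates <- function(rm, tokens = NULL) {
  tok <- rm$events$token
  words <- if (is.null(tokens)) sort(unique(tok)) else tokens
  out <- vapply(words, function(w) {
    rowMeans(rm$rates[, tok == w, drop = FALSE])
  }, numeric(nrow(rm$rates)))
  matrix(out, nrow = nrow(rm$rates),
         dimnames = list(rownames(rm$rates), words))
}
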