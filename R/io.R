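# Plain-text serialization of the pipeline's data objects.

#' Write and read word events as TSV
#'
#' @param events Word-event tibble.
#' @param path File path.
#' @return `read_events_tsv()` returns the events tibble.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write and read a domain partition as two-column TSV
#'
#' Centroids travel in a `<path>.centroids.tsv` sidecar so a partition
#' round-trips completely.
#'
#' @param partition A [domain_partition()].
#' @param path File path for the word/domain table.
#' @return `read_partition_tsv()` returns the [domain_partition()].
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(as_tibble(partition), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(format(partition$centroids, digits = 12),
                     paste0(path, ".centroids.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cen <- as.matrix(utils::read.delim(paste0(path, ".centroids.tsv"),
                                     header = FALSE))
  domain_partition(setNames(tab$domain, tab$word), unname(cen))
}

#' Write a response matrix as TSV with a JSON sidecar
#'
#' Events are rows and units are columns; the sidecar records the window and
#' z-scoring convention.
#'
#' @param rm A `response_matrix`.
#' @param path File path for the rates table.
#' @return `read_response_matrix_tsv()` returns the `response_matrix`.
#' @export
write_response_matrix_tsv <- function(rm, path) {
  tab <- cbind(event_id = rm$events$event_id, as.data.frame(t(rm$rates)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_events_tsv(rm$events, paste0(path, ".events.tsv"))
  jsonlite::write_json(
    list(window = rm$window, zscored = rm$zscored,
         units = rownames(rm$rates)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_response_matrix_tsv
#' @export
read_response_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rates <- t(as.matrix(tab[, -1L, drop = FALSE]))
  rownames(rates) <- meta$units
  colnames(rates) <- as.character(tab$event_id)
  structure(
    list(rates = rates, events = read_events_tsv(paste0(path, ".events.tsv")),
         window = meta$window, zscored = isTRUE(meta$zscored)),
    class = "response_matrix"
  )
}

#' Write spike data as one file per unit plus a JSON manifest
#'
#' Each unit's sorted spike times (seconds) go to `<unit>.txt`; the manifest
#' carries unit ids and the ground-truth tuning table.
#'
#' @param spikes A `spike_data` object.
#' @param dir Output directory (created if missing).
#' @return `read_spikes_dir()` returns the `spike_data`.
#' @export
write_spikes_dir <- function(spikes, dir) {
  stopifnot(inherits(spikes, "spike_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (u in names(spikes$spikes)) {
    writeLines(format(spikes$spikes[[u]], digits = 12, trim = TRUE,
                      scientific = FALSE),
               file.path(dir, paste0(u, ".txt")))
  }
  jsonlite::write_json(
    list(units = names(spikes$spikes), window = spikes$window,
         ground_truth = spikes$ground_truth),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_spikes_dir
#' @export
read_spikes_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  spikes <- lapply(meta$units, function(u) {
    f <- file.path(dir, paste0(u, ".txt"))
    lines <- readLines(f)
    as.numeric(lines[nzchar(lines)])
  })
  names(spikes) <- meta$units
  structure(
    list(spikes = spikes, ground_truth = as_tibble(meta$ground_truth),
         window = unlist(meta$window)),
    class = "spike_data"
  )
}
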