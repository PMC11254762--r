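# Word-embedding tables: construction, word2vec text I/O, frequency filtering.

#' Construct a word-embedding table
#'
#' An embedding table pairs a vocabulary of unique lowercase tokens with
#' real-valued vectors of a common dimension. Vectors are L2-normalized on
#' construction (cosine geometry is used throughout the package), with the
#' raw norms retained as an attribute.
#'
#' @param words Character vector of unique tokens (lowercased internally).
#' @param vectors Numeric matrix, one row per word.
#' @param normalize Normalize rows to unit L2 norm (default `TRUE`).
#' @return An object of class `embedding_tbl`.
#' @export
embedding_tbl <- function(words, vectors, normalize = TRUE) {
  words <- tolower(as.character(words))
  vectors <- as.matrix(vectors)
  if (length(words) != nrow(vectors)) {
    stop("`words` and rows of `vectors` differ in length", call. = FALSE)
  }
  if (anyDuplicated(words)) {
    stop("duplicate words in embedding table: ",
         paste(unique(words[duplicated(words)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(vectors))) stop("non-finite embedding entries", call. = FALSE)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero-norm embedding vector", call. = FALSE)
  if (normalize) vectors <- vectors / norms
  rownames(vectors) <- words
  structure(
    list(words = words, vectors = vectors, dim = ncol(vectors)),
    norms = norms,
    class = "embedding_tbl"
  )
}

#' @export
print.embedding_tbl <- function(x, ...) {
  cat("<embedding_tbl> ", length(x$words), " words x ", x$dim, " dims\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.embedding_tbl <- function(x, ...) {
  tibble(word = x$words, vector = unname(split(x$vectors, row(x$vectors))))
}

#' Number of words in an embedding table
#' @param x An `embedding_tbl`.
#' @export
n_words <- function(x) length(x$words)

# Subset an embedding table by word, preserving order of `words`.
subset_embeddings <- function(x, words) {
  keep <- intersect(words, x$words)
  if (length(keep) == 0L) stop("no words left after subsetting", call. = FALSE)
  embedding_tbl(keep, x$vectors[keep, , drop = FALSE], normalize = FALSE)
}

#' Read word vectors in word2vec text format
#'
#' Parses the plain-text word2vec dialect: a header line `"n d"` followed by
#' one `"word v1 ... vd"` line per word. Matching against `vocab` is
#' case-insensitive; words requested but absent from the file are recorded in
#' the `"missing_words"` attribute.
#'
#' @param path Path to the text file.
#' @param vocab Optional character vector restricting which words to load.
#' @param on_duplicate `"last"` (keep last occurrence, default) or `"error"`.
#' @return An [embedding_tbl()].
#' @export
read_word2vec <- function(path, vocab = NULL, on_duplicate = c("last", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty embedding file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.numeric(hdr)))) {
    stop("malformed header (expected \"n d\") at line 1 of ", path, call. = FALSE)
  }
  n_decl <- as.integer(hdr[[1L]])
  d <- as.integer(hdr[[2L]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != n_decl) {
    warning("header declares ", n_decl, " words but file has ", length(body),
            call. = FALSE)
  }
  words <- character(length(body))
  vecs <- matrix(NA_real_, length(body), d)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop("malformed line ", i + 1L, ": expected ", d + 1L, " fields, got ",
           length(parts), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(v)) stop("non-numeric vector entry at line ", i + 1L, call. = FALSE)
    words[[i]] <- tolower(parts[[1L]])
    vecs[i, ] <- v
  }
  if (anyDuplicated(words)) {
    dups <- unique(words[duplicated(words)])
    if (on_duplicate == "error") {
      stop("duplicate words in file: ", paste(dups, collapse = ", "), call. = FALSE)
    }
    message("duplicate words (keeping last occurrence): ",
            paste(dups, collapse = ", "))
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  missing_words <- character(0)
  if (!is.null(vocab)) {
    vocab <- tolower(vocab)
    missing_words <- setdiff(vocab, words)
    if (length(missing_words)) {
      message(length(missing_words), " requested word(s) absent from file")
    }
    sel <- words %in% vocab
    if (!any(sel)) stop("no requested words found in file", call. = FALSE)
    words <- words[sel]
    vecs <- vecs[sel, , drop = FALSE]
  }
  out <- embedding_tbl(words, vecs)
  attr(out, "missing_words") <- missing_words
  out
}

#' Write an embedding table in word2vec text format
#'
#' @param x An [embedding_tbl()].
#' @param path Output path.
#' @param digits Significant digits per coordinate (default 10, round-trips
#'   well below 1e-6).
#' @export
write_word2vec <- function(x, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(length(x$words), x$dim), con)
  body <- vapply(seq_along(x$words), function(i) {
    paste(x$words[[i]], paste(formatC(x$vectors[i, ], digits = digits,
                                      format = "g"), collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Remove high-frequency words from an embedding table
#'
#' Drops words whose frequency score exceeds (by default) a threshold, the
#' standard stop-word removal step before semantic clustering: very frequent
#' function words carry little lexical meaning. Words with no score are kept
#' and reported.
#'
#' @param x An [embedding_tbl()].
#' @param freq Named numeric vector of frequency scores (names are words).
#' @param threshold Score cutoff (default 2.5).
#' @param direction `"above"` removes scores strictly greater than
#'   `threshold` (default); `"below"` removes scores strictly smaller.
#' @return A filtered [embedding_tbl()].
#' @export
filter_frequent_words <- function(x, freq, threshold = 2.5,
                                  direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(freq))
  names(freq) <- tolower(names(freq))
  scores <- freq[x$words]
  unscored <- x$words[is.na(scores)]
  if (length(unscored)) {
    message(length(unscored), " word(s) without frequency score kept")
  }
  drop <- if (direction == "above") scores > threshold else scores < threshold
  drop[is.na(drop)] <- FALSE
  if (all(drop)) stop("all words filtered", call. = FALSE)
  subset_embeddings(x, x$words[!drop])
}
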