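#' Build a document-term matrix from cleaned documents
#'
#' Rows are documents, columns are terms (the union of all tokens, sorted),
#' entries are occurrence counts. The matrix is held sparse
#' ([Matrix::dgCMatrix-class]) by default; all operations behave
#' identically for dense storage.
#'
#' @param docs named list of token vectors as returned by [clean_corpus()];
#'   names are the document ids.
#' @param sparse logical; store counts as a sparse `Matrix` (default) or a
#'   dense base matrix.
#' @return an object of class `ais_dtm`: a list with `counts` (docs x
#'   terms), `doc_ids`, `terms` and `doc_freq` (per-term number of
#'   documents containing it).
#' @export
build_dtm <- function(docs, sparse = TRUE) {
  if (length(docs) == 0L) stop("cannot build a DTM from an empty corpus")
  ids <- names(docs)
  if (is.null(ids)) ids <- as.character(seq_along(docs))
  if (anyDuplicated(ids)) stop("document ids must be unique")
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  n <- length(docs); p <- length(vocab)
  if (p == 0L) {
    counts <- Matrix::Matrix(0, n, p, sparse = TRUE,
                             dimnames = list(ids, vocab))
  } else {
    triplets <- lapply(seq_along(docs), function(d) {
      if (length(docs[[d]]) == 0L) return(NULL)
      tab <- table(docs[[d]])
      cbind(d, match(names(tab), vocab), as.integer(tab))
    })
    trip <- do.call(rbind, triplets)
    if (is.null(trip)) {
      counts <- Matrix::sparseMatrix(integer(), integer(), x = numeric(),
                                     dims = c(n, p),
                                     dimnames = list(ids, vocab))
    } else {
      counts <- Matrix::sparseMatrix(trip[, 1L], trip[, 2L], x = trip[, 3L],
                                     dims = c(n, p),
                                     dimnames = list(ids, vocab))
    }
  }
  if (!sparse) counts <- as.matrix(counts)
  new_ais_dtm(counts)
}

new_ais_dtm <- function(counts) {
  structure(
    list(counts = counts,
         doc_ids = as.character(rownames(counts)),
         terms = as.character(colnames(counts)),
         doc_freq = doc_frequencies(counts)),
    class = "ais_dtm")
}

## transpose that works for both storage backends (Matrix's t is an S4
## method we do not import as a generic)
t_counts <- function(m) {
  if (inherits(m, "Matrix")) Matrix::t(m) else t(m)
}

doc_frequencies <- function(counts) {
  df <- if (inherits(counts, "Matrix")) {
    Matrix::colSums(counts > 0)
  } else {
    colSums(counts > 0)
  }
  stats::setNames(as.integer(df), colnames(counts))
}

#' @export
print.ais_dtm <- function(x, ...) {
  cat(sprintf("<ais_dtm> %d documents x %d terms (%s storage)\n",
              nrow(x$counts), ncol(x$counts),
              if (inherits(x$counts, "Matrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.ais_dtm <- function(x) dim(x$counts)

#' Remove sparse terms from a DTM
#'
#' Keeps exactly the terms whose document frequency (number of documents
#' containing the term at least once) exceeds `k`. Sparse terms are mostly
#' noise and dominate the vocabulary of short-text corpora; dropping them
#' is the standard dimension-reduction step before univariate screening.
#' Document rows are preserved, so rows may become all-zero.
#'
#' @param dtm an `ais_dtm`.
#' @param k non-negative integer threshold; terms appearing in `<= k`
#'   documents are removed. The study default is 500.
#' @return filtered `ais_dtm` (possibly with an empty vocabulary).
#' @export
filter_sparse <- function(dtm, k = 500) {
  stopifnot(inherits(dtm, "ais_dtm"), length(k) == 1L, k >= 0)
  keep <- dtm$doc_freq > k
  new_ais_dtm(dtm$counts[, keep, drop = FALSE])
}

#' Transpose a document-term matrix
#'
#' Returns the term-document matrix: rows become terms, columns documents.
#' `t(t(dtm))` restores the original.
#'
#' @param x an `ais_dtm`.
#' @return an object of class `ais_tdm` with fields `counts`, `terms`
#'   (rows) and `doc_ids` (columns).
#' @export
t.ais_dtm <- function(x) {
  structure(list(counts = t_counts(x$counts),
                 terms = x$terms, doc_ids = x$doc_ids),
            class = "ais_tdm")
}

#' @export
t.ais_tdm <- function(x) new_ais_dtm(t_counts(x$counts))

#' @export
print.ais_tdm <- function(x, ...) {
  cat(sprintf("<ais_tdm> %d terms x %d documents\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Attach document outcomes to a DTM
#'
#' Aligns outcome columns of the raw document table to the DTM rows by
#' document id (never by position) and returns an analysis table.
#'
#' @param dtm an `ais_dtm`.
#' @param raw_docs data frame with a `doc_id` column plus any outcome
#'   columns (`outcome_count`, `topic_label`, ...).
#' @return data frame with one row per DTM document: `doc_id` followed by
#'   the outcome columns of `raw_docs`, in DTM row order.
#' @export
join_outcomes <- function(dtm, raw_docs) {
  stopifnot(inherits(dtm, "ais_dtm"), is.data.frame(raw_docs),
            "doc_id" %in% names(raw_docs))
  idx <- match(dtm$doc_ids, as.character(raw_docs$doc_id))
  if (anyNA(idx)) {
    stop("documents missing from raw_docs: ",
         paste(utils::head(dtm$doc_ids[is.na(idx)], 5L), collapse = ", "))
  }
  out <- raw_docs[idx, , drop = FALSE]
  out$doc_id <- dtm$doc_ids
  rownames(out) <- NULL
  out[, c("doc_id", setdiff(names(out), "doc_id")), drop = FALSE]
}

#' Export / import a DTM as Matrix Market files
#'
#' Writes `<stem>.mtx` (counts), `<stem>.terms.txt` and
#' `<stem>.doc_ids.txt`; `read_dtm_mtx()` reads them back. Plain-text
#' round-trip so pipeline stages compose across processes.
#'
#' @param dtm an `ais_dtm`.
#' @param stem path stem without extension.
#' @return `write_dtm_mtx()` the stem, invisibly; `read_dtm_mtx()` an
#'   `ais_dtm`.
#' @export
write_dtm_mtx <- function(dtm, stem) {
  stopifnot(inherits(dtm, "ais_dtm"))
  m <- methods::as(methods::as(Matrix::Matrix(dtm$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(dtm$terms, paste0(stem, ".terms.txt"))
  writeLines(dtm$doc_ids, paste0(stem, ".doc_ids.txt"))
  invisible(stem)
}

#' @rdname write_dtm_mtx
#' @export
read_dtm_mtx <- function(stem) {
  counts <- Matrix::readMM(paste0(stem, ".mtx"))
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(readLines(paste0(stem, ".doc_ids.txt")),
                           readLines(paste0(stem, ".terms.txt")))
  new_ais_dtm(counts)
}
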