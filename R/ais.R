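## Aggregated influence scores: per-document summaries of the
## frequency-weighted term weights (RRs or ORs).
##
## For a document containing weighted terms i = 1..k with in-document
## frequencies n_i and weights w_i:
##   AIS-mean   = sum(n_i w_i) / sum(n_i)
##   AIS-sum    = sum(n_i w_i)
##   AIS-median = median of the multiset where w_i is replicated n_i times
## Terms whose weight is absent (NA) never enter the calculation; a
## document with no weighted term has missing scores.

#' Per-term propensity scores of one document
#'
#' Pairs each weighted term occurring in the document with its in-document
#' frequency and its weight; the propensity score of a term is frequency
#' times weight. Terms with an absent (`NA`) weight are silently dropped.
#'
#' @param doc_counts named numeric vector: term frequencies of one document
#'   (zeros allowed and ignored).
#' @param weights term-weight data frame ([screen_terms_count()] /
#'   [screen_terms_logistic()] output) or a named numeric vector of
#'   weights.
#' @return data frame with columns `term`, `frequency`, `weight`,
#'   `propensity` (possibly zero rows).
#' @export
propensity_scores <- function(doc_counts, weights) {
  w <- as_weight_vector(weights)
  doc_counts <- doc_counts[doc_counts > 0]
  terms <- intersect(names(doc_counts), names(w)[is.finite(w)])
  data.frame(term = terms,
             frequency = as.numeric(doc_counts[terms]),
             weight = as.numeric(w[terms]),
             propensity = as.numeric(doc_counts[terms]) * as.numeric(w[terms]),
             stringsAsFactors = FALSE)
}

as_weight_vector <- function(weights) {
  if (is.data.frame(weights)) {
    stopifnot(all(c("term", "weight") %in% names(weights)))
    stats::setNames(weights$weight, weights$term)
  } else {
    stopifnot(!is.null(names(weights)))
    weights
  }
}

#' AIS aggregations over (frequency, weight) pairs
#'
#' `ais_mean()` is the frequency-weighted mean of the weights,
#' `ais_sum()` the total propensity, and `ais_median()` the median of the
#' multiset in which each weight is replicated by its frequency (sorted
#' ascending; even total frequency averages the two middle entries). All
#' three return `NA` for a document with no weighted term.
#'
#' @param pairs data frame from [propensity_scores()], or any data frame
#'   with `frequency` and `weight` columns.
#' @return numeric scalar (`NA` if `pairs` has no rows).
#' @examples
#' pairs <- data.frame(frequency = c(1, 1, 1),
#'                     weight = c(3.6210, 4.3122, 4.529))
#' ais_mean(pairs)    # 4.1541
#' ais_median(pairs)  # 4.3122
#' ais_sum(pairs)     # 12.4622
#' @export
ais_mean <- function(pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  sum(pairs$frequency * pairs$weight) / sum(pairs$frequency)
}

#' @rdname ais_mean
#' @export
ais_sum <- function(pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  sum(pairs$frequency * pairs$weight)
}

#' @rdname ais_mean
#' @export
ais_median <- function(pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  stats::median(rep(pairs$weight, times = pairs$frequency))
}

#' Score every document of a corpus
#'
#' Computes AIS-mean, AIS-median and AIS-sum for each DTM row from a term
#' weight table. Documents containing no weighted term get missing scores
#' (they are excluded from downstream final models, mirroring the handling
#' of documents whose every term fell below the sparsity threshold).
#'
#' @param dtm an `ais_dtm`.
#' @param weights term-weight data frame or named numeric vector.
#' @return data frame with one row per document: `doc_id`, `ais_mean`,
#'   `ais_median`, `ais_sum`, `n_terms_used` (number of distinct weighted
#'   terms present).
#' @export
score_corpus <- function(dtm, weights) {
  stopifnot(inherits(dtm, "ais_dtm"))
  w <- as_weight_vector(weights)
  w <- w[is.finite(w)]
  shared <- intersect(dtm$terms, names(w))
  sub <- dtm$counts[, shared, drop = FALSE]
  out <- data.frame(doc_id = dtm$doc_ids,
                    ais_mean = NA_real_, ais_median = NA_real_,
                    ais_sum = NA_real_, n_terms_used = 0L,
                    stringsAsFactors = FALSE)
  if (length(shared) == 0L || nrow(sub) == 0L) return(out)
  wv <- as.numeric(w[shared])
  tot_prop <- as.numeric(sub %*% wv)
  tot_freq <- if (inherits(sub, "Matrix")) Matrix::rowSums(sub)
              else rowSums(sub)
  n_used <- if (inherits(sub, "Matrix")) Matrix::rowSums(sub > 0)
            else rowSums(sub > 0)
  hit_doc <- n_used > 0
  out$ais_sum[hit_doc] <- tot_prop[hit_doc]
  out$ais_mean[hit_doc] <- tot_prop[hit_doc] / tot_freq[hit_doc]
  out$n_terms_used <- as.integer(n_used)
  dense <- as.matrix(sub[hit_doc, , drop = FALSE])
  med <- apply(dense, 1L, function(cnt) {
    hit <- cnt > 0
    stats::median(rep(wv[hit], times = cnt[hit]))
  })
  out$ais_median[hit_doc] <- as.numeric(med)
  out
}

#' Write an AIS table to CSV
#'
#' @param ais data frame from [score_corpus()].
#' @param path output CSV path.
#' @export
write_ais_csv <- function(ais, path) {
  utils::write.csv(ais, path, row.names = FALSE)
  invisible(path)
}
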