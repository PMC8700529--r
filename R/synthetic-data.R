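## Seeded synthetic short-text corpora with planted term effects.
##
## The generator emulates the statistical skeleton the AIS method assumes:
## two topic groups sharing a background vocabulary whose per-term usage is
## mildly group-skewed, group-specific topic terms that occasionally leak
## into the other group, and a count outcome driven by a hurdle process
## whose linear predictor is a sum of planted per-term log relative risks.

#' Specification of a synthetic two-topic corpus
#'
#' @param n_docs length-2 integer vector: documents per group (group 1 is
#'   the positive / topic class, label 1).
#' @param vocabulary_size number of shared background terms (letter-only
#'   tokens, so they survive text cleaning unchanged).
#' @param doc_length length-2 vector `(min, max)`: background tokens per
#'   document, uniform.
#' @param topic_term_sets list of two named numeric vectors: per-term
#'   probability that a document of that group contains the term once.
#' @param cross_leakage multiplier applied to a topic term's probability
#'   when sampling documents of the *other* group; keeps topic terms
#'   shared between groups (as real vocabularies are) while preserving a
#'   strong group contrast.
#' @param background_skew_sd standard deviation of the per-background-term
#'   log usage skew between groups; 0 makes background usage identical in
#'   both groups.
#' @param planted_count_effects named numeric vector of true log relative
#'   risks entering the count outcome's linear predictor.
#' @param gamma0,gamma1 zero-component (hurdle) coefficients: the
#'   probability of a positive count is `plogis(gamma0 + gamma1 * eta)`
#'   with `eta` the count linear predictor.
#' @param beta0 count-component intercept; the positive-part mean is
#'   `exp(eta)` with `eta = beta0 + sum(effects * term frequencies)`.
#' @param theta NB dispersion of the positive-count component.
#' @param decorate prefix/append tweet furniture (an `RT @user` marker and
#'   a URL) to each raw text, exercising the cleaning stage.
#' @param seed integer seed; a fixed seed makes the corpus byte-identical.
#' @return a `corpus_spec` list.
#' @export
corpus_spec <- function(n_docs = c(2500L, 2500L),
                        vocabulary_size = 40L,
                        doc_length = c(3L, 8L),
                        topic_term_sets = list(
                          c(spectrum = 0.35, awareness = 0.30, child = 0.30,
                            support = 0.25, world = 0.20),
                          c(outbreak = 0.35, vaccine = 0.30, campaign = 0.30,
                            safety = 0.25, violence = 0.20)),
                        cross_leakage = 0.1,
                        background_skew_sd = 0.4,
                        planted_count_effects = c(child = 0.7),
                        gamma0 = -0.5, gamma1 = 0.8, beta0 = 0.3,
                        theta = 2, decorate = FALSE, seed = 1L) {
  spec <- list(n_docs = as.integer(n_docs), vocabulary_size = vocabulary_size,
               doc_length = as.integer(doc_length),
               topic_term_sets = topic_term_sets,
               cross_leakage = cross_leakage,
               background_skew_sd = background_skew_sd,
               planted_count_effects = planted_count_effects,
               gamma0 = gamma0, gamma1 = gamma1, beta0 = beta0,
               theta = theta, decorate = isTRUE(decorate),
               seed = as.integer(seed))
  validate_corpus_spec(spec)
  structure(spec, class = "corpus_spec")
}

validate_corpus_spec <- function(spec) {
  stopifnot(length(spec$n_docs) == 2L, all(spec$n_docs >= 1L),
            spec$vocabulary_size >= 1L,
            length(spec$doc_length) == 2L,
            spec$doc_length[1L] >= 1L,
            spec$doc_length[2L] >= spec$doc_length[1L],
            length(spec$topic_term_sets) == 2L,
            spec$cross_leakage >= 0, spec$cross_leakage <= 1,
            spec$background_skew_sd >= 0, spec$theta > 0,
            length(spec$seed) == 1L, is.finite(spec$seed))
  probs <- unlist(spec$topic_term_sets, use.names = FALSE)
  if (length(probs) && (any(probs < 0) || any(probs > 1)))
    stop("topic term probabilities must lie in [0, 1]")
  invisible(spec)
}

## letter-only background vocabulary: "wordaa", "wordab", ...
background_vocab <- function(p) {
  idx <- seq_len(p) - 1L
  paste0("word", letters[idx %/% 26L + 1L], letters[idx %% 26L + 1L])
}

## run code under a local seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

## zero-truncated NB draws by inverse-cdf restricted to (P(0), 1]
rztnbinom <- function(n, mu, theta) {
  p0 <- exp(-theta * log1p(mu / theta))
  u <- stats::runif(n, p0, 1)
  y <- stats::qnbinom(u, size = theta, mu = mu)
  pmax(y, 1L)
}

#' Generate a synthetic two-topic corpus
#'
#' Draws, per document: uniform-length background token sequence (term
#' usage mildly group-skewed), group topic terms by per-term Bernoulli
#' inclusion (with cross-group leakage), then the count outcome from the
#' hurdle process of the spec -- linear predictor
#' `eta = beta0 + sum(planted log-RR * term frequency)`, positive
#' indicator `Bernoulli(plogis(gamma0 + gamma1 * eta))`, positive counts
#' zero-truncated NB with mean `exp(eta)` and dispersion `theta`.
#'
#' @param spec a [corpus_spec()].
#' @return data frame with columns `doc_id`, `text`, `outcome_count`,
#'   `topic_label` (1 for group 1), one row per document; the token order
#'   within a text is randomised.
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) spec <- do.call(corpus_spec, spec)
  validate_corpus_spec(spec)
  with_seed(spec$seed, {
    bg <- background_vocab(spec$vocabulary_size)
    skew <- stats::rnorm(spec$vocabulary_size, 0, spec$background_skew_sd)
    wA <- exp(skew / 2); wB <- exp(-skew / 2)
    n_tot <- sum(spec$n_docs)
    texts <- character(n_tot)
    ys <- integer(n_tot)
    labels <- integer(n_tot)
    k <- 0L
    eff <- spec$planted_count_effects
    for (g in 1:2) {
      own <- spec$topic_term_sets[[g]]
      other <- spec$topic_term_sets[[3L - g]]
      bw <- if (g == 1L) wA else wB
      for (d in seq_len(spec$n_docs[g])) {
        k <- k + 1L
        len <- sample(spec$doc_length[1L]:spec$doc_length[2L], 1L)
        tokens <- sample(bg, len, replace = TRUE, prob = bw)
        if (length(own))
          tokens <- c(tokens, names(own)[stats::runif(length(own)) < own])
        if (length(other)) {
          p_leak <- other * spec$cross_leakage
          tokens <- c(tokens,
                      names(other)[stats::runif(length(other)) < p_leak])
        }
        tokens <- sample(tokens)
        freq <- if (length(eff))
          vapply(names(eff), function(tm) sum(tokens == tm), numeric(1))
        else numeric()
        eta <- spec$beta0 + sum(eff * freq)
        pos <- stats::runif(1) < stats::plogis(spec$gamma0 +
                                                 spec$gamma1 * eta)
        ys[k] <- if (pos) rztnbinom(1L, exp(eta), spec$theta) else 0L
        text <- paste(tokens, collapse = " ")
        if (spec$decorate)
          text <- paste("RT @someone", text, "http://t.co/xyz123")
        texts[k] <- text
        labels[k] <- if (g == 1L) 1L else 0L
      }
    }
    data.frame(doc_id = sprintf("doc%06d", seq_len(n_tot)), text = texts,
               outcome_count = ys, topic_label = labels,
               stringsAsFactors = FALSE)
  })
}

#' The worked-example tweet and its printed term weights
#'
#' A fixed fixture: the cleaned token sequence of the example tweet
#' ("father take his child with to see his favorite band coldplay") and
#' the hurdle-model relative risks of its three vocabulary-retained terms
#' (take 3.6210, child 4.3122, see 4.529). Under these weights the
#' document's AIS-mean, AIS-median and AIS-sum are 4.1541, 4.3122 and
#' 12.4622 (4 d.p.).
#'
#' @return list with `doc` (fields `doc_id`, `tokens`), `weights` (a
#'   term-weight data frame), and `raw_text` (the pre-cleaning text).
#' @export
worked_example_fixture <- function() {
  list(
    doc = list(
      doc_id = "example_tweet",
      tokens = c("father", "take", "his", "child", "with", "to", "see",
                 "his", "favorite", "band", "coldplay")),
    weights = data.frame(
      term = c("take", "child", "see"),
      weight = c(3.6210, 4.3122, 4.529),
      std_err = NA_real_, p_value = NA_real_, converged = TRUE,
      source = "hurdle_count", stringsAsFactors = FALSE),
    raw_text = paste("Father takes his child with #Autism to see his",
                     "favorite band Coldplay"))
}

#' Write a synthetic corpus to the CSV schema the reader consumes
#'
#' @param corpus data frame from [generate_corpus()].
#' @param path output CSV path.
#' @export
write_corpus_csv <- function(corpus, path) {
  utils::write.csv(corpus, path, row.names = FALSE)
  invisible(path)
}
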