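#' Clean a raw short-text document into tokens
#'
#' Applies, in order: removal of topic words (case-insensitive, including
#' their hashtag forms), removal of URLs, `@`-mentions and the retweet
#' marker `"RT"`, removal of characters other than letters, digits, `"#"`
#' and whitespace, lowercasing, optional dropping of hashtag tokens,
#' removal of standalone numbers, and whitespace tokenization. Topic words
#' are the query terms that appear in (almost) every document of a
#' topic-restricted corpus and therefore carry no information; they are
#' stripped at token boundaries so that other tokens are never affected.
#'
#' @param text character scalar; the raw document text. `NA` is treated as
#'   empty.
#' @param topic_words character vector of lowercase topic words to remove
#'   (e.g. the search keywords used to collect the corpus).
#' @param drop_hashtags logical; if `TRUE`, any token beginning with `"#"`
#'   is removed entirely. If `FALSE`, the leading `"#"` is stripped and the
#'   tag body kept as an ordinary token.
#' @param stem `"none"` (default) or `"light"`. Light stemming strips a
#'   trailing `"s"` from tokens longer than three characters that do not
#'   end in `"ss"`, mapping plain plurals and third-person verbs
#'   (`"takes"` to `"take"`) onto their base form.
#' @return character vector of cleaned lowercase tokens (possibly empty).
#' @examples
#' clean_text("Father takes his child to see Coldplay", stem = "light")
#' clean_text("RT @user http://x.y #flu flu!!", topic_words = "flu",
#'            drop_hashtags = TRUE)
#' @export
clean_text <- function(text, topic_words = character(), drop_hashtags = TRUE,
                       stem = c("none", "light")) {
  stem <- match.arg(stem)
  stopifnot(length(text) <= 1L)
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character())
  txt <- text

  ## topic words first, incl. hashtag forms, case-insensitive, at token
  ## boundaries only
  for (w in topic_words) {
    txt <- gsub(paste0("(?i)#?\\b", escape_regex(w), "\\b"), " ", txt,
                perl = TRUE)
  }

  ## URLs and mentions are dropped as whole whitespace-delimited tokens
  txt <- gsub("(^|\\s)https?\\S*", " ", txt, perl = TRUE)
  txt <- gsub("(^|\\s)http\\S*", " ", txt, perl = TRUE)
  txt <- gsub("(^|\\s)@\\S*", " ", txt, perl = TRUE)
  txt <- gsub("\\bRT\\b", " ", txt)

  ## keep only letters, digits, '#' and whitespace; then lowercase
  txt <- gsub("[^A-Za-z0-9#[:space:]]", "", txt)
  txt <- tolower(txt)

  tokens <- strsplit(trimws(txt), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (drop_hashtags) {
    tokens <- tokens[!startsWith(tokens, "#")]
  } else {
    tokens <- sub("^#+", "", tokens)
    tokens <- tokens[nzchar(tokens)]
  }
  ## leftover URL fragments; digits delimit tokens during character
  ## filtering but do not survive into the vocabulary (standalone numbers
  ## vanish entirely, alphanumeric codes keep their letters)
  tokens <- tokens[!startsWith(tokens, "http")]
  tokens <- gsub("[0-9]+", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (stem == "light") tokens <- light_stem(tokens)
  tokens
}

## minimal plural / 3rd-person-s stripper; deliberately conservative
light_stem <- function(tokens) {
  hit <- nchar(tokens) > 3L & endsWith(tokens, "s") & !endsWith(tokens, "ss")
  tokens[hit] <- substr(tokens[hit], 1L, nchar(tokens[hit]) - 1L)
  tokens
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Clean every document of a raw corpus
#'
#' @param corpus data frame with at least the columns named by `text_col`
#'   and `id_col`; typically read with [read_corpus_csv()] or produced by
#'   [generate_corpus()].
#' @param text_col,id_col column names holding the raw text and the unique
#'   document identifier.
#' @inheritParams clean_text
#' @return named list of token vectors, one per document, names = doc ids.
#' @export
clean_corpus <- function(corpus, text_col = "text", id_col = "doc_id",
                         topic_words = character(), drop_hashtags = TRUE,
                         stem = c("none", "light")) {
  stem <- match.arg(stem)
  stopifnot(is.data.frame(corpus), text_col %in% names(corpus),
            id_col %in% names(corpus))
  ids <- as.character(corpus[[id_col]])
  if (anyDuplicated(ids)) stop("document ids must be unique")
  out <- lapply(corpus[[text_col]], clean_text, topic_words = topic_words,
                drop_hashtags = drop_hashtags, stem = stem)
  names(out) <- ids
  out
}

#' Read a document table from CSV
#'
#' Thin wrapper around [utils::read.csv()] (UTF-8) that checks the
#' configured columns exist and that the count outcome, when present, is a
#' non-negative integer.
#'
#' @param path CSV file path.
#' @param text_col name of the free-text column.
#' @param count_col name of the non-negative integer outcome column, or
#'   `NULL` if the corpus carries no count outcome.
#' @param label_col name of the binary (0/1) topic label column, or `NULL`.
#' @param id_col name of the document identifier column, or `NULL` to
#'   assign row numbers.
#' @return data frame with standardised columns `doc_id`, `text`, and
#'   (when configured) `outcome_count` and `topic_label`.
#' @export
read_corpus_csv <- function(path, text_col = "text", count_col = NULL,
                            label_col = NULL, id_col = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!text_col %in% names(raw))
    stop("text column '", text_col, "' not found in ", path)
  out <- data.frame(
    doc_id = if (is.null(id_col)) as.character(seq_len(nrow(raw)))
             else as.character(raw[[id_col]]),
    text = as.character(raw[[text_col]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$doc_id)) stop("document ids must be unique")
  if (!is.null(count_col)) {
    if (!count_col %in% names(raw))
      stop("count column '", count_col, "' not found in ", path)
    y <- raw[[count_col]]
    if (any(!is.na(y) & (y < 0 | y != round(y))))
      stop("count outcome must be a non-negative integer")
    out$outcome_count <- as.integer(y)
  }
  if (!is.null(label_col)) {
    if (!label_col %in% names(raw))
      stop("label column '", label_col, "' not found in ", path)
    lab <- raw[[label_col]]
    if (any(!is.na(lab) & !lab %in% c(0, 1)))
      stop("topic label must be 0/1")
    out$topic_label <- as.integer(lab)
  }
  out
}
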