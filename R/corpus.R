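#' Preprocess a tweet stream into a modelling corpus
#'
#' Lowercases tokens, removes stopwords, drops tokens appearing in fewer
#' than `min_doc_freq` documents, and drops documents left empty (the count
#' of dropped documents is reported with a message and stored as an
#' attribute).
#'
#' @param tweets tweet data.frame with `id`, `day`, `author_id` and a
#'   `tokens` list-column.
#' @param stopwords character vector of tokens to remove (matched after
#'   lowercasing).
#' @param min_doc_freq minimum number of distinct documents a token must
#'   appear in to stay in the vocabulary.
#' @return an `ra_corpus`: list with `docs` (integer token-id vectors,
#'   1-based into `vocab`), `vocab`, `doc_id`, `doc_day`, `doc_author`.
#' @export
preprocess_corpus <- function(tweets, stopwords = character(),
                              min_doc_freq = 1L) {
  toks <- lapply(tweets$tokens, function(t) {
    t <- tolower(t)
    t[!t %in% tolower(stopwords)]
  })
  df_tab <- table(unlist(lapply(toks, unique)))
  vocab <- sort(names(df_tab)[df_tab >= min_doc_freq])
  docs <- lapply(toks, function(t) {
    i <- match(t, vocab)
    i[!is.na(i)]
  })
  keep <- lengths(docs) > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("all documents empty after preprocessing")
  if (n_dropped > 0) {
    message(sprintf("preprocess_corpus: dropped %d empty document(s)", n_dropped))
  }
  structure(
    list(docs = docs[keep], vocab = vocab,
         doc_id = tweets$id[keep],
         doc_day = as.Date(tweets$day[keep]),
         doc_author = tweets$author_id[keep]),
    class = "ra_corpus", n_dropped = n_dropped
  )
}

#' @export
print.ra_corpus <- function(x, ...) {
  cat(sprintf("<ra_corpus> %d documents, %d token types, %d tokens\n",
              length(x$docs), length(x$vocab), sum(lengths(x$docs))))
  invisible(x)
}

#' Write / read a corpus as sparse triplets plus a vocabulary list
#'
#' The counts file holds `doc word count` triplets (1-based indices); the
#' vocabulary and document metadata are sidecar delimited files.
#'
#' @param corpus an `ra_corpus`.
#' @param dir directory to hold `counts.txt`, `vocab.txt`, `docs.csv`.
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` an
#'   `ra_corpus` (token order within documents is not preserved — only
#'   counts are, which is all the exchangeable model uses).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- do.call(rbind, lapply(seq_along(corpus$docs), function(d) {
    tab <- table(corpus$docs[[d]])
    data.frame(doc = d, word = as.integer(names(tab)),
               count = as.integer(tab))
  }))
  write.table(trip, file.path(dir, "counts.txt"), row.names = FALSE,
              quote = FALSE)
  writeLines(corpus$vocab, file.path(dir, "vocab.txt"))
  write.csv(data.frame(id = corpus$doc_id, day = as.character(corpus$doc_day),
                       author = corpus$doc_author),
            file.path(dir, "docs.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  trip <- read.table(file.path(dir, "counts.txt"), header = TRUE)
  vocab <- readLines(file.path(dir, "vocab.txt"))
  meta <- read.csv(file.path(dir, "docs.csv"), stringsAsFactors = FALSE)
  docs <- lapply(split(trip, trip$doc), function(g) rep(g$word, g$count))
  structure(
    list(docs = unname(docs), vocab = vocab, doc_id = meta$id,
         doc_day = as.Date(meta$day), doc_author = meta$author),
    class = "ra_corpus", n_dropped = 0L
  )
}
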