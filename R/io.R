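#' Read / write tweet records as line-delimited JSON
#'
#' One JSON object per line with fields `id`, `author_id`, `day` (ISO
#' date), `tokens` (array), `retweeted_author_id` (null when the record is
#' not a retweet).
#'
#' @param tweets tweet data.frame.
#' @param path file path.
#' @return `write_tweets` returns `path` invisibly; `read_tweets` a tweet
#'   data.frame with a `tokens` list-column.
#' @export
write_tweets <- function(tweets, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    rec <- list(id = tweets$id[i], author_id = tweets$author_id[i],
                day = as.character(tweets$day[i]),
                tokens = as.list(tweets$tokens[[i]]),
                retweeted_author_id = tweets$retweeted_author_id[i])
    if (is.na(rec$retweeted_author_id)) rec["retweeted_author_id"] <- list(NULL)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_tweets
#' @export
read_tweets <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    author_id = vapply(recs, `[[`, "", "author_id"),
    day = as.Date(vapply(recs, `[[`, "", "day")),
    retweeted_author_id = vapply(recs, function(r) {
      r$retweeted_author_id %||% NA_character_
    }, NA_character_),
    stringsAsFactors = FALSE
  )
  out$tokens <- lapply(recs, function(r) unlist(r$tokens) %||% character(0))
  out
}
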