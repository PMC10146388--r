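#' Read / write an NRC-style emotion lexicon
#'
#' Delimited table `word, positive, negative, trust, anger, fear, joy,
#' sadness, surprise, anticipation, disgust` with 0/1 flags; a word may
#' carry several categories.
#'
#' @param path file path.
#' @return `read_lexicon` returns the validated lexicon data.frame.
#' @export
read_lexicon <- function(path) {
  lex <- read.csv(path, stringsAsFactors = FALSE)
  validate_lexicon(lex)
}

#' @rdname read_lexicon
#' @param lexicon lexicon data.frame.
#' @export
write_lexicon <- function(lexicon, path) {
  write.csv(validate_lexicon(lexicon), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_lexicon <- function(lex) {
  cats <- lexicon_categories()
  stopifnot(is.data.frame(lex), "word" %in% names(lex),
            all(cats %in% names(lex)))
  for (cat in cats) {
    if (!all(lex[[cat]] %in% c(0L, 1L))) {
      stop(sprintf("lexicon column '%s' must contain only 0/1 flags", cat))
    }
  }
  lex[, c("word", cats)]
}

#' Count lexicon category hits in one token list
#'
#' Each token occurrence whose word carries a category flag contributes one
#' to that category's count (repeated tokens count repeatedly; unknown
#' words contribute nothing). The net score is positive minus negative,
#' exactly.
#'
#' @param tokens character token list of one tweet.
#' @param lexicon lexicon data.frame (see [read_lexicon()]).
#' @return an `emotion_counts`: named integer vector over the ten
#'   categories plus `net`.
#' @export
score_tweet <- function(tokens, lexicon) {
  cats <- lexicon_categories()
  i <- match(tolower(tokens), lexicon$word)
  i <- i[!is.na(i)]
  counts <- vapply(cats, function(cat) sum(lexicon[[cat]][i]), numeric(1))
  counts <- as.integer(counts)
  names(counts) <- cats
  structure(c(counts, net = counts[["positive"]] - counts[["negative"]]),
            class = "emotion_counts")
}

#' Score every tweet in a stream against a lexicon
#'
#' Vectorized equivalent of [score_tweet()] over a tweet data.frame.
#'
#' @param tweets tweet data.frame with a `tokens` list-column.
#' @param lexicon lexicon data.frame.
#' @return data.frame with one row per tweet: `id`, the ten category
#'   counts, and `net`.
#' @export
score_tweets <- function(tweets, lexicon) {
  cats <- lexicon_categories()
  flags <- as.matrix(lexicon[, cats])
  rownames(flags) <- lexicon$word
  rows <- t(vapply(tweets$tokens, function(tok) {
    i <- match(tolower(tok), lexicon$word)
    i <- i[!is.na(i)]
    if (length(i)) colSums(flags[i, , drop = FALSE]) else numeric(length(cats))
  }, numeric(length(cats))))
  out <- as.data.frame(rows)
  names(out) <- cats
  out$net <- out$positive - out$negative
  cbind(data.frame(id = tweets$id, stringsAsFactors = FALSE), out)
}

#' Topic-weight a sentiment score
#'
#' The study's displayed weighting: the tweet's category score multiplied
#' by its topic-cluster probability. Bilinear in both arguments.
#'
#' @param counts an `emotion_counts` (or any named vector with the category).
#' @param cluster_prob topic-cluster probability in \[0, 1\].
#' @param category `"net"` or `"trust"`.
#' @return the weighted score (numeric scalar).
#' @export
weighted_topic_score <- function(counts, cluster_prob, category = c("net", "trust")) {
  category <- match.arg(category)
  if (any(cluster_prob < 0 | cluster_prob > 1)) {
    stop("cluster_prob must lie in [0, 1]")
  }
  unname(counts[[category]] * cluster_prob)
}

#' Aggregate per-tweet weighted scores to a daily series
#'
#' One value per calendar day over the configured range; days with no
#' tweets are missing (`NA`), never zero.
#'
#' @param scores data.frame with columns `id`, `day`, `value`.
#' @param mode `"mean"` (default) or `"sum"`.
#' @param dates optional `Date` vector (its range defines the calendar);
#'   defaults to the observed day range.
#' @return a [daily_series()] with per-day `n` tweet counts.
#' @export
aggregate_daily_scores <- function(scores, mode = c("mean", "sum"),
                                   dates = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(scores$id)) {
    stop("duplicate tweet ids in the score stream")
  }
  day <- as.Date(scores$day)
  rng <- if (is.null(dates)) range(day) else range(as.Date(dates))
  cal <- seq(rng[1], rng[2], by = "day")
  f <- factor(as.character(day), levels = as.character(cal))
  agg_fun <- if (mode == "mean") mean else sum
  vals <- tapply(scores$value, f, agg_fun)
  n <- tapply(scores$value, f, length)
  n[is.na(n)] <- 0L
  out <- daily_series(cal, as.numeric(vals), name = paste0("daily_", mode),
                      n_obs = as.integer(n))
  attr(out, "mode") <- mode
  out
}

#' Daily topic-weighted sentiment of a cluster
#'
#' End-to-end scoring stage: counts lexicon categories per tweet, weights
#' the chosen score (net sentiment or trust) by the tweet's topic-cluster
#' probability (summed gamma over the cluster's topics), and aggregates to
#' a daily series.
#'
#' @param tweets tweet data.frame (must align with the documents of `fit`
#'   via tweet ids).
#' @param lexicon lexicon data.frame.
#' @param fit an `lda_fit`.
#' @param cluster a [cluster_map()].
#' @param label cluster label.
#' @param category `"net"` or `"trust"`.
#' @param mode daily aggregation mode.
#' @param dates optional calendar range.
#' @return a [daily_series()].
#' @export
daily_weighted_sentiment <- function(tweets, lexicon, fit, cluster, label,
                                     category = c("net", "trust"),
                                     mode = c("mean", "sum"), dates = NULL) {
  category <- match.arg(category)
  mode <- match.arg(mode)
  idx <- setdiff(cluster$clusters[[label]], cluster$boilerplate)
  keep <- match(fit$doc_id, tweets$id)
  stopifnot(!anyNA(keep))
  sc <- score_tweets(tweets[keep, , drop = FALSE], lexicon)
  prob <- if (length(idx)) rowSums(fit$gamma[, idx, drop = FALSE]) else
    numeric(nrow(fit$gamma))
  val <- sc[[category]] * prob
  out <- aggregate_daily_scores(
    data.frame(id = sc$id, day = fit$doc_day, value = val),
    mode = mode, dates = dates
  )
  attr(out, "name") <- paste0("weighted_", category)
  out
}
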