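#' Configuration for the synthetic study generator
#'
#' Declares every parameter of the synthetic data-generating process: a
#' community-structured directed retweet graph with designated hub accounts,
#' daily tweet streams mixing planted topics (Dirichlet mixtures) with
#' lexicon-tagged emotion words, and an acceptance series produced by an
#' autoregression with known coefficients linking sentiment to acceptance.
#'
#' Defaults describe the study design emulated throughout the package:
#' 231 daily observations on the 0-1 acceptance scale, short 12-token posts,
#' a dominant "vaccination" topic (topic 1 by convention), a positive lag-1
#' sentiment-to-acceptance coefficient of 0.5, and deterministic terms
#' (constant plus linear trend) in the acceptance process.
#'
#' @param n_communities,nodes_per_community,hubs_per_community retweet-graph
#'   block structure; hubs are the first accounts of each community.
#' @param p_retweet_in,p_retweet_out per ordered node pair, per-trial retweet
#'   probability within / across communities.
#' @param hub_boost multiplier applied to the target's retweet probability
#'   when the target is a hub (capped at 1).
#' @param retweet_trials Binomial trial count per ordered pair, so arc
#'   weights are integers with mean `trials * p`.
#' @param n_days,tweets_per_day corpus size; days start at `start_date`.
#' @param K_topics,vocab_size,doc_topic_alpha,topic_word_sharpness planted
#'   topic structure: topic k places `topic_word_sharpness` of its mass
#'   uniformly on its own vocabulary block.
#' @param tokens_per_tweet tokens drawn per post (short-text regime).
#' @param retweet_fraction probability a generated post is a retweet of one
#'   of its author's graph out-neighbours.
#' @param emotion_word_fraction fraction of the vocabulary tagged per
#'   lexicon category.
#' @param emotion_boost on good-news (bad-news) days, probability that a
#'   vaccination-topic token is replaced by a positive/trust-tagged
#'   (negative-tagged) word.
#' @param good_news_days,bad_news_days integer day indices carrying elevated
#'   positive/trust or negative word rates in the vaccination topic. The
#'   defaults interleave both through the whole window so the daily
#'   sentiment signal varies at high frequency.
#' @param var_coeffs list with numeric vectors `a` (acceptance lags) and `b`
#'   (sentiment lags) of the acceptance-generating recursion.
#' @param var_const,var_trend deterministic terms of that recursion.
#' @param noise_sd innovation standard deviation (> 0).
#' @param sentiment_scale_mean,sentiment_scale_sd before entering the
#'   acceptance recursion, the realized daily sentiment signal is
#'   standardized to this mean and sd (defaults on the scale of the daily
#'   topic-weighted sentiment measure, keeping acceptance inside \[0, 1\]).
#' @param start_date first calendar day of the window.
#' @param seed integer master seed; every generator call derives its stream
#'   from it, so identical configs reproduce identical data bit-for-bit.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_communities = 3L,
                         nodes_per_community = 20L,
                         hubs_per_community = 2L,
                         p_retweet_in = 0.3,
                         p_retweet_out = 0.03,
                         hub_boost = 3,
                         retweet_trials = 10L,
                         n_days = 231L,
                         tweets_per_day = 40L,
                         K_topics = 3L,
                         vocab_size = 150L,
                         doc_topic_alpha = 0.1,
                         topic_word_sharpness = 0.95,
                         tokens_per_tweet = 12L,
                         retweet_fraction = 0.3,
                         emotion_word_fraction = 0.2,
                         emotion_boost = 0.5,
                         good_news_days = NULL,
                         bad_news_days = NULL,
                         var_coeffs = list(a = 0.6, b = 0.5),
                         var_const = 0.25,
                         var_trend = 0.0003,
                         noise_sd = 0.01,
                         sentiment_scale_mean = 0.018,
                         sentiment_scale_sd = 0.008,
                         start_date = as.Date("2020-12-21"),
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$good_news_days <- good_news_days %||% seq(1L, n_days, by = 3L)
  cfg$bad_news_days <- bad_news_days %||% seq(2L, n_days, by = 3L)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  probs <- c("p_retweet_in", "p_retweet_out", "retweet_fraction",
             "emotion_word_fraction", "emotion_boost", "topic_word_sharpness")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("invalid config: field '%s' must be a probability in [0,1]", f))
    }
  }
  counts <- c("n_communities", "nodes_per_community", "n_days",
              "tweets_per_day", "K_topics", "vocab_size", "tokens_per_tweet",
              "retweet_trials")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(sprintf("invalid config: field '%s' must be >= 1", f))
  }
  if (cfg$hubs_per_community < 0) stop("invalid config: field 'hubs_per_community' must be >= 0")
  if (cfg$noise_sd <= 0) stop("invalid config: field 'noise_sd' must be > 0")
  if (cfg$vocab_size < cfg$K_topics) {
    stop("invalid config: field 'vocab_size' must be >= K_topics (degenerate topic-word rows)")
  }
  a <- cfg$var_coeffs$a
  if (length(a) && spectral_radius(a) >= 1) {
    stop(sprintf(paste0("invalid config: field 'var_coeffs$a' = (%s) is ",
                        "non-stationary (companion spectral radius >= 1)"),
                 paste(signif(a, 4), collapse = ", ")))
  }
  invisible(cfg)
}

#' Simulate a community-structured directed retweet graph
#'
#' Accounts are arranged in blocks; per ordered pair (j, i) the arc weight
#' (times j retweeted i) is Binomial(`retweet_trials`, p), where p is
#' `p_retweet_in` within a community, `p_retweet_out` across, and the
#' target's p is multiplied by `hub_boost` (capped at 1) when i is a hub.
#'
#' @param config a [synth_config()].
#' @return list with `network` (a [retweet_network()]) and `truth`
#'   (community labels per node, hub node set, generating parameters).
#' @export
simulate_retweet_graph <- function(config) {
  validate_synth_config(config)
  C <- config$n_communities
  npc <- config$nodes_per_community
  nodes <- sprintf("acct%03d", seq_len(C * npc))
  community <- stats::setNames(rep(seq_len(C), each = npc), nodes)
  hubs <- unlist(lapply(seq_len(C), function(cc) {
    nodes[(cc - 1) * npc + seq_len(config$hubs_per_community)]
  }))
  is_hub <- nodes %in% hubs
  edges <- with_local_seed(config$seed, {
    from <- rep(nodes, each = length(nodes))
    to <- rep(nodes, times = length(nodes))
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    p <- ifelse(community[from] == community[to],
                config$p_retweet_in, config$p_retweet_out)
    p <- ifelse(to %in% hubs, pmin(1, p * config$hub_boost), p)
    w <- rbinom(length(p), size = config$retweet_trials, prob = p)
    data.frame(from = from, to = to, weight = w)[w > 0, , drop = FALSE]
  })
  list(network = retweet_network(edges, nodes = nodes),
       truth = list(community_of_node = community, hub_nodes = hubs,
                    p_in = config$p_retweet_in, p_out = config$p_retweet_out))
}

# Planted vocabulary: topic k owns a contiguous block; block 1 (the
# vaccination topic) is named after the study's search phrases so the
# phrase filter naturally retains vaccination-topic content.
synth_vocab <- function(config) {
  V <- config$vocab_size
  K <- config$K_topics
  block <- sort(rep(seq_len(K), length.out = V))
  words <- character(V)
  for (k in seq_len(K)) {
    ii <- which(block == k)
    if (k == 1) {
      stems <- rep(c("covid", "vacuna"), length.out = length(ii))
      words[ii] <- sprintf("%s%03d", stems, seq_along(ii))
    } else {
      words[ii] <- sprintf("t%02dw%03d", k, seq_along(ii))
    }
  }
  list(words = words, block = block)
}

#' Simulate an NRC-style emotion lexicon over the synthetic vocabulary
#'
#' Each of the ten categories tags `emotion_word_fraction` of the
#' vocabulary. Inside the vaccination-topic block, a designated "good" word
#' set is tagged positive + trust and a disjoint "bad" set negative, so
#' news-day modulation in [simulate_corpus()] produces a known daily
#' sentiment signal. All other tags are drawn at random.
#'
#' @param config a [synth_config()].
#' @return list with `lexicon` (data.frame `word` + ten 0/1 flag columns),
#'   and the planted `good_words` / `bad_words` sets.
#' @export
simulate_lexicon <- function(config) {
  vocab <- synth_vocab(config)
  V <- config$vocab_size
  cats <- lexicon_categories()
  n_tag <- max(1L, floor(config$emotion_word_fraction * V))
  block1 <- which(vocab$block == 1)
  q <- max(2L, floor(config$emotion_word_fraction * length(block1)))
  q <- min(q, floor(length(block1) / 2))
  good <- vocab$words[block1[seq_len(q)]]
  bad <- vocab$words[block1[q + seq_len(q)]]
  lex <- with_local_seed(config$seed + 101L, {
    flags <- matrix(0L, V, length(cats), dimnames = list(NULL, cats))
    for (cat in cats) flags[sample.int(V, min(n_tag, V)), cat] <- 1L
    flags[, "positive"] <- 0L; flags[, "negative"] <- 0L; flags[, "trust"] <- 0L
    extra <- setdiff(seq_len(V), block1)
    for (cat in c("positive", "negative", "trust")) {
      n_extra <- max(0L, n_tag - q)
      if (n_extra > 0 && length(extra)) {
        flags[sample(extra, min(n_extra, length(extra))), cat] <- 1L
      }
    }
    flags[match(good, vocab$words), "positive"] <- 1L
    flags[match(good, vocab$words), "trust"] <- 1L
    flags[match(bad, vocab$words), "negative"] <- 1L
    # planted signal words carry only their planted valence
    flags[match(good, vocab$words), "negative"] <- 0L
    flags[match(bad, vocab$words), c("positive", "trust")] <- 0L
    cbind(data.frame(word = vocab$words, stringsAsFactors = FALSE),
          as.data.frame(flags))
  })
  if (config$emotion_word_fraction == 0) {
    lex[cats] <- 0L
    good <- character(0); bad <- character(0)
  }
  list(lexicon = lex, good_words = good, bad_words = bad)
}

lexicon_categories <- function() {
  c("positive", "negative", "trust", "anger", "fear", "joy", "sadness",
    "surprise", "anticipation", "disgust")
}

#' Simulate a daily tweet stream with planted topics and emotion words
#'
#' Each post draws a Dirichlet topic mixture, then `tokens_per_tweet` tokens
#' from the per-topic word distributions (topic k concentrates
#' `topic_word_sharpness` of its mass on its own vocabulary block). On
#' good-news days, vaccination-topic tokens are replaced with probability
#' `emotion_boost` by planted positive/trust words; on bad-news days by
#' planted negative words — so the daily net-sentiment signal of the
#' vaccination topic is known by construction. If `network` is supplied,
#' each post is a retweet with probability `retweet_fraction`, directed at
#' one of the author's out-neighbours proportionally to arc weight.
#'
#' @param config a [synth_config()].
#' @param authors character vector of posting accounts.
#' @param network optional [retweet_network()] used to attach retweet links.
#' @return list with `tweets` (data.frame: `id`, `author_id`, `day`,
#'   `tokens` list-column, `retweeted_author_id`), `lexicon`, and `truth`
#'   (planted `phi`, per-tweet mixtures `theta`, good/bad word sets and the
#'   realized `daily_signal` = per-day mean of net-sentiment x vaccination-
#'   topic weight).
#' @export
simulate_corpus <- function(config, authors, network = NULL) {
  validate_synth_config(config)
  K <- config$K_topics
  V <- config$vocab_size
  vocab <- synth_vocab(config)
  lex <- simulate_lexicon(config)
  phi <- matrix(0, K, V)
  for (k in seq_len(K)) {
    own <- vocab$block == k
    if (K == 1) {
      phi[k, ] <- 1 / V
    } else {
      phi[k, own] <- config$topic_word_sharpness / sum(own)
      phi[k, !own] <- (1 - config$topic_word_sharpness) / sum(!own)
    }
  }
  good_idx <- match(lex$good_words, vocab$words)
  bad_idx <- match(lex$bad_words, vocab$words)
  D <- config$n_days * config$tweets_per_day
  out <- with_local_seed(config$seed + 202L, {
    theta <- if (K == 1) matrix(1, D, 1) else
      rdirichlet_mat(D, rep(config$doc_topic_alpha, K))
    day_of <- rep(seq_len(config$n_days), each = config$tweets_per_day)
    tokens <- vector("list", D)
    for (d in seq_len(D)) {
      z <- sample.int(K, config$tokens_per_tweet, replace = TRUE,
                      prob = theta[d, ])
      w <- integer(length(z))
      for (k in unique(z)) {
        ii <- which(z == k)
        w[ii] <- sample.int(V, length(ii), replace = TRUE, prob = phi[k, ])
      }
      day <- day_of[d]
      vac <- which(z == 1)
      if (length(vac) && config$emotion_boost > 0) {
        if (day %in% config$good_news_days && length(good_idx)) {
          swap <- vac[runif(length(vac)) < config$emotion_boost]
          if (length(swap)) w[swap] <- sample(good_idx, length(swap), replace = TRUE)
        } else if (day %in% config$bad_news_days && length(bad_idx)) {
          swap <- vac[runif(length(vac)) < config$emotion_boost]
          if (length(swap)) w[swap] <- sample(bad_idx, length(swap), replace = TRUE)
        }
      }
      tokens[[d]] <- vocab$words[w]
    }
    author <- sample(authors, D, replace = TRUE)
    rt <- rep(NA_character_, D)
    if (!is.null(network) && config$retweet_fraction > 0) {
      by_from <- split(seq_len(nrow(network$edges)), network$edges$from)
      is_rt <- runif(D) < config$retweet_fraction
      for (d in which(is_rt)) {
        ee <- by_from[[author[d]]]
        if (length(ee)) {
          pick <- if (length(ee) == 1) ee else
            sample(ee, 1, prob = network$edges$weight[ee])
          rt[d] <- network$edges$to[pick]
        }
      }
    }
    list(theta = theta, tokens = tokens, author = author, rt = rt,
         day_of = day_of)
  })
  tweets <- data.frame(
    id = sprintf("t%07d", seq_len(D)),
    author_id = out$author,
    day = config$start_date + out$day_of - 1L,
    retweeted_author_id = out$rt,
    stringsAsFactors = FALSE
  )
  tweets$tokens <- out$tokens
  net_score <- vapply(out$tokens, function(tok) {
    i <- match(tok, lex$lexicon$word)
    sum(lex$lexicon$positive[i], na.rm = TRUE) -
      sum(lex$lexicon$negative[i], na.rm = TRUE)
  }, numeric(1))
  weighted <- net_score * out$theta[, 1]
  daily_signal <- as.numeric(tapply(weighted, out$day_of, mean))
  list(tweets = tweets, lexicon = lex$lexicon,
       truth = list(topic_word_dists = phi,
                    per_tweet_topic_mixture = out$theta,
                    vocab = vocab$words,
                    good_words = lex$good_words, bad_words = lex$bad_words,
                    daily_signal = daily_series(
                      config$start_date + seq_len(config$n_days) - 1L,
                      daily_signal, name = "true_signal")))
}

#' Generate an acceptance series from a known autoregressive process
#'
#' acceptance_t = const + trend * t + sum_l a_l * acceptance_(t-l) +
#' sum_l b_l * sentiment_(t-l) + e_t with e_t ~ Normal(0, noise_sd^2).
#' Pre-sample acceptance values are initialized at the deterministic steady
#' state. Values are clipped to \[0, 1\] only at the end, and any clipping
#' is reported via the `n_clipped` attribute and a warning.
#'
#' @param config a [synth_config()]; uses `var_coeffs`, `var_const`,
#'   `var_trend`, `noise_sd`, `seed`.
#' @param sentiment_series a [daily_series()] (or numeric vector) with
#'   `n_days` entries.
#' @return a [daily_series()] named `"acceptance"` with attribute
#'   `n_clipped`.
#' @export
simulate_acceptance_series <- function(config, sentiment_series) {
  validate_synth_config(config)
  s <- series_values(sentiment_series)
  n <- config$n_days
  if (length(s) != n) stop("sentiment_series must have n_days entries")
  a <- config$var_coeffs$a %||% numeric(0)
  b <- config$var_coeffs$b %||% numeric(0)
  if (length(a) && spectral_radius(a) >= 1) {
    stop(sprintf("non-stationary acceptance coefficients a = (%s)",
                 paste(signif(a, 4), collapse = ", ")))
  }
  p <- max(length(a), length(b), 1L)
  a <- c(a, numeric(p - length(a)))
  b <- c(b, numeric(p - length(b)))
  # pre-sample values: deterministic steady state, with the first observed
  # sentiment value carried back (keeps the recursion local in its inputs)
  steady <- (config$var_const + sum(b) * s[1]) /
    max(1 - sum(a), .Machine$double.eps)
  eps <- with_local_seed(config$seed + 303L, rnorm(n, 0, config$noise_sd))
  y <- numeric(n + p)
  y[seq_len(p)] <- steady
  s_pad <- c(rep(s[1], p), s)
  for (t in seq_len(n)) {
    tt <- t + p
    y[tt] <- config$var_const + config$var_trend * t +
      sum(a * y[tt - seq_len(p)]) + sum(b * s_pad[tt - seq_len(p)]) + eps[t]
  }
  y <- y[p + seq_len(n)]
  clipped <- sum(y < 0 | y > 1)
  if (clipped > 0) {
    warning(sprintf("acceptance series clipped to [0,1] on %d day(s)", clipped))
    y <- pmin(1, pmax(0, y))
  }
  out <- daily_series(config$start_date + seq_len(n) - 1L, y,
                      name = "acceptance")
  attr(out, "n_clipped") <- clipped
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining the three generators: retweet graph, daily
#' tweet stream (with retweet links from the graph), and an acceptance
#' series driven by the realized daily sentiment signal. The signal is
#' standardized to `sentiment_scale_mean` / `sentiment_scale_sd` before
#' entering the acceptance recursion so the series stays inside \[0, 1\].
#'
#' @param config a [synth_config()].
#' @return list with `graph`, `corpus`, `acceptance`, and `truth` (the union
#'   of the per-stage ground truths plus the scaled driving signal).
#' @export
simulate_study <- function(config = synth_config()) {
  g <- simulate_retweet_graph(config)
  corp <- simulate_corpus(config, authors = g$network$nodes,
                          network = g$network)
  sig <- corp$truth$daily_signal
  v <- sig$value
  scaled <- if (sd(v) > 0) {
    (v - mean(v)) / sd(v) * config$sentiment_scale_sd + config$sentiment_scale_mean
  } else {
    rep(config$sentiment_scale_mean, length(v))
  }
  sig_scaled <- daily_series(sig$date, scaled, name = "sentiment_signal")
  acc <- simulate_acceptance_series(config, sig_scaled)
  list(graph = g$network, corpus = corp$tweets, lexicon = corp$lexicon,
       acceptance = acc,
       truth = c(g$truth, corp$truth, list(driving_signal = sig_scaled,
                                           var_coeffs_true = config$var_coeffs)))
}
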