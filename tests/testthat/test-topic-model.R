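toy_corpus <- function() {
  tw <- make_tweets(
    sprintf("t%d", 1:6),
    rep("u", 6),
    rep("2021-01-01", 6),
    list(c("Perro", "gato", "gato"), c("perro", "VACUNA"),
         c("vacuna", "vacuna", "dosis"), c("dosis", "gato"),
         c("el", "la"), c("el", "el", "raro"))
  )
  tw
}

test_that("preprocessing lowercases, filters, and drops empty documents", {
  tw <- toy_corpus()
  # stopwords covering a whole tweet drop it
  expect_message(
    corp <- preprocess_corpus(tw, stopwords = c("el", "la")),
    "dropped 1"
  )
  expect_equal(length(corp$docs), 5)
  expect_false(any(c("el", "la") %in% corp$vocab))

  # identity setting preserves the token multiset (lowercased)
  corp2 <- preprocess_corpus(tw, min_doc_freq = 1)
  got <- sort(corp2$vocab[unlist(corp2$docs)])
  expect_equal(got, sort(tolower(unlist(tw$tokens))))

  # count-then-filter oracle for min_doc_freq = 2
  corp3 <- preprocess_corpus(tw, min_doc_freq = 2)
  df_oracle <- table(unlist(lapply(tw$tokens, function(t) unique(tolower(t)))))
  expect_setequal(corp3$vocab, names(df_oracle)[df_oracle >= 2])

  expect_error(preprocess_corpus(tw, stopwords = unique(tolower(unlist(tw$tokens)))),
               "empty")
})

test_that("corpus round-trips through the sparse triplet format", {
  corp <- preprocess_corpus(toy_corpus())
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir)
  expect_equal(back$vocab, corp$vocab)
  expect_equal(lapply(back$docs, sort), lapply(corp$docs, sort))
  expect_equal(back$doc_id, corp$doc_id)
})

test_that("K = 1 LDA degenerates to corpus-wide word frequencies", {
  corp <- preprocess_corpus(toy_corpus())
  fit <- fit_lda(corp, K = 1, beta = 0.01, iters = 20, burn_in = 5, seed = 1)
  expect_true(all(fit$gamma > 0.9))  # single topic: gamma ~ 1 up to smoothing
  V <- length(corp$vocab)
  counts <- tabulate(unlist(corp$docs), V)
  expect_equal(as.numeric(fit$phi),
               (counts + 0.01) / (sum(counts) + V * 0.01),
               tolerance = 1e-12)
})

test_that("LDA is deterministic under a fixed seed and validates K", {
  corp <- preprocess_corpus(toy_corpus())
  f1 <- fit_lda(corp, K = 2, iters = 50, burn_in = 10, seed = 7)
  f2 <- fit_lda(corp, K = 2, iters = 50, burn_in = 10, seed = 7)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$phi, f2$phi)
  expect_error(fit_lda(corp, K = 100), "distinct tokens")
})

test_that("phi and gamma rows are stochastic and the likelihood trace is finite", {
  cfg <- synth_config(K_topics = 3, n_days = 8, tweets_per_day = 15,
                      vocab_size = 60, seed = 5)
  corp <- simulate_corpus(cfg, authors = "u")
  pc <- preprocess_corpus(corp$tweets)
  fit <- fit_lda(pc, K = 3, iters = 80, burn_in = 20, seed = 2)
  expect_equal(rowSums(fit$phi), rep(1, 3), tolerance = 1e-9)
  expect_equal(rowSums(fit$gamma), rep(1, nrow(fit$gamma)), tolerance = 1e-9)
  expect_true(all(is.finite(fit$loglik_trace)))
  # no systematic downward drift over the last 20% of sweeps
  tail_ll <- tail(fit$loglik_trace, 16)
  drift <- coef(lm(tail_ll ~ seq_along(tail_ll)))[2]
  expect_gt(drift, -abs(mean(tail_ll)) * 1e-3)
})

test_that("documents with identical content get exchangeable topic loads", {
  tw <- make_tweets(sprintf("t%d", 1:40), rep("u", 40),
                    rep("2021-01-01", 40),
                    c(rep(list(c("alpha", "beta", "alpha")), 20),
                      rep(list(c("gamma", "delta", "delta")), 20)))
  corp <- preprocess_corpus(tw)
  fit <- fit_lda(corp, K = 2, iters = 600, burn_in = 200, seed = 3)
  # doc 1 and doc 2 share content; their posterior-mean loads agree
  expect_lt(max(abs(fit$gamma[1, ] - fit$gamma[2, ])), 0.05)
})

test_that("planted two-topic structure is recovered with high cosine", {
  cfg <- synth_config(K_topics = 2, vocab_size = 80, n_days = 10,
                      tweets_per_day = 40, topic_word_sharpness = 1,
                      emotion_boost = 0, seed = 19)
  corp <- simulate_corpus(cfg, authors = "u")
  pc <- preprocess_corpus(corp$tweets)
  fit <- fit_lda(pc, K = 2, iters = 200, burn_in = 50, seed = 4)
  keep <- match(pc$vocab, corp$truth$vocab)
  mt <- match_topics(fit$phi, corp$truth$topic_word_dists[, keep])
  expect_gt(mt$mean_cosine, 0.9)
})

test_that("selection metrics match hand arithmetic on tiny distributions", {
  # K = 3, V = 4 toy: all four metrics vs an independent arithmetic oracle
  phi <- rbind(c(0.4, 0.3, 0.2, 0.1),
               c(0.1, 0.2, 0.3, 0.4),
               c(0.25, 0.25, 0.25, 0.25))
  gamma <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))
  ll <- c(-50, -52, -51)
  fit3 <- list(K = 3L, phi = phi, gamma = gamma,
               loglik_trace = c(-99, ll), burn_in = 1L)
  fit2 <- list(K = 2L, phi = phi[1:2, ], gamma = gamma[, 1:2] / rowSums(gamma[, 1:2]),
               loglik_trace = c(-99, ll), burn_in = 1L)
  corp2 <- list(docs = list(c(1, 2, 3), c(2, 4)))
  tab3 <- k_selection_metrics(list(fit2, fit3), corp2)
  row3 <- tab3[tab3$K == 3, ]

  # identical rows: cosine contribution 1, JS divergence 0
  phi_same <- rbind(c(0.5, 0.3, 0.2, 0), c(0.5, 0.3, 0.2, 0))
  fit_same <- list(K = 2L, phi = phi_same, gamma = matrix(0.5, 2, 2),
                   loglik_trace = c(-10, -10), burn_in = 1L)
  # disjoint supports: cosine 0, JSD = log 2 (natural-log convention)
  phi_disj <- rbind(c(0.7, 0.3, 0, 0), c(0, 0, 0.4, 0.6))
  fit_disj <- list(K = 2L, phi = phi_disj, gamma = matrix(0.5, 2, 2),
                   loglik_trace = c(-10, -10), burn_in = 1L)
  tab_same <- k_selection_metrics(list(fit_same, fit3), corp2)
  expect_equal(tab_same$caojuan2009[tab_same$K == 2], 1, tolerance = 1e-12)
  expect_equal(tab_same$deveaud2014[tab_same$K == 2], 0, tolerance = 1e-12)
  tab_disj <- k_selection_metrics(list(fit_disj, fit3), corp2)
  expect_equal(tab_disj$caojuan2009[tab_disj$K == 2], 0, tolerance = 1e-12)
  expect_equal(tab_disj$deveaud2014[tab_disj$K == 2], log(2), tolerance = 1e-12)

  # oracle: explicit scalar arithmetic, no shared helpers
  hm <- log(3) - (max(-ll) + log(sum(exp(-ll - max(-ll)))))
  expect_equal(row3$griffiths2004, hm, tolerance = 1e-12)
  cos_ab <- function(a, b) sum(a * b) / sqrt(sum(a^2)) / sqrt(sum(b^2))
  expect_equal(row3$caojuan2009,
               mean(c(cos_ab(phi[1, ], phi[2, ]), cos_ab(phi[1, ], phi[3, ]),
                      cos_ab(phi[2, ], phi[3, ]))), tolerance = 1e-12)
  jsd <- function(a, b) {
    m <- (a + b) / 2
    kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
    (kl(a, m) + kl(b, m)) / 2
  }
  expect_equal(row3$deveaud2014,
               mean(c(jsd(phi[1, ], phi[2, ]), jsd(phi[1, ], phi[3, ]),
                      jsd(phi[2, ], phi[3, ]))), tolerance = 1e-12)
  sv <- svd(phi)$d; sv <- sv / sum(sv)
  dl <- c(3, 2)
  pr <- as.numeric(dl %*% gamma); pr <- pr / sum(pr)
  kl2 <- function(p, q) sum(p * log(p / q))
  expect_equal(row3$arun2010, kl2(sv, pr) + kl2(pr, sv), tolerance = 1e-12)

  # K = 1 entries report the pairwise metrics as missing
  fit1 <- list(K = 1L, phi = matrix(0.25, 1, 4), gamma = matrix(1, 2, 1),
               loglik_trace = c(-99, ll), burn_in = 1L)
  tab1 <- k_selection_metrics(list(fit1, fit3), corp2)
  expect_true(is.na(tab1$caojuan2009[tab1$K == 1]))
  expect_true(is.na(tab1$deveaud2014[tab1$K == 1]))
})

test_that("the four metrics jointly prefer the planted topic count", {
  hits <- 0
  reps <- 10
  for (s in seq_len(reps)) {
    cfg <- synth_config(K_topics = 3, vocab_size = 60, n_days = 6,
                        tweets_per_day = 30, topic_word_sharpness = 1,
                        emotion_boost = 0, doc_topic_alpha = 0.1, seed = 400 + s)
    corp <- simulate_corpus(cfg, authors = "u")
    pc <- preprocess_corpus(corp$tweets)
    fits <- lapply(c(2, 3, 5), function(K) {
      fit_lda(pc, K = K, iters = 120, burn_in = 40, seed = s)
    })
    tab <- k_selection_metrics(fits, pc)
    if (preferred_k(tab) == 3) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("daily prominence aggregates gamma by calendar day", {
  # 2-day fixture with known gamma rows
  fit <- list(K = 3L,
              gamma = rbind(c(0.7, 0.2, 0.1), c(0.5, 0.4, 0.1),
                            c(0.1, 0.8, 0.1)),
              doc_day = as.Date(c("2021-01-01", "2021-01-01", "2021-01-02")),
              doc_id = c("t1", "t2", "t3"))
  cm <- cluster_map(list(vac = 1L, rest = c(2L, 3L)), K = 3)
  prom <- daily_prominence(fit, cm, "vac")
  expect_equal(prom$value, c(mean(c(0.7, 0.5)), 0.1))
  prom_sum <- daily_prominence(fit, cm, "rest", mode = "sum")
  expect_equal(prom_sum$value, c(0.3 + 0.5, 0.9))

  # cluster of all topics: prominence identically 1 under the mean
  cm_all <- cluster_map(list(all = 1:3), K = 3)
  expect_equal(daily_prominence(fit, cm_all, "all")$value, c(1, 1))

  # empty cluster: identically 0; unknown label errors
  cm_empty <- cluster_map(list(vac = integer(0)), K = 3)
  expect_equal(daily_prominence(fit, cm_empty, "vac")$value, c(0, 0))
  expect_error(daily_prominence(fit, cm, "nope"), "nope")

  # a zero-tweet day inside the range is missing, not zero
  fit2 <- fit
  fit2$doc_day <- as.Date(c("2021-01-01", "2021-01-01", "2021-01-03"))
  prom2 <- daily_prominence(fit2, cm, "vac")
  expect_true(is.na(prom2$value[2]))
  expect_equal(prom2$n[2], 0L)

  # boilerplate topics are disjoint from clusters by construction and
  # never contribute to prominence
  expect_error(cluster_map(list(vac = c(1L, 2L)), boilerplate = 2L, K = 3))
  cm_boiler <- cluster_map(list(vac = 1L), boilerplate = 2L, K = 3)
  expect_equal(daily_prominence(fit, cm_boiler, "vac")$value,
               daily_prominence(fit, cm, "vac")$value)
})

test_that("cluster maps validate and round-trip through JSON", {
  expect_error(cluster_map(list(a = 1L, b = 1L), K = 3))
  expect_error(cluster_map(list(a = 5L), K = 3))
  cm <- cluster_map(list(covid_vaccination = 1L, other = 2:3),
                    boilerplate = integer(0), K = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_map(cm, path)
  back <- read_cluster_map(path)
  expect_equal(back$clusters, cm$clusters)
  expect_equal(back$K, cm$K)
  # the shipped default fixture map parses
  shipped <- read_cluster_map(system.file("extdata", "topic_clusters.json",
                                          package = "riskamp"))
  expect_true("covid_vaccination" %in% names(shipped$clusters))
})
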