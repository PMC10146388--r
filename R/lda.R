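#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Tokens are resampled from the collapsed conditional
#' p(z = k) proportional to (n_dk + alpha) (n_kw + beta) / (n_k + V beta).
#' Topic-word (`phi`) and document-topic (`gamma`) probabilities are
#' posterior means averaged over post-burn-in sweeps.
#'
#' @param corpus an `ra_corpus` from [preprocess_corpus()].
#' @param K number of topics (the study default is 65).
#' @param alpha document-topic concentration (study default 0.1).
#' @param beta topic-word concentration.
#' @param iters,burn_in total and discarded Gibbs sweeps.
#' @param seed RNG seed; identical corpus + seed reproduce identical fits.
#' @param keep_z_trace store the per-sweep assignment vectors (only sensible
#'   for tiny corpora; used by posterior-enumeration checks).
#' @return an `lda_fit`: `K`, `alpha`, `beta`, `phi` (K x V), `gamma`
#'   (D x K), `loglik_trace` (complete-data log likelihood per sweep),
#'   final assignments `z`, and `seed`.
#' @export
fit_lda <- function(corpus, K, alpha = 0.1, beta = 0.01,
                    iters = 1000L, burn_in = 200L, seed = 1L,
                    keep_z_trace = FALSE) {
  stopifnot(K >= 1, iters > burn_in)
  V <- length(corpus$vocab)
  if (K > V) stop("K exceeds the number of distinct tokens")
  doc_id <- rep(seq_along(corpus$docs), lengths(corpus$docs)) - 1L
  word_id <- unlist(corpus$docs) - 1L
  res <- with_local_seed(seed, {
    gibbs_lda_cpp(doc_id, word_id, length(corpus$docs), V, as.integer(K),
                  alpha, beta, as.integer(iters), as.integer(burn_in),
                  keep_z_trace)
  })
  colnames(res$phi) <- corpus$vocab
  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta,
         phi = res$phi, gamma = res$gamma,
         loglik_trace = as.numeric(res$loglik),
         burn_in = as.integer(burn_in), z = res$z + 1L,
         z_trace = if (keep_z_trace) res$z_trace + 1L else NULL,
         doc_day = corpus$doc_day, doc_id = corpus$doc_id, seed = seed),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("<lda_fit> K = %d topics, %d documents, alpha = %g, beta = %g\n",
              x$K, nrow(x$gamma), x$alpha, x$beta))
  invisible(x)
}

#' Topic-number selection metrics
#'
#' Scores a ladder of fitted models with the four standard selection
#' metrics: the harmonic-mean marginal likelihood (maximize), mean pairwise
#' cosine similarity between topic-word rows (minimize), the symmetric KL
#' divergence between the normalized singular values of phi and the
#' doc-length-weighted topic proportions (minimize), and the mean pairwise
#' Jensen-Shannon divergence between topic-word rows, natural-log
#' convention (maximize).
#'
#' @param fits list of `lda_fit` objects with at least two distinct `K`.
#' @param corpus the `ra_corpus` the fits were estimated on.
#' @return data.frame with columns `K`, `griffiths2004`, `caojuan2009`,
#'   `arun2010`, `deveaud2014`. For a K = 1 fit the pairwise metrics are
#'   undefined and reported as `NA`.
#' @export
k_selection_metrics <- function(fits, corpus) {
  Ks <- vapply(fits, function(f) f$K, integer(1))
  stopifnot(length(unique(Ks)) >= 2)
  doc_len <- lengths(corpus$docs)
  rows <- lapply(fits, function(f) {
    ll <- f$loglik_trace[(f$burn_in + 1):length(f$loglik_trace)]
    griffiths <- log(length(ll)) - logsumexp(-ll)   # log harmonic mean
    if (f$K >= 2) {
      pairs <- utils::combn(f$K, 2)
      cos_v <- apply(pairs, 2, function(ij) cosine_sim(f$phi[ij[1], ], f$phi[ij[2], ]))
      jsd_v <- apply(pairs, 2, function(ij) js_divergence(f$phi[ij[1], ], f$phi[ij[2], ]))
      cao <- mean(cos_v)
      deveaud <- mean(jsd_v)
    } else {
      cao <- NA_real_
      deveaud <- NA_real_
    }
    sv <- svd(f$phi, nu = 0, nv = 0)$d
    cm1 <- sv / sum(sv)
    props <- as.numeric(doc_len %*% f$gamma)
    cm2 <- props / sum(props)
    arun <- sym_kl(cm1, cm2)
    data.frame(K = f$K, griffiths2004 = griffiths, caojuan2009 = cao,
               arun2010 = arun, deveaud2014 = deveaud)
  })
  do.call(rbind, rows)
}

kl_divergence <- function(p, q) {
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(q[i])))
}

sym_kl <- function(p, q) kl_divergence(p, q) + kl_divergence(q, p)

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
}

#' Preferred K by majority vote of the four selection metrics
#'
#' @param metrics the table from [k_selection_metrics()].
#' @return the K winning the most metric arg-optima (ties to smallest K).
#' @export
preferred_k <- function(metrics) {
  votes <- c(
    metrics$K[which.max(metrics$griffiths2004)],
    metrics$K[which.min(metrics$caojuan2009)],
    metrics$K[which.min(metrics$arun2010)],
    metrics$K[which.max(metrics$deveaud2014)]
  )
  tab <- table(votes)
  as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
}

#' Topic-cluster map
#'
#' Carries the (externally supplied) collapsing of fitted topics into named
#' clusters, plus a set of boilerplate topics excluded from every analysis.
#'
#' @param clusters named list: cluster label -> integer topic indices.
#' @param boilerplate integer topic indices excluded from analysis.
#' @param K topic count for bounds checking.
#' @return a `cluster_map`.
#' @export
cluster_map <- function(clusters, boilerplate = integer(0), K) {
  all_idx <- c(unlist(clusters), boilerplate)
  stopifnot(all(all_idx >= 1), all(all_idx <= K),
            !anyDuplicated(all_idx))
  structure(list(clusters = lapply(clusters, as.integer),
                 boilerplate = as.integer(boilerplate), K = as.integer(K)),
            class = "cluster_map")
}

#' Daily topic-cluster prominence
#'
#' Per tweet, the cluster probability is the sum of its document-topic
#' probabilities (gamma) over the cluster's topics; per day, prominence is
#' the mean (default) or sum over that day's tweets. Days with no tweets
#' are recorded as missing, and boilerplate topics never contribute.
#'
#' @param fit an `lda_fit`.
#' @param cluster a [cluster_map()].
#' @param label cluster label to score.
#' @param mode `"mean"` (default) or `"sum"` daily aggregation.
#' @param dates optional full calendar range (`Date` length-2 or vector);
#'   defaults to the corpus's observed day range.
#' @return a [daily_series()] with per-day `n` tweet counts.
#' @export
daily_prominence <- function(fit, cluster, label, mode = c("mean", "sum"),
                             dates = NULL) {
  mode <- match.arg(mode)
  if (!label %in% names(cluster$clusters)) {
    stop(sprintf("cluster label '%s' not in the cluster map", label))
  }
  idx <- setdiff(cluster$clusters[[label]], cluster$boilerplate)
  per_tweet <- if (length(idx)) rowSums(fit$gamma[, idx, drop = FALSE]) else
    numeric(nrow(fit$gamma))
  agg <- aggregate_daily_scores(
    data.frame(id = fit$doc_id, day = fit$doc_day, value = per_tweet),
    mode = mode, dates = dates
  )
  attr(agg, "name") <- paste0("prominence_", label)
  agg
}

#' Read / write a cluster map as structured JSON
#' @param map a [cluster_map()].
#' @param path file path.
#' @return `write_cluster_map` returns `path` invisibly; `read_cluster_map`
#'   a [cluster_map()].
#' @export
write_cluster_map <- function(map, path) {
  jsonlite::write_json(list(K = map$K, boilerplate = map$boilerplate,
                            clusters = map$clusters),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cluster_map(as.list(x$clusters), boilerplate = x$boilerplate, K = x$K)
}
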