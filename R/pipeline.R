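#' Pipeline configuration
#'
#' One config drives the four analysis stages end to end. Either a
#' [synth_config()] is supplied (the generator writes every input) or
#' paths to existing tweet / lexicon / survey files are given.
#'
#' @param out_dir output directory; artifacts are written at every stage
#'   boundary so each stage is independently re-runnable.
#' @param synth a [synth_config()], or `NULL` to read from `paths`.
#' @param paths list with `tweets` (JSONL), `lexicon` (CSV), `survey`
#'   (daily `date,value` CSV); ignored when `synth` is given.
#' @param phrases phrase filter for the sentinel stage (study defaults).
#' @param seed_k,final_k,per_node_cap sentinel-selection parameters
#'   (study defaults 50, 80, 3200).
#' @param lda list of LDA parameters `K`, `alpha`, `beta`, `iters`,
#'   `burn_in` (study defaults K = 65, alpha = 0.1). The synthetic default
#'   uses the generator's planted topic count.
#' @param clusters a [cluster_map()] or `NULL` for the default map sending
#'   topic 1 to cluster `"covid_vaccination"`.
#' @param agg_mode daily aggregation mode for prominence and sentiment.
#' @param var list of VAR parameters `p`, `deterministic`, `H`, `n_boot`
#'   (study defaults p = 4, const+trend).
#' @param seed master seed; per-stage streams are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synth = synth_config(),
                            paths = NULL,
                            phrases = c("covid", "coronavirus", "pandemia", "vacuna"),
                            seed_k = 50L, final_k = 80L, per_node_cap = 3200L,
                            lda = list(),
                            clusters = NULL,
                            agg_mode = "mean",
                            var = list(),
                            seed = 1L) {
  lda_def <- list(K = if (is.null(synth)) 65L else synth$K_topics,
                  alpha = 0.1, beta = 0.01, iters = 300L, burn_in = 100L)
  lda <- utils::modifyList(lda_def, lda)
  var_def <- list(p = 4L, deterministic = "const+trend", H = 10L,
                  n_boot = 500L)
  var <- utils::modifyList(var_def, var)
  structure(
    list(out_dir = out_dir, synth = synth, paths = paths, phrases = phrases,
         seed_k = seed_k, final_k = final_k, per_node_cap = per_node_cap,
         lda = lda, clusters = clusters, agg_mode = agg_mode, var = var,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the four-stage pipeline end to end
#'
#' simulate (optional) -> sentinel selection -> topic model -> sentiment
#' scoring -> VAR/IRF. Intermediate artifacts are written at stage
#' boundaries; rerunning with the same config and seed reproduces every
#' artifact byte-for-byte (the manifest, which records wall-clock timings,
#' is the one exception and is documented as such). On a stage failure the
#' manifest records the stage and message and downstream stages are
#' skipped.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), stages = list(),
                   warnings = character(0), failed = NULL)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!is.null(manifest$failed)) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e
    )
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$failed <<- name
      manifest$stages[[name]] <<- list(status = "error", seconds = el,
                                       message = conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok", seconds = el), res)
    }
  }

  run_stage("simulate", function() {
    if (!is.null(config$synth)) {
      study <- simulate_study(config$synth)
      state$tweets <- study$corpus
      state$lexicon <- study$lexicon
      state$acceptance <- study$acceptance
      state$truth <- study$truth
      write_tweets(study$corpus, file.path(config$out_dir, "tweets.jsonl"))
      write_lexicon(study$lexicon, file.path(config$out_dir, "lexicon.csv"))
      write_daily_series(study$acceptance,
                         file.path(config$out_dir, "acceptance.csv"))
    } else {
      state$tweets <- read_tweets(config$paths$tweets)
      state$lexicon <- read_lexicon(config$paths$lexicon)
      state$acceptance <- read_daily_series(config$paths$survey,
                                            name = "acceptance")
    }
    list(n_tweets = nrow(state$tweets),
         n_days = nrow(state$acceptance))
  })

  run_stage("sentinel", function() {
    tw <- filter_by_phrases(state$tweets, config$phrases)
    net <- build_retweet_network(tw)
    lcc <- largest_connected_component(net)
    part <- louvain_partition(lcc, seed = config$seed + 1L)
    seeds <- top_retweeted_per_community(lcc, part, k = config$seed_k,
                                         provenance = "seed")
    sent <- snowball_expand(seeds, state$tweets, config$phrases,
                            per_node_cap = config$per_node_cap,
                            k = config$final_k, seed = config$seed + 1L)
    state$sentinels <- sent
    write_edge_list(net, file.path(config$out_dir, "retweet_network.tsv"))
    write_partition(part, file.path(config$out_dir, "communities.tsv"))
    write_partition(sent, file.path(config$out_dir, "sentinels.tsv"))
    list(n_filtered_tweets = nrow(tw), n_nodes = length(net$nodes),
         n_lcc_nodes = length(lcc$nodes),
         n_communities = part$n_communities, Q = part$Q,
         n_sentinels = length(sent$members))
  })

  run_stage("topics", function() {
    keep <- state$tweets$author_id %in% state$sentinels$members
    corp_tweets <- state$tweets[keep, , drop = FALSE]
    corpus <- preprocess_corpus(corp_tweets)
    fit <- fit_lda(corpus, K = config$lda$K, alpha = config$lda$alpha,
                   beta = config$lda$beta, iters = config$lda$iters,
                   burn_in = config$lda$burn_in, seed = config$seed + 2L)
    cmap <- config$clusters %||%
      cluster_map(list(covid_vaccination = 1L), K = config$lda$K)
    prom <- daily_prominence(fit, cmap, "covid_vaccination",
                             mode = config$agg_mode)
    state$corpus_tweets <- corp_tweets
    state$fit <- fit
    state$cmap <- cmap
    write_daily_series(prom, file.path(config$out_dir, "prominence.csv"))
    list(n_docs = nrow(fit$gamma), vocab_size = ncol(fit$phi),
         n_dropped_docs = attr(corpus, "n_dropped"), K = fit$K)
  })

  run_stage("sentiment", function() {
    for (cat in c("net", "trust")) {
      s <- daily_weighted_sentiment(state$corpus_tweets, state$lexicon,
                                    state$fit, state$cmap,
                                    "covid_vaccination", category = cat,
                                    mode = config$agg_mode)
      state[[paste0("daily_", cat)]] <- s
      write_daily_series(s, file.path(config$out_dir,
                                      sprintf("daily_weighted_%s.csv", cat)))
    }
    list(n_days_net = sum(!is.na(state$daily_net$value)))
  })

  run_stage("var", function() {
    out <- list()
    for (cat in c("net", "trust")) {
      sent <- state[[paste0("daily_", cat)]]
      attr(sent, "name") <- cat
      al <- align_series(sent, state$acceptance, na_action = "interpolate")
      Y <- as.matrix(al[, c(cat, "acceptance")])
      t_idx <- seq_len(nrow(Y))
      adf <- adf_test(stats::residuals(lm(Y[, "acceptance"] ~ t_idx)),
                      deterministic = "const")
      fit <- fit_var(Y, p = config$var$p,
                     deterministic = config$var$deterministic)
      ir <- irf(fit, H = config$var$H, ordering = colnames(Y),
                n_boot = config$var$n_boot, seed = config$seed + 3L)
      ct <- var_coef_table(fit, response = "acceptance")
      rev <- reverse_robustness(Y, p = config$var$p,
                                deterministic = config$var$deterministic)
      write.csv(format_num_df(ct),
                file.path(config$out_dir, sprintf("var_coefs_%s.csv", cat)),
                row.names = FALSE, quote = FALSE)
      write.csv(format_num_df(irf_table(ir, impulse = cat,
                                        response = "acceptance")),
                file.path(config$out_dir, sprintf("irf_%s.csv", cat)),
                row.names = FALSE, quote = FALSE)
      out[[paste0(cat, "_lag1_coef")]] <-
        ct$estimate[ct$term == paste0(cat, ".l1")]
      out[[paste0(cat, "_adf_reject")]] <- adf$reject
      out[[paste0(cat, "_reverse_significant")]] <- rev$any_significant
      state[[paste0("varfit_", cat)]] <- fit
      state[[paste0("irf_", cat)]] <- ir
    }
    out
  })

  manifest$n_warnings <- length(manifest$warnings)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  }
  df
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a run report from pipeline artifacts
#'
#' Produces a timeline figure of the three daily series (weighted net
#' sentiment, weighted trust, acceptance), an IRF figure per sentiment
#' model with point estimates and bands (the caption notes when bands were
#' not computed), a coefficient table per model, and a Markdown summary.
#' Regeneration is idempotent given unchanged artifacts.
#'
#' @param run_dir directory holding a completed run's artifacts.
#' @return invisible character vector of report file paths.
#' @export
make_report <- function(run_dir) {
  need <- c("daily_weighted_net.csv", "daily_weighted_trust.csv",
            "acceptance.csv", "var_coefs_net.csv", "var_coefs_trust.csv",
            "irf_net.csv", "irf_trust.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop(sprintf("missing artifacts: %s", paste(missing, collapse = ", ")))
  }
  net <- read_daily_series(file.path(run_dir, "daily_weighted_net.csv"))
  trust <- read_daily_series(file.path(run_dir, "daily_weighted_trust.csv"))
  acc <- read_daily_series(file.path(run_dir, "acceptance.csv"))

  timeline <- file.path(run_dir, "timeline.pdf")
  grDevices::pdf(timeline, width = 8, height = 5)
  graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  for (s in list(net, trust, acc)) {
    graphics::plot(s$date, s$value, type = "l", xlab = "",
                   ylab = attr(s, "name"), main = attr(s, "name"))
  }
  grDevices::dev.off()

  irf_fig <- file.path(run_dir, "irf.pdf")
  grDevices::pdf(irf_fig, width = 8, height = 4)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (cat in c("net", "trust")) {
    tab <- read.csv(file.path(run_dir, sprintf("irf_%s.csv", cat)))
    has_bands <- all(c("lower", "upper") %in% names(tab))
    ylim <- range(c(tab$response, if (has_bands) c(tab$lower, tab$upper)))
    graphics::plot(tab$horizon, tab$response, type = "l", col = "red",
                   lwd = 2, ylim = ylim, xlab = "lag (days)",
                   ylab = "response of acceptance",
                   main = sprintf("shock: weighted %s%s", cat,
                                  if (has_bands) "" else " (no bands)"))
    if (has_bands) {
      graphics::lines(tab$horizon, tab$lower, lty = 2)
      graphics::lines(tab$horizon, tab$upper, lty = 2)
    }
    graphics::abline(h = 0, col = "grey")
  }
  grDevices::dev.off()

  md <- file.path(run_dir, "report.md")
  lines <- c("# Pipeline run report", "",
             "## Timeline", "", "![timeline](timeline.pdf)", "",
             "## Impulse responses", "", "![irf](irf.pdf)", "")
  for (cat in c("net", "trust")) {
    ct <- read.csv(file.path(run_dir, sprintf("var_coefs_%s.csv", cat)))
    lines <- c(lines, sprintf("## VAR model: weighted %s -> acceptance", cat), "",
               paste(names(ct), collapse = " | "),
               paste(rep("---", ncol(ct)), collapse = " | "),
               apply(ct, 1, function(r) paste(r, collapse = " | ")), "")
  }
  writeLines(lines, md)
  invisible(c(timeline, irf_fig, md))
}
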