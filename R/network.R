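#' Weighted directed retweet network
#'
#' Constructor for the `retweet_network` class. Arcs are directed j -> i with
#' integer weight equal to the number of times account j retweeted account i.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (positive).
#' @param nodes character vector of account ids; defaults to ids seen in
#'   `edges`. Isolated nodes (no arcs) are allowed.
#' @return a `retweet_network`: list with `nodes`, `edges`, total arc weight
#'   `m`, and named `out_strength` / `in_strength` vectors.
#' @export
retweet_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$weight < 0)) stop("arc weights must be non-negative")
  edges <- edges[edges$weight > 0, , drop = FALSE]
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  out_s <- stats::setNames(numeric(length(nodes)), nodes)
  in_s <- out_s
  if (nrow(edges)) {
    os <- tapply(edges$weight, edges$from, sum)
    is_ <- tapply(edges$weight, edges$to, sum)
    out_s[names(os)] <- os
    in_s[names(is_)] <- is_
  }
  structure(
    list(nodes = nodes, edges = edges, m = sum(edges$weight),
         out_strength = out_s, in_strength = in_s),
    class = "retweet_network"
  )
}

#' @export
print.retweet_network <- function(x, ...) {
  cat(sprintf("<retweet_network> %d nodes, %d arcs, total weight m = %g\n",
              length(x$nodes), nrow(x$edges), x$m))
  invisible(x)
}

#' Filter tweets containing any of a set of phrases
#'
#' Keeps exactly the tweets whose token list contains at least one phrase,
#' matched case-insensitively either as a substring of a token (default) or
#' as a whole token.
#'
#' @param tweets tweet data.frame (columns `id`, `author_id`, `day`, `tokens`
#'   list-column, `retweeted_author_id`).
#' @param phrases non-empty character vector of search phrases.
#' @param mode `"substring"` (default) or `"token"`.
#' @return the filtered tweet data.frame (possibly zero rows).
#' @export
filter_by_phrases <- function(tweets, phrases, mode = c("substring", "token")) {
  mode <- match.arg(mode)
  if (length(phrases) == 0) stop("phrases must be non-empty")
  phr <- tolower(phrases)
  hit <- vapply(tweets$tokens, function(tok) {
    tok <- tolower(tok)
    if (mode == "token") {
      any(tok %in% phr)
    } else {
      any(vapply(phr, function(p) any(grepl(p, tok, fixed = TRUE)), logical(1)))
    }
  }, logical(1))
  tweets[hit, , drop = FALSE]
}

#' Build a retweet network from tweet records
#'
#' Arc j -> i receives weight equal to the number of records in which author
#' j retweeted author i. Records with no retweeted author contribute only
#' their author to the node set.
#'
#' @param tweets tweet data.frame; `retweeted_author_id` may be `NA`.
#' @param keep_self_loops keep arcs j -> j (default `TRUE`).
#' @return a [retweet_network()].
#' @export
build_retweet_network <- function(tweets, keep_self_loops = TRUE) {
  rt <- tweets[!is.na(tweets$retweeted_author_id), , drop = FALSE]
  if (!keep_self_loops && nrow(rt)) {
    rt <- rt[rt$author_id != rt$retweeted_author_id, , drop = FALSE]
  }
  if (nrow(rt)) {
    tab <- aggregate(list(weight = rep(1L, nrow(rt))),
                     by = list(from = as.character(rt$author_id),
                               to = as.character(rt$retweeted_author_id)),
                     FUN = sum)
  } else {
    tab <- data.frame(from = character(), to = character(), weight = numeric())
  }
  retweet_network(tab, nodes = unique(as.character(tweets$author_id)))
}

#' Directed modularity of a partition
#'
#' Q = (1/m) * sum_ij \[A_ij - k_i^out * k_j^in / m\] * delta(c_i, c_j),
#' the directed null model comparing within-community arc weight to the
#' product of out- and in-strengths.
#'
#' @param net a [retweet_network()]; must have positive total weight.
#' @param membership named vector (node -> community label) covering all nodes.
#' @return modularity value in \[-1, 1\].
#' @export
directed_modularity <- function(net, membership) {
  if (length(net$nodes) == 0 || net$m <= 0) stop("modularity undefined on an empty graph")
  memb <- membership[net$nodes]
  if (anyNA(memb)) stop("membership must label every node")
  m <- net$m
  e <- net$edges
  within <- sum(e$weight[memb[e$from] == memb[e$to]])
  comms <- unique(memb)
  null_term <- sum(vapply(comms, function(cc) {
    idx <- names(memb)[memb == cc]
    sum(net$out_strength[idx]) * sum(net$in_strength[idx])
  }, numeric(1))) / m
  (within - null_term) / m
}

#' Largest weakly connected component
#'
#' Componenthood ignores arc direction. Ties in component size are broken by
#' the smallest lexicographic node id among each component's members.
#'
#' @param net a [retweet_network()].
#' @return the induced subnetwork on the largest component.
#' @export
largest_connected_component <- function(net) {
  if (length(net$nodes) == 0) stop("empty graph has no components")
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE, vertices = net$nodes)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: component containing the smallest node id among tied ones
    mins <- vapply(best, function(b) min(net$nodes[comp$membership == b]), character(1))
    best <- best[order(mins)][1]
  }
  keep <- net$nodes[comp$membership == best]
  e <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
  retweet_network(e, nodes = keep)
}

#' Read / write an edge list
#'
#' Tab-delimited `source target weight` round-trip.
#' @param net a [retweet_network()].
#' @param path file path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a [retweet_network()].
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges[order(net$edges$from, net$edges$to), , drop = FALSE]
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  e <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", "character", "numeric"))
  names(e) <- c("from", "to", "weight")
  retweet_network(e)
}
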