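#' Select the most-retweeted accounts per community
#'
#' Within each community, picks the `k` nodes with the largest weighted
#' in-strength (total times retweeted). Ties are broken by smallest node id;
#' communities with fewer than `k` nodes contribute all of their nodes.
#'
#' @param net a [retweet_network()].
#' @param partition a `community_partition` over the nodes of `net`.
#' @param k number of nodes to keep per community (the seed stage uses 50,
#'   the final stage 80).
#' @param provenance label recorded for the selected members.
#' @return a `sentinel_set`: list with `members`, named `community_of`, and
#'   named `provenance`.
#' @export
top_retweeted_per_community <- function(net, partition, k = 80L,
                                        provenance = "seed") {
  stopifnot(k >= 1)
  memb <- partition$membership[net$nodes]
  picked <- character(0)
  for (cc in sort(unique(memb))) {
    nodes_c <- names(memb)[memb == cc]
    s <- net$in_strength[nodes_c]
    ord <- order(-s, nodes_c)
    picked <- c(picked, nodes_c[ord][seq_len(min(k, length(nodes_c)))])
  }
  sentinel_set(picked, partition$membership[picked],
               stats::setNames(rep(provenance, length(picked)), picked))
}

sentinel_set <- function(members, community_of, provenance) {
  stopifnot(all(members %in% names(community_of)))
  structure(
    list(members = members,
         community_of = community_of[members],
         provenance = provenance[members]),
    class = "sentinel_set"
  )
}

#' @export
print.sentinel_set <- function(x, ...) {
  cat(sprintf("<sentinel_set> %d members across %d communities (%s)\n",
              length(x$members), length(unique(x$community_of)),
              paste(sprintf("%s: %d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Snowball-expand a seed sentinel set
#'
#' Takes the `per_node_cap` most recent tweets of each seed account (most
#' recent by day, then by tweet id), filters them to the given phrases,
#' rebuilds the retweet network, re-runs community detection, selects the
#' `k` most-retweeted accounts per community, and unions the result with the
#' seeds. Members keep their first-assigned community label permanently:
#' seeds retain their seed-stage label, and only accounts new to the set
#' receive labels from the snowball-stage partition.
#'
#' @param seeds a `sentinel_set` (non-empty).
#' @param tweets tweet data.frame to draw from.
#' @param phrases phrase filter applied after the recency cap.
#' @param per_node_cap most-recent-tweet cap per seed account (default 3200).
#' @param k per-community selection size for the expansion (default 80).
#' @param seed RNG seed forwarded to [louvain_partition()].
#' @return the expanded `sentinel_set`. If no tweets survive filtering, the
#'   seeds are returned unchanged with a warning.
#' @export
snowball_expand <- function(seeds, tweets, phrases, per_node_cap = 3200L,
                            k = 80L, seed = 1L) {
  stopifnot(length(seeds$members) > 0)
  mine <- tweets[tweets$author_id %in% seeds$members, , drop = FALSE]
  if (nrow(mine)) {
    keep <- unlist(lapply(split(seq_len(nrow(mine)), mine$author_id), function(ii) {
      ord <- ii[order(mine$day[ii], mine$id[ii], decreasing = TRUE)]
      head(ord, per_node_cap)
    }))
    mine <- mine[sort(keep), , drop = FALSE]
  }
  mine <- filter_by_phrases(mine, phrases)
  mine <- mine[!is.na(mine$retweeted_author_id), , drop = FALSE]
  if (nrow(mine) == 0) {
    warning("no tweets survive the phrase filter; returning seeds unchanged")
    return(seeds)
  }
  net <- build_retweet_network(mine)
  part <- louvain_partition(net, seed = seed)
  expansion <- top_retweeted_per_community(net, part, k = k,
                                           provenance = "snowball")
  new <- setdiff(expansion$members, seeds$members)
  sentinel_set(
    members = c(seeds$members, new),
    community_of = c(seeds$community_of,
                     # offset snowball labels so they never collide with
                     # seed-stage labels (labels are permanent identifiers)
                     stats::setNames(expansion$community_of[new] +
                                       max(seeds$community_of), new)),
    provenance = c(seeds$provenance,
                   stats::setNames(rep("snowball", length(new)), new))
  )
}

#' Write / read a node-community partition table
#'
#' @param partition a `community_partition` or `sentinel_set`.
#' @param path file path for the tab-delimited `node community` table.
#' @return `write_partition` returns `path` invisibly; `read_partition` a
#'   named integer vector.
#' @export
write_partition <- function(partition, path) {
  memb <- if (inherits(partition, "sentinel_set")) partition$community_of else partition$membership
  df <- data.frame(node = names(memb), community = as.integer(memb))
  df <- df[order(df$node), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer"))
  stats::setNames(df$community, df$node)
}
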