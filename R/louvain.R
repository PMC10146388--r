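#' Community detection by directed-modularity Louvain
#'
#' Greedy local moving plus graph aggregation maximizing directed modularity
#' (see [directed_modularity()]). Node visit order within each pass is a
#' seeded shuffle; a node moves to the neighbouring community with the
#' largest strictly positive modularity gain, ties broken toward the
#' smallest community label, so runs are reproducible for a fixed seed.
#'
#' @param net a [retweet_network()] with positive total weight.
#' @param seed integer seed controlling visit order.
#' @param resolution multiplier on the null-model term (1 = plain modularity).
#' @return a `community_partition`: list with named integer `membership`
#'   (labels are consecutive integers ordered by each community's smallest
#'   node id), modularity `Q`, and `n_communities`.
#' @export
louvain_partition <- function(net, seed = 1L, resolution = 1) {
  if (length(net$nodes) == 0 || net$m <= 0) stop("cannot partition an empty graph")
  nodes <- net$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  ef <- idx[net$edges$from]
  et <- idx[net$edges$to]
  ew <- net$edges$weight
  m <- net$m

  assign_final <- with_local_seed(seed, {
    node_map <- seq_len(n)   # original node -> current super-node
    from <- ef; to <- et; w <- ew
    nn <- n
    repeat {
      comm <- louvain_local_move(nn, from, to, w, m, resolution)
      labs <- sort(unique(comm))
      if (length(labs) == nn) break   # no merge at this level: converged
      relab <- match(comm, labs)
      node_map <- relab[node_map]
      # aggregate: communities become super-nodes, parallel arcs summed
      key <- (relab[from] - 1) * length(labs) + relab[to]
      agg <- rowsum(w, key)
      k <- as.integer(rownames(agg))
      from <- ((k - 1) %/% length(labs)) + 1L
      to <- ((k - 1) %% length(labs)) + 1L
      w <- as.numeric(agg)
      nn <- length(labs)
      if (nn == 1) break
    }
    node_map
  })

  # canonical labels: communities numbered by their smallest member node id
  first_member <- tapply(seq_len(n), assign_final, min)
  ord <- order(nodes[first_member])
  relabel <- match(assign_final, as.integer(names(first_member))[ord])
  membership <- stats::setNames(as.integer(relabel), nodes)
  structure(
    list(membership = membership,
         Q = directed_modularity(net, membership),
         n_communities = max(relabel),
         resolution = resolution, seed = seed),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$Q))
  invisible(x)
}

# One level of local moving. Returns a community vector over 1..nn.
louvain_local_move <- function(nn, from, to, w, m, resolution) {
  kout <- numeric(nn)
  tmp <- rowsum(w, from)
  kout[as.integer(rownames(tmp))] <- tmp
  kin <- numeric(nn)
  tmp <- rowsum(w, to)
  kin[as.integer(rownames(tmp))] <- tmp
  # adjacency lists excluding self-loops (a self-loop moves with its node
  # and contributes identically to every candidate community)
  nl <- from != to
  out_nb <- split(data.frame(j = to[nl], w = w[nl]), factor(from[nl], levels = seq_len(nn)))
  in_nb <- split(data.frame(j = from[nl], w = w[nl]), factor(to[nl], levels = seq_len(nn)))
  comm <- seq_len(nn)
  Sin <- kin
  Sout <- kout
  repeat {
    improved <- FALSE
    for (i in sample.int(nn)) {
      old <- comm[i]
      # remove i from its community
      Sin[old] <- Sin[old] - kin[i]
      Sout[old] <- Sout[old] - kout[i]
      ob <- out_nb[[i]]; ib <- in_nb[[i]]
      cand_comms <- unique(c(old, comm[ob$j], comm[ib$j]))
      link <- stats::setNames(numeric(length(cand_comms)), cand_comms)
      if (nrow(ob)) for (r in seq_len(nrow(ob))) {
        cc <- as.character(comm[ob$j[r]]); link[cc] <- link[cc] + ob$w[r]
      }
      if (nrow(ib)) for (r in seq_len(nrow(ib))) {
        cc <- as.character(comm[ib$j[r]]); link[cc] <- link[cc] + ib$w[r]
      }
      gain <- link / m -
        resolution * (kout[i] * Sin[cand_comms] + kin[i] * Sout[cand_comms]) / m^2
      best_gain <- max(gain)
      best <- min(cand_comms[gain >= best_gain - 1e-14])
      if (best != old && best_gain > gain[[as.character(old)]] + 1e-14) {
        comm[i] <- best
        improved <- TRUE
      }
      Sin[comm[i]] <- Sin[comm[i]] + kin[i]
      Sout[comm[i]] <- Sout[comm[i]] + kout[i]
    }
    if (!improved) break
  }
  comm
}
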