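# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: dense double loops, union-find,
# exhaustive enumeration, and textbook normal equations.

# Directed modularity by the dense double sum over all ordered node pairs.
dense_modularity_oracle <- function(net, membership) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    A[net$edges$from[r], net$edges$to[r]] <-
      A[net$edges$from[r], net$edges$to[r]] + net$edges$weight[r]
  }
  kout <- rowSums(A)
  kin <- colSums(A)
  m <- sum(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[nodes[i]] == membership[nodes[j]]) {
        q <- q + A[i, j] - kout[i] * kin[j] / m
      }
    }
  }
  unname(q / m)
}

# All set partitions of 1..n as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(rgs, v), max(mx, v))
  }
  grow(integer(0), 0L)
  out
}

# Best modularity over every partition (exhaustive; n small).
exhaustive_max_modularity <- function(net) {
  best <- -Inf
  for (p in all_set_partitions(length(net$nodes))) {
    memb <- stats::setNames(p, net$nodes)
    q <- dense_modularity_oracle(net, memb)
    if (q > best) best <- q
  }
  best
}

# Weak components by union-find.
union_find_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges$from[r]); b <- find(edges$to[r])
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, character(1))
}

# Random weighted digraph on n nodes.
random_digraph <- function(n, p = 0.4, max_w = 3, seed = 1) {
  set.seed(seed)
  from <- character(0); to <- character(0); w <- numeric(0)
  nodes <- sprintf("n%02d", seq_len(n))
  for (i in nodes) for (j in nodes) {
    if (i != j && runif(1) < p) {
      from <- c(from, i); to <- c(to, j); w <- c(w, sample.int(max_w, 1))
    }
  }
  if (!length(from)) {
    from <- nodes[1]; to <- nodes[2]; w <- 1
  }
  retweet_network(data.frame(from = from, to = to, weight = w), nodes = nodes)
}

# Textbook OLS by explicit normal equations.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se, res = drop(res))
}

# Exact collapsed posterior over all K^N topic-assignment vectors for a
# tiny corpus (docs: list of word-id vectors), via the Dirichlet-
# multinomial complete-data joint.
enum_lda_posterior <- function(docs, V, K, alpha, beta) {
  doc_of <- rep(seq_along(docs), lengths(docs))
  words <- unlist(docs)
  N <- length(words)
  D <- length(docs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(grid, 1, function(z) {
    lp <- 0
    for (d in seq_len(D)) {
      ndk <- tabulate(z[doc_of == d], K)
      lp <- lp + sum(lgamma(ndk + alpha)) - lgamma(sum(ndk) + K * alpha) +
        lgamma(K * alpha) - K * lgamma(alpha)
    }
    for (k in seq_len(K)) {
      nkw <- tabulate(words[z == k], V)
      lp <- lp + sum(lgamma(nkw + beta)) - lgamma(sum(nkw) + V * beta) +
        lgamma(V * beta) - V * lgamma(beta)
    }
    lp
  })
  p <- exp(logp - max(logp))
  list(states = grid, prob = p / sum(p))
}

# Small deterministic tweet fixture builder.
make_tweets <- function(ids, authors, days, tokens, retweeted = NULL) {
  df <- data.frame(id = ids, author_id = authors, day = as.Date(days),
                   retweeted_author_id = retweeted %||% rep(NA_character_, length(ids)),
                   stringsAsFactors = FALSE)
  df$tokens <- tokens
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two dense blocks joined by a single weight-1 arc.
two_block_graph <- function(block_n = 4) {
  nodes_a <- sprintf("a%d", seq_len(block_n))
  nodes_b <- sprintf("b%d", seq_len(block_n))
  e <- expand.grid(from = nodes_a, to = nodes_a, stringsAsFactors = FALSE)
  e2 <- expand.grid(from = nodes_b, to = nodes_b, stringsAsFactors = FALSE)
  e <- rbind(e, e2)
  e <- e[e$from != e$to, ]
  e$weight <- 2
  e <- rbind(e, data.frame(from = "a1", to = "b1", weight = 1))
  retweet_network(e)
}
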