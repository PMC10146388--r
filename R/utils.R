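`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates the
#' expression, and restores the previous RNG state so seeded operations do
#' not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Dirichlet draws via normalized gammas; rows sum to 1 exactly after division.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against all-zero rows at tiny concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k
  x / rowSums(x)
}

# Spectral radius of the VAR companion matrix built from a list/matrix of
# lag coefficient matrices (k x k per lag) or a numeric vector (univariate).
companion_matrix <- function(A) {
  if (is.numeric(A) && is.null(dim(A))) A <- lapply(A, function(a) matrix(a, 1, 1))
  if (is.matrix(A)) A <- list(A)
  k <- nrow(A[[1]])
  p <- length(A)
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[seq_len(k), (l - 1) * k + seq_len(k)] <- A[[l]]
  if (p > 1) comp[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  comp
}

spectral_radius <- function(A) {
  comp <- companion_matrix(A)
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# All permutations of 1..n (n small), used for topic alignment.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (perm in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
    }
  }
  out
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Align estimated topics to reference topics
#'
#' Finds the topic permutation maximizing the mean cosine similarity between
#' rows of two topic-word matrices (exhaustive over permutations; intended
#' for small K).
#'
#' @param phi_hat,phi_true K x V topic-word probability matrices.
#' @return list with `perm` (index into rows of `phi_hat` for each reference
#'   row) and `mean_cosine`.
#' @export
match_topics <- function(phi_hat, phi_true) {
  K <- nrow(phi_true)
  stopifnot(nrow(phi_hat) == K, K <= 8)
  best <- NULL
  best_val <- -Inf
  for (perm in all_permutations(K)) {
    val <- mean(vapply(seq_len(K), function(k) {
      cosine_sim(phi_hat[perm[[k]], ], phi_true[k, ])
    }, numeric(1)))
    if (val > best_val) {
      best_val <- val
      best <- unlist(perm)
    }
  }
  list(perm = best, mean_cosine = best_val)
}
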