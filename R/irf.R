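#' Orthogonalized impulse-response functions with bootstrap bands
#'
#' Moving-average coefficients Psi_h follow the recursion
#' `Psi_h = sum_{l=1..min(h,p)} A_l Psi_{h-l}` with `Psi_0 = I`; the
#' orthogonalized response to a one-standard-deviation shock is
#' `Theta_h = Psi_h P`, where `P` is the lower Cholesky factor of `Sigma_u`
#' under the chosen variable ordering (the shock donor should come first).
#' Confidence bands come from a seeded recursive residual bootstrap
#' (percentile method); bands are widened, if ever necessary, to contain
#' the point estimate. For an unstable fit (companion spectral radius >= 1)
#' the point IRF is still computed but bands are refused with a message.
#'
#' @param fit a `var_fit`.
#' @param H largest horizon (default 10).
#' @param ordering variable ordering used for the Cholesky factor; defaults
#'   to the fit's variable order.
#' @param n_boot bootstrap replicates (0 disables bands).
#' @param seed RNG seed for the bootstrap.
#' @param level band coverage level.
#' @return an `irf_result`: arrays `response`, `lower`, `upper` of shape
#'   (H+1) x k x k indexed `[horizon, impulse, response]`, plus metadata.
#' @export
irf <- function(fit, H = 10L, ordering = fit$variables, n_boot = 500L,
                seed = 1L, level = 0.95) {
  stopifnot(setequal(ordering, fit$variables))
  k <- length(fit$variables)
  stable <- spectral_radius(fit$A) < 1
  theta <- irf_point(fit, H, ordering)
  lower <- upper <- NULL
  if (n_boot > 0) {
    if (!stable) {
      message("fit is unstable (companion spectral radius >= 1); bootstrap bands refused")
    } else {
      boot <- with_local_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          Yb <- var_bootstrap_series(fit)
          fb <- fit_var(Yb, p = fit$p, deterministic = fit$deterministic)
          irf_point(fb, H, ordering)
        }, array(0, dim = c(H + 1, k, k)))
      })
      qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
      lower <- apply(boot, 1:3, quantile, probs = qs[1])
      upper <- apply(boot, 1:3, quantile, probs = qs[2])
      # invariant: bands contain the point estimate
      lower <- pmin(lower, theta)
      upper <- pmax(upper, theta)
      dimnames(lower) <- dimnames(upper) <- dimnames(theta)
    }
  }
  structure(
    list(horizons = 0:H, response = theta, lower = lower, upper = upper,
         ordering = ordering, n_boot = if (is.null(lower)) 0L else as.integer(n_boot),
         seed = seed, level = level, stable = stable),
    class = "irf_result"
  )
}

# Point orthogonalized IRF under a variable ordering; returns
# (H+1) x k x k array [horizon, impulse, response].
irf_point <- function(fit, H, ordering) {
  k <- length(fit$variables)
  perm <- match(ordering, fit$variables)
  A <- lapply(fit$A, function(a) a[perm, perm, drop = FALSE])
  Sigma <- fit$Sigma_u[perm, perm, drop = FALSE]
  P <- t(chol(Sigma))
  Psi <- vector("list", H + 1)
  Psi[[1]] <- diag(k)
  for (h in seq_len(H)) {
    Ph <- matrix(0, k, k)
    for (l in seq_len(min(h, fit$p))) Ph <- Ph + A[[l]] %*% Psi[[h - l + 1]]
    Psi[[h + 1]] <- Ph
  }
  out <- array(0, dim = c(H + 1, k, k),
               dimnames = list(horizon = 0:H, impulse = ordering,
                               response = ordering))
  for (h in 0:H) {
    Th <- Psi[[h + 1]] %*% P
    # Th[resp, imp]: response of variable `resp` to orthogonal shock `imp`
    out[h + 1, , ] <- t(Th)
  }
  out
}

# Recursive residual bootstrap: resample centered residual rows with
# replacement and regenerate the sample from the fitted coefficients and
# deterministic terms, seeding with the original first p observations.
var_bootstrap_series <- function(fit) {
  k <- length(fit$variables)
  p <- fit$p
  U <- scale(fit$residuals, scale = FALSE)
  n <- fit$nobs
  idx <- sample.int(n, n, replace = TRUE)
  Yb <- matrix(0, n + p, k)
  colnames(Yb) <- fit$variables
  Yb[seq_len(p), ] <- fit$Y[seq_len(p), , drop = FALSE]
  for (t in seq_len(n)) {
    tt <- t + p
    acc <- numeric(k)
    for (l in seq_len(p)) acc <- acc + fit$A[[l]] %*% Yb[tt - l, ]
    if (!is.null(fit$c_vec)) acc <- acc + fit$c_vec
    if (!is.null(fit$d_vec)) acc <- acc + fit$d_vec * tt
    Yb[tt, ] <- acc + U[idx[t], ]
  }
  Yb
}

#' @export
print.irf_result <- function(x, ...) {
  cat(sprintf("orthogonalized IRF, horizons 0..%d, ordering: %s\n",
              max(x$horizons), paste(x$ordering, collapse = " -> ")))
  if (x$n_boot > 0) {
    cat(sprintf("  %d bootstrap replicates, %g%% percentile bands\n",
                x$n_boot, 100 * x$level))
  } else {
    cat("  no bootstrap bands\n")
  }
  invisible(x)
}

#' Extract one impulse-response path as a table
#'
#' @param x an `irf_result`.
#' @param impulse,response variable names.
#' @return data.frame with `horizon`, `response`, and (if bands were
#'   computed) `lower`, `upper`.
#' @export
irf_table <- function(x, impulse, response) {
  out <- data.frame(horizon = x$horizons,
                    response = x$response[, impulse, response])
  if (!is.null(x$lower)) {
    out$lower <- x$lower[, impulse, response]
    out$upper <- x$upper[, impulse, response]
  }
  out
}

#' Reverse-causality robustness check
#'
#' Refits the same bivariate system with the roles swapped — acceptance as
#' the shock donor and the sentiment measure as the response — and reports
#' whether any lagged coefficient of the (former) dependent variable on the
#' sentiment equation is individually significant.
#'
#' @param endog list of two [daily_series()] or a two-column matrix, in the
#'   original order `(sentiment, acceptance)`.
#' @param p lag order.
#' @param deterministic deterministic terms.
#' @param H,n_boot,seed forwarded to [irf()].
#' @param alpha significance level for the per-lag t tests.
#' @return list with the swapped `fit`, its `irf`, the per-lag `tstats` of
#'   acceptance lags in the sentiment equation, and `any_significant`.
#' @export
reverse_robustness <- function(endog, p = 4L, deterministic = "const+trend",
                               H = 10L, n_boot = 0L, seed = 1L, alpha = 0.05) {
  Y <- endog_matrix(endog)
  stopifnot(ncol(Y) == 2)
  Yrev <- Y[, c(2, 1), drop = FALSE]
  fit <- fit_var(Yrev, p = p, deterministic = deterministic)
  donor <- colnames(Yrev)[1]      # acceptance, now the shock donor
  target <- colnames(Yrev)[2]     # sentiment equation
  rows <- paste0(donor, ".l", seq_len(p))
  tst <- fit$tstat[rows, target]
  crit <- qnorm(1 - alpha / 2)
  list(fit = fit,
       irf = irf(fit, H = H, ordering = colnames(Yrev), n_boot = n_boot,
                 seed = seed),
       tstats = tst,
       any_significant = any(abs(tst) > crit))
}
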