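#' Augmented Dickey-Fuller unit-root test
#'
#' Estimates the augmented regression
#' `diff(y)_t = rho * y_(t-1) + sum_j phi_j diff(y)_(t-j) + deterministics`
#' by OLS and reports the t-ratio of `rho`. The augmentation order is
#' chosen by information criterion over 0..`max_lag` on a common sample,
#' then the regression is refit at the chosen order on the longest usable
#' sample. Critical values come from the MacKinnon (2010) response
#' surfaces.
#'
#' @param series a [daily_series()] or numeric vector, no missing values.
#' @param deterministic `"const"` (default), `"const+trend"`, or `"none"`.
#' @param max_lag maximum augmentation lag (default `trunc(12 * (n/100)^0.25)`,
#'   the usual Schwert rule).
#' @param ic `"AIC"` (default) or `"BIC"` lag selection.
#' @param alpha significance level for the reject/accept decision.
#' @return an `adf_result`: `statistic`, `lags_used`, `deterministic`,
#'   `critical_values` (1/5/10 percent), `reject` at `alpha`, `nobs`.
#' @export
adf_test <- function(series, deterministic = c("const", "const+trend", "none"),
                     max_lag = NULL, ic = c("AIC", "BIC"), alpha = 0.05) {
  deterministic <- match.arg(deterministic)
  ic <- match.arg(ic)
  y <- series_values(series)
  if (anyNA(y)) stop("series must be complete (no missing values)")
  n <- length(y)
  max_lag <- max_lag %||% trunc(12 * (n / 100)^0.25)
  if (n < max_lag + 10) stop("series too short for the requested max_lag")

  dy <- diff(y)
  # lag selection on the common sample implied by max_lag
  ics <- vapply(0:max_lag, function(L) {
    fit <- adf_ols(y, L, deterministic, trim = max_lag)
    k <- length(fit$coef)
    nn <- fit$nobs
    ll <- -nn / 2 * (1 + log(2 * pi) + log(fit$rss / nn))
    if (ic == "AIC") -2 * ll + 2 * k else -2 * ll + log(nn) * k
  }, numeric(1))
  L <- (0:max_lag)[which.min(ics)]
  fit <- adf_ols(y, L, deterministic, trim = L)
  stat <- fit$coef[["ylag"]] / fit$se[["ylag"]]
  cv <- mackinnon_cv(deterministic, fit$nobs)
  key <- sprintf("%g%%", 100 * alpha)
  if (!key %in% names(cv)) {
    stop("alpha must be one of 0.01, 0.05, 0.10 (tabulated critical values)")
  }
  structure(
    list(statistic = stat, lags_used = L, deterministic = deterministic,
         critical_values = cv, alpha = alpha,
         reject = stat < cv[[key]],
         nobs = fit$nobs, ic = ic),
    class = "adf_result"
  )
}

# OLS of the augmented regression with L lagged differences; `trim` rows are
# dropped from the front of the difference series so candidate lag orders
# can share a sample during selection.
adf_ols <- function(y, L, deterministic, trim = L) {
  dy <- diff(y)
  n <- length(dy)
  rows <- (trim + 1):n
  X <- cbind(ylag = y[rows])           # y_{t-1} for dy_t
  if (L > 0) {
    for (j in seq_len(L)) {
      X <- cbind(X, dy[rows - j])
      colnames(X)[ncol(X)] <- paste0("dlag", j)
    }
  }
  if (deterministic %in% c("const", "const+trend")) {
    X <- cbind(X, const = 1)
  }
  if (deterministic == "const+trend") {
    X <- cbind(X, trend = rows)
  }
  yy <- dy[rows]
  qr_ <- qr(X)
  beta <- qr.coef(qr_, yy)
  res <- yy - X %*% beta
  nobs <- length(yy)
  df <- nobs - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(s2 * diag(XtXinv))
  names(se) <- colnames(X)
  list(coef = beta, se = se, rss = sum(res^2), nobs = nobs, df = df)
}

# MacKinnon (2010) response-surface critical values for the ADF t statistic,
# one unit root, deterministic cases none / const / const+trend.
mackinnon_cv <- function(deterministic, nobs) {
  tab <- switch(deterministic,
    "none" = rbind(`1%`  = c(-2.56574, -2.2358, -3.627),
                   `5%`  = c(-1.94100, -0.2686, -3.365),
                   `10%` = c(-1.61682, 0.2656, -2.714)),
    "const" = rbind(`1%`  = c(-3.43035, -6.5393, -16.786),
                    `5%`  = c(-2.86154, -2.8903, -4.234),
                    `10%` = c(-2.56677, -1.5384, -2.809)),
    "const+trend" = rbind(`1%`  = c(-3.95877, -9.0531, -28.428),
                          `5%`  = c(-3.41049, -4.3904, -9.036),
                          `10%` = c(-3.12705, -2.5856, -3.925))
  )
  vals <- tab[, 1] + tab[, 2] / nobs + tab[, 3] / nobs^2
  as.list(vals)
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF test (%s, %d augmentation lag(s), n = %d)\n",
              x$deterministic, x$lags_used, x$nobs))
  cat(sprintf("  statistic = %.4f; critical values 1%%: %.3f, 5%%: %.3f, 10%%: %.3f\n",
              x$statistic, x$critical_values[["1%"]],
              x$critical_values[["5%"]], x$critical_values[["10%"]]))
  cat(sprintf("  unit root %s at alpha = %g\n",
              if (x$reject) "REJECTED (stationary)" else "not rejected", x$alpha))
  invisible(x)
}
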