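#' Fit a vector autoregression by equation-wise OLS
#'
#' Each equation regresses a variable on lags 1..p of every variable plus
#' deterministic terms (constant and, by default, a linear trend —
#' "controlled for linear trends in the dependent variable"). Coefficient
#' standard errors use the usual OLS covariance with degrees of freedom
#' `nobs - n_params`; the residual covariance `Sigma_u` uses the same
#' degrees-of-freedom correction.
#'
#' @param endog list of [daily_series()] (aligned, complete) or a numeric
#'   matrix/data.frame with one column per variable.
#' @param p lag order (study default 4).
#' @param deterministic `"const+trend"` (default), `"const"`, or `"none"`.
#' @return a `var_fit`: lag coefficient matrices `A` (list of k x k,
#'   response in rows), constant `c_vec`, trend `d_vec`, `Sigma_u`,
#'   per-coefficient `se` / `tstat` / `pvalue`, per-equation `R2` /
#'   `R2_adj`, Gaussian `loglik`, `nobs`, residuals and the regressor
#'   matrix.
#' @export
fit_var <- function(endog, p = 4L, deterministic = c("const+trend", "const", "none")) {
  deterministic <- match.arg(deterministic)
  Y <- endog_matrix(endog)
  k <- ncol(Y)
  n <- nrow(Y)
  if (anyNA(Y)) stop("endogenous series must be complete; align/interpolate first")
  if (n <= 2 * p + 3) stop("series too short for the requested lag order")

  rows <- (p + 1):n
  nobs <- length(rows)
  X <- matrix(NA_real_, nobs, k * p)
  cn <- character(k * p)
  for (l in seq_len(p)) {
    X[, (l - 1) * k + seq_len(k)] <- Y[rows - l, , drop = FALSE]
    cn[(l - 1) * k + seq_len(k)] <- paste0(colnames(Y), ".l", l)
  }
  colnames(X) <- cn
  if (deterministic %in% c("const", "const+trend")) X <- cbind(X, const = 1)
  if (deterministic == "const+trend") X <- cbind(X, trend = rows)

  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient regressor matrix; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  B <- qr.coef(qr_, Y[rows, , drop = FALSE])      # (kp + ndet) x k
  U <- Y[rows, , drop = FALSE] - X %*% B
  n_par <- ncol(X)
  df <- nobs - n_par
  Sigma_u <- crossprod(U) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(outer(diag(XtXinv), diag(Sigma_u)))
  dimnames(se) <- dimnames(B)
  tstat <- B / se
  pvalue <- 2 * pt(-abs(tstat), df)

  A <- lapply(seq_len(p), function(l) {
    t(B[(l - 1) * k + seq_len(k), , drop = FALSE])
  })
  rss <- colSums(U^2)
  tss <- colSums(scale(Y[rows, , drop = FALSE], scale = FALSE)^2)
  R2 <- 1 - rss / tss
  R2_adj <- 1 - (1 - R2) * (nobs - 1) / df
  Sigma_ml <- crossprod(U) / nobs
  loglik <- -(nobs * k / 2) * (1 + log(2 * pi)) -
    (nobs / 2) * determinant(Sigma_ml, logarithm = TRUE)$modulus[1]

  structure(
    list(p = as.integer(p), variables = colnames(Y), deterministic = deterministic,
         A = A, c_vec = if ("const" %in% colnames(X)) B["const", ] else NULL,
         d_vec = if ("trend" %in% colnames(X)) B["trend", ] else NULL,
         B = B, se = se, tstat = tstat, pvalue = pvalue,
         Sigma_u = Sigma_u, R2 = R2, R2_adj = R2_adj,
         loglik = as.numeric(loglik), nobs = nobs, df = df,
         residuals = U, X = X, Y = Y),
    class = "var_fit"
  )
}

endog_matrix <- function(endog) {
  if (is.list(endog) && all(vapply(endog, inherits, logical(1), "daily_series"))) {
    al <- do.call(align_series, c(endog, list(na_action = "none")))
    Y <- as.matrix(al[, -1, drop = FALSE])
  } else {
    Y <- as.matrix(endog)
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  Y
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("VAR(%d) with %s, variables: %s, nobs = %d\n",
              x$p, x$deterministic, paste(x$variables, collapse = ", "), x$nobs))
  cat(sprintf("  R2: %s; log-likelihood: %.2f\n",
              paste(sprintf("%s = %.3f", x$variables, x$R2), collapse = ", "),
              x$loglik))
  invisible(x)
}

#' Coefficient table in the study's reporting layout
#'
#' One block per response equation: lag coefficients with standard errors
#' and 95 percent confidence intervals, then the constant and trend rows,
#' then observations, R-squared (plain and adjusted), and log-likelihood.
#'
#' @param fit a `var_fit`.
#' @param response response variable (default: the last variable).
#' @return data.frame with columns `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `pvalue`.
#' @export
var_coef_table <- function(fit, response = utils::tail(fit$variables, 1)) {
  j <- match(response, fit$variables)
  est <- fit$B[, j]
  se <- fit$se[, j]
  crit <- qnorm(0.975)
  data.frame(term = rownames(fit$B), estimate = unname(est), se = unname(se),
             ci_lower = unname(est - crit * se),
             ci_upper = unname(est + crit * se),
             pvalue = unname(fit$pvalue[, j]))
}

#' Select the VAR lag order by information criterion
#'
#' Fits p = 1..`p_max` on the common sample implied by `p_max` and returns
#' the argmin of the chosen criterion (standard multivariate forms with the
#' maximum-likelihood residual covariance).
#'
#' @param endog as in [fit_var()].
#' @param p_max largest candidate order.
#' @param criterion `"AIC"`, `"BIC"`, or `"HQ"`.
#' @param deterministic deterministic terms used in every candidate fit.
#' @return the selected lag order (integer); the per-p criterion values are
#'   attached as attribute `"values"`.
#' @export
select_lag <- function(endog, p_max = 8L, criterion = c("AIC", "BIC", "HQ"),
                       deterministic = "const+trend") {
  criterion <- match.arg(criterion)
  stopifnot(p_max >= 1)
  Y <- endog_matrix(endog)
  n <- nrow(Y)
  k <- ncol(Y)
  if (n <= 2 * p_max + 3 + p_max) stop("series too short for p_max")
  vals <- vapply(seq_len(p_max), function(p) {
    # common sample: drop the first p_max rows regardless of p
    fit <- fit_var(Y[(p_max - p + 1):n, , drop = FALSE], p = p,
                   deterministic = deterministic)
    nobs <- fit$nobs
    Sigma_ml <- crossprod(fit$residuals) / nobs
    ld <- determinant(Sigma_ml, logarithm = TRUE)$modulus[1]
    pen <- switch(criterion, AIC = 2 / nobs, BIC = log(nobs) / nobs,
                  HQ = 2 * log(log(nobs)) / nobs)
    as.numeric(ld + pen * p * k^2)
  }, numeric(1))
  out <- which.min(vals)
  attr(out, "values") <- stats::setNames(vals, paste0("p", seq_len(p_max)))
  out
}
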