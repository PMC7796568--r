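# Rubin's-rules combination of per-imputation estimates.

#' Pool per-imputation estimates by Rubin's rules
#'
#' Given M point estimates \eqn{\hat{Q}_m} and their within-imputation
#' variances \eqn{\hat{U}_m}, the pooled estimate is
#' \eqn{\bar{Q} = \sum \hat{Q}_m / M} with total variance
#' \eqn{T = U + (1 + 1/M)B}, where \eqn{U} is the mean within-imputation
#' variance and \eqn{B} the between-imputation variance. Degrees of freedom
#' follow the classic formula \eqn{\nu = (M-1)(1 + U/((1+1/M)B))^2}; with
#' B = 0 the normal quantile is used.
#'
#' @param Q numeric vector of per-imputation point estimates (length M >= 2).
#' @param U numeric vector of their variances (all >= 0).
#' @param alpha two-sided error level; the default 0.10 gives 90% intervals.
#' @return an object of class `pooled_estimate` with elements `qbar`, `U`,
#'   `B`, `T`, `M`, `df`, `ci` (length-2), `alpha`.
#' @export
pool <- function(Q, U, alpha = 0.10) {
  stopifnot(is.numeric(Q), is.numeric(U), length(Q) == length(U))
  M <- length(Q)
  if (M < 2) stop("Rubin pooling needs M >= 2 imputations")
  if (any(U < 0)) stop("within-imputation variances must be >= 0")
  stopifnot(alpha > 0, alpha < 1)
  qbar <- mean(Q)
  u <- mean(U)
  b <- sum((Q - qbar)^2) / (M - 1)
  tt <- u + (1 + 1 / M) * b
  if (b > 0) {
    df <- (M - 1) * (1 + u / ((1 + 1 / M) * b))^2
    tq <- stats::qt(1 - alpha / 2, df)
  } else {
    df <- Inf
    tq <- stats::qnorm(1 - alpha / 2)
  }
  half <- tq * sqrt(tt)
  structure(
    list(qbar = qbar, U = u, B = b, T = tt, M = M, df = df,
         ci = c(qbar - half, qbar + half), alpha = alpha),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f, %d%% CI (%.4f, %.4f)\n",
              x$qbar, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2]))
  cat(sprintf("  U = %.5g, B = %.5g, T = %.5g, M = %d, df = %.2f\n",
              x$U, x$B, x$T, x$M, x$df))
  invisible(x)
}

#' Pool per-imputation correlations on the Fisher-z scale
#'
#' Each correlation is transformed with `atanh`, pooled by [pool()] with
#' within-imputation variance `1/(n_eff - 3)`, and the point estimate and
#' interval are back-transformed with `tanh`.
#'
#' @param r per-imputation correlation coefficients, all strictly inside
#'   (-1, 1).
#' @param n_eff sample size behind each correlation (>= 4).
#' @param alpha two-sided error level (default 0.10).
#' @return list with `r` (pooled correlation), `ci`, and `z` (the
#'   z-scale `pooled_estimate`).
#' @export
pool_correlation <- function(r, n_eff, alpha = 0.10) {
  stopifnot(is.numeric(r), n_eff >= 4)
  if (any(abs(r) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  z <- atanh(r)
  pz <- pool(z, rep(1 / (n_eff - 3), length(r)), alpha = alpha)
  list(r = tanh(pz$qbar), ci = tanh(pz$ci), z = pz)
}
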