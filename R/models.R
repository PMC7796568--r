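# Univariate conditional models: one family per variable kind
#   continuous  -> linear          (exact conjugate posterior draw)
#   binary      -> logistic        (ML + asymptotic-normal perturbation)
#   categorical -> multinomial     (ML + asymptotic-normal perturbation)
#   ordinal     -> proportional odds (ML + asymptotic-normal perturbation)

family_for_kind <- function(kind) {
  switch(kind,
         continuous = "linear",
         binary = "logistic",
         categorical = "multinomial",
         ordinal = "proportional_odds",
         stop("unknown kind: ", kind))
}

# Numeric codes for an ordinal variable. Levels with numeric labels (WHO
# performance status "0".."3") keep their face value, so they can double as
# the multiplier in the WHO-dependent shift; otherwise 0-based positions.
ordinal_codes <- function(x, spec) {
  lv <- spec$levels
  suppressWarnings(num <- as.numeric(lv))
  codes <- if (!anyNA(num)) num else seq_along(lv) - 1
  codes[as.integer(x)]
}

#' Build a numeric design matrix
#'
#' Continuous predictors enter as-is, ordinal predictors as integer scores,
#' binary/categorical predictors as reference-coded indicator columns
#' (reference = first declared level). An intercept column is prepended.
#'
#' @param data completed data.frame (typed as by [masked_dataset()]).
#' @param predictors character vector of predictor names (may be empty:
#'   intercept-only design).
#' @param schema an [mi_schema].
#' @return numeric matrix with `nrow(data)` rows.
#' @keywords internal
build_design <- function(data, predictors, schema) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  for (nm in predictors) {
    s <- schema[[nm]]
    x <- data[[nm]]
    if (s$kind == "continuous") {
      cols[[nm]] <- as.numeric(x)
    } else if (s$kind == "ordinal") {
      cols[[nm]] <- ordinal_codes(x, s)
    } else {
      for (lv in s$levels[-1]) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

mvn_perturb <- function(mean, vcov) {
  p <- length(mean)
  ch <- tryCatch(chol(vcov), error = function(e) {
    chol(vcov + diag(1e-8 + 1e-6 * mean(diag(vcov)), p))
  })
  as.numeric(mean + t(ch) %*% stats::rnorm(p))
}

# ---- linear --------------------------------------------------------------

fit_linear <- function(y, X) {
  qrx <- qr(X)
  rank_ok <- qrx$rank == ncol(X)
  if (rank_ok) {
    beta <- qr.coef(qrx, y)
    R <- qr.R(qrx)
    XtXinv <- chol2inv(R)
  } else {
    # ridge-stabilised fallback for singular designs
    warning("singular linear design; ridge-stabilised fit", call. = FALSE)
    lam <- 1e-6 * sum(diag(crossprod(X))) / ncol(X)
    XtXinv <- solve(crossprod(X) + diag(lam, ncol(X)))
    beta <- XtXinv %*% crossprod(X, y)
  }
  beta <- as.numeric(beta)
  res <- y - as.numeric(X %*% beta)
  rss <- sum(res^2)
  n <- length(y); p <- ncol(X)
  df <- max(n - p, 1L)
  sigma2_mle <- rss / n
  loglik <- if (sigma2_mle > 0) {
    -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  } else Inf
  list(family = "linear", beta = beta, XtXinv = XtXinv, rss = rss, df = df,
       loglik = loglik, npar = p + 1L, converged = TRUE)
}

# Exact draw from the noninformative-prior conjugate posterior:
# sigma^2 | y ~ rss / chisq(df),  beta | sigma^2 ~ N(betahat, sigma^2 (X'X)^-1)
draw_linear <- function(fit) {
  sigma2 <- if (fit$rss > 0) fit$rss / stats::rchisq(1, fit$df) else 0
  beta <- if (sigma2 > 0) {
    mvn_perturb(fit$beta, sigma2 * fit$XtXinv)
  } else fit$beta
  list(beta = beta, sigma = sqrt(sigma2))
}

impute_linear <- function(draw, Xmis) {
  mu <- as.numeric(Xmis %*% draw$beta)
  mu + stats::rnorm(nrow(Xmis), sd = draw$sigma)
}

# ---- logistic ------------------------------------------------------------

# IRLS with optional ridge penalty (used when the unpenalised fit separates
# or the design is singular).
irls_logistic <- function(y, X, lambda = 0, maxit = 60, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, p)
    g <- crossprod(X, y - mu) - lambda * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) {
      eta <- as.numeric(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(X, X * w) + diag(lambda, p)
      ll <- sum(y * eta - log1p(exp(eta)))
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(vcov)) return(NULL)
      return(list(beta = beta, vcov = vcov, loglik = ll, converged = TRUE))
    }
  }
  NULL
}

fit_logistic <- function(y01, X) {
  fit <- irls_logistic(y01, X)
  if (is.null(fit) || max(abs(fit$beta)) > 25) {
    warning("separation or singular logistic design; ridge-stabilised fit",
            call. = FALSE)
    fit <- irls_logistic(y01, X, lambda = 1e-3 * length(y01))
    if (is.null(fit)) stop("logistic fit failed even with ridge")
  }
  c(fit, list(family = "logistic", npar = ncol(X)))
}

draw_logistic <- function(fit) list(beta = mvn_perturb(fit$beta, fit$vcov))

impute_logistic <- function(draw, Xmis, levels) {
  p1 <- stats::plogis(as.numeric(Xmis %*% draw$beta))
  levels[1L + (stats::runif(nrow(Xmis)) < p1)]
}

# ---- multinomial ---------------------------------------------------------

# Baseline-category multinomial logit, Newton-Raphson with the analytic
# block Hessian  H[(k,l)] = X' diag(p_k (1{k=l} - p_l)) X.
multinom_probs <- function(B, X) {
  eta <- X %*% B                        # n x (K-1)
  m <- pmax(apply(eta, 1, max), 0)
  ee <- exp(eta - m)
  denom <- exp(-m) + rowSums(ee)
  cbind(exp(-m) / denom, ee / denom)    # n x K, baseline first
}

fit_multinomial <- function(y_int, X, K, lambda = 0, maxit = 80, tol = 1e-8) {
  p <- ncol(X)
  B <- matrix(0, p, K - 1)
  Yind <- matrix(0, length(y_int), K - 1)
  for (k in 2:K) Yind[y_int == k, k - 1] <- 1
  npar <- p * (K - 1)
  for (it in seq_len(maxit)) {
    P <- multinom_probs(B, X)
    Pk <- P[, -1, drop = FALSE]
    grad <- as.numeric(crossprod(X, Yind - Pk)) - lambda * as.numeric(B)
    H <- matrix(0, npar, npar)
    for (k in seq_len(K - 1)) {
      for (l in k:(K - 1)) {
        w <- if (k == l) Pk[, k] * (1 - Pk[, k]) else -Pk[, k] * Pk[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        if (k != l) H[ci, ri] <- t(blk)
      }
    }
    H <- H + diag(lambda, npar)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    B <- B + matrix(step, p, K - 1)
    if (max(abs(step)) < tol) {
      P <- multinom_probs(B, X)
      ll <- sum(log(pmax(P[cbind(seq_along(y_int), y_int)], 1e-300)))
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(vcov)) return(NULL)
      return(list(B = B, vcov = vcov, loglik = ll, converged = TRUE))
    }
    if (max(abs(B)) > 30) return(NULL)   # diverging: separation
  }
  NULL
}

fit_multinomial_safe <- function(y_int, X, K) {
  fit <- fit_multinomial(y_int, X, K)
  if (is.null(fit)) {
    warning("separation or singular multinomial design; ridge-stabilised fit",
            call. = FALSE)
    fit <- fit_multinomial(y_int, X, K, lambda = 1e-3 * length(y_int))
    if (is.null(fit)) stop("multinomial fit failed even with ridge")
  }
  c(fit, list(family = "multinomial", K = K, p = ncol(X),
              npar = ncol(X) * (K - 1)))
}

draw_multinomial <- function(fit) {
  b <- mvn_perturb(as.numeric(fit$B), fit$vcov)
  list(B = matrix(b, fit$p, fit$K - 1))
}

impute_multinomial <- function(draw, Xmis, levels) {
  P <- multinom_probs(draw$B, Xmis)
  idx <- apply(P, 1, function(pr) sample.int(length(pr), 1L, prob = pr))
  levels[idx]
}

# ---- proportional odds ---------------------------------------------------

fit_polr <- function(y_ord, X) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  has_pred <- ncol(df) > 0
  names(df) <- if (has_pred) paste0("x", seq_len(ncol(df))) else character()
  df$.y <- y_ord
  fml <- if (has_pred) {
    stats::as.formula(paste(".y ~", paste(names(df)[names(df) != ".y"],
                                          collapse = " + ")))
  } else stats::as.formula(".y ~ 1")
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = df, Hess = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) return(NULL)
  nb <- length(stats::coef(fit))
  list(family = "proportional_odds",
       beta = as.numeric(stats::coef(fit)), zeta = as.numeric(fit$zeta),
       vcov = vc, nbeta = nb, loglik = as.numeric(stats::logLik(fit)),
       npar = nb + length(fit$zeta), converged = fit$convergence == 0)
}

draw_polr <- function(fit) {
  par <- mvn_perturb(c(fit$beta, fit$zeta), fit$vcov)
  nb <- fit$nbeta
  zeta <- par[(nb + 1):length(par)]
  list(beta = par[seq_len(nb)], zeta = sort(zeta))  # keep cutpoints ordered
}

impute_polr <- function(draw, Xmis, levels) {
  eta <- if (length(draw$beta)) {
    as.numeric(Xmis[, -1, drop = FALSE] %*% draw$beta)
  } else numeric(nrow(Xmis))
  K <- length(levels)
  cum <- vapply(draw$zeta, function(z) stats::plogis(z - eta),
                numeric(nrow(Xmis)))
  if (nrow(Xmis) == 1L) cum <- matrix(cum, nrow = 1L)
  probs <- cbind(cum, 1) - cbind(0, cum)
  probs[probs < 0] <- 0
  idx <- apply(probs, 1, function(pr) {
    sample.int(K, 1L, prob = pmax(pr, 1e-12))
  })
  levels[idx]
}

# ---- unified front-end ---------------------------------------------------

# Fit the conditional model for a target given its kind. Returns NULL when
# the model cannot be fit (caller falls back to a marginal draw).
fit_conditional <- function(y, X, spec) {
  fam <- family_for_kind(spec$kind)
  switch(fam,
    linear = fit_linear(as.numeric(y), X),
    logistic = {
      if (length(unique(y[!is.na(y)])) < 2L) return(NULL)
      fit_logistic(as.numeric(y == spec$levels[2]), X)
    },
    multinomial = {
      if (length(unique(y[!is.na(y)])) < 2L) return(NULL)
      fit_multinomial_safe(as.integer(y), X, K = length(spec$levels))
    },
    proportional_odds = {
      if (length(unique(y[!is.na(y)])) < 2L) return(NULL)
      fit_polr(y, X)
    })
}

#' Draw model parameters from their (approximate) posterior
#'
#' Linear models use the exact conjugate posterior under the noninformative
#' prior; the other families use a single multivariate-normal perturbation of
#' the maximum-likelihood estimate with the asymptotic covariance.
#'
#' @param fit a fit from `fit_conditional`.
#' @return a parameter draw (list), family-specific.
#' @keywords internal
draw_parameters <- function(fit) {
  switch(fit$family,
         linear = draw_linear(fit),
         logistic = draw_logistic(fit),
         multinomial = draw_multinomial(fit),
         proportional_odds = draw_polr(fit))
}

#' Draw imputations from the posterior predictive distribution
#'
#' @param fit model fit (for family/levels bookkeeping).
#' @param draw a parameter draw from [draw_parameters()].
#' @param Xmis design rows of the cells to impute.
#' @param spec the target's [variable_spec].
#' @return numeric vector (linear) or character vector of level labels.
#' @keywords internal
draw_imputations <- function(fit, draw, Xmis, spec) {
  switch(fit$family,
         linear = impute_linear(draw, Xmis),
         logistic = impute_logistic(draw, Xmis, spec$levels),
         multinomial = impute_multinomial(draw, Xmis, spec$levels),
         proportional_odds = impute_polr(draw, Xmis, spec$levels))
}

model_aic <- function(fit) {
  if (is.null(fit) || !is.finite(fit$loglik)) return(Inf)
  -2 * fit$loglik + 2 * fit$npar
}
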