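# Per-family fits, approximate-Bayesian parameter draws, and predictive
# imputation draws. The internal fitters are reached through deltami:::.

fit_conditional <- deltami:::fit_conditional
draw_parameters <- deltami:::draw_parameters
draw_imputations <- deltami:::draw_imputations
build_design <- deltami:::build_design

cont_spec <- function(name = "y") variable_spec(name, "continuous")

test_that("design matrices encode predictor kinds as documented", {
  sc <- toy_schema()
  d <- data.frame(
    gender = factor(c("male", "female", "female"), c("male", "female")),
    who_status = factor(c("0", "2", "3"), as.character(0:3), ordered = TRUE),
    qol_base = c(10, 20, 30), qol_fu = c(1, 2, 3), pain_fu = c(4, 5, 6)
  )
  X <- build_design(d, c("gender", "who_status", "qol_base"), sc)
  expect_equal(colnames(X),
               c("(Intercept)", "gender=female", "who_status", "qol_base"))
  expect_equal(unname(X[, "gender=female"]), c(0, 1, 1))
  # numeric level labels keep their face value (WHO codes 0..3)
  expect_equal(unname(X[, "who_status"]), c(0, 2, 3))
  expect_equal(nrow(build_design(d, character(), sc)), 3)  # intercept-only
})

test_that("linear draws collapse to the OLS solution when residuals vanish", {
  x <- 1:20
  y <- 3 + 2 * x
  X <- cbind(1, x)
  fit <- fit_conditional(y, X, cont_spec())
  set.seed(1)
  for (i in 1:5) {
    dr <- draw_parameters(fit)
    expect_equal(dr$beta, c(3, 2), tolerance = 1e-10)
    expect_equal(dr$sigma, 0)
    expect_equal(draw_imputations(fit, dr, cbind(1, c(30, 40)), cont_spec()),
                 c(63, 83))
  }
})

test_that("linear parameter draws match the conjugate posterior moments", {
  set.seed(42)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- 1 + 0.5 * X[, 2] - X[, 3] + rnorm(n)
  fit <- fit_conditional(y, X, cont_spec())

  ndraw <- 4000
  set.seed(7)
  draws <- t(vapply(seq_len(ndraw), function(i) {
    d <- draw_parameters(fit)
    c(d$beta, d$sigma^2)
  }, numeric(4)))

  # closed form: beta | y ~ multivariate t around betahat with scale
  # s^2 (X'X)^-1 and df = n - p; sigma^2 ~ scaled inverse chi-square
  p <- ncol(X); df <- n - p
  s2 <- fit$rss / df
  exp_s2 <- fit$rss / (df - 2)                 # E[rss / chisq(df)]
  cov_beta <- df / (df - 2) * s2 * fit$XtXinv  # t covariance inflation

  se_mean <- sqrt(diag(cov_beta) / ndraw)
  expect_true(all(abs(colMeans(draws[, 1:3]) - fit$beta) < 5 * se_mean))
  expect_equal(mean(draws[, 4]), exp_s2, tolerance = 0.1)
  expect_equal(cov(draws[, 1:3]), cov_beta, tolerance = 0.15)
})

test_that("intercept-only logistic draws center on the observed rate", {
  set.seed(5)
  y <- c(rep("yes", 30), rep("no", 70))
  spec <- variable_spec("b", "binary", levels = c("no", "yes"))
  X <- matrix(1, 100, 1)
  fit <- fit_conditional(factor(y, c("no", "yes")), X, spec)
  probs <- replicate(2000, plogis(draw_parameters(fit)$beta[1]))
  expect_equal(mean(probs), 0.30, tolerance = 0.02)
})

test_that("the in-package multinomial fitter matches an optim oracle", {
  set.seed(8)
  n <- 300
  x <- rnorm(n)
  eta2 <- 0.8 * x; eta3 <- -0.5 + 0.5 * x
  pr <- cbind(1, exp(eta2), exp(eta3))
  pr <- pr / rowSums(pr)
  y <- apply(pr, 1, function(p) sample.int(3, 1, prob = p))
  X <- cbind(1, x)

  fit <- deltami:::fit_multinomial_safe(y, X, K = 3)

  # oracle: direct optim on the multinomial log-likelihood
  nll <- function(b) {
    B <- matrix(b, 2, 2)
    P <- deltami:::multinom_probs(B, X)
    -sum(log(P[cbind(seq_len(n), y)]))
  }
  o <- optim(rep(0, 4), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(as.numeric(fit$B), o$par, tolerance = 1e-4)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-6)
})

test_that("a degenerate multinomial draw always returns the sure category", {
  spec <- variable_spec("c", "categorical", levels = c("a", "b", "c"))
  draw <- list(B = matrix(c(-50, 0, -50, 0), 2, 2))  # all mass on category 1
  X <- cbind(1, rnorm(20))
  out <- deltami:::impute_multinomial(draw, X, spec$levels)
  expect_true(all(out == "a"))
})

test_that("intercept-only proportional-odds imputations match the fitted
           cumulative-logit frequencies", {
  set.seed(21)
  lev <- as.character(1:4)
  y <- factor(sample(lev, 400, replace = TRUE), lev, ordered = TRUE)
  spec <- variable_spec("o", "ordinal", levels = lev)
  X <- matrix(1, 400, 1)
  fit <- fit_conditional(y, X, spec)
  expect_equal(fit$family, "proportional_odds")

  # oracle frequencies from the fitted cutpoints (no perturbation)
  draw0 <- list(beta = numeric(0), zeta = fit$zeta)
  p_fit <- diff(c(0, plogis(fit$zeta), 1))
  set.seed(22)
  imp <- deltami:::impute_polr(draw0, matrix(1, 10000, 1), lev)
  freq <- as.numeric(table(factor(imp, lev))) / 10000
  se <- sqrt(p_fit * (1 - p_fit) / 10000)
  expect_true(all(abs(freq - p_fit) < 4 * se))
  # data were uniform over 4 levels: fitted probabilities near 0.25
  expect_true(all(abs(p_fit - 0.25) < 0.06))
})

test_that("categorical fits with a single observed class fall back cleanly", {
  spec <- variable_spec("b", "binary", levels = c("no", "yes"))
  y <- factor(rep("no", 30), c("no", "yes"))
  expect_null(fit_conditional(y, matrix(1, 30, 1), spec))
})

test_that("separation triggers the ridge-stabilised logistic fit", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x                                  # perfectly separated
  spec <- variable_spec("b", "binary", levels = c("no", "yes"))
  X <- cbind(1, x)
  expect_warning(
    fit <- fit_conditional(factor(c("no", "yes")[y + 1], c("no", "yes")), X,
                           spec),
    "ridge"
  )
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(diag(fit$vcov))))
})
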