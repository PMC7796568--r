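# Chained-equations driver: step 0, shift construction/application, and the
# run-level invariants (reduction to MAR, reproducibility, no touching of
# observed cells).

test_that("initial_impute draws from the empirical marginals", {
  # constant observed value -> constant fill
  d <- toy_data(10)
  d$qol_base <- c(rep(5, 6), rep(NA, 4))
  ds <- masked_dataset(d, toy_schema())
  set.seed(1)
  filled <- initial_impute(ds)
  expect_equal(filled$qol_base, rep(5, 10))

  # no missing cells -> unchanged
  ds0 <- masked_dataset(toy_data(8), toy_schema())
  expect_identical(initial_impute(ds0), ds0$data)

  # 70% "male" observed -> fills approximately 70% male (binomial oracle)
  n <- 5000
  d <- data.frame(g = c(rep(c("male", "male", "male", "male", "male",
                              "male", "male", "female", "female", "female"),
                            100), rep(NA, n - 1000)))
  sc <- mi_schema(variable_spec("g", "binary", levels = c("male", "female")))
  ds <- masked_dataset(d, sc)
  set.seed(2)
  filled <- initial_impute(ds)
  frac <- mean(filled$g[1001:n] == "male")
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / (n - 1000)))
})

test_that("constant shifts are the descending quarter-grid of IQR/2", {
  # observed IQR = 32 -> (16, 12, 8, 4)
  d <- toy_data(9)
  d$qol_base <- c(10, 20, 26, 30, 40, 50, 58, 70, NA)
  ds <- masked_dataset(d, toy_schema())
  iqr <- IQR(c(10, 20, 26, 30, 40, 50, 58, 70), type = 7)
  k <- compute_constant_shifts(ds, "qol_base")
  expect_equal(unname(k), iqr / 2 * c(1, 3 / 4, 1 / 2, 1 / 4))
  expect_equal(names(k), c("k1", "k2", "k3", "k4"))

  # direct arithmetic case: 9 equispaced observed values, quartiles land on
  # data points, IQR = 60 - 20 = 40 -> (20, 15, 10, 5)
  d <- toy_data(10)
  d$qol_base <- c(seq(0, 80, 10), NA)
  ds <- masked_dataset(d, toy_schema())
  expect_equal(unname(compute_constant_shifts(ds, "qol_base")),
               c(20, 15, 10, 5))

  # brute-force quantile oracle on the documented type-7 rule
  v <- c(0, 10, 20, 30, 40, 60, 80, 100)
  d <- toy_data(9)
  d$qol_base <- c(v, NA)
  ds <- masked_dataset(d, toy_schema())
  q <- function(p) {                           # type-7: linear interpolation
    h <- (length(v) - 1) * p
    sv <- sort(v)
    sv[floor(h) + 1] + (h - floor(h)) * (sv[min(floor(h) + 2, length(v))] -
                                           sv[floor(h) + 1])
  }
  iqr_oracle <- q(0.75) - q(0.25)
  expect_equal(unname(compute_constant_shifts(ds, "qol_base")),
               iqr_oracle * c(1 / 2, 3 / 8, 1 / 4, 1 / 8))

  # degenerate: constant variable -> all shifts 0 with a warning
  d$qol_base <- c(rep(50, 8), NA)
  ds <- masked_dataset(d, toy_schema())
  expect_warning(k0 <- compute_constant_shifts(ds, "qol_base"), "zero IQR")
  expect_equal(unname(k0), rep(0, 4))
})

test_that("apply_shift moves only form-missing draws, in the worsening
           direction, with clipping", {
  sc <- toy_schema()
  qol <- sc[["qol_fu"]]; pain <- sc[["pain_fu"]]

  # QOL draw 70, constant k = 10, sign -1 -> 60; item-missing draw untouched
  out <- apply_shift(c(70, 70), form = c(TRUE, FALSE),
                     shift_constant(c(qol_fu = 10)), qol)
  expect_equal(out$values, c(60, 70))
  expect_equal(out$n_clipped, 0L)

  # PA draw 95, k = 10, sign +1, range [0,100] -> clipped to 100
  out <- apply_shift(95, form = TRUE, shift_constant(c(pain_fu = 10)), pain)
  expect_equal(out$values, 100)
  expect_equal(out$n_clipped, 1L)

  # WHO-dependent: code 2, sd_obs = 24 -> k = 2 * 24 / 4 = 12
  sh <- shift_who("who_status", c(qol_fu = 24))
  out <- apply_shift(c(70, 50), form = c(TRUE, TRUE), sh, qol,
                     who_codes = c(2, 0))
  expect_equal(out$values, c(70 - 12, 50))   # WHO 0 -> no shift
})

test_that("run_chain on a complete dataset returns M identical copies", {
  ds <- masked_dataset(toy_data(15), toy_schema())
  imp <- run_chain(ds, list(), shift_none(),
                   chain_config(M = 3, n_iter = 2, seed = 9))
  expect_equal(imp$M, 3)
  for (m in 1:3) expect_identical(imp$completed[[m]], ds$data)
})

test_that("with zero form-missing cells every scenario reproduces MAR
           bit-for-bit", {
  res <- generate(one_score_config(n = 120, fu_item = 0.3, seed = 31))
  ds <- res$dataset
  expect_equal(sum(ds$form_mask), 0)
  preds <- select_all_predictors(ds, n_predictors = 3, seed = 4)
  cfg <- chain_config(M = 3, n_iter = 5, seed = 17)
  mar <- run_chain(ds, preds, shift_none(), cfg)
  for (sh in list(shift_constant(c(qol_fu = 12)),
                  shift_who("who_status", c(qol_fu = 20)))) {
    alt <- run_chain(ds, preds, sh, cfg)
    expect_same_imputations(mar, alt)
  }
})

test_that("identical seed and config give identical output; different seeds
           differ", {
  res <- generate(one_score_config(n = 100, fu_item = 0.25, form_prob = 0.2,
                                   seed = 8))
  ds <- res$dataset
  preds <- select_all_predictors(ds, n_predictors = 3, seed = 4)
  cfg <- chain_config(M = 2, n_iter = 3, seed = 23)
  a <- run_chain(ds, preds, shift_none(), cfg)
  b <- run_chain(ds, preds, shift_none(), cfg)
  expect_same_imputations(a, b)
  c <- run_chain(ds, preds, shift_none(),
                 chain_config(M = 2, n_iter = 3, seed = 24))
  expect_false(identical(a$completed[[1]], c$completed[[1]]))
})

test_that("observed cells are never modified; item-missing cells are never
           shifted", {
  res <- generate(one_score_config(n = 150, fu_item = 0.15, form_prob = 0.25,
                                   seed = 13))
  ds <- res$dataset
  preds <- select_all_predictors(ds, n_predictors = 3, seed = 4)
  cfg <- chain_config(M = 2, n_iter = 4, seed = 5)
  mar <- run_chain(ds, preds, shift_none(), cfg)
  shifted <- run_chain(ds, preds, shift_constant(c(qol_fu = 15)), cfg)

  obs <- !is.na(ds$data$qol_fu)
  item <- ds$item_mask[, "qol_fu"]
  form <- ds$form_mask[, "qol_fu"]
  for (m in 1:2) {
    # observed cells equal the input in every copy
    for (v in names(ds$data)) {
      ok <- !is.na(ds$data[[v]])
      expect_identical(mar$completed[[m]][[v]][ok], ds$data[[v]][ok])
      expect_identical(shifted$completed[[m]][[v]][ok], ds$data[[v]][ok])
    }
    # common random numbers: item-missing draws agree, form-missing draws
    # differ by exactly the shift (single incomplete variable, no clipping
    # interference at k = 15 here means "differ", not a fixed amount)
    expect_equal(mar$completed[[m]]$qol_fu[item],
                 shifted$completed[[m]]$qol_fu[item])
    expect_true(all(shifted$completed[[m]]$qol_fu[form] <=
                      mar$completed[[m]]$qol_fu[form]))
  }
})

test_that("default_M follows the max-missingness rule of thumb", {
  d <- toy_data(10)
  d$qol_fu[1:4] <- NA                         # 40% missing
  ds <- masked_dataset(d, toy_schema())
  expect_equal(default_M(ds), 40L)
  d2 <- toy_data(10); d2$qol_fu[1] <- NA
  expect_equal(default_M(masked_dataset(d2, toy_schema())), 10L)
})

test_that("a fully missing variable cannot be imputed", {
  d <- toy_data(6)
  d$qol_base <- NA_real_
  ds <- masked_dataset(d, toy_schema())
  expect_error(initial_impute(ds), "entirely missing")
})

test_that("imputation-set invariants hold on a mixed-type run", {
  res <- generate(generator_config(
    n = 120,
    scores = list(score_spec("qol", 65, 20, 64, 21, "functioning", mnar = TRUE)),
    item_missing = c(baseline = 0.05, followup = 0.05),
    cov_missing = 0.08, form_prob = 0.25, seed = 77))
  ds <- res$dataset
  preds <- select_all_predictors(ds, n_predictors = 4, seed = 3)
  imp <- run_chain(ds, preds, make_shift_model(ds, "k1"),
                   chain_config(M = 2, n_iter = 3, seed = 6, scenario = "k1"))
  for (m in 1:2) {
    cm <- imp$completed[[m]]
    expect_false(anyNA(cm))
    expect_true(all(cm$qol_fu >= 0 & cm$qol_fu <= 100))
    expect_true(all(cm$who_status %in% as.character(0:3)))
    expect_true(all(cm$cancer_type %in% levels(ds$data$cancer_type)))
  }
  expect_equal(imp$scenario, "k1")
  expect_named(imp$shift_log, "qol_fu")
})
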