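# Shared fixtures: tiny schemas/datasets built in code.

toy_schema <- function() {
  mi_schema(
    variable_spec("gender", "binary", levels = c("male", "female"),
                  phase = "covariate", forced_predictor = TRUE),
    variable_spec("who_status", "ordinal", levels = as.character(0:3),
                  phase = "covariate", forced_predictor = TRUE),
    variable_spec("qol_base", "continuous", range = c(0, 100),
                  phase = "baseline"),
    variable_spec("qol_fu", "continuous", range = c(0, 100),
                  phase = "followup", mnar_endpoint = TRUE, shift_sign = -1L),
    variable_spec("pain_fu", "continuous", range = c(0, 100),
                  phase = "followup", mnar_endpoint = TRUE, shift_sign = 1L)
  )
}

toy_data <- function(n = 20, seed = 42) {
  set.seed(seed)
  data.frame(
    gender = sample(c("male", "female"), n, replace = TRUE),
    who_status = sample(as.character(0:3), n, replace = TRUE),
    qol_base = round(runif(n, 20, 90), 1),
    qol_fu = round(runif(n, 20, 90), 1),
    pain_fu = round(runif(n, 5, 70), 1),
    stringsAsFactors = FALSE
  )
}

# one-score generator config used across engine tests: covariates and
# baseline complete, follow-up score incomplete
one_score_config <- function(n = 300, fu_item = 0.30, form_prob = 0,
                             form_shift = 0, form_mechanism = "mcar",
                             seed = 1L, ...) {
  generator_config(
    n = n,
    scores = list(score_spec("qol", 65, 20, 64, 21, "functioning",
                             mnar = TRUE)),
    item_missing = c(baseline = 0, followup = fu_item),
    cov_missing = 0,
    form_prob = form_prob, form_shift = form_shift,
    form_mechanism = form_mechanism,
    seed = seed, ...
  )
}

# mid-scale scores (means well inside [0, 100]) keep truncation effects
# negligible, so recovery and shift-algebra checks measure the mechanism
# under test rather than boundary artifacts
midscale_config <- function(n = 300, fu_item = 0, form_prob = 0,
                            form_shift = 0, seed = 1L, two_endpoints = FALSE,
                            ...) {
  scores <- list(score_spec("qol", 52, 18, 50, 18, "functioning", mnar = TRUE))
  if (two_endpoints) {
    scores <- c(scores, list(score_spec("pain", 42, 15, 40, 15, "symptom",
                                        mnar = TRUE)))
  }
  generator_config(
    n = n, scores = scores,
    item_missing = c(baseline = 0, followup = fu_item),
    cov_missing = 0, form_prob = form_prob, form_shift = form_shift,
    seed = seed, ...
  )
}

expect_same_imputations <- function(a, b) {
  expect_equal(a$M, b$M)
  for (m in seq_len(a$M)) expect_identical(a$completed[[m]], b$completed[[m]])
}
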