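# Synthetic trial-like data with known ground truth and controllable
# missingness mechanisms.
#
# Patients carry a latent health factor h (higher = healthier). Baseline and
# follow-up scores load on h (positively for functioning / quality-of-life
# scores, negatively for symptom scores), share a score-specific stable
# component, and carry transient noise; follow-up health is an AR(1) update
# of baseline health. Scores are truncated to [0, 100], so configured means
# are pre-truncation targets and the TruthRecord stores the realized
# (post-truncation) means as the recovery target for tests.

#' Declare a synthetic score
#'
#' @param name score stem; the generator emits `<name>_base` and `<name>_fu`.
#' @param base_mean,base_sd,fu_mean,fu_sd pre-truncation normal moments at
#'   baseline and follow-up, on the 0-100 scale.
#' @param role `"functioning"` (higher = better; delta shifts subtract) or
#'   `"symptom"` (higher = worse; delta shifts add).
#' @param mnar flag the follow-up score as an MNAR endpoint.
#' @return a list consumed by [generator_config()].
#' @export
score_spec <- function(name, base_mean, base_sd, fu_mean, fu_sd,
                       role = c("functioning", "symptom"), mnar = FALSE) {
  role <- match.arg(role)
  list(name = name, base_mean = base_mean, base_sd = base_sd,
       fu_mean = fu_mean, fu_sd = fu_sd, role = role, mnar = isTRUE(mnar),
       dir = if (role == "functioning") 1 else -1,
       shift_sign = if (role == "functioning") -1L else 1L)
}

default_scores <- function() {
  list(
    score_spec("qol",        65.05, 20.27, 64.16, 21.84, "functioning", mnar = TRUE),
    score_spec("phys_func",  69.58, 23.91, 68.69, 25.60, "functioning", mnar = TRUE),
    score_spec("emot_func",  78.41, 20.50, 79.84, 21.22, "functioning", mnar = TRUE),
    score_spec("pain",       21.41, 24.03, 20.67, 25.16, "symptom",     mnar = TRUE),
    score_spec("dyspnoea",   25.28, 28.08, 26.33, 27.83, "symptom",     mnar = TRUE),
    score_spec("fatigue",    41.66, 26.22, 41.68, 25.70, "symptom",     mnar = TRUE),
    score_spec("involvement",  74.71, 18.24, 75.80, 18.30, "functioning"),
    score_spec("quality_care", 76.21, 21.48, 73.03, 22.16, "functioning"),
    score_spec("active_coping", 71.34, 25.49, 68.26, 27.40, "functioning"),
    score_spec("denial",       23.20, 27.04, 20.68, 25.37, "symptom")
  )
}

#' Generator configuration
#'
#' Defaults emulate the structure of a ~487-patient end-of-life care cohort:
#' baseline covariates (gender, age, WHO performance status 0-3, cancer
#' type), 0-100 scores at baseline (low item missingness) and follow-up
#' (~36-39% missingness, ~35% of patients contributing a completely missing
#' form).
#'
#' @param n number of patients.
#' @param scores list of [score_spec()] entries.
#' @param p_male probability of male gender.
#' @param gender_effect latent-health advantage of males (SD units); drives
#'   realistic male/female score differences.
#' @param age_mean,age_sd age distribution.
#' @param who_probs probabilities of WHO performance status 0-3.
#' @param who_health_cor correlation of the WHO latent with (poor) health.
#' @param cancer_probs named probabilities of the cancer-type categories.
#' @param loading loading of every score on latent health.
#' @param stable share (SD units) of the score-specific stable component.
#' @param autocorr AR(1) coefficient of follow-up vs baseline latent health.
#' @param item_missing named vector: item-missingness probabilities
#'   `c(baseline = ..., followup = ...)`.
#' @param cov_missing item-missingness probability for covariates (age, WHO,
#'   cancer type; gender is always observed).
#' @param item_mechanism `"mcar"` or `"mar"` (logistic in the WHO code).
#' @param item_mar_slope log-odds slope per WHO code under `"mar"` items.
#' @param form_prob marginal probability of a completely missing follow-up
#'   form.
#' @param form_mechanism `"mcar"`, `"mar"` (logistic in the baseline value of
#'   the first score) or `"mnar"` (logistic in the unobserved follow-up
#'   latent health).
#' @param form_mar_slope log-odds slope per baseline score point (`"mar"`).
#' @param form_mnar_delta log-odds slope per SD of *poor* follow-up health
#'   (`"mnar"`); larger delta = stronger selection, >= 0.
#' @param form_shift pattern shift in score points: form-missing patients'
#'   true follow-up MNAR-endpoint values are moved by `form_shift` in the
#'   worsening direction before truncation (0 = no pattern effect). This is
#'   the generative counterpart of the constant-delta imputation model.
#' @param seed RNG seed used by [generate()] unless overridden.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n = 487,
                             scores = default_scores(),
                             p_male = 0.60,
                             gender_effect = 0.5,
                             age_mean = 66, age_sd = 9.9,
                             who_probs = c(0.346, 0.529, 0.121, 0.004),
                             who_health_cor = 0.6,
                             cancer_probs = c(small_cell_lung = 0.128,
                                              non_small_cell_lung = 0.451,
                                              colon = 0.322, rectal = 0.099),
                             loading = 0.6,
                             stable = 0.55,
                             autocorr = 0.8,
                             item_missing = c(baseline = 0.03, followup = 0.02),
                             cov_missing = 0.02,
                             item_mechanism = c("mcar", "mar"),
                             item_mar_slope = 0.5,
                             form_prob = 0.35,
                             form_mechanism = c("mcar", "mar", "mnar"),
                             form_mar_slope = -0.03,
                             form_mnar_delta = 1.0,
                             form_shift = 0,
                             seed = 1L) {
  item_mechanism <- match.arg(item_mechanism)
  form_mechanism <- match.arg(form_mechanism)
  probs <- c(p_male, who_probs, cancer_probs, item_missing, cov_missing,
             form_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(who_probs) - 1) > 1e-8 || abs(sum(cancer_probs) - 1) > 1e-8) {
    stop("category probabilities must sum to 1")
  }
  if (form_mnar_delta < 0 || form_shift < 0) {
    stop("form_mnar_delta and form_shift must be >= 0")
  }
  if (loading^2 + stable^2 >= 1) stop("loading^2 + stable^2 must be < 1")
  if (abs(autocorr) > 1) stop("|autocorr| must be <= 1")
  for (s in scores) {
    for (m in c(s$base_mean, s$fu_mean)) {
      if (m < 0 || m > 100) stop("score mean outside [0, 100]: ", s$name)
    }
    if (s$base_sd <= 0 || s$fu_sd <= 0) stop("score sd must be > 0: ", s$name)
  }
  structure(
    list(n = n, scores = scores, p_male = p_male,
         gender_effect = gender_effect, age_mean = age_mean, age_sd = age_sd,
         who_probs = who_probs, who_health_cor = who_health_cor,
         cancer_probs = cancer_probs, loading = loading, stable = stable,
         autocorr = autocorr, item_missing = item_missing,
         cov_missing = cov_missing, item_mechanism = item_mechanism,
         item_mar_slope = item_mar_slope, form_prob = form_prob,
         form_mechanism = form_mechanism, form_mar_slope = form_mar_slope,
         form_mnar_delta = form_mnar_delta, form_shift = form_shift,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Schema implied by a generator configuration
#'
#' @param cfg a [generator_config()].
#' @return the [mi_schema] of the generated datasets.
#' @export
synthetic_schema <- function(cfg) {
  specs <- list(
    variable_spec("gender", "binary", levels = c("male", "female"),
                  phase = "covariate", forced_predictor = TRUE),
    variable_spec("age", "continuous", phase = "covariate",
                  forced_predictor = TRUE),
    variable_spec("who_status", "ordinal", levels = as.character(0:3),
                  phase = "covariate", forced_predictor = TRUE),
    variable_spec("cancer_type", "categorical",
                  levels = names(cfg$cancer_probs),
                  phase = "covariate", forced_predictor = TRUE)
  )
  for (s in cfg$scores) {
    specs <- c(specs, list(
      variable_spec(paste0(s$name, "_base"), "continuous", range = c(0, 100),
                    phase = "baseline"),
      variable_spec(paste0(s$name, "_fu"), "continuous", range = c(0, 100),
                    phase = "followup", mnar_endpoint = s$mnar,
                    shift_sign = if (s$mnar) s$shift_sign else 0L)
    ))
  }
  mi_schema(specs)
}

# calibrate a logistic intercept so the mean selection probability over the
# sampled linear predictor equals the target marginal probability
calibrate_intercept <- function(lin, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + lin)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Generate a synthetic masked dataset with ground truth
#'
#' @param cfg a [generator_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `dataset` (a [masked_dataset()]) and `truth` (class
#'   `truth_record`: `complete` data.frame before masking, `means` — realized
#'   follow-up endpoint means overall / by gender / by form stratum — and
#'   `params`, the realized mechanism parameters).
#' @export
generate <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  n <- cfg$n
  schema <- synthetic_schema(cfg)

  gender <- factor(ifelse(stats::runif(n) < cfg$p_male, "male", "female"),
                   levels = c("male", "female"))
  male <- gender == "male"

  # latent health, standardized over the population
  h_raw <- stats::rnorm(n) + cfg$gender_effect * male
  mu_h <- cfg$gender_effect * cfg$p_male
  sd_h <- sqrt(1 + cfg$gender_effect^2 * cfg$p_male * (1 - cfg$p_male))
  h_base <- (h_raw - mu_h) / sd_h
  h_fu <- cfg$autocorr * h_base + sqrt(1 - cfg$autocorr^2) * stats::rnorm(n)

  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  rho <- cfg$who_health_cor
  who_lat <- -rho * h_base + sqrt(1 - rho^2) * stats::rnorm(n)
  who <- cut(who_lat, breaks = c(-Inf, stats::qnorm(cumsum(cfg$who_probs))),
             labels = as.character(0:3), ordered_result = TRUE)
  who <- factor(who, levels = as.character(0:3), ordered = TRUE)
  cancer <- factor(
    sample(names(cfg$cancer_probs), n, replace = TRUE, prob = cfg$cancer_probs),
    levels = names(cfg$cancer_probs))

  lam <- cfg$loading; om <- cfg$stable
  tau <- sqrt(1 - lam^2 - om^2)
  complete <- data.frame(gender = gender, age = age, who_status = who,
                         cancer_type = cancer)
  raw_fu <- list()
  for (s in cfg$scores) {
    psi <- stats::rnorm(n)
    zb <- lam * s$dir * h_base + om * psi + tau * stats::rnorm(n)
    zf <- lam * s$dir * h_fu + om * psi + tau * stats::rnorm(n)
    complete[[paste0(s$name, "_base")]] <-
      pmin(pmax(s$base_mean + s$base_sd * zb, 0), 100)
    raw_fu[[s$name]] <- s$fu_mean + s$fu_sd * zf
  }

  # form-missing indicator
  lin <- switch(cfg$form_mechanism,
    mcar = numeric(n),
    mar = cfg$form_mar_slope *
      (complete[[paste0(cfg$scores[[1]]$name, "_base")]] -
         cfg$scores[[1]]$base_mean),
    mnar = cfg$form_mnar_delta * (-h_fu))
  a <- calibrate_intercept(lin, cfg$form_prob)
  p_form <- stats::plogis(a + lin)
  form <- stats::runif(n) < p_form

  # pattern effect: form-missers' true MNAR-endpoint follow-up values are
  # worse by form_shift (pre-truncation)
  for (s in cfg$scores) {
    x <- raw_fu[[s$name]]
    if (cfg$form_shift > 0 && s$mnar) {
      x[form] <- x[form] + s$shift_sign * cfg$form_shift
    }
    complete[[paste0(s$name, "_fu")]] <- pmin(pmax(x, 0), 100)
  }

  # realized truth means (follow-up endpoints)
  fu_eps <- paste0(vapply(cfg$scores, `[[`, character(1), "name"), "_fu")
  means <- lapply(stats::setNames(fu_eps, fu_eps), function(v) {
    x <- complete[[v]]
    list(overall = mean(x),
         by_gender = c(male = mean(x[male]), female = mean(x[!male])),
         completers = mean(x[!form]),
         form_missing = if (any(form)) mean(x[form]) else NA_real_)
  })

  # masking
  masked <- complete
  fu_cols <- followup_vars(schema)
  for (v in fu_cols) masked[[v]][form] <- NA

  item_p <- function(p0) {
    if (p0 <= 0) return(rep(0, n))
    if (cfg$item_mechanism == "mcar") return(rep(p0, n))
    linw <- cfg$item_mar_slope * ordinal_codes(who, schema[["who_status"]])
    stats::plogis(calibrate_intercept(linw, p0) + linw)
  }
  p_base <- item_p(unname(cfg$item_missing["baseline"]))
  p_fu <- item_p(unname(cfg$item_missing["followup"]))
  p_cov <- item_p(cfg$cov_missing)
  for (v in schema_names(schema)) {
    if (v == "gender") next
    ph <- schema[[v]]$phase
    p <- switch(ph, covariate = p_cov, baseline = p_base, followup = p_fu)
    hit <- stats::runif(n) < p & !is.na(masked[[v]])
    # never mask a variable completely
    if (sum(!is.na(masked[[v]][!hit])) == 0L) next
    masked[[v]][hit] <- NA
  }

  ds <- masked_dataset(masked, schema, form_indicator = form)
  truth <- structure(
    list(complete = complete, means = means,
         params = list(form_intercept = a, form_prob_realized = mean(form),
                       n_form = sum(form), mechanism = cfg$form_mechanism,
                       form_shift = cfg$form_shift, seed = seed)),
    class = "truth_record"
  )
  list(dataset = ds, truth = truth)
}

#' Write a truth record as JSON
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(means = truth$means, params = truth$params),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Small deterministic benchmark suite
#'
#' A fixed grid of reduced-size scenarios for fast testing: MCAR items only,
#' MAR items, and MCAR forms with a generative pattern shift of 0, 5 and 10
#' points on the endpoints.
#'
#' @param seed master seed.
#' @param n patients per scenario (reduced for speed).
#' @return named list of `list(dataset, truth)` pairs.
#' @export
make_benchmark_suite <- function(seed = 1L, n = 150L) {
  scores <- list(
    score_spec("qol", 65, 20, 64, 21, "functioning", mnar = TRUE),
    score_spec("pain", 25, 22, 26, 23, "symptom", mnar = TRUE),
    score_spec("quality_care", 75, 21, 73, 22, "functioning")
  )
  base <- function(...) {
    generator_config(n = n, scores = scores, cov_missing = 0, ...)
  }
  cfgs <- list(
    mcar_items = base(form_prob = 0,
                      item_missing = c(baseline = 0.05, followup = 0.25)),
    mar_items = base(form_prob = 0, item_mechanism = "mar",
                     item_missing = c(baseline = 0.05, followup = 0.25)),
    form_delta0 = base(form_prob = 0.35, form_shift = 0),
    form_delta5 = base(form_prob = 0.35, form_shift = 5),
    form_delta10 = base(form_prob = 0.35, form_shift = 10)
  )
  out <- vector("list", length(cfgs))
  names(out) <- names(cfgs)
  for (i in seq_along(cfgs)) {
    out[[i]] <- generate(cfgs[[i]], seed = seed + i)
  }
  out
}
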