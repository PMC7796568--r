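# Sensitivity-analysis driver: impute under each scenario, compute
# per-imputation statistics on the completed data, pool by Rubin's rules,
# and compare the MNAR scenarios against MAR.

detect_gender_variable <- function(schema) {
  nms <- schema_names(schema)
  kinds <- vapply(schema, `[[`, character(1), "kind")
  hit <- nms[grepl("gender|sex", nms, ignore.case = TRUE) & kinds == "binary"]
  if (length(hit)) hit[1] else NULL
}

# mean and variance-of-the-mean (s^2/n) of one column, optionally on a subset
mean_stat <- function(x, idx = NULL) {
  if (!is.null(idx)) x <- x[idx]
  x <- x[!is.na(x)]
  n <- length(x)
  c(est = mean(x), var = stats::var(x) / n, n = n)
}

#' Run the full scenario grid
#'
#' For every scenario label, builds the matching shift model, runs the
#' chained-equations engine at the *same master seed* (so scenario contrasts
#' are common-random-number comparisons), computes per-imputation means
#' (overall and by gender) and correlations of the MNAR endpoints with the
#' secondary scores on each completed dataset, and pools by Rubin's rules. A
#' complete-case ("observed") reference report is always included.
#'
#' @param ds a [masked_dataset()].
#' @param cfg a [chain_config()]; its `scenario` field is overridden per run.
#' @param scenarios character vector of scenario labels (see
#'   [make_shift_model()]).
#' @param predictors optional precomputed [select_all_predictors()] result;
#'   computed once at `cfg$seed` when `NULL`.
#' @param endpoints endpoint names; default: the schema's MNAR endpoints.
#' @param secondary secondary score names; default: continuous follow-up
#'   variables not flagged MNAR.
#' @param gender_var gender variable name; auto-detected when `NULL`.
#' @param who_variable WHO variable for the `"kwho"` scenario.
#' @param alpha two-sided error level (default 0.10: 90% intervals).
#' @param n_predictors AIC-selection size when predictors are computed here.
#' @return an object of class `scenario_reports`: list with `reports` (one
#'   `scenario_report` per successful scenario plus `"observed"`), `errors`
#'   (failed scenarios), `alpha`, `seed`.
#' @export
run_scenarios <- function(ds, cfg,
                          scenarios = c("mar", "kwho", "k1", "k2", "k3", "k4"),
                          predictors = NULL,
                          endpoints = NULL, secondary = NULL,
                          gender_var = NULL, who_variable = NULL,
                          alpha = 0.10, n_predictors = 15) {
  stopifnot(inherits(ds, "masked_dataset"), inherits(cfg, "chain_config"))
  schema <- ds$schema
  endpoints <- endpoints %||% mnar_endpoints(schema)
  if (!length(endpoints)) stop("no endpoints to analyse")
  if (is.null(secondary)) {
    kinds <- vapply(schema, `[[`, character(1), "kind")
    fu <- followup_vars(schema)
    secondary <- setdiff(fu[kinds[fu] == "continuous"], endpoints)
  }
  gender_var <- gender_var %||% detect_gender_variable(schema)
  if (is.null(predictors)) {
    predictors <- select_all_predictors(ds, n_predictors = n_predictors,
                                        seed = cfg$seed)
  }

  reports <- list(observed = observed_report(ds, endpoints, secondary,
                                             gender_var, alpha))
  errors <- list()
  for (sc in scenarios) {
    res <- tryCatch({
      shift <- make_shift_model(ds, sc, who_variable = who_variable)
      scfg <- cfg
      scfg$scenario <- sc
      imp <- run_chain(ds, predictors, shift, scfg)
      scenario_report(imp, endpoints, secondary, gender_var, alpha)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("scenario '", sc, "' failed: ", conditionMessage(res),
              call. = FALSE)
      errors[[sc]] <- conditionMessage(res)
    } else {
      reports[[sc]] <- res
    }
  }
  structure(list(reports = reports, errors = errors, alpha = alpha,
                 seed = cfg$seed),
            class = "scenario_reports")
}

#' Pool the analysis statistics of one imputation set
#'
#' @param imp an `imputation_set`.
#' @param endpoints,secondary variable names to analyse.
#' @param gender_var optional gender variable for stratified means.
#' @param alpha two-sided error level.
#' @return a `scenario_report`: list with `scenario`, `means` (data.frame:
#'   endpoint, group, estimate, lo, hi, U, B, T, df) and `correlations`
#'   (data.frame: endpoint, secondary, r, lo, hi).
#' @export
scenario_report <- function(imp, endpoints, secondary = character(),
                            gender_var = NULL, alpha = 0.10) {
  stopifnot(inherits(imp, "imputation_set"))
  n <- nrow(imp$completed[[1]])
  groups <- list(overall = NULL)
  if (!is.null(gender_var)) {
    lv <- levels(imp$completed[[1]][[gender_var]])
    for (g in lv) groups[[g]] <- g
  }

  mean_rows <- list()
  for (ep in endpoints) {
    for (gname in names(groups)) {
      stats_m <- vapply(imp$completed, function(d) {
        idx <- if (is.null(groups[[gname]])) NULL else
          d[[gender_var]] == groups[[gname]]
        mean_stat(as.numeric(d[[ep]]), idx)
      }, numeric(3))
      p <- pool(stats_m["est", ], stats_m["var", ], alpha = alpha)
      mean_rows[[length(mean_rows) + 1L]] <- data.frame(
        scenario = imp$scenario, endpoint = ep, group = gname,
        estimate = p$qbar, lo = p$ci[1], hi = p$ci[2],
        U = p$U, B = p$B, T = p$T, df = p$df)
    }
  }

  cor_rows <- list()
  for (ep in endpoints) {
    for (sv in secondary) {
      r_m <- vapply(imp$completed, function(d) {
        stats::cor(as.numeric(d[[ep]]), as.numeric(d[[sv]]))
      }, numeric(1))
      r_m <- pmin(pmax(r_m, -0.999999), 0.999999)
      pc <- pool_correlation(r_m, n_eff = n, alpha = alpha)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        scenario = imp$scenario, endpoint = ep, secondary = sv,
        r = pc$r, lo = pc$ci[1], hi = pc$ci[2])
    }
  }

  structure(list(scenario = imp$scenario,
                 means = do.call(rbind, mean_rows),
                 correlations = if (length(cor_rows))
                   do.call(rbind, cor_rows) else NULL,
                 alpha = alpha),
            class = "scenario_report")
}

# complete-case reference: observed values only, t / Fisher intervals
observed_report <- function(ds, endpoints, secondary, gender_var, alpha) {
  d <- ds$data
  mean_rows <- list()
  groups <- list(overall = NULL)
  if (!is.null(gender_var)) {
    for (g in levels(d[[gender_var]])) groups[[g]] <- g
  }
  for (ep in endpoints) {
    for (gname in names(groups)) {
      idx <- if (is.null(groups[[gname]])) rep(TRUE, nrow(d)) else
        !is.na(d[[gender_var]]) & d[[gender_var]] == groups[[gname]]
      st <- mean_stat(as.numeric(d[[ep]]), idx)
      half <- stats::qt(1 - alpha / 2, max(st["n"] - 1, 1)) * sqrt(st["var"])
      mean_rows[[length(mean_rows) + 1L]] <- data.frame(
        scenario = "observed", endpoint = ep, group = gname,
        estimate = unname(st["est"]), lo = unname(st["est"] - half),
        hi = unname(st["est"] + half), U = unname(st["var"]), B = 0,
        T = unname(st["var"]), df = unname(st["n"] - 1))
    }
  }
  cor_rows <- list()
  for (ep in endpoints) {
    for (sv in secondary) {
      ok <- !is.na(d[[ep]]) & !is.na(d[[sv]])
      if (sum(ok) < 4) next
      r <- stats::cor(as.numeric(d[[ep]][ok]), as.numeric(d[[sv]][ok]))
      z <- atanh(min(max(r, -0.999999), 0.999999))
      hz <- stats::qnorm(1 - alpha / 2) / sqrt(sum(ok) - 3)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        scenario = "observed", endpoint = ep, secondary = sv, r = r,
        lo = tanh(z - hz), hi = tanh(z + hz))
    }
  }
  structure(list(scenario = "observed",
                 means = do.call(rbind, mean_rows),
                 correlations = if (length(cor_rows))
                   do.call(rbind, cor_rows) else NULL,
                 alpha = alpha),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>", x$scenario, "\n")
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.scenario_reports <- function(x, ...) {
  cat("<scenario_reports>", length(x$reports), "reports:",
      paste(names(x$reports), collapse = ", "), "\n")
  invisible(x)
}

ci_overlap_fraction <- function(lo1, hi1, lo2, hi2) {
  ov <- max(0, min(hi1, hi2) - max(lo1, lo2))
  w <- min(hi1 - lo1, hi2 - lo2)
  if (w <= 0) return(as.numeric(ov >= 0 && lo1 <= hi2 && lo2 <= hi1))
  ov / w
}

#' Compare scenario reports against the MAR reference
#'
#' For each pooled mean and correlation, computes the divergence from the
#' MAR scenario, the fraction of overlap between the two confidence
#' intervals (overlap length over the narrower interval's width), and for
#' correlations a direction-stability flag (same sign, and the interval's
#' zero-crossing status agrees with MAR).
#'
#' @param reports a `scenario_reports` object (or a plain list of
#'   `scenario_report`s) containing a `"mar"` report and at least one other.
#' @return list with data.frames `means` and `correlations`, plus
#'   `max_divergence` per scenario.
#' @export
compare_report <- function(reports) {
  reps <- if (inherits(reports, "scenario_reports")) reports$reports else reports
  if (length(reps) < 2) stop("need at least two reports to compare")
  if (!"mar" %in% names(reps)) stop("comparison requires a 'mar' report")
  ref <- reps[["mar"]]
  others <- reps[setdiff(names(reps), "mar")]

  mean_rows <- list(); cor_rows <- list()
  for (nm in names(others)) {
    rep <- others[[nm]]
    mm <- merge(rep$means, ref$means,
                by = c("endpoint", "group"), suffixes = c("", "_mar"))
    mm$divergence <- mm$estimate - mm$estimate_mar
    mm$ci_overlap <- mapply(ci_overlap_fraction,
                            mm$lo, mm$hi, mm$lo_mar, mm$hi_mar)
    mean_rows[[nm]] <- data.frame(scenario = nm,
                                  mm[c("endpoint", "group", "estimate",
                                       "estimate_mar", "divergence",
                                       "ci_overlap")])
    if (!is.null(rep$correlations) && !is.null(ref$correlations)) {
      cc <- merge(rep$correlations, ref$correlations,
                  by = c("endpoint", "secondary"), suffixes = c("", "_mar"))
      cc$divergence <- cc$r - cc$r_mar
      cc$ci_overlap <- mapply(ci_overlap_fraction,
                              cc$lo, cc$hi, cc$lo_mar, cc$hi_mar)
      spans0 <- cc$lo < 0 & cc$hi > 0
      spans0_mar <- cc$lo_mar < 0 & cc$hi_mar > 0
      cc$direction_stable <- sign(cc$r) == sign(cc$r_mar) &
        spans0 == spans0_mar
      cor_rows[[nm]] <- data.frame(scenario = nm,
                                   cc[c("endpoint", "secondary", "r", "r_mar",
                                        "divergence", "ci_overlap",
                                        "direction_stable")])
    }
  }
  means <- do.call(rbind, mean_rows)
  list(
    means = means,
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL,
    max_divergence = tapply(abs(means$divergence), means$scenario, max)
  )
}

#' Write scenario reports to CSV
#'
#' @param reports a `scenario_reports` object.
#' @param means_path,correlations_path output CSV paths (correlations file
#'   skipped when `NULL` or no correlations were computed).
#' @return `means_path`, invisibly.
#' @export
write_reports <- function(reports, means_path, correlations_path = NULL) {
  reps <- reports$reports
  means <- do.call(rbind, lapply(reps, `[[`, "means"))
  utils::write.csv(means, means_path, row.names = FALSE)
  if (!is.null(correlations_path)) {
    cors <- do.call(rbind, lapply(reps, `[[`, "correlations"))
    if (!is.null(cors)) utils::write.csv(cors, correlations_path,
                                         row.names = FALSE)
  }
  invisible(means_path)
}
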