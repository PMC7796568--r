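# Chained-equations driver with pattern-mixture delta adjustment of
# form-missing imputations.
#
# MAR algorithm: step 0 fills every missing cell from its empirical
# marginal; each of n_iter sweeps then visits the incomplete variables in
# ascending-missing-count order, refits the conditional model on the current
# completed data, draws parameters from the (approximate) posterior and
# imputations from the posterior predictive. The MNAR modification adds a
# step 3: imputations landing on form-missing cells of a flagged endpoint
# are shifted by a delta in the direction that worsens the patient's
# condition, inside the sweep, so the adjustment propagates through the
# subsequent conditional models.

#' Shift models for the MNAR pattern-mixture adjustment
#'
#' `shift_none()` encodes the MAR scenario. `shift_constant(k)` subtracts or
#' adds (per the endpoint's `shift_sign`) a constant `k` to every
#' form-missing imputation of each flagged endpoint. `shift_who(...)` uses an
#' individual shift `k_i = who_code_i * sd_obs / 4`, where `who_code_i` is
#' the patient's (possibly chained-imputed) WHO performance status and
#' `sd_obs` the standard deviation of the endpoint's observed follow-up
#' values, computed once before imputation.
#'
#' @param k named numeric vector of shift magnitudes (one per MNAR endpoint),
#'   or a single value recycled to all endpoints; magnitudes must be >= 0.
#' @return an object of class `shift_model`.
#' @export
shift_none <- function() {
  structure(list(mode = "none"), class = "shift_model")
}

#' @rdname shift_none
#' @export
shift_constant <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0))
  structure(list(mode = "constant", k = k), class = "shift_model")
}

#' @rdname shift_none
#' @param who_variable name of the WHO performance-status variable (ordinal).
#' @param sd_obs named numeric vector: per-endpoint standard deviation of the
#'   observed follow-up values.
#' @export
shift_who <- function(who_variable, sd_obs) {
  stopifnot(is.character(who_variable), length(who_variable) == 1L,
            is.numeric(sd_obs), all(sd_obs >= 0), !is.null(names(sd_obs)))
  structure(list(mode = "who_dependent", who_variable = who_variable,
                 sd_obs = sd_obs),
            class = "shift_model")
}

shift_magnitude <- function(shift, endpoint) {
  k <- shift$k
  if (length(k) == 1L && is.null(names(k))) return(unname(k))
  if (!endpoint %in% names(k)) {
    stop("no constant shift declared for endpoint '", endpoint, "'")
  }
  unname(k[[endpoint]])
}

#' Constant-shift grid from the interquartile range
#'
#' The four constant shifts are the equispaced values spanning (0, IQR/2] of
#' the endpoint's observed distribution, labelled in descending order:
#' k1 = IQR/2, k2 = 3 IQR/8, k3 = IQR/4, k4 = IQR/8 (k1 produces the largest
#' departure from MAR). Quantiles use the default type-7 definition.
#'
#' @param ds a [masked_dataset()].
#' @param endpoint name of a continuous variable with >= 4 observed values.
#' @return named numeric vector `c(k1, k2, k3, k4)`.
#' @export
compute_constant_shifts <- function(ds, endpoint) {
  spec <- ds$schema[[endpoint]]
  if (is.null(spec) || spec$kind != "continuous") {
    stop("'", endpoint, "' is not a continuous variable")
  }
  obs <- ds$data[[endpoint]]
  obs <- obs[!is.na(obs)]
  if (length(obs) < 4L) stop("endpoint '", endpoint, "' has < 4 observed values")
  iqr <- stats::IQR(obs, type = 7)
  if (iqr == 0) {
    warning("zero IQR for '", endpoint, "'; all shifts 0", call. = FALSE)
    return(stats::setNames(rep(0, 4), paste0("k", 1:4)))
  }
  stats::setNames(iqr / 2 * c(4, 3, 2, 1) / 4, paste0("k", 1:4))
}

#' Observed-data standard deviation of an endpoint
#'
#' @inheritParams compute_constant_shifts
#' @return sample standard deviation of the observed (unimputed) values.
#' @export
compute_sd_obs <- function(ds, endpoint) {
  x <- ds$data[[endpoint]]
  stats::sd(x[!is.na(x)])
}

# locate the WHO performance-status variable in a schema
detect_who_variable <- function(schema) {
  nms <- schema_names(schema)
  hit <- nms[grepl("who", nms, ignore.case = TRUE) &
               vapply(schema, `[[`, character(1), "kind") == "ordinal"]
  if (length(hit)) hit[1] else NULL
}

#' Apply the delta adjustment to a vector of imputed draws
#'
#' Only draws landing on form-missing cells are shifted; item-missing draws
#' pass through untouched. Adjusted values are clipped to the declared range.
#'
#' @param draws numeric imputed values, one per missing cell of the endpoint.
#' @param form logical, same length: is the cell form-missing?
#' @param shift a `shift_model`.
#' @param spec the endpoint's [variable_spec] (must have
#'   `mnar_endpoint = TRUE`).
#' @param who_codes numeric WHO codes (current chained values) for the
#'   same cells; required in `who_dependent` mode.
#' @return list with `values` (adjusted draws) and `n_clipped`.
#' @export
apply_shift <- function(draws, form, shift, spec, who_codes = NULL) {
  stopifnot(inherits(shift, "shift_model"), isTRUE(spec$mnar_endpoint),
            length(draws) == length(form))
  if (shift$mode == "none" || !any(form)) {
    return(list(values = draws, n_clipped = 0L))
  }
  k <- switch(shift$mode,
    constant = shift_magnitude(shift, spec$name),
    who_dependent = {
      if (is.null(who_codes)) stop("who_dependent shift needs WHO codes")
      sd_j <- shift$sd_obs[[spec$name]]
      if (is.null(sd_j)) stop("no sd_obs for endpoint '", spec$name, "'")
      who_codes[form] * sd_j / 4
    })
  draws[form] <- draws[form] + spec$shift_sign * k
  n_clipped <- 0L
  if (!is.null(spec$range)) {
    out <- draws[form] < spec$range[1] | draws[form] > spec$range[2]
    n_clipped <- sum(out)
    draws[form] <- pmin(pmax(draws[form], spec$range[1]), spec$range[2])
  }
  list(values = draws, n_clipped = n_clipped)
}

#' Build the shift model for a named scenario
#'
#' Scenario labels follow the sensitivity-analysis grid: `"mar"` (no shift),
#' `"kwho"` (WHO-dependent shift), `"k1"` ... `"k4"` (constant shifts from
#' [compute_constant_shifts()], k1 largest).
#'
#' @param ds a [masked_dataset()].
#' @param scenario scenario label.
#' @param who_variable WHO variable name; auto-detected when `NULL`.
#' @return a `shift_model`.
#' @export
make_shift_model <- function(ds, scenario, who_variable = NULL) {
  eps <- mnar_endpoints(ds$schema)
  if (scenario == "mar") return(shift_none())
  if (!length(eps)) stop("schema declares no MNAR endpoints")
  if (scenario == "kwho") {
    who <- who_variable %||% detect_who_variable(ds$schema)
    if (is.null(who)) stop("scenario 'kwho' needs a WHO performance-status ",
                           "variable (ordinal, name containing 'who')")
    sd_obs <- vapply(eps, function(e) compute_sd_obs(ds, e), numeric(1))
    return(shift_who(who, sd_obs))
  }
  if (grepl("^k[1-4]$", scenario)) {
    i <- as.integer(substring(scenario, 2))
    k <- vapply(eps, function(e) compute_constant_shifts(ds, e)[i], numeric(1))
    names(k) <- eps
    return(shift_constant(k))
  }
  stop("unknown scenario '", scenario, "'")
}

#' Initial imputation from the empirical marginals (step 0)
#'
#' @param ds a [masked_dataset()].
#' @return a completed data.frame; each missing cell is an independent draw
#'   (with replacement) from the variable's observed values.
#' @export
initial_impute <- function(ds) {
  stopifnot(inherits(ds, "masked_dataset"))
  prelim_complete(ds)
}

#' Chain configuration
#'
#' @param M number of imputations; default (`NULL`) is the rule of thumb
#'   `ceiling(max per-variable missingness percentage)` resolved at run time
#'   (about 40 for ~39% missingness), with a floor of 2.
#' @param n_iter sweeps per chain (default 100; lower in tests).
#' @param seed master RNG seed; per-chain seeds are spawned from it so chains
#'   are exchangeable, and scenarios run at the same master seed share common
#'   random numbers.
#' @param scenario label stored in the output metadata.
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(M = NULL, n_iter = 100, seed = 1, scenario = "mar") {
  if (!is.null(M)) stopifnot(M >= 2)
  stopifnot(n_iter >= 1)
  structure(list(M = M, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), scenario = scenario),
            class = "chain_config")
}

#' @rdname chain_config
#' @param ds a [masked_dataset()].
#' @export
default_M <- function(ds) {
  pct <- missingness_summary(ds)$per_variable$pct_missing
  max(2L, as.integer(ceiling(max(pct))))
}

#' Run the (modified) chained-equations algorithm
#'
#' @param ds a [masked_dataset()].
#' @param predictors named list of `predictor_set` objects covering every
#'   incomplete variable (see [select_all_predictors()]).
#' @param shift a `shift_model`; `shift_none()` gives the plain MAR run. With
#'   zero form-missing cells any shift model reproduces the MAR run exactly.
#' @param cfg a [chain_config()].
#' @return an object of class `imputation_set`: list with `completed` (M
#'   complete data.frames), `scenario`, `M`, `n_iter`, `seed`, `shift_log`,
#'   `n_clipped`, `n_fallback`.
#' @export
run_chain <- function(ds, predictors, shift = shift_none(),
                      cfg = chain_config()) {
  stopifnot(inherits(ds, "masked_dataset"), inherits(cfg, "chain_config"),
            inherits(shift, "shift_model"))
  schema <- ds$schema
  n <- nrow(ds$data)
  incomplete <- names(ds$data)[vapply(ds$data, anyNA, logical(1))]
  lacking <- setdiff(incomplete, names(predictors))
  if (length(lacking)) {
    stop("no predictor set for incomplete variable(s): ",
         paste(lacking, collapse = ", "))
  }
  M <- cfg$M %||% default_M(ds)

  # visit order: ascending missing count, ties by schema column order
  n_miss <- vapply(incomplete, function(v) sum(is.na(ds$data[[v]])), integer(1))
  visit <- incomplete[order(n_miss, match(incomplete, schema_names(schema)))]

  who <- if (shift$mode == "who_dependent") shift$who_variable else NULL
  pre <- lapply(visit, function(v) {
    mis <- is.na(ds$data[[v]])
    list(name = v, spec = schema[[v]], mis = mis, obs = !mis,
         form = ds$form_mask[, v][mis],
         y_obs = ds$data[[v]][!mis],
         preds = predictors[[v]]$final)
  })

  set.seed(cfg$seed)
  chain_seeds <- sample.int(2147483646L, M)

  completed <- vector("list", M)
  n_clipped <- 0L; n_fallback <- 0L
  shift_log <- list()

  for (m in seq_len(M)) {
    set.seed(chain_seeds[m])
    cur <- initial_impute(ds)
    for (it in seq_len(cfg$n_iter)) {
      for (vb in pre) {
        res <- tryCatch(
          impute_one(vb, cur, schema, shift, who),
          error = function(e) {
            stop("chain ", m, ", iteration ", it, ", variable '", vb$name,
                 "': ", conditionMessage(e), call. = FALSE)
          })
        cur[[vb$name]][vb$mis] <- res$values
        n_clipped <- n_clipped + res$n_clipped
        n_fallback <- n_fallback + res$fallback
      }
    }
    if (anyNA(cur)) stop("internal error: incomplete chain output")
    completed[[m]] <- cur
  }

  if (shift$mode == "constant") shift_log <- as.list(shift$k)
  if (shift$mode == "who_dependent") shift_log <- as.list(shift$sd_obs)

  structure(
    list(completed = completed, scenario = cfg$scenario, M = M,
         n_iter = cfg$n_iter, seed = cfg$seed, shift = shift,
         shift_log = shift_log, n_clipped = n_clipped,
         n_fallback = n_fallback),
    class = "imputation_set"
  )
}

# one variable, one sweep: fit -> parameter draw -> predictive draw ->
# delta adjustment of the form-missing cells
impute_one <- function(vb, cur, schema, shift, who) {
  spec <- vb$spec
  X <- build_design(cur, vb$preds, schema)
  Xobs <- X[vb$obs, , drop = FALSE]
  Xmis <- X[vb$mis, , drop = FALSE]
  fallback <- 0L

  fit <- NULL
  if (sum(vb$obs) >= ncol(Xobs) + 2L) {
    fit <- tryCatch(fit_conditional(vb$y_obs, Xobs, spec),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    # too few observed cases or degenerate fit: empirical-marginal draw
    fallback <- 1L
    imp <- sample(as.character(vb$y_obs), nrow(Xmis), replace = TRUE)
    values <- if (spec$kind == "continuous") as.numeric(imp) else imp
  } else {
    draw <- draw_parameters(fit)
    values <- draw_imputations(fit, draw, Xmis, spec)
  }

  n_clipped <- 0L
  if (spec$kind == "continuous" && !is.null(spec$range)) {
    out <- values < spec$range[1] | values > spec$range[2]
    n_clipped <- n_clipped + sum(out)
    values <- pmin(pmax(values, spec$range[1]), spec$range[2])
  }

  if (spec$mnar_endpoint && shift$mode != "none" && any(vb$form)) {
    who_codes <- NULL
    if (shift$mode == "who_dependent") {
      who_codes <- ordinal_codes(cur[[who]][vb$mis], schema[[who]])
    }
    adj <- apply_shift(values, vb$form, shift, spec, who_codes)
    values <- adj$values
    n_clipped <- n_clipped + adj$n_clipped
  }
  list(values = values, n_clipped = n_clipped, fallback = fallback)
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> scenario:", x$scenario, "| M =", x$M,
      "| iterations =", x$n_iter, "| seed =", x$seed, "\n")
  cat("  clipped draws:", x$n_clipped,
      "| marginal fallbacks:", x$n_fallback, "\n")
  invisible(x)
}

#' Write an imputation set to disk
#'
#' The M completed copies are stacked into one long CSV with an `.imp`
#' index column; run metadata goes to a JSON sidecar.
#'
#' @param imp an `imputation_set`.
#' @param data_path output CSV path.
#' @param meta_path optional JSON metadata path.
#' @return `data_path`, invisibly.
#' @export
write_imputations <- function(imp, data_path, meta_path = NULL) {
  stopifnot(inherits(imp, "imputation_set"))
  long <- do.call(rbind, lapply(seq_len(imp$M), function(m) {
    d <- imp$completed[[m]]
    for (j in seq_along(d)) d[[j]] <- as.character(d[[j]])
    cbind(.imp = m, d)
  }))
  utils::write.csv(long, data_path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(scenario = imp$scenario, M = imp$M, n_iter = imp$n_iter,
                 seed = imp$seed, shift_mode = imp$shift$mode,
                 shift_log = imp$shift_log, n_clipped = imp$n_clipped,
                 n_fallback = imp$n_fallback)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(data_path)
}
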