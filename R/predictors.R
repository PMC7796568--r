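# AIC preselection of imputation-model predictors.
#
# Each incomplete variable is regressed, one candidate at a time, on every
# other variable (the dataset having first been completed by a single draw
# from the empirical marginals). The n_predictors candidates with the
# smallest AIC are kept and the set is enriched with the forced covariates.

prelim_complete <- function(ds) {
  cur <- ds$data
  for (nm in names(cur)) {
    x <- cur[[nm]]
    mis <- is.na(x)
    if (!any(mis)) next
    obs <- x[!mis]
    if (!length(obs)) stop("variable '", nm, "' is entirely missing")
    cur[[nm]][mis] <- sample(obs, sum(mis), replace = TRUE)
  }
  cur
}

#' Select predictors for one incomplete variable
#'
#' Implements the single-predictor AIC screen: all variables are completed
#' once by draws from their empirical marginal distributions, then for each
#' candidate a one-predictor regression of the target's *observed* values on
#' the candidate is fitted (family matching the target's kind) and scored by
#' AIC. The `n_predictors` best candidates are selected, and the final set is
#' the union of the selection with the forced covariates. AIC ties break by
#' schema column order.
#'
#' @param ds a [masked_dataset()]; the target must have at least one missing
#'   cell and the dataset at least two variables.
#' @param target name of the variable to be imputed.
#' @param n_predictors number of AIC-selected predictors to keep (default 15).
#' @param seed RNG seed for the preliminary marginal completion (the only
#'   stochastic step); `NULL` uses the current RNG state.
#' @return an object of class `predictor_set`: list with `target`,
#'   `selected` (ordered by ascending AIC), `aic` (named, all candidates),
#'   `forced`, `final`.
#' @export
select_predictors <- function(ds, target, n_predictors = 15, seed = NULL) {
  stopifnot(inherits(ds, "masked_dataset"))
  if (!target %in% names(ds$data)) stop("unknown target '", target, "'")
  if (!anyNA(ds$data[[target]])) {
    stop("target '", target, "' has no missing cells")
  }
  if (ncol(ds$data) < 2L) stop("dataset needs at least two variables")
  if (!is.null(seed)) set.seed(seed)
  completed <- prelim_complete(ds)
  select_predictors_impl(ds, completed, target, n_predictors)
}

select_predictors_impl <- function(ds, completed, target, n_predictors) {
  schema <- ds$schema
  spec <- schema[[target]]
  obs <- !is.na(ds$data[[target]])
  y <- ds$data[[target]][obs]
  candidates <- setdiff(schema_names(schema), target)

  aic <- rep(Inf, length(candidates))
  names(aic) <- candidates
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    cnd <- candidates[i]
    xc <- completed[[cnd]]
    nx <- if (is.factor(xc)) as.integer(xc) else as.numeric(xc)
    if (stats::var(nx[obs]) == 0) {
      warning("candidate '", cnd, "' has zero variance after preliminary ",
              "imputation; excluded", call. = FALSE)
      keep[i] <- FALSE
      next
    }
    X <- build_design(completed, cnd, schema)[obs, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(fit_conditional(y, X, spec)),
      error = function(e) NULL
    )
    aic[i] <- model_aic(fit)
  }

  eligible <- candidates[keep]
  ord <- order(aic[eligible], match(eligible, schema_names(schema)))
  selected <- eligible[ord][seq_len(min(n_predictors, length(eligible)))]
  selected <- selected[is.finite(aic[selected])]
  forced <- setdiff(forced_predictors(schema), target)
  final <- union(selected, forced)

  structure(
    list(target = target, selected = selected, aic = aic,
         forced = forced, final = final),
    class = "predictor_set"
  )
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("<predictor_set> target:", x$target, "\n")
  cat("  selected (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  forced: ", paste(x$forced, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select predictors for every incomplete variable
#'
#' One shared preliminary marginal completion is drawn, then the AIC screen
#' of [select_predictors()] runs for each variable with missing cells.
#'
#' @inheritParams select_predictors
#' @return named list of `predictor_set` objects, one per incomplete
#'   variable.
#' @export
select_all_predictors <- function(ds, n_predictors = 15, seed = NULL) {
  stopifnot(inherits(ds, "masked_dataset"))
  if (!is.null(seed)) set.seed(seed)
  completed <- prelim_complete(ds)
  incomplete <- names(ds$data)[vapply(ds$data, anyNA, logical(1))]
  out <- lapply(incomplete, function(tg) {
    select_predictors_impl(ds, completed, tg, n_predictors)
  })
  names(out) <- incomplete
  out
}

#' Write a per-target predictor report
#'
#' @param psets named list of `predictor_set` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictor_report <- function(psets, path) {
  rows <- do.call(rbind, lapply(psets, function(ps) {
    data.frame(target = ps$target,
               rank = seq_along(ps$final),
               predictor = ps$final,
               source = ifelse(ps$final %in% ps$selected, "aic", "forced"),
               aic = unname(ps$aic[ps$final]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
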