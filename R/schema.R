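# Variable specifications and dataset schemas.

#' Declare a variable
#'
#' A variable specification records everything the imputation machinery needs
#' to know about one column: its measurement type, its admissible values, the
#' study phase it belongs to, whether its form-missing values are suspected of
#' being missing not at random (MNAR), and in which direction a delta shift
#' worsens the patient's condition.
#'
#' @param name column name (single string).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`, `"ordinal"`.
#' @param levels character vector of category labels, in order, for
#'   non-continuous kinds; must be empty for continuous variables.
#' @param range closed numeric interval `c(lo, hi)` for continuous scores
#'   (questionnaire scales live on `c(0, 100)`), or `NULL` for unbounded.
#' @param phase `"baseline"`, `"followup"` or `"covariate"`.
#' @param mnar_endpoint logical; `TRUE` for follow-up scores whose
#'   form-missing values are handled by the pattern-mixture shift.
#' @param shift_sign -1 if the shift is subtracted (functioning and quality of
#'   life scores, where lower is worse), +1 if added (symptom scores, where
#'   higher is worse), 0 for variables that are never shifted.
#' @param forced_predictor logical; forced into every imputation model
#'   regardless of the AIC screen (gender, age, cancer type, WHO status).
#'
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind,
                          levels = character(),
                          range = NULL,
                          phase = c("covariate", "baseline", "followup"),
                          mnar_endpoint = FALSE,
                          shift_sign = 0L,
                          forced_predictor = FALSE) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical", "ordinal"))
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  shift_sign <- as.integer(shift_sign)
  if (kind == "continuous") {
    if (length(levels)) stop("continuous variable '", name, "' cannot have levels")
    if (!is.null(range)) {
      stopifnot(is.numeric(range), length(range) == 2L, range[1] < range[2])
    }
  } else {
    if (!length(levels)) {
      stop(kind, " variable '", name, "' needs a non-empty level set")
    }
    if (kind == "binary" && length(levels) != 2L) {
      stop("binary variable '", name, "' must have exactly 2 levels")
    }
    range <- NULL
  }
  if (mnar_endpoint) {
    if (phase != "followup" || kind != "continuous") {
      stop("MNAR endpoint '", name, "' must be a continuous follow-up score")
    }
    if (!shift_sign %in% c(-1L, 1L)) {
      stop("MNAR endpoint '", name, "' needs shift_sign -1 or +1")
    }
  } else if (shift_sign != 0L) {
    stop("'", name, "': shift_sign must be 0 unless mnar_endpoint is TRUE")
  }
  structure(
    list(name = name, kind = kind, levels = as.character(levels),
         range = range, phase = phase,
         mnar_endpoint = isTRUE(mnar_endpoint),
         shift_sign = shift_sign,
         forced_predictor = isTRUE(forced_predictor)),
    class = "variable_spec"
  )
}

#' Assemble a dataset schema
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return an object of class `mi_schema`: a named list of specs in column
#'   order.
#' @export
mi_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "variable_spec")) {
    specs <- specs[[1]]
  }
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "variable_spec"))) {
    stop("mi_schema() expects variable_spec objects")
  }
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicated variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(specs) <- nms
  structure(specs, class = "mi_schema")
}

#' @export
print.mi_schema <- function(x, ...) {
  cat("<mi_schema> ", length(x), " variables\n", sep = "")
  for (s in x) {
    cat(sprintf("  %-24s %-11s %-9s%s%s\n", s$name, s$kind, s$phase,
                if (s$mnar_endpoint)
                  sprintf(" mnar(%+d)", s$shift_sign) else "",
                if (s$forced_predictor) " forced" else ""))
  }
  invisible(x)
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

forced_predictors <- function(schema) {
  schema_names(schema)[vapply(schema, `[[`, logical(1), "forced_predictor")]
}

mnar_endpoints <- function(schema) {
  schema_names(schema)[vapply(schema, `[[`, logical(1), "mnar_endpoint")]
}

followup_vars <- function(schema) {
  schema_names(schema)[vapply(schema, `[[`, character(1), "phase") == "followup"]
}

#' Read / write a schema sidecar
#'
#' Schemas travel with the data CSV as a JSON sidecar: an array of objects
#' with the `variable_spec` fields.
#'
#' @param path file path of the JSON sidecar.
#' @return `read_schema` returns an `mi_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(v) {
    variable_spec(
      name = v$name,
      kind = v$kind,
      levels = as.character(unlist(v$levels %||% character())),
      range = if (!is.null(v$range)) as.numeric(unlist(v$range)) else NULL,
      phase = v$phase %||% "covariate",
      mnar_endpoint = isTRUE(v$mnar_endpoint),
      shift_sign = as.integer(v$shift_sign %||% 0L),
      forced_predictor = isTRUE(v$forced_predictor)
    )
  })
  mi_schema(specs)
}

#' @rdname read_schema
#' @param schema an `mi_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "mi_schema"))
  out <- lapply(unname(schema), function(s) {
    v <- list(name = s$name, kind = s$kind, phase = s$phase,
              mnar_endpoint = s$mnar_endpoint,
              shift_sign = s$shift_sign,
              forced_predictor = s$forced_predictor)
    if (length(s$levels)) v$levels <- as.list(s$levels)
    if (!is.null(s$range)) v$range <- s$range
    v
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
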