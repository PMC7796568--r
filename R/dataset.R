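# Masked datasets: a data table plus the two-way partition of its missing
# cells into item-missing (R^I) and form-missing (R^F) sets.

#' Construct a masked dataset
#'
#' Missing cells are partitioned into two disjoint sets: *item-missing* cells
#' (isolated unanswered items, assumed missing at random) and *form-missing*
#' cells (the patient's entire follow-up questionnaire is absent, for which a
#' missing-not-at-random mechanism may be hypothesised). Form-missingness is
#' a patient-level event: it can affect only follow-up variables, and a
#' form-missing patient has every follow-up cell masked.
#'
#' @param data data.frame whose columns match `schema` (missing cells `NA`).
#'   Factor columns are re-levelled to the schema's level sets.
#' @param schema an [mi_schema].
#' @param form_indicator optional logical/0-1 vector of length `nrow(data)`
#'   marking patients whose follow-up form is entirely missing. When `NULL`,
#'   the indicator is inferred: a patient is form-missing iff *all* of their
#'   follow-up cells are missing. When supplied, the explicit indicator wins
#'   on conflict with the inference rule (a warning is raised if a patient is
#'   flagged but has observed follow-up cells, which would be inconsistent).
#'
#' @return an object of class `masked_dataset` with elements `data`,
#'   `schema`, `item_mask`, `form_mask` (n x J logical matrices) and
#'   `form_indicator` (logical, length n).
#' @export
masked_dataset <- function(data, schema, form_indicator = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "mi_schema"))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols)) {
    stop("data lacks schema column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(data), nms)
  if (length(extra)) {
    stop("data has column(s) not in schema: ", paste(extra, collapse = ", "))
  }
  data <- data[nms]
  n <- nrow(data)

  # coerce columns to their declared types and validate values
  for (s in schema) {
    x <- data[[s$name]]
    if (s$kind == "continuous") {
      x <- as.numeric(x)
      if (!is.null(s$range)) {
        bad <- which(!is.na(x) & (x < s$range[1] | x > s$range[2]))
        if (length(bad)) {
          stop("value out of range [", s$range[1], ",", s$range[2],
               "] in column '", s$name, "', row ", bad[1])
        }
      }
    } else {
      if (is.factor(x)) x <- as.character(x)
      x <- as.character(x)
      bad <- which(!is.na(x) & !x %in% s$levels)
      if (length(bad)) {
        stop("value '", x[bad[1]], "' not among declared levels of column '",
             s$name, "', row ", bad[1])
      }
      x <- factor(x, levels = s$levels, ordered = s$kind == "ordinal")
    }
    data[[s$name]] <- x
  }

  miss <- vapply(data, is.na, logical(n))
  if (n == 1L) miss <- matrix(miss, nrow = 1L, dimnames = list(NULL, nms))
  fu <- nms %in% followup_vars(schema)

  if (any(fu)) {
    all_fu_missing <- rowSums(!miss[, fu, drop = FALSE]) == 0L
  } else {
    all_fu_missing <- rep(FALSE, n)
  }
  if (is.null(form_indicator)) {
    form_indicator <- all_fu_missing & any(fu)
  } else {
    form_indicator <- as.logical(form_indicator)
    stopifnot(length(form_indicator) == n, !anyNA(form_indicator))
    clash <- form_indicator & !all_fu_missing
    if (any(clash)) {
      warning(sum(clash), " patient(s) flagged form-missing but have observed ",
              "follow-up cells; keeping the explicit indicator for their ",
              "missing cells only")
    }
  }

  form_mask <- matrix(FALSE, n, length(nms), dimnames = list(NULL, nms))
  if (any(fu)) {
    form_mask[, fu] <- form_indicator & miss[, fu, drop = FALSE]
  }
  item_mask <- miss & !form_mask

  ds <- structure(
    list(data = data, schema = schema,
         item_mask = item_mask, form_mask = form_mask,
         form_indicator = form_indicator),
    class = "masked_dataset"
  )
  validate_masked_dataset(ds)
  ds
}

validate_masked_dataset <- function(ds) {
  with(ds, {
    if (any(item_mask & form_mask)) stop("item and form masks overlap")
    miss <- vapply(data, is.na, logical(nrow(data)))
    if (nrow(data) == 1L) miss <- matrix(miss, nrow = 1L)
    if (!identical(unname(miss), unname(item_mask | form_mask))) {
      stop("mask union does not equal the missing-cell set")
    }
    non_fu <- !colnames(form_mask) %in% followup_vars(schema)
    if (any(form_mask[, non_fu, drop = FALSE])) {
      stop("form mask flags a baseline/covariate cell (forms can be missing ",
           "only at follow-up)")
    }
  })
  invisible(ds)
}

#' @export
print.masked_dataset <- function(x, ...) {
  n <- nrow(x$data)
  cat("<masked_dataset> ", n, " patients x ", ncol(x$data), " variables\n",
      sep = "")
  cat("  item-missing cells:", sum(x$item_mask),
      "| form-missing cells:", sum(x$form_mask),
      "| form-missing patients:", sum(x$form_indicator), "\n")
  invisible(x)
}

#' @export
dim.masked_dataset <- function(x) dim(x$data)

#' Load a dataset and its schema from disk
#'
#' @param data_path CSV file (UTF-8, header row). Missing cells are encoded
#'   by one of `na_strings` (empty field by default).
#' @param schema_path JSON schema sidecar (see [read_schema()]).
#' @param form_col name of an optional 0/1 column in the CSV marking
#'   form-missing patients. If the column is absent, form-missingness is
#'   inferred from an all-missing follow-up block.
#' @param na_strings values treated as missing.
#' @return a [masked_dataset].
#' @export
load_dataset <- function(data_path, schema_path,
                         form_col = ".form_missing",
                         na_strings = c("", "NA", ".")) {
  schema <- read_schema(schema_path)
  raw <- utils::read.csv(data_path, colClasses = "character",
                         na.strings = na_strings, check.names = FALSE)
  form_indicator <- NULL
  if (form_col %in% names(raw)) {
    form_indicator <- as.integer(raw[[form_col]]) == 1L
    raw[[form_col]] <- NULL
  }
  unknown <- setdiff(names(raw), schema_names(schema))
  if (length(unknown)) {
    stop("unknown column(s) in ", data_path, ": ",
         paste(unknown, collapse = ", "))
  }
  masked_dataset(raw, schema, form_indicator = form_indicator)
}

#' Write a masked dataset back to CSV (+ schema sidecar)
#'
#' Writes missing cells as empty fields and includes the explicit
#' form-missing indicator column so that [load_dataset()] round-trips the
#' mask partition exactly.
#'
#' @param ds a [masked_dataset].
#' @param data_path output CSV path.
#' @param schema_path optional output path for the JSON schema sidecar.
#' @param form_col name of the indicator column to emit.
#' @return `data_path`, invisibly.
#' @export
write_dataset <- function(ds, data_path, schema_path = NULL,
                          form_col = ".form_missing") {
  stopifnot(inherits(ds, "masked_dataset"))
  out <- ds$data
  for (j in seq_along(out)) {
    out[[j]] <- as.character(out[[j]])
  }
  out[[form_col]] <- as.integer(ds$form_indicator)
  utils::write.csv(out, data_path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(schema_path)) write_schema(ds$schema, schema_path)
  invisible(data_path)
}

#' Summarise missingness
#'
#' Per-variable missing counts and the overall split of missing cells between
#' the item-missing and form-missing partitions.
#'
#' @param ds a [masked_dataset].
#' @return a list with `per_variable` (data.frame: variable, n_missing,
#'   pct_missing, n_form, pct_from_form) and `overall` (n_item, n_form,
#'   pct_item, pct_form of all missing cells, n_form_patients).
#' @export
missingness_summary <- function(ds) {
  stopifnot(inherits(ds, "masked_dataset"))
  n <- nrow(ds$data)
  n_item <- colSums(ds$item_mask)
  n_form <- colSums(ds$form_mask)
  n_miss <- n_item + n_form
  per_variable <- data.frame(
    variable = colnames(ds$item_mask),
    n_missing = as.integer(n_miss),
    pct_missing = 100 * n_miss / n,
    n_form = as.integer(n_form),
    pct_from_form = ifelse(n_miss > 0, 100 * n_form / n_miss, 0),
    row.names = NULL
  )
  tot_item <- sum(n_item); tot_form <- sum(n_form)
  tot <- tot_item + tot_form
  overall <- list(
    n_item = tot_item, n_form = tot_form,
    pct_item = if (tot > 0) 100 * tot_item / tot else 0,
    pct_form = if (tot > 0) 100 * tot_form / tot else 0,
    n_form_patients = sum(ds$form_indicator)
  )
  list(per_variable = per_variable, overall = overall)
}
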