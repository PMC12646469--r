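# Cohort schema, delimited-text I/O, validation, active-ingredient
# binarization and descriptive summaries.

#' Canonical feature order of the modified IVF dataset
#'
#' Returns the fixed, ordered names of the 22 predictors of the modified
#' clinical dataset: supplement/lifestyle indicators, oocyte count, embryo
#' quality, dietician support and age. The order is part of the on-disk
#' contract: feature masks are index-based, so reordering columns would
#' silently change the meaning of a saved mask.
#'
#' @return Character vector of length 22 (predictors, in canonical order).
#' @seealso [cohort_outcome_name()], [table2_binary_features()]
#' @export
table2_features <- function() {
  c("working_status", "diagnosed_illness", "dha", "omega3", "folic_acid",
    "coq10", "vit_b12", "ferritin", "vit_c", "vit_b6", "vit_b5", "vit_d",
    "phytoalexin", "magnesium", "selenium", "zinc", "melatonin", "exercise",
    "oocyte_count", "embryo_quality", "dietician_support", "age")
}

#' @rdname table2_features
#' @export
table2_binary_features <- function() {
  setdiff(table2_features(), c("oocyte_count", "age"))
}

#' @rdname table2_features
#' @export
cohort_outcome_name <- function() "transfer_state"

#' Construct a validated cohort table
#'
#' A `cohort_table` is a data frame of one row per patient holding the
#' predictors in canonical order plus a binary outcome column, with the
#' feature/outcome split recorded as attributes. Binary columns must be
#' strictly 0/1; missing values are rejected rather than imputed.
#'
#' @param data data frame containing all `features` columns and the
#'   `outcome` column.
#' @param features ordered predictor names; defaults to [table2_features()].
#' @param outcome outcome column name; defaults to `"transfer_state"`.
#' @param provenance free-text note recorded on the object.
#' @param validate if `TRUE`, hard-fails on structural violations (missing
#'   cells, non-binary values in binary columns).
#' @return An object of class `cohort_table` (a data frame).
#' @export
cohort_table <- function(data, features = table2_features(),
                         outcome = cohort_outcome_name(),
                         provenance = "", validate = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(features, outcome), names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, c(features, outcome), drop = FALSE]
  rownames(data) <- NULL
  for (col in names(data)) {
    if (nrow(data) == 0L) {
      data[[col]] <- numeric(0)
    } else if (!is.numeric(data[[col]])) {
      stop("cohort validation error: non-numeric column '", col, "'",
           call. = FALSE)
    } else {
      data[[col]] <- as.numeric(data[[col]])
    }
  }
  if (validate && nrow(data) > 0L) {
    if (anyNA(data)) {
      bad <- which(is.na(data), arr.ind = TRUE)
      stop(sprintf("cohort validation error: missing value at row %d, column '%s'",
                   bad[1, 1], names(data)[bad[1, 2]]), call. = FALSE)
    }
    bin_cols <- intersect(c(table2_binary_features(), outcome), names(data))
    for (col in bin_cols) {
      v <- data[[col]]
      bad <- which(!(v %in% c(0, 1)))
      if (length(bad) > 0L) {
        stop(sprintf("cohort validation error: non-binary value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], col), call. = FALSE)
      }
    }
  }
  structure(data,
            class = c("cohort_table", "data.frame"),
            features = features, outcome = outcome,
            provenance = provenance)
}

#' @export
print.cohort_table <- function(x, ...) {
  y <- cohort_outcome(x)
  cat(sprintf("cohort_table: %d patients, %d predictors, outcome '%s' (prevalence %s)\n",
              nrow(x), length(attr(x, "features")), attr(x, "outcome"),
              if (nrow(x) > 0L) sprintf("%.3f", mean(y)) else "NA"))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subsetting returns a plain data frame: a partial view is no longer a
# schema-complete cohort
#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "features") <- NULL
    attr(out, "outcome") <- NULL
    attr(out, "provenance") <- NULL
  }
  out
}

#' Accessors for cohort tables
#'
#' @param cohort a [cohort_table()].
#' @return `cohort_features()` the ordered predictor names;
#'   `cohort_outcome()` the numeric 0/1 outcome vector;
#'   `cohort_matrix()` the numeric n x p predictor matrix.
#' @export
cohort_features <- function(cohort) attr(cohort, "features")

#' @rdname cohort_features
#' @export
cohort_outcome <- function(cohort) as.numeric(cohort[[attr(cohort, "outcome")]])

#' @rdname cohort_features
#' @export
cohort_matrix <- function(cohort) {
  as.matrix(as.data.frame(cohort)[, attr(cohort, "features"), drop = FALSE])
}

# case/space/punctuation-insensitive header normalization
normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a cohort from a CSV file
#'
#' Reads an RFC 4180 CSV with a header row, maps headers onto the schema
#' case- and punctuation-insensitively, validates binary columns, and logs
#' n, p and outcome prevalence.
#'
#' @param path CSV file path.
#' @param features,outcome schema; see [cohort_table()].
#' @param quiet suppress the log line.
#' @return A [cohort_table()]. Row order is preserved. An empty file with a
#'   valid header yields an n = 0 cohort (useful for I/O round trips only).
#' @export
read_cohort <- function(path, features = table2_features(),
                        outcome = cohort_outcome_name(), quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idx <- match(normalize_name(c(features, outcome)), normalize_name(names(raw)))
  if (anyNA(idx)) {
    stop("cohort schema error: missing column(s): ",
         paste(c(features, outcome)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  raw <- raw[, idx, drop = FALSE]
  names(raw) <- c(features, outcome)
  ct <- cohort_table(raw, features = features, outcome = outcome,
                     provenance = paste0("read from ", path))
  if (!quiet) {
    message(sprintf("read_cohort: n = %d, p = %d, outcome prevalence = %s",
                    nrow(ct), length(features),
                    if (nrow(ct) > 0L) sprintf("%.3f", mean(cohort_outcome(ct))) else "NA"))
  }
  ct
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` is the
#' identity on validated cohorts, cell-exact.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Report invariant violations in a cohort
#'
#' Report-only companion of the hard validation in [cohort_table()]:
#' checks binary domains, non-negative oocyte counts, a plausible age
#' range, and flags a single-class outcome. Never throws.
#'
#' @param cohort a [cohort_table()] (or plain data frame with the schema).
#' @param age_range inclusive plausible age bounds, default `c(18, 60)`.
#' @return data frame with columns `row`, `column`, `issue`; zero rows when
#'   clean. A degenerate single-class outcome is reported with `row = NA`.
#' @export
validate_cohort <- function(cohort, age_range = c(18, 60)) {
  viol <- list()
  add <- function(row, column, issue) {
    viol[[length(viol) + 1L]] <<- data.frame(row = row, column = column,
                                             issue = issue)
  }
  d <- as.data.frame(cohort)
  outcome <- attr(cohort, "outcome") %||% cohort_outcome_name()
  for (col in intersect(c(table2_binary_features(), outcome), names(d))) {
    bad <- which(!(d[[col]] %in% c(0, 1)))
    for (r in bad) add(r, col, sprintf("non-binary value %s", d[[col]][r]))
  }
  if ("oocyte_count" %in% names(d)) {
    for (r in which(d$oocyte_count < 0)) add(r, "oocyte_count", "negative count")
  }
  if ("age" %in% names(d)) {
    bad <- which(d$age < age_range[1] | d$age > age_range[2])
    for (r in bad) {
      add(r, "age", sprintf("age %s outside plausible range [%d, %d]",
                            d$age[r], age_range[1], age_range[2]))
    }
  }
  if (outcome %in% names(d) && nrow(d) > 0L &&
      length(unique(d[[outcome]])) < 2L) {
    add(NA_integer_, outcome, "single-class outcome")
  }
  if (length(viol) == 0L) {
    return(data.frame(row = integer(), column = character(), issue = character()))
  }
  do.call(rbind, viol)
}

#' Per-feature descriptive summary
#'
#' One row per feature plus the outcome with mean, standard deviation,
#' minimum and maximum. The SD uses the sample (n - 1) convention with a
#' guard returning 0 for n = 1. Means of binary columns equal class
#' proportions exactly.
#'
#' @param cohort a [cohort_table()] with n >= 1.
#' @return data frame with columns `feature`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("summarize_cohort: empty cohort", call. = FALSE)
  cols <- c(attr(cohort, "features"), attr(cohort, "outcome"))
  d <- as.data.frame(cohort)[, cols, drop = FALSE]
  data.frame(
    feature = cols,
    mean = vapply(d, mean, numeric(1)),
    sd = vapply(d, function(v) if (length(v) < 2L) 0 else stats::sd(v), numeric(1)),
    min = vapply(d, min, numeric(1)),
    max = vapply(d, max, numeric(1)),
    row.names = NULL
  )
}

#' Read a daily-requirement (RDI) reference table
#'
#' CSV with columns `ingredient`, `daily_requirement`, `unit`. Ingredient
#' identifiers must be unique and requirements strictly positive.
#'
#' @param path CSV file path.
#' @return data frame with the three columns above.
#' @export
read_rdi <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ingredient", "daily_requirement", "unit")
  if (!all(req %in% names(d))) {
    stop("RDI table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(duplicated(d$ingredient))) {
    stop("RDI table: duplicate ingredient identifiers", call. = FALSE)
  }
  if (any(d$daily_requirement <= 0)) {
    stop("RDI table: daily_requirement must be > 0", call. = FALSE)
  }
  d[, req]
}

#' Read raw intake records
#'
#' Long-format CSV with columns `patient_id`, `product`, `ingredient`,
#' `amount`, `unit`; one row per (patient, product, ingredient), amounts
#' are per day and non-negative.
#'
#' @param path CSV file path.
#' @return data frame with the five columns above.
#' @export
read_intakes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "product", "ingredient", "amount", "unit")
  if (!all(req %in% names(d))) {
    stop("intake table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(d$amount < 0)) stop("intake table: negative amount", call. = FALSE)
  d[, req]
}

#' Active-ingredient binarization of intake records
#'
#' Converts raw supplement/drug intake into per-ingredient binary flags: a
#' flag is 1 exactly when the patient's total daily amount of that active
#' ingredient reaches 100% of its daily requirement. Under the default
#' `sum_across_products` policy amounts are summed over all products a
#' patient takes before thresholding (so the operator is monotone: adding
#' an intake record can never clear a flag); under `per_product` a single
#' product must meet the requirement on its own.
#'
#' @param intakes data frame as returned by [read_intakes()].
#' @param rdi data frame as returned by [read_rdi()].
#' @param policy `"sum_across_products"` (default) or `"per_product"`.
#' @param patient_ids optional character vector of patients that must appear
#'   in the output even with no intake records (all-zero flags).
#' @return data frame: `patient_id` plus one 0/1 column per RDI ingredient.
#' @export
binarize_intakes <- function(intakes, rdi,
                             policy = c("sum_across_products", "per_product"),
                             patient_ids = NULL) {
  policy <- match.arg(policy)
  unknown <- setdiff(unique(intakes$ingredient), rdi$ingredient)
  if (length(unknown) > 0L) {
    warning("binarize_intakes: unknown ingredient(s) excluded: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    intakes <- intakes[intakes$ingredient %in% rdi$ingredient, , drop = FALSE]
  }
  if (nrow(intakes) > 0L) {
    m <- match(intakes$ingredient, rdi$ingredient)
    mismatch <- which(intakes$unit != rdi$unit[m])
    if (length(mismatch) > 0L) {
      stop("binarize_intakes: unit mismatch for ingredient '",
           intakes$ingredient[mismatch[1]], "' (got '",
           intakes$unit[mismatch[1]], "', RDI uses '",
           rdi$unit[m[mismatch[1]]], "')", call. = FALSE)
    }
  }
  pts <- union(patient_ids, unique(intakes$patient_id))
  flags <- matrix(0L, nrow = length(pts), ncol = nrow(rdi),
                  dimnames = list(NULL, rdi$ingredient))
  if (nrow(intakes) > 0L) {
    for (i in seq_along(rdi$ingredient)) {
      ing <- rdi$ingredient[i]
      sub <- intakes[intakes$ingredient == ing, , drop = FALSE]
      if (nrow(sub) == 0L) next
      if (policy == "sum_across_products") {
        tot <- tapply(sub$amount, sub$patient_id, sum)
      } else {
        per <- tapply(sub$amount, list(sub$patient_id, sub$product), sum)
        tot <- apply(per, 1, max, na.rm = TRUE)
      }
      hit <- names(tot)[tot >= rdi$daily_requirement[i]]
      flags[match(hit, pts), i] <- 1L
    }
  }
  cbind(data.frame(patient_id = pts, stringsAsFactors = FALSE),
        as.data.frame(flags))
}
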