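# Fixed design-matrix term order shared by every model in the package.
.term_names <- c(
  "log2psa_std", "age_std", "dre", "african", "famhx", "priorneg",
  "log2psa_std:dre", "age_std:dre", "age_std:african"
)

.binary_factors <- c("dre", "african", "famhx", "priorneg")
.required_cols <- c("cohort", "outcome", "psa", "age", .binary_factors)

#' Coerce a data frame to a cohort table
#'
#' A cohort table is the package's universal patient-level input: one row per
#' biopsy with a cohort label, a binary high-grade outcome, PSA (ng/ml), age
#' (years) and four binary risk factors (abnormal DRE, African ancestry,
#' first-degree family history, prior negative biopsy). Missing values are
#' allowed in the four binary factors; `psa` and `age` must be positive where
#' present.
#'
#' @param x data frame with columns `cohort`, `outcome`, `psa`, `age`, `dre`,
#'   `african`, `famhx`, `priorneg`; an optional `patient_id` column is carried
#'   through but never used for clustering.
#' @return `x` with class `cohort_table`.
#' @export
as_cohort_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.required_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$cohort <- as.character(x$cohort)
  for (col in c("outcome", "psa", "age", .binary_factors)) {
    x[[col]] <- as.numeric(x[[col]])
  }
  bad_outcome <- !is.na(x$outcome) & !x$outcome %in% c(0, 1)
  if (any(bad_outcome)) {
    stop("outcome must be 0/1; found other values in ",
         sum(bad_outcome), " row(s)", call. = FALSE)
  }
  for (col in .binary_factors) {
    bad <- !is.na(x[[col]]) & !x[[col]] %in% c(0, 1)
    if (any(bad)) stop("column '", col, "' must be 0/1 or missing", call. = FALSE)
  }
  class(x) <- unique(c("cohort_table", class(x)))
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", nrow(x), " rows, ",
      length(unique(x$cohort)), " cohorts\n", sep = "")
  prev <- tapply(x$outcome, x$cohort, mean, na.rm = TRUE)
  cat("  outcome prevalence by cohort:\n")
  print(round(prev, 3))
  invisible(x)
}

# Parse one raw column of 0/1/true/false/yes/no (case-insensitive) entries;
# anything unparseable (incl. "NA", "") becomes missing.
.parse_binary <- function(v) {
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA_real_, length(v))
  out[v %in% c("1", "true", "yes")] <- 1
  out[v %in% c("0", "false", "no")] <- 0
  out
}

#' Read a multi-cohort patient CSV
#'
#' Reads a comma-separated, header-bearing patient table and types its columns.
#' Binary risk-factor entries accept `0/1`, `true/false`, `yes/no`
#' (case-insensitive); unparseable or empty entries become missing values and
#' the row is retained. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   (`cohort`, `outcome`, `psa`, ...) to the file's column names, e.g.
#'   `c(cohort = "site", psa = "psa_ng_ml")`.
#' @return a [as_cohort_table()] cohort table.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column '", src, "' (mapped to '", canon, "') not found in ",
             path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(cohort = raw$cohort, stringsAsFactors = FALSE)
  for (col in c("outcome", "psa", "age")) {
    tab[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  for (col in .binary_factors) tab[[col]] <- .parse_binary(raw[[col]])
  if ("patient_id" %in% names(raw)) tab$patient_id <- raw$patient_id
  as_cohort_table(tab)
}

#' Write a cohort table to CSV
#'
#' @param x a cohort table.
#' @param path output path.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Exclude records unusable for model fitting
#'
#' Removes rows with missing age, missing or non-positive PSA, or missing
#' outcome. Binary risk factors are left untouched (they are reference-value
#' imputed later, see [impute_binary_missing()]). The returned report counts
#' removals by reason; a row triggering several reasons is counted under each.
#'
#' @param x a cohort table.
#' @return list with elements `table` (the filtered cohort table) and `report`
#'   (named integer vector of exclusion counts).
#' @export
apply_exclusions <- function(x) {
  x <- as_cohort_table(x)
  reasons <- list(
    missing_age     = is.na(x$age),
    missing_psa     = is.na(x$psa),
    nonpositive_psa = !is.na(x$psa) & x$psa <= 0,
    missing_outcome = is.na(x$outcome)
  )
  drop <- Reduce(`|`, reasons)
  report <- vapply(reasons, sum, integer(1))
  report <- report[report > 0L]
  kept <- x[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all rows excluded; no analyzable records", call. = FALSE)
  rownames(kept) <- NULL
  list(table = as_cohort_table(kept), report = report)
}

#' Impute reference values for missing binary risk factors
#'
#' Missing entries in the four binary factors are set to the low-risk
#' reference category: non-African ancestry, normal DRE, no family history,
#' no prior negative biopsy. Non-missing entries are untouched.
#'
#' @param x a cohort table with exclusions already applied.
#' @return the cohort table with no missing values in the binary factors.
#' @export
impute_binary_missing <- function(x) {
  x <- as_cohort_table(x)
  for (col in .binary_factors) x[[col]][is.na(x[[col]])] <- 0
  x
}

#' Estimate standardization constants
#'
#' PSA enters all models on the log-base-2 scale, standardized by subtracting
#' the mean and dividing by the standard deviation; age is standardized the
#' same way. The constants are frozen from whichever rows are supplied so that
#' test-set predictions reuse the training constants: inside cross-validation
#' fit them on the training split only (`source = "training_only"`); for a
#' final model on all pooled data use `source = "all_data"`.
#'
#' @param x a cohort table (exclusions applied; psa and age complete).
#' @param source provenance tag recorded on the result.
#' @return object of class `preproc_params`.
#' @export
fit_preprocessing <- function(x, source = c("training_only", "all_data")) {
  source <- match.arg(source)
  x <- as_cohort_table(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  if (anyNA(x$psa) || anyNA(x$age)) {
    stop("psa/age missing; apply exclusions first", call. = FALSE)
  }
  lp <- log2(x$psa)
  p <- structure(list(
    psa_log2_mean = mean(lp), psa_log2_sd = stats::sd(lp),
    age_mean = mean(x$age), age_sd = stats::sd(x$age),
    source = source
  ), class = "preproc_params")
  if (p$psa_log2_sd == 0) stop("log2(psa) has zero variance", call. = FALSE)
  if (p$age_sd == 0) stop("age has zero variance", call. = FALSE)
  p
}

#' @export
print.preproc_params <- function(x, ...) {
  cat(sprintf(
    "Standardization constants (%s):\n  log2(PSA): mean %.4f, sd %.4f\n  age:       mean %.2f, sd %.2f\n",
    x$source, x$psa_log2_mean, x$psa_log2_sd, x$age_mean, x$age_sd))
  invisible(x)
}

#' Build the fixed 9-term design matrix
#'
#' Encodes a fully imputed cohort table into the covariate matrix used by every
#' model: standardized log2 PSA, standardized age, the four binary factors, and
#' the interactions log2PSA:DRE, age:DRE and age:African ancestry, in that
#' fixed order. Standardization always uses the supplied constants, never the
#' table's own moments.
#'
#' @param x a cohort table with no missing values.
#' @param params a [fit_preprocessing()] result.
#' @return object of class `design_matrix`: list with `x` (n x 9 matrix),
#'   `outcome` and `cohort` vectors.
#' @export
build_design_matrix <- function(x, params) {
  x <- as_cohort_table(x)
  stopifnot(inherits(params, "preproc_params"))
  if (anyNA(x[, c("psa", "age", "outcome", .binary_factors)])) {
    stop("design matrix requires a fully imputed table; ",
         "run apply_exclusions() and impute_binary_missing() first",
         call. = FALSE)
  }
  z_psa <- (log2(x$psa) - params$psa_log2_mean) / params$psa_log2_sd
  z_age <- (x$age - params$age_mean) / params$age_sd
  m <- cbind(
    z_psa, z_age, x$dre, x$african, x$famhx, x$priorneg,
    z_psa * x$dre, z_age * x$dre, z_age * x$african
  )
  colnames(m) <- .term_names
  structure(list(x = m, outcome = x$outcome, cohort = x$cohort,
                 preprocessing = params),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix: ", nrow(x$x), " rows x ", ncol(x$x), " terms, ",
      length(unique(x$cohort)), " cohorts\n", sep = "")
  invisible(x)
}
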