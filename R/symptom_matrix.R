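#' Construct a symptom matrix
#'
#' A `symptom_matrix` is an integer patients-by-symptoms matrix of binary
#' lifetime indicators (1 = symptom ever present, 0 = absent) with unique
#' column names and an optional cohort label (e.g. `"young"`, `"adult"`).
#' It is the input container for the whole analysis pipeline.
#'
#' @param values matrix or data.frame coercible to a numeric matrix whose
#'   cells are all exactly 0 or 1.
#' @param variable_names optional character vector of column labels;
#'   defaults to the column names of `values`.
#' @param cohort_label free-text cohort tag carried through to reports.
#' @return an object of class `symptom_matrix` (an integer matrix with
#'   attributes `cohort_label`).
#' @examples
#' m <- symptom_matrix(cbind(a = c(0, 1, 1), b = c(1, 1, 0)))
#' prevalence_summary(m)
#' @export
symptom_matrix <- function(values, variable_names = NULL, cohort_label = "") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix or data.frame")
  if (is.null(variable_names)) variable_names <- colnames(values)
  if (is.null(variable_names)) {
    stop("variable names are required (column names or `variable_names`)")
  }
  variable_names <- as.character(variable_names)
  if (length(variable_names) != ncol(values)) {
    stop("`variable_names` length does not match the number of columns")
  }
  if (anyDuplicated(variable_names)) {
    dups <- unique(variable_names[duplicated(variable_names)])
    stop("duplicate variable names: ", paste(dups, collapse = ", "))
  }
  if (any(!nzchar(variable_names))) stop("variable names must be nonempty")
  storage <- suppressWarnings(as.numeric(values))
  if (anyNA(storage)) {
    bad <- which(is.na(matrix(storage, nrow(values))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1], variable_names[bad[2]]))
  }
  if (any(storage != 0 & storage != 1)) {
    bad <- which(matrix(storage != 0 & storage != 1, nrow(values)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell at row %d, column '%s' (value %s)",
                 bad[1], variable_names[bad[2]],
                 format(values[bad[1], bad[2]])))
  }
  if (nrow(values) < 2) stop("a symptom matrix needs at least 2 patients")
  if (ncol(values) < 2) stop("a symptom matrix needs at least 2 variables")
  out <- matrix(as.integer(storage), nrow(values), ncol(values),
                dimnames = list(NULL, variable_names))
  structure(out, cohort_label = as.character(cohort_label)[1],
            class = c("symptom_matrix", class(out)))
}

#' @export
print.symptom_matrix <- function(x, ...) {
  lab <- attr(x, "cohort_label")
  cat(sprintf("symptom_matrix: %d patients x %d variables%s\n",
              nrow(x), ncol(x),
              if (nzchar(lab)) paste0(" (cohort: ", lab, ")") else ""))
  prev <- colMeans(x)
  cat("prevalence range:",
      sprintf("%.1f%%", 100 * min(prev)), "-",
      sprintf("%.1f%%", 100 * max(prev)), "\n")
  invisible(x)
}

#' Read a symptom matrix from delimited text
#'
#' Reads a patients-by-symptoms table with a header row of variable names
#' and one row per patient. Cells must be 0/1 (`TRUE`/`FALSE` are accepted
#' and mapped to 1/0); anything else, including blanks, is a parse error —
#' missing values are not supported because the mutual-information
#' estimator assumes complete 2x2 tables.
#'
#' @param path file path.
#' @param sep field delimiter; tab by default, use `","` for CSV.
#' @param cohort_label cohort tag attached to the result.
#' @return a [symptom_matrix].
#' @seealso [write_symptom_matrix()]
#' @export
read_symptom_matrix <- function(path, sep = "\t", cohort_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          fileEncoding = "UTF-8", comment.char = "")
  if (nrow(df) == 0) stop("empty body: no patient rows in ", path)
  vals <- as.matrix(df)
  vals[vals %in% c("TRUE", "true")] <- "1"
  vals[vals %in% c("FALSE", "false")] <- "0"
  ok <- vals == "0" | vals == "1"
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell at data row %d, column '%s' (value '%s')",
                 bad[1], colnames(df)[bad[2]], vals[bad[1], bad[2]]))
  }
  storage.mode(vals) <- "integer"
  symptom_matrix(vals, colnames(df), cohort_label = cohort_label)
}

#' Write a symptom matrix to delimited text
#'
#' @param m a [symptom_matrix].
#' @param path output file path.
#' @param sep field delimiter (tab default).
#' @return `path`, invisibly.
#' @export
write_symptom_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "symptom_matrix"))
  utils::write.table(m, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-variable lifetime prevalence
#'
#' Counts and percentages of patients with each symptom present, formatted
#' the way clinical prevalence tables print them (percent rounded half-up
#' to one decimal).
#'
#' @param m a [symptom_matrix].
#' @return data.frame with columns `variable`, `n` (count present) and
#'   `percent` (one decimal).
#' @export
prevalence_summary <- function(m) {
  stopifnot(inherits(m, "symptom_matrix"))
  counts <- colSums(m)
  data.frame(
    variable = colnames(m),
    n = as.integer(counts),
    percent = round_half_up(100 * counts / nrow(m), 1),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Drop near-degenerate variables before network inference
#'
#' A variable whose minority class (the smaller of its ones-count and
#' zeros-count) falls below `min_minority_count` carries essentially no
#' entropy and cannot form informative edges; such variables — e.g. a
#' symptom present in all but one patient — are removed before analysis.
#' The default threshold of 2 drops constant and single-exception columns
#' while retaining rare-but-observed symptoms (minority count >= 3, such
#' as a disorder reported by only 3 patients in a cohort of 529).
#'
#' @param m a [symptom_matrix].
#' @param min_minority_count smallest admissible minority-class count
#'   (>= 1); a variable is dropped when its minority count is strictly
#'   below this.
#' @return a list with `matrix` (the filtered [symptom_matrix], column
#'   order preserved) and `exclusions` (data.frame `variable`, `reason`
#'   with reasons `all-present`, `all-absent` or `below-min-variability`).
#' @export
exclude_degenerate <- function(m, min_minority_count = 2) {
  stopifnot(inherits(m, "symptom_matrix"))
  if (min_minority_count < 1) stop("`min_minority_count` must be >= 1")
  ones <- colSums(m)
  zeros <- nrow(m) - ones
  minority <- pmin(ones, zeros)
  drop <- minority < min_minority_count
  reason <- ifelse(zeros == 0, "all-present",
                   ifelse(ones == 0, "all-absent", "below-min-variability"))
  exclusions <- data.frame(
    variable = colnames(m)[drop],
    reason = reason[drop],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (all(drop)) stop("all variables are degenerate; nothing to analyze")
  kept <- m[, !drop, drop = FALSE]
  out <- symptom_matrix(kept, colnames(m)[!drop],
                        cohort_label = attr(m, "cohort_label"))
  list(matrix = out, exclusions = exclusions)
}
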