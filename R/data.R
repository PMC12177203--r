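# Paired-outcome dataset container and delimited-text reader.

#' Paired-outcome dataset
#'
#' Bundles \eqn{n} observations of two positive outcome components
#' \eqn{(u_i, v_i)} with a numeric covariate matrix, validating positivity
#' and completeness.  The derived ratios \eqn{r_i = u_i / v_i} are stored
#' alongside.  Rows with missing entries are not repaired here; use
#' [read_paired_csv()] for complete-case filtering with a per-row log.
#'
#' @param u,v Positive numeric vectors of equal length.
#' @param covariates Numeric matrix (or data frame of numeric columns) with
#'   one row per observation; may have zero columns.  Binary covariates must
#'   be coded 0/1.
#' @return An object of class `"paired_dataset"` with elements `u`, `v`,
#'   `x` (matrix) and `ratio`.
#' @export
paired_dataset <- function(u, v, covariates = NULL) {
  u <- as.numeric(u); v <- as.numeric(v)
  n <- length(u)
  if (length(v) != n) stop("'u' and 'v' must have equal length")
  if (n == 0L) stop("empty dataset")
  if (anyNA(u) || anyNA(v)) stop("'u' and 'v' must not contain missing values")
  if (any(u <= 0) || any(v <= 0)) stop("'u' and 'v' must be strictly positive")
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  rownames(x) <- NULL
  if (nrow(x) != n) stop("'covariates' must have one row per observation")
  if (anyNA(x) || any(!is.finite(x))) stop("covariates must be finite and complete")
  if (is.null(colnames(x)) && ncol(x) > 0L)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(u = u, v = v, x = x, ratio = u / v),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("Paired dataset: %d observations, %d covariate(s)%s\n",
              length(x$u), ncol(x$x),
              if (ncol(x$x)) paste0(" [", paste(colnames(x$x), collapse = ", "), "]")
              else ""))
  cat(sprintf("  ratio range: [%.4g, %.4g], median %.4g\n",
              min(x$ratio), max(x$ratio), stats::median(x$ratio)))
  invisible(x)
}

#' @export
length.paired_dataset <- function(x) length(x$u)

#' @export
as.data.frame.paired_dataset <- function(x, ...) {
  data.frame(u = x$u, v = x$v, x$x, check.names = FALSE)
}

#' Read a paired-outcome dataset from a delimited text file
#'
#' Loads a CSV (comma-separated, header required, '.' decimal) and performs
#' complete-case validation: rows with missing values in any used column or
#' with nonpositive outcome values are excluded, each with a logged reason,
#' mirroring the complete-case handling typical of biomarker cohort
#' analyses.
#'
#' @param path Path to the CSV file.
#' @param u_col,v_col Names of the two outcome columns.
#' @param covariate_cols Character vector of covariate column names (may be
#'   empty).
#' @param quiet If `TRUE`, suppress the per-row exclusion messages.
#' @return A [paired_dataset()].  The number of excluded rows is attached as
#'   attribute `"n_excluded"`.
#' @export
read_paired_csv <- function(path, u_col, v_col, covariate_cols = character(),
                            quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  cols <- c(u_col, v_col, covariate_cols)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  for (cc in cols) {
    if (!is.numeric(df[[cc]]))
      stop("column '", cc, "' is not numeric in ", path)
  }
  keep <- rep(TRUE, nrow(df))
  reason <- character(nrow(df))
  bad_na <- !stats::complete.cases(df[cols])
  reason[bad_na] <- "missing value"
  bad_pos <- !bad_na & (df[[u_col]] <= 0 | df[[v_col]] <= 0)
  reason[bad_pos] <- "nonpositive outcome"
  keep <- !(bad_na | bad_pos)
  if (!quiet && any(!keep)) {
    for (i in which(!keep))
      message("excluding row ", i, ": ", reason[i])
    message(sum(!keep), " row(s) excluded, ", sum(keep), " retained")
  }
  if (!any(keep)) stop("no usable rows in ", path)
  x <- if (length(covariate_cols))
    as.matrix(df[keep, covariate_cols, drop = FALSE]) else NULL
  out <- paired_dataset(df[[u_col]][keep], df[[v_col]][keep], x)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Write a paired-outcome dataset as CSV
#'
#' @param data A [paired_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(data, path) {
  stopifnot(inherits(data, "paired_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
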