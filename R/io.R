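# Plain-text file formats: tab-delimited expression matrices (rows =
# samples, columns = kinases) and comma-delimited clinical tables.

#' Write / read an expression matrix as TSV
#'
#' The dialect is a tab-delimited table with a leading `sample_id` column and
#' one column per kinase.  Write-then-read reproduces values to full
#' precision and preserves column order.
#'
#' @param matrix an [expression_matrix()].
#' @param path output file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(matrix, path) {
  matrix <- as_expression_matrix(matrix)
  vals <- matrix$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(vals)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param cohort cohort tag attached to the matrix on read.
#' @param normalized whether the stored values are already z-scored.
#' @export
read_expression_tsv <- function(path, cohort = "cohort1", normalized = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample IDs in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cells in ", path)
  rownames(vals) <- df$sample_id
  expression_matrix(vals, cohort = cohort, normalized = normalized)
}

clinical_required_cols <- c("sample_id", "os_months", "os_event")

#' Write / read a clinical table as CSV
#'
#' The clinical dialect carries `sample_id`, `cohort`, demographic and
#' treatment columns, and the outcome pair `os_months` (> 0) / `os_event`
#' (0/1, 1 = death observed).  The reader validates required columns and
#' outcome coding and coerces character covariates to factors on demand.
#'
#' @param clinical data.frame (or `PatientCohort`, whose clinical table is
#'   used).
#' @param path file path.
#' @return `write_clinical_csv` returns `path` invisibly;
#'   `read_clinical_csv` returns a data.frame.
#' @export
write_clinical_csv <- function(clinical, path) {
  if (inherits(clinical, "PatientCohort")) clinical <- clinical$clinical
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(clinical_required_cols, names(d))
  if (length(miss)) {
    stop("clinical table missing required columns: ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    dup <- unique(d$sample_id[duplicated(d$sample_id)])
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  }
  if (any(!is.na(d$os_months) & d$os_months <= 0)) {
    stop("os_months must be > 0")
  }
  if (!all(na.omit(d$os_event) %in% c(0, 1))) {
    stop("os_event must be coded 0/1")
  }
  d
}

#' Write subgroup calls as CSV
#' @param calls a `SubgroupCalls` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  write.csv(as.data.frame(calls)[, c("sample_id", "label", "vote_fraction",
                                     "confident")],
            path, row.names = FALSE)
  invisible(path)
}
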