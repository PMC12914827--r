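#' Construct an ExpressionMatrix
#'
#' A samples-by-features abundance table with sample IDs, kinase feature
#' names, a cohort tag and an explicit missing-value mask (`NA` entries in
#' `values`).  This is the common currency of the harmonisation, ensemble and
#' selection stages.
#'
#' @param values numeric matrix, samples in rows, kinase features in columns.
#'   Row and column names are taken as sample IDs and feature names; `NA`
#'   entries are treated as missing.
#' @param cohort single character cohort tag.
#' @param normalized logical; whether `values` are already z-scored.
#' @return object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cohort = "cohort1", normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate feature names: ", paste(dup, collapse = ", "))
  }
  structure(
    list(values = values, cohort = as.character(cohort)[1],
         normalized = isTRUE(normalized),
         zero_variance = character(0)),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d samples x %d features (cohort '%s')\n",
              nrow(x$values), ncol(x$values), x$cohort))
  cat(sprintf("  normalized: %s; missing entries: %d\n",
              x$normalized, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
feature_names <- function(x) colnames(x$values)

as_expression_matrix <- function(x, ...) {
  if (inherits(x, "ExpressionMatrix")) x else expression_matrix(as.matrix(x), ...)
}
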