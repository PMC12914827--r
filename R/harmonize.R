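# Cross-platform harmonisation: feature subsetting, minimum-value imputation,
# per-cohort z-scoring, and a pooled-PCA cohort-outlier diagnostic.

#' Restrict an expression matrix to a required feature panel
#'
#' @param matrix an [expression_matrix()].
#' @param required_features character vector of feature names; the result
#'   keeps them in this order.
#' @return the restricted `ExpressionMatrix`.  Errors if any required feature
#'   is absent, naming the missing features (this is the mechanism by which a
#'   40-kinase panel shrinks to the features a platform actually measures).
#' @export
select_features <- function(matrix, required_features) {
  matrix <- as_expression_matrix(matrix)
  missing <- setdiff(required_features, feature_names(matrix))
  if (length(missing)) {
    stop("required features absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  matrix$values <- matrix$values[, required_features, drop = FALSE]
  matrix$zero_variance <- intersect(matrix$zero_variance, required_features)
  matrix
}

#' Minimum-value imputation of missing abundances
#'
#' Replaces each missing entry with the observed minimum of its feature
#' within the cohort — the convention of the proteomic source studies, where
#' missingness is concentrated at the low-abundance end.
#'
#' @param matrix an [expression_matrix()] with `NA` holes.
#' @return the matrix with no missing values; attribute `n_imputed` records
#'   how many entries were filled.  Errors if a feature has no observed value.
#' @export
impute_minimum <- function(matrix) {
  matrix <- as_expression_matrix(matrix)
  v <- matrix$values
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("features entirely missing, cannot impute: ",
         paste(colnames(v)[all_missing], collapse = ", "))
  }
  n_imp <- sum(is.na(v))
  if (n_imp > 0) {
    mins <- apply(v, 2, min, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mins[idx[, 2]]
    matrix$values <- v
  }
  attr(matrix, "n_imputed") <- n_imp
  matrix
}

#' Per-cohort z-score normalisation
#'
#' Centres every feature to mean 0 and scales to SD 1 using the population
#' SD (ddof = 0).  Zero-variance features are mapped to all-zero and recorded
#' in the `zero_variance` field rather than dropped, so the feature count of
#' a signature stays fixed.  Already-normalized input passes through with a
#' warning (idempotent).
#'
#' @param matrix an [expression_matrix()] with no missing values
#'   (run [impute_minimum()] first).
#' @return normalized `ExpressionMatrix` with the `normalized` flag set.
#' @export
zscore_normalize <- function(matrix) {
  matrix <- as_expression_matrix(matrix)
  if (anyNA(matrix$values)) {
    stop("matrix contains missing values; impute before normalising")
  }
  if (isTRUE(matrix$normalized)) {
    warning("matrix already normalized; returning input unchanged")
    return(matrix)
  }
  v <- matrix$values
  n <- nrow(v)
  mu <- colMeans(v)
  sdev <- sqrt(colMeans(v^2) - mu^2)  # population SD, ddof = 0
  zero_var <- sdev < 1e-12
  sdev[zero_var] <- 1
  v <- sweep(sweep(v, 2, mu, "-"), 2, sdev, "/")
  v[, zero_var] <- 0
  matrix$values <- v
  matrix$normalized <- TRUE
  matrix$zero_variance <- colnames(v)[zero_var]
  matrix
}

#' PCA cohort-outlier diagnostic on pooled normalized cohorts
#'
#' Pools normalized cohorts sharing one feature set, computes principal
#' components, and reports per-sample 2-D coordinates plus the fraction of
#' PC1 variance explained by cohort membership (between-cohort sum of squares
#' over total).  A small fraction indicates no outlier cohort after
#' z-scoring.
#'
#' @param matrices list of normalized [expression_matrix()] objects with
#'   identical feature sets.
#' @return list with `coordinates` (data.frame: sample_id, cohort, pc1, pc2),
#'   `cohort_variance_fraction_pc1`, `variance_explained` (per component),
#'   and `cohort_dispersion` (per-cohort SD of PC1/PC2 scores).
#' @export
pca_cohort_check <- function(matrices) {
  if (inherits(matrices, "ExpressionMatrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  feats <- feature_names(matrices[[1]])
  for (m in matrices) {
    if (!identical(sort(feature_names(m)), sort(feats))) {
      stop("feature sets differ across cohorts")
    }
  }
  pooled <- do.call(rbind, lapply(matrices, function(m) {
    m$values[, feats, drop = FALSE]
  }))
  cohort <- unlist(lapply(matrices, function(m) {
    rep(m$cohort, nrow(m$values))
  }))
  if (nrow(pooled) < 2) stop("need at least two samples in total")

  pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  pc1 <- scores[, 1]
  grand <- mean(pc1)
  ss_tot <- sum((pc1 - grand)^2)
  ss_between <- sum(tapply(pc1, cohort, function(z) {
    length(z) * (mean(z) - grand)^2
  }))
  frac <- if (ss_tot > 0) ss_between / ss_tot else 0

  coords <- data.frame(
    sample_id = rownames(pooled), cohort = cohort,
    pc1 = pc1, pc2 = if (k >= 2) scores[, 2] else 0,
    stringsAsFactors = FALSE)
  dispersion <- do.call(rbind, lapply(split(coords, coords$cohort), function(d) {
    data.frame(cohort = d$cohort[1], n = nrow(d),
               sd_pc1 = sd(d$pc1), sd_pc2 = sd(d$pc2))
  }))
  rownames(dispersion) <- NULL
  list(coordinates = coords,
       cohort_variance_fraction_pc1 = unname(frac),
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       cohort_dispersion = dispersion)
}
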