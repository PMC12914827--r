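# 500-member bootstrap random-forest ensemble with majority-vote subgroup
# calls and averaged impurity importance.

label_levels <- c("EMT", "metabolism")

panel_expr_labels <- function(panel) {
  if (inherits(panel, "CellLinePanel")) {
    list(expr = panel$expr, labels = panel$labels, line_id = panel$line_id)
  } else if (is.list(panel) && !is.null(panel$expr) && !is.null(panel$labels)) {
    list(expr = as_expression_matrix(panel$expr),
         labels = factor(panel$labels, levels = label_levels),
         line_id = panel$line_id %||% sample_ids(as_expression_matrix(panel$expr)))
  } else {
    stop("expected a CellLinePanel or a list with `expr` and `labels`")
  }
}

#' Split a labelled panel into training and validation portions
#'
#' The validation portion holds `ceiling((1 - ratio) * n)` samples (9 of 42
#' at the default 8:2 ratio).  The default split is at sample level, so
#' replicates of one cell line may straddle the split; `group_by_line = TRUE`
#' assigns whole lines to one side to avoid that leakage.
#'
#' @param panel a `CellLinePanel`.
#' @param ratio training fraction (default 0.8).
#' @param seed integer RNG seed; the same seed reproduces the partition.
#' @param stratify logical; balance the two class labels across portions.
#' @param group_by_line logical; split by cell line instead of by sample.
#' @return list with `train` and `validation`, each a `CellLinePanel`
#'   restricted to its samples.
#' @export
split_train_validation <- function(panel, ratio = 0.8, seed = 1L,
                                   stratify = FALSE, group_by_line = FALSE) {
  pl <- panel_expr_labels(panel)
  n <- nrow(pl$expr$values)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_val <- ceiling((1 - ratio) * n)

  idx_val <- with_seed(seed, {
    if (group_by_line) {
      lines <- unique(pl$line_id)
      n_val_lines <- ceiling((1 - ratio) * length(lines))
      val_lines <- sample(lines, n_val_lines)
      which(pl$line_id %in% val_lines)
    } else if (stratify) {
      idx_by_class <- split(seq_len(n), pl$labels)
      alloc <- vapply(idx_by_class, function(ii) {
        round(n_val * length(ii) / n)
      }, numeric(1))
      # fix rounding so the total matches
      while (sum(alloc) > n_val) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
      while (sum(alloc) < n_val) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1
      sort(unlist(mapply(function(ii, k) sample(ii, k),
                         idx_by_class, alloc, SIMPLIFY = FALSE)))
    } else {
      sort(sample(n, n_val))
    }
  })
  idx_train <- setdiff(seq_len(n), idx_val)
  if (length(unique(pl$labels[idx_train])) < 2) {
    stop("a class is absent from the training portion")
  }
  subset_panel <- function(idx) {
    expr <- pl$expr
    expr$values <- expr$values[idx, , drop = FALSE]
    out <- if (inherits(panel, "CellLinePanel")) panel else pl
    out$expr <- expr
    out$labels <- droplevels(factor(pl$labels[idx], levels = label_levels))
    out$labels <- factor(out$labels, levels = label_levels)
    out$line_id <- pl$line_id[idx]
    if (!is.null(out$replicate)) out$replicate <- out$replicate[idx]
    class(out) <- "CellLinePanel"
    out
  }
  list(train = subset_panel(idx_train), validation = subset_panel(idx_val))
}

#' Train the bootstrap random-forest voting ensemble
#'
#' Each of `n_members` members is a random forest of `n_trees` CART trees
#' trained on a bootstrap resample of the training set (same size, with
#' replacement) drawn with the member's own recorded seed.  Feature
#' importance is the impurity-based (mean-decrease-in-Gini) score of each
#' member, normalised to sum 1, averaged over members.
#'
#' @param train a `CellLinePanel` (or list with `expr`, `labels`).  If the
#'   expression matrix is not flagged normalized it is z-scored first.
#' @param n_members number of ensemble members (default 500).
#' @param seed base seed; member seeds are derived deterministically from it.
#' @param n_trees trees per member (default 100).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param vote_threshold confidence threshold on the winning-class vote
#'   fraction (default 0.6, i.e. the ">60%" majority rule).
#' @param member_bootstrap logical; resample the training set per member
#'   (default TRUE).  FALSE trains every member on the full training set, so
#'   members differ only through tree-level randomness.
#' @return an `EnsembleModel`.
#' @export
train_ensemble <- function(train, n_members = 500L, seed = 1L,
                           n_trees = 100L, mtry = NULL,
                           vote_threshold = 0.6, member_bootstrap = TRUE) {
  pl <- panel_expr_labels(train)
  expr <- pl$expr
  if (!expr$normalized) expr <- zscore_normalize(expr)
  y <- pl$labels
  if (any(is.na(y))) stop("labels contain NA")
  if (length(unique(y)) < 2) stop("training data contain a single class")
  p <- ncol(expr$values)
  if (p < 1) stop("empty feature set")
  n_members <- as.integer(n_members)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))

  member_seeds <- vapply(seq_len(n_members), function(m) {
    derive_seed(seed, 7L, m)
  }, integer(1))
  fit <- .rf_train_cpp(expr$values, as.integer(y == "metabolism"),
                       n_members, as.integer(n_trees), as.integer(mtry),
                       as.numeric(member_seeds), isTRUE(member_bootstrap))
  imp <- fit$importance
  colnames(imp) <- colnames(expr$values)
  importance <- data.frame(
    feature = colnames(expr$values),
    importance = colMeans(imp),
    importance_sd = apply(imp, 2, sd),
    stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance, importance$feature), ]
  rownames(importance) <- NULL

  structure(
    list(forest = fit, feature_names = colnames(expr$values),
         member_seeds = member_seeds, n_members = n_members,
         n_trees = as.integer(n_trees), mtry = as.integer(mtry),
         vote_threshold = vote_threshold,
         member_bootstrap = isTRUE(member_bootstrap),
         importance = importance,
         metadata = list(base_seed = seed, criterion = "gini",
                         min_samples_split = 2L, max_depth = Inf,
                         bootstrap_scheme = "member+tree bootstrap, full size")),
    class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf("EnsembleModel: %d members x %d trees, %d features, vote threshold %.2f\n",
              x$n_members, x$n_trees, length(x$feature_names), x$vote_threshold))
  cat("Top features by averaged importance:\n")
  print(head(x$importance, 5))
  invisible(x)
}

#' Majority-vote subgroup calls for new samples
#'
#' Every ensemble member casts one vote (the majority class of its trees);
#' a sample's label is the class with more member votes and `vote_fraction`
#' is the winning-class share.  Exact 50/50 ties are broken to `EMT` and
#' flagged non-confident.  A call is `confident` iff its vote fraction
#' strictly exceeds the model's threshold (default 0.6).
#'
#' @param model an `EnsembleModel`.
#' @param matrix a normalized [expression_matrix()] whose features include
#'   the model's features (order is handled internally).
#' @param strict logical; if TRUE, unnormalized input is an error instead of
#'   a warning.
#' @return a `SubgroupCalls` data.frame: `sample_id`, `label`,
#'   `vote_fraction`, `confident`, plus `vote_fraction_met` (metabolism-class
#'   share, the score used for AUC).
#' @export
predict_subgroup <- function(model, matrix, strict = FALSE) {
  stopifnot(inherits(model, "EnsembleModel"))
  matrix <- as_expression_matrix(matrix)
  missing <- setdiff(model$feature_names, feature_names(matrix))
  if (length(missing)) {
    stop("matrix lacks model features: ", paste(missing, collapse = ", "))
  }
  if (!matrix$normalized) {
    msg <- "input matrix is not flagged normalized; z-score it before prediction"
    if (strict) stop(msg) else warning(msg)
  }
  X <- matrix$values[, model$feature_names, drop = FALSE]
  votes <- .rf_member_votes_cpp(model$forest, X)
  frac_met <- rowMeans(votes)
  label <- ifelse(frac_met > 0.5, "metabolism", "EMT")  # tie -> EMT
  vote_fraction <- pmax(frac_met, 1 - frac_met)
  vote_fraction[frac_met == 0.5] <- 0.5
  confident <- vote_fraction > model$vote_threshold & frac_met != 0.5
  out <- data.frame(
    sample_id = rownames(X),
    label = factor(label, levels = label_levels),
    vote_fraction = vote_fraction,
    confident = confident,
    vote_fraction_met = frac_met,
    stringsAsFactors = FALSE)
  class(out) <- c("SubgroupCalls", "data.frame")
  out
}

#' Classifier performance metrics from calls and truth
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, F1 `2TP/(2TP+FP+FN)` and AUC
#' (probability a random positive outranks a random negative by the
#' metabolism vote share, ties counted half), with `metabolism` as the
#' positive class.
#'
#' @param calls a `SubgroupCalls` data.frame from [predict_subgroup()], or a
#'   factor/character vector of labels (AUC then uses 0/1 labels as scores).
#' @param truth true labels (factor/character with levels EMT/metabolism).
#' @param positive positive class (default "metabolism").
#' @return list with `accuracy`, `f1`, `auc`, `confusion`
#'   (named TP/TN/FP/FN vector) and `auc_defined` (FALSE when truth has one
#'   class, in which case `auc` is NA).
#' @export
evaluate_classifier <- function(calls, truth, positive = "metabolism") {
  if (inherits(calls, "SubgroupCalls") || is.data.frame(calls)) {
    pred <- as.character(calls$label)
    score <- calls$vote_fraction_met
    if (positive == "EMT") score <- 1 - score
  } else {
    pred <- as.character(calls)
    score <- as.numeric(pred == positive)
  }
  truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("calls and truth differ in length")
  pos <- truth == positive
  tp <- sum(pred == positive & pos)
  tn <- sum(pred != positive & !pos)
  fp <- sum(pred == positive & !pos)
  fn <- sum(pred != positive & pos)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)

  auc_defined <- any(pos) && any(!pos)
  auc <- if (auc_defined) {
    r <- rank(score, ties.method = "average")
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else {
    NA_real_
  }
  list(accuracy = accuracy, f1 = f1, auc = auc,
       confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
       auc_defined = auc_defined)
}
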