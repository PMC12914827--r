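# Importance-ranked forward signature simplification driven by the
# per-subgroup treatment-benefit criteria.
#
# The loop mirrors the six-step simplification procedure: rank features once
# by averaged ensemble importance from a full-feature ensemble, then for
# k = 1, 2, ... retrain the voting ensemble on the top-k features, stratify
# the patient cohort(s), assess the treatment-benefit criteria within the
# predicted subgroups, and keep the smallest k that passes.

#' Simplify a kinase signature by survival-criteria-driven forward selection
#'
#' @param train_panel a `CellLinePanel` with two classes.
#' @param cohort a `PatientCohort` (or list of them; with several cohorts the
#'   criteria must pass in all of them at a given k).
#' @param treatment_flag treatment column name (default: each cohort's
#'   `treatment_col`).
#' @param max_k largest panel size to try (default: all features).
#' @param base_seed base of the deterministic seed schedule; member seeds are
#'   derived from (base_seed, k, member) so traces are reproducible and
#'   k-to-k differences are attributable to the feature set.
#' @param n_members,n_trees ensemble size per k (defaults 500 x 100).
#' @param split_ratio internal 8:2 split used both to fit each k-ensemble and
#'   to record its internal-validation metrics.
#' @param stability_window require the criteria to also hold at
#'   k+1, ..., k+window before accepting k (default 0: accept the first
#'   passing k).
#' @param early_stop stop iterating once a k (plus its stability window) has
#'   passed; set FALSE to trace all k up to `max_k`.
#' @param confident_only restrict survival fits to confident calls.
#' @return a `SelectionTrace`: list with `trace` (one data.frame row per k),
#'   `chosen_k`, `chosen_features`, `status` ("passed"/"none_passed"),
#'   `ranking` (full importance ranking), and
#'   `cumulative_importance_at_chosen`.
#' @export
simplify_signature <- function(train_panel, cohort, treatment_flag = NULL,
                               max_k = NULL, base_seed = 1L,
                               n_members = 500L, n_trees = 100L,
                               split_ratio = 0.8, stability_window = 0L,
                               early_stop = TRUE, confident_only = FALSE) {
  stopifnot(inherits(train_panel, "CellLinePanel"))
  cohorts <- if (inherits(cohort, "PatientCohort")) list(cohort) else cohort
  if (!length(cohorts)) stop("at least one cohort required")
  for (co in cohorts) {
    tf <- treatment_flag %||% co$treatment_col
    trt <- co$clinical[[tf]]
    if (is.null(trt)) stop("treatment column not found: ", tf)
    if (length(unique(trt)) < 2) {
      stop("cohort lacks both treated and untreated patients")
    }
    if (sum(co$clinical$os_event) < 1) stop("cohort has no events")
  }
  p <- ncol(train_panel$expr$values)
  max_k <- as.integer(max_k %||% p)
  if (max_k > p) stop("max_k exceeds the number of features")

  # normalise once; the per-k ensembles see pre-normalised columns
  panel <- train_panel
  if (!panel$expr$normalized) panel$expr <- zscore_normalize(panel$expr)
  split <- split_train_validation(panel, ratio = split_ratio,
                                  seed = derive_seed(base_seed, 0L),
                                  stratify = TRUE)
  cohort_exprs <- lapply(cohorts, function(co) {
    e <- co$expr
    if (!e$normalized) e <- zscore_normalize(impute_minimum(e))
    e
  })

  # Step 1: importance ranking from the full-feature ensemble, frozen.
  full_model <- train_ensemble(split$train, n_members = n_members,
                               seed = derive_seed(base_seed, 0L),
                               n_trees = n_trees)
  ranking <- full_model$importance  # sorted by (-importance, feature)
  ranked_features <- ranking$feature
  cum_importance <- cumsum(ranking$importance)

  subset_features <- function(pnl, feats) {
    pnl$expr <- select_features(pnl$expr, feats)
    pnl
  }

  rows <- list()
  chosen_k <- NA_integer_
  pass_vec <- logical(max_k)
  eval_k <- function(k) {
    feats <- ranked_features[seq_len(k)]
    model_k <- train_ensemble(subset_features(split$train, feats),
                              n_members = n_members,
                              seed = derive_seed(base_seed, k),
                              n_trees = n_trees)
    val_calls <- predict_subgroup(model_k,
                                  select_features(split$validation$expr, feats))
    val_metrics <- evaluate_classifier(val_calls, split$validation$labels)
    crits <- mapply(function(co, ex) {
      calls <- predict_subgroup(model_k, select_features(ex, feats))
      treatment_effect_by_subgroup(co, calls,
                                   treatment_flag = treatment_flag %||% co$treatment_col,
                                   confident_only = confident_only)$criteria
    }, cohorts, cohort_exprs, SIMPLIFY = FALSE)
    c1 <- crits[[1]]
    list(pass = all(vapply(crits, function(cr) cr$pass, logical(1))),
         row = data.frame(
           k = k,
           features = paste(feats, collapse = ";"),
           added_feature = feats[k],
           cumulative_importance = cum_importance[k],
           hr_emt = c1$hr_emt, p_emt = c1$p_emt,
           hr_met = c1$hr_met, p_met = c1$p_met,
           pass = NA,  # filled below (multi-cohort aware)
           val_accuracy = val_metrics$accuracy,
           val_f1 = val_metrics$f1,
           val_auc = if (val_metrics$auc_defined) val_metrics$auc else NA_real_,
           stringsAsFactors = FALSE))
  }

  k <- 1L
  while (k <= max_k) {
    res <- eval_k(k)
    pass_vec[k] <- res$pass
    res$row$pass <- res$pass
    rows[[k]] <- res$row
    # accept the smallest k whose criteria pass, optionally demanding the
    # next `stability_window` panel sizes to pass as well
    if (is.na(chosen_k) && k > stability_window) {
      cand <- k - stability_window
      if (all(pass_vec[cand:k])) chosen_k <- as.integer(cand)
    }
    if (!is.na(chosen_k) && early_stop) break
    k <- k + 1L
  }

  trace <- do.call(rbind, rows)
  status <- if (!is.na(chosen_k)) "passed" else "none_passed"
  structure(
    list(trace = trace, chosen_k = chosen_k,
         chosen_features = if (!is.na(chosen_k)) {
           ranked_features[seq_len(chosen_k)]
         } else {
           character(0)
         },
         status = status,
         ranking = ranking,
         cumulative_importance_at_chosen =
           if (!is.na(chosen_k)) cum_importance[chosen_k] else NA_real_,
         base_seed = base_seed,
         settings = list(n_members = n_members, n_trees = n_trees,
                         max_k = max_k, stability_window = stability_window,
                         early_stop = early_stop)),
    class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf("SelectionTrace: status %s", x$status))
  if (x$status == "passed") {
    cat(sprintf(", chosen_k = %d (cumulative importance %.1f%%)",
                x$chosen_k, 100 * x$cumulative_importance_at_chosen))
  }
  cat("\n")
  print(x$trace[, c("k", "added_feature", "cumulative_importance",
                    "hr_emt", "p_emt", "hr_met", "p_met", "pass")],
        digits = 3)
  invisible(x)
}

#' Selection stability across seeds
#'
#' @param trace_list list of `SelectionTrace` objects over different seeds,
#'   all on the same feature universe.
#' @return list with `feature_frequency` (fraction of passing traces whose
#'   chosen set contains each feature), `chosen_k` (per-trace vector, NA for
#'   non-passing), `n_passed`, and `n_traces`.
#' @export
stability_report <- function(trace_list) {
  if (length(trace_list) < 2) stop("need at least two traces")
  universes <- lapply(trace_list, function(tr) sort(tr$ranking$feature))
  for (u in universes[-1]) {
    if (!identical(u, universes[[1]])) {
      stop("traces cover different feature universes")
    }
  }
  passed <- vapply(trace_list, function(tr) tr$status == "passed", logical(1))
  chosen_k <- vapply(trace_list, function(tr) {
    if (tr$status == "passed") tr$chosen_k else NA_integer_
  }, integer(1))
  feats <- universes[[1]]
  freq <- if (any(passed)) {
    sel <- lapply(trace_list[passed], function(tr) tr$chosen_features)
    vapply(feats, function(f) {
      mean(vapply(sel, function(s) f %in% s, logical(1)))
    }, numeric(1))
  } else {
    setNames(rep(NA_real_, length(feats)), feats)
  }
  list(feature_frequency = sort(freq, decreasing = TRUE),
       chosen_k = chosen_k, n_passed = sum(passed),
       n_traces = length(trace_list))
}
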