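test_that("8:2 split gives 33/9 on 42 samples, is deterministic, and stratifies", {
  panel <- strong_panel()
  sp <- split_train_validation(panel, ratio = 0.8, seed = 5)
  expect_equal(nrow(sp$train$expr$values), 33L)
  expect_equal(nrow(sp$validation$expr$values), 9L)
  sp2 <- split_train_validation(panel, ratio = 0.8, seed = 5)
  expect_identical(rownames(sp$validation$expr$values),
                   rownames(sp2$validation$expr$values))
  # stratified split keeps the 50/50 class ratio within one sample
  st <- split_train_validation(panel, seed = 6, stratify = TRUE)
  tab <- table(st$validation$labels)
  expect_lte(abs(tab[1] - tab[2]), 1)
  # group-aware split never straddles a cell line
  gr <- split_train_validation(panel, seed = 7, group_by_line = TRUE)
  expect_length(intersect(unique(gr$train$line_id),
                          unique(gr$validation$line_id)), 0)
})

test_that("training preconditions are enforced", {
  panel <- strong_panel()
  single <- panel
  single$labels <- factor(rep("EMT", length(panel$labels)),
                          levels = c("EMT", "metabolism"))
  expect_error(train_ensemble(single, n_members = 2), "single class")
})

test_that("ensemble importance ranks informative features like a t-statistic oracle", {
  panel <- strong_panel()
  model <- small_model()
  expect_length(model$member_seeds, 50L)
  # per-member importance rows are non-negative and sum to 1
  imp_rows <- model$forest$importance
  expect_true(all(imp_rows >= 0))
  expect_lt(max(abs(rowSums(imp_rows) - 1)), 1e-9)

  top12 <- model$importance$feature[1:12]
  expect_gte(sum(panel$informative_features %in% top12), 8)

  # independent oracle: absolute two-sample t statistic on the same data
  z <- zscore_normalize(panel$expr)$values
  met <- panel$labels == "metabolism"
  tstat <- abs(vapply(seq_len(ncol(z)), function(j) {
    t.test(z[met, j], z[!met, j])$statistic
  }, numeric(1)))
  oracle_top12 <- colnames(z)[order(-tstat)][1:12]
  expect_gte(length(intersect(top12, oracle_top12)), 8)
})

test_that("training and prediction are deterministic in the seed", {
  panel <- strong_panel()
  m1 <- train_ensemble(panel, n_members = 20, seed = 42)
  m2 <- train_ensemble(panel, n_members = 20, seed = 42)
  expect_identical(m1$importance, m2$importance)
  new <- zscore_normalize(generate_cellline_panel(panel_spec(seed = 50))$expr)
  expect_identical(predict_subgroup(m1, new), predict_subgroup(m2, new))
  m3 <- train_ensemble(panel, n_members = 20, seed = 43)
  expect_false(identical(m1$importance$importance, m3$importance$importance))
})

test_that("vote bookkeeping: fractions, threshold rule, tie handling", {
  model <- small_model()
  co <- generate_patient_cohort(cohort_spec(n_patients = 120, effect_size = 3,
                                            profile_noise_sd = 1, seed = 8))
  calls <- predict_subgroup(model, zscore_normalize(co$expr))
  expect_true(all(calls$vote_fraction >= 0.5 & calls$vote_fraction <= 1))
  # vote conservation: winning + losing shares sum to 1 by construction
  expect_equal(pmax(calls$vote_fraction_met, 1 - calls$vote_fraction_met),
               calls$vote_fraction)
  expect_identical(calls$confident,
                   calls$vote_fraction > model$vote_threshold &
                     calls$vote_fraction_met != 0.5)
  # strongly separated cohort: confident and correct
  expect_gte(mean(calls$confident), 0.95)
  expect_gte(mean(as.character(calls$label) == co$clinical$latent_subgroup),
             0.99)
  # unnormalized input warns, errors under strict mode
  expect_warning(predict_subgroup(model, co$expr), "not flagged normalized")
  expect_error(predict_subgroup(model, co$expr, strict = TRUE),
               "not flagged normalized")
  # missing model features error
  short <- zscore_normalize(co$expr)
  short$values <- short$values[, 1:10]
  expect_error(predict_subgroup(model, short), "lacks model features")
})

test_that("evaluate_classifier reproduces the printed formulas", {
  # perfect predictions
  truth <- rep(c("metabolism", "EMT"), c(5, 5))
  perfect <- evaluate_classifier(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  # enumerated confusion: TP=3 TN=4 FP=1 FN=2 -> accuracy .7, F1 = 6/9
  pred <- c(rep("metabolism", 3), rep("EMT", 2),   # 3 TP, 2 FN
            rep("EMT", 4), "metabolism")           # 4 TN, 1 FP
  tr <- c(rep("metabolism", 5), rep("EMT", 5))
  m <- evaluate_classifier(pred, tr)
  expect_identical(m$confusion, c(TP = 3L, TN = 4L, FP = 1L, FN = 2L))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 3 / (2 * 3 + 1 + 2))
  # all inverted
  inv <- evaluate_classifier(ifelse(tr == "EMT", "metabolism", "EMT"), tr)
  expect_equal(inv$accuracy, 0)
  expect_equal(inv$f1, 0)
  # single-class truth flags AUC undefined
  one <- evaluate_classifier(rep("EMT", 3), rep("EMT", 3))
  expect_false(one$auc_defined)
  expect_true(is.na(one$auc))
})

test_that("AUC counts ties as half (hand-checked ranking)", {
  calls <- data.frame(label = c("metabolism", "metabolism", "EMT", "EMT"),
                      vote_fraction_met = c(0.9, 0.5, 0.5, 0.1))
  truth <- c("metabolism", "metabolism", "EMT", "EMT")
  # pairs: (0.9 vs 0.5) win, (0.9 vs 0.1) win, (0.5 vs 0.5) half,
  # (0.5 vs 0.1) win -> (3 + 0.5) / 4
  expect_equal(evaluate_classifier(calls, truth)$auc, 3.5 / 4)
})

test_that("zero effect size carries no signal: held-out accuracy in the binomial band", {
  # scaled-down label-permutation null (spec band [0.35, 0.65] at n = 200)
  panel <- generate_cellline_panel(panel_spec(effect_size = 0, seed = 21))
  model <- train_ensemble(panel, n_members = 60, seed = 21)
  co <- generate_patient_cohort(cohort_spec(n_patients = 200, effect_size = 0,
                                            seed = 22))
  calls <- predict_subgroup(model, zscore_normalize(co$expr))
  acc <- mean(as.character(calls$label) == co$clinical$latent_subgroup)
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
  ev <- evaluate_classifier(calls, co$clinical$latent_subgroup)
  expect_gte(ev$auc, 0.40)
  expect_lte(ev$auc, 0.60)
})

test_that("held-out accuracy is monotone in effect size (3-point grid)", {
  # scaled down: 150-member ensembles, 6 seeds per effect level
  mean_acc <- vapply(c(0.3, 1, 3), function(eff) {
    mean(vapply(1:6, function(s) {
      panel <- generate_cellline_panel(panel_spec(effect_size = eff,
                                                  seed = 100 + s))
      sp <- split_train_validation(panel, seed = s, stratify = TRUE)
      m <- train_ensemble(sp$train, n_members = 150, seed = s)
      calls <- predict_subgroup(m, zscore_normalize(sp$validation$expr))
      evaluate_classifier(calls, sp$validation$labels)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= 0))
})

test_that("averaged importance recovers informative features at least as well as the median member", {
  panel <- strong_panel()
  model <- small_model()
  k <- 10
  inf <- panel$informative_features
  ens_hits <- sum(model$importance$feature[1:k] %in% inf)
  member_hits <- apply(model$forest$importance, 1, function(w) {
    sum(model$feature_names[order(-w)][1:k] %in% inf)
  })
  expect_gte(ens_hits, median(member_hits))
})
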