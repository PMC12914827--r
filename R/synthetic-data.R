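# Synthetic cell-line panels and patient cohorts.
#
# The generator states a simple world with the structure the downstream
# analysis assumes: two latent kinomic subgroups ("EMT", "metabolism"), a
# subset of kinase features whose means differ between subgroups, replicate
# noise within cell lines, and patient survival drawn from a proportional-
# hazards model in which treatment benefit exists only in the metabolism
# subgroup.

# 40 kinase-like feature identifiers; panels default to the first 37 so that
# feature-subsetting against a richer universe can be exercised.
kinase_universe <- c(
  "AAK1", "AKT1", "AURKA", "BRAF", "CAMK2D", "CDK1", "CDK2", "CHEK1",
  "CSNK2A1", "EGFR", "EPHA2", "ERBB3", "FGFR2", "FYN", "GSK3B", "ILK",
  "JAK1", "KALRN", "LYN", "MAP2K1", "MAP2K4", "MAP3K7", "MAPK1", "MAPK3",
  "MAPK14", "MET", "NEK2", "PAK1", "PAK4", "PDK1", "PLK1", "PRKACA",
  "PRKCA", "PRKD2", "PTK2", "RIPK2", "ROCK1", "SRC", "STK39", "TGM2")

#' Specification of a synthetic cell-line kinase panel
#'
#' @param n_lines number of distinct cell lines (default 14).
#' @param n_replicates biological replicates per line (default 3).
#' @param n_features number of kinase features (default 37).
#' @param n_informative number of features whose means differ between the two
#'   subgroups (default 10); must not exceed `n_features`.
#' @param effect_size mean shift between subgroups on informative features, in
#'   units of a feature's marginal noise SD (default 2).
#' @param replicate_sd within-line replicate noise SD (default 0.4).
#' @param line_sd between-line noise SD shared by replicates of one line
#'   (default 0.6).  The marginal noise SD is
#'   `sqrt(line_sd^2 + replicate_sd^2)`.
#' @param subgroup_fraction fraction of lines labelled "metabolism"
#'   (default 0.5); both subgroups must be non-empty.
#' @param seed integer RNG seed.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_lines = 14L, n_replicates = 3L, n_features = 37L,
                       n_informative = 10L, effect_size = 2,
                       replicate_sd = 0.4, line_sd = 0.6,
                       subgroup_fraction = 0.5, seed = 1L) {
  spec <- list(n_lines = as.integer(n_lines),
               n_replicates = as.integer(n_replicates),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               effect_size = effect_size, replicate_sd = replicate_sd,
               line_sd = line_sd, subgroup_fraction = subgroup_fraction,
               seed = as.integer(seed))
  if (spec$n_informative > spec$n_features) {
    stop("n_informative (", spec$n_informative,
         ") exceeds n_features (", spec$n_features, ")")
  }
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  n_met <- round(spec$subgroup_fraction * spec$n_lines)
  if (n_met < 1 || n_met > spec$n_lines - 1) {
    stop("subgroup_fraction yields an empty subgroup class")
  }
  structure(spec, class = "panel_spec")
}

panel_feature_names <- function(n_features) {
  if (n_features <= length(kinase_universe)) {
    kinase_universe[seq_len(n_features)]
  } else {
    c(kinase_universe, sprintf("KIN%03d", seq_len(n_features - length(kinase_universe))))
  }
}

#' Generate a labelled synthetic cell-line kinase panel
#'
#' Produces a (`n_lines * n_replicates`) x `n_features` abundance matrix in
#' which replicates of one line share a line-level random effect, and the
#' first `n_informative` features have subgroup means separated by
#' `effect_size` marginal noise SDs (metabolism shifted up, EMT down).
#'
#' @param spec a [panel_spec()].
#' @return a `CellLinePanel`: list with `expr` ([expression_matrix()]),
#'   `labels` (factor, levels `EMT`/`metabolism`), `line_id`, `replicate`,
#'   `informative_features`, and the generating `spec`.
#' @export
generate_cellline_panel <- function(spec = panel_spec()) {
  if (!inherits(spec, "panel_spec")) spec <- do.call(panel_spec, spec)
  n <- spec$n_lines * spec$n_replicates
  p <- spec$n_features
  feats <- panel_feature_names(p)
  informative <- feats[seq_len(spec$n_informative)]
  s_marg <- sqrt(spec$line_sd^2 + spec$replicate_sd^2)
  n_met <- round(spec$subgroup_fraction * spec$n_lines)

  with_seed(spec$seed, {
    line_group <- sample(rep(c("metabolism", "EMT"),
                             c(n_met, spec$n_lines - n_met)))
    line_eff <- matrix(rnorm(spec$n_lines * p, sd = spec$line_sd),
                       spec$n_lines, p)
    shift <- matrix(0, spec$n_lines, p)
    shift[, seq_len(spec$n_informative)] <-
      ifelse(line_group == "metabolism", 1, -1) * spec$effect_size * s_marg / 2
    line_mean <- shift + line_eff

    line_id <- rep(sprintf("GC%02d", seq_len(spec$n_lines)),
                   each = spec$n_replicates)
    replicate <- rep(seq_len(spec$n_replicates), spec$n_lines)
    values <- line_mean[rep(seq_len(spec$n_lines), each = spec$n_replicates), ,
                        drop = FALSE] +
      matrix(rnorm(n * p, sd = spec$replicate_sd), n, p)
    rownames(values) <- paste0(line_id, "_R", replicate)
    colnames(values) <- feats
    labels <- factor(rep(line_group, each = spec$n_replicates),
                     levels = c("EMT", "metabolism"))
    structure(
      list(expr = expression_matrix(values, cohort = "cellline"),
           labels = labels, line_id = line_id, replicate = replicate,
           informative_features = informative, spec = spec),
      class = "CellLinePanel")
  })
}

#' @export
print.CellLinePanel <- function(x, ...) {
  cat(sprintf("CellLinePanel: %d lines x %d replicates, %d features (%d informative)\n",
              x$spec$n_lines, x$spec$n_replicates, x$spec$n_features,
              x$spec$n_informative))
  print(table(x$labels))
  invisible(x)
}

#' Specification of a synthetic patient survival cohort
#'
#' Patients carry a latent kinomic subgroup, a kinase profile drawn from the
#' same subgroup-conditional model as the cell-line generator (patient-level
#' marginal noise SD 1), clinical covariates, a treatment flag, and an
#' exponential (optionally Weibull) survival time with administrative
#' censoring.  Treatment acts on the hazard through a subgroup-specific
#' hazard ratio; the default world gives treated metabolism patients HR 0.45
#' and treated EMT patients HR 1 (no benefit).
#'
#' @param n_patients cohort size.
#' @param subgroup_prevalence probability a patient is latently metabolism.
#' @param treatment_rate probability of being treated (independent of
#'   subgroup unless `treatment_confounding` is nonzero).
#' @param hr_treatment_emt treatment hazard ratio in the EMT subgroup.
#' @param hr_treatment_met treatment hazard ratio in the metabolism subgroup.
#' @param baseline_median_os untreated median overall survival, months.
#' @param admin_censor_time administrative censoring horizon, months; may be
#'   `Inf`.
#' @param n_features,n_informative,effect_size kinase-profile structure,
#'   matching [panel_spec()] semantics.
#' @param profile_noise_sd per-feature noise SD of patient profiles
#'   (default 2).  `effect_size` is stated in cell-line marginal-SD units, so
#'   the default halves the per-feature class separation in patients relative
#'   to cell lines, emulating bulk-tumour heterogeneity and cross-platform
#'   transfer: single kinases under-stratify patients and a multi-kinase
#'   panel is required, as observed on real cohorts.
#' @param weibull_shape Weibull shape of the baseline hazard; 1 (default)
#'   gives the exponential model.
#' @param age_log_hr log hazard ratio per year of (centred) age; 0 by default.
#' @param stage_log_hr log hazard ratio per TNM stage step; 0 by default.
#' @param treatment_confounding added treatment probability for metabolism
#'   patients (default 0: assignment independent of subgroup).
#' @param cohort_tag cohort label.
#' @param seed integer RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 500L, subgroup_prevalence = 0.5,
                        treatment_rate = 0.4, hr_treatment_emt = 1.0,
                        hr_treatment_met = 0.45, baseline_median_os = 48,
                        admin_censor_time = 120, n_features = 37L,
                        n_informative = 10L, effect_size = 2,
                        profile_noise_sd = 2, weibull_shape = 1,
                        age_log_hr = 0, stage_log_hr = 0,
                        treatment_confounding = 0, cohort_tag = "synthetic",
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               subgroup_prevalence = subgroup_prevalence,
               treatment_rate = treatment_rate,
               hr_treatment_emt = hr_treatment_emt,
               hr_treatment_met = hr_treatment_met,
               baseline_median_os = baseline_median_os,
               admin_censor_time = admin_censor_time,
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               effect_size = effect_size,
               profile_noise_sd = profile_noise_sd,
               weibull_shape = weibull_shape,
               age_log_hr = age_log_hr, stage_log_hr = stage_log_hr,
               treatment_confounding = treatment_confounding,
               cohort_tag = cohort_tag, seed = as.integer(seed))
  if (spec$n_patients < 1) stop("n_patients must be positive")
  if (spec$hr_treatment_emt <= 0 || spec$hr_treatment_met <= 0) {
    stop("hazard ratios must be > 0")
  }
  if (spec$subgroup_prevalence < 0 || spec$subgroup_prevalence > 1 ||
      spec$treatment_rate < 0 || spec$treatment_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (spec$baseline_median_os <= 0) stop("baseline_median_os must be > 0")
  if (spec$admin_censor_time <= 0) stop("admin_censor_time must be > 0")
  if (spec$n_informative > spec$n_features) {
    stop("n_informative exceeds n_features")
  }
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic patient cohort with kinase profiles and survival
#'
#' @param spec a [cohort_spec()].
#' @return a `PatientCohort`: list with `expr` ([expression_matrix()]),
#'   `clinical` (data.frame with `sample_id`, `cohort`, `age`, `sex`,
#'   `tnm_stage`, `lauren`, `location`, `chemo`, `radio`, `os_months`,
#'   `os_event`, and oracle-only `latent_subgroup`), `treatment_col`
#'   (the column whose flag drives the subgroup-specific hazard ratio),
#'   and the generating `spec`.
#' @export
generate_patient_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_patients
  p <- spec$n_features
  feats <- panel_feature_names(p)

  with_seed(spec$seed, {
    latent <- ifelse(runif(n) < spec$subgroup_prevalence, "metabolism", "EMT")
    p_treat <- pmin(1, spec$treatment_rate +
                      spec$treatment_confounding * (latent == "metabolism"))
    chemo <- as.integer(runif(n) < p_treat)
    radio <- as.integer(runif(n) < 0.2)

    shift <- matrix(0, n, p)
    shift[, seq_len(spec$n_informative)] <-
      ifelse(latent == "metabolism", 1, -1) * spec$effect_size / 2
    values <- shift + matrix(rnorm(n * p, sd = spec$profile_noise_sd), n, p)
    rownames(values) <- sprintf("%s_P%05d", spec$cohort_tag, seq_len(n))
    colnames(values) <- feats

    age <- pmin(90, pmax(24, round(rnorm(n, 63, 11))))
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.65, 0.35))
    tnm <- sample(c("II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.40, 0.38, 0.22))
    lauren <- sample(c("intestinal", "diffuse", "mixed"), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.10))
    location <- sample(c("cardia", "body", "antrum", "whole"), n,
                       replace = TRUE, prob = c(0.20, 0.30, 0.40, 0.10))

    hr_treat <- ifelse(latent == "metabolism",
                       spec$hr_treatment_met, spec$hr_treatment_emt)
    log_hr <- log(hr_treat) * chemo +
      spec$age_log_hr * (age - 63) +
      spec$stage_log_hr * (match(tnm, c("II", "III", "IV")) - 1)
    lambda0 <- log(2) / spec$baseline_median_os
    shape <- spec$weibull_shape
    # PH Weibull: S(t) = exp(-HR * (lambda0 * t)^shape); shape 1 = exponential
    u <- runif(n)
    t_event <- (-log(u) / exp(log_hr))^(1 / shape) / lambda0
    os_months <- pmin(t_event, spec$admin_censor_time)
    os_event <- as.integer(t_event <= spec$admin_censor_time)

    clinical <- data.frame(
      sample_id = rownames(values), cohort = spec$cohort_tag,
      age = age, sex = sex, tnm_stage = tnm, lauren = lauren,
      location = location, chemo = chemo, radio = radio,
      os_months = os_months, os_event = os_event,
      latent_subgroup = latent, stringsAsFactors = FALSE)

    structure(
      list(expr = expression_matrix(values, cohort = spec$cohort_tag),
           clinical = clinical, treatment_col = "chemo", spec = spec),
      class = "PatientCohort")
  })
}

#' @export
print.PatientCohort <- function(x, ...) {
  cat(sprintf("PatientCohort '%s': %d patients, %d kinase features\n",
              x$spec$cohort_tag, nrow(x$clinical), ncol(x$expr$values)))
  cat(sprintf("  events: %d / %d; treated (%s): %d\n",
              sum(x$clinical$os_event), nrow(x$clinical), x$treatment_col,
              sum(x$clinical[[x$treatment_col]])))
  invisible(x)
}

#' Inject missing-completely-at-random holes into an expression matrix
#'
#' Per-feature missingness rates are drawn from a log-normal distribution
#' whose median equals `target_median_rate` (truncated at 0.95), then entries
#' are masked independently, emulating the uneven per-predictor missingness
#' of proteomic cohorts.
#'
#' @param matrix an [expression_matrix()].
#' @param target_median_rate target median per-feature missing rate in
#'   `[0, 1)`.
#' @param seed integer RNG seed.
#' @param rate_log_sd log-scale SD of the per-feature rate distribution
#'   (default 0.4).
#' @return the matrix with `NA` holes; attribute `missing_mask` records the
#'   injected logical mask.
#' @export
inject_missingness <- function(matrix, target_median_rate, seed = 1L,
                               rate_log_sd = 0.4) {
  matrix <- as_expression_matrix(matrix)
  if (target_median_rate < 0 || target_median_rate >= 1) {
    stop("target_median_rate must lie in [0, 1)")
  }
  if (target_median_rate == 0) {
    attr(matrix, "missing_mask") <-
      matrix(FALSE, nrow(matrix$values), ncol(matrix$values))
    return(matrix)
  }
  with_seed(seed, {
    p <- ncol(matrix$values)
    rates <- pmin(0.95, target_median_rate * exp(rnorm(p, 0, rate_log_sd)))
    mask <- matrix(runif(length(matrix$values)), nrow(matrix$values), p) <
      matrix(rates, nrow(matrix$values), p, byrow = TRUE)
    matrix$values[mask] <- NA_real_
    attr(matrix, "missing_mask") <- mask
    matrix
  })
}
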