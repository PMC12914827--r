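# Survival machinery: Kaplan-Meier, log-rank, Cox PH fits (Efron ties),
# the per-subgroup treatment-benefit criteria, multiplicative and additive
# (RERI) interaction, proportional-hazards and linearity checks, and the
# gated baseline-comparison battery.

# Normalise survival input to a data.frame with `time` (> 0) and
# `event` (0/1) columns plus covariates.  Accepts a PatientCohort (clinical
# table), or a data.frame with either time/event or os_months/os_event.
as_survival_df <- function(records) {
  if (inherits(records, "PatientCohort")) records <- records$clinical
  if (!is.data.frame(records)) stop("records must be a data.frame or PatientCohort")
  d <- records
  if (!"time" %in% names(d) && "os_months" %in% names(d)) d$time <- d$os_months
  if (!"event" %in% names(d) && "os_event" %in% names(d)) d$event <- d$os_event
  if (!all(c("time", "event") %in% names(d))) {
    stop("records need time/event (or os_months/os_event) columns")
  }
  if (any(!is.na(d$time) & d$time <= 0)) stop("survival times must be > 0")
  if (!all(na.omit(d$event) %in% c(0, 1))) stop("event must be coded 0/1")
  d
}

#' Kaplan-Meier estimate with median OS and its 95% CI
#'
#' Product-limit estimator; the median is the earliest time at which the
#' survival curve drops to 0.5 or below, with the confidence interval from
#' the log-log (Greenwood) transform.  An undefined median is reported as
#' not reached (`NA`).
#'
#' @param records survival records (see package conventions: `time`/`event`
#'   or `os_months`/`os_event` columns, or a `PatientCohort`).
#' @param conf_level confidence level (default 0.95).
#' @return list with `curve` (data.frame: time, n_risk, n_event, surv,
#'   lower, upper), `median`, `median_ci` (length-2), `n`, `n_events`,
#'   and `median_reached`.
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  d <- as_survival_df(records)
  if (nrow(d) == 0) stop("empty input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  ci <- unname(c(tab["0.95LCL"], tab["0.95UCL"]))
  list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv,
                          lower = fit$lower, upper = fit$upper),
       median = med, median_ci = ci,
       n = sum(fit$n), n_events = sum(fit$n.event),
       median_reached = is.finite(med))
}

#' Log-rank test between survival groups
#'
#' @param records survival records.
#' @param group_factor grouping variable (vector aligned with records, or the
#'   name of a column in them).
#' @return list with `chisq`, `df`, `p`, and per-group observed/expected
#'   counts.
#' @export
logrank_test <- function(records, group_factor) {
  d <- as_survival_df(records)
  g <- if (is.character(group_factor) && length(group_factor) == 1 &&
           group_factor %in% names(d)) d[[group_factor]] else group_factor
  g <- factor(g)
  if (length(g) != nrow(d)) stop("group factor length mismatch")
  if (nlevels(droplevels(g)) < 2) stop("need at least two non-empty groups")
  if (any(table(g) == 0)) stop("empty group level: ",
                               paste(names(which(table(g) == 0)), collapse = ", "))
  if (sum(d$event) == 0) stop("no events observed in any group")
  d$..group <- g
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ ..group, data = d)
  df <- length(sd_fit$n) - 1
  p <- pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  list(chisq = unname(sd_fit$chisq), df = df, p = p,
       observed = sd_fit$obs, expected = sd_fit$exp)
}

#' Cox proportional-hazards fit with Efron tie handling
#'
#' Wraps a partial-likelihood Cox fit: characters become reference-coded
#' factors, rows with missing covariates are dropped (complete-case
#' analysis), and each term is reported with its hazard ratio, Wald CI and
#' Wald P.  Perfect separation (monotone likelihood) is flagged rather than
#' silently reported.
#'
#' @param records survival records.
#' @param covariate_list character vector of covariate column names.
#' @param ties "efron" (default) or "breslow".
#' @param conf_level Wald CI level (default 0.95).
#' @return a `CoxFit`: list with `terms` (data.frame: term, coef, hr,
#'   ci_low, ci_high, se, p), `loglik`, `n`, `n_events`, `ties`,
#'   `converged`, `separation`, and the underlying `coxph` object in
#'   `object`.
#' @export
cox_fit <- function(records, covariate_list, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  d <- as_survival_df(records)
  missing_cov <- setdiff(covariate_list, names(d))
  if (length(missing_cov)) {
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  }
  d <- d[, c("time", "event", covariate_list), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0) stop("no complete-case rows")
  if (sum(d$event) < 1) stop("need at least one event")
  for (v in covariate_list) {
    if (is.character(d[[v]]) || is.logical(d[[v]])) d[[v]] <- factor(d[[v]])
    if (length(unique(d[[v]])) < 2) {
      stop("covariate constant after complete-case filtering: ", v)
    }
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(covariate_list, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  s <- summary(fit, conf.int = conf_level)
  z <- qnorm(1 - (1 - conf_level) / 2)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  terms <- data.frame(
    term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
    ci_low = exp(unname(cf) - z * se), ci_high = exp(unname(cf) + z * se),
    se = unname(se),
    p = 2 * pnorm(-abs(unname(cf) / se)),
    stringsAsFactors = FALSE)
  separation <- any(abs(cf) > 10 & se > 10) || any(!is.finite(se))
  structure(
    list(terms = terms, loglik = fit$loglik[length(fit$loglik)],
         n = fit$n, n_events = fit$nevent, ties = ties,
         converged = fit$iter < 50 && all(is.finite(cf)),
         separation = separation, conf_level = conf_level, object = fit,
         data = d),
    class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit (%s ties): n = %d, events = %d, loglik = %.3f\n",
              x$ties, x$n, x$n_events, x$loglik))
  print(x$terms, digits = 4)
  if (x$separation) cat("  WARNING: possible monotone likelihood (separation)\n")
  invisible(x)
}

#' Assemble a treatment-benefit criteria result
#'
#' The validation rule for a correctly stratifying signature: the treatment
#' hazard ratio in the EMT subgroup must exceed that in the metabolism
#' subgroup, treatment must be significantly protective in metabolism
#' (P < 0.05) and not significant in EMT (P > 0.05).  Inestimable entries
#' (`NA`) fail with a recorded reason.
#'
#' @param hr_emt,p_emt,hr_met,p_met treatment HR and Wald P per subgroup.
#' @param alpha significance level (default 0.05).
#' @return a `CriteriaResult` list with `pass` and `reasons`.
#' @export
criteria_result <- function(hr_emt, p_emt, hr_met, p_met, alpha = 0.05) {
  reasons <- character(0)
  est <- !anyNA(c(hr_emt, p_emt, hr_met, p_met))
  if (!est) {
    reasons <- c(reasons, "inestimable subgroup treatment effect")
  } else {
    if (!(hr_emt > hr_met)) {
      reasons <- c(reasons, sprintf("HR ordering violated: hr_emt %.3f <= hr_met %.3f",
                                    hr_emt, hr_met))
    }
    if (!(p_met < alpha)) {
      reasons <- c(reasons, sprintf("metabolism P %.4f not < %.2f", p_met, alpha))
    }
    if (!(p_emt > alpha)) {
      reasons <- c(reasons, sprintf("EMT P %.4f not > %.2f", p_emt, alpha))
    }
  }
  structure(
    list(hr_emt = hr_emt, p_emt = p_emt, hr_met = hr_met, p_met = p_met,
         alpha = alpha, pass = length(reasons) == 0, reasons = reasons),
    class = "CriteriaResult")
}

#' @export
print.CriteriaResult <- function(x, ...) {
  cat(sprintf("CriteriaResult: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  EMT:        HR = %s, P = %s\n", format(x$hr_emt), format(x$p_emt)))
  cat(sprintf("  metabolism: HR = %s, P = %s\n", format(x$hr_met), format(x$p_met)))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Per-subgroup treatment-benefit assessment
#'
#' Fits a univariable Cox model of the treatment flag within each predicted
#' subgroup and assembles the treatment-benefit criteria.  A subgroup that is
#' empty, has a one-sided treatment arm, or has no events yields a flagged
#' inestimable entry (criteria fail) instead of an error, so selection loops
#' can continue.
#'
#' @param cohort a `PatientCohort` or clinical data.frame.
#' @param calls `SubgroupCalls` from [predict_subgroup()], or a vector of
#'   labels aligned with the cohort rows.
#' @param treatment_flag name of the 0/1 treatment column (default the
#'   cohort's `treatment_col`, typically "chemo").
#' @param confident_only drop non-confident calls before fitting
#'   (sensitivity analysis; default FALSE keeps all samples).
#' @return list with `criteria` (a `CriteriaResult`), `fits` (per-subgroup
#'   `CoxFit` or NULL), and `n_by_subgroup`.
#' @export
treatment_effect_by_subgroup <- function(cohort, calls, treatment_flag = NULL,
                                         confident_only = FALSE) {
  clin <- if (inherits(cohort, "PatientCohort")) cohort$clinical else cohort
  treatment_flag <- treatment_flag %||%
    (if (inherits(cohort, "PatientCohort")) cohort$treatment_col else "chemo")
  if (!treatment_flag %in% names(clin)) {
    stop("treatment column not found: ", treatment_flag)
  }
  if (is.data.frame(calls)) {
    idx <- match(clin$sample_id, calls$sample_id)
    if (anyNA(idx)) stop("calls missing for some cohort samples")
    lab <- as.character(calls$label)[idx]
    conf <- calls$confident[idx]
  } else {
    lab <- as.character(calls)
    conf <- rep(TRUE, length(lab))
    if (length(lab) != nrow(clin)) stop("calls length mismatch")
  }
  keep <- if (confident_only) conf else rep(TRUE, nrow(clin))

  one_subgroup <- function(sub) {
    d <- clin[keep & lab == sub, , drop = FALSE]
    if (nrow(d) < 2 || length(unique(d[[treatment_flag]])) < 2 ||
        sum(d$os_event %||% d$event) < 1) {
      return(list(fit = NULL, hr = NA_real_, p = NA_real_, n = nrow(d)))
    }
    fit <- tryCatch(cox_fit(d, treatment_flag),
                    error = function(e) NULL)
    if (is.null(fit) || fit$separation || !fit$converged) {
      return(list(fit = fit, hr = NA_real_, p = NA_real_, n = nrow(d)))
    }
    list(fit = fit, hr = fit$terms$hr[1], p = fit$terms$p[1], n = nrow(d))
  }
  emt <- one_subgroup("EMT")
  met <- one_subgroup("metabolism")
  list(criteria = criteria_result(emt$hr, emt$p, met$hr, met$p),
       fits = list(EMT = emt$fit, metabolism = met$fit),
       n_by_subgroup = c(EMT = emt$n, metabolism = met$n))
}

#' Multiplicative treatment-by-subgroup interaction
#'
#' Cox model with subgroup and treatment main effects plus their product
#' term (and optional adjusters); reports the interaction coefficient, its
#' exponential (the ratio of per-subgroup treatment HRs) and the Wald P.
#'
#' @param records survival records containing the two variables.
#' @param subgroup_col,treatment_col column names of the two binary factors.
#' @param adjust_covariates optional character vector of adjusters.
#' @return list with `coef`, `hr_ratio`, `ci`, `p`, and the full `CoxFit`.
#' @export
multiplicative_interaction <- function(records, subgroup_col, treatment_col,
                                       adjust_covariates = NULL) {
  d <- as_survival_df(records)
  for (v in c(subgroup_col, treatment_col)) {
    if (!v %in% names(d)) stop("column not found: ", v)
  }
  g <- interaction(d[[subgroup_col]], d[[treatment_col]], drop = FALSE)
  cell_events <- tapply(d$event, g, sum)
  if (any(is.na(cell_events)) || any(cell_events == 0)) {
    stop("every subgroup x treatment cell needs at least one event")
  }
  d$..sub <- factor(d[[subgroup_col]])
  d$..trt <- factor(d[[treatment_col]])
  rhs <- c("..sub * ..trt", adjust_covariates)
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(rhs, collapse = " + ")))
  dd <- d[complete.cases(d[, c("time", "event", "..sub", "..trt",
                               adjust_covariates), drop = FALSE]), ]
  fit <- survival::coxph(fml, data = dd, ties = "efron")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ix <- grep(":", names(cf))[1]
  if (is.na(ix)) stop("interaction term not estimable")
  z <- cf[ix] / se[ix]
  list(coef = unname(cf[ix]), hr_ratio = exp(unname(cf[ix])),
       ci = exp(unname(cf[ix]) + c(-1, 1) * qnorm(0.975) * se[ix]),
       p = 2 * pnorm(-abs(unname(z))),
       fit = fit)
}

#' Relative excess risk due to interaction (RERI) with delta-method CI
#'
#' From a Cox model with indicator terms for (subgroup only), (treatment
#' only) and (both), computes RERI = HR11 - HR10 - HR01 + 1; its variance by
#' the delta method on the coefficient covariance; Wald CI and P.  RERI = 0
#' under additivity of the two exposures on the hazard-ratio scale.
#'
#' @param records survival records.
#' @param subgroup_col,treatment_col binary exposure columns.  The "exposed"
#'   level of the subgroup is `metabolism` when labels are EMT/metabolism,
#'   otherwise the second factor level; treatment is exposed at 1.
#' @param adjust_covariates optional adjusters.
#' @return list with `reri`, `se`, `ci`, `p`, component HRs and the fit.
#' @export
reri <- function(records, subgroup_col, treatment_col,
                 adjust_covariates = NULL) {
  d <- as_survival_df(records)
  sub <- d[[subgroup_col]]
  sub01 <- if (all(na.omit(sub) %in% label_levels)) {
    as.integer(sub == "metabolism")
  } else if (is.numeric(sub)) {
    as.integer(sub != 0)
  } else {
    as.integer(factor(sub)) - 1L
  }
  trt01 <- as.integer(d[[treatment_col]] != 0)
  cells <- table(factor(sub01, 0:1), factor(trt01, 0:1))
  if (any(cells == 0)) stop("all four exposure cells must be populated")
  d$..e10 <- as.integer(sub01 == 1 & trt01 == 0)
  d$..e01 <- as.integer(sub01 == 0 & trt01 == 1)
  d$..e11 <- as.integer(sub01 == 1 & trt01 == 1)
  rhs <- c("..e10", "..e01", "..e11", adjust_covariates)
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(rhs, collapse = " + ")))
  dd <- d[complete.cases(d[, c("time", "event", rhs), drop = FALSE]), ]
  fit <- survival::coxph(fml, data = dd, ties = "efron")
  cf <- coef(fit)[c("..e10", "..e01", "..e11")]
  V <- vcov(fit)[c("..e10", "..e01", "..e11"), c("..e10", "..e01", "..e11")]
  if (anyNA(cf) || anyNA(V)) stop("inestimable exposure-cell coefficients")
  hr10 <- exp(cf[1]); hr01 <- exp(cf[2]); hr11 <- exp(cf[3])
  reri_hat <- unname(hr11 - hr10 - hr01 + 1)
  grad <- c(-hr10, -hr01, hr11)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- reri_hat + c(-1, 1) * qnorm(0.975) * se
  list(reri = reri_hat, se = unname(se), ci = unname(ci),
       p = 2 * pnorm(-abs(reri_hat / se)),
       hr10 = unname(hr10), hr01 = unname(hr01), hr11 = unname(hr11),
       fit = fit)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Correlation-type test of the scaled Schoenfeld residuals against
#' transformed event time (Kaplan-Meier transform by default), per covariate
#' and globally.
#'
#' @param fit a `CoxFit` (from [cox_fit()]) or a `coxph` object.
#' @param transform time transform: "km" (default), "rank", or "identity".
#' @return data.frame with rows per covariate plus GLOBAL: `chisq`, `df`,
#'   `p`.
#' @export
ph_check_schoenfeld <- function(fit, transform = c("km", "rank", "identity")) {
  transform <- match.arg(transform)
  obj <- if (inherits(fit, "CoxFit")) fit$object else fit
  if (!inherits(obj, "coxph")) stop("fit must be a CoxFit or coxph object")
  if (obj$nevent < length(coef(obj)) + 2) {
    stop("too few events for the Schoenfeld check")
  }
  zp <- survival::cox.zph(obj, transform = transform, global = TRUE)
  tab <- as.data.frame(zp$table)
  tab$term <- rownames(zp$table)
  rownames(tab) <- NULL
  tab[, c("term", "chisq", "df", "p")]
}

# Restricted cubic spline basis (Harrell parameterisation) for 3 knots:
# returns the single nonlinear term to add to the linear one.
rcs3_nonlinear <- function(x, knots) {
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp <- function(u) pmax(u, 0)^3
  (pp(x - t1) - pp(x - t2) * (t3 - t1) / (t3 - t2) +
      pp(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}

#' Linearity check of a continuous covariate via 3-knot restricted cubic spline
#'
#' Compares a linear-term Cox model against a 3-knot restricted-cubic-spline
#' model (knots at the 10th/50th/90th percentiles) with a likelihood-ratio
#' test on 1 df.  A small P indicates departure from log-linearity.
#'
#' @param records survival records.
#' @param continuous_covariate column name of the continuous predictor.
#' @param adjust_covariates optional adjusters present in both models.
#' @return list with `lr_stat`, `df`, `p`, `knots`, and both fits.
#' @export
linearity_check_rcs <- function(records, continuous_covariate,
                                adjust_covariates = NULL) {
  d <- as_survival_df(records)
  x <- d[[continuous_covariate]]
  if (is.null(x) || !is.numeric(x)) stop("continuous covariate not found/numeric")
  use <- complete.cases(d[, c("time", "event", continuous_covariate,
                              adjust_covariates), drop = FALSE])
  d <- d[use, , drop = FALSE]
  x <- d[[continuous_covariate]]
  if (length(unique(x)) < 4) {
    stop("need at least 4 distinct covariate values for 3-knot placement")
  }
  knots <- unname(quantile(x, c(0.1, 0.5, 0.9), type = 7))
  if (length(unique(knots)) < 3) stop("degenerate knots; covariate too discrete")
  d$..rcs <- rcs3_nonlinear(x, knots)
  rhs1 <- c(continuous_covariate, adjust_covariates)
  rhs2 <- c(continuous_covariate, "..rcs", adjust_covariates)
  f1 <- survival::coxph(as.formula(paste("survival::Surv(time, event) ~",
                                         paste(rhs1, collapse = " + "))),
                        data = d, ties = "efron")
  f2 <- survival::coxph(as.formula(paste("survival::Surv(time, event) ~",
                                         paste(rhs2, collapse = " + "))),
                        data = d, ties = "efron")
  lr <- 2 * (f2$loglik[2] - f1$loglik[2])
  df <- 1
  list(lr_stat = unname(lr), df = df,
       p = pchisq(lr, df = df, lower.tail = FALSE),
       knots = knots, fit_linear = f1, fit_spline = f2)
}

# Classic (mean-centred) Levene test for equality of variances.
levene_test <- function(x, g) {
  g <- factor(g)
  z <- abs(x - ave(x, g, FUN = mean))
  a <- anova(aov(z ~ g))
  list(statistic = a[["F value"]][1], p = a[["Pr(>F)"]][1])
}

#' Gated baseline-characteristic comparison between subgroups
#'
#' Continuous variables: Shapiro-Wilk normality (per subgroup) and classic
#' Levene equal-variance gates select Student's t-test (both pass, P >= 0.05)
#' or the Wilcoxon rank-sum test.  Categorical variables: Pearson chi-square
#' when all expected counts are >= 5, Fisher's exact otherwise.  All tests
#' two-sided.
#'
#' @param data data.frame of clinical variables.
#' @param group_col name of the two-level grouping column.
#' @param variables character vector of variables to compare (default: all
#'   columns except the group, IDs and outcome columns).
#' @param alpha gate significance level (default 0.05).
#' @return data.frame: `variable`, `type`, `test`, `statistic`, `p`.
#' @export
baseline_comparison <- function(data, group_col, variables = NULL,
                                alpha = 0.05) {
  if (inherits(data, "PatientCohort")) data <- data$clinical
  g <- factor(data[[group_col]])
  if (nlevels(droplevels(g)) != 2) stop("need exactly two subgroups")
  variables <- variables %||%
    setdiff(names(data), c(group_col, "sample_id", "cohort", "time", "event",
                           "os_months", "os_event", "latent_subgroup"))
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; gg <- droplevels(g[ok])
    if (length(unique(x)) < 2) {
      stop("variable constant in both groups: ", v)
    }
    if (is.numeric(x) && length(unique(x)) > 5) {
      sw_p <- vapply(split(x, gg), function(z) {
        if (length(z) < 3) return(0)
        if (length(z) > 5000) z <- z[seq_len(5000)]
        shapiro.test(z)$p.value
      }, numeric(1))
      lev <- levene_test(x, gg)
      if (all(sw_p >= alpha) && lev$p >= alpha) {
        tt <- t.test(x ~ gg, var.equal = TRUE)
        data.frame(variable = v, type = "continuous", test = "t",
                   statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- wilcox.test(x ~ gg, exact = FALSE)
        data.frame(variable = v, type = "continuous", test = "wilcoxon",
                   statistic = unname(wt$statistic), p = wt$p.value)
      }
    } else {
      tab <- table(factor(x), gg)
      expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
      if (all(expected >= 5)) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        data.frame(variable = v, type = "categorical", test = "chisq",
                   statistic = unname(ct$statistic), p = ct$p.value)
      } else {
        ft <- fisher.test(tab)
        data.frame(variable = v, type = "categorical", test = "fisher",
                   statistic = NA_real_, p = ft$p.value)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
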