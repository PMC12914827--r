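# Shared fixtures, built in code.  Heavier objects are memoised so several
# test files can reuse one trained ensemble.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# strongly separated panel + small ensemble used across classifier tests
strong_panel <- function() memo("strong_panel", {
  generate_cellline_panel(panel_spec(effect_size = 3, seed = 1))
})

small_model <- function() memo("small_model", {
  train_ensemble(strong_panel(), n_members = 50, seed = 1)
})

# plain exponential two-arm survival frame (no kinase machinery)
sim_surv <- function(n, hr = 1, median0 = 20, censor = Inf, seed = 1,
                     treat_rate = 0.5) {
  with_seed_test(seed, {
    trt <- rbinom(n, 1, treat_rate)
    lam <- log(2) / median0 * ifelse(trt == 1, hr, 1)
    t_ev <- rexp(n, lam)
    data.frame(time = pmin(t_ev, censor),
               event = as.integer(t_ev <= censor),
               trt = trt)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Efron/Breslow partial log-likelihood for untied single-covariate data;
# independent oracle for the Cox fitter.
cox_pl_oracle <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}
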