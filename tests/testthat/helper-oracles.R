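# Independent brute-force oracle for the 2-parameter (k, beta_temp) models:
# minimum negative log-likelihood over a dense log-spaced grid, computed
# straight from the model equations without the package's fitting path.
grid_nll_min <- function(records, model, n_k = 100, n_beta = 100,
                         k_range = c(1e-5, 2), beta_range = c(1e-3, 100)) {
  rec <- records[records$choice != "MISS", ]
  k_grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  b_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]), length.out = n_beta))
  disc <- function(k, d) if (model == "hyperbolic") 1 / (1 + k * d) else exp(-k * d)
  best <- Inf
  for (k in k_grid) {
    sv_ss <- rec$early_amount_usd * disc(k, rec$early_delay_days)
    sv_ll <- rec$late_amount_usd * disc(k, rec$late_delay_days)
    # signed value difference of the chosen option
    ds <- ifelse(rec$choice == "SS", sv_ss - sv_ll, sv_ll - sv_ss)
    p <- stats::plogis(outer(b_grid, ds))
    nll <- -rowSums(log(pmax(p, 1e-12)))
    best <- min(best, min(nll))
  }
  best
}

# Leave-one-out oracle for Cook's distance: D_i = sum_j (yhat_j - yhat_j(-i))^2
# / (p * s^2) computed by literally refitting without each point.
cooks_loo <- function(x, y) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  yhat <- stats::fitted(fit)
  p <- 2
  s2 <- sum(stats::residuals(fit)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    fi <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- cbind(1, x) %*% stats::coef(fi)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Shared simulated cohort at the study's cohort parameters, fitted once per
# test run and memoised (used by recovery, model-selection, and oracle tests).
.fixture_env <- new.env(parent = emptyenv())

recovery_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    records <- simulate_cohort(50, seed = 4242)
    fits_hyp <- fit_cohort(records, models = "hyperbolic")
    fits_rand <- fit_cohort(records, models = "random")
    truth <- dplyr::distinct(records, subject_id, true_ln_k)
    .fixture_env$cohort <- list(records = records, fits_hyp = fits_hyp,
                                fits_rand = fits_rand, truth = truth)
  }
  .fixture_env$cohort
}
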