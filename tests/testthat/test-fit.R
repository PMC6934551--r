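make_records <- function(n = 84, seed = 1, k = exp(-4.6), beta_temp = 3.74,
                         miss_rate = 0) {
  tr <- generate_trials(n, 2, seed = seed)
  ag <- dd_agent("hyperbolic", k = k, beta_temp = beta_temp,
                 miss_rate = miss_rate)
  simulate_choices(tr, ag, seed = seed + 1000)
}

test_that("negative log-likelihood matches closed forms", {
  rec <- make_records(84, seed = 21)
  # zero temperature: every choice has probability 1/2
  expect_equal(
    negative_log_likelihood(rec, "hyperbolic",
                            list(k = 0.01, beta_temp = 0)),
    84 * log(2)
  )
  expect_equal(negative_log_likelihood(rec, "random"), 84 * log(2))
  expect_equal(84 * log(2), 58.22436, tolerance = 1e-6)

  # two trials whose chosen option wins by exactly 1 SV unit at beta = 1
  two <- tibble::tibble(
    trial_index = 0:1, run_index = 0L, onset_s = c(0, 12),
    early_amount_usd = c(2, 2), late_amount_usd = c(1, 1),
    early_delay_days = 0, late_delay_days = 0,
    choice = c("SS", "SS"), rt_s = c(1, 1)
  )
  expect_equal(
    negative_log_likelihood(two, "hyperbolic", list(k = 1, beta_temp = 1)),
    -2 * log(exp(1) / (exp(1) + 1)),
    tolerance = 1e-12
  )
  expect_equal(-2 * log(exp(1) / (exp(1) + 1)), 0.62652, tolerance = 1e-5)

  miss_only <- dplyr::mutate(rec, choice = "MISS")
  expect_error(negative_log_likelihood(miss_only, "random"), "no non-miss")
})

test_that("BIC uses natural log of valid-trial count", {
  expect_equal(bic_score(-58.22436, 0, 84), 116.4487, tolerance = 1e-3)
  expect_equal(bic_score(-84 * log(2), 0, 84), 2 * 84 * log(2))
  expect_equal(bic_score(-20, 2, 84), 2 * log(84) + 40)
  expect_equal(2 * log(84) + 40, 48.8618, tolerance = 1e-4)
  expect_equal(bic_score(0, 0, 1), 0)
  expect_error(bic_score(-1, 2, 0), "at least 1")
})

test_that("deterministic predictions use the SV comparison with ties to LL", {
  rec <- make_records(84, seed = 22)
  pred <- predict_choices(rec, "hyperbolic", list(k = 1e-9))
  expect_true(all(pred == "LL"))  # negligible discounting: LL always larger

  one <- tibble::tibble(
    trial_index = 0L, run_index = 0L, onset_s = 0,
    early_amount_usd = 15, late_amount_usd = 20,
    early_delay_days = 0, late_delay_days = 14,
    choice = "LL", rt_s = 1
  )
  expect_equal(predict_choices(one, "hyperbolic", list(k = 1)), "SS")
  # exact tie: 10 now vs 20 at the delay where 20/(1+kD) = 10
  tie <- dplyr::mutate(one, early_amount_usd = 10, late_delay_days = 10)
  expect_equal(predict_choices(tie, "hyperbolic", list(k = 0.1)), "LL")
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c(tSS = 3, fSS = 1, tLL = 4, fLL = 2)),
               0.5 * (3 / 4 + 4 / 6))
  expect_equal(round(balanced_accuracy(c(tSS = 3, fSS = 1, tLL = 4, fLL = 2)), 4),
               0.7083)
  expect_equal(balanced_accuracy(c(tSS = 10, fSS = 0, tLL = 7, fLL = 0)), 1)
  deg <- balanced_accuracy(c(tSS = 0, fSS = 0, tLL = 6, fLL = 2))
  expect_equal(as.numeric(deg), 0.75)
  expect_true(attr(deg, "degenerate"))
  expect_error(balanced_accuracy(c(tSS = 0, fSS = 0, tLL = 0, fLL = 0)),
               "no trials")

  cc <- confusion_counts(c("SS", "SS", "LL"), c("SS", "LL", "LL"))
  expect_equal(cc, c(tSS = 1L, fSS = 1L, tLL = 1L, fLL = 0L))
})

test_that("proportion sooner excludes misses", {
  rec <- tibble::tibble(
    trial_index = 0:11, run_index = 0L, onset_s = 12 * (0:11),
    early_amount_usd = 10, late_amount_usd = 20,
    early_delay_days = 0, late_delay_days = 14,
    choice = c(rep("SS", 5), rep("LL", 5), "MISS", "MISS"),
    rt_s = c(rep(1, 10), NA, NA)
  )
  expect_equal(proportion_sooner(rec), 0.5)
  expect_equal(proportion_sooner(dplyr::mutate(rec, choice = "SS")), 1)
  expect_error(proportion_sooner(dplyr::mutate(rec, choice = "MISS")),
               "no valid")
})

test_that("the random baseline has a closed-form fit with zero parameters", {
  rec <- make_records(84, seed = 23)
  f <- fit_model(rec, "random")
  expect_equal(f$ll_max, -84 * log(2))
  expect_equal(f$n_params, 0L)
  expect_equal(f$bic, 2 * 84 * log(2))
  expect_true(is.na(f$ln_k))
})

test_that("multi-start fitting recovers a known discount rate", {
  rec <- make_records(84, seed = 7, k = exp(-4.6), beta_temp = 3.74)
  f <- fit_model(rec, "hyperbolic")
  expect_lt(abs(f$ln_k - (-4.6)), 0.75)
  expect_gt(f$n_starts_converged, 0)
  expect_lte(f$ll_max, 0)
  expect_equal(f$bic, 2 * log(f$n_valid) - 2 * f$ll_max)
  expect_equal(f$ln_k, log(f$params$k))

  td <- tidy(f)
  expect_equal(td$term, c("k", "beta_temp"))
  gl <- glance(f)
  expect_equal(gl$bic, f$bic)
  expect_error(fit_model(rec[1:5, ], "hyperbolic"), "valid trials")
})

test_that("fitted optima beat an exhaustive dense grid search", {
  for (s in c(31, 32)) {
    rec <- make_records(84, seed = s)
    for (model in c("hyperbolic", "exponential")) {
      f <- fit_model(rec, model)
      oracle <- grid_nll_min(rec, model, n_k = 60, n_beta = 60)
      expect_lte(-f$ll_max, oracle + 1e-4)
    }
  }
})

test_that("all six families fit the same subject and fill the fit table", {
  rec <- dplyr::mutate(make_records(84, seed = 33), subject_id = "sub-01")
  fits <- fit_cohort(rec, models = dd_models())
  expect_equal(nrow(fits), 6)
  expect_setequal(fits$model, dd_models())
  expect_true(all(fits$ll_max <= 0))
  expect_true(all(fits$bic ==
                    fits$n_params * log(fits$n_valid) - 2 * fits$ll_max))
  # beta-delta and discounted utility pay a 3-parameter penalty
  expect_equal(fits$n_params[fits$model == "beta_delta"], 3L)
  expect_equal(fits$n_params[fits$model == "random"], 0L)
})

test_that("model comparison computes paired t statistics by hand rules", {
  fits <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), 2),
    model = rep(c("hyperbolic", "exponential"), each = 3),
    bic = c(1, 2, 3, 2, 3, 5),
    balanced_accuracy = rep(0.8, 6)
  )
  cmp <- compare_models(fits, reference = "hyperbolic")
  other <- cmp[cmp$model == "exponential", ]
  expect_equal(other$t, -4)
  expect_equal(other$df, 2L)
  expect_equal(other$p, 2 * pt(-4, df = 2))
  expect_equal(cmp$mean_bic[cmp$model == "hyperbolic"], 2)

  same <- dplyr::mutate(fits, bic = rep(c(1, 2, 3), 2))
  cmp0 <- compare_models(same, reference = "hyperbolic")
  expect_equal(cmp0$t[cmp0$model == "exponential"], 0)
  expect_true(cmp0$zero_variance[cmp0$model == "exponential"])

  # cross-check the t statistic against stats::t.test
  tt <- t.test(c(1, 2, 3), c(2, 3, 5), paired = TRUE)
  expect_equal(other$t, unname(tt$statistic))

  misaligned <- fits[-1, ]
  expect_error(compare_models(misaligned, reference = "hyperbolic"),
               "misaligned")
})

test_that("cohort summary mirrors the sample-characteristics layout", {
  fits <- tibble::tibble(
    subject_id = rep(c("a", "b"), 2),
    model = rep(c("hyperbolic", "random"), each = 2),
    bic = c(30, 32, 116, 117),
    balanced_accuracy = c(0.8, 0.7, 0.5, 0.5),
    ln_k = c(-4, -5, NA, NA),
    beta_temp = c(3, 4, NA, NA),
    prop_sooner = c(0.5, 0.6, 0.5, 0.6)
  )
  sm <- summarize_cohort(fits)
  lnk_row <- sm[sm$variable == "ln_k_hyperbolic", ]
  expect_equal(lnk_row$mean, -4.5)
  expect_equal(lnk_row$sd, sd(c(-4, -5)))
  expect_setequal(
    sm$variable,
    c("prop_sooner", "ln_k_hyperbolic", "beta_temp_hyperbolic",
      "bic_hyperbolic", "bic_random")
  )
  expect_error(summarize_cohort(fits[c(1, 3), ]), "at least 2")
})
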