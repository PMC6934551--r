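test_that("Fisher-z intervals reproduce closed-form and reported values", {
  ci0 <- fisher_ci(0, 403)
  expect_equal(unname(ci0), c(-1, 1) * tanh(qnorm(0.975) / 20))
  expect_equal(round(unname(ci0), 4), c(-0.0977, 0.0977))
  expect_error(fisher_ci(1, 20), "\\|r\\| < 1")
  expect_error(fisher_ci(0.5, 3), "at least 4")
})

test_that("standardized simple regression equals Pearson r with t-test p", {
  set.seed(101)
  n <- 22
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n)
  res <- standardized_regression(d, "x", "y")
  expect_equal(res$std_beta, cor(d$x, d$y), tolerance = 1e-12)
  r <- res$std_beta
  expect_equal(res$p, 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
  # cross-check against lm on z-scores
  lm_beta <- unname(coef(lm(scale(d$y) ~ scale(d$x)))[2])
  expect_equal(res$std_beta, lm_beta, tolerance = 1e-12)
  expect_true(res$ci_low < res$std_beta & res$std_beta < res$ci_high)

  exact <- standardized_regression(dplyr::mutate(d, y = x * 2 + 1), "x", "y")
  expect_equal(exact$std_beta, 1, tolerance = 1e-12)
  expect_lt(exact$p, 1e-12)

  expect_error(standardized_regression(dplyr::mutate(d, x = 1), "x", "y"),
               "zero variance")
  expect_error(standardized_regression(d, "nope", "y"), "not found")
})

test_that("null calibration: |std_beta| quantile matches the Fisher-z law", {
  set.seed(202)
  n <- 22
  reps <- 1000
  r <- replicate(reps, cor(rnorm(n), rnorm(n)))
  # 95th percentile of |r| under the null vs the Fisher-z prediction
  pred <- tanh(qnorm(0.975) / sqrt(n - 3))
  expect_lt(abs(quantile(abs(r), 0.95) - pred), 0.05)
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroni_alpha(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_alpha(0.05, 12), 6), 0.004167)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("influence diagnostics flag a planted gross outlier and match a
           leave-one-out oracle", {
  # 21 near-collinear points plus one gross vertical outlier
  x <- c(seq(1, 21), 11)
  y <- c(2 * seq(1, 21) + 0.001 * rep_len(c(1, -1), 21), 2 * 11 + 40)
  d <- tibble::tibble(x = x, y = y)
  diag <- outlier_diagnostics(d, "x", "y")
  expect_equal(which(diag$influential), 22L)
  expect_equal(sum(diag$influential), 1)

  # near-linear data with equal-magnitude alternating residuals: no point
  # stands out, so nothing is flagged influential
  d2 <- tibble::tibble(x = 1:20,
                       y = 3 + 0.5 * (1:20) + 0.01 * rep(c(1, -1), 10))
  diag2 <- outlier_diagnostics(d2, "x", "y")
  expect_false(any(diag2$influential))

  # Cook's distances equal brute-force leave-one-out refits
  set.seed(302)
  x3 <- rnorm(15); y3 <- 1 + x3 + rnorm(15)
  d3 <- tibble::tibble(x = x3, y = y3)
  diag3 <- outlier_diagnostics(d3, "x", "y")
  expect_equal(diag3$cooks_d, cooks_loo(x3, y3), tolerance = 1e-10)
})

test_that("removing a flagged point shifts the estimate as its influence
           predicts", {
  set.seed(303)
  n <- 21
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, sd = 0.5)
  x <- c(x, 3); y <- c(y, -4)  # influential low-y point at high x
  d <- tibble::tibble(x = x, y = y)
  diag <- outlier_diagnostics(d, "x", "y")
  stopifnot(any(diag$influential))
  full <- standardized_regression(d, "x", "y")$std_beta
  drop <- standardized_regression(d[!diag$influential, ], "x", "y")$std_beta
  expect_gt(drop, full)  # excluding the low outlier strengthens the slope
  expect_gt(max(diag$cooks_d[diag$influential]), 4 * mean(diag$cooks_d))
})

test_that("covariate adjustment returns the partial standardized effect", {
  set.seed(304)
  n <- 40
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  # build covariates exactly orthogonal to x and y
  raw <- cbind(rnorm(n), rnorm(n))
  covs <- qr.resid(qr(cbind(1, x, y)), raw)
  d <- tibble::tibble(x = x, y = y, age = covs[, 1], sexn = covs[, 2])
  adj <- adjusted_regression(d, "x", "y", covariates = c("age", "sexn"))
  simple <- standardized_regression(d, "x", "y")
  expect_equal(adj$std_beta, simple$std_beta, tolerance = 1e-6)

  d2 <- tibble::tibble(x = x, y = y, x2 = x, sex = rep(c("F", "M"), n / 2))
  expect_error(adjusted_regression(d2, "x", "y", covariates = c("x2")),
               "rank-deficient")

  # planted partial effect recovers at large n
  set.seed(305)
  n <- 200
  age <- rnorm(n); sex <- rep(c("F", "M"), n / 2)
  xx <- rnorm(n) + 0.3 * age
  yy <- 0.5 * xx + 0.4 * age + rnorm(n) * sqrt(1 - 0.5^2)
  d3 <- tibble::tibble(x = xx, y = yy, age = age, sex = sex)
  adj3 <- adjusted_regression(d3, "x", "y")
  expect_lt(abs(adj3$std_beta - 0.5 * sd(xx) / sd(yy)), 0.1)
})

test_that("the association grid covers 3 x 4 PET-fMRI pairs at the corrected
           threshold", {
  tab <- simulate_subject_table(22, seed = 55)
  grid <- run_association_grid(tab)
  expect_equal(nrow(grid), 12)
  expect_true(all(grid$alpha == 0.05 / 12))
  expect_true(all(grid$family_size == 12))
  expect_equal(grid$significant, grid$p < 0.05 / 12)

  single <- run_association_grid(tab, pet_rois = "vs", fmri_rois = "vmpfc")
  expect_equal(nrow(single), 1)
  expect_equal(single$alpha, 0.05)

  beh <- run_association_grid(tab, behaviors = c("ln_k", "prop_sooner"))
  expect_equal(nrow(beh), 12 + 3 * 2 + 4 * 2)
  expect_true(all(beh$alpha[beh$family != "pet_x_fmri"] == 0.05))
  expect_equal(unique(beh$family_size[beh$family == "pet_x_behavior"]), 6)

  expect_error(run_association_grid(dplyr::select(tab, -bp_vs)),
               "missing column")
})

test_that("a planted association outranks eleven null pairs most of the time", {
  hits <- 0L
  reps <- 300
  for (i in seq_len(reps)) {
    tab <- simulate_subject_table(
      22, seed = 7000 + i,
      planted = list(predictor = "bp_vs", outcome = "sv_vmpfc", r = 0.7)
    )
    grid <- run_association_grid(tab)
    best <- grid[which.min(grid$p), ]
    hits <- hits + (best$predictor == "bp_vs" && best$outcome == "sv_vmpfc")
  }
  expect_gte(hits / reps, 0.9)
})

test_that("family-wise error of the Bonferroni grid stays controlled under
           the null", {
  set.seed(606)
  n <- 22
  reps <- 2000
  thr <- bonferroni_alpha(0.05, 12)
  crit_r <- sqrt(qt(thr / 2, n - 2, lower.tail = FALSE)^2 /
                   (n - 2 + qt(thr / 2, n - 2, lower.tail = FALSE)^2))
  fw <- replicate(reps, {
    pet <- matrix(rnorm(n * 3), n)
    fmri <- matrix(rnorm(n * 4), n)
    any(abs(cor(pet, fmri)) > crit_r)
  })
  expect_lte(mean(fw), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("synthetic subject tables mirror the cohort's marginal structure", {
  tab <- simulate_subject_table(2000, seed = 77)
  expect_true(all(tab$bp_vs > 0 & tab$bp_midbrain > 0 & tab$bp_vmpfc > 0))
  expect_lt(abs(mean(tab$bp_vs) - 17.3), 0.3)
  expect_lt(abs(mean(tab$ln_k) - (-4.68)), 0.15)
  expect_gt(cor(tab$ln_k, tab$prop_sooner), 0.8)
  expect_identical(simulate_subject_table(22, seed = 5),
                   simulate_subject_table(22, seed = 5))
})
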