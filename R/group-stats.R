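#' Fisher-z confidence interval for a correlation
#'
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{level} / \sqrt{n - 3})}: the
#' variance-stabilised interval whose asymmetry about r matches the intervals
#' reported for standardized simple-regression coefficients (which equal
#' Pearson r).
#'
#' @param r Sample correlation, `|r| < 1`.
#' @param n Sample size, at least 4.
#' @param level Confidence level (default 0.95).
#' @return A named numeric vector `c(low, high)`.
#' @examples
#' fisher_ci(0.911, 22)  # c(0.794, 0.963)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (abs(r) >= 1) stop("`r` must satisfy |r| < 1", call. = FALSE)
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(low = tanh(z - half), high = tanh(z + half))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests in the family, at least 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 12)  # 0.004167
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  alpha / m
}

#' Standardized simple regression with Fisher-z interval
#'
#' Regresses the z-scored outcome on the z-scored predictor. In the simple
#' (no-covariate) case the standardized slope equals Pearson r; its p-value
#' comes from the t distribution with n − 2 degrees of freedom and its 95%
#' interval from the Fisher z-transform. Per-point influence diagnostics
#' ([outlier_diagnostics()]) are attached as a list-column.
#'
#' @param data Data frame of subject rows.
#' @param predictor,outcome Column names (strings).
#' @param alpha Significance threshold the `significant` flag uses (pass a
#'   Bonferroni-adjusted value for family-corrected decisions).
#' @param level Confidence level of the interval.
#' @return One-row tibble: `predictor`, `outcome`, `n`, `std_beta`, `ci_low`,
#'   `ci_high`, `p`, `alpha`, `significant`, `outliers` (list-column of the
#'   diagnostics tibble).
#' @export
standardized_regression <- function(data, predictor, outcome, alpha = 0.05,
                                    level = 0.95) {
  x <- data[[predictor]]
  y <- data[[outcome]]
  if (is.null(x) || is.null(y)) {
    stop("column not found: ", if (is.null(x)) predictor else outcome,
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in inputs", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance in predictor or outcome",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  # a numerically perfect correlation still gets a (collapsed) interval
  r_ci <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  ci <- fisher_ci(r_ci, n, level)
  diag <- outlier_diagnostics(data, predictor, outcome)
  tibble::tibble(
    predictor = predictor, outcome = outcome, n = n,
    std_beta = r, ci_low = ci[["low"]], ci_high = ci[["high"]], p = p,
    alpha = alpha, significant = p < alpha,
    outliers = list(diag)
  )
}

#' Bivariate influence and outlier diagnostics
#'
#' Fits `outcome ~ predictor` by least squares and reports, per point:
#' Cook's distance with a flag at 4x the mean distance, the externally
#' studentized residual with a two-sided p-value against t with n − 3 df,
#' and the model-level Breusch-Pagan heteroskedasticity p-value (constant
#' across rows). A point is marked `influential` only when the Cook's flag
#' and the studentized-residual test (p < 0.05) agree; single-criterion flags
#' are reported but points are never dropped automatically.
#'
#' @param data Data frame of subject rows.
#' @param predictor,outcome Column names (strings).
#' @return A tibble with one row per observation: `row`, `subject_id` (if
#'   present in `data`), `cooks_d`, `cooks_flag`, `studentized`,
#'   `studentized_p`, `studentized_flag`, `bp_p`, `influential`.
#' @export
outlier_diagnostics <- function(data, predictor, outcome) {
  x <- data[[predictor]]
  y <- data[[outcome]]
  n <- length(x)
  if (n < 5) stop("need at least 5 observations for diagnostics", call. = FALSE)
  fit <- stats::lm(y ~ x)
  if (fit$rank < 2) stop("degenerate design", call. = FALSE)
  cd <- stats::cooks.distance(fit)
  rs <- stats::rstudent(fit)
  rs_p <- 2 * stats::pt(-abs(rs), df = n - 3)
  bp <- lmtest::bptest(fit)$p.value
  cooks_flag <- cd > 4 * mean(cd)
  stud_flag <- rs_p < 0.05
  tibble::tibble(
    row = seq_len(n),
    subject_id = if ("subject_id" %in% names(data)) data$subject_id else NA_character_,
    cooks_d = as.numeric(cd),
    cooks_flag = unname(cooks_flag),
    studentized = as.numeric(rs),
    studentized_p = as.numeric(rs_p),
    studentized_flag = unname(stud_flag),
    bp_p = as.numeric(bp),
    influential = unname(cooks_flag & stud_flag)
  )
}

#' Covariate-adjusted standardized regression
#'
#' Multiple least squares of the z-scored outcome on the z-scored predictor
#' plus covariates of no interest (continuous covariates z-scored; a
#' character/factor `sex` column becomes a 0/1 indicator). The reported
#' coefficient is the standardized partial effect of the predictor, with a
#' t-based Wald interval and p-value.
#'
#' @param data Data frame of subject rows.
#' @param predictor,outcome Column names (strings).
#' @param covariates Character vector of covariate column names
#'   (default `c("age", "sex")`).
#' @param alpha Significance threshold for the `significant` flag.
#' @param level Confidence level.
#' @return One-row tibble as [standardized_regression()] (without the
#'   diagnostics list-column), plus `covariates`.
#' @export
adjusted_regression <- function(data, predictor, outcome,
                                covariates = c("age", "sex"), alpha = 0.05,
                                level = 0.95) {
  n <- nrow(data)
  if (n <= length(covariates) + 2) {
    stop("too few observations for the adjusted model", call. = FALSE)
  }
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  X <- cbind(x = zscore(data[[predictor]]))
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate column not found: ", cv, call. = FALSE)
    v <- if (is.numeric(v)) zscore(v) else as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  y <- zscore(data[[outcome]])
  fit <- stats::lm(y ~ X)
  if (fit$rank < ncol(X) + 1) {
    stop("rank-deficient design: predictor and covariates are collinear",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  est <- sm["Xx", "Estimate"]
  se <- sm["Xx", "Std. Error"]
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - level) / 2, df)
  p <- sm["Xx", "Pr(>|t|)"]
  tibble::tibble(
    predictor = predictor, outcome = outcome, n = n,
    covariates = paste(covariates, collapse = "+"),
    std_beta = est, ci_low = est - tq * se, ci_high = est + tq * se,
    p = p, alpha = alpha, significant = p < alpha
  )
}

#' Run the PET x fMRI association grid
#'
#' One standardized regression per PET-ROI binding-potential column crossed
#' with each fMRI subjective-value column, Bonferroni-corrected as a single
#' family (3 x 4 = 12 tests at the default ROIs, threshold 0.05/12 ≈ 0.004).
#' Optional behaviour columns (e.g. `ln_k`, `prop_sooner`) are each crossed
#' with the PET and fMRI columns as separate, uncorrected families whose
#' family sizes are still recorded in the output.
#'
#' @param data Subject table (one row per subject) with `bp_<roi>` and
#'   `sv_<roi>` columns; see [simulate_subject_table()].
#' @param pet_rois,fmri_rois ROI names; column names are formed as
#'   `paste0("bp_", pet_rois)` and `paste0("sv_", fmri_rois)`.
#' @param behaviors Optional character vector of behaviour column names.
#' @param alpha Family-wise alpha before correction.
#' @return A tibble of association results with `family`, `family_size`, and
#'   the per-test columns of [standardized_regression()].
#' @export
run_association_grid <- function(data,
                                 pet_rois = c("vs", "midbrain", "vmpfc"),
                                 fmri_rois = c("vs", "midbrain", "vmpfc", "pcc"),
                                 behaviors = NULL, alpha = 0.05) {
  pet_cols <- paste0("bp_", pet_rois)
  fmri_cols <- paste0("sv_", fmri_rois)
  absent <- setdiff(c(pet_cols, fmri_cols, behaviors), names(data))
  if (length(absent) > 0) {
    stop("subject table is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pairs <- tidyr::expand_grid(predictor = pet_cols, outcome = fmri_cols)
  m <- nrow(pairs)
  thr <- bonferroni_alpha(alpha, m)
  main <- purrr::pmap_dfr(pairs, function(predictor, outcome) {
    standardized_regression(data, predictor, outcome, alpha = thr) |>
      dplyr::mutate(family = "pet_x_fmri", family_size = m, .before = 1)
  })
  beh <- NULL
  if (!is.null(behaviors)) {
    beh_pairs <- dplyr::bind_rows(
      tidyr::expand_grid(family = "pet_x_behavior", predictor = pet_cols,
                         outcome = behaviors),
      tidyr::expand_grid(family = "fmri_x_behavior", predictor = fmri_cols,
                         outcome = behaviors)
    )
    beh <- purrr::pmap_dfr(beh_pairs, function(family, predictor, outcome) {
      fam_m <- sum(beh_pairs$family == family)
      standardized_regression(data, predictor, outcome, alpha = alpha) |>
        dplyr::mutate(family = family, family_size = fam_m, .before = 1)
    })
  }
  dplyr::bind_rows(main, beh)
}

#' Simulate a subject-level scalar table
#'
#' Synthetic stand-in for the per-subject table the association stage
#' consumes: PET binding potentials (BP_ND) at the study sample's means and
#' SDs (VS 17.3 ± 2.90, midbrain 1.50 ± 0.236, vmPFC 0.762 ± 0.139,
#' truncated positive), fMRI subjective-value parameter estimates (percent
#' signal change, standard normal scaled by 0.1), discounting behaviour
#' (Ln(k) ~ N(−4.68, 1.27), proportion-sooner strongly correlated with it),
#' age ~ N(20.9, 1.95), and sex at the sample's 12F/10M ratio. All variables
#' are mutually independent unless an association is planted with
#' `planted = list(predictor =, outcome =, r =)`, which regenerates the
#' outcome column with the requested population correlation to the predictor
#' while preserving its marginal mean and SD.
#'
#' @param n Number of subjects (default 22, the analysed sample size).
#' @param seed Integer seed.
#' @param planted Optional planted association (see above).
#' @return A tibble with columns `subject_id`, `bp_vs`, `bp_midbrain`,
#'   `bp_vmpfc`, `sv_vs`, `sv_midbrain`, `sv_vmpfc`, `sv_pcc`, `ln_k`,
#'   `prop_sooner`, `age`, `sex`.
#' @export
simulate_subject_table <- function(n = 22, seed, planted = NULL) {
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    lnk <- stats::rnorm(n, -4.68, 1.27)
    z <- (lnk - mean(lnk)) / stats::sd(lnk)
    ps <- 0.550 + 0.212 * (0.911 * z + sqrt(1 - 0.911^2) * stats::rnorm(n))
    out <- tibble::tibble(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      bp_vs = rtruncnorm(n, 17.3, 2.90, 0.01, Inf),
      bp_midbrain = rtruncnorm(n, 1.50, 0.236, 0.01, Inf),
      bp_vmpfc = rtruncnorm(n, 0.762, 0.139, 0.01, Inf),
      sv_vs = stats::rnorm(n, 0, 0.1),
      sv_midbrain = stats::rnorm(n, 0, 0.1),
      sv_vmpfc = stats::rnorm(n, 0, 0.1),
      sv_pcc = stats::rnorm(n, 0, 0.1),
      ln_k = lnk,
      prop_sooner = pmin(pmax(ps, 0), 1),
      age = stats::rnorm(n, 20.9, 1.95),
      sex = sample(c(rep("F", ceiling(n * 12 / 22)),
                     rep("M", n - ceiling(n * 12 / 22))))
    )
    if (!is.null(planted)) {
      stopifnot(all(c("predictor", "outcome", "r") %in% names(planted)))
      xp <- out[[planted$predictor]]
      yo <- out[[planted$outcome]]
      zx <- (xp - mean(xp)) / stats::sd(xp)
      eps <- stats::rnorm(n)
      mix <- planted$r * zx + sqrt(1 - planted$r^2) * eps
      out[[planted$outcome]] <- mean(yo) + stats::sd(yo) *
        (mix - mean(mix)) / stats::sd(mix)
    }
    out
  })
}
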