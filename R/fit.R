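#' Fitting configuration
#'
#' Controls the multi-start Nelder-Mead maximum-likelihood fit. Starts are the
#' Cartesian product of per-parameter grids (value-function parameters crossed
#' with the inverse-temperature grid); optimisation runs in log-parameter
#' space so positivity constraints hold by construction, and the best
#' converged start wins (ties broken by lowest negative log-likelihood, then
#' lexicographic parameter order).
#'
#' @param k_grid,beta_temp_grid,r_grid,s_grid,beta_dd_grid,delta_grid Start
#'   grids for each parameter (on the natural scale).
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param prob_floor Floor applied to choice probabilities before taking logs,
#'   preventing infinite negative log-likelihoods at extreme temperatures.
#' @param min_valid Minimum number of non-miss trials required to fit.
#' @param beta_temp_flag Fitted temperatures above this raise the
#'   `unbounded_beta` flag (the likelihood has plateaued in the
#'   near-deterministic regime).
#' @param seed Seed for the random baseline's coin-flip predictions (its
#'   balanced accuracy is stochastic by definition).
#' @return A list of class `dd_fit_config`.
#' @export
fit_config <- function(k_grid = c(1e-4, 1e-3, 1e-2, 0.1, 1),
                       beta_temp_grid = c(0.1, 1, 10),
                       r_grid = c(0.01, 0.1, 1),
                       s_grid = c(0.5, 1, 2),
                       beta_dd_grid = c(1e-3, 1e-2, 0.1),
                       delta_grid = c(1e-3, 1e-2, 0.1),
                       reltol = 1e-6, maxit = 2000,
                       prob_floor = 1e-12, min_valid = 10,
                       beta_temp_flag = 100, seed = 1L) {
  structure(as.list(environment()), class = "dd_fit_config")
}

# subjective values of both options for non-miss records under one model
sv_pair <- function(records, model, params) {
  list(
    ss = subjective_value(model, records$early_amount_usd,
                          records$early_delay_days, params),
    ll = subjective_value(model, records$late_amount_usd,
                          records$late_delay_days, params)
  )
}

valid_records <- function(records) {
  records[records$choice != "MISS", , drop = FALSE]
}

#' Negative log-likelihood of choices under a value model
#'
#' Sums \eqn{-\log p(\text{chosen option})} over non-miss trials, with the
#' softmax probability of the chosen option floored at `prob_floor`. The
#' random baseline assigns probability 0.5 to every choice, contributing
#' \eqn{\log 2} per valid trial.
#'
#' @param records Choice-record tibble (misses are excluded internally).
#' @param model Model family name.
#' @param params Named list/vector with the family's value parameters and
#'   `beta_temp` (not needed for `"random"`).
#' @param prob_floor Probability floor before the log.
#' @return The negative log-likelihood in nats (non-negative).
#' @export
negative_log_likelihood <- function(records, model, params = list(),
                                    prob_floor = 1e-12) {
  model <- match.arg(model, dd_models())
  rec <- valid_records(records)
  if (nrow(rec) == 0) stop("no non-miss trials to evaluate", call. = FALSE)
  if (model == "random") return(nrow(rec) * log(2))
  p <- as.list(params)
  if (is.null(p$beta_temp)) stop("`params` must include beta_temp", call. = FALSE)
  sv <- sv_pair(rec, model, p)
  p_ss <- choice_probability(sv$ss, sv$ll, p$beta_temp)
  p_chosen <- ifelse(rec$choice == "SS", p_ss, 1 - p_ss)
  -sum(log(pmax(p_chosen, prob_floor)))
}

#' Bayesian Information Criterion
#'
#' \eqn{BIC = p \ln(n) - 2 \ell_{max}} with natural logarithm, `p` free
#' parameters, and `n` the number of valid (non-miss) trials. Lower is better.
#'
#' @param ll_max Maximised log-likelihood (nats, non-positive for discrete
#'   choice data).
#' @param n_params Number of free parameters.
#' @param n_valid Number of valid trials, at least 1.
#' @return The BIC score.
#' @export
bic_score <- function(ll_max, n_params, n_valid) {
  if (any(n_valid < 1)) stop("`n_valid` must be at least 1", call. = FALSE)
  n_params * log(n_valid) - 2 * ll_max
}

#' Deterministic choice predictions from fitted parameters
#'
#' Predicts smaller-sooner (`"SS"`) whenever the model's subjective value of
#' the early option strictly exceeds that of the late option, and
#' larger-later (`"LL"`) otherwise — exact ties go to LL, whose face amount
#' is strictly larger. Miss trials are excluded.
#'
#' @param records Choice-record tibble.
#' @param model Model family name (not `"random"`, whose predictions are coin
#'   flips, not value comparisons).
#' @param params Named value parameters for the family.
#' @return Character vector of `"SS"`/`"LL"`, one per non-miss trial.
#' @export
predict_choices <- function(records, model, params) {
  rec <- valid_records(records)
  sv <- sv_pair(rec, model, params)
  ifelse(sv$ss > sv$ll, "SS", "LL")
}

#' Confusion counts and balanced accuracy
#'
#' `confusion_counts()` tallies predictions against actual choices: `tSS`
#' (actual SS, predicted SS), `fSS` (actual SS, mispredicted), `tLL`, `fLL`
#' likewise. `balanced_accuracy()` is the mean per-class recall,
#' \eqn{\frac{1}{2}(tSS/(tSS+fSS) + tLL/(tLL+fLL))}, which does not assume
#' the two preference classes are balanced. If one class is absent the
#' present class's recall is returned with attribute `degenerate = TRUE`.
#'
#' @param actual,predicted Character vectors of `"SS"`/`"LL"` labels.
#' @param counts Named vector/list with `tSS`, `fSS`, `tLL`, `fLL`.
#' @return `confusion_counts()`: a named integer vector.
#'   `balanced_accuracy()`: a proportion in \[0, 1\].
#' @examples
#' balanced_accuracy(c(tSS = 3, fSS = 1, tLL = 4, fLL = 2))  # 0.70833
#' @export
confusion_counts <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  c(tSS = sum(actual == "SS" & predicted == "SS"),
    fSS = sum(actual == "SS" & predicted != "SS"),
    tLL = sum(actual == "LL" & predicted == "LL"),
    fLL = sum(actual == "LL" & predicted != "LL"))
}

#' @rdname confusion_counts
#' @export
balanced_accuracy <- function(counts) {
  counts <- unlist(counts)
  tSS <- counts[["tSS"]]; fSS <- counts[["fSS"]]
  tLL <- counts[["tLL"]]; fLL <- counts[["fLL"]]
  n_ss <- tSS + fSS
  n_ll <- tLL + fLL
  if (n_ss + n_ll == 0) stop("no trials to score", call. = FALSE)
  if (n_ss == 0 || n_ll == 0) {
    ba <- if (n_ss == 0) tLL / n_ll else tSS / n_ss
    return(structure(ba, degenerate = TRUE))
  }
  (tSS / n_ss + tLL / n_ll) / 2
}

#' Proportion of smaller-sooner choices
#'
#' SS / (SS + LL) over valid trials; misses are excluded from both numerator
#' and denominator.
#'
#' @param records Choice-record tibble.
#' @return A proportion in \[0, 1\].
#' @export
proportion_sooner <- function(records) {
  rec <- valid_records(records)
  if (nrow(rec) == 0) stop("no valid trials", call. = FALSE)
  mean(rec$choice == "SS")
}

#' Fit one value model to one participant's choices
#'
#' Maximum-likelihood estimation under the softmax choice rule, via
#' Nelder-Mead in log-parameter space from a deterministic multi-start grid
#' (see [fit_config()]). The random baseline has no free parameters and a
#' closed-form likelihood. The returned object carries the MLE, the maximised
#' log-likelihood, BIC, balanced accuracy of the MLE's deterministic choice
#' predictions (coin flips for the random baseline), Ln(k) when the family
#' has a discount rate `k`, and the observed proportion of smaller-sooner
#' choices.
#'
#' @param records Choice-record tibble for one participant.
#' @param model Model family name.
#' @param config A [fit_config()].
#' @return An object of class `dd_fit`; see [tidy.dd_fit()] and
#'   [glance.dd_fit()].
#' @export
fit_model <- function(records, model, config = fit_config()) {
  model <- match.arg(model, dd_models())
  stopifnot(inherits(config, "dd_fit_config"))
  rec <- valid_records(records)
  n_valid <- nrow(rec)
  if (n_valid < config$min_valid) {
    stop("only ", n_valid, " valid trials; at least ", config$min_valid,
         " required", call. = FALSE)
  }
  subject_id <- if ("subject_id" %in% names(records)) records$subject_id[1] else NA_character_
  prop_ss <- proportion_sooner(rec)

  if (model == "random") {
    ll <- -n_valid * log(2)
    pred <- withr::with_seed(config$seed,
      ifelse(stats::runif(n_valid) < 0.5, "SS", "LL"))
    ba <- balanced_accuracy(confusion_counts(rec$choice, pred))
    return(new_dd_fit(
      subject_id = subject_id, model = model, params = list(),
      ll_max = ll, n_valid = n_valid, n_params = 0L,
      bic = bic_score(ll, 0L, n_valid), balanced_accuracy = as.numeric(ba),
      ln_k = NA_real_, prop_sooner = prop_ss, n_starts_converged = 0L,
      unbounded_beta = FALSE))
  }

  par_names <- dd_param_names(model)
  starts <- start_grid(model, config)
  objective <- function(theta) {
    p <- as.list(exp(theta))
    names(p) <- par_names
    negative_log_likelihood(rec, model, p, prob_floor = config$prob_floor)
  }
  fits <- purrr::map(starts, function(th0) {
    res <- tryCatch(
      stats::optim(log(th0), objective, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      error = function(e) NULL
    )
    res
  })
  fits <- purrr::compact(fits)
  converged <- purrr::keep(fits, ~ .x$convergence == 0)
  if (length(converged) == 0) {
    stop("fit failure for model '", model, "': no start converged (",
         length(fits), " starts attempted)", call. = FALSE)
  }
  # best NLL wins; ties broken by lexicographic order of the parameter vector
  ord <- order(purrr::map_dbl(converged, "value"),
               purrr::map_dbl(converged, ~ .x$par[1]),
               purrr::map_dbl(converged, ~ .x$par[min(2, length(.x$par))]))
  best <- converged[[ord[1]]]
  mle <- as.list(exp(best$par))
  names(mle) <- par_names
  ll <- -best$value
  pred <- predict_choices(rec, model, mle)
  ba <- balanced_accuracy(confusion_counts(rec$choice, pred))
  new_dd_fit(
    subject_id = subject_id, model = model, params = mle,
    ll_max = ll, n_valid = n_valid, n_params = length(par_names),
    bic = bic_score(ll, length(par_names), n_valid),
    balanced_accuracy = as.numeric(ba),
    ln_k = if ("k" %in% names(mle)) log(mle$k) else NA_real_,
    prop_sooner = prop_ss, n_starts_converged = length(converged),
    unbounded_beta = mle$beta_temp > config$beta_temp_flag)
}

start_grid <- function(model, config) {
  grids <- list(k = config$k_grid, beta_temp = config$beta_temp_grid,
                r = config$r_grid, s = config$s_grid,
                beta_dd = config$beta_dd_grid, delta = config$delta_grid)
  g <- expand.grid(grids[dd_param_names(model)], KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(g, function(...) c(...))
}

new_dd_fit <- function(...) structure(list(...), class = "dd_fit")

#' @export
print.dd_fit <- function(x, ...) {
  cat("<dd_fit> subject:", x$subject_id, " model:", x$model, "\n")
  if (length(x$params) > 0) {
    cat("  MLE:", paste(names(x$params),
                        signif(unlist(x$params), 4), sep = " = ",
                        collapse = ", "), "\n")
  }
  cat(sprintf("  logLik %.3f on %d trials | BIC %.2f | balanced accuracy %.3f\n",
              x$ll_max, x$n_valid, x$bic, x$balanced_accuracy))
  invisible(x)
}

#' Tidy and glance methods for fitted choice models
#'
#' `tidy()` returns one row per free parameter (MLE on the natural scale);
#' `glance()` returns a one-row summary with log-likelihood, BIC, balanced
#' accuracy, Ln(k), proportion of sooner choices, and fit diagnostics.
#'
#' @param x A `dd_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dd_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, model = x$model,
    term = names(x$params) %||% character(0),
    estimate = as.numeric(unlist(x$params))
  )
}

#' @rdname tidy.dd_fit
#' @export
glance.dd_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, model = x$model,
    k = x$params$k %||% NA_real_,
    beta_temp = x$params$beta_temp %||% NA_real_,
    ll_max = x$ll_max, n_valid = x$n_valid, n_params = x$n_params,
    bic = x$bic, balanced_accuracy = x$balanced_accuracy,
    ln_k = x$ln_k, prop_sooner = x$prop_sooner,
    n_starts_converged = x$n_starts_converged,
    unbounded_beta = x$unbounded_beta
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit models across a cohort
#'
#' Fits each requested model family to each subject's records and binds the
#' per-fit summaries ([glance.dd_fit()]) into one tibble — the cohort fit
#' table consumed by [compare_models()], [summarize_cohort()], and the
#' regressor builders.
#'
#' @param records Choice-record tibble with a `subject_id` column.
#' @param models Character vector of model families (default: all six).
#' @param config A [fit_config()].
#' @return A tibble with one row per subject x model.
#' @export
fit_cohort <- function(records, models = dd_models(), config = fit_config()) {
  if (!"subject_id" %in% names(records)) {
    stop("`records` must carry a subject_id column", call. = FALSE)
  }
  models <- match.arg(models, dd_models(), several.ok = TRUE)
  records |>
    dplyr::group_split(.data$subject_id) |>
    purrr::map_dfr(function(rec) {
      purrr::map_dfr(models, ~ glance.dd_fit(fit_model(rec, .x, config)))
    })
}

#' Compare model fits against a reference family
#'
#' Cohort-level model comparison: per-model mean and SD of BIC and mean
#' balanced accuracy, plus a paired two-sided t-test of the reference model's
#' BIC against each other model's BIC across subjects (differences are
#' reference minus other, so negative t favours the reference). A
#' zero-variance difference vector is flagged rather than producing NaN.
#'
#' @param fits Cohort fit table from [fit_cohort()].
#' @param reference Reference model family (default `"hyperbolic"`).
#' @return A tibble with one row per model: `mean_bic`, `sd_bic`,
#'   `mean_balanced_accuracy`, and for non-reference rows `t`, `df`, `p`,
#'   `zero_variance`.
#' @export
compare_models <- function(fits, reference = "hyperbolic") {
  models <- unique(fits$model)
  if (!reference %in% models) {
    stop("reference model '", reference, "' not present in fits", call. = FALSE)
  }
  subj <- sort(unique(fits$subject_id))
  wide <- lapply(stats::setNames(models, models), function(m) {
    rows <- fits[fits$model == m, ]
    if (!identical(sort(rows$subject_id), subj)) {
      stop("subject sets differ across models: model '", m,
           "' is misaligned", call. = FALSE)
    }
    rows[order(rows$subject_id), ]
  })
  ref_bic <- wide[[reference]]$bic
  purrr::map_dfr(models, function(m) {
    rows <- wide[[m]]
    out <- tibble::tibble(
      model = m,
      mean_bic = mean(rows$bic), sd_bic = stats::sd(rows$bic),
      mean_balanced_accuracy = mean(rows$balanced_accuracy),
      t = NA_real_, df = NA_integer_, p = NA_real_, zero_variance = NA
    )
    if (m != reference) {
      d <- ref_bic - rows$bic
      n <- length(d)
      sd_d <- stats::sd(d)
      if (sd_d == 0) {
        out$t <- 0; out$p <- 1; out$zero_variance <- TRUE
      } else {
        tval <- mean(d) / (sd_d / sqrt(n))
        out$t <- tval
        out$p <- 2 * stats::pt(-abs(tval), df = n - 1)
        out$zero_variance <- FALSE
      }
      out$df <- n - 1L
    }
    out
  })
}

#' Cohort descriptive summary
#'
#' Mean and SD of the behavioural and fit quantities reported for a study
#' sample: proportion of smaller-sooner choices, Ln(k) and inverse
#' temperature of the hyperbolic fit (when present), and BIC per fitted
#' model.
#'
#' @param fits Cohort fit table from [fit_cohort()].
#' @return A tibble with columns `variable`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(fits) {
  if (length(unique(fits$subject_id)) < 2) {
    stop("cohort summary needs at least 2 subjects", call. = FALSE)
  }
  first_model <- fits$model[1]
  base <- fits[fits$model == first_model, ]
  row <- function(variable, x) {
    tibble::tibble(variable = variable, mean = mean(x), sd = stats::sd(x),
                   n = length(x))
  }
  out <- row("prop_sooner", base$prop_sooner)
  if ("hyperbolic" %in% fits$model) {
    hyp <- fits[fits$model == "hyperbolic", ]
    out <- dplyr::bind_rows(out,
                            row("ln_k_hyperbolic", hyp$ln_k),
                            row("beta_temp_hyperbolic", hyp$beta_temp))
  }
  bics <- purrr::map_dfr(unique(fits$model), function(m) {
    row(paste0("bic_", m), fits$bic[fits$model == m])
  })
  dplyr::bind_rows(out, bics)
}
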