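#' Generate a delay-discounting task design
#'
#' Builds the trial table for the two-run intertemporal choice task. On each
#' trial a smaller-sooner (SS) amount at an early delay is pitted against a
#' larger-later (LL) amount at a late delay. The late amount is drawn from a
#' Gaussian with mean $15 and SD $10, truncated to \[$5, $30\] by rejection
#' sampling; the early amount is 1--50% smaller (uniform reduction fraction),
#' rounded to cents. The early delay is drawn uniformly from
#' \{today, 2 weeks, 1 month\} = \{0, 14, 30\} days and the late delay adds a
#' uniform offset from \{2 weeks, 1 month, 6 weeks\} = \{14, 30, 42\} days.
#' Trials are assigned to runs sequentially; consecutive onsets within a run
#' are 12 s apart (the fixed choice-plus-ITI trial length).
#'
#' @param n_trials Total number of trials (default 84, the task length).
#' @param n_runs Number of runs (default 2); must divide `n_trials`.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A tibble with one row per trial: `trial_index` (0-based, across
#'   runs), `run_index` (0-based), `onset_s`, `early_amount_usd`,
#'   `late_amount_usd`, `early_delay_days`, `late_delay_days`.
#' @examples
#' trials <- generate_trials(84, 2, seed = 1)
#' @export
generate_trials <- function(n_trials = 84, n_runs = 2, seed) {
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  if (n_trials < 1 || n_runs < 1 || n_trials %% n_runs != 0) {
    stop("invalid design: `n_trials` must be a positive multiple of `n_runs`",
         call. = FALSE)
  }
  per_run <- n_trials %/% n_runs
  withr::with_seed(as.integer(seed), {
    late <- rtruncnorm(n_trials, mean = 15, sd = 10, lower = 5, upper = 30)
    frac <- stats::runif(n_trials, min = 0.01, max = 0.50)
    early_delay <- sample(c(0, 14, 30), n_trials, replace = TRUE)
    offset <- sample(c(14, 30, 42), n_trials, replace = TRUE)
    late_r <- round(late, 2)
    early_r <- round(late * (1 - frac), 2)
    # cent rounding can nudge the reduction a hair past the 1-50% band;
    # pull such trials back by one cent so the band holds exactly
    early_r <- pmin(pmax(early_r, ceiling(50 * late_r - 1e-9) / 100),
                    floor(99 * late_r + 1e-9) / 100)
    tibble::tibble(
      trial_index = seq_len(n_trials) - 1L,
      run_index = rep(seq_len(n_runs) - 1L, each = per_run),
      onset_s = rep(12 * (seq_len(per_run) - 1), times = n_runs),
      early_amount_usd = early_r,
      late_amount_usd = late_r,
      early_delay_days = early_delay,
      late_delay_days = early_delay + offset
    )
  })
}

# truncated-normal draws by rejection; bounds are a few SD wide so the
# acceptance rate (~0.7 here) never makes this a bottleneck
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Specify a simulated decision-making agent
#'
#' An agent couples a value-model family with ground-truth parameters, a
#' softmax inverse temperature, and an independent miss (no-response) rate.
#' Agents are the ground truth for parameter- and model-recovery tests: their
#' choices invert the same softmax likelihood the fitting stage maximises.
#'
#' @param model Model family name (see [dd_models()]).
#' @param ... Named value-function parameters for the family (e.g. `k = 0.01`
#'   for hyperbolic; `beta_dd`, `delta` for beta-delta). Ignored for
#'   `"random"`.
#' @param beta_temp Softmax inverse temperature (ignored for `"random"`).
#' @param miss_rate Probability of a missed (no-response) trial, in \[0, 1).
#' @return An object of class `dd_agent`.
#' @examples
#' a <- dd_agent("hyperbolic", k = exp(-4.68), beta_temp = 3.74)
#' @export
dd_agent <- function(model, ..., beta_temp = NULL, miss_rate = 0) {
  model <- match.arg(model, dd_models())
  params <- list(...)
  if (model != "random") {
    needed <- setdiff(dd_param_names(model), "beta_temp")
    missing_p <- setdiff(needed, names(params))
    if (length(missing_p) > 0) {
      stop("agent for model '", model, "' needs parameter(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    if (is.null(beta_temp) || beta_temp < 0) {
      stop("`beta_temp` must be supplied and non-negative", call. = FALSE)
    }
  }
  if (miss_rate < 0 || miss_rate >= 1) {
    stop("`miss_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(model = model, params = params, beta_temp = beta_temp,
         miss_rate = miss_rate),
    class = "dd_agent"
  )
}

#' Simulate choices from an agent on a task design
#'
#' For each trial the agent's subjective values of both options are computed,
#' the SS option is chosen with softmax probability
#' [choice_probability()]`(sv_ss, sv_ll, beta_temp)`, and a miss is drawn
#' independently at the agent's `miss_rate`. Reaction times are drawn from a
#' lognormal (median `rt_median` s) truncated to (0.3, 7.95\] s, the response
#' window of the task; they are plumbing for regressor timing and never enter
#' the likelihood.
#'
#' @param trials Trial tibble from [generate_trials()].
#' @param agent A [dd_agent()].
#' @param seed Integer seed for the choice, miss, and RT draws.
#' @param rt_median,rt_sdlog Location (median, seconds) and log-scale SD of
#'   the reaction-time lognormal.
#' @return The trial tibble with `choice` (`"SS"`, `"LL"`, or `"MISS"`) and
#'   `rt_s` (NA for misses) appended.
#' @export
simulate_choices <- function(trials, agent, seed, rt_median = 1.5,
                             rt_sdlog = 0.5) {
  stopifnot(inherits(agent, "dd_agent"))
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  n <- nrow(trials)
  withr::with_seed(as.integer(seed), {
    if (agent$model == "random") {
      p_ss <- rep(0.5, n)
    } else {
      sv_ss <- subjective_value(agent$model, trials$early_amount_usd,
                                trials$early_delay_days, agent$params)
      sv_ll <- subjective_value(agent$model, trials$late_amount_usd,
                                trials$late_delay_days, agent$params)
      p_ss <- choice_probability(sv_ss, sv_ll, agent$beta_temp)
    }
    choice <- ifelse(stats::runif(n) < p_ss, "SS", "LL")
    choice[stats::runif(n) < agent$miss_rate] <- "MISS"
    rt <- rtrunclnorm(n, meanlog = log(rt_median), sdlog = rt_sdlog,
                      lower = 0.3, upper = 7.95)
    rt[choice == "MISS"] <- NA_real_
    dplyr::mutate(trials, choice = choice, rt_s = rt)
  })
}

rtrunclnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)
    out <- c(out, x[x > lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of participants
#'
#' Draws per-subject hyperbolic discount rates from
#' `Ln(k) ~ Normal(lnk_mean, lnk_sd)` — defaulting to the cohort estimates of
#' the study sample (mean −4.68, SD 1.27, inverse temperature 3.74) — and
#' simulates each subject on an independently generated 84-trial, two-run
#' design.
#'
#' @param n_subjects Number of simulated participants.
#' @param lnk_mean,lnk_sd Mean and SD of the population Ln(k) distribution.
#' @param beta_temp Softmax inverse temperature shared across subjects.
#' @param n_trials,n_runs Design size per subject.
#' @param miss_rate Per-trial miss probability.
#' @param seed Integer master seed; subject-level seeds are derived from it.
#' @return A tibble of choice records with `subject_id` and `true_ln_k`
#'   columns prepended.
#' @export
simulate_cohort <- function(n_subjects, lnk_mean = -4.68, lnk_sd = 1.27,
                            beta_temp = 3.74, n_trials = 84, n_runs = 2,
                            miss_rate = 0, seed) {
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  seed <- as.integer(seed)
  true_lnk <- withr::with_seed(seed, stats::rnorm(n_subjects, lnk_mean, lnk_sd))
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    agent <- dd_agent("hyperbolic", k = exp(true_lnk[i]),
                      beta_temp = beta_temp, miss_rate = miss_rate)
    trials <- generate_trials(n_trials, n_runs, seed = subseed(seed, 2L * i))
    simulate_choices(trials, agent, seed = subseed(seed, 2L * i + 1L)) |>
      dplyr::mutate(subject_id = sprintf("sub-%02d", i),
                    true_ln_k = true_lnk[i], .before = 1)
  })
}

# derive a distinct 31-bit seed from a master seed and an index
subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Read and write BIDS-style events tables
#'
#' Choice records are serialised as tab-separated events files with columns
#' `onset`, `duration`, `early_amount`, `late_amount`, `early_delay`,
#' `late_delay`, `choice`, `response_time` (seconds/USD/days; `"n/a"` for the
#' missing reaction time of a missed trial). `duration` is the choice-period
#' length: the reaction time, or the full 7.95 s response window on a miss.
#' Onsets restart at 0 for each run, so `read_events()` reconstructs run
#' membership from onset resets and trial indices from row order;
#' `read_events(write_events(x)) ` reproduces `x` exactly.
#'
#' @param records Choice-record tibble from [simulate_choices()].
#' @param path File path of the events TSV.
#' @return `read_events()` returns the choice-record tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(records, path) {
  out <- tibble::tibble(
    onset = records$onset_s,
    duration = ifelse(records$choice == "MISS", 7.95, records$rt_s),
    early_amount = records$early_amount_usd,
    late_amount = records$late_amount_usd,
    early_delay = records$early_delay_days,
    late_delay = records$late_delay_days,
    choice = records$choice,
    response_time = records$rt_s
  )
  readr::write_tsv(out, path, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character())
  needed <- c("onset", "duration", "early_amount", "late_amount",
              "early_delay", "late_delay", "choice", "response_time")
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0) {
    stop("events file is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col, allow_na = FALSE, non_negative = TRUE) {
    v <- raw[[col]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & !(allow_na & v == "n/a"))
    if (length(bad) > 0) {
      stop(sprintf("events file row %d, column '%s': non-numeric value '%s'",
                   bad[1], col, v[bad[1]]), call. = FALSE)
    }
    neg <- which(x < 0)
    if (non_negative && length(neg) > 0) {
      stop(sprintf("events file row %d, column '%s': negative value %s",
                   neg[1], col, v[neg[1]]), call. = FALSE)
    }
    x
  }
  onset <- num("onset")
  bad_choice <- which(!raw$choice %in% c("SS", "LL", "MISS"))
  if (length(bad_choice) > 0) {
    stop(sprintf("events file row %d, column 'choice': invalid label '%s'",
                 bad_choice[1], raw$choice[bad_choice[1]]), call. = FALSE)
  }
  run_index <- cumsum(c(0L, diff(onset) <= 0))
  tibble::tibble(
    trial_index = seq_len(nrow(raw)) - 1L,
    run_index = as.integer(run_index),
    onset_s = onset,
    early_amount_usd = num("early_amount"),
    late_amount_usd = num("late_amount"),
    early_delay_days = num("early_delay"),
    late_delay_days = num("late_delay"),
    choice = raw$choice,
    rt_s = num("response_time", allow_na = TRUE)
  )
}
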