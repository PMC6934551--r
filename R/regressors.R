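#' Per-trial subjective value of the chosen option
#'
#' For each non-miss trial, evaluates the fitted value model at the option
#' the participant actually chose: the early amount at its delay for SS
#' choices, the late amount at its delay for LL choices. This series is the
#' trial-by-trial quantity the parametric-modulation regressor carries.
#'
#' @param records Choice-record tibble for one subject.
#' @param model Model family name.
#' @param params Named fitted value parameters (e.g. `list(k = 0.01)`).
#' @return A tibble with `trial_index`, `run_index`, and `sv` for each
#'   non-miss trial.
#' @export
chosen_sv_series <- function(records, model, params) {
  rec <- valid_records(records)
  sv <- sv_pair(rec, model, params)
  tibble::tibble(
    trial_index = rec$trial_index,
    run_index = rec$run_index,
    sv = ifelse(rec$choice == "SS", sv$ss, sv$ll)
  )
}

#' Chosen-option subjective value under a group-averaged discount rate
#'
#' A supplementary regressor variant that replaces the subject-specific
#' hyperbolic discount rate with the cohort-level rate
#' \eqn{k = \exp(\overline{Ln(k)})} — the geometric mean of the subjects'
#' fitted rates. Because the hyperbolic value function is monotone in amount
#' for any fixed delay menu, this variant preserves the within-subject rank
#' order of trial values when only k differs.
#'
#' @param records Choice-record tibble for one subject.
#' @param cohort_fits Cohort fit table ([fit_cohort()]) containing hyperbolic
#'   rows with an `ln_k` column; at least one subject.
#' @return As [chosen_sv_series()].
#' @export
group_average_sv_series <- function(records, cohort_fits) {
  hyp <- cohort_fits[cohort_fits$model == "hyperbolic", ]
  if (nrow(hyp) == 0) stop("no hyperbolic fits in cohort", call. = FALSE)
  k_bar <- exp(mean(hyp$ln_k))
  chosen_sv_series(records, "hyperbolic", list(k = k_bar))
}

#' Build GLM event regressors from choices and a subjective-value series
#'
#' Produces the two event regressors of the first-level fMRI design:
#'
#' * **unmodulated**: one event per trial spanning the choice period — onset
#'   at stimulus onset, duration equal to the reaction time (7.95 s, the full
#'   response window, for misses), weight 1;
#' * **sv_modulated**: one zero-duration event per *non-miss* trial at the
#'   moment of response (stimulus onset + reaction time), weighted by the
#'   chosen-option subjective value, mean-centred within each run.
#'
#' Setting `modulated_onset = "stimulus"` instead places the modulated event
#' at stimulus onset with duration equal to the reaction time.
#'
#' @param records Choice-record tibble for one subject.
#' @param sv_series Tibble from [chosen_sv_series()] (or the group-average
#'   variant), aligned with `records`' non-miss trials.
#' @param modulated_onset Either `"response"` (default) or `"stimulus"`.
#' @return A tibble with `kind` (`"unmodulated"`/`"sv_modulated"`),
#'   `run_index`, `trial_index`, `onset_s`, `duration_s`, `weight`.
#' @export
build_regressors <- function(records, sv_series,
                             modulated_onset = c("response", "stimulus")) {
  modulated_onset <- match.arg(modulated_onset)
  rec <- valid_records(records)
  if (!identical(rec$trial_index, sv_series$trial_index)) {
    stop("`sv_series` is misaligned with the non-miss trials of `records`",
         call. = FALSE)
  }
  unmod <- tibble::tibble(
    kind = "unmodulated",
    run_index = records$run_index,
    trial_index = records$trial_index,
    onset_s = records$onset_s,
    duration_s = ifelse(records$choice == "MISS", 7.95, records$rt_s),
    weight = 1
  )
  mod <- tibble::tibble(
    kind = "sv_modulated",
    run_index = rec$run_index,
    trial_index = rec$trial_index,
    onset_s = if (modulated_onset == "response") rec$onset_s + rec$rt_s else rec$onset_s,
    duration_s = if (modulated_onset == "response") 0 else rec$rt_s,
    weight = sv_series$sv
  ) |>
    dplyr::group_by(.data$run_index) |>
    dplyr::mutate(weight = .data$weight - mean(.data$weight)) |>
    dplyr::ungroup()
  dplyr::bind_rows(unmod, mod)
}

#' Export and read FSL three-column EV files
#'
#' Writes a regressor as plain text with three whitespace-separated columns
#' (onset, duration, weight), one row per event, fixed six-decimal format —
#' the format FSL FEAT consumes for custom EVs. An empty regressor is an
#' error: FEAT rejects empty EV files, so one is never written.
#'
#' @param regressor Tibble with `onset_s`, `duration_s`, `weight` (typically
#'   one `kind` of one run from [build_regressors()]).
#' @param path Output file path.
#' @return `export_ev3()` returns `path` invisibly; `read_ev3()` returns a
#'   tibble with `onset_s`, `duration_s`, `weight`.
#' @export
export_ev3 <- function(regressor, path) {
  needed <- c("onset_s", "duration_s", "weight")
  stopifnot(all(needed %in% names(regressor)))
  if (nrow(regressor) == 0) {
    stop("refusing to write an empty EV file", call. = FALSE)
  }
  lines <- sprintf("%.6f\t%.6f\t%.6f",
                   regressor$onset_s, regressor$duration_s, regressor$weight)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_ev3
#' @export
read_ev3 <- function(path) {
  m <- utils::read.table(path, col.names = c("onset_s", "duration_s", "weight"))
  tibble::as_tibble(m)
}

#' Rank agreement between subject-specific and group-average SV regressors
#'
#' Spearman correlation of the per-trial modulated weights under the
#' subject's own discount rate versus the group-averaged rate — the measured
#' version of the argument that a group-level rate preserves each subject's
#' value ordering.
#'
#' @param records Choice-record tibble for one subject.
#' @param params Subject-specific fitted parameters (`list(k = ...)`).
#' @param cohort_fits Cohort fit table with hyperbolic rows.
#' @return Spearman rho (scalar).
#' @export
sv_rank_agreement <- function(records, params, cohort_fits) {
  own <- chosen_sv_series(records, "hyperbolic", params)
  grp <- group_average_sv_series(records, cohort_fits)
  stats::cor(own$sv, grp$sv, method = "spearman")
}
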