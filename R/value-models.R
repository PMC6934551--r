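#' Discounted subjective-value functions
#'
#' The five candidate value functions for intertemporal choice, each mapping a
#' monetary amount `amount` (USD) delivered after `delay` days to its
#' subjective value (USD-equivalent). All are vectorised over `amount` and
#' `delay`.
#'
#' * `sv_hyperbolic()`: \eqn{SV = A / (1 + kD)}.
#' * `sv_exponential()`: \eqn{SV = A e^{-kD}}.
#' * `sv_beta_delta()`: the double-exponential beta-delta form
#'   \eqn{SV = A (e^{-\beta D} + e^{-\delta D})}. Note this form gives
#'   \eqn{SV = 2A} at zero delay; it is implemented exactly in this
#'   two-exponential-sum form (no 1/2 factor), which is the form the model
#'   comparison uses. See the methods vignette for discussion.
#' * `sv_discounted_utility()`: \eqn{SV = e^{-rA} / (r (1 + kD))} with
#'   concavity weight `r`. In this form subjective value decreases with
#'   amount; it is implemented as such (see the methods vignette).
#' * `sv_quasi_hyperbolic()`: hyperbolic with exponentiated delay,
#'   \eqn{SV = A / (1 + k D^s)}.
#'
#' @param amount Monetary amount in USD, non-negative.
#' @param k Discount rate per day, strictly positive.
#' @param delay Delay in days, non-negative.
#' @param beta_dd,delta Immediate and delayed exponential discount rates
#'   (per day, non-negative) of the beta-delta model.
#' @param r Concavity (risk-aversion) weight, strictly positive.
#' @param s Delay exponent, strictly positive.
#'
#' @return Numeric vector of subjective values.
#' @examples
#' sv_hyperbolic(20, k = 0.1, delay = 10)   # 10
#' sv_exponential(10, k = 0.1, delay = 10)  # 10 * exp(-1)
#' sv_quasi_hyperbolic(10, k = 0.5, s = 0.5, delay = 4)
#' @name subjective_value_models
NULL

#' @rdname subjective_value_models
#' @export
sv_hyperbolic <- function(amount, k, delay) {
  check_amount_delay(amount, delay)
  if (any(k <= 0)) stop("`k` must be strictly positive", call. = FALSE)
  amount / (1 + k * delay)
}

#' @rdname subjective_value_models
#' @export
sv_exponential <- function(amount, k, delay) {
  check_amount_delay(amount, delay)
  if (any(k <= 0)) stop("`k` must be strictly positive", call. = FALSE)
  amount * exp(-k * delay)
}

#' @rdname subjective_value_models
#' @export
sv_beta_delta <- function(amount, beta_dd, delta, delay) {
  check_amount_delay(amount, delay)
  if (any(beta_dd < 0) || any(delta < 0)) {
    stop("`beta_dd` and `delta` must be non-negative", call. = FALSE)
  }
  amount * (exp(-beta_dd * delay) + exp(-delta * delay))
}

#' @rdname subjective_value_models
#' @export
sv_discounted_utility <- function(amount, r, k, delay) {
  check_amount_delay(amount, delay)
  if (any(r <= 0)) stop("`r` must be strictly positive", call. = FALSE)
  if (any(k <= 0)) stop("`k` must be strictly positive", call. = FALSE)
  exp(-r * amount) / (r * (1 + k * delay))
}

#' @rdname subjective_value_models
#' @export
sv_quasi_hyperbolic <- function(amount, k, s, delay) {
  check_amount_delay(amount, delay)
  if (any(k <= 0)) stop("`k` must be strictly positive", call. = FALSE)
  if (any(s <= 0)) stop("`s` must be strictly positive", call. = FALSE)
  amount / (1 + k * delay^s)
}

check_amount_delay <- function(amount, delay) {
  if (any(amount < 0)) stop("`amount` must be non-negative", call. = FALSE)
  if (any(delay < 0)) stop("`delay` must be non-negative", call. = FALSE)
  invisible(NULL)
}

#' Model families and their free parameters
#'
#' `dd_models()` returns the names of the six candidate choice models: the
#' five discounted-value families plus the `"random"` baseline that assigns
#' probability 0.5 to each option. `dd_n_params()` returns the number of free
#' parameters (softmax inverse temperature included) used in the BIC penalty.
#'
#' @param model Model family name.
#' @return A character vector of model names, or an integer count.
#' @export
dd_models <- function() {
  c("hyperbolic", "exponential", "beta_delta", "discounted_utility",
    "quasi_hyperbolic_s", "random")
}

#' @rdname dd_models
#' @export
dd_n_params <- function(model) {
  counts <- c(hyperbolic = 2L, exponential = 2L, beta_delta = 3L,
              discounted_utility = 3L, quasi_hyperbolic_s = 3L, random = 0L)
  model <- match.arg(model, dd_models())
  unname(counts[[model]])
}

# value-function parameter names per family, in the order the optimiser uses
# (softmax temperature appended last everywhere)
dd_param_names <- function(model) {
  switch(model,
    hyperbolic = c("k", "beta_temp"),
    exponential = c("k", "beta_temp"),
    beta_delta = c("beta_dd", "delta", "beta_temp"),
    discounted_utility = c("r", "k", "beta_temp"),
    quasi_hyperbolic_s = c("k", "s", "beta_temp"),
    random = character(0),
    stop("unsupported model family: ", model, call. = FALSE)
  )
}

#' Evaluate a value model for arbitrary parameter sets
#'
#' Dispatches on `model` to the corresponding `sv_*()` function. `params` is a
#' named list or vector holding the value-function parameters of that family
#' (`k`; `beta_dd` and `delta`; `r` and `k`; or `k` and `s`); any `beta_temp`
#' entry is ignored here since the softmax temperature does not enter the
#' value function.
#'
#' @param model Model family name (see [dd_models()]); `"random"` is not a
#'   value model and is rejected.
#' @param amount,delay Amounts (USD) and delays (days), vectorised.
#' @param params Named list/vector of parameters for `model`.
#' @return Numeric vector of subjective values.
#' @export
subjective_value <- function(model, amount, delay, params) {
  model <- match.arg(model, dd_models())
  p <- as.list(params)
  needed <- setdiff(dd_param_names(model), "beta_temp")
  missing_p <- setdiff(needed, names(p))
  if (length(missing_p) > 0) {
    stop("params for model '", model, "' lack required field(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  switch(model,
    hyperbolic = sv_hyperbolic(amount, p$k, delay),
    exponential = sv_exponential(amount, p$k, delay),
    beta_delta = sv_beta_delta(amount, p$beta_dd, p$delta, delay),
    discounted_utility = sv_discounted_utility(amount, p$r, p$k, delay),
    quasi_hyperbolic_s = sv_quasi_hyperbolic(amount, p$k, p$s, delay),
    random = stop("the random baseline has no value function", call. = FALSE)
  )
}

#' Softmax choice probability
#'
#' Probability of choosing option a over option b given their subjective
#' values and the inverse temperature `beta_temp`:
#' \eqn{p(a) = e^{\beta SV_a} / (e^{\beta SV_a} + e^{\beta SV_b})}.
#' Computed through the logistic of \eqn{\beta (SV_a - SV_b)}, which cannot
#' overflow; results are clamped symmetrically to `[1e-12, 1 - 1e-12]` so the
#' two options' probabilities still sum to one after clamping.
#'
#' @param sv_a,sv_b Subjective values of the two options (finite, vectorised).
#' @param beta_temp Softmax inverse temperature, non-negative. Zero yields
#'   probability 0.5 regardless of the values (fully random choice).
#' @return Probabilities in (0, 1).
#' @examples
#' choice_probability(1, 0, 1)  # exp(1)/(exp(1) + 1) = 0.7311
#' @export
choice_probability <- function(sv_a, sv_b, beta_temp) {
  if (any(beta_temp < 0)) stop("`beta_temp` must be non-negative", call. = FALSE)
  if (any(!is.finite(sv_a)) || any(!is.finite(sv_b))) {
    stop("subjective values must be finite", call. = FALSE)
  }
  p <- stats::plogis(beta_temp * (sv_a - sv_b))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Natural-log discount rate
#'
#' Discount rates from the hyperbolic family are right-skewed across
#' individuals, so group-level statistics use the natural-log transform
#' Ln(k).
#'
#' @param k Discount rate, strictly positive.
#' @return `log(k)`.
#' @export
ln_k <- function(k) {
  if (any(k <= 0)) stop("`k` must be strictly positive", call. = FALSE)
  log(k)
}
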