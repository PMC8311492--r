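#' Prospect-theory choice parameters
#'
#' Bundles the three parameters of the behavioral choice model: loss aversion
#' `lambda` (multiplicative weight on losses; > 1 means losses loom larger
#' than equal gains), utility curvature `rho` (power-utility exponent; < 1
#' implies diminishing marginal utility), and logit sensitivity `tau`
#' (inverse temperature of the softmax rule; 0 is random choice).
#'
#' @param lambda Loss-aversion weight, strictly positive.
#' @param rho Utility curvature, strictly positive.
#' @param tau Logit sensitivity, non-negative.
#' @return An object of class `prospect_params`.
#' @examples
#' prospect_params(1.58, 0.60, 3.07)
#' @export
prospect_params <- function(lambda, rho, tau) {
  assert_scalar_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rho, "rho", lower = 0, strict_lower = TRUE)
  assert_scalar_number(tau, "tau", lower = 0)
  structure(list(lambda = lambda, rho = rho, tau = tau),
            class = "prospect_params")
}

#' @export
print.prospect_params <- function(x, ...) {
  cat(sprintf("prospect_params: lambda = %.3f, rho = %.3f, tau = %.3f\n",
              x$lambda, x$rho, x$tau))
  invisible(x)
}

#' Subjective value of a signed amount
#'
#' Power utility with loss aversion: `x^rho` for gains and `-lambda *
#' (-x)^rho` for losses. Losses carry negative subjective value, so
#' `lambda > 1` down-weights gambles with large potential losses.
#'
#' @param x Signed dollar amount(s); losses are negative.
#' @param params A [prospect_params()] object.
#' @return Numeric vector of utilities (dimensionless).
#' @examples
#' subjective_value(30, prospect_params(1.58, 0.60, 3.07))
#' @export
subjective_value <- function(x, params) {
  stopifnot(inherits(params, "prospect_params"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  ifelse(x >= 0, x^params$rho, -params$lambda * (-x)^params$rho)
}

#' Subjective value of a 50/50 mixed gamble
#'
#' The gamble pays `gain` or `-loss` with equal probability, so its value is
#' the even mixture of the two branch utilities. The certain alternative is
#' the status quo, whose value is identically zero.
#'
#' @param gain,loss Positive dollar magnitudes (vectorized).
#' @param params A [prospect_params()] object.
#' @return Numeric vector of gamble utilities.
#' @export
gamble_value <- function(gain, loss, params) {
  if (any(gain <= 0) || any(loss <= 0)) {
    stop("gain and loss must be positive magnitudes", call. = FALSE)
  }
  0.5 * subjective_value(gain, params) + 0.5 * subjective_value(-loss, params)
}

#' Softmax probability of accepting the gamble
#'
#' Logistic in the scaled value difference:
#' `p = 1 / (1 + exp(-tau * (sv_gamble - sv_certain)))`. With `tau = 0` every
#' choice is a coin flip; as `tau` grows, choice becomes deterministic in the
#' sign of the value difference.
#'
#' @param sv_gamble Utility of the gamble (vectorized).
#' @param sv_certain Utility of the certain option (default 0, the status
#'   quo).
#' @param tau Logit sensitivity, non-negative scalar.
#' @return Probabilities in the open interval (0, 1).
#' @export
accept_probability <- function(sv_gamble, sv_certain = 0, tau) {
  assert_scalar_number(tau, "tau", lower = 0)
  stats::plogis(tau * (sv_gamble - sv_certain))
}

#' Simulate a subject's choices on a task design
#'
#' Draws one Bernoulli accept/reject per trial from [accept_probability()],
#' then splits each accept (reject) uniformly into its strong/weak variant so
#' that downstream response collapsing is exercised. Reaction times come from
#' a log-normal distribution truncated to the 3-second response window; a
#' configurable fraction of trials time out (no response) or get an
#' implausibly fast RT, mimicking lapses that the cleaning stage must remove.
#'
#' @param design A task design from [generate_design()].
#' @param params A [prospect_params()] object.
#' @param seed Integer seed.
#' @param subject_id Identifier stored in the output.
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (log-seconds); the
#'   defaults give a mean RT near 1.45 s.
#' @param rt_max Response window in seconds (trials never exceed it).
#' @param p_timeout Probability a trial elapses with no response.
#' @param p_fast Probability a trial's RT is replaced by a sub-200 ms draw.
#' @return A data frame with columns `subject_id, trial_index, gain, loss,
#'   response, rt`; `response` is coded 1 = strong accept, 2 = weak accept,
#'   3 = weak reject, 4 = strong reject, `NA` = no response.
#' @export
simulate_choices <- function(design, params, seed = 1L, subject_id = "s01",
                             rt_meanlog = 0.2, rt_sdlog = 0.4, rt_max = 3,
                             p_timeout = 0, p_fast = 0) {
  validate_design(design)
  stopifnot(inherits(params, "prospect_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n <- nrow(design)
  p <- accept_probability(gamble_value(design$gain, design$loss, params),
                          0, params$tau)
  accept <- stats::runif(n) < p
  strength <- stats::runif(n) < 0.5
  response <- ifelse(accept, ifelse(strength, 1L, 2L),
                     ifelse(strength, 4L, 3L))

  rt <- stats::rlnorm(n, rt_meanlog, rt_sdlog)
  resample <- which(rt > rt_max)
  while (length(resample)) {
    rt[resample] <- stats::rlnorm(length(resample), rt_meanlog, rt_sdlog)
    resample <- which(rt > rt_max)
  }
  if (p_fast > 0) {
    fast <- stats::runif(n) < p_fast
    rt[fast] <- stats::runif(sum(fast), 0.03, 0.19)
  }
  if (p_timeout > 0) {
    timeout <- stats::runif(n) < p_timeout
    response[timeout] <- NA_integer_
    rt[timeout] <- NA_real_
  }
  data.frame(subject_id = subject_id, trial_index = design$trial_index,
             gain = design$gain, loss = design$loss,
             response = response, rt = rt)
}
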