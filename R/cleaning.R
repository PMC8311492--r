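#' Collapse four-level responses to binary accept/reject
#'
#' Strong and weak accepts are both treated as accepting the gamble; strong
#' and weak rejects as rejecting it. Missing responses (timeouts) stay
#' missing.
#'
#' @param response Integer codes 1 = strong accept, 2 = weak accept,
#'   3 = weak reject, 4 = strong reject, `NA` = no response (vectorized).
#' @return Integer vector: 1 = accept, 0 = reject, `NA` = missing.
#' @export
collapse_response <- function(response) {
  known <- is.na(response) | response %in% 1:4
  if (!all(known)) {
    stop(sprintf("unknown response code(s): %s",
                 paste(unique(response[!known]), collapse = ", ")),
         call. = FALSE)
  }
  ifelse(is.na(response), NA_integer_,
         ifelse(response <= 2L, 1L, 0L))
}

#' Trial-level reaction-time filter
#'
#' Removes trials with implausible reaction times (strictly below `rt_min`,
#' default 200 ms) and trials with no response (the 3-second window elapsed).
#' Trials at exactly the threshold are kept. Idempotent.
#'
#' @param trials Trial data frame with at least `response` and `rt` columns.
#' @param rt_min Lower RT bound in seconds (default 0.200).
#' @return A list with `trials` (kept rows, with an added binary `accept`
#'   column) and `report` (counts: `n_total`, `n_fast`, `n_missing`,
#'   `n_removed`, `pct_removed`).
#' @export
filter_trials <- function(trials, rt_min = 0.200) {
  assert_columns(trials, c("response", "rt"), "trial table")
  n <- nrow(trials)
  missing <- is.na(trials$response)
  fast <- !missing & !is.na(trials$rt) & trials$rt < rt_min
  drop <- missing | fast
  kept <- trials[!drop, , drop = FALSE]
  kept$accept <- collapse_response(kept$response)
  report <- list(n_total = n,
                 n_fast = sum(fast),
                 n_missing = sum(missing),
                 n_removed = sum(drop),
                 pct_removed = if (n) 100 * sum(drop) / n else 0)
  list(trials = kept, report = report)
}

# Direction of the accept trend in `x`; logistic point-estimate slope with a
# sign-test fallback when the fit separates or fails to converge.
#' @noRd
trend_sign <- function(accept, x) {
  fit <- suppressWarnings(
    tryCatch(stats::glm(accept ~ x, family = stats::binomial()),
             error = function(e) NULL))
  separated <- is.null(fit) || !fit$converged || abs(stats::coef(fit)[2L]) > 10
  if (!separated) return(sign(stats::coef(fit)[[2L]]))
  hi <- x > stats::median(x)
  if (!any(hi) || all(hi)) return(0)
  sign(mean(accept[hi]) - mean(accept[!hi]))
}

#' Participant-level preference-consistency screen
#'
#' A subject's choices must follow the directional trends the structural
#' model predicts: more likely to accept for larger gains, less likely for
#' larger losses, and more likely for larger expected value. Each trend is
#' checked by the sign of a univariate logistic slope (no significance
#' threshold); subjects who always accept or always reject fail as
#' degenerate, and subjects with too few analyzable trials fail outright.
#'
#' @param trials Filtered trial data frame for one subject, with `gain`,
#'   `loss`, `accept` columns (see [filter_trials()]).
#' @param min_trials Minimum number of analyzable trials (default 64).
#' @return A list with `pass` (logical) and `reasons` (character vector drawn
#'   from `too_few_trials`, `degenerate_all_same`, `non_monotone_gain`,
#'   `non_monotone_loss`, `non_monotone_ev`).
#' @export
screen_subject <- function(trials, min_trials = 64L) {
  assert_columns(trials, c("gain", "loss", "accept"), "trial table")
  trials <- trials[!is.na(trials$accept), , drop = FALSE]
  reasons <- character(0)
  if (nrow(trials) < min_trials) reasons <- c(reasons, "too_few_trials")
  if (nrow(trials) == 0L || length(unique(trials$accept)) < 2L) {
    reasons <- c(reasons, "degenerate_all_same")
    return(list(pass = FALSE, reasons = reasons))
  }
  if (length(reasons)) return(list(pass = FALSE, reasons = reasons))

  ev <- (trials$gain - trials$loss) / 2
  if (trend_sign(trials$accept, trials$gain) <= 0) {
    reasons <- c(reasons, "non_monotone_gain")
  }
  if (trend_sign(trials$accept, trials$loss) >= 0) {
    reasons <- c(reasons, "non_monotone_loss")
  }
  if (trend_sign(trials$accept, ev) <= 0) {
    reasons <- c(reasons, "non_monotone_ev")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Two-stage cohort cleaning
#'
#' Applies the trial-level RT filter, then the participant-level consistency
#' screen, to a long trial table covering many subjects.
#'
#' @param trials Long trial table (`subject_id, trial_index, gain, loss,
#'   response, rt`).
#' @param rt_min Reaction-time threshold in seconds.
#' @param min_trials Minimum analyzable trials per subject.
#' @return A list with `trials` (cleaned long table restricted to passing
#'   subjects, with `accept` column) and `report`, a `cleaning_report` list:
#'   `n_trials_removed`, `pct_trials_removed`, and `excluded_subjects`
#'   (data frame of `subject_id`, `reason`).
#' @export
clean_cohort <- function(trials, rt_min = 0.200, min_trials = 64L) {
  assert_columns(trials, c("subject_id", "gain", "loss", "response", "rt"),
                 "trial table")
  filt <- filter_trials(trials, rt_min = rt_min)
  kept <- filt$trials

  ids <- unique(trials$subject_id)
  excluded <- list()
  for (id in ids) {
    sub <- kept[kept$subject_id == id, , drop = FALSE]
    scr <- screen_subject(sub, min_trials = min_trials)
    if (!scr$pass) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = id, reason = scr$reasons)
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject_id = character(0), reason = character(0))
  out <- kept[!kept$subject_id %in% excluded$subject_id, , drop = FALSE]
  report <- structure(list(n_trials_removed = filt$report$n_removed,
                           pct_trials_removed = filt$report$pct_removed,
                           n_subjects_in = length(ids),
                           n_subjects_excluded =
                             length(unique(excluded$subject_id)),
                           excluded_subjects = excluded),
                      class = "cleaning_report")
  list(trials = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning report: %d trial(s) removed (%s%% of trials)\n",
              x$n_trials_removed, signif(x$pct_trials_removed, 4)))
  cat(sprintf("subjects excluded: %d of %d\n",
              x$n_subjects_excluded, x$n_subjects_in))
  if (nrow(x$excluded_subjects)) print(x$excluded_subjects)
  invisible(x)
}
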