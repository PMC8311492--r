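#' Read or write a trial-data CSV
#'
#' Schema: `subject_id, trial_index, gain, loss, response, rt` with response
#' coded 1 = strong accept, 2 = weak accept, 3 = weak reject, 4 = strong
#' reject, empty = no response.
#'
#' @param trials Long trial table.
#' @param path CSV path.
#' @return `read_trials()` returns the validated table; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  assert_columns(df, c("subject_id", "trial_index", "gain", "loss",
                       "response", "rt"), "trial CSV")
  bad <- !is.na(df$response) & !df$response %in% 1:4
  if (any(bad)) stop("trial CSV has response codes outside 1..4",
                     call. = FALSE)
  if (any(df$rt < 0, na.rm = TRUE)) stop("negative reaction times",
                                         call. = FALSE)
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  assert_columns(trials, c("subject_id", "trial_index", "gain", "loss",
                           "response", "rt"), "trial table")
  utils::write.csv(trials[, c("subject_id", "trial_index", "gain", "loss",
                              "response", "rt")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-subject estimates CSV
#'
#' Schema: `subject_id, lambda_mean, lambda_sd, rho_mean, rho_sd, tau_mean,
#' tau_sd, mean_rt`.
#'
#' @param estimates Table from [subject_estimates()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  assert_columns(estimates, c("subject_id", "lambda_mean", "lambda_sd",
                              "rho_mean", "rho_sd", "tau_mean", "tau_sd"),
                 "estimates table")
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path)
  assert_columns(df, c("subject_id", "lambda_mean", "rho_mean", "tau_mean"),
                 "estimates CSV")
  df
}
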