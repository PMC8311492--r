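#' Posterior predictive check of the choice model
#'
#' Replicates the cohort's choices from random posterior draws and compares
#' observed acceptance rates, binned by gain level and by loss level, with
#' the replicated predictive distribution. A well-calibrated model should
#' leave roughly 90% of bins inside their 90% predictive intervals;
#' systematic exceedances indicate misfit (e.g., choices generated by a
#' deterministic threshold rule).
#'
#' @param fit An `la_hbayes` object from [fit_hierarchical()].
#' @param trials The cleaned trial table the fit used.
#' @param n_rep Number of replicated datasets (default 200).
#' @param level Predictive interval level (default 0.90).
#' @param seed Seed for the replicate draws.
#' @return A list of class `la_ppc` with `bins` (data frame: predictor, bin
#'   value, observed rate, predictive interval, inside flag) and `coverage`
#'   (fraction of bins inside their intervals).
#' @export
posterior_predictive_check <- function(fit, trials, n_rep = 200L,
                                       level = 0.90, seed = 1L) {
  stopifnot(inherits(fit, "la_hbayes"))
  assert_columns(trials, c("subject_id", "gain", "loss", "accept"),
                 "trial table")
  if (n_rep < 1L) stop("n_rep must be at least 1", call. = FALSE)
  trials <- trials[!is.na(trials$accept), , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  theta <- do.call(abind1, lapply(fit$draws, `[[`, "theta"))
  idx <- match(trials$subject_id, fit$subject_ids)
  if (anyNA(idx)) stop("trials contain subjects absent from the fit",
                       call. = FALSE)
  n <- nrow(trials)
  draw_ids <- sample.int(dim(theta)[1L], n_rep, replace = TRUE)

  bin_rates <- function(acc) {
    c(tapply(acc, trials$gain, mean), tapply(acc, trials$loss, mean))
  }
  obs <- bin_rates(trials$accept)
  reps <- matrix(NA_real_, n_rep, length(obs))
  for (r in seq_len(n_rep)) {
    lam <- theta[draw_ids[r], idx, 1L]
    rho <- theta[draw_ids[r], idx, 2L]
    tau <- theta[draw_ids[r], idx, 3L]
    sv <- 0.5 * trials$gain^rho - 0.5 * lam * trials$loss^rho
    acc <- as.numeric(stats::runif(n) < stats::plogis(tau * sv))
    reps[r, ] <- bin_rates(acc)
  }
  alpha <- (1 - level) / 2
  lo <- apply(reps, 2L, stats::quantile, probs = alpha)
  hi <- apply(reps, 2L, stats::quantile, probs = 1 - alpha)
  bins <- data.frame(
    predictor = rep(c("gain", "loss"),
                    c(length(unique(trials$gain)),
                      length(unique(trials$loss)))),
    level_value = as.numeric(names(obs)),
    observed = as.numeric(obs),
    pred_lower = lo, pred_upper = hi,
    inside = obs >= lo & obs <= hi)
  rownames(bins) <- NULL
  structure(list(bins = bins, coverage = mean(bins$inside),
                 n_rep = n_rep, level = level),
            class = "la_ppc")
}

#' @export
print.la_ppc <- function(x, ...) {
  cat(sprintf("posterior predictive check: %.0f%% of %d bins inside %d%% intervals (%d replicates)\n",
              100 * x$coverage, nrow(x$bins), round(100 * x$level), x$n_rep))
  invisible(x)
}
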