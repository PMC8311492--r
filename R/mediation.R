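# Quasi-Bayesian causal mediation for the age -> cortical thickness ->
# loss aversion chain. Because the outcome's age trajectory is quadratic,
# the squared age term is the treatment of interest, with linear age (and
# head size, demographics, scanner) as covariates, and the mediator's square
# optionally in the outcome model to absorb curvature.

#' Quasi-Bayesian causal mediation analysis
#'
#' Fits a linear mediator model `M ~ T + covariates` and outcome model
#' `Y ~ T + M (+ M^2) + covariates`, draws parameter vectors from their
#' asymptotic sampling distributions, and for each draw computes potential
#' outcomes at treatment values `t1` and `t0` to form the average causal
#' mediation effect (ACME), average direct effect (ADE), and total effect.
#' Point estimates are means over draws; confidence intervals are the 2.5th
#' and 97.5th percentiles; p-values are `2 * min(frac <= 0, frac >= 0)`.
#' Mediator error draws are propagated so nonlinear (squared) mediator terms
#' are handled correctly.
#'
#' @param data Complete-case subject-level data frame.
#' @param outcome,mediator Column names of the outcome (loss aversion) and
#'   mediator (ROI thickness).
#' @param treatment Treatment column name. The default, `"age2"`, is created
#'   as `age^2` when absent.
#' @param covariates Covariate column names (intersected with the data;
#'   default age, eTIV, race/ethnicity, scanner).
#' @param mediator_sq Include the mediator's square in the outcome model
#'   (default `TRUE`).
#' @param t0,t1 Treatment contrast; defaults are the 25th and 75th
#'   percentiles of the treatment in the data.
#' @param n_sims Number of parameter draws (>= 1000 recommended; enforced
#'   minimum 100).
#' @param seed Integer seed.
#' @param conf_level Interval level (default 0.95).
#' @return Object of class `la_mediation` with `acme`, `ade`, `total`
#'   (each: estimate, ci, p_value), `prop_mediated`, the two models, and the
#'   simulation settings.
#' @export
mediate <- function(data, outcome = "lambda", mediator = "pcc",
                    treatment = "age2",
                    covariates = c("age", "etiv", "race_ethnicity",
                                   "scanner_id"),
                    mediator_sq = TRUE, t0 = NULL, t1 = NULL,
                    n_sims = 1000L, seed = 1L, conf_level = 0.95) {
  if (treatment == "age2" && !"age2" %in% names(data)) {
    assert_columns(data, "age", "mediation data")
    data$age2 <- data$age^2
  }
  covariates <- intersect(covariates, names(data))
  assert_columns(data, c(outcome, mediator, treatment, covariates),
                 "mediation data")
  used <- c(outcome, mediator, treatment, covariates)
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), ,
               drop = FALSE]
  tvec <- data[[treatment]]
  if (stats::sd(tvec) == 0) stop("treatment is constant", call. = FALSE)
  if (n_sims < 100L) stop("n_sims too small (>= 100 required)",
                          call. = FALSE)
  t0 <- t0 %||% unname(stats::quantile(tvec, 0.25))
  t1 <- t1 %||% unname(stats::quantile(tvec, 0.75))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  df <- data
  df$.t <- df[[treatment]]
  df$.m <- df[[mediator]]
  df$.y <- df[[outcome]]
  fm <- stats::lm(stats::reformulate(c(".t", covariates), response = ".m"),
                  data = df)
  y_terms <- c(".t", ".m", if (mediator_sq) "I(.m^2)", covariates)
  fy <- stats::lm(stats::reformulate(y_terms, response = ".y"), data = df)
  if (anyNA(stats::coef(fm)) || anyNA(stats::coef(fy))) {
    stop("singular mediator or outcome model", call. = FALSE)
  }

  bm <- MASS::mvrnorm(n_sims, stats::coef(fm), stats::vcov(fm))
  by <- MASS::mvrnorm(n_sims, stats::coef(fy), stats::vcov(fy))
  sigma_m <- summary(fm)$sigma
  n <- nrow(df)

  # fixed design pieces, with the treatment column swapped per scenario
  Xm_at <- function(tval) {
    d <- df
    d$.t <- tval
    stats::model.matrix(stats::delete.response(stats::terms(fm)), data = d)
  }
  Xm1 <- Xm_at(t1)
  Xm0 <- Xm_at(t0)
  Xy_at <- function(tval, mvals) {
    d <- df
    d$.t <- tval
    d$.m <- mvals
    stats::model.matrix(stats::delete.response(stats::terms(fy)), data = d)
  }

  d1 <- d0 <- z1 <- z0 <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    e <- stats::rnorm(n, 0, sigma_m)
    m1 <- as.numeric(Xm1 %*% bm[s, ]) + e
    m0 <- as.numeric(Xm0 %*% bm[s, ]) + e
    y_t1m1 <- as.numeric(Xy_at(t1, m1) %*% by[s, ])
    y_t1m0 <- as.numeric(Xy_at(t1, m0) %*% by[s, ])
    y_t0m1 <- as.numeric(Xy_at(t0, m1) %*% by[s, ])
    y_t0m0 <- as.numeric(Xy_at(t0, m0) %*% by[s, ])
    d1[s] <- mean(y_t1m1 - y_t1m0)  # ACME under treatment
    d0[s] <- mean(y_t0m1 - y_t0m0)  # ACME under control
    z1[s] <- mean(y_t1m1 - y_t0m1)  # ADE with mediator at treated value
    z0[s] <- mean(y_t1m0 - y_t0m0)
  }
  acme_s <- (d1 + d0) / 2
  ade_s <- (z1 + z0) / 2
  total_s <- d1 + z0

  summarize <- function(x) {
    alpha <- (1 - conf_level) / 2
    list(estimate = mean(x),
         ci = unname(stats::quantile(x, c(alpha, 1 - alpha))),
         p_value = min(1, 2 * min(mean(x <= 0), mean(x >= 0))))
  }
  acme <- summarize(acme_s)
  ade <- summarize(ade_s)
  total <- summarize(total_s)
  structure(list(acme = acme, ade = ade, total = total,
                 prop_mediated = acme$estimate / total$estimate,
                 t0 = t0, t1 = t1, n = n, n_sims = n_sims,
                 conf_level = conf_level,
                 mediator_model = fm, outcome_model = fy,
                 sims = list(acme = acme_s, ade = ade_s, total = total_s)),
            class = "la_mediation")
}

#' @export
print.la_mediation <- function(x, ...) {
  line <- function(nm, s) {
    cat(sprintf("%-12s %9.4f  [%.4f, %.4f]  p = %.4g\n", nm, s$estimate,
                s$ci[1L], s$ci[2L], s$p_value))
  }
  cat(sprintf("causal mediation (quasi-Bayesian, %d simulations, n = %d)\n",
              x$n_sims, x$n))
  cat(sprintf("treatment contrast: t0 = %.3g, t1 = %.3g\n", x$t0, x$t1))
  line("ACME", x$acme)
  line("ADE", x$ade)
  line("Total", x$total)
  cat(sprintf("prop. mediated: %.3f\n", x$prop_mediated))
  invisible(x)
}
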