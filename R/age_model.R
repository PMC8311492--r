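#' Hierarchical linear-vs-quadratic age regression
#'
#' Step 1 regresses the outcome (loss aversion by default) on age and the
#' covariates; step 2 adds age squared. The two steps are compared by a
#' nested-model F test (which, for a single added term, equals the squared t
#' statistic of the age-squared coefficient). Age may be mean-centered before
#' squaring to reduce collinearity; reported coefficients are always
#' converted back to the raw-age scale, so the vertex (the age at the
#' extremum, `-b_age / (2 * b_age2)`) is in calendar years either way.
#'
#' @param data Subject-level data frame with `age`, the outcome, and any
#'   covariates.
#' @param outcome Outcome column name (default `"lambda"`).
#' @param covariates Covariate column names (default `"race_ethnicity"`);
#'   coding follows the column type (factor vs numeric).
#' @param center_age Mean-center age before squaring (default `TRUE`).
#' @return Object of class `la_quadfit`: `linear_model`, `quadratic_model`
#'   (lm fits), `coef` (raw-scale intercept/age/age2 estimates with t and p
#'   for the age terms), `f_statistic`, `df`, `p_value`, `delta_r2`,
#'   `vertex_age`.
#' @export
fit_quadratic_age <- function(data, outcome = "lambda",
                              covariates = "race_ethnicity",
                              center_age = TRUE) {
  covariates <- intersect(covariates, names(data))
  assert_columns(data, c("age", outcome), "subject table")
  df <- data
  a_bar <- if (center_age) mean(df$age) else 0
  df$.age_c <- df$age - a_bar
  df$.age_c2 <- df$.age_c^2
  if (nrow(df) <= length(covariates) + 4L) {
    stop("too few rows for the quadratic model", call. = FALSE)
  }

  f1 <- stats::reformulate(c(".age_c", covariates), response = outcome)
  f2 <- stats::reformulate(c(".age_c", ".age_c2", covariates),
                           response = outcome)
  m1 <- stats::lm(f1, data = df)
  m2 <- stats::lm(f2, data = df)
  if (anyNA(stats::coef(m2))) {
    bad <- names(stats::coef(m2))[is.na(stats::coef(m2))]
    stop(sprintf("rank-deficient quadratic model; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  cmp <- stats::anova(m1, m2)
  sm2 <- summary(m2)$coefficients
  b1c <- stats::coef(m2)[[".age_c"]]
  b2c <- stats::coef(m2)[[".age_c2"]]
  # raw-scale conversion: b2 unchanged, b1_raw = b1_c - 2 b2 a_bar
  b2 <- b2c
  b1 <- b1c - 2 * b2c * a_bar
  coef_tab <- data.frame(
    term = c("age", "age2"),
    estimate = c(b1, b2),
    t_value = sm2[c(".age_c", ".age_c2"), "t value"],
    p_value = sm2[c(".age_c", ".age_c2"), "Pr(>|t|)"])
  # t/p of the centered age term equal the raw-age marginal test only when
  # uncentered; the age2 row is invariant to centering.
  rownames(coef_tab) <- NULL

  r2 <- c(summary(m1)$r.squared, summary(m2)$r.squared)
  vertex <- if (b2 != 0) -b1 / (2 * b2) else NA_real_
  structure(list(linear_model = m1, quadratic_model = m2,
                 coef = coef_tab,
                 f_statistic = cmp$F[2L],
                 df = c(df1 = cmp$Df[2L], df2 = cmp$Res.Df[2L]),
                 p_value = cmp$`Pr(>F)`[2L],
                 delta_r2 = r2[2L] - r2[1L],
                 vertex_age = vertex,
                 centered = center_age, age_mean = a_bar),
            class = "la_quadfit")
}

#' @export
print.la_quadfit <- function(x, ...) {
  cat("quadratic age regression (raw-age scale):\n")
  print(transform(x$coef, estimate = signif(estimate, 4),
                  t_value = round(t_value, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  cat(sprintf("nested F(%d, %d) = %.3f, p = %.4g, delta R^2 = %.4f\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value, x$delta_r2))
  cat(sprintf("vertex age: %.1f years\n", x$vertex_age))
  invisible(x)
}

#' Age-related thinning fit per ROI
#'
#' Step 1: thickness ~ age + covariates; step 2 adds age squared to check for
#' curvature. Used to confirm (approximately linear) age-related cortical
#' thinning before mediation.
#'
#' @param data Subject-level data frame containing the ROI thickness column,
#'   `age`, and covariates.
#' @param roi ROI column name (default `"pcc"`).
#' @param covariates Covariates for both steps (default sex, race/ethnicity
#'   and eTIV, intersected with available columns).
#' @return List with `slope` (linear age slope, mm/year), `t_value`,
#'   `p_value`, the two `lm` fits, and the age-squared term's estimate/t/p
#'   from step 2.
#' @export
fit_thinning <- function(data, roi = "pcc",
                         covariates = c("sex", "race_ethnicity", "etiv")) {
  covariates <- intersect(covariates, names(data))
  assert_columns(data, c("age", roi), "subject table")
  f1 <- stats::reformulate(c("age", covariates), response = roi)
  m1 <- stats::lm(f1, data = data)
  data$.age2 <- data$age^2
  f2 <- stats::reformulate(c("age", ".age2", covariates), response = roi)
  m2 <- stats::lm(f2, data = data)
  s1 <- summary(m1)$coefficients
  s2 <- summary(m2)$coefficients
  list(slope = s1["age", "Estimate"],
       t_value = s1["age", "t value"],
       p_value = s1["age", "Pr(>|t|)"],
       quad_estimate = s2[".age2", "Estimate"],
       quad_t = s2[".age2", "t value"],
       quad_p = s2[".age2", "Pr(>|t|)"],
       linear_model = m1, quadratic_model = m2)
}

#' Thickness-outcome correlation by age stratum
#'
#' Splits subjects at `split_age` (by default 35 years, the approximate
#' vertex of the age trajectory of loss aversion) and reports the Pearson
#' correlation between ROI thickness and the outcome within each stratum.
#' The headline pattern is a negative correlation in the older group only.
#'
#' @param data Subject-level data frame with `age`, the ROI column, and the
#'   outcome.
#' @param roi ROI column name (default `"pcc"`).
#' @param outcome Outcome column name (default `"lambda"`).
#' @param split_age Split point in years; younger = `age < split_age`.
#' @return Data frame with one row per group (`younger`, `older`): `n`, `r`,
#'   `p_value`, `flagged` (TRUE when n < 3, in which case r is omitted).
#' @export
age_split_summary <- function(data, roi = "pcc", outcome = "lambda",
                              split_age = 35) {
  assert_columns(data, c("age", roi, outcome), "subject table")
  groups <- list(younger = data$age < split_age,
                 older = data$age >= split_age)
  if (!any(groups$younger) || !any(groups$older)) {
    stop("both age strata must be non-empty", call. = FALSE)
  }
  out <- lapply(names(groups), function(g) {
    d <- data[groups[[g]], , drop = FALSE]
    if (nrow(d) < 3L) {
      return(data.frame(group = g, n = nrow(d), r = NA_real_,
                        p_value = NA_real_, flagged = TRUE))
    }
    ct <- stats::cor.test(d[[roi]], d[[outcome]])
    data.frame(group = g, n = nrow(d), r = unname(ct$estimate),
               p_value = ct$p.value, flagged = FALSE)
  })
  do.call(rbind, out)
}
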