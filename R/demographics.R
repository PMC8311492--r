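#' Demographic covariate screen
#'
#' Tests whether the outcome (loss aversion by default) is associated with
#' each candidate demographic: one-way ANOVA for categorical covariates,
#' Pearson correlation for continuous ones. Covariates with p below `alpha`
#' are retained for the downstream models. Categories with fewer than two
#' observations are dropped from their ANOVA with a warning.
#'
#' @param data Subject-level data frame containing `outcome` and the listed
#'   covariates.
#' @param outcome Outcome column name (default `"lambda"`).
#' @param categorical,continuous Covariate column names by type. Defaults
#'   mirror the study's screen: sex, race/ethnicity, smoking; estimated IQ,
#'   mother's education.
#' @param alpha Retention threshold (default 0.05).
#' @return Data frame: `covariate`, `type`, `statistic` (F or r), `df`,
#'   `p_value`, `retained`.
#' @export
demographic_screen <- function(data, outcome = "lambda",
                               categorical = c("sex", "race_ethnicity",
                                               "smoking"),
                               continuous = c("iq", "mother_education"),
                               alpha = 0.05) {
  categorical <- intersect(categorical, names(data))
  continuous <- intersect(continuous, names(data))
  assert_columns(data, outcome, "subject table")
  rows <- list()
  y <- data[[outcome]]

  for (v in categorical) {
    g <- factor(data[[v]])
    keep <- !is.na(g) & !is.na(y)
    tab <- table(g[keep])
    small <- names(tab)[tab < 2L]
    if (length(small)) {
      warning(sprintf("screen of %s: dropping level(s) with < 2 obs: %s",
                      v, paste(small, collapse = ", ")), call. = FALSE)
      keep <- keep & !g %in% small
    }
    gk <- droplevels(g[keep])
    if (nlevels(gk) < 2L) next
    fit <- stats::aov(y[keep] ~ gk)
    s <- summary(fit)[[1L]]
    rows[[v]] <- data.frame(covariate = v, type = "categorical",
                            statistic = s$`F value`[1L],
                            df = paste(s$Df, collapse = ","),
                            p_value = s$`Pr(>F)`[1L])
  }
  for (v in continuous) {
    keep <- !is.na(data[[v]]) & !is.na(y)
    ct <- stats::cor.test(data[[v]][keep], y[keep])
    rows[[v]] <- data.frame(covariate = v, type = "continuous",
                            statistic = unname(ct$estimate),
                            df = as.character(unname(ct$parameter)),
                            p_value = ct$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$retained <- out$p_value < alpha
  out
}
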