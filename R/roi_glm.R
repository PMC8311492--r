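#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the raw p-values, multiplies the i-th smallest by (m - i + 1), and
#' enforces monotonicity; rejection at level alpha of an adjusted p implies
#' rejection of all smaller ones. Implemented directly so the multiple-
#' comparison step is self-contained and testable against the hand-worked
#' step-down.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order, each >= its raw value.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03, 0.04)) # 0.04 0.06 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1L) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-ROI general linear models for thickness effects
#'
#' For each ROI, fits `outcome ~ thickness + thickness^2 + covariates`
#' (estimated intracranial volume by default) and reports the linear and
#' quadratic thickness coefficients with raw and Holm-adjusted p-values.
#' Each term's p-values are adjusted across the ROI family.
#'
#' @param data Subject-level data frame with the ROI columns, the outcome,
#'   and the covariates.
#' @param rois ROI column names (default insula, OFC, ACC, PCC).
#' @param outcome Outcome column name (default `"lambda"`).
#' @param covariates Covariate column names (default `"etiv"`).
#' @param alpha Familywise significance level (default 0.05).
#' @return Data frame, one row per ROI x term (`linear`, `quadratic`):
#'   estimate, t, raw p, Holm-adjusted p, `significant` flag.
#' @export
roi_glms <- function(data, rois = c("insula", "ofc", "acc", "pcc"),
                     outcome = "lambda", covariates = "etiv",
                     alpha = 0.05) {
  covariates <- intersect(covariates, names(data))
  assert_columns(data, c(rois, outcome), "subject table")
  if (length(rois) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  rows <- list()
  for (r in rois) {
    th <- data[[r]]
    if (stats::sd(th) == 0) {
      stop(sprintf("ROI %s has constant thickness", r), call. = FALSE)
    }
    df <- data
    df$.th <- th
    df$.th2 <- th^2
    fit <- stats::lm(stats::reformulate(c(".th", ".th2", covariates),
                                        response = outcome), data = df)
    sm <- summary(fit)$coefficients
    rows[[r]] <- data.frame(
      roi = r, term = c("linear", "quadratic"),
      estimate = sm[c(".th", ".th2"), "Estimate"],
      t_value = sm[c(".th", ".th2"), "t value"],
      p_raw = sm[c(".th", ".th2"), "Pr(>|t|)"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_holm <- NA_real_
  for (tm in unique(out$term)) {
    sel <- out$term == tm
    out$p_holm[sel] <- holm_adjust(out$p_raw[sel])
  }
  out$significant <- out$p_holm < alpha
  out
}
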