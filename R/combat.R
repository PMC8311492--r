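# Parametric empirical-Bayes batch harmonization (ComBat) for parcel-wise
# cortical thickness. Per-feature batch location/scale effects are estimated
# after standardizing on a model that includes protected biological
# covariates (age by default), shrunk toward batch-level priors (normal for
# location, inverse-gamma for scale, hyperparameters by method of moments),
# removed, and the covariate effects restored. This keeps age-related
# variance while removing scanner differences.

#' Harmonize thickness features across scanners
#'
#' @param table Thickness table (see [read_thickness_table()]).
#' @param batch Name of the batch column (default `"scanner_id"`).
#' @param covariates Biological covariates whose variance must be preserved
#'   (default `"age"`). Numeric columns enter linearly; factors as dummies.
#' @param features Columns to harmonize; default every `*_thickness` column.
#' @param eb_iter,eb_tol Iteration cap and convergence tolerance of the
#'   empirical-Bayes fixed-point solve.
#' @return The table with harmonized feature columns; attribute
#'   `"combat"` stores the estimated batch effects.
#' @export
combat_harmonize <- function(table, batch = "scanner_id",
                             covariates = "age",
                             features = NULL,
                             eb_iter = 100L, eb_tol = 1e-4) {
  assert_columns(table, c(batch, covariates), "thickness table")
  features <- features %||% thickness_cols(table)
  if (!length(features)) stop("no feature columns to harmonize",
                              call. = FALSE)
  b <- factor(table[[batch]])
  n_batches <- nlevels(b)
  if (n_batches < 2L) {
    warning("single batch: harmonization is the identity", call. = FALSE)
    return(table)
  }
  counts <- table(b)
  if (any(counts < 3L)) {
    stop(sprintf("each batch needs >= 3 subjects (smallest has %d)",
                 min(counts)), call. = FALSE)
  }

  Y <- t(as.matrix(table[, features, drop = FALSE]))  # features x n
  n <- ncol(Y)
  G <- nrow(Y)
  B <- stats::model.matrix(~ -1 + b)                  # n x n_batches
  X_cov <- stats::model.matrix(
    stats::reformulate(covariates, intercept = FALSE), data = table)
  design <- cbind(B, X_cov)

  # per-feature OLS on batch dummies + covariates
  beta_hat <- solve(crossprod(design), crossprod(design, t(Y)))  # p x G
  grand_mean <- crossprod(as.numeric(counts) / n,
                          beta_hat[seq_len(n_batches), , drop = FALSE])
  var_pooled <- rowMeans((Y - t(design %*% beta_hat))^2)
  if (any(var_pooled <= 0)) stop("constant feature column", call. = FALSE)

  stand_mean <- matrix(grand_mean, G, n) +
    t(X_cov %*% beta_hat[-seq_len(n_batches), , drop = FALSE])
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  # batch-wise EB shrinkage
  gamma_star <- delta_star <- matrix(NA_real_, n_batches, G)
  for (j in seq_len(n_batches)) {
    in_b <- which(b == levels(b)[j])
    nj <- length(in_b)
    Zj <- Z[, in_b, drop = FALSE]
    g_hat <- rowMeans(Zj)
    d_hat <- apply(Zj, 1L, stats::var)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    g_old <- g_hat
    d_old <- d_hat
    if (G < 2L || !is.finite(t2) || !is.finite(s2) || s2 <= 0) {
      # a single feature gives no across-feature prior: skip shrinkage
      gamma_star[j, ] <- g_hat
      delta_star[j, ] <- d_hat
      next
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    for (it in seq_len(eb_iter)) {
      g_new <- (t2 * nj * g_hat + d_old * g_bar) / (t2 * nj + d_old)
      sum2 <- rowSums((Zj - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (nj / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < eb_tol) break
    }
    gamma_star[j, ] <- g_old
    delta_star[j, ] <- d_old
  }

  # adjust and restore
  jb <- as.integer(b)
  Z_adj <- (Z - t(gamma_star[jb, , drop = FALSE])) /
    sqrt(t(delta_star[jb, , drop = FALSE]))
  Y_adj <- Z_adj * sqrt(var_pooled) + stand_mean

  out <- table
  out[, features] <- t(Y_adj)
  attr(out, "combat") <- list(batch_levels = levels(b),
                              gamma_star = gamma_star,
                              delta_star = delta_star,
                              features = features)
  out
}
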