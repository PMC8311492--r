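test_that("the demographic screen matches hand-computed ANOVA and cor", {
  # 3 groups x 4 observations, worked by the one-way ANOVA identities
  y <- c(1.2, 1.4, 1.3, 1.5, 1.8, 1.9, 2.0, 1.7, 1.1, 1.0, 1.2, 1.3)
  g <- rep(c("a", "b", "c"), each = 4)
  df <- data.frame(lambda = y, race_ethnicity = g)
  scr <- demographic_screen(df, categorical = "race_ethnicity",
                            continuous = character(0))
  k <- 3; n <- 12
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  ssw <- sum((y - ave(y, g))^2)
  f_hand <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(scr$statistic, f_hand, tolerance = 1e-10)
  expect_equal(scr$p_value, pf(f_hand, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical outcome values copied across groups: F = 0, p = 1
  df0 <- data.frame(lambda = rep(c(1.1, 1.5, 1.9), times = 3),
                    sex = rep(c("F", "M", "X"), each = 3))
  scr0 <- demographic_screen(df0, categorical = "sex",
                             continuous = character(0))
  expect_equal(scr0$statistic, 0, tolerance = 1e-12)
  expect_equal(scr0$p_value, 1, tolerance = 1e-12)

  # continuous covariate reproduces cor.test
  set.seed(3)
  dfc <- data.frame(lambda = rnorm(40), iq = rnorm(40))
  scrc <- demographic_screen(dfc, categorical = character(0),
                             continuous = "iq")
  ct <- cor.test(dfc$iq, dfc$lambda)
  expect_equal(scrc$statistic, unname(ct$estimate))
  expect_equal(scrc$p_value, ct$p.value)
})

test_that("a real group offset is retained and small cells are dropped", {
  set.seed(11)
  df <- data.frame(
    lambda = c(rnorm(30, 1.5, 0.2), rnorm(30, 2.0, 0.2), rnorm(30, 1.5, 0.2)),
    race_ethnicity = rep(c("1", "2", "3"), each = 30))
  scr <- demographic_screen(df, categorical = "race_ethnicity",
                            continuous = character(0))
  expect_true(scr$retained)
  df$race_ethnicity[1] <- "4"  # singleton level
  expect_warning(demographic_screen(df, categorical = "race_ethnicity",
                                    continuous = character(0)),
                 "< 2 obs")
})

test_that("quadratic age regression is exact on noiseless data", {
  age <- seq(18, 52, length.out = 50)
  df <- data.frame(age = age, lambda = 2 - 0.06 * age + 0.001 * age^2)
  for (ctr in c(TRUE, FALSE)) {
    qf <- suppressWarnings(
      fit_quadratic_age(df, covariates = character(0), center_age = ctr))
    expect_equal(qf$coef$estimate, c(-0.06, 0.001), tolerance = 1e-8)
    expect_equal(qf$vertex_age, 30, tolerance = 1e-6)
    expect_gt(qf$f_statistic, 1e6)
  }
  lin <- data.frame(age = age, lambda = 1.9 - 0.01 * age + rnorm(50, 0, 1e-9))
  ql <- suppressWarnings(fit_quadratic_age(lin, covariates = character(0)))
  expect_lt(abs(ql$coef$estimate[2]), 1e-6)
  expect_lt(ql$delta_r2, 1e-6)
})

test_that("the nested F equals the squared t of the added quadratic term", {
  set.seed(21)
  for (i in 1:5) {
    df <- data.frame(age = runif(80, 17, 54),
                     race_ethnicity = factor(sample(1:4, 80, TRUE)))
    df$lambda <- 1.6 - 0.05 * df$age + 0.0009 * df$age^2 +
      0.1 * as.integer(df$race_ethnicity) + rnorm(80, 0, 0.3)
    qf <- fit_quadratic_age(df)
    t_age2 <- qf$coef$t_value[qf$coef$term == "age2"]
    expect_equal(qf$f_statistic, t_age2^2, tolerance = 1e-8)
  }
})

test_that("vertex age is recovered across replicates at study scale", {
  ok <- vapply(1:100, function(r) {
    set.seed(300 + r)
    age <- runif(106, 17, 54)
    lam <- 2 - 0.07 * age + 0.001 * age^2 + rnorm(106, 0, 0.35)
    qf <- fit_quadratic_age(data.frame(age = age, lambda = lam),
                            covariates = character(0))
    abs(qf$vertex_age - 35) <= 4
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("rank-deficient quadratic models fail loudly", {
  df <- data.frame(age = rep(30, 20), lambda = rnorm(20))
  expect_error(suppressWarnings(
    fit_quadratic_age(df, covariates = character(0), center_age = FALSE)),
    "collinear|too few|rank")
})

test_that("Holm step-down reproduces the hand-worked adjustment", {
  # 0.01*4 = 0.04 reject; 0.02*3 = 0.06 stop
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.06, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"))          # independent oracle
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw p
    # Holm rejections are a superset of Bonferroni rejections
    expect_true(all(which(p.adjust(p, "bonferroni") < 0.05) %in%
                      which(adj < 0.05)))
  }
})

test_that("ROI GLMs report Holm-adjusted thickness effects per ROI", {
  co <- generate_cohort(cohort_config(n_subjects = 60, seed = 9))
  dd <- cohort_truth_table(co)
  out <- roi_glms(dd)
  expect_equal(nrow(out), 8L)
  expect_setequal(unique(out$roi), c("insula", "ofc", "acc", "pcc"))
  for (tm in c("linear", "quadratic")) {
    sel <- out$term == tm
    expect_equal(out$p_holm[sel], p.adjust(out$p_raw[sel], "holm"))
  }
  ddc <- dd
  ddc$pcc <- 2.5
  expect_error(roi_glms(ddc), "constant")
  expect_error(roi_glms(dd, rois = "pcc"), "at least 2")
})

test_that("age-related thinning fits are exact and well calibrated", {
  age <- seq(17, 54, length.out = 40)
  df <- data.frame(age = age, pcc = 3.0 - 0.007 * age)
  ft <- suppressWarnings(fit_thinning(df, covariates = character(0)))
  expect_equal(ft$slope, -0.007, tolerance = 1e-10)

  hits <- vapply(1:60, function(r) {
    set.seed(700 + r)
    a <- runif(78, 17, 54)
    d <- data.frame(age = a, pcc = 3.0 - 0.0073 * a + rnorm(78, 0, 0.05))
    abs(fit_thinning(d, covariates = character(0))$slope + 0.0073) <= 0.002
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  null_t <- vapply(1:60, function(r) {
    set.seed(900 + r)
    a <- runif(78, 17, 54)
    d <- data.frame(age = a, pcc = 2.5 + rnorm(78, 0, 0.05))
    abs(fit_thinning(d, covariates = character(0))$t_value) < 2
  }, logical(1))
  expect_gte(mean(null_t), 0.85)
})

test_that("the age-split summary mirrors threshold-coupled generators", {
  co <- generate_cohort(cohort_config(n_subjects = 30, seed = 2))
  dd <- cohort_truth_table(co)
  split <- age_split_summary(dd)
  dup <- rbind(dd, dd)
  dup$age <- c(rep(20, nrow(dd)), rep(50, nrow(dd)))
  s2 <- age_split_summary(dup)
  expect_equal(s2$r[1], s2$r[2], tolerance = 1e-12)

  small <- dd[c(which(dd$age < 35), which(dd$age >= 35)[1:2]), ]
  s3 <- age_split_summary(small)
  expect_true(s3$flagged[s3$group == "older"])
  expect_true(is.na(s3$r[s3$group == "older"]))
  expect_error(age_split_summary(dd[dd$age < 35, ]), "non-empty")

  # coupling only above 35: negative correlation concentrated in the older
  # stratum (majority of replicates; descriptive pattern, not a sharp test)
  res <- vapply(1:25, function(r) {
    cfg <- cohort_config(n_subjects = 78, seed = 5000 + r,
                         coupling_onset_age = 35, lambda_sd = 0.15,
                         pcc_noise_sd = 0.08, scanner_offsets = c(0, 0, 0))
    dd_r <- cohort_truth_table(generate_cohort(cfg))
    s <- age_split_summary(dd_r)
    c(young = s$r[s$group == "younger"], old = s$r[s$group == "older"])
  }, numeric(2))
  expect_gte(mean(res["old", ] < 0), 0.9)
  expect_gt(mean(abs(res["young", ]) < abs(res["old", ])), 0.6)
})
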