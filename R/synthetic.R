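# Synthetic cohorts with the statistical structure the analysis assumes:
# uniform ages, a quadratic age trajectory of loss aversion partially
# transmitted through posterior cingulate thickness, linear (plus a small
# quadratic) age-related thinning, scanner batch offsets, and trial-level
# choices generated from the prospect-theory model. The generator is the
# pipeline's offline testbed, not a claim about the brain.

#' Synthetic-cohort configuration
#'
#' Defaults restate the study's stated world: 106 behavioral subjects aged
#' 17-54 (83 scanned, 5 failing quality control), group choice parameters
#' lambda 1.58, rho 0.60, tau 3.07, raw-age quadratic trajectory
#' `lambda ~ -0.067 * age + 0.0010 * age^2`, PCC thinning -0.0073 mm/year
#' with a small quadratic component, and three scanners with additive
#' offsets. `mediated_fraction` is the share of the quadratic age effect
#' routed through PCC thickness; the generator chooses the thickness-to-
#' lambda coefficient `b = mediated_fraction * beta_age2 / pcc_quad` so the
#' marginal age trajectory keeps its stated coefficients and the true ACME
#' has the closed form `mediated_fraction * beta_age2 * (t1 - t0)`.
#'
#' @param n_subjects Behavioral sample size.
#' @param n_mri Number of scanned subjects (<= `n_subjects`).
#' @param n_qc_fail Scanned subjects flagged by quality control.
#' @param age_range Two-element age range in years.
#' @param lambda_mean,lambda_sd Group mean of lambda and the SD of its
#'   subject-level residual around the age trajectory.
#' @param rho_mean,rho_sd,tau_mean,tau_sd Group distributions of the other
#'   choice parameters (truncated normal).
#' @param beta_age,beta_age2 Raw-age quadratic trajectory coefficients of
#'   lambda (per year, per year^2).
#' @param pcc_intercept,pcc_slope,pcc_quad,pcc_noise_sd,pcc_center_age PCC
#'   thickness model, parameterized around `pcc_center_age` (default 35,
#'   the trajectory vertex): mm at the centering age, marginal mm/year,
#'   mm/year^2 curvature, residual SD.
#' @param mediated_fraction Share of the age^2 effect carried by PCC
#'   thickness, in \[0, 1\].
#' @param coupling_onset_age When non-`NULL`, the thickness-to-lambda path
#'   acts only on subjects older than this age (threshold-atrophy variant
#'   used to probe the age-split descriptive analysis); the marginal
#'   trajectory algebra then holds only approximately.
#' @param scanner_offsets Additive per-scanner thickness offsets (mm).
#' @param n_trials Trials per subject.
#' @param p_timeout,p_fast Rates of no-response trials and sub-200 ms RTs.
#' @param seed Integer seed.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 106L, n_mri = NULL, n_qc_fail = NULL,
                          age_range = c(17, 54),
                          lambda_mean = 1.58, lambda_sd = 0.35,
                          rho_mean = 0.60, rho_sd = 0.10,
                          tau_mean = 3.07, tau_sd = 1.2,
                          beta_age = -0.067, beta_age2 = 0.0010,
                          pcc_intercept = 2.50, pcc_slope = -0.0073,
                          pcc_quad = -0.000243, pcc_noise_sd = 0.05,
                          pcc_center_age = 35,
                          mediated_fraction = 0.5,
                          coupling_onset_age = NULL,
                          scanner_offsets = c(0, 0.15, -0.10),
                          n_trials = 128L,
                          p_timeout = 0.004, p_fast = 0.002,
                          seed = 1L) {
  # study proportions (83 scanned of 106, 5 QC failures) scale with n
  n_mri <- n_mri %||% max(3L, round(n_subjects * 83 / 106))
  n_qc_fail <- n_qc_fail %||% min(max(0L, round(n_mri * 5 / 83)), n_mri - 1L)
  cfg <- as.list(environment())
  if (any(c(lambda_sd, rho_sd, tau_sd, pcc_noise_sd) <= 0)) {
    stop("all SDs must be positive", call. = FALSE)
  }
  if (mediated_fraction < 0 || mediated_fraction > 1) {
    stop("mediated_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (mediated_fraction > 0 && pcc_quad == 0) {
    stop("pcc_quad must be nonzero when mediated_fraction > 0",
         call. = FALSE)
  }
  if (n_mri > n_subjects) stop("n_mri cannot exceed n_subjects",
                               call. = FALSE)
  if (n_qc_fail >= n_mri) stop("n_qc_fail must be below n_mri",
                               call. = FALSE)
  if (age_range[1L] >= age_range[2L]) stop("bad age_range", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# fixed parcel atlas used by the generator: typical Desikan-Killiany mean
# thicknesses (mm), age slopes (mm/year), and gray-matter volumes (mm^3)
#' @noRd
synthetic_parcels <- function() {
  data.frame(
    parcel = c("insula", "medialorbitofrontal", "lateralorbitofrontal",
               "rostralanteriorcingulate", "caudalanteriorcingulate",
               "posteriorcingulate", "superiorfrontal", "precentral",
               "lateraloccipital", "superiortemporal"),
    base = c(3.00, 2.40, 2.60, 2.90, 2.60, 2.75, 2.70, 2.50, 2.10, 2.80),
    slope = c(-0.0045, -0.0050, -0.0048, -0.0055, -0.0042, NA,
              -0.0060, -0.0040, -0.0030, -0.0052),
    volume = c(6800, 5200, 7500, 2400, 2000, 3100, 22000, 13000, 11000,
               12000))
}

#' Generate a complete synthetic study
#'
#' Draws ages uniformly in range, builds each subject's PCC thickness from
#' the thinning model plus scanner offset and noise, derives loss aversion
#' from the quadratic age trajectory with its mediated share expressed
#' through thickness, draws the remaining choice parameters from their group
#' distributions, and simulates every trial through the choice model. A
#' shared 128-trial design is used for all subjects.
#'
#' @param config A [cohort_config()].
#' @return List of class `la_cohort`: `trials` (long trial table),
#'   `thickness` (one row per scanned subject, pipeline schema),
#'   `demographics` (one row per behavioral subject), `design`, `truth`
#'   (per-subject generating parameters plus the structural coefficients),
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))

  S <- cfg$n_subjects
  ids <- sprintf("s%03d", seq_len(S))
  age <- stats::runif(S, cfg$age_range[1L], cfg$age_range[2L])
  scanner <- sample(seq_along(cfg$scanner_offsets), S, replace = TRUE)
  offs <- cfg$scanner_offsets[scanner]

  # structural model ------------------------------------------------------
  f <- cfg$mediated_fraction
  b_path <- if (f > 0) f * cfg$beta_age2 / cfg$pcc_quad else 0
  # thickness expands to (pcc_slope - 2 c pcc_quad) age + pcc_quad age^2 in
  # raw age (c the centering age); correct the direct terms so the marginal
  # lambda trajectory keeps the configured raw-age coefficients
  beta1_dir <- cfg$beta_age -
    b_path * (cfg$pcc_slope - 2 * cfg$pcc_center_age * cfg$pcc_quad)
  beta2_dir <- (1 - f) * cfg$beta_age2

  # thinning is parameterized around the trajectory vertex age so that the
  # stated linear slope is the marginal mm/year and the small quadratic
  # term stays a small perturbation over the studied age range
  ac <- age - cfg$pcc_center_age
  pcc_mean <- cfg$pcc_intercept + cfg$pcc_slope * ac + cfg$pcc_quad * ac^2
  pcc <- pcc_mean + offs + stats::rnorm(S, 0, cfg$pcc_noise_sd)

  lo <- cfg$age_range[1L]
  hi <- cfg$age_range[2L]
  e_age <- (lo + hi) / 2
  e_age2 <- (lo^2 + lo * hi + hi^2) / 3
  e_ac <- e_age - cfg$pcc_center_age
  e_ac2 <- e_age2 - 2 * cfg$pcc_center_age * e_age + cfg$pcc_center_age^2
  e_pcc <- cfg$pcc_intercept + cfg$pcc_slope * e_ac +
    cfg$pcc_quad * e_ac2 + mean(cfg$scanner_offsets)
  alpha <- cfg$lambda_mean - beta1_dir * e_age - beta2_dir * e_age2 -
    b_path * (e_pcc - cfg$pcc_intercept)

  coupled <- if (is.null(cfg$coupling_onset_age)) rep(TRUE, S) else
    age > cfg$coupling_onset_age
  lambda <- alpha + beta1_dir * age + beta2_dir * age^2 +
    b_path * coupled * (pcc - cfg$pcc_intercept) +
    stats::rnorm(S, 0, cfg$lambda_sd)
  lambda <- pmin(pmax(lambda, 0.05), 4.95)
  rho <- rtnorm(S, cfg$rho_mean, cfg$rho_sd, 0.05, 1.95)
  tau <- rtnorm(S, cfg$tau_mean, cfg$tau_sd, 0.2, 25)

  # demographics -----------------------------------------------------------
  demographics <- data.frame(
    subject_id = ids, age = age,
    sex = sample(c("F", "M"), S, replace = TRUE, prob = c(0.35, 0.65)),
    race_ethnicity = sample(1:4, S, replace = TRUE,
                            prob = c(0.45, 0.25, 0.20, 0.10)),
    smoking = stats::rbinom(S, 1L, 0.35),
    iq = round(stats::rnorm(S, 108, 10), 1),
    mother_education = round(rtnorm(S, 13.5, 2.5, 6, 20), 1),
    scanner_id = scanner)

  # thickness table for the scanned subset ---------------------------------
  mri_idx <- sort(sample.int(S, cfg$n_mri))
  qc_fail <- sample(mri_idx, cfg$n_qc_fail)
  atlas <- synthetic_parcels()
  thick <- data.frame(subject_id = ids[mri_idx],
                      age = age[mri_idx],
                      sex = demographics$sex[mri_idx],
                      race_ethnicity = demographics$race_ethnicity[mri_idx],
                      scanner_id = scanner[mri_idx],
                      etiv = round(rtnorm(length(mri_idx), 1.5e6, 1.3e5,
                                          1e6, 2.1e6)),
                      qc_pass = !(mri_idx %in% qc_fail))
  for (r in seq_len(nrow(atlas))) {
    p <- atlas$parcel[r]
    for (h in c("lh", "rh")) {
      if (p == "posteriorcingulate") {
        th <- pcc[mri_idx] + stats::rnorm(length(mri_idx), 0, 0.01)
      } else {
        th <- atlas$base[r] + atlas$slope[r] * age[mri_idx] + offs[mri_idx] +
          stats::rnorm(length(mri_idx), 0, 0.05)
      }
      thick[[paste0(p, "_", h, "_thickness")]] <-
        pmin(pmax(th, 0.55), 4.95)
      thick[[paste0(p, "_", h, "_volume")]] <-
        round(atlas$volume[r] * stats::rnorm(length(mri_idx), 1, 0.08))
    }
  }

  # trials ------------------------------------------------------------------
  design <- generate_design(cfg$n_trials, seed = cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, S)
  trials <- do.call(rbind, lapply(seq_len(S), function(i) {
    simulate_choices(design, prospect_params(lambda[i], rho[i], tau[i]),
                     seed = subj_seeds[i], subject_id = ids[i],
                     p_timeout = cfg$p_timeout, p_fast = cfg$p_fast)
  }))

  truth <- list(subjects = data.frame(subject_id = ids, age = age,
                                      lambda = lambda, rho = rho, tau = tau,
                                      pcc = pcc, scanner_id = scanner),
                b_path = b_path, beta1_direct = beta1_dir,
                beta2_direct = beta2_dir, alpha = alpha)
  structure(list(trials = trials, thickness = thick,
                 demographics = demographics, design = design,
                 truth = truth, config = cfg),
            class = "la_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `trials.csv`, `thickness.csv`, and `demographics.csv` in the exact
#' schemas the pipeline readers consume.
#'
#' @param cohort An `la_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param digits Decimal places used for continuous columns, so rewrites are
#'   byte-stable.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, digits = 4L) {
  stopifnot(inherits(cohort, "la_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(df) {
    for (j in names(df)) {
      if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
        df[[j]] <- round(df[[j]], digits)
      }
    }
    df
  }
  utils::write.csv(num(cohort$trials), file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num(cohort$thickness), file.path(dir, "thickness.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num(cohort$demographics),
                   file.path(dir, "demographics.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Deterministic miniature fixture
#'
#' Five subjects, 20 trials each, two scanners; subject `s005` is forced to
#' accept every gamble so the degeneracy screen has a guaranteed hit. Used
#' by unit tests and documentation; regenerating with the fixed internal
#' seed reproduces the files byte for byte.
#'
#' @param dir Optional directory; when given, the three CSVs are written
#'   there.
#' @return The `la_cohort`, invisibly when `dir` is given.
#' @export
generate_worked_fixture <- function(dir = NULL) {
  # high choice consistency so the four honest subjects pass the screen
  # even at 20 trials; subject s005 is overwritten below
  cfg <- cohort_config(n_subjects = 5L, n_mri = 4L, n_qc_fail = 1L,
                       n_trials = 20L, p_timeout = 0, p_fast = 0,
                       tau_mean = 6, tau_sd = 0.5, lambda_sd = 0.2,
                       scanner_offsets = c(0, 0.15), seed = 424242L)
  cohort <- generate_cohort(cfg)
  force_accept <- cohort$trials$subject_id == "s005"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(7L)
  cohort$trials$response[force_accept] <-
    sample(1:2, sum(force_accept), replace = TRUE)
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    return(invisible(cohort))
  }
  cohort
}
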