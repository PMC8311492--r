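# shared fixtures built in code

# small cohort of model-consistent subjects simulated on a shared design
sim_cohort_trials <- function(n_subjects, lambda, rho, tau, n_trials = 128L,
                              design_seed = 1L, seed = 100L) {
  d <- generate_design(n_trials, seed = design_seed)
  lambda <- rep_len(lambda, n_subjects)
  rho <- rep_len(rho, n_subjects)
  tau <- rep_len(tau, n_subjects)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    simulate_choices(d, prospect_params(lambda[i], rho[i], tau[i]),
                     seed = seed + i, subject_id = sprintf("s%03d", i))
  }))
  out$accept <- collapse_response(out$response)
  out
}

# merged subject-level analysis table from a synthetic cohort, using the
# generator's true parameters in place of the estimation stage
cohort_truth_table <- function(cohort) {
  tt <- merge(cohort$truth$subjects[, c("subject_id", "age", "lambda",
                                        "rho", "tau")],
              cohort$demographics[, c("subject_id", "race_ethnicity",
                                      "sex")],
              by = "subject_id")
  tt$race_ethnicity <- factor(tt$race_ethnicity)
  th <- cohort$thickness[cohort$thickness$qc_pass, , drop = FALSE]
  rois <- build_rois(th)
  merge(merge(rois, tt, by = "subject_id"),
        th[, c("subject_id", "etiv", "scanner_id")], by = "subject_id")
}
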