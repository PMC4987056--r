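# shared fixtures: small acquisition configs and reference concentration sets

acq_clean <- function(...) {
  acquisition_params(noise_sd = 0, phase_range = c(0, 0),
                     offset_range = c(0, 0), background = FALSE, ...)
}

plasma_t1_conc <- function() {
  tab <- plasma_reference_table()
  stats::setNames(tab$med_t1, tab$metabolite)[tab$identified]
}

urine_t1_conc <- function() {
  tab <- urine_reference_table()
  stats::setNames(tab$med_t1, tab$metabolite)[tab$identified]
}

# a quick paired plasma cohort at the concentration level
paired_cohort_matrices <- function(n = 100, material = "plasma", seed = 1,
                                   timepoints = c("t1", "t2")) {
  coh <- sample_cohort(demo_design(ceiling(n / 2)), seed = seed)
  tab <- if (material == "plasma") plasma_reference_table()
         else urine_reference_table()
  mod <- concentration_model(tab)
  conc <- sample_concentrations(mod, coh, timepoints = timepoints,
                                seed = seed + 1)
  lapply(stats::setNames(timepoints, timepoints),
         function(tp) concentration_matrix(conc, tp)[seq_len(n), , drop = FALSE])
}
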