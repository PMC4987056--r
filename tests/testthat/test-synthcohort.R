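test_that("log-normal fits reproduce printed medians and IQRs", {
  # degenerate IQR
  expect_equal(fit_lognormal_from_median_iqr(1, 1, 1), list(mu = 0, sigma = 0))
  # closed form for a symmetric-on-log-scale IQR
  fit <- fit_lognormal_from_median_iqr(10, 5, 20)
  expect_equal(fit$mu, log(10))
  expect_equal(fit$sigma, log(4) / (2 * qnorm(0.75)))
  # brute-force grid search over sigma reproduces the closed form
  q75 <- function(sigma) exp(log(10) + sigma * qnorm(0.75))
  grid <- seq(0.01, 3, by = 1e-4)
  best <- grid[which.min(abs(q75(grid) - 20))]
  expect_equal(fit$sigma, best, tolerance = 1e-3)
  # Monte-Carlo quantile oracle on the plasma lactate baseline parameters
  fit_lac <- fit_lognormal_from_median_iqr(2.9, 1.5, 5.3)
  set.seed(1)
  draws <- exp(fit_lac$mu + fit_lac$sigma * rnorm(1e5))
  qs <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(qs[2], 2.9, tolerance = 0.03)
  expect_equal(qs[1], 1.5, tolerance = 0.03)
  expect_equal(qs[3], 5.3, tolerance = 0.03)
  # invalid summaries are rejected
  expect_error(fit_lognormal_from_median_iqr(1, 2, 3), "q1 <= median")
  expect_error(fit_lognormal_from_median_iqr(1, 0, 3), "positive")
})

test_that("cohort sampling matches the study design and is deterministic", {
  des <- study_design()
  coh <- sample_cohort(des, seed = 4)
  expect_equal(nrow(coh$animals), sum(c(21, 32, 21, 8, 16, 12)))
  expect_equal(as.vector(table(coh$animals$group)), c(21, 32, 21, 8, 16, 12))
  expect_true(all(coh$animals$time_to_asystole > 0))
  expect_true(all(coh$animals$time_to_rosc > 0))
  # non-survivors never contribute post-baseline samples
  dead <- coh$animals$animal[!coh$animals$survived]
  post <- coh$manifest$timepoint != "t1"
  expect_false(any(coh$manifest$available[post &
                                            coh$manifest$animal %in% dead]))
  # determinism
  coh2 <- sample_cohort(des, seed = 4)
  expect_identical(coh, coh2)
  # full availability design has every sample for survivors
  av <- sample_availability_table()
  for (cn in setdiff(names(av), c("group", "n"))) av[[cn]] <- av$n
  des_full <- study_design(groups = group_design_table(), availability = av,
                           survival_prob = 1)
  coh_full <- sample_cohort(des_full, seed = 1)
  expect_true(all(coh_full$manifest$available))
  # zero availability at t3 removes all t3 samples
  av0 <- av; av0$plasma_t3 <- 0L; av0$urine_t3 <- 0L
  coh0 <- sample_cohort(study_design(groups = group_design_table(),
                                     availability = av0, survival_prob = 1),
                        seed = 1)
  expect_false(any(coh0$manifest$available[coh0$manifest$timepoint == "t3"]))
})

test_that("concentration trajectories apply signed fold changes multiplicatively", {
  coh <- sample_cohort(demo_design(5), seed = 1)
  tab <- plasma_reference_table()[1:3, ]
  tab$q1_t1 <- tab$med_t1; tab$q3_t1 <- tab$med_t1   # sigma = 0
  tab$fc_t1_t2 <- c(2, -2, 1)
  mod <- concentration_model(tab, noise_sd = 0)
  conc <- sample_concentrations(mod, coh, timepoints = c("t1", "t2"), seed = 2)
  w1 <- concentration_matrix(conc, "t1")
  w2 <- concentration_matrix(conc, "t2")
  expect_equal(w2[, 1], 2 * w1[, 1])        # FC +2 doubles
  expect_equal(w2[, 2], w1[, 2] / 2)        # FC -2 halves
  expect_equal(w2[, 3], w1[, 3])            # FC 1 unchanged
  # missing fold change errors with the metabolite name
  tab$fc_t1_t2[2] <- NA
  expect_error(sample_concentrations(concentration_model(tab, 0), coh,
                                     timepoints = c("t1", "t2"), seed = 2),
               tab$metabolite[2], fixed = TRUE)
  # determinism
  conc2 <- sample_concentrations(mod, coh, timepoints = c("t1", "t2"), seed = 2)
  mod_full <- concentration_model(plasma_reference_table())
  expect_identical(sample_concentrations(mod_full, coh, seed = 9),
                   sample_concentrations(mod_full, coh, seed = 9))
})

test_that("cohort marginals reproduce the configured succinate transition", {
  coh <- sample_cohort(demo_design(50), seed = 3)
  mod <- concentration_model(plasma_reference_table())
  conc <- sample_concentrations(mod, coh, timepoints = c("t1", "t2"), seed = 4)
  w1 <- concentration_matrix(conc, "t1")
  w2 <- concentration_matrix(conc, "t2")
  ratio <- median(w2[, "Succinate"]) / median(w1[, "Succinate"])
  expect_equal(ratio, 7.67, tolerance = 0.10)
})

test_that("quantile fidelity: large-sample marginals match configured summaries", {
  tab <- plasma_reference_table()
  mod <- concentration_model(tab)
  set.seed(5)
  # the two-parameter log-normal can hit median and IQR *ratio* exactly for
  # every metabolite; it can hit both individual quartiles only when the
  # printed IQR is symmetric on the log scale
  for (i in seq_len(nrow(tab))) {
    draws <- exp(mod$mu_t1[i] + mod$sigma_t1[i] * rnorm(1e5))
    qs <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(qs[2], tab$med_t1[i], tolerance = 0.03)
    if (tab$q1_t1[i] >= tab$med_t1[i] / 10) {
      expect_equal(qs[3] / qs[1], tab$q3_t1[i] / tab$q1_t1[i],
                   tolerance = 0.05)
      log_sym <- abs(log((tab$med_t1[i] / tab$q1_t1[i]) /
                           (tab$q3_t1[i] / tab$med_t1[i])))
      if (log_sym < 0.03) {
        expect_equal(qs[1], tab$q1_t1[i], tolerance = 0.03)
        expect_equal(qs[3], tab$q3_t1[i], tolerance = 0.03)
      }
    }
  }
})

test_that("rendered spectra satisfy the area identities", {
  pan <- metabolite_panel("plasma")
  acq <- acq_clean()
  # TSP + water only when all concentrations are zero and no background
  s0 <- render_spectrum(c(Lactate = 0), pan, acq, seed = 1)
  expect_lt(max(abs(spec_real(s0)[s0$ppm > 1 & s0$ppm < 4])), 0.5)
  # lactate doublet area over TSP area equals the proton-weighted ratio
  s <- render_spectrum(c(Lactate = 2.9), pan, acq, seed = 1)
  a_lac <- integrate_signal(s, c(1.33 - 0.05, 1.33 + 0.05))
  a_tsp <- integrate_signal(s, c(-0.08, 0.08))
  expect_equal(a_lac / a_tsp, (2.9 * 3) / (0.5 * 9), tolerance = 0.01)
  # area linearity: doubling the concentration doubles the signal area
  s2 <- render_spectrum(c(Lactate = 5.8), pan, acq, seed = 1)
  a2 <- integrate_signal(s2, c(1.33 - 0.05, 1.33 + 0.05))
  expect_equal(a2 / a_lac, 2, tolerance = 1e-3)
  # conservation: total area equals the sum of configured component areas
  conc <- c(Lactate = 2.9, Alanine = 0.64, Glucose = 6)
  s3 <- render_spectrum(conc, pan, acq, seed = 1)
  pro <- pan$protons[match(names(conc), pan$metabolite)]
  expected <- sum(conc * pro) + 0.5 * 9
  total <- asphyxNMR:::trapz(s3$ppm, spec_real(s3))
  expect_equal(total, expected, tolerance = 0.02 * expected)
  # ground truth recorded in metadata
  s4 <- render_spectrum(c(Lactate = 1), pan, acquisition_params(), seed = 9)
  expect_true(is.finite(s4$meta$phase_deg))
  expect_true(is.finite(s4$meta$ppm_offset))
  # unknown metabolite names rejected
  expect_error(render_spectrum(c(NotAMetabolite = 1), pan, acq),
               "absent from panel")
  # bit determinism
  expect_identical(render_spectrum(conc, pan, acquisition_params(), seed = 3),
                   render_spectrum(conc, pan, acquisition_params(), seed = 3))
})

test_that("endpoint link injects the configured correlation", {
  des <- demo_design(100)
  coh <- sample_cohort(des, seed = 28)
  mod <- concentration_model(plasma_reference_table())
  conc <- sample_concentrations(mod, coh, timepoints = "t1", seed = 29,
                                endpoint_link = list(metabolite = "Hypoxanthine",
                                                     score = "z_asystole",
                                                     rho = -0.23))
  w <- concentration_matrix(conc, "t1")
  r <- cor(log(w[, "Hypoxanthine"]), log(coh$animals$time_to_asystole))
  expect_lt(abs(r - (-0.23)), 0.1)
})
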