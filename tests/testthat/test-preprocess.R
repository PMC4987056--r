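test_that("zero-order phase correction recovers injected phase errors", {
  pan <- metabolite_panel("plasma")
  acq <- acq_clean()
  s0 <- render_spectrum(c(Lactate = 2.9), pan, acq, seed = 1, phase_deg = 0)
  p0 <- phase_correct_zero_order(s0)
  expect_lt(abs(p0$qc$phase_deg), 0.5)
  s30 <- render_spectrum(c(Lactate = 2.9), pan, acq, seed = 1, phase_deg = 30)
  p30 <- phase_correct_zero_order(s30)
  expect_equal(p30$qc$phase_deg, -30, tolerance = 0.5)
  # TSP area restored to the unphased value
  a0 <- integrate_signal(s0, c(-0.08, 0.08))
  a30 <- integrate_signal(p30, c(-0.08, 0.08))
  expect_equal(a30 / a0, 1, tolerance = 1e-3)
  # idempotence: rerunning adds (almost) no extra rotation
  p30b <- phase_correct_zero_order(p30)
  expect_lt(abs(p30b$qc$phase_deg - p30$qc$phase_deg), 0.5)
  # real-only input: warning and no-op
  sr <- nmr_spectrum(s0$ppm, spec_real(s0))
  expect_warning(pr <- phase_correct_zero_order(sr), "real-valued")
  expect_equal(pr$intensity, sr$intensity)
  # noisy render with backgrounds: recovery within 1.5 degrees
  sN <- render_spectrum(plasma_t1_conc(), pan, acquisition_params(), seed = 5)
  pN <- phase_correct_zero_order(sN)
  expect_equal(-pN$qc$phase_deg, sN$meta$phase_deg, tolerance = 1.5)
})

test_that("separate linear baselines are removed on both sides of the water", {
  pan <- metabolite_panel("plasma")
  s <- render_spectrum(c(Lactate = 2.9, Formate = 0.5), pan, acq_clean(),
                       seed = 1)
  s$intensity <- Re(s$intensity)
  # zero baseline: output equals input up to the residual grass level of
  # far peak tails picked up by the support points
  out0 <- subtract_linear_baselines(s)
  expect_lt(max(abs(spec_real(out0) - spec_real(s))), 0.1)
  # different lines on each side are recovered to < 1% of their amplitude
  lo <- s$ppm < 4.55; hi <- s$ppm >= 5.0
  tilted <- s
  y <- spec_real(s)
  y[lo] <- y[lo] + (3 - 2 * s$ppm[lo])
  y[hi] <- y[hi] + (-1 + 4 * s$ppm[hi])
  tilted$intensity <- y
  out <- subtract_linear_baselines(tilted, water = c(4.55, 5.0))
  resid <- spec_real(out) - spec_real(s)
  quiet <- (s$ppm > 6 & s$ppm < 8) | (s$ppm > 2 & s$ppm < 2.3)
  expect_lt(sqrt(mean(resid[quiet]^2)), 0.01 * 30)
  # peak areas preserved within 2%
  a_ref <- integrate_signal(s, c(1.28, 1.38))
  a_cor <- integrate_signal(out, c(1.28, 1.38))
  expect_equal(a_cor / a_ref, 1, tolerance = 0.02)
  # degenerate water interval
  expect_error(subtract_linear_baselines(s, water = c(-2, 5)),
               "no data on one side")
})

test_that("axis referencing recovers injected offsets for both materials", {
  pan <- metabolite_panel("plasma")
  acq <- acq_clean()
  conc <- plasma_t1_conc()
  # already aligned: shift ~ 0
  s0 <- render_spectrum(conc, pan, acq, seed = 1, ppm_offset = 0)
  r0 <- reference_axis(s0)
  expect_lt(abs(r0$qc$ppm_shift), 7e-4)
  # injected +0.02 ppm offset is removed
  s1 <- render_spectrum(conc, pan, acq, seed = 1, ppm_offset = 0.02)
  r1 <- reference_axis(s1)
  expect_equal(r1$qc$ppm_shift, -0.02, tolerance = 7e-4)
  # urine anchors on TSP
  panu <- metabolite_panel("urine")
  su <- render_spectrum(urine_t1_conc(), panu, acq_clean(), seed = 1,
                        ppm_offset = -0.008)
  ru <- reference_axis(su)
  expect_equal(unname(ru$qc$ppm_shift), 0.008, tolerance = 7e-4)
  # missing anchor errors with its name
  flat <- nmr_spectrum(seq(-1, 10, length.out = 2048),
                       complex(real = rep(0, 2048), imaginary = rep(0, 2048)))
  expect_error(reference_axis(flat), "anchor")
})

test_that("clipping and excision retain exactly the expected points", {
  pan <- metabolite_panel("plasma")
  s <- render_spectrum(c(Lactate = 1), pan, acq_clean(), seed = 1)
  # empty regions: only clipping
  c0 <- clip_and_excise(s, regions = list())
  expect_true(all(c0$ppm >= -0.5 & c0$ppm <= 9))
  expect_equal(length(c0$ppm), sum(s$ppm >= -0.5 & s$ppm <= 9))
  # default plasma regions leave no points inside water or TSP intervals
  regs <- default_regions("plasma")
  c1 <- clip_and_excise(s, regions = regs)
  for (r in regs)
    expect_equal(sum(c1$ppm >= r[1] & c1$ppm < r[2]), 0)
  # counting identity
  inside <- s$ppm >= -0.5 & s$ppm <= 9
  removed <- rep(FALSE, length(s$ppm))
  for (r in regs) removed <- removed | (s$ppm >= r[1] & s$ppm < r[2])
  expect_equal(length(c1$ppm), sum(inside & !removed))
  expect_error(clip_and_excise(s, regions = list(all = c(-2, 11))),
               "entire spectrum")
})

test_that("TSP normalization fixes the reference area and is scale invariant", {
  pan <- metabolite_panel("plasma")
  s <- render_spectrum(c(Lactate = 2.9), pan, acq_clean(), seed = 1)
  s$intensity <- Re(s$intensity)
  n1 <- normalize_to_tsp(s)
  # the recorded pre-normalization area matches the configured TSP signal
  expect_equal(n1$qc$tsp_area, 0.5 * 9, tolerance = 0.04 * 4.5)
  # post-normalization area over the integration window is 1
  w <- n1$history[[length(n1$history)]]$params$window
  expect_equal(integrate_signal(n1, w), 1, tolerance = 1e-6)
  # global gain cancels exactly
  s2 <- s; s2$intensity <- 2 * s2$intensity
  n2 <- normalize_to_tsp(s2)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  # non-positive TSP area rejected
  neg <- s; neg$intensity <- -abs(spec_real(s))
  expect_error(normalize_to_tsp(neg), "not resolved|non-positive")
})

test_that("TSP FWHM measurement matches the Lorentzian closed form", {
  pan <- metabolite_panel("plasma")
  acq <- acq_clean()       # base TSP FWHM 0.003, i.e. gamma = 0.0015
  s <- render_spectrum(c(Lactate = 0), pan, acq, seed = 1)
  s$intensity <- Re(s$intensity)
  dx <- diff(s$ppm[1:2])
  expect_equal(measure_tsp_fwhm(s), 0.003, tolerance = dx / 0.003)
  # generator broadening factor is recovered as a FWHM ratio
  s15 <- render_spectrum(c(Lactate = 0), pan, acq, seed = 1,
                         tsp_broadening = 1.5)
  s15$intensity <- Re(s15$intensity)
  expect_equal(measure_tsp_fwhm(s15) / measure_tsp_fwhm(s), 1.5,
               tolerance = 0.05)
  # independent of global intensity scale
  sg <- s; sg$intensity <- 7.3 * sg$intensity
  expect_equal(measure_tsp_fwhm(sg), measure_tsp_fwhm(s))
})

test_that("adaptive baseline removes broad backgrounds and keeps narrow peaks", {
  pan <- metabolite_panel("plasma")
  acq <- acq_clean()
  s <- render_spectrum(c(Lactate = 2.9, Alanine = 0.64, Glucose = 6),
                       pan, acq, seed = 1)
  s$intensity <- Re(s$intensity)
  # zero background: output ~ input away from the tall peaks (block
  # medians inside a peak are elevated, so the baseline may rise by a few
  # intensity units right under it; quiet regions must be untouched and
  # peak areas preserved)
  b0 <- adaptive_baseline(s)
  quiet0 <- (s$ppm > 2 & s$ppm < 3) | (s$ppm > 6 & s$ppm < 8)
  expect_lt(max(abs((spec_real(b0) - spec_real(s))[quiet0])), 0.6)
  expect_equal(integrate_signal(b0, c(1.30, 1.36)) /
                 integrate_signal(s, c(1.30, 1.36)), 1, tolerance = 0.05)
  # narrow Lorentzians on a 1-ppm-wide Gaussian hump
  hump <- 60 * dnorm(s$ppm, 3, 1)
  sh <- s; sh$intensity <- spec_real(s) + hump
  bh <- adaptive_baseline(sh)
  resid_bg <- spec_real(bh) - spec_real(s)
  quiet <- (s$ppm > 2 & s$ppm < 2.3) | (s$ppm > 3.6 & s$ppm < 4)
  expect_lt(sqrt(mean(resid_bg[quiet]^2)), 0.05 * max(hump))
  # narrow-peak areas preserved within 10%
  a_ref <- integrate_signal(s, c(1.30, 1.36))
  a_cor <- integrate_signal(bh, c(1.30, 1.36))
  expect_equal(a_cor / a_ref, 1, tolerance = 0.1)
  # degenerate flat input returned unchanged
  flat <- nmr_spectrum(seq(0, 1, length.out = 512), rep(2, 512))
  expect_equal(spec_real(adaptive_baseline(flat)), rep(2, 512))
})

test_that("the full chain is ordered, logged, and stable under re-running", {
  pan <- metabolite_panel("plasma")
  s <- render_spectrum(plasma_t1_conc(), pan, acquisition_params(), seed = 21)
  p <- preprocess_spectrum(s)
  ops <- vapply(p$history, `[[`, "", "op")
  expect_equal(ops, c("phase_correct_zero_order", "subtract_linear_baselines",
                      "reference_axis", "clip_and_excise", "normalize_to_tsp",
                      "adaptive_baseline", "clip_and_excise"))
  expect_true(all(is.finite(unlist(p$qc[c("tsp_area", "tsp_fwhm",
                                          "phase_deg", "ppm_shift")]))))
  # QC table collects one row per sample
  qc <- qc_table(list(a = p, b = p))
  expect_equal(dim(qc), c(2L, 5L))
  # scale invariance end to end
  s2 <- s; s2$intensity <- 3.7 * s2$intensity
  p2 <- preprocess_spectrum(s2)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-9)
  # every operation appended exactly one history entry
  expect_equal(length(p$history), 7L)
})
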