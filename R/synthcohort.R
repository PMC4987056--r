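#' Fit a log-normal distribution to a printed median and interquartile range
#'
#' Moment-matches a log-normal to published summary statistics: the location
#' is `log(median)` and the scale is `log(q3/q1) / (2 * qnorm(0.75))`, so that
#' the distribution's median and IQR reproduce the printed values exactly.
#'
#' @param median,q1,q3 median and quartiles, all positive, `q1 <= median <= q3`.
#' @return list with elements `mu` and `sigma` (`sigma = 0` when `q1 == q3`).
#' @examples
#' fit_lognormal_from_median_iqr(2.9, 1.5, 5.3)
#' @export
fit_lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0))
    stop("median and quartiles must be positive and finite")
  if (q1 > median || median > q3)
    stop("quartiles must satisfy q1 <= median <= q3")
  list(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# tolerant variant used when building generator configs from printed tables:
# a printed lower quartile of 0 (or one sitting far below the median, i.e.
# at a detection floor) says nothing usable about log-normal spread and
# would imply molar-range upper tails, so the scale is then taken from the
# upper half-spread alone (median and q3 are reproduced exactly; q1 is not)
lognormal_params_tolerant <- function(median, q1, q3) {
  if (q1 >= median / 10) return(fit_lognormal_from_median_iqr(median, q1, q3))
  list(mu = log(median), sigma = log(q3 / median) / stats::qnorm(0.75))
}

# unsigned multiplicative ratio from a signed fold change (|fc| >= 1):
# +2 doubles, -2 halves
signed_fc_to_ratio <- function(fc) {
  if (any(!is.finite(fc)) || any(abs(fc) < 1))
    stop("signed fold changes must satisfy |FC| >= 1")
  ifelse(fc > 0, fc, -1 / fc)
}

# n standard-normal scores by stratified inversion (one draw per probability
# stratum, randomly ordered); marginally N(0,1) but with near-exact sample
# quantiles, so a finite cohort reproduces the configured median/IQR
rnorm_stratified <- function(n) {
  stats::qnorm((sample.int(n) - stats::runif(n)) / n)
}

draw_scores <- function(n, sampling = c("stratified", "iid")) {
  sampling <- match.arg(sampling)
  z <- if (sampling == "stratified") rnorm_stratified(n) else stats::rnorm(n)
  # winsorize extreme latent scores: quartiles (hence configured median/IQR)
  # are untouched, but unphysical concentration extremes implied by
  # extrapolating printed summaries over 3+ sd are avoided
  pmax(-3, pmin(3, z))
}

#' Study design for the synthetic cohort generator
#'
#' Bundles the resuscitation-group table (sizes, ventilation parameters,
#' time-to-asystole and time-to-ROSC summaries), the ordered time points and
#' per-group sample-availability rates into a validated design object. The
#' default is the pooled six-protocol design of the emulated study.
#'
#' @param groups `data.frame` as returned by [group_design_table()].
#' @param availability `data.frame` as returned by
#'   [sample_availability_table()]; converted to rates within each group.
#' @param timepoints ordered character vector of time-point labels.
#' @param survival_prob probability that an animal survives to t2/t3
#'   (non-survivors contribute no post-ROSC samples).
#' @param asystole_unit,rosc_unit unit labels stored with the endpoint times.
#'   The asystole clock is stored in minutes by default (the progressive
#'   asphyxiation protocol operates on a minutes scale), ROSC in seconds.
#' @return object of class `study_design`.
#' @export
study_design <- function(groups = group_design_table(),
                         availability = sample_availability_table(),
                         timepoints = c("t1", "t2", "t3"),
                         survival_prob = 0.85,
                         asystole_unit = "min", rosc_unit = "s") {
  stopifnot(all(groups$n > 0), !anyDuplicated(groups$group),
            length(timepoints) >= 1, !anyDuplicated(timepoints),
            survival_prob >= 0, survival_prob <= 1)
  rates <- availability
  for (m in c("plasma", "urine")) for (tp in c("t1", "t2", "t3")) {
    cn <- paste(m, tp, sep = "_")
    if (cn %in% names(rates)) {
      rates[[cn]] <- rates[[cn]] / rates$n
      if (any(rates[[cn]] < 0 | rates[[cn]] > 1))
        stop("availability rates must lie in [0, 1]")
    }
  }
  structure(list(groups = groups, availability = rates,
                 timepoints = timepoints, survival_prob = survival_prob,
                 asystole_unit = asystole_unit, rosc_unit = rosc_unit),
            class = "study_design")
}

#' Simulate a cohort of animals and its sample manifest
#'
#' Draws one animal per design slot with log-normal time-to-asystole and
#' time-to-ROSC (matched to the per-group median/IQR), a survival flag, a
#' per-animal TSP-broadening factor (plasma lipoprotein proxy), and latent
#' standard-normal endpoint scores that concentration draws can be correlated
#' against. The manifest marks, per animal, time point and material, whether a
#' sample is available (per-group availability rates; non-survivors lack
#' t2/t3 samples).
#'
#' @param design a [study_design()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param tsp_broadening_params list `(med, q1, q3)` of the plasma TSP
#'   broadening factor distribution relative to the unbroadened linewidth.
#' @return list with `animals` and `manifest` data frames.
#' @export
sample_cohort <- function(design = study_design(), seed = 1,
                          tsp_broadening_params = list(med = 0.0047 / 0.003,
                                                       q1 = 0.003 / 0.003,
                                                       q3 = 0.007 / 0.003)) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  g <- design$groups
  n_tot <- sum(g$n)
  bp <- do.call(fit_lognormal_from_median_iqr, tsp_broadening_params)
  rows <- vector("list", nrow(g))
  idx0 <- 0L
  for (i in seq_len(nrow(g))) {
    n <- g$n[i]
    pa <- fit_lognormal_from_median_iqr(g$asystole_med[i], g$asystole_q1[i],
                                        g$asystole_q3[i])
    pr <- fit_lognormal_from_median_iqr(g$rosc_med[i], g$rosc_q1[i],
                                        g$rosc_q3[i])
    z_asy <- stats::rnorm(n)
    z_rosc <- stats::rnorm(n)
    rows[[i]] <- data.frame(
      animal = sprintf("A%03d", idx0 + seq_len(n)),
      group = g$group[i],
      time_to_asystole = exp(pa$mu + pa$sigma * z_asy),
      time_to_rosc = exp(pr$mu + pr$sigma * z_rosc),
      z_asystole = z_asy, z_rosc = z_rosc,
      survived = stats::runif(n) < design$survival_prob,
      tsp_broadening = exp(bp$mu + bp$sigma * stats::rnorm(n)),
      stringsAsFactors = FALSE)
    idx0 <- idx0 + n
  }
  animals <- do.call(rbind, rows)
  attr(animals, "asystole_unit") <- design$asystole_unit
  attr(animals, "rosc_unit") <- design$rosc_unit

  man <- expand.grid(animal = animals$animal,
                     timepoint = design$timepoints,
                     material = c("plasma", "urine"),
                     stringsAsFactors = FALSE)
  man <- man[order(man$animal, man$material, man$timepoint), ]
  man$group <- animals$group[match(man$animal, animals$animal)]
  av <- design$availability
  rate_of <- function(material, tp, grp) {
    cn <- paste(material, tp, sep = "_")
    if (!cn %in% names(av)) return(1)
    av[[cn]][match(grp, av$group)]
  }
  r <- mapply(rate_of, man$material, man$timepoint, man$group)
  man$available <- stats::runif(nrow(man)) < r
  surv <- animals$survived[match(man$animal, animals$animal)]
  post <- man$timepoint != design$timepoints[1]
  man$available[post & !surv] <- FALSE
  man$sample_id <- paste(man$animal, man$material, man$timepoint, sep = "_")
  rownames(man) <- NULL
  list(animals = animals, manifest = man)
}

#' Metabolite signal panel for a material
#'
#' The panel names each quantifiable signal: position (ppm), multiplicity,
#' protons per signal and whether the compound is identified (mM) or an
#' unknown signal (arbitrary units; excluded from the spectral forward model
#' because its proton count is unknown).
#'
#' @param material `"plasma"` or `"urine"`.
#' @param identified_only drop unknown signals.
#' @return `data.frame` with columns `metabolite`, `ppm`, `multiplicity`,
#'   `protons`, `identified`.
#' @export
metabolite_panel <- function(material = c("plasma", "urine"),
                             identified_only = FALSE) {
  material <- match.arg(material)
  tab <- if (material == "plasma") plasma_reference_table()
         else urine_reference_table()
  pan <- tab[, c("metabolite", "ppm", "multiplicity", "protons", "identified")]
  if (any(pan$ppm < -0.5 | pan$ppm > 9.0)) stop("panel ppm outside [-0.5, 9]")
  if (anyDuplicated(pan$metabolite)) stop("panel names must be unique")
  if (identified_only) pan <- pan[pan$identified, ]
  pan$material <- material
  rownames(pan) <- NULL
  pan
}

#' Concentration model derived from a reference table
#'
#' Converts per-metabolite printed medians/IQRs at baseline into log-normal
#' parameters and carries the signed within-animal fold changes for the
#' t1->t2 and t2->t3 transitions plus a within-animal log-scale noise sd.
#'
#' @param table reference table shaped like [plasma_reference_table()].
#' @param noise_sd within-animal log-scale noise applied on each transition.
#' @return object of class `concentration_model`.
#' @export
concentration_model <- function(table, noise_sd = 0.25) {
  stopifnot(noise_sd >= 0)
  par <- lapply(seq_len(nrow(table)), function(i)
    lognormal_params_tolerant(table$med_t1[i], table$q1_t1[i], table$q3_t1[i]))
  structure(list(
    metabolite = table$metabolite,
    mu_t1 = vapply(par, `[[`, 0, "mu"),
    sigma_t1 = vapply(par, `[[`, 0, "sigma"),
    fc_t1_t2 = table$fc_t1_t2,
    fc_t2_t3 = table$fc_t2_t3,
    med_t1 = table$med_t1,
    noise_sd = noise_sd), class = "concentration_model")
}

#' Draw concentration trajectories for a cohort
#'
#' Baseline (t1) values are log-normal draws from the model; each later time
#' point multiplies the previous one by the unsigned ratio of the configured
#' signed fold change times `exp(noise)` (log-scale AR structure). Optionally
#' one metabolite's baseline score is correlated with a latent endpoint score
#' stored in the cohort.
#'
#' @param model a [concentration_model()].
#' @param cohort result of [sample_cohort()] (or a list with an `animals`
#'   data frame).
#' @param timepoints time points to generate, a prefix of `c("t1","t2","t3")`.
#' @param seed integer seed.
#' @param sampling `"stratified"` (default; per-metabolite stratified normal
#'   scores giving finite-cohort quantile fidelity) or `"iid"`.
#' @param endpoint_link optional list `(metabolite, score, rho)` correlating
#'   the metabolite's baseline log-concentration with the cohort latent score
#'   column (e.g. `"z_asystole"`) at Pearson correlation `rho`.
#' @return `data.frame` (long): `animal`, `timepoint`, `metabolite`, `conc`,
#'   with attribute `noise_sd`.
#' @export
sample_concentrations <- function(model, cohort, timepoints = c("t1", "t2", "t3"),
                                  seed = 1, sampling = c("stratified", "iid"),
                                  endpoint_link = NULL) {
  stopifnot(inherits(model, "concentration_model"))
  sampling <- match.arg(sampling)
  set.seed(as.integer(seed))
  animals <- cohort$animals
  n <- nrow(animals)
  tps <- match.arg(timepoints, c("t1", "t2", "t3"), several.ok = TRUE)
  out <- vector("list", length(model$metabolite))
  for (j in seq_along(model$metabolite)) {
    met <- model$metabolite[j]
    z1 <- draw_scores(n, sampling)
    if (!is.null(endpoint_link) && identical(endpoint_link$metabolite, met)) {
      ze <- animals[[endpoint_link$score]]
      rho <- endpoint_link$rho
      z1 <- rho * ze + sqrt(1 - rho^2) * z1
    }
    conc <- matrix(NA_real_, n, length(tps),
                   dimnames = list(NULL, tps))
    prev <- exp(model$mu_t1[j] + model$sigma_t1[j] * z1)
    if ("t1" %in% tps) conc[, "t1"] <- prev
    for (tp in c("t2", "t3")) {
      if (!tp %in% tps) next
      fc <- if (tp == "t2") model$fc_t1_t2[j] else model$fc_t2_t3[j]
      if (is.na(fc))
        stop("missing fold change for metabolite '", met, "' transition to ", tp)
      prev <- prev * signed_fc_to_ratio(fc) *
        exp(model$noise_sd * draw_scores(n, sampling))
      conc[, tp] <- prev
    }
    out[[j]] <- data.frame(animal = rep(animals$animal, length(tps)),
                           timepoint = rep(tps, each = n),
                           metabolite = met,
                           conc = as.vector(conc),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  stopifnot(all(res$conc >= 0))
  attr(res, "noise_sd") <- model$noise_sd
  res
}

#' Wide samples-x-metabolites matrix from long concentrations
#'
#' @param conc long concentration table from [sample_concentrations()].
#' @param timepoint optional single time point to select.
#' @return numeric matrix, rows named `animal_timepoint` (or `animal` when a
#'   single time point is selected).
#' @export
concentration_matrix <- function(conc, timepoint = NULL) {
  if (!is.null(timepoint)) conc <- conc[conc$timepoint %in% timepoint, ]
  key <- if (!is.null(timepoint) && length(timepoint) == 1L) conc$animal
         else paste(conc$animal, conc$timepoint, sep = "_")
  mets <- unique(conc$metabolite)
  keys <- unique(key)
  m <- matrix(NA_real_, length(keys), length(mets),
              dimnames = list(keys, mets))
  m[cbind(match(key, keys), match(conc$metabolite, mets))] <- conc$conc
  m
}

#' Acquisition parameters of the spectral forward model
#'
#' @param ppm_min,ppm_max,n_points the ppm grid (default -1..10 ppm, 16384
#'   points).
#' @param tsp_conc TSP concentration in mM (9 protons at 0.0 ppm).
#' @param tsp_fwhm unbroadened TSP full width at half maximum (ppm).
#' @param linewidth Lorentzian half width at half maximum of metabolite lines
#'   (ppm); the rendered FWHM is twice this.
#' @param j_doublet,j_triplet,j_multiplet line spacings (ppm) used for
#'   doublets/triplets and the generic five-line multiplet.
#' @param noise_sd additive complex Gaussian noise sd (intensity units where
#'   one unit of integrated area corresponds to 1 mM x 1 proton).
#' @param phase_range zero-order phase error range (degrees) drawn per
#'   spectrum; use `c(0, 0)` for none.
#' @param offset_range chemical-shift referencing error range (ppm).
#' @param baseline `c(intercept, slope)` of a linear baseline drift.
#' @param background logical, include material-specific broad backgrounds
#'   (plasma lipid bands near 0.9/1.3 ppm and a macromolecule hump; urine urea
#'   band around 5.8 ppm) plus the residual water artifact at 4.7 ppm.
#' @return list of acquisition parameters.
#' @export
acquisition_params <- function(ppm_min = -1, ppm_max = 10, n_points = 16384,
                               tsp_conc = 0.5, tsp_fwhm = 0.003,
                               linewidth = 0.0015, j_doublet = 0.012,
                               j_triplet = 0.012, j_multiplet = 0.008,
                               noise_sd = 1.0, phase_range = c(-20, 20),
                               offset_range = c(-0.01, 0.01),
                               baseline = c(2, 0.3), background = TRUE) {
  stopifnot(n_points >= 1024, ppm_min < -0.5, ppm_max > 9.0,
            tsp_conc > 0, tsp_fwhm > 0, linewidth > 0, noise_sd >= 0)
  as.list(environment())
}

# line offsets (ppm, relative to the multiplet center) and weights for a
# multiplicity code
multiplet_lines <- function(multiplicity, acq) {
  switch(multiplicity,
    s = list(offsets = 0, weights = 1),
    d = list(offsets = c(-0.5, 0.5) * acq$j_doublet, weights = c(1, 1) / 2),
    t = list(offsets = c(-1, 0, 1) * acq$j_triplet, weights = c(1, 2, 1) / 4),
    m = list(offsets = (-2:2) * acq$j_multiplet,
             weights = c(1, 2, 3, 2, 1) / 9),
    stop("unknown multiplicity: ", multiplicity))
}

# complex Lorentzian with unit integrated absorption area
lorentz_complex <- function(x, center, gamma) {
  d <- x - center
  den <- gamma^2 + d^2
  complex(real = gamma / pi / den, imaginary = d / pi / den)
}

gauss_bg <- function(x, center, area, sd) {
  area * stats::dnorm(x, center, sd)
}

#' Render a synthetic 1H-NMR spectrum
#'
#' Forward model: each panel signal is a Lorentzian multiplet with total
#' integrated absorption area `concentration x protons` (one global area
#' constant shared with the 9-proton TSP singlet at 0.0 ppm), plus a residual
#' water artifact, optional material-specific broad backgrounds, a linear
#' baseline drift, an injected zero-order phase error and chemical-shift
#' offset (both recorded in `meta` as ground truth), and complex Gaussian
#' noise.
#'
#' @param concentrations named numeric vector (mM) over panel metabolites;
#'   names absent from the panel are an error; unknown signals in the panel
#'   are skipped.
#' @param panel a [metabolite_panel()].
#' @param acq an [acquisition_params()] list.
#' @param seed integer seed (noise and the drawn phase/offset).
#' @param tsp_broadening multiplicative broadening of the TSP linewidth.
#' @param phase_deg,ppm_offset fixed injected errors; `NULL` draws them from
#'   the acquisition ranges.
#' @param noise_sd overrides `acq$noise_sd` when not `NULL`.
#' @return an [nmr_spectrum()] with complex intensity and ground-truth `meta`.
#' @export
render_spectrum <- function(concentrations, panel, acq = acquisition_params(),
                            seed = 1, tsp_broadening = 1,
                            phase_deg = NULL, ppm_offset = NULL,
                            noise_sd = NULL) {
  set.seed(as.integer(seed))
  bad <- setdiff(names(concentrations), panel$metabolite)
  if (length(bad))
    stop("concentrations given for metabolites absent from panel: ",
         paste(bad, collapse = ", "))
  material <- panel$material[1]
  if (is.null(phase_deg))
    phase_deg <- stats::runif(1, acq$phase_range[1], acq$phase_range[2])
  if (is.null(ppm_offset))
    ppm_offset <- stats::runif(1, acq$offset_range[1], acq$offset_range[2])
  if (is.null(noise_sd)) noise_sd <- acq$noise_sd

  x <- seq(acq$ppm_min, acq$ppm_max, length.out = acq$n_points)
  spec <- complex(real = rep(0, acq$n_points), imaginary = rep(0, acq$n_points))

  add_signal <- function(spec, center, area, gamma, multiplicity) {
    ml <- multiplet_lines(multiplicity, acq)
    for (k in seq_along(ml$offsets))
      spec <- spec + area * ml$weights[k] *
        lorentz_complex(x, center + ml$offsets[k] + ppm_offset, gamma)
    spec
  }
  # TSP reference: 9 protons at 0.0 ppm, per-animal broadened
  spec <- add_signal(spec, 0.0, acq$tsp_conc * 9,
                     tsp_broadening * acq$tsp_fwhm / 2, "s")
  for (met in names(concentrations)) {
    i <- match(met, panel$metabolite)
    if (!panel$identified[i]) next
    if (concentrations[[met]] <= 0) next
    spec <- add_signal(spec, panel$ppm[i],
                       concentrations[[met]] * panel$protons[i],
                       acq$linewidth, panel$multiplicity[i])
  }

  bg <- rep(0, acq$n_points)
  if (isTRUE(acq$background)) {
    bg <- bg + gauss_bg(x, 4.7 + ppm_offset, 150, 0.08)  # residual water
    if (material == "plasma") {
      bg <- bg + gauss_bg(x, 0.9, 20, 0.08) + gauss_bg(x, 1.3, 20, 0.09) +
        gauss_bg(x, 2.2, 60, 1.2)
    } else {
      bg <- bg + gauss_bg(x, 5.8, 60, 0.12)               # urea band
    }
    bg <- bg + acq$baseline[1] + acq$baseline[2] * x
  }
  spec <- spec + bg

  phi <- phase_deg * pi / 180
  spec <- spec * exp(1i * phi)
  if (noise_sd > 0)
    spec <- spec + complex(real = stats::rnorm(acq$n_points, 0, noise_sd),
                           imaginary = stats::rnorm(acq$n_points, 0, noise_sd))

  nmr_spectrum(x, spec, material = material,
               meta = list(true_concentrations = concentrations,
                           phase_deg = phase_deg, ppm_offset = ppm_offset,
                           tsp_broadening = tsp_broadening,
                           tsp_conc = acq$tsp_conc, noise_sd = noise_sd,
                           seed = seed))
}

#' Simulate rendered spectra for a set of samples
#'
#' Convenience wrapper: one rendered spectrum per row of `samples`
#' (columns `animal`, and optionally `tsp_broadening`), using the
#' concentrations of the given time point.
#'
#' @param conc long concentration table from [sample_concentrations()].
#' @param cohort the cohort the concentrations were drawn for.
#' @param panel a [metabolite_panel()].
#' @param timepoint which time point to render.
#' @param acq acquisition parameters.
#' @param seed integer seed; each spectrum gets an independent substream.
#' @param animals optional subset of animal ids.
#' @return named list of [nmr_spectrum()] objects (names = animal ids).
#' @export
simulate_spectra <- function(conc, cohort, panel, timepoint = "t1",
                             acq = acquisition_params(), seed = 1,
                             animals = NULL) {
  ids <- if (is.null(animals)) cohort$animals$animal else animals
  cc <- conc[conc$timepoint == timepoint & conc$metabolite %in% panel$metabolite, ]
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    rows <- cc[cc$animal == ids[i], ]
    v <- stats::setNames(rows$conc, rows$metabolite)
    b <- if (panel$material[1] == "plasma")
      cohort$animals$tsp_broadening[match(ids[i], cohort$animals$animal)]
    else 1
    out[[i]] <- render_spectrum(v, panel, acq,
                                seed = as.integer(seed) + 7L * i,
                                tsp_broadening = b)
  }
  out
}
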