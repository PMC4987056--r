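#' Trapezoidal integration of a spectral window
#'
#' @param s an [nmr_spectrum()].
#' @param window `c(lo, hi)` ppm interval; must contain retained axis points.
#' @param floor_negative floor negative integrals at 0 (with a warning).
#' @return scalar area (attribute `floored` set when flooring occurred).
#' @export
integrate_signal <- function(s, window, floor_negative = TRUE) {
  idx <- ppm_window_idx(s, window[1], window[2])
  if (length(idx) < 2L)
    stop("integration window [", window[1], ", ", window[2],
         ") is fully excised or empty")
  a <- trapz(s$ppm[idx], spec_real(s)[idx])
  if (floor_negative && a < 0) {
    warning("negative integral floored at 0 in [", window[1], ", ",
            window[2], ")")
    a <- structure(0, floored = TRUE)
  }
  a
}

#' Convert a signal area to a concentration via the TSP reference
#'
#' `c = (area / protons) / (tsp_area / 9) * tsp_conc`: areas scale with
#' concentration times protons, and TSP contributes 9 protons at its known
#' concentration.
#'
#' @param area signal area, @param protons protons per signal (>= 1),
#' @param tsp_area TSP reference area (> 0), @param tsp_conc TSP
#'   concentration in mM.
#' @return concentration in mM.
#' @export
area_to_concentration <- function(area, protons, tsp_area, tsp_conc) {
  if (any(tsp_area <= 0)) stop("TSP area must be positive")
  stopifnot(all(protons >= 1))
  (area / protons) / (tsp_area / 9) * tsp_conc
}

# integration window of one panel signal: center +/- (multiplet half-span +
# k_gamma Lorentzian half-widths)
signal_window <- function(ppm, multiplicity, linewidth = 0.0015,
                          j_doublet = 0.012, j_triplet = 0.012,
                          j_multiplet = 0.008, k_gamma = 6) {
  span2 <- switch(multiplicity, s = 0, d = j_doublet / 2, t = j_triplet,
                  m = 2 * j_multiplet, stop("unknown multiplicity"))
  c(ppm - span2 - k_gamma * linewidth, ppm + span2 + k_gamma * linewidth)
}

# fraction of a unit-area Lorentzian multiplet (lines `centers`, weights
# `weights`, common half-width gamma) falling inside [lo, hi]
lorentz_coverage <- function(window, centers, weights, gamma) {
  sum(weights * (atan((window[2] - centers) / gamma) -
                 atan((window[1] - centers) / gamma)) / pi)
}

# geometry of a chord-subtracted window: inside grid points plus mean
# positions of `flank` points just outside each edge (falling back to the
# window's own endpoints when a flank is excised or at an axis boundary)
chord_geometry <- function(xall, window, flank = 10L) {
  dx <- stats::median(diff(xall))
  inside <- which(xall >= window[1] & xall < window[2])
  if (length(inside) < 2L) return(NULL)
  left <- which(xall < window[1] & xall >= window[1] - (flank + 0.5) * dx)
  right <- which(xall >= window[2] & xall < window[2] + (flank + 0.5) * dx)
  list(inside = inside,
       left = if (length(left)) left else inside[1],
       right = if (length(right)) right else inside[length(inside)])
}

# area above the local chord: trapezoidal integral inside the window minus
# the straight line through the mean flank levels. Linear in the signal, so
# the same operation applied to unit-area model multiplets (coverage_matrix)
# corrects it exactly; any locally linear background drops out.
chord_area <- function(xall, yall, geom) {
  xi <- xall[geom$inside]; yi <- yall[geom$inside]
  xL <- mean(xall[geom$left]); vL <- mean(yall[geom$left])
  xR <- mean(xall[geom$right]); vR <- mean(yall[geom$right])
  chord <- if (xR > xL) vL + (vR - vL) * (xi - xL) / (xR - xL) else vL
  trapz(xi, yi - chord)
}

# evaluate the unit-area Lorentzian multiplet of panel row j at positions x
unit_multiplet <- function(x, ppm, multiplicity, acq_like) {
  ml <- multiplet_lines(multiplicity, acq_like)
  y <- rep(0, length(x))
  for (k in seq_along(ml$offsets))
    y <- y + ml$weights[k] *
      Re(lorentz_complex(x, ppm + ml$offsets[k], acq_like$linewidth))
  y
}

# coverage matrix C[i, j]: chord-subtracted area of signal j's unit-area
# multiplet measured in signal i's window, computed on the spectrum's own
# retained grid so the correction matches exactly what the chord-subtracted
# integration measures (grid sampling, edge and flank effects included).
# Only local neighbours (centers within `reach` ppm) enter off-diagonal
# terms; farther tails are locally linear and cancel in the chord.
coverage_matrix <- function(panel, geoms, acq_like, s, reach = 0.1) {
  n <- nrow(panel)
  C <- diag(n)
  for (i in seq_len(n)) {
    if (is.null(geoms[[i]])) next
    for (j in seq_len(n)) {
      if (i != j && abs(panel$ppm[i] - panel$ppm[j]) > reach) next
      yg <- unit_multiplet(s$ppm, panel$ppm[j], panel$multiplicity[j],
                           acq_like)
      C[i, j] <- chord_area(s$ppm, yg, geoms[[i]])
    }
  }
  C
}

# chord-subtracted coverage of the TSP Lorentzian (half-width gamma) in its
# +/- k_fwhm x FWHM window, on a grid with the spectrum's spacing and
# alignment (reconstructed around 0 ppm; the TSP region itself is excised
# from the retained axis)
tsp_numeric_coverage <- function(s, gamma, k_fwhm, flank = 10L) {
  dx <- stats::median(diff(s$ppm))
  p0 <- s$ppm[1]
  w <- k_fwhm * 2 * gamma
  span <- w + (flank + 2) * dx
  xg <- p0 + dx * seq(floor((-span - p0) / dx), ceiling((span - p0) / dx))
  geom <- chord_geometry(xg, c(-w, w), flank)
  chord_area(xg, Re(lorentz_complex(xg, 0, gamma)), geom)
}

#' Quantify panel metabolites in one preprocessed spectrum
#'
#' Integrates each identified panel signal over a narrow window around its
#' multiplet and converts areas to mM against the TSP reference. Because the
#' windows are narrow, two analytic corrections (both derived from the
#' Lorentzian lineshape with a common linewidth, no fitting involved) are
#' applied by default: the captured fraction of each signal's own tails, and
#' the spill-over of neighbouring panel signals into the window, inverted as
#' one small linear system. The TSP reference area is likewise corrected for
#' the finite +/- 10 FWHM normalization window.
#'
#' @param s a preprocessed (TSP-normalized, excised) [nmr_spectrum()].
#' @param panel a [metabolite_panel()]; unknown signals are reported in
#'   arbitrary units (their raw window area) and flagged.
#' @param tsp_conc TSP concentration in mM.
#' @param linewidth assumed metabolite Lorentzian half width at half maximum
#'   (ppm).
#' @param j_doublet,j_triplet,j_multiplet multiplet line spacings (ppm).
#' @param crosstalk apply the cross-window spill-over correction.
#' @param k_fwhm_tsp half-width of the TSP normalization window in FWHM
#'   units (must match [normalize_to_tsp()]).
#' @return named numeric vector of concentrations (mM for identified
#'   metabolites, arbitrary units otherwise), with attribute `units`.
#' @export
quantify_spectrum <- function(s, panel, tsp_conc = 0.5, linewidth = 0.0015,
                              j_doublet = 0.012, j_triplet = 0.012,
                              j_multiplet = 0.008, crosstalk = TRUE,
                              k_fwhm_tsp = 10) {
  acq_like <- list(linewidth = linewidth, j_doublet = j_doublet,
                   j_triplet = j_triplet, j_multiplet = j_multiplet)
  pan <- panel
  windows <- lapply(seq_len(nrow(pan)), function(i)
    signal_window(pan$ppm[i], pan$multiplicity[i], linewidth,
                  j_doublet, j_triplet, j_multiplet))
  geoms <- lapply(windows, function(w) chord_geometry(s$ppm, w))
  yreal <- spec_real(s)
  excised <- vapply(geoms, is.null, TRUE)
  if (any(excised))
    warning("window(s) fully excised, reported as NA: ",
            paste(pan$metabolite[excised], collapse = ", "))
  raw <- rep(NA_real_, length(windows))
  raw[!excised] <- vapply(which(!excised), function(i)
    chord_area(s$ppm, yreal, geoms[[i]]), 0)

  id <- which(pan$identified & !excised)
  areas <- raw
  if (length(id)) {
    C <- coverage_matrix(pan[id, ], geoms[id], acq_like, s)
    corrected <- if (crosstalk) solve(C, raw[id]) else raw[id] / diag(C)
    corrected[corrected < 0] <- 0
    areas[id] <- corrected
  }
  id <- which(pan$identified)

  # TSP reference area: measured on the same baseline-corrected spectrum as
  # the metabolite windows when available (qc$tsp_area_post), else the
  # normalized area 1; divided by the grid-sampled coverage fraction of its
  # +/- k FWHM window
  gamma_tsp <- if (is.finite(s$qc$tsp_fwhm)) s$qc$tsp_fwhm / 2
               else 2 * linewidth
  tsp_meas <- if (!is.null(s$qc$tsp_area_post)) s$qc$tsp_area_post else 1
  tsp_total <- tsp_meas / tsp_numeric_coverage(s, gamma_tsp, k_fwhm_tsp)
  conc <- areas
  conc[id] <- area_to_concentration(areas[id], pan$protons[id],
                                    tsp_total, tsp_conc)
  conc[!is.na(conc) & conc < 0] <- 0
  names(conc) <- pan$metabolite
  attr(conc, "units") <- ifelse(pan$identified, "mM", "arbitrary")
  conc
}

#' Quantify a list of preprocessed spectra
#'
#' @param spectra named list of preprocessed spectra.
#' @param panel a [metabolite_panel()].
#' @param ... passed to [quantify_spectrum()].
#' @return samples x metabolites numeric matrix with attribute `units`.
#' @export
quantify_cohort <- function(spectra, panel, ...) {
  rows <- lapply(spectra, quantify_spectrum, panel = panel, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(spectra)
  attr(m, "units") <- attr(rows[[1]], "units")
  m
}

#' Creatinine-normalize a urine concentration table
#'
#' Divides every metabolite of each sample by the same-sample creatinine
#' concentration (the creatinine column becomes 1). Samples with missing or
#' non-positive creatinine are excluded and reported in the
#' `excluded_samples` attribute rather than silently dropped.
#'
#' @param x samples x metabolites matrix containing a `Creatinine` column.
#' @param creatinine column name of the creatinine signal.
#' @return normalized matrix with attributes `creatinine_normalized = TRUE`
#'   and `excluded_samples`.
#' @export
creatinine_normalize <- function(x, creatinine = "Creatinine") {
  if (!creatinine %in% colnames(x))
    stop("no '", creatinine, "' column present")
  cr <- x[, creatinine]
  bad <- !is.finite(cr) | cr <= 0
  if (any(bad))
    warning(sum(bad), " sample(s) with missing/non-positive creatinine excluded")
  units <- attr(x, "units")
  out <- x[!bad, , drop = FALSE] / x[!bad, creatinine]
  attr(out, "creatinine_normalized") <- TRUE
  attr(out, "excluded_samples") <- rownames(x)[bad]
  attr(out, "units") <- units
  out
}
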