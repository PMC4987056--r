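#' Reference metabolite tables parameterizing the synthetic cohort generator
#'
#' `plasma_reference_table()` and `urine_reference_table()` return the bundled
#' per-metabolite summary statistics of the newborn-pig
#' asphyxia/resuscitation study that this package emulates: signal position
#' (ppm), multiplicity, protons per signal, median concentration and
#' interquartile range at the three sampling time points (baseline t1, 2 h
#' after ROSC t2, 4 h after ROSC t3), and the signed pairwise fold changes
#' t1->t2 and t2->t3. Concentrations are mM for identified metabolites and
#' arbitrary units for unknown signals (`identified = FALSE`, `protons = NA`).
#'
#' These tables are the package's study conditions: the generator draws
#' log-normal baseline concentrations matching the printed median/IQR and
#' applies the printed fold changes as within-animal transitions.
#'
#' @return a `data.frame` with columns `metabolite`, `ppm`, `multiplicity`
#'   (`s`, `d`, `t`, `m`), `protons`, `identified`, `med_t1`, `q1_t1`,
#'   `q3_t1`, `med_t2`, `q1_t2`, `q3_t2`, `med_t3`, `q1_t3`, `q3_t3`,
#'   `fc_t1_t2`, `fc_t2_t3`.
#' @export
plasma_reference_table <- function() {
  tab <- read.csv(text = '
metabolite,ppm,multiplicity,protons,med_t1,q1_t1,q3_t1,med_t2,q1_t2,q3_t2,med_t3,q1_t3,q3_t3,fc_t1_t2,fc_t2_t3
Acetate,1.91,s,3,0.0053,0.000061,0.018,0.014,0.00023,0.087,0.014,0.0028,0.1,2.82,1.6
Alanine,1.48,d,3,0.64,0.37,1.0,1.5,0.64,2.6,1.2,0.43,2.6,2.21,-1.38
Choline,3.19,s,9,0.013,0,0.049,0.061,0.012,0.14,0.077,0.021,0.22,4.85,1.22
Creatinine,4.05,s,2,0.034,0.023,0.05,0.045,0.022,0.063,0.061,0.038,0.082,1.29,1.27
Dimethylamine,2.72,s,6,0.0078,0.0042,0.012,0.0088,0.0048,0.012,0.0099,0.0058,0.013,1.15,1.09
Formate,8.45,s,1,0.0083,0,0.043,0.012,0,0.054,0.018,0,0.035,1.4,1.81
Fumarate,6.51,s,2,0.0056,0.0017,0.013,0.033,0.0047,0.083,0.019,0.0012,0.085,4.85,-1.56
Glucose,5.24,d,1,6,4.1,8.6,11,5.5,20,6.6,2.7,16,1.77,-1.53
Glutamine,2.45,m,2,0.27,0.19,0.4,0.45,0.25,0.76,0.51,0.25,1.0,1.65,1.06
Glycerol,3.57,m,2,0.18,0.0041,0.39,0.35,0.045,1.0,0.2,0.018,2.2,1.8,-1.2
Glycine,3.55,s,2,0.61,0.39,1.0,0.95,0.39,1.5,0.89,0.43,1.7,1.44,1.03
Hypoxanthine,8.20,s,1,0.041,0.023,0.068,0.12,0.036,0.26,0.06,0.017,0.27,2.63,-1.6
Isoleucine,1.00,d,3,0.097,0.061,0.16,0.1,0.055,0.2,0.065,0.044,0.18,1.06,-1.39
Lactate,1.33,d,3,2.9,1.5,5.3,10,3.7,16,5.3,1.3,16,3.07,-1.75
Leucine,0.95,d,6,0.11,0.074,0.17,0.14,0.054,0.32,0.089,0.053,0.29,1.23,-1.37
Malate,2.65,m,1,0.013,0,0.062,0.13,0.013,0.28,0.088,0.02,0.29,6.69,-1.07
Methionine,2.63,s,3,0.032,0.0019,0.077,0.032,0.0045,0.087,0.03,0,0.088,1.02,-1.22
Myo-inositol,4.06,t,1,0.064,0,0.39,0.2,0.045,0.6,0.23,0.037,0.6,2.26,1.02
Phenylalanine,7.33,m,3,0.051,0.026,0.079,0.064,0.018,0.14,0.046,0.018,0.13,1.22,-1.27
Proline,4.14,m,1,0.49,0.32,0.84,0.57,0.34,0.92,0.57,0.32,0.94,1.08,-1.09
Pyruvate,2.37,s,3,0.1,0.059,0.21,0.21,0.11,0.34,0.2,0.058,0.33,2.0,-1.22
Succinate,2.40,s,4,0.015,0.0054,0.035,0.17,0.0095,0.62,0.072,0.0035,0.44,7.67,-1.54
Trimethylamine,2.88,s,9,0.0011,0,0.0033,0.0046,0.00083,0.016,0.0054,0.00092,0.019,4.43,1.26
Tyrosine,7.20,d,2,0.11,0.059,0.2,0.13,0.066,0.22,0.11,0.047,0.19,1.21,-1.22
Valine,1.03,d,3,0.19,0.11,0.34,0.22,0.082,0.45,0.16,0.069,0.36,1.08,-1.36
Unknown doublet 1.06,1.06,d,NA,1.6,0.094,4.5,2.1,0.0015,5.1,1.9,0.7,4.6,1.34,-1.04
Unknown doublet 1.11,1.11,d,NA,2.7,1.8,3.8,2.2,0.33,3.7,2.4,1.1,3.9,-1.59,1.09
Unknown doublet 1.14,1.14,d,NA,0.19,0.12,0.47,0.14,0.083,0.43,0.14,0.063,0.28,-1.27,-1.07
Unknown multiplet 1.40,1.40,m,NA,40,24,63,23,9.1,43,25,9.4,43,-1.92,-1.06
Unknown singlet 3.92,3.92,s,NA,2.7,1.3,7.7,3.3,0.8,14,3.4,1.4,25,1.14,1.3
Unknown singlet 5.39,5.39,s,NA,1.1,0.24,2.8,1.9,0.25,6,2.6,0.34,8,1.78,1.16
', stringsAsFactors = FALSE)
  tab$identified <- !is.na(tab$protons)
  tab
}

#' @rdname plasma_reference_table
#' @export
urine_reference_table <- function() {
  tab <- read.csv(text = '
metabolite,ppm,multiplicity,protons,med_t1,q1_t1,q3_t1,med_t2,q1_t2,q3_t2,med_t3,q1_t3,q3_t3,fc_t1_t2,fc_t2_t3
1-Methylnicotinamide,8.95,s,1,0.14,0.042,0.93,0.15,0.055,0.7,0.19,0.055,0.6,1.14,1.16
3-Hydroxyisovalerate,1.27,s,6,0.035,0.025,0.078,0.03,0.022,0.068,0.028,0.02,0.06,-1.18,-1.1
Alanine,1.48,d,3,0.42,0.17,1.5,1.1,0.4,2.9,1.3,0.54,4.5,2.29,1.25
Ascorbate,4.52,d,1,0.83,0.11,3.9,0.9,0.17,3.4,0.86,0.15,3.2,1.21,-1.04
Choline,3.21,s,9,0.12,0.041,0.67,0.29,0.051,1.1,0.32,0.076,1.9,1.91,1.12
Creatinine,4.05,s,2,3,1.5,8.6,2.5,0.92,7.4,2,0.76,5.1,-1.27,-1.17
Formate,8.47,s,1,0.49,0.16,1.2,0.31,0.12,0.92,0.26,0.11,0.86,-1.32,-1.25
Fumarate,6.52,s,2,0.22,0.077,1.2,0.29,0.11,0.98,0.25,0.1,0.55,1.24,-1.09
Glucose,5.24,d,1,2,0.5,7.9,10,2.3,50,13,2.3,70,5.2,1.2
Glycine,3.57,s,2,2.4,0.56,9.8,2.8,1,7.2,2.9,0.99,11,1.39,1.04
Hippurate,7.55,d,2,0.71,0.099,5.4,0.75,0.18,4.3,0.57,0.067,4,1.28,-1.19
Hypoxanthine,8.21,s,1,0.13,0,0.79,0.41,0.065,1.4,0.38,0.07,1.7,3.44,1.1
Lactate,1.33,d,3,1.2,0.81,3.7,9.7,1.6,28,12,1.8,32,6.17,1.14
Leucine,0.97,d,6,0.058,0.039,0.1,0.089,0.051,0.26,0.1,0.053,0.21,1.59,1.1
Lysine,1.72,m,2,0.14,0,2.3,0.16,0,0.89,0.16,0.035,0.89,-1.11,1.04
N-N-Dimethylglycine,2.93,s,6,1,0.21,3.1,0.63,0.16,2.4,0.53,0.071,2,-1.45,-1.23
N-Phenylacetylglycine,7.43,m,2,1.3,0.45,6.8,0.92,0.2,4.7,0.84,0.18,3.3,-1.38,-1.17
Succinate,2.41,s,4,0.28,0.088,1,0.6,0.18,1.3,0.48,0.17,1.2,1.92,1
Trimethylamine,2.88,s,9,0.15,0,1.2,0.16,0,0.72,0.17,0,1.5,1.09,1.2
Trimethylamine-N-Oxide,3.27,s,9,1.5,0,6,1.3,0,4,1.2,0,3.8,-1.03,1.01
Valine,1.05,d,3,0.039,0.016,0.093,0.12,0.03,0.35,0.14,0.042,0.35,2.81,1.42
Unknown doublet 1.08,1.08,d,NA,0.059,0.038,0.24,0.062,0.042,0.15,0.062,0.04,0.21,-1.02,-1.06
Unknown doublet 1.11,1.11,d,NA,0.089,0.069,0.17,0.085,0.067,0.16,0.081,0.065,0.12,-1.06,-1.03
Unknown doublet 1.15,1.15,d,NA,0.16,0.05,0.48,0.3,0.12,0.74,0.3,0.15,0.71,2.06,1.06
Unknown doublet 1.25,1.25,d,NA,0.18,0.11,0.37,0.12,0.061,0.29,0.11,0.052,0.2,-1.46,-1.19
Unknown doublet 1.38,1.38,d,NA,0.069,0.033,0.21,0.062,0.029,0.19,0.057,0.026,0.15,-1.16,-1.02
Unknown doublet 5.10,5.10,d,NA,0.0038,0,0.0057,0.0059,0.0015,0.022,0.007,0.0027,0.03,1.99,1.16
Unknown doublet 5.48,5.48,d,NA,0.00074,0,0.0054,0.00056,0,0.0038,0.00062,0.0002,0.0031,-1.31,-1.08
Unknown doublet 5.70,5.70,d,NA,0.12,0.019,0.54,0.098,0.0061,0.45,0.082,0.013,0.39,-1.38,-1.16
Unknown multiplet 6.65,6.65,m,NA,0.0072,0.0025,0.028,0.0044,0.0014,0.028,0.0042,0,0.015,-1.42,-1.17
Unknown multiplet 6.76,6.76,m,NA,0.011,0.0054,0.037,0.0081,0.003,0.034,0.008,0.0012,0.018,-1.33,-1.26
Unknown multiplet 6.79,6.79,m,NA,0.0081,0.0034,0.027,0.0057,0.0011,0.026,0.0041,0.00045,0.014,-1.53,-1.45
Unknown multiplet 7.68,7.68,m,NA,0.18,0.083,0.53,0.14,0.047,0.46,0.12,0.029,0.29,-1.32,-1.24
Unknown singlet 6.78,6.78,s,NA,0.0034,0,0.017,0.0016,0,0.011,0.0013,0,0.0095,-2.12,-1.06
Unknown triplet 6.29,6.29,t,NA,0.0062,0,0.067,0.003,0,0.039,0.0032,0,0.031,-1.4,-1.1
', stringsAsFactors = FALSE)
  tab$identified <- !is.na(tab$protons)
  tab
}

#' Reference TSP linewidth summaries (plasma)
#'
#' Median (IQR) full width at half maximum of the TSP signal per time point,
#' in spectral ppm, together with its pairwise signed fold changes. In plasma
#' the TSP linewidth tracks lipoprotein content and is carried through the
#' pipeline as a QC variable.
#' @return one-row `data.frame` shaped like [plasma_reference_table()].
#' @export
tsp_fwhm_reference <- function() {
  data.frame(metabolite = "TSP FWHM", ppm = 0.0, multiplicity = "s",
             protons = 9, med_t1 = 0.0047, q1_t1 = 0.003, q3_t1 = 0.007,
             med_t2 = 0.004, q1_t2 = 0.0026, q3_t2 = 0.0052,
             med_t3 = 0.0038, q1_t3 = 0.0027, q3_t3 = 0.0051,
             fc_t1_t2 = -1.24, fc_t2_t3 = -1.02, identified = TRUE,
             stringsAsFactors = FALSE)
}

#' Resuscitation-protocol study design tables
#'
#' `group_design_table()` returns the six pooled resuscitation protocol groups
#' (group id, animals, initial ventilation in s, oxygen fraction,
#' compression-to-ventilation ratio, and median/IQR of the time to asystole
#' and time to ROSC). `sample_availability_table()` returns the number of
#' animals with an available plasma/urine sample per group and time point,
#' from which per-group availability rates are derived.
#'
#' @return `data.frame`s; see Details.
#' @export
group_design_table <- function() {
  data.frame(
    group = 1:6,
    n = c(21L, 32L, 21L, 8L, 16L, 12L),
    initial_ventilation_s = c(30, 30, 60, 90, 30, 30),
    oxygen_fraction = c(1.0, 0.21, 0.21, 0.21, 0.21, 0.21),
    cv_ratio = c("3:1", "3:1", "3:1", "3:1", "9:3", "15:2"),
    asystole_med = c(28.0, 32.5, 32.0, 33.0, 35.0, 37.0),
    asystole_q1 = c(24.0, 27.8, 29.0, 30.3, 30.8, 33.5),
    asystole_q3 = c(35.0, 35.5, 35.0, 36.0, 40.3, 39.0),
    rosc_med = c(135, 146, 170, 250, 145, 195),
    rosc_q1 = c(121, 125, 146, 202.5, 118, 155),
    rosc_q3 = c(168, 173, 184, 330, 173, 315),
    stringsAsFactors = FALSE)
}

#' @rdname group_design_table
#' @export
sample_availability_table <- function() {
  data.frame(
    group = 1:6,
    n = c(21L, 32L, 21L, 8L, 16L, 12L),
    plasma_t1 = c(20L, 32L, 21L, 8L, 16L, 11L),
    urine_t1 = c(18L, 29L, 17L, 7L, 16L, 11L),
    plasma_t2 = c(21L, 28L, 20L, 8L, 16L, 8L),
    urine_t2 = c(16L, 24L, 13L, 5L, 15L, 8L),
    plasma_t3 = c(17L, 25L, 15L, 7L, 15L, 9L),
    urine_t3 = c(7L, 12L, 9L, 4L, 7L, 8L),
    stringsAsFactors = FALSE)
}
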