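#' NMR spectrum container
#'
#' An `nmr_spectrum` holds a strictly increasing chemical-shift axis (ppm), a
#' real or complex intensity vector of the same length, the sample material,
#' an append-only processing history, and a QC record filled in by the
#' preprocessing chain (TSP area, TSP FWHM, applied phase angle, applied ppm
#' shift).
#'
#' @param ppm numeric, strictly increasing chemical-shift axis in ppm.
#' @param intensity numeric or complex vector, same length as `ppm`.
#' @param material `"plasma"` or `"urine"`.
#' @param meta named list of acquisition / provenance metadata (e.g. ground
#'   truth injected by the simulator).
#' @return an object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, material = c("plasma", "urine"),
                         meta = list()) {
  material <- match.arg(material)
  ppm <- as.numeric(ppm)
  if (length(ppm) != length(intensity))
    stop("ppm axis and intensity must have the same length")
  if (length(ppm) < 2L || any(diff(ppm) <= 0))
    stop("ppm axis must be strictly increasing")
  structure(
    list(ppm = ppm, intensity = intensity, material = material,
         meta = meta, history = list(),
         qc = list(tsp_area = NA_real_, tsp_fwhm = NA_real_,
                   phase_deg = NA_real_, ppm_shift = NA_real_)),
    class = "nmr_spectrum")
}

#' @exportS3Method base::print
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s, %d points, %.3f..%.3f ppm, %s\n",
              x$material, length(x$ppm), min(x$ppm), max(x$ppm),
              if (is.complex(x$intensity)) "complex" else "real"))
  if (length(x$history))
    cat("  history:", paste(vapply(x$history, `[[`, "", "op"),
                            collapse = " -> "), "\n")
  invisible(x)
}

# append one history entry (op name + parameter list); every preprocessing
# operation calls this exactly once
add_history <- function(s, op, params = list()) {
  s$history <- c(s$history, list(list(op = op, params = params)))
  s
}

#' Real part of a spectrum's intensity
#' @param s an `nmr_spectrum`.
#' @return numeric vector.
#' @export
spec_real <- function(s) {
  if (is.complex(s$intensity)) Re(s$intensity) else s$intensity
}

# indices of the axis falling in the half-open interval [lo, hi)
ppm_window_idx <- function(s, lo, hi) {
  which(s$ppm >= lo & s$ppm < hi)
}

#' Trapezoidal integral of a sampled curve
#' @param x ordinates (increasing), @param y values.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
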