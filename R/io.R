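#' Write a spectrum to disk
#'
#' Two plain-text dialects are supported: `tabular` (comment header plus
#' tab-separated `ppm`, `real`, `imaginary` columns) and a JCAMP-DX-style
#' single-spectrum dialect (`##KEY=value` header records followed by
#' `##XYPOINTS=` data lines `ppm,real,imaginary` and `##END=`). Both
#' round-trip losslessly at full double precision.
#'
#' @param s an [nmr_spectrum()].
#' @param path output file.
#' @param dialect `"tabular"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("tabular", "jcamp")) {
  dialect <- match.arg(dialect)
  re <- spec_real(s)
  im <- if (is.complex(s$intensity)) Im(s$intensity) else rep(0, length(re))
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  if (dialect == "tabular") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# material: ", s$material),
                 paste0("# complex: ", is.complex(s$intensity)),
                 "ppm\treal\timaginary"), con)
    writeLines(paste(fmt(s$ppm), fmt(re), fmt(im), sep = "\t"), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##TITLE=synthetic 1H spectrum",
                 "##DATA TYPE=NMR SPECTRUM",
                 "##XUNITS=PPM",
                 paste0("##MATERIAL=", s$material),
                 paste0("##COMPLEX=", tolower(is.complex(s$intensity))),
                 paste0("##NPOINTS=", length(s$ppm)),
                 "##XYPOINTS=(XY..XY)"), con)
    writeLines(paste(fmt(s$ppm), fmt(re), fmt(im), sep = ","), con)
    writeLines("##END=", con)
  }
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Accepts the two dialects written by [write_spectrum()]; the dialect is
#' auto-detected from the first line unless given. Malformed or
#' non-finite data lines and non-monotone axes are rejected with the
#' offending line number.
#'
#' @param path input file.
#' @param dialect `"auto"`, `"tabular"` or `"jcamp"`.
#' @return an [nmr_spectrum()] with empty history.
#' @export
read_spectrum <- function(path, dialect = c("auto", "tabular", "jcamp")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "auto")
    dialect <- if (startsWith(lines[1], "##")) "jcamp" else "tabular"
  material <- "plasma"
  cplx <- TRUE
  if (dialect == "tabular") {
    hdr <- grep("^#", lines)
    mline <- grep("^# material:", lines, value = TRUE)
    if (length(mline)) material <- trimws(sub("^# material:", "", mline[1]))
    cline <- grep("^# complex:", lines, value = TRUE)
    if (length(cline))
      cplx <- tolower(trimws(sub("^# complex:", "", cline[1]))) == "true"
    first_data <- max(c(hdr, grep("^ppm\t", lines))) + 1L
    data_lines <- seq(first_data, length(lines))
    sep <- "\t"
  } else {
    mline <- grep("^##MATERIAL=", lines, value = TRUE)
    if (length(mline)) material <- sub("^##MATERIAL=", "", mline[1])
    cline <- grep("^##COMPLEX=", lines, value = TRUE)
    if (length(cline)) cplx <- sub("^##COMPLEX=", "", cline[1]) == "true"
    start <- grep("^##XYPOINTS=", lines)
    if (!length(start)) stop("no ##XYPOINTS= record found")
    end <- grep("^##END=", lines)
    end <- if (length(end)) end[1] else length(lines) + 1L
    data_lines <- seq(start[1] + 1L, end - 1L)
    sep <- ","
  }
  n <- length(data_lines)
  ppm <- re <- im <- numeric(n)
  for (i in seq_len(n)) {
    ln <- data_lines[i]
    parts <- strsplit(lines[ln], sep, fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) < 3L || any(!is.finite(v[1:3])))
      stop("malformed or non-finite data on line ", ln, " of ", path)
    ppm[i] <- v[1]; re[i] <- v[2]; im[i] <- v[3]
  }
  if (any(diff(ppm) <= 0))
    stop("non-monotone ppm axis in ", path, " (first violation near line ",
         data_lines[which(diff(ppm) <= 0)[1] + 1L], ")")
  intensity <- if (cplx) complex(real = re, imaginary = im) else re
  nmr_spectrum(ppm, intensity, material = material)
}
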