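#' Log-transform a concentration matrix
#'
#' Natural log after replacing zeros in each column by half the smallest
#' positive value of that column (the replacement is recorded per column in
#' the `zero_replacement` attribute). All-zero columns are dropped with a
#' warning.
#'
#' @param x samples x metabolites matrix, values >= 0.
#' @return log-concentration matrix.
#' @export
log_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  allzero <- apply(x, 2, function(v) all(!is.finite(v) | v == 0))
  if (any(allzero)) {
    warning("dropped all-zero column(s): ",
            paste(colnames(x)[allzero], collapse = ", "))
    x <- x[, !allzero, drop = FALSE]
  }
  repl <- apply(x, 2, function(v) {
    pos <- v[is.finite(v) & v > 0]
    min(pos) / 2
  })
  for (j in seq_len(ncol(x))) {
    z <- is.finite(x[, j]) & x[, j] == 0
    x[z, j] <- repl[j]
  }
  out <- log(x)
  attr(out, "zero_replacement") <- repl
  out
}

#' Back-transformed medians of log concentrations
#' @param logx log-concentration matrix.
#' @return named vector `exp(colMeans(logx))`, the geometric means used for
#'   reporting back-transformed medians.
#' @export
backtransformed_median <- function(logx) {
  exp(colMeans(logx, na.rm = TRUE))
}

#' One-way ANOVA per metabolite across groups
#'
#' @param logconc log-concentration matrix.
#' @param groups group labels, one per row; empty groups are excluded.
#' @param pairwise also run all pairwise Welch t-tests per metabolite.
#' @return `data.frame` with per-metabolite `F` and `p` (and a `pairwise`
#'   attribute when requested).
#' @export
group_anova <- function(logconc, groups, pairwise = FALSE) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 samples")
  res <- t(apply(as.matrix(logconc), 2, function(v) {
    a <- stats::anova(stats::lm(v ~ g))
    c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }))
  out <- data.frame(metabolite = colnames(logconc), F = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (pairwise) {
    lv <- levels(g)
    pw <- list()
    for (i in seq_len(nlevels(g) - 1L)) for (j in seq(i + 1L, nlevels(g))) {
      key <- paste(lv[i], lv[j], sep = "_vs_")
      pw[[key]] <- apply(as.matrix(logconc), 2, function(v)
        stats::t.test(v[g == lv[i]], v[g == lv[j]])$p.value)
    }
    attr(out, "pairwise") <- pw
  }
  out
}

#' Paired signed fold changes between two time points
#'
#' For each metabolite, computes the mean within-animal log difference
#' (`b - a`), reports it as a signed fold change (the ratio when >= 1, minus
#' its reciprocal otherwise), a paired t-test p-value on the log
#' differences, and Benjamini-Hochberg q-values across metabolites.
#' Metabolites with fewer than `min_pairs` complete pairs are skipped.
#'
#' @param logconc_a,logconc_b log-concentration matrices (same columns),
#'   rows identified by `pairing_a`/`pairing_b`.
#' @param pairing_a,pairing_b animal ids per row (default rownames).
#' @param min_pairs minimum complete pairs.
#' @return `data.frame`: `metabolite`, `fc` (signed), `log_ratio`, `p`, `q`,
#'   `n_pairs`.
#' @export
paired_fold_change <- function(logconc_a, logconc_b,
                               pairing_a = rownames(logconc_a),
                               pairing_b = rownames(logconc_b),
                               min_pairs = 3L) {
  common <- intersect(pairing_a, pairing_b)
  A <- as.matrix(logconc_a)[match(common, pairing_a), , drop = FALSE]
  B <- as.matrix(logconc_b)[match(common, pairing_b), , drop = FALSE]
  mets <- intersect(colnames(A), colnames(B))
  rows <- lapply(mets, function(m) {
    d <- B[, m] - A[, m]
    d <- d[is.finite(d)]
    if (length(d) < min_pairs) {
      message("skipping '", m, "': fewer than ", min_pairs, " complete pairs")
      return(NULL)
    }
    dbar <- mean(d)
    ratio <- exp(dbar)
    fc <- if (ratio >= 1) ratio else -1 / ratio
    # constant differences: identical pairs give p = 1, a constant non-zero
    # shift is maximally significant
    p <- if (stats::sd(d) < 1e-12 * max(1, abs(dbar))) {
      if (abs(dbar) < 1e-12) 1 else 1e-300
    } else {
      stats::t.test(d)$p.value
    }
    data.frame(metabolite = m, fc = fc, log_ratio = dbar, p = p,
               n_pairs = length(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("metabolite", "fc", "log_ratio", "p", "q", "n_pairs")]
}

#' Pearson correlations between variables and a continuous endpoint
#'
#' @param vars matrix of log concentrations and/or QC variables (e.g. TSP
#'   FWHM), one row per sample.
#' @param endpoint numeric endpoint (time to asystole or time to ROSC),
#'   matched to the rows.
#' @param min_n minimum complete cases per variable.
#' @return `data.frame`: `variable`, `r`, `p`, `n`; zero-variance variables
#'   are reported with `r = NA`.
#' @export
endpoint_correlation <- function(vars, endpoint, min_n = 5L) {
  vars <- as.matrix(vars)
  stopifnot(nrow(vars) == length(endpoint))
  rows <- lapply(colnames(vars), function(v) {
    ok <- is.finite(vars[, v]) & is.finite(endpoint)
    if (sum(ok) < min_n)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    if (stats::sd(vars[ok, v]) == 0)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- stats::cor.test(vars[ok, v], endpoint[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare baseline concentrations between survivors and non-survivors
#'
#' Welch unpaired t-test per metabolite. If either outcome group has fewer
#' than two samples an empty result is returned with a warning.
#'
#' @param logconc baseline log-concentration matrix.
#' @param survived logical vector per row.
#' @return `data.frame`: `metabolite`, `t`, `p`, `n_survived`, `n_died`.
#' @export
survival_comparison <- function(logconc, survived) {
  logconc <- as.matrix(logconc)
  stopifnot(nrow(logconc) == length(survived))
  n1 <- sum(survived); n0 <- sum(!survived)
  if (n1 < 2L || n0 < 2L) {
    warning("an outcome group has fewer than two samples; no tests run")
    return(data.frame(metabolite = character(), t = numeric(),
                      p = numeric(), n_survived = integer(),
                      n_died = integer(), stringsAsFactors = FALSE))
  }
  res <- t(apply(logconc, 2, function(v) {
    tt <- stats::t.test(v[survived], v[!survived])
    c(t = unname(tt$statistic), p = tt$p.value)
  }))
  data.frame(metabolite = colnames(logconc), t = res[, 1], p = res[, 2],
             n_survived = n1, n_died = n0,
             stringsAsFactors = FALSE, row.names = NULL)
}
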