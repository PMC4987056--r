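#' All-pairs Pearson correlation matrix of log-concentration variables
#'
#' Pairwise-complete Pearson correlations over matched samples, with the
#' per-cell number of complete pairs recorded. Variables with fewer than
#' `min_pairs` complete pairs against any partner are excluded and logged.
#'
#' @param x samples x variables matrix (typically matched plasma plus
#'   creatinine-normalized urine log concentrations; tag variable names with
#'   their material, e.g. `"plasma:Lactate"`).
#' @param materials optional character vector of material tags per column.
#' @param min_pairs minimum complete pairs per variable pair.
#' @return object of class `correlation_matrix`: `r` (symmetric, unit
#'   diagonal), `n` (pairs per cell), `materials`, and empty `ordering` /
#'   `mask` slots.
#' @export
all_pairs_pearson <- function(x, materials = NULL, min_pairs = 5L) {
  x <- as.matrix(x)
  if (is.null(materials)) {
    materials <- ifelse(grepl("^urine", colnames(x)), "urine", "plasma")
  }
  ok <- colSums(!is.na(x)) >= min_pairs
  if (any(!ok))
    message("excluded ", sum(!ok), " variable(s) with < ", min_pairs,
            " complete pairs: ", paste(colnames(x)[!ok], collapse = ", "))
  if (!any(ok)) stop("no variable has enough complete observations")
  x <- x[, ok, drop = FALSE]
  materials <- materials[ok]
  r <- stats::cor(x, use = "pairwise.complete.obs")
  npairs <- crossprod(!is.na(x))
  r[npairs < min_pairs] <- NA_real_
  r[!is.finite(r)] <- NA_real_
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(r = r, n = npairs, materials = materials,
                 ordering = seq_len(ncol(x)), mask = NULL,
                 dendrogram = NULL),
            class = "correlation_matrix")
}

# average-linkage agglomerative clustering on distance 1 - r; returns the
# leaf order and the hclust tree
cluster_block <- function(r) {
  if (ncol(r) < 3L) return(list(order = seq_len(ncol(r)), tree = NULL))
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  list(order = hc$order, tree = hc)
}

#' Hierarchical-cluster ordering of a correlation matrix
#'
#' Agglomerative clustering on distance `1 - r` (signed; inverse
#' correlations are distant) with average linkage; the dendrogram leaf order
#' becomes the row/column permutation. With `scope = "per-material"` the
#' plasma and urine blocks are clustered independently and concatenated, as
#' used for the per-time-point matrices.
#'
#' @param m a [all_pairs_pearson()] result.
#' @param scope `"all"` or `"per-material"`.
#' @return the matrix object with `ordering` (a permutation) and
#'   `dendrogram` filled in; correlation values are never altered.
#' @export
cluster_order <- function(m, scope = c("all", "per-material")) {
  scope <- match.arg(scope)
  if (scope == "all") {
    cb <- cluster_block(m$r)
    m$ordering <- cb$order
    m$dendrogram <- cb$tree
  } else {
    ord <- integer(0)
    trees <- list()
    for (mat in unique(m$materials)) {
      idx <- which(m$materials == mat)
      cb <- cluster_block(m$r[idx, idx, drop = FALSE])
      ord <- c(ord, idx[cb$order])
      trees[[mat]] <- cb$tree
    }
    m$ordering <- ord
    m$dendrogram <- trees
  }
  m$scope <- scope
  m
}

#' Mask weak correlations in the lower triangle
#'
#' Cells of the designated triangle (in the cluster ordering) with
#' `|r| <= cutoff` are masked; the other triangle and the diagonal are left
#' untouched, mirroring display matrices that show all correlations above
#' the diagonal and only strong ones below.
#'
#' @param m a [all_pairs_pearson()] result (ordered or not).
#' @param cutoff threshold in `[0, 1)`.
#' @param region `"lower"` or `"upper"` triangle of the ordered matrix.
#' @return the matrix object with a logical `mask` (TRUE = masked).
#' @export
threshold_mask <- function(m, cutoff = 0.5, region = c("lower", "upper")) {
  region <- match.arg(region)
  stopifnot(cutoff >= 0, cutoff < 1)
  p <- ncol(m$r)
  ord <- m$ordering
  r_ord <- m$r[ord, ord]
  mask_ord <- matrix(FALSE, p, p)
  tri <- if (region == "lower") lower.tri(r_ord) else upper.tri(r_ord)
  mask_ord[tri & abs(r_ord) <= cutoff] <- TRUE
  # store in original variable order
  mask <- matrix(FALSE, p, p)
  mask[ord, ord] <- mask_ord
  dimnames(mask) <- dimnames(m$r)
  m$mask <- mask
  m$cutoff <- cutoff
  m
}

#' Ordered correlation matrix as a plain matrix
#' @param m a `correlation_matrix`.
#' @param apply_mask set masked cells to `NA`.
#' @return numeric matrix in cluster order.
#' @export
ordered_correlations <- function(m, apply_mask = FALSE) {
  r <- m$r
  if (apply_mask && !is.null(m$mask)) r[m$mask] <- NA_real_
  r[m$ordering, m$ordering]
}

#' Export the dendrogram of a clustered correlation matrix as Newick text
#' @param m a [cluster_order()] result with `scope = "all"`.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(m) {
  hc <- m$dendrogram
  if (is.null(hc) || !inherits(hc, "hclust"))
    stop("cluster_order(scope = 'all') must be run first")
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  node <- function(i) {
    if (i < 0) return(lab[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    paste0("(", node(kids[1]), ":", format(h, digits = 6), ",",
           node(kids[2]), ":", format(h, digits = 6), ")")
  }
  paste0(node(nrow(hc$merge)), ";")
}

#' Heatmap of a clustered, masked correlation matrix
#'
#' Pure function of (matrix, ordering, mask): masked cells are drawn blank.
#'
#' @param m a `correlation_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot_correlation_heatmap <- function(m, ...) {
  r <- ordered_correlations(m, apply_mask = TRUE)
  p <- ncol(r)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(seq_len(p), seq_len(p), t(r[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(p), labels = colnames(r), las = 2,
                 cex.axis = 0.5)
  graphics::axis(2, at = seq_len(p), labels = rev(rownames(r)), las = 2,
                 cex.axis = 0.5)
  invisible(m)
}
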