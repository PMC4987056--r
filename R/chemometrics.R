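#' Unit-variance (auto) scaling
#'
#' Mean-centers every column and divides by its sample standard deviation.
#' Zero-variance columns are dropped with a warning; the retained means and
#' sds are stored for back-scaling.
#'
#' @param X numeric samples x variables matrix, `n >= 2`.
#' @return scaled matrix with attributes `center`, `scale`, `dropped`.
#' @export
uv_scale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  if (!any(keep)) stop("all columns are constant")
  if (any(!keep))
    warning("dropped ", sum(!keep), " zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  attr(Xs, "center") <- mu[keep]
  attr(Xs, "scale") <- sd[keep]
  attr(Xs, "dropped") <- colnames(X)[!keep]
  Xs
}

#' Principal component analysis by singular value decomposition
#'
#' PCA of an already-scaled matrix, components ordered by explained
#' variance, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param X scaled samples x variables matrix (see [uv_scale()]).
#' @param k number of components, `k <= min(n - 1, p)`.
#' @return list with `scores` (n x k), `loadings` (p x k), `explained`
#'   (fraction of variance per component, all components).
#' @export
pca_svd <- function(X, k = 2L) {
  X <- as.matrix(X)
  if (k > min(nrow(X) - 1L, ncol(X)))
    stop("k exceeds min(n - 1, p)")
  sv <- svd(X)
  ev <- sv$d^2 / sum(sv$d^2)
  flip <- vapply(seq_len(k), function(a) {
    l <- sv$v[, a]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(loadings) <- colnames(X)
  list(scores = scores, loadings = loadings, explained = ev)
}

# dummy-code a class vector into an n x nclass indicator matrix
dummy_code <- function(y) {
  f <- factor(y)
  if (nlevels(f) < 2L) stop("response has a single class")
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "levels") <- levels(f)
  Y
}

#' Fit a PLS / PLS-DA model (NIPALS)
#'
#' Sequential NIPALS extraction: each component's weight vector is the
#' dominant direction of the X'Y covariance, scores are projections, and X
#' and Y are deflated by the extracted component. Class responses are
#' dummy-coded then centered; X is unit-variance scaled by default (the
#' scaling is part of the model and re-applied during prediction).
#'
#' @param X raw samples x variables matrix.
#' @param Y numeric response (vector/matrix) or a factor/character vector of
#'   class labels.
#' @param ncomp number of latent components.
#' @param scale unit-variance scale X (default TRUE).
#' @return object of class `pls_model`: weights `W`, X-loadings `P`, scores
#'   `TT`, Y-loadings `Q`, cumulative `r2` per component, scaling and
#'   response metadata.
#' @export
pls_fit <- function(X, Y, ncomp = 1L, scale = TRUE) {
  X <- as.matrix(X)
  is_da <- is.factor(Y) || is.character(Y)
  Ymat <- if (is_da) dummy_code(Y) else as.matrix(Y)
  lev <- if (is_da) attr(Ymat, "levels") else NULL
  if (!is_da && stats::sd(Ymat) == 0) stop("degenerate constant response")

  xmu <- colMeans(X)
  xsd <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(xsd == 0)) stop("zero-variance predictor column; scale first or drop it")
  Xc <- sweep(sweep(X, 2, xmu), 2, xsd, "/")
  ymu <- colMeans(Ymat)
  Yc <- sweep(Ymat, 2, ymu)
  Y0 <- Yc

  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); Q <- matrix(0, q, ncomp)
  r2 <- numeric(ncomp)
  sstot <- sum(Y0^2)
  for (a in seq_len(ncomp)) {
    S <- crossprod(Xc, Yc)                 # p x q covariance
    if (q == 1L) {
      w <- S[, 1]
    } else {
      # dominant left singular vector of X'Y via its small q x q Gram matrix
      eg <- eigen(crossprod(S), symmetric = TRUE)
      w <- S %*% eg$vectors[, 1]
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- Xc %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xc, tt) / tt2
    qq <- crossprod(Yc, tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, qq)
    W[, a] <- w; P[, a] <- pp; TT[, a] <- tt; Q[, a] <- qq
    r2[a] <- 1 - sum(Yc^2) / sstot
  }
  if (ncomp < 1L) stop("no PLS component could be extracted")
  structure(list(W = W[, seq_len(ncomp), drop = FALSE],
                 P = P[, seq_len(ncomp), drop = FALSE],
                 TT = TT[, seq_len(ncomp), drop = FALSE],
                 Q = Q[, seq_len(ncomp), drop = FALSE],
                 ncomp = ncomp, r2 = r2[seq_len(ncomp)],
                 x_center = xmu, x_scale = xsd, y_center = ymu,
                 levels = lev, is_da = is_da,
                 var_names = colnames(X)),
            class = "pls_model")
}

#' Regression coefficients of a fitted PLS model
#' @param model a [pls_fit()] model.
#' @param ncomp number of components to use.
#' @return p x q coefficient matrix on the scaled X / centered Y scale.
#' @export
pls_coef <- function(model, ncomp = model$ncomp) {
  a <- seq_len(ncomp)
  W <- model$W[, a, drop = FALSE]
  P <- model$P[, a, drop = FALSE]
  Q <- model$Q[, a, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict from a PLS model
#'
#' @param object a [pls_fit()] model.
#' @param newdata raw matrix on the original variable scale.
#' @param ncomp components to use.
#' @param type `"response"` (numeric predictions, original Y scale) or
#'   `"class"` (nearest dummy target; for two classes this is the midpoint
#'   threshold rule).
#' @param ... unused.
#' @return matrix of predictions or character vector of classes.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xc <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  B <- pls_coef(object, ncomp)
  Yhat <- sweep(Xc %*% B, 2, object$y_center, "+")
  if (type == "response") return(Yhat)
  if (!object$is_da) stop("class prediction requires a PLS-DA model")
  # nearest target: each class target is its indicator row
  lev <- object$levels
  targ <- diag(length(lev))
  d2 <- outer(rowSums(Yhat^2), rep(1, length(lev))) -
    2 * Yhat %*% t(targ) + outer(rep(1, nrow(Yhat)), rowSums(targ^2))
  lev[max.col(-d2, ties.method = "first")]
}

# contiguous segment assignment of n ordered samples into k folds
segment_folds <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), times = sizes)
}

#' Segment-wise cross-validation of a PLS / PLS-DA model
#'
#' Samples are split into `folds` contiguous segments of the given ordering;
#' per fold, scaling and model are refit on the complement and the held-out
#' segment predicted. `Q2` per cumulative component is `1 - PRESS / TSS`
#' with TSS measured against the training means. Every sample is predicted
#' exactly once.
#'
#' @param X raw matrix, @param Y response (numeric or class labels).
#' @param folds number of segments (default 7).
#' @param ncomp maximum number of components.
#' @param ordering sample ordering defining the segments (default the given
#'   order; [nmc_repetitions()] re-randomizes it per repetition).
#' @param scale unit-variance scale within each training fold.
#' @return list: `q2` (per cumulative component), `pred` (n x q x ncomp
#'   array of held-out predictions), `fold` assignment, `class` (held-out
#'   class predictions at `ncomp`, PLS-DA only).
#' @export
cross_validate <- function(X, Y, folds = 7L, ncomp = 1L,
                           ordering = seq_len(nrow(as.matrix(X))),
                           scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("more folds than samples")
  is_da <- is.factor(Y) || is.character(Y)
  Ymat <- if (is_da) dummy_code(Y) else as.matrix(Y)
  q <- ncol(Ymat)
  fold_of <- integer(n)
  fold_of[ordering] <- segment_folds(n, folds)
  pred <- array(NA_real_, c(n, q, ncomp))
  cls <- if (is_da) character(n) else NULL
  press <- matrix(0, folds, ncomp)
  tss <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    if (is_da && length(unique(Y[tr])) < 2L) {
      warning("fold ", f, " training set lost a class; fold skipped in Q2")
      next
    }
    fit <- tryCatch(pls_fit(X[tr, , drop = FALSE],
                            if (is_da) Y[tr] else Ymat[tr, , drop = FALSE],
                            ncomp = ncomp, scale = scale),
                    error = function(e) NULL)
    if (is.null(fit)) next
    for (a in seq_len(fit$ncomp))
      pred[te, , a] <- predict(fit, X[te, , drop = FALSE], ncomp = a)
    if (fit$ncomp < ncomp)
      for (a in seq(fit$ncomp + 1L, ncomp))
        pred[te, , a] <- pred[te, , fit$ncomp]
    if (is_da)
      cls[te] <- predict(fit, X[te, , drop = FALSE],
                         ncomp = min(ncomp, fit$ncomp), type = "class")
    ytr_mu <- colMeans(Ymat[tr, , drop = FALSE])
    resid0 <- sweep(Ymat[te, , drop = FALSE], 2, ytr_mu)
    tss[f] <- sum(resid0^2)
    for (a in seq_len(ncomp))
      press[f, a] <- sum((Ymat[te, , drop = FALSE] -
                            matrix(pred[te, , a], ncol = q))^2)
  }
  list(q2 = 1 - colSums(press) / sum(tss), pred = pred,
       fold = fold_of, class = cls, folds = folds, ncomp = ncomp)
}

#' Repeated cross-validated misclassification counts (observed arm)
#'
#' Re-randomizes the sample ordering before each segment assignment, runs
#' one segment-wise CV per repetition, predicts held-out classes by the
#' nearest dummy target, and counts misclassifications.
#'
#' @param X raw matrix, @param labels class labels (two or more classes).
#' @param folds CV segments, @param ncomp components.
#' @param reps repetitions (>= 1).
#' @param seed integer seed (the NMC vector is reproducible).
#' @return list: `nmc` (integer vector over repetitions), `median`, `ci`
#'   (2.5/97.5 percentiles).
#' @export
nmc_repetitions <- function(X, labels, folds = 7L, ncomp = 1L, reps = 500L,
                            seed = 1) {
  if (reps < 1L) stop("reps must be >= 1")
  if (length(unique(labels)) < 2L) stop("need two or more classes")
  set.seed(as.integer(seed))
  X <- as.matrix(X)
  n <- nrow(X)
  nmc <- integer(reps)
  for (r in seq_len(reps)) {
    cv <- cross_validate(X, labels, folds = folds, ncomp = ncomp,
                         ordering = sample.int(n))
    nmc[r] <- sum(cv$class != as.character(labels))
  }
  list(nmc = nmc, median = stats::median(nmc),
       ci = stats::quantile(nmc, c(0.025, 0.975), names = FALSE))
}

#' Misclassification permutation test for PLS-DA
#'
#' Builds the null NMC distribution by repeating the cross-validation with
#' randomly permuted class labels (one CV repetition per permutation) and
#' compares it with the observed repeated-CV NMC distribution. Two clearly
#' distinct p-values are reported: `p_empirical`, the exceedance probability
#' `(1 + #\{null <= observed median\}) / (nperm + 1)` whose resolution is
#' limited by `nperm`, and `p_ranksum`, a Wilcoxon rank-sum comparison of
#' the two NMC distributions (observed < null).
#'
#' @inheritParams nmc_repetitions
#' @param nperm number of label permutations (>= 20).
#' @return list with the observed summary (`observed`), `null` NMC vector,
#'   `p_empirical` and `p_ranksum`.
#' @export
nmc_permutation_null <- function(X, labels, folds = 7L, ncomp = 1L,
                                 reps = 500L, nperm = 500L, seed = 1) {
  if (nperm < 20L) stop("nperm must be >= 20 for usable p resolution")
  obs <- nmc_repetitions(X, labels, folds = folds, ncomp = ncomp,
                         reps = reps, seed = seed)
  set.seed(as.integer(seed) + 1L)
  X <- as.matrix(X)
  n <- nrow(X)
  null <- integer(nperm)
  labels <- as.character(labels)
  for (k in seq_len(nperm)) {
    perm <- sample(labels)
    cv <- cross_validate(X, perm, folds = folds, ncomp = ncomp,
                         ordering = sample.int(n))
    null[k] <- sum(cv$class != perm)
  }
  p_emp <- (1 + sum(null <= obs$median)) / (nperm + 1)
  p_rank <- suppressWarnings(
    stats::wilcox.test(obs$nmc, null, alternative = "less")$p.value)
  list(observed = obs, null = null, p_empirical = p_emp, p_ranksum = p_rank)
}

#' Back-scaled loading weights
#'
#' Reverts first-component loading weights from unit variance to natural
#' scale (`amplitude = weight x original sd`, proportional to the
#' covariance of each variable with the score) and attaches a correlation
#' color value in [-1, 1] (Pearson correlation of each variable with the
#' response).
#'
#' @param model a [pls_fit()] model fitted with `scale = TRUE`.
#' @param X the raw data matrix the model was fitted on.
#' @param y numeric response vector (for PLS-DA, an indicator of the second
#'   class is derived from `labels`).
#' @param labels class labels (PLS-DA).
#' @param comp component to back-scale.
#' @return `data.frame` with `variable`, `amplitude`, `color`.
#' @export
backscale_loadings <- function(model, X, y = NULL, labels = NULL, comp = 1L) {
  X <- as.matrix(X)
  sds <- model$x_scale
  if (length(sds) != ncol(X)) stop("sd length mismatch with X")
  if (is.null(y)) {
    if (is.null(labels)) stop("provide y or labels")
    y <- as.numeric(factor(labels)) - 1
  }
  amp <- model$W[, comp] * sds
  col <- suppressWarnings(apply(X, 2, function(v)
    if (stats::sd(v) == 0) 0 else stats::cor(v, y)))
  data.frame(variable = if (is.null(model$var_names)) seq_along(amp)
             else model$var_names,
             amplitude = amp, color = col, stringsAsFactors = FALSE)
}

#' Plot back-scaled loadings as a pseudo-spectrum
#'
#' @param bl result of [backscale_loadings()].
#' @param ppm optional numeric positions for the x axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot_backscaled_loadings <- function(bl, ppm = NULL, ...) {
  x <- if (is.null(ppm)) seq_len(nrow(bl)) else ppm
  pal <- grDevices::colorRampPalette(c("blue", "grey80", "red"))(101)
  ci <- pal[pmin(101, pmax(1, round((bl$color + 1) * 50) + 1))]
  graphics::plot(x, bl$amplitude, type = "h", col = ci,
                 xlab = if (is.null(ppm)) "variable" else "ppm",
                 ylab = "back-scaled loading weight", ...)
  graphics::abline(h = 0, col = "grey50")
  invisible(bl)
}

#' Smallest component count attaining the maximal cross-validated Q2
#' @param cv result of [cross_validate()].
#' @param tol Q2 values within `tol` of the maximum count as maximal.
#' @return integer component count.
#' @export
select_ncomp <- function(cv, tol = 1e-8) {
  which(cv$q2 >= max(cv$q2) - tol)[1]
}
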