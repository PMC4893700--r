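## PCA by NIPALS with deflation. Kept self-contained (power iteration per
## component) so the decomposition used for scores plots shares the
## numerical conventions of the PLS code; agreement with the SVD is part
## of the test suite.

.fixSign <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1

#' Fit a principal component model
#'
#' Components of the column-centered (optionally unit-variance scaled)
#' matrix, extracted sequentially by NIPALS with deflation. Sign
#' convention: the largest-magnitude loading entry of each component is
#' positive, so fits are reproducible.
#'
#' @param x numeric matrix (rows = entities/samples) or a log-scale
#'   [EntityMatrix-class].
#' @param ncomp number of components, at most `min(nrow - 1, ncol)`.
#' @param scale. also divide columns by their standard deviation.
#' @param tol,maxIter NIPALS convergence controls.
#' @return a [PcaModel-class].
#' @export
fitPca <- function(x, ncomp = 2L, scale. = TRUE, tol = 1e-12, maxIter = 1000L) {
  if (is(x, "EntityMatrix")) x <- entityValues(x)
  x <- as.matrix(x)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("ncomp must lie in [1, min(nrow - 1, ncol)]")
  ctr <- colMeans(x)
  Xc <- sweep(x, 2, ctr, `-`)
  scl <- rep(1, ncol(x))
  if (scale.) {
    scl <- apply(Xc, 2, sd)
    if (any(scl < .Machine$double.eps^0.5))
      stop("constant column(s); drop zero-variance features before PCA")
    Xc <- sweep(Xc, 2, scl, `/`)
  }
  total <- sum(Xc^2)
  if (total < .Machine$double.eps)
    stop("degenerate (all-constant) matrix")
  n <- nrow(Xc); p <- ncol(Xc)
  TT <- matrix(0, n, ncomp); PP <- matrix(0, p, ncomp)
  ve <- numeric(ncomp)
  Xd <- Xc
  for (a in seq_len(ncomp)) {
    t <- Xd[, which.max(colSums(Xd^2))]
    for (it in seq_len(maxIter)) {
      pv <- crossprod(Xd, t)[, 1] / sum(t^2)
      pv <- pv / sqrt(sum(pv^2))
      tNew <- Xd %*% pv
      if (sqrt(sum((tNew - t)^2)) < tol * sqrt(sum(tNew^2))) { t <- tNew[, 1]; break }
      t <- tNew[, 1]
    }
    s <- .fixSign(pv)
    pv <- s * pv; t <- s * t
    TT[, a] <- t; PP[, a] <- pv
    ve[a] <- sum(t^2) / total
    Xd <- Xd - tcrossprod(t, pv)
  }
  dimnames(TT) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(PP) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  new("PcaModel", scores = TT, loadings = PP, varExplained = ve,
      center = ctr, scale = scl)
}
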