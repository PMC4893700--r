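## Stratified repeated k-fold cross-validation of PLS-DA models.
## Scaling is re-estimated inside each training fold (no leakage);
## pooled PRESS over the held-out predictions gives Q2.

.stratifiedFolds <- function(classes, nFolds) {
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) < nFolds && length(idx) == 1L)
      warning("class '", cl, "' has a single member; it is tested in one fold only")
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

## lean fit + predict used inside the CV loop: same algorithm as
## fitPlsda/predict but without S4 construction or confidence grading
.leanPlsdaPredict <- function(xtr, trLabels, xte, lv, ncomp, scale = TRUE,
                              tol = 1e-10, maxIter = 500L) {
  ctr <- colMeans(xtr)
  Xc <- sweep(xtr, 2, ctr, `-`)
  keep <- seq_len(ncol(xtr))
  if (scale) {
    scl <- apply(Xc, 2, sd)
    zero <- scl < .Machine$double.eps^0.5
    if (any(zero)) {
      keep <- which(!zero); Xc <- Xc[, keep, drop = FALSE]
      ctr <- ctr[keep]; scl <- scl[keep]
    }
  } else scl <- rep(1, ncol(Xc))
  Xc <- sweep(Xc, 2, scl, `/`)
  trLv <- sort(unique(trLabels))
  Y <- .oneHot(trLabels, trLv)
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2, yMeans, `-`)
  ncomp <- min(ncomp, nrow(Xc) - 1L, ncol(Xc))
  p <- ncol(Xc); n <- nrow(Xc); K <- length(trLv)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, K, ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t <- rep(0, n)
    for (it in seq_len(maxIter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tNew <- (Xd %*% w)[, 1]
      q <- crossprod(Yd, tNew)[, 1] / sum(tNew^2)
      u <- (Yd %*% q)[, 1] / sum(q^2)
      conv <- sqrt(sum((tNew - t)^2)) < tol * sqrt(sum(tNew^2))
      t <- tNew
      if (conv) break
    }
    if (sum(t^2) < 1e-12) { ncomp <- a - 1L; break }
    pv <- crossprod(Xd, t)[, 1] / sum(t^2)
    W[, a] <- w; Q[, a] <- q; P[, a] <- pv
    Xd <- Xd - tcrossprod(t, pv)
    Yd <- Yd - tcrossprod(t, q)
  }
  if (ncomp < 1L) stop("degenerate training fold (no usable component)")
  W <- W[, seq_len(ncomp), drop = FALSE]; P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[, seq_len(ncomp), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  xs <- sweep(sweep(xte[, keep, drop = FALSE], 2, ctr, `-`), 2, scl, `/`)
  yhatTe <- sweep(xs %*% B, 2, yMeans, `+`)
  colnames(yhatTe) <- trLv
  list(yhat = yhatTe, class = trLv[max.col(yhatTe, ties.method = "first")])
}

#' Cross-validate a PLS-DA model
#'
#' Stratified `nFolds`-fold cross-validation repeated `nRepeats` times.
#' In each round the model (including column scaling) is fitted on the
#' training folds only and the left-out fold is predicted; every entity
#' is tested exactly once per repeat. Reported per repeat:
#' misclassification error, (multiclass) AUROC of the pooled held-out
#' predictions, and pooled Q2 = 1 - PRESS / SSY (centered one-hot Y).
#'
#' @param x log-scale feature matrix (rows = entities) or log-scale
#'   [EntityMatrix-class].
#' @param classes class labels (defaults to the EntityMatrix metadata).
#' @param ncomp number of latent variables.
#' @param nFolds folds per repeat (default 5: leave one fifth out).
#' @param nRepeats number of repeats (fold draws) to average over.
#' @param seed optional RNG seed; `NULL` uses the ambient RNG state.
#' @param scale autoscale within each training fold.
#' @return a [CvResult-class].
#' @export
crossValidate <- function(x, classes = NULL, ncomp = 2L, nFolds = 5L,
                          nRepeats = 20L, seed = NULL, scale = TRUE) {
  inp <- .resolveXClasses(x, classes)
  x <- inp$x; classes <- inp$classes
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be at least 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lv <- sort(unique(classes))
  Y <- .oneHot(classes, lv)
  ssy <- sum(sweep(Y, 2, colMeans(Y), `-`)^2)

  mis <- auc <- q2 <- numeric(nRepeats)
  foldList <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    fold <- .stratifiedFolds(classes, nFolds)
    foldList[[r]] <- fold
    yhat <- matrix(NA_real_, nrow(x), length(lv), dimnames = list(rownames(x), lv))
    pred <- character(nrow(x))
    for (f in sort(unique(fold))) {
      te <- fold == f; tr <- !te
      pr <- .leanPlsdaPredict(x[tr, , drop = FALSE], classes[tr],
                              x[te, , drop = FALSE], lv, ncomp, scale = scale)
      yhat[te, colnames(pr$yhat)] <- pr$yhat
      pred[te] <- pr$class
    }
    yhat[is.na(yhat)] <- 0   # classes absent from a training fold
    mis[r] <- mean(pred != classes)
    auc[r] <- multiclassAuroc(yhat, classes)
    q2[r] <- 1 - sum((Y - yhat)^2) / ssy
  }
  new("CvResult", misclassification = mis, auroc = auc, q2 = q2,
      folds = foldList, nFolds = nFolds, nRepeats = as.integer(nRepeats),
      ncomp = as.integer(ncomp))
}
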