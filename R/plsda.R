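## PLS2 discriminant analysis by classical NIPALS: one-hot class coding
## with column centering, deflation of both X and Y, unit-norm weights,
## deterministic sign convention. VIP scores, Hotelling T2 limits and
## ellipse membership, prediction with confidence grading, and binary /
## pairwise-averaged multiclass AUROC.

.oneHot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels),
              dimnames = list(names(labels), levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  Y
}

.resolveXClasses <- function(x, classes) {
  if (is(x, "EntityMatrix")) {
    if (x@transform == "linear")
      stop("log-transform the entity matrix before modeling (see logTransform)")
    if (is.null(classes)) classes <- entityClasses(x)
    x <- entityValues(x)
  }
  if (is.null(classes)) stop("class labels required")
  list(x = as.matrix(x), classes = as.character(classes))
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 regression of the column-centered one-hot class membership
#' matrix on the autoscaled feature matrix. Per component the weight
#' vector is normalized to unit length, scores of different components
#' are mutually orthogonal, and both X and Y are deflated. The sign of
#' each component is fixed so its largest-magnitude weight entry is
#' positive. Iteration stops when the score vector changes by less than
#' `tol` (relative) or after `maxIter` sweeps.
#'
#' @param x numeric matrix (rows = entities) on log scale, or a log-scale
#'   [EntityMatrix-class] (class labels then default to its metadata).
#' @param classes class labels, one per row; levels are ordered
#'   lexicographically (prediction ties go to the first level).
#' @param ncomp number of latent variables.
#' @param scale autoscale columns (center always applied); the training
#'   column statistics are stored in the model and re-applied at
#'   prediction time.
#' @param tol,maxIter NIPALS convergence controls.
#' @return a [PlsModel-class].
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' x[, 1] <- rep(c(0, 1), each = 5) + rnorm(10, sd = 0.05)
#' m <- fitPlsda(x, rep(c("a", "b"), each = 5), ncomp = 1)
#' r2Y(m)
#' @export
fitPlsda <- function(x, classes = NULL, ncomp = 2L, scale = TRUE,
                     tol = 1e-10, maxIter = 500L) {
  inp <- .resolveXClasses(x, classes)
  x <- inp$x; classes <- inp$classes
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ncomp <- as.integer(ncomp)
  lv <- sort(unique(classes))
  if (length(lv) < 2L) stop("at least two classes required")
  cnt <- table(factor(classes, levels = lv))
  if (any(cnt == 0L)) stop("class with zero rows: ", paste(lv[cnt == 0], collapse = ", "))
  if (ncomp < 1L || ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("ncomp must lie in [1, min(nrow - 1, ncol)]")

  ctr <- colMeans(x)
  scl <- rep(1, ncol(x)); names(scl) <- colnames(x)
  Xc <- sweep(x, 2, ctr, `-`)
  if (scale) {
    scl <- apply(Xc, 2, sd)
    zero <- scl < .Machine$double.eps^0.5
    if (any(zero)) {
      Xc <- Xc[, !zero, drop = FALSE]
      ctr <- ctr[!zero]; scl <- scl[!zero]
    }
    Xc <- sweep(Xc, 2, scl, `/`)
  }
  feats <- colnames(Xc)
  p <- length(feats); n <- nrow(Xc); K <- length(lv)
  if (ncomp > min(n - 1L, p)) ncomp <- min(n - 1L, p)

  Y <- .oneHot(classes, lv)
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2, yMeans, `-`)
  ssyTotal <- sum(Yc^2)

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); Q <- matrix(0, K, ncomp)
  ssy <- numeric(ncomp); iters <- integer(ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t <- rep(0, n)
    for (it in seq_len(maxIter)) {
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) stop("degenerate component ", a, ": X exhausted")
      w <- w / nw
      tNew <- (Xd %*% w)[, 1]
      q <- crossprod(Yd, tNew)[, 1] / sum(tNew^2)
      u <- (Yd %*% q)[, 1] / sum(q^2)
      conv <- sqrt(sum((tNew - t)^2)) < tol * sqrt(sum(tNew^2))
      t <- tNew
      if (conv) break
    }
    iters[a] <- it
    if (sum(t^2) < 1e-12)
      stop("component ", a, " has vanishing score variance (rank exceeded)")
    s <- .fixSign(w)
    w <- s * w; t <- s * t; q <- s * q
    pv <- crossprod(Xd, t)[, 1] / sum(t^2)
    W[, a] <- w; TT[, a] <- t; Q[, a] <- q; P[, a] <- pv
    ssy[a] <- sum(q^2) * sum(t^2)
    Xd <- Xd - tcrossprod(t, pv)
    Yd <- Yd - tcrossprod(t, q)
  }
  dimnames(W) <- dimnames(P) <- list(feats, paste0("LV", seq_len(ncomp)))
  dimnames(TT) <- list(rownames(x), paste0("LV", seq_len(ncomp)))
  dimnames(Q) <- list(lv, paste0("LV", seq_len(ncomp)))
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(feats, lv)
  new("PlsModel", ncomp = ncomp, weights = W, xloadings = P, scores = TT,
      yloadings = Q, coefficients = B, classes = lv,
      labels = as.character(classes), yMeans = yMeans, center = ctr,
      scale = scl, features = feats, ssy = ssy, ssyTotal = ssyTotal,
      r2y = cumsum(ssy) / ssyTotal, iterations = iters)
}

#' Variable importance in the projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ) with unit-norm
#' weight vectors; the mean of the squared VIP scores equals 1.
#'
#' @param model a fitted [PlsModel-class].
#' @return named numeric vector of per-feature VIP scores.
#' @export
vip <- function(model) {
  stopifnot(is(model, "PlsModel"))
  if (sum(model@ssy) <= 0)
    stop("model explains no Y variance; VIP undefined")
  p <- length(model@features)
  w2 <- sweep(model@weights^2, 2, colSums(model@weights^2), `/`)
  v <- sqrt(p * as.numeric(w2 %*% model@ssy) / sum(model@ssy))
  names(v) <- model@features
  v
}

#' Hotelling T2 critical value
#'
#' T2_crit = A (n - 1) / (n - A) * F_{1-alpha}(A, n - A). A score vector t
#' lies inside the (1 - alpha) region iff sum_a t_a^2 / var(t_a) <= T2_crit.
#'
#' @param n number of observations behind the scores.
#' @param ncomp number of score dimensions A (must be < n).
#' @param alpha significance level (default 0.05).
#' @return the critical value (numeric scalar).
#' @examples
#' hotellingLimit(30, 2)  # ~6.92
#' @export
hotellingLimit <- function(n, ncomp, alpha = 0.05) {
  stopifnot(ncomp >= 1)
  if (n <= ncomp) stop("need n > ncomp for a Hotelling limit")
  ncomp * (n - 1) / (n - ncomp) * qf(1 - alpha, ncomp, n - ncomp)
}

#' 95% confidence ellipse of a two-component scores plot
#'
#' @param scores n x 2 score matrix (assumed centered at the origin
#'   overall; pass class scores and `center = TRUE` for per-class
#'   ellipses).
#' @param alpha significance level.
#' @param center center the ellipse at the score means.
#' @param npoints number of polygon points.
#' @return data.frame with the ellipse outline (`x`, `y`) plus attributes
#'   `semiAxes` and `tcrit`.
#' @export
hotellingEllipse <- function(scores, alpha = 0.05, center = FALSE, npoints = 200L) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  mu <- if (center) colMeans(scores) else c(0, 0)
  v <- apply(scores, 2, var)
  tcrit <- hotellingLimit(nrow(scores), 2L, alpha)
  ang <- seq(0, 2 * pi, length.out = npoints)
  semi <- sqrt(tcrit * v)
  out <- data.frame(x = mu[1] + semi[1] * cos(ang), y = mu[2] + semi[2] * sin(ang))
  attr(out, "semiAxes") <- semi
  attr(out, "tcrit") <- tcrit
  out
}

.t2Distance <- function(scores, mu, v) {
  sweep2 <- sweep(scores, 2, mu, `-`)
  rowSums(sweep(sweep2^2, 2, v, `/`))
}

#' Project new samples through a fitted PLS-DA model
#'
#' Rows are transformed with the scaling stored at training time, scored
#' via t = X W (P'W)^-1, and assigned the class with the largest predicted
#' Y (ties by lexicographic class order). Each row receives a confidence
#' grade: `high` when inside the predicted class's own 95% score ellipse,
#' `medium` when only inside the global 95% Hotelling limit, `low`
#' outside.
#'
#' @param object a fitted [PlsModel-class].
#' @param newdata matrix (rows = entities, log scale, raw feature space)
#'   or a log-scale [EntityMatrix-class]; must contain the model features.
#' @param alpha significance level of the confidence regions.
#' @param ... unused.
#' @return list with `class` (character), `grade` (high/medium/low),
#'   `yhat` (predicted class-membership values), `scores`.
#' @export
setMethod("predict", "PlsModel", function(object, newdata, alpha = 0.05, ...) {
  if (is(newdata, "EntityMatrix")) {
    if (newdata@transform == "linear")
      stop("log-transform the entity matrix before projection")
    newdata <- entityValues(newdata)
  }
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object@features))
    colnames(newdata) <- object@features
  miss <- setdiff(object@features, colnames(newdata))
  if (length(miss))
    stop("newdata lacks model feature(s): ", paste(head(miss, 5), collapse = ", "))
  x <- newdata[, object@features, drop = FALSE]
  xs <- sweep(sweep(x, 2, object@center, `-`), 2, object@scale, `/`)
  R <- object@weights %*% solve(crossprod(object@xloadings, object@weights))
  sc <- xs %*% R
  colnames(sc) <- colnames(object@scores)
  yhat <- sweep(xs %*% object@coefficients, 2, object@yMeans, `+`)
  cls <- object@classes[max.col(yhat, ties.method = "first")]

  A <- object@ncomp
  n <- nrow(object@scores)
  vGlob <- apply(object@scores, 2, var)
  inGlobal <- unname(.t2Distance(sc, rep(0, A), vGlob) <= hotellingLimit(n, A, alpha))
  grade <- ifelse(inGlobal, "medium", "low")
  for (cl in unique(cls)) {
    tc <- object@scores[object@labels == cl, , drop = FALSE]
    if (nrow(tc) <= A + 1L) next   # too few rows for a class ellipse
    rows <- which(cls == cl)
    d <- .t2Distance(sc[rows, , drop = FALSE], colMeans(tc), apply(tc, 2, var))
    high <- d <= hotellingLimit(nrow(tc), A, alpha)
    grade[rows][high & inGlobal[rows]] <- "high"
  }
  list(class = cls, grade = grade, yhat = yhat, scores = sc)
})

#' Area under the ROC curve
#'
#' Binary AUROC in the Mann-Whitney rank form (tie-aware). For more than
#' two classes use [multiclassAuroc()].
#'
#' @param scores numeric vector, larger = more `positive`.
#' @param labels class labels (two levels present).
#' @param positive label treated as positive; default the lexicographically
#'   last level.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.8, 0.2, 0.5, 0.1), c("pos", "pos", "neg", "neg"), "pos")  # 0.75
#' @export
auroc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("auroc needs exactly two classes present")
  if (is.null(positive)) positive <- lv[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("a class is absent from labels")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUROC (mean of pairwise AUCs)
#'
#' Unweighted mean over all unordered class pairs of the binary AUROC
#' computed, on the samples of the two classes, from the contrast of
#' their predicted class-membership values.
#'
#' @param yhat matrix of predicted class-membership values (columns named
#'   by class).
#' @param labels true labels; every class named in `yhat` columns that
#'   occurs in `labels` enters the average.
#' @return multiclass AUROC in \[0, 1\].
#' @export
multiclassAuroc <- function(yhat, labels) {
  labels <- as.character(labels)
  lv <- intersect(colnames(yhat), unique(labels))
  if (length(lv) < 2L) stop("need at least two classes present")
  if (length(lv) == 2L) {
    sel <- labels %in% lv
    return(auroc(yhat[sel, lv[2]] - yhat[sel, lv[1]], labels[sel], positive = lv[2]))
  }
  prs <- utils::combn(lv, 2)
  mean(apply(prs, 2, function(pr) {
    sel <- labels %in% pr
    auroc(yhat[sel, pr[2]] - yhat[sel, pr[1]], labels[sel], positive = pr[2])
  }))
}
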