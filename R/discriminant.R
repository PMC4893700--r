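## Univariate testing and the dual discriminant-metabolite criterion:
## a metabolite is flagged when q < 0.05 (BH-FDR over the comparison's
## Mann-Whitney or ANOVA p-values) OR its VIP from the comparison's
## PLS-DA model exceeds 1.2.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration of the
#' U null distribution) when `min(n1, n2) <= 8` and the data are
#' tie-free, otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y numeric value vectors (both non-empty).
#' @return list with `U` (statistic of `x`) and `p`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # all values tied: no evidence either way
  list(U = unname(wt$statistic), p = min(1, p))
}

#' One-way analysis of variance
#'
#' Classical between/within F test on k groups with (k - 1, N - k)
#' degrees of freedom. Degenerate inputs are handled explicitly: zero
#' within-group variance with unequal means reports p = 0 with a warning;
#' all values identical is an error (F undefined).
#'
#' @param groups list of at least two numeric vectors, each with at least
#'   two values.
#' @return list with `F`, `p`, `dfBetween`, `dfWithin`.
#' @examples
#' anovaOneway(list(c(1, 2), c(3, 4)))  # F = 8 on (1, 2) df
#' @export
anovaOneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs at least two values")
  allv <- unlist(groups, use.names = FALSE)
  k <- length(groups); N <- length(allv)
  gm <- mean(allv)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw < .Machine$double.eps * max(1, sum(allv^2))) {
    if (ssb < .Machine$double.eps * max(1, sum(allv^2)))
      stop("all values identical; F undefined")
    warning("zero within-group variance with unequal means; p = 0")
    return(list(F = Inf, p = 0, dfBetween = df1, dfWithin = df2))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       dfBetween = df1, dfWithin = df2)
}

#' Benjamini-Hochberg q-values
#'
#' q_(i) = min_{j >= i} ( m p_(j) / j ), capped at 1 and mapped back to
#' the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bhFdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Discriminant metabolites by the dual q-value / VIP criterion
#'
#' Per metabolite: a Mann-Whitney p (pairwise comparison of two groups)
#' or one-way ANOVA p (four-group comparison), BH-corrected across the
#' metabolites of the comparison; a VIP score from the comparison's
#' PLS-DA model; the direction of change (sign of the group-mean
#' difference on the log scale); and the flag
#' `q < qThreshold OR VIP > vipThreshold`.
#'
#' @param matrix a log-scale [EntityMatrix-class].
#' @param comparison `"pairwise"` (two groups via `groups`) or
#'   `"four_group"` (all classes at once, ANOVA + multiclass PLS-DA).
#' @param groups for `"pairwise"`: the two class labels to compare, the
#'   first being the reference (direction = sign of second minus first).
#' @param model optional pre-fitted [PlsModel-class] for the comparison;
#'   fitted on the comparison's entities with `ncomp` components when
#'   omitted.
#' @param ncomp latent variables for an internally fitted model.
#' @param qThreshold,vipThreshold the dual criterion thresholds
#'   (defaults 0.05 and 1.2).
#' @return data.frame: `metabolite`, `comparison`, `p`, `q`, `vip`,
#'   `direction`, `flagged`.
#' @export
discriminantFeatures <- function(matrix, comparison = c("pairwise", "four_group"),
                                 groups = NULL, model = NULL, ncomp = NULL,
                                 qThreshold = 0.05, vipThreshold = 1.2) {
  comparison <- match.arg(comparison)
  stopifnot(is(matrix, "EntityMatrix"))
  if (matrix@transform == "linear")
    stop("discriminantFeatures expects a log-scale matrix")
  x <- entityValues(matrix)
  classes <- as.character(entityClasses(matrix))

  if (comparison == "pairwise") {
    if (is.null(groups) || length(groups) != 2L)
      stop("pairwise comparison needs exactly two group labels")
    sel <- classes %in% groups
    xs <- x[sel, , drop = FALSE]; cls <- classes[sel]
    if (any(table(factor(cls, levels = groups)) < 2L))
      stop("each compared group needs at least two entities")
    g1 <- cls == groups[1]
    pv <- apply(xs, 2, function(v) mannWhitney(v[g1], v[!g1])$p)
    dir <- sign(colMeans(xs[!g1, , drop = FALSE]) - colMeans(xs[g1, , drop = FALSE]))
    desc <- paste(groups[2], "vs", groups[1])
    if (is.null(model)) {
      if (is.null(ncomp)) ncomp <- 1L
      model <- fitPlsda(xs, cls, ncomp = ncomp)
    }
  } else {
    if (any(table(classes) < 2L)) stop("each class needs at least two entities")
    pv <- apply(x, 2, function(v) anovaOneway(split(v, classes))$p)
    grandMeans <- colMeans(x)
    toxMeans <- colMeans(x[classes != "control", , drop = FALSE])
    ctlMeans <- if (any(classes == "control"))
      colMeans(x[classes == "control", , drop = FALSE]) else grandMeans
    dir <- sign(toxMeans - ctlMeans)
    desc <- paste(sort(unique(classes)), collapse = " | ")
    if (is.null(model)) {
      if (is.null(ncomp)) ncomp <- min(3L, length(unique(classes)) - 1L)
      model <- fitPlsda(x, classes, ncomp = ncomp)
    }
  }
  q <- bhFdr(pv)
  v <- vip(model)
  vAll <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  vAll[names(v)] <- v
  out <- data.frame(metabolite = colnames(x), comparison = desc,
                    p = unname(pv), q = unname(q), vip = unname(vAll),
                    direction = unname(dir),
                    stringsAsFactors = FALSE)
  out$flagged <- out$q < qThreshold | (!is.na(out$vip) & out$vip > vipThreshold)
  attr(out, "thresholds") <- c(q = qThreshold, vip = vipThreshold)
  out
}
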