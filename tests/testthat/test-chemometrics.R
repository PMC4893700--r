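test_that("NIPALS PCA matches the SVD on random matrices", {
  set.seed(101)
  dims <- list(c(5, 4), c(8, 5), c(10, 6), c(12, 8))
  for (d in dims) {
    x <- matrix(rnorm(d[1] * d[2]), d[1], d[2])
    a <- min(d) - 1L
    fit <- fitPca(x, ncomp = a, scale. = FALSE)
    sv <- svd(scale(x, scale = FALSE))
    for (k in seq_len(a)) {
      s <- sign(sum(fit@loadings[, k] * sv$v[, k]))
      expect_lt(max(abs(fit@loadings[, k] - s * sv$v[, k])), 1e-8)
      expect_lt(max(abs(fit@scores[, k] - s * sv$u[, k] * sv$d[k])), 1e-8)
    }
    expect_lt(max(abs(fit@varExplained - sv$d[1:a]^2 / sum(sv$d^2))), 1e-10)
  }
})

test_that("PCA handles rank-1 structure and duplicated rows", {
  u <- 1:6; v <- c(2, -1, 3)
  x <- outer(u, v) + 5
  fit <- fitPca(x, ncomp = 2, scale. = FALSE)
  expect_equal(fit@varExplained[1], 1, tolerance = 1e-12)
  set.seed(3)
  y <- matrix(rnorm(20), 5, 4)
  y2 <- y[c(1:5, 3), ]
  f2 <- fitPca(y2, ncomp = 2, scale. = FALSE)
  expect_equal(f2@scores[3, ], f2@scores[6, ], tolerance = 1e-10)
  expect_error(fitPca(matrix(1, 4, 3), 1), "constant|degenerate")
})

test_that("a perfect predictor column yields a one-component perfect fit", {
  set.seed(7)
  cls <- rep(c("a", "b"), each = 6)
  dummy <- ifelse(cls == "b", 0.5, -0.5)   # centered dummy of y
  x <- matrix(rnorm(60), 12, 5)
  x <- x - outer(dummy, dummy) %*% x / sum(dummy^2)  # noise _|_ y
  x[, 3] <- dummy
  m <- fitPlsda(x, cls, ncomp = 1, scale = FALSE)
  expect_equal(r2Y(m)[1], 1, tolerance = 1e-8)
  pr <- predict(m, x)
  expect_equal(pr$class, cls)
})

test_that("the first PLS weight tracks the dominant singular vector of X'Y", {
  set.seed(11)
  for (rep in 1:5) {
    td <- toyClassData(seed = 100 + rep, n = 14, p = 7, shift = 1.5)
    xs <- scale(td$x)
    Y <- scale(stats::model.matrix(~ 0 + factor(td$classes)), scale = FALSE)
    w1 <- fitPlsda(td$x, td$classes, ncomp = 1)@weights[, 1]
    v1 <- svd(crossprod(xs, Y))$u[, 1]
    s <- sign(sum(w1 * v1))
    expect_lt(max(abs(w1 - s * v1)), 1e-6)
  }
})

test_that("two-class one-component PLS-DA aligns with the class-mean difference", {
  td <- toyClassData(seed = 21, n = 12, p = 5, shift = 2)
  xs <- scale(td$x)
  delta <- colMeans(xs[td$classes == "b", ]) - colMeans(xs[td$classes == "a", ])
  w1 <- fitPlsda(td$x, td$classes, ncomp = 1)@weights[, 1]
  s <- sign(sum(w1 * delta))
  expect_lt(max(abs(w1 - s * delta / sqrt(sum(delta^2)))), 1e-8)
})

test_that("fitted models satisfy the PLS algebra", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(10:16, 1); p <- sample(6:12, 1)
    x <- matrix(rnorm(n * p), n, p)
    cls <- sample(rep(c("a", "b", "c"), length.out = n))
    a <- 3L
    m <- fitPlsda(x, cls, ncomp = a)
    TT <- crossprod(m@scores)
    expect_lt(max(abs(TT - diag(diag(TT), a))), 1e-8 * max(diag(TT)))
    expect_lt(max(abs(colSums(m@weights^2) - 1)), 1e-10)
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)
    # R2Y non-decreasing in the number of components
    r <- r2Y(m)
    expect_true(all(diff(r) >= -1e-12))
    rLess <- r2Y(fitPlsda(x, cls, ncomp = 2))
    expect_equal(rLess, r[1:2], tolerance = 1e-8)
  }
})

test_that("VIP reflects symmetry and single-feature degeneracy", {
  td <- toyClassData(seed = 5, n = 12, p = 4, shift = 2)
  x <- cbind(td$x, dup = td$x[, 1])
  m <- fitPlsda(x, td$classes, ncomp = 2)
  v <- vip(m)
  expect_equal(unname(v["f1"]), unname(v["dup"]), tolerance = 1e-8)
  m1 <- fitPlsda(td$x[, 1, drop = FALSE], td$classes, ncomp = 1)
  expect_equal(unname(vip(m1)), 1, tolerance = 1e-12)
})

test_that("Hotelling limits match the F quantile and cover Gaussian scores", {
  expect_equal(hotellingLimit(30, 2, 0.05),
               2 * 29 / 28 * qf(0.95, 2, 28), tolerance = 1e-12)
  expect_equal(round(hotellingLimit(30, 2, 0.05), 2), 6.92)
  expect_error(hotellingLimit(3, 3), "n > ncomp")
  # larger confidence, larger region
  expect_gt(hotellingLimit(30, 2, 0.01), hotellingLimit(30, 2, 0.10))
  # the origin is always inside
  expect_lt(0, hotellingLimit(10, 2, 0.05))
  # empirical coverage on Gaussian scores
  set.seed(61)
  n <- 500
  sc <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 0.5))
  d2 <- sc[, 1]^2 / var(sc[, 1]) + sc[, 2]^2 / var(sc[, 2])
  inside <- mean(d2 <= hotellingLimit(n, 2, 0.05))
  band <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_gt(inside, 0.95 - band)
  expect_lt(inside, 0.95 + band)
})

test_that("prediction reproduces training and grades projections", {
  td <- toyClassData(seed = 51, n = 16, p = 6, shift = 3)
  m <- fitPlsda(td$x, td$classes, ncomp = 2)
  pr <- predict(m, td$x)
  expect_equal(pr$scores, m@scores, tolerance = 1e-10)
  expect_equal(pr$class, td$classes)
  expect_true(all(pr$grade %in% c("high", "medium")))
  # a far-away noise row is graded low
  far <- matrix(20, 1, 6, dimnames = list("noise", colnames(td$x)))
  expect_equal(predict(m, far)$grade, "low")
  expect_error(predict(m, td$x[, -1]), "lacks")
})

test_that("AUROC follows the rank form, pairwise averaging and null symmetry", {
  expect_equal(auroc(c(5, 4, 3, 1), rep(c("pos", "neg"), each = 2), "pos"), 1)
  expect_equal(auroc(c(0.8, 0.2, 0.5, 0.1),
                     c("pos", "pos", "neg", "neg"), "pos"), 0.75)
  # ties count one half
  expect_equal(auroc(c(1, 1), c("a", "b"), "b"), 0.5)
  set.seed(71)
  sc <- rnorm(2000); lab <- sample(rep(c("x", "y"), 1000))
  expect_lt(abs(auroc(sc, lab, "y") - 0.5), 0.05)
  # multiclass: unweighted mean of the three pairwise AUCs
  yhat <- rbind(c(0.9, 0.1, 0.0), c(0.6, 0.3, 0.1),
                c(0.2, 0.7, 0.1), c(0.3, 0.5, 0.2),
                c(0.1, 0.3, 0.6), c(0.2, 0.2, 0.6))
  colnames(yhat) <- c("a", "b", "c")
  lab3 <- rep(c("a", "b", "c"), each = 2)
  manual <- mean(c(
    auroc(yhat[1:4, "b"] - yhat[1:4, "a"], lab3[1:4], "b"),
    auroc(yhat[c(1, 2, 5, 6), "c"] - yhat[c(1, 2, 5, 6), "a"], lab3[c(1, 2, 5, 6)], "c"),
    auroc(yhat[3:6, "c"] - yhat[3:6, "b"], lab3[3:6], "c")))
  expect_equal(multiclassAuroc(yhat, lab3), manual, tolerance = 1e-12)
})

test_that("cross-validation partitions entities and scores honestly", {
  set.seed(81)
  cls <- rep(c("a", "b"), each = 10)
  x <- matrix(rnorm(20 * 6, sd = 0.3), 20, 6,
              dimnames = list(paste0("e", 1:20), paste0("f", 1:6)))
  x[cls == "b", 1] <- x[cls == "b", 1] + 4   # clean separation
  x[cls == "b", 2] <- x[cls == "b", 2] - 4
  td <- list(x = x, classes = cls)
  cv <- crossValidate(td$x, td$classes, ncomp = 2, nFolds = 5,
                      nRepeats = 3, seed = 9)
  for (f in cv@folds) {
    expect_equal(sort(unique(f)), 1:5)
    expect_equal(length(f), 20L)
    # stratification: each fold holds two entities per class
    expect_true(all(table(f, td$classes) == 2))
  }
  expect_equal(mean(cv@misclassification), 0)
  expect_equal(mean(cv@auroc), 1)
  expect_true(all(cv@q2 <= 1))
  # label scrambling destroys predictive power (Q2 <= 0 in most runs)
  set.seed(91)
  q2 <- vapply(1:10, function(i) {
    mean(crossValidate(td$x, sample(td$classes), ncomp = 2,
                       nRepeats = 1)@q2)
  }, numeric(1))
  expect_gte(mean(q2 <= 0), 0.8)
  expect_error(crossValidate(td$x, td$classes, nFolds = 1), "nFolds")
})
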