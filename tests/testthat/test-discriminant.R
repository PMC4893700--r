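test_that("Mann-Whitney matches hand and brute-force results", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)            # 2/20 under full enumeration
  expect_equal(mannWhitney(c(1, 1), c(1, 1))$p, 1)
  r2 <- mannWhitney(c(10, 12), c(11))
  expect_equal(r2$p, bruteMannWhitneyP(c(10, 12), c(11)))
})

test_that("exact Mann-Whitney equals enumeration for all small tie-free samples", {
  set.seed(17)
  for (n1 in 1:5) for (n2 in 1:5) {
    for (rep in 1:3) {
      x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
      expect_equal(mannWhitney(x, y)$p, bruteMannWhitneyP(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("one-way ANOVA reproduces the classical F decomposition", {
  r <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r2 <- anovaOneway(list(c(1, 2), c(3, 4)))
  expect_equal(r2$F, 8)             # SSB = 4, SSW = 1 on (1, 2) df
  expect_equal(r2$dfBetween, 1L)
  expect_equal(r2$dfWithin, 2L)
  expect_equal(r2$p, pf(8, 1, 2, lower.tail = FALSE))
  # agreement with the stats machinery on a general case
  g <- list(rnorm(5), rnorm(6, 1), rnorm(4, 2))
  ours <- anovaOneway(g)
  ref <- stats::oneway.test(y ~ f,
                            data.frame(y = unlist(g),
                                       f = rep(letters[1:3], lengths(g))),
                            var.equal = TRUE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # shift invariance
  shifted <- lapply(g, `+`, 100)
  expect_equal(anovaOneway(shifted)$F, ours$F, tolerance = 1e-9)
  # degenerate inputs
  expect_warning(z <- anovaOneway(list(c(1, 1), c(2, 2))), "zero within-group")
  expect_equal(z$p, 0)
  expect_error(anovaOneway(list(c(1, 1), c(1, 1))), "identical")
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(c(0.005, 0.5)), c(0.01, 0.5))
  # monotone in p and order-invariant
  set.seed(23)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  o <- sample(50)
  expect_equal(bhFdr(p[o]), q[o])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("discriminant flagging applies the dual q/VIP criterion", {
  em <- benchmarkMatrix(301, catalog = smallMarkerCatalog(),
                        signatures = data.frame(
                          metabolite = "M1", class = "oxidative_stress",
                          lfc = 2.5, dose_dependent = FALSE))
  res <- discriminantFeatures(em, "pairwise",
                              groups = c("control", "oxidative_stress"))
  expect_true(all(res$q >= res$p))
  expect_equal(res$flagged, res$q < 0.05 | (!is.na(res$vip) & res$vip > 1.2))
  m1 <- res[res$metabolite == "M1", ]
  expect_true(m1$flagged)
  expect_gt(m1$vip, 1.2)           # the VIP arm of the OR rule
  expect_equal(m1$p, 2 / choose(12, 6))  # smallest attainable exact p, 6 vs 6
  expect_gt(m1$direction, 0)
  expect_equal(unname(attr(res, "thresholds")), c(0.05, 1.2))
  # four-group comparison uses ANOVA and the multiclass model
  res4 <- discriminantFeatures(em, "four_group")
  expect_true(res4[res4$metabolite == "M1", "flagged"])
  expect_error(discriminantFeatures(em, "pairwise", groups = "control"),
               "two group")
})

test_that("a strongly planted marker is flagged across repeated simulations", {
  hits <- vapply(1:20, function(r) {
    em <- benchmarkMatrix(400 + r, catalog = smallMarkerCatalog(),
                          signatures = data.frame(
                            metabolite = "M1", class = "steatosis",
                            lfc = 2, dose_dependent = FALSE),
                          nBackground = 0)
    res <- discriminantFeatures(em, "pairwise",
                                groups = c("control", "steatosis"))
    res[res$metabolite == "M1", "flagged"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
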