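# Hand-built two-feature tables keep the arithmetic transparent.
makeTable <- function(x, roles, protein = NULL, isResp = NULL,
                      entity = NULL, class = NULL, state = "raw") {
  n <- ncol(x)
  sd <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    entity_id = if (is.null(entity)) paste0("e", seq_len(n)) else entity,
    compound = "cmp", concentration_uM = 1,
    class = if (is.null(class)) "control" else class,
    replicate = 1L, role = roles, injection_order = seq_len(n),
    protein_mg = if (is.null(protein)) rep(1, n) else protein,
    is_response = if (is.null(isResp)) rep(1, n) else isResp)
  fd <- data.frame(feature_id = paste0("f", seq_len(nrow(x))), block = 1L,
                   metabolite = paste0("met", seq_len(nrow(x))),
                   monoisotopic_mass = 100 + seq_len(nrow(x)),
                   is_channel = FALSE)
  FeatureTable(x, sd, fd, state = state)
}

test_that("qcMonitor computes per-channel CV over QC injections", {
  x <- rbind(c(100, 100, 100, 50), c(100, 110, 90, 50))
  ft <- makeTable(x, roles = c("qc", "qc", "qc", "study"))
  rep <- qcMonitor(ft, cvThreshold = 0.05)
  expect_equal(rep$cv[1], 0)
  expect_true(rep$pass[1])
  expect_equal(rep$cv[2], sd(c(100, 110, 90)) / 100)
  # the two-point example: sd/mean of (100, 110) = 6.73%
  ft2 <- makeTable(rbind(c(100, 110, 1)), roles = c("qc", "qc", "study"))
  rep2 <- qcMonitor(ft2, cvThreshold = 0.1)
  expect_equal(rep2$cv, sd(c(100, 110)) / 105, tolerance = 1e-12)
  expect_equal(round(100 * rep2$cv, 2), 6.73)
  expect_true(rep2$pass)
  expect_error(qcMonitor(makeTable(rbind(c(1, 2)), roles = c("study", "study"))),
               "QC")
})

test_that("blankFilter applies the study/blank mean ratio rule", {
  # f1: zero in blanks -> kept; f2: study 30 vs blank 20 -> removed at ratio 3
  x <- rbind(c(0, 0, 30, 30), c(20, 20, 30, 30))
  ft <- makeTable(x, roles = c("blank", "blank", "study", "study"))
  out <- blankFilter(ft, minRatio = 3)
  expect_equal(rownames(out), "f1")
  expect_equal(S4Vectors::metadata(out)$blank_removed, "f2")
  expect_equal(tableState(out), "blank_filtered")
  expect_error(blankFilter(out), "raw")         # state machine
  ft2 <- makeTable(rbind(c(1, 2)), roles = c("study", "study"))
  expect_warning(out2 <- blankFilter(ft2), "no blank")
  expect_equal(nrow(out2), 1L)
})

test_that("normalize divides by IS response and protein, once", {
  x <- rbind(c(100, 100))
  ft <- makeTable(x, roles = c("study", "study"),
                  protein = c(0.5, 1), isResp = c(2, 1))
  out <- normalize(ft)
  expect_equal(unname(intensities(out)[1, ]), c(100 / (2 * 0.5), 100))
  expect_equal(tableState(out), "normalized")
  expect_error(normalize(out), "already")
  # identity when IS and protein are 1
  ft1 <- makeTable(x, roles = c("study", "study"))
  expect_equal(intensities(normalize(ft1)), intensities(ft1))
  # IS channel becomes exactly constant
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), smallMarkerCatalog(),
                               signatures = NULL, seed = 2)
  nt <- normalize(sim$tables[[1]])
  isRow <- intensities(nt)[rowData(nt)$is_channel, ]
  expect_equal(sd(isRow), 0)
  # bad sample named in the error
  ftBad <- makeTable(x, roles = c("study", "qc"), isResp = c(1, 0))
  expect_error(normalize(ftBad), "s2")
})

test_that("matchMass honours the ppm window", {
  ref <- data.frame(metabolite = c("A", "B"),
                    monoisotopic_mass = c(308.0911, 500.1))
  hit <- matchMass(308.0911, ref)
  expect_equal(hit$metabolite, "A")
  expect_equal(hit$ppm, 0)
  # 308.0916 vs 308.0911 is ~1.6 ppm, inside the 10 ppm window
  hit2 <- matchMass(308.0916, ref, tolPpm = 10)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$ppm, abs(308.0916 - 308.0911) / 308.0911 * 1e6,
               tolerance = 1e-9)
  expect_lt(hit2$ppm, 10)
  # 11 ppm away: no match at 10 ppm
  expect_equal(nrow(matchMass(308.0911 * (1 + 11e-6), ref, tolPpm = 10)), 0L)
  expect_error(matchMass(100, ref[0, ]), "empty")
})

test_that("fuseBlocks joins on sample id and preserves width", {
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), featureCatalog(),
                               signatures = NULL, seed = 4)
  tabs <- lapply(sim$tables, function(t) normalize(blankFilter(t)))
  fused <- fuseBlocks(tabs)
  expect_equal(nrow(fused), 272L)  # 120 + 60 + 50 + 42 after blank filtering
  # single block: identity on the intensity matrix
  one <- fuseBlocks(tabs[1])
  expect_equal(unname(intensities(one)),
               unname(intensities(tabs[[1]])[!rowData(tabs[[1]])$is_channel, ]))
  # shuffling the sample order of one block does not change the result
  shuf <- tabs
  shuf[[2]] <- shuf[[2]][, sample(ncol(shuf[[2]]))]
  expect_equal(intensities(fuseBlocks(shuf)), intensities(fused))
  # missing sample is an error naming the discrepancy
  broken <- tabs
  broken[[3]] <- broken[[3]][, -1]
  expect_error(fuseBlocks(broken), "differ")
})

test_that("averageReplicates yields one mean row per entity", {
  x <- rbind(c(10, 20, 30, 5, 7))
  ft <- makeTable(x, roles = rep("study", 5),
                  entity = c("e1", "e1", "e1", "e2", "e2"),
                  state = "normalized")
  em <- averageReplicates(ft)
  expect_equal(unname(entityValues(em)[, 1]), c(20, 6))
  expect_equal(rownames(entityValues(em)), c("e1", "e2"))
  # identical replicates reproduce the replicate value
  x2 <- rbind(c(4, 4, 4))
  ft2 <- makeTable(x2, roles = rep("study", 3), entity = rep("e1", 3),
                   state = "normalized")
  expect_equal(unname(entityValues(averageReplicates(ft2))[1, 1]), 4)
  # default design: 30 entity rows
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), smallMarkerCatalog(),
                               signatures = NULL, seed = 6)
  em30 <- preprocessTables(sim$tables)
  expect_equal(nrow(entityValues(em30)), 30L)
})

test_that("transformScale centers, scales, stores and replays parameters", {
  set.seed(9)
  vals <- matrix(10^rnorm(60, 3, 0.3), 10, 6,
                 dimnames = list(paste0("e", 1:10), paste0("m", 1:6)))
  em <- EntityMatrix(vals, data.frame(class = rep("control", 10)))
  sc <- transformScale(em)
  expect_lt(max(abs(colMeans(entityValues(sc)))), 1e-12)
  expect_lt(max(abs(apply(entityValues(sc), 2, sd) - 1)), 1e-12)
  # log10 of 100 is 2 before centering
  expect_equal(logTransform(EntityMatrix(matrix(100, 1, 1), data.frame(x = 1)))@values[1, 1], 2)
  # projecting the training matrix through its own params reproduces it
  again <- transformScale(em, params = scalingParams(sc))
  expect_equal(entityValues(again), entityValues(sc), tolerance = 1e-12)
  # scaling round trip
  back <- unscale(sc)
  expect_equal(entityValues(back), vals, tolerance = 1e-10)
  # zero-variance column dropped with a warning
  vals2 <- cbind(vals, m7 = 5)
  em2 <- EntityMatrix(vals2, data.frame(class = rep("control", 10)))
  expect_warning(sc2 <- transformScale(em2), "zero-variance")
  expect_false("m7" %in% colnames(entityValues(sc2)))
  expect_true("m7" %in% scalingParams(sc2)$dropped)
})
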