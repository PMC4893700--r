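test_that("default study design reproduces the screen layout", {
  d <- hepatotoxStudyDesign()
  ent <- designEntities(d)
  expect_equal(nrow(ent), 30L)
  expect_equal(as.vector(table(ent$class)[c("control", "oxidative_stress",
                                            "phospholipidosis", "steatosis")]),
               c(6L, 6L, 9L, 9L))
  expect_equal(ent$concentration_uM[ent$abbreviation == "Tet"],
               c(50, 100, 200, 400))
  noVeh <- designEntities(hepatotoxStudyDesign(includeVehicleControls = FALSE))
  expect_equal(nrow(noVeh), 28L)
  expect_false(any(c("C", "DMSO") %in% noVeh$entity_id))
})

test_that("feature catalog partitions blocks and keeps mandatory markers", {
  cat272 <- featureCatalog()
  expect_equal(nrow(cat272), 272L)
  expect_equal(as.vector(table(cat272$block)), c(120L, 60L, 50L, 42L))
  expect_true(all(c("GSH", "GSSG", "CSSG", "Ophthalmic acid", "Glutamate",
                    "Glutamine") %in% cat272$metabolite))
  expect_false(anyDuplicated(cat272$feature_id) > 0)
  # too few features for the mandatory markers
  expect_error(featureCatalog(20, c(5, 5, 5, 5)), "mandatory")
  expect_error(featureCatalog(100, c(50, 30, 10, 5)), "sum")
  # a catalog that is exactly a custom marker set
  mk <- data.frame(metabolite = paste0("X", 1:8), category = "m",
                   block = rep(1:4, each = 2), monoisotopic_mass = 100 + 1:8)
  cat8 <- featureCatalog(8, c(2, 2, 2, 2), markers = mk)
  expect_setequal(cat8$metabolite, mk$metabolite)
})

test_that("default signatures encode the mechanism fingerprints", {
  cat272 <- featureCatalog()
  sig <- defaultSignatures(cat272)
  gsh <- sig[sig$metabolite == "GSH", ]
  expect_setequal(gsh$class, c("oxidative_stress", "phospholipidosis", "steatosis"))
  expect_true(all(gsh$lfc < 0))  # GSH depleted in every mechanism
  lpl <- sig[sig$class == "phospholipidosis" &
             sig$metabolite %in% cat272$metabolite[cat272$category == "LysoPL"], ]
  expect_true(all(lpl$lfc < 0))
  tg <- sig[sig$class == "steatosis" &
            sig$metabolite %in% cat272$metabolite[cat272$category == "TG"], ]
  expect_true(all(tg$lfc > 0))
  expect_false("control" %in% sig$class)
})

test_that("simulation is deterministic and follows the injection layout", {
  d <- hepatotoxStudyDesign()
  cat40 <- smallMarkerCatalog()
  s1 <- simulateFeatureTables(d, cat40, signatures = NULL, seed = 7)
  s2 <- simulateFeatureTables(d, cat40, signatures = NULL, seed = 7)
  expect_identical(lapply(s1$tables, intensities), lapply(s2$tables, intensities))
  s3 <- simulateFeatureTables(d, cat40, signatures = NULL, seed = 8)
  expect_false(identical(intensities(s1$tables[[1]]), intensities(s3$tables[[1]])))

  cd <- as.data.frame(SummarizedExperiment::colData(s1$tables[[1]]))
  expect_equal(sum(cd$role == "study"), 90L)   # 30 entities x 3 replicates
  expect_equal(sum(cd$role == "blank"), 3L)
  # at most 10 study injections between consecutive QCs
  ord <- cd[order(cd$injection_order), ]
  qcPos <- which(ord$role == "qc")
  runs <- diff(c(0, qcPos)) - 1
  expect_true(all(runs[-1] <= 10))
  expect_true(any(rowData(s1$tables[[1]])$is_channel))
})

test_that("planted effects are recovered by direct averaging", {
  # two compounds, one control and one oxidative stress, many replicates:
  # the empirical OS/control log2 ratio of GSH recovers the planted 1.5
  d <- hepatotoxStudyDesign(nReplicates = 100, includeVehicleControls = FALSE)
  d$compounds <- list(
    list(name = "Ctl", abbreviation = "Ctl", mechanism_class = "control",
         concentrations = 100, ic10 = NA_real_, cmax = NA_real_),
    list(name = "Ox", abbreviation = "Ox", mechanism_class = "oxidative_stress",
         concentrations = 100, ic10 = NA_real_, cmax = NA_real_))
  cat40 <- smallMarkerCatalog()
  sig <- data.frame(metabolite = "M1", class = "oxidative_stress",
                    lfc = 1.5, dose_dependent = FALSE)
  sim <- simulateFeatureTables(d, cat40, sig,
                               noise = noiseDefaults(entitySd = 0),
                               seed = 11, nBackground = 0)
  ft <- normalize(blankFilter(sim$tables[[1]]))
  cd <- SummarizedExperiment::colData(ft)
  x <- intensities(ft)["B1_F001", ]  # M1 sits first in block 1
  lr <- log2(x[cd$role == "study" & cd$class == "oxidative_stress"]) -
    mean(log2(x[cd$role == "study" & cd$class == "control"]))
  se <- sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr) - 1.5), 3 * se + 1e-8)
})

test_that("blank channel separates background from biological features", {
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), smallMarkerCatalog(),
                               signatures = NULL, seed = 3, nBackground = 4)
  ft <- sim$tables[[1]]
  cd <- SummarizedExperiment::colData(ft)
  x <- intensities(ft)
  bg <- grepl("_BG", rownames(x))
  bio <- !bg & !rowData(ft)$is_channel
  expect_true(all(x[bio, cd$role == "blank"] == 0))
  # background ions: similar mean intensity in blanks and study samples
  rat <- rowMeans(x[bg, cd$role == "study", drop = FALSE]) /
    rowMeans(x[bg, cd$role == "blank", drop = FALSE])
  expect_true(all(rat > 1 / 3 & rat < 3))
  # and the blank filter removes exactly the background ions at ratio 3
  filt <- blankFilter(ft, minRatio = 3)
  expect_setequal(S4Vectors::metadata(filt)$blank_removed, rownames(x)[bg])
})

test_that("simulation input validation catches bad signatures and noise", {
  d <- hepatotoxStudyDesign()
  cat40 <- smallMarkerCatalog()
  expect_error(simulateFeatureTables(d, cat40,
    data.frame(metabolite = "nope", class = "steatosis", lfc = 1,
               dose_dependent = FALSE), seed = 1), "unknown")
  expect_error(simulateFeatureTables(d, cat40,
    data.frame(metabolite = "M1", class = "control", lfc = 1,
               dose_dependent = FALSE), seed = 1), "control")
  expect_error(noiseDefaults(replicateCv = 0), "non-positive")
  expect_error(simulateFeatureTables(d, cat40, NULL), "seed")
})

test_that("CSV interchange round-trips the simulated tables", {
  dir <- withr::local_tempdir()
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), smallMarkerCatalog(),
                               signatures = NULL, seed = 5, nBackground = 2)
  writeFeatureTables(sim, dir)
  back <- readFeatureTables(dir)
  expect_equal(length(back$tables), 4L)
  expect_equal(unname(intensities(back$tables[["B1"]])),
               unname(intensities(sim$tables[["B1"]])), tolerance = 1e-12)
  expect_equal(nrow(back$truth), nrow(sim$truth))
})
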