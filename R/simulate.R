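## Synthetic LC-MS feature-table generator. Simulation starts at the
## integrated feature-intensity level: log-normal baselines, class- and
## dose-dependent multiplicative effects with per-entity heterogeneity,
## multiplicative replicate noise, a per-sample instrument response (IS
## channel) optionally drifting with injection order, per-sample protein
## amounts, pooled-QC injections and blank (no-cell) injections.

#' Default noise parameters of the simulator
#'
#' @param baselineLog10Mean,baselineLog10Sd log10-normal baseline abundance
#'   distribution (typical LC-MS dynamic range).
#' @param replicateCv coefficient of variation of multiplicative
#'   replicate-level noise.
#' @param entitySd additive per-entity heterogeneity (log2) of planted
#'   effects: compounds of the same mechanism respond with different
#'   strength.
#' @param isCv CV of the per-sample instrument response (IS channel).
#' @param proteinCv CV of per-sample protein amounts around 1 mg.
#' @param qcCv CV of pooled-QC injections around the study-sample pool.
#' @param drift linear multiplicative instrument drift per injection
#'   (0 = stable run).
#' @return named list of noise parameters.
#' @export
noiseDefaults <- function(baselineLog10Mean = 4, baselineLog10Sd = 0.5,
                          replicateCv = 0.15, entitySd = 0.2, isCv = 0.05,
                          proteinCv = 0.08, qcCv = 0.05, drift = 0) {
  n <- list(baselineLog10Mean = baselineLog10Mean,
            baselineLog10Sd = baselineLog10Sd, replicateCv = replicateCv,
            entitySd = entitySd, isCv = isCv, proteinCv = proteinCv,
            qcCv = qcCv, drift = drift)
  pos <- c("baselineLog10Sd", "replicateCv", "isCv", "proteinCv", "qcCv")
  bad <- pos[vapply(pos, function(k) !is.finite(n[[k]]) || n[[k]] <= 0, logical(1))]
  if (length(bad))
    stop("non-positive noise scale: ", paste(bad, collapse = ", "))
  if (!is.finite(n$entitySd) || n$entitySd < 0) stop("entitySd must be >= 0")
  n
}

.sdlog <- function(cv) sqrt(log(1 + cv^2))

## effect (log2) of entity i on feature j: planted lfc, dose-scaled when
## dose-dependent, plus per-entity heterogeneity on affected features only
.effectMatrix <- function(ent, features, signatures, entitySd) {
  delta <- matrix(0, nrow(ent), length(features$metabolite),
                  dimnames = list(ent$entity_id, features$feature_id))
  if (is.null(signatures) || !nrow(signatures)) return(delta)
  unknown <- setdiff(signatures$metabolite, features$metabolite)
  if (length(unknown))
    stop("signature refers to unknown metabolites: ",
         paste(head(unknown, 5), collapse = ", "))
  if (any(signatures$class == "control"))
    stop("the control class cannot carry a signature")
  met2col <- match(signatures$metabolite, features$metabolite)
  for (k in seq_len(nrow(signatures))) {
    rows <- which(ent$class == signatures$class[k])
    if (!length(rows)) next
    eff <- signatures$lfc[k] *
      (if (isTRUE(signatures$dose_dependent[k])) ent$dose_frac[rows] else 1)
    if (entitySd > 0) eff <- eff + rnorm(length(rows), 0, entitySd)
    delta[rows, met2col[k]] <- delta[rows, met2col[k]] + eff
  }
  delta
}

#' Simulate per-block LC-MS feature tables
#'
#' Generates one raw [FeatureTable-class] per analytical block under a
#' study design, a metabolite catalog and a list of planted mechanism
#' signatures, together with the ground truth needed to test every
#' downstream stage. The same seed always produces identical tables.
#'
#' Background (non-biological) ions can be added per block: they have the
#' same expected intensity in blanks and study samples, while biological
#' features have zero intensity in blanks.
#'
#' @param design a `StudyDesign` from [hepatotoxStudyDesign()].
#' @param catalog feature catalog from [featureCatalog()].
#' @param signatures data.frame of planted effects (see
#'   [defaultSignatures()]); `NULL` for a fully null dataset.
#' @param noise noise parameter list from [noiseDefaults()].
#' @param seed integer RNG seed (required).
#' @param nBackground number of background ions added per block.
#' @return list with elements `tables` (named list of raw FeatureTable,
#'   one per block), `truth` (per-feature ground-truth data.frame with
#'   per-class log2 fold changes, affected flags, background flag and
#'   category/set membership), `catalog`, `entities`.
#' @examples
#' sim <- simulateFeatureTables(hepatotoxStudyDesign(), featureCatalog(),
#'                              defaultSignatures(), seed = 1)
#' sim$tables[[1]]
#' @export
simulateFeatureTables <- function(design, catalog = featureCatalog(),
                                  signatures = defaultSignatures(catalog),
                                  noise = noiseDefaults(), seed,
                                  nBackground = 5L) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  noise <- do.call(noiseDefaults, noise[names(noise) %in% names(formals(noiseDefaults))])
  set.seed(as.integer(seed))
  ent <- designEntities(design)
  nEnt <- nrow(ent); nRep <- design$nReplicates
  study <- data.frame(
    sample_id = paste0(rep(ent$entity_id, each = nRep), "_r", seq_len(nRep)),
    entity_id = rep(ent$entity_id, each = nRep),
    compound = rep(ent$compound, each = nRep),
    concentration_uM = rep(ent$concentration_uM, each = nRep),
    class = rep(ent$class, each = nRep),
    replicate = rep(seq_len(nRep), nEnt),
    role = "study", stringsAsFactors = FALSE)
  nStudy <- nrow(study)
  runOrder <- sample.int(nStudy)                  # randomized injection order
  protein <- exp(rnorm(nStudy, 0, .sdlog(noise$proteinCv)))
  names(protein) <- study$sample_id

  ## append background ions to the catalog copy used internally
  bg <- NULL
  if (nBackground > 0) {
    bg <- do.call(rbind, lapply(1:4, function(b)
      data.frame(feature_id = sprintf("B%d_BG%02d", b, seq_len(nBackground)),
                 block = b,
                 metabolite = sprintf("Background ion B%d-%02d", b, seq_len(nBackground)),
                 category = "background",
                 monoisotopic_mass = round(80 + (seq_len(nBackground) * 91.3 + b * 7.1) %% 600, 4),
                 stringsAsFactors = FALSE)))
  }
  fullCat <- rbind(catalog, bg)
  fullCat$background <- fullCat$category == "background"
  delta <- .effectMatrix(ent, fullCat, signatures, noise$entitySd)

  blockNames <- paste0("B", 1:4)
  sdRep <- .sdlog(noise$replicateCv)
  tables <- setNames(vector("list", 4), blockNames)
  for (b in 1:4) {
    fb <- fullCat[fullCat$block == b, , drop = FALSE]
    nf <- nrow(fb)
    baseline <- 10^rnorm(nf, noise$baselineLog10Mean, noise$baselineLog10Sd)
    names(baseline) <- fb$feature_id
    db <- delta[, fb$feature_id, drop = FALSE]

    ## injection layout: blanks, then QC / study interleaved every qcInterval
    nQc <- floor(nStudy / design$qcInterval) + 1L
    studyOrdered <- study$sample_id[runOrder]
    seqIds <- character(0); seqRoles <- character(0)
    if (design$nBlanks > 0) {
      seqIds <- sprintf("blank_%02d", seq_len(design$nBlanks))
      seqRoles <- rep("blank", design$nBlanks)
    }
    qi <- 1L; done <- 0L
    seqIds <- c(seqIds, sprintf("qc_%02d", qi)); seqRoles <- c(seqRoles, "qc")
    while (done < nStudy) {
      take <- min(design$qcInterval, nStudy - done)
      seqIds <- c(seqIds, studyOrdered[done + seq_len(take)])
      seqRoles <- c(seqRoles, rep("study", take))
      done <- done + take
      if (qi < nQc) {
        qi <- qi + 1L
        seqIds <- c(seqIds, sprintf("qc_%02d", qi)); seqRoles <- c(seqRoles, "qc")
      }
    }
    nTot <- length(seqIds)
    inj <- seq_len(nTot)
    isResp <- exp(rnorm(nTot, 0, .sdlog(noise$isCv))) *
      (1 + noise$drift * (inj - 1))

    X <- matrix(0, nf, nTot, dimnames = list(fb$feature_id, seqIds))
    sIdx <- which(seqRoles == "study")
    entOfSample <- match(study$entity_id[match(seqIds[sIdx], study$sample_id)],
                         ent$entity_id)
    level <- t(2^db[entOfSample, , drop = FALSE]) * baseline   # nf x nStudy
    level[fb$background, ] <- baseline[fb$background]
    level <- level * exp(matrix(rnorm(nf * length(sIdx), 0, sdRep), nf))
    X[, sIdx] <- level
    bIdx <- which(seqRoles == "blank")
    if (length(bIdx)) {
      bl <- matrix(0, nf, length(bIdx))
      if (any(fb$background))
        bl[fb$background, ] <- baseline[fb$background] *
          exp(matrix(rnorm(sum(fb$background) * length(bIdx), 0, sdRep),
                     sum(fb$background)))
      X[, bIdx] <- bl
    }
    qIdx <- which(seqRoles == "qc")
    pool <- rowMeans(X[, sIdx, drop = FALSE])
    X[, qIdx] <- pool * exp(matrix(rnorm(nf * length(qIdx), 0, .sdlog(noise$qcCv)), nf))

    ## instrument scale: per-sample response and protein loading
    protCol <- rep(1, nTot)
    protCol[sIdx] <- protein[seqIds[sIdx]]
    X <- sweep(X, 2, isResp * protCol, `*`)
    isRow <- matrix(1e4 * isResp, 1, nTot,
                    dimnames = list(sprintf("B%d_IS", b), seqIds))
    X <- rbind(X, isRow)

    sampleData <- data.frame(
      sample_id = seqIds,
      entity_id = ifelse(seqRoles == "study",
                         study$entity_id[match(seqIds, study$sample_id)], NA),
      compound = ifelse(seqRoles == "study",
                        study$compound[match(seqIds, study$sample_id)], NA),
      concentration_uM = ifelse(seqRoles == "study",
                                study$concentration_uM[match(seqIds, study$sample_id)], NA),
      class = ifelse(seqRoles == "study",
                     study$class[match(seqIds, study$sample_id)], NA),
      replicate = ifelse(seqRoles == "study",
                         study$replicate[match(seqIds, study$sample_id)], NA),
      role = seqRoles, injection_order = inj,
      protein_mg = protCol, is_response = isResp,
      stringsAsFactors = FALSE)
    featureData <- rbind(
      data.frame(feature_id = fb$feature_id, block = b,
                 metabolite = fb$metabolite, category = fb$category,
                 monoisotopic_mass = fb$monoisotopic_mass,
                 is_channel = FALSE, stringsAsFactors = FALSE),
      data.frame(feature_id = sprintf("B%d_IS", b), block = b,
                 metabolite = sprintf("Internal standard (block %d)", b),
                 category = "is_channel", monoisotopic_mass = 170.1124,
                 is_channel = TRUE, stringsAsFactors = FALSE))
    tables[[b]] <- FeatureTable(X, sampleData, featureData, state = "raw")
  }

  classes <- setdiff(.MECHANISM_CLASSES, "control")
  truth <- fullCat
  for (cl in classes) {
    lfc <- numeric(nrow(fullCat))
    if (!is.null(signatures) && nrow(signatures)) {
      s <- signatures[signatures$class == cl, , drop = FALSE]
      lfc[match(s$metabolite, fullCat$metabolite)] <- s$lfc
    }
    truth[[paste0("lfc_", cl)]] <- lfc
    truth[[paste0("affected_", cl)]] <- lfc != 0
  }
  rownames(truth) <- truth$feature_id
  list(tables = tables, truth = truth, catalog = fullCat, entities = ent)
}

#' Write / read the simulator's CSV interchange files
#'
#' `writeFeatureTables` writes one per-block CSV (rows = samples, first
#' columns = sample metadata, then one column per feature), a
#' feature-metadata CSV and the truth CSV. `readFeatureTables`
#' reconstructs the list of raw [FeatureTable-class] objects.
#'
#' @param sim result of [simulateFeatureTables()].
#' @param dir output/input directory.
#' @return `writeFeatureTables`: invisibly, the written paths;
#'   `readFeatureTables`: list with elements `tables` and `truth`.
#' @export
writeFeatureTables <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sim$tables)) {
    ft <- sim$tables[[nm]]
    df <- cbind(as.data.frame(colData(ft)), t(intensities(ft)))
    p <- file.path(dir, paste0("features_", nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  fm <- do.call(rbind, lapply(sim$tables, function(ft) as.data.frame(rowData(ft))))
  write.csv(fm, file.path(dir, "feature_metadata.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(c(paths, file.path(dir, c("feature_metadata.csv", "truth.csv"))))
}

#' @rdname writeFeatureTables
#' @export
readFeatureTables <- function(dir) {
  fm <- read.csv(file.path(dir, "feature_metadata.csv"))
  files <- sort(list.files(dir, pattern = "^features_.*\\.csv$", full.names = TRUE))
  tables <- lapply(files, function(p) {
    df <- read.csv(p, check.names = FALSE)
    metaCols <- .REQUIRED_SAMPLE_COLS
    feats <- setdiff(colnames(df), metaCols)
    FeatureTable(t(as.matrix(df[, feats, drop = FALSE])),
                 df[, metaCols], fm[match(feats, fm$feature_id), ],
                 state = "raw")
  })
  names(tables) <- sub("^features_(.*)\\.csv$", "\\1", basename(files))
  truthPath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthPath)) read.csv(truthPath) else NULL
  list(tables = tables, truth = truth)
}
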