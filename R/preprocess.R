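## Preprocessing: QC monitoring, blank-based background filtering,
## IS/protein normalization, block fusion, replicate averaging and the
## log / autoscaling transform. The state slot of FeatureTable enforces
## the stage order (raw -> blank_filtered -> normalized).

#' Monitor instrument stability from pooled-QC injections
#'
#' Computes, per feature channel (internal standards included), the
#' coefficient of variation of the intensity across QC injections, and
#' flags channels whose CV exceeds the threshold.
#'
#' @param table a [FeatureTable-class] with at least two QC-role samples.
#' @param cvThreshold maximal acceptable CV (fraction, default 0.3).
#' @return data.frame with columns `channel`, `metabolite`, `is_channel`,
#'   `cv`, `pass`; the threshold is stored in attribute `cv_threshold`.
#' @export
qcMonitor <- function(table, cvThreshold = 0.3) {
  qc <- colData(table)$role == "qc"
  if (sum(qc) < 2L)
    stop("qcMonitor needs at least two QC injections; run unusable")
  x <- intensities(table)[, qc, drop = FALSE]
  m <- rowMeans(x)
  cv <- apply(x, 1, sd) / m
  cv[m == 0] <- NA_real_
  out <- data.frame(channel = rownames(x),
                    metabolite = rowData(table)$metabolite,
                    is_channel = rowData(table)$is_channel,
                    cv = cv, pass = !is.na(cv) & cv <= cvThreshold,
                    row.names = NULL)
  attr(out, "cv_threshold") <- cvThreshold
  out
}

#' Remove background ions using blank injections
#'
#' A feature is retained iff its mean intensity over study samples is at
#' least `minRatio` times its mean intensity over blank injections
#' (features absent from blanks are always retained). Internal-standard
#' channels are never removed. Without blanks the table passes through
#' unchanged with a warning.
#'
#' @param table a raw [FeatureTable-class].
#' @param minRatio minimal study/blank mean-intensity ratio (default 3).
#' @return a `blank_filtered` FeatureTable; removed feature ids are
#'   recorded in `metadata(x)$blank_removed`.
#' @export
blankFilter <- function(table, minRatio = 3) {
  stopifnot(minRatio > 0)
  if (tableState(table) != "raw")
    stop("blankFilter expects a raw table, got state ", tableState(table))
  role <- colData(table)$role
  if (!any(role == "blank")) {
    warning("no blank samples: blank filtering skipped")
    table@state <- "blank_filtered"
    return(table)
  }
  x <- intensities(table)
  studyMean <- rowMeans(x[, role == "study", drop = FALSE])
  blankMean <- rowMeans(x[, role == "blank", drop = FALSE])
  keep <- studyMean >= minRatio * blankMean | rowData(table)$is_channel
  removed <- rownames(x)[!keep]
  out <- table[keep, ]
  out@state <- "blank_filtered"
  metadata(out)$blank_removed <- removed
  validObject(out)
  out
}

#' Normalize intensities by internal-standard response and protein amount
#'
#' Each intensity is divided by the sample's block IS response and then by
#' the sample's protein amount; the IS channel itself becomes the constant
#' 1. Double normalization is forbidden by the state machine.
#'
#' @param object a raw or blank-filtered [FeatureTable-class].
#' @param ... unused.
#' @return a `normalized` FeatureTable.
#' @export
setMethod("normalize", "FeatureTable", function(object, ...) {
  if (tableState(object) == "normalized")
    stop("table is already normalized")
  cd <- colData(object)
  bad <- which(!is.finite(cd$is_response) | cd$is_response <= 0 |
               !is.finite(cd$protein_mg) | cd$protein_mg <= 0)
  if (length(bad))
    stop("non-positive IS response or protein amount for sample(s): ",
         paste(cd$sample_id[bad], collapse = ", "))
  x <- sweep(intensities(object), 2, cd$is_response * cd$protein_mg, `/`)
  isCh <- rowData(object)$is_channel
  if (any(isCh)) x[isCh, ] <- 1
  assay(object, "intensity") <- x
  object@state <- "normalized"
  object
})

#' Match an observed mass against a local reference table
#'
#' Returns the reference compounds whose relative mass deviation
#' |m_obs - m_ref| / m_ref x 1e6 is within `tolPpm`, sorted by ppm error.
#'
#' @param observedMass positive number (Da).
#' @param referenceMasses data.frame with columns `metabolite` (or
#'   `compound`) and `monoisotopic_mass` (or `mass`).
#' @param tolPpm mass tolerance in parts per million (default 10).
#' @return data.frame of candidate identities with their `ppm` error.
#' @export
matchMass <- function(observedMass, referenceMasses, tolPpm = 10) {
  stopifnot(is.numeric(observedMass), observedMass > 0, tolPpm > 0)
  ref <- as.data.frame(referenceMasses)
  if (!nrow(ref)) stop("empty reference mass table")
  massCol <- intersect(c("monoisotopic_mass", "mass"), colnames(ref))[1]
  nameCol <- intersect(c("metabolite", "compound"), colnames(ref))[1]
  if (is.na(massCol) || is.na(nameCol))
    stop("referenceMasses needs a metabolite/compound and a mass column")
  ppm <- abs(observedMass - ref[[massCol]]) / ref[[massCol]] * 1e6
  hit <- which(ppm <= tolPpm)
  out <- data.frame(metabolite = ref[[nameCol]][hit],
                    monoisotopic_mass = ref[[massCol]][hit],
                    ppm = ppm[hit])
  out[order(out$ppm), , drop = FALSE]
}

#' Fuse per-block feature tables into a single sample-level matrix
#'
#' Column-wise concatenation of the blocks keyed on `sample_id`, so the
#' sample order of the individual blocks is irrelevant. All tables must be
#' normalized and contain the same samples; internal-standard channels
#' (constant after normalization) are dropped. Feature provenance is
#' preserved in the fused feature metadata.
#'
#' @param tables list of normalized [FeatureTable-class] objects.
#' @return a fused, normalized [FeatureTable-class].
#' @export
fuseBlocks <- function(tables) {
  stopifnot(length(tables) >= 1L)
  states <- vapply(tables, tableState, character(1))
  if (any(states != "normalized"))
    stop("all tables must be normalized before fusion")
  ids <- lapply(tables, function(t) sort(colData(t)$sample_id))
  for (i in seq_along(tables)[-1]) {
    extra <- setdiff(ids[[i]], ids[[1]]); miss <- setdiff(ids[[1]], ids[[i]])
    if (length(extra) || length(miss))
      stop("sample sets differ between blocks: missing [",
           paste(head(miss, 5), collapse = ", "), "], extra [",
           paste(head(extra, 5), collapse = ", "), "]")
  }
  keyOrder <- colData(tables[[1]])$sample_id
  parts <- lapply(tables, function(t) {
    t <- t[!rowData(t)$is_channel, ]
    t[, match(keyOrder, colData(t)$sample_id)]
  })
  x <- do.call(rbind, lapply(parts, intensities))
  rd <- do.call(rbind, lapply(parts, function(t) as.data.frame(rowData(t))))
  cd <- as.data.frame(colData(parts[[1]]))
  cd$is_response <- 1  # block-specific responses already divided out
  FeatureTable(x, cd, rd, state = "normalized")
}

#' Average biological replicates into the entity matrix
#'
#' One row per drug-concentration entity: the arithmetic mean of its study
#' replicates. QC and blank rows are dropped.
#'
#' @param fused a fused, normalized [FeatureTable-class].
#' @return an [EntityMatrix-class] in linear intensity scale.
#' @export
averageReplicates <- function(fused) {
  cd <- colData(fused)
  keep <- cd$role == "study"
  if (!any(keep)) stop("no study samples to average")
  x <- intensities(fused)[, keep, drop = FALSE]
  ids <- cd$entity_id[keep]
  entities <- unique(ids)
  sums <- rowsum(t(x), group = ids, reorder = FALSE)
  vals <- sums / as.vector(table(ids)[rownames(sums)])
  vals <- vals[entities, , drop = FALSE]
  colnames(vals) <- rowData(fused)$metabolite
  meta <- as.data.frame(cd[keep, c("entity_id", "compound", "concentration_uM", "class")])
  meta <- meta[!duplicated(meta$entity_id), ]
  rownames(meta) <- meta$entity_id
  meta <- meta[entities, ]
  rownames(vals) <- entities
  EntityMatrix(vals, meta, transform = "linear")
}

.imputeHalfMin <- function(x) {
  drop <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    bad <- !is.finite(v) | v <= 0
    if (all(bad)) { drop[j] <- TRUE; next }
    if (any(bad)) x[bad, j] <- min(v[!bad]) / 2
  }
  list(x = x[, !drop, drop = FALSE], dropped = colnames(x)[drop])
}

#' Log-transform an entity matrix
#'
#' Missing/non-positive values are imputed as half the metabolite's
#' minimum positive value; metabolites with no positive value are dropped
#' with a warning.
#'
#' @param object a linear-scale [EntityMatrix-class].
#' @param logBase log base (default 10).
#' @return a log-scale EntityMatrix.
#' @export
logTransform <- function(object, logBase = 10) {
  stopifnot(is(object, "EntityMatrix"))
  if (object@transform != "linear")
    stop("logTransform expects a linear-scale matrix")
  imp <- .imputeHalfMin(object@values)
  if (length(imp$dropped))
    warning("dropped metabolites without positive values: ",
            paste(imp$dropped, collapse = ", "))
  object@values <- log(imp$x, base = logBase)
  object@logBase <- logBase
  object@dropped <- c(object@dropped, imp$dropped)
  object@transform <- "log"
  object
}

#' Log-transform, mean-center and unit-variance scale an entity matrix
#'
#' Fresh scaling (no `params`): log-transform if needed, then subtract the
#' column mean and divide by the column standard deviation, storing both;
#' zero-variance columns are dropped with a warning rather than producing
#' a division by zero. Projection mode (`params` given, e.g. from
#' [scalingParams()] of the training matrix): applies the stored transform
#' and never re-estimates.
#'
#' @param object an [EntityMatrix-class] (linear or log scale).
#' @param params optional stored scaling parameters.
#' @param logBase log base for a fresh transform (default 10).
#' @return a scaled EntityMatrix carrying its scaling parameters.
#' @export
transformScale <- function(object, params = NULL, logBase = 10) {
  stopifnot(is(object, "EntityMatrix"))
  if (object@transform == "scaled") stop("matrix is already scaled")
  if (!is.null(params)) {
    if (object@transform == "linear")
      object <- logTransform(object, logBase = params$logBase)
    x <- object@values[, setdiff(colnames(object@values), params$dropped), drop = FALSE]
    x <- x[, names(params$center), drop = FALSE]
    x <- sweep(sweep(x, 2, params$center, `-`), 2, params$scale, `/`)
    object@values <- x
    object@center <- params$center; object@scale <- params$scale
    object@dropped <- unique(c(object@dropped, params$dropped))
    object@transform <- "scaled"
    return(object)
  }
  if (object@transform == "linear") object <- logTransform(object, logBase)
  x <- object@values
  sds <- apply(x, 2, sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning("dropped zero-variance metabolites: ",
            paste(colnames(x)[zero], collapse = ", "))
    object@dropped <- c(object@dropped, colnames(x)[zero])
    x <- x[, !zero, drop = FALSE]; sds <- sds[!zero]
  }
  ctr <- colMeans(x)
  object@values <- sweep(sweep(x, 2, ctr, `-`), 2, sds, `/`)
  object@center <- ctr; object@scale <- sds
  object@transform <- "scaled"
  object
}

#' Undo the scaling and log transform of an entity matrix
#'
#' @param object a scaled [EntityMatrix-class].
#' @return the matrix back on the linear intensity scale (imputed values
#'   stay imputed; dropped columns stay dropped).
#' @export
unscale <- function(object) {
  stopifnot(is(object, "EntityMatrix"))
  if (object@transform != "scaled") stop("unscale expects a scaled matrix")
  x <- sweep(sweep(object@values, 2, object@scale, `*`), 2, object@center, `+`)
  object@values <- object@logBase^x
  object@center <- numeric(0); object@scale <- numeric(0)
  object@transform <- "linear"
  object
}

#' Run the whole preprocessing chain on simulated/raw block tables
#'
#' Blank filtering, IS/protein normalization, block fusion and replicate
#' averaging in the canonical order.
#'
#' @param tables list of raw [FeatureTable-class] objects (one per block).
#' @param blankRatio study/blank ratio for [blankFilter()]; `NULL` skips
#'   blank filtering.
#' @return a linear-scale [EntityMatrix-class].
#' @export
preprocessTables <- function(tables, blankRatio = 3) {
  step <- lapply(tables, function(t) {
    if (!is.null(blankRatio)) t <- blankFilter(t, minRatio = blankRatio)
    else t@state <- "blank_filtered"
    normalize(t)
  })
  averageReplicates(fuseBlocks(step))
}
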