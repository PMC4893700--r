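## Central S4 containers. FeatureTable wraps SummarizedExperiment
## (rows = LC-MS features, columns = injected samples); everything
## downstream of replicate averaging lives in EntityMatrix.

.FT_STATES <- c("raw", "blank_filtered", "normalized")
.SAMPLE_ROLES <- c("study", "qc", "blank")
.MECHANISM_CLASSES <- c("control", "oxidative_stress", "phospholipidosis", "steatosis")
.REQUIRED_SAMPLE_COLS <- c("sample_id", "entity_id", "compound", "concentration_uM",
                           "class", "replicate", "role", "injection_order",
                           "protein_mg", "is_response")
.REQUIRED_FEATURE_COLS <- c("feature_id", "block", "metabolite", "monoisotopic_mass")

#' FeatureTable: a per-block LC-MS feature intensity table
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a processing
#' `state` flag. Rows are LC-MS features, columns are injected samples
#' (study, pooled QC or blank role).
#'
#' @slot state one of `"raw"`, `"blank_filtered"`, `"normalized"`.
#' @export
setClass("FeatureTable",
         contains = "SummarizedExperiment",
         slots = c(state = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@state) != 1L || !object@state %in% .FT_STATES)
    msg <- c(msg, sprintf("state must be one of %s", paste(.FT_STATES, collapse = ", ")))
  cd <- colData(object)
  rd <- rowData(object)
  miss <- setdiff(.REQUIRED_SAMPLE_COLS, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing sample metadata columns:", paste(miss, collapse = ", ")))
  missf <- setdiff(.REQUIRED_FEATURE_COLS, colnames(rd))
  if (length(missf))
    msg <- c(msg, paste("missing feature metadata columns:", paste(missf, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(cd$sample_id)) msg <- c(msg, "duplicated sample_id")
    if (anyDuplicated(rd$feature_id)) msg <- c(msg, "duplicated feature_id")
    if (!all(cd$role %in% .SAMPLE_ROLES))
      msg <- c(msg, "sample role must be study, qc or blank")
    study <- cd$role == "study"
    if (any(study) && (any(!is.finite(cd$protein_mg[study]) | cd$protein_mg[study] <= 0) ||
                       any(!is.finite(cd$is_response[study]) | cd$is_response[study] <= 0)))
      msg <- c(msg, "every study sample needs positive protein_mg and is_response")
    if (any(assay(object) < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, features x samples, non-negative.
#' @param sampleData data.frame (or DataFrame) of per-sample metadata with
#'   columns `sample_id`, `entity_id`, `compound`, `concentration_uM`,
#'   `class`, `replicate`, `role`, `injection_order`, `protein_mg`,
#'   `is_response`.
#' @param featureData data.frame of per-feature metadata with columns
#'   `feature_id`, `block`, `metabolite`, `monoisotopic_mass` (an optional
#'   logical `is_channel` marks internal-standard channels).
#' @param state processing state flag.
#' @return a [FeatureTable-class] object.
#' @export
FeatureTable <- function(intensities, sampleData, featureData, state = "raw") {
  intensities <- as.matrix(intensities)
  featureData <- as.data.frame(featureData)
  sampleData <- as.data.frame(sampleData)
  if (is.null(featureData$is_channel)) featureData$is_channel <- FALSE
  rownames(intensities) <- featureData$feature_id
  colnames(intensities) <- sampleData$sample_id
  se <- SummarizedExperiment(assays = list(intensity = intensities),
                             rowData = DataFrame(featureData, row.names = featureData$feature_id),
                             colData = DataFrame(sampleData, row.names = sampleData$sample_id))
  new("FeatureTable", se, state = state)
}

#' Processing state of a FeatureTable
#' @param object a [FeatureTable-class].
#' @return character scalar.
#' @export
tableState <- function(object) object@state

#' Intensity matrix of a FeatureTable
#' @param object a [FeatureTable-class].
#' @return numeric matrix, features x samples.
#' @export
intensities <- function(object) assay(object, "intensity")

setMethod("show", "FeatureTable", function(object) {
  cd <- colData(object)
  cat(sprintf("FeatureTable [%s]: %d features x %d samples (%d study, %d qc, %d blank)\n",
              object@state, nrow(object), ncol(object),
              sum(cd$role == "study"), sum(cd$role == "qc"), sum(cd$role == "blank")))
  cat(sprintf("  blocks: %s\n", paste(unique(rowData(object)$block), collapse = ", ")))
})

#' EntityMatrix: entity x metabolite abundance matrix
#'
#' One row per drug-concentration entity (the modeling unit: mean of its
#' biological replicates), one column per metabolite. Sample-level matrices
#' produced by [fuseBlocks()] use one row per study sample instead.
#'
#' @slot values numeric matrix with entity row names and metabolite column
#'   names.
#' @slot entityData data.frame of per-row metadata (`compound`,
#'   `concentration_uM`, `class`, ...).
#' @slot transform `"linear"`, `"log"` or `"scaled"`.
#' @slot center,scale per-column scaling parameters (empty unless scaled).
#' @slot logBase base of the log transform (default 10).
#' @slot dropped metabolites removed as zero-variance during scaling.
#' @export
setClass("EntityMatrix",
         slots = c(values = "matrix", entityData = "data.frame",
                   transform = "character", center = "numeric",
                   scale = "numeric", logBase = "numeric",
                   dropped = "character"))

setValidity("EntityMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@entityData))
    msg <- c(msg, "values and entityData disagree on the number of rows")
  if (!object@transform %in% c("linear", "log", "scaled"))
    msg <- c(msg, "transform must be linear, log or scaled")
  if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "duplicated metabolite columns")
  if (anyDuplicated(rownames(object@values)))
    msg <- c(msg, "duplicated entity rows")
  if (object@transform == "scaled" &&
      (length(object@center) != ncol(object@values) ||
       length(object@scale) != ncol(object@values)))
    msg <- c(msg, "scaled matrix must carry one center/scale per column")
  if (length(msg)) msg else TRUE
})

#' Construct an EntityMatrix
#' @param values numeric matrix (rows = entities or samples).
#' @param entityData per-row metadata data.frame.
#' @param transform transform state.
#' @param logBase log base used/to be used.
#' @return an [EntityMatrix-class].
#' @export
EntityMatrix <- function(values, entityData, transform = "linear", logBase = 10) {
  new("EntityMatrix", values = as.matrix(values),
      entityData = as.data.frame(entityData),
      transform = transform, center = numeric(0), scale = numeric(0),
      logBase = logBase, dropped = character(0))
}

#' @describeIn EntityMatrix value matrix accessor.
#' @param object an EntityMatrix.
#' @export
entityValues <- function(object) object@values

#' @describeIn EntityMatrix per-row metadata accessor.
#' @export
entityInfo <- function(object) object@entityData

#' @describeIn EntityMatrix class labels of the rows.
#' @export
entityClasses <- function(object) object@entityData$class

#' @describeIn EntityMatrix stored scaling parameters (`center`, `scale`,
#'   `dropped`, `logBase`), for projecting new data through the training
#'   transform.
#' @export
scalingParams <- function(object) {
  list(center = object@center, scale = object@scale,
       dropped = object@dropped, logBase = object@logBase)
}

setMethod("show", "EntityMatrix", function(object) {
  cat(sprintf("EntityMatrix [%s]: %d rows x %d metabolites\n",
              object@transform, nrow(object@values), ncol(object@values)))
  if (!is.null(object@entityData$class)) {
    tb <- table(object@entityData$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' PcaModel: principal component model fitted by NIPALS
#'
#' @slot scores n x A component scores.
#' @slot loadings p x A orthonormal loadings.
#' @slot varExplained per-component fraction of total (centered) variance.
#' @slot center,scale column statistics applied before decomposition.
#' @export
setClass("PcaModel",
         slots = c(scores = "matrix", loadings = "matrix",
                   varExplained = "numeric", center = "numeric",
                   scale = "numeric"))

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d components on %d x %d data\n",
              ncol(object@scores), nrow(object@scores), nrow(object@loadings)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varExplained), collapse = ", "), "\n")
})

#' PlsModel: PLS2 discriminant-analysis model (NIPALS)
#'
#' @slot ncomp number of latent variables A.
#' @slot weights p x A X-weights W (unit norm columns).
#' @slot xloadings p x A X-loadings P.
#' @slot scores n x A X-scores T (mutually orthogonal columns).
#' @slot yloadings K x A Y-loadings Q.
#' @slot coefficients p x K regression coefficients B = W (P'W)^-1 Q'.
#' @slot classes class levels (lexicographic order fixes tie-breaking).
#' @slot labels training labels, one per row of `scores`.
#' @slot yMeans column means of the one-hot Y.
#' @slot center,scale training column statistics of X (autoscaling).
#' @slot features metabolites entering the model, in model column order.
#' @slot ssy per-component explained Y sum of squares.
#' @slot ssyTotal total centered Y sum of squares.
#' @slot r2y cumulative R2Y per component.
#' @slot iterations NIPALS iteration count per component.
#' @export
setClass("PlsModel",
         slots = c(ncomp = "integer", weights = "matrix", xloadings = "matrix",
                   scores = "matrix", yloadings = "matrix",
                   coefficients = "matrix", classes = "character",
                   labels = "character", yMeans = "numeric",
                   center = "numeric", scale = "numeric",
                   features = "character", ssy = "numeric",
                   ssyTotal = "numeric", r2y = "numeric",
                   iterations = "integer"))

setValidity("PlsModel", function(object) {
  msg <- character()
  A <- object@ncomp
  if (A < 1L) msg <- c(msg, "at least one latent variable required")
  if (ncol(object@scores) != A) msg <- c(msg, "scores must have ncomp columns")
  TT <- crossprod(object@scores)
  off <- TT - diag(diag(TT), nrow = nrow(TT))
  if (max(abs(off)) >= 1e-8 * max(diag(TT)))
    msg <- c(msg, "score columns must be mutually orthogonal")
  wn <- sqrt(colSums(object@weights^2))
  if (any(abs(wn - 1) > 1e-8)) msg <- c(msg, "weight columns must have unit norm")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d latent variables, %d features, %d classes (%s)\n",
              object@ncomp, length(object@features), length(object@classes),
              paste(object@classes, collapse = ", ")))
  cat(sprintf("  n = %d training rows; cumulative R2Y: %s\n",
              nrow(object@scores),
              paste(sprintf("%.3f", object@r2y), collapse = ", ")))
})

#' Model accessors
#'
#' Small accessors for fitted [PlsModel-class] objects.
#' @param object a PlsModel.
#' @return `nComponents`: integer; `modelScores`: n x A matrix;
#'   `modelFeatures`: character; `r2Y`: cumulative R2Y per component.
#' @export
nComponents <- function(object) object@ncomp

#' @rdname nComponents
#' @export
modelScores <- function(object) object@scores

#' @rdname nComponents
#' @export
modelFeatures <- function(object) object@features

#' @rdname nComponents
#' @export
r2Y <- function(object) object@r2y

#' CvResult: repeated stratified cross-validation figures of merit
#'
#' @slot misclassification per-repeat misclassification error.
#' @slot auroc per-repeat (multiclass) AUROC.
#' @slot q2 per-repeat pooled Q2 (1 - PRESS / SSY).
#' @slot folds fold assignment of each row, one integer vector per repeat.
#' @slot nFolds,nRepeats,ncomp settings used.
#' @export
setClass("CvResult",
         slots = c(misclassification = "numeric", auroc = "numeric",
                   q2 = "numeric", folds = "list", nFolds = "integer",
                   nRepeats = "integer", ncomp = "integer"))

setMethod("show", "CvResult", function(object) {
  fmt <- function(x) sprintf("%.3f +/- %.3f", mean(x), if (length(x) > 1) sd(x) else 0)
  cat(sprintf("CvResult: %d-fold x %d repeats, %d latent variables\n",
              object@nFolds, object@nRepeats, object@ncomp))
  cat("  misclassification error:", fmt(object@misclassification), "\n")
  cat("  AUROC                  :", fmt(object@auroc), "\n")
  cat("  Q2                     :", fmt(object@q2), "\n")
})

#' Cross-validation summary
#' @param object a [CvResult-class].
#' @return data.frame with mean and sd of each figure of merit.
#' @export
cvSummary <- function(object) {
  s <- function(x) if (length(x) > 1) sd(x) else 0
  data.frame(metric = c("misclassification_error", "auroc", "q2"),
             mean = c(mean(object@misclassification), mean(object@auroc), mean(object@q2)),
             sd = c(s(object@misclassification), s(object@auroc), s(object@q2)))
}

#' PermutationResult: response-permutation test of a PLS-DA model
#'
#' @slot metric `"misclassification_error"` or `"auroc"`.
#' @slot observed figure of merit of the real-label model.
#' @slot permuted figure of merit of each label-permuted model.
#' @slot exceedances number of permuted models at least as good as the
#'   observed one (direction-aware).
#' @slot p empirical p-value, (exceedances + 1) / (permutations + 1).
#' @slot seed RNG seed used.
#' @export
setClass("PermutationResult",
         slots = c(metric = "character", observed = "numeric",
                   permuted = "numeric", exceedances = "integer",
                   p = "numeric", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  b <- if (object@metric == "auroc") sum(object@permuted >= object@observed)
       else sum(object@permuted <= object@observed)
  if (b != object@exceedances) msg <- c(msg, "exceedance count inconsistent with permuted values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult [%s]: observed %.4f, %d permutations, b = %d, empirical p = %.4g\n",
              object@metric, object@observed, length(object@permuted),
              object@exceedances, object@p))
})

#' Empirical p-value of a permutation test
#' @param object a [PermutationResult-class].
#' @return numeric scalar in (0, 1].
#' @export
empiricalP <- function(object) object@p

#' SplitSpec: development / external-validation split of the entities
#'
#' @slot development,validation entity ids of each subset (disjoint;
#'   together they cover every entity, every class is represented in the
#'   validation subset).
#' @slot fraction requested validation fraction.
#' @slot seed RNG seed used for the draw.
#' @export
setClass("SplitSpec",
         slots = c(development = "character", validation = "character",
                   fraction = "numeric", seed = "integer"))

setValidity("SplitSpec", function(object) {
  if (length(intersect(object@development, object@validation)))
    "development and validation sets overlap" else TRUE
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d development / %d validation entities (fraction %.2f, seed %d)\n",
              length(object@development), length(object@validation),
              object@fraction, object@seed))
})

#' @describeIn SplitSpec development entity ids.
#' @param object a SplitSpec.
#' @export
developmentIds <- function(object) object@development

#' @describeIn SplitSpec validation entity ids.
#' @export
validationIds <- function(object) object@validation
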