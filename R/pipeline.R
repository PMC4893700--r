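## End-to-end predictive-model construction: stratified 80/20 split,
## VIP-ranked incremental variable selection chosen by cross-validation
## figures of merit, dual-metric response-permutation testing, and
## external-set projection.

#' Split entities into development and external-validation subsets
#'
#' Per class, `round(fraction * class size)` entities (at least one) are
#' drawn at random into the validation subset, so every class is
#' represented there; the rest form the development subset. The draw is
#' seeded and reproducible.
#'
#' @param x an [EntityMatrix-class] or a named character vector /
#'   data.frame of class labels (names or rownames = entity ids).
#' @param fraction validation fraction in (0, 1), default 0.20.
#' @param seed integer RNG seed.
#' @return a [SplitSpec-class].
#' @examples
#' cls <- setNames(rep(c("a", "b"), c(6, 9)), paste0("e", 1:15))
#' splitDevValidation(cls, 0.2, seed = 1)
#' @export
splitDevValidation <- function(x, fraction = 0.20, seed) {
  if (missing(seed)) stop("a seed is required")
  if (is(x, "EntityMatrix")) {
    classes <- setNames(as.character(entityClasses(x)), rownames(entityValues(x)))
  } else if (is.data.frame(x)) {
    classes <- setNames(as.character(x$class), rownames(x))
  } else classes <- x
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  cnt <- table(classes)
  if (any(cnt < 2L))
    stop("every class needs at least two entities to be split: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  set.seed(as.integer(seed))
  val <- unlist(lapply(sort(unique(classes)), function(cl) {
    ids <- names(classes)[classes == cl]
    sample(ids, max(1L, round(fraction * length(ids))))
  }), use.names = FALSE)
  new("SplitSpec", development = setdiff(names(classes), val),
      validation = val, fraction = fraction, seed = as.integer(seed))
}

.cvMerit <- function(cv) {
  c(auroc = mean(cv@auroc), mis = mean(cv@misclassification),
    q2 = mean(cv@q2), aurocSd = if (cv@nRepeats > 1) sd(cv@auroc) else 0,
    misSd = if (cv@nRepeats > 1) sd(cv@misclassification) else 0)
}

#' VIP-ranked incremental variable selection
#'
#' Ranks the features by their VIP in a full-feature PLS-DA model (stable
#' ties broken by feature name), then refits and cross-validates models on
#' the top-k features for every candidate size and component count. The
#' chosen configuration maximizes the mean cross-validated AUROC, with
#' ties broken by lower misclassification error, then smaller size
#' (parsimony), then fewer components. The final model is refitted on all
#' development entities at the chosen configuration.
#'
#' @param x log-scale development feature matrix or
#'   [EntityMatrix-class] (development entities only).
#' @param classes class labels.
#' @param componentGrid candidate latent-variable counts.
#' @param sizeGrid candidate numbers of top-ranked features.
#' @param nFolds,nRepeats cross-validation settings per candidate.
#' @param seed integer RNG seed (fold draws are derived from it).
#' @return list with `model` (final [PlsModel-class]), `trace`
#'   (data.frame of per-candidate figures of merit, the chosen row
#'   flagged), `ranking` (VIP-ordered feature names), `size`, `ncomp`.
#' @export
selectVariables <- function(x, classes = NULL, componentGrid = 1:5,
                            sizeGrid = c(seq(2, 30, 2), seq(35, 60, 5)),
                            nFolds = 5L, nRepeats = 5L, seed) {
  if (missing(seed)) stop("a seed is required")
  inp <- .resolveXClasses(x, classes)
  x <- inp$x; classes <- inp$classes
  if (!length(componentGrid) || !length(sizeGrid)) stop("empty search grid")
  sizeGrid <- sort(unique(pmin(as.integer(sizeGrid), ncol(x))))
  maxA <- min(max(componentGrid), nrow(x) - 1L, ncol(x))
  full <- fitPlsda(x, classes, ncomp = maxA)
  v <- vip(full)
  ranking <- names(v)[order(-v, names(v))]

  rows <- list(); i <- 0L
  for (k in sizeGrid) {
    feats <- ranking[seq_len(k)]
    for (a in componentGrid) {
      if (a > min(k, nrow(x) - 1L)) next
      i <- i + 1L
      cv <- crossValidate(x[, feats, drop = FALSE], classes, ncomp = a,
                          nFolds = nFolds, nRepeats = nRepeats,
                          seed = as.integer(seed) + i)
      m <- .cvMerit(cv)
      rows[[i]] <- data.frame(size = k, ncomp = a, auroc = m["auroc"],
                              aurocSd = m["aurocSd"], misclassification = m["mis"],
                              misclassificationSd = m["misSd"], q2 = m["q2"],
                              row.names = NULL)
    }
  }
  trace <- do.call(rbind, rows)
  ord <- order(-round(trace$auroc, 10), round(trace$misclassification, 10),
               trace$size, trace$ncomp)
  best <- trace[ord[1], ]
  trace$chosen <- seq_len(nrow(trace)) == ord[1]
  feats <- ranking[seq_len(best$size)]
  model <- fitPlsda(x[, feats, drop = FALSE], classes, ncomp = best$ncomp)
  list(model = model, trace = trace, ranking = ranking,
       size = best$size, ncomp = best$ncomp)
}

#' Response-permutation test of a PLS-DA configuration
#'
#' Compares the cross-validated figure of merit of the real-label model
#' with the distribution obtained after repeatedly randomizing the class
#' labels over the entities, refitting and cross-validating at the fixed
#' configuration (feature set and component count of the real-label
#' model). The empirical p-value is (b + 1) / (nPerm + 1) where b counts
#' permuted models at least as good as the observed one (<= for
#' misclassification error, >= for AUROC), so p is never zero and equals
#' 1/(nPerm + 1) < 0.001 for nPerm = 1000 with no exceedances.
#'
#' @param x log-scale development matrix or [EntityMatrix-class].
#' @param classes class labels.
#' @param features fixed feature set (from the real-label model).
#' @param ncomp fixed number of latent variables.
#' @param metric `"misclassification_error"` or `"auroc"`.
#' @param nPerm number of permutations (default 1000).
#' @param nFolds,nRepeats cross-validation settings, applied identically
#'   to the observed and every permuted model.
#' @param seed integer RNG seed.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(x, classes = NULL, features, ncomp,
                            metric = c("misclassification_error", "auroc"),
                            nPerm = 1000L, nFolds = 5L, nRepeats = 1L, seed) {
  metric <- match.arg(metric)
  if (missing(seed)) stop("a seed is required")
  if (nPerm < 1L) stop("nPerm must be at least 1")
  inp <- .resolveXClasses(x, classes)
  xs <- inp$x[, features, drop = FALSE]; classes <- inp$classes
  set.seed(as.integer(seed))
  getMetric <- function(lab) {
    cv <- crossValidate(xs, lab, ncomp = ncomp, nFolds = nFolds,
                        nRepeats = nRepeats, seed = NULL)
    if (metric == "auroc") mean(cv@auroc) else mean(cv@misclassification)
  }
  observed <- getMetric(classes)
  permuted <- vapply(seq_len(nPerm), function(i) getMetric(sample(classes)),
                     numeric(1))
  b <- if (metric == "auroc") sum(permuted >= observed) else sum(permuted <= observed)
  new("PermutationResult", metric = metric, observed = observed,
      permuted = permuted, exceedances = as.integer(b),
      p = (b + 1) / (nPerm + 1), seed = as.integer(seed))
}

#' Project an external validation set through a fitted model
#'
#' Applies [predict()] (training scaling, fixed feature set) to entities
#' that never participated in model building and reports per-entity
#' assignments, confidence grades and the overall accuracy.
#'
#' @param model a fitted [PlsModel-class].
#' @param x log-scale validation matrix or [EntityMatrix-class].
#' @param classes true class labels of the validation entities.
#' @param developmentIds optional development entity ids; overlap with the
#'   validation rows is an error.
#' @return list with `table` (entity, true/predicted class, grade,
#'   correct) and `accuracy`.
#' @export
externalValidate <- function(model, x, classes = NULL, developmentIds = NULL) {
  inp <- .resolveXClasses(x, classes)
  if (!is.null(developmentIds)) {
    ov <- intersect(rownames(inp$x), developmentIds)
    if (length(ov))
      stop("validation entities overlap the development set: ",
           paste(head(ov, 5), collapse = ", "))
  }
  pr <- predict(model, inp$x)
  tab <- data.frame(entity = rownames(inp$x), true = inp$classes,
                    predicted = pr$class, grade = pr$grade,
                    correct = pr$class == inp$classes,
                    stringsAsFactors = FALSE)
  list(table = tab, accuracy = mean(tab$correct))
}

#' Run the full synthetic benchmark pipeline
#'
#' Generates the default synthetic benchmark (30 entities, planted
#' mechanism signatures), preprocesses it, splits development/validation
#' (80/20 stratified), performs VIP-ranked variable selection on the
#' development entities, optionally runs the dual-metric permutation
#' test at the chosen configuration, and projects the external set.
#' Everything is driven by one master seed; the same seed yields
#' bit-identical models and reports.
#'
#' @param seed master integer seed.
#' @param componentGrid,sizeGrid selection grids.
#' @param nRepeats cross-validation repeats during selection.
#' @param nPerm permutations for the validation test (0 skips it).
#' @param signatures planted signatures (default [defaultSignatures()]).
#' @param noise noise parameters (default [noiseDefaults()]).
#' @return list with `split`, `selection`, `model`, `permutation`
#'   (misclassification and AUROC results or NULL), `validation`,
#'   `entityMatrix`.
#' @export
runBenchmarkPipeline <- function(seed, componentGrid = 1:4,
                                 sizeGrid = c(5, 10, 15, 20, 26, 30, 40),
                                 nRepeats = 5L, nPerm = 0L,
                                 signatures = NULL, noise = noiseDefaults()) {
  seed <- as.integer(seed)
  catalog <- featureCatalog()
  if (is.null(signatures)) signatures <- defaultSignatures(catalog)
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), catalog, signatures,
                               noise = noise, seed = seed)
  em <- logTransform(preprocessTables(sim$tables))
  split <- splitDevValidation(em, 0.20, seed = seed + 1L)
  dev <- entityValues(em)[developmentIds(split), , drop = FALSE]
  devCls <- setNames(entityClasses(em), rownames(entityValues(em)))[developmentIds(split)]
  sel <- selectVariables(dev, devCls, componentGrid = componentGrid,
                         sizeGrid = sizeGrid, nRepeats = nRepeats,
                         seed = seed + 2L)
  perm <- NULL
  if (nPerm > 0L) {
    perm <- list(
      misclassification_error = permutationTest(
        dev, devCls, features = modelFeatures(sel$model),
        ncomp = nComponents(sel$model), metric = "misclassification_error",
        nPerm = nPerm, seed = seed + 3L),
      auroc = permutationTest(
        dev, devCls, features = modelFeatures(sel$model),
        ncomp = nComponents(sel$model), metric = "auroc",
        nPerm = nPerm, seed = seed + 4L))
  }
  valX <- entityValues(em)[validationIds(split), , drop = FALSE]
  valCls <- setNames(entityClasses(em), rownames(entityValues(em)))[validationIds(split)]
  val <- externalValidate(sel$model, valX, valCls,
                          developmentIds = developmentIds(split))
  list(split = split, selection = sel, model = sel$model,
       permutation = perm, validation = val, entityMatrix = em)
}
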