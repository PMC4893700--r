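## JSON serialization of fitted PLS-DA models. Matrices are stored
## row-major with explicit dimensions and dimnames; numbers are written
## at full precision so a load/save round trip is bit-faithful.

.mat2list <- function(m) {
  list(dim = dim(m), rownames = rownames(m), colnames = colnames(m),
       data = as.numeric(t(m)))
}

.list2mat <- function(l) {
  m <- matrix(l$data, nrow = l$dim[1], ncol = l$dim[2], byrow = TRUE)
  dimnames(m) <- list(l$rownames, l$colnames)
  m
}

#' Serialize / deserialize a PLS-DA model as JSON
#'
#' `writePlsModel` writes every slot of the model (dimensions, row-major
#' matrices, class encoding, scaling parameters, feature list) to a
#' single JSON document at full numeric precision; `readPlsModel`
#' restores a bit-identical [PlsModel-class].
#'
#' @param model a fitted [PlsModel-class].
#' @param path output/input file path.
#' @return `writePlsModel`: invisibly, `path`; `readPlsModel`: the model.
#' @export
writePlsModel <- function(model, path) {
  stopifnot(is(model, "PlsModel"))
  doc <- list(
    format = "metabotox-plsmodel", version = 1L,
    ncomp = model@ncomp,
    classes = model@classes, labels = model@labels,
    features = model@features,
    yMeans = as.list(setNames(model@yMeans, model@classes)),
    center = as.list(setNames(model@center, model@features)),
    scale = as.list(setNames(model@scale, model@features)),
    ssy = model@ssy, ssyTotal = model@ssyTotal, r2y = model@r2y,
    iterations = model@iterations,
    weights = .mat2list(model@weights), xloadings = .mat2list(model@xloadings),
    scores = .mat2list(model@scores), yloadings = .mat2list(model@yloadings),
    coefficients = .mat2list(model@coefficients))
  write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname writePlsModel
#' @export
readPlsModel <- function(path) {
  doc <- read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "metabotox-plsmodel"))
    stop("not a metabotox PLS model file")
  num <- function(x) {
    out <- unlist(x); storage.mode(out) <- "double"; out
  }
  new("PlsModel",
      ncomp = as.integer(doc$ncomp),
      weights = .list2mat(doc$weights), xloadings = .list2mat(doc$xloadings),
      scores = .list2mat(doc$scores), yloadings = .list2mat(doc$yloadings),
      coefficients = .list2mat(doc$coefficients),
      classes = doc$classes, labels = doc$labels,
      yMeans = num(doc$yMeans), center = num(doc$center), scale = num(doc$scale),
      features = doc$features, ssy = as.numeric(doc$ssy),
      ssyTotal = as.numeric(doc$ssyTotal), r2y = as.numeric(doc$r2y),
      iterations = as.integer(doc$iterations))
}
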