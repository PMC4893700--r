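## Over-representation analysis of discriminant metabolites against
## user-supplied metabolite sets (hypergeometric upper tail + BH-FDR).

#' Read metabolite sets from a GMT file
#'
#' The standard tab-separated gene-set format, reused with metabolite
#' identifiers: one set per line (name, description, members...).
#'
#' @param path path to a `.gmt` file.
#' @return named list of metabolite-id character vectors.
#' @export
readMetaboliteSets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each metabolite set, the upper-tail probability
#' P(X >= overlap) of drawing at least the observed overlap when
#' `length(hits)` metabolites are sampled without replacement from the
#' universe; BH correction across the sets. Sets are intersected with the
#' universe first; sets left empty are dropped with a warning.
#'
#' @param hits character vector of discriminant metabolite ids (must be
#'   a subset of `universe`).
#' @param sets named list of metabolite-id vectors (see
#'   [defaultMetaboliteSets()] or [readMetaboliteSets()]).
#' @param universe all measured metabolites (after preprocessing).
#' @return data.frame sorted by p: `set`, `overlap`, `setSize`,
#'   `hitSize`, `universeSize`, `p`, `q`.
#' @examples
#' u <- paste0("m", 1:20)
#' ora(u[1:5], list(s = u[1:5]), u)  # p = 1 / choose(20, 5)
#' @export
ora <- function(hits, sets, universe) {
  hits <- unique(hits)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hit(s) outside the universe: ", paste(head(bad, 5), collapse = ", "))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropped empty set(s): ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no non-empty sets to test")
  N <- length(universe); h <- length(hits)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    ov <- length(intersect(sets[[nm]], hits))
    data.frame(set = nm, overlap = ov, setSize = K, hitSize = h,
               universeSize = N,
               p = phyper(ov - 1, K, N - K, h, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- bhFdr(res$p)
  res[order(res$p, res$set), , drop = FALSE]
}
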