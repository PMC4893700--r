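## Metabolite catalog: 272 identified metabolites split over four
## analytical blocks (two HILIC, two reversed-phase conditions), plus the
## generator's ground-truth mechanism signatures and the default
## metabolite-set collection used for over-representation analysis.

.markerFrame <- function(metabolite, category, block, mass) {
  data.frame(metabolite = metabolite, category = category,
             block = as.integer(block), monoisotopic_mass = mass,
             stringsAsFactors = FALSE)
}

#' Built-in marker metabolites
#'
#' The named metabolites that every default catalog must contain: the
#' glutathione / gamma-glutamyl cycle panel (GSH, GSSG, CSSG, ophthalmic
#' acid, gamma-glutamyl dipeptides, glutamate, glutamine, ...), proteinogenic
#' amino acids, and representative acylcarnitine, fatty acid (FA),
#' triacylglyceride (TG), diacylglyceride (DG), phospholipid (PL) and
#' lysophospholipid (LysoPL) species.
#'
#' @return data.frame with columns `metabolite`, `category`, `block`,
#'   `monoisotopic_mass`.
#' @export
defaultMarkers <- function() {
  glut <- .markerFrame(
    c("GSH", "GSSG", "CSSG", "Ophthalmic acid",
      "gamma-Glutamylglutamate", "gamma-Glutamylglutamine",
      "gamma-Glutamylcysteine", "Glutamate", "Glutamine",
      "5-Oxoproline", "Cysteinylglycine", "Cysteine"),
    "glutathione", 1L,
    c(307.0838, 612.1520, 426.0883, 289.1274, 276.0957, 275.1117,
      250.0623, 147.0532, 146.0691, 129.0426, 178.0412, 121.0197))
  aa <- .markerFrame(
    c("Glycine", "Alanine", "Serine", "Proline", "Valine", "Threonine",
      "Leucine", "Isoleucine", "Asparagine", "Aspartate", "Lysine",
      "Methionine", "Histidine", "Phenylalanine", "Arginine", "Tyrosine",
      "Tryptophan", "Ornithine", "Citrulline", "Taurine"),
    "amino_acid", 1L,
    c(75.0320, 89.0477, 105.0426, 115.0633, 117.0790, 119.0582,
      131.0946, 131.0947, 132.0535, 133.0375, 146.1055, 149.0510,
      155.0695, 165.0790, 174.1117, 181.0739, 204.0899, 132.0899,
      175.0957, 125.0147))
  ac <- .markerFrame(
    c("Carnitine", "Acetylcarnitine", "Propionylcarnitine",
      "Butyrylcarnitine", "Hexanoylcarnitine", "Octanoylcarnitine",
      "Decanoylcarnitine", "Lauroylcarnitine", "Myristoylcarnitine",
      "Palmitoylcarnitine"),
    "acylcarnitine", 3L,
    161.1052 + c(0, 42.0106, 56.0262, 70.0419, 98.0732, 126.1045,
                 154.1358, 182.1671, 210.1984, 238.2297))
  tgSpecies <- c("48:0", "48:1", "48:2", "50:1", "50:2", "50:3", "52:1",
                 "52:2", "52:3", "52:4", "54:2", "54:3", "54:4", "54:5",
                 "54:6", "56:4", "56:6", "56:8")
  tg <- .markerFrame(paste("TG", tgSpecies), "TG", 3L,
                     780.65 + seq_along(tgSpecies) * 4.513)
  dgSpecies <- c("32:0", "34:1", "34:2", "36:2", "36:3", "36:4", "38:4", "38:6")
  dg <- .markerFrame(paste("DG", dgSpecies), "DG", 3L,
                     568.47 + seq_along(dgSpecies) * 5.021)
  pcSpecies <- c("30:0", "32:0", "32:1", "34:1", "34:2", "36:1", "36:2",
                 "36:3", "36:4", "38:4", "38:5", "38:6", "40:6", "40:7")
  pc <- .markerFrame(paste("PC", pcSpecies), "PL", 3L,
                     705.53 + seq_along(pcSpecies) * 4.207)
  peSpecies <- c("34:1", "34:2", "36:1", "36:2", "36:4", "38:4", "38:6", "40:6")
  pe <- .markerFrame(paste("PE", peSpecies), "PL", 4L,
                     717.53 + seq_along(peSpecies) * 3.914)
  faSpecies <- c("12:0", "14:0", "16:0", "16:1", "17:0", "18:0", "18:1",
                 "18:2", "18:3", "20:0", "20:3", "20:4", "20:5", "22:0",
                 "22:6", "24:0")
  fa <- .markerFrame(paste("FA", faSpecies), "FA", 4L,
                     c(200.1776, 228.2089, 256.2402, 254.2246, 270.2559,
                       284.2715, 282.2559, 280.2402, 278.2246, 312.3028,
                       306.2559, 304.2402, 302.2246, 340.3341, 328.2402,
                       368.3654))
  lplSpecies <- c("LPC 14:0", "LPC 16:0", "LPC 16:1", "LPC 18:0",
                  "LPC 18:1", "LPC 18:2", "LPC 20:3", "LPC 20:4",
                  "LPC 22:6", "LPE 16:0", "LPE 18:0", "LPE 18:1",
                  "LPE 18:2", "LPE 20:4")
  lpl <- .markerFrame(lplSpecies, "LysoPL", 4L,
                      453.28 + seq_along(lplSpecies) * 5.733)
  other <- .markerFrame(
    c("Cholesterol", "SM 34:1", "Ceramide d18:1/16:0", "Sphingosine"),
    "other_lipid", 4L,
    c(386.3549, 702.5676, 537.5121, 299.2824))
  rbind(glut, aa, ac, tg, dg, pc, pe, fa, lpl, other)
}

#' Build the metabolite feature catalog
#'
#' Partitions `nFeatures` identified metabolites into four analytical
#' blocks. Named marker metabolites (see [defaultMarkers()]) are always
#' included in their natural block; the remaining slots are padded with
#' generic polar/organic-acid metabolites carrying deterministic plausible
#' monoisotopic masses, so the catalog is reproducible without a seed.
#'
#' @param nFeatures total number of identified metabolites (default 272).
#' @param blockSizes integer vector of four block sizes summing to
#'   `nFeatures` (default `c(120, 60, 50, 42)`).
#' @param markers data.frame of mandatory metabolites (columns
#'   `metabolite`, `category`, `block`, `monoisotopic_mass`).
#' @return data.frame with columns `feature_id`, `block`, `metabolite`,
#'   `category`, `monoisotopic_mass`, ordered by block.
#' @examples
#' cat272 <- featureCatalog()
#' table(cat272$block)
#' @export
featureCatalog <- function(nFeatures = 272L, blockSizes = c(120L, 60L, 50L, 42L),
                           markers = defaultMarkers()) {
  blockSizes <- as.integer(blockSizes)
  if (length(blockSizes) != 4L || any(blockSizes <= 0L))
    stop("blockSizes must be four positive integers")
  if (sum(blockSizes) != nFeatures)
    stop("blockSizes must sum to nFeatures")
  if (nFeatures < nrow(markers))
    stop(sprintf("nFeatures (%d) is below the %d mandatory marker metabolites",
                 nFeatures, nrow(markers)))
  perBlock <- vapply(1:4, function(b) sum(markers$block == b), integer(1))
  if (any(blockSizes < perBlock))
    stop("a block is smaller than its mandatory marker count")
  fillerCat <- c("polar_other", "organic_acid_other", "lipid_other", "lipid_other")
  fillerLab <- c("Polar metabolite", "Organic acid", "Lipid feature", "Lipid feature")
  blocks <- lapply(1:4, function(b) {
    m <- markers[markers$block == b, , drop = FALSE]
    nFill <- blockSizes[b] - nrow(m)
    if (nFill > 0) {
      i <- seq_len(nFill)
      fill <- data.frame(
        metabolite = sprintf("%s B%d-%03d", fillerLab[b], b, i),
        category = fillerCat[b], block = b,
        monoisotopic_mass = round(100 + (i * 53.77 + b * 17.3) %% 800 + i * 1e-4, 4),
        stringsAsFactors = FALSE)
      m <- rbind(m, fill)
    }
    m
  })
  cat <- do.call(rbind, blocks)
  cat$feature_id <- sprintf("B%d_F%03d", cat$block,
                            unlist(lapply(blockSizes, seq_len)))
  rownames(cat) <- cat$feature_id
  cat[, c("feature_id", "block", "metabolite", "category", "monoisotopic_mass")]
}

#' Default mechanism signatures
#'
#' Ground-truth log2 fold changes (at the top tested dose) planted by the
#' simulator, encoding the qualitative mechanism fingerprints of the
#' screen: oxidative stress depletes GSH and raises GSSG, CSSG, ophthalmic
#' acid and gamma-glutamyl cycle intermediates (the redox core is
#' dose-dependent and appears attenuated in the other two mechanisms);
#' phospholipidosis lowers lysophospholipids (hence the LysoPL/PL ratio)
#' while leaving phospholipids themselves essentially unchanged; steatosis
#' accumulates TG (the hallmark), DG and, mildly, PL and LysoPL while free
#' fatty acids fall. Mild TG/FA/acylcarnitine involvement is shared across
#' mechanisms, reflecting common mitochondrial impairment.
#'
#' @param catalog a feature catalog from [featureCatalog()]; category-level
#'   entries are expanded over its member species.
#' @return data.frame with columns `metabolite`, `class`, `lfc` (log2 fold
#'   change at top dose), `dose_dependent`.
#' @export
defaultSignatures <- function(catalog = featureCatalog()) {
  sig <- function(met, class, lfc, dd = FALSE) {
    if (!length(met)) return(NULL)
    data.frame(metabolite = met, class = class, lfc = lfc,
               dose_dependent = dd, stringsAsFactors = FALSE)
  }
  byCat <- function(category, class, lfc)
    sig(catalog$metabolite[catalog$category == category], class, lfc)
  redox <- rbind(
    sig("GSH", "oxidative_stress", -2.0, TRUE),
    sig("GSSG", "oxidative_stress", 1.5, TRUE),
    sig("CSSG", "oxidative_stress", 2.0),
    sig("Ophthalmic acid", "oxidative_stress", 1.5, TRUE),
    sig(c("gamma-Glutamylglutamate", "gamma-Glutamylglutamine",
          "gamma-Glutamylcysteine"), "oxidative_stress", 1.2),
    sig(c("Glutamate", "Glutamine", "5-Oxoproline", "Cysteinylglycine"),
        "oxidative_stress", 1.0),
    sig("Cysteine", "oxidative_stress", -1.0))
  sharedRedox <- do.call(rbind, lapply(c("phospholipidosis", "steatosis"), function(cl)
    rbind(sig("GSH", cl, -1.0, TRUE), sig("GSSG", cl, 0.5, TRUE),
          sig("CSSG", cl, 0.8), sig("Ophthalmic acid", cl, 0.8, TRUE))))
  lipids <- rbind(
    byCat("TG", "oxidative_stress", 0.2),
    byCat("FA", "oxidative_stress", 0.2),
    byCat("acylcarnitine", "oxidative_stress", 0.2),
    byCat("LysoPL", "phospholipidosis", -1.5),
    byCat("TG", "phospholipidosis", 0.2),
    byCat("TG", "steatosis", 2.0),
    byCat("DG", "steatosis", 1.2),
    byCat("PL", "steatosis", 0.3),
    byCat("LysoPL", "steatosis", 0.5),
    byCat("FA", "steatosis", -0.8),
    byCat("acylcarnitine", "steatosis", 0.5))
  out <- rbind(redox, sharedRedox, lipids)
  out <- out[out$metabolite %in% catalog$metabolite, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default metabolite-set collection
#'
#' Category-derived metabolite sets mirroring the pathway vocabulary of
#' the screen (glutathione / gamma-glutamyl cycle, amino acids,
#' acylcarnitines, fatty acids, TG, DG, phospholipids, lysophospholipids),
#' for over-representation analysis against the measured universe.
#'
#' @param catalog a feature catalog from [featureCatalog()].
#' @return named list of metabolite-id character vectors.
#' @export
defaultMetaboliteSets <- function(catalog = featureCatalog()) {
  pick <- function(category) catalog$metabolite[catalog$category == category]
  list(glutathione_gamma_glutamyl = pick("glutathione"),
       amino_acids = pick("amino_acid"),
       acylcarnitines = pick("acylcarnitine"),
       fatty_acids = pick("FA"),
       triacylglycerols = pick("TG"),
       diacylglycerols = pick("DG"),
       phospholipids = pick("PL"),
       lysophospholipids = pick("LysoPL"))
}
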