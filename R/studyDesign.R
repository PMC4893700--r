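## Study design: 12 model compounds at the tested concentrations, two
## vehicle controls, 3 biological replicates per entity, pooled QC every
## 10 study injections.

#' Default HepG2 hepatotoxicity study design
#'
#' Twelve model compounds (two non-hepatotoxic controls, two oxidative
#' stress inducers, five phospholipidogenic and three steatogenic drugs)
#' at the sub-lethal concentrations used in the screen, plus optional
#' medium-only and DMSO vehicle-control entities. Each drug-at-one-
#' concentration condition is an independent entity; the default design
#' yields 30 entities (28 drug-concentration + 2 vehicle) with class
#' counts control = 6, oxidative_stress = 6, phospholipidosis = 9,
#' steatosis = 9.
#'
#' @param nReplicates biological replicates per entity (default 3).
#' @param qcInterval pooled-QC injection interval in study samples
#'   (default 10).
#' @param nBlanks number of blank (no-cell) injections per block.
#' @param includeVehicleControls add medium-only and DMSO entities.
#' @return a list of class `StudyDesign` with elements `compounds`
#'   (list of compound records), `nReplicates`, `qcInterval`, `nBlanks`,
#'   `includeVehicleControls`.
#' @examples
#' d <- hepatotoxStudyDesign()
#' nrow(designEntities(d))  # 30
#' @export
hepatotoxStudyDesign <- function(nReplicates = 3L, qcInterval = 10L,
                                 nBlanks = 3L, includeVehicleControls = TRUE) {
  cmp <- function(name, abbr, class, conc, ic10 = NA_real_, cmax = NA_real_) {
    stopifnot(length(conc) >= 1L, all(conc > 0), !is.unsorted(conc, strictly = TRUE))
    list(name = name, abbreviation = abbr, mechanism_class = class,
         concentrations = conc, ic10 = ic10, cmax = cmax)
  }
  compounds <- list(
    cmp("Citrate",                  "Cit",  "control",          c(500, 1000), NA,   NA),
    cmp("Ketotifen",                "Ket",  "control",          c(50, 100),   130,  0.0014),
    cmp("Cumene hydroperoxide",     "Cum",  "oxidative_stress", c(50, 100, 250), 480, NA),
    cmp("tert-Butyl hydroperoxide", "Tert", "oxidative_stress", c(50, 100, 250), 280, NA),
    cmp("Amiodarone",               "Am",   "phospholipidosis", c(5, 10, 20), 26,   2.2),
    cmp("Clozapine",                "Clo",  "phospholipidosis", c(10, 20),    41,   1.09),
    cmp("Fluoxetine",               "Fluo", "phospholipidosis", c(20),        12,   0.93),
    cmp("Tilorone",                 "Til",  "phospholipidosis", c(5, 20),     14,   NA),
    cmp("Tamoxifen",                "Tam",  "phospholipidosis", c(15),        32,   0.27),
    cmp("Doxycycline",              "Dox",  "steatosis",        c(250, 500),  600,  8.77),
    cmp("Tetracycline",             "Tet",  "steatosis",        c(50, 100, 200, 400), 640, 14.2),
    cmp("Valproate",                "Val",  "steatosis",        c(2000, 4000, 8000), 8870, 481)
  )
  structure(list(compounds = compounds,
                 nReplicates = as.integer(nReplicates),
                 qcInterval = as.integer(qcInterval),
                 nBlanks = as.integer(nBlanks),
                 includeVehicleControls = isTRUE(includeVehicleControls)),
            class = "StudyDesign")
}

#' Expand a study design into its entity table
#'
#' One row per drug-concentration entity. `dose_frac` is the concentration
#' rank divided by the number of concentrations tested for that compound;
#' dose-dependent signature effects are scaled by it.
#'
#' @param design a `StudyDesign` from [hepatotoxStudyDesign()].
#' @return data.frame with columns `entity_id`, `compound`, `abbreviation`,
#'   `concentration_uM`, `class`, `dose_frac`.
#' @export
designEntities <- function(design) {
  rows <- lapply(design$compounds, function(cc) {
    k <- length(cc$concentrations)
    data.frame(entity_id = paste(cc$abbreviation, cc$concentrations, sep = "_"),
               compound = cc$name, abbreviation = cc$abbreviation,
               concentration_uM = cc$concentrations,
               class = cc$mechanism_class,
               dose_frac = seq_len(k) / k,
               stringsAsFactors = FALSE)
  })
  ent <- do.call(rbind, rows)
  if (design$includeVehicleControls) {
    veh <- data.frame(entity_id = c("C", "DMSO"),
                      compound = c("Culture medium", "DMSO 0.5%"),
                      abbreviation = c("C", "DMSO"),
                      concentration_uM = c(0, 0),
                      class = "control", dose_frac = 0)
    ent <- rbind(ent, veh)
  }
  if (anyDuplicated(ent$entity_id)) stop("duplicated entity ids in design")
  rownames(ent) <- ent$entity_id
  ent
}
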