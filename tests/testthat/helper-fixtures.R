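# Shared fixtures and independent oracles, built in code at test time.

# Brute-force two-sided Mann-Whitney p by enumeration of all
# choose(n1 + n2, n1) label assignments (independent of wilcox.test).
bruteMannWhitneyP <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  uStat <- function(idx) {
    xx <- v[idx]; yy <- v[-idx]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  }
  obs <- uStat(seq_len(n1))
  all <- utils::combn(length(v), n1)
  us <- apply(all, 2, uStat)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Small 40-feature catalog with 8 named markers, two per block.
smallMarkerCatalog <- function() {
  mk <- data.frame(metabolite = paste0("M", 1:8), category = "marker",
                   block = rep(1:4, each = 2), monoisotopic_mass = 100 + 1:8)
  featureCatalog(40, c(10, 10, 10, 10), markers = mk)
}

# Balanced custom design: nPerClass compounds per mechanism class at two
# concentrations each (no vehicle controls).
balancedDesign <- function(nPerClass = 6) {
  d <- hepatotoxStudyDesign(includeVehicleControls = FALSE)
  cmp <- function(name, class)
    list(name = name, abbreviation = name, mechanism_class = class,
         concentrations = c(10, 100), ic10 = NA_real_, cmax = NA_real_)
  classes <- c("control", "oxidative_stress", "phospholipidosis", "steatosis")
  d$compounds <- unlist(lapply(classes, function(cl)
    lapply(seq_len(nPerClass), function(i) cmp(paste0(substr(cl, 1, 2), i), cl))),
    recursive = FALSE)
  d
}

# Five informative features in a 40-feature catalog: one strong oxidative
# stress marker, weak complementary pairs for phospholipidosis and
# steatosis (each pair member individually insufficient).
fiveFeatureSignatures <- function() {
  data.frame(metabolite = c("M1", "M3", "M4", "M5", "M6"),
             class = c("oxidative_stress", "phospholipidosis",
                       "phospholipidosis", "steatosis", "steatosis"),
             lfc = c(1.5, 0.3, -0.3, 0.3, -0.3), dose_dependent = FALSE)
}

# Simulated default benchmark reduced to one call: entity matrix (log)
# with planted mechanism signatures.
benchmarkMatrix <- function(seed, catalog = featureCatalog(),
                            signatures = defaultSignatures(catalog), ...) {
  sim <- simulateFeatureTables(hepatotoxStudyDesign(), catalog, signatures,
                               seed = seed, ...)
  logTransform(preprocessTables(sim$tables))
}

# Deterministic small matrix with class structure for model unit tests.
toyClassData <- function(seed = 42, n = 16, p = 6, shift = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("e", seq_len(n)), paste0("f", seq_len(p))))
  cls <- rep(c("a", "b"), each = n / 2)
  x[cls == "b", 1] <- x[cls == "b", 1] + shift
  x[cls == "b", 2] <- x[cls == "b", 2] - shift
  list(x = x, classes = cls)
}
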