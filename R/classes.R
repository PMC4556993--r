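#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA study generator. The defaults encode
#' the study conditions the package's analyses are validated against: 22-nt
#' mature products, a ~4:1 5P:3P arm read ratio, precise 5' / imprecise 3'
#' read ends, tandem duplicate families spaced over 0-50 kb with a short-range
#' mode, a sister species at ~1% divergence, and a global miRNA knockdown
#' averaging a -1.04 log2 fold change.
#'
#' @slot seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @slot nScaffolds,scaffoldLength genome shape (count, bp).
#' @slot nMirnas,nConserved,nFamilies planted precursor counts; `nConserved`
#'   of them are copied into the synthetic reference mature set.
#' @slot familySizes integer vector of family sizes to sample from.
#' @slot familySpacingRange,familySpacingMean tandem spacing model (bp):
#'   truncated exponential with the given mean over the given range.
#' @slot familyDivergence per-base substitution probability applied to
#'   non-founder family members.
#' @slot matureLen,loopLen hairpin anatomy (nt).
#' @slot armRatio5p3p expected 5P:3P read ratio.
#' @slot p5Precision,p3Precision probability a read end is exact.
#' @slot readsPerLibrary,backgroundFraction,nDecoys library composition;
#'   decoys are stacked degradation-like reads at non-hairpin loci.
#' @slot adapter 3' adapter appended to simulated raw reads.
#' @slot sisterMutRate per-base substitution rate of the sister genome.
#' @slot kdLog2fcMean,kdLog2fcSd knockdown effect on miRNA rows (log2 scale).
#' @slot tissueNames,nTissueSpecific,tissueFold tissue panel and the planted
#'   fold enrichment of tissue-specific rows.
#' @slot abundanceShape gamma shape of relative miRNA abundances.
#' @export
setClass("SimConfig", representation(
  seed = "integer", nScaffolds = "integer", scaffoldLength = "integer",
  nMirnas = "integer", nConserved = "integer", nFamilies = "integer",
  familySizes = "integer", familySpacingRange = "numeric",
  familySpacingMean = "numeric", familyDivergence = "numeric",
  matureLen = "integer", loopLen = "integer", armRatio5p3p = "numeric",
  p5Precision = "numeric", p3Precision = "numeric",
  readsPerLibrary = "integer", backgroundFraction = "numeric",
  nDecoys = "integer", adapter = "character", sisterMutRate = "numeric",
  kdLog2fcMean = "numeric", kdLog2fcSd = "numeric",
  tissueNames = "character", nTissueSpecific = "integer",
  tissueFold = "numeric", abundanceShape = "numeric"))

setValidity("SimConfig", function(object) {
  p <- c(object@familyDivergence, object@p5Precision, object@p3Precision,
         object@backgroundFraction, object@sisterMutRate)
  if (any(p < 0 | p > 1)) return("all probabilities must lie in [0, 1]")
  if (object@matureLen < 16L) return("matureLen must be >= 16")
  if (object@loopLen < 3L) return("loopLen must be >= 3")
  if (object@armRatio5p3p <= 0) return("armRatio5p3p must be positive")
  if (object@nConserved > object@nMirnas) return("nConserved > nMirnas")
  if (object@nTissueSpecific > object@nMirnas)
    return("nTissueSpecific > nMirnas")
  if (length(object@familySpacingRange) != 2L ||
      any(object@familySpacingRange < 0) ||
      diff(object@familySpacingRange) < 0)
    return("familySpacingRange must be an increasing non-negative pair")
  if (nchar(object@adapter) > 0 &&
      !grepl("^[ACGT]+$", object@adapter)) return("adapter must be DNA")
  TRUE
})

#' Construct a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param ... named overrides of any [SimConfig-class] slot.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nMirnas = 10L, nFamilies = 2L)
#' @export
simConfig <- function(seed = 1L, ...) {
  cfg <- new("SimConfig",
    seed = as.integer(seed), nScaffolds = 4L, scaffoldLength = 60000L,
    nMirnas = 60L, nConserved = 15L, nFamilies = 8L, familySizes = 2:4,
    familySpacingRange = c(100, 50000), familySpacingMean = 7000,
    familyDivergence = 0.13, matureLen = 22L, loopLen = 15L,
    armRatio5p3p = 4.0, p5Precision = 0.9, p3Precision = 0.5,
    readsPerLibrary = 20000L, backgroundFraction = 0.1, nDecoys = 12L,
    adapter = "TGGAATTCTCGGGTGCCAAGG", sisterMutRate = 0.01,
    kdLog2fcMean = -1.04, kdLog2fcSd = 0.3,
    tissueNames = c("pronotum", "testes", "antennae", "fat_body", "brain"),
    nTissueSpecific = 10L, tissueFold = 30, abundanceShape = 2)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% slotNames("SimConfig")) stop("unknown SimConfig field: ", nm)
    proto <- slot(cfg, nm)
    val <- dots[[nm]]
    if (is.integer(proto)) val <- as.integer(val)
    slot(cfg, nm) <- val
  }
  validObject(cfg)
  cfg
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nMirnas, " miRNAs (", object@nConserved,
      " conserved) in ", object@nFamilies, " families on ",
      object@nScaffolds, " x ", object@scaffoldLength, " bp scaffolds\n",
      "  mature ", object@matureLen, " nt, loop ", object@loopLen,
      " nt, 5P:3P ", object@armRatio5p3p, ", reads/library ",
      object@readsPerLibrary, ", seed ", object@seed, "\n", sep = "")
})

#' RNA secondary structure
#'
#' A nested (pseudoknot-free) base-pair set for one sequence, with the
#' weighted pairing energy (kcal/mol-equivalent; GC -3, AU -2, GU -1).
#'
#' @slot sequence the folded sequence (RNA alphabet).
#' @slot pairs integer matrix, one row per pair, 1-based columns i < j.
#' @slot dotBracket dot-bracket string of the structure.
#' @slot energy total pairing energy, <= 0.
#' @export
setClass("SecondaryStructure", representation(
  sequence = "character", pairs = "matrix", dotBracket = "character",
  energy = "numeric"))

setValidity("SecondaryStructure", function(object) {
  n <- nchar(object@sequence)
  p <- object@pairs
  if (nrow(p) > 0) {
    if (any(p < 1 | p > n)) return("pair index out of range")
    if (any(p[, 2] - p[, 1] - 1 < 3)) return("hairpin loop shorter than 3")
    idx <- c(p[, 1], p[, 2])
    if (anyDuplicated(idx)) return("a base participates in > 1 pair")
    # nestedness: no crossing pairs
    if (nrow(p) > 1) {
      o <- order(p[, 1])
      pi <- p[o, 1]; pj <- p[o, 2]
      for (a in seq_len(nrow(p) - 1)) {
        b <- (a + 1):nrow(p)
        if (any(pi[b] < pj[a] & pj[b] > pj[a])) return("crossing pairs")
      }
    }
  }
  if (object@energy > 1e-9) return("energy must be <= 0")
  if (nchar(object@dotBracket) != n) return("dot-bracket length mismatch")
  TRUE
})

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure (", nchar(object@sequence), " nt, ",
      nrow(object@pairs), " pairs, energy ", object@energy, ")\n", sep = "")
  if (nchar(object@sequence) <= 80) {
    cat(" ", object@sequence, "\n ", object@dotBracket, "\n", sep = "")
  }
})

#' @describeIn SecondaryStructure-class total pairing energy.
#' @param x a `SecondaryStructure`.
#' @export
structureEnergy <- function(x) x@energy

#' @describeIn SecondaryStructure-class 1-based pair matrix.
#' @export
structurePairs <- function(x) x@pairs

#' @describeIn SecondaryStructure-class dot-bracket string.
#' @export
dotBracket <- function(x) x@dotBracket
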