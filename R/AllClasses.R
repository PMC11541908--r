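#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix sparseMatrix Diagonal t rowSums colSums
#' @importFrom stats cor lm median pchisq quantile rnorm rpois runif sd setNames
#' @importFrom utils head tail
NULL

#' GenomeSpec: a binned genome
#'
#' Holds an ordered set of chromosomes, a bin size, and (optionally) a per-bin
#' GC-fraction track.  Bins tile each chromosome exactly; the last bin of a
#' chromosome may be short.  Global bin indices are 1-based and contiguous in
#' chromosome order.
#'
#' @slot chromNames ordered chromosome names.
#' @slot chromLengths chromosome lengths in bp, parallel to `chromNames`.
#' @slot binSize bin size in bp.
#' @slot gc per-bin GC fraction in `[0, 1]`, or `numeric(0)` when absent.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(
    chromNames = "character",
    chromLengths = "numeric",
    binSize = "numeric",
    gc = "numeric"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@chromNames) == 0L) {
    msg <- c(msg, "at least one chromosome required")
  }
  if (anyDuplicated(object@chromNames)) {
    msg <- c(msg, "chromosome names must be unique")
  }
  if (length(object@chromLengths) != length(object@chromNames)) {
    msg <- c(msg, "chromNames and chromLengths lengths differ")
  }
  if (any(object@chromLengths <= 0)) {
    msg <- c(msg, "chromosome lengths must be positive")
  }
  if (length(object@binSize) != 1L || object@binSize <= 0) {
    msg <- c(msg, "binSize must be a single positive number")
  } else if (length(object@chromLengths) &&
             object@binSize > min(object@chromLengths)) {
    msg <- c(msg, "binSize must not exceed the shortest chromosome")
  }
  nb <- sum(ceiling(object@chromLengths / object@binSize))
  if (length(object@gc) && length(object@gc) != nb) {
    msg <- c(msg, "gc track length must equal the number of bins")
  }
  if (length(object@gc) && any(object@gc < 0 | object@gc > 1, na.rm = TRUE)) {
    msg <- c(msg, "gc values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp), in the
#'   desired chromosome order.
#' @param binSize bin size in bp; must not exceed the shortest chromosome.
#' @param gc optional per-bin GC fraction (global bin order), e.g. from
#'   [gcFromSequences()] or [readBedGraphTrack()].
#' @return a [GenomeSpec-class] object.
#' @examples
#' gs <- GenomeSpec(c(chr1 = 1e6, chr2 = 8e5), binSize = 1e4)
#' nBins(gs)
#' @export
GenomeSpec <- function(chromLengths, binSize, gc = NULL) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths)))) {
    stop("chromLengths must be a named vector")
  }
  new("GenomeSpec",
      chromNames = names(chromLengths),
      chromLengths = unname(as.numeric(chromLengths)),
      binSize = as.numeric(binSize),
      gc = if (is.null(gc)) numeric(0) else as.numeric(gc))
}

#' ContactMatrix: binned, symmetric Hi-C counts with balancing metadata
#'
#' Raw counts are kept untouched by masking and balancing; `weights` holds the
#' multiplicative per-bin balancing factor (NA on masked bins, `numeric(0)`
#' before balancing) so that the balanced value is
#' `counts[i, j] / (weights[i] * weights[j])`.
#'
#' @slot genome the [GenomeSpec-class] the matrix is binned on.
#' @slot counts symmetric non-negative sparse matrix over global bins.
#' @slot weights per-bin balancing factor; NA for masked bins.
#' @slot mask logical per-bin; TRUE marks a bin excluded from statistics.
#' @slot metadata free-form provenance list.
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(
    genome = "GenomeSpec",
    counts = "Matrix",
    weights = "numeric",
    mask = "logical",
    metadata = "list"
  )
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  nb <- nBins(object@genome)
  if (!all(dim(object@counts) == c(nb, nb))) {
    msg <- c(msg, "counts dimensions must equal the number of bins")
  }
  if (length(object@mask) != nb) {
    msg <- c(msg, "mask length must equal the number of bins")
  }
  if (length(object@weights) && length(object@weights) != nb) {
    msg <- c(msg, "weights length must equal the number of bins")
  }
  if (length(object@weights) &&
      any(!is.na(object@weights) & object@weights <= 0)) {
    msg <- c(msg, "weights must be positive where defined")
  }
  if (min(object@counts) < 0) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (!Matrix::isSymmetric(object@counts, tol = 1e-8)) {
    msg <- c(msg, "counts must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix from a full symmetric count matrix
#'
#' @param counts symmetric non-negative matrix (base or Matrix) over the
#'   genome's global bins.
#' @param genome a [GenomeSpec-class].
#' @param weights optional per-bin balancing factors.
#' @param mask optional logical mask (TRUE = excluded); defaults to all FALSE.
#' @param metadata provenance list.
#' @return a [ContactMatrix-class].
#' @export
ContactMatrix <- function(counts, genome, weights = numeric(0),
                          mask = NULL, metadata = list()) {
  nb <- nBins(genome)
  if (is.null(mask)) mask <- rep(FALSE, nb)
  new("ContactMatrix",
      genome = genome,
      counts = methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix"),
      weights = as.numeric(weights),
      mask = mask,
      metadata = metadata)
}

#' CompartmentTrack: per-bin leading-eigenvector compartment call
#'
#' @slot genome the [GenomeSpec-class] the track is binned on.
#' @slot e1 per-bin leading eigenvector loading (NA on masked bins).
#' @slot label per-bin label, one of `"A"`, `"B"`, `"masked"`.
#' @slot borders data.frame of A/B borders (chrom, pos, from, to); `pos` is
#'   the bp coordinate of the bin edge separating the two compartments.
#' @slot mode `"cis"` or `"trans"` (which eigenvector decomposition was used).
#' @slot metadata provenance (per-chromosome GC correlations, flips, ...).
#' @exportClass CompartmentTrack
setClass("CompartmentTrack",
  representation(
    genome = "GenomeSpec",
    e1 = "numeric",
    label = "character",
    borders = "data.frame",
    mode = "character",
    metadata = "list"
  )
)

setValidity("CompartmentTrack", function(object) {
  msg <- character()
  nb <- nBins(object@genome)
  if (length(object@e1) != nb) msg <- c(msg, "e1 length must equal bins")
  if (length(object@label) != nb) msg <- c(msg, "label length must equal bins")
  if (!all(object@label %in% c("A", "B", "masked"))) {
    msg <- c(msg, "labels must be A, B or masked")
  }
  ok <- object@label != "masked"
  if (any(ok & is.na(object@e1))) {
    msg <- c(msg, "unmasked bins must carry finite e1")
  }
  if (any(object@label == "A" & !is.na(object@e1) & object@e1 <= 0) ||
      any(object@label == "B" & !is.na(object@e1) & object@e1 >= 0)) {
    msg <- c(msg, "label must match the sign of e1")
  }
  if (!object@mode %in% c("cis", "trans")) {
    msg <- c(msg, "mode must be 'cis' or 'trans'")
  }
  if (length(msg)) msg else TRUE
})

#' InsulationTrack: diamond insulation scores and boundaries
#'
#' @slot genome the [GenomeSpec-class].
#' @slot window diamond window in bp.
#' @slot score per-bin log2 insulation score (NA where the full diamond does
#'   not fit or the chromosome was skipped).
#' @slot boundaries data.frame (chrom, bin, pos, strength) of detected
#'   boundaries; empty until [detectBoundaries()] is run.
#' @exportClass InsulationTrack
setClass("InsulationTrack",
  representation(
    genome = "GenomeSpec",
    window = "numeric",
    score = "numeric",
    boundaries = "data.frame"
  )
)

#' DecayFit: fitted interaction decay exponent
#'
#' @slot distances log-binned distance centers (bp) of the full curve.
#' @slot ps contact probability P(s) at those distances.
#' @slot exponent fitted IDE (signed slope of log10 P vs log10 s).
#' @slot intercept OLS intercept.
#' @slot r2 coefficient of determination of the fit.
#' @slot fitRange `(s_min, s_max)` in bp.
#' @slot nBands number of bands used in the fit.
#' @exportClass DecayFit
setClass("DecayFit",
  representation(
    distances = "numeric",
    ps = "numeric",
    exponent = "numeric",
    intercept = "numeric",
    r2 = "numeric",
    fitRange = "numeric",
    nBands = "integer"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (any(object@ps < 0, na.rm = TRUE)) msg <- c(msg, "ps must be >= 0")
  if (length(object@fitRange) != 2L || object@fitRange[1] >= object@fitRange[2]) {
    msg <- c(msg, "fitRange must be (s_min, s_max) with s_min < s_max")
  }
  if (!is.finite(object@exponent)) msg <- c(msg, "exponent must be finite")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted parameters for the synthetic Hi-C generator
#'
#' The generator emulates, on a small genome, the architecture signals the
#' pipeline is designed to measure: power-law cis decay, a checkerboard
#' compartment structure, trans centromere/telomere clustering, an insulated
#' domain with optional elevated trans-telomere contact, an optional
#' Rabl-style arm-alignment band, and a centromere-confined repeat family.
#'
#' @slot genome the [GenomeSpec-class] simulated over.
#' @slot alpha cis decay exponent (> 0; intensity ~ s^-alpha).
#' @slot labels per-bin planted compartment labels ("A"/"B").
#' @slot fAA,fBB,fAB compartment contact factors.
#' @slot transFraction target fraction of contacts that are trans.
#' @slot centromeres named per-chromosome centromere midpoints (bp).
#' @slot centromereHalfWidth half-width of the centromeric plateau, in bins.
#' @slot betaC,betaT centromere-centromere and telomere-telomere trans boosts.
#' @slot telomereWidth width of the boosted telomeric region per end, in bins.
#' @slot insulatedRegions data.frame (chrom, start, end, delta, betaQ):
#'   cross-boundary attenuation delta in (0, 1]; betaQ multiplies trans
#'   contact between the region and telomeres.
#' @slot betaR arm-alignment (Rabl) trans boost; 1 disables it.
#' @slot rablTol relative-arm-position tolerance for the Rabl band.
#' @slot repeatFamily name of the planted centromeric repeat family.
#' @slot seed default random seed for the generator.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    genome = "GenomeSpec",
    alpha = "numeric",
    labels = "character",
    fAA = "numeric",
    fBB = "numeric",
    fAB = "numeric",
    compartmentMinDist = "numeric",
    transFraction = "numeric",
    centromeres = "numeric",
    centromereHalfWidth = "numeric",
    betaC = "numeric",
    betaT = "numeric",
    telomereWidth = "numeric",
    insulatedRegions = "data.frame",
    insulationRange = "numeric",
    betaR = "numeric",
    rablTol = "numeric",
    repeatFamily = "character",
    seed = "numeric"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (length(object@labels) != nBins(object@genome)) {
    msg <- c(msg, "labels must cover all bins")
  }
  if (any(c(object@betaC, object@betaT, object@betaR) < 1)) {
    msg <- c(msg, "boosts must be >= 1")
  }
  ins <- object@insulatedRegions
  if (nrow(ins)) {
    if (any(ins$delta <= 0 | ins$delta > 1)) {
      msg <- c(msg, "insulation delta must lie in (0, 1]")
    }
    if (any(!ins$chrom %in% object@genome@chromNames)) {
      msg <- c(msg, "insulated regions must lie on known chromosomes")
    }
  }
  if (object@transFraction <= 0 || object@transFraction >= 1) {
    msg <- c(msg, "transFraction must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})
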