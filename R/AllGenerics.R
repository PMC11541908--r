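#' @importFrom BiocGenerics counts
NULL

#' Number of bins
#' @param x a GenomeSpec or ContactMatrix
#' @return integer bin count
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bin size in bp
#' @param x a GenomeSpec or ContactMatrix
#' @return bin size in bp
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Chromosome names
#' @param x a GenomeSpec or ContactMatrix
#' @return character vector of chromosome names
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' Chromosome lengths (bp)
#' @param x a GenomeSpec or ContactMatrix
#' @return named numeric vector of lengths
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' Per-bin GC fraction track
#' @param x a GenomeSpec or ContactMatrix
#' @return numeric per-bin GC, or NULL when absent
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' Bins as GRanges
#' @param x a GenomeSpec or ContactMatrix
#' @return GRanges of bins with an `bin` metadata column (global index)
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Per-bin balancing weights
#'
#' NA on masked bins; `numeric(0)` before [iceBalance()] has been run.
#' @param x a ContactMatrix
#' @return numeric weights
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))

#' Per-bin mask (TRUE = excluded from statistics)
#' @param x a ContactMatrix
#' @return logical vector
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' Balanced contact matrix
#'
#' Dense matrix of `counts[i, j] / (weights[i] * weights[j])`, NA on masked
#' rows/columns.
#' @param x a ContactMatrix (balanced)
#' @return dense numeric matrix
#' @export
setGeneric("balancedMatrix", function(x) standardGeneric("balancedMatrix"))

#' Total contact count (sum over unordered bin pairs)
#' @param x a ContactMatrix
#' @return numeric scalar
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' Per-bin leading-eigenvector loadings
#' @param x a CompartmentTrack
#' @return numeric E1 values (NA on masked bins)
#' @export
setGeneric("e1Values", function(x) standardGeneric("e1Values"))

#' Per-bin compartment labels
#' @param x a CompartmentTrack
#' @return character vector of "A"/"B"/"masked"
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))

#' Compartment borders
#' @param x a CompartmentTrack
#' @return data.frame (chrom, pos, from, to)
#' @export
setGeneric("compartmentBorders", function(x) standardGeneric("compartmentBorders"))

#' Insulation scores
#' @param x an InsulationTrack
#' @return numeric per-bin log2 insulation score
#' @export
setGeneric("insulationScores", function(x) standardGeneric("insulationScores"))

#' Detected insulation boundaries
#' @param x an InsulationTrack
#' @return data.frame (chrom, bin, pos, strength)
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
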