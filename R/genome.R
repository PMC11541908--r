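#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# ---- GenomeSpec accessors ---------------------------------------------------

binsPerChrom <- function(genome) {
  setNames(as.integer(ceiling(genome@chromLengths / genome@binSize)),
           genome@chromNames)
}

# first global bin index of each chromosome, minus one
chromOffsets <- function(genome) {
  nb <- binsPerChrom(genome)
  setNames(c(0L, cumsum(nb))[seq_along(nb)], names(nb))
}

#' @describeIn nBins total bin count of the genome
#' @export
setMethod("nBins", "GenomeSpec", function(x) sum(binsPerChrom(x)))

#' @describeIn binSize bin size of the genome
#' @export
setMethod("binSize", "GenomeSpec", function(x) x@binSize)

#' @describeIn chromNames chromosome names of the genome
#' @export
setMethod("chromNames", "GenomeSpec", function(x) x@chromNames)

#' @describeIn chromLengths chromosome lengths of the genome
#' @export
setMethod("chromLengths", "GenomeSpec",
          function(x) setNames(x@chromLengths, x@chromNames))

#' @describeIn gcContent per-bin GC of the genome (NULL when absent)
#' @export
setMethod("gcContent", "GenomeSpec",
          function(x) if (length(x@gc)) x@gc else NULL)

#' Bin table of a genome
#'
#' @param genome a [GenomeSpec-class]
#' @return data.frame with columns chrom, start, end (1-based, inclusive),
#'   and bin (global index).
#' @export
binTable <- function(genome) {
  nb <- binsPerChrom(genome)
  chrom <- rep(genome@chromNames, nb)
  local <- unlist(lapply(nb, seq_len), use.names = FALSE)
  start <- (local - 1) * genome@binSize + 1
  len <- rep(genome@chromLengths, nb)
  end <- pmin(local * genome@binSize, len)
  data.frame(chrom = chrom, start = start, end = end,
             bin = seq_along(chrom))
}

#' @describeIn binRanges bins of the genome as GRanges
#' @export
setMethod("binRanges", "GenomeSpec", function(x) {
  bt <- binTable(x)
  gr <- GenomicRanges::GRanges(bt$chrom, IRanges::IRanges(bt$start, bt$end),
                               seqlengths = chromLengths(x))
  gr$bin <- bt$bin
  gr
})

#' Global bin index for genomic positions
#'
#' @param genome a [GenomeSpec-class]
#' @param chrom chromosome name(s)
#' @param pos 1-based position(s) in bp
#' @return integer global bin indices (NA for unknown chromosome or
#'   out-of-range position)
#' @export
binAt <- function(genome, chrom, pos) {
  off <- chromOffsets(genome)
  len <- chromLengths(genome)
  i <- match(chrom, names(off))
  ok <- !is.na(i) & pos >= 1 & pos <= len[i]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- as.integer(off[i[ok]] + ((pos[ok] - 1) %/% genome@binSize) + 1)
  out
}

#' Global bin indices of one chromosome
#'
#' @param genome a [GenomeSpec-class]
#' @param chrom chromosome name
#' @return integer vector of global bin indices
#' @export
chromBins <- function(genome, chrom) {
  nb <- binsPerChrom(genome)
  if (!chrom %in% names(nb)) stop("unknown chromosome: ", chrom)
  off <- chromOffsets(genome)[[chrom]]
  off + seq_len(nb[[chrom]])
}

# widths in bp of every bin (last bin of a chromosome may be short)
binWidths <- function(genome) {
  bt <- binTable(genome)
  bt$end - bt$start + 1
}

sameBinning <- function(a, b) {
  identical(a@chromNames, b@chromNames) &&
    isTRUE(all.equal(a@chromLengths, b@chromLengths)) &&
    isTRUE(all.equal(a@binSize, b@binSize))
}

#' Attach a GC track to a genome
#'
#' @param genome a [GenomeSpec-class]
#' @param gc numeric per-bin GC fraction
#' @return the genome with its `gc` slot filled
#' @export
setGC <- function(genome, gc) {
  genome@gc <- as.numeric(gc)
  methods::validObject(genome)
  genome
}

#' Per-bin GC fraction from chromosome sequences
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) whose
#'   names and lengths match the genome's chromosomes
#' @param genome a [GenomeSpec-class]
#' @return numeric per-bin GC fraction (global bin order); bins consisting
#'   only of non-ACGT characters get NA
#' @export
gcFromSequences <- function(seqs, genome) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  missing <- setdiff(chromNames(genome), names(seqs))
  if (length(missing)) {
    stop("sequences missing for: ", paste(missing, collapse = ", "))
  }
  bt <- binTable(genome)
  gc <- numeric(nrow(bt))
  for (ch in chromNames(genome)) {
    rows <- which(bt$chrom == ch)
    v <- Biostrings::Views(seqs[[ch]], start = bt$start[rows],
                           end = pmin(bt$end[rows], length(seqs[[ch]])))
    freq <- Biostrings::letterFrequency(v, letters = c("GC", "AT"))
    tot <- rowSums(freq)
    gc[rows] <- ifelse(tot > 0, freq[, "G|C"] / tot, NA_real_)
  }
  gc
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", length(object@chromNames), "chromosomes,",
      format(sum(object@chromLengths), big.mark = ","), "bp,",
      "bin size", format(object@binSize, big.mark = ","), "bp,",
      nBins(object), "bins",
      if (length(object@gc)) "(GC track attached)" else "", "\n")
})
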