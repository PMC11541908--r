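# Seeded synthetic Hi-C generator with planted architecture ground truth.

#' Construct a SyntheticTruth
#'
#' Defaults describe a small genome (4 chromosomes x 2 Mb at 10 kb bins)
#' carrying every architecture signal the pipeline measures: smooth
#' power-law cis decay (alpha = 0.9), a 200-kb A/B checkerboard
#' (fAA = fBB = 1.6, fAB = 0.7), ~5% trans contacts, centromere clustering
#' (betaC = 5 over a ~110 kb centromeric plateau), telomere clustering
#' (betaT = 3 over 100 kb ends), one insulated 300 kb domain
#' (delta = 0.3) with elevated trans-telomere contact (betaQ = 4), and a
#' centromere-confined repeat family.  The Rabl arm-alignment boost is off
#' (betaR = 1) by default, matching a clustered non-Rabl architecture.
#'
#' @param nChrom number of chromosomes (default 4)
#' @param chromLength chromosome length in bp (default 2 Mb)
#' @param binSize bin size in bp (default 10 kb)
#' @param alpha cis decay exponent (intensity ~ s^-alpha; default 0.9)
#' @param blockSize compartment block size in bp (default 200 kb)
#' @param fAA,fBB,fAB compartment contact factors (defaults 1.6, 1.6, 0.7)
#' @param compartmentMinDist genomic distance (bp) below which the
#'   compartment factor does not act (default 200 kb): short-range contact
#'   is dominated by polymer decay, not compartment identity, which also
#'   keeps a compartmented but domain-free genome flat at the insulation
#'   scale
#' @param transFraction target trans contact fraction (default 0.05)
#' @param centromereFractions per-chromosome centromere position as a
#'   fraction of length (recycled; default c(0.4, 0.5, 0.6, 0.45))
#' @param centromereHalfWidth centromeric plateau half-width in bins
#'   (default 5)
#' @param betaC centromere-centromere trans boost (default 5)
#' @param betaT telomere-telomere trans boost (default 3)
#' @param telomereWidth boosted telomeric width per end in bins (default 10)
#' @param insulatedRegions data.frame (chrom, start, end, delta, betaQ);
#'   default: one 300 kb domain on chr3 with delta 0.3 and betaQ 4.
#'   Use a zero-row data.frame for a TAD-free genome.
#' @param insulationRange genomic distance (bp) up to which cross-boundary
#'   attenuation acts (default 600 kb): insulation is a local, sub-Mb
#'   phenomenon, so a domain does not also dominate the chromosome-scale
#'   correlation structure
#' @param betaR Rabl arm-alignment boost (default 1 = off)
#' @param rablTol relative-arm-position tolerance of the Rabl band
#'   (default 0.05)
#' @param repeatFamily planted centromeric repeat family name
#' @param seed default generator seed
#' @return a [SyntheticTruth-class]
#' @export
syntheticTruth <- function(nChrom = 4L, chromLength = 2e6, binSize = 1e4,
                           alpha = 0.9, blockSize = 2e5,
                           fAA = 1.6, fBB = 1.6, fAB = 0.7,
                           compartmentMinDist = 2e5,
                           transFraction = 0.05,
                           centromereFractions = c(0.4, 0.5, 0.6, 0.45),
                           centromereHalfWidth = 5L,
                           betaC = 5, betaT = 3, telomereWidth = 10L,
                           insulatedRegions = data.frame(
                             chrom = "chr3", start = 1.2e6 + 1, end = 1.5e6,
                             delta = 0.3, betaQ = 4),
                           insulationRange = 6e5,
                           betaR = 1, rablTol = 0.05,
                           repeatFamily = "CRT-1", seed = 1) {
  lens <- setNames(rep(chromLength, nChrom), paste0("chr", seq_len(nChrom)))
  genome <- GenomeSpec(lens, binSize)
  bt <- binTable(genome)
  block <- ((bt$start - 1) %/% blockSize) %% 2L
  labels <- ifelse(block == 0L, "A", "B")
  cf <- rep_len(centromereFractions, nChrom)
  cens <- setNames(round(lens * cf / binSize) * binSize + binSize / 2,
                   names(lens))
  new("SyntheticTruth",
      genome = genome, alpha = alpha, labels = labels,
      fAA = fAA, fBB = fBB, fAB = fAB,
      compartmentMinDist = compartmentMinDist,
      transFraction = transFraction,
      centromeres = cens, centromereHalfWidth = centromereHalfWidth,
      betaC = betaC, betaT = betaT, telomereWidth = telomereWidth,
      insulatedRegions = insulatedRegions,
      insulationRange = insulationRange, betaR = betaR, rablTol = rablTol,
      repeatFamily = repeatFamily, seed = seed)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(chromNames(object@genome)),
      "chromosomes,", nBins(object@genome), "bins; alpha =", object@alpha,
      "; betaC =", object@betaC, "; betaT =", object@betaT,
      "; trans fraction =", object@transFraction, "\n")
})

# per-chromosome bin index of the centromere midpoint
truthCentromereBins <- function(truth) {
  vapply(chromNames(truth@genome), function(ch) {
    local <- binAt(truth@genome, ch, truth@centromeres[[ch]]) -
      chromOffsets(truth@genome)[[ch]]
    as.integer(local)
  }, integer(1))
}

# logical per-bin indicators used by the intensity model
truthIndicators <- function(truth) {
  genome <- truth@genome
  nb <- nBins(genome)
  nbc <- binsPerChrom(genome)
  off <- chromOffsets(genome)
  cenBin <- truthCentromereBins(truth)
  isCen <- isTel <- rep(FALSE, nb)
  relPos <- rep(NA_real_, nb)
  for (ch in chromNames(genome)) {
    n <- nbc[[ch]]
    loc <- seq_len(n)
    g <- off[[ch]] + loc
    isCen[g] <- abs(loc - cenBin[[ch]]) <= truth@centromereHalfWidth
    isTel[g] <- loc <= truth@telomereWidth | loc > n - truth@telomereWidth
    # relative arm position: centromere at 0.5
    cb <- cenBin[[ch]]
    relPos[g] <- ifelse(loc <= cb, 0.5 * (loc - 0.5) / cb,
                        0.5 + 0.5 * (loc - cb - 0.5) / (n - cb))
  }
  isIns <- rep(FALSE, nb)
  insQ <- rep(1, nb)
  ins <- truth@insulatedRegions
  for (k in seq_len(nrow(ins))) {
    b <- regionBins(genome, ins$chrom[k], ins$start[k], ins$end[k])
    isIns[b] <- TRUE
    insQ[b] <- ins$betaQ[k]
  }
  list(isCen = isCen, isTel = isTel, isIns = isIns, insQ = insQ,
       relPos = relPos)
}

#' Simulate a Hi-C contact map from planted truth
#'
#' Expected cis intensity is `s^-alpha * f(label_i, label_j) * ins(i, j)`
#' where `ins = delta` when exactly one bin lies inside an insulated region;
#' the compartment factor is divided by its exact per-distance mean so the
#' planted exponent remains the true P(s) slope.  Expected trans intensity
#' is `t0 * boost(i, j)` with boosts betaC (centromere x centromere), betaT
#' (telomere x telomere), betaQ (insulated region x telomere) and betaR
#' (equal relative arm position, Rabl mode); `t0` is set so the expected
#' trans share equals the truth's `transFraction`.  Counts are independent
#' Poisson draws scaled so the expected total equals `depth`.
#'
#' @param truth a [SyntheticTruth-class]
#' @param depth expected total contact count (default 1e6; must be >= 1e4)
#' @param seed RNG seed (default: the truth's seed)
#' @return an unbalanced [ContactMatrix-class] (deterministic for a fixed
#'   seed and truth)
#' @export
simulateContactMap <- function(truth, depth = 1e6, seed = truth@seed) {
  if (depth < 1e4) stop("depth must be at least 1e4")
  methods::validObject(truth)
  genome <- truth@genome
  nb <- nBins(genome)
  ind <- truthIndicators(truth)
  fmap <- matrix(c(truth@fAA, truth@fAB, truth@fAB, truth@fBB), 2, 2)
  labNum <- ifelse(truth@labels == "A", 1L, 2L)
  lamCis <- matrix(0, nb, nb)
  for (ch in chromNames(genome)) {
    g <- chromBins(genome, ch)
    n <- length(g)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    base <- pmax(d, 0.5)^(-truth@alpha)
    f <- fmap[cbind(rep(labNum[g], n), rep(labNum[g], each = n))]
    f <- matrix(f, n, n)
    # compartment identity shapes contact only beyond the short range that
    # polymer decay dominates (keeps domain-free genomes flat at the
    # insulation scale)
    f[d <= truth@compartmentMinDist / binSize(genome)] <- 1
    insF <- matrix(1, n, n)
    insRangeBins <- truth@insulationRange / binSize(genome)
    for (k in seq_len(nrow(truth@insulatedRegions))) {
      reg <- truth@insulatedRegions[k, ]
      if (reg$chrom != ch) next
      b <- regionBins(genome, reg$chrom, reg$start, reg$end)
      inR <- g %in% b
      oneK <- xor(outer(inR, inR, "&"), outer(inR, inR, "|")) &
        d <= insRangeBins
      insF[oneK] <- insF[oneK] * reg$delta
    }
    # decay-neutralise the combined modulation: divide by its exact mean at
    # each distance so the planted exponent stays the true P(s) slope
    f <- f * insF
    gbar <- vapply(0:(n - 1L), function(dd) {
      ii <- seq_len(n - dd)
      mean(f[cbind(ii, ii + dd)])
    }, numeric(1))
    fN <- f / matrix(gbar[d + 1L], n, n)
    lamCis[g, g] <- base * fN
  }
  lamTrans <- matrix(0, nb, nb)
  chroms <- chromNames(genome)
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (a >= b) next
      ia <- chromBins(genome, chroms[a])
      ib <- chromBins(genome, chroms[b])
      boost <- matrix(1, length(ia), length(ib))
      boost <- boost *
        ifelse(outer(ind$isCen[ia], ind$isCen[ib], "&"), truth@betaC, 1)
      boost <- boost *
        ifelse(outer(ind$isTel[ia], ind$isTel[ib], "&"), truth@betaT, 1)
      qa <- ifelse(outer(ind$isIns[ia] , ind$isTel[ib], "&"),
                   outer(ind$insQ[ia], rep(1, length(ib))), 1)
      qb <- ifelse(outer(ind$isTel[ia], ind$isIns[ib], "&"),
                   outer(rep(1, length(ia)), ind$insQ[ib]), 1)
      boost <- boost * qa * qb
      if (truth@betaR > 1) {
        near <- abs(outer(ind$relPos[ia], ind$relPos[ib], "-")) <=
          truth@rablTol
        boost <- boost * ifelse(near, truth@betaR, 1)
      }
      lamTrans[ia, ib] <- boost
      lamTrans[ib, ia] <- t(boost)
    }
  }
  sumCis <- upperSum(lamCis)
  sumTrans <- upperSum(lamTrans)
  t0 <- if (sumTrans > 0) {
    truth@transFraction / (1 - truth@transFraction) * sumCis / sumTrans
  } else 0
  lam <- lamCis + t0 * lamTrans
  lam <- lam * (depth / upperSum(lam))
  counts <- withSeed(seed, {
    up <- matrix(0, nb, nb)
    sel <- upper.tri(lam, diag = TRUE)
    up[sel] <- rpois(sum(sel), lam[sel])
    up + t(up) - diag(diag(up))
  })
  ContactMatrix(counts, genome,
                metadata = list(simulated = TRUE, depth = depth,
                                seed = seed, alpha = truth@alpha,
                                transFraction = truth@transFraction))
}

#' Simulate matched feature tracks for a planted truth
#'
#' Generates the side-channel data the integration and annotation modules
#' consume: a per-bin GC track correlated with the planted compartments, a
#' gene table with log-normal TPM (A-shifted) and differential-expression
#' columns with a planted sex-biased fraction, activation- and
#' repressive-mark peak tables with compartment-shifted fold enrichment, a
#' repeat annotation whose planted family is confined to centromere spans,
#' and (optionally) chromosome sequences with telomeric tracts planted at
#' chosen ends.  Sequences are random apart from the planted telomere
#' motifs; their base composition does not reproduce the GC track.
#'
#' @param truth a [SyntheticTruth-class]
#' @param nGenes number of genes (default 1000)
#' @param nPeaksPerMark peaks per histone mark (default 300)
#' @param gcMeanA,gcMeanB,gcSd GC model per compartment (defaults 0.55,
#'   0.50, 0.01)
#' @param exprMeanA,exprMeanB,exprSd log2(TPM+1) model per compartment
#'   (defaults 4, 2, 1)
#' @param markShift log2 fold-enrichment shift added in the favoured
#'   compartment (default 1; 0 gives null tracks)
#' @param sbgFraction planted fraction of sex-biased genes (default 0.1)
#' @param telomereEnds named list of planted telomeric ends per chromosome
#'   (subset of c("5p", "3p")); default plants both ends of chr1 and chr2
#'   and the 3' end of chr3
#' @param telomereCopies motif copies planted per tract (default 30)
#' @param fasta generate chromosome sequences (default TRUE)
#' @param seed RNG seed (default: the truth's seed + 1)
#' @return list: `genome` (GC attached), `gc`, `genes`, `peaks`,
#'   `repeats`, `sequences` (DNAStringSet or NULL), `telomereEnds`
#' @export
simulateFeatureTracks <- function(truth, nGenes = 1000L,
                                  nPeaksPerMark = 300L,
                                  gcMeanA = 0.55, gcMeanB = 0.50,
                                  gcSd = 0.01,
                                  exprMeanA = 4, exprMeanB = 2, exprSd = 1,
                                  markShift = 1, sbgFraction = 0.1,
                                  telomereEnds = list(
                                    chr1 = c("5p", "3p"),
                                    chr2 = c("5p", "3p"),
                                    chr3 = "3p"),
                                  telomereCopies = 30L,
                                  fasta = TRUE, seed = truth@seed + 1) {
  genome <- truth@genome
  bt <- binTable(genome)
  lens <- chromLengths(genome)
  isA <- truth@labels == "A"
  cenBin <- truthCentromereBins(truth)
  hw <- truth@centromereHalfWidth * binSize(genome)
  withSeed(seed, {
    gc <- pmin(1, pmax(0, rnorm(nBins(genome),
                                ifelse(isA, gcMeanA, gcMeanB), gcSd)))
    labelAt <- function(chrom, pos) {
      truth@labels[binAt(genome, chrom, pmin(pos, lens[chrom]))]
    }
    # genes
    gch <- sample(names(lens), nGenes, replace = TRUE,
                  prob = lens / sum(lens))
    gw <- round(runif(nGenes, 500, 3000))
    gst <- floor(runif(nGenes, 1, lens[gch] - gw))
    glab <- labelAt(gch, floor(gst + gw / 2))
    l2tpm <- pmax(0, rnorm(nGenes, ifelse(glab == "A", exprMeanA,
                                          exprMeanB), exprSd))
    nSBG <- round(sbgFraction * nGenes)
    sbgIdx <- sample(nGenes, nSBG)
    lfc <- rnorm(nGenes, 0, 0.4)
    padj <- runif(nGenes, 0.02, 1)
    half <- length(sbgIdx) %/% 2L
    lfc[sbgIdx[seq_len(half)]] <- runif(half, 1, 3)
    lfc[sbgIdx[-seq_len(half)]] <- -runif(length(sbgIdx) - half, 1, 3)
    padj[sbgIdx] <- runif(length(sbgIdx), 0, 0.009)
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nGenes)),
                        chrom = gch, start = gst, end = gst + gw - 1,
                        TPM = 2^l2tpm - 1, log2FC = lfc, padj = padj)
    # peaks: activation mark favours A, repressive mark favours B
    mkPeaks <- function(mark, favour) {
      pch <- sample(names(lens), nPeaksPerMark, replace = TRUE,
                    prob = lens / sum(lens))
      pw <- round(runif(nPeaksPerMark, 1000, 3000))
      pst <- floor(runif(nPeaksPerMark, 1, lens[pch] - pw))
      plab <- labelAt(pch, floor(pst + pw / 2))
      l2fe <- rnorm(nPeaksPerMark, 1, 0.5) +
        markShift * (plab == favour)
      data.frame(chrom = pch, start = pst, end = pst + pw - 1,
                 mark = mark, fold_enrichment = 2^l2fe)
    }
    peaks <- rbind(mkPeaks("H3K4me3", "A"), mkPeaks("H3K79me2", "B"))
    # repeats: planted centromeric family + scattered background families
    repRows <- list()
    for (ch in names(lens)) {
      cen <- truth@centromeres[[ch]]
      nC <- sample(4:10, 1)
      w <- round(runif(nC, 800, 2000))
      st <- floor(runif(nC, max(1, cen - hw), cen + hw - w))
      repRows[[ch]] <- data.frame(chrom = ch, start = st, end = st + w - 1,
                                  family = truth@repeatFamily,
                                  class = "interspersed")
    }
    bgFam <- function(family, class, n, wlo, whi) {
      ch <- sample(names(lens), n, replace = TRUE)
      w <- round(runif(n, wlo, whi))
      st <- floor(runif(n, 1, lens[ch] - w))
      data.frame(chrom = ch, start = st, end = st + w - 1,
                 family = family, class = class)
    }
    repeats <- rbind(do.call(rbind, repRows),
                     bgFam("LTR-X", "interspersed", 120, 1000, 5000),
                     bgFam("DNA-Y", "interspersed", 80, 500, 2000),
                     bgFam("Sat-Z", "tandem", 50, 200, 2000),
                     bgFam("simple", "low_complexity", 40, 100, 500))
    rownames(repeats) <- NULL
    # sequences with planted telomeric tracts
    sequences <- NULL
    if (fasta) {
      motif <- "TTAGGG"
      rcMotif <- "CCCTAA"
      sequences <- Biostrings::DNAStringSet(vapply(names(lens), function(ch) {
        s <- paste(sample(c("A", "C", "G", "T"), lens[[ch]],
                          replace = TRUE), collapse = "")
        ends <- telomereEnds[[ch]]
        if ("5p" %in% ends) {
          tr <- strrep(rcMotif, telomereCopies)
          substr(s, 1, nchar(tr)) <- tr
        }
        if ("3p" %in% ends) {
          tr <- strrep(motif, telomereCopies)
          substr(s, nchar(s) - nchar(tr) + 1, nchar(s)) <- tr
        }
        s
      }, character(1)))
    }
    list(genome = setGC(genome, gc), gc = gc, genes = genes, peaks = peaks,
         repeats = repeats, sequences = sequences,
         telomereEnds = telomereEnds)
  })
}

#' Truth centromere bins at an arbitrary bin size
#'
#' Helper for recovery tests: the global bin index containing each planted
#' centromere midpoint on a genome binned at `binSize`.
#'
#' @param truth a [SyntheticTruth-class]
#' @param genome a [GenomeSpec-class] over the same chromosomes (defaults
#'   to the truth's genome)
#' @return named integer vector of global bin indices
#' @export
truthCentromereGlobalBins <- function(truth, genome = truth@genome) {
  vapply(chromNames(genome), function(ch) {
    binAt(genome, ch, truth@centromeres[[ch]])
  }, integer(1))
}
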