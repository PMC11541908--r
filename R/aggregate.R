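# Centromere-centred aggregate chromosomal analysis (ACA), clustering
# scores, Rabl/non-Rabl classification, per-pair trans enrichment, and
# region-to-telomere contact tests.

# area-weighted mapping matrix from source bins (bp intervals) to nPseudo/2
# pseudo-bins covering [armStart, armEnd); rows normalised to sum 1
armMapping <- function(genome, chrom, armStart, armEnd, nHalf) {
  bt <- binTable(genome)
  rows <- which(bt$chrom == chrom)
  src0 <- bt$start[rows] - 1   # 0-based half-open source bins
  src1 <- bt$end[rows]
  edges <- seq(armStart, armEnd, length.out = nHalf + 1L)
  W <- matrix(0, nHalf, length(rows))
  for (t in seq_len(nHalf)) {
    ov <- pmax(0, pmin(src1, edges[t + 1L]) - pmax(src0, edges[t]))
    s <- sum(ov)
    if (s > 0) W[t, ] <- ov / s
  }
  W
}

# pseudo-bin mapping for a whole chromosome: p arm -> rows 1..H, q arm ->
# rows H+1..nPseudo, centromere at the H | H+1 boundary
chromMapping <- function(genome, chrom, cenBp, nPseudo) {
  H <- nPseudo / 2L
  len <- chromLengths(genome)[[chrom]]
  rbind(armMapping(genome, chrom, 0, cenBp, H),
        armMapping(genome, chrom, cenBp, len, H))
}

#' Aggregate chromosomal analysis (ACA)
#'
#' Each chromosome arm is linearly rescaled to `nPseudo / 2` pseudo-bins
#' (p arm left, q arm right) so the centromere sits at the centre; pseudo-cell
#' values are area-weighted means of the contributing O/E cells, averaged over
#' all chromosomes (intra) and all ordered chromosome pairs (inter).
#'
#' @param m a balanced [ContactMatrix-class]
#' @param centromeres named per-chromosome centromere midpoints in bp,
#'   strictly inside each chromosome
#' @param nPseudo even number of pseudo-bins (default 100)
#' @param oe optional precomputed O/E matrix
#' @return list with `intra` and `inter` `AggregateMap`s (each: `map`,
#'   `kind`, `n`, `nPseudo`)
#' @export
aca <- function(m, centromeres, nPseudo = 100L, oe = NULL) {
  if (nPseudo %% 2L != 0L) stop("nPseudo must be even")
  if (is.null(oe)) oe <- observedOverExpected(m)
  chroms <- intersect(chromNames(m), names(centromeres))
  if (!length(chroms)) stop("no centromeres on known chromosomes")
  lens <- chromLengths(m)
  bs <- binSize(m)
  maps <- list()
  for (ch in chroms) {
    cen <- centromeres[[ch]]
    if (cen <= 0 || cen >= lens[[ch]]) {
      stop("centromere of ", ch, " must be strictly inside the chromosome")
    }
    if (cen < 2 * bs || lens[[ch]] - cen < 2 * bs) {
      warning("chromosome ", ch, " has an arm shorter than 2 bins; excluded")
      next
    }
    maps[[ch]] <- chromMapping(m@genome, ch, cen, nPseudo)
  }
  if (!length(maps)) stop("no chromosomes usable for ACA")
  used <- names(maps)
  num <- den <- matrix(0, nPseudo, nPseudo)
  for (ch in used) {
    idx <- chromBins(m@genome, ch)
    A <- oe[idx, idx, drop = FALSE]
    ind <- !is.na(A)
    A[!ind] <- 0
    W <- maps[[ch]]
    num <- num + W %*% A %*% t(W)
    den <- den + W %*% ind %*% t(W)
  }
  intra <- ifelse(den > 0, num / den, NA_real_)
  numI <- denI <- matrix(0, nPseudo, nPseudo)
  nPairs <- 0L
  if (length(used) > 1L) {
    for (a in used) {
      for (b in used) {
        if (a == b) next
        ia <- chromBins(m@genome, a)
        ib <- chromBins(m@genome, b)
        A <- oe[ia, ib, drop = FALSE]
        ind <- !is.na(A)
        A[!ind] <- 0
        numI <- numI + maps[[a]] %*% A %*% t(maps[[b]])
        denI <- denI + maps[[a]] %*% ind %*% t(maps[[b]])
        nPairs <- nPairs + 1L
      }
    }
  }
  inter <- ifelse(denI > 0, numI / denI, NA_real_)
  list(
    intra = structure(list(map = intra, kind = "intra", n = length(used),
                           nPseudo = nPseudo), class = "AggregateMap"),
    inter = structure(list(map = inter, kind = "inter", n = nPairs,
                           nPseudo = nPseudo), class = "AggregateMap"))
}

#' @export
print.AggregateMap <- function(x, ...) {
  cat("AggregateMap (", x$kind, "): ", x$nPseudo, "x", x$nPseudo,
      " pseudo-bins, averaged over ", x$n,
      if (x$kind == "intra") " chromosomes\n" else " chromosome pairs\n",
      sep = "")
  invisible(x)
}

# index sets used by clusterScores: centre (C) and corner (T) squares
acaWindows <- function(nPseudo, window) {
  H <- nPseudo / 2L
  w2 <- floor(window / 2)
  centre <- (H - w2):(H - w2 + window - 1L)
  corner1 <- seq_len(window)
  corner2 <- (nPseudo - window + 1L):nPseudo
  inC <- matrix(FALSE, nPseudo, nPseudo)
  inC[centre, centre] <- TRUE
  inT <- matrix(FALSE, nPseudo, nPseudo)
  inT[corner1, corner1] <- TRUE
  inT[corner1, corner2] <- TRUE
  inT[corner2, corner1] <- TRUE
  inT[corner2, corner2] <- TRUE
  list(inC = inC, inT = inT)
}

#' Centromere/telomere clustering scores of an inter-chromosomal aggregate
#'
#' `ccScore` is the mean of the central window over the background mean (the
#' aggregate excluding the centromere and telomere windows), `ttScore` the
#' mean of the four corner windows over background, and
#' `armAlignmentScore` the mean of the main-diagonal band (equal relative arm
#' position, C/T windows excluded) over background -- the Rabl signature.
#'
#' @param inter an inter `AggregateMap` from [aca()]
#' @param window window size in pseudo-bins (default 5)
#' @param tauC,tauR classification thresholds passed to
#'   [classifyConfiguration()]
#' @return a `ClusterScores` list: `ccScore`, `ttScore`,
#'   `armAlignmentScore`, `background`, `call`
#' @export
clusterScores <- function(inter, window = 5L, tauC = 1.5, tauR = 1.5) {
  M <- inter$map
  n <- inter$nPseudo
  win <- acaWindows(n, window)
  bg <- meanNA(M[!win$inC & !win$inT])
  if (is.na(bg) || bg <= 0) stop("aggregate background undefined")
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  band <- dmat <= floor(window / 2) & !win$inC & !win$inT
  s <- list(
    ccScore = meanNA(M[win$inC]) / bg,
    ttScore = meanNA(M[win$inT]) / bg,
    armAlignmentScore = meanNA(M[band]) / bg,
    background = bg)
  s$call <- classifyConfiguration(s$ccScore, s$ttScore, s$armAlignmentScore,
                                  tauC = tauC, tauR = tauR)
  structure(s, class = "ClusterScores")
}

#' @export
print.ClusterScores <- function(x, ...) {
  cat(sprintf(
    "ClusterScores: C-C %.2f, T-T %.2f, arm alignment %.2f -> %s\n",
    x$ccScore, x$ttScore, x$armAlignmentScore, x$call))
  invisible(x)
}

#' Classify the chromosomal configuration
#'
#' `clustered-non-Rabl` when centromere and telomere clustering both exceed
#' `tauC` while the arm-alignment score stays below `tauR`; `Rabl-like` when
#' the arm-alignment score reaches `tauR`; `dispersed` otherwise.
#'
#' @param cc,tt,arm centromere, telomere and arm-alignment scores
#' @param tauC clustering threshold (default 1.5)
#' @param tauR arm-alignment (Rabl) threshold (default 1.5)
#' @return one of "clustered-non-Rabl", "Rabl-like", "dispersed"
#' @export
classifyConfiguration <- function(cc, tt, arm, tauC = 1.5, tauR = 1.5) {
  if (arm >= tauR) return("Rabl-like")
  if (cc >= tauC && tt >= tauC) return("clustered-non-Rabl")
  "dispersed"
}

#' Per-chromosome-pair trans enrichment
#'
#' Mean log2 trans O/E over unmasked, positive cells for every chromosome
#' pair (symmetric table); a chromosome's row mean flags globally enriched
#' chromosomes.  The expectation here is the *global* mean balanced trans
#' value, not the per-pair mean: a per-pair expectation would cancel
#' exactly the pair-level enrichment this table measures.
#'
#' @param m a balanced [ContactMatrix-class]
#' @return symmetric matrix of mean log2 O/E (NA diagonal)
#' @export
transEnrichmentByPair <- function(m) {
  B <- balancedMatrix(m)
  chroms <- chromNames(m)
  idx <- lapply(chroms, function(ch) chromBins(m@genome, ch))
  allTrans <- unlist(lapply(seq_along(chroms), function(a) {
    unlist(lapply(seq_along(chroms), function(b) {
      if (a >= b) return(NULL)
      as.vector(B[idx[[a]], idx[[b]]])
    }))
  }))
  globalExpected <- meanNA(allTrans)
  if (is.na(globalExpected) || globalExpected <= 0) {
    stop("no trans contacts to form an expectation")
  }
  out <- matrix(NA_real_, length(chroms), length(chroms),
                dimnames = list(chroms, chroms))
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (a >= b) next
      vals <- B[idx[[a]], idx[[b]]] / globalExpected
      vals <- vals[!is.na(vals) & vals > 0]
      out[a, b] <- out[b, a] <- if (length(vals)) mean(log2(vals)) else NA
    }
  }
  out
}

#' Telomere bin indices of a genome
#'
#' @param genome a [GenomeSpec-class]
#' @param nTel bins per chromosome end (default 2)
#' @return integer global bin indices
#' @export
telomereBins <- function(genome, nTel = 2L) {
  sort(unique(unlist(telomereBinIndices(genome, nTel), use.names = FALSE)))
}

#' Sample control regions of matched length
#'
#' Uniformly placed single-chromosome intervals of width `width`, avoiding
#' an exclusion set of bins (e.g. telomeres and the query itself).
#'
#' @param genome a [GenomeSpec-class]
#' @param width region width in bp
#' @param n number of regions
#' @param excludeBins global bin indices a control may not overlap
#' @param seed RNG seed
#' @return data.frame (chrom, start, end)
#' @export
sampleControlRegions <- function(genome, width, n, excludeBins = integer(0),
                                 seed = 1) {
  lens <- chromLengths(genome)
  ok <- names(lens)[lens > width + 2 * binSize(genome)]
  if (!length(ok)) stop("no chromosome long enough for control regions")
  withSeed(seed, {
    out <- vector("list", n)
    k <- 0L
    guard <- 0L
    while (k < n && guard < 50L * n) {
      guard <- guard + 1L
      ch <- sample(ok, 1L)
      st <- floor(runif(1, 1, lens[[ch]] - width))
      bins <- regionBins(genome, ch, st, st + width - 1)
      if (length(intersect(bins, excludeBins))) next
      k <- k + 1L
      out[[k]] <- data.frame(chrom = ch, start = st, end = st + width - 1)
    }
    if (k < n) stop("could not place ", n, " control regions")
    do.call(rbind, out)
  })
}

#' Trans contact between a region and telomeres, with an empirical test
#'
#' The score is the mean trans O/E between the query's bins and telomere
#' bins on *other* chromosomes.  The null distribution comes from matched-
#' length control regions (supplied and/or sampled); the empirical p uses the
#' add-one rule and is therefore never 0.
#'
#' @param m a balanced [ContactMatrix-class]
#' @param queryRegion list or data.frame row with `chrom`, `start`, `end`
#'   (single chromosome)
#' @param telomereBinsIdx global bin indices of telomeres (default: terminal
#'   2 bins of every chromosome end)
#' @param controlRegions optional data.frame (chrom, start, end) of matched-
#'   length controls; when fewer than `nPerm`, additional matched-length
#'   regions are sampled (seeded) to reach `nPerm` null draws
#' @param nPerm total null draws (default 1000)
#' @param seed RNG seed for control sampling
#' @param oe optional precomputed O/E matrix
#' @return list: `score`, `empiricalP`, `nullScores`, `nNull`
#' @export
regionTelomereContact <- function(m, queryRegion, telomereBinsIdx = NULL,
                                  controlRegions = NULL, nPerm = 1000,
                                  seed = 1, oe = NULL) {
  if (is.null(oe)) oe <- observedOverExpected(m)
  if (is.null(telomereBinsIdx)) telomereBinsIdx <- telomereBins(m@genome)
  bt <- binTable(m@genome)
  scoreOf <- function(chrom, start, end) {
    q <- regionBins(m@genome, chrom, start, end)
    q <- q[!m@mask[q]]
    tel <- setdiff(telomereBinsIdx, chromBins(m@genome, chrom))
    tel <- tel[!m@mask[tel]]
    if (!length(tel)) stop("no trans telomere bins available")
    meanNA(oe[q, tel, drop = FALSE])
  }
  score <- scoreOf(queryRegion$chrom, queryRegion$start, queryRegion$end)
  width <- queryRegion$end - queryRegion$start + 1
  qBins <- regionBins(m@genome, queryRegion$chrom,
                      queryRegion$start, queryRegion$end)
  nullScores <- numeric(0)
  if (!is.null(controlRegions) && nrow(controlRegions)) {
    nullScores <- vapply(seq_len(nrow(controlRegions)), function(k) {
      scoreOf(controlRegions$chrom[k], controlRegions$start[k],
              controlRegions$end[k])
    }, numeric(1))
  }
  nMore <- max(0L, nPerm - length(nullScores))
  if (nMore > 0L) {
    extra <- sampleControlRegions(m@genome, width, nMore,
                                  excludeBins = c(telomereBinsIdx, qBins),
                                  seed = seed)
    nullScores <- c(nullScores, vapply(seq_len(nrow(extra)), function(k) {
      scoreOf(extra$chrom[k], extra$start[k], extra$end[k])
    }, numeric(1)))
  }
  nullScores <- nullScores[!is.na(nullScores)]
  if (!length(nullScores)) stop("no usable control regions")
  p <- (1 + sum(nullScores >= score)) / (1 + length(nullScores))
  list(score = score, empiricalP = p, nullScores = nullScores,
       nNull = length(nullScores))
}
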