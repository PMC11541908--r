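# Hi-C centromere localisation, centromeric repeat-family discovery from
# annotations, centromere spans and composition, telomeric tract detection.

# boxcar-smooth the trans blocks of an O/E matrix (NA-aware); smoothBins = 0
# leaves the matrix untouched
smoothTransOE <- function(oe, genome, smoothBins = 1L) {
  if (smoothBins <= 0L) return(oe)
  out <- oe
  chroms <- chromNames(genome)
  k <- 2L * smoothBins + 1L
  box <- function(M) {
    num <- M
    num[is.na(num)] <- 0
    ind <- !is.na(M) + 0
    cs <- function(X) {
      X <- apply(X, 2L, function(col) stats::filter(col, rep(1, k),
                                                    sides = 2))
      t(apply(X, 1L, function(row) stats::filter(row, rep(1, k),
                                                 sides = 2)))
    }
    sm <- cs(num) / cs(ind)
    sm
  }
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (a == b) next
      ia <- chromBins(genome, chroms[a])
      ib <- chromBins(genome, chroms[b])
      out[ia, ib] <- box(oe[ia, ib, drop = FALSE])
    }
  }
  out
}

#' Locate candidate centromere bins from trans Hi-C contacts
#'
#' Centromeres of different chromosomes cluster in trans; the candidate bin
#' of each chromosome is the fixed point of the iterative update
#' `c_i <- argmax_b sum_{j != i} transOE(b, c_j)`, initialised at each
#' chromosome's maximal total-trans bin, with ties broken to the lowest bin
#' index.  Trans O/E is locally averaged over `+-smoothBins` bins before
#' scoring (NA-aware boxcar), which stabilises single-cell noise.
#'
#' @param m a balanced [ContactMatrix-class] with >= 2 chromosomes
#' @param smoothBins half-width of an optional NA-aware boxcar smoother in
#'   bins (default 0: at the coarse resolutions this operation is meant for,
#'   cells hold enough counts and smoothing only dilutes a narrow
#'   centromeric plateau)
#' @param maxRounds maximum update sweeps (default 50)
#' @param enrichmentFloor a chromosome whose converged score is below
#'   `enrichmentFloor` times the mean score over its bins is flagged
#'   `enriched = FALSE` ("no enrichment")
#' @param excludeTerminalBins number of bins at each chromosome end barred
#'   from candidacy (default 2): telomere clustering and the balancing
#'   edge effect (end bins compensate their missing cis contacts with
#'   inflated trans values) otherwise masquerade as a trans cluster
#' @param oe optional precomputed O/E matrix
#' @return data.frame (chrom, bin = within-chromosome index, globalBin,
#'   pos = bin midpoint bp, score, enriched, converged)
#' @export
locateCentromeresHiC <- function(m, smoothBins = 0L, maxRounds = 50L,
                                 enrichmentFloor = 1.2,
                                 excludeTerminalBins = 2L, oe = NULL) {
  chroms <- chromNames(m)
  if (length(chroms) < 2L) stop("at least 2 chromosomes required")
  if (is.null(oe)) oe <- observedOverExpected(m)
  S <- smoothTransOE(oe, m@genome, smoothBins)
  for (ch in chroms) {
    idx <- chromBins(m@genome, ch)
    S[idx, idx] <- NA_real_
  }
  if (all(is.na(S)) || sum(S, na.rm = TRUE) == 0) {
    stop("no trans contacts available")
  }
  idxList <- lapply(chroms, function(ch) {
    idx <- chromBins(m@genome, ch)
    k <- excludeTerminalBins
    if (length(idx) > 2L * k + 1L && k > 0L) {
      idx <- idx[(k + 1L):(length(idx) - k)]
    }
    idx
  })
  names(idxList) <- chroms
  refine <- function(cand) {
    conv <- FALSE
    for (round in seq_len(maxRounds)) {
      changed <- FALSE
      for (i in seq_along(chroms)) {
        rows <- idxList[[chroms[i]]]
        sc <- rowSums(S[rows, cand[-i], drop = FALSE], na.rm = TRUE)
        best <- rows[which.max(sc)]  # which.max takes the lowest on ties
        if (best != cand[i]) {
          cand[i] <- best
          changed <- TRUE
        }
      }
      if (!changed) {
        conv <- TRUE
        break
      }
    }
    list(cand = cand, converged = conv)
  }
  objective <- function(cand) {
    tot <- 0
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i < j) {
          v <- S[cand[i], cand[j]]
          if (!is.na(v)) tot <- tot + v
        }
      }
    }
    tot
  }
  # primary start: maximal total trans bin per chromosome
  init <- vapply(chroms, function(ch) {
    rows <- idxList[[ch]]
    tot <- rowMeans(S[rows, , drop = FALSE], na.rm = TRUE)
    tot[is.na(tot)] <- -Inf
    rows[which.max(tot)]
  }, integer(1))
  best <- refine(init)
  bestObj <- objective(best$cand)
  # restarts anchored at every bin of the first chromosome: coordinate
  # ascent has local optima (e.g. the telomere cluster), the global
  # maximiser is wanted
  for (b1 in idxList[[1L]]) {
    cand <- init
    cand[1L] <- b1
    for (i in seq_along(chroms)[-1L]) {
      rows <- idxList[[chroms[i]]]
      sc <- S[rows, b1]
      sc[is.na(sc)] <- -Inf
      cand[i] <- rows[which.max(sc)]
    }
    r <- refine(cand)
    o <- objective(r$cand)
    if (o > bestObj + 1e-12) {
      best <- r
      bestObj <- o
    }
  }
  cand <- best$cand
  converged <- best$converged
  bt <- binTable(m@genome)
  res <- lapply(seq_along(chroms), function(i) {
    rows <- idxList[[chroms[i]]]
    sc <- rowSums(S[rows, cand[-i], drop = FALSE], na.rm = TRUE)
    bg <- mean(sc[is.finite(sc)])
    top <- sc[match(cand[i], rows)]
    data.frame(chrom = chroms[i],
               bin = match(cand[i], chromBins(m@genome, chroms[i])),
               globalBin = cand[i],
               pos = floor((bt$start[cand[i]] + bt$end[cand[i]]) / 2),
               score = top,
               enriched = is.finite(bg) && bg > 0 &&
                 top >= enrichmentFloor * bg,
               converged = converged)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scan repeat families for centromere specificity and ubiquity
#'
#' A family passes when (i) at least `minSpecificity` of its genome-wide
#' copies fall inside the candidate centromeric windows and (ii) at least
#' `minChromFraction` of the windowed chromosomes carry a copy in their
#' window.  Families are ranked by specificity times in-window copy count.
#' A copy is "inside" a window when its midpoint is.
#'
#' @param repeats data.frame (chrom, start, end, family, class)
#' @param windows data.frame (chrom, start, end), one candidate window per
#'   chromosome
#' @param minSpecificity minimum in-window fraction of copies (default 0.9)
#' @param minChromFraction minimum fraction of windowed chromosomes with a
#'   copy (default 1: common to all chromosomes)
#' @return data.frame (family, copies, inWindow, specificity, ubiquity,
#'   score) of passing families, ranked by score
#' @export
scanCentromericFamilies <- function(repeats, windows, minSpecificity = 0.9,
                                    minChromFraction = 1) {
  if (!nrow(repeats)) stop("empty repeat annotation")
  mid <- floor((repeats$start + repeats$end) / 2)
  inWin <- rep(FALSE, nrow(repeats))
  for (k in seq_len(nrow(windows))) {
    sel <- repeats$chrom == windows$chrom[k] &
      mid >= windows$start[k] & mid <= windows$end[k]
    inWin <- inWin | sel
  }
  fams <- unique(repeats$family)
  nChromWin <- length(unique(windows$chrom))
  rows <- lapply(fams, function(f) {
    sel <- repeats$family == f
    nIn <- sum(sel & inWin)
    chromsIn <- unique(repeats$chrom[sel & inWin])
    data.frame(family = f,
               copies = sum(sel),
               inWindow = nIn,
               specificity = nIn / sum(sel),
               ubiquity = length(chromsIn) / nChromWin)
  })
  tab <- do.call(rbind, rows)
  tab$score <- tab$specificity * tab$inWindow
  tab <- tab[tab$specificity >= minSpecificity &
               tab$ubiquity >= minChromFraction, , drop = FALSE]
  tab <- tab[order(-tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Define centromere spans from selected repeat families
#'
#' The span on each chromosome runs from the first to the last copy of the
#' selected families; chromosomes without a copy get no call (warning).
#'
#' @param repeats data.frame (chrom, start, end, family, class)
#' @param families character vector of selected family names (non-empty)
#' @param chroms chromosomes to call (default: all present in `repeats`)
#' @return data.frame (chrom, start, end, method, nCopies, families)
#' @export
defineCentromereSpans <- function(repeats, families,
                                  chroms = unique(repeats$chrom)) {
  if (!length(families)) stop("empty family list")
  sel <- repeats[repeats$family %in% families, , drop = FALSE]
  out <- list()
  for (ch in chroms) {
    rows <- sel[sel$chrom == ch, , drop = FALSE]
    if (!nrow(rows)) {
      warning("no copy of selected families on ", ch, "; no call")
      next
    }
    out[[ch]] <- data.frame(chrom = ch,
                            start = min(rows$start),
                            end = max(rows$end),
                            method = "repeat-span",
                            nCopies = nrow(rows),
                            families = paste(sort(unique(rows$family)),
                                             collapse = ","))
  }
  if (!length(out)) stop("no chromosome carries the selected families")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# non-overlapping coverage (bp) of a set of intervals inside [start, end]
coverageWithin <- function(starts, ends, lo, hi) {
  if (!length(starts)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(pmax(starts, lo), pmin(ends, hi)))
  ir <- ir[IRanges::width(ir) > 0]
  sum(IRanges::width(ir))
}

#' Composition of centromere spans
#'
#' Per-centromere and averaged base fractions contributed by each selected
#' family, by other interspersed repeats and by tandem repeats (overlaps
#' resolved with precedence selected family > tandem > other interspersed,
#' so per-span fractions sum to <= 1), plus span vs rest-of-genome GC when
#' sequences are supplied and gene counts when a gene table is supplied.
#'
#' @param calls data.frame of spans from [defineCentromereSpans()]
#' @param repeats data.frame (chrom, start, end, family, class) with class
#'   in `interspersed`, `tandem`, `low_complexity`
#' @param families selected centromeric families
#' @param sequences optional [Biostrings::DNAStringSet] of chromosomes
#' @param genes optional data.frame (chrom, start, end, ...) of gene models
#' @return list: `perCentromere` data.frame, `averageFractions`, `gc`
#'   (span vs rest), `notes`
#' @export
centromereComposition <- function(calls, repeats, families,
                                  sequences = NULL, genes = NULL) {
  rows <- lapply(seq_len(nrow(calls)), function(k) {
    ch <- calls$chrom[k]
    lo <- calls$start[k]
    hi <- calls$end[k]
    span <- hi - lo + 1
    rr <- repeats[repeats$chrom == ch & repeats$end >= lo &
                    repeats$start <= hi, , drop = FALSE]
    famBp <- vapply(families, function(f) {
      sub <- rr[rr$family == f, , drop = FALSE]
      coverageWithin(sub$start, sub$end, lo, hi)
    }, numeric(1))
    # precedence: selected families > tandem > other interspersed
    famIR <- IRanges::reduce(IRanges::IRanges(
      pmax(rr$start[rr$family %in% families], lo),
      pmin(rr$end[rr$family %in% families], hi)))
    tanRows <- rr$class %in% c("tandem", "low_complexity") &
      !rr$family %in% families
    tanIR <- IRanges::reduce(IRanges::IRanges(
      pmax(rr$start[tanRows], lo), pmin(rr$end[tanRows], hi)))
    tanBp <- sum(IRanges::width(IRanges::setdiff(tanIR, famIR)))
    othRows <- rr$class == "interspersed" & !rr$family %in% families
    othIR <- IRanges::reduce(IRanges::IRanges(
      pmax(rr$start[othRows], lo), pmin(rr$end[othRows], hi)))
    othBp <- sum(IRanges::width(
      IRanges::setdiff(IRanges::setdiff(othIR, famIR), tanIR)))
    nGenes <- if (!is.null(genes)) {
      sum(genes$chrom == ch & genes$end >= lo & genes$start <= hi)
    } else NA_integer_
    df <- data.frame(chrom = ch, start = lo, end = hi, spanBp = span,
                     tandemFraction = tanBp / span,
                     otherInterspersedFraction = othBp / span,
                     nGenes = nGenes)
    for (f in families) df[[paste0("frac_", f)]] <- famBp[[f]] / span
    df
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  fracCols <- c(paste0("frac_", families), "tandemFraction",
                "otherInterspersedFraction")
  avg <- colMeans(per[, fracCols, drop = FALSE])
  gc <- NULL
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      sequences <- Biostrings::DNAStringSet(sequences)
    }
    gcOf <- function(views) {
      f <- Biostrings::letterFrequency(views, letters = c("GC", "AT"))
      sums <- colSums(f)
      unname(sums[1] / sum(sums))
    }
    spanViews <- lapply(seq_len(nrow(calls)), function(k) {
      Biostrings::Views(sequences[[calls$chrom[k]]],
                        start = calls$start[k],
                        end = min(calls$end[k],
                                  length(sequences[[calls$chrom[k]]])))
    })
    spanFreq <- vapply(spanViews, function(v) {
      Biostrings::letterFrequency(v, letters = c("GC", "AT"))[1, ]
    }, numeric(2))
    totFreq <- vapply(names(sequences), function(ch) {
      Biostrings::letterFrequency(sequences[[ch]],
                                  letters = c("GC", "AT"))
    }, numeric(2))
    spanGC <- sum(spanFreq[1, ]) / sum(spanFreq)
    restGC <- (sum(totFreq[1, ]) - sum(spanFreq[1, ])) /
      (sum(totFreq) - sum(spanFreq))
    gc <- list(centromere = spanGC, rest = restGC)
  }
  list(perCentromere = per, averageFractions = avg, gc = gc,
       notes = "fractions per span sum to <= 1 (family > tandem > other)")
}

#' Detect telomeric repeat tracts at chromosome ends
#'
#' Scans up to `maxOffset` bp from each chromosome end for a tandem run of
#' at least `minCopies` motif copies (the reverse complement at 5' ends); a
#' chromosome is telomere-to-telomere (T2T) when both ends carry a tract.
#'
#' @param sequences a [Biostrings::DNAStringSet] or named character vector
#' @param motif telomeric motif on the forward strand at 3' ends
#'   (default "TTAGGG")
#' @param minCopies minimum tandem copies (default 5)
#' @param maxOffset maximal distance from the end scanned (default 2000 bp)
#' @return list: `perEnd` data.frame (chrom, end, present, start, endPos,
#'   lengthBp, copies), `t2t` data.frame (chrom, t2t), `summary`
#'   (nEnds, nResolvedEnds, nT2T)
#' @export
detectTelomericTracts <- function(sequences, motif = "TTAGGG",
                                  minCopies = 5L, maxOffset = 2000L) {
  if (methods::is(sequences, "DNAStringSet")) {
    seqChar <- as.character(sequences)
  } else {
    seqChar <- sequences
  }
  rcMotif <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  k <- nchar(motif)
  findTract <- function(sub, mot) {
    pat <- paste0("(?:", mot, "){", minCopies, ",}")
    mm <- gregexpr(pat, sub, perl = TRUE)[[1]]
    if (mm[1] == -1L) return(NULL)
    len <- attr(mm, "match.length")
    j <- which.max(len)
    list(start = mm[j], length = len[j])
  }
  perEnd <- list()
  t2t <- list()
  for (ch in names(seqChar)) {
    s <- seqChar[[ch]]
    n <- nchar(s)
    off <- min(maxOffset, n)
    # 5' end: reverse-complement motif
    hit5 <- findTract(substr(s, 1L, off), rcMotif)
    row5 <- data.frame(chrom = ch, end = "5p",
                       present = !is.null(hit5),
                       start = if (is.null(hit5)) NA else hit5$start,
                       endPos = if (is.null(hit5)) NA else
                         hit5$start + hit5$length - 1L,
                       lengthBp = if (is.null(hit5)) NA else hit5$length,
                       copies = if (is.null(hit5)) NA else hit5$length / k)
    # 3' end: forward motif
    from <- n - off + 1L
    hit3 <- findTract(substr(s, from, n), motif)
    row3 <- data.frame(chrom = ch, end = "3p",
                       present = !is.null(hit3),
                       start = if (is.null(hit3)) NA else from + hit3$start - 1L,
                       endPos = if (is.null(hit3)) NA else
                         from + hit3$start + hit3$length - 2L,
                       lengthBp = if (is.null(hit3)) NA else hit3$length,
                       copies = if (is.null(hit3)) NA else hit3$length / k)
    perEnd[[ch]] <- rbind(row5, row3)
    t2t[[ch]] <- data.frame(chrom = ch, t2t = row5$present && row3$present)
  }
  perEnd <- do.call(rbind, perEnd)
  t2t <- do.call(rbind, t2t)
  rownames(perEnd) <- rownames(t2t) <- NULL
  list(perEnd = perEnd, t2t = t2t,
       summary = list(nEnds = nrow(perEnd),
                      nResolvedEnds = sum(perEnd$present),
                      nT2T = sum(t2t$t2t)))
}

#' Candidate centromeric windows around Hi-C calls
#'
#' @param hicCalls data.frame from [locateCentromeresHiC()]
#' @param genome a [GenomeSpec-class]
#' @param halfWidth window half-width in bp (default 200 kb)
#' @return data.frame (chrom, start, end)
#' @export
centromereWindows <- function(hicCalls, genome, halfWidth = 2e5) {
  lens <- chromLengths(genome)
  data.frame(chrom = hicCalls$chrom,
             start = pmax(1, hicCalls$pos - halfWidth),
             end = pmin(lens[hicCalls$chrom], hicCalls$pos + halfWidth))
}
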