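# Contact-map core: binning, masking, iterative balancing, expected profiles,
# observed/expected and correlation maps.

#' @describeIn nBins bin count of the underlying genome
#' @export
setMethod("nBins", "ContactMatrix", function(x) nBins(x@genome))

#' @describeIn binSize bin size of the underlying genome
#' @export
setMethod("binSize", "ContactMatrix", function(x) binSize(x@genome))

#' @describeIn chromNames chromosome names of the underlying genome
#' @export
setMethod("chromNames", "ContactMatrix", function(x) chromNames(x@genome))

#' @describeIn chromLengths chromosome lengths of the underlying genome
#' @export
setMethod("chromLengths", "ContactMatrix", function(x) chromLengths(x@genome))

#' @describeIn gcContent GC track of the underlying genome
#' @export
setMethod("gcContent", "ContactMatrix", function(x) gcContent(x@genome))

#' @describeIn binRanges bins of the underlying genome
#' @export
setMethod("binRanges", "ContactMatrix", function(x) binRanges(x@genome))

#' Raw contact counts
#' @param object a ContactMatrix
#' @return sparse symmetric count matrix
#' @export
setMethod("counts", "ContactMatrix", function(object) object@counts)

#' @describeIn balancingWeights weights of a ContactMatrix
#' @export
setMethod("balancingWeights", "ContactMatrix", function(x) x@weights)

#' @describeIn binMask mask of a ContactMatrix
#' @export
setMethod("binMask", "ContactMatrix", function(x) x@mask)

#' @describeIn totalContacts sum of counts over unordered bin pairs
#' @export
setMethod("totalContacts", "ContactMatrix", function(x) upperSum(x@counts))

#' Genome of a ContactMatrix
#' @param x a ContactMatrix
#' @return the GenomeSpec
#' @export
genomeOf <- function(x) x@genome

#' @describeIn balancedMatrix balanced values of a ContactMatrix
#' @export
setMethod("balancedMatrix", "ContactMatrix", function(x) {
  if (!length(x@weights)) {
    stop("matrix is not balanced; run iceBalance() first")
  }
  w <- x@weights
  B <- denseMat(x@counts) / outer(w, w)
  B[x@mask, ] <- NA_real_
  B[, x@mask] <- NA_real_
  B
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", nBins(object), "bins on",
      length(chromNames(object)), "chromosomes;",
      format(totalContacts(object), big.mark = ","), "contacts;",
      sum(object@mask), "bins masked;",
      if (length(object@weights)) "balanced" else "unbalanced", "\n")
})

# ---- binning ---------------------------------------------------------------

#' Bin read pairs into a contact matrix
#'
#' Each pair increments exactly one unordered bin-pair cell (the bins holding
#' the two mates' positions).  Positions are 1-based bp.
#'
#' @param pairs data.frame with columns chrom1, pos1, chrom2, pos2 (extra
#'   columns ignored), e.g. from [readPairsFile()].
#' @param genome a [GenomeSpec-class]; its `binSize` sets the resolution.
#' @param strict if TRUE, an unknown chromosome or out-of-range position is an
#'   error; otherwise such records are dropped with a message.
#' @return an unbalanced [ContactMatrix-class]; `totalContacts()` equals the
#'   number of valid pairs.
#' @export
binPairs <- function(pairs, genome, strict = FALSE) {
  nb <- nBins(genome)
  if (nrow(pairs) == 0L) {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(nb, nb))
    return(ContactMatrix(counts, genome,
                         metadata = list(nPairs = 0L, nRejected = 0L)))
  }
  b1 <- binAt(genome, as.character(pairs$chrom1), as.numeric(pairs$pos1))
  b2 <- binAt(genome, as.character(pairs$chrom2), as.numeric(pairs$pos2))
  bad <- is.na(b1) | is.na(b2)
  if (any(bad)) {
    if (strict) {
      stop(sum(bad), " pair(s) with unknown chromosome or out-of-range ",
           "position")
    }
    message("binPairs: dropped ", sum(bad), " invalid pair record(s)")
  }
  i <- pmin(b1[!bad], b2[!bad])
  j <- pmax(b1[!bad], b2[!bad])
  up <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nb, nb))
  counts <- up + Matrix::t(up) - Matrix::Diagonal(nb, x = Matrix::diag(up))
  ContactMatrix(counts, genome,
                metadata = list(nPairs = length(i), nRejected = sum(bad)))
}

# ---- masking ---------------------------------------------------------------

#' Mask low-coverage bins
#'
#' Bins whose marginal raw count falls below `minFrac` times the median
#' non-zero marginal are masked; masked rows/columns are excluded from all
#' downstream statistics.  Raw counts are untouched.
#'
#' @param m a [ContactMatrix-class]
#' @param minFrac fraction of the median non-zero marginal below which a bin
#'   is masked (default 0.02)
#' @return the matrix with its mask updated (weights reset)
#' @export
maskLowCoverage <- function(m, minFrac = 0.02) {
  marg <- Matrix::rowSums(m@counts)
  med <- median(marg[marg > 0])
  if (!length(med) || is.na(med)) stop("degenerate matrix: no contacts")
  newMask <- m@mask | (marg < minFrac * med)
  if (all(newMask)) stop("degenerate matrix: all bins masked")
  m@mask <- newMask
  m@weights <- numeric(0)
  m
}

# ---- iterative balancing ---------------------------------------------------

#' Iteratively balance a contact matrix
#'
#' Iterative correction over unmasked bins so that balanced marginals are
#' equal.  Balanced matrices target a unit *mean* marginal, making
#' observed/expected values scale-free.  Raw counts are untouched; the result
#' is stored in the `weights` slot.
#'
#' @param m a [ContactMatrix-class] with its mask applied
#'   (see [maskLowCoverage()])
#' @param tol relative tolerance on marginal equality (default 1e-5)
#' @param maxIter maximum number of iterations (default 200)
#' @return the matrix with positive weights on unmasked bins (NA on masked)
#' @export
iceBalance <- function(m, tol = 1e-5, maxIter = 200) {
  idx <- which(!m@mask)
  if (length(idx) < 2L) stop("fewer than 2 unmasked bins")
  A <- denseMat(m@counts)[idx, idx, drop = FALSE]
  marg <- rowSums(A)
  if (any(marg == 0)) {
    stop("unmasked bins with zero marginal; run maskLowCoverage() first")
  }
  b <- rep(1, length(idx))
  resid <- Inf
  for (it in seq_len(maxIter)) {
    mvec <- as.vector(A %*% (1 / b)) / b
    d <- mvec / mean(mvec)
    resid <- max(abs(d - 1))
    if (resid < tol) break
    b <- b * d
  }
  if (resid >= tol) {
    stop(sprintf(
      "iceBalance did not converge in %d iterations (last residual %.3g)",
      maxIter, resid))
  }
  # rescale so the mean balanced marginal is exactly 1
  mvec <- as.vector(A %*% (1 / b)) / b
  b <- b * sqrt(mean(mvec))
  w <- rep(NA_real_, nBins(m))
  w[idx] <- b
  m@weights <- w
  m@metadata$balancing <- list(method = "iterative-correction", tol = tol,
                               iterations = it, residual = resid)
  m
}

# ---- expected profiles -----------------------------------------------------

#' Distance-expected and trans-expected contact profile
#'
#' Per-chromosome mean balanced contact at every diagonal distance (in bins,
#' distance 0 included), plus the mean balanced trans value for every
#' chromosome pair.  Masked bins are excluded from both numerator and
#' denominator.
#'
#' @param m a balanced [ContactMatrix-class]
#' @return an object of class `ExpectedProfile`: list with `cis` (named list
#'   of per-distance means), `trans` (chromosome-pair matrix) and `genome`
#' @export
expectedProfile <- function(m) {
  B <- balancedMatrix(m)
  chroms <- chromNames(m)
  cis <- list()
  for (ch in chroms) {
    idx <- chromBins(m@genome, ch)
    n <- length(idx)
    if (sum(!m@mask[idx]) < 2L) {
      warning("chromosome ", ch, " has < 2 unmasked bins; profile undefined")
      cis[[ch]] <- rep(NA_real_, n)
      next
    }
    M <- B[idx, idx, drop = FALSE]
    prof <- numeric(n)
    for (d in 0:(n - 1L)) {
      ii <- seq_len(n - d)
      prof[d + 1L] <- meanNA(M[cbind(ii, ii + d)])
    }
    cis[[ch]] <- prof
  }
  nc <- length(chroms)
  trans <- matrix(NA_real_, nc, nc, dimnames = list(chroms, chroms))
  if (nc > 1L) {
    for (a in seq_len(nc - 1L)) {
      for (b in (a + 1L):nc) {
        va <- chromBins(m@genome, chroms[a])
        vb <- chromBins(m@genome, chroms[b])
        trans[a, b] <- trans[b, a] <- meanNA(B[va, vb])
      }
    }
  }
  structure(list(cis = cis, trans = trans, genome = m@genome),
            class = "ExpectedProfile")
}

#' Observed/expected matrix
#'
#' Cis cells are divided by the per-chromosome distance expectation, trans
#' cells by the chromosome-pair mean.  Cells with zero or undefined
#' expectation propagate as NA, never as 0.
#'
#' @param m a balanced [ContactMatrix-class]
#' @param expected an `ExpectedProfile` (computed from `m` if omitted)
#' @return dense O/E matrix with NA on masked/undefined cells
#' @export
observedOverExpected <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- expectedProfile(m)
  B <- balancedMatrix(m)
  chroms <- chromNames(m)
  oe <- matrix(NA_real_, nrow(B), ncol(B))
  for (a in seq_along(chroms)) {
    ia <- chromBins(m@genome, chroms[a])
    # cis block
    prof <- expected$cis[[chroms[a]]]
    n <- length(ia)
    dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
    e <- matrix(prof[dmat + 1L], n, n)
    e[!is.na(e) & e == 0] <- NA_real_
    oe[ia, ia] <- B[ia, ia] / e
    # trans blocks
    if (a < length(chroms)) {
      for (b in (a + 1L):length(chroms)) {
        ib <- chromBins(m@genome, chroms[b])
        te <- expected$trans[chroms[a], chroms[b]]
        if (is.na(te) || te == 0) next
        oe[ia, ib] <- B[ia, ib] / te
        oe[ib, ia] <- B[ib, ia] / te
      }
    }
  }
  oe
}

#' Per-chromosome correlation map
#'
#' Pearson correlation of cis O/E rows over unmasked columns.  Rows with zero
#' variance are masked (NA) in the output; the diagonal is 1 for defined rows.
#'
#' @param oe dense O/E matrix (from [observedOverExpected()])
#' @param genome the [GenomeSpec-class] the matrix is binned on
#' @param chroms chromosomes to compute (default all)
#' @return named list of per-chromosome correlation matrices
#' @export
correlationMap <- function(oe, genome, chroms = chromNames(genome)) {
  out <- list()
  for (ch in chroms) {
    idx <- chromBins(genome, ch)
    X <- oe[idx, idx, drop = FALSE]
    cm <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
    zv <- apply(X, 1L, function(r) {
      r <- r[!is.na(r)]
      length(r) < 2L || stats::sd(r) == 0
    })
    cm[zv, ] <- NA_real_
    cm[, zv] <- NA_real_
    diag(cm)[!zv] <- 1
    out[[ch]] <- cm
  }
  out
}

# ---- rebinning -------------------------------------------------------------

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts into bins of `newBinSize` (a multiple of the current bin
#' size).  A coarse bin is masked when all of its constituent fine bins were
#' masked.  Weights are dropped; re-balance after coarsening.  GC is averaged.
#'
#' @param m a [ContactMatrix-class]
#' @param newBinSize target bin size in bp (integer multiple of `binSize(m)`)
#' @return a new [ContactMatrix-class] at the coarser resolution
#' @export
coarsen <- function(m, newBinSize) {
  bs <- binSize(m)
  k <- newBinSize / bs
  if (k < 1 || abs(k - round(k)) > 1e-8) {
    stop("newBinSize must be an integer multiple of the current bin size")
  }
  g2 <- GenomeSpec(chromLengths(m), newBinSize)
  bt <- binTable(m@genome)
  mid <- floor((bt$start + bt$end) / 2)
  map <- binAt(g2, bt$chrom, mid)
  P <- Matrix::sparseMatrix(i = seq_along(map), j = map, x = 1,
                            dims = c(nBins(m), nBins(g2)))
  counts2 <- Matrix::t(P) %*% m@counts %*% P
  # fine off-diagonal pairs merging into one coarse bin appear twice in the
  # symmetric product; the coarse diagonal must count each pair once
  fineDiag <- as.vector(Matrix::t(P) %*% Matrix::diag(m@counts))
  counts2 <- methods::as(counts2, "generalMatrix")
  Matrix::diag(counts2) <- (Matrix::diag(counts2) + fineDiag) / 2
  mask2 <- as.vector(Matrix::t(P) %*% m@mask) == as.vector(Matrix::colSums(P))
  gc <- gcContent(m)
  if (!is.null(gc)) {
    num <- as.vector(Matrix::t(P) %*% ifelse(is.na(gc), 0, gc))
    den <- as.vector(Matrix::t(P) %*% as.numeric(!is.na(gc)))
    g2 <- setGC(g2, ifelse(den > 0, num / den, NA_real_))
  }
  ContactMatrix(counts2, g2, mask = mask2,
                metadata = c(m@metadata, list(coarsenedFrom = bs)))
}
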