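# Fixtures and independent oracles shared across the suite.  All fixtures
# are built in code; oracles are deliberately naive (loops, enumeration)
# and independent of the package's implementation paths.

# small two-chromosome genome
toyGenome <- function(lens = c(c1 = 2e4, c2 = 1e4), binSize = 2e3) {
  GenomeSpec(lens, binSize)
}

# ContactMatrix from a dense symmetric matrix, optionally pre-balanced with
# unit weights (handy for feeding exact O/E structures through the stack)
toyMatrix <- function(M, genome, unitWeights = FALSE, mask = NULL) {
  cm <- ContactMatrix(M, genome, mask = mask)
  if (unitWeights) {
    w <- rep(1, nBins(genome))
    if (!is.null(mask)) w[mask] <- NA
    cm@weights <- w
  }
  cm
}

# single-chromosome matrix whose diagonals carry prescribed mean values
diagMatrix <- function(diagVals, genome) {
  n <- nBins(genome)
  M <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    v <- if (d + 1 <= length(diagVals)) diagVals[d + 1] else 0
    ii <- seq_len(n - d)
    M[cbind(ii, ii + d)] <- v
    M[cbind(ii + d, ii)] <- v
  }
  M
}

# brute-force Pearson correlation of matrix rows over shared non-NA columns
bruteCorrelation <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (sum(ok) >= 2 && sd(X[i, ok]) > 0 && sd(X[j, ok]) > 0) {
        out[i, j] <- cor(X[i, ok], X[j, ok])
      }
    }
  }
  out
}

# exhaustive insulation-boundary oracle: recompute diamond scores and scan
# every bin for a qualifying prominent minimum
bruteBoundaries <- function(score, w, minStrength) {
  hits <- integer(0)
  n <- length(score)
  for (i in seq_len(n)) {
    if (is.na(score[i])) next
    lft <- if (i > 1) score[i - 1] else NA
    rgt <- if (i < n) score[i + 1] else NA
    if (!(!is.na(lft) && score[i] < lft && (is.na(rgt) || score[i] <= rgt))) {
      next
    }
    wl <- score[max(1, i - w):(i - 1)]
    wr <- score[(i + 1):min(n, i + w)]
    if (all(is.na(wl)) || all(is.na(wr))) next
    strength <- min(max(wl, na.rm = TRUE), max(wr, na.rm = TRUE)) - score[i]
    if (strength >= minStrength) hits <- c(hits, i)
  }
  hits
}

# exact two-sided permutation p for the rank-sum statistic
brutePermutationP <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  eW <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - eW)
  splits <- combn(n, n1)
  stat <- abs(colSums(matrix(r[splits], nrow = n1)) - eW)
  mean(stat >= obs - 1e-9)
}

# closed-form 2x2 chi-square: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
closedFormChi2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# truth with no insulated domain (TAD-free genome)
tadFreeTruth <- function(...) {
  syntheticTruth(insulatedRegions = data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    delta = numeric(), betaQ = numeric()), ...)
}

# balanced default-truth map (memoised per seed to keep the suite fast)
.simCache <- new.env(parent = emptyenv())
balancedSim <- function(seed, depth = 1e6, truth = syntheticTruth()) {
  key <- paste0("s", seed, "d", depth, "ins", nrow(truth@insulatedRegions))
  if (is.null(.simCache[[key]])) {
    m <- simulateContactMap(truth, depth = depth, seed = seed)
    .simCache[[key]] <- iceBalance(maskLowCoverage(m))
  }
  .simCache[[key]]
}
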