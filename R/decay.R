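# Contact probability vs distance and interaction decay exponent (IDE)
# fitting.

#' Contact probability curve P(s)
#'
#' P(s) is the observed contact per possible bin pair at genomic separation
#' s: within each distance band, the summed (balanced, when weights are
#' available) contact is divided by the number of possible unmasked pairs in
#' the band.  Distances are optionally pooled into logarithmic bands.
#'
#' @param m a [ContactMatrix-class]
#' @param chrom chromosome to profile
#' @param start,end optional 1-based bp bounds restricting the region
#' @param logBinsPerDecade number of logarithmic distance bands per decade
#'   (default 8); `NULL` keeps every native bin distance as its own band
#' @param useBalanced use balanced values when weights are present (default);
#'   raw counts otherwise
#' @return data.frame with columns `s` (bp, band center), `ps`, `n`
#'   (possible pairs in band)
#' @export
contactProbability <- function(m, chrom, start = NULL, end = NULL,
                               logBinsPerDecade = 8, useBalanced = TRUE) {
  idx <- if (is.null(start)) {
    chromBins(m@genome, chrom)
  } else {
    regionBins(m@genome, chrom, start, end)
  }
  keep <- idx[!m@mask[idx]]
  if (length(keep) < 3L) stop("region has fewer than 3 unmasked bins")
  V <- if (useBalanced && length(m@weights)) {
    balancedMatrix(m)[idx, idx, drop = FALSE]
  } else {
    X <- denseMat(m@counts)[idx, idx, drop = FALSE]
    X[m@mask[idx], ] <- NA_real_
    X[, m@mask[idx]] <- NA_real_
    X
  }
  n <- length(idx)
  bs <- binSize(m)
  dSum <- dN <- numeric(n - 1L)
  for (d in seq_len(n - 1L)) {
    ii <- seq_len(n - d)
    vals <- V[cbind(ii, ii + d)]
    dSum[d] <- sum(vals, na.rm = TRUE)
    dN[d] <- sum(!is.na(vals))
  }
  s <- seq_len(n - 1L) * bs
  if (is.null(logBinsPerDecade) || logBinsPerDecade == 0) {
    keepD <- dN > 0
    return(data.frame(s = s[keepD], ps = dSum[keepD] / dN[keepD],
                      n = dN[keepD]))
  }
  lb <- as.numeric(logBinsPerDecade)
  edges <- 10^seq(log10(bs) - 1e-9, log10(max(s)) + 1 / lb, by = 1 / lb)
  if (length(edges) < 2L) stop("region smaller than one distance band")
  band <- findInterval(s, edges)
  res <- lapply(sort(unique(band)), function(bd) {
    sel <- band == bd & dN > 0
    if (!any(sel)) return(NULL)
    nTot <- sum(dN[sel])
    data.frame(s = 10^(sum(dN[sel] * log10(s[sel])) / nTot),
               ps = sum(dSum[sel]) / nTot,
               n = nTot)
  })
  do.call(rbind, res)
}

#' Fit the interaction decay exponent (IDE)
#'
#' Ordinary least squares of log10 P on log10 s over the requested distance
#' range; zero-valued bands are dropped, not imputed.  The exponent is the
#' signed slope (negative for decaying contact).
#'
#' @param curve data.frame from [contactProbability()] (columns `s`, `ps`)
#' @param sMin,sMax fit range in bp (defaults 10 kb and 500 kb, the standard
#'   range for 10 kb matrices)
#' @return a [DecayFit-class]
#' @export
fitIDE <- function(curve, sMin = 1e4, sMax = 5e5) {
  sel <- curve$s >= sMin & curve$s <= sMax & curve$ps > 0 & !is.na(curve$ps)
  if (sum(sel) < 3L) {
    stop("fewer than 3 usable bands in [", sMin, ", ", sMax, "]")
  }
  x <- log10(curve$s[sel])
  y <- log10(curve$ps[sel])
  fit <- stats::lm(y ~ x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  new("DecayFit",
      distances = curve$s,
      ps = curve$ps,
      exponent = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = r2,
      fitRange = c(sMin, sMax),
      nBands = sum(sel))
}

#' IDE of a ContactMatrix region in one call
#'
#' Convenience wrapper: [contactProbability()] followed by [fitIDE()].
#'
#' @inheritParams contactProbability
#' @inheritParams fitIDE
#' @return a [DecayFit-class]
#' @export
fitIDERegion <- function(m, chrom, start = NULL, end = NULL,
                         sMin = 1e4, sMax = 5e5, logBinsPerDecade = 8) {
  fitIDE(contactProbability(m, chrom, start, end,
                            logBinsPerDecade = logBinsPerDecade),
         sMin = sMin, sMax = sMax)
}

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit: exponent %.4f (r2 %.3f) over [%g, %g] bp, %d bands\n",
    object@exponent, object@r2, object@fitRange[1], object@fitRange[2],
    object@nBands))
})

#' Exponent of a DecayFit
#' @param fit a [DecayFit-class]
#' @return the fitted signed slope
#' @export
ideExponent <- function(fit) fit@exponent
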