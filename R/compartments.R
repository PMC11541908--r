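# A/B compartment calling from the leading eigenvector, sign orientation by
# GC, sub-compartment splitting, and male/female compartment comparison.

#' @describeIn e1Values E1 loadings of a CompartmentTrack
#' @export
setMethod("e1Values", "CompartmentTrack", function(x) x@e1)

#' @describeIn compartmentLabels labels of a CompartmentTrack
#' @export
setMethod("compartmentLabels", "CompartmentTrack", function(x) x@label)

#' @describeIn compartmentBorders borders of a CompartmentTrack
#' @export
setMethod("compartmentBorders", "CompartmentTrack", function(x) x@borders)

setMethod("show", "CompartmentTrack", function(object) {
  tab <- table(factor(object@label, c("A", "B", "masked")))
  cat("CompartmentTrack (mode ", object@mode, "): ",
      tab[["A"]], " A bins, ", tab[["B"]], " B bins, ",
      tab[["masked"]], " masked; ", nrow(object@borders), " borders\n",
      sep = "")
})

# leading (largest algebraic) eigenpair of a symmetric matrix, with a
# degeneracy guard: a tie between the two top eigenvalues is an error.
# Algebraic ordering (not magnitude) is deliberate: a two-chromosome
# trans-only matrix is bipartite and its spectrum is symmetric about zero.
leadingEigen <- function(S, tol = 1e-9) {
  eg <- eigen(S, symmetric = TRUE)
  v1 <- eg$values[1]
  if (length(eg$values) > 1L) {
    v2 <- eg$values[2]
    if (abs(v1 - v2) <= tol * max(abs(v1), 1e-12)) {
      stop("ambiguous E1: leading eigenvalues tie within tolerance")
    }
  }
  list(value = v1, vector = eg$vectors[, 1])
}

# orient a per-chromosome eigenvector segment so that corr(E1, track) >= 0;
# near-zero correlation falls back to gene density, else keeps the sign with
# a warning.  Returns list(e1, corGC, flipped).
orientSegment <- function(e1, gc, geneDensity = NULL, chrom = "?",
                          signTol = 0.05) {
  ok <- !is.na(e1) & !is.na(gc)
  r <- if (sum(ok) >= 3L) suppressWarnings(stats::cor(e1[ok], gc[ok])) else NA
  ref <- r
  if (is.na(ref) || abs(ref) <= signTol) {
    if (!is.null(geneDensity)) {
      ok2 <- !is.na(e1) & !is.na(geneDensity)
      ref <- if (sum(ok2) >= 3L) {
        suppressWarnings(stats::cor(e1[ok2], geneDensity[ok2]))
      } else NA
    }
    if (is.na(ref) || abs(ref) <= signTol) {
      warning("chromosome ", chrom, ": E1 orientation ambiguous ",
              "(|corr with GC| <= ", signTol, "); sign kept as computed")
      return(list(e1 = e1, corGC = r, flipped = FALSE))
    }
  }
  if (ref < 0) {
    return(list(e1 = -e1, corGC = if (is.na(r)) r else -r, flipped = TRUE))
  }
  list(e1 = e1, corGC = r, flipped = FALSE)
}

#' Call A/B compartments
#'
#' E1 is the leading eigenvector of either the per-chromosome correlation map
#' of cis O/E (`mode = "cis"`) or of the genome-wide mean-centred trans O/E
#' matrix (`mode = "trans"`, cis blocks excluded).  The sign of each
#' chromosome's segment is oriented so that E1 correlates positively with GC
#' (A = GC-rich, active); positive E1 is labelled A, negative B.  Borders are
#' placed at the bin edge between consecutive unmasked bins of opposite sign.
#'
#' @param m a balanced [ContactMatrix-class]
#' @param gc per-bin GC fraction (defaults to the genome's GC track)
#' @param mode `"trans"` (default) or `"cis"`
#' @param geneDensity optional per-bin gene density used as orientation
#'   fallback when |corr(E1, GC)| is below `signTol`
#' @param signTol correlation magnitude under which orientation falls back
#'   (default 0.05)
#' @param oe optional precomputed O/E matrix
#' @return a [CompartmentTrack-class]
#' @export
callCompartments <- function(m, gc = NULL, mode = c("trans", "cis"),
                             geneDensity = NULL, signTol = 0.05, oe = NULL) {
  mode <- match.arg(mode)
  if (is.null(gc)) gc <- gcContent(m)
  if (is.null(gc)) {
    stop("missing input: per-bin GC track (genome gc slot or `gc` argument) ",
         "is required for E1 sign orientation")
  }
  if (is.null(oe)) oe <- observedOverExpected(m)
  nb <- nBins(m)
  e1 <- rep(NA_real_, nb)
  info <- list()
  if (mode == "cis") {
    cmaps <- correlationMap(oe, m@genome)
    for (ch in chromNames(m)) {
      idx <- chromBins(m@genome, ch)
      cm <- cmaps[[ch]]
      def <- which(!is.na(diag(cm)))
      if (length(def) < 3L) next
      le <- leadingEigen(cm[def, def, drop = FALSE])
      seg <- rep(NA_real_, length(idx))
      seg[def] <- le$vector
      ori <- orientSegment(seg, gc[idx],
                           if (is.null(geneDensity)) NULL else geneDensity[idx],
                           chrom = ch, signTol = signTol)
      e1[idx] <- ori$e1
      info[[ch]] <- list(corGC = ori$corGC, flipped = ori$flipped,
                         eigenvalue = le$value)
    }
  } else {
    if (length(chromNames(m)) < 2L) stop("trans mode needs >= 2 chromosomes")
    Z <- oe - 1
    for (ch in chromNames(m)) {
      idx <- chromBins(m@genome, ch)
      Z[idx, idx] <- NA_real_
    }
    def <- which(apply(Z, 1L, function(r) any(!is.na(r))) & !m@mask)
    Z[is.na(Z)] <- 0
    le <- leadingEigen(Z[def, def, drop = FALSE])
    e1[def] <- le$vector
    for (ch in chromNames(m)) {
      idx <- chromBins(m@genome, ch)
      ori <- orientSegment(e1[idx], gc[idx],
                           if (is.null(geneDensity)) NULL else geneDensity[idx],
                           chrom = ch, signTol = signTol)
      e1[idx] <- ori$e1
      info[[ch]] <- list(corGC = ori$corGC, flipped = ori$flipped,
                         eigenvalue = le$value)
    }
  }
  e1[m@mask] <- NA_real_
  label <- ifelse(is.na(e1) | abs(e1) < 1e-12, "masked",
                  ifelse(e1 > 0, "A", "B"))
  e1[label == "masked"] <- NA_real_
  borders <- compartmentBordersFromLabels(m@genome, label)
  new("CompartmentTrack", genome = m@genome, e1 = e1, label = label,
      borders = borders, mode = mode,
      metadata = list(orientation = info))
}

# borders at sign changes between consecutive unmasked bins
compartmentBordersFromLabels <- function(genome, label) {
  bt <- binTable(genome)
  out <- list()
  for (ch in chromNames(genome)) {
    idx <- chromBins(genome, ch)
    lab <- label[idx]
    unm <- which(lab != "masked")
    if (length(unm) < 2L) next
    chg <- which(lab[unm[-length(unm)]] != lab[unm[-1L]])
    if (!length(chg)) next
    left <- idx[unm[chg]]
    out[[ch]] <- data.frame(chrom = ch,
                            pos = bt$end[left],
                            from = label[left],
                            to = label[idx[unm[chg + 1L]]])
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      from = character(), to = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split one compartment into sub-compartments by trans affinity
#'
#' The leading eigenvector of the mean-centred trans O/E restricted to bins
#' carrying `whichLabel` is split by sign into two sub-compartments.  When a
#' set of centromere bins is supplied, the sub-compartment containing the
#' majority of them is reported (mirroring the observation that centromeres
#' form their own A sub-compartment).
#'
#' @param m a balanced [ContactMatrix-class]
#' @param track a [CompartmentTrack-class] on the same binning
#' @param whichLabel compartment to split (default "A")
#' @param centromereBins optional global bin indices of centromeres
#' @param noiseFloor leading-eigenvalue magnitude under which the split is
#'   reported as "no sub-structure" (default: `max(2 * RMS(other
#'   eigenvalues), 1e-6)`)
#' @param oe optional precomputed O/E matrix
#' @return list with `subLabel` (per-bin, `"A1"`/`"A2"`/NA), `eigenvalue`,
#'   `hasSubstructure`, and `centromereSub` (when centromere bins given)
#' @export
subcompartmentPCA <- function(m, track, whichLabel = "A",
                              centromereBins = NULL, noiseFloor = NULL,
                              oe = NULL) {
  idx <- which(compartmentLabels(track) == whichLabel & !m@mask)
  if (length(idx) < 4L) {
    stop("fewer than 4 unmasked bins carry label ", whichLabel)
  }
  if (is.null(oe)) oe <- observedOverExpected(m)
  Z <- oe[idx, idx, drop = FALSE] - 1
  for (ch in chromNames(m)) {
    loc <- which(idx %in% chromBins(m@genome, ch))
    Z[loc, loc] <- 0  # cis affinity excluded
  }
  Z[is.na(Z)] <- 0
  eg <- eigen(Z, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  l1 <- abs(eg$values[ord[1]])
  rest <- eg$values[ord[-1]]
  if (is.null(noiseFloor)) {
    noiseFloor <- max(2 * sqrt(mean(rest^2)), 1e-6)
  }
  vec <- eg$vectors[, ord[1]]
  hasSub <- l1 >= noiseFloor
  if (!hasSub) {
    warning("no sub-structure: leading eigenvalue below noise floor")
  }
  # orient so that the centromere-containing side (if known) is A1
  if (!is.null(centromereBins)) {
    cenLoc <- which(idx %in% centromereBins)
    if (length(cenLoc) && mean(vec[cenLoc] > 0) < 0.5) vec <- -vec
  }
  subLabel <- rep(NA_character_, nBins(m))
  subLabel[idx] <- ifelse(vec > 0, paste0(whichLabel, "1"),
                          paste0(whichLabel, "2"))
  cenSub <- NULL
  if (!is.null(centromereBins)) {
    labs <- subLabel[intersect(centromereBins, idx)]
    if (length(labs)) {
      cenSub <- names(sort(table(labs), decreasing = TRUE))[1]
    }
  }
  list(subLabel = subLabel, eigenvalue = l1, hasSubstructure = hasSub,
       centromereSub = cenSub)
}

#' Compare two compartment tracks (e.g. male vs female)
#'
#' Per-bin joint labels over bins unmasked in both tracks are merged into
#' maximal runs; lengths are reported in bp of the underlying bins.  The
#' switched fraction is `(A->B + B->A bp) / total unmasked bp`.
#'
#' @param trackM,trackF two [CompartmentTrack-class] objects on the same
#'   genome and bin size (e.g. male and female)
#' @return a `SwitchTable` list: `regions` (chrom, start, end, from, to, bp),
#'   `categoryBp` (named A->A/B->B/A->B/B->A totals), `fractionSwitched`
#' @export
compareCompartments <- function(trackM, trackF) {
  if (!sameBinning(trackM@genome, trackF@genome)) {
    stop("mismatched binning: tracks must share chromosomes and bin size")
  }
  genome <- trackM@genome
  bt <- binTable(genome)
  widths <- bt$end - bt$start + 1
  lm <- compartmentLabels(trackM)
  lf <- compartmentLabels(trackF)
  keep <- lm != "masked" & lf != "masked"
  cats <- c("A->A", "B->B", "A->B", "B->A")
  catBp <- setNames(numeric(4), cats)
  regions <- list()
  for (ch in chromNames(genome)) {
    idx <- chromBins(genome, ch)
    sel <- idx[keep[idx]]
    if (!length(sel)) next
    joint <- paste0(lm[sel], "->", lf[sel])
    r <- rle(joint)
    endI <- cumsum(r$lengths)
    startI <- c(1L, head(endI, -1L) + 1L)
    regions[[ch]] <- data.frame(
      chrom = ch,
      start = bt$start[sel[startI]],
      end = bt$end[sel[endI]],
      from = sub("->.*", "", r$values),
      to = sub(".*->", "", r$values),
      bp = vapply(seq_along(r$values), function(k) {
        sum(widths[sel[startI[k]:endI[k]]])
      }, numeric(1)))
    for (cc in cats) {
      catBp[cc] <- catBp[cc] + sum(widths[sel][joint == cc])
    }
  }
  totalBp <- sum(catBp)
  structure(list(
    regions = if (length(regions)) {
      res <- do.call(rbind, regions); rownames(res) <- NULL; res
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 from = character(), to = character(), bp = numeric())
    },
    categoryBp = catBp,
    fractionSwitched = if (totalBp > 0) {
      unname((catBp["A->B"] + catBp["B->A"]) / totalBp)
    } else NA_real_,
    totalBp = totalBp),
    class = "SwitchTable")
}

#' @export
print.SwitchTable <- function(x, ...) {
  cat("SwitchTable:", nrow(x$regions), "regions;",
      sprintf("%.2f%%", 100 * x$fractionSwitched), "of",
      format(x$totalBp, big.mark = ","), "bp switched\n")
  print(x$categoryBp)
  invisible(x)
}
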