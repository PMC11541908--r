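# Compartment x histone-mark, expression, and sex-biased-gene statistics.

#' Assign features to compartments by midpoint
#'
#' The feature's label is the compartment label of the bin containing its
#' midpoint; features on masked bins are labelled "masked" and excluded from
#' downstream tests.
#'
#' @param features data.frame with `chrom`, `start`, `end` columns (1-based)
#' @param track a [CompartmentTrack-class]
#' @return the features with a `compartment` column added
#' @export
assignToCompartment <- function(features, track) {
  mid <- floor((features$start + features$end) / 2)
  bin <- binAt(track@genome, as.character(features$chrom), mid)
  if (anyNA(bin)) {
    stop(sum(is.na(bin)), " feature(s) on unknown chromosomes or out of ",
         "range")
  }
  features$compartment <- compartmentLabels(track)[bin]
  features
}

# two-sample rank-sum test: exact split enumeration (tie-aware) when the
# number of splits is small, else the normal approximation with tie and
# continuity corrections (stats::wilcox.test).  W is the Mann-Whitney U of
# the first sample, p is two-sided.
rankSumTest <- function(x, y, maxSplits = 50000) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n, n1) <= maxSplits) {
    eW <- n1 * (n1 + n2 + 1) / 2   # expected rank sum under the null
    obs <- abs(sum(r[seq_len(n1)]) - eW)
    splits <- utils::combn(n, n1)
    stat <- abs(colSums(matrix(r[splits], nrow = n1)) - eW)
    p <- mean(stat >= obs - 1e-9)
    list(W = W, p = p, method = "exact permutation")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(W = unname(wt$statistic), p = wt$p.value,
         method = "normal approximation")
  }
}

compartmentGroups <- function(features, values, minPerGroup = 3L,
                              what = "features") {
  a <- values[features$compartment == "A"]
  b <- values[features$compartment == "B"]
  if (!length(a)) stop("empty group A")
  if (!length(b)) stop("empty group B")
  if (length(a) < minPerGroup || length(b) < minPerGroup) {
    stop("fewer than ", minPerGroup, " ", what, " in a compartment group")
  }
  list(A = a, B = b)
}

#' Histone-mark enrichment by compartment
#'
#' For each mark, peaks are assigned to compartments by midpoint and their
#' log2 fold-enrichment values (IP over control) compared between A and B
#' with a two-sample Wilcoxon rank-sum test.
#'
#' @param peaks data.frame (chrom, start, end, mark, fold_enrichment)
#' @param track a [CompartmentTrack-class]
#' @return named list per mark: `A`, `B` (log2 values), `W`, `p`, `nA`,
#'   `nB`, `method`
#' @export
markEnrichmentByCompartment <- function(peaks, track) {
  if (any(peaks$fold_enrichment <= 0)) {
    stop("fold_enrichment must be positive")
  }
  peaks <- assignToCompartment(peaks, track)
  out <- list()
  for (mk in unique(peaks$mark)) {
    sub <- peaks[peaks$mark == mk & peaks$compartment != "masked", ,
                 drop = FALSE]
    g <- compartmentGroups(sub, log2(sub$fold_enrichment), what = "peaks")
    tst <- rankSumTest(g$A, g$B)
    out[[mk]] <- list(A = g$A, B = g$B, W = tst$W, p = tst$p,
                      nA = length(g$A), nB = length(g$B),
                      method = tst$method)
  }
  out
}

#' Gene expression by compartment
#'
#' Genes are assigned to compartments by midpoint and their log2(TPM + 1)
#' values compared between A and B with a Wilcoxon rank-sum test.
#'
#' @param genes data.frame with `chrom`, `start`, `end` and a TPM column
#' @param track a [CompartmentTrack-class]
#' @param tpmColumn name of the TPM column (default "TPM")
#' @return list: `A`, `B` (log2(TPM+1) values), `W`, `p`, `nA`, `nB`,
#'   `method`
#' @export
expressionByCompartment <- function(genes, track, tpmColumn = "TPM") {
  if (!tpmColumn %in% names(genes)) stop("missing column: ", tpmColumn)
  if (any(genes[[tpmColumn]] < 0, na.rm = TRUE)) stop("TPM must be >= 0")
  genes <- assignToCompartment(genes, track)
  sub <- genes[genes$compartment != "masked", , drop = FALSE]
  g <- compartmentGroups(sub, log2(sub[[tpmColumn]] + 1), what = "genes")
  tst <- rankSumTest(g$A, g$B)
  list(A = g$A, B = g$B, W = tst$W, p = tst$p,
       nA = length(g$A), nB = length(g$B), method = tst$method)
}

#' Classify sex-biased genes from differential-expression statistics
#'
#' Thresholds follow the usual DE convention: male-biased (MBG) when
#' `padj <= padjMax` and `log2FC >= lfcMin` (male-high orientation),
#' female-biased (FBG) when `padj <= padjMax` and `log2FC <= -lfcMin`,
#' otherwise unbiased (Unb).  Genes with missing statistics are Unb.
#'
#' @param genes data.frame with `log2FC` and `padj` columns
#' @param padjMax adjusted-p threshold (default 0.01)
#' @param lfcMin absolute log2 fold-change threshold (default 1)
#' @return the genes with an `sbg_label` column added
#' @export
classifySBG <- function(genes, padjMax = 0.01, lfcMin = 1) {
  padj <- genes$padj
  lfc <- genes$log2FC
  lab <- rep("Unb", nrow(genes))
  sig <- !is.na(padj) & !is.na(lfc) & padj <= padjMax
  lab[sig & lfc >= lfcMin] <- "MBG"
  lab[sig & lfc <= -lfcMin] <- "FBG"
  genes$sbg_label <- lab
  genes
}

#' Are sex-biased genes enriched in compartment-switching regions?
#'
#' 2x2 contingency table {SBG, non-SBG} x {switching, conserved} by gene
#' midpoint, tested with a Pearson chi-square (df = 1, no continuity
#' correction).  Genes whose midpoint falls in no switch-table region
#' (masked bins) are excluded.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `sbg_label`
#'   (from [classifySBG()])
#' @param switchTable a `SwitchTable` from [compareCompartments()]
#' @param yates apply Yates continuity correction (default FALSE, matching
#'   a plain chi-square)
#' @return list: `table`, `chi2`, `p`, `df`, `nExcluded`
#' @export
sbgSwitchEnrichment <- function(genes, switchTable, yates = FALSE) {
  reg <- switchTable$regions
  mid <- floor((genes$start + genes$end) / 2)
  status <- rep(NA_character_, nrow(genes))
  for (k in seq_len(nrow(reg))) {
    sel <- genes$chrom == reg$chrom[k] & mid >= reg$start[k] &
      mid <= reg$end[k]
    status[sel] <- if (reg$from[k] == reg$to[k]) "conserved" else "switching"
  }
  keep <- !is.na(status)
  sbg <- genes$sbg_label[keep] %in% c("MBG", "FBG")
  tab <- table(factor(ifelse(sbg, "SBG", "non-SBG"),
                      levels = c("SBG", "non-SBG")),
               factor(status[keep], levels = c("switching", "conserved")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) stop("chi-square invalid; use exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(table = tab, chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), nExcluded = sum(!keep))
}
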