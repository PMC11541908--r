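# Compartment assignment, Wilcoxon comparisons, SBG classification,
# chi-square switch enrichment.

# a deterministic track: first half A, second half B, a masked tail bin
simpleTrack <- function(nb = 20, binSize = 1e4) {
  g <- GenomeSpec(c(c1 = nb * binSize), binSize)
  lab <- c(rep("A", nb / 2), rep("B", nb / 2))
  lab[nb] <- "masked"
  e1 <- ifelse(lab == "A", 1, ifelse(lab == "B", -1, NA))
  new("CompartmentTrack", genome = g, e1 = e1, label = lab,
      borders = data.frame(), mode = "cis", metadata = list())
}

test_that("features are assigned by midpoint, including border straddlers", {
  tr <- simpleTrack()
  feats <- data.frame(chrom = "c1",
                      start = c(1e4, 9.5e4, 1.95e56, 1.91e5),
                      end = c(2e4, 1.15e5, NA, 1.99e5))
  feats <- data.frame(chrom = "c1",
                      start = c(1e4 + 1, 9.5e4 + 1, 1.9e5 + 1),
                      end = c(2e4, 1.15e5, 2e5))
  out <- assignToCompartment(feats, tr)
  expect_equal(out$compartment, c("A", "B", "masked"))
  # straddling the A|B border with the midpoint in B -> B
  expect_equal(out$compartment[2], "B")
  expect_error(assignToCompartment(
    data.frame(chrom = "cX", start = 1, end = 10), tr), "unknown")
})

test_that("the rank-sum test matches exact permutation enumeration", {
  tr <- simpleTrack()
  # A = {3,4,5}, B = {1,2}: compare against the C(5,3) enumeration oracle
  x <- c(3, 4, 5)
  y <- c(1, 2)
  got <- kelpfold:::rankSumTest(x, y)
  expect_equal(got$p, brutePermutationP(x, y))
  expect_equal(got$W, 6)  # Mann-Whitney U: all 6 (x, y) pairs won by x
  # a tied sample still matches the enumeration oracle
  x2 <- c(1, 2, 2, 5)
  y2 <- c(2, 3, 4)
  expect_equal(kelpfold:::rankSumTest(x2, y2)$p, brutePermutationP(x2, y2))
  # several random small samples
  set.seed(20)
  for (k in 1:10) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x3 <- round(rnorm(n1), 1)
    y3 <- round(rnorm(n2, 0.5), 1)
    expect_equal(kelpfold:::rankSumTest(x3, y3)$p,
                 brutePermutationP(x3, y3))
  }
})

test_that("identical groups give p ~ 1; large samples use the approximation", {
  v <- rep(c(1, 2, 3), 2)
  got <- kelpfold:::rankSumTest(v[1:3], v[4:6])
  expect_equal(got$p, 1)
  set.seed(21)
  x <- rnorm(40)
  y <- rnorm(40, 1)
  got2 <- kelpfold:::rankSumTest(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got2$p, ref$p.value)
  expect_equal(got2$W, unname(ref$statistic))
  expect_equal(got2$method, "normal approximation")
})

test_that("mark enrichment detects planted compartment shifts", {
  tr <- syntheticTruth()
  tk <- simulateFeatureTracks(tr, fasta = FALSE, seed = 5)
  track <- new("CompartmentTrack", genome = tr@genome,
               e1 = ifelse(tr@labels == "A", 1, -1), label = tr@labels,
               borders = data.frame(), mode = "cis", metadata = list())
  res <- markEnrichmentByCompartment(tk$peaks, track)
  expect_setequal(names(res), c("H3K4me3", "H3K79me2"))
  # activation-mark analog is A-shifted, repressive analog B-shifted
  expect_lt(res$H3K4me3$p, 1e-6)
  expect_gt(mean(res$H3K4me3$A), mean(res$H3K4me3$B))
  expect_lt(res$H3K79me2$p, 1e-6)
  expect_lt(mean(res$H3K79me2$A), mean(res$H3K79me2$B))
  expect_error(markEnrichmentByCompartment(
    data.frame(chrom = "chr1", start = 1, end = 10, mark = "m",
               fold_enrichment = -1), track), "positive")
})

test_that("expression comparison uses log2(TPM + 1) and planted shifts", {
  tr <- simpleTrack()
  genes <- data.frame(chrom = "c1",
                      start = c(1, 2e4, 4e4, 1.1e5, 1.3e5, 1.5e5) + 1,
                      end = c(1e4, 3e4, 5e4, 1.2e5, 1.4e5, 1.6e5),
                      TPM = c(7, 3, 1, 0, 15, 31))
  res <- expressionByCompartment(genes, tr)
  expect_equal(sort(res$A), sort(log2(c(7, 3, 1) + 1)))
  expect_equal(sort(res$B), sort(log2(c(0, 15, 31) + 1)))
  # planted A > B shift is detected at n = 200 per group
  trS <- syntheticTruth()
  tk <- simulateFeatureTracks(trS, nGenes = 400, fasta = FALSE, seed = 6)
  track <- new("CompartmentTrack", genome = trS@genome,
               e1 = ifelse(trS@labels == "A", 1, -1), label = trS@labels,
               borders = data.frame(), mode = "cis", metadata = list())
  resS <- expressionByCompartment(tk$genes, track)
  expect_lte(resS$p, 0.05)
  expect_gt(median(resS$A), median(resS$B))
  # all genes in one compartment is a degenerate design
  genesA <- data.frame(chrom = "c1", start = c(1, 1e4 + 1, 3e4 + 1),
                       end = c(1e4, 2e4, 4e4), TPM = c(1, 2, 3))
  expect_error(expressionByCompartment(genesA, tr), "empty group B")
})

test_that("SBG classification partitions genes at the stated thresholds", {
  genes <- data.frame(
    gene_id = paste0("g", 1:6),
    chrom = "c1", start = 1, end = 10,
    log2FC = c(1.5, -2, 0.5, 3, -1, 1),
    padj = c(0.005, 0.001, 0.001, 0.5, 0.01, NA))
  out <- classifySBG(genes)
  expect_equal(out$sbg_label,
               c("MBG", "FBG", "Unb", "Unb", "FBG", "Unb"))
  # every gene gets exactly one label; counts invariant to row order
  expect_false(any(is.na(out$sbg_label)))
  shuf <- classifySBG(genes[sample(6), ])
  expect_equal(table(shuf$sbg_label), table(out$sbg_label))
})

test_that("the generator round-trips the planted SBG fraction", {
  tr <- syntheticTruth()
  tk <- simulateFeatureTracks(tr, nGenes = 1000, sbgFraction = 0.1,
                              fasta = FALSE, seed = 7)
  out <- classifySBG(tk$genes)
  nSBG <- sum(out$sbg_label != "Unb")
  expect_lt(abs(nSBG - 100), 4 * sqrt(100))  # binomial noise
})

test_that("chi-square matches the closed 2x2 form and flags bad designs", {
  mkGenes <- function(tab) {
    # build genes whose midpoints fall in two regions (switching at
    # 0-1e5, conserved at 1e5-2e6) with prescribed SBG counts
    n <- sum(tab)
    data.frame(chrom = "c1",
               start = c(rep(1e4, tab[1, 1]), rep(3e5, tab[1, 2]),
                         rep(2e4, tab[2, 1]), rep(4e5, tab[2, 2])),
               end = c(rep(1e4, tab[1, 1]), rep(3e5, tab[1, 2]),
                       rep(2e4, tab[2, 1]), rep(4e5, tab[2, 2])) + 10,
               sbg_label = c(rep("MBG", sum(tab[1, ])),
                             rep("Unb", sum(tab[2, ]))))
  }
  sw <- structure(list(regions = data.frame(
    chrom = "c1", start = c(1, 1e5 + 1), end = c(1e5, 2e6),
    from = c("A", "B"), to = c("B", "B"), bp = c(1e5, 1.9e6))),
    class = "SwitchTable")
  tab <- matrix(c(20, 80, 50, 850), 2, byrow = TRUE)
  res <- sbgSwitchEnrichment(mkGenes(tab), sw)
  expect_equal(res$chi2, closedFormChi2(tab), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, 1 - pchisq(closedFormChi2(tab), 1))
  # proportional rows: chi2 exactly 0
  tab0 <- matrix(c(10, 90, 100, 900), 2, byrow = TRUE)
  expect_equal(sbgSwitchEnrichment(mkGenes(tab0), sw)$chi2, 0,
               tolerance = 1e-12)
  # an expected cell below 1 is rejected
  tab1 <- matrix(c(1, 1, 1, 200), 2, byrow = TRUE)
  expect_error(sbgSwitchEnrichment(mkGenes(tab1), sw),
               "chi-square invalid")
})

test_that("random 2x2 tables agree with the closed form", {
  sw <- structure(list(regions = data.frame(
    chrom = "c1", start = c(1, 1e5 + 1), end = c(1e5, 2e6),
    from = c("A", "B"), to = c("B", "B"), bp = c(1e5, 1.9e6))),
    class = "SwitchTable")
  set.seed(30)
  for (k in 1:5) {
    tab <- matrix(sample(5:200, 4), 2)
    genes <- data.frame(
      chrom = "c1",
      start = c(rep(1e4, tab[1, 1]), rep(3e5, tab[1, 2]),
                rep(2e4, tab[2, 1]), rep(4e5, tab[2, 2])),
      sbg_label = c(rep("FBG", sum(tab[1, ])), rep("Unb", sum(tab[2, ]))))
    genes$end <- genes$start + 10
    expect_equal(sbgSwitchEnrichment(genes, sw)$chi2, closedFormChi2(tab),
                 tolerance = 1e-12)
  }
})
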