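# Hi-C centromere localisation, repeat-family scans, centromere spans and
# composition, telomeric tract detection.

test_that("locateCentromeresHiC equals exhaustive search on a 3x10 toy", {
  g <- GenomeSpec(c(a = 1e5, b = 1e5, c = 1e5), 1e4)  # 3 x 10 bins
  n <- nBins(g)
  M <- matrix(2, n, n)
  cen <- c(5, 14, 26)  # global bins (local 5, 4, 6)
  for (i in cen) for (j in cen) if (i != j) M[i, j] <- 12
  cm <- toyMatrix(M, g, unitWeights = TRUE)
  oe <- observedOverExpected(cm)
  for (ch in chromNames(g)) {
    idx <- chromBins(g, ch)
    oe[idx, idx] <- NA
  }
  calls <- locateCentromeresHiC(cm, excludeTerminalBins = 0)
  # exhaustive search over all 1000 triples
  best <- NULL
  bestVal <- -Inf
  for (i in 1:10) for (j in 11:20) for (k in 21:30) {
    v <- oe[i, j] + oe[i, k] + oe[j, k]
    if (v > bestVal) {
      bestVal <- v
      best <- c(i, j, k)
    }
  }
  expect_equal(calls$globalBin, best)
  expect_equal(calls$globalBin, cen)
  expect_true(all(calls$enriched))
  expect_true(all(calls$converged))
})

test_that("a uniform trans map converges and is flagged unenriched", {
  g <- GenomeSpec(c(a = 1e5, b = 1e5), 1e4)
  cm <- toyMatrix(matrix(4, 20, 20), g, unitWeights = TRUE)
  calls <- locateCentromeresHiC(cm, excludeTerminalBins = 0)
  expect_true(all(calls$converged))
  expect_false(any(calls$enriched))
  expect_error(locateCentromeresHiC(
    toyMatrix(matrix(4, 10, 10), GenomeSpec(c(a = 1e5), 1e4),
              unitWeights = TRUE)), "at least 2 chromosomes")
})

test_that("planted centromere clustering is recovered within one bin", {
  tr <- syntheticTruth()
  m <- simulateContactMap(tr, depth = 1e6, seed = 4)
  m <- iceBalance(maskLowCoverage(m))
  mc <- iceBalance(maskLowCoverage(coarsen(m, 5e4)), tol = 1e-4)
  calls <- locateCentromeresHiC(mc)
  truthBins <- truthCentromereGlobalBins(tr, genomeOf(mc))
  expect_true(all(abs(calls$globalBin - truthBins) <= 1))
  expect_true(all(calls$enriched))
})

test_that("family scan applies specificity and ubiquity filters", {
  reps <- rbind(
    data.frame(chrom = rep(paste0("chr", 1:4), each = 3),
               start = rep(c(5e5, 5.2e5, 5.4e5), 4),
               end = rep(c(5e5, 5.2e5, 5.4e5), 4) + 1000,
               family = "CenFam", class = "interspersed"),
    data.frame(chrom = "chr1", start = 5.1e5, end = 5.11e5,
               family = "OneChrom", class = "interspersed"),
    data.frame(chrom = paste0("chr", 1:4), start = 1e5, end = 1.01e5,
               family = "Outside", class = "interspersed"))
  wins <- data.frame(chrom = paste0("chr", 1:4), start = 4.5e5, end = 6e5)
  tab <- scanCentromericFamilies(reps, wins)
  expect_equal(tab$family, "CenFam")
  expect_equal(tab$specificity, 1)
  expect_equal(tab$ubiquity, 1)
  # OneChrom passes specificity but fails ubiquity (1 of 4 chromosomes)
  loose <- scanCentromericFamilies(reps, wins, minChromFraction = 0.25)
  expect_true("OneChrom" %in% loose$family)
  expect_false("Outside" %in% loose$family)
})

test_that("two centromeric families are both returned when both pass", {
  reps <- do.call(rbind, lapply(paste0("chr", 1:4), function(ch) {
    data.frame(chrom = ch,
               start = c(5e5, 5.3e5, 5.6e5, 5.1e5),
               end = c(5e5, 5.3e5, 5.6e5, 5.1e5) + 2000,
               family = c("CRT-1", "CRT-1", "CRT-1", "CRT-2"),
               class = "interspersed")
  }))
  wins <- data.frame(chrom = paste0("chr", 1:4), start = 4.5e5, end = 6e5)
  tab <- scanCentromericFamilies(reps, wins)
  expect_setequal(tab$family, c("CRT-1", "CRT-2"))
  expect_equal(tab$family[1], "CRT-1")  # more copies, ranked first
})

test_that("centromere spans run from the first to the last family copy", {
  reps <- data.frame(chrom = c("c1", "c1", "c2"),
                     start = c(1e4, 8e4, 3e4),
                     end = c(1.6e4, 8.6e4, 3.7e4),
                     family = "F", class = "interspersed")
  spans <- defineCentromereSpans(reps, "F", chroms = c("c1", "c2"))
  expect_equal(spans$start, c(1e4, 3e4))
  expect_equal(spans$end, c(8.6e4, 3.7e4))
  # single copy: the span is that copy's interval
  expect_equal(spans$end[2] - spans$start[2], 7e3)
  # idempotence/monotonicity: a copy inside the span changes nothing
  reps2 <- rbind(reps, data.frame(chrom = "c1", start = 4e4, end = 4.5e4,
                                  family = "F", class = "interspersed"))
  spans2 <- defineCentromereSpans(reps2, "F", chroms = c("c1", "c2"))
  expect_equal(spans2[, c("start", "end")], spans[, c("start", "end")])
  expect_warning(defineCentromereSpans(reps, "F", chroms = c("c1", "c3")),
                 "no copy")
  expect_error(defineCentromereSpans(reps, character(0)), "empty family")
})

test_that("composition fractions follow interval arithmetic and precedence", {
  calls <- data.frame(chrom = "c1", start = 1e4 + 1, end = 3e4,
                      method = "repeat-span")
  reps <- data.frame(
    chrom = "c1",
    start = c(1.2e4 + 1, 2.4e4 + 1, 1.4e4 + 1),
    end = c(1.8e4, 2.6e4, 1.5e4),
    family = c("A", "SatZ", "SatZ"),
    class = c("interspersed", "tandem", "tandem"))
  res <- centromereComposition(calls, reps, families = "A")
  per <- res$perCentromere
  expect_equal(per$frac_A, 0.30)          # 6 kb of a 20 kb span
  expect_equal(per$tandemFraction, 0.10)  # 2 kb outside the family
  expect_equal(per$otherInterspersedFraction, 0)
  # tandem overlapping the family is not double counted
  expect_lte(per$frac_A + per$tandemFraction +
               per$otherInterspersedFraction, 1)

  # span fully covered by one family
  calls2 <- data.frame(chrom = "c1", start = 1e4, end = 2e4)
  reps2 <- data.frame(chrom = "c1", start = 9e3, end = 2.1e4,
                      family = "A", class = "interspersed")
  res2 <- centromereComposition(calls2, reps2, families = "A")
  expect_equal(res2$perCentromere$frac_A, 1)
  expect_equal(res2$perCentromere$tandemFraction, 0)
})

test_that("composition reports span vs rest-of-genome GC and gene counts", {
  seqs <- Biostrings::DNAStringSet(c(
    c1 = paste0(strrep("AT", 5000), strrep("GC", 5000))))
  calls <- data.frame(chrom = "c1", start = 1, end = 1e4)  # the AT half
  reps <- data.frame(chrom = "c1", start = 1, end = 100,
                     family = "A", class = "interspersed")
  genes <- data.frame(chrom = "c1", start = c(50, 1.5e4),
                      end = c(150, 1.6e4))
  res <- centromereComposition(calls, reps, families = "A",
                               sequences = seqs, genes = genes)
  expect_equal(res$gc$centromere, 0)
  expect_equal(res$gc$rest, 1)
  expect_equal(res$perCentromere$nGenes, 1)
})

test_that("telomeric tracts are found at the right ends with right length", {
  set.seed(8)
  mid <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  seqs <- c(
    both = paste0(strrep("CCCTAA", 20), mid, strrep("TTAGGG", 30)),
    none = mid,
    only3 = paste0(mid, strrep("TTAGGG", 30)))
  res <- detectTelomericTracts(seqs)
  pe <- res$perEnd
  expect_equal(pe$present[pe$chrom == "both"], c(TRUE, TRUE))
  expect_equal(pe$lengthBp[pe$chrom == "both" & pe$end == "3p"], 180)
  expect_equal(pe$copies[pe$chrom == "both" & pe$end == "3p"], 30)
  expect_equal(pe$present[pe$chrom == "none"], c(FALSE, FALSE))
  expect_equal(pe$present[pe$chrom == "only3"], c(FALSE, TRUE))
  expect_equal(res$t2t$t2t, c(TRUE, FALSE, FALSE))
  expect_equal(res$summary$nResolvedEnds, 3)
  expect_equal(res$summary$nT2T, 1)
})

test_that("tract detection ignores motifs beyond the scan offset", {
  mid <- strrep("ACGT", 2000)
  withT <- paste0(strrep("TTAGGG", 10), mid)  # motif at the 5' end but
  res <- detectTelomericTracts(c(c1 = withT))  # forward motif: not 5' type
  expect_false(res$perEnd$present[res$perEnd$end == "5p"])
  # appending non-motif sequence beyond maxOffset changes nothing
  base <- paste0(strrep("CCCTAA", 10), mid, strrep("TTAGGG", 10))
  ext <- paste0(strrep("CCCTAA", 10), mid, strrep("TTAGGG", 10))
  r1 <- detectTelomericTracts(c(c1 = base), maxOffset = 2000)
  r2 <- detectTelomericTracts(c(c1 = ext), maxOffset = 2000)
  expect_equal(r1$perEnd$present, r2$perEnd$present)
  # below the copy threshold nothing is called
  weak <- paste0(mid, strrep("TTAGGG", 4))
  expect_false(any(detectTelomericTracts(c(c1 = weak))$perEnd$present))
})

test_that("centromere windows close the loop between the two methods", {
  g <- GenomeSpec(c(chr1 = 2e6), 1e4)
  calls <- data.frame(chrom = "chr1", pos = 1e5)
  w <- centromereWindows(calls, g, halfWidth = 2e5)
  expect_equal(w$start, 1)  # clipped at the chromosome start
  expect_equal(w$end, 3e5)
})
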