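# Binning, masking, balancing, expected profiles, O/E and correlation maps.

test_that("binPairs assigns pairs to unordered bin-pair cells", {
  g <- toyGenome()
  pairs <- data.frame(chrom1 = c("c1", "c1", "c1"),
                      pos1 = c(1500, 3500, 100),
                      chrom2 = c("c1", "c1", "c2"),
                      pos2 = c(3500, 1500, 100))
  cm <- binPairs(pairs, g)
  M <- as.matrix(counts(cm))
  b0 <- binAt(g, "c1", 1500)  # c1 bin 0
  b1 <- binAt(g, "c1", 3500)  # c1 bin 1
  b2 <- binAt(g, "c2", 100)   # c2 bin 0
  expect_equal(M[b0, b1], 2)
  expect_equal(M[b1, b0], 2)
  expect_equal(M[b0, b2], 1)
  expect_equal(totalContacts(cm), 3)
  expect_true(Matrix::isSymmetric(counts(cm)))
})

test_that("binPairs on an empty stream yields a zero matrix", {
  g <- toyGenome()
  cm <- binPairs(data.frame(chrom1 = character(), pos1 = numeric(),
                            chrom2 = character(), pos2 = numeric()), g)
  expect_equal(totalContacts(cm), 0)
  expect_equal(sum(counts(cm)), 0)
})

test_that("binPairs rejects invalid records, strictly on demand", {
  g <- toyGenome()
  pairs <- data.frame(chrom1 = c("c1", "cX", "c1"),
                      pos1 = c(100, 100, 999999),
                      chrom2 = c("c1", "c1", "c1"),
                      pos2 = c(200, 200, 200))
  expect_message(cm <- binPairs(pairs, g), "dropped 2")
  expect_equal(totalContacts(cm), 1)
  expect_error(binPairs(pairs, g, strict = TRUE), "2 pair")
})

test_that("the standard multi-resolution bin sizes form valid genome specs", {
  for (bs in c(2e3, 5e3, 1e4, 2e4, 5e4, 1e5, 5e5)) {
    g <- GenomeSpec(c(chrA = 1.2e6, chrB = 0.9e6), bs)
    expect_s4_class(g, "GenomeSpec")
    bt <- binTable(g)
    # bins tile each chromosome exactly
    expect_equal(sum(bt$end - bt$start + 1), 2.1e6)
    expect_equal(bt$bin, seq_len(nrow(bt)))
  }
  expect_error(GenomeSpec(c(chrA = 1e3), 2e3), "shortest")
})

test_that("maskLowCoverage masks exactly the low-marginal bins", {
  g <- GenomeSpec(c(c1 = 1e4), 1e3)  # 10 bins
  M <- matrix(10, 10, 10)
  diag(M) <- 10
  # bin 4 at 5% of the median marginal
  M[4, ] <- M[, 4] <- 0.05 * 10
  cm <- ContactMatrix(M, g)
  masked <- binMask(maskLowCoverage(cm, minFrac = 0.1))
  expect_equal(which(masked), 4L)

  # uniform matrix: nothing masked
  cmU <- ContactMatrix(matrix(5, 10, 10), g)
  expect_equal(sum(binMask(maskLowCoverage(cmU, minFrac = 0.1))), 0)

  # an all-zero bin is masked
  M2 <- matrix(5, 10, 10)
  M2[7, ] <- M2[, 7] <- 0
  expect_equal(which(binMask(maskLowCoverage(ContactMatrix(M2, g)))), 7L)

  # degenerate: everything masked
  expect_error(maskLowCoverage(ContactMatrix(matrix(0, 10, 10), g)),
               "degenerate")
})

test_that("iceBalance solves the 2x2 case in closed form", {
  g <- GenomeSpec(c(c1 = 4e3), 2e3)
  cm <- ContactMatrix(matrix(c(0, 4, 4, 0), 2), g)
  cm <- iceBalance(cm)
  w <- balancingWeights(cm)
  expect_equal(w, c(2, 2), tolerance = 1e-6)
  B <- balancedMatrix(cm)
  expect_equal(B[1, 2], 1, tolerance = 1e-6)   # unit-target marginals
  expect_equal(B[1, 2], B[2, 1])
})

test_that("iceBalance equalises marginals and is scale invariant", {
  g <- GenomeSpec(c(c1 = 2e4, c2 = 2e4), 2e3)  # 20 bins
  set.seed(42)
  A <- matrix(rpois(400, 20) + 1, 20, 20)
  A <- A + t(A)
  cm <- iceBalance(ContactMatrix(A, g), tol = 1e-8)
  B <- balancedMatrix(cm)
  marg <- rowSums(B)
  expect_lt(sd(marg) / mean(marg), 1e-6)  # CV below tolerance
  expect_equal(mean(marg), 1, tolerance = 1e-6)

  # equal marginals in -> equal weights out (up to global scale)
  cmU <- iceBalance(ContactMatrix(matrix(3, 20, 20), g))
  wU <- balancingWeights(cmU)
  expect_lt(diff(range(wU)), 1e-8 * mean(wU))

  # doubling all counts leaves weight ratios and O/E unchanged
  cm2 <- iceBalance(ContactMatrix(2 * A, g), tol = 1e-8)
  r <- balancingWeights(cm2) / balancingWeights(cm)
  expect_lt(diff(range(r)), 1e-6 * mean(r))
  oe1 <- observedOverExpected(cm)
  oe2 <- observedOverExpected(cm2)
  expect_equal(oe1, oe2, tolerance = 1e-6)
  # raw counts untouched by balancing
  expect_equal(as.matrix(counts(cm)), A)
})

test_that("iceBalance reports non-convergence with the residual", {
  g <- GenomeSpec(c(c1 = 2e4), 2e3)
  set.seed(7)
  A <- matrix(rpois(100, 5) + 1, 10, 10)
  A <- A + t(A)
  expect_error(iceBalance(ContactMatrix(A, g), tol = 1e-12, maxIter = 1),
               "did not converge")
})

test_that("expectedProfile recovers hand-averaged diagonals", {
  g <- GenomeSpec(c(c1 = 8e3), 2e3)  # 4 bins
  cm <- toyMatrix(diagMatrix(c(10, 4, 2, 1), g), g, unitWeights = TRUE)
  e <- expectedProfile(cm)
  expect_equal(e$cis$c1, c(10, 4, 2, 1))

  # constant matrix: expected equals the constant at every distance
  cmC <- toyMatrix(matrix(3, 4, 4), g, unitWeights = TRUE)
  expect_equal(expectedProfile(cmC)$cis$c1, rep(3, 4))
})

test_that("expectedProfile excludes masked bins from both sides", {
  g <- GenomeSpec(c(c1 = 8e3), 2e3)
  M <- diagMatrix(c(10, 4, 2, 1), g)
  M[2, ] <- M[, 2] <- 100  # would distort every diagonal if not masked
  mask <- c(FALSE, TRUE, FALSE, FALSE)
  cm <- toyMatrix(M, g, unitWeights = TRUE, mask = mask)
  e <- expectedProfile(cm)
  # distance 1: only pairs (3,4) remain unmasked
  expect_equal(e$cis$c1[2], 4)
  # distance 2: only (1,3)
  expect_equal(e$cis$c1[3], 2)
})

test_that("observedOverExpected divides cell-wise and propagates NA", {
  g <- GenomeSpec(c(c1 = 8e3), 2e3)
  M <- diagMatrix(c(10, 4, 2, 1), g)
  M[1, 2] <- M[2, 1] <- 8  # distance-1 mean becomes (8 + 4 + 4)/3
  cm <- toyMatrix(M, g, unitWeights = TRUE)
  e <- expectedProfile(cm)
  oe <- observedOverExpected(cm, e)
  expect_equal(oe[1, 2], 8 / mean(c(8, 4, 4)))
  expect_equal(oe[2, 3], 4 / mean(c(8, 4, 4)))
  expect_equal(oe[1, 3], 1)  # distance-2 cells equal their mean
  # matrix equal to its own expectation: all-ones O/E
  cmC <- toyMatrix(diagMatrix(c(10, 4, 2, 1), g), g, unitWeights = TRUE)
  oeC <- observedOverExpected(cmC)
  expect_true(all(abs(oeC - 1) < 1e-12))
  # zero expectation yields NA, never 0
  M3 <- diagMatrix(c(10, 0, 2, 1), g)
  oe3 <- observedOverExpected(toyMatrix(M3, g, unitWeights = TRUE))
  expect_true(all(is.na(oe3[cbind(1:3, 2:4)])))
})

test_that("masking keeps O/E cells NA on masked rows and columns", {
  g <- GenomeSpec(c(c1 = 8e3), 2e3)
  cm <- toyMatrix(diagMatrix(c(10, 4, 2, 1), g), g, unitWeights = TRUE,
                  mask = c(FALSE, FALSE, TRUE, FALSE))
  oe <- observedOverExpected(cm)
  expect_true(all(is.na(oe[3, ])))
  expect_true(all(is.na(oe[, 3])))
})

test_that("correlationMap matches a brute-force Pearson oracle", {
  g <- GenomeSpec(c(c1 = 1e4), 2e3)  # 5 bins
  set.seed(11)
  A <- matrix(rpois(25, 30) + 1, 5, 5)
  A <- A + t(A)
  cm <- iceBalance(ContactMatrix(A, g), tol = 1e-10)
  oe <- observedOverExpected(cm)
  cmap <- correlationMap(oe, g)$c1
  ref <- bruteCorrelation(oe[1:5, 1:5])
  diag(ref) <- 1
  expect_equal(cmap, ref, tolerance = 1e-12)
  expect_equal(unname(diag(cmap)), rep(1, 5))

  # a larger instance, 20 bins
  g2 <- GenomeSpec(c(c1 = 4e4), 2e3)
  A2 <- matrix(rpois(400, 25) + 1, 20, 20)
  A2 <- A2 + t(A2)
  cm2 <- iceBalance(ContactMatrix(A2, g2), tol = 1e-10)
  oe2 <- observedOverExpected(cm2)
  cmap2 <- correlationMap(oe2, g2)$c1
  ref2 <- bruteCorrelation(oe2)
  diag(ref2) <- 1
  expect_equal(cmap2, ref2, tolerance = 1e-12)
})

test_that("identical O/E rows correlate at 1; zero-variance rows are masked", {
  g <- GenomeSpec(c(c1 = 1e4), 2e3)
  X <- matrix(c(1, 2, 3, 4, 5,
                1, 2, 3, 4, 5,
                5, 4, 3, 2, 1,
                2, 2, 2, 2, 2,
                1, 3, 2, 5, 4), 5, 5, byrow = TRUE)
  cmap <- correlationMap(X, g)$c1
  expect_equal(cmap[1, 2], 1)
  expect_true(all(is.na(cmap[4, ])))  # zero variance
  expect_true(all(is.na(cmap[, 4])))
})

test_that("coarsen sums counts and preserves the total", {
  g <- toyGenome()  # c1: 10 bins, c2: 5 bins at 2 kb
  set.seed(3)
  A <- matrix(rpois(225, 4), 15, 15)
  A <- A + t(A)
  cm <- ContactMatrix(A, g)
  cm2 <- coarsen(cm, 1e4)
  expect_equal(nBins(cm2), 3)  # c1 -> 2 bins, c2 -> 1 bin
  expect_equal(totalContacts(cm2), totalContacts(cm))
  expect_true(Matrix::isSymmetric(counts(cm2)))
  expect_error(coarsen(cm, 3e3), "integer multiple")
})
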