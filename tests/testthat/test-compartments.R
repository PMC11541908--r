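# A/B compartment calling, orientation, sub-compartments, switching.

# single-chromosome checkerboard counts: blocks of `blockBins` bins
# alternate labels; same-label contact `hi`, cross-label `lo`
checkerboardMatrix <- function(nBins, blockBins, hi = 16, lo = 7,
                               base = 20) {
  lab <- (((seq_len(nBins) - 1) %/% blockBins) %% 2)
  same <- outer(lab, lab, "==")
  M <- matrix(base, nBins, nBins)
  M[same] <- M[same] + hi
  M[!same] <- M[!same] - lo
  M
}

test_that("a planted cis checkerboard is recovered on every unmasked bin", {
  nb <- 40
  g <- GenomeSpec(c(c1 = nb * 1e4), 1e4)
  M <- checkerboardMatrix(nb, blockBins = 5)
  cm <- iceBalance(maskLowCoverage(ContactMatrix(M, g)))
  truthLab <- ifelse((((seq_len(nb) - 1) %/% 5) %% 2) == 0, "A", "B")
  gc <- ifelse(truthLab == "A", 0.55, 0.50)
  tr <- callCompartments(cm, gc = gc, mode = "cis")
  lab <- compartmentLabels(tr)
  expect_true(all(lab[lab != "masked"] ==
                    truthLab[lab != "masked"]))
  expect_equal(mean(lab == truthLab), 1)
  # borders sit exactly at the sign changes
  expect_equal(nrow(compartmentBorders(tr)), 7)
  expect_equal(compartmentBorders(tr)$pos,
               seq(5e4, 3.5e5, by = 5e4))
})

test_that("orientation makes corr(E1, GC) non-negative per chromosome", {
  m <- balancedSim(seed = 1)
  tk <- simulateFeatureTracks(syntheticTruth(), fasta = FALSE, seed = 500)
  tr <- callCompartments(m, gc = tk$gc, mode = "cis")
  for (ch in chromNames(m)) {
    idx <- chromBins(genomeOf(m), ch)
    ok <- !is.na(e1Values(tr)[idx])
    expect_gte(cor(e1Values(tr)[idx][ok], tk$gc[idx][ok]), 0)
  }
})

test_that("negating the eigenvector before orientation changes nothing", {
  nb <- 30
  g <- GenomeSpec(c(c1 = nb * 1e4), 1e4)
  M <- checkerboardMatrix(nb, blockBins = 6)
  cm <- iceBalance(maskLowCoverage(ContactMatrix(M, g)))
  gc <- ifelse((((seq_len(nb) - 1) %/% 6) %% 2) == 0, 0.56, 0.5)
  t1 <- callCompartments(cm, gc = gc, mode = "cis")
  # flipping GC flips which phase is A, proving the sign rule is GC-driven
  t2 <- callCompartments(cm, gc = -gc, mode = "cis")
  expect_equal(compartmentLabels(t1),
               ifelse(compartmentLabels(t2) == "A", "B",
                      ifelse(compartmentLabels(t2) == "B", "A", "masked")))
  # and calling twice is deterministic
  t3 <- callCompartments(cm, gc = gc, mode = "cis")
  expect_identical(e1Values(t1), e1Values(t3))
})

test_that("trans mode recovers a planted trans checkerboard", {
  nb <- 20  # per chromosome
  g <- GenomeSpec(c(c1 = nb * 1e4, c2 = nb * 1e4), 1e4)
  lab <- rep(c(0, 1), each = 10)
  same <- outer(lab, lab, "==")
  Mtrans <- matrix(10, nb, nb)
  Mtrans[same] <- 18
  Mtrans[!same] <- 6
  M <- matrix(10, 2 * nb, 2 * nb)
  M[1:nb, nb + 1:nb] <- Mtrans
  M[nb + 1:nb, 1:nb] <- t(Mtrans)
  cm <- iceBalance(maskLowCoverage(ContactMatrix(M, g)), tol = 1e-8)
  gc <- rep(ifelse(lab == 0, 0.56, 0.5), 2)
  tr <- callCompartments(cm, gc = gc, mode = "trans")
  expect_equal(tr@mode, "trans")
  truthLab <- rep(ifelse(lab == 0, "A", "B"), 2)
  got <- compartmentLabels(tr)
  expect_true(mean(got == truthLab) >= 0.95)
})

test_that("degenerate leading eigenvalues raise an error", {
  expect_error(kelpfold:::leadingEigen(diag(2)), "ambiguous E1")
})

test_that("missing GC is a clear error", {
  g <- GenomeSpec(c(c1 = 2e5), 1e4)
  cm <- iceBalance(maskLowCoverage(
    ContactMatrix(checkerboardMatrix(20, 5), g)))
  expect_error(callCompartments(cm, mode = "cis"), "GC track")
})

test_that("subcompartmentPCA separates two planted trans-affinity groups", {
  nb <- 20
  g <- GenomeSpec(c(c1 = nb * 1e4, c2 = nb * 1e4), 1e4)
  # all bins labelled A; two affinity groups alternate within chromosomes
  grp <- rep(rep(c(0, 1), each = 5), 4)  # per-bin group over 40 bins
  M <- matrix(10, 2 * nb, 2 * nb)
  trBlock <- outer(grp[1:nb], grp[nb + 1:nb], "==")
  M[1:nb, nb + 1:nb][trBlock] <- 20
  M[1:nb, nb + 1:nb][!trBlock] <- 5
  M[nb + 1:nb, 1:nb] <- t(M[1:nb, nb + 1:nb])
  cm <- iceBalance(maskLowCoverage(ContactMatrix(M, g)), tol = 1e-8)
  track <- new("CompartmentTrack", genome = g,
               e1 = rep(1, 2 * nb), label = rep("A", 2 * nb),
               borders = data.frame(), mode = "cis", metadata = list())
  sub <- subcompartmentPCA(cm, track, centromereBins = which(grp == 1))
  expect_true(sub$hasSubstructure)
  got <- sub$subLabel
  agree <- mean(got[grp == 1] == "A1") + mean(got[grp == 0] == "A2")
  expect_gte(agree / 2, 0.95)
  expect_equal(sub$centromereSub, "A1")
})

test_that("a homogeneous compartment reports no sub-structure", {
  nb <- 10
  g <- GenomeSpec(c(c1 = nb * 1e4, c2 = nb * 1e4), 1e4)
  M <- matrix(10, 2 * nb, 2 * nb)
  cm <- iceBalance(maskLowCoverage(ContactMatrix(M, g)))
  track <- new("CompartmentTrack", genome = g,
               e1 = rep(1, 2 * nb), label = rep("A", 2 * nb),
               borders = data.frame(), mode = "cis", metadata = list())
  expect_warning(sub <- subcompartmentPCA(cm, track), "no sub-structure")
  expect_false(sub$hasSubstructure)
  expect_error(suppressWarnings(
    subcompartmentPCA(cm, track, whichLabel = "B")), "fewer than 4")
})

test_that("compareCompartments on identical tracks shows zero switching", {
  m <- balancedSim(seed = 1)
  tk <- simulateFeatureTracks(syntheticTruth(), fasta = FALSE, seed = 501)
  tr <- callCompartments(m, gc = tk$gc, mode = "cis")
  sw <- compareCompartments(tr, tr)
  expect_equal(sw$fractionSwitched, 0)
  expect_equal(unname(sw$categoryBp[c("A->B", "B->A")]), c(0, 0))
  expect_true(sum(sw$categoryBp) > 0)
})

test_that("a 20-bin toy with 2 flipped bins switches 10% of the genome", {
  nb <- 20
  g <- GenomeSpec(c(c1 = nb * 1e4), 1e4)
  mkTrack <- function(lab) {
    e1 <- ifelse(lab == "A", 1, -1)
    new("CompartmentTrack", genome = g, e1 = e1, label = lab,
        borders = data.frame(), mode = "cis", metadata = list())
  }
  labM <- rep(c("A", "B"), each = 10)
  labF <- labM
  labF[c(3, 14)] <- c("B", "A")
  sw <- compareCompartments(mkTrack(labM), mkTrack(labF))
  expect_equal(sw$fractionSwitched, 0.10)
  expect_setequal(names(sw$categoryBp), c("A->A", "B->B", "A->B", "B->A"))
  expect_equal(unname(sw$categoryBp["A->B"]), 1e4)
  expect_equal(unname(sw$categoryBp["B->A"]), 1e4)
  # regions tile the unmasked genome
  expect_equal(sum(sw$regions$bp), 2e5)
})

test_that("tracks on different binnings cannot be compared", {
  g1 <- GenomeSpec(c(c1 = 2e5), 1e4)
  g2 <- GenomeSpec(c(c1 = 2e5), 2e4)
  mk <- function(g) {
    nb <- nBins(g)
    new("CompartmentTrack", genome = g, e1 = rep(1, nb),
        label = rep("A", nb), borders = data.frame(), mode = "cis",
        metadata = list())
  }
  expect_error(compareCompartments(mk(g1), mk(g2)), "mismatched binning")
})

test_that("label counts plus masked bins account for the whole genome", {
  m <- balancedSim(seed = 1)
  tk <- simulateFeatureTracks(syntheticTruth(), fasta = FALSE, seed = 502)
  tr <- callCompartments(m, gc = tk$gc, mode = "cis")
  lab <- compartmentLabels(tr)
  expect_equal(sum(lab == "A") + sum(lab == "B") + sum(lab == "masked"),
               nBins(m))
  # border count equals the number of label sign changes
  nChanges <- sum(vapply(chromNames(m), function(ch) {
    l <- lab[chromBins(genomeOf(m), ch)]
    l <- l[l != "masked"]
    sum(l[-1] != l[-length(l)])
  }, numeric(1)))
  expect_equal(nrow(compartmentBorders(tr)), nChanges)
})
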