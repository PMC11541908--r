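# internal helpers

# run code with a fixed RNG state, restoring the caller's state afterwards
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# dense matrix from a Matrix object
denseMat <- function(m) as.matrix(m)

# sum over unordered bin pairs (upper triangle including the diagonal)
upperSum <- function(m) {
  m <- denseMat(m)
  sum(m[upper.tri(m, diag = FALSE)]) + sum(diag(m))
}

# mean ignoring NA, returning NA (not NaN) on empty input
meanNA <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

# global bin indices of the terminal `nTel` bins of each chromosome end
telomereBinIndices <- function(genome, nTel = 2L) {
  nb <- binsPerChrom(genome)
  off <- chromOffsets(genome)
  out <- lapply(names(nb), function(ch) {
    n <- nb[[ch]]
    k <- min(nTel, n)
    unique(c(off[[ch]] + seq_len(k), off[[ch]] + n - seq_len(k) + 1L))
  })
  setNames(out, names(nb))
}

# expand (chrom, start, end) to global bin indices (bins overlapping region)
regionBins <- function(genome, chrom, start, end) {
  if (!chrom %in% chromNames(genome)) stop("unknown chromosome: ", chrom)
  bt <- binTable(genome)
  which(bt$chrom == chrom & bt$end >= start & bt$start <= end)
}
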