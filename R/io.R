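# Readers and writers for the field's text formats: 4DN pairs, COO
# triplets, chrom.sizes, bedGraph, BED, TSV tables, FASTA.

#' Read a chrom.sizes table
#'
#' @param path two-column TSV (chrom, length), no header
#' @return named numeric vector of chromosome lengths
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  setNames(as.numeric(dt$length), as.character(dt$chrom))
}

#' Read a 4DN-style pairs file
#'
#' Plain or gzipped; `#` header lines are skipped and a `#columns:` line, if
#' present, names the columns.  Without one, the default 4DN layout
#' (readID chrom1 pos1 chrom2 pos2 [strand1 strand2 ...]) is assumed.
#' Positions are 1-based.
#'
#' @param path pairs file path
#' @return data.frame with chrom1, pos1, chrom2, pos2
#' @export
readPairsFile <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con)
  colLine <- grep("^#columns:", hdr, value = TRUE)
  cols <- if (length(colLine)) {
    strsplit(sub("^#columns:\\s*", "", colLine[1]), "\\s+")[[1]]
  } else {
    c("readID", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
  }
  dt <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                        fill = TRUE,
                                        blank.lines.skip = TRUE,
                                        skip = length(hdr)))
  dt <- dt[!startsWith(as.character(dt[[1]]), "#"), , drop = FALSE]
  names(dt)[seq_along(cols)] <- cols[seq_len(min(length(cols), ncol(dt)))]
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(dt))) {
    stop("pairs file lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  data.frame(chrom1 = as.character(dt$chrom1), pos1 = as.numeric(dt$pos1),
             chrom2 = as.character(dt$chrom2), pos2 = as.numeric(dt$pos2))
}

#' Write a pairs file
#'
#' @param pairs data.frame with chrom1, pos1, chrom2, pos2
#' @param path output path (plain text)
#' @param genome optional [GenomeSpec-class] used for the chromsize header
#' @export
writePairsFile <- function(pairs, path, genome = NULL) {
  hdr <- "## pairs format v1.0"
  if (!is.null(genome)) {
    lens <- chromLengths(genome)
    hdr <- c(hdr, paste0("#chromsize: ", names(lens), " ",
                         format(lens, scientific = FALSE, trim = TRUE)))
  }
  hdr <- c(hdr, "#columns: readID chrom1 pos1 chrom2 pos2")
  writeLines(hdr, path)
  data.table::fwrite(data.frame(readID = seq_len(nrow(pairs)),
                                pairs[, c("chrom1", "pos1",
                                          "chrom2", "pos2")]),
                     path, sep = "\t", col.names = FALSE, append = TRUE)
}

#' Expand a contact matrix into a pairs table at bin midpoints
#'
#' @param m a [ContactMatrix-class]
#' @return data.frame (chrom1, pos1, chrom2, pos2), one row per contact
#' @export
pairsFromMatrix <- function(m) {
  bt <- binTable(m@genome)
  mid <- floor((bt$start + bt$end) / 2)
  M <- denseMat(m@counts)
  sel <- which(upper.tri(M, diag = TRUE) & M > 0, arr.ind = TRUE)
  cnt <- M[sel]
  i <- rep(sel[, 1], cnt)
  j <- rep(sel[, 2], cnt)
  data.frame(chrom1 = bt$chrom[i], pos1 = mid[i],
             chrom2 = bt$chrom[j], pos2 = mid[j])
}

#' Read a COO triplet matrix
#'
#' Three columns (bin1, bin2, count) with 0-based global bin indices, as in
#' text exports of cooler-style stores.
#'
#' @param path triplet TSV path (with or without header)
#' @param genome the [GenomeSpec-class] the bins refer to
#' @return a [ContactMatrix-class]
#' @export
readCOO <- function(path, genome) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 3L) stop("COO file needs 3 columns")
  names(dt)[1:3] <- c("bin1", "bin2", "count")
  nb <- nBins(genome)
  i <- as.integer(dt$bin1) + 1L
  j <- as.integer(dt$bin2) + 1L
  if (any(i < 1 | i > nb | j < 1 | j > nb)) stop("bin index out of range")
  ii <- pmin(i, j)
  jj <- pmax(i, j)
  up <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(dt$count),
                             dims = c(nb, nb))
  counts <- up + Matrix::t(up) - Matrix::Diagonal(nb, x = Matrix::diag(up))
  ContactMatrix(counts, genome)
}

#' Write a contact matrix as COO triplets
#'
#' Upper-triangle (canonical) cells with 0-based global bin indices.
#'
#' @param m a [ContactMatrix-class]
#' @param path output TSV path
#' @export
writeCOO <- function(m, path) {
  M <- denseMat(m@counts)
  sel <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  dt <- data.table::data.table(bin1 = sel[, 1] - 1L, bin2 = sel[, 2] - 1L,
                               count = M[sel])
  data.table::setorder(dt, bin1, bin2)
  data.table::fwrite(dt, path, sep = "\t")
}

#' Read a per-bin bedGraph track
#'
#' Values are averaged (coverage-weighted) over each bin.
#'
#' @param path bedGraph path
#' @param genome a [GenomeSpec-class]
#' @return numeric per-bin values (NA where the track has no coverage)
#' @export
readBedGraphTrack <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- binRanges(genome)
  hits <- GenomicRanges::findOverlaps(bins, gr)
  num <- den <- numeric(length(bins))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(bins)[q], IRanges::ranges(gr)[s]))
    num <- as.vector(tapply(ov * gr$score[s], factor(q, seq_along(bins)),
                            sum, default = 0))
    den <- as.vector(tapply(ov, factor(q, seq_along(bins)), sum,
                            default = 0))
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Write a per-bin track as bedGraph
#'
#' @param values numeric per-bin values (NA bins skipped)
#' @param genome a [GenomeSpec-class]
#' @param path output path
#' @export
writeBedGraphTrack <- function(values, genome, path) {
  bins <- binRanges(genome)
  keep <- !is.na(values)
  gr <- bins[keep]
  gr$score <- values[keep]
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["score"]
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end (1-based closed) and optional
#'   `name` and `score` columns
#' @param path output path
#' @export
writeBED <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "bed")
}

#' Read a repeat-annotation table
#'
#' TSV with columns chrom, start, end, family, class (header required);
#' BED-derived 0-based starts can be flagged with `zeroBased = TRUE`.
#'
#' @param path TSV path
#' @param zeroBased starts are 0-based half-open (default FALSE)
#' @return data.frame (chrom, start, end, family, class)
#' @export
readRepeatTable <- function(path, zeroBased = FALSE) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("chrom", "start", "end", "family", "class")
  if (!all(need %in% names(dt))) {
    stop("repeat table lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  if (zeroBased) dt$start <- dt$start + 1
  dt[, need]
}

#' Read a peak table
#'
#' @param path TSV with chrom, start, end, mark, fold_enrichment
#' @return data.frame
#' @export
readPeakTable <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("chrom", "start", "end", "mark", "fold_enrichment")
  if (!all(need %in% names(dt))) {
    stop("peak table lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  dt
}

#' Read a gene table
#'
#' @param path TSV with gene_id, chrom, start, end plus TPM / DE columns
#' @return data.frame
#' @export
readGeneTable <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(dt))) {
    stop("gene table lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  dt
}

#' Export the genome's bins as BED
#'
#' @param genome a [GenomeSpec-class]
#' @param path output path
#' @export
writeBinsBED <- function(genome, path) {
  bt <- binTable(genome)
  bt$name <- paste0("bin", bt$bin)
  writeBED(bt, path)
}
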