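# Standard-format I/O and read-level QC: quality filtering, 3' adapter
# trimming, read collapsing and length profiling.

#' Read a genome FASTA into a scaffold set
#'
#' Sequences are folded to upper case; multi-line wrapping is accepted.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet] (unique names enforced).
#' @export
readFastaGenome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate scaffold names in ", path)
  if (any(width(x) == 0)) stop("empty FASTA record in ", path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a scaffold set to FASTA
#' @param set named DNAStringSet (or named character vector).
#' @param path output file.
#' @export
writeFastaGenome <- function(set, path) {
  set <- asScaffoldSet(set)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read small-RNA FASTQ (Phred+33)
#' @param path FASTQ file.
#' @return data.frame with columns id, seq, qual.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write small-RNA reads to FASTQ (Phred+33)
#' @param reads data.frame with id, seq, qual.
#' @param path output file.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

phredValues <- function(qual) utf8ToInt(qual) - 33L

# Low-complexity ("simple repeat") rule: a single base covering >= 80% of the
# read, or a 1-2 nt motif whose tandem repetition covers >= 90% of it.
isSimpleRepeat <- function(seq) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  if (max(table(ch)) / n >= 0.8) return(TRUE)
  for (w in 1:2) {
    for (off in seq_len(w)) {
      # longest tandem coverage of any motif of width w starting anywhere
      s <- substr(seq, off, n)
      m <- nchar(s) %/% w
      if (m < 2) next
      motifs <- substring(s, (0:(m - 1)) * w + 1, (0:(m - 1)) * w + w)
      r <- rle(motifs)
      if (max(r$lengths) * w / n >= 0.9) return(TRUE)
    }
  }
  FALSE
}

#' Quality-filter small-RNA reads
#'
#' Applies the read-level QC rules used for small-RNA libraries: reads are
#' discarded when, in this order, their length falls outside
#' `[min_len, max_len]`, they contain more than `max_n` Ns, any base is below
#' `min_phred`, or they are simple-repeat sequences (one base >= 80% of the
#' read or a 1-2 nt motif tandemly covering >= 90%). Each discarded read is
#' counted once, under the first matching reason.
#'
#' @param reads data.frame with id, seq, qual (Phred+33), e.g. from
#'   [readFastq()] after [trimAdapter()].
#' @param min_phred minimum per-base Phred score (default 20).
#' @param max_n maximum number of N bases (default 3).
#' @param min_len,max_len length window after trimming (default 18-30).
#' @return list with `reads` (kept rows) and `report` (named counts:
#'   kept, length, max_n, quality, simple_repeat).
#' @export
filterReads <- function(reads, min_phred = 20, max_n = 3,
                        min_len = 18, max_len = 30) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed record: sequence/quality length mismatch at index ",
         which(nchar(reads$seq) != nchar(reads$qual))[1])
  n <- nchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  bad_len <- n < min_len | n > max_len
  reason[bad_len] <- "length"
  nN <- vapply(strsplit(reads$seq, ""), function(x) sum(x == "N"), integer(1))
  reason[is.na(reason) & nN > max_n] <- "max_n"
  minq <- vapply(reads$qual, function(q) min(phredValues(q)), numeric(1),
                 USE.NAMES = FALSE)
  reason[is.na(reason) & minq < min_phred] <- "quality"
  simple <- vapply(reads$seq, isSimpleRepeat, logical(1), USE.NAMES = FALSE)
  reason[is.na(reason) & simple] <- "simple_repeat"
  keep <- is.na(reason)
  report <- c(kept = sum(keep),
              length = sum(reason == "length", na.rm = TRUE),
              max_n = sum(reason == "max_n", na.rm = TRUE),
              quality = sum(reason == "quality", na.rm = TRUE),
              simple_repeat = sum(reason == "simple_repeat", na.rm = TRUE))
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' Trim a 3' adapter from one or more reads
#'
#' Finds the longest adapter prefix that aligns (ungapped) at the read's 3'
#' end with a mismatch rate <= `max_err_rate` and overlap >= `min_overlap`,
#' and removes it. Ties are broken toward the longer match. Reads without a
#' qualifying overlap are returned unchanged and flagged.
#'
#' @param seqs character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter prefix length (default 6).
#' @param max_err_rate maximum mismatch fraction within the overlap (0.1).
#' @return data.frame with `seq` (trimmed) and `trimmed` flag.
#' @export
trimAdapter <- function(seqs, adapter, min_overlap = 6, max_err_rate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  ov <- .adapter_overlap(seqs, adapter, as.integer(min_overlap), max_err_rate)
  data.frame(seq = substr(seqs, 1L, nchar(seqs) - ov), trimmed = ov > 0L,
             stringsAsFactors = FALSE)
}

#' Collapse reads to unique sequences with copy numbers
#'
#' Identical sequences are merged and their copies summed; entries with fewer
#' than `min_copy` copies are dropped (low-copy reads carry no stack
#' evidence). Output order is deterministic: copy number descending, then
#' sequence.
#'
#' @param seqs character vector of QC'd read sequences.
#' @param min_copy minimum copy number kept (default 3).
#' @return data.frame with id, seq, count.
#' @export
collapseReads <- function(seqs, min_copy = 3) {
  if (length(seqs) == 0)
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0)))
  tab <- table(seqs)
  d <- data.frame(seq = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[d$count >= min_copy, , drop = FALSE]
  d <- d[order(-d$count, d$seq), , drop = FALSE]
  d$id <- if (nrow(d)) sprintf("cr%06d", seq_len(nrow(d))) else character(0)
  rownames(d) <- NULL
  d[, c("id", "seq", "count")]
}

#' Read-length histogram
#' @param seqs character vector of read sequences.
#' @param min_len,max_len histogram range (default 18-30).
#' @return named integer vector of counts per length; lengths outside the
#'   range are counted in the flanking bins' complement (dropped) -- with
#'   QC'd input every read falls inside the range.
#' @export
lengthDistribution <- function(seqs, min_len = 18, max_len = 30) {
  lens <- factor(nchar(seqs), levels = min_len:max_len)
  tab <- table(lens)
  setNames(as.integer(tab), names(tab))
}

#' Read a BED file of exclusion annotations
#'
#' BED is 0-based half-open on disk; intervals are returned as a 1-based
#' [GenomicRanges::GRanges] with a `category` metadata column taken from the
#' BED name field (CDS, tRNA, rRNA, snRNA, snoRNA, repeat).
#'
#' @param path BED file (3-6 columns, tab-separated).
#' @return GRanges with mcols `category`.
#' @export
readBed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED needs at least 3 columns")
  if (any(d[[2]] >= d[[3]])) stop("BED interval with start >= end")
  gr <- GenomicRanges::GRanges(d[[1]],
          IRanges::IRanges(start = d[[2]] + 1L, end = d[[3]]),
          strand = if (ncol(d) >= 6) d[[6]] else "*")
  mcols(gr)$category <- if (ncol(d) >= 4) d[[4]] else NA_character_
  gr
}

#' Write annotation intervals to BED
#' @param gr GRanges with optional `category` mcol.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
  d <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                  mcols(gr)$category %||% ".", 0L,
                  as.character(GenomicRanges::strand(gr)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write miRNA calls to GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per precursor and a nested
#' `miRNA` feature per mature arm, with 1-based inclusive coordinates.
#'
#' @param calls a calls GRanges from [discoverMirnas()] / [mergeCallSets()].
#' @param path output file.
#' @param genome optional scaffold set used to check coordinate overflow.
#' @export
writeGff3 <- function(calls, path, genome = NULL) {
  if (!is.null(genome)) {
    genome <- asScaffoldSet(genome)
    w <- setNames(width(genome), names(genome))
    sc <- as.character(GenomicRanges::seqnames(calls))
    if (any(!(sc %in% names(w))) ||
        any(GenomicRanges::end(calls) > w[sc]) ||
        any(GenomicRanges::start(calls) < 1))
      stop("call coordinates overflow the scaffold")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  m <- mcols(calls)
  for (k in seq_along(calls)) {
    sc <- as.character(GenomicRanges::seqnames(calls)[k])
    st <- as.character(GenomicRanges::strand(calls)[k])
    if (st == "*") st <- "+"
    id <- m$id[k]
    writeLines(sprintf(
      "%s\tmirburst\tmiRNA_primary_transcript\t%d\t%d\t%s\t%s\t.\tID=%s",
      sc, GenomicRanges::start(calls)[k], GenomicRanges::end(calls)[k],
      format(m$score[k] %||% ".", trim = TRUE), st, id), con)
    if (!is.null(m$matureStart) && !is.na(m$matureStart[k]))
      writeLines(sprintf(
        "%s\tmirburst\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_mature;Parent=%s",
        sc, m$matureStart[k], m$matureEnd[k], st, id, id), con)
    if (!is.null(m$starStart) && !is.na(m$starStart[k]))
      writeLines(sprintf(
        "%s\tmirburst\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_star;Parent=%s",
        sc, m$starStart[k], m$starEnd[k], st, id, id), con)
  }
  invisible(path)
}
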