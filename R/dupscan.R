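# Duplication scanning: local and glocal alignment, Karlin-Altschul
# E-values, all-vs-all precursor similarity, divergence rates, family
# clustering/consensus, and glocal flank scans with distance binning.

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Scoring: `match` +1, `mismatch` -2, first gap column `gap_open` -5, each
#' further gap column `gap_extend` -2 by default. Ties are broken toward the
#' smallest end coordinates.
#'
#' @param a,b DNA sequences.
#' @param match,mismatch,gap_open,gap_extend scoring scheme.
#' @return list with score, cols, matches, mismatches, gapcols, identity and
#'   0-based half-open aligned spans (a_start, a_end, b_start, b_end).
#' @export
localAlign <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                       gap_extend = -2) {
  .sw_align(a, b, match, mismatch, gap_open, gap_extend)
}

#' Query-global, target-local ("glocal") alignment
#'
#' The whole query is aligned; end gaps are free in the target only. Same
#' scoring scheme and tie-break as [localAlign()].
#'
#' @inheritParams localAlign
#' @param with_path also return the per-column alignment path.
#' @return list as in [localAlign()] (the query span is always 0..len(a)).
#' @export
glocalAlign <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                        gap_extend = -2, with_path = FALSE) {
  if (nchar(a) > nchar(b)) stop("query longer than target")
  .glocal_align(a, b, match, mismatch, gap_open, gap_extend, with_path)
}

#' Solve Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' lambda is the unique positive root of
#' `sum_ij p_i p_j exp(lambda s_ij) = 1`, solved by bisection to 1e-9.
#' K is fixed at 0.35, a documented approximation for DNA scoring schemes
#' of this family; it scales all E-values by a constant that is absorbed
#' into the (configurable) significance threshold.
#'
#' @param match,mismatch scoring scheme (expected pairwise score must be
#'   negative).
#' @param composition base composition (default uniform).
#' @return list with lambda, K, composition.
#' @export
solveKA <- function(match = 1, mismatch = -2,
                    composition = rep(0.25, 4)) {
  composition <- composition / sum(composition)
  p_match <- sum(composition^2)
  es <- p_match * match + (1 - p_match) * mismatch
  if (es >= 0)
    stop("scoring scheme not local-alignment valid (expected score >= 0)")
  f <- function(l) p_match * exp(l * match) +
    (1 - p_match) * exp(l * mismatch) - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  list(lambda = (lo + hi) / 2, K = 0.35, composition = composition)
}

#' Karlin-Altschul E-value
#'
#' `E = K m n exp(-lambda S)`: the expected number of chance local
#' alignments scoring >= S between sequences of lengths m and n.
#'
#' @param score alignment score.
#' @param m,n sequence lengths.
#' @param ka parameters from [solveKA()].
#' @return the E-value.
#' @export
evalue <- function(score, m, n, ka) {
  ka$K * m * n * exp(-ka$lambda * score)
}

#' Percent divergence of an alignment
#'
#' `100 (mismatches + gap columns) / aligned columns`. Gap columns count as
#' mismatched bases by default; set `count_gaps = FALSE` to exclude them
#' from both numerator and denominator.
#'
#' @param hit alignment list from [localAlign()]/[glocalAlign()].
#' @param count_gaps include gap columns (default TRUE).
#' @return percent divergence.
#' @export
divergenceRate <- function(hit, count_gaps = TRUE) {
  if (hit$cols < 1) stop("empty alignment")
  if (count_gaps) 100 * (hit$mismatches + hit$gapcols) / hit$cols
  else 100 * hit$mismatches / (hit$cols - hit$gapcols)
}

#' All-vs-all precursor similarity search
#'
#' Aligns every precursor pair locally and keeps pairs with
#' `E < evalue_max` and coverage of the shorter precursor above
#' `min_coverage`. Self-pairs are excluded; the kept set is symmetric.
#'
#' @param precursors named character vector (>= 2).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param min_coverage minimum aligned fraction of the shorter precursor
#'   (default 0.5).
#' @param match,mismatch,gap_open,gap_extend scoring scheme.
#' @return data.frame with query, target, score, identity, coverage, evalue,
#'   divergence.
#' @export
allVsAllSimilarity <- function(precursors, evalue_max = 1e-5,
                               min_coverage = 0.5, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  if (length(precursors) < 2) stop("need >= 2 precursors")
  ids <- names(precursors) %||% as.character(seq_along(precursors))
  ka <- solveKA(match, mismatch)
  out <- list()
  for (i in seq_along(precursors)) {
    for (j in seq_along(precursors)) {
      if (j <= i) next
      h <- localAlign(precursors[[i]], precursors[[j]], match, mismatch,
                      gap_open, gap_extend)
      if (h$cols == 0) next
      m <- nchar(precursors[[i]]); n <- nchar(precursors[[j]])
      E <- evalue(h$score, m, n, ka)
      shorter <- min(m, n)
      covShort <- if (m <= n) (h$a_end - h$a_start) / m
                  else (h$b_end - h$b_start) / n
      if (E < evalue_max && covShort > min_coverage)
        out[[length(out) + 1L]] <- data.frame(
          query = ids[i], target = ids[j], score = h$score,
          identity = h$identity, coverage = covShort, evalue = E,
          divergence = divergenceRate(h), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(query = character(0), target = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), evalue = numeric(0),
                      divergence = numeric(0)))
  do.call(rbind, out)
}

#' Cluster precursors into families (connected components)
#'
#' @param pairs data.frame from [allVsAllSimilarity()].
#' @param ids all precursor ids (singletons become their own family).
#' @return list of character vectors, one per family.
#' @export
familyCluster <- function(pairs, ids) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(match(pairs$query[k], ids))
      b <- find(match(pairs$target[k], ids))
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_along(ids), find, numeric(1))
  unname(split(ids, root))
}

#' Majority-rule family consensus
#'
#' Glocally aligns every member to the longest member and takes the
#' per-column majority base; ties are resolved alphabetically and flagged.
#'
#' @param family character vector of member ids.
#' @param precursors named character vector of sequences.
#' @return list with `consensus` (string over the longest member's columns)
#'   and `ties` (1-based tied positions).
#' @export
familyConsensus <- function(family, precursors) {
  seqs <- precursors[family]
  anchor <- which.max(nchar(seqs))
  target <- seqs[[anchor]]
  L <- nchar(target)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, L, dimnames = list(bases, NULL))
  for (s in seqs) {
    h <- glocalAlign(s, target, with_path = TRUE)
    path <- h$path
    qc <- strsplit(toupper(s), "")[[1]]
    for (r in seq_len(nrow(path))) {
      qi <- path[r, 1]; tj <- path[r, 2]
      if (qi > 0 && tj > 0 && qc[qi] %in% bases)
        counts[qc[qi], tj] <- counts[qc[qi], tj] + 1
    }
  }
  cons <- character(L); ties <- integer(0)
  for (j in seq_len(L)) {
    mx <- max(counts[, j])
    best <- bases[counts[, j] == mx]
    if (length(best) > 1) ties <- c(ties, j)
    cons[j] <- best[1]
  }
  list(consensus = paste(cons, collapse = ""), ties = ties)
}

#' Scan genomic flanks for duplicated precursor copies
#'
#' For each call, extracts the +/- `window` bp flank (clipped at scaffold
#' ends) and repeatedly glocally aligns the precursor against both strands,
#' masking each hit, until the best identity drops below `min_identity`.
#' Hits overlapping the original precursor span are excluded from the
#' report (the self-hit is masked and the scan continues). Distances are
#' edge-to-edge (0 when abutting).
#'
#' @param genome named DNAStringSet.
#' @param calls calls GRanges with `id` and `precursorSeq` mcols.
#' @param window flank size each side (default 50000 bp).
#' @param min_identity identity floor for reported hits (default 0.7,
#'   calibrated above the background of best random glocal alignments over
#'   flanks of this size, which tops out near 0.64 for 60-110 nt queries).
#' @param max_iter per-strand iteration cap (default 16).
#' @return data.frame of duplication hits: id, scaffold, start, end, strand,
#'   score, identity, distance.
#' @export
flankScan <- function(genome, calls, window = 50000, min_identity = 0.7,
                      max_iter = 16) {
  genome <- asScaffoldSet(genome)
  chrs <- as.character(genome)
  out <- list()
  for (k in seq_along(calls)) {
    sc <- as.character(GenomicRanges::seqnames(calls)[k])
    os <- GenomicRanges::start(calls)[k]; oe <- GenomicRanges::end(calls)[k]
    q <- mcols(calls)$precursorSeq[k]
    if (is.na(q) || !nzchar(q)) next
    fs <- max(1L, os - window); fe <- min(nchar(chrs[[sc]]), oe + window)
    tgt <- substr(chrs[[sc]], fs, fe)
    for (strand in c("+", "-")) {
      t <- if (strand == "-") revComp(tgt) else tgt
      for (it in seq_len(max_iter)) {
        h <- glocalAlign(q, t)
        if (h$identity < min_identity) break
        # genome coordinates of the hit
        if (strand == "-") {
          gs <- fe - h$b_end + 1L; ge <- fe - h$b_start
        } else {
          gs <- fs + h$b_start; ge <- fs + h$b_end - 1L
        }
        overlaps_original <- gs <= oe && ge >= os
        if (!overlaps_original) {
          distance <- if (ge < os) os - ge - 1L else gs - oe - 1L
          out[[length(out) + 1L]] <- data.frame(
            id = mcols(calls)$id[k], scaffold = sc, start = gs, end = ge,
            strand = strand, score = h$score, identity = h$identity,
            distance = distance, stringsAsFactors = FALSE)
        }
        # mask and continue
        substr(t, h$b_start + 1L, h$b_end) <-
          strrep("N", h$b_end - h$b_start)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      identity = numeric(0), distance = numeric(0)))
  do.call(rbind, out)
}

#' Bin duplication distances into 5-kb intervals
#'
#' Ten bins [0, 5k), [5k, 10k), ..., [45k, 50k]; hits beyond `max` are
#' dropped and tallied.
#'
#' @param hits data.frame from [flankScan()] (needs `distance`).
#' @param bin bin width (default 5000).
#' @param max maximum distance (default 50000).
#' @return list with `counts` (named integer vector) and `dropped`.
#' @export
distanceHistogram <- function(hits, bin = 5000, max = 50000) {
  breaks <- seq(0, max, by = bin)
  labels <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  d <- hits$distance
  dropped <- sum(d > max)
  d <- d[d <= max]
  idx <- pmin(length(labels), floor(d / bin) + 1L)
  counts <- setNames(integer(length(labels)), labels)
  if (length(idx)) {
    t <- table(idx)
    counts[as.integer(names(t))] <- as.integer(t)
  }
  list(counts = counts, dropped = dropped)
}

#' Compare duplication-distance histograms across genomes
#'
#' @param genome_calls named list; each element is a list with `genome` and
#'   `calls` as taken by [flankScan()].
#' @param ... passed to [flankScan()].
#' @return data.frame with one row per genome x bin plus totals.
#' @export
compareGenomes <- function(genome_calls, ...) {
  rows <- lapply(names(genome_calls), function(nm) {
    g <- genome_calls[[nm]]
    hits <- flankScan(g$genome, g$calls, ...)
    h <- distanceHistogram(hits)
    data.frame(genome = nm, bin = names(h$counts),
               count = as.integer(h$counts), total = nrow(hits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
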