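# miRNA discovery from read stacks: genome mapping, candidate hairpin
# excision, read-evidence scoring, permutation signal-to-noise calibration,
# annotation filtering and conserved/lineage-specific classification.

#' Map collapsed reads to a genome (exact or mismatch-tolerant)
#'
#' All hits on both strands with at most `max_mismatch` mismatches are
#' reported; reads hitting more than `max_hits` genomic locations are
#' discarded and counted (multimappers are dominated by repeat-derived
#' fragments). Exact matching uses a preprocessed dictionary per read width;
#' mismatch-tolerant matching uses a full sliding scan.
#'
#' @param genome named DNAStringSet.
#' @param creads collapsed reads data.frame (id, seq, count).
#' @param max_mismatch maximum mismatches (default 0).
#' @param max_hits maximum genomic hits per read (default 5).
#' @return list with `mappings` (data.frame: id, seq, count, scaffold, start,
#'   end, strand, mismatches, n_hits; 1-based inclusive coordinates) and
#'   `discarded` (multimapper count).
#' @export
mapReads <- function(genome, creads, max_mismatch = 0, max_hits = 5) {
  if (length(genome) == 0) stop("genome is empty")
  genome <- asScaffoldSet(genome)
  if (sum(width(genome)) == 0) stop("genome is empty")
  if (nrow(creads) == 0)
    return(list(mappings = emptyMappings(), discarded = 0L))
  hits <- list()
  addHits <- function(idx, scaffold, start, strand, mm) {
    if (length(idx) == 0) return()
    hits[[length(hits) + 1L]] <<- data.frame(
      row = idx, scaffold = scaffold, start = start, strand = strand,
      mismatches = mm, stringsAsFactors = FALSE)
  }
  if (max_mismatch == 0) {
    widths <- nchar(creads$seq)
    for (w in unique(widths)) {
      rows <- which(widths == w)
      fwd <- Biostrings::DNAStringSet(creads$seq[rows])
      rev <- Biostrings::reverseComplement(fwd)
      pdF <- Biostrings::PDict(fwd)
      pdR <- Biostrings::PDict(rev)
      for (sc in names(genome)) {
        mF <- Biostrings::matchPDict(pdF, genome[[sc]])
        mR <- Biostrings::matchPDict(pdR, genome[[sc]])
        sF <- Biostrings::startIndex(mF); sR <- Biostrings::startIndex(mR)
        for (k in seq_along(rows)) {
          if (length(sF[[k]]))
            addHits(rep(rows[k], length(sF[[k]])), sc, sF[[k]], "+", 0L)
          if (length(sR[[k]]))
            addHits(rep(rows[k], length(sR[[k]])), sc, sR[[k]], "-", 0L)
        }
      }
    }
  } else {
    for (sc in names(genome)) {
      subj <- as.character(genome[[sc]])
      hF <- .mismatch_scan(subj, creads$seq, max_mismatch)
      addHits(hF$query, sc, hF$pos + 1L, "+", hF$mismatches)
      hR <- .mismatch_scan(subj, revComp(creads$seq), max_mismatch)
      addHits(hR$query, sc, hR$pos + 1L, "-", hR$mismatches)
    }
  }
  if (length(hits) == 0)
    return(list(mappings = emptyMappings(), discarded = 0L))
  h <- do.call(rbind, hits)
  nh <- table(h$row)
  h$n_hits <- as.integer(nh[as.character(h$row)])
  keep <- h$n_hits <= max_hits
  discarded <- length(unique(h$row[!keep]))
  h <- h[keep, , drop = FALSE]
  m <- data.frame(
    id = creads$id[h$row], seq = creads$seq[h$row],
    count = creads$count[h$row], scaffold = h$scaffold, start = h$start,
    end = h$start + nchar(creads$seq[h$row]) - 1L, strand = h$strand,
    mismatches = h$mismatches, n_hits = h$n_hits, stringsAsFactors = FALSE)
  m <- m[order(m$scaffold, m$strand, m$start, m$id), , drop = FALSE]
  rownames(m) <- NULL
  list(mappings = m, discarded = discarded)
}

emptyMappings <- function() {
  data.frame(id = character(0), seq = character(0), count = integer(0),
             scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), mismatches = integer(0),
             n_hits = integer(0), stringsAsFactors = FALSE)
}

# Pick the pair ladder that best explains a read stack inside a folded
# window: the longest nested pair chain whose span overlaps the stack
# (side branches are skipped, so bulged stems are recovered whole).
stackLadder <- function(struct, stack_lo, stack_hi) {
  p <- struct@pairs
  ch <- longestNestedChain(p, lo = stack_lo, hi = stack_hi)
  if (is.null(ch)) return(NULL)
  c(min(p[ch, 1]), max(p[ch, 2]))
}

#' Excise candidate precursor hairpins around read stacks
#'
#' Read stacks (maximal runs of overlapping same-strand hits) seed two
#' windows each, one extended `extension` nt downstream of the stack and one
#' upstream. Each window is folded; the pair ladder through the stack defines
#' the candidate stem-loop, which is trimmed (plus `pad` nt of context),
#' refolded and kept only when its dominant ladder has at least `min_pairs`
#' pairs, it spans at least `min_len` nt, and its energy is at most
#' `per_base` x length. The dinucleotide-shuffle z-score is computed and
#' carried into the evidence score (`S_struct`); by default it is not a hard
#' gate (`z_max = Inf`), because under a pair-counting energy model a hard z
#' cutoff misclassifies a sizeable share of genuine but diverged hairpins --
#' the permutation signal-to-noise cutoff provides the false-positive
#' control. Read coordinates are attached in transcript orientation.
#'
#' @param genome named DNAStringSet.
#' @param mappings mappings data.frame from [mapReads()].
#' @param extension window extension in nt (default 110).
#' @param n_shuffles shuffled controls per stability z-score.
#' @param z_max,per_base folding stability criterion.
#' @param min_len minimum candidate length (default 40 nt).
#' @param min_pairs minimum pairs in the dominant ladder (default 10).
#' @param pad nt added on each side of the trimmed stem-loop (default 6).
#' @param seed RNG seed (fans out per locus, so candidate order is
#'   irrelevant).
#' @return list of candidates; each has scaffold, strand, start, end, seq,
#'   struct, mfe_z, paired fraction and a reads data.frame (local transcript
#'   coordinates s, e, count).
#' @export
exciseCandidates <- function(genome, mappings, extension = 110,
                             n_shuffles = 100, z_max = Inf, per_base = -0.2,
                             min_len = 40, min_pairs = 10, pad = 6,
                             seed = 1L) {
  genome <- asScaffoldSet(genome)
  if (nrow(mappings) == 0) return(list())
  gr <- GenomicRanges::GRanges(mappings$scaffold,
          IRanges::IRanges(mappings$start, mappings$end),
          strand = mappings$strand)
  stacks <- GenomicRanges::reduce(gr)
  cands <- list()
  seen <- character(0)
  chrs <- as.character(genome)
  for (k in seq_along(stacks)) {
    sc <- as.character(GenomicRanges::seqnames(stacks)[k])
    st <- as.character(GenomicRanges::strand(stacks)[k])
    s <- GenomicRanges::start(stacks)[k]; e <- GenomicRanges::end(stacks)[k]
    slen <- nchar(chrs[[sc]])
    for (win in list(c(s, min(slen, e + extension)),
                     c(max(1L, s - extension), e))) {
      wseq <- substr(chrs[[sc]], win[1], win[2])
      tseq <- if (st == "-") revComp(wseq) else wseq
      wlen <- nchar(wseq)
      # stack span in transcript coords
      if (st == "-") {
        lo <- win[2] - e + 1L; hi <- win[2] - s + 1L
      } else {
        lo <- s - win[1] + 1L; hi <- e - win[1] + 1L
      }
      struct <- foldMFE(tseq)
      span <- stackLadder(struct, lo, hi)
      if (is.null(span)) next
      # pad: precursor boundaries extend slightly past the outermost pair
      span <- c(max(1L, span[1] - pad), min(wlen, span[2] + pad))
      cseq <- substr(tseq, span[1], span[2])
      clen <- nchar(cseq)
      if (clen < min_len) next
      # genome coordinates of the trimmed candidate
      if (st == "-") {
        gstart <- win[2] - span[2] + 1L; gend <- win[2] - span[1] + 1L
      } else {
        gstart <- win[1] + span[1] - 1L; gend <- win[1] + span[2] - 1L
      }
      key <- paste(sc, st, gstart, gend)
      if (key %in% seen) next
      cstruct <- hairpinModel(cseq)
      hp <- isHairpin(cstruct)
      if (!hp$is_hairpin || nrow(cstruct@pairs) < min_pairs) next
      z <- mfeZ(cseq, n_shuffles = n_shuffles,
                seed = stageSeed(seed, key))
      if (!mfeCriterion(.nussinov_energy(cseq), z, clen,
                        z_max = z_max, per_base = per_base)) next
      seen <- c(seen, key)
      rows <- mappings$scaffold == sc & mappings$strand == st &
        mappings$start <= gend & mappings$end >= gstart
      rd <- mappings[rows, , drop = FALSE]
      if (st == "-") {
        rs <- gend - rd$end + 1L; re <- gend - rd$start + 1L
      } else {
        rs <- rd$start - gstart + 1L; re <- rd$end - gstart + 1L
      }
      cands[[length(cands) + 1L]] <- list(
        scaffold = sc, strand = st, start = gstart, end = gend,
        seq = cseq, struct = cstruct, energy = .nussinov_energy(cseq),
        mfe_z = z,
        paired_fraction = hp$paired_fraction, stem_length = hp$stem_length,
        reads = data.frame(s = rs, e = re, count = rd$count,
                           id = rd$id, stringsAsFactors = FALSE))
    }
  }
  cands
}

# Partner lookup table for a pair matrix over a sequence of length n.
partnerVector <- function(pairs, n) {
  part <- integer(n)
  if (nrow(pairs)) {
    part[pairs[, 1]] <- pairs[, 2]
    part[pairs[, 2]] <- pairs[, 1]
  }
  part
}

# Arm spans of a single-ladder structure: [i0, iK] (5P) and [jK, j0] (3P).
armSpans <- function(struct) {
  p <- struct@pairs
  if (nrow(p) == 0) return(NULL)
  list(arm5 = c(min(p[, 1]), max(p[, 1])), arm3 = c(min(p[, 2]), max(p[, 2])))
}

# Core evidence computation from a candidate structure and a read table
# (local transcript coordinates). Used for both real and permuted reads.
scoreFromReads <- function(cand, reads, arm_tol = 5, end_tol = 2) {
  arms <- armSpans(cand$struct)
  n <- nchar(cand$seq)
  part <- partnerVector(cand$struct@pairs, n)
  in5 <- reads$s >= arms$arm5[1] - arm_tol & reads$e <= arms$arm5[2] + arm_tol
  in3 <- !in5 & reads$s >= arms$arm3[1] - arm_tol &
    reads$e <= arms$arm3[2] + arm_tol
  arm <- ifelse(in5, "5P", ifelse(in3, "3P", "none"))
  modal <- list()
  n_c <- 0
  for (a in c("5P", "3P")) {
    rows <- arm == a
    if (!any(rows)) { modal[[a]] <- NULL; next }
    m5 <- weightedMode(reads$s[rows], reads$count[rows])
    m3 <- weightedMode(reads$e[rows], reads$count[rows])
    modal[[a]] <- c(m5, m3)
    n_c <- n_c + sum(reads$count[rows][abs(reads$s[rows] - m5) <= end_tol])
  }
  n_i <- sum(reads$count) - n_c
  s_reads <- log2((n_c + 1) / (n_i + 1))
  # duplex geometry of the modal products: 2 +/- 1 nt 3' overhangs. The
  # product end may be frayed or sit next to a bulge, so the implied duplex
  # partner is extrapolated from each paired anchor within 2 nt of the 5'
  # end and the interpretation closest to the canonical 2-nt overhang wins.
  s_duplex <- -2
  if (!is.null(modal[["5P"]]) && !is.null(modal[["3P"]])) {
    overhang <- function(pos, partner_end) {
      best <- NA_real_
      for (d in -2:2) {
        p <- pos + d
        if (p < 1 || p > n || part[p] == 0) next
        ov <- partner_end - (part[p] + (p - pos))
        if (is.na(best) || abs(ov - 2) < abs(best - 2)) best <- ov
      }
      best
    }
    ov1 <- overhang(modal[["5P"]][1], modal[["3P"]][2])
    ov2 <- overhang(modal[["3P"]][1], modal[["5P"]][2])
    if (!is.na(ov1) && !is.na(ov2) &&
        ov1 >= 1 && ov1 <= 3 && ov2 >= 1 && ov2 <= 3) s_duplex <- 2
  }
  list(s_reads = s_reads, s_duplex = s_duplex, modal = modal,
       n_consistent = n_c, n_inconsistent = n_i)
}

#' Score a candidate with read-stack evidence
#'
#' The evidence score combines the three signals that distinguish genuine
#' miRNA loci: `S_reads = log2((n_c + 1) / (n_i + 1))` where `n_c` counts
#' copies whose 5' end lies within 2 nt of their arm's modal 5' end (and that
#' lie fully within an arm) and `n_i` all other copies; `S_duplex` is +2 when
#' the modal 5P and 3P products pair with a 2 +/- 1 nt 3' overhang on both
#' strands (the RNase III signature) and -2 otherwise; and
#' `S_struct = -z` of the folding stability z-score. `total` is their sum.
#'
#' @param cand one candidate from [exciseCandidates()].
#' @return list with s_reads, s_duplex, s_struct, total and the modal
#'   products.
#' @export
scoreCandidate <- function(cand) {
  if (is.null(cand$struct)) stop("candidate has not been folded")
  ev <- scoreFromReads(cand, cand$reads)
  s_struct <- -cand$mfe_z
  c(ev, list(s_struct = s_struct,
             total = ev$s_reads + ev$s_duplex + s_struct))
}

#' Permutation signal-to-noise table over score cutoffs
#'
#' For each permutation round, every candidate's read positions are re-drawn
#' uniformly within its window and the candidate is rescored (the structure
#' term is positional-evidence-free and unchanged). The signal-to-noise ratio
#' at a cutoff c is `N_real(total >= c) / mean_perm N(total >= c)`; 0/0 is
#' reported as `Inf`.
#'
#' @param candidates list from [exciseCandidates()].
#' @param n_perm permutation rounds (>= 10, default 100).
#' @param seed RNG seed.
#' @param cutoffs score grid (default: 0.5-steps spanning the real scores).
#' @return list with `table` (cutoff, n_real, mean_perm, sn), `scores`
#'   (per-candidate score lists) and `totals`.
#' @export
signalToNoise <- function(candidates, n_perm = 100, seed = 1L,
                          cutoffs = NULL) {
  if (length(candidates) == 0) stop("no candidates to calibrate")
  if (n_perm < 10) stop("n_perm must be >= 10")
  scores <- lapply(candidates, scoreCandidate)
  totals <- vapply(scores, `[[`, numeric(1), "total")
  perm <- withSeed(seed, {
    vapply(seq_len(n_perm), function(r) {
      vapply(candidates, function(cand) {
        rd <- cand$reads
        if (nrow(rd)) {
          len <- rd$e - rd$s + 1L
          n <- nchar(cand$seq)
          rd$s <- vapply(len, function(l)
            sample.int(max(1L, n - l + 1L), 1L), integer(1))
          rd$e <- rd$s + len - 1L
        }
        ev <- scoreFromReads(cand, rd)
        ev$s_reads + ev$s_duplex - cand$mfe_z
      }, numeric(1))
    }, numeric(length(candidates)))
  })
  perm <- matrix(perm, nrow = length(candidates))
  if (is.null(cutoffs))
    cutoffs <- seq(floor(min(c(totals, perm))),
                   ceiling(max(totals)) + 0.5, by = 0.5)
  tab <- data.frame(cutoff = cutoffs)
  tab$n_real <- vapply(cutoffs, function(c) sum(totals >= c), numeric(1))
  tab$mean_perm <- vapply(cutoffs, function(c)
    mean(colSums(perm >= c)), numeric(1))
  tab$sn <- ifelse(tab$mean_perm == 0,
                   ifelse(tab$n_real == 0, Inf, Inf),
                   tab$n_real / tab$mean_perm)
  list(table = tab, scores = scores, totals = totals)
}

#' Choose a score cutoff from a signal-to-noise table
#'
#' @param table the `table` element of [signalToNoise()].
#' @param target_sn required signal-to-noise ratio (default 10).
#' @return the smallest cutoff whose S/N meets the target (`Inf` when none
#'   does, i.e. no call clears the bar).
#' @export
chooseCutoff <- function(table, target_sn = 10) {
  ok <- which(table$sn >= target_sn)
  if (length(ok) == 0) return(Inf)
  table$cutoff[ok[1]]
}

# Build a calls GRanges from scored candidates above a cutoff. A sequencing
# call requires read products on `min_arms` arms: with min_arms = 2 the star
# strand must be observed, the duplex-consensus requirement that separates
# genuine Dicer products from one-sided degradation stacks. A one-arm
# candidate is rescued when its stem carries an unbroken helix of at least
# `rescue_stem` stacked pairs -- a structure one-sided degradation stacks on
# random sequence essentially never sit in.
candidatesToCalls <- function(candidates, scores, cutoff, min_arms = 2,
                              rescue_stem = 10) {
  narms <- vapply(scores, function(s)
    sum(!vapply(s$modal, is.null, logical(1))), numeric(1))
  stems <- vapply(candidates, function(cd) cd$stem_length, numeric(1))
  keep <- which(vapply(scores, `[[`, numeric(1), "total") >= cutoff &
                  (narms >= min_arms | stems >= rescue_stem))
  if (length(keep) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr) <- emptyCallMcols(0)
    return(gr)
  }
  rows <- lapply(keep, function(k) {
    cand <- candidates[[k]]; sc <- scores[[k]]
    # mature = modal product of the better-supported arm, star = the other
    support <- vapply(c("5P", "3P"), function(a) {
      if (is.null(sc$modal[[a]])) 0 else {
        arms <- armSpans(cand$struct)
        span <- if (a == "5P") arms$arm5 else arms$arm3
        sum(cand$reads$count[cand$reads$s >= span[1] - 5 &
                             cand$reads$e <= span[2] + 5])
      }
    }, numeric(1))
    marm <- if (support[["5P"]] >= support[["3P"]]) "5P" else "3P"
    sarm <- setdiff(c("5P", "3P"), marm)
    toGenome <- function(local) {
      if (is.null(local)) return(c(NA_integer_, NA_integer_))
      if (cand$strand == "-") c(cand$end - local[2] + 1L,
                                cand$end - local[1] + 1L)
      else c(cand$start + local[1] - 1L, cand$start + local[2] - 1L)
    }
    mg <- toGenome(sc$modal[[marm]]); sg <- toGenome(sc$modal[[sarm]])
    mseq <- if (!is.null(sc$modal[[marm]]))
      substr(cand$seq, sc$modal[[marm]][1], sc$modal[[marm]][2]) else NA
    data.frame(scaffold = cand$scaffold, start = cand$start, end = cand$end,
               strand = cand$strand, matureArm = marm,
               matureStart = mg[1], matureEnd = mg[2], matureSeq = mseq,
               starStart = sg[1], starEnd = sg[2],
               sReads = sc$s_reads, sDuplex = sc$s_duplex,
               sStruct = sc$s_struct, score = sc$total,
               energy = cand$energy, mfeZ = cand$mfe_z,
               pairedFraction = cand$paired_fraction,
               precursorSeq = cand$seq, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(d$scaffold, IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  mcols(gr) <- DataFrame(
    id = sprintf("call%04d", seq_len(nrow(d))),
    d[, setdiff(names(d), c("scaffold", "start", "end", "strand"))],
    classLabel = NA_character_, family = NA_character_,
    provenance = "sequencing")
  gr
}

emptyCallMcols <- function(n) {
  DataFrame(id = character(n), matureArm = character(n),
            matureStart = integer(n), matureEnd = integer(n),
            matureSeq = character(n), starStart = integer(n),
            starEnd = integer(n), sReads = numeric(n), sDuplex = numeric(n),
            sStruct = numeric(n), score = numeric(n), energy = numeric(n),
            mfeZ = numeric(n), pairedFraction = numeric(n),
            precursorSeq = character(n), classLabel = character(n),
            family = character(n), provenance = character(n))
}

#' Remove calls overlapping exclusion annotations
#'
#' Calls whose precursor overlaps at least 1 bp of a CDS, other-ncRNA or
#' repeat interval are removed as likely degradation fragments or
#' repeat-derived sequences; removal reasons are tallied per category.
#'
#' @param calls calls GRanges.
#' @param annotations GRanges with a `category` mcol (see [readBed()]).
#' @param genome optional scaffold set; annotation intervals on unknown
#'   scaffolds are dropped with a warning.
#' @return list with `calls` (kept) and `removed` (named tally per category).
#' @export
filterAnnotations <- function(calls, annotations, genome = NULL) {
  if (length(annotations) == 0 || length(calls) == 0)
    return(list(calls = calls, removed = integer(0)))
  if (!is.null(genome)) {
    genome <- asScaffoldSet(genome)
    unknown <- !(as.character(GenomicRanges::seqnames(annotations)) %in%
                   names(genome))
    if (any(unknown)) {
      warning("ignoring ", sum(unknown),
              " annotation interval(s) on unknown scaffolds")
      annotations <- annotations[!unknown]
    }
    if (length(annotations) == 0)
      return(list(calls = calls, removed = integer(0)))
  }
  ov <- GenomicRanges::findOverlaps(calls, annotations, ignore.strand = TRUE)
  bad <- unique(queryHits(ov))
  reason <- vapply(bad, function(q) {
    cats <- mcols(annotations)$category[subjectHits(ov)[queryHits(ov) == q]]
    as.character(cats[1])
  }, character(1))
  removed <- if (length(reason)) table(reason) else integer(0)
  list(calls = if (length(bad)) calls[-bad] else calls,
       removed = setNames(as.integer(removed), names(removed)))
}

#' Classify a mature sequence as conserved or lineage-specific
#'
#' A mature is conserved when some reference mature matches it in an
#' ungapped, equal-length sliding comparison with zero mismatches in the seed
#' region (mature positions `seed_start`-`seed_end`, 1-based) and no maximal
#' run of more than two adjacent mismatches elsewhere. The family assignment
#' is the best match (fewest mismatches; ties go to the first reference).
#'
#' @param mature mature sequence (>= 16 nt).
#' @param refs named character vector of reference matures (miRBase-style).
#' @param seed_start,seed_end seed region bounds (default 2-8).
#' @return list with `classLabel` ("conserved" or "lineage"), `family`
#'   (reference name or NA) and `mismatches` of the best hit.
#' @export
classifyHomology <- function(mature, refs, seed_start = 2, seed_end = 8) {
  if (is.na(mature) || nchar(mature) < 16) stop("mature length must be >= 16")
  if (length(refs) == 0)
    return(list(classLabel = "lineage", family = NA_character_,
                mismatches = NA_integer_))
  m <- strsplit(chartr("U", "T", toupper(mature)), "")[[1]]
  lm <- length(m)
  best <- list(classLabel = "lineage", family = NA_character_,
               mismatches = NA_integer_)
  bestmm <- Inf
  for (ri in seq_along(refs)) {
    r <- strsplit(chartr("U", "T", toupper(refs[[ri]])), "")[[1]]
    lr <- length(r)
    offs <- if (lr >= lm) 0:(lr - lm) else 0:(lm - lr)
    for (off in offs) {
      if (lr >= lm) {           # slide mature along the reference
        cmp <- m != r[(off + 1):(off + lm)]
        seedmm <- sum(cmp[seed_start:seed_end])
        other <- cmp; other[seed_start:seed_end] <- FALSE
      } else {                  # reference shorter: slide it along the mature
        cmp <- rep(TRUE, lm)    # uncovered mature positions count as mismatch
        cmp[(off + 1):(off + lr)] <- m[(off + 1):(off + lr)] != r
        seedmm <- sum(cmp[seed_start:seed_end])
        other <- cmp; other[seed_start:seed_end] <- FALSE
      }
      mm <- sum(cmp)
      runs <- rle(other)
      maxrun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
      if (seedmm == 0 && maxrun <= 2 && mm < bestmm) {
        bestmm <- mm
        best <- list(classLabel = "conserved",
                     family = names(refs)[ri] %||% as.character(ri),
                     mismatches = mm)
      }
    }
  }
  best
}

#' Homology-based precursor scan
#'
#' Maps each reference mature to the genome with at most `max_mm` mismatches,
#' excises and folds windows extended by `extension` nt on each side, and
#' keeps hits whose surrogate score `50 (1 - mm/len) + 50 (paired fraction of
#' the mature within the hairpin)` reaches `score_min` and whose trimmed
#' window is a hairpin.
#'
#' @param genome named DNAStringSet.
#' @param refs named character vector of reference matures.
#' @param max_mm maximum mature mismatches (default 3).
#' @param extension flank extension (default 110 nt).
#' @param score_min minimum surrogate score on the 0-100 scale (default 70).
#' @return calls GRanges with provenance "homology".
#' @export
homologScan <- function(genome, refs, max_mm = 3, extension = 110,
                        score_min = 70) {
  genome <- asScaffoldSet(genome)
  if (length(refs) == 0) stop("reference set is empty")
  chrs <- as.character(genome)
  out <- list()
  for (sc in names(genome)) {
    for (st in c("+", "-")) {
      qs <- if (st == "+") unname(unlist(refs)) else revComp(unlist(refs))
      h <- .mismatch_scan(chrs[[sc]], qs, max_mm)
      if (nrow(h) == 0) next
      for (k in seq_len(nrow(h))) {
        ri <- h$query[k]
        len <- nchar(refs[[ri]])
        hs <- h$pos[k] + 1L; he <- hs + len - 1L
        slen <- nchar(chrs[[sc]])
        win <- c(max(1L, hs - extension), min(slen, he + extension))
        wseq <- substr(chrs[[sc]], win[1], win[2])
        tseq <- if (st == "-") revComp(wseq) else wseq
        if (st == "-") { lo <- win[2] - he + 1L; hi <- win[2] - hs + 1L }
        else { lo <- hs - win[1] + 1L; hi <- he - win[1] + 1L }
        struct <- foldMFE(tseq)
        span <- stackLadder(struct, lo, hi)
        if (is.null(span)) next
        cseq <- substr(tseq, span[1], span[2])
        cstruct <- hairpinModel(cseq)
        if (!isHairpin(cstruct)$is_hairpin || nrow(cstruct@pairs) < 10) next
        part <- partnerVector(cstruct@pairs, nchar(cseq))
        mlo <- max(1L, lo - span[1] + 1L)
        mhi <- min(nchar(cseq), hi - span[1] + 1L)
        pairedFrac <- if (mhi >= mlo)
          sum(part[mlo:mhi] > 0) / len else 0
        score <- 50 * (1 - h$mismatches[k] / len) + 50 * pairedFrac
        if (score < score_min) next
        if (st == "-") {
          gstart <- win[2] - span[2] + 1L; gend <- win[2] - span[1] + 1L
        } else {
          gstart <- win[1] + span[1] - 1L; gend <- win[1] + span[2] - 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, start = gstart, end = gend, strand = st,
          matureStart = hs, matureEnd = he,
          matureSeq = substr(chrs[[sc]], hs, he),
          family = names(refs)[ri] %||% as.character(ri),
          mismatches = h$mismatches[k], hscore = score,
          precursorSeq = cseq, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr) <- emptyCallMcols(0)
    return(gr)
  }
  d <- do.call(rbind, out)
  # several references can land on the same locus: keep the best score
  key <- paste(d$scaffold, d$strand, d$start, d$end)
  d <- d[order(key, -d$hscore), , drop = FALSE]
  d <- d[!duplicated(paste(d$scaffold, d$strand, d$start, d$end)), ,
         drop = FALSE]
  gr <- GenomicRanges::GRanges(d$scaffold, IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  mcols(gr) <- DataFrame(
    id = sprintf("hom%04d", seq_len(nrow(d))), matureArm = NA_character_,
    matureStart = d$matureStart, matureEnd = d$matureEnd,
    matureSeq = d$matureSeq, starStart = NA_integer_, starEnd = NA_integer_,
    sReads = NA_real_, sDuplex = NA_real_, sStruct = NA_real_,
    score = d$hscore, energy = NA_real_, mfeZ = NA_real_,
    pairedFraction = NA_real_, precursorSeq = d$precursorSeq,
    classLabel = "conserved", family = d$family, provenance = "homology")
  gr
}

#' Merge sequencing-based and homology-based call sets
#'
#' Calls whose precursor loci overlap reciprocally by at least
#' `min_reciprocal` are merged into one call with provenance "both" (the
#' sequencing call's evidence is kept; the homology call contributes its
#' class and family). Unmatched calls keep their provenance.
#'
#' @param seq_calls,homolog_calls calls GRanges.
#' @param min_reciprocal reciprocal overlap fraction (default 0.5).
#' @return list with `calls` (unified GRanges) and `report`
#'   (n_both, n_seq_only, n_homolog_only).
#' @export
mergeCallSets <- function(seq_calls, homolog_calls, min_reciprocal = 0.5) {
  if (length(seq_calls) == 0 && length(homolog_calls) == 0)
    return(list(calls = seq_calls,
                report = c(n_both = 0L, n_seq_only = 0L, n_homolog_only = 0L)))
  ov <- GenomicRanges::findOverlaps(seq_calls, homolog_calls)
  if (length(ov)) {
    wq <- GenomicRanges::width(seq_calls)[queryHits(ov)]
    ws <- GenomicRanges::width(homolog_calls)[subjectHits(ov)]
    wo <- GenomicRanges::width(GenomicRanges::pintersect(
      seq_calls[queryHits(ov)], homolog_calls[subjectHits(ov)]))
    good <- wo / wq >= min_reciprocal & wo / ws >= min_reciprocal
    ov <- ov[good]
  }
  qh <- unique(queryHits(ov)); sh <- unique(subjectHits(ov))
  merged <- seq_calls
  if (length(qh)) {
    take <- vapply(qh, function(q) subjectHits(ov)[queryHits(ov) == q][1],
                   integer(1))
    mcols(merged)$provenance[qh] <- "both"
    mcols(merged)$classLabel[qh] <- mcols(homolog_calls)$classLabel[take]
    mcols(merged)$family[qh] <- mcols(homolog_calls)$family[take]
  }
  rest <- if (length(sh)) homolog_calls[-sh] else homolog_calls
  calls <- c(merged, rest)
  list(calls = calls,
       report = c(n_both = length(qh),
                  n_seq_only = length(seq_calls) - length(qh),
                  n_homolog_only = length(homolog_calls) - length(sh)))
}

# Collapse near-duplicate calls (>= 50% reciprocal overlap, same strand),
# keeping the best-scoring one.
dedupeCalls <- function(calls, min_reciprocal = 0.5) {
  if (length(calls) <= 1) return(calls)
  keep <- rep(TRUE, length(calls))
  o <- order(-mcols(calls)$score)
  for (a in seq_along(o)) {
    i <- o[a]
    if (!keep[i]) next
    ov <- GenomicRanges::findOverlaps(calls[i], calls, ignore.strand = TRUE)
    for (j in subjectHits(ov)) {
      if (j == i || !keep[j]) next
      w <- GenomicRanges::width(GenomicRanges::pintersect(calls[i], calls[j]))
      if (w / GenomicRanges::width(calls)[i] >= min_reciprocal &&
          w / GenomicRanges::width(calls)[j] >= min_reciprocal &&
          mcols(calls)$score[j] <= mcols(calls)$score[i])
        keep[j] <- FALSE
    }
  }
  calls[keep]
}

#' Discover miRNAs end to end from collapsed reads
#'
#' Chains [mapReads()], [exciseCandidates()], [scoreCandidate()],
#' [signalToNoise()] / [chooseCutoff()], [filterAnnotations()],
#' [classifyHomology()] on each call, an optional [homologScan()] and
#' [mergeCallSets()].
#'
#' @param genome named DNAStringSet.
#' @param creads collapsed reads data.frame.
#' @param refs optional named reference mature set.
#' @param annotations optional exclusion GRanges.
#' @param target_sn required signal-to-noise ratio (default 10).
#' @param n_perm permutation rounds (default 100).
#' @param extension window extension (default 110).
#' @param n_shuffles shuffled controls per candidate (default 100).
#' @param max_mismatch,max_hits mapping parameters.
#' @param min_arms arms that must carry read products for a sequencing call
#'   (default 2: mature and star strand both observed, the duplex-consensus
#'   requirement; set to 1 to accept one-sided stacks).
#' @param seed RNG seed.
#' @param run_homology also run the homology scan (default TRUE when refs
#'   given).
#' @return list with `calls` (GRanges), `sn_table`, `cutoff`, `candidates`,
#'   `n_multimapper_discarded`, `removed_by_annotation`, `merge_report`.
#' @export
discoverMirnas <- function(genome, creads, refs = NULL, annotations = NULL,
                           target_sn = 10, n_perm = 100, extension = 110,
                           n_shuffles = 100, max_mismatch = 0, max_hits = 5,
                           min_arms = 2, seed = 1L,
                           run_homology = !is.null(refs)) {
  mp <- mapReads(genome, creads, max_mismatch = max_mismatch,
                 max_hits = max_hits)
  cands <- exciseCandidates(genome, mp$mappings, extension = extension,
                            n_shuffles = n_shuffles,
                            seed = stageSeed(seed, "excise"))
  if (length(cands) == 0) {
    calls <- GenomicRanges::GRanges(); mcols(calls) <- emptyCallMcols(0)
    sn <- NULL; cutoff <- Inf
  } else {
    sn <- signalToNoise(cands, n_perm = n_perm,
                        seed = stageSeed(seed, "permute"))
    cutoff <- chooseCutoff(sn$table, target_sn = target_sn)
    calls <- candidatesToCalls(cands, sn$scores, cutoff,
                               min_arms = min_arms)
    calls <- dedupeCalls(calls)
  }
  removed <- integer(0)
  if (!is.null(annotations) && length(calls)) {
    fa <- filterAnnotations(calls, annotations, genome = genome)
    calls <- fa$calls; removed <- fa$removed
  }
  if (length(calls) && !is.null(refs) && length(refs)) {
    for (k in seq_along(calls)) {
      cl <- classifyHomology(mcols(calls)$matureSeq[k], refs)
      mcols(calls)$classLabel[k] <- cl$classLabel
      mcols(calls)$family[k] <- cl$family
    }
  } else if (length(calls)) {
    mcols(calls)$classLabel <- "lineage"
  }
  merge_report <- c(n_both = 0L, n_seq_only = length(calls),
                    n_homolog_only = 0L)
  if (isTRUE(run_homology) && !is.null(refs) && length(refs)) {
    hom <- homologScan(genome, refs)
    if (!is.null(annotations) && length(hom))
      hom <- filterAnnotations(hom, annotations, genome = genome)$calls
    mg <- mergeCallSets(calls, hom)
    calls <- mg$calls; merge_report <- mg$report
  }
  list(calls = calls, sn_table = sn$table %||% NULL, cutoff = cutoff,
       candidates = cands, n_multimapper_discarded = mp$discarded,
       removed_by_annotation = removed, merge_report = merge_report)
}
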