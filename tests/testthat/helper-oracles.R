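# Independent brute-force oracles used to verify the dynamic programs.
# These deliberately avoid the implementations they check: the fold oracle
# enumerates structures recursively without memoisation; the alignment
# oracles enumerate substring pairs and score each pair with a plain
# recursive alignment.

oraclePairWeight <- function(a, b) {
  ab <- paste0(a, b)
  if (ab %in% c("GC", "CG")) return(-3)
  if (ab %in% c("AU", "UA")) return(-2)
  if (ab %in% c("GU", "UG")) return(-1)
  NA_real_
}

# Minimum energy over all nested structures of seq (RNA letters), by naive
# recursion: position i is unpaired, or pairs with any k >= i + 4.
oracleFoldEnergy <- function(seq) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1, j)
    if (j >= i + 4) {
      for (k in (i + 4):j) {
        w <- oraclePairWeight(ch[i], ch[k])
        if (is.na(w)) next
        e <- w + rec(i + 1, k - 1) + rec(k + 1, j)
        if (e < best) best <- e
      }
    }
    best
  }
  rec(1, length(ch))
}

# Global alignment score of a vs b: forward iteration over an affine-gap
# state machine (M = match/mismatch column, X = gap in b, Y = gap in a),
# written independently of the package's traceback kernel.
oracleGlobalScore <- function(a, b, match = 1, mismatch = -2,
                              gap_open = -5, gap_extend = -2) {
  ac <- strsplit(toupper(a), "")[[1]]; bc <- strsplit(toupper(b), "")[[1]]
  m <- length(ac); n <- length(bc)
  M <- X <- Y <- matrix(-Inf, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m) + 1)
    X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in seq_len(n) + 1)
    Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (ac[i - 1] == bc[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(X[i, j], M[i - 1, j] + gap_open,
                     X[i - 1, j] + gap_extend)
      Y[i, j] <- max(Y[i, j], M[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_extend)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Best local alignment score: max global score over all substring pairs.
oracleLocalScore <- function(a, b, ...) {
  best <- 0
  for (i in seq_len(nchar(a))) for (ii in i:nchar(a)) {
    sa <- substr(a, i, ii)
    for (j in seq_len(nchar(b))) for (jj in j:nchar(b)) {
      s <- oracleGlobalScore(sa, substr(b, j, jj), ...)
      if (s > best) best <- s
    }
  }
  best
}

# Best glocal score: max global score of the full query vs any target
# substring (free target end gaps).
oracleGlocalScore <- function(q, t, ...) {
  best <- -Inf
  for (j in seq_len(nchar(t))) for (jj in j:nchar(t)) {
    s <- oracleGlobalScore(q, substr(t, j, jj), ...)
    if (s > best) best <- s
  }
  best
}

# Brute-force genome scan: every placement of the read (both strands) with
# zero mismatches.
oracleMapHits <- function(genome, read) {
  hits <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (sc in names(genome)) {
    g <- as.character(genome[[sc]])
    w <- nchar(read)
    for (s in seq_len(nchar(g) - w + 1)) {
      sub <- substr(g, s, s + w - 1)
      if (sub == read)
        hits[[length(hits) + 1]] <- c(sc, s, "+")
      if (sub == rc)
        hits[[length(hits) + 1]] <- c(sc, s, "-")
    }
  }
  hits
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# All permutations of a character vector (small n only).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

dinucCounts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# Small simulation settings shared by several tests: two 15-kb scaffolds,
# 10 planted miRNAs, modest library.
smallConfig <- function(seed = 7, ...) {
  defaults <- list(seed = seed, nScaffolds = 2L, scaffoldLength = 15000L,
                   nMirnas = 10L, nFamilies = 2L, nConserved = 3L,
                   familySpacingMean = 2500, familySpacingRange = c(100, 6000),
                   readsPerLibrary = 5000L, nDecoys = 4L,
                   nTissueSpecific = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# Simulate up to collapsed reads; returns the pieces the discovery tests use.
simulateLibrary <- function(cfg) {
  sim <- generateGenome(cfg)
  ab <- drawAbundances(sim$truth, cfg)
  reads <- generateReads(sim$genome, sim$truth, cfg, ab, decoys = sim$decoys)
  tr <- trimAdapter(reads$seq, cfg@adapter)
  qc <- filterReads(data.frame(id = reads$id, seq = tr$seq,
                               qual = substr(reads$qual, 1, nchar(tr$seq))))
  list(sim = sim, abundance = ab, raw = reads, qc = qc,
       collapsed = collapseReads(qc$reads$seq))
}
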