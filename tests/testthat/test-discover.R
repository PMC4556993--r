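test_that("mapReads finds exact hits on both strands and drops multimappers", {
  set.seed(21)
  g <- c(s1 = randomSeq(5000), s2 = randomSeq(5000))
  read <- substr(g[["s1"]], 1001, 1022)
  cr <- data.frame(id = "r1", seq = read, count = 5L)
  out <- mapReads(g, cr)
  expect_equal(nrow(out$mappings), 1L)
  expect_equal(out$mappings$start, 1001L)
  expect_identical(out$mappings$strand, "+")

  # minus-strand hit
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out2 <- mapReads(g, data.frame(id = "r2", seq = rc, count = 1L))
  expect_equal(out2$mappings$start, 1001L)
  expect_identical(out2$mappings$strand, "-")

  # a read planted at 6 loci is discarded at max_hits = 5
  seg <- randomSeq(22)
  g6 <- setNames(paste0(
    paste(replicate(6, paste0(randomSeq(50), seg)), collapse = ""),
    randomSeq(50)), "s")
  out6 <- mapReads(g6, data.frame(id = "r", seq = seg, count = 2L))
  expect_equal(nrow(out6$mappings), 0L)
  expect_equal(out6$discarded, 1L)

  expect_error(mapReads(Biostrings::DNAStringSet(), cr), "empty")
})

test_that("mapReads agrees with a brute-force scan", {
  set.seed(22)
  g <- c(chr = randomSeq(10000))
  reads <- character(0)
  for (k in 1:30) {                      # planted
    st <- sample(1:9970, 1)
    reads <- c(reads, substr(g[["chr"]], st, st + 21))
  }
  for (k in 1:20) reads <- c(reads, randomSeq(22))  # mostly unmappable
  cr <- data.frame(id = sprintf("r%02d", seq_along(reads)), seq = reads,
                   count = 1L)
  out <- mapReads(Biostrings::DNAStringSet(g), cr, max_hits = 1000)
  for (k in seq_along(reads)) {
    oracle <- oracleMapHits(Biostrings::DNAStringSet(g), reads[k])
    got <- out$mappings[out$mappings$id == cr$id[k], ]
    expect_equal(nrow(got), length(oracle), info = k)
    if (length(oracle)) {
      o <- t(vapply(oracle, identity, character(3)))
      expect_setequal(paste(got$start, got$strand),
                      paste(as.integer(o[, 2]), o[, 3]))
    }
  }
})

test_that("excision trims stem-loops around stacks and survives edges", {
  cfg <- smallConfig(seed = 14, nMirnas = 4L, nFamilies = 0L, nDecoys = 0L,
                     backgroundFraction = 0, readsPerLibrary = 2000L,
                     scaffoldLength = 4000L)
  lib <- simulateLibrary(cfg)
  mp <- mapReads(lib$sim$genome, lib$collapsed)
  cands <- exciseCandidates(lib$sim$genome, mp$mappings, n_shuffles = 20,
                            seed = 1)
  expect_gt(length(cands), 0)
  # at least one candidate contains each truth mature span
  for (r in seq_len(nrow(lib$sim$truth))) {
    hit <- any(vapply(cands, function(cd)
      cd$scaffold == lib$sim$truth$scaffold[r] &&
      cd$start <= lib$sim$truth$m5Start[r] &&
      cd$end >= lib$sim$truth$m5End[r], logical(1)))
    expect_true(hit, info = lib$sim$truth$id[r])
  }
  # stack at a scaffold edge: no out-of-range access
  g <- c(tiny = paste0(lib$sim$truth$precursorSeq[1], randomSeq(30)))
  m <- data.frame(id = "r", seq = substr(g[["tiny"]], 1, 22), count = 10L,
                  scaffold = "tiny", start = 1L, end = 22L, strand = "+",
                  mismatches = 0L, n_hits = 1L)
  expect_no_error(exciseCandidates(g, m, n_shuffles = 20, seed = 1))
})

test_that("evidence scores decompose and reward clean stacks", {
  cfg <- smallConfig(seed = 15, nMirnas = 3L, nFamilies = 0L, nDecoys = 0L,
                     backgroundFraction = 0, p5Precision = 1, p3Precision = 1,
                     readsPerLibrary = 3000L, scaffoldLength = 4000L)
  lib <- simulateLibrary(cfg)
  mp <- mapReads(lib$sim$genome, lib$collapsed)
  cands <- exciseCandidates(lib$sim$genome, mp$mappings, n_shuffles = 20,
                            seed = 1)
  scored <- lapply(cands, scoreCandidate)
  for (s in scored)
    expect_equal(s$total, s$s_reads + s$s_duplex + s$s_struct)
  # the best-scoring candidate is a perfect two-arm stack: true duplex
  # geometry and all reads at the modal ends
  best <- scored[[which.max(vapply(scored, `[[`, numeric(1), "total"))]]
  expect_equal(best$s_duplex, 2)
  expect_equal(best$n_inconsistent, 0)
  expect_equal(best$s_reads, log2(best$n_consistent + 1))
  # scattering reads uniformly destroys the positional evidence
  cand <- cands[[1]]
  set.seed(3)
  rd <- cand$reads
  rd$s <- sample.int(nchar(cand$seq) - 22L, nrow(rd), replace = TRUE)
  rd$e <- rd$s + 21L
  scat <- mirburst:::scoreFromReads(cand, rd)
  expect_lte(scat$s_reads, scored[[1]]$s_reads)
})

test_that("signal-to-noise calibration chooses a separating cutoff", {
  cfg <- smallConfig(seed = 16, nMirnas = 6L, readsPerLibrary = 4000L)
  lib <- simulateLibrary(cfg)
  mp <- mapReads(lib$sim$genome, lib$collapsed)
  cands <- exciseCandidates(lib$sim$genome, mp$mappings, n_shuffles = 20,
                            seed = 1)
  sn <- signalToNoise(cands, n_perm = 20, seed = 2)
  expect_true(all(c("cutoff", "n_real", "mean_perm", "sn") %in%
                    names(sn$table)))
  cut <- chooseCutoff(sn$table, target_sn = 10)
  expect_true(is.finite(cut))
  expect_gte(sn$table$sn[match(cut, sn$table$cutoff)], 10)
  # cutoff semantics: smallest qualifying cutoff
  smaller <- sn$table$cutoff < cut
  expect_true(all(sn$table$sn[smaller] < 10))
  expect_error(signalToNoise(list(), n_perm = 20), "no candidates")
})

test_that("filterAnnotations removes exactly the overlapping calls", {
  calls <- GenomicRanges::GRanges("s", IRanges::IRanges(c(100, 300, 500),
                                                        c(180, 380, 580)))
  S4Vectors::mcols(calls) <- S4Vectors::DataFrame(
    id = c("a", "b", "c"), score = c(1, 2, 3))
  ann <- GenomicRanges::GRanges("s", IRanges::IRanges(c(150, 381), c(160, 420)))
  S4Vectors::mcols(ann)$category <- c("rRNA", "CDS")
  out <- filterAnnotations(calls, ann)
  # call "a" overlaps the rRNA interval; "b" ends 1 bp before the CDS one
  expect_identical(S4Vectors::mcols(out$calls)$id, c("b", "c"))
  expect_equal(unname(out$removed["rRNA"]), 1L)
  # empty annotations: identity
  none <- filterAnnotations(calls, GenomicRanges::GRanges())
  expect_identical(S4Vectors::mcols(none$calls)$id, c("a", "b", "c"))
  # unknown scaffold warned and ignored when a genome is given
  ann2 <- GenomicRanges::GRanges("nope", IRanges::IRanges(1, 10))
  S4Vectors::mcols(ann2)$category <- "repeat"
  expect_warning(filterAnnotations(calls, ann2, genome = c(s = randomSeq(600))),
                 "unknown scaffold")
})

test_that("filterAnnotations matches an interval-stabbing oracle", {
  set.seed(30)
  for (rep in 1:5) {
    ncall <- 20
    starts <- sample(1:5000, ncall)
    calls <- GenomicRanges::GRanges("s", IRanges::IRanges(starts, starts + 80))
    S4Vectors::mcols(calls) <- S4Vectors::DataFrame(
      id = sprintf("c%02d", 1:ncall), score = runif(ncall))
    astart <- sample(1:5000, 10)
    ann <- GenomicRanges::GRanges("s", IRanges::IRanges(astart, astart + 40))
    S4Vectors::mcols(ann)$category <- sample(c("CDS", "repeat"), 10, TRUE)
    kept <- S4Vectors::mcols(filterAnnotations(calls, ann)$calls)$id
    manual <- vapply(seq_len(ncall), function(i)
      !any(starts[i] <= astart + 40 & starts[i] + 80 >= astart), logical(1))
    expect_setequal(kept, sprintf("c%02d", which(manual)))
  }
})

test_that("seed-region homology classification follows the mismatch rules", {
  ref <- c(`mir-x` = "TGAGGTAGTAGGTTGTATAGTT")
  expect_identical(classifyHomology(ref[[1]], ref)$classLabel, "conserved")
  expect_identical(classifyHomology(ref[[1]], ref)$family, "mir-x")

  sub1 <- function(s, i, b) { substr(s, i, i) <- b; s }
  # one mismatch at seed position 4: not conserved
  m <- sub1(ref[[1]], 4, "C")
  expect_identical(classifyHomology(m, ref)$classLabel, "lineage")
  # 3 adjacent mismatches at positions 12-14, seed clean: not conserved
  m <- sub1(sub1(sub1(ref[[1]], 12, "C"), 13, "A"), 14, "C")
  expect_identical(classifyHomology(m, ref)$classLabel, "lineage")
  # 2 adjacent mismatches outside the seed: still conserved
  m <- sub1(sub1(ref[[1]], 12, "C"), 13, "A")
  expect_identical(classifyHomology(m, ref)$classLabel, "conserved")
  # empty reference set: everything lineage-specific
  expect_identical(classifyHomology(ref[[1]], character(0))$classLabel,
                   "lineage")
  expect_error(classifyHomology("ACGTACGTACGT", ref), "length")
})

test_that("homology scan recovers planted conserved precursors", {
  cfg <- smallConfig(seed = 17, nMirnas = 5L, nConserved = 5L,
                     nFamilies = 0L, nDecoys = 0L)
  sim <- generateGenome(cfg)
  refs <- setNames(sim$truth$mature5, paste0("ref-", sim$truth$id))
  hom <- homologScan(sim$genome, refs)
  expect_gte(length(hom), nrow(sim$truth))
  perf <- matchCallsToTruth(hom, sim$truth)
  expect_equal(perf$sensitivity, 1)
  # an exact, fully paired mature scores at the top of the 0-100 scale
  expect_gte(max(S4Vectors::mcols(hom)$score), 95)
  expect_error(homologScan(sim$genome, character(0)), "empty")
})

test_that("merging call sets tracks provenance and overlap", {
  a <- GenomicRanges::GRanges("s", IRanges::IRanges(c(100, 400), c(160, 460)),
                              strand = "+")
  S4Vectors::mcols(a) <- S4Vectors::DataFrame(
    id = c("s1", "s2"), score = c(5, 6),
    classLabel = NA_character_, family = NA_character_,
    provenance = "sequencing")
  b <- GenomicRanges::GRanges("s", IRanges::IRanges(c(105, 800), c(158, 860)),
                              strand = "+")
  S4Vectors::mcols(b) <- S4Vectors::DataFrame(
    id = c("h1", "h2"), score = c(90, 95),
    classLabel = "conserved", family = c("mir-a", "mir-b"),
    provenance = "homology")
  out <- mergeCallSets(a, b)
  expect_equal(unname(out$report), c(1L, 1L, 1L))
  m <- S4Vectors::mcols(out$calls)
  expect_identical(m$provenance[m$id == "s1"], "both")
  expect_identical(m$family[m$id == "s1"], "mir-a")
  expect_identical(m$provenance[m$id == "s2"], "sequencing")
  expect_true("h2" %in% m$id)
  # disjoint sets: sizes add
  out2 <- mergeCallSets(a, b[2])
  expect_equal(length(out2$calls), 3L)
  # identical sets: everything merges
  out3 <- mergeCallSets(a, a)
  expect_true(all(S4Vectors::mcols(out3$calls)$provenance == "both"))
})
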