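test_that("generateGenome is deterministic and internally consistent", {
  cfg <- smallConfig(seed = 3)
  a <- generateGenome(cfg)
  b <- generateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)

  # every truth locus re-extracted from the emitted genome matches
  g <- as.character(a$genome)
  expect_identical(unname(substr(g[a$truth$scaffold], a$truth$start, a$truth$end)),
                   unname(a$truth$precursorSeq))
  expect_identical(unname(substr(g[a$truth$scaffold], a$truth$m5Start, a$truth$m5End)),
                   unname(a$truth$mature5))
  # mature spans are 22 nt, nested in the precursor, non-overlapping
  expect_true(all(a$truth$m5End - a$truth$m5Start + 1 == cfg@matureLen))
  expect_true(all(a$truth$m3End - a$truth$m3Start + 1 == cfg@matureLen))
  expect_true(all(a$truth$m5Start >= a$truth$start &
                  a$truth$m3End <= a$truth$end))
  expect_true(all(a$truth$m5End < a$truth$m3Start))
  # every family id has >= 1 member
  expect_true(all(table(a$truth$family) >= 1))
})

test_that("generateGenome with no miRNAs yields an empty truth table", {
  cfg <- smallConfig(seed = 1, nMirnas = 0L, nFamilies = 0L, nConserved = 0L,
                     nTissueSpecific = 0L, nDecoys = 0L)
  out <- generateGenome(cfg)
  expect_equal(nrow(out$truth), 0L)
  expect_equal(length(out$genome), 2L)
})

test_that("generateGenome errors when scaffolds cannot host the plantings", {
  cfg <- smallConfig(seed = 1, scaffoldLength = 900L, nMirnas = 30L)
  expect_error(generateGenome(cfg), "scaffold too short")
})

test_that("generateReads honours end precision and arm ratio", {
  cfg <- smallConfig(seed = 9, p5Precision = 1, p3Precision = 1,
                     backgroundFraction = 0, nDecoys = 0L,
                     readsPerLibrary = 12000L)
  sim <- generateGenome(cfg)
  ab <- drawAbundances(sim$truth, cfg)
  reads <- generateReads(sim$genome, sim$truth, cfg, ab)
  tr <- trimAdapter(reads$seq, cfg@adapter)
  matures <- c(sim$truth$mature5, sim$truth$mature3)
  expect_true(all(tr$seq %in% matures))

  # pooled 5P:3P ratio near 4 at >= 10,000 reads
  n5 <- sum(tr$seq %in% sim$truth$mature5)
  n3 <- sum(tr$seq %in% sim$truth$mature3)
  # matures shared between arms across copies are counted once on each side;
  # the planted sequences are distinct at this seed
  expect_gte(n5 / n3, 3.2)
  expect_lte(n5 / n3, 4.8)
})

test_that("background-only libraries contain no exact mature reads", {
  cfg <- smallConfig(seed = 4, backgroundFraction = 1, nDecoys = 0L,
                     readsPerLibrary = 2000L)
  sim <- generateGenome(cfg)
  reads <- generateReads(sim$genome, sim$truth, cfg,
                         expression = drawAbundances(sim$truth, cfg))
  tr <- trimAdapter(reads$seq, cfg@adapter)
  expect_equal(sum(tr$seq %in% c(sim$truth$mature5, sim$truth$mature3)), 0L)
})

test_that("generateReads requires an expression table when planting reads", {
  cfg <- smallConfig(seed = 4)
  sim <- generateGenome(cfg)
  expect_error(generateReads(sim$genome, sim$truth, cfg, expression = NULL),
               "expression")
})

test_that("mutateSister records exactly the substitutions in mature spans", {
  cfg <- smallConfig(seed = 6)
  sim <- generateGenome(cfg)

  none <- mutateSister(sim$genome, sim$truth,
                       smallConfig(seed = 6, sisterMutRate = 0))
  expect_identical(as.character(none$genome), as.character(sim$genome))
  expect_equal(nrow(none$variants), 0L)

  mut <- mutateSister(sim$genome, sim$truth,
                      smallConfig(seed = 6, sisterMutRate = 0.01))
  # brute-force diff over mature spans
  g0 <- as.character(sim$genome); g1 <- as.character(mut$genome)
  expected <- 0L
  for (r in seq_len(nrow(sim$truth))) {
    for (sp in list(c(sim$truth$m5Start[r], sim$truth$m5End[r]),
                    c(sim$truth$m3Start[r], sim$truth$m3End[r]))) {
      a <- strsplit(substr(g0[[sim$truth$scaffold[r]]], sp[1], sp[2]), "")[[1]]
      b <- strsplit(substr(g1[[sim$truth$scaffold[r]]], sp[1], sp[2]), "")[[1]]
      expected <- expected + sum(a != b)
    }
  }
  expect_equal(nrow(mut$variants), expected)
  # positions recorded 1-based within the mature
  if (nrow(mut$variants) > 0)
    expect_true(all(mut$variants$posInMature >= 1 &
                    mut$variants$posInMature <= cfg@matureLen))
})

test_that("simulateKnockdown scales classes as configured", {
  cfg <- smallConfig(seed = 2)
  counts <- setNames(rep(500, 400), sprintf("x%03d", 1:400))
  cls <- rep(c("miRNA", "snoRNA", "tRNA", "rRNA"), each = 100)
  expect_error(simulateKnockdown(counts, rep("mRNA", 400), cfg), "class")

  # zero effect: control and knockdown agree in expectation
  null_cfg <- smallConfig(seed = 2, kdLog2fcMean = 0, kdLog2fcSd = 0)
  kd0 <- simulateKnockdown(counts, cls, null_cfg, seed = 5)
  expect_lt(abs(mean(kd0$knockdown) - mean(kd0$control)), 15)

  kd <- simulateKnockdown(counts, cls, cfg, seed = 5)
  mir <- kd$class == "miRNA"
  expect_lt(mean(log2(kd$knockdown[mir] + 1) - log2(kd$control[mir] + 1)), -0.8)
  expect_lt(abs(mean(log2(kd$knockdown[!mir] + 1) -
                     log2(kd$control[!mir] + 1))), 0.15)
})

test_that("generateTissueProfiles boosts flagged rows in their tissue", {
  cfg <- smallConfig(seed = 8)
  sim <- generateGenome(cfg)
  prof <- generateTissueProfiles(sim$truth, cfg)
  expect_identical(dim(prof), c(nrow(sim$truth), length(cfg@tissueNames)))
  flagged <- which(sim$truth$tissueSpecific)
  for (r in flagged) {
    expect_identical(colnames(prof)[which.max(prof[r, ])],
                     sim$truth$tissue[r])
  }
  # unflagged rows show no 20-fold max/median enrichment in expectation
  un <- prof[!sim$truth$tissueSpecific, , drop = FALSE]
  ratios <- apply(un, 1, function(x) max(x) / max(1, median(x)))
  expect_lt(mean(ratios), 20)
})

test_that("planted family divergence is recovered by the alignment kit", {
  set.seed(77)
  base <- randomSeq(200)
  for (rate in c(0.05, 0.13)) {
    div <- replicate(6, {
      m <- mirburst:::mutateString(base, rate)
      divergenceRate(glocalAlign(base, m)) / 100
    })
    expect_lt(abs(mean(div) - rate), 0.05)
  }
})

test_that("read libraries are byte-identical under a fixed seed", {
  cfg <- smallConfig(seed = 10)
  sim <- generateGenome(cfg)
  ab <- drawAbundances(sim$truth, cfg)
  r1 <- generateReads(sim$genome, sim$truth, cfg, ab, decoys = sim$decoys)
  r2 <- generateReads(sim$genome, sim$truth, cfg, ab, decoys = sim$decoys)
  expect_identical(r1, r2)
  t1 <- tempfile(); t2 <- tempfile()
  writeFastq(r1, t1); writeFastq(r2, t2)
  expect_identical(readLines(t1), readLines(t2))
})
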