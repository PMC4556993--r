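test_that("local alignment matches trivial and hand-derived cases", {
  h <- localAlign("ACGT", "ACGT")
  expect_equal(h$score, 4)
  expect_equal(h$identity, 1)
  expect_equal(localAlign("ACGT", "AGGT")$score, 2)   # best substring "GT"
  expect_error(localAlign("ACXT", "ACGT"), "non-DNA")
  # score symmetry
  set.seed(61)
  for (rep in 1:10) {
    a <- randomSeq(sample(8:20, 1)); b <- randomSeq(sample(8:20, 1))
    expect_equal(localAlign(a, b)$score, localAlign(b, a)$score)
  }
})

test_that("local alignment equals brute-force substring-pair scoring", {
  set.seed(62)
  for (rep in 1:30) {
    a <- randomSeq(sample(4:10, 1)); b <- randomSeq(sample(4:10, 1))
    expect_equal(localAlign(a, b)$score, oracleLocalScore(a, b), info = paste(a, b))
  }
})

test_that("glocal alignment is query-global with free target ends", {
  set.seed(63)
  q <- randomSeq(20)
  t <- paste0(randomSeq(15), q, randomSeq(15))
  h <- glocalAlign(q, t)
  expect_equal(h$score, 20)
  expect_equal(h$identity, 1)
  expect_equal(h$b_start, 15)
  expect_equal(h$b_end, 35)
  expect_equal((h$a_end - h$a_start), 20)   # whole query consumed
  expect_error(glocalAlign("ACGTACGT", "ACG"), "longer than target")
})

test_that("glocal alignment equals enumeration for small cases", {
  set.seed(64)
  for (rep in 1:30) {
    q <- randomSeq(sample(3:6, 1)); t <- randomSeq(sample(6:10, 1))
    expect_equal(glocalAlign(q, t)$score, oracleGlocalScore(q, t),
                 info = paste(q, t))
  }
})

test_that("Karlin-Altschul parameters solve the composition equation", {
  ka <- solveKA(1, -2)
  expect_equal(0.25 * exp(ka$lambda) + 0.75 * exp(-2 * ka$lambda), 1,
               tolerance = 1e-6)
  expect_equal(round(ka$lambda, 2), 1.33)
  expect_error(solveKA(2, -0.4), "not local-alignment valid")
  # E monotone decreasing in score, linear in database length
  e1 <- evalue(20, 100, 1e4, ka); e2 <- evalue(25, 100, 1e4, ka)
  expect_gt(e1, e2)
  expect_equal(evalue(20, 100, 2e4, ka), 2 * e1)
})

test_that("all-vs-all similarity keeps duplicates and rejects random pairs", {
  set.seed(65)
  p <- randomSeq(100)
  precs <- c(a = p, b = p, r1 = randomSeq(100), r2 = randomSeq(100),
             r3 = randomSeq(100))
  pairs <- allVsAllSimilarity(precs)
  expect_true(any(pairs$query == "a" & pairs$target == "b"))
  expect_false(any(grepl("^r", pairs$query) & grepl("^r", pairs$target)))
  id_pair <- pairs[pairs$query == "a" & pairs$target == "b", ]
  expect_equal(id_pair$identity, 1)
  expect_equal(id_pair$coverage, 1)
  expect_lt(id_pair$evalue, 1e-5)
  expect_error(allVsAllSimilarity(c(x = "ACGT")), ">= 2")
})

test_that("random precursor pairs are never reported at default thresholds", {
  set.seed(66)
  precs <- setNames(vapply(1:15, function(i) randomSeq(100), character(1)),
                    sprintf("n%02d", 1:15))
  expect_equal(nrow(allVsAllSimilarity(precs)), 0L)
})

test_that("divergence rate counts mismatch and gap columns", {
  h <- localAlign("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(divergenceRate(h), 0)
  # hand-built alignment record
  toy <- list(score = 61, cols = 100, matches = 87, mismatches = 13,
              gapcols = 0)
  expect_equal(divergenceRate(toy), 13)
  toy2 <- list(score = 1, cols = 100, matches = 85, mismatches = 13,
               gapcols = 2)
  expect_equal(divergenceRate(toy2), 15)
  expect_equal(divergenceRate(toy2, count_gaps = FALSE),
               100 * 13 / 98)
  # hand count on a concrete pair
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGAACGTACCTACGTACGA"  # 3 substitutions
  h <- glocalAlign(a, b)
  expect_equal(divergenceRate(h), 100 * 3 / 20)
})

test_that("family clustering gives connected components and consensus", {
  pairs <- data.frame(query = c("a", "b"), target = c("b", "c"))
  fams <- familyCluster(pairs, c("a", "b", "c", "d"))
  sizes <- sort(lengths(fams))
  expect_equal(sizes, c(1L, 3L))
  # no pairs: all singletons
  fams0 <- familyCluster(pairs[0, ], c("x", "y"))
  expect_equal(lengths(fams0), c(1L, 1L))
  # consensus of identical members is the member sequence
  set.seed(67)
  s <- randomSeq(80)
  cons <- familyConsensus(c("a", "b"), c(a = s, b = s))
  expect_identical(cons$consensus, s)
  expect_equal(length(cons$ties), 0L)
  # majority wins at a mutated column
  s2 <- s; substr(s2, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                         substr(s, 40, 40))[1]
  cons3 <- familyConsensus(c("a", "b", "c"), c(a = s, b = s, c = s2))
  expect_identical(cons3$consensus, s)
})

test_that("flank scan finds planted tandem copies at the right distance", {
  set.seed(68)
  prec <- randomSeq(80)
  gap <- 3000
  g <- c(chr = paste0(randomSeq(500), prec, randomSeq(gap), prec,
                      randomSeq(500)))
  calls <- GenomicRanges::GRanges("chr", IRanges::IRanges(501, 580),
                                  strand = "+")
  S4Vectors::mcols(calls) <- S4Vectors::DataFrame(id = "m1",
                                                  precursorSeq = prec)
  hits <- flankScan(g, calls, window = 20000)
  expect_equal(nrow(hits), 1L)
  expect_lte(abs(hits$distance - gap), 1)
  # the self-hit (overlapping the original span) is excluded
  expect_false(any(hits$start <= 580 & hits$end >= 501))
  # random flanks yield no hits
  g2 <- c(chr = paste0(randomSeq(500), prec, randomSeq(4000)))
  hits2 <- flankScan(g2, calls, window = 20000)
  expect_equal(nrow(hits2), 0L)
})

test_that("distance histogram bins at 5 kb and conserves counts", {
  hits <- data.frame(distance = c(100, 4999, 5000))
  h <- distanceHistogram(hits)
  expect_equal(unname(h$counts[1:3]), c(2L, 1L, 0L))
  expect_equal(h$dropped, 0L)
  # empty input
  h0 <- distanceHistogram(data.frame(distance = numeric(0)))
  expect_true(all(h0$counts == 0))
  # conservation including dropped
  hits2 <- data.frame(distance = c(100, 60000, 49999, 50000))
  h2 <- distanceHistogram(hits2)
  expect_equal(sum(h2$counts) + h2$dropped, nrow(hits2))
  expect_equal(h2$dropped, 1L)
})
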