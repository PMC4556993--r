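test_that("cross-species detection respects the mismatch tolerance", {
  set.seed(51)
  prec <- setNames(randomSeq(60), "p1")
  mature <- substr(prec[[1]], 1, 22)
  sub <- function(s, i) { substr(s, i, i) <- setdiff(c("A","C","G","T"),
                                                     substr(s, i, i))[1]; s }
  reads0 <- data.frame(id = "r1", seq = mature, count = 20L)
  expect_identical(crossSpeciesDetect(prec, reads0)$detected, "p1")
  # two mismatches still align
  r2 <- data.frame(id = "r2", seq = sub(sub(mature, 3), 9), count = 20L)
  expect_identical(crossSpeciesDetect(prec, r2)$detected, "p1")
  # three mismatches do not
  r3 <- data.frame(id = "r3", seq = sub(sub(sub(mature, 3), 9), 15), count = 20L)
  expect_identical(crossSpeciesDetect(prec, r3)$detected, character(0))
})

test_that("cross-species detection equals a brute-force alignment scan", {
  set.seed(52)
  precs <- setNames(vapply(1:10, function(i) randomSeq(60), character(1)),
                    sprintf("p%02d", 1:10))
  reads <- data.frame(
    id = sprintf("r%02d", 1:12),
    seq = c(vapply(1:6, function(i) substr(precs[[i]], 11, 32), character(1)),
            vapply(1:6, function(i) randomSeq(22), character(1))),
    count = 5L)
  got <- crossSpeciesDetect(precs, reads, max_mismatch = 2)
  # oracle: ungapped scan of every read (both orientations) over every precursor
  oracle <- character(0)
  for (p in names(precs)) {
    ps <- precs[[p]]
    found <- FALSE
    for (rs in c(reads$seq, revComp(reads$seq))) {
      w <- nchar(rs)
      for (s in seq_len(nchar(ps) - w + 1)) {
        mm <- sum(strsplit(substr(ps, s, s + w - 1), "")[[1]] !=
                    strsplit(rs, "")[[1]])
        if (mm <= 2) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) oracle <- c(oracle, p)
  }
  expect_setequal(got$detected, oracle)
})

test_that("variant calling masks mature ends and honours AF/coverage floors", {
  prec <- paste0(strrep("A", 10), strrep("C", 22), strrep("A", 10))
  span <- c(11, 32)
  mkPile <- function(pos, base, cov) {
    pile <- matrix(0, 4, nchar(prec), dimnames = list(c("A","C","G","T"), NULL))
    pile["C", span[1]:span[2]] <- cov
    pile[base, pos] <- cov
    pile["C", pos] <- 0
    pile
  }
  # interior substitution at mature position 10, AF 1, cov 50: called
  v <- callMatureVariants(mkPile(span[1] + 9, "G", 50), prec, span)
  expect_equal(v$posInMature, 10L)
  expect_identical(v$alt, "G")
  expect_equal(v$af, 1)
  # position 2 (inside the 5' trim): never called
  v <- callMatureVariants(mkPile(span[1] + 1, "G", 50), prec, span)
  expect_equal(nrow(v), 0L)
  # last-3 positions: never called
  v <- callMatureVariants(mkPile(span[2] - 1, "G", 50), prec, span)
  expect_equal(nrow(v), 0L)
  # zero coverage and low coverage: no call
  v <- callMatureVariants(mkPile(span[1] + 9, "G", 5), prec, span)
  expect_equal(nrow(v), 0L)
  # sub-threshold allele fraction: no call
  pile <- mkPile(span[1] + 9, "G", 50)
  pile["C", span[1] + 9] <- 60
  expect_equal(nrow(callMatureVariants(pile, prec, span)), 0L)
})

test_that("variant calls never fall in trimmed positions (property)", {
  set.seed(53)
  prec <- randomSeq(60)
  span <- c(15, 36)
  for (rep in 1:25) {
    pile <- matrix(rpois(4 * 60, 8), 4, 60,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    v <- callMatureVariants(pile, prec, span, min_af = 0.3, min_cov = 5)
    if (nrow(v))
      expect_true(all(v$posInMature > 3 & v$posInMature <= 22 - 3))
  }
})

test_that("contingency tables reproduce a hand tally and partition groups", {
  detected <- sprintf("m%02d", 1:10)
  cl <- setNames(rep(c("conserved", "lineage"), each = 5), detected)
  eg <- setNames(rep(c("moderate/high", "low"), times = 5), detected)
  variants <- c("m01", "m06", "m08")
  tabs <- variantContingency(variants, detected, cl, eg)
  expect_equal(unname(tabs$by_class["conserved", ]), c(1, 4))
  expect_equal(unname(tabs$by_class["lineage", ]), c(2, 3))
  expect_equal(sum(tabs$by_class), 10)
  # lineage-specific by expression: m06 (low), m08 (low) are the variants
  expect_equal(unname(tabs$by_expression["low", "variant"]), 2)
  expect_equal(sum(tabs$by_expression), 5)
  # row sums equal group sizes
  expect_equal(unname(rowSums(tabs$by_class)), c(5, 5))
  expect_error(variantContingency(variants, c(detected, "zz"), cl, eg),
               "class")
})

test_that("chi-squared 2x2 matches the closed form and handles margins", {
  t <- chi2_2x2(c(2, 3, 4, 1))
  expect_equal(round(t$statistic, 4), 1.6667)
  expect_equal(t$p, pchisq(1.66667, 1, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(chi2_2x2(c(5, 5, 5, 5))$statistic, 0)
  expect_equal(chi2_2x2(c(5, 5, 5, 5))$p, 1)
  expect_equal(chi2_2x2(c(0, 0, 3, 4))$statistic, 0)  # zero margin
  expect_error(chi2_2x2(c(-1, 2, 3, 4)), "negative")
  # the published conserved vs lineage-specific variant contrast
  expect_lt(chi2_2x2(rbind(c(1, 143), c(26, 229)))$p, 0.001)
  expect_lt(chi2_2x2(rbind(c(1, 143), c(26, 229)), yates = TRUE)$p, 0.001)
  # invariance to simultaneous row and column swaps
  expect_equal(chi2_2x2(rbind(c(2, 3), c(4, 1)))$statistic,
               chi2_2x2(rbind(c(1, 4), c(3, 2)))$statistic)
  # agreement with the base implementation (no correction)
  m <- rbind(c(12, 7), c(5, 19))
  expect_equal(chi2_2x2(m)$statistic,
               unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic))
})

test_that("Mann-Whitney U matches exact enumeration and base R", {
  out <- mwuTest(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  # identical samples: p near 1
  expect_gte(mwuTest(c(1, 5, 9), c(1, 5, 9))$p, 0.99)
  expect_error(mwuTest(numeric(0), 1), "empty")

  # exact regime vs full enumeration for |x| = |y| = 4 without ties
  set.seed(54)
  for (rep in 1:20) {
    v <- sample(1:100, 8)
    x <- v[1:4]; y <- v[5:8]
    U <- sum(outer(x, y, ">"))
    combs <- utils::combn(8, 4)
    Us <- apply(combs, 2, function(ix) sum(outer(v[ix], v[-ix], ">")))
    p_enum <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    expect_equal(mwuTest(x, y)$p, p_enum, tolerance = 1e-12, info = rep)
  }

  # normal-approximation regime tracks wilcox.test with continuity correction
  set.seed(55)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  ours <- mwuTest(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})

test_that("KS statistic equals the hand-computed ECDF supremum", {
  out <- ksTest(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 1)
  expect_identical(ksTest(c(1, 5, 9), c(1, 5, 9))$statistic, 0)
  set.seed(56)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ref <- suppressWarnings(ks.test(x, y))
  expect_equal(ksTest(x, y)$statistic, unname(ref$statistic))
  expect_error(ksTest(1, c(1, 2)), ">= 2")
})

test_that("Pearson correlation and its t-test match base R", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCorr(x, x)$statistic, 1)
  expect_equal(pearsonCorr(x, x)$p, 0)
  expect_error(pearsonCorr(x, rep(1, 5)), "constant")
  expect_error(pearsonCorr(x, c(1, 2)), "equal length")
  set.seed(57)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  ref <- cor.test(a, b)
  ours <- pearsonCorr(a, b)
  expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})
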