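# Cross-species detection, end-trimmed mature variant calling, contingency
# analysis, and the statistical test kit (chi-squared, Mann-Whitney U,
# Kolmogorov-Smirnov, Pearson).

#' Detect precursors in a second species' read set
#'
#' Aligns collapsed reads (both orientations, ungapped) to each precursor
#' sequence with at most `max_mismatch` mismatches. A precursor is detected
#' when at least `min_reads` distinct reads align within it. Per-precursor
#' base pileups (copy-weighted, in precursor orientation) are retained for
#' variant calling.
#'
#' @param precursors named character vector of precursor sequences.
#' @param reads_b collapsed reads data.frame (id, seq, count) of the second
#'   species.
#' @param max_mismatch mismatch tolerance (default 2).
#' @param min_reads distinct aligned reads required for detection (default 1).
#' @return list with `detected` (ids), `coverage` (mean pileup depth per
#'   precursor) and `pileups` (list of 4 x L count matrices, rows ACGT).
#' @export
crossSpeciesDetect <- function(precursors, reads_b, max_mismatch = 2,
                               min_reads = 1) {
  bases <- c("A", "C", "G", "T")
  detected <- character(0)
  pileups <- list()
  coverage <- setNames(numeric(length(precursors)), names(precursors))
  for (pid in names(precursors)) {
    pseq <- precursors[[pid]]
    L <- nchar(pseq)
    pile <- matrix(0, 4, L, dimnames = list(bases, NULL))
    nAligned <- 0L
    if (nrow(reads_b) > 0) {
      for (orient in c("+", "-")) {
        qs <- if (orient == "+") reads_b$seq else revComp(reads_b$seq)
        h <- .mismatch_scan(pseq, qs, max_mismatch)
        if (nrow(h) == 0) next
        nAligned <- nAligned + length(unique(h$query))
        for (k in seq_len(nrow(h))) {
          rseq <- strsplit(qs[h$query[k]], "")[[1]]
          cnt <- reads_b$count[h$query[k]]
          pos <- h$pos[k] + seq_along(rseq)
          for (z in seq_along(rseq)) {
            b <- rseq[z]
            if (b %in% bases) pile[b, pos[z]] <- pile[b, pos[z]] + cnt
          }
        }
      }
    }
    if (nAligned >= min_reads) detected <- c(detected, pid)
    pileups[[pid]] <- pile
    coverage[pid] <- mean(colSums(pile))
  }
  list(detected = detected, coverage = coverage, pileups = pileups)
}

#' Call mature-region variants from a pileup
#'
#' A position is a variant when its coverage reaches `min_cov` and the modal
#' non-reference base fraction reaches `min_af`. The first and last `trim`
#' bases of the mature region never emit calls: read ends carry frequent
#' untemplated modifications that would masquerade as substitutions.
#'
#' @param pileup 4 x L count matrix (rows ACGT) from [crossSpeciesDetect()].
#' @param precursor_seq the reference precursor sequence.
#' @param mature_span c(start, end), 1-based inclusive within the precursor.
#' @param trim bases masked at each mature end (default 3).
#' @param min_af minimum alternate allele fraction (default 0.5).
#' @param min_cov minimum coverage (default 10).
#' @return data.frame with posInMature, ref, alt, af, coverage.
#' @export
callMatureVariants <- function(pileup, precursor_seq, mature_span, trim = 3,
                               min_af = 0.5, min_cov = 10) {
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(toupper(precursor_seq), "")[[1]]
  lo <- mature_span[1] + trim
  hi <- mature_span[2] - trim
  out <- list()
  if (hi >= lo) {
    for (pos in lo:hi) {
      cov <- sum(pileup[, pos])
      if (cov < min_cov) next
      alt <- setdiff(bases, ref[pos])
      af <- pileup[alt, pos] / cov
      best <- which.max(af)
      if (af[best] >= min_af)
        out[[length(out) + 1L]] <- data.frame(
          posInMature = pos - mature_span[1] + 1L, ref = ref[pos],
          alt = alt[best], af = af[best], coverage = cov,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(posInMature = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0),
                      coverage = numeric(0)))
  do.call(rbind, out)
}

#' Variant-by-group contingency tables
#'
#' A miRNA is "variant" when it carries at least one mature variant call.
#' Builds the conserved vs lineage-specific table over the detected set, and
#' the moderate/high vs low expression table within the lineage-specific
#' detected miRNAs.
#'
#' @param variant_ids ids of miRNAs with >= 1 variant call.
#' @param detected ids of miRNAs detected in the second species.
#' @param class_labels named vector ("conserved"/"lineage") over detected ids.
#' @param expression_groups named vector ("moderate/high"/"low").
#' @return list of 2x2 matrices `by_class` and `by_expression`
#'   (rows = groups, cols = variant / no variant).
#' @export
variantContingency <- function(variant_ids, detected, class_labels,
                               expression_groups) {
  if (any(!detected %in% names(class_labels)) ||
      any(!detected %in% names(expression_groups)))
    stop("every detected miRNA needs a class and an expression group")
  cl <- class_labels[detected]
  eg <- expression_groups[detected]
  if (any(!cl %in% c("conserved", "lineage")) ||
      any(!eg %in% c("moderate/high", "low")))
    stop("unrecognized group label")
  isv <- detected %in% variant_ids
  by_class <- rbind(
    conserved = c(sum(cl == "conserved" & isv), sum(cl == "conserved" & !isv)),
    lineage = c(sum(cl == "lineage" & isv), sum(cl == "lineage" & !isv)))
  colnames(by_class) <- c("variant", "no_variant")
  lin <- cl == "lineage"
  by_expression <- rbind(
    `moderate/high` = c(sum(lin & eg == "moderate/high" & isv),
                        sum(lin & eg == "moderate/high" & !isv)),
    low = c(sum(lin & eg == "low" & isv), sum(lin & eg == "low" & !isv)))
  colnames(by_expression) <- c("variant", "no_variant")
  list(by_class = by_class, by_expression = by_expression)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1; any zero
#' margin gives statistic 0 and p 1. The Yates correction subtracts n/2 from
#' |ad - bc| (floored at 0).
#'
#' @param t 2x2 matrix or length-4 vector (a, b, c, d row-wise).
#' @param yates apply continuity correction (default FALSE).
#' @return list with statistic, p, method, n.
#' @export
chi2_2x2 <- function(t, yates = FALSE) {
  v <- as.numeric(t)
  if (length(v) != 4) stop("need a 2x2 table")
  if (any(v < 0)) stop("negative counts")
  if (is.matrix(t)) { a <- t[1, 1]; b <- t[1, 2]; cc <- t[2, 1]; d <- t[2, 2] }
  else { a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4] }
  n <- a + b + cc + d
  if (n < 1) stop("empty table")
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0))
    return(list(statistic = 0, p = 1,
                method = if (yates) "chi2-yates" else "chi2", n = n))
  dd <- abs(a * d - b * cc)
  if (yates) dd <- max(0, dd - n / 2)
  stat <- n * dd^2 / prod(marg)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       method = if (yates) "chi2-yates" else "chi2", n = n)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when both samples have at most 8 observations and
#' there are no ties; otherwise a normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with statistic (U of x), p, method, n.
#' @export
mwuTest <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (m <= 8 && n <= 8 && !ties) {
    p <- 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))
    p <- min(1, p)
    return(list(statistic = U, p = p, method = "mwu-exact", n = c(m, n)))
  }
  N <- m + n
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  mu <- m * n / 2
  if (sigma2 <= 0)
    return(list(statistic = U, p = 1, method = "mwu-normal", n = c(m, n)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p = min(1, 2 * pnorm(-abs(z))),
       method = "mwu-normal", n = c(m, n))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; p-value from the asymptotic Kolmogorov
#' distribution with the Stephens small-sample adjustment.
#'
#' @param x,y numeric samples (length >= 2).
#' @return list with statistic (D), p, method, n.
#' @export
ksTest <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) stop("need >= 2 observations per sample")
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- m * n / (m + n)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p = min(1, max(0, p)), method = "ks", n = c(m, n))
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-constant).
#' @return list with statistic (r), p, method, n.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(statistic = r, p = 0, method = "pearson", n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = r, p = 2 * pt(-abs(tstat), df = n - 2),
       method = "pearson", n = n)
}
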