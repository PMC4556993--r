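# Expression quantification, TPM, tissue-specificity calling, processing
# precision and knockdown-response analysis.

# Accept either a SummarizedExperiment or a plain matrix (+ librarySize).
asCounts <- function(x, librarySize = NULL) {
  if (is(x, "SummarizedExperiment")) {
    list(counts = SummarizedExperiment::assay(x, "counts"),
         librarySize = x$librarySize)
  } else {
    m <- as.matrix(x)
    list(counts = m, librarySize = librarySize %||% colSums(m))
  }
}

#' Quantify miRNA expression from read mappings
#'
#' A mapped read contributes its copy number to a call when its 5' end lies
#' within `end_tol` nt of the call's annotated mature 5' end (same scaffold
#' and strand). Reads compatible with k calls are split fractionally (1/k).
#'
#' @param calls calls GRanges (needs mcols id, matureStart, matureEnd).
#' @param mappings_by_sample named list of mappings data.frames from
#'   [mapReads()], one per sample.
#' @param end_tol 5' end tolerance in nt (default 2).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (calls x samples) and `librarySize` in colData (total mapped
#'   copies per sample).
#' @export
quantifyExpression <- function(calls, mappings_by_sample, end_tol = 2) {
  stopifnot(length(calls) > 0)
  samples <- names(mappings_by_sample) %||%
    sprintf("sample%d", seq_along(mappings_by_sample))
  m <- matrix(0, length(calls), length(mappings_by_sample),
              dimnames = list(mcols(calls)$id, samples))
  lib <- numeric(length(mappings_by_sample))
  csc <- as.character(GenomicRanges::seqnames(calls))
  cst <- as.character(GenomicRanges::strand(calls))
  c5 <- ifelse(cst == "-", mcols(calls)$matureEnd, mcols(calls)$matureStart)
  for (j in seq_along(mappings_by_sample)) {
    mp <- mappings_by_sample[[j]]
    if (nrow(mp) == 0) stop("sample ", samples[j], " has zero mapped reads")
    lib[j] <- sum(mp$count)
    r5 <- ifelse(mp$strand == "-", mp$end, mp$start)
    # compatibility per unique read occurrence
    for (r in seq_len(nrow(mp))) {
      hit <- which(csc == mp$scaffold[r] & cst == mp$strand[r] &
                     abs(c5 - r5[r]) <= end_tol)
      if (length(hit))
        m[hit, j] <- m[hit, j] + mp$count[r] / length(hit)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(librarySize = lib, row.names = samples))
}

#' Transcripts per million
#'
#' `TPM = count / library_size x 1e6`. When library sizes equal the column
#' sums, TPM columns sum to 1e6.
#'
#' @param x counts matrix or SummarizedExperiment from
#'   [quantifyExpression()].
#' @param librarySize per-sample library sizes (defaults to column sums for
#'   a matrix input).
#' @return matrix of TPM values (or the SummarizedExperiment with an added
#'   `tpm` assay).
#' @export
tpm <- function(x, librarySize = NULL) {
  cl <- asCounts(x, librarySize)
  if (any(cl$librarySize <= 0)) stop("library sizes must be positive")
  t <- sweep(cl$counts, 2, cl$librarySize, "/") * 1e6
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "tpm", withDimnames = FALSE) <- t
    x
  } else t
}

#' Expression-group label from mean TPM
#'
#' Classifies each row as "moderate/high" when its mean TPM strictly exceeds
#' the cutoff, else "low".
#'
#' @param tpm_means numeric vector of per-row mean TPM.
#' @param cutoff TPM cutoff (default 10; 5 and 15 are the standard
#'   sensitivity settings).
#' @return character vector of labels.
#' @export
expressionGroup <- function(tpm_means, cutoff = 10) {
  ifelse(tpm_means > cutoff, "moderate/high", "low")
}

#' Call tissue-specific miRNAs (one tissue vs the aggregate of the others)
#'
#' For every miRNA x tissue, the copy count in the tissue (against its
#' library size) is compared with the summed count in all other tissues
#' (against their summed library sizes) by a two-sided exact conditional test
#' on the 2x2 count table, with Benjamini-Hochberg correction across all
#' tests. A flag requires q < `fdr`, a normalized fold change >= `min_fold`
#' and higher expression in the tissue.
#'
#' @param x counts matrix (miRNA x tissue) or SummarizedExperiment.
#' @param librarySize per-tissue library sizes.
#' @param fdr false discovery rate (default 0.05).
#' @param min_fold normalized fold-change floor (default 4).
#' @return data.frame with id, tissue, fold, p, q, flag.
#' @export
tissueSpecificity <- function(x, librarySize = NULL, fdr = 0.05,
                              min_fold = 4) {
  cl <- asCounts(x, librarySize)
  m <- cl$counts; lib <- cl$librarySize
  if (ncol(m) < 2) stop("need at least two tissues")
  ids <- rownames(m) %||% sprintf("row%d", seq_len(nrow(m)))
  res <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  ps <- numeric(nrow(res)); fold <- numeric(nrow(res)); up <- logical(nrow(res))
  for (k in seq_len(nrow(res))) {
    i <- res$row[k]; j <- res$col[k]
    a <- round(m[i, j]); b <- round(lib[j]) - a
    cc <- round(sum(m[i, -j])); d <- round(sum(lib[-j])) - cc
    ps[k] <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    r1 <- (a + 0.5) / (a + b + 1); r2 <- (cc + 0.5) / (cc + d + 1)
    fold[k] <- r1 / r2
    up[k] <- r1 > r2
  }
  q <- p.adjust(ps, method = "BH")
  data.frame(id = ids[res$row], tissue = colnames(m)[res$col],
             fold = fold, p = ps, q = q,
             flag = q < fdr & fold >= min_fold & up,
             stringsAsFactors = FALSE)
}

#' Processing precision of mature 5' and 3' ends
#'
#' For each call, arm reads are the mapped reads on the call's strand whose
#' span overlaps the annotated mature span by at least half the read length.
#' `p5` is the copy-weighted fraction whose 5' end coincides exactly with the
#' annotated mature 5' end; `p3` analogously for the 3' end. Calls without
#' arm reads are omitted with a warning.
#'
#' @param calls calls GRanges.
#' @param mappings mappings data.frame from [mapReads()].
#' @return data.frame with id, arm, p5, p3, n_reads.
#' @export
endPrecision <- function(calls, mappings) {
  out <- list()
  skipped <- 0L
  csc <- as.character(GenomicRanges::seqnames(calls))
  cst <- as.character(GenomicRanges::strand(calls))
  for (k in seq_along(calls)) {
    ms <- mcols(calls)$matureStart[k]; me <- mcols(calls)$matureEnd[k]
    if (is.na(ms)) { skipped <- skipped + 1L; next }
    rows <- mappings$scaffold == csc[k] & mappings$strand == cst[k] &
      pmin(mappings$end, me) - pmax(mappings$start, ms) + 1 >=
        (mappings$end - mappings$start + 1) / 2
    rd <- mappings[rows, , drop = FALSE]
    if (nrow(rd) == 0) { skipped <- skipped + 1L; next }
    if (cst[k] == "-") {
      p5 <- sum(rd$count[rd$end == me]) / sum(rd$count)
      p3 <- sum(rd$count[rd$start == ms]) / sum(rd$count)
    } else {
      p5 <- sum(rd$count[rd$start == ms]) / sum(rd$count)
      p3 <- sum(rd$count[rd$end == me]) / sum(rd$count)
    }
    out[[length(out) + 1L]] <- data.frame(
      id = mcols(calls)$id[k], arm = mcols(calls)$matureArm[k] %||% NA,
      p5 = p5, p3 = p3, n_reads = sum(rd$count), stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(skipped, " call(s) without arm reads omitted")
  if (length(out) == 0)
    return(data.frame(id = character(0), arm = character(0), p5 = numeric(0),
                      p3 = numeric(0), n_reads = numeric(0)))
  do.call(rbind, out)
}

#' Percentile-ordered processing-precision curve
#'
#' Sorts precision values descending; the most precise miRNA sits at
#' percentile 1 and the least precise at percentile 100.
#'
#' @param records data.frame from [endPrecision()].
#' @param metric "p5" or "p3".
#' @return data.frame with percentile and value, monotone non-increasing.
#' @export
precisionCurve <- function(records, metric = c("p5", "p3")) {
  metric <- match.arg(metric)
  v <- sort(records[[metric]], decreasing = TRUE)
  n <- length(v)
  pct <- if (n == 0) numeric(0)
         else if (n == 1) 1
         else round(1 + 99 * (seq_len(n) - 1) / (n - 1))
  data.frame(percentile = pct, value = v)
}

#' Knockdown response by RNA class
#'
#' Library-size-normalizes the control and knockdown counts, computes
#' per-row `log2((kd + 1) / (ctrl + 1))`, per-class means, and a two-sided
#' Mann-Whitney U test of every other class against the miRNA class. Classes
#' with fewer than 3 rows are skipped with a notice.
#'
#' Because a global miRNA knockdown shifts a large share of the library,
#' normalizing to total counts would absorb the effect being measured;
#' library sizes are therefore computed over the classes in `norm_classes`
#' (default: every non-miRNA class, the biogenesis-independent negative
#' controls), falling back to all rows when none are present.
#'
#' @param control,knockdown non-negative count vectors (matched rows).
#' @param classes character vector of RNA classes per row.
#' @param norm_classes classes whose summed counts define the library size.
#' @return list with `log2fc` (data.frame id, class, log2fc), `class_means`,
#'   `mwu` (data.frame class, statistic, p vs miRNA) and `cumulative`
#'   (per-class ECDF table).
#' @export
knockdownAnalysis <- function(control, knockdown, classes,
                              norm_classes = setdiff(unique(classes),
                                                     "miRNA")) {
  stopifnot(length(control) == length(knockdown),
            length(classes) == length(control))
  if (any(control < 0) || any(knockdown < 0)) stop("counts must be >= 0")
  norm_rows <- classes %in% norm_classes
  if (!any(norm_rows)) norm_rows <- rep(TRUE, length(classes))
  sc <- sum(control[norm_rows]); sk <- sum(knockdown[norm_rows])
  scale <- mean(c(sc, sk))
  cn <- control / sc * scale
  kn <- knockdown / sk * scale
  lfc <- log2((kn + 1) / (cn + 1))
  ids <- names(control) %||% sprintf("rna%04d", seq_along(control))
  d <- data.frame(id = ids, class = classes, log2fc = lfc,
                  stringsAsFactors = FALSE, row.names = NULL)
  cm <- tapply(d$log2fc, d$class, mean)
  mwu <- list()
  for (cl in setdiff(unique(classes), "miRNA")) {
    if (sum(classes == cl) < 3 || sum(classes == "miRNA") < 3) {
      message("class ", cl, " has < 3 rows; MWU skipped")
      next
    }
    t <- mwuTest(d$log2fc[d$class == "miRNA"], d$log2fc[d$class == cl])
    mwu[[length(mwu) + 1L]] <- data.frame(class = cl,
                                          statistic = t$statistic,
                                          p = t$p, stringsAsFactors = FALSE)
  }
  cum <- do.call(rbind, lapply(split(d$log2fc, d$class), function(v) {
    v <- sort(v)
    data.frame(log2fc = v, frac = seq_along(v) / length(v))
  }))
  cum$class <- sub("\\.\\d+$", "", rownames(cum))
  rownames(cum) <- NULL
  list(log2fc = d, class_means = cm,
       mwu = if (length(mwu)) do.call(rbind, mwu) else NULL,
       cumulative = cum)
}
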