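# End-to-end orchestration on synthetic data, plus truth-matching metrics.

#' Match discovered calls against planted truth
#'
#' A call matches a truth precursor when their spans overlap on the same
#' scaffold. Sensitivity is the fraction of truth loci hit by >= 1 call;
#' precision the fraction of calls hitting a truth locus.
#'
#' @param calls calls GRanges.
#' @param truth truth table from [generateGenome()].
#' @return list with sensitivity, precision, n_calls, n_truth, matched truth
#'   ids and false-call ids.
#' @export
matchCallsToTruth <- function(calls, truth) {
  if (nrow(truth) == 0)
    return(list(sensitivity = NA_real_, precision = NA_real_,
                n_calls = length(calls), n_truth = 0L,
                matched = character(0),
                false_calls = mcols(calls)$id))
  tg <- GenomicRanges::GRanges(truth$scaffold,
                               IRanges::IRanges(truth$start, truth$end))
  if (length(calls) == 0)
    return(list(sensitivity = 0, precision = NA_real_, n_calls = 0L,
                n_truth = nrow(truth), matched = character(0),
                false_calls = character(0)))
  ov <- GenomicRanges::findOverlaps(calls, tg, ignore.strand = TRUE)
  matched_truth <- unique(subjectHits(ov))
  matched_calls <- unique(queryHits(ov))
  list(sensitivity = length(matched_truth) / nrow(truth),
       precision = length(matched_calls) / length(calls),
       n_calls = length(calls), n_truth = nrow(truth),
       matched = truth$id[matched_truth],
       false_calls = mcols(calls)$id[setdiff(seq_along(calls),
                                             matched_calls)])
}

# Reference mature set for the conserved truth rows (miRBase-style names).
truthReferenceSet <- function(truth) {
  rows <- truth$classLabel == "conserved"
  setNames(truth$mature5[rows], paste0("ref-", truth$id[rows]))
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates a genome, read library, sister species, tissue panel and
#' knockdown experiment from `config`, then runs QC, collapsing, discovery,
#' quantification, precision, tissue-specificity, knockdown, cross-species
#' variant and duplication analyses, writing all tables to `out_dir` and
#' returning a machine-readable summary. Every stage seeds its own RNG from
#' the global seed, so stages are reproducible in isolation.
#'
#' @param out_dir output directory (created if missing); NULL for no files.
#' @param config a [SimConfig-class].
#' @param target_sn discovery signal-to-noise target (default 10).
#' @param n_perm,n_shuffles discovery calibration depth.
#' @param verbose log stage progress (default TRUE).
#' @return list of per-stage results and a `summary` vector.
#' @export
runPipeline <- function(out_dir = NULL, config = simConfig(),
                        target_sn = 10, n_perm = 100, n_shuffles = 100,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[mirburst] ", ...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(d, f) {
    if (!is.null(out_dir))
      write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  seed <- config@seed

  say("simulate: genome with ", config@nMirnas, " planted precursors")
  sim <- generateGenome(config)
  abund <- drawAbundances(sim$truth, config)
  reads <- generateReads(sim$genome, sim$truth, config, abund,
                         decoys = sim$decoys)
  if (!is.null(out_dir)) {
    writeFastaGenome(sim$genome, file.path(out_dir, "genome.fa"))
    writeFastq(reads, file.path(out_dir, "reads.fastq"))
    emit(sim$truth, "truth.tsv")
  }

  say("qc: adapter trim + quality filter on ", nrow(reads), " reads")
  tr <- trimAdapter(reads$seq, config@adapter)
  reads$seq <- tr$seq
  reads$qual <- substr(reads$qual, 1, nchar(reads$seq))
  qc <- filterReads(reads)
  lenDist <- lengthDistribution(qc$reads$seq)

  say("collapse: ", nrow(qc$reads), " QC'd reads")
  creads <- collapseReads(qc$reads$seq)

  say("discover: mapping and scoring")
  refs <- truthReferenceSet(sim$truth)
  disc <- discoverMirnas(sim$genome, creads, refs = refs,
                         target_sn = target_sn, n_perm = n_perm,
                         n_shuffles = n_shuffles,
                         seed = stageSeed(seed, "discover"))
  calls <- disc$calls
  perf <- matchCallsToTruth(calls, sim$truth)
  say("discover: ", length(calls), " calls (sensitivity ",
      round(perf$sensitivity, 3), ", precision ", round(perf$precision, 3),
      ")")
  if (!is.null(out_dir) && length(calls))
    writeGff3(calls, file.path(out_dir, "calls.gff3"), genome = sim$genome)

  say("quantify + precision")
  mp <- mapReads(sim$genome, creads)
  se <- if (length(calls)) quantifyExpression(calls, list(main = mp$mappings))
        else NULL
  prec <- if (length(calls)) endPrecision(calls, mp$mappings) else NULL
  if (!is.null(prec)) emit(prec, "precision.tsv")

  say("tissue specificity")
  tprof <- generateTissueProfiles(sim$truth, config)
  tflags <- tissueSpecificity(tprof)
  emit(tflags, "tissue_flags.tsv")

  say("knockdown analysis")
  ctrlMeans <- c(abund[sim$truth$id] * 5e4,
                 setNames(rep(50, 90), sprintf("other%02d", 1:90)))
  kdClasses <- c(rep("miRNA", nrow(sim$truth)),
                 rep(c("snoRNA", "tRNA", "rRNA"), each = 30))
  kd <- simulateKnockdown(ctrlMeans, kdClasses, config)
  kda <- knockdownAnalysis(kd$control, kd$knockdown, kd$class)
  emit(kd, "knockdown_counts.tsv")

  say("cross-species analysis")
  sis <- mutateSister(sim$genome, sim$truth, config)
  sisReads <- generateReads(sis$genome, sis$truth, config,
                            expression = abund,
                            seed = stageSeed(seed, "sister_reads"),
                            lib = "sister")
  sisTrim <- trimAdapter(sisReads$seq, config@adapter)
  sisC <- collapseReads(filterReads(data.frame(
    id = sisReads$id, seq = sisTrim$seq,
    qual = substr(sisReads$qual, 1, nchar(sisTrim$seq))))$reads$seq)
  precs <- setNames(sim$truth$precursorSeq, sim$truth$id)
  xsp <- crossSpeciesDetect(precs, sisC)
  variants <- lapply(names(precs), function(pid) {
    r <- match(pid, sim$truth$id)
    span <- c(sim$truth$m5Start[r] - sim$truth$start[r] + 1L,
              sim$truth$m5End[r] - sim$truth$start[r] + 1L)
    callMatureVariants(xsp$pileups[[pid]], precs[[pid]], span)
  })
  names(variants) <- names(precs)
  variant_ids <- names(variants)[vapply(variants, nrow, integer(1)) > 0]

  say("duplication scan")
  pairs <- if (nrow(sim$truth) >= 2)
    allVsAllSimilarity(setNames(sim$truth$precursorSeq, sim$truth$id))
  else NULL
  tg <- GenomicRanges::GRanges(sim$truth$scaffold,
          IRanges::IRanges(sim$truth$start, sim$truth$end), strand = "+")
  mcols(tg)$id <- sim$truth$id
  mcols(tg)$precursorSeq <- sim$truth$precursorSeq
  dup <- flankScan(sim$genome, tg)
  dhist <- distanceHistogram(dup)
  if (!is.null(pairs)) emit(pairs, "similarity_pairs.tsv")
  emit(dup, "duplication_hits.tsv")

  summary <- c(
    n_reads = nrow(reads), n_qc = unname(qc$report["kept"]),
    n_collapsed = nrow(creads), n_calls = length(calls),
    sensitivity = perf$sensitivity, precision = perf$precision,
    sn_cutoff = disc$cutoff,
    mean_mirna_log2fc = unname(kda$class_means["miRNA"]),
    n_detected_sister = length(xsp$detected),
    n_variant_mirnas = length(variant_ids),
    n_similarity_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    n_duplication_hits = nrow(dup))
  if (!is.null(out_dir))
    write.table(data.frame(metric = names(summary),
                           value = unname(summary)),
                file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  say("done")
  invisible(list(
    config = config, sim = sim, reads = reads, qc_report = qc$report,
    length_distribution = lenDist, collapsed = creads, discovery = disc,
    calls = calls, performance = perf, expression = se, precision = prec,
    tissue_profiles = tprof, tissue_flags = tflags, knockdown = kda,
    sister = sis, cross_species = xsp, variants = variants,
    variant_ids = variant_ids, similarity_pairs = pairs,
    duplication_hits = dup, distance_histogram = dhist, summary = summary))
}
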