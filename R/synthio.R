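# Synthetic study generator: genomes with planted hairpin precursors and
# tandem duplicate families, small-RNA read libraries with realistic end
# jitter, a mutated sister-species genome, tissue-biased expression profiles
# and biogenesis-knockdown count tables -- all with recorded ground truth.

precursorLength <- function(config) 2L * config@matureLen + config@loopLen

# Build one pristine hairpin precursor: mature 5P + loop + 3P arm, where the
# 3P arm is the reverse complement of the 5P mature offset to leave a 2-nt 3'
# overhang on each strand of the modelled Dicer duplex. The loop is drawn
# from {A, C} so that it cannot base-pair with itself.
makePrecursor <- function(config) {
  L <- config@matureLen
  mature <- randomDna(L)
  loop <- randomDna(config@loopLen, alphabet = c("A", "C"))
  arm3 <- paste0(revComp(substr(mature, 1L, L - 2L)), randomDna(2L))
  paste0(mature, loop, arm3)
}

mutateString <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

drawSpacing <- function(config) {
  lo <- config@familySpacingRange[1]; hi <- config@familySpacingRange[2]
  repeat {
    s <- rexp(1L, rate = 1 / config@familySpacingMean)
    if (s >= lo && s <= hi) return(round(s))
  }
}

#' Generate a synthetic genome with planted miRNA precursors
#'
#' Assembles `nScaffolds` scaffolds of i.i.d. uniform ACGT background and
#' plants `nMirnas` hairpin precursors, organised into `nFamilies` tandem
#' families whose non-founder members carry per-base substitutions at
#' `familyDivergence` and sit at truncated-exponential spacings, plus
#' `nDecoys` decoy loci (plain background positions that will receive
#' stacked degradation-like reads). All truth sequences are re-extracted
#' from the final genome, so truth and genome can never disagree.
#'
#' @param config a [SimConfig-class].
#' @return list with `genome` (DNAStringSet), `truth` (data.frame, 1-based
#'   inclusive coordinates: id, scaffold, start, end, strand, m5Start, m5End,
#'   m3Start, m3End, mature5, mature3, precursorSeq, family, classLabel,
#'   tissueSpecific, tissue, spacing) and `decoys` (data.frame).
#' @export
generateGenome <- function(config) {
  withSeed(stageSeed(config@seed, "genome"), {
    plen <- precursorLength(config)
    n <- config@nMirnas
    # family plan
    sizes <- integer(0)
    if (n > 0 && config@nFamilies > 0) {
      for (f in seq_len(config@nFamilies)) {
        s <- config@familySizes[sample.int(length(config@familySizes), 1L)]
        if (sum(sizes) + s > n) break
        sizes <- c(sizes, s)
      }
    }
    nSingle <- n - sum(sizes)
    groups <- c(lapply(seq_along(sizes), function(f)
                  list(family = sprintf("fam%02d", f), size = sizes[f])),
                lapply(seq_len(nSingle), function(k)
                  list(family = NA_character_, size = 1L)))
    # per-scaffold assembly state
    segs <- lapply(seq_len(config@nScaffolds), function(i) character(0))
    cur <- rep(0L, config@nScaffolds)
    names(cur) <- sprintf("scaf%02d", seq_len(config@nScaffolds))
    truth <- list()
    idn <- 0L
    for (g in groups) {
      spacings <- if (g$size > 1L)
        vapply(seq_len(g$size - 1L), function(i) drawSpacing(config),
               numeric(1)) else numeric(0)
      lead <- round(runif(1L, 200, 1500))
      need <- lead + g$size * plen + sum(spacings) + 100L
      sc <- which(cur + need <= config@scaffoldLength)
      if (length(sc) == 0)
        stop("scaffold too short for requested plantings (",
             "need ", need, " bp more on every scaffold; smallest is ",
             names(cur)[which.min(cur)], ")")
      sc <- sc[which.min(cur[sc])]
      founder <- makePrecursor(config)
      segs[[sc]] <- c(segs[[sc]], randomDna(lead))
      cur[sc] <- cur[sc] + lead
      for (k in seq_len(g$size)) {
        if (k > 1L) {
          gap <- spacings[k - 1L]
          segs[[sc]] <- c(segs[[sc]], randomDna(gap))
          cur[sc] <- cur[sc] + gap
        }
        seqk <- if (k == 1L) founder
                else mutateString(founder, config@familyDivergence)
        idn <- idn + 1L
        start <- cur[[sc]] + 1L
        segs[[sc]] <- c(segs[[sc]], seqk)
        cur[sc] <- cur[sc] + plen
        truth[[idn]] <- data.frame(
          id = sprintf("mir%03d", idn), scaffold = names(cur)[sc],
          start = start, end = cur[[sc]], strand = "+",
          m5Start = start, m5End = start + config@matureLen - 1L,
          m3Start = start + config@matureLen + config@loopLen,
          m3End = start + plen - 1L,
          family = if (is.na(g$family)) sprintf("mir%03d", idn) else g$family,
          spacing = if (k == 1L) NA_real_ else spacings[k - 1L],
          stringsAsFactors = FALSE)
      }
    }
    # pad scaffolds to full length
    for (i in seq_len(config@nScaffolds)) {
      pad <- config@scaffoldLength - cur[i]
      if (pad < 0) stop("scaffold too short: ", names(cur)[i])
      if (pad > 0) segs[[i]] <- c(segs[[i]], randomDna(pad))
    }
    genome <- Biostrings::DNAStringSet(vapply(segs, paste, character(1),
                                              collapse = ""))
    names(genome) <- names(cur)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(0), scaffold = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 m5Start = integer(0), m5End = integer(0),
                 m3Start = integer(0), m3End = integer(0),
                 family = character(0), spacing = numeric(0))
    # class labels and tissue flags
    nt <- nrow(truth)
    truth$classLabel <- rep("lineage", nt)
    if (nt > 0 && config@nConserved > 0)
      truth$classLabel[sample.int(nt, min(config@nConserved, nt))] <- "conserved"
    truth$tissueSpecific <- rep(FALSE, nt)
    truth$tissue <- rep(NA_character_, nt)
    if (nt > 0 && config@nTissueSpecific > 0) {
      ts <- sample.int(nt, min(config@nTissueSpecific, nt))
      truth$tissueSpecific[ts] <- TRUE
      truth$tissue[ts] <- sample(config@tissueNames, length(ts), replace = TRUE)
    }
    # re-extract truth sequences from the emitted genome
    if (nt > 0) {
      truth$precursorSeq <- substr(as.character(genome[truth$scaffold]),
                                   truth$start, truth$end)
      truth$mature5 <- substr(as.character(genome[truth$scaffold]),
                              truth$m5Start, truth$m5End)
      truth$mature3 <- substr(as.character(genome[truth$scaffold]),
                              truth$m3Start, truth$m3End)
    } else {
      truth$precursorSeq <- truth$mature5 <- truth$mature3 <- character(0)
    }
    # decoy loci on background sequence
    decoys <- data.frame(id = character(0), scaffold = character(0),
                         start = integer(0), end = integer(0))
    if (config@nDecoys > 0) {
      got <- 0L
      while (got < config@nDecoys) {
        sc <- sample(names(genome), 1L)
        st <- sample.int(config@scaffoldLength - config@matureLen - 300L, 1L) + 150L
        en <- st + config@matureLen - 1L
        clash <- nt > 0 && any(truth$scaffold == sc &
                               truth$start - 200L <= en &
                               truth$end + 200L >= st)
        if (!clash) {
          got <- got + 1L
          decoys <- rbind(decoys, data.frame(
            id = sprintf("decoy%02d", got), scaffold = sc,
            start = st, end = en, stringsAsFactors = FALSE))
        }
      }
    }
    rownames(truth) <- NULL
    list(genome = genome, truth = truth, decoys = decoys)
  })
}

#' Draw relative miRNA abundances
#'
#' Gamma-distributed relative expression weights, the shared abundance model
#' of all simulated libraries.
#'
#' @param truth truth table from [generateGenome()].
#' @param config a [SimConfig-class].
#' @param seed RNG seed (default: derived from the config seed).
#' @return named numeric vector summing to 1.
#' @export
drawAbundances <- function(truth, config,
                           seed = stageSeed(config@seed, "abundance")) {
  withSeed(seed, {
    a <- rgamma(nrow(truth), shape = config@abundanceShape, rate = 1) + 0.05
    setNames(a / sum(a), truth$id)
  })
}

jitterEnds <- function(start, end, p5, p3, five_off = c(-2, -1, 1, 2),
                       three_off = c(-3, -2, -1, 1, 2, 3)) {
  if (runif(1) > p5) start <- start + sample(five_off, 1L)
  if (runif(1) > p3) end <- end + sample(three_off, 1L)
  c(start, end)
}

#' Simulate a small-RNA read library
#'
#' Draws reads from the planted mature arms (5P:3P at `armRatio5p3p`, 5' ends
#' exact with probability `p5Precision` else off by 1-2 nt, 3' ends exact
#' with probability `p3Precision` else off by 1-3 nt), stacked
#' degradation-like reads at decoy loci, and `backgroundFraction` random
#' genome fragments of 18-30 nt. The 3' adapter is appended to every read and
#' qualities are constant Q30.
#'
#' @param genome scaffold set the truth loci live on.
#' @param truth truth table from [generateGenome()] (may have zero rows).
#' @param config a [SimConfig-class].
#' @param expression named abundance vector over `truth$id` (see
#'   [drawAbundances()]); required when any miRNA reads are to be drawn.
#' @param decoys decoy table from [generateGenome()] (optional).
#' @param seed RNG seed.
#' @param lib library name used in read ids.
#' @return data.frame with id, seq, qual (Phred+33).
#' @export
generateReads <- function(genome, truth, config, expression = NULL,
                          decoys = NULL, seed = stageSeed(config@seed, "reads"),
                          lib = "lib1") {
  genome <- asScaffoldSet(genome)
  chrs <- as.character(genome)
  ndecoy <- if (is.null(decoys)) 0L else nrow(decoys)
  nTotal <- config@readsPerLibrary
  nBg <- round(nTotal * config@backgroundFraction)
  nDecoyReads <- min(40L * ndecoy, max(0L, nTotal - nBg))
  nFg <- nTotal - nBg - nDecoyReads
  if (nrow(truth) == 0) nFg <- 0L
  if (nFg > 0 && (is.null(expression) || length(expression) == 0))
    stop("empty expression table")
  withSeed(seed, {
    out <- vector("list", 3)
    p53 <- config@armRatio5p3p / (1 + config@armRatio5p3p)
    if (nFg > 0) {
      pick <- sample(truth$id, nFg, replace = TRUE,
                     prob = expression[truth$id])
      rows <- match(pick, truth$id)
      is5 <- runif(nFg) < p53
      seqs <- character(nFg)
      for (k in seq_len(nFg)) {
        r <- rows[k]
        span <- if (is5[k]) c(truth$m5Start[r], truth$m5End[r])
                else c(truth$m3Start[r], truth$m3End[r])
        se <- jitterEnds(span[1], span[2], config@p5Precision,
                         config@p3Precision)
        se <- pmax(1L, pmin(nchar(chrs[[truth$scaffold[r]]]), se))
        seqs[k] <- substr(chrs[[truth$scaffold[r]]], se[1], se[2])
      }
      out[[1]] <- seqs
    }
    if (nDecoyReads > 0) {
      drow <- sample.int(ndecoy, nDecoyReads, replace = TRUE)
      seqs <- character(nDecoyReads)
      for (k in seq_len(nDecoyReads)) {
        r <- drow[k]
        se <- jitterEnds(decoys$start[r], decoys$end[r], 0.9, 0.5)
        se <- pmax(1L, pmin(nchar(chrs[[decoys$scaffold[r]]]), se))
        seqs[k] <- substr(chrs[[decoys$scaffold[r]]], se[1], se[2])
      }
      out[[2]] <- seqs
    }
    if (nBg > 0) {
      sc <- sample(names(genome), nBg, replace = TRUE)
      len <- sample(18:30, nBg, replace = TRUE)
      seqs <- character(nBg)
      for (k in seq_len(nBg)) {
        maxs <- nchar(chrs[[sc[k]]]) - len[k]
        st <- sample.int(maxs, 1L)
        seqs[k] <- substr(chrs[[sc[k]]], st, st + len[k] - 1L)
      }
      out[[3]] <- seqs
    }
    seqs <- unlist(out)
    if (length(seqs) == 0)
      return(data.frame(id = character(0), seq = character(0),
                        qual = character(0)))
    seqs <- paste0(seqs, config@adapter)
    data.frame(
      id = sprintf("%s_r%06d", lib, seq_along(seqs)),
      seq = seqs,
      qual = strrep("?", nchar(seqs)),   # Q30 in Phred+33
      stringsAsFactors = FALSE)
  })
}

#' Mutate a sister-species genome
#'
#' Applies i.i.d. per-base substitutions at `sisterMutRate` to every scaffold
#' and records every substitution falling inside a truth mature span as
#' variant ground truth (1-based position within the mature).
#'
#' @param genome scaffold set.
#' @param truth truth table from [generateGenome()].
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @return list with `genome` (mutated DNAStringSet), `truth` (mature
#'   sequences re-extracted from the mutated genome) and `variants`
#'   (data.frame: id, arm, posInMature, ref, alt).
#' @export
mutateSister <- function(genome, truth, config,
                         seed = stageSeed(config@seed, "sister")) {
  genome <- asScaffoldSet(genome)
  withSeed(seed, {
    rate <- config@sisterMutRate
    chrs <- as.character(genome)
    mut <- vapply(chrs, mutateString, character(1), rate = rate,
                  USE.NAMES = TRUE)
    sister <- Biostrings::DNAStringSet(mut)
    names(sister) <- names(genome)
    variants <- data.frame(id = character(0), arm = character(0),
                           posInMature = integer(0), ref = character(0),
                           alt = character(0), stringsAsFactors = FALSE)
    st <- truth
    if (nrow(truth) > 0) {
      for (r in seq_len(nrow(truth))) {
        for (arm in c("5P", "3P")) {
          sp <- if (arm == "5P") c(truth$m5Start[r], truth$m5End[r])
                else c(truth$m3Start[r], truth$m3End[r])
          a <- strsplit(substr(chrs[[truth$scaffold[r]]], sp[1], sp[2]), "")[[1]]
          b <- strsplit(substr(mut[[truth$scaffold[r]]], sp[1], sp[2]), "")[[1]]
          d <- which(a != b)
          if (length(d))
            variants <- rbind(variants, data.frame(
              id = truth$id[r], arm = arm, posInMature = d,
              ref = a[d], alt = b[d], stringsAsFactors = FALSE))
        }
      }
      st$precursorSeq <- substr(mut[st$scaffold], st$start, st$end)
      st$mature5 <- substr(mut[st$scaffold], st$m5Start, st$m5End)
      st$mature3 <- substr(mut[st$scaffold], st$m3Start, st$m3End)
    }
    list(genome = sister, truth = st, variants = variants)
  })
}

#' Simulate a biogenesis-knockdown experiment
#'
#' Scales miRNA rows by `2^x` with `x ~ Normal(kdLog2fcMean, kdLog2fcSd)` and
#' non-miRNA rows (snoRNA, tRNA, rRNA) by `2^y`, `y ~ Normal(0, kdLog2fcSd)`,
#' then applies Poisson resampling to both conditions.
#'
#' @param counts named non-negative base mean counts per RNA.
#' @param classes character vector (same length) in
#'   {miRNA, snoRNA, tRNA, rRNA}.
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @return data.frame with id, class, control, knockdown.
#' @export
simulateKnockdown <- function(counts, classes, config,
                              seed = stageSeed(config@seed, "knockdown")) {
  if (any(counts < 0)) stop("counts must be non-negative")
  ok <- c("miRNA", "snoRNA", "tRNA", "rRNA")
  if (!all(classes %in% ok))
    stop("unknown class label: ", paste(setdiff(classes, ok), collapse = ", "))
  withSeed(seed, {
    n <- length(counts)
    x <- rnorm(n, ifelse(classes == "miRNA", config@kdLog2fcMean, 0),
               config@kdLog2fcSd)
    data.frame(
      id = names(counts) %||% sprintf("rna%04d", seq_len(n)),
      class = classes,
      control = rpois(n, counts),
      knockdown = rpois(n, counts * 2^x),
      stringsAsFactors = FALSE)
  })
}

#' Simulate tissue expression profiles
#'
#' Non-specific miRNAs draw a shared Gamma-Poisson count in every tissue;
#' tissue-specific rows get a `tissueFold`-fold mean in their flagged tissue.
#'
#' @param truth truth table with `tissueSpecific` and `tissue` columns.
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @param base_mean mean count of the shared component (default 50).
#' @return integer matrix miRNA x tissue.
#' @export
generateTissueProfiles <- function(truth, config,
                                   seed = stageSeed(config@seed, "tissue"),
                                   base_mean = 50) {
  withSeed(seed, {
    n <- nrow(truth)
    tn <- config@tissueNames
    mu <- rgamma(n, shape = 2, scale = base_mean / 2) + 1
    m <- matrix(0L, n, length(tn), dimnames = list(truth$id, tn))
    for (j in seq_along(tn)) {
      mj <- mu
      boost <- truth$tissueSpecific & !is.na(truth$tissue) & truth$tissue == tn[j]
      mj[boost] <- mj[boost] * config@tissueFold
      m[, j] <- rpois(n, mj)
    }
    m
  })
}
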