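# Hairpin folding, hairpin-shape testing and dinucleotide-shuffle null models.

#' Fold a sequence by weighted base-pair maximization
#'
#' Predicts the minimum-energy nested secondary structure with a weighted
#' Nussinov dynamic program: pair weights GC -3, AU -2, GU -1
#' (kcal/mol-equivalent), minimum hairpin loop of 3 unpaired bases.
#' T is treated as U. Ties are broken deterministically: pairing the 5' base
#' beats leaving it unpaired, and the smallest partner index wins.
#'
#' @param seq a single DNA/RNA string (ACGT/ACGU).
#' @return a [SecondaryStructure-class].
#' @examples
#' foldMFE("GGGAAAACCC")
#' @export
foldMFE <- function(seq) {
  if (length(seq) != 1L || !nzchar(seq)) stop("seq must be one non-empty string")
  res <- .nussinov_fold(seq)
  p <- res$pairs + 1L
  if (nrow(p) > 1) p <- p[order(p[, 1]), , drop = FALSE]
  db <- rep(".", nchar(seq))
  if (nrow(p) > 0) { db[p[, 1]] <- "("; db[p[, 2]] <- ")" }
  rna <- chartr("Tt", "Uu", toupper(seq))
  new("SecondaryStructure", sequence = rna, pairs = p,
      dotBracket = paste(db, collapse = ""), energy = res$energy)
}

#' Test whether a structure is a single stem-loop
#'
#' A structure is a hairpin when its pairs form one ladder: sorted by the
#' 5' index, the 3' indices are strictly decreasing (bulges and internal
#' loops allowed, no branching).
#'
#' @param struct a [SecondaryStructure-class].
#' @return list with `is_hairpin` flag, `stem_length` (longest run of
#'   directly stacked pairs) and `paired_fraction` of bases.
#' @export
isHairpin <- function(struct) {
  p <- struct@pairs
  n <- nchar(struct@sequence)
  if (nrow(p) == 0)
    return(list(is_hairpin = FALSE, stem_length = 0L, paired_fraction = 0))
  o <- order(p[, 1])
  pi <- p[o, 1]; pj <- p[o, 2]
  flag <- all(diff(pj) < 0)
  stem <- run <- 1L
  if (nrow(p) > 1) {
    for (k in 2:nrow(p)) {
      run <- if (pi[k] == pi[k - 1] + 1L && pj[k] == pj[k - 1] - 1L)
        run + 1L else 1L
      stem <- max(stem, run)
    }
  }
  list(is_hairpin = flag, stem_length = stem,
       paired_fraction = 2 * nrow(p) / n)
}

# Longest nested chain of pairs: with pairs sorted by the 5' index, the
# longest strictly-decreasing subsequence of 3' indices. Side branches
# (e.g. a small hairpin budding off an interior loop) are skipped, so a
# bulged stem is recovered in full. Optionally the chain's outermost span
# must overlap [lo, hi]. Returns row indices into `pairs` (outermost first),
# or NULL.
longestNestedChain <- function(pairs, lo = NULL, hi = NULL) {
  n <- nrow(pairs)
  if (n == 0) return(NULL)
  o <- order(pairs[, 1])
  pi <- pairs[o, 1]; pj <- pairs[o, 2]
  len <- rep(1L, n); parent <- rep(0L, n)
  for (k in seq_len(n)) {
    for (m in seq_len(k - 1L)) {
      if (pj[m] > pj[k] && pi[m] < pi[k] && len[m] + 1L > len[k]) {
        len[k] <- len[m] + 1L
        parent[k] <- m
      }
    }
  }
  root_of <- function(k) { while (parent[k] > 0L) k <- parent[k]; k }
  best <- 0L; bestLen <- 0L
  for (k in seq_len(n)) {
    r <- root_of(k)
    if (!is.null(lo) && (pi[r] > hi || pj[r] < lo)) next
    if (len[k] > bestLen) { best <- k; bestLen <- len[k] }
  }
  if (best == 0L) return(NULL)
  chain <- integer(0); k <- best
  while (k > 0L) { chain <- c(k, chain); k <- parent[k] }
  o[chain]
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide counts
#' (and hence mononucleotide counts and the first and last characters),
#' using the Altschul-Erickson Eulerian-walk construction: a random last-edge
#' arborescence into the terminal character is drawn, remaining edges are
#' permuted, and the Eulerian walk is read off.
#'
#' @param seq a string of length >= 3.
#' @param seed optional integer seed for reproducibility.
#' @return a shuffled string over the same alphabet.
#' @export
dinucleotideShuffle <- function(seq, seed = NULL) {
  if (nchar(seq) < 3) stop("sequence too short to shuffle")
  run <- function() {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    verts <- unique(ch)
    last <- ch[n]
    # out-edge lists
    edges <- split(ch[-1], factor(ch[-n], levels = verts))
    repeat {
      # pick a candidate last edge for every non-terminal vertex
      lastEdge <- vapply(verts, function(v) {
        if (v == last || length(edges[[v]]) == 0) NA_character_
        else sample(edges[[v]], 1L)
      }, character(1))
      # validity: following last edges from every vertex must reach `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(edges[[v]]) == 0) next
        seen <- character(0); cur <- v
        while (!is.na(cur) && cur != last && !(cur %in% seen)) {
          seen <- c(seen, cur)
          cur <- if (cur %in% names(lastEdge)) lastEdge[[cur]] else NA_character_
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # shuffle remaining edges, append the chosen last edge
    pool <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!is.na(lastEdge[[v]])) {
        drop1 <- match(lastEdge[[v]], e)
        e <- e[-drop1]
      }
      c(if (length(e)) sample(e) else character(0),
        if (!is.na(lastEdge[[v]])) lastEdge[[v]] else character(0))
    })
    names(pool) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n); out[1] <- ch[1]
    for (k in 2:n) {
      v <- out[k - 1]
      out[k] <- pool[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Folding-stability z-score against dinucleotide-shuffled nulls
#'
#' Folds the sequence and `n_shuffles` dinucleotide-preserving shuffles of it,
#' and returns z = (E_seq - mean(E_shuffled)) / sd(E_shuffled). A strongly
#' negative z marks a sequence that folds better than its composition
#' predicts, the behaviour expected of a genuine hairpin precursor.
#'
#' @param seq sequence to score.
#' @param n_shuffles number of shuffled controls (>= 10).
#' @param seed integer seed.
#' @return the z-score (0 when the shuffled energies are constant).
#' @export
mfeZ <- function(seq, n_shuffles = 100, seed = 1L) {
  if (n_shuffles < 10) stop("n_shuffles must be >= 10")
  e <- .nussinov_energy(seq)
  es <- withSeed(seed, vapply(seq_len(n_shuffles), function(i)
    .nussinov_energy(dinucleotideShuffle(seq)), numeric(1)))
  s <- sd(es)
  if (!is.finite(s) || s < 1e-12) return(0)
  (e - mean(es)) / s
}

#' Dominant-ladder hairpin model of a sequence
#'
#' Folds the sequence by [foldMFE()] and keeps only the longest nested pair
#' chain (the dominant ladder). Pure base-pair maximization lacks helix
#' stacking terms and therefore decorates genuine stem-loops with spurious
#' side stems; the dominant ladder is the hairpin those pairs describe, and
#' it is the structure candidate geometry (arms, duplex overhangs) is read
#' from. The returned energy is the summed weight of the ladder pairs only.
#'
#' @param seq a DNA/RNA string.
#' @return a [SecondaryStructure-class] whose pairs form a single ladder.
#' @export
hairpinModel <- function(seq) {
  full <- foldMFE(seq)
  p <- full@pairs
  best <- longestNestedChain(p)
  if (is.null(best)) return(full)
  keep <- p[best, , drop = FALSE]
  db <- rep(".", nchar(full@sequence))
  db[keep[, 1]] <- "("; db[keep[, 2]] <- ")"
  w <- pairWeights(full@sequence, keep)
  new("SecondaryStructure", sequence = full@sequence, pairs = keep,
      dotBracket = paste(db, collapse = ""), energy = sum(w))
}

# Weight of each pair under the GC -3 / AU -2 / GU -1 scheme.
pairWeights <- function(rna, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  ch <- strsplit(rna, "")[[1]]
  vapply(seq_len(nrow(pairs)), function(k) {
    ab <- paste0(ch[pairs[k, 1]], ch[pairs[k, 2]])
    switch(ab, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, 0)
  }, numeric(1))
}

# Default hairpin-stability acceptance rule for candidate windows.
mfeCriterion <- function(energy, z, len, z_max = -1.5, per_base = -0.2) {
  is.finite(z) && z <= z_max && energy <= per_base * len
}
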