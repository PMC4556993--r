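---
title: "mirburst: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirburst: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirburst re-implements, as one tested pipeline, the computational core of an
evidence-based miRNA survey in a large insect genome: discovery of miRNA
precursors from small-RNA read stacks, authenticity statistics (hairpin
folding stability, processing precision, biogenesis-knockdown response),
cross-species conservation and mature-sequence variation, tissue-specific
expression calling, and local-duplication scanning. Everything runs on
synthetic data with planted ground truth, so each stage's parameter recovery
is testable end to end. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic validation does and
does not demonstrate.

## The discovery model

Small-RNA reads are quality-filtered (length 18–30 nt after 3' adapter
trimming, at most 3 Ns, every base at or above Q20, no simple repeats),
collapsed to unique sequences, and sequences seen fewer than 3 times are
discarded: a genuine Dicer product is sequenced repeatedly, a random
degradation fragment rarely is. Collapsed reads are mapped exactly to the
genome on both strands; reads hitting more than 5 locations are removed as
repeat-derived. Maximal runs of overlapping same-strand hits ("stacks") seed
candidate loci: each stack is extended by 110 nt downstream and upstream,
each window is folded, and the stem-loop through the stack is excised.

Folding uses a weighted base-pair maximization dynamic program (Nussinov
recursion) with pair weights GC = −3, AU = −2, GU = −1 kcal/mol-equivalent
and a minimum hairpin loop of 3 nt. This energy model is deliberately simple:
it is fully specified, verifiable against exhaustive enumeration (a property
the test suite exercises for all short sequences), and adequate for ranking
hairpins. Its absolute energies are not comparable to thermodynamic
minimum-free-energy values, and two consequences shape the pipeline design:

* **Over-branching.** Without helix stacking terms, the optimal structure of
  a window decorates a genuine stem-loop with side stems. Candidate geometry
  is therefore read from the *dominant ladder*: the longest chain of mutually
  nested pairs (the longest strictly decreasing subsequence of 3' partners
  after sorting pairs by their 5' index). Side branches are skipped, so a
  bulged stem is recovered whole. `hairpinModel()` exposes this structure;
  `isHairpin()` retains the strict single-ladder definition.
* **Weak shuffle contrast.** A hairpin's composition is roughly half
  reverse-complementary, so dinucleotide-preserving shuffles
  (Altschul–Erickson Eulerian-walk construction, exact dinucleotide counts,
  ends preserved) fold almost as well under pair counting. The folding
  z-score `mfeZ()` — (E_seq − mean E_shuffled)/sd — is therefore informative
  but noisy: planted precursors score z between −6 and +0.3. It enters the
  evidence score as a component rather than acting as a hard gate; excision
  instead gates on structure substance (dominant ladder of at least 10
  pairs, candidate at least 40 nt, energy at most −0.2 per base), and hard z
  gating can be restored via `z_max`.

Each surviving candidate is scored with three read-evidence terms:

* `S_reads = log2((n_c + 1) / (n_i + 1))`, where `n_c` counts read copies
  lying fully within an arm whose 5' end is within 2 nt of that arm's modal
  5' end, and `n_i` all other copies — sharp 5' processing is the hallmark
  of Drosha/Dicer products;
* `S_duplex = +2` if the modal 5P and 3P products pair in the hairpin with a
  2 ± 1 nt 3' overhang on both strands (the RNase III signature), else −2.
  Product ends may be frayed or sit against a bulge, so the implied duplex
  partner is extrapolated from each paired anchor within 2 nt of the
  product's 5' end and the interpretation closest to the canonical 2-nt
  overhang is used;
* `S_struct = −z`, the folding-stability bonus.

A sequencing call additionally requires read products on both arms
(`min_arms = 2`); a one-arm candidate is rescued only when its stem contains
an unbroken helix of at least 10 stacked pairs. This duplex-consensus
requirement is what separates genuine two-strand Dicer duplexes from
one-sided degradation stacks, which otherwise defeat the permutation
calibration below (a stacked fragment always outscores its position-permuted
rescoring, whether or not it comes from a miRNA).

The score cutoff is not fixed but calibrated by the signal-to-noise
procedure: read positions are re-drawn uniformly within each candidate
window over 100 permutation rounds, candidates are rescored, and
`S/N(c) = N_real(total ≥ c) / mean_perm N(total ≥ c)`. The reported call set
uses the smallest cutoff with S/N at least 10.

Calls overlapping annotated CDS, tRNA/rRNA/snRNA/snoRNA or repeat intervals
are removed as likely degradation fragments. Each mature is classified as
evolutionarily conserved if some reference mature matches it with zero
mismatches in the seed region (positions 2–8) and no run of more than two
adjacent mismatches elsewhere; otherwise it is lineage-specific. A homology
scan maps reference matures to the genome (up to 3 mismatches), folds the
flanks, and keeps hits scoring at least 70 on the surrogate scale
`50·(1 − mm/len) + 50·(paired fraction of the mature)`; sequencing and
homology call sets are merged at 50% reciprocal overlap with provenance
tracking.

## Expression, precision, knockdown

Expression counts are copy-weighted sums of reads whose 5' end lies within
2 nt of a call's mature 5' end, split fractionally across compatible calls;
TPM is `count / library size × 1e6`, and expression groups use a strict
`TPM > 10` cutoff (5 and 15 as sensitivity settings). Tissue specificity
tests each miRNA × tissue against the aggregate of the other tissues with an
exact conditional test on the 2×2 count-vs-library table,
Benjamini–Hochberg correction, a 4-fold normalized change floor, and a
higher-in-tissue direction requirement.

Processing precision is the copy-weighted fraction of a call's arm reads
whose 5' (respectively 3') end coincides exactly with the annotated mature
end; curves order miRNAs from percentile 1 (most precise) to 100. Precision
is a read-level statistic and should be estimated on the unfiltered mapping
(collapse at `min_copy = 1`): the copy-number filter used for discovery
preferentially removes rare end variants and inflates exact-end fractions
(by about 0.05 at the shipped library sizes).

Knockdown analysis computes `log2((kd + 1)/(ctrl + 1))` after library-size
normalization and compares classes with the Mann–Whitney U test. Library
sizes are summed over the *non-miRNA* classes (snoRNA, tRNA, rRNA — the
biogenesis-independent negative controls): a global miRNA knockdown shifts a
large share of total counts, and normalizing to the total would absorb the
effect being measured (with miRNAs at ~25% of the library, a planted −1.04
mean log2 fold change reads as −0.8 under total-count normalization and as
−1.04 under control-class normalization).

## Cross-species variation

Reads from the second species are aligned to precursor sequences, ungapped,
both orientations, with up to two mismatches. Copy-weighted base pileups
feed variant calling: a mature position is a variant when coverage reaches
10 and the modal non-reference base fraction reaches 0.5; the first and last
three bases of the mature are always masked, because read ends carry
frequent untemplated additions that mimic substitutions. Variant-by-group
2×2 tables (conserved vs lineage-specific; moderate/high vs low expression)
are tested with the Pearson chi-squared closed form
`n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, df = 1, optional Yates correction.
The statistical kit also provides the Mann–Whitney U test (exact null via
the Wilcoxon distribution for samples of at most 8 without ties, otherwise
normal approximation with tie and continuity corrections), the two-sample
Kolmogorov–Smirnov test (asymptotic p with the Stephens small-sample factor;
note the statistic is lattice-valued at small n, so its null p is only
approximately uniform), and Pearson correlation with the t-test.

## Duplication scanning

All precursor pairs are aligned with an affine-gap Smith–Waterman
(match +1, mismatch −2, first gap column −5, each further −2). Significance
uses the ungapped Karlin–Altschul model `E = K·m·n·exp(−λS)`: λ solves
`Σ p_i p_j exp(λ s_ij) = 1` by bisection to 1e-9 (λ ≈ 1.333 for this scheme
at uniform composition) and K is fixed at 0.35, a documented approximation
that scales E by a constant absorbed into the configurable threshold. Pairs
with `E < 1e-5` and over 50% coverage of the shorter precursor are kept;
families are connected components; the family consensus is the per-column
majority over glocal alignments of members to the longest member
(ties resolved alphabetically and flagged).

The flank scan extracts ±50 kb around each precursor and repeatedly aligns
the precursor glocally (query global, free target end gaps) against both
strands, masking each hit. The identity floor is 0.7: the best random glocal
alignment over flanks of this size reaches identity ~0.64 (measured on the
null), while copies at up to 20% divergence align at 0.75 or better, so 0.7
separates the two populations; a 0.6 floor admits several spurious hits per
scan. Distances are edge-to-edge (0 when abutting), hits overlapping the
original span are excluded, and histograms use ten 5-kb bins over 0–50 kb.

## The synthetic study generator

`simConfig()` encodes the study conditions. A planted precursor is
mature(22 nt) + loop(15 nt, drawn from {A,C} so the loop cannot self-pair) +
3P arm, where the 3P arm is the reverse complement of the first 20 mature
bases plus 2 free bases — the canonical duplex with 2-nt 3' overhangs on
both strands. Families are tandem near-copies: non-founders carry i.i.d.
substitutions at 13% per base (the observed divergence mode of duplicate
precursors) and sit at truncated-exponential spacings (mean 7 kb over
0.1–50 kb), which puts the modal edge-to-edge interval below 5 kb. Reads are
drawn from the arms at a 4:1 5P:3P ratio with exact 5' ends at probability
0.9 (else off by 1–2 nt) and exact 3' ends at 0.5 (else off by 1–3 nt) —
a quantification of "precise 5', imprecise 3'" processing; a 3' adapter is
appended and qualities are constant Q30. Libraries also contain
`backgroundFraction` random genome fragments of 18–30 nt and ~40 stacked
degradation-like reads at each of `nDecoys` non-hairpin loci; the decoys
are what make the false-positive tests meaningful. The sister genome applies
i.i.d. substitutions at 1% per base and records every hit to a mature span
as variant truth. Knockdown tables scale miRNA rows by `2^x`,
`x ~ N(−1.04, 0.3)`, non-miRNA rows by `2^y`, `y ~ N(0, 0.3)`, with Poisson
resampling. Tissue profiles draw a shared Gamma–Poisson count per miRNA and
multiply the flagged tissue of tissue-specific rows by 30 (comfortably above
the 20-fold definition of a planted specific row).

What passing the synthetic tests shows: the pipeline recovers its own
planted parameters — discovery sensitivity and precision at least 0.9 at the
S/N-chosen cutoff with at most ~1 false call per signal-free library,
end-precision means within 0.05, the knockdown class means within the stated
band, 100% family-cluster and flank-scan recovery with distances to ±1 bp.
What it does not show: behaviour on real repeat landscapes (background is
i.i.d. uniform; transposon-derived multimapping is only modelled through the
max-hits rule), sequencing error (substitution-free reads), isomiR biology
beyond uniform end jitter, or thermodynamic folding accuracy (the energy
model ranks, it does not predict ΔG).

## Problem sizes and determinism

All stochastic steps are seeded; a fixed `SimConfig` reproduces byte-identical
FASTA/FASTQ/TSV outputs, and the pipeline fans a global seed out to stages by
stable string hashing, so any stage can be re-run in isolation. The shipped
validation uses 60 planted precursors (15 conserved) in 8 families on four
60-kb scaffolds with 20,000-read libraries; signal-free calibration uses 50
single-scaffold libraries of 1,200 reads with 6 decoy stacks; duplication
recovery uses families of three at 13% divergence on 22-kb scaffolds. These
sizes give stable statistics while keeping the full suite comfortably
runnable on a laptop core.

## Known limitations

* The Nussinov-weight energies are rank statistics, not free energies; the
  published MFE values of real precursors are not reproduction targets.
* The signal-to-noise ratio is unstable where the permutation tail count is
  near zero (0/0 is reported as infinity, per definition); the two-arm call
  requirement, not the S/N alone, controls one-sided degradation stacks.
* The exact conditional tissue test assumes independent sampling per tissue;
  overdispersion beyond the planted Gamma–Poisson would inflate calls, and
  the fold-change floor is the practical guard.
* Mature variant calling is substitution-only (no indels), matching the
  ungapped cross-species alignment model.
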