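# mirburst

Evidence-based microRNA discovery and evolution analysis from small-RNA read
stacks, for genomes where miRNA catalogues are built from sequencing evidence
rather than curated annotation — large insect genomes with rich
lineage-specific miRNA repertoires and locally duplicated precursor families
are the motivating case. The package covers the full analysis arc:

* **Discovery** — QC/adapter-trim/collapse small-RNA reads, map them to
  genome scaffolds, excise candidate hairpins around read stacks, score them
  with read-position, duplex-geometry and folding-stability evidence, and
  pick the score cutoff by permutation signal-to-noise calibration.
* **Authenticity** — hairpin stability against dinucleotide-shuffle null
  models, 5'/3' processing precision, and the transcriptome-wide response to
  a biogenesis (Drosha) knockdown by RNA class.
* **Evolution** — conserved vs lineage-specific classification by seed-region
  homology, cross-species detection with mismatch-tolerant alignment,
  end-trimmed mature variant calling, and contingency statistics.
* **Expression** — TPM quantification and one-vs-aggregate tissue-specificity
  calls with an exact conditional test.
* **Duplication** — all-vs-all precursor similarity with Karlin–Altschul
  E-values (`E = K·m·n·e^{−λS}`), family clustering and consensus, and
  query-global/target-local ("glocal") scans of ±50 kb genomic flanks with
  5-kb distance binning.
* **Synthetic studies** — a generator that plants hairpin precursors
  (22-nt matures, 4:1 5P:3P arm ratio, precise 5' / imprecise 3' ends),
  tandem duplicate families at controlled divergence and spacing, decoy
  degradation stacks, a mutated sister-species genome, tissue-biased
  profiles, and knockdown count tables — all with recorded ground truth, so
  every stage above is validated by parameter recovery.

The scoring core combines, per candidate,
`S = log2((n_c+1)/(n_i+1)) + S_duplex + (−z)`: consistent 5'-end read
evidence, ±2 for presence/absence of the 2-nt 3' overhang duplex geometry,
and the folding z-score against dinucleotide-preserving shuffles. Calls
require the cutoff chosen at signal-to-noise ≥ 10 over 100 read-position
permutations. The models and all numerical choices are documented in
`vignettes/mirburst-methods.Rmd`.

## Worked example

```r
library(mirburst)

cfg <- simConfig(seed = 7, nScaffolds = 2L, scaffoldLength = 20000L,
                 nMirnas = 12L, nFamilies = 2L, nConserved = 4L,
                 familySpacingMean = 3000, familySpacingRange = c(100, 8000),
                 readsPerLibrary = 6000L, nDecoys = 5L, nTissueSpecific = 3L)
res <- runPipeline("demo_out", config = cfg, n_perm = 50, n_shuffles = 50)
round(res$summary, 4)
```

```
           n_reads               n_qc        n_collapsed            n_calls
         6000.0000          5987.0000           240.0000            30.0000
       sensitivity          precision          sn_cutoff  mean_mirna_log2fc
            0.9167             1.0000             4.5000            -0.9862
 n_detected_sister   n_variant_mirnas n_similarity_pairs n_duplication_hits
           12.0000             2.0000             9.0000            20.0000
```

Reading the numbers: 6,000 simulated reads pass QC almost completely (the
13 losses are length failures after adapter trimming) and collapse to 240
unique sequences; discovery calls 30 loci that recover 11 of the 12 planted
precursors (sensitivity 0.917) with no false positives (precision 1) at the
signal-to-noise-chosen cutoff of 4.5. The knockdown simulation planted a
−1.04 mean log2 fold change on miRNA rows and the analysis recovers −0.99.
All 12 precursors are detected in the mutated sister species; the two
planted families produce 9 significant precursor pairs and 20 flank-scan
duplication hits. `demo_out/` holds the genome FASTA, read FASTQ, truth
table, GFF3 calls and per-stage TSV tables.

At the validation scale used by the test suite (60 planted precursors, 12
decoy stacks, 20,000 reads on four 60-kb scaffolds), discovery reaches
sensitivity 0.90 and precision 1.0, with a mean of about 0.35 false calls per
signal-free library.

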