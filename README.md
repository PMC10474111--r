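# iibprofiler

Species identification and taxonomic-abundance estimation from
whole-metagenome shotgun (WMS) reads using in-silico extracted Type IIB
restriction fragments ("2b tags").

## The problem and the method

Reference-based metagenomic profilers trade precision against recall:
whole-genome (DNA-to-DNA) methods report many false-positive species because
conserved and low-complexity regions cross-map, while universal-marker
methods miss species whose markers are absent or under-sequenced — and false
positives are *not* reliably low-abundance, so no abundance threshold fixes
this. `iibprofiler` implements a marker strategy built on Type IIB
restriction enzymes, which excise fixed-length fragments at every
recognition site. Digesting all reference genomes in silico yields, per
species *i*, its total tag count *H<sub>i</sub>* and a set of
*E<sub>i</sub>* **species-specific tags**: single-copy within the species'
genomes and absent from every other species. Sample reads are digested the
same way and matched exactly against this index.

Profiling is done in two rounds:

1. **Qualitative.** For each candidate species with *Q* matched tag
   instances over *U* distinct tags, compute genome coverage *C = U/E*,
   inferred sequenced tags *Q̃ = Q/C*, taxonomic count *N = Q/U*, sequence
   count *R<sub>seq</sub> = Q̃/R* (*R* = total reads) and G-score
   *G = √(QU)*. A random forest on the log features removes false-positive
   candidates: a present species spreads evidence across its whole marker
   set (high *C*, *N* near the per-marker coverage), a spurious one
   saturates a small shared subset (low *C*, inflated *N*).
2. **Quantitative.** The marker database is rebuilt restricted to the
   identified species — dropping competitors can only enlarge each species'
   specific-tag set (*E′ ≥ E*) — and the sample is re-matched. The
   taxonomic abundance (cell fraction) is
   *T<sub>i</sub> = (Q<sub>i</sub>/H<sub>i</sub>) / Σ<sub>j</sub>
   (Q<sub>j</sub>/H<sub>j</sub>)*, with second-round coverage
   *O<sub>i</sub> = U<sub>i</sub>/E′<sub>i</sub>*.

The package also ships a ground-truth WMS simulator (random genomes,
log-normal communities with dual taxonomic/sequence-abundance truth, genome
divergence, read errors, mosaic out-of-database species for classifier
training) and the evaluation metrics (precision/recall/F1, L2 and
Bray-Curtis similarity), so the entire method is testable without any
external downloads.

## Worked example

```r
library(iibprofiler)

u  <- build_toy_universe(n_species = 20, genome_length = 1e5, seed = 5)
tr <- train_default_model(u, seed = 9000)

truth <- sample_composition(u$genomes, 10, seed = 77)
sim   <- simulate_reads(truth, u$genomes, sim_config(depth = 200000, seed = 77))
res   <- profile_sample(sim$reads, u$db, tr$model)

res$profile[, .(species_id, T, O, Q2, U2, E2, prob)]
#>     species_id          T         O     Q2    U2    E2  prob
#>  1:      sp011 0.26354746 1.0000000 130246  3108  3108     1
#>  2:      sp019 0.19216455 1.0000000  94785  3102  3102     1
#>  3:      sp001 0.13015312 1.0000000  66640  3220  3220     1
#>  4:      sp012 0.10221039 1.0000000  49180  3026  3026     1
#>  5:      sp016 0.08915887 0.9993707  45055  3176  3178     1
#>  6:      sp014 0.07396426 1.0000000  39082  3323  3323     1
#>  7:      sp007 0.05695374 1.0000000  28192  3113  3113     1
#>  8:      sp004 0.03597011 0.9968424  18114  3157  3167     1
#>  9:      sp018 0.03307588 0.9903697  16930  3188  3219     1
#> 10:      sp005 0.02280163 0.9792947  11207  3027  3091     1

evaluate_run(res$profile, truth)
#>    precision recall    f1 l2_similarity bc_similarity  n_tp  n_fp  n_fn
#> 1:         1      1     1     0.9981699     0.9976203    10     0     0
```

All ten community members are identified (no false positives, classifier
probability 1), `T` sums to 1 and tracks the simulated taxonomic abundances
to the third decimal (e.g. 0.2635 vs. a true 0.2639 for the most abundant
species), and the second-round coverage `O` is near 1 at this depth.
`res$features` additionally records the first-round counts, the four
features and the keep decision for every candidate, for auditing.

A thin CLI wraps the same functions
(`digest`, `build-db`, `simulate`, `train-fp`, `profile`, `evaluate`,
`benchmark`, `mock`):

```sh
Rscript $(Rscript -e 'cat(system.file("exec", "iibprofiler", package = "iibprofiler"))') \
  profile --reads sample.fastq --db db/ --model fp.model --out profile.tsv
```

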