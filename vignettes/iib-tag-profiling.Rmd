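---
title: "Taxonomic profiling from Type IIB restriction tags: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomic profiling from Type IIB restriction tags: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The profiling model

Type IIB restriction enzymes cleave DNA at fixed offsets on both sides of a
(usually degenerate) recognition site, excising iso-length fragments. Because
the fragments have fixed length and fixed position relative to each site, the
complete fragment set of any genome — and of any sequencing read long enough
to contain a full fragment window — can be enumerated *in silico*. We call
these fragments 2b tags. `iibprofiler` uses them as exact-match markers for
species identification and abundance estimation in whole-metagenome shotgun
(WMS) data.

**Database.** Every genome in a reference collection is digested in silico
under one enzyme. For species $i$, $H_i$ is the total number of tag
occurrences over its genome(s). A canonical tag (the lexicographic minimum of
the window and its reverse complement, making matching strand-insensitive) is
*species-specific* when it (a) occurs in at least one genome of species $i$,
(b) occurs in no genome of any other species, and (c) is single-copy within
each conspecific genome where it occurs. The $E_i$ species-specific tags are
indexed for exact lookup. Because specificity is computed per genome against
all other species, it is unaffected by strain-level variation within a
species, and specificity at higher ranks could be derived the same way (the
builder exposes species rank only).

**First round (qualitative).** Sample reads are digested; the canonical tag
counts are matched against the index. For every candidate species with at
least one matched specific tag we compute, with $Q_i$ matched specific-tag
instances, $U_i$ distinct matched tags and $R$ total reads:

$$C_i = U_i/E_i, \qquad \tilde{Q}_i = Q_i/C_i, \qquad
  N_i = \tilde{Q}_i/E_i = Q_i/U_i, \qquad
  R_i = \tilde{Q}_i/R, \qquad G_i = \sqrt{Q_i U_i}.$$

$C_i$ is the fraction of the species' markers seen at all (genome coverage);
$N_i$ estimates the mean copy number of a sequenced marker (taxonomic count);
$R_i$ rescales it per read (sequence count); $G_i$ is high only when both
volume and breadth of evidence are high. A genuinely present species
accumulates markers *across its whole genome*, so $C_i$ grows with depth
while $N_i$ stays near the per-marker coverage. A false positive — reads from
a related or absent organism hitting the shared fraction of a species'
markers — saturates a small marker subset: $C_i$ stalls low while $N_i$
inflates. No single abundance threshold can separate the two (false positives
are not necessarily rare), which is why the four features together, log
transformed, are passed to a classifier.

**False-positive elimination.** A random forest (500 trees, `mtry = 2`,
inverse-class weighting, fixed seed) is trained on candidates labeled against
simulation ground truth and applied at a probability threshold of 0.5. The
natural log is used for the log transform; tree splits are invariant to the
base, so the choice is conventional only. No min–max scaling is applied
before classification.

**Second round (quantitative).** The database is rebuilt restricted to the
identified species. Shrinking the comparison universe can only release tags
that were shared with dropped species, so each retained species' marker set
can only grow ($E'_i \ge E_i$ — in practice roughly doubling in the original
large-database setting). Matching the sample again against this
sample-specific index gives $Q_i$ and $U_i$ over the enlarged marker sets,
from which the taxonomic abundance (cell fraction) and second-round coverage
are

$$T_i = \frac{Q_i/H_i}{\sum_j Q_j/H_j}, \qquad O_i = U_i/E'_i.$$

Normalizing matched counts by $H_i$, a genome-size-like quantity, converts
DNA fractions into cell fractions; $H_i$ counts occurrences (not distinct
tags) by default, with a `distinct` switch on the builder. An optional
coverage-corrected variant divides $Q_i$ by $O_i$ before normalizing; the
plain form is the default.

## The synthetic universe: what it emulates and what it does not

All tests and benchmarks run on a self-contained synthetic universe, so no
genome downloads are required.

* **Genomes** are i.i.d. random sequences (default 100 kb, GC 0.5), one per
  species. They emulate the *combinatorial* properties of real genomes (tag
  density, marker uniqueness at 20-bp scale) but none of their phylogenetic
  structure: two random genomes share essentially no 20-mers
  ($\sim 4^{-20}$ collisions), so cross-species marker collisions are absent
  by construction.
* **The enzyme** is a designed geometry, `SynB1`: recognition `CNRYNNNC`
  (three fixed-base equivalents), 6-bp flanks, 20-bp tags. This yields about
  3,100 sites per 100-kb genome — a scaled-down analogue of the thousands of
  unique tags per species a real Type IIB enzyme produces on bacterial
  genomes. The recognition was chosen so that its two orientations are
  mutually incompatible (position 1 requires C on one strand, G on the
  other): a pattern whose forward and reverse-complement orientations can
  match at the same position would emit the same physical window twice, and
  the single-copy rule would then discard those loci from $E_i$ at random
  rates per species, distorting the $E_i/H_i$ ratio that abundance
  estimation relies on. Real-enzyme descriptors (CjePI, BcgI) ship as config
  data, but no test depends on their transcription.
* **Compositions** are normalized log-normal draws (meanlog 0, sdlog 1),
  carrying dual ground truth: taxonomic abundance $T^*$ and sequence
  abundance $S^* \propto T^* L$ (interconvertible via genome length, exact
  to 1e-9).
* **Reads** (default 100 bp single-end, error rate 0.001) are uniform
  positions and strands with independent per-base substitution errors;
  paired mode draws mates from fragment ends. Indels and quality-score
  structure are not modeled: exact-match tag lookup makes substitutions the
  binding error mode, and an indel would simply destroy a window like
  several substitutions would. Genome-wide divergence between the sampled
  strain and the database genome is modeled as per-base substitution at rate
  $r$ applied before read sampling (the 1–3% range used in robustness
  checks).
* **Out-of-database ("novel") species** are mosaic genomes: a random
  backbone carrying three ~2%-length segments copied from randomly chosen
  database genomes at 1% divergence. This is the one feature of real data
  that pure random genomes cannot produce and that the method's classifier
  exists to handle: reads from a mosaic species hit the donor's markers
  inside the shared segments only, producing genuine false-positive
  candidates (low $C$, saturating $N$). Training communities include three
  such species; evaluation grids (which measure the headline accuracy) use
  database species only, mirroring the benchmark design the method was
  originally validated with. Passing benchmarks here therefore demonstrates
  the machinery end to end at desk scale; it does not certify performance on
  real communities, where marker sharing is pervasive and graded rather than
  confined to discrete segments.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand; windows that
  would extend past a sequence end are dropped, as is any window containing
  a non-ACGT base (no IUPAC expansion — expansion would inflate $E_i$ and
  make the database depend on ambiguity conventions). Overlapping sites each
  emit a tag: in-silico digestion enumerates theoretical fragments, not a
  single-pass physical cut.
* Candidates enter the first round with $U_i \ge 1$; deliberately, no
  abundance floor is applied anywhere — separating true from false
  positives is the classifier's job, not a threshold's.
* Read pairs are digested as two independent reads and $R$ counts mates
  separately (the convention matters only through $R_i$'s scale, which the
  forest absorbs).
* Tag-count aggregation joins on exact canonical tags; ties in the final
  profile ordering are broken by species id for byte-stable output.
* The sample-specific rebuild reuses the per-genome tag tables cached at
  build time; digestion is deterministic, so this is exactly equivalent to
  re-digesting the genome FASTA and avoids keeping sequences around.
* Zero identified species yields an empty profile and a warning rather than
  an error; depth-0 simulations are valid degenerate inputs throughout.
* All randomness flows through explicit integer seeds; child streams are
  derived arithmetically (not from the global RNG state), so every artifact
  — genomes, communities, reads, forest, reports — is byte-reproducible
  from its seed.

## Benchmark problem sizes

The shipped benchmarks use a universe of 100 species × 100 kb; a main grid
of richness {10, 20, 50} × depth {50k, 200k, 500k} reads × 3 replicates; a
divergence grid at $r = 3\%$, depth 500k, richness {10, 20, 50} × 3
replicates; and a 20-species equal-abundance mock at depth 500k. The
classifier trains on a disjoint-seed grid of richness {10, 50} × depth
{50k, 200k} × divergence {0, 2%} with three mosaic species per community.
These sizes keep a full run on a single CPU in the tens of minutes while
leaving every per-species statistic (thousands of markers, hundreds to
thousands of reads per community member) in a regime where the method's
asymptotics are visible.

## Known limitations

* Random genomes make cross-species identification artificially easy;
  precision on the evaluation grid is near 1 by construction, and the
  discriminative burden falls on the mosaic-trained classifier.
* Held-out-genome experiments (species absent from the database) are
  supported as negative controls only: an unrelated random held-out genome
  matches nothing, which exercises the empty-profile path but cannot
  reproduce relatedness-driven recall numbers from real genome collections.
* Single-enzyme digestion only; enzyme combinations, partial digestion,
  methylation sensitivity and star activity are out of scope.
* Species rank only in the profiler; higher-rank profiles can be obtained
  by summing $T_i$ downstream.

## A worked example

```{r}
library(iibprofiler)

u <- build_toy_universe(n_species = 20, genome_length = 1e5, seed = 5)
tr <- train_default_model(u, seed = 9000)

truth <- sample_composition(u$genomes, 10, seed = 77)
sim <- simulate_reads(truth, u$genomes, sim_config(depth = 200000, seed = 77))
res <- profile_sample(sim$reads, u$db, tr$model)

res$profile     # species_id, lineage, T, O, Q2, U2, E2, prob
evaluate_run(res$profile, truth)
```

The features table (`res$features`) records, for every first-round
candidate, the raw counts, the four features, the classifier probability and
the keep decision, so any identification can be audited after the fact.
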