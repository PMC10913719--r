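---
title: "Profiling low-biomass metatranscriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling low-biomass metatranscriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxbench)
```

## The problem

Shotgun RNA sequencing of human tissue recovers a community transcriptome
in which host RNA dominates: in mucosal specimens well over 95 % of reads
can be host-derived, leaving only a sliver of sequencing capacity for the
microbiome. Classifiers tuned on microbe-rich samples (stool, environmental
communities) behave very differently in this regime — marker-gene methods
lose sensitivity because too few reads land on their small marker panels,
while whole-genome k-mer methods retain recall but need a confidence
threshold to control false positives.

`mtxbench` makes this regime reproducible at desk scale. It simulates a
defined bacterial community spiked with host material under full ground
truth, reimplements each computational stage of a low-biomass profiling
workflow as an isolated, testable function, and scores the results against
the truth. Everything is seeded; nothing is downloaded.

## The synthetic universe

`build_toy_reference()` creates the closed world reads are simulated from
and classified against:

* **20 species across 18 genera** (configurable), mirroring an even-cell
  mock community standard; two genera hold congeneric pairs.
* **Genomes** are i.i.d. random DNA (default 20 kb). Congeneric species
  additionally share one identical block (default `2k = 62` bp) placed
  inside a transcribed gene of both species, so a subset of k-mers resolves
  only to genus rank and the LCA machinery is genuinely exercised.
* **Transcript pools**: each species carries pangenome genes (default 12,
  600–1200 bp, non-overlapping substrings of its genome), each with a
  gene-family id and a stored frame-1 peptide translation (a stand-in for a
  UniRef-style protein database). Reads are drawn from genes, not naked
  genome, because a transcriptome only ever shows transcribed sequence.
* **Host transcriptome, rRNA and viral references** as independent random
  pools; **optional contaminant species** that exist in the classifier
  database but not in the community.

Because the toy genomes are random, cross-species k-mer collisions are
essentially absent outside the designed shared blocks. Real genomes share
far more sequence; the fixture therefore measures mechanism (thresholds,
redistribution, tier routing), not database-scale ambiguity. Passing tests
show the machinery implements its contracts — they do not certify accuracy
on real data.

## Mixing models

Two sample designs are supported, matching the two ways host background can
be titrated:

**Cell-ratio mixtures** (`simulate_sample()`): a fraction `f` of *cells* is
host. The library samples transcripts, so the expected host *read* share is

$$\frac{f\,h}{f\,h + (1-f)\sum_s c_s a_s},$$

with `h` the host transcripts-per-cell weight (default 20), and `c_s`,
`a_s` each species' cell fraction and transcriptional activity. The
default `h = 20` was chosen once so that a 97 %-host-cell sample yields
roughly 99.8 % host reads — the regime where a 100 M-read tissue library
collapses to a few hundred thousand microbial reads after depletion. No
per-cell transcript counts are published for this design; `h` is a free
parameter, stated here as such, and is deliberately not tuned per
experiment. Setting a species' activity to 0 makes it transcriptionally
silent: it contributes zero reads at every seed, emulating a community
member whose transcripts are absent from the library. Small rRNA (2 %) and
viral (0.5 %) nuisance fractions are taken off the top of the depth.

**Read-fraction mixtures** (`mix_reads()`): reads are drawn *without
replacement* from a pure-microbial and a pure-host pool and combined to an
exact host read fraction at fixed depth (subsampling semantics of the
usual FASTQ subsampling tools). Replicates use distinct integer seeds.

Reads get independent per-base substitution errors (default 0.5 %; no
indels — sufficient to stress exact k-mer matching) and Phred+33 qualities
in which a configurable fraction of reads (default 10 %) carries a sub-Q20
3' tail so that quality trimming has something to do.

**Contaminants** (`inject_contaminants()`) follow a constant-mass model:
expected contaminant reads per sample are `load / concentration`, Poisson
distributed, so contaminant *frequency* is inversely related to sample
concentration — the signature frequency-mode decontamination looks for.

## Pre-processing

`quality_trim()` scans 4-base windows left to right and truncates at the
start of the first window whose mean quality drops below Q20; reads losing
more than half their length are discarded. (Where exactly to cut within a
failing window is tool-internal lore; we fix "window start" and document
it.) `deplete_by_reference()` removes a read when at least half of its
k-mers (default k = 31) occur in the reference k-mer set — an
alignment-free stand-in for mapping-based host/virus/rRNA removal, applied
in the fixed order host → virus → rRNA so per-stage counts are
well-defined. The containment filter is leakier than a real aligner: a
read with two well-spaced errors can fall below 50 % containment and
survive. Such survivors stay unclassified downstream (the host is not in
the bacterial index) but do inflate the unmapped fraction of the
functional profile, which is worth remembering when reading tier totals.

## Taxonomic profiling

**k-mer LCA classification** (`build_kmer_index()`, `classify_reads()`).
Every canonical k-mer of every genome is stored with the LCA of its source
species. For a read with `V` valid k-mers, hits are collected per taxon;
the candidate maximizes summed hits along its root-to-node path (ties:
deepest node, then lowest taxonomy-table index — determinism matters more
than the particular choice). The confidence of taxon `t` is the fraction
of the read's k-mers hitting anywhere in the clade rooted at `t`; if the
candidate falls below the threshold the assignment ascends, re-testing at
each ancestor (rather than jumping straight to root), and a read whose
root confidence still fails is unclassified. At threshold 0 any read with
a single hit is classified; at 1 only reads fully contained in one clade
are.

**Species reestimation** (`reestimate_species()`): counts on internal
nodes are redistributed to descendant species proportionally to the
species' direct counts, falling back to per-species distinct-k-mer totals
when no descendant has direct counts. This is a deliberate simplification
of Bayesian abundance reestimation — proportional reallocation captures
the mechanism (internal counts must end up at species rank, weighted by
evidence) without a per-read probabilistic model. Total counts are
conserved exactly.

**Marker profiling** (`build_marker_db()`, `profile_markers()`): markers
are windows (default 10 × 150 bp per species) drawn from transcribed
regions and verified unique against every other genome (both strands), so
windows overlapping congeneric shared blocks are rejected. A read hits a
marker by the same ≥ 50 % containment rule; coverage is
`hits × read_len / marker_len`; a species is called at `g_min` or more hit
markers (default 3), and its abundance is the robust average — sort the
marker coverages, drop `floor(stat_q · n)` values at each end (default
`stat_q = 0.2`), average the rest. One profiler intentionally carries both
tuning knobs (`stat_q`, `g_min`) so their effects can be compared within a
single implementation. Markers occupy ~7 % of each transcript pool, which
is why the profiler's sensitivity collapses as host fraction rises while
the k-mer classifier, which can use every microbial read, keeps recall —
the central contrast the workbench is designed to reproduce.

## Decontamination

`score_frequency()` fits, per taxon, log frequency against log
concentration under two fixed-slope models: slope −1 with free intercept
(contaminant: constant mass diluted by the sample) and slope 0 (real
community member). The score is
`pf(RSS_0 / RSS_-1, n-1, n-1, lower.tail = FALSE)`: 0 for a perfect
inverse fit, 1 for a perfect constant. The flagging threshold defaults to
0.1 — the conventional default of this method family, chosen here as a
package default rather than a published value. Zero frequencies are
excluded from the fit rather than pseudo-counted; taxa with fewer than 4
usable samples are retained and flagged `"insufficient data"`.
`clean_profile()` removes flagged and unclassified-named taxa, never
touches protected taxa (e.g. the known community, or a pathogen expected
in the tissue), and renormalizes. Cleaning is idempotent.

## Functional profiling

The tiered design follows taxonomy-guided functional profilers:
`prescreen()` keeps species at relative abundance ≥ 0.001 (applied to the
*cleaned* profile — the threshold is about trusting the taxonomic call, so
it should see post-decontamination abundances); `nucleotide_search()`
assigns reads to pangenome genes of prescreened species by best k-mer
containment (ties: longest gene, then gene id), then drops genes whose
covered position fraction is below 25 % (covered = union of assigned-read
intervals, computed with IRanges) and reroutes their reads;
`translated_search()` translates leftovers in six frames, splits at stop
codons, and assigns to the gene family sharing the most peptide 7-mers
(minimum one), reported under the community-level contributor
`"unclassified"`. Peptide k = 7 rather than a shorter k: against this
database size, 5-mers match random reads at chance level ~30 % and 6-mers
at ~15 %, which would fill the translated tier with host noise, whereas
true reads share ~25 consecutive 7-mers through their frame-aligned
peptide run. `quantify()` reports RPK (translated families use the median
source-gene length) and CPM summing to 10⁶, with per-tier totals and the
unmapped count as attributes; reads are conserved exactly across
nucleotide + translated + unmapped.

## Evaluation

`score_profile()` works on presence/absence only (detected ⇔ relative
abundance > 0), because an even-cell community does not imply even
transcript abundances; precision is defined as 0 when nothing is detected
so F1 is always computable. Profiles are scored after cleaning.
`aggregate_to_genus()` conserves abundance exactly; the 20-species mock
collapses to 18 genera. `profile_correlation()` uses Spearman with
average-rank ties over the union of detected taxa (all-zero taxa dropped;
a constant profile yields `NA`, not a number). `trend_vs_host_fraction()`
summarizes a metric's monotonicity across the host-fraction series.

## Problem sizes and determinism

The shipped checks run the full pipeline on the 20-species universe at
depths of 2×10⁵ (pure mock) and 5×10⁵ reads (host-fraction series at
90–100 % host), three replicates each, which completes in a couple of
minutes on a single CPU; unit tests use an 8 kb-genome universe and
hand-built 3–5 species trees small enough for brute-force oracles
(exhaustive path-score enumeration, substring containment, position-set
unions). All generators and pipelines are deterministic given their seed;
k-mer indexes are in-memory external pointers and must be rebuilt per
session rather than serialized.

## Known limitations

* Random-sequence genomes understate database ambiguity; false-positive
  rates here are structurally lower than on real references.
* The depletion filter is containment-based; its error tolerance differs
  from a gapped aligner's, and residual host reads inflate unmapped
  counts at high host fractions.
* No paired-end reads, indels, rRNA-depletion chemistry, PCR bias, or
  mapping-quality modeling; prevalence-mode decontamination and
  pathway-level functional regrouping are out of scope.
* Reestimation is proportional, not a per-read Bayesian model; with the
  default read length (100 bp) exceeding the shared-block length (62 bp),
  pipeline runs place few reads at internal nodes, so redistribution
  mostly matters for shorter reads or larger shared regions.
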