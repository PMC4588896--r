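---
title: "Deconvoluting mutually exclusive exons from noisy long reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting mutually exclusive exons from noisy long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonweaver)
```

## The problem

Some genes diversify their products through *mutually exclusive exon
clusters*: groups of homologous alternative exons of which exactly one is
spliced into each mature mRNA. The extreme case is Drosophila *Dscam1*,
whose exon 4, 6, and 9 clusters hold 12, 48, and 33 variants — 19,008
possible combinations over the exon 3–10 region alone, and 38,016 with the
two exon 17 variants included. Because the clusters sit far apart on the
mRNA and the variants within a cluster can be up to ~80% identical to one
another, establishing *exon connectivity* — which variant of cluster 4
travels with which variant of clusters 6 and 9 on one molecule — requires
a full-length, single-molecule readout. Long-read amplicon sequencing
provides it, at the price of a high per-base error rate and a PCR artifact
(template switching) that fabricates exactly the kind of novel exon
combinations the experiment is designed to detect.

`exonweaver` implements the full analysis path for this design: per-cluster
exon assignment by exact local alignment, reconciliation of the
template/complement/2D read classes of each sequenced molecule, isoform
calling and tabulation, spike-in–based template-switch quantification,
richness estimation by subsampling and capture–recapture, and short-read
cross-validation of per-cluster variant frequencies. A synthetic-data
generator reproduces the statistical structure of such an experiment so
every stage is testable without any external data.

## Gene models and the isoform space

A `gene_model()` is an ordered alternation of constitutive segments and
exon clusters, beginning and ending with a constitutive segment. Variant
identifiers follow the `"<cluster>.<index>"` convention, so an isoform is
the comma-joined tuple of its per-cluster variants (`"4.2,6.32,9.31"`).
The isoform space is the product of per-cluster variant counts;
`enumerate_isoforms()` yields it in lexicographic cluster order and
`isoform_space_size()` gives counts directly, with `allowed`/`exclude`
subsetting (e.g. dropping a variant never observed in a tissue).
Coordinates are 0-based half-open throughout; ambiguity codes are rejected
at load time because the scoring scheme is defined on `{A, C, G, T}` only.

## Alignment: an exact scorer behind a seeded aligner's contract

All assignment decisions rest on local alignment scores under a seeded
aligner's default amplicon contract: match +1, mismatch −1, and affine
gaps costing `open + extend × length` with open = extend = 1 (a gap of
length 1 costs 2), both strands searched, base qualities ignored. Rather
than reproduce a heuristic seeded search, `align_local()` computes the
exact optimum by Smith–Waterman/Gotoh dynamic programming: at the few-kb
scale of amplicon reads exact DP is affordable, and every decision
downstream depends only on the score. The batch kernel used by read
assignment vectorizes eight equal-length queries across SSE2 integer
lanes, which is what makes exact DP practical at tens of millions of
read-by-variant comparisons.

Determinism is part of the contract: among equal-scoring alignments the
reported one has the smallest query start, then smallest target start,
then fewest columns. Percent identity is identical columns over all
aligned columns, gaps included in the denominator. Reverse-strand hits
report target intervals in forward coordinates.

Correctness is checked two independent ways: against exhaustive
maximization over all monotone chains of aligned column pairs (an
enumeration of the full local-alignment space, tractable for short
strings and sharing no affine-state machinery with the DP), and against
`Biostrings::pairwiseAlignment()` on longer random pairs.

## Per-cluster assignment and read-level status

`assign_reads()` aligns every read to every variant of every cluster and
keeps the top-scoring variant per cluster with its *margin* (best minus
second-best score). Two thresholds govern acceptance, both exposed as
configuration because the original protocol states no explicit values:

* `min_score = 50` — a floor below which a cluster has no hit. Random
  ~1 kb sequence against a ~130 bp variant scores far below 50 under ±1
  scoring (empirically ~15–25), while a true variant occurrence at even
  10% read error scores near 0.75 × variant length, so the floor
  separates noise from signal with a wide dead band.
* `min_margin = 1` — "uniquely or preferentially aligned" is read
  strictly: an exact score tie (margin 0) between two variants is flagged
  ambiguous and the read cannot support a call through that cluster.

A read is *full-length* when every cluster has a hit and all best hits
fall on one strand. The strand-concordance requirement is our own
tightening: a single cDNA molecule has one orientation, so strand-mixed
assignments indicate a chimeric or corrupt read.

## Molecule-level calling

A nanopore event can yield up to three reads of one molecule: template
and complement strand reads (1D) and, when the two strands are linked, a
higher-accuracy 2D consensus. `call_isoforms()` works per molecule so one
pore event is never counted twice, with 2D precedence: a usable 2D read
determines the call (`accepted_2d`); otherwise a usable, fully agreeing
template/complement pair is accepted (`accepted_1d_pair`); otherwise the
molecule is rejected with a typed reason (lone 1D read, discordant pair,
partial, or unaligned). The 2D-over-pair precedence reflects that strand
pairs carry independent errors and are only trustworthy when they agree,
while the 2D consensus already integrates both strands; consulting the
pair only in the absence of a 2D call also matches how the read-class
usage counts of such experiments decompose.

`tabulate_isoforms()` counts accepted calls per isoform and tracks the
singleton/multiple split; `cluster_marginals()` and
`cumulative_isoform_distribution()` derive the per-cluster variant
frequencies and the rank-ordered cumulative read share.

## Template switching against a spike-in truth set

With a library built from a known pool of isoforms chosen to share no
variant in any cluster, per-cluster assignment is unambiguous, so any
observed isoform outside the pool must be an RT-PCR template-switch
chimera. `classify_isoforms()` labels observed isoforms genuine or
chimeric and reports the chimeric *read* fraction (reads, not distinct
isoforms — the quantity that tracks PCR cycle number).
`infer_parents()` enumerates all ordered truth pairs and inter-cluster
crossover points consistent with a single switch; isoforms with no
single-switch explanation are kept chimeric with parents unresolved.
The crossover is localized only to the constitutive interval between
clusters: base-level breakpoint refinement inside the homologous
constitutive sequence is not meaningful at these error rates and is out
of scope.

## Richness: subsampling and capture–recapture

`subsample_unique_isoforms()`/`saturation_scan()` draw read pools without
replacement and count distinct isoforms — Monte Carlo rarefaction, with
`expected_unique_isoforms()` giving the closed-form expectation through
`vegan::rarefy()` as an independent check.

`capture_recapture()` estimates total richness from two random read
pools, treating isoform presence/absence per pool (species, not
individuals). Both classical estimators are implemented; Chapman's
bias-corrected form `(u1+1)(u2+1)/(m+1) − 1` is the default because it is
defined at zero overlap and less biased at small overlap, while
Lincoln–Petersen `u1·u2/m` errors at `m = 0` with advice to switch. Pools
are drawn disjoint by default, mimicking a split of one read set; an
overlapping-draw mode is available by flag. The 95% interval is a
nonparametric bootstrap over pool redraws (default 200), reported as
`estimate ± 1.96 × sd(redraw estimates)`; the normal-scale form keeps the
point estimate inside its own interval by construction, and a
closed-form Chapman-variance interval is available as `ci = "analytic"`.
Calibration at known richness 500 (uniform abundance, two disjoint pools
of 1,000 reads from a 4,000-read set) puts coverage of the bootstrap
interval at ~92–96% across replicate sets — at or above the nominal goal.
Richer estimators (Chao1, ACE) are deliberately not implemented.

## Short-read cross-validation

`short_read_exon_count()` reproduces the amplicon-counting check:
a short read is considered only if the cluster primer occurs in it with
zero mismatches; the sequence after the primer is aligned against the
leading 51 bp of each variant (whole variant if shorter) under the same
scoring contract as the long-read path — one scoring convention across
the package — and exact best-score ties are discarded.
`compare_frequencies()` returns the squared Pearson correlation of paired
per-variant inclusion frequencies, pooled across clusters by default
(per-cluster values by flag), with missing variants entering at
frequency 0.

## The synthetic-data generator

`sim_config()` fixes the simulated experiment; the defaults are the
package's standing study conditions:

| knob | default | rationale |
|---|---|---|
| cluster sizes | 12 / 48 / 33, named "4"/"6"/"9" | the three-cluster topology of the motivating gene |
| exon lengths | 110–140 bp (one length per cluster) | the scale of real variable exons in such clusters |
| within-cluster identity | 0.80 | the "up to ~80% identical" regime that makes assignment hard |
| constitutive segments | 90 bp each | scaled down from the real amplicon; discriminability is governed by the variable exons, so the constitutive length only sets runtime |
| 2D error (sub, ins, del) | 0.06, 0.02, 0.02 | ~90% read identity, the 2D regime |
| 1D error | 0.09, 0.03, 0.03 | strand reads are distinctly worse than 2D; no published per-class figure, so a 1.5× factor is used and exposed |
| fraction with 2D | 0.43 | the fraction of strand pairs that yield a 2D consensus in such runs |
| truncation probability | 0.05 | occasional incomplete reads; truncated reads keep a random 20–90% window from a random end |
| abundance model | log-normal, sdlog 1.5 | reproduces the singleton-heavy tabulations of real libraries |
| switch rate | 0 | chimeras are opt-in; the 0.2%/1%/32% regimes are simulation settings for the spike-in analyses |

Cluster variants are independently mutated copies of a random cluster
ancestor. For a per-base substitution rate `p` applied to two copies, the
expected pairwise identity is `(1 − p)² + p²/3`; the generator inverts
this for the target (0.80 → p ≈ 0.108) and the realized mean pairwise
alignment identity lands within ±3 points of target (slightly above it,
because local alignment trims divergent ends). Substitution-only
divergence keeps variants within a cluster equal-length — a deliberate
simplification that also feeds the vectorized aligner its best case.

Read errors are i.i.d. per base (substitution/insertion/deletion), not
homopolymer-aware: the analysis depends only on aggregate identity, which
the generator anchors at the documented per-class rates. Template reads
are emitted forward, complement reads reverse-complemented, 2D reads
forward. A `SimLedger` records the truth for every molecule — isoform,
chimera parents and crossover, emitted classes, per-read error counts —
and every pipeline test reduces to comparing calls against the ledger.
Chimeras are always single-crossover, drawn from two distinct pool
isoforms with a uniform inter-cluster crossover; when the pool shares
variants across members a chimera can coincide with a genuine pool
isoform, exactly as in a real library (the shipped six-isoform spike-in
set avoids this by construction).

What the generator does *not* emulate — systematic (non-i.i.d.) error
modes, quality strings, abundance biases tied to specific biological
samples, chimeras with base-level crossover positions inside homologous
sequence — bounds what passing tests show: they validate the method's
logic and its robustness to the documented noise regime, not performance
on any particular wet-lab library.

## Numerical and design choices

* Scores are integers; margins of 0 are exact ties, so `min_margin = 1`
  is equivalent to "strictly preferred".
* Assignment ties are broken by variant order within the cluster (and
  flagged); alignment ties by the coordinate rule above — all outputs are
  deterministic functions of (input, seed).
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical configs give byte-identical FASTA output.
* Degenerate inputs fail loudly: empty allowed sets name the cluster,
  unknown variants name cluster and id, Lincoln–Petersen at `m = 0`
  points to Chapman, empty tables refuse cumulative/rank analyses.
* Problem sizes used by the shipped checks (our own choice of scale):
  recovery and chimera runs simulate 2,000–5,000 molecules against the
  full 93-variant model; capture–recapture calibration uses 100–200
  replicate read sets; the alignment oracle runs 1,000 random pairs of
  length ≤ 8.

## Known limitations

* The aligner is exact but quality-blind; no use is made of FASTQ
  qualities even when present.
* Chimera detection requires a truth set; on biological (non-spike-in)
  libraries the chimeric fraction is not identifiable from isoform
  labels alone.
* Capture–recapture assumes exchangeable reads within the library;
  strong lane- or time-structured sampling would violate it.
* The generator's equal-length variants slightly flatter the aligner
  relative to real clusters, where length differences add further
  discriminating signal — the simulation is, if anything, conservative.
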