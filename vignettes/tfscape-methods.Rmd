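---
title: "Models and methods behind tfscape"
author: "tfscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscape)
```

# The scientific setting

Site-specific transcription factors (TFs) — roughly 5% of the genes in a
fly genome — drive developmental gene expression programs. tfscape
implements a system-level analysis of when and where TFs are expressed
during embryogenesis and adulthood, working from five data modalities
that embryo-scale surveys typically provide:

1. a curated **gene catalog** flagging TFs and their DNA-binding-domain
   (DBD) family;
2. an **in situ annotation matrix**: for each gene, the set of anatomical
   terms annotated at each of six embryonic stage-range windows
   (1-3, 4-6, 7-8, 9-10, 11-12, 13-16), using a *slim* anatomy of ~30
   lineage-level terms including a distinguished `ubiquitous` term;
3. a **time-course matrix** of per-timepoint log-ratios against a pooled
   all-stages reference;
4. a replicate-level **present/absent and up/down call table** over adult
   tissues;
5. **ChIP peak intervals** for two factors at two timepoints.

The package's own contributions are the statistics layered on these
inputs: a total temporal classification of binary stage supports, a
resampling Z score for TF over-representation per tissue and stage (with
an exact hypergeometric oracle), repertoire-overlap Z scores, a
permutation test for co-expression module conservation, and
occupancy-state transition analysis for ChIP co-occupancy. Because the
original survey datasets are moving targets (annotation vocabularies
drift between releases), the package validates itself on synthetic data
with planted, recorded ground truth rather than on snapshots of the real
databases; readers for generic TSV/BED representations of the real
modalities are provided.

# Expression-call rules

Four rules convert raw modality values into binary expressed/not-expressed
decisions (`call_thresholds()` bundles their knobs):

* **Time-course reclassification.** A log-ratio `v` is `low` if
  `v < -0.5`, `high` if `v > 0.5`, else `average`; both inequalities are
  strict, so the boundary values fall into `average`. The cut points come
  from the observation that in situ-positive genes have a median
  per-timepoint value of 0.72 and in situ-negative genes 0.14: 0.5
  separates the two medians with a margin, and no sharper threshold is
  supportable given the spread. Missing values yield an explicit
  `no_call`, never a silent `average`.
* **Replicate voting.** A gene is expressed if at least 2 of 3 (GeneChip
  style) or 3 of 4 (adult-tissue-array style) replicates give a present
  call.
* **Adult-tissue disjunction.** Expressed iff 3-of-4 present **or** an
  `up` call (significant up-regulation against whole-body reference) —
  an `up` call alone suffices.
* **Transfrag coverage.** Expressed iff at least 10% (inclusive) of the
  gene's merged coding region is covered by transcribed fragments. The
  default counts the coverage *union* of all fragments, so splitting a
  fragment into abutting pieces changes nothing; a stricter mode
  requiring a single fragment to reach 10% is available
  (`mode = "single"`). Union is the default because the 10% criterion is
  a statement about the covered portion of the coding region, not about
  any one fragment.

Both rules are monotone: raising the vote requirement or the coverage
threshold can only shrink the expressed set (tested as a property).

# Temporal classification

A gene's *support* is the binary vector of "any annotation at stage
range r" over the six windows. `classify_temporal_class()` maps each of
the 64 possible supports to exactly one of six classes:

| class | definition (`early_cutoff = 3`) |
|---|---|
| `no_expression` | empty support |
| `maternal_continuous` | all six windows |
| `continuous_zygotic` | contiguous run of **≥ 2** windows reaching window 6, not starting at window 1 |
| `early_only` | contiguous prefix from window 1 ending at or before the cutoff |
| `late_only` | contiguous run starting after the cutoff that is not `continuous_zygotic` |
| `diverse` | everything else |

The verbal class descriptions in the survey literature ("early TFs",
"late TFs", "not maternal but continuous", "maternal and continuous") do
not pin down every edge case, so three decisions were needed:

* **"Continuous" means more than one window.** A gene seen only at
  stages 13-16 is a *late* gene, not a "continuously" expressed one, so
  `continuous_zygotic` requires the terminal run to span at least two
  windows; the single-window terminal support classifies as `late_only`.
* **Gapped supports are `diverse`.** Whether an "early" gene may skip a
  window (expressed at ranges 1 and 3 but not 2) is unstated; we require
  contiguity everywhere, which is the simplest total rule.
* **`early_cutoff` is a knob** (default 3, i.e. stage range 7-8), since
  the early/late boundary is a convention, not a biological constant.

Exhaustive enumeration over all 64 supports (a unit test and an
acceptance check) confirms the six classes partition the support space,
with a census of 1/3/4/4/1/51 supports per class in the order of the
table above.

`maternal_fraction()` reports the share of TFs expressed at stage range
1-3 among all TFs in the annotation universe — transcripts present
before zygotic genome activation are maternally deposited. The
denominator deliberately includes annotated-but-never-detected TFs,
matching how such fractions are quoted for in situ databases.

# Tissue enrichment: resampling Z with an exact oracle

For each (stage range, slim term) cell, let `n` and `m` be the
non-redundant counts of expressed TFs and non-TFs. The resampling test
draws `n + m` genes without replacement from the universe, counts TFs,
repeats (default 10,000 iterations), and standardizes the observed `n`:
`z = (n - mean) / sd`. A cell is over-represented iff `z >= 3`
(inclusive).

Because the number of TFs in a without-replacement draw of size `d` from
a universe of `N` genes with `K` TFs is exactly hypergeometric, the
sampling procedure is implemented by drawing hypergeometric variates
(`stats::rhyper`) — distribution-identical to materializing gene samples
and counting, at a fraction of the cost — and the closed form

$$\mu = d\,K/N,\qquad
\sigma^2 = d\,\frac{K}{N}\Big(1-\frac{K}{N}\Big)\frac{N-d}{N-1}$$

is available as a zero-cost exact alternative
(`enrichment_z_analytic()`, `method = "analytic"` in `enrich_all()`).
The two routes are kept strictly separate so the analytic form can serve
as the independent oracle for the sampling code in tests. The error of
the sampled z around the analytic z has standard error approximately
`sqrt((1 + z^2/2) / n_iter)` (the mean estimate contributes `1/n_iter`,
the sd estimate `z^2/(2 n_iter)`); the test suite requires agreement
within five such standard errors on ≥ 99% of random configurations.

Two universes are supported: all genes with expression information (the
default — enrichment is then relative to the assayed set) or the whole
catalog. Degenerate nulls (draw size = universe, or a one-gene universe)
are flagged, never silently dropped.

A calibration note: the hypergeometric right tail at +3σ is noticeably
heavier than the normal 0.135% when the expected TF count in a cell is
small (exact tail ≈ 0.4% for cells of a few hundred genes at 5% TFs).
The suite's null-calibration experiment therefore uses cells of
2,000-5,000 genes in a 10,000-gene universe, where the exact tail is
0.15% and indistinguishable from the normal value at the experiment's
Monte-Carlo resolution (≥ 5,000 permuted cells). On small-cell data a
Z ≥ 3 call is accordingly somewhat anti-conservative; the analytic
method plus an exact `phyper` tail is the remedy when calibrated
per-cell p-values are needed.

`tissue_overlap_z()` applies the same machinery to repertoire overlap:
the observed `|A ∩ B|` is standardized against overlaps of independent
uniform draws of sizes `|A|` and `|B|` (again hypergeometric). Negative
z is meaningful and reads as avoidance of overlap.

# Specificity analyses

*Ubiquity.* Per stage (or pooled over a stage window, since the original
wording "between stages 4 and 12" is ambiguous — both modes exist), the
genes expressed at the stage are cross-tabulated TF × ubiquitous and
tested with a Pearson chi-square (1 df, no continuity correction). Any
zero marginal flags the table degenerate with a missing p-value.
"Ubiquitous" is an annotation term, not a derived breadth threshold,
matching in situ annotation practice.

*Narrow TFs.* `never_ubiquitous_narrow_tfs()` keeps TFs never annotated
ubiquitous at any stage whose union breadth over stages is strictly
below 3 terms; `exclusively_ubiquitous()` returns genes whose every
nonempty stage annotation is exactly `{ubiquitous}`.

*Adult clusters.* Binary up-call vectors are clustered with Jaccard
distance (`stats::dist(method = "binary")`) and average linkage; the
clustering method is not stated in the survey literature, and Jaccard +
average linkage is the standard pairing for sparse binary profiles. The
tree cut height is a **required** argument — there is no defensible
universal default on Jaccard distances, so the caller must own it.
Genes with no up call are excluded (their Jaccard distance is undefined)
and reported. Input order cannot matter: genes are sorted internally
before clustering. Clusters are named by the tissues with the most up
calls among members. `embryo_adult_crosstab()` then asks, per adult
cluster, how many members carry late-embryo (stages 13-16) annotation
and which embryonic terms dominate.

# Co-expression modularity

Two distinct notions are implemented and named separately, because both
appear in this style of analysis:

* **Precise co-expression** (`coexpression_partition()`): genes with
  *identical* term sets at a stage form a group. Pairs/triplets within
  groups are comodules: `count_comodules()` sums `choose(|g|, k)`.
* **Co-occurrence** (`pairwise_cooccurrence()`): two TFs co-occur at a
  stage if their term sets merely *intersect*; the statistic is the
  fraction of the six windows with co-occurrence, plus the potential-pair
  bookkeeping (`choose(n, 2)` exactly; `n²/2` as the coarse
  approximation used in prose).

A comodule is *conserved* between consecutive stages if its members
share a group at both stages; `conserved_comodules()` counts these via
the partition intersection — `sum(choose(cell, k))` over cells — which
is mathematically identical to enumerating all `C(n, k)` subsets but
linear in the number of genes. Exhaustive-enumeration equivalence is
asserted for all random instances with n ≤ 12 in the tests.

Significance comes from a label permutation: hold the earlier partition
fixed, reshuffle which gene carries which row of the later stage's
pairing matrix (a uniform permutation within the genes expressed at the
later stage — a variant permuting over the whole universe would break
the conditioning on the expressed set), recount, repeat 1,000 times, and
standardize. `random_geneset_baseline()` repeats the whole procedure on
random gene sets of a fixed size (default 373, matching a TF-repertoire
sized draw, 100 repetitions) to give the background distribution against
which TF-only conservation is read.

Calibration of this permutation z deserves a note: each z on independent
data is approximately standard normal, so the mean over 50 independent
experiments has standard error ≈ 0.14 — too coarse to certify a
near-zero center. The suite therefore averages z over all five stage
transitions of fifty generator runs with carry-over disabled (250
values, SE ≈ 0.07), which bounds the center within ±0.2 with high
confidence.

# ChIP co-occupancy

All peaks of both factors at both timepoints are merged by single
linkage (≥ 1 shared base; half-open intervals that merely abut do not
merge) into a disjoint *site universe* — there is no accepted definition
of cis-regulatory module boundaries, so partial or complete peak overlap
is read as common action within a region. Each region gets one of four
states per timepoint (`A_only`, `B_only`, `double`, `none`) from which
factors' peaks overlap it. `transition_fractions()` cross-tabulates the
two timepoints: rows (origin states) are normalized to sum to 1, empty
origin rows are reported missing, and summary fractions are emitted
against **two** denominators — regions ever occupied, and regions
occupied at t1 — because percentage statements about "occupied sites"
are ambiguous between the two. Merging is idempotent and states are
invariant to splitting peaks into abutting pieces (tested properties).

# The synthetic-data generator

`simulation_config()` fixes the study conditions; all generators are
pure functions of (config, seed). The master seed is expanded into named
substreams — `catalog`, `annotations`, `timecourse`, `calls`, `chip`,
`aux`, in that fixed order — by seeding the base RNG once and drawing
one 31-bit integer per generator; new generators append to the list, so
adding one never perturbs existing streams.

Reference conditions (the defaults):

* 2,000 genes, 5% TFs; DBD families drawn with zinc-finger-dominated
  weights echoing the fly repertoire (the 14 families with more than
  five members cover ~70% of TFs).
* Temporal class mixture proportional to an in situ TF survey
  (22 : 46 : 55 : 64 : 113 : 73 over
  none/early/late/zygotic-continuous/maternal-continuous/diverse).
  Each gene's support is drawn uniformly from the enumerated supports of
  its class, so the classifier recovers every planted label exactly.
* Maternal fraction 0.5, planted **exactly**: `round(0.5 · n)` genes per
  TF/non-TF stratum receive maternal-compatible classes. At the
  reference size there are only 100 TFs, and a Bernoulli plant would
  have sd 0.05 — exact stratified planting makes "maternal fraction
  among TFs" a sharp, recoverable quantity rather than a noisy one.
* Term sets: an expressed gene-stage is `{ubiquitous}` with probability
  0.15 (TFs) / 0.30 (non-TFs) — TFs are the more restricted group —
  else each of the 29 restricted terms enters independently with
  probability 0.10 (one uniform term is forced if none enters, since
  expressed means nonempty). With probability 0.5 a gene expressed at
  consecutive stages carries its set over unchanged, planting conserved
  comodules.
* One planted enrichment: TFs with restricted expression at
  ("ventral nerve cord", stages 13-16) additionally include the term
  with probability from 6× odds on the base rate
  (`p* = 6·(0.1/0.9) / (1 + 6·(0.1/0.9)) = 0.4`). The draw is applied
  after carry-over as an "ensure-present" union, so conservation cannot
  dilute the planted signal; non-TF rates are untouched, which makes the
  planted Z sign unambiguous.
* Time-course values: Gaussian with means 0.72 (expressed, per the
  stage support mapped to hour bins) and 0.14 (unexpressed), sd 0.3 —
  the sd chosen so the two populations overlap realistically (the
  ±0.5 reclassification then misclassifies a visible minority, as real
  data would).
* Call table: present calls i.i.d. Bernoulli(0.8); seven planted TF
  clusters, each owning 2-3 signature tissues of a 15-tissue adult
  panel, with up-call probability 0.9 inside the signature and 0.02
  outside (0.02 reflecting the specificity of a differential
  "up" call; non-TFs get 0.02 everywhere).
* ChIP: 3,000 disjoint 500 bp sites with 1,500 bp gaps; initial state
  distribution (0.43, 0.06, 0.08, 0.43) over (A_only, B_only, double,
  none) and a transition matrix in which double-occupancy is absorbing
  and one third of A-only sites gain a partner — the planted 1/3 that
  the transition analysis must recover within ±0.03. Emitted peaks are
  jittered within ±200 bp, which never breaks site disjointness
  (jitter < gap/4) and never splits a site across regions
  (jitter < width/2 keeps same-site peaks overlapping).

What the generator does **not** emulate: real genome coordinates or
sequence, ontology identifiers, probe-level microarray noise,
correlated replicate structure, or annotation biases of curated
databases. Passing recovery tests therefore certifies the statistical
machinery, not robustness to those real-data artifacts.

# Problem sizes and numerical choices

The validation suite runs the reference configuration at 2,000 genes,
3,000 ChIP sites, 10,000 resampling iterations and 1,000 permutation
reshuffles; scaled-down sizes (300-500 genes, 100-400 iterations) are
used where many repetitions are needed (50-seed calibrations, 500
enumeration instances), keeping the whole suite under a minute of
compute while leaving every statistic in its asymptotic regime.
Tie-breaks and degeneracies are explicit throughout: boundary values at
the ±0.5 cuts classify `average`, 10% coverage and z = 3 are inclusive,
zero-sd nulls and zero marginals are flagged `degenerate` with missing
statistics, and empty inputs (no peaks, no up calls, empty stages)
return empty-but-typed results rather than errors wherever the empty
case is meaningful.

# Known limitations

* The six-class temporal vocabulary is tied to the six-window stage
  axis; finer time axes must be binned first.
* The resampling enrichment z is anti-conservative at Z ≥ 3 for small
  cells (hypergeometric skew); use the analytic method with exact tails
  when calibrated p-values matter.
* Average-linkage clustering with a fixed cut is order-invariant here
  only because gene order is canonicalized; exact tie configurations in
  the Jaccard matrix can still flip merges between near-identical
  profiles.
* `enrich_all` treats cells independently; no multiplicity correction is
  applied because the Z ≥ 3 convention plays that role in this analysis
  style.
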