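---
title: "Tumor cladistics from copy-number profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor cladistics from copy-number profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoclade)
```

`oncoclade` treats a cohort of tumors the way a systematist treats a set
of taxa: each copy-number aberration is a derived character shared by
descent within the tumor population of a patient cohort's "character
space", and tumors are grouped by the aberrations they share. This
vignette explains the models behind each stage, the tunable parameters,
the numerical choices, what the synthetic-data generator does and does
not emulate, and the known limitations.

## From probes to aberration calls

**Segmentation** (`segment_probes()`). The input is a probe-level
log2-ratio track (tumor versus sex-matched normal). A moving average
over a `window_bp` genomic window (default 0.2 Mb) is standardised by a
robust estimate of probe noise — 1.4826 × the median absolute deviation
of *all* of the sample's log-ratios, because aberrant segments would
inflate a plain standard deviation — and probes whose standardised
window mean reaches `z_threshold` (default 2.5) seed a call. Two
numerical details matter in practice:

- *Hysteresis*: a seeded run is extended over flanking probes holding at
  least half the threshold, so a brief dip inside one aberration does
  not split the call into fragments.
- *Edge trimming*: window means are diluted near segment boundaries, so
  each run is trimmed of edge probes whose own log-ratio is below half
  the run's median magnitude. On a noiseless track this recovers a
  planted interval exactly over its covered probes, with the fold change
  `2^(mean log-ratio)` exact.

The reported interval is half-open `[first probe, last probe + spacing)`.
The commercial two-stage detection pipeline this emulates pairs the
z-score stage with a proprietary second algorithm (threshold 6.0 in the
vendor's settings); that second stage is out of scope and the threshold
is recorded in the pipeline configuration for provenance only.

**Fold-change filtering** (`filter_by_fold()`). Interval reports carry a
linear fold change per event. Gains are kept strictly above 1.2, losses
strictly below 0.8 — deliberately sensitive thresholds, read literally
as strict inequalities ("above"/"below"), so the boundary values 1.2 and
0.8 themselves are dropped. Both thresholds are exposed.

**Gene intersection** (`intersect_genes()`). A gene event is emitted for
every (interval, gene) pair overlapping by at least 1 bp on the same
chromosome. All coordinates are 0-based half-open throughout the
package; adjacent intervals (`end == start`) do not overlap. Two gene
panels ship as editable BED fixtures with *synthetic* coordinates on the
simplified genome — symbolic stand-ins, not assembly positions.

## MSI and methylation

MSI status follows the mononucleotide-panel convention: at least two of
the five markers unstable → MSI-H, exactly one → MSI-L, none → MSS.
Missing markers are a real possibility in archival material and the
convention has no stated policy, so `classify_msi()` refuses to
classify a sample with fewer than `min_evaluable = 4` evaluable markers
rather than defaulting it to MSS; the refusal is an explicit
`Unclassifiable` status.

Methylation calls are tabulated gene-wise (NA states removed per gene,
which maximises the evaluable n, matching how MSP panels report).
Associations are Pearson chi-square *without* continuity correction —
the convention of the statistics package the reference tables were
produced with — with the Fisher exact test substituted and flagged when
any expected cell falls below 1. The `msi` covariate means MSI-H versus
the rest: the reference association table's column sizes (5 vs 22) only
fit that reading, so it is adopted and documented here. Age is
dichotomised at 60 years.

One calibration caveat: the asymptotic chi-square p and a
margin-conditioned permutation p can differ by several hundredths at
MSP-panel sample sizes (n ≈ 25) because the permutation null is
discrete. The test suite checks close agreement at n = 100 and
order-of-magnitude agreement at panel sizes.

## The polarity matrix

All aberrations of all specimens are pooled and deduplicated; each
specimen scores 1 (derived, present) or 0 (ancestral, absent) for each
pooled aberration. Character identity is a genuine modelling choice the
interval reports do not resolve, so two modes exist:

- *interval* (default): exact canonical interval + direction, with an
  optional `merge_tolerance_bp` grid snap (coordinates floored to the
  grid) for platforms with jittered breakpoints; and
- *gene*: `gene:direction` pairs from `intersect_genes()`, coarser but
  robust to breakpoint noise.

The mode and tolerance are recorded in the matrix's attributes and in
the pipeline manifest. Characters shared by *every* specimen are
retained although parsimony-uninformative: they belong to the pooled
aberration list and are assigned to the root at annotation time.
All-absent characters are impossible by construction. The matrix is
serialized in PHYLIP discrete format (name padded to 10 characters,
then the 0/1 string); names are truncated/disambiguated with a mapping
sidecar when needed.

## Maximum parsimony

The estimator prefers the tree needing the fewest character-state
changes. The default model is Wagner parsimony (free 0↔1 reversals),
counted with Fitch's downpass — the default of the classic
discrete-character program this workflow follows; Camin-Sokal
(irreversible 0→1, natural if aberrations are never undone) is
available as an option, counted as the minimal number of 0→1 origins on
the tree rooted by the aberration-free ancestor.

Three searches share one contract (all optimal trees found, up to a cap
of 1000):

- `exhaustive_search()` enumerates all unrooted binary topologies,
  refusing more than 9 taxa (135 135 topologies);
- `branch_and_bound_search()` is exact for mid-sized cohorts: taxa are
  inserted one at a time on every edge, and a partial tree is pruned
  when its length exceeds the best complete tree (valid because adding
  a leaf never decreases parsimony length); the first bound comes from
  a quick heuristic run, and a configurable node budget guards resource
  use — exhausting it returns the best-so-far flagged incomplete;
- `heuristic_search()` is stepwise addition under a seeded random
  addition order followed by best-improvement NNI hill-climbing,
  repeated over `n_starts` starts; deterministic given the seed.

`parsimony_search()` dispatches between them (`auto`: exhaustive ≤ 7
taxa, branch and bound ≤ 15, heuristic above). All searches first
separate characters whose cost is topology-independent (singletons and
complements of singletons under Wagner: exactly one step on any binary
tree; constants: zero) and add their cost back as an offset — an exact
reduction that makes cohorts with thousands of private aberrations
tractable, since only the shared aberrations drive the search. The
scoring kernels are C++ (bit-packed state sets, 64 characters per
word).

**Rooting and node annotation** (`root_and_annotate()`). The natural
root of a tumor cladogram is the aberration-free normal genome. An
all-zero outgroup is attached on the edge where it adds the fewest
steps (only characters with placement-dependent cost are scored; ties
resolve to the first edge in canonical order), the tree is rooted
there, and internal nodes are numbered `Nd1` (root) onward in preorder.
Each node gets two character lists:

- *strict synapomorphies*: characters present in exactly the node's
  leaves — reading directly off the matrix, independent of any
  reconstruction; and
- *reconstructed gains*: characters whose Fitch final pass (root forced
  to the ancestral absent state wherever the downpass allows) places a
  0→1 change on the node's stem.

Private characters appear as leaf autapomorphies; characters shared by
all specimens land on the root.

**Ties and consensus** (`strict_consensus()`). Equally parsimonious
trees are surfaced, not hidden: the fit keeps all optimal trees (up to
the cap) and the strict consensus — exactly the unrooted bipartitions
present in every optimal tree, everything else collapsed to polytomies
— is reported alongside one deterministic exemplar. The consensus is
rooted by attaching the all-zero ancestor at the internal *node* where
it adds the fewest changes: node placement cannot create a clade that
is not a shared split, so the root never resolves what the tied trees
left open. Because consensus trees are polytomous, these placements are
scored with the exact unit-cost (Sankoff) recursion rather than the
binary-tree Fitch fold, which undercounts changes at polytomies. (A single binary tree, by contrast, is rooted on an *edge*,
the classic outgroup rooting.) Node numbering is preorder within a run;
it is reproducible for a fixed input and recorded in the outputs, but
not comparable across different runs or software.

## Cohort statistics

Group summaries are the median and 25–75% interquartiles under the
Hyndman–Fan **type 6** rule (interpolation at rank `h = p(n+1)`,
clamped): this is the HAVERAGE convention of the statistics package the
reference tables came from, and it is the single rule that reproduces
every printed interquartile of the reference cohort exactly (12.75,
105, 62.5, 31, 55, 54.75, 70.5, 6.5, 34). A few printed values appear
truncated rather than rounded (54.7 for 54.75, 256 for 256.5, 713.7
for 713.75, 148 for 148.75, 67 for 67.5); the package reports the exact
type-6 arithmetic and documents the discrepancy rather than emulating
truncation.

Which test produced the reference cohort's group p-values is not
recoverable from its methods (the caption names a correlation, the text
names t-test/ANOVA/chi-square), so `group_tests()` reports the
mean-based family (Student t / one-way ANOVA) and the rank-based family
(Mann-Whitney / Kruskal-Wallis) side by side and privileges neither.
Contingency tables use Pearson chi-square, no continuity correction,
empty margins dropped.

## The synthetic-data generator

`generate_cohort()` draws, per tumor: an MSI group (default mixture
18/4/5 over MSS/MSI-L/MSI-H, the reference cohort's composition); an
aberration count from a negative binomial with group means 37/256/10 —
the reference group medians — and dispersion `size = 1.5` (tumor
aberration burdens span 1 to several hundred within a group, far wider
than Poisson; the dispersion is a modelling choice exposed in the
config); tumor location (right-sided with probability 0.8 for MSI-H,
1/18 for MSS, 0 for MSI-L); age from group-specific normals (means
63/40/57 years, sd 12, the reference group medians); sex as a fair
coin; stage and differentiation from the reference frequencies.
Aberrant intervals are placed uniformly on a simplified genome of 24
round-length chromosomes (no placement model is stated for the real
data); lengths are exponential around 1 Mb; within a sample,
same-direction overlaps merge and the longer interval wins a
cross-direction conflict. Events on chrX are directed by sex
(amplification in males, deletion in females) with probability 0.9.
Gains draw folds in 1.3–2.5 and losses in 0.3–0.75, clear of the
1.2/0.8 thresholds, so planted counts survive filtering. Methylation is
per-gene Bernoulli with MSI-H versus non-MSI-H probabilities taken from
the reference frequency table (P16 0.60 vs 0.045, hMLH1 0.80 vs 0.045,
SYNE1/MMP2 always, RNF182 never). MSI marker panels are consistent
with the group by construction.

Planted clades inject identical intervals into exactly their member
samples; random intervals overlapping a planted interval are discarded
first, so the planted characters are perfect (1 on exactly the clade).
All randomness flows from one master seed with per-sample sub-streams,
so a cohort is reproducible even under partial regeneration, and the
planted truth is written to a sidecar file that no analysis stage
reads.

What the generator does **not** emulate: GC waves and probe-level
artefacts, tumor purity and ploidy, recurrent breakpoint hotspots,
linkage between methylation and copy-number state within a tumor, and
real genome coordinates. Passing recovery tests on synthetic cohorts
therefore demonstrates the pipeline's correctness under its own model
assumptions — planted effects of the stated sizes are found — not
calling accuracy on raw arrays.

## Problem sizes used by the checks

The packaged checks run, by the package's own choice of problem sizes:
search-agreement on one hundred 7-taxon × 20-character matrices
(branch-and-bound must match exhaustive enumeration always, the
heuristic in ≥ 95%); perfect-phylogeny recovery at 8–15 taxa;
planted-effect recovery on one hundred 200-tumor cohorts (MSI-H
aberration deficit by rank test, P16-MSI association, and a planted
8-member clade with 6 shared aberrations in the strict consensus, each
in ≥ 95%); segmentation recovery of a 1 Mb fold-1.5 interval at noise
sd 0.2 over two hundred tracks (≥ 95% at ≥ 50% reciprocal overlap);
and chi-square type-I error within [0.03, 0.07] over two thousand null
tables of n = 500.

## Known limitations

- Interval-identity characters require exact breakpoint agreement at
  tolerance 0; real platforms jitter breakpoints, so gene mode or a
  positive tolerance is advisable on real data.
- The heuristic search offers no optimality certificate (use branch and
  bound up to ~20 taxa when exactness matters), and NNI is the only
  rearrangement implemented.
- Camin-Sokal searches use R-level scoring and are practical only for
  small cohorts.
- Fitch reconstruction (and hence reconstructed gains) is defined on
  binary trees only; consensus trees carry strict synapomorphies alone.
- The cohort statistics deliberately apply no multiple-testing
  correction, mirroring the descriptive use of the reference tables.
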