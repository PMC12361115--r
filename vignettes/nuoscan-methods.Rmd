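---
title: "Context-calibrated annotation of multi-subunit complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-calibrated annotation of multi-subunit complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuoscan)
```

## The problem

Profile-HMM searches for the subunits of a multi-gene respiratory
complex — here NADH:quinone oxidoreductase (Complex I), encoded in
prokaryotes by the 14-gene *nuo* operon — return a mixture of genuine
subunits and cross-hits from paralogous families. The NuoB profile, for
example, also matches hydrogenase subunits; the antiporter-like NuoL,
NuoM and NuoN match one another. Because profiles differ in length and
conservation, no single e-value cutoff works for all subunits, and no
external gold standard exists to calibrate per-subunit cutoffs against.

`nuoscan`'s premise is that the genome itself provides the calibration:
genes of one complex co-locate in operon-like clusters, and hits found
inside a cluster that contains *all* subunits are almost certainly
genuine. Their score distribution then defines, per subunit, the region
of e-value space that genuine hits occupy.

## Clustering by genomic context

Hit-bearing genes are grouped per replicon and strand. The intergenic
distance between genes $a$ and $b$ (with $a$ starting first) is

$$d(a,b) = \max(0,\; \mathrm{start}_b - \mathrm{end}_a - 1),$$

so overlapping and book-ended genes are at distance zero; there is no
standard convention for overlapping gene pairs, and clamping is the
conservative choice. A cluster is a maximal run of hit-bearing genes in which
consecutive genes satisfy $d \le g$. Intervening genes without hits do
not join the cluster but their span counts toward the distance, so a
long foreign insertion breaks a cluster naturally. The implementation
chains genes sorted by start position against the running maximum of
gene ends, which equals the transitive closure of the pairwise relation
(verified against a union-find oracle in the test suite); clusters
never span replicons because intergenic distance is undefined across
molecules.

The default $g$ is 250 bp. Because the right value is dataset-dependent,
`scan_gap_thresholds()` re-clusters over a grid (default 0–500 bp in
25 bp steps) and counts species holding at least one Complete cluster.
That count is provably non-decreasing in $g$ (clusters only merge), and
`detect_plateau()` returns the smallest threshold at which its relative
growth over one step drops below `rel_epsilon` (default 1%). When the
scan never flattens the largest threshold is returned with a warning.
The scan counts species rather than genomes when a taxonomy is
available, since multi-strain species would otherwise dominate; a
`unit` switch restores genome counting.

A cluster is *Complete* when its fusion-resolved subunit content covers
the scheme's required set — a 13-gene run with a fused CD gene is
Complete — and *Partial* otherwise.

## E-value calibration

All scoring happens in $\log_{10}$(e-value) space because e-values span
hundreds of decades; exact zeros (HMMER underflow) are preserved at
parse time and floored to $10^{-300}$ only when transformed. Full
per-sequence e-values are used by default; whether full-sequence or
best-domain scores were used upstream is not always knowable, so
`read_hmm_hits()` exposes a `score_type` switch.

For each profile, `estimate_kde()` fits a Gaussian KDE (512-point grid
spanning the data ± 4 bandwidths). The bandwidth follows Silverman's
rule of thumb by default, with a fixed-bandwidth override for
reproducibility; degenerate inputs (zero spread) fall back to 0.1
decades. Modes are interior local maxima of the discrete density; maxima
below `min_density_frac` (default 0.001) of the peak are discarded as
numerical ripples, and each antimode is the density minimum between two
consecutive retained modes, so modes and antimodes alternate by
construction.

`derive_threshold()` segregates each profile's hits by membership in
any Complete cluster. Member density is evaluated on the same grid with
the same bandwidth; the member-dominated mode is the mode with the
highest member density, and the cutoff is the first antimode to its
right. When the pooled distribution is unimodal there is no cross-hit
population to separate, and the cutoff falls back to the right edge of
the dominant mode — the first grid point past the mode where density
drops below `min_density_frac` of the peak. We initially used one fixed
decade of slack beyond the largest member e-value here, but that
clipped genuine hits in genomes that lack a Complete cluster (the
complex-like and split-operon genomes, whose hits are by definition
non-members); the mode edge covers the whole genuine mode while still
sitting tens of decades below any decoy population. In all cases the
cutoff is raised if needed so that at least 99% of member hits pass,
and capped at an e-value of 1.

Protein-length filtering removes unusual-length outliers: the band is
either a scheme-supplied reference range (the default Nuo scheme ships
ranges loosely anchored on reviewed bacterial sequences) or the 1st-99th
percentile band of member lengths. Sequence identity is deliberately
not a filtering criterion. Profiles whose hits never occur in a
Complete cluster yield no calibration; their hits are rejected with
reason `no_threshold` unless a `default_cutoff` is supplied — rejecting
matches the philosophy that confidence flows from context.

`filter_hits()` partitions hits into retained and rejected (with reason
`evalue`, `length`, `both` or `no_threshold`) and is idempotent.

## Fusion resolution and variant classification

A gene carrying hits from several single-subunit profiles is a fusion
candidate. Domain envelopes decide: profiles whose envelopes overlap at
most `max_overlap_frac` (default 0.2) of the shorter envelope all
contribute their subunits; envelopes that coincide are paralog
ambiguity and collapse to the best e-value profile. The 0.2 tolerance
is a package choice (exposed in the API): genuine two-domain fusions
show essentially disjoint envelopes, while paralog double-hits overlap
almost completely, so the exact value is uncritical between ~0.1 and
~0.5. Hits without envelopes (plain tblout input) are treated as
spanning the whole protein and therefore always collapse. Dedicated
fused profiles (NuoCD, NuoBCD) expand directly to their subunit lists.

Genome classification uses the union of subunits across all clusters,
because genuinely complete complexes can be encoded in split clusters:
`Absent` (no subunits), a `Complete*` variant (union covers the
required set; fused-gene sub-variants take precedence, largest fusion
first), `CI_like` (the missing set equals exactly {E,F} or {E,F,G} —
only these N-module losses are named; a genome with fused CD *and* a
missing N-module is classified `CI_like` with the fusion recorded in
`has_fused_gene`), else `Incomplete`. The number of independent
complete gene sets is counted greedily — clusters ranked by subunit
completeness then mean e-value, genes consumed in that order — which
matches exhaustive search on the realistic instances in the test suite;
exact set cover is overkill at 14 subunits. Arrangement distinguishes
`single_cluster` (one cluster covers everything) from `split`; plasmid
placement is `exclusive`/`complete`/`partial`/`none` from the replicon
types of hit genes, with replicon typing precedence: explicit metadata,
then a case-insensitive "plasmid" keyword, then unknown.

Species aggregation reports all observed variants, a consistency flag,
and a modal representative (ties resolved toward the more complete
variant). Rank summaries exclude taxa below `min_species` (default 10)
to avoid percentage noise from tiny taxa.

## Assembly QC and the association test

N50 uses the common descending-cumulative-sum convention (the tie
convention is unstated in the sources, so the first contig reaching
half the total defines N50). Quality tiers are conjunctive and
evaluated Excellent → Good → Moderate: N50 at least 90/70/50% of the
total length *and* at most 5/10/50 contigs; boundary values classify
upward ("at least"/"at most").

The lifestyle association is a plain chi-square test of independence on
the species-level lifestyle × variant count matrix (species, not
strains, are the counting unit; four lifestyle groups: aerobe,
anaerobe, facultative anaerobe, microaerobe). No continuity correction
is applied — the table is 4 × k, not 2 × 2. Cellwise Pearson residuals
$(O - E)/\sqrt{E}$ are reported rather than standardized residuals, the
convention for "deviation from expected" heatmaps. Zero-marginal rows
or columns are dropped with a warning; expected counts below 5 raise a
warning rather than an error, and a `--min-col-total`-style collapsing
of rare variants is left to the caller (rare columns are visible in the
output and can be merged before testing).

## The synthetic-data generator

`simulate_dataset()` emulates the structure this pipeline is built to
exploit, with a single global seed driving one RNG stream:

* ~40 species (about 50 genomes with the 75/20/5% one/two/three-strain
  mix), variants allocated by largest remainder so every category is
  present: 30% fully complete, 14% fused CD, 10% fused BCD, 12%
  complex-like (alternating {E,F} and {E,F,G} losses), 16% incomplete
  (random 5–9 subunit subsets), 18% absent. Strains of a species share
  the variant, mirroring the near-perfect intraspecies consistency of
  real data.
* operons are same-strand gene runs; each operon draws a spacing scale
  uniformly below `gap_max` = 100 bp and its intergenic gaps uniformly
  below that scale, so the Complete-vs-threshold curve rises roughly
  linearly and levels off at the gap bound — the qualitative shape seen
  in real genome collections. Independent runs (second copies, split
  halves, background genes) are separated by at least 2000 bp, ten
  times the scanned range's upper end.
* genuine hits draw $\log_{10}$ e-values from N(−50, 2); decoy
  cross-hits (wrong-profile hits on background genes, mimicking
  hydrogenase-versus-NuoB confusion) from N(−5, 2) at ~2 per genome.
  The 45-decade separation reflects how far paralog scores sit from
  genuine subunit scores in practice; sensitivity targets in the tests
  assume at least 6 decades.
* a few complete species get a second full operon copy, a split operon,
  or a plasmid-exclusive operon (disjoint sets, at least one each);
  protein lengths are N(subunit mean, 5%) around values anchored on
  *E. coli* subunits.

What the generator does *not* emulate: sequence content (only
coordinates, lengths and scores are produced), overlapping operons of
other respiratory complexes, taxonomic correlation of variants,
assembly fragmentation (every genome is one or two replicons), and
e-value distributions with heavy tails or more than two components.
Passing the end-to-end tests therefore demonstrates the machinery —
clustering, calibration, classification, association — not the
field performance of any particular HMM profile set.

## Pipeline ordering and determinism

`run_pipeline()` runs curate → cluster (provisional) → calibrate →
filter → re-cluster → scan → classify → aggregate → associate. One
re-cluster pass follows filtering because decoy removal can split
provisional clusters; `iterate = TRUE` repeats
calibrate/filter/re-cluster to a fixpoint (at most 10 rounds) for
datasets where filtering changes cluster membership materially. Every
output table is explicitly sorted, so pipeline output is a pure
function of inputs and parameters; the run manifest records versions, a
parameter hash and the timestamp (the only non-deterministic field).
Stage failures name the stage and leave a `FAILED` marker.

## Problem sizes and limitations

The shipped tests and the acceptance script run on generated datasets
of about 40 species / 50 genomes / ~700 hits, 200 randomized
clustering instances of up to 50 genes, 10-seed mixture calibrations at
500 + 500 draws, and 1000-replicate null simulations for the test-size
check — sizes chosen so the full suite completes in a few minutes while
every statistical claim is still measured, not assumed.

Known limitations: cluster-based calibration needs at least one genome
with a Complete cluster per profile, so a profile found *only* in
split or partial form across an entire dataset cannot be calibrated
from context; the greedy copy count can in principle undercount
adversarial fusion arrangements (it is exact on realistic ones); plasmid
attribution inherits whatever replicon labelling the input provides;
and the variant taxonomy, while scheme-driven, names only the N-module
losses as complex-like — other biologically meaningful partial forms
all fall into `Incomplete`.
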