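---
title: "Methods: multi-scale enhancer dissection with credissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale enhancer dissection with credissect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credissect)
library(dplyr)
```

# Overview

`credissect` implements the computational side of a multi-scale dissection of
cis-regulatory elements (CREs): quantifying regulatory activity from
barcoded reporter (MPRA) counts, estimating single-variant effects from
multi-hit saturation-mutagenesis libraries, scanning sequences with
biophysical binding models to call transcription-factor binding sites
(TFBSs), measuring sub-tile synergy and promoter-distance effects,
scoring pairwise TFBS epistasis against a multiplicative null, compacting
enhancers by greedy single-base deletion under a pluggable sequence scorer,
and generating the three classes of TFBS-anchored derivative sequences
(reconstitution, random deposition, synthetic thripsis). A
seed-deterministic synthetic-data generator with fully recorded ground
truth is a first-class module: it is how every estimator in the package is
validated.

# Activity quantification

The unit of measurement is the barcode. For each replicate, a barcode's RNA
and DNA UMI counts are normalized by the replicate's total RNA and DNA UMIs
over *all* dictionary barcodes. The activity of an element is

$$A = \frac{\sum_b \mathrm{winsorized}(r_b)}{\sum_b \mathrm{winsorized}(d_b)}$$

over the element's barcodes, where $r_b, d_b$ are the normalized RNA and
DNA values and winsorization clips at the 1st/99th percentiles within the
element. Choices worth stating:

* **Winsorization is two-sided and within-element.** "1% winsorization" is
  ambiguous between one- and two-sided and between element-wise and
  library-wide clipping; we adopt the standard two-sided definition within
  the element's barcode set, and `winsor_frac = 0` reproduces the plain
  ratio exactly (tested).
* **Cross-replicate summary is the geometric mean.** All reported
  comparative statistics (replicate R², fold-changes, variance
  decompositions) are on the log scale, so log-scale averaging is the
  consistent choice. An element with zero RNA in a replicate has activity
  zero, which propagates.
* **Missing barcodes count as zeros.** A dictionary barcode absent from a
  replicate's count table contributes 0 UMIs rather than being dropped:
  missingness is informative about DNA representation.
* **Activities are relative.** Because totals normalize each library,
  estimated activities are defined up to the library-average activity;
  all downstream quantities are ratios (fold-changes vs a wild-type or
  basal reference), which are invariant to this scale (tested as a
  rescaling invariance).

Dictionary filtering keeps barcodes with at least a library-specific read
count (the valley between the two modes of the log-coverage distribution,
`suggest_min_reads()`, with a configured fallback when unimodal), at least
95% of reads attributable to one element, and — for variant dictionaries —
more than 90% of reads supporting the called variant set.

# Saturation mutagenesis with multi-hit barcodes

Real mutagenesis libraries carry, besides the programmed substitution, a
Poisson-distributed number of additional PCR-induced mutations (rate 1.3,
i.e. 2.3 mutations per insert on average). The variant-effect estimator
embraces this: the effect of a mutation is computed over *all* barcodes
carrying it, on the assumption that co-occurring mutations average out
across the ensemble and at worst shift all estimates by a common factor.
That factor is absorbed by the **self-consistent wild-type reference**: the
reference activity is chosen on a 41-point log-spaced grid spanning 0.5-2
times the designed wild-type activity as the value minimizing the number of
significant non-zero calls (|log2 FC| > 0.32 and BH FDR < 0.006), with ties
broken toward the designed value. This is the most conservative baseline;
note it centers effects on the *mode* of the effect distribution, so when
most positions of an element are genuinely deleterious the reference
absorbs part of that shared shift — an identifiability limit of the method
itself, not of the implementation.

Significance uses a two-sided Mann-Whitney test of per-barcode normalized
RNA/DNA ratios against wild-type barcodes, pooled across replicates (the
test's unit — barcode vs replicate — is a deliberate choice recorded here),
with Benjamini-Hochberg correction across the full variant set. Variants
with fewer than 5 barcodes are reported as missing. Deletion variants are
tracked but excluded from affinity regressions, where a deletion's
alignment within homopolymers is ambiguous.

Site-level interpretation:

* **Singleton-functional TFBSs**: per site, log2 activity fold-change is
  regressed on log2 predicted-affinity fold-change across the site's
  substitutions; R² > 0.195 calls the site singleton-functional. Sites
  whose substitutions all produce the same affinity fold-change are
  degenerate for this regression and flagged instead of called.
* **Necessity**: `1 - (A_disrupted - minP) / (A_WT - minP)`, with
  `A_disrupted` the *median* activity over the site's strong
  affinity-disrupting substitutions (predicted normalized-affinity drop
  > 0.075). Median was chosen over min/mean for robustness; the
  aggregator is configurable. Values above 1 (below-baseline) are allowed
  and flagged; sites above 0.75 are flagged high-LoF.
* **Gain-of-function classes**: large-effect GoF variants (log2 FC > 0.5)
  are classified from their maximal local affinity change across module
  TFs: `unrelated` (< 0.02 change on every TF), `create_new_site`
  (starting affinity < 0.05), otherwise strengthening of a functional or
  sub-functional site according to the singleton-functional call.

# Affinity scanning

A binding model is a k x 4 matrix of positive per-base multipliers; a
k-mer's unnormalized affinity is the product of one multiplier per
position, and both orientations are scored with the maximum retained
(with the winning orientation recorded). Affinities are normalized by the
99.99th percentile of unnormalized affinities over one million uniform
random k-mers (seeded, linear-interpolation order statistic), so a rare
sequence can legitimately score above 1. Edges are scored only where a
full k-mer fits. Two cutoffs are used by convention: 0.05 for putative
sites in mutagenesis interpretation, 0.1 for the stricter anchor
definition.

Per-position tracks become discrete sites by greedy non-maximum
suppression with window k — one site per local optimum; the suppression
window is our choice since no collapse rule is implied by a per-position
track. Near-redundant factor pairs (e.g. two GATA-family models) can be
max-merged position-wise, optionally flipping the second model's reported
orientation when its consensus is stored in the opposite sense. Anchors
are the maximal merged intervals of called sites across the module's TFs;
anchors and their complementary gaps tile the element.

# Tiling, synergy and positional effects

Multi-size tile designs enumerate, for each size w, all
`floor((L - w)/stride) + 1` left-aligned tiles per orientation (defaults:
sizes 40/70/120/170/220/270/300, stride 5, both orientations). Profiles are
smoothed with a 3-point sliding median — interpreted as three consecutive
tile positions (a 15 bp span at stride 5), the profile's native
resolution — with truncated windows at the edges.

Synergy compares a long tile L (120 bp) with the two short tiles S1, S2
(70 bp) sharing its outer boundaries (central overlap 20 bp, wider than
one TFBS):

$$\mathrm{ratio} = \frac{A(L)}{\max(A(S_1) + A(S_2) - \mathrm{minP},\ \varepsilon)}$$

The basal minP activity is subtracted once so the baseline is not counted
twice; a flag switches to the raw sum for sensitivity analysis. The floor
ε (default minP/10) prevents division blow-up when the denominator is at
or below zero; floored rows are flagged and excluded from ranking.

Positional analysis measures Δx from the tile's minP-proximal end — the 3'
end as cloned, i.e. the right edge in parent coordinates for forward tiles
and the left edge for reverse tiles — to the *nearest* edge of an active
subregion (the anchor point is our choice and recorded). An exponential
distance-decay model `A = minP + A0 exp(-Δx/τ)` can be fit to collapsed
profiles; the generator's distance-decay preset is recovered within 10%.

# Epistasis against the multiplicative null

For each TFBS, a disrupting mutation set is chosen in two stages: the top
15 substitutions by predicted affinity loss, then the 10 with lowest
measured activity. For a pair of sites, barcodes carrying at least one
selected mutation from *both* sites estimate the observed double
disruption; single-constituent barcode sets estimate the marginals; the
score is `log2(observed_fc / (fc_i * fc_j))`. Barcodes hitting three or
more selected sites are excluded to isolate second-order effects. The
nominal p-value is a rank-sum test of the double-hit barcodes' log ratios
against a composite null resampled under multiplicativity
(`r_i + r_j - r_wt`); under the generator's independently-acting-sites
preset the false-positive rate at p < 0.01 is consistent with 1%
(binomial test, acceptance suite). Pairs whose multiplicative expectation
falls below the basal minP activity are flagged: observed activity cannot
fall below basal, so apparent buffering there is uninterpretable.

# Compaction and the activity-size Pareto front

Greedy compaction scores all L single-base deletions of the current
sequence with a pluggable scorer (`function(seq) -> scalar`), applies the
argmax (ties broken leftmost for determinism), and iterates to the stop
length (default 40 bp), recording every intermediate sequence — a 300 bp
start yields 261 sequences. The default test scorer is summed
above-threshold normalized TFBS affinity; any external accessibility
model can be wrapped into the same contract, and the marginal embedding
score (mean prediction over a sequence written at the center of 1,000
background sequences, normalized by the backgrounds' own mean) is
available for scorers whose raw output depends on context length. Both
the raw and the embedded score can drive the greedy argmax; the embedded
form is the default recommendation, the raw form is cheaper.

Pareto fronts over (length, activity) points keep exactly the points not
dominated by any shorter-or-equal, stronger-or-equal alternative
(computed by a length-sweep; verified in tests against an O(n²) pairwise
oracle), globally or per source class.

# Derivatization

All derivative classes hold the TFBS anchors intact:

* **Reconstitution** writes each anchor substring over a background at
  its native coordinates (preserving inter-anchor spacing), with variants
  trimming 1 or 2 bp from each anchor flank, plus randomized position
  sets that keep wild-type orientation. With the default design — 5
  position sets x 400 backgrounds — each CRE yields 2,000 reconstitution
  derivatives.
* **Random deposition** places the anchors at uniformly drawn
  non-overlapping positions (candidate starts uniform over all valid
  offsets; accepted if non-overlapping; longest anchor placed first with
  bounded rejection sampling and seeded restarts — placement order is our
  choice, recorded in the manifest). 100 position sets x 6 designated
  backgrounds give 600 depositions per CRE.
* **Synthetic thripsis** cuts at N positions drawn uniformly without
  replacement from gap (non-anchor) positions, producing N + 1 fragments
  that are concatenated in a uniformly random order with orientations
  preserved; 3 breakage densities (5/10/20) x 200 seeds give 600 per CRE.
  Fragment identity in a thripsized sequence is recovered by iterated
  longest-common-substring masking (ties broken leftmost in the original,
  then in the derivative); adjacent fragments that remain adjacent merge,
  which is the intended behavior of the reconstruction.

Backgrounds pair each primary sequence with one dinucleotide shuffle — a
uniform random Eulerian-path shuffle (Altschul-Erickson) preserving exact
transition counts and terminal bases. In this package the 200 primary
backgrounds are synthetic random sequences at genome-like GC content
(0.42) standing in for inaccessible genomic regions; selecting real
inaccessible regions from accessibility data is out of scope, and the
stand-ins are labeled as synthetic throughout. The negative-control panel
is under-specified beyond its size (2,400); we use the 400 backgrounds
plus additional independent shuffles up to the configured count, all
labeled. Randomized reconstitution position sets randomize positions
while preserving orientation (a spacing-preserving variant is available
via `reconstitute()`'s explicit `positions` argument).

The full default library is 18,405 designs (10,000 reconstitution + 3,000
deposition + 3,000 thripsis + 2,400 negative controls + 5 wild types),
rebuilt byte-identically from its configuration seed; every row records
the derived seed that produced it, and `audit_anchor_integrity()` verifies
anchor substrings in every CRE-derived design.

Summary statistics over derivative activities are deliberately simple:
`variance_explained()` is the one-way ANOVA between-group share of
log-activity variance, and `wt_position_rank()` is the mid-rank quantile
of the wild-type position set among its randomized counterparts.

# The synthetic-data generator

The generator emulates the statistical structure the estimators assume:

* **Sequences**: random backgrounds with consensus motifs planted at
  non-overlapping positions, random orientation.
* **Dictionaries**: every substitution represented; one programmed
  mutation plus Poisson(1.3) extras per insert (20% of extras are 1-bp
  deletions — the exact fraction is not constrained by any reported
  value, so it is configurable), giving 2.3 mutations per insert on
  average; default barcode depths of 492 per element and 100 per variant;
  a pool of unmutagenized wild-type barcodes serves as the reference set.
* **Counts**: log-normal per-barcode DNA abundances (sdlog 1), negative
  binomial UMI noise (sizes 10 for DNA, 4 for RNA; negative binomial
  rather than Poisson because real MPRA UMI counts are overdispersed),
  RNA means proportional to abundance times the barcode's composite
  activity. Composite genotypes are multiplicative across mutations —
  consistent with the multiplicative epistasis null — with an
  `interaction_fn` hook for planting epistasis in calibration tests.
* **Effects**: mutations inside planted sites carry the site's disruption
  multiplier (drawn from 0.1-0.5) with 0.2 log2 jitter; other mutations
  draw from a slightly LoF-biased distribution (mean -0.1, sd 0.4 log2),
  reflecting that most positions of a strong developmental enhancer are
  mutation-sensitive. Estimator-validation presets set the non-site mean
  to zero (so the self-consistent reference is identifiable) or switch
  off all non-site effects (the independently-acting-sites preset used
  for epistasis type-I calibration).

What the generator does *not* emulate — barcode sequencing errors and
collisions, UMI deduplication artifacts, transfection batch structure,
chromatin context, and any sequence-intrinsic activity model beyond
planted-site multiplicativity — bounds what passing tests show: they
certify the estimators against the stated noise model, not against every
failure mode of real libraries.

Problem sizes in the test suite are scaled to the property being checked:
mutation-load statistics use 10^5 inserts; variant-effect recovery uses a
100 bp element at 200 barcodes per variant; epistasis calibration pools
~60 site pairs across four simulated elements at 40,000 barcodes each;
thripsis audits cover 10^3 random designs. The full 18,405-design library
is built at study scale because it is deterministic and fast.

# Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere, including BED output (BED's
native convention, so no shifts exist anywhere in the code base).
Minus-strand extraction reverse-complements. Ambiguity codes are rejected
at ingest: every sequence here is fully specified. Quantiles are type-7
(linear interpolation). Ties in the greedy compaction argmax break
leftmost; ties in wild-type quantile ranks use mid-ranks; ties in
longest-common-substring search break leftmost-original then
leftmost-derivative. Homopolymer shuffles return the identity; elements
with zero DNA in all replicates are an error, while zero RNA yields
activity zero. All randomness flows through per-call integer seeds; child
seeds are derived with a fixed integer recurrence kept inside the 32-bit
range, and generator manifests record every seed so outputs are
byte-identical on regeneration.

# Known limitations

* Estimated activities are relative to the library average; only ratios
  are meaningful across libraries.
* The self-consistent wild-type reference is unidentifiable from a
  uniformly shifted effect distribution (discussed above).
* The rank-sum epistasis p-value compares distributions whose variances
  differ (one noise term vs three in the composite); calibration is
  verified empirically at the 1% level rather than guaranteed
  analytically.
* The singleton-functional regression fails by design where overlapping
  sites of different TFs break the affinity-activity correlation.
* The default affinity-content scorer is a stand-in for a trained
  accessibility model; compaction results with it demonstrate the
  machinery, not chromatin biology.
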