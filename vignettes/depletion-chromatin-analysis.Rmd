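---
title: "Quantifying chromatin contact and cohesin occupancy shifts after factor depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin contact and cohesin occupancy shifts after factor depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromshift)
```

chromshift implements the downstream statistics of a degron-style
chromatin study: a transcription factor is acutely depleted, and the
question is how cohesin occupancy and 3D genome organization respond.
This vignette is the package's account of the models behind each
statistic, the parameters that matter, what the synthetic-data generator
emulates (and what it does not), and the numerical choices made where the
procedures are conventionally underspecified.

## Coordinate and container conventions

All coordinates are 0-based, half-open `[start, end)`; chromosome order
is always the order declared in the `genome_model()`, never alphabetical.
Contact maps are per-chromosome upper-triangle sparse pixel tables at a
fixed bin size with a state flag (`raw` counts, `balanced`, or `oe`),
per-bin balancing weights, and `NA` weights marking masked bins. Signal
tracks are dense fixed-bin tibbles. Only intrachromosomal contacts are
modeled; interchromosomal records are dropped at load with a message.

## Matrix normalization

**Balancing (`ice_balance`).** Iterative correction assumes sequencing
and mappability biases factorize per bin: the observed count is
`c_ij = t_ij · b_i · b_j` with `t` the true contact frequency. Weights
`w_i ≈ 1/b_i` are found by repeatedly dividing out the square root of
each bin's relative marginal until the unmasked marginals of
`c_ij w_i w_j` agree to within `tol` (default `1e-5` relative; at most
`max_iter = 200` iterations, non-convergence is flagged on the result,
never silent). Low-coverage bins are masked first by a median-absolute-
deviation cut on log marginals (`mad_max = 5`, the convention of
cooler-style balancing); zero-marginal bins are always masked. Weights
are finally scaled so every unmasked row of the balanced matrix sums
to 1. Balancing a balanced matrix therefore returns weights of 1 — an
idempotence the tests assert.

**Distance filtering.** Pairs separated by at most 20 kb are removed
before balancing (`filter_min_distance`, strict inequality: at 25 kb bins
the self-diagonal goes, distance-1 pixels stay). At ~25 kb map
resolution, shorter-range ligation products are dominated by
sub-resolution noise.

**Expected and O/E.** The expected value at bin distance `d` is the mean
balanced contact over *all* unmasked pairs at `d`, counting structural
zeros: omitting them would inflate long-range expectation where pixels
are sparse. The O/E transform divides each pixel by its distance
expectation, so every populated diagonal has mean exactly 1 (asserted to
`1e-9`). Distances whose expectation is zero or undefined (for example
the filtered short range) are treated as *missing*, not as zero, in every
downstream average.

## Compartments and the saddle score

The compartment signal is the leading eigenvector E1 of the Pearson
correlation matrix of the dense O/E map, computed per chromosome over
unmasked bins (pairwise-complete correlations; chromosomes with fewer
than 20 usable bins, or with constant O/E, are skipped with a warning —
degenerate input is flagged, never guessed). The eigenvector sign is
arbitrary, so `orient_eigenvector()` flips it per chromosome whenever its
correlation with an active-chromatin reference track (e.g. H3K27ac
coverage on the same binning) is negative; afterwards positive E1 marks
the A compartment.

`saddle()` ranks bins per chromosome into `n_quantiles = 50`
equal-occupancy E1 quantiles (ties broken by bin index, so the
assignment is deterministic) and pools the mean O/E for every quantile
pair genome-wide. The compartmentalization score is
`(AA + BB) / (2·AB)`, where AA and BB are the pixel-weighted mean O/E
within the top and bottom 20% of bins and AB across the rectangle between
them. Because both off-diagonal rectangles are equal by symmetry, they
are pooled. The score is invariant to global rescaling of the map.

**A selection-bias caveat, and how the tests handle it.** E1 is estimated
from the same pixels the saddle then averages. On maps with *no*
compartment signal this circularity is not harmless: the leading
eigenvector of a noise correlation matrix aligns with whatever random
structure is present, and conditioning the quantile extremes on it biases
the null score (about −0.07 at the 400-bin-per-chromosome scale used
here; the same bias appears on ideal i.i.d. unit-mean matrices, so it is
a property of the design, not of this implementation). The validation
suite therefore measures the saddle with a cross-replicate design: E1
from one Poisson replicate of a planted structure, the saddle on an
independent replicate. Under the null this recovers 1.00 ± 0.01, and the
score rises strictly with the planted compartment amplitude. Real
studies have biological replicates, so the same guard is available in
practice; on deeply sequenced full-size chromosomes the bias shrinks with
the ratio of bins to noise scale.

## Pileups and insulation

`apa()` stacks the `(2F+1)²` O/E window centered on each loop pixel
(default flank `F = 10` bins) and averages cell-wise with per-cell
denominators, so masked source cells dilute nothing. The enrichment score
is the central 3×3 mean — the convention for aggregate peak analysis.
`local_pileup()` is the on-diagonal variant for promoters/enhancers/CTCF
sites; `rescaled_domain_pileup()` pads each domain by its own length
(`pad_factor = 1`), extracts the on-diagonal window and block-averages it
to a fixed grid (block averaging, not interpolation: mass-preserving and
deterministic). Windows that fall off a chromosome are skipped and
counted, never truncated.

`insulation_score()` computes, at each bin, the mean balanced contact in
the `w×w` diamond pairing the `w` bins upstream with the `w` bins
downstream, then reports `log2(raw / chromosome mean of raw)` — the
normalization cworld-style insulation uses; a global rescaling of the
matrix cancels exactly. The window is a free parameter with units of bp.
It should sit well below the domain length scale being probed: a diamond
comparable to the domain size produces a flat insulation valley around
each boundary wider than the valley of a small diamond, which blurs
boundary localization. For the 250–750 kb TADs of the synthetic fixture,
boundary-localization checks use a 50 kb window (2 bins); aggregate
before/after profiles (`aggregate_insulation_delta`) are less sensitive
to the choice.

## Loop statistics and the three permutation nulls

**Merging.** Loop calls from 5/10/25 kb resolutions are merged by
extending every anchor to its enclosing 25 kb bin (anchor midpoint rule)
and deduplicating identical bin pairs, keeping the finest source
resolution as provenance; merging is idempotent.

**Strength.** A single loop's strength is the mean O/E over the central
3×3 block at its pixel — the single-loop analogue of the APA readout —
and the change between conditions is `log2(after/before)`.

**Loop-length GSEA.** Loops are ranked by decreasing length; the classic
unweighted running sum gains `1/n_hits` at hits and loses
`1/(N − n_hits)` elsewhere, and the enrichment statistic is the signed
maximum deviation. The null permutes hit labels. The implementation
evaluates the extremum only at hit positions (where the running sum can
peak), which makes each permutation O(n_hits).

**Anchor-element enrichment.** Observed: element peaks overlapping loop
anchors. Null: every loop relocated uniformly on its own chromosome,
preserving length and anchor widths (relocation across chromosomes would
make long loops infeasible on short chromosomes and change per-chromosome
composition). Enrichment is observed over null mean.

**Gene-category enrichment.** Genes are assigned to a loop when their
TSS lies in the loop span; the per-category fraction is divided by the
genome-wide fraction, and the same length-preserving relocation builds
the null (default 10 000 rounds). The p-value is two-sided (doubled
smaller tail). All permutation p-values use the add-one correction
`(1 + #{null ≥ observed}) / (1 + n_perm)`, are reproducible bit-for-bit
under a seed, and calibrate to the nominal level: under their nulls both
tests reject at 5% with empirical rates inside [0.03, 0.07] (1000
replicates in the test suite).

**Responsive loops.** Candidates are loops strictly longer than 500 kb.
Each is scored by the sum over contained ATAC peaks (midpoint
containment — deterministic and boundary-stable) of the TF ChIP signal at
the peak plus the absolute cohesin log2 fold change. Responsive loops are
the `top_n = 500` highest-scoring candidates containing at least one TF
peak and one down-regulated cohesin peak; less-responsive are the bottom
scorers containing neither. Down-regulated cohesin peaks are *inputs*
(a differential-binding caller's labels): the differential model itself
is out of scope here. Ties break by (score, chromosome order, start), so
the classification is deterministic, and it matches an exhaustive
brute-force oracle on random instances.

## ChIP quantification, ChIP-MS, 4C

RPGC scaling multiplies a coverage track by `genome_size / total
coverage` so mean per-bp coverage is 1; spike-in scaling multiplies by
`reference spike reads / sample spike reads`, which removes planted depth
differences to within a few percent in the generator's paired designs.
Feature matrices are strand-aware (minus-strand rows are column-flipped)
and length-weighted over track bins. Peak annotation applies the fixed
priority promoter > enhancer > CTCF site > gene body > other, after
building the element sets with their exclusion rules (promoters are
TSS ± 1 kb; enhancers are active peaks off promoters; CTCF sites are
CTCF peaks off both). Row z-scores use the sample SD (n−1); constant
rows come back as zeros, flagged. Differential-signal clustering is
Ward-linkage hierarchical clustering (`stats::hclust`, `ward.D2`) with
the elbow chosen as the k maximizing the second difference of the
within-cluster dispersion over the candidate range — both the linkage and
the elbow criterion are exposed because "hierarchical clustering with an
elbow" underdetermines them.

ChIP-MS: isoform PSM counts are summed per protein; candidates require
total ChIP PSMs at least twice the input total (proteins seen only in
ChIP qualify; the ratio is configurable because "at least twice more
than" admits a stricter reading); the display value is
`log2((chip + 1)/(input + 1))`. ChIP-qPCR percent input is
`100 · f · 2^(ΔCt)` with `f = 0.05` by default.

4C profiles on 50 bp bins are smoothed for display with a centered
moving mean spanning 5 kb — exactly `span/bin` bins, so an impulse
spreads to a plateau of `v/(span/bin)`; windows shrink at chromosome ends
rather than zero-pad, avoiding artificial dilution at termini.
Quantification always uses the *unsmoothed* track: the mean over a region
of interest divided by the mean over a far-cis background region.

## The synthetic-data generator

`sim_config()` fixes the study conditions: two 10 Mb chromosomes at
25 kb bins (400 bins each), 2×10⁶ total pairs, distance decay
`(d+1)^(−α)` with α = 1 (the classic fractal-globule-range scaling
exponent), lognormal bin biases (σ = 0.2), plaid compartments
`exp(A·e_i·e_j)` with A = 0.5 on 500 kb blocks, tiled TADs of 250–750 kb
with within-TAD contrast τ = 1.5, and focal loops of strength 2. Counts
are Poisson; biases are multiplicative — exactly the assumptions
balancing is built on, which is what makes parameter recovery a fair
test of the estimators. At this scale every acceptance run finishes in
minutes on one CPU.

Two generator semantics deserve explicit statement:

* **Loop strength is defined in the APA currency.** The planted bump is
  a Gaussian of radius 1 bin whose amplitude is normalized so the mean
  planted enrichment over the central 3×3 pixels equals the
  `loop_strength` parameter. Without the normalization, "strength 2"
  would plant a 3×3 mean of only 1.54 and no estimator could honestly
  report 2. Defining the parameter as the quantity APA measures makes
  recovery well-posed.
* **Recovery is assessed under single-parameter isolation.** APA
  recovery runs on maps with compartments and TADs at their null
  settings. With the full structure on, planted loops that straddle TAD
  boundaries are diluted by the same-TAD component of the distance
  expectation (about 10% at these settings) — a real property of O/E
  pileups on structured genomes, documented here, not an estimator
  defect. Null configurations (A = 0, τ = 1, strength 1, PSM ratio 1,
  reduction 1) drive every downstream statistic to its null value, which
  the tests verify.

The paired-perturbation generator plants: responsive and less-responsive
long loops (550 kb–1 Mb) in non-overlapping territories per chromosome,
each seeded with dedicated genes (TF-bound with ATAC peaks and
down-regulated cohesin in the responsive class; unbound in the
less-responsive class); background loops at or below the 500 kb
classification threshold, mirroring the observation that the longest
loops carry the depletion response; a cohesin track whose signal at
TF-bound promoters is multiplied by the reduction factor (0.5 by
default, so the measured log2FC recovers ≈ −1); and gene expression
categories enriched for down-regulation inside responsive loops. The
cohesin log2FC attached to ATAC peaks is *measured* from the two
rendered tracks, not copied from the plan, so classification runs on the
same kind of noisy evidence a real analysis would see.

What the generator does **not** emulate: read-level artifacts (ligation
chemistry, duplicates, mapping), trans contacts, copy-number structure,
nested sub-TADs, condition-dependent compartment shifts, and peptide
identification noise beyond Poisson counts. Passing tests therefore show
that the estimators recover planted parameters under the stated
generative model — they do not certify performance on artifacts the
model excludes.

## Numerical choices and degenerate inputs

* Quantile ties in the saddle, score ties in classification, and equal
  signals in bound/unbound gene selection all break deterministically
  (bin index, genome order, gene id).
* `0/0` situations are flagged `NA`, never silently 0: anchor enrichment
  with empty observed and null overlap, 4C ratios over a zero
  background, fully masked loop centers.
* Insulation at a structural-zero diamond is `−Inf` (a genuine minimum),
  and bins whose diamond does not fit are `NA`.
* The GSEA running-sum extremum is evaluated analytically at hit
  positions; permutation draws use R's default generator under
  `set.seed`, so results are bit-reproducible per seed.
* `downsample_pairs` uses a single multinomial draw, which conserves the
  target total exactly and preserves per-pixel proportions in
  expectation.

## Known limitations

The eigenvector selection bias discussed above affects same-data saddle
scores near the null on small matrices. The elbow criterion for cluster
number inherits the usual elbow ambiguity when the k = 1 to 2 drop
dominates; the dispersion curve is returned so the choice can be
inspected. Insulation boundary localization degrades when the diamond
window approaches the domain length. The pipeline treats loop calls,
differential-peak labels and expression categories as trusted inputs;
errors in those upstream calls propagate untested.
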