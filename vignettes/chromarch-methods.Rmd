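---
title: "Methods: two-condition comparison of multiscale Hi-C architecture"
author: "chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition comparison of multiscale Hi-C architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chromarch` compares three-dimensional genome organization between two
conditions (for example a control and a stress treatment) from binned Hi-C
contact data, at the three scales the field distinguishes: megabase-scale
A/B compartments, sub-megabase topologically associating domains (TADs),
and kilobase-scale chromatin loops, and then asks how changes at each scale
relate to differential gene expression. Everything downstream of binned
contacts is implemented here; read processing, peak calling and
differential-expression testing are consumed as inputs (pair lists, BED
intervals, a gene table with FPKM values and DEG labels).

Because real two-condition Hi-C experiments come with no ground truth, the
package ships a synthetic-data generator that plants a known architecture —
compartment checkerboard, TAD blocks, focal loops, and matched gene,
histone-mark and DNase-hypersensitivity tracks — so that every stage of the
pipeline can be scored against what was planted. The generator is
first-class, tested code, not a fixture.

# The contact-matrix model

Contacts are stored per chromosome as symmetric matrices on a fixed binning
(`BinnedGenome`; 0-based half-open coordinates, bin = `floor(pos/binSize)`,
partial last bins kept at true length). Preparation follows standard
practice:

* **Depth normalization** scales two maps to the smaller total so that
  differential statistics compare rates, not library sizes.
* **Masking** removes bins whose marginal is below `minFraction` (default
  0.1) of the median positive marginal; the rule is scale-free.
* **KR balancing** finds x > 0 with `diag(x) M diag(x)` having equal
  unmasked row sums, via the Knight-Ruiz inner-outer Newton iteration
  (inner conjugate-gradient solve; tolerance 1e-6 on the residual norm,
  up to 1000 outer iterations, failure is an error rather than a silent
  fallback). Masked bins are excluded from the computation, not
  zero-imputed.
* **O/E** divides every diagonal by its unmasked mean, removing distance
  decay; each O/E diagonal has mean 1 by construction and the transform is
  invariant to global scaling.

Matrix-level comparisons include the distance-decay curve P(s) (log-spaced
distance bins; a pure power law of exponent a has log-log slope -a), the
log2 differential map `log2((a+1)/(b+1))` (pseudocount of one raw-count
equivalent keeps sparse pixels bounded; the map is antisymmetric under
swapping conditions), the stratum-adjusted correlation coefficient (SCC:
per-distance Pearson correlations after a 3x3 mean filter, combined with
weights `N_d * sqrt(var_a var_b)`), and sliding-window structural
similarity: per 500 kb window the SSIM index (luminance-contrast-structure
form, stabilizers `c1=(0.01 L)^2`, `c2=(0.03 L)^2` with L the dynamic range
of the two log2 O/E windows) is z-scaled per chromosome, so low z marks the
windows whose local contact structure changed most. The z-normalization
scope (per chromosome) is recorded in the output because a genome-wide
variant would mix chromosomes of different noise levels.

A caveat the synthetic benchmark makes explicit: a window that sits wholly
inside a switched compartment block looks *identical* before and after the
switch (same-label pairs keep the same contact factor), so structural-
similarity z-scores respond to switch-block edges and boundary changes, not
to the interior of large switched blocks.

# Compartments

PC1 is the leading eigenvector of the Pearson correlation matrix of the
per-chromosome O/E map (correlation, not covariance, which stabilizes
against marginal effects), scaled by the square root of its eigenvalue.
Signs are fixed per chromosome against an active-chromatin track (H3K27ac
coverage; gene density as fallback): positive PC1 = A compartment.

The saddle statistic ranks bins by PC1 and averages O/E over percentile-
class pairs (2% classes, intra-chromosomal pairs at least 2 bins apart).
Ranking is per chromosome: eigenvectors carry an arbitrary per-chromosome
scale, and genome-pooled ranking can put every extreme-A bin on one
chromosome and every extreme-B bin on another, leaving the AB corner of
the saddle empty. With AA and BB the mean O/E over the 10 extreme classes
on each side (20% of bins per corner, configurable) and AB the pooled
off-corners, compartment strength is

    strength = ln( AA * BB / AB^2 )

which is 0 for a structureless map and increases with checkerboard
contrast; on the synthetic sweep it is strictly monotone over planted
amplitudes 0, 0.25, 0.5, 1. Per-bin switch classes (A-to-A, A-to-B,
B-to-A, B-to-B) are reported as bp over jointly unmasked bins.

# TADs

The insulation score of bin i at window w is the mean unmasked contact in
the square `[i-w, i) x [i, i+w)`. Windows run 20-300 kb in 5 kb steps by
default; per window the log2 ratio to the chromosome mean is z-scaled per
chromosome, and the per-bin combined score is the mean over windows
(available windows near chromosome ends; a bin inside the smallest window
of an end stays NaN). Lower combined score means stronger insulation.

Boundaries are local minima of the combined score that pass two filters:
a prominence filter (`delta` = mean score over 10 flanking bins each side
minus the minimum, default threshold 0.01) and a contact test. The contact
test is a one-sided Wilcoxon rank-sum comparing the crossing square
against the pooled flanking triangles **on the O/E transform** — on raw
contacts the crossing square spans genomic distances up to 2w while the
triangles stop at w, so distance decay alone makes every candidate look
insulated. The test window is a fixed 40 kb (domain scale): a
chromosome-scale window dilutes the signal of a boundary between small
TADs. The test is evaluated at *every* eligible bin and BH-adjusted
genome-wide before intersecting with the minima, so the false-discovery
guarantee is not distorted by the fact that minima are selected for low
scores; on structureless matrices the caller returns essentially nothing
at FDR 0.01.

Consensus between conditions matches boundaries greedily by increasing
shift (ties broken leftmost-first, each boundary used once) within a
2-bin window; the conserved count is symmetric in the input order.
Differential TADs compare the intra-TAD triangle and both flanking
rectangles between conditions with rank-sum tests (mode `"all"` demands
all available tests significant, `"one"` any). A TAD is mark-enriched when
it overlaps at least one peak and its mean signal ranks in the top 25%
across TADs — both conditions are required, so a peak-free genome yields
no enriched TADs regardless of signal.

# Loops

Loop calling works on raw contact-pair coordinates. Candidates come from
DBSCAN under the Chebyshev (box) metric in (pos1, pos2) space, run for
every (eps, minPts) combination (defaults 2000/5000/10000 bp x 20/50);
pairs closer than `2*max(eps)` are removed as self-ligation, and clusters
whose anchor span exceeds `6*max(eps)` are discarded as diffuse — at deep
coverage the near-diagonal background forms one giant cluster that is not
loop-like.

The significance stage guards against two scan biases that dominate at
benchmark depth. First, candidate boxes are padded to at least
`1.5*max(eps)` before counting: a bounding box shrink-wrapped around a
random clump of points otherwise beats any honest background. Second, the
Poisson upper-tail p of the observed count against the expected count
(50/50 blend of the local background — same-size boxes shifted along the
diagonal by 5 and 10 anchor widths — and the empirical distance-decay
rate) is Bonferroni-scaled by the number of window-sized tiles on the
chromosome before BH adjustment: the clustering stage effectively scanned
every window position, and an uncorrected tail of 1e-4 is meaningless
among tens of thousands of windows. Kept loops need q <= 0.01 and at least
2-fold enrichment. Surviving candidates from the different runs are then
merged, smallest eps (tightest box) first; merging after the filter
matters, because merging before it lets weak noise boxes from small-eps
runs shadow genuine loops found at larger eps. On structureless synthetic
pairs the caller returns zero loops.

APA averages O/E submatrices centered on loop bin pairs (half-width 10
bins); the score is the center pixel over the mean of the 3x3 corner at
shorter distance, the conservative background. Differential loops
subsample both pair lists to equal depth (seeded) and compare each union
loop's padded anchor counts (n1, n2) against its local background counts
(b1, b2) with a two-sided Fisher exact test on [n1 n2; b1 b2] — the
conditional two-sample Poisson rate comparison. A plug-in binomial test
against the estimated background ratio is anticonservative because it
ignores the background's own sampling noise. Loops significantly weaker in
condition 2 (p < 0.01, following the convention for this analysis) are
lost, stronger ones gained; labels swap when the conditions swap. On
replicate-level data (two samples of one truth) a handful of borderline
raw-p calls remain, because the anchors themselves were placed by one
condition's sample; the BH-adjusted q column removes them.

# Integration with genes, marks and accessibility

Promoters are the 2 kb upstream of the TSS, strand-aware (minus-strand
promoters sit at the end coordinate). Enrichment of DEGs in a feature set
uses the two-sided Fisher exact test with the genome-wide DEG prevalence
as the control (background includes the foreground, matching the usual
"overall prevalence" control; an exclusive variant is available).
Interval-permutation enrichment relocates each query interval uniformly
within its own chromosome (length-preserving, chromosome-preserving, no
non-overlap constraint) and reports the empirical p
`(1 + #{perm >= obs}) / (nPerm + 1)` together with a mid-p that
half-weights ties: the overlap fraction is a discrete statistic, so the
conservative formula sits above uniform under the null while the mid-p is
calibrated (the package's calibration check verifies near-uniformity of
the mid-p over 200 replicate runs). The genome-reorganization summary is
the deduplicated union of DEGs in switched compartment bins, in
condition-specific boundary flanks (boundary bin +- 2 bins by default; the
flank is exposed because conventions differ), or with promoters at
differential loop anchors, as a fraction of all DEGs.

# The synthetic generator

`architectureConfig()` fixes the benchmark conditions used throughout the
package's tests and acceptance script: a 10 Mb genome (two 5 Mb
chromosomes) binned at 5 kb, power-law decay exponent 1, compartment
checkerboard amplitude 0.5 in alternating blocks of geometric length
(mean 200 bins = 1 Mb), TADs with geometric sizes (mean 40 bins = 200 kb,
minimum 6 bins = 30 kb — domains below the smallest insulation window
cannot exist at the emulated resolution), 80 focal loops at 5-fold
enrichment on their 3x3 bin neighborhood with log-uniform anchor
separations of 60 kb-1.5 Mb (anchors inside TAD interiors, loops may span
TADs), and Poisson sampling at 5e6 expected pairs. The paired condition
flips whole compartment blocks until 15.5% of bins have switched (9:1
A-to-B bias), loses and gains 30% of boundaries, and deletes 30% of loops
with probability proportional to distance squared (long-range-biased loss)
while adding 0.8 new short-range-biased loops per lost one. Genes
(125/Mb) land with 2:1 per-bin density in favour of A — about 70% of genes
in A when the genome is half A, and robust to the realized A share — with
log-normally higher expression in A; 9.5% are DEGs at baseline, boosted
2-fold near changed boundaries (up-biased at gains, down-biased at losses)
and lost-loop anchors; H3K27ac peaks sit at TSSs of high-expression genes,
H3K27me3 domains over low-expression gene blocks, and DHSs at every loop
anchor plus background sites. All draws are deterministic given the
config seed, and the exact change sets are recorded for recovery scoring.

What the generator does *not* emulate — restriction-fragment structure,
mappability and GC biases, inter-chromosomal contacts, diploid effects,
nested TAD hierarchies, condition-specific compartment-strength changes —
bounds what a passing benchmark shows about real data: it validates the
statistical machinery on data whose generative model matches the methods'
assumptions, not the robustness of those methods to every artifact of a
real library.

Each architectural layer is benchmarked on a map where the other layers
are flat (compartments at TAD-enrichment 1 and no loops; TADs at amplitude
0 and no loops; loops at amplitude 0 and TAD-enrichment 1), so recovery
errors attribute to the stage under test; the full-structure map is
exercised end-to-end in the pipeline tests. Benchmark problem sizes —
10 Mb, 5 kb bins, 5e6 pairs, 200 permutation-calibration runs at
nPerm = 199 — are the package's chosen trade-off between statistical
resolution and a test suite that runs in minutes.

# Known limitations

* Intra-chromosomal analysis only; `.hic`/`.cool` binary dialects are not
  read or written (COO text, dense TSV, BED/bedGraph/BEDPE and pair lists
  are).
* The boundary caller reports one boundary per insulation minimum; nested
  or hierarchical domains are out of scope, as are directionality-index
  and arrowhead-style callers.
* Compartment calling assumes at least ~20 usable bins per chromosome at
  the compartment resolution; very short scaffolds are rejected.
* The loop significance model is a documented re-implementation of the
  density-clustering approach in simplified form, with its background
  model (local boxes + decay blend, scan correction) stated here rather
  than inherited from any external tool; parameter choices are exposed.
* Differential-loop anchors inherit the calling condition's box placement;
  raw-p labels at the margin should be read alongside the q column.

# Running the full comparison

`runComparison(comparisonConfig(...))` executes matrix preparation,
compartments, TADs, loops and integration for a pair of conditions and
returns (optionally writes) a versioned JSON report with all thresholds
echoed; the per-stage functions are the same ones exported to users, so
any stage can be reproduced interactively from the same inputs.

```{r}
library(chromarch)
cfg <- architectureConfig(seed = 1)
normal <- generateArchitecture(cfg)
cold <- perturbCondition(normal, cfg)
cmN <- sampleContacts(expectedIntensity(normal, cfg), normal@grid,
                      cfg$depth, seed = 2, pairs = TRUE)
cmC <- sampleContacts(expectedIntensity(cold, cfg), cold@grid,
                      cfg$depth, seed = 3, pairs = TRUE)
report <- runComparison(comparisonConfig(
  pairs1 = attr(cmN, "pairs"), pairs2 = attr(cmC, "pairs"),
  chromSizes = chromSizes(normal@grid), genes = cold@genes,
  markPeaks = normal@markPeaks, dhs = normal@dhs, seed = 4))
```
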