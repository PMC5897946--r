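---
title: "Methods: spot quantification, clustering statistics and variance-component QTL mapping"
author: "salmospot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot quantification, clustering statistics and variance-component QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`salmospot` implements a complete pipeline for studying melanin spot
patterns on the flanks of Atlantic salmon (*Salmo salar*) and their
genetic basis: image-based spot quantification in a standardized,
landmark-anchored region of interest (ROI); the Clark-Evans average
nearest-neighbour (ANN) index of spot aggregation; and a pedigree-based
variance-component QTL scan with REML mixed models, position-wise
identity-by-descent (IBD) matrices and Churchill-Doerge permutation
thresholds.  A synthetic-data module simulates point patterns, rendered
images and multi-strain half-sib cohorts with known ground truth, so that
every downstream stage is testable without any external data.

This vignette records the models, the assumptions behind them, the
numerical choices, and the places where a design decision was genuinely
open.  It states no empirical result that the package's tests or
`scripts/acceptance.R` do not themselves compute.

# Spot quantification

## ROI construction

The measurement rectangle is anchored to four anatomical landmarks
supplied with each image: the gill crease, the front of the dorsal fin,
the lateral line and the top of the pectoral fin.  An initial rectangle
spans horizontally from the gill crease to the dorsal-fin front and
vertically from the lateral line down to the pectoral-fin top; the final
ROI keeps this width and height but is translated vertically so that its
vertical midline sits on the lateral line.  Pixels are 0-based and
rectangles half-open, `[x0, x0 + w) x [y0, y0 + h)`; physical units come
from a single isotropic scale (cm per pixel) supplied per image.  The
lateral line is treated as a horizontal row across the ROI span;
curvature is out of scope.  Landmarks outside the image are an error, not
a clip: a silently clipped ROI would bias the density denominator.

## Spot detection

Detection is deliberately simple and fully parameterized, because the
original macro-based analysis does not publish its internal settings:
grayscale conversion, binarization (Otsu's threshold on the ROI histogram
by default, with a fixed-threshold override), 8-connected component
labeling, and a minimum-area filter (default 0.005 cm^2, configurable).
8-connectivity matches the diagonal-touch behaviour of common
particle-analysis tools.  The labeling is compiled code; the test suite
checks it against an independent pure-R flood-fill oracle on randomly
generated images.

## Densities and exclusion rules

Spot counts scale strongly with fish size, so counts are normalized:
automatic counts by ROI area (spots/cm^2), manual head counts by body
weight (count/g).  Three exclusion rules are applied explicitly and
logged per fish: fish with zero spots are excluded from density analyses
(the ROI denominator is only meaningful when spots exist) rather than
scored 0; fish with fewer than ten spots are excluded from ANN analyses
(aggregation is noise-dominated at low counts; a fish with exactly ten is
retained); and single-member families are excluded from family-variance
models.

# Spot clustering: the ANN ratio

For `n >= 2` points in a window of area `A`, the ANN ratio is the mean
nearest-neighbour distance divided by its expectation under complete
spatial randomness, `0.5 / sqrt(n / A)`.  Values below 1 indicate
aggregation, above 1 over-dispersion.  Three conventions are declared
rather than assumed silently:

* **No edge correction by default.**  The plain Clark-Evans ratio is
  mildly biased upwards because points near the boundary lack neighbours
  beyond it.  A Donnelly-corrected expectation is available behind
  `edge_correction = "donnelly"` for sensitivity analysis, but the
  uncorrected form is the default and the one all reported numbers use.
* **The window is the measurement rectangle** (the ROI, or the simulated
  pattern window), not the convex hull of the points: the geometry of the
  measurement, not of the realization.
* **Classification labels are descriptive only** (clustered / random /
  scattered around ratio 1, zero tolerance); no CSR hypothesis test is
  attached.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; they are first-class, tested code.

## Point processes

Three planar processes emulate the observed spot regimes: homogeneous
Poisson (scattered-to-random, high density — the hatchery-like regime, at
the scale of ~1.5 spots/cm^2), a Thomas cluster process (clustered, low
density — the river-like regime, ~0.2-0.8 spots/cm^2 scale), and a
hard-core (random sequential adsorption) process for over-dispersion.
The Thomas process was chosen for the clustered regime because Gaussian
offspring dispersal around Poisson parents is the simplest mechanism
producing compact aggregates; parents are simulated in a window dilated
by four dispersal standard deviations so edges are not artificially
thinned.  Neither choice is a claim about the biology of pattern
formation in salmon skin: they are controllable fixtures whose direction
of aggregation is known, which is exactly what the directional tests
need.  Intensity always means expected points per cm^2 of the final
pattern; for the Thomas process the parent intensity is
`intensity / mean_per_cluster`.

## Rendered images

`render_spot_image()` draws dark disks on a light background and embeds
landmarks placed so the constructed ROI covers the pattern window
exactly; with zero pixel noise the image round-trips through PNG
losslessly.  This gives the quantification stage a closed loop: pattern
in, count out, truth known.  Real photographs differ in ways the renderer
does not emulate — uneven illumination, scale variation, fish curvature,
spot shape irregularity — so passing tests demonstrate correctness of the
measurement chain, not robustness to field imaging conditions.

## Pedigree, gene dropping and phenotypes

The default cohort mirrors a hatchery-scale common-garden design: 6
strains/crosses x 6 full-sib families x 20 offspring = 720 phenotyped
fish, with half-sib links (consecutive families within a cross share a
sire).  Genotypes are gene-dropped over a sparse regular map (default ~15
linkage groups x 7 markers at 25 cM — about a hundred SNPs at the 20-30 cM
spacing typical of sparse genome scans), using the Haldane map function
(no interference), the simplest model consistent with such a sparse map.
Founder alleles are drawn at a configurable frequency (default 0.5,
maximizing marker informativeness).

Phenotypes decompose as strain effect + polygenic breeding value +
additive QTL effect + residual, with total variance 1.  Strain enters as
a fixed shift by default (matching its role as a fixed effect in the QTL
models) with an option to draw it as a random component (matching the
strain/family variance-split analysis); both usages occur in practice and
are kept distinct.  Breeding values descend by parent-average plus
Mendelian sampling, giving exactly the additive-relationship covariance
for non-inbred pedigrees.  The QTL is a biallelic locus placed on a
marker by default — so IBD at the QTL can be made fully informative — with
an off-marker option that exercises interpolation.  Recorded "realized"
components are second moments about the construction mean, which are
unbiased for the generative variances even though relatives shrink the
in-cohort sample variance.

# The genetic analysis

## Relationship and IBD matrices

The numerator relationship matrix **A** uses the tabular method
(`a_ii = 1 + a_sd/2`, `a_ij` = half the sum of the relationships to the
parents).  Position-wise IBD matrices come from nuclear-family haplotype
reconstruction: per meiosis and marker, the transmitted allele is
resolved from the trio genotypes where possible; a heterozygous parent
with a resolved transmission is informative.  Parental phase is chained
along each linkage group by majority concordance of transmissions across
the parent's meioses (pooling across families for half-sib parents), and
origins propagate as a two-state Markov chain under Haldane
recombination — an uninformative marker takes the origin probability
implied by its nearest informative flanking markers.  The recursive
pedigree-IBD algorithm of the wider literature is deliberately replaced
by this Lander-Green-style nuclear-family model: the study design is two
generations with unrelated founders, where the two coincide, and the
flanking-marker posterior is exact for that case.  Mendelian-inconsistent
trios are flagged, silenced for that meiosis, and reported once as a
warning.

Pair IBD then follows definitionally: each shared parent contributes one
half times the probability that the two offspring received the same
parental haplotype; parent-offspring pairs share 1/2; founders are
assumed unrelated and non-inbred.  `true_ibd_matrix()` builds the same
matrix from simulation ground truth (fully informative), which is what
parameter-recovery tests use to separate estimator behaviour from
haplotype-reconstruction noise; the scan itself always uses the estimated
matrices.

## The mixed models

The QTL model at a genomic position is a Gaussian linear mixed model

  y = X b + a + q + e,  a ~ N(0, s2_a A),  q ~ N(0, s2_q Pi),
  e ~ N(0, s2_e I),

compared against the polygenic-only model (no `q`) by a restricted
likelihood-ratio statistic, floored at zero.  The hierarchical-model
formulation with adjusted profile likelihood that this mirrors coincides
with Gaussian REML for Gaussian responses; that interpretation is the
package's declared reading.  Fixed effects default to intercept + strain;
no replicate or tank effects are modelled.

Numerics (all declared, none silent):

* Variance components are optimized on the log scale; residual scale is
  profiled out analytically in the scan path, reducing the dimension by
  one.  Boundary handling: components below `1e-8` of the total snap to
  zero.
* Convergence tolerance is `1e-8` on the restricted log-likelihood; the
  general-purpose fitter uses Nelder-Mead with a generous evaluation cap
  and an equal-split start plus (for the full model) a warm start at the
  null-model optimum with a near-zero QTL variance.  The warm start
  guarantees the full model's likelihood cannot fall below the null's
  beyond tolerance, so LRT >= 0 holds structurally.
* The likelihood is evaluated block-wise over the connected components of
  the relatedness graph (families linked by shared parents).  This is
  exact — the covariance matrices are block diagonal — and is what makes
  full-REML permutation thresholds affordable; the scan path additionally
  keeps all optimizer iterations in compiled code.
* PSD of user-supplied structures is checked by a ridged Cholesky
  (`1e-7` relative ridge); scan internals check once and then skip.

## Scan grid and permutation thresholds

The scan grid is every marker plus regular steps (default 5 cM; the
original analysis does not state its grid).  Genome-wide significance
uses Churchill-Doerge phenotype permutation: `y` is shuffled against the
fixed (pedigree, genotype, design) structure, the maximum LRT per shuffle
is recorded, and the threshold is the smallest observed maximum whose
empirical exceedance is at most alpha; the genome-wide p of an observed
statistic is `(1 + #{max >= obs}) / (n_perm + 1)`.  Default
`n_perm = 1000` (the source analysis reports only "p < 0.01"; 1000 is the
smallest round count that resolves that quantile comfortably).

Phenotype permutation assumes exchangeability of `y` under the null.
Strain fixed effects, polygenic covariance and family structure all break
exchangeability, which is a known limitation of the procedure itself, not
of its implementation.  The calibration suite therefore simulates fully
exchangeable nulls (all variance residual): it calibrates the permutation
machinery under the conditions where its own assumption holds.  On
structured nulls the realized size can drift from nominal; that behaviour
belongs to the method and is left visible rather than patched.

## Heritability and QTL variance fractions

Narrow-sense heritability is `s2_a / (s2_a + s2_q + s2_e)` (the QTL term
included when fitted); the QTL is summarized both as a fraction of
genetic variance `s2_q / (s2_q + s2_a)` and of total variance.  Strain is
a fixed effect and therefore not part of the phenotypic variance in these
ratios.

## Allele contrasts

For a parent informative at a position, offspring are grouped by the
inherited parental haplotype (posterior origin probability beyond 0.8
either way; less certain meioses are left out) and the group means of the
trait are contrasted with a Welch test, optionally stratified by the
mate's strain background.

# Cohort-level statistics

The strain/family variance split uses `lme4::lmer` with random strain and
family-within-strain intercepts — family is nested because families never
cross strains in the breeding design.  Group comparisons go through the
standard routines: Welch t (fractional df), Mann-Whitney in its
large-sample uncorrected form (so the two-group Kruskal-Wallis test is
exactly its square), Kruskal-Wallis, and one-way ANOVA reported as R^2.
Fold differences between group means are rendered by one explicit
convention (round to one decimal; integer roundings collapse to the
spelled form, "sevenfold") because reported prose mixes styles.

# Problem sizes used by the test suite

Chosen so the suite exercises each claim at a meaningful scale:

* Calibration of the permutation test: 200 exchangeable null cohorts of
  n = 200 (2 crosses x 5 families x 20), 3 linkage groups x 3 markers at
  25 cM, scan at markers, `n_perm = 200`, checking the empirical
  genome-wide rejection rate at alpha = 0.05 and the uniformity of the
  genome-wide p.
* Parameter recovery: the default 720-fish design, heritabilities
  {0.06, 0.30, 0.54} with a QTL at 11% of genetic variance, 20 replicates
  per point, fully informative IBD at the QTL.
* Directional ANN checks: 200 Thomas and 200 hard-core patterns in a
  40 cm^2 window.

# Known limitations

* The renderer does not emulate field imaging artifacts; detection
  robustness on real photographs depends on threshold choice, which is
  exposed rather than guessed.
* Head-region spot counting is manual by design; only the
  weight-adjustment of supplied counts is implemented.
* The IBD model covers two-generation nuclear-family designs with
  unrelated, non-inbred founders; deeper pedigrees would need the general
  recursive algorithm.
* Permutation thresholds inherit the exchangeability assumption discussed
  above.
* Single-QTL models only; no epistasis, no marker-based genomic
  relationship alternative.
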