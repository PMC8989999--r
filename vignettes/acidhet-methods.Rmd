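---
title: "Methods: quantifying heterogeneity of acid-resistance reporters"
author: "acidhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heterogeneity of acid-resistance reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidhet)
```

## The measurement model

*E. coli* protects itself against acid stress with three inducible
decarboxylase/antiporter systems (Gad, Adi, Cad). Translational fusions of
each antiporter to a fluorophore (GadC:eGFP, AdiC:mCerulean, CadB:mCherry)
turn per-cell fluorescence into a proxy for system activation, and the
distribution of those intensities across a population is the object this
package analyses.

The measured intensity of cell $i$ in channel $c$ is modelled as

$$x_{ic}^{\text{meas}} = x_{ic}^{\text{true}}
  + \sum_{d \ne c} f_{cd}\, x_{id}^{\text{true}} + b_{F(i),c},$$

a latent true signal, plus linear additive spectral bleed-through from
donor channels with proportionality factors $f_{cd}$, plus a background
level drawn once per field of view $F(i)$ and channel. The processing
chain inverts this model term by term:

1. **Background subtraction** removes $b_{F,c}$ per field (the imaging
   pad's level; when images are available it is estimated as the median of
   non-cell pixels, otherwise supplied with the table).
2. **Crosstalk correction** subtracts $\hat f \cdot x_d$ from the receiver
   channel. $\hat f$ is the zero-intercept least-squares slope
   $\sum x_d x_r / \sum x_d^2$: a pure bleed-through model has no offset
   once background is gone, which is why the intercept is fixed at zero.
   The experimentally determined value for the eGFP←mCerulean pair in this
   setup is 0.456; it is a configuration value, never hard-coded as truth.
3. **Brightness normalization** multiplies each channel by
   $B_{\max}/B_c$ (eGFP 33, mCerulean 16, mCherry 15) so the three
   fluorophores plot on a comparable nRF scale. "Normalized to the highest
   values" admits a second reading — rescaling a population to $[0,1]$ by
   its own maximum for histogram axes — so both operations exist and are
   separable (`normalize_brightness()`, `max_scale()`); the analysis uses
   the brightness-relative one.

## The noise statistic

Heterogeneity is summarized per sample as

$$\text{noise} = \frac{\operatorname{sd}(y)}{\operatorname{mean}(y)},
  \qquad y_i = \ln(x_i + 1).$$

The log transform makes the coefficient of variation meaningful for the
non-normal, right-skewed Cad distributions and damps the inflation of CV
at low expression. Numerical conventions (the data do not pin them down,
and they are stated here once): the natural logarithm — sd/mean of
logarithms is base-invariant up to the additive offset, so the choice is
cosmetic; the sample ($n-1$) standard deviation; the offset $+1$ keeps
$y$ finite at $x = 0$ and is configurable (`log_offset`). Negative
intensities produced by subtraction are measurement artifacts and are
clipped to 0 by default (`clip_negative`), since $\ln(x+1)$ needs
$x > -1$.

A constant sample has noise exactly 0; an all-zero sample has
$\operatorname{mean}(y) = 0$ and the statistic is reported as an explicit
error rather than an `Inf`.

## ON/OFF calling, correlations, histogram comparison

The source data report ON fractions (83% CadB, 47.7% AdiC, 99% GadC at
pH 4.4) without stating the calling rule. The package adopts a
control-based threshold: a cell is ON when its intensity exceeds
$\text{mean} + k \cdot \text{sd}$ of a non-tagged control population
measured alongside ($k = 3$ by default, configurable). This matches the
observation that untagged cells show only low background fluorescence,
and it is monotone in $k$ by construction.

Inter-system dependence is measured with Pearson's $r$ on per-cell nRF
values (the correlation figure axes are nRF), with the two-sided p-value
from the $t$ transform at $n-2$ degrees of freedom. Distribution shapes
are compared with a chi-square homogeneity test on shared equal-width
histograms; because the test's sampling theory needs expected counts
$\ge 5$, bins are pooled from the tails inward (offending bin merged
toward the centre) until that holds, with $B-1$ degrees of freedom on the
final $2 \times B$ table and no continuity correction. The default 20
initial bins is a plotting convention, not a claim from the data.
Skewness uses the population moment estimator $g_1 = m_3/m_2^{3/2}$;
samples with $g_1 > 0.5$ are labelled right-skewed (the Cad signature),
the cutoff being a configurable convention.

Luminescence reporter curves are normalized to relative light units,
$\text{RLU} = \text{counts s}^{-1}\,\text{mL}^{-1}\,\text{OD}_{600}^{-1}$,
with the maximum and its time reported.

## Imaging

Segmentation re-implements the intent of the original tooling (MicrobeJ
defaults) rather than its internals: Otsu threshold on the intensity
histogram, hole filling, connected components, border-touching components
dropped because their shape would be truncated. Per-cell intensity is the
mean over mask pixels — size-independent, matching per-cell "relative
fluorescence" without an integration convention.

Shape descriptors come from the medial axis (Zhang–Suen thinning, ordered
as the longest path through the skeleton):

* width = 2 × mean distance-transform value along the axis;
* length = axis arc length + a spherocylinder cap correction, measured by
  marching from each axis endpoint along the local axis direction to the
  mask boundary (equal to one width on ideal input, and robust when
  thinning over- or under-shoots into the caps);
* curvature = 1 − chord/arc of the axis;
* angularity = mean absolute turning angle per step, divided by $\pi$.

The published gate values (area 0.1–max µm², length 1.2–5 µm, width
0.1–1 µm, curvature 0–0.15, angularity 0–0.25) are closed intervals and
every gate is configurable or disableable, because the original tool's
exact curvature/angularity formulas are not published; the definitions
above reproduce the filtering intent, not the tool bit-for-bit.

Two numerical choices matter here. The raw 8-connected skeleton is a
staircase whose arc length overestimates a tilted straight axis by up to
~8% and whose per-pixel turning angles would mis-classify straight rods as
angular, so the path is subsampled every 3 pixels before measuring. And
thinning can collapse the skeleton of steeply diagonal rods entirely (a
known Zhang–Suen artifact); when the axis-derived length falls below 70%
of the mask's principal-component extent, the measure falls back to that
extent with curvature/angularity 0. On noise-free synthetic rods both
length and width are then accurate to well under 2 pixels.

## Comparative genomics

Homolog hit tables (BLAST tabular) are filtered with strict per-component
e-value cutoffs (antiporters: GadC $<10^{-100}$, AdiC and CadB
$<10^{-120}$; regulators each have their own) and a length tolerance: hit
length within ±10% of the query length. The tolerance is interpreted
two-sided (the source states only "10% of the amino acid length");
one best hit (lowest e-value, ties by accession) is kept per
(component, species), with the table's `species_id` taken as the unit of
counting. Co-occurrence is the percentage of anchor-carrying species that
also carry each component; taxonomy is read from the input table rather
than fetched live, so analyses are reproducible offline.

Tree building follows the classical distance pipeline: p-distance with
pairwise gap deletion, the generalized Jukes-Cantor correction
$d = -\tfrac{a-1}{a}\ln(1 - \tfrac{a}{a-1}p)$ with $a = 20$ for proteins
and $a = 4$ for nucleotides (the original tool's protein JC variant is
undocumented; the equal-rates formula is the standard generalization),
and Saitou–Nei neighbor joining. Saturated pairs ($p \ge (a-1)/a$)
receive a configurable cap distance (default 5 substitutions/site) and a
flag instead of an exception, so a divergent alignment still yields a
tree. Negative NJ branch lengths are clamped to zero with the deficit
moved to the sister branch, preserving the joined pair's path length;
Q-criterion ties break deterministically at the lowest (row, column)
index. Bootstrap supports use Felsenstein column resampling (the
conventional 100 replicates by default), counting how many replicate NJ
trees contain each internal bipartition of the reference tree.

## What the generators emulate — and what they do not

`simulate_population()` reproduces the statistical structure the analysis
assumes: per-channel ON/OFF mixtures (independent Bernoulli per channel),
ON intensities from a normal (Gad/Adi-like) or lognormal (Cad-like)
marginal, latent inter-channel correlation imposed by a Gaussian copula
*before* the marginal transforms (so the stated families are preserved
exactly while the latent correlation hits its target), additive linear
bleed-through, and one Gaussian background draw per field and channel
(the distributional family of background is not reported; Gaussian is
assumed). Both true and measured values are retained so estimators can be
validated against the generating parameters. OFF cells emit only their
`off_level` plus background, consistent with the low fluorescence of
non-tagged controls.

`simulate_images()` renders non-overlapping spherocylinders with uniform
interior intensity, an optional Gaussian PSF and Gaussian/Poisson noise —
the simplest geometry consistent with the shape gates. It does not model
vignetting, chromatic shift, cell growth or motion, so passing tests
establish correctness of the estimators under the assumed model, not
robustness to every real-microscope artifact. Likewise the sequence
evolver uses i.i.d. columns under the equal-rates model matching the JC
correction; real alignments with rate variation or gaps will behave less
cleanly than the tests.

Default study conditions mirror the source design: three channels, three
conditions (pH 7.6, pH 5.8 + 10 mM lysine, pH 4.4) at t0/t150/t300,
~1000 cells per sample, noise regimes 0.37/0.12/0.11, ON fractions
0.83/0.477/0.99, correlation targets 0.45/0.11/−0.07/0.10, and an
857-species CadB presence table with CadA 94.3%, CadC 95.5%, LysP 66.9%.

## Problem sizes and reproducibility

The test and acceptance runs use n = 1000 cells per population (20–50
seed replicates for recovery studies), 200 replicates for the chi-square
type-I calibration, 50 random additive matrices of 4–8 taxa for the NJ
equivalence study (with an exhaustive least-squares topology search as
the independent oracle up to 6 taxa), 2000 alignment columns × 100
bootstrap replicates for the support study, and 5-cell 256×256 px fields
for segmentation — sizes at which every sampling-error bound in the tests
is comfortably resolved. All randomness flows from explicit seeds; there
is no global RNG state, and identical spec + seed reproduces every table,
image and alignment byte-for-byte.

## Known limitations

* Only the single GFP←CFP crosstalk term used in the study is corrected;
  there is no multi-way spectral unmixing or photobleaching correction.
* The ON/OFF rule is a calling convention, not a recovered ground truth;
  reported ON fractions depend on the control sample and $k$.
* Shape descriptors are medial-axis re-definitions, not the original
  tool's unpublished formulas; gate survivors can differ at the margins.
* NJ is exact on additive matrices but, like all NJ, offers no optimality
  guarantee on strongly non-additive inputs; saturated distances are
  capped, which compresses deep divergences.
* The co-occurrence machinery counts whatever `species_id` encodes;
  taxonomic resolution is the caller's responsibility.
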