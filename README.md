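# acidhet

Single-cell heterogeneity and homolog co-occurrence analysis of the three
inducible acid-resistance (AR) systems of *Escherichia coli* — Gad
(glutamate), Adi (arginine) and Cad (lysine). Each system pairs a
proton-consuming decarboxylase with an antiporter; chromosomal
antiporter–fluorophore fusions (GadC:eGFP, AdiC:mCerulean, CadB:mCherry)
report per-cell activation, and the population-level statistics of those
reporters quantify phenotypic heterogeneity and division of labour under
acid stress. The package is written for microbiologists analysing
three-colour reporter micrographs and for anyone reproducing the
comparative-genomics side of such studies.

## What it computes

**Single-cell intensity chain** (per field of view, per channel):

1. background subtraction: `RF = raw − background(field, channel)`;
2. spectral crosstalk correction of the GFP channel for CFP bleed-through,
   `RF_gfp ← RF_gfp − f · RF_cfp`, with `f` fitted by zero-intercept least
   squares (`f = Σ x y / Σ x²`; the experimentally determined value for
   this fluorophore pair is 0.456);
3. brightness normalization across fluorophores (eGFP 33, mCerulean 16,
   mCherry 15): `nRF = RF · B_max / B_fluor`;
4. the heterogeneity ("noise") statistic on each sample,
   `noise = sd(y) / mean(y)` with `y_i = ln(x_i + 1)`,
   robust to the non-normal (right-skewed) Cad distributions;
5. ON/OFF calling against a non-tagged control
   (`threshold = mean + 3·sd`), Pearson correlations between systems, and
   chi-square histogram comparisons with tail pooling.

**Imaging**: a built-in segmenter (Otsu threshold, hole filling, border
removal) and medial-axis shape measures with the rod-shape gates
area ≥ 0.1 µm², length 1.2–5 µm, width 0.1–1 µm, curvature ≤ 0.15,
angularity ≤ 0.25.

**Comparative genomics**: BLAST-hit filtering (per-component e-value
cutoffs, e.g. GadC < 1e−100, AdiC/CadB < 1e−120; hit length within ±10% of
the query), presence/absence co-occurrence matrices and percentages,
Jukes-Cantor corrected distances
`d = −((a−1)/a) · ln(1 − (a/(a−1)) p)` for protein (a = 20) or nucleotide
(a = 4) alignments, Saitou–Nei neighbor joining, Felsenstein bootstrap
(column resampling, 100 replicates), Newick/PHYLIP/iTOL export.

**Synthetic data**: every stage is testable offline via generators for
correlated three-channel populations (Gaussian copula over configurable
marginals, additive bleed-through, per-field background), rod-cell
micrographs (spherocylinders + PSF + noise), presence tables, and
sequence evolution along a known tree under the equal-rates model.

## Worked example

```r
library(acidhet)

# a Cad-like ON/OFF mixture: 83% ON, right-skewed ON intensities
sp <- population_spec(
  list(channel_spec("cad", on_fraction = 0.83, family = "lognormal",
                    loc = 5, scale = 0.6, off_level = 2)),
  background_mean = 3, background_sd = 0.5,
  cells_per_field = 1000, seed = 21)
cells <- simulate_population(sp)

compute_noise(cells$cad_raw)$noise
#> [1] 0.2890924
skewness_g1(cells$cad_raw)
#> [1] 1.517843
#> attr(,"classification")
#> [1] "right-skewed"
set.seed(22)
call_on_off(cells$cad_raw, control_values = 2 + rnorm(500, 3, 0.5))$on_fraction
#> [1] 0.834
```

The noise value ~0.29 and the right-skewed classification reproduce the
Cad reporter's signature under mild acid stress, and the control-based
threshold recovers the generating 83% ON fraction (n = 1000, binomial
sampling error ~1.2%).

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate_populations.R` … `06_phylogeny.R`), each a thin driver over
the package that prints what it found and writes its tables under
`results/`.

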