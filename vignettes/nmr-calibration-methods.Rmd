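---
title: "Calibrating bee pollen properties from solid-state 13C NMR spectra"
author: "nmrcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating bee pollen properties from solid-state 13C NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcal)
```

## The problem

Bee pollen is a chemically complex natural product whose nutritional and
antioxidant properties — protein, fat, reducing sugars, total polyphenols
(TP), ABTS antioxidant activity, elemental composition and pH — are normally
measured by slow, destructive wet-chemistry assays. A single solid-state
¹³C CPMAS NMR spectrum of the powdered granules, however, carries the
signatures of every major organic constituent at once: aliphatic lipid
chains near 36/30/23/14 ppm with the ester carbonyl at ~175 ppm,
polysaccharide carbons across 60–110 ppm, protein aliphatics below 40 ppm
with the amide envelope near 180 ppm, and polyphenol aromatics across
100–170 ppm. `nmrcal` implements the multivariate calibration workflow that
turns such spectra into quantitative property predictions.

## The model

For each property separately, a PLS1 regression links the spectral matrix
$X$ (n samples × p channels) to the property vector $y$:

$$ y = X\,b + e $$

with $X$ decomposed into a small number of latent variables,
$X = T P^\top + E_X$, extracted sequentially by NIPALS so that each score
direction has maximal covariance with the (deflated) response. The
regression vector is composed as $b = W (P^\top W)^{-1} q$, where $W$ holds
the unit-norm weight vectors and $q$ the per-component y-loadings. For a
single response the NIPALS inner loop converges in one pass, so the
implementation computes each weight directly as the normalized covariance
direction $X^\top y / \lVert X^\top y \rVert$; an iterative textbook NIPALS
serves as an independent oracle in the test suite. Component signs are fixed
(largest-magnitude weight element positive) so refits are bit-reproducible.

Model quality is summarized the way spectroscopic calibrations usually are:

* **RSEP (%)** — relative standard error of prediction,
  $100 \sqrt{\sum_i (C_i - C^A_i)^2 / \sum_i (C^A_i)^2}$, where $C$ is the
  model prediction and $C^A$ the reference-assay value. It is unit-free:
  jointly rescaling predictions and references leaves it unchanged, making
  errors comparable across properties measured in mg/g, %, or pH units.
  It relates to the RMSE by $\mathrm{RSEP} = 100\sqrt{n/\sum (C^A_i)^2}\,
  \mathrm{RMSE}$, an identity the tests verify to 1e-10.
* **R / R_cv** — Pearson correlation between predicted and reference values
  on the calibration set (fitted values) and under leave-one-out
  cross-validation. The fitted-value convention for R is a documented
  choice; the alternative (correlation of a refit calibration curve) is
  indistinguishable at the reported precision.

## Pretreatment

The modeling chain is fixed as **windowing → (MSC | SNV | none) →
mean-centering**:

* **ppm windows** are closed `(high, low)` intervals on the descending
  chemical-shift axis. Informative ranges per property are configuration,
  chosen by the analyst (VIP profiles are the usual screen); the default
  configuration restricts only the reducing-sugars model, to 220–55 ppm.
* **MSC** regresses each spectrum on the mean calibration spectrum and
  inverts the fitted affine scatter; the reference spectrum is stored and
  reused for validation/unknown samples.
* **SNV** centers and scales each spectrum to unit standard deviation
  (sample sd, n−1 denominator — a convention, stated because nothing in the
  method forces it).
* **Mean-centering** always precedes PLS; the column means are calibration
  parameters too.

Every fitted parameter (MSC reference, column means) is learned on the
calibration set only and applied verbatim to validation spectra. This is
what makes the reported RSEP on the validation set an honest external
error: the held-out spectra never influence any fitted quantity.

## Calibration/validation split

25 of 35 samples calibrate, 10 validate. The partition combines bootstrap
resampling with PCA score plots: samples are embedded in a 5-component PCA
score space; across 200 bootstrap resamples a Kennard–Stone maximin design
nominates calibration candidates; the most frequently nominated samples
calibrate. Per-component score extremes are forced into calibration, so
every validation sample interpolates the calibration domain. The procedure
is deterministic given a seed and invariant to row order. The specific
algorithm is this package's documented construction — published accounts of
"bootstrap + PCA score plots" splits rarely pin down an algorithm — with
the same intent: representative coverage. The 25/10 membership itself is
not claimed to match any particular experimental study.

## Choosing the number of latent variables

Leave-one-out RMSECV is computed for 1..a_max components, refitting the
entire chain (pretreatment included) in every fold. The component count is
the smallest one whose RMSECV lies within 2% (configurable) of the curve
minimum: with 25 calibration samples the bare argmin chases noise, and this
parsimony plateau rule formalizes the usual "first elbow" reading of an
RMSECV plot. The default configuration instead fixes per-property counts
(sugars 4, protein 4, fat 4, NHCS 5, C 5, N 4, S 5, TP 4, ABTS 3, pH 7) as
modeling choices; "auto" selection is available and capped at a_max = 10.

## VIP scores

Variable importance in projection follows the standard Wold form
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$ with
$SS_a = q_a^2\, t_a^\top t_a$. The mean squared VIP is exactly 1, so
channels above 1 carry above-average predictive weight; profiles are
exported so an analyst can choose spectral windows from them.

## The synthetic-data generator

No experimental pollen spectra are distributed with the reference table, so
the generator produces spectra with the statistical structure the analysis
assumes, making every stage testable end to end.

**Compositions.** Property vectors are drawn from a multivariate normal
fitted to the packaged 35-sample table (means, covariance, and per-column
ranges), clipped to the observed ranges. Two hard constraints follow:
protein is exactly 6.25 × N (the Kjeldahl conversion used to produce the
reference protein values in the first place), and ABTS is regenerated as an
affine function of TP plus noise calibrated so the population TP–ABTS
correlation is 0.84, the value the reference table itself shows.

**Spectra.** Each clean spectrum is a linear mixture of unit-mean component
bases: lipid ← fat, polysaccharide ← reducing sugars, protein ← protein,
polyphenol ← 0.5 × TP, tannin ← 0.1 × TP, plus a broad carbohydrate-weighted
**background** whose loading closes the composition to 100% of the dry
mass. The closure matters: real CPMAS intensities carry no meaningful
absolute scale (rotor packing, scan count), and constituent percentages of
a closed composition are recoverable from intensity *ratios* — exactly the
information MSC/SNV preserve. Without a closing component, normalization
destroys genuine scale information and imposes an artificial error floor of
several percent on every normalized model; with it, the noise-free limit is
recovered essentially exactly (the tests assert RSEP ≤ 0.1% for the
spectrally encoded properties at zero noise).

Lineshapes are Lorentzian by default (Gaussian allowed per peak) with
widths of 2–8 ppm to mimic CPMAS broadening; lipid lines are the narrowest
(1.8–2.5 ppm) because mobile chains give narrower solid-state lines.
Per-sample multiplicative slope (sd 0.04 around 1) and additive offset
(sd 0.02 of the peak mean intensity) emulate the scatter-like variation
MSC/SNV exist to remove, and white Gaussian noise is added per channel
(sd 0.015 of the peak mean intensity). The noise and scatter defaults were
calibrated once against the generator's two realism targets — five PCs
explaining roughly 75% of total variance (moderate S/N) and macronutrient
validation errors in low single-digit percent under the default
configuration — and are fixed; they pull in opposite directions, and the
defaults sit where both hold.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: spinning sidebands, cross-polarization dynamics
(CPMAS intensities are not proportional to carbon counts — in real pollen
spectra the 36 ppm lipid peak is the tallest, while the generator's mean
spectrum peaks in the carbohydrate region), baseline roll, field drift, and
any direct spectral signature of pH or sulfur. pH and S enter only through
their covariance with the composition (a knob, `ph_s_assoc`), mirroring the
argument that composition determines such parameters; their synthetic
predictability is by construction, and their validation errors are
accordingly the weakest.

## Numerical choices

* PCA via SVD of the centered matrix (safer than covariance
  eigendecomposition on 3072-point grids); explained variance as percent of
  total centered variance; loading signs fixed as in PLS.
* Grid alignment by linear interpolation only — spectra are smooth at 3072
  points over 220 ppm; out-of-span grid points are an error, never
  zero-filled.
* NIPALS rank exhaustion is detected by the weight norm falling below
  1e-12 relative to the initial deflation scale and is an error, not a
  silent truncation.
* The reference table ships verbatim at printed precision; the Kjeldahl
  identity is validated with a 0.006 tolerance (the two-decimal rounding
  bound), and the table's own internal inconsistencies (pH 6.30 and
  C 43.73 outside the summary ranges quoted for the calibration subset)
  are deliberately not reconciled.
* Serialized models store numbers at 17 significant digits, enough for
  bit-reproducible predictions after a round-trip.

## Problem sizes

The shipped analyses and tests run the full-size problem: 35 samples ×
3072 channels, 25/10 split, 200 bootstrap resamples, leave-one-out over 25
calibration samples. Oracle comparisons (textbook NIPALS, least squares,
brute-force LOO) use batteries of small random instances (n ≤ 12, p ≤ 15,
20+ instances) where the alternatives are exact and fast; population-level
generator checks use n = 500 compositions.

## Known limitations

* Spectral ranges per property beyond the reducing-sugars window are left
  to configuration; no automated range search is provided.
* PLS2 (joint multi-property) modeling is out of scope; each property gets
  its own PLS1 model, matching how such calibrations are usually reported.
* The generator's realism is statistical, not physical; conclusions about
  real spectrometer data require real spectra.
* Uncertainty intervals on predictions are not computed.
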