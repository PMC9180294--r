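---
title: "Non-destructive discrimination of strawberry ripening stages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-destructive discrimination of strawberry ripening stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripestage)
```

## The problem

Strawberries are non-climacteric: they must be picked at the right maturity,
and the usual field criteria (days after flowering, visual colour calls) are
subjective. `ripestage` implements a chemometric workflow that discriminates
two commercial maturity stages — *half-red* (about 50% red surface) and
*red* (fully coloured) — from three non-destructive fingerprints:

* a 10-sensor metal-oxide-semiconductor (MOS) electronic nose reading the
  headspace aroma as conductance ratios G/G0;
* ATR-FTIR absorbance spectra of freeze-dried fruit on a 600–4000 cm⁻¹
  grid (3401 variables);
* RGB images of berry lots on a dark background, summarised as CIELAB
  colour features and red/green surface percentages.

Around these sit a univariate discrimination battery (linear mixed-effect
stage test, Benjamini–Hochberg FDR at δ = 0.05, fold change, ROC AUC with
bootstrap CI), PCA with cross-validated Q², and two-block Pearson
correlation maps clustered with Ward's method, the cluster count chosen by
silhouette analysis.

No public dataset accompanies the workflow, so the package ships a
first-class synthetic-data module that generates every modality with the
statistical structure the analysis assumes. All statements below about what
the pipeline recovers are computed by the test suite on that generator.

## Study design and the synthetic generator

`study_design()` encodes the nested layout: 2 stages × 3 harvests ×
4 biological samples, with 11 e-nose, 5 FTIR and 8 image technical
replicates per sample. That yields the characteristic dataset shapes:
264 e-nose observations × 10 sensors, 30 spectra × 3401 wavenumbers
(FTIR pools one sample per stage and harvest), and 192 image observations
× 5 colour features. A single integer seed fully determines every output.

### E-nose plateaus from quantile summaries

Sensor behaviour is specified per stage as a median with a 5th–95th
percentile range (`quantile_spec`). A plateau level is drawn from a normal
with mean equal to the median and sd `(p95 − p5)/3.29` (the normal
5th-to-95th spacing), then **clamped** to `[p5, p95]`. Clamping rather than
rejection sampling was a deliberate choice: it guarantees the support never
leaves the reported range — so sensors whose printed stage ranges are
disjoint (S7, S9) separate perfectly, AUC = 1 — and for a symmetric
specification it leaves the median and both tail percentiles exactly at
their nominal values, which rejection-truncation would pull inward by about
a third of an sd. For asymmetric specifications (e.g. S7 red:
median 1.930, range 1.506–2.198) no symmetric normal can match all three
quantiles; the clamped draw keeps the median and the hard bounds and lets
the tail quantiles deviate. The quantile-fidelity property test therefore
uses symmetric specs.

Technical replication is modelled as a sample-level random intercept with
variance 10% of the stage-level variance (the replicate share is reduced to
90% so the marginal variance is preserved). The within- vs between-sample
split is not reported for the real data; 10% encodes the qualitative
statement that technical spread is visibly smaller than biological spread,
and the mixed-model tests verify exactly that structure.

Traces rise from G/G0 = 1 with exponential saturation (τ = 6 s), holding
the plateau long before the 70–75 s feature window; only the window value
is contractually meaningful. Additive trace noise defaults to 5 × 10⁻⁴ so
that the window mean and the trapezoidal mean agree to the asserted 0.1%
even for the small-signal sensors (S1 sits near 0.4).

### FTIR spectra

A spectrum is a sum of Gaussian bands, a random linear baseline, a
per-spectrum multiplicative scatter factor (uniform on 0.75–1.3) and
additive noise — so the standard normal variate (SNV) transform is
non-trivially exercised. Three bands carry the ripening signal with the
directions known from strawberry chemistry: the O–H band at 3295 cm⁻¹
(organic acids) is stronger in half-red fruit; the C=O band at 1717 cm⁻¹
and the sugar-fingerprint band at 1026 cm⁻¹ are stronger in red fruit.
Bands at 2928, 2891 and ~1400 cm⁻¹ are stage-invariant. The 3295 band
width is 80 cm⁻¹: broad relative to the fingerprint bands, yet narrow
enough that its loading extremum is localisable to ±5 cm⁻¹ under the
default noise — with a much broader flat top, no extremum detector can pin
the centre that precisely, so the width was fixed once at generator-design
time together with the noise level (sd 0.002 absorbance units).

The grid is 600–4000 cm⁻¹ at 1 cm⁻¹: the only uniform grid consistent with
3401 variables, which is why it is preferred over the nominal 650 cm⁻¹
acquisition edge.

### Berry images

Each observation is a lot of 12 ellipse-shaped berries on a near-black
background. The red surface fraction per berry is realised exactly at
pixel level (ground-truth masks partition the berry pixels), with ±4–5%
jitter except at the exact bounds 0 and 1. Half-red lots carry bright red
patches (RGB ≈ 205, 42, 47) over pale green flesh (≈ 150, 172, 78); fully
ripe lots darken and desaturate (≈ 80, 46, 42). That tone choice reproduces
the direction seen in the real feature tables — *every* whole-berry colour
feature (L\*, a\*, b\*, Chroma, hue) is lower for red lots — which in turn
drives the signs of the colour–chemistry correlation map. The default
frame is 1024 × 864 (echoing the 3.2 MPixel camera's aspect); tests use
smaller frames except where segmentation accuracy is measured, which runs
at camera-like scale (2064 × 1744) because the fixed 2 px edge erosion is a
boundary effect whose relative cost shrinks with berry size.

An optional 24-patch colour chart with the classic published sRGB
reference colours is rendered at a fixed position for the calibration
operation.

### Chemistry and VOC panel

TA (titratable acidity), TP (total phenols) and AA (antioxidant activity)
load positively on a shared "acidity" latent that is higher in half-red
fruit; TSS (°Brix) loads on ripeness with the opposite sign. The VOC table
has 57 non-negative relative-peak-area columns; 55 rise in red fruit
through a shared aroma latent, while 2-methylbutanoic acid (`Ac4`) and
mesifurane (`F1`) get a deliberately weak stage effect plus an independent
shared latent, so that correlation-profile clustering isolates exactly
that pair — the structure the two-block sensor × VOC heatmap is expected
to discover.

## Statistical methods

### Mixed-effect stage test

For each feature, a random-intercept model with maturity stage as the
fixed factor and the biological sample as the grouping factor, fitted by
REML; the stage contrast is tested with a Wald t using between-sample
degrees of freedom (n_samples − 2). For balanced designs this test has an
exact closed form — it equals the pooled two-sample t-test on the
per-sample replicate means, and the ANOVA variance-component estimators
coincide with REML — which the package uses directly (and the tests verify
against `lme4` and against the t-test reduction). Unbalanced designs fall
back to a numeric `lme4` fit. Satterthwaite degrees of freedom are out of
scope; with the between-sample df the test holds its nominal size (the
suite checks the empirical type-I rate over 1000 null simulations against
[0.03, 0.07] at nominal 0.05).

"Technical replicate as the random factor" is read as sample-level
grouping — replicates of one sample share an intercept — the only reading
under which replication structure enters the test at all.

### Fold change, ROC, FDR

Fold change is the ratio of the red to the half-red median (type-7
percentile convention throughout). Published tables of this kind sometimes
print the reciprocal in the FC column, so `fold_change()` returns both
directions rather than guessing. ROC AUC uses the midrank formula
(concordant pairs + half ties), verified pair-by-pair against brute-force
enumeration; the reported AUC is folded to ≥ 0.5 with the direction flag
retained, because a feature that drops with ripening discriminates just as
well. The AUC confidence interval is a stratified bootstrap percentile
interval (B = 2000): the DeLong variance degenerates at AUC = 1, which
saturated sensors actually reach, whereas the bootstrap interval collapses
gracefully to [1, 1]. FDR control is Benjamini–Hochberg step-up at
δ = 0.05, delegated to `stats::p.adjust` and cross-checked in the tests
against the max–min closed form.

### PCA and cross-validated Q²

PCA is fitted by SVD after one of three preprocessing modes: mean-centring
(e-nose), autoscaling (colour features), or row-wise SNV followed by
mean-centring (spectra). Explained variance per component is the squared
singular value over the total sum of squares of the preprocessed matrix;
loading signs follow the largest-element-positive convention so outputs
are reproducible.

Q² is the largest methodological choice in the package, since the source
workflow names no scheme. The implementation uses venetian-blind fold
assignment over biological samples (replicates never straddle folds, which
would leak technical structure), refits the preprocessing parameters on
each training fold, and reconstructs held-out rows element-wise with a
leave-one-variable-out projection: variable *j* is predicted from scores
computed without variable *j* (via a rank-one Sherman–Morrison update of
the projection). Naive row projection would include each variable in its
own prediction and push Q² trivially toward R²; row-wise deletion schemes
cannot be compared against because the original choice is unknown, which
is recorded as an open point. On strongly low-rank data Q² tracks R²
within 0.1; on i.i.d. noise it goes negative.

One honest consequence of the generator: synthetic sensors are drawn
independently within stage, so their only shared variance is the stage and
sample structure, and the element-wise e-nose Q² is far below the value
reported for real fruit — real MOS arrays respond to a common aroma
chemistry that induces strong inter-sensor correlation. The headline
multivariate R²/Q² values of the real study are therefore not reproduction
targets (they require the authors' raw data); the package's claims are
structural: stage separation along PC1, band recovery in the PC1 loading,
and Q² behaviour on data of known rank.

### Two-block correlation maps

Pearson correlations between two feature blocks over shared observations,
with per-coefficient two-sided t-tests at α = 0.05. Clustering operates on
the correlation *profiles* (rows/columns of the ρ matrix) with Euclidean
distance and Ward's method (`ward.D2`); the cluster count is chosen by
maximum mean silhouette width over k = 2…min(8, n−1), ties to the smallest
k — the cap reflects that 2–3 clusters are the relevant regime here.
Whether the original analysis clustered ρ profiles or raw feature vectors
is not stated; ρ profiles match what a two-block heatmap displays.
Non-significant cells are blanked on the rendered heatmap but always kept
in the exported TSV, which round-trips ρ at full precision (`%.17g`).

## Image pipeline choices

Otsu's criterion serves both thresholds (background vs fruit on the R
channel; red vs green on the clipped R−G enhancement restricted to the
fruit mask) — the original work cites only "a threshold method". Otsu
always splits, so the red/green step accepts the split only when the two
classes are genuinely separated (class-mean gap > 4 pooled sd and the
upper class above red-level enhancement); otherwise the whole berry is one
colour class. Edge erosion uses a disk of radius 2 px at camera scale,
followed by border flood-fill so interior dark specks (glare defects) are
closed. sRGB → CIELAB goes through the standard IEC 61966-2-1 matrix and
the D65/2° white point — implemented directly because `convertColor`
deviates from the sRGB standard by ~0.3 L\* units, outside the package's
own accuracy contract (pure red must map to 53.24, 80.09, 67.20 within
0.1). The studio lamps were ~5500 K; chart calibration is the mechanism
meant to absorb that difference, so D65 is used throughout. The hue angle
is `atan(b*/a*)` in radians, not `atan2`: whole-berry means sit in the
first quadrant, and the published hue magnitudes (0.4–0.6) are radian
values. Colour features are averaged in Lab space over the whole berry
mask of a 12-berry lot, one observation per replicate image; the red/green
percentages are returned alongside because it is not recorded whether the
original five-variable analysis used them.

## Problem sizes used by the tests

The suite exercises the full design where it is cheap (264-observation
e-nose tables, 30 × 3401 spectra) and reduced designs elsewhere: image
sets at 160–320 px frames (segmentation accuracy at 2064 × 1744),
1000 null simulations for the test size, 100 seeded simulations for
silhouette recovery, 500 random instances for the AUC oracle. These sizes
were chosen so the whole suite completes in well under a minute of compute
while every rate estimate still has a usable standard error.

## Known limitations

* The generator emulates summary statistics and correlation structure, not
  instrument physics: no sensor drift, humidity response or chamber-flow
  transients; no ATR penetration-depth or atmospheric compensation; no
  berry morphology (calyx, glare, touching fruit). Passing tests show the
  analysis recovers planted structure, not that it would survive those
  artefacts.
* Harvest time is carried as a label only; no H1/H2/H3 effect is simulated.
* The within-sample variance share (10%) is a stand-in for an unreported
  quantity.
* S4 and S10 are generated from their printed medians, which differ
  slightly between stages; with 264 observations the mixed model can
  detect even that small a shift, so their non-significance in the real
  data is mirrored only as "weakest discriminators, far from AUC
  saturation", not as a guaranteed negative.
* Cross-validated Q² on the synthetic e-nose block is structurally low
  (independent sensors); see above.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
generate_dataset(cfg, "data")
res <- analyze_dataset(cfg, "data", "results")
res$enose$univariate[, c("feature", "p", "fdr_significant", "FC", "AUC")]
```
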