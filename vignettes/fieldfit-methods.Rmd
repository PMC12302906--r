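---
title: "Modeling diel rice gene expression from meteorological time series"
author: "fieldfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling diel rice gene expression from meteorological time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fieldfit)
```

## The problem

Rice leaves in a paddy field experience temperature and irradiance that
rise and fall together over every day: warm hours are bright hours. A
statistical model that predicts a gene's expression from meteorological
history can therefore fit field data almost equally well with either
variable, and the identity of the true environmental driver is left
undetermined. Growth chambers break this confounding: photoperiod,
light-phase temperature and dark-phase temperature can be set
independently, so across a factorial grid of chamber conditions the
temperature a plant experienced carries no information about the light it
received. `fieldfit` implements the full analysis around this idea: a
per-gene dynamic expression model, the per-gene choice between temperature
and irradiance as its environmental predictor, training-set-composition
experiments (chamber-only, field-only, and 50/50 mixed pools), held-out
prediction error, diel summary statistics, and the data-integrity
procedures (plate-swap detection, genotype concordance) that such a study
needs. Because the analysis is developed and tested against synthetic
data, the package also contains a first-class generator that emulates the
study's statistical structure with known ground truth.

## The per-gene model

Expression on the log2(rpm+1) scale is modeled as the sum of three
sub-models and their interactions:

$$
y(t) \;=\; b_0 + b_a\,\mathrm{age} +
b_c \cos\tfrac{2\pi h}{24} + b_s \sin\tfrac{2\pi h}{24} +
x(t)\,\bigl(b_e + b_{ea}\,\mathrm{age} + b_{ec}\cos\tfrac{2\pi h}{24} +
b_{es}\sin\tfrac{2\pi h}{24}\bigr) + \varepsilon,
$$

where $h$ is the clock time of sampling and $x(t)$ is the *gated
environmental input*: the mean over the look-back window
$[t - D - T,\, t - D)$ of

$$
g(h(s))\cdot \mathrm{clip}\bigl(E(s);\,\theta_{lo},\theta_{hi}\bigr),
\qquad
g(h) = (1-\gamma) + \gamma\left(\tfrac{1+\cos\frac{2\pi (h-\phi)}{24}}{2}\right)^{w}.
$$

$E$ is either the temperature or the irradiance trace; the model never
uses both (a two-variable model is explicitly out of scope). The seven
nonlinear parameters are the window length $T$, the lag $D$ (with
$T + D \le 72$ h, the model's look-back limit), the gate peak $\phi$,
depth $\gamma$, sharpness $w$, and the clipping bounds. The clock phase of
the periodic sub-model is carried by the cos/sin pair, so it is estimated
by the penalized linear fit rather than by nonlinear search. These
functional forms are a faithful-in-structure reconstruction of the gate
class of model rather than a bit-level port of any particular
implementation; the forms above are fixed so that every number the
package produces is well defined.

## Two-tier fitting

**Linear coefficients — adaptive group LASSO.** The eight coefficients are
penalized in three groups: G1 = age, G2 = the clock pair, G3 = the four
environmental terms. A lightly ridge-penalized pilot fit supplies adaptive
weights $1/\lVert\hat\beta^{pilot}_g\rVert$; a group-LASSO path is then
solved by block coordinate descent and the solution with the smallest
$\mathrm{BIC} = n\log(\mathrm{RSS}/n) + \mathrm{df}\log n$ (df = 1 + number
of nonzero coefficients) is kept. Whole groups are zeroed exactly, which
is what later allows a gene to be classified as driven by *neither*
variable. Numerically, each group is rotated to orthonormal coordinates
through the eigen decomposition of its centered Gram block (the
"standardized" group LASSO), making every block update closed-form; the
path is driven entirely by 7x7 sufficient statistics, so one fit costs
$O(np^2)$ regardless of the path length. A penalty of exactly zero is
special-cased to the least-squares solution. Directions with negligible
singular value (for example the irradiance input of a continuous-dark
condition) are dropped, so degenerate designs degrade gracefully instead
of failing.

**Nonlinear parameters — grid search plus Nelder–Mead.** The criterion is
evaluated on a default grid of 768 settings ($T \in \{1,3,6,12,24,48\}$,
$D \in \{0,3,6,12\}$, $\phi \in \{0,6,12,18\}$, $\gamma \in \{0,1\}$,
$w \in \{1,4\}$, clipping at the full observed range or the central 80%
of the training values; duplicate clipping options collapse, e.g. for
binary chamber irradiance). Nelder–Mead then refines the best grid point
under bound-respecting transforms: log for $T$ and $w$, a shifted log for
$D$, logit for $\gamma$, wrap-around modulo 24 for $\phi$, and a log-width
parameterization that keeps $\theta_{lo} < \theta_{hi}$. The refined
solution is kept only if it improves the criterion, so refinement can
never do harm. Because the window boundaries snap to the trace grid, the
objective is piecewise constant in $T$ and $D$ below the 0.5-h trace
resolution; Nelder–Mead tolerates these plateaus, and the grid stage
guarantees a sensible starting basin.

**Choosing the predictor.** Each gene is fitted once with temperature and
once with irradiance; the fit with the lower BIC wins, and the gene is
classified as `neither` when the winning fit zeroes G3. Criterion ties
(difference under 1e-8) resolve to `neither` if both fits drop G3,
otherwise to the sparser fit, otherwise to temperature — an explicit,
deterministic rule because ties must not depend on evaluation order.

## The synthetic study

The generator reproduces the statistical structure of the study design,
not its biology:

* **Chamber grid.** Three photoperiods crossed with five light and five
  dark temperatures, equal-temperature pairs excluded, plus five
  continuous-dark and five continuous-light conditions: 73 conditions.
  Traces are square waves on a 0.5-h grid (which resolves the 1.5-h
  structure of the sampling scheme at modest cost); chamber irradiance is
  a normalized 0/1 flux because the physical lamp flux is a chamber
  property, not a per-sample covariate. Sampling follows the study
  cadence: eight samplings every 3 h starting 1.5 h after lights-on (the
  eighth at 22.5 h), two cultivars, 1168 planned samples, each with a
  full 72-h history before it.
* **Field weather.** A phenomenological model: temperature is a seasonal
  mean plus a diel sinusoid peaking at 13:00 plus smooth AR(1)
  excursions; irradiance is a half-sinusoid over daylight scaled by a
  log-normal day weather factor. Two couplings make the variables share
  information the way real weather does — cloudy days are cooler (the
  day factor scales the diel temperature amplitude) and sunny spells are
  warmer (a fraction of the AR excursions modulates daytime irradiance).
  These couplings are the point of the generator: without them, each
  variable carries private structure that makes the predictor choice
  artificially easy on field data, which would misrepresent the very
  confounding the analysis is about. At the defaults the pooled
  temperature–irradiance correlation exceeds 0.3.
* **Decorrelation, precisely stated.** Pooled over the whole chamber
  grid the raw correlation between temperature and irradiance is *not*
  near zero: the light-temperature levels (20–40 °C) sit about 6 °C above
  the dark levels (15–35 °C), which induces a pooled point-biserial
  correlation of roughly 0.37 by construction. What the design actually
  guarantees — and what the tests assert — is independence *given the
  light state* (partial correlation ≈ 0) and a pooled correlation well
  below the field's. That conditional independence is what makes the
  predictors separable.
* **Ground-truth genes.** Each gene has a driver (temperature, radiation
  or neither), nonlinear parameters, linear coefficients whose
  environmental scale is matched to the driver's dynamic range, and
  Gaussian log2-scale noise. We define SNR as the ratio of signal to
  noise *variances*; `calibrateNoise()` sets each gene's noise to
  $\mathrm{sd(signal)}/\sqrt{\mathrm{SNR}}$ over a reference sample set.
  Simulated values are clipped at zero to stay in the observable
  log2(rpm+1) range. `neither` genes have exactly zero environmental
  coefficients, and noiseless simulation is exactly invertible by the
  forward model — an identity the tests exercise.

What the generator does *not* emulate: count-level sampling noise,
transcriptome-wide co-expression, real weather-station data, or seasonal
development beyond a linear age trend. Passing tests therefore show that
the statistical machinery behaves as designed under known ground truth;
they do not certify biological conclusions on real data.

## The training-set-composition experiment

`runSelectionExperiment()` subsamples each pool without replacement
(mixed pools draw half from each source, ceiling to the chamber half for
odd sizes), shares each (pool, size, replicate) subsample across all genes
— one data draw trains every gene's model, as in the study design — and
records, per gene and replicate, the chosen predictor and the held-out
MAE on an independent field test set generated from a different weather
realization. Genes whose fit fails in any replicate are flagged excluded.
Replicate seeds derive deterministically from the master seed and are
independent between pools by default; `paired = TRUE` reuses the same
replicate seed stream across pools. The default experiment is scaled to
30 genes, 20 replicates and sizes {64, 256} so the complete discrimination
analysis runs in minutes on one CPU; the full-scale 466 x 100 x 4 design
is a parameter choice away. Consistency is classified at an inclusive 80%
of replicates; MAE >= 5 (inclusive) marks a poor prediction;
exemplar-level selections convert to genome-wide member-gene percentages
by cluster size, reported to one decimal.

Two qualitative outcomes are reproduced on synthetic data and asserted in
the acceptance tests: chamber-trained selection is more accurate than
field-trained selection (the decorrelated design identifies the driver),
and mixed training predicts held-out field data better than chamber-only
training. The latter arises because chamber plants are all young while the
field test spans a wide age range — chamber-only models extrapolate the
age sub-model far outside its support, the overfitting signature the
experiment is designed to expose.

## Diel statistics

Expression filtering keeps genes with grand mean log2(rpm+1) strictly
above 1. Diel amplitude fits `stats::smooth.spline` with `spar = 0.3` and
takes max minus min of the fitted curve on a 1.5-h grid over the observed
span; `spar` is a normalized smoothing parameterization, and the package
standardizes on this documented convention so any implementation matching
it agrees. A noiseless 24-h cosine of amplitude $A$ sampled every 3 h
yields a fitted range in $[1.8A, 2.0A]$ — the mild attenuation is the
expected cost of smoothing at this setting. Oscillating genes need mean
amplitude strictly above 2 in *both* cultivars (amplitudes are averaged
over conditions per cultivar, the reading we adopt of the averaging
rule). Cultivar-specific genes require a mean difference above 2 with the
lower mean below 0.5. Differential expression between cultivars within a
condition uses a paired t-test over the time-point pairs with
Benjamini–Hochberg control across genes (q < 0.05), directions labelled
"higher in" the winning cultivar; zero-variance difference vectors yield
`NA` p-values and are never called. The temperature screen uses Pearson
correlation across all samples pooled (per-condition screening is a
non-default option) with strict cutoffs at |r| > 0.5; zero-variance genes
are excluded and reported.

## Quality control

**Plate swaps.** Expression encodes growth temperature, so a lasso
regression (glmnet) of nominal temperature on the transcriptome, trained
on all plates except one and applied to the held-out plate, exposes
plates whose annotations lie. The regularization strength is chosen by
5-fold cross-validated MAE within the training plates — the in-training
rule is stated ambiguously in this analysis tradition and is degenerate
read literally (training MAE is minimized by no penalty), so
cross-validation within the training portion is the deliberate,
documented choice. Fold assignment follows the sample-id sort order, so
results are deterministic and invariant to row order. Plates with MAE at
least 3x the median plate MAE are flagged (a robust, scale-free default;
the choice of outlier rule was open), and an exhaustive search over
pairings of flagged plates proposes the exchange minimizing total MAE
against the swapped nominal labels. A second leave-one-plate-out round on
the corrected annotations must leave no plate flagged for the correction
to be accepted.

**Genotypes.** Cultivar-specific SNP calls per sample are summarized as
the proportion of *called* loci (unknown and no-sequence calls excluded)
matching the nominal cultivar: at least 0.7 passes, at most 0.3 indicates
exchanged cultivar labels, and the open band in between — including the
~50% signature of a mixed or contaminated sample — is discarded.

## Numerical choices and degenerate inputs

* Environmental grid step 0.5 h; traces must be uniform, and all traces
  in one analysis must share a step.
* Insufficient look-back history is rejected with the earliest valid
  time named.
* Constant response vectors return an intercept-only fit with a warning;
  constant nominal temperature short-circuits the plate regression to an
  exact constant predictor.
* The coordinate-descent tolerance is 1e-8 relative to the response SD;
  the zero-penalty path point is solved exactly, and the λ = 0 fit
  matches `lm()` to well below 1e-6.
* Subsample seeds are derived as `seed * 1000 + rep (+ pool offset)`,
  keeping every derived seed well inside 32-bit integer range.

## Problem sizes

The shipped defaults are deliberately desk-scale: the discrimination
analysis uses 30 genes x 20 replicates x n = 256 x 3 pools over the full
768-point grid (about 12 minutes on one CPU); parameter recovery uses 20
genes at SNR 20; QC fixtures use 12 plates x 40 genes. These sizes are
the package's chosen study conditions for the synthetic reproduction;
all of them are function arguments.

## Known limitations

* The gate/window forms are one concrete member of the model family;
  other parameterizations of the same structure would fit real data
  differently in detail.
* The selection criterion is BIC throughout; the original choice of
  criterion for the temperature-vs-radiation decision is not pinned down
  in the analysis tradition this package follows, and AIC or
  cross-validation would shift individual gene calls.
* Window and lag estimates snap to the 0.5-h trace grid.
* The field generator is phenomenological; its couplings are designed to
  reproduce the confounding structure, not any particular site's
  meteorology.
* With a single sample per (condition, cultivar, time point), the paired
  t-test's replication unit is the time point, as in the study design;
  it tests mean cultivar differences within a condition, not
  time-resolved ones.
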