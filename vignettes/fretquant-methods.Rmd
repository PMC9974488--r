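---
title: "Models and methods behind fretquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

fretquant quantifies experiments built around a semisynthetic FRET
biosensor: a fusion of an analyte-binding protein, a fluorescent-protein
donor and a self-labeling protein tag carrying a synthetic acceptor dye with
a tethered ligand. Analyte binding displaces the tethered ligand, switches
the sensor between a closed (high-FRET) and an open (low-FRET) state, and so
converts free analyte concentration into an optical readout. This vignette
records the models the package implements, the assumptions behind them, and
the numerical and design choices a maintainer would want to know.

## Binding isotherm

The plate-reader response is modeled as the one-site hyperbola

$$R(c) = R_\mathrm{min} + \frac{R_\mathrm{max} - R_\mathrm{min}}{1 + c_{50}/c},$$

where $R$ is the donor/acceptor emission ratio and $c_{50}$ the
concentration of half-maximal ratio change. $c_{50}$ is an operational
constant of the tethered-ligand competition, not a thermodynamic $K_d$. The
model is strictly hyperbolic — no Hill coefficient — and the zero-analyte
point is kept in the fit via the limit $R(0) = R_\mathrm{min}$.

Fitting is unweighted Levenberg–Marquardt least squares (`minpack.lm`),
replicates pooled. Choices that matter:

* **Positivity** of $c_{50}$ (and $K_d$, below) is structural: the parameter
  is log-transformed inside the optimizer and reported on the linear scale,
  with the delta method mapping its standard error back.
* **Starts** are data-driven and deterministic: $R_\mathrm{min}$ and
  $R_\mathrm{max}$ from the 5th/95th percentiles of the observed ratios
  (orientation from the low- vs high-concentration means), $c_{50}$ from the
  concentration whose response is nearest the midpoint.
* **Degenerate input**: a flat series is reported with dynamic range 1 and
  an `unidentifiable_c50` flag instead of an error; a fitted $c_{50}$ more
  than 10× outside the sampled range is flagged `extrapolated`.
* Standard errors come from the Jacobian-based covariance at the optimum; no
  bootstrap.
* Weighting by replicate scatter is deliberately not applied; readouts at
  this noise level (~1% CV) gain little from it and the unweighted fit is
  the common default for plate-reader titrations.

Concentrations are micromolar throughout the API; callers convert.

## Fluorescence polarization

Polarization is computed as $FP = (I_\parallel - G I_\perp)/(I_\parallel + G
I_\perp)$ with the instrument grating factor $G$. Direct titrations of
protein against a fixed tracer fit the exact 1:1 equilibrium solution with
ligand depletion,

$$FP = FP_0 + (FP_s - FP_0)\,
\frac{(L + K_d + P) - \sqrt{(L + P + K_d)^2 - 4 L P}}{2L},$$

because the tracer concentration (50 nM by default) is not negligible
against micromolar-range $K_d$ values. When $L/K_d \le 0.01$ this form
collapses onto the simple hyperbola, and the test suite verifies the two
agree within 1% there. Competition titrations fit the hyperbolic
displacement model with free $FP_0$ (bound), $FP_s$ (free) and $c_{50}$. No
correction is attempted for incomplete tracer occupancy at the chosen
protein concentration — the displacement model is taken as the operational
definition of $c_{50}$.

## Sensitized-emission imaging

Per pixel, bleedthrough-corrected net FRET is

$$\mathrm{netFRET} = \frac{I_\mathrm{FRET} - BT_d I_\mathrm{donor} -
BT_a I_\mathrm{acceptor}}{\sqrt{I_\mathrm{donor} I_\mathrm{acceptor}}},$$

the geometric-mean normalization making the statistic insensitive to probe
amount. Implementation decisions:

* **Bleedthrough factors** are the median FRET/source intensity ratio over
  pixels whose source intensity exceeds a floor, estimated on
  single-fluorophore control images. The median resists hot pixels; the
  default floor is median + 3 MAD of the source channel, a robust "3 SD
  above background" rule when most pixels are background. Factors are
  constant — no intensity-dependent bleedthrough model.
* **Invalid pixels** (donor–acceptor product at or below the floor squared)
  are masked and excluded from ROI means, never clipped or NaN.
* **Segmentation** thresholds the donor/GFP channel by Otsu's method
  (256-level histogram) and labels 8-connected components, dropping regions
  under `min_pixels` (default 50). EBImage provides the threshold and the
  primitive labeling; a union-find pass merges diagonally touching labels to
  the 8-connectivity convention. Labels are deterministic, in raster order.
* **Normalization** divides by a matched non-responsive control probe
  (fully open sensor). Both orientations — control/sensor (default) and
  sensor/control — are available behind an explicit `orientation` flag,
  because both conventions circulate in the sensitized-emission literature;
  within one experiment the choice only rescales, and condition contrasts
  are invariant to it up to direction.
* **Statistics** run on field-of-view means (the FOV is the independent
  unit), with the relative change's s.e.m. from the delta method for a ratio
  of independent means and a Welch two-tailed t-test for condition
  comparisons. Zero-variance degeneracies yield `NaN` with a warning.
* Optional constant-background subtraction exists upstream of these
  statistics but is off by default; flat-field correction and cell tracking
  are out of scope.

## TCSPC decay fitting and absolute quantification

Decays are modeled as $I(t) = \sum_i \alpha_i e^{-t/\tau_i} + b$, fit by
Poisson maximum likelihood (default; correct at low counts) or
Neyman-weighted least squares. Without an instrument response the fit is a
tail fit from the peak bin; with `use_irf = TRUE` the model is numerically
convolved with the stored IRF histogram (reconvolution). Numerical choices:

* Amplitudes and lifetimes are log-parameterized; lifetimes are bounded
  below by one bin width, since sub-bin lifetimes are unresolvable by
  construction.
* The likelihood surface of multi-exponential models is multimodal, so the
  optimizer multi-starts from three lifetime configurations (one anchored on
  the tail slope of the data) with amplitudes initialized by linear least
  squares on the trial exponential basis, then polishes the best optimum.
* Components that collapse onto the same lifetime (within 1%) are merged,
  and components carrying under 0.5% of the photons are pruned, each with a
  warning — both are signatures of an over-parameterized fit.
* Goodness of fit is the reduced Pearson $\chi^2$ against the fitted
  expectation; values under 1.2 are the conventional acceptance bound for
  lifetime fits, and the test suite verifies the fitter attains it when the
  generating model matches the fitted one.

The amplitude-weighted mean lifetime is $\tau = \sum_i \alpha_i \tau_i /
\sum_i \alpha_i$. (The normalizing sum in the denominator is occasionally
dropped in print; the normalized form is the only dimensionally meaningful
one and is what the package computes.) FRET efficiency is $E = 1 -
\tau_\mathrm{FRET}/\tau_D$ with $\tau_D$ fitted from a donor-only decay;
negative values are reported with a flag, never clipped. All fitted
components enter the amplitude-weighted mean — no attempt is made to assign
individual components to FRET vs non-FRET populations, which the lifetime
statistic does not require.

Calibration fits $E(c) = E_\mathrm{min} + (E_\mathrm{max} -
E_\mathrm{min})/(1 + c_{50}/c)$ to per-concentration efficiencies from an in
vitro lifetime titration, and quantification inverts it:

$$[\mathrm{analyte}] = c_{50}\,\frac{E - E_\mathrm{min}}{E_\mathrm{max} - E}.$$

The inverse diverges at $E_\mathrm{max}$, so efficiencies at or beyond the
calibrated range are flagged (`below_range` → 0, `saturated` → NA) rather
than extrapolated. Transferring an in vitro calibration into cells is a
scientific caveat the software cannot resolve (cytosolic composition shifts
$c_{50}$); any calibration object can be supplied.

## Synthetic data: what it emulates and what it does not

Every input class the pipeline consumes can be generated with known ground
truth from a `synthetic_scenario()`. Defaults encode the study design the
package targets: a 12-point log-spaced ladder from 12.8 nM to 1 mM in
triplicate with 1% multiplicative Gaussian readout noise (plate-reader noise
is signal-proportional); a 50 nM FP tracer with $K_d$ = 1.2 μM and 2 mFP
additive noise; 512 × 512 px fields holding 55 non-overlapping soft-edged
disc "cells" over a uniform background of 5 counts with Poisson photon noise
in all three channels and bleedthrough truth (0.15 donor, 0.10 acceptor);
256-bin/25 ns decay histograms (40 MHz pulse period) sampled multinomially
from bin-integrated multi-exponential masses at ~10⁶ photons per ROI; and an
efficiency calibration ($E$ 0.05–0.45, $c_{50}$ 58.9 μM, donor lifetime
2.6 ns, FRET lifetime 0.8 ns). The two default imaging conditions are
constructed so the treated condition's true normalized FRET differs from
control by exactly +20%.

Per-pixel truth is built so the estimators invert it exactly in the
noiseless limit: the sensitized-emission term is `netFRET_true ×
sqrt(donor × acceptor)`, and detector background appears in every channel.
One deliberate discretization: decays are generated from bin-integrated
masses while the fit model evaluates at bin centers; at 256 bins over 25 ns
the resulting lifetime bias is ~0.06%, far below every tolerance used.

Generators are seeded (each modality derives an independent stream from the
scenario seed) and byte-stable. What they do **not** emulate — and what
passing tests therefore cannot certify on real data: cell-to-cell
variability of analyte concentration and expression level, non-uniform
illumination and detector gain, cell shapes beyond discs, autofluorescence
spectra beyond a constant background, IRF drift, dead-time/pile-up in photon
counting, and any biology connecting conditions to concentrations (truth
values are injected, not mechanistically generated).

## Problem sizes and tolerances in the test suite

The suite runs at deliberately desk-scale sizes: 128 px imaging fields with
12 cells for unit tests, full 512 px fields with 55 cells for the
bleedthrough and end-to-end checks; 500-replicate titration and
100-replicate FP and decay ensembles for recovery statistics; 50 random
image triplets for the bitwise oracle-equivalence check of the net-FRET
kernel. Noiseless-recovery assertions use 1e-6 relative tolerance (1e-3 for
decay histograms, whose counts are integers by construction); round-trip
identities use 1e-9.

One tolerance deserves its derivation: for two-component decays
(τ = 0.8/3.0 ns, amplitudes 1:2, 256 bins/25 ns) the Cramér–Rao bound gives
the short lifetime a relative standard deviation of 6.0% at 10⁵ photons and
1.9% at 10⁶. Per-replicate 5% recovery is therefore asserted at the 10⁶
photon budget, where it is attainable, while across mixed 10⁵–10⁶ budgets
the suite asserts the ensemble median — the observed MLE scatter sits at the
bound, i.e. the estimator is efficient, and no tolerance can buy back
information the photons do not carry.

## Known limitations

* Spectral unmixing is limited to the two constant bleedthrough terms.
* ROI-summed decays only; no per-pixel lifetime maps, no phasor analysis.
* The tethered-ligand competition is treated operationally through $c_{50}$;
  no mechanistic multi-equilibrium sensor model is fitted.
* TIFF interchange rounds intensities into a 16-bit integer container.
* The plateau rule for labeling time-courses (consecutive relative changes
  below 2%) is a pragmatic detection device, not a kinetic model.
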