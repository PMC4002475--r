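---
title: "A fluctuation model for single-wavelength calcium-dye linescan imaging"
author: "puffsnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fluctuation model for single-wavelength calcium-dye linescan imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffsnr)
```

## The problem

Localized Ca²⁺ release events (puffs) are imaged with single-wavelength
indicator dyes such as Fluo-4 or Rhod-2 in confocal linescan mode.
Whether a puff is visible at all depends on a tangle of experimental
choices — dye identity and concentration, EGTA concentration, laser
power, detector gain — and a setting that works with one dye can fail
silently with another.  `puffsnr` implements a quantitative route out:
a generative model of the per-pixel fluorescence fluctuations whose
parameters are measured in stationary (no-signal) experiments, combined
with a reaction–diffusion simulation of the puff itself, so that the
expected signal-to-noise ratio of any candidate setting can be computed
*before* doing the experiment, and settings can be sorted into
equivalence classes of comparable detectability.

## The generative pixel model

The fluorescence reported at one pixel is modeled as the end of a
four-stage stochastic chain:

1. the number of dye molecules contributing to the pixel,
   $N \sim \mathrm{Poisson}(\langle N\rangle)$;
2. the number of them that are Ca²⁺-bound,
   $B \mid N \sim \mathrm{Binomial}(N, \lambda)$, where $\lambda$ is
   the probability that a dye molecule is bound;
3. the detected photon count,
   $P \sim \mathrm{Poisson}(\varepsilon_b B + \varepsilon_f (N - B))$,
   with $\varepsilon_b \ge \varepsilon_f$ the molecular brightnesses
   (photons per molecule per pixel dwell) of the bound and free forms —
   for a single-wavelength dye both forms emit, with a fixed ratio
   $r = \varepsilon_f/\varepsilon_b$ of the order of the ratio of their
   quantum efficiencies;
4. the detector output, $F = A\,P'$ with
   $P' \sim \mathrm{Poisson}(P\text{-mean})$ and $A$ the amplification
   factor.  The detector is modeled as pure Poisson resampling with no
   offset, appropriate for photon-counting acquisition.

Because binomial thinning of a Poisson count yields independent Poisson
counts for $B$ and $N - B$, the chain has closed-form moments:

$$\langle F\rangle = A\,\langle N\rangle\,
  \bigl(\varepsilon_b \lambda + \varepsilon_f (1-\lambda)\bigr),$$

$$\sigma_F^2 = A^2 \langle N\rangle\,
  \bigl[(\varepsilon_b \lambda + \varepsilon_f(1-\lambda))
      + (\varepsilon_b^2 \lambda + \varepsilon_f^2(1-\lambda))\bigr].$$

The first bracket term is photon shot noise ($\sigma_F^2 \ge A \langle
F\rangle$ always); the second carries molecule-number and occupancy
fluctuations.  `mean_fluorescence()`, `variance_fluorescence()` and
`sample_pixel()` implement the moments and the chain, and the test
suite holds them to each other by Monte-Carlo at $10^6$ draws per
parameter-grid point.

The pixels are treated as statistically independent; correlations
introduced by diffusion during the dwell time are ignored, which is
consistent with pooling all cytosol pixels of an image into one moment
pair.

## Calibration from stationary experiments

Three kinds of stationary recordings trace out variance-versus-mean
curves that isolate different parameters (`fit_type1()`, `fit_type2()`,
`fit_type3()`):

* **Region sweeps (Type I)** vary only $\langle N\rangle$ (dye
  concentration differs slightly between cytosolic regions):
  $\sigma_F^2 = A\bigl[1 + \varepsilon_b\,\varphi(\lambda,
  r)\bigr]\langle F\rangle$ with $\varphi(\lambda, r) = (\lambda +
  r^2(1-\lambda))/(\lambda + r(1-\lambda))$ — a line through the
  origin.
* **Laser-power sweeps (Type II)** vary both brightnesses together at
  fixed $r$: $\sigma_F^2 = a_1\langle F\rangle + a_2\langle F\rangle^2$
  with $a_1 = A$ exactly and $a_2 = (\lambda +
  r^2(1-\lambda))/(\langle N\rangle (\lambda + r(1-\lambda))^2)$.  The
  crossover $\langle F\rangle^* = a_1/a_2$ marks where the quadratic
  term becomes visible; a sweep that stays below it looks perfectly
  linear and cannot constrain $\langle N\rangle$ (`fit_type2()` flags
  this "linear regime" explicitly, because it is itself diagnostic of a
  poorly detecting setting).
* **Ca²⁺-addition sweeps (Type III)** vary $\lambda$:
  $\sigma_F^2 = A(1+\varepsilon_b+\varepsilon_f)\langle F\rangle -
  A^2\langle N\rangle \varepsilon_b \varepsilon_f$, an affine relation
  whose high-occupancy limit pins $\varepsilon_b$ and whose
  low-fluorescence points can be inverted for the basal occupancy.

All three forms are algebraic rearrangements of the two moment
expressions; the test suite verifies each against the exact variance to
$10^{-12}$ relative over random parameter sets, so the fitted curves
and the generative model cannot drift apart.

### Numerical conditioning choices

Two estimator details matter in practice and were chosen deliberately:

* **The gain anchor.**  The raw Type I slope estimates
  $A(1+\varepsilon_b\varphi)$, not $A$; at $\varepsilon_b \sim 0.1$–$0.2$
  the bias is 5–15%.  `calibrate()` therefore prefers $a_1$ from the
  Type II polynomial, which is unbiased in every regime, and reports
  the Type I/Type II comparison as a self-consistency check instead of
  averaging them.  Without a Type II ensemble, $A$ and $\varepsilon_b$
  are solved jointly by damped alternation of the Type I and Type III
  relations.
* **The brightness extraction.**  Estimating $\varepsilon_b$ as
  $\mathrm{slope}/A - 1$ amplifies any percent-level slope error
  several-fold (the interesting quantity is the small excess above 1).
  With $A$ known, the same line is instead fitted in excess-variance
  form — $\sigma_F^2 - A\langle F\rangle$ regressed through the origin
  on $A\langle F\rangle$ — whose slope *is*
  $\varepsilon_b\varphi$, followed by a three-step fixed-point
  correction for the top points not being fully saturated.  The
  recovery tests (84/21/55 images of $10^5$ pixels, ten seeds) hold the
  consolidated estimates to 5% ($A$), 15% ($\varepsilon_b$) and 30%
  ($\langle N\rangle$, basal $\lambda$).

The per-point basal-occupancy inversion
(`invert_type3_occupancy()`) uses the excess-variance ratio
$\rho = (\sigma_F^2 - A\langle F\rangle)/(A\langle F\rangle)$, in which
the molecule number cancels, so region-to-region concentration
differences do not bias it.  It remains intrinsically sensitive — $\rho$
is a small difference of large numbers — which is why results are
reported as ranges with validity flags rather than single values, and
why the brightness ratio $r$ is a *required* user input: with
$\varepsilon_f = 0$ the basal fluorescence carries no occupancy
information at all.

The high-/low-fluorescence subsets default to the top and bottom 30%
quantiles, and the sensitivity of $\varepsilon_b$ to that cut is always
reported, because the estimate genuinely depends on it.  Confidence
intervals are standard 95% linear-regression intervals on unweighted
ordinary least squares.  Self-consistency between independent
parameter routes is judged on a factor scale (default factor 3):
moment methods agree at that level, not at percent level, and
pretending otherwise would manufacture false alarms.

## The puff simulator

Puffs are simulated as a spherically symmetric reaction–diffusion
system (`rd_run()`) for free Ca²⁺, the indicator dye, EGTA, an immobile
endogenous buffer and (optionally) two mobile endogenous buffers, each
binding Ca²⁺ with single-site mass-action kinetics; free and bound
forms of each buffer diffuse equally, so each total concentration stays
uniform and only the bound pools are evolved.  Ca²⁺ is removed by a
linearized pump $J = \gamma(\mathrm{Ca} - \mathrm{Ca}_{basal})$ with
$\gamma = k_{off,P}[P]_T/\mathrm{Ca}_{basal} = 0.9\,\mathrm{s}^{-1}$ at
the default pump parameters — a form chosen because it is
units-consistent and leaves the equilibrium initial state exactly
stationary.  The source is a cluster of 6 channels that open together
at $t = 0$ and close independently after exponential times of mean
20 ms, each injecting a configurable ion flux into the innermost radial
shell.  The per-channel flux is an experiment-scale quantity with no
universal value; `calibrate_source_flux()` tunes it so the blurred peak
occupancy reaches a target, by default twice its basal value — a signal
of the order of the smallest detectable one, which is the regime where
noise comparisons between settings are informative.

Numerics: backward Euler in time with Lie splitting.  The stiff
reaction/source/pump system is solved implicitly per node — backward
Euler turns it into a single scalar equation in the new free Ca²⁺
(every bound pool is an explicit monotone function of it, and total
mass closes the system), solved by vectorized Newton iteration with a
strictly increasing residual.  Diffusion is then solved implicitly per
mobile field with a cached tridiagonal factorization.  Space is
discretized by a radial finite-volume scheme (cell centers at
$(i-\tfrac12)\Delta r$, face-area-weighted first-neighbor fluxes):
second-order, exactly conservative under the no-flux boundaries, and
regular at $r = 0$ because the innermost face has zero area.  Defaults
are $\Delta r = 0.05\,\mu m$, $\Delta t = 0.01$ ms, $R = 5\,\mu m$
(multi-set pipeline runs use $\Delta t = 0.02$ ms, which the
convergence tests cover).  The verification suite checks equilibrium
stationarity to $10^{-9}$, global Ca²⁺ mass balance against the
injected-minus-pumped ledger, agreement with the free-space
point-source profile $\mathrm{Ca}_{basal} + \sigma/(4\pi D r)$ to 5%
over 0.2–2 µm, and a Richardson ratio near 4 under grid halving.

## Confocal observation and image synthesis

The simulated bound-dye field is turned into a linescan observable by a
normalized anisotropic 3-D Gaussian point-spread function in the
$1/e^2$ convention, truncated at three half-widths
(`blur_radial_field()`).  The PSF widths default to
$w_r = 0.3\,\mu m$, $w_z = 1.0\,\mu m$, typical of a 60× high-NA
oil-immersion confocal; the scan grid defaults to 0.2 µm pixels and a
2 ms line period.  All of these are configurable and are recorded in
image sidecars, since none is universal.  Dividing the blurred bound-dye
concentration by the total dye concentration gives the occupancy map
$\lambda(x, t)$, and `synthesize_image()` draws every pixel
independently through the generative chain with that pixel's
$\lambda$.  Optional "granule rows" — dark fringes emulating the
cortical granules of oocyte linescans at ~10% of the cytosolic mean —
exist purely so the preprocessing has something realistic to remove;
no attempt is made to model granule morphology or autofluorescence.

What the synthetic data do *not* emulate: diffusion-induced pixel
correlations, detector afterpulsing or dead time, photobleaching, scan
jitter, and out-of-focus structured background.  Tests passing on these
fixtures therefore validate the model algebra, the solver and the
estimator implementations — not the claim that any real microscope is
fully described by the five parameters.

## Signal-to-noise ratios and equivalence classes

Two SN definitions are implemented:

* `snr_analytic()`: $[\langle F\rangle(\lambda_{peak}) - \langle
  F\rangle(\lambda_{basal})]/\sigma_F(\lambda_{basal})$ from the exact
  moments.  The gain cancels exactly, and SN scales as
  $\sqrt{\langle N\rangle}$ — raising the dye concentration 2.5-fold
  (90 µM versus 36 µM) raises SN by $\sqrt{2.5} \approx 1.6$.  A
  documented small-brightness variant (photon shot noise only) is
  available for comparison.
* `snr_image()`: $(F_{max} - F_{min})/\sigma_F(\lambda_{basal})$ with
  literal extrema over the cytosol pixels of an image.  Literal extrema
  of $n$ noisy pixels include the extreme-value spread of the
  background, roughly $2\sqrt{2\ln n}\,\sigma \approx 6$–$8\sigma$ for
  $10^3$–$10^5$ pixels, *before any signal*.  For near-threshold
  signals this floor dominates and dilutes differences between
  settings.  The function implements the plain definition (with an
  off-by-default percentile variant) and documents the bias; the
  pipeline-level comparisons below therefore use the model-based SN,
  fed with the peak occupancy that the simulation pipeline actually
  produced, with the stochastic channel-closing realization as the
  source of run-to-run variability.

`classify_equivalence()` groups settings by single linkage on relative
SN difference, default threshold 0.25 — chosen to separate ~40%
differences (distinct detectability) from ~16% ones (equivalent
detectability), and recorded in every report.

The end-to-end property the pipeline tests enforce, with one shared
calibrated source across the three shipped concentration sets
(set i: Fluo-4 36 µM + EGTA 90 µM; set ii: Rhod-2 36 µM + EGTA 90 µM;
set iii: Rhod-2 90 µM + EGTA 45 µM):

* the *noiseless* blurred bound-dye elevation (peak over basal) agrees
  across the three sets to within 15% — the underlying chemistry does
  not explain detectability differences;
* with realistic free-dye brightness ($\varepsilon_f = r\varepsilon_b >
  0$) the SN ordering is set ii < set iii ≤ set i, while setting
  $\varepsilon_f = 0$ *reverses* sets i and iii — so the free-dye
  fluorescence, not the noise chain per se, is what degrades the
  low-concentration Rhod-2 setting.

## Default study conditions

Values that the source experiments do not pin down were fixed once, as
follows, and are not tuned per run: detector gain 1 (photon counting);
$\varepsilon_b = 0.1$ photons/molecule/dwell at standard illumination;
$\langle N\rangle$ proportional to dye concentration (100 at 36 µM,
250 at 90 µM, one confocal volume); brightness ratios $r = 0.01$ for
Fluo-4 (~100-fold enhancement on binding) and $r = 0.07$ for Rhod-2
(~14-fold); basal free Ca²⁺ 0.1 µM, giving basal occupancies from each
dye's dissociation constant (0.75 µM for Fluo-4; 1.86 or 2 µM for the
two published Rhod-2 rate pairs, both shipped as explicit variants).
Per-channel flux defaults to $3\times10^5$ ions/s (~0.1 pA) before
calibration.

Problem sizes used by the shipped tests: moment-identity grid of 27
parameter points at $10^6$ draws; recovery ensembles of 84/21/55 images
at $10^5$ pixels across ten seeds; reaction–diffusion verification on
grids up to 600 cells and 5000 steps; pipeline runs of three sets at
$\Delta t = 0.02$ ms to 40 ms across ten source realizations.

## Known limitations

* The basal-occupancy inversion is ill-conditioned by construction;
  treat its output as a range, and do not use it with dyes whose free
  form is dark ($r \approx 0$).
* The pump is a linear surrogate; strongly saturating pumps would need
  the configurable alternative forms.
* Spherical symmetry excludes geometry effects (membrane proximity,
  cluster shape), and channel gating is open-at-zero/exponential-close
  only.
* The image-based SN definition is extreme-value dominated for large
  images; compare settings with the model-based SN.
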