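---
title: "Models and methods behind ramantrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramantrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramantrap)
```

# Scope

`ramantrap` is a software re-implementation of an automated single-particle
Raman trapping platform: an acquisition state machine that recognises
trapped particles by a spectral threshold, the standard preprocessing chain
for trapped-particle Raman spectra, internal-standard (perchlorate)
volume-displacement sizing, mixture-resolution chemometrics, and dynamic
reaction-trace analysis. Because no public raw dataset exists for this kind
of instrument, the package ships a physics-based *virtual instrument* that
renders trapped-particle spectral streams with known ground truth; every
analysis module is exercised against it. This vignette records the models,
the tunable parameters, the design decisions taken where the design was
genuinely open, and what a green test does and does not establish.

# The virtual instrument

## Spectral model

A spectrum on the axis $\nu$ (cm$^{-1}$, 3 cm$^{-1}$ channel spacing) is
rendered as expected counts

$$
E(\nu) = t_\mathrm{int}\Big[\,b(\nu) + g(\nu)
 + f \sum_c w_c S_c(\nu)\, V_p\, \rho
 + P(\nu)\big(1 - f\,V_p/V_c\big)\Big],
$$

followed by Poisson shot noise, Gaussian read noise (default s.d. 2
counts), and a cosmic spike with probability 0.01 per spectrum. Here
$b(\nu)$ is a slowly varying fluorescence baseline, $g(\nu)$ a broad water
background, $S_c$ the pseudo-Voigt signature of component $c$ (50 %
Lorentzian, half-widths 6–60 cm$^{-1}$), $w_c$ its weight fraction, $V_p$
the particle volume, $\rho$ the detector response (2×10⁴ counts s$^{-1}$
per unit amplitude per µm³), $f \in [0,1]$ the fill fraction (how long the
particle was present during the integration), and $P(\nu)$ the perchlorate
marker band at 938 cm$^{-1}$. The factor $(1 - f V_p/V_c)$ is the
volume-displacement law: a particle displaces its own volume of marker
solution from the confocal volume $V_c$ (default 1 µm³).

Component band positions follow the published assignments (C–D 2105, CH₂
1450, perchlorate 938, alkyne 2129, azide 2116, triazole 1331, S–S 452/512,
tyrosine 840/860, PDMS 490/709 cm$^{-1}$, heparin 930/1070 cm$^{-1}$).
Band amplitudes within each component are rescaled so that every component
has the same integrated scattering cross-section per unit mass (a `scatter`
multiplier then expresses genuinely stronger scatterers, e.g. deuterated
lipid). This convention makes area-normalised band fractions track weight
fractions, which is the premise of comparing measured band-area ratios
against theoretical composition ratios; without it the comparison would
confound composition with arbitrary library amplitudes.

## Baseline shape

The fluorescence baseline is an exponential tail,
$b(\nu) = A\,e^{-(\nu-\nu_0)/\Delta}$ with $\Delta$ the axis span. An
earlier candidate (a cosine-squared hump) was rejected: the asymmetric
least squares baseline estimator (below) becomes effectively $1/p$ times
stiffer at its equilibrium and straightens strongly curved backgrounds,
leaving several percent residual. The exponential tail is the standard
picture of near-infrared fluorescence decay and keeps the peak-free
baseline residual below 2 % of the baseline amplitude, which is the
package's own acceptance property for the preprocessing chain.

## Trap occupancy dynamics

Occupancy evolves per acquisition step. With the laser on and the trap
empty, a particle arrives within $\mathrm{d}t$ with probability
$1-e^{-k_a \mathrm{d}t}$, where $k_a = 4\pi D a c$ is the Smoluchowski rate
($D$ Stokes–Einstein diffusivity, $a$ = 0.5 µm capture radius, $c$ the
number concentration, default 10¹¹ ml$^{-1}$, inside the stated working
range of such instruments). The arrival instant is uniform in the interval,
so mid-iteration arrivals produce partial fill fractions — this is why they
tend to fail the recognition threshold. With the laser off for
$t_\mathrm{off}$, a trapped particle is retained with probability

$$
P_\mathrm{ret} = P\!\left(\chi^2_3 \le \frac{a^2}{2 D t_\mathrm{off}}\right),
\qquad D = \frac{k_B T}{3\pi\eta d},
$$

the probability that an isotropic 3-D Brownian displacement has not carried
it beyond the capture radius. Defaults: $T = 298$ K, $\eta = 0.89$ mPa·s,
$a = 0.5$ µm, none of which the source platform quantifies; $a$
approximates the diffraction-limited focus of a 785 nm, NA 1.0 objective.
For a 200 nm sphere this gives 0.84 % retention after 0.5 s and 98.3 %
after a 5 ms blink — the mechanism behind the "disable long enough"
operating rule. The closed form is verified in the test suite against a
Monte-Carlo displacement oracle written before the implementation.

## What the generator does not emulate

Polarisability-dependent trap stiffness, photothermal effects, detector
nonlinearity and wavelength-dependent collection efficiency are not
modelled; spectra are statistically stationary given occupancy. A green
test therefore establishes the correctness of the *algorithms* under the
stated noise model, not instrument-level accuracy on any real hardware.

# Acquisition controller

The controller alternates short *iteration* acquisitions (default 1 s)
with long high-SNR acquisitions (default 10 s). A threshold is calibrated
as the **median** band intensity over occupied-trap iteration spectra of an
initial particle; recognition is a strict `>` comparison. Up to 10
iterations per attempt cycle are made; the first pass triggers exactly one
high-SNR acquisition and a trap record, then the laser is disabled.
Unsuccessful cycles disable the laser identically. No high-SNR spectrum is
ever taken without a threshold pass, and every high-SNR spectrum has
exactly one record — both are asserted as properties.

One modelling consequence deserves a note. For a single particle whose
intensity fluctuates symmetrically, a median-calibrated threshold is passed
on only ~50 % of occupied iterations. The observed pile-up of successes at
iteration 1 under short disabling times emerges only with *across-particle*
brightness variation (intensity scales with $d^3$, so a realistic size
spread dominates within-particle noise) combined with selection: only
above-threshold particles yield successful traps, and precisely those
particles pass again immediately when re-trapped after a too-short
disable. The simulated acquisition fixtures therefore carry a particle
size spread, and the iteration-number check (fraction of successes at
iteration 1, monotone non-increasing in the disabling time) is tested in
that world.

# Preprocessing chain

Order: truncation → cosmic-spike repair → baseline subtraction →
Savitzky–Golay smoothing → area normalisation.

* **Truncation**: 350–1825 cm$^{-1}$ standard; 606–2254 cm$^{-1}$ when the
  silent region (C–D 2105, alkyne 2129 cm$^{-1}$) is needed. The range is a
  configuration item because the two acquisition windows coexist in
  practice.
* **Spike repair**: modified z-score (median/MAD) of the second difference,
  threshold 8, plus an amplitude guard requiring counts above twice the
  local 7-channel median; flagged channels are linearly interpolated from
  the nearest unflagged neighbours and reported. The guard keeps sharp
  genuine peaks (which rise only fractionally above their local
  neighbourhood) from being repaired; flagging more than 10 % of channels
  raises a suspect flag instead of silently dropping data.
* **Baseline**: asymmetric least squares Whittaker smoother, penalty
  $\lambda = 10^5$ on second differences, asymmetry $p = 0.001$, 10
  reweighting passes. The estimator deliberately hugs the lower envelope;
  under heavy shot noise this biases residual areas upward by roughly one
  noise s.d., which is why sizing spectra (ratios of areas on the *same*
  spectrum) and normalised group comparisons are robust to it but absolute
  areas are not.
* **Smoothing**: Savitzky–Golay, 3 points, first order — a 3-point moving
  average on interior channels, shrinking symmetrically at the edges.
* **Normalisation**: division by the trapezoidal integral; exact for
  band-area *ratios*, skipped for sizing spectra because the perchlorate
  ratio normalises internally.

# Sizing

The perchlorate ratio is $(A_t - A_p)/A_p$ with $A_t$ the total area of the
baseline-subtracted spectrum and $A_p$ the marker-band area over
938 ± 15 cm$^{-1}$ (windows are unstated in the source; ±15 cm$^{-1}$ ≈ 5
channels). Calibration is ordinary least squares of the **mean** ratio per
reference size on $\log_{10}$ volume (nominal manufacturer diameters,
$V = \pi d^3/6$); inversion is $V = 10^{(r-\mathrm{intercept})/\mathrm{slope}}$.
Ratios outside the calibrated span ± half its range are flagged as
extrapolations rather than rejected.

The generator's sizing preset draws ratios from a log-linear law
$r = \alpha + \beta \log_{10} V$ ($\alpha = -4$, $\beta = 1$, chosen once
so the 50/100/200 nm series spans ratios ≈ 0.8–2.6) with multiplicative
noise, and realises each ratio as a noise-free baseline-subtracted spectrum
(unit marker band plus a polystyrene signature of total area $r A_p$). A
first-principles displacement model is *not* log-linear over a 1:64 volume
range, so the empirical law is stated directly for sizing while the
physical displacement law governs the spectral render — the tension is
intentional and documented. Because band areas are evaluated over finite
windows while pseudo-Voigt tails extend beyond them, the measured ratio is
an affine transform of the generated one; the calibration absorbs this
exactly (the affine factor cancels between calibration and inversion), so
round trips recover diameters and the error-propagation identity
$\mathrm{PDI} \approx (\ln 10 \cdot \tau\, r / 3\beta)^2$ for relative
ratio noise $\tau$ holds on the generator-law scale.

The PDI is defined as $(\mathrm{s.d.}/\mathrm{mean})^2$ with the $n-1$
standard deviation.

# Chemometrics

* **Two-component Gaussian mixture EM** on band intensities: median-split
  initialisation, variance floor $10^{-12} \times \mathrm{range}^2$,
  tolerance $10^{-8}$ on the relative log-likelihood change, at most 500
  iterations, component 1 = lower mean, hard labels by larger
  responsibility. The log-likelihood trace is returned and its monotone
  non-decrease asserted in the tests.
* **PCA**: mean-centred SVD with a deterministic sign convention (largest
  loading element positive).
* **Ward clustering**: own Lance–Williams implementation on merge costs
  initialised to half squared Euclidean distances, so merge heights equal
  the increase in within-cluster sum of squares; ties break towards the
  lexicographically smallest pair of original indices. `stats::hclust` is
  deliberately not used, so the brute-force $O(n^3)$ oracle in the tests is
  an independent check. Features for clustering are PCA scores covering
  ≥ 95 % of variance (minimum 2 components). Samples whose distance to
  their cluster centroid exceeds the 97.5th percentile of within-cluster
  distances are reported "not classified" — the source describes such a
  class without giving a rule, so the rule here is the package's own.
* **PLS-DA**: NIPALS PLS1 on a 0/1 class indicator, prediction threshold
  0.5, venetian-blinds cross-validation (sample $i$ → fold
  $(i-1) \bmod 10 + 1$ in acquisition order). The latent-variable count
  maximises CV balanced accuracy when not fixed. Raw normalised spectra are
  used as features (whether the source compressed via PCA first is
  unstated; raw spectra are the more conservative choice). A
  permuted-label guard asserts chance-level CV accuracy.
* **Trend check**: Spearman rank correlation of PCA scores against trap
  index with a permutation p-value, α = 0.05.

# Kinetics

Band-intensity traces are min–max scaled per band (the source's
normalisation is unstated; per-band scaling makes reactant and product
curves comparable on one plot, and zero-range bands are flagged rather than
divided by zero). Completion time is the first linear-interpolated crossing
of the scaled product intensity at threshold 0.95 (a configuration item).
The click-reaction preset uses first-order conversion
$x(t) = 1-e^{-kt}$ with $k = \ln 20 / 480\,\mathrm{s}^{-1}$, i.e. 95 %
conversion at 8 min, matching the population-mode observation it emulates;
hold-mode lead time is a configurable offset. The photostability check
reports per-band relative s.d. and a permutation test on the least-squares
slope; "stable" means no band drifts significantly.

# Numerical choices and degenerate inputs

Axes must be strictly increasing with ≥ 16 channels; descending input files
are re-sorted, duplicated wavenumbers are format errors. File round trips
are exact to 9 significant digits. Zero or negative total area makes
normalisation an error; a vanished marker band makes the perchlorate ratio
an error, while a negative ratio (possible under noise) is returned with a
flag. EM on constant data is an error; collapsed variances are floored and
flagged. Ward on more clusters than samples is an error. All simulation
randomness flows from a single user-supplied seed.

# Known limitations

The virtual instrument is a stated world, not a calibrated emulator: its
defaults (capture radius, confocal volume, concentration, detector
response, band widths) are field-plausible choices, fixed once. Published
experiment-specific numbers that depend on the original instrument's raw
spectra (the measured 1:0.898 polymersome band ratio, the 49/47/4 % Ward
split, the 38/62 % PLS-DA split, 97.9 % specificity) are reproduced only
qualitatively by the presets; the package's tests assert the synthetic
counterparts at stated tolerances instead. PLS-DA is two-class only, and
multivariate curve regression is out of scope.
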