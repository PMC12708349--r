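---
title: "Optical inference of mitochondrial membrane potential: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical inference of mitochondrial membrane potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopsi)
```

# The measurement principle

The cytochrome *bc*₁ complex carries two b-type hemes on opposite faces of
the mitochondrial inner membrane. Electron transfer between them moves
charge across part of the membrane field, so their equilibrium reduction
ratio responds to the membrane potential ΔΨ_m: a high potential favors
reduced b_L, a collapse of the potential pushes electrons onto b_H. Each
reduced heme absorbs distinctly in the α band, which makes the reduction
ratio — and hence ΔΨ_m — optically readable in turbid preparations, from
stirred mitochondrial suspensions to transmural recordings of a perfused
heart, without any exogenous probe.

`mitopsi` implements the full inference chain and, because real raw
recordings of this kind are not generally available, pairs every inference
module with a synthetic generator that emits the same instrument streams
from known ground truth. This vignette documents the models, the tunable
parameters with their defaults and units, the numerical choices, and the
boundaries of what the synthetic studies do and do not demonstrate.

# Absorbance and unmixing

## Absorbance

`compute_absorbance()` forms A(λ) = log₁₀((I₀−D)/(T−D)). The instruments
record incident light I₀ and dark current D once per session, then
transmitted spectra T at 1 Hz. We subtract the dark current from *both*
numerator and denominator. Whether I₀ should be dark-corrected is genuinely
ambiguous in common practice; symmetric treatment is the only convention
under which an empty light path yields exactly A = 0, so the package fixes
it and documents it here. Nonpositive dark-corrected counts (saturated or
blocked channels) are a hard error naming the offending wavelengths rather
than silent clipping — a clipped channel would bias every downstream
coefficient.

## The linear model and its solver

Over the fit band the absorbance is modeled as a nonnegative-free linear
combination of unit-peak reduced references plus a line:

$$A(\lambda) = a\,b_H(\lambda) + b\,b_L(\lambda) + c\,c_1(\lambda) +
  d\,c(\lambda)\;[+\,\mathrm{MbO},\mathrm{MbD}] + e\lambda + f.$$

The line absorbs residual scattering and the weak, spectrally flat
absorbance of oxidized cytochromes; no explicit oxidized references are fit.
Although instrument software historically runs an iterative nonlinear
least-squares routine here, the model is *linear* in its coefficients, so
`fit_spectrum()` solves it directly by QR decomposition: deterministic,
fast, and testably identical (to 1e-8 relative and better) to both the
normal-equations closed form and an independent Levenberg–Marquardt run.
The wavelength column is centred and scaled internally for conditioning and
mapped back to the slope-per-nm/intercept parametrization. Rank deficiency
(e.g. duplicated references) is refused with the condition number reported;
we deliberately do not regularize, because ridge shrinkage would bias the
b_L/b_H ratio, which is the quantity of interest. An optional nonnegativity
mode (clamp-and-refit on the chromophore coefficients only) is available
for noisy low-signal data but off by default, since the unconstrained
estimator is unbiased.

## Fit bands and references

The default band is 540–580 nm. When myoglobin is present (wild-type heart
tissue), MbO and MbD references join the model and the band widens to
535–585 nm automatically; the band actually used is stamped on the output.
Reference libraries are unit-peak normalized *within the fit band* — the
empirical references from which such libraries are built have arbitrary
absolute optical density, so a convention must be imposed, and it must be
shared between calibration and application. The library carries a
`normalization` stamp and `run_pipeline()` refuses to combine a library and
a calibration curve whose stamps disagree. References are always resampled
(linearly) onto the experimental grid, never the reverse, preserving raw
data.

## The fb_L statistic and quality control

`compute_fbl()` returns fb_L = b_L/(b_L + b_H) with amplitude defined as
coefficient × in-band reference peak (equal to the coefficient under
unit-peak normalization). Since both hemes share the optical path, fb_L is
exactly invariant to path-length scaling — verified to 1e-10 under k ∈
{0.5, 2, 10} — which is what makes the statistic robust to tissue geometry
changes such as hypercontracture.

The signal-to-noise statistic is the band-wise sum of the four reconstructed
chromophore component spectra (b_L, b_H, c₁, c only — baseline and myoglobin
terms excluded) divided by the sum of squared residuals, with exclusion
below 100. Whether the numerator sums over wavelengths or over the four
amplitudes is underdetermined in common descriptions; we adopt the
wavelength-sum convention and expose the threshold, noting that the
statistic's scale depends on grid density (the default 100 belongs with the
default 1024-point grid). Zero residuals give an infinite statistic, never
excluded.

# Electrode-based ΔΨ_m

The orthogonal ΔΨ_m measurement uses a TPMP⁺-selective electrode (TPP⁺ is
treated identically; the probe name is metadata). Calibration: six equal
probe additions up to a total of 2.17 µM in a 5.5 ml bath — the addition
count, spacing (default 60 s) and amounts are configurable, since only the
endpoint is standard — then a line V = intercept + slope·log₁₀(c) through
the plateau voltages, each plateau being the mean from 10 s after its
addition (settling exclusion) to the next event. An ideal electrode is
recovered to 1e-9; 0.2 mV plateau noise leaves the slope biased by well
under 0.1 mV/decade.

Conversion of a voltage trace to ΔΨ_m follows the standard uptake
arithmetic: c_out from the inverted electrode law (µM); uptake =
(total − c_out)·volume (nmol); matrix free concentration c_in =
uptake/protein × 0.17 mg µl⁻¹ (the empirical binding correction, applied
verbatim), which lands in nmol µl⁻¹ ≡ mM; then ΔΨ_m = 61.5·log₁₀(c_in/c_out)
with c_out converted to mM first. The unit harmonization deserves emphasis
because the conventional description leaves it implicit: the ratio is taken
with both concentrations in mM. Mass balance (c_out·V + uptake = total·V)
holds exactly by construction. Negative uptakes are clipped to zero and
flagged; only a *systematic* excess (more than 1% of samples beyond a 2%
tolerance of the total) is fatal, because isolated excursions beyond any
fixed per-sample tolerance are statistically certain near zero uptake under
realistic voltage noise.

# The sigmoidal calibration

fb_L maps to ΔΨ_m through the Prism-style "sigmoidal dose–response,
variable slope" logistic in untransformed millivolts,

$$\mathrm{fb_L}(\Delta\Psi) = \mathrm{bottom} +
  \frac{\mathrm{top} - \mathrm{bottom}}
       {1 + 10^{(v_{50} - \Delta\Psi)\,\mathrm{hill}}},$$

with decade base (natural-log variants are absorbed into `hill`, units
per mV). Fitting uses Levenberg–Marquardt from a fixed multi-start grid —
bottom/top from the 5%/95% data quantiles, v50 from the median potential,
hill ∈ {0.01, 0.03, 0.1} per mV in fixed order — making the fit
deterministic; the covariance comes from the final Jacobian. Weighting is
available but off by default (it is usually unknown whether condition means
should be weighted by replicate count). Degenerate inputs (constant fb_L,
or points that do not span both limbs of the sigmoid) are refused before
fitting.

Inverse prediction uses the closed-form inverse on the interior and
*censors* outside: within `margin` (default 1%) of either asymptote, or
where the implied potential leaves the calibrated domain, the estimate is
pinned to the corresponding domain bound and labeled `above`/`below`. This
mirrors the physical situation — near the asymptotes a small fb_L change
corresponds to an enormous potential change, so a number there would be
meaningless; a bound is honest. Confidence bands use case-resampling
bootstrap (percentile, default B = 500, ≥ 200 enforced, seed-reproducible)
rather than the delta method, because the inverse is strongly nonlinear
exactly where censoring matters. In the package's calibration study
(23 condition means, fb_L noise SD 0.02), v50 is recovered with bias below
0.1 mV and the 95% band covers the true curve at ≈ 92% of grid points —
pointwise percentile bands at n = 23 are known to undercover slightly.

# The ischemia–reperfusion pipeline

`run_pipeline()` composes absorbance → trailing rolling average (default 4
consecutive spectra; trailing because the acquisition is causal at 1 Hz) →
unmixing → SNR flagging → fb_L → censored inversion, one row per averaged
spectrum, deterministically. Phase summaries take mean ± SD over windows
centred on named checkpoints (control; 10/20 min of ischemia; 1/2/5/10/20
min of reperfusion); the 30 s window width is a package choice, as
checkpoint averaging windows are not standardized. Any window containing
censored rows yields a bound, never a plain mean (a mean over
censored-above bounds and interior points is still a valid lower bound);
windows with both censoring directions report NA.

The secondary-decline detector finds the late-ischemic collapse of ΔΨ_m
(when glycolytic ATP can no longer sustain the potential via reverse
operation of the ATP synthase, coinciding with hypercontracture). It is a
smoothed-derivative threshold detector, not formal changepoint inference —
the event is descriptive, and a transparent detector with exposed
parameters is easier to reason about. Defaults: centred 61 s smoothing
window, slope threshold −0.15 mV s⁻¹ sustained for 5 s, after a plateau of
at least 120 s with |slope| below half the threshold. These were chosen
from the noise analysis of the default scenario: with per-spectrum fb_L
noise propagated through the steep mid-range of the sigmoid, the smoothed
slope noise is ≈ 0.02 mV s⁻¹, giving a detection jitter of a few seconds
against an injected decline of ≈ 0.34 mV s⁻¹ and no false triggers on the
plateau. With the degenerate threshold 0 the detector fires at the first
sustained negative slope.

Heart rate is peak counting on the pulsatile flow trace (each flow wave =
one beat): peaks above 20% of the wave amplitude, minimum inter-beat
interval 0.1 s, counted per sliding minute; a flat trace is 0 bpm.
Metabolite utilities implement the internal-standard ratio (succinate),
the CoQH₂/(CoQH₂+CoQ) percent reduction, and PCHIP interpolation for sparse
timecourses — PCHIP rather than the base monotone Hermite spline because
the latter guarantees monotonicity only over monotone data runs and
overshoots next to local extrema, whereas PCHIP clamps slopes at extrema
and introduces no new extrema between points, which is the property sparse
biochemical timecourses need.

# The synthetic-data generators

## What they emulate

Reference spectra are sums of Gaussian sub-bands standing in for the
empirically collected references (which are not published as data):
cytochrome c at 550 nm, c₁ at 552 nm, b_H at 562 nm. The b_L reference is
modeled with its main feature at 566 nm plus a 558 nm shoulder at half
height — the two features that characterize the empirical b_L difference
spectrum — rather than as a single band at its nominal 564 nm peak; the
shape distinction between b_L and b_H, not the 2 nm peak separation, is
what makes the pair separable in noise, for the synthetic references
exactly as for the empirical ones. Libraries carry per-chromophore nominal
peak metadata, and all band parameters are configuration, so empirical
references can replace the Gaussians without code changes. MbO is twin
bands at 542/580 nm, MbD one broad band at 556 nm.

Noise is added in the *count* domain (on transmitted intensity), matching
the physical instrument and inducing the wavelength-dependent
heteroscedasticity of real absorbance noise — which is precisely what the
SNR exclusion rule must handle. `noise_for_target_snr()` inverts the SNR
statistic analytically so studies can be run at a prescribed statistic
level (e.g. ten times the exclusion threshold).

Amplitude scales are fixed per instrument context: mitochondrial-suspension
scenarios use a total b-heme amplitude of 0.05 OD (c₁ 0.03, c 0.04);
transmural heart scenarios use four times that (b total 0.2 OD, c₁ 0.12,
c 0.16), reflecting the much longer, scattering-amplified transmural path.
The default ground-truth calibration curve (bottom 0.15, top 0.65, v50
140 mV, hill 0.03 per mV, domain 60–208 mV) is consistent with the
observable anchors of the method: fb_L ≈ 0.18–0.20 near 101 mV, ≈ 0.58 at
166 mV, and a ceiling of ≈ 0.645 at the 208 mV domain top above which
estimates are censored.

The default ischemia–reperfusion scenario (10 min control / 20 min
ischemia / 20 min reperfusion at 1 Hz) injects: a 166 mV control plateau; an
exponential drop (τ = 20 s) to a 133 mV ischemic plateau; a linear secondary
decline to 92 mV beginning 13 min into ischemia and lasting 120 s; a
hypercontracture path-length step (×1.3 on every chromophore coefficient,
leaving true fb_L untouched) at the minimum; an exponential reperfusion
rebound (τ = 15 s) to the control level with a late drift to 150 mV; and a
cytochrome c reduction trace that rises at the onset of ischemia and
reverses on reperfusion. Default count noise is calibrated to a
per-raw-spectrum SNR statistic of 2000 — comfortably above threshold, as
continuous Mb-free recordings are in practice.

The titration generator emits paired optical and electrode streams from one
truth: external probe concentration from probe mass balance and the Nernst
relation (closed form), electrode voltage from the Nernstian electrode law
with first-order settling (τ = 1.5 s), and spectra from the true curve's
fb_L at each commanded potential.

## What passing tests do and do not show

Every generator is seed-deterministic and emits truth aligned row-for-row,
and every forward–inverse pairing is tested: noise-free generator output
passed through the corresponding inference module reproduces truth to the
stated tolerance. These studies verify the *inference chain* — that the
estimators are unbiased, that censoring and exclusion trigger exactly where
the formulas say, that recovery degrades as theory predicts with noise.
They cannot validate the *physics*: Gaussian sub-bands are an idealization
of empirical reference shapes, count noise is an idealization of real
detector statistics, and the true fb_L–ΔΨ_m relationship in tissue is
exactly what a real calibration must establish. Recovery results on
synthetic data therefore transfer to real data only to the extent that the
fitted references match the tissue's chromophores — reference-shape
mismatch is the dominant unmodeled risk, and sensitivity to it should be
studied, not assumed away.

# Numerical choices and degenerate inputs

* Resampling is plain linear interpolation, never smoothing; extrapolation
  is refused.
* Unit-peak normalization is asserted to 1e-12 after every library
  construction or alignment.
* The unmixing design is solved with the wavelength column standardized;
  rank deficiency errors out with the condition number.
* The 4PL constructor normalizes the representation (bottom < top; the
  bottom/top swap with hill negation is the same curve) and refuses
  bottom = top.
* Bootstrap bands error out if more than 10% of refits fail.
* Rolling averages require window ≤ series length; summaries require ≥ 3
  samples.
* Problem sizes in the verification studies — 1,000 spectra for the oracle
  comparison, 200 replicates for the noisy-recovery RMSE, 100 seeds for the
  electrode and coverage studies, one 50-min scenario for the end-to-end
  run — were chosen to bring Monte-Carlo error well below the tolerances
  being checked while keeping the whole suite to about a minute.

# Known limitations

* No scattering physics beyond the linear baseline term; integrating-sphere
  optics are not modeled.
* No electrode drift correction or probe-toxicity corrections; the
  electrode model assumes isolated mitochondria (no plasma-membrane
  potential component).
* The calibration model is single-level (no hierarchical per-replicate
  structure) and temperature dependence of the Nernst slope is not modeled
  (61.5 mV/decade is used as the conventional constant).
* The hypercontracture path-length artifact is deliberately *not* corrected
  in the cytochrome c amplitude output — it is a real optical effect that
  fb_L, by construction, does not share; downstream users of `cytc_amp`
  should treat late-ischemic apparent increases with caution.
* ΔpH, and hence the full protonmotive force, is out of scope: the package
  estimates ΔΨ_m only.
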