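# mitopsi

Real-time optical inference of mitochondrial membrane potential (ΔΨ_m) from
cytochrome *bc*₁ b-heme absorbance.

## The problem

ΔΨ_m — the electrical component of the protonmotive force across the
mitochondrial inner membrane — drives ATP synthesis and shapes
ischemia–reperfusion injury, but conventional probe-based measurements are
too slow and too invasive for the intact, perfused heart. The *bc*₁ complex
offers an endogenous voltmeter: its two b hemes, b_L and b_H, sit near
opposite faces of the inner membrane, exchange electrons on a microsecond
timescale, and shift their relative reduction state with ΔΨ_m. Because each
reduced heme has a distinct α-band absorbance (b_H ≈ 562 nm, b_L ≈ 564–566 nm
with a 558 nm shoulder), multi-wavelength transmission spectroscopy can read
ΔΨ_m out of the tissue continuously, with no exogenous probe.

`mitopsi` is a tested R implementation of that whole inference chain, for
spectroscopists and mitochondrial physiologists who want to apply it to
their own recordings or study its statistical behavior on synthetic data
with known ground truth.

## The model

**Unmixing.** A dark-corrected absorbance spectrum
A(λ) = log₁₀((I₀−D)/(T−D)) over the α band (540–580 nm; 535–585 nm when
myoglobin must be co-fit) is decomposed by linear least squares into

    A(λ) = a·b_H(λ) + b·b_L(λ) + c·c₁(λ) + d·cytc(λ) [+ MbO, MbD] + e·λ + f

where the references are unit-peak-normalized reduced-chromophore spectra and
the line absorbs residual scattering and flat oxidized-cytochrome absorbance.
The model is linear in a–f, so the fit is solved directly by QR; a
signal-to-noise statistic (quartet component sum / sum-squared residuals,
exclusion below 100) flags unusable spectra.

**The fb_L statistic.** fb_L = b_L/(b_L + b_H) — the fraction of reduced
b-heme absorbance attributable to b_L. Both hemes scale identically with
optical path length, so fb_L is invariant to tissue geometry (and to
hypercontracture, which lengthens the optical path).

**Calibration.** In isolated mitochondria, ΔΨ_m is measured independently
from the Nernstian distribution of the lipophilic cation TPMP⁺
(ΔΨ_m = 61.5·log₁₀([TPMP⁺]_in/[TPMP⁺]_out) mV, with an electrode calibrated
by stepwise additions and a 0.17 mg µl⁻¹ binding correction). fb_L relates to
ΔΨ_m through a variable-slope four-parameter logistic,

    fb_L(ΔΨ) = bottom + (top − bottom) / (1 + 10^((v50 − ΔΨ)·hill)),

fit with multi-start Levenberg–Marquardt, with bootstrap confidence bands.
Inverse prediction (fb_L → ΔΨ_m) is censored near the asymptotes: values
beyond the calibrated range are reported as bounds, never as numbers.

**Pipeline.** For an ischemia–reperfusion recording (1 spectrum/s), the chain
is: absorbance → trailing rolling average of 4 spectra → unmixing → SNR
flagging → fb_L → censored inverse prediction → phase summaries, secondary-
decline event detection, heart rate from the pulsatile flow trace, and
metabolite ratio utilities (succinate vs internal standard, CoQ percent
reduction, shape-preserving PCHIP timecourses).

A first-class synthetic-data module generates every instrument stream
(reference libraries from Gaussian band models, count-noise spectra,
Nernstian electrode traces, full ischemia–reperfusion scenarios, flow
traces) seed-deterministically, with truth tables aligned row-for-row.

## Worked example

```r
library(mitopsi)

# 1. Simulate a 50-min ischemia-reperfusion recording (1 spectrum/s)
sim <- simulate_ir_experiment(seed = 42)

# 2. Run the inference chain
series <- run_pipeline(sim$record, sim$library, sim$curve, sim$timeline)

# 3. Summaries at the standard checkpoints
summ <- phase_summary(series, sim$timeline)
print(summ[, c("label", "fbl_mean", "psi_mean", "psi_sd", "n_used")], digits = 3)
#>                label fbl_mean psi_mean psi_sd n_used
#> 1            control    0.576    165.6  2.250     31
#> 2    ischemia 10 min    0.341    133.0  1.593     31
#> 3    ischemia 20 min    0.165     87.6     NA     31
#> 4  reperfusion 1 min    0.574    165.1  2.248     31
#> 5  reperfusion 2 min    0.569    163.9  1.707     31
#> 6  reperfusion 5 min    0.584    167.4  2.174     31
#> 7 reperfusion 10 min    0.552    160.5  1.638     31
#> 8 reperfusion 20 min    0.488    150.7  0.832     31

# 4. Secondary decline during ischemia
ev <- detect_secondary_decline(series, c(600, 1800))
cat(sprintf("secondary decline at %.0f s (injected: %d s); minimum %.1f mV\n",
            ev$event_time_s, sim$events$secondary_onset_s, ev$min_value_mV))
#> secondary decline at 1378 s (injected: 1380 s); minimum 73.7 mV
```

Reading the output: the control plateau is recovered at 165.6 mV against an
injected truth of 166 mV, the ischemic plateau at 133.0 mV (truth 133), and
the reperfusion rebound returns to the control level within the first
minute. The `psi_sd = NA` at 20 min of ischemia marks a *bound*: the window
contains censored estimates (the true potential there, 92 mV, sits near the
flat bottom limb of the sigmoid, where single-spectrum inversions are
unreliable and are reported as censored), so the summary is not a plain
mean. The detected secondary-decline onset (1378 s) is within 2 s of the
injected event.

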