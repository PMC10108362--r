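# sabresim

Density-matrix simulation of **SABRE** (signal amplification by reversible
exchange) hyperpolarization of 1-¹³C-pyruvate at microtesla magnetic fields,
for spin physicists and hyperpolarized-MR methods developers who want to
predict and analyze continuous-wave (LIGHT-SABRE/SLIC) and SABRE-SHEATH
transfer without access to an ultralow-field spectrometer.

## The model

The active Ir complex is a six-spin system — two parahydrogen-derived
hydrides, three methyl protons, one carboxylate ¹³C — with couplings
J_HH = −10.5 Hz, J_HC = {0.06, 0} Hz and J_C–CH₃ = 1.2 Hz, at
B₀ = 121 µT. Hydrogen exchange at rate 1/τ_Ir (τ_Ir = 31 ms) feeds fresh
singlet pairs into the complex while pyruvate stays bound, which the package
integrates as the generalized Liouville–von Neumann equation

    dρ/dt = −2πi [H, ρ] + (1/τ_Ir) (Σ̂ Π̂ ρ − ρ),

where Π̂ removes the hydride pair (partial trace) and Σ̂ re-attaches fresh
parahydrogen. A weak CW drive near the ¹³C Larmor frequency (≈1.3 kHz)
converts singlet order to carbon polarization when it matches the
J-coupling network:

* transverse (x) polarization at ν_CW^A = −J_HH on resonance, carried by the
  ΔJ_CH/4 coupling between |S₀X₋⟩ and |T₀X₊⟩;
* longitudinal (z) polarization slightly off resonance, matched at
  ν_eff = √(Δν² + ν_A²) = −J_HH and maximized at the magic tilt angle
  arctan √2 ≈ 54.7°;
* ¹³C–¹H zz two-spin order, read out SEPP-style;
* SABRE-SHEATH as the static-field analogue, matched at
  (γ_H − γ_C) B₀ = |J_HH| ≈ 0.33 µT (lab-frame engine).

The package provides the spin-operator algebra, lab- and rotating-frame
Hamiltonians, the exchange generator with three propagation paths (Krylov
exponential action, dense superoperator exponential, Strang splitting),
protocol/readout emulation (direct transverse, crusher + 90°, SEPP), 2D
amplitude/offset scans, broadband spectrum synthesis with exchange
narrowing, mono-exponential build-up fitting, and seeded synthetic-data
generators. See the vignette `vignettes/sabresim-methods.Rmd` for the
methods account.

## Worked example

```r
library(sabresim)

## the catalyst-bound pyruvate spin system (reduced 3-spin oracle model)
preset <- presetPyruvateSabre(reduced = TRUE)

## analytic matching conditions for the coupling set
matchingReport(-10.5, 0.06, 0)
#>    mechanism amplitude_hz offset_hz  field_ut theta_deg transfer_element_hz
#> 1 x_transfer    10.500000  0.000000        NA  90.00000               0.015
#> 2 z_transfer     8.573214  6.062178        NA  54.73561               0.015
#> 3     sheath           NA        NA 0.3294779        NA                  NA

## 10 s of on-resonance LIGHT-SABRE at the matching amplitude
spec <- protocolSpec("light_sabre", t_hyp_s = 10,
                     drive = driveSpec("13C", 10.5, 0))
recs <- runProtocol(spec, preset)
recs$x_C
#> polarizationRecord: x[C1] = 0.005164 (bound basis)

## report as experiment would: empirical 13C scale, averaged over
## free + bound substrate
applyReporting(recs$x_C, scale = "empirical", basis = "averaged")
#> polarizationRecord: x[C1] = 0.005164 (averaged basis, scaled = 0.0001962)

## recover a build-up constant from synthetic noisy data
curve <- genBuildup(p_max = 0.011, T_hyp_s = 25.8,
                    noise = noiseSpec(5e-4, seed = 1))
fitMonoexp(curve)
#> fitResult: p_max = 0.01137 +/- 0.00036, T_hyp = 26.65 +/- 2.3 s (|r| = 0.00126)
```

The first table says: on-resonance transfer matches at a CW amplitude of
10.5 Hz; z-transfer matches at (Δν, ν_A) ≈ (6.06, 8.57) Hz, i.e. the magic
angle 54.74°; the coupling element driving both is ΔJ_CH/4 = 0.015 Hz; and
the equivalent SHEATH static field is 0.33 µT. The protocol run shows 0.52 %
transverse ¹³C polarization on the bound complex after 10 s in the reduced
model; the reporting step rescales it the way measured values are quoted.
The fit recovers the generating time constant (25.8 s) within its reported
uncertainty.

A thin CLI over the same functions lives at
`inst/scripts/sabresim-cli.R` (subcommands `simulate-scan`,
`simulate-buildup`, `fit-buildup`, `matching-report`, `spectrum`,
`gen-data`), writing CSV results plus a JSON run manifest.

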