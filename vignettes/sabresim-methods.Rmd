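---
title: "Simulating continuous SABRE hyperpolarization of 1-13C-pyruvate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating continuous SABRE hyperpolarization of 1-13C-pyruvate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabresim)
```

## The physical problem

Signal amplification by reversible exchange (SABRE) converts the nuclear
singlet order of parahydrogen (pH~2~) into polarization of a substrate bound
to an Ir catalyst. For 1-^13^C-pyruvate the package models the **active
complex** as six spin-1/2 nuclei: the two pH~2~-derived hydrides, the three
methyl protons and the carboxylate ^13^C. The coupling network that matters
at microtesla field is sparse:

* hydride–hydride $J_\mathrm{HH} = -10.5$ Hz (dominant),
* one hydride–^13^C coupling of $0.06$ Hz, the other zero — their
  *difference* $\Delta J_\mathrm{CH}$ is the transfer channel,
* ^13^C–methyl couplings of $1.2$ Hz.

Two matching strategies move singlet order onto the carbon:

* **SABRE-SHEATH** drops the static field to the level anti-crossing
  condition $(\gamma_H - \gamma_C)\,B_0 = |J_\mathrm{HH}|$, i.e.
  $B_0 \approx 0.33$ µT.
* **LIGHT-SABRE / SLIC** keeps $B_0 = 121$ µT and applies a weak
  continuous-wave (CW) field near the ^13^C Larmor frequency
  ($\approx 1.3$ kHz, audio range). On resonance, amplitude
  $\nu_\mathrm{CW}^A = -J_\mathrm{HH}$ closes the gap between
  $|S_0 X_-\rangle$ and $|T_0 X_+\rangle$, which are coupled by
  $\Delta J_\mathrm{CH}/4$; transverse (x) carbon polarization builds up
  along the CW field. Slightly off resonance the carbon quantization axis
  tilts by $\theta = \arctan(\nu_A/\Delta\nu)$ and matching at
  $\nu_\mathrm{eff} = \sqrt{\Delta\nu^2 + \nu_A^2} = -J_\mathrm{HH}$
  generates longitudinal (z) polarization, most efficiently where
  $\sin 2\theta \sin\theta$ peaks — the magic angle
  $\arctan\sqrt{2} \approx 54.7^\circ$:

```{r magic}
magicAngle()
zTransferCondition(-10.5)[c("delta_nu_hz", "nu_A_hz")]
sheathMatchingField(-10.5)
```

## The evolution model

Hydrogen exchange is the engine of the method: the bound pair leaves and
fresh pH~2~ arrives while the substrate stays bound. The package integrates
the generalized Liouville–von Neumann equation

$$\dot\rho \;=\; -\,2\pi i\,[H,\rho]\;+\;\frac{1}{\tau_\mathrm{Ir}}
\bigl(\hat\Sigma\hat\Pi\,\rho-\rho\bigr),$$

where $\hat\Pi$ traces the hydride pair out of the complex density matrix
and $\hat\Sigma$ re-attaches a fresh pair in the feed state (pure singlet by
default, or $f\,|S\rangle\!\langle S| + \tfrac{1-f}{3}\sum_i
|T_i\rangle\!\langle T_i|$ for enrichment $f$). $\tau_\mathrm{Ir} = 31$ ms
is the complex lifetime. The replacement map is idempotent, trace-preserving
and completely positive, so the exchange term is a valid dissipator; the
model deliberately treats exchange as a deterministic first-order flow, not
stochastic jumps, which keeps the generator time-independent in the rotating
frame and makes single-exponential propagation possible. Transient complexes
and substrate (pyruvate) dissociation are not modeled. No relaxation
superoperator is included by default (an optional uniform damping toward
$I/d$ exists but is off): experimental polarization magnitudes are instead
connected to simulated ones by the post-hoc reporting factors below.

### Frames and truncation

Two Hamiltonian constructions cover the two regimes:

* `rotatingFrameHamiltonian()` — each isotope in its own rotating frame
  (^13^C at the drive frequency), rotating-wave approximation on the drive,
  homonuclear couplings kept in full, heteronuclear couplings truncated to
  $I_zS_z$ *only* when the Larmor separation exceeds
  `truncation_threshold` (default 100) times the coupling. At 121 µT the
  ^1^H–^13^C separation is $\approx 3.9$ kHz, far above $100\times1.2$ Hz,
  so the truncation is safe; at SHEATH fields it is not, and the
  constructor refuses with an error directing to the lab frame.
* `labHamiltonian()` — full non-secular $J\,\mathbf{I}\cdot\mathbf{S}$
  couplings and, when a drive is present, the linearly oscillating
  transverse field sampled in time. `evolveLabFrame()` integrates it with
  piecewise-constant steps, at least 50 per period of the fastest
  frequency; the step unitaries repeat with the drive period and are
  cached, and the exchange step is interleaved in Strang fashion every few
  hundred microseconds. A standing regression test checks the two frames
  agree within 1 % on the reduced model after 1 s of CW.

Units: $J$, drive amplitudes and offsets in Hz; fields in µT; times in s.
The single $2\pi$ lives inside the generator. Positive offset means the
drive is above the ^13^C Larmor frequency; z-polarization is odd and
x-polarization even under offset sign flip, which fixes every other sign
convention observably. Basis ordering is big-endian over the declared spin
list (hydrides, then methyls, then carbon), $|\alpha\rangle$ before
$|\beta\rangle$. Hydride chemical shifts are set to 0 and 2 ppm — only the
2 ppm *difference* is physical input; absolute shifts are irrelevant at
121 µT (the difference amounts to 0.01 Hz, retained anyway).

### Propagation paths and tolerances

Three interchangeable integrators back `evolve()`:

* **Krylov** (`"krylov"`, default for the 64-dimensional full system):
  Arnoldi approximation of the exact exponential action of the full
  generator on vec($\rho$), matrix-free, subspace dimension 30 with
  adaptive substeps, truncation tolerance $10^{-10}$.
* **Dense superoperator** (`"superop"`, default at $d \le 8$): the
  $d^2\times d^2$ generator matrix exponentiated by a complex Padé-13
  scaling-and-squaring routine. This is the exact cross-check path; the
  Krylov path agrees with it to $\sim10^{-15}$ on the reduced model.
* **Strang splitting** (`"split"`): exact phase evolution in the
  Hamiltonian eigenbasis alternated with the closed-form exchange step
  $e^{tR}\rho = e^{-t/\tau}\rho + (1-e^{-t/\tau})\hat\Sigma\hat\Pi\rho$
  (available in closed form because the replacement map is idempotent).
  Every sub-step is completely positive and exactly trace preserving;
  the $O(\mathrm{d}t^2)$ splitting error is $\sim10^{-7}$ at the 1 ms
  default step over 1 s. Used for the time-dependent lab engine and for
  dwell-time stepping in spectrum synthesis.

State invariants (trace, Hermiticity, positivity) are asserted at
$10^{-8}$; observable comparisons at $10^{-6}$ absolute unless a test
states otherwise. Quasi-steady values are obtained by long-time
propagation (ten build-up times), never by null-space solving — the
exchange generator has slow, nearly degenerate modes and only finite-time
values are physically reported.

## Protocols, readouts and reporting

`runProtocol()`/`scan2d()` emulate the experimental sequences: evolve the
freshly loaded complex (singlet hydrides, everything else maximally mixed —
thermal polarization at 121 µT is $\sim10^{-9}$ and ignored) for
$t_\mathrm{hyp}$, then read out:

* *direct transverse* — the x record along the CW phase, no pulses;
* *crusher + 90°* — coherences are zeroed (ideal-gradient limit:
  projection onto the Zeeman product-basis diagonal), then ideal
  instantaneous 90° pulses on both channels convert z order to observable
  transverse magnetization; records are the pre-pulse z values;
* *SEPP* — crusher, 90° on ^1^H only, then 180° on both channels; records
  the ^13^C–methyl zz order and the resulting in-phase proton observable.

One evolution per scan grid point serves all three maps. The default grids
reproduce the published maps: amplitude 2–20 Hz in 0.5 Hz steps, offset
−15…15 Hz in 0.3 Hz steps, $t_\mathrm{hyp} = 10$ s. On one CPU a 37-point
amplitude scan of the full system runs in roughly a minute and the
101-point offset scan in about three (Krylov path); these are the problem
sizes used throughout the tests and the acceptance script, with the 3-spin
reduced model (two hydrides + ^13^C) as the fast oracle for property
tests.

Two reporting conventions connect raw bound-complex polarization to
reported numbers, both pure arithmetic applied by `applyReporting()`:
empirical per-isotope scale factors (0.38 for ^13^C, 3.4 for ^1^H) that
absorb unmodeled losses, and the bound→averaged division by 10 reflecting
the 10-fold excess of free substrate (free pyruvate receives no transfer at
the working temperature and is not simulated). The simulation itself never
uses these factors; polarization *positions* (matching amplitudes, extrema
offsets, build-up constants) are scale-free predictions.

## Spectra and exchange narrowing

`simulateSpectrum()` emulates broadband (SQUID-style) detection: the FID is
$\mathrm{Tr}\,[D\rho(t)]$ with $D=\sum_i w_i\gamma_i(I_{x,i}-iI_{y,i})$,
sampled at the dwell time (Nyquist-checked against every detected Larmor
frequency), exponentially apodized (default 0.1 Hz, small enough that
exchange dominates lineshapes), zero-filled fourfold and Fourier
transformed. Peaks and widths are measured on the magnitude spectrum — note
a magnitude-mode Lorentzian of absorption width $lb$ has FWHM
$\sqrt{3}\,lb$. With the quartet fixture (one ^13^C coupled at 1.2 Hz to
three exchanging protons) the 1:3:3:1 multiplet is resolved without
exchange and collapses to a single line at $\tau_\mathrm{Ir}=31$ ms,
because couplings below $\sim1/\tau_\mathrm{Ir}\sim30$ Hz cannot survive
the replacement rate; resolvability shrinks monotonically with
$\tau_\mathrm{Ir}$.

## Synthetic data

The generators in `genBuildup()`, `genScanMap()` and `genSpectrum()` stand
in for the measurements: mono-exponential build-up curves (defaults:
plateau 1.1 % averaged basis, constants 15.8/25.8 s, 12 points over
[0, 80] s), noisy scan maps, and Lorentzian spectra with sub-0.3 Hz lines
scaled to a requested peak/noise-RMS (8000 emulates single-shot
sensitivity). Noise is i.i.d. Gaussian — the experiments publish only an
SNR, so the simplest exchangeable model is the honest choice; the build-up
noise level $\sigma = 5\times10^{-4}$ is a convention chosen to make the
published scatter plausible, not a measured quantity. All generators are
pure functions of (parameters, seed) and restore the caller's RNG stream.
What passing the pipeline tests shows is parameter recovery under *these*
assumptions; real data may carry correlated drift (e.g. slow sample
degradation), which is deliberately not emulated.

`fitMonoexp()` fits $p(t)=p_\mathrm{max}(1-e^{-t/T_\mathrm{hyp}})$ by
bounded Levenberg–Marquardt (offset optional, off by default since curves
start at zero by construction; initialization from the last sample and the
$1-1/e$ crossing; $T$ bounded by ten times the observation window;
unweighted least squares, as no error bars per point are available).
Standard errors come from the Gauss–Newton covariance; at the default noise
level the recovered $T$ scatters by roughly 10 % and is unbiased to < 5 %
over 200 replicates.

## Known limitations

* No relaxation ($T_1$, $T_{1\rho}$) and no transient-complex chemistry:
  absolute polarization magnitudes are only meaningful after the empirical
  reporting scale, which is fitted, not predicted.
* The crusher and all pulses are ideal and instantaneous; shaped RF and
  gradient physics are out of scope.
* The pairwise secular-truncation criterion is local: it does not detect
  multi-spin anti-crossings, which is why SHEATH simulations always use
  the lab-frame engine.
* Spins > 1/2 and nuclei other than ^1^H/^13^C are not supported.
* Detection weighting across isotopes is a cosmetic choice (it affects
  spectra, not polarization records).
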