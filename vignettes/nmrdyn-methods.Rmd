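---
title: "Models and numerical choices in nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

`nmrdyn` implements the quantitative analysis chain of a
denaturant-destabilization NMR study of a small folded protein domain:
chemical-shift-perturbation titrations with one-site Kd fitting,
Lipari–Szabo model-free analysis of backbone ¹⁵N relaxation,
two-state CPMG relaxation-dispersion fitting across two static fields,
and two-state van't Hoff thermal melts. This vignette explains each
model, the tunable parameters and their defaults, the numerical choices
made where the methodology literature leaves them open, and what the
synthetic-data generators do and do not emulate.

## Titration analysis

An HSQC titration follows each backbone amide cross-peak over a series
of ligand (here: chaotropic salt) concentrations. Peak displacement is
summarized by the weighted shift index

$$\mathrm{CSD} = \sqrt{(\Delta\delta_{1H})^2 +
  (\Delta\delta_{15N}/4)^2}\ \text{(ppm)},$$

the standard 1/4 weighting reflecting the roughly four-fold larger
dispersion of amide ¹⁵N shifts. `csd_index()` / `compute_csd()`
implement this; the index is a norm on the shift deltas (nonnegative,
zero only at identity, absolutely homogeneous), which the test suite
asserts property-style.

Residues that move significantly are flagged by `flag_significant()`
against a mean + 1 SD threshold across residues at a chosen
concentration. Because the study tier this reproduces did not state its
SD convention, both are available; the default is the population
(n-denominator) form, switchable via `sd_type`. Whether termini or
prolines enter the mean is likewise left to the caller through
`exclude`.

Binding is quantified per residue with the one-site quadratic isotherm
without the free-ligand approximation,

$$\mathrm{CSD}_{obs} = \mathrm{CSD}_{max}\,
  \frac{([P]+[L]+K_d) - \sqrt{([P]+[L]+K_d)^2 - 4[P][L]}}{2[P]},$$

with the protein concentration fixed (0.25 mM in the emulated study;
with millimolar $K_d$ and micromolar protein the curve is close to the
hyperbolic limit, and the quadratic form costs nothing). `fit_kd()`
uses Levenberg–Marquardt least squares with multi-start initialization
($K_d \in \{10, 50, 100, 500\}$ mM, $\mathrm{CSD}_{max}$ at 1.2× the
largest observed CSD), the best residual winning and ties broken toward
the smaller $K_d$. Missing (exchange-broadened) peaks are dropped, not
imputed. Fits whose $\mathrm{CSD}_{max}$ falls below three times the
per-point noise estimate are flagged unreliable — this mirrors the
practical situation where weakly interacting denaturants produce CSDs
too small to fit.

## ¹⁵N relaxation and model-free analysis

Backbone amide ¹⁵N relaxation is modeled with the dipolar + CSA rate
expressions

$$R_1 = \tfrac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
  6J(\omega_H+\omega_N)] + c^2 J(\omega_N)$$
$$R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
  6J(\omega_H) + 6J(\omega_H+\omega_N)] +
  \tfrac{c^2}{6}[4J(0) + 3J(\omega_N)] + R_{ex}$$
$$\mathrm{NOE} = 1 + \tfrac{d^2}{4}\,\tfrac{\gamma_H}{\gamma_N}\,
  \tfrac{1}{R_1}[6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]$$

with $d = \mu_0 h \gamma_H|\gamma_N|/(8\pi^2 r_{NH}^3)$ and
$c^2 = (\omega_N\Delta\sigma)^2/3$. Since $\gamma_N < 0$, the
steady-state NOE is bounded above by 1 — asserted over a $10^4$-draw
parameter sweep. Physical constants not fixed by the emulated study are
set to standard backbone-amide values and are all overridable in
`spin_constants()`: $r_{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm,
$\gamma_H = 2.6752\times10^8$, $\gamma_N = -2.7116\times10^7$
rad s⁻¹ T⁻¹, and a ¹⁵N/¹H frequency ratio of 0.101329446 for all
ppm↔rad/s conversions.

The spectral density is the extended Lipari–Szabo form

$$J(\omega) = \tfrac{2}{5} S_f^2\left[\frac{S_s^2\,\tau_m}
  {1+(\omega\tau_m)^2} + \frac{(1-S_s^2)\,\tau}{1+(\omega\tau)^2}\right],
  \qquad \tau = \frac{\tau_s\tau_m}{\tau_s+\tau_m},$$

reducing to the classic one-timescale form when $S_f^2 = 1$. The model
catalogue is the usual five: {S²}, {S², τe}, {S², Rex}, {S², τe, Rex},
{Sf², Ss², τs}.

Numerical and design choices:

* **Diffusion model.** Overall tumbling is isotropic ($\tau_m$ only).
  The study tier this emulates selected an axially symmetric tensor from
  a structure-based analysis; that requires per-residue N–H vectors from
  a coordinate file and is out of scope here. For a nearly spherical
  39-residue domain the anisotropy correction perturbs absolute S² only
  mildly, but it is a documented deviation: per-residue parity with a
  tensor-based analysis is not claimed, only recovery on synthetic data
  generated under the isotropic model.
* **τm estimation.** `estimate_tau_m()` inverts the rigid-limit
  (S² = 1, Rex = 0) R2/R1 ratio at the 10 %-trimmed mean of per-residue
  ratios, over residues with NOE > 0.65. Both thresholds are arguments.
  Trimming makes the estimate exactly insensitive to a single
  exchange-inflated residue, which the tests assert.
* **Model selection.** Candidates are scored by χ² + 2k (Akaike
  criterion). With three observables per residue at a single field, the
  small-sample "corrected" AIC denominator $n-k-1$ vanishes for two-
  and three-parameter models, so the correction term is undefined; the
  plain AIC penalty is used instead, and it still enforces the nesting
  guard (a larger model is never selected without a strictly smaller
  residual). An ascending F-test selection (α = 0.2) is available via
  `criterion = "ftest"`.
* **Weights and errors.** Residuals are weighted by 1/SE²; when a
  record carries no uncertainties, 2 % of the rate (0.02 absolute for
  the NOE) is assumed. Parameter SEs come from seedable Monte-Carlo
  resampling of the observables (`n_mc`).
* **Exclusions.** Prolines, overlapped peaks and incomplete records are
  dropped by `fit_dataset()` via `exclude` and completeness checks, and
  recorded in the output.

The measured rotating-frame rate is converted with
`r2_from_r1rho()`: $R_2 = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta$,
$\tan\theta = \omega_{SL}/\Omega$ (1.6 kHz spin-lock default). When
offsets are not supplied the on-resonance identity $R_2 = R_{1\rho}$ is
used — the emulated acquisition did not publish its offset handling, so
this default is declared rather than inferred.

## CPMG relaxation dispersion

Effective rates come from the constant-time intensity ratio
$R_2^{eff} = -\ln(I(\nu_{CPMG})/I_0)/T_{CP}$ with $T_{CP}$ = 50 ms. The
two-state forward model assumes ideal 180° pulses and equal intrinsic
rates in both exchanging states; schedule algebra is
$\delta = 1/(4\nu_{CPMG})$ with $n = T_{CP}\nu_{CPMG}$
echo cycles of duration $4\delta$.

For single-quantum dispersions ($\Delta\omega_H = 0$) the closed form in
`cr_dispersion()` is *exact*: the one-cycle evolution map
$U = P(\delta)\,\overline{P(2\delta)}\,P(\delta)$ (free precession with
exchange, conjugation for each ideal refocusing pulse) is diagonalized
analytically, giving the Carver–Richards dominant eigenvalue together
with the exact mode-mixing amplitude factor. The perturbative amplitude
correction often quoted with the multiple-quantum closed form was found
to leave residuals up to ~0.5 s⁻¹ in slow exchange, whereas the exact
factor agrees with independent Bloch–McConnell propagation
(`bm_oracle()`, which steps the magnetization through every pulse and
delay) to ~10⁻¹² s⁻¹; the test suite asserts < 0.1 s⁻¹ over 100 random
draws, and the Luz–Meiboom expression is reproduced within 2 % in fast
exchange. For multiple-quantum profiles ($\Delta\omega_H \ne 0$) the
Korzhnev closed form (eigenvalue plus $-\ln(Q)/T_{CP}$) is used; it is
validated only through its SQ limit here.

`fit_two_state()` shares ($p_B$, $\Delta\omega_N$, $k_{ex}$) across
fields with one $R_2^0$ per field, weighted by reported R2eff errors.
Two fields are required — at a single field $p_B$ and $\Delta\omega$
are degenerate outside slow exchange, so single-field input is refused
rather than fitted. Multi-start covers
$p_B \in \{0.01, 0.03, 0.08, 0.15\}$,
$\Delta\omega \in \{0.1, 0.3, 0.6, 1.0\}$ ppm,
$k_{ex} \in \{100, 400, 1000, 3000\}$ s⁻¹; best reduced χ² wins, ties
toward the smaller $k_{ex}$. SEs come from seedable Monte-Carlo
resampling.

**Flat-curve guard.** Curves with dispersion amplitude below 1 s⁻¹
*relative to their reported uncertainties* return a no-exchange result
($p_B$ pinned to 0) instead of a spurious fit. Exact (noiseless) curves
are held only to a machine-flatness threshold (10⁻³ s⁻¹): several
published parameter sets produce real but sub-1 s⁻¹ dispersions at
R₂⁰ = 8 s⁻¹, and with noiseless input these are perfectly well
determined, so refusing them would be wrong. This split threshold is a
deliberate package choice.

The scalar profile summary `delta_r2eff()` differences R2eff at 80 and
960 Hz and flags a residue as dispersing when the difference strictly
exceeds 4 s⁻¹.

The exact SQ profile is *not* monotone in $\nu_{CPMG}$ everywhere: in
deep slow exchange ($\Delta\omega \gg k_{ex}$) it genuinely oscillates
as echo spacing and shift difference go in and out of resonance.
Monotonicity is asserted only over the validated regime
($p_B \le 0.15$, $\Delta\omega \le 1$ ppm, $k_{ex}\in[50, 5000]$ s⁻¹).

## Thermal unfolding

Melts are fit with the minimal two-state van't Hoff model consistent
with a reversible unfolding transition: temperature-linear folded and
unfolded baselines mixed by

$$f_U(T) = \frac{K}{1+K},\qquad
  K = \exp\!\left[-\frac{\Delta H_{vH}}{R}
  \left(\frac{1}{T}-\frac{1}{T_m}\right)\right]$$

(T in kelvin internally, $\Delta C_p$ fixed at 0 — not identifiable
from a single melt). Six parameters: $T_m$, $\Delta H_{vH}$ and the two
baselines. $f_U(T_m) = 1/2$ by construction. A transition must be
present: if a single straight line explains the curve at the edge-noise
level (flat curve *or* pure baseline drift), `fit_melting()` raises an
error instead of returning an unbounded fit. The fit is invariant to
affine rescaling of the ellipticity axis. Reversibility of the melt is
a user-asserted property, not something the fit checks.

`delta_tm()` reports $T_m(\mathrm{reference}) -
T_m(\mathrm{perturbed})$, so destabilization is positive.

## Synthetic data: what it emulates, and what it does not

Every analysis stage has a seeded forward-model generator producing the
same tab-delimited tables the readers accept, at the emulated study's
acquisition schedules: titration at 0, 3, 6, 10, 20, 30, 40, 60, 80,
100, 125, 150, 200 mM ligand with 0.25 mM protein; T1 delays 10–500 ms
(repeat at 200 ms) and T1ρ delays 1–180 ms (repeat at 90 ms); CPMG
frequencies 40–960 Hz (repeat at 120 Hz) with $T_{CP}$ = 50 ms at 500
and 800 MHz; melts on a 20–90 °C grid.

Design choices of the generators:

* Noise is homoscedastic Gaussian — on ppm for peak positions, on
  intensities for relaxation/CPMG (thermal noise dominates HSQC
  detection), on ellipticity for melts. The emulated study published no
  noise magnitudes, so defaults are config values, stated not inferred.
* Random streams are split per residue by a deterministic hash of the
  residue id, so adding residues to a configuration never perturbs
  existing residues' draws; identical (seed, config) gives
  bit-identical tables, and `noise_sd = 0` returns the forward model
  exactly.
* Titration peaks move along a per-residue unit direction in
  $(\Delta\delta_{1H}, \Delta\delta_{15N}/4)$ space (default 45°,
  configurable); the ¹⁵N component is scaled ×4 so the weighted index
  of the displacement equals the model CSD. Published CSD analyses do
  not decompose the index back into axes, so this geometry is a
  generator convention.
* On-resonance R1ρ decays are generated at the model R2.

What passing tests on these data do **not** show: the generators draw
from the same forward models the fitters invert, so recovery tests
establish correctness and identifiability of the estimators — not
robustness to lineshape overlap, peak-tracking errors, baseline
artifacts, off-resonance effects, anisotropic tumbling, or temperature
instability, none of which are simulated. Raw FIDs, 2D lineshapes and
peak assignment are out of scope by design.

## Problem sizes and runtime

The shipped test-suite and acceptance problem sizes are chosen as the
smallest that exercise each claim meaningfully: 100-draw
closed-form/oracle sweeps, a 200-draw model-free recovery sweep at 2 %
noise, a 50-rep melt recovery sweep, 10⁴-draw identity sweeps, and
full-schedule noiseless recoveries for the published parameter sets.
The whole suite runs in under two minutes on one core; the acceptance
script in well under one.

## Known limitations

* Isotropic tumbling only; no per-residue diffusion models and no
  simultaneous multi-field model-free fitting.
* Equal intrinsic rates in both exchange states; no off-resonance or
  finite-pulse-width CPMG corrections; no three-site exchange; no
  TROSY-type dispersions.
* Multi-site/cooperative binding and ΔG extraction from isothermal
  denaturation are out of scope.
* The MQ dispersion branch is validated only in its SQ limit.
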