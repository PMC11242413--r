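# nmrdyn

Quantitative analysis of protein stability and backbone dynamics from
solution NMR and CD data, built around the measurement chain used to
study how chaotropic denaturants (GdmCl, NaSCN) destabilize a small
folded WW domain at pre-unfolding concentrations. It is aimed at
protein NMR spectroscopists who have assigned peak lists, relaxation
decay tables, CPMG dispersion profiles and thermal melts in hand and
want a scripted, reproducible path from those tables to binding
constants, order parameters, exchange parameters and melting
temperatures.

Four analysis stages, each usable on its own:

* **Chemical-shift-perturbation titrations** — weighted amide shift
  index CSD = √((Δδ₁H)² + (Δδ₁₅N/4)²), mean + SD significance
  flagging, and per-residue dissociation constants from the one-site
  quadratic isotherm
  CSD_obs = CSD_max · {([P]+[L]+K_d) − √(([P]+[L]+K_d)² − 4[P][L])} / (2[P]).
* **¹⁵N relaxation / model-free analysis** — dipolar + CSA rate
  equations for (R₁, R₂, NOE), extended Lipari–Szabo spectral densities
  J(ω), monoexponential decay fitting, R₁ρ→R₂ conversion, overall
  correlation time from trimmed R₂/R₁ inversion, and per-residue model
  selection over the five-model catalogue {S²}, {S², τe}, {S², Rex},
  {S², τe, Rex}, {Sf², Ss², τs}.
* **CPMG relaxation dispersion** — R₂eff = −ln(I(ν)/I₀)/T_CP, an exact
  closed-form two-state single-quantum dispersion profile (Carver–
  Richards eigenvalue with exact amplitude factor), an independent
  Bloch–McConnell propagation oracle, and global two-field fits sharing
  (p_B, Δω, k_ex) with per-field R₂⁰.
* **Thermal unfolding** — six-parameter two-state van't Hoff melts with
  linear baselines; Tm, ΔH_vH and denaturant-induced ΔTm.

A fifth module generates synthetic input tables for all four stages
from the same forward models (seeded, per-residue noise streams), so
every estimator is testable end-to-end without spectrometer data, and
`run_pipeline()` orchestrates all stages from one configuration.

## Worked example

```r
library(nmrdyn)

cfg <- generator_config(seed = 42, noise_sd = 0)

# 1. titration: fit a dissociation constant from a CSD trace
series <- gen_titration(kd_map = c(T28 = 62.4), csd_max_map = c(T28 = 0.25),
                        p_total = 0.25,
                        concentrations = default_schedules()$titration_mM,
                        config = cfg)
print(fit_kd(series, "T28"))
#> T28: Kd = 62.4 +/- 0.0 mM, CSD_max = 0.250 +/- 0.000 ppm

# 2. CPMG: global two-field fit of a two-state dispersion
nu <- unique(default_schedules()$nu_cpmg_hz)
ep <- exchange_params(p_b = 0.10, delta_omega_n = 0.33, kex = 166.1, r20 = 8)
curves <- do.call(rbind, lapply(c(500, 800), function(f)
  data.frame(field_mhz = f, nu_cpmg_hz = nu,
             r2eff = cr_dispersion(ep, nu, f, t_cp = 0.05))))
print(fit_two_state(curves))
#> two-state fit: p_b = 10.00%, dw(15N) = 0.330 ppm, kex = 166.1 s^-1
#>   r20_500 = 8.00, r20_800 = 8.00; reduced chi2 = 3.5e-26

# 3. thermal melts: Tm and the denaturant-induced shift
ref <- fit_melting(gen_melting(63.5, 250, config = cfg, condition = "none"))
gdm <- fit_melting(gen_melting(54.5, 250, config = cfg,
                               condition = "200 mM GdmCl"))
print(ref)
#> none: Tm = 63.50 +/- 0.00 C, dH_vH = 250 +/- 0 kJ/mol
cat(sprintf("delta Tm = %.1f C\n", delta_tm(ref, gdm)))
#> delta Tm = 9.0 C
```

The titration fit returns the generating K_d of 62.4 mM exactly
(noiseless round trip); the dispersion fit recovers the minor-state
population (10 %), the ¹⁵N shift difference between the exchanging
states (0.33 ppm) and the total exchange rate (166.1 s⁻¹) shared across
the 500/800 MHz curves; and the melt pair gives the 9.0 °C melting-
temperature depression of the destabilized sample.

Real tables are read with `read_nmr_table(path, schema_id)` — see
`nmr_schemas()` for the tab-delimited layouts — and an end-to-end run
over all stages is one call:

```r
run_pipeline(default_pipeline_config(seed = 42, out_dir = "out"))
```

## Documentation

The methods vignette (`vignettes/nmrdyn-methods.Rmd`) describes every
model and its assumptions, the defaults and units of all tunable
parameters, the numerical choices (multi-start grids, model-selection
scoring, flat-curve and no-transition guards), what the synthetic data
do and do not emulate, and known limitations.
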