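# qensbilayer

Quasielastic neutron scattering (QENS), fixed-elastic-window-scan (FEWS)
and trajectory analysis of lipid-bilayer dynamics, built around the
phase behaviour of DODAB (dioctadecyldimethylammonium bromide) vesicles
— coagel, gel and fluid phases of decreasing chain order. It is aimed at
neutron-scattering practitioners and simulators who need the complete
modelling chain for backscattering data on bilayers: scattering laws,
per-spectrum decomposition, geometric and rate model fits, elastic-scan
analysis, and matching trajectory observables, all exercisable on seeded
synthetic data.

## Models

Spectra are decomposed per momentum transfer Q with the bilayer law

    S_bl(Q,E) = A(Q) L(Γ_lat, E) + (1 − A(Q)) L(Γ_lat + Γ_int, E)

where `L` is a unit-area Lorentzian, `Γ_lat = ħ D_lat Q²` is the Fickian
width of whole-lipid lateral diffusion, and `A(Q)` / `Γ_int(Q)` carry the
geometry and timescales of the internal motions. The coagel phase has no
resolvable lateral motion and uses `A(Q) δ(E) + (1 − A(Q)) L(Γ_int, E)`
with a resolution-shaped elastic line. The internal models are

- methyl 3-fold reorientation: elastic fraction `(1 + 2 j₀(Qb))/3`,
  width `3ħ/τ_MG` (b = 1.8 Å);
- coagel/gel chains: uniaxial jump rotation of a mobile fraction `p_x`
  on a circle of radius `a` with N_s = 12 sites, structure factors
  `B_n(Qa) = (1/N_s) Σ_i j₀(2Qa sin(πi/N_s)) cos(2πni/N_s)`;
- fluid chains: localized translational diffusion in reflecting spheres
  with linearly distributed radii `R_i` and diffusivities `D_i` over the
  18 CH₂ units (Volino–Dianoux eigenmodes, rates `ħ (x_n^l)² D_i/R_i²`),
  EISF `(P_h/3)(1+2j₀(Qb)) + (P_t/N_c) Σ_i [3j₁(QR_i)/QR_i]²`.

Hydrogen fractions are counted from the molecular formula
((C₁₈H₃₇)₂N(CH₃)₂ → P_h = 6/80, P_t = 74/80). The model half-width
`Γ_int(Q)` has no analytic form and is computed numerically. Elastic
scans give `⟨u²⟩(T)` through the Gaussian approximation
`ln[I_el(Q,T)/I_el(Q,T_min)] = −⟨u²⟩Q²/6`, with transitions located by
BIC-selected piecewise-linear change points. Trajectories yield the
incoherent intermediate scattering function `I(Q,t)` (analytic powder or
in-plane orientation averaging), its three-process decomposition
`e^{−Γ_lat t}[A₁+(1−A₁)e^{−Γ_int t}][A₂+(1−A₂)e^{−Γ_fast t}]`, C–H order
parameters `S_CH = ½(3⟨cos²θ⟩ − 1)`, and gauche/trans dihedral ratios
(gauche |φ| ∈ [45°, 75°], trans |φ| ∈ [165°, 180°] after folding).

## Worked example

Generate fluid-phase spectra at the 345 K parameter set with Poisson
counting noise, run the full inference chain, and fit the Arrhenius law
to the measured lateral diffusion pair:

```r
library(qensbilayer)

params  <- fluid_params(R_min = 0.3, R_max = 5.4,
                        D_min = cm2s_to_A2ps(0.6e-6),
                        D_max = cm2s_to_A2ps(26.1e-6), tau_MG = 2.6)
lateral <- lateral_model(3.5e-6)            # cm^2/s
ds <- generate_qens_dataset("fluid", params, lateral,
                            q = seq(0.5, 1.8, by = 0.1),
                            noise = "poisson", peak_counts = 1e4, seed = 7)
chain <- qens_inference_chain(ds$spectra, ds$resolution, "fluid",
                              n_starts = 2, seed = 7)
ar <- fit_arrhenius(c(315, 345), c(1.5e-6, 3.5e-6))
```

This prints (via the `sprintf` calls in `analysis/`-style drivers):

```
lateral diffusion D_lat = 3.51 x 10^-6 cm^2/s
largest confinement radius R_max = 5.36 A
largest chain diffusivity D_max = 25.7 x 10^-6 cm^2/s
methyl residence time tau_MG = 0.4 ps
Arrhenius activation energy E_a = 6.10 kcal/mol
```

The generating values were D_lat = 3.5×10⁻⁶ cm²/s, R_max = 5.4 Å,
D_max = 26.1×10⁻⁶ cm²/s: lateral diffusion, confinement geometry and the
chain diffusivity come back to about a percent on a single synthetic
dataset. The methyl residence time (truth 2.6 ps) does not — it is
weakly identified at these counting statistics because the methyl group
carries only 6 of 80 hydrogens; the methods vignette
(`vignettes/bilayer-dynamics.Rmd`) quantifies this.

## Analysis workflow

Numbered drivers under `analysis/` run the studies end to end on
synthetic data and write tables under `results/`:

1. `01_fews_transitions.R` — heating/cooling elastic scans, transition
   detection (sharp drop at 327 K on heating; slope changes near 311 and
   299 K on cooling), MSD curves.
2. `02_qens_coagel_gel.R` — ordered-phase spectra and inference
   (mobile fractions, rotation radii, rotational rates).
3. `03_qens_fluid_arrhenius.R` — fluid-phase spectra at three
   temperatures, LTD parameters, Fickian and Arrhenius fits.
4. `04_trajectory_observables.R` — ISF three-process decomposition,
   lateral diffusivity from trajectories, gauche/trans and S_CH
   profiles for ordered vs fluid-like chains.

`run_pipeline()` drives the same stages from a single (YAML-able)
config with one seed.

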