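# mfcsim

Simulation toolkit for bench-scale **microbial fuel cells (MFCs)** —
bioelectrochemical reactors in which electrogenic bacteria oxidize an organic
substrate (here glucose) at an anode and drive a current through an external
circuit while treating wastewater. The package is aimed at early-stage design
studies: comparing candidate anode materials and operating choices under
shared, explicitly stated modelling assumptions.

Five coupled stages, each usable on its own:

| Stage | Model | Key functions |
|---|---|---|
| Electrode kinetics | Butler–Volmer law `i = i0[exp(αnFη/RT) − exp(−(1−α)nFη/RT)]`, loss-decomposed cell voltage `V(i) = E0 − η_act − η_conc − i·ASR` | `bv_current_density`, `bv_overpotential`, `polarization_curve`, `calibrate_i0` |
| Microbial growth | Monod batch ODEs `dX/dt = (μ(S) − kd)X`, `dS/dt = −μ(S)X/Y`, `μ = μmax·S/(Ks+S)` | `monod_mu`, `simulate_batch`, `time_to_fraction` |
| Flowsheet balance | Specified-conversion stoichiometric chain: anode reactor → proton-selective separator → cathode reactor, with exact C/H/O and charge closure | `anode_reaction`, `react_stream`, `separate`, `run_flowsheet`, `max_electron_flow` |
| 2-D transport | Explicit finite-difference diffusion–reaction on a rectangular anode domain with a static biofilm band (glucose sink, 24:6 H⁺:CO₂ source) | `build_domain`, `simulate_transport`, `biofilm_profile` |
| Material screening | Seeded synthetic voltage datasets; one-way ANOVA, Anderson–Darling / Levene diagnostics, Fisher protected LSD, compact-letter ranking | `generate_dataset`, `anova_oneway`, `fisher_lsd`, `rank_materials`, `screen_materials` |

Per-material Butler–Volmer presets are shipped in
`inst/extdata/material_presets.csv`, calibrated once so that each material's
mean polarization voltage over the default envelope (50-point grid on
[0, 10] A/m², 303.15 K, `E_cell0` = 0.80 V, ASR = 0.04 Ω·m²) reproduces its
benchmark mean voltage (platinum 0.375 V … stainless steel 0.30 V). See
`vignettes/mfcsim-methods.Rmd` for every model, default and caveat.

## Worked example

```r
library(mfcsim)
report <- run_workflow(load_config())   # all five stages, default config
print(report)
```

```
MFC workflow run (seed 42)
stages: balance, electrochem, growth, transport, screening
mean voltages (V):
       platinum        graphene carbon_nanotube   graphite_felt stainless_steel
          0.375           0.360           0.342           0.320           0.300
screening: F = 22325.31, p = 3.77e-201, R2 = 0.9984, top = platinum
```

Reading the output: the mean polarization voltages rank the five anode
materials under a shared operating envelope (platinum best — lowest
activation loss). The screening block generates 30 replicate voltages per
material (σ = 0.0011 V, seed 42) and runs the one-way ANOVA: the material
effect is overwhelming (R² ≈ 99.8% of the voltage variance is between
materials), and Fisher LSD separates every pair, so platinum's first place
is statistically supported. `report$balance` additionally carries the exact
element residuals (all zero) and the coulombic bound of the flowsheet
(636.8 A equivalent for 1 mol/h glucose at 99% conversion), and
`report$growth` the terminal biomass 0.85 g/L = X0 + Y·S0.

A command-line front end for the individual stages lives at
`inst/cli/mfcsim.R`:

```sh
Rscript inst/cli/mfcsim.R polarize --material platinum --out pt.csv
Rscript inst/cli/mfcsim.R workflow --out-dir out/
```

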