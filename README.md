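# deltafold

Analysis of equilibrium chemical denaturation, aggregation kinetics and
subunit-interface geometry for oligomeric proteins, built around the
folding study of δ-crystallin — the avian lens homotetramer homologous
to argininosuccinate lyase — and its interface mutants.

The package is for protein biophysicists who measure unfolding by
tryptophan/ANS fluorescence, circular dichroism and enzymatic activity,
follow aggregation by turbidity and thioflavin T, and post-process
structure trajectories of multimeric assemblies. It covers the full
path from raw scans to thermodynamic parameters, with a synthetic-data
generator that carries known ground truth so every step is validated by
parameter recovery.

## Models at the core

**Two-state linear extrapolation (Santoro–Bolen).** An observable *y*
versus denaturant *D* with linear baselines and
ΔG(D) = ΔG°ᵤ − m·D:

    y(D) = [(yₙ + m_f D) + (yᵤ + mᵤ D) e^{−(ΔG°ᵤ − mD)/RT}] / [1 + e^{−(ΔG°ᵤ − mD)/RT}]

with midpoint D₁/₂ = ΔG°ᵤ/m, RT ≈ 0.5925 kcal/mol at 25 °C.

**Sequential four-state model.** N ⇌ I₁ ⇌ I₂ ⇌ U with per-step
(ΔGᵢ°, mᵢ); state *j* is Boltzmann-weighted by the cumulative free
energy Σᵢ≤ⱼ (ΔGᵢ° − mᵢD), the signal is the population-weighted mean of
the state signals, and the total stability is ΔG₁°+ΔG₂°+ΔG₃°. Global
fits share thermodynamic parameters across curves (variable-projection
least squares with multi-start, ordering constraint
ΔG₁/m₁ < ΔG₂/m₂ < ΔG₃/m₃ built into the parameterisation).

**Aggregation kinetics.** Turbidity rises
y(t) = y₀ + Σᵢ yᵢ(1 − e^{−kᵢt}) with one or two phases, or linear
growth; model choice by AICc.

**Interface geometry.** Per-frame Cα–Cα distances of named residue
pairs across subunit interfaces, least-squares separation rates, and
distance-based cross-chain N/O contact listings.

## Worked example

Recover the published monomer-unfolding thermodynamics of the K315A
mutant (ΔG 1.3/2.6/8.9 kcal/mol, m 2.1/1.2/2.3 kcal/mol/M) from twelve
simulated replicate AEW curves with 0.2 nm noise:

```r
library(deltafold)
k <- thermo_constants()
truth <- four_state_params(1.3, 2.6, 8.9, 2.1, 1.2, 2.3,
                           yN = 348, yI1 = 352, yI2 = 354, yU = 357)
cfg <- generator_config("four_state", truth, seq(0, 6, 0.25),
                        noise_sigma = 0.2, n_replicates = 12, seed = 1,
                        denaturant = "GdmCl")
fit <- fit_four_state(gen_unfolding_curve(cfg, k), k,
                      fit_options(share_signals = TRUE))
fit
#> 4_state unfolding fit: 12 curve(s), 300 points, RSS 11.68
#>   N-I1   dG =   1.33 +/- 0.16 kcal/mol, m =  2.09 +/- 0.26, D1/2 = 0.63 M
#>   I1-I2  dG =   3.93 +/- 1.57 kcal/mol, m =  1.84 +/- 0.67, D1/2 = 2.13 M
#>   I2-U   dG =   8.40 +/- 0.64 kcal/mol, m =  2.18 +/- 0.15, D1/2 = 3.85 M
```

The three transition midpoints (0.63, 2.13, 3.85 M) recover the truth
(0.62, 2.17, 3.87 M) well inside their standard errors even though the
middle transition is broad and shallow; `fit$total_dG` gives the total
stability (13.7 ± 1.7 vs 12.8 kcal/mol true).

Aggregation kinetics of a refolding intermediate:

```r
trace <- gen_aggregation_trace(0.14, 1, sigma = 0.02, seed = 1)
select_kinetic_model(trace)
#> aggregation_fit: exp1, RMS 0.01778
#>   phase 1: k = 0.1392 /min, amplitude = 1.002
#>   offset y0 = 0.002909
```

AICc picks the single exponential and returns the generating rate
(0.139 vs 0.14 /min true).

Subunit separation on a toy dissociation trajectory:

```r
tet <- gen_toy_tetramer()
v <- 0.1 / sqrt(2)
traj <- gen_trajectory(tet, velocities = list(B = c(v, v, 0)),
                       n_frames = 101, jitter = 0.02, seed = 1)
track_distances(traj, "A:315-B:315")[[1]]$rate_A_per_ps
#> [1] 0.1000364
```

A config-driven pipeline (`run_unfolding_analysis()`,
`run_aggregation_analysis()`, `run_structure_analysis()`) orchestrates
reduce → fit → report runs with JSON output; a thin CLI wrapper with
`fixtures`/`unfold`/`aggregate`/`structure` subcommands ships in
`inst/cli/deltafold.R`.

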