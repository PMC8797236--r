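# ictalwave

Simulation of seizure-like **ictal discharges (IDs)** — their spontaneous
generation, ionic underpinnings, and slow wavefront propagation — in a
one-dimensional strip of hyperexcitable cortical tissue, for computational
neuroscientists studying seizure initiation and spread in slice-like
(4-aminopyridine-type) conditions.

## The model

Two interacting neuronal populations (pyramidal cells *E*, interneurons
*I*) occupy each node of a 2.5-mm strip. Each population follows the
**conductance-based refractory density (CBRD)** approach: the density
ρ(t, t\*) of neurons over time-since-last-spike t\* is transported with a
hazard-function sink,

  ∂ρ/∂t + ∂ρ/∂t\* = −ρ·H(U, g_tot),  ν(t) = ρ(t, 0) = ∫ρH dt\*,

where the membrane potential U(t, t\*) and gating variables obey
Hodgkin–Huxley-type equations parameterized by t\*, and the hazard
H = A + B combines a noise-driven escape rate A(T), with
T = (V_th − U)/(√2 σ_V) and σ_V = σ_V0·√(1 + g_syn/g_L), and the exact
threshold-crossing flux B ∝ [−dT/dt]₊·e^(−T²)/(1 + erf T). A dynamic
threshold (sigmoid in the 100-ms-filtered voltage around −40 mV)
implements depolarization block.

The populations are coupled through AMPA/NMDA/GABA-A conductances
(second-order kernels, magnesium block, Tsodyks–Markram depression) with
a Gaussian spatial footprint (λ = 50 µm), and embedded in full ionic mass
balances: intra/extracellular K⁺, Cl⁻, Na⁺ with Nernst reversals, the
4:1 Cl:HCO₃ GABA-A reversal, KCC2/NKCC1 cotransport, an electrogenic
Na⁺/K⁺-ATPase (discharge terminator), bath exchange and lateral diffusion
of K⁺, calcium-dependent adaptation, optional glial buffering, and
osmotically driven extracellular-space volume. Discharges arm through
slow chloride accumulation (depolarizing GABA), ignite from
interneuron noise, propagate as potassium-accompanied fronts, and
terminate when the sodium-activated pump hyperpolarizes the tissue.

The measurement layer reproduces the standard analyses: ion-sensitive
electrode calibration ([K⁺]ₒ = 2.5·e^{SV}), ID detection, front speed by
the slowest-fragment slope and by the half-maximum delay between two
virtual electrodes, and median/IQR summary statistics.

## Worked example

```r
library(ictalwave)

cfg <- ictal_config("control", duration_s = 60)
rec <- run_scenario(cfg, seed = 1)
print(rec)
#> Ictal-discharge simulation recording
#>   scenario: control, 60 s simulated, seed 1
#>   6000 trace samples at S1/S2, 600 field frames over 64 nodes
#>   max |density mass - 1| = 4.96e-14

speed_from_slope(rec$fields$K_o, rec$field_time_s, rec$x_mm)
#>  t_start_s t_end_s speed_mm_s
#>       12.4    21.8   2.419205
#>       43.5    51.9   2.247902

max(rec$fields$K_o)   # peak extracellular potassium, mM
#> 10.0
min(rec$fields$vol)   # minimal ECS volume ratio
#> 0.35
```

Two spontaneous discharges occur in the first minute; each row of the
front table is one discharge episode with its slowest-fragment wavefront
speed (mm/s). Peak extracellular potassium reaches 10 mM during the
events and the extracellular space transiently shrinks to about a third
of its resting volume. `plot(rec)` draws the space–time potassium field
and the electrode traces; `summary(rec)` tabulates detected events.

Scenario presets (`no_diffusion`, `long_connections`, `all_to_all`,
`fixed_volume`, `glial_buffer`, ...) rebind the spatial-coupling switches;
every biophysical constant is exposed through `ictal_params()` and YAML
configs (`load_config()`). A thin command-line wrapper with
`simulate` / `analyze` / `validate` / `sweep` subcommands is installed at
`inst/cli/ictalwave`.

The methods vignette (`vignettes/ictal-discharge-model.Rmd`) documents
the governing equations, the resolution of the genuinely open design
choices (pump and cotransporter forms, chloride driving force, baseline
anchoring, noise calibration), the numerical scheme, and the known
quantitative limitations of the calibrated regime.

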