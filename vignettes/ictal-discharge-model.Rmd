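---
title: "A refractory-density model of ictal discharge generation and propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A refractory-density model of ictal discharge generation and propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package simulates

`ictalwave` simulates seizure-like ictal discharges (IDs) in a
one-dimensional strip of cortical tissue, 2.5 mm long, under conditions
resembling a 4-aminopyridine-treated slice: a hyperexcitable network in
which inhibitory interneurons fire spontaneously, GABA-A signalling is
depolarizing once intracellular chloride accumulates, and the ionic
environment (extracellular potassium, intracellular chloride and sodium,
extracellular-space volume) evolves on time scales of seconds to minutes.

Two neuronal populations live at every spatial node: excitatory
regular-spiking pyramidal cells (E) and inhibitory fast-spiking
interneurons (I). Each population is described by the conductance-based
refractory density (CBRD) approach: instead of simulating individual
neurons, the model evolves the probability density `rho(t, t*)` of neurons
over the time `t*` elapsed since their last spike, together with the
membrane voltage `U(t, t*)` and gating variables parameterized by `t*`.
The population firing rate is the flux of density through the spiking
boundary:

    d rho/dt + d rho/dt* = -rho H(U, g_tot)
    nu(t) = rho(t, 0)    = integral of rho H dt*

The hazard `H = A + B` converts subthreshold state plus noise into an
instantaneous spike probability: `A` is the escape rate of a neuron whose
voltage fluctuates (amplitude `sigma_V`, correlation time `tau_Noise`)
below threshold, approximated by an exponential-polynomial in the scaled
threshold distance `T = (V_th - U) / (sqrt(2) sigma_V)` with a correction
in `k = tau_m / tau_Noise`; `B` is the exact probability flux of an
advected Gaussian voltage density through threshold,
`(2/sqrt(pi)) [-dT/dt]_+ exp(-T^2)/(1 + erf(T))`, active only while the
distance to threshold shrinks. The noise amplitude grows with synaptic
conductance, `sigma_V = sigma_V0 sqrt(1 + g_syn/g_L)`, which is what
allows strong synaptic events to recruit a population whose mean voltage
still sits below threshold. After a spike, neurons spend `dt_AP = 1.5 ms`
in a frozen window with voltage at `V_reset = -40 mV` and the
delayed-rectifier gate at 0.5; the slow Ca-dependent K gate re-enters with
its value at the peak of the spike-release distribution.

Depolarization block is a dynamic threshold: `V_th = V_th0 +
100 mV * sigmoid((U_inf - V_DB)/7 mV)` with `V_DB = -40 mV`, where
`U_inf` low-pass filters the voltage with a 100-ms time constant. Because
the filter lags, brief synaptic events can ignite a population while
sustained depolarization silences it; this shapes discharges into bursts.

# The membrane equation and the potassium coupling

The population voltage obeys

    C dU/dt = -g_L (U - V_L,eff) - I_DR - I_M - I_KCa - I_pump
              + I_noise + g_GABA (V_GABA - U) + g_AMPA (0 - U)
              + g_NMDA f_NMDA(U) (0 - U)

with `C = 1 uF/cm2`. The leak conductance of each population is set from
the printed resting membrane time constants, `g_L = C/tau_m0 - g_vg,rest`
(`tau_m0` 28 ms for E, 9 ms for I), so the leak plus the resting
voltage-gated conductance reproduces the nominal input resistance. The
potassium share of the leak (`g_KL/g_L`, scaled by the parameter
`k_leak_coupling`, default 1) carries a Nernst reversal: when
extracellular potassium rises, the leak reversal — and with it the
operating point of the membrane — depolarizes. This is the pathway by
which potassium elevation sustains a discharge once it has started. The
remainder of the leak reversal is fixed and back-computed so that the
resting potential is exactly `V_L = -70 mV` at the initial
concentrations.

Two terms deserve comment because they do not appear explicitly in the
classical population voltage equation but are required by the mechanism:

* the electrogenic pump current `-I_pump` (one net charge exported per
  cycle). It is the discharge terminator: as intracellular sodium
  accumulates during a discharge the pump activates and hyperpolarizes
  the membrane by up to ~20 mV, and its slow decay sets the silent
  interval that follows. Its resting value is absorbed into the leak
  reversal so the rest point is unchanged.
* the voltage-gated potassium currents `I_DR`, `I_M`, `I_KCa` at their
  printed (microsiemens-scale) amplitudes. At this scale they contribute
  ionic bookkeeping but negligible voltage feedback; spikes are handled
  entirely by the hazard-and-reset mechanism. The representative
  "observer" neurons (one E and one I at each electrode site) are the
  exception: they carry millisiemens-scale transient sodium and
  delayed-rectifier currents (`g_Na_rep = 7`, `g_DR_rep = 4 mS/cm2`) so
  that they produce genuine action potentials for display, without
  feeding back into the population dynamics.

# Synapses and short-term depression

AMPA, NMDA and GABA-A conductances follow second-order kernels
`(tau_r tau_d m'' + (tau_r + tau_d) m' + m) = tau_s (1 - m) phi` driven by
the presynaptic rate field `phi`, with the normalizing time scale
`tau_s` chosen so the peak response to a brief pulse is independent of the
`(tau_r, tau_d)` pair. NMDA carries the magnesium block
`f_NMDA(V) = 1/(1 + Mg/3.57 exp(-0.062 V))` at `Mg = 0.25 mM` (the
reduced-magnesium condition of the in-vitro preparation). Glutamatergic
and GABAergic resources deplete by Tsodyks-Markram depression
(`u_glu = 0.2`, `u_GABA = 0.1`, recovery 500 ms); without depression the
network locks into a non-terminating high-activity state.

The maximal AMPA conductance onto E-cells is graded linearly in space,
zero at `x = 0` and maximal (0.3 mS/cm2) at `x = L`; all other maxima are
uniform. Spatial coupling applies a row-normalized Gaussian kernel of
length `lambda = 50 um` to the somatic rate fields (all four projections
share `lambda`), optionally mixed with a fraction of the domain-mean rate
(the all-to-all variant).

# Ionic dynamics

For each population the intracellular potassium, chloride and sodium
balances collect the leak currents (with Nernst reversals), the
voltage-gated potassium currents, the potassium and sodium fractions (0.2
and 0.4) of the glutamatergic conductance, the GABA-A chloride flux, the
per-spike sodium load `q_Na nu`, the Na/K pump (3 Na out : 2 K in), and
the KCC2 and NKCC1 cotransporters (NKCC1 on interneurons only).
Extracellular concentrations evolve as volume-weighted products
`v [X]_o`, mirrored from the intracellular rates with the 10:1
intra:extracellular volume ratio and the 1:3 interneuron fraction, plus
— for potassium only — bath exchange (0.25 1/s toward 3.5 mM), lateral
diffusion (`D1d = 0.39 um2/ms`, zero-flux boundaries) and the optional
glial buffer. Reversal potentials come from Nernst relations (26.6 mV
scale); the GABA-A reversal is the 4:1 chloride:bicarbonate permeability
mixture, which keeps it above the chloride reversal and is what makes
GABA depolarizing once chloride accumulates.

Three design choices in this block were genuinely open and are worth
recording:

* **GABA-A chloride flux.** The chloride balance uses the chloride-only
  driving force, `I_GABA,Cl = g_GABA (U - V_Cl)`: chloride enters whenever
  the membrane sits above the chloride reversal, even while the total
  GABA current (reversal `V_GABA`, partly carried by bicarbonate) is
  inward. With the total-current form instead, chloride loading stalls as
  soon as `V_GABA` reaches the resting potential and the interictal
  chloride accumulation that arms the network never completes.
* **KCC2 form.** The default flux is the saturating odd function
  `I_KCC2 = I_max (V_K - V_Cl)/(|V_K - V_Cl| + 40 mV)`: extrusion of K and
  Cl at rest, reversal to import under pathological potassium elevation,
  no pole. A literal rational variant with the signed denominator
  `(V_K - V_Cl - 40)` is available (`kcc2_form = "literal"`); it acts as a
  chloride-import ratchet with no resting equilibrium and is retained for
  comparison only.
* **Pump model.** The default is the double-sigmoid pump,
  `I_max / ((1 + exp(3.5 - K_o)) (1 + exp((25 - Na_i)/3)))`, clamped
  nonnegative: it stalls when extracellular potassium is depleted and
  activates steeply with sodium load, which gives clean discharge
  termination and post-discharge recovery. The full four-state
  kinetic-cycle ATPase (King-Altman net flux) is available
  (`pump_model = "kinetic"`).

**Baseline anchoring.** The nominal initial state (K_o 3.5, K_i 129,
Cl_i 5/9, Na_i 17 mM) is not an exact flux equilibrium of the printed
parameter set; the residual imbalances (a few tenths of uA/cm2) would
otherwise shift the interictal baseline over minutes and push both
populations into a silent depolarized state. With
`anchor_baseline = TRUE` (default) constant correction fluxes, computed
once at initialization, make the initial state an exact potassium and
sodium equilibrium. Chloride is deliberately not anchored: its
activity-driven loading (GABA events, NKCC1) is the slow process that
arms each discharge, and its passive leak plus KCC2 provide the recovery
between discharges.

**ECS volume.** Volume follows the osmotic relaxation
`dv/dt = (1 + 1.029 (exp(dpi/20) - 1) - v)/250 ms` where `dpi` is the
change of extracellular-minus-intracellular osmolarity relative to the
initial state (zero at rest; negative when cells gain osmolytes, so the
ECS shrinks during discharges and recovers afterwards — the
self-stabilizing sign). `dpi` is clamped to ±60 mM and `v` to [0.2, 3]:
the exponential response is an empirical fit valid for moderate
imbalances, and outside that range it would otherwise produce unphysical
volumes.

**Availability guards.** In the density framework, firing does not feel
the sodium gradient (there is no explicit spike sodium current), so
nothing intrinsic stops a strong discharge from drawing more sodium or
chloride than the extracellular space contains. The per-spike sodium load
and the GABA-A chloride influx therefore scale down linearly once the
extracellular pool of the carrier ion falls below 40 mM. In ordinary
operation the pools stay far above this level and the guards are inert.

# Noise and ignition

Background drive is an Ornstein-Uhlenbeck current to the interneurons
only (correlation time 4 ms), independent per spatial node, mimicking the
enhanced spontaneous transmitter release of the preparation. The
amplitude is specified as 25 pA through the 3e-5 cm2 membrane; we
interpret it as the quasi-static voltage-equivalent drive (the OU
low-pass attenuation by the membrane is compensated) and scale it by the
calibration factor `noise_gain`. `noise_gain = 1` is the default and was
fixed, once, by matching the interictal inhibitory event rate to the
experimentally reported scale of about one per second. This noise is the
ignition
seed: interneuron bursts load chloride into both populations through the
depolarizing GABA pathway; the GABA reversal creeps upward over tens of
seconds; eventually a GABAergic volley depolarizes the pyramidal
population through its own raised reversal, glutamate takes over, and a
discharge front propagates along the strip. Sodium load then activates
the pump, the discharge terminates, potassium undershoots, chloride is
re-exported, and the cycle repeats.

# Numerical scheme

* Time step `dt = 0.5 ms`, equal to the `t*` bin width
  (characteristics-aligned upwind transport: exact advection, no
  numerical diffusion). The `t*` grid extends to 60 ms; the last bin
  absorbs all older neurons and is treated as a quasi-stationary pool
  whose voltage and gating continue to evolve. Because state advects
  together with density, bins carrying negligible mass (< 1e-8/ms) are
  skipped, and firing below 1e-7/ms is routed directly to the pool; both
  cutoffs are far below any dynamically relevant rate.
* Gating and voltage use exponential-Euler updates; gating rate functions
  and their per-step decay factors, the NMDA block, the block sigmoid, and
  the hazard terms are tabulated once per run (voltage resolution
  0.05 mV, bilinear in `(T, log k)` for the noise term) — agreement with
  the direct formulas is at the 1e-4 level.
* The second-order synaptic kernels integrate with a midpoint rule,
  substepped when `dt` exceeds half the rise time (relevant for GABA,
  `tau_r = 0.5 ms`). Depression and calcium use exact one-step relaxation
  solutions; ionic balances use forward Euler at the global step (their
  time scales are seconds).
* Removable singularities of the rate functions are evaluated by 3-term
  Taylor expansions within 1e-3 mV of the singular voltage.
* Diffusion uses the conservative second-difference Laplacian with
  zero-flux ends; the configuration validator rejects grids violating
  `D dt/dx^2 <= 0.5`.
* Per-node RNG streams derive from the master seed by counter-based
  splitting (splitmix64 into xorshift128+, Box-Muller normals), so runs
  are bit-reproducible and changing the node count does not reorder the
  noise of existing nodes.
* Default grid: 64 nodes over 2.5 mm (dx = 39.7 um, below the 50-um
  connection length). Electrodes S1/S2 sit at one quarter of the length
  from either end (1.25 mm apart); positions are configurable.

# Validation against an ensemble of individual neurons

`monte_carlo_population()` simulates thousands of individual neurons with
the same membrane equations, threshold, reset and frozen-window
convention as the density model, each with independent colored voltage
noise, under frozen ionic concentrations. `cbrd_population_rate()` is the
density-model counterpart. For a strong step input the two agree in rate
to a relative L2 error below 1% (the package's acceptance suite asserts
15%). The comparison is run with the dynamic-threshold block disabled on
both sides: the block's slow filtered-voltage state is carried per neuron
in the ensemble but per `t*`-bin in the density model, and under
sustained reset-above-threshold drive the two bookkeepings legitimately
diverge — disabling it isolates the density approximation itself, which
is what the oracle is for.

# What the simulated conditions do and do not reproduce

The generator's default conditions reproduce, qualitatively: spontaneous
repeating discharges led by GABAergic events, with extracellular
potassium surging and undershooting, intracellular sodium peaking after
potassium, extracellular space shrinking during events, propagating
fronts whose speed scales with the connection length, insensitivity to
blocking potassium diffusion, and synchronous weak pre-ictal potassium
rises under all-to-all mixing.

Quantitative caveats a user should know before comparing numbers to
slice recordings:

* Discharge episodes in the calibrated model last seconds (the
  acceptance suite measures their median duration at 3-4 s) and recur
  every few tens of seconds — shorter and more frequent than the
  tens-of-seconds events recurring on a minutes scale seen in
  recordings. The local potassium dwell above detection threshold is
  correspondingly brief (under a second per front passage).
* Slowest-fragment front speeds come out around 1-2 mm/s in control
  (recruitment at the front is limited by synaptic and membrane time
  constants, roughly 25 ms per 40-um node); recorded ictal fronts near
  0.3 mm/s imply an additional ~150 ms of local buildup per node that
  this implementation does not capture. Under long (250 um) connections
  recruitment becomes near-simultaneous and the measured apparent speeds
  exceed the 10 mm/s discrimination cutoff.
* The minimum extracellular-space volume reaches about a third of
  baseline (a reduction around 65%) rather than the ~50% reported; the
  osmotic load of a discharge is overestimated for the same reason the
  events are intense.
* The model is 1-D; no axonal conduction delays (folded into synaptic
  time constants); no pH or dynamic bicarbonate; no explicit astrocyte
  compartment beyond the optional buffer ODE; representative neurons are
  observers only.

Passing tests on this synthetic system demonstrate internal consistency
of the method and the analysis layer — mass conservation, ionic
bookkeeping, estimator correctness on known ground truth — not fidelity
to any particular slice experiment.

# Scenario presets

| preset | change relative to control |
|---|---|
| `control` | Gaussian connections `lambda = 50 um`, diffusion on, dynamic volume, no glia |
| `no_diffusion` | `D1d = 0` |
| `local_only` | `lambda = 0` (presynaptic rate = local somatic rate) |
| `high_diffusion` | `lambda = 0`, `D1d = 390 um2/ms` |
| `long_connections` | `lambda = 250 um` |
| `all_to_all` | 0.2 of the presynaptic rate from the domain mean |
| `fixed_volume` | `v` held at 1 |
| `glial_buffer` | glial potassium buffer on (`k1 = 0.02 1/s`, `B_max = 500 mM`) |

# Measurement procedures

`detect_ids()` marks an event when extracellular potassium exceeds
baseline + 3 mM for at least `min_on_s` and closes it after
`min_off_s` below baseline + 1 mM; thresholds separate discharges from
brief transients and are exposed because the source recordings specify
none. For this model's short-dwelling events the run scripts use
`min_on_s = 0.3`, `min_off_s = 1` with a 20th-percentile baseline.
`speed_from_slope()` reconstructs the front from per-node threshold
crossing times (default 6 mM) and reports the minimum absolute slope of
sliding-window linear fits, excluding apparent speeds above 10 mm/s
(near-simultaneous events). `speed_from_delay()` divides the electrode
separation by the lag between half-maximum crossings of the normalized
potassium rises; zero or missing lags are flagged, never converted to
numbers. `id_statistics()` excludes the first event of each run (the
start-up transient is atypical) and reports medians with interquartile
ranges. The reduced protocols used by the bundled scripts (240 s control,
150 s variants, one seed per condition) are the package's desk-scale
choice; all durations are arguments.

# Reproducing the headline numbers

`scripts/acceptance.R` reruns the four scenario experiments from scratch
(control, long connections, diffusion blockade, all-to-all) with the
installed package and writes the measured front speeds, peak potassium,
volume reduction and delay-based speed as JSON:

    Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
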