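---
title: "Phasic/tonic dopamine imbalance in basal-ganglia reinforcement learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic/tonic dopamine imbalance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonicphasic)
```

This vignette documents the scientific and numerical choices behind
`tonicphasic`: what each sub-model assumes, which parameters matter and
why they hold their default values, what the virtual-cohort generator does
and does not emulate, and where the design was genuinely open.

## 1. The dopamine terminal

The terminal model tracks two state variables, the extracellular dopamine
concentration `C_DA` (µM/L) and the presynaptic autoreceptor occupancy
`AR` (fraction):

\[
\frac{dC}{dt} = I_{tonic} + I_{phasic}(t)
  - \frac{V_{max}\,C}{k_m + C} - k_{rem}\,C,
\qquad
\frac{dAR}{dt} = k_{on}\,C\,(1-AR) - k_{off}\,AR .
\]

Assumptions worth making explicit:

* **Tonic release is autoreceptor-independent**; only burst (phasic)
  release is autoregulated. Both the burst firing rate and the burst
  vesicle release probability are taken inversely proportional to `AR`,
  normalised at the control operating point, giving the
  \((0.334/AR)^2\) factor in `phasic_release_rate()`. The exact functional
  form of autoreceptor feedback is not known; inverse proportionality is
  the simplest monotone choice.
* **Autoreceptor desensitisation is excluded** — the model addresses
  short-term (within-session) dynamics only.
* **Punishments are firing pauses applied as a hard clamp**: `C_DA = 0`
  throughout the 50 ms event window. Integrating the pause explicitly
  (release switched off) empties the cleft in roughly half a second
  (`punishment_decay_time()`, with the small-concentration limit decaying
  exponentially at rate \(V_{max}/k_m + k_{rem}\)); since that is an order
  of magnitude slower than the event window, the clamp is the cleaner
  idealisation, and the explicit pause integration is retained only as a
  verification path. During the clamp `AR` keeps evolving by pure
  unbinding.

Parameter defaults (`da_params()`) are literature-anchored kinetic
constants; the terminal density is the calibration degree of freedom and
is set so the **control** tonic steady state is 0.02 µM/L, at which point
the autoreceptor occupancy is 1/3 (the closed form
\(k_{on}C/(k_{on}C+k_{off})\) gives \(0.2/0.6\)). The **imbalance**
condition raises only \(V_{max}\) from 1.2 to 1.8 µM/L·s. Raising
reuptake lowers tonic dopamine, lowers `AR`, and thereby amplifies bursts:
the burst-to-tonic ratio \((C_{peak}-C_{tonic})/C_{tonic}\) computed by
`da_ratio()` moves from ≈3 to ≈8.3. `C_peak` is defined operationally as
the maximum of a single unit-RPE burst transient started from the tonic
steady state, with `AR` tracked continuously through the burst (sampling
`AR` only at burst onset changes the ratio by a few percent; continuous
tracking is the default because nothing in the terminal model stops
between-burst adaptation).

Units are fixed once at parameter load: concentrations µM/L, time s;
release rates assembled from terminals/L and molecules/vesicle are
converted to µM/L·s through Avogadro's constant and the extracellular
volume fraction. The control steady state of 0.02 µM/L doubles as the
verification of that conversion.

## 2. The action-selection network

Each of eight regions (cortex, striatal Go and NoGo populations, GPe,
GPi, thalamus, a diffuse STN unit, and a constant cholinergic drive) is a
first-order leaky integrator with sigmoidal output normalised to [0, 1],
divided into four action channels. Wiring follows the classical scheme:
Go inhibits GPi channel-wise (direct); NoGo inhibits GPe, which inhibits
GPi and STN (indirect); cortex excites STN which excites GPi diffusely
(hyperdirect); GPi inhibits thalamus; thalamus and cortex excite each
other; cortical self-excitation plus lateral inhibition yields
winner-takes-all selection. D1 occupancy multiplies the Go pathway gain
up, D2 occupancy multiplies the NoGo gain down, and both striatal
pathways share a constant multiplicative cholinergic potentiation `chi`
(no interneuron dynamics are modelled).

The detailed equations of the reference architecture this network follows
are not publicly specified, so all region parameters are explicit
tunables in `network_params()` and the model is calibrated against
*behavioural* anchors rather than per-unit traces: a naive network must
respond to the canonical stimulus within the 800 ms training trial with
an essentially noise-driven (uniform) choice; a trained control subject
must respond in ≈150 ms with winner-takes-all exclusivity and near-100 %
accuracy; the trained imbalance group must show partial, heterogeneous
impairment. Two structural choices beyond the textbook wiring deserve
justification:

* **NoGo→Go collateral inhibition** (`w_nogo_go`). The Hebb rule (below)
  applies its positive-part gate only presynaptically, so the sign of a
  weight change is set by postsynaptic activity relative to threshold.
  During a punishment window the dopamine clamp removes the D2 brake and
  NoGo activates — but the chosen channel's Go unit still receives full
  cortical drive, and without a pathway from NoGo activation to Go
  suppression, punishment would *potentiate* the wrong action's Go
  synapses (a runaway observed directly during development: histories
  collapse to near-100 % punishments). Striatal D2→D1 medium-spiny-neuron
  collaterals are well documented physiologically, and one inhibitory
  coupling term makes punishment depress Go and potentiate NoGo, which is
  the opponency the learning account requires.
* **Structural gains on the two striatal input paths**
  (`w_stim_striatum`, `w_cortex_striatum`). The race must weigh
  stimulus-specific evidence (`w^GS·S`) more heavily than the learned
  response prior (`w^GC·y_C`); with equal weighting, the response prior
  forms a two-channel attractor that absorbs all choices regardless of
  the stimulus.

Cortical noise is uniform on [0, 0.2], redrawn independently per channel
per integration step; per-step redraw (rather than per-trial) is what
gives within-trial fluctuation, and hence reaction-time variability, in
otherwise identical trials. The steep cortical sigmoid (slope 12) makes
the threshold crossing sharp, keeping trained control reaction times
tight; the shallow pallidal/thalamic sigmoids (slope 4) keep selection
graded, so that the modest tonic D1/D2 differences between groups shift
response probabilities smoothly instead of silencing one group outright.
The common 33 ms time constant sets the absolute reaction-time scale
(trained control ≈ 150 ms).

Numerical details: explicit Euler at `dt = 1` ms (the fastest time
constant is 33 ms; the dopamine module uses classical RK4 at the same
step and is verified against closed forms). Each trial starts from the
network's settled resting state (300 ms, no stimulus, no noise) so that
initialisation transients cannot contaminate reaction times. A response
is the first channel crossing 0.9; if two channels cross within one step
the larger activity wins and exact ties go to the lowest index (with
per-channel noise, exact ties have measure zero; the rule exists so the
integrator is fully deterministic given its random stream). Trial
integration stops at the end of the learning window — later dynamics have
no observable consequence because weights update once per epoch and
states reset between trials.

## 3. Plasticity

The four plastic matrices start naive (all active entries 0.5; `w^GC`,
`w^NC` diagonal and trained only on their diagonals). Once per epoch,
activities are time-averaged over the dopamine event window
([response + 0.1 s, + 0.15 s]) and every entry is updated by

\[
\Delta w_{ij} = \phi\,[y^{pre}_j - \vartheta_{pre}]^+\,(y^{post}_i - \vartheta_{post}),
\qquad \phi = 0.0013\,|RPE|\,\cdot\,\text{DA ratio} .
\]

Presynaptic activities are the stimulus vector (for `w^GS`, `w^NS`) and
the cortical outputs (for the diagonals); postsynaptic activities are Go
and NoGo. Both thresholds default to 0.5, the midpoint of the normalised
activity range — with the canonical stimulus values (1 / 0.2 / 0.1) this
places the gate so that only the strong stimulus channel drives
stimulus-indexed learning. Weights are clipped to [0, 1]; unbounded
growth is meaningless for inputs to saturating units. No explicit
anti-Hebbian term exists: punishment learning emerges from the activity
pattern during the clamp (Go low → depression, NoGo high → potentiation).
The DA ratio is computed once per subject and held constant, making the
imbalance group's updates ≈2.8× larger — the only mechanistic difference
between groups downstream of the terminal model.

## 4. Protocols: what the virtual cohort emulates

`build_cohort()` creates seed-paired subjects: control #k and imbalance
#k share one noise seed (identical stimulus orders and noise streams)
and differ only in \(V_{max}\), so outcome differences within a pair are
attributable to the dopamine imbalance interacting with a shared
"environment". Training runs 250 blocks of the four canonical stimuli in
random order (1,000 epochs, 800 ms trials); the reinforcement history is
coded +1 / +0.1 / −1 / 0 and each epoch is attributed to the target
channel of the stimulus presented. The learning criterion is the strict
one — 5 *large*-reward outcomes within 10 successive trials — because
small rewards mark choices of the wrong (second-strongest) channel.

The test phase freezes the weights and presents 100 trials of 1,800 ms
with a clean unit stimulus on a random target channel; the background
cortical noise is always on. A per-trial amplitude jitter on the target
stimulus was considered and rejected: it sweeps the trained drive across
the mid-slope of the striatal sigmoid and inflates control reaction-time
variability far beyond the tight distribution the trained network
otherwise produces. The noise sweep then *adds* Gaussian noise with mean
1 and standard deviation 0–1 to the unit stimulus. The mean-1 noise is
deliberate: it is what makes the sweep consistent with the gain curve.
Since the trained control only ignites above roughly half its nominal
drive, zero-mean noise would degrade success long before sd 0.6; with the
added mean, weak total drives only become likely at large sd, and control
success stays at ceiling until sd ≈ 0.6 while the imbalance group — whose
unevenly learned weights leave some channels marginal — degrades earlier
and more variably. The gain curve (`io_gain_curve()`) probes channel 1
with amplitudes 0.1–1 under test-phase timing and reports the maximum
cortical output per trial.

What the generator does **not** emulate: inter-individual variability in
the physiological parameters (all subjects within a group are
parameter-identical; only noise seeds differ), inhibitory (go/no-go)
task demands, medication effects, long-term DAT regulation, and any
noradrenergic contribution. Passing tests therefore show that the
phasic/tonic mechanism *suffices* to produce the response phenotype under
idealised conditions — not that real ADHD cohorts, with their parameter
heterogeneity, would separate as cleanly.

## 5. Analysis battery

`fit_exgaussian()` fits the exponentially-modified Gaussian by maximum
likelihood (own density implementation, log-scale for tail stability;
moment-based initialisation; L-BFGS-B with box constraints, because on
strongly bimodal reaction-time sets the unconstrained likelihood can run
σ to absurd values with τ → 0). Censored (no-response) trials are
excluded from reaction-time statistics and fits.

The history-variability statistic works on the 4 × epochs cumulative
history matrix: `std_history` is the epoch-averaged across-channel
Euclidean spread, and it is weighted by a negativity ratio. The printed
formula for that ratio counts negative vs positive cells (with the 1/1000
scaling on the numerator only, exactly as displayed — the scaling is
cosmetic and cancels in group comparisons); the accompanying prose
describes a sum of magnitudes instead. Both readings preserve the
property that matters (the ratio grows when failures dominate), so both
are implemented — `method = "count"` (default, the displayed formula) and
`method = "sum"`. Group regressions of per-subject reaction-time SD on
the weighted statistic use ordinary least squares, linear for the control
group and quadratic for the imbalance group; subgroup labels (a/b/c) are
assigned by explicit thresholds (perfect accuracy; τ-dominated
distribution; the remainder), since the severity boundaries are visual
conventions, not fitted quantities.

## 6. Problem sizes and reproducibility

The study conditions are 10 subjects per group, 1,000 training epochs and
100 test stimuli; the full experiment, including the ex-Gaussian fits and
history statistics, runs in tens of seconds thanks to the compiled trial
integrator, and the acceptance script (`scripts/acceptance.R`) recomputes
everything from a single seed. The test suite runs the full-condition
cohort once and shares it across the study-level checks; the
stimulus-noise sweep inside the suite uses three subjects per group and
50 stimuli per noise level, with the full grid available through the
exported functions. Unit tests use much smaller cohorts (tens to hundreds
of epochs). All randomness flows from one base seed through per-subject
streams drawn once at cohort construction, so cohorts are reproducible
and extensible without reshuffling existing subjects.

## 7. Known limitations

* The network equations are a reconstruction calibrated to behavioural
  anchors; per-unit trajectories are not expected to match any particular
  reference implementation, and region parameters should be treated as a
  self-consistent set rather than individually meaningful.
* Group-level stochastic outcomes (mean trials to criterion, the number
  of subjects that never reach criterion, the pooled ex-Gaussian τ) have
  large seed-to-seed variance at n = 10 subjects — comparable to the
  between-subject SDs themselves — so single-cohort values scatter
  noticeably around their expectations.
* In the calibrated model, severely impaired imbalance subjects usually
  still encounter an above-criterion window at some point in 1,000
  trials; complete training failure (a censored criterion) is rarer here
  than the heterogeneity of test-phase accuracy would suggest.
* The hard punishment clamp discards the dependence of pause depth on
  prior firing; this is deliberate (the model is qualitative about
  punishment magnitude) but means punishment strength cannot be graded.
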