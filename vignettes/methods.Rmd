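---
title: "Simulation and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretfinger)
```

# The measurement

During bacterial transcription initiation, a loop of the sigma factor (the
"sigma-finger") occupies the RNA polymerase active-site cleft and must be
displaced as the nascent RNA grows. `fretfinger` models the single-molecule
FRET (smFRET) assay used to watch this happen: surface-immobilized,
doubly-labelled transcription complexes imaged by TIRF microscopy with
alternating-laser excitation (ALEX). Each ALEX period yields three
intensities — donor emission under donor excitation (`I_DD`), acceptor
emission under donor excitation (`I_DA`), and acceptor emission under
acceptor excitation (`I_AA`) — from which the apparent FRET efficiency
`E* = I_DA / (I_DD + I_DA)` and the stoichiometry
`S = (I_DD + I_DA) / (I_DD + I_DA + I_AA)` follow.

Two experimental modes are represented:

* **equilibrium**: 0.1 s ALEX periods, ~50 s traces; the observable is the
  framewise E* histogram (populations) plus per-molecule dynamics;
* **real-time**: 0.4 s periods, ~500 s traces, nucleotides injected at
  `t_inj`; the observable is the per-molecule displacement delay `t_d` and
  the four-class trajectory taxonomy (fast displacers, slow displacers,
  dynamic non-displacers, static molecules).

# The generative model

## States and archetypes

A `ground_truth` object (see `build_fixture()`) holds an inventory of E*
states and an *archetype* mixture over molecules:

* **static** — one state for the whole trace. Each molecule draws a small
  offset of its state mean (`between_sd`, default 0.03 E* units): real
  ensembles have molecule-to-molecule variation in detection factor and
  dye environment, and this heterogeneity is what makes population peaks
  in framewise histograms Gaussian rather than artificially sharp.
* **dynamic** — continuous-time switching between substates with
  exponential dwells and an embedded branching matrix (below).
* **displacer** — a pre-displacement state until `t_inj + Exp(tau)`, then
  a permanent switch to the displaced state. Pre-displacement means have a
  larger between-molecule spread (0.08), as fitted pre-injection E* values
  differ between fast and slow displacers by less than that.

## Matching printed occupancies *and* dwell times

For a semi-Markov switcher the stationary time-occupancy is
`occ_i ∝ p_i · dwell_i` with `p` the stationary law of the embedded jump
chain. Given target occupancies and per-state mean dwells,
`dynamic_branching()` constructs a reversible zero-diagonal branching
matrix from symmetric edge flows `f_ij = (v_i + v_j − v_k)/2`, where
`v_i ∝ occ_i / dwell_i` is the jump-flux of state `i`. For three states
this solves the flow-balance equations exactly; feasibility requires
`max(v) ≤ 1/2` (no state can receive more jump flux than the others emit),
which constrains which dwell values are admissible inside a reported dwell
range. Infeasible combinations error rather than silently renormalizing.

## Photophysics and emission

Per green half-frame the expected intensities are `I_DA = rate · E` and
`I_DD = rate · (1 − E)`; per red half-frame `I_AA = rate`. `E` is the
current state mean plus per-period Gaussian emission noise. Donor and
acceptor photobleach at exponential times; donor bleach sends `I_DD` and
`I_DA` to background, acceptor bleach collapses the FRET pathway (donor
de-quenches to the full rate, `I_DA` and `I_AA` go to background). Counts
get Poisson shot noise on signal-plus-background and Gaussian read noise;
traces are background-corrected, so values can dip below zero.

Known limits: no diffusion, stage drift, or spectral cross-talk in the
movie renderer; channels are pre-registered; blinking is not simulated
(but is detected and filtered by QC); bleaching is single-step
exponential.

## Real-time censoring and the underlying displacer fraction

A displacement event is only *recorded* if both dyes survive past
`t_d + t_stab` (the classifier needs `min_stable = 10` periods of stable
displaced signal). With exponential bleaching at joint rate
`1/τ_eff = 1/τ_D + 1/τ_A`, the probability of recording an event is

```
P(record) = Σ_i w_i · exp(−(t_inj + t_stab)/τ_eff) / (1 + τ_i/τ_eff)
```

(`displacer_detection_prob()`). Published class fractions are treated as
*observed* (post-censoring) fractions; the generator inverts the formula
above to set the underlying displacer fraction, so that the simulated
observed Class I+II fraction matches the published one while ~20% of
displacement events are lost to bleaching — matching the reported miss
rate. Bleach means (donor 400 s, acceptor 667 s at 0.4 s framing) follow
from that closed form.

# Photometry and corrections

`detect_spots()` band-pass filters (difference of Gaussians) the
per-excitation average images, finds local maxima above a robust
threshold, refines subpixel centroids, pairs donor/acceptor detections,
and rejects overlapping spots. `extract_traces()` does aperture photometry
with a local-annulus median background (Twotone-style). Downstream,
`accurate_fret()` applies the standard leakage (`Lk`), direct-excitation
(`Dir`) and detection-factor (`γ`) corrections; `Lk` and `Dir` come from
donor-only/acceptor-only molecules (`leakage_factor()`,
`direct_excitation_factor()`), `γ` from intensity changes across acceptor
photobleach events (`gamma_factor()`). `fret_to_distance()` converts
corrected efficiencies with a 60 Å Förster radius.

# Trace quality control

`qc_trace()` codifies the selection rules: pre-bleach mean `I_DD` in
[100, 1500] and `I_AA` in [100, 1000] counts; at most one photobleach step
per fluorophore (binary-segmentation change-point detection with a
persistence requirement, `bleach_steps()`). Donor bleaching is detected on
the total green-excitation intensity `I_DD + I_DA`, which is invariant to
FRET state changes and to acceptor bleaching (the donor de-quenches), so
dynamic molecules are not mistaken for multi-step bleachers — detection on
`I_DD` alone would reject switching molecules preferentially and bias
every class fraction. Acceptor bleaching is detected on `I_AA`. Remaining
rules: no acceptor blinking no acceptor blinking
(down-then-up signature, `blink_filter()`); doubly-labelled species by
mean stoichiometry (`species_sort()`). Accepted molecules contribute their
pre-bleach E* series (`estar_series()`), kept time-aligned to trace
periods so state paths map directly onto times.

# State inference: variational-Bayes HMM

`fit_hmm()` fits one K-state HMM with Gaussian emissions *shared across
all molecules* (ebFRET-style). Priors are conjugate: Dirichlet(1) on the
initial law and transition rows, Normal-Gamma on emission mean/precision
with `beta0 = 0.25` (weak mean coupling), `a0 = 2.5`, `b0 = 0.015` (prior
emission sd `sqrt(b0/a0) ≈ 0.077`, a typical smFRET peak width), and
prior means at the k-means initialization centers. The VBEM E-step runs a
scaled forward-backward (compiled) with the usual digamma "tilde"
parameters; the M-step updates the hyperparameters in closed form; the
evidence lower bound is monotone and is the model-selection score
(`select_model()`, ties to the smaller K). States with < 1% weight or
means closer than 0.02 are flagged degenerate and step the selection down.
Initialization is deterministic given the seed, so fits are reproducible.
A maximum-likelihood EM with BIC scoring (`method = "em"`) provides an
independent cross-check. Molecules with ≥ 3 Viterbi transitions are
classified dynamic (`classify_dynamic()`), matching how switching
molecules are counted; `transition_density()` builds the standard
transition-density plot.

# Population fitting

`fit_mixture()` decomposes the pooled framewise E* histogram into K
Gaussians by Levenberg-Marquardt least squares on bin counts — the way
published population fractions are extracted — reporting *area* fractions
`A_i σ_i / Σ A_j σ_j`. For two components the initializer places the
minor component at the mass centre of the low-E* flank and the major at
the global mode: the decomposition in this workflow separates the
displaced band from the in-cleft band, and initializing at the physically
expected peaks selects that optimum rather than a nested broad+narrow
solution when dynamic molecules blur the valley. A maximum-likelihood EM
path (`method = "em"`, via mclust) cross-checks the least-squares fit;
the two agree on well-separated mixtures. `subset_error()` quantifies
uncertainty by splitting molecules into random subsets, as done when an
experiment was performed once.

# Kinetics

`extract_dwells()` turns Viterbi paths into dwells, flagging the censored
first/last runs; the single-exponential estimator is the mean of the
uncensored dwells (the MLE), cross-checked against a histogram fit, with a
peaked two-exponential alternative that falls back (with a warning) when
its time constants collapse.

`categorize_realtime()` implements the terminal-displacement rule: the
maximal terminal run in displaced-band states (fitted mean < 0.2), at
least 10 periods long and entered after injection, defines a displacement
at `t_d = entry − t_inj`; remaining molecules are Class III (≥ 3
transitions) or Class IV. `analyze_realtime()` runs the chain two-pass:
pass 1 fits all molecules and classifies; pass 2 refits the displacer
subset so the displaced-band means (and hence the delays) are not biased
by non-displacers. Accepted molecules whose usable (pre-bleach) region is
too short to fit remain in the denominator as Class IV — censoring is a
property of the data, not a reason to shrink the denominator.

`fit_displacement()` fits the delay distribution as a two-exponential
mixture by EM (event-fraction weights are the mixture weights), with a
histogram least-squares cross-check. The histogram bin width defaults to
the Freedman-Diaconis rule clamped to `[frame period, 5 s]`: a fixed wide
bin cannot resolve time constants of a few seconds, and for exponentials
binning biases amplitudes, not time constants, so the clamp protects the
amplitude estimates used by `fastslow_boundary()`, which computes the
equal-contribution boundary `t_b = log(A1/A2) / (1/τ1 − 1/τ2)` in closed
form (cross-checked numerically).

# Reproducibility and scale

Every stochastic step takes an explicit seed and derives per-molecule
child seeds, so ensembles are reproducible element-wise. `run_pipeline()`
writes per-stage tabular/JSON outputs plus a manifest with the config and
its MD5 hash but no timestamps: re-running a config reproduces the data
outputs byte-for-byte. Default problem sizes (hundreds of molecules,
hundreds of periods) are chosen so each analysis runs in minutes on a
single core while leaving enough statistics to recover the encoded
parameters within their published precision.

```{r example, eval = FALSE}
gt <- build_fixture("GT-RPitc2-lacCONS")
sim <- simulate_ensemble(gt, 300, seed = 1)
qc <- qc_ensemble(sim$traces)
series <- estar_series(sim$traces, qc)
fit_mixture(unlist(series), K = 2)
```
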