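---
title: "Models and methods: gap-startle tinnitus classification and fusiform-cell biophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fusiform)
```

# The problem

After traumatic noise exposure some mice develop tinnitus and some do not.
Behaviorally, tinnitus is inferred from the gap-detection startle assay: a
silent gap inserted in background sound normally suppresses a subsequent
acoustic startle; an animal with tinnitus at that background frequency
"fills in" the gap and startles almost as strongly as without it.
Biophysically, the tinnitus-vulnerable versus resilient outcome tracks
plasticity in two subthreshold conductances of dorsal cochlear nucleus (DCN)
fusiform cells: the KCNQ2/3 (Kv7, M-type) potassium current and the HCN
(I~h~) current. This package implements the full quantitative workflow on
both sides — startle-trial quality control, ratio statistics and
Gaussian-null classification on the behavioral side; a conductance-based
fusiform-cell simulator and feature extraction on the cellular side — plus
the statistical decision tree that connects them. Because no raw data are
deposited for this kind of study, seeded synthetic generators for both data
types are first-class, tested components: they define the study conditions
under which the pipeline is validated.

# Behavioral pipeline

## Trial structure and quality control

A test session has three rounds; each round contains 72 gap/no-gap trial
pairs (12 per background frequency: 10, 12, 16, 20, 24, 32 kHz) and 30
prepulse/startle-only pairs (5 per frequency). Within a pair the reference
trial (no-gap or startle-only) and probe trial (gap or prepulse) alternate.
For every trial we record the peak-to-peak startle amplitude over the
response window, the maximum absolute amplitude (provenance only), and the
RMS of baseline movement preceding the stimulus.

Quality control applies, in order:

1. **Baseline elimination.** Within each round, pooling all four trial
   types, trials with baseline RMS outside mean ± 2.5 SD are eliminated;
   an eliminated trial takes its paired trial with it. Pooling per
   session-round is a configurable choice (`pool_by`); per-round pooling is
   the default because baseline movement drifts between rounds.
2. **Pair ratios.** ratio = probe p2p / reference p2p; pairs with a zero
   reference are flagged invalid.
3. **Sorted-jump filter (gap ratios only).** Within one frequency and
   round, ratios are sorted ascending; at the first increase of more than
   0.5 over the preceding value, that ratio and all larger ones are
   excluded. More than 5 exclusions drop the frequency for that round. The
   first offending jump governs: once the tail is gone, later jumps cannot
   exist. Whether the rule also applies to PPI ratios is not specified in
   the source protocol; we default to gap-only (`jump_filter_ppi = FALSE`).
4. **Averaging.** Mean of retained ratios within each round, then mean
   across the three rounds — not a pooled mean, so rounds with different
   retention counts weigh equally.
5. **Final exclusions.** Final gap ratios > 0.9 pre-exposure or > 1.1
   post-exposure, and PPI ratios > 1 in either phase, mark the frequency
   absent. Absence is recorded (`drop_reason`), never silently dropped, and
   a frequency absent in either phase produces no change score.

## Classification

The change score is Δ = post − pre per mouse × frequency. The protocol
text describes the subtraction in the opposite order, but the threshold it
derives is positive and tinnitus animals *increase* their gap ratio, so
post − pre is the only self-consistent convention; it is the package
default and configurable. Control-cohort change scores are fitted with a
Gaussian by sample moments (bin-free, rather than fitting a curve to a
histogram); the threshold is μ + 2δ. With the canonical control parameters
(μ = −0.02, δ = 0.15) the threshold is 0.28. A mouse is labeled tinnitus
when Δ strictly exceeds the threshold at ≥ 1 tested frequency; mice with no
usable frequency are reported as unclassifiable. Note the analytic tail
mass below μ + 2δ is Φ(2) = 97.7%; we report the analytic value.
Group-level comparisons use a threshold sweep (fractions above thresholds
from 1 to −1 in 0.02 steps, compared to the diagonal) and exact incidence
tests (Fisher's exact by default; a conditional binomial option is
provided because a "binomial test" between two observed proportions is
otherwise underdetermined).

## The behavioral generator

Each trial waveform is a damped-sinusoid startle transient (40 Hz carrier,
50 ms decay, normalized to unit peak-to-peak) on a Gaussian baseline
confined to the pre-stimulus window; only peak-to-peak amplitude and
baseline RMS are consumed downstream, so waveform shape is a plumbing
choice. Expected p2p is `startle_scale` × latent ratio (× 1 for reference
trials), with multiplicative log-normal noise of unit mean
(`trial_noise_sd` on the log scale, default 0.15 — a within-mouse
trial-to-trial variability the source protocol does not report; chosen as a
typical startle CV). With probability `baseline_artifact_rate` (default
0.02) the baseline SD is inflated 10×, exercising the baseline filter.
Latent ratios are clipped to (0, 1.2] so the final exclusion rules are
occasionally triggered.

The control Δ distribution Normal(−0.02, 0.15) is a *pipeline-level*
target: the generator assigns latent between-mouse change SD
√(δ² − δ²~meas~), where δ²~meas~ is the closed-form measurement variance of
a final ratio under the log-normal noise model (≈ 0.035 per phase at the
defaults, 36 retained pairs), so the fitted pipeline Gaussian recovers
(−0.02, 0.15). Tinnitus-cohort mice add a latent shift at 20–32 kHz only
(defaults +0.20/+0.25/+0.35); low-frequency changes are folded below the
control mean so the deficit is confined to high frequencies, and draws are
repeated until at least one high-frequency latent Δ clears μ + 2δ, which is
the cohort's defining property. What the generator does **not** emulate:
startle habituation across rounds, frequency-correlated latent changes,
hearing-threshold shifts, and any dependence of trial noise on amplitude —
so passing tests validate the pipeline's rules and statistics, not those
aspects of real data.

# Fusiform-cell model

A single compartment with

$$C_m \frac{dV}{dt} = -\big[g_L(V-E_L) + g_X(V-E_X) + \bar g_{KCNQ}\, m\,(V-E_K) + \bar g_{HCN}\, h\,(V-E_h)\big] + \psi(V) + I_{inj},$$

first-order gates relaxing to Boltzmann steady states
$m_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$ (KCNQ, k > 0) and
$h_\infty(V) = 1/(1+e^{(V-V_{1/2,h})/k_h})$ (HCN, negative-going), and an
exponential integrate-and-fire spike term
$\psi = g_L \Delta_T e^{(V-V_T)/\Delta_T}$ with reset and refractory
period. The spike mechanism is deliberately phenomenological: the study
measures spikes but never models them, and an EIF pacemaker reproduces the
needed behaviors (tonic ~14 Hz firing, silencing by TTX, rate reduction by
KCNQ openers and by hyperpolarizing leak). $E_K = -85.5$ mV and
$E_h = -30$ mV are fixed by the recording solutions.

Defaults and where they come from: `C_m` 60 pF and `g_leak` 10 nS put the
passive input resistance at 100 MΩ, matching the measured onset R~in~
(~98 MΩ). KCNQ `V_half` −28.3 mV and `G_max` 39.1 nS are the sham G–V
values; slope k = 6 mV and τ = 130 ms are not printed anywhere and were
chosen so the deactivation tail is clearly visible in a 1-s step at −50 mV.
HCN `V_half` −90 mV, slope 8 mV, τ 400 ms are standard I~h~ values; the HCN
maximal conductance is **calibrated per preset** (`calibrate_hcn_gmax()`,
a root search on the simulated ZD7288-sensitive sag) against the group sag
ratios 15.5 / 14.1 / 8.3%. Preset resting potentials are pinned exactly by
solving the steady-state balance for `E_leak` (or, for the 4-day preset,
for an extra inward-rectifier-like conductance with reversal at E~K~,
modeling the unidentified hyperpolarizing conductance of that group). The
EIF soft threshold was calibrated once so the control preset fires at
~14 Hz.

Pharmacology is parameter switching: XE991 zeroes $\bar g_{KCNQ}$, ZD7288
zeroes $\bar g_{HCN}$, TTX disables the spike mechanism including its
depolarizing drive, retigabine shifts KCNQ `V_half` by −10 mV
(configurable). Series-resistance artifacts are not modeled (experimentally
compensated), nor are synaptic conductances (pharmacologically blocked in
the experiments) or temperature effects.

## Numerics

Fixed-step integration at dt ≤ 0.025 ms: exponential Euler for the gates,
forward Euler for the voltage (membrane time constant ~6 ms, so the voltage
step error is far below the gate error). The accuracy contract — halving dt
changes reported features by < 0.5% — is tested for the sag ratio and
resting potential. Voltage-clamp initial state is the steady state of the
first command value; current-clamp starts from the passive resting
potential (or the bias target). The optional noise current is an
Ornstein–Uhlenbeck process (τ 5 ms) generated from R's seeded RNG; it is
off by default so reference runs are deterministic.

## Feature extraction choices

* **Tail current**: instantaneous current after the −30 → −50 mV step
  (median over a 20–60 ms post-settle window) minus the steady current
  (mean over the final 100 ms). Both windows are unstated in the source
  protocol; they are configurable and logged, and the alternative
  peak-minus-holding reading is always returned alongside.
* **G–V ramp**: the 10 mV/s ramp is run up *and* down, and
  `ramp_to_GV()` averages the branch means within 0.5 mV voltage bins.
  With τ~KCNQ~ = 130 ms a single 10 mV/s sweep lags by ≈ 1.3 mV, enough to
  shift the apparent V~1/2~; two-branch averaging cancels the lag to first
  order (the fitted V~1/2~ and G~max~ recover the generating values to
  3 significant figures on noiseless traces; a second-order residual of
  ≤ 0.5% of G~max~ remains, concentrated in the deactivated tail). Points
  within 5 mV of the reversal are excluded and the fit span is
  [−80, 0] mV by default.
* **Boltzmann fits** use multi-start Levenberg–Marquardt; non-convergence
  (e.g. a flat curve) is flagged, never silently defaulted.
* **Sag**: V~peak~ is the largest deflection from the pre-step baseline,
  V~ss~ the mean over the final 100 ms of the step (window unstated in the
  protocol; configurable); sag ratio = (V~peak~ − V~ss~)/V~peak~ × 100.
  The measurement depends only on deflections, hence is invariant to
  vertical offsets.
* **Input resistance**: per-step onset voltage = mean over 100 ms from the
  response peak; steady state = mean over the final 250 ms; R~in~ is the
  least-squares slope of the V–I relation.
* **Spikes**: detection by upward crossings of −20 mV with a 2 ms
  refractory merge (the source protocol never states its detector); 20
  consecutive spikes aligned at the post-spike negative peak and averaged;
  threshold = first voltage on the upstroke where dV/dt > 10 V/s, with
  dV/dt from central differences after a light 0.2 ms moving average —
  a heavy (≈1 kHz) low-pass would smear a sub-millisecond upstroke at our
  40 kHz sampling, so smoothing is kept minimal and configurable.

## Known inconsistencies and limitations

* The printed sham tail amplitude (73.8 pA) and the printed sham G–V
  parameters (39.1 nS, −28.3 mV) cannot coexist under a single Boltzmann
  conductance: the G–V scale implies a ~410 pA tail. Ramp and step
  measurements were made under different recording conditions, so the
  presets carry the G–V scale and `calibrate_kcnq_gmax_for_tail()`
  provides a separate tail-amplitude calibration context (as with the sag
  values, which also differ between experimental contexts — 15.5% vs 27.2%
  for equivalent groups in different figures — and are calibrated
  per-context, not reconciled).
* The deterministic EIF pacemaker ties firing rate tightly to the resting
  drive: presets with hyperpolarized RMP (non-tinnitus, 4-day) fall below
  the pacemaker bifurcation and are silent, whereas real cells fire at
  reduced-but-nonzero rates sustained by channel noise. Rate comparisons
  are therefore directional only. Enabling the OU noise current produces
  intermediate rates but breaks determinism of reference runs.
* The onset-vs-steady-state R~in~ *direction* (steady < onset, from slow
  subthreshold conductance recruitment) is reproduced; its measured
  magnitude (98 → 58 MΩ) is not, because the calibrated HCN conductance —
  sized to the sag under a −550 pA step — contributes far less chord
  conductance at rest than the cells' full subthreshold complement.

# Statistics

`lilliefors_test()` computes the KS distance of the sample against a
normal with estimated mean and SD, with the null distribution of the
statistic built by Monte Carlo (parameters re-estimated per replicate) —
exact for any n, no tabulated critical values; the seed is exposed. Its
statistic matches the tabulated reference implementation to machine
precision and its type-I error is calibrated to 0.05 ± 0.02 for
n ∈ {10, 20, 50}. Power is what the test has, not what one might hope:
against uniform(0, 1) at n = 100 it rejects ~60% of the time (the
reference implementation agrees).

`compare_groups()` gates on per-group normality at α = 0.05 (groups with
n < 5 pass the gate — the test cannot reject there), then runs Student's
t-test (2 groups) or one-way ANOVA with Tukey HSD (more) on the parametric
branch, Wilcoxon rank-sum or Kruskal–Wallis otherwise. "Tukey's least
significant test" in the source protocol conflates Tukey's HSD with
Fisher's LSD; Tukey HSD is implemented. All tests are two-sided; the
protocol never states sidedness.

# Problem sizes

The test suite validates the pipeline at the study's own scale where that
is cheap (21-mouse control cohorts, full 3 × 102-pair sessions, 200
replicate null fits, 9-s voltage ramps at dt = 0.025 ms) and at reduced
replicate counts where a property is being spot-checked rather than
estimated (e.g. 10 full-pipeline cohort replicates for the normality
acceptance property, 40 noisy-fit replicates for Boltzmann bias); the
acceptance script uses 200 replicate cohorts for the null-recovery
quantities and single deterministic simulations for the biophysical ones.
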