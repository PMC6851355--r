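---
title: "Measuring phasic and tonic inhibition of spinal GRPR interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phasic and tonic inhibition of spinal GRPR interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(spinaltone)
```

Dorsal horn GRPR interneurons relay itch. Their excitability is held down by
an inhibitory tone with two components: phasic (spontaneous glycinergic,
GABAergic and glycine/GABA co-release IPSCs) and tonic (a persistent chloride
conductance through high-affinity peri-/extra-synaptic receptors). This
vignette documents how each quantity the package reports is defined,
estimated and validated, and which choices were genuinely open.

## The synthetic recording model

A voltage-clamp trace is generated as

    I(t) = baseline + g_tonic (V_hold − E_Cl) + Σ_k A_k K(t − t_k) + ε(t)

with event times `t_k` from independent Poisson processes per transmitter
class, Gaussian noise `ε`, and a difference-of-exponentials kernel
`K(t) ∝ e^{−t/τ_d} − e^{−t/τ_r}` normalized to unit peak. Per-event decay
constants are drawn from truncated normals: glycinergic 6.2 ± 2.2 ms,
GABAergic 42 ± 6 ms. The GABAergic spread is not a reported value (only the
42 ms point estimate is); 6 ms keeps most events above the intermediate band
while acknowledging biological variability, and it is a parameter
(`tau_decay_sd`), not a constant. The rise constant defaults to 0.7 ms: rise
times of chloride-channel IPSCs are sub-millisecond and nearly irrelevant to
decay fitting at 20 kHz, which is why only decay kinetics are used for
classification.

Co-release events superpose one glycine-kernel and one gaba-kernel component
with weights 0.5/0.5. The source recordings only establish that intermediate
decays correspond to co-release, not a component ratio; equal weights are the
symmetric default, and a drug that removes one component leaves a genuinely
half-sized residual event, which is then re-detected only if it still clears
the detection threshold.

Event polarity follows the driving force at the holding potential: AMPA
events (reversal 0 mV) are inward at the −70 mV hold used for EPSC
recordings; chloride events (reversal −70 mV) are outward at the 0 mV hold
used for IPSC recordings. The tonic conductance contributes
`g·(V_hold − E_Cl)` pA; the preset splits it into glycine and GABA shares
carrying 10.25 and 22.5 pA at 0 mV — the two cohort-mean tonic currents the
antagonist experiments revealed.

The default spontaneous IPSC rate is 5 Hz, a typical spontaneous-event
frequency for these neurons; it also keeps tail overlap moderate, which
matters for the baseline estimator below. Study-condition runs use 60 s
recordings for profiling and 400 s (≈2000 events) for mixture-recovery
checks; these sizes give ±1 percentage-point multinomial error on the
recovered fractions.

Simulated pharmacology (`apply_drug()`): strychnine zeroes the glycinergic
rate, the glycine component of co-release events and the glycine tonic
share; bicuculline the GABA counterparts; CNQX and NBQX remove 90 % of AMPA
events (the observed block), with CNQX adding an 11.5 pA depolarizing
baseline shift — it has one, NBQX does not, which is how the recordings
excluded a presynaptic explanation for the shift; GRP depolarizes only cells
flagged as expressing its receptor.

## Event detection and decay fitting

Detection finds local maxima of the baseline-subtracted trace exceeding
`threshold_k` (default 4) times the robust noise SD, separated by at least
5 ms. Noise is 1.4826 × MAD of the high-pass residual, insensitive to event
contamination. The baseline is a running median (200 ms window); detection is
therefore exactly invariant under constant offsets and insensitive to slow
drift. A 0.5 ms boxcar is applied for thresholding only, so single noise
samples can neither split one event into several nor promote isolated
spikes; a candidate riding the decay tail of an accepted event must re-rise
by at least one threshold above the intervening minimum (a prominence rule)
to count as a new event. The 4 SD / 5 ms defaults are conventional for
spontaneous PSC analysis — the original recordings were scored with a
commercial detector whose criteria are not public — and are exposed in the
pipeline configuration.

Decay fitting is a least-squares single exponential from the event peak to
the first of: 10 % of peak, 5× a data-driven initial guess (time to 1/e), or
the next event's onset. The primary optimizer is Levenberg–Marquardt with a
fallback that profiles the amplitude in closed form and optimizes log-τ in
one dimension, which cannot fail to converge; events whose window is shorter
than 3 samples or whose fit collapses stay `unclassified` and are excluded
from mixture denominators. Two details matter for unbiased slow decays:

* the fitting baseline is a *two-pass event-masked* running median — samples
  occupied by events (and 2 ms margins) are excluded and the baseline
  interpolated across the gaps, then the mask is tightened on a second pass.
  A plain running median rides up under dense 42 ms tails and steepens every
  fitted decay by 2–4 ms, which is enough to push GABAergic events into the
  intermediate band.
* an earlier event's fitted tail is subtracted from the next event's window,
  so moderate-rate trains remain fittable.

Classification assigns τ < 16.8 ms to glycinergic, τ > 35.7 ms to GABAergic
and the closed interval [16.8, 35.7] ms to co-release. The interval is
stated inclusively in the source and no tie rule is given, so the closed
convention was chosen; the boundaries are configurable.

On 2000-event study-condition recordings the recovered fractions track the
planted 34/25/41 mixture within ±3 percentage points. The residual confusion
is dominated by the generator's own τ distributions: a GABAergic event drawn
at τ = 34 ms genuinely lies in the intermediate band, and no fit can undo
that overlap.

## Tonic currents

The holding current of an epoch (≥ 5 s) is the mean of a Gaussian fitted to
the dominant peak of the all-points histogram, with Freedman–Diaconis bin
widths (the histogram rule in the source is unspecified; FD adapts to both
noise scale and epoch length). Because synaptic events deflect the trace to
one side only, the histogram mode is robust where the epoch mean is not. If
the fitted peak region holds less than a configurable fraction of the
samples (default 0.25) the estimate is flagged rather than silently
returned. Planted offsets are recovered within 0.5 pA at the preset 2 pA
noise.

A tonic current is the difference of two holding currents across a drug
boundary, reported signed (`shift_pa`) and as a magnitude (`tonic_pa`) —
positive magnitudes at a 0 mV hold, matching how the cohort figures report
them. Sequential blockade is additive by construction of the estimator:
strychnine shift plus bicuculline-in-strychnine shift equals the
both-blocked shift.

## The model cell and the rheobase identity

The current-clamp stage uses a leaky integrate-and-fire cell with a
switchable tonic conductance, integrated by fixed-step exponential Euler at
the trace sampling rate — exact for piecewise-constant input, hence stable at
20 kHz with tens-of-millisecond membrane time constants. Spikes are drawn as
a single +20 mV sample so that a fixed −20 mV crossing criterion detects
them in the rendered trace; spike *times* in the ground truth are exact.

The `preset_cell()` parameters are solved exactly from five recorded cohort
means: input resistance 911.9 MΩ (control) and 2920 MΩ (after antagonists),
rheobase 39.8 and 7.4 pA, resting potential −56.96 mV. The solve yields
`g_L = 0.342 nS`, `g_tonic = 0.754 nS`, `E_L = −42.3 mV`,
`E_tonic = −63.6 mV` (a plausible chloride reversal) and `V_th = −20.7 mV`.
One printed mean could not be honored: the post-antagonist resting potential
appears as "48.6 mV" (sign evidently dropped in print), and −48.6 mV is
inconsistent with the printed rheobase/input-resistance pair; the preset
uses the solved E_L instead.

For any LIF cell the rheobase drop on removing the tonic conductance is
algebraically `g_tonic (V_th − E_tonic)` — the tonic current at spike
threshold. For the preset this equals 32.4 pA exactly, the printed rheobase
difference, and it is within 0.35 pA of the 32.75 pA sum of the two tonic
currents measured at the 0 mV hold. That near-equality is the quantitative
form of the claim that blocking the tonic currents is what makes the cells
more excitable, and the package states it as a simulator invariant (checked
to 2 pA, covering the 1 pA protocol quantization).

Rheobase is searched with ascending 1 pA, 500 ms steps, as in the recording
protocol; the search window starts just below the analytic value purely as a
runtime optimization, and backs off if the first probe already spikes, so
the simulation—not the formula—decides. Input resistance uses the mean of
the last 20 % of the pulse (500 ms ≫ τ_m for all presets; a plateau-drift
check warns otherwise).

## Calcium imaging

ΔF/F is `100·(F − F0)/F0` with F0 the mean over a baseline window: the first
60 s for agonist runs (bath arrival is fixed at 1 minute) and the first 30 s
for control runs, whose baseline is otherwise unspecified. Peaks are local
maxima *strictly above* the threshold — the stated rule discards signals
"lower than" the threshold, leaving equality ambiguous, and the strict
convention is implemented — separated by ≥ 2 s (4 frames at 2 Hz; GCaMP6f
transients span seconds, the source gives no separation rule). Peak height
above baseline, not prominence, is thresholded; that too is a resolved
ambiguity. A cell is `active` with ≥ 1 peak and `repeated_bursting` with
≥ 3 peaks inside any sliding 300 s window — control recordings were 5
minutes, agonist recordings 15, and a sliding window applies the 5-minute
rule uniformly to both.

The threshold itself is calibrated, not assumed: from a table of (injected
current, mean spike count, mean ΔF/F) the threshold is the mean ΔF/F of the
lowest current step whose mean spike count reaches 1. On the three published
calibration points this yields 3.5 %. The package can also simulate the
whole 8-step staircase (10–80 pA, 500 ms pulses, 1000 ms intervals) on a
model cell with a GCaMP6f-like kernel (50 ms rise, 600 ms decay, 1.3 % ΔF/F
per spike — tuned once so a 19-spike burst lands near the top published
transient of 17.5 %). The simulated staircase is monotone in both spike
count and ΔF/F and reproduces the *rule*; it does not reproduce the
published per-step spike counts, because an LIF f–I curve is steeper than
the biological one, and the published spike→ΔF/F relation is superlinear
where linear kernel superposition cannot be. Reaction time is measured from
the 1-minute bath arrival to the first suprathreshold peak; cells with
pre-arrival peaks are flagged spontaneously active and excluded from the
responder set.

The cohort generator plants responder status (Bernoulli), lognormal-free
latencies (normal, mean 5.8 ± 0.8 min truncated at 0.5 min) and repeated
bursts per responder; recovery tests confirm the analysis reproduces the
planted responder count exactly and the planted mean latency within one
frame.

## Single-cell prevalence

Counts are normalized by scaling every cell to the median of the original
per-cell totals, then `log1p`-transformed. The *Grpr* population is cells
with normalized expression strictly above 0.01; prevalence of a panel gene
is the percentage of those cells above the same threshold. The source prints
the gate direction both ways (">" for selection, "<" for prevalence); ">" is
implemented for both — the "<" reading would call a gene "expressed" in
cells where it is absent — and the direction is an argument for anyone who
disagrees. Whether the 0.01 threshold applies before or after the log is
also ambiguous; post-log is implemented (at 0.01 the two differ by 5 × 10⁻⁵,
far below one count). Default panels cover the markers (Slc17a6, Slc32a1,
Pax2, Tlx3, Ebf2) and the Gria1–4, Gabra1–6, Glra1–4/Glrb subunit families.

The deposited 24,384 × 1,545 dataset is not bundled; the synthetic generator
plants per-gene prevalences (Binomial expression indicators, 1 + Poisson
counts with lognormal per-cell depths) and recovery is verified to ±3
percentage points at 2000 cells. Dropping all-zero cells (with a warning)
slightly inflates prevalences in toy matrices; real matrices have none.

## Reproducibility and limits

Every generator takes an explicit integer seed and is bit-reproducible;
pipeline reports are a pure function of (config, seed). The configuration
round-trips through JSON and rejects unknown keys.

What passing tests on synthetic data do **not** show: the detector's
performance under recording artifacts (access-resistance drift, line noise,
seal instability) that the generator does not emulate; classification
accuracy when real decay-constant distributions overlap more than the
planted ones; imaging behavior under photobleaching, focal drift or ROI
cross-contamination; and any biology in the planted animal-level means —
presets tuned to cohort means (39.8 pA control rheobase, 11.5 pA CNQX
shift, 10.25/22.5 pA tonic currents) are regression anchors that keep the
pipeline honest, not reproductions of empirical results.
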