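---
title: "Models and methods behind dyndse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyndse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dyndse is a simulation-based design-space-exploration (DSE) toolkit for
wearable biosignal devices that spot events in a continuous stream on the
device itself. A candidate device is a *configuration*: one component per
system functionality — spotting algorithm, data-sampling strategy,
microcontroller, runtime mode — with every component parameter bound to a
value from a finite grid. The toolkit enumerates the configuration space
exhaustively, simulates each candidate on annotated EMG streams, scores it
on six objectives (precision P, recall R, execution time ET, energy EC,
memory demand MD, communication latency CL), and reports the feasible set
and a constrained optimum. This vignette explains the underlying models,
the defaults, and the choices made where the design was genuinely open.

## The design space and the optimisation

A design space is an ordered list of functionalities; each carries one or
more components; each component has finite parameter domains. The number
of configurations is the product over functionalities of the sum over
components of the product of their domain sizes, and enumeration is
lexicographic over declaration order (last parameter fastest). A
deterministic order keeps reports reproducible and gives tie-breaking a
well-defined meaning.

The multi-objective problem — maximise benefits (P, R), minimise costs
(ET, EC, MD, CL), subject to requirements — is relaxed to a constrained
maximisation: a configuration is *feasible* when every
requirement-normalised cost is at most 1 and every normalised benefit is
at least 1, and among feasible candidates the one maximising P + R wins.
A direct weighted sum of benefits minus costs is not offered as a
selector: the objectives live on incommensurate scales (fractions, mWh,
bytes), so an unweighted scalarisation has no defensible meaning, whereas
the normalise-then-constrain relaxation needs no weights. Ties are broken
by lower total energy, then by enumeration order. Infeasibility of an
entire space is an expected, reported outcome, not an error: part of the
point of DSE is discovering that a requirement set cannot be met on a
given platform. `pareto_front()` is provided for trade-off inspection; the
selector itself never returns a dominated feasible configuration.

## Retrieval scoring

Spotting quality is scored at the *sample* level: truth and retrieved
event lists are expanded to per-sample masks, precision is the fraction of
retrieved samples that are truly event samples, recall the fraction of
truth samples retrieved, F1 their harmonic mean. Conventions for the empty
corners (chosen, and applied consistently): both lists empty gives
P = R = F1 = 1; an empty retrieval against non-empty truth gives 0.
Per-participant scores are combined as an unweighted mean, so every person
counts equally regardless of recording length; the per-participant values
are retained in the diagnostics because population-mean feasibility does
not imply per-person feasibility — energy use under context-adaptive
sampling tracks individual behaviour.

## Analytical cost models

**Execution time.** Every pipeline stage is priced in elementary
operations (add/subtract, multiply, divide, square root, compare,
exponential). Machine cycles are the dot product of those tallies with the
per-operation cycle costs of the target microcontroller, and ET is cycles
over clock frequency. In real-time mode the constraint is per frame
(ET < frame length m); in online mode it is the total over the runtime
(ET < T), with frames buffered meanwhile.

Two counting conventions circulate for kernel methods and both are
implemented. For the one-class-SVM decision function the additive constant
can be charged (v+1 additions) or not (v); for the RBF kernel the
multiplications can be priced as v(d−1) (only the squared-difference
products) or v(d+1) (also charging the scaling and accumulation
multiplies). The defaults are the summary-table forms for pipeline
accounting and the per-stage worked forms where a single kernel evaluation
is being quoted; both are exposed (`add_convention`,
`rbf_mult_convention`) because the ~0.03% difference matters only when
matching a printed figure. The depth-2 wavelet-packet stage is priced as
Add = Σᵢ((m/2ⁱ − 1)·2 + 1)·2ⁱ and Mult = Σᵢ((m/2ⁱ) + 1)·4·2ⁱ over levels
i = 1..2, the cost of a 4-tap filter bank applied at 2ⁱ nodes per level.
The FFT stage's working buffer is taken as m float cells (the spectrum).

**Energy.** Four additive terms, all in mWh. The microcontroller spends
active power I_act·V for the computed ET and stand-by power for the rest
of the runtime; a schedule whose active time exceeds the runtime is
reported as infeasible. The sensor draws
[I_act·D_t + I_stb·(1−D_t)]·V per simulation step of the duty trace
(step t_r = 1 s by default, matching the sampler's decision period).
Non-volatile memory charges write current × voltage × write time per
block; read energy is neglected and the memory stand-by current defaults
to 0 mA (the shipped profiles do not specify one; the field
`I_stb_mem_mA` overrides). The radio charges transmit current × voltage ×
packet time per packet, at the 3.3 V system rail; one retrieved event
(two timestamps) fits one packet, and batching is out of scope. The
energy *budget* follows from the battery: capacity / required runtime ×
a derating factor φ = 0.9 for external effects on battery life, i.e.
925 mWh / 16 h × 0.9 = 52.03125 mWh for the shipped battery. Datasheet
summaries sometimes round such budgets differently; the constructor
accepts an explicit override.

**Memory.** MD = m_c + m_d + Σ m_f + m_e: a configurable code-memory
constant (default 8 KiB — linker-map territory that no analytical model
predicts well), the data memory (one frame of K channels × 4-byte floats
in real-time mode; the simulated ring-buffer peak in online mode), the
per-function working cells from the operation tables (floats 4 bytes,
integers sized by the microcontroller's word resolution), and 4 bytes per
stored event (two 2-byte timestamps). The ring-buffer peak comes from a
deterministic queue argument: arrivals every m seconds, service at ET per
frame; when ET ≤ m the peak is one frame, otherwise the backlog at the
last arrival.

**Latency.** CL = ET + payload / rate, with the BLE rate equal to the
maximum payload size per connection event divided by the connection
interval (216 bits / 7.5 ms = 28.8 kbit/s at the minimum interval; the
payload size is a profile field since stack revisions differ by a bit or
two). CL is excluded from the default feasibility conjunction — at
realistic event frequencies the event payload is negligible — and joins
it when a latency tolerance is supplied.

## Context-adaptive sampling

The sampler wakes the sensor once per decision period (default 1 s),
takes an n-shot measure (n = 4 samples), and summarises it as the mean
*rectified* amplitude per channel, maximum over channels. Rectification
is deliberate: surface EMG is zero-mean, so a raw mean would vanish; mean
absolute amplitude is the standard proxy for short-window EMG energy. The
context measure θ_t maps linearly onto a candidate duty rate, anchored at
(θ_l → D_l) and (θ_h → D_h) and clamped outside — θ_l = 10 mV sits at the
noise floor, and θ_h (default 180 mV) is the sensitivity knob swept in the
trade-off experiments.

The response model has two states. Whenever the candidate duty exceeds
the threshold D_TH the model is attentive: the duty becomes
max(current, candidate) — never decreasing — and the attention clock
resets to τ = 3 s. Below D_TH with the clock still running, the duty is
held and the clock decremented (the state equations leave this case
implicit; holding is the reading consistent with "the attention time
expires" triggering the relaxation). Below D_TH with the clock expired,
the candidate is adopted directly. Within a period the kept samples are
evenly spaced (⌈D_t × samples-per-period⌉ of them), and the n-shot
samples are counted as kept — they were physically acquired — so the
reported sampling *reduction* (fraction of samples not taken) includes
the measurement overhead. Samples not taken are zero-filled when the
stream is handed to a spotting pipeline: the sensor was off, and no
sample-and-hold is assumed.

## Spotting pipelines

Both pipelines segment the stream into non-overlapping frames of m
seconds and classify each frame with an RBF one-class SVM trained on
eating frames only (one-class because non-eating activity is unboundedly
heterogeneous). Maximal runs of positive frames merge into retrieved
events.

The **FFT-based** pipeline smooths each frame with a first-order
exponential filter (β = 0.5) and extracts, per channel, the standard
deviation and the peak FFT magnitude (frames zero-padded to the next
power of two), concatenated, padded to d and L2-normalised. This compact
schema is an interpretation — spectral-peak feature sets for chewing EMG
vary across implementations — and is configurable.

The **WPD-based** pipeline first gates each raw frame on its maximum
rectified amplitude: below the gate the frame is labelled non-event and
skips the pipeline entirely (saving its full per-frame cost). The gate is
inclusive (≥) and defaults, when unset, to the 95th percentile of
non-event frame maxima in the training folds. Gated-in frames pass a
50 Hz notch (second-order RBJ biquad, Q = 30), a 20 Hz 4th-order
Butterworth high-pass for de-trending, and rectification; cutoffs are the
physiologically motivated constants, the realisations are package
choices. Each channel is then decomposed with a full depth-2 wavelet
packet tree (db2, periodised — orthonormal, so the leaf coefficients
conserve energy), the concatenated coefficients are reduced to d
dimensions by a PCA fitted on training event frames, and the scores are
normalised with per-component centre/scale constants, also fitted on the
training event frames. Per-vector L2 normalisation was rejected for this
pipeline after it proved to destroy the amplitude information that
separates chewing bursts from gated-in noise: direction-only features
reduce the one-class boundary to chew-phase geometry, which does not
transfer across participants.

Training uses leave-one-participant-out folds: for each hyperparameter
grid point (defaults ν ∈ {0.01, 0.05}, γ ∈ {1/(8d), 1/(4d)} on
standardised scores) a model is fitted on all-but-one participant and the
full spot-and-score pipeline is evaluated on the held-out stream; the
point with the best mean F1 wins and the final model is refitted on all
participants. Everything is seeded and deterministic. The support-vector
budget v = 1500 is a *cost-accounting* constant: the fitted model's
actual SV count is recorded, and a warning is raised if it exceeds the
budget, since the cycle model would then undercharge.

## The synthetic cohort generator

Real day-long chewing-EMG recordings are not shippable, so every pipeline
is exercised on synthetic cohorts with a generator that is itself
first-class, tested code. A participant is 16 h of two-channel 256 Hz
signal by default: a zero-mean Gaussian noise floor scaled to 10 mV mean
rectified amplitude; eating events (five per day, 10–40 min) filled with
chewing bursts — band-limited 20–120 Hz noise, the surface-EMG passband,
amplitude-modulated at the 1.5 Hz chew rate with a sin² envelope peaking
at 150 mV mean rectified amplitude; optional 50 Hz line interference;
optional short confounder bursts (off by default — no principled default
intensity exists for speaking/frowning artefacts). Channel gains taper
slightly (1 to 0.85) to mimic electrode asymmetry. Annotations are
rounded *outward* to whole minutes, mimicking a hand-kept diet journal
and deliberately injecting boundary label noise.

What passing tests on this cohort do and do not show: the generator
produces bursts that are genuinely separable from the floor, so
end-to-end F1 near 0.9 demonstrates that the pipeline machinery —
gating, filtering, decomposition, projection, one-class boundary, run
merging, sample-level scoring — is wired correctly and transfers across
(synthetic) participants. It does not certify retrieval performance on
real free-living EMG, where confounders, electrode drift and
inter-person spectral variation are harsher. The cost models, by
contrast, are data-independent and carry over as-is.

## Problem sizes, tolerances and degenerate inputs

The shipped trade-off experiment uses 5 participants × 2 h with two
10–20 min events each, LOPO training, a θ_h grid {60, 120, 180, 360} mV
and 5 master seeds — sizes chosen so the full study runs comfortably on a
laptop while leaving hundreds of event frames per fold. Monotonicity of
the seed-averaged F1 along the θ_h grid is asserted with 0.03 absolute
slack (Monte-Carlo noise); sampling reduction must increase strictly;
F1 at ≥50% reduction must stay within 15 points of the uniform-sampling
F1. Master seeds fan out to per-participant and per-fold sub-seeds by a
fixed counter scheme (seed × 100003 + counter, mod 2³¹−1).

Numerical corner cases are pinned down explicitly: an all-zero frame
yields a zero feature vector (L2 guard); WPD requires frame lengths
divisible by 4; filters run with zero initial conditions; `map_duty`
clamps outside its anchors; empty operation counts price to zero cycles;
an over-committed real-time schedule surfaces as an infeasible metric
row, not an exception, so a sweep never aborts.

## Known limitations

Cycle tallies are architecture-nominal, not compiler-accurate; circuit
overheads (regulators, ADC front-ends) are not modelled; the radio model
is a fixed per-packet cost without back-off or retransmission; the
sampler does not model sensor wake-up latency; parameter domains are
finite grids (no continuous optimisation); and the synthetic generator is
not a physiological motor-unit model — it is a test harness with the
right spectral envelope, not a substitute for real recordings.
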