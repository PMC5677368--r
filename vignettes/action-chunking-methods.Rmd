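---
title: "Methods: operant schedules, action-sequence chunking and activation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operant schedules, action-sequence chunking and activation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionchunks)
```

# Overview

`actionchunks` simulates and analyses single-lever operant conditioning
sessions recorded as time-stamped event streams. A session is a sequence of
events — active and inactive lever presses, magazine (food receptacle)
entries, pellet deliveries and cue onsets — stamped on a 10-ms grid. The
package covers four layers:

1. **Schedule state machines** — the reinforcement rules that decide which
   presses earn pellets (continuous reinforcement, random ratio, a
   sequence-trigger gate, lever-hold and random-time schedules, and a
   pellet-drop calibration procedure).
2. **Synthetic agents** — parametric generative models of pressing
   behaviour that drive the schedules and emit ground-truth element labels
   for every event.
3. **Sequence parsing and chunking analysis** — classification of events
   into initiation, execution and termination elements; assembly of action
   sequences; categorisation of intervals into within-sequence
   inter-press intervals (IPIs) and sequence-boundary intervals; chunking
   scatter plots and kernel-density summaries; fastest-burst extraction;
   and acoustic recovery of true IPIs from session audio.
4. **Activation mapping** — soma detection on section images, polygonal
   atlas assignment, regional counts and densities, and region-by-region
   and activity-by-performance Pearson correlation analyses.

All internal time arithmetic uses integer centiseconds (1 cs = 10 ms, the
recording resolution of the behavioural apparatus). Seconds appear only at
API boundaries. This avoids floating-point drift when intervals are
composed, and makes the timestamp quantisation artefact (below) explicit
rather than accidental.

# Schedules

## Random ratio and continuous reinforcement

A random-ratio schedule RR-$n$ reinforces each press independently with
probability $p = 1/n$: RR5 has $p = 0.2$, RR10 $p = 0.1$, RR20 $p = 0.05$.
Continuous reinforcement (CRF) is the $p = 1$ limit. `rr_step()` draws one
Bernoulli variate per press from R's seeded RNG stream. Sessions terminate
at a reward cap (20 pellets by default) or a timeout (30 min by default),
whichever comes first.

## The sequence-trigger gate

Sequence training adds a gate in front of the RR program: only sequences
*initiated* with at least $N$ consecutive presses ($N = 5$, later $N = 7$)
may consult the RR draw. `st_gate_step()` keeps a consecutive-press counter
and a lock:

* a press increments the counter; at counter $\ge N$ the gate unlocks, and
  the RR program is consulted for that press and all later presses of the
  same sequence;
* a termination element (press followed by a magazine check) before
  unlocking resets the counter — the RR program was never consulted;
* a termination after unlocking but before reward resets the RR trial:
  counter cleared, lock re-imposed;
* a reward completes the sequence; the lock is re-imposed for the next one.

Because the per-press RR draw is memoryless there is no ratio progress to
clear, so "resetting the RR trial" is exactly re-locking the gate. One
open point is whether a reinforced press that breaks through the gate also
resets the counter mid-sequence; here the counter simply continues until a
termination element, which is indistinguishable in behaviour because the
agent heads to the magazine after a reward anyway. The gate is driven by
parsed element identity; tests verify it against a brute-force recount
that re-walks the element stream, which is the array-lookback formulation
of the same rule.

## Lever-hold requirements

Lever-hold (LH) schedules reward a press only if the lever is held at
least as long as a requirement drawn fresh each trial. Each training stage
states a mean and hard bounds: LH0.3 has mean 0.3 s on [0.05, 0.88] s, and
the final LH5 stage averages 5 s with holds up to 11.7 s. Both constraints
are honoured simultaneously by drawing from an exponential distribution
truncated to $[a, b]$ with the rate $\lambda$ solved (once per parameter
set, by `uniroot`) so that the truncated mean

$$\mathbb{E}[X] = a + \frac{1}{\lambda} - \frac{b-a}{e^{\lambda (b-a)} - 1}$$

equals the stage mean. As $\lambda \to 0$ this recovers the uniform mean
$(a+b)/2$; negative $\lambda$ (density increasing towards $b$) covers
stage means above the midpoint. Draws use the inverse CDF, so every draw
respects the bounds exactly. Two parameters are not part of the published
stage table and are package defaults: the minimum hold for stages other
than LH0.3 (kept at the 0.05-s LH0.3 floor) and the maxima of the
intermediate stages LH0.8–LH3.2 (scaled by the final stage's max/mean
ratio, 11.7/5 = 2.34). The hold-versus-requirement comparison is boundary
inclusive (`hold >= requirement` is reinforced); the choice is arbitrary,
documented here, and pinned by a test.

## Random-time and pellet-drop procedures

Magazine training delivers pellets at exponentially distributed intervals
(RT 60 s) regardless of behaviour. The pellet-drop procedure activates the
dispenser with probability 0.1 at each 1-s tick and stops at the 10th
pellet; the duration is a sum of ten geometric waiting times with
expectation $10 / 0.1 = 100$ s $\approx$ 1.66 min, which the simulation
reproduces and the acceptance script recomputes.

# The synthetic-agent generator

`generate_session()` emits sessions with a controlled statistical
structure: a sampled sequence length, sampled within-sequence IPIs, one or
more magazine checks after each sequence, and a boundary interval before
the next sequence, occasionally replaced by a long off-task pause. The
schedule is consulted press by press; a reinforced press truncates the
ongoing sequence because the agent leaves to collect. Every emitted event
carries a ground-truth element label, which makes the generator the oracle
for the parser: the parser must reproduce the labels exactly.

Distribution families are deliberate fixtures, configurable per profile:
negative-binomial (shifted to $\ge 1$) sequence lengths, lognormal IPIs
and boundary intervals, shifted-Poisson check counts. Two presets ship:

* `young_like` — longer sequences (mean length 5), slower pressing
  (median IPI 0.5 s), boundary intervals spread well above the chunking
  space (medians 2.5 s press-to-check, 4.5 s check-to-press), off-task
  pauses with probability 0.12;
* `aged_like` — the "microchunk" phenotype: short sequences (mean length
  2.6), fast pressing (median IPI 0.2 s), boundary intervals compressed
  towards the chunking space (medians 1.1 and 1.6 s), fewer pauses.

Only the *orderings* between the presets are contractual (higher sequence
rate, shorter durations, shorter IPIs, more sub-20-s boundary events for
`aged_like`); the parameter values themselves are invented and are not
estimates of any animal data. Pauses are generated with explicit
probability and a lognormal duration centred near 45 s so that the 20-s
boundary filter has genuine work to do in tests.

Sampled gaps are floored onto the centisecond grid with a 1-cs minimum.
This reproduces the pile-up artefact of timestamp-based recording: true
intervals shorter than the grid accumulate on the first grid steps, which
is why the acoustic module exists. `quantization_bias()` quantifies
exactly this.

What the generator does *not* emulate: satiety and within-session rate
drift, inactive-lever pressing, post-reinforcement pauses distinct from
ordinary boundary intervals, day-to-day learning trajectories (each
simulated day is exchangeable), and any reinforcement-learning dynamics.
Passing tests therefore demonstrate that the analysis pipeline measures
what it claims on streams with known structure — not that real mice obey
these distributions.

Cohorts derive one seed per (subject, day) cell from a master seed via a
multiplicative string hash (`derive_seed()`), so a subject's data are
invariant to cohort size and any cell can be regenerated in isolation.

# Parsing and chunking

Element classification follows predecessor identity within the behavioural
subsequence (presses and checks only): a press after a check (or the first
press) is an initiation, a press after a press an execution, a check after
a press a termination, and a check after a check is ignored. Pellets and
cues pass through unlabelled. Sequences span initiation → termination; a
trailing sequence with no termination is flagged open and excluded from
duration, speed and interval summaries (its duration is unmeasurable).

Two conventions deserve note:

* **Duration** defaults to initiation press → termination check
  ("initiation to termination"); a first-press → last-press alternative is
  available (`duration = "press_span"`) since "duration of a press
  sequence" is ambiguous in common usage.
* **Speed** is $(L - 1) / \text{press span}$, the reciprocal of the mean
  IPI — the burst-rate reading consistent with acoustic burst speeds.
  It is undefined for $L = 1$.

Interval categorisation produces one within-sequence record per execution
press and pools press-to-check and check-to-press intervals into a single
boundary category; boundary values above 20 s are discarded as engagement
in other behaviours. The check-to-press interval is measured from the
immediately preceding check, including trailing ignored checks — the
moment the animal last left the magazine — while ignored checks never
generate intervals of their own. A variant that sums each termination
interval with the following initiation interval into one per-boundary
value is exposed (`boundary = "summed"`) because "adding up press-check
and check-press intervals" admits both readings; pooling is the default as
it matches the two-cluster structure of the chunking scatter plots.

The chunking representation plots each interval at $x = \log_{10}(\text{interval})$
with uniform random $y$-jitter, with one Gaussian kernel density curve per
category on the log axis. Bandwidth uses Silverman's rule on the log scale
(overridable); each curve integrates to one, verified by trapezoid
quadrature to $10^{-3}$. IPI frequency histograms default to 10-ms bins
over 0–2 s, aligned with the timestamp grid.

# Acoustic recovery of true IPIs

Timestamp flooring biases short IPIs; the acoustic module recovers press
times from session audio instead. The synthetic fixture generator plants a
click — by default a 3-ms exponentially decaying 4-kHz transient — at each
press time over Gaussian noise, optionally followed 2–5 ms later by a
smaller lever-bounce artefact. The detector computes a zero-phase
Butterworth band-pass envelope (2–6 kHz, rectified, 0.5-ms moving
average), thresholds it at the median plus 6 robust SDs (MAD-based), and
reports the envelope's threshold crossing as the onset; a 20-ms refractory
window absorbs bounce artefacts, safely below the fastest plausible IPI of
interest (about 77 ms, or 13 presses per second). On synthetic truth the
detector achieves recall = precision = 1 with sub-millisecond timing at 20
dB SNR; tests also pin the monotone degradation of recall with noise. The
automated detector is a principled stand-in for manual
spectrogram-and-waveform inspection and is validated on synthetic truth
only.

# Activation mapping

Section images are modelled as matrices indexed `[x + 1, y + 1]` with
0-based pixel-centre coordinates, origin top-left, x rightward, y downward
— the image-format convention, stated here because atlas authors must use
it. The synthetic section generator plants Poisson counts of somata
(expected count = density × polygon area) uniformly inside each atlas
polygon, rendered as Gaussian blobs over background noise, and returns the
planted truth.

Detection mirrors thresholded particle analysis: a global threshold
(Otsu's method by default; a fixed level can be supplied), 8-connected
component labelling, an area filter, and intensity-weighted centroids.
Component labelling runs a 4-connected pass and then merges diagonally
adjacent labels by union–find, giving 8-connectivity, the common
particle-analysis convention.

Region assignment is ray-casting point-in-polygon with an explicit
**boundary-inclusive** convention (edge and vertex points count as
inside); tests check it against an independent implementation on 10,000
random points and on adversarial vertex/edge cases. Overlapping polygons
resolve to the first region in atlas order with a warning — a manually
drawn atlas is disjoint by construction, so this only matters for
malformed user atlases. Region areas use the shoelace formula scaled by
the squared pixel size; densities are counts per mm².

Correlation analyses are plain Pearson: region-by-region correlation of
activation across animals, and region-by-feature correlation against
behavioural summaries (sequence length, duration, speed, total presses).
Two-sided p-values come from the $t$ transform with $n - 2$ degrees of
freedom. P-values are reported raw by default, matching per-pair
correlation diagrams; Benjamini–Hochberg adjustment is available but off
by default. Constant columns have undefined correlation and are reported
as `NA`. The included `synthetic_atlas()` is an invented, non-anatomical
polygon layout that borrows only the region *names* (PrL, aCg/M2, aDS,
Core, Shell, DMS, DLS, FPx) for realistic table shapes.

# Numerical and design choices

* Centisecond integer time; sampled gaps floored with a 1-cs minimum; a
  press and a check never share a timestamp in simulation (events tied at
  a centisecond keep stream order, and the parser is order-dependent).
* Session logs are plain text: YAML front matter (subject, day, schedule)
  between `---` delimiters, then `time_cs,kind,hold_cs` CSV. Byte output
  is deterministic; reading preserves tie order; unsorted input is
  repaired with a stable sort and a warning.
* The truncated-exponential rate is solved to `uniroot` tolerance 1e-12;
  the degenerate `min = mean = max` case short-circuits to a point mass.
* KDE bandwidth: Silverman's rule on log10 values; histogram bins 10 ms;
  both overridable.
* Onset detector: band 2–6 kHz, threshold median + 6 MAD, refractory
  20 ms; all arguments.
* Otsu threshold on the `[0, 1]` intensity range; area filter bounds in
  px²; fixed-level override for images where Otsu's bimodality assumption
  fails (e.g. nearly empty sections).
* Master-seed splitting uses a 31-bit multiplicative string hash; derived
  seeds stay in `[1, 2^31 - 2]`.

# Problem sizes used by the test suite

The shipped tests run at sizes chosen to give stable statistical contracts
while remaining quick on one CPU: 100,000 presses for RR rate contracts;
10,000 draws for LH and RT distributional checks; 10,000 simulated
pellet-drop sessions; 1,000 random element streams for the gate oracle;
100 random-profile sessions (2 min each) for parser/ground-truth
equivalence; 8-seed cohorts of 20-min sessions per preset for the
phenotype orderings; 10,000 random points for the containment oracle; and
1,000 null-cohort replicates for the false-positive calibration of the
correlation matrix. The whole suite runs in well under a minute.

# Known limitations

* The agents are descriptive, not learning models; they cannot reproduce
  acquisition curves, only steady-state structure.
* The acoustic detector assumes a broadly stationary noise floor; strongly
  non-stationary noise would need an adaptive (windowed) threshold.
* Soma detection assumes roughly isotropic blob-like somata and a global
  threshold; heavy intensity gradients across a section would require
  local thresholding, which is out of scope.
* Group-level inferential statistics (mixed ANOVAs and their corrections)
  are intentionally not implemented; the package exports tidy per-sequence
  and per-session tables for external statistical software.
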