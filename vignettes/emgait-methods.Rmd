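---
title: "Methods: detectors, triggering, synergies, and the synthetic gait generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detectors, triggering, synergies, and the synthetic gait generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the algorithms, parameter choices and numerical
conventions implemented in `emgait`, and the design of the synthetic gait
generator the package is validated against. Everything quantitative stated
here is either a definition or a property the test suite actually computes;
the package makes no empirical claims beyond those.

```{r setup}
library(emgait)
```

## 1. Signal model and preprocessing

Raw surface EMG is modeled as a zero-mean, band-limited interference signal
whose instantaneous amplitude is modulated by muscle activation. Two derived
representations are used:

- **Raw amplitude** `|x[t]|` — for onset detection, where latency matters and
  smoothing would delay the decision.
- **Linear envelope** — full-wave rectification followed by a low-pass
  Butterworth filter, for offset detection, cycle averaging and synergy
  extraction.

`compute_envelope()` defaults to a **2nd-order, 6 Hz** Butterworth low-pass.
A 6 Hz cutoff keeps the burst structure of gait (cycle ~2 s, bursts
~100–300 ms) while removing the carrier; 2nd order gives a gentle roll-off
that does not ring on burst edges. Offline the filter is applied forward and
backward (`signal::filtfilt`, zero phase, squared magnitude response); with
`zero_phase = FALSE` the same coefficients run causally
(`signal::filter`), which is what an online controller would see. Filtered
values are clipped at zero: the envelope is an amplitude and a filter
undershoot below zero is an artifact, not information.

`estimate_baseline()` computes, over a quiet-standing window, the raw mean
square power `P0`, the rectified mean/SD, and the envelope mean/SD per
channel. If the envelope cutoff is not below Nyquist (possible only for toy
sampling rates), envelope statistics are returned as `NA` and amplitude
statistics are still computed.

### Cycle segmentation and time normalization

A gait cycle is the half-open interval `[c_i, c_{i+1})` between consecutive
foot contacts of the *same* side (`segment_cycles()`).
`normalize_cycles()` resamples each cycle onto a `grid`-point 0–100 % axis
(default **100 points**, i.e. 1 % resolution — the conventional gait grid) by
linear interpolation at fractions `(0:(grid-1))/grid` of the cycle, so point
`g` sits at phase `g-1` percent and the end of the cycle (≡ the start of the
next) is excluded. Sample positions are computed in index space from `t0` and
`fs` rather than by comparing floating-point times, and index arithmetic uses
`round()` rather than truncation: `0.57 * 100` is `56.999…` in binary floating
point, and truncation would silently shift events by one sample.

## 2. Onset detection (single-threshold, on raw EMG)

The onset threshold of muscle *m* is an amplitude proportional to its resting
RMS:

$$h_{on}(m) = k_{on}\sqrt{P_0(m)}$$

An onset is the first sample with `|x[t]| >= h_on`. A single-sample test on
the raw signal is the lowest-latency detector available; its cost is
sensitivity to noise tails, which the choice of `k_on` must control.

**Why `k_on = 6`.** For a zero-mean Gaussian signal, a single-sample test at
`k` standard deviations fires at roughly the band-limited signal's level
crossing rate times `exp(-k²/2)`. A 20–450 Hz interference signal at 2000 Hz
has a mean zero-crossing rate of several hundred per second; at `k = 3` the
expected false-onset rate on *pure noise* is on the order of several per
second — a noise-only (detached or silent) channel would fire constantly and
could never be screened out. At `k = 6` the noise-only false-alarm probability
per sample is ~2 × 10⁻⁹, i.e. essentially zero over a session, while genuine
bursts — an order of magnitude above baseline RMS — still cross within a few
samples of burst start. `k_on` is exposed in `calibrate()` /
`analysis_config()` so users can trade latency against false alarms. If a
channel's baseline power is exactly zero (synthetic or clipped data), a small
floor is used and a warning issued, since a zero threshold would fire on the
first nonzero sample.

**Channel re-arm.** After an onset, a channel does not report again until it
re-arms. Two policies are implemented: a fixed refractory interval (default
**0.4 s**, the same constant the trigger FSM uses, so channel-level and
controller-level suppression agree), or re-arm at the double-threshold offset
of the burst just detected (`rearm = "offset"` in `detect_onset_st()`). The
refractory policy is the default because it is what a minimal online
controller would run; the offset policy ties re-arm to the actual burst
length and is the right choice when bursts can exceed the refractory period.

## 3. Offset detection (double-threshold, on the envelope)

The offset threshold is computed from the *envelope* baseline:

$$h_{off}(m) = \mu_0(m) + k_{off}\,\sigma_0(m), \qquad k_{off} = 2$$

A burst ends at the first time the envelope stays **below `h_off`
continuously for `t_off` seconds** (default **50 ms**, i.e. 100 samples at
2000 Hz). The dwell requirement is the point of the double threshold: gait
envelopes dip transiently between motor-unit bursts, and a single-sample
offset test would fragment one burst into many. The reported offset time is
the *start* of the qualifying below-threshold run — the burst ended when the
envelope went down, not `t_off` later when we became sure of it. The search
starts one sample after the onset sample so that an onset on an
already-quiet envelope cannot return an offset at the onset itself.
`k_off = 2` places the threshold two baseline SDs above the resting envelope
mean: low enough to catch the true end of the decay, high enough that
baseline noise does not hold the envelope above threshold indefinitely.

Degenerate case: if no qualifying run exists before the end of the recording,
`detect_offset_dt()` returns `NULL` (burst still ongoing), never a fabricated
time.

## 4. Calibration

`calibrate()` takes a *passive* walking trial (the exoskeleton walks, the
user follows — muscles show gait-locked activity but no triggering is at
stake) plus its foot-contact events:

1. Baseline statistics from the quiet-standing window preceding the first
   contact (or an explicit `baseline_window`).
2. `h_on`, `h_off` per trigger muscle from the formulas above.
3. **Usability screening:** a trigger muscle that produces *no* ST onset
   during the whole passive walk is flagged unusable — if it will not cross
   threshold when walking, it cannot drive the trigger. Unusable channels are
   reported but kept in the threshold set, so the record of *why* a channel
   was excluded travels with the calibration (`write_thresholds()` /
   `read_thresholds()` round-trip it as JSON).
4. If both muscles of a step pair are unusable, calibration errors: the
   controller could never command that side.

## 5. The trigger state machine

`run_trigger()` implements a strictly alternating finite-state machine:

```
AWAIT(side) --first ST onset from side's usable pair--> COMMAND(side)
COMMAND --> REFRACTORY (0.4 s) --> AWAIT(opposite side)
```

Each step side is served by a **redundant pair** of muscles, so the loss of
either single channel leaves the controller functional. Two pairings are
implemented in `muscle_step_map()` because both are defensible and the
package does not have grounds to declare one canonical:

- `"table2"` (default): right step ← {right rectus femoris, left soleus};
  left step ← {left rectus femoris, right soleus}. Rationale: the swing
  side's rectus femoris (hip flexor, early swing) and the stance side's
  soleus (push-off) both signal the same step.
- `"sec233"`: the mirror assignment (right step ← {right soleus, left rectus
  femoris}).

The two conventions relabel which side a given onset commands; all detector
mathematics is identical. Onsets arriving during the FSM refractory or from
the non-pending side are appended to `run$ignored` with a reason
(`"refractory"` / `"wrong_side"`) rather than dropped — the ignored stream is
the controller's error log. The refractory default of **0.4 s** is a step
execution time scale: long enough that one burst cannot double-trigger,
comfortably shorter than a half-cycle (~1 s) so it never blocks the next
contralateral step.

`onset_cycle_stats()` converts accepted commands to phases,
`100·(t − start)/(end − start)` % of the containing cycle, and
`detection_shares()` reports each trigger muscle's share of accepted
commands in % (summing to 100). Phase means are arithmetic, not circular:
shares and phases are diagnostics of a specific run, and a muscle firing near
the cycle wrap shows up as a large SD — visible, not hidden.

## 6. Muscle synergies

`extract_synergies()` arranges a `cycle_matrix` of envelopes as a
muscles × (cycles · grid) matrix `E`, normalizes each muscle row by its
maximum (so no muscle dominates the factorization by amplitude), and solves

$$\min_{W,H \ge 0} \lVert E - WH \rVert_F^2$$

by classical multiplicative updates. Implementation choices:

- **Restarts:** NMF is non-convex; the fit is the best (lowest SSE) of
  `restarts` runs (default **20**) from seeded uniform random starts scaled
  to match the data's mean, so results are reproducible given `seed`.
- **Convergence:** relative SSE change below `1e-6`, checked every 10
  iterations, cap 2000 iterations. A small epsilon (`1e-16`) in update
  denominators prevents 0/0.
- **Normalization convention:** each column of `W` is scaled to unit maximum
  with the inverse scale pushed into `H`, so synergy vectors are
  dimensionless weight profiles and all amplitude lives in the activation
  patterns.
- **Reported patterns:** `H` is averaged per grid point across cycles, giving
  one 100-point *basic activation pattern* per synergy.
- **Quality:** uncentered variance accounted for,
  `VAF = 1 − Σ(E−WH)²/ΣE²` (uncentered because the envelope's mean is
  signal, not offset).

The default **4 synergies** is the standard low-dimensional description of
lower-limb gait EMG and is also the generative dimensionality of the
simulator, which makes recovery testable; `n_syn` is a free argument.
`extract_synergies()` returns a classed fit with `print`, `summary`, `coef`
(W), `fitted`, `residuals` and `predict` (project new cycles onto fixed W by
non-negative multiplicative updates on H alone) methods.

### Pattern descriptors

- **FWHM** (`fwhm()`): after subtracting the pattern's minimum, the number of
  grid points at or above half of the resulting maximum, in % cycle. Defined
  by counting (not interval edges) so multi-modal patterns are handled
  without arbitrary choices; a flat pattern has no width and returns `NA`.
- **CoA** (`coa()`): the circular mean of the grid angles weighted by
  activation, `atan2(Σ a sinθ, Σ a cosθ)` mapped back to % cycle — the
  correct "center" for a quantity that lives on a cycle. A pattern whose
  resultant vector is (numerically) zero, e.g. perfectly uniform, has no
  defined center and returns `NA`. Both descriptors are scale-invariant, and
  CoA is shift-equivariant; the test suite checks both properties against
  brute-force implementations.

## 7. Kinematics and condition statistics

`joint_cycle_stats()` reduces time-normalized joint-angle cycles to per-cycle
max, min and range of motion, plus mean/SD/median/max/min aggregates.

`compare_conditions()` takes a subjects × conditions matrix of any scalar
summary and applies the standard nonparametric chain for small repeated
measures samples: **Friedman test**, then pairwise **Wilcoxon signed-rank**
tests with **Bonferroni** correction, at `alpha = 0.05`. Choices:

- *Protected* by default: pairwise results are flagged significant only if
  the Friedman test rejects, controlling the chain's overall type-I error
  (verified by simulation in the tests: ≤ 7 % empirical rate at nominal 5 %).
- Exact Wilcoxon p-values for `n ≤ 25` (no normal approximation where the
  exact null is cheap), the usual approximation above.
- Degenerate inputs are defined, not errors: a fully tied matrix yields a
  Friedman statistic of 0 with p = 1; an all-zero-difference pair yields
  p = 1 (no evidence of a difference, rather than `wilcox.test`'s error).

## 8. The synthetic gait generator

`simulate_gait()` exists so that every stage of the pipeline can be tested
against known ground truth. It is a *generative model of the signals the
pipeline consumes*, not a biomechanical simulation.

**Events.** Cycle periods are drawn i.i.d. from a truncated normal
(**2.0 ± 0.1 s**, a typical comfortable gait cycle with realistic
variability); right contacts are the cumulative sums after a **2 s**
quiet-standing lead-in (the calibration baseline window), left contacts are
offset by 50 % of each cycle.

**Envelopes.** Right-side envelopes follow an exact 4-synergy model
`W0 · H0`, with circular Gaussian activation bumps centered at
**8, 42, 65 and 92 %** of the cycle (widths 6, 7, 5, 6 %) — an early-stance
loading synergy (vastus + biceps femoris), a push-off synergy
(soleus + gastrocnemius), a swing-initiation synergy (rectus femoris +
tibialis) and a late-swing synergy. The two trigger muscles are deliberately
*single-burst* (soleus only in the push-off synergy, rectus femoris only in
swing initiation) so each has one unambiguous planted onset phase,
`(center − 2·width) mod 100`. Left-side trigger channels reuse the matching
right-side pattern shifted by half a cycle. Multiplicative envelope noise is
**10 %** (`env · (1 + 0.1·N(0,1))`, clipped at 0).

**Raw EMG.** Each channel is its noisy envelope times an independent
unit-variance Gaussian carrier band-limited to **20–450 Hz** (the
conventional surface-EMG band), plus a Gaussian noise floor of
**σ = 0.02** — about 6 % of the planted burst amplitudes, so thresholds are
exercised against a realistic baseline. Channels named in `corrupt_channels`
carry the noise floor *only*: the model of a detached electrode or silent
muscle, and the input for testing usability screening and pair redundancy.

**Kinematics.** Hip, knee and ankle angles are single-harmonic templates
(offset ± amplitude: 7 ± 18°, 26 ± 24°, 4.5 ± 8° — magnitudes in the range of
normal-gait curves) with 5 % per-cycle amplitude jitter; the truth records
each cycle's planted max/min/ROM.

**Determinism.** All randomness flows through seeded streams
(`with_seed()` preserves the caller's RNG state), so
`simulate_gait(cfg, seed)` is a pure function of its arguments.

**What it does not emulate** — and therefore what the package's validation
cannot speak to: non-stationary baselines and movement artifacts, electrode
cross-talk, motor-unit structure (the carrier is Gaussian, not a
superposition of MUAPs), fatigue-related spectral compression, within-cycle
timing variability of bursts (bump centers are fixed in phase), double
support and asymmetric gait, and any closed-loop interaction between trigger
decisions and subsequent muscle activity (the simulated walker ignores the
commands). Results on synthetic data bound what the code does, not how a
controller performs on patients.

## 9. Problem sizes and reference checks

The package's own end-to-end checks (in `tests/testthat/test-acceptance.R`,
recomputed by `scripts/acceptance.R`) use sizes chosen as the smallest that
make the quantities stable: **30 cycles** for the synergy-VAF check
(VAF of a 4-synergy fit under 10 % envelope noise must stay ≥ 90 %),
**50 cycles** for the corrupt-channel trigger run (the baseline-noise-only
left rectus femoris must account for exactly 0 % of accepted commands while
commands keep alternating), 1000-instance brute-force oracle sweeps for the
detectors and indicators, and 2000 null simulations at n = 7 subjects × 3
conditions for the statistics chain. These are the package's validation
conditions; they are not measurements of any physical system.

## 10. Limitations

- The controller runs *offline* on recorded or simulated signals; the causal
  envelope path exists, but no real-time I/O or latency accounting is
  provided.
- `k_on = 6` is derived from Gaussian crossing-rate arguments; heavy-tailed
  artifacts (cable motion) will still cross it, and no artifact rejection is
  implemented.
- Phase statistics are linear, not circular; interpret near-wrap means via
  the per-onset table.
- NMF rank selection is left to the user (`n_syn`); the package reports VAF
  but does not automate the rank choice.
- The Wilcoxon step assumes exchangeable paired differences; with many ties
  at moderate n the approximate p-values are conservative at best.
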