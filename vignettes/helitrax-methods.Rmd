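---
title: "Models and estimators in helitrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in helitrax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helitrax)
```

`helitrax` packages the quantitative stages of a single-molecule helicase
study — kymograph tracking, motion classification, unwinding and binding
kinetics, smFRET state analysis, polymer elasticity fits, and repair-outcome
classification — together with synthetic-data generators that carry ground
truth. This vignette documents the models behind each stage, the parameters
that matter, the numerical choices made where the design was open, and what
the synthetic data do and do not establish about real recordings.

## The synthetic-data layer

Every analysis stage in the package can be exercised on data whose
generating parameters are known exactly, because the corresponding
generator stores them. The generators emulate the *data-generating models*
of the assays, at the acquisition constants of confocal line scanning
(100 nm per pixel, 0.997 s per line, 30 ms smFRET exposure):

- `simulate_kymograph()` renders fluorophores on a 1D DNA axis as Gaussian
  line profiles (PSF sigma default 1.5 px) over a constant background, with
  Poisson shot noise by default (optionally additive Gaussian read noise,
  emulating an EM-CCD, or both). Motion models: static; Brownian with
  Gaussian increments of variance `2·D·dt`, reflecting at the DNA ends
  (tethered-molecule geometry); and constant-velocity translocation that
  leaves the field. Photobleaching is an optional exponential truncation of
  emission, off by default. The PSF width and photon budget are free
  parameters — typical acquisition values, not measured ones.
- `simulate_distance_trace()` produces monotone burst–pause bead-distance
  paths: alternating segments of fixed duration whose burst rates are drawn
  from a truncated Gaussian, plus additive Gaussian noise.
- `simulate_decay_trace()` is the exponential fluorescence-loss model
  `I(t) = A·e^{−kt} + C` with Gaussian noise, time in minutes.
- `simulate_fret_trace()` is a two-state continuous-time Markov chain:
  the free (high-FRET) state ends at rate `k_bind`, the bound (low-FRET)
  state at `k_release`, so holding times are exponential with means
  `1/k_bind` (t_on) and `1/k_release` (t_off). Frames sample the state at
  the frame start; donor/acceptor intensities follow from E and a total
  photon budget.
- `simulate_fd_curve()` concatenates worm-like chain branches; each
  configured event adds `ΔLc` of contour length once the force reaches its
  trigger, the force dropping onto the next branch.
- `simulate_repair_reads()` emits amplicon reads that are unedited, carry a
  single 1–5 bp deletion spanning the cut site (NHEJ), a single >5 bp
  deletion placed at a repeat pair of the reference so the junction carries
  ≥2 bp microhomology (MMEJ; the generator searches the reference for such
  repeat pairs itself), or exactly the three donor substitutions (SSTR).

What the generators deliberately do not model: fluorophore blinking and
other photophysics beyond bleaching, 2D camera frames, drift, sequencing
errors beyond substitutions, and instrument-specific file formats. Passing
tests on this synthetic data therefore establishes estimator correctness
under the stated models — recovery of known rates, exponents and class
labels — not robustness to every artefact of real recordings.

Determinism is part of the contract: identical seed and configuration give
bit-identical output, with the caller's RNG state left untouched.

## Tracking

Localization follows the three-frame-window scheme: the profiles of frames
`f−1, f, f+1` are averaged (the window degrades to two frames at the
sequence edges so the first and last frames remain usable) and each
candidate peak is fitted with `offset + A·exp(−(p−μ)²/2σ²)` over a ±5 px
window. Averaging, rather than a joint fit across the three frames, was
chosen for simplicity and robustness; for a particle moving at `v` the
symmetric window leaves the interior-frame centroid unbiased. Candidates
are pixels brighter than `median + 3·MAD` of the averaged profile
(a robust default; the threshold multiplier is `detect_params(threshold_k=)`),
separated by ≥3 px. Non-convergent fits are dropped. Because two candidates
occasionally converge onto the same emitter, converged fits closer than the
minimum separation are deduplicated, keeping the brightest — without this,
duplicated localizations capture links and fragment tracks.

Coordinates: pixel indices are 0-based, position `= μ · pixel_size` nm,
and frame `f` (1-based in R) is at time `(f−1)·line_time`.

Linking is greedy nearest-neighbour: a link needs displacement
≤ `max_step` (default 300 nm) and frame gap ≤ `max_gap`; the smallest
displacement wins and losers start new tracks. Unlinked singletons
(typically shot-noise blips) are dropped below `min_length = 2`.

## Motion analysis

`compute_msd()` evaluates the defining sum exactly — the test suite checks
it against a literal double loop. The power-law fit is linear least squares
on the log–log curve over lags `1..⌈0.25·N⌉`; short lags carry the best
statistics, and 0.25 is the conventional compromise between bias and
variance (the fit range is a parameter). Exponent α ≤ 1 is classified
diffusive, α > 1 superdiffusive; α = 1 sits on the diffusive side.
An identically zero MSD (constant trajectory) has no defined exponent and
is flagged `static` rather than forced through the log fit.

`estimate_velocity()` smooths with a Savitzky–Golay filter of window 51
frames and polynomial order 3 (the window follows the analysis convention
for these kymographs; the order is unstated there and 3 is the filter's
common default), then divides the summed absolute frame-to-frame
displacements by the trajectory time. Summing absolute displacements equals
the net displacement for unidirectional motion and is robust when the
direction wanders; this reading of "total route" is an interpretation and
is kept symmetric under axis flip and position offset.

`extract_stroke_rates()` differentiates the smoothed trace
(Savitzky–Golay, window 21 samples at 1 s sampling, order 3), labels
samples as moving when the derivative exceeds `pause_threshold`
(0.5 nm/s — half the smallest rates of interest, well above the derivative
noise after smoothing), merges runs shorter than 5 samples, and reports
**the median of the derivative within each run** as the segment rate. The
median rather than the mean is deliberate: threshold crossings extend each
run into the smoothing-blurred ramps at its boundaries, where the
derivative is between 0 and the plateau value, and the mean over the run is
biased low by roughly `dur/(dur + 0.7·window)`; the median sits on the
plateau as long as the run is longer than about twice the smoothing window.
The segment-rate distribution is then fitted with a 1- or 2-component
Gaussian mixture, selected by BIC (the natural criterion when "single or
double" is the stated choice); with fewer than three segments the mixture
stage reports a single component directly.

## Kinetics

The dwell-time estimator defaults to the censored-exponential MLE,
`tau = (Σ all durations) / (# uncensored dwells)`, which is bin-free,
handles recording-end truncation, and reduces exactly to the sample mean
when nothing is censored (an identity the tests assert). A histogram
variant — least squares of `N₀·e^{−t/tau}` on Freedman–Diaconis binned
counts — is retained because figure-style fits are often reported that
way; on n ≥ 500 samples the two agree within a few percent. Rates from
fluorescence-loss traces are fitted as `A·e^{−kt} + C` with
`minpack.lm::nlsLM`, reported in min⁻¹; a trace with no net decrease
returns `k = 0` with a flag instead of a forced fit.

`count_events()` counts tracks lasting at least `min_duration` per
molecule and flags tracks reaching the end of the recording as censored.
Durations include the final frame (`span + dt`); with the three-frame
detection window a track can start or end one frame beyond the true
emission interval, so recovered dwells match ground truth within about two
frames.

## smFRET

Efficiencies are `E = I_A/(I_D + I_A)`; zero-total frames are missing, not
zero. Population histograms average the first 10 frames of each trace into
one value and use left-closed bins of width 0.1 (E = 1.0 falls in the last
bin). Segmentation thresholds E — the threshold defaults to 0.5, or the
midpoint of the two mixture modes via `fret_threshold()` when the data
support a bimodal fit, since the original analysis does not state its
threshold — and merges runs shorter than `min_dwell = 2` frames to
suppress single-frame noise crossings. This filter is a deviation knob:
it also absorbs genuinely short dwells, which inflates the neighbouring
dwell means by the probability mass below two frames, so dwell-recovery
analyses should keep mean dwells well above the 30 ms frame time (the
package's own tests use dwells ≳ 100 frames). First and last intervals are
censored and excluded from exponential fits by default.

## Polymer elasticity

The worm-like chain uses the Marko–Siggia interpolation
`F = (kT/Lp)·[1/4·(1−z)⁻² − 1/4 + z]`, `z = x/Lc`, with Lp = 50 nm and
kT = 4.114 pN·nm defaults (dsDNA at room temperature; the original fits do
not state their constants). An extensible variant replaces `z` by
`z − F/S` (S = 1200 pN suggested for dsDNA above ~10 pN) and solves for F
self-consistently. A freely jointed chain with Kuhn length 1.5 nm and
S = 800 pN is provided as the standard ssDNA reference. One numerical
property worth knowing: the interpolation formula approaches the Hooke
line `(3kT/2Lp)·z` with a leading relative deviation of `z/2`, so
agreement is within 2% only up to `z ≈ 0.038` — at `z = 0.05` the formula
sits 2.7% above the Hooke line. That is a property of the formula itself,
not of the implementation.

Branch fitting leaves Lc as the only free parameter (golden-section
minimisation of the residual sum of squares, standard error from the
curvature at the optimum — a branch sampled only at low force is
insensitive to Lc and duly reports a wide error). Event detection scans
the curve in extension order with a running single-branch fit and opens a
new branch when a point's force residual exceeds `residual_threshold`
(default 2 pN, several times the typical force noise); residual
change-points were preferred over derivative spikes because they are
robust to noise. Branches shorter than 20 points merge into their
neighbour, which sets the method's resolution: two events closer in
extension than 20 samples are not separable, so curves should be sampled
densely (the tests use 1500–2000 points per curve). Loop sizes are
successive contour-length differences; negative differences are
non-physical and flagged but retained.

## Repair-outcome classification

Reads are aligned globally (affine gaps, nucleotide scoring +2/−3 with gap
open 5 and extend 2 — a protein matrix would be meaningless for DNA) in
both orientations, keeping the better score. Deletions are left-aligned to
a canonical placement before interval reporting, which makes the junction
microhomology — the longest prefix of the deleted segment repeated
immediately after the deletion — well defined regardless of where the
aligner placed the gap. Intervals are 1-based and closed, the native
convention of R and Biostrings. The outcome rules are: intact (no edits),
NHEJ (single 1–5 bp deletion), MMEJ (single >5 bp deletion with ≥2 bp
microhomology), SSTR (exactly the three donor substitutions, no indel).
The rules are silent on >5 bp deletions with <2 bp microhomology,
insertions, multiple indels and deletion+substitution compounds; all are
routed to `other` rather than guessing intent.

## Problem sizes and known limitations

The parameter-recovery analyses (tests and `scripts/acceptance.R`) use: 30
burst–pause traces of 450 s at 1 s sampling (bursts 60 s, pauses 30 s —
durations chosen as realistic for published unwinding traces and long
against the 21 s smoothing window); 10 kymographs of 300 frames for
velocity recovery at 14 nm/s; 500 exponential dwell draws per tau; 10
decay traces per stripping rate; and 1000 simulated reads for the
classifier. These sizes keep every analysis within minutes on one CPU
while holding stochastic recovery tolerances (2–10%).

Known limitations: tracking assumes well-separated particles (no overlap
resolution); linking is greedy, not globally optimal; the MSD fit assumes
a single motion regime per trajectory; stroke-rate segmentation needs
bursts longer than the smoothing window; the smFRET segmentation is a
threshold method, not an HMM, and inherits the min-dwell bias described
above; WLC fitting does not model composite ssDNA/dsDNA constructs; and
the repair classifier assumes pre-merged single-amplicon reads.
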