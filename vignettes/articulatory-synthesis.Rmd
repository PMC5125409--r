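---
title: "From multimodal speech recordings to a concatenative talking head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multimodal speech recordings to a concatenative talking head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artic)
```

## The problem

Animating the speech articulators of a virtual character by interpolating
between stored key frames cannot reproduce real articulation: parameter
trajectories measured on a speaker are strongly nonlinear in time, and the
tongue — largely occluded, yet informative for speech reading — is not
captured by facial key frames at all.  The alternative implemented here is
data-driven: record a speaker with electromagnetic articulography (EMA
coils on the tongue, 100 Hz) and optical motion capture (active markers on
the face and a rigid headset, 60 Hz), reduce the sensor trajectories to a
small set of articulatory parameters, cut the parameter trajectories into
diphones, and synthesize new utterances by unit selection and
concatenation.

`artic` implements that entire pipeline, together with a synthetic-data
generator that plants a known model and known trajectories so that every
stage can be validated against a recoverable truth — the original
recordings of any one speaker are not required to test the machinery.

## The guided-PCA articulatory model

The model is linear: a frame of stacked sensor coordinates \(p \in
\mathbb{R}^D\) is

\[ p \approx m + E\,\alpha, \qquad \alpha \in [-3, 3]^M , \]

with \(m\) the mean configuration, \(E\) the \(D \times M\) loading matrix
and \(\alpha\) the articulatory parameters.  Plain PCA would mix
articulators in every component; instead each parameter is extracted from
a designated landmark subset, in a fixed articulatory order (`jaw1`,
`tongue1`–`tongue4`, `lips1`–`lips3`, `jaw2`, `eyebrows1`):

1. take the first principal direction of the *current residual* restricted
   to the subset (jaw sensors; tongue body TB+TD; tongue tip TT; all lip
   sensors; lower lip; upper lip; eyebrows);
2. standardize the resulting score to unit variance;
3. regress *every* residual coordinate on the score — the whole-face
   loading, which is how a jaw parameter legitimately carries tongue
   motion ("the tongue rides on the jaw");
4. subtract the rank-one contribution and continue.

Scores are kept in standard-deviation units so the inversion box
\([-3,3]\) means \(\pm 3\,\mathrm{SD}\) for every parameter alike.  The
percentage of global variance removed at each step is the model's variance
accounting; `variance_report()` recomputes it on any frame set.  Jaw
extraction comes first because the jaw carries the tongue and lips;
within a repeated subset the order is the listed one (tongue-tip vertical
before horizontal).  Extraction order is configurable through
`extraction_scheme()` because no single ordering is canonical.

```{r fit, eval = FALSE}
truth <- make_ground_truth_model(ground_truth_spec(seed = 42))
X <- simulate_model_frames(truth, 20000, seed = 42)
model <- fit_guided_pca(prune_frames(X, min_dist = 1.0), truth$scheme)
summary(model)
```

Before fitting, near-duplicate frames are removed by greedy vector
quantization (`prune_frames()`): a frame is kept iff its distance to every
previously kept frame is at least 1.0 mm.  Long steady stretches —
silences, holds — would otherwise dominate the covariance.  Greedy
first-come scanning against *all* kept frames was chosen over
nearest-previous-only because it is deterministic, order-stable, and
actually enforces the pairwise separation it claims.

## Preprocessing: one clock, one head frame

The two devices share a clock but not a rate.  The EMA stream is
anti-alias filtered (Butterworth, 6th order, 20 Hz cutoff, applied
forward–backward) and linearly interpolated onto the 60 Hz mocap
timestamps (`synchronize()`).  All filtering in the package is zero-phase:
causal filtering would lag articulation relative to the audio it must stay
synchronous with.  The stock forward–backward filter implementation
corrupts signal edges (it pads with zeros); the package's filter removes
the channel mean and mirror-pads (odd extension, 120 samples) so constants
pass through exactly and transients stay inside the padding.

Head pose is estimated per frame from the sensors that are rigid with the
skull (headset markers, nasion, tragi) by unweighted orthogonal
Procrustes (Kabsch) against a reference configuration, with one centre of
rotation for the whole recording found as the least-squares point that
minimizes residual translation magnitude.  Rotations are intrinsic
z–y–x Euler angles in degrees — a convention the package states explicitly
because none is standard.  Frames with fewer than three visible,
non-collinear rigid sensors are flagged and their pose interpolated.
`remove_rigid_motion()` then expresses every frame in the head frame;
apply-then-remove is an exact round trip, and re-estimating motion on the
corrected series yields identity.

## Inversion

Each frame is inverted independently — the per-frame objective is exactly
the model equation, and temporal structure is restored afterwards by the
explicit smoothing step.  For the face the objective is linear, so each
frame is a bounded linear least-squares problem over the *visible*
coordinates only:

\[ \hat\alpha = \arg\min_{\alpha \in [-3,3]^M}
   \lVert m + E\alpha - p \rVert_2 . \]

The solver is an active-set bounded least squares written for this package
(`bvls()`), with a \(10^{-12}\) ridge as a smallest-norm tie-break on
rank-deficient systems; it reproduces ordinary least squares whenever the
unconstrained optimum is interior, and is tested against an exhaustive
active-set oracle.  Missing sensors are excluded from the objective and
then *reconstructed* from the fitted parameters — the model's inter-sensor
covariance is what fills the gap.  Frames with fewer visible coordinates
than parameters are flagged and interpolated from their neighbours.

The headset objective is nonlinear through the rotations.  It is solved by
bounded quasi-Newton (L-BFGS-B) from the resting pose followed by a
Gauss–Newton polish with bounded linear steps; the polish converges
quadratically near the optimum and recovers planted scores to ~1e-12
when the motion model is well conditioned.

Inverted trajectories are smoothed with a 6th-order 8 Hz zero-phase
Butterworth filter.  Values the filter pushes outside the box are clipped
back to \([-3,3]\) rather than re-optimized — the excursions are at most a
few per cent of the box and re-optimizing would couple frames through the
filter, losing the per-frame semantics.

## Avatar retargeting

Face key frames become one-sided synthetic parameters: each key frame's
displacement from the neutral mesh is scaled so its RMS per-vertex
displacement is 1, and its activation ranges over \([0, +3]\) — key frames
are extreme poses, and a mesh has no physical pose "beyond neutral" in the
negative direction, hence one-sided rather than symmetric.

The avatar tongue has no articulatory key frames, so tongue postures are
fitted directly: for each quantized EMA posture, the bounded mixture of
the \(N = 9\) tongue key frames (weights in \([-10,10]\), evaluated on the
3 mesh vertices tied to TT, TB, TD) that best matches the sensors is found
with the same bounded solver; the mixture evaluated on all 50 vertices
gives the posture database.  Running the guided-PCA procedure on mesh
coordinates concatenated with sensor coordinates yields the 5-parameter
avatar tongue model (`jaw1`, `tongue1`–`tongue4`) whose loadings extend
over the full mesh.  The sensor-to-vertex correspondence is explicit
configuration, and per-parameter sign flips
(`align_parameter_signs()`) reconcile the avatar's and the speaker's
directions, which are not guaranteed to agree.  Speaker trajectories then
drive the avatar directly after sign alignment; no re-inversion through
the avatar model is performed.

## Diphones and synthesis

A diphone spans from the temporal midpoint of one phone to the midpoint of
the next — the steadiest part of each allophone, which is where
concatenation joins hurt least.  Midpoints map to frames as
\(\lfloor t \cdot 60 \rfloor\) with half-open \([start, end)\) ranges, so
a sentence's units partition its frames exactly and silence `"_"`
participates like any phone (boundary diphones `_w`, `m_`).

Synthesis selects one unit per target diphone through a trellis by dynamic
programming on the concatenation cost — the RMS parameter mismatch between
the last frame of one unit and the first frame of the next.  Units that
are contiguous in their source utterance join at zero cost.  Ties break
toward the lowest candidate index (stable in source-utterance order), so
reruns are identical.  An optional duration penalty
(`w_sel * |log(dur/target)|`) exists but defaults to off.  A target with
no unit falls back to units sharing its second phone, then to a 2-frame
linear bridge between its neighbours, with a warning — synthesis degrades
gracefully instead of failing.

Selected units are linearly time-warped to their target durations
(endpoints preserved exactly), then joined gaplessly: at each
non-contiguous join the gap \(\Delta\) (next first frame minus current
last frame, per parameter) is removed by adding \(\Delta \cdot i/T\) to
frame \(i = 1..T\) of the current unit, and the now-duplicated boundary
frame is dropped.  Because the ramp also moves a unit's *first* frame,
joins are processed from the last boundary backwards, so every processed
join is exact (below \(10^{-9}\)) after one pass.  The ramp is linear in
time, so within-unit second differences — the nonlinear shape of the
movement, which is the whole point of concatenative synthesis — are
preserved exactly.  Contiguous joins are genuine trajectory and are
concatenated untouched; this is also what makes a sentence resynthesized
from its own units reproduce its inverted trajectory.

```{r synth, eval = FALSE}
dict <- build_dictionary(corpus_entries)
out <- synthesize_trajectories(c("_", "w", "E", "l", "k", "@", "m", "_"),
                               durations, dict)
attr(out, "boundary_audit")
```

## What the generator emulates — and what it does not

`ground_truth_spec()` fixes the study conditions: 3 jaw + 8 lip + 6
eyebrow mocap sensors and a 4-marker headset at 60 Hz; TT/TB/TD tongue
coils plus nasion and both tragi at 100 Hz on a shared clock; 10 s
sessions; sensor noise 0.5 mm SD; slow sinusoidal head motion about a
fixed neck point (8 mm / 4° peak); 0.5 % missing samples.  The sensor
itemization is configurable because published hardware counts in this
literature are frequently internally inconsistent; the functional grouping
is what matters to the pipeline.

The planted model's per-parameter variance shares follow the 10-entry
profile of its articulatory-model inventory (13.40, 13.17, 4.83, 5.13,
5.69, 10.06, 0.93, 2.66, 2.04, 4.23 % — summing to 62.14 %), realized as
mutually orthogonal loading vectors on a total variance of 100 mm².  Three
constructions make the planted decomposition identifiable by the guided
extraction:

* jaw opening carries 70/20/10 % of its variance on jaw / tongue-body /
  tongue-tip coordinates — the jaw-carries-the-tongue coupling;
* when the tongue-tip *horizontal* parameter outweighs the vertical one,
  its excess variance (above 0.85× the vertical's) is carried on the
  tongue body, so the tip subset still yields vertical-before-horizontal
  in extraction order;
* the 37.86 % of variance not owned by named parameters lives in
  orthogonal nuisance directions confined to the landmark groups, each
  capped at 0.7× the weakest parameter extracted from its group so it can
  never win a subset PCA step.

`simulate_model_frames()` draws unit-variance scores and by default
*empirically whitens* them (centres, decorrelates, rescales), so the
sample variance accounting of a generated frame set equals the planted
profile by construction rather than only in expectation; recovery tests
can therefore demand near-exact agreement instead of statistical
tolerance.  Sentence simulation maps each SAMPA label to a fixed seeded
target posture in \([-2,2]^M\) (silence maps to neutral), holds targets
with raised-cosine transitions (at most 80 ms, at most half of each
adjacent phone) and low-pass filters at 8 Hz on a 300 Hz master grid —
divisible by both stream rates, so both streams sample the same underlying
trajectory exactly.

What passing these tests shows is that the *machinery* — synchronization,
head correction, extraction, inversion, selection, concatenation — is
correct.  What it does not show: the generator's articulation is linear in
its parameters by construction, its phone targets are random rather than
phonetic, coarticulation beyond the transition ramp is absent, and sensor
noise is i.i.d. Gaussian.  Results on real recordings additionally depend
on how well a linear model fits a real vocal tract, which no synthetic
test can certify.

## Numerical choices and problem sizes

* Variance uses the \(n-1\) denominator throughout; fit and report agree
  to 1e-9.
* Subset principal directions get a deterministic sign (largest-magnitude
  coordinate positive), then any configured per-parameter flip.
* BVLS: convergence tolerance 1e-10, ridge 1e-12; head inversion:
  L-BFGS-B then Gauss–Newton, step tolerance 1e-11.
* Frame mapping uses floor with a 1e-9 guard; frame counts use round-half-
  away-from-zero, so results do not depend on banker's rounding.
* Degenerate inputs fail loudly and early: zero-variance subsets name the
  step, non-monotone segmentations name the interval, schema mismatches
  name the file.
* The validation suite runs on deliberately modest sizes — 20,000-frame
  recovery experiments, corpora of a few hundred sentences, trellises up
  to 5×4 — chosen so the full suite completes in about a minute while
  still separating correct from incorrect behaviour by orders of
  magnitude.

## Known limitations

* The model is linear per frame; genuinely nonlinear articulatory
  geometry (tongue compression against the palate, lip contact) is outside
  its span and shows up as reconstruction residual.
* Gap handling is linear interpolation; dropouts longer than the
  articulation timescale are reconstructed from the model, not imputed
  from dynamics.
* The duration warp is linear in time; no phone-internal duration model is
  attempted.
* Eyebrow motion is carried through synthesis like any parameter; driving
  it from prosody instead would require information the phone+duration
  input does not contain.
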