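---
title: "Classifying the five gaits of the Icelandic horse from phone sensors"
author: "EquiGait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the five gaits of the Icelandic horse from phone sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EquiGait)
```

## The problem

Icelandic horses perform up to five gaits: walk, trot, tölt, canter and
flying pace. Telling them apart automatically matters to riders and
breeders — tölt and flying pace are the breed's defining gaits — and the
sensors needed are already in every rider's pocket. A phone logs 3-axis
acceleration, 3-axis angular velocity, an orientation quaternion and a
1 Hz GPS fix. EquiGait implements the full pipeline from such logs to a
per-moment gait label:

1. **Frames.** The device-frame signal is rotated into the world frame
   using the logged quaternion, and optionally into the *horse frame*,
   whose x axis follows the direction of travel. The heading comes from
   consecutive GPS fixes and is circularly smoothed over 1 s.
2. **Dataset.** Gait labels arrive as variable-rate events from a
   limb-mounted labelling system (one label per hoof-on, 4–10 Hz). They
   become a piecewise-constant timeline; the signal is cut into 1.5 s
   windows with 90 % overlap, discarding windows within 2 s of a gait
   switch.
3. **Models.** Four sequence architectures — LSTM, bidirectional LSTM,
   GRU (single recurrent layer) and a 4-layer dilated 1-D CNN — map each
   window to a probability over the five gaits.
4. **Smoothing.** Sequential predictions are refined by exponential
   weight decay, $z_0 = h_0$, $z_t = (z_{t-1} + h_t)/2$, followed by a
   sliding majority vote of width 7 over $g_t = \arg\max z_t$.
5. **Metrics.** Micro accuracy (diagonal over total of the confusion
   matrix), per-gait one-vs-all accuracy, macro averages, and
   leave-one-horse-out cross-validation.
6. **Agreement.** An independent validation protocol compares the
   labelling system against a panel of four judges with exclusion
   periods around transitions.

Because no public corpus of pocket-phone recordings of five-gaited horses
exists, the package also contains a **simulator** that generates complete
ride bundles — IMU, GPS, label events, judge streams — from per-gait
footfall schedules, so every stage is testable end to end.

## Conventions

* World frame: x = east, y = north, z = up. Horse frame: x = forward,
  y = left, z = vertical. Both right-handed.
* Quaternions are Hamilton, scalar-first (w, x, y, z), and rotate device
  vectors into the world frame. Non-unit quaternions are rejected rather
  than silently normalized: a drifting norm means something upstream is
  broken, and hiding it would corrupt every later rotation.
* Heading is degrees in [0, 360), clockwise from geographic north. We fix
  geographic north for both the quaternion yaw reference and the GPS
  bearing; a real phone's quaternion may be magnetically referenced and
  differ by the local declination, which would appear as a constant yaw
  offset in the horse frame.
* Units: m/s² for acceleration (gravity is **not** removed), deg/s for
  angular velocity, seconds from ride start for time.
* Gait codes are fixed: Walk 0, Trot 1, Tolt 2, Canter 3, FlyingPace 4.
  Argmax ties break toward the lowest code, deterministically.

## Preprocessing choices

**Resampling** uses plain linear interpolation onto a uniform grid, with
no anti-aliasing filter. Downsampling from phone rates (50–1200 Hz) to
50 Hz has little effect on gait information, and exact interpolation
semantics make the operation testable against closed forms (a linear
ramp resamples exactly; a 1 Hz sine at 200 Hz resamples to 50 Hz within
10⁻³ of the analytic values). Irregular input timestamps are accepted;
uniformity is only guaranteed after `resampleTrace()`.

**Heading smoothing** unwraps the bearing sequence left-to-right (an
element differing from its corrected predecessor by more than 180° is
replaced by its period-complementary value; a difference of exactly 180°
is left alone), takes a centered 1 s moving average, and wraps back to
[0, 360). Between 1 Hz fixes the heading is held piecewise-constant when
rotating 50 Hz samples — the data provide no basis for interpolating it
faster than the GPS rate. A stationary horse gives no bearing; such
intervals inherit the previous defined heading.

**Segmentation** snaps candidate start times to the sample grid; the
step is `(1 − overlap) · window` rounded to a whole number of samples,
so segment counts are deterministic and an independent brute-force
enumerator reproduces them exactly (57 windows for a 10 s single-gait
trace at window 1.5 s / overlap 0.9; 42 for a 10 s trace with a switch
at 5 s, window 1 s, exclusion 2 s). Within flying-pace intervals the
step is 20 ms regardless of window size — dense stepping compensates the
scarcity of that gait. The exclusion test is strict: a switch exactly
`exclusion` seconds from the window's edge does not discard it. A
segment's label is that of its single covering interval; no per-sample
vote is needed because exclusion guarantees uniformity.

**Splits** are by horse: held-out horses contribute all their segments
to the test set (default ids 1, 2, 8, 9, 11), and the remaining segments
are shuffled 85/15 into training and validation *at the segment level*.
With 90 % overlap, neighbouring segments share samples, so a per-segment
validation split leaks information between train and validation; we keep
it because it mirrors the original protocol, and generalization is
measured on held-out horses, which the leak cannot touch.

## The models and their training engine

All four architectures feed a 128-unit linear layer (ReLU) and a 5-class
softmax. The LSTM and GRU have a single 200-unit recurrent layer; the
bidirectional LSTM has 200 units per direction (400 total), keeping
parameter parity with the LSTM. The classifier reads the final hidden
state (concatenated directions for the Bi-LSTM). The CNN has four
layers, kernel 3, dilations 12/8/4/1, channels $n_i$→16→32→64→128, valid
padding, global average pooling over time before the head. Training is
Adam (step size 10⁻³), cross-entropy, 20 epochs, batch 64, early
stopping on validation loss with patience 3 and best-checkpoint restore.
Input channels are standardized per channel with training-set statistics
(m/s² and deg/s scales differ by an order of magnitude; the statistics
travel with the model).

No deep-learning framework is attached: the forward and backward passes
and the Adam update are implemented directly on base matrix operations.
This keeps the dependency surface minimal and the arithmetic inspectable;
correctness rests on finite-difference gradient checks for every
architecture in the test suite (relative error below 10⁻⁵ on random
probes of every parameter tensor). At the window lengths used here
(75 samples) the vectorized batch updates train the small-profile models
in seconds per epoch on one CPU.

Where experiments need to run at desk scale, we use a *small profile* —
64 recurrent units, 10 epochs — which preserves the architecture and
training procedure.

## Smoothing

Exponential decay makes each output a convex combination of the current
and all previous network outputs with geometrically decaying weights
(1/2, 1/4, …), so rows remain on the probability simplex. The majority
window is centered and truncated at sequence edges (no labels are
invented at the boundaries); a tie for the most common label keeps the
center label. The method is offline by construction — it uses future
predictions — matching its use on sequential test rides rather than live
deployment. On streams whose errors are isolated single steps at rate
below 1/7, the pipeline strictly reduces the error rate; on clean
constant-gait streams it changes nothing.

## Metrics and the macro-average arithmetic

One-vs-all accuracy counts true negatives, so a gait a horse never
performed can still score; we mark a gait *missing* for a horse when the
horse has no truth rows for it, and macro averages are taken over
present values only. The bundled reference tables (per-horse one-vs-all
accuracies of a Bi-LSTM under leave-one-horse-out cross-validation, and
per-horse seconds of data per gait) reproduce the published macro row —
walk 0.97, trot 0.82, tölt 0.89, canter 0.94, overall 0.91 — only under
one further rule: a horse whose contribution to a gait is zero seconds
is excluded from that gait's macro even when a (false-positive-driven)
value was reported for it. The trot column demonstrates this: the naive
mean over all printed values gives 0.76, not 0.82; excluding the single
zero-trot horse gives 0.8186 ≈ 0.82. The flying-pace macro is the one
cell this rule does not explain (its three entries average 0.9067, not
the printed 0.93); we report the computed value.

## The agreement protocol

Judges click a label when the gait changes; the label holds until the
next click (click-and-hold). Every 250 ms the held labels are polled and
the strict-plurality winner becomes the consensus; any tie is "no
majority" (−2), and the stretch before a judge's first click is "not
classified" (−1). The labelling system's events pass through a 1 s
window sliding in 0.5 s steps; each window's modal label is stamped at
the window center, and times are re-based so the timeline starts at 0 s.
Prediction–truth pairs with truth −1/−2 are discarded, and exclusion
radii around transitions of either series (identified as the change
points of each) remove cases near transitions — inclusively, so a 1000 ms
radius removes a case exactly 1 s from a transition. Halt is kept as a
truth class here (coded 0), distinct from the model pipeline where
standing is discarded; left and right canter remain distinct classes
throughout the protocol.

Aggregation polls the judges' *held label at each tick* rather than
integrating clicks within the tick; with click-and-hold streams the two
readings differ only when a judge clicks twice within 250 ms.

## What the simulator does and does not emulate

Per-gait profiles define footfall phases (walk/tölt: even four-beat
lateral sequence; trot: diagonal pairs; flying pace: lateral pairs;
canter: three-beat), duty factor, stride-frequency band and impulse
amplitudes. Each hoof-on contributes a raised-cosine bump to vertical
acceleration, a side-signed bump to lateral acceleration and a zero-mean
couplet longitudinally; trunk roll/pitch/yaw rates oscillate at the beat
and stride frequencies. Gravity sits on the vertical channel. The
device-frame output rotates the horse-frame truth through the heading and
a fixed random device orientation, then adds Gaussian noise (0.3 m/s²,
3 deg/s by default). These choices preserve what a classifier exploits —
beat count, beat frequency, duty, lateral symmetry — and make the
dominant vertical spectral peak equal the beat rate, which the tests
assert. Walk and tölt intentionally share the four-beat footfall order
and differ in tempo, duty and amplitude, as they do in the field; trot
and flying pace share the two-beat count and differ in their lateral
signature, which is what makes the horse frame genuinely more
informative than the world frame in the end-to-end experiment.

Not modelled: soft-tissue and clothing dynamics of a pocket-carried
phone, rider technique (sitting/rising/two-point), surface effects,
within-bout tempo drift, and any biomechanically validated kinematics.
Amplitudes are free parameters of the generator, not claims about real
horses. A model that separates the synthetic gaits perfectly therefore
shows the pipeline's machinery is correct — not that real-world
accuracy will match.

The 17-horse corpus preset mirrors the reference gait-mix table: bout
durations are proportional to each horse's per-gait seconds, clamped to
6–20 s (so every available gait yields segments at desk scale), and only
the three horses that paced in the reference data pace here. Problem
sizes in the tests and the acceptance script — 17 rides of 18–80 s,
roughly 2 500 segments, small-profile Bi-LSTM — were chosen once to keep
a full run around a minute on one CPU while leaving the study's window,
overlap and exclusion parameters untouched.

## Numerical and degenerate-input policy

* Errors are classed conditions (`eqFormatError`, `eqVocabularyError`,
  `eqShapeError`, …) so callers can distinguish failure modes.
* A window longer than the trace yields an empty segment set, not an
  error; an empty confusion matrix, an all-missing macro, or a
  single-sample resample input are errors.
* Sequential unwrap corrects each element against its already-corrected
  predecessor; exactly-180° differences are not unwrapped.
* The simulator deduplicates simultaneous hoof-on label events
  (diagonal or lateral pairs strike together) to one event per beat,
  keeping label logs strictly time-ordered.
* Ten-label vocabulary: the labelling system's documented mapping table
  lists nine strings; we additionally accept "Halt" as a synonym of
  "Standing" to close the set at ten.
* All randomness flows through explicit seeds: a ride plan's seed fixes
  the bundle byte-for-byte, and a training config's seed fixes the final
  weights bitwise.

## Known limitations

* Synthetic separability is optimistic; see above.
* The per-segment validation split leaks across overlapping windows
  (inherited from the protocol it mirrors).
* Heading is undefined at rest and coarse at 1 Hz; sharp turns alias
  into the horse frame between fixes.
* The offline majority vote can *lower* accuracy around genuine gait
  switches on otherwise-perfect streams, since it delays the reported
  transition; its benefit is specific to isolated spurious flips.
* Sensor-fusion orientation estimation is out of scope: world-frame
  rotation requires the logged quaternion.
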