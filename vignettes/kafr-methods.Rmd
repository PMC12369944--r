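---
title: "Kinematics-adaptive key-frame selection: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics-adaptive key-frame selection: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kafr)
```

## The problem

Operative video of robotic procedures runs from thirty minutes to several
hours. Phase-segmentation models that consume every extracted frame spend
most of their capacity on redundant, nearly identical frames — particularly
during idle stretches — while the clinically informative moments are brief
bursts of instrument motion. `kafr` implements a content-aware alternative
to uniform frame sampling: it tracks the centroids of detected surgical
tool parts and retains a frame only when the accumulated kinematic change
since the last retained frame crosses a threshold. Because only tool
pixels matter, the selection is invariant to the moving-organ background
that defeats whole-image similarity measures.

## The selection model

Let $s$ index the tracked channels (a channel is one `(hand, part)`
combination, e.g. the right jaws) and $x_i$ the frame at index $i$. Frame
pairs are scanned greedily from the first frame: with anchor $i$ and
candidate $j$, the displacement accumulation is

$$z_d(i,j) \;=\; \sum_{s}\ \sum_{k=i+1}^{j} \lVert s(x_i) - s(x_k)\rVert,$$

the sum over channels and intermediate frames of the Euclidean distance
between the channel's centroid at the anchor and at frame $k$. The pair
$(i,j)$ is declared a *key pair* at the first $j$ where the similarity
transform $f(z) = 1/(z+\epsilon)^{\beta}$ drops to the threshold $d$ —
equivalently, where $z \ge z^\* = d^{-1/\beta}-\epsilon$. Frames strictly
between $i$ and $j$ are discarded as similar, $j$ becomes the next anchor,
and the scan continues to the last frame. Both pair members are retained,
as are the first and last frames, so every video keeps at least two frames.

The second selector replaces displacement with velocity variation,

$$z_v(i,j) \;=\; \sum_{s}\ \sum_{k=i+1}^{j} \lVert V_s(x_i) - V_s(x_k)\rVert,$$

where $V_s$ is the channel's backward-difference velocity. Displacement
accumulation fires on sustained translation; velocity variation fires on
changes of motion — accelerations and reversals characteristic of
deliberate surgical maneuvers.

Two literal-form consequences are worth stating plainly:

* **Anchor-relative, not path length.** $z_d$ sums distances *from the
  anchor*, not along the path. A tool that oscillates tightly around the
  anchor position accumulates slowly even while moving; this is the
  implemented, literal form. One visible consequence: on constant-speed
  motion $z_d(i,i+k) \approx v\,k(k+1)/2$, so the inter-key-frame gap
  scales as $1/\sqrt{v}$, not $1/v$ — doubling tool speed shrinks the gap
  by about $\sqrt 2$.
* **Absence contributes zero.** A term is dropped whenever the channel is
  absent (or its velocity undefined) at either endpoint. A tool that slows
  down or disappears therefore produces fewer key frames, which matches
  the observed behavior of the method on real procedures.

### Dead anchors

The velocity at a channel's first present frame is undefined (there is no
previous present frame to difference against). Taken literally, the
contribute-zero rule would make the very first anchor of the
velocity-variation scan permanently sterile: nothing ever accumulates,
no pair closes, and every video degenerates to `{first, last}` regardless
of the threshold — which would make calibrated 10–20% retention
impossible. The scan therefore silently re-anchors away from any *dead*
anchor (one with no present channel, or no defined velocity) to the next
frame with usable data. Pair closing takes precedence, so a zero
threshold still retains every frame. The accumulation-sum functions
themselves keep the literal contribute-zero semantics.

## Threshold calibration

$\beta$ and $\epsilon$ are never needed numerically: selection is
implemented on the raw $z$ scale, and a similarity-scale threshold is
converted through the strictly monotone $f$. Rather than choosing $d$
directly, the threshold is calibrated so that a desired *retention
fraction* of the training frames survives (`calibrate_threshold()`):
bisection over $z^\*$, exploiting that larger thresholds close fewer
pairs. Calibration is global over the supplied pool of videos — one
$z^\*$ for all — matching the convention of choosing a percentage of the
total training samples; per-video calibration is simply calibration on a
pool of one.

The retained fraction is a step function of $z^\*$, so a tolerance is
required; the default `tol = 0.005` on the fraction. When the step
function jumps over the target the closest achievable fraction from above
is returned with a warning; targets below the floor of
$2/n_{\text{frames}}$ per video raise an error reporting the achievable
range.

**On monotonicity.** "Larger $z^\*$, fewer retained frames" is exact for
smooth, continuously present motion (we verify it on a 50-point grid over
20 simulated procedures, both selectors), but it is *not* a theorem for
the greedy chain: from a later anchor the accumulation can run faster and
close earlier, so jagged random-walk motion or occlusion dropout can
realign the chain and add an isolated frame or two at a larger threshold.
Bisection needs only the global trend and is unaffected in practice.

## Ingestion conventions

Detections (YOLO-style per-frame text or JSON-lines) are filtered to
confidence strictly greater than 0.5, duplicate instrument ids are merged
(default map `3→2, 4→1, 5→0`, two needle drivers under one identity), and
each detection's centroid — box center, or area-weighted (shoelace)
centroid for polygons — is assigned to the left or right hand by which
half of the frame it falls in, with the exact midline going right (a
deterministic tie rule; none is prescribed by convention). Channels are
keyed per frame by `(hand, part)`, never by raw tracker ids, which are
reassigned after occlusions. Competing detections for one channel in one
frame resolve by highest confidence, then larger box area. The part modes
mirror the object-count naming used for needle-driver tracking: `one` =
right jaws; `two` = both jaws; `four` = jaws + wrists; `six` = jaws +
wrists + shafts.

Velocity uses the backward difference to the previous *present* frame,
scaled by true elapsed time, and is declared undefined across presence
gaps longer than `max_gap = 3` frames (0.5 s at 6 fps) — bridging longer
occlusions would manufacture teleport-speed spikes.

## Baselines

Uniform sampling keeps every $k$-th frame with $k = \mathrm{round}(1/f)$.
The pixel-MSE selector reuses the identical greedy anchor scan with the
dissimilarity functional swapped to the mean squared intensity difference
between the anchor and the current frame (anchor-to-current is our
structural-parity choice; whether published MSE baselines compared
consecutive frames instead is not documented). RGB is reduced to
luminance (0.299/0.587/0.114) first. Because every pixel votes,
background perturbations displace the MSE selection while leaving the
kinematic selection untouched — the property the noise-robustness
acceptance test formalizes: with static tools and background noise
$\sigma = 20$, expected inter-frame MSE is $\approx 2\sigma^2$ on the
noise-affected pixels, so any threshold below that floor retains
everything, while $z_d \equiv 0$ throughout.

## Downstream phase pipeline

* **Rebalancing** (`balance_phase_frames()`): each phase contributes
  exactly `target_n = 250` frames — longer phases are evenly subsampled,
  shorter ones oversampled by verbatim cyclic duplication at evenly
  spaced insertion points via the deterministic index map
  $\lfloor k\,n/\text{target}\rfloor + 1$. The reported `dup` equals
  $\sum_{\text{phases}} \max(0, \text{target} - n)$.
* **Positional encoding**: standard sinusoidal embedding of the frame
  index, components $\sin(p/10000^{2k/\text{dim}})$ and
  $\cos(p/10000^{2k/\text{dim}})$.
* **Loss**: cross-entropy plus $\lambda \cdot$ EMD, where the EMD over the
  ordered phase axis reduces to the $L_1$ distance between cumulative
  distributions with unit ground metric. Phases are ordinal in time, so
  the EMD term penalizes confusions proportionally to their phase
  distance. The original training weight $\lambda$ is not documented;
  the default is 1 and it is configurable.
* **Temporal smoothing**: 31-frame centered majority vote, truncated at
  boundaries, ties keeping the original prediction. (A 31-frame window at
  6 fps spans about 5 s; descriptions of the window as "15 seconds before
  and after" are inconsistent with that extraction rate, so the window is
  parameterized in samples and no time span is asserted.)
* **Ensembling**: per-frame mean of two streams' class probabilities,
  renormalized, argmax with ties to the lower class index.
* **Metrics**: accuracy as correct/total; per-class F1 with macro
  averaging by default (sensitive to rare phases such as enterotomy;
  weighted averaging is available behind a flag, since the published
  convention is not stated); improvements reported as relative change
  $(\text{new}-\text{old})/\text{old}\times 100$.

The classifier between rebalancing and smoothing is a pluggable external
command (`classifier_cmd` in `run_config()`); the shipped
nearest-centroid-on-kinematic-features model exists only so the pipeline
can be exercised end to end, and its accuracy on synthetic procedures is
a smoke floor, not a claim about any published network.

## The synthetic world

No public dataset carries these procedures, so every module is exercised
against a built-in simulator whose defaults state the emulated world
once:

| parameter | default | rationale |
|---|---|---|
| fps | 6 | common extraction rate (gcd of 24/30 fps cameras) |
| frame size | 300 × 300 px | the training image size convention |
| phases | 7 (labels 0–6, 0 = idle) | six tasks + idle |
| frames/phase | 120–360 | 20–60 s at 6 fps; scaled down in some tests for runtime only |
| task speeds | 18–42 px/s, idle 1 px/s | distinct regimes per phase; idle is near-motionless |
| oscillation period | 3 s | cyclic suturing-like gesture |
| drift | OU, step 0.3 px, τ = 2 s | slow repositioning of the gesture center |
| dropout | 0.05 i.i.d. (burst mode optional) | detector misses / occlusion |
| measurement noise | 1 px | centroid jitter |

Each channel moves on a circular path at constant tangential speed
(radius $v/\omega$, scaled 1/0.75/0.5 for jaw/wrist/shaft), its center
drifting by a mean-reverting walk, left and right hands clamped to their
screen halves. The simulator stores both the observed tracks (noise +
dropout) and the noiseless ground truth, including the *realized*
per-phase mean speed computed by the same backward-difference rule —
parameter-recovery tests compare against the realized value so that
chord-versus-arc discretization (about 0.5% at these defaults) is not
mistaken for a pipeline defect.

What the simulator does **not** emulate: camera motion (a stationary
endoscope is assumed), tools crossing the midline, deformable-organ
backgrounds (rendering uses flat background + Gaussian noise), detector
confidence correlated with image content, and identity switches between
visually identical tools. A green test on this world therefore
establishes the algorithmic contracts — selection, calibration,
invariances, metric arithmetic — not clinical performance.

## Numerical and degenerate-input choices

* Selection thresholds live on the raw $z$ scale; $\beta = 1$,
  $\epsilon = 10^{-8}$ matter only when converting a user-supplied
  $d$-scale threshold.
* Cross-entropy guards $\log 0$ with $10^{-12}$; probability rows must
  sum to 1 within $10^{-6}$.
* A zero-area polygon falls back to the vertex mean; self-intersecting
  polygons are rejected (their shoelace centroid is not the centroid of
  any region).
* Two-frame videos retain both frames at any threshold; calibration
  targets below the achievable floor error out rather than silently
  under-delivering.
* All randomness — simulation, rendering, detection emission — flows from
  integer seeds; reruns are byte-identical.

## Known limitations

The selectors assume tools are detected at all: a fully occluded channel
never triggers key frames, so long occlusions degrade selection density
(the absence-contributes-zero rule makes this graceful, not catastrophic).
Retention calibrated globally can be locally uneven across videos with
very different motion statistics. The monotonicity caveat above applies
when motion is dominated by frame-to-frame jitter. And the reference
classifier is deliberately simplistic; any serious use plugs a real model
into the external-command hook.
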