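---
title: "Methods: motion-based surgical tool classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-based surgical tool classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`toolmotion` classifies hand-held surgical tools whose appearance is too
similar for per-frame recognition — scissors versus needle holders — from
the motion of the operating hand. The pipeline has three phases with a
deliberate division of labour:

1. **Localization** produces per-frame axis-aligned boxes labelled `hand`
   or `tool` with confidence scores. The tool *category* is not decided
   here; "tool" is a single detection class. The package treats the
   detector as an exchangeable backend: detections arrive either as a
   data.frame/JSON file produced elsewhere, or from the built-in oracle
   detector over synthetic ground truth.
2. **Selection** associates each tool with the single hand operating it by
   the overlap ratio (intersection over union) of their boxes, taking the
   argmax over candidate hands. IoU is a good association statistic here
   because a hand gripping a tool must share image support with it.
3. **Classification** crops the selected hand from `T` consecutive frames,
   resizes each crop to 252×252, extracts a 128-d visual feature per frame,
   aggregates the sequence causally with a single-layer LSTM, and emits one
   probability per timestep through an MLP head with a sigmoid output unit.
   Training uses class-weighted binary cross-entropy.

The assumptions this rests on: the video is egocentric at a fixed frame
rate (25 fps), so hand motion is observable and roughly scale-stable; the
tool is held (hand and tool boxes overlap whenever the tool is operated);
and the discriminative signal has a time scale of roughly two seconds — a
cutting stroke or one suturing wrist rotation completes within the default
window.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tFrames` (T) | 50 | frames | 2 s at 25 fps; one full gesture. Sweepable via `sweepWindowLength()`. |
| crop size | 252×252 | px | fixed input contract of the feature extractor. |
| `pad` | 0 | fraction of longer box side | crop exactly the hand box; padding is exposed because the tool tip may lie outside it. |
| `featureDim` | 128 | – | per-frame feature dimension ψ. |
| `recurrentHidden` | 128 | – | LSTM output size; tanh cell activation. |
| `dropout` | 0.5 | prob. | on the projected features (the LSTM/head inputs), training only. |
| `learningRate` | 1e-3 | – | Adam. |
| `batchSize` | 5 | sequences | small batches; 60 updates/epoch at the default scale. |
| `epochs` | 15 | – | training loss is flat by then at the default scale (see `lossHistory`). |
| `classWeights` | inverse frequency | – | `w_c = N/(K n_c)`, count-normalized so the loss scale is unchanged. |
| `fusion` | mean | – | how `p_1..p_T` become one decision; `last` and `max` available. |
| `stride` | 25 | frames | window cutting offset at inference; training additionally resamples fragment offsets per epoch where runs exceed T. |

Selection has one rule worth stating precisely: when no hand overlaps the
tool (all ratios zero) **no** hand is selected and the frame breaks the
sequence — an argmax over an all-zero set would be arbitrary, and a
non-overlapping hand cannot be operating the tool. Exact ratio ties (which
have measure zero for real detections but occur in tests) break by higher
detection score, then by list position. Each tool is resolved
independently, so one hand may legitimately serve two tools.

## The feature extractor

The reference design for the per-frame extractor in this family of models
is a pretrained deep CNN. This package's built-in extractors are
deliberately small so that the full pipeline trains in minutes on one CPU,
while keeping the 128-d feature contract and the property that matters for
the method: **spatial layout must survive into the features.** The class
signal in a hand crop is *where and at what angle* the tool shaft sits
relative to the hand over time; features that are globally pooled over
space are translation-invariant and would erase it. The default
(`smallcnn`) therefore uses a fixed, seeded bank of eight oriented 3×3
filters (ReLU) whose responses are average-pooled onto a 7×7 spatial grid,
alongside the three color planes pooled onto a 9×9 grid — a 635-d
descriptor that preserves coarse geometry and orientation energy. The
learnable stage of the extractor is a linear projection from the descriptor
to the 128-d feature ψ, trained end-to-end with the LSTM and the head (the
fixed descriptor stage makes per-frame features cacheable, which is what
keeps the experiment fast). A cheaper purely photometric backend (`pool`)
and a flatten-plus-projection backend for oracle tests (`flatproj`) sit
behind the same contract.

The LSTM, head, exact backpropagation through all three stages, and the
Adam optimizer are implemented in the package in vectorized base R; the
gradients are verified against finite differences in the test suite.

## The synthetic scene generator

The generator exists to make the method's central claim testable without
surgical footage: *two classes that cannot be told apart from any single
frame, but separate cleanly from motion.* Each scene renders one target
hand (ellipse sprite) holding an elongated tool sprite over a muted
textured background, plus up to three distractor hands drifting far from
the action:

- **oscillate** (scissors): the rigid hand+tool pair translates
  sinusoidally along a random axis, amplitude 12 px, period 12 frames — a
  cutting stroke.
- **rotate** (needle holders): the hand sweeps a circle of radius 48 px
  about the fixed tool tip, period 40 frames — the suturing wrist
  rotation.

Both periods complete within one 50-frame window. Sprites, colors, sizes
and the hand-to-tip distance are identical across classes, and the
per-frame appearance distributions are checked for indistinguishability in
the tests (KS test on crop statistics across classes). Distractor hands are
parked at least 160 px from the tool anchor so their boxes never overlap
the tool box (IoU ≤ 0.05 asserted in tests), making the selection ground
truth unambiguous; `makeScene(..., adversarial = TRUE)` lifts that
guarantee for stress testing. The oracle detector perturbs truth boxes with
corner jitter N(0, σ²), drops boxes with a miss probability, adds
Poisson-distributed spurious low-score boxes, and perturbs scores; with all
noise at zero its output *is* the ground truth, which is what makes the
noise-free end-to-end selection audit exact rather than statistical.

**Study conditions.** The default experiment (`runConfig()`) uses 400
scenes of 55 frames at 480×270 px — one T=50 window per scene — split 75/25
at the scene level into 300 training and 100 test windows. One window per
scene is a deliberate choice: every clip carries its own background,
geometry and motion phase, emulating clips drawn from different surgeries.
Early in development we used few long scenes with many windows each; the
classifier then memorized scene-specific backgrounds (training loss near
zero, held-out AUC at chance), which is the synthetic analogue of
overfitting to a surgery's operating field rather than learning the
gesture. Scene diversity, not regularization strength, is what fixes this,
and the default conditions encode that lesson. The window-length sweep
needs longer runs (`framesPerScene ≥ max(T)`), e.g. 125 frames for
T ∈ {25, 50, 100}.

**What the generator does not emulate:** photorealistic hands and tools,
glove color variation, occlusion of the hand by the surgical field, camera
shake and motion blur, gradual tool hand-overs, or detector failure modes
correlated with image content (the oracle's noise is i.i.d.). Passing the
synthetic experiment therefore demonstrates that the pipeline's machinery
— selection, windowing, recurrent aggregation, weighted loss — correctly
extracts a motion signal that is present; it does not certify performance
on real surgical video, where the detector and the visual front end carry
much more of the burden.

## Numerical choices and degenerate inputs

- Boxes are 0-based, half-open, real-valued (`[x_min, x_max) ×
  [y_min, y_max)`), matching the COCO `[x, y, w, h]` convention up to an
  exact, invertible conversion; areas and IoU are closed-form and agree
  with lattice pixel counting on integer boxes to machine precision.
  Degenerate (zero-area) boxes are rejected at construction.
- Crops snap outward to the pixel grid and clamp to frame bounds; a box
  entirely outside the frame is an error (an inconsistent detection, not a
  recoverable case). Resizing is plain bilinear to 252×252 with no aspect
  preservation.
- Probabilities are clipped to `[1e-7, 1 − 1e-7]` inside the loss only;
  gradients use the unclipped sigmoid output.
- Weight init is Glorot-uniform; the LSTM forget-gate bias starts at 1.
  One integer seed drives init, shuffling, dropout masks and fragment
  offsets, so a run is reproducible bit for bit.
- Undefined metrics (zero denominators in recall/precision/F) are reported
  as `NaN` with a warning, never silently as 0. Average precision is
  all-point interpolated; detection matching is greedy in descending score
  order with each truth box claimable once.
- `sequenceLabel` uses `p ≥ 0.5 → scissors`; the boundary case fuses to
  the positive class by convention.

## Open design decisions

Several aspects of the method are underdetermined by its description, and
the package had to commit:

- **Fusion of `p_1..p_T`.** The architecture emits one probability per
  timestep but no fusion rule is stated. Mean fusion is the default (it
  uses every timestep and is the natural companion of the per-timestep
  loss); `last` (the LSTM has seen the whole window) and `max` are
  configurable alternatives.
- **Class-weight formula.** "Weighted cross-entropy" admits many
  weightings; inverse frequency with count normalization is the standard
  choice and reduces exactly to unweighted CE on balanced data.
- **Output parameterization.** A single sigmoid unit (not a two-way
  softmax), as the sigmoid-output description suggests; scissors is coded
  positive so precision/recall have a fixed reading.
- **Crop extent.** The crop is the hand box alone (`pad = 0`); whether the
  union with the tool box was intended is unknowable, and the `pad`
  parameter covers both readings.
- **Window stride.** Non-overlapping inference windows (stride = T) would
  be the conservative reading; the default pipeline uses stride 25 with a
  scene-level train/test split so no frame can leak across the split.
- **Joint training.** The learnable extractor stage trains jointly with
  the aggregator and head; a frozen-extractor mode falls out of setting
  `epochs` appropriately per stage but is not separately exposed.

## Known limitations

Binary classification only (the two-class design is structural: one
sigmoid unit); no tracking or re-identification across selection gaps — a
hand that disappears for one frame starts a new run; the oracle detector's
noise is independent across frames, which is kinder than a real detector's
correlated failures; and the built-in extractors are not transferable
visual front ends — plugging in a pretrained CNN behind the
`featureExtractor` contract is the intended path for real footage.
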