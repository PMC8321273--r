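# toolmotion

Classifying similarly shaped surgical tools from egocentric video by the
motion of the hand that operates them.

## The problem

In open surgery recorded with a head-mounted camera, scissors and needle
holders are almost indistinguishable frame by frame: both are elongated
metallic instruments whose discriminative tips are usually buried in the
surgical field or occluded by the hand. What *does* differ is how they are
used — cutting is a short linear stroke, suturing a characteristic wrist
rotation. `toolmotion` implements a three-phase pipeline that turns that
observation into a classifier, for researchers analyzing surgical workflow,
skill, or tool usage from first-person video:

1. **Localization.** Per-frame hand and tool bounding boxes come from a
   pluggable detector backend (a detections-JSON exchange format) or from
   the built-in oracle detector that corrupts synthetic ground truth with
   jitter, misses and spurious boxes.
2. **Selection.** For the *k*-th tool box `b_k^tool` and each candidate hand
   box `b_i^hand`, the overlap ratio
   `r_ik = |b_i ∩ b_k| / |b_i ∪ b_k|` is computed and the operating hand is
   `i* = argmax_i r_ik`; frames where no hand overlaps the tool yield no
   selection and break the sequence.
3. **Classification.** Windows of `T` consecutive crops of the selected
   hand (`T = 50` frames = 2 s at 25 fps), each resized to 252×252, are
   mapped to per-frame 128-d visual features `ψ_t`, aggregated causally by
   a single-layer LSTM (`ψ̂_1..ψ̂_T = B(ψ_1..ψ_T)`, 128 hidden units, tanh),
   and scored per timestep by an MLP head (one ReLU hidden layer, sigmoid
   output) giving `p_1..p_T`. Training minimizes class-weighted binary
   cross-entropy `w_y · mean_t[−y log p_t − (1−y) log(1−p_t)]` with Adam
   (lr 1e-3, batch 5, dropout 0.5); inverse-frequency weights
   `w_c = N/(K·n_c)` compensate class imbalance. A sequence decision fuses
   `p_1..p_T` (mean by default; scissors is the positive class at
   threshold 0.5).

Because real surgical footage cannot ship with a package, `toolmotion`
includes a synthetic egocentric scene simulator designed around the method's
central claim: its two tool classes are rendered with *identical* sprites
and placement statistics and differ **only** in their motion programs
(oscillation vs. rotation about the tool tip). Any classifier that beats
chance on these scenes is provably using motion, not appearance — the same
contrast the per-frame "only hand" baseline makes measurable.

The LSTM, MLP head, backpropagation and Adam optimizer are implemented in
vectorized base R inside the package; evaluation covers greedy IoU
detection matching, all-point average precision, accuracy / recall /
precision / F-measure, and ROC/AUC.

## Worked example

```r
library(toolmotion)

spec <- sceneSpec(nFrames = 55, toolClass = "needle_holders", seed = 42)
spec
#> SceneSpec: 55 frames @ 25 fps, 480x270 px
#>   tool class: needle_holders (motion: rotate), 2 distractor hand(s), seed 42

truth <- makeScene(spec)
dets  <- oracleDetect(truth)          # noise-free: truth boxes, score 1
selectAllTargets(dets[dets$frame_index == 0, ])
#>   frame_index tool_index selected_hand_index    ratio
#> 1           0          1                   1 0.153017
```

The selected hand (index 1) is the one overlapping the tool; the two
distractor hands have ratio 0. A small end-to-end run — simulate, select,
window, train, evaluate on a held-out 25% of scenes:

```r
cfg <- runConfig(nScenes = 60, framesPerScene = 55, epochs = 15, seed = 42)
res <- runPipeline(cfg)
res$selection$accuracy            # 1       (zero detector noise)
res$classification$accuracy       # 0.867   (sequential classifier, 15 test windows)
res$baseline$accuracy             # 0.510   (per-frame baseline: chance)
res$auc                           # 0.732
```

Even at this small scale the expected contrast appears: the
sequential model recovers the tool class from motion while the per-frame
baseline — same features, same head, no temporal aggregation — sits at the
0.5 chance rate, because single frames carry no class signal by
construction. At the default study conditions (`runConfig()`: 400 scenes,
one window each) the sequential classifier reaches accuracy ~1.0 with the
baseline still at chance.

A window-length comparison in the style of the T ∈ {25, 50, 100} experiment:

```r
cfg <- runConfig(nScenes = 100, framesPerScene = 125, stride = 25, seed = 1)
sweepWindowLength(cfg, c(25, 50, 100))   # one metrics row per T
```

Command-line front end (simulate / pipeline / sweep-t subcommands):

```sh
Rscript inst/scripts/toolmotion-cli.R pipeline --config cfg.yaml --out out/
```

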