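---
title: "Methods: slice navigation for patient-level tumor grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice navigation for patient-level tumor grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gradenav)
```

## The problem

Prostate cancer severity is summarized by five Gleason grade groups (GG1-GG5).
The grade assigned from a needle biopsy (GG-NB) frequently disagrees with the
grade established at radical prostatectomy (GG-RP): cohort studies report
upgrading (biopsy under-called the tumor) in roughly 26-40% of patients and
downgrading in 5-15%. Because treatment choices hinge on the biopsy grade,
both directions of error carry clinical cost. `gradenav` implements a
radiologist-mimicking framework that predicts the patient-level GG-RP directly
from a single 3D MR sequence: a slice-level convolutional classifier (the
"generator net") coupled to a deep-Q-network agent (the "action net") that
scrolls through the stack the way a reader does, settles on an attentional
*decision slice*, and emits its predicted grade as the patient-level call.

## The model

**Slice classifier.** Each slice is reduced to a centered 200 x 200 pixel
region of interest (the gland sits mid-image in routine acquisitions), scaled
to 331 x 331 by bilinear interpolation, replicated to three channels, and
standardized per channel to mean 0.5 and variance 0.5. We interpret the target
moments as the affine map `x' = (x - mean)/sd * sqrt(0.5) + 0.5` computed from
per-image moments; a slice with vanishing variance (sd < 1e-8) maps to the
constant 0.5. The backbone is pluggable. The default is a compact stack of
five 3x3 convolution + ReLU + 2x2 max-pool blocks over a fixed 5x average-pool
of the input (331 -> 66), followed by a fully connected feature layer
(default 4,320 units — the interface consumed by the agent) and a softmax over
the five grades. Any backbone exposing `slice_readout()` can replace it; the
original design used a large pretrained progressive-search network fine-tuned
in its last layers, which is out of scope on one CPU.

**Reward and navigation.** The agent sees the 4,320-dim feature vector of the
current slice and chooses among 7 actions: displacements
{-3,-2,-1,0,+1,+2,+3}, with 0 = stay-in-place doubling as the early-stop
signal. The value network is `4320 -> 50 -> 30 -> 7`. The reward of arriving
on a slice is `r = c * (y + alpha * P)` with basic reward `y = 1`, rate
`alpha = 0.5`, `P` the classifier's confidence in its prediction there, and
the gate `c = +1` only when the slice is a tumor slice *and* the predicted
grade equals the true patient grade, `c = -1` otherwise. Training uses
experience replay (FIFO pool, default capacity 2,000; updates begin only once
the pool has overflowed), an epsilon-greedy policy annealed linearly from 1.0
to 0.05, discount 0.9, and a target network re-synchronized every 100
accumulated gradient steps. Episodes start at a uniformly random slice as
environment augmentation. Inference queries the target net with epsilon = 0.

**End-to-end loop.** Prediction starts at the median slice (`floor(n/2)`,
0-based; for even counts this is the documented convention). Each *circle*
classifies the current slice and asks the agent for an action; a stay action
or the completion of the fourth circle adopts the current slice as the
decision slice and returns its predicted grade. Displacements beyond the
stack are clipped rather than terminating the episode, so every patient
always receives a grade — the 100%-sensitivity rule. The circle cap makes
termination a hard bound: at most 4 classifications and 3 moves per patient.

## Synthetic phantoms

No imaging cohort is distributed, so the package ships a volumetric phantom
generator whose defaults emulate the acquisition statistics the framework
assumes: stacks with median 24 slices (range 18-24), a contiguous gland run
with median 9 slices (range 8-12) centered mid-stack (+/- 1 slice), and a
contiguous lesion run with median 5 slices (range 4-10) centered in the gland
(+/- 1). Grade priors default to the pooled prostatectomy marginals of a
575-patient two-hospital cohort, (82, 152, 117, 85, 139)/575.

The lesion signature combines a first-order cue — a mean intensity shift of
`0.06 * signal_separation * grade` — with a texture cue, sinusoidal stripes of
amplitude `0.05 * signal_separation` whose wavelength shortens with grade
(40 px for GG1 down to 20 px for GG5 at 256 px slices; orientation and phase
are drawn per patient). Nuisance terms make the task non-trivial: a
patient-level intensity offset (sd 0.05), a slice-level offset (sd 0.02), a
low-frequency background field and white pixel noise (sd 0.05). At
`signal_separation = 0` lesions are indistinguishable from gland tissue and
classification collapses to chance; at 2 the grades are cleanly separable —
the difficulty curve in between is monotone, which the test suite checks.

A simulated biopsy grade accompanies each phantom: `gg_nb = gg_rp + delta`
with `delta` in {-2,...,+2} drawn with probabilities
(0.10, 0.30, 0.45, 0.10, 0.05) and clipped to 1..5. The sub-diagonal mass of
0.40 and super-diagonal mass of 0.15 reproduce the reported clinical
upgrading/downgrading rates (40.4% / 14.7%, concordance 44.9%). The joint
NB-RP table behind those marginal rates is not published, so this kernel is a
stand-in exposed as the `nb_kernel` argument, not a calibration.

What the phantoms do *not* model: pelvic anatomy, partial-volume and bias
fields, scanner- and protocol-dependent contrast, multifocal disease beyond
an optional second lesion run, and any pathology-to-MRI registration error.
Passing the phantom benchmarks therefore demonstrates that the machinery —
preprocessing, training, replay, navigation, checkpointing, evaluation — is
correct and that the coupled system can recover a graded signal it is
theoretically able to see; it says nothing about accuracy on clinical data.

## Training choices

The classifier's default optimizer follows the original recipe: SGD with
momentum 0.9, batch 64, learning rate 0.01 with exponential decay 0.97 per
epoch, early stopping once validation accuracy has stagnated for 5
consecutive epochs, best-epoch weights returned. Two stabilizers are applied
regardless of optimizer, both exposed in `train_config()`:

* **Layer-scale calibration at initialization.** The all-positive ReLU chain
  of a from-scratch network inflates activation scale with depth; a probe
  batch is forwarded once and every convolution and the feature layer are
  rescaled to unit output RMS (the output layer to logit RMS 0.5). This is a
  data-dependent initialization, not a change to the optimization schedule.
* **Global gradient-norm clipping** (default cap 1): the first few momentum
  steps otherwise overshoot and collapse the softmax.

Those original hyperparameters presume a large pretrained backbone with most
filters frozen. Training the compact backbone from scratch is a different
optimization problem, and plain momentum SGD proved poorly conditioned for
it: validation accuracy plateaued near 0.55 with strong oscillation. The
*benchmark configuration* (`benchmark_train_config()`) therefore uses Adam
(learning rate 1e-3, same 0.97 decay), decoupled weight decay 1e-4, batch 16
and per-epoch Polyak averaging of the evaluated weights.

The benchmark also selects a different head for the backbone. With the
flatten head, the network shortcut-learns: stripe orientation, phase and
lesion position are constant within a phantom patient, so a high-dimensional
positional representation can memorize training patients perfectly (training
accuracy 1.0) while transferring almost nothing (validation near chance), and
even heavy rotation augmentation only partly suppresses this. The
global-average-pooling head plus eight global intensity quantiles of the
input removes the shortcut by construction — channel energies are
position-free texture descriptors and the upper quantiles carry the
lesion-contrast cue directly — and lifts held-out slice accuracy from ~0.7
to ~0.93 at separation 2. A linear-discriminant check on the quantile
features alone confirms the phantom signal supports that level. Geometric
augmentation is disabled in this configuration since the representation is
already orientation-insensitive; the augmentation machinery (mirror,
rotation, affine, always label-preserving) remains available and on by
default elsewhere.

The agent's unstated hyperparameters are package choices, all in
`dqn_config()`: discount 0.9, epsilon 1.0 -> 0.05 over the first 80% of
episodes, pool 2,000, replay batch 32, learning rate 1e-3, 1,000 episodes of
at most 4 steps. Features are scaled to unit root-mean-square (scale stored
in the agent) before entering the value net, making Q-learning insensitive
to the backbone's activation scale. "Accumulations" for the target-net sync
are counted as gradient steps (the alternative reading, environment
transitions, is one configuration switch away).

One training-episode choice matters a great deal and is worth spelling out.
If the stay action *terminates* a training episode, stopping on a rewarding
slice forfeits the remaining discounted horizon, so the optimal policy is to
drift back and forth along the lesion rather than settle on it — and the
function-approximation noise of that drifting policy steps off the tumor run
in a substantial fraction of patients. The package therefore treats stay as
an ordinary action during training (episodes always run to the step cap, the
terminal flag marks only the horizon), which makes "settle on the
highest-reward slice" the value-optimal behavior; at inference the stay
action still triggers the checkpoint decision. The alternative semantics
remain available as `dqn_config(stay_terminal = TRUE)`.

## Numerical conventions

* Slice indices are 0-based everywhere (manifests, traces, decision indices);
  canonical slice order is inferior -> superior, and NIfTI volumes whose
  xform maps the third axis against world z are reversed on read.
* Argmax ties in the classifier break toward the lower grade (conservative
  under-call); Q-value ties break toward the smallest absolute displacement,
  negative before positive, so an all-tied vector stays in place.
* The quadratic kappa uses weights `(i-j)^2/(K-1)^2` and the outer-product
  expectation; a table with all mass in one diagonal cell returns kappa 1,
  off-diagonal degenerate tables are an error.
* Bootstrap intervals are percentile intervals over patient-level resamples
  (N = 1,000 by default), seeded; resamples on which a statistic is undefined
  are redrawn and counted.
* Pearson chi-square is computed without continuity correction; `auto` mode
  switches to Fisher's exact test when any expected count is below 5 (exact
  enumeration for 2x2, seeded Monte-Carlo for larger tables).
* Upgrading means the reference (RP) grade exceeds the compared (biopsy or
  predicted) grade. Confusion matrices are reference-by-compared.

## The standard benchmark

`phantom_benchmark(seed)` is the package's reference experiment and what
`scripts/acceptance.R` reports: 80 phantoms at separation 2 split 50/10/20
(the training environment holds 50 patients, validation 10, and 20 test
patients are never seen), classifier trained with
`benchmark_train_config()`, agent with `dqn_config()` defaults, and the
end-to-end loop evaluated on the test patients — decision-slice tumor rate, a
uniform random-walk navigation baseline from the same start slice, five-way
accuracy, quadratic kappa, grouped AUCs, and the upgrading/downgrading
decomposition of the model against the simulated biopsy. Cohort and image
sizes were chosen so the whole three-seed study runs in minutes on one CPU;
they are stated here as the package's standard problem size.

## Known limitations

* The published equations for the slice loss and the reward are figures in
  the source document; the loss is reconstructed as standard multiclass
  cross-entropy and the reward as the additive sign-gated form above. Both
  are isolated behind single functions (`cross_entropy()`,
  `compute_reward()`) so alternative compositions are one-line swaps.
* Whether standardization uses per-image or dataset moments is unstated;
  per-image is implemented.
* Whether a "circle" counts one action or one classify+act pair is unstated;
  one classify+act pair is implemented, making "median+3" the farthest
  reachable decision slice under unit steps.
* DICOM series reading is not implemented (no R-native reader available);
  convert series to NIfTI first. The NumPy-style `.npz` fixture format is
  realized as RDS with the same round-trip contract.
* The six-class variant (class 0 = non-tumor slice) is implemented and
  tested for the qualitative finding that overall accuracy can rise while
  grade accuracy on tumor slices does not improve; the five-class model
  remains the default generator net, as in the original design.
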