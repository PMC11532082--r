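---
title: "Classifying neuronal morphologies with a dual-branch fusion network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying neuronal morphologies with a dual-branch fusion network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Digitally reconstructed neurons are stored as SWC files: a rooted tree of 3D
sample points with radii and type codes. Two feature families dominate
morphology-based classification. Hand-crafted morphometrics (total length,
bifurcation counts, contraction, branch angles, ...) summarize local geometry
as a short vector of statistics; they are precise but blind to the arbor's
holistic shape. Rasterized 2D projections of the arbor capture that holistic
shape and suit convolutional networks, but discard exact measurements. The
two views are complementary, and simply concatenating them at the end of two
independent encoders leaves most of that complementarity unused.

`neurofuse` implements a dual-branch network in which the two encoders talk
to each other *during* feature extraction. A fully connected branch (FCN)
encodes a 43-element morphometric vector; a convolutional branch (CNN)
encodes a 3-channel stack of orthogonal projections. After CNN stages 2-4, a
fusion module bridges the branches: a channel-attention Feature Enhancement
Module (FEM) re-weights each branch's features, and a cross-attention
Feature Interaction Module (FIM) passes information across branches. The
final branch features are fused (element-wise sum by default) and classified
by a two-layer head.

## Inputs

**Morphometric vector.** `compute_feature_vector()` reduces a tree to the
43-function L-Measure registry (`morphometric_names()`), one scalar each:
counts and extents as totals (maximum for branch order), per-node and
per-branch quantities as means over their defined elements. A metric that
is undefined on a degenerate tree (angle metrics without a bifurcation, for
example) is emitted as 0 and flagged in a mask so the FCN always receives a
finite vector. Four of the metrics deserve a note:

* `Bif_tilt_*` is the smaller angle between the extended parent direction
  and the two daughters; `Bif_torque_*` is the angle between the daughter
  planes of a bifurcation and its nearest ancestor bifurcation. Both follow
  the toolbox's intent but are in-package definitions and documented as
  approximate.
* `Helix` is the normalized triple product over sliding 4-node windows
  along descending paths.
* `Fractal_Dim` is the box-count slope over 5 dyadic scales. Boxes are laid
  on PCA-aligned coordinates, which makes the estimate invariant to rigid
  motions of the input - a property the test suite checks for every
  non-extent metric.

Dimensional bookkeeping is part of the registry: scaling coordinates and
radii by $s$ multiplies each metric by $s^{d}$ with $d$ its length
dimension (0 for the dimensionless metrics, 1 for lengths, 2 for areas,
3 for volumes, 1.5 for `Diameter_pow`), and the suite tests exactly that.

**Projection stack.** `pca_normalize()` centers the coordinates and rotates
them into the principal frame, giving every laboratory's reconstructions a
common orientation. The eigenvector sign ambiguity is fixed
deterministically: each axis must have a non-negative third moment, with
the farthest-from-centroid node's sign as a tie-break. `render_views()`
draws each parent-child segment as a 1-pixel anti-aliased line onto the
x-y, y-z, and x-z planes with one isotropic fit-to-frame scale shared by
the three views (preserving 3D proportions; the longest principal extent
spans the usable frame). Radii are not rendered - the radius information
already lives in the morphometric branch - and intensities live in [0, 1]
with background 0. The default `pad_fraction` is 0.05.

## The network

Let $F$ be the FCN feature and $C$ the CNN feature map entering a fusion
module; the FCN block widths are tied to the CNN stage channels so
$\mathrm{length}(F)$ equals the channel count of $C$. Each FCN block is
three FC layers with batch normalization and ReLU after the first two, with
internal widths $\lfloor d/2 \rfloor$ and $\lfloor d/4 \rfloor$ (never
below 4) of its input width $d$.

**FEM.** Channel weights are
$W_f = \sigma(\mathrm{fc}_2(\delta(\mathrm{BN}(\mathrm{fc}_1(F)))))$ with
hidden width $\lfloor C/2 \rfloor$, and the enhanced feature is
$F_e = W_f \odot \mathrm{BN}(F)$. In parallel, $F$ is split into $N_s = 3$
channel groups (the first $C \bmod N_s$ groups take one extra channel),
each refined by an fc-BN-fc module; the refined groups are concatenated to
$F_{s1}$, and an FC layer reduces $[F_e, F_{s1}]$ back to length $C$. On
the CNN side the same module runs on the globally average-pooled channel
vector, modulates the map channel-wise, and a $1 \times 1$ convolution
restores $C$ channels.

**FIM.** Both branch features are reduced to equal-length vectors, reshaped
into $T = 4$ tokens of dimension $d = C/T$, and attended with
$Q_e = \mathrm{softmax}(QK^\top/\sqrt{d})\,V$, where the query comes from
one branch and key/value from the other. The interacted feature is the
residual update $F'' = \mathrm{BN}(\mathrm{fc}(\mathrm{BN}(F') + Q_e)) + F'$.
No learned Q/K/V projections are used: the pooled features act directly as
query, key, and value. A single-token reading of the attention would make
$Q_e \equiv V$ and the softmax degenerate, which is why the vectors are
tokenized; this was a genuinely open design point and the chosen default is
$T = 4$.

**Module output.** The fusion module returns
$f_l = \mathrm{fc}([F', F''])$ with the dimension of $F$, and
$f_c = \mathrm{conv}_{1\times1}([C', \mathrm{bcast}(C'')])$ with the shape
of $C$, where $\mathrm{bcast}$ broadcasts the interacted channel vector
over space. The broadcast-and-concatenate rule is this package's choice for
re-injecting the pooled result into the spatial stream; only the
$1\times1$ reduction itself is prescribed by the method. Disabling FEM or
FIM (`use_fem`, `use_fim`) removes the module (and its parameters) and
passes features through, leaving the concat-reduction - the ablation
baseline.

**Head and loss.** The final FCN feature is projected by one FC layer to
the dimension of the last CNN stage and fused with the pooled CNN feature
by element-wise sum (`fusion_strategy` also offers concatenation and
averaging; summation is the default because it performed best in the
method's own ablation). A two-layer classifier yields logits, with dropout
0.5 after the hidden FC layer — not after the output layer, since dropping
logits would inject label-independent noise into the class scores rather
than regularize a representation. Training minimizes the cross-entropy
$L = -\tfrac{1}{N}\sum_i \sum_j y_{ij} \log p_{ij}$ with probabilities
clamped at $10^{-12}$.

Backbones: ResNet-50 is the reference CNN (224 x 224 inputs); ResNet-18/34/
101 and 4-stage VGG-16/19 variants are available, plus a `tiny` 4-stage
backbone (channels 8/16/32/64, 32 x 32 inputs) for desk-scale work. The
VGG variants group the standard convolution stacks into 4 stages (channels
64/128/256/512) so the FCN block count and fusion-module placement stay
uniform across backbones. Every layer, including the convolutions and the
attention, runs on a small reverse-mode autodiff tape implemented in this
package; all gradients are validated against central finite differences in
the test suite.

## Training protocol

`fit()` uses Adam with initial learning rate $10^{-3}$ and cosine decay to
zero over the epoch budget, mini-batches of 16 (a trailing singleton batch
is merged into its predecessor to keep batch-norm statistics sane), and
per-epoch logging of training loss and accuracy. The reference protocol is
100 epochs; the desk-scale study below uses 50. Morphometric inputs are
z-scored with statistics of the training fold only, and the held-out fold
reuses those statistics - the standardization is part of the model, so
cross-validation has no leakage. `stratified_folds()` keeps per-fold class
proportions within one sample of the global proportions.
`evaluate()` reports the confusion matrix, accuracy, per-class and macro
precision/recall/F1 (macro averaging, appropriate for balanced classes),
and one-vs-rest AUC computed in rank form - identical to trapezoidal
integration of the empirical ROC and cross-checked against an independent
implementation in the tests.

## Synthetic study conditions

Real reconstruction archives cannot ship with a package, so
`generate_neuron()` grows labeled synthetic morphologies: stems leave the
soma in random directions and elongate in noisy steps (per-step angular
jitter `tortuosity`), bifurcate with a per-segment Bernoulli probability
into daughters separated by a sampled amplitude (default mean 60 degrees),
and taper at each bifurcation. Depth, per-branch step count and a global
node budget bound the tree; every draw comes from a private stream derived
from `(seed, class, index)` so datasets are reproducible and
order-independent.

The desk-scale study conditions, fixed up front and used by both the
acceptance tests and `scripts/acceptance.R`, are: three classes whose
expected total length and bifurcation count are separated by roughly a
factor of two between neighbors (`default_class_params(3)`), 50 neurons
per class, 32 x 32 projection stacks, the tiny backbone, 2-fold stratified
cross-validation, 50 epochs, three seeds. These sizes keep a full run in
the minutes range on one CPU while leaving the classes non-trivially
separable.

What the generator does *not* emulate matters for interpreting green
tests: real arbors have type-dependent radii, soma contours, reconstruction
artifacts (gaps, multifurcations, duplicate points), and class differences
far subtler than scaled branching statistics. Passing the desk-scale study
shows the pipeline learns and that fusion does not hurt on cleanly
separable data; it says nothing about accuracy on archive-scale neuron
collections, which requires the full-resolution ResNet-50 configuration
and real data.

## Numerical choices and degenerate inputs

* Batch normalization uses biased batch variance, $\epsilon = 10^{-5}$,
  running-statistic momentum 0.1; evaluation mode uses running statistics.
* The Rall-power exponent solves $d_p^n = d_1^n + d_2^n$ by bisection on
  $[0, 5]$ (tolerance $10^{-9}$); bifurcations without a root in that
  bracket are excluded and masked. `Pk` uses the tree-mean exponent, so it
  is informative rather than identically 1.
* Zero-length branches, zero daughter vectors, and zero parent diameters
  are excluded from their metric's average and masked, never propagated as
  NaN.
* Extra SWC roots of type 1 (soma contours) are re-attached to the first
  soma node; any other multi-root file is rejected. Written files carry
  enough significant digits to round-trip coordinates exactly.
* A single-node tree renders as a centered dot; degenerate-rank point
  clouds (collinear neurons) get zero coordinates on the deficient axes.

## Known limitations

The network trains on one CPU at desk scale only; the pure-R tape makes a
224 x 224 ResNet-50 forward feasible but training it impractical -
`pretrained` exists as a hook for externally supplied weights and no
pretraining is performed here. Tilt, torque, helix, and fractal dimension
are approximate re-definitions, adequate for classification features but
not drop-in replacements for every published variant of those metrics.
The attention tokenization ($T = 4$) and the spatial re-injection rule are
package choices on points the method leaves open; both are exposed in
`fusion_config()` so their effect can be measured.
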