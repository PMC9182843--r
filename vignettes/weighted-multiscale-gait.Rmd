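---
title: "Weighted multi-scale networks for inertial gait recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multi-scale networks for inertial gait recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsgait)
```

## The problem

Smartphones record walking as six synchronous inertial channels: tri-axial
acceleration $(A_x, A_y, A_z)$ and tri-axial angular rate $(G_x, G_y, G_z)$.
A fixed-length window $X = [x_1, \dots, x_N]$ with
$x_t = (A_x, A_y, A_z, G_x, G_y, G_z)$ carries enough of a person's gait
signature to identify them — but the signal is distorted by *covariate
factors*: walking speed, a load carried on one side, a hand in the pocket,
how the phone sits. `wsgait` implements a recognition network built around
two ideas for coping with these distortions:

1. **Multi-scale analysis.** The window is coarse-grained by non-overlapping
   block averaging at several time scales
   $$x_t^{\tau} = \frac{1}{\tau} \sum_{k = (t-1)\tau + 1}^{t\tau} X_k,
   \qquad 1 \le t \le \lfloor N / \tau \rfloor,$$
   and each scaled signal is processed by an *independent* 1-D CNN. Fine
   scales see pose detail, coarse scales see the overall cycle.
2. **Fisher-discriminant feature weighting (the "Ws" branch).** Each branch
   classifies its feature map *locally* — the classifier weights are applied
   at every temporal location — and the resulting per-location class-score
   vectors are treated as labelled samples. Their within-class scatter
   $\Sigma_w = \sum_i \sum_{\hat f \in c_i} (\hat f - m_i)(\hat f - m_i)'$
   and between-class scatter
   $\Sigma_b = \sum_i (m_i - m)(m_i - m)'$
   define a generalized eigenproblem; the leading eigenvalues
   $\lambda = \mathrm{eig}(\Sigma_w^{-1} \Sigma_b)$ measure how
   discriminative each direction of score space is, and are used to weight
   the per-branch feature before fusion.

A learned fusion layer $\hat F_{global} = \sum_s W_{\tau_s} \hat F_{\tau_s}$
sums the weighted per-scale features into one global feature, which a fully
connected softmax layer classifies. Training minimizes
$$L_{overall} = \alpha \sum_i \alpha_i L_i(\hat F_i, y)
  + \beta\, L_{global}(F_{global}, y),$$
where every $L$ is a categorical cross-entropy, $\alpha = 0.99$ and
$\beta = 0.87$, and $\alpha_i$ are uniform per-scale weights.

## Architecture

The per-scale backbone (for a 200-sample window):

```{r}
backbone_shapes(backbone_config(), 200)
count_parameters(backbone_config())
```

Conventions worth stating. Convolution uses the cross-correlation convention
(no kernel flip), ReLU activations, Kaiming-normal initialization, an L2
kernel penalty (default coefficient `1e-4`), dropout 0.5 after the
convolutional stack and 0.8 after the fusion layer. `Conv2_2` maps 92
locations to 46 with a 5-wide kernel, which forces stride 2 with "same"
padding; the parameter count is unchanged by that choice. The same layer
plan is applied to every scale, but the weights are never shared across
scales — each branch is an independent feature extractor.

The default scale set is $\tau \in \{2, 3, 4, 5\}$, the four-branch ensemble
used as the reference configuration. Scale 1 (the raw window) can
be added via `wmscnn_spec(scales = 1:5)`.

## The Fisher branch in detail

Per branch and per training batch:

1. The feature map ($h$ locations $\times$ 128 channels) is pooled by
   global average pooling (`global_average_pool`) and classified by the
   branch head, giving the *local* prediction used in $L_{local}$.
2. The same head is applied at every location (`localized_scores`), and the
   $B \cdot h$ score vectors of the batch update running scatter matrices
   with momentum 0.9 (first batch initializes them directly). The momentum
   makes $\lambda$ stable across small batches.
3. `fisher_weights` solves $\Sigma_w^{-1} \Sigma_b$; eigenvalues are clipped
   at zero, eigenvectors unit-normalized with a deterministic sign
   convention. If $\Sigma_w$ is singular, a ridge
   $\varepsilon I$ with $\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma_w)/d$
   (floored at $10^{-6}$ when the trace vanishes) is added with a warning.
4. The branch feature entering fusion is the head's score image of the
   pooled feature, projected onto the Fisher eigenvectors and scaled
   componentwise by $\lambda_j / \max_j \lambda_j$ (`reweight_features`).

Two design points here were genuinely open. First, several mechanisms could
let $\lambda$ multiply features; we project onto the
eigenvectors and scale by max-normalized eigenvalues, which is bounded,
scale-free, and reduces to a plain projection when all directions are
equally discriminative. Second, the localized-score samples live in class
space, so the projected vector must too; the branch logits (the classifier
image of the pooled feature) are the smallest consistent choice. $\lambda$
and the eigenvectors are *not* trained by backprop — they are recomputed
analytically from the running statistics, while the heads, fusion maps and
classifier are trained end-to-end (verified against finite differences to
$10^{-4}$ in the test suite; the implemented gradients agree to ~$10^{-11}$).

The number of discriminant directions defaults to
$N' = \min(K - 1, \text{channels})$, the rank bound of $\Sigma_b$; if a
caller requests more than the score dimension supports, the surplus
directions carry zero weight.

**Ablation switch.** `wmscnn_spec(ws = FALSE)` replaces the Fisher
projection with a fixed identity truncation of score space and unit weights.
This removes the mechanism while keeping every tensor shape identical, which
is what makes the with/without comparison clean.

## Training recipe

`train_config()` defaults: Adam, learning rate 0.001, batch size 32, up to
200 epochs, early stopping when the validation loss fails to improve for 50
consecutive epochs, $\alpha = 0.99$, $\beta = 0.87$. The validation monitor
is a stratified 10% split of the training (gallery) windows, seeded; the
best-validation weights are returned (optimizer state is not restored). All
randomness — split, shuffling, initialization, dropout — derives from the
single `seed`, so runs are bit-reproducible.

One empirical note from the test suite: with uniform $\alpha_i = 1/4$, each
branch's local gradient carries weight $\approx 0.25$, so the *local* losses
converge noticeably more slowly than the global loss (on noiseless 5-class
data the four-branch local loss passes 0.1 around epoch 150 of the standard
recipe, while the global classifier is already near zero). This is the
expected behaviour of the composite objective, not a defect; the full
200-epoch budget accommodates it.

## The synthetic generator

No public gait dataset ships with the package; `simulate_gait()` generates
the study conditions instead. Each subject is a fixed harmonic signature:
per channel, 3–5 harmonics of a base cadence (uniform on 1.6–2.2 steps/s,
the normal walking range) with subject-specific amplitudes (template
$\propto 1/h$ plus Gaussian deviations scaled by `signature_scale`) and
phases, a gravity offset on $A_z$, sampled at 100 Hz. Windows of one
subject differ by additive Gaussian noise (`noise_sd`, default 0.1 —
moderate relative to unit-order signal amplitudes), ±2% cadence jitter and
±0.15 rad phase jitter. Covariate perturbations map to physical effects:

| kind          | effect at magnitude $m$                                        |
|---------------|----------------------------------------------------------------|
| `fast_walk`   | period compressed by $1 + m/2$ (resampling)                    |
| `load_left/right` | accelerometer bias $\mp/\pm 0.3m$ and amplitude asymmetry $1 \mp/\pm 0.2m$ |
| `pocket_hand` | gyroscope amplitude scaled by $1 - m/2$                        |
| `mixed`       | one of the above, drawn per window                             |

What this emulates — and what it does not. The generator reproduces the
*structure* of the problem: quasi-periodic class-structured signals,
controllable inter-subject separability, label-preserving covariate
distortions. It does not attempt biomechanical realism, sensor-noise
physics, orientation drift, or the heavy class imbalance of real corpora.
Tests passing on this data therefore certify the mechanics of the method
(shapes, gradients, the Fisher mechanism, the evaluation protocol, the
direction of the Ws effect), not field accuracy on real smartphone data.

## Preprocessing

Raw channels are L2-normalized *per time step, per sensor triple*: each
accelerometer 3-vector and each gyroscope 3-vector is divided by its
Euclidean norm (steps with norm below $10^{-12}$ stay zero). Of the
plausible normalization granularities, the per-step triple is the one that
cancels device-orientation and gain effects, which is the stated purpose of
the normalization. Fixed 200-sample windows with configurable stride replace
gait-cycle segmentation (a learned cycle segmenter is out of scope here;
the synthetic windows are generated pre-segmented).

## Evaluation protocol

Identification: softmax scores on probe windows, rank-$k$ identification
rate with ties broken toward the lowest class index. Verification: cosine
similarity between probe and gallery global features; pairs sharing an
identity are genuine. `roc_curve()` sweeps every distinct score; TAR
defaults to the conventional true-positive rate $TP/(TP+FN)$ (required for
a meaningful ROC), with the precision form $TP/(TP+FP)$ available as
`tar = "precision"`.
`vr_at_far()` interpolates TAR at a target FAR, default $10^{-3}$, the
standard biometric operating point.

## Numerical choices

* Cross-entropy probabilities are clipped at $10^{-7}$ before the log.
* Softmax subtracts the row maximum (no overflow at extreme logits).
* Block averaging discards the trailing $N \bmod \tau$ samples — the scale
  index set never reaches past $\lfloor N/\tau \rfloor \tau$.
* Fisher eigenvectors take a deterministic orientation (largest-magnitude
  component positive), so repeated fits are identical.
* Max-pooling ties resolve to the earlier location.
* All-zero Fisher weights (degenerate batches) fall back to unit weights in
  the training loop so gradients keep flowing; the standalone
  `reweight_features()` keeps the documented zero-vector-with-warning
  contract.

## Problem sizes used in the checks

The packaged checks run the full pipeline on 10 subjects × 40 windows
(stratified 75/25 gallery/probe split, `noise_sd = 0.1`) with the standard
training recipe — the scale at which the four-branch model and its ablation
can be trained on one CPU in a few minutes. Smaller configurations (3–5
subjects, 2–3 scales, shortened windows) back the unit tests.

## Known limitations

* The per-batch Fisher refresh assumes batches large enough that
  $\Sigma_w$ is well-conditioned in class space; very small batches lean on
  the exponential averaging.
* A curriculum that pretrains branches from coarse to fine before joint
  training is plausible but unspecified; the package trains everything
  jointly from the start.
* Real-data covariates (shoe/clothing change, surface slope) have no
  synthetic counterpart here; conclusions about them require real corpora
  converted to the documented CSV schema.
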