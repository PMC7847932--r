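---
title: "Sparse-response deep belief networks with ELM classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-response deep belief networks with ELM classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdbnelm)
```

# The problem

Computer-aided discrimination of Alzheimer's disease (AD), mild cognitive
impairment (MCI) and normal controls (NC) from multimodal brain images —
amyloid-PET uptake maps together with gray-matter and white-matter
segmentations from structural MRI — faces a chronic imbalance: voxel
features number in the tens of thousands while subject cohorts number in
the hundreds. Deep autoencoder stacks fitted by end-to-end backpropagation
overfit and suffer vanishing or exploding gradients at that sample size.
This package implements an alternative four-stage pipeline: (1) per-modality
min-max normalization, (2) exact PCA computed by the snapshot method,
(3) one *sparse-response deep belief network* (SR-DBN) per modality for
nonlinear feature learning, and (4) a single *extreme learning machine*
(ELM) classifier on the concatenated features, evaluated by repeated
stratified five-fold cross-validation.

# Model components

## Restricted Boltzmann machines and contrastive divergence

An RBM couples a visible layer $v \in \{0,1\}^{n_v}$ and a hidden layer
$h \in \{0,1\}^{n_h}$ through the energy

$$E(v, h) = -\sum_{ij} w_{ij} v_i h_j - \sum_i c_i v_i - \sum_j b_j h_j,$$

with $p(v, h) \propto e^{-E(v,h)}$. Conditionals factorize:
$p(h_j = 1 \mid v) = \sigma(\sum_i v_i w_{ij} + b_j)$ and symmetrically for
the visible units. Maximum-likelihood gradients require model expectations
$\langle v_i h_j \rangle_{p_\theta^\infty}$, which are intractable at scale;
contrastive divergence (CD-$k$) replaces them with statistics after $k$
block-Gibbs steps started at the data, giving the updates

$$w_{ij} \mathrel{+}= \epsilon\,(\langle v_i h_j\rangle_{p^0} -
  \langle v_i h_j\rangle_{p_\theta^k}), \qquad
  c_i \mathrel{+}= \epsilon\,(\langle v_i\rangle_{p^0} -
  \langle v_i\rangle_{p_\theta^k}), \qquad
  b_j \mathrel{+}= \epsilon\,(\langle h_j\rangle_{p^0} -
  \langle h_j\rangle_{p_\theta^k}).$$

A note on symbols: in this package (and in the update rules above) $c$ is
always the visible-layer bias and $b$ the hidden-layer bias — the convention
that makes the bias updates consistent with the statistics they consume.

## The sparse-response penalty

The sparse-response RBM adds an L1 penalty on the hidden conditional
activation probabilities,
$\lambda \sum_{l=1}^m \lVert p(h^{(l)} \mid v^{(l)}) \rVert_1$, motivated by
rate-distortion theory: among representations with equal distortion, prefer
the one transmitting fewer expected active bits. Because each probability is
a sigmoid, the penalty's negative gradient is available in closed form:

$$-\frac{\partial}{\partial w_{ij}} = -\sum_l p_j^{(l)}(1 - p_j^{(l)})\,v_i^{(l)},
 \qquad
 -\frac{\partial}{\partial b_j} = -\sum_l p_j^{(l)}(1 - p_j^{(l)}),$$

with no contribution to the visible bias. `sparsity_gradient()` returns
exactly these batch-summed quantities (they are what a finite-difference
check of the penalty must reproduce). During training the penalty is applied
as a *second additive update* after each CD step, scaled by
$\epsilon \lambda / m$ for a batch of $m$ examples. The division by $m$ is a
deliberate design choice: the CD term uses batch-*averaged* statistics, so
the penalty is brought onto the same per-example scale. Applying the raw
batch sum instead makes the effective penalty strength grow with the batch
size; at the defaults ($\lambda = 0.1$, batches of 16) that drove hidden
biases to around $-3$ within a few epochs and collapsed the activations of
deeper layers to nearly constant values, destroying the class signal that
downstream stages need.

## Gibbs chain and negative-phase estimators

Two estimator choices are unstated in the literature this design follows and
had to be fixed here:

* The chain itself is **true block Gibbs** — sampled hidden states *and*
  sampled visible states. A popular variance-reduction variant propagates
  visible probabilities instead of samples, but that chain's stationary
  distribution is not the model equilibrium; on a 4+3-unit model it
  mis-estimated $\langle v_i h_j\rangle$ by about 0.05 at CD-50, which would
  defeat the exact-enumeration convergence checks this package ships.
* The negative-phase statistics are **Rao-Blackwellised**: the visible mean
  uses $p(v \mid h)$, and the pairwise statistic pairs sampled visibles with
  $p(h \mid v)$. Both are unbiased for the chain's state distribution while
  cutting Monte-Carlo variance; the positive phase pairs the data with
  hidden probabilities, the standard choice.

The reconstruction-error trace uses the one-step visible probabilities.

`exact_model_statistics()` provides the ground truth for tiny models by
summing the hidden layer out analytically ($2^{n_v}$ terms), and the test
suite checks it against a second, fully joint $2^{n_v+n_h}$ enumeration.

## Stacking, pretraining and fine-tuning

A DBN stacks RBMs; training is greedy and layerwise, each layer's
*deterministic hidden probabilities* (never samples) feeding the next
layer — so the whole feature map is a pure function and results are
bit-reproducible from the seed. The default architecture is three hidden
layers of equal size (equal to the retained PCA dimension when the DBN
follows PCA).

After pretraining, a softmax head is attached to the top layer and the whole
network is fine-tuned by plain gradient descent on the training-fold
cross-entropy. Whether this stage should be supervised at all is genuinely
open in the source design; supervised fine-tuning was chosen because the
stage sits between feature learning and classification in a labeled
workflow, and it is exposed as `finetune = "supervised" | "off"`. The head
is kept only for diagnostics — classification is always done by the ELM on
the extracted features.

## Extreme learning machine

The ELM is a single-hidden-layer network whose input weights $A$ and biases
$d$ are drawn once, uniformly on $[-1, 1]$ (the canonical range), and never
trained. With $H = \sigma(XA + d)$ and one-hot targets $T$, the output
weights are the minimum-norm least-squares solution

$$\hat\beta = H^{+} T,$$

computed via SVD with singular values below $10^{-10}\sigma_{max}$
truncated. Predictions are the arg-max score, ties broken toward the lowest
class code; the positive class's continuous score feeds ROC analysis. The
default hidden width is $10\times$ the feature dimension, capped at 1000.

## Snapshot ("fast") PCA

With $p \gg n$ (voxels vs subjects), exact PCA is computed from the
$n \times n$ Gram matrix of the centered data and mapped back to feature
space — identical to a direct SVD, not an approximation, at a fraction of
the cost. Retained components are the smallest number reaching 90%
cumulative explained variance, capped at 20 by default. Component signs are
fixed so each component's largest-magnitude loading is positive. PCA is fit
per modality and, inside cross-validation, on the training fold only.

## Cross-validation protocol

`run_task_cv()` implements repeated stratified $k$-fold CV (default 5 folds;
the reference protocol repeats 200 times, the package's test scale uses 10).
Within every fold the entire pipeline — normalization, PCA, score
rescaling, DBNs, ELM — is refitted on the training 80% only; the held-out
20% is transformed with frozen parameters, which the test suite verifies by
perturbing held-out rows and checking the fitted bundle is unchanged.
ACC/SEN/SPE are reported in percent, AUC by trapezoidal integration over the
tie-grouped ROC (equal to the Mann-Whitney concordance with half credit for
ties). Fold metrics are averaged per repeat (AUC fold-averaged, not pooled —
the pooled alternative mixes fold-specific score scales), and aggregates are
mean ± SD across repeats. The positive class defaults to the more impaired
group of each task (AD in AD-vs-NC and AD-vs-MCI; MCI in MCI-vs-NC), which
orients sensitivity toward detecting disease.

# The synthetic data generator

Real amyloid-PET/MRI cohorts are access-controlled, so the package ships a
generator whose statistical structure exercises every pipeline stage:

* per modality, a class-conditional Gaussian low-rank factor model
  $x = \mu_c + F z + e$, $z \sim N(0, I_r)$, $e \sim N(0, \sigma^2 I)$,
  squashed elementwise by the logistic function so features lie in $(0,1)$
  like normalized image intensities (and like the Bernoulli-probability
  interpretation the RBM visible layer assumes);
* class means collinear, adjacent classes `separation` within-class standard
  deviations apart (measured along the mean-difference direction), so a
  three-class dataset has the NC/MCI/AD property that the extreme pair is
  easiest to separate;
* modalities share labels but draw independent mixing matrices — partially
  redundant signal, as with PET/GM/WM;
* all randomness flows from one master seed through named substreams, so
  identical specs are bit-identical.

Defaults (60 subjects per class, 3 modalities, 50 features each, rank-5
factors, noise SD 0.5, separation 4.0) describe a deliberately
well-separated cohort: large enough to exercise stratified folds, small
enough that the full repeated-CV suite runs in minutes on one CPU. What
passing tests on these data show is that the *machinery* is correct —
losslessly plumbed, leakage-free, convergent to its oracles. They do not
show that the pipeline reaches any particular accuracy on real ADNI images,
whose noise structure (scanner effects, registration error, partial-volume
effects, demographic confounds) the generator makes no attempt to emulate.

`generate_toy_volumes()` additionally writes small NIfTI volumes with an
attenuated-sphere "lesion" plus a CSV manifest, to exercise the volume
reading, masking and dataset-assembly path end to end.

# Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `epsilon` | 0.1 | CD learning rate; stable for [0,1] inputs at these sizes |
| `lam` | 0.1 | sparsity weight (per-example scale); 0 disables the penalty |
| `cd_steps` | 1 | CD-1, the standard training compromise |
| `epochs` | 30 | pretraining passes per layer at desk scale |
| `batch_size` | 16 | mini-batch size |
| `weight_init_sd` | 0.01 | $N(0, sd^2)$ weight init; biases start at 0 |
| `pca_threshold` | 0.90 | cumulative explained-variance target |
| `pca_max_k` | 20 | cap on retained components |
| `n_hidden_layers` | 3 | DBN depth |
| `hidden_size` | PCA dim | shared hidden width |
| `finetune_lr`, `finetune_epochs` | 0.1, 50 | full-batch gradient descent |
| `elm_L` | 10 × features, ≤ 1000 | ELM hidden width |
| `rcond` | 1e-10 | pseudoinverse singular-value cutoff |
| `n_folds`, `n_repeats` | 5, 200 | CV protocol (tests use 10 repeats) |

No momentum or weight decay is used anywhere — the reference design
mentions none.

# Numerical and degenerate-input choices

* Min-max normalization maps constant columns to 0 (avoids 0/0) and clips
  out-of-range test values into [0, 1].
* Zero-variance data yield a PCA model with zero components and a warning;
  a variance threshold unreachable with the available components returns
  all of them with a warning.
* Undefined sensitivity/specificity (empty class after prediction
  restriction) is reported as `NA` with a warning rather than silently as 0.
* Voxel flattening is fixed C-order (last axis fastest) and recorded in
  dataset metadata.
* Non-finite parameters or losses abort training with the epoch named.
* `exact_model_statistics()` uses a log-sum-exp partition function and is
  limited to $n_v + n_h \le 20$.

# Known limitations

* Gaussian visible units are not supported; inputs must be rescaled to
  [0, 1] and are treated as Bernoulli activation probabilities.
* Fine-tuning uses plain full-batch gradient descent; with the default
  small weight initialisation and short pretraining, deep stacks can sit on
  a small-gradient plateau, so its practical effect at desk scale is modest.
* The sparsity penalty, learning rates and epochs were never published for
  the reference design; all defaults here are package choices and may need
  retuning for real voxel-scale data.
* No persistent CD, parallel tempering, generative sampling, kernel or
  ridge ELM variants, and no hyperparameter search.
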