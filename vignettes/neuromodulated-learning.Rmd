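---
title: "Neuromodulated learning rules: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromodulated learning rules: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromod)
```

This package implements a family of learning systems modelled on the
neuromodulatory circuit of the insect mushroom body: sensory input is
lifted into a large, sparsely driven hidden population (the Kenyon-cell
expansion), the expansion converges onto a small set of output neurons
(the mushroom-body output neurons), and the plasticity of those
convergent synapses is not fixed but regulated — by a modulatory signal
carrying the output error in the shallow network, and by a
backpropagation-trained episodic trace in the deep one.  This vignette
explains each model, the parameters that matter, what the synthetic data
emulate, and the design decisions taken where the design was genuinely
open.

## 1. ModNet: the shallow modulatory network

### Model

ModNet is a three-layer network `n_in -> n_hidden -> n_out`.  The
input-to-hidden projection is **fixed sparse random** (uniform on
`[-1, 1]`, density `projection_density`); only the hidden-to-output
weights `w_ij` learn, as in a random-projection (ELM-style) classifier.
Hidden and output units use logistic activations.

During training each sample triggers, in order:

1. a forward pass: `x_j = sigmoid(W_proj input)`,
   `x_i = sigmoid(sum_j w_ij x_j)`;
2. the output error `e_i = onehot(label)_i - x_i`;
3. the modulatory activation `M_i = sum_j w'_ij e_j` — a second set of
   weights `w'` reads the error, playing the role of the dopaminergic
   valence signal;
4. an adaptive learning-rate update (below);
5. the gated Hebbian weight update
   `dw_ij = sigmoid(M_i / n) * eta_ij (b1 x_i x_j + b2 (x_j - x_i) + b3)`,
   where the sigmoid of the scaled modulatory activation is a pure
   *magnitude* gate in `(0, 1)` and the plasticity term carries the
   direction: a correlation term `b1`, a difference term `b2`, and a
   constant `b3` that lets a synapse move even with silent pre- and
   postsynaptic partners;
6. the modulatory-weight update `dw'_ij = eta'_ij * scale`.

Updates are strictly online (batch size 1) and training runs for two
epochs by default.  The presentation order is a seeded per-epoch
permutation: online Hebbian learning collapses if samples arrive grouped
by class, so an interleaved order is part of the training contract.

### The adaptive rate, and two readings the text leaves open

The adaptive rate couples the error and the output activation
divisively.  Two functional forms are implemented:

* `rate_form = "inverse"` (default): `eta_i = eta_in / (e_i x_i)`.
  Rates are *largest* where the error-activation product is smallest,
  i.e. on confidently wrong outputs; magnitudes are clipped at
  `eta_clip` (default `10 * eta_in`) because the quotient is singular,
  and a literal zero in `e_i` or `x_i` resets the rate to `eta_in`.
* `rate_form = "ratio"`: `eta_i = eta_in * e_i / x_i` — only the
  activation is divisive.

Both were evaluated on the separable benchmark below; the inverse form
learns (it is also the reading consistent with a fully divisive
description), the ratio form equilibrates all outputs at a common low
activation and never separates the classes, so inverse is the default.

A second open point is the *polarity* of the rate.  One reading changes
the sign per synapse as `sign(x_j - x_i) * sign(w_ij)` (available as
`polarity = "diff_weight"`); under it, the error influences only the
update magnitude, and in every configuration tried the modulatory
activations grow without bound while accuracy stays at chance — the
rich-get-richer drift has no corrective force.  The default
(`polarity = "error"`) keeps the sign the quotient inherits from the
error, which gives the rule its delta-rule-like character and is the
reading under which the network actually learns.

The modulatory weights use the same quotient with error and activation
exchanged; their update is `dw'_ij = mod_eta_in * e_i * x_i * scale`,
the literal product of the two stated influences (sign directly
correlated with the error, magnitude scaled by the output activation).
This product form matters: it vanishes as errors vanish, so the
modulatory weights — and with them the mean absolute modulatory
activation — settle as learning saturates, reproducing the
high-early / low-late modulation profile the architecture is designed
around.  A variant with error-independent magnitude drifts
monotonically instead.

### Defaults

| parameter | default | meaning |
|---|---|---|
| `n_hidden` | 1000 | hidden expansion size |
| `beta1, beta2, beta3` | 0.1, 0.2, 0.001 | correlation / difference / bias coefficients |
| `eta_in` | 0.01 | rate scale, within the tuned range 0.001–0.01 |
| `mod_eta_in` | 0.001 | modulatory rate scale (slow relative to `eta_in`) |
| `eta_clip` | `10 * eta_in` | singularity guard on the divisive rate |
| `n_scale` | 10 | divisor flattening the magnitude gate |
| `mod_scale` | 1 | modulatory update magnitude |
| `epochs` | 2 | training epochs |

`eta_in = 0.01` and `mod_eta_in = 0.001` were fixed once by calibrating
on the 10-class separable vector task (the only free choices the rule's
published range leaves open) and are not tuned per experiment.

## 2. Region attention, pruning, and compartments

### Activity factors

During training the hidden layer is split into `n_regions` contiguous
equal blocks.  Every `eval_period` samples (default 100) each region's
activity factor is computed from the window-mean activation of its
neurons: `A_k = mean(a_ik) / max(a_ik)` — the mean normalized by the
most active neuron of the region, 0 for a silent region.  Because the
normalizer is an extreme statistic, `A_k` drifts downward as regions
grow; region count should scale with layer size (about 100 neurons per
region) if thresholds are to keep their meaning.

Regions at or above `activity_threshold` are *active*: their pending
updates are applied scaled by `A_k`, boosting the busier regions.  (The
update equation can be read with a minus sign; the package implements
the boost reading consistent with the mechanism's stated purpose, and
`sign = "literal"` provides the subtractive variant.)  Regions below
threshold are *inhibited*: weights decay toward zero by `|A_k dw|` per
step, are clamped to exactly 0 when they cross it, and a clamped
connection is marked pruned and never revived.  The pruned fraction is
therefore non-decreasing by construction.

The default `activity_threshold` is 0.1, which on homogeneous random
projections prunes nothing (all `A_k ~ 0.8`) and preserves baseline
accuracy; thresholds approaching the typical `A_k` prune aggressively
(over half the connections on the benchmark task) at a cost of several
accuracy points.  The self-regulation property — dense and 50%-sparse
initializations converge to nearby final sparsity — holds because
pruning is driven by region activity, which does not depend on the
output-weight initialization.

### The compartmentalized network

The deeper variant inserts a second hidden layer.  Both hidden layers
are split into `n_compartments` (default 10); hidden1-to-hidden2 wiring
is block-diagonal-dominant (80% of connections within compartment) so
compartments are meaningful units.  Three rules run at once:

* the modulatory rule trains hidden2-to-output, with per-compartment
  attention and inhibition as above;
* the **slow covariance rule**
  `dw_ij = eta' (x_pre - s1)(x_post - s2) w_ij` trains
  hidden1-to-hidden2 every `n_slow` samples (default 100) from
  window-mean activations; it is multiplicative, so a zero weight is a
  fixed point and pruning is permanent here too;
* **gating**: a compartment whose net activity factor (the mean of its
  neurons' activity) stays below `gating_threshold` for two consecutive
  evaluations is masked — outputs forced to zero, updates skipped.  If
  every compartment gates off, training aborts with an error rather
  than silently producing a dead network.

One representational choice deserves note: the hidden2 drive is
computed from the *deviation* `h1 - s1` rather than from `h1` itself,
with the local weights scaled to give the pre-activations a usable
spread.  `s1` is exactly the baseline the covariance rule measures
correlations against; driving the next layer with raw `h1` buries the
class-dependent pattern under each unit's static offset (the readout
then learns at little better than chance), while the centred drive
carries pattern.  The covariance thresholds default to
`s1 = s2 = 0.5`, the midpoint of the logistic range.

## 3. The modulatory-trace plastic readout

### Model

For few-shot learning, plasticity moves into a single readout layer on
top of a convolutional embedding.  Every connection has a fixed (but
backpropagation-trained) weight `w_ij`, a trained plasticity
coefficient `delta_ij`, and an episodic trace `Mod_ij`, combined as
`W_tot = w + delta * Mod`.  The readout output is a softmax over
`W_tot x_in`; during support presentations the one-hot label is fed to
the output layer, implemented as a logit bonus (`clamp_bonus`, default
10) on the labelled unit, so the post-clamp output is effectively the
label and the trace binds the presented features to the correct unit.

The trace accumulates co-activations with an Oja-like self-limiting
term,

    Mod(t) = Mod(t-1) + alpha [x_out (x_in - x_out Mod(t-1))],

with a shared scalar rate
`alpha = gamma * sigmoid(sum(x_out) / n_out)` — the modulatory context
evaluating the overall network response.  For constant input and
output the recursion has the closed-form fixed point
`Mod* = x_in / x_out`, which bounds the trace and is verified in the
tests.  With softmax outputs the context term is constant within an
episode (the outputs sum to one); it remains the differentiable path
through which `gamma` learns its scale.  The trace resets to exactly
zero at every episode boundary; `w`, `delta`, `gamma` persist and are
the meta-learned parameters.

Gradients flow through the whole unrolled episode — the trace recursion
included — into `w`, `delta`, `gamma`, and the convolutional embedding.
The backward pass is written by hand (no autodiff framework is used)
and is checked against central finite differences to 1e-4 relative
error on toy episodes, as is the convolutional backward pass.

Initialization: `delta = 0.01` and `gamma = 0.02` everywhere (the
published operating point); `w` starts small (uniform, half-width
`w_scale = 0.05`).  The small start for `w` matters: episode labels are
freshly permuted every episode, so at the query step the fixed
component is class-uninformative noise that competes with the
`delta * Mod` binding term; a conventional Glorot-scale `w` drowns the
binding signal early in training and stalls meta-learning.

### Episodic protocol

`sample_episode()` draws N classes without replacement, K support
samples each plus one disjoint query from one of the N classes,
permutes labels to `0..N-1`, applies one rotation from
{0, 90, 180, 270} degrees per class (rotated variants act as distinct
classes), and shuffles the support order.  Training and test class
splits are disjoint and checked.  The full-scale plan
(`fewshot_plan()`) follows the published protocol: Adam at 3e-5,
decayed by 2/3 every 100,000 episodes over 500,000 episodes, evaluated
on 200 episodes of held-out classes.

### The desk-scale plan

`scaled_fewshot_plan()` is the configuration the test suite and the
acceptance script run: a 220-class glyph bank split 200/20, 20,000
episodes in meta-batches of 5 episodes per Adam step, learning rate
3e-3 decayed by 2/3 every 4,000 episodes (five milestones, mirroring
the full plan's structure), and a 16-filter embedding.  The embedding
width, batch size and learning rate were calibrated once for this
problem size; the parameter-count accounting always uses the standard
64-filter embedding, which with a 5-way readout has exactly
640 + 3×36,928 + 320 + 320 + 1 = 112,065 trainable scalars
(convolution biases included, batch normalization without learnable
affine, bias-free readout, one global `gamma`).

Batch normalization uses batch statistics at training and evaluation
alike (no running averages) — the convention of episodic few-shot
pipelines; evaluation batches 50 episodes per step so the statistics
are well-mixed, and results are deterministic under the plan seed.

## 4. Fixed-point inference

`qformat()` describes a signed fixed-point grid; the default Q6.10 uses
16 bits with a 6-bit signed integer part, step `2^-10`, range about
`[-32, 32)`.  Rounding is nearest with ties away from zero, saturating
at the range ends.  `quantized_matmul()` emulates integer
multiply-accumulate: products of fixed-point integers accumulate into a
32-bit saturating partial sum which is then rounded back to the storage
format.  The emulation is exact (doubles represent the partial sums
exactly) for accumulators up to 53 bits; wider accumulators — needed
only for the high-precision control configurations — fall back to
unsaturated floating-point accumulation, which is the same arithmetic
at that precision.

The quantized forward path computes logistic activations through the
four-segment piecewise-linear tanh (`pla_tanh`, maximum deviation from
tanh below 0.09 on `[-4, 4]`) via `sigmoid(x) = (1 + tanh(x/2)) / 2`,
and rounds each layer's outputs to the storage format.  The output
layer can be kept in floating point; on the trained benchmark model
this configuration tracks full-precision accuracy, while quantizing the
output layer can be catastrophic — its logits sit deep in the saturated
tail of the piecewise-linear sigmoid, where a 16-bit grid collapses the
ordering.  That asymmetry (and its direction) is asserted in the tests.
`precision_sweep()` repeats inference across storage widths at a fixed
6-bit integer part; accuracy degrades at coarse widths and plateaus
once the grid outresolves the weights, with fluctuations within
evaluation noise (about a percentage point) on the plateau.

## 5. The synthetic data: what it emulates, and what it does not

`make_vector_task()` draws class means as orthonormal directions scaled
so all pairwise distances equal `separation`, plus isotropic Gaussian
noise — a maximally symmetric stand-in for "easy benchmark image
classes" with a closed-form difficulty dial.  The nearest-class-mean
accuracy (`nearest_mean_accuracy()`) is the Bayes-like reference: at
the default 10 classes / separation 6 / unit noise it is about 0.988
(union bound `1 - 9 pnorm(-3)`), monotone in `separation`.

`make_glyph_bank()` emulates the class/sample structure of
handwritten-character corpora: each class is a prototype of 2–5 random
quadratic strokes; samples jitter the prototype (rotation up to 10
degrees, translation up to 2 px, up to 1% pixel flips).  Within-class
pixel correlation exceeds between-prototype correlation, and a raw-pixel
nearest-neighbour already solves 5-way 1-shot at well above chance —
the structure, not the stroke statistics, is what is reproduced.
Neither generator models stroke dynamics, writer identity, ink texture,
or class imbalance, so passing results here demonstrate that the
*mechanisms* work (binding, pruning, gating, quantization robustness),
not that the published benchmark accuracies transfer.

## 6. Numerical and degenerate-input conventions

* `sign(0)` is `+1` in the polarity rules; `sign()` proper (0 at 0) is
  used where a zero must gate an update off entirely.
* The divisive rate is clipped symmetrically at `eta_clip`; a literal
  zero in error or activation resets to `eta_in` per the rule's stated
  special case.
* Ties in `argmax` classification resolve to the first index.
* An all-zero region has activity factor 0; an empty region is an
  error.
* Weight decay under inhibition clamps on the zero crossing, so pruned
  weights are exactly 0, not denormal residue.
* Checkpoints serialize uncompressed, so save→load→save round-trips
  byte-identically.

## 7. Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run: the 10-class, 100-dim
separable task (200 samples/class, 2 epochs, 5 seeds); attention and
compartment runs at 300 hidden units with a biting threshold (0.75);
the 220-class glyph bank with the desk-scale episodic plan above (3
seeds in the suite, 1 in the script); and the quantization checks on
the trained benchmark model.  These sizes are the package's reference
configuration for demonstrating the mechanisms at desk scale; the
full-scale protocol objects (`fewshot_plan()`, 64-filter
`conv_config()`) are provided for users who want to run the published
configuration on the real corpora via `read_idx()` /
`read_image_folder()`.

## 8. Known limitations

* The ModNet rule as published leaves the rate form, polarity rule and
  modulatory magnitude underdetermined; the package fixes them as
  described above and exposes the rejected readings as options.  Other
  resolutions may behave differently.
* Output activations under the inverse rate rule collapse toward zero
  rather than calibrating to one-hot targets; classification is by
  argmax margin, and per-sample errors do not vanish even when accuracy
  is high.
* Compartment gating depends on activity heterogeneity; on perfectly
  homogeneous synthetic input no compartment ever gates, so gating is
  exercised through constructed silent populations.
* The trace readout assumes the embedding output is non-negative and
  roughly norm-comparable across classes (ReLU features); with raw
  unnormalized features the binding term inherits a norm bias that
  only embedding training removes — a frozen random embedding needs
  the full 64-filter width to beat chance.
* Fixed-point emulation targets inference only; quantization-aware
  training is out of scope.
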