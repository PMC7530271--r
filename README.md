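# neuromod

Neuromodulation-inspired learning systems in R, modelled on the insect
mushroom body: sensory input is expanded into a large random hidden code
(the Kenyon-cell lift), the expansion converges onto a few output
neurons, and the *plasticity* of those convergent synapses — not just
their weights — is itself regulated.  The package implements four such
mechanisms as tested, reusable components:

* **ModNet** — a shallow classifier with a fixed random projection whose
  hidden-to-output weights learn by a gated Hebbian rule,
  `dw_ij = sigmoid(M_i / n) * eta_ij (b1 x_i x_j + b2 (x_j - x_i) + b3)`,
  where the gate `M_i = sum_j w'_ij e_j` is a modulatory activation
  driven by the output error and `eta_ij` is an adaptive, error-divisive
  learning rate.  It trains online and reaches its working accuracy
  within two epochs.
* **Region attention and compartments** — hidden regions are scored by
  an activity factor `A_k = mean(a_ik) / max(a_ik)`; active regions have
  their updates boosted by `A_k`, inactive regions decay to exactly zero
  and are pruned.  A two-hidden-layer variant splits both layers into
  compartments wired block-diagonally, trains the local connections with
  a slow covariance rule `dw = eta' (x_pre - s1)(x_post - s2) w`, and
  gates persistently silent compartments off.
* **Modulatory-trace plastic readout** — for N-way K-shot episodic
  learning: every readout connection carries a fixed weight `w`, a
  plasticity coefficient `delta`, and an episodic trace updated as
  `Mod += alpha * x_out (x_in - x_out Mod)` with
  `alpha = gamma * sigmoid(sum(x_out)/n)`.  The effective weight is
  `w + delta * Mod`; labels are clamped during support presentations so
  the trace binds features to the right output within a single episode,
  and `w`, `delta`, `gamma` plus a small convolutional embedding are
  meta-trained by backpropagation through the unrolled episode (the
  backward pass is hand-written and finite-difference checked).
* **Fixed-point inference** — Q6.10 (16-bit, 10 fractional bits)
  quantization with 32-bit saturating accumulators and a four-segment
  piecewise-linear tanh, plus a bit-precision sweep.

Synthetic generators (separable Gaussian vector tasks; procedural glyph
banks with many classes and few jittered samples per class) make every
mechanism testable offline; IDX and image-folder readers accept the real
benchmark formats.

## A worked example

```r
library(neuromod)

task <- make_vector_task(10, 100, 200, separation = 6, noise_sd = 1, seed = 1)
cfg  <- modnet_config(n_in = 100, n_out = 10, seed = 1)
res  <- modnet_train(modnet_init(cfg), task)
held <- sample_vector_task(task, 50, seed = 1001)
modnet_accuracy(res$state, held)
#> [1] 0.956
head(res$history[, c("samples", "accuracy", "mean_abs_M")], 3)
#>   samples accuracy mean_abs_M
#> 1     100     0.12 0.05362710
#> 2     200     0.19 0.05008203
#> 3     300     0.28 0.05060715
```

Ten classes of 100-dimensional Gaussians at separation 6 are almost
perfectly separable (the nearest-mean reference is ≈ 0.99).  The
history tracks the running training accuracy per 100 online samples as
it climbs from chance, and ModNet reaches 0.956 held-out accuracy
after two epochs; the mean absolute modulatory activation `|M|` is at
its largest over the first hundred samples and settles as the error
shrinks — the modulatory layer rewards and penalizes hardest early in
training.

Few-shot learning on a synthetic glyph bank (200 training classes, 20
held-out classes, 5-way 1-shot):

```r
bank <- make_glyph_bank(220, 20, 28, seed = 3)
fs <- train_fewshot(bank, scaled_fewshot_plan(seed = 1),
                    train_classes = 0:199, test_classes = 200:219)
fs$eval$accuracy
#> [1] 0.895
evaluate_fewshot(fs$model, bank, 200:219, episodes = 200, seed = 99,
                 delta_zero = TRUE)$accuracy
#> [1] 0.145
```

After 20,000 training episodes the query accuracy on unseen classes is
0.895; forcing the plasticity coefficients to zero collapses it to
chance (0.2), showing the association is carried by the episodic trace,
not the fixed weights.  The standard 64-filter embedding with a 5-way
plastic readout has exactly `count_parameters(conv_config(), 5)` =
112,065 trainable parameters.

## Command line

A thin dispatcher over the same functions is installed at
`system.file("cli", "neuromod", package = "neuromod")`:

```sh
neuromod gen-data      --config cfg.yaml --seed 1 --out-dir out/
neuromod train-modnet  --config cfg.yaml --seed 1 --out-dir out/
neuromod train-fewshot --config cfg.yaml --seed 1 --out-dir out/
neuromod quantize-eval --config cfg.yaml --seed 1 --out-dir out/
```

Each run writes its resolved configuration and a log beside its results.

## Scope

The package implements the learning mechanisms and their evaluation
harnesses at desk scale.  Full-scale benchmark runs (the 500,000-episode
episodic protocol, the real handwritten-character corpora) are supported
through `fewshot_plan()`, `read_idx()` and `read_image_folder()` but are
not downloaded or executed by the tests.
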