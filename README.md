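# spikeseg

Three-stage training of spiking U-Nets for biomedical image segmentation, in R.

## The problem

Spiking neural networks (SNNs) communicate through discrete spike events over
simulated time steps. Because a neuron only consumes energy when it fires,
SNNs are a promising low-power substrate for always-on and edge medical
imaging — but they are hard to train: the spike nonlinearity has zero
derivative almost everywhere. For segmentation of small brain structures such
as the hippocampus from MR image crops, the two standard routes both
disappoint. Converting a trained ReLU network needs thousands of simulation
steps before firing rates faithfully approximate activations, and training an
SNN from scratch with surrogate gradients converges slowly.

`spikeseg` implements the hybrid scheme that takes the best of both, for
U-shaped fully-convolutional networks:

1. **ANN training.** A conversion-friendly U-Net (average pooling, no biases,
   no batch-norm, dropout, sigmoid pixel head) is trained to convergence.
2. **Early-stop conversion.** Weights are copied into a spiking twin built
   from the same declarative spec; per-layer firing thresholds start at 1 and
   are balanced sequentially (SpikeNorm) with a deliberately *short*
   calibration simulation.
3. **Spike-based fine-tuning.** The converted network is trained with
   surrogate-gradient backpropagation through time, recovering near-ANN
   accuracy at a small time-step budget and converging far faster than direct
   SNN training.

Synthetic MRI-like hippocampus-crop volumes (NIfTI in/out) make every stage
testable without any external data.

## The model in brief

Hidden units are integrate-and-fire neurons with subtractive reset: with
weighted input `z_t` and threshold `v > 0`,

    m_t = u_{t-1} + z_t,   s_t = 1[m_t > v],   u_t = m_t - v * s_t

Output-layer neurons never fire; they accumulate `u_t = u_{t-1} + z_t`, and
the probability map is the sigmoid of the rate-decoded final potential.
Inputs are Poisson rate-coded — binary spikes `{0,1}` for `[0,1]`-normalized
images, ternary spikes `{-1,0,1}` for zero-mean normalization. Training uses
BCE, Dice, or the weighted combination `0.3*BCE + 0.7*Dice`, and the backward
pass substitutes the linear surrogate

    ds/dm  ≈  alpha * max(0, 1 - |m - v|)

for the spike derivative. Conversion sets each threshold to the maximum
weighted input observed at that layer during a short calibration run, layer by
layer in topological order. See the vignette
(`vignettes/three-stage-spiking-unet.Rmd`) for assumptions, parameter tables
and design rationale.

## Worked example

```r
library(spikeseg)

res <- run_three_stage_experiment(seed = 1)

res$ann_report
#> Dice @ threshold 0.50: 2D 0.9722 +/- 0.0207 (64 slices), 3D 0.9722 +/- 0.0207 (64 subjects)
res$converted_report
#> Dice @ threshold 0.50: 2D 0.8560 +/- 0.0306 (64 slices), 3D 0.8560 +/- 0.0306 (64 subjects)
res$finetuned_report
#> Dice @ threshold 0.50: 2D 0.9471 +/- 0.0279 (64 slices), 3D 0.9471 +/- 0.0279 (64 subjects)

res$convergence$table
#>   batch  finetune    direct
#> 1     8 0.8813304 0.1255516
#> 2    16 0.9143329 0.1984634
#> 3    24 0.9469867 0.2643569
res$convergence$crossing
#> finetune   direct
#>        8       NA
```

Reading: on 256 synthetic 32×48 slices (192 train / 64 test), the ANN reaches
a 2D Dice of 0.972. Early-stop conversion at `T = 32` time steps drops it to
0.856 — the characteristic conversion loss at a small step budget. Three
epochs of surrogate-gradient fine-tuning bring it back to 0.947 (97% of the
ANN, within 24 batches), while direct training from scratch is still at Dice
0.26 at batch 24 and never reaches Dice 0.8 within its 64-batch budget
(`crossing = NA`). `res$firing_before` / `res$firing_after` show the
per-layer firing rates rising after fine-tuning — the mechanism behind the
recovery. (Dice values for seeds other than 1 differ in the third decimal;
single-slice subjects make the 2D and 3D scores coincide by construction.)

Individual stages are plain functions returning classed objects with
`print`/`predict`/`plot` methods:

```r
spec <- network_spec(c(32, 48), levels = 2, channels = c(4, 8), bottleneck = 16)
ann  <- train_ann(build_ann(spec, seed = 1), images, masks, run_config("ann"))
snn0 <- convert(ann, calibration_images, conversion_config(T_balance = 200))
snn  <- finetune_snn(snn0, images, masks, run_config("finetune", T_train = 200))
evaluate_model(snn, test_volumes)
threshold_sweep(snn, test_volumes)        # Dice across decision thresholds
firing_frequencies(snn, test_images)      # per-layer spiking activity
```

A thin command-line wrapper over these functions, including NIfTI data
generation, lives at `inst/cli/spikeseg.R`
(`Rscript inst/cli/spikeseg.R gen-data --n 8 --dir data`, then `train-ann`,
`convert`, `finetune`, `evaluate`, ...).

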