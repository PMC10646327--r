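---
title: "Three-stage training of spiking U-Nets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage training of spiking U-Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spiking neural networks (SNNs) transmit information as discrete spike events
over simulated time, which makes them attractive for low-power neuromorphic
hardware but hard to train: the spike nonlinearity has zero derivative almost
everywhere. For dense prediction tasks such as segmenting the hippocampus from
MR image crops, two standard workarounds both have costs. Converting a trained
ReLU network into an SNN needs very many simulation time steps before firing
rates approximate the ReLU activations well, and training an SNN from scratch
with surrogate gradients is slow and brittle. This package implements the
hybrid, three-stage alternative for U-shaped segmentation networks:

1. **ANN training** — a conversion-friendly ReLU U-Net is trained to
   convergence on (image, mask) slices with standard minibatch Adam;
2. **early-stop conversion** — the weights are copied into a spiking twin of
   the network and the per-layer firing thresholds are balanced with a
   deliberately *short* calibration simulation;
3. **spike-based fine-tuning** — the converted network is trained further with
   surrogate-gradient backpropagation through time (BPTT), recovering
   near-ANN accuracy at a small time-step budget.

### Neuron model

Hidden units are integrate-and-fire (IF) neurons with subtractive (soft)
reset. With membrane potential $u$, per-step weighted input $z_t$ and layer
threshold $v > 0$:

$$m_t = u_{t-1} + z_t,\qquad
  s_t = \mathbb{1}[m_t > v],\qquad
  u_t = m_t - v\,s_t .$$

The potential never decays (no leak) and firing requires *strictly* exceeding
the threshold. Integration, comparison and subtraction happen within one step,
so a neuron never carries a super-threshold potential across steps; this is
the convention under which the standard rate-code analysis of conversion
holds, and it satisfies the exact conservation law
$u_T = \sum_t z_t - v\,N_{\text{spikes}}$ that the test suite checks to
`1e-6`. Output-layer neurons (one per pixel) never fire: they accumulate
$u_t = u_{t-1} + z_t$, and a sigmoid of the scaled final potential gives the
per-pixel foreground probability.

### Rate coding

Inputs are Poisson rate-coded: at each step a uniform draw on $[0,1)$ is
compared with the target value and a spike is emitted when the draw falls
below it, so the expected firing rate equals $|x|$. Images normalized to
$[0,1]$ yield binary spikes $\{0,1\}$; zero-mean normalization to $[-1,1]$
yields *ternary* spikes $\{-1,0,1\}$, where the spike carries the sign of the
value. Out-of-range encoder inputs are rejected rather than clipped — silent
clipping would mask exactly the normalization mistakes the binary/ternary
comparison is about. Hidden layers always emit binary spikes regardless of the
encoder; only the input lines can go negative.

### Architecture constraints

Both builds share one declarative `network_spec()`: convolutions without
biases, no batch normalization, average pooling only, transposed-convolution
upsampling, skip connections concatenating encoder and decoder feature maps,
and a 1×1 convolution + sigmoid head the same size as the input. Biases and
batch-norm would interact with the firing thresholds after conversion, and
max-pooling has no faithful rate-coded equivalent; the spec constructor
rejects such requests outright rather than silently adapting them. Dropout
layers provide regularization for both ANN and SNN training.

### Losses

Three interchangeable losses: pixel-mean binary cross-entropy (predictions
clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-5}$), the
smoothed Dice loss $1 - (2\sum s r + \varepsilon)/(\sum s + \sum r +
\varepsilon)$ computed per sample and averaged, and their weighted combination
$0.3\,L_{\mathrm{BCE}} + 0.7\,L_{\mathrm{Dice}}$ (the default). The Dice
*ratio* itself (higher is better) is also the evaluation metric, reported both
slice-wise ("2D") and per-subject on re-stacked volumes ("3D").

### Conversion: SpikeNorm threshold balancing

After a pure weight copy all thresholds start at 1. Layers are then balanced
sequentially in topological order: the network is simulated for `T_balance`
steps on a calibration batch with all *earlier* thresholds already balanced,
and the layer's threshold is set to the maximum weighted input any of its
neurons receives at any step (optionally a percentile, which is less
outlier-sensitive on noisy synthetic data), times a configurable scale.
Sequential processing matters: the statistic at layer $l$ must reflect actual
spiking inputs under the thresholds the earlier layers will really use. The
output layer has no threshold and is excluded. "Early stop" simply means a
small `T_balance` budget (200 at full scale); there is no convergence
criterion — the budget is the stop. A layer that never receives positive
drive keeps threshold 1 with a warning.

### Surrogate-gradient fine-tuning

The fine-tuning forward pass unrolls the spiking simulation for `T_train`
steps; the loss is computed once, on the sigmoid of the scaled accumulated
output. The backward pass runs through all time steps, substituting the linear
hat

$$\frac{\partial s}{\partial m} \approx \alpha \max\{0,\ 1 - |m - v|\}$$

for the spike derivative at every hidden neuron (the output layer is a plain
summation and needs no surrogate). The reverse-time recurrence per IF layer is
$\mathrm{d}m_t = \mathrm{d}s_t\,g_t + \mathrm{d}u_t (1 - v\,g_t)$ with
$g_t$ the surrogate evaluated at the stored pre-reset membrane. The
implementation is verified against an independent forward-mode (dual-number)
differentiation of the unrolled graph, exactly, for both dense and
convolutional networks. Thresholds are frozen during fine-tuning — the weights
adjust *to* the thresholds. Direct training (the baseline) runs the identical
loop from random weights with thresholds fixed at 1.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `lr` | 0.001 | initial Adam rate for all stages (protocol value), reduced on plateau |
| `batch_size` | 26 | minibatch size for training and evaluation (protocol value) |
| ANN `epochs` | 100 | full-scale stage-1 budget (protocol value); 25 on the toy task |
| SNN `epochs` | 35 | full-scale stage-3 budget (protocol value); 3 on the toy task |
| `T_balance` | 200 | early-stop conversion budget (protocol value); 32 on the toy task |
| `T_train` | = conversion `T` | one knob for fine-tuning and inference time steps |
| `alpha` | 0.3 | surrogate hat scale; the source model leaves it a free constant |
| `epsilon` | 1e-5 | BCE clamp and Dice smoother |
| loss weights | 0.3 / 0.7 | BCE / Dice in the combined loss |
| `threshold_scale` | 1.0 | multiplier on balanced thresholds (sweep knob) |
| `dropout` | 0.1 | per-block dropout rate |
| plateau `patience`/`factor` | 5 / 0.1 | reduce-on-plateau schedule; **not** protocol values, package defaults |

## Numerical and design choices

**Output scale (rate decoding).** The obvious probability readout
`sigmoid(u_out / T)` turned out to be wrong once thresholds are balanced: a
spiking layer with threshold $v_l$ transmits roughly $\text{activation}/v_l$,
so the accumulated output potential carries the ANN logit *attenuated by the
product of all thresholds* (two orders of magnitude on the toy network). The
probabilities then collapse toward 0.5, the training loss is flat, and
fine-tuning can wander. The default readout is therefore
`sigmoid(u_out * prod(v) / T)` — decoding the rate code back onto the ANN's
logit scale. This is a monotone transform (converted-network Dice at the 0.5
threshold is unchanged) that restores a usable loss landscape; with unit
thresholds (direct training) it reduces to the plain time average. The scale
remains exposed as configuration.

**Firing order.** The printed IF recurrences in the conversion literature are
ambiguous about whether the reset uses the previous or the current step's
spike; we integrate, compare and subtract within the same step (see above) and
document that choice rather than leaving it implicit.

**Dropout in the SNN.** One mask per sample, held fixed across all `T` steps —
a mask resampled per step would destroy the rate code the network is supposed
to carry. Masked spikes are zeroed *without* the usual 1/(1-p) rescale:
rescaling would place non-binary values on the spike lines and break the
invariant that hidden activity is exactly {0,1}. Dropout is off during
evaluation and balancing, so conversion calibration is unaffected; during
training this behaves like a mild (≈10%) rate attenuation, which is part of
the regularization.

**Toy architecture sizing.** The default desk-scale network has 2 encoder
levels with 4/8 channels and a 16-channel bottleneck on 32×48 inputs. The
decoder convolutions after skip-concatenation dominate the BPTT cost, and this
size keeps the full three-seed, three-stage experiment within a desk-scale
compute budget while still reaching ANN Dice ≥ 0.95 on the synthetic task.
Larger configurations (and the full 24×56×48 crop geometry) are plain
`network_spec()` / `synth_config()` arguments away.

**Toy experiment sizes.** The reference toy study uses 256 single-slice
subjects (192 train / 64 test via subject-level folds), 25 ANN epochs, T = 32
for balancing, fine-tuning and inference, 3 fine-tuning epochs, 8
direct-training epochs, and evaluation checkpoints every 8 batches. Single
slices make the 2D and 3D Dice coincide, which the tests exploit as a
consistency check.

**Strict decision threshold.** Pixels are labeled foreground when
`p > threshold` (strictly), matching the strict spike comparison; an all-0.5
probability map at threshold 0.5 therefore predicts all-background. Slices
where both prediction and ground truth are empty are excluded from the 2D
mean — the smoothing term would score them 1.0 and inflate the average; this
is a convention of this package and is stated here because the evaluation
protocol it mimics does not specify the case.

**Determinism.** Every stochastic component (volume synthesis, batch
shuffling, dropout masks, Poisson encodings) draws from R's RNG seeded from
the relevant config, and same-seed runs are bit-reproducible; the test suite
asserts this for the generator, the encoders, balancing and both training
loops.

## What the synthetic generator does and does not emulate

`generate_volume()` produces a bright, smooth, roughly ellipsoidal foreground
at a jittered but consistent position (semi-axes ≈ 0.2 of each dimension,
±10% jitter, a low-frequency boundary deformation) over a darker background,
plus i.i.d. Gaussian noise and a smooth multiplicative bias field mimicking MR
intensity inhomogeneity; the mask is the noiseless foreground support. The
default geometry is the 24×56×48 hippocampus crop with a 2–8% foreground
fraction. It does **not** emulate Rician noise statistics, partial-volume
effects, multi-structure anatomy, inter-subject registration error, or
scanner-protocol variation. Passing tests therefore certify the *mechanics*
of the training scheme — conversion fidelity, recovery by fine-tuning,
convergence advantage, firing-rate shifts — not clinical segmentation
performance on real MRI.

The toy classification generator emits k oriented-bar classes, min-max
normalized to [0,1] and re-emitted as 2x−1 zero-mean twins of the *same*
samples, so binary and ternary encoders can be compared with everything else
held fixed. At the default noise level the task is easy enough that both
converted classifiers typically saturate; the comparison checks that ternary
encoding is never the worse choice, not that it dominates.

## Known limitations

- IF neurons only: no leak, refractoriness, adaptive thresholds, or temporal
  codes beyond rate coding.
- Conversion is data-driven SpikeNorm; weight-normalization-only ("data-free")
  conversion and bias/batch-norm absorption are out of scope, as the
  architecture has neither biases nor batch-norm.
- BPTT stores the full spike/membrane trace (memory scales with `T ×` network
  size); a truncation window for memory-constrained runs is deliberately not
  the default.
- The Dice-vs-threshold sweep reports the fine 0.43–0.54 grid by default; the
  equivalence "threshold t ≡ scaling outputs by 0.5/t" is exact on the
  probability scale and is asserted as an identity there, but re-scaling
  *logits* through a sigmoid is not equivalent — the caveat applies if the
  sweep is interpreted on the logit scale.
- 2D slice models only (slices of 3D crops); no 3D convolutions.
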