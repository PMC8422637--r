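---
title: "Fixed-point inference and accelerator simulation for 3D U-Net segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-point inference and accelerator simulation for 3D U-Net segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain-tumor segmentation networks of the 3D U-Net family are deployed on
FPGA accelerators in 8-bit integer arithmetic. Three transformations
separate the trained floating-point network from what the hardware
executes: batch-normalization (BN) layers are folded into the preceding
convolutions; parameters and activations are quantized to signed 8-bit
fixed-point codes with power-of-two scale factors; and each layer is cut
into computation blocks that fit on-chip memory and flow through a
four-stage instruction pipeline. quantseg implements all three so the
integer pipeline can be validated bit for bit in software.

This vignette records the model, the tunable parameters, and the design
decisions taken where the problem statement leaves the choice open.

## Network model

A `unet_graph` is an ordered acyclic list of typed layers (`conv`,
`deconv`, `bn`, `relu`, `maxpool`, `concat`) with explicit predecessor
ids. `build_unet3d(channels_base, depth_levels, in_channels, out_classes)`
emits the encoder--decoder topology with:

* two 3×3×3 conv--BN--ReLU blocks per level, channel widths doubling per
  level (`channels_base * 2^(level-1)`). With base 32 and 4 input
  modalities the channel patterns are 4→32, 32→32, 32→64, 64→64, … — these
  are exactly the three channel shapes the modelled PE array supports.
  The figure-level description of the reference topology does not pin the
  second convolution's width; this pattern was chosen once because it
  realizes all three PE modes.
* "same" zero-padding 1 on all 3×3×3 convolutions, so skip and upsampled
  branches have equal spatial shape without cropping.
* deconvolution = transposed convolution with kernel 2×2×2, stride 2,
  padding 0: each spatial axis doubles exactly.
* concatenation order: skip-connection channels first, upsampled channels
  second (a fixed order is needed for reproducible weights).
* a 1×1×1 classifier convolution. Probabilities are never materialized:
  per-voxel argmax on scores equals argmax on softmax outputs (softmax is
  monotone), with ties broken toward the lowest class index.
* axis order (batch, channel, depth, height, width) everywhere.

`infer_float()` is the double-precision reference; every other execution
path in the package is tested against it (or against bit-exact equality
with `infer_int8()`).

## BN folding

For `Y = W·X + B` followed by BN with per-channel statistics μ, σ², scale
γ, offset β and stabilizer ε:

$$W' = W\,\frac{\gamma}{\sqrt{\sigma^2+\varepsilon}},\qquad
  B' = (B-\mu)\,\frac{\gamma}{\sqrt{\sigma^2+\varepsilon}} + \beta.$$

The `+ β` term is required for the folded layer to reproduce conv-then-BN
(the defining property of the merge, enforced by the test suite on random
conv/deconv--BN--input triples at 1e-5 relative tolerance); a published
form of the bias merge that omits β does not satisfy that property and is
treated as a typographical slip. When a stored BN record carries no ε the
common framework default 1e-5 is used; ε's only role is keeping the
denominator positive, and results are insensitive at that scale.

Folding requires each BN layer to directly follow a conv or deconv layer;
anything else is a structural error, never a silent skip. The operation is
idempotent.

## Quantization

All scale factors are powers of two, so scaling is a bit shift on
hardware. For a tensor with maximum absolute value *m* and bit width
`b_w = 8`:

$$b_s = b_w - 1 - \lceil \log_2 m \rceil,$$

and codes are `clamp(round(x · 2^{b_s}), −128, 127)`. Numerical choices:

* **Rounding** is round-half-away-from-zero everywhere (quantization and
  requantization shifts): it matches the arithmetic-shift-plus-offset
  hardware idiom, and fixing one rule everywhere is what makes the
  pipeline bit-reproducible.
* **`m = 0`** (an all-zero tensor): `b_s = b_w − 1` by convention — any
  scale represents the zero tensor exactly, and this avoids `log2(0)`.
* **Exact powers of two**: `m = 2^k` gives `m · 2^{b_s} = 128`, which
  saturates to 127. The formula is followed literally; only elements at
  the maximum can saturate, and every non-saturated element has error at
  most half a step, `2^{-b_s-1}`.
* **Schemes are per tensor**, not per channel; weight and bias scales are
  computed separately per layer, activation scales per layer input and
  output.

Activation ranges come from `calibrate()`: the folded float network is run
on a small set of representative volumes (two, in the full-scale workflow) and the
running per-layer max-|input| and max-|output| are recorded. Calibration
deliberately uses the float network, not the quantized one — it emulates
the "training mode" pass that precedes quantized evaluation.

In `quantize_network()`, ReLU and max-pooling pass their incoming scheme
through unchanged (requantizing at a code-preserving operation would only
risk clamping), and a concatenation requantizes both branches to the
coarser (smaller `b_s`) scheme, which cannot overflow. Edges whose
producer and consumer schemes differ carry explicit requantization shifts.

## Integer inference

`infer_int8()` carries integer values in doubles (exact far beyond the
ranges used) and emulates:

* int8×int8 multiplies accumulated at scale `2^{b_s,in} + b_s,w`; the
  accumulator is modelled as 32-bit signed and *checked*: exceeding it is
  an error, not a wrap. The width is an assumption; the test suite
  compares 50 random quantized networks against an unbounded-precision
  reimplementation bit for bit, confirming no hidden overflow at these
  scales.
* int8 bias codes shifted to the accumulator scale before addition,
* requantization to the output scheme by an arithmetic shift with the
  rounding rule above, then clamping,
* ReLU as `max(0, code)`, max pooling as integer max.

Every 3D convolution — float or integer — is computed by depth-slice
decomposition: the kd×kh×kw kernel splits into kd 2-D kernels, each
convolves its input slice, and partial results accumulate slice-major
(slice 0 fully accumulated before slice 1, mirroring per-block hardware
accumulation). For integers this equals direct 3-D convolution exactly;
for floats to rounding error. Deconvolution is realized as zero-insertion
upsampling followed by convolution with the spatially flipped kernel —
the construction that explains the characteristic sparsity of
deconvolution outputs.

## Accelerator model

`simulate_accelerator()` is a behavioural + timing model, parametric in a
`resource_config`: on-chip input/parameter/output capacities (bytes),
multiplier count, load and write-back bandwidths (bytes/cycle), and a
fixed configuration cost (cycles). No cycle counts are published for the
modelled chip, so stage costs are linear in bytes and MACs with these
configurable coefficients; the model is validated by its invariants
(ordering, overlap, preservation of values), not by absolute times.

* **PE modes**: 4-32 (4 pixels/issue), 32-32 (2), 32-64 (1). Layers whose
  channels match none of the modes are padded with zero channels to the
  nearest mode; padded lanes count as idle in the utilization report.
* **Partitioning**: layer outputs are tiled channel-group-major, then z,
  y, x ascending (a deterministic order); the spatial tile is halved
  along its largest axis (ties: depth, height, width) until input region,
  parameters and output all fit. Shrinking any capacity can only increase
  the block count. A single minimal block that does not fit is an
  infeasible-partition error naming the layer.
* **Execution discipline** is layer by layer: no instruction of layer
  k+1 enters EX before all layer-k write-backs complete; under double
  buffering the next instruction's CF/LD may prefetch. CF is issued per
  block (whether hardware amortizes CF across a layer is unstated; per
  block is the conservative choice).
* **Double buffering** splits each memory into two disjoint ping-pong
  banks, so partitioning runs against the half capacities; at most two
  instructions are in flight. For N uniform instructions with dominant EX
  (e ≥ c+l+w) the makespan is exactly c + l + N·e + w.
* **Zero-block skipping** is detected per computation block on the
  block's entire required input region. A skipped block's output is the
  bias-only value — the convolution of a zero region is the aligned,
  requantized bias, not zero — which is what makes skipping bit-exact.
  Skipped blocks issue no instruction.
* **Instruction format**: fixed-width little-endian fields (opcode, mode,
  scheduling layer, four stage costs, four addresses) behind a versioned
  header; the hardware's own format is unpublished, so this one is
  documented and round-trip tested.
* ReLU, max pooling and concatenation are computed exactly by the integer
  engine but treated as fused (not partitioned or timed); the PE array
  computes only conv/deconv blocks.

The simulated scores are bit-identical to `infer_int8()` for every
partition, ordering, and skipping decision — partitioning changes the
schedule, never the values — and the scheduler is checked against an
independent event-driven simulator.

## Synthetic phantoms and the toy fit

`make_phantom()` emulates the structure of a four-modality (flair, t1,
t2, t1ce) brain MRI at toy scale: spherical "tumor" blobs with smooth
intensity falloff and additive Gaussian noise over a noisy "brain"
background, surrounded by an exactly-zero outer shell. The zero shell
covers a requested fraction of the background voxels (default 0.7, the
average sparsity of such images), hit exactly by ranking background
voxels on radius. The shell is contiguous *by construction*: real MRI
background is contiguous air, and only contiguous zeros can ever make a
whole computation block skippable — independently scattered zeros would
make the zero-skip mechanism untestable. Defaults: 16³ voxels, two blobs
of radius 3–5 voxels, tumor/background intensity means of roughly
0.7–0.9 vs 0.25–0.32 (arbitrary units) with noise s.d. 0.04 — strong but
not clean contrast, chosen once as a plausible toy analogue of tumor
conspicuity across modalities.

What the phantoms do **not** emulate: MRI physics (bias fields, Rician
noise), anatomical texture, multi-class tumor substructure, or BraTS file
layouts beyond modality naming. Passing tests on phantoms therefore
demonstrate the correctness and near-losslessness of the *pipeline*, not
clinical-grade segmentation accuracy.

`make_random_network()` uses a delta-orthogonal-style initialization
(identity-passing centre tap plus fan-in-scaled Gaussian noise, zero
biases, BN variances in [0.5, 1.5]) so that the frozen backbone mixes but
does not destroy input intensities. `fit_toy()` then fits only the 1×1×1
classifier head by full-batch gradient descent on a class-weighted
softmax cross-entropy over standardized backbone features, folding the
standardization back into the head weights. Fitting only the head keeps
the problem convex, so the outcome is insensitive to the random seed —
important because the end-to-end check must pass for any seed — while
still being a genuine "simple gradient steps on a voxelwise objective"
fit. Full training (optimizers, epochs, schedules) is out of scope at
this scale. The fitted float network reaches Dice ≥ 0.8 on held-out
phantoms (typically ≥ 0.99), and the int8 network tracks it to within a
few thousandths — the same order as the degradation reported for the
full-scale quantized segmentation network.

## Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes that still exercise every mechanism: random
conv/BN triples on 5–6³ inputs; tiny 2–3-layer networks on 5–6³ volumes
for the integer-soundness oracle; 16³ four-modality phantoms with a
channels-base-8, two-level network for the end-to-end fit (ten held-out
phantoms); a 32³ phantom with a channels-base-2 network for zero-skip and
scheduling statistics; 200 random instruction programs of up to 12
instructions for the scheduling invariants.

## Known limitations

* Per-tensor (not per-channel) scales; no quantization-aware retraining,
  no mixed precision.
* The cycle model is approximate by design: it predicts orderings and
  relative effects (masking, skipping), not wall-clock times of any
  specific chip, and makes no claims about LUT/DSP/BRAM budgets or power.
* Accumulator width (32 bit) and bias alignment are documented
  assumptions validated at toy scale by the unbounded-precision oracle.
* Calibration with very few volumes can clamp activations outside the
  calibrated range at evaluation time; this is inherent to the method
  (codes saturate rather than overflow).
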