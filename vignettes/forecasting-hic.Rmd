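---
title: "Forecasting spatiotemporal Hi-C contact matrices"
author: "hicforecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting spatiotemporal Hi-C contact matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicforecast)
```

## The problem

Time-resolved ("spatiotemporal") Hi-C experiments capture a series of
genome-wide contact matrices along a developmental process — for example the
six stages of mouse preimplantation development, during which topologically
associating domains (TADs) are progressively established. Given the contact
matrices of the first three time-steps, `hicforecast` predicts the matrices
of the following time-steps. The forecast operates on one chromosome at a
fixed resolution (40 kb by default), on contact values rescaled into
$[0, 1]$.

The pipeline is:

1. **Preprocess**: keep long-range ($>$ 20 kb) intra-chromosomal valid read
   pairs, optionally downsample them to a common depth across time-steps,
   bin them into symmetric contact matrices, and rescale by a depth-adaptive
   cap ("maxHiC") so values live in $[0, 1]$.
2. **Sample**: slide a $50 \times 50$ window along the matrix diagonal with
   a stride of 3 bins, across all time-steps, producing an
   $n \times t \times 1 \times 50 \times 50$ tensor.
3. **Forecast**: run a recurrent convolutional network in the *next-frame*
   scheme — each frame predicts the following one, and from the fourth step
   onwards the network consumes its own output — or a 3D-convolutional
   baseline that maps the three observed frames to the three future frames
   in a single pass.
4. **Reassemble**: average the overlapping window predictions per pixel,
   symmetrize, and mark never-covered pixels missing.
5. **Evaluate**: distance-stratified Pearson correlations, the
   stratum-adjusted correlation coefficient (SCC), insulation scores and
   TAD-boundary recovery.

## Models

All recurrent cells use same-padding convolutions, so the $50 \times 50$
grid is preserved through every layer, and all gates are sigmoids with tanh
candidates.

* **ConvLSTM** (variants 1–3). Variant 1 is the classical peephole
  formulation: the input, forget and output gates receive Hadamard products
  $W_{c\cdot} \circ C$ with the cell state, where the peephole weights have
  the full spatial shape of the state. Variant 2 drops the peepholes;
  variant 3 replaces them with convolutions. A network is a stack of cells
  (4 layers by default) plus a linear $3 \times 3$ output projection.
* **Residual ConvLSTM**. A $3 \times 3$ convolution lifts the single input
  channel to `hidden` channels; a chain of residual blocks follows, each
  containing two peephole-ConvLSTM layers and a skip connection
  $H^{i} = H^{i-1} + H^{i_2}$; a final $3 \times 3$ convolution projects
  back to one channel. With 25 blocks this counts 52 layers (2 convolutions
  + 50 cell layers). Variants: every cell replaced by a convolutional GRU;
  and a "concatenating" variant whose output projection consumes the
  channel-concatenated outputs of every 5th block.
* **ST-LSTM**. ConvLSTM extended with a spatiotemporal memory $M$ built by
  primed input/forget gates; $M$ flows bottom-up through the layers within a
  time-step and from the top layer back to layer 1 at the next time-step
  (the "zigzag"). The output gate reads $C$ and $M$ through convolutions and
  the hidden state is $o \circ \tanh(W_1 \ast [C, M])$ with a $1 \times 1$
  channel-reducing mix.
* **NaiveNet** (baseline). Three 3D convolutions with $7 \times 7$ spatial
  and size-1 temporal kernels, the first two followed by group
  normalization (2 groups) and LeakyReLU (slope 0.2). Because the temporal
  kernel is 1 we fold the time axis into the batch axis: this makes the
  absence of temporal mixing exact, including through the normalization
  statistics (a literal 3D group normalization would couple time-steps
  through shared moments).
* **identity**. Returns its input; under the next-frame rollout this is
  exactly the persistence baseline (predict step 3 forever) and is used as
  the reference any trained model must beat.

### Training

The compute core is the package's own reverse-mode tape over
(height, width, channel, batch) arrays, with RcppArmadillo im2col/GEMM
convolution kernels and fused pointwise LSTM updates; every gradient path
is validated against central finite differences in the test suite. The loss
is the mean squared error — pooled over the reconstructions of steps
2..T for the next-frame scheme, or over the three future frames for the
three-step scheme — optimized with Adam at learning rate $10^{-4}$ and
global gradient-norm clipping at 1.0 (the clip stabilizes the deeper
residual recurrences). Initial recurrent states are zero; weights use
uniform fan-in initialization with an exposed seed; peephole grids start at
zero. The checkpoint returned is the epoch with the best validation loss
(best training loss when no validation set is given). Runs are bit-for-bit
reproducible given a seed in single-threaded BLAS.

## The synthetic generator

Real spatiotemporal Hi-C is hundreds of millions of read pairs deep; the
package instead ships a seeded generator whose structure mirrors what the
forecasting task exploits:

* contact probability decays with genomic distance $d$ (in bins) as
  $(1 + d)^{-a}$, $a = 1$ by default;
* TADs are half-open bin intervals between configured boundaries; a
  within-TAD pair at step $t$ is enriched by $1 + s_t$;
* the strength schedule $s_t$ defaults to a linear ramp $0 \to 2$ across
  the six steps, emulating TAD establishment during embryogenesis: domains
  are absent at step 1 and enrich contacts threefold by step 6;
* counts are independent Poisson draws on the upper triangle (diagonal
  included), mirrored for exact symmetry, with the mean surface scaled so a
  matrix totals `depth` expected counts.

What it deliberately does **not** emulate: A/B compartment checkerboards,
loop dots, inter-chromosomal contacts, coverage biases or distance-dependent
noise correlations. Tests passing on this generator therefore demonstrate
that the machinery (sampling, recurrence, training, reassembly, metrics) is
correct and that the models can learn a TAD-establishment signal at desk
scale — not that any architecture ranks best on real embryogenesis data.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `resolution` | 40000 bp | bin size of the contact matrices |
| `min_distance` | 20000 bp | strict lower bound for kept pair distances |
| `max_hic` | 99.9th percentile | rescaling cap; see below |
| `window`, `step` | 50, 3 bins | diagonal sampling geometry |
| `hidden` | 128 (32 residual) | hidden channels |
| `n_blocks` | 25 | residual blocks (52 layers) |
| `lr`, `batch_size` | 1e-4, 32 | Adam rate and minibatch size |
| SCC `h`, bounds | 5; 0.4–1.6 Mb | smoothing half-width, stratum range |
| insulation window | 10 bins | 400 kb at 40 kb resolution |
| boundary prominence | 0.1 | log2 depth below flanking maxima |

**maxHiC.** The cap must adapt to sequencing depth; we pool the nonzero
entries of all time-steps and take their 99.9th percentile (inverse-ECDF
quantile), which guarantees at most 0.1% of nonzero pixels saturate. The cap
is a single overridable number recorded in the run manifest.

**Insulation and boundaries.** The insulation score of bin $b$ is the log2
ratio of the mean contact in the $w$-square just below the diagonal
($[b-w, b-1] \times [b+1, b+w]$, 0-based) to the chromosome-wide mean of
that statistic. With this square the valley floor at a sharp boundary is a
two-bin plateau ($b$ and $b-1$ are both fully cross-domain), so boundary
positions are only defined to $\pm 1$ bin; the caller reports the leftmost
bin of a flat valley floor and filters minima by prominence.

## Numerical choices

* Window contents are read from the symmetric matrix without masking the
  lower triangle; trailing bins that do not admit a full window are dropped
  (training requires fixed $50 \times 50$ inputs).
* Predicted windows are clamped to $[0, 1]$ before overlap-averaging and
  the reassembled matrix is symmetrized as $(M + M^\top)/2$; pixels outside
  the sampled band are `NA`, and every downstream metric drops `NA` pixels
  pairwise.
* Output projections are linear; no activation restricts the range, so
  clamping at reassembly is the only nonlinearity applied to predictions.
* SCC smoothing uses a uniform $(2h+1)^2$ mean filter truncated at the
  matrix borders; HiCRep dialects differ here, and the package pins this
  choice in a dual-implementation test. Strata that are constant after
  smoothing are excluded from the weighted sum, never imputed as zero.
* Constant strata in the distance-stratified Pearson are flagged undefined
  (`NA`) rather than silently zero.
* `lr = 0` is accepted and leaves parameters bit-identical (a useful
  determinism diagnostic).

## Design decisions taken where the design was open

* The convolutional-GRU cell follows the standard GRU gate wiring
  (update/reset gates, candidate on the reset-gated state) with
  convolutions; published residual-GRU variants differ in detail and no
  single canonical convolutional form exists.
* The concatenating residual variant taps blocks
  $5, 10, 15, 20, 25$ (every `concat_every`-th block, counting from the
  input side) for its final projection.
* A MUT1-style residual variant is not provided: no canonical convolutional
  MUT1 formulation exists to pin its equations against, and the remaining
  cells cover the benchmarked design space.
* Validation mirrors a held-out-chromosome protocol: train on some
  synthetic chromosomes, select the checkpoint on another, test blind on
  the rest. The `train()` API takes the validation tensor explicitly so any
  split can be expressed.
* The self-attention ConvLSTM variant and external video-prediction
  architectures are out of scope; the cell set here is the one whose
  equations the package states and tests.

## Problem sizes used by the tests and the acceptance script

The scaled-down study trains a 2-block, hidden-8 residual ConvLSTM for 30
epochs on the windows of one synthetic 120-bin chromosome (24 samples) with
the default TAD-establishment ramp at depth $10^5$, and evaluates on a
held-out synthetic chromosome with different boundary positions and seed.
Its optimizer settings are scaled with the problem: minibatch 4 and lr
$10^{-3}$, because 30 epochs over 24 samples afford the optimizer only
about 180 steps and a tiny network tolerates — and needs — a larger rate
than the full-scale default of $10^{-4}$ at batch 32. Under these conditions the training
loss decreases strictly and the model beats the persistence baseline at the
last forecast step in the majority of seeds; the acceptance script
re-derives these numbers from scratch, along with SCC and TAD-boundary
recovery of the forecasts.

## Known limitations

* Determinism is guaranteed in single-threaded BLAS only.
* The tape keeps all forward activations of a minibatch in memory; very
  large batches on 50-bin windows are memory-hungry (minibatch 8 is a good
  default on a laptop).
* No ICE/KR balancing is applied anywhere; the method consumes raw
  (downsampled, rescaled) counts by design.
* Only intra-chromosomal, single-resolution forecasting is supported.
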