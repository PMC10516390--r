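# hicforecast

Forecasting spatiotemporal Hi-C contact matrices with residual
convolutional recurrent networks.

Time-resolved Hi-C experiments measure genome-wide contact matrices at
successive developmental stages — for example the six stages of mouse
preimplantation development, during which TADs (topologically associating
domains) are progressively established. `hicforecast` addresses the
forecasting problem on such series: given the contact matrices of the first
three time-steps of one chromosome, predict the matrices of the last three.
It is aimed at computational genomicists who have binned Hi-C (or valid
read pairs) for several time points and want to extrapolate chromatin
organization forward in time, or to benchmark sequence-prediction
architectures on Hi-C dynamics.

## Method

Contact values are rescaled to `[0, 1]` by a depth-adaptive cap (`maxHiC`,
by default the 99.9th percentile of nonzero entries). A `50 × 50` window
slides along the matrix diagonal with stride 3, across all time-steps,
giving an `n × t × 1 × 50 × 50` sample tensor. A recurrent network is
trained in the *next-frame* scheme,

    X̂(t+1) = F(X(t), H(t), C(t)),   loss = MSE over X̂(2) … X̂(6),

where the inputs are the true frames for t ≤ 3 and the network's own
predictions afterwards. The flagship architecture is the **residual
ConvLSTM**: a 3×3 convolution lifting 1 → h channels, a chain of residual
blocks — each two peephole-ConvLSTM layers with a skip connection
`H(i) = H(i−1) + H(i₂)` — and a 3×3 convolution back to one channel
(25 blocks = 52 layers at full scale). Stacked ConvLSTM (three gate
dialects), a convolutional GRU variant, a channel-concatenating variant,
ST-LSTM with zigzag spatiotemporal memory, and a 3D-convolutional
`NaiveNet` baseline are included, plus an `identity` architecture that
realizes the persistence baseline. Overlapping window predictions are
averaged per pixel and symmetrized into genome-scale matrices.

Predictions are evaluated with distance-stratified Pearson correlations
(10–30 bins), the stratum-adjusted correlation coefficient (SCC, HiCRep
weighting, smoothing h = 5, 0.4–1.6 Mb), insulation scores and strong
TAD-boundary recovery.

Everything runs on plain CPU R: the recurrent cells, the reverse-mode
tape and Adam are implemented in the package with RcppArmadillo
convolution kernels, and every gradient path is finite-difference tested.
A seeded synthetic generator (power-law distance decay, TAD blocks whose
strength ramps up across steps, Poisson noise at configurable depth)
makes the full pipeline testable without downloads.

## Worked example

Simulate a six-step TAD-establishment series, train a small residual
ConvLSTM on the first chromosome, and forecast a held-out one:

```r
library(hicforecast)

train_stack <- generate_stack(synthetic_config(
  n_bins = 120, tad_boundaries = c(30, 60, 90), depth = 1e5, seed = 1))
test_stack <- generate_stack(synthetic_config(
  n_bins = 120, tad_boundaries = c(25, 55, 85), depth = 1e5, seed = 2))

cap <- choose_max_hic(train_stack)          # depth-adaptive rescaling cap
samples <- extract_windows(rescale_hic(train_stack, cap), window = 50, step = 3)
samples
#> <sample_tensor> 24 samples x 6 steps x 1 x 50 x 50 (chrS, 120 bins, step 3)

model <- build_network(
  model_config("resconvlstm", hidden = 8, n_blocks = 2, window = 50), seed = 1)
model
#> <hic_forecaster> resconvlstm: 6 layers, hidden 8, 258,713 parameters

fit <- train(model, samples,
             train_config("next_frame", batch_size = 4, lr = 1e-3,
                          epochs = 30, seed = 1))
round(fit$history$train_loss[c(1, 10, 20, 30)], 5)
#> [1] 0.01879 0.00215 0.00148 0.00127

test_rs <- rescale_hic(test_stack, cap)
pred <- predict_genome(fit$model, test_rs, window = 50, step = 3)

# forecast quality at the last step vs the persistence baseline
truth6 <- test_rs[[6]]$values
mask   <- !is.na(pred[[3]]$values)
c(model       = mean((pred[[3]]$values[mask] - truth6[mask])^2),
  persistence = mean((test_rs[[3]]$values[mask] - truth6[mask])^2))
#>        model  persistence
#> 0.0008279848 0.0011340935

scc(pred[[3]], test_rs[[6]])
#> <scc_result> SCC = 0.7757 over 31 strata (h = 5, 400000-1600000 bp)
```

The training loss falls by an order of magnitude in 30 epochs, and the
forecast at the third future step reproduces the held-out chromosome better
than carrying the last observed matrix forward — the model has learned the
TAD-establishment trend, not just copied its input. `metric_report()`
tabulates SCC/Pearson/boundary counts per step, `insulation()` +
`call_strong_boundaries()` recover domain boundaries, and
`plot_contact_matrix()` / `plot_insulation()` draw the results.

A command-line front end (`inst/scripts/hicforecast`) exposes the same
pipeline as `simulate | preprocess | sample | train | predict | evaluate`
subcommands; every run writes a `manifest.json` with its configuration,
seeds and input digests.

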