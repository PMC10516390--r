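Package: hicforecast
Title: Forecasting Spatiotemporal Hi-C Contact Matrices with Residual
    Convolutional Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting future time-steps of spatiotemporal Hi-C
    contact matrices from early time-steps. Implements convolutional LSTM
    cells (with and without peephole connections), convolutional GRU and
    spatiotemporal LSTM cells, residual ConvLSTM forecasting networks, and a
    3D-convolutional baseline, together with the Hi-C-specific plumbing:
    valid-pair filtering and binning, depth-adaptive rescaling to [0, 1],
    diagonal sliding-window sampling into n x t x 1 x 50 x 50 tensors,
    overlap-averaged reassembly of predictions, and an evaluation stack with
    distance-stratified Pearson correlation, stratum-adjusted correlation
    (SCC), insulation scores and TAD-boundary recovery. A seeded synthetic
    data generator emulating TAD establishment across developmental
    time-steps makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
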