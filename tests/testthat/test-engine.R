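tiny_tensor <- function(n = 4, t = 6, w = 8, seed = 1) {
  set.seed(seed)
  array(runif(n * t * 1 * w * w), c(n, t, 1, w, w))
}

test_that("an identity model rolls out to persistence", {
  m <- build_network(model_config("identity", window = 8))
  x <- tiny_tensor()
  out <- rollout_next_frame(m, x)
  # reconstructions of steps 2, 3 are the true previous frames; from step 4
  # on the fed-back prediction is a fixed point at frame 3
  expect_equal(out$reconstructions[, 1, , , ], x[, 1, , , ])
  expect_equal(out$reconstructions[, 2, , , ], x[, 2, , , ])
  for (k in 1:3) expect_equal(out$predicted[, k, , , ], x[, 3, , , ])
})

test_that("an all-zero model predicts zero everywhere", {
  m <- build_network(model_config("convlstm", hidden = 2, n_layers = 2, window = 8))
  m$params <- rapply(m$params, function(a) a * 0, classes = "ANY", how = "replace")
  out <- rollout_next_frame(m, tiny_tensor())
  expect_equal(max(abs(out$reconstructions)), 0)
})

test_that("rollout equals a hand-unrolled loop of cell steps", {
  # 2-layer ConvLSTM network unrolled manually with the exported pure steps
  cfg <- model_config("convlstm", hidden = 3, n_layers = 2, window = 8)
  m <- build_network(cfg, seed = 31)
  x <- tiny_tensor(n = 2, w = 8, seed = 32)
  out <- rollout_next_frame(m, x, n_future = 3)
  conv_plain <- function(a, W, b) hicforecast:::.conv2d_fwd(a, W, b)
  frame <- function(t) {
    f <- array(0, c(8, 8, 1, 2))
    for (s in 1:2) f[, , 1, s] <- x[s, t, 1, , ]
    f
  }
  st1 <- recurrent_state(c(8, 8), 3, n = 2)
  st2 <- recurrent_state(c(8, 8), 3, n = 2)
  recon <- vector("list", 5)
  inp <- NULL
  for (t in 1:5) {
    inp <- if (t <= 3) frame(t) else recon[[t - 1]]
    st1 <- convlstm_step(inp, st1, m$params$cells[[1]])
    st2 <- convlstm_step(st1$h, st2, m$params$cells[[2]])
    recon[[t]] <- conv_plain(st2$h, m$params$proj$W, m$params$proj$b)
  }
  for (t in 1:5) {
    got <- array(0, c(8, 8, 1, 2))
    for (s in 1:2) got[, , 1, s] <- out$reconstructions[s, t, 1, , ]
    expect_identical(got, recon[[t]]) # bit-exact
  }
})

test_that("losses match their closed forms and brute-force oracles", {
  x <- tiny_tensor(n = 3, t = 6, w = 8, seed = 41)
  truth <- x[, 2:6, , , , drop = FALSE]
  # perfect reconstruction -> 0
  expect_equal(loss_next_frame(truth, truth), 0)
  # constant offset delta -> delta^2
  delta <- 0.17
  expect_equal(loss_next_frame(truth + delta, truth), delta^2, tolerance = 1e-12)
  # brute-force elementwise oracle
  set.seed(42)
  pred <- truth + array(rnorm(length(truth), sd = 0.1), dim(truth))
  acc <- 0; n_el <- 0
  for (i in seq_along(truth)) {
    acc <- acc + (pred[i] - truth[i])^2
    n_el <- n_el + 1
  }
  expect_equal(loss_next_frame(pred, truth), acc / n_el, tolerance = 1e-12)
  # three-step loss on its own support
  t3 <- x[, 4:6, , , , drop = FALSE]
  expect_equal(loss_three_step(t3, t3), 0)
  p3 <- t3 + delta
  expect_equal(loss_three_step(p3, t3), delta^2, tolerance = 1e-12)
  # the two schemes score different supports; their values need not agree
  expect_false(isTRUE(all.equal(
    loss_next_frame(pred, truth),
    loss_three_step(pred[, 3:5, , , , drop = FALSE], t3)
  )))
  expect_error(loss_next_frame(truth[, 1:4, , , , drop = FALSE], truth), "mismatch")
})

test_that("lr = 0 leaves the model and its loss history frozen", {
  x <- tiny_tensor(n = 6, w = 8, seed = 51)
  m <- build_network(model_config("resconvlstm", hidden = 2, n_blocks = 1, window = 8), seed = 51)
  fit <- train(m, x, train_config("next_frame", batch_size = 3, lr = 0, epochs = 3, seed = 1))
  expect_equal(length(unique(round(fit$history$train_loss, 12))), 1)
  expect_identical(fit$model$params, m$params)
})

test_that("training is seeded-deterministic and reduces the loss on a tiny problem", {
  x <- tiny_tensor(n = 8, w = 8, seed = 61)
  m <- build_network(model_config("resconvlstm", hidden = 4, n_blocks = 1, window = 8), seed = 61)
  cfg <- train_config("next_frame", batch_size = 4, lr = 2e-3, epochs = 12, seed = 7)
  fit1 <- train(m, x, cfg)
  fit2 <- train(m, x, cfg)
  expect_identical(fit1$history, fit2$history) # full determinism
  expect_lt(fit1$history$train_loss[12], fit1$history$train_loss[1])
})

test_that("three-step training drives NaiveNet below its initial loss", {
  x <- tiny_tensor(n = 8, w = 8, seed = 71)
  m <- build_network(model_config("naivenet", hidden = 4, window = 8), seed = 71)
  cfg <- train_config("three_step", batch_size = 4, lr = 2e-3, epochs = 12, seed = 7)
  fit <- train(m, x, cfg)
  expect_lt(fit$history$train_loss[12], fit$history$train_loss[1])
  # scheme/architecture mismatches are rejected
  expect_error(train(m, x, train_config("next_frame", epochs = 1)), "recurrent")
  m2 <- build_network(model_config("convlstm", hidden = 2, n_layers = 1, window = 8))
  expect_error(train(m2, x, train_config("three_step", epochs = 1)), "NaiveNet")
})

test_that("validation selects the checkpoint and reload reproduces its loss", {
  x <- tiny_tensor(n = 8, w = 8, seed = 81)
  xv <- tiny_tensor(n = 4, w = 8, seed = 82)
  m <- build_network(model_config("resconvlstm", hidden = 3, n_blocks = 1, window = 8), seed = 81)
  cfg <- train_config("next_frame", batch_size = 4, lr = 2e-3, epochs = 6, seed = 3)
  fit <- train(m, x, cfg, val_samples = xv)
  expect_true(is.finite(fit$best_epoch))
  expect_equal(
    min(fit$history$val_loss),
    fit$history$val_loss[fit$best_epoch]
  )
  hf <- asNamespace("hicforecast")
  val_now <- hf$eval_loss(fit$model, xv, "next_frame")
  expect_equal(val_now, min(fit$history$val_loss), tolerance = 1e-10)
  ckpt <- tempfile(fileext = ".rds")
  save_forecaster(fit$model, ckpt)
  back <- load_forecaster(ckpt)
  expect_lt(abs(hf$eval_loss(back, xv, "next_frame") - val_now), 1e-6)
})

test_that("rollout is blind to frames after the observed window", {
  x <- tiny_tensor(n = 3, t = 6, w = 8, seed = 91)
  m <- build_network(model_config("resconvlstm", hidden = 3, n_blocks = 1, window = 8), seed = 91)
  out1 <- rollout_next_frame(m, x)
  x2 <- x
  x2[, 4:6, , , ] <- runif(length(x2[, 4:6, , , ])) # perturb the "future"
  out2 <- rollout_next_frame(m, x2)
  expect_identical(out1$predicted, out2$predicted)
  expect_identical(out1$reconstructions, out2$reconstructions)
})

test_that("genome-wide prediction composes windowing, rollout and reassembly", {
  cfg <- synthetic_config(n_bins = 70, tad_boundaries = c(25, 45), depth = 1e5, seed = 101)
  stack <- generate_stack(cfg)
  rs <- rescale_hic(stack, choose_max_hic(stack))
  # identity model: every future matrix equals the band of step 3
  m <- build_network(model_config("identity", window = 20))
  pred <- predict_genome(m, rs, window = 20, step = 4)
  expect_equal(length(pred), 3)
  band3 <- reassemble(
    extract_windows(hic_stack(rs[1:3]), 20, 4)$data[, 3, , , , drop = FALSE],
    extract_windows(hic_stack(rs[1:3]), 20, 4)$offsets, 70
  )[[1]]
  for (k in 1:3) {
    v <- pred[[k]]$values
    expect_identical(v, t(v))
    expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
    expect_equal(v, band3$values, tolerance = 1e-12)
  }
  expect_error(predict_genome(m, hic_stack(rs[1:2])), "observed")
})
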