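test_that("zero weights give the hand-derived fixed point (0.5 gates, zero states)", {
  x <- array(runif(5 * 5 * 1 * 2), c(5, 5, 1, 2))
  for (type in c("convlstm1", "convlstm2", "convlstm3")) {
    w <- zero_weights(cell_weights(type, 1, 3, spatial = c(5, 5), seed = 1))
    st <- recurrent_state(c(5, 5), 3, n = 2)
    out <- convlstm_step(x, st, w)
    expect_equal(max(abs(out$c)), 0) # c = 0.5 * 0 + 0.5 * tanh(0)
    expect_equal(max(abs(out$h)), 0) # h = 0.5 * tanh(0)
    # gates are exactly 0.5: from nonzero c_prev, c_new = f * c_prev = 0.5 c_prev
    st$c[] <- 0.8
    out2 <- convlstm_step(x, st, w)
    expect_equal(out2$c, st$c * 0.5, tolerance = 1e-12)
  }
  wg <- zero_weights(cell_weights("convgru", 1, 3, spatial = c(5, 5), seed = 1))
  outg <- convgru_step(x, recurrent_state(c(5, 5), 3, n = 2), wg)
  expect_equal(max(abs(outg$h)), 0) # (1 - z) * 0 + z * tanh(0)
  ws <- zero_weights(cell_weights("stlstm", 1, 3, spatial = c(5, 5), seed = 1))
  outs <- stlstm_step(x, recurrent_state(c(5, 5), 3, n = 2, stlstm = TRUE), ws)
  expect_equal(max(abs(outs$c)), 0)
  expect_equal(max(abs(outs$m)), 0)
  expect_equal(max(abs(outs$h)), 0)
})

test_that("1x1 ConvLSTM equals the scalar peephole-LSTM oracle", {
  set.seed(7)
  for (rep in 1:5) {
    w <- cell_weights("convlstm1", 1, 1, kernel = 1, spatial = c(1, 1))
    w$Pci[] <- rnorm(1); w$Pcf[] <- rnorm(1); w$Pco[] <- rnorm(1)
    w$b[] <- rnorm(4)
    xs <- rnorm(1); hs <- rnorm(1); cs <- rnorm(1)
    out <- convlstm_step(
      array(xs, c(1, 1, 1, 1)),
      list(h = array(hs, c(1, 1, 1, 1)), c = array(cs, c(1, 1, 1, 1))), w
    )
    orc <- scalar_lstm_step(xs, hs, cs, list(
      wxi = w$Wx[1, 1, 1, 1], wxf = w$Wx[1, 1, 1, 2], wxc = w$Wx[1, 1, 1, 3], wxo = w$Wx[1, 1, 1, 4],
      whi = w$Wh[1, 1, 1, 1], whf = w$Wh[1, 1, 1, 2], whc = w$Wh[1, 1, 1, 3], who = w$Wh[1, 1, 1, 4],
      wci = w$Pci[1, 1, 1], wcf = w$Pcf[1, 1, 1], wco = w$Pco[1, 1, 1],
      bi = w$b[1], bf = w$b[2], bc = w$b[3], bo = w$b[4]
    ))
    expect_lt(abs(out$h[1] - orc$h), 1e-6)
    expect_lt(abs(out$c[1] - orc$c), 1e-6)
  }
})

test_that("1x1 ConvGRU equals the scalar GRU oracle", {
  set.seed(8)
  for (rep in 1:5) {
    w <- cell_weights("convgru", 1, 1, kernel = 1, spatial = c(1, 1))
    w$b[] <- rnorm(3)
    xs <- rnorm(1); hs <- rnorm(1)
    out <- convgru_step(
      array(xs, c(1, 1, 1, 1)),
      list(h = array(hs, c(1, 1, 1, 1))), w
    )
    orc <- scalar_gru_step(xs, hs, list(
      wxz = w$Wx[1, 1, 1, 1], wxr = w$Wx[1, 1, 1, 2], wxg = w$Wx[1, 1, 1, 3],
      whz = w$Whzr[1, 1, 1, 1], whr = w$Whzr[1, 1, 1, 2], whg = w$Whg[1, 1, 1, 1],
      bz = w$b[1], br = w$b[2], bg = w$b[3]
    ))
    expect_lt(abs(out$h[1] - orc), 1e-6)
  }
})

test_that("a saturated forget gate carries the cell memory unchanged", {
  w <- zero_weights(cell_weights("convlstm1", 1, 2, spatial = c(6, 6), seed = 1))
  w$b[3:4] <- 20 # f-gate bias (slots ch+1..2ch) -> sigmoid(20) ~ 1
  st <- recurrent_state(c(6, 6), 2, n = 1)
  set.seed(9)
  st$c[] <- rnorm(length(st$c))
  x <- array(runif(6 * 6 * 1 * 1), c(6, 6, 1, 1))
  out <- convlstm_step(x, st, w)
  expect_lt(max(abs(out$c - st$c)), 1e-6) # c_t ~ c_{t-1}
})

test_that("a suppressed update gate makes the GRU carry its hidden state", {
  w <- zero_weights(cell_weights("convgru", 1, 2, spatial = c(6, 6), seed = 1))
  w$b[1:2] <- -20 # z -> 0: h_t = (1 - z) h_{t-1} + z cand ~ h_{t-1}
  st <- list(h = array(rnorm(6 * 6 * 2), c(6, 6, 2, 1)))
  x <- array(runif(36), c(6, 6, 1, 1))
  out <- convgru_step(x, st, w)
  expect_lt(max(abs(out$h - st$h)), 1e-6)
})

test_that("variant 2 equals variant 1 with vanished peepholes, exactly", {
  set.seed(10)
  w1 <- cell_weights("convlstm1", 2, 3, spatial = c(7, 7), seed = 10)
  w1$Pci[] <- 0; w1$Pcf[] <- 0; w1$Pco[] <- 0
  w2 <- list(Wx = w1$Wx, Wh = w1$Wh, b = w1$b)
  attr(w2, "type") <- "convlstm2"
  x <- array(runif(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  st <- recurrent_state(c(7, 7), 3, n = 2)
  st$c[] <- rnorm(length(st$c), sd = 0.3)
  st$h[] <- rnorm(length(st$h), sd = 0.3)
  o1 <- convlstm_step(x, st, w1, variant = 1)
  o2 <- convlstm_step(x, st, w2, variant = 2)
  expect_identical(o1$h, o2$h)
  expect_identical(o1$c, o2$c)
})

test_that("variant 3 with 1x1 scalar peephole kernels reproduces variant 1", {
  # a 1x1 convolutional peephole acting on one channel is the Hadamard
  # product with a spatially constant grid
  set.seed(11)
  w3 <- cell_weights("convlstm3", 1, 1, kernel = 3, spatial = c(6, 6), seed = 11)
  a_i <- 0.7; a_f <- -0.4; a_o <- 0.9
  w3$Wci <- array(0, c(1, 1, 1, 1)); w3$Wci[1, 1, 1, 1] <- a_i
  w3$Wcf <- array(0, c(1, 1, 1, 1)); w3$Wcf[1, 1, 1, 1] <- a_f
  w3$Wco <- array(0, c(1, 1, 1, 1)); w3$Wco[1, 1, 1, 1] <- a_o
  w1 <- list(
    Wx = w3$Wx, Wh = w3$Wh, b = w3$b,
    Pci = array(a_i, c(6, 6, 1)), Pcf = array(a_f, c(6, 6, 1)),
    Pco = array(a_o, c(6, 6, 1))
  )
  attr(w1, "type") <- "convlstm1"
  x <- array(runif(36), c(6, 6, 1, 1))
  st <- recurrent_state(c(6, 6), 1, n = 1)
  st$c[] <- rnorm(36, sd = 0.5)
  st$h[] <- rnorm(36, sd = 0.5)
  o3 <- convlstm_step(x, st, w3, variant = 3)
  o1 <- convlstm_step(x, st, w1, variant = 1)
  expect_lt(max(abs(o3$h - o1$h)), 1e-12)
  expect_lt(max(abs(o3$c - o1$c)), 1e-12)
})

test_that("ST-LSTM with zero memory path and C-selecting mix reduces to ConvLSTM-2", {
  set.seed(12)
  ch <- 2
  ws <- cell_weights("stlstm", 1, ch, kernel = 3, spatial = c(5, 5), seed = 12)
  ws$Wm[] <- 0 # sever the incoming-memory terms
  ws$Wco[] <- 0 # output gate reads only x and h
  ws$Wmo[] <- 0
  ws$W1[] <- 0 # 1x1 mix selects the C half, identity per channel
  for (c in seq_len(ch)) ws$W1[1, 1, c, c] <- 1
  w2 <- list(
    Wx = ws$Wx[, , , 1:(3 * ch), drop = FALSE], # i, f, c slices match
    Wh = ws$Wh,
    b = c(ws$b[1:(3 * ch)], ws$b[6 * ch + 1:ch])
  )
  # align gate order: convlstm expects (i, f, g, o); stlstm Wx holds
  # (i, f, c, i', f', m, o) and Wh holds (i, f, c, o)
  w2$Wx <- array(0, c(3, 3, 1, 4 * ch))
  w2$Wx[, , , 1:(3 * ch)] <- ws$Wx[, , , 1:(3 * ch)]
  w2$Wx[, , , 3 * ch + 1:ch] <- ws$Wx[, , , 6 * ch + 1:ch]
  w2$b <- c(ws$b[1:(3 * ch)], ws$b[6 * ch + 1:ch])
  attr(w2, "type") <- "convlstm2"
  x <- array(runif(5 * 5 * 1 * 2), c(5, 5, 1, 2))
  st <- recurrent_state(c(5, 5), ch, n = 2, stlstm = TRUE)
  st$h[] <- rnorm(length(st$h), sd = 0.3)
  st$c[] <- rnorm(length(st$c), sd = 0.3)
  st$m[] <- rnorm(length(st$m), sd = 0.3) # must be ignored entirely
  os <- stlstm_step(x, st, ws)
  o2 <- convlstm_step(x, list(h = st$h, c = st$c), w2, variant = 2)
  expect_lt(max(abs(os$h - o2$h)), 1e-6)
  expect_lt(max(abs(os$c - o2$c)), 1e-6)
})

test_that("ST-LSTM output keeps the configured hidden width despite [C, M] concat", {
  w <- cell_weights("stlstm", 1, 4, spatial = c(6, 6), seed = 13)
  st <- recurrent_state(c(6, 6), 4, n = 2, stlstm = TRUE)
  out <- stlstm_step(array(runif(6 * 6 * 1 * 2), c(6, 6, 1, 2)), st, w)
  expect_equal(dim(out$h), c(6, 6, 4, 2))
  expect_equal(dim(out$m), c(6, 6, 4, 2))
  # missing memory input is a structural error
  expect_error(stlstm_step(
    array(0, c(6, 6, 1, 2)),
    list(h = st$h, c = st$c), w
  ), "memory")
})

test_that("cell updates respect the tanh bound and preserve spatial shape", {
  set.seed(14)
  for (kernel in c(3, 5)) {
    w <- cell_weights("convlstm1", 1, 2, kernel = kernel, spatial = c(9, 9))
    st <- recurrent_state(c(9, 9), 2, n = 2)
    st$c[] <- rnorm(length(st$c))
    x <- array(runif(9 * 9 * 1 * 2, -1, 1), c(9, 9, 1, 2))
    out <- convlstm_step(x, st, w)
    expect_equal(dim(out$h), c(9, 9, 2, 2))
    # |c_t| <= |c_{t-1}| + 1 elementwise (f, i in (0,1); |tanh| <= 1)
    expect_true(all(abs(out$c) <= abs(st$c) + 1 + 1e-12))
    expect_true(all(abs(out$h) <= 1)) # o in (0,1), |tanh(c)| <= 1
  }
})
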