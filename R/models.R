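# Forecasting networks assembled from the recurrent cells:
#   - stacked ConvLSTM / ST-LSTM (cells + a 3x3 output projection),
#   - residual ConvLSTM: 3x3 conv (1 -> hidden) -> n_blocks residual blocks
#     (two peephole ConvLSTM layers + skip connection) -> 3x3 conv (hidden -> 1),
#   - variants: convolutional-GRU blocks; channel-concatenation of every
#     concat_every-th block output feeding the projection,
#   - NaiveNet: three 3D convolutions with temporal kernel 1 (baseline),
#   - identity: passes the input frame through (persistence baseline).
# Output projections are linear; clamping to [0, 1] happens at reassembly.

#' Configuration of a forecasting network
#'
#' @param architecture One of `"convlstm"`, `"stlstm"`, `"resconvlstm"`,
#'   `"resconvlstm2"`, `"resconvgru"`, `"naivenet"`, `"identity"`.
#' @param hidden Hidden channels. Defaults: 128 for `convlstm`/`stlstm`/
#'   `naivenet`, 32 for the residual networks.
#' @param n_layers Cell layers for stacked architectures (default 4).
#' @param n_blocks Residual blocks (default 25).
#' @param kernel Odd gate-convolution kernel size (default 3; NaiveNet uses
#'   7 for its two spatial dimensions and 1 for the temporal dimension).
#' @param variant ConvLSTM gate dialect for `"convlstm"` stacks (1, 2 or 3;
#'   default 1). Residual blocks always use the peephole dialect (variant 1).
#' @param concat_every For `"resconvlstm2"`: the outputs of blocks
#'   `concat_every, 2 * concat_every, ..., n_blocks` are channel-concatenated
#'   as the input of the output projection (default 5).
#' @param window Spatial grid size the network operates on (default 50).
#' @param n_input Observed time-steps fed before autoregressive feedback
#'   (default 3).
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c(
                           "convlstm", "stlstm", "resconvlstm",
                           "resconvlstm2", "resconvgru", "naivenet", "identity"
                         ),
                         hidden = NULL, n_layers = 4, n_blocks = 25,
                         kernel = NULL, variant = 1, concat_every = 5,
                         window = 50, n_input = 3) {
  architecture <- match.arg(architecture)
  residual <- architecture %in% c("resconvlstm", "resconvlstm2", "resconvgru")
  hidden <- hidden %||% if (residual) 32L else 128L
  kernel <- kernel %||% if (architecture == "naivenet") 7L else 3L
  if (architecture == "resconvlstm2" && n_blocks %% concat_every != 0) {
    stopf("n_blocks must be a multiple of concat_every")
  }
  structure(
    list(
      architecture = architecture, hidden = as.integer(hidden),
      n_layers = as.integer(n_layers), n_blocks = as.integer(n_blocks),
      kernel = as.integer(kernel), variant = as.integer(variant),
      concat_every = as.integer(concat_every), window = as.integer(window),
      n_input = as.integer(n_input), groups = 2L, slope = 0.2
    ),
    class = "model_config"
  )
}

#' Layer census of a forecasting network
#'
#' Counts the layers of a network configuration the way deep architectures
#' are usually sized in print: the residual networks count their two 2D
#' convolutions plus the two cell layers of each block (so 25 blocks report
#' 52 layers); stacked networks count their cell layers plus the output
#' projection; NaiveNet counts its three 3D convolutions. Cells' internal
#' gate convolutions are not counted separately.
#'
#' @param config A [model_config()] (or a fitted `hic_forecaster`).
#' @return Integer layer count.
#' @export
layer_census <- function(config) {
  if (inherits(config, "hic_forecaster")) config <- config$config
  stopifnot(inherits(config, "model_config"))
  switch(config$architecture,
    resconvlstm = ,
    resconvlstm2 = ,
    resconvgru = 2L + 2L * config$n_blocks,
    convlstm = ,
    stlstm = config$n_layers + 1L,
    naivenet = 3L,
    identity = 0L
  )
}

#' Build a forecasting network with initialized weights
#'
#' @param config A [model_config()].
#' @param seed Seed for the fan-in uniform weight initialization.
#'
#' @return An object of class `hic_forecaster`: list with `config`, `params`
#'   (nested named list of weight arrays) and `census`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  a <- config$architecture
  ch <- config$hidden
  k <- config$kernel
  sp <- c(config$window, config$window)
  params <- with_seed(seed, switch(a,
    identity = list(),
    convlstm = list(
      cells = lapply(seq_len(config$n_layers), function(l) {
        cell_weights(paste0("convlstm", config$variant),
          in_ch = if (l == 1) 1L else ch, hidden = ch, kernel = k, spatial = sp
        )
      }),
      proj = list(W = conv_init(k, k, ch, 1), b = numeric(1))
    ),
    stlstm = list(
      cells = lapply(seq_len(config$n_layers), function(l) {
        cell_weights("stlstm",
          in_ch = if (l == 1) 1L else ch, hidden = ch, kernel = k, spatial = sp
        )
      }),
      proj = list(W = conv_init(k, k, ch, 1), b = numeric(1))
    ),
    resconvlstm = ,
    resconvlstm2 = ,
    resconvgru = {
      cell_type <- if (a == "resconvgru") "convgru" else "convlstm1"
      n_cat <- if (a == "resconvlstm2") config$n_blocks %/% config$concat_every else 1L
      list(
        conv_in = list(W = conv_init(k, k, 1, ch), b = numeric(ch)),
        blocks = lapply(seq_len(config$n_blocks), function(i) {
          list(
            cell1 = cell_weights(cell_type, in_ch = ch, hidden = ch, kernel = k, spatial = sp),
            cell2 = cell_weights(cell_type, in_ch = ch, hidden = ch, kernel = k, spatial = sp)
          )
        }),
        conv_out = list(W = conv_init(k, k, n_cat * ch, 1), b = numeric(1))
      )
    },
    naivenet = list(
      conv1 = list(W = conv_init(k, k, 1, ch), b = numeric(ch)),
      gn1 = list(gamma = rep(1, ch), beta = numeric(ch)),
      conv2 = list(W = conv_init(k, k, ch, ch), b = numeric(ch)),
      gn2 = list(gamma = rep(1, ch), beta = numeric(ch)),
      conv3 = list(W = conv_init(k, k, ch, 1), b = numeric(1))
    )
  ))
  structure(
    list(config = config, params = params, census = layer_census(config)),
    class = "hic_forecaster"
  )
}

#' @export
print.hic_forecaster <- function(x, ...) {
  cat(sprintf(
    "<hic_forecaster> %s: %d layers, hidden %d, %s parameters\n",
    x$config$architecture, x$census, x$config$hidden,
    format(param_count(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total trainable parameter count of a network
#' @param model A `hic_forecaster`.
#' @return Integer count.
#' @export
param_count <- function(model) {
  stopifnot(inherits(model, "hic_forecaster"))
  leaves <- rapply(model$params, length, classes = "ANY", how = "unlist")
  if (is.null(leaves)) 0L else as.integer(sum(leaves))
}

# ---- state plumbing --------------------------------------------------------

# Zero initial states for one network as tape constants.
init_states <- function(tp, config, n) {
  sp <- config$window
  z <- function(ch) ag_const(tp, array(0, c(sp, sp, ch, n)))
  switch(config$architecture,
    identity = ,
    naivenet = list(),
    convlstm = list(layers = lapply(seq_len(config$n_layers), function(l) {
      list(h = z(config$hidden), c = z(config$hidden))
    })),
    stlstm = list(
      layers = lapply(seq_len(config$n_layers), function(l) {
        list(h = z(config$hidden), c = z(config$hidden))
      }),
      m_top = z(config$hidden)
    ),
    resconvlstm = ,
    resconvlstm2 = list(blocks = lapply(seq_len(config$n_blocks), function(i) {
      list(
        cell1 = list(h = z(config$hidden), c = z(config$hidden)),
        cell2 = list(h = z(config$hidden), c = z(config$hidden))
      )
    })),
    resconvgru = list(blocks = lapply(seq_len(config$n_blocks), function(i) {
      list(cell1 = list(h = z(config$hidden)), cell2 = list(h = z(config$hidden)))
    }))
  )
}

# One residual block on the tape: two inner cells plus the skip connection.
ag_resblock <- function(tp, h_in, st, pw, gru = FALSE) {
  if (gru) {
    s1 <- ag_convgru_step(tp, h_in, st$cell1$h, pw$cell1)
    s2 <- ag_convgru_step(tp, s1$h, st$cell2$h, pw$cell2)
    new_st <- list(cell1 = list(h = s1$h), cell2 = list(h = s2$h))
  } else {
    s1 <- ag_convlstm_step(tp, h_in, st$cell1$h, st$cell1$c, pw$cell1, 1L)
    s2 <- ag_convlstm_step(tp, s1$h, st$cell2$h, st$cell2$c, pw$cell2, 1L)
    new_st <- list(
      cell1 = list(h = s1$h, c = s1$c),
      cell2 = list(h = s2$h, c = s2$c)
    )
  }
  list(h = ag_add(tp, h_in, s2$h), states = new_st)
}

# One next-frame pass of the network: frame in, frame out, states threaded.
ag_model_step <- function(tp, ph, config, x, states) {
  a <- config$architecture
  if (a == "identity") {
    return(list(y = x, states = states))
  }
  if (a == "convlstm") {
    h <- x
    new_layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      st <- ag_convlstm_step(
        tp, h, states$layers[[l]]$h, states$layers[[l]]$c,
        ph$cells[[l]], config$variant
      )
      new_layers[[l]] <- st
      h <- st$h
    }
    y <- ag_conv(tp, h, ph$proj$W, ph$proj$b)
    return(list(y = y, states = list(layers = new_layers)))
  }
  if (a == "stlstm") {
    h <- x
    m <- states$m_top
    new_layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      st <- ag_stlstm_step(
        tp, h, states$layers[[l]]$h, states$layers[[l]]$c, m,
        ph$cells[[l]]
      )
      new_layers[[l]] <- list(h = st$h, c = st$c)
      h <- st$h
      m <- st$m
    }
    y <- ag_conv(tp, h, ph$proj$W, ph$proj$b)
    return(list(y = y, states = list(layers = new_layers, m_top = m)))
  }
  # residual networks
  gru <- a == "resconvgru"
  h <- ag_conv(tp, x, ph$conv_in$W, ph$conv_in$b)
  new_blocks <- vector("list", config$n_blocks)
  taps <- list()
  for (i in seq_len(config$n_blocks)) {
    blk <- ag_resblock(tp, h, states$blocks[[i]], ph$blocks[[i]], gru = gru)
    h <- blk$h
    new_blocks[[i]] <- blk$states
    if (a == "resconvlstm2" && i %% config$concat_every == 0) {
      taps[[length(taps) + 1L]] <- h
    }
  }
  out_in <- if (a == "resconvlstm2") ag_concat_c(tp, taps) else h
  y <- ag_conv(tp, out_in, ph$conv_out$W, ph$conv_out$b)
  list(y = y, states = list(blocks = new_blocks))
}

# NaiveNet on the tape: input frames as (h, w, 1, t * n) with the time axis
# folded into the batch so the temporal kernel of 1 is exact (no temporal
# mixing, including through the group-normalization statistics).
ag_naivenet <- function(tp, ph, config, x) {
  h <- ag_conv(tp, x, ph$conv1$W, ph$conv1$b)
  h <- ag_groupnorm(tp, h, ph$gn1$gamma, ph$gn1$beta, config$groups)
  h <- ag_leaky_relu(tp, h, config$slope)
  h <- ag_conv(tp, h, ph$conv2$W, ph$conv2$b)
  h <- ag_groupnorm(tp, h, ph$gn2$gamma, ph$gn2$beta, config$groups)
  h <- ag_leaky_relu(tp, h, config$slope)
  ag_conv(tp, h, ph$conv3$W, ph$conv3$b)
}

# ---- exported pure operations ---------------------------------------------

#' One residual-block step
#'
#' Feeds the block input through its two inner peephole ConvLSTM cells and
#' adds the skip connection: `h_out = h_in + h2`, where `h2` is the hidden
#' output of the second inner cell. With all inner weights zero the block is
#' exactly the identity mapping.
#'
#' @param h_in Input grid `(h, w, hidden, batch)`.
#' @param states List with `cell1` and `cell2` recurrent states (see
#'   [recurrent_state()]).
#' @param weights List with `cell1` and `cell2` entries from
#'   [cell_weights()] (type `"convlstm1"` or `"convgru"`).
#'
#' @return `list(h_out =, states =)` with the updated inner-cell states.
#' @export
resblock_step <- function(h_in, states, weights) {
  gru <- identical(attr(weights$cell1, "type"), "convgru")
  tp <- ag_tape()
  pw <- ag_params(tp, weights)
  st <- list(
    cell1 = lapply(states$cell1, function(v) ag_const(tp, v)),
    cell2 = lapply(states$cell2, function(v) ag_const(tp, v))
  )
  out <- ag_resblock(tp, ag_const(tp, h_in), st, pw, gru = gru)
  list(
    h_out = out$h$val,
    states = lapply(out$states, function(cell) lapply(cell, function(nd) nd$val))
  )
}

#' NaiveNet forward pass
#'
#' The three-step-ahead baseline: three 3D convolutional layers with spatial
#' kernels 7x7 and temporal kernel 1, the first two followed by group
#' normalization (2 groups) and LeakyReLU (negative slope 0.2). Because the
#' temporal kernel is 1, each output step depends only on the matching input
#' step; the three outputs are interpreted as the three future time-steps.
#'
#' @param x Input array `[n, 3, 1, h, w]` (the three observed time-steps).
#' @param model A `hic_forecaster` with architecture `"naivenet"`.
#'
#' @return Array `[n, 3, 1, h, w]` of predicted future frames.
#' @export
naivenet_forward <- function(x, model) {
  stopifnot(inherits(model, "hic_forecaster"))
  if (model$config$architecture != "naivenet") stopf("model is not a NaiveNet")
  d <- dim(x)
  if (length(d) != 5 || d[2] != model$config$n_input) {
    stopf("input must be [n, %d, 1, h, w]", model$config$n_input)
  }
  tp <- ag_tape()
  ph <- ag_params(tp, model$params)
  xin <- ag_const(tp, tensor_to_batch(x))
  y <- ag_naivenet(tp, ph, model$config, xin)
  batch_to_tensor(y$val, n = d[1], t = d[2])
}

# ---- tensor-layout helpers -------------------------------------------------

# [n, t, 1, h, w] -> (h, w, 1, t * n): time folded into the batch axis
# (sample-major, step-minor).
tensor_to_batch <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[4], d[5], 1, d[2] * d[1]))
  for (s in seq_len(d[1])) {
    for (t in seq_len(d[2])) {
      out[, , 1, (s - 1) * d[2] + t] <- x[s, t, 1, , ]
    }
  }
  out
}

batch_to_tensor <- function(x, n, t) {
  d <- dim(x)
  out <- array(0, c(n, t, 1, d[1], d[2]))
  for (s in seq_len(n)) {
    for (tt in seq_len(t)) {
      out[s, tt, 1, , ] <- x[, , 1, (s - 1) * t + tt]
    }
  }
  out
}

# Extract time-step t of [n, t, 1, h, w] as (h, w, 1, n).
tensor_frame <- function(x, t) {
  d <- dim(x)
  out <- array(0, c(d[4], d[5], 1, d[1]))
  for (s in seq_len(d[1])) out[, , 1, s] <- x[s, t, 1, , ]
  out
}

# Stack frames (h, w, 1, n) back into [n, length(frames), 1, h, w].
frames_to_tensor <- function(frames) {
  d <- dim(frames[[1]])
  out <- array(0, c(d[4], length(frames), 1, d[1], d[2]))
  for (t in seq_along(frames)) {
    for (s in seq_len(d[4])) out[s, t, 1, , ] <- frames[[t]][, , 1, s]
  }
  out
}
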