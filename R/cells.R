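# Recurrent cells.  Gate transformations are same-padding stride-1
# convolutions; the spatial grid is preserved at every step.  Each cell has
# a tape version (ag_*_step, used by the networks for both prediction and
# training) and an exported pure wrapper operating on plain arrays.
#
# Array layout: activations and states are (height, width, channels, batch);
# convolution kernels are (kh, kw, in_channels, out_channels).

zero_bias <- function(tp, k) ag_const(tp, numeric(k))

# Register every array of a nested named weight list as tape parameters,
# preserving structure, and remember the flat order for gradient collection.
ag_params <- function(tp, weights) {
  rapply(weights, function(w) ag_param(tp, w), classes = "ANY", how = "replace")
}

conv_init <- function(kh, kw, ci, co) {
  s <- 1 / sqrt(kh * kw * ci)
  array(stats::runif(kh * kw * ci * co, -s, s), c(kh, kw, ci, co))
}

#' Create initialized weights for a recurrent cell
#'
#' Gate convolutions use uniform fan-in initialization
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))` with `fan_in = kh * kw * in_channels`);
#' biases and the Hadamard peephole grids of the peephole ConvLSTM start at
#' zero. The peephole grids of the `"convlstm1"` cell have the full spatial
#' shape of the cell state, so `spatial` must match the grids the cell will
#' see.
#'
#' @param type One of `"convlstm1"` (peephole ConvLSTM), `"convlstm2"`
#'   (peepholes removed), `"convlstm3"` (peepholes as convolutions),
#'   `"convgru"`, `"stlstm"`.
#' @param in_ch Input channels.
#' @param hidden Hidden channels.
#' @param kernel Odd spatial kernel size (default 3).
#' @param spatial Spatial grid size `c(h, w)` (needed for the Hadamard
#'   peephole grids of `"convlstm1"`; default `c(50, 50)`).
#' @param seed Optional seed for reproducible initialization.
#'
#' @return A named list of weight arrays with attributes `type`, `in_ch`,
#'   `hidden`, `kernel`.
#' @export
cell_weights <- function(type = c("convlstm1", "convlstm2", "convlstm3", "convgru", "stlstm"),
                         in_ch, hidden, kernel = 3, spatial = c(50, 50), seed = NULL) {
  type <- match.arg(type)
  if (kernel %% 2 == 0) stopf("kernel size must be odd")
  k <- kernel
  ch <- hidden
  w <- with_seed(seed, switch(type,
    convlstm1 = list(
      Wx = conv_init(k, k, in_ch, 4 * ch), Wh = conv_init(k, k, ch, 4 * ch),
      b = numeric(4 * ch),
      Pci = array(0, c(spatial[1], spatial[2], ch)),
      Pcf = array(0, c(spatial[1], spatial[2], ch)),
      Pco = array(0, c(spatial[1], spatial[2], ch))
    ),
    convlstm2 = list(
      Wx = conv_init(k, k, in_ch, 4 * ch), Wh = conv_init(k, k, ch, 4 * ch),
      b = numeric(4 * ch)
    ),
    convlstm3 = list(
      Wx = conv_init(k, k, in_ch, 4 * ch), Wh = conv_init(k, k, ch, 4 * ch),
      b = numeric(4 * ch),
      Wci = conv_init(k, k, ch, ch), Wcf = conv_init(k, k, ch, ch),
      Wco = conv_init(k, k, ch, ch)
    ),
    convgru = list(
      Wx = conv_init(k, k, in_ch, 3 * ch), Whzr = conv_init(k, k, ch, 2 * ch),
      Whg = conv_init(k, k, ch, ch), b = numeric(3 * ch)
    ),
    stlstm = list(
      Wx = conv_init(k, k, in_ch, 7 * ch), Wh = conv_init(k, k, ch, 4 * ch),
      Wm = conv_init(k, k, ch, 3 * ch),
      Wco = conv_init(k, k, ch, ch), Wmo = conv_init(k, k, ch, ch),
      W1 = conv_init(1, 1, 2 * ch, ch),
      b = numeric(7 * ch)
    )
  ))
  attr(w, "type") <- type
  attr(w, "in_ch") <- as.integer(in_ch)
  attr(w, "hidden") <- as.integer(ch)
  attr(w, "kernel") <- as.integer(k)
  w
}

#' Zero-initialized recurrent state
#'
#' @param spatial Spatial grid `c(h, w)`.
#' @param hidden Hidden channels.
#' @param n Batch size.
#' @param stlstm Also allocate the spatiotemporal memory grid `m`.
#'
#' @return List with arrays `h`, `c` (and `m` for ST-LSTM cells), each of
#'   shape `(h, w, hidden, n)` and all zero.
#' @export
recurrent_state <- function(spatial, hidden, n = 1, stlstm = FALSE) {
  z <- array(0, c(spatial[1], spatial[2], hidden, n))
  st <- list(h = z, c = z)
  if (stlstm) st$m <- z
  st
}

# ---- tape steps ------------------------------------------------------------

ag_convlstm_step <- function(tp, x, h, c, pw, variant) {
  ch <- dim(pw$Wh$val)[3]
  # conv(x, Wx) + conv(h, Wh) computed as one convolution of the
  # channel-concatenated input with the channel-concatenated kernels;
  # gate order in z is i, f, g, o
  z <- ag_conv(
    tp, ag_concat_c(tp, list(x, h)),
    ag_concat_c(tp, list(pw$Wx, pw$Wh)), pw$b
  )
  if (variant == 3) { # convolutional peepholes enter the i/f pre-activations
    z <- ag_add_slice(tp, z, ag_conv(tp, c, pw$Wci, zero_bias(tp, ch)), 1L)
    z <- ag_add_slice(tp, z, ag_conv(tp, c, pw$Wcf, zero_bias(tp, ch)), ch + 1L)
  }
  c_new <- if (variant == 1) {
    ag_lstm_cnew(tp, z, c, pw$Pci, pw$Pcf)
  } else {
    ag_lstm_cnew(tp, z, c)
  }
  zo_extra <- if (variant == 3) ag_conv(tp, c_new, pw$Wco, zero_bias(tp, ch)) else NULL
  h_new <- ag_lstm_hout(tp, z, c_new,
    pco = if (variant == 1) pw$Pco else NULL,
    zo_extra = zo_extra
  )
  list(h = h_new, c = c_new)
}

ag_convgru_step <- function(tp, x, h, pw) {
  ch <- dim(pw$Whg$val)[3]
  zx <- ag_conv(tp, x, pw$Wx, pw$b)
  hz <- ag_conv(tp, h, pw$Whzr, zero_bias(tp, 2 * ch))
  z <- ag_sigmoid(tp, ag_add(
    tp, ag_slice_c(tp, zx, 1, ch),
    ag_slice_c(tp, hz, 1, ch)
  ))
  r <- ag_sigmoid(tp, ag_add(
    tp, ag_slice_c(tp, zx, ch + 1, 2 * ch),
    ag_slice_c(tp, hz, ch + 1, 2 * ch)
  ))
  cand <- ag_tanh(tp, ag_add(
    tp, ag_slice_c(tp, zx, 2 * ch + 1, 3 * ch),
    ag_conv(tp, ag_mul(tp, r, h), pw$Whg, zero_bias(tp, ch))
  ))
  h_new <- ag_add(
    tp, ag_mul(tp, ag_one_minus(tp, z), h),
    ag_mul(tp, z, cand)
  )
  list(h = h_new)
}

ag_stlstm_step <- function(tp, x, h, c, m, pw) {
  ch <- dim(pw$Wh$val)[3]
  zx <- ag_conv(tp, x, pw$Wx, pw$b) # i, f, c, i', f', m, o
  zh <- ag_conv(tp, h, pw$Wh, zero_bias(tp, 4 * ch)) # i, f, c, o
  zm <- ag_conv(tp, m, pw$Wm, zero_bias(tp, 3 * ch)) # i', f', m
  sl <- function(node, k) ag_slice_c(tp, node, (k - 1) * ch + 1, k * ch)
  i <- ag_sigmoid(tp, ag_add(tp, sl(zx, 1), sl(zh, 1)))
  f <- ag_sigmoid(tp, ag_add(tp, sl(zx, 2), sl(zh, 2)))
  g <- ag_tanh(tp, ag_add(tp, sl(zx, 3), sl(zh, 3)))
  c_new <- ag_add(tp, ag_mul(tp, f, c), ag_mul(tp, i, g))
  ip <- ag_sigmoid(tp, ag_add(tp, sl(zx, 4), sl(zm, 1)))
  fp <- ag_sigmoid(tp, ag_add(tp, sl(zx, 5), sl(zm, 2)))
  gm <- ag_tanh(tp, ag_add(tp, sl(zx, 6), sl(zm, 3)))
  m_new <- ag_add(tp, ag_mul(tp, fp, m), ag_mul(tp, ip, gm))
  zo <- ag_add(
    tp,
    ag_add(tp, sl(zx, 7), sl(zh, 4)),
    ag_add(
      tp, ag_conv(tp, c_new, pw$Wco, zero_bias(tp, ch)),
      ag_conv(tp, m_new, pw$Wmo, zero_bias(tp, ch))
    )
  )
  o <- ag_sigmoid(tp, zo)
  mix <- ag_conv(
    tp, ag_concat_c(tp, list(c_new, m_new)), pw$W1,
    zero_bias(tp, ch)
  )
  h_new <- ag_mul(tp, o, ag_tanh(tp, mix))
  list(h = h_new, c = c_new, m = m_new)
}

# ---- exported pure wrappers ------------------------------------------------

as_state_array <- function(x, name) {
  if (is.null(dim(x)) || length(dim(x)) != 4) {
    stopf("%s must be a 4-axis (h, w, channels, batch) array", name)
  }
  x
}

#' One ConvLSTM time-step
#'
#' Advances a convolutional LSTM cell by one time-step. Three gate dialects
#' are supported: variant 1 couples the input/forget/output gates to the cell
#' state through Hadamard-product peephole grids, variant 2 removes the
#' peepholes, and variant 3 replaces them with convolutions. The recurrence
#' (gates via sigmoid, candidate via tanh, `c_t = f * c_{t-1} + i * g`,
#' `h_t = o * tanh(c_t)`) is otherwise identical.
#'
#' The step is a pure function of `(x, state, weights)`: repeated calls are
#' bit-identical and the inputs are never modified.
#'
#' @param x Input grid, array `(h, w, in_ch, batch)`.
#' @param state List with `h` and `c` arrays `(h, w, hidden, batch)`; see
#'   [recurrent_state()].
#' @param weights From [cell_weights()] with a `convlstm*` type.
#' @param variant 1, 2 or 3; defaults to the variant the weights were built
#'   for.
#'
#' @return Updated `list(h =, c =)` state.
#' @export
convlstm_step <- function(x, state, weights, variant = NULL) {
  type <- attr(weights, "type")
  variant <- variant %||% as.integer(sub("convlstm", "", type))
  if (!variant %in% 1:3) stopf("variant must be 1, 2 or 3")
  as_state_array(x, "x")
  tp <- ag_tape()
  pw <- ag_params(tp, weights)
  st <- ag_convlstm_step(
    tp, ag_const(tp, x),
    ag_const(tp, as_state_array(state$h, "state$h")),
    ag_const(tp, as_state_array(state$c, "state$c")), pw, variant
  )
  list(h = st$h$val, c = st$c$val)
}

#' One convolutional GRU time-step
#'
#' Standard GRU recurrence with convolutional transformations: update gate
#' `z`, reset gate `r`, candidate `tanh(conv(x) + conv(r * h))`, and
#' `h_t = (1 - z) * h_{t-1} + z * candidate`. There is no cell-memory state.
#'
#' @inheritParams convlstm_step
#' @param state List with an `h` array `(h, w, hidden, batch)`.
#' @param weights From [cell_weights()] with type `"convgru"`.
#'
#' @return Updated `list(h =)` state.
#' @export
convgru_step <- function(x, state, weights) {
  if (!identical(attr(weights, "type"), "convgru")) stopf("weights are not convgru weights")
  tp <- ag_tape()
  pw <- ag_params(tp, weights)
  st <- ag_convgru_step(
    tp, ag_const(tp, as_state_array(x, "x")),
    ag_const(tp, as_state_array(state$h, "state$h")), pw
  )
  list(h = st$h$val)
}

#' One spatiotemporal LSTM (ST-LSTM) time-step
#'
#' Extends the ConvLSTM with a spatiotemporal memory state `m` that flows
#' bottom-up through the layer stack within a time-step and from the top
#' layer back to layer 1 at the next time-step. Primed input/forget gates
#' build `m_t` from the incoming memory; the output gate reads both `c_t`
#' and `m_t` through convolutions; the new hidden state is
#' `o * tanh(W1 * [c_t, m_t])` with `W1` a 1x1 channel-reducing convolution.
#'
#' @inheritParams convlstm_step
#' @param state List with `h`, `c` arrays and the incoming spatiotemporal
#'   memory `m` (from layer `l - 1` at this time-step, or from the top layer
#'   at the previous time-step for layer 1). A missing `m` is an error.
#' @param weights From [cell_weights()] with type `"stlstm"`.
#'
#' @return Updated `list(h =, c =, m =)` state.
#' @export
stlstm_step <- function(x, state, weights) {
  if (!identical(attr(weights, "type"), "stlstm")) stopf("weights are not stlstm weights")
  if (is.null(state$m)) stopf("ST-LSTM needs the spatiotemporal memory state 'm'")
  tp <- ag_tape()
  pw <- ag_params(tp, weights)
  st <- ag_stlstm_step(
    tp, ag_const(tp, as_state_array(x, "x")),
    ag_const(tp, as_state_array(state$h, "state$h")),
    ag_const(tp, as_state_array(state$c, "state$c")),
    ag_const(tp, as_state_array(state$m, "state$m")), pw
  )
  list(h = st$h$val, c = st$c$val, m = st$m$val)
}
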