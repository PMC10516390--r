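# Training loops (Adam + BPTT through the tape), autoregressive rollout,
# checkpointing and genome-wide prediction.

#' Training configuration
#'
#' @param scheme `"next_frame"` (each frame reconstructs the next one, with
#'   the model's own outputs fed back after the observed steps; loss pooled
#'   over reconstructions of steps 2..T) or `"three_step"` (one pass maps the
#'   three observed frames to the three future frames; loss over those
#'   three).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Training epochs.
#' @param seed Seed controlling minibatch shuffling.
#' @param clip_norm Global gradient-norm clip (default 1.0) stabilizing the
#'   deep residual recurrences; `Inf` disables clipping.
#'
#' @return An object of class `train_config`.
#' @export
train_config <- function(scheme = c("next_frame", "three_step"),
                         batch_size = 32, lr = 1e-4, epochs = 10,
                         seed = 1L, clip_norm = 1.0) {
  scheme <- match.arg(scheme)
  if (!(lr >= 0)) stopf("lr must be nonnegative") # lr = 0 allowed as a diagnostic
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  structure(
    list(
      scheme = scheme, batch_size = as.integer(batch_size), lr = lr,
      epochs = as.integer(epochs), seed = as.integer(seed), clip_norm = clip_norm
    ),
    class = "train_config"
  )
}

# ---- tape rollout ----------------------------------------------------------

# Next-frame rollout on an open tape. frames: list of (h, w, 1, n) const
# nodes (the observed steps; length >= n_input). Reconstructs steps
# 2..(n_input + n_future): true previous frames feed steps 2..n_input, then
# the model's own output is fed back.
ag_rollout <- function(tp, ph, config, frames, n_future) {
  states <- init_states(tp, config, n = dim(frames[[1]]$val)[4])
  n_in <- config$n_input
  recon <- vector("list", n_in - 1L + n_future)
  for (t in seq_len(n_in - 1L + n_future)) {
    input <- if (t <= n_in) frames[[t]] else recon[[t - 1L]]
    out <- ag_model_step(tp, ph, config, input, states)
    states <- out$states
    recon[[t]] <- out$y
  }
  recon # recon[[t]] is the reconstruction of step t + 1
}

#' Autoregressive next-frame rollout
#'
#' Runs a next-frame network over the observed frames and then feeds its own
#' predictions back: steps 2..3 are reconstructed from true previous frames,
#' and from step 4 onward the input is the previous prediction. The rollout
#' consumes only the first `n_input` observed frames; later frames in the
#' input tensor are ignored.
#'
#' @param model A `hic_forecaster` with a next-frame architecture.
#' @param inputs A `sample_tensor` or a 5-axis array `[n, t, 1, w, w]` with
#'   at least `n_input` time-steps.
#' @param n_future Future steps to forecast after the observed ones
#'   (default 3).
#'
#' @return List with `reconstructions` (array `[n, n_input - 1 + n_future,
#'   1, w, w]` holding the reconstructions of steps `2 .. n_input + n_future`)
#'   and `predicted` (array `[n, n_future, 1, w, w]`, the forecast steps
#'   only).
#' @export
rollout_next_frame <- function(model, inputs, n_future = 3) {
  stopifnot(inherits(model, "hic_forecaster"))
  config <- model$config
  if (config$architecture == "naivenet") {
    stopf("NaiveNet is a three-step-ahead model; use naivenet_forward()")
  }
  data <- if (inherits(inputs, "sample_tensor")) inputs$data else inputs
  d <- dim(data)
  if (length(d) != 5) stopf("inputs must be an [n, t, 1, w, w] array")
  if (d[2] < config$n_input) stopf("need at least %d observed steps, got %d", config$n_input, d[2])
  tp <- ag_tape()
  ph <- ag_params(tp, model$params)
  frames <- lapply(seq_len(config$n_input), function(t) ag_const(tp, tensor_frame(data, t)))
  recon <- ag_rollout(tp, ph, config, frames, n_future)
  recon_arr <- frames_to_tensor(lapply(recon, `[[`, "val"))
  n_in <- config$n_input
  list(
    reconstructions = recon_arr,
    predicted = recon_arr[, n_in - 1L + seq_len(n_future), , , , drop = FALSE]
  )
}

#' Pooled next-frame reconstruction loss
#'
#' Mean squared error pooled over all next-frame reconstructions (steps
#' 2..T) against the true frames.
#'
#' @param result Output of [rollout_next_frame()] (or its `reconstructions`
#'   array).
#' @param truth Array of the true frames being reconstructed, same shape as
#'   `reconstructions` (steps 2..T of the sample tensor).
#'
#' @return Nonnegative scalar.
#' @export
loss_next_frame <- function(result, truth) {
  recon <- if (is.list(result)) result$reconstructions else result
  if (!identical(dim(recon), dim(truth))) stopf("reconstruction/truth shape mismatch")
  mean((recon - truth)^2)
}

#' Three-step-ahead loss
#'
#' Mean squared error over the three forecast frames only. Note that
#' next-frame and three-step losses live on different supports (the former
#' also pools the easy early-step reconstructions), so their values are not
#' comparable across schemes.
#'
#' @param predictions Array `[n, 3, 1, w, w]` of forecast frames.
#' @param truth Matching array of true future frames.
#'
#' @return Nonnegative scalar.
#' @export
loss_three_step <- function(predictions, truth) {
  if (!identical(dim(predictions), dim(truth))) stopf("prediction/truth shape mismatch")
  mean((predictions - truth)^2)
}

# ---- parameter-tree utilities ---------------------------------------------

tree_leaves_apply <- function(ph, grads) {
  # map handle tree -> gradient tree (zeros where a parameter got no grad)
  if (is.list(ph) && !is.null(ph$id) && !is.null(ph$val) && length(ph) == 2) {
    g <- grads[[ph$id]]
    if (is.null(g)) {
      g <- ph$val * 0
    }
    return(g)
  }
  lapply(ph, tree_leaves_apply, grads = grads)
}

tree_map <- function(f, ...) {
  trees <- list(...)
  if (!is.list(trees[[1]])) {
    return(do.call(f, trees))
  }
  out <- vector("list", length(trees[[1]]))
  for (k in seq_along(out)) {
    out[[k]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, k)))
  }
  attributes(out) <- attributes(trees[[1]]) # keep names and cell-type tags
  out
}

tree_sumsq <- function(tree) {
  if (!is.list(tree)) {
    return(sum(tree^2))
  }
  sum(vapply(tree, tree_sumsq, numeric(1)))
}

# ---- loss on the tape for one minibatch ------------------------------------

ag_minibatch_loss <- function(tp, ph, config, scheme, batch) {
  d <- dim(batch)
  total_t <- d[2]
  if (scheme == "next_frame") {
    frames <- lapply(seq_len(total_t), function(t) ag_const(tp, tensor_frame(batch, t)))
    n_future <- total_t - config$n_input
    recon <- ag_rollout(tp, ph, config, frames[seq_len(config$n_input)], n_future)
    losses <- lapply(seq_along(recon), function(t) {
      ag_mse(tp, recon[[t]], frames[[t + 1L]]$val)
    })
    ag_mean_scalars(tp, losses)
  } else {
    n_in <- config$n_input
    if (total_t < 2L * n_in) stopf("three_step scheme needs %d time-steps", 2L * n_in)
    xin <- ag_const(tp, tensor_to_batch(batch[, seq_len(n_in), , , , drop = FALSE]))
    y <- ag_naivenet(tp, ph, config, xin)
    truth <- tensor_to_batch(batch[, n_in + seq_len(n_in), , , , drop = FALSE])
    ag_mse(tp, y, truth)
  }
}

# Forward-only loss, evaluated in chunks to bound the tape's memory.
eval_loss <- function(model, samples, scheme, chunk = 8L) {
  data <- if (inherits(samples, "sample_tensor")) samples$data else samples
  n <- dim(data)[1]
  starts <- seq.int(1L, n, by = chunk)
  losses <- numeric(length(starts))
  sizes <- numeric(length(starts))
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + chunk - 1L, n)
    tp <- ag_tape()
    ph <- ag_params(tp, model$params)
    losses[bi] <- ag_minibatch_loss(
      tp, ph, model$config, scheme,
      data[idx, , , , , drop = FALSE]
    )$val
    sizes[bi] <- length(idx)
  }
  sum(losses * sizes) / sum(sizes)
}

# ---- training --------------------------------------------------------------

#' Train a forecasting network
#'
#' Minibatch Adam on the scheme's pooled MSE loss, with global
#' gradient-norm clipping. Per-epoch training loss (mean over minibatches)
#' and validation loss are recorded; the returned model carries the weights
#' of the epoch with the best validation loss (best training loss when no
#' validation samples are given). Given the same seed the whole run,
#' including shuffling, is deterministic.
#'
#' @param model A `hic_forecaster` (freshly built or to be fine-tuned).
#' @param samples Training `sample_tensor` (6 time-steps for the full
#'   3-in/3-out protocol; at least `n_input + 1` for next-frame).
#' @param config A [train_config()].
#' @param val_samples Optional validation `sample_tensor` (typically the
#'   windows of a held-out chromosome).
#'
#' @return List with `model` (best checkpoint), `history` (tibble with
#'   `epoch`, `train_loss`, `val_loss`) and `best_epoch`.
#' @export
train <- function(model, samples, config, val_samples = NULL) {
  stopifnot(inherits(model, "hic_forecaster"), inherits(config, "train_config"))
  data <- if (inherits(samples, "sample_tensor")) samples$data else samples
  d <- dim(data)
  min_t <- if (config$scheme == "next_frame") model$config$n_input + 1L else 2L * model$config$n_input
  if (d[2] < min_t) stopf("samples have %d time-steps; the %s scheme needs >= %d", d[2], config$scheme, min_t)
  if (config$scheme == "three_step" && model$config$architecture != "naivenet") {
    stopf("three_step scheme requires a NaiveNet model")
  }
  if (config$scheme == "next_frame" && model$config$architecture == "naivenet") {
    stopf("next_frame scheme requires a recurrent model")
  }

  params <- model$params
  adam_m <- tree_map(function(p) p * 0, params)
  adam_v <- tree_map(function(p) p * 0, params)
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  step <- 0L

  n <- d[1]
  hist_train <- numeric(config$epochs)
  hist_val <- rep(NA_real_, config$epochs)
  best <- Inf
  best_params <- params
  best_epoch <- NA_integer_

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        batch <- data[idx, , , , , drop = FALSE]
        tp <- ag_tape()
        ph <- ag_params(tp, params)
        loss_nd <- ag_minibatch_loss(tp, ph, model$config, config$scheme, batch)
        if (!is.finite(loss_nd$val)) {
          stopf(
            "non-finite loss at epoch %d, minibatch %d (loss=%g); try a smaller lr",
            epoch, bi, loss_nd$val
          )
        }
        batch_losses[bi] <- loss_nd$val
        grads <- ag_backward(tp, loss_nd)
        gtree <- tree_leaves_apply(ph, grads)
        gnorm <- sqrt(tree_sumsq(gtree))
        if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
          gtree <- tree_map(function(g) g * (config$clip_norm / gnorm), gtree)
        }
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        adam_m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, adam_m, gtree)
        adam_v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, adam_v, gtree)
        params <- tree_map(
          function(p, m, v) p - config$lr * corr * m / (sqrt(v) + eps),
          params, adam_m, adam_v
        )
      }
      hist_train[epoch] <- mean(batch_losses)
      cand <- list(config = model$config, params = params, census = model$census)
      class(cand) <- "hic_forecaster"
      score <- if (!is.null(val_samples)) {
        hist_val[epoch] <- eval_loss(cand, val_samples, config$scheme)
        hist_val[epoch]
      } else {
        hist_train[epoch]
      }
      if (score < best) {
        best <- score
        best_params <- params
        best_epoch <- epoch
      }
    }
  })

  out_model <- structure(
    list(config = model$config, params = best_params, census = model$census),
    class = "hic_forecaster"
  )
  list(
    model = out_model,
    history = tibble::tibble(
      epoch = seq_len(config$epochs),
      train_loss = hist_train, val_loss = hist_val
    ),
    best_epoch = best_epoch
  )
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the weights, the [model_config()] and the package
#' version in a single file. Reloading reproduces predictions (and hence
#' validation losses) exactly.
#'
#' @param model A `hic_forecaster`.
#' @param path Checkpoint file path.
#' @return `save_forecaster()` returns `path` invisibly; `load_forecaster()`
#'   returns the `hic_forecaster`.
#' @export
save_forecaster <- function(model, path) {
  stopifnot(inherits(model, "hic_forecaster"))
  saveRDS(
    list(
      config = model$config, params = model$params, census = model$census,
      version = as.character(utils::packageVersion("hicforecast"))
    ),
    path
  )
  invisible(path)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(path) {
  x <- readRDS(path)
  structure(
    list(config = x$config, params = x$params, census = x$census),
    class = "hic_forecaster"
  )
}

# ---- genome-wide prediction ------------------------------------------------

#' Predict future genome-wide contact matrices
#'
#' End-to-end forecasting for one chromosome: slide windows along the
#' diagonal of the observed (rescaled) time-steps, roll the model forward,
#' and reassemble the overlapping window predictions by per-pixel averaging.
#' Pixels outside the sampled diagonal band are `NA`.
#'
#' @param model A trained `hic_forecaster`.
#' @param stack [hic_stack()] with at least `n_input` observed time-steps,
#'   already rescaled to `[0, 1]` (see [rescale_hic()]).
#' @param window,step Sliding-window size and stride in bins (defaults 50
#'   and 3).
#' @param n_future Future steps to forecast (default 3).
#'
#' @return List of `n_future` [contact_matrix()] objects (steps
#'   `n_input + 1, ...`), symmetric with entries in `[0, 1]` where defined.
#' @export
predict_genome <- function(model, stack, window = 50, step = 3, n_future = 3) {
  stopifnot(inherits(model, "hic_forecaster"), inherits(stack, "hic_stack"))
  n_in <- model$config$n_input
  if (length(stack) < n_in) stopf("stack has %d steps; model needs %d observed", length(stack), n_in)
  obs <- hic_stack(stack[seq_len(n_in)])
  st <- extract_windows(obs, window = window, step = step)
  pred <- if (model$config$architecture == "naivenet") {
    naivenet_forward(st$data, model)
  } else {
    rollout_next_frame(model, st, n_future = n_future)$predicted
  }
  reassemble(pred, st$offsets, st$n_bins,
    chrom = st$chrom, resolution = st$resolution, clamp = TRUE
  )
}
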