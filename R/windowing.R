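#' Extract diagonal sliding-window samples from a stack
#'
#' Slides a `window x window` square along the main diagonal of every
#' time-step with a stride of `step` bins and stacks the submatrices into the
#' 5-axis sample tensor `[n, t, 1, window, window]` used by the forecasting
#' networks. Sample `s` covers bins `[offset_s, offset_s + window)` with
#' `offset_s = 0, step, 2 * step, ...` while the window fits; trailing bins
#' that do not admit a full window are dropped.
#'
#' @param stack An [hic_stack()] whose matrices all have at least `window`
#'   bins. For training the stack should already be rescaled to `[0, 1]`
#'   (see [rescale_hic()]).
#' @param window Window size in bins (default 50).
#' @param step Stride in bins (default 3).
#'
#' @return An object of class `sample_tensor`: list with `data` (array
#'   `[n, t, 1, window, window]`), `offsets` (0-based diagonal start bin per
#'   sample), `window`, `step`, `n_bins`, `chrom`, `resolution`.
#' @examples
#' stack <- generate_stack(synthetic_config(n_bins = 110, tad_boundaries = c(40, 70)))
#' rs <- rescale_hic(stack, choose_max_hic(stack))
#' sw <- extract_windows(rs, window = 50, step = 3)
#' sw # 21 diagonal windows per time-step
#' rec <- reassemble(sw$data, sw$offsets, sw$n_bins) # exact on covered pixels
#' @export
extract_windows <- function(stack, window = 50, step = 3) {
  stopifnot(inherits(stack, "hic_stack"))
  nb <- n_bins(stack[[1]])
  if (nb < window) {
    stopf(
      "matrix has %d bins but the window needs %d; use more bins or a smaller window",
      nb, window
    )
  }
  if (!is_count(window) || !is_count(step)) stopf("window and step must be positive integers")
  offsets <- seq.int(0L, nb - window, by = step)
  n <- length(offsets)
  tt <- length(stack)
  data <- array(0, c(n, tt, 1, window, window))
  for (s in seq_len(n)) {
    rows <- offsets[s] + seq_len(window)
    for (t in seq_len(tt)) {
      data[s, t, 1, , ] <- stack[[t]]$values[rows, rows]
    }
  }
  structure(
    list(
      data = data, offsets = as.integer(offsets),
      window = as.integer(window), step = as.integer(step),
      n_bins = as.integer(nb),
      chrom = stack[[1]]$chrom, resolution = stack[[1]]$resolution
    ),
    class = "sample_tensor"
  )
}

#' @export
print.sample_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sample_tensor> %d samples x %d steps x 1 x %d x %d (%s, %d bins, step %d)\n",
    d[1], d[2], d[4], d[5], x$chrom, x$n_bins, x$step
  ))
  invisible(x)
}

#' Reassemble windowed predictions into genome-scale matrices
#'
#' Inverse of [extract_windows()]: every pixel of the output matrix is the
#' arithmetic mean of all window predictions covering it. Predictions are
#' clamped to `[0, 1]` before accumulation (network outputs can slightly
#' overshoot the rescaled range), the result is symmetrized as
#' `(M + t(M)) / 2`, and pixels never covered by any window (the far
#' off-diagonal band) are `NA`.
#'
#' @param predictions Array `[n, t_pred, 1, window, window]` (or
#'   `[n, window, window]` for a single step) of predicted windows.
#' @param offsets 0-based diagonal start bin of each sample (as produced by
#'   [extract_windows()]).
#' @param n_bins Number of bins of the full matrix.
#' @param chrom,resolution Metadata for the output matrices.
#' @param clamp Clamp predictions to `[0, 1]` before averaging (default TRUE).
#'
#' @return A list of [contact_matrix()] objects, one per predicted step.
#' @export
reassemble <- function(predictions, offsets, n_bins,
                       chrom = "chrS", resolution = 40000, clamp = TRUE) {
  d <- dim(predictions)
  if (length(d) == 3) {
    predictions <- array(predictions, c(d[1], 1, 1, d[2], d[3]))
    d <- dim(predictions)
  }
  if (length(d) != 5) stopf("predictions must be an [n, t, 1, w, w] array")
  n <- d[1]
  window <- d[4]
  if (length(offsets) != n) stopf("offsets length (%d) != samples (%d)", length(offsets), n)
  if (any(offsets < 0 | offsets + window > n_bins)) {
    stopf("offset out of range for %d bins and window %d", n_bins, window)
  }
  out <- vector("list", d[2])
  for (t in seq_len(d[2])) {
    acc_sum <- matrix(0, n_bins, n_bins)
    acc_cnt <- matrix(0L, n_bins, n_bins)
    for (s in seq_len(n)) {
      rows <- offsets[s] + seq_len(window)
      w <- predictions[s, t, 1, , ]
      if (clamp) w <- pmin(pmax(w, 0), 1)
      acc_sum[rows, rows] <- acc_sum[rows, rows] + w
      acc_cnt[rows, rows] <- acc_cnt[rows, rows] + 1L
    }
    vals <- acc_sum / ifelse(acc_cnt > 0, acc_cnt, NA_integer_)
    vals <- (vals + t(vals)) / 2
    out[[t]] <- contact_matrix(vals, chrom = chrom, resolution = resolution)
  }
  out
}
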