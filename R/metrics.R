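# Evaluation stack: distance-stratified Pearson correlation, HiCRep-style
# stratum-adjusted correlation (SCC), insulation scores and TAD-boundary
# recovery.

as_cm_values <- function(x) {
  if (inherits(x, "contact_matrix")) {
    return(x$values)
  }
  as.matrix(x)
}

diag_at <- function(m, d) m[cbind(seq_len(nrow(m) - d), seq_len(nrow(m) - d) + d)]

#' Distance-stratified Pearson correlation
#'
#' For each genomic distance `d` (in bins) the Pearson correlation between
#' the `d`-th diagonals of the two matrices. Matrices from several
#' chromosomes can be pooled by passing lists: the diagonal vectors are
#' concatenated per distance before correlating. Pixels that are `NA` in
#' either matrix are dropped pairwise. A stratum whose retained values are
#' constant in either matrix is flagged undefined (`r` is `NA`), never
#' silently zero.
#'
#' @param a,b [contact_matrix()] objects (or plain matrices), or lists of
#'   them to pool. Shapes must match elementwise.
#' @param d_min,d_max Distance range in bins (defaults 10 and 30).
#'
#' @return Tibble with `distance`, `r`, `n` (pairs used) and `defined`.
#' @export
stratified_pearson <- function(a, b, d_min = 10, d_max = 30) {
  if (!is.list(a) || inherits(a, "contact_matrix")) a <- list(a)
  if (!is.list(b) || inherits(b, "contact_matrix")) b <- list(b)
  if (length(a) != length(b)) stopf("a and b must have the same number of matrices")
  av <- lapply(a, as_cm_values)
  bv <- lapply(b, as_cm_values)
  for (k in seq_along(av)) {
    if (!identical(dim(av[[k]]), dim(bv[[k]]))) stopf("matrix %d: shape mismatch", k)
  }
  ds <- d_min:d_max
  r <- rep(NA_real_, length(ds))
  n_used <- integer(length(ds))
  for (k in seq_along(ds)) {
    x <- unlist(lapply(av, diag_at, d = ds[k]))
    y <- unlist(lapply(bv, diag_at, d = ds[k]))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    n_used[k] <- length(x)
    if (length(x) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      r[k] <- stats::cor(x, y)
    }
  }
  tibble::tibble(distance = ds, r = r, n = n_used, defined = !is.na(r))
}

# Uniform (2h+1) x (2h+1) mean filter with the window truncated at the
# matrix borders (shrink-at-edges), NA-tolerant.
smooth_mean <- function(m, h) {
  if (h == 0) {
    return(m)
  }
  n <- nrow(m)
  na_mask <- !is.finite(m)
  vals <- ifelse(na_mask, 0, m)
  ones <- ifelse(na_mask, 0, 1)
  # summed-area tables with a zero border row/column
  sat <- function(x) {
    s <- apply(apply(x, 2, cumsum), 1, cumsum) # t(cumsum rows) of cumsum cols
    rbind(0, cbind(0, t(s)))
  }
  sv <- sat(vals)
  so <- sat(ones)
  lo_i <- pmax(seq_len(n) - h, 1)
  hi_i <- pmin(seq_len(n) + h, n)
  box <- function(s) {
    s[hi_i + 1, hi_i + 1, drop = FALSE] - s[lo_i, hi_i + 1, drop = FALSE] -
      s[hi_i + 1, lo_i, drop = FALSE] + s[lo_i, lo_i, drop = FALSE]
  }
  num <- box(sv)
  den <- box(so)
  out <- ifelse(den > 0, num / den, NA_real_)
  out[na_mask] <- NA_real_
  out
}

# Rank transform to the unit interval (empirical CDF), as in HiCRep's
# variance-stabilizing transformation.
rank_unit <- function(x) rank(x, ties.method = "average") / length(x)

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' HiCRep-style reproducibility score between two contact matrices. Both
#' matrices are first mean-smoothed with a `(2h+1) x (2h+1)` uniform filter
#' (window truncated at the matrix borders). Strata are the diagonals whose
#' genomic distance lies within `[lower_bp, upper_bp]`; each contributes its
#' Pearson correlation `r_k`, combined with weights
#' `N_k * sqrt(var(rank(x)/N) * var(rank(y)/N))` (stratum size times the
#' rank-based variance-stabilization term). Strata that are constant in
#' either matrix are excluded from the weighted sum rather than imputed.
#'
#' @param a,b [contact_matrix()] objects (or plain matrices with
#'   `resolution` supplied).
#' @param h Smoothing half-width in bins (default 5).
#' @param lower_bp,upper_bp Genomic-distance bounds in bp (defaults 400000
#'   and 1600000).
#' @param resolution Bin size in bp; taken from `a` when it is a
#'   `contact_matrix`.
#'
#' @return Object of class `scc_result`: list with `scc`, `strata` (tibble
#'   with `distance`, `r`, `weight`, `n`), `h`, `lower_bp`, `upper_bp`.
#'   `scc` is `NA` when every stratum is undefined.
#' @examples
#' cfg <- synthetic_config(n_bins = 80, tad_boundaries = c(30, 55), depth = 1e5)
#' stack <- generate_stack(cfg)
#' scc(stack[[5]], stack[[6]]) # adjacent time-steps are highly reproducible
#' @export
scc <- function(a, b, h = 5, lower_bp = 400000, upper_bp = 1600000, resolution = NULL) {
  if (inherits(a, "contact_matrix")) resolution <- resolution %||% a$resolution
  if (is.null(resolution)) stopf("resolution must be supplied for plain matrices")
  av <- as_cm_values(a)
  bv <- as_cm_values(b)
  if (!identical(dim(av), dim(bv))) stopf("matrices must have the same shape")
  d_lo <- as.integer(round(lower_bp / resolution))
  d_hi <- as.integer(round(upper_bp / resolution))
  if (d_hi >= nrow(av)) d_hi <- nrow(av) - 1L
  if (d_lo > d_hi) stopf("distance bounds leave no strata")
  as_ <- smooth_mean(av, h)
  bs_ <- smooth_mean(bv, h)
  ds <- d_lo:d_hi
  r <- rep(NA_real_, length(ds))
  w <- rep(0, length(ds))
  n_used <- integer(length(ds))
  for (k in seq_along(ds)) {
    x <- diag_at(as_, ds[k])
    y <- diag_at(bs_, ds[k])
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    n_used[k] <- length(x)
    if (length(x) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      r[k] <- stats::cor(x, y)
      w[k] <- length(x) * sqrt(stats::var(rank_unit(x)) * stats::var(rank_unit(y)))
    }
  }
  ok <- !is.na(r) & w > 0
  val <- if (any(ok)) sum(w[ok] * r[ok]) / sum(w[ok]) else NA_real_
  structure(
    list(
      scc = val,
      strata = tibble::tibble(distance = ds, r = r, weight = w, n = n_used),
      h = h, lower_bp = lower_bp, upper_bp = upper_bp
    ),
    class = "scc_result"
  )
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf(
    "<scc_result> SCC = %.4f over %d strata (h = %d, %s-%s bp)\n",
    x$scc, sum(!is.na(x$strata$r)), x$h,
    format(x$lower_bp, scientific = FALSE), format(x$upper_bp, scientific = FALSE)
  ))
  invisible(x)
}

#' Insulation score track
#'
#' For each bin `b`, the mean contact within the `window_bins`-square
#' below/left of the diagonal spanning bins `[b - w, b - 1] x [b + 1, b + w]`
#' (0-based), normalized by the chromosome-wide mean of that statistic and
#' log2-transformed. Minima of the track mark TAD boundaries. Bins too close
#' to the matrix edge for the full square (and windows touching `NA` or
#' all-zero pixels) are flagged invalid.
#'
#' @param m A [contact_matrix()] or plain matrix.
#' @param window_bins Square size in bins (default 10, i.e. 400 kb at 40-kb
#'   resolution). Requires `n_bins > 2 * window_bins`.
#'
#' @return Tibble with `bin` (0-based), `score` and `valid`. All scores are
#'   `NA` when the chromosome-wide mean is zero or undefined.
#' @export
insulation <- function(m, window_bins = 10) {
  mv <- as_cm_values(m)
  n <- nrow(mv)
  w <- as.integer(window_bins)
  if (n <= 2 * w) stopf("need n_bins > 2 * window_bins (%d bins, window %d)", n, w)
  raw <- rep(NA_real_, n)
  for (b in seq.int(w, n - 1L - w)) { # 0-based bin index
    block <- mv[(b - w + 1L):b, (b + 2L):(b + 1L + w)]
    raw[b + 1L] <- mean(block)
  }
  norm <- mean(raw[is.finite(raw)])
  score <- rep(NA_real_, n)
  if (is.finite(norm) && norm > 0) {
    pos <- is.finite(raw) & raw > 0
    score[pos] <- log2(raw[pos] / norm)
  }
  tibble::tibble(bin = seq_len(n) - 1L, score = score, valid = !is.na(score))
}

#' Call strong boundaries from an insulation track
#'
#' Local minima of the insulation score whose prominence (depth below the
#' lower of the two flanking maxima, scanning outwards until the track drops
#' below the minimum again) exceeds `prominence`.
#'
#' @param track Tibble from [insulation()].
#' @param prominence Minimum prominence in log2 units (default 0.1).
#'
#' @return Sorted integer vector of 0-based boundary bins (possibly empty).
#' @export
call_strong_boundaries <- function(track, prominence = 0.1) {
  s <- track$score
  ok <- which(track$valid)
  if (length(ok) < 3) {
    return(integer())
  }
  lo <- min(ok)
  hi <- max(ok)
  out <- integer()
  for (b in (lo + 1L):(hi - 1L)) {
    if (!track$valid[b]) next
    if (is.na(s[b - 1]) || is.na(s[b + 1])) next
    # local minimum; a flat valley floor is reported at its leftmost bin
    if (!(s[b] < s[b - 1] && s[b] <= s[b + 1])) next
    # scan left / right for the flanking maxima
    max_l <- -Inf
    i <- b - 1L
    while (i >= lo && !is.na(s[i]) && s[i] >= s[b]) {
      max_l <- max(max_l, s[i])
      i <- i - 1L
    }
    max_r <- -Inf
    i <- b + 1L
    while (i <= hi && !is.na(s[i]) && s[i] >= s[b]) {
      max_r <- max(max_r, s[i])
      i <- i + 1L
    }
    if (min(max_l, max_r) - s[b] > prominence) out <- c(out, track$bin[b])
  }
  sort(out)
}

#' Average insulation profile around boundaries
#'
#' Mean insulation score in windows of `+/- flank_bins` centered at each
#' boundary. For true insulation valleys the profile attains its minimum at
#' offset 0; for random positions it is flat.
#'
#' @param track Tibble from [insulation()].
#' @param boundaries 0-based boundary bins.
#' @param flank_bins Half-width of the profile in bins (default 10).
#'
#' @return Tibble with `offset` (`-flank_bins .. flank_bins`), `mean_score`
#'   and `n` (boundaries contributing at each offset). All-`NA` profile when
#'   `boundaries` is empty.
#' @export
boundary_pileup <- function(track, boundaries, flank_bins = 10) {
  offs <- seq.int(-flank_bins, flank_bins)
  if (!length(boundaries)) {
    return(tibble::tibble(offset = offs, mean_score = NA_real_, n = 0L))
  }
  n <- nrow(track)
  if (any(boundaries < 0 | boundaries >= n)) stopf("boundary outside the track")
  prof <- matrix(NA_real_, length(boundaries), length(offs))
  for (k in seq_along(boundaries)) {
    pos <- boundaries[k] + offs # 0-based
    inside <- pos >= 0 & pos < n
    prof[k, inside] <- track$score[pos[inside] + 1L]
  }
  tibble::tibble(
    offset = offs,
    mean_score = colMeans(prof, na.rm = TRUE),
    n = colSums(!is.na(prof))
  )
}

#' Per-time-step evaluation report
#'
#' Convenience wrapper producing the standard per-step report: SCC, the mean
#' and per-distance stratified Pearson correlations, and the number of
#' strong boundaries recovered.
#'
#' @param truth List of ground-truth [contact_matrix()] objects (future
#'   steps).
#' @param pred List of predicted matrices, same length and shapes.
#' @param d_min,d_max Stratified-Pearson distance range in bins.
#' @param scc_h,scc_lower_bp,scc_upper_bp SCC parameters, see [scc()].
#' @param insulation_window,prominence Boundary-calling parameters.
#'
#' @return Tibble with one row per time-step: `step`, `scc`,
#'   `mean_pearson`, `n_boundaries_truth`, `n_boundaries_pred`.
#' @export
metric_report <- function(truth, pred, d_min = 10, d_max = 30,
                          scc_h = 5, scc_lower_bp = 400000, scc_upper_bp = 1600000,
                          insulation_window = 10, prominence = 0.1) {
  if (length(truth) != length(pred)) stopf("truth/pred step counts differ")
  rows <- lapply(seq_along(truth), function(t) {
    sp <- stratified_pearson(truth[[t]], pred[[t]], d_min, d_max)
    sc <- scc(truth[[t]], pred[[t]], h = scc_h, lower_bp = scc_lower_bp, upper_bp = scc_upper_bp)
    bt <- call_strong_boundaries(insulation(truth[[t]], insulation_window), prominence)
    bp_ <- call_strong_boundaries(insulation(pred[[t]], insulation_window), prominence)
    tibble::tibble(
      step = t, scc = sc$scc, mean_pearson = mean(sp$r, na.rm = TRUE),
      n_boundaries_truth = length(bt), n_boundaries_pred = length(bp_)
    )
  })
  do.call(rbind, rows)
}
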