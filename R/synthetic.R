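#' Configuration for the synthetic spatiotemporal Hi-C generator
#'
#' Describes a T-step series of symmetric contact matrices with power-law
#' distance decay, TAD block structure whose within-domain enrichment changes
#' across time-steps, and Poisson count noise at a configurable read depth.
#' The default strength schedule is a linear ramp from 0 to 2 across
#' time-steps, emulating the progressive establishment of TADs during early
#' embryogenesis: at the first step domains are absent, at the last they
#' enrich within-domain contacts threefold over the distance-decay baseline.
#'
#' @param n_bins Number of genomic bins (>= 50 recommended so the default
#'   50-bin sampling window fits).
#' @param n_steps Number of time-steps (default 6).
#' @param decay_exponent Positive exponent `a` of the contact-probability
#'   decay `(1 + d)^(-a)` with genomic distance `d` in bins (default 1).
#' @param tad_boundaries Strictly increasing 0-based bin indices in
#'   `[1, n_bins - 1]` separating consecutive TADs. TADs are the half-open
#'   bin intervals between consecutive boundaries (with 0 and `n_bins` as
#'   implicit outer limits).
#' @param tad_strength_schedule Nonnegative per-step multipliers `s_t`; a
#'   within-TAD pair at step `t` is enriched by the factor `1 + s_t`.
#'   Length `n_steps`. Default: linear ramp from 0 to 2.
#' @param depth Expected total count per matrix (default 1e5).
#' @param seed Integer seed for the Poisson draws.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_stack()], [expected_contact()]
#' @export
synthetic_config <- function(n_bins,
                             n_steps = 6,
                             decay_exponent = 1,
                             tad_boundaries = integer(),
                             tad_strength_schedule = seq(0, 2, length.out = n_steps),
                             depth = 1e5,
                             seed = 1L) {
  if (!is_count(n_bins)) stopf("n_bins must be a positive integer")
  if (!is_count(n_steps)) stopf("n_steps must be a positive integer")
  if (!(is.numeric(decay_exponent) && decay_exponent > 0)) {
    stopf("decay_exponent must be a positive real")
  }
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries)) {
    if (any(diff(tad_boundaries) <= 0)) stopf("tad_boundaries must be strictly increasing")
    if (any(tad_boundaries < 1 | tad_boundaries > n_bins - 1)) {
      stopf("tad_boundaries must lie in [1, n_bins - 1]")
    }
  }
  if (length(tad_strength_schedule) != n_steps) {
    stopf(
      "tad_strength_schedule must have length n_steps (%d), got %d",
      n_steps, length(tad_strength_schedule)
    )
  }
  if (any(tad_strength_schedule < 0)) stopf("tad_strength_schedule values must be nonnegative")
  if (!(is.numeric(depth) && length(depth) == 1 && depth > 0)) stopf("depth must be > 0")
  structure(
    list(
      n_bins = as.integer(n_bins),
      n_steps = as.integer(n_steps),
      decay_exponent = decay_exponent,
      tad_boundaries = tad_boundaries,
      tad_strength_schedule = as.numeric(tad_strength_schedule),
      depth = depth,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# 0-based TAD id per bin: bins between consecutive boundaries share an id.
tad_id <- function(config) {
  findInterval(seq_len(config$n_bins) - 1L, config$tad_boundaries)
}

#' Expected (noise-free) contact intensity of a synthetic bin pair
#'
#' Relative contact intensity of the pair `(i, j)` at one time-step:
#' `(1 + |i - j|)^(-a)`, multiplied by `1 + s_step` when `i` and `j` fall in
#' the same TAD. Intensities are on an arbitrary scale; [expected_matrix()]
#' rescales them so the expected matrix total equals `depth`.
#'
#' @param config A [synthetic_config()].
#' @param step Time-step, 0-based (`0 <= step < n_steps`).
#' @param i,j 0-based bin indices.
#'
#' @return Nonnegative real intensity (vectorized over `i`, `j`).
#' @export
expected_contact <- function(config, step, i, j) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(step < 0 | step >= config$n_steps)) stopf("step out of range [0, n_steps)")
  if (any(i < 0 | i >= config$n_bins | j < 0 | j >= config$n_bins)) {
    stopf("bin index out of range [0, n_bins)")
  }
  base <- (1 + abs(i - j))^(-config$decay_exponent)
  tid <- tad_id(config)
  same <- tid[i + 1L] == tid[j + 1L]
  base * ifelse(same, 1 + config$tad_strength_schedule[step + 1L], 1)
}

#' Expected contact matrix of one synthetic time-step
#'
#' The analytic (noise-free) mean matrix at a time-step, scaled so that its
#' total equals `depth`. This is the Poisson mean surface that
#' [generate_stack()] samples from, and is useful as a ground-truth target
#' (for example, for checking that insulation minima sit at the configured
#' TAD boundaries).
#'
#' @inheritParams expected_contact
#' @param chrom Chromosome name attached to the output.
#' @param resolution Bin size in bp attached to the output.
#'
#' @return A [contact_matrix()] of expected counts (not integers).
#' @export
expected_matrix <- function(config, step, chrom = "chrS", resolution = 40000) {
  stopifnot(inherits(config, "synthetic_config"))
  if (step < 0 || step >= config$n_steps) stopf("step out of range [0, n_steps)")
  nb <- config$n_bins
  d <- abs(outer(seq_len(nb) - 1L, seq_len(nb) - 1L, `-`))
  base <- (1 + d)^(-config$decay_exponent)
  tid <- tad_id(config)
  same <- outer(tid, tid, `==`)
  e <- base * (1 + config$tad_strength_schedule[step + 1L] * same)
  e <- e * (config$depth / sum(e))
  contact_matrix(e, chrom = chrom, resolution = resolution)
}

#' Generate a seeded synthetic spatiotemporal Hi-C stack
#'
#' Draws each time-step as independent Poisson counts around the analytic
#' mean surface of [expected_matrix()]. Noise is applied to the upper
#' triangle (diagonal included) only and mirrored to the lower triangle, so
#' the result is exactly symmetric. The same configuration and seed always
#' produce a bit-identical stack.
#'
#' @inheritParams expected_matrix
#'
#' @return An [hic_stack()] of `n_steps` integer-count contact matrices.
#' @examples
#' cfg <- synthetic_config(n_bins = 60, tad_boundaries = c(20, 40), depth = 1e4)
#' stack <- generate_stack(cfg)
#' stack
#' sum(stack[[1]]$values) # close to the configured depth
#' @export
generate_stack <- function(config, chrom = "chrS", resolution = 40000) {
  stopifnot(inherits(config, "synthetic_config"))
  nb <- config$n_bins
  upper <- upper.tri(matrix(0, nb, nb), diag = TRUE)
  mats <- with_seed(config$seed, {
    lapply(seq_len(config$n_steps) - 1L, function(step) {
      mu <- expected_matrix(config, step, chrom, resolution)$values
      m <- matrix(0, nb, nb)
      m[upper] <- stats::rpois(sum(upper), mu[upper])
      m <- m + t(m) - diag(diag(m))
      contact_matrix(m, chrom = chrom, resolution = resolution)
    })
  })
  hic_stack(mats)
}
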