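# Independent oracles used across the suite.  These are deliberately written
# as direct transcriptions of the defining formulas (loops, scalars), never
# calling the implementation paths they check.

# scalar peephole LSTM (one unit, 1x1 grid)
scalar_lstm_step <- function(x, h, c, W) {
  i <- plogis(W$wxi * x + W$whi * h + W$wci * c + W$bi)
  f <- plogis(W$wxf * x + W$whf * h + W$wcf * c + W$bf)
  cn <- f * c + i * tanh(W$wxc * x + W$whc * h + W$bc)
  o <- plogis(W$wxo * x + W$who * h + W$wco * cn + W$bo)
  list(h = o * tanh(cn), c = cn)
}

# scalar GRU (one unit)
scalar_gru_step <- function(x, h, W) {
  z <- plogis(W$wxz * x + W$whz * h + W$bz)
  r <- plogis(W$wxr * x + W$whr * h + W$br)
  cand <- tanh(W$wxg * x + W$whg * (r * h) + W$bg)
  (1 - z) * h + z * cand
}

# brute-force dense 2D same-padding cross-correlation
conv2d_oracle <- function(x, w, b) {
  d <- dim(x)
  dw <- dim(w)
  H <- d[1]; W_ <- d[2]; ci <- d[3]; n <- d[4]
  kh <- dw[1]; kw <- dw[2]; co <- dw[4]
  ph <- kh %/% 2; pw <- kw %/% 2
  y <- array(0, c(H, W_, co, n))
  for (s in 1:n) for (o in 1:co) for (i in 1:H) for (j in 1:W_) {
    acc <- b[o]
    for (cc in 1:ci) for (di in 1:kh) for (dj in 1:kw) {
      ii <- i + di - 1 - ph; jj <- j + dj - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W_) {
        acc <- acc + x[ii, jj, cc, s] * w[di, dj, cc, o]
      }
    }
    y[i, j, o, s] <- acc
  }
  y
}

# per-diagonal Pearson by the direct formula
pearson_direct <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

stratified_pearson_oracle <- function(a, b, d_min, d_max) {
  vapply(d_min:d_max, function(d) {
    x <- a[cbind(seq_len(nrow(a) - d), seq_len(nrow(a) - d) + d)]
    y <- b[cbind(seq_len(nrow(b) - d), seq_len(nrow(b) - d) + d)]
    pearson_direct(x, y)
  }, numeric(1))
}

# literal stratum-by-stratum transcription of the HiCRep SCC: smooth both
# matrices with a truncated uniform filter (explicit loops), then combine
# per-stratum Pearson r_k with weights N_k * sqrt(var(rank x / N) var(rank y / N))
scc_oracle <- function(a, b, h, d_lo, d_hi) {
  n <- nrow(a)
  sm <- function(m) {
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      ri <- max(1, i - h):min(n, i + h)
      rj <- max(1, j - h):min(n, j + h)
      out[i, j] <- mean(m[ri, rj])
    }
    out
  }
  as_ <- sm(a); bs_ <- sm(b)
  num <- 0; den <- 0
  for (d in d_lo:d_hi) {
    x <- as_[cbind(seq_len(n - d), seq_len(n - d) + d)]
    y <- bs_[cbind(seq_len(n - d), seq_len(n - d) + d)]
    if (sd(x) == 0 || sd(y) == 0) next
    r <- pearson_direct(x, y)
    w <- length(x) * sqrt(var(rank(x) / length(x)) * var(rank(y) / length(y)))
    num <- num + w * r
    den <- den + w
  }
  num / den
}

# brute-force insulation on a plain matrix (0-based bins)
insulation_oracle <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (b in w:(n - 1 - w)) {
    raw[b + 1] <- mean(m[(b - w + 1):b, (b + 2):(b + 1 + w)])
  }
  log2(raw / mean(raw, na.rm = TRUE))
}

# random symmetric matrix with values in [0, 1]
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  (m + t(m)) / 2
}

# set every weight array of a nested parameter list to zero
zero_weights <- function(w) {
  at <- attributes(w)
  w <- rapply(w, function(a) a * 0, classes = "ANY", how = "replace")
  attributes(w) <- at
  w
}

# shared synthetic study conditions for the scaled-down training benchmark:
# 120 bins, depth 1e5, six steps, TAD-establishment ramp (generator default)
bench_stack <- function(seed, boundaries) {
  generate_stack(synthetic_config(
    n_bins = 120, n_steps = 6, decay_exponent = 1,
    tad_boundaries = boundaries, depth = 1e5, seed = seed
  ))
}
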