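test_that("stratified Pearson hits its closed-form cases", {
  a <- random_symmetric(60, seed = 1)
  sp <- stratified_pearson(a, a, 10, 30)
  expect_equal(sp$distance, 10:30)
  expect_true(all(sp$defined))
  expect_true(all(abs(sp$r - 1) < 1e-12))
  # perfect anti-correlation: B = -A + const
  b <- -a + 2
  spb <- stratified_pearson(a, b, 10, 30)
  expect_true(all(abs(spb$r + 1) < 1e-12))
  # constant strata are flagged undefined, never silently 0
  cst <- matrix(1, 60, 60)
  spc <- stratified_pearson(contact_matrix(cst), contact_matrix(cst), 10, 12)
  expect_true(all(!spc$defined))
  expect_true(all(is.na(spc$r)))
  expect_error(stratified_pearson(a, random_symmetric(50, 2)), "shape")
})

test_that("stratified Pearson equals the direct per-diagonal formula", {
  a <- random_symmetric(60, seed = 3)
  b <- random_symmetric(60, seed = 4)
  got <- stratified_pearson(a, b, 10, 30)$r
  want <- stratified_pearson_oracle(a, b, 10, 30)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("pooling chromosomes concatenates diagonals before correlating", {
  a1 <- random_symmetric(50, 5)
  a2 <- random_symmetric(64, 6)
  b1 <- random_symmetric(50, 7)
  b2 <- random_symmetric(64, 8)
  got <- stratified_pearson(list(a1, a2), list(b1, b2), 12, 15)$r
  for (k in seq_along(12:15)) {
    d <- (12:15)[k]
    x <- c(
      a1[cbind(seq_len(50 - d), seq_len(50 - d) + d)],
      a2[cbind(seq_len(64 - d), seq_len(64 - d) + d)]
    )
    y <- c(
      b1[cbind(seq_len(50 - d), seq_len(50 - d) + d)],
      b2[cbind(seq_len(64 - d), seq_len(64 - d) + d)]
    )
    expect_equal(got[k], pearson_direct(x, y), tolerance = 1e-12)
  }
})

test_that("SCC matches an independent stratum-by-stratum transcription", {
  res <- 40000
  a <- random_symmetric(70, seed = 9) * 20
  b <- a * 0.6 + random_symmetric(70, seed = 10) * 8
  got <- scc(contact_matrix(a, resolution = res), contact_matrix(b, resolution = res))
  want <- scc_oracle(a, b, h = 5, d_lo = 400000 / res, d_hi = 1600000 / res)
  expect_lt(abs(got$scc - want), 1e-10)
  expect_true(got$scc >= -1 && got$scc <= 1)
  # weights are nonnegative and the combination is weight-normalized
  ok <- !is.na(got$strata$r)
  expect_true(all(got$strata$weight[ok] >= 0))
  expect_equal(
    got$scc,
    sum(got$strata$weight[ok] * got$strata$r[ok]) / sum(got$strata$weight[ok])
  )
})

test_that("SCC is reflexive, symmetric and scale invariant", {
  a <- random_symmetric(70, seed = 11) * 15
  b <- random_symmetric(70, seed = 12) * 15
  ca <- contact_matrix(a, resolution = 40000)
  cb <- contact_matrix(b, resolution = 40000)
  expect_equal(scc(ca, ca)$scc, 1, tolerance = 1e-12)
  expect_lt(abs(scc(ca, cb)$scc - scc(cb, ca)$scc), 1e-12)
  # common positive rescaling changes nothing
  s1 <- scc(ca, cb)$scc
  s2 <- scc(
    contact_matrix(a * 7.3, resolution = 40000),
    contact_matrix(b * 7.3, resolution = 40000)
  )$scc
  expect_lt(abs(s1 - s2), 1e-10)
  # stratified Pearson shares the invariance
  p1 <- stratified_pearson(a, b, 10, 20)$r
  p2 <- stratified_pearson(a * 7.3, b * 7.3, 10, 20)$r
  expect_lt(max(abs(p1 - p2)), 1e-10)
  # all-constant strata give the undefined marker
  cst <- contact_matrix(matrix(2, 70, 70), resolution = 40000)
  expect_true(is.na(scc(cst, cst)$scc))
})

test_that("insulation matches its brute-force oracle and masks edges", {
  m <- random_symmetric(50, seed = 13) * 10 + 1
  tr <- insulation(m, window_bins = 8)
  want <- insulation_oracle(m, 8)
  expect_equal(nrow(tr), 50)
  expect_true(all(!tr$valid[c(1:8, 43:50)])) # first/last w bins masked
  ok <- tr$valid
  expect_lt(max(abs(tr$score[ok] - want[ok])), 1e-12)
  # constant matrix: every defined score is exactly 0
  trc <- insulation(matrix(5, 40, 40), window_bins = 6)
  expect_true(all(trc$score[trc$valid] == 0))
  expect_gt(sum(trc$valid), 0)
  # positive-scale invariance
  tr2 <- insulation(m * 3.7, window_bins = 8)
  expect_lt(max(abs(tr$score[ok] - tr2$score[tr2$valid])), 1e-12)
  expect_error(insulation(m, window_bins = 25), "window_bins")
})

test_that("a two-block matrix puts the insulation minimum at the boundary", {
  cfg <- synthetic_config(
    n_bins = 60, n_steps = 1, tad_boundaries = 30,
    tad_strength_schedule = 2, depth = 1e5
  )
  e <- expected_matrix(cfg, 0)
  tr <- insulation(e, window_bins = 10)
  # the below-diagonal square is fully cross-domain at both b and b - 1,
  # so the valley floor is a two-bin plateau at the boundary
  expect_lte(abs(tr$bin[which.min(tr$score)] - 30), 1)
})

test_that("strong-boundary calling keys on prominence", {
  # monotone track: no local minima, empty result
  mono <- tibble::tibble(bin = 0:29, score = seq(0, 3, length.out = 30), valid = TRUE)
  expect_identical(call_strong_boundaries(mono, 0.1), integer())
  # one clear dip of depth 0.4: called at exactly the dip for threshold 0.2
  s <- rep(0.5, 30)
  s[15] <- 0.1
  s[14] <- 0.3
  s[16] <- 0.3
  dip <- tibble::tibble(bin = 0:29, score = s, valid = TRUE)
  expect_equal(call_strong_boundaries(dip, 0.2), 14L) # 0-based bin
  # too-shallow dips are ignored
  expect_identical(call_strong_boundaries(dip, 0.5), integer())
})

test_that("boundaries called on a noiseless 3-TAD matrix match the truth within 1 bin", {
  cfg <- synthetic_config(
    n_bins = 120, n_steps = 1, tad_boundaries = c(30, 60, 90),
    tad_strength_schedule = 2, depth = 1e5
  )
  tr <- insulation(expected_matrix(cfg, 0), window_bins = 10)
  called <- call_strong_boundaries(tr, prominence = 0.1)
  for (b in c(30, 60, 90)) expect_true(any(abs(called - b) <= 1))
  # nothing far from a true boundary is called
  expect_true(all(vapply(
    called,
    function(cb) min(abs(cb - c(30, 60, 90))) <= 1, logical(1)
  )))
})

test_that("the boundary pileup dips at offset zero for true valleys and is flat for random ones", {
  cfg <- synthetic_config(
    n_bins = 120, n_steps = 1, tad_boundaries = c(30, 60, 90),
    tad_strength_schedule = 2, depth = 1e5
  )
  tr <- insulation(expected_matrix(cfg, 0), window_bins = 10)
  prof <- boundary_pileup(tr, c(30, 60, 90), flank_bins = 8)
  expect_lte(abs(prof$offset[which.min(prof$mean_score)]), 1)
  expect_lt(prof$mean_score[prof$offset == 0], min(prof$mean_score[abs(prof$offset) >= 5]))
  # single boundary: the profile is the local track slice
  p1 <- boundary_pileup(tr, 60, flank_bins = 5)
  expect_equal(p1$mean_score, tr$score[60 + (-5:5) + 1])
  # random positions: centre within 1 sd of the flanks across 20 seeds
  centres <- numeric(20)
  flanks <- numeric(20)
  for (s in 1:20) {
    set.seed(200 + s)
    rnd <- sample(15:104, 3)
    pr <- boundary_pileup(tr, rnd, flank_bins = 8)
    centres[s] <- pr$mean_score[pr$offset == 0]
    flanks[s] <- mean(pr$mean_score[abs(pr$offset) >= 5], na.rm = TRUE)
  }
  expect_lt(abs(mean(centres) - mean(flanks)), sd(flanks - centres))
  # empty boundary list: undefined-marker profile
  p0 <- boundary_pileup(tr, integer(), flank_bins = 4)
  expect_true(all(is.na(p0$mean_score)))
})

test_that("the per-step metric report aggregates SCC, Pearson and boundary counts", {
  cfg <- synthetic_config(n_bins = 80, tad_boundaries = c(30, 55), depth = 2e5, seed = 14)
  st <- generate_stack(cfg)
  truth <- st[4:6]
  pred <- lapply(truth, function(m) {
    contact_matrix(m$values + 0.0, chrom = m$chrom, resolution = m$resolution)
  })
  rep_ <- metric_report(truth, pred)
  expect_equal(nrow(rep_), 3)
  expect_true(all(abs(rep_$scc - 1) < 1e-12))
  expect_true(all(rep_$n_boundaries_truth == rep_$n_boundaries_pred))
})
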