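test_that("stance detection finds the maximal loaded run, circularly", {
  grf <- rep(0, 100); grf[10:60] <- 1
  st <- detect_stance(grf, threshold = 0.5)
  expect_equal(st$indices, 10:60)
  expect_equal(st$fraction, 51 / 100)

  expect_error(detect_stance(rep(0, 50)), "no stance")

  # stance wrapping around the cycle end
  grf <- rep(0, 40); grf[c(35:40, 1:8)] <- 0.9
  st <- detect_stance(grf, threshold = 0.1)
  expect_equal(st$start, 35L)
  expect_equal(st$end, 8L)
  expect_equal(st$fraction, 14 / 40)

  expect_equal(detect_stance(rep(1, 10), 0.5)$fraction, 1)
})

test_that("spatiotemporal variables follow the periodicity identities", {
  res <- fake_result(N = 20, speed = 1.4)
  # make the right-foot GRF a clean square pulse and close the heel path
  res$contacts[4, ] <- 0; res$contacts[8, ] <- 0
  res$contacts[4, 3:13] <- 0.6 * 75 * 9.81 / (75 * 9.81)
  res$contacts[1, ] <- 0.1 + res$speed * res$duration * (0:20) / 20
  st <- spatiotemporal(res)
  expect_equal(st$stride_length, res$speed * res$duration, tolerance = 1e-12)
  expect_equal(st$speed, res$speed, tolerance = 1e-12)
  expect_equal(st$stance_fraction, 11 / 20)
  expect_equal(st$stance_time, st$stance_fraction * res$duration)

  # doubling the duration at fixed stride halves the speed
  res2 <- res; res2$duration <- 2 * res$duration
  expect_equal(spatiotemporal(res2)$speed, st$speed / 2)
})

test_that("rmsd is the root mean square deviation with window support", {
  x <- sin(1:50)
  expect_equal(rmsd(x, x), 0)
  expect_equal(rmsd(x + 0.7, x), 0.7, tolerance = 1e-12)
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(rmsd(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_equal(rmsd(a, b, window = 5:14), sqrt(mean((a - b)[5:14]^2)))
  expect_error(rmsd(a, b[1:10]), "length")
  expect_error(rmsd(a, b, window = integer(0)), "empty")
})

test_that("linear-fit R^2 matches least squares and its invariances", {
  ref <- sin(seq(0, 2 * pi, length.out = 60))
  expect_equal(lfm_r2(2 * ref + 1, ref), 1)
  # zero-covariance waveforms
  expect_equal(lfm_r2(cos(seq(0, 2 * pi, length.out = 61))[-61],
                      sin(seq(0, 2 * pi, length.out = 61))[-61]), 0,
               tolerance = 1e-10)
  set.seed(11)
  sim <- rnorm(50); ref2 <- rnorm(50)
  expect_equal(lfm_r2(sim, ref2), summary(lm(sim ~ ref2))$r.squared,
               tolerance = 1e-10)
  # affine invariance in both arguments
  expect_equal(lfm_r2(3 * sim - 2, ref2), lfm_r2(sim, ref2), tolerance = 1e-10)
  expect_equal(lfm_r2(sim, -0.5 * ref2 + 4), lfm_r2(sim, ref2), tolerance = 1e-10)
  expect_error(lfm_r2(sim, rep(1, 50)), "constant reference")
})

test_that("Fisher-Z averaging of R^2 values behaves as specified", {
  expect_equal(fisher_mean(rep(0.64, 5)), 0.64, tolerance = 1e-12)
  expect_equal(fisher_mean(0.42), 0.42, tolerance = 1e-12)
  # hand-computed oracle for {0.49, 0.81}: mean of atanh(0.7), atanh(0.9)
  zbar <- (atanh(0.7) + atanh(0.9)) / 2
  expect_equal(fisher_mean(c(0.49, 0.81)), tanh(zbar)^2, tolerance = 1e-12)
  x <- c(0.2, 0.5, 0.9)
  fm <- fisher_mean(x)
  expect_gte(fm, min(x)); expect_lte(fm, max(x))
  expect_true(is.finite(fisher_mean(c(0.5, 1))))   # clamped atanh(1)
  expect_error(fisher_mean(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("relationship categories use the published thresholds", {
  expect_equal(classify(0.71), "strong")
  expect_equal(classify(0.29), "none")
  expect_equal(classify(c(0.5, 0.7, 0.3)), c("weak", "moderate", "none"))
  expect_equal(classify(c(0.99, 0.55, 0.35, 0)),
               c("strong", "moderate", "weak", "none"))
})

test_that("kinetic normalization closed forms", {
  sub <- subject_descriptor(1.8, 75)
  nk <- normalize_kinetics(moments = 75 * 9.81 * 1.8, grf = 75 * 9.81, sub)
  expect_equal(nk$moments_bwbh, 100)
  expect_equal(nk$grf_bw, 1)
  nk2 <- normalize_kinetics(moments = 100, grf = 0, sub)
  expect_equal(nk2$moments_bwbh, 100 * 100 / (75 * 9.81 * 1.8), tolerance = 1e-12)
  expect_equal(round(nk2$moments_bwbh, 2), 7.55)
})
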