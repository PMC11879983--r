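test_that("track synthesis is seed-deterministic with exact zero-noise means", {
  truth <- fake_result(N = 14)
  nm <- noise_model(0.5, 0.05, 10, seed = 42)
  t1 <- synthesize_tracks(truth, "FS", nm)
  t2 <- synthesize_tracks(truth, "FS", nm)
  expect_identical(t1, t2)
  t3 <- synthesize_tracks(truth, "FS", noise_model(0.5, 0.05, 10, seed = 43))
  expect_false(identical(t1$sensors$foot_r$mean, t3$sensors$foot_r$mean))

  clean <- synthesize_tracks(truth, "FS", noise_model(0, 0, 10, seed = 1))
  sig <- gaitrec:::.result_signals(truth,
                                   sensor_placements("FS", truth$problem$seg))
  for (s in names(clean$sensors)) {
    expect_equal(clean$sensors[[s]]$mean["a_x", ], sig[[s]]$a_x)
    expect_equal(clean$sensors[[s]]$mean["omega_z", ], sig[[s]]$omega_z)
    # zero noise: the variance equals the preparation floor
    fl <- 1e-4 * rowMeans(clean$sensors[[s]]$mean^2) + 1e-6
    expect_equal(clean$sensors[[s]]$var,
                 matrix(fl, 3, truth$N, dimnames = dimnames(clean$sensors[[s]]$var)))
  }
})

test_that("sample variance of noisy cycles matches the sampling distribution", {
  truth <- fake_result(N = 40)
  sdn <- 0.5
  tr <- synthesize_tracks(truth, "F", noise_model(sdn, 0.05, 10, seed = 7))
  v <- c(tr$sensors$foot_r$var[1:2, ], tr$sensors$foot_l$var[1:2, ])
  # each per-node sample variance is sigma^2 * chisq(9)/9; check every node
  # against the 99.9% interval and the pooled mean against its CLT band
  lo <- sdn^2 * qchisq(0.0005, 9) / 9
  hi <- sdn^2 * qchisq(0.9995, 9) / 9
  expect_gt(mean(v >= lo & v <= hi), 0.99)
  se <- sdn^2 * sqrt(2 / 9) / sqrt(length(v))
  expect_lt(abs(mean(v) - sdn^2), 5 * se)
})

test_that("speed conditions cover the three walking and running bands", {
  sc <- speed_conditions()
  expect_equal(nrow(sc), 6L)
  expect_equal(sc$lo, c(0.9, 1.3, 1.7, 3.1, 3.9, 4.7))
  expect_equal(sc$hi, c(1.0, 1.4, 1.8, 3.3, 4.1, 4.9))
  expect_true(all(sc$mid >= sc$lo & sc$mid <= sc$hi))
})

test_that("noise model validates its fields", {
  expect_error(noise_model(accel_sd = -1), "accel_sd")
  expect_error(noise_model(cycles = 0), "cycles")
  nm <- noise_model()
  expect_equal(nm$cycles, 10L)
})
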