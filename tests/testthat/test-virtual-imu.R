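seg <- scale_segments(default_subject())

test_that("a sensor at rest reads one g on its vertical channel only", {
  q0 <- c(0, 0.95, rep(0, 7))
  for (s in c("foot_r", "shank_l", "hat")) {
    vs <- virtual_signals(q0, rep(0, 9), rep(0, 9), s, c(0.05, 0.02), seg)
    expect_equal(vs$omega_z, 0)
    expect_equal(sqrt(vs$a_x^2 + vs$a_y^2), 9.81, tolerance = 1e-12)
  }
  # tilted segment: gravity splits across channels but magnitude is fixed
  q1 <- c(0, 0.95, 0.4, rep(0, 6))
  vs <- virtual_signals(q1, rep(0, 9), rep(0, 9), "hat", c(-0.08, 0.10), seg)
  expect_equal(sqrt(vs$a_x^2 + vs$a_y^2), 9.81, tolerance = 1e-12)
  expect_gt(abs(vs$a_x), 0.1)
})

test_that("a sensor at the rotation center sees only gravity plus spin", {
  # HAT sensor at the hip, trunk spinning at constant rate about the hip
  w <- 2.3
  q <- c(0, 1, 0.7, rep(0, 6))
  v <- c(0, 0, w, rep(0, 6))
  vs <- virtual_signals(q, v, rep(0, 9), "hat", c(0, 0), seg)
  expect_equal(vs$omega_z, w)
  expect_equal(sqrt(vs$a_x^2 + vs$a_y^2), 9.81, tolerance = 1e-10)
})

test_that("virtual signals match the finite-difference specific-force oracle", {
  q_of <- function(t) c(0.4 * t, 1 + 0.04 * sin(2 * t), 0.15 * sin(3 * t),
                        0.5 * sin(t), 0.3 + 0.25 * cos(2 * t), 0.15 * sin(2 * t),
                        0.3 * cos(t), 0.4 + 0.2 * sin(t), 0.1 * cos(3 * t))
  v_of <- function(t) c(0.4, 0.08 * cos(2 * t), 0.45 * cos(3 * t),
                        0.5 * cos(t), -0.5 * sin(2 * t), 0.3 * cos(2 * t),
                        -0.3 * sin(t), 0.2 * cos(t), -0.3 * sin(3 * t))
  a_of <- function(t) c(0, -0.16 * sin(2 * t), -1.35 * sin(3 * t),
                        -0.5 * sin(t), -1.0 * cos(2 * t), -0.6 * sin(2 * t),
                        -0.3 * cos(t), -0.2 * sin(t), -0.9 * cos(3 * t))
  loc <- c(0.03, -0.2); segm <- "shank_r"
  t0 <- 1.1; h <- 1e-4
  pos <- function(t) {
    o <- oracle_points(q_of(t), seg)
    phi <- o$phis["shank_r"]
    zz <- complex(real = loc[1], imaginary = loc[2]) * exp(1i * phi)
    o$knee_r + c(Re(zz), Im(zz))
  }
  acc <- (pos(t0 + h) - 2 * pos(t0) + pos(t0 - h)) / h^2
  phi <- oracle_points(q_of(t0), seg)$phis["shank_r"]
  sf <- acc + c(0, 9.81)
  expected_ax <- cos(phi) * sf[1] + sin(phi) * sf[2]
  expected_ay <- -sin(phi) * sf[1] + cos(phi) * sf[2]
  expected_wz <- (oracle_points(q_of(t0 + h), seg)$phis["shank_r"] -
                  oracle_points(q_of(t0 - h), seg)$phis["shank_r"]) / (2 * h)
  vs <- virtual_signals(q_of(t0), v_of(t0), a_of(t0), segm, loc, seg)
  expect_lt(abs(vs$a_x - expected_ax), 1e-6)
  expect_lt(abs(vs$a_y - expected_ay), 1e-6)
  expect_lt(abs(vs$omega_z - expected_wz), 1e-6)
})

test_that("gyroscope channel is independent of the placement position", {
  q <- c(0, 1, rnorm(7, 0, 0.4)); v <- rnorm(9); a <- rnorm(9)
  w1 <- virtual_signals(q, v, a, "thigh_l", c(0.03, -0.2), seg)$omega_z
  w2 <- virtual_signals(q, v, a, "thigh_l", c(-0.05, -0.35), seg)$omega_z
  expect_identical(w1, w2)
})

test_that("the setup catalog matches the seven named sensor sets", {
  cat7 <- setup_catalog()
  expect_named(cat7, c("F", "FP", "FS", "FT", "FSP", "FTP", "FSTP"))
  nsens <- vapply(cat7, function(s) length(s$sensors), 1L)
  expect_equal(unname(nsens), c(2L, 3L, 4L, 4L, 5L, 5L, 7L))
  for (s in cat7) {
    expect_true(all(c("foot_r", "foot_l") %in% s$sensors))
    lefts <- grepl("_l$", s$sensors); rights <- grepl("_r$", s$sensors)
    expect_equal(sum(lefts), sum(rights))
  }
  pl <- sensor_placements("FTP", seg)
  expect_equal(nrow(pl), 5L)
  expect_setequal(pl$sensor, c("foot_r", "foot_l", "thigh_r", "thigh_l", "pelvis"))
  expect_error(sensor_placements("XYZ", seg), "unknown setup")
})
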