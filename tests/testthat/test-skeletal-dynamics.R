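seg <- scale_segments(default_subject())
p <- seg$p

test_that("forward kinematics matches the reference pose and the chain oracle", {
  hip_h <- p$LTH + p$LSH + 0.039 * 1.75
  q0 <- c(0, hip_h, rep(0, 7))
  fk <- forward_kinematics(q0, seg)
  expect_equal(unname(fk$joints["knee_r", ]), c(0, hip_h - p$LTH))
  expect_equal(unname(fk$joints["ankle_r", ]), c(0, hip_h - p$LTH - p$LSH))
  expect_equal(unname(fk$contact_points[, "y"]), rep(0, 4), tolerance = 1e-12)

  # pure pelvis translation moves every point by the same offset
  fk2 <- forward_kinematics(q0 + c(0.37, 0, rep(0, 7)), seg)
  expect_equal(fk2$joints, fk$joints + rep(c(0.37, 0), each = nrow(fk$joints)))
  expect_equal(fk2$contact_points[, "x"], fk$contact_points[, "x"] + 0.37)

  set.seed(7)
  for (rep in 1:5) {
    q <- c(rnorm(2), rnorm(7, 0, 0.8))
    fk <- forward_kinematics(q, seg)
    o <- oracle_points(q, seg)
    expect_equal(unname(fk$joints["ankle_r", ]), o$ankle_r, tolerance = 1e-10)
    expect_equal(unname(fk$joints["knee_l", ]), o$knee_l, tolerance = 1e-10)
    expect_equal(unname(fk$contact_points["toe_r", ]), o$toe_r, tolerance = 1e-10)
    expect_equal(unname(fk$contact_points["heel_l", ]), o$heel_l, tolerance = 1e-10)
  }
})

test_that("point kinematics differentiate consistently along trajectories", {
  loc <- c(0.04, -0.18)
  pk <- point_kinematics(c(0, 1, rnorm(7, 0, 0.3)), rep(0, 9), rep(0, 9),
                         "shank_r", loc, seg)
  expect_equal(pk$velocity, c(0, 0))
  expect_equal(pk$acceleration, c(0, 0))

  # uniform translation: velocity equals the pelvis velocity, acceleration 0
  pk <- point_kinematics(c(0, 1, rnorm(7, 0, 0.3)), c(1.1, -0.2, rep(0, 7)),
                         rep(0, 9), "foot_l", loc, seg)
  expect_equal(pk$velocity, c(1.1, -0.2))
  expect_equal(pk$acceleration, c(0, 0))

  # sinusoidal trajectory: analytic acceleration vs central differences
  q_of <- function(t) c(0.5 * t, 1 + 0.05 * sin(3 * t), 0.1 * sin(2 * t),
                        0.4 * sin(t), 0.3 + 0.3 * cos(2 * t), 0.2 * sin(3 * t),
                        0.2 * cos(t), 0.4 + 0.2 * sin(2 * t), 0.1 * cos(2 * t))
  v_of <- function(t) c(0.5, 0.15 * cos(3 * t), 0.2 * cos(2 * t),
                        0.4 * cos(t), -0.6 * sin(2 * t), 0.6 * cos(3 * t),
                        -0.2 * sin(t), 0.4 * cos(2 * t), -0.2 * sin(2 * t))
  a_of <- function(t) c(0, -0.45 * sin(3 * t), -0.4 * sin(2 * t),
                        -0.4 * sin(t), -1.2 * cos(2 * t), -1.8 * sin(3 * t),
                        -0.2 * cos(t), -0.8 * sin(2 * t), -0.4 * cos(2 * t))
  t0 <- 0.73; h <- 1e-4
  pos <- function(t) point_kinematics(q_of(t), v_of(t), a_of(t),
                                      "thigh_r", loc, seg)$position
  an <- point_kinematics(q_of(t0), v_of(t0), a_of(t0), "thigh_r", loc, seg)
  fd_acc <- (pos(t0 + h) - 2 * pos(t0) + pos(t0 - h)) / h^2
  expect_lt(max(abs(an$acceleration - fd_acc)), 1e-6)

  expect_error(point_kinematics(rep(0, 9), rep(0, 9), rep(0, 9),
                                "forearm", loc, seg), "unknown segment")
})

test_that("contact force is a smooth penetration/friction law", {
  par <- default_contact_params()
  # 5 cm above ground: vertical force at most the documented smoothing floor
  f <- contact_force(0.05, 1, -0.5, par)
  expect_lt(f$fy, 1.0)
  # zero slip velocity -> no friction force (odd law)
  f <- contact_force(-0.01, 0, 0, par)
  expect_identical(f$fx, 0 * f$fy)
  expect_gt(f$fy, 0)
  # friction opposes slip
  expect_lt(contact_force(-0.01, 0.5, 0, par)$fx, 0)
  expect_gt(contact_force(-0.01, -0.5, 0, par)$fx, 0)
  # strictly increasing over a penetration grid
  fy <- contact_force(seq(0.02, -0.05, length.out = 40), 0, 0, par)$fy
  expect_true(all(diff(fy) > 0))
  # analytic partials match finite differences
  d <- contact_force(-0.013, 0.21, -0.33, par, deriv = TRUE)
  h <- 1e-7
  expect_equal(d$dfy_py,
               (contact_force(-0.013 + h, 0.21, -0.33, par)$fy - d$fy) / h,
               tolerance = 1e-4)
  expect_equal(d$dfx_vx,
               (contact_force(-0.013, 0.21 + h, -0.33, par)$fx - d$fx) / h,
               tolerance = 1e-4)
})

test_that("multibody residual satisfies free fall, Newton and energy checks", {
  mus <- default_muscle_table()
  zero_c <- data.frame(px = rep(0, 4), py = 0, fx = 0, fy = 0)
  q <- c(0, 1, 0.1, 0.2, 0.3, -0.1, 0.15, 0.25, 0.05)
  v <- rnorm(9, 0, 0.5)

  r <- multibody_residual(q, v, rep(0, 9), rep(0, 6), zero_c, seg)
  expect_length(r, 18L)
  expect_equal(r[1:9], rep(0, 9))  # qdot defaults to v

  # solve the implicit dynamics for the acceleration: free fall
  eom <- gaitrec:::.dyn_eom(matrix(q, 9), matrix(v, 9), matrix(0, 9),
                            matrix(0, 6), matrix(0, 8), seg$p)
  a <- solve(eom$Ja[1, , ], -eom$res[1, ])
  expect_lt(max(abs(multibody_residual(q, v, a, rep(0, 6), zero_c, seg)[10:18])),
            1e-9)
  h <- 1e-4
  com_y <- function(q) oracle_points(q, seg)$com[2]
  fd <- (com_y(q + h * v + 0.5 * h^2 * a) - 2 * com_y(q) +
         com_y(q - h * v + 0.5 * h^2 * a)) / h^2
  expect_equal(fd, -9.81, tolerance = 1e-5)

  # Newton check: gravity off, uniform velocity, no forces -> zero residual
  seg0 <- seg; seg0$p$grav <- 0
  r0 <- multibody_residual(q, c(1.2, 0.4, rep(0, 7)), rep(0, 9), rep(0, 6),
                           zero_c, seg0)
  expect_lt(max(abs(r0)), 1e-10)

  # energy rate equals joint-moment power plus contact-force power
  set.seed(21)
  tau <- rnorm(6, 0, 5); fc <- rnorm(8, 0, 40)
  contacts <- data.frame(px = rep(0, 4), py = 0,
                         fx = fc[c(1, 3, 5, 7)], fy = fc[c(2, 4, 6, 8)])
  eom <- gaitrec:::.dyn_eom(matrix(q, 9), matrix(v, 9), matrix(0, 9),
                            matrix(tau, 6), matrix(fc, 8), seg$p)
  a <- solve(eom$Ja[1, , ], -eom$res[1, ])
  dE <- oracle_energy_rate(q, v, a, seg)
  ck <- gaitrec:::.dyn_cpkin(matrix(q, 9), matrix(v, 9), seg$p)
  power <- sum(tau * v[4:9]) + sum(fc[c(1, 3, 5, 7)] * ck$vx[1, ]) +
    sum(fc[c(2, 4, 6, 8)] * ck$vy[1, ])
  expect_lt(abs(dE - power) / max(1, abs(power)), 1e-8)
})

test_that("dynamics residual derivatives are smooth (finite-difference check)", {
  set.seed(5)
  q <- matrix(c(0, 1, rnorm(7, 0, 0.4)), 9)
  v <- matrix(rnorm(9), 9); a <- matrix(rnorm(9), 9)
  tau <- matrix(rnorm(6), 6); fc <- matrix(rnorm(8, 0, 50), 8)
  eom <- gaitrec:::.dyn_eom(q, v, a, tau, fc, seg$p)
  h <- 1e-6
  for (j in c(2, 4, 9)) {
    q2 <- q; q2[j, ] <- q2[j, ] + h
    fd <- (gaitrec:::.dyn_eom(q2, v, a, tau, fc, seg$p)$res - eom$res) / h
    expect_lt(max(abs(fd - eom$Jq[, , j])), 1e-5 * max(1, max(abs(eom$Jq[, , j]))))
  }
})

test_that("per-foot GRF sums heel and toe forces", {
  contacts <- data.frame(px = 1:4, py = 0,
                         fx = c(1, 2, -3, 4), fy = c(10, 20, 0, 0))
  g <- grf_per_foot(contacts)
  expect_equal(unname(g["right", ]), c(3, 30))
  expect_equal(unname(g["left", ]), c(1, 0))
  expect_equal(unname(grf_per_foot(data.frame(px = 0, py = 0, fx = rep(0, 4),
                                              fy = rep(0, 4)))["right", ]),
               c(0, 0))
  set.seed(1)
  m <- matrix(rnorm(8), 4, 2)
  contacts <- data.frame(px = 0, py = 0, fx = m[, 1], fy = m[, 2])
  expect_equal(unname(grf_per_foot(contacts)["left", ]), colSums(m[3:4, ]))
})
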