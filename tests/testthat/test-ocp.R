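sub <- default_subject()

test_that("collocation layout follows the closed-form dimensions", {
  for (N in c(10L, 37L)) {
    prob <- assemble_nlp(setup = "F", tracks = NULL, subject = sub, N = N)
    expect_equal(prob$layout$nz, (N + 1L) * 82L + 2L)
    expect_equal(prob$layout$nc, N * 66L + 82L)
    z <- initial_guess(prob, "static")
    co <- gaitrec:::.ocp_constraints(z, prob, jac = TRUE)
    expect_length(co$c, prob$layout$nc)
    expect_equal(dim(co$A), c(prob$layout$nc, prob$layout$nz))
  }
  # N = 10: 11*82 + 2 = 904 variables, 10*66 + 82 = 742 constraints
  prob <- assemble_nlp(setup = "FSTP", tracks = NULL, subject = sub, N = 10L)
  expect_equal(prob$layout$nz, 904L)
  expect_equal(prob$layout$nc, 742L)
  # dimensions do not depend on the sensor setup
  for (s in c("F", "FS", "FSTP")) {
    p2 <- assemble_nlp(setup = s, tracks = NULL, subject = sub, N = 10L)
    expect_equal(p2$layout$nz, 904L)
    expect_equal(p2$layout$nc, 742L)
  }
  expect_error(assemble_nlp(subject = sub, N = 10, speed_bounds = c(2, 1)),
               "infeasible bounds")
})

test_that("tracking cost obeys its closed forms", {
  truth <- fake_result(N = 16)
  tracks <- synthesize_tracks(truth, "FP", noise_model(0, 0, 10, seed = 3))
  sim <- gaitrec:::.result_signals(truth, sensor_placements("FP", truth$problem$seg))
  expect_equal(tracking_cost(sim, tracks), 0)

  # constant deviation d on one channel of one sensor, sigma constant
  tr1 <- tracks
  tr1$sensors <- tr1$sensors["pelvis"]
  tr1$sensors$pelvis$var[] <- 0.04
  d <- 0.3
  sim1 <- sim["pelvis"]
  sim1$pelvis$a_x <- tr1$sensors$pelvis$mean["a_x", ] + d
  sim1$pelvis$a_y <- tr1$sensors$pelvis$mean["a_y", ]
  sim1$pelvis$omega_z <- tr1$sensors$pelvis$mean["omega_z", ]
  expect_equal(tracking_cost(sim1, tr1), d^2 / 0.04 / 3)

  # doubling sigma divides the cost by four
  tr2 <- tr1
  tr2$sensors$pelvis$var[] <- 4 * tr1$sensors$pelvis$var
  expect_equal(tracking_cost(sim1, tr2), tracking_cost(sim1, tr1) / 4)

  # a non-positive variance is a preparation error
  tr3 <- tr1; tr3$sensors$pelvis$var[1, 1] <- 0
  expect_error(tracking_cost(sim1, tr3), "preparation error")
})

test_that("effort and regularization costs obey their closed forms", {
  expect_equal(effort_cost(matrix(0, 16, 20), v = 1.3), 0)
  cc <- 0.37
  expect_equal(effort_cost(matrix(cc, 16, 20), v = 1.5), cc^2 / 1.5^2)
  expect_error(effort_cost(matrix(0.1, 16, 5), v = 0), "positive")
  set.seed(4)
  u <- matrix(runif(16 * 12), 16, 12)
  expect_equal(effort_cost(u, v = 2), sum(u^2) / (16 * 12 * 4), tolerance = 1e-12)

  N <- 12; T <- 1.1
  u_const <- matrix(0.5, 16, N + 1)
  v_traj <- matrix(rnorm(9 * (N + 1)), 9, N + 1)
  v_const <- matrix(0.2, 9, N + 1)
  expect_equal(regularization_cost(u_const, v_const, T), 0)
  alt <- matrix(rep(c(0, 1), length.out = N + 1), 16, N + 1, byrow = TRUE)
  expect_gt(regularization_cost(alt, v_const, T),
            regularization_cost(u_const, v_const, T))
  # direct finite-difference-sum oracle
  u <- matrix(runif(16 * (N + 1)), 16, N + 1)
  manual <- (sum((u[, -1] - u[, -(N + 1)])^2) / 16 +
             sum((v_traj[, -1] - v_traj[, -(N + 1)])^2) / 9) / (N * T)
  expect_equal(regularization_cost(u, v_traj, T), manual, tolerance = 1e-12)
})

test_that("initial guesses are in-bounds and modes behave as documented", {
  prob <- assemble_nlp(setup = "FSTP", tracks = NULL, subject = sub, N = 8L,
                       speed_bounds = c(1.1, 1.1))
  for (mode in c("static", "nominal")) {
    z <- initial_guess(prob, mode)
    expect_true(all(z >= prob$lb & z <= prob$ub))
    expect_true(all(is.finite(z)))
  }
  z <- initial_guess(prob, "static")
  st <- gaitrec:::.ocp_unpack(z, prob)
  # standing posture translating linearly at the prescribed speed
  expect_equal(diff(st$Q[1, ]), rep(1.1 * st$T / 8, 8), tolerance = 1e-12)
  expect_equal(sd(st$Q[2, ]), 0)
  expect_equal(unique(as.vector(st$U)), 0.1)
  expect_error(initial_guess(prob, "warm", warm = rnorm(10)),
               "dimension mismatch")
  z2 <- initial_guess(prob, "warm", warm = z)
  expect_equal(z2, z)
})

test_that("objective gradient and constraint Jacobian match finite differences", {
  set.seed(31)
  truth <- fake_result(N = 6)
  tracks <- synthesize_tracks(truth, "FS", noise_model(0.3, 0.05, 6, seed = 8))
  prob <- assemble_nlp(tracks = tracks, subject = sub, N = 6L)
  z <- initial_guess(prob, "nominal", speed = 1.2)
  z <- pmin(pmax(z * (1 + 0.01 * rnorm(length(z))) + 1e-3 * rnorm(length(z)),
                 prob$lb + 1e-3), prob$ub - 1e-3)
  fo <- gaitrec:::.ocp_objective(z, prob, derivs = TRUE)
  co <- gaitrec:::.ocp_constraints(z, prob, jac = TRUE)
  cols <- sort(sample(length(z), 60))
  h <- 1e-6
  for (j in cols) {
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    fd_g <- (gaitrec:::.ocp_objective(zp, prob, derivs = FALSE)$f -
             gaitrec:::.ocp_objective(zm, prob, derivs = FALSE)$f) / (2 * h)
    expect_lt(abs(fd_g - fo$g[j]) / max(1, abs(fo$g[j])), 1e-5)
    fd_c <- (gaitrec:::.ocp_constraints(zp, prob, jac = FALSE)$c -
             gaitrec:::.ocp_constraints(zm, prob, jac = FALSE)$c) / (2 * h)
    expect_lt(max(abs(fd_c - co$A[, j])) / max(1, max(abs(co$A[, j]))), 1e-5)
  }
})

test_that("the periodicity rows tie the extra node to node one with the shift", {
  prob <- assemble_nlp(setup = "F", tracks = NULL, subject = sub, N = 6L,
                       speed_bounds = c(1.2, 1.2))
  z <- initial_guess(prob, "static")
  co <- gaitrec:::.ocp_constraints(z, prob, jac = FALSE)
  per <- co$c[6 * 66 + 1:82]
  expect_length(per, 82L)
  # the static guess is built periodic: all periodicity rows vanish
  expect_lt(max(abs(per)), 1e-10)
  # breaking node N+1 by delta shows up only in the matching row
  st <- gaitrec:::.ocp_unpack(z, prob)
  st$ACT[3, 7] <- st$ACT[3, 7] + 0.123
  z2 <- gaitrec:::.ocp_pack(st$Q, st$V, st$LCEn, st$ACT, st$U, st$C, st$speed, st$T)
  per2 <- gaitrec:::.ocp_constraints(z2, prob, jac = FALSE)$c[6 * 66 + 1:82]
  expect_equal(per2[34 + 3], 0.123)
  expect_lt(max(abs(per2[-(34 + 3)])), 1e-10)
})
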