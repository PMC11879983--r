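mus <- default_muscle_table()

test_that("musculotendon length differentiates to minus the moment arms", {
  q <- c(0, 1, rnorm(7, 0, 0.3))
  mt <- musculotendon_length(q, mus)
  # reference posture -> documented reference lengths
  mt0 <- musculotendon_length(c(0, 1, 0, rep(0, 6)), mus)
  expect_equal(drop(mt0$lmt), mus$table$lmt_ref, ignore_attr = TRUE)

  h <- 1e-7
  for (j in 4:9) {
    q2 <- q; q2[j] <- q2[j] + h
    fd <- (musculotendon_length(q2, mus)$lmt - mt$lmt) / h
    expect_lt(max(abs(drop(fd) + mus$D[, j - 3])), 1e-8)
  }
  # uniarticular soleus is insensitive to the knee
  qk <- q; qk[5] <- qk[5] + 0.5
  expect_equal(musculotendon_length(qk, mus)$lmt["soleus_r", ],
               mt$lmt["soleus_r", ])
})

test_that("activation dynamics have the right fixed point and time constants", {
  u <- matrix(runif(16), 16)
  r <- activation_residual(u, u, matrix(0, 16), mus)
  expect_equal(dim(r), c(16L, 1L))
  expect_lt(max(abs(r)), 1e-12)

  # integrate a 0 -> 1 excitation step; activation reaches ~63% at tau_act
  act <- rep(0, 16); dt <- 2e-4
  rate_of <- function(act) {
    m <- gaitrec:::.activation_mech(matrix(1, 16), matrix(act, 16),
                                    matrix(0, 16), mus)
    -drop(m$res)      # residual = rate - law  =>  law = -res at rate 0
  }
  tgrid <- seq(0, 0.0100, by = dt)
  for (i in seq_along(tgrid)[-1]) {
    k1 <- rate_of(act); k2 <- rate_of(act + 0.5 * dt * k1)
    k3 <- rate_of(act + 0.5 * dt * k2); k4 <- rate_of(act + dt * k3)
    act <- act + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  expect_equal(mean(act), 1 - exp(-1), tolerance = 0.03)
  expect_true(all(act >= 0 & act <= 1))

  # deactivation is slower than activation
  dec <- gaitrec:::.activation_mech(matrix(0, 16), matrix(0.5, 16),
                                    matrix(0, 16), mus)
  acc <- gaitrec:::.activation_mech(matrix(1, 16), matrix(0.5, 16),
                                    matrix(0, 16), mus)
  expect_true(all(abs(dec$res) < abs(acc$res)))
})

test_that("contraction equilibrium holds at the isometric force-length apex", {
  lce <- matrix(mus$table$lceopt, 16)
  # tendon stretched to its reference strain: SEE force equals fmax
  lmt <- lce + matrix(mus$table$slack * 1.04, 16)
  r <- contraction_residual(matrix(1, 16), lce, matrix(0, 16), lmt, mus)
  expect_equal(dim(r), c(16L, 1L))
  expect_lt(max(abs(r)), 0.02)   # smoothing-scale deviation from the apex
})

test_that("the force-velocity branch yields shortening below isometric load", {
  m <- 3L  # hamstrings_r
  tb <- mus$table[m, ]
  lce <- tb$lceopt
  # tendon strain such that SEE force is half the isometric capacity
  target <- 0.5 * tb$fmax * gaitrec:::.fl(1, tb$width)
  stretch <- sqrt(target / tb$fmax) * 0.04   # invert the quadratic SEE
  lmt <- lce + tb$slack * (1 + stretch)
  resid <- function(rate) contraction_residual(
    matrix(1, 1), matrix(lce, 1), matrix(rate, 1), matrix(lmt, 1),
    structure(list(table = tb, D = mus$D[m, , drop = FALSE], n = 1L),
              class = "gaitrec_muscles"))[1, 1]
  sol <- uniroot(resid, c(-tb$vmax * lce, 0.5))
  expect_lt(sol$root, 0)   # concentric (shortening)
})

test_that("tendon force is slack-zero, monotone and fmax at reference strain", {
  tb <- mus$table
  slackf <- tendon_force(matrix(tb$lceopt, 16),
                         matrix(tb$lceopt + tb$slack * 0.98, 16), mus)
  expect_true(all(slackf < 0.01 * tb$fmax))
  # monotone non-decreasing in (lMT - lce)
  m <- 7L
  stretch <- seq(-0.02, 0.06, length.out = 30)
  f <- vapply(stretch, function(s) tendon_force(
    matrix(tb$lceopt[m], 1), matrix(tb$lceopt[m] + tb$slack[m] * (1 + s), 1),
    structure(list(table = tb[m, ], D = mus$D[m, , drop = FALSE], n = 1L),
              class = "gaitrec_muscles"))[1, 1], 0)
  expect_true(all(diff(f) >= 0))
  # closed form of the smoothed quadratic SEE at the 4% reference strain
  sp <- function(x, e) 0.5 * (x + sqrt(x^2 + e^2))
  expected <- tb$fmax[m] * (sp(0.04, 0.002) / 0.04)^2
  at_ref <- tendon_force(matrix(tb$lceopt[m], 1),
                         matrix(tb$lceopt[m] + tb$slack[m] * 1.04, 1),
                         structure(list(table = tb[m, ], D = mus$D[m, , drop = FALSE],
                                        n = 1L), class = "gaitrec_muscles"))[1, 1]
  expect_equal(at_ref, expected, tolerance = 1e-10)
  expect_equal(at_ref / tb$fmax[m], 1, tolerance = 0.01)
})

test_that("joint moments sum muscle force times arm plus passive moments", {
  q <- c(0, 1, 0, 0.3, 0.6, -0.1, 0.2, 0.5, 0.1)
  v <- rep(0, 9)
  # slack-consistent CE lengths at zero activation: moments near passive floor
  lmt <- musculotendon_length(q, mus)$lmt
  lce <- lmt - mus$table$slack
  jm <- joint_moments(q, v, lce, mus)
  expect_equal(dim(jm), c(6L, 1L))
  expect_lt(max(abs(jm)), 3)

  # brute-force sum over muscles of tendon force times arm, plus passive
  set.seed(9)
  lce2 <- lce * runif(16, 0.97, 1.03)
  v2 <- rnorm(9)
  jm2 <- joint_moments(q, v2, lce2, mus)
  f <- tendon_force(lce2, lmt, mus)
  brute <- vapply(1:6, function(j) sum(f * mus$D[, j]), 0)
  passive <- gaitrec:::.passive_mech(q[4:9], v2[4:9], deriv = FALSE)$tau
  expect_equal(unname(drop(jm2)), brute + drop(passive), tolerance = 1e-10)

  # single-muscle additivity: perturbing one CE length changes only the
  # spanned joints by force-difference times arm
  lce3 <- lce2; lce3[5] <- lce3[5] - 0.004   # vasti_r
  dM <- unname(drop(joint_moments(q, v2, lce3, mus) - jm2))
  df <- (tendon_force(lce3, lmt, mus) - f)[5]
  expect_equal(dM, unname(df * mus$D[5, ]), tolerance = 1e-10)
})

test_that("force-velocity curve orders concentric, isometric, eccentric force", {
  fv <- gaitrec:::.fv
  expect_lt(fv(-0.5), fv(0))
  expect_equal(fv(0), 1)
  expect_gt(fv(0.5), 1)
  expect_lt(fv(1e3), 1.5 + 1e-9)   # eccentric plateau
  s <- seq(-1.5, 1.5, length.out = 200)
  expect_true(all(diff(fv(s)) > 0))
})
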