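test_that("segment scaling conserves mass and scales homogeneously", {
  seg <- scale_segments(subject_descriptor(1.80, 75))
  expect_equal(sum(seg$segments$mass), 75, tolerance = 1e-12)
  expect_true(all(seg$segments$mass > 0))
  expect_true(all(seg$segments$length > 0))
  # thigh mass follows the tabulated fraction (0.100 of body mass)
  expect_equal(seg$segments$mass[seg$segments$segment == "thigh_r"], 0.100 * 75)

  seg2 <- scale_segments(subject_descriptor(1.80, 150))
  expect_equal(seg2$segments$mass, 2 * seg$segments$mass, tolerance = 1e-12)
  expect_equal(seg2$segments$length, seg$segments$length)
  seg3 <- scale_segments(subject_descriptor(3.60, 75))
  expect_equal(seg3$segments$length, 2 * seg$segments$length, tolerance = 1e-12)

  # deterministic
  expect_identical(scale_segments(subject_descriptor(1.80, 75))$p, seg$p)
})

test_that("invalid subjects are rejected", {
  expect_error(subject_descriptor(0, 75), "invalid subject")
  expect_error(subject_descriptor(1.8, -1), "invalid subject")
  expect_error(subject_descriptor(NA_real_, 75), "invalid subject")
})

test_that("muscle table has 16 mirrored muscles with the named anatomy", {
  mus <- default_muscle_table()
  expect_equal(mus$n, 16L)
  expect_equal(nrow(mus$table), 16L)
  right <- mus$table[mus$table$side == "r", ]
  left <- mus$table[mus$table$side == "l", ]
  for (col in c("fmax", "lceopt", "slack", "vmax", "tau_act", "tau_deact"))
    expect_equal(right[[col]], left[[col]])
  expect_equal(unname(mus$D[1:8, 1:3]), unname(mus$D[9:16, 4:6]))

  arm <- function(name) mus$D[paste0(name, "_r"), 1:3] != 0
  expect_equal(unname(arm("soleus")), c(FALSE, FALSE, TRUE))
  expect_equal(unname(arm("rectus_femoris")), c(TRUE, TRUE, FALSE))
  expect_equal(unname(arm("gastrocnemius")), c(FALSE, TRUE, TRUE))
  expect_equal(unname(arm("hamstrings")), c(TRUE, TRUE, FALSE))
  expect_equal(unname(arm("iliopsoas")), c(TRUE, FALSE, FALSE))
  expect_equal(unname(arm("vasti")), c(FALSE, TRUE, FALSE))
})

test_that("contact defaults are positive and support quiet standing", {
  par <- default_contact_params()
  expect_true(all(unlist(par) > 0))
  expect_true(par$friction > 0 && par$friction <= 2)

  # static solve: find the pelvis height where the four contact points carry
  # body weight; the implied penetration must be under 2 cm
  seg <- scale_segments(default_subject())
  bw <- 75 * 9.81
  load_at <- function(hip_y) {
    fk <- forward_kinematics(c(0, hip_y, rep(0, 7)), seg)
    sum(contact_force(fk$contact_points[, "y"], 0, 0, par)$fy) - bw
  }
  leg <- seg$leg_length
  sol <- uniroot(load_at, c(leg - 0.05, leg + 0.01), tol = 1e-10)
  fk <- forward_kinematics(c(0, sol$root, rep(0, 7)), seg)
  expect_true(all(fk$contact_points[, "y"] > -0.02))
  expect_lt(abs(load_at(sol$root)), 1)
})
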