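# shared fixtures and independent oracles (no reliance on package internals)

default_subject <- function() subject_descriptor(1.75, 75)

# independent planar forward kinematics using complex-number rotations --
# a different mechanism than the package's rotation-matrix chain
oracle_points <- function(q, seg) {
  p <- seg$p
  rot <- function(phi, rx, ry) {
    zz <- complex(real = rx, imaginary = ry) * exp(1i * phi)
    c(Re(zz), Im(zz))
  }
  hip <- q[1:2]
  phT <- q[3]
  phTr <- q[3] + q[4]; phSr <- phTr - q[5]; phFr <- phSr + q[6]
  phTl <- q[3] + q[7]; phSl <- phTl - q[8]; phFl <- phSl + q[9]
  knee_r <- hip + rot(phTr, 0, -p$LTH); ank_r <- knee_r + rot(phSr, 0, -p$LSH)
  knee_l <- hip + rot(phTl, 0, -p$LTH); ank_l <- knee_l + rot(phSl, 0, -p$LSH)
  list(hip = hip, knee_r = knee_r, ankle_r = ank_r,
       knee_l = knee_l, ankle_l = ank_l,
       heel_r = ank_r + rot(phFr, p$hx, p$hy),
       toe_r = ank_r + rot(phFr, p$tx, p$ty),
       heel_l = ank_l + rot(phFl, p$hx, p$hy),
       toe_l = ank_l + rot(phFl, p$tx, p$ty),
       com = {
         ms <- c(p$mHAT, p$mTH, p$mSH, p$mFT, p$mTH, p$mSH, p$mFT)
         pts <- rbind(hip + rot(phT, 0, p$cHAT),
                      hip + rot(phTr, 0, -p$cTH),
                      knee_r + rot(phSr, 0, -p$cSH),
                      ank_r + rot(phFr, p$fcx, p$fcy),
                      hip + rot(phTl, 0, -p$cTH),
                      knee_l + rot(phSl, 0, -p$cSH),
                      ank_l + rot(phFl, p$fcx, p$fcy))
         colSums(pts * ms) / sum(ms)
       },
       phis = c(hat = phT, thigh_r = phTr, shank_r = phSr, foot_r = phFr,
                thigh_l = phTl, shank_l = phSl, foot_l = phFl))
}

# total mechanical energy via analytic complex-arithmetic kinematics:
# a chain point is hip + sum r_k exp(i phi_k), its velocity
# vhip + sum i phidot_k r_k exp(i phi_k) -- exact, no inner differencing
oracle_energy <- function(q, v, seg) {
  p <- seg$p
  phis <- c(q[3], q[3] + q[4], q[3] + q[4] - q[5], q[3] + q[4] - q[5] + q[6],
            q[3] + q[7], q[3] + q[7] - q[8], q[3] + q[7] - q[8] + q[9])
  wz <- c(v[3], v[3] + v[4], v[3] + v[4] - v[5], v[3] + v[4] - v[5] + v[6],
          v[3] + v[7], v[3] + v[7] - v[8], v[3] + v[7] - v[8] + v[9])
  names(phis) <- names(wz) <- c("hat", "thigh_r", "shank_r", "foot_r",
                                "thigh_l", "shank_l", "foot_l")
  hip <- complex(real = q[1], imaginary = q[2])
  vhip <- complex(real = v[1], imaginary = v[2])
  lnk <- function(seg_id, rx, ry) {
    zz <- complex(real = rx, imaginary = ry) * exp(1i * phis[seg_id])
    list(p = zz, v = 1i * wz[seg_id] * zz)
  }
  add <- function(a, b) list(p = a$p + b$p, v = a$v + b$v)
  base <- list(p = hip, v = vhip)
  knee_r <- add(base, lnk("thigh_r", 0, -p$LTH))
  ank_r <- add(knee_r, lnk("shank_r", 0, -p$LSH))
  knee_l <- add(base, lnk("thigh_l", 0, -p$LTH))
  ank_l <- add(knee_l, lnk("shank_l", 0, -p$LSH))
  coms <- list(add(base, lnk("hat", 0, p$cHAT)),
               add(base, lnk("thigh_r", 0, -p$cTH)),
               add(knee_r, lnk("shank_r", 0, -p$cSH)),
               add(ank_r, lnk("foot_r", p$fcx, p$fcy)),
               add(base, lnk("thigh_l", 0, -p$cTH)),
               add(knee_l, lnk("shank_l", 0, -p$cSH)),
               add(ank_l, lnk("foot_l", p$fcx, p$fcy)))
  ms <- c(p$mHAT, p$mTH, p$mSH, p$mFT, p$mTH, p$mSH, p$mFT)
  Is <- c(p$IHAT, p$ITH, p$ISH, p$IFT, p$ITH, p$ISH, p$IFT)
  kin <- sum(0.5 * ms * vapply(coms, function(cc) Mod(cc$v)^2, 0)) +
    sum(0.5 * Is * wz^2)
  pot <- sum(ms * 9.81 * vapply(coms, function(cc) Im(cc$p), 0))
  list(kinetic = kin, potential = pot, total = kin + pot)
}

# exact analytic energy rate: dE/dt = sum m vcom . acom + sum I w alpha +
# sum m g vy, with accelerations from the same complex chain
# (d^2/dt^2 of r exp(i phi) = (i alpha - w^2) r exp(i phi))
oracle_energy_rate <- function(q, v, a, seg) {
  p <- seg$p
  sel <- function(x) c(x[3], x[3] + x[4], x[3] + x[4] - x[5],
                       x[3] + x[4] - x[5] + x[6],
                       x[3] + x[7], x[3] + x[7] - x[8],
                       x[3] + x[7] - x[8] + x[9])
  phis <- sel(q); wz <- sel(v); al <- sel(a)
  names(phis) <- names(wz) <- names(al) <-
    c("hat", "thigh_r", "shank_r", "foot_r", "thigh_l", "shank_l", "foot_l")
  base <- list(p = complex(real = q[1], imaginary = q[2]),
               v = complex(real = v[1], imaginary = v[2]),
               a = complex(real = a[1], imaginary = a[2]))
  lnk <- function(id, rx, ry) {
    zz <- complex(real = rx, imaginary = ry) * exp(1i * phis[id])
    list(p = zz, v = 1i * wz[id] * zz, a = (1i * al[id] - wz[id]^2) * zz)
  }
  add <- function(x, y) list(p = x$p + y$p, v = x$v + y$v, a = x$a + y$a)
  knee_r <- add(base, lnk("thigh_r", 0, -p$LTH))
  ank_r <- add(knee_r, lnk("shank_r", 0, -p$LSH))
  knee_l <- add(base, lnk("thigh_l", 0, -p$LTH))
  ank_l <- add(knee_l, lnk("shank_l", 0, -p$LSH))
  coms <- list(add(base, lnk("hat", 0, p$cHAT)),
               add(base, lnk("thigh_r", 0, -p$cTH)),
               add(knee_r, lnk("shank_r", 0, -p$cSH)),
               add(ank_r, lnk("foot_r", p$fcx, p$fcy)),
               add(base, lnk("thigh_l", 0, -p$cTH)),
               add(knee_l, lnk("shank_l", 0, -p$cSH)),
               add(ank_l, lnk("foot_l", p$fcx, p$fcy)))
  ms <- c(p$mHAT, p$mTH, p$mSH, p$mFT, p$mTH, p$mSH, p$mFT)
  Is <- c(p$IHAT, p$ITH, p$ISH, p$IFT, p$ITH, p$ISH, p$IFT)
  dKE <- sum(ms * vapply(coms, function(cc)
    Re(cc$v) * Re(cc$a) + Im(cc$v) * Im(cc$a), 0)) + sum(Is * wz * al)
  dPE <- sum(ms * 9.81 * vapply(coms, function(cc) Im(cc$v), 0))
  dKE + dPE
}

# a minimal hand-built "result" (no solver) for track-synthesis and metric
# tests: a smooth periodic, not dynamically consistent, motion
fake_result <- function(N = 16, speed = 1.2, subject = default_subject()) {
  prob <- assemble_nlp(setup = "FSTP", tracks = NULL, subject = subject,
                       N = N, speed_bounds = c(speed, speed))
  T0 <- 1.0
  ph <- (0:N) / N
  Q <- matrix(0, 9, N + 1)
  Q[1, ] <- speed * T0 * ph
  Q[2, ] <- 0.92 + 0.02 * sin(2 * pi * ph)
  Q[4, ] <- 0.3 * cos(2 * pi * ph); Q[7, ] <- 0.3 * cos(2 * pi * (ph + 0.5))
  Q[5, ] <- 0.4 + 0.3 * sin(2 * pi * ph); Q[8, ] <- 0.4 + 0.3 * sin(2 * pi * (ph + 0.5))
  Q[6, ] <- 0.1 * sin(2 * pi * ph); Q[9, ] <- 0.1 * sin(2 * pi * (ph + 0.5))
  h <- T0 / N
  V <- matrix(0, 9, N + 1)
  V[, 2:(N + 1)] <- (Q[, 2:(N + 1)] - Q[, 1:N]) / h
  V[, 1] <- V[, N + 1]
  C <- gaitrec:::.contacts_from_kinematics(Q, V, prob)
  lce <- matrix(prob$lceopt, 16, N + 1)
  structure(list(z = gaitrec:::.ocp_pack(Q, V, lce / prob$lceopt,
                                         matrix(0.1, 16, N + 1),
                                         matrix(0.1, 16, N + 1), C, speed, T0),
                 N = N, setup = "FSTP", subject = subject,
                 q = Q, v = V, lce = lce, act = matrix(0.1, 16, N + 1),
                 u = matrix(0.1, 16, N + 1), contacts = C,
                 speed = speed, duration = T0,
                 status = "fake", problem = prob),
            class = "gaitrec_result")
}
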