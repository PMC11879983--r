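# Objective evaluation for the collocation NLP: variance-weighted IMU
# tracking + weighted effort + weighted roughness regularization, with exact
# analytic gradient and a Gauss-Newton-type sparse Hessian (exact for the
# quadratic effort/regularization terms, J^T J for the tracking term;
# second-order constraint curvature is left to the solver's inertia
# regularization).

.ocp_objective <- function(z, prob, derivs = TRUE) {
  N <- prob$N; lay <- prob$layout; nz <- lay$nz
  st <- .ocp_unpack(z, prob)
  Tt <- st$T; h <- Tt / N
  i2 <- 2:(N + 1L); i1 <- 1:N
  Q2 <- st$Q[, i2, drop = FALSE]; V2 <- st$V[, i2, drop = FALSE]
  V1 <- st$V[, i1, drop = FALSE]
  Av <- (V2 - V1) / h
  U2 <- st$U[, i2, drop = FALSE]
  w <- prob$weights
  base1 <- (i1 - 1L) * .NODE_LEN; base2 <- i1 * .NODE_LEN

  g <- if (derivs) numeric(nz) else NULL
  Hi <- list(); Hj <- list(); Hx <- list(); nh <- 0L
  hput <- function(i, j, x) {
    nh <<- nh + 1L; Hi[[nh]] <<- i; Hj[[nh]] <<- j; Hx[[nh]] <<- x
  }

  # ---- tracking ----
  J_track <- 0
  H_track <- NULL
  if (!is.null(prob$tracks)) {
    nS <- nrow(prob$placements)
    # track_scale < 1 emulates inflated measurement variance; used by the
    # tempered continuation in solve_reconstruction, 1 at the final stage
    wn <- (prob$track_scale %||% 1) / (3 * nS * N)
    sig <- if (derivs)
      .virtual_signals_jac(Q2, V2, Av, prob$placements, prob$seg)
    else
      lapply(seq_len(nS), function(i) {
        pl <- prob$placements[i, ]
        .dyn_imu_val_fns[[pl$segment]](Q2, V2, Av, pl$rx, pl$ry, prob$seg$p)
      })
    ti <- list(); tj <- list(); tx <- list(); nt <- 0L
    tput <- function(i, j, x) {
      nt <<- nt + 1L; ti[[nt]] <<- i; tj[[nt]] <<- j; tx[[nt]] <<- x
    }
    for (si in seq_len(nS)) {
      o <- sig[[si]]
      tr <- prob$tracks$sensors[[prob$placements$sensor[si]]]
      chans <- list(
        list(sim = o$ax, Jq = o$Jax_q, Jv = o$Jax_v, Ja = o$Jax_a),
        list(sim = o$ay, Jq = o$Jay_q, Jv = o$Jay_v, Ja = o$Jay_a),
        list(sim = o$wz, Jq = NULL, Jv = o$Jwz_v, Ja = NULL))
      for (ch in 1:3) {
        cd <- chans[[ch]]
        mu <- tr$mean[ch, ]; s2 <- tr$var[ch, ]
        e <- cd$sim - mu
        J_track <- J_track + wn * sum(e^2 / s2)
        if (!derivs) next
        w2 <- 2 * wn * e / s2
        sq <- sqrt(s2)
        r0 <- (si - 1L) * 3L * N + (ch - 1L) * N + i1
        Jveff <- cd$Jv
        if (!is.null(cd$Ja)) Jveff <- Jveff + cd$Ja / h
        if (!is.null(cd$Jq)) {
          for (j in 1:9) g[base2 + j] <- g[base2 + j] + w2 * cd$Jq[, j]
          tput(rep(r0, 9L), rep(1:9, each = N) + rep(base2, 9L),
               as.vector(cd$Jq) / sq)
        }
        for (j in 1:9) g[base2 + 9L + j] <- g[base2 + 9L + j] + w2 * Jveff[, j]
        tput(rep(r0, 9L), 9L + rep(1:9, each = N) + rep(base2, 9L),
             as.vector(Jveff) / sq)
        if (!is.null(cd$Ja)) {
          for (j in 1:9) g[base1 + 9L + j] <- g[base1 + 9L + j] - w2 * cd$Ja[, j] / h
          tput(rep(r0, 9L), 9L + rep(1:9, each = N) + rep(base1, 9L),
               as.vector(-cd$Ja / h) / sq)
          dT <- -rowSums(cd$Ja * t(Av)) / Tt
          g[lay$i_T] <- g[lay$i_T] + sum(w2 * dT)
          tput(r0, rep(lay$i_T, N), dT / sq)
        }
      }
    }
    if (derivs) {
      Jw <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                                 dims = c(3L * nS * N, nz))
      H_track <- 2 * wn * Matrix::crossprod(Jw)
    }
  }

  # ---- effort ----
  vsp <- st$speed
  S2 <- sum(U2^2)
  ce <- w$effort / (16 * N)
  J_effort_raw <- S2 / (16 * N * vsp^2)
  ucols2 <- rep(base2, each = 16L) + 50L + 1:16
  if (derivs) {
    g[ucols2] <- g[ucols2] + 2 * ce * as.vector(U2) / vsp^2
    g[lay$i_speed] <- g[lay$i_speed] - 2 * ce * S2 / vsp^3
    hput(ucols2, ucols2, rep(2 * ce / vsp^2, length(ucols2)))
    cross <- -4 * ce * as.vector(U2) / vsp^3
    hput(ucols2, rep(lay$i_speed, length(ucols2)), cross)
    hput(rep(lay$i_speed, length(ucols2)), ucols2, cross)
    hput(lay$i_speed, lay$i_speed, 6 * ce * S2 / vsp^4)
  }

  # ---- regularization ----
  cr_u <- w$reg / (16 * N * Tt); cr_v <- w$reg / (9 * N * Tt)
  DU <- st$U[, i2, drop = FALSE] - st$U[, i1, drop = FALSE]
  DV <- st$V[, i2, drop = FALSE] - st$V[, i1, drop = FALSE]
  J_reg_raw <- (sum(DU^2) / 16 + sum(DV^2) / 9) / (N * Tt)
  if (derivs) {
    GU <- matrix(0, 16L, N + 1L); GV <- matrix(0, 9L, N + 1L)
    GU[, i1] <- GU[, i1] - 2 * DU; GU[, i2] <- GU[, i2] + 2 * DU
    GV[, i1] <- GV[, i1] - 2 * DV; GV[, i2] <- GV[, i2] + 2 * DV
    allu <- rep((0:N) * .NODE_LEN, each = 16L) + 50L + 1:16
    allv <- rep((0:N) * .NODE_LEN, each = 9L) + 9L + 1:9
    g[allu] <- g[allu] + cr_u * as.vector(GU)
    g[allv] <- g[allv] + cr_v * as.vector(GV)
    g[lay$i_T] <- g[lay$i_T] - (cr_u * sum(DU^2) + cr_v * sum(DV^2)) / Tt
    deg <- c(1, rep(2, N - 1L), 1)
    du_diag <- rep(2 * cr_u * deg, each = 16L)
    dv_diag <- rep(2 * cr_v * deg, each = 9L)
    hput(allu, allu, du_diag)
    hput(allv, allv, dv_diag)
    u_lo <- rep((0:(N - 1L)) * .NODE_LEN, each = 16L) + 50L + 1:16
    u_hi <- rep((1:N) * .NODE_LEN, each = 16L) + 50L + 1:16
    v_lo <- rep((0:(N - 1L)) * .NODE_LEN, each = 9L) + 9L + 1:9
    v_hi <- rep((1:N) * .NODE_LEN, each = 9L) + 9L + 1:9
    hput(u_lo, u_hi, rep(-2 * cr_u, length(u_lo)))
    hput(u_hi, u_lo, rep(-2 * cr_u, length(u_lo)))
    hput(v_lo, v_hi, rep(-2 * cr_v, length(v_lo)))
    hput(v_hi, v_lo, rep(-2 * cr_v, length(v_lo)))
  }

  # gauge fixing: accelerometers only observe the pelvis x position up to a
  # constant, so anchor the first-node pelvis x (a pure numerical gauge term);
  # predictive problems additionally pin the cycle phase (time-shift gauge)
  wg <- 1e-2
  J_gauge <- wg * z[1]^2
  if (derivs) {
    g[1] <- g[1] + 2 * wg * z[1]
    hput(1L, 1L, 2 * wg)
  }
  if (!is.null(prob$phase_anchor)) {
    # the phase anchor must dominate the discretization-scale objective
    # ripple along the cyclic-shift orbit, so it is weighted more strongly
    # than the translation gauge
    wp <- 0.5
    dev <- z[4] - prob$phase_anchor
    J_gauge <- J_gauge + wp * dev^2
    if (derivs) {
      g[4] <- g[4] + 2 * wp * dev
      hput(4L, 4L, 2 * wp)
    }
  }

  # optional quadratic pull toward a reference posture trajectory (used by
  # the predictive-gait continuation; absent in data reconstructions)
  J_state <- 0
  if (!is.null(prob$state_track)) {
    Qref <- prob$state_track$Q; wst <- prob$state_track$w / (9 * (N + 1L))
    dq <- st$Q - Qref
    J_state <- wst * sum(dq^2)
    if (derivs) {
      qcols <- rep((0:N) * .NODE_LEN, each = 9L) + 1:9
      g[qcols] <- g[qcols] + 2 * wst * as.vector(dq)
      hput(qcols, qcols, rep(2 * wst, length(qcols)))
    }
  }

  f <- J_track + w$effort * J_effort_raw + w$reg * J_reg_raw + J_gauge + J_state
  out <- list(f = f, components = list(track = J_track, effort = J_effort_raw,
                                       reg = J_reg_raw, gauge = J_gauge,
                                       state = J_state))
  if (derivs) {
    H <- Matrix::sparseMatrix(i = unlist(Hi[seq_len(nh)]),
                              j = unlist(Hj[seq_len(nh)]),
                              x = unlist(Hx[seq_len(nh)]),
                              dims = c(nz, nz))
    if (!is.null(H_track)) H <- H + H_track
    out$g <- g
    out$H <- H
  }
  out
}
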