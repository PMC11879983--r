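# Direct-collocation transcription of the gait reconstruction optimal control
# problem (backward Euler, N intervals, one extra node for periodicity).
#
# Decision vector layout (per node, 82 values):
#   q (9) | v (9) | lce (16, normalized to lceopt) | act (16) | u (16) |
#   contact (4 points x (px, py, fx, fy); forces in bodyweights)
# followed by the global speed (m/s) and cycle duration (s):
#   length = (N + 1) * 82 + 2.
# Constraints (per interval k = 1..N, residuals evaluated at the right node
# k+1 with backward-Euler rates (x_{k+1} - x_k)/h, h = T/N):
#   9 kinematic rows | 9 dynamics rows | 16 contraction rows |
#   16 activation rows | 16 contact-consistency rows   (66 per interval),
# plus 82 periodicity rows tying node N+1 to node 1 with the horizontal shift
# speed*T on the pelvis x and the four contact-point x positions:
#   length = N * 66 + 82.
# Rows are scaled to order one: dynamics and contact-force rows by 1/bodyweight
# (force decision variables are stored in bodyweights), activation rows by the
# deactivation time constant; CE lengths are stored normalized to lceopt.

.NODE_LEN <- 82L
.ROWS_PER_INT <- 66L

.ocp_layout <- function(N) {
  nz <- (N + 1L) * .NODE_LEN + 2L
  list(N = N, nz = nz, nc = N * .ROWS_PER_INT + 82L,
       i_speed = nz - 1L, i_T = nz)
}

# ---------------------------------------------------------------------------
# objective terms (exported closed forms)

#' Variance-weighted IMU tracking cost
#'
#' Discrete tracking objective
#' `1/(3 nIMU N) * sum_nodes sum_sensors sum_channels ((sim - mu)^2 / sigma^2)`,
#' the rectangle-rule discretization of the continuous variance-weighted
#' squared tracking error averaged over the cycle (the `dt/T` weights cancel
#' to `1/N`).
#'
#' @param sim named list (by sensor) of lists with vectors `a_x`, `a_y`,
#'   `omega_z`, each of length N.
#' @param tracks a track set as produced by [synthesize_tracks()] or
#'   [read_imu_csv()].
#' @param T cycle duration (s); accepted for interface completeness, the
#'   discrete cost does not depend on it.
#' @return scalar cost (non-negative; 0 for perfect tracking).
#' @export
tracking_cost <- function(sim, tracks, T = NULL) {
  sensors <- names(tracks$sensors)
  if (!all(sensors %in% names(sim))) stop("sim is missing sensors: ",
    paste(setdiff(sensors, names(sim)), collapse = ", "))
  nS <- length(sensors)
  total <- 0
  for (s in sensors) {
    tr <- tracks$sensors[[s]]
    if (any(tr$var <= 0)) stop("track variances must be floored positive (preparation error)")
    smat <- rbind(sim[[s]]$a_x, sim[[s]]$a_y, sim[[s]]$omega_z)
    if (ncol(smat) != ncol(tr$mean)) stop("node count mismatch for sensor ", s)
    total <- total + sum((smat - tr$mean)^2 / tr$var)
  }
  total / (3 * nS * ncol(tracks$sensors[[1]]$mean))
}

#' Muscular effort cost
#'
#' `1/(T v^2 n_mus) * integral(sum_i u_i(t)^2 dt)` discretized with rectangle
#' weights `dt = T/N`, i.e. `sum(u^2) / (n_mus N v^2)`.
#'
#' @param u matrix of muscle excitations at the N integration nodes
#'   (muscles x nodes).
#' @param v gait speed (m/s), must be positive.
#' @param T cycle duration (s); cancels in the discrete form.
#' @export
effort_cost <- function(u, v, T = NULL) {
  if (!is.numeric(v) || v <= 0) stop("speed must be positive")
  u <- as.matrix(u)
  sum(u^2) / (nrow(u) * ncol(u) * v^2)
}

#' Trajectory roughness regularization
#'
#' Mean squared first difference of the excitations and of the generalized
#' velocities across nodes, scaled by `1/T`:
#' `1/(N T) * (sum_k ||u_{k+1}-u_k||^2 / 16 + sum_k ||v_{k+1}-v_k||^2 / 9)`.
#' Zero for constant controls; penalizes node-to-node roughness.
#'
#' @param u 16 x (N+1) excitation trajectory.
#' @param gen_vel 9 x (N+1) generalized-velocity trajectory.
#' @param T cycle duration (s).
#' @export
regularization_cost <- function(u, gen_vel, T) {
  u <- as.matrix(u); gv <- as.matrix(gen_vel)
  N <- ncol(u) - 1L
  du <- u[, -1L, drop = FALSE] - u[, -ncol(u), drop = FALSE]
  dv <- gv[, -1L, drop = FALSE] - gv[, -ncol(gv), drop = FALSE]
  (sum(du^2) / nrow(u) + sum(dv^2) / nrow(gv)) / (N * T)
}

# ---------------------------------------------------------------------------
# track preparation (variance floor)

.prepare_tracks <- function(tracks, floor_rel = 1e-4, floor_abs = 1e-6) {
  tracks$sensors <- lapply(tracks$sensors, function(tr) {
    fl <- floor_rel * rowMeans(tr$mean^2) + floor_abs
    tr$var <- pmax(tr$var, matrix(fl, 3, ncol(tr$var)))
    tr
  })
  tracks$prepared <- TRUE
  tracks
}

# ---------------------------------------------------------------------------
# problem assembly

#' Assemble the collocation NLP for one reconstruction
#'
#' Builds the decision/constraint layout, bounds and objective data for a
#' periodic gait reconstruction.  With `tracks = NULL` the problem is the
#' predictive (effort-minimal) variant; fix the speed through `speed_bounds`.
#' The layout dimensions depend only on `N` (the sensor setup only changes
#' the objective): `(N+1)*82 + 2` decision variables and `N*66 + 82`
#' constraint rows.
#'
#' @param setup sensor setup name (one of the seven catalog names); ignored
#'   when `tracks` is given (the track setup is used).
#' @param tracks an IMU track set ([synthesize_tracks()], [read_imu_csv()]),
#'   or NULL for a predictive problem.
#' @param subject a [subject_descriptor()].
#' @param N number of collocation intervals (default 100).
#' @param weights named vector/list with `effort` and `reg` objective weights
#'   (defaults 300 and 1e-5).
#' @param contact contact parameters ([default_contact_params()]).
#' @param speed_bounds length-2 bounds on the speed decision variable
#'   (default c(0.2, 6)); use c(v, v) to prescribe the speed.
#' @param duration_bounds bounds on the cycle duration (default c(0.2, 2)).
#' @return A `gaitrec_problem` object with fields `lb`, `ub`, `layout`, etc.
#' @export
assemble_nlp <- function(setup = "FSTP", tracks = NULL, subject, N = 100L,
                         weights = c(effort = 300, reg = 1e-5),
                         contact = default_contact_params(),
                         speed_bounds = c(0.2, 6),
                         duration_bounds = c(0.2, 2)) {
  N <- as.integer(N)
  if (N < 2) stop("N must be at least 2")
  if (!is.null(tracks)) {
    setup <- tracks$setup
    if (!isTRUE(tracks$prepared)) tracks <- .prepare_tracks(tracks)
    nt <- unique(vapply(tracks$sensors, function(tr) ncol(tr$mean), 1))
    if (length(nt) != 1L) stop("tracks have inconsistent node counts")
    if (nt != N) stop("tracks have ", nt, " nodes but N = ", N)
  }
  if (!setup %in% names(.SETUP_SEGMENTS)) stop("unknown setup: ", setup)
  if (speed_bounds[1] > speed_bounds[2] || duration_bounds[1] > duration_bounds[2])
    stop("infeasible bounds")
  seg <- scale_segments(subject)
  mus <- default_muscle_table()
  lay <- .ocp_layout(N)
  placements <- sensor_placements(setup, seg)
  if (!is.null(tracks) &&
      !setequal(names(tracks$sensors), placements$sensor))
    stop("tracks do not cover the sensors of setup ", setup)

  leg <- seg$leg_length
  q_lb <- c(-5, 0.5 * leg, -1, -1, -0.1, -1, -1, -0.1, -1)
  q_ub <- c(15, 1.5 * leg, 1, 1.6, 2.4, 1, 1.6, 2.4, 1)
  v_lb <- c(-2, -3, rep(-25, 7)); v_ub <- c(10, 3, rep(25, 7))
  blk_lb <- c(q_lb, v_lb, rep(0.3, 16), rep(0, 16), rep(0, 16),
              rep(c(-5, -0.05, -3, -0.05), 4))
  blk_ub <- c(q_ub, v_ub, rep(1.9, 16), rep(1, 16), rep(1, 16),
              rep(c(16, 1.6, 3, 5), 4))
  lb <- c(rep(blk_lb, N + 1L), speed_bounds[1], duration_bounds[1])
  ub <- c(rep(blk_ub, N + 1L), speed_bounds[2], duration_bounds[2])

  w <- as.list(weights)
  if (is.null(w$effort)) w$effort <- 300
  if (is.null(w$reg)) w$reg <- 1e-5

  # predictive problems are invariant to cyclic time shifts; a soft anchor on
  # the first-node hip flexion pins the cycle to start near right heel strike
  phase_anchor <- if (is.null(tracks))
    .hip_template(mean(speed_bounds), 0) else NULL

  mus$Dpair <- local({   # 16 x 36 columns D[,jj]*D[,j2], jj outer over 6x6
    out <- matrix(0, 16, 36)
    for (jj in 1:6) for (j2 in 1:6) out[, (jj - 1L) * 6L + j2] <- mus$D[, jj] * mus$D[, j2]
    out
  })

  structure(list(
    cache = new.env(parent = emptyenv()),
    N = N, layout = lay, setup = setup, tracks = tracks,
    subject = seg$subject, seg = seg, mus = mus, contact = contact,
    placements = placements, weights = w,
    lb = lb, ub = ub,
    bw = seg$subject$mass * 9.81,
    lceopt = mus$table$lceopt,
    phase_anchor = phase_anchor,
    scale_act_row = 0.04),
    class = "gaitrec_problem")
}

.ocp_unpack <- function(z, prob) {
  N <- prob$N
  M <- matrix(z[seq_len((N + 1L) * .NODE_LEN)], .NODE_LEN, N + 1L)
  list(Q = M[1:9, , drop = FALSE], V = M[10:18, , drop = FALSE],
       LCEn = M[19:34, , drop = FALSE], ACT = M[35:50, , drop = FALSE],
       U = M[51:66, , drop = FALSE], C = M[67:82, , drop = FALSE],
       speed = z[prob$layout$i_speed], T = z[prob$layout$i_T])
}

.ocp_pack <- function(Q, V, LCEn, ACT, U, C, speed, T) {
  c(rbind(Q, V, LCEn, ACT, U, C), speed, T)
}

.FROW <- c(3L, 4L, 7L, 8L, 11L, 12L, 15L, 16L)  # fx1 fy1 ... within contact block

# ---------------------------------------------------------------------------
# constraint evaluation with sparse Jacobian
#
# Returns list(c = residual vector, A = sparse nc x nz Jacobian (if jac)).

.ocp_constraints <- function(z, prob, jac = TRUE) {
  N <- prob$N; lay <- prob$layout
  p <- prob$seg$p; mus <- prob$mus; bw <- prob$bw
  lo <- prob$lceopt; sdyn <- 1 / bw; sact <- prob$scale_act_row
  st <- .ocp_unpack(z, prob)
  Tt <- st$T; h <- Tt / N
  i2 <- 2:(N + 1L); i1 <- 1:N
  Q1 <- st$Q[, i1, drop = FALSE]; Q2 <- st$Q[, i2, drop = FALSE]
  V1 <- st$V[, i1, drop = FALSE]; V2 <- st$V[, i2, drop = FALSE]
  L1 <- st$LCEn[, i1, drop = FALSE] * lo; L2 <- st$LCEn[, i2, drop = FALSE] * lo
  A1 <- st$ACT[, i1, drop = FALSE]; A2 <- st$ACT[, i2, drop = FALSE]
  U2 <- st$U[, i2, drop = FALSE]
  C2 <- st$C[, i2, drop = FALSE]
  Aq <- (Q2 - Q1) / h; Av <- (V2 - V1) / h
  Alce <- (L2 - L1) / h; Aact <- (A2 - A1) / h

  mm <- .moments_mech(Q2, V2, L2, mus, include_passive = TRUE, deriv = jac)
  fdec <- C2[.FROW, , drop = FALSE] * bw            # N-column 8-row, newtons
  if (jac) {
    eom <- .dyn_eom(Q2, V2, Av, mm$tau, fdec, p)
    ck <- .dyn_cpkin(Q2, V2, p)
    if (!is.null(prob$cache)) {
      prob$cache$z <- z
      prob$cache$eom <- eom
      prob$cache$ck <- ck
    }
  } else {
    eom <- .dyn_eom_val(Q2, V2, Av, mm$tau, fdec, p)
    ck <- .dyn_cpkin_val(Q2, V2, p)
  }
  cm <- .contraction_mech(A2, L2, Alce, musculotendon_length(Q2, mus)$lmt,
                          mus, deriv = jac)
  am <- .activation_mech(U2, A2, Aact, mus)
  cf <- contact_force(ck$py, ck$vx, ck$vy, prob$contact, deriv = jac)

  # ---- residual vector ----
  res <- numeric(lay$nc)
  rb <- (i1 - 1L) * .ROWS_PER_INT                      # interval row bases
  idx9 <- function(off) rep(rb, each = 9L) + off + 1:9
  idx16 <- function(off) rep(rb, each = 16L) + off + 1:16
  res[idx9(0L)] <- as.vector(Aq - V2)
  res[idx9(9L)] <- as.vector(t(eom$res)) * sdyn
  res[idx16(18L)] <- as.vector(cm$res)
  res[idx16(34L)] <- as.vector(am$res) * sact
  cres <- matrix(0, 16L, N)
  for (pt in 1:4) {
    b <- (pt - 1L) * 4L
    cres[b + 1L, ] <- C2[b + 1L, ] - ck$px[, pt]
    cres[b + 2L, ] <- C2[b + 2L, ] - ck$py[, pt]
    cres[b + 3L, ] <- C2[b + 3L, ] - cf$fx[, pt] / bw
    cres[b + 4L, ] <- C2[b + 4L, ] - cf$fy[, pt] / bw
  }
  res[idx16(50L)] <- as.vector(cres)
  # periodicity
  shift <- numeric(.NODE_LEN)
  shift[c(1L, 66L + c(1L, 5L, 9L, 13L))] <- 1
  zN1 <- z[N * .NODE_LEN + 1:.NODE_LEN]
  z1 <- z[1:.NODE_LEN]
  res[N * .ROWS_PER_INT + 1:.NODE_LEN] <- zN1 - z1 - shift * st$speed * Tt
  if (!jac) return(list(c = res))

  # ---- Jacobian triplets ----
  ii <- vector("list", 80L); jj <- vector("list", 80L); xx <- vector("list", 80L)
  nb <- 0L
  put <- function(i, j, x) {
    nb <<- nb + 1L
    ii[[nb]] <<- i; jj[[nb]] <<- j
    xx[[nb]] <<- rep_len(as.vector(x), length(i))
  }
  base1 <- (i1 - 1L) * .NODE_LEN                      # node k block starts
  base2 <- i1 * .NODE_LEN                              # node k+1 block starts
  # helpers: entries ordered i fastest within each k (matches 16xN / 9xN mats)
  diag_blk <- function(rowoff, coloff, nbk, val, node = 2L) {
    bs <- if (node == 2L) base2 else base1
    put(rep(rb, each = nbk) + rowoff + 1:nbk,
        rep(bs, each = nbk) + coloff + 1:nbk, val)
  }
  # entries ordered k fastest (matches (N, ni, nj) arrays)
  full_blk <- function(rowoff, coloff, ni, nj, arr, node = 2L) {
    bs <- if (node == 2L) base2 else base1
    put(rowoff + rep(rep(1:ni, each = N), nj) + rep(rb, ni * nj),
        coloff + rep(1:nj, each = N * ni) + rep(bs, ni * nj), arr)
  }
  T_blk <- function(rowoff, nbk, val) {   # val nbk x N, i fastest
    put(rep(rb, each = nbk) + rowoff + 1:nbk,
        rep(lay$i_T, N * nbk), val)
  }

  # kinematic rows
  diag_blk(0L, 0L, 9L, 1 / h, node = 2L)
  diag_blk(0L, 0L, 9L, -1 / h, node = 1L)
  diag_blk(0L, 9L, 9L, -1, node = 2L)
  T_blk(0L, 9L, -Aq / Tt)

  # dynamics rows (scale sdyn)
  full_blk(9L, 0L, 9L, 9L, eom$Jq * sdyn, node = 2L)
  full_blk(9L, 9L, 9L, 9L, (eom$Jv + eom$Ja / h) * sdyn, node = 2L)
  full_blk(9L, 9L, 9L, 9L, -eom$Ja / h * sdyn, node = 1L)
  # joint-moment chain: joint rows of the eom get -dtau/d(.)
  # muscle part: -dtau/dq = +[t(D) diag(dF/dlse) D], symmetric per node
  Pm <- t(mm$d_lse) %*% mus$Dpair                      # N x 36
  full_blk(12L, 3L, 6L, 6L, array(Pm, c(N, 6L, 6L)) * sdyn, node = 2L)
  # passive stiffness/damping (diagonal on joints)
  diag_blk(12L, 3L, 6L, -mm$passive$d_q * sdyn, node = 2L)
  diag_blk(12L, 12L, 6L, -mm$passive$d_v * sdyn, node = 2L)
  # muscle lce coupling into moments: rows 4..9, lce cols
  Sl <- mm$d_lse * lo                                   # 16 x N
  arr_lce <- vapply(1:6, function(jjx) t(Sl) * rep(mus$D[, jjx], each = N),
                    matrix(0, N, 16L))
  full_blk(12L, 18L, 6L, 16L, aperm(arr_lce, c(1L, 3L, 2L)) * sdyn, node = 2L)
  # contact force decision variables
  fcols <- 66L + .FROW
  put(9L + rep(rep(1:9, each = N), 8L) + rep(rb, 72L),
      rep(fcols, each = N * 9L) + rep(base2, 72L),
      as.vector(eom$Jf) * bw * sdyn)
  # dres/dT = Ja %*% dAv/dT, dAv/dT = -Av/T
  dT_dyn <- matrix(0, 9L, N)
  for (i in 1:9) dT_dyn[i, ] <- -rowSums(eom$Ja[, i, ] * t(Av)) / Tt
  T_blk(9L, 9L, dT_dyn * sdyn)

  # contraction rows
  diag_blk(18L, 34L, 16L, cm$d_act, node = 2L)
  diag_blk(18L, 18L, 16L, (cm$d_lce + cm$d_rate / h) * lo, node = 2L)
  diag_blk(18L, 18L, 16L, -(cm$d_rate / h) * lo, node = 1L)
  arr_q <- vapply(1:6, function(jjx) -t(cm$d_lmt) * rep(mus$D[, jjx], each = N),
                  matrix(0, N, 16L))
  full_blk(18L, 3L, 16L, 6L, arr_q, node = 2L)
  T_blk(18L, 16L, cm$d_rate * (-Alce / Tt))

  # activation rows (scale sact)
  diag_blk(34L, 50L, 16L, am$d_u * sact, node = 2L)
  diag_blk(34L, 34L, 16L, (am$d_act + 1 / h) * sact, node = 2L)
  diag_blk(34L, 34L, 16L, (-1 / h) * sact, node = 1L)
  T_blk(34L, 16L, (-Aact / Tt) * sact)

  # contact-consistency rows
  diag_blk(50L, 66L, 16L, 1)
  for (pt in 1:4) {
    b <- (pt - 1L) * 4L
    # position rows vs q
    full_blk(50L + b, 0L, 1L, 9L, -ck$Jpx[, pt, ], node = 2L)
    full_blk(51L + b, 0L, 1L, 9L, -ck$Jpy[, pt, ], node = 2L)
    # force rows vs q and v (model kinematics chain), scaled 1/bw
    dfx_q <- -(cf$dfx_py[, pt] * ck$Jpy[, pt, ] + cf$dfx_vx[, pt] * ck$Jvx[, pt, ] +
               cf$dfx_vy[, pt] * ck$Jvy[, pt, ]) / bw
    dfy_q <- -(cf$dfy_py[, pt] * ck$Jpy[, pt, ] + cf$dfy_vy[, pt] * ck$Jvy[, pt, ]) / bw
    dfx_v <- -(cf$dfx_vx[, pt] * ck$Jpx[, pt, ] + cf$dfx_vy[, pt] * ck$Jpy[, pt, ]) / bw
    dfy_v <- -(cf$dfy_vy[, pt] * ck$Jpy[, pt, ]) / bw
    full_blk(52L + b, 0L, 1L, 9L, dfx_q, node = 2L)
    full_blk(53L + b, 0L, 1L, 9L, dfy_q, node = 2L)
    full_blk(52L + b, 9L, 1L, 9L, dfx_v, node = 2L)
    full_blk(53L + b, 9L, 1L, 9L, dfy_v, node = 2L)
  }

  # periodicity rows
  prow <- N * .ROWS_PER_INT + 1:.NODE_LEN
  put(prow, N * .NODE_LEN + 1:.NODE_LEN, rep(1, .NODE_LEN))
  put(prow, 1:.NODE_LEN, rep(-1, .NODE_LEN))
  sh <- which(shift == 1)
  put(N * .ROWS_PER_INT + sh, rep(lay$i_speed, 5L), rep(-Tt, 5L))
  put(N * .ROWS_PER_INT + sh, rep(lay$i_T, 5L), rep(-st$speed, 5L))

  iv <- unlist(ii[seq_len(nb)]); jv <- unlist(jj[seq_len(nb)])
  xv <- unlist(xx[seq_len(nb)])
  keep <- xv != 0
  A <- Matrix::sparseMatrix(i = iv[keep], j = jv[keep], x = xv[keep],
                            dims = c(lay$nc, lay$nz))
  list(c = res, A = A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
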