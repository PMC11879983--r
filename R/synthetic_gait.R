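# Synthetic ground truth: predictive (effort-minimal) periodic gaits at the
# study speed bands, virtual IMU tracks with additive Gaussian across-cycle
# noise, and the end-to-end recovery harness.

#' Speed bands of the study conditions
#'
#' Three walking and three running bands; `mid` is the representative speed
#' used by the synthetic generator.
#'
#' @return data.frame with condition, lo, hi, mid (m/s).
#' @export
speed_conditions <- function() {
  data.frame(
    condition = c("slow_walk", "normal_walk", "fast_walk",
                  "slow_run", "normal_run", "fast_run"),
    lo = c(0.9, 1.3, 1.7, 3.1, 3.9, 4.7),
    hi = c(1.0, 1.4, 1.8, 3.3, 4.1, 4.9),
    mid = c(0.95, 1.35, 1.75, 3.2, 4.0, 4.8))
}

# nominal hip-flexion waveform; phase 0 is (approximately) right heel strike.
# Shared between the template guess and the predictive phase anchor.
.hip_template <- function(speed, ph) {
  if (speed >= 2.2) 0.25 + 0.50 * cos(2 * pi * ph + 0.3)
  else 0.14 + 0.37 * cos(2 * pi * ph + 0.18)
}

# nominal gait pattern used as initial guess: joint-angle harmonics shaped
# like normal walking/running waveforms, speed-scaled stride and cadence,
# backward-Euler-consistent velocities, model-consistent contact values.
.gait_template <- function(prob, speed) {
  N <- prob$N; lay <- prob$layout
  run <- speed >= 2.2
  stride <- if (run) 0.62 * speed + 0.42 else 0.75 * speed + 0.40
  T0 <- min(max(stride / speed, prob$lb[lay$i_T] + 1e-3),
            prob$ub[lay$i_T] - 1e-3)
  stride <- speed * T0
  ph <- (0:N) / N
  hipf <- function(ph) .hip_template(speed, ph)
  kneef <- function(ph) if (run) {
    0.60 + 0.55 * cos(2 * pi * (ph - 0.65)) + 0.15 * cos(4 * pi * (ph - 0.20))
  } else {
    0.40 + 0.42 * cos(2 * pi * (ph - 0.72)) + 0.12 * cos(4 * pi * (ph - 0.12))
  }
  anklef <- function(ph) if (run) {
    0.05 + 0.15 * cos(2 * pi * (ph - 0.05)) + 0.10 * cos(4 * pi * (ph - 0.55))
  } else {
    -0.02 + 0.10 * cos(2 * pi * (ph - 1.10 / (2 * pi))) +
      0.12 * cos(4 * pi * (ph - 2.60 / (4 * pi)))
  }
  leg <- prob$seg$leg_length
  Q <- matrix(0, 9L, N + 1L)
  Q[1, ] <- stride * ph
  Q[2, ] <- if (run) 0.955 * leg + 0.03 * cos(4 * pi * ph - 0.5)
            else 0.975 * leg + 0.015 * cos(4 * pi * ph - 0.6)
  Q[3, ] <- if (run) -0.12 else -0.05
  Q[4, ] <- hipf(ph);        Q[7, ] <- hipf(ph + 0.5)
  Q[5, ] <- pmax(kneef(ph), 0.02);  Q[8, ] <- pmax(kneef(ph + 0.5), 0.02)
  Q[6, ] <- anklef(ph);      Q[9, ] <- anklef(ph + 0.5)
  # drop the pelvis so the deepest contact point just penetrates the ground
  ck0 <- .dyn_cpkin(Q, matrix(0, 9L, N + 1L), prob$seg$p)
  Q[2, ] <- Q[2, ] + (-0.005 - min(ck0$py))
  h <- T0 / N
  V <- matrix(0, 9L, N + 1L)
  V[, 2:(N + 1L)] <- (Q[, 2:(N + 1L)] - Q[, 1:N]) / h
  V[, 1L] <- V[, N + 1L]
  mus <- prob$mus
  lmt <- musculotendon_length(Q, mus)$lmt
  LCEn <- (lmt - mus$table$slack) / mus$table$lceopt
  LCEn <- pmin(pmax(LCEn, 0.55), 1.6)
  ACT <- matrix(0.1, 16L, N + 1L)
  U <- matrix(0.1, 16L, N + 1L)
  C <- .contacts_from_kinematics(Q, V, prob)
  # replace the contact-law forces by per-node inverse-dynamics forces: the
  # least-squares forces zeroing the equations of motion.  This leaves the
  # initial infeasibility concentrated in the decoupled contact-consistency
  # rows, which conditions the first solver iterations much better.
  i2 <- 2:(N + 1L)
  Av <- (V[, i2, drop = FALSE] - V[, 1:N, drop = FALSE]) / h
  mm <- .moments_mech(Q[, i2, drop = FALSE], V[, i2, drop = FALSE],
                      LCEn[, i2, drop = FALSE] * mus$table$lceopt, mus,
                      deriv = FALSE)
  eo <- .dyn_eom(Q[, i2, drop = FALSE], V[, i2, drop = FALSE], Av, mm$tau,
                 matrix(0, 8L, N), prob$seg$p)
  for (k in seq_len(N)) {
    Jf <- eo$Jf[k, , ]
    fk <- solve(crossprod(Jf) + 1e-4 * diag(8L), -crossprod(Jf, eo$res[k, ]))
    C[.FROW, k + 1L] <- fk / prob$bw
  }
  C[.FROW, 1L] <- C[.FROW, N + 1L]
  .ocp_pack(Q, V, LCEn, ACT, U, C, speed, T0)
}

#' Predictive (effort-minimal) periodic gait
#'
#' Solves the collocation problem with no data tracking: the objective is the
#' weighted effort plus regularization, the speed decision variable is fixed
#' at the target, and periodicity plus the full system dynamics are enforced,
#' yielding a dynamically consistent synthetic gait cycle.
#'
#' @param speed target average speed (m/s), within the problem speed bounds.
#' @param subject a [subject_descriptor()].
#' @param N collocation intervals.
#' @param options solver options (see [solve_reconstruction()]).
#' @param weights objective weights as in [assemble_nlp()].
#' @return A converged `gaitrec_result`; solver failures are raised as errors
#'   carrying the solver diagnostics.
#' @export
predictive_gait <- function(speed, subject, N = 50L,
                            options = list(), weights = c(effort = 300, reg = 1e-5)) {
  if (speed < 0.2 || speed > 6) stop("target speed outside bounds (0.2, 6) m/s")
  Nc <- as.integer(options$coarse_N %||% min(N, 12L))
  options$coarse_N <- NULL
  # the cycle duration of the synthetic truth is prescribed from the nominal
  # speed-stride relationship (effort per distance alone under-determines
  # cadence); T stays a decision variable structurally, held by equal bounds
  fixT <- function(prob, T0) {
    prob$lb[prob$layout$i_T] <- T0; prob$ub[prob$layout$i_T] <- T0
    prob
  }
  run_stages <- function(prob, z) {
    # continuation: pull toward the nominal kinematics first, then release
    # the pull so only effort remains; each stage warm-starts the next
    Qref <- .ocp_unpack(z, prob)$Q
    duals <- NULL; iters <- 0L; res <- NULL
    stages <- list(list(w = 20, it = options$stage1_iter %||% 300L),
                   list(w = 0, it = options$max_iter %||% 1500L))
    for (si in seq_along(stages)) {
      sg <- stages[[si]]
      prob$state_track <- if (sg$w > 0) list(Q = Qref, w = sg$w) else NULL
      o <- options
      o$stage1_iter <- NULL
      o$hessian <- "exact"
      o$max_iter <- sg$it
      o$polish <- (si == length(stages))
      if (!is.null(duals)) o <- modifyList(o, list(y0 = duals$y, zl0 = duals$zl,
                                                   zu0 = duals$zu,
                                                   mu_init = 1e-4))
      res <- solve_reconstruction(prob, guess = z, options = o)
      z <- res$z; duals <- res$duals
      iters <- iters + res$iterations
    }
    res$iterations <- iters
    res
  }
  prob <- assemble_nlp(setup = "FSTP", tracks = NULL, subject = subject,
                       N = Nc, weights = weights, speed_bounds = c(speed, speed))
  z0 <- initial_guess(prob, "nominal")
  prob <- fixT(prob, z0[prob$layout$i_T])
  res <- run_stages(prob, z0)
  # mesh-refinement ladder: interpolate each converged solution onto the next
  # finer collocation grid and re-solve from the warm start
  ladder <- sort(unique(pmin(c(2L * Nc, N), N)))
  for (Ni in ladder[ladder > Nc]) {
    probf <- assemble_nlp(setup = "FSTP", tracks = NULL, subject = subject,
                          N = Ni, weights = weights,
                          speed_bounds = c(speed, speed))
    probf <- fixT(probf, res$duration)
    zf <- .refine_guess(res, probf)
    o <- options
    o$stage1_iter <- NULL
    o$hessian <- "exact"; o$max_iter <- options$refine_iter %||% 400L
    o$refine_iter <- NULL
    o$mu_init <- 1e-3
    coarse_iters <- res$iterations
    res <- solve_reconstruction(probf, guess = zf, options = o)
    res$iterations <- res$iterations + coarse_iters
  }
  if (!res$status %in% c("converged", "acceptable"))
    stop("predictive gait solve failed: status ", res$status, " after ",
         res$iterations, " iterations (constraint violation ",
         signif(res$constraint_violation, 3), ")")
  res
}

# interpolate a result's node trajectories onto a finer collocation grid,
# removing/re-adding the steady horizontal drift of the shifted entries
.refine_guess <- function(res, prob2) {
  N1 <- res$N; N2 <- prob2$N
  s1 <- (0:N1) / N1; s2 <- (0:N2) / N2
  drift <- res$speed * res$duration
  M1 <- rbind(res$q, res$v, res$lce / prob2$lceopt, res$act, res$u, res$contacts)
  shift_rows <- c(1L, 66L + c(1L, 5L, 9L, 13L))
  M1[shift_rows, ] <- M1[shift_rows, ] - drift * rep(s1, each = length(shift_rows))
  M2 <- t(apply(M1, 1L, function(row) stats::approx(s1, row, xout = s2)$y))
  M2[shift_rows, ] <- M2[shift_rows, ] + drift * rep(s2, each = length(shift_rows))
  z <- c(as.vector(M2), res$speed, res$duration)
  pmin(pmax(z, prob2$lb), prob2$ub)
}

#' Noise model for synthetic IMU tracks
#'
#' Additive i.i.d. Gaussian noise per node and channel, applied independently
#' to each synthetic gait cycle; the track mean and variance then mimic the
#' across-cycle statistics of repeated measured strides.
#'
#' @param accel_sd accelerometer noise standard deviation (m/s^2).
#' @param gyro_sd gyroscope noise standard deviation (rad/s).
#' @param cycles number of synthetic cycles averaged (default 10).
#' @param seed RNG seed making synthesis deterministic.
#' @export
noise_model <- function(accel_sd = 0.5, gyro_sd = 0.05, cycles = 10L, seed = 1L) {
  stopifnot(accel_sd >= 0, gyro_sd >= 0, cycles >= 1)
  structure(list(accel_sd = accel_sd, gyro_sd = gyro_sd,
                 cycles = as.integer(cycles), seed = as.integer(seed)),
            class = "gaitrec_noise")
}

#' Synthesize noisy IMU tracks from a reference gait
#'
#' Computes the reference's virtual sensor signals for the given setup, draws
#' `cycles` noisy copies, and stores their per-node mean and (floored) sample
#' variance -- the same format a measured multi-cycle recording is reduced to.
#'
#' @param reference a converged `gaitrec_result` (e.g. [predictive_gait()]).
#' @param setup sensor setup name.
#' @param noise a [noise_model()].
#' @return A `gaitrec_tracks` object (sensors with `mean`/`var` 3 x N
#'   matrices, rows a_x, a_y, omega_z; track node j corresponds to
#'   collocation node j + 1).
#' @export
synthesize_tracks <- function(reference, setup, noise = noise_model()) {
  placements <- sensor_placements(setup, reference$problem$seg)
  sig <- .result_signals(reference, placements)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  N <- reference$N
  sensors <- lapply(sig, function(s) {
    clean <- rbind(s$a_x, s$a_y, s$omega_z)
    sds <- c(noise$accel_sd, noise$accel_sd, noise$gyro_sd)
    draws <- array(clean, c(3, N, noise$cycles)) +
      array(rnorm(3L * N * noise$cycles, 0, sds), c(3, N, noise$cycles))
    m <- apply(draws, c(1, 2), mean)
    v <- if (noise$cycles > 1) apply(draws, c(1, 2), var) else matrix(0, 3, N)
    rownames(m) <- rownames(v) <- c("a_x", "a_y", "omega_z")
    list(mean = m, var = v)
  })
  names(sensors) <- placements$sensor
  tr <- structure(list(setup = setup, N = N, sensors = sensors,
                       meta = list(speed = reference$speed,
                                   duration = reference$duration,
                                   noise = unclass(noise))),
                  class = "gaitrec_tracks")
  .prepare_tracks(tr)
}

#' End-to-end synthetic recovery experiment
#'
#' Generates an effort-minimal truth gait at the given speed, synthesizes
#' (optionally noisy) IMU tracks for a sensor setup, reconstructs the motion
#' from the tracks alone, and compares the reconstruction against the truth:
#' RMSD and linear-fit R^2 for the six joint angles (deg, full cycle) and the
#' right-foot ground reaction forces (BW), plus spatiotemporal differences.
#'
#' @param speed gait speed (m/s).
#' @param setup sensor setup name.
#' @param noise a [noise_model()]; its `seed` is replaced by `seed`.
#' @param N collocation intervals.
#' @param seed seed controlling the synthetic noise.
#' @param subject subject descriptor (defaults to a 1.75 m, 75 kg adult).
#' @param truth optionally a precomputed truth gait (matching speed/N) to
#'   amortize the predictive solve across noise levels and seeds.
#' @param options solver options for the reconstruction.
#' @return list(truth, tracks, reconstruction, metrics) where `metrics` is a
#'   data.frame with columns variable, unit, rmsd, r2.
#' @export
recovery_experiment <- function(speed, setup, noise = noise_model(), N = 50L,
                                seed = 1L,
                                subject = subject_descriptor(1.75, 75),
                                truth = NULL, options = list()) {
  if (!setup %in% names(.SETUP_SEGMENTS)) stop("unknown setup: ", setup)
  if (is.null(truth)) truth <- predictive_gait(speed, subject, N = N,
                                               options = options)
  noise$seed <- as.integer(seed)
  tracks <- synthesize_tracks(truth, setup, noise)
  prob <- assemble_nlp(tracks = tracks, subject = subject, N = N)
  rec <- solve_reconstruction(
    prob, guess = initial_guess(prob, "nominal", speed = speed),
    options = options)
  metrics <- .recovery_metrics(truth, rec)
  list(truth = truth, tracks = tracks, reconstruction = rec, metrics = metrics)
}

.recovery_metrics <- function(truth, rec) {
  joints <- c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")
  rows <- list()
  for (j in seq_along(joints)) {
    sim <- rec$q[3 + j, ]; ref <- truth$q[3 + j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0("angle_", joints[j]), unit = "deg",
      rmsd = rmsd(sim, ref) * 180 / pi, r2 = lfm_r2(sim, ref))
  }
  gt <- grf_trajectory(truth); gr <- grf_trajectory(rec)
  for (cmp in c("fx", "fy")) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0("grf_right_", cmp), unit = "BW",
      rmsd = rmsd(gr$right[cmp, ], gt$right[cmp, ]),
      r2 = lfm_r2(gr$right[cmp, ], gt$right[cmp, ]))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "speed", unit = "m/s",
    rmsd = abs(rec$speed - truth$speed), r2 = NA_real_)
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "stride_length", unit = "m",
    rmsd = abs(rec$speed * rec$duration - truth$speed * truth$duration),
    r2 = NA_real_)
  do.call(rbind, rows)
}
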