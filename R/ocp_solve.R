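# Initial guesses, the solve driver and the reconstruction-result container.

.contacts_from_kinematics <- function(Q, V, prob) {
  ck <- .dyn_cpkin(Q, V, prob$seg$p)
  cf <- contact_force(ck$py, ck$vx, ck$vy, prob$contact)
  C <- matrix(0, 16L, ncol(Q))
  for (pt in 1:4) {
    b <- (pt - 1L) * 4L
    C[b + 1L, ] <- ck$px[, pt]
    C[b + 2L, ] <- ck$py[, pt]
    C[b + 3L, ] <- cf$fx[, pt] / prob$bw
    C[b + 4L, ] <- cf$fy[, pt] / prob$bw
  }
  C
}

#' Initial guess for a collocation problem
#'
#' Modes: `"nominal"` (default) seeds the solver with a speed-scaled nominal
#' gait pattern (joint-angle harmonics of normal walking or running, with
#' backward-Euler-consistent velocities and model-consistent contact values);
#' `"static"` is a standing pose at every node with the pelvis translating
#' linearly by `speed * T` and all excitations at 0.1; `"warm"` reuses the
#' decision vector of a previous result of the same size.
#'
#' All guess entries are clamped into the problem bounds.
#'
#' @param problem a [assemble_nlp()] problem.
#' @param mode one of `"nominal"`, `"static"`, `"warm"`.
#' @param warm a `gaitrec_result` (or decision vector) for `mode = "warm"`.
#' @param speed target speed used to scale the guess (defaults to the
#'   prescribed speed when the speed bounds are equal, else 1.3 m/s clamped
#'   into bounds).
#' @return numeric decision vector of length `problem$layout$nz`.
#' @export
initial_guess <- function(problem, mode = c("nominal", "static", "warm"),
                          warm = NULL, speed = NULL) {
  mode <- match.arg(mode)
  lay <- problem$layout; N <- problem$N
  sb <- c(problem$lb[lay$i_speed], problem$ub[lay$i_speed])
  if (is.null(speed))
    speed <- if (abs(sb[1] - sb[2]) < 1e-12) sb[1] else min(max(1.3, sb[1]), sb[2])
  if (mode == "warm") {
    zw <- if (inherits(warm, "gaitrec_result")) warm$z else warm
    if (is.null(zw) || length(zw) != lay$nz)
      stop("warm-start dimension mismatch: expected ", lay$nz, " values")
    return(pmin(pmax(zw, problem$lb), problem$ub))
  }
  if (mode == "nominal") {
    z <- .gait_template(problem, speed)
  } else {
    T0 <- min(max(1.1, problem$lb[lay$i_T]), problem$ub[lay$i_T])
    hipH <- problem$seg$leg_length - 0.003
    Q <- matrix(0, 9L, N + 1L)
    Q[1, ] <- speed * T0 * (0:N) / N
    Q[2, ] <- hipH
    V <- matrix(0, 9L, N + 1L); V[1, ] <- speed
    C <- .contacts_from_kinematics(Q, V, problem)
    z <- .ocp_pack(Q, V, matrix(1, 16L, N + 1L), matrix(0.1, 16L, N + 1L),
                   matrix(0.1, 16L, N + 1L), C, speed, T0)
  }
  pmin(pmax(z, problem$lb), problem$ub)
}

#' Solve a gait reconstruction problem
#'
#' Runs the package's sparse primal-dual interior-point method on the
#' collocation NLP.  Status is `"converged"` when the scaled KKT error meets
#' the tolerance (with constraints additionally polished to `con_tol`),
#' `"acceptable"` for a near-converged point with feasible constraints,
#' `"max_iterations"` when the iteration budget runs out, and
#' `"restoration_failure"` when the step computation stalls (reported
#' distinctly, as for interior-point restoration failures).
#'
#' Reconstructions with tracks are solved, by default, through two
#' continuations: a mesh ladder (coarse interpolated track grids first, each
#' solution warm-starting the next; disable with `options$mesh = FALSE`) and
#' tracking-weight tempering within each level (`options$temper`, default
#' `c(1e-3, 1)`, emulating inflated measurement variance that is then
#' tightened).  Predictive problems (no tracks) default to a single
#' exact-Hessian solve; [predictive_gait()] wraps this in its own
#' kinematic-pull and mesh continuation.
#'
#' @param problem a `gaitrec_problem` from [assemble_nlp()].
#' @param guess decision vector (see [initial_guess()]); default nominal.
#' @param options list overriding solver options: `max_iter`, `tol` (scaled
#'   KKT tolerance), `con_tol` (post-polish feasibility target), `mu_init`,
#'   `time_limit` (seconds per interior-point run), `verbose`, `hessian`
#'   (`"exact"`, `"gauss_newton"`, `"tempered"`), `mesh`, `temper`,
#'   `temper_iter`.
#' @return A `gaitrec_result` with node trajectories (`q`, `v`, `lce` in m,
#'   `act`, `u`, `contacts` with positions in m and forces in bodyweights),
#'   `speed`, `duration`, objective components, solver status and iteration
#'   count.
#' @export
solve_reconstruction <- function(problem, guess = NULL, options = list()) {
  if (!inherits(problem, "gaitrec_problem")) stop("problem must come from assemble_nlp()")
  if (is.null(guess)) guess <- initial_guess(problem, "nominal")
  if (length(guess) != problem$layout$nz)
    stop("guess has wrong length (", length(guess), " vs ", problem$layout$nz, ")")

  # mesh continuation for data reconstructions: solve on interpolated coarse
  # track grids first, refining the solution upward; the stiff fine-grid
  # problem then starts from a near-feasible, near-optimal warm start
  mesh <- options$mesh %||% (!is.null(problem$tracks) && problem$N > 16L)
  options$mesh <- NULL
  if (isTRUE(mesh)) {
    N <- problem$N
    ladder <- unique(c(max(12L, ceiling(N / 4)), max(12L, ceiling(N / 2))))
    ladder <- ladder[ladder < N]
    sb <- c(problem$lb[problem$layout$i_speed], problem$ub[problem$layout$i_speed])
    db <- c(problem$lb[problem$layout$i_T], problem$ub[problem$layout$i_T])
    res <- NULL; iters <- 0L
    guess0 <- guess
    for (Ni in ladder) {
      probi <- assemble_nlp(tracks = .coarsen_tracks(problem$tracks, Ni),
                            subject = problem$subject, N = Ni,
                            weights = problem$weights, contact = problem$contact,
                            speed_bounds = sb, duration_bounds = db)
      gi <- if (is.null(res)) .refine_guess(.z_to_pseudo(guess0, problem), probi)
            else .refine_guess(res, probi)
      oi <- options
      oi$mesh <- FALSE
      if (!is.null(res)) { oi$temper <- 1; oi$mu_init <- 1e-3 }
      res <- solve_reconstruction(probi, gi, oi)
      iters <- iters + res$iterations
    }
    of <- options
    of$mesh <- FALSE; of$temper <- 1; of$mu_init <- 1e-3
    zf <- .refine_guess(res, problem)
    res <- solve_reconstruction(problem, zf, of)
    res$iterations <- res$iterations + iters
    return(res)
  }
  eval_f <- function(z, derivs) .ocp_objective(z, problem, derivs)
  eval_c <- function(z, jac) .ocp_constraints(z, problem, jac)
  eval_h <- function(z, y) .ocp_lag_hess(z, problem, y)
  hmode <- options$hessian %||%
    (if (is.null(problem$tracks)) "exact" else "tempered")
  options$hessian <- NULL
  if (hmode == "gauss_newton") {
    res <- .ipsolve(guess, problem$lb, problem$ub, eval_f, eval_c,
                    opts = options)
  } else if (hmode == "exact") {
    res <- .ipsolve(guess, problem$lb, problem$ub, eval_f, eval_c,
                    opts = options, eval_h = eval_h)
  } else {
    # tempered: continuation on the tracking weight (equivalent to starting
    # from inflated measurement variance and tightening it), each stage an
    # exact-Hessian solve warm-starting the next
    scales <- options$temper %||% c(1e-3, 1)
    stage_it <- options$temper_iter %||% 200L
    options$temper <- NULL; options$temper_iter <- NULL
    res <- NULL; iters <- 0L
    for (si in seq_along(scales)) {
      problem$track_scale <- scales[si]
      eval_fs <- function(z, derivs) .ocp_objective(z, problem, derivs)
      eval_hs <- function(z, y) .ocp_lag_hess(z, problem, y)
      o <- options
      if (si < length(scales)) {
        o$max_iter <- stage_it
        o$polish <- FALSE
      }
      if (!is.null(res)) o <- modifyList(o, list(
        y0 = res$y, zl0 = res$zl, zu0 = res$zu, mu_init = 1e-4))
      res <- .ipsolve(guess, problem$lb, problem$ub, eval_fs, eval_c,
                      opts = o, eval_h = eval_hs)
      guess <- res$z
      iters <- iters + res$iterations
    }
    problem$track_scale <- NULL
    res$iterations <- iters
  }
  st <- .ocp_unpack(res$z, problem)
  obj <- .ocp_objective(res$z, problem, derivs = FALSE)
  w <- problem$weights
  structure(list(
    z = res$z, N = problem$N, setup = problem$setup,
    subject = problem$subject,
    q = st$Q, v = st$V, lce = st$LCEn * problem$lceopt, act = st$ACT,
    u = st$U, contacts = st$C,
    speed = st$speed, duration = st$T,
    objective = list(total = obj$f,
                     track = obj$components$track,
                     effort = obj$components$effort,
                     reg = obj$components$reg,
                     w_effort = w$effort, w_reg = w$reg),
    status = res$status, iterations = res$iterations,
    kkt = res$kkt, constraint_violation = res$cinf,
    duals = list(y = res$y, zl = res$zl, zu = res$zu),
    problem = problem), class = "gaitrec_result")
}

#' @export
print.gaitrec_result <- function(x, ...) {
  cat("gait reconstruction (", x$setup, ", N = ", x$N, ")\n", sep = "")
  cat(sprintf("  status: %s after %d iterations (max constraint violation %.2e)\n",
              x$status, x$iterations, x$constraint_violation))
  cat(sprintf("  speed %.3f m/s, cycle duration %.3f s, stride %.3f m\n",
              x$speed, x$duration, x$speed * x$duration))
  cat(sprintf("  objective %.6g (track %.4g, effort %.4g, reg %.4g)\n",
              x$objective$total, x$objective$track, x$objective$effort,
              x$objective$reg))
  invisible(x)
}

#' Per-foot ground reaction force trajectories of a result
#'
#' @param result a `gaitrec_result`.
#' @return list with matrices `right` and `left` (rows `fx`, `fy`, columns =
#'   nodes 1..N+1), in bodyweights.
#' @export
grf_trajectory <- function(result) {
  C <- result$contacts
  list(right = rbind(fx = C[3, ] + C[7, ], fy = C[4, ] + C[8, ]),
       left = rbind(fx = C[11, ] + C[15, ], fy = C[12, ] + C[16, ]))
}

# wrap a bare decision vector as a result-like list for grid interpolation
.z_to_pseudo <- function(z, prob) {
  st <- .ocp_unpack(z, prob)
  list(N = prob$N, q = st$Q, v = st$V, lce = st$LCEn * prob$lceopt,
       act = st$ACT, u = st$U, contacts = st$C,
       speed = st$speed, duration = st$T)
}

# interpolate a track set onto a different node count (periodic linear
# interpolation over cycle phase); used by the mesh continuation
.coarsen_tracks <- function(tracks, N2) {
  N1 <- tracks$N
  x1 <- (1:N1) / N1; x2 <- (1:N2) / N2
  xpad <- c(x1[N1] - 1, x1);
  out <- tracks
  out$N <- as.integer(N2)
  out$sensors <- lapply(tracks$sensors, function(s) {
    warp <- function(m) {
      m2 <- t(apply(m, 1L, function(row)
        stats::approx(xpad, c(row[N1], row), xout = x2)$y))
      rownames(m2) <- rownames(m)
      m2
    }
    list(mean = warp(s$mean), var = warp(s$var))
  })
  out
}

# virtual signals of a result at the N integration nodes (2..N+1), for a
# placement table; returns the named list format accepted by tracking_cost().
.result_signals <- function(result, placements, seg = result$problem$seg) {
  N <- result$N
  i2 <- 2:(N + 1L); i1 <- 1:N
  h <- result$duration / N
  Q2 <- result$q[, i2, drop = FALSE]
  V2 <- result$v[, i2, drop = FALSE]
  Av <- (V2 - result$v[, i1, drop = FALSE]) / h
  sig <- .virtual_signals_jac(Q2, V2, Av, placements, seg)
  out <- lapply(seq_len(nrow(placements)), function(i)
    list(a_x = sig[[i]]$ax, a_y = sig[[i]]$ay, omega_z = sig[[i]]$wz))
  names(out) <- placements$sensor
  out
}
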