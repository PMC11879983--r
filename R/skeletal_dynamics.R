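# Planar multibody layer: forward kinematics, point kinematics, the smooth
# foot-ground contact law, and the 18-row implicit multibody residual.
#
# Frame conventions: +x is the direction of progression, +y is up, gravity is
# (0, -9.81) m/s^2 and the ground is the line y = 0.  Generalized coordinates
# q = (pelvis x, pelvis y, trunk angle, R hip, R knee, R ankle, L hip, L knee,
# L ankle); hip flexion, knee flexion and ankle dorsiflexion are positive.

.SEGMENTS <- c("hat", "thigh_r", "shank_r", "foot_r", "thigh_l", "shank_l", "foot_l")

# signed selectors: absolute segment angle = sum(sel * q)
.PHI_SEL <- local({
  sel <- matrix(0, 7, 9, dimnames = list(.SEGMENTS, NULL))
  sel["hat", 3] <- 1
  sel["thigh_r", c(3, 4)] <- 1
  sel["shank_r", c(3, 4)] <- 1; sel["shank_r", 5] <- -1
  sel["foot_r", c(3, 4, 6)] <- 1; sel["foot_r", 5] <- -1
  sel["thigh_l", c(3, 7)] <- 1
  sel["shank_l", c(3, 7)] <- 1; sel["shank_l", 8] <- -1
  sel["foot_l", c(3, 7, 9)] <- 1; sel["foot_l", 8] <- -1
  sel
})

.rot2 <- function(phi, rx, ry) {
  c_ <- cos(phi); s_ <- sin(phi)
  list(x = c_ * rx - s_ * ry, y = s_ * rx + c_ * ry)
}

#' Forward kinematics of the 7-segment chain
#'
#' @param q generalized coordinates (length 9).
#' @param seg a [scale_segments()] object.
#' @return A list with per-segment origins and orientations, joint positions
#'   and the four contact-point positions (R heel, R toe, L heel, L toe).
#' @export
forward_kinematics <- function(q, seg) {
  stopifnot(length(q) == 9, all(is.finite(q)))
  p <- seg$p
  phi <- drop(.PHI_SEL %*% q)
  hip <- q[1:2]
  knee_r <- hip + unlist(.rot2(phi["thigh_r"], 0, -p$LTH))
  ank_r <- knee_r + unlist(.rot2(phi["shank_r"], 0, -p$LSH))
  knee_l <- hip + unlist(.rot2(phi["thigh_l"], 0, -p$LTH))
  ank_l <- knee_l + unlist(.rot2(phi["shank_l"], 0, -p$LSH))
  origins <- rbind(hat = hip, thigh_r = hip, shank_r = knee_r, foot_r = ank_r,
                   thigh_l = hip, shank_l = knee_l, foot_l = ank_l)
  cp <- rbind(
    heel_r = ank_r + unlist(.rot2(phi["foot_r"], p$hx, p$hy)),
    toe_r = ank_r + unlist(.rot2(phi["foot_r"], p$tx, p$ty)),
    heel_l = ank_l + unlist(.rot2(phi["foot_l"], p$hx, p$hy)),
    toe_l = ank_l + unlist(.rot2(phi["foot_l"], p$tx, p$ty)))
  colnames(origins) <- colnames(cp) <- c("x", "y")
  list(origins = origins, phi = phi,
       joints = rbind(hip = hip, knee_r = knee_r, ankle_r = ank_r,
                      knee_l = knee_l, ankle_l = ank_l),
       contact_points = cp)
}

#' Position, velocity and acceleration of a segment-fixed point
#'
#' @param q,v,a generalized coordinates, velocities and accelerations (9 each).
#' @param segment one of `"hat"`, `"thigh_r"`, `"shank_r"`, `"foot_r"`,
#'   `"thigh_l"`, `"shank_l"`, `"foot_l"`.
#' @param local point coordinates in the segment frame (origin at the proximal
#'   joint -- the ankle for the feet, the hip for HAT -- axes aligned with the
#'   global frame in the standing reference posture).
#' @param seg a [scale_segments()] object.
#' @return list(position, velocity, acceleration), each length 2.
#' @export
point_kinematics <- function(q, v, a, segment, local, seg) {
  if (!segment %in% .SEGMENTS) stop("unknown segment id: ", segment)
  p <- seg$p
  # walk the chain from the pelvis accumulating origin pos/vel/acc
  pos <- q[1:2]; vel <- v[1:2]; acc <- a[1:2]
  step <- function(state, phi_sel, rx, ry) {
    phi <- sum(phi_sel * q); w <- sum(phi_sel * v); al <- sum(phi_sel * a)
    r <- unlist(.rot2(phi, rx, ry))
    rp <- c(-r[2], r[1])                   # perp(r) = d r / d phi
    list(pos = state$pos + r,
         vel = state$vel + w * rp,
         acc = state$acc + al * rp - w^2 * r)
  }
  st <- list(pos = pos, vel = vel, acc = acc)
  chain <- switch(segment,
    hat = list(),
    thigh_r = list(), thigh_l = list(),
    shank_r = list(list("thigh_r", 0, -p$LTH)),
    shank_l = list(list("thigh_l", 0, -p$LTH)),
    foot_r = list(list("thigh_r", 0, -p$LTH), list("shank_r", 0, -p$LSH)),
    foot_l = list(list("thigh_l", 0, -p$LTH), list("shank_l", 0, -p$LSH)))
  for (lnk in chain) st <- step(st, .PHI_SEL[lnk[[1]], ], lnk[[2]], lnk[[3]])
  st <- step(st, .PHI_SEL[segment, ], local[1], local[2])
  list(position = unname(st$pos), velocity = unname(st$vel),
       acceleration = unname(st$acc))
}

#' Smooth penetration/friction contact force for one point
#'
#' Vertical force: `fy = clamp(k * softplus(-py) * (1 - damping * vy))`,
#' where softplus is `0.5 * (x + sqrt(x^2 + pen_smooth^2))` and the clamp is
#' the same smoothed positive part with scale `force_smooth`, keeping the
#' force non-negative (up to the documented smoothing floor) and infinitely
#' differentiable.  Horizontal force: `fx = -fy * friction * tanh(vx /
#' slip_vel)`, an odd, smoothed Coulomb law opposing slip.
#'
#' All arguments vectorize.
#'
#' @param py point height above ground (m; negative = penetration).
#' @param vx,vy point velocity components (m/s).
#' @param params a [default_contact_params()] list.
#' @param deriv if TRUE also return the partial derivatives of (fx, fy) with
#'   respect to (py, vx, vy).
#' @return list(fx, fy) plus derivative fields when `deriv = TRUE`.
#' @export
contact_force <- function(py, vx, vy, params = default_contact_params(),
                          deriv = FALSE) {
  k <- params$stiffness; cdamp <- params$damping; mu <- params$friction
  vs <- params$slip_vel; ep <- params$pen_smooth; ef <- params$force_smooth
  sp <- function(x, e) 0.5 * (x + sqrt(x^2 + e^2))
  dsp <- function(x, e) 0.5 * (1 + x / sqrt(x^2 + e^2))
  pen <- -py
  raw <- k * sp(pen, ep) * (1 - cdamp * vy)
  fy <- sp(raw, ef)
  th <- tanh(vx / vs)
  fx <- -fy * mu * th
  out <- list(fx = fx, fy = fy)
  if (deriv) {
    draw_py <- -k * dsp(pen, ep) * (1 - cdamp * vy)
    draw_vy <- -k * sp(pen, ep) * cdamp
    dfy <- dsp(raw, ef)
    out$dfy_py <- dfy * draw_py
    out$dfy_vy <- dfy * draw_vy
    out$dfy_vx <- 0 * fy
    dth <- (1 - th^2) / vs
    out$dfx_py <- -mu * th * out$dfy_py
    out$dfx_vy <- -mu * th * out$dfy_vy
    out$dfx_vx <- -fy * mu * dth
  }
  out
}

# first and second partial derivatives of the contact law with respect to
# (py, vx, vy); all arguments vectorize
.contact_force_d2 <- function(py, vx, vy, params) {
  k <- params$stiffness; cdamp <- params$damping; mu <- params$friction
  vs <- params$slip_vel; ep <- params$pen_smooth; ef <- params$force_smooth
  sp <- function(x, e) 0.5 * (x + sqrt(x^2 + e^2))
  dsp <- function(x, e) 0.5 * (1 + x / sqrt(x^2 + e^2))
  d2sp <- function(x, e) 0.5 * e^2 / sqrt(x^2 + e^2)^3
  pen <- -py
  dv <- 1 - cdamp * vy
  raw <- k * sp(pen, ep) * dv
  r_py <- -k * dsp(pen, ep) * dv
  r_vy <- -k * sp(pen, ep) * cdamp
  r_pypy <- k * d2sp(pen, ep) * dv
  r_pyvy <- k * dsp(pen, ep) * cdamp
  S1 <- dsp(raw, ef); S2 <- d2sp(raw, ef)
  fy <- sp(raw, ef)
  fy_py <- S1 * r_py
  fy_vy <- S1 * r_vy
  fy_pypy <- S2 * r_py^2 + S1 * r_pypy
  fy_pyvy <- S2 * r_py * r_vy + S1 * r_pyvy
  fy_vyvy <- S2 * r_vy^2
  th <- tanh(vx / vs); th1 <- (1 - th^2) / vs; th2 <- -2 * th * (1 - th^2) / vs^2
  fx <- -mu * fy * th
  list(fy = fy, fx = fx,
       fy_py = fy_py, fy_vy = fy_vy, fy_vx = 0 * fy,
       fx_py = -mu * th * fy_py, fx_vy = -mu * th * fy_vy, fx_vx = -mu * fy * th1,
       fy_pypy = fy_pypy, fy_pyvy = fy_pyvy, fy_vyvy = fy_vyvy,
       fy_pyvx = 0 * fy, fy_vxvx = 0 * fy, fy_vyvx = 0 * fy,
       fx_pypy = -mu * th * fy_pypy, fx_pyvy = -mu * th * fy_pyvy,
       fx_vyvy = -mu * th * fy_vyvy,
       fx_pyvx = -mu * th1 * fy_py, fx_vyvx = -mu * th1 * fy_vy,
       fx_vxvx = -mu * fy * th2)
}

#' Implicit multibody residual (18 rows)
#'
#' Rows 1-9 are the kinematic identity `qdot - v`; rows 10-18 are the implicit
#' equations of motion `d/dt(dT/dv) - dT/dq + dV/dq - Q = 0` with generalized
#' forces from the six joint moments and the four contact-point forces applied
#' at the model's kinematic point positions.  The residual is zero exactly when
#' the inputs satisfy the equations of motion.
#'
#' @param q,v,a coordinates, velocities, accelerations (9 each).
#' @param joint_moments 6 values (R hip, R knee, R ankle, L hip, L knee,
#'   L ankle), positive acting to increase the joint angle.
#' @param contacts data.frame/matrix with columns px, py, fx, fy and rows
#'   R heel, R toe, L heel, L toe (positions are carried for interface
#'   compatibility; forces are applied at the kinematic point locations).
#' @param seg a [scale_segments()] object.
#' @param qdot time derivative of q (defaults to v, making rows 1-9 zero).
#' @return numeric(18).
#' @export
multibody_residual <- function(q, v, a, joint_moments, contacts, seg, qdot = v) {
  stopifnot(length(q) == 9, length(v) == 9, length(a) == 9,
            length(joint_moments) == 6)
  contacts <- as.matrix(as.data.frame(contacts)[, c("px", "py", "fx", "fy")])
  if (nrow(contacts) != 4) stop("contacts must have 4 points")
  f <- as.numeric(t(contacts[, c("fx", "fy")]))  # fx1 fy1 fx2 fy2 ...
  eom <- .dyn_eom(matrix(q, 9, 1), matrix(v, 9, 1), matrix(a, 9, 1),
                  matrix(joint_moments, 6, 1), matrix(f, 8, 1), seg$p)
  c(qdot - v, drop(eom$res))
}

#' Per-foot ground reaction force
#'
#' Sums heel and toe contact forces per foot.
#'
#' @param contacts as in [multibody_residual()] (rows R heel, R toe, L heel,
#'   L toe).
#' @return A 2 x 2 matrix with rows `right`, `left` and columns `fx`, `fy` (N).
#' @export
grf_per_foot <- function(contacts) {
  contacts <- as.matrix(as.data.frame(contacts)[, c("fx", "fy")])
  if (nrow(contacts) != 4) stop("contacts must have 4 points")
  out <- rbind(right = colSums(contacts[1:2, , drop = FALSE]),
               left = colSums(contacts[3:4, , drop = FALSE]))
  colnames(out) <- c("fx", "fy")
  out
}
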