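# Three-element Hill-type muscle mechanics for the 16 muscles, in an implicit
# formulation: all residuals are smooth (C-infinity) in states and controls so
# the collocation NLP has exact analytic derivatives.
#
# Normalizations: CE length lce is divided by lceopt, CE velocity by
# vmax * lceopt, and forces by fmax; the contraction residual is the
# dimensionless series-elastic vs contractile+parallel force imbalance.

.HILL <- list(gmax = 1.5, kv = 12, umax = 0.04, wpee = 0.56,
              beta = 0.01, e_see = 0.002, e_pee = 0.01, k_act = 10)

.PASSIVE <- list(c = 2, s = 15, damping = 1.0,
                 qlo = c(-0.5, -0.05, -0.9, -0.5, -0.05, -0.9),
                 qhi = c(2.0, 2.3, 0.9, 2.0, 2.3, 0.9))

.softplus <- function(x, e) 0.5 * (x + sqrt(x^2 + e^2))
.dsoftplus <- function(x, e) 0.5 * (1 + x / sqrt(x^2 + e^2))
.d2softplus <- function(x, e) 0.5 * e^2 / sqrt(x^2 + e^2)^3

.fl <- function(l, w) exp(-((l - 1) / w)^2)
.dfl <- function(l, w) .fl(l, w) * (-2 * (l - 1) / w^2)
.d2fl <- function(l, w) .fl(l, w) * ((2 * (l - 1) / w^2)^2 - 2 / w^2)
.fv <- function(s) {
  g <- .HILL$gmax
  g / (1 + (g - 1) * exp(-.HILL$kv * s))
}
.dfv <- function(s) {
  fv <- .fv(s)
  .HILL$kv * fv * (1 - fv / .HILL$gmax)
}
.d2fv <- function(s) .HILL$kv * .dfv(s) * (1 - 2 * .fv(s) / .HILL$gmax)

# series-elastic force (N) and d/d lse, vectorized over muscles
.fsee <- function(lse, slack, fmax, deriv = FALSE, deriv2 = FALSE) {
  e <- (lse - slack) / slack
  u <- .softplus(e, .HILL$e_see) / .HILL$umax
  out <- list(f = fmax * u^2)
  if (deriv || deriv2) {
    du <- .dsoftplus(e, .HILL$e_see) / (.HILL$umax * slack)
    out$d_lse <- fmax * 2 * u * du
    if (deriv2) {
      d2u <- .d2softplus(e, .HILL$e_see) / (.HILL$umax * slack^2)
      out$d2_lse <- fmax * 2 * (du^2 + u * d2u)
    }
  }
  out
}

.fpee <- function(lnorm, fmax, lceopt, deriv = FALSE, deriv2 = FALSE) {
  u <- .softplus(lnorm - 1, .HILL$e_pee) / .HILL$wpee
  out <- list(f = fmax * u^2)
  if (deriv || deriv2) {
    du <- .dsoftplus(lnorm - 1, .HILL$e_pee) / .HILL$wpee
    out$d_lce <- fmax * 2 * u * du / lceopt
    if (deriv2) {
      d2u <- .d2softplus(lnorm - 1, .HILL$e_pee) / .HILL$wpee
      out$d2_lce <- fmax * 2 * (du^2 + u * d2u) / lceopt^2
    }
  }
  out
}

# second derivative of the passive joint-limit moment with respect to q
.passive_d2 <- function(qj) {
  pp <- .PASSIVE
  -pp$c * pp$s^2 * exp(pp$s * (qj - pp$qhi)) +
    pp$c * pp$s^2 * exp(-pp$s * (qj - pp$qlo))
}

#' Musculotendon length and moment arms
#'
#' With constant moment arms, `lMT(q) = slack + lceopt - sum_j d_j q_j` over
#' the spanned joints, so `d lMT / d q_j = -d_j` exactly.
#'
#' @param q generalized coordinates, a length-9 vector or a 9 x n matrix.
#' @param muscles a [default_muscle_table()] object.
#' @return list with `lmt` (16 x n matrix, m) and the 16 x 6 moment-arm
#'   matrix `arms` (m) over (R hip, R knee, R ankle, L hip, L knee, L ankle).
#' @export
musculotendon_length <- function(q, muscles = default_muscle_table()) {
  q <- as.matrix(q)
  if (nrow(q) != 9) stop("q must have 9 rows")
  qj <- q[4:9, , drop = FALSE]
  lmt <- matrix(muscles$table$lmt_ref, muscles$n, ncol(q)) - muscles$D %*% qj
  list(lmt = lmt, arms = muscles$D)
}

#' Activation dynamics residual
#'
#' First-order excitation-to-activation dynamics
#' `da/dt = (u - a) * r(u, a)` with rate `r` blending smoothly between
#' `1/tau_act` (when u > a) and `1/tau_deact` (when u < a) through a tanh
#' switch, so activation is faster than deactivation and the residual is
#' smooth.  Returns `act_rate - (u - act) * r`, one row per muscle.
#'
#' @param u excitations in `[0, 1]` (16 x n).
#' @param act activations in `[0, 1]` (16 x n).
#' @param act_rate activation time derivatives (16 x n).
#' @param muscles a [default_muscle_table()] object.
#' @export
activation_residual <- function(u, act, act_rate, muscles = default_muscle_table()) {
  m <- .activation_mech(as.matrix(u), as.matrix(act), as.matrix(act_rate), muscles)
  m$res
}

.activation_mech <- function(u, act, act_rate, muscles) {
  ta <- muscles$table$tau_act; td <- muscles$table$tau_deact
  kk <- .HILL$k_act
  d <- u - act
  s <- 0.5 + 0.5 * tanh(kk * d)
  ds <- 0.5 * kk * (1 - tanh(kk * d)^2)
  rate <- 1 / td + (1 / ta - 1 / td) * s
  drate <- (1 / ta - 1 / td) * ds
  res <- act_rate - d * rate
  list(res = res,
       d_u = -(rate + d * drate),
       d_act = rate + d * drate,
       d_rate = matrix(1, nrow(res), ncol(res)))
}

#' Contraction dynamics residual (implicit muscle-tendon equilibrium)
#'
#' Dimensionless force balance between the series-elastic element and the
#' contractile + parallel-elastic elements:
#' `F_SEE(lMT - lce)/fmax - act * fL(lce) * fV(dlce/dt) - F_PEE(lce)/fmax -
#' beta * vnorm`, where `fL` is a Gaussian force-length curve, `fV` a smooth
#' monotone force-velocity curve with eccentric plateau, and `beta` a small
#' damping making the residual solvable for the CE velocity at any activation.
#'
#' @param act activations (16 x n).
#' @param lce CE lengths, m (16 x n).
#' @param lce_rate CE velocities, m/s (16 x n).
#' @param lmt musculotendon lengths, m (16 x n), e.g. from
#'   [musculotendon_length()].
#' @param muscles a [default_muscle_table()] object.
#' @return 16 x n residual matrix.
#' @export
contraction_residual <- function(act, lce, lce_rate, lmt,
                                 muscles = default_muscle_table()) {
  m <- .contraction_mech(as.matrix(act), as.matrix(lce), as.matrix(lce_rate),
                         as.matrix(lmt), muscles)
  m$res
}

.contraction_mech <- function(act, lce, lce_rate, lmt, muscles, deriv = TRUE) {
  tb <- muscles$table
  lo <- tb$lceopt; fm <- tb$fmax; w <- tb$width; vm <- tb$vmax; sl <- tb$slack
  ln <- lce / lo
  vn <- lce_rate / (vm * lo)
  see <- .fsee(lmt - lce, sl, fm, deriv = deriv)
  pee <- .fpee(ln, fm, lo, deriv = deriv)
  fl <- .fl(ln, w); fv <- .fv(vn)
  res <- see$f / fm - act * fl * fv - pee$f / fm - .HILL$beta * vn
  out <- list(res = res, f_see = see$f)
  if (deriv) {
    dfl <- .dfl(ln, w) / lo
    out$d_act <- -fl * fv
    out$d_lce <- -see$d_lse / fm - act * dfl * fv - pee$d_lce / fm
    out$d_rate <- (-act * fl * .dfv(vn) - .HILL$beta) / (vm * lo)
    out$d_lmt <- see$d_lse / fm
  }
  out
}

#' Tendon (series-elastic) force
#'
#' Non-negative; zero for a slack tendon and equal to `fmax` at the reference
#' strain of the series-elastic curve (4% by default).
#'
#' @inheritParams contraction_residual
#' @return 16 x n matrix of forces (N).
#' @export
tendon_force <- function(lce, lmt, muscles = default_muscle_table()) {
  .fsee(as.matrix(lmt) - as.matrix(lce), muscles$table$slack,
        muscles$table$fmax)$f
}

#' Net joint moments from muscle and passive structures
#'
#' Sums tendon force times moment arm over the 16 muscles and adds smooth
#' exponential joint-limit moments plus light viscous joint damping (the
#' passive structures keep effort-minimal gaits from hyperextending joints).
#'
#' @param q,v generalized coordinates and velocities (9 each, or 9 x n).
#' @param lce CE lengths (16 x n).
#' @param muscles a [default_muscle_table()] object.
#' @param include_passive include passive joint-limit and damping moments.
#' @return 6 x n matrix (N m): R hip, R knee, R ankle, L hip, L knee, L ankle,
#'   positive acting to increase the joint angle.
#' @export
joint_moments <- function(q, v, lce, muscles = default_muscle_table(),
                          include_passive = TRUE) {
  m <- .moments_mech(as.matrix(q), as.matrix(v), as.matrix(lce), muscles,
                     include_passive, deriv = FALSE)
  m$tau
}

.passive_mech <- function(qj, vj, deriv = TRUE) {
  pp <- .PASSIVE
  e_hi <- exp(pp$s * (qj - pp$qhi)); e_lo <- exp(-pp$s * (qj - pp$qlo))
  tau <- -pp$c * e_hi + pp$c * e_lo - pp$damping * vj
  out <- list(tau = tau)
  if (deriv) {
    out$d_q <- -pp$c * pp$s * e_hi - pp$c * pp$s * e_lo
    out$d_v <- -pp$damping + 0 * vj
  }
  out
}

.moments_mech <- function(q, v, lce, muscles, include_passive = TRUE, deriv = TRUE) {
  n <- ncol(q)
  mt <- musculotendon_length(q, muscles)
  see <- .fsee(mt$lmt - lce, muscles$table$slack, muscles$table$fmax, deriv = deriv)
  tau <- t(muscles$D) %*% see$f                    # 6 x n
  out <- list(tau = tau, force = see$f)
  if (deriv) out$d_lse <- see$d_lse   # dF_m/d lse; dF/dlmt = +d_lse, dF/dlce = -d_lse
  if (include_passive) {
    ps <- .passive_mech(q[4:9, , drop = FALSE], v[4:9, , drop = FALSE], deriv = deriv)
    out$tau <- out$tau + ps$tau
    out$passive <- ps
  }
  out
}
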