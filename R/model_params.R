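#' @importFrom stats rnorm sd var setNames cov
#' @importFrom utils read.csv write.csv modifyList
NULL

.param_csv <- function(name) {
  path <- system.file("extdata", "params", name, package = "gaitrec")
  if (!nzchar(path)) stop("parameter file not found: ", name)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Subject descriptor
#'
#' Minimal anthropometric description used to personalize the model.
#'
#' @param height body height in m.
#' @param mass body mass in kg.
#' @return An object of class `gaitrec_subject`.
#' @export
subject_descriptor <- function(height, mass) {
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("invalid subject: height must be a positive number (m)")
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("invalid subject: mass must be a positive number (kg)")
  structure(list(height = height, mass = mass), class = "gaitrec_subject")
}

#' Scale the 7-segment skeleton to a subject
#'
#' Applies published anthropometric fractions (Winter-style regression table,
#' shipped as `extdata/params/segment_fractions.csv`) to a subject's height and
#' mass.  Segment masses are scaled proportionally to body mass with the
#' head-arms-trunk (HAT) segment absorbing the remainder, so the segment masses
#' sum to the subject mass exactly.  Lengths scale proportionally to height;
#' moments of inertia use the tabulated radii of gyration.
#'
#' The foot is a rigid segment with heel and toe contact offsets expressed in
#' the foot frame (origin at the ankle): the sole lies at the tabulated ankle
#' height below the ankle, the heel 25% of foot length behind it and the toe
#' 75% ahead.
#'
#' @param subject a [subject_descriptor()].
#' @return A list of class `gaitrec_segments` with elements `segments` (a
#'   data.frame of the 7 segments with mass, length, com offset and inertia),
#'   `p` (the flat parameter list consumed by the dynamics kernels), and
#'   `subject`.
#' @export
scale_segments <- function(subject) {
  if (!inherits(subject, "gaitrec_subject")) subject <- do.call(subject_descriptor, as.list(subject))
  H <- subject$height; M <- subject$mass
  fr <- .param_csv("segment_fractions.csv")
  row <- function(s) fr[fr$segment == s, ]
  th <- row("thigh"); sh <- row("shank"); ft <- row("foot"); hat <- row("HAT")

  m_th <- th$mass_frac * M; m_sh <- sh$mass_frac * M; m_ft <- ft$mass_frac * M
  m_hat <- M - 2 * (m_th + m_sh + m_ft)   # remainder: mass conservation exact
  L_th <- th$length_frac * H; L_sh <- sh$length_frac * H
  L_ft <- ft$length_frac * H; L_hat <- hat$length_frac * H
  ankle_h <- 0.039 * H

  seg <- data.frame(
    segment = c("HAT", "thigh_r", "thigh_l", "shank_r", "shank_l", "foot_r", "foot_l"),
    mass = c(m_hat, m_th, m_th, m_sh, m_sh, m_ft, m_ft),
    length = c(L_hat, L_th, L_th, L_sh, L_sh, L_ft, L_ft),
    com_offset = c(hat$com_frac * L_hat, rep(th$com_frac * L_th, 2),
                   rep(sh$com_frac * L_sh, 2), rep(ft$com_frac * L_ft, 2)),
    inertia = c(m_hat * (hat$rog_frac * L_hat)^2,
                rep(m_th * (th$rog_frac * L_th)^2, 2),
                rep(m_sh * (sh$rog_frac * L_sh)^2, 2),
                rep(m_ft * (ft$rog_frac * L_ft)^2, 2)))

  p <- list(mHAT = m_hat, mTH = m_th, mSH = m_sh, mFT = m_ft,
            IHAT = seg$inertia[1], ITH = seg$inertia[2], ISH = seg$inertia[4],
            IFT = seg$inertia[6],
            cHAT = seg$com_offset[1], LTH = L_th, cTH = seg$com_offset[2],
            LSH = L_sh, cSH = seg$com_offset[4],
            fcx = 0.25 * L_ft, fcy = -0.5 * ankle_h,
            hx = -0.25 * L_ft, hy = -ankle_h,
            tx = 0.75 * L_ft, ty = -ankle_h,
            grav = 9.81)

  structure(list(segments = seg, p = p, subject = subject,
                 leg_length = L_th + L_sh + ankle_h, foot_length = L_ft,
                 ankle_height = ankle_h),
            class = "gaitrec_segments")
}

#' Default Hill-type muscle table
#'
#' Returns the 16-muscle parameter table (8 per leg, right then left) used by
#' the muscle dynamics: maximal isometric force, optimal contractile-element
#' length, force-length width, maximal shortening velocity, series-elastic
#' slack length, activation/deactivation time constants, and constant moment
#' arms for the spanned joints.  The left-leg block mirrors the right one.
#'
#' The musculotendon reference length at the reference (standing) posture is
#' `slack + lceopt`, so `lMT(q) = slack + lceopt - sum(d_j * q_j)` over the
#' spanned joints with the package's angle conventions (hip flexion, knee
#' flexion and ankle dorsiflexion positive).
#'
#' @return A list of class `gaitrec_muscles` with the per-muscle data.frame
#'   `table` (16 rows) and the 16 x 6 moment-arm matrix `D` over the joint
#'   order (R hip, R knee, R ankle, L hip, L knee, L ankle).
#' @export
default_muscle_table <- function() {
  base <- .param_csv("muscles.csv")
  mk <- function(side) {
    d <- base
    d$name <- paste(d$name, side, sep = "_")
    d$side <- side
    d
  }
  tab <- rbind(mk("r"), mk("l"))
  D <- matrix(0, nrow(tab), 6,
              dimnames = list(tab$name,
                              c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")))
  right <- tab$side == "r"
  D[right, 1:3] <- as.matrix(base[, c("d_hip", "d_knee", "d_ankle")])
  D[!right, 4:6] <- as.matrix(base[, c("d_hip", "d_knee", "d_ankle")])
  tab$lmt_ref <- tab$slack + tab$lceopt
  structure(list(table = tab, D = D, n = nrow(tab)), class = "gaitrec_muscles")
}

#' Default foot-ground contact parameters
#'
#' Penetration-based vertical force with velocity damping and a smoothed
#' Coulomb friction law for the horizontal force, applied at two contact
#' points per foot (heel and toe).  All smoothing scales are strictly
#' positive so the contact force is infinitely differentiable.
#'
#' @return A named list of class `gaitrec_contact`.
#' @export
default_contact_params <- function() {
  d <- .param_csv("contact.csv")
  par <- as.list(setNames(d$value, d$parameter))
  stopifnot(all(unlist(par) > 0))
  structure(par, class = "gaitrec_contact")
}
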