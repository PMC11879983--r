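# Virtual sagittal-plane IMU model: a sensor fixed to a segment measures the
# planar angular velocity of its host segment (gyroscope, omega_z) and the
# specific force at the sensor point (accelerometer): the point acceleration
# minus gravity, expressed in the sensor frame.  Sensor frames are aligned
# with their segment frame, so a sensor at rest reads +1 g on its vertical
# channel, exactly like a physical accelerometer.

.SETUP_SEGMENTS <- list(
  F    = c("foot_r", "foot_l"),
  FP   = c("foot_r", "foot_l", "pelvis"),
  FS   = c("foot_r", "foot_l", "shank_r", "shank_l"),
  FT   = c("foot_r", "foot_l", "thigh_r", "thigh_l"),
  FSP  = c("foot_r", "foot_l", "shank_r", "shank_l", "pelvis"),
  FTP  = c("foot_r", "foot_l", "thigh_r", "thigh_l", "pelvis"),
  FSTP = c("foot_r", "foot_l", "shank_r", "shank_l", "thigh_r", "thigh_l", "pelvis"))

#' Catalog of the seven sensor setups
#'
#' Setups are named by the first letters of the instrumented segments
#' (F feet, S shanks, T thighs, P pelvis); every setup includes both feet and
#' is left/right symmetric.  `FSTP` is the full lower-body setup with seven
#' sensors.
#'
#' @return Named list; each element has `name` and the character vector
#'   `sensors` of sensor ids.
#' @export
setup_catalog <- function() {
  lapply(.SETUP_SEGMENTS, function(s) list(name = names(which(vapply(
    .SETUP_SEGMENTS, identical, logical(1), s))), sensors = s))
}

#' Resolve default sensor placements for a setup
#'
#' Default local positions (segment frame, origin at the proximal joint or the
#' ankle for the feet): pelvis sensor on the posterior HAT just above the hip;
#' thigh and shank sensors anterior at 45% segment length; foot sensors on the
#' instep slightly anterior and above the ankle.  Positions are overridable by
#' supplying `local` columns.
#'
#' @param setup setup name, one of `r paste(names(.SETUP_SEGMENTS), collapse = ", ")`.
#' @param seg a [scale_segments()] object (placements scale with the subject).
#' @return data.frame with columns sensor, segment, rx, ry (m).
#' @export
sensor_placements <- function(setup, seg) {
  if (!setup %in% names(.SETUP_SEGMENTS)) stop("unknown setup: ", setup)
  sensors <- .SETUP_SEGMENTS[[setup]]
  p <- seg$p
  loc <- list(
    pelvis = c("hat", -0.08, 0.10),
    thigh_r = c("thigh_r", 0.03, -0.45 * p$LTH),
    thigh_l = c("thigh_l", 0.03, -0.45 * p$LTH),
    shank_r = c("shank_r", 0.03, -0.45 * p$LSH),
    shank_l = c("shank_l", 0.03, -0.45 * p$LSH),
    foot_r = c("foot_r", 0.05, 0.02),
    foot_l = c("foot_l", 0.05, 0.02))
  out <- do.call(rbind, lapply(sensors, function(s) {
    e <- loc[[s]]
    data.frame(sensor = s, segment = e[[1]], rx = as.numeric(e[[2]]),
               ry = as.numeric(e[[3]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$sensor
  out
}

#' Virtual accelerometer and gyroscope signals for one sensor
#'
#' @param q,v,a generalized coordinates, velocities and accelerations; length-9
#'   vectors or 9 x n matrices (columns = time nodes).
#' @param segment host segment (`"hat"` for a pelvis sensor, or thigh/shank/
#'   foot left/right).
#' @param local sensor position in the segment frame (2 values, m).
#' @param seg a [scale_segments()] object.
#' @return list with numeric vectors `a_x`, `a_y` (specific force in the
#'   sensor frame, m/s^2) and `omega_z` (rad/s), one value per column.
#' @export
virtual_signals <- function(q, v, a, segment, local, seg) {
  if (!segment %in% .SEGMENTS) stop("unknown segment id: ", segment)
  q <- as.matrix(q); v <- as.matrix(v); a <- as.matrix(a)
  o <- .dyn_imu_fns[[segment]](q, v, a, local[1], local[2], seg$p)
  list(a_x = o$ax, a_y = o$ay, omega_z = o$wz)
}

# all sensors of a placement table at once, with Jacobians for the NLP.
# Returns a list per sensor of the raw .dyn_imu_* output.
.virtual_signals_jac <- function(q, v, a, placements, seg) {
  lapply(seq_len(nrow(placements)), function(i) {
    pl <- placements[i, ]
    .dyn_imu_fns[[pl$segment]](q, v, a, pl$rx, pl$ry, seg$p)
  })
}
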