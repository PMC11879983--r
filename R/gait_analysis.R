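# Spatiotemporal variables and waveform comparison metrics: stance detection
# on the vertical GRF, stride/speed from the right-heel translation, RMSD,
# the linear-fit-method coefficient of determination, Fisher-Z averaging of
# R^2 values, the relationship categories, and bodyweight/bodyheight
# normalization of kinetics.

#' Detect the stance phase from a vertical GRF trajectory
#'
#' Stance is the maximal circular run of nodes whose vertical GRF is at or
#' above the threshold (default 0.05 bodyweights).  For walking, cycles are
#' conventionally windowed heel-strike to heel-strike, for running toe-off to
#' toe-off; the returned `start` index is the first loaded node of the
#' maximal run in the cycle's own windowing.
#'
#' @param grf_y vertical GRF per node (BW), one periodic cycle.
#' @param threshold load threshold (BW).
#' @return list(indices, start, end, fraction) -- node indices of stance, the
#'   circular run boundaries and the stance fraction of the cycle.
#' @export
detect_stance <- function(grf_y, threshold = 0.05) {
  n <- length(grf_y)
  loaded <- grf_y >= threshold
  if (!any(loaded)) stop("no stance: threshold ", threshold,
                         " BW above the maximal vertical GRF")
  if (all(loaded))
    return(list(indices = seq_len(n), start = 1L, end = n, fraction = 1))
  # longest circular run of TRUE: unroll twice, cap run length at n
  x <- c(loaded, loaded)
  best_len <- 0L; best_end <- 0L; cur <- 0L
  for (i in seq_along(x)) {
    cur <- if (x[i]) cur + 1L else 0L
    if (cur > best_len && i <= n + cur - 1L) { best_len <- min(cur, n); best_end <- i }
  }
  start <- ((best_end - best_len) %% n) + 1L
  idx <- ((start - 1L + 0:(best_len - 1L)) %% n) + 1L
  list(indices = idx, start = start, end = ((start + best_len - 2L) %% n) + 1L,
       fraction = best_len / n)
}

#' Spatiotemporal variables of a reconstruction
#'
#' Stride length is the horizontal translation of the right heel over the
#' cycle (equal to `speed * duration` by the periodicity constraint), speed is
#' stride over duration, and stance time/fraction come from [detect_stance()]
#' on the right-foot vertical GRF.
#'
#' @param result a `gaitrec_result`.
#' @param threshold stance threshold (BW).
#' @return list(speed, stride_length, stance_time, stance_fraction), SI units.
#' @export
spatiotemporal <- function(result, threshold = 0.05) {
  C <- result$contacts
  stride <- C[1, ncol(C)] - C[1, 1]          # right heel horizontal translation
  speed <- stride / result$duration
  fy_r <- grf_trajectory(result)$right["fy", -1L]   # the N integration nodes
  stance <- detect_stance(fy_r, threshold)
  list(speed = speed, stride_length = stride,
       stance_time = stance$fraction * result$duration,
       stance_fraction = stance$fraction)
}

#' Root mean square deviation between two waveforms
#'
#' @param sim,ref equal-length numeric vectors.
#' @param window optional index vector restricting the comparison (e.g. the
#'   stance nodes for kinetic variables).
#' @export
rmsd <- function(sim, ref, window = NULL) {
  if (length(sim) != length(ref)) stop("trajectories differ in length")
  if (!is.null(window)) { sim <- sim[window]; ref <- ref[window] }
  if (length(sim) == 0L) stop("empty comparison window")
  sqrt(mean((sim - ref)^2))
}

#' Linear-fit-method coefficient of determination
#'
#' Least-squares fit of `a * ref + b` to `sim`; returns the coefficient of
#' determination of that fit, i.e. the squared correlation.  Errors on a
#' constant reference (undefined fit); returns 0 when the simulated waveform
#' carries no variance or is orthogonal to the reference.
#'
#' @param sim estimated waveform (response).
#' @param ref reference waveform (regressor).
#' @export
lfm_r2 <- function(sim, ref) {
  if (length(sim) != length(ref)) stop("trajectories differ in length")
  vref <- stats::var(ref)
  if (!is.finite(vref) || vref <= .Machine$double.eps * max(1, mean(ref)^2))
    stop("undefined fit: constant reference waveform")
  vsim <- stats::var(sim)
  if (vsim == 0) return(0)
  (stats::cov(sim, ref))^2 / (vsim * vref)
}

#' Fisher-Z mean of coefficients of determination
#'
#' Averages the square roots of R^2 values through the Fisher Z-transform:
#' `r_i = sqrt(R2_i)`, `zbar = mean(atanh(r_i))`, returning `tanh(zbar)^2`.
#' Values numerically at 1 are clamped just below (atanh(1) is infinite).
#'
#' @param r2 vector of values in `[0, 1]`.
#' @export
fisher_mean <- function(r2) {
  if (any(r2 < 0 | r2 > 1)) stop("R^2 values must lie in [0, 1]")
  r <- sqrt(pmin(r2, 1 - 1e-12))
  tanh(mean(atanh(r)))^2
}

#' Categorize an R^2 relationship
#'
#' Strong above 0.7, moderate above 0.5, weak above 0.3, otherwise none;
#' boundary values fall in the lower category.
#'
#' @param r2 vector of values in `[0, 1]`.
#' @return character vector of categories.
#' @export
classify <- function(r2) {
  if (any(r2 < 0 | r2 > 1)) stop("R^2 values must lie in [0, 1]")
  out <- rep("none", length(r2))
  out[r2 > 0.3] <- "weak"
  out[r2 > 0.5] <- "moderate"
  out[r2 > 0.7] <- "strong"
  out
}

#' Normalize kinetic variables to bodyweight (and bodyheight)
#'
#' Joint moments are scaled to bodyweight-bodyheight percent
#' (`100 * M / (mass * 9.81 * height)`), ground reaction forces to
#' bodyweights (`F / (mass * 9.81)`).
#'
#' @param moments joint moments (N m), any shape.
#' @param grf ground reaction forces (N), any shape.
#' @param subject a [subject_descriptor()].
#' @return list(moments_bwbh, grf_bw) matching the input shapes.
#' @export
normalize_kinetics <- function(moments, grf, subject) {
  if (!inherits(subject, "gaitrec_subject"))
    subject <- do.call(subject_descriptor, as.list(subject))
  bw <- subject$mass * 9.81
  list(moments_bwbh = 100 * moments / (bw * subject$height),
       grf_bw = grf / bw)
}
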