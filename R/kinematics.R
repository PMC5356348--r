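# Movement-time extraction from fingertip position traces: 5 Hz
# second-order Butterworth smoothing, speed from the first derivative of
# position, MT between the 5%-of-peak-speed onset and the first
# at-or-after-peak sample where speed drops below 5% of peak while the
# fingertip is inside the target disk.

# Validate a trajectory table and return its sampling rate. Requires
# uniform sampling (1e-6 s tolerance) and at least 3 samples.
traj_sample_rate <- function(traj) {
  if (!is.data.frame(traj) || !all(c("t_s", "x_cm", "y_cm") %in% names(traj))) {
    stop("trajectory must be a data frame with columns t_s, x_cm, y_cm",
         call. = FALSE)
  }
  if (nrow(traj) < 3L) stop("trajectory needs >= 3 samples", call. = FALSE)
  dt <- diff(traj$t_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6) {
    stop("trajectory must be uniformly sampled in increasing time",
         call. = FALSE)
  }
  1 / mean(dt)
}

#' Target geometry
#'
#' @param x,y Target centre (cm).
#' @param diameter Target diameter (cm), default 3 (the training-target
#'   size).
#' @return A `target_spec` list with `x`, `y`, `radius`.
#' @export
target_spec <- function(x, y, diameter = 3) {
  if (diameter <= 0) stop("`diameter` must be > 0", call. = FALSE)
  structure(list(x = x, y = y, radius = diameter / 2), class = "target_spec")
}

#' Low-pass filter a trajectory
#'
#' Second-order Butterworth filter at `cutoff` Hz applied to the x and y
#' channels. By default the filter is run forward and backward
#' (zero-phase), so threshold-crossing times are not lagged; `zero_phase =
#' FALSE` gives the plain causal filter.
#'
#' @param traj Trajectory data frame (`t_s`, `x_cm`, `y_cm`), uniformly
#'   sampled.
#' @param cutoff Cutoff frequency in Hz (default 5); must be below the
#'   Nyquist frequency.
#' @param zero_phase Apply forward-backward filtering (default `TRUE`)?
#' @return The trajectory with filtered `x_cm`, `y_cm` (same length).
#' @export
lowpass_filter <- function(traj, cutoff = 5, zero_phase = TRUE) {
  fs <- traj_sample_rate(traj)
  if (cutoff >= fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  n <- nrow(traj)
  # odd-reflection padding so the filter's edge transients (it assumes
  # zero signal outside the record) fall on the pads, not the data
  npad <- min(n - 1L, max(12L, 3L * ceiling(fs / cutoff)))
  run <- function(z) {
    front <- 2 * z[1L] - z[(npad + 1L):2L]
    back <- 2 * z[n] - z[(n - 1L):(n - npad)]
    zp <- c(front, z, back)
    out <- if (zero_phase) signal::filtfilt(bf, zp)
      else as.numeric(signal::filter(bf, zp))
    out[(npad + 1L):(npad + n)]
  }
  traj$x_cm <- run(traj$x_cm)
  traj$y_cm <- run(traj$y_cm)
  traj
}

#' Planar fingertip speed
#'
#' Componentwise first derivative of position (central differences at
#' interior samples, one-sided at the endpoints), combined as the
#' Euclidean norm.
#'
#' @inheritParams lowpass_filter
#' @param method `"central"` (default) or `"forward"` first differences
#'   (forward repeats the last value to preserve length).
#' @return Numeric vector of speeds (cm/s), one per sample.
#' @export
compute_speed <- function(traj, method = c("central", "forward")) {
  method <- match.arg(method)
  fs <- traj_sample_rate(traj)
  deriv <- function(z) {
    n <- length(z)
    if (method == "central") {
      d <- c(z[2L] - z[1L],
             (z[3:n] - z[1:(n - 2L)]) / 2,
             z[n] - z[n - 1L])
    } else {
      d <- c(diff(z), z[n] - z[n - 1L])
    }
    d * fs
  }
  sqrt(deriv(traj$x_cm)^2 + deriv(traj$y_cm)^2)
}

#' Extract movement time from a trajectory
#'
#' Onset is the first sample whose speed exceeds 5% of the trace's peak
#' speed; offset is the first sample at or after the peak whose speed is
#' below that threshold while the fingertip lies inside the target disk.
#' The offset search starts at the peak so sub-threshold jitter before the
#' movement cannot terminate it early. Movement time is the onset-offset
#' interval in ms; movements longer than 5000 ms are flagged as timeouts.
#'
#' @inheritParams lowpass_filter
#' @param target A [target_spec()].
#' @param threshold Speed threshold as a fraction of peak speed (default
#'   0.05).
#' @param speed Optional precomputed speed vector (else
#'   [compute_speed()] is used).
#' @return A `movement_segment` list: `onset_s`, `offset_s`, `mt_ms`,
#'   `peak_speed`, `timeout`.
#' @export
extract_movement_time <- function(traj, target, threshold = 0.05,
                                  speed = NULL) {
  stopifnot(inherits(target, "target_spec"))
  if (is.null(speed)) speed <- compute_speed(traj)
  peak <- max(speed)
  if (!is.finite(peak) || peak <= 0) {
    stop("no movement: peak speed is zero", call. = FALSE)
  }
  thr <- threshold * peak
  onset_i <- which(speed > thr)[1L]
  peak_i <- which.max(speed)
  dist2 <- (traj$x_cm - target$x)^2 + (traj$y_cm - target$y)^2
  candidates <- which(seq_along(speed) >= peak_i &
                        speed < thr &
                        dist2 <= target$radius^2)
  if (length(candidates) == 0L) {
    stop("target never acquired: speed never fell below threshold inside ",
         "the target disk", call. = FALSE)
  }
  offset_i <- candidates[1L]
  mt <- (traj$t_s[offset_i] - traj$t_s[onset_i]) * 1000
  structure(list(
    onset_s = traj$t_s[onset_i], offset_s = traj$t_s[offset_i],
    mt_ms = mt, peak_speed = peak, timeout = mt > 5000
  ), class = "movement_segment")
}

#' Mirror left-hemiparesis records onto the right-side frame
#'
#' So that all subjects can be analysed in one frame, records from
#' left-hemiparesis subjects are "flipped" left-to-right: target `k`
#' becomes `n_targets + 1 - k`, and any trajectory x coordinate is
#' mirrored about the home-position sagittal axis. Right-side records pass
#' through unchanged. The flip is an involution and leaves MT values
#' untouched.
#'
#' @param records Trial-record data frame with a `target` column (and
#'   optionally `x_cm` for trajectory rows).
#' @param side Side label(s), `"left"` or `"right"`: a scalar or one per
#'   row. Defaults to `records$side` when present.
#' @param n_targets Number of targets in the array (default 5).
#' @param home_x x coordinate of the home-position sagittal axis (cm),
#'   used only when mirroring trajectory coordinates.
#' @return `records` with left-side rows remapped.
#' @export
flip_left_hemiparesis <- function(records, side = NULL, n_targets = 5L,
                                  home_x = 0) {
  side <- side %||% records$side
  if (is.null(side)) stop("no `side` given and no `side` column present",
                          call. = FALSE)
  side <- rep_len(as.character(side), nrow(records))
  if (!all(side %in% c("left", "right"))) {
    stop("`side` labels must be \"left\" or \"right\"", call. = FALSE)
  }
  left <- side == "left"
  if (!is.null(records$target)) {
    records$target[left] <- n_targets + 1L - records$target[left]
  }
  if (!is.null(records$x_cm)) {
    records$x_cm[left] <- 2 * home_x - records$x_cm[left]
  }
  records
}

#' Extract movement times for a batch of trajectories
#'
#' Convenience wrapper running [lowpass_filter()] then
#' [extract_movement_time()] over a list of trajectories.
#'
#' @param trajs Named list of trajectory data frames.
#' @param targets List of [target_spec()]s, one per trajectory (recycled
#'   if length 1).
#' @param cutoff Butterworth cutoff in Hz; `NULL` skips filtering.
#' @return Data frame with one row per trajectory: `trial`, `mt_ms`,
#'   `onset_s`, `offset_s`, `peak_speed`, `timeout`.
#' @export
extract_mt_batch <- function(trajs, targets, cutoff = 5) {
  if (inherits(targets, "target_spec")) targets <- list(targets)
  targets <- rep_len(targets, length(trajs))
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    if (!is.null(cutoff)) tr <- lowpass_filter(tr, cutoff)
    seg <- extract_movement_time(tr, targets[[i]])
    data.frame(trial = i, mt_ms = seg$mt_ms, onset_s = seg$onset_s,
               offset_s = seg$offset_s, peak_speed = seg$peak_speed,
               timeout = seg$timeout)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(trajs))) out$trial <- names(trajs)
  out
}
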