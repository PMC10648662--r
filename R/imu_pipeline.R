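# IMU processing chain: calibration, quiet-period detection, bias removal,
# dual-range saturation fusion, zero-phase Butterworth filtering, Madgwick
# orientation estimation with gravity removal, segment (SCS) and
# tilt-corrected (TCCS) coordinate construction, and stance windowing.
#
# Frame conventions (all right-handed): sensor/WCS +x anteroposterior,
# +y longitudinal (up during quiet standing), +z right; the inertial frame
# keeps +y vertical.

#' Construct a raw IMU recording
#'
#' @param time time base in seconds (uniform).
#' @param primary n x 3 primary accelerometer matrix (g, +/-16 g range).
#' @param secondary n x 3 secondary accelerometer matrix (g, +/-100 g
#'   range); defaults to the primary channels.
#' @param gyro n x 3 gyroscope matrix (rad/s).
#' @param placement placement tag ("shank", "hip", "sacrum", ...).
#' @param calibration optional list with `accel` and `gyro` entries, each
#'   `list(A = 3x3 matrix, b = length-3 offset)`.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(time, primary, secondary = primary, gyro,
                          placement = "sacrum", calibration = NULL) {
  primary <- as.matrix(primary); secondary <- as.matrix(secondary)
  gyro <- as.matrix(gyro)
  n <- length(time)
  if (nrow(primary) != n || nrow(secondary) != n || nrow(gyro) != n) {
    stop("all channels must share the time base")
  }
  if (ncol(primary) != 3 || ncol(secondary) != 3 || ncol(gyro) != 3) {
    stop("channels must have 3 axes")
  }
  fs <- 1 / stats::median(diff(time))
  structure(list(time = time, primary = primary, secondary = secondary,
                 gyro = gyro, placement = placement,
                 calibration = calibration, fs = fs, calibrated = FALSE),
            class = "imu_recording")
}

apply_affine <- function(x, cal) {
  A <- as.matrix(cal$A)
  b <- cal$b %||% rep(0, 3)
  if (!all(dim(A) == c(3, 3)) || length(b) != 3) {
    stop("calibration shape mismatch: need a 3x3 matrix and length-3 offset")
  }
  sweep(x %*% t(A), 2, b, "+")
}

#' Apply per-channel affine calibration matrices
#'
#' @param rec an [imu_recording()] whose `calibration` field (or the
#'   `calibration` argument) supplies `accel` and/or `gyro` affine maps.
#' @param calibration optional calibration overriding the recording's own.
#' @return the recording with calibrated channels and `calibrated = TRUE`.
#' @export
apply_calibration <- function(rec, calibration = NULL) {
  cal <- calibration %||% rec$calibration
  if (is.null(cal)) {
    rec$calibrated <- TRUE
    return(rec)
  }
  if (!is.null(cal$accel)) {
    rec$primary <- apply_affine(rec$primary, cal$accel)
    rec$secondary <- apply_affine(rec$secondary, cal$accel)
  }
  if (!is.null(cal$gyro)) rec$gyro <- apply_affine(rec$gyro, cal$gyro)
  rec$calibrated <- TRUE
  rec
}

#' Detect quiet periods from gyroscope and accelerometer magnitudes
#'
#' A quiet period is a maximal run where the angular-velocity magnitude
#' stays below `omega_thresh` and the jerk magnitude (time derivative of
#' the acceleration magnitude, in m/s^3) stays below `jerk_thresh`, for at
#' least `min_duration` seconds. Jerk is computed on the raw magnitude by
#' default; `smooth_cutoff` optionally low-passes the magnitude first.
#'
#' @param gyro n x 3 gyroscope matrix (rad/s).
#' @param accel n x 3 accelerometer matrix (g).
#' @param fs sampling rate (Hz).
#' @param omega_thresh angular-velocity threshold (rad/s), default 0.5.
#' @param jerk_thresh jerk threshold (m/s^3), default 0.01.
#' @param min_duration minimum quiet duration (s), default 0.1.
#' @param smooth_cutoff optional low-pass cutoff (Hz) applied to the
#'   acceleration magnitude before differentiation.
#' @return data.frame with columns `start`, `end` (1-based, half-open); zero
#'   rows when no quiet period exists.
#' @export
detect_quiet_periods <- function(gyro, accel, fs = 1000,
                                 omega_thresh = 0.5, jerk_thresh = 0.01,
                                 min_duration = 0.1, smooth_cutoff = NULL) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  if (nrow(gyro) != nrow(accel)) stop("signals must share the time base")
  omega <- sqrt(rowSums(gyro^2))
  amag <- sqrt(rowSums(accel^2)) * GRAVITY
  if (!is.null(smooth_cutoff)) amag <- lowpass_filter(amag, fs, smooth_cutoff)
  jerk <- c(0, diff(amag) * fs)
  jerk[1] <- jerk[2]
  quiet <- omega < omega_thresh & abs(jerk) < jerk_thresh
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(min_duration * fs)
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Remove sensor biases using a quiet period
#'
#' Gyroscope bias is the mean over the quiet range, subtracted from the
#' whole series. Accelerometer bias is the deviation of the quiet-range
#' mean magnitude from 1 g, removed along the quiet gravity direction.
#'
#' @param rec an [imu_recording()].
#' @param quiet_ranges data.frame from [detect_quiet_periods()]; the first
#'   range is used.
#' @return the bias-corrected recording.
#' @export
remove_bias <- function(rec, quiet_ranges) {
  if (is.null(quiet_ranges) || nrow(quiet_ranges) == 0) {
    stop("no quiet period available: cannot remove biases; ",
         "record a quiet-standing segment or pass explicit ranges")
  }
  idx <- quiet_ranges$start[1]:(quiet_ranges$end[1] - 1)
  gbias <- colMeans(rec$gyro[idx, , drop = FALSE])
  rec$gyro <- sweep(rec$gyro, 2, gbias, "-")
  fix_accel <- function(a) {
    m <- colMeans(a[idx, , drop = FALSE])
    mag <- sqrt(sum(m^2))
    if (mag < 1e-6) return(a)   # free-fall quiet range: nothing to anchor on
    u <- m / mag
    sweep(a, 2, u * (mag - 1), "-")
  }
  rec$primary <- fix_accel(rec$primary)
  rec$secondary <- fix_accel(rec$secondary)
  rec
}

#' Fuse dual-range accelerometer channels at a saturation limit
#'
#' Frames where any axis of the primary accelerometer exceeds the limit in
#' absolute value are replaced, on all axes, by the corresponding secondary
#' frames (per-frame replacement keeps each frame on one calibration).
#'
#' @param primary,secondary n x 3 accelerometer matrices (g).
#' @param limit saturation limit in g (default 15.5).
#' @return n x 3 fused matrix.
#' @export
fuse_saturated_channels <- function(primary, secondary, limit = 15.5) {
  primary <- as.matrix(primary); secondary <- as.matrix(secondary)
  if (!all(dim(primary) == dim(secondary))) {
    stop("primary and secondary channels must have equal dimensions")
  }
  sat <- apply(abs(primary) > limit, 1, any)
  fused <- primary
  fused[sat, ] <- secondary[sat, ]
  fused
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a Butterworth design (default 4th order,
#' 50 Hz), preserving peak timing. Matrix input is filtered per column.
#'
#' @param x numeric vector or matrix.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (must be below Nyquist).
#' @param order filter order.
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs = 1000, cutoff_hz = 50, order = 4) {
  if (cutoff_hz >= fs / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  one <- function(col) {
    n <- length(col)
    if (n < 4) return(col)
    # odd-reflection padding absorbs the zero-initial-condition start-up
    # transient of the forward and reverse passes
    np <- min(n - 1, max(100L, 30L * order))
    head_pad <- 2 * col[1] - col[(np + 1):2]
    tail_pad <- 2 * col[n] - col[(n - 1):(n - np)]
    y <- signal::filtfilt(bf, c(head_pad, col, tail_pad))
    y[(np + 1):(np + n)]
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

# one Madgwick IMU update (y-up world); q is sensor-to-world
madgwick_step <- function(q, gyro, accel, beta, dt) {
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))
  anorm <- sqrt(sum(accel^2))
  if (anorm > .Machine$double.eps && beta > 0) {
    a <- accel / anorm
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    # predicted sensor-frame gravity for world up = (0, 1, 0)
    f <- c(2 * (x * y + w * z) - a[1],
           1 - 2 * (x^2 + z^2) - a[2],
           2 * (y * z - w * x) - a[3])
    J <- matrix(c(2 * z, 2 * y, 2 * x, 2 * w,
                  0, -4 * x, 0, -4 * z,
                  -2 * x, -2 * w, 2 * z, 2 * y), 3, 4, byrow = TRUE)
    grad <- as.vector(crossprod(J, f))
    gn <- sqrt(sum(grad^2))
    if (gn > .Machine$double.eps) qdot <- qdot - beta * grad / gn
  }
  quat_normalize(q + qdot * dt)
}

#' Madgwick orientation estimation and gravity removal
#'
#' Tracks the sensor-to-world orientation with a Madgwick complementary
#' filter (gyroscope integration corrected toward the accelerometer gravity
#' direction with gain `beta`), initialized from quiet-standing gravity
#' with zero yaw, then rotates the accelerations into the inertial frame
#' (+y vertical) and subtracts 1 g.
#'
#' Frames with zero-norm acceleration skip the gradient correction (the
#' count is reported in the result).
#'
#' @param accel n x 3 bias-corrected accelerometer matrix (g).
#' @param gyro n x 3 bias-corrected gyroscope matrix (rad/s).
#' @param fs sampling rate (Hz).
#' @param beta Madgwick gain (default 0.1; 0 integrates the gyroscope
#'   only, exact for noiseless rotation-free data).
#' @param init_range quiet range (data.frame row or `c(start, end)`) used
#'   for the initial orientation; defaults to the first 100 samples.
#' @return object of class `processed_acceleration`: list with `accel`
#'   (n x 3 gravity-free, g, inertial frame), `accel_sensor` (gravity-free
#'   in the sensor frame, for segment-frame transforms), `quat` (n x 4
#'   unit quaternions), `frame = "inertial"`, `units = "g"`, `fs`,
#'   `skipped_updates`.
#' @export
estimate_orientation_and_degravitate <- function(accel, gyro, fs = 1000,
                                                 beta = 0.1,
                                                 init_range = NULL) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- nrow(accel)
  if (nrow(gyro) != n) stop("accel and gyro must share the time base")
  if (is.null(init_range)) {
    init_range <- c(1, min(100, n) + 1)
  } else if (is.data.frame(init_range)) {
    init_range <- c(init_range$start[1], init_range$end[1])
  }
  g_quiet <- colMeans(accel[init_range[1]:(init_range[2] - 1), ,
                            drop = FALSE])
  if (sqrt(sum(g_quiet^2)) < 1e-8) {
    stop("cannot initialize orientation: quiet-range acceleration is zero")
  }
  # sensor-to-world q0: minimal rotation taking measured gravity to +y
  q0 <- quat_between(g_quiet / sqrt(sum(g_quiet^2)), c(0, 1, 0))
  dt <- 1 / fs
  quat <- matrix(NA_real_, n, 4)
  q <- q0
  skipped <- 0L
  for (i in seq_len(n)) {
    if (i > 1) {
      if (sum(accel[i, ]^2) < .Machine$double.eps) skipped <- skipped + 1L
      q <- madgwick_step(q, gyro[i, ], accel[i, ], beta, dt)
    }
    quat[i, ] <- q
  }
  out <- matrix(NA_real_, n, 3)
  out_sensor <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(quat[i, ])
    out[i, ] <- R %*% accel[i, ]
    # R^T e_y is the second row of R: gravity expressed in sensor axes
    out_sensor[i, ] <- accel[i, ] - R[2, ]
  }
  out[, 2] <- out[, 2] - 1
  structure(list(accel = out, accel_sensor = out_sensor, quat = quat,
                 frame = "inertial", units = "g", fs = fs,
                 skipped_updates = skipped),
            class = "processed_acceleration")
}

#' Build the segment coordinate system (SCS) rotation
#'
#' The SCS z-axis (mediolateral, +z right) is the first principal axis of
#' the angular velocity over the running window; the y-axis is the
#' quiet-standing gravity direction orthogonalized against z; x = y x z
#' (anterior). The z sign is chosen so the mean anteroposterior
#' acceleration over the running window is positive along +x (forward
#' running); ties fall back to alignment with the raw sensor +z.
#'
#' @param gyro n x 3 gyroscope matrix (rad/s), sensor frame.
#' @param accel n x 3 accelerometer matrix (g), sensor frame.
#' @param running_range,quiet_range index ranges `c(start, end)` (half-open)
#'   or single-row data.frames with `start`/`end`.
#' @param min_condition minimum ratio of first to second principal variance
#'   of the angular velocity; below it the PCA is considered degenerate.
#' @return 3x3 rotation matrix mapping sensor-frame vectors to SCS
#'   (rows = SCS axes expressed in the sensor frame).
#' @export
build_scs <- function(gyro, accel, running_range, quiet_range,
                      min_condition = 5) {
  rng <- function(r) {
    if (is.data.frame(r)) r <- c(r$start[1], r$end[1])
    if (r[2] <= r[1]) stop("empty window")
    r[1]:(r[2] - 1)
  }
  run_idx <- rng(running_range)
  quiet_idx <- rng(quiet_range)
  W <- as.matrix(gyro)[run_idx, , drop = FALSE]
  pc <- stats::prcomp(W, center = TRUE)
  lambda <- pc$sdev^2
  if (lambda[1] < 1e-12 || lambda[1] / max(lambda[2], 1e-300) <
      min_condition) {
    stop(sprintf(paste0("degenerate angular-velocity PCA (variance ratio ",
                        "%.2f < %.2f): cannot identify the mediolateral ",
                        "axis"),
                 lambda[1] / max(lambda[2], 1e-300), min_condition))
  }
  z <- pc$rotation[, 1]
  g <- colMeans(as.matrix(accel)[quiet_idx, , drop = FALSE])
  gn <- sqrt(sum(g^2))
  if (gn < 1e-8) stop("quiet-range gravity is zero")
  y <- g / gn - sum(g / gn * z) * z
  yn <- sqrt(sum(y^2))
  if (yn < 1e-8) stop("gravity is parallel to the mediolateral axis")
  y <- y / yn
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  # sign disambiguation: forward running has positive mean accel along +x
  ap_mean <- mean(as.matrix(accel)[run_idx, , drop = FALSE] %*% x)
  if (abs(ap_mean) > 1e-9) {
    if (ap_mean < 0) { z <- -z; x <- -x }
  } else if (z[3] < 0) {
    z <- -z; x <- -x
  }
  R <- rbind(x = x, y = y, z = z)
  stopifnot(is_rotation_matrix(R, tol = 1e-6))
  R
}

#' Tilt-corrected coordinate system (TCCS) rotation
#'
#' In the inertial frame (+y vertical), the TCCS keeps +y vertical, sets +x
#' to the horizontal projection of the progression direction, and completes
#' the right-handed triad with +z = x cross y (pointing right).
#'
#' @param progression length-3 progression-direction estimate in the
#'   inertial frame.
#' @return 3x3 rotation matrix mapping inertial-frame vectors to TCCS.
#' @export
tccs_rotation <- function(progression) {
  p <- progression
  p[2] <- 0
  pn <- sqrt(sum(p^2))
  if (pn < 1e-8) {
    stop("progression direction is parallel to vertical: TCCS undefined")
  }
  x <- p / pn
  y <- c(0, 1, 0)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  R <- rbind(x = x, y = y, z = z)
  stopifnot(is_rotation_matrix(R, tol = 1e-6))
  R
}

#' Re-express processed accelerations in another frame
#'
#' @param processed a `processed_acceleration`.
#' @param rotation 3x3 rotation (rows = target axes in the current frame).
#' @param frame label for the target frame ("SCS" or "TCCS").
#' @return the processed object with rotated accelerations and new frame
#'   tag.
#' @export
rotate_processed <- function(processed, rotation, frame) {
  stopifnot(is_rotation_matrix(rotation, tol = 1e-6))
  processed$accel <- processed$accel %*% t(rotation)
  processed$frame <- frame
  processed
}

#' Convert processed accelerations to the TCCS
#'
#' @param processed a `processed_acceleration` in the inertial frame.
#' @param progression progression-direction estimate (inertial frame).
#' @return the processed object in the TCCS.
#' @export
to_tccs <- function(processed, progression) {
  if (!identical(processed$frame, "inertial")) {
    stop("TCCS conversion expects inertial-frame data")
  }
  rotate_processed(processed, tccs_rotation(progression), "TCCS")
}

#' Extract the stance window from processed accelerations
#'
#' @param processed a `processed_acceleration`.
#' @param bounds a `stance_bounds` from [detect_stance_bounds()] on the
#'   time-synchronized force.
#' @return n_stance x 3 acceleration matrix covering `[start, end)`.
#' @export
segment_stance_window <- function(processed, bounds) {
  n <- nrow(processed$accel)
  if (bounds$end <= bounds$start) stop("empty stance bounds")
  if (bounds$start < 1 || bounds$end > n + 1) {
    stop("stance bounds fall outside the recording")
  }
  processed$accel[bounds$start:(bounds$end - 1), , drop = FALSE]
}

#' Run the full IMU chain for one placement of a synthetic stance
#'
#' Convenience wrapper: calibrate, detect quiet periods, remove biases,
#' fuse saturated frames, low-pass filter, estimate orientation and remove
#' gravity, rotate to the requested frame, and cut the stance window at the
#' force-derived bounds.
#'
#' @param stance a `synthetic_stance`.
#' @param placement "shank", "hip", or "sacrum".
#' @param frame output frame: "SCS" (default), "inertial", or "TCCS".
#' @param cutoff low-pass cutoff in Hz, or `NULL` to skip filtering.
#' @param beta Madgwick gain.
#' @param bounds optional precomputed `stance_bounds` on the stance's force
#'   series (computed at 10 N when missing).
#' @return list with `stance_accel` (stance-window n x 3 matrix, g,
#'   gravity-free), `processed`, `bounds`, `scs` (when `frame = "SCS"`).
#' @export
process_stance_imu <- function(stance, placement = "sacrum",
                               frame = c("SCS", "inertial", "TCCS"),
                               cutoff = 50, beta = 0.1, bounds = NULL) {
  frame <- match.arg(frame)
  imu <- stance$imu[[placement]]
  if (is.null(imu)) stop("unknown placement: ", placement)
  rec <- imu_recording(stance$time, imu$primary, imu$secondary, imu$gyro,
                       placement = placement)
  rec <- apply_calibration(rec)
  quiet <- detect_quiet_periods(rec$gyro, rec$primary, rec$fs)
  if (nrow(quiet) == 0) {
    # synthetic prefixes are exactly quiet; fall back to the known prefix
    quiet <- data.frame(start = 1L, end = stance$stance_range[1])
  }
  rec <- remove_bias(rec, quiet)
  fused <- fuse_saturated_channels(rec$primary, rec$secondary)
  if (!is.null(cutoff)) {
    n_pre <- quiet$end[1] - 1
    filt <- lowpass_filter(fused, rec$fs, cutoff)
    gyro <- lowpass_filter(rec$gyro, rec$fs, cutoff)
    # keep the quiet prefix exactly constant (filter edge effects would
    # otherwise corrupt the orientation initialization window)
    keep <- seq_len(max(1, n_pre - 50))
    filt[keep, ] <- fused[keep, ]
    gyro[keep, ] <- rec$gyro[keep, ]
  } else {
    filt <- fused
    gyro <- rec$gyro
  }
  proc <- estimate_orientation_and_degravitate(filt, gyro, rec$fs,
                                               beta = beta,
                                               init_range = quiet[1, ])
  scs <- NULL
  if (frame == "SCS") {
    run_range <- c(stance$stance_range[1], stance$stance_range[2] + 1L)
    scs <- tryCatch(
      build_scs(gyro, filt, run_range, quiet[1, ]),
      error = function(e) NULL)
    # the SCS is a sensor-to-segment rotation, so it acts on the
    # sensor-frame gravity-free acceleration (an identity SCS when the
    # angular-velocity PCA is degenerate, i.e. the sensor is already
    # anatomy-aligned)
    proc$accel <- if (is.null(scs)) proc$accel_sensor
                  else proc$accel_sensor %*% t(scs)
    proc$frame <- "SCS"
  } else if (frame == "TCCS") {
    prog <- colMeans(proc$accel)
    prog[2] <- 0
    if (sqrt(sum(prog^2)) < 1e-8) prog <- c(1, 0, 0)
    proc <- to_tccs(proc, prog)
  }
  if (is.null(bounds)) {
    bounds <- detect_stance_bounds(stance$force, fs = stance$fs)
  }
  list(stance_accel = segment_stance_window(proc, bounds),
       processed = proc, bounds = bounds, scs = scs)
}
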