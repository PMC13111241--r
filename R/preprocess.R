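#' Signal conditioning for wearable gait data
#'
#' Zero-phase Butterworth low-pass filtering, quaternion complementary-filter
#' orientation estimation from gyroscope/accelerometer/magnetometer triads,
#' modified-Z-score outlier repair and reference z-score normalization.
#'
#' @name preprocess
NULL

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth filter applied forward and backward
#' (\code{signal::filtfilt}) so the net result has zero phase lag and the
#' squared magnitude response of a single pass.
#'
#' @param x numeric series
#' @param rate sampling rate (Hz); must exceed twice the cutoff
#' @param cutoff cutoff frequency (Hz), default 20
#' @param order filter order per pass, default 4
#' @return filtered series, same length as input
#' @export
#' @examples
#' y <- lowpass(sin(2 * pi * 2 * seq(0, 2, by = 0.01)), rate = 100)
lowpass <- function(x, rate, cutoff = 20, order = 4) {
  n <- length(x)
  if (n < 3 * order)
    stop("series too short for zero-phase filtering: need at least ",
         3 * order, " samples, got ", n)
  if (rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff (", 2 * cutoff, " Hz)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (the plain filtfilt assumes zero initial state)
  pad <- min(3L * (2L * order + 1L), n - 1L)
  mu <- mean(x)
  xc <- x - mu            # the DC component passes through untouched
  xp <- c(2 * xc[1] - xc[(pad + 1L):2],
          xc,
          2 * xc[n] - xc[(n - 1L):(n - pad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  mu + yp[(pad + 1L):(pad + n)]
}

## ---- quaternion helpers (w, x, y, z convention) -------------------------

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

## rotation matrix (sensor -> world) to quaternion, Shepperd's method
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(max(R[i, i] - R[j, j] - R[k, k] + 1, 0)) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  quat_normalize(q)
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## accelerometer-magnetometer absolute orientation (TRIAD-style): tilt from
## the gravity direction, heading from the horizontal magnetometer projection.
## World frame: x east, y north, z up. Returns NULL for degenerate inputs.
quat_am <- function(accel, mag) {
  na <- sqrt(sum(accel^2))
  if (na < 1e-8) return(NULL)
  up <- accel / na
  mh <- mag - sum(mag * up) * up
  nm <- sqrt(sum(mh^2))
  if (nm < 1e-8) return(NULL)
  north <- mh / nm
  east <- c(north[2] * up[3] - north[3] * up[2],
            north[3] * up[1] - north[1] * up[3],
            north[1] * up[2] - north[2] * up[1])
  R <- rbind(east, north, up)            # v_world = R %*% v_sensor
  rotmat_to_quat(R)
}

#' Complementary-filter orientation estimation
#'
#' Recursive quaternion orientation estimate blending high-frequency gyroscope
#' integration with low-frequency accelerometer/magnetometer absolute
#' orientation: at each step the gyroscope propagates the previous estimate
#' through the quaternion increment \code{q (x) [1, w dt/2]}, the
#' accelerometer/magnetometer pair provides an absolute attitude, and the two
#' are mixed linearly with weight \code{alpha} on the gyroscope path before
#' renormalization to unit length. Samples with a degenerate (near-zero)
#' accelerometer reading fall back to the gyro-only update.
#'
#' @param gyro T x 3 angular velocity (rad/s), sensor frame
#' @param accel T x 3 specific force (m/s^2), sensor frame
#' @param mag T x 3 magnetic field, sensor frame (any consistent unit)
#' @param alpha gyroscope mixing coefficient, default 0.98
#' @param dt sampling interval (s)
#' @return object of class \code{orientation_estimate}: \code{quaternions}
#'   (T x 4, unit rows, w-first, sensor-to-world), \code{filter_alpha},
#'   \code{dt}
#' @export
estimate_orientation <- function(gyro, accel, mag, alpha = 0.98, dt = 0.01) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  T_ <- nrow(gyro)
  stopifnot(ncol(gyro) == 3L, nrow(accel) == T_, nrow(mag) == T_,
            alpha >= 0, alpha <= 1, dt > 0)
  q <- quat_am(accel[1L, ], mag[1L, ])
  if (is.null(q)) q <- c(1, 0, 0, 0)
  Q <- matrix(NA_real_, T_, 4L)
  Q[1L, ] <- q
  for (t in seq_len(T_)[-1L]) {
    w <- gyro[t, ]
    dq <- c(1, w * dt / 2)
    q_gyro <- quat_normalize(quat_mul(q, dq))
    q_am <- quat_am(accel[t, ], mag[t, ])
    if (is.null(q_am)) {
      q <- q_gyro
    } else {
      if (sum(q_gyro * q_am) < 0) q_am <- -q_am
      q <- quat_normalize(alpha * q_gyro + (1 - alpha) * q_am)
    }
    Q[t, ] <- q
  }
  structure(list(quaternions = Q, filter_alpha = alpha, dt = dt),
            class = "orientation_estimate")
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("orientation estimate: %d samples, alpha = %.2f, dt = %g s\n",
              nrow(x$quaternions), x$filter_alpha, x$dt))
  invisible(x)
}

#' Modified-Z-score outlier repair
#'
#' Flags samples whose Iglewicz-Hoaglin modified Z-score
#' \code{0.6745 (x - median) / MAD} exceeds \code{z_thresh} in magnitude.
#' Runs of at most \code{max_gap} consecutive flagged samples are replaced by
#' cubic-spline interpolation over the unflagged neighbours; longer runs are
#' reported unrepaired. A constant signal (MAD = 0) is returned unchanged.
#'
#' @param x numeric series, length at least 10
#' @param z_thresh modified-Z threshold, default 3.5
#' @param max_gap longest repairable run of consecutive outliers, default 4
#' @return list: \code{x} repaired series, \code{outliers} logical flags,
#'   \code{repaired} logical (subset of \code{outliers} actually interpolated)
#' @export
repair_outliers <- function(x, z_thresh = 3.5, max_gap = 4) {
  if (length(x) < 10L) stop("repair_outliers needs at least 10 samples")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  out <- logical(length(x))
  rep_mask <- logical(length(x))
  if (mad0 == 0) {
    return(list(x = x, outliers = out, repaired = rep_mask))
  }
  z <- 0.6745 * (x - med) / mad0
  out <- abs(z) > z_thresh
  if (any(out)) {
    r <- rle(out)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    xr <- x
    good <- which(!out)
    for (k in which(r$values)) {
      if (r$lengths[k] <= max_gap && length(good) >= 4L) {
        idx <- starts[k]:ends[k]
        xr[idx] <- stats::spline(good, x[good], xout = idx, method = "natural")$y
        rep_mask[idx] <- TRUE
      }
    }
    x <- xr
  }
  list(x = x, outliers = out, repaired = rep_mask)
}

#' Z-score normalization against reference statistics
#'
#' Normalizes a channel using mean and standard deviation computed on
#' reference (training-split) data, so evaluation data never leaks into the
#' statistics.
#'
#' @param x numeric series
#' @param ref_mean reference mean
#' @param ref_sd reference standard deviation, strictly positive
#' @return \code{(x - ref_mean) / ref_sd}
#' @export
zscore <- function(x, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop("ref_sd must be strictly positive, got ", ref_sd)
  (x - ref_mean) / ref_sd
}
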