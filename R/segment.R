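#' Gait-cycle segmentation, temporal normalization and quality control
#'
#' Force-based contact detection with a kinematic backup, slicing of per-foot
#' gait cycles between successive initial contacts of the same foot, cubic
#' spline resampling to the canonical 101-point grid, and the three-rule
#' quality filter.
#'
#' @name segment
NULL

#' Force-based contact event detection
#'
#' Initial contacts at upward crossings of the 20 N threshold, terminal
#' contacts at downward crossings of 30 N, with hysteresis (after an initial
#' contact only a terminal contact is accepted and vice versa) and a 50 ms
#' debounce between successive events to suppress threshold chatter.
#'
#' @param grf_v nonnegative vertical ground-reaction-force series (N)
#' @param rise_thresh rising-edge threshold (N), default 20
#' @param fall_thresh falling-edge threshold (N), default 30
#' @param rate sampling rate (Hz)
#' @param debounce minimum time between successive events (s)
#' @return object of class \code{contact_events}: integer vectors
#'   \code{initial_contacts}, \code{terminal_contacts}, \code{source}
#' @export
detect_contacts_force <- function(grf_v, rise_thresh = 20, fall_thresh = 30,
                                  rate = 100, debounce = 0.05) {
  stopifnot(all(grf_v >= 0 | is.na(grf_v)))
  n <- length(grf_v)
  ic <- integer(0); tc <- integer(0)
  state <- if (isTRUE(grf_v[1] >= rise_thresh)) "stance" else "swing"
  min_gap <- ceiling(debounce * rate)
  last <- -Inf
  for (t in 2:n) {
    if (state == "swing" &&
        grf_v[t - 1] < rise_thresh && grf_v[t] >= rise_thresh &&
        t - last >= min_gap) {
      ic <- c(ic, t); state <- "stance"; last <- t
    } else if (state == "stance" &&
               grf_v[t - 1] >= fall_thresh && grf_v[t] < fall_thresh &&
               t - last >= min_gap) {
      tc <- c(tc, t); state <- "swing"; last <- t
    }
  }
  structure(list(initial_contacts = ic, terminal_contacts = tc,
                 source = "force"), class = "contact_events")
}

#' Kinematic backup contact detection from shank angular velocity
#'
#' Detects initial contacts at negative-to-positive zero crossings of the
#' sagittal shank gyroscope channel (axis pointing to the subject's right),
#' the crossing that immediately follows the late-swing extreme and precedes
#' the stance phase. Intended for low-pass-filtered input and used only when
#' force events are unavailable.
#'
#' @param shank_gyro sagittal shank angular velocity series (rad/s)
#' @param rate sampling rate (Hz)
#' @param debounce minimum time between successive events (s)
#' @return a \code{contact_events} object (initial contacts only,
#'   \code{source = "kinematic"})
#' @export
detect_contacts_kinematic <- function(shank_gyro, rate = 100,
                                      debounce = 0.05) {
  n <- length(shank_gyro)
  ic <- integer(0)
  min_gap <- ceiling(debounce * rate)
  last <- -Inf
  for (t in 2:n) {
    if (shank_gyro[t - 1] < 0 && shank_gyro[t] >= 0 && t - last >= min_gap) {
      ic <- c(ic, t); last <- t
    }
  }
  structure(list(initial_contacts = ic, terminal_contacts = integer(0),
                 source = "kinematic"), class = "contact_events")
}

#' @export
print.contact_events <- function(x, ...) {
  cat(sprintf("contact events (%s): %d initial, %d terminal\n", x$source,
              length(x$initial_contacts), length(x$terminal_contacts)))
  invisible(x)
}

#' Temporal normalization of one gait cycle to the 101-point grid
#'
#' Resamples every channel of a variable-length cycle onto 101 uniformly
#' distributed points spanning 0-100\% of cycle duration by cubic spline
#' interpolation; endpoints are preserved exactly.
#'
#' @param raw list describing the cycle: \code{time} (strictly increasing
#'   seconds), \code{channels} (T x K matrix), optional \code{grf} (T x 3),
#'   optional \code{theta_true} (T x 6), \code{side} ("left"/"right"),
#'   optional \code{subject_id}, \code{fatigue_level}
#' @return object of class \code{normalized_cycle}: \code{grid} (101 values in
#'   [0, 1]), \code{channels} (101 x K), \code{grf}, \code{theta_true},
#'   \code{duration}, \code{side}, plus passed-through identifiers
#' @export
normalize_cycle <- function(raw) {
  t0 <- raw$time
  if (length(t0) < 4L) stop("cycle too short to resample: ", length(t0))
  if (any(diff(t0) <= 0)) stop("non-monotonic timestamp sequence")
  grid <- seq(t0[1], t0[length(t0)], length.out = 101L)
  resample <- function(m) {
    m <- as.matrix(m)
    out <- apply(m, 2L, function(y) stats::spline(t0, y, xout = grid)$y)
    colnames(out) <- colnames(m)
    out
  }
  structure(list(
    grid = seq(0, 1, length.out = 101L),
    channels = resample(raw$channels),
    grf = if (!is.null(raw$grf)) resample(raw$grf) else NULL,
    theta_true = if (!is.null(raw$theta_true)) resample(raw$theta_true) else NULL,
    duration = t0[length(t0)] - t0[1] + (t0[2] - t0[1]),
    side = raw$side %||% NA_character_,
    subject_id = raw$subject_id %||% NA,
    fatigue_level = raw$fatigue_level %||% NA,
    peak_vertical_force = if (!is.null(raw$grf))
      max(as.matrix(raw$grf)[, ncol(as.matrix(raw$grf))]) else NA_real_,
    timestamps_monotonic = TRUE),
    class = "normalized_cycle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf("normalized gait cycle (%s): 101 points, %.3f s, %d channels\n",
              x$side, x$duration, ncol(x$channels)))
  invisible(x)
}

#' Quality control of segmented cycles
#'
#' Keeps exactly the cycles that pass all three rules: duration inside
#' [0.4, 1.2] s, peak vertical force at least 80\% of body weight
#' (mass x 9.81 N), and a monotonic timestamp sequence. Idempotent by
#' construction.
#'
#' @param cycles list of \code{normalized_cycle} objects
#' @param body_mass subject mass (kg), > 0
#' @return list: \code{kept} (surviving cycles), \code{log} (data.frame with
#'   columns \code{cycle}, \code{reason} for every rejection)
#' @export
quality_filter <- function(cycles, body_mass) {
  stopifnot(body_mass > 0)
  bw <- body_mass * GRAVITY
  kept <- list()
  log <- data.frame(cycle = integer(0), reason = character(0))
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    reason <- NULL
    if (is.na(cy$duration) || cy$duration < 0.4 || cy$duration > 1.2) {
      reason <- "duration"
    } else if (!is.na(cy$peak_vertical_force) &&
               cy$peak_vertical_force < 0.8 * bw) {
      reason <- "force"
    } else if (!isTRUE(cy$timestamps_monotonic)) {
      reason <- "timestamps"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- cy
    } else {
      log <- rbind(log, data.frame(cycle = i, reason = reason))
    }
  }
  list(kept = kept, log = log)
}

#' Segment a continuous recording into normalized per-foot gait cycles
#'
#' Detects per-foot initial contacts from the vertical GRF (kinematic shank
#' backup when force events are absent), slices half-open cycles between
#' successive initial contacts of the same foot, normalizes each to the
#' 101-point grid and applies the quality filter. First and last partial
#' cycles are discarded by construction.
#'
#' @param rec a \code{gait_recording} (or compatible list with
#'   \code{sensors}, \code{grf}, \code{rate}, \code{profile}, optional
#'   \code{theta}, \code{fatigue_level})
#' @return list: \code{cycles} (kept \code{normalized_cycle}s),
#'   \code{rejections} (quality log), \code{events} (per-side contact events)
#' @export
segment_recording <- function(rec) {
  rate <- rec$rate
  X <- sensor_matrix(rec$sensors)
  all_raw <- list()
  events <- list()
  for (side in c("L", "R")) {
    grf <- rec$grf[[side]]
    ev <- detect_contacts_force(grf[, "vertical"], rate = rate)
    if (length(ev$initial_contacts) == 0L) {
      g <- lowpass(X[, paste0("shank_", side, ".gyro_y")], rate, cutoff = 6)
      ev <- detect_contacts_kinematic(g, rate = rate)
    }
    events[[side]] <- ev
    ics <- ev$initial_contacts
    if (length(ics) >= 2L) {
      for (i in seq_len(length(ics) - 1L)) {
        idx <- ics[i]:(ics[i + 1L] - 1L)   # half-open [IC_i, IC_{i+1})
        all_raw[[length(all_raw) + 1L]] <- list(
          time = (idx - 1L) / rate,
          channels = X[idx, , drop = FALSE],
          grf = grf[idx, , drop = FALSE],
          theta_true = if (!is.null(rec$theta)) rec$theta[idx, , drop = FALSE],
          side = if (side == "L") "left" else "right",
          fatigue_level = rec$fatigue_level)
      }
    }
  }
  cycles <- lapply(all_raw, normalize_cycle)
  qf <- quality_filter(cycles, rec$profile$mass)
  list(cycles = qf$kept, rejections = qf$log, events = events)
}
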