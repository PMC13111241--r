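#' Seeded synthetic gait cohort simulator
#'
#' Generates inertial-sensor and ground-reaction-force recordings with the
#' statistical structure the fatigue-assessment pipeline assumes: quasi-periodic
#' joint-angle trajectories from truncated Fourier gait templates, double-bump
#' vertical GRF scaled to body weight, fatigue-dependent growth of bilateral
#' asymmetry and stride-to-stride variability, and additive Gaussian sensor
#' noise. Everything is deterministic under a fixed seed so downstream stages
#' are testable without laboratory data.
#'
#' The fatigue model has three effects per level \code{l}: (a) the right-limb
#' joint amplitudes shrink by \code{2.5\% * l * asymmetry_gain} about the
#' template mean, (b) cycle-to-cycle multiplicative amplitude jitter with
#' standard deviation \code{1.5\% * l * variability_gain} on each side, and
#' (c) stride-duration drift with standard deviation
#' \code{0.8\% * l * variability_gain}. Level 0 is perfectly rhythmic.
#'
#' @name synthetic
NULL

SENSOR_NAMES <- c("trunk", "pelvis", "thigh_L", "thigh_R",
                  "shank_L", "shank_R", "foot_L", "foot_R")
CHANNEL_NAMES <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
                   "mag_x", "mag_y", "mag_z")

## 3-harmonic Fourier gait templates (degrees), phase 0 = initial contact.
## columns: a0, cos1..cos3, sin1..sin3; fitted once to physiologic keypoints.
GAIT_TEMPLATE <- rbind(
  hip   = c(9.6173, 18.4161, -0.6683, 0.6681, -7.0417, -0.6135, 0.8086),
  knee  = c(21.7343, -3.2661, -12.7787, 1.6229, -19.5684, 9.0253, 3.8558),
  ankle = c(1.1625, 5.0007, -6.4124, 1.9023, 5.2579, -2.2946, 1.3287))

eval_template <- function(joint, phi, amplitude_scale = 1) {
  cf <- GAIT_TEMPLATE[joint, ]
  v <- cf[1]
  for (m in 1:3)
    v <- v + cf[1 + m] * cos(2 * pi * m * phi) + cf[4 + m] * sin(2 * pi * m * phi)
  # amplitude scaling about the template mean preserves the offset, scales ROM
  (cf[1] + amplitude_scale * (v - cf[1])) * pi / 180
}

#' Synthetic subject profile
#'
#' @param height stature (m), in [1.4, 2.1]
#' @param mass body mass (kg), in [40, 120]
#' @param base_cadence steps per minute
#' @param asymmetry_gain scaling of fatigue-dependent bilateral asymmetry
#'   (dimensionless, >= 0)
#' @param variability_gain scaling of fatigue-dependent stride variability
#'   (dimensionless, >= 0)
#' @param seed integer RNG seed for everything derived from this subject
#' @return object of class \code{subject_profile}
#' @export
subject_profile <- function(height = 1.72, mass = 68.2, base_cadence = 112,
                            asymmetry_gain = 1, variability_gain = 1,
                            seed = 1L) {
  stopifnot(height >= 1.4, height <= 2.1, mass >= 40, mass <= 120,
            asymmetry_gain >= 0, variability_gain >= 0, base_cadence > 0)
  structure(list(height = height, mass = mass, base_cadence = base_cadence,
                 asymmetry_gain = asymmetry_gain,
                 variability_gain = variability_gain, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Specification of one synthetic gait cycle
#'
#' Fully determines one cycle: all randomness (jitter, drift) is realized
#' upstream when specs are drawn, so trajectory generation is bit-reproducible
#' from the specification object alone.
#'
#' @param fatigue_level integer 0-4
#' @param stride_duration stride time (s), in [0.4, 1.2]
#' @param joint_amplitude_scale length-6 multiplier for
#'   (hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R) amplitudes
#' @param left_right_offset length-3 additive offset (radians) applied to the
#'   right hip/knee/ankle
#' @param noise_sd named numeric: per-channel-class noise standard deviations
#'   (\code{accel} m/s^2, \code{gyro} rad/s, \code{mag}, \code{grf} N)
#' @return object of class \code{cycle_spec}
#' @export
cycle_spec <- function(fatigue_level = 0L, stride_duration = 1.0,
                       joint_amplitude_scale = rep(1, 6),
                       left_right_offset = rep(0, 3),
                       noise_sd = c(accel = 0, gyro = 0, mag = 0, grf = 0)) {
  if (!fatigue_level %in% 0:4)
    stop("fatigue_level must be an integer in 0..4, got ", fatigue_level)
  if (!is.finite(stride_duration) || stride_duration < 0.4 ||
      stride_duration > 1.2)
    stop("stride_duration must lie in [0.4, 1.2] s, got ", stride_duration)
  stopifnot(length(joint_amplitude_scale) == 6L,
            length(left_right_offset) == 3L)
  structure(list(fatigue_level = as.integer(fatigue_level),
                 stride_duration = stride_duration,
                 joint_amplitude_scale = joint_amplitude_scale,
                 left_right_offset = left_right_offset,
                 noise_sd = noise_sd),
            class = "cycle_spec")
}

## draw a realized cycle spec for one cycle at a fatigue level (jitter + drift)
draw_cycle_spec <- function(profile, fatigue_level, noise_sd) {
  l <- fatigue_level
  asym <- 0.025 * l * profile$asymmetry_gain
  jit_sd <- 0.015 * l * profile$variability_gain
  drift_sd <- 0.008 * l * profile$variability_gain
  base_stride <- 2 * 60 / profile$base_cadence
  stride <- base_stride * (1 + if (drift_sd > 0) stats::rnorm(1, 0, drift_sd) else 0)
  stride <- min(max(stride, 0.4), 1.2)
  jit <- if (jit_sd > 0) stats::rnorm(6, 0, jit_sd) else numeric(6)
  scale <- pmax(c(1, 1, 1, 1 - asym, 1 - asym, 1 - asym) * (1 + jit), 0.2)
  cycle_spec(fatigue_level = l, stride_duration = stride,
             joint_amplitude_scale = scale,
             left_right_offset = rep(0, 3), noise_sd = noise_sd)
}

#' Generate joint-angle trajectories for one gait cycle
#'
#' Evaluates the per-joint truncated Fourier gait templates at the cycle's
#' stride frequency. The right limb equals the left shifted by half a cycle,
#' scaled by the right-side amplitude factors and offset by
#' \code{left_right_offset}; with unit scales and zero offsets the cycle is
#' perfectly antiphase-symmetric.
#'
#' @param spec a \code{\link{cycle_spec}}
#' @param profile a \code{\link{subject_profile}}
#' @param rate sampling rate (Hz)
#' @return T x 6 matrix of joint angles (radians), columns
#'   \code{hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R}; stride phase in
#'   attribute \code{phase}
#' @export
generate_joint_trajectories <- function(spec, profile, rate = 100) {
  stopifnot(inherits(spec, "cycle_spec"), inherits(profile, "subject_profile"))
  T_ <- max(round(spec$stride_duration * rate), 4L)
  phi <- (seq_len(T_) - 1L) / T_
  s <- spec$joint_amplitude_scale
  off <- spec$left_right_offset
  th <- cbind(
    hip_L = eval_template("hip", phi, s[1]),
    knee_L = eval_template("knee", phi, s[2]),
    ankle_L = eval_template("ankle", phi, s[3]),
    hip_R = eval_template("hip", phi + 0.5, s[4]) + off[1],
    knee_R = eval_template("knee", phi + 0.5, s[5]) + off[2],
    ankle_R = eval_template("ankle", phi + 0.5, s[6]) + off[3])
  attr(th, "phase") <- phi
  attr(th, "rate") <- rate
  th
}

## double-bump vertical GRF over stance phase s in [0,1], unit peak ~ 1
grf_shape <- function(s) (sin(pi * s) + 0.4 * sin(3 * pi * s)) / 1.045

#' Synthesize sensor and ground-reaction-force channels from joint kinematics
#'
#' Places the eight sensor frames (trunk, pelvis, bilateral thigh/shank/foot)
#' on the rigid-body chain via forward kinematics, differentiates positions
#' twice for the accelerometer (adding gravity in the sensor frame),
#' differentiates segment orientation for the sagittal gyroscope channel, and
#' synthesizes the magnetometer as a rotated constant north field. The
#' sagittal gyroscope axis points to the subject's right, so the shank channel
#' crosses zero from negative to positive at initial contact. Vertical GRF is
#' a double-bump curve over the stance phase scaled to a peak of about 1.15
#' body weight (zero in swing, crossing 20 N upward exactly once per cycle);
#' anterior-posterior GRF is a braking/propulsive sinusoid.
#'
#' @param theta T x 6 joint angles (radians) for one or more concatenated
#'   cycles
#' @param profile a \code{\link{subject_profile}}
#' @param noise_sd named per-class noise standard deviations as in
#'   \code{\link{cycle_spec}}; all zero for noiseless output
#' @param seed RNG seed for the additive noise
#' @param rate sampling rate (Hz), output is emitted directly at this rate
#' @param cycle_starts integer start indices of cycles within \code{theta}
#'   (default: the whole series is one cycle); used to phase the GRF
#' @param stance_frac stance fraction of the cycle, default 0.62
#' @param root_sway fore-aft and vertical pelvis excursion amplitudes (m);
#'   \code{c(0, 0)} pins the root (static fixtures)
#' @return list: \code{sensors} (a \code{sensor_array}: T x 8 x 9 array, 100
#'   Hz), \code{grf} with per-side T x 3 force matrices (columns ap, ml,
#'   vertical) and \code{total}
#' @export
synthesize_sensors <- function(theta, profile, noise_sd = c(accel = 0,
                               gyro = 0, mag = 0, grf = 0), seed = 1L,
                               rate = 100, cycle_starts = 1L,
                               stance_frac = 0.62,
                               root_sway = c(0.012, 0.018)) {
  theta <- as.matrix(theta)
  T_ <- nrow(theta)
  dt <- 1 / rate
  model <- anthropometrics(profile$height, profile$mass)
  # phase within cycle for every sample (last cycle extends to the end)
  bounds <- c(sort(unique(as.integer(cycle_starts))), T_ + 1L)
  phase <- numeric(T_)
  for (k in seq_len(length(bounds) - 1L)) {
    i <- bounds[k]:(bounds[k + 1L] - 1L)
    phase[i] <- (i - bounds[k]) / length(i)
  }
  # pelvis excursion: small vertical double oscillation + fore-aft sway
  root <- cbind(root_sway[1] * sin(2 * pi * phase),
                root_sway[2] * sin(4 * pi * phase))
  fk <- forward_kinematics(theta, model, root = root)
  ang <- list(L = segment_angles(theta, "L"), R = segment_angles(theta, "R"))
  trunk_angle <- rep(0.05, T_) + 0.03 * sin(2 * pi * phase)
  L <- model$length
  sites <- list(
    trunk = list(pos = fk$root + 0.75 * L$pelvis_trunk *
                   cbind(sin(trunk_angle), cos(trunk_angle)),
                 ang = trunk_angle),
    pelvis = list(pos = fk$root, ang = rep(0, T_)),
    thigh_L = list(pos = fk$com$thigh_L, ang = ang$L$thigh),
    thigh_R = list(pos = fk$com$thigh_R, ang = ang$R$thigh),
    shank_L = list(pos = fk$com$shank_L, ang = ang$L$shank),
    shank_R = list(pos = fk$com$shank_R, ang = ang$R$shank),
    foot_L = list(pos = fk$com$foot_L, ang = ang$L$foot),
    foot_R = list(pos = fk$com$foot_R, ang = ang$R$foot))
  X <- array(0, dim = c(T_, length(SENSOR_NAMES), length(CHANNEL_NAMES)),
             dimnames = list(NULL, SENSOR_NAMES, CHANNEL_NAMES))
  for (s in SENSOR_NAMES) {
    st <- sites[[s]]
    acc_w <- finite_diff(st$pos, dt)$d2          # sagittal (x fwd, y up)
    omega <- finite_diff(matrix(st$ang), dt)$d1[, 1L]
    ca <- cos(st$ang); sa <- sin(st$ang)
    # world frame: x forward, y left, z up; sensor rotated about y by angle
    ax_w <- acc_w[, 1L]; az_w <- acc_w[, 2L] + GRAVITY
    X[, s, "acc_x"] <- ca * ax_w - sa * az_w
    X[, s, "acc_z"] <- sa * ax_w + ca * az_w
    X[, s, "gyro_y"] <- -omega                   # axis to the subject's right
    X[, s, "mag_x"] <- ca * 1                    # north = world x
    X[, s, "mag_z"] <- sa * 1
  }
  # per-side GRF: left stance starts at phase 0, right at phase 0.5
  bw <- profile$mass * GRAVITY
  grf_side <- function(ph) {
    s <- ph / stance_frac
    in_stance <- ph < stance_frac
    fz <- ifelse(in_stance, 1.15 * bw * grf_shape(pmin(pmax(s, 0), 1)), 0)
    fap <- ifelse(in_stance, -0.18 * bw * sin(2 * pi * pmin(pmax(s, 0), 1)), 0)
    cbind(ap = fap, ml = 0, vertical = pmax(fz, 0))
  }
  grf_L <- grf_side(phase)
  grf_R <- grf_side((phase + 0.5) %% 1)
  if (any(noise_sd > 0)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    cls <- c(acc_x = "accel", acc_y = "accel", acc_z = "accel",
             gyro_x = "gyro", gyro_y = "gyro", gyro_z = "gyro",
             mag_x = "mag", mag_y = "mag", mag_z = "mag")
    for (ch in CHANNEL_NAMES) {
      sd_ch <- noise_sd[[cls[[ch]]]]
      if (isTRUE(sd_ch > 0))
        X[, , ch] <- X[, , ch] + stats::rnorm(T_ * dim(X)[2], 0, sd_ch)
    }
    if (isTRUE(noise_sd[["grf"]] > 0)) {
      grf_L[, "vertical"] <- pmax(grf_L[, "vertical"] +
        stats::rnorm(T_, 0, noise_sd[["grf"]]), 0)
      grf_R[, "vertical"] <- pmax(grf_R[, "vertical"] +
        stats::rnorm(T_, 0, noise_sd[["grf"]]), 0)
    }
  }
  sensors <- sensor_array(X, rate = rate)
  list(sensors = sensors,
       grf = list(L = grf_L, R = grf_R, total = grf_L + grf_R))
}

#' Simulate a continuous multi-cycle recording at one fatigue level
#'
#' Draws per-cycle specs (jitter, drift, asymmetry per the fatigue model),
#' generates joint trajectories, synthesizes sensors and GRF, and concatenates
#' everything into one recording with ground-truth cycle boundaries.
#'
#' @param profile a \code{\link{subject_profile}}
#' @param fatigue_level integer 0-4
#' @param n_cycles number of gait cycles
#' @param seed RNG seed
#' @param noise_sd named per-class noise standard deviations (see
#'   \code{\link{cycle_spec}})
#' @param rate sampling rate (Hz)
#' @return object of class \code{gait_recording}: \code{sensors}
#'   (\code{sensor_array}), \code{grf} (per-side + total), \code{theta} (true
#'   joint angles), \code{ic_L}/\code{ic_R} true initial-contact sample
#'   indices, \code{cycle_specs}, \code{fatigue_level}, \code{profile}
#' @export
simulate_recording <- function(profile, fatigue_level, n_cycles = 10,
                               seed = 1L,
                               noise_sd = c(accel = 0, gyro = 0, mag = 0,
                                            grf = 0),
                               rate = 100) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  specs <- replicate(n_cycles,
                     draw_cycle_spec(profile, fatigue_level, noise_sd),
                     simplify = FALSE)
  thetas <- lapply(specs, generate_joint_trajectories, profile = profile,
                   rate = rate)
  lens <- vapply(thetas, nrow, 0L)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  theta <- do.call(rbind, thetas)
  syn <- synthesize_sensors(theta, profile, noise_sd = noise_sd,
                            seed = seed + 1L, rate = rate,
                            cycle_starts = starts)
  # right-foot contacts at mid-cycle
  ic_R <- starts + as.integer(round(lens * 0.5))
  structure(list(sensors = syn$sensors, grf = syn$grf, theta = theta,
                 ic_L = starts, ic_R = ic_R[ic_R <= nrow(theta)],
                 cycle_specs = specs, fatigue_level = fatigue_level,
                 profile = profile, rate = rate),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("gait recording: %d samples at %d Hz, fatigue level %d, %d cycles\n",
              nrow(x$theta), x$rate, x$fatigue_level, length(x$ic_L)))
  invisible(x)
}

#' Per-channel noise for a requested signal-to-noise ratio
#'
#' Computes the additive Gaussian noise standard deviation that yields the
#' requested SNR for a signal, defining signal power about the channel mean.
#'
#' @param x numeric series (or matrix; power pooled over all elements)
#' @param snr_db requested SNR in decibels
#' @return noise standard deviation
#' @export
snr_noise_sd <- function(x, snr_db) {
  p_sig <- mean((x - mean(x))^2)
  sqrt(p_sig / 10^(snr_db / 10))
}

#' Simulate a labelled synthetic cohort of normalized gait cycles
#'
#' Runs the full chain per subject and fatigue level: recording simulation,
#' per-foot force-based segmentation, temporal normalization to the 101-point
#' grid and quality control. Returns normalized cycles together with fatigue
#' labels, per-cycle asymmetry targets derived from the generating joint
#' angles, and subject identifiers for subject-disjoint splits.
#'
#' @param n_subjects number of subjects
#' @param cycles_per_level gait cycles simulated per fatigue level
#' @param seed cohort RNG seed
#' @param fatigue_levels integer levels to include, default 0:4
#' @param noise_sd named per-class noise standard deviations
#' @param asymmetry_gain,variability_gain fatigue effect gains applied to all
#'   subjects
#' @return object of class \code{gait_cohort}: \code{cycles} (list of
#'   \code{normalized_cycle}), \code{meta} (data.frame: subject, level, side,
#'   duration), \code{asym} (matrix of per-cycle asymmetry targets)
#' @export
simulate_cohort <- function(n_subjects = 4, cycles_per_level = 10, seed = 1L,
                            fatigue_levels = 0:4,
                            noise_sd = c(accel = 0.05, gyro = 0.02,
                                         mag = 0.005, grf = 2),
                            asymmetry_gain = 1, variability_gain = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  subj_seeds <- sample.int(1e6, n_subjects)
  cycles <- list(); meta <- list(); asym <- list()
  for (i in seq_len(n_subjects)) {
    prof <- subject_profile(
      height = min(max(stats::rnorm(1, 1.724, 0.081), 1.5), 2.0),
      mass = min(max(stats::rnorm(1, 68.2, 11.3), 45), 110),
      base_cadence = stats::rnorm(1, 112, 6),
      asymmetry_gain = asymmetry_gain,
      variability_gain = variability_gain,
      seed = subj_seeds[i])
    for (lev in fatigue_levels) {
      rec <- simulate_recording(prof, lev, n_cycles = cycles_per_level + 2L,
                                seed = subj_seeds[i] + 13L * lev,
                                noise_sd = noise_sd)
      seg <- segment_recording(rec)
      for (cy in seg$cycles) {
        cy$subject_id <- i
        cy$fatigue_level <- lev
        cy$height <- prof$height
        cy$mass <- prof$mass
        cycles[[length(cycles) + 1L]] <- cy
        meta[[length(meta) + 1L]] <- data.frame(
          subject = i, level = lev, side = cy$side, duration = cy$duration)
        asym[[length(asym) + 1L]] <- cycle_asymmetry_targets(cy$theta_true)
      }
    }
  }
  structure(list(cycles = cycles, meta = do.call(rbind, meta),
                 asym = do.call(rbind, asym), seed = seed),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("synthetic gait cohort: %d cycles, %d subjects, levels %s\n",
              length(x$cycles), length(unique(x$meta$subject)),
              paste(sort(unique(x$meta$level)), collapse = ",")))
  invisible(x)
}

#' The easy smoke-test cohort
#'
#' A deliberately well-separated five-level cohort used for end-to-end
#' learning checks: eight subjects, strong fatigue-dependent asymmetry
#' (gain 2.5, i.e. right-limb amplitudes shrink 6.25\% per level), low
#' stride variability (gain 0.3) and the default low sensor noise. These
#' conditions are fixed; they define what "easy" means for this package.
#'
#' @param seed cohort RNG seed
#' @param cycles_per_level gait cycles per fatigue level and subject
#' @return a \code{gait_cohort}
#' @export
easy_cohort <- function(seed = 1L, cycles_per_level = 3) {
  simulate_cohort(n_subjects = 8, cycles_per_level = cycles_per_level,
                  seed = seed, asymmetry_gain = 2.5, variability_gain = 0.3)
}

#' Per-cycle asymmetry regression targets
#'
#' Six bilateral asymmetry quantities derived from the joint-angle ranges of
#' motion of one cycle: the normalized symmetry index (percent, as the
#' symmetry-index convention prints it) and the signed normalized difference
#' (percent) for each of hip, knee and ankle ROM.
#'
#' @param theta T x 6 joint angles for the cycle
#' @return named numeric vector of length 6
#' @export
cycle_asymmetry_targets <- function(theta) {
  rom <- apply(theta, 2L, function(v) diff(range(v)))
  out <- numeric(6)
  nm <- character(6)
  joints <- c("hip", "knee", "ankle")
  for (j in 1:3) {
    l <- rom[j]; r <- rom[j + 3L]
    denom <- 0.5 * (l + r)
    out[j] <- if (denom > 0) abs(l - r) / denom * 100 else 0
    out[j + 3L] <- if (denom > 0) (l - r) / denom * 100 else 0
    nm[j] <- paste0("s_", joints[j], "_rom")
    nm[j + 3L] <- paste0("dnorm_", joints[j], "_rom")
  }
  stats::setNames(out, nm)
}

#' Write a synthetic cohort to disk
#'
#' One directory per subject holding a long-format delimited sensor file per
#' cycle is deliberately avoided at cohort scale; instead each subject gets a
#' long CSV (\code{time_s, sensor_id, channel, value}) concatenating its
#' cycles, a JSON-lines label file (\code{cycle_id, fatigue_level}) and the
#' cohort root a manifest recording the seed and generator parameters.
#'
#' @param cohort a \code{\link{simulate_cohort}} result
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- unique(cohort$meta$subject)
  for (s in subs) {
    sd <- file.path(dir, sprintf("subject_%02d", s))
    dir.create(sd, showWarnings = FALSE)
    idx <- which(cohort$meta$subject == s)
    rows <- list(); labs <- character(0)
    for (k in idx) {
      cy <- cohort$cycles[[k]]
      ch <- cy$channels
      long <- data.frame(
        cycle_id = k,
        time_s = rep(cy$grid * cy$duration, ncol(ch)),
        sensor_id = rep(sub("\\..*$", "", colnames(ch)), each = nrow(ch)),
        channel = rep(sub("^[^.]*\\.", "", colnames(ch)), each = nrow(ch)),
        value = as.vector(ch))
      rows[[length(rows) + 1L]] <- long
      labs <- c(labs, jsonlite::toJSON(
        list(cycle_id = k, fatigue_level = cy$fatigue_level, side = cy$side),
        auto_unbox = TRUE))
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(sd, "sensors_long.csv"), row.names = FALSE)
    writeLines(labs, file.path(sd, "labels.jsonl"))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = cohort$seed,
                            n_cycles = length(cohort$cycles),
                            subjects = length(subs),
                            generator = "pigait synthetic gait cohort",
                            version = as.character(utils::packageVersion("pigait"))),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
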