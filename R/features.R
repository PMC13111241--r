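#' Biomechanical descriptor extraction
#'
#' A fixed, documented manifest of exactly 127 descriptors per cycle pair,
#' organized in five domains: spatiotemporal (11), kinematic (33), kinetic
#' (9), bilateral symmetry (39 = 13 base features x ratio/difference/index)
#' and frequency (35 = 7 channels x 5 spectral descriptors). The manifest
#' order is frozen; extraction is deterministic. When ground reaction force
#' is unavailable the kinetic descriptors and the symmetry descriptors based
#' on them are flagged missing (NA) while the count remains 127.
#'
#' @name features
NULL

SYMMETRY_BASE <- c("stride_duration", "stance_fraction", "swing_fraction",
                   "contact_time", "hip_rom", "knee_rom", "ankle_rom",
                   "hip_peak_flexion", "knee_peak_flexion",
                   "ankle_peak_flexion", "peak_vertical_force",
                   "loading_rate", "braking_impulse")

SPECTRAL_CHANNELS <- c("trunk.acc_z", "pelvis.acc_z", "shank_L.gyro_y",
                       "shank_R.gyro_y", "foot_L.acc_z", "foot_R.acc_z",
                       "grf.vertical")

#' The frozen 127-descriptor manifest
#'
#' @return data.frame with columns \code{name}, \code{domain}, \code{unit};
#'   exactly 127 rows in extraction order
#' @export
feature_manifest <- function() {
  rows <- list()
  add <- function(name, domain, unit)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, domain = domain,
                                             unit = unit)
  for (s in c("left", "right")) add(paste0("stride_duration_", s),
                                    "spatiotemporal", "s")
  for (s in c("left", "right")) add(paste0("stance_fraction_", s),
                                    "spatiotemporal", "fraction")
  for (s in c("left", "right")) add(paste0("swing_fraction_", s),
                                    "spatiotemporal", "fraction")
  for (s in c("left", "right")) add(paste0("contact_time_", s),
                                    "spatiotemporal", "s")
  add("aerial_time", "spatiotemporal", "s")
  add("cadence", "spatiotemporal", "steps/min")
  add("double_support_fraction", "spatiotemporal", "fraction")
  for (j in c("hip", "knee", "ankle")) for (s in c("left", "right"))
    for (q in c("peak_flexion", "peak_extension", "rom", "ic_angle",
                "tc_angle"))
      add(paste(j, q, s, sep = "_"), "kinematic", "rad")
  for (q in c("trunk_lateral_inclination_range",
              "trunk_anterior_inclination_range",
              "trunk_axial_rotation_range"))
    add(q, "kinematic", "rad")
  for (s in c("left", "right")) add(paste0("peak_vertical_force_", s),
                                    "kinetic", "N")
  for (s in c("left", "right")) add(paste0("loading_rate_", s),
                                    "kinetic", "N/s")
  for (s in c("left", "right")) add(paste0("braking_impulse_", s),
                                    "kinetic", "N s")
  for (s in c("left", "right")) add(paste0("propulsive_impulse_", s),
                                    "kinetic", "N s")
  add("vertical_com_displacement", "kinetic", "m")
  for (b in SYMMETRY_BASE) {
    add(paste0("sym_ratio_", b), "symmetry", "dimensionless")
    add(paste0("sym_diff_", b), "symmetry", "feature units")
    add(paste0("sym_index_", b), "symmetry", "percent")
  }
  for (ch in SPECTRAL_CHANNELS)
    for (q in c("dominant_freq", "spectral_entropy", "band_low", "band_med",
                "band_high"))
      add(paste(gsub("[.]", "_", ch), q, sep = "_"), "frequency",
          if (q == "dominant_freq") "Hz" else "fraction")
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 127L, !anyDuplicated(out$name))
  out
}

#' Bilateral symmetry indices
#'
#' Ratio \code{r = x_L / x_R}, absolute difference \code{d = x_L - x_R} and
#' the normalized symmetry index
#' \code{s = |x_L - x_R| / (0.5 (x_L + x_R)) * 100} (percent). Zero
#' denominators yield NA (flagged missing), never infinities.
#'
#' @param x_left,x_right scalar feature values for the two limbs
#' @return list with elements \code{r}, \code{d}, \code{s}
#' @export
#' @examples
#' symmetry_indices(12, 8)  # r = 1.5, d = 4, s = 40
symmetry_indices <- function(x_left, x_right) {
  if (is.na(x_left) || is.na(x_right))
    return(list(r = NA_real_, d = NA_real_, s = NA_real_))
  r <- if (x_right != 0) x_left / x_right else NA_real_
  d <- x_left - x_right
  den <- 0.5 * (x_left + x_right)
  s <- if (den != 0) abs(x_left - x_right) / den * 100 else NA_real_
  list(r = r, d = d, s = s)
}

#' FFT spectral descriptors of a cycle-normalized channel
#'
#' Dominant frequency, spectral entropy (natural log, normalized by the log
#' of the number of positive-frequency bins, so 0 = pure tone and 1 = flat
#' spectrum) and the fractions of in-band power in the low (0-3 Hz), medium
#' (3-8 Hz) and high (8-20 Hz) bands. The signal is mean-detrended before the
#' FFT. An all-zero signal yields NA descriptors.
#'
#' @param x numeric series (typically the 101-point cycle grid)
#' @param rate effective sampling rate of \code{x} (Hz)
#' @return list: \code{dominant_freq}, \code{spectral_entropy},
#'   \code{band_low}, \code{band_med}, \code{band_high}
#' @export
spectral_descriptors <- function(x, rate) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0))
    return(list(dominant_freq = NA_real_, spectral_entropy = NA_real_,
                band_low = NA_real_, band_med = NA_real_,
                band_high = NA_real_))
  p <- Mod(stats::fft(x))^2
  k <- 2:(floor(n / 2) + 1L)             # positive-frequency bins
  freq <- (k - 1L) * rate / n
  p <- p[k]
  ph <- p / sum(p)
  ent <- -sum(ifelse(ph > 0, ph * log(ph), 0)) / log(length(ph))
  inband <- freq <= 20
  tot <- sum(p[inband])
  band <- function(lo, hi) if (tot > 0)
    sum(p[freq > lo & freq <= hi & inband]) / tot else NA_real_
  list(dominant_freq = freq[which.max(p)],
       spectral_entropy = ent,
       band_low = band(0, 3), band_med = band(3, 8), band_high = band(8, 20))
}

## trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

## max slope of a series over a sliding time window
max_window_slope <- function(y, dt, window_s = 0.02) {
  w <- max(1L, round(window_s / dt))
  n <- length(y)
  if (n <= w) return(NA_real_)
  max((y[(1 + w):n] - y[1:(n - w)]) / (w * dt))
}

## joint-angle block features for one side of a cycle
joint_feats <- function(theta, side, stance_end_idx) {
  cols <- if (side == "left") 1:3 else 4:6
  out <- c()
  for (ji in seq_along(cols)) {
    v <- theta[, cols[ji]]
    out <- c(out, max(v), min(v), diff(range(v)), v[1],
             v[min(stance_end_idx, length(v))])
  }
  out
}

#' Extract the 127-descriptor feature set for a left/right cycle pair
#'
#' @param cycle_left,cycle_right \code{normalized_cycle} objects for the two
#'   feet (each carrying its own-side GRF); joint angles are taken from
#'   \code{theta} if supplied, else from the cycles' \code{theta_true}
#' @param mass subject body mass (kg), used for unit checks downstream
#' @param theta optional list with 101 x 6 joint-angle matrices \code{left}
#'   and \code{right} overriding the cycles' stored angles
#' @return object of class \code{feature_set}: \code{values} (named numeric,
#'   length 127, manifest order), \code{manifest}
#' @export
extract_features <- function(cycle_left, cycle_right, mass, theta = NULL) {
  man <- feature_manifest()
  v <- stats::setNames(rep(NA_real_, nrow(man)), man$name)
  th_l <- if (!is.null(theta)) theta$left else cycle_left$theta_true
  th_r <- if (!is.null(theta)) theta$right else cycle_right$theta_true
  dur <- c(left = cycle_left$duration, right = cycle_right$duration)
  dt <- c(left = dur[["left"]] / 100, right = dur[["right"]] / 100)
  grf <- list(left = cycle_left$grf, right = cycle_right$grf)
  has_grf <- !is.null(grf$left) && !is.null(grf$right)

  stance_frac <- c(left = NA, right = NA)
  stance_end <- c(left = 63L, right = 63L)
  if (has_grf) {
    for (s in c("left", "right")) {
      on <- grf[[s]][, "vertical"] > 20
      stance_frac[[s]] <- mean(on)
      stance_end[[s]] <- max(which(on), 1L)
    }
  }
  v["stride_duration_left"] <- dur[["left"]]
  v["stride_duration_right"] <- dur[["right"]]
  v["stance_fraction_left"] <- stance_frac[["left"]]
  v["stance_fraction_right"] <- stance_frac[["right"]]
  v["swing_fraction_left"] <- 1 - stance_frac[["left"]]
  v["swing_fraction_right"] <- 1 - stance_frac[["right"]]
  v["contact_time_left"] <- stance_frac[["left"]] * dur[["left"]]
  v["contact_time_right"] <- stance_frac[["right"]] * dur[["right"]]
  v["aerial_time"] <- max(0, 1 - stance_frac[["left"]] -
                            stance_frac[["right"]]) * mean(dur)
  v["cadence"] <- 2 * 60 / mean(dur)
  v["double_support_fraction"] <- max(0, stance_frac[["left"]] +
                                        stance_frac[["right"]] - 1)

  kin <- c(joint_feats(th_l, "left", stance_end[["left"]]),
           joint_feats(th_r, "right", stance_end[["right"]]))
  # manifest order is joint x side x quantity; joint_feats is side x joint
  kin_names <- as.vector(vapply(c("hip", "knee", "ankle"), function(j)
    as.vector(vapply(c("left", "right"), function(s)
      paste(j, c("peak_flexion", "peak_extension", "rom", "ic_angle",
                 "tc_angle"), s, sep = "_"), character(5))), character(10)))
  built_names <- as.vector(vapply(c("left", "right"), function(s)
    as.vector(vapply(c("hip", "knee", "ankle"), function(j)
      paste(j, c("peak_flexion", "peak_extension", "rom", "ic_angle",
                 "tc_angle"), s, sep = "_"), character(5))), character(15)))
  v[kin_names] <- kin[match(kin_names, built_names)]

  # trunk orientation ranges from the trunk sensor channels of the left cycle
  ch <- cycle_left$channels
  trunk_cols <- paste0("trunk.", c("gyro_x", "gyro_y", "gyro_z"))
  if (all(trunk_cols %in% colnames(ch)) &&
      all(paste0("trunk.", c("acc_x", "acc_y", "acc_z")) %in% colnames(ch))) {
    oe <- estimate_orientation(
      ch[, paste0("trunk.", c("gyro_x", "gyro_y", "gyro_z"))],
      ch[, paste0("trunk.", c("acc_x", "acc_y", "acc_z"))],
      ch[, paste0("trunk.", c("mag_x", "mag_y", "mag_z"))],
      dt = dt[["left"]])
    eul <- t(apply(oe$quaternions, 1L, function(q) {
      R <- quat_to_rotmat(q)
      c(roll = atan2(R[3, 2], R[3, 3]),
        pitch = -asin(max(min(R[3, 1], 1), -1)),
        yaw = atan2(R[2, 1], R[1, 1]))
    }))
    v["trunk_lateral_inclination_range"] <- diff(range(eul[, "roll"]))
    v["trunk_anterior_inclination_range"] <- diff(range(eul[, "pitch"]))
    v["trunk_axial_rotation_range"] <- diff(range(eul[, "yaw"]))
  }

  if (has_grf) {
    for (s in c("left", "right")) {
      fz <- grf[[s]][, "vertical"]
      fap <- grf[[s]][, "ap"]
      tt <- cycle_left$grid * dur[[s]]
      v[paste0("peak_vertical_force_", s)] <- max(fz)
      v[paste0("loading_rate_", s)] <- max_window_slope(fz, dt[[s]])
      v[paste0("braking_impulse_", s)] <- abs(trapz(tt, pmin(fap, 0)))
      v[paste0("propulsive_impulse_", s)] <- trapz(tt, pmax(fap, 0))
    }
    # vertical COM excursion: drift-corrected double integration of the
    # trunk vertical acceleration
    if ("trunk.acc_z" %in% colnames(ch)) {
      a <- ch[, "trunk.acc_z"]
      a <- a - mean(a)
      vel <- cumsum(a) * dt[["left"]]
      vel <- vel - stats::fitted(stats::lm(vel ~ seq_along(vel)))
      pos <- cumsum(vel) * dt[["left"]]
      pos <- pos - stats::fitted(stats::lm(pos ~ seq_along(pos)))
      v["vertical_com_displacement"] <- diff(range(pos))
    }
  }

  base_vals <- function(b, s) {
    key <- switch(b,
      stride_duration = paste0("stride_duration_", s),
      stance_fraction = paste0("stance_fraction_", s),
      swing_fraction = paste0("swing_fraction_", s),
      contact_time = paste0("contact_time_", s),
      hip_rom = paste0("hip_rom_", s),
      knee_rom = paste0("knee_rom_", s),
      ankle_rom = paste0("ankle_rom_", s),
      hip_peak_flexion = paste0("hip_peak_flexion_", s),
      knee_peak_flexion = paste0("knee_peak_flexion_", s),
      ankle_peak_flexion = paste0("ankle_peak_flexion_", s),
      peak_vertical_force = paste0("peak_vertical_force_", s),
      loading_rate = paste0("loading_rate_", s),
      braking_impulse = paste0("braking_impulse_", s))
    v[[key]]
  }
  for (b in SYMMETRY_BASE) {
    si <- symmetry_indices(base_vals(b, "left"), base_vals(b, "right"))
    v[paste0("sym_ratio_", b)] <- si$r
    v[paste0("sym_diff_", b)] <- si$d
    v[paste0("sym_index_", b)] <- si$s
  }

  rate_l <- 101 / dur[["left"]]
  for (chn in SPECTRAL_CHANNELS) {
    sig <- if (chn == "grf.vertical") {
      if (has_grf) grf$left[, "vertical"] else NULL
    } else if (chn %in% colnames(ch)) ch[, chn] else NULL
    pre <- paste(gsub("[.]", "_", chn), "", sep = "_")
    if (!is.null(sig)) {
      sp <- spectral_descriptors(sig, rate_l)
      v[paste0(gsub("[.]", "_", chn), "_",
               c("dominant_freq", "spectral_entropy", "band_low", "band_med",
                 "band_high"))] <-
        unlist(sp[c("dominant_freq", "spectral_entropy", "band_low",
                    "band_med", "band_high")])
    }
  }
  structure(list(values = v, manifest = man), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature set: %d descriptors (%d missing)\n",
              length(x$values), sum(is.na(x$values))))
  tab <- table(x$manifest$domain)
  cat("  domains:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write feature sets to a wide CSV plus a JSON manifest
#'
#' @param fsets list of \code{feature_set} objects
#' @param path CSV output path; the manifest is written next to it with a
#'   \code{_manifest.json} suffix
#' @param ids optional cycle identifiers (first column)
#' @return invisibly, the CSV path
#' @export
write_features <- function(fsets, path, ids = seq_along(fsets)) {
  man <- feature_manifest()
  m <- do.call(rbind, lapply(fsets, function(f) f$values))
  df <- data.frame(cycle_id = ids, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(man, sub("\\.csv$", "_manifest.json", path),
                       pretty = TRUE)
  invisible(path)
}
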