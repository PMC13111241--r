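#' Seven-segment sagittal rigid-body model
#'
#' Differentiable biomechanical layer: anthropometric scaling, planar forward
#' kinematics for a seven-segment chain (bilateral feet, shanks, thighs, and a
#' pelvis-trunk assembly), finite-difference derivatives, the whole-body
#' centre-of-mass chain, recursive Newton-Euler inverse dynamics and total
#' mechanical energy. Joint angles are stored in radians as a T x 6 matrix with
#' columns \code{hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R}; positive hip
#' flexion rotates the thigh forward, knee flexion is one-sided (0 = straight
#' leg), positive ankle angle is dorsiflexion. The sagittal plane uses x
#' forward and y up; gravity is 9.81 m/s^2 downward.
#'
#' @name biomech
NULL

GRAVITY <- 9.81

JOINT_COLS <- c("hip_L", "knee_L", "ankle_L", "hip_R", "knee_R", "ankle_R")

#' Anthropometric model from height and mass
#'
#' Scales a standard published body-segment proportion table (shipped with the
#' package as \code{extdata/segment_parameters.csv}) to an individual: segment
#' lengths as fractions of stature, masses as fractions of body mass with the
#' pelvis-trunk segment absorbing the residual so masses sum exactly to total
#' mass, centre-of-mass offsets as fractions of segment length, and moments of
#' inertia from radii of gyration (\code{I = m (r L)^2}).
#'
#' @param height stature in metres, within [1.4, 2.1]
#' @param mass body mass in kilograms, within [40, 120]
#' @return an object of class \code{anthropometrics}: lists of segment lengths
#'   (m), masses (kg), COM offset fractions and inertias (kg m^2), plus
#'   \code{total_mass}
#' @export
#' @examples
#' am <- anthropometrics(1.72, 68)
#' sum(unlist(am$mass)) - am$total_mass  # 0 by construction
anthropometrics <- function(height, mass) {
  if (!is.finite(height) || height < 1.4 || height > 2.1)
    stop("height must be in [1.4, 2.1] m, got ", height)
  if (!is.finite(mass) || mass < 40 || mass > 120)
    stop("mass must be in [40, 120] kg, got ", mass)
  key <- sprintf("%.17g_%.17g", height, mass)
  hit <- .pigait_cache$anthro[[key]]
  if (!is.null(hit)) return(hit)
  tab <- utils::read.csv(system.file("extdata", "segment_parameters.csv",
                                     package = "pigait"),
                         comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$segment
  segs <- c("foot", "shank", "thigh", "pelvis_trunk")
  len <- as.list(tab[segs, "length_frac"] * height)
  names(len) <- segs
  mf <- tab[segs, "mass_frac"]
  # pelvis_trunk absorbs the residual: bilateral limbs count twice
  mf[segs == "pelvis_trunk"] <- 1 - 2 * sum(mf[segs != "pelvis_trunk"])
  ms <- as.list(mf * mass)
  names(ms) <- segs
  com <- as.list(tab[segs, "com_frac"]); names(com) <- segs
  gy <- tab[segs, "gyration_frac"]
  In <- as.list(unlist(ms) * (gy * unlist(len))^2)
  names(In) <- segs
  out <- structure(list(length = len, mass = ms, com = com, inertia = In,
                        total_mass = mass, height = height),
                   class = "anthropometrics")
  .pigait_cache$anthro[[key]] <- out
  out
}

# per-session caches for the anthropometric table and the dense
# finite-difference operator matrices (keyed by length and step)
.pigait_cache <- new.env(parent = emptyenv())
.pigait_cache$anthro <- list()
.pigait_cache$mats <- list()

cached_matrix <- function(key, build) {
  hit <- .pigait_cache$mats[[key]]
  if (!is.null(hit)) return(hit)
  m <- build()
  .pigait_cache$mats[[key]] <- m
  m
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat("Seven-segment anthropometric model\n")
  cat(sprintf("  stature %.2f m, mass %.1f kg\n", x$height, x$total_mass))
  for (s in names(x$length))
    cat(sprintf("  %-12s L=%.3f m  m=%.2f kg  com=%.3f  I=%.4f kg m^2\n",
                s, x$length[[s]], x$mass[[s]], x$com[[s]], x$inertia[[s]]))
  invisible(x)
}

## absolute segment angles (from vertical-down for thigh/shank, from horizontal
## for foot) as linear combinations of the joint columns; side in {"L","R"}
segment_angles <- function(theta, side) {
  j <- if (side == "L") 1:3 else 4:6
  th_h <- theta[, j[1]]; th_k <- theta[, j[2]]; th_a <- theta[, j[3]]
  list(thigh = th_h, shank = th_h - th_k, foot = th_h - th_k + th_a)
}

#' Planar forward kinematics of the seven-segment chain
#'
#' Maps joint angles to segment endpoint and centroid positions. The chain is
#' rooted at the pelvis (both sagittal hip centres coincide at the root);
#' an optional root trajectory translates the whole body.
#'
#' @param theta T x 6 joint angle matrix (radians), columns
#'   \code{hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R}
#' @param model an \code{\link{anthropometrics}} object
#' @param root optional T x 2 pelvis trajectory (m); default origin
#' @param trunk_angle optional length-T trunk lean from vertical (rad)
#' @return list with per-side joint points (\code{hip, knee, ankle, toe}, each
#'   T x 2), trunk top, and per-segment centroids \code{com} (named list of
#'   T x 2 matrices, keys like \code{thigh_L}, \code{pelvis_trunk})
#' @export
forward_kinematics <- function(theta, model, root = NULL, trunk_angle = NULL) {
  theta <- as.matrix(theta)
  stopifnot(ncol(theta) == 6L, all(is.finite(theta)))
  T_ <- nrow(theta)
  if (is.null(root)) root <- matrix(0, T_, 2L)
  if (is.null(trunk_angle)) trunk_angle <- rep(0, T_)
  L <- model$length; cm <- model$com
  out <- list(com = list())
  for (side in c("L", "R")) {
    a <- segment_angles(theta, side)
    hip <- root
    knee <- hip + L$thigh * cbind(sin(a$thigh), -cos(a$thigh))
    ankle <- knee + L$shank * cbind(sin(a$shank), -cos(a$shank))
    toe <- ankle + L$foot * cbind(cos(a$foot), sin(a$foot))
    out[[side]] <- list(hip = hip, knee = knee, ankle = ankle, toe = toe)
    out$com[[paste0("thigh_", side)]] <- hip + cm$thigh * (knee - hip)
    out$com[[paste0("shank_", side)]] <- knee + cm$shank * (ankle - knee)
    out$com[[paste0("foot_", side)]]  <- ankle + cm$foot * (toe - ankle)
  }
  top <- root + L$pelvis_trunk * cbind(sin(trunk_angle), cos(trunk_angle))
  out$trunk_top <- top
  out$com$pelvis_trunk <- root + cm$pelvis_trunk * (top - root)
  out$root <- root
  out$theta <- theta
  out
}

#' First and second finite-difference derivatives along time
#'
#' Central differences on interior samples with second-order one-sided stencils
#' at both boundaries, so results are exact for polynomials up to degree two.
#' A purely linear fixed-coefficient operation, hence transparent to the
#' automatic-differentiation tape.
#'
#' @param x T x k matrix (or vector)
#' @param dt sampling interval in seconds
#' @return list with elements \code{d1} and \code{d2}, same shape as \code{x}
#' @export
finite_diff <- function(x, dt) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  if (T_ < 3L) stop("finite_diff needs at least 3 samples, got ", T_)
  i <- 2:(T_ - 1L)
  d1 <- x * 0; d2 <- x * 0
  d1[i, ] <- (x[i + 1L, , drop = FALSE] - x[i - 1L, , drop = FALSE]) / (2 * dt)
  d1[1L, ] <- (-3 * x[1L, ] + 4 * x[2L, ] - x[3L, ]) / (2 * dt)
  d1[T_, ] <- (3 * x[T_, ] - 4 * x[T_ - 1L, ] + x[T_ - 2L, ]) / (2 * dt)
  d2[i, ] <- (x[i + 1L, , drop = FALSE] - 2 * x[i, , drop = FALSE] +
                x[i - 1L, , drop = FALSE]) / dt^2
  d2[1L, ] <- (x[1L, ] - 2 * x[2L, ] + x[3L, ]) / dt^2
  d2[T_, ] <- (x[T_, ] - 2 * x[T_ - 1L, ] + x[T_ - 2L, ]) / dt^2
  list(d1 = d1, d2 = d2)
}

#' Whole-body centre-of-mass chain
#'
#' Mass-weighted centroid of the seven segment centres, with velocity and
#' acceleration from central finite differences of the position series.
#'
#' @param fk output of \code{\link{forward_kinematics}}
#' @param model an \code{\link{anthropometrics}} object
#' @param dt sampling interval (s)
#' @return list \code{p_c}, \code{v_c}, \code{a_c} (each T x 2)
#' @export
com_chain <- function(fk, model, dt = 0.01) {
  m <- model$mass
  segw <- function(key) {
    base <- sub("_[LR]$", "", key)
    m[[base]]
  }
  keys <- names(fk$com)
  tot <- sum(vapply(keys, segw, 0))
  p <- Reduce(`+`, lapply(keys, function(k) segw(k) * fk$com[[k]])) / tot
  d <- finite_diff(p, dt)
  list(p_c = p, v_c = d$d1, a_c = d$d2)
}

#' Recursive Newton-Euler inverse dynamics (planar)
#'
#' Computes sagittal joint torques at the ankle, knee and hip of each side by
#' recursing from the feet upward: for every segment the proximal joint force
#' follows from Newton's second law and the proximal torque from the Euler
#' equation about the segment COM. The ground reaction force acts at a fixed
#' centre-of-pressure fraction of foot length; when no force is supplied the
#' dynamics are gravity-only and the result carries a \code{gravity_only}
#' attribute.
#'
#' @param fk output of \code{\link{forward_kinematics}}
#' @param model an \code{\link{anthropometrics}} object
#' @param dt sampling interval (s)
#' @param grf optional per-side external force: list with T x 2 matrices
#'   \code{L} and \code{R} (N); \code{NULL} for gravity-only dynamics
#' @param cop_frac centre-of-pressure location as fraction of foot length from
#'   the ankle
#' @return T x 6 torque matrix (N m), columns
#'   \code{hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R}
#' @export
inverse_dynamics <- function(fk, model, dt = 0.01, grf = NULL, cop_frac = 0.5) {
  theta <- fk$theta
  T_ <- nrow(theta)
  gravity_only <- is.null(grf)
  if (gravity_only) {
    warning("no ground reaction force supplied; gravity-only inverse dynamics")
    grf <- list(L = matrix(0, T_, 2L), R = matrix(0, T_, 2L))
  }
  cross2 <- function(r, f) r[, 1L] * f[, 2L] - r[, 2L] * f[, 1L]
  gvec <- cbind(rep(0, T_), rep(-GRAVITY, T_))
  tau <- matrix(0, T_, 6L, dimnames = list(NULL, JOINT_COLS))
  for (side in c("L", "R")) {
    ang <- segment_angles(theta, side)
    pts <- fk[[side]]
    segs <- list(
      foot  = list(P = pts$ankle, D = pts$toe,
                   com = fk$com[[paste0("foot_", side)]], ang = ang$foot),
      shank = list(P = pts$knee, D = pts$ankle,
                   com = fk$com[[paste0("shank_", side)]], ang = ang$shank),
      thigh = list(P = pts$hip, D = pts$knee,
                   com = fk$com[[paste0("thigh_", side)]], ang = ang$thigh))
    # external load at the COP, distal to the ankle along the foot
    cop <- pts$ankle + cop_frac * (pts$toe - pts$ankle)
    F_dist <- grf[[side]]
    P_dist <- cop
    tau_dist <- rep(0, T_)
    jn <- c(foot = "ankle", shank = "knee", thigh = "hip")
    for (s in names(segs)) {
      sg <- segs[[s]]
      m_s <- model$mass[[s]]; I_s <- model$inertia[[s]]
      a_com <- finite_diff(sg$com, dt)$d2
      alpha <- finite_diff(matrix(sg$ang), dt)$d2[, 1L]
      F_prox <- m_s * a_com - m_s * gvec - F_dist
      r_P <- sg$P - sg$com
      r_D <- P_dist - sg$com
      tau_prox <- I_s * alpha - tau_dist - cross2(r_P, F_prox) - cross2(r_D, F_dist)
      tau[, paste0(jn[[s]], "_", side)] <- tau_prox
      # reaction on the next (proximal) segment
      F_dist <- -F_prox
      P_dist <- sg$P
      tau_dist <- -tau_prox
    }
  }
  attr(tau, "gravity_only") <- gravity_only
  tau
}

#' Total mechanical energy
#'
#' \code{E(t) = 1/2 m |v_c|^2 + 1/2 sum_s I_s w_s^2 + m g h_c}: translational
#' kinetic energy of the whole-body COM, rotational kinetic energy of the
#' segments about their own centres, and gravitational potential energy of the
#' COM height above the chosen reference.
#'
#' @param v_c T x 2 COM velocity (m/s)
#' @param omega named list of length-T segment angular velocity vectors
#'   (rad/s); names must match anthropometric segments after stripping a
#'   \code{_L}/\code{_R} suffix. May be \code{NULL} (no rotational term).
#' @param h_c length-T COM height above reference (m)
#' @param model an \code{\link{anthropometrics}} object
#' @return length-T energy series (J)
#' @export
total_energy <- function(v_c, omega, h_c, model) {
  m <- model$total_mass
  E <- 0.5 * m * rowSums(as.matrix(v_c)^2) + m * GRAVITY * h_c
  if (!is.null(omega)) {
    for (k in names(omega)) {
      base <- sub("_[LR]$", "", k)
      E <- E + 0.5 * model$inertia[[base]] * omega[[k]]^2
    }
  }
  E
}

## ---- tape (differentiable) versions -------------------------------------

## central second-difference operator as a dense constant matrix acting on
## a T-row series; interior rows only ((T-2) x T)
second_diff_matrix <- function(T_, dt) {
  cached_matrix(sprintf("d2_%d_%.17g", T_, dt), function() {
    D <- matrix(0, T_ - 2L, T_)
    for (i in seq_len(T_ - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1) / dt^2
    D
  })
}

first_diff_matrix <- function(T_, dt) {
  cached_matrix(sprintf("d1_%d_%.17g", T_, dt), function() {
    D <- matrix(0, T_ - 2L, T_)
    for (i in seq_len(T_ - 2L)) D[i, c(i, i + 2L)] <- c(-1, 1) / (2 * dt)
    D
  })
}

#' Differentiable chain theta -> segment positions -> COM -> acceleration
#'
#' Builds the forward-kinematics / COM / finite-difference chain on an
#' autodiff tape so that gradients with respect to the joint-angle input
#' propagate end-to-end. Used by the dynamic and energy constraint losses and
#' by the gradient-correctness checks.
#'
#' @param tape an autodiff tape
#' @param th tape node holding T x 6 joint angles
#' @param model an \code{\link{anthropometrics}} object
#' @param dt sampling interval (s)
#' @return list of tape nodes: \code{p_c} (T x 2), \code{v_c}, \code{a_c}
#'   ((T-2) x 2, interior grid), \code{h_c} (T x 1) and per-side segment angle
#'   nodes
#' @keywords internal
biomech_chain_tape <- function(tape, th, model, dt = 0.01) {
  T_ <- nrow(th$value)
  L <- model$length; cm <- model$com; m <- model$mass
  tot <- m$pelvis_trunk + 2 * (m$thigh + m$shank + m$foot)
  zero <- ad_leaf(tape, matrix(0, T_, 1L))
  addw <- function(acc, nodexy, w) {
    sc <- list(ad_scale(tape, nodexy[[1]], w), ad_scale(tape, nodexy[[2]], w))
    if (is.null(acc)) sc else
      list(ad_add(tape, acc[[1]], sc[[1]]), ad_add(tape, acc[[2]], sc[[2]]))
  }
  seg_angles <- list()
  for (side in c("L", "R")) {
    j <- if (side == "L") 1:3 else 4:6
    th_h <- ad_cols(tape, th, j[1])
    th_k <- ad_cols(tape, th, j[2])
    th_a <- ad_cols(tape, th, j[3])
    a_thigh <- th_h
    a_shank <- ad_sub(tape, th_h, th_k)
    a_foot <- ad_add(tape, a_shank, th_a)
    seg_angles[[paste0("thigh_", side)]] <- a_thigh
    seg_angles[[paste0("shank_", side)]] <- a_shank
    seg_angles[[paste0("foot_", side)]] <- a_foot
    hip <- list(zero, zero)
    knee <- list(
      ad_scale(tape, ad_sin(tape, a_thigh), L$thigh),
      ad_scale(tape, ad_cos(tape, a_thigh), -L$thigh))
    ankle <- list(
      ad_add(tape, knee[[1]], ad_scale(tape, ad_sin(tape, a_shank), L$shank)),
      ad_add(tape, knee[[2]], ad_scale(tape, ad_cos(tape, a_shank), -L$shank)))
    toe <- list(
      ad_add(tape, ankle[[1]], ad_scale(tape, ad_cos(tape, a_foot), L$foot)),
      ad_add(tape, ankle[[2]], ad_scale(tape, ad_sin(tape, a_foot), L$foot)))
    lerp <- function(a, b, f)
      list(ad_add(tape, ad_scale(tape, a[[1]], 1 - f), ad_scale(tape, b[[1]], f)),
           ad_add(tape, ad_scale(tape, a[[2]], 1 - f), ad_scale(tape, b[[2]], f)))
    com_thigh <- lerp(hip, knee, cm$thigh)
    com_shank <- lerp(knee, ankle, cm$shank)
    com_foot <- lerp(ankle, toe, cm$foot)
    key <- paste0("segcom_", side)
    assign(key, list(thigh = com_thigh, shank = com_shank, foot = com_foot))
  }
  # trunk lean fixed at zero: trunk COM sits at a constant height above root
  trunk_com_y <- ad_leaf(tape, matrix(cm$pelvis_trunk * L$pelvis_trunk, T_, 1L))
  acc <- NULL
  for (side in c("L", "R")) {
    sc <- get(paste0("segcom_", side))
    acc <- addw(acc, sc$thigh, m$thigh / tot)
    acc <- addw(acc, sc$shank, m$shank / tot)
    acc <- addw(acc, sc$foot, m$foot / tot)
  }
  acc <- addw(acc, list(zero, trunk_com_y), m$pelvis_trunk / tot)
  p_c <- ad_cbind(tape, acc[[1]], acc[[2]])
  D2 <- ad_leaf(tape, second_diff_matrix(T_, dt))
  D1 <- ad_leaf(tape, first_diff_matrix(T_, dt))
  list(p_c = p_c,
       v_c = ad_matmul(tape, D1, p_c),
       a_c = ad_matmul(tape, D2, p_c),
       h_c = acc[[2]],
       seg_angles = seg_angles)
}
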