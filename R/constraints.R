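#' Differentiable physics-constraint losses
#'
#' The four biomechanical constraint penalties: kinematic feasibility (joint
#' limits plus trajectory smoothness), Newton-Euler dynamic consistency,
#' bilateral antiphase symmetry with fatigue-dependent relaxation, and
#' cyclic mechanical-energy balance with a learnable dissipation coefficient.
#' Every loss is nonnegative, exactly zero on its feasible input, and built
#' from autodiff-tape primitives so analytic gradients with respect to all
#' inputs (and the dissipation coefficient) are available.
#'
#' @name constraints
NULL

#' Constraint configuration
#'
#' Anatomical joint limits (hip flexion-extension within 35 degrees of
#' neutral, knee flexion 0-80 degrees one-sided, ankle within 30 degrees;
#' the hip abduction-adduction limit of 15 degrees is retained in the table
#' for an optional second hip DOF but unused by the sagittal default),
#' smoothness weight, dynamic sub-term weights, symmetry base weights and
#' decay, dissipation initialization and the denominator guard.
#'
#' @param kappa smoothness weight in the kinematic loss, default 0.1
#' @param kappa1 linear-momentum weight in the dynamic loss, default 0.5
#' @param kappa2 rotational weight in the dynamic loss, default 0.3
#' @param w_k0 base symmetry weights (length matches the feature count,
#'   default unit weights for the 6 joint-angle trajectories)
#' @param beta_sym fatigue decay rate of the symmetry weights, default 0.15
#' @param c0 dissipation coefficient initialization, default 0.05
#' @param eps denominator guard in the symmetry loss, default 1e-6
#' @return object of class \code{constraint_config}; \code{joint_limits} is a
#'   6 x 2 matrix of [min, max] radians in joint-column order
#' @export
constraint_config <- function(kappa = 0.1, kappa1 = 0.5, kappa2 = 0.3,
                              w_k0 = rep(1, 6), beta_sym = 0.15, c0 = 0.05,
                              eps = 1e-6) {
  stopifnot(kappa >= 0, kappa1 >= 0, kappa2 >= 0, beta_sym >= 0, c0 >= 0,
            all(w_k0 >= 0))
  deg <- pi / 180
  lim <- rbind(hip = c(-35, 35), knee = c(0, 80), ankle = c(-30, 30)) * deg
  joint_limits <- rbind(lim, lim)
  rownames(joint_limits) <- JOINT_COLS
  colnames(joint_limits) <- c("min", "max")
  structure(list(joint_limits = joint_limits,
                 hip_abduction_limit = 15 * deg,
                 kappa = kappa, kappa1 = kappa1, kappa2 = kappa2,
                 w_k0 = w_k0, beta_sym = beta_sym, c0 = c0, eps = eps),
            class = "constraint_config")
}

## second-difference operator without dt scaling (smoothness term)
smooth_diff_matrix <- function(T_) {
  cached_matrix(sprintf("sm_%d", T_), function() {
    D <- matrix(0, T_ - 2L, T_)
    for (i in seq_len(T_ - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
    D
  })
}

## ---- tape builders (inputs are tape nodes) ------------------------------

kinematic_loss_node <- function(tape, th, cfg) {
  T_ <- nrow(th$value)
  lim <- cfg$joint_limits[colnames(th$value) %||% JOINT_COLS, , drop = FALSE]
  hi <- ad_leaf(tape, matrix(lim[, "max"], 1L))
  lo <- ad_leaf(tape, matrix(lim[, "min"], 1L))
  over <- ad_relu(tape, ad_sub(tape, th, hi))
  under <- ad_relu(tape, ad_sub(tape, lo, th))
  loss <- ad_add(tape, ad_sumsq(tape, over), ad_sumsq(tape, under))
  if (cfg$kappa > 0 && T_ >= 3L) {
    D <- ad_leaf(tape, smooth_diff_matrix(T_))
    sm <- ad_sumsq(tape, ad_matmul(tape, D, th))
    loss <- ad_add(tape, loss, ad_scale(tape, sm, cfg$kappa))
  }
  loss
}

dynamic_loss_node <- function(tape, F_pred, a_c, m, cfg, F_meas = NULL,
                              tau_e = NULL, I_alpha = NULL,
                              gravity = GRAVITY) {
  T_ <- nrow(F_pred$value)
  d <- ncol(F_pred$value)
  gvec <- matrix(0, 1L, d)
  gvec[1L, d] <- -gravity * m            # last column is vertical
  loss <- NULL
  if (!is.null(F_meas)) {
    loss <- ad_sumsq(tape, ad_sub(tape, F_pred, F_meas))
  }
  # net external force (GRF + gravity) minus m * a_c
  Fnet <- ad_add(tape, F_pred, ad_leaf(tape, gvec))
  mom <- ad_sub(tape, Fnet, ad_scale(tape, a_c, m))
  mom_term <- ad_scale(tape, ad_sumsq(tape, mom), cfg$kappa1)
  loss <- if (is.null(loss)) mom_term else ad_add(tape, loss, mom_term)
  if (!is.null(tau_e) && !is.null(I_alpha)) {
    rot <- ad_scale(tape, ad_sumsq(tape, ad_sub(tape, tau_e, I_alpha)),
                    cfg$kappa2)
    loss <- ad_add(tape, loss, rot)
  }
  loss
}

## cyclic half-period shift on the 101-point grid: points 0 and 100 coincide,
## so the shift acts on the 100 distinct points
half_cycle_index <- function(T_ = 101L) {
  n <- T_ - 1L
  c(((seq_len(n) - 1L + n %/% 2L) %% n) + 1L, (n %/% 2L) + 1L)
}

symmetry_loss_node <- function(tape, xl, xr, y_f, cfg) {
  T_ <- nrow(xl$value)
  K <- ncol(xl$value)
  xr_s <- ad_rows(tape, xr, half_cycle_index(T_))
  den <- ad_add(tape, xl, xr_s)
  mask <- (abs(den$value) >= cfg$eps) + 0
  dsafe <- ad_add(tape, den, ad_leaf(tape, 1 - mask))
  ratio <- ad_mul(tape, ad_div(tape, ad_sub(tape, xl, xr_s), dsafe),
                  ad_leaf(tape, mask))
  w <- cfg$w_k0[seq_len(K)] * exp(-cfg$beta_sym * y_f)
  sq <- ad_square(tape, ratio)
  wsum <- ad_sum(tape, ad_mul(tape, sq, ad_leaf(tape, matrix(w, 1L))))
  attr(wsum, "skipped") <- sum(mask == 0)
  wsum
}

energy_loss_node <- function(tape, E, F_mag, c_node, dt, cycles) {
  T_ <- nrow(E$value)
  loss <- NULL
  for (cy in cycles) {
    ti <- cy[1]; tf <- cy[2]
    if (tf - ti < 1L) next
    n <- tf - ti + 1L
    w <- rep(dt, n); w[c(1L, n)] <- dt / 2   # trapezoid weights
    sel <- matrix(0, 1L, T_); sel[1L, ti:tf] <- w
    imp <- ad_matmul(tape, ad_leaf(tape, sel), F_mag)
    wd <- ad_mul(tape, c_node, imp)
    ei <- matrix(0, 1L, T_); ei[1L, ti] <- -1; ei[1L, tf] <- 1
    dE <- ad_matmul(tape, ad_leaf(tape, ei), E)    # E(tf) - E(ti)
    res <- ad_square(tape, ad_add(tape, dE, wd))
    loss <- if (is.null(loss)) res else ad_add(tape, loss, res)
  }
  if (is.null(loss)) {
    warning("no cycle with at least 2 samples; energy loss is zero")
    loss <- ad_leaf(tape, matrix(0, 1L, 1L))
  }
  loss
}

## ---- public numeric wrappers --------------------------------------------

#' Kinematic constraint loss
#'
#' Hinge-squared penalty for excursions outside the anatomical interval
#' limits (the one-sided knee range generalizes the symmetric form) plus a
#' smoothness penalty on discrete second differences weighted by
#' \code{kappa}.
#'
#' @param theta T x J joint angles (radians); columns matched to the limit
#'   table by name, defaulting to the canonical six-joint order
#' @param cfg a \code{\link{constraint_config}}
#' @param grad if TRUE also return the analytic gradient wrt \code{theta}
#' @return list: \code{value}, \code{max_violation} (rad),
#'   \code{violating_fraction}, optionally \code{grad_theta}
#' @export
kinematic_loss <- function(theta, cfg = constraint_config(), grad = FALSE) {
  theta <- as.matrix(theta)
  tape <- ad_tape()
  th <- ad_leaf(tape, theta)
  loss <- kinematic_loss_node(tape, th, cfg)
  lim <- cfg$joint_limits[colnames(theta) %||% JOINT_COLS, , drop = FALSE]
  over <- sweep(theta, 2L, lim[, "max"], `-`)
  under <- sweep(-theta, 2L, -lim[, "min"], `-`)
  viol <- pmax(over, under, 0)
  out <- list(value = loss$value[1L], max_violation = max(viol),
              violating_fraction = mean(viol > 0))
  if (grad) {
    ad_backward(tape, loss)
    out$grad_theta <- th$grad
  }
  out
}

#' Dynamic (Newton-Euler) constraint loss
#'
#' Three residuals: predicted-versus-measured ground reaction force (masked
#' out when no measurement is available, e.g. at inference), linear-momentum
#' balance \code{|F_g + m g - m a_c|^2} weighted by \code{kappa1}, and the
#' rotational balance \code{|tau_e - I alpha|^2} weighted by \code{kappa2}
#' (skipped when the rotational quantities are not supplied).
#'
#' @param F_pred T x d predicted external force (last column vertical, N)
#' @param a_c T x d centre-of-mass acceleration (m/s^2)
#' @param m body mass (kg)
#' @param cfg a \code{\link{constraint_config}}
#' @param F_meas optional T x d measured force
#' @param tau_e optional length-T net external moment about the COM (N m)
#' @param I_alpha optional length-T whole-body inertia times angular
#'   acceleration (N m)
#' @param grad if TRUE also return analytic gradients wrt \code{F_pred} and
#'   \code{a_c}
#' @return list: \code{value}, per-term diagnostics, optional gradients
#' @export
dynamic_loss <- function(F_pred, a_c, m, cfg = constraint_config(),
                         F_meas = NULL, tau_e = NULL, I_alpha = NULL,
                         grad = FALSE) {
  F_pred <- as.matrix(F_pred); a_c <- as.matrix(a_c)
  if (!all(dim(F_pred) == dim(a_c)))
    stop("F_pred and a_c must have identical shape")
  if (!is.null(F_meas) && !all(dim(as.matrix(F_meas)) == dim(F_pred)))
    stop("F_meas shape mismatch")
  tape <- ad_tape()
  Fp <- ad_leaf(tape, F_pred)
  ac <- ad_leaf(tape, a_c)
  Fm <- if (!is.null(F_meas)) ad_leaf(tape, as.matrix(F_meas))
  te <- if (!is.null(tau_e)) ad_leaf(tape, matrix(tau_e))
  ia <- if (!is.null(I_alpha)) ad_leaf(tape, matrix(I_alpha))
  loss <- dynamic_loss_node(tape, Fp, ac, m, cfg, F_meas = Fm,
                            tau_e = te, I_alpha = ia)
  out <- list(value = loss$value[1L])
  if (grad) {
    ad_backward(tape, loss)
    out$grad_F_pred <- Fp$grad
    out$grad_a_c <- ac$grad
  }
  out
}

#' Bilateral symmetry constraint loss
#'
#' Penalizes the squared normalized difference between left-side trajectories
#' and the right-side trajectories cyclically shifted by half a cycle on the
#' 101-point grid, with per-feature weights decayed as
#' \code{w_k0 exp(-beta y_f)} so the constraint relaxes with fatigue. Time
#' points where both sides are near zero (|denominator| below the guard) are
#' skipped and counted.
#'
#' @param x_left,x_right T x K series on the cycle grid (default use: the 6
#'   joint-angle trajectories)
#' @param y_f fatigue level 0-4
#' @param cfg a \code{\link{constraint_config}}
#' @param grad if TRUE also return analytic gradients
#' @return list: \code{value}, \code{n_skipped}, optional gradients
#' @export
symmetry_loss <- function(x_left, x_right, y_f, cfg = constraint_config(),
                          grad = FALSE) {
  xl <- as.matrix(x_left); xr <- as.matrix(x_right)
  stopifnot(all(dim(xl) == dim(xr)))
  if (!y_f %in% 0:4) stop("fatigue level must be in 0..4, got ", y_f)
  tape <- ad_tape()
  nl <- ad_leaf(tape, xl); nr <- ad_leaf(tape, xr)
  loss <- symmetry_loss_node(tape, nl, nr, y_f, cfg)
  out <- list(value = loss$value[1L], n_skipped = attr(loss, "skipped"))
  if (grad) {
    ad_backward(tape, loss)
    out$grad_left <- nl$grad
    out$grad_right <- nr$grad
  }
  out
}

#' Cyclic energy-balance constraint loss
#'
#' For each gait cycle the residual \code{E(t_f) + W_d - E(t_i)} must vanish,
#' where the dissipated work \code{W_d = c * trapz(|F_g|) } is proportional
#' to the cumulative force impulse with learnable coefficient \code{c}. The
#' loss is the sum of squared residuals over cycles; cycles shorter than two
#' samples are skipped with a warning.
#'
#' @param E length-T mechanical energy series (J)
#' @param F_mag length-T ground-reaction-force magnitude series (N)
#' @param dt sampling interval (s)
#' @param c dissipation coefficient (learnable scalar)
#' @param cycles list of integer pairs \code{c(start, end)} delimiting cycles
#' @param grad if TRUE also return gradients wrt \code{E}, \code{F_mag} and
#'   \code{c}
#' @return list: \code{value}, optional \code{grad_E}, \code{grad_F},
#'   \code{grad_c}
#' @export
energy_loss <- function(E, F_mag, dt, c = 0.05,
                        cycles = list(c(1L, length(E))), grad = FALSE) {
  tape <- ad_tape()
  En <- ad_leaf(tape, matrix(E))
  Fn <- ad_leaf(tape, matrix(F_mag))
  cn <- ad_leaf(tape, matrix(c, 1L, 1L))
  loss <- energy_loss_node(tape, En, Fn, cn, dt, cycles)
  out <- list(value = loss$value[1L])
  if (grad) {
    ad_backward(tape, loss)
    out$grad_E <- En$grad[, 1L]
    out$grad_F <- Fn$grad[, 1L]
    out$grad_c <- if (!is.null(cn$grad)) cn$grad[1L] else 0
  }
  out
}

#' Fit the dissipation coefficient to observed energy profiles
#'
#' Gradient-descent recovery of the dissipation coefficient \code{c} from
#' per-cycle energy and force series, using the analytic gradient of the
#' energy-balance loss. With data generated under a true coefficient the
#' minimizer converges to it.
#'
#' @param E_list list of per-cycle energy series
#' @param F_list list of matching force-magnitude series
#' @param dt sampling interval (s)
#' @param c_init starting value
#' @param steps gradient steps
#' @param lr learning rate (scaled internally by the mean squared impulse)
#' @return list: \code{c} fitted coefficient, \code{trace} per-step values
#' @export
fit_dissipation <- function(E_list, F_list, dt, c_init = 0.05, steps = 500,
                            lr = 0.05) {
  imp <- vapply(seq_along(F_list), function(i) {
    f <- F_list[[i]]; n <- length(f)
    w <- rep(dt, n); w[c(1L, n)] <- dt / 2
    sum(w * f)
  }, 0)
  scale <- mean(imp^2)
  cc <- c_init
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    g <- 0
    for (i in seq_along(E_list)) {
      el <- energy_loss(E_list[[i]], F_list[[i]], dt, c = cc, grad = TRUE)
      g <- g + el$grad_c
    }
    cc <- cc - lr * g / (length(E_list) * scale)
    trace[s] <- cc
  }
  list(c = cc, trace = trace)
}
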