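# Independent oracles used across the suite. These never call the package's
# own differentiable/tape code paths: finite differences, closed forms and
# textbook formulas only.

# central finite-difference gradient of f at matrix x (tape-independent)
fd_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  den <- max(abs(a), abs(b), 1e-8)
  max(abs(a - b)) / den
}

# closed-form planar two-link pendulum inverse dynamics (Lagrangian form):
# link i has length L[i], point masses are replaced by distributed segments
# with COM at r[i]*L[i] from the proximal joint, mass m[i], inertia I[i]
# about the COM. Angles q are absolute from vertical-down, gravity g down.
# Returns torques at the two proximal joints given q, qd, qdd trajectories
# evaluated at one instant.
lagrangian_two_link <- function(q, qd, qdd, L, m, r, I, g = 9.81) {
  a1 <- q[1]; a2 <- q[2]
  c1 <- r[1] * L[1]; c2 <- r[2] * L[2]
  # mass matrix in absolute-angle coordinates
  M11 <- I[1] + m[1] * c1^2 + m[2] * L[1]^2
  M12 <- m[2] * L[1] * c2 * cos(a1 - a2)
  M22 <- I[2] + m[2] * c2^2
  # velocity (Coriolis/centrifugal) terms
  h <- m[2] * L[1] * c2 * sin(a1 - a2)
  C1 <- h * qd[2]^2
  C2 <- -h * qd[1]^2
  # gravity terms (potential: -cos(angle) height convention, angle from
  # vertical-down, x forward = sin, y = -cos)
  G1 <- (m[1] * c1 + m[2] * L[1]) * g * sin(a1)
  G2 <- m[2] * c2 * g * sin(a2)
  tau1_abs <- M11 * qdd[1] + M12 * qdd[2] + C1 + G1
  tau2_abs <- M12 * qdd[1] + M22 * qdd[2] + C2 + G2
  # joint torques: proximal joint carries both; distal joint the second only
  c(tau1 = tau1_abs + tau2_abs, tau2 = tau2_abs)
}

# RK4 integrator for a frictionless planar pendulum (single link, absolute
# angle from vertical-down): qdd = -(m g c / J) sin(q)
rk4_pendulum <- function(q0, qd0, J, mgc, dt, n) {
  f <- function(s) c(s[2], -(mgc / J) * sin(s[1]))
  out <- matrix(NA_real_, n, 2L)
  s <- c(q0, qd0)
  for (i in seq_len(n)) {
    out[i, ] <- s
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

# digital magnitude response of a filter (b, a) at frequency f (Hz)
filter_mag_response <- function(b, a, f, rate) {
  w <- 2 * pi * f / rate
  z <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * w * (seq_along(a) - 1))
  den <- sum(a * z)
  Mod(num / den)
}

# tiny cohort cached per test session (built once, reused across files)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(n_subjects = 2, cycles_per_level = 4,
                                seed = 421, fatigue_levels = c(0, 2, 4))
    cache
  }
})
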