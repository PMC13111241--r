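test_that("each constraint loss vanishes on its analytically feasible input", {
  cfg <- constraint_config()
  # kinematic: within-limits linear trajectories (zero second differences)
  th <- matrix(seq(-0.2, 0.2, length.out = 50), 50, 6,
               dimnames = list(NULL, pigait:::JOINT_COLS))
  th[, "knee_L"] <- th[, "knee_R"] <- seq(0.1, 0.5, length.out = 50)
  expect_lte(kinematic_loss(th, cfg)$value, 1e-10)
  # dynamic: ballistic segment, F = 0 and a_c = g downward
  T_ <- 30
  Fp <- matrix(0, T_, 3)
  ac <- cbind(0, 0, rep(-9.81, T_))
  expect_lte(dynamic_loss(Fp, ac, m = 70, cfg)$value, 1e-10)
  # symmetry: perfect antiphase bilateral pair on the 101-point grid
  phi <- seq(0, 1, length.out = 101)
  xl <- cbind(sin(2 * pi * phi), cos(2 * pi * phi) + 2)
  xr <- xl[c(51:100, 1:50, 51), ]   # right = left advanced half a cycle
  expect_lte(symmetry_loss(xl, xr, y_f = 0, cfg)$value, 1e-10)
  # energy: conservative cycle with c = 0
  E <- 700 + 5 * sin(2 * pi * phi)
  E[101] <- E[1]
  expect_lte(energy_loss(E, rep(700, 101), dt = 0.01, c = 0)$value, 1e-10)
})

test_that("kinematic loss evaluates the printed hinge and smoothness forms", {
  cfg <- constraint_config(kappa = 0)
  th <- matrix(0, 20, 6, dimnames = list(NULL, pigait:::JOINT_COLS))
  lim <- cfg$joint_limits["hip_L", "max"]
  th[7, "hip_L"] <- lim + 0.1
  r <- kinematic_loss(th, cfg)
  expect_equal(r$value, 0.01, tolerance = 1e-12)
  expect_equal(r$max_violation, 0.1, tolerance = 1e-12)
  # knee range is one-sided: a negative knee angle violates at zero
  th2 <- matrix(0, 20, 6, dimnames = list(NULL, pigait:::JOINT_COLS))
  th2[3, "knee_R"] <- -0.2
  expect_equal(kinematic_loss(th2, cfg)$value, 0.04, tolerance = 1e-12)
  # smoothness: kappa * sum of squared second differences, loop oracle
  cfg2 <- constraint_config(kappa = 0.1)
  ths <- matrix(0.2 * sin(seq(0, 3, length.out = 40)), 40, 6,
                dimnames = list(NULL, pigait:::JOINT_COLS))
  oracle <- 0
  for (j in 1:6) for (t in 2:39)
    oracle <- oracle + (ths[t + 1, j] - 2 * ths[t, j] + ths[t - 1, j])^2
  expect_equal(kinematic_loss(ths, cfg2)$value, 0.1 * unname(oracle),
               tolerance = 1e-12)
})

test_that("dynamic loss reproduces closed-form residuals and weight scaling", {
  cfg <- constraint_config()
  T_ <- 25
  set.seed(31)
  Fm <- matrix(rnorm(T_ * 3, 0, 50), T_, 3)
  delta <- c(3, -2, 5)
  Fp <- Fm + matrix(delta, T_, 3, byrow = TRUE)
  m <- 70
  # make momentum and rotation terms exactly consistent so only the
  # measurement term remains
  ac <- sweep(Fp, 2, c(0, 0, -m * 9.81), `+`) / m
  r <- dynamic_loss(Fp, ac, m, cfg, F_meas = Fm)
  expect_equal(r$value, T_ * sum(delta^2), tolerance = 1e-9)
  # doubling kappa1 doubles exactly the momentum term
  ac2 <- ac + 0.5
  r1 <- dynamic_loss(Fp, ac2, m, cfg, F_meas = Fm)
  cfg2 <- constraint_config(kappa1 = 2 * cfg$kappa1)
  r2 <- dynamic_loss(Fp, ac2, m, cfg2, F_meas = Fm)
  mom <- r1$value - T_ * sum(delta^2)
  expect_equal(r2$value - T_ * sum(delta^2), 2 * mom, tolerance = 1e-8)
  # rotational term: tau_e = I alpha gives no extra cost
  te <- rnorm(T_); ia <- te
  r3 <- dynamic_loss(Fp, ac, m, cfg, F_meas = Fm, tau_e = te, I_alpha = ia)
  expect_equal(r3$value, r$value, tolerance = 1e-9)
  expect_error(dynamic_loss(Fp, ac[1:10, ], m, cfg), "shape")
})

test_that("symmetry loss decays as exp(-0.15 y_f) and respects zero weights", {
  cfg <- constraint_config()
  set.seed(5)
  xl <- matrix(rnorm(101 * 6, 2, 0.3), 101, 6)
  xr <- matrix(rnorm(101 * 6, 2.4, 0.3), 101, 6)
  l0 <- symmetry_loss(xl, xr, y_f = 0, cfg)$value
  l4 <- symmetry_loss(xl, xr, y_f = 4, cfg)$value
  expect_equal(l4 / l0, exp(-0.6), tolerance = 1e-9)
  # monotone nonincreasing across levels
  ls <- vapply(0:4, function(y) symmetry_loss(xl, xr, y, cfg)$value, 0)
  expect_true(all(diff(ls) < 0))
  cfg0 <- constraint_config(w_k0 = rep(0, 6))
  expect_equal(symmetry_loss(xl, xr, 2, cfg0)$value, 0)
  # near-zero denominators are skipped, not infinite
  xz <- matrix(0, 101, 1); xz[3, 1] <- 1e-9
  r <- symmetry_loss(xz, -xz, 1, cfg)
  expect_true(is.finite(r$value))
  expect_gt(r$n_skipped, 0)
})

test_that("energy loss matches the constructed-dissipation fixture", {
  dt <- 0.01
  T_ <- 101
  Fmag <- rep(100, T_)
  impulse <- pigait:::trapz((0:100) * dt, Fmag)
  expect_equal(impulse, 100, tolerance = 1e-9)   # 100 N over 1 s
  c_true <- 0.05
  E <- seq(500, 500 - c_true * impulse, length.out = T_)
  expect_lte(energy_loss(E, Fmag, dt, c = c_true)$value, 1e-18)
  r0 <- energy_loss(E, Fmag, dt, c = 0)
  expect_equal(r0$value, (c_true * impulse)^2, tolerance = 1e-9)
  expect_warning(energy_loss(E[1], Fmag[1], dt, c = 0.05,
                             cycles = list(c(1L, 1L))), "2 samples")
})

test_that("analytic gradients of all four losses match finite differences", {
  cfg <- constraint_config()
  set.seed(41)
  # kinematic wrt theta
  th <- matrix(rnorm(10 * 6, 0, 0.6), 10, 6,
               dimnames = list(NULL, pigait:::JOINT_COLS))
  g <- kinematic_loss(th, cfg, grad = TRUE)$grad_theta
  gn <- fd_gradient(function(m) {
    colnames(m) <- pigait:::JOINT_COLS
    kinematic_loss(m, cfg)$value
  }, th)
  expect_lt(rel_err(g, gn), 1e-6)
  # dynamic wrt F_pred and a_c
  T_ <- 12
  Fp <- matrix(rnorm(T_ * 3), T_, 3)
  Fm <- matrix(rnorm(T_ * 3), T_, 3)
  ac <- matrix(rnorm(T_ * 3), T_, 3)
  te <- rnorm(T_); ia <- rnorm(T_)
  rd <- dynamic_loss(Fp, ac, 2, cfg, F_meas = Fm, tau_e = te, I_alpha = ia,
                     grad = TRUE)
  expect_lt(rel_err(rd$grad_F_pred, fd_gradient(function(m)
    dynamic_loss(m, ac, 2, cfg, F_meas = Fm, tau_e = te,
                 I_alpha = ia)$value, Fp)), 1e-6)
  expect_lt(rel_err(rd$grad_a_c, fd_gradient(function(m)
    dynamic_loss(Fp, m, 2, cfg, F_meas = Fm, tau_e = te,
                 I_alpha = ia)$value, ac)), 1e-6)
  # symmetry wrt both sides
  xl <- matrix(rnorm(101 * 2, 3, 0.4), 101, 2)
  xr <- matrix(rnorm(101 * 2, 3, 0.4), 101, 2)
  rs <- symmetry_loss(xl, xr, 2, cfg, grad = TRUE)
  expect_lt(rel_err(rs$grad_left, fd_gradient(function(m)
    symmetry_loss(m, xr, 2, cfg)$value, xl)), 1e-5)
  expect_lt(rel_err(rs$grad_right, fd_gradient(function(m)
    symmetry_loss(xl, m, 2, cfg)$value, xr)), 1e-5)
  # energy wrt E, F and c
  E <- 600 + cumsum(rnorm(60, 0, 0.5))
  Fmag <- abs(rnorm(60, 90, 5))
  re <- energy_loss(E, Fmag, 0.01, c = 0.04, grad = TRUE)
  expect_lt(rel_err(re$grad_E, fd_gradient(function(m)
    energy_loss(m[, 1], Fmag, 0.01, c = 0.04)$value, matrix(E))), 1e-5)
  expect_lt(rel_err(re$grad_c, (energy_loss(E, Fmag, 0.01, c = 0.04 + 1e-6)$value -
    energy_loss(E, Fmag, 0.01, c = 0.04 - 1e-6)$value) / 2e-6), 1e-5)
})

test_that("gradient descent on the energy loss recovers the dissipation
           coefficient from synthetic cycles", {
  set.seed(53)
  c_true <- 0.05
  E_list <- list(); F_list <- list()
  for (k in 1:20) {
    T_ <- 101; dt <- 0.01
    Fmag <- 650 + 80 * sin(2 * pi * seq(0, 1, length.out = T_)) +
      rnorm(T_, 0, 10)
    w <- rep(dt, T_); w[c(1, T_)] <- dt / 2
    imp <- sum(w * Fmag)
    drop <- c_true * imp * (1 + rnorm(1, 0, 0.05))   # 5% cycle noise
    E_list[[k]] <- seq(720, 720 - drop, length.out = T_) + rnorm(T_, 0, 0.1)
    F_list[[k]] <- Fmag
  }
  fit <- fit_dissipation(E_list, F_list, dt = 0.01, c_init = 0.02,
                         steps = 500)
  expect_lt(abs(fit$c - c_true) / c_true, 0.2)
})
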