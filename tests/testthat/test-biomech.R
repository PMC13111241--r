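test_that("anthropometric scaling closes mass and follows the table", {
  am <- anthropometrics(1.80, 75)
  # seven segments: bilateral limbs count twice, trunk absorbs the residual
  total <- am$mass$pelvis_trunk +
    2 * (am$mass$foot + am$mass$shank + am$mass$thigh)
  expect_equal(total, 75, tolerance = 1e-9)
  tab <- read.csv(system.file("extdata", "segment_parameters.csv",
                              package = "pigait"), comment.char = "#")
  expect_equal(am$length$thigh,
               tab$length_frac[tab$segment == "thigh"] * 1.80)
  # homogeneity: doubling mass doubles segment masses and inertias
  am2 <- anthropometrics(1.80, 75 * 1.5)
  for (s in names(am$mass)) {
    expect_equal(am2$mass[[s]], 1.5 * am$mass[[s]], tolerance = 1e-9)
    expect_equal(am2$inertia[[s]], 1.5 * am$inertia[[s]], tolerance = 1e-9)
  }
  expect_error(anthropometrics(1.0, 70), "height")
  expect_error(anthropometrics(1.7, 20), "mass")
})

test_that("forward kinematics honours the reference posture and trigonometry", {
  am <- anthropometrics(1.72, 68)
  th0 <- matrix(0, 3, 6, dimnames = list(NULL, pigait:::JOINT_COLS))
  fk <- forward_kinematics(th0, am)
  # zero angles: knee directly below the hip at thigh length
  expect_equal(fk$L$knee[1, ], c(0, -am$length$thigh), tolerance = 1e-12)
  expect_equal(fk$L$ankle[1, ],
               c(0, -(am$length$thigh + am$length$shank)), tolerance = 1e-12)
  # two-link check: hip 30 deg, knee 0 -> straight leg rotated 30 deg forward
  th <- th0; th[, "hip_L"] <- 30 * pi / 180
  fk2 <- forward_kinematics(th, am)
  L2 <- am$length$thigh + am$length$shank
  expect_equal(fk2$L$ankle[1, ], c(L2 * sin(pi / 6), -L2 * cos(pi / 6)),
               tolerance = 1e-12)
  # rigid-length invariant under random angles
  set.seed(4)
  thr <- matrix(rnorm(60, 0, 0.5), 10, 6,
                dimnames = list(NULL, pigait:::JOINT_COLS))
  fkr <- forward_kinematics(thr, am)
  for (side in c("L", "R")) {
    dk <- sqrt(rowSums((fkr[[side]]$knee - fkr[[side]]$hip)^2))
    da <- sqrt(rowSums((fkr[[side]]$ankle - fkr[[side]]$knee)^2))
    expect_lt(max(abs(dk - am$length$thigh)), 1e-9)
    expect_lt(max(abs(da - am$length$shank)), 1e-9)
  }
})

test_that("finite differences are exact on polynomials and O(dt^2) on sine", {
  tt <- seq(0, 1, by = 0.01)
  lin <- 2 + 3 * tt
  d <- finite_diff(lin, 0.01)
  expect_equal(d$d1[, 1], rep(3, length(tt)), tolerance = 1e-9)
  expect_equal(d$d2[, 1], rep(0, length(tt)), tolerance = 1e-6)
  quad <- 1 - 2 * tt + 4 * tt^2
  dq <- finite_diff(quad, 0.01)
  expect_equal(dq$d2[, 1], rep(8, length(tt)), tolerance = 1e-6)
  expect_error(finite_diff(1:2, 0.01), "at least 3")
  # convergence order on sin(2 pi t)
  errs <- vapply(c(0.01, 0.005), function(dt) {
    t2 <- seq(0, 1, by = dt)
    d1 <- finite_diff(sin(2 * pi * t2), dt)$d1[, 1]
    max(abs(d1 - 2 * pi * cos(2 * pi * t2)))
  }, 0)
  ratio <- errs[1] / errs[2]
  expect_gt(ratio, 3)   # halving dt should shrink error ~4x
  expect_lt(ratio, 5)
})

test_that("COM chain recovers centroids and constructed accelerations", {
  am <- anthropometrics(1.72, 68)
  th0 <- matrix(0, 50, 6, dimnames = list(NULL, pigait:::JOINT_COLS))
  # uniformly accelerating root: p = 0.5 a t^2, a = (1.3, -2.1)
  tt <- (0:49) * 0.01
  a_true <- c(1.3, -2.1)
  root <- cbind(0.5 * a_true[1] * tt^2, 0.5 * a_true[2] * tt^2)
  fk <- forward_kinematics(th0, am, root = root)
  cc <- com_chain(fk, am, dt = 0.01)
  expect_lt(max(abs(sweep(cc$a_c, 2, a_true))), 1e-6)
  # static posture: COM is the mass-weighted centroid, manually recomputed
  fks <- forward_kinematics(th0[1, , drop = FALSE], am)
  w <- vapply(names(fks$com), function(k)
    am$mass[[sub("_[LR]$", "", k)]], 0)
  manual <- Reduce(`+`, Map(function(k, wt) wt * fks$com[[k]],
                            names(fks$com), w)) / sum(w)
  ccs <- com_chain(forward_kinematics(th0, am), am)
  expect_equal(ccs$p_c[1, ], manual[1, ], tolerance = 1e-12)
})

test_that("static inverse dynamics matches hand-computed moment arms", {
  am <- anthropometrics(1.72, 68)
  th <- matrix(0, 20, 6, dimnames = list(NULL, pigait:::JOINT_COLS))
  th[, "hip_L"] <- 0.3  # left leg held forward, stationary
  fk <- forward_kinematics(th, am)
  tau <- suppressWarnings(inverse_dynamics(fk, am, dt = 0.01))
  # gravity-only statics: the hip torque balances the summed gravity moments
  # of the leg segments about the hip (positive to hold the leg forward)
  hip <- fk$L$hip[1, ]
  arm <- function(p) p[1] - hip[1]
  tau_hand <- 9.81 * (am$mass$thigh * arm(fk$com$thigh_L[1, ]) +
                      am$mass$shank * arm(fk$com$shank_L[1, ]) +
                      am$mass$foot * arm(fk$com$foot_L[1, ]))
  expect_equal(unname(tau[10, "hip_L"]), tau_hand,
               tolerance = 1e-6 * abs(tau_hand))
  # no gravity load (vanishing masses), no motion, no external force: zero
  am0 <- am
  for (s in names(am0$mass)) {
    am0$mass[[s]] <- 1e-12
    am0$inertia[[s]] <- 1e-15
  }
  tau0 <- suppressWarnings(
    inverse_dynamics(forward_kinematics(matrix(0, 20, 6,
      dimnames = list(NULL, pigait:::JOINT_COLS)), am0), am0))
  expect_lt(max(abs(tau0[10, ])), 1e-9)
})

test_that("recursive Newton-Euler agrees with the Lagrangian two-link oracle", {
  # pure two-link instances: the foot's mass and inertia are nulled so the
  # swing chain is exactly thigh + shank, for which the closed-form
  # Lagrangian dynamics are the independent oracle
  am <- anthropometrics(1.72, 68)
  am$mass$foot <- 1e-12
  am$inertia$foot <- 1e-15
  L <- c(am$length$thigh, am$length$shank)
  m <- c(am$mass$thigh, am$mass$shank)
  r <- c(am$com$thigh, am$com$shank)
  I <- c(am$inertia$thigh, am$inertia$shank)
  dt <- 5e-4
  tt <- seq(0, 0.1, by = dt)
  set.seed(17)
  for (trial in 1:8) {
    a <- runif(2, 0.2, 0.5); b <- runif(2, 0.5, 1.5); ph <- runif(2, 0, 2 * pi)
    q1 <- a[1] * sin(b[1] * tt + ph[1])
    q2 <- a[2] * sin(b[2] * tt + ph[2])
    th <- matrix(0, length(tt), 6, dimnames = list(NULL, pigait:::JOINT_COLS))
    th[, "hip_L"] <- q1
    th[, "knee_L"] <- q1 - q2   # knee angle = hip minus shank absolute angle
    fk <- forward_kinematics(th, am)
    tau <- suppressWarnings(inverse_dynamics(fk, am, dt = dt))
    mid <- round(length(tt) / 2)
    qd <- b * a * cos(b * tt[mid] + ph)
    qdd <- -b^2 * a * sin(b * tt[mid] + ph)
    ora <- lagrangian_two_link(c(q1[mid], q2[mid]), qd, qdd, L, m, r, I)
    scale <- max(abs(ora), 1e-3)
    expect_lt(abs(tau[mid, "hip_L"] - ora["tau1"]) / scale, 1e-5)
    expect_lt(abs(tau[mid, "knee_L"] - ora["tau2"]) / scale, 1e-5)
  }
})

test_that("total mechanical energy matches closed forms and is conserved", {
  am <- anthropometrics(1.72, 68)
  # at rest at height h: E = m g h
  T_ <- 10
  E <- total_energy(matrix(0, T_, 2), NULL, rep(1.1, T_), am)
  expect_equal(E, rep(68 * 9.81 * 1.1, T_), tolerance = 1e-9)
  # pure translation at speed v, reference height 0
  v <- 1.7
  E2 <- total_energy(cbind(rep(v, T_), 0), NULL, rep(0, T_), am)
  expect_equal(E2, rep(0.5 * 68 * v^2, T_), tolerance = 1e-9)
  # adding a constant reference height shifts E by exactly m g dh
  E3 <- total_energy(cbind(rep(v, T_), 0), NULL, rep(0.25, T_), am)
  expect_equal(E3 - E2, rep(68 * 9.81 * 0.25, T_), tolerance = 1e-9)
  # frictionless pendulum: energy constant along an RK4 trajectory
  J <- am$inertia$shank + am$mass$shank * (am$com$shank * am$length$shank)^2
  mgc <- am$mass$shank * 9.81 * am$com$shank * am$length$shank
  dt <- 0.001
  traj <- rk4_pendulum(0.6, 0, J, mgc, dt, 2000)
  # feed kinematics in: COM velocity and height from the angle series
  cfrac <- am$com$shank * am$length$shank
  vx <- cfrac * cos(traj[, 1]) * traj[, 2]
  vy <- cfrac * sin(traj[, 1]) * traj[, 2]
  hc <- -cfrac * cos(traj[, 1])
  m_eff <- am$mass$shank
  E_t <- 0.5 * m_eff * (vx^2 + vy^2) +
    0.5 * am$inertia$shank * traj[, 2]^2 + m_eff * 9.81 * hc
  expect_lt(diff(range(E_t)), 1e-6 * max(abs(E_t)))
})

test_that("the differentiable chain matches the numeric chain and its
           gradients match finite differences", {
  am <- anthropometrics(1.72, 68)
  set.seed(23)
  T_ <- 12
  th0 <- matrix(rnorm(T_ * 6, 0, 0.3), T_, 6,
                dimnames = list(NULL, pigait:::JOINT_COLS))
  dt <- 0.01
  tape <- ad_tape()
  thn <- pigait:::ad_leaf(tape, th0)
  chain <- pigait:::biomech_chain_tape(tape, thn, am, dt)
  # values agree with the plain numeric path
  fk <- forward_kinematics(th0, am)
  cc <- com_chain(fk, am, dt)
  expect_lt(max(abs(chain$p_c$value - cc$p_c)), 1e-10)
  expect_lt(max(abs(chain$a_c$value - cc$a_c[2:(T_ - 1), ])), 1e-8)
  # gradient of a scalar functional of a_c w.r.t. theta
  loss <- ad_sumsq(tape, chain$a_c)
  pigait:::ad_backward(tape, loss)
  f <- function(m) {
    fk2 <- forward_kinematics(m, am)
    sum(com_chain(fk2, am, dt)$a_c[2:(T_ - 1), ]^2)
  }
  gn <- fd_gradient(f, th0, eps = 1e-6)
  expect_lt(rel_err(thn$grad, gn), 1e-4)
})
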