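make_input <- function(seed = 1, cfg = model_config("tiny")) {
  set.seed(seed)
  matrix(rnorm(101 * cfg$n_sensors * cfg$n_channels), 101,
         cfg$n_sensors * cfg$n_channels)
}

test_that("sensor attention maps are row-stochastic and symmetric cases are
           uniform", {
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 2)
  X <- make_input(3, cfg)
  tape <- pigait:::ad_tape()
  fw <- pigait:::model_forward(mdl, X, tape)
  for (A in fw$attn_maps) {
    expect_equal(rowSums(A), rep(1, cfg$n_sensors), tolerance = 1e-6)
  }
  # identical streams on every sensor with zeroed positional encodings
  mdl0 <- mdl
  mdl0$params$fus_pos <- mdl0$params$fus_pos * 0
  one <- X[, 1:cfg$n_channels]
  Xid <- do.call(cbind, replicate(cfg$n_sensors, one, simplify = FALSE))
  t2 <- pigait:::ad_tape()
  fw2 <- pigait:::model_forward(mdl0, Xid, t2)
  for (A in fw2$attn_maps)
    expect_equal(A, matrix(1 / cfg$n_sensors, cfg$n_sensors, cfg$n_sensors),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("masking a failed sensor removes its attention and keeps shapes", {
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 4)
  X <- make_input(5, cfg)
  mask <- rep(1, cfg$n_sensors); mask[3] <- 0
  tape <- pigait:::ad_tape()
  fw <- pigait:::model_forward(mdl, X, tape, sensor_mask = mask)
  t0 <- pigait:::ad_tape()
  fw0 <- pigait:::model_forward(mdl, X, t0)
  expect_identical(dim(fw$Z1$value), dim(fw0$Z1$value))
  for (A in fw$attn_maps) {
    expect_lt(max(A[, 3]), 1e-6)                 # no attention to sensor 3
    expect_equal(rowSums(A), rep(1, cfg$n_sensors), tolerance = 1e-6)
  }
})

test_that("the pathway gate interpolates exactly between conv and transformer", {
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 6)
  X <- make_input(7, cfg)
  t1 <- pigait:::ad_tape()
  f1 <- pigait:::model_forward(mdl, X, t1, gate_force = 1)
  expect_equal(f1$Z1$value, f1$Zc$value, tolerance = 1e-12)
  t2 <- pigait:::ad_tape()
  f0 <- pigait:::model_forward(mdl, X, t2, gate_force = 0)
  expect_equal(f0$Z1$value, f0$Zt$value, tolerance = 1e-12)
})

test_that("the conv pathway receptive field is exactly 127 samples", {
  # Jacobian-sparsity probe on the dilated stack alone: with kernel 3 and
  # dilations 1..32 the causal receptive field is 1 + 2 * 63 = 127 samples
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 8)
  D <- cfg$temporal_dim
  T_ <- 160L
  set.seed(9)
  H0 <- matrix(rnorm(T_ * D), T_, D)
  tape <- pigait:::ad_tape()
  h <- pigait:::ad_leaf(tape, H0)
  p <- lapply(mdl$params, function(m) pigait:::ad_leaf(tape, m))
  H <- h
  for (l in seq_len(cfg$conv_blocks)) {
    cv <- pigait:::ad_relu(tape, pigait:::ad_conv3(tape, H,
            p[[paste0("cnv", l, "_W0")]], p[[paste0("cnv", l, "_W1")]],
            p[[paste0("cnv", l, "_W2")]], p[[paste0("cnv", l, "_b")]],
            cfg$dilations[l]))
    H <- pigait:::ad_add(tape, H, cv)
  }
  loss <- pigait:::ad_sum(tape, pigait:::ad_rows(tape, H, T_))
  pigait:::ad_backward(tape, loss)
  reach <- rowSums(abs(h$grad)) > 0
  expect_true(all(reach[(T_ - 126L):T_]))      # last 127 samples influence
  expect_false(any(reach[seq_len(T_ - 127L)])) # nothing before them does
})

test_that("biomech heads emit contract shapes and bounded joint angles", {
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 10)
  X <- make_input(11, cfg)
  tape <- pigait:::ad_tape()
  fw <- pigait:::model_forward(mdl, X, tape)
  expect_identical(dim(fw$theta$value), c(101L, 6L))
  expect_identical(dim(fw$F_g$value), c(101L, 3L))
  expect_identical(dim(fw$v_c$value), c(101L, 3L))
  expect_identical(dim(fw$E_aux$value), c(101L, 1L))
  bounds <- pigait:::theta_head_scale(cfg)
  for (j in 1:6) expect_lte(max(abs(fw$theta$value[, j])), bounds[j])
  expect_equal(sum(fw$class_probs$value), 1, tolerance = 1e-9)
})

test_that("kinematic-loss gradients reach the sensor-fusion parameters", {
  cfg <- model_config("tiny")
  mdl <- init_model(cfg, seed = 12)
  X <- make_input(13, cfg)
  tape <- pigait:::ad_tape()
  pn <- lapply(mdl$params, function(m) pigait:::ad_leaf(tape, m))
  fw <- pigait:::model_forward(mdl, X, tape, params_nodes = pn)
  # force violations so the hinge is active, then backprop end-to-end
  loss <- pigait:::kinematic_loss_node(tape, fw$theta,
                                       constraint_config(kappa = 0.1))
  pigait:::ad_backward(tape, loss)
  for (k in c("fus_convW0", "fus_Wq", "fus_Wv", "cnv1_W0", "gate_W",
              "head_thW")) {
    expect_false(is.null(pn[[k]]$grad))
    expect_true(all(is.finite(pn[[k]]$grad)))
  }
  # at least the head and one upstream block carry nonzero gradient
  expect_gt(sum(abs(pn$head_thW$grad)), 0)
  expect_gt(sum(abs(pn$fus_convW0$grad)), 0)
})

test_that("predictions are deterministic with dropout off and MC moments
           match a two-pass oracle", {
  cfg <- model_config("tiny", mc_passes = 40)
  mdl <- init_model(cfg, seed = 14)
  X <- make_input(15, cfg)
  p1 <- predict_cycle(mdl, X, dropout_on = FALSE)
  p2 <- predict_cycle(mdl, X, dropout_on = FALSE)
  expect_identical(p1$asym_mean, p2$asym_mean)
  expect_equal(p1$asym_var, rep(0, cfg$asym_dim))
  expect_equal(sum(p1$class_probs), 1, tolerance = 1e-9)
  expect_error(predict_cycle(mdl, X, mc_passes = 1, dropout_on = TRUE),
               "mc_passes")
  # MC moments: replay the same dropout stream and recompute two-pass moments
  K <- 40
  pmc <- predict_cycle(mdl, X, mc_passes = K, dropout_on = TRUE, seed = 99)
  set.seed(99 %% .Machine$integer.max)
  draws <- matrix(NA_real_, K, cfg$asym_dim)
  for (k in seq_len(K)) {
    tk <- pigait:::ad_tape()
    fwk <- pigait:::model_forward(mdl, X, tk, dropout_rng = stats::runif)
    draws[k, ] <- as.numeric(fwk$asym_mu$value)
  }
  expect_equal(pmc$asym_mean, colMeans(draws), tolerance = 1e-12)
  expect_equal(pmc$asym_var,
               apply(draws, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-12)
  expect_gt(max(pmc$asym_var), 0)
})

test_that("checkpoints round-trip through save and load", {
  mdl <- init_model(model_config("tiny"), seed = 16)
  mdl$norm_stats <- list(mean = rep(0, 72), sd = rep(1, 72))
  path <- file.path(tempdir(), "ckpt_test.rds")
  save_checkpoint(mdl, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, mdl$params)
  expect_identical(m2$cfg$profile, "tiny")
  X <- make_input(17)
  expect_identical(predict_cycle(mdl, X, dropout_on = FALSE)$class_probs,
                   predict_cycle(m2, X, dropout_on = FALSE)$class_probs)
  unlink(path)
})
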