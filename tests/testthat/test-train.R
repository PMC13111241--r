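test_that("loss breakdown matches closed forms and sums to its total", {
  # uniform probabilities: per-sample CE = ln 5
  p <- matrix(0.2, 4, 5)
  y <- c(0, 1, 3, 4)
  lb <- total_loss(p, y, asym_mu = matrix(0, 4, 2),
                   asym_logvar = matrix(0, 4, 2),
                   asym_target = matrix(0, 4, 2))
  expect_equal(lb$L_c, log(5), tolerance = 1e-12)
  expect_equal(lb$L_r, 0)
  # Gaussian NLL at y-hat = y, sigma^2 = 1: 0.5 log(2 pi) per sample
  expect_equal(lb$L_u, 0.5 * log(2 * pi), tolerance = 1e-12)
  # perfect one-hot predictions and exact regression
  ph <- diag(5)[y + 1, ]
  ph <- pmax(ph, 1e-12); ph <- ph / rowSums(ph)
  lb2 <- total_loss(ph, y, asym_mu = matrix(1, 4, 2),
                    asym_logvar = matrix(0, 4, 2),
                    asym_target = matrix(1, 4, 2))
  expect_lt(lb2$L_c, 1e-10)
  expect_equal(lb2$L_r, 0)
  # components sum to total, including weighted constraints and L2
  lam <- c(0.1, 0.15, 0.08, 0.12)
  cons <- c(2, 3, 0.5, 1)
  pars <- list(a = matrix(1:4, 2), b = matrix(0.5, 1, 2))
  lb3 <- total_loss(p, y, matrix(0.3, 4, 2), matrix(0.1, 4, 2),
                    matrix(0, 4, 2), constraints = cons, lambda = lam,
                    params = pars, eta = 1e-5)
  expect_equal(lb3$total,
               lb3$L_c + lb3$L_r + lb3$L_u + sum(lam * cons) + lb3$l2,
               tolerance = 1e-9)
  expect_equal(lb3$l2, 1e-5 * (sum((1:4)^2) + 2 * 0.25), tolerance = 1e-12)
})

test_that("classification metrics match the textbook confusion-matrix oracle", {
  # hand-built 2-class confusion matrix [[40,10],[20,30]]
  truth <- c(rep(0, 50), rep(1, 50))
  pred <- c(rep(0, 40), rep(1, 10), rep(0, 20), rep(1, 30))
  m <- evaluate(pred, truth)
  expect_equal(m$accuracy, 0.7)
  # kappa: po = 0.7, pe = (60*50 + 40*50)/100^2 = 0.5 -> 0.4
  expect_equal(m$kappa, 0.4, tolerance = 1e-12)
  # macro-F1: class0 F1 = 2*(2/3)*(4/5)/(2/3+4/5); class1 = 2*(3/4)*(3/5)/...
  f0 <- 2 * (40 / 60) * (40 / 50) / (40 / 60 + 40 / 50)
  f1 <- 2 * (30 / 40) * (30 / 50) / (30 / 40 + 30 / 50)
  expect_equal(m$macro_f1, mean(c(f0, f1)), tolerance = 1e-12)
  # perfect predictions
  mp <- evaluate(truth, truth, reg_pred = c(1, 2, 3), reg_truth = c(1, 2, 3))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$kappa, 1)
  expect_equal(mp$mae, 0)
  expect_equal(mp$r2, 1)
  # constant regression at the target mean: R^2 = 0 by definition
  yt <- c(1, 2, 3, 4)
  mr <- evaluate(c(0, 0), c(0, 0), reg_pred = rep(mean(yt), 4),
                 reg_truth = yt)
  expect_equal(mr$r2, 0, tolerance = 1e-12)
  # absent class excluded from the macro mean with a warning
  expect_warning(m2 <- evaluate(c(0, 0, 1), c(0, 0, 0)), "excluded")
})

test_that("metrics agree with an independent random-label oracle", {
  set.seed(61)
  for (rep in 1:5) {
    truth <- sample(0:4, 200, replace = TRUE)
    pred <- ifelse(runif(200) < 0.6, truth, sample(0:4, 200, replace = TRUE))
    m <- evaluate(pred, truth)
    # independent oracle: direct counting
    acc_o <- mean(pred == truth)
    cm <- matrix(0, 5, 5)
    for (i in seq_along(truth)) cm[truth[i] + 1, pred[i] + 1] <-
        cm[truth[i] + 1, pred[i] + 1] + 1
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    expect_equal(m$accuracy, acc_o, tolerance = 1e-12)
    expect_equal(m$kappa, (acc_o - pe) / (1 - pe), tolerance = 1e-12)
    f1s <- vapply(1:5, function(i) {
      prec <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
      rec <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }, 0)
    expect_equal(m$macro_f1, mean(f1s[rowSums(cm) > 0]), tolerance = 1e-12)
  }
})

test_that("a short training run decreases the loss and logs all components", {
  co <- tiny_cohort()
  ds <- prepare_dataset(co)
  mdl <- init_model(model_config("tiny"), seed = 3)
  tcfg <- train_config("desk", epochs = 5, batch = 8, seed = 7, lr = 5e-3)
  fit <- train(ds, mdl, tcfg)
  expect_s3_class(fit$log, "data.frame")
  expect_true(all(c("L_c", "L_r", "L_u", "kin", "dyn", "sym", "eng",
                    "total", "val_accuracy", "c_diss") %in% names(fit$log)))
  expect_equal(nrow(fit$log), 5L)
  # smoke: total loss decreases over the first epochs
  expect_lt(fit$log$total[5], fit$log$total[1])
  expect_true(all(is.finite(fit$log$total)))
  # subject-disjoint split
  tr_subj <- unique(ds$subjects[fit$split$train])
  va_subj <- unique(ds$subjects[fit$split$val])
  expect_length(intersect(tr_subj, va_subj), 0)
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  co <- tiny_cohort()
  ds <- prepare_dataset(co)
  mdl <- init_model(model_config("tiny"), seed = 5)
  split <- subject_split(ds, 0.25, 5)
  tA <- train_config("desk", epochs = 4, batch = 8, seed = 9, lr = 5e-3,
                     scheduler = "constant")
  full <- train(ds, init_model(model_config("tiny"), seed = 5), tA,
                split = split)
  # two epochs, checkpoint, then two more
  t1 <- train_config("desk", epochs = 2, batch = 8, seed = 9, lr = 5e-3,
                     scheduler = "constant")
  part <- train(ds, init_model(model_config("tiny"), seed = 5), t1,
                split = split)
  t2 <- train_config("desk", epochs = 4, batch = 8, seed = 9, lr = 5e-3,
                     scheduler = "constant")
  resumed <- train(ds, part$model, t2, split = split,
                   resume = list(model = part$model, opt = part$opt,
                                 epoch = part$epoch))
  for (k in names(full$model$params)) {
    expect_lt(max(abs(full$model$params[[k]] - resumed$model$params[[k]])),
              1e-4)
  }
})

test_that("the robustness harness injects calibrated noise and masks sensors", {
  co <- tiny_cohort()
  ds <- prepare_dataset(co)
  mdl <- init_model(model_config("tiny"), seed = 11)
  tcfg <- train_config("desk", epochs = 2, batch = 8, seed = 13, lr = 5e-3)
  fit <- train(ds, mdl, tcfg)
  tab <- robustness_suite(fit$model, ds, idx = fit$split$val,
                          snr_levels = c(20, 10),
                          failure_sensors = c("trunk", "shank_L"), seed = 3)
  expect_s3_class(tab, "data.frame")
  expect_equal(tab$scenario[1], "clean")
  expect_equal(tab$delta_acc[1], 0)
  noise <- tab[tab$condition == "noise", ]
  expect_equal(nrow(noise), 2L)
  # realized SNR within half a decibel of requested
  expect_lt(abs(noise$snr_measured[1] - 20), 0.5)
  expect_lt(abs(noise$snr_measured[2] - 10), 0.5)
  expect_equal(nrow(tab[tab$condition == "sensor failure", ]), 2L)
  # SNR = Inf (no noise) equals the clean evaluation exactly
  r_inf <- classify_samples(fit$model, ds$samples[fit$split$val])
  r_clean <- classify_samples(fit$model, ds$samples[fit$split$val])
  expect_identical(r_inf$pred, r_clean$pred)
})

test_that("run configuration validates keys, round-trips and hashes stably", {
  cfg <- load_run_config()
  expect_s3_class(cfg, "run_config")
  h1 <- config_hash(cfg)
  expect_identical(h1, config_hash(load_run_config()))
  path <- file.path(tempdir(), "cfg_test.yaml")
  save_run_config(cfg, path)
  reread <- yaml::read_yaml(path)
  expect_equal(reread$segment$grid_points, 101)
  expect_equal(reread$provenance$hash, h1)
  bad <- file.path(tempdir(), "cfg_bad.yaml")
  writeLines("nonsense:\n  key: 1", bad)
  expect_error(load_run_config(bad), "unknown configuration section")
  writeLines("segment:\n  bogus_key: 1", bad)
  expect_error(load_run_config(bad), "unknown configuration key")
  unlink(c(path, bad))
})
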