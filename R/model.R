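#' Hierarchical attention network for multi-task fatigue assessment
#'
#' The network processes one normalized gait cycle (101 x N sensors x C
#' channels) through four stages: (1) sensor fusion - a shared kernel-3
#' convolution embeds each sensor stream, learned positional encodings inject
#' the anatomical slot, and multi-head self-attention across the sensor axis
#' (queries/keys from time-pooled embeddings, values time-varying) produces a
#' fused sequence via residual + layer-norm + feed-forward; (2) temporal
#' extraction - a causal dilated convolutional pathway (six residual blocks,
#' dilations 1..32, kernel 3) in parallel with a transformer pathway, merged
#' by a learned elementwise sigmoid gate; (3) biomechanical heads predicting
#' joint angles (bounded tanh activation scaled beyond the anatomical range so
#' the kinematic constraint stays active), ground reaction force, COM velocity
#' and an auxiliary energy trace; (4) output heads - mean-pooled MLP softmax
#' classification over the five fatigue levels and max-pooled linear
#' regression of six bilateral asymmetry quantities, with a log-variance head
#' for heteroscedastic uncertainty and Monte-Carlo dropout for epistemic
#' spread at inference.
#'
#' @name model
NULL

#' Model configuration
#'
#' The \code{full} profile mirrors the reference architecture (64-dim sensor
#' embeddings, 8 fusion heads, 256-dim temporal embeddings, 8 heads, 4
#' transformer layers); the \code{tiny} profile keeps the same topology at
#' desk scale for CPU training and testing.
#'
#' @param profile "tiny" or "full"
#' @param n_sensors number of sensor sites
#' @param n_channels channels per sensor
#' @param ... overrides for individual fields
#' @return object of class \code{model_config}
#' @export
model_config <- function(profile = c("tiny", "full"), n_sensors = 8,
                         n_channels = 9, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(embed_dim_sensor = 64, fusion_heads = 8, temporal_dim = 256,
         temporal_heads = 8, transformer_layers = 4,
         mlp_widths = c(256, 128, 64), dropout = 0.1)
  } else {
    list(embed_dim_sensor = 16, fusion_heads = 4, temporal_dim = 32,
         temporal_heads = 4, transformer_layers = 1,
         mlp_widths = c(32, 16), dropout = 0.05)
  }
  cfg <- utils::modifyList(c(base, list(
    conv_blocks = 6, dilations = c(1, 2, 4, 8, 16, 32), kernel = 3,
    n_classes = 5, asym_dim = 6, mc_passes = 30,
    n_sensors = n_sensors, n_channels = n_channels,
    theta_scale = 1.5, profile = profile)), list(...))
  stopifnot(cfg$embed_dim_sensor %% cfg$fusion_heads == 0,
            cfg$temporal_dim %% cfg$temporal_heads == 0,
            identical(cfg$dilations, c(1, 2, 4, 8, 16, 32)))
  structure(cfg, class = "model_config")
}

rmat <- function(n, m) matrix(stats::rnorm(n * m, 0, sqrt(2 / (n + m))), n, m)
zrow <- function(m) matrix(0, 1L, m)
orow <- function(m) matrix(1, 1L, m)

#' Initialize a model
#'
#' @param cfg a \code{\link{model_config}}
#' @param seed RNG seed for the parameter draw
#' @return object of class \code{pigait_model}: flat named parameter list,
#'   config, the learnable dissipation coefficient and (once trained)
#'   normalization statistics
#' @export
init_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- cfg$embed_dim_sensor; D <- cfg$temporal_dim
  C <- cfg$n_channels; N <- cfg$n_sensors
  p <- list()
  # sensor fusion
  for (k in 0:2) p[[paste0("fus_convW", k)]] <- rmat(C, d)
  p$fus_convb <- zrow(d)
  p$fus_pos <- rmat(N, d)
  for (w in c("q", "k", "v", "o")) p[[paste0("fus_W", w)]] <- rmat(d, d)
  p$fus_ln1g <- orow(d); p$fus_ln1b <- zrow(d)
  p$fus_ffW1 <- rmat(d, 2 * d); p$fus_ffb1 <- zrow(2 * d)
  p$fus_ffW2 <- rmat(2 * d, d); p$fus_ffb2 <- zrow(d)
  p$fus_ln2g <- orow(d); p$fus_ln2b <- zrow(d)
  # temporal
  p$tmp_Win <- rmat(d, D); p$tmp_bin <- zrow(D)
  for (l in seq_len(cfg$conv_blocks)) {
    for (k in 0:2) p[[paste0("cnv", l, "_W", k)]] <- rmat(D, D)
    p[[paste0("cnv", l, "_b")]] <- zrow(D)
  }
  for (l in seq_len(cfg$transformer_layers)) {
    for (w in c("q", "k", "v", "o")) p[[paste0("trf", l, "_W", w)]] <- rmat(D, D)
    p[[paste0("trf", l, "_ln1g")]] <- orow(D); p[[paste0("trf", l, "_ln1b")]] <- zrow(D)
    p[[paste0("trf", l, "_ffW1")]] <- rmat(D, 2 * D)
    p[[paste0("trf", l, "_ffb1")]] <- zrow(2 * D)
    p[[paste0("trf", l, "_ffW2")]] <- rmat(2 * D, D)
    p[[paste0("trf", l, "_ffb2")]] <- zrow(D)
    p[[paste0("trf", l, "_ln2g")]] <- orow(D); p[[paste0("trf", l, "_ln2b")]] <- zrow(D)
  }
  p$gate_W <- rmat(2 * D, D); p$gate_b <- zrow(D)
  p$head_lng <- orow(D); p$head_lnb <- zrow(D)
  # biomech heads start small: near-zero (smooth) initial joint angles and
  # forces keep the physics residuals finite before learning shapes them
  p$head_thW <- rmat(D, 6) * 0.1; p$head_thb <- zrow(6)
  p$head_fW <- rmat(D, 3) * 0.1; p$head_fb <- zrow(3)
  p$head_vW <- rmat(D, 3) * 0.1; p$head_vb <- zrow(3)
  p$head_eW <- rmat(D, 1) * 0.1; p$head_eb <- zrow(1)
  # classification MLP
  dims <- c(D, cfg$mlp_widths, cfg$n_classes)
  for (l in seq_len(length(dims) - 1L)) {
    p[[paste0("cls", l, "_W")]] <- rmat(dims[l], dims[l + 1L])
    p[[paste0("cls", l, "_b")]] <- zrow(dims[l + 1L])
  }
  # regression heads
  p$reg_W <- rmat(D, cfg$asym_dim) * 0.1; p$reg_b <- zrow(cfg$asym_dim)
  p$reglv_W <- rmat(D, cfg$asym_dim) * 0.1
  # start the heteroscedastic head at a broad prior variance (~e^3) so the
  # Gaussian NLL is well-scaled against percent-scale asymmetry targets
  p$reglv_b <- zrow(cfg$asym_dim) + 3
  structure(list(params = p, cfg = cfg, c_diss = 0.05, norm_stats = NULL),
            class = "pigait_model")
}

#' @export
print.pigait_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("pigait model (%s profile): %d parameters, c_diss = %.4f\n",
              x$cfg$profile, np, x$c_diss))
  invisible(x)
}

## joint-angle activation scale: theta_scale x the largest absolute limit per
## column, so predictions can exceed anatomy and the kinematic loss bites
theta_head_scale <- function(cfg, ccfg = constraint_config()) {
  lim <- ccfg$joint_limits
  cfg$theta_scale * pmax(abs(lim[, "min"]), abs(lim[, "max"]))
}

#' Forward pass on an autodiff tape
#'
#' @param model a \code{pigait_model}
#' @param X 101 x (N*C) sensor-major cycle matrix (already normalized)
#' @param tape an autodiff tape (fresh per call)
#' @param params_nodes optional pre-made leaf nodes for the parameters (reused
#'   across the losses for gradient accumulation)
#' @param dropout_rng function() returning a uniform draw, or NULL for
#'   deterministic (dropout off)
#' @param sensor_mask optional 0/1 vector of length N (0 = failed sensor)
#' @param gate_force NULL, 0 or 1: force the pathway gate (testing hook)
#' @return list of tape nodes (\code{Z0}, \code{Zc}, \code{Zt}, \code{Z1},
#'   \code{theta}, \code{F_g}, \code{v_c}, \code{E_aux}, \code{class_probs},
#'   \code{asym_mu}, \code{asym_logvar}) plus attention map values
#' @keywords internal
model_forward <- function(model, X, tape, params_nodes = NULL,
                          dropout_rng = NULL, sensor_mask = NULL,
                          gate_force = NULL) {
  cfg <- model$cfg
  p <- params_nodes %||% lapply(model$params, function(m) ad_leaf(tape, m))
  N <- cfg$n_sensors; C <- cfg$n_channels
  d <- cfg$embed_dim_sensor; D <- cfg$temporal_dim
  T_ <- nrow(X)
  if (any(!is.finite(X))) stop("non-finite values in model input")
  if (is.null(sensor_mask)) sensor_mask <- rep(1, N)
  drop_mask <- function(nr, nc) {
    if (is.null(dropout_rng) || cfg$dropout <= 0) return(NULL)
    matrix((stats::runif(nr * nc) > cfg$dropout) + 0, nr, nc)
  }
  maybe_drop <- function(nd) {
    mk <- drop_mask(nrow(nd$value), ncol(nd$value))
    if (is.null(mk)) nd else ad_dropout(tape, nd, mk, cfg$dropout)
  }
  ## ---- sensor fusion ----
  E <- vector("list", N)
  for (n in seq_len(N)) {
    Xn <- ad_leaf(tape, X[, ((n - 1L) * C + 1L):(n * C), drop = FALSE] *
                    sensor_mask[n])
    conv <- ad_conv3(tape, Xn, p$fus_convW0, p$fus_convW1, p$fus_convW2,
                     p$fus_convb, 1L)
    pos <- ad_rows(tape, p$fus_pos, rep(n, 1L))
    E[[n]] <- ad_add(tape, conv, pos)
  }
  Ebar <- ad_vstack(tape, lapply(E, function(e) ad_colmeans(tape, e)))  # N x d
  Q <- ad_matmul(tape, Ebar, p$fus_Wq)
  K <- ad_matmul(tape, Ebar, p$fus_Wk)
  V <- lapply(E, function(e) ad_matmul(tape, e, p$fus_Wv))
  nh <- cfg$fusion_heads; dh <- d / nh
  # column j penalized when sensor j failed: no attention flows to it
  mask_pen <- matrix(rep(ifelse(sensor_mask > 0, 0, -1e9), each = N), N, N)
  heads <- list(); attn_maps <- list()
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_cols(tape, Q, cols); Kh <- ad_cols(tape, K, cols)
    S <- ad_scale(tape, ad_matmul(tape, Qh, ad_t(tape, Kh)), 1 / sqrt(dh))
    if (any(sensor_mask == 0)) S <- ad_add(tape, S, ad_leaf(tape, mask_pen))
    A <- ad_softmax_rows(tape, S)                      # N x N
    attn_maps[[h]] <- A$value
    abar <- ad_colmeans(tape, A)                       # 1 x N
    fused <- NULL
    for (n in seq_len(N)) {
      Vh <- ad_cols(tape, V[[n]], cols)
      term <- ad_mul(tape, Vh, ad_cols(tape, abar, n))
      fused <- if (is.null(fused)) term else ad_add(tape, fused, term)
    }
    heads[[h]] <- fused
  }
  Hcat <- Reduce(function(a, b) ad_cbind(tape, a, b), heads)
  attn_out <- ad_matmul(tape, Hcat, p$fus_Wo)
  Emean <- Reduce(function(a, b) ad_add(tape, a, b), E)
  Emean <- ad_scale(tape, Emean, 1 / N)
  Hf <- ad_add(tape, attn_out, Emean)
  Hf <- ad_layernorm(tape, Hf, p$fus_ln1g, p$fus_ln1b)
  ff <- ad_affine(tape, ad_relu(tape,
          ad_affine(tape, Hf, p$fus_ffW1, p$fus_ffb1)),
          p$fus_ffW2, p$fus_ffb2)
  Z0 <- ad_layernorm(tape, ad_add(tape, Hf, ff), p$fus_ln2g, p$fus_ln2b)
  ## ---- temporal extraction ----
  Zin <- ad_affine(tape, Z0, p$tmp_Win, p$tmp_bin)
  H <- Zin
  for (l in seq_len(cfg$conv_blocks)) {
    cv <- ad_relu(tape, ad_conv3(tape, H, p[[paste0("cnv", l, "_W0")]],
                                 p[[paste0("cnv", l, "_W1")]],
                                 p[[paste0("cnv", l, "_W2")]],
                                 p[[paste0("cnv", l, "_b")]],
                                 cfg$dilations[l]))
    H <- ad_add(tape, H, cv)
  }
  Zc <- H
  Ht <- Zin
  nh2 <- cfg$temporal_heads; dh2 <- D / nh2
  for (l in seq_len(cfg$transformer_layers)) {
    pre <- paste0("trf", l, "_")
    Qt <- ad_matmul(tape, Ht, p[[paste0(pre, "Wq")]])
    Kt <- ad_matmul(tape, Ht, p[[paste0(pre, "Wk")]])
    Vt <- ad_matmul(tape, Ht, p[[paste0(pre, "Wv")]])
    hh <- list()
    for (h in seq_len(nh2)) {
      cols <- ((h - 1L) * dh2 + 1L):(h * dh2)
      A <- ad_softmax_rows(tape, ad_scale(tape,
            ad_matmul(tape, ad_cols(tape, Qt, cols),
                      ad_t(tape, ad_cols(tape, Kt, cols))), 1 / sqrt(dh2)))
      hh[[h]] <- ad_matmul(tape, A, ad_cols(tape, Vt, cols))
    }
    O <- ad_matmul(tape, Reduce(function(a, b) ad_cbind(tape, a, b), hh),
                   p[[paste0(pre, "Wo")]])
    Ht <- ad_layernorm(tape, ad_add(tape, Ht, O),
                       p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    ffh <- ad_affine(tape, ad_relu(tape,
             ad_affine(tape, Ht, p[[paste0(pre, "ffW1")]],
                       p[[paste0(pre, "ffb1")]])),
             p[[paste0(pre, "ffW2")]], p[[paste0(pre, "ffb2")]])
    Ht <- ad_layernorm(tape, ad_add(tape, Ht, ffh),
                       p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
  }
  Zt <- Ht
  if (is.null(gate_force)) {
    G <- ad_sigmoid(tape, ad_affine(tape, ad_cbind(tape, Zc, Zt),
                                    p$gate_W, p$gate_b))
  } else {
    G <- ad_leaf(tape, matrix(gate_force, T_, D))
  }
  one_minus_G <- ad_scale(tape, ad_addc(tape, ad_scale(tape, G, -1), 1), 1)
  Z1 <- ad_add(tape, ad_mul(tape, G, Zc), ad_mul(tape, one_minus_G, Zt))
  ## ---- biomechanical heads ----
  # heads read a layer-normalized view of Z1 so their input scale is stable
  # regardless of the depth of the residual convolutional pathway
  Z1h <- ad_layernorm(tape, Z1, p$head_lng, p$head_lnb)
  th_scale <- ad_leaf(tape, matrix(theta_head_scale(cfg), 1L))
  theta <- ad_mul(tape, ad_tanh(tape,
             ad_affine(tape, Z1h, p$head_thW, p$head_thb)), th_scale)
  theta$value <- theta$value + 0          # force copy before naming
  colnames(theta$value) <- JOINT_COLS
  F_g <- ad_affine(tape, Z1h, p$head_fW, p$head_fb)
  v_c <- ad_affine(tape, Z1h, p$head_vW, p$head_vb)
  E_aux <- ad_affine(tape, Z1h, p$head_eW, p$head_eb)
  ## ---- output heads ----
  zbar <- maybe_drop(ad_colmeans(tape, Z1h))
  hcur <- zbar
  nl <- length(cfg$mlp_widths) + 1L
  for (l in seq_len(nl)) {
    hcur <- ad_affine(tape, hcur, p[[paste0("cls", l, "_W")]],
                      p[[paste0("cls", l, "_b")]])
    if (l < nl) hcur <- maybe_drop(ad_relu(tape, hcur))
  }
  class_probs <- ad_softmax_rows(tape, hcur)
  zmax <- maybe_drop(ad_colmax(tape, Z1h))
  asym_mu <- ad_affine(tape, zmax, p$reg_W, p$reg_b)
  asym_logvar <- ad_affine(tape, zmax, p$reglv_W, p$reglv_b)
  list(Z0 = Z0, Zc = Zc, Zt = Zt, Z1 = Z1, theta = theta, F_g = F_g,
       v_c = v_c, E_aux = E_aux, class_logits = hcur,
       class_probs = class_probs, asym_mu = asym_mu,
       asym_logvar = asym_logvar, attn_maps = attn_maps, params = p)
}

#' Predict fatigue level and asymmetry with Monte-Carlo-dropout uncertainty
#'
#' Runs one deterministic pass for the class probabilities and, when
#' \code{mc_passes >= 2} and dropout is active, K stochastic passes for the
#' asymmetry predictive mean and variance (epistemic spread); the
#' heteroscedastic log-variance head contributes the aleatoric part.
#'
#' @param model a trained \code{pigait_model}
#' @param X 101 x (N*C) normalized cycle matrix
#' @param mc_passes number of stochastic passes K (default from config)
#' @param dropout_on logical; FALSE gives deterministic predictions with zero
#'   epistemic variance
#' @param seed RNG seed for the dropout masks
#' @return object of class \code{pigait_prediction}: \code{class_probs}
#'   (length 5, sums to 1), \code{fatigue_argmax} (0-4), \code{asym_mean},
#'   \code{asym_var} (length M, >= 0), \code{attn_maps}
#' @export
predict_cycle <- function(model, X, mc_passes = NULL, dropout_on = TRUE,
                          seed = 1L) {
  cfg <- model$cfg
  K <- mc_passes %||% cfg$mc_passes
  if (dropout_on && K < 2L)
    stop("mc_passes must be >= 2 when dropout is on (variance undefined)")
  tape <- ad_tape()
  fw <- model_forward(model, X, tape)
  probs <- as.numeric(fw$class_probs$value)
  base_mu <- as.numeric(fw$asym_mu$value)
  if (!dropout_on || cfg$dropout <= 0) {
    mu <- base_mu
    va <- rep(0, length(mu))
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    draws <- matrix(NA_real_, K, cfg$asym_dim)
    for (k in seq_len(K)) {
      tk <- ad_tape()
      fwk <- model_forward(model, X, tk, dropout_rng = stats::runif)
      draws[k, ] <- as.numeric(fwk$asym_mu$value)
    }
    mu <- colMeans(draws)
    va <- apply(draws, 2L, function(v) mean((v - mean(v))^2))
  }
  structure(list(class_probs = probs,
                 fatigue_argmax = which.max(probs) - 1L,
                 asym_mean = mu, asym_var = va,
                 asym_logvar = as.numeric(fw$asym_logvar$value),
                 attn_maps = fw$attn_maps),
            class = "pigait_prediction")
}

#' @export
print.pigait_prediction <- function(x, ...) {
  cat("fatigue prediction: level", x$fatigue_argmax, "\n")
  cat("  probs:", paste(sprintf("%.3f", x$class_probs), collapse = " "), "\n")
  cat("  asymmetry mean:", paste(sprintf("%.3f", x$asym_mean), collapse = " "),
      "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the weights, configuration, dissipation
#' coefficient and normalization statistics.
#'
#' @param model a \code{pigait_model}
#' @param path file path
#' @return \code{save_checkpoint} invisibly returns \code{path};
#'   \code{load_checkpoint} returns the model
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pigait_model"))
  m
}
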