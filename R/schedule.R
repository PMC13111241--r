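#' Adaptive constraint weighting
#'
#' Effective constraint weights factorize as
#' \code{lambda_i(e, y_f) = lambda_i0 * alpha(e) * beta(y_f)}: a two-phase
#' curriculum over training epochs (reduced weight 0.1 during warmup, linear
#' ramp to 1 over the ramp phase, then full weight) and a linear
#' fatigue-state amplification \code{beta = 1 + gamma y_f}. During training
#' the ground-truth label drives \code{beta}; at inference the predicted
#' (argmax) fatigue state is used.
#'
#' @name schedule
NULL

#' Curriculum configuration
#'
#' @param lambda0 base weights for (kinematic, dynamic, symmetry, energy);
#'   defaults (0.1, 0.15, 0.08, 0.12)
#' @param warmup_epochs warmup length E_w (epochs), default 20
#' @param ramp_epochs ramp length E_r (epochs), default 80
#' @param gamma fatigue amplification slope, default 0.15
#' @return object of class \code{curriculum_config}
#' @export
curriculum_config <- function(lambda0 = c(kinematic = 0.1, dynamic = 0.15,
                                          symmetry = 0.08, energy = 0.12),
                              warmup_epochs = 20, ramp_epochs = 80,
                              gamma = 0.15) {
  stopifnot(all(lambda0 >= 0), warmup_epochs >= 0, ramp_epochs >= 0,
            gamma >= 0)
  structure(list(lambda0 = lambda0, warmup_epochs = warmup_epochs,
                 ramp_epochs = ramp_epochs, gamma = gamma,
                 warmup_floor = 0.1),
            class = "curriculum_config")
}

#' Curriculum factor alpha(e)
#'
#' 0.1 for \code{e < E_w}; \code{0.1 + 0.9 (e - E_w) / E_r} for
#' \code{E_w <= e < E_w + E_r}; 1 afterwards. Piecewise linear, continuous
#' and bounded in [0.1, 1].
#'
#' @param e epoch index (>= 0)
#' @param cfg a \code{\link{curriculum_config}}
#' @return alpha in [0.1, 1]
#' @export
curriculum_alpha <- function(e, cfg = curriculum_config()) {
  stopifnot(all(e >= 0))
  ew <- cfg$warmup_epochs; er <- cfg$ramp_epochs
  a <- ifelse(e < ew, cfg$warmup_floor,
              ifelse(er > 0 & e < ew + er,
                     cfg$warmup_floor + (1 - cfg$warmup_floor) * (e - ew) / er,
                     1))
  pmin(pmax(a, cfg$warmup_floor), 1)
}

#' Fatigue scaling beta(y_f) = 1 + gamma y_f
#'
#' @param y_f fatigue level, integer 0-4 (ground truth during training,
#'   predicted argmax at inference)
#' @param cfg a \code{\link{curriculum_config}}
#' @return beta >= 1
#' @export
fatigue_beta <- function(y_f, cfg = curriculum_config()) {
  if (!all(y_f %in% 0:4)) stop("fatigue level must be in 0..4")
  1 + cfg$gamma * y_f
}

#' Effective constraint weights lambda_i(e, y_f)
#'
#' @param e epoch index
#' @param y_f fatigue level 0-4
#' @param cfg a \code{\link{curriculum_config}}
#' @return named numeric of length 4
#' @export
effective_weights <- function(e, y_f, cfg = curriculum_config()) {
  cfg$lambda0 * curriculum_alpha(e, cfg) * fatigue_beta(y_f, cfg)
}
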