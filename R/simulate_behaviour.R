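#' Behavioural generator configuration
#'
#' Per-trial behavioural measures are generated from two latent constructs:
#' appraisal `a` (how positively the option set is evaluated) and choice
#' difficulty `c` (how hard the comparison is). Both are standard normal
#' with correlation `latent_cor`. The set-level value structure follows the
#' latents, and the remaining measures are the deterministic identities of
#' a binary value-based choice plus noisy ratings:
#'
#' * overall value `OV = ov_mean + ov_loading * a + noise` (0-10 value scale)
#' * value difference `VD = vd_mean + vd_loading * c + noise`, clipped at 0
#'   (harder sets, larger `c`, have more similar options, so
#'   `vd_loading < 0`)
#' * item values `OV +- VD/2`; the better item is chosen with probability
#'   `plogis(choice_beta * VD)` (accuracy grows with value difference);
#'   chosen/unchosen value follow from the choice
#' * set salience `= |OV - mean(OV)|`
#' * liking `= 3 + liking_loading * a + noise`
#' * confidence `= 3.5 + confidence_loading * c + noise`
#'   (`confidence_loading < 0`)
#' * anxiety `= 2.5 + anxiety_loading * c + noise`
#'
#' The three subjective ratings are given on a 5-point key-press scale, so
#' by default (`rating_scale = "discrete"`) they are rounded to integers
#' and clipped to 1..5; `"continuous"` keeps the latent linear values
#' (useful for noiseless identities).
#'
#' RTs come from a shifted lognormal whose log-scale location decreases
#' with value difference and overall value (`beta_vd <= 0`, `beta_ov <= 0`):
#' `rt = rt_shift + exp(rt_meanlog0 + beta_vd*VD + beta_ov*OV +
#' rt_sdlog * z)`. Trials slower than `rt_cap` are recorded as
#' "no response" (`rt = NA`). The defaults yield a median RT near 1.7 s
#' under a 4 s deadline, with a usable fast subset below 1.25 s.
#'
#' @param n_trials number of trials (default 4637, pooled across
#'   participants).
#' @param n_participants trials are split evenly across this many ids.
#' @param latent_cor correlation between `a` and `c` (default 0: set
#'   construction decorrelates overall value and value difference).
#' @param ov_mean,ov_loading,ov_sd overall-value model.
#' @param vd_mean,vd_loading,vd_sd value-difference model (`vd_loading < 0`).
#' @param liking_loading,confidence_loading,anxiety_loading rating loadings
#'   on `a` (liking) and `c` (confidence negative, anxiety positive).
#' @param rating_sd noise sd of the three ratings.
#' @param rating_scale `"discrete"` (1..5 integer key presses, default) or
#'   `"continuous"`.
#' @param choice_beta softmax slope of accuracy on value difference.
#' @param rt_shift,rt_meanlog0,rt_sdlog,beta_vd,beta_ov,rt_cap RT model.
#' @return list of class `behaviour_config`.
#' @export
behaviour_config <- function(n_trials = 4637, n_participants = 39,
                             latent_cor = 0,
                             ov_mean = 5, ov_loading = 1.5, ov_sd = 0.5,
                             vd_mean = 2.5, vd_loading = -0.8, vd_sd = 0.5,
                             liking_loading = 0.8,
                             confidence_loading = -0.8,
                             anxiety_loading = 0.8,
                             rating_sd = 0.4,
                             rating_scale = c("discrete", "continuous"),
                             choice_beta = 1,
                             rt_shift = 0.3, rt_meanlog0 = 0.74,
                             rt_sdlog = 0.35,
                             beta_vd = -0.08, beta_ov = -0.04,
                             rt_cap = 4) {
  if (rt_cap <= rt_shift) stop2("rt_cap must exceed rt_shift")
  if (rating_sd < 0 || ov_sd < 0 || vd_sd < 0) stop2("noise sd must be >= 0")
  if (beta_vd > 0 || beta_ov > 0)
    stop2("RT coefficients beta_vd and beta_ov must be <= 0")
  rating_scale <- match.arg(rating_scale)
  cfg <- as.list(environment())
  ## loading matrix (a, c) -> linear measures; used for the rank check and
  ## exposed for analytic-covariance oracles
  L <- rbind(overall_value = c(ov_loading, 0),
             value_difference = c(0, vd_loading),
             liking = c(liking_loading, 0),
             confidence = c(0, confidence_loading),
             anxiety = c(0, anxiety_loading))
  if (qr(L)$rank < 2) stop2("degenerate loading matrix: rank < 2")
  cfg$loadings <- L
  structure(cfg, class = "behaviour_config")
}

#' Simulate per-trial behavioural measures
#'
#' Draws the two latent constructs and generates the eight trial measures
#' and RTs described in [behaviour_config()]. Deterministic identities hold
#' exactly: `value_difference = max - min` of the two item values,
#' `overall_value` their mean, `set_salience = |mean-centred overall value|`.
#'
#' @param config a [behaviour_config()].
#' @return list with `measures` (data frame: eight measures plus
#'   `participant_id`, `rt`, `responded`, `chose_better`) and `latents`
#'   (n x 2 matrix, columns `a`, `c`).
#' @export
simulate_trial_measures <- function(config = behaviour_config()) {
  stopifnot(inherits(config, "behaviour_config"))
  n <- config$n_trials
  rho <- config$latent_cor
  z <- matrix(rnorm(2 * n), n, 2)
  a <- z[, 1]
  c_ <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]

  ov <- config$ov_mean + config$ov_loading * a + rnorm(n, 0, config$ov_sd)
  vd <- config$vd_mean + config$vd_loading * c_ + rnorm(n, 0, config$vd_sd)
  n_clip <- sum(vd < 0)
  vd <- pmax(vd, 0)
  chose_better <- rbinom(n, 1, plogis(config$choice_beta * vd)) == 1
  chosen <- ifelse(chose_better, ov + vd / 2, ov - vd / 2)
  unchosen <- ifelse(chose_better, ov - vd / 2, ov + vd / 2)
  salience <- abs(ov - mean(ov))
  liking <- 3 + config$liking_loading * a + rnorm(n, 0, config$rating_sd)
  confidence <- 3.5 + config$confidence_loading * c_ +
    rnorm(n, 0, config$rating_sd)
  anxiety <- 2.5 + config$anxiety_loading * c_ + rnorm(n, 0, config$rating_sd)
  if (config$rating_scale == "discrete") {
    as_key <- function(x) pmin(pmax(round(x), 1), 5)
    liking <- as_key(liking)
    confidence <- as_key(confidence)
    anxiety <- as_key(anxiety)
  }

  mu <- config$rt_meanlog0 + config$beta_vd * vd + config$beta_ov * ov
  rt <- config$rt_shift + exp(mu + config$rt_sdlog * rnorm(n))
  responded <- rt <= config$rt_cap
  rt[!responded] <- NA_real_

  measures <- data.frame(
    participant_id = rep_len(seq_len(config$n_participants), n),
    chosen_value = chosen, unchosen_value = unchosen,
    value_difference = vd, overall_value = ov, set_salience = salience,
    anxiety = anxiety, liking = liking, confidence = confidence,
    rt = rt, responded = responded, chose_better = chose_better)
  attr(measures, "n_vd_clipped") <- n_clip
  list(measures = measures, latents = cbind(a = a, c = c_))
}
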