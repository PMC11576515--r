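#' Drift-diffusion configuration with stimulus/motor non-decision jitter
#'
#' A neurally informed drift-diffusion model: accumulation starts a
#' stimulus non-decision time `t_s ~ U(0, stim_jitter)` after stimulus
#' onset, runs from `bound/2` between absorbing bounds at 0 and `bound`,
#' and the overt response follows absorption after a motor time
#' `t_m ~ U(0, motor_jitter)`. The ratio `stim_jitter / motor_jitter`
#' controls whether the accumulation window is more tightly coupled to the
#' stimulus or to the response. Canonical jitter scenarios: 2/1
#' (0.2 s / 0.1 s), 1/1 (0.2 s / 0.2 s) and 1/2 (0.1 s / 0.2 s); see
#' [ddm_scenarios()].
#'
#' Drift/bound/noise defaults are package choices (documented in the
#' methods vignette): `bound = 1`, `noise_sd = 0.8`, drift 1.5 for strong
#' and 0.7 for weak evidence, giving decision times of roughly 0.3-0.4 s.
#'
#' @param n_trials trials to simulate.
#' @param drift drift rate v (signal strength).
#' @param bound separation a (> 0); start point is `bound/2`.
#' @param noise_sd diffusion coefficient s.
#' @param dt Euler step (s).
#' @param stim_jitter,motor_jitter uniform non-decision jitter widths (s).
#' @param max_time cap on decision time; non-absorbed runs are flagged.
#' @param motor_mode trace behaviour during motor time: `"hold"` keeps the
#'   hit bound value until the response then drops to 0; `"end"` ends the
#'   trace at absorption.
#' @param boundary_correction apply the Euler continuity correction
#'   (shrinks the effective bound by `0.5826 * s * sqrt(dt)` to offset the
#'   discrete-time absorption bias).
#' @return list of class `ddm_config`.
#' @export
ddm_config <- function(n_trials = 300, drift = 1.5, bound = 1,
                       noise_sd = 0.8, dt = 0.002,
                       stim_jitter = 0.2, motor_jitter = 0.1,
                       max_time = 3, motor_mode = c("hold", "end"),
                       boundary_correction = TRUE) {
  stopifnot(dt > 0, bound > 0, stim_jitter >= 0, motor_jitter >= 0,
            noise_sd >= 0, max_time > 0)
  motor_mode <- match.arg(motor_mode)
  structure(as.list(environment()), class = "ddm_config")
}

#' Canonical stimulus/motor jitter scenarios
#'
#' Returns the three jitter regimes used throughout: ratio 2/1
#' (`stim_jitter = 0.2`, `motor_jitter = 0.1`), 1/1 (both 0.2) and 1/2
#' (0.1 / 0.2), in that order.
#' @export
ddm_scenarios <- function() {
  list(`2/1` = c(stim_jitter = 0.2, motor_jitter = 0.1),
       `1/1` = c(stim_jitter = 0.2, motor_jitter = 0.2),
       `1/2` = c(stim_jitter = 0.1, motor_jitter = 0.2))
}

#' Simulate drift-diffusion accumulator traces
#'
#' Euler-Maruyama integration of all trials in lock step. Decision time is
#' the (linearly interpolated) bound-crossing time, so with `noise_sd = 0`
#' the deterministic first-passage time `(bound/2) / drift` is exact. With
#' noise, the continuity correction (on by default) removes the leading
#' discretization bias of the absorption time, so the mean decision time
#' matches the closed form `(a/(2v)) * tanh(a v / (2 s^2))` up to
#' Monte-Carlo error (see [ddm_mean_decision_time()]).
#'
#' Traces are returned on a common grid at `dt`: zero before `t_s`, the
#' simulated accumulator path during accumulation, then (default) the hit
#' bound value held during the motor time and zero after the response.
#'
#' @param config a [ddm_config()].
#' @param store_traces set `FALSE` to skip trace storage (e.g. for large
#'   first-passage-time checks).
#' @return list of class `ddm_traces`: `traces` (trials x time matrix or
#'   `NULL`), `times`, `dt`, `rts` (s), `decision_times`, `t_s`, `t_m`,
#'   `choices` (+1 upper / -1 lower bound), `flagged` (non-absorbed
#'   trials), `config`, and `scenario_ratio`
#'   (`stim_jitter / motor_jitter`, echoed for provenance).
#' @export
simulate_ddm <- function(config = ddm_config(), store_traces = TRUE) {
  stopifnot(inherits(config, "ddm_config"))
  n <- config$n_trials; dt <- config$dt
  a <- config$bound; v <- config$drift; s <- config$noise_sd
  corr <- if (config$boundary_correction && s > 0) 0.5826 * s * sqrt(dt) else 0
  up <- a - corr; lo <- corr
  t_s <- runif(n, 0, config$stim_jitter)
  t_m <- runif(n, 0, config$motor_jitter)
  k0 <- floor(t_s / dt)                       # pre-accumulation bins

  max_steps <- ceiling(config$max_time / dt)
  path <- if (store_traces) matrix(NA_real_, n, max_steps) else NULL
  x <- rep(a / 2, n)
  prev <- x
  dtime <- rep(NA_real_, n)
  choice <- integer(n)
  active <- rep(TRUE, n)
  step <- 0L
  while (any(active) && step < max_steps) {
    step <- step + 1L
    idx <- which(active)
    prev[idx] <- x[idx]
    x[idx] <- x[idx] + v * dt +
      if (s > 0) s * sqrt(dt) * rnorm(length(idx)) else 0
    hit_up <- idx[x[idx] >= up]
    hit_lo <- idx[x[idx] <= lo]
    if (length(hit_up)) {
      frac <- (up - prev[hit_up]) / (x[hit_up] - prev[hit_up])
      dtime[hit_up] <- (step - 1 + frac) * dt
      x[hit_up] <- a
      choice[hit_up] <- 1L
      active[hit_up] <- FALSE
    }
    if (length(hit_lo)) {
      frac <- (lo - prev[hit_lo]) / (x[hit_lo] - prev[hit_lo])
      dtime[hit_lo] <- (step - 1 + frac) * dt
      x[hit_lo] <- 0
      choice[hit_lo] <- -1L
      active[hit_lo] <- FALSE
    }
    if (store_traces) path[cbind(idx, step)] <- x[idx]
  }
  flagged <- which(is.na(dtime))
  if (length(flagged)) {
    dtime[flagged] <- config$max_time
    choice[flagged] <- ifelse(x[flagged] >= a / 2, 1L, -1L)
  }
  rts <- t_s + dtime + t_m

  traces <- NULL; times <- NULL
  if (store_traces) {
    nt <- ceiling((max(rts) + 0.05) / dt) + 1L
    times <- (seq_len(nt) - 1L) * dt
    traces <- matrix(0, n, nt)
    for (i in seq_len(n)) {
      kd <- min(ceiling(dtime[i] / dt), max_steps)      # accumulation bins
      idx <- k0[i] + seq_len(kd)
      idx <- idx[idx <= nt]
      traces[i, idx] <- path[i, seq_along(idx)]
      target <- if (choice[i] > 0) a else 0
      if (config$motor_mode == "hold") {
        km <- round(t_m[i] / dt)
        if (km > 0) {
          last <- k0[i] + kd
          midx <- (last + 1L):min(last + km, nt)
          if (length(midx) && midx[1] <= nt) traces[i, midx] <- target
        }
      }
    }
  }
  structure(list(traces = traces, times = times, dt = dt, rts = rts,
                 decision_times = dtime, t_s = t_s, t_m = t_m,
                 choices = choice, flagged = flagged, config = config,
                 scenario_ratio = config$stim_jitter / config$motor_jitter),
            class = "ddm_traces")
}

#' Closed-form mean decision time of the symmetric DDM
#'
#' Mean first-passage time to either of two absorbing bounds at 0 and `a`
#' from the midpoint, with drift `v` and diffusion `s`:
#' `(a/(2v)) * tanh(a v / (2 s^2))`. For `v = 0` the limit `a^2/(4 s^2)`.
#' The analytic oracle for the simulator.
#'
#' @param drift,bound,noise_sd DDM parameters.
#' @export
ddm_mean_decision_time <- function(drift, bound, noise_sd) {
  if (drift == 0) return(bound^2 / (4 * noise_sd^2))
  (bound / (2 * drift)) * tanh(bound * drift / (2 * noise_sd^2))
}

#' Concatenate DDM traces into a continuous single-channel recording
#'
#' Lays the per-trial accumulator traces out sequentially with an
#' intertrial interval, producing an [eeg_recording()] (one channel,
#' arbitrary units) and an [event_table()] with stimulus onsets and
#' responses, ready for [time_expand()] / [solve_deconv()].
#'
#' @param ddm a `ddm_traces` object (with stored traces).
#' @param iti intertrial interval (s).
#' @param pad leading/trailing quiet time (s).
#' @export
ddm_traces_to_recording <- function(ddm, iti = 1.5, pad = 2) {
  stopifnot(inherits(ddm, "ddm_traces"), !is.null(ddm$traces))
  srate <- 1 / ddm$dt
  n <- nrow(ddm$traces); nt <- ncol(ddm$traces)
  occupied <- nt + sec_to_samp(iti, srate)
  ns <- sec_to_samp(pad, srate) * 2L + n * occupied
  x <- numeric(ns)
  stim <- integer(n)
  for (i in seq_len(n)) {
    s0 <- sec_to_samp(pad, srate) + (i - 1L) * occupied + 1L
    stim[i] <- s0
    x[s0 + seq_len(nt) - 1L] <- ddm$traces[i, ]
  }
  resp <- stim + sec_to_samp(ddm$rts, srate)
  rec <- eeg_recording(matrix(x, 1), srate, "ACC")
  ev <- event_table(data.frame(participant_id = 1L, stimulus_sample = stim,
                               response_sample = resp, rt = ddm$rts),
                    srate)
  list(recording = rec, events = ev)
}
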