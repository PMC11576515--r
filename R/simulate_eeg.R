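#' Component kernel generators
#'
#' `stimulus_kernel` is a positivity shaped as a half-sine over
#' `[0, 2*peak]` seconds multiplied by a Gaussian window centred on the
#' peak (default peak latency 0.35 s, width 0.4 s), normalized to unit
#' maximum. `response_kernel` is a biphasic wave (one sine cycle, Gaussian
#' windowed) centred on the response, normalized to unit maximum absolute
#' amplitude. Both return a list with `values` and `onset_s`, the kernel's
#' start time relative to its event; any such list (a "kernel") can be
#' passed to [eeg_sim_config()], so shapes are pluggable.
#'
#' @param srate sampling rate (Hz).
#' @param peak peak latency in seconds after the event.
#' @param width Gaussian window full width (s); the sd is `width/4`.
#' @export
stimulus_kernel <- function(srate, peak = 0.35, width = 0.4) {
  tt <- seq(0, 2 * peak, by = 1 / srate)
  v <- sin(pi * tt / (2 * peak)) * exp(-(tt - peak)^2 / (2 * (width / 4)^2))
  list(values = v / max(v), onset_s = 0)
}

#' @rdname stimulus_kernel
#' @param half half-duration of the biphasic wave (s).
#' @export
response_kernel <- function(srate, half = 0.3, width = 0.5) {
  tt <- seq(-half, half, by = 1 / srate)
  v <- sin(pi * tt / half) * exp(-tt^2 / (2 * (width / 4)^2))
  list(values = v / max(abs(v)), onset_s = -half)
}

#' EEG simulation configuration
#'
#' Describes how a continuous recording is assembled from per-trial
#' component placements:
#'
#' * a stimulus-locked transient at each stimulus onset with amplitude
#'   `stim_base + appraisal_gain * a` (microvolts), parietal topography;
#' * an optional response-locked component at each response with amplitude
#'   `resp_base + choice_gain * (-c)` (easier trials, lower difficulty `c`,
#'   give larger amplitudes), frontocentral topography;
#' * an optional accumulation ramp rising linearly from
#'   `stimulus + ramp_onset` to a peak of `ramp_amplitude` at the response,
#'   then decaying over `ramp_fall` seconds, centroparietal topography;
#' * additive noise: white Gaussian `noise_sd`, optionally spectrally
#'   shaped as `1/f^noise_exponent`.
#'
#' Setting a gain/base to 0 switches a component off; with
#' `resp_base = choice_gain = ramp_amplitude = 0` any response-locked
#' structure downstream is attributable solely to stimulus-component
#' overlap.
#'
#' @param channels channel labels; positions are looked up in
#'   [template_montage()].
#' @param srate sampling rate (Hz; default 250, a typical analysis rate).
#' @param iti intertrial interval (s) between response and next stimulus
#'   (default 1.5 as in the choice task emulated).
#' @param stim_kernel,resp_kernel kernels (see [stimulus_kernel()]).
#' @param stim_base,appraisal_gain stimulus amplitude model (microvolts).
#' @param resp_base,choice_gain response amplitude model.
#' @param ramp_amplitude,ramp_onset,ramp_fall accumulation-ramp component
#'   (`ramp_amplitude = 0` disables it).
#' @param stim_topo,resp_topo,ramp_topo named per-channel weights; missing
#'   channels get 0.
#' @param noise_sd white-noise sd (microvolts).
#' @param noise_exponent spectral exponent alpha of `1/f^alpha` noise
#'   (0 = white).
#' @param pad leading/trailing quiet time (s); keep it at least as long as
#'   the widest deconvolution window.
#' @return list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(channels = c("Fz", "Cz", "Pz", "Oz"),
                           srate = 250, iti = 1.5,
                           stim_kernel = NULL, resp_kernel = NULL,
                           stim_base = 10, appraisal_gain = 2,
                           resp_base = 6, choice_gain = 2,
                           ramp_amplitude = 0, ramp_onset = 0.2,
                           ramp_fall = 0.1,
                           stim_topo = c(Fz = 0.2, Cz = 0.6, Pz = 1, Oz = 0.5),
                           resp_topo = c(Fz = 1, Cz = 0.8, Pz = 0.3, Oz = 0.1),
                           ramp_topo = c(Cz = 0.7, Pz = 1, Oz = 0.3),
                           noise_sd = 10, noise_exponent = 0,
                           pad = 3) {
  stopifnot(srate > 0, iti >= 0, noise_sd >= 0, pad >= 0)
  if (is.null(stim_kernel)) stim_kernel <- stimulus_kernel(srate)
  if (is.null(resp_kernel)) resp_kernel <- response_kernel(srate)
  montage <- template_montage(channels)
  topo_vec <- function(w) {
    v <- setNames(numeric(length(channels)), channels)
    v[intersect(names(w), channels)] <- w[intersect(names(w), channels)]
    v
  }
  structure(list(
    channels = channels, positions = as.matrix(montage[, c("x", "y", "z")]),
    srate = srate, iti = iti,
    stim_kernel = stim_kernel, resp_kernel = resp_kernel,
    stim_base = stim_base, appraisal_gain = appraisal_gain,
    resp_base = resp_base, choice_gain = choice_gain,
    ramp_amplitude = ramp_amplitude, ramp_onset = ramp_onset,
    ramp_fall = ramp_fall,
    stim_topo = topo_vec(stim_topo), resp_topo = topo_vec(resp_topo),
    ramp_topo = topo_vec(ramp_topo),
    noise_sd = noise_sd, noise_exponent = noise_exponent, pad = pad),
    class = "eeg_sim_config")
}

shaped_noise <- function(nch, ns, sd, exponent) {
  if (sd == 0) return(matrix(0, nch, ns))
  w <- matrix(rnorm(nch * ns, 0, sd), nch, ns)
  if (exponent == 0) return(w)
  f <- c(1, seq_len(ns - 1))                  # avoid f = 0
  f <- pmin(f, ns - f + 1)                    # symmetric frequency index
  g <- f^(-exponent / 2)
  out <- t(apply(w, 1, function(v) Re(stats::fft(stats::fft(v) * g,
                                                 inverse = TRUE)) / ns))
  out * (sd / sd(out))                        # restore requested sd
}

#' Simulate a continuous EEG recording with known ground truth
#'
#' Lays trials out sequentially (stimulus, response after `rt`, then `iti`),
#' places the configured component kernels with per-trial amplitudes driven
#' by the latent constructs, applies channel topographies and adds noise.
#' Trials without a response contribute only a stimulus component and
#' occupy `rt_cap` seconds.
#'
#' The returned ground truth stores every placement (component, onset
#' sample, amplitude) together with the kernels, topographies and the noise
#' realization, so that `recording = sum of placements + noise` holds
#' exactly; see [reconstruct_ground_truth()].
#'
#' @param measures data frame from [simulate_trial_measures()] (needs `rt`,
#'   `responded`, `participant_id`).
#' @param latents n x 2 matrix of latent `a`, `c`.
#' @param config an [eeg_sim_config()].
#' @param rt_cap time allotted to no-response trials (s).
#' @return list with `recording` ([eeg_recording()]), `events`
#'   ([event_table()]) and `truth` (class `eeg_ground_truth`).
#' @export
simulate_recording <- function(measures, latents, config = eeg_sim_config(),
                               rt_cap = 4) {
  stopifnot(inherits(config, "eeg_sim_config"),
            nrow(measures) == nrow(latents))
  srate <- config$srate
  n <- nrow(measures)
  rt <- measures$rt
  occupied <- ifelse(is.na(rt), rt_cap, rt) + config$iti
  resp_post <- with(config$resp_kernel,
                    onset_s + (length(values) - 1) / srate)
  if (config$iti < resp_post)
    stop2("iti (", config$iti, " s) too short for the response kernel tail (",
          resp_post, " s): consecutive trials would overlap")
  stim_s <- config$pad + c(0, cumsum(occupied[-n]))
  stim_samp <- sec_to_samp(stim_s, srate) + 1L
  resp_samp <- ifelse(is.na(rt), NA_integer_,
                      stim_samp + sec_to_samp(rt, srate))
  ns <- max(stim_samp + sec_to_samp(rt_cap, srate)) +
    sec_to_samp(config$pad, srate)
  nch <- length(config$channels)

  signal <- matrix(0, nch, ns)
  placements <- vector("list", 3 * n); np <- 0L
  put <- function(component, values, onset_samp, amplitude, topo) {
    idx <- onset_samp + seq_along(values) - 1L
    keep <- idx >= 1 & idx <= ns
    signal[, idx[keep]] <<- signal[, idx[keep]] +
      amplitude * outer(topo, values[keep])
    np <<- np + 1L
    placements[[np]] <<- data.frame(component = component,
                                    onset_sample = onset_samp,
                                    amplitude = amplitude,
                                    n_samples = length(values))
  }
  a <- latents[, 1]; c_ <- latents[, 2]
  ramp_kernels <- vector("list", n)
  for (i in seq_len(n)) {
    amp_s <- config$stim_base + config$appraisal_gain * a[i]
    if (amp_s != 0)
      put("stimulus", config$stim_kernel$values,
          stim_samp[i] + sec_to_samp(config$stim_kernel$onset_s, srate),
          amp_s, config$stim_topo)
    if (!is.na(resp_samp[i])) {
      amp_r <- config$resp_base + config$choice_gain * (-c_[i])
      if (amp_r != 0)
        put("response", config$resp_kernel$values,
            resp_samp[i] + sec_to_samp(config$resp_kernel$onset_s, srate),
            amp_r, config$resp_topo)
      if (config$ramp_amplitude != 0) {
        n_rise <- resp_samp[i] - stim_samp[i] -
          sec_to_samp(config$ramp_onset, srate)
        if (n_rise > 1) {
          n_fall <- sec_to_samp(config$ramp_fall, srate)
          rv <- c(seq(0, 1, length.out = n_rise),
                  seq(1, 0, length.out = n_fall + 1)[-1])
          ramp_kernels[[i]] <- rv
          put("ramp", rv,
              stim_samp[i] + sec_to_samp(config$ramp_onset, srate),
              config$ramp_amplitude, config$ramp_topo)
        }
      }
    }
  }
  noise <- shaped_noise(nch, ns, config$noise_sd, config$noise_exponent)
  rec <- eeg_recording(signal + noise, srate, config$channels,
                       channel_positions = config$positions)
  ev_df <- cbind(data.frame(stimulus_sample = stim_samp,
                            response_sample = resp_samp),
                 measures)
  events <- event_table(ev_df, srate)
  truth <- structure(list(
    placements = do.call(rbind, placements[seq_len(np)]),
    kernels = list(stimulus = config$stim_kernel$values,
                   response = config$resp_kernel$values,
                   ramp = ramp_kernels),
    topographies = list(stimulus = config$stim_topo,
                        response = config$resp_topo,
                        ramp = config$ramp_topo),
    noise = noise, latents = latents, config = config,
    n_samples = ns), class = "eeg_ground_truth")
  list(recording = rec, events = events, truth = truth)
}

#' Reconstruct the noiseless signal from a ground-truth object
#'
#' Sums all stored component placements; adding `truth$noise` reproduces
#' the simulated recording exactly (to machine precision).
#'
#' @param truth an `eeg_ground_truth` from [simulate_recording()].
#' @return channels x samples matrix.
#' @export
reconstruct_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "eeg_ground_truth"))
  cfg <- truth$config
  nch <- length(cfg$channels)
  out <- matrix(0, nch, truth$n_samples)
  pl <- truth$placements
  ramp_i <- 0L
  for (k in seq_len(nrow(pl) %||% 0)) {
    comp <- pl$component[k]
    values <- switch(comp,
      stimulus = truth$kernels$stimulus,
      response = truth$kernels$response,
      ramp = {
        ramp_i <- ramp_i + 1L
        # ramp kernels are per-trial; placements store them in trial order
        Filter(Negate(is.null), truth$kernels$ramp)[[ramp_i]]
      })
    topo <- truth$topographies[[comp]]
    idx <- pl$onset_sample[k] + seq_along(values) - 1L
    keep <- idx >= 1 & idx <= truth$n_samples
    out[, idx[keep]] <- out[, idx[keep]] +
      pl$amplitude[k] * outer(topo, values[keep])
  }
  out
}
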