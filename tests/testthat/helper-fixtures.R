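# Small fixtures shared across tests; everything is generated in code.

# A recording that is exactly `kernel` placed at each event, plus optional
# noise - the canonical placement fixture.
kernel_recording <- function(events_at, kernel, srate = 100, n = 2000,
                             nch = 1, noise_sd = 0) {
  x <- matrix(rnorm(nch * n, 0, noise_sd), nch, n)
  for (e in events_at)
    x[, e + seq_along(kernel) - 1] <- x[, e + seq_along(kernel) - 1] +
      matrix(rep(kernel, each = nch), nch)
  eeg_recording(x, srate, paste0("ch", seq_len(nch)))
}

simple_events <- function(stim, rt = NULL, srate = 100, extra = NULL) {
  resp <- if (is.null(rt)) rep(NA_integer_, length(stim)) else
    stim + as.integer(round(rt * srate))
  df <- data.frame(participant_id = 1L, stimulus_sample = stim,
                   response_sample = resp,
                   rt = if (is.null(rt)) NA_real_ else rt)
  if (!is.null(extra)) df <- cbind(df, extra)
  event_table(df, srate)
}

# Two-factor measures with known loadings for construct recovery.
# orthogonal = TRUE makes the empirical latent correlation exactly 0
# (the noiseless-recovery identity needs it).
two_factor_measures <- function(n = 500, noise = 0.1, orthogonal = FALSE) {
  a <- rnorm(n); c_ <- rnorm(n)
  if (orthogonal) {
    a <- as.vector(scale(a))
    c_ <- as.vector(scale(residuals(lm(c_ ~ a))))
  }
  L <- cbind(a = c(1, 0.8, 0, 0, 0.6, 0),
             c = c(0, 0, 1, 0.8, 0, -0.7))
  X <- cbind(a, c_) %*% t(L) + matrix(rnorm(n * 6, 0, noise), n)
  colnames(X) <- paste0("m", 1:6)
  list(X = X, loadings = L)
}
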