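#' Segment a continuous recording into event-locked epochs
#'
#' Cuts fixed-length windows around stimulus onsets or responses. Windows
#' are half-open `[start, end)` in seconds and converted to sample offsets
#' by rounding, so the sample at time 0 is exactly the lock event's sample.
#'
#' With `mask_outside_trial = TRUE` (the default), samples that fall outside
#' their trial's stimulus-to-response range are invalidated (`NA` plus mask):
#' stimulus-locked samples after the response and response-locked samples
#' before the stimulus. This prevents spill-over from neighbouring trials
#' and intertrial intervals from entering trial-locked statistics.
#'
#' Trials whose window extends beyond the recording are excluded (count
#' reported via a message and the `n_excluded` attribute); response-locked
#' epoching drops trials without a response. An empty result is an error.
#'
#' @param recording an [eeg_recording()].
#' @param events an [event_table()] (sample indices at the recording's rate).
#' @param lock `"stimulus"` or `"response"`.
#' @param window numeric length-2, `[start, end)` seconds relative to lock.
#' @param mask_outside_trial invalidate out-of-trial samples?
#' @param verbose emit exclusion messages?
#' @return An object of class `eeg_epochs`: list with `data`
#'   (trials x channels x time, `NA` where masked), `mask` (same shape,
#'   `TRUE` = missing), `times`, `srate`, `lock`, `baseline_window`,
#'   `kept_trial_ids`, `channel_labels`, and the retained `events` rows.
#' @export
epoch_events <- function(recording, events, lock = c("stimulus", "response"),
                         window, mask_outside_trial = TRUE, verbose = TRUE) {
  lock <- match.arg(lock)
  stopifnot(inherits(recording, "eeg_recording"), length(window) == 2L,
            window[2] > window[1])
  srate <- recording$srate
  ev_srate <- attr(events, "srate")
  if (!is.null(ev_srate) && abs(ev_srate - srate) > 1e-9)
    stop2("event table srate (", ev_srate, ") does not match recording (",
          srate, ")")
  ev <- as.data.frame(events)
  ev$.trial <- seq_len(nrow(ev))
  if (lock == "response") {
    dropped <- sum(is.na(ev$response_sample))
    ev <- ev[!is.na(ev$response_sample), , drop = FALSE]
    if (dropped > 0) log_msg(verbose, dropped, " trial(s) without response dropped")
  }
  lock_samp <- if (lock == "stimulus") ev$stimulus_sample else ev$response_sample
  off0 <- sec_to_samp(window[1], srate)
  nt <- sec_to_samp(window[2], srate) - off0
  first <- lock_samp + off0
  ok <- first >= 1 & (first + nt - 1) <= n_samples(recording)
  if (any(!ok)) log_msg(verbose, sum(!ok),
                        " trial(s) excluded: window outside recording")
  ev <- ev[ok, , drop = FALSE]; lock_samp <- lock_samp[ok]; first <- first[ok]
  if (nrow(ev) == 0L) stop2("no epochs left after exclusion")
  nch <- nrow(recording$data)
  times <- (off0 + seq_len(nt) - 1L) / srate
  data <- array(NA_real_, dim = c(nrow(ev), nch, nt))
  mask <- array(FALSE, dim = c(nrow(ev), nch, nt))
  for (i in seq_len(nrow(ev))) {
    idx <- first[i]:(first[i] + nt - 1L)
    data[i, , ] <- recording$data[, idx, drop = FALSE]
    if (mask_outside_trial) {
      if (lock == "stimulus" && !is.na(ev$response_sample[i])) {
        bad <- idx > ev$response_sample[i]
      } else if (lock == "response") {
        bad <- idx < ev$stimulus_sample[i]
      } else bad <- rep(FALSE, nt)
      if (any(bad)) {
        mask[i, , bad] <- TRUE
        data[i, , bad] <- NA_real_
      }
    }
  }
  structure(
    list(data = data, mask = mask, times = times, srate = srate, lock = lock,
         baseline_window = NULL, kept_trial_ids = ev$.trial,
         channel_labels = recording$channel_labels,
         events = ev[setdiff(names(ev), ".trial")],
         n_excluded = sum(!ok)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples, ", x$lock, "-locked [", x$times[1], ", ",
      x$times[length(x$times)] + 1 / x$srate, ") s @ ", x$srate, " Hz\n",
      sep = "")
  if (!is.null(x$baseline_window))
    cat("  baseline: [", x$baseline_window[1], ", ", x$baseline_window[2],
        ") s\n", sep = "")
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over unmasked samples in the
#' baseline window (half-open, seconds). Trials with no unmasked baseline
#' sample on some channel are flagged (attribute `flagged_trials`), not
#' silently zeroed.
#'
#' @param epochs an `eeg_epochs` object.
#' @param window length-2 `[start, end)` seconds; must overlap the epoch
#'   time axis.
#' @return corrected `eeg_epochs` with `baseline_window` recorded.
#' @export
baseline_correct <- function(epochs, window) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(window) == 2L)
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) stop2("baseline window does not overlap the epoch time axis")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean,
                na.rm = TRUE)                       # trials x channels
  flagged <- which(apply(is.na(base), 1, any))
  if (length(flagged))
    warning(length(flagged), " trial(s) with no unmasked baseline samples",
            call. = FALSE)
  base[is.na(base)] <- 0
  epochs$data <- epochs$data - as.vector(base)  # recycles over time (3rd dim)
  epochs$baseline_window <- window
  attr(epochs, "flagged_trials") <- flagged
  epochs
}

#' Reject epochs containing artefacts
#'
#' Removes trials on which any unmasked sample exceeds `amp_limit` in
#' absolute amplitude, or any successive-sample absolute difference exceeds
#' `gradient_limit`, on any channel. Defaults follow common practice for
#' clean adult EEG (+-150 microvolt amplitude, 50 microvolt gradient).
#'
#' @param epochs an `eeg_epochs` object.
#' @param amp_limit amplitude threshold in microvolts (> 0).
#' @param gradient_limit successive-difference threshold in microvolts (> 0).
#' @return list with `epochs` (survivors) and `rejected` (logical per input
#'   trial, for audit).
#' @export
reject_epochs <- function(epochs, amp_limit = 150, gradient_limit = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"), amp_limit > 0, gradient_limit > 0)
  n <- n_trials(epochs)
  rejected <- logical(n)
  for (i in seq_len(n)) {
    x <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    amp_bad <- any(abs(x) > amp_limit, na.rm = TRUE)
    grad_bad <- any(abs(x[, -1, drop = FALSE] -
                        x[, -ncol(x), drop = FALSE]) > gradient_limit,
                    na.rm = TRUE)
    rejected[i] <- amp_bad || grad_bad
  }
  if (all(rejected)) stop2("all trials rejected")
  keep <- which(!rejected)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$mask <- epochs$mask[keep, , , drop = FALSE]
  out$kept_trial_ids <- epochs$kept_trial_ids[keep]
  out$events <- epochs$events[keep, , drop = FALSE]
  list(epochs = out, rejected = rejected)
}

#' Electrode adjacency from channel positions
#'
#' Channels are neighbours iff their Euclidean distance is strictly below
#' `distance_threshold` (same units as the positions). The relation is
#' symmetric and irreflexive. Duplicate coordinates trigger a warning
#' (neighbours at distance 0). The default threshold on the unit-sphere
#' [template_montage()] (0.7) gives a median neighbour count of 4.
#'
#' @param positions channels x 3 coordinate matrix (or montage data frame).
#' @param distance_threshold positive distance cutoff.
#' @return object of class `adjacency_graph`: `n_channels`, `neighbors`
#'   (list of integer vectors), `labels`, `matrix` (logical adjacency).
#' @export
build_adjacency <- function(positions, distance_threshold = 0.7) {
  if (is.data.frame(positions)) {
    labels <- positions$label %||% rownames(positions)
    positions <- as.matrix(positions[, c("x", "y", "z")])
  } else {
    labels <- rownames(positions)
    positions <- as.matrix(positions)
  }
  stopifnot(nrow(positions) >= 1, distance_threshold > 0)
  d <- as.matrix(stats::dist(positions))
  if (nrow(positions) > 1 && any(d[upper.tri(d)] < 1e-12))
    warning("duplicate channel coordinates: neighbours at distance 0",
            call. = FALSE)
  adj <- d < distance_threshold
  diag(adj) <- FALSE
  structure(
    list(n_channels = nrow(positions),
         neighbors = lapply(seq_len(nrow(adj)),
                            function(i) unname(which(adj[i, ]))),
         labels = labels, matrix = adj,
         distance_threshold = distance_threshold),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", x$n_channels, " channels, median ",
      median(lengths(x$neighbors)), " neighbours (threshold ",
      x$distance_threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname resample
#' @export
resample.eeg_epochs <- function(x, target_srate, order = 30) {
  q <- x$srate / target_srate
  if (abs(q - round(q)) > 1e-9)
    stop2("target rate must divide the source rate evenly (factor ", q, ")")
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  d <- dim(x$data)
  pick <- seq(1, d[3], by = q)
  nd <- array(NA_real_, c(d[1], d[2], length(pick)))
  nm <- array(FALSE, c(d[1], d[2], length(pick)))
  blk <- findInterval(seq_len(d[3]) - 1, pick - 1) # block index per sample
  for (i in seq_len(d[1])) {
    m <- x$data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    filled <- m; filled[is.na(filled)] <- 0
    nd[i, , ] <- decimate_rows(filled, q, order)[, seq_along(pick)]
    msk <- x$mask[i, , , drop = TRUE]
    if (is.null(dim(msk))) msk <- matrix(msk, nrow = 1)
    for (ch in seq_len(d[2]))
      nm[i, ch, ] <- as.logical(tapply(msk[ch, ], blk, any))
  }
  nd[nm] <- NA_real_
  x$data <- nd; x$mask <- nm
  x$times <- x$times[pick]
  x$srate <- target_srate
  x
}
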