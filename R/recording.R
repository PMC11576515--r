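#' Continuous multi-channel EEG recording
#'
#' Container for a continuous voltage series. Voltages are in microvolts,
#' stored as a channels x samples matrix. Channel positions, when present,
#' are 3D coordinates in arbitrary (head-radius) units and are only used to
#' derive electrode neighbourhoods.
#'
#' @param data numeric matrix, channels x samples (microvolts). Finite except
#'   for explicitly missing (`NA`) samples.
#' @param srate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param channel_positions optional numeric matrix (channels x 3).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channel_labels,
                          channel_positions = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop2("`srate` must be a single positive number")
  if (length(channel_labels) != nrow(data))
    stop2("row count of `data` (", nrow(data),
          ") does not match number of channel labels (",
          length(channel_labels), ")")
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    if (nrow(channel_positions) != nrow(data) || ncol(channel_positions) != 3L)
      stop2("`channel_positions` must be a channels x 3 matrix")
    rownames(channel_positions) <- channel_labels
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, srate = srate,
         channel_labels = as.character(channel_labels),
         channel_positions = channel_positions),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz (",
      round(ncol(x$data) / x$srate, 2), " s)\n", sep = "")
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

#' Write / read a recording as raw binary + JSON sidecar
#'
#' The fixture interchange format: little-endian float64 samples in channel
#' order (sample-major: all channels for sample 1, then sample 2, ...),
#' alongside `<path>.json` holding srate, labels and positions.
#'
#' @param rec an [eeg_recording()].
#' @param path path of the binary file; the sidecar is `<path>.json`.
#' @return `write_recording_raw` returns `path` invisibly;
#'   `read_recording_raw` returns an [eeg_recording()].
#' @export
write_recording_raw <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(srate = rec$srate, channel_labels = rec$channel_labels,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data))
  if (!is.null(rec$channel_positions))
    meta$channel_positions <- unname(apply(rec$channel_positions, 1, c,
                                           simplify = FALSE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_raw
#' @export
read_recording_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  pos <- NULL
  if (!is.null(meta$channel_positions)) {
    p <- meta$channel_positions
    pos <- if (is.matrix(p)) p else do.call(rbind, lapply(p, as.numeric))
  }
  eeg_recording(matrix(x, nrow = meta$n_channels),
                srate = meta$srate,
                channel_labels = meta$channel_labels,
                channel_positions = pos)
}

#' Read / write a montage table
#'
#' Montages are tab-separated files with columns `label`, `x`, `y`, `z`.
#'
#' @param path file path.
#' @export
read_montage <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(m)))
    stop2("montage file must have columns: ", paste(need, collapse = ", "))
  m[need]
}

#' @rdname read_montage
#' @param montage data frame with columns label, x, y, z.
#' @export
write_montage <- function(montage, path) {
  write.table(montage, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Template 10-20 electrode positions
#'
#' Approximate unit-sphere coordinates for a 26-channel 10-20 layout.
#' Midline and outer-ring electrodes are placed from standard inclination /
#' azimuth angles; intermediate electrodes are great-circle midpoints of
#' their 10-20 neighbours. Axes: x right, y anterior, z superior. These are
#' template positions intended for neighbourhood construction, not for
#' source analysis.
#'
#' @param labels optional subset of labels to return (in the given order).
#' @return data frame with columns label, x, y, z.
#' @export
template_montage <- function(labels = NULL) {
  sph <- function(incl, az) { # degrees; az 0 = nasion, positive to the right
    i <- incl * pi / 180; a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  pos <- list(
    Cz  = sph(0, 0),
    Fz  = sph(45, 0),    Pz  = sph(45, 180),
    Fpz = sph(90, 0),    Oz  = sph(90, 180),
    Fp1 = sph(90, -18),  Fp2 = sph(90, 18),
    F7  = sph(90, -54),  F8  = sph(90, 54),
    T7  = sph(90, -90),  T8  = sph(90, 90),
    P7  = sph(90, -126), P8  = sph(90, 126),
    O1  = sph(90, -162), O2  = sph(90, 162)
  )
  mid <- function(a, b) { v <- pos[[a]] + pos[[b]]; v / sqrt(sum(v^2)) }
  pos$C3 <- mid("Cz", "T7"); pos$C4 <- mid("Cz", "T8")
  pos$F3 <- mid("Fz", "F7"); pos$F4 <- mid("Fz", "F8")
  pos$P3 <- mid("Pz", "P7"); pos$P4 <- mid("Pz", "P8")
  pos$FC1 <- mid("Fz", "C3"); pos$FC2 <- mid("Fz", "C4")
  pos$CP1 <- mid("Pz", "C3"); pos$CP2 <- mid("Pz", "C4")
  pos$PO3 <- mid("Pz", "O1"); pos$PO4 <- mid("Pz", "O2")
  m <- data.frame(label = names(pos),
                  do.call(rbind, lapply(pos, function(v) {
                    data.frame(x = v[1], y = v[2], z = v[3])
                  })), row.names = NULL)
  if (!is.null(labels)) {
    miss <- setdiff(labels, m$label)
    if (length(miss)) stop2("labels not in template montage: ",
                            paste(miss, collapse = ", "))
    m <- m[match(labels, m$label), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

## ---------------------------------------------------------------------------
## EDF interchange (16-bit European Data Format). A deliberately small
## implementation covering the subset needed for interchange: one common
## sampling rate, 1-second data records, physical units microvolts. The true
## sample count is stored in the reserved header field so that zero-padding
## of the final record round-trips exactly.

pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

#' Write a recording to an EDF file
#'
#' Minimal EDF (16-bit) writer. Data are scaled per channel to the full
#' digital range, written in 1-second records; the final record is
#' zero-padded and the true sample count recorded in the reserved header
#' field (`NSAMP=`), which [read_edf()] uses to truncate on reading.
#' Requires an integer sampling rate.
#'
#' @param rec an [eeg_recording()] (no missing samples).
#' @param path output file path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$srate != round(rec$srate))
    stop2("EDF writer requires an integer sampling rate")
  if (anyNA(rec$data)) stop2("EDF writer does not support missing samples")
  ns <- nrow(rec$data); spr <- as.integer(rec$srate)
  nrec <- ceiling(ncol(rec$data) / spr)
  ntot <- nrec * spr
  x <- cbind(rec$data, matrix(0, ns, ntot - ncol(rec$data)))
  if (any(abs(x) > 9999))
    stop2("EDF writer supports amplitudes up to +-9999 uV")
  ## physical bounds are written with 2 decimals; widen to those exact
  ## values so reader and writer use identical calibration
  pmin_ <- floor(apply(x, 1, min) * 100) / 100
  pmax_ <- ceiling(apply(x, 1, max) * 100) / 100
  flat <- pmax_ - pmin_ < 0.01
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((x - pmin_) * scale + dmin)
  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(s, n) writeChar(pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("erpdeconv", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8)
  wr(sprintf("NSAMP=%d", ncol(rec$data)), 44)
  wr(nrec, 8); wr("1", 8); wr(ns, 4)
  for (l in rec$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in formatC(pmin_, format = "f", digits = 2)) wr(v, 8)
  for (v in formatC(pmax_, format = "f", digits = 2)) wr(v, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Counterpart of [write_edf()]. Supports EDF files with a common sampling
#' rate across channels. Digital values are mapped back to physical units
#' using the per-channel calibration in the header.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  nrec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop2("EDF reader supports a single common sampling rate only")
  out <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nrow = spr[1])[, seq_len(ns)] |> t()
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- (out - dmin) * gain + pmin_
  if (grepl("^NSAMP=", reserved)) {
    n <- as.integer(sub("^NSAMP=", "", reserved))
    out <- out[, seq_len(n), drop = FALSE]
  }
  eeg_recording(out, srate = spr[1] / dur, channel_labels = labels)
}

## ---------------------------------------------------------------------------

#' Downsample a recording or epoch set by integer decimation
#'
#' Anti-alias FIR low-pass (cutoff at the new Nyquist, taps normalized to
#' exact unit DC gain so constant signals are preserved exactly) followed by
#' integer decimation. Edges are handled by replicate-padding. The target
#' rate must divide the source rate evenly.
#'
#' For epoch sets, a decimated sample is marked missing if any source sample
#' in its decimation block was missing (conservative mask propagation).
#'
#' @param x an [eeg_recording()] or [epoch_events()] result.
#' @param target_srate new sampling rate in Hz.
#' @param order FIR filter order (default 30).
#' @return object of the same class as `x` at the new rate.
#' @export
resample <- function(x, target_srate, order = 30) UseMethod("resample")

decimate_rows <- function(mat, q, order) {
  if (q == 1L) return(mat)
  h <- signal::fir1(order, 1 / q)
  h <- h / sum(h) # exact unit DC gain
  np <- length(h)
  t(apply(mat, 1, function(v) {
    vp <- c(rep(v[1], np), v, rep(v[length(v)], np))
    f <- stats::filter(vp, h, sides = 2)
    f[(np + 1):(np + length(v))][seq(1, length(v), by = q)]
  }))
}

#' @export
resample.eeg_recording <- function(x, target_srate, order = 30) {
  q <- x$srate / target_srate
  if (abs(q - round(q)) > 1e-9)
    stop2("target rate must divide the source rate evenly (factor ", q, ")")
  q <- as.integer(round(q))
  out <- x
  out$data <- decimate_rows(x$data, q, order)
  rownames(out$data) <- x$channel_labels
  out$srate <- target_srate
  out
}
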