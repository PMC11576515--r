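#' Build a trial design matrix
#'
#' Assembles an intercept plus named per-trial predictors into a design
#' matrix for [fit_mass_univariate()], checking full column rank.
#'
#' @param ... named numeric vectors (one value per trial), or a single data
#'   frame / matrix of predictors.
#' @param intercept include an intercept column (default TRUE).
#' @param n_trials row count, needed only for an intercept-only design.
#' @export
rerp_design <- function(..., intercept = TRUE, n_trials = NULL) {
  args <- list(...)
  if (length(args) == 0L) {
    if (!intercept || is.null(n_trials))
      stop2("an intercept-only design needs `n_trials`")
    return(cbind("(Intercept)" = rep(1, n_trials)))
  }
  if (length(args) == 1L &&
      (is.data.frame(args[[1]]) || is.matrix(args[[1]]))) {
    X <- as.matrix(args[[1]])
  } else {
    if (is.null(names(args)) || any(names(args) == ""))
      stop2("predictors must be named")
    X <- do.call(cbind, args)
  }
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  if (qr(X)$rank < ncol(X)) stop2("design matrix is rank deficient")
  X
}

#' Mass-univariate regression of single-trial voltages
#'
#' Ordinary least squares independently at each channel x time point:
#' voltages across trials are regressed on the design, using only trials
#' with unmasked data at that point (listwise per point). Coefficients are
#' also returned as t-values (beta divided by its standard error), with
#' residual degrees of freedom `n_used - n_predictors` per point. Points
#' with too few trials or a rank-deficient reduced design are set missing
#' and counted in `n_dropped_points`.
#'
#' @param epochs an `eeg_epochs` object.
#' @param design trials x predictors matrix from [rerp_design()]; rows must
#'   match epoch trials.
#' @return list of class `rerp_tmaps`: `beta`, `se`, `t` (arrays
#'   predictors x channels x time), `df` and `n_used` (channels x time),
#'   `predictors`, `times`, `channel_labels`, `lock`, `srate`.
#' @export
fit_mass_univariate <- function(epochs, design) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  design <- as.matrix(design)
  d <- dim(epochs$data)
  if (nrow(design) != d[1])
    stop2("design has ", nrow(design), " rows but epochs have ", d[1],
          " trials")
  p <- ncol(design)
  beta <- se <- array(NA_real_, c(p, d[2], d[3]))
  df <- n_used <- matrix(NA_real_, d[2], d[3])
  dropped <- 0L
  for (ti in seq_len(d[3])) {
    Y_all <- matrix(epochs$data[, , ti], d[1], d[2])
    miss <- is.na(Y_all)
    ## channels sharing a missingness pattern are fitted together
    pat <- apply(miss, 2, function(z) paste(which(z), collapse = ","))
    for (pp in unique(pat)) {
      chs <- which(pat == pp)
      keep <- !miss[, chs[1]]
      nu <- sum(keep)
      if (nu < p + 2) { dropped <- dropped + length(chs); next }
      X <- design[keep, , drop = FALSE]
      qrx <- qr(X)
      if (qrx$rank < p) { dropped <- dropped + length(chs); next }
      Y <- Y_all[keep, chs, drop = FALSE]
      B <- qr.coef(qrx, Y)
      res <- Y - X %*% B
      dfp <- nu - p
      sigma2 <- colSums(res^2) / dfp
      XtXinv_d <- diag(chol2inv(qr.R(qrx)))
      beta[, chs, ti] <- B
      se[, chs, ti] <- sqrt(outer(XtXinv_d, sigma2))
      df[chs, ti] <- dfp
      n_used[chs, ti] <- nu
    }
  }
  if (dropped > 0)
    message(dropped, " channel x time point(s) dropped ",
            "(insufficient trials or rank deficiency)")
  tmap <- beta / se
  structure(list(beta = beta, se = se, t = tmap, df = df, n_used = n_used,
                 predictors = colnames(design) %||% paste0("b", seq_len(p) - 1),
                 times = epochs$times, channel_labels = epochs$channel_labels,
                 lock = epochs$lock, srate = epochs$srate,
                 n_dropped_points = dropped),
            class = "rerp_tmaps")
}

#' @export
print.rerp_tmaps <- function(x, ...) {
  cat("<rerp_tmaps> ", length(x$predictors), " predictor(s) x ",
      length(x$channel_labels), " channels x ", length(x$times),
      " time points (", x$lock, "-locked)\n", sep = "")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted ERPs at discrete predictor levels
#'
#' Evaluates the fitted linear model `intercept + level * beta` per channel
#' and time point, at the mean predictor value within each tercile (or at
#' user-supplied levels), producing the familiar tercile-banded display
#' curves.
#'
#' @param tmaps an `rerp_tmaps` fit (the design must contain an intercept).
#' @param predictor predictor name.
#' @param values per-trial predictor values used to form terciles, or
#'   `NULL` if `levels` given.
#' @param levels explicit level values (optional).
#' @return list: `curves` (levels x channels x time), `levels`.
#' @export
predicted_erps <- function(tmaps, predictor, values = NULL, levels = NULL) {
  stopifnot(inherits(tmaps, "rerp_tmaps"))
  ip <- match(predictor, tmaps$predictors)
  if (is.na(ip)) stop2("unknown predictor: ", predictor)
  i0 <- match("(Intercept)", tmaps$predictors)
  if (is.na(i0)) stop2("fit has no intercept term")
  if (is.null(levels)) {
    if (is.null(values)) stop2("give `values` or `levels`")
    levels <- tercile_levels(values)
  }
  nl <- length(levels)
  d <- dim(tmaps$beta)
  curves <- array(NA_real_, c(nl, d[2], d[3]))
  for (k in seq_len(nl))
    curves[k, , ] <- tmaps$beta[i0, , ] + levels[k] * tmaps$beta[ip, , ]
  list(curves = curves, levels = levels)
}

#' Within-tercile means of a predictor
#' @param x numeric vector.
#' @export
tercile_levels <- function(x) {
  br <- quantile(x, c(0, 1 / 3, 2 / 3, 1), names = FALSE)
  g <- cut(x, unique(br), include.lowest = TRUE)
  as.numeric(tapply(x, g, mean))
}

#' RT-sorted single-trial ERP image
#'
#' Orders trials at one channel by a per-trial key (typically RT), with an
#' optional moving average over adjacent sorted trials, and returns the
#' sorted trial x time matrix plus a per-row event-marker track: for
#' response-locked epochs the stimulus onset time (`-rt`) in the epoch
#' frame, for stimulus-locked epochs the response time (`rt`).
#'
#' @param epochs an `eeg_epochs` object.
#' @param channel channel label or index.
#' @param sort_key finite per-trial values to sort by.
#' @param smooth moving-average window in trials (1 = none; must not exceed
#'   the trial count).
#' @return list of class `erp_image`: `image` (sorted trials x time),
#'   `order`, `sort_key` (sorted), `markers`, `times`.
#' @export
erp_image <- function(epochs, channel, sort_key, smooth = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.character(channel)) channel <- match(channel, epochs$channel_labels)
  if (is.na(channel)) stop2("unknown channel")
  if (any(!is.finite(sort_key))) stop2("sort_key must be finite for all trials")
  n <- n_trials(epochs)
  if (length(sort_key) != n) stop2("sort_key length must equal trial count")
  if (smooth > n) stop2("smoothing window exceeds number of trials")
  ord <- order(sort_key)
  img <- matrix(epochs$data[ord, channel, ], n, length(epochs$times))
  if (smooth > 1) {
    half <- floor(smooth / 2)
    sm <- img
    for (i in seq_len(n)) {
      rows <- max(1, i - half):min(n, i + half)
      sm[i, ] <- colMeans(img[rows, , drop = FALSE], na.rm = TRUE)
    }
    img <- sm
  }
  rt <- epochs$events$rt[ord]
  markers <- if (epochs$lock == "response") -rt else rt
  structure(list(image = img, order = ord, sort_key = sort_key[ord],
                 markers = markers, times = epochs$times, smooth = smooth,
                 lock = epochs$lock),
            class = "erp_image")
}

#' @export
plot.erp_image <- function(x, ...) {
  graphics::image(x$times, seq_len(nrow(x$image)), t(x$image),
                  xlab = "time (s)", ylab = "trial (sorted)",
                  useRaster = TRUE, ...)
  graphics::points(x$markers, seq_len(nrow(x$image)), pch = ".", col = 1)
  invisible(x)
}

#' Median-split average ERPs by response time
#'
#' Retains trials with `rt <= rt_max` (if given), splits them at the median
#' RT (ties go to the fast group), and returns per-group mean ERPs over
#' unmasked samples together with histograms of stimulus-onset times
#' relative to the response (the overlap diagnostic of the single-trial
#' display).
#'
#' @param epochs an `eeg_epochs` object (response-locked for the canonical
#'   display, but any lock works).
#' @param rt per-trial RTs in seconds (defaults to the epochs' event RTs).
#' @param rt_max optional RT cutoff in seconds (e.g. 1.25 to emulate
#'   fast-paced tasks).
#' @param hist_breaks bin width (s) for the onset histograms.
#' @return list of class `median_split`: `fast`, `slow` (channels x time
#'   mean ERPs), `n_fast`, `n_slow`, `coverage_fast`, `coverage_slow`
#'   (fraction of trials unmasked per time point), `rt_fast`, `rt_slow`,
#'   `hist_fast`, `hist_slow`, `median_rt`, `n_filtered`.
#' @export
median_split_average <- function(epochs, rt = NULL, rt_max = NULL,
                                 hist_breaks = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  rt <- rt %||% epochs$events$rt
  keep <- is.finite(rt)
  if (!is.null(rt_max)) keep <- keep & rt <= rt_max
  if (sum(keep) < 2) stop2("fewer than 2 trials after rt_max filtering")
  med <- median(rt[keep])
  fast <- keep & rt <= med
  slow <- keep & rt > med
  if (!any(fast) || !any(slow)) stop2("empty group after median split")
  grp_mean <- function(sel) {
    apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
  }
  coverage <- function(sel) {
    apply(!is.na(epochs$data[sel, , , drop = FALSE]), c(2, 3), mean)
  }
  onset_hist <- function(sel) {
    x <- if (epochs$lock == "response") -rt[sel] else rep(0, sum(sel))
    graphics::hist(x, breaks = seq(floor(min(x) / hist_breaks) * hist_breaks,
                                   0, by = hist_breaks),
                   plot = FALSE)
  }
  structure(list(fast = grp_mean(fast), slow = grp_mean(slow),
                 n_fast = sum(fast), n_slow = sum(slow),
                 coverage_fast = coverage(fast), coverage_slow = coverage(slow),
                 rt_fast = rt[fast], rt_slow = rt[slow],
                 hist_fast = if (epochs$lock == "response") onset_hist(fast),
                 hist_slow = if (epochs$lock == "response") onset_hist(slow),
                 median_rt = med, n_filtered = sum(keep),
                 times = epochs$times,
                 channel_labels = epochs$channel_labels),
            class = "median_split")
}

#' Peak latency of an ERP curve
#'
#' Time of the maximum of `curve` within `window`, optionally requiring a
#' minimum fraction of contributing trials (`coverage`) so that sparsely
#' covered epoch edges do not dominate.
#'
#' @param curve numeric vector over `times`.
#' @param times time axis (s).
#' @param window length-2 search window (s).
#' @param coverage optional vector of per-point trial coverage.
#' @param min_coverage minimum coverage (default 0.5).
#' @export
erp_peak <- function(curve, times, window = range(times), coverage = NULL,
                     min_coverage = 0.5) {
  sel <- times >= window[1] & times <= window[2] & is.finite(curve)
  if (!is.null(coverage)) sel <- sel & coverage >= min_coverage
  if (!any(sel)) return(NA_real_)
  times[sel][which.max(curve[sel])]
}
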