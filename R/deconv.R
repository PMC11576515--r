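#' Event design specification for deconvolution
#'
#' Declares, per event type (typically `stimulus` and `response`), which
#' per-trial covariates modulate that event's response and over which FIR
#' window the kernel is estimated. Every event type always has an intercept
#' kernel; covariates are taken by name from the event table. Windows are
#' half-open `[start, end)` seconds relative to the event; the stick basis
#' has one latency bin per sample at the working rate.
#'
#' Continuous covariates are mean-centred within event type before time
#' expansion (`center = TRUE`, default) so that intercept kernels are the
#' average event-locked waveform.
#'
#' @param ... per-event-type specs: named lists with `window` (length 2)
#'   and optional `predictors` (character vector of event-table columns).
#' @param srate working sampling rate (Hz).
#' @param center mean-centre covariates within event type?
#' @return list of class `event_design_spec`.
#' @examples
#' event_design_spec(
#'   stimulus = list(window = c(-2, 2), predictors = "appraisal"),
#'   response = list(window = c(-2, 2), predictors = c("choice", "rt")),
#'   srate = 250)
#' @export
event_design_spec <- function(..., srate, center = TRUE) {
  types <- list(...)
  if (length(types) == 0) stop2("give at least one event type")
  if (is.null(names(types)) || any(names(types) == ""))
    stop2("event types must be named")
  for (nm in names(types)) {
    tp <- types[[nm]]
    if (is.null(tp$window) || length(tp$window) != 2 ||
        !all(is.finite(tp$window)) || tp$window[2] <= tp$window[1])
      stop2("event type '", nm, "': `window` must be finite [start, end)")
    types[[nm]]$predictors <- tp$predictors %||% character()
  }
  pred_ids <- unlist(lapply(names(types), function(nm)
    paste0(nm, ":", c("(Intercept)", types[[nm]]$predictors))))
  if (anyDuplicated(pred_ids)) stop2("duplicate predictor within event type")
  structure(list(types = types, srate = srate, center = center),
            class = "event_design_spec")
}

#' Add a response-time covariate to the stimulus event type
#'
#' Mirrors the response-side RT regressor on the stimulus side, letting
#' stimulus-locked activity vary with response time: either the continuous
#' RT or a median-split indicator (slow = 1, fast = 0). Trials without an
#' RT are modelled intercept-only on the stimulus side (their covariate is
#' set to the centring value), with a message.
#'
#' @param spec an [event_design_spec()] containing a `stimulus` type.
#' @param type `"continuous"` or `"median_split"`.
#' @export
add_rt_modulation <- function(spec, type = c("continuous", "median_split")) {
  stopifnot(inherits(spec, "event_design_spec"))
  type <- match.arg(type)
  if (is.null(spec$types$stimulus)) stop2("spec has no 'stimulus' event type")
  pred <- if (type == "continuous") "rt" else "rt_split"
  spec$types$stimulus$predictors <-
    union(spec$types$stimulus$predictors, pred)
  spec
}

event_samples <- function(events, type) {
  switch(type,
         stimulus = events$stimulus_sample,
         response = events$response_sample,
         if (!is.null(events[[paste0(type, "_sample")]]))
           events[[paste0(type, "_sample")]]
         else stop2("no sample column for event type '", type, "'"))
}

#' Time-expand an event table into a sparse FIR design matrix
#'
#' Builds the stick-basis design: for each event of each type, each latency
#' bin of the type's window contributes the predictor value at row
#' `event_sample + latency` in the column for (type, predictor, latency).
#' Rows are recording samples; the column count is the sum over event types
#' of `n_predictors * n_bins`. Events whose window extends beyond the
#' recording are clipped (counted in `n_clipped`). Trials without a
#' response contribute stimulus events only.
#'
#' The derived covariate `rt_split` (median-split RT indicator) is computed
#' from the event table on the fly; any other predictor must be an event
#' table column.
#'
#' @param events an [event_table()].
#' @param spec an [event_design_spec()] at the recording's sampling rate.
#' @param n_samples number of samples in the recording.
#' @return list of class `time_expanded_design`: sparse `X`
#'   (n_samples x columns), `colmap` (column, event_type, predictor,
#'   latency in s), `excluded` row mask, `centers`, `spec`, `n_clipped`.
#' @export
time_expand <- function(events, spec, n_samples) {
  stopifnot(inherits(spec, "event_design_spec"))
  ev <- as.data.frame(events)
  srate <- spec$srate
  ii <- list(); jj <- list(); xx <- list()
  colmaps <- list()
  centers <- list()
  offset <- 0L
  n_clipped <- 0L
  for (nm in names(spec$types)) {
    tp <- spec$types[[nm]]
    samp <- event_samples(ev, nm)
    keep <- !is.na(samp)
    samp <- samp[keep]
    if (length(samp) == 0) next
    if (any(samp < 1 | samp > n_samples))
      stop2("event samples outside the recording for type '", nm, "'")
    b0 <- sec_to_samp(tp$window[1], srate)
    nb <- sec_to_samp(tp$window[2], srate) - b0
    lat <- b0 + seq_len(nb) - 1L
    preds <- c("(Intercept)", tp$predictors)
    P <- matrix(1, length(samp), length(preds))
    for (k in seq_along(tp$predictors)) {
      pn <- tp$predictors[k]
      v <- if (pn == "rt_split") {
        as.numeric(ev$rt[keep] > median(ev$rt[keep], na.rm = TRUE))
      } else {
        if (is.null(ev[[pn]])) stop2("no event-table column '", pn, "'")
        ev[[pn]][keep]
      }
      if (anyNA(v)) {
        message(sum(is.na(v)), " event(s) of type '", nm,
                "' without '", pn, "': modelled intercept-only")
      }
      if (spec$center) {
        ctr <- mean(v, na.rm = TRUE)
        v <- v - ctr
        centers[[paste0(nm, ":", pn)]] <- ctr
      }
      v[is.na(v)] <- 0
      P[, k + 1L] <- v
    }
    rows <- rep(samp, each = nb) + rep(lat, times = length(samp))
    inside <- rows >= 1 & rows <= n_samples
    n_clipped <- n_clipped + sum(!inside)
    for (k in seq_along(preds)) {
      ii[[length(ii) + 1L]] <- rows[inside]
      jj[[length(jj) + 1L]] <- offset + (k - 1L) * nb +
        rep(seq_len(nb), times = length(samp))[inside]
      xx[[length(xx) + 1L]] <- rep(P[, k], each = nb)[inside]
    }
    colmaps[[nm]] <- data.frame(
      event_type = nm,
      predictor = rep(preds, each = nb),
      latency = rep(lat / srate, times = length(preds)),
      column = offset + seq_len(length(preds) * nb))
    offset <- offset + length(preds) * nb
  }
  X <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                    dims = c(n_samples, offset))
  structure(list(X = X, colmap = do.call(rbind, colmaps), spec = spec,
                 srate = srate, excluded = logical(n_samples),
                 centers = centers, n_clipped = n_clipped),
            class = "time_expanded_design")
}

#' @export
print.time_expanded_design <- function(x, ...) {
  cat("<time_expanded_design> ", nrow(x$X), " samples x ", ncol(x$X),
      " columns (", sum(x$excluded), " samples excluded)\n", sep = "")
  print(table(x$colmap$event_type, x$colmap$predictor))
  invisible(x)
}

#' Exclude artefact-contaminated samples from a deconvolution fit
#'
#' Samples on which any channel exceeds `amp_limit` in absolute amplitude
#' (plus `guard` samples on each side) are dropped from the least-squares
#' fit: their design rows are ignored and the mask is recorded in the
#' design. More than 90% excluded is an error.
#'
#' @param recording the [eeg_recording()] the design was built for.
#' @param design a [time_expand()] result.
#' @param amp_limit threshold in microvolts (default 250).
#' @param guard extra samples excluded around each crossing (default 0).
#' @export
exclude_artifact_intervals <- function(recording, design, amp_limit = 250,
                                       guard = 0) {
  stopifnot(inherits(design, "time_expanded_design"), amp_limit > 0)
  bad <- apply(abs(recording$data) > amp_limit, 2, any)
  bad[is.na(bad)] <- TRUE
  if (guard > 0 && any(bad)) {
    w <- which(bad)
    for (g in seq_len(guard)) bad[pmax(w - g, 1)] <- bad[pmin(w + g, length(bad))] <- TRUE
  }
  if (mean(bad) > 0.9) stop2(">90% of samples excluded as artefacts")
  design$excluded <- design$excluded | bad
  design
}

cgls_solve <- function(X, Y, tol = 1e-10, max_iter = NULL, ridge = 0) {
  ## conjugate gradient on the normal equations, all channels jointly
  max_iter <- max_iter %||% (10L * ncol(X))
  B <- matrix(0, ncol(X), ncol(Y))
  for (ch in seq_len(ncol(Y))) {
    y <- Y[, ch]
    x <- numeric(ncol(X))
    r <- y
    s <- as.vector(Matrix::crossprod(X, r)) - ridge * x
    p <- s
    g0 <- sum(s^2); g <- g0
    it <- 0L
    while (sqrt(g) > tol * sqrt(g0) && it < max_iter && g0 > 0) {
      it <- it + 1L
      q <- as.vector(X %*% p)
      alpha <- g / (sum(q^2) + ridge * sum(p^2))
      x <- x + alpha * p
      r <- r - alpha * q
      s <- as.vector(Matrix::crossprod(X, r)) - ridge * x
      gn <- sum(s^2)
      p <- s + (gn / g) * p
      g <- gn
    }
    if (it >= max_iter && sqrt(g) > tol * sqrt(g0))
      stop2("CGLS did not converge within ", max_iter,
            " iterations (relative gradient ", signif(sqrt(g / g0), 3), ")")
    B[, ch] <- x
  }
  B
}

#' Solve the deconvolution least-squares problem
#'
#' Estimates all event-type kernels jointly, per channel, as the
#' least-squares solution of `design %*% kernels ~ data` over non-excluded
#' samples. The default solver forms the (sparse, band-limited) normal
#' equations and factorises them with a sparse Cholesky decomposition,
#' which for these stick-basis designs is exact and fast; `method =
#' "cgls"` is an iterative conjugate-gradient alternative (relative
#' tolerance `tol`, iteration cap `10 * ncol`) that yields the
#' minimum-norm solution for singular designs. A small `ridge` can
#' stabilise genuinely ill-conditioned designs (off by default).
#'
#' @param design a [time_expand()] result (possibly after
#'   [exclude_artifact_intervals()]).
#' @param recording the matching [eeg_recording()].
#' @param method `"normal"` (sparse Cholesky) or `"cgls"`.
#' @param tol CGLS relative tolerance.
#' @param ridge L2 penalty (0 = plain least squares).
#' @param keep_design store the design in the model (needed by
#'   [correct_overlap()]).
#' @return list of class `deconv_model`: `kernels` (per event type, arrays
#'   predictors x latency x channels with latency dimnames in seconds),
#'   `coef` (columns x channels), `colmap`, `centers`, `diagnostics`
#'   (`residual_norm`, `r_squared`), `srate`, `channel_labels`.
#' @export
solve_deconv <- function(design, recording, method = c("normal", "cgls"),
                         tol = 1e-10, ridge = 0, keep_design = TRUE) {
  stopifnot(inherits(design, "time_expanded_design"),
            inherits(recording, "eeg_recording"))
  method <- match.arg(method)
  if (ncol(design$X) == 0) stop2("empty design")
  keep <- !design$excluded
  if (!any(keep)) stop2("design empty after artefact exclusion")
  X <- design$X[keep, , drop = FALSE]
  Y <- t(recording$data[, keep, drop = FALSE])
  if (method == "normal") {
    A <- Matrix::crossprod(X)
    if (ridge > 0) A <- A + ridge * Matrix::Diagonal(ncol(A))
    ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ch)) {
      message("normal equations singular; falling back to CGLS")
      B <- cgls_solve(X, Y, tol = tol, ridge = ridge)
    } else {
      B <- as.matrix(Matrix::solve(ch, Matrix::crossprod(X, Y)))
    }
  } else {
    B <- cgls_solve(X, Y, tol = tol, ridge = ridge)
  }
  dimnames(B) <- NULL
  fitted <- as.matrix(X %*% B)
  res <- Y - fitted
  rn <- sqrt(colSums(res^2))
  tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  kernels <- list()
  for (nm in unique(design$colmap$event_type)) {
    cm <- design$colmap[design$colmap$event_type == nm, ]
    preds <- unique(cm$predictor)
    lats <- sort(unique(cm$latency))
    arr <- array(NA_real_,
                 c(length(preds), length(lats), nrow(recording$data)),
                 dimnames = list(preds, format(lats, trim = TRUE),
                                 recording$channel_labels))
    for (p in seq_along(preds)) {
      cols <- cm$column[cm$predictor == preds[p]]
      arr[p, , ] <- B[cols, , drop = FALSE]
    }
    kernels[[nm]] <- arr
  }
  structure(list(kernels = kernels, coef = B, colmap = design$colmap,
                 centers = design$centers, srate = design$srate,
                 channel_labels = recording$channel_labels,
                 design = if (keep_design) design,
                 diagnostics = list(residual_norm = rn,
                                    r_squared = 1 - colSums(res^2) / tot,
                                    method = method, ridge = ridge)),
            class = "deconv_model")
}

#' @export
print.deconv_model <- function(x, ...) {
  cat("<deconv_model> event types:",
      paste(names(x$kernels), collapse = ", "), "\n")
  for (nm in names(x$kernels)) {
    d <- dim(x$kernels[[nm]])
    cat("  ", nm, ": ", d[1], " predictor(s) x ", d[2], " latency bins x ",
        d[3], " channel(s)\n", sep = "")
  }
  cat("  mean R^2:", round(mean(x$diagnostics$r_squared), 4), "\n")
  invisible(x)
}

#' Kernel time axis of a deconvolution model
#' @param model a `deconv_model`.
#' @param type event type name.
#' @export
kernel_times <- function(model, type) {
  as.numeric(dimnames(model$kernels[[type]])[[2]])
}

#' Subtract modelled event-type contributions from a recording
#'
#' Reconstructs the contribution of the named event types from the fitted
#' kernels and subtracts it from the data - e.g. removing the stimulus
#' contribution before response-locked epoching (RT-agnostic overlap
#' correction when the stimulus side was modelled without RT terms).
#' Removing all modelled types leaves `data - design %*% coef`, the fit
#' residual, exactly.
#'
#' @param recording the [eeg_recording()] the model was fitted on.
#' @param model a [solve_deconv()] result with `keep_design = TRUE`.
#' @param remove character vector of event types to subtract.
#' @return corrected [eeg_recording()].
#' @export
correct_overlap <- function(recording, model, remove) {
  stopifnot(inherits(model, "deconv_model"))
  if (is.null(model$design))
    stop2("model was fitted with keep_design = FALSE")
  unknown <- setdiff(remove, names(model$kernels))
  if (length(unknown)) stop2("unknown event type(s): ",
                             paste(unknown, collapse = ", "))
  cols <- model$colmap$column[model$colmap$event_type %in% remove]
  contrib <- model$design$X[, cols, drop = FALSE] %*%
    model$coef[cols, , drop = FALSE]
  out <- recording
  out$data <- recording$data - Matrix::t(contrib)
  out$data <- as.matrix(out$data)
  rownames(out$data) <- recording$channel_labels
  out
}

#' Event-type share of reconstructed signal energy
#'
#' Fraction of the summed squared reconstructed contribution attributable
#' to each event type: `sum(contribution^2)` per type, normalized across
#' types. Used to quantify how deconvolution assigns accumulation energy
#' between stimulus and response events.
#'
#' @param model a [solve_deconv()] result with stored design.
#' @return named numeric vector summing to 1.
#' @export
energy_share <- function(model) {
  stopifnot(inherits(model, "deconv_model"))
  if (is.null(model$design)) stop2("model needs keep_design = TRUE")
  types <- names(model$kernels)
  e <- vapply(types, function(nm) {
    cols <- model$colmap$column[model$colmap$event_type == nm]
    contrib <- model$design$X[, cols, drop = FALSE] %*%
      model$coef[cols, , drop = FALSE]
    sum(contrib@x^2)
  }, 0)
  e / sum(e)
}
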