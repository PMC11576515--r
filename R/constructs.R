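#' Min-max normalize trial measures to [0, 1]
#'
#' Per column: `(x - min) / (max - min)`. The observed bounds are stored in
#' the `bounds` attribute for provenance and for projecting new data.
#'
#' @param measures data frame or matrix of trial measures (columns named).
#' @return numeric matrix in \[0, 1\] with attribute `bounds` (2 x p).
#' @export
normalize_measures <- function(measures) {
  if (is.data.frame(measures)) {
    keep <- intersect(measure_names(), names(measures))
    if (length(keep) == 0) keep <- names(measures)[vapply(measures, is.numeric, TRUE)]
    measures <- as.matrix(measures[keep])
  }
  X <- as.matrix(measures)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  const <- hi - lo < 1e-12
  if (any(const))
    stop2("constant measure(s): ",
          paste(colnames(X)[const] %||% which(const), collapse = ", "))
  out <- sweep(sweep(X, 2, lo), 2, hi - lo, "/")
  attr(out, "bounds") <- rbind(min = lo, max = hi)
  out
}

eigvals <- function(X, use) {
  S <- if (use == "cor") stats::cor(X) else stats::cov(X)
  eigen(S, symmetric = TRUE, only.values = TRUE)$values
}

#' Permutation test for the number of principal components
#'
#' Compares each observed eigenvalue of the (covariance, by default) matrix
#' of `X` with the same-rank eigenvalue distribution obtained from datasets
#' in which every column is independently shuffled - destroying all
#' cross-column structure while preserving the marginals. Component `k` is
#' significant iff its observed eigenvalue exceeds the `percentile` (default
#' 95th) of its null distribution. The standard criterion uses 1,000
#' shuffles and the 95th percentile.
#'
#' @param X normalized trials x measures matrix (see
#'   [normalize_measures()]); must have more rows than columns.
#' @param n_perm number of shuffled datasets (>= 100).
#' @param percentile null percentile (default 95).
#' @param use `"cov"` (default; the measures are already range-normalized)
#'   or `"cor"`.
#' @return list of class `ncomp_permutation`: `n_significant`, `observed`
#'   eigenvalues, `null` (n_perm x p matrix), `null_quantile`, parameters.
#' @export
estimate_ncomp_permutation <- function(X, n_perm = 1000, percentile = 95,
                                       use = c("cov", "cor")) {
  use <- match.arg(use)
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop2("X must have more rows than columns")
  if (n_perm < 100) stop2("n_perm must be at least 100")
  obs <- eigvals(X, use)
  p <- ncol(X)
  null <- matrix(NA_real_, n_perm, p)
  Xp <- X
  for (b in seq_len(n_perm)) {
    for (j in seq_len(p)) Xp[, j] <- X[sample.int(nrow(X)), j]
    null[b, ] <- eigvals(Xp, use)
  }
  qn <- apply(null, 2, quantile, probs = percentile / 100, names = FALSE)
  sig <- obs > qn
  structure(list(n_significant = sum(sig), significant = sig,
                 observed = obs, null = null, null_quantile = qn,
                 n_perm = n_perm, percentile = percentile, use = use),
            class = "ncomp_permutation")
}

#' @export
print.ncomp_permutation <- function(x, ...) {
  cat("<ncomp_permutation> ", x$n_significant, " significant component(s) (",
      x$percentile, "th percentile of ", x$n_perm, " column shuffles)\n",
      sep = "")
  tab <- data.frame(eigenvalue = round(x$observed, 4),
                    null_q = round(x$null_quantile, 4),
                    significant = x$significant)
  print(tab)
  invisible(x)
}

#' Fit appraisal/choice construct scores by rotated PCA
#'
#' PCA of the normalized measures (covariance by default), retaining
#' `n_comp` components; loadings (eigenvectors scaled by component sd) are
#' rotated with Kaiser-normalized ("normalized") varimax, and trial-wise
#' scores are the centred data multiplied by the rotated loadings.
#'
#' With two components and the standard measure names, components are
#' labelled: *appraisal* is the component with the larger absolute loading
#' on liking (ties broken by overall value), the other is *choice*.
#' Signs are fixed so that appraisal loads positively on liking and choice
#' loads positively on difficulty, i.e. negatively on confidence.
#'
#' @param X normalized trials x measures matrix.
#' @param n_comp components to retain (>= 1).
#' @param use `"cov"` or `"cor"`.
#' @param tol varimax convergence tolerance (iteration cap 1000).
#' @return list of class `construct_model`: `eigenvalues` (all),
#'   `loadings` (rotated, measures x components), `unrotated`, `rotmat`,
#'   `scores` (trials x components), `labels`, `center`, `bounds`.
#' @export
fit_constructs <- function(X, n_comp = 2, use = c("cov", "cor"),
                           tol = 1e-8) {
  use <- match.arg(use)
  X <- as.matrix(X)
  stopifnot(n_comp >= 1, n_comp <= ncol(X))
  pca <- prcomp(X, center = TRUE, scale. = (use == "cor"))
  load <- pca$rotation[, seq_len(n_comp), drop = FALSE] %*%
    diag(pca$sdev[seq_len(n_comp)], n_comp)
  colnames(load) <- paste0("C", seq_len(n_comp))
  if (n_comp > 1) {
    rot <- tryCatch(
      stats::varimax(load, normalize = TRUE, eps = tol),
      warning = function(w) stop2("varimax did not converge: ",
                                  conditionMessage(w)))
    rotated <- load %*% rot$rotmat
    rotmat <- rot$rotmat
  } else {
    rotated <- load; rotmat <- diag(1)
  }
  labels <- colnames(rotated) <- paste0("C", seq_len(n_comp))
  meas <- rownames(rotated)
  if (n_comp == 2 && !is.null(meas) && "liking" %in% meas) {
    app <- which.max(abs(rotated["liking", ]))
    if (abs(rotated["liking", 1]) == abs(rotated["liking", 2]) &&
        "overall_value" %in% meas)
      app <- which.max(abs(rotated["overall_value", ]))
    cho <- 3L - app
    rotated <- rotated[, c(app, cho), drop = FALSE]
    rotmat <- rotmat[, c(app, cho), drop = FALSE]
    if (rotated["liking", 1] < 0) {
      rotated[, 1] <- -rotated[, 1]; rotmat[, 1] <- -rotmat[, 1]
    }
    if ("confidence" %in% meas && rotated["confidence", 2] > 0) {
      rotated[, 2] <- -rotated[, 2]; rotmat[, 2] <- -rotmat[, 2]
    }
    labels <- colnames(rotated) <- c("appraisal", "choice")
  }
  Xc <- scale(X, center = pca$center,
              scale = if (use == "cor") pca$scale else FALSE)
  scores <- Xc %*% rotated
  colnames(scores) <- labels
  structure(list(eigenvalues = pca$sdev^2, loadings = rotated,
                 unrotated = load, rotmat = rotmat, scores = scores,
                 labels = labels, center = pca$center,
                 use = use, n_comp = n_comp,
                 bounds = attr(X, "bounds")),
            class = "construct_model")
}

#' @export
print.construct_model <- function(x, ...) {
  cat("<construct_model> ", x$n_comp, " rotated components (",
      paste(x$labels, collapse = ", "), "), ", nrow(x$scores),
      " trials\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence after matching columns greedily by absolute
#' congruence, ignoring sign and column order. Returns the per-column
#' coefficients of the best matching.
#'
#' @param A,B loading matrices with the same number of rows.
#' @export
congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  phi <- abs(crossprod(A, B) /
               outer(sqrt(Matrix::colSums(A^2)), sqrt(Matrix::colSums(B^2))))
  out <- numeric(min(ncol(A), ncol(B)))
  for (k in seq_along(out)) {
    ij <- which(phi == max(phi), arr.ind = TRUE)[1, ]
    out[k] <- phi[ij[1], ij[2]]
    phi[ij[1], ] <- -Inf; phi[, ij[2]] <- -Inf
  }
  out
}
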