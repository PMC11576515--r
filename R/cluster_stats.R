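#' Group-level one-sample t-map
#'
#' One-sample t statistic across participants at each channel x time point,
#' with `df = n - 1`. Points with zero variance across participants are set
#' to `NA` (excluded from clustering) and counted.
#'
#' @param maps participants x channels x time array, or a list of
#'   channels x time matrices.
#' @return list: `t` (channels x time), `df`, `n`, `n_zero_variance`.
#' @export
group_tmap <- function(maps) {
  if (is.list(maps)) maps <- simplify2array(maps, higher = TRUE) |>
      aperm(c(3, 1, 2))
  stopifnot(length(dim(maps)) == 3)
  n <- dim(maps)[1]
  if (n < 3) stop2("need at least 3 participants")
  m <- apply(maps, c(2, 3), mean)
  s <- apply(maps, c(2, 3), sd)
  zero <- s < 1e-14
  t <- m / (s / sqrt(n))
  t[zero] <- NA_real_
  if (any(zero)) message(sum(zero), " zero-variance point(s) excluded")
  list(t = t, df = n - 1, n = n, n_zero_variance = sum(zero))
}

## Connected components of suprathreshold points. Connectivity: adjacent
## channels at the same time point, or the same channel at adjacent time
## points; optional diagonal (adjacent channel AND adjacent time) links.
## Opposite polarities never merge. Returns a list of integer index
## vectors into the channels x time grid.
connected_components <- function(supra, neighbors, diagonal = FALSE) {
  nch <- nrow(supra); nt <- ncol(supra)
  idx <- which(supra)
  if (length(idx) == 0) return(list())
  comp <- integer(0)
  labels <- integer(nch * nt)
  out <- list()
  for (seed in idx) {
    if (labels[seed] != 0L) next
    id <- length(out) + 1L
    queue <- seed
    labels[seed] <- id
    members <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, p)
      ch <- ((p - 1L) %% nch) + 1L
      ti <- ((p - 1L) %/% nch) + 1L
      cand <- c(
        if (ti > 1L) p - nch, if (ti < nt) p + nch,
        (neighbors[[ch]] - ch) + p,
        if (diagonal && ti > 1L) (neighbors[[ch]] - ch) + p - nch,
        if (diagonal && ti < nt) (neighbors[[ch]] - ch) + p + nch)
      cand <- cand[cand >= 1 & cand <= nch * nt]
      cand <- cand[supra[cand] & labels[cand] == 0L]
      labels[cand] <- id
      queue <- c(queue, cand)
    }
    out[[id]] <- members
  }
  out
}

#' Find suprathreshold spatiotemporal clusters
#'
#' Thresholds a t-map at the two-tailed critical value for
#' `threshold_p` (default 0.005) with `df` degrees of freedom, then groups
#' suprathreshold points of equal polarity that are connected through
#' neighbouring channels (same time) or adjacent time samples (same
#' channel). Cluster mass is the sum of absolute t-values over members.
#'
#' @param tmap channels x time matrix of t-values (`NA` = excluded).
#' @param adjacency an [build_adjacency()] graph matching the channels.
#' @param threshold_p cluster-forming p (two-tailed).
#' @param df degrees of freedom (>= 1).
#' @param diagonal allow diagonal spatiotemporal links (default FALSE).
#' @return list of clusters, each with `members` (matrix with columns
#'   channel, time), `polarity` (+1/-1), `mass`, `peak` (channel, time
#'   index of max |t|).
#' @export
find_clusters <- function(tmap, adjacency, threshold_p = 0.005, df,
                          diagonal = FALSE) {
  stopifnot(inherits(adjacency, "adjacency_graph"), df >= 1,
            nrow(tmap) == adjacency$n_channels)
  tcrit <- qt(1 - threshold_p / 2, df)
  ok <- !is.na(tmap)
  out <- list()
  for (pol in c(1, -1)) {
    supra <- ok & (pol * tmap > tcrit)
    for (members in connected_components(supra, adjacency$neighbors)) {
      tv <- tmap[members]
      pk <- members[which.max(abs(tv))]
      out[[length(out) + 1L]] <- list(
        members = cbind(channel = ((members - 1L) %% nrow(tmap)) + 1L,
                        time = ((members - 1L) %/% nrow(tmap)) + 1L),
        polarity = pol, mass = sum(abs(tv)),
        peak = c(channel = ((pk - 1L) %% nrow(tmap)) + 1L,
                 time = ((pk - 1L) %/% nrow(tmap)) + 1L))
    }
  }
  out[order(-vapply(out, `[[`, 0, "mass"))]
}

max_mass_by_polarity <- function(tmap, neighbors, tcrit) {
  ok <- !is.na(tmap)
  res <- c(pos = 0, neg = 0)
  for (pol in c(1, -1)) {
    supra <- ok & (pol * tmap > tcrit)
    if (!any(supra)) next
    comps <- connected_components(supra, neighbors)
    m <- max(vapply(comps, function(ix) sum(abs(tmap[ix])), 0))
    res[if (pol > 0) "pos" else "neg"] <- m
  }
  res
}

#' Cluster-mass permutation test on per-participant maps
#'
#' Group-level two-sided cluster-mass test: the observed group t-map is
#' clustered at the `threshold_p` forming threshold; each permutation
#' randomly sign-flips whole participants' maps, and the maximum cluster
#' mass per polarity is recorded. An observed cluster is significant iff
#' its mass exceeds the top 2.5% of the corresponding max-mass null
#' distribution (a two-sided test at 0.05). Its p-value is the inverted
#' percentile rank of its mass in that null, divided by 100 and multiplied
#' by 2, floored at `2/n_perm`.
#'
#' @param maps participants x channels x time array (or list of matrices)
#'   of first-level statistics (t-maps or betas).
#' @param adjacency an [build_adjacency()] graph.
#' @param threshold_p cluster-forming p (default 0.005).
#' @param n_perm number of sign-flip permutations (default 1000, >= 100).
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `cluster_result`: `clusters` (data frame: id,
#'   polarity, mass, p, significant, peak_channel, peak_time, extent),
#'   `cluster_members`, `tmap`, `df`, `null_max_mass` (n_perm x 2),
#'   `params`.
#' @export
permutation_pvalues <- function(maps, adjacency, threshold_p = 0.005,
                                n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop2("n_perm must be at least 100")
  if (2 / n_perm >= 0.05)
    warning("n_perm too small for the p floor to undercut 0.05",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.list(maps)) maps <- simplify2array(maps, higher = TRUE) |>
      aperm(c(3, 1, 2))
  n <- dim(maps)[1]; nch <- dim(maps)[2]; nt <- dim(maps)[3]
  g <- group_tmap(maps)
  tcrit <- qt(1 - threshold_p / 2, g$df)
  obs <- find_clusters(g$t, adjacency, threshold_p, g$df)

  ## flat matrix for fast sign-flip t-maps: sum(x^2) is flip-invariant
  Xf <- matrix(aperm(maps, c(1, 2, 3)), n, nch * nt)
  ss <- colSums(Xf^2)
  null <- matrix(0, n_perm, 2, dimnames = list(NULL, c("pos", "neg")))
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.vector(s %*% Xf) / n
    v <- (ss - n * m^2) / (n - 1)
    tv <- m / sqrt(v / n)
    tv[v < 1e-28] <- NA_real_
    null[b, ] <- max_mass_by_polarity(matrix(tv, nch, nt),
                                      adjacency$neighbors, tcrit)
  }
  q975 <- apply(null, 2, quantile, probs = 0.975, names = FALSE)
  rows <- lapply(seq_along(obs), function(i) {
    cl <- obs[[i]]
    nn <- null[, if (cl$polarity > 0) "pos" else "neg"]
    p <- max(2 / n_perm, 2 * mean(nn >= cl$mass))
    data.frame(id = i, polarity = cl$polarity, mass = cl$mass,
               p = min(p, 1),
               significant = cl$mass > q975[if (cl$polarity > 0) 1 else 2],
               peak_channel = cl$peak["channel"], peak_time = cl$peak["time"],
               extent = nrow(cl$members))
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), polarity = numeric(), mass = numeric(),
               p = numeric(), significant = logical(),
               peak_channel = integer(), peak_time = integer(),
               extent = integer())
  rownames(clusters) <- NULL
  structure(list(clusters = clusters,
                 cluster_members = lapply(obs, `[[`, "members"),
                 tmap = g$t, df = g$df, null_max_mass = null,
                 null_q975 = q975,
                 params = list(threshold_p = threshold_p, n_perm = n_perm,
                               seed = seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), ",
      sum(x$clusters$significant), " significant (threshold p = ",
      x$params$threshold_p, ", ", x$params$n_perm, " permutations)\n",
      sep = "")
  if (nrow(x$clusters)) print(head(x$clusters, 10))
  invisible(x)
}

#' Write a cluster table as TSV
#' @param result a `cluster_result`.
#' @param path file path.
#' @param channel_labels,times optional axes to translate peak indices.
#' @export
write_cluster_table <- function(result, path, channel_labels = NULL,
                                times = NULL) {
  tab <- result$clusters
  if (!is.null(channel_labels))
    tab$peak_channel <- channel_labels[tab$peak_channel]
  if (!is.null(times)) tab$peak_time <- times[tab$peak_time]
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
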