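# Paired cluster-based permutation inference over channels (optionally x time).
#
# First-level statistic: pointwise paired t. Supra-threshold nodes are grouped
# into connected components of the channel adjacency graph (plus temporal
# adjacency for channel x time maps), separately for positive and negative
# excursions; components spanning fewer than `min_channels` distinct channels
# are discarded; the cluster statistic is the summed t. The null distribution
# of the maximum |cluster statistic| is built by random sign flips of the
# per-participant difference maps.

#' Pointwise paired t-map
#'
#' @param a,b Participant x node matrices (or participants x channels x time
#'   arrays) of the two conditions, same shape, >= 2 participants.
#' @return t statistic per node, with the participant dimension dropped.
#'   Zero-variance nodes yield t = 0 with a warning.
#' @export
pointwise_paired_t <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  d <- a - b
  dm <- if (is.matrix(d)) d else matrix(d, dim(d)[1])
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 participants")
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / n)
  zv <- !is.finite(tt)
  if (any(zv)) {
    warning(sum(zv), " zero-variance node(s); t set to 0")
    tt[zv] <- 0
  }
  if (is.matrix(d)) tt else array(tt, dim(d)[-1])
}

# Union-find over supra-threshold nodes of a t-map.
# tmap: numeric vector (channels) or matrix (channels x time).
# Returns list of clusters: list(nodes, channels, stat, sign).
cluster_search <- function(tmap, threshold, adjacency, min_channels) {
  is_mat <- is.matrix(tmap)
  nch <- if (is_mat) nrow(tmap) else length(tmap)
  nt <- if (is_mat) ncol(tmap) else 1L
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmap > threshold else tmap < -threshold
    supra <- which(mask)
    if (!length(supra)) next
    pos <- integer(nch * nt); pos[supra] <- seq_along(supra)
    parent <- seq_along(supra)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (s in seq_along(supra)) {
      node <- supra[s]
      ch <- (node - 1L) %% nch + 1L
      tt <- (node - 1L) %/% nch + 1L
      nb_ch <- adjacency[[ch]]
      nbs <- nb_ch + (tt - 1L) * nch
      if (is_mat) {
        if (tt > 1L) nbs <- c(nbs, node - nch)
        if (tt < nt) nbs <- c(nbs, node + nch)
      }
      for (nb in nbs) {
        q <- pos[nb]
        if (q > 0L) {
          ra <- find(s); rb <- find(q)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_along(supra), find, integer(1))
    comps <- split(seq_along(supra), roots)
    for (cc in comps) {
      nodes <- supra[cc]
      chans <- unique((nodes - 1L) %% nch + 1L)
      if (length(chans) < min_channels) next
      out[[length(out) + 1L]] <- list(nodes = nodes, channels = sort(chans),
                                      stat = sum(tmap[nodes]), sign = sgn)
    }
  }
  out
}

#' Find supra-threshold clusters in a t-map
#'
#' @param t_map Numeric vector (one value per channel) or channels x time
#'   matrix.
#' @param threshold Cluster-forming threshold (applied as `t > threshold` and
#'   `t < -threshold` separately).
#' @param adjacency Channel adjacency: list of neighbour index vectors (e.g.
#'   from a `sensor_array`).
#' @param min_channels Minimum number of distinct channels a cluster must
#'   span (study value 3).
#' @return List of clusters, each with `nodes` (linear indices into `t_map`),
#'   `channels`, `stat` (summed t) and `sign`.
#' @export
find_clusters <- function(t_map, threshold, adjacency, min_channels = 3) {
  nch <- if (is.matrix(t_map)) nrow(t_map) else length(t_map)
  if (length(adjacency) != nch)
    stop("adjacency must cover all ", nch, " channels")
  cluster_search(t_map, threshold, adjacency, min_channels)
}

#' Paired cluster-based permutation test
#'
#' Two-tailed paired test on participant-level condition maps. The
#' cluster-forming threshold is the two-sided paired-t critical value at
#' `alpha_cf` (df = n - 1). The permutation null records, for each of
#' `n_perm` random sign-flips of the participant difference maps, the
#' maximum |summed cluster t| over clusters found in the permuted map (same
#' threshold and channel minimum). Each observed cluster's p-value is
#' `(1 + #{perm max >= |observed|}) / (1 + n_perm)`.
#'
#' @param a,b Participant x channel matrices or participant x channel x time
#'   arrays (>= 4 participants).
#' @param adjacency Channel adjacency list.
#' @param n_perm Number of permutations (study value 1000).
#' @param min_channels Minimum distinct channels per cluster (study value 3).
#' @param alpha_cf Cluster-forming alpha.
#' @param seed RNG seed for the sign flips.
#' @return A `cluster_result`: `clusters` (each with members, channels,
#'   summed stat, p), `t_map`, `threshold`, `n_perm`, `null_max`.
#' @export
permutation_cluster_test <- function(a, b, adjacency, n_perm = 1000,
                                     min_channels = 3, alpha_cf = 0.05,
                                     seed = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  n <- dim(a)[1]
  if (n < 4) stop("need at least 4 participants for a meaningful permutation null")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value resolution")
  local_rng(seed)

  node_dim <- dim(a)[-1]
  dmat <- matrix(a - b, nrow = n)          # participants x nodes
  ss <- colSums(dmat^2)
  threshold <- stats::qt(1 - alpha_cf / 2, df = n - 1)

  shape_map <- function(tvec) {
    if (length(node_dim) == 2) matrix(tvec, node_dim[1], node_dim[2]) else tvec
  }
  t_from_signs <- function(s) {
    m <- as.numeric(crossprod(dmat, s)) / n
    v <- (ss - n * m^2) / (n - 1)
    v[v < 1e-300] <- 1e-300
    m / sqrt(v / n)
  }

  t_obs <- t_from_signs(rep(1, n))
  tmap <- shape_map(t_obs)
  clusters <- cluster_search(tmap, threshold, adjacency, min_channels)

  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tp <- shape_map(t_from_signs(s))
    cl <- cluster_search(tp, threshold, adjacency, min_channels)
    null_max[p] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "stat"))) else 0
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (1 + sum(null_max >= abs(clusters[[i]]$stat))) /
      (1 + n_perm)
  }
  if (length(clusters)) {
    clusters <- clusters[order(vapply(clusters, `[[`, 0, "p"))]
  }
  structure(list(clusters = clusters, t_map = tmap, threshold = threshold,
                 n_perm = n_perm, min_channels = min_channels,
                 null_max = null_max, n_participants = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d clusters (threshold |t| > %.2f, %d permutations)\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %d channels, sum t = %.1f, p = %.4f\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$channels), cl$stat, cl$p))
  }
  invisible(x)
}

#' Smallest cluster p-value (1 if no clusters)
#' @param result A `cluster_result`.
#' @export
min_cluster_p <- function(result) {
  if (!length(result$clusters)) return(1)
  min(vapply(result$clusters, `[[`, 0, "p"))
}
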