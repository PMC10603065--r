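#' OPTICS hyperparameters
#'
#' @param min_pts minimum neighborhood size (the point itself counts),
#'   default 2.
#' @param eps_opt optimal epsilon, typically from [elbow_epsilon()].
#' @param max_eps reachability cutoff; default 10 x `eps_opt`. Points not
#'   reachable within `max_eps` are ordered as fresh seeds and can only
#'   become noise or start new clusters.
#' @param xi minimum steepness (fraction) on the reachability plot that
#'   constitutes a cluster boundary, default 0.01.
#' @return list of class `optics_params`.
#' @export
optics_params <- function(min_pts = 2L, eps_opt, max_eps = 10 * eps_opt,
                          xi = 0.01) {
  stopifnot(min_pts >= 2L, eps_opt > 0, max_eps >= eps_opt, xi > 0, xi < 1)
  structure(list(min_pts = as.integer(min_pts), eps_opt = eps_opt,
                 max_eps = max_eps, xi = xi), class = "optics_params")
}

# Core OPTICS ordering on a precomputed symmetric distance matrix.
# Deterministic: seeds and ties resolved by smallest row index.
# Returns ordering (1-based), core distances, reachability and
# predecessor per point.
optics_graph <- function(d, min_pts, max_eps) {
  n <- nrow(d)
  stopifnot(n >= 1L, ncol(d) == n)
  core <- apply(d, 1L, function(r) sort.int(r, partial = min_pts)[min_pts])
  core[core > max_eps] <- Inf
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ordering <- integer(n)
  for (step in seq_len(n)) {
    idx <- which(!processed)
    point <- idx[which.min(reach[idx])]
    processed[point] <- TRUE
    ordering[step] <- point
    if (is.finite(core[point])) {
      dp <- d[point, ]
      unproc <- !processed & dp <= max_eps
      if (any(unproc)) {
        rdist <- pmax(dp[unproc], core[point])
        better <- rdist < reach[unproc]
        targets <- which(unproc)[better]
        reach[targets] <- rdist[better]
        pred[targets] <- point
      }
    }
  }
  list(ordering = ordering, core = core, reach = reach, pred = pred)
}

# DBSCAN-style flat extraction from an OPTICS ordering at threshold eps.
extract_eps_cut <- function(g, eps) {
  n <- length(g$ordering)
  labels <- rep(-1L, n)
  cl <- 0L
  for (p in g$ordering) {
    if (g$reach[p] > eps) {
      if (g$core[p] <= eps) {
        cl <- cl + 1L
        labels[p] <- cl
      }
    } else {
      labels[p] <- cl
    }
  }
  labels
}

# Extend a steep region to its maximal end (canonical xi procedure;
# regions tolerate at most min_pts consecutive non-steep points).
extend_region <- function(steep_point, xward_point, start, min_pts) {
  n <- length(steep_point)
  non_xward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep_point[index]) {
      non_xward <- 0L
      end <- index
    } else if (!xward_point[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_pts) break
    } else {
      return(end)
    }
    index <- index + 1L
  }
  end
}

update_filter_sdas <- function(sdas, mib, xi_complement, rplot) {
  if (is.infinite(mib)) return(list())
  keep <- Filter(function(sda) mib <= rplot[sda$start] * xi_complement, sdas)
  lapply(keep, function(sda) {
    sda$mib <- max(sda$mib, mib)
    sda
  })
}

correct_predecessor <- function(rplot, pplot, ordering, s, e) {
  while (s < e) {
    if (rplot[s] > rplot[e]) return(c(s, e))
    p_e <- pplot[e]
    if (!is.na(p_e) && p_e %in% ordering[s:(e - 1L)]) return(c(s, e))
    e <- e - 1L
  }
  c(NA_integer_, NA_integer_)
}

# Xi cluster extraction over the reachability plot (indices are positions
# in the OPTICS ordering; both ends inclusive). Canonical steep-area
# algorithm with predecessor correction.
xi_clusters <- function(rplot, pplot, ordering, xi, min_pts,
                        min_cluster_size = min_pts) {
  rplot <- c(rplot, Inf)
  xi_complement <- 1 - xi
  n <- length(rplot)
  ratio <- rplot[-n] / rplot[-1L]
  steep_up <- !is.na(ratio) & ratio <= xi_complement
  steep_down <- !is.na(ratio) & ratio >= 1 / xi_complement
  upward <- !is.na(ratio) & ratio < 1
  downward <- !is.na(ratio) & ratio > 1

  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  for (steep_index in which(steep_up | steep_down)) {
    if (steep_index < index) next
    mib <- max(mib, max(rplot[index:steep_index]))
    if (steep_down[steep_index]) {
      sdas <- update_filter_sdas(sdas, mib, xi_complement, rplot)
      D_start <- steep_index
      D_end <- extend_region(steep_down, upward, D_start, min_pts)
      sdas <- c(sdas, list(list(start = D_start, end = D_end, mib = 0)))
      index <- D_end + 1L
      mib <- rplot[index]
    } else {
      sdas <- update_filter_sdas(sdas, mib, xi_complement, rplot)
      U_start <- steep_index
      U_end <- extend_region(steep_up, downward, U_start, min_pts)
      index <- U_end + 1L
      mib <- rplot[index]
      U_clusters <- list()
      for (D in sdas) {
        c_start <- D$start
        c_end <- U_end
        if (rplot[c_end + 1L] * xi_complement < D$mib) next
        D_max <- rplot[D$start]
        if (D_max * xi_complement >= rplot[c_end + 1L]) {
          while (c_start < D$end &&
                 rplot[c_start + 1L] > rplot[c_end + 1L]) {
            c_start <- c_start + 1L
          }
        } else if (rplot[c_end + 1L] * xi_complement >= D_max) {
          while (c_end > U_start && rplot[c_end - 1L] > D_max) {
            c_end <- c_end - 1L
          }
        }
        se <- correct_predecessor(rplot, pplot, ordering, c_start, c_end)
        if (is.na(se[1])) next
        c_start <- se[1]; c_end <- se[2]
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > D$end) next
        if (c_end < U_start) next
        U_clusters <- c(U_clusters, list(c(c_start, c_end)))
      }
      clusters <- c(clusters, rev(U_clusters))
    }
  }
  if (!length(clusters)) {
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  out <- do.call(rbind, clusters)
  colnames(out) <- c("start", "end")
  out
}

# Flat labels from hierarchical xi clusters: smaller (leaf) clusters come
# first and claim their points; encompassing clusters only label what is
# still unlabeled.
extract_xi_labels <- function(ordering, clusters) {
  labels_plot <- rep(-1L, length(ordering))
  label <- 0L
  if (nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      span <- clusters[i, 1]:clusters[i, 2]
      if (all(labels_plot[span] == -1L)) {
        label <- label + 1L
        labels_plot[span] <- label
      }
    }
  }
  labels <- integer(length(ordering))
  labels[ordering] <- labels_plot
  labels
}

#' Optimal epsilon by the elbow of the k-nearest-neighbor distance curve
#'
#' Computes every point's distance to its k-th nearest neighbor (self
#' excluded), sorts the distances ascending and returns the value at the
#' knee, located as the point of maximum perpendicular distance to the
#' chord joining the curve endpoints. Ties break to the smallest index.
#' The result is floored at the smallest positive pairwise distance; a
#' fully degenerate (all-zero) matrix returns `min_eps`.
#'
#' @param d symmetric distance matrix (zero diagonal).
#' @param k neighbor rank, default 2 (the customary `min_pts`).
#' @param min_eps value returned for degenerate input, default 1.
#' @return positive scalar epsilon.
#' @export
elbow_epsilon <- function(d, k = 2L, min_eps = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  pos <- d[upper.tri(d)]
  pos <- pos[pos > 0]
  floor_eps <- if (length(pos)) min(pos) else min_eps
  if (n < 2L) return(min_eps)
  if (n == 2L) return(max(d[1, 2], floor_eps, min_eps))
  # k-distance with OPTICS core-distance semantics: the k-th smallest
  # entry of each row, the point itself included (at min_pts = 2 this is
  # the nearest-neighbor distance, i.e. each point's core distance)
  kd <- apply(d, 1L, function(r) {
    rs <- sort.int(r)
    rs[min(k, length(rs))]
  })
  y <- sort(kd)
  x <- seq_along(y)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  # perpendicular distance of each point to the chord (up to a constant)
  perp <- abs((y2 - y1) * (x - x1) - (x2 - x1) * (y - y1))
  knee <- which.max(perp)
  max(y[knee], floor_eps)
}
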