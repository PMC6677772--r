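# Reconstruction quality alerts and inter-reconstruction comparison:
# sharp-turn outlier detection, Sholl analysis, total-length consistency,
# pairwise spatial apartness, and the give-up-rate statistic.

#' Detect sharp-turn outliers in a reconstruction
#'
#' At every node with at least one predecessor and one successor, the
#' turning angle is measured between the incoming direction (from the node
#' `window` edges upstream) and the outgoing direction (to the node
#' `window` edges downstream), shortened where a root, branch point or tip
#' intervenes. The convention is 0 deg = straight continuation, 180 deg =
#' full reversal; an alert is emitted when the angle strictly exceeds the
#' threshold. At branch points each parent-to-child continuation is
#' evaluated independently. Zero-length direction vectors are skipped.
#' Angles are intrinsic, so alerts are invariant under rigid motions of
#' the coordinate frame.
#'
#' @param tree A single-root `neuron_tree`.
#' @param threshold Angle threshold in degrees, in (0, 180); typical
#'   values are 90 or 135.
#' @param window Number of edges spanned by each direction vector.
#' @return Data frame with columns `node_id`, `child_id`,
#'   `turning_angle`, `threshold_used`, `segment_id`.
#' @export
detect_sharp_turns <- function(tree, threshold = 90, window = 1L) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 180) {
    stop_structural("threshold must lie in (0, 180) degrees")
  }
  if (window < 1) stop_structural("window must be >= 1")
  validate_neuron_tree(tree)
  nd <- tree$nodes
  children <- tree_children(tree)
  parent_of <- stats::setNames(nd$parent, nd$id)
  pos <- function(id) {
    i <- match(id, nd$id)
    c(nd$x[i], nd$y[i], nd$z[i])
  }
  segs <- decompose_segments(tree)
  seg_of_child <- integer(0)
  for (s in segs) {
    ch <- s$node_ids[-1]
    seg_of_child[as.character(ch)] <- s$id
  }
  walk_up <- function(id, k) {
    cur <- id
    while (k > 0 && parent_of[[as.character(cur)]] != -1L) {
      cur <- parent_of[[as.character(cur)]]
      k <- k - 1
    }
    cur
  }
  walk_down <- function(id, k) {
    cur <- id
    while (k > 0) {
      nxt <- children[[as.character(cur)]]
      if (length(nxt) != 1) break
      cur <- nxt[1]
      k <- k - 1
    }
    cur
  }
  out <- list()
  for (i in seq_len(nrow(nd))) {
    u <- nd$id[i]
    if (parent_of[[as.character(u)]] == -1L) next
    for (v in children[[as.character(u)]]) {
      up <- walk_up(u, window)
      dn <- walk_down(v, window - 1L)
      vin <- pos(u) - pos(up)
      vout <- pos(dn) - pos(u)
      nin <- sqrt(sum(vin^2)); nout <- sqrt(sum(vout^2))
      if (nin < 1e-12 || nout < 1e-12) next
      cosang <- max(-1, min(1, sum(vin * vout) / (nin * nout)))
      ang <- acos(cosang) * 180 / pi
      if (ang > threshold) {
        out[[length(out) + 1L]] <- data.frame(
          node_id = u, child_id = v, turning_angle = ang,
          threshold_used = threshold,
          segment_id = unname(seg_of_child[[as.character(v)]]))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(node_id = integer(), child_id = integer(),
                      turning_angle = numeric(), threshold_used = numeric(),
                      segment_id = integer()))
  }
  do.call(rbind, out)
}

#' Sholl analysis
#'
#' Counts neurite crossings of concentric spheres centered at the soma
#' (the root node): the crossing count at radius r is the number of
#' parent-child edges with one endpoint at distance < r and the other at
#' distance >= r from the center. The half-open straddle counts a node
#' sitting exactly on a sphere once.
#'
#' @param tree A single-root `neuron_tree`.
#' @param radius_step Positive spacing between consecutive sphere radii.
#' @param max_radius Largest radius; defaults to the first multiple of
#'   `radius_step` at or beyond the most distal node.
#' @return An object of class `sholl_curve` with `center`, `radii`,
#'   `crossings`.
#' @export
sholl_analysis <- function(tree, radius_step, max_radius = NULL) {
  if (!is.finite(radius_step) || radius_step <= 0) {
    stop_structural("radius_step must be positive")
  }
  validate_neuron_tree(tree)
  roots <- tree_roots(tree)
  if (length(roots) != 1) stop_structural("Sholl analysis requires a single root")
  nd <- tree$nodes
  ri <- match(roots, nd$id)
  center <- c(nd$x[ri], nd$y[ri], nd$z[ri])
  d <- sqrt((nd$x - center[1])^2 + (nd$y - center[2])^2 + (nd$z - center[3])^2)
  has_par <- nd$parent != -1L
  dp <- d[match(nd$parent[has_par], nd$id)]
  dc <- d[has_par]
  lo <- pmin(dp, dc); hi <- pmax(dp, dc)
  if (is.null(max_radius)) {
    max_radius <- radius_step * max(1, ceiling(max(d) / radius_step))
  }
  radii <- seq(radius_step, max_radius, by = radius_step)
  crossings <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  structure(list(center = center, radii = radii, crossings = crossings),
            class = "sholl_curve")
}

#' @export
print.sholl_curve <- function(x, ...) {
  cat(sprintf("<sholl_curve> %d radii up to %.4g, peak %d crossing(s)\n",
              length(x$radii), max(x$radii), max(x$crossings)))
  invisible(x)
}

# resample every edge of a tree at arc-length spacing `step`, inclusive of
# both endpoints; returns an m x 3 matrix of (x, y, z) sample points
resample_tree_points <- function(tree, step) {
  nd <- tree$nodes
  has_par <- which(nd$parent != -1L)
  if (length(has_par) == 0) return(node_xyz(tree))
  pi <- match(nd$parent[has_par], nd$id)
  pts <- list()
  for (k in seq_along(has_par)) {
    i <- has_par[k]
    a <- c(nd$x[pi[k]], nd$y[pi[k]], nd$z[pi[k]])
    b <- c(nd$x[i], nd$y[i], nd$z[i])
    L <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(L / step))
    t <- (0:nseg) / nseg
    pts[[k]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, pts)
}

# edge list of a tree as start/end coordinate matrices
tree_edges_xyz <- function(tree) {
  nd <- tree$nodes
  has_par <- which(nd$parent != -1L)
  pi <- match(nd$parent[has_par], nd$id)
  list(a = cbind(nd$x[pi], nd$y[pi], nd$z[pi]),
       b = cbind(nd$x[has_par], nd$y[has_par], nd$z[has_par]))
}

# minimum distance from each row of P to any segment (a_i, b_i); `lateral`
# drops the third (z) coordinate. Exact point-to-piece distances.
min_dist_to_edges <- function(P, edges, lateral = FALSE) {
  ncol_use <- if (lateral) 2L else 3L
  A <- edges$a[, 1:ncol_use, drop = FALSE]
  B <- edges$b[, 1:ncol_use, drop = FALSE]
  P <- P[, 1:ncol_use, drop = FALSE]
  m <- nrow(P)
  if (nrow(A) == 0) stop_structural("tree has no edges to compare against")
  best <- rep(Inf, m)
  for (i in seq_len(nrow(A))) {
    v <- B[i, ] - A[i, ]
    L2 <- sum(v^2)
    W <- sweep(P, 2, A[i, ])
    t <- if (L2 > 0) pmin(pmax(as.vector(W %*% v) / L2, 0), 1) else rep(0, m)
    D2 <- rowSums((W - outer(t, v))^2)
    best <- pmin(best, D2)
  }
  sqrt(best)
}

#' Spatial apartness of two reconstructions
#'
#' Resamples each tree's polylines at `sampling_step` and measures, for
#' every sample of one tree, the exact distance to the nearest point on
#' the other tree's polylines. Reported are the two directed means, their
#' symmetrised average, and the lateral (XY-plane, ignoring z) variants —
#' "lateral" being the imaging plane of a z-stack, where tracing
#' displacement is usually assessed. Both the full-3D and lateral values
#' are always reported.
#'
#' @param a,b Nonempty `neuron_tree`s in the same coordinate unit.
#' @param sampling_step Arc-length resampling step (default 1 voxel).
#' @return An object of class `distance_report` with `mean_ab`, `mean_ba`,
#'   `mean_bidirectional`, `lateral_mean_ab`, `lateral_mean_ba`,
#'   `lateral_mean_bidirectional`.
#' @export
reconstruction_distance <- function(a, b, sampling_step = 1) {
  if (nrow(a$nodes) == 0 || nrow(b$nodes) == 0) {
    stop_structural("cannot compare an empty reconstruction")
  }
  if (!is.finite(sampling_step) || sampling_step <= 0) {
    stop_structural("sampling_step must be positive")
  }
  Pa <- resample_tree_points(a, sampling_step)
  Pb <- resample_tree_points(b, sampling_step)
  Ea <- tree_edges_xyz(a)
  Eb <- tree_edges_xyz(b)
  mean_ab <- mean(min_dist_to_edges(Pa, Eb))
  mean_ba <- mean(min_dist_to_edges(Pb, Ea))
  lat_ab <- mean(min_dist_to_edges(Pa, Eb, lateral = TRUE))
  lat_ba <- mean(min_dist_to_edges(Pb, Ea, lateral = TRUE))
  structure(list(mean_ab = mean_ab, mean_ba = mean_ba,
                 mean_bidirectional = (mean_ab + mean_ba) / 2,
                 lateral_mean_ab = lat_ab, lateral_mean_ba = lat_ba,
                 lateral_mean_bidirectional = (lat_ab + lat_ba) / 2,
                 sampling_step = sampling_step),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(paste0("<distance_report> bidirectional mean %.4g ",
                     "(a->b %.4g, b->a %.4g); lateral %.4g\n"),
              x$mean_bidirectional, x$mean_ab, x$mean_ba,
              x$lateral_mean_bidirectional))
  invisible(x)
}

#' Total-length consistency across repeated reconstructions
#'
#' Summarises how much the total cable length varies across reconstructions
#' of the same neuron, as the spread (max - min) expressed as a percentage
#' of the mean length.
#'
#' @param trees List of at least two `neuron_tree`s.
#' @return List with `lengths`, `mean_length`, `max_abs_diff`,
#'   `percent_of_mean`.
#' @export
length_consistency <- function(trees) {
  if (length(trees) < 2) stop_structural("need at least 2 reconstructions")
  lengths <- vapply(trees, total_length, numeric(1))
  mean_len <- mean(lengths)
  spread <- max(lengths) - min(lengths)
  list(lengths = lengths, mean_length = mean_len, max_abs_diff = spread,
       percent_of_mean = 100 * spread / mean_len)
}

#' Give-up rate of annotation attempts
#'
#' Fraction of failed attempts among all attempts on a tract:
#' (#failed attempts) / (#all attempts).
#'
#' @param attempts Data frame with a logical `succeeded` column (an
#'   `annotator` column is allowed and ignored), or a logical vector of
#'   per-attempt success flags.
#' @return Scalar in \[0, 1\].
#' @export
give_up_rate <- function(attempts) {
  succ <- if (is.data.frame(attempts)) attempts$succeeded else attempts
  if (length(succ) == 0) stop_structural("no attempts recorded")
  if (!is.logical(succ) || any(is.na(succ))) {
    stop_structural("succeeded flags must be TRUE/FALSE")
  }
  mean(!succ)
}
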