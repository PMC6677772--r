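# Fixtures built in code plus independent brute-force oracles used to
# cross-check the vectorised implementations.

swc_lines <- function(...) paste(c(...), collapse = "\n")

# fresh scratch directory under the session tempdir
withr_local_tempdir <- function() {
  d <- tempfile("neurotrace")
  dir.create(d)
  d
}

chain_tree <- function(xs, ys = 0, zs = 0, radius = 1) {
  n <- length(xs)
  neuron_tree(data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1)),
                         x = xs, y = rep_len(ys, n), z = rep_len(zs, n),
                         radius = radius,
                         parent = c(-1L, seq_len(n - 1))))
}

# root 1 -> 2 -> 3 (branch) -> {4, 5}
y_tree <- function() {
  neuron_tree(data.frame(id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
                         x = c(0, 1, 2, 3, 3), y = c(0, 0, 0, 1, -1),
                         z = 0, radius = 1,
                         parent = c(-1L, 1L, 2L, 3L, 3L)))
}

# soma stem leading into a full binary tree with 2^depth tips
full_binary_tree <- function(depth) {
  nodes <- data.frame(id = 1:2, type = c(1L, 3L), x = 0, y = c(-1, 0), z = 0,
                      radius = 1, parent = c(-1L, 1L))
  frontier <- data.frame(id = 2L, x = 0, y = 0)
  next_id <- 3L
  for (d in seq_len(depth)) {
    nf <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (s in c(-1, 1)) {
        nodes <- rbind(nodes, data.frame(
          id = next_id, type = 3L, x = frontier$x[i] + s * 2^(depth - d),
          y = frontier$y[i] + 1, z = d * 0.5, radius = 1,
          parent = frontier$id[i]))
        nf <- rbind(nf, data.frame(id = next_id, x = frontier$x[i] + s * 2^(depth - d),
                                   y = frontier$y[i] + 1))
        next_id <- next_id + 1L
      }
    }
    frontier <- nf
  }
  neuron_tree(nodes)
}

# random valid tree, independent of the synthgen module: nodes attach to a
# uniformly chosen earlier node
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = runif(1, 0.5, 2), parent = -1L)
  for (i in 2:n_nodes) {
    p <- sample(i - 1L, 1)
    nodes <- rbind(nodes, data.frame(
      id = i, type = 3L, x = nodes$x[p] + rnorm(1), y = nodes$y[p] + rnorm(1),
      z = nodes$z[p] + rnorm(1), radius = runif(1, 0.2, 2), parent = p))
  }
  neuron_tree(nodes)
}

# flat-contrast phantom: constant-background volume with the tree's tube
# painted at bg + fg (built through voxelize_segment, checked against the
# brute-force oracle elsewhere)
paint_tube_volume <- function(tree, dims, bg = 100, fg = 100,
                              dtype = "uint16") {
  vol <- volume(array(bg, dims), dtype = dtype)
  for (s in decompose_segments(tree)) {
    idx <- attr(suppressWarnings(voxelize_segment(s, dims)), "linear")
    vol$data[idx] <- bg + fg
  }
  vol
}

# ---------------------------------------------------------------------------
# brute-force oracles (scalar loops, kept independent of the implementation)

# exact point-to-polyline distance and interpolated radius at the nearest
# point, one voxel at a time
oracle_voxelize <- function(nd, dims) {
  hits <- NULL
  rmax <- max(nd$radius)
  zr <- max(0, floor(min(nd$z) - rmax)):min(dims[1] - 1, ceiling(max(nd$z) + rmax))
  yr <- max(0, floor(min(nd$y) - rmax)):min(dims[2] - 1, ceiling(max(nd$y) + rmax))
  xr <- max(0, floor(min(nd$x) - rmax)):min(dims[3] - 1, ceiling(max(nd$x) + rmax))
  for (z in zr) for (y in yr) for (x in xr) {
    bd <- Inf; br <- 0
    if (nrow(nd) == 1) {
      bd <- sqrt((x - nd$x)^2 + (y - nd$y)^2 + (z - nd$z)^2)
      br <- nd$radius
    } else {
      for (i in seq_len(nrow(nd) - 1)) {
        ax <- nd$x[i]; ay <- nd$y[i]; az <- nd$z[i]
        vx <- nd$x[i + 1] - ax; vy <- nd$y[i + 1] - ay; vz <- nd$z[i + 1] - az
        L2 <- vx^2 + vy^2 + vz^2
        t <- if (L2 > 0) ((x - ax) * vx + (y - ay) * vy + (z - az) * vz) / L2 else 0
        t <- min(max(t, 0), 1)
        d <- sqrt((x - ax - t * vx)^2 + (y - ay - t * vy)^2 + (z - az - t * vz)^2)
        if (d < bd) {
          bd <- d
          br <- nd$radius[i] + t * (nd$radius[i + 1] - nd$radius[i])
        }
      }
    }
    if (bd <= br) hits <- rbind(hits, c(z, y, x))
  }
  if (is.null(hits)) return(matrix(integer(), ncol = 3))
  hits[order(hits[, 1] + dims[1] * (hits[, 2] + dims[2] * hits[, 3])), ,
       drop = FALSE]
}

# straddle count per radius, one edge at a time
oracle_sholl <- function(tree, radii) {
  nd <- tree$nodes
  root <- nd[nd$parent == -1L, ]
  counts <- integer(length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    for (i in seq_len(nrow(nd))) {
      if (nd$parent[i] == -1L) next
      p <- nd[nd$id == nd$parent[i], ]
      dc <- sqrt((nd$x[i] - root$x)^2 + (nd$y[i] - root$y)^2 + (nd$z[i] - root$z)^2)
      dp <- sqrt((p$x - root$x)^2 + (p$y - root$y)^2 + (p$z - root$z)^2)
      if (min(dp, dc) < r && max(dp, dc) >= r) counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# directed mean nearest distance, scalar loops over samples and edges;
# replicates the documented inclusive arc-length resampling rule
oracle_directed_mean <- function(a, b, step, lateral = FALSE) {
  nd <- a$nodes
  samples <- NULL
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    p <- nd[nd$id == nd$parent[i], ]
    L <- sqrt((nd$x[i] - p$x)^2 + (nd$y[i] - p$y)^2 + (nd$z[i] - p$z)^2)
    nseg <- max(1, ceiling(L / step))
    for (t in (0:nseg) / nseg) {
      samples <- rbind(samples, c(p$x + t * (nd$x[i] - p$x),
                                  p$y + t * (nd$y[i] - p$y),
                                  p$z + t * (nd$z[i] - p$z)))
    }
  }
  if (is.null(samples)) samples <- cbind(nd$x, nd$y, nd$z)
  bd <- b$nodes
  total <- 0
  for (s in seq_len(nrow(samples))) {
    best <- Inf
    for (i in seq_len(nrow(bd))) {
      if (bd$parent[i] == -1L) next
      p <- bd[bd$id == bd$parent[i], ]
      ax <- p$x; ay <- p$y; az <- p$z
      vx <- bd$x[i] - ax; vy <- bd$y[i] - ay; vz <- bd$z[i] - az
      px <- samples[s, 1]; py <- samples[s, 2]
      pz <- if (lateral) 0 else samples[s, 3]
      if (lateral) { az <- 0; vz <- 0 }
      L2 <- vx^2 + vy^2 + vz^2
      t <- if (L2 > 0) ((px - ax) * vx + (py - ay) * vy + (pz - az) * vz) / L2 else 0
      t <- min(max(t, 0), 1)
      d <- sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2 + (pz - az - t * vz)^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / nrow(samples)
}

# a scripted three-annotator session with known per-client contributions
scripted_session <- function() {
  s <- collab_session()
  a <- session_connect(s, "annotatorA"); s <- a$state
  b <- session_connect(s, "annotatorB"); s <- b$state
  c3 <- session_connect(s, "annotatorC"); s <- c3$state
  seg <- function(n, x0, y0) data.frame(id = seq_len(n), type = 3L,
                                        x = x0 + seq_len(n), y = y0, z = 0,
                                        radius = 1, parent = c(-1L, seq_len(n - 1)))
  r <- session_submit(s, a$client_id, "add_segment", list(nodes = seg(3, 0, 0)))
  s <- r$state
  r <- session_submit(s, b$client_id, "add_segment",
                      list(nodes = seg(4, 0, 5), attrs = list(gen_method = "VR")))
  s <- r$state
  r <- session_submit(s, c3$client_id, "add_segment",
                      list(nodes = seg(2, 0, 10),
                           attrs = list(gen_method = "nonVR")))
  s <- r$state
  r <- session_submit(s, a$client_id, "add_marker",
                      list(x = 1, y = 2, z = 3, name = "check-me"))
  s <- r$state
  r <- session_submit(s, b$client_id, "set_node_attr",
                      list(node_id = 1L, key = "gen_method", value = "VR"))
  s <- r$state
  # B prunes C's 2-node stretch; attribution stays in the log
  r <- session_submit(s, b$client_id, "delete_segment", list(node_ids = 8:9))
  r$state
}
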