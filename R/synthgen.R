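# Seeded generators of synthetic neuron morphologies and rendered image
# volumes emulating sparse-labeled fMOST-like data: bright tube signal
# along a tree, intensity dropout along axons, constant-plus-Gaussian
# background, bright clutter blobs, and optional anisotropic z-blur.

# run expr with a locally seeded, restorable RNG (fixed kind for
# cross-machine determinism)
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Specification of a synthetic neuron morphology
#'
#' @param n_branch_events Number of bifurcation events; the resulting tree
#'   has `n_branch_events` branch nodes and `n_branch_events + 1` tips.
#' @param segment_length_mean,segment_length_sd Mean and SD (voxels) of the
#'   arc length grown between consecutive critical points.
#' @param tortuosity Per-step angular jitter of the growth direction, in
#'   degrees; 0 gives straight segments.
#' @param radius_root Node radius at the soma (voxels).
#' @param radius_taper Multiplicative radius taper applied at each branch
#'   generation.
#' @param step Arc-length spacing between consecutive nodes (voxels).
#' @param dims Optional volume dims (z, y, x) that growth must stay
#'   inside (directions reflect at the walls).
#' @param origin Soma position (x, y, z); defaults to the volume center
#'   when `dims` is given, the coordinate origin otherwise.
#' @param seed Integer seed; identical spec and seed give a byte-identical
#'   tree.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(n_branch_events = 3L, segment_length_mean = 30,
                            segment_length_sd = 8, tortuosity = 12,
                            radius_root = 1.5, radius_taper = 0.9,
                            step = 1, dims = NULL, origin = NULL,
                            seed = 1L) {
  if (segment_length_mean <= 0 || step <= 0) {
    stop_structural("segment_length_mean and step must be positive")
  }
  if (segment_length_mean < step) {
    stop_structural("segment_length_mean below the node spacing gives ",
                    "zero-length segments")
  }
  if (n_branch_events < 0) stop_structural("n_branch_events must be >= 0")
  structure(list(n_branch_events = as.integer(n_branch_events),
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd,
                 tortuosity = tortuosity, radius_root = radius_root,
                 radius_taper = radius_taper, step = step, dims = dims,
                 origin = origin, seed = as.integer(seed)),
            class = "morphology_spec")
}

rand_unit_vec <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# jitter a unit direction by a Gaussian angular perturbation (degrees sd)
jitter_direction <- function(dir, sd_deg) {
  if (sd_deg <= 0) return(dir)
  v <- dir + stats::rnorm(3, sd = tan(pmin(sd_deg, 60) * pi / 180))
  n <- sqrt(sum(v^2))
  if (n < 1e-8) dir else v / n
}

#' Generate a synthetic neuron morphology
#'
#' Grows a single-root tree by a seeded random walk: segments of random
#' arc length are grown node by node with per-step angular jitter; each
#' branch event splits a growing tip into two daughters at divergent
#' angles. Growth reflects at the walls when `dims` is given, so all nodes
#' stay inside the declared volume.
#'
#' @param spec A [morphology_spec()].
#' @return A `neuron_tree` in voxel units.
#' @export
generate_morphology <- function(spec) {
  with_local_seed(spec$seed, {
    margin <- spec$radius_root + 2
    lo <- rep(margin, 3)
    hi <- if (!is.null(spec$dims)) rev(spec$dims) - 1 - margin else NULL
    origin <- spec$origin %||% (if (!is.null(hi)) (lo + hi) / 2 else c(0, 0, 0))
    nodes <- data.frame(id = 1L, type = 1L, x = origin[1], y = origin[2],
                        z = origin[3], radius = spec$radius_root,
                        parent = -1L, stringsAsFactors = FALSE)
    # tips waiting to grow a segment: (attach node id, direction, generation)
    tips <- list(list(at = 1L, dir = rand_unit_vec(), gen = 0L))
    branches_left <- spec$n_branch_events
    next_id <- 2L
    while (length(tips) > 0) {
      tip <- tips[[1]]
      tips <- tips[-1]
      L <- max(2 * spec$step,
               stats::rnorm(1, spec$segment_length_mean, spec$segment_length_sd))
      nsteps <- max(2L, as.integer(round(L / spec$step)))
      pos <- as.numeric(nodes[match(tip$at, nodes$id), c("x", "y", "z")])
      dir <- tip$dir
      rad <- spec$radius_root * spec$radius_taper^tip$gen
      parent <- tip$at
      for (k in seq_len(nsteps)) {
        dir <- jitter_direction(dir, spec$tortuosity)
        cand <- pos + dir * spec$step
        if (!is.null(hi)) {  # reflect at the walls
          for (ax in 1:3) {
            if (cand[ax] < lo[ax] || cand[ax] > hi[ax]) {
              dir[ax] <- -dir[ax]
              cand[ax] <- pos[ax] + dir[ax] * spec$step
              cand[ax] <- min(max(cand[ax], lo[ax]), hi[ax])
            }
          }
        }
        pos <- cand
        nodes <- rbind(nodes, data.frame(
          id = next_id, type = if (tip$gen == 0L) 3L else 2L,
          x = pos[1], y = pos[2], z = pos[3], radius = rad,
          parent = parent, stringsAsFactors = FALSE))
        parent <- next_id
        next_id <- next_id + 1L
      }
      if (branches_left > 0L) {
        branches_left <- branches_left - 1L
        axis <- rand_unit_vec()
        split <- 0.6 * axis
        d1 <- dir + split; d1 <- d1 / sqrt(sum(d1^2))
        d2 <- dir - split; d2 <- d2 / sqrt(sum(d2^2))
        tips <- c(tips, list(list(at = parent, dir = d1, gen = tip$gen + 1L),
                             list(at = parent, dir = d2, gen = tip$gen + 1L)))
      }
    }
    neuron_tree(nodes, unit = "voxel",
                provenance = sprintf("synthetic morphology (seed %d)", spec$seed))
  })
}

#' Specification of a synthetic rendered volume
#'
#' Defaults emulate a sparse-labeled fMOST-like imaging regime: moderate
#' tube contrast over a constant background with Gaussian noise, occasional
#' signal dropout along axons ("punctuated" fibers), bright clutter blobs,
#' and mild anisotropic blur along z.
#'
#' @param fg_amplitude Tube signal added above background at the
#'   centerline.
#' @param bg_level Constant background intensity.
#' @param bg_noise_sd SD of additive Gaussian background noise (truncated
#'   at zero intensity).
#' @param dropout_prob Probability that an individual rendered centerline
#'   piece (one inter-node edge) is dropped, emulating punctuated axons.
#' @param clutter_density Expected clutter blobs per 1000 voxels.
#' @param z_blur_sigma SD (voxels) of a 1-D Gaussian blur applied to the
#'   signal along z; 0 disables it.
#' @param dims Volume dims (z, y, x).
#' @param dtype Stored dtype; intensities are clipped to its range.
#' @param profile `"flat"` renders a constant-intensity tube core (the
#'   calibration mode whose expected SNR is exactly
#'   `(bg + fg) / bg`); `"gaussian"` applies a radial falloff
#'   `exp(-d^2 / (2 (r/2)^2))` inside the tube for softer, more realistic
#'   cross-sections.
#' @param seed Integer seed; identical spec and seed give an identical
#'   volume.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(fg_amplitude = 120, bg_level = 100, bg_noise_sd = 15,
                        dropout_prob = 0.1, clutter_density = 2,
                        z_blur_sigma = 1, dims = c(64, 64, 64),
                        dtype = "uint16", profile = c("flat", "gaussian"),
                        seed = 1L) {
  profile <- match.arg(profile)
  if (fg_amplitude < 0 || bg_level < 0) {
    stop_structural("fg_amplitude and bg_level must be non-negative")
  }
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop_structural("dropout_prob must lie in [0, 1)")
  }
  structure(list(fg_amplitude = fg_amplitude, bg_level = bg_level,
                 bg_noise_sd = bg_noise_sd, dropout_prob = dropout_prob,
                 clutter_density = clutter_density,
                 z_blur_sigma = z_blur_sigma, dims = as.integer(dims),
                 dtype = match.arg(dtype, names(VOL_DTYPES)),
                 profile = profile, seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a neuron morphology into a synthetic image volume
#'
#' The tube signal is composed by maximum where tubes or clutter overlap
#' (crossing neurites brighten, they do not add without bound), then
#' optionally blurred along z, and finally laid over
#' `bg_level + N(0, bg_noise_sd)` noise, truncated at zero and clipped to
#' the dtype range. Per-edge dropout removes whole centerline pieces.
#'
#' @param tree A `neuron_tree` in voxel coordinates inside `spec$dims`.
#' @param spec A [render_spec()].
#' @param fg_node Optional named numeric vector of per-node multipliers of
#'   `fg_amplitude` (names are node ids; an edge uses its child node's
#'   multiplier), for rendering designed per-segment contrasts.
#' @return A [volume()].
#' @export
render_volume <- function(tree, spec, fg_node = NULL) {
  dims <- spec$dims
  nd <- tree$nodes
  if (any(nd$x < 0 | nd$x > dims[3] - 1 | nd$y < 0 | nd$y > dims[2] - 1 |
          nd$z < 0 | nd$z > dims[1] - 1)) {
    stop_structural("tree extends outside the rendered dims")
  }
  with_local_seed(spec$seed, {
    S <- array(0, dim = dims)
    has_par <- which(nd$parent != -1L)
    keep <- stats::runif(length(has_par)) >= spec$dropout_prob
    for (k in seq_along(has_par)) {
      if (!keep[k]) next
      i <- has_par[k]
      pi <- match(nd$parent[i], nd$id)
      piece <- nd[c(pi, i), , drop = FALSE]
      seg <- list(nodes = piece)
      vox <- suppressWarnings(voxelize_segment(seg, dims))
      lin <- attr(vox, "linear")
      if (length(lin) == 0) next
      amp <- spec$fg_amplitude
      if (!is.null(fg_node)) {
        mult <- fg_node[[as.character(nd$id[i])]]
        if (!is.null(mult) && is.finite(mult)) amp <- amp * mult
      }
      if (spec$profile == "flat") {
        S[lin] <- pmax(S[lin], amp)
      } else {
        P <- cbind(vox[, "x"], vox[, "y"], vox[, "z"])
        d <- point_polyline_distance(P, piece)
        sig <- pmax(mean(piece$radius) / 2, 0.5)
        S[lin] <- pmax(S[lin], amp * exp(-d^2 / (2 * sig^2)))
      }
    }
    # bright clutter blobs between background and signal amplitude
    n_spots <- stats::rpois(1, spec$clutter_density * prod(dims) / 1000)
    if (n_spots > 0) {
      cz <- stats::runif(n_spots, 0, dims[1] - 1)
      cy <- stats::runif(n_spots, 0, dims[2] - 1)
      cx <- stats::runif(n_spots, 0, dims[3] - 1)
      srad <- stats::runif(n_spots, 0.8, 2.2)
      samp <- stats::runif(n_spots, 0.25, 1) * spec$fg_amplitude
      for (s in seq_len(n_spots)) {
        ext <- ceiling(3 * srad[s])
        zz <- max(0, floor(cz[s] - ext)):min(dims[1] - 1, ceiling(cz[s] + ext))
        yy <- max(0, floor(cy[s] - ext)):min(dims[2] - 1, ceiling(cy[s] + ext))
        xx <- max(0, floor(cx[s] - ext)):min(dims[3] - 1, ceiling(cx[s] + ext))
        g <- expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE)
        d2 <- (g$z - cz[s])^2 + (g$y - cy[s])^2 + (g$x - cx[s])^2
        lin <- g$z + 1L + dims[1] * (g$y + dims[2] * g$x)
        S[lin] <- pmax(S[lin], samp[s] * exp(-d2 / (2 * srad[s]^2)))
      }
    }
    if (spec$z_blur_sigma > 0) S <- blur_z(S, spec$z_blur_sigma)
    out <- spec$bg_level + S
    if (spec$bg_noise_sd > 0) {
      out <- out + array(stats::rnorm(prod(dims), 0, spec$bg_noise_sd),
                         dim = dims)
    }
    out <- pmax(out, 0)
    if (spec$dtype != "float") {
      out <- pmin(round(out), dtype_max(spec$dtype))
    }
    volume(array(out, dim = dims), dtype = spec$dtype)
  })
}

# exact distance from (x, y, z) points to a 2-node polyline piece
point_polyline_distance <- function(P, nd) {
  a <- c(nd$x[1], nd$y[1], nd$z[1])
  b <- c(nd$x[2], nd$y[2], nd$z[2])
  v <- b - a
  L2 <- sum(v^2)
  W <- sweep(P, 2, a)
  t <- if (L2 > 0) pmin(pmax(as.vector(W %*% v) / L2, 0), 1) else
    rep(0, nrow(P))
  sqrt(rowSums((W - outer(t, v))^2))
}

# 1-D Gaussian blur along the z axis with reflective padding
blur_z <- function(a, sigma) {
  d <- dim(a)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  idx <- outer(seq_len(d[1]), -half:half, "+")
  idx[idx < 1] <- 2 - idx[idx < 1]                # reflect low edge
  idx[idx > d[1]] <- 2 * d[1] - idx[idx > d[1]]   # reflect high edge
  m <- matrix(a, nrow = d[1])
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (k in seq_along(kern)) out <- out + kern[k] * m[idx[, k], , drop = FALSE]
  array(out, dim = d)
}
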