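# 3-D image volumes, chunked multi-resolution pyramid store, ROI fetch,
# and geometric voxelization of neurite segments.
#
# Index order is (z, y, x) everywhere, 0-based, with half-open ROIs.
# A voxel (z, y, x) has its center at SWC coordinate (x, y, z).

VOL_DTYPES <- c(uint8 = 1L, uint16 = 2L, float = 8L)

#' Construct an image volume
#'
#' @param data 3-D numeric array indexed `[z, y, x]` (1-based in R).
#' @param voxel_size Physical size per voxel along (z, y, x); default 1.
#' @param dtype `"uint8"`, `"uint16"` or `"float"`. Integer dtypes bound
#'   the representable intensity range; `"float"` stores doubles.
#' @return An object of class `volume` with fields `data`, `dims`
#'   (z, y, x), `voxel_size`, `dtype`.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1), dtype = "float") {
  if (length(dim(data)) != 3) stop_structural("volume data must be 3-D (z, y, x)")
  storage.mode(data) <- "double"
  dtype <- match.arg(dtype, names(VOL_DTYPES))
  if (any(!is.finite(data))) stop_structural("volume intensities must be finite")
  if (dtype != "float") {
    mx <- if (dtype == "uint8") 255 else 65535
    if (any(data < 0 | data > mx)) {
      stop_structural("intensities out of range for ", dtype)
    }
  }
  structure(list(data = data, dims = dim(data),
                 voxel_size = as.numeric(voxel_size), dtype = dtype),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> dims (z,y,x) = %s, dtype=%s, range [%.4g, %.4g]\n",
              paste(x$dims, collapse = "x"), x$dtype,
              min(x$data), max(x$data)))
  invisible(x)
}

dtype_max <- function(dtype) switch(dtype, uint8 = 255, uint16 = 65535, Inf)

# ---------------------------------------------------------------------------
# Volume I/O: TIFF stacks, NRRD (raw little-endian encoding), raw + JSON.

guess_volume_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tif = , tiff = "tiff", nrrd = "nrrd", bin = , raw = "rawjson",
         stop_parse("cannot guess volume format from extension: ", path))
}

#' Read a 3-D image volume
#'
#' Supported containers: multi-page TIFF stacks (one page per z-slice,
#' 8/16-bit grayscale), NRRD with `raw` little-endian encoding, and a raw
#' binary payload with a JSON metadata sidecar (`<path>.json`).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tiff"`, `"nrrd"`, or
#'   `"rawjson"`.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = "auto") {
  if (!file.exists(path)) stop_parse("volume file not found: ", path)
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
         tiff = read_volume_tiff(path),
         nrrd = read_volume_nrrd(path),
         rawjson = read_volume_rawjson(path),
         stop_parse("unsupported volume format: ", format))
}

#' Write a 3-D image volume
#'
#' @param vol A [volume()].
#' @param path Output file.
#' @param format As in [read_volume()]. TIFF supports the integer dtypes;
#'   `float` volumes go to NRRD or raw+JSON.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "auto") {
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
         tiff = write_volume_tiff(vol, path),
         nrrd = write_volume_nrrd(vol, path),
         rawjson = write_volume_rawjson(vol, path),
         stop_parse("unsupported volume format: ", format))
  invisible(path)
}

read_volume_tiff <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop_parse("unreadable TIFF: ",
                                                   conditionMessage(e)))
  if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2) {
    stop_parse("TIFF pages must be single-channel grayscale")
  }
  nz <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nz, ny, nx))
  for (s in seq_len(nz)) data[s, , ] <- pages[[s]]
  bps <- attr(pages[[1]], "bits.per.sample") %||% if (max(data) > 255) 16 else 8
  volume(data, dtype = if (bps > 8) "uint16" else "uint8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_volume_tiff <- function(vol, path) {
  if (vol$dtype == "float") {
    stop_parse("TIFF writer supports uint8/uint16 only; use nrrd or rawjson")
  }
  bits <- if (vol$dtype == "uint8") 8L else 16L
  mx <- dtype_max(vol$dtype)
  pages <- lapply(seq_len(vol$dims[1]),
                  function(s) matrix(vol$data[s, , ], vol$dims[2], vol$dims[3]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

nrrd_type_name <- function(dtype) switch(dtype, uint8 = "uint8",
                                         uint16 = "uint16", float = "double")

write_volume_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# written by neurotrace",
           paste0("type: ", nrrd_type_name(vol$dtype)),
           "dimension: 3",
           # NRRD sizes are fastest axis first: x, y, z
           paste0("sizes: ", vol$dims[3], " ", vol$dims[2], " ", vol$dims[1]),
           paste0("spacings: ", vol$voxel_size[3], " ", vol$voxel_size[2],
                  " ", vol$voxel_size[1]),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  write_payload(con, vol$data, vol$dtype)
  invisible(path)
}

read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop_parse("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop_parse("NRRD header not terminated by blank line")
    if (!nzchar(ln)) break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  type <- fields[["type"]]
  dtype <- switch(type, uint8 = , uchar = "uint8",
                  uint16 = , ushort = "uint16",
                  double = , float = "float",
                  stop_parse("unsupported NRRD type: ", type))
  if (!identical(fields[["encoding"]], "raw")) {
    stop_parse("only raw NRRD encoding is supported")
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])  # x y z
  dims <- rev(sizes)
  data <- read_payload(con, dims, dtype)
  vs <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    vs <- rev(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]))
  }
  volume(data, voxel_size = vs, dtype = dtype)
}

write_volume_rawjson <- function(vol, path) {
  meta <- list(format = "neurotrace-raw", version = 1L,
               dims = vol$dims, dtype = vol$dtype,
               voxel_size = vol$voxel_size,
               byte_order = "little", fastest_axis = "x")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  write_payload(con, vol$data, vol$dtype)
  invisible(path)
}

read_volume_rawjson <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop_parse("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  data <- read_payload(con, as.integer(meta$dims), meta$dtype)
  volume(data, voxel_size = as.numeric(meta$voxel_size), dtype = meta$dtype)
}

# payload layout: x fastest, then y, then z (C order over (z, y, x))
write_payload <- function(con, data, dtype) {
  v <- as.vector(aperm(data, c(3, 2, 1)))
  if (dtype == "float") {
    writeBin(v, con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(round(v)), con, size = VOL_DTYPES[[dtype]],
             endian = "little")
  }
}

read_payload <- function(con, dims, dtype) {
  n <- prod(dims)
  v <- if (dtype == "float") {
    readBin(con, numeric(), n = n, size = 8, endian = "little")
  } else {
    readBin(con, integer(), n = n, size = VOL_DTYPES[[dtype]],
            signed = FALSE, endian = "little")
  }
  if (length(v) != n) stop_parse("truncated volume payload")
  aperm(array(as.numeric(v), dim = rev(dims)), c(3, 2, 1))
}

# ---------------------------------------------------------------------------
# Multi-resolution pyramid store

#' Build a chunked multi-resolution pyramid store
#'
#' Writes a directory holding `n_levels` resolutions of a volume. Level 0
#' reproduces the source exactly; each further level halves every axis
#' (`ceil(d / 2^l)`) by mean-pooling 2x2x2 blocks, averaging partial
#' boundary blocks over their existing voxels only, and rounding half-even
#' to the stored dtype. Mean pooling (rather than max) keeps downsampled
#' intensities representative of the mean-based SNR statistics computed on
#' them. Chunks are raw little-endian files `L{level}/{bz}_{by}_{bx}.bin`
#' beside one `meta.json`.
#'
#' @param vol Source [volume()].
#' @param path Directory to create.
#' @param block_size Chunk shape (z, y, x); default 32^3.
#' @param n_levels Number of levels including level 0.
#' @return A `pyramid_store` handle (see [open_pyramid()]).
#' @export
build_pyramid <- function(vol, path, block_size = c(32, 32, 32), n_levels = 1) {
  if (n_levels < 1) stop_structural("n_levels must be >= 1")
  block_size <- as.integer(block_size)
  if (any(block_size < 1)) stop_structural("block_size must be positive")
  dims <- vol$dims
  level_dims <- lapply(0:(n_levels - 1), function(l) as.integer(ceiling(dims / 2^l)))
  if (n_levels > 1 && 2^(n_levels - 1) > max(dims)) {
    stop_structural("n_levels = ", n_levels, " leaves no voxels to pool for ",
                    "dims ", paste(dims, collapse = "x"))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cur <- vol$data
  for (l in 0:(n_levels - 1)) {
    if (l > 0) cur <- pool_mean2(cur, vol$dtype)
    write_level_blocks(cur, file.path(path, paste0("L", l)), block_size,
                       vol$dtype)
  }
  meta <- list(format = "neurotrace-pyramid", version = 1L,
               dims = level_dims, block_size = block_size,
               n_levels = as.integer(n_levels), dtype = vol$dtype,
               downsample = "mean", voxel_size = vol$voxel_size)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  open_pyramid(path)
}

# 2x2x2 mean pooling with partial boundary blocks averaged over existing
# voxels; integer dtypes rounded half-even (base round()).
pool_mean2 <- function(a, dtype) {
  d <- dim(a)
  nd <- ceiling(d / 2)
  gz <- (seq_len(d[1]) + 1L) %/% 2L
  gy <- (seq_len(d[2]) + 1L) %/% 2L
  gx <- (seq_len(d[3]) + 1L) %/% 2L
  s <- a
  s <- pool_axis_sum(s, 1, gz, nd[1])
  s <- pool_axis_sum(s, 2, gy, nd[2])
  s <- pool_axis_sum(s, 3, gx, nd[3])
  cnt <- outer(outer(tabulate(gz, nd[1]), tabulate(gy, nd[2])),
               tabulate(gx, nd[3]))
  m <- s / cnt
  if (dtype != "float") m <- pmin(round(m), dtype_max(dtype))
  m
}

pool_axis_sum <- function(a, axis, groups, nout) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  sm <- rowsum(m, group = groups, reorder = TRUE)
  out <- array(sm, dim = c(nout, d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

write_level_blocks <- function(a, dir, block_size, dtype) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(a)
  nb <- ceiling(d / block_size)
  for (bz in 0:(nb[1] - 1)) for (by in 0:(nb[2] - 1)) for (bx in 0:(nb[3] - 1)) {
    z0 <- bz * block_size[1]; y0 <- by * block_size[2]; x0 <- bx * block_size[3]
    blk <- a[(z0 + 1):min(z0 + block_size[1], d[1]),
             (y0 + 1):min(y0 + block_size[2], d[2]),
             (x0 + 1):min(x0 + block_size[3], d[3]), drop = FALSE]
    con <- file(file.path(dir, sprintf("%d_%d_%d.bin", bz, by, bx)), "wb")
    write_payload(con, blk, dtype)
    close(con)
  }
}

#' Open an existing pyramid store
#'
#' @param path Directory written by [build_pyramid()].
#' @return A `pyramid_store` handle with the parsed metadata.
#' @export
open_pyramid <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_parse("not a pyramid store: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "neurotrace-pyramid")) {
    stop_parse("unrecognised pyramid metadata in ", meta_path)
  }
  meta$dims <- lapply(seq_len(nrow(meta$dims)),
                      function(i) as.integer(meta$dims[i, ]))
  structure(list(root = path, meta = meta), class = "pyramid_store")
}

#' @export
print.pyramid_store <- function(x, ...) {
  cat(sprintf("<pyramid_store> %s: %d level(s), dtype=%s, block %s\n",
              x$root, x$meta$n_levels, x$meta$dtype,
              paste(x$meta$block_size, collapse = "x")))
  invisible(x)
}

#' Describe a region of interest
#'
#' Half-open 0-based box `[origin, origin + shape)` at a pyramid level, in
#' (z, y, x) order.
#'
#' @param level Pyramid level (0 = full resolution).
#' @param origin Integer triple (z, y, x); may be negative for an unclipped
#'   bounding box, but must be in range before fetching.
#' @param shape Positive integer triple (z, y, x).
#' @return An object of class `roi`.
#' @export
roi <- function(level = 0L, origin, shape) {
  if (any(shape < 1)) stop_structural("roi shape must be positive")
  structure(list(level = as.integer(level), origin = as.integer(origin),
                 shape = as.integer(shape)), class = "roi")
}

#' @rdname roi
#' @param r An `roi`.
#' @param dims Level dims (z, y, x) to clip against.
#' @export
clip_roi <- function(r, dims) {
  lo <- pmax(r$origin, 0L)
  hi <- pmin(r$origin + r$shape, as.integer(dims))
  if (any(hi <= lo)) stop_structural("roi lies entirely outside the volume")
  roi(r$level, lo, hi - lo)
}

#' Fetch an ROI from a pyramid store
#'
#' Reads exactly the chunks overlapping the request and assembles the
#' contiguous sub-grid. Out-of-bounds requests are an error, never silently
#' zero-padded (padding would corrupt background statistics computed on the
#' result).
#'
#' @param store A `pyramid_store`.
#' @param r An [roi()].
#' @return A [volume()] of shape `r$shape`; at level 0 it is bit-exact with
#'   the corresponding crop of the source volume.
#' @export
fetch_roi <- function(store, r) {
  meta <- store$meta
  if (r$level < 0 || r$level >= meta$n_levels) {
    stop_structural("level ", r$level, " not present (", meta$n_levels, " levels)")
  }
  dims <- meta$dims[[r$level + 1]]
  if (any(r$origin < 0) || any(r$origin + r$shape > dims)) {
    stop_structural("roi out of bounds at level ", r$level, ": origin ",
                    paste(r$origin, collapse = ","), " shape ",
                    paste(r$shape, collapse = ","), " vs dims ",
                    paste(dims, collapse = ","))
  }
  bs <- as.integer(meta$block_size)
  out <- array(0, dim = r$shape)
  b0 <- r$origin %/% bs
  b1 <- (r$origin + r$shape - 1L) %/% bs
  for (bz in b0[1]:b1[1]) for (by in b0[2]:b1[2]) for (bx in b0[3]:b1[3]) {
    borig <- c(bz, by, bx) * bs
    bdim <- pmin(bs, dims - borig)
    f <- file.path(store$root, paste0("L", r$level),
                   sprintf("%d_%d_%d.bin", bz, by, bx))
    if (!file.exists(f)) stop_parse("missing pyramid chunk: ", f)
    con <- file(f, "rb")
    blk <- read_payload(con, bdim, meta$dtype)
    close(con)
    lo <- pmax(r$origin, borig)            # global coords, 0-based
    hi <- pmin(r$origin + r$shape, borig + bdim)
    out[(lo[1] - r$origin[1] + 1):(hi[1] - r$origin[1]),
        (lo[2] - r$origin[2] + 1):(hi[2] - r$origin[2]),
        (lo[3] - r$origin[3] + 1):(hi[3] - r$origin[3])] <-
      blk[(lo[1] - borig[1] + 1):(hi[1] - borig[1]),
          (lo[2] - borig[2] + 1):(hi[2] - borig[2]),
          (lo[3] - borig[3] + 1):(hi[3] - borig[3]), drop = FALSE]
  }
  volume(out, voxel_size = as.numeric(meta$voxel_size) * 2^r$level,
         dtype = meta$dtype)
}

# ---------------------------------------------------------------------------
# Segment geometry: bounding boxes and tube voxelization

#' Bounding box of a neurite segment
#'
#' Tight axis-aligned box covering every node position expanded by that
#' node's radius, then by `margin` voxels on every side. The box is the
#' background region for SNR profiling; it is returned unclipped (the
#' origin may be negative) and clipped to the volume bounds at use time via
#' [clip_roi()].
#'
#' @param segment A `neuron_segment` (or any object with a `nodes` table).
#' @param margin Non-negative integer voxel margin.
#' @return A level-0 [roi()].
#' @export
segment_bbox <- function(segment, margin = 0L) {
  nd <- segment$nodes
  if (is.null(nd) || nrow(nd) == 0) stop_structural("empty segment")
  lo <- floor(c(min(nd$z - nd$radius), min(nd$y - nd$radius),
                min(nd$x - nd$radius))) - margin
  hi <- ceiling(c(max(nd$z + nd$radius), max(nd$y + nd$radius),
                  max(nd$x + nd$radius))) + margin
  roi(0L, as.integer(lo), as.integer(hi - lo + 1L))
}

#' Voxelize a neurite segment as a sphere-swept tube
#'
#' Returns the set of voxels whose centers lie within the tube swept along
#' the segment's polyline: a voxel center is foreground when its distance
#' to the polyline does not exceed the node radius linearly interpolated at
#' the nearest polyline point. Distances are computed per linear piece with
#' endpoint clamping; the nearest piece is chosen by minimum distance with
#' ties broken by piece order, making the result deterministic.
#'
#' @param segment A `neuron_segment` in voxel coordinates.
#' @param dims Volume dims (z, y, x) clipping the candidate voxels.
#' @return Integer matrix with columns `z`, `y`, `x` (0-based voxel
#'   indices, sorted by linear index) and attribute `"linear"` holding the
#'   1-based R linear indices into an array of those dims. Empty (with a
#'   warning) when the segment lies entirely outside `dims`.
#' @export
voxelize_segment <- function(segment, dims) {
  nd <- segment$nodes
  if (is.null(nd) || nrow(nd) == 0) stop_structural("empty segment")
  dims <- as.integer(dims)
  bb <- segment_bbox(segment, margin = 0L)
  lo <- pmax(bb$origin, 0L)
  hi <- pmin(bb$origin + bb$shape, dims)
  if (any(hi <= lo)) {
    warning("segment lies entirely outside the volume; empty foreground")
    return(empty_voxel_set(dims))
  }
  zz <- lo[1]:(hi[1] - 1L); yy <- lo[2]:(hi[2] - 1L); xx <- lo[3]:(hi[3] - 1L)
  grid <- expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE)
  keep <- points_in_tube(as.matrix(grid[, c("x", "y", "z")]), nd)
  sel <- grid[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("segment tube contains no voxel centers inside the volume")
    return(empty_voxel_set(dims))
  }
  lin <- sel$z + 1L + dims[1] * (sel$y + dims[2] * sel$x)
  o <- order(lin)
  out <- as.matrix(sel[o, c("z", "y", "x")])
  rownames(out) <- NULL
  structure(out, linear = lin[o], dims = dims)
}

empty_voxel_set <- function(dims) {
  structure(matrix(integer(), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x"))),
            linear = integer(), dims = dims)
}

# P: m x 3 matrix of (x, y, z) points; nd: node table with x,y,z,radius.
# TRUE where the point lies inside the sphere-swept, radius-interpolated tube.
points_in_tube <- function(P, nd) {
  m <- nrow(P)
  if (m == 0) return(logical(0))
  n <- nrow(nd)
  if (n == 1) {
    d2 <- (P[, 1] - nd$x)^2 + (P[, 2] - nd$y)^2 + (P[, 3] - nd$z)^2
    return(d2 <= nd$radius^2)
  }
  best_d <- rep(Inf, m)
  best_r <- rep(0, m)
  for (i in seq_len(n - 1)) {
    a <- c(nd$x[i], nd$y[i], nd$z[i])
    b <- c(nd$x[i + 1], nd$y[i + 1], nd$z[i + 1])
    v <- b - a
    L2 <- sum(v^2)
    wx <- P[, 1] - a[1]; wy <- P[, 2] - a[2]; wz <- P[, 3] - a[3]
    t <- if (L2 > 0) pmin(pmax((wx * v[1] + wy * v[2] + wz * v[3]) / L2, 0), 1)
         else rep(0, m)
    dx <- wx - t * v[1]; dy <- wy - t * v[2]; dz <- wz - t * v[3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    r <- nd$radius[i] + t * (nd$radius[i + 1] - nd$radius[i])
    upd <- d < best_d  # strict: ties keep the earlier piece
    best_r[upd] <- r[upd]
    best_d[upd] <- d[upd]
  }
  best_d <= best_r
}
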