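test_that("volume containers round trip through every supported format", {
  set.seed(301)
  v <- volume(array(sample(0:65535, 4 * 5 * 6, replace = TRUE), c(4, 5, 6)),
              dtype = "uint16")
  td <- withr_local_tempdir()
  for (f in c("v.tif", "v.nrrd", "v.bin")) {
    p <- file.path(td, f)
    write_volume(v, p)
    rt <- read_volume(p)
    expect_identical(rt$data, v$data)
    expect_identical(rt$dtype, "uint16")
  }
  vf <- volume(array(rnorm(60), c(3, 4, 5)), dtype = "float",
               voxel_size = c(1, 0.5, 0.5))
  p <- file.path(td, "vf.nrrd")
  write_volume(vf, p)
  rt <- read_volume(p)
  expect_identical(rt$data, vf$data)
  expect_equal(rt$voxel_size, c(1, 0.5, 0.5))

  expect_error(read_volume(file.path(td, "absent.tif")),
               class = "neurotrace_parse_error")
  writeLines("not nrrd", file.path(td, "junk.nrrd"))
  expect_error(read_volume(file.path(td, "junk.nrrd")),
               class = "neurotrace_parse_error")
})

test_that("constant and sized volumes read back with expected dims", {
  td <- withr_local_tempdir()
  v <- volume(array(17, c(4, 4, 4)), dtype = "uint8")
  write_volume(v, file.path(td, "c.tif"))
  rt <- read_volume(file.path(td, "c.tif"))
  expect_true(all(rt$data == 17))
  v2 <- volume(array(0, c(10, 32, 32)), dtype = "uint8")
  write_volume(v2, file.path(td, "s.tif"))
  expect_equal(read_volume(file.path(td, "s.tif"))$dims, c(10, 32, 32))
})

test_that("pyramid levels halve dims, pool means and reproduce level 0", {
  td <- withr_local_tempdir()
  # 2x2x2 block of 0..7 pools to its mean, rounded half-even
  v8 <- volume(array(0:7, c(2, 2, 2)), dtype = "uint16")
  ps <- build_pyramid(v8, file.path(td, "p8"), block_size = c(2, 2, 2),
                      n_levels = 2)
  expect_equal(as.numeric(fetch_roi(ps, roi(1, c(0, 0, 0), c(1, 1, 1)))$data), 4)
  vf8 <- volume(array(0:7, c(2, 2, 2)), dtype = "float")
  psf <- build_pyramid(vf8, file.path(td, "pf8"), n_levels = 2)
  expect_equal(as.numeric(fetch_roi(psf, roi(1, c(0, 0, 0), c(1, 1, 1)))$data), 3.5)

  # constant volumes stay constant at every level
  vc <- volume(array(9, c(5, 6, 7)), dtype = "uint8")
  psc <- build_pyramid(vc, file.path(td, "pc"), n_levels = 3)
  for (l in 0:2) {
    d <- psc$meta$dims[[l + 1]]
    expect_equal(d, as.integer(ceiling(c(5, 6, 7) / 2^l)))
    expect_true(all(fetch_roi(psc, roi(l, c(0, 0, 0), d))$data == 9))
  }

  set.seed(77)
  v <- volume(array(sample(0:65535, 11 * 9 * 14, replace = TRUE), c(11, 9, 14)),
              dtype = "uint16")
  ps <- build_pyramid(v, file.path(td, "pr"), block_size = c(4, 4, 4),
                      n_levels = 3)
  expect_identical(fetch_roi(ps, roi(0, c(0, 0, 0), c(11, 9, 14)))$data, v$data)
  expect_equal(ps$meta$dims, list(c(11L, 9L, 14L), c(6L, 5L, 7L), c(3L, 3L, 4L)))
  expect_error(build_pyramid(v, file.path(td, "bad"), n_levels = 20),
               class = "neurotrace_structural_error")
})

test_that("float pyramids with even dims conserve the global mean exactly", {
  td <- withr_local_tempdir()
  set.seed(41)
  v <- volume(array(rnorm(32^3), c(32, 32, 32)), dtype = "float")
  ps <- build_pyramid(v, file.path(td, "pf"), n_levels = 4)
  m0 <- mean(v$data)
  for (l in 1:3) {
    d <- ps$meta$dims[[l + 1]]
    expect_equal(mean(fetch_roi(ps, roi(l, c(0, 0, 0), d))$data), m0,
                 tolerance = 1e-13)
  }
})

test_that("level-0 ROI fetch equals a direct crop and bounds are enforced", {
  td <- withr_local_tempdir()
  set.seed(55)
  dims <- c(13, 17, 11)
  v <- volume(array(sample(0:255, prod(dims), replace = TRUE), dims),
              dtype = "uint8")
  ps <- build_pyramid(v, file.path(td, "p"), block_size = c(5, 6, 4),
                      n_levels = 2)
  expect_identical(fetch_roi(ps, roi(0, c(0, 0, 0), dims))$data, v$data)
  for (k in 1:60) {
    o <- c(sample(0:(dims[1] - 1), 1), sample(0:(dims[2] - 1), 1),
           sample(0:(dims[3] - 1), 1))
    sh <- pmin(dims - o, c(sample(1:6, 1), sample(1:6, 1), sample(1:6, 1)))
    got <- fetch_roi(ps, roi(0, o, sh))$data
    expect_identical(got, v$data[(o[1] + 1):(o[1] + sh[1]),
                                 (o[2] + 1):(o[2] + sh[2]),
                                 (o[3] + 1):(o[3] + sh[3]), drop = FALSE])
  }
  expect_error(fetch_roi(ps, roi(0, c(0, 0, 10), c(1, 1, 5))),
               class = "neurotrace_structural_error", regexp = "out of bounds")
  expect_error(fetch_roi(ps, roi(5, c(0, 0, 0), c(1, 1, 1))),
               class = "neurotrace_structural_error")
})

test_that("segment bounding boxes cover node spheres plus the margin", {
  seg1 <- list(nodes = data.frame(id = 1, type = 1, x = 5, y = 5, z = 5,
                                  radius = 1, parent = -1))
  bb <- segment_bbox(seg1)
  expect_equal(bb$origin, c(4L, 4L, 4L))
  expect_equal(bb$shape, c(3L, 3L, 3L))
  seg2 <- list(nodes = data.frame(id = 1:2, type = 1, x = c(0, 9), y = 0,
                                  z = 0, radius = 0, parent = c(-1, 1)))
  bb2 <- segment_bbox(seg2)
  expect_equal(bb2$shape, c(1L, 1L, 10L))
  bb3 <- segment_bbox(seg1, margin = 2)
  expect_equal(bb3$origin, c(2L, 2L, 2L))
  expect_equal(bb3$shape, c(7L, 7L, 7L))
  # clipping respects volume bounds
  cl <- clip_roi(segment_bbox(seg2), c(5, 5, 5))
  expect_equal(cl$origin + cl$shape <= c(5L, 5L, 5L), rep(TRUE, 3))
})

test_that("voxelization matches the single-sphere and on-axis examples", {
  seg1 <- list(nodes = data.frame(id = 1, type = 1, x = 5, y = 5, z = 5,
                                  radius = 1, parent = -1))
  vx <- voxelize_segment(seg1, c(11, 11, 11))
  expect_equal(nrow(vx), 7)  # center plus 6 face neighbours
  expect_true(all(abs(vx[, "z"] - 5) + abs(vx[, "y"] - 5) + abs(vx[, "x"] - 5) <= 1))
  # zero-radius straight tube through voxel centers hits exactly that line
  seg2 <- list(nodes = data.frame(id = 1:2, type = 1, x = c(2, 8), y = 4,
                                  z = 3, radius = 0, parent = c(-1, 1)))
  vx2 <- voxelize_segment(seg2, c(10, 10, 10))
  expect_equal(unname(vx2), cbind(rep(3L, 7), rep(4L, 7), 2:8),
               ignore_attr = TRUE)
  expect_warning(voxelize_segment(
    list(nodes = data.frame(id = 1, type = 1, x = 50, y = 50, z = 50,
                            radius = 1, parent = -1)), c(10, 10, 10)),
    regexp = "outside")
})

test_that("enlarging radii never removes a foreground voxel", {
  set.seed(91)
  for (k in 1:10) {
    n <- sample(2:4, 1)
    nd <- data.frame(id = seq_len(n), type = 3, x = runif(n, 4, 20),
                     y = runif(n, 4, 20), z = runif(n, 4, 20),
                     radius = runif(n, 0.5, 2), parent = c(-1, seq_len(n - 1)))
    small <- voxelize_segment(list(nodes = nd), c(25, 25, 25))
    nd2 <- nd; nd2$radius <- nd$radius + 0.7
    big <- voxelize_segment(list(nodes = nd2), c(25, 25, 25))
    expect_true(all(attr(small, "linear") %in% attr(big, "linear")))
  }
})
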