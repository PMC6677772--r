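test_that("SNR categories use right-closed intervals at 1.0/1.2/1.4", {
  cfg <- snr_config()
  expect_equal(categorize_snr(1.0, cfg), "very_low")
  expect_equal(categorize_snr(0.2, cfg), "very_low")
  expect_equal(categorize_snr(1.2, cfg), "low")
  expect_equal(categorize_snr(1.2 + 1e-12, cfg), "mid")
  expect_equal(categorize_snr(1.4, cfg), "mid")
  expect_equal(categorize_snr(1.41, cfg), "high")
  expect_error(categorize_snr(NaN, cfg), class = "neurotrace_structural_error")
  expect_error(snr_config(thresholds = c(1, 1, 2)),
               class = "neurotrace_structural_error")
})

test_that("profile_segment computes mean(F)/(mean(B_crt)+eps) analytically", {
  tube <- chain_tree(c(4, 16), ys = 10, zs = 10, radius = 1.5)
  seg <- decompose_segments(tube)[[1]]
  vol <- paint_tube_volume(tube, c(21, 21, 21), bg = 100, fg = 100)
  p <- profile_segment(seg, vol)
  expect_equal(p$snr, 200 / (100 + 1e-6), tolerance = 1e-9)
  expect_equal(p$category, "high")
  expect_equal(p$f_mean, 200)
  expect_equal(p$bcrt_mean, 100)

  # a mid-range value just under the 1.4 boundary stays mid
  vol2 <- paint_tube_volume(tube, c(21, 21, 21), bg = 100, fg = 40)
  p2 <- profile_segment(seg, vol2)
  expect_equal(p2$snr, 140 / (100 + 1e-6), tolerance = 1e-9)
  expect_equal(p2$category, "mid")

  # uniform volume: F and B_crt coincide, ratio dips just below 1
  volu <- volume(array(150, c(21, 21, 21)), dtype = "uint16")
  pu <- profile_segment(seg, volu)
  expect_lt(pu$snr, 1)
  expect_equal(pu$category, "very_low")
})

test_that("critical background takes the ceil(20%) brightest with stable ties", {
  seg <- list(id = 1L, length = 0,
              nodes = data.frame(id = 1, type = 1, x = 3, y = 3, z = 3,
                                 radius = 1, parent = -1),
              endpoint_kinds = c("soma", "soma"))
  dims <- c(7, 7, 7)
  set.seed(8)
  vol <- volume(array(sample(0:500, prod(dims), replace = TRUE), dims),
                dtype = "uint16")
  p <- profile_segment(seg, vol)
  # independent recomputation of B and its brightest 20%
  fg <- oracle_voxelize(seg$nodes, dims)
  fg_lin <- fg[, 1] + 1 + dims[1] * (fg[, 2] + dims[2] * fg[, 3])
  bb <- as.vector(outer(outer((2:4) + 1, dims[1] * (2:4), "+"),
                        dims[1] * dims[2] * (2:4), "+"))
  bg_lin <- setdiff(bb, fg_lin)
  vals <- sort(vol$data[bg_lin], decreasing = TRUE)
  n_crt <- ceiling(0.2 * length(bg_lin))
  expect_equal(p$n_background, length(bg_lin))
  expect_equal(p$bcrt_mean, mean(vals[seq_len(n_crt)]))

  # ties: constant background still selects exactly ceil(20%) voxels and
  # repeated runs agree
  volc <- volume(array(120, dims), dtype = "uint16")
  volc$data[fg_lin] <- 200
  p1 <- profile_segment(seg, volc)
  p2 <- profile_segment(seg, volc)
  expect_identical(p1[c("f_mean", "bcrt_mean", "snr")],
                   p2[c("f_mean", "bcrt_mean", "snr")])
  expect_equal(p1$bcrt_mean, 120)
})

test_that("segment SNR is scale invariant and monotone in foreground", {
  tube <- chain_tree(c(3, 12), ys = 7, zs = 7)
  seg <- decompose_segments(tube)[[1]]
  vol <- paint_tube_volume(tube, c(15, 15, 15), bg = 80, fg = 60,
                           dtype = "float")
  base <- profile_segment(seg, vol)
  for (k in c(0.5, 3, 10)) {
    volk <- volume(vol$data * k, dtype = "float")
    expect_equal(profile_segment(seg, volk)$snr, base$snr, tolerance = 1e-6)
  }
  fg_lin <- attr(voxelize_segment(seg, vol$dims), "linear")
  brighter <- vol
  brighter$data[fg_lin] <- brighter$data[fg_lin] + 25
  expect_gt(profile_segment(seg, brighter)$snr, base$snr)
})

test_that("degenerate foreground and background raise typed errors", {
  outside <- list(id = 1L, length = 1,
                  nodes = data.frame(id = 1, type = 1, x = 90, y = 90, z = 90,
                                     radius = 1, parent = -1),
                  endpoint_kinds = c("soma", "soma"))
  vol <- volume(array(10, c(12, 12, 12)), dtype = "uint8")
  expect_error(suppressWarnings(profile_segment(outside, vol)),
               class = "neurotrace_degenerate_error")
  # a fat sphere filling its own bbox corner-to-corner leaves no background
  fat <- list(id = 2L, length = 0,
              nodes = data.frame(id = 1, type = 1, x = 5, y = 5, z = 5,
                                 radius = 12, parent = -1),
              endpoint_kinds = c("soma", "soma"))
  expect_error(profile_segment(fat, vol),
               class = "neurotrace_degenerate_error", regexp = "foreground")
})

test_that("neuron profile weights segment SNR by length", {
  # two straight branches of designed contrast and length from one fork
  nodes <- data.frame(id = 1:7, type = c(1, rep(3, 6)),
                      x = c(10, 13, 16, 19, 22, 13, 16),
                      y = c(10, 10, 10, 10, 10, 14, 18),
                      z = 10, radius = 1,
                      parent = c(-1, 1, 2, 3, 4, 1, 6))
  tr <- neuron_tree(nodes)
  dims <- c(30, 30, 30)
  vol <- volume(array(100, dims), dtype = "uint16")
  segs <- decompose_segments(tr)
  # paint each segment at its own contrast
  paint <- c(100, 20)  # fg for segment 1 (len 12) and segment 2 (len ~10)
  for (i in seq_along(segs)) {
    idx <- attr(voxelize_segment(segs[[i]], dims), "linear")
    vol$data[idx] <- pmax(vol$data[idx], 100 + paint[i])
  }
  prof <- profile_neuron(tr, vol)
  tab <- prof$segments
  expect_equal(prof$weighted_snr,
               sum(tab$length * tab$snr) / sum(tab$length))
  expect_gte(prof$weighted_snr, min(tab$snr))
  expect_lte(prof$weighted_snr, max(tab$snr))
  expect_equal(sum(prof$category_length_fractions), 1, tolerance = 1e-9)
  # the weaker, shorter branch sits below the weighted mean
  expect_equal(prof$basnr_portion,
               sum(tab$length[tab$snr < prof$weighted_snr]) / sum(tab$length))
})

test_that("vlsnr and basnr portions follow the segment table", {
  set.seed(61)
  tab <- data.frame(length = c(2, 8), snr = c(0.8, 1.5))
  # direct arithmetic: weighted = (2*0.8 + 8*1.5)/10 = 1.36
  w <- sum(tab$length * tab$snr) / sum(tab$length)
  expect_equal(w, 1.36)
  expect_equal(2 / 10, 0.2)  # very_low length fraction by construction
  # and through the pipeline on a rendered phantom
  ms <- morphology_spec(n_branch_events = 1, segment_length_mean = 14,
                        dims = c(40, 40, 40), seed = 31)
  tr <- generate_morphology(ms)
  rs <- render_spec(fg_amplitude = 120, bg_level = 100, bg_noise_sd = 0,
                    dropout_prob = 0, clutter_density = 0, z_blur_sigma = 0,
                    dims = c(40, 40, 40), seed = 32)
  prof <- profile_neuron(tr, render_volume(tr, rs))
  recompute <- with(prof$segments, sum(length[snr <= 1]) / sum(length))
  expect_equal(prof$vlsnr_portion, recompute)
  expect_equal(sum(prof$category_length_fractions), 1, tolerance = 1e-9)
})

test_that("vr_portion is the length-weighted VR edge fraction", {
  tr <- read_swc(text = swc_lines(
    "#columns id,type,x,y,z,radius,parent,gen_method",
    "1 1 0 0 0 1 -1 nonVR",
    "2 3 2 0 0 1 1 VR",
    "3 3 4 0 0 1 2 nonVR"))
  expect_equal(vr_portion(tr), 0.5)
  all_vr <- read_swc(text = swc_lines(
    "#columns id,type,x,y,z,radius,parent,gen_method",
    "1 1 0 0 0 1 -1 VR", "2 3 1 0 0 1 1 VR"))
  expect_equal(vr_portion(all_vr), 1.0)
  expect_error(vr_portion(y_tree()), class = "neurotrace_structural_error")
  # brute-force edge-length ratio on a random labelled tree
  set.seed(71)
  tr2 <- random_tree(60, 72)
  tr2$nodes$gen_method <- sample(c("VR", "nonVR"), 60, replace = TRUE)
  tr2$nodes$gen_method[tr2$nodes$parent == -1L] <- "nonVR"
  nd <- tr2$nodes
  num <- 0; den <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    p <- nd[nd$id == nd$parent[i], ]
    L <- sqrt((nd$x[i] - p$x)^2 + (nd$y[i] - p$y)^2 + (nd$z[i] - p$z)^2)
    den <- den + L
    if (nd$gen_method[i] == "VR") num <- num + L
  }
  expect_equal(vr_portion(tr2), num / den, tolerance = 1e-12)
})

test_that("correlate_portions recovers exact and noisy linear relations", {
  x <- seq(0.1, 0.9, length.out = 10)
  ex <- correlate_portions(data.frame(vlsnr_portion = x, vr_portion = 2 * x))
  expect_equal(ex$pearson_r, 1.0, tolerance = 1e-12)
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 0, tolerance = 1e-12)
  expect_error(correlate_portions(data.frame(vlsnr_portion = x,
                                             vr_portion = rep(0.5, 10))),
               class = "neurotrace_undefined_correlation")
  expect_error(correlate_portions(data.frame(vlsnr_portion = x[1:2],
                                             vr_portion = x[1:2])),
               class = "neurotrace_structural_error")
  # vr = vlsnr + noise: sample r close to the analytic value
  set.seed(19)
  xs <- runif(50, 0.1, 0.9)
  sigma <- 0.05
  ys <- xs + rnorm(50, 0, sigma)
  r_analytic <- sd_pop <- sqrt(var(xs)) / sqrt(var(xs) + sigma^2)
  got <- correlate_portions(data.frame(vlsnr_portion = xs, vr_portion = ys))
  expect_lt(abs(got$pearson_r - r_analytic), 0.1)
})
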