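# Per-segment and per-neuron image-quality profiling.
#
# For each neurite segment the foreground F is the set of voxels enclosed
# within the (interpolated) radius of the reconstructed tube, the
# background B is the segment's bounding box minus F, and the critical
# background B_crt is the brightest 20% of B — a conservative estimate of
# the local noise floor that an annotator actually competes against. The
# segment SNR is mean(F) / (mean(B_crt) + epsilon).

#' SNR profiling configuration
#'
#' @param epsilon Small positive stabiliser added to the critical-background
#'   mean (keeps the ratio finite on empty background); default `1e-6`.
#' @param bcrt_fraction Fraction of the brightest background voxels forming
#'   the critical background; default 0.2 (the "20% brightest" rule). The
#'   count is `ceiling(bcrt_fraction * |B|)`, minimum 1, with ties broken
#'   by ascending linear voxel index after descending intensity so repeated
#'   profiling selects identical voxel sets.
#' @param bbox_margin Extra voxels added around the segment bounding box
#'   before taking the background; default 0.
#' @param thresholds Strictly increasing category boundaries; default
#'   `c(1.0, 1.2, 1.4)`. Intervals are right-closed: very_low (-Inf, 1.0],
#'   low (1.0, 1.2], mid (1.2, 1.4], high (1.4, Inf).
#' @return An object of class `snr_config`.
#' @export
snr_config <- function(epsilon = 1e-6, bcrt_fraction = 0.2,
                       bbox_margin = 0L, thresholds = c(1.0, 1.2, 1.4)) {
  if (epsilon <= 0) stop_structural("epsilon must be positive")
  if (bcrt_fraction <= 0 || bcrt_fraction > 1) {
    stop_structural("bcrt_fraction must be in (0, 1]")
  }
  if (bbox_margin < 0) stop_structural("bbox_margin must be non-negative")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    stop_structural("thresholds must be three strictly increasing values")
  }
  structure(list(epsilon = epsilon, bcrt_fraction = bcrt_fraction,
                 bbox_margin = as.integer(bbox_margin),
                 thresholds = as.numeric(thresholds)),
            class = "snr_config")
}

SNR_CATEGORIES <- c("very_low", "low", "mid", "high")

#' Classify an SNR value into the four quality ranges
#'
#' Ranges are right-closed at each threshold: with the defaults, very_low
#' is (-Inf, 1.0], low is (1.0, 1.2], mid is (1.2, 1.4] and high is
#' (1.4, Inf).
#'
#' @param snr Finite numeric vector of SNR values.
#' @param cfg An [snr_config()].
#' @return Character vector over `"very_low"`, `"low"`, `"mid"`, `"high"`.
#' @export
categorize_snr <- function(snr, cfg = snr_config()) {
  if (any(!is.finite(snr))) stop_structural("SNR values must be finite")
  idx <- findInterval(snr, cfg$thresholds, left.open = TRUE) + 1L
  SNR_CATEGORIES[idx]
}

#' Profile the image SNR of one neurite segment
#'
#' Extracts foreground, background and critical background from the volume
#' and computes the segment SNR. Segments clipped by the volume border are
#' profiled on their in-bounds part (flagged `clipped`); a segment with no
#' in-bounds foreground voxel, or whose bounding box is entirely
#' foreground, raises a degenerate-profile error.
#'
#' @param segment A `neuron_segment` in voxel coordinates.
#' @param vol The underlying [volume()].
#' @param cfg An [snr_config()].
#' @param exclude Optional extra 1-based linear voxel indices removed from
#'   the background (used by [profile_neuron()] to keep the neuron's own
#'   signal in neighbouring segments out of a segment's noise estimate).
#' @return An object of class `segment_snr`: `segment_id`, `f_mean`,
#'   `bcrt_mean`, `snr`, `category`, `length`, `n_foreground`,
#'   `n_background`, `clipped`.
#' @export
profile_segment <- function(segment, vol, cfg = snr_config(),
                            exclude = NULL) {
  dims <- vol$dims
  fg <- suppressWarnings(voxelize_segment(segment, dims))
  fg_lin <- attr(fg, "linear")
  if (length(fg_lin) == 0) {
    stop_degenerate("segment ", segment$id,
                    ": no foreground voxel inside the volume")
  }
  bb <- segment_bbox(segment, margin = cfg$bbox_margin)
  clipped <- any(bb$origin < 0) || any(bb$origin + bb$shape > dims)
  cb <- clip_roi(bb, dims)
  lin_box <- box_linear_indices(cb, dims)
  bg_lin <- setdiff(lin_box, fg_lin)
  if (!is.null(exclude)) bg_lin <- setdiff(bg_lin, exclude)
  if (length(bg_lin) == 0) {
    stop_degenerate("segment ", segment$id,
                    ": bounding box is entirely foreground")
  }
  inten <- as.numeric(vol$data[bg_lin])
  n_crt <- max(1L, as.integer(ceiling(cfg$bcrt_fraction * length(bg_lin))))
  # brightest first; ties resolved by ascending linear voxel index
  ord <- order(-inten, bg_lin)
  crt <- inten[ord[seq_len(n_crt)]]
  f_mean <- mean(as.numeric(vol$data[fg_lin]))
  bcrt_mean <- mean(crt)
  snr <- f_mean / (bcrt_mean + cfg$epsilon)
  structure(list(segment_id = segment$id, f_mean = f_mean,
                 bcrt_mean = bcrt_mean, snr = snr,
                 category = categorize_snr(snr, cfg),
                 length = segment$length,
                 endpoint_kinds = segment$endpoint_kinds,
                 n_foreground = length(fg_lin),
                 n_background = length(bg_lin), clipped = clipped),
            class = "segment_snr")
}

# 1-based linear indices of every voxel in a clipped roi
box_linear_indices <- function(r, dims) {
  zz <- r$origin[1]:(r$origin[1] + r$shape[1] - 1L)
  yy <- r$origin[2]:(r$origin[2] + r$shape[2] - 1L)
  xx <- r$origin[3]:(r$origin[3] + r$shape[3] - 1L)
  as.integer(outer(outer(zz + 1L, dims[1] * yy, "+"),
                   dims[1] * dims[2] * xx, "+"))
}

#' Profile the image SNR of a whole neuron
#'
#' Decomposes the neuron into segments, profiles each against the volume
#' and summarises: the neuron SNR is the segment-wise SNR averaged with
#' each segment weighted by its length; `vlsnr_portion` is the length
#' fraction falling in the very-low range; `basnr_portion` is the length
#' fraction of segments whose SNR lies below the neuron's own
#' length-weighted SNR (the "below average SNR" reference is the weighted
#' neuron SNR). Degenerate segments are excluded from the summaries and
#' reported in `skipped`. Every segment's background excludes the
#' foreground of the whole neuron, not only the segment's own tube, so a
#' bright sibling neurite crossing a bounding box is never mistaken for
#' background noise.
#'
#' @param tree A single-root `neuron_tree` in voxel coordinates.
#' @param vol The underlying [volume()].
#' @param cfg An [snr_config()].
#' @param count_weighted Use unweighted (per-segment) averaging instead of
#'   length weighting for the summaries.
#' @return An object of class `neuron_snr_profile`: `segments` (data
#'   frame), `weighted_snr`, `category_length_fractions`, `vlsnr_portion`,
#'   `basnr_portion`, `vr_portion` (`NA` unless `gen_method` labels are
#'   present), `skipped`.
#' @export
profile_neuron <- function(tree, vol, cfg = snr_config(),
                           count_weighted = FALSE) {
  segs <- decompose_segments(tree)
  neuron_fg <- sort(unique(unlist(lapply(segs, function(s) {
    attr(suppressWarnings(voxelize_segment(s, vol$dims)), "linear")
  }))))
  records <- list()
  skipped <- list()
  for (s in segs) {
    rec <- tryCatch(profile_segment(s, vol, cfg, exclude = neuron_fg),
                    neurotrace_degenerate_error = function(e) e)
    if (inherits(rec, "segment_snr")) records[[length(records) + 1L]] <- rec
    else skipped[[length(skipped) + 1L]] <- list(segment_id = s$id,
                                                 reason = conditionMessage(rec))
  }
  if (length(records) == 0) {
    stop_degenerate("no profilable segment in this neuron/volume pair")
  }
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(segment_id = r$segment_id, length = r$length,
               f_mean = r$f_mean, bcrt_mean = r$bcrt_mean, snr = r$snr,
               category = r$category, n_foreground = r$n_foreground,
               n_background = r$n_background, clipped = r$clipped,
               start_kind = r$endpoint_kinds[1], end_kind = r$endpoint_kinds[2],
               stringsAsFactors = FALSE)
  }))
  w <- if (count_weighted) rep(1, nrow(tab)) else tab$length
  if (sum(w) <= 0) w <- rep(1, nrow(tab))  # all-zero-length edge case
  weighted_snr <- sum(w * tab$snr) / sum(w)
  frac <- vapply(SNR_CATEGORIES,
                 function(cc) sum(w[tab$category == cc]) / sum(w), numeric(1))
  vr <- tryCatch(vr_portion(tree), error = function(e) NA_real_)
  structure(list(segments = tab, weighted_snr = weighted_snr,
                 category_length_fractions = frac,
                 vlsnr_portion = unname(frac["very_low"]),
                 basnr_portion = sum(w[tab$snr < weighted_snr]) / sum(w),
                 vr_portion = vr, skipped = skipped, config = cfg),
            class = "neuron_snr_profile")
}

#' @export
print.neuron_snr_profile <- function(x, ...) {
  cat(sprintf("<neuron_snr_profile> %d segment(s), weighted SNR %.4f\n",
              nrow(x$segments), x$weighted_snr))
  cat(sprintf("  length fractions: very_low %.3f | low %.3f | mid %.3f | high %.3f\n",
              x$category_length_fractions[1], x$category_length_fractions[2],
              x$category_length_fractions[3], x$category_length_fractions[4]))
  cat(sprintf("  VLSNR portion %.3f, BASNR portion %.3f", x$vlsnr_portion,
              x$basnr_portion))
  if (is.finite(x$vr_portion)) cat(sprintf(", VR portion %.3f", x$vr_portion))
  cat("\n")
  if (length(x$skipped) > 0) {
    cat("  skipped", length(x$skipped), "degenerate segment(s)\n")
  }
  invisible(x)
}

#' Length-weighted fraction of a neuron reconstructed in VR
#'
#' Each parent-child edge is attributed to its child node's `gen_method`
#' label (`"VR"` or `"nonVR"`); the VR portion is the summed length of
#' VR edges divided by the total length.
#'
#' @param tree A `neuron_tree` whose non-root nodes carry a `gen_method`
#'   label.
#' @return Scalar in \[0, 1\].
#' @export
vr_portion <- function(tree) {
  nd <- tree$nodes
  if (!"gen_method" %in% names(nd)) {
    stop_structural("tree has no gen_method labels")
  }
  has_par <- nd$parent != -1L
  gm <- nd$gen_method[has_par]
  bad <- is.na(gm) | !(gm %in% c("VR", "nonVR"))
  if (any(bad)) {
    stop_structural("missing/invalid gen_method label on node(s): ",
                    paste(utils::head(nd$id[has_par][bad], 10), collapse = ", "))
  }
  pi <- match(nd$parent[has_par], nd$id)
  len <- sqrt((nd$x[has_par] - nd$x[pi])^2 + (nd$y[has_par] - nd$y[pi])^2 +
              (nd$z[has_par] - nd$z[pi])^2)
  if (sum(len) == 0) return(mean(gm == "VR"))
  sum(len[gm == "VR"]) / sum(len)
}

#' Correlate VR usage with very-low-SNR portion across neurons
#'
#' Pearson correlation and the least-squares line of VR portion (y) on
#' VLSNR portion (x) over a set of neurons, as used to ask whether VR-mode
#' tracing concentrates in low-quality image regions.
#'
#' @param records Data frame with columns `vr_portion` and `vlsnr_portion`
#'   (or any two-column numeric data frame taken as x = first, y = second
#'   when the named columns are absent).
#' @return List with `pearson_r`, `slope`, `intercept`, `n`.
#' @export
correlate_portions <- function(records) {
  records <- as.data.frame(records)
  if (all(c("vlsnr_portion", "vr_portion") %in% names(records))) {
    x <- records$vlsnr_portion; y <- records$vr_portion
  } else {
    x <- records[[1]]; y <- records[[2]]
  }
  if (length(x) < 3) stop_structural("need at least 3 records")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_structural("non-finite portion values")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_typed("neurotrace_undefined_correlation",
               "correlation undefined: zero variance in x or y")
  }
  fit <- stats::lm(y ~ x)
  list(pearson_r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x))
}

#' Write a per-segment profile table and neuron summary
#'
#' @param profile A `neuron_snr_profile`.
#' @param tsv_path Tab-separated per-segment table (one row per segment).
#' @param json_path Optional JSON neuron-level summary.
#' @return `tsv_path`, invisibly.
#' @export
write_profile <- function(profile, tsv_path, json_path = NULL) {
  utils::write.table(profile$segments, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- list(weighted_snr = profile$weighted_snr,
                 category_length_fractions = as.list(profile$category_length_fractions),
                 vlsnr_portion = profile$vlsnr_portion,
                 basnr_portion = profile$basnr_portion,
                 vr_portion = if (is.finite(profile$vr_portion))
                   profile$vr_portion else NULL,
                 n_segments = nrow(profile$segments),
                 n_skipped = length(profile$skipped))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tsv_path)
}
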