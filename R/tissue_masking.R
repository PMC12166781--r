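#' Tissue-masking configuration
#'
#' Parameters of the tissue-detection stage. Defaults follow the pipeline's
#' published rules: black scan-edge pixels (all channels below 20 on the
#' 8-bit scale) are whitened before thresholding; the Otsu threshold is
#' capped by a fixed upper bound so near-white slides cannot push the
#' threshold into the background; a 32 x 32 low-resolution tile is a tissue
#' patch when strictly more than 60 % of its sixteen 8 x 8 sub-patches each
#' contain at least five tissue pixels; at most 500 tissue patches per
#' slide are used for training.
#'
#' @param black_edge_cutoff per-channel 8-bit cutoff below which a pixel
#'   counts as scan-edge black (all three channels must be below it).
#' @param otsu_upper_bound cap applied to the Otsu threshold (0..255). The
#'   published rule states that a fixed upper bound exists without giving
#'   its value; the default 220 excludes near-white background.
#' @param subpatch_px sub-patch edge length at low resolution.
#' @param min_tissue_px_per_subpatch minimum tissue pixels for a sub-patch
#'   to count as tissue (inclusive).
#' @param min_coverage_fraction fraction of tissue sub-patches a tile must
#'   strictly exceed to qualify.
#' @param training_patch_cap maximum number of patches sampled per slide
#'   for training.
#' @param rng_seed seed for the training-patch subsample.
#' @return object of class `masking_config`.
#' @export
masking_config <- function(black_edge_cutoff = 20,
                           otsu_upper_bound = 220,
                           subpatch_px = 8L,
                           min_tissue_px_per_subpatch = 5L,
                           min_coverage_fraction = 0.60,
                           training_patch_cap = 500L,
                           rng_seed = 0L) {
  stopifnot(
    black_edge_cutoff > 0, otsu_upper_bound > 0, otsu_upper_bound <= 255,
    subpatch_px > 0, min_tissue_px_per_subpatch > 0,
    min_coverage_fraction > 0, min_coverage_fraction < 1,
    training_patch_cap > 0
  )
  structure(
    list(
      black_edge_cutoff = black_edge_cutoff,
      otsu_upper_bound = otsu_upper_bound,
      subpatch_px = as.integer(subpatch_px),
      min_tissue_px_per_subpatch = as.integer(min_tissue_px_per_subpatch),
      min_coverage_fraction = min_coverage_fraction,
      training_patch_cap = as.integer(training_patch_cap),
      rng_seed = as.integer(rng_seed)
    ),
    class = "masking_config"
  )
}

#' Downscale an RGB image by block averaging
#'
#' Used to bring a working-resolution slide to the 1/16 resolution at which
#' tissue thresholding operates. Edge blocks smaller than `factor` are
#' averaged over their actual extent, so output dimensions are
#' `ceiling(dim / factor)`.
#'
#' @param img RGB array `H x W x 3` (0..255) or a single-channel matrix.
#' @param factor positive integer downscale factor (default 16).
#' @return array/matrix of dimensions `ceiling(dim(img)[1:2] / factor)`.
#' @export
downscale_image <- function(img, factor = 16L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  block_mean <- function(m) {
    gi <- (seq_len(nrow(m)) - 1L) %/% factor
    m <- rowsum(m, gi) / as.vector(table(gi))
    gj <- (seq_len(ncol(m)) - 1L) %/% factor
    t(rowsum(t(m), gj) / as.vector(table(gj)))
  }
  if (is.matrix(img)) return(block_mean(img))
  stopifnot_rgb(img)
  out <- lapply(1:3, function(k) block_mean(img[, , k]))
  array(unlist(out), dim = c(dim(out[[1]]), 3L))
}

#' Prepare the single-channel raster used for tissue thresholding
#'
#' Black scan-edge pixels (all three channels strictly below
#' `cfg$black_edge_cutoff`) are replaced by white, then the image is
#' reduced to one channel: PD-L1 slides are converted to grayscale
#' (ITU-R BT.601 luma); H&E slides are deconvolved to HED space and the
#' eosin density is used alone, mapped so that stain-rich pixels are dark
#' and stain-free background is bright (the polarity the thresholding step
#' assumes), and min-max rescaled to `[0, 255]`.
#'
#' @param img RGB array `H x W x 3` (0..255) at the thresholding (1/16)
#'   resolution.
#' @param stain_kind `"pdl1"` or `"he"`.
#' @param cfg a [masking_config()].
#' @return numeric matrix in `[0, 255]`; low values indicate tissue.
#' @export
prepare_threshold_channel <- function(img, stain_kind = c("pdl1", "he"),
                                      cfg = masking_config()) {
  stopifnot_rgb(img)
  stain_kind <- match.arg(stain_kind)
  black <- img[, , 1] < cfg$black_edge_cutoff &
    img[, , 2] < cfg$black_edge_cutoff &
    img[, , 3] < cfg$black_edge_cutoff
  if (any(black)) {
    for (k in 1:3) {
      ch <- img[, , k]
      ch[black] <- 255
      img[, , k] <- ch
    }
  }
  if (stain_kind == "pdl1") {
    luma(img)
  } else {
    e <- rgb_to_hed(img)[, , 2]
    rng <- range(e)
    if (diff(rng) == 0) {
      matrix(255, nrow(e), ncol(e))
    } else {
      255 - 255 * (e - rng[1]) / diff(rng)
    }
  }
}

#' Otsu-threshold a channel into a binary tissue mask
#'
#' The threshold is `min(otsu(channel), cfg$otsu_upper_bound)`; pixels
#' strictly below it (darker than the white background) are tissue. A
#' constant channel has no Otsu threshold: the function warns and returns
#' an empty mask with the upper bound recorded as the threshold applied.
#'
#' @param channel numeric matrix in `[0, 255]` from
#'   [prepare_threshold_channel()].
#' @param cfg a [masking_config()].
#' @return list with `mask` (logical matrix, `TRUE` = tissue) and
#'   `threshold_used` (the threshold actually applied).
#' @export
compute_tissue_mask <- function(channel, cfg = masking_config()) {
  stopifnot(is.matrix(channel))
  if (diff(range(channel)) == 0) {
    warning("constant channel: Otsu threshold undefined, returning empty mask")
    return(list(
      mask = matrix(FALSE, nrow(channel), ncol(channel)),
      threshold_used = cfg$otsu_upper_bound
    ))
  }
  t_otsu <- 255 * EBImage::otsu(EBImage::Image(channel / 255),
                                range = c(0, 1), levels = 256L)
  thr <- min(t_otsu, cfg$otsu_upper_bound)
  list(mask = channel < thr, threshold_used = thr)
}

#' Enumerate tissue patches from a low-resolution mask
#'
#' Tiles the mask into non-overlapping 32 x 32 tiles (partial border tiles
#' are discarded), splits each tile into sixteen 8 x 8 sub-patches, and
#' keeps a tile when strictly more than `min_coverage_fraction` of its
#' sub-patches each contain at least `min_tissue_px_per_subpatch` tissue
#' pixels. Kept tile origins are scaled by 16 back to working resolution.
#'
#' @param grid_mask logical matrix at 1/16 resolution (`TRUE` = tissue).
#' @param cfg a [masking_config()].
#' @return data frame with 0-based working-resolution columns `row`, `col`
#'   (top-left corners of 512 x 512 patches), in row-major tile order.
#' @export
enumerate_tissue_patches <- function(grid_mask, cfg = masking_config()) {
  stopifnot(is.matrix(grid_mask))
  s <- cfg$subpatch_px                  # 8 px sub-patch
  tile <- 4L * s                        # 32 px tile, 16 sub-patches
  n_tr <- nrow(grid_mask) %/% tile
  n_tc <- ncol(grid_mask) %/% tile
  if (n_tr == 0L || n_tc == 0L) {
    return(data.frame(row = integer(0), col = integer(0)))
  }
  m <- grid_mask[seq_len(n_tr * tile), seq_len(n_tc * tile), drop = FALSE] * 1
  # tissue-pixel count per 8x8 sub-patch
  gi <- (seq_len(nrow(m)) - 1L) %/% s
  m8 <- rowsum(m, gi)
  gj <- (seq_len(ncol(m)) - 1L) %/% s
  m8 <- t(rowsum(t(m8), gj))
  sub_ok <- (m8 >= cfg$min_tissue_px_per_subpatch) * 1
  # tissue sub-patch count per 32x32 tile (4x4 sub-patches)
  gi4 <- (seq_len(nrow(sub_ok)) - 1L) %/% 4L
  t16 <- rowsum(sub_ok, gi4)
  gj4 <- (seq_len(ncol(sub_ok)) - 1L) %/% 4L
  t16 <- t(rowsum(t(t16), gj4))
  keep <- which(t(t16) / 16 > cfg$min_coverage_fraction)  # row-major order
  if (length(keep) == 0L) {
    return(data.frame(row = integer(0), col = integer(0)))
  }
  ti <- (keep - 1L) %/% n_tc            # 0-based tile row
  tj <- (keep - 1L) %% n_tc             # 0-based tile col
  data.frame(row = ti * tile * 16L, col = tj * tile * 16L)
}

#' Combine the tissue masks of paired stains
#'
#' Elementwise logical AND, used when a patch grid must lie in tissue on
#' both slides of an H&E / PD-L1 pair.
#'
#' @param mask_a,mask_b logical matrices of equal dimensions.
#' @return logical matrix.
#' @export
combine_overlap_mask <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask dimensions differ: ", paste(dim(mask_a), collapse = "x"),
         " vs ", paste(dim(mask_b), collapse = "x"), call. = FALSE)
  }
  mask_a & mask_b
}

#' Subsample tissue patches for training
#'
#' Slides with more than `cfg$training_patch_cap` tissue patches contribute
#' a uniform random subset of exactly that many (without replacement,
#' reproducible under `cfg$rng_seed`); slides with fewer contribute all.
#'
#' @param locs data frame of patch locations (rows are patches).
#' @param cfg a [masking_config()].
#' @return data frame with at most `training_patch_cap` rows, in the
#'   original row order.
#' @export
sample_training_patches <- function(locs, cfg = masking_config()) {
  n <- nrow(locs)
  if (n <= cfg$training_patch_cap) return(locs)
  idx <- with_seed(cfg$rng_seed, sample.int(n, cfg$training_patch_cap))
  locs[sort(idx), , drop = FALSE]
}

#' Full tissue-masking stage for one slide
#'
#' Downscales a working-resolution slide by 16, prepares the stain-specific
#' thresholding channel, computes the capped-Otsu tissue mask, and
#' enumerates candidate 512 x 512 tissue patches.
#'
#' @param img RGB array `H x W x 3` (0..255) at working resolution.
#' @param stain_kind `"pdl1"` or `"he"`.
#' @param cfg a [masking_config()].
#' @return object of class `tissue_grid`: list with `mask` (lowres logical
#'   matrix), `threshold_used`, `patch_locations` (data frame `row`, `col`,
#'   working-resolution 0-based), `patch_size_px` (512) and
#'   `step_lowres_px` (32).
#' @export
tissue_grid <- function(img, stain_kind = c("pdl1", "he"),
                        cfg = masking_config()) {
  stain_kind <- match.arg(stain_kind)
  low <- downscale_image(img, 16L)
  channel <- prepare_threshold_channel(low, stain_kind, cfg)
  tm <- compute_tissue_mask(channel, cfg)
  structure(
    list(
      mask = tm$mask,
      threshold_used = tm$threshold_used,
      patch_locations = enumerate_tissue_patches(tm$mask, cfg),
      patch_size_px = 512L,
      step_lowres_px = 32L
    ),
    class = "tissue_grid"
  )
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("tissue_grid:", nrow(x$patch_locations), "tissue patches,",
      "threshold", format(x$threshold_used, digits = 4),
      sprintf("(lowres mask %d x %d)\n", nrow(x$mask), ncol(x$mask)))
  invisible(x)
}
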