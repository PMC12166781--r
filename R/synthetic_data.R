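#' Specification of a synthetic IHC slide
#'
#' Describes a synthetic PD-L1-stained mini-slide with known ground
#' truth: pale-pink tissue blobs on a white background, tumor regions as
#' 512-px-grid-aligned rectangles with a distinct tint, dark blue-purple
#' elliptical nuclei, a brown DAB-like membrane ring around PD-L1
#' positive tumor cells, smaller and darker nuclei for other cells, and
#' an optional black scan-edge band. Tumor regions are snapped to the
#' patch grid so every tumor cell lies in a patch of tumor fraction 1,
#' which makes ground-truth bookkeeping exact. Cell-type counts realize
#' `true_tps` exactly by construction
#' (`TC+ = round(true_tps/100 * n_tumor_cells)`).
#'
#' @param canvas_size `c(H, W)` in working-resolution pixels.
#' @param n_tissue_blobs number of non-tumor tissue blobs.
#' @param blob_radius_range min/max blob radius in pixels.
#' @param tumor_fraction fraction of the slide's patch grid designated
#'   tumor (0 disables tumor entirely).
#' @param n_cells total number of cells to place.
#' @param true_tps target tumor proportion score in `[0, 100]`.
#' @param oc_fraction fraction of cells that are other (non-tumor) cells,
#'   placed anywhere in tissue.
#' @param nucleus_diameter_px mean tumor-nucleus diameter (other cells
#'   are drawn at 60 % of this).
#' @param min_spacing_diameters minimum center spacing between cells, in
#'   nucleus diameters (>= 1).
#' @param stain_jitter per-pixel intensity noise SD (8-bit counts).
#' @param black_edge logical; add a black scan-edge band.
#' @param black_edge_px band width in pixels.
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(canvas_size = c(1536L, 1536L),
                                 n_tissue_blobs = 2L,
                                 blob_radius_range = c(300, 420),
                                 tumor_fraction = 0.25,
                                 n_cells = 300L,
                                 true_tps = 30,
                                 oc_fraction = 0.3,
                                 nucleus_diameter_px = 15,
                                 min_spacing_diameters = 1.3,
                                 stain_jitter = 4,
                                 black_edge = FALSE,
                                 black_edge_px = 64L,
                                 rng_seed = 0L) {
  stopifnot(true_tps >= 0, true_tps <= 100, oc_fraction >= 0, oc_fraction <= 1,
            tumor_fraction >= 0, tumor_fraction <= 1, n_cells >= 0,
            min_spacing_diameters >= 1)
  structure(
    list(canvas_size = as.integer(canvas_size),
         n_tissue_blobs = as.integer(n_tissue_blobs),
         blob_radius_range = blob_radius_range,
         tumor_fraction = tumor_fraction, n_cells = as.integer(n_cells),
         true_tps = true_tps, oc_fraction = oc_fraction,
         nucleus_diameter_px = nucleus_diameter_px,
         min_spacing_diameters = min_spacing_diameters,
         stain_jitter = stain_jitter, black_edge = black_edge,
         black_edge_px = as.integer(black_edge_px),
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_slide_spec"
  )
}

# Palette (8-bit RGB). Chosen so that (a) tissue is far from white, so Otsu
# separates it; (b) tumor and non-tumor tissue are distinguishable by tint;
# (c) the brown DAB ring and the bluish nuclei have similar grayscale luma,
# reproducing the known failure mode of grayscale-based nucleus detection.
.syn_palette <- list(
  tissue = c(228, 203, 214),
  tumor_tissue = c(222, 190, 186),
  nucleus_tumor = c(72, 61, 139),
  nucleus_oc = c(38, 48, 100),
  dab_ring = c(130, 80, 42),
  black_edge = 8
)

# pixel set of a filled ellipse, as linear indices into an H x W matrix
.ellipse_pixels <- function(cx, cy, rx, ry, theta, h, w) {
  r_out <- ceiling(max(rx, ry))
  xs <- max(0L, floor(cx - r_out)):min(w - 1L, ceiling(cx + r_out))
  ys <- max(0L, floor(cy - r_out)):min(h - 1L, ceiling(cy + r_out))
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  px <- rep(xs, each = length(ys))[inside]
  py <- rep(ys, times = length(xs))[inside]
  (py + 1L) + px * h
}

#' Generate a synthetic slide with ground truth
#'
#' Renders the slide described by a [synthetic_slide_spec()] and returns
#' both the RGB image and the full ground truth. Cell centers are placed
#' by rejection sampling with a minimum spacing of
#' `min_spacing_diameters` nucleus diameters; if the requested cells do
#' not fit the available area the function errors.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return list with `image` (`H x W x 3`, 0..255) and `truth`, a list
#'   with `tissue_mask` (logical `H x W`), `tumor_mask`, `tumor_polygons`
#'   (x/y matrices), `tumor_tiles` (data frame `row`, `col`), `cells`
#'   (data frame `x`, `y`, `type`, `radius_px`), `cell_masks` (list of
#'   linear pixel indices, nucleus only), `counts` ([cell_counts()]) and
#'   `true_tps`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  with_seed(spec$rng_seed, {
    h <- spec$canvas_size[1]; w <- spec$canvas_size[2]
    n_tr <- h %/% 512L; n_tc <- w %/% 512L
    stopifnot(n_tr >= 1, n_tc >= 1)

    # --- tumor tiles (grid-aligned rectangles) ---
    n_tiles <- n_tr * n_tc
    n_tumor_tiles <- if (spec$tumor_fraction > 0) {
      max(1L, round(spec$tumor_fraction * n_tiles))
    } else 0L
    tile_idx <- if (n_tumor_tiles > 0) {
      sample.int(n_tiles, n_tumor_tiles)
    } else integer(0)
    tumor_tiles <- data.frame(
      row = ((tile_idx - 1L) %/% n_tc) * 512L,
      col = ((tile_idx - 1L) %% n_tc) * 512L
    )
    tumor_mask <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(tumor_tiles))) {
      r <- tumor_tiles$row[i]; c <- tumor_tiles$col[i]
      tumor_mask[(r + 1):(r + 512), (c + 1):(c + 512)] <- TRUE
    }
    tumor_polygons <- lapply(seq_len(nrow(tumor_tiles)), function(i) {
      r <- tumor_tiles$row[i]; c <- tumor_tiles$col[i]
      cbind(x = c(c, c + 511, c + 511, c),
            y = c(r, r, r + 511, r + 511))
    })

    # --- tissue mask: tumor rectangles + elliptical blobs ---
    tissue <- tumor_mask
    margin <- max(96L, spec$black_edge_px + 32L)
    for (b in seq_len(spec$n_tissue_blobs)) {
      r_b <- stats::runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
      cx <- stats::runif(1, margin + r_b, w - margin - r_b)
      cy <- stats::runif(1, margin + r_b, h - margin - r_b)
      tissue[.ellipse_pixels(cx, cy, r_b, r_b * stats::runif(1, 0.6, 1),
                             stats::runif(1, 0, pi), h, w)] <- TRUE
    }

    # --- paint the canvas (per-channel matrices, assembled at the end) ---
    pal <- .syn_palette
    non_tumor_tissue <- tissue & !tumor_mask
    chans <- lapply(1:3, function(k) {
      ch <- matrix(255, h, w)
      ch[non_tumor_tissue] <- pal$tissue[k]
      ch[tumor_mask] <- pal$tumor_tissue[k]
      ch
    })

    # --- cells ---
    n_oc <- round(spec$oc_fraction * spec$n_cells)
    n_tum <- spec$n_cells - n_oc
    if (n_tumor_tiles == 0L) {
      n_oc <- spec$n_cells
      n_tum <- 0L
    }
    n_pos <- if (n_tum > 0) round(spec$true_tps / 100 * n_tum) else 0L
    n_neg <- n_tum - n_pos
    d <- spec$nucleus_diameter_px
    min_sp2 <- (spec$min_spacing_diameters * d)^2
    ring_out <- d / 2 + 4

    types <- c(rep("TC+", n_pos), rep("TC-", n_neg), rep("OC", n_oc))
    # fast feasibility check: each cell occupies ~min_sp2 of area
    tumor_area <- n_tumor_tiles * 512^2
    if (n_tum * min_sp2 > tumor_area ||
        spec$n_cells * min_sp2 > sum(tissue) + 1) {
      stop("requested cells exceed the packable tissue area", call. = FALSE)
    }
    placed_x <- numeric(0); placed_y <- numeric(0)
    cells <- vector("list", length(types))
    for (i in seq_along(types)) {
      ty <- types[i]
      rad <- if (ty == "OC") 0.6 * d / 2 else d / 2
      rad <- rad * stats::runif(1, 0.9, 1.1)
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 2000L) {
          stop("requested cells exceed the packable tissue area",
               call. = FALSE)
        }
        if (ty == "OC") {
          x <- stats::runif(1, ring_out + 1, w - ring_out - 2)
          y <- stats::runif(1, ring_out + 1, h - ring_out - 2)
          reg_ok <- tissue[round(y) + 1, round(x) + 1] &&
            tissue[round(y - rad) + 1, round(x) + 1] &&
            tissue[round(y + rad) + 1, round(x) + 1] &&
            tissue[round(y) + 1, round(x - rad) + 1] &&
            tissue[round(y) + 1, round(x + rad) + 1]
        } else {
          # inside a tumor tile, ring fully contained
          ti <- sample.int(nrow(tumor_tiles), 1)
          x <- stats::runif(1, tumor_tiles$col[ti] + ring_out + 1,
                            tumor_tiles$col[ti] + 512 - ring_out - 2)
          y <- stats::runif(1, tumor_tiles$row[ti] + ring_out + 1,
                            tumor_tiles$row[ti] + 512 - ring_out - 2)
          reg_ok <- TRUE
        }
        if (reg_ok &&
            (length(placed_x) == 0 ||
             min((placed_x - x)^2 + (placed_y - y)^2) >= min_sp2)) break
      }
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      cells[[i]] <- list(x = x, y = y, type = ty, radius = rad)
    }

    cell_masks <- vector("list", length(cells))
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      ratio <- stats::runif(1, 0.8, 1)
      theta <- stats::runif(1, 0, pi)
      mask <- .ellipse_pixels(cl$x, cl$y, cl$radius, cl$radius * ratio,
                              theta, h, w)
      cell_masks[[i]] <- mask
      col_nuc <- if (cl$type == "OC") pal$nucleus_oc else pal$nucleus_tumor
      if (cl$type == "TC+") {
        ring <- setdiff(
          .ellipse_pixels(cl$x, cl$y, cl$radius + 4, cl$radius * ratio + 4,
                          theta, h, w),
          .ellipse_pixels(cl$x, cl$y, cl$radius - 1, cl$radius * ratio - 1,
                          theta, h, w)
        )
        for (k in 1:3) chans[[k]][ring] <- pal$dab_ring[k]
      }
      for (k in 1:3) chans[[k]][mask] <- col_nuc[k]
    }

    # --- stain jitter and black edge ---
    if (spec$stain_jitter > 0) {
      for (k in 1:3) {
        chans[[k]] <- clip(chans[[k]] +
                             matrix(stats::rnorm(h * w, sd = spec$stain_jitter),
                                    h, w), 0, 255)
      }
    }
    if (spec$black_edge) {
      b <- spec$black_edge_px
      for (k in 1:3) {
        chans[[k]][c(1:b, (h - b + 1):h), ] <- pal$black_edge
        chans[[k]][, c(1:b, (w - b + 1):w)] <- pal$black_edge
      }
    }
    img <- array(c(chans[[1]], chans[[2]], chans[[3]]), dim = c(h, w, 3))

    counts <- cell_counts(n_pos, n_neg, n_oc)
    list(
      image = img,
      truth = list(
        tissue_mask = tissue,
        tumor_mask = tumor_mask,
        tumor_polygons = tumor_polygons,
        tumor_tiles = tumor_tiles,
        cells = data.frame(
          x = vapply(cells, `[[`, numeric(1), "x"),
          y = vapply(cells, `[[`, numeric(1), "y"),
          type = vapply(cells, `[[`, character(1), "type"),
          radius_px = vapply(cells, `[[`, numeric(1), "radius")
        ),
        cell_masks = cell_masks,
        counts = counts,
        true_tps = compute_tps(counts)
      )
    )
  })
}

#' Export ground-truth annotations in the pipeline's input formats
#'
#' Writes tumor polygons as GeoJSON, cell point annotations as CSV
#' (`x,y,label`), the tissue mask as a 0/255 PNG, and a small JSON with
#' the true counts and TPS — exactly the formats the pipeline consumes.
#'
#' @param truth the `truth` element returned by [generate_slide()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
export_annotations <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_roi <- file.path(dir, "tumor_rois.geojson")
  p_cells <- file.path(dir, "cells.csv")
  p_mask <- file.path(dir, "tissue_mask.png")
  p_truth <- file.path(dir, "truth.json")
  write_rois_geojson(truth$tumor_polygons, p_roi)
  utils::write.csv(
    data.frame(x = truth$cells$x, y = truth$cells$y,
               label = truth$cells$type),
    p_cells, row.names = FALSE
  )
  write_image_png(truth$tissue_mask, p_mask)
  jsonlite::write_json(
    list(n_tcpos = truth$counts$n_tcpos, n_tcneg = truth$counts$n_tcneg,
         n_oc = truth$counts$n_oc, true_tps = truth$true_tps),
    p_truth, auto_unbox = TRUE, digits = NA
  )
  c(rois = p_roi, cells = p_cells, mask = p_mask, truth = p_truth)
}

#' Simulate pathologist TPS assessments
#'
#' Each rater's score is the true TPS plus an optional systematic bias
#' and Gaussian noise, clipped to `[0, 100]`. Bias rules model the
#' over-/under-scoring behaviours seen in practice (e.g. cytoplasmic
#' staining read as membranous) for configurable case subsets.
#'
#' @param true_tps numeric vector of true TPS values (one per patient).
#' @param n_raters number of simulated raters.
#' @param noise_sd SD of the Gaussian scoring noise (percentage points).
#' @param bias_rules optional data frame with columns `patient` (index
#'   into `true_tps`), `rater` (index, or `NA` for all raters) and `bias`
#'   (percentage points, positive = overscoring).
#' @param seed integer seed.
#' @return data frame `patient_id`, `rater_id`, `tps`.
#' @export
simulate_pathologists <- function(true_tps, n_raters = 3L, noise_sd = 5,
                                  bias_rules = NULL, seed = 0L) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    n <- length(true_tps)
    out <- expand.grid(patient_id = seq_len(n), rater_id = seq_len(n_raters))
    bias <- numeric(nrow(out))
    if (!is.null(bias_rules)) {
      for (i in seq_len(nrow(bias_rules))) {
        hit <- out$patient_id == bias_rules$patient[i] &
          (is.na(bias_rules$rater[i]) | out$rater_id == bias_rules$rater[i])
        bias[hit] <- bias[hit] + bias_rules$bias[i]
      }
    }
    out$tps <- clip(true_tps[out$patient_id] + bias +
                      stats::rnorm(nrow(out), 0, noise_sd), 0, 100)
    out
  })
}
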