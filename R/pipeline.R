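#' Ground-truth label helpers for synthetic slides
#'
#' `truth_tumor_label_map()` crops the per-pixel tumor labels (1 =
#' non-tumor, 2 = tumor) of a patch; `truth_type_code_map()` returns the
#' full-canvas cell-type codes (1 = TC+, 2 = TC-, 3 = OC, 4 =
#' background); `truth_cell_annotations()` lists the cell point marks
#' falling inside a patch in patch-local 0-based coordinates.
#'
#' @param truth the `truth` element of [generate_slide()].
#' @param row,col 0-based patch origin (working resolution).
#' @param size patch edge length.
#' @return see above.
#' @export
truth_tumor_label_map <- function(truth, row, col, size = 512L) {
  m <- truth$tumor_mask[(row + 1):(row + size), (col + 1):(col + size)]
  matrix(ifelse(m, 2L, 1L), size, size)
}

#' @rdname truth_tumor_label_map
#' @export
truth_type_code_map <- function(truth) {
  h <- nrow(truth$tissue_mask)
  w <- ncol(truth$tissue_mask)
  code <- matrix(4L, h, w)
  type_code <- match(truth$cells$type, CELL_CLASSES)
  for (i in seq_along(truth$cell_masks)) {
    code[truth$cell_masks[[i]]] <- type_code[i]
  }
  code
}

#' @rdname truth_tumor_label_map
#' @export
truth_cell_annotations <- function(truth, row, col, size = 512L) {
  inside <- truth$cells$y >= row & truth$cells$y < row + size &
    truth$cells$x >= col & truth$cells$x < col + size
  data.frame(
    x = pmin(pmax(round(truth$cells$x[inside]) - col, 0), size - 1),
    y = pmin(pmax(round(truth$cells$y[inside]) - row, 0), size - 1),
    label = truth$cells$type[inside]
  )
}

#' Ground-truth oracle backends
#'
#' Builds reference backends that emit the synthetic ground truth as
#' saturated one-hot raw scores (or as the true instance masks). They
#' satisfy the same contracts as the trained backends and are used to
#' validate the aggregation logic end-to-end: with oracle backends the
#' pipeline must recover the true TPS exactly.
#'
#' @param truth the `truth` element of [generate_slide()].
#' @return list with `tumor` (two-class pixel backend), `instance`
#'   (instance backend returning true nucleus masks for cells whose
#'   center lies in the patch) and `type` (four-class pixel backend).
#' @export
truth_oracle_backends <- function(truth) {
  h <- nrow(truth$tissue_mask)
  type_code <- truth_type_code_map(truth)
  tumor <- structure(list(tumor_mask = truth$tumor_mask),
                     class = c("oracle_tumor_backend", "pixel_backend"))
  type <- structure(list(type_code = type_code),
                    class = c("oracle_type_backend", "pixel_backend"))
  inst <- structure(list(cells = truth$cells, masks = truth$cell_masks,
                         canvas_h = h),
                    class = c("oracle_instance_backend", "instance_backend"))
  list(tumor = tumor, instance = inst, type = type)
}

#' @export
predict_pixel_scores.oracle_tumor_backend <- function(backend, patch, ...) {
  o <- attr(patch, "origin")
  stopifnot(!is.null(o))
  size <- dim(patch)[1]
  m <- backend$tumor_mask[(o[1] + 1):(o[1] + size), (o[2] + 1):(o[2] + size)]
  array(c(ifelse(m, -20, 20), ifelse(m, 20, -20)), dim = c(size, size, 2L))
}

#' @export
predict_pixel_scores.oracle_type_backend <- function(backend, patch, ...) {
  o <- attr(patch, "origin")
  stopifnot(!is.null(o))
  size <- dim(patch)[1]
  code <- backend$type_code[(o[1] + 1):(o[1] + size), (o[2] + 1):(o[2] + size)]
  out <- array(-20, dim = c(size, size, 4L))
  for (k in 1:4) {
    ch <- out[, , k]
    ch[code == k] <- 20
    out[, , k] <- ch
  }
  out
}

#' @export
detect_instances.oracle_instance_backend <- function(backend, patch, ...) {
  o <- attr(patch, "origin")
  stopifnot(!is.null(o))
  size <- dim(patch)[1]
  h <- backend$canvas_h
  # cells assigned to the patch holding their center
  inside <- backend$cells$y >= o[1] & backend$cells$y < o[1] + size &
    backend$cells$x >= o[2] & backend$cells$x < o[2] + size
  lapply(which(inside), function(i) {
    lin <- backend$masks[[i]]
    r <- ((lin - 1L) %% h) + 1L
    c <- ((lin - 1L) %/% h) + 1L
    keep <- r > o[1] & r <= o[1] + size & c > o[2] & c <= o[2] + size
    (r[keep] - o[1]) + (c[keep] - o[2] - 1L) * size
  })
}

#' Estimate the slide-level TPS end to end
#'
#' Runs the full pipeline on one working-resolution slide image: tissue
#' masking and patch enumeration, patch tumor scoring and selection with
#' the minimum-count fallback, dual-branch cell instance detection,
#' per-cell typing, and TPS aggregation over all selected tumor patches.
#'
#' @param img RGB array `H x W x 3` (0..255) at working resolution.
#' @param tumor_backend two-class pixel backend for tumor scoring.
#' @param inst instance backend for nucleus detection.
#' @param type_backend four-class pixel backend for cell typing.
#' @param hema optional hema-transform function for the detection
#'   fallback branch (e.g. [hema_transform_hed()]).
#' @param stain_kind stain of the slide (`"pdl1"` or `"he"`).
#' @param mask_cfg a [masking_config()].
#' @param threshold tumor-score selection threshold (default 0.6).
#' @param min_count minimum selected tumor patches (default 10).
#' @param slide_id,patient_id identifiers carried into the result.
#' @return object of class `slide_score`: list with `slide_id`,
#'   `patient_id`, `counts` ([cell_counts()]), `tps_percent` (`NA` when
#'   no tumor cells were found), `patches` (scored patch table) and
#'   `cells` (per-cell table with patch origins).
#' @export
estimate_slide_tps <- function(img, tumor_backend, inst, type_backend,
                               hema = NULL, stain_kind = "pdl1",
                               mask_cfg = masking_config(),
                               threshold = 0.6, min_count = 10L,
                               slide_id = "slide", patient_id = slide_id) {
  grid <- tissue_grid(img, stain_kind, mask_cfg)
  locs <- grid$patch_locations
  if (nrow(locs) == 0L) {
    return(structure(
      list(slide_id = slide_id, patient_id = patient_id,
           counts = cell_counts(0L, 0L, 0L), tps_percent = NA_real_,
           patches = locs, cells = NULL),
      class = "slide_score"
    ))
  }
  scored <- score_tumor_patches(img, locs, tumor_backend, grid$patch_size_px)
  scored <- select_tumor_patches(scored, threshold, min_count)
  sel <- scored[scored$selected, , drop = FALSE]
  all_cells <- NULL
  for (i in seq_len(nrow(sel))) {
    p <- crop_patch(img, sel$row[i], sel$col[i], grid$patch_size_px)
    cells <- type_cells_in_patch(p, inst, type_backend, hema)
    if (nrow(cells) > 0) {
      cells$patch_row <- sel$row[i]
      cells$patch_col <- sel$col[i]
      all_cells <- rbind(all_cells, cells)
    }
  }
  counts <- if (is.null(all_cells)) cell_counts(0L, 0L, 0L) else {
    cell_counts(sum(all_cells$type == "TC+"),
                sum(all_cells$type == "TC-"),
                sum(all_cells$type == "OC"))
  }
  structure(
    list(slide_id = slide_id, patient_id = patient_id, counts = counts,
         tps_percent = compute_tps(counts), patches = scored,
         cells = all_cells),
    class = "slide_score"
  )
}

#' @export
print.slide_score <- function(x, ...) {
  tps <- if (is.na(x$tps_percent)) "undefined (no tumor cells)" else
    sprintf("%.2f%%", x$tps_percent)
  cat(sprintf("slide_score %s: TPS %s (TC+ %d, TC- %d, OC %d; %d patches selected)\n",
              x$slide_id, tps, x$counts$n_tcpos, x$counts$n_tcneg,
              x$counts$n_oc, sum(x$patches$selected)))
  invisible(x)
}
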