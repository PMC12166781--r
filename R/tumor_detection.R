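#' Patch tumor score from per-pixel two-class raw scores
#'
#' Applies a softmax to every pixel of a two-channel (non-tumor, tumor)
#' raw-score map and averages the tumor-channel probability over all
#' pixels, giving a patch-level tumor score in `[0, 1]`. Channel 2 is the
#' tumor channel.
#'
#' @param raw_scores numeric array `H x W x 2` of finite raw scores.
#' @return scalar tumor score in `[0, 1]`.
#' @export
tumor_score <- function(raw_scores) {
  stopifnot(is.array(raw_scores), length(dim(raw_scores)) == 3L,
            dim(raw_scores)[3] == 2L)
  if (!all(is.finite(raw_scores))) {
    stop("raw scores contain non-finite values", call. = FALSE)
  }
  p <- softmax_last_dim(raw_scores)
  mean(p[, , 2])
}

#' Score candidate patches for tumor content
#'
#' Crops each candidate patch from the slide, obtains per-pixel two-class
#' raw scores from the backend, and records the mean softmaxed tumor
#' probability as the patch score.
#'
#' @param img RGB slide array (0..255) at working resolution.
#' @param locs data frame of patch locations (`row`, `col`, 0-based).
#' @param backend a pixel-classification backend with two output classes.
#' @param patch_size patch edge length (default 512).
#' @return data frame `row`, `col`, `score`.
#' @export
score_tumor_patches <- function(img, locs, backend, patch_size = 512L) {
  scores <- vapply(seq_len(nrow(locs)), function(i) {
    p <- crop_patch(img, locs$row[i], locs$col[i], patch_size)
    tumor_score(predict_pixel_scores(backend, p))
  }, numeric(1))
  data.frame(row = locs$row, col = locs$col, score = scores)
}

#' Select tumor patches by threshold with a minimum-count fallback
#'
#' Patches whose score strictly exceeds `threshold` are selected. If fewer
#' than `min_count` qualify, the threshold is effectively lowered by
#' taking the `min_count` highest-scoring patches instead (ties broken by
#' row-major coordinate order); if fewer than `min_count` patches exist at
#' all, every patch is selected. The smallest selected score is recorded
#' as the threshold actually applied.
#'
#' @param scores data frame with columns `row`, `col`, `score`.
#' @param threshold tumor-score cut (default 0.6, strict).
#' @param min_count minimum number of selected patches (default 10).
#' @return the input data frame with logical column `selected` and scalar
#'   attribute-like column `threshold_applied` repeated per row.
#' @export
select_tumor_patches <- function(scores, threshold = 0.6, min_count = 10L) {
  if (nrow(scores) == 0L) stop("empty score list", call. = FALSE)
  selected <- scores$score > threshold
  if (sum(selected) < min_count) {
    k <- min(min_count, nrow(scores))
    ord <- order(-scores$score, scores$row, scores$col)
    selected <- logical(nrow(scores))
    selected[ord[seq_len(k)]] <- TRUE
  }
  scores$selected <- selected
  scores$threshold_applied <- min(scores$score[selected])
  scores
}

#' Rasterize polygons to a binary pixel mask
#'
#' Even-odd (ray casting) point-in-polygon test evaluated at pixel
#' centers. Coordinates follow the annotation convention: `x` = 0-based
#' column, `y` = 0-based row.
#'
#' @param polygons list of matrices with columns `x`, `y` (open rings).
#' @param nrow_px,ncol_px mask dimensions in pixels.
#' @return logical matrix; `TRUE` inside any polygon.
#' @export
rasterize_polygons <- function(polygons, nrow_px, ncol_px) {
  mask <- matrix(FALSE, nrow_px, ncol_px)
  if (length(polygons) == 0L) return(mask)
  px <- rep(seq_len(ncol_px) - 1L, each = nrow_px)   # x of every pixel
  py <- rep(seq_len(nrow_px) - 1L, times = ncol_px)  # y of every pixel
  inside_total <- rep(FALSE, nrow_px * ncol_px)
  for (poly in polygons) {
    xs <- poly[, "x"]; ys <- poly[, "y"]
    n <- length(xs)
    inside <- rep(FALSE, nrow_px * ncol_px)
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    inside_total <- inside_total | inside
  }
  matrix(inside_total, nrow_px, ncol_px)
}

#' Patch-level tumor ground truth from region polygons
#'
#' A patch is a true tumor patch when its ground-truth tumor-pixel
#' fraction exceeds `min_fraction` (default 0.5).
#'
#' @param tumor_mask logical matrix at working resolution (`TRUE` = tumor),
#'   e.g. from [rasterize_polygons()].
#' @param locs data frame of patch locations (`row`, `col`).
#' @param patch_size patch edge length.
#' @param min_fraction tumor-pixel fraction above which a patch counts as
#'   tumor (strict).
#' @return the input data frame with columns `tumor_fraction` and
#'   `is_tumor`.
#' @export
patch_tumor_truth <- function(tumor_mask, locs, patch_size = 512L,
                              min_fraction = 0.5) {
  frac <- vapply(seq_len(nrow(locs)), function(i) {
    r <- locs$row[i]; c <- locs$col[i]
    mean(tumor_mask[(r + 1):(r + patch_size), (c + 1):(c + patch_size)])
  }, numeric(1))
  locs$tumor_fraction <- frac
  locs$is_tumor <- frac > min_fraction
  locs
}

#' Train the tumor-detection backend
#'
#' Two-class (non-tumor, tumor) wrapper around [train_pixel_backend()].
#' Pixel labels are typically derived by rasterizing tumor-region
#' polygons over the training patches (label 1 = non-tumor, 2 = tumor).
#'
#' @param patches list of RGB patch arrays.
#' @param label_maps list of integer matrices (1 = non-tumor, 2 = tumor,
#'   `NA` = ignore).
#' @param cfg a [train_config()]; the stage default is 50 epochs.
#' @return trained backend.
#' @export
train_tumor_backend <- function(patches, label_maps, cfg = train_config(epochs = 50L)) {
  train_pixel_backend(patches, label_maps, n_classes = 2L,
                      classes = c("non_tumor", "tumor"), cfg = cfg)
}

#' Evaluate tumor-patch detection
#'
#' Patch-level precision and recall against ground-truth tumor patches,
#' plus a pixel-level Dice coefficient aggregated over all evaluated
#' patches (`2 |A n B| / (|A| + |B|)` with intersections and sizes summed
#' across patches).
#'
#' @param selected data frame of selected patches (`row`, `col`).
#' @param truth data frame of true tumor patches (`row`, `col`).
#' @param pred_masks,truth_masks optional lists of logical pixel masks
#'   (same length and order) for the Dice computation.
#' @return list with `precision`, `recall` (`NA` when the truth set is
#'   empty), `dice` (`NA` when no masks are given), `tp`, `fp`, `fn`.
#' @export
evaluate_detection <- function(selected, truth,
                               pred_masks = NULL, truth_masks = NULL) {
  key <- function(df) paste(df$row, df$col, sep = ",")
  sk <- key(selected); tk <- key(truth)
  tp <- sum(sk %in% tk)
  fp <- sum(!sk %in% tk)
  fn <- sum(!tk %in% sk)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (length(tk) > 0) tp / (tp + fn) else NA_real_
  dice <- NA_real_
  if (!is.null(pred_masks) && !is.null(truth_masks)) {
    stopifnot(length(pred_masks) == length(truth_masks))
    inter <- sum(vapply(seq_along(pred_masks), function(i) {
      sum(pred_masks[[i]] & truth_masks[[i]])
    }, numeric(1)))
    size <- sum(vapply(pred_masks, sum, numeric(1))) +
      sum(vapply(truth_masks, sum, numeric(1)))
    dice <- if (size > 0) 2 * inter / size else NA_real_
  }
  list(precision = precision, recall = recall, dice = dice,
       tp = tp, fp = fp, fn = fn)
}
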