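CELL_CLASSES <- c("TC+", "TC-", "OC", "background")

#' Nucleus instance-detection backend
#'
#' Classical instance segmentation satisfying the instance-backend
#' contract: the patch is converted to grayscale and inverted (so nuclei
#' are bright), Otsu-thresholded, and touching nuclei are split by a
#' distance-map watershed. Objects smaller than `min_area` pixels are
#' discarded. Detected instances are disjoint, nonempty pixel sets.
#'
#' With `use_augmentation = TRUE` the detection is repeated on an
#' intensity-perturbed copy of the patch and the run detecting more cells
#' is kept — a stand-in for test-time augmentation/averaging; the output
#' is then nondeterministic, so the flag defaults to off.
#'
#' @param diameter nominal nucleus diameter in pixels (default 15).
#' @param min_area minimum instance area in pixels; default scales with
#'   `diameter`.
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects before they are split; raising it keeps a stained membrane
#'   ring attached to its nucleus instead of splitting it off.
#' @param use_augmentation logical, see above.
#' @return object of class `instance_backend_nuclei`.
#' @export
instance_backend_nuclei <- function(diameter = 15,
                                    min_area = NULL,
                                    watershed_tolerance = 3,
                                    use_augmentation = FALSE) {
  if (is.null(min_area)) min_area <- max(9L, round(0.15 * pi * (diameter / 2)^2))
  structure(
    list(diameter = diameter, min_area = min_area,
         watershed_tolerance = watershed_tolerance,
         use_augmentation = use_augmentation),
    class = c("instance_backend_nuclei", "instance_backend")
  )
}

#' Detect cell instances in a patch
#'
#' Generic of the instance-backend contract. Methods return a list of
#' instances, each a vector of linear pixel indices into the `H x W`
#' patch raster (column-major, as produced by `which()` on a matrix).
#'
#' @param backend an instance backend.
#' @param patch RGB array `H x W x 3` (0..255).
#' @param ... passed to methods.
#' @return list of integer vectors (one per detected instance).
#' @export
detect_instances <- function(backend, patch, ...) {
  UseMethod("detect_instances")
}

#' @export
detect_instances.function <- function(backend, patch, ...) {
  # a bare function is the minimal instance backend: patch -> masks
  backend(patch, ...)
}

#' @export
detect_instances.instance_backend_nuclei <- function(backend, patch, ...) {
  run <- function(p) {
    inv <- 255 - luma(p)
    if (diff(range(inv)) == 0) return(list())
    thr <- 255 * EBImage::otsu(EBImage::Image(inv / 255),
                               range = c(0, 1), levels = 256L)
    bin <- inv > thr
    if (!any(bin)) return(list())
    dm <- EBImage::distmap(EBImage::Image(bin * 1))
    lab <- EBImage::imageData(EBImage::watershed(dm,
                                                 tolerance = backend$watershed_tolerance))
    ids <- setdiff(unique(as.vector(lab)), 0)
    masks <- lapply(ids, function(i) which(lab == i))
    masks[vapply(masks, length, integer(1)) >= backend$min_area]
  }
  out <- run(patch)
  if (isTRUE(backend$use_augmentation)) {
    jit <- patch + array(stats::rnorm(length(patch), sd = 2), dim = dim(patch))
    out2 <- run(clip(jit, 0, 255))
    if (length(out2) > length(out)) out <- out2
  }
  out
}

#' Detect instances on the original and hematoxylin-transformed patch
#'
#' Runs the instance backend on the original patch and, when a
#' hema-transform backend is supplied, also on the transformed patch; the
#' branch detecting strictly more cells wins, and ties keep the original
#' branch. Strong DAB staining makes brown membrane signal resemble the
#' bluish nuclei in grayscale, which suppresses detections on the
#' original branch — the transformed branch recovers them.
#'
#' @param patch RGB array `H x W x 3` (0..255).
#' @param inst an instance backend (see [detect_instances()]).
#' @param hema optional hema-transform function mapping an RGB patch to a
#'   hematoxylin-only RGB patch (e.g. [hema_transform_hed()]), or `NULL`.
#' @return list with `instances` (list of pixel-index vectors) and
#'   `source_branch` (`"original"` or `"hema_transformed"`).
#' @export
detect_instances_with_fallback <- function(patch, inst, hema = NULL) {
  res_orig <- tryCatch(detect_instances(inst, patch), error = function(e) e)
  if (is.null(hema)) {
    if (inherits(res_orig, "error")) stop(res_orig)
    return(list(instances = res_orig, source_branch = "original"))
  }
  res_hema <- tryCatch(detect_instances(inst, hema(patch)), error = function(e) e)
  if (inherits(res_orig, "error") && inherits(res_hema, "error")) {
    stop("instance detection failed on both branches: ",
         conditionMessage(res_orig), call. = FALSE)
  }
  if (inherits(res_orig, "error")) {
    return(list(instances = res_hema, source_branch = "hema_transformed"))
  }
  if (!inherits(res_hema, "error") && length(res_hema) > length(res_orig)) {
    list(instances = res_hema, source_branch = "hema_transformed")
  } else {
    list(instances = res_orig, source_branch = "original")
  }
}

#' Rasterize point cell annotations into a training label map
#'
#' Turns sparse point marks (x, y, class) into per-pixel training labels:
#' a point lying inside a detected instance labels that instance's whole
#' mask; a point with no containing instance labels a disk of the given
#' radius around it. Every other pixel carries the ignore-label (`NA`),
#' except that with `label_background = "outside_instances"` (the default
#' when instances are supplied) pixels belonging to no detected instance
#' are labeled background — background supervision is then down-weighted
#' in the loss rather than ignored, while detected but unannotated cells
#' stay ignored. Conflicting labels (overlapping disks, or two marks of
#' different classes on one instance, which also warns) are resolved by
#' the nearest annotation.
#'
#' @param annotations data frame with columns `x`, `y` (0-based pixel
#'   coordinates) and `label` in `"TC+"`, `"TC-"`, `"OC"`.
#' @param dim_px integer vector `c(H, W)` of the patch.
#' @param instances optional list of instance pixel-index vectors from
#'   [detect_instances()].
#' @param radius fallback disk radius in pixels (default 7).
#' @param label_background `"outside_instances"` or `"none"`.
#' @return integer matrix `H x W`; codes 1 = TC+, 2 = TC-, 3 = OC,
#'   4 = background, `NA` = ignore.
#' @export
rasterize_point_annotations <- function(annotations, dim_px,
                                        instances = NULL, radius = 7,
                                        label_background =
                                          c("outside_instances", "none")) {
  label_background <- match.arg(label_background)
  h <- dim_px[1]; w <- dim_px[2]
  stopifnot(all(annotations$x >= 0), all(annotations$x < w),
            all(annotations$y >= 0), all(annotations$y < h),
            all(annotations$label %in% CELL_CLASSES[1:3]))
  lab <- matrix(NA_integer_, h, w)
  if (!is.null(instances) && label_background == "outside_instances") {
    covered <- logical(h * w)
    for (m in instances) covered[m] <- TRUE
    lab[!covered] <- 4L
  }
  best_d <- matrix(Inf, h, w)
  # pixel coordinate grids (0-based, x = column, y = row)
  px <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  py <- matrix(rep(seq_len(h) - 1L, times = w), h, w)

  containing_instance <- function(x, y) {
    lin <- (y + 1L) + x * h
    for (i in seq_along(instances)) if (lin %in% instances[[i]]) return(i)
    NA_integer_
  }
  inst_of <- vapply(seq_len(nrow(annotations)), function(i) {
    if (is.null(instances)) NA_integer_ else
      containing_instance(annotations$x[i], annotations$y[i])
  }, integer(1))
  # warn on class conflicts within one instance
  for (ii in unique(stats::na.omit(inst_of))) {
    cls <- unique(annotations$label[which(inst_of == ii)])
    if (length(cls) > 1) {
      warning("annotations of different classes on one instance; ",
              "nearest point wins")
    }
  }
  for (i in seq_len(nrow(annotations))) {
    cls <- match(annotations$label[i], CELL_CLASSES)
    x <- annotations$x[i]; y <- annotations$y[i]
    target <- if (!is.na(inst_of[i])) {
      instances[[inst_of[i]]]
    } else {
      which((px - x)^2 + (py - y)^2 <= radius^2)
    }
    d <- (px[target] - x)^2 + (py[target] - y)^2
    take <- d < best_d[target]
    lab[target[take]] <- cls
    best_d[target[take]] <- d[take]
  }
  lab
}

#' Train the four-class cell-typing backend
#'
#' Wrapper around [train_pixel_backend()] for classes TC+, TC-, OC and
#' background. The background class is down-weighted in the cross-entropy
#' loss (weight 0.0004 versus 1 for the three cell classes) to counter
#' its overwhelming pixel count, and ignore-label pixels contribute zero
#' loss.
#'
#' @param patches list of RGB patch arrays.
#' @param label_maps list of integer label matrices from
#'   [rasterize_point_annotations()].
#' @param cfg a [train_config()]; the stage default is 25 epochs.
#' @param background_weight loss weight of the background class.
#' @return trained four-class backend.
#' @export
train_celltype_backend <- function(patches, label_maps,
                                   cfg = train_config(epochs = 25L),
                                   background_weight = 0.0004) {
  cfg$class_weights <- c(1, 1, 1, background_weight)
  train_pixel_backend(patches, label_maps, n_classes = 4L,
                      classes = CELL_CLASSES, cfg = cfg)
}

#' Classify detected cells from a per-pixel softmax map
#'
#' For each instance, the four-class softmax vectors of all pixels inside
#' its mask are averaged into a single score vector. The background entry
#' is then discarded and the cell type is the argmax over TC+, TC- and
#' OC, with exact ties resolved by the fixed priority TC+ > TC- > OC.
#'
#' @param softmax_map array `H x W x 4` of per-pixel class probabilities
#'   (ordered TC+, TC-, OC, background).
#' @param instances list of instance pixel-index vectors.
#' @return data frame with one row per instance: `cell_id`, `type`,
#'   `prob_tcpos`, `prob_tcneg`, `prob_oc`, `prob_background`, `n_px`.
#' @export
classify_cells <- function(softmax_map, instances) {
  stopifnot(is.array(softmax_map), length(dim(softmax_map)) == 3L,
            dim(softmax_map)[3] == 4L)
  hw <- prod(dim(softmax_map)[1:2])
  flat <- matrix(softmax_map, nrow = hw)
  rows <- lapply(seq_along(instances), function(i) {
    m <- instances[[i]]
    if (length(m) == 0L) stop("instance ", i, " has an empty mask", call. = FALSE)
    pr <- colMeans(flat[m, , drop = FALSE])
    type <- CELL_CLASSES[which.max(pr[1:3])]  # ties: first max wins (TC+ > TC- > OC)
    data.frame(cell_id = i, type = type,
               prob_tcpos = pr[1], prob_tcneg = pr[2],
               prob_oc = pr[3], prob_background = pr[4],
               n_px = length(m))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), type = character(0),
                      prob_tcpos = numeric(0), prob_tcneg = numeric(0),
                      prob_oc = numeric(0), prob_background = numeric(0),
                      n_px = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Detect and type all cells in one patch
#'
#' Convenience wrapper: dual-branch instance detection, per-pixel softmax
#' prediction with the typing backend, and per-cell classification.
#'
#' @param patch RGB array `H x W x 3` (0..255).
#' @param inst instance backend.
#' @param type_backend trained four-class pixel backend.
#' @param hema optional hema-transform function.
#' @return data frame as [classify_cells()] plus a `source_branch` column.
#' @export
type_cells_in_patch <- function(patch, inst, type_backend, hema = NULL) {
  det <- detect_instances_with_fallback(patch, inst, hema)
  cells <- classify_cells(predict_softmax_map(type_backend, patch),
                          det$instances)
  if (nrow(cells) > 0) cells$source_branch <- det$source_branch
  else cells$source_branch <- character(0)
  cells
}
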