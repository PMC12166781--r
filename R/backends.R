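#' Training configuration for pixel-classification backends
#'
#' Mirrors the training recipe used by both segmentation stages: AdamW
#' with decoupled weight decay, initial learning rate 0.001 decayed by
#' cosine annealing, batch size 8 (patches per step), cross-entropy loss
#' with optional per-class weights and an ignore-label, flip augmentation
#' with probability 0.5 per axis plus brightness/contrast/saturation
#' jitter, and channel normalization to fixed means/standard deviations
#' (defaults are the standard natural-image dataset statistics).
#'
#' @param epochs number of passes over the training patches (tumor stage
#'   default 50, cell-typing stage default 25; toy runs use far fewer).
#' @param initial_lr initial learning rate for AdamW.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size patches per optimization step.
#' @param class_weights numeric vector of per-class loss weights, or
#'   `NULL` for uniform weights.
#' @param augment logical; apply flip + color-jitter augmentation
#'   (training only).
#' @param flip_p per-axis flip probability.
#' @param jitter brightness/contrast/saturation jitter half-range (each
#'   factor drawn uniformly from `1 +/- jitter`).
#' @param norm_means,norm_sds per-channel normalization constants on the
#'   0..1 scale.
#' @param context_sigmas Gaussian blur scales (pixels) of the context
#'   features appended to the raw channels.
#' @param max_px_per_patch labeled pixels subsampled per patch per step
#'   (caps memory and time; the full patch is used at inference).
#' @param steps_per_epoch optimization steps per epoch; `NULL` (default)
#'   means one pass over the patches (`ceiling(n_patches / batch_size)`).
#'   Toy runs on few patches raise this so the optimizer takes enough
#'   steps to converge.
#' @param rng_seed seed controlling shuffling, subsampling, augmentation
#'   and weight initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L,
                         initial_lr = 0.001,
                         weight_decay = 0.01,
                         batch_size = 8L,
                         class_weights = NULL,
                         augment = TRUE,
                         flip_p = 0.5,
                         jitter = 0.2,
                         norm_means = c(0.485, 0.456, 0.406),
                         norm_sds = c(0.229, 0.224, 0.225),
                         context_sigmas = c(2, 6),
                         max_px_per_patch = 2000L,
                         steps_per_epoch = NULL,
                         rng_seed = 0L) {
  stopifnot(epochs >= 1, initial_lr > 0, batch_size >= 1,
            length(norm_means) == 3L, length(norm_sds) == 3L)
  structure(
    list(
      epochs = as.integer(epochs), initial_lr = initial_lr,
      weight_decay = weight_decay, batch_size = as.integer(batch_size),
      class_weights = class_weights, augment = augment, flip_p = flip_p,
      jitter = jitter, norm_means = norm_means, norm_sds = norm_sds,
      context_sigmas = context_sigmas,
      max_px_per_patch = as.integer(max_px_per_patch),
      steps_per_epoch = if (!is.null(steps_per_epoch)) as.integer(steps_per_epoch),
      rng_seed = as.integer(rng_seed)
    ),
    class = "train_config"
  )
}

# Per-pixel feature matrix: normalized RGB plus Gaussian-context channels.
# Returns an N x d matrix (N = H * W, column-major pixel order).
pixel_features <- function(patch, norm_means, norm_sds, context_sigmas) {
  stopifnot_rgb(patch)
  h <- dim(patch)[1]; w <- dim(patch)[2]
  chans <- lapply(1:3, function(k) (patch[, , k] / 255 - norm_means[k]) / norm_sds[k])
  feats <- chans
  for (s in context_sigmas) {
    for (k in 1:3) {
      b <- EBImage::gblur(EBImage::Image(chans[[k]]), sigma = s,
                          boundary = "replicate")
      feats[[length(feats) + 1L]] <- EBImage::imageData(b)
    }
  }
  matrix(unlist(feats), nrow = h * w)
}

#' Per-pixel multinomial softmax classification backend
#'
#' A compact pixel classifier: a linear softmax model over per-pixel
#' color features augmented with Gaussian-smoothed context channels.
#' It satisfies the pixel-classifier contract used by the tumor-detection
#' and cell-typing stages — it maps an RGB patch to a raster of per-pixel
#' raw scores over `n_classes` classes with the same spatial dimensions,
#' and inference is deterministic given fixed weights. Train it with
#' [train_pixel_backend()].
#'
#' @param n_classes number of classes.
#' @param classes character vector of class names (length `n_classes`).
#' @param cfg a [train_config()] supplying the feature/normalization
#'   settings.
#' @return object of class `pixel_softmax_backend` with zero-initialized
#'   weights.
#' @export
pixel_softmax_backend <- function(n_classes, classes = NULL,
                                  cfg = train_config()) {
  d <- 3L * (1L + length(cfg$context_sigmas))
  if (is.null(classes)) classes <- paste0("class", seq_len(n_classes))
  stopifnot(length(classes) == n_classes)
  structure(
    list(
      W = matrix(0, nrow = d + 1L, ncol = n_classes),
      n_classes = as.integer(n_classes), classes = classes,
      norm_means = cfg$norm_means, norm_sds = cfg$norm_sds,
      context_sigmas = cfg$context_sigmas, history = NULL
    ),
    class = c("pixel_softmax_backend", "pixel_backend")
  )
}

#' Per-pixel raw class scores for a patch
#'
#' Generic entry point of the pixel-classifier contract: returns an
#' `H x W x C` array of raw (pre-softmax) scores with the spatial
#' dimensions of the input patch.
#'
#' @param backend a pixel-classification backend.
#' @param patch RGB array `H x W x 3` (0..255).
#' @param ... passed to methods.
#' @return numeric array `H x W x n_classes`.
#' @export
predict_pixel_scores <- function(backend, patch, ...) {
  UseMethod("predict_pixel_scores")
}

#' @export
predict_pixel_scores.pixel_softmax_backend <- function(backend, patch, ...) {
  x <- pixel_features(patch, backend$norm_means, backend$norm_sds,
                      backend$context_sigmas)
  s <- cbind(1, x) %*% backend$W
  array(s, dim = c(dim(patch)[1], dim(patch)[2], backend$n_classes))
}

#' Per-pixel softmax probability map for a patch
#'
#' @inheritParams predict_pixel_scores
#' @return array `H x W x n_classes`; entries sum to 1 across classes at
#'   every pixel.
#' @export
predict_softmax_map <- function(backend, patch, ...) {
  softmax_last_dim(predict_pixel_scores(backend, patch, ...))
}

# flip + color-jitter augmentation applied to a (patch, label map) pair
augment_pair <- function(patch, labels, cfg) {
  if (stats::runif(1) < cfg$flip_p) {
    patch <- patch[rev(seq_len(dim(patch)[1])), , , drop = FALSE]
    labels <- labels[rev(seq_len(nrow(labels))), , drop = FALSE]
  }
  if (stats::runif(1) < cfg$flip_p) {
    patch <- patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
    labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
  }
  if (cfg$jitter > 0) {
    br <- stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)
    ct <- stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)
    sat <- stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)
    patch <- clip((patch - 127.5) * ct + 127.5, 0, 255) * br
    g <- luma(patch)
    for (k in 1:3) patch[, , k] <- g + sat * (patch[, , k] - g)
    patch <- clip(patch, 0, 255)
  }
  list(patch = patch, labels = labels)
}

#' Train a per-pixel softmax backend
#'
#' Minimizes weighted cross-entropy over labeled pixels with AdamW and a
#' cosine-annealed learning rate, per [train_config()]. Label maps are
#' integer matrices with values `1..n_classes`; `NA` marks ignore-label
#' pixels, which contribute zero loss. Per-class weights rescale each
#' pixel's loss contribution (used to down-weight the abundant background
#' class in the cell-typing stage). Training is reproducible under
#' `cfg$rng_seed`.
#'
#' @param patches list of RGB arrays (0..255), all the same size.
#' @param label_maps list of integer matrices matching `patches`.
#' @param n_classes number of classes.
#' @param classes optional class names.
#' @param cfg a [train_config()].
#' @return a trained [pixel_softmax_backend()] whose `history` element
#'   holds the per-epoch mean training loss.
#' @export
train_pixel_backend <- function(patches, label_maps, n_classes,
                                classes = NULL, cfg = train_config()) {
  stopifnot(length(patches) == length(label_maps), length(patches) >= 1)
  n_lab <- sum(vapply(label_maps, function(m) sum(!is.na(m)), numeric(1)))
  if (n_lab == 0) stop("no labeled pixels in the training data", call. = FALSE)
  backend <- pixel_softmax_backend(n_classes, classes, cfg)
  wc <- cfg$class_weights %||% rep(1, n_classes)
  stopifnot(length(wc) == n_classes)

  with_seed(cfg$rng_seed, {
    d1 <- nrow(backend$W)
    backend$W <- matrix(stats::rnorm(d1 * n_classes, sd = 0.01),
                        nrow = d1, ncol = n_classes)
    m_t <- v_t <- matrix(0, d1, n_classes)
    n_p <- length(patches)
    steps_per_epoch <- cfg$steps_per_epoch %||% ceiling(n_p / cfg$batch_size)
    total_steps <- cfg$epochs * steps_per_epoch
    step <- 0L
    eps <- 1e-8
    history <- numeric(cfg$epochs)

    # Without augmentation the features of each patch are fixed, so the
    # labeled-pixel subsample can be extracted once and cached.
    patch_rows <- function(p, lm) {
      lab_idx <- which(!is.na(lm))
      if (length(lab_idx) == 0L) return(NULL)
      if (length(lab_idx) > cfg$max_px_per_patch) {
        lab_idx <- sample(lab_idx, cfg$max_px_per_patch)
      }
      x <- pixel_features(p, cfg$norm_means, cfg$norm_sds, cfg$context_sigmas)
      list(x = x[lab_idx, , drop = FALSE], y = lm[lab_idx])
    }
    cache <- if (!cfg$augment) {
      lapply(seq_len(n_p), function(i) patch_rows(patches[[i]], label_maps[[i]]))
    }

    for (ep in seq_len(cfg$epochs)) {
      ep_cache <- if (cfg$augment) {
        lapply(seq_len(n_p), function(i) {
          a <- augment_pair(patches[[i]], label_maps[[i]], cfg)
          patch_rows(a$patch, a$labels)
        })
      } else {
        cache
      }
      ep_loss <- 0; ep_wsum <- 0
      for (b in seq_len(steps_per_epoch)) {
        idx <- sample.int(n_p, min(cfg$batch_size, n_p))
        rows <- ep_cache[idx]
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows) == 0L) next
        xs <- lapply(rows, `[[`, "x")
        ys <- unlist(lapply(rows, `[[`, "y"))
        x1 <- cbind(1, do.call(rbind, xs))
        wpx <- wc[ys]
        scores <- x1 %*% backend$W
        p_soft <- softmax_last_dim(scores)
        y1h <- matrix(0, length(ys), n_classes)
        y1h[cbind(seq_along(ys), ys)] <- 1
        wsum <- sum(wpx)
        loss <- -sum(wpx * log(pmax(p_soft[y1h == 1], 1e-12))) / wsum
        grad <- crossprod(x1, (p_soft - y1h) * wpx) / wsum

        step <- step + 1L
        lr <- cfg$initial_lr * 0.5 * (1 + cos(pi * (step - 1L) / total_steps))
        m_t <- 0.9 * m_t + 0.1 * grad
        v_t <- 0.999 * v_t + 0.001 * grad^2
        m_hat <- m_t / (1 - 0.9^step)
        v_hat <- v_t / (1 - 0.999^step)
        backend$W <- backend$W - lr * (m_hat / (sqrt(v_hat) + eps) +
                                         cfg$weight_decay * backend$W)
        ep_loss <- ep_loss + loss * wsum
        ep_wsum <- ep_wsum + wsum
      }
      history[ep] <- if (ep_wsum > 0) ep_loss / ep_wsum else NA_real_
    }
    backend$history <- history
  })
  backend
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a working-resolution patch from a slide image
#'
#' The crop carries its 0-based top-left origin as an `"origin"` attribute
#' so that location-aware backends (e.g. ground-truth oracles) can recover
#' where the patch came from.
#'
#' @param img RGB array `H x W x 3`.
#' @param row,col 0-based top-left corner in working-resolution pixels.
#' @param size patch edge length (default 512).
#' @return RGB array `size x size x 3` with attribute `origin = c(row, col)`.
#' @export
crop_patch <- function(img, row, col, size = 512L) {
  stopifnot(row >= 0, col >= 0,
            row + size <= dim(img)[1], col + size <= dim(img)[2])
  p <- img[(row + 1):(row + size), (col + 1):(col + size), , drop = FALSE]
  attr(p, "origin") <- c(row = row, col = col)
  p
}
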