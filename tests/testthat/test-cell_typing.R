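test_that("per-cell typing averages the softmax over the mask and drops background", {
  # single pixel, direct argmax
  sm <- array(rep(c(0.7, 0.1, 0.1, 0.1), each = 1), dim = c(1, 1, 4))
  expect_equal(classify_cells(sm, list(1L))$type, "TC+")

  # two-pixel mean: (0.6,0.2,0.1,0.1) and (0.0,0.8,0.1,0.1) -> (0.3,0.5,...) -> TC-
  sm2 <- array(0, dim = c(2, 1, 4))
  sm2[1, 1, ] <- c(0.6, 0.2, 0.1, 0.1)
  sm2[2, 1, ] <- c(0.0, 0.8, 0.1, 0.1)
  res2 <- classify_cells(sm2, list(c(1L, 2L)))
  expect_equal(res2$type, "TC-")
  expect_equal(res2$prob_tcpos, 0.3)
  expect_equal(res2$prob_tcneg, 0.5)

  # background dominant per pixel still never wins
  smb <- array(rep(c(0.05, 0.1, 0.15, 0.7), each = 4), dim = c(2, 2, 4))
  expect_equal(classify_cells(smb, list(1:4))$type, "OC")

  # exact tie resolves by fixed priority TC+ > TC- > OC
  smt <- array(rep(c(0.4, 0.4, 0.1, 0.1), each = 1), dim = c(1, 1, 4))
  expect_equal(classify_cells(smt, list(1L))$type, "TC+")

  expect_error(classify_cells(sm, list(integer(0))), "empty")
})

test_that("per-cell typing matches the loop-and-argmax oracle and its invariances", {
  set.seed(19)
  for (rep in 1:10) {
    raw <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
    sm <- pdl1tps:::softmax_last_dim(raw)
    masks <- lapply(1:5, function(i) sample(16 * 16, sample(3:30, 1)))
    res <- classify_cells(sm, masks)
    expect_equal(res$type, classify_oracle(sm, masks))
    expect_equal(nrow(res), length(masks))           # one row per instance
    expect_false(any(res$type == "background"))      # background never assigned
    # permutation invariance of pixel order within a mask
    res_perm <- classify_cells(sm, lapply(masks, sample))
    expect_equal(res_perm$type, res$type)
    expect_equal(res_perm$prob_tcpos, res$prob_tcpos)
  }
})

test_that("dual-branch detection keeps the branch with more cells, original on ties", {
  # stub backend: the number of detections is encoded in pixel [1,1,1]
  stub <- function(patch, ...) {
    n <- round(patch[1, 1, 1])
    lapply(seq_len(n), function(i) i)
  }
  mk <- function(n) {
    p <- array(100, dim = c(4, 4, 3))
    p[1, 1, 1] <- n
    p
  }
  bump <- function(delta) function(p) { p[1, 1, 1] <- p[1, 1, 1] + delta; p }

  more <- detect_instances_with_fallback(mk(50), stub, hema = bump(20))
  expect_equal(more$source_branch, "hema_transformed")
  expect_length(more$instances, 70)

  tie <- detect_instances_with_fallback(mk(50), stub, hema = bump(0))
  expect_equal(tie$source_branch, "original")

  fewer <- detect_instances_with_fallback(mk(50), stub, hema = bump(-10))
  expect_equal(fewer$source_branch, "original")

  none <- detect_instances_with_fallback(mk(5), stub, hema = NULL)
  expect_equal(none$source_branch, "original")
  expect_length(none$instances, 5)

  # metamorphic sweep: ties always return the original branch
  set.seed(29)
  for (i in 1:20) {
    n <- sample(0:40, 1)
    d <- sample(-5:5, 1)
    out <- detect_instances_with_fallback(mk(n), stub, hema = bump(d))
    expect_equal(out$source_branch,
                 if (d > 0) "hema_transformed" else "original")
  }
})

test_that("point annotations rasterize by instance containment with a disk fallback", {
  # containment: one TC+ point inside a 40-px instance labels the whole mask
  inst <- list(1:40)
  ann <- data.frame(x = 0, y = 5, label = "TC+")  # pixel (x=0,y=5) -> index 6
  lab <- rasterize_point_annotations(ann, c(20, 20), instances = inst)
  expect_equal(sum(lab == 1L, na.rm = TRUE), 40)
  expect_equal(sum(lab == 4L, na.rm = TRUE), 400 - 40)  # outside instances = background

  # no instance: disk of radius 7 around the point, bounded by pi r^2
  ann2 <- data.frame(x = 10, y = 10, label = "OC")
  lab2 <- rasterize_point_annotations(ann2, c(21, 21), instances = NULL)
  n_disk <- sum(lab2 == 3L, na.rm = TRUE)
  expect_gt(n_disk, 100)
  expect_lte(n_disk, ceiling(pi * 49) + 8)
  expect_true(all(is.na(lab2) | lab2 == 3L))      # no background without instances

  # two same-class points on disjoint instances: union equals per-instance labels
  inst3 <- list(1:20, 201:230)
  ann3 <- data.frame(x = c(0, 10), y = c(2, 9), label = "TC-")
  lab3 <- rasterize_point_annotations(ann3, c(20, 20), instances = inst3)
  expect_true(all(lab3[1:20] == 2L))
  expect_true(all(lab3[201:230] == 2L))

  # conflicting classes on one instance warn and resolve by nearest point
  ann4 <- data.frame(x = 0, y = c(0, 19), label = c("TC+", "OC"))
  expect_warning(
    lab4 <- rasterize_point_annotations(ann4, c(20, 20), instances = list(1:20)),
    "different classes"
  )
  expect_equal(lab4[1, 1], 1L)    # nearest to the TC+ mark
  expect_equal(lab4[20, 1], 3L)   # nearest to the OC mark
})

test_that("ignore-labeled pixels contribute nothing to the training loss", {
  set.seed(47)
  p <- array(runif(96 * 96 * 3, 0, 255), dim = c(96, 96, 3))
  lm <- matrix(NA_integer_, 96, 96)
  lm[1:20, 1:20] <- sample(1:4, 400, replace = TRUE)
  cfg <- train_config(epochs = 2, augment = FALSE, steps_per_epoch = 4,
                      max_px_per_patch = 400, rng_seed = 3L)
  b1 <- train_celltype_backend(list(p), list(lm), cfg)
  p2 <- p
  p2[80:96, 80:96, ] <- runif(17 * 17 * 3, 0, 255)  # far from labeled region
  b2 <- train_celltype_backend(list(p2), list(lm), cfg)
  # equality up to FFT round-off in the blur features
  expect_equal(b1$history, b2$history, tolerance = 1e-9)
  expect_equal(b1$W, b2$W, tolerance = 1e-9)
})

test_that("nucleus detection finds approximately the planted cells on a synthetic patch", {
  sl <- small_slide(true_tps = 40, seed = 61, n_cells = 140)
  tt <- sl$truth$tumor_tiles
  p <- crop_patch(sl$image, tt$row[1], tt$col[1])
  n_truth <- sum(sl$truth$cells$y >= tt$row[1] & sl$truth$cells$y < tt$row[1] + 512 &
                   sl$truth$cells$x >= tt$col[1] & sl$truth$cells$x < tt$col[1] + 512)
  det <- detect_instances(instance_backend_nuclei(), p)
  expect_gt(length(det), 0.75 * n_truth)
  expect_lt(length(det), 1.25 * n_truth)
  # masks are disjoint and nonempty
  all_px <- unlist(det)
  expect_equal(length(all_px), length(unique(all_px)))
  expect_true(all(lengths(det) > 0))
})

test_that("ground-truth one-hot maps classify every synthetic cell correctly", {
  sl <- small_slide(true_tps = 35, seed = 71, n_cells = 120)
  ob <- truth_oracle_backends(sl$truth)
  tt <- sl$truth$tumor_tiles
  p <- crop_patch(sl$image, tt$row[1], tt$col[1])
  inst <- detect_instances(ob$instance, p)
  cells <- classify_cells(predict_softmax_map(ob$type, p), inst)
  inside <- sl$truth$cells$y >= tt$row[1] & sl$truth$cells$y < tt$row[1] + 512 &
    sl$truth$cells$x >= tt$col[1] & sl$truth$cells$x < tt$col[1] + 512
  count_types <- function(x) {
    vapply(c("TC+", "TC-", "OC"), function(k) sum(x == k), numeric(1))
  }
  expect_equal(count_types(cells$type),
               count_types(sl$truth$cells$type[inside]))
})

test_that("short training on separable synthetic patches types held-out cells accurately", {
  ib <- instance_backend_nuclei()
  train <- lapply(c(25, 55), function(tps) small_slide(tps, seed = 80 + tps, n_cells = 130))
  cps <- list(); cls <- list()
  for (sl in train) {
    tt <- sl$truth$tumor_tiles
    p <- crop_patch(sl$image, tt$row[1], tt$col[1])
    det <- detect_instances(ib, p)
    ann <- truth_cell_annotations(sl$truth, tt$row[1], tt$col[1])
    cps[[length(cps) + 1]] <- p
    cls[[length(cls) + 1]] <- rasterize_point_annotations(ann, c(512, 512),
                                                          instances = det)
  }
  cb <- train_celltype_backend(cps, cls,
    cfg = train_config(epochs = 8, initial_lr = 0.05, augment = FALSE,
                       steps_per_epoch = 30, rng_seed = 7L))
  expect_lt(cb$history[length(cb$history)], cb$history[1])

  ho <- small_slide(40, seed = 90, n_cells = 130)
  tt <- ho$truth$tumor_tiles
  p <- crop_patch(ho$image, tt$row[1], tt$col[1])
  det <- detect_instances(ib, p)
  cells <- classify_cells(predict_softmax_map(cb, p), det)
  # match detected instances to true cells by centroid
  cent <- t(vapply(det, function(m) {
    c(x = mean((m - 1) %/% 512), y = mean((m - 1) %% 512))
  }, numeric(2)))
  ann <- truth_cell_annotations(ho$truth, tt$row[1], tt$col[1])
  hit <- vapply(seq_len(nrow(cent)), function(i) {
    d2 <- (ann$x - cent[i, "x"])^2 + (ann$y - cent[i, "y"])^2
    j <- which.min(d2)
    if (d2[j] < 15^2) j else NA_integer_
  }, integer(1))
  ok <- !is.na(hit)
  expect_gt(sum(ok), 50)
  acc <- mean(cells$type[ok] == ann$label[hit[ok]])
  expect_gte(acc, 0.8)
})
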