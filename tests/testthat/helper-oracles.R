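# Independent brute-force oracles used to verify the vectorized /
# library-backed implementations. Deliberately written as plain loops.

# Otsu threshold by exhaustive search over all 256 integer thresholds,
# maximizing between-class variance of the (floor-binned) channel.
otsu_oracle <- function(channel) {
  v <- floor(as.vector(channel))
  best_t <- NA_real_
  best_var <- -1
  for (t in 1:255) {
    lo <- v[v < t]
    hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    wb <- length(lo) / length(v)
    bc <- wb * (1 - wb) * (mean(lo) - mean(hi))^2
    if (bc > best_var) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# Tissue-patch enumeration by explicit sub-patch loops.
enum_oracle <- function(mask, cfg = masking_config()) {
  rows <- integer(0)
  cols <- integer(0)
  for (ti in seq_len(nrow(mask) %/% 32)) {
    for (tj in seq_len(ncol(mask) %/% 32)) {
      n_ok <- 0L
      for (si in 0:3) {
        for (sj in 0:3) {
          sub <- mask[((ti - 1) * 32 + si * 8 + 1):((ti - 1) * 32 + si * 8 + 8),
                      ((tj - 1) * 32 + sj * 8 + 1):((tj - 1) * 32 + sj * 8 + 8)]
          if (sum(sub) >= cfg$min_tissue_px_per_subpatch) n_ok <- n_ok + 1L
        }
      }
      if (n_ok / 16 > cfg$min_coverage_fraction) {
        rows <- c(rows, (ti - 1L) * 512L)
        cols <- c(cols, (tj - 1L) * 512L)
      }
    }
  }
  data.frame(row = rows, col = cols)
}

# Patch tumor score by per-pixel exp-normalization and explicit averaging.
tumor_score_oracle <- function(raw) {
  acc <- 0
  for (i in seq_len(dim(raw)[1])) {
    for (j in seq_len(dim(raw)[2])) {
      e <- exp(raw[i, j, ] - max(raw[i, j, ]))
      acc <- acc + e[2] / sum(e)
    }
  }
  acc / (dim(raw)[1] * dim(raw)[2])
}

# Per-cell typing by explicit pixel loops: sum, divide, argmax over the
# first three classes (ties: TC+ > TC- > OC by scan order).
classify_oracle <- function(softmax_map, instances) {
  h <- dim(softmax_map)[1]
  out <- character(length(instances))
  for (i in seq_along(instances)) {
    s <- c(0, 0, 0, 0)
    for (lin in instances[[i]]) {
      r <- ((lin - 1) %% h) + 1
      c <- ((lin - 1) %/% h) + 1
      s <- s + softmax_map[r, c, ]
    }
    s <- s / length(instances[[i]])
    out[i] <- c("TC+", "TC-", "OC")[which.max(s[1:3])]
  }
  out
}

# Small synthetic slide used across tests (4 patch tiles, 1 tumor tile).
small_slide <- function(true_tps = 30, seed = 1, n_cells = 150, ...) {
  generate_slide(synthetic_slide_spec(
    canvas_size = c(1024L, 1024L), n_tissue_blobs = 1L,
    blob_radius_range = c(280, 360), tumor_fraction = 0.25,
    n_cells = n_cells, true_tps = true_tps, oc_fraction = 0.3,
    rng_seed = seed, ...
  ))
}
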