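#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All user-facing stochastic operations route through this so that a seed in a
# config object never leaks into (or depends on) the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Numerically stable softmax along the last dimension of an array
#'
#' @param x numeric array whose last dimension indexes classes, or a matrix
#'   with classes in columns.
#' @return array of the same shape with nonnegative entries summing to 1
#'   along the class dimension.
#' @keywords internal
softmax_last_dim <- function(x) {
  d <- dim(x)
  nc <- d[length(d)]
  m <- matrix(x, ncol = nc)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e <- e / rowSums(e)
  array(e, dim = d)
}

# ITU-R BT.601 luma. `img` is an H x W x 3 array on a 0..255 scale.
luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

stopifnot_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    stop("expected an RGB image as an H x W x 3 array", call. = FALSE)
  }
  invisible(img)
}

# Round half to even at `digits` decimals (banker's rounding, the base R
# default for round()).
round_percent <- function(x, digits = 2) round(x, digits)
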