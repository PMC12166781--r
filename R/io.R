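#' Read a slide image from PNG or TIFF
#'
#' Returns the raster as an `H x W x 3` numeric array on a 0..255 scale,
#' the in-memory representation used throughout the package. Grayscale
#' images are replicated to three channels; an alpha channel is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric array `H x W x 3`, values in `[0, 255]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF slides", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write a slide image or binary mask as PNG
#'
#' Masks (logical or 0/1 matrices) are written as single-channel 0/255
#' images; RGB arrays on the 0..255 scale are written as color PNG.
#'
#' @param x logical/numeric matrix (mask) or `H x W x 3` array (0..255).
#' @param path output path.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  if (is.matrix(x) && max(x) <= 1) {
    png::writePNG(x, path)
  } else {
    png::writePNG(clip01(x / 255), path)
  }
  invisible(path)
}

#' Read a binary mask written by [write_image_png()]
#'
#' @param path PNG path.
#' @return logical matrix (`TRUE` = foreground).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m >= 0.5
}

#' Write / read patch coordinate tables
#'
#' Patch coordinates are exchanged as CSV with columns
#' `slide_id,row,col,patch_size` in 0-based working-resolution pixels.
#'
#' @param patches data frame with columns `row`, `col` (and optionally
#'   `slide_id`, `patch_size`).
#' @param path CSV path.
#' @param slide_id slide identifier used when `patches` lacks the column.
#' @param patch_size patch edge length in pixels.
#' @export
write_patch_csv <- function(patches, path, slide_id = "slide", patch_size = 512L) {
  df <- data.frame(
    slide_id = if ("slide_id" %in% names(patches)) patches$slide_id else slide_id,
    row = patches$row,
    col = patches$col,
    patch_size = if ("patch_size" %in% names(patches)) patches$patch_size else patch_size
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_csv
#' @export
read_patch_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write tumor-region polygons as GeoJSON
#'
#' Polygons are written as a `FeatureCollection` of `Polygon` features in
#' image pixel coordinates (x = column, y = row, 0-based).
#'
#' @param polygons list of numeric matrices with columns `x`, `y`; each
#'   matrix is one polygon ring (closed implicitly).
#' @param path output `.geojson` path.
#' @export
write_rois_geojson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])  # close the ring
    coords <- lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
    list(
      type = "Feature",
      properties = list(id = i, class = "tumor"),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read tumor-region polygons from GeoJSON
#'
#' @param path `.geojson` path written by [write_rois_geojson()] (or any
#'   FeatureCollection of Polygon features).
#' @return list of numeric matrices with columns `x`, `y` (open rings).
#' @export
read_rois_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("x", "y")
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
}
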