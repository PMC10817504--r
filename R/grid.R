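#' Define a raster grid
#'
#' A `grid_spec` fixes the pixel lattice every raster object in the package
#' lives on: `width` x `height` pixels of `pixel_size` map units, anchored at
#' the lower-left corner (`origin_x`, `origin_y`). Row 1 of a value matrix is
#' the northernmost row, matching the usual image convention.
#'
#' @param width,height Grid dimensions in pixels (>= 1).
#' @param pixel_size Pixel edge length in map units (metres); default 10,
#'   the native resolution of the Sentinel-2 visible/NIR bands.
#' @param origin_x,origin_y Map coordinates of the lower-left grid corner.
#' @param crs_label Free-text identifier of the coordinate reference system.
#'   Rasters and vectors are only combined when their labels agree; no
#'   reprojection is attempted.
#' @return An object of class `fm_grid`.
#' @export
grid_spec <- function(width, height, pixel_size = 10,
                      origin_x = 0, origin_y = 0,
                      crs_label = "local-metric") {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("grid dimensions must be >= 1")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(
    list(width = width, height = height, pixel_size = pixel_size,
         origin_x = origin_x, origin_y = origin_y, crs_label = crs_label),
    class = "fm_grid"
  )
}

#' @export
print.fm_grid <- function(x, ...) {
  cat(sprintf("<fm_grid> %d x %d px @ %g m, origin (%g, %g), crs '%s'\n",
              x$width, x$height, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b)) stop("grid mismatch between ", what)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with matrices `x` and `y` (height x width) of pixel-centre
#'   map coordinates, row 1 = north.
#' @export
pixel_centres <- function(grid) {
  px <- grid$pixel_size
  xs <- grid$origin_x + (seq_len(grid$width) - 0.5) * px
  ys <- grid$origin_y + (grid$height - seq_len(grid$height) + 0.5) * px
  list(x = matrix(xs, grid$height, grid$width, byrow = TRUE),
       y = matrix(ys, grid$height, grid$width))
}

empty_raster <- function(grid, fill = NA_real_) {
  matrix(fill, grid$height, grid$width)
}
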