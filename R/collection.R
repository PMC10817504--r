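#' Construct a scene
#'
#' One acquisition date's multiband surface-reflectance raster plus its
#' cloud bitmask band and metadata. All bands and the QA band must share the
#' grid shape; nodata is NA; finite values are unitless reflectance.
#'
#' @param bands Named list of numeric matrices (e.g. B2, B3, B4, B8).
#' @param qa Integer-valued matrix, the cloud bitmask (bits 10 and 11 flag
#'   opaque cloud and cirrus; both clear means cloudless).
#' @param date Acquisition date (`Date` or coercible).
#' @param cloud_pct Scene-level cloudy-pixel percentage metadatum, in
#'   \[0, 100\].
#' @param grid The [grid_spec()] the rasters live on.
#' @return An object of class `fm_scene`.
#' @export
scene <- function(bands, qa, date, cloud_pct, grid) {
  stopifnot(inherits(grid, "fm_grid"))
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be a named list")
  dims <- c(grid$height, grid$width)
  for (b in names(bands)) {
    if (!all(dim(bands[[b]]) == dims))
      stop("band ", b, " does not match the grid shape")
    v <- bands[[b]]
    if (any(!is.na(v) & !is.finite(v)))
      stop("band ", b, " contains non-finite, non-nodata values")
  }
  if (!all(dim(qa) == dims)) stop("qa band does not match the grid shape")
  if (cloud_pct < 0 || cloud_pct > 100)
    stop("cloud_pct must lie in [0, 100]")
  structure(
    list(bands = bands, qa = qa, date = as.Date(date),
         cloud_pct = cloud_pct, grid = grid),
    class = "fm_scene"
  )
}

#' @export
print.fm_scene <- function(x, ...) {
  cat(sprintf("<fm_scene> %s | bands: %s | cloud %.1f%%\n",
              format(x$date), paste(names(x$bands), collapse = ","),
              x$cloud_pct))
  invisible(x)
}

#' Construct a scene collection
#'
#' An ordered list of scenes sharing one grid; acquisition dates must be
#' strictly increasing (scenes are sorted, duplicates rejected).
#'
#' @param scenes List of [scene()] objects (may be empty only with `grid`).
#' @param grid Grid for an empty collection; otherwise taken from the scenes.
#' @return An object of class `fm_collection`.
#' @export
scene_collection <- function(scenes, grid = NULL) {
  if (length(scenes) == 0L) {
    if (is.null(grid)) stop("an empty collection needs an explicit grid")
    return(structure(list(scenes = list(), grid = grid),
                     class = "fm_collection"))
  }
  for (s in scenes) stopifnot(inherits(s, "fm_scene"))
  g <- scenes[[1]]$grid
  for (s in scenes) stop_if_grid_mismatch(g, s$grid, "scenes in a collection")
  dates <- as.Date(vapply(scenes, function(s) as.character(s$date), ""))
  if (anyDuplicated(dates)) stop("scene dates must be strictly increasing")
  scenes <- scenes[order(dates)]
  structure(list(scenes = scenes, grid = g), class = "fm_collection")
}

#' @export
length.fm_collection <- function(x) length(x$scenes)

#' @export
print.fm_collection <- function(x, ...) {
  cat(sprintf("<fm_collection> %d scene(s) on %d x %d grid\n",
              length(x$scenes), x$grid$height, x$grid$width))
  invisible(x)
}

scene_dates <- function(coll) {
  as.Date(vapply(coll$scenes, function(s) as.character(s$date), ""))
}

roi_mask <- function(roi, grid) {
  # roi: fm_compartments, a single ring matrix, or a list of ring matrices
  if (inherits(roi, "fm_compartments"))
    return(!is.na(rasterize_compartments(roi, grid)))
  rings <- if (is.matrix(roi)) list(roi) else roi
  if (!length(rings)) stop("empty roi")
  ctr <- pixel_centres(grid)
  pts <- cbind(as.vector(ctr$x), as.vector(ctr$y))
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) < 2) stop("roi rings must be n x 2 matrices")
    inside <- inside | mgcv::in.out(cbind(r[, 1], r[, 2]), pts)
  }
  matrix(inside, grid$height, grid$width)
}

#' Spatial filter: mask pixels outside a region of interest
#'
#' Pixels whose centre lies outside the ROI polygons are set to nodata in
#' every band; scenes are otherwise unchanged (the QA band is kept so cloud
#' statistics remain inspectable).
#'
#' @param coll An `fm_collection`.
#' @param roi An `fm_compartments`, a closed-ring `n x 2` matrix, or a list
#'   of such rings, in the grid's coordinate frame.
#' @return Filtered `fm_collection`.
#' @export
filter_bounds <- function(coll, roi) {
  stopifnot(inherits(coll, "fm_collection"))
  keep <- roi_mask(roi, coll$grid)
  if (!any(keep))
    warning("roi is disjoint from the grid: all pixels set to nodata")
  out <- coll
  out$scenes <- lapply(coll$scenes, function(s) {
    s$bands <- lapply(s$bands, function(b) { b[!keep] <- NA_real_; b })
    s
  })
  out
}

#' Temporal filter with a half-open window
#'
#' Retains scenes with `start <= date < end`, the convention of Earth-Engine
#' style date filtering.
#'
#' @param coll An `fm_collection`.
#' @param start,end Dates (coercible); `start` must precede `end`.
#' @return Filtered `fm_collection`.
#' @export
filter_date <- function(coll, start, end) {
  stopifnot(inherits(coll, "fm_collection"))
  start <- as.Date(start); end <- as.Date(end)
  if (!start < end) stop("start date must precede end date")
  d <- scene_dates(coll)
  keep <- d >= start & d < end
  out <- coll
  out$scenes <- coll$scenes[keep]
  out
}

#' Metadata cloud filter
#'
#' Keeps scenes whose scene-level cloudy-pixel percentage is less than or
#' equal to `max_pct` (inclusive, matching the usual
#' `CLOUDY_PIXEL_PERCENTAGE <= 5` prefilter).
#'
#' @param coll An `fm_collection`.
#' @param max_pct Maximum allowed cloudy-pixel percentage, in \[0, 100\].
#' @return Filtered `fm_collection`.
#' @export
filter_cloud_metadata <- function(coll, max_pct = 5) {
  stopifnot(inherits(coll, "fm_collection"))
  if (max_pct < 0 || max_pct > 100) stop("max_pct must lie in [0, 100]")
  keep <- vapply(coll$scenes, function(s) s$cloud_pct <= max_pct, logical(1))
  out <- coll
  out$scenes <- coll$scenes[keep]
  out
}

#' Mask cloudy pixels via the QA bitmask
#'
#' Any pixel with one of the cloud bits set (default bits 10 and 11: opaque
#' cloud and cirrus) becomes nodata in every band; clear pixels are
#' untouched.
#'
#' @param x An `fm_scene` or `fm_collection`.
#' @param cloud_bits Integer bit positions flagging clouds.
#' @return Object of the same class with cloudy pixels masked.
#' @export
mask_clouds <- function(x, cloud_bits = c(10L, 11L)) {
  if (inherits(x, "fm_collection")) {
    x$scenes <- lapply(x$scenes, mask_clouds, cloud_bits = cloud_bits)
    return(x)
  }
  stopifnot(inherits(x, "fm_scene"))
  if (is.null(x$qa)) stop("scene has no qa band")
  bitsum <- sum(bitwShiftL(1L, as.integer(cloud_bits)))
  cloudy <- bitwAnd(as.integer(x$qa), bitsum) != 0L
  cloudy <- matrix(cloudy, nrow(x$qa), ncol(x$qa))
  x$bands <- lapply(x$bands, function(b) { b[cloudy] <- NA_real_; b })
  x
}

#' Reduce a scene collection to a composite
#'
#' Per-pixel, per-band reduction over the non-nodata observations only.
#' `std` is the population standard deviation (divide by n), matching the
#' stdDev reducer used to standardize vegetation indices; set
#' `sample_std = TRUE` for the n-1 denominator. Pixels with zero valid
#' observations are nodata and the per-pixel observation count is returned.
#'
#' @param coll An `fm_collection` (may be empty: all-nodata composite).
#' @param reducer One of `"median"`, `"mean"`, `"std"`.
#' @param sample_std Use the sample (n-1) standard deviation instead of the
#'   population one.
#' @return An object of class `fm_composite`: `bands`, `reducer`, `period`
#'   (range of scene dates), `n_used` count matrix, `grid`.
#' @export
reduce_collection <- function(coll, reducer = c("median", "mean", "std"),
                              sample_std = FALSE) {
  stopifnot(inherits(coll, "fm_collection"))
  reducer <- match.arg(reducer)
  grid <- coll$grid
  band_names <- if (length(coll$scenes)) names(coll$scenes[[1]]$bands)
                else character()
  n_used <- matrix(0L, grid$height, grid$width)
  bands <- list()
  for (b in band_names) {
    arr <- band_stack(coll, b)
    bands[[b]] <- stack_reduce(arr, reducer, sample_std)
  }
  if (length(band_names)) {
    arr <- band_stack(coll, band_names[1])
    n_used <- matrix(as.integer(rowSums(!is.na(arr), dims = 2)),
                     grid$height, grid$width)
  }
  period <- if (length(coll$scenes)) range(scene_dates(coll))
            else as.Date(c(NA, NA))
  structure(list(bands = bands, reducer = reducer, period = period,
                 n_used = n_used, grid = grid),
            class = "fm_composite")
}

# height x width x n_scenes array of one band's observations.
band_stack <- function(coll, band) {
  g <- coll$grid
  array(unlist(lapply(coll$scenes, function(s) s$bands[[band]]),
               use.names = FALSE),
        dim = c(g$height, g$width, length(coll$scenes)))
}

# Vectorized masked reduction of a height x width x n array.
stack_reduce <- function(arr, reducer, sample_std = FALSE) {
  n <- rowSums(!is.na(arr), dims = 2)
  if (reducer == "median") {
    out <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
    out[n == 0] <- NA_real_
    return(out)
  }
  s <- rowSums(arr, dims = 2, na.rm = TRUE)
  m <- s / n
  if (reducer == "mean") {
    m[n == 0] <- NA_real_
    return(m)
  }
  ss <- rowSums(arr^2, dims = 2, na.rm = TRUE)
  v <- ss / n - m^2
  v[v < 0] <- 0 # guard tiny negative round-off
  if (sample_std) {
    v <- v * n / (n - 1)
    v[n < 2] <- NA_real_
  }
  out <- sqrt(v)
  out[n == 0] <- NA_real_
  out
}

#' @export
print.fm_composite <- function(x, ...) {
  cat(sprintf("<fm_composite> %s of %s | period %s..%s\n", x$reducer,
              paste(names(x$bands), collapse = ","),
              format(x$period[1]), format(x$period[2])))
  invisible(x)
}

#' True-colour display raster from a composite
#'
#' Stacks B4, B3, B2 as R, G, B and linearly stretches reflectance from
#' `range` to 0-255 (clamped, round-half-to-even). Nodata pixels get NA in
#' all three channels (transparent on export).
#'
#' @param comp An `fm_composite` containing B2, B3, B4.
#' @param range Length-2 reflectance stretch range; default 0 to 0.3.
#' @return height x width x 3 numeric array of 0-255 display values.
#' @export
make_rgb <- function(comp, range = c(0, 0.3)) {
  stopifnot(inherits(comp, "fm_composite"))
  need <- c("B4", "B3", "B2")
  miss <- setdiff(need, names(comp$bands))
  if (length(miss)) stop("composite lacks band(s): ",
                         paste(miss, collapse = ", "))
  stretch <- function(b) {
    v <- (b - range[1]) / (range[2] - range[1])
    v <- pmin(pmax(v, 0), 1)
    round(v * 255)
  }
  out <- array(NA_real_, c(comp$grid$height, comp$grid$width, 3L))
  for (i in 1:3) out[, , i] <- stretch(comp$bands[[need[i]]])
  out
}
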