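#' Construct an index raster
#'
#' Single-band floating-point raster (NDVI in \[-1, 1\], standardized
#' anomaly unbounded) with nodata as NA.
#'
#' @param values Numeric matrix.
#' @param index Index name, e.g. `"NDVI"` or `"ZNDVI"`.
#' @param period Free-text year or period label.
#' @param grid The [grid_spec()].
#' @return An object of class `fm_index`.
#' @export
index_raster <- function(values, index, period, grid) {
  stopifnot(inherits(grid, "fm_grid"))
  if (!all(dim(values) == c(grid$height, grid$width)))
    stop("values do not match the grid shape")
  structure(list(values = values, index = index, period = period,
                 grid = grid),
            class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<fm_index> %s (%s): %d valid px, range [%.3f, %.3f]\n",
              x$index, x$period, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - RED) / (NIR + RED)` per pixel, with RED = band 4 and
#' NIR = band 8. Nodata where either band is nodata or NIR + RED = 0
#' (division guard).
#'
#' @param x An `fm_composite` or `fm_scene` containing B4 and B8.
#' @param period Period label for the result; defaults to the composite
#'   period or scene date.
#' @return An `fm_index` named `"NDVI"`.
#' @export
ndvi <- function(x, period = NULL) {
  if (!inherits(x, c("fm_composite", "fm_scene")))
    stop("ndvi() expects a composite or scene")
  miss <- setdiff(c("B4", "B8"), names(x$bands))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  red <- x$bands$B4; nir <- x$bands$B8
  denom <- nir + red
  v <- (nir - red) / denom
  v[!is.na(denom) & denom == 0] <- NA_real_
  if (is.null(period)) {
    period <- if (inherits(x, "fm_scene")) format(x$date)
              else paste(format(x$period), collapse = "..")
  }
  index_raster(v, "NDVI", period, x$grid)
}

#' Per-pixel multi-year mean and standard deviation of annual index rasters
#'
#' The per-pixel statistics that standardize an annual NDVI into an anomaly:
#' the mean and population standard deviation over the years in which the
#' pixel is valid. Pixels valid in fewer than 2 years get nodata std (a
#' baseline cannot be estimated from one year).
#'
#' @param annual List of >= 2 `fm_index` rasters on one grid.
#' @param sample_std Use the n-1 denominator instead of the population one.
#' @return List with `fm_index` elements `mean` and `std`.
#' @export
multi_year_stats <- function(annual, sample_std = FALSE) {
  if (length(annual) < 2L) stop("need at least 2 annual rasters")
  grid <- annual[[1]]$grid
  for (a in annual) {
    stopifnot(inherits(a, "fm_index"))
    stop_if_grid_mismatch(grid, a$grid, "annual index rasters")
  }
  arr <- array(unlist(lapply(annual, `[[`, "values"), use.names = FALSE),
               dim = c(grid$height, grid$width, length(annual)))
  n <- rowSums(!is.na(arr), dims = 2)
  m <- stack_reduce(arr, "mean")
  s <- stack_reduce(arr, "std", sample_std = sample_std)
  s[n < 2] <- NA_real_
  lab <- paste(range(vapply(annual, function(a) a$period, "")),
               collapse = "-")
  list(mean = index_raster(m, paste0(annual[[1]]$index, "_mean"), lab, grid),
       std = index_raster(s, paste0(annual[[1]]$index, "_std"), lab, grid))
}

#' Standardized NDVI anomaly
#'
#' `Z = (NDVI - NDVI_mean) / NDVI_std` per pixel, the year's index
#' standardized against the multi-year baseline. Negative values mean
#' below-baseline vitality. Nodata where any input is nodata or where the
#' baseline std is 0 (a degenerate baseline must not masquerade as "no
#' anomaly").
#'
#' @param year_raster Annual `fm_index` (typically NDVI of the year's
#'   median composite).
#' @param mean,std Baseline rasters from [multi_year_stats()].
#' @return An `fm_index` named `"ZNDVI"`.
#' @export
zndvi <- function(year_raster, mean, std) {
  stopifnot(inherits(year_raster, "fm_index"), inherits(mean, "fm_index"),
            inherits(std, "fm_index"))
  stop_if_grid_mismatch(year_raster$grid, mean$grid, "index rasters")
  stop_if_grid_mismatch(year_raster$grid, std$grid, "index rasters")
  s <- std$values
  s[!is.na(s) & s == 0] <- NA_real_
  z <- (year_raster$values - mean$values) / s
  index_raster(z, "ZNDVI", year_raster$period, year_raster$grid)
}

#' ROI-median NDVI time series of a collection
#'
#' For each scene, NDVI is computed per pixel and the median over the
#' non-nodata ROI pixels is taken; scenes with zero valid ROI pixels are
#' omitted with a warning. This is the chart view of a forest's seasonal
#' greenness trajectory.
#'
#' @param coll An `fm_collection` (filter and mask it first as desired).
#' @param roi ROI as in [filter_bounds()], or NULL for the whole grid.
#' @return Data frame with columns `date` and `median_ndvi`, dates strictly
#'   increasing.
#' @export
median_timeseries <- function(coll, roi = NULL) {
  stopifnot(inherits(coll, "fm_collection"))
  keep <- if (is.null(roi)) matrix(TRUE, coll$grid$height, coll$grid$width)
          else roi_mask(roi, coll$grid)
  if (!any(keep)) stop("empty roi")
  rows <- lapply(coll$scenes, function(s) {
    v <- ndvi(s)$values[keep]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(date = s$date, median_ndvi = stats::median(v))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " scene(s) omitted: no valid ROI pixels")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(date = as.Date(character()),
                                      median_ndvi = numeric())
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality check on randomly sampled index pixels
#'
#' Samples `n` distinct non-nodata pixel locations uniformly without
#' replacement (seeded) and tests the sampled values for normality.
#'
#' @param index An `fm_index`.
#' @param n Sample size (default 100).
#' @param seed Integer seed for the sampling.
#' @return List with `statistic` (W), `p_value`, `n` and `seed`.
#' @export
normality_check <- function(index, n = 100, seed = 1L) {
  stopifnot(inherits(index, "fm_index"))
  valid <- which(!is.na(index$values))
  if (length(valid) < n)
    stop("fewer than ", n, " valid pixels available for sampling")
  vals <- with_seed(as.integer(seed), {
    index$values[sample(valid, n)]
  })
  if (length(unique(vals)) == 1L)
    stop("sampled values are constant; normality test undefined")
  ht <- stats::shapiro.test(vals)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = n, seed = as.integer(seed))
}
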