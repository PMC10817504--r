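#' Damage ratio of a compartment report
#'
#' Damaged area as a percentage of the compartment's total area:
#' `ratio = damaged_area / total_area * 100`.
#'
#' @param damaged_area,total_area Areas in hectares; `total_area > 0` and
#'   `0 <= damaged_area <= total_area`.
#' @return Percentage in \[0, 100\] (vectorized).
#' @export
damage_ratio <- function(damaged_area, total_area) {
  if (any(total_area <= 0)) stop("total_area must be > 0")
  if (any(damaged_area < 0 | damaged_area > total_area))
    stop("damaged_area must lie in [0, total_area]")
  100 * damaged_area / total_area
}

new_damage_map <- function(values, source, year, grid) {
  ok <- is.na(values) | values %in% c(0, 1)
  if (!all(ok)) stop("damage map values must be 0, 1 or nodata")
  structure(list(values = values, source = source, year = year, grid = grid),
            class = "fm_damage_map")
}

#' @export
print.fm_damage_map <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<fm_damage_map> %s %s: %d damage / %d no-damage / %d nodata px\n",
    x$source, as.character(x$year), sum(v == 1, na.rm = TRUE),
    sum(v == 0, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Rasterized reference damage map from compartment reports
#'
#' Each compartment's pixels (pixel-centre containment) are set to 1 when
#' the compartment's reported damage ratio for the year reaches the
#' threshold and 0 otherwise; compartments without a report for the year
#' count as 0 (no damage); pixels outside all compartments are nodata.
#' A ratio exactly at the threshold counts as damage (ties toward damage:
#' the reclassification rule assigns "below" to 0 and "above" to 1 and
#' leaves the boundary open, so the conservative-for-detection side is
#' taken and documented).
#'
#' @param compartments An `fm_compartments`.
#' @param reports Report data frame as produced by [make_reports()] (needs
#'   `compartment_id`, `year`, and either `damage_ratio_pct` or the two
#'   area columns).
#' @param year Year to rasterize.
#' @param grid Target grid (defaults to the compartments' grid).
#' @param ratio_threshold Damage-ratio reclassification threshold in
#'   percent; default 30.
#' @return An `fm_damage_map` with source `"reference"`.
#' @export
reference_damage_map <- function(compartments, reports, year,
                                 grid = compartments$grid,
                                 ratio_threshold = 30) {
  stopifnot(inherits(compartments, "fm_compartments"))
  tab <- compartments$table
  if (nrow(reports) && any(!reports$compartment_id %in% tab$id))
    stop("report references unknown compartment id: ",
         paste(setdiff(reports$compartment_id, tab$id), collapse = ", "))
  rep_y <- reports[reports$year == year, , drop = FALSE]
  ratio <- if ("damage_ratio_pct" %in% names(rep_y)) rep_y$damage_ratio_pct
           else damage_ratio(rep_y$damaged_area_ha, rep_y$total_area_ha)
  damaged_ids <- rep_y$compartment_id[ratio >= ratio_threshold]
  ids <- rasterize_compartments(compartments, grid)
  vals <- ifelse(is.na(ids), NA_real_,
                 ifelse(ids %in% damaged_ids, 1, 0))
  vals <- matrix(vals, grid$height, grid$width)
  new_damage_map(vals, "reference", year, grid)
}

#' Threshold a standardized-anomaly raster into a binary damage map
#'
#' A pixel is classified as forest damage when its anomaly value is
#' strictly below the threshold (default -0.5); values at or above the
#' threshold are no-damage; nodata propagates. Internally damage is coded
#' 1; use [damage_coding()] to export the inverted convention in which 0
#' marks damage.
#'
#' @param z An `fm_index` (standardized anomaly).
#' @param threshold Z-score threshold; default -0.5.
#' @param year Year tag for the result (defaults to the raster's period).
#' @return An `fm_damage_map` with source `"classified"`.
#' @export
classify_damage <- function(z, threshold = -0.5, year = z$period) {
  stopifnot(inherits(z, "fm_index"))
  vals <- ifelse(is.na(z$values), NA_real_,
                 ifelse(z$values < threshold, 1, 0))
  vals <- matrix(vals, z$grid$height, z$grid$width)
  new_damage_map(vals, "classified", year, z$grid)
}

#' Flip between the two binary damage codings
#'
#' Internally the package codes damage as 1. Field rasters sometimes use
#' the inverted convention (0 = damage, 1 = no damage); this flips a map
#' between the two. Applying it twice is the identity.
#'
#' @param map An `fm_damage_map`.
#' @param convention `"damage1"` (package-internal) or `"damage0"`.
#' @return The map, recoded; nodata untouched.
#' @export
damage_coding <- function(map, convention = c("damage1", "damage0")) {
  stopifnot(inherits(map, "fm_damage_map"))
  convention <- match.arg(convention)
  current <- attr(map, "coding")
  if (is.null(current)) current <- "damage1"
  if (current != convention) {
    map$values <- 1 - map$values
    attr(map, "coding") <- convention
  }
  map
}

#' Confusion matrix of classified against reference damage
#'
#' Counts over pixels that are non-nodata in both maps; rows are the
#' classified map, columns the reference.
#'
#' @param classified,reference `fm_damage_map`s on one grid and year.
#' @return An object of class `fm_confusion` with counts `n11` (classified
#'   damage, reference damage), `n10` (classified damage only), `n01`
#'   (reference damage only), `n00`, plus `total` and `year`.
#' @export
confusion <- function(classified, reference) {
  stopifnot(inherits(classified, "fm_damage_map"),
            inherits(reference, "fm_damage_map"))
  stop_if_grid_mismatch(classified$grid, reference$grid, "damage maps")
  c_ <- classified$values; r_ <- reference$values
  ok <- !is.na(c_) & !is.na(r_)
  if (!any(ok))
    warning("no co-valid pixels: empty confusion matrix")
  n11 <- sum(c_ == 1 & r_ == 1 & ok, na.rm = TRUE)
  n10 <- sum(c_ == 1 & r_ == 0 & ok, na.rm = TRUE)
  n01 <- sum(c_ == 0 & r_ == 1 & ok, na.rm = TRUE)
  n00 <- sum(c_ == 0 & r_ == 0 & ok, na.rm = TRUE)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 total = n11 + n10 + n01 + n00, year = classified$year),
            class = "fm_confusion")
}

#' @export
print.fm_confusion <- function(x, ...) {
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2, 2,
              dimnames = list(classified = c("damage", "no damage"),
                              reference = c("damage", "no damage")))
  cat(sprintf("<fm_confusion> year %s, %d px\n", as.character(x$year),
              x$total))
  print(m)
  invisible(x)
}

#' Producer's, user's and total accuracy of a damage confusion matrix
#'
#' `PA = 100 n11 / (n11 + n01)` (reference damage correctly found),
#' `UA = 100 n11 / (n11 + n10)` (classified damage that is real),
#' `TA = 100 (n11 + n00) / total`. An empty denominator yields NA (flagged
#' not-applicable rather than 0). Values are returned at full precision;
#' round to 2 decimals (half-to-even) for reporting.
#'
#' @param m An `fm_confusion`.
#' @return Data frame row with `year`, `producer_pct`, `user_pct`,
#'   `total_pct`.
#' @export
accuracies <- function(m) {
  stopifnot(inherits(m, "fm_confusion"))
  if (m$total == 0) stop("empty confusion matrix: no co-valid pixels")
  pa <- if (m$n11 + m$n01 > 0) 100 * m$n11 / (m$n11 + m$n01) else NA_real_
  ua <- if (m$n11 + m$n10 > 0) 100 * m$n11 / (m$n11 + m$n10) else NA_real_
  ta <- 100 * (m$n11 + m$n00) / m$total
  data.frame(year = m$year, producer_pct = pa, user_pct = ua,
             total_pct = ta)
}

#' Mean accuracies over years
#'
#' Arithmetic mean of the per-year producer's, user's and total accuracies
#' (NA entries excluded with a warning).
#'
#' @param per_year Data frame of [accuracies()] rows.
#' @return One-row data frame with `producer_pct`, `user_pct`, `total_pct`.
#' @export
mean_accuracies <- function(per_year) {
  if (nrow(per_year) < 1L) stop("need at least one year of accuracies")
  if (anyNA(per_year[c("producer_pct", "user_pct", "total_pct")]))
    warning("NA accuracy entries excluded from the mean")
  data.frame(
    producer_pct = mean(per_year$producer_pct, na.rm = TRUE),
    user_pct = mean(per_year$user_pct, na.rm = TRUE),
    total_pct = mean(per_year$total_pct, na.rm = TRUE)
  )
}
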