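# Raster files are written as multi-page TIFF (one 32-bit page per band,
# one 1-bit-equivalent mask page per band) plus a JSON sidecar
# ("<file>.json") carrying the grid, band names, per-band offset/scale and
# object metadata. Values are stored as (v - offset)/scale quantized to
# 32 bits, so integer rasters round-trip bit-exactly and floats to well
# below float32 precision. Readers accept any TIFF whose page count matches
# its sidecar; no GeoTIFF geo-tags are interpreted.

sidecar_path <- function(path) paste0(path, ".json")

encode_band <- function(v) {
  fin <- v[!is.na(v)]
  if (!length(fin)) {
    return(list(data = matrix(0, nrow(v), ncol(v)),
                mask = matrix(0, nrow(v), ncol(v)),
                offset = 0, scale = 1,
                integer = FALSE))
  }
  off <- min(fin); rng <- max(fin) - off
  scale <- if (rng > 0) rng else 1
  u <- (v - off) / scale
  u[is.na(u)] <- 0
  list(data = u, mask = (!is.na(v)) * 1, offset = off, scale = scale,
       integer = all(fin == round(fin)))
}

#' Write a multiband raster with sidecar metadata
#'
#' @param bands Named list of numeric matrices (NA = nodata).
#' @param path Output TIFF path; a `<path>.json` sidecar is written next to
#'   it.
#' @param grid The [grid_spec()].
#' @param meta Optional list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(bands, path, grid, meta = list()) {
  stopifnot(inherits(grid, "fm_grid"))
  if (is.null(names(bands))) stop("bands must be named")
  enc <- lapply(bands, encode_band)
  pages <- c(lapply(enc, `[[`, "data"), lapply(enc, `[[`, "mask"))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(
    format = "forestmon-raster-v1",
    grid = unclass(grid),
    bands = lapply(names(bands), function(b) list(
      name = b, offset = enc[[b]]$offset, scale = enc[[b]]$scale,
      integer = enc[[b]]$integer)),
    meta = meta
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return List with `bands` (named matrices, NA = nodata), `grid`, `meta`.
#' @export
read_raster <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (!file.exists(sp))
    stop("missing sidecar for ", path, ": ", sp,
         " (field 'grid' unavailable)")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  g <- side$grid
  grid <- grid_spec(g$width, g$height, g$pixel_size, g$origin_x, g$origin_y,
                    g$crs_label)
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- if (is.data.frame(side$bands)) nrow(side$bands) else length(side$bands)
  if (length(pages) != 2L * nb)
    stop("malformed raster ", path, ": expected ", 2L * nb,
         " TIFF pages (field 'bands'), found ", length(pages))
  getb <- function(i, f) {
    if (is.data.frame(side$bands)) side$bands[[f]][i] else side$bands[[i]][[f]]
  }
  bands <- list()
  maxint <- 2^32 - 1
  for (i in seq_len(nb)) {
    u <- pages[[i]]
    mask <- pages[[nb + i]] > 0.5
    v <- u * getb(i, "scale") + getb(i, "offset")
    if (isTRUE(getb(i, "integer"))) v <- round(v)
    v[!mask] <- NA_real_
    if (!all(dim(v) == c(grid$height, grid$width)))
      stop("malformed raster ", path, ": page shape does not match grid")
    bands[[getb(i, "name")]] <- v
  }
  meta <- side$meta
  list(bands = bands, grid = grid, meta = if (is.null(meta)) list() else meta)
}

#' Write / read a scene (bands + QA bitmask + metadata)
#'
#' @param s An `fm_scene`.
#' @param path TIFF path.
#' @return `write_scene`: the path, invisibly; `read_scene`: an `fm_scene`.
#' @export
write_scene <- function(s, path) {
  stopifnot(inherits(s, "fm_scene"))
  bands <- c(s$bands, list(QA = s$qa + 0))
  write_raster(bands, path, s$grid,
               meta = list(type = "scene", date = format(s$date),
                           cloud_pct = s$cloud_pct))
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  r <- read_raster(path)
  if (!"QA" %in% names(r$bands))
    stop("malformed scene ", path, ": no QA band")
  qa <- r$bands$QA
  qa[is.na(qa)] <- 0
  scene(bands = r$bands[setdiff(names(r$bands), "QA")],
        qa = matrix(as.integer(qa), r$grid$height, r$grid$width),
        date = as.Date(r$meta$date), cloud_pct = r$meta$cloud_pct,
        grid = r$grid)
}

#' Write / read an index raster
#'
#' @param x An `fm_index`.
#' @param path TIFF path.
#' @return `write_index`: the path, invisibly; `read_index`: an `fm_index`.
#' @export
write_index <- function(x, path) {
  stopifnot(inherits(x, "fm_index"))
  write_raster(stats::setNames(list(x$values), x$index), path, x$grid,
               meta = list(type = "index", index = x$index,
                           period = as.character(x$period)))
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  r <- read_raster(path)
  index_raster(r$bands[[1]], r$meta$index, r$meta$period, r$grid)
}

#' Write / read a binary damage map
#'
#' @param map An `fm_damage_map`.
#' @param path TIFF path.
#' @param convention Binary coding to export, see [damage_coding()].
#' @return `write_damage_map`: the path, invisibly; `read_damage_map`: an
#'   `fm_damage_map` (normalized back to the internal 1 = damage coding).
#' @export
write_damage_map <- function(map, path, convention = "damage1") {
  stopifnot(inherits(map, "fm_damage_map"))
  map <- damage_coding(map, convention)
  write_raster(list(damage = map$values), path, map$grid,
               meta = list(type = "damage", source = map$source,
                           year = as.character(map$year),
                           coding = convention))
}

#' @rdname write_damage_map
#' @export
read_damage_map <- function(path) {
  r <- read_raster(path)
  map <- new_damage_map(r$bands$damage, r$meta$source, r$meta$year, r$grid)
  attr(map, "coding") <- r$meta$coding
  damage_coding(map, "damage1")
}

#' Write compartments as GeoJSON
#'
#' Features carry `id`, `species_code`, `species_name` and `area_ha`;
#' geometry is the compartment polygon ring in the grid's coordinate frame
#' (the `crs_label` is recorded as a foreign member).
#'
#' @param comp An `fm_compartments`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(comp, path) {
  stopifnot(inherits(comp, "fm_compartments"))
  feats <- lapply(seq_len(nrow(comp$table)), function(i) {
    ring <- comp$polygons[[i]]
    list(
      type = "Feature",
      properties = list(id = comp$table$id[i],
                        species_code = comp$table$species_code[i],
                        species_name = comp$table$species_name[i],
                        area_ha = comp$table$area_ha[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ])))
    )
  })
  obj <- list(type = "FeatureCollection", crs_label = comp$grid$crs_label,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read compartments from GeoJSON
#'
#' Accepts Polygon features with `id` and `species_code` properties
#' (`area_ha` is recomputed from the rasterized geometry when absent).
#'
#' @param path GeoJSON path.
#' @param grid The [grid_spec()] the compartments refer to.
#' @return An `fm_compartments` (general-polygon flavour: rasterization
#'   uses pixel-centre point-in-polygon).
#' @export
read_compartments <- function(path, grid) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$features)) stop("not a FeatureCollection: ", path)
  leg <- species_legend()
  rows <- list(); polys <- list()
  for (k in seq_along(obj$features)) {
    f <- obj$features[[k]]
    p <- f$properties
    fid <- if (!is.null(p$id)) p$id else k
    if (is.null(p$species_code))
      stop("feature id ", fid, " in ", path, " lacks field 'species_code'")
    code <- as.integer(p$species_code)
    if (!code %in% leg)
      stop("feature id ", fid, " has species_code ", code,
           " outside the legend")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) as.numeric(unlist(xy))))
    rows[[k]] <- data.frame(
      id = as.integer(fid), species_code = code,
      species_name = names(leg)[match(code, leg)],
      npx = NA_integer_,
      area_ha = if (!is.null(p$area_ha)) as.numeric(p$area_ha) else NA_real_)
    polys[[k]] <- m
  }
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$id)) stop("duplicate compartment ids in ", path)
  comp <- structure(list(table = tab, rects = NULL, polygons = polys,
                         grid = grid),
                    class = "fm_compartments")
  ids <- rasterize_compartments(comp)
  comp$table$npx <- as.integer(tabulate(match(ids, comp$table$id),
                                        nbins = nrow(tab)))
  need <- is.na(comp$table$area_ha)
  comp$table$area_ha[need] <-
    comp$table$npx[need] * grid$pixel_size^2 / 1e4
  comp
}

#' Write / read damage-report tables as CSV
#'
#' Reading validates the report domain: areas non-negative,
#' `damaged_area_ha <= total_area_ha` (the damage ratio is only defined on
#' that domain), percentages in \[0, 100\].
#'
#' @param reports Report data frame ([make_reports()] schema).
#' @param path CSV path.
#' @return `write_reports`: the path, invisibly; `read_reports`: the
#'   validated data frame.
#' @export
write_reports <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  rep <- utils::read.csv(path)
  need <- c("compartment_id", "year", "damaged_area_ha", "total_area_ha")
  miss <- setdiff(need, names(rep))
  if (length(miss))
    stop("report file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(rep$total_area_ha <= 0))
    stop("report file ", path, ": total_area_ha must be > 0")
  bad <- rep$damaged_area_ha > rep$total_area_ha | rep$damaged_area_ha < 0
  if (any(bad))
    stop("report file ", path, ": damaged_area_ha outside [0, total_area_ha] ",
         "(damage ratio undefined) in row(s) ",
         paste(which(bad), collapse = ", "))
  if (!"damage_ratio_pct" %in% names(rep))
    rep$damage_ratio_pct <- damage_ratio(rep$damaged_area_ha,
                                         rep$total_area_ha)
  rep
}

#' Read a simulation/run configuration from YAML
#'
#' The YAML mirrors the [sim_config()] arguments (`grid:` with
#' width/height/pixel_size/..., `years`, `doys`, `n_compartments`,
#' `species_mix`, `noise_sd`, `damage_events:` list, cloud settings,
#' `seed`) plus optional pipeline parameters (`max_cloud_pct`,
#' `z_threshold`, `ratio_threshold`, `species_year`, `rf:` with
#' `n_trees`/`vars_per_split`).
#'
#' @param path YAML file.
#' @return List with `config` (an `fm_simconfig`) and `params` (pipeline
#'   parameter list).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$grid)) stop("config ", path, " lacks a 'grid' section")
  g <- y$grid
  grid <- grid_spec(g$width, g$height,
                    pixel_size = g$pixel_size %||% 10,
                    origin_x = g$origin_x %||% 0,
                    origin_y = g$origin_y %||% 0,
                    crs_label = g$crs_label %||% "local-metric")
  ev <- if (is.null(y$damage_events)) empty_damage_events() else
    do.call(rbind, lapply(y$damage_events, as.data.frame))
  cfg <- sim_config(
    grid = grid,
    years = y$years %||% 2017:2020,
    doys = y$doys %||% c(105, 135, 165, 195, 225, 255, 285),
    n_compartments = y$n_compartments %||% 24,
    species_mix = y$species_mix %||% c(0.20, 0.15, 0.35, 0.15, 0.15),
    phenology = default_phenology(noise_sd = y$noise_sd %||% 0.02),
    damage_events = ev,
    cloud_prob_clear = y$cloud_prob_clear %||% 0.4,
    cloud_max_fraction = y$cloud_max_fraction %||% 0.25,
    seed = y$seed %||% 42L
  )
  params <- list(
    max_cloud_pct = y$max_cloud_pct %||% 5,
    z_threshold = y$z_threshold %||% -0.5,
    ratio_threshold = y$ratio_threshold %||% 30,
    species_year = y$species_year %||% max(cfg$years),
    rf_n_trees = (y$rf$n_trees) %||% 100,
    rf_vars_per_split = (y$rf$vars_per_split) %||% 10
  )
  list(config = cfg, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
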