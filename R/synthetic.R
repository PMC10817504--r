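#' Generate forest compartment polygons with known attributes
#'
#' Tiles the full grid extent with `n_compartments` non-overlapping
#' axis-aligned rectangles by recursive seeded splitting (always splitting
#' the currently largest rectangle at a random pixel boundary along its
#' longer side), then assigns each compartment a dominant-species code drawn
#' from the configured mixture by largest-remainder apportionment followed
#' by a seeded shuffle — so per-class compartment counts always sum to
#' `n_compartments` and every class with a positive share of the
#' apportionment is present.
#'
#' @param config An [sim_config()].
#' @return An object of class `fm_compartments`: a `table` data frame
#'   (`id`, `species_code`, `species_name`, `npx`, `area_ha`), the pixel
#'   rectangles, closed polygon rings in map coordinates, and the grid.
#' @export
make_compartments <- function(config) {
  stopifnot(inherits(config, "fm_simconfig"))
  grid <- config$grid
  n <- config$n_compartments
  if (n < 1L) stop("n_compartments must be >= 1")
  if (n > grid$width * grid$height)
    stop("grid too small to host ", n, " compartments (",
         grid$width * grid$height, " pixels)")

  min_px <- max(1L, config$min_compartment_px %||% 1L)
  if (n * min_px > grid$width * grid$height)
    stop("grid too small to host ", n, " compartments of >= ", min_px,
         " pixels")

  with_seed(derive_seed(config$seed, salt = 1L), {
    # rects as (row0, row1, col0, col1), 1-based inclusive pixel ranges;
    # always split the largest rect, at a cut keeping both children >= min_px
    rects <- list(c(1L, grid$height, 1L, grid$width))
    while (length(rects) < n) {
      sizes <- vapply(rects, function(r)
        (r[2] - r[1] + 1L) * (r[4] - r[3] + 1L), numeric(1))
      ord <- order(sizes, decreasing = TRUE)
      split_done <- FALSE
      for (i in ord) {
        r <- rects[[i]]
        h <- r[2] - r[1] + 1L; w <- r[4] - r[3] + 1L
        # candidate child sizes k along the longer side, shorter side s
        if (h >= w) { len <- h; s <- w } else { len <- w; s <- h }
        kmin <- ceiling(min_px / s)
        if (2L * kmin > len) next # cannot split without undershooting
        k <- kmin + sample.int(len - 2L * kmin + 1L, 1L) - 1L
        if (h >= w) {
          cut <- r[1] + k - 1L
          a <- c(r[1], cut, r[3], r[4]); b <- c(cut + 1L, r[2], r[3], r[4])
        } else {
          cut <- r[3] + k - 1L
          a <- c(r[1], r[2], r[3], cut); b <- c(r[1], r[2], cut + 1L, r[4])
        }
        rects[[i]] <- a
        rects[[length(rects) + 1L]] <- b
        split_done <- TRUE
        break
      }
      if (!split_done)
        stop("grid too small to host ", n, " compartments of >= ", min_px,
             " pixels")
    }

    codes <- apportion_species(config$species_mix, n)
    codes <- codes[sample.int(n)]

    px <- grid$pixel_size
    npx <- vapply(rects, function(r)
      (r[2] - r[1] + 1) * (r[4] - r[3] + 1), numeric(1))
    polys <- lapply(rects, function(r) {
      x0 <- grid$origin_x + (r[3] - 1) * px
      x1 <- grid$origin_x + r[4] * px
      y1 <- grid$origin_y + (grid$height - r[1] + 1) * px # north edge
      y0 <- grid$origin_y + (grid$height - r[2]) * px     # south edge
      cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
    })
    leg <- species_legend()
    tab <- data.frame(
      id = seq_len(n),
      species_code = codes,
      species_name = names(leg)[codes],
      npx = as.integer(npx),
      area_ha = npx * px * px / 1e4
    )
    structure(list(table = tab, rects = rects, polygons = polys, grid = grid),
              class = "fm_compartments")
  })
}

# Largest-remainder apportionment of n compartments over mixture shares.
apportion_species <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(mix), times = base)
}

#' @export
print.fm_compartments <- function(x, ...) {
  cat(sprintf("<fm_compartments> %d compartments on %d x %d grid\n",
              nrow(x$table), x$grid$height, x$grid$width))
  print(utils::head(x$table, 6))
  invisible(x)
}

#' Rasterize compartments to a compartment-id grid
#'
#' Pixel-centre containment: a pixel belongs to the compartment whose
#' polygon contains its centre; pixels outside all compartments are NA.
#' Rectangle-tiled synthetic compartments are rasterized exactly from their
#' pixel bounds; general polygons (e.g. read from GeoJSON) use a
#' point-in-polygon test on the pixel centres.
#'
#' @param comp An `fm_compartments`.
#' @param grid Target [grid_spec()]; defaults to the compartments' own grid.
#' @return Integer matrix of compartment ids (NA outside).
#' @export
rasterize_compartments <- function(comp, grid = comp$grid) {
  stop_if_grid_mismatch(comp$grid, grid, "compartments and target grid")
  ids <- matrix(NA_integer_, grid$height, grid$width)
  if (!is.null(comp$rects)) {
    for (i in seq_along(comp$rects)) {
      r <- comp$rects[[i]]
      ids[r[1]:r[2], r[3]:r[4]] <- comp$table$id[i]
    }
  } else {
    ctr <- pixel_centres(grid)
    pts <- cbind(as.vector(ctr$x), as.vector(ctr$y))
    for (i in seq_along(comp$polygons)) {
      inside <- mgcv::in.out(comp$polygons[[i]], pts)
      ids[matrix(inside, grid$height, grid$width)] <- comp$table$id[i]
    }
  }
  ids
}

#' Generate one year's synthetic scene collection
#'
#' One [scene()] per configured acquisition day. Reflectance follows the
#' species phenology of the pixel's compartment plus Gaussian noise; damage
#' events of the requested year reduce NIR reflectance by `severity` over
#' the affected fraction of the compartment (pixels taken in row-major
#' order, so the affected set is deterministic); random elliptical cloud
#' fields set QA bits 10 and 11, brighten the covered pixels, and the
#' scene's cloudy-pixel percentage metadatum is computed from the final
#' bitmask. The exact set of damage-depressed pixels is attached as
#' attribute `damage_truth` (and via [damage_truth()]), so detection
#' precision/recall can be scored against ground truth.
#'
#' @param config An [sim_config()].
#' @param year One of `config$years`.
#' @param compartments Optional precomputed [make_compartments()] result for
#'   the same config (it is deterministic, so passing it is only a speed-up).
#' @return An `fm_collection` with attributes `year` and `damage_truth`.
#' @export
make_collection <- function(config, year, compartments = NULL) {
  stopifnot(inherits(config, "fm_simconfig"))
  year <- as.integer(year)
  if (!year %in% config$years) stop("year ", year, " is not simulated")
  if (is.null(compartments)) compartments <- make_compartments(config)
  grid <- config$grid
  ids <- rasterize_compartments(compartments)
  code_of <- compartments$table$species_code[match(ids, compartments$table$id)]
  species <- matrix(code_of, grid$height, grid$width)
  leg <- species_legend()
  phen <- config$phenology[names(leg)]

  truth <- damage_truth_mask(config, year, compartments)

  scenes <- lapply(config$doys, function(doy) {
    with_seed(derive_seed(config$seed, year, doy), {
      bands <- synth_bands(species, phen, doy, leg)
      # damage: multiplicative NIR depression over the affected pixels
      ev <- config$damage_events
      ev <- ev[ev$year == year, , drop = FALSE]
      if (nrow(ev)) {
        sev <- severity_mask(ev, compartments, grid)
        bands$B8 <- bands$B8 * (1 - sev)
      }
      # clouds
      qa <- matrix(0L, grid$height, grid$width)
      u <- stats::runif(1)
      frac <- if (u < config$cloud_prob_clear) 0 else
        stats::runif(1, 0, config$cloud_max_fraction)
      if (frac > 0) {
        cl <- cloud_field(grid, frac)
        qa[cl] <- bitwOr(bitwShiftL(1L, 10L), bitwShiftL(1L, 11L)) # 3072
        for (b in names(bands)) bands[[b]][cl] <- 0.85
      }
      noise_by <- vapply(phen, function(p) p$noise_sd, numeric(1))
      sdmat <- matrix(noise_by[species], grid$height, grid$width)
      if (any(sdmat > 0)) {
        for (b in names(bands)) {
          bands[[b]] <- bands[[b]] +
            stats::rnorm(length(sdmat), 0, 1) * sdmat
          bands[[b]] <- pmin(pmax(bands[[b]], 0), 1)
        }
      }
      scene(bands = bands, qa = qa,
            date = as.Date(doy - 1, origin = as.Date(sprintf("%d-01-01", year))),
            cloud_pct = 100 * mean(qa != 0L),
            grid = grid)
    })
  })
  coll <- scene_collection(scenes)
  attr(coll, "year") <- year
  attr(coll, "damage_truth") <- truth
  coll
}

# Noiseless band stack for a species-code raster at one day of year.
synth_bands <- function(species, phen, doy, leg) {
  refl <- vapply(phen, phenology_reflectance, numeric(4), doy = doy)
  # refl: 4 x 5 matrix, rows B2,B3,B4,B8
  out <- lapply(seq_len(4), function(b) {
    m <- matrix(refl[b, species], nrow(species), ncol(species))
    m
  })
  names(out) <- rownames(refl)
  out
}

# Per-pixel NIR-reduction severity implied by this year's events.
severity_mask <- function(ev, compartments, grid) {
  sev <- matrix(0, grid$height, grid$width)
  tab <- compartments$table
  for (k in seq_len(nrow(ev))) {
    i <- match(ev$compartment_id[k], tab$id)
    if (is.na(i)) stop("damage event references unknown compartment id ",
                       ev$compartment_id[k])
    r <- compartments$rects[[i]]
    nr <- r[2] - r[1] + 1L; nc <- r[4] - r[3] + 1L
    n_aff <- floor(ev$affected_fraction[k] * nr * nc)
    if (n_aff < 1) next
    sub <- matrix(FALSE, nr, nc)
    ord <- order(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
    sub[ord[seq_len(n_aff)]] <- TRUE
    block <- sev[r[1]:r[2], r[3]:r[4]]
    block[sub] <- pmax(block[sub], ev$severity[k])
    sev[r[1]:r[2], r[3]:r[4]] <- block
  }
  sev
}

# Logical mask of pixels whose NIR is depressed in `year` (severity > 0).
damage_truth_mask <- function(config, year, compartments) {
  ev <- config$damage_events
  ev <- ev[ev$year == year, , drop = FALSE]
  if (!nrow(ev)) return(matrix(FALSE, config$grid$height, config$grid$width))
  severity_mask(ev, compartments, config$grid) > 0
}

#' Ground-truth damaged-pixel mask of a synthetic collection
#'
#' @param coll A collection produced by [make_collection()].
#' @return Logical matrix, TRUE where the generator depressed NIR that year.
#' @export
damage_truth <- function(coll) {
  t <- attr(coll, "damage_truth")
  if (is.null(t)) stop("collection carries no damage ground truth")
  t
}

# Random elliptical cloud blobs until the masked fraction reaches `frac`.
cloud_field <- function(grid, frac) {
  mask <- matrix(FALSE, grid$height, grid$width)
  target <- frac * length(mask)
  rows <- row(mask); cols <- col(mask)
  tries <- 0L
  while (sum(mask) < target && tries < 200L) {
    cx <- stats::runif(1, 1, grid$width)
    cy <- stats::runif(1, 1, grid$height)
    a <- stats::runif(1, 2, max(4, grid$width / 4))
    b <- stats::runif(1, 2, max(4, grid$height / 4))
    th <- stats::runif(1, 0, pi)
    dx <- cols - cx; dy <- rows - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
    tries <- tries + 1L
  }
  mask
}

#' Build compartment-level damage reports from the configured events
#'
#' One report row per (compartment, year) pair that has at least one damage
#' event: the damaged area is the affected fraction times the compartment
#' area (summed over events, capped at the compartment area) and the damage
#' ratio is damaged area / total area x 100. Compartment-years without
#' events get no row; downstream they count as 0% damage.
#'
#' @param config An [sim_config()].
#' @param compartments Optional precomputed compartment set.
#' @return Data frame with columns `compartment_id`, `year`, `damage_type`,
#'   `damaged_area_ha`, `total_area_ha`, `damage_ratio_pct`,
#'   `frequency_pct`, `intensity_pct`.
#' @export
make_reports <- function(config, compartments = NULL) {
  stopifnot(inherits(config, "fm_simconfig"))
  if (is.null(compartments)) compartments <- make_compartments(config)
  ev <- config$damage_events
  tab <- compartments$table
  if (nrow(ev) && any(!ev$compartment_id %in% tab$id))
    stop("damage event references unknown compartment id: ",
         paste(setdiff(ev$compartment_id, tab$id), collapse = ", "))
  if (!nrow(ev)) {
    return(data.frame(compartment_id = integer(), year = integer(),
                      damage_type = character(), damaged_area_ha = numeric(),
                      total_area_ha = numeric(), damage_ratio_pct = numeric(),
                      frequency_pct = numeric(), intensity_pct = numeric()))
  }
  key <- interaction(ev$compartment_id, ev$year, drop = TRUE)
  rows <- lapply(split(ev, key), function(g) {
    area <- tab$area_ha[match(g$compartment_id[1], tab$id)]
    frac <- min(sum(g$affected_fraction), 1)
    data.frame(
      compartment_id = g$compartment_id[1],
      year = g$year[1],
      damage_type = paste(unique(g$damage_type), collapse = "+"),
      damaged_area_ha = frac * area,
      total_area_ha = area,
      damage_ratio_pct = 100 * frac,
      frequency_pct = 100 * frac,
      intensity_pct = 100 * max(g$severity)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$compartment_id), ]
  rownames(out) <- NULL
  out
}
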