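#' Simulation configuration
#'
#' Bundles everything the synthetic-scene generator needs: the pixel grid,
#' the simulated years and acquisition days, the compartment count and
#' species mixture, the phenology set, damage events, the cloud model and
#' the master seed. Identical configs (including seed) produce bit-identical
#' scenes, compartments and reports.
#'
#' @param grid A [grid_spec()].
#' @param years Integer vector of simulated years.
#' @param doys Integer vector of acquisition days-of-year, used in every
#'   year; must lie inside the vegetation window.
#' @param n_compartments Number of forest compartments to tile the grid with.
#' @param species_mix Numeric vector of length 5, proportions over the
#'   legend classes (black locust, Scots pine, pedunculate oak, red oak,
#'   clearcut); must sum to 1 within 1e-9.
#' @param phenology Named list of [phenology_model()]s covering every legend
#'   class, e.g. [default_phenology()].
#' @param damage_events Data frame with columns `compartment_id`, `year`,
#'   `damage_type` (one of drought/frost/clearcut/game), `severity` (fraction
#'   in \[0,1\] by which NIR reflectance is reduced) and `affected_fraction`
#'   (fraction of the compartment area hit). May be empty.
#' @param cloud_prob_clear Probability that a scene is generated fully clear.
#' @param cloud_max_fraction Upper bound of the uniform cloud-cover fraction
#'   drawn for non-clear scenes, in \[0,1\].
#' @param seed Master integer seed; per-scene substreams are derived from it
#'   by (year, day) so adding a date leaves other scenes untouched.
#' @param window_doys Length-2 vector, the vegetation window (default
#'   day 104 to day 288, mid-April to mid-October) that all `doys` must lie in.
#' @param min_compartment_px Minimum compartment size in pixels enforced by
#'   the tiling (default 1; raise it when compartment-level statistics need
#'   a minimum support).
#' @return An object of class `fm_simconfig`.
#' @export
sim_config <- function(grid,
                       years = 2017:2020,
                       doys = c(105L, 135L, 165L, 195L, 225L, 255L, 285L),
                       n_compartments = 24,
                       species_mix = c(0.20, 0.15, 0.35, 0.15, 0.15),
                       phenology = default_phenology(),
                       damage_events = empty_damage_events(),
                       cloud_prob_clear = 0.4,
                       cloud_max_fraction = 0.25,
                       seed = 42L,
                       window_doys = c(104L, 288L),
                       min_compartment_px = 1L) {
  stopifnot(inherits(grid, "fm_grid"))
  years <- as.integer(years)
  doys <- sort(as.integer(doys))
  if (length(years) < 1L) stop("years must be non-empty")
  if (any(doys < window_doys[1] | doys > window_doys[2]))
    stop("acquisition days must lie within the vegetation window [",
         window_doys[1], ", ", window_doys[2], "]")
  if (length(species_mix) != 5L)
    stop("species_mix must have one proportion per legend class (5)")
  if (abs(sum(species_mix) - 1) > 1e-9)
    stop("species_mix must sum to 1 (tolerance 1e-9)")
  if (any(species_mix < 0)) stop("species_mix proportions must be >= 0")
  needed <- names(species_legend())
  if (!all(needed %in% names(phenology)))
    stop("phenology must cover classes: ", paste(needed, collapse = ", "))
  damage_events <- validate_damage_events(damage_events, years)
  if (cloud_max_fraction < 0 || cloud_max_fraction > 1)
    stop("cloud_max_fraction must lie in [0, 1]")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a fixed integer")
  structure(
    list(grid = grid, years = years, doys = doys,
         n_compartments = as.integer(n_compartments),
         species_mix = species_mix, phenology = phenology,
         damage_events = damage_events,
         cloud_prob_clear = cloud_prob_clear,
         cloud_max_fraction = cloud_max_fraction,
         seed = seed, window_doys = as.integer(window_doys),
         min_compartment_px = as.integer(min_compartment_px)),
    class = "fm_simconfig"
  )
}

#' Empty damage-event table with the expected schema
#' @return Zero-row data frame.
#' @export
empty_damage_events <- function() {
  data.frame(compartment_id = integer(), year = integer(),
             damage_type = character(), severity = numeric(),
             affected_fraction = numeric())
}

validate_damage_events <- function(ev, years) {
  need <- c("compartment_id", "year", "damage_type", "severity",
            "affected_fraction")
  if (!all(need %in% names(ev)))
    stop("damage_events must have columns: ", paste(need, collapse = ", "))
  if (nrow(ev)) {
    if (any(ev$severity < 0 | ev$severity > 1))
      stop("damage severity must lie in [0, 1]")
    if (any(ev$affected_fraction < 0 | ev$affected_fraction > 1))
      stop("affected_fraction must lie in [0, 1]")
    if (any(!ev$year %in% years))
      stop("damage_events reference years outside the simulated range")
    bad <- setdiff(ev$damage_type, c("drought", "frost", "clearcut", "game"))
    if (length(bad))
      stop("unknown damage_type: ", paste(bad, collapse = ", "))
  }
  ev
}

#' Ready-made demonstration configuration
#'
#' A 60 x 60 pixel (10 m) grid, four years (2017-2020) with seven
#' acquisitions per year inside the vegetation window, 24 compartments with
#' an oak-dominated species mixture, and one severe damage year (2017):
#' frost/drought events of severity 0.7 covering whole compartments until
#' roughly 75% of the forest area is affected. That damaged-area share
#' mirrors the reference marginals of compartment-level damage reporting in
#' an intensively damaged lowland forest, where validation matrices show
#' about three quarters of compared pixels as reference damage in damage
#' years.
#'
#' @param seed Master seed.
#' @param noise_sd Reflectance noise sd for every class (set 0 for the
#'   noiseless limit).
#' @param clouds Logical; FALSE generates perfectly clear scenes.
#' @param damage_share Target damaged-area share of the grid in the damage
#'   year (default 0.75).
#' @param damage_year Year receiving the severe damage events.
#' @return An `fm_simconfig`.
#' @export
demo_config <- function(seed = 42L, noise_sd = 0.02, clouds = TRUE,
                        damage_share = 0.75, damage_year = 2017L) {
  cfg <- sim_config(
    grid = grid_spec(60, 60),
    phenology = default_phenology(noise_sd = noise_sd),
    cloud_prob_clear = if (clouds) 0.4 else 1,
    cloud_max_fraction = if (clouds) 0.25 else 0,
    seed = seed,
    min_compartment_px = 20L
  )
  comp <- make_compartments(cfg)
  tab <- comp$table[order(comp$table$id), ]
  total <- sum(tab$npx)
  cum <- cumsum(tab$npx) / total
  k <- which(cum >= damage_share)[1]
  if (is.na(k)) k <- nrow(tab)
  hit <- tab$id[seq_len(k)]
  cfg$damage_events <- data.frame(
    compartment_id = hit,
    year = as.integer(damage_year),
    damage_type = rep_len(c("frost", "drought"), length(hit)),
    severity = 0.7,
    affected_fraction = 1.0
  )
  cfg
}
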