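#' Run the full monitoring chain on a synthetic configuration
#'
#' Per year: generate (or accept) the scene collection, apply the temporal
#' window, the scene-level cloud-percentage prefilter and the QA bitmask
#' mask, reduce to the annual median composite and compute NDVI. Across
#' years: per-pixel multi-year mean/std, standardized anomaly (Z) maps,
#' binary damage classification (Z below threshold), reference damage maps
#' rasterized from the compartment reports (damage ratio at or above the
#' threshold), per-year confusion matrices and accuracies plus their means.
#' On top: random-forest dominant-species classification of one year's
#' median composite with compartment-majority aggregation and agreement
#' accuracy, the ROI-median NDVI time series, and a Shapiro-Wilk normality
#' check of each anomaly map. All artifacts can be written to `out_dir`
#' together with a machine-readable run manifest.
#'
#' @param config An [sim_config()] (e.g. [demo_config()]).
#' @param out_dir Optional output directory (created if missing); inputs
#'   are never touched, outputs go only here.
#' @param max_cloud_pct Scene-level cloud prefilter threshold (default 5).
#' @param z_threshold Anomaly damage threshold (default -0.5).
#' @param ratio_threshold Damage-ratio reclassification threshold
#'   (default 30).
#' @param species_year Year whose median composite feeds the species
#'   classifier (default: last simulated year).
#' @param rf_n_trees,rf_vars_per_split Random-forest settings (defaults
#'   100 and 10; the latter clamps to the feature count).
#' @param normality_n Sample size of the per-year normality check.
#' @return List with `annual` (per-year collections/composites/indices/
#'   z/damage maps), `accuracy` (per-year rows), `mean_accuracy`,
#'   `confusions`, `species` (map, table, accuracy with and without
#'   clearcuts), `timeseries`, `normality`, `compartments`, `reports`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         max_cloud_pct = 5, z_threshold = -0.5,
                         ratio_threshold = 30,
                         species_year = max(config$years),
                         rf_n_trees = 100, rf_vars_per_split = 10,
                         normality_n = 100) {
  stopifnot(inherits(config, "fm_simconfig"))
  comp_set <- make_compartments(config)
  reports <- make_reports(config, comp_set)

  annual <- list()
  for (y in config$years) {
    coll <- make_collection(config, y, comp_set)
    w <- config$window_doys
    start <- as.Date(w[1] - 1, origin = as.Date(sprintf("%d-01-01", y)))
    end <- as.Date(w[2], origin = as.Date(sprintf("%d-01-01", y)))
    coll_f <- filter_date(coll, start, end)
    coll_f <- filter_cloud_metadata(coll_f, max_cloud_pct)
    coll_m <- mask_clouds(coll_f)
    med <- reduce_collection(coll_m, "median")
    annual[[as.character(y)]] <- list(
      collection = coll_m, n_scenes = length(coll_m),
      composite = med, ndvi = ndvi(med, period = as.character(y)),
      truth = damage_truth(coll))
  }

  ndvi_list <- lapply(annual, `[[`, "ndvi")
  stats <- multi_year_stats(unname(ndvi_list))

  acc_rows <- list(); confusions <- list(); normality <- list()
  for (y in names(annual)) {
    z <- zndvi(annual[[y]]$ndvi, stats$mean, stats$std)
    classified <- classify_damage(z, z_threshold, year = y)
    reference <- reference_damage_map(comp_set, reports, as.integer(y),
                                      ratio_threshold = ratio_threshold)
    cm <- confusion(classified, reference)
    annual[[y]]$z <- z
    annual[[y]]$classified <- classified
    annual[[y]]$reference <- reference
    confusions[[y]] <- cm
    acc_rows[[y]] <- accuracies(cm)
    normality[[y]] <- tryCatch(
      normality_check(z, n = normality_n,
                      seed = derive_seed(config$seed, as.integer(y),
                                         salt = 3L)),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               n = normality_n, error = conditionMessage(e)))
  }
  accuracy <- do.call(rbind, acc_rows)
  rownames(accuracy) <- NULL
  mean_accuracy <- mean_accuracies(accuracy)

  # species classification on the chosen year's median composite
  sp_comp <- annual[[as.character(species_year)]]$composite
  pts <- make_training_points(comp_set,
                              seed = derive_seed(config$seed, salt = 4L))
  ts <- sample_training(pts, sp_comp)
  rf <- train_rf(ts, n_trees = rf_n_trees,
                 vars_per_split = min(rf_vars_per_split,
                                      length(sp_comp$bands)),
                 seed = derive_seed(config$seed, salt = 5L))
  smap <- classify_species(rf, sp_comp)
  sp_table <- zonal_majority(smap, comp_set)
  sp_acc <- species_accuracy(sp_table)
  sp_acc_forest <- species_accuracy(sp_table, exclude_clearcut = TRUE)

  all_scenes <- unlist(lapply(annual, function(a) a$collection$scenes),
                       recursive = FALSE)
  timeseries <- median_timeseries(scene_collection(all_scenes,
                                                   grid = config$grid),
                                  roi = comp_set)

  manifest <- list(
    package = "forestmon",
    version = as.character(utils::packageVersion("forestmon")),
    seed = config$seed,
    years = config$years,
    grid = unclass(config$grid),
    n_compartments = config$n_compartments,
    parameters = list(max_cloud_pct = max_cloud_pct,
                      z_threshold = z_threshold,
                      ratio_threshold = ratio_threshold,
                      species_year = species_year,
                      rf_n_trees = rf_n_trees,
                      rf_vars_per_split = rf_vars_per_split),
    n_scenes_used = vapply(annual, `[[`, numeric(1), "n_scenes")
  )

  result <- list(annual = annual, accuracy = accuracy,
                 mean_accuracy = mean_accuracy, confusions = confusions,
                 species = list(map = smap, table = sp_table,
                                accuracy = sp_acc,
                                accuracy_forest_only = sp_acc_forest,
                                model = rf),
                 timeseries = timeseries, normality = normality,
                 compartments = comp_set, reports = reports,
                 manifest = manifest)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (y in names(result$annual)) {
    a <- result$annual[[y]]
    write_raster(a$composite$bands, p(sprintf("composite_median_%s.tif", y)),
                 a$composite$grid, meta = list(type = "composite",
                                               reducer = "median", year = y))
    write_index(a$ndvi, p(sprintf("ndvi_%s.tif", y)))
    write_index(a$z, p(sprintf("zndvi_%s.tif", y)))
    write_damage_map(a$classified, p(sprintf("damage_classified_%s.tif", y)))
    write_damage_map(a$reference, p(sprintf("damage_reference_%s.tif", y)))
  }
  acc <- cbind(result$accuracy)
  utils::write.csv(acc, p("accuracy_per_year.csv"), row.names = FALSE)
  utils::write.csv(result$mean_accuracy, p("accuracy_mean.csv"),
                   row.names = FALSE)
  cm_rows <- do.call(rbind, lapply(result$confusions, function(m)
    data.frame(year = m$year, n11 = m$n11, n10 = m$n10, n01 = m$n01,
               n00 = m$n00, total = m$total)))
  utils::write.csv(cm_rows, p("confusion_matrices.csv"), row.names = FALSE)
  write_raster(list(species = result$species$map$values + 0),
               p("species_map.tif"), result$species$map$grid,
               meta = list(type = "species",
                           legend = as.list(result$species$map$legend)))
  utils::write.csv(result$species$table, p("species_majority.csv"),
                   row.names = FALSE)
  utils::write.csv(result$timeseries, p("ndvi_timeseries.csv"),
                   row.names = FALSE)
  write_compartments(result$compartments, p("compartments.geojson"))
  write_reports(result$reports, p("damage_reports.csv"))
  jsonlite::write_json(result$manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
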