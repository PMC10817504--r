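test_that("compartments tile the grid disjointly with conserved class counts", {
  cfg <- sim_config(grid_spec(40, 40), n_compartments = 4, seed = 11L)
  comp <- make_compartments(cfg)
  expect_equal(nrow(comp$table), 4L)
  ids <- rasterize_compartments(comp)
  # tiling: every pixel belongs to exactly one compartment
  expect_false(anyNA(ids))
  expect_setequal(unique(as.vector(ids)), comp$table$id)
  expect_equal(sort(tabulate(ids)), sort(comp$table$npx))
  # pixel counts consistent with areas (10 m pixels: 1 px = 0.01 ha)
  expect_equal(comp$table$area_ha, comp$table$npx / 100)
  # per-class counts sum to n_compartments
  expect_equal(sum(table(comp$table$species_code)), 4L)
})

test_that("identical config and seed reproduce compartments, scenes and reports", {
  cfg <- sim_config(grid_spec(20, 15), n_compartments = 6, seed = 5L,
                    damage_events = data.frame(
                      compartment_id = 1L, year = 2018L,
                      damage_type = "drought", severity = 0.5,
                      affected_fraction = 0.5))
  expect_identical(make_compartments(cfg), make_compartments(cfg))
  c1 <- make_collection(cfg, 2018)
  c2 <- make_collection(cfg, 2018)
  expect_identical(c1, c2)
  expect_identical(make_reports(cfg), make_reports(cfg))
})

test_that("adding an acquisition date leaves other scenes bit-identical", {
  base <- sim_config(grid_spec(12, 12), n_compartments = 3, seed = 9L,
                     doys = c(135L, 195L, 255L))
  more <- sim_config(grid_spec(12, 12), n_compartments = 3, seed = 9L,
                     doys = c(135L, 165L, 195L, 255L))
  ca <- make_collection(base, 2019)
  cb <- make_collection(more, 2019)
  shared <- match(sapply(ca$scenes, function(s) format(s$date)),
                  sapply(cb$scenes, function(s) format(s$date)))
  for (k in seq_along(ca$scenes))
    expect_identical(ca$scenes[[k]], cb$scenes[[shared[k]]])
})

test_that("a degenerate species mixture labels every compartment alike", {
  cfg <- sim_config(grid_spec(20, 20), n_compartments = 5,
                    species_mix = c(1, 0, 0, 0, 0), seed = 2L)
  comp <- make_compartments(cfg)
  expect_true(all(comp$table$species_code == species_legend()[["black_locust"]]))
})

test_that("a grid too small for the requested compartments errors", {
  expect_error(make_compartments(sim_config(grid_spec(2, 2),
                                            n_compartments = 5, seed = 1L)),
               "too small")
})

test_that("noiseless scenes reproduce the phenology reflectance exactly", {
  cfg <- sim_config(grid_spec(10, 10), n_compartments = 2,
                    species_mix = c(0, 0, 1, 0, 0),
                    phenology = default_phenology(noise_sd = 0),
                    cloud_prob_clear = 1, cloud_max_fraction = 0,
                    doys = c(135L, 195L), seed = 3L)
  coll <- make_collection(cfg, 2017)
  expected <- forestmon:::phenology_reflectance(
    cfg$phenology$pedunculate_oak, 195)
  s <- coll$scenes[[2]]
  for (b in names(expected))
    expect_equal(unique(as.vector(s$bands[[b]])), unname(expected[b]))
  expect_true(all(s$qa == 0L))
  expect_equal(s$cloud_pct, 0)
})

test_that("full-severity damage forces NIR to 0 and NDVI to -1", {
  cfg <- sim_config(grid_spec(10, 10), n_compartments = 2,
                    phenology = default_phenology(noise_sd = 0),
                    cloud_prob_clear = 1, cloud_max_fraction = 0,
                    doys = 195L, seed = 3L,
                    damage_events = data.frame(
                      compartment_id = 1L, year = 2017L,
                      damage_type = "frost", severity = 1,
                      affected_fraction = 1))
  coll <- make_collection(cfg, 2017)
  truth <- damage_truth(coll)
  comp <- make_compartments(cfg)
  expect_equal(sum(truth), comp$table$npx[comp$table$id == 1L])
  s <- coll$scenes[[1]]
  expect_true(all(s$bands$B8[truth] == 0))
  v <- ndvi(s)$values
  expect_true(all(v[truth] == -1))
  # outside the event nothing is depressed
  expect_true(all(v[!truth] > 0))
})

test_that("scene cloud metadata equals the bitmask cloudy-pixel share", {
  cfg <- sim_config(grid_spec(30, 30), n_compartments = 4, seed = 21L,
                    cloud_prob_clear = 0, cloud_max_fraction = 0.4)
  coll <- make_collection(cfg, 2020)
  for (s in coll$scenes) {
    pct <- 100 * mean(bitwAnd(as.integer(s$qa), 3072L) != 0L)
    expect_lt(abs(s$cloud_pct - pct), 0.5)
  }
})

test_that("reports apply the damage-ratio formula to affected areas", {
  cfg <- sim_config(grid_spec(40, 20), n_compartments = 1, seed = 8L,
                    damage_events = data.frame(
                      compartment_id = 1L, year = c(2017L, 2018L),
                      damage_type = "game",
                      severity = 0.4,
                      affected_fraction = c(0.25, 1)))
  comp <- make_compartments(cfg)
  expect_equal(comp$table$area_ha, 8) # 800 px of 0.01 ha
  rep <- make_reports(cfg, comp)
  r17 <- rep[rep$year == 2017, ]
  expect_equal(r17$damaged_area_ha, 2)
  expect_equal(r17$total_area_ha, 8)
  expect_equal(r17$damage_ratio_pct, 25)
  expect_equal(rep$damage_ratio_pct[rep$year == 2018], 100)
  # no event for a compartment-year -> no row
  expect_equal(nrow(rep), 2L)
})

test_that("reports reject events for unknown compartments", {
  cfg <- sim_config(grid_spec(10, 10), n_compartments = 2, seed = 8L)
  cfg$damage_events <- data.frame(compartment_id = 99L, year = 2017L,
                                  damage_type = "frost", severity = 0.5,
                                  affected_fraction = 0.5)
  expect_error(make_reports(cfg), "unknown compartment")
})

test_that("config validation rejects bad mixtures, dates and events", {
  g <- grid_spec(10, 10)
  expect_error(sim_config(g, species_mix = c(0.5, 0.5, 0.1, 0, 0)),
               "sum to 1")
  expect_error(sim_config(g, doys = c(50L, 195L)), "vegetation window")
  expect_error(sim_config(g, damage_events = data.frame(
    compartment_id = 1L, year = 2017L, damage_type = "frost",
    severity = 1.4, affected_fraction = 0.5)), "severity")
  expect_error(sim_config(g, damage_events = data.frame(
    compartment_id = 1L, year = 1999L, damage_type = "frost",
    severity = 0.4, affected_fraction = 0.5)), "outside the simulated range")
})
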