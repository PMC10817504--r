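# Noiseless, cloud-free config whose classes are exactly separable.
separable_cfg <- function(seed = 5L, noise_sd = 0, n_comp = 12,
                          grid = grid_spec(30, 30)) {
  sim_config(grid, n_compartments = n_comp,
             phenology = default_phenology(noise_sd = noise_sd),
             cloud_prob_clear = 1, cloud_max_fraction = 0, seed = seed)
}

test_that("training features are looked up at the containing pixel", {
  grid <- grid_spec(4, 4)
  bands <- list(B2 = matrix(0.1, 4, 4), B3 = matrix(0.2, 4, 4),
                B4 = matrix(0.3, 4, 4), B8 = matrix(0.6, 4, 4))
  bands$B8[1, 1] <- NA # north-west pixel nodata
  coll <- scene_collection(list(mk_scene(bands, "2017-06-01", grid = grid)))
  comp <- reduce_collection(coll, "median")
  pts <- data.frame(x = c(15, 105, 5), y = c(15, 15, 35),
                    species_code = c(3L, 1L, 2L))
  expect_warning(expect_warning(ts <- sample_training(pts, comp),
                                "outside the grid"), "nodata")
  expect_equal(nrow(ts$features), 1L)
  expect_equal(unname(ts$features[1, ]), c(0.1, 0.2, 0.3, 0.6))
})

test_that("auto-sampled training points preserve the campaign class counts", {
  cfg <- separable_cfg(seed = 31L, n_comp = 20, grid = grid_spec(40, 40))
  comp <- make_compartments(cfg)
  pts <- make_training_points(comp, seed = 2L)
  expect_equal(nrow(pts), 123L)
  leg <- species_legend()
  cnt <- table(factor(pts$species_code, levels = leg))
  expect_equal(unname(c(cnt)),
               c(15L, 27L, 40L, 22L, 19L)) # legend (code) order
  # points carry the ground-truth class of their pixel
  ids <- rasterize_compartments(comp)
  px <- comp$grid$pixel_size
  cc <- floor(pts$x / px) + 1
  rr <- comp$grid$height - floor(pts$y / px)
  truth <- comp$table$species_code[match(ids[cbind(rr, cc)], comp$table$id)]
  expect_equal(pts$species_code, truth)
})

test_that("a seeded forest on separable classes is exact and reproducible", {
  cfg <- separable_cfg()
  comp_set <- make_compartments(cfg)
  med <- reduce_collection(mask_clouds(make_collection(cfg, 2020, comp_set)),
                           "median")
  pts <- make_training_points(comp_set, seed = 3L)
  ts <- sample_training(pts, med)
  expect_warning(rf <- train_rf(ts, vars_per_split = 10, seed = 1L),
                 "clamped to 4")
  # noiseless separable signatures: zero out-of-bag error
  expect_equal(sum(rf$fit$confusion[, "class.error"]), 0)
  rf2 <- suppressWarnings(train_rf(ts, vars_per_split = 10, seed = 1L))
  m1 <- classify_species(rf, med)
  m2 <- classify_species(rf2, med)
  expect_identical(m1$values, m2$values)

  single <- ts
  keep <- single$points$species_code == 3L
  single$points <- single$points[keep, , drop = FALSE]
  single$features <- single$features[keep, , drop = FALSE]
  expect_error(train_rf(single), "single class")
})

test_that("pixel classification recovers noiseless ground truth", {
  cfg <- separable_cfg(seed = 7L)
  comp_set <- make_compartments(cfg)
  med <- reduce_collection(mask_clouds(make_collection(cfg, 2019, comp_set)),
                           "median")
  ts <- sample_training(make_training_points(comp_set, seed = 4L), med)
  rf <- suppressWarnings(train_rf(ts, seed = 2L))
  sm <- classify_species(rf, med)
  ids <- rasterize_compartments(comp_set)
  truth <- matrix(comp_set$table$species_code[match(ids, comp_set$table$id)],
                  30, 30)
  expect_gte(mean(sm$values == truth, na.rm = TRUE), 0.99)
  # nodata propagates
  med$bands$B8[1, 1] <- NA
  sm2 <- classify_species(rf, med)
  expect_true(is.na(sm2$values[1, 1]))
  med$bands$B8 <- NULL
  expect_error(classify_species(rf, med), "lacks training band")
})

test_that("zonal majority takes the mode, breaking ties toward low codes", {
  g <- grid_spec(3, 1)
  comp <- structure(list(
    table = data.frame(id = 1L, species_code = 3L,
                       species_name = "pedunculate_oak",
                       npx = 3L, area_ha = 0.03),
    rects = list(c(1L, 1L, 1L, 3L)),
    polygons = list(NULL), grid = g),
    class = "fm_compartments")
  sm <- structure(list(values = matrix(c(3L, 3L, 2L), 1, 3),
                       legend = species_legend(), grid = g),
                  class = "fm_species_map")
  t1 <- zonal_majority(sm, comp)
  expect_equal(t1$majority_code, 3L) # mode of (oak, oak, pine)
  expect_true(t1$agreement)
  expect_false(t1$tie)

  sm$values <- matrix(c(2L, 3L, NA), 1, 3)
  t2 <- zonal_majority(sm, comp)
  expect_equal(t2$majority_code, 2L) # tie (oak, pine) -> lower code
  expect_true(t2$tie)
  expect_false(t2$agreement)

  sm$values <- matrix(NA_integer_, 1, 3)
  expect_warning(t3 <- zonal_majority(sm, comp), "no valid pixels")
  expect_true(is.na(t3$majority_code))
  expect_equal(t3$n_valid_px, 0L)
})

test_that("agreement accuracy follows the compartment-count formula", {
  tab <- data.frame(compartment_id = 1:339,
                    field_code = rep(1L, 339),
                    majority_code = c(rep(1L, 258), rep(2L, 81)),
                    agreement = c(rep(TRUE, 258), rep(FALSE, 81)),
                    tie = FALSE, n_valid_px = 10L)
  acc <- species_accuracy(tab)
  expect_equal(acc$accuracy_pct, 100 * 258 / 339) # 76.106...
  expect_equal(acc$n_agree, 258L)
  # invariant to row order
  acc2 <- species_accuracy(tab[sample.int(339), ])
  expect_equal(acc2, acc)
  tab$agreement <- TRUE
  expect_equal(species_accuracy(tab)$accuracy_pct, 100)
  tab$agreement <- FALSE
  expect_equal(species_accuracy(tab)$accuracy_pct, 0)
  expect_error(species_accuracy(tab[0, ]), "empty")
  # no-majority compartments are excluded and counted
  tab$agreement[1] <- TRUE
  tab$majority_code[2] <- NA
  tab$agreement[2] <- NA
  acc3 <- species_accuracy(tab)
  expect_equal(acc3$n_total, 338L)
  expect_equal(acc3$n_excluded, 1L)
  # clearcut exclusion drops by field class
  tab2 <- data.frame(compartment_id = 1:4, field_code = c(1L, 5L, 5L, 3L),
                     majority_code = c(1L, 5L, 1L, 1L),
                     agreement = c(TRUE, TRUE, FALSE, FALSE),
                     tie = FALSE, n_valid_px = 5L)
  expect_equal(species_accuracy(tab2)$accuracy_pct, 50)
  expect_equal(species_accuracy(tab2, exclude_clearcut = TRUE)$n_total, 2L)
  expect_equal(species_accuracy(tab2, exclude_clearcut = TRUE)$accuracy_pct,
               50)
})

test_that("a per-pixel perfect map yields 100% compartment agreement", {
  cfg <- separable_cfg(seed = 13L)
  comp_set <- make_compartments(cfg)
  ids <- rasterize_compartments(comp_set)
  truth <- matrix(comp_set$table$species_code[match(ids, comp_set$table$id)],
                  30, 30)
  sm <- structure(list(values = truth, legend = species_legend(),
                       grid = comp_set$grid),
                  class = "fm_species_map")
  tab <- zonal_majority(sm, comp_set)
  expect_equal(species_accuracy(tab)$accuracy_pct, 100)
})
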