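mk_three_scene_coll <- function(grid = tiny_grid()) {
  s1 <- const_scene(list(B4 = 0.2, B8 = 0.6), "2017-04-13", grid)
  s2 <- const_scene(list(B4 = 0.3, B8 = 0.5), "2017-04-14", grid)
  s3 <- const_scene(list(B4 = 0.1, B8 = 0.7), "2017-10-15", grid)
  scene_collection(list(s1, s2, s3))
}

test_that("spatial filtering keeps pixels by centre containment", {
  grid <- tiny_grid(4, 3)
  coll <- mk_three_scene_coll(grid)
  # full extent: identity
  same <- filter_bounds(coll, full_extent_ring(grid))
  expect_identical(same$scenes, coll$scenes)
  # a single 10 m cell: exactly one valid pixel per scene
  ring <- cbind(c(10, 20, 20, 10, 10), c(10, 10, 20, 20, 10))
  one <- filter_bounds(coll, ring)
  for (s in one$scenes)
    expect_equal(sum(!is.na(s$bands$B4)), 1L)
  # disjoint roi: everything nodata, with a warning
  far <- cbind(c(900, 910, 910, 900, 900), c(900, 900, 910, 910, 900))
  expect_warning(none <- filter_bounds(coll, far), "disjoint")
  expect_true(all(is.na(none$scenes[[1]]$bands$B8)))
  expect_error(filter_bounds(coll, list()), "empty roi")
})

test_that("date filtering uses a half-open window", {
  coll <- mk_three_scene_coll()
  kept <- filter_date(coll, "2017-04-14", "2017-10-15")
  expect_equal(length(kept), 1L)
  expect_equal(kept$scenes[[1]]$date, as.Date("2017-04-14"))
  expect_equal(length(filter_date(coll, "2017-01-01", "2018-01-01")), 3L)
  empty <- filter_date(coll, "2018-01-01", "2018-02-01")
  expect_equal(length(empty), 0L)
  expect_error(filter_date(coll, "2017-05-01", "2017-05-01"),
               "start date must precede")
})

test_that("the metadata cloud filter is inclusive at the threshold", {
  grid <- tiny_grid()
  mk <- function(pct, d) {
    s <- const_scene(list(B4 = 0.2, B8 = 0.6), d, grid)
    s$cloud_pct <- pct
    s
  }
  coll <- scene_collection(list(mk(3, "2017-05-01"), mk(5, "2017-05-02"),
                                mk(7, "2017-05-03")))
  kept <- filter_cloud_metadata(coll, 5)
  expect_equal(vapply(kept$scenes, function(s) s$cloud_pct, numeric(1)),
               c(3, 5))
  expect_equal(length(filter_cloud_metadata(coll, 100)), 3L)
  expect_equal(length(filter_cloud_metadata(coll, 0)), 0L)
})

test_that("QA bits 10/11 mask pixels in every band", {
  grid <- tiny_grid(3, 1)
  qa <- matrix(c(0L, 1024L, 3072L), 1, 3)
  s <- mk_scene(list(B4 = matrix(0.2, 1, 3), B8 = matrix(0.6, 1, 3)),
                "2017-06-01", grid = grid, qa = qa)
  m <- mask_clouds(s)
  expect_equal(is.na(m$bands$B4[1, ]), c(FALSE, TRUE, TRUE))
  expect_equal(is.na(m$bands$B8[1, ]), c(FALSE, TRUE, TRUE))
  s$qa <- NULL
  expect_error(mask_clouds(s), "no qa band")
})

test_that("masking monotonicity: more cloud bits never add valid pixels", {
  grid <- tiny_grid(4, 4)
  set.seed(31)
  qa <- matrix(sample(c(0L, 1024L, 2048L, 512L), 16, replace = TRUE), 4, 4)
  s <- mk_scene(list(B8 = matrix(runif(16), 4, 4)), "2017-06-01",
                grid = grid, qa = qa)
  v10 <- sum(!is.na(mask_clouds(s, cloud_bits = 10L)$bands$B8))
  v1011 <- sum(!is.na(mask_clouds(s, cloud_bits = c(10L, 11L))$bands$B8))
  v910 <- sum(!is.na(mask_clouds(s, cloud_bits = c(9L, 10L, 11L))$bands$B8))
  expect_true(v1011 <= v10)
  expect_true(v910 <= v1011)
})

test_that("reducers follow the masked per-pixel formulas", {
  grid <- tiny_grid(1, 1)
  mk <- function(v, d) {
    b <- matrix(v, 1, 1)
    mk_scene(list(B8 = b), d, grid = grid)
  }
  coll <- scene_collection(list(mk(0.2, "2017-05-01"), mk(0.4, "2017-05-02"),
                                mk(NA_real_, "2017-05-03")))
  med <- reduce_collection(coll, "median")
  expect_equal(med$bands$B8[1, 1], 0.3) # median of the two valid obs
  expect_equal(med$n_used[1, 1], 2L)

  coll2 <- scene_collection(list(mk(1, "2017-05-01"), mk(1, "2017-05-02"),
                                 mk(1, "2017-05-03")))
  expect_equal(reduce_collection(coll2, "std")$bands$B8[1, 1], 0)

  coll3 <- scene_collection(list(mk(0, "2017-05-01"), mk(2, "2017-05-02")))
  expect_equal(reduce_collection(coll3, "std")$bands$B8[1, 1], 1) # population
  expect_equal(reduce_collection(coll3, "std", sample_std = TRUE)$bands$B8[1, 1],
               sqrt(2))
  expect_error(reduce_collection(coll3, "max"))
})

test_that("median of a single-scene collection returns the scene exactly", {
  grid <- tiny_grid(5, 5)
  set.seed(7)
  b <- matrix(runif(25), 5, 5); b[2, 3] <- NA
  s <- mk_scene(list(B8 = b), "2017-06-01", grid = grid)
  med <- reduce_collection(scene_collection(list(s)), "median")
  expect_identical(med$bands$B8, b)
  expect_equal(med$n_used[2, 3], 0L)
})

test_that("an empty collection reduces to an all-nodata composite", {
  grid <- tiny_grid()
  empty <- scene_collection(list(), grid = grid)
  comp <- reduce_collection(empty, "median")
  expect_equal(comp$n_used, matrix(0L, grid$height, grid$width))
  expect_equal(length(comp$bands), 0L)
})

test_that("per-pixel reductions match a naive loop on small random stacks", {
  set.seed(42)
  for (trial in 1:20) {
    h <- sample(2:8, 1); w <- sample(2:8, 1); n <- sample(2:6, 1)
    grid <- grid_spec(w, h)
    mats <- lapply(seq_len(n), function(k) {
      m <- matrix(runif(h * w), h, w)
      m[runif(h * w) < 0.3] <- NA
      m
    })
    scenes <- lapply(seq_len(n), function(k)
      mk_scene(list(B8 = mats[[k]]),
               as.Date("2017-05-01") + k, grid = grid))
    coll <- scene_collection(scenes)
    for (red in c("median", "mean", "std"))
      expect_equal(reduce_collection(coll, red)$bands$B8,
                   oracle_reduce(mats, red), tolerance = 1e-12)
  }
})

test_that("filters compose in any order", {
  cfg <- sim_config(grid_spec(12, 12), n_compartments = 3, seed = 13L,
                    cloud_prob_clear = 0.3, cloud_max_fraction = 0.3)
  coll <- make_collection(cfg, 2018)
  comp <- make_compartments(cfg)
  ring <- cbind(c(0, 60, 60, 0, 0), c(0, 0, 60, 60, 0))
  f1 <- filter_cloud_metadata(
    filter_date(filter_bounds(coll, ring), "2018-05-01", "2018-09-01"), 10)
  f2 <- filter_bounds(
    filter_cloud_metadata(filter_date(coll, "2018-05-01", "2018-09-01"), 10),
    ring)
  f3 <- filter_date(
    filter_bounds(filter_cloud_metadata(coll, 10), ring),
    "2018-05-01", "2018-09-01")
  attr(f1, "year") <- attr(f2, "year") <- attr(f3, "year") <- NULL
  attr(f1, "damage_truth") <- attr(f2, "damage_truth") <- NULL
  attr(f3, "damage_truth") <- NULL
  expect_identical(f1, f2)
  expect_identical(f1, f3)
})

test_that("RGB stretch maps reflectance to 0-255 with banker's rounding", {
  grid <- tiny_grid(1, 1)
  mk <- function(v) {
    coll <- scene_collection(list(const_scene(
      list(B2 = v, B3 = v, B4 = v), "2017-06-01", grid)))
    make_rgb(reduce_collection(coll, "median"))
  }
  expect_true(all(mk(0.3) == 255))
  expect_true(all(mk(0.45) == 255)) # clamped above the stretch range
  expect_true(all(mk(0) == 0))
  expect_true(all(mk(0.15) == 128)) # 127.5 rounds half-to-even
  coll <- scene_collection(list(const_scene(list(B2 = 0.1, B8 = 0.5),
                                            "2017-06-01", grid)))
  expect_error(make_rgb(reduce_collection(coll, "median")), "lacks band")
})
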