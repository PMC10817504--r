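# Shared fixtures and independent brute-force oracles.

tiny_grid <- function(w = 4, h = 3, px = 10) grid_spec(w, h, px)

# Build a scene from a named list of matrices (qa defaults to all-clear).
mk_scene <- function(bands, date, grid = NULL, qa = NULL, cloud_pct = 0) {
  if (is.null(grid)) {
    d <- dim(bands[[1]])
    grid <- grid_spec(d[2], d[1])
  }
  if (is.null(qa)) qa <- matrix(0L, grid$height, grid$width)
  scene(bands = bands, qa = qa, date = date, cloud_pct = cloud_pct,
        grid = grid)
}

# Constant-valued scene over a grid.
const_scene <- function(vals, date, grid) {
  bands <- lapply(vals, function(v)
    matrix(v, grid$height, grid$width))
  mk_scene(bands, date, grid)
}

# Ring covering the full grid extent.
full_extent_ring <- function(grid) {
  px <- grid$pixel_size
  x0 <- grid$origin_x; x1 <- grid$origin_x + grid$width * px
  y0 <- grid$origin_y; y1 <- grid$origin_y + grid$height * px
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}

# --- independent oracles (naive loops) ---------------------------------

oracle_reduce <- function(mats, reducer) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    obs <- vapply(mats, function(m) m[i, j], numeric(1))
    obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    out[i, j] <- switch(reducer,
      median = stats::median(obs),
      mean = sum(obs) / length(obs),
      std = sqrt(sum((obs - mean(obs))^2) / length(obs)))
  }
  out
}

oracle_confusion <- function(cl, ref) {
  n <- c(n11 = 0L, n10 = 0L, n01 = 0L, n00 = 0L)
  for (k in seq_along(cl)) {
    if (is.na(cl[k]) || is.na(ref[k])) next
    key <- paste0("n", cl[k], ref[k])
    n[key] <- n[key] + 1L
  }
  n
}

oracle_majority <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_integer_)
  cnt <- table(vals)
  winners <- as.integer(names(cnt)[cnt == max(cnt)])
  min(winners)
}

# A small, fast configuration exercising the whole chain (one severe
# damage year over five of eight compartments).
small_cfg <- function(seed = 42L, ...) {
  cfg <- sim_config(grid_spec(24, 24), n_compartments = 8,
                    doys = c(135L, 165L, 195L, 225L, 255L),
                    seed = seed, ...)
  comp <- make_compartments(cfg)
  hit <- comp$table$id[1:5]
  cfg$damage_events <- data.frame(
    compartment_id = hit, year = 2018L, damage_type = "drought",
    severity = 0.7, affected_fraction = 1.0)
  cfg
}

# Small damage map from a matrix of 0/1/NA values.
mk_damage <- function(values, source = "classified", year = 2017) {
  g <- grid_spec(ncol(values), nrow(values))
  forestmon:::new_damage_map(values, source, year, g)
}
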