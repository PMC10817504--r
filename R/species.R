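#' Extract training features at point locations from a composite
#'
#' Looks up every available composite band at the pixel containing each
#' training point. Points falling outside the grid or on nodata pixels are
#' dropped with a warning.
#'
#' @param points Data frame with `x`, `y` (map coordinates) and
#'   `species_code` (legend code).
#' @param comp An `fm_composite`.
#' @return An object of class `fm_training`: `points` (kept rows) and
#'   `features` (matrix, one column per band).
#' @export
sample_training <- function(points, comp) {
  stopifnot(inherits(comp, "fm_composite"))
  need <- c("x", "y", "species_code")
  if (!all(need %in% names(points)))
    stop("points must have columns: ", paste(need, collapse = ", "))
  grid <- comp$grid
  px <- grid$pixel_size
  col_ <- floor((points$x - grid$origin_x) / px) + 1L
  row_ <- grid$height - floor((points$y - grid$origin_y) / px)
  inside <- col_ >= 1L & col_ <= grid$width & row_ >= 1L & row_ <= grid$height
  if (any(!inside))
    warning(sum(!inside), " point(s) outside the grid dropped")
  feat <- matrix(NA_real_, nrow(points), length(comp$bands),
                 dimnames = list(NULL, names(comp$bands)))
  idx <- cbind(row_[inside], col_[inside])
  for (b in names(comp$bands))
    feat[inside, b] <- comp$bands[[b]][idx]
  valid <- inside & !apply(is.na(feat), 1, any)
  if (any(inside & !valid))
    warning(sum(inside & !valid), " point(s) on nodata pixels dropped")
  structure(list(points = points[valid, , drop = FALSE],
                 features = feat[valid, , drop = FALSE]),
            class = "fm_training")
}

#' @export
print.fm_training <- function(x, ...) {
  cat(sprintf("<fm_training> %d points, %d features; class counts:\n",
              nrow(x$features), ncol(x$features)))
  print(table(x$points$species_code))
  invisible(x)
}

#' Auto-sample training points from ground-truth compartments
#'
#' Draws seeded random pixel centres from compartments of each legend
#' class, with the per-class point counts of a field-calibrated training
#' campaign (default 15 black locust, 22 red oak, 27 Scots pine, 40
#' pedunculate oak, 19 clearcut: 123 points in total), emulating manually
#' digitized training geometry over known stands.
#'
#' @param compartments An `fm_compartments` carrying `species_code`.
#' @param counts Named vector of points per class (legend names).
#' @param seed Integer seed.
#' @return Data frame with `x`, `y`, `species_code`.
#' @export
make_training_points <- function(compartments,
                                 counts = c(black_locust = 15, red_oak = 22,
                                            scots_pine = 27,
                                            pedunculate_oak = 40,
                                            clearcut = 19),
                                 seed = 7L) {
  stopifnot(inherits(compartments, "fm_compartments"))
  leg <- species_legend()
  grid <- compartments$grid
  ids <- rasterize_compartments(compartments)
  code <- matrix(compartments$table$species_code[
    match(ids, compartments$table$id)], grid$height, grid$width)
  ctr <- pixel_centres(grid)
  with_seed(as.integer(seed), {
    rows <- lapply(names(counts), function(cl) {
      code_cl <- leg[[cl]]
      cand <- which(code == code_cl)
      n <- counts[[cl]]
      if (length(cand) < n)
        stop("class ", cl, " has only ", length(cand),
             " pixels; cannot sample ", n, " training points")
      sel <- sample(cand, n)
      data.frame(x = ctr$x[sel], y = ctr$y[sel], species_code = code_cl)
    })
    do.call(rbind, rows)
  })
}

#' Train a random-forest species classifier
#'
#' A seeded random forest over the training features; defaults follow the
#' operational setup of 100 trees and 10 candidate variables per split.
#' When fewer features than `vars_per_split` are available (e.g. the
#' minimal 4-band synthetic scenes), the value is clamped with a warning.
#'
#' @param ts An `fm_training`.
#' @param n_trees Number of trees (default 100).
#' @param vars_per_split Candidate variables per split (default 10,
#'   clamped to the feature count).
#' @param seed Integer seed.
#' @return An object of class `fm_rf` wrapping the fitted forest.
#' @export
train_rf <- function(ts, n_trees = 100, vars_per_split = 10, seed = 1L) {
  stopifnot(inherits(ts, "fm_training"))
  classes <- unique(ts$points$species_code)
  if (length(classes) < 2L)
    stop("training set contains a single class; cannot train")
  p <- ncol(ts$features)
  if (vars_per_split > p) {
    warning("vars_per_split = ", vars_per_split, " clamped to ", p,
            " (number of features)")
    vars_per_split <- p
  }
  leg <- species_legend()
  y <- factor(ts$points$species_code, levels = unname(leg),
              labels = names(leg))
  fit <- with_seed(as.integer(seed), {
    randomForest::randomForest(x = as.data.frame(ts$features), y = droplevels(y),
                               ntree = n_trees, mtry = vars_per_split)
  })
  structure(list(fit = fit, bands = colnames(ts$features),
                 n_trees = n_trees, vars_per_split = vars_per_split,
                 seed = as.integer(seed)),
            class = "fm_rf")
}

#' @export
print.fm_rf <- function(x, ...) {
  cat(sprintf("<fm_rf> %d trees, %d vars/split, bands %s\n", x$n_trees,
              x$vars_per_split, paste(x$bands, collapse = ",")))
  oob <- 100 * (1 - sum(diag(x$fit$confusion[, seq_len(nrow(x$fit$confusion))])) /
                  sum(x$fit$confusion[, seq_len(nrow(x$fit$confusion))]))
  cat(sprintf("  OOB error: %.2f%%\n", oob))
  invisible(x)
}

#' Classify every composite pixel into a species class
#'
#' Per-pixel random-forest prediction from the composite bands the model
#' was trained on; pixels with nodata in any feature band are nodata.
#'
#' @param model An `fm_rf` from [train_rf()].
#' @param comp An `fm_composite` carrying at least the training bands.
#' @return An object of class `fm_species_map`: integer code matrix,
#'   legend, grid.
#' @export
classify_species <- function(model, comp) {
  stopifnot(inherits(model, "fm_rf"), inherits(comp, "fm_composite"))
  miss <- setdiff(model$bands, names(comp$bands))
  if (length(miss))
    stop("composite lacks training band(s): ", paste(miss, collapse = ", "))
  grid <- comp$grid
  feat <- vapply(model$bands, function(b) as.vector(comp$bands[[b]]),
                 numeric(grid$height * grid$width))
  ok <- !apply(is.na(feat), 1, any)
  codes <- rep(NA_integer_, nrow(feat))
  if (any(ok)) {
    pred <- stats::predict(model$fit,
                           as.data.frame(feat[ok, , drop = FALSE]))
    codes[ok] <- species_legend()[as.character(pred)]
  }
  structure(list(values = matrix(codes, grid$height, grid$width),
                 legend = species_legend(), grid = grid),
            class = "fm_species_map")
}

#' @export
print.fm_species_map <- function(x, ...) {
  cat("<fm_species_map> class counts:\n")
  print(table(factor(x$values, levels = unname(x$legend),
                     labels = names(x$legend)), useNA = "ifany"))
  invisible(x)
}

#' Compartment-level majority species from a classified map
#'
#' For each compartment, the modal class over its non-nodata pixels
#' (pixel-centre containment). Ties are broken toward the lowest class code
#' and flagged; compartments with zero valid pixels get NA majority and are
#' flagged so they can be excluded from agreement scoring.
#'
#' @param sm An `fm_species_map`.
#' @param compartments An `fm_compartments` (field species in
#'   `species_code`).
#' @return Data frame with `compartment_id`, `field_code`, `majority_code`,
#'   `agreement`, `tie`, `n_valid_px`.
#' @export
zonal_majority <- function(sm, compartments) {
  stopifnot(inherits(sm, "fm_species_map"),
            inherits(compartments, "fm_compartments"))
  stop_if_grid_mismatch(sm$grid, compartments$grid,
                        "species map and compartments")
  ids <- rasterize_compartments(compartments)
  tab <- compartments$table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- sm$values[!is.na(ids) & ids == tab$id[i]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      return(data.frame(compartment_id = tab$id[i],
                        field_code = tab$species_code[i],
                        majority_code = NA_integer_, agreement = NA,
                        tie = NA, n_valid_px = 0L))
    }
    cnt <- table(vals)
    top <- max(cnt)
    winners <- as.integer(names(cnt)[cnt == top])
    maj <- min(winners) # deterministic tie-break: lowest class code
    data.frame(compartment_id = tab$id[i],
               field_code = tab$species_code[i],
               majority_code = maj,
               agreement = maj == tab$species_code[i],
               tie = length(winners) > 1L,
               n_valid_px = length(vals))
  })
  out <- do.call(rbind, rows)
  if (any(out$n_valid_px == 0L))
    warning(sum(out$n_valid_px == 0L),
            " compartment(s) with no valid pixels have no majority class")
  out
}

#' Compartment-level species agreement accuracy
#'
#' Share of compartments whose majority classified species equals the field
#' species: `100 * agreeing / total`, over compartments that have a
#' majority class. Optionally restricted to forest-covered compartments
#' (field class not clearcut).
#'
#' @param table Data frame from [zonal_majority()].
#' @param exclude_clearcut Drop compartments whose field class is clearcut.
#' @return List with `accuracy_pct`, `n_agree`, `n_total` (scored
#'   compartments) and `n_excluded` (no-majority compartments left out).
#' @export
species_accuracy <- function(table, exclude_clearcut = FALSE) {
  if (nrow(table) < 1L) stop("empty compartment table")
  t <- table
  if (exclude_clearcut)
    t <- t[t$field_code != species_legend()[["clearcut"]], , drop = FALSE]
  excl <- sum(is.na(t$majority_code))
  t <- t[!is.na(t$majority_code), , drop = FALSE]
  if (nrow(t) < 1L) stop("no comparable compartments")
  list(accuracy_pct = 100 * sum(t$agreement) / nrow(t),
       n_agree = sum(t$agreement), n_total = nrow(t), n_excluded = excl)
}
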