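#' Region-growing configuration
#'
#' A frontier pixel `p` is accepted into the growing region iff
#' `|I_p - mean| <= max(k_sigma * sd, t_min)`, where `mean` and `sd` are the
#' region's running mean and (population) standard deviation. `t_min` is the
#' floor tolerance that lets a region leave its single-pixel cold start, where
#' the standard deviation is exactly zero.
#'
#' @param neighborhood `"eight"` (default), `"four"` (axial) or
#'   `"diagonal-four"`.
#' @param k_sigma Unitless multiplier on the region standard deviation, >= 0.
#' @param t_min Floor tolerance in intensity units, >= 0. The default of 10
#'   assumes a 0-255 intensity scale.
#' @param class_order Character vector naming the classes in the order they
#'   are grown; earlier classes claim contested pixels first.
#' @param variance_update `"welford"` (numerically stable incremental
#'   variance, the default) or `"printed"`, the raw recurrence
#'   `V_N = ((N-2) V_{N-1} + I_N) / N`, retained for comparison only — it is
#'   not a variance and is not recommended.
#' @return A `grow_config` object.
#' @export
grow_config <- function(neighborhood = c("eight", "four", "diagonal-four"),
                        k_sigma = 2.5, t_min = 10,
                        class_order = c("csf", "gm", "wm"),
                        variance_update = c("welford", "printed")) {
  neighborhood <- match.arg(neighborhood)
  variance_update <- match.arg(variance_update)
  if (!is.finite(k_sigma) || k_sigma < 0)
    config_error("k_sigma must be a finite value >= 0")
  if (!is.finite(t_min) || t_min < 0)
    config_error("t_min must be a finite value >= 0")
  if (!all(class_order %in% names(tissue_classes)))
    config_error("class_order entries must be among: csf, gm, wm")
  structure(list(neighborhood = neighborhood, k_sigma = k_sigma,
                 t_min = t_min, class_order = class_order,
                 variance_update = variance_update),
            class = "grow_config")
}

neigh_code <- function(neighborhood) {
  switch(neighborhood, four = 4L, `diagonal-four` = 5L, eight = 8L)
}

var_code <- function(variance_update) {
  switch(variance_update, welford = 1L, printed = 2L)
}

#' Initialize the running statistics of a region
#'
#' A region starts from its seed pixel with `N = 1`, mean equal to the seed
#' intensity and standard deviation zero.
#'
#' @param intensity Seed pixel intensity (finite scalar).
#' @param label Integer class id of the region.
#' @param variance_update `"welford"` or `"printed"`; see [grow_config()].
#' @return A `region_state` object with fields `label`, `n`, `mean`, `disp`.
#' @export
region_state <- function(intensity, label = 1L,
                         variance_update = c("welford", "printed")) {
  variance_update <- match.arg(variance_update)
  if (!is.finite(intensity)) data_error("seed intensity must be finite")
  structure(list(label = as.integer(label), n = 1L,
                 mean = as.numeric(intensity), disp = 0,
                 variance_update = variance_update),
            class = "region_state")
}

#' Incrementally update region statistics with one accepted pixel
#'
#' Adds one intensity to a region's running statistics. The mean follows
#' `mean_N = ((N-1) * mean_{N-1} + I_N) / N`; the dispersion follows Welford's
#' numerically stable recurrence by default (so that `sd` always equals the
#' population standard deviation of the accepted intensities), or the raw
#' printed recurrence when the state was created with
#' `variance_update = "printed"`.
#'
#' @param state A `region_state`.
#' @param intensity The newly accepted pixel's intensity.
#' @return The updated `region_state` (the input is unmodified).
#' @examples
#' s <- region_state(2)
#' s <- update_stats(s, 4)
#' s <- update_stats(s, 6)
#' c(mean = s$mean, sd = region_sd(s)) # 4, population sd of c(2,4,6)
#' @export
update_stats <- function(state, intensity) {
  if (!inherits(state, "region_state"))
    config_error("state must be a region_state")
  if (!is.finite(intensity)) data_error("intensity must be finite")
  n <- state$n + 1L
  if (state$variance_update == "welford") {
    d <- intensity - state$mean
    mean <- state$mean + d / n
    disp <- state$disp + d * (intensity - mean)
  } else {
    mean <- ((n - 1) * state$mean + intensity) / n
    disp <- ((n - 2) * state$disp + intensity) / n
  }
  state$n <- n
  state$mean <- mean
  state$disp <- disp
  state
}

#' Region standard deviation from a region state
#'
#' Population standard deviation of the accepted intensities (zero for a
#' single-pixel region). For `"printed"` states, the square root of the raw
#' recurrence value, floored at zero.
#'
#' @param state A `region_state`.
#' @return Non-negative scalar.
#' @export
region_sd <- function(state) {
  if (state$variance_update == "welford") sqrt(state$disp / state$n)
  else sqrt(max(state$disp, 0))
}

#' In-bounds neighbors of a pixel
#'
#' @param coord Integer `c(row, col)`, 1-based, inside the grid.
#' @param shape Integer `c(rows, cols)`.
#' @param neighborhood `"eight"`, `"four"` or `"diagonal-four"`.
#' @return A matrix with one `(row, col)` neighbor per row, in row-major
#'   order over the 3x3 window; never includes `coord` itself.
#' @export
neighbors <- function(coord, shape,
                      neighborhood = c("eight", "four", "diagonal-four")) {
  neighborhood <- match.arg(neighborhood)
  coord <- as.integer(coord)
  if (coord[1] < 1L || coord[1] > shape[1] ||
      coord[2] < 1L || coord[2] > shape[2])
    config_error("coord is outside the grid")
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  diag <- dr != 0L & dc != 0L
  keep <- switch(neighborhood, eight = rep(TRUE, 8L),
                 four = !diag, `diagonal-four` = diag)
  out <- cbind(row = coord[1] + dr[keep], col = coord[2] + dc[keep])
  out[out[, 1] >= 1L & out[, 1] <= shape[1] &
        out[, 2] >= 1L & out[, 2] <= shape[2], , drop = FALSE]
}

#' Grow one region from a seed
#'
#' Breadth-first growth from the seed over the configured neighborhood with a
#' FIFO frontier; neighbor candidates are enqueued in row-major order over the
#' 3x3 window, so the traversal is deterministic. A frontier pixel is accepted
#' iff it is eligible and `|I - mean| <= max(k_sigma * sd, t_min)`; the region
#' statistics are updated incrementally on each acceptance. Growth stops when
#' the frontier is empty.
#'
#' @param image Numeric matrix of intensities (finite values).
#' @param seed Integer `c(row, col)`, 1-based; must be inside the grid and
#'   eligible.
#' @param config A [grow_config()].
#' @param eligible Optional logical matrix of pixels the region may claim
#'   (default: all).
#' @param frozen If `TRUE`, the acceptance test uses `frozen_mean` and
#'   `frozen_sd` instead of the live statistics; the growth then equals a
#'   flood fill of the thresholded image restricted to `eligible`.
#' @param frozen_mean,frozen_sd Statistics used in frozen mode; the defaults
#'   are the seed intensity and zero.
#' @param label Integer class id recorded in the returned state.
#' @return List with `mask` (logical matrix, connected, containing the seed)
#'   and `state` (the final `region_state`).
#' @export
grow_region <- function(image, seed, config = grow_config(), eligible = NULL,
                        frozen = FALSE, frozen_mean = NULL, frozen_sd = 0,
                        label = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    data_error("image must be a numeric matrix")
  if (any(!is.finite(image))) data_error("image contains non-finite values")
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > nrow(image) ||
      seed[2] < 1L || seed[2] > ncol(image))
    config_error(sprintf("seed (%s) is outside the image",
                         paste(seed, collapse = ",")))
  if (is.null(eligible)) eligible <- matrix(TRUE, nrow(image), ncol(image))
  if (!eligible[seed[1], seed[2]])
    config_error(sprintf("seed (%d,%d) is not eligible", seed[1], seed[2]))
  if (is.null(frozen_mean)) frozen_mean <- image[seed[1], seed[2]]
  res <- grow_region_core(image, seed[1] - 1L, seed[2] - 1L, eligible,
                          neigh_code(config$neighborhood),
                          config$k_sigma, config$t_min,
                          frozen, frozen_mean, frozen_sd,
                          var_code(config$variance_update))
  state <- structure(list(label = as.integer(label), n = as.integer(res$n),
                          mean = res$mean,
                          disp = res$disp,
                          variance_update = config$variance_update),
                     class = "region_state")
  list(mask = res$mask, state = state)
}

#' Segment an image by sequential seeded region growing
#'
#' Grows one region per class in `config$class_order`, each restricted to the
#' pixels not yet claimed by an earlier class; pixels never accepted remain
#' label 0 (background). If a later class's seed has already been claimed by
#' an earlier-grown class, that class grows an empty region (deterministic,
#' documented behavior — the pixel belongs to whichever class reached it
#' first).
#'
#' @param image Numeric matrix of intensities.
#' @param seeds Named list of `c(row, col)` seeds, one per class in
#'   `config$class_order`; seeds must be pairwise distinct.
#' @param config A [grow_config()].
#' @return Integer label matrix (0 = background) with attribute `classes`,
#'   the named class-id vector.
#' @export
segment_image <- function(image, seeds, config = grow_config()) {
  missing <- setdiff(config$class_order, names(seeds))
  if (length(missing))
    config_error(paste("missing seeds for class(es):",
                       paste(missing, collapse = ", ")))
  coords <- do.call(rbind, seeds[config$class_order])
  if (anyDuplicated(coords))
    config_error("seeds must be pairwise distinct")
  labels <- matrix(0L, nrow(image), ncol(image))
  eligible <- matrix(TRUE, nrow(image), ncol(image))
  for (cls in config$class_order) {
    id <- tissue_classes[[cls]]
    seed <- as.integer(seeds[[cls]])
    if (seed[1] < 1L || seed[1] > nrow(image) ||
        seed[2] < 1L || seed[2] > ncol(image))
      config_error(sprintf("seed for class %s (%s) is outside the image",
                           cls, paste(seed, collapse = ",")))
    if (!eligible[seed[1], seed[2]]) next # claimed by an earlier class
    res <- grow_region(image, seed, config, eligible, label = id)
    labels[res$mask] <- id
    eligible[res$mask] <- FALSE
  }
  attr(labels, "classes") <- tissue_classes[config$class_order]
  labels
}
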