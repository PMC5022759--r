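#' Specification for a synthetic brain phantom
#'
#' Describes a BrainWeb-style 2-D phantom: piecewise-constant tissue classes
#' (background, cerebrospinal fluid, gray matter, white matter) with distinct
#' mean intensities, additive Gaussian noise and an optional smooth
#' multiplicative intensity non-uniformity (bias) field. The defaults place
#' the class means in T1-weighted order (CSF darkest of the tissues, white
#' matter brightest) on a 0-255 scale.
#'
#' @param shape Integer vector `c(rows, cols)`, both >= 8.
#' @param class_means Named numeric vector with entries `background`, `csf`,
#'   `gm`, `wm`; all values must be distinct.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   intensity units; >= 0.
#' @param bias_amplitude Amplitude of the multiplicative bias field as a
#'   fraction; the field spans `1 +/- bias_amplitude`. >= 0.
#' @param geometry `"nested-ellipses"` (CSF ring outside a GM ring outside a
#'   WM core, mimicking cortical topology) or `"voronoi-blobs"` (irregular
#'   convex patches).
#' @param rng_seed Integer seed controlling the noise (and, for
#'   `"voronoi-blobs"`, the site placement).
#' @return A `phantom_spec` object (a validated list).
#' @examples
#' spec <- phantom_spec(shape = c(64, 64), noise_sigma = 5)
#' ph <- generate_phantom(spec)
#' table(ph$reference$labels)
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         class_means = c(background = 0, csf = 60,
                                         gm = 120, wm = 200),
                         noise_sigma = 0,
                         bias_amplitude = 0,
                         geometry = c("nested-ellipses", "voronoi-blobs"),
                         rng_seed = 1L) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    config_error("phantom shape must be two dimensions, each >= 8")
  needed <- c("background", "csf", "gm", "wm")
  if (!all(needed %in% names(class_means)))
    config_error("class_means must name background, csf, gm and wm")
  class_means <- class_means[needed]
  if (anyDuplicated(class_means))
    config_error("all class means must be distinct")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    config_error("noise_sigma must be a finite value >= 0")
  if (!is.finite(bias_amplitude) || bias_amplitude < 0)
    config_error("bias_amplitude must be a finite value >= 0")
  structure(list(shape = shape, class_means = class_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 geometry = geometry, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Ground-truth label matrix (0 bg, 1 csf, 2 gm, 3 wm) for a spec's geometry.
# Deterministic given the spec; voronoi sites come from a geometry-only
# substream (rng_seed + 1) so that two specs differing only in rng_seed
# share no geometry change unless sites are involved.
phantom_labels <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  labels <- matrix(0L, nr, nc)
  if (spec$geometry == "nested-ellipses") {
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    u <- (row(labels) - cr) / (nr / 2)
    v <- (col(labels) - cc) / (nc / 2)
    r2 <- u * u + v * v
    labels[r2 <= 0.90^2] <- tissue_classes[["csf"]]
    labels[r2 <= 0.72^2] <- tissue_classes[["gm"]]
    labels[r2 <= 0.45^2] <- tissue_classes[["wm"]]
  } else {
    margin_r <- max(1L, nr %/% 8L); margin_c <- max(1L, nc %/% 8L)
    sites <- with_rng_seed(spec$rng_seed + 1L, {
      k <- 6L # two convex patches per tissue
      cbind(r = runif(k, margin_r + 1, nr - margin_r),
            c = runif(k, margin_c + 1, nc - margin_c),
            class = rep(unname(tissue_classes), each = 2L))
    })
    interior <- row(labels) > margin_r & row(labels) <= nr - margin_r &
      col(labels) > margin_c & col(labels) <= nc - margin_c
    idx <- which(interior)
    rr <- row(labels)[idx]; cc2 <- col(labels)[idx]
    d2 <- sapply(seq_len(nrow(sites)), function(s)
      (rr - sites[s, "r"])^2 + (cc2 - sites[s, "c"])^2)
    labels[idx] <- as.integer(sites[max.col(-d2, ties.method = "first"), "class"])
  }
  labels
}

# Smooth multiplicative bias field scaled to span 1 +/- amplitude:
# a fixed low-order polynomial surface, normalized to [-1, 1].
bias_field <- function(shape, amplitude) {
  nr <- shape[1]; nc <- shape[2]
  if (amplitude == 0) return(matrix(1, nr, nc))
  xn <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  yn <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  p <- xn + 0.6 * yn + 0.8 * xn * yn - 0.5 * xn^2
  p <- 2 * (p - min(p)) / (max(p) - min(p)) - 1
  1 + amplitude * p
}

#' Generate a synthetic phantom with exact ground truth
#'
#' Renders the spec's geometry as a class-mean raster, multiplies it by the
#' bias field and adds `N(0, noise_sigma^2)` noise. The same spec (including
#' `rng_seed`) always yields a bit-identical image.
#'
#' @param spec A [phantom_spec()] object.
#' @return A `phantom` object: a list with `image` (numeric matrix),
#'   `reference` (a `reference_segmentation`: logical masks `csf`, `gm`, `wm`
#'   plus the integer `labels` map) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    config_error("spec must be a phantom_spec object")
  labels <- phantom_labels(spec)
  means <- c(spec$class_means[["background"]], spec$class_means[["csf"]],
             spec$class_means[["gm"]], spec$class_means[["wm"]])
  image <- matrix(means[labels + 1L], spec$shape[1], spec$shape[2])
  image <- image * bias_field(spec$shape, spec$bias_amplitude)
  if (spec$noise_sigma > 0) {
    noise <- with_rng_seed(spec$rng_seed,
                           matrix(rnorm(length(labels), 0, spec$noise_sigma),
                                  spec$shape[1], spec$shape[2]))
    image <- image + noise
  }
  structure(list(image = image,
                 reference = as_reference(labels),
                 spec = spec),
            class = "phantom")
}

#' Reference segmentation from a label map
#'
#' Splits an integer label map (0 = background, 1 = CSF, 2 = GM, 3 = WM) into
#' the per-class binary maps used by the fitness and evaluation routines.
#'
#' @param labels Integer matrix of class labels.
#' @return A `reference_segmentation`: list of logical matrices `csf`, `gm`,
#'   `wm` plus the original `labels`.
#' @export
as_reference <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  out <- lapply(tissue_classes, function(id) labels == id)
  out$labels <- labels
  structure(out, class = "reference_segmentation")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d %s, noise_sigma=%g, bias=%g, seed=%d\n",
              x$shape[1], x$shape[2], x$geometry, x$noise_sigma,
              x$bias_amplitude, x$rng_seed))
  invisible(x)
}
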