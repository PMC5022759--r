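has_ext <- function(path, exts) {
  any(vapply(exts, function(e) grepl(paste0("\\.", e, "$"), path,
                                     ignore.case = TRUE), logical(1)))
}

#' Read a scalar intensity image
#'
#' Supports grayscale PNG (intensities rescaled to 0-255) and NIfTI-1
#' (`.nii` / `.nii.gz`, intensities as stored). An RGB PNG is accepted only
#' if all channels are equal (i.e. gray stored as RGB); otherwise it is a
#' format error. 3-D NIfTI volumes are returned as arrays unless `slice`
#' selects a 2-D axial slice.
#'
#' @param path Input file.
#' @param slice Optional integer: for 3-D NIfTI input, the index along the
#'   third dimension to extract.
#' @return Numeric matrix (or 3-D array for volumetric NIfTI without
#'   `slice`).
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path)) data_error(paste("no such file:", path))
  if (has_ext(path, "png")) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) {
      ch <- dim(px)[3]
      rgb <- px[, , seq_len(min(ch, 3L)), drop = FALSE]
      if (any(rgb != rgb[, , rep(1L, dim(rgb)[3])]))
        data_error(paste("not a grayscale PNG (RGB channels differ):", path))
      px <- px[, , 1]
    }
    return(px * 255)
  }
  if (has_ext(path, c("nii", "nii.gz"))) {
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) == 3 && !is.null(slice))
      vol <- vol[, , slice]
    if (length(dim(vol)) == 2) vol <- matrix(as.numeric(vol), dim(vol)[1])
    return(vol)
  }
  data_error(paste("unsupported image format:", path))
}

#' Write a scalar intensity image
#'
#' PNG output clamps to the 0-255 range and quantizes to 8 bits; NIfTI output
#' stores the values as-is (float).
#'
#' @param image Numeric matrix.
#' @param path Output file (`.png`, `.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  if (has_ext(path, "png")) {
    png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  } else if (has_ext(path, c("nii", "nii.gz"))) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else {
    data_error(paste("unsupported image format:", path))
  }
  invisible(path)
}

#' Write a label map losslessly
#'
#' Labels are stored as integers, never scaled floats, so that the
#' squared-difference cost and RMS arithmetic on a round-tripped map stay
#' exact: PNG stores the raw label value per pixel (8-bit gray, labels must
#' be in 0-255; label 0 renders as black), NIfTI uses an int16 datatype.
#'
#' @param labels Integer matrix of class labels.
#' @param path Output file (`.png`, `.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_label_map <- function(labels, path) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (has_ext(path, "png")) {
    if (max(labels) > 255L || min(labels) < 0L)
      data_error("PNG label maps require labels in 0..255")
    png::writePNG(labels / 255, path)
  } else if (has_ext(path, c("nii", "nii.gz"))) {
    RNifti::writeNifti(RNifti::asNifti(labels), path, datatype = "int16")
  } else {
    data_error(paste("unsupported label-map format:", path))
  }
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path Input file.
#' @return Integer label matrix.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) data_error(paste("no such file:", path))
  if (has_ext(path, "png")) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    m <- round(px * 255)
  } else if (has_ext(path, c("nii", "nii.gz"))) {
    m <- as.array(RNifti::readNifti(path))
  } else {
    data_error(paste("unsupported label-map format:", path))
  }
  matrix(as.integer(m), dim(m)[1])
}

#' Read a reference segmentation from per-class mask files
#'
#' Each file is a binary mask image (any nonzero value is foreground); the
#' three masks must share a shape and be pairwise disjoint.
#'
#' @param csf,gm,wm Paths to the per-class mask images.
#' @return A `reference_segmentation`.
#' @export
read_reference <- function(csf, gm, wm) {
  masks <- lapply(list(csf = csf, gm = gm, wm = wm),
                  function(p) read_image(p) > 0)
  dims <- lapply(masks, dim)
  if (!identical(dims$csf, dims$gm) || !identical(dims$csf, dims$wm))
    data_error("reference mask shapes differ")
  if (any(masks$csf & masks$gm) || any(masks$csf & masks$wm) ||
      any(masks$gm & masks$wm))
    data_error("reference class masks overlap")
  labels <- matrix(0L, nrow(masks$csf), ncol(masks$csf))
  for (cls in names(tissue_classes))
    labels[masks[[cls]]] <- tissue_classes[[cls]]
  as_reference(labels)
}

#' Write seed coordinates as JSON
#'
#' @param seeds Named list of `c(row, col)` (1-based).
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  jsonlite::write_json(lapply(seeds, as.integer), path)
  invisible(path)
}

#' Read seed coordinates from JSON
#'
#' @param path JSON file mapping class name to `[row, col]` (1-based).
#' @return Named list of integer `c(row, col)`.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) data_error(paste("no such file:", path))
  seeds <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seeds, as.integer)
}

#' Write a phantom's artifacts to a directory
#'
#' Writes the intensity image, the three per-class ground-truth masks
#' (foreground stored as 255) and the spec (with provenance: package version
#' and seed) as JSON.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"nii.gz"`.
#' @return Character vector of the five paths written.
#' @export
write_phantom <- function(phantom, dir, format = c("png", "nii.gz")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(c("image", "csf", "gm", "wm"), ".", format))
  write_image(phantom$image, paths[1])
  for (i in seq_along(tissue_classes)) {
    cls <- names(tissue_classes)[i]
    write_label_map(phantom$reference[[cls]] * 255L, paths[i + 1])
  }
  spec_path <- file.path(dir, "spec.json")
  spec <- phantom$spec
  jsonlite::write_json(
    list(shape = spec$shape, class_means = as.list(spec$class_means),
         noise_sigma = spec$noise_sigma,
         bias_amplitude = spec$bias_amplitude, geometry = spec$geometry,
         rng_seed = spec$rng_seed,
         provenance = list(package = "growseg",
                           version = as.character(packageVersion("growseg")))),
    spec_path, auto_unbox = TRUE, digits = NA)
  c(paths, spec_path)
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report An `eval_report` from [evaluate_segmentation()].
#' @param json_path,csv_path Output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(rms = report$rms, per_class_rms = as.list(report$per_class_rms),
           label_rms = report$label_rms,
           dice_per_class = as.list(report$dice_per_class)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    df <- data.frame(class = names(report$per_class_rms),
                     rms = unname(report$per_class_rms),
                     dice = unname(report$dice_per_class))
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
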