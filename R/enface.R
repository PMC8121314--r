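#' En-face image of Haller's layer
#'
#' Container for a square grayscale en-face slab image. Pixel values are
#' intensities in \[0, 255\] (vessels dark, background bright), stored as a
#' numeric matrix indexed \[row, column\] with row 1 at the top of the image.
#' In the right-eye (OD) frame the temporal side is the left half.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\]; must be square
#'   with side length >= 64.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param scale_mm_per_px physical pixel pitch in mm/px. The default
#'   `7/512` corresponds to a 7x7 mm macular scan rendered at 512x512 px.
#' @param eye_id opaque identifier carried through feature tables.
#'
#' @return An object of class `enface`.
#' @export
#' @examples
#' img <- enface(matrix(200, 64, 64) - diag(150, 64), "OD")
#' img
enface <- function(pixels, laterality = c("OD", "OS"),
                   scale_mm_per_px = 7 / 512, eye_id = "eye") {
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) != ncol(pixels)) {
    abort(sprintf(
      "non-square image: %d x %d (en-face slabs must be square)",
      nrow(pixels), ncol(pixels)
    ))
  }
  if (nrow(pixels) < 64) {
    abort(sprintf("image side %d < 64 px", nrow(pixels)))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel intensities must lie in [0, 255] with no missing values")
  }
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1 ||
      scale_mm_per_px <= 0) {
    abort("`scale_mm_per_px` must be a single positive number")
  }
  structure(
    list(
      pixels = pixels,
      laterality = laterality,
      scale_mm_per_px = scale_mm_per_px,
      eye_id = as.character(eye_id)
    ),
    class = "enface"
  )
}

#' @export
print.enface <- function(x, ...) {
  cat(sprintf(
    "<enface> %s  %d x %d px  %s  %.5f mm/px  intensity [%d, %d]\n",
    x$eye_id, nrow(x$pixels), ncol(x$pixels), x$laterality,
    x$scale_mm_per_px, round(min(x$pixels)), round(max(x$pixels))
  ))
  invisible(x)
}

#' @export
dim.enface <- function(x) dim(x$pixels)

#' Read a grayscale en-face image from disk
#'
#' Reads a PNG or TIFF file, collapses multi-channel rasters to gray by
#' channel averaging, and rescales intensities to \[0, 255\].
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams enface
#' @return An [enface] object.
#' @export
read_enface <- function(path, laterality = c("OD", "OS"),
                        scale_mm_per_px = 7 / 512, eye_id = NULL) {
  laterality <- match.arg(laterality)
  if (!file.exists(path)) abort(paste0("cannot read image: ", path))
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  )
  if (length(dim(raster)) == 3) {
    # average color channels (drop a 4th alpha channel if present)
    nc <- min(dim(raster)[3], 3)
    raster <- apply(raster[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  px <- raster * 255
  enface(px, laterality, scale_mm_per_px,
         eye_id = eye_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write an en-face image (or binary mask) as an 8-bit grayscale PNG
#'
#' @param x an [enface] object or a logical/0-1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(x, path) {
  m <- if (inherits(x, "enface")) x$pixels / 255 else (x != 0) * 1
  png::writePNG(m, target = path)
  invisible(path)
}

#' Normalize laterality to the right-eye frame
#'
#' All orientation statistics assume the right-eye (OD) convention, in which
#' the temporal side is on the left and natural drainage in the upper
#' hemifield runs from lower-right to upper-left. Left-eye (OS) images are
#' mirrored left-right and relabeled OD; OD images pass through unchanged,
#' so the operation is idempotent.
#'
#' @param img an [enface] object.
#' @param strict if `TRUE`, refuse OS input instead of mirroring.
#' @return An OD-framed [enface] object.
#' @export
normalize_laterality <- function(img, strict = FALSE) {
  stopifnot(inherits(img, "enface"))
  if (img$laterality == "OD") return(img)
  if (strict) abort("OS image rejected (strict right-eye mode)")
  img$pixels <- img$pixels[, rev(seq_len(ncol(img$pixels))), drop = FALSE]
  img$laterality <- "OD"
  img
}

#' Read and validate a dataset manifest
#'
#' The manifest is a UTF-8 CSV with one row per eye and required columns
#' `eye_id`, `image_path`, `label` (`symmetric`/`asymmetric`) and
#' `laterality` (`OD`/`OS`). Optional columns: `rater1`..`rater3`
#' (independent rater labels) and numeric demographics (`age`, `va`,
#' `refraction`, `axial_length`, `cct`).
#'
#' @param path path to the manifest CSV.
#' @return A tibble with one validated row per eye.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("eye_id", "image_path", "label", "laterality")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(m$eye_id)) {
    abort(paste0("duplicate eye_id in manifest: ",
                 paste(unique(m$eye_id[duplicated(m$eye_id)]), collapse = ", ")))
  }
  m$eye_id <- as.character(m$eye_id)
  m$label <- as.character(choro_label_factor(m$label))
  bad_lat <- setdiff(unique(m$laterality), c("OD", "OS"))
  if (length(bad_lat) > 0) {
    abort(paste0("unknown laterality value(s): ", paste(bad_lat, collapse = ", ")))
  }
  rater_cols <- intersect(paste0("rater", 1:3), names(m))
  if (length(rater_cols) > 0) {
    if (length(rater_cols) != 3) {
      abort("rater columns must be rater1, rater2 and rater3 (all three)")
    }
    for (rc in rater_cols) m[[rc]] <- as.character(choro_label_factor(m[[rc]]))
  }
  as_tibble(m)
}

#' Write / read a per-eye feature table
#'
#' The on-disk format is a CSV with `eye_id`, the 28 feature columns in
#' canonical order (see [feature_keys()]), and `label`. Values round-trip
#' at 10 significant digits. Non-finite feature values are written as the
#' ratio cap sentinel with a warning (they indicate a degenerate eye that
#' slipped past the capping policy).
#'
#' @param features tibble with columns `eye_id`, the 28 features, `label`.
#' @param path output CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_feature_table <- function(features, path) {
  keys <- feature_keys()
  missing <- setdiff(c("eye_id", keys, "label"), names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- features[, c("eye_id", keys, "label")]
  bad <- !vapply(out[keys], function(v) all(is.finite(v)), logical(1))
  if (any(bad) && nrow(out) > 0) {
    warn(paste0("non-finite feature values written as sentinel in: ",
                paste(keys[bad], collapse = ", ")))
    for (k in keys[bad]) {
      v <- out[[k]]
      v[!is.finite(v)] <- .ratio_cap_default
      out[[k]] <- v
    }
  }
  for (k in keys) out[[k]] <- signif(out[[k]], 10)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("eye_id", feature_keys(), "label"), names(ft))
  if (length(missing) > 0) {
    abort(paste0("feature table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ft$eye_id <- as.character(ft$eye_id)
  ft$label <- as.character(choro_label_factor(ft$label))
  as_tibble(ft)
}
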