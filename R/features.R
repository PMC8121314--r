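.ratio_cap_default <- 100

# safe ratio with the zero-denominator sentinel policy: a (numerically)
# zero denominator and any quotient beyond the cap yield +/- cap, keeping
# downstream classifiers finite on degenerate eyes.
capped_ratio <- function(num, den, cap = .ratio_cap_default) {
  if (abs(den) < 1e-9) return(cap)
  max(min(num / den, cap), -cap)
}

#' Canonical feature names and column keys
#'
#' The 28 engineered quantities describing the choroidal vascular running
#' pattern, in fixed order. [feature_names()] gives the descriptive names;
#' [feature_keys()] gives the machine-safe column keys used in feature
#' tables (`f01_...` to `f28_...`).
#'
#' @return Character vector of length 28.
#' @export
feature_names <- function() {
  c(
    "vessel area, upper side (mm^2)",
    "vessel length, upper side (mm)",
    "mean vessel diameter, upper side (mm)",
    "vessel area, lower side (mm^2)",
    "vessel length, lower side (mm)",
    "mean vessel diameter, lower side (mm)",
    "Upper to lower ratio of mean vessel diameter",
    "Upper to lower difference of mean vessel diameter",
    "ratio of vessels flowing from upper temporal side to lower nasal side",
    "ratio of vessels flowing from upper nasal side to lower temporal side",
    "ratio of natural oblique vessel, upper side (%)",
    "ratio of unnatural oblique vessel, upper side (%)",
    "ratio of natural oblique vessel, lower side (%)",
    "ratio of unnatural oblique vessel, lower side (%)",
    "Ratio of natural to unnatural oblique vessel, upper side",
    "Ratio of natural to unnatural oblique vessel, lower side",
    "Ratio of No.15 feature to No.16 feature",
    "Difference of No.15 feature between No.16 feature",
    "Upper to lower ratio of natural oblique vessel",
    "Upper to lower difference of natural oblique vessel",
    "Upper to lower difference of mean vessel diameter, ladder pattern image (mm)",
    "Upper to lower difference of total vessel length, ladder pattern image (mm)",
    "Upper to lower ratio of mean vessel diameter, ladder pattern image",
    "Upper to lower ratio of total vessel length, ladder pattern image",
    "Temporal to nasal difference of mean vessel diameter, ladder pattern image (mm)",
    "Temporal to nasal difference of total vessel length, ladder pattern image (mm)",
    "Temporal to nasal ratio of mean vessel diameter, ladder pattern image",
    "Temporal to nasal ratio of total vessel length, ladder pattern image"
  )
}

#' @rdname feature_names
#' @export
feature_keys <- function() {
  c(
    "f01_vessel_area_upper_mm2",
    "f02_vessel_length_upper_mm",
    "f03_mean_diameter_upper_mm",
    "f04_vessel_area_lower_mm2",
    "f05_vessel_length_lower_mm",
    "f06_mean_diameter_lower_mm",
    "f07_upper_lower_ratio_mean_diameter",
    "f08_upper_lower_diff_mean_diameter",
    "f09_crossing_upper_temporal_ratio",
    "f10_crossing_upper_nasal_ratio",
    "f11_natural_pct_upper",
    "f12_unnatural_pct_upper",
    "f13_natural_pct_lower",
    "f14_unnatural_pct_lower",
    "f15_natural_unnatural_ratio_upper",
    "f16_natural_unnatural_ratio_lower",
    "f17_ratio_f15_f16",
    "f18_diff_f15_f16",
    "f19_upper_lower_ratio_natural",
    "f20_upper_lower_diff_natural",
    "f21_upper_lower_diff_mean_diameter_ladder_mm",
    "f22_upper_lower_diff_total_length_ladder_mm",
    "f23_upper_lower_ratio_mean_diameter_ladder",
    "f24_upper_lower_ratio_total_length_ladder",
    "f25_temporal_nasal_diff_mean_diameter_ladder_mm",
    "f26_temporal_nasal_diff_total_length_ladder_mm",
    "f27_temporal_nasal_ratio_mean_diameter_ladder",
    "f28_temporal_nasal_ratio_total_length_ladder"
  )
}

#' Pipeline configuration
#'
#' Tunable parameters of the vessel-quantification pipeline, with the
#' defaults used throughout.
#'
#' @param min_component_px denoising cutoff; `NULL` scales 30 px at
#'   512x512 by the squared size ratio.
#' @param min_segment_px minimum segment pixel count for orientation
#'   statistics.
#' @param ladder_spacing,ladder_strip ladder line spacing and strip height.
#' @param ratio_cap sentinel/cap for zero-denominator and runaway ratios.
#' @return A list of class `choro_config`.
#' @export
choro_config <- function(min_component_px = NULL, min_segment_px = 5,
                         ladder_spacing = 25, ladder_strip = 7,
                         ratio_cap = 100) {
  structure(
    list(
      min_component_px = min_component_px,
      min_segment_px = min_segment_px,
      ladder_spacing = ladder_spacing,
      ladder_strip = ladder_strip,
      ratio_cap = ratio_cap
    ),
    class = "choro_config"
  )
}

#' Compute the 28-feature vector for one eye
#'
#' Runs the full pipeline (binarize, denoise, skeletonize, segment,
#' ladder) on an OD-framed en-face image and assembles the 28 features.
#' OS images are mirrored to the OD frame first.
#'
#' @param img an [enface] object.
#' @param config a [choro_config()].
#' @return A one-row tibble with `eye_id` and the 28 feature columns
#'   (keys from [feature_keys()]).
#' @export
compute_features <- function(img, config = choro_config()) {
  stopifnot(inherits(img, "enface"))
  img <- normalize_laterality(img)
  mask <- denoise(binarize(img), config$min_component_px)
  if (!any(mask)) abort("no vasculature detected after binarization/denoising")
  fv <- features_from_mask(mask, img$scale_mm_per_px, config)
  dplyr::bind_cols(tibble(eye_id = img$eye_id), fv)
}

#' @rdname compute_features
#' @param mask logical vessel mask (already binarized and denoised),
#'   OD frame.
#' @param scale_mm_per_px pixel pitch in mm/px.
#' @export
features_from_mask <- function(mask, scale_mm_per_px = 7 / 512,
                               config = choro_config()) {
  s <- scale_mm_per_px
  cap <- config$ratio_cap
  skel <- skeletonize(mask)
  segs <- extract_segments(skel, config$min_segment_px)
  lad <- to_ladder(mask, config$ladder_spacing, config$ladder_strip)

  up <- region_metrics(mask, skel, "upper", s)
  lo <- region_metrics(mask, skel, "lower", s)
  cross <- midline_crossing_ratios(segs)
  obl <- oblique_ratios(segs)
  lad_up <- ladder_metrics(lad, "upper", s)
  lad_lo <- ladder_metrics(lad, "lower", s)
  lad_t <- ladder_metrics(lad, "temporal", s)
  lad_n <- ladder_metrics(lad, "nasal", s)

  f15 <- capped_ratio(obl$upper_natural_pct, obl$upper_unnatural_pct, cap)
  f16 <- capped_ratio(obl$lower_natural_pct, obl$lower_unnatural_pct, cap)

  v <- c(
    up$vessel_area_mm2,
    up$vessel_length_mm,
    up$mean_diameter_mm,
    lo$vessel_area_mm2,
    lo$vessel_length_mm,
    lo$mean_diameter_mm,
    capped_ratio(up$mean_diameter_mm, lo$mean_diameter_mm, cap),
    up$mean_diameter_mm - lo$mean_diameter_mm,
    cross$upper_temporal,
    cross$upper_nasal,
    obl$upper_natural_pct,
    obl$upper_unnatural_pct,
    obl$lower_natural_pct,
    obl$lower_unnatural_pct,
    f15,
    f16,
    capped_ratio(f15, f16, cap),
    f15 - f16,
    capped_ratio(obl$upper_natural_pct, obl$lower_natural_pct, cap),
    obl$upper_natural_pct - obl$lower_natural_pct,
    lad_up$mean_diameter_mm - lad_lo$mean_diameter_mm,
    lad_up$total_length_mm - lad_lo$total_length_mm,
    capped_ratio(lad_up$mean_diameter_mm, lad_lo$mean_diameter_mm, cap),
    capped_ratio(lad_up$total_length_mm, lad_lo$total_length_mm, cap),
    lad_t$mean_diameter_mm - lad_n$mean_diameter_mm,
    lad_t$total_length_mm - lad_n$total_length_mm,
    capped_ratio(lad_t$mean_diameter_mm, lad_n$mean_diameter_mm, cap),
    capped_ratio(lad_t$total_length_mm, lad_n$total_length_mm, cap)
  )
  out <- as_tibble(as.list(stats::setNames(v, feature_keys())))
  out
}

#' Extract features for every eye in a manifest
#'
#' Reads each image listed in the manifest, normalizes laterality, and
#' computes the 28-feature vector, returning a feature table ready for
#' model training or [write_feature_table()].
#'
#' @param manifest tibble from [read_manifest()] (or with the same
#'   columns). `image_path` entries are resolved relative to `base_dir`
#'   when not absolute.
#' @param config a [choro_config()].
#' @param scale_mm_per_px pixel pitch in mm/px.
#' @param base_dir base directory for relative image paths.
#' @return A tibble: `eye_id`, 28 feature columns, `label`.
#' @export
extract_features <- function(manifest, config = choro_config(),
                             scale_mm_per_px = 7 / 512, base_dir = ".") {
  rows <- purrr::pmap(
    list(manifest$eye_id, manifest$image_path, manifest$laterality),
    function(eye_id, image_path, laterality) {
      p <- if (file.exists(image_path)) image_path else file.path(base_dir, image_path)
      img <- read_enface(p, laterality, scale_mm_per_px, eye_id = eye_id)
      compute_features(img, config)
    }
  )
  out <- dplyr::bind_rows(rows)
  out$label <- manifest$label
  out
}
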