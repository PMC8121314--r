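#' Ladder-pattern transform of a vessel mask
#'
#' Samples the binary vessel mask along horizontal lines drawn every
#' `spacing` pixels. For each line a strip of `strip` rows centered on the
#' line is examined column by column: the ladder pixel is white when a
#' strict majority of the strip rows at that column are vessel (>= 4 of 7
#' with the defaults). The strip is clipped at the image border and the
#' majority is taken over the available rows. The result is a sparse
#' binary image that captures coarse caliber and length trends.
#'
#' @param mask logical vessel mask.
#' @param spacing line spacing in px (default 25); must be >= `strip`.
#' @param strip odd strip height in px (default 7).
#' @return A logical matrix of the same shape, white only on the line
#'   rows; attributes `line_rows` (1-based) and `spacing`, `strip`.
#' @export
to_ladder <- function(mask, spacing = 25, strip = 7) {
  stopifnot(is.matrix(mask))
  if (strip %% 2 == 0) abort("`strip` must be odd")
  if (spacing < strip) abort("`spacing` must be >= `strip`")
  mask <- mask != 0
  H <- nrow(mask)
  hw <- (strip - 1) / 2
  line_rows <- seq(spacing, H - 1, by = spacing)
  lad <- matrix(FALSE, H, ncol(mask))
  for (r in line_rows) {
    rows <- max(1, r - hw):min(H, r + hw)
    votes <- colSums(mask[rows, , drop = FALSE])
    lad[r, ] <- votes >= floor(length(rows) / 2) + 1
  }
  attr(lad, "line_rows") <- line_rows
  attr(lad, "spacing") <- spacing
  attr(lad, "strip") <- strip
  lad
}

# maximal runs of TRUE in a logical vector -> integer run lengths
white_runs <- function(x) {
  if (!any(x)) return(integer(0))
  r <- rle(x)
  r$lengths[r$values]
}

#' Region-wise length and caliber summaries of a ladder image
#'
#' Within the requested image half, maximal horizontal white runs on the
#' ladder lines are enumerated. Each run is one vessel's horizontal
#' cross-section, so total length is the white pixel count and the mean
#' run length is the caliber proxy. Runs are split at the region boundary
#' for the temporal/nasal halves.
#'
#' @param lad ladder image from [to_ladder()].
#' @param region `"upper"`, `"lower"`, `"temporal"`, `"nasal"` or
#'   `"whole"`.
#' @param scale_mm_per_px pixel pitch in mm/px.
#' @return A one-row tibble: `region`, `total_length_mm`,
#'   `mean_diameter_mm` (0 when the region has no runs), `n_runs`.
#' @export
ladder_metrics <- function(lad, region = "whole", scale_mm_per_px = 7 / 512) {
  region <- match.arg(region, c("upper", "lower", "temporal", "nasal", "whole"))
  sel <- region_selector(nrow(lad), ncol(lad), region)
  line_rows <- attr(lad, "line_rows") %||% which(apply(lad, 1, any))
  rows <- intersect(line_rows, sel$rows)
  runs <- integer(0)
  for (r in rows) runs <- c(runs, white_runs(lad[r, sel$cols]))
  tibble(
    region = region,
    total_length_mm = sum(runs) * scale_mm_per_px,
    mean_diameter_mm = if (length(runs) > 0) mean(runs) * scale_mm_per_px else 0,
    n_runs = length(runs)
  )
}
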