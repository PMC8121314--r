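#' Otsu threshold of an 8-bit intensity histogram
#'
#' Discriminant-analysis thresholding: the threshold maximizing the
#' between-class variance of the two intensity classes. Intensities are
#' binned at integers 0..255; among tied maximizers the mean tied level
#' (rounded down) is returned, which centers the cut between well-separated
#' modes.
#'
#' @param pixels numeric vector or matrix of intensities in \[0, 255\].
#' @return Integer threshold `t` in 0..254; class 1 is `intensity <= t`.
#' @export
otsu_threshold <- function(pixels) {
  v <- round(as.numeric(pixels))
  if (length(unique(v)) < 2) {
    abort("degenerate histogram: image has fewer than 2 distinct intensities")
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  omega <- cumsum(p)                  # class-1 weight for t = 0..255
  mu <- cumsum(p * levels)            # class-1 partial mean numerator
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254
  w1 <- omega[1:255]
  m1 <- mu[1:255]
  sb <- (mu_t * w1 - m1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- -Inf          # empty class -> invalid threshold
  best <- which(sb == max(sb))
  as.integer(floor(mean(best))) - 1L  # back to 0-based intensity level
}

#' Binarize an en-face image into a vessel mask
#'
#' Vessels are dark in the en-face slab, so pixels at or below the Otsu
#' threshold become foreground (`TRUE`).
#'
#' @param img an [enface] object.
#' @return A logical matrix (`TRUE` = vessel) with attribute `threshold`.
#' @export
binarize <- function(img) {
  stopifnot(inherits(img, "enface"))
  t <- otsu_threshold(img$pixels)
  mask <- round(img$pixels) <= t
  attr(mask, "threshold") <- t
  mask
}

# 8 (or 4) neighbor offsets, (drow, dcol)
.nbr8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)
.nbr4 <- .nbr8[c(2, 4, 5, 7), ]

#' Label connected components of a binary matrix
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, foreground convention) or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  H <- nrow(mask)
  offs <- if (connectivity == 8) .nbr8 else .nbr4
  # only forward offsets to build each undirected edge once
  offs <- offs[offs[, "dr"] > 0 | (offs[, "dr"] == 0 & offs[, "dc"] > 0), ,
               drop = FALSE]
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)           # pixel linear index -> vertex id
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    rr <- r + offs[k, "dr"]
    cc <- c + offs[k, "dc"]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= ncol(mask)
    j <- (cc[ok] - 1L) * H + rr[ok]
    ok2 <- mask[j]
    if (any(ok2)) {
      edges <- c(edges, rbind(pos[idx[ok]][ok2], pos[j][ok2]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Remove small components and fill small holes in a vessel mask
#'
#' Foreground is 8-connected; components smaller than `min_component_px`
#' are removed. Holes (4-connected background components not touching the
#' image border) smaller than the same cutoff are filled. The default
#' cutoff is 30 px at 512x512, scaled by the squared image-size ratio.
#'
#' @param mask logical vessel mask.
#' @param min_component_px minimum component/hole size to keep/preserve;
#'   `NULL` for the scaled default.
#' @return A logical matrix.
#' @export
denoise <- function(mask, min_component_px = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  H <- nrow(mask)
  if (is.null(min_component_px)) {
    min_component_px <- max(1, round(30 * (H / 512)^2))
  }
  lab <- label_components(mask, 8)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0])
    mask[lab > 0 & sz[pmax(lab, 1L)] < min_component_px] <- FALSE
  }
  # fill small enclosed holes
  bg <- label_components(!mask, 4)
  if (max(bg) > 0) {
    border <- unique(c(bg[1, ], bg[H, ], bg[, 1], bg[, ncol(bg)]))
    sz <- tabulate(bg[bg > 0])
    fill <- setdiff(which(sz < min_component_px), border)
    if (length(fill) > 0) mask[bg %in% fill] <- TRUE
  }
  if (!any(mask)) warn("denoising produced an empty vessel mask")
  mask
}

# shift a matrix by (dr, dc), zero-filling, preserving shape
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen skeletonization
#'
#' Iterative two-subiteration parallel thinning of an 8-connected binary
#' mask down to one-pixel-wide centerlines; iterates to a fixpoint, so
#' re-thinning a skeleton changes nothing. The output is a subset of the
#' input mask.
#'
#' The neighbor-count window is restricted to 3..6 rather than the
#' original 2..6: the unmodified parallel scheme is known to erode
#' constant-width diagonal bands completely (both borders of a 2-px-wide
#' 45-degree line satisfy the deletion conditions simultaneously), which
#' would erase straight vessels running near 45/135 degrees. Requiring
#' three neighbors protects those structures while leaving ordinary
#' thinning unchanged; residual double-pixel staircase steps are handled
#' downstream by [prune_skeleton()].
#'
#' @param mask logical vessel mask.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors in Zhang-Suen order P2..P9, starting north, clockwise.
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
        (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
      if (sub == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1L & b >= 3 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Region-wise basic vessel metrics
#'
#' Splits the image at the horizontal midline (upper/lower) or the vertical
#' midline (temporal/nasal; temporal is the left half in the OD frame) and
#' reports vessel area, centerline length and the mean caliber estimate
#' area/length within the region.
#'
#' @param mask logical vessel mask.
#' @param skel logical skeleton, same shape.
#' @param region one of `"upper"`, `"lower"`, `"temporal"`, `"nasal"`,
#'   `"whole"`.
#' @param scale_mm_per_px pixel pitch in mm/px.
#' @return A one-row tibble: `region`, `vessel_area_mm2`,
#'   `vessel_length_mm`, `mean_diameter_mm`.
#' @export
region_metrics <- function(mask, skel, region = "whole",
                           scale_mm_per_px = 7 / 512) {
  stopifnot(identical(dim(mask), dim(skel)))
  region <- match.arg(region, c("upper", "lower", "temporal", "nasal", "whole"))
  sel <- region_selector(nrow(mask), ncol(mask), region)
  area <- sum(mask[sel$rows, sel$cols]) * scale_mm_per_px^2
  len <- sum(skel[sel$rows, sel$cols]) * scale_mm_per_px
  tibble(
    region = region,
    vessel_area_mm2 = area,
    vessel_length_mm = len,
    mean_diameter_mm = if (len > 0) area / len else 0
  )
}

# half-open halves: rows [1, H/2] are "upper" in 1-based indexing
# (equivalently rows [0, H/2) zero-based); temporal = left half (OD frame).
region_selector <- function(H, W, region) {
  switch(region,
    upper    = list(rows = seq_len(ceiling(H / 2)), cols = seq_len(W)),
    lower    = list(rows = (ceiling(H / 2) + 1):H, cols = seq_len(W)),
    temporal = list(rows = seq_len(H), cols = seq_len(ceiling(W / 2))),
    nasal    = list(rows = seq_len(H), cols = (ceiling(W / 2) + 1):W),
    whole    = list(rows = seq_len(H), cols = seq_len(W))
  )
}
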