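# Pixel-adjacency graph of a binary matrix: vertices are foreground pixels
# (in `which()` order), edges connect neighbors. Returns the edge list as a
# 2-column matrix of vertex ids plus the pixel linear indices.
pixel_edges <- function(mask, connectivity = 8) {
  H <- nrow(mask)
  idx <- which(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  offs <- if (connectivity == 8) .nbr8 else .nbr4
  offs <- offs[offs[, "dr"] > 0 | (offs[, "dr"] == 0 & offs[, "dc"] > 0), ,
               drop = FALSE]
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    rr <- r + offs[k, "dr"]
    cc <- c + offs[k, "dc"]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= ncol(mask)
    j <- (cc[ok] - 1L) * H + rr[ok]
    hit <- mask[j]
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[j][hit])
  }
  list(edges = cbind(from, to), idx = idx, H = H)
}

#' Count skeleton neighbors of every pixel
#'
#' @param skel logical skeleton matrix.
#' @return Integer matrix: number of 8-neighbors that are skeleton pixels.
#' @export
skeleton_degree <- function(skel) {
  s <- (skel != 0) * 1L
  d <- matrix(0L, nrow(s), ncol(s))
  for (k in seq_len(nrow(.nbr8))) {
    d <- d + shift_mat(s, .nbr8[k, "dr"], .nbr8[k, "dc"])
  }
  d[!skel] <- 0L
  d
}

#' Remove redundant staircase pixels from a skeleton
#'
#' Zhang-Suen output is one pixel wide but not minimal: along
#' shallow-angle lines the staircase corners touch three neighbors, which
#' would be mistaken for bifurcations by a neighbor-count rule and would
#' shatter long vessels into micro-segments. This pass deletes any pixel
#' with 2 or 3 neighbors whose neighbors remain mutually 8-connected
#' without it (so connectivity is preserved), iterating to a fixpoint in
#' scan order. Straight 4- or 8-digital lines and genuine junctions are
#' untouched; free ends are never removed.
#'
#' @param skel logical skeleton matrix.
#' @return A logical matrix, subset of `skel`.
#' @export
prune_skeleton <- function(skel) {
  m <- skel != 0
  H <- nrow(m); W <- ncol(m)
  repeat {
    changed <- FALSE
    idx <- which(m)
    for (j in idx) {
      r <- ((j - 1L) %% H) + 1L
      c <- ((j - 1L) %/% H) + 1L
      nb <- matrix(NA_integer_, 0, 2)
      for (k in seq_len(8)) {
        rr <- r + .nbr8[k, "dr"]; cc <- c + .nbr8[k, "dc"]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && m[rr, cc]) {
          nb <- rbind(nb, c(rr, cc))
        }
      }
      n <- nrow(nb)
      if (n < 2 || n > 3) next
      # neighbors pairwise chebyshev-adjacent as one cluster?
      ok <- if (n == 2) {
        max(abs(nb[1, ] - nb[2, ])) == 1
      } else {
        a12 <- max(abs(nb[1, ] - nb[2, ])) == 1
        a13 <- max(abs(nb[1, ] - nb[3, ])) == 1
        a23 <- max(abs(nb[2, ] - nb[3, ])) == 1
        sum(a12, a13, a23) >= 2
      }
      if (ok) {
        m[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Find vessel bifurcation points on a skeleton
#'
#' A branch (bifurcation) point is a skeleton pixel with three or more
#' skeleton neighbors under 8-connectivity; a pixel with exactly one
#' neighbor is a free end.
#'
#' @param skel logical skeleton matrix.
#' @return A tibble with columns `row`, `col` (1-based, row 1 at the top).
#' @export
find_branch_points <- function(skel) {
  d <- skeleton_degree(skel)
  w <- which(skel & d >= 3L, arr.ind = TRUE)
  tibble(row = as.integer(w[, 1]), col = as.integer(w[, 2]))
}

#' Decompose a skeleton into branch-to-branch vessel segments
#'
#' The skeleton is first canonicalized with [prune_skeleton()], then
#' partitioned into maximal paths whose interior pixels have exactly two
#' neighbors; segment endpoints are bifurcation points or free ends.
#' Every non-branch pixel of the pruned skeleton belongs to exactly one
#' segment.
#' Segments with fewer than `min_segment_px` pixels are flagged
#' (`kept = FALSE`) and excluded from orientation statistics, but their
#' pixels still count toward skeleton length totals.
#'
#' Orientation is the chord angle between the two endpoints, measured in
#' degrees from the horizontal with y increasing upward (image row
#' decreasing), folded into \[0, 180). The hemifield (`region`) is decided
#' by the row of the path midpoint.
#'
#' @param skel logical skeleton matrix (OD frame).
#' @param min_segment_px minimum path pixel count for orientation
#'   statistics (default 5).
#' @return A tibble with one row per segment: `segment_id`, `path`
#'   (list-column of n x 2 row/col matrices), `n_px`, `length_px`,
#'   `orientation_deg` (`NA` for closed loops), `region`,
#'   `crosses_midline`, `kept`. Image height is stored in
#'   `attr(, "height")`.
#' @export
extract_segments <- function(skel, min_segment_px = 5) {
  skel <- prune_skeleton(skel)   # staircase corners are not bifurcations
  H <- nrow(skel)
  empty <- tibble(
    segment_id = integer(), path = list(), n_px = integer(),
    length_px = numeric(), orientation_deg = numeric(),
    region = character(), crosses_midline = logical(), kept = logical()
  )
  attr(empty, "height") <- H
  if (!any(skel)) return(empty)

  pe <- pixel_edges(skel, 8)
  nv <- length(pe$idx)
  deg <- tabulate(c(pe$edges[, 1], pe$edges[, 2]), nbins = nv)
  branch <- deg >= 3L
  rows <- ((pe$idx - 1L) %% H) + 1L
  cols <- ((pe$idx - 1L) %/% H) + 1L

  # adjacency lists over all skeleton pixels
  adj <- vector("list", nv)
  if (nrow(pe$edges) > 0) {
    ord <- order(pe$edges[, 1])
    adj_from <- split(pe$edges[ord, 2], factor(pe$edges[ord, 1], levels = seq_len(nv)))
    ord2 <- order(pe$edges[, 2])
    adj_to <- split(pe$edges[ord2, 1], factor(pe$edges[ord2, 2], levels = seq_len(nv)))
    adj <- mapply(function(a, b) sort(unique(c(a, b))), adj_from, adj_to,
                  SIMPLIFY = FALSE)
  }

  interior <- which(!branch)
  if (length(interior) == 0) return(empty)
  in_interior <- !branch

  visited <- logical(nv)
  segs <- list()
  sid <- 0L
  up_rows <- ceiling(H / 2)

  for (v0 in interior) {
    if (visited[v0]) next
    # walk to one end of this interior path (or detect a cycle)
    comp_deg <- function(v) sum(in_interior[adj[[v]]])
    start <- v0
    prev <- 0L
    steps <- 0L
    while (comp_deg(start) == 2 && steps <= nv) {
      nbrs <- adj[[start]][in_interior[adj[[start]]]]
      nxt <- nbrs[nbrs != prev][1]
      if (is.na(nxt) || nxt == v0 && steps > 0) break
      prev <- start
      start <- nxt
      steps <- steps + 1L
      if (start == v0) break  # cycle
    }
    is_cycle <- comp_deg(start) == 2 && all(in_interior[adj[[start]]])
    # ordered walk from `start`
    path_v <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      path_v <- c(path_v, cur)
      nbrs <- adj[[cur]][in_interior[adj[[cur]]]]
      nbrs <- nbrs[nbrs != prev & !visited[nbrs]]
      if (length(nbrs) == 0) break
      prev <- cur
      cur <- nbrs[1]
    }
    # attach adjacent branch pixels at each end (if any)
    head_v <- path_v[1]; tail_v <- path_v[length(path_v)]
    pick_branch <- function(v) {
      b <- adj[[v]][branch[adj[[v]]]]
      if (length(b) == 0) return(NA_integer_)
      # prefer 4-adjacent branch pixels, then lowest id, for determinism
      d4 <- abs(rows[b] - rows[v]) + abs(cols[b] - cols[v])
      b[order(d4, b)][1]
    }
    bh <- pick_branch(head_v)
    bt <- pick_branch(tail_v)
    full <- path_v
    if (!is.na(bh)) full <- c(bh, full)
    if (!is.na(bt) && (length(full) == 1 || bt != full[1])) full <- c(full, bt)
    pr <- rows[full]; pc <- cols[full]
    stepd <- if (length(full) > 1) {
      sqrt(diff(pr)^2 + diff(pc)^2)
    } else numeric(0)
    e1 <- c(pr[1], pc[1]); e2 <- c(pr[length(full)], pc[length(full)])
    theta <- if (is_cycle || (e1[1] == e2[1] && e1[2] == e2[2])) {
      NA_real_
    } else {
      segment_orientation(e1, e2)
    }
    mid <- ceiling(length(full) / 2)
    sid <- sid + 1L
    segs[[sid]] <- list(
      segment_id = sid,
      path = cbind(row = pr, col = pc),
      n_px = length(full),
      length_px = sum(stepd),
      orientation_deg = theta,
      region = if (pr[mid] <= up_rows) "upper" else "lower",
      crosses_midline = any(pr <= up_rows) && any(pr > up_rows)
    )
  }

  out <- tibble(
    segment_id = vapply(segs, `[[`, integer(1), "segment_id"),
    path = lapply(segs, `[[`, "path"),
    n_px = vapply(segs, `[[`, integer(1), "n_px"),
    length_px = vapply(segs, `[[`, numeric(1), "length_px"),
    orientation_deg = vapply(segs, `[[`, numeric(1), "orientation_deg"),
    region = vapply(segs, `[[`, character(1), "region"),
    crosses_midline = vapply(segs, `[[`, logical(1), "crosses_midline")
  )
  out$kept <- out$n_px >= min_segment_px
  attr(out, "height") <- H
  out
}

#' Chord orientation of a segment
#'
#' Angle of the line through two pixels, in degrees from the horizontal
#' with y increasing upward (i.e. using -delta(row)), folded into
#' \[0, 180). 45 degrees runs up-right; 135 degrees runs up-left.
#'
#' @param p1,p2 numeric length-2 vectors `c(row, col)`.
#' @return Orientation in degrees, in \[0, 180).
#' @export
segment_orientation <- function(p1, p2) {
  dr <- p2[1] - p1[1]
  dc <- p2[2] - p1[2]
  if (dr == 0 && dc == 0) abort("coincident endpoints have no orientation")
  theta <- atan2(-dr, dc) * 180 / pi
  theta <- theta %% 180
  if (theta >= 180) theta <- theta - 180
  theta
}

#' Natural / unnatural oblique classification
#'
#' In the right-eye frame, venous drainage in the upper hemifield runs
#' toward the upper-temporal vortex vein (up-left, 95-175 degrees) and in
#' the lower hemifield toward the lower-temporal vortex vein (down-left,
#' i.e. chord orientation 5-85 degrees). A segment following the expected
#' direction for its hemifield is "natural", the opposite band is
#' "unnatural", and near-horizontal or near-vertical segments (within 5
#' degrees of either axis) are "neither".
#'
#' @param orientation_deg numeric vector of chord orientations in \[0, 180).
#' @param region character vector, `"upper"` or `"lower"`.
#' @return Character vector: `"natural"`, `"unnatural"` or `"neither"`
#'   (`NA` orientation gives `"neither"`).
#' @export
classify_oblique <- function(orientation_deg, region) {
  stopifnot(length(orientation_deg) == length(region) || length(region) == 1)
  region <- rep_len(region, length(orientation_deg))
  up_band <- !is.na(orientation_deg) &
    orientation_deg >= 95 & orientation_deg <= 175
  low_band <- !is.na(orientation_deg) &
    orientation_deg >= 5 & orientation_deg <= 85
  out <- rep("neither", length(orientation_deg))
  out[region == "upper" & up_band] <- "natural"
  out[region == "upper" & low_band] <- "unnatural"
  out[region == "lower" & low_band] <- "natural"
  out[region == "lower" & up_band] <- "unnatural"
  out
}

#' Length-weighted natural/unnatural oblique vessel ratios
#'
#' Percentages of classified (natural + unnatural) segment length per
#' hemifield; "neither" segments and segments below the minimum length are
#' excluded from numerator and denominator. A hemifield with no classified
#' segments yields 0 with a warning.
#'
#' @param segments tibble from [extract_segments()].
#' @return A named list: `upper_natural_pct`, `upper_unnatural_pct`,
#'   `lower_natural_pct`, `lower_unnatural_pct`.
#' @export
oblique_ratios <- function(segments) {
  s <- segments[segments$kept, , drop = FALSE]
  s$class <- classify_oblique(s$orientation_deg, s$region)
  out <- list(
    upper_natural_pct = 0, upper_unnatural_pct = 0,
    lower_natural_pct = 0, lower_unnatural_pct = 0
  )
  for (reg in c("upper", "lower")) {
    cls <- s[s$region == reg & s$class != "neither", , drop = FALSE]
    tot <- sum(cls$length_px)
    if (tot == 0) {
      warn(paste0("no classified oblique segments in ", reg, " hemifield"))
      next
    }
    nat_len <- sum(cls$length_px[cls$class == "natural"])
    out[[paste0(reg, "_natural_pct")]] <- 100 * nat_len / tot
    out[[paste0(reg, "_unnatural_pct")]] <- 100 * (tot - nat_len) / tot
  }
  out
}

#' Watershed-crossing flow ratios
#'
#' Among segments whose path crosses the horizontal midline, the fraction
#' oriented along the upper-temporal / lower-nasal axis (95-175 degrees)
#' and along the upper-nasal / lower-temporal axis (5-85 degrees), in the
#' OD frame. With no crossing segments both ratios are 0.
#'
#' @param segments tibble from [extract_segments()].
#' @return A named list `list(upper_temporal = ..., upper_nasal = ...)`.
#' @export
midline_crossing_ratios <- function(segments) {
  s <- segments[segments$kept & segments$crosses_midline &
                  !is.na(segments$orientation_deg), , drop = FALSE]
  if (nrow(s) == 0) return(list(upper_temporal = 0, upper_nasal = 0))
  th <- s$orientation_deg
  list(
    upper_temporal = mean(th >= 95 & th <= 175),
    upper_nasal = mean(th >= 5 & th <= 85)
  )
}
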