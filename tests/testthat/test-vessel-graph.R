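test_that("branch points are skeleton pixels with 3+ neighbors", {
  # "Y": two diagonal arms meeting the top of a vertical stem
  y <- matrix(FALSE, 21, 21)
  y <- set_px(y, line_vert(11, 11, 8))            # stem, rows 11..18
  y <- set_px(y, cbind(11 - 1:6, 11 - 1:6))       # up-left arm
  y <- set_px(y, cbind(11 - 1:6, 11 + 1:6))       # up-right arm
  bp <- find_branch_points(y)
  expect_equal(nrow(bp), 1)
  expect_equal(unlist(bp), c(row = 11, col = 11))
  deg <- skeleton_degree(y)
  expect_equal(sum(y & deg == 1), 3)              # three free ends

  # direct neighbor-count oracle on a random skeleton
  set.seed(5)
  m <- skeletonize(denoise(matrix(runif(48 * 48) < 0.35, 48, 48), 4))
  w <- which(m, arr.ind = TRUE)
  n_nbr <- vapply(seq_len(nrow(w)), function(i) {
    r <- w[i, 1]; c <- w[i, 2]
    cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 48 && cc >= 1 && cc <= 48 && m[rr, cc]) cnt <- cnt + 1
    }
    cnt
  }, numeric(1))
  want <- w[n_nbr >= 3, , drop = FALSE]
  got <- as.matrix(find_branch_points(m))
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
               ignore_attr = TRUE)

  line <- matrix(FALSE, 10, 10)
  line <- set_px(line, line_horiz(5, 2, 7))
  expect_equal(nrow(find_branch_points(line)), 0)
})

test_that("segment extraction partitions the skeleton into maximal paths", {
  # "+" cross with arms of 10: four segments of ~11 px each
  cross <- matrix(FALSE, 25, 25)
  cross[13, 3:23] <- TRUE
  cross[3:23, 13] <- TRUE
  segs <- extract_segments(cross)
  expect_equal(nrow(segs), 4)
  expect_true(all(segs$n_px >= 10 & segs$n_px <= 12))

  # straight line: one segment
  line <- matrix(FALSE, 12, 12)
  line <- set_px(line, line_horiz(6, 2, 9))
  segs1 <- extract_segments(line)
  expect_equal(nrow(segs1), 1)
  expect_equal(segs1$orientation_deg, 0)

  # empty skeleton: empty table
  expect_equal(nrow(extract_segments(matrix(FALSE, 8, 8))), 0)

  # partition invariant on the canonical (pruned) skeleton:
  # interior pixels + branch pixels = skeleton pixels
  set.seed(6)
  for (i in 1:6) {
    m <- prune_skeleton(skeletonize(denoise(matrix(runif(56 * 56) < 0.35,
                                                   56, 56), 5)))
    segs <- extract_segments(m)
    n_branch <- nrow(find_branch_points(m))
    interior <- sum(vapply(seq_len(nrow(segs)), function(j) {
      p <- segs$path[[j]]
      # subtract attached branch endpoints from the path pixel count
      is_branch <- skeleton_degree(m)[p] >= 3
      sum(!is_branch)
    }, numeric(1)))
    expect_equal(interior + n_branch, sum(m))
  }

  # pruning never touches straight digital lines or free ends
  toy <- toy_mask()
  expect_identical(prune_skeleton(toy), toy)
})

test_that("chord orientation follows the upward-y convention", {
  expect_equal(segment_orientation(c(10, 10), c(0, 20)), 45)
  expect_equal(segment_orientation(c(0, 0), c(10, 10)), 135)
  expect_equal(segment_orientation(c(5, 1), c(5, 9)), 0)
  expect_equal(segment_orientation(c(9, 4), c(1, 4)), 90)
  expect_true(all(vapply(1:50, function(i) {
    set.seed(i)
    p1 <- sample(0:50, 2); p2 <- sample(0:50, 2)
    if (all(p1 == p2)) return(TRUE)
    th <- segment_orientation(p1, p2)
    th >= 0 && th < 180
  }, logical(1))))
  expect_error(segment_orientation(c(3, 3), c(3, 3)), "coincident")
})

test_that("oblique classification applies the hemifield drainage bands", {
  expect_equal(classify_oblique(135, "upper"), "natural")
  expect_equal(classify_oblique(45, "lower"), "natural")
  expect_equal(classify_oblique(90, "upper"), "neither")
  expect_equal(classify_oblique(90, "lower"), "neither")
  expect_equal(classify_oblique(45, "upper"), "unnatural")
  expect_equal(classify_oblique(135, "lower"), "unnatural")
  # band edges are inclusive; the 5-degree slack bands are 'neither'
  expect_equal(classify_oblique(c(95, 175, 94.9, 175.1), "upper"),
               c("natural", "natural", "neither", "neither"))
  expect_equal(classify_oblique(c(5, 85, 4.9, 85.1), "lower"),
               c("natural", "natural", "neither", "neither"))

  # exhaustive and exclusive over a fine grid, both regions
  th <- seq(0, 179.9, by = 0.1)
  for (reg in c("upper", "lower")) {
    cls <- classify_oblique(th, reg)
    expect_true(all(cls %in% c("natural", "unnatural", "neither")))
  }
  # horizontal mirror (theta -> 180 - theta) swaps natural and unnatural
  # (integer grid keeps the mirrored angles exactly representable)
  th2 <- setdiff(1:179, c(5, 85, 95, 175))
  up <- classify_oblique(th2, "upper")
  upm <- classify_oblique((180 - th2) %% 180, "upper")
  swap <- c(natural = "unnatural", unnatural = "natural", neither = "neither")
  expect_equal(upm, unname(swap[up]))
  # vertical mirror maps each region's natural set onto the other's
  lo <- classify_oblique((180 - th2) %% 180, "lower")
  expect_equal(lo, up)
})

test_that("oblique ratios are length-weighted over classified segments", {
  mk_seg <- function(theta, region, len, crosses = FALSE, kept = TRUE) {
    tibble::tibble(segment_id = 1L, path = list(cbind(1, 1)), n_px = 10L,
                   length_px = len, orientation_deg = theta, region = region,
                   crosses_midline = crosses, kept = kept)
  }
  segs <- dplyr::bind_rows(
    mk_seg(135, "upper", 100), mk_seg(45, "upper", 100),
    mk_seg(45, "lower", 30), mk_seg(60, "lower", 50)
  )
  r <- oblique_ratios(segs)
  expect_equal(r$upper_natural_pct, 50)
  expect_equal(r$upper_unnatural_pct, 50)
  expect_equal(r$lower_natural_pct, 100)

  # hand-summed mixed case from the toy mask (lengths in the step metric)
  toy_segs <- extract_segments(toy_mask())
  r2 <- oblique_ratios(toy_segs)
  expect_equal(r2$upper_natural_pct, 100 * 21 / 28)  # (11 + 10) / (11 + 10 + 7)
  expect_equal(r2$lower_natural_pct, 100 * 11 / 18)

  # empty hemifield: 0 with a warning
  only_up <- mk_seg(135, "upper", 10)
  expect_warning(r3 <- oblique_ratios(only_up), "lower")
  expect_equal(r3$lower_natural_pct, 0)

  # 'neither' and discarded segments enter neither numerator nor denominator
  segs4 <- dplyr::bind_rows(
    mk_seg(135, "upper", 100), mk_seg(90, "upper", 500),
    mk_seg(45, "upper", 25, kept = FALSE)
  )
  expect_warning(r4 <- oblique_ratios(segs4), "lower")
  expect_equal(r4$upper_natural_pct, 100)
})

test_that("midline-crossing ratios count crossing segments by band", {
  mk <- function(theta, crosses = TRUE) {
    tibble::tibble(segment_id = 1L, path = list(cbind(1, 1)), n_px = 10L,
                   length_px = 10, orientation_deg = theta, region = "upper",
                   crosses_midline = crosses, kept = TRUE)
  }
  one <- mk(135)
  expect_equal(midline_crossing_ratios(one),
               list(upper_temporal = 1, upper_nasal = 0))
  none <- mk(135, crosses = FALSE)
  expect_equal(midline_crossing_ratios(none),
               list(upper_temporal = 0, upper_nasal = 0))
  three <- dplyr::bind_rows(mk(30), mk(120), mk(150))
  r <- midline_crossing_ratios(three)
  expect_equal(r$upper_temporal, 2 / 3)
  expect_equal(r$upper_nasal, 1 / 3)

  # from pixels: the toy mask's only crosser runs at 135 degrees
  toy_segs <- extract_segments(toy_mask())
  expect_equal(midline_crossing_ratios(toy_segs),
               list(upper_temporal = 1, upper_nasal = 0))
})

test_that("vertical mirror of a thin mask swaps hemifield statistics exactly", {
  m <- toy_mask()
  flipped <- m[64:1, ]
  r <- oblique_ratios(extract_segments(m))
  rf <- oblique_ratios(extract_segments(flipped))
  expect_equal(rf$upper_natural_pct, r$lower_natural_pct)
  expect_equal(rf$lower_natural_pct, r$upper_natural_pct)
  # total natural length is invariant (equal percentages re-weighted)
  segs <- extract_segments(m); segsf <- extract_segments(flipped)
  nat_len <- function(s) {
    cl <- classify_oblique(s$orientation_deg, s$region)
    sum(s$length_px[cl == "natural" & s$kept])
  }
  expect_equal(nat_len(segsf), nat_len(segs))
})
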