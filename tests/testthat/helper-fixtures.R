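# Fixture builders shared across tests. All fixtures are built in code.

# set pixels (n x 2 matrix of row, col) in a logical mask
set_px <- function(mask, px) {
  mask[px] <- TRUE
  mask
}

# 1-px digital lines; these are Zhang-Suen fixpoints, so skeleton == mask
line_diag_down <- function(r0, c0, n) cbind(r0 + 0:(n - 1), c0 + 0:(n - 1)) # 135 deg
line_diag_up <- function(r0, c0, n) cbind(r0 - 0:(n - 1), c0 + 0:(n - 1))   # 45 deg
line_vert <- function(r0, c0, n) cbind(r0 + 0:(n - 1), rep(c0, n))          # 90 deg
line_horiz <- function(r0, c0, n) cbind(rep(r0, n), c0 + 0:(n - 1))         # 0 deg

# The hand-built 64x64 toy mask: seven 1-px components with known
# geometry, so every Table-style feature can be recomputed from first
# principles by toy_feature_oracle() below.
#   U1 135-deg line rows 8..19          (upper, natural,  12 px)
#   U2  45-deg line rows 13..20         (upper, unnatural, 8 px)
#   U3  vertical   col 58, rows 18..30  (upper, neither,  13 px)
#   U5  vertical   col 45, rows 20..28  (upper, neither,   9 px)
#   C1 135-deg line rows 27..37         (crosses midline, 11 px)
#   L1  45-deg line rows 49..60         (lower, natural,  12 px)
#   L2 135-deg line rows 49..56         (lower, unnatural, 8 px)
#   L3  vertical   col 20, rows 44..58  (lower, neither,  15 px)
toy_components <- function() {
  list(
    U1 = list(px = line_diag_down(8, 40, 12), theta = 135, region = "upper"),
    U2 = list(px = line_diag_up(20, 8, 8), theta = 45, region = "upper"),
    U3 = list(px = line_vert(18, 58, 13), theta = 90, region = "upper"),
    U5 = list(px = line_vert(20, 45, 9), theta = 90, region = "upper"),
    C1 = list(px = line_diag_down(27, 27, 11), theta = 135, region = "upper"),
    L1 = list(px = line_diag_up(60, 40, 12), theta = 45, region = "lower"),
    L2 = list(px = line_diag_down(49, 8, 8), theta = 135, region = "lower"),
    L3 = list(px = line_vert(44, 20, 15), theta = 90, region = "lower")
  )
}

toy_mask <- function() {
  m <- matrix(FALSE, 64, 64)
  for (comp in toy_components()) m <- set_px(m, comp$px)
  m
}

# enface image whose binarization recovers `mask` exactly
mask_to_enface <- function(mask, scale = 7 / 512, eye_id = "toy") {
  px <- matrix(255, nrow(mask), ncol(mask))
  px[mask] <- 0
  enface(px, "OD", scale, eye_id = eye_id)
}

# From-scratch oracle for the 28 features of the toy mask: every value is
# recomputed from the component pixel lists with direct counting, no
# pipeline code involved.
toy_feature_oracle <- function(scale) {
  comps <- toy_components()
  H <- 64
  upper_rows <- 1:32
  px_all <- do.call(rbind, lapply(comps, `[[`, "px"))

  # region pixel counts (area/length; skeleton == mask for 1-px lines)
  n_up <- sum(px_all[, 1] %in% upper_rows)
  n_lo <- nrow(px_all) - n_up
  f1 <- n_up * scale^2; f2 <- n_up * scale; f3 <- f1 / f2
  f4 <- n_lo * scale^2; f5 <- n_lo * scale; f6 <- f4 / f5
  f7 <- f3 / f6; f8 <- f3 - f6

  # per-component chord classification; chord length in the (1, sqrt(2))
  # step metric equals (n_px - 1) * step
  seg_len <- function(comp) {
    d <- diff(comp$px[, 1])^2 + diff(comp$px[, 2])^2
    sum(sqrt(d))
  }
  # region by midpoint row; C1 midpoint (6th of 11 px) is row 32 -> upper
  seg_region <- function(comp) {
    mid <- comp$px[ceiling(nrow(comp$px) / 2), 1]
    if (mid <= 32) "upper" else "lower"
  }
  nat <- c(upper = 0, lower = 0)
  unnat <- c(upper = 0, lower = 0)
  for (comp in comps) {
    reg <- seg_region(comp)
    band <- if (comp$theta >= 95 && comp$theta <= 175) "up" else
      if (comp$theta >= 5 && comp$theta <= 85) "low" else "none"
    if (band == "none") next
    natural <- (reg == "upper" && band == "up") ||
      (reg == "lower" && band == "low")
    if (natural) nat[reg] <- nat[reg] + seg_len(comp)
    else unnat[reg] <- unnat[reg] + seg_len(comp)
  }
  f11 <- 100 * nat["upper"] / (nat["upper"] + unnat["upper"])
  f12 <- 100 - f11
  f13 <- 100 * nat["lower"] / (nat["lower"] + unnat["lower"])
  f14 <- 100 - f13
  f15 <- f11 / f12
  f16 <- f13 / f14
  f17 <- f15 / f16; f18 <- f15 - f16
  f19 <- f11 / f13; f20 <- f11 - f13

  # crossing segments: only C1 spans rows <= 32 and > 32; theta 135
  f9 <- 1; f10 <- 0

  # ladder: line rows 25 and 50, strip of 7; only the vertical lines
  # produce a majority (7 of 7), giving single-pixel runs at
  # (25, 58), (25, 45) and (50, 20)
  up_runs <- c(1, 1)   # row 25: cols 58 and 45
  lo_runs <- c(1)      # row 50: col 20
  te_runs <- c(1)      # col 20 (temporal half)
  na_runs <- c(1, 1)   # cols 58, 45 (nasal half)
  f21 <- (mean(up_runs) - mean(lo_runs)) * scale
  f22 <- (sum(up_runs) - sum(lo_runs)) * scale
  f23 <- mean(up_runs) / mean(lo_runs)
  f24 <- sum(up_runs) / sum(lo_runs)
  f25 <- (mean(te_runs) - mean(na_runs)) * scale
  f26 <- (sum(te_runs) - sum(na_runs)) * scale
  f27 <- mean(te_runs) / mean(na_runs)
  f28 <- sum(te_runs) / sum(na_runs)

  unname(c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14,
           f15, f16, f17, f18, f19, f20, f21, f22, f23, f24, f25, f26,
           f27, f28))
}

# Exactly mirror-symmetric 74x74 phantom. H = 74 makes the ladder line
# rows (25, 50) mirror images (mirror row of r is 75 - r) and the
# hemifield split (rows 1..37 / 38..74) exact. Oblique information comes
# from 1-px diagonals (Zhang-Suen fixpoints, mirrored exactly); ladder
# runs come from translated 5-px-wide vertical bars whose thinning is
# translation-invariant, so per-hemifield pixel counts match exactly.
symmetric_phantom_mask <- function() {
  m <- matrix(FALSE, 74, 74)
  m <- set_px(m, line_diag_down(10, 30, 14))      # upper natural (135)
  # its mirror: pixels (75 - (10 + t), 30 + t) = line_diag_up(65, 30, 14)
  m <- set_px(m, line_diag_up(65, 30, 14))        # lower natural (45)
  m <- set_px(m, line_diag_up(26, 8, 10))         # upper unnatural (45)
  m <- set_px(m, line_diag_down(49, 8, 10))       # lower unnatural (135)
  # vertical bars, 5 px wide, spanning the ladder strips (22..28 / 47..53)
  m[15:33, 55:59] <- TRUE                         # upper bar
  m[75 - (33:15), 55:59] <- TRUE                  # lower bar (rows 42..60)
  m
}

symmetric_phantom_enface <- function(scale = 7 / 512) {
  mask_to_enface(symmetric_phantom_mask(), scale, eye_id = "sym_phantom")
}

# quick feature-vector accessor by index
fvec <- function(features_row) {
  v <- as.numeric(features_row[1, feature_keys()])
  names(v) <- feature_keys()
  v
}

# Gaussian two-cloud feature data, 28 columns, labels driven by the
# first `k_inf` columns only.
make_cloud_data <- function(n = 100, k_inf = 2, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("symmetric", "asymmetric"), length.out = n)
    X <- matrix(rnorm(n * 28), n, 28)
    shift <- ifelse(y == "symmetric", sep / 2, -sep / 2)
    for (j in seq_len(k_inf)) X[, j] <- X[, j] + shift
    colnames(X) <- feature_keys()
    dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(label = y))
  })
}
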