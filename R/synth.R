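#' Synthetic phantom configuration
#'
#' Parameters of the vascular phantom generator. Phantoms are square
#' 8-bit images with dark branching strokes on a brighter background,
#' emulating the en-face appearance of Haller's layer vessels. The scalar
#' `alpha` in \[0, 1\] controls hemifield asymmetry:
#'
#' * `alpha = 0`: lower-hemifield strokes are exact mirror copies of the
#'   upper ones, so orientations fall in the natural band of each
#'   hemifield (95-175 degrees above, 5-85 below) and calibers match.
#' * as `alpha` grows, a fraction `alpha` of upper-hemifield strokes
#'   (and `lower_flip_scale * alpha` of lower ones; the asymmetric
#'   phenotype is upper-dominant) flips to the opposite orientation
#'   band, half of the flipped strokes are dragged onto the watershed so
#'   vessels cross the midline, and lower-hemifield calibers inflate by
#'   the factor `1 + alpha`.
#'
#' The class label is `"symmetric"` when `alpha < label_threshold`
#' (default 0.5), `"asymmetric"` otherwise.
#'
#' @param image_size side length in px (default 256; 512 supported).
#' @param n_trunks vessel trunks per hemifield.
#' @param n_branches branches sprouted per trunk.
#' @param diameter_mean,diameter_sd trunk caliber (px) distribution.
#' @param vessel_intensity,background_intensity 8-bit means (vessels must
#'   be darker than background).
#' @param noise_sd Gaussian pixel noise SD (8-bit units).
#' @param alpha hemifield asymmetry in \[0, 1\].
#' @param lower_flip_scale relative band-flip rate of the lower
#'   hemifield (the asymmetric phenotype is upper-dominant).
#' @param label_threshold `alpha` cut defining the asymmetric class.
#' @param scale_mm_per_px pixel pitch; default keeps the 7 mm field of
#'   view of the clinical scans at any `image_size`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size = 256, n_trunks = 5, n_branches = 2,
                         diameter_mean = 6, diameter_sd = 1,
                         vessel_intensity = 70, background_intensity = 180,
                         noise_sd = 8, alpha = 0, lower_flip_scale = 0.3,
                         label_threshold = 0.5,
                         scale_mm_per_px = 7 / image_size) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (vessel_intensity >= background_intensity) {
    abort("vessels must be darker than the background")
  }
  if (n_trunks < 1) abort("degenerate config: need at least one trunk")
  structure(
    list(
      image_size = image_size, n_trunks = n_trunks, n_branches = n_branches,
      diameter_mean = diameter_mean, diameter_sd = diameter_sd,
      vessel_intensity = vessel_intensity,
      background_intensity = background_intensity,
      noise_sd = noise_sd, alpha = alpha,
      lower_flip_scale = lower_flip_scale,
      label_threshold = label_threshold,
      scale_mm_per_px = scale_mm_per_px
    ),
    class = "synth_config"
  )
}

# render one anti-aliased stroke (capsule around segment p0-p1, width w px)
# into intensity matrix `img` (darkest-wins compositing).
render_stroke <- function(img, p0, p1, w, vessel_int, bg_int) {
  H <- nrow(img); W <- ncol(img)
  hw <- w / 2
  r0 <- max(1, floor(min(p0[1], p1[1]) - hw - 2))
  r1 <- min(H, ceiling(max(p0[1], p1[1]) + hw + 2))
  c0 <- max(1, floor(min(p0[2], p1[2]) - hw - 2))
  c1 <- min(W, ceiling(max(p0[2], p1[2]) + hw + 2))
  if (r0 > r1 || c0 > c1) return(img)
  rs <- r0:r1; cs <- c0:c1
  ry <- matrix(rs, length(rs), length(cs))
  cx <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  vx <- p1[2] - p0[2]; vy <- p1[1] - p0[1]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    t <- 0
    dx <- cx - p0[2]; dy <- ry - p0[1]
  } else {
    t <- pmin(1, pmax(0, ((cx - p0[2]) * vx + (ry - p0[1]) * vy) / len2))
    dx <- cx - (p0[2] + t * vx); dy <- ry - (p0[1] + t * vy)
  }
  d <- sqrt(dx^2 + dy^2)
  cov <- pmin(1, pmax(0, hw - d + 0.5))  # 1-px soft edge
  patch <- img[rs, cs]
  shaded <- cov * vessel_int + (1 - cov) * bg_int
  img[rs, cs] <- pmin(patch, shaded)     # darkest stroke wins
  img
}

# sample the stroke set (trunks + branches) for one phantom, in stroke
# parameter space; returns a tibble of strokes (one row per stroke).
sample_strokes <- function(cfg) {
  S <- cfg$image_size
  up_mid <- S / 4          # vertical center of the upper hemifield
  strokes <- list()
  for (i in seq_len(cfg$n_trunks)) {
    theta <- runif(1, 105, 165)               # upper natural band, inset 10
    len <- runif(1, 0.35, 0.55) * S
    w <- max(2, rnorm(1, cfg$diameter_mean, cfg$diameter_sd))
    # start near the lower-right of the upper hemifield, run up-left;
    # truncate so the whole stroke stays inside a small margin
    r0 <- runif(1, 0.28, 0.46) * S
    c0 <- runif(1, 0.45, 0.9) * S
    ang <- theta * pi / 180
    len <- min(len, (r0 - 0.04 * S) / sin(ang), (c0 - 0.03 * S) / (-cos(ang)))
    r1 <- r0 - len * sin(ang)
    c1 <- c0 + len * cos(ang)
    trunk <- tibble(
      hemifield = "upper", kind = "trunk", trunk_id = i,
      r0 = r0, c0 = c0, r1 = r1, c1 = c1, theta = theta, width = w,
      length_px = len
    )
    brs <- list()
    for (b in seq_len(cfg$n_branches)) {
      u <- runif(1, 0.3, 0.8)
      bth <- theta + runif(1, -25, 25)
      bth <- min(170, max(100, bth))          # stay inside the band
      blen <- len * runif(1, 0.35, 0.6)
      br0 <- r0 - u * len * sin(ang)
      bc0 <- c0 + u * len * cos(ang)
      bang <- bth * pi / 180
      blen <- min(blen, (br0 - 0.04 * S) / sin(bang),
                  (bc0 - 0.03 * S) / (-cos(bang)))
      brs[[b]] <- tibble(
        hemifield = "upper", kind = "branch", trunk_id = i,
        r0 = br0, c0 = bc0,
        r1 = br0 - blen * sin(bang), c1 = bc0 + blen * cos(bang),
        theta = bth, width = max(2, w * 0.7), length_px = blen
      )
    }
    strokes[[i]] <- dplyr::bind_rows(trunk, dplyr::bind_rows(brs))
  }
  upper <- dplyr::bind_rows(strokes)

  # symmetric counterparts: mirror rows about the horizontal midline
  lower <- upper
  lower$hemifield <- "lower"
  lower$r0 <- S + 1 - upper$r0
  lower$r1 <- S + 1 - upper$r1
  lower$theta <- (180 - upper$theta) %% 180

  all <- dplyr::bind_rows(upper, lower)

  # asymmetry: per-stroke band flip (+ some watershed crossing) and
  # lower-hemifield caliber inflation. Flips are hemifield-biased (the
  # asymmetric phenotype shows counter-drainage vessels mainly in the
  # upper area), which makes the upper/lower feature contrasts grow
  # monotonically with alpha.
  p_flip <- ifelse(all$hemifield == "upper",
                   cfg$alpha, cfg$alpha * cfg$lower_flip_scale)
  flip <- runif(nrow(all)) < p_flip
  if (any(flip)) {
    mid_r <- (S + 1) / 2
    # reflect the stroke about the horizontal line through its own center:
    # same row span (same hemifield), opposite orientation band
    r0f <- all$r0[flip]
    all$r0[flip] <- all$r1[flip]
    all$r1[flip] <- r0f
    all$theta[flip] <- (180 - all$theta[flip]) %% 180
    # half of the flipped strokes are dragged onto the watershed so that
    # vessels visibly cross the midline in asymmetric eyes
    crossers <- which(flip)[runif(sum(flip)) < 0.5]
    if (length(crossers) > 0) {
      shift <- mid_r + runif(length(crossers), -0.05, 0.05) * S -
        (all$r0[crossers] + all$r1[crossers]) / 2
      all$r0[crossers] <- all$r0[crossers] + shift
      all$r1[crossers] <- all$r1[crossers] + shift
    }
  }
  all$width[all$hemifield == "lower"] <-
    all$width[all$hemifield == "lower"] * (1 + cfg$alpha)
  all$flipped <- flip
  all
}

#' Generate one synthetic phantom
#'
#' Renders the sampled strokes with anti-aliasing, adds Gaussian pixel
#' noise, and quantizes to 8 bits. Deterministic for a fixed seed.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed (required for reproducibility).
#' @param eye_id identifier for the generated eye.
#' @return A list of class `synth_sample`: `image` ([enface]), `label`,
#'   `alpha`, `truth` (stroke table: hemifield, orientation, caliber,
#'   length in px).
#' @export
synth_image <- function(cfg = synth_config(), seed = 1, eye_id = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  sample <- with_seed_if(seed, {
    strokes <- sample_strokes(cfg)
    S <- cfg$image_size
    img <- matrix(cfg$background_intensity, S, S)
    for (i in seq_len(nrow(strokes))) {
      img <- render_stroke(
        img,
        c(strokes$r0[i], strokes$c0[i]), c(strokes$r1[i], strokes$c1[i]),
        strokes$width[i], cfg$vessel_intensity, cfg$background_intensity
      )
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd), S, S)
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(img = img, strokes = strokes)
  })
  label <- if (cfg$alpha < cfg$label_threshold) "symmetric" else "asymmetric"
  eye_id <- eye_id %||% sprintf("synth_a%03d_s%d", round(cfg$alpha * 100), seed)
  structure(
    list(
      image = enface(sample$img, "OD", cfg$scale_mm_per_px, eye_id = eye_id),
      label = label,
      alpha = cfg$alpha,
      truth = sample$strokes
    ),
    class = "synth_sample"
  )
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n` phantoms, balanced between a symmetric-regime configuration
#' and an asymmetric-regime one, optionally writing PNG images plus a
#' manifest CSV to `dir`. Per-sample seeds are derived from the master
#' seed, so the whole dataset is reproducible.
#'
#' @param n number of eyes (>= 10).
#' @param cfg_symmetric,cfg_asymmetric [synth_config()]s for the two
#'   regimes (defaults: `alpha` 0.1 and 0.9).
#' @param class_balance fraction of symmetric eyes.
#' @param seed master seed.
#' @param dir output directory for images + `manifest.csv`; `NULL` keeps
#'   everything in memory.
#' @return A tibble manifest (`eye_id`, `image_path`, `label`,
#'   `laterality`, `alpha`, `seed`) with the generated samples in
#'   `attr(, "samples")` (a list of `synth_sample`).
#' @export
synth_dataset <- function(n = 200,
                          cfg_symmetric = synth_config(alpha = 0.1),
                          cfg_asymmetric = synth_config(alpha = 0.9),
                          class_balance = 0.5, seed = 7, dir = NULL) {
  if (n < 10) abort("`n` must be at least 10")
  n_sym <- round(n * class_balance)
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1, n))
  is_sym <- c(rep(TRUE, n_sym), rep(FALSE, n - n_sym))
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- if (is_sym[i]) cfg_symmetric else cfg_asymmetric
    eye_id <- sprintf("eye%04d", i)
    smp <- synth_image(cfg, seed = seeds[i], eye_id = eye_id)
    samples[[i]] <- smp
    path <- paste0(eye_id, ".png")
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_enface_png(smp$image, file.path(dir, path))
    }
    rows[[i]] <- tibble(
      eye_id = eye_id, image_path = path, label = smp$label,
      laterality = "OD", alpha = cfg$alpha, seed = seeds[i]
    )
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  }
  attr(manifest, "samples") <- samples
  manifest
}

#' Feature table of an in-memory synthetic dataset
#'
#' Convenience wrapper: runs [compute_features()] on every generated
#' sample of a [synth_dataset()] manifest without touching the disk.
#'
#' @param manifest manifest returned by [synth_dataset()].
#' @param config a [choro_config()].
#' @return A feature tibble (`eye_id`, 28 features, `label`).
#' @export
synth_features <- function(manifest, config = choro_config()) {
  samples <- attr(manifest, "samples")
  if (is.null(samples)) abort("manifest carries no in-memory samples")
  out <- dplyr::bind_rows(
    lapply(samples, function(s) compute_features(s$image, config))
  )
  out$label <- manifest$label
  out
}
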