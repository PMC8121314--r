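# Independent brute-force reference implementations used to validate the
# package's algorithms. These are deliberately written as plain loops,
# straight from the textbook definitions, sharing no code with R/.

# exhaustive discriminant-analysis threshold search: between-class
# variance computed directly from the pixel values for every threshold.
oracle_otsu_curve <- function(pixels) {
  v <- round(as.numeric(pixels))
  vapply(0:254, function(t) {
    g1 <- v[v <= t]
    g2 <- v[v > t]
    if (length(g1) == 0 || length(g2) == 0) return(-Inf)
    w1 <- length(g1) / length(v)
    w2 <- 1 - w1
    w1 * w2 * (mean(g1) - mean(g2))^2
  }, numeric(1))
}

# naive per-pixel Zhang-Suen thinning (two sub-iterations to fixpoint,
# with the same 3..6 neighbor-count guard against diagonal over-erosion
# as the implementation under test)
oracle_zhang_suen <- function(mask) {
  m <- (mask != 0) * 1L
  H <- nrow(m); W <- ncol(m)
  at <- function(mm, r, c) {
    if (r < 1 || r > H || c < 1 || c > W) 0L else mm[r, c]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- matrix(FALSE, H, W)
      for (r in seq_len(H)) for (c in seq_len(W)) {
        if (m[r, c] == 0L) next
        p <- c(
          at(m, r - 1, c), at(m, r - 1, c + 1), at(m, r, c + 1),
          at(m, r + 1, c + 1), at(m, r + 1, c), at(m, r + 1, c - 1),
          at(m, r, c - 1), at(m, r - 1, c - 1)
        ) # P2..P9: N, NE, E, SE, S, SW, W, NW
        b <- sum(p)
        if (b < 3 || b > 6) next
        seqp <- c(p, p[1])
        a <- sum(seqp[-length(seqp)] == 0 & seqp[-1] == 1)
        if (a != 1) next
        if (sub == 1) {
          if (p[1] * p[3] * p[5] != 0) next
          if (p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0) next
          if (p[1] * p[5] * p[7] != 0) next
        }
        del[r, c] <- TRUE
      }
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# brute-force ladder transform: explicit per-line, per-column majority vote
oracle_ladder <- function(mask, spacing = 25, strip = 7) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  hw <- (strip - 1) / 2
  out <- matrix(FALSE, H, W)
  for (r in seq(spacing, H - 1, by = spacing)) {
    for (cc in seq_len(W)) {
      rows <- max(1, r - hw):min(H, r + hw)
      white <- sum(mask[rows, cc])
      out[r, cc] <- white > length(rows) / 2
    }
  }
  out
}

# AUC by explicit concordant-pair counting (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "asymmetric" | labels == 1 | labels == TRUE)
  neg <- setdiff(seq_along(scores), pos)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# exact Wilcoxon signed-rank p by full enumeration of all sign patterns
oracle_wilcoxon_exact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (k in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(k))[1:n]
    ws[k + 1] <- sum(r[signs == 1])
  }
  mu <- n * (n + 1) / 4
  # two-sided: double the smaller tail
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(1, p)
}

# brute-force 8-connected component count (BFS flood fill)
oracle_component_count <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || seen[r, c]) next
    count <- count + 1
    queue <- list(c(r, c))
    seen[r, c] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  count
}
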