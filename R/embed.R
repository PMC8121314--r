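#' Bilinear image resize
#'
#' @param m numeric matrix.
#' @param size target side length (output is `size` x `size`).
#' @return Resized numeric matrix.
#' @export
resize_bilinear <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  if (H == size && W == size) return(m)
  # map output pixel centers into input coordinates
  ry <- (seq_len(size) - 0.5) * H / size + 0.5 - 0.5
  cx <- (seq_len(size) - 0.5) * W / size + 0.5 - 0.5
  ry <- pmin(pmax(ry, 1), H)
  cx <- pmin(pmax(cx, 1), W)
  r0 <- pmin(floor(ry), H - 1); r1 <- r0 + 1; fr <- ry - r0
  c0 <- pmin(floor(cx), W - 1); c1 <- c0 + 1; fc <- cx - c0
  a <- m[r0, c0, drop = FALSE] * (1 - fr) + m[r1, c0, drop = FALSE] * fr
  b <- m[r0, c1, drop = FALSE] * (1 - fr) + m[r1, c1, drop = FALSE] * fr
  a * matrix(1 - fc, size, size, byrow = TRUE) +
    b * matrix(fc, size, size, byrow = TRUE)
}

# nearest-neighbor rotation about the image center (degrees, CCW)
rotate_nn <- function(m, degrees) {
  H <- nrow(m); W <- ncol(m)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- matrix(m[1, 1], H, W)
  rr <- matrix(seq_len(H), H, W) - cy
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sr <- round(cy + rr * cos(th) - cc * sin(th))
  sc <- round(cx + rr * sin(th) + cc * cos(th))
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out[ok] <- m[cbind(sr[ok], sc[ok])]
  out
}

#' Image-embedding extractors
#'
#' An embedding extractor is a pluggable object turning an OD-framed
#' en-face image into a fixed-length real vector, used as the image
#' pathway of the fused random forest. Two built-ins are provided:
#'
#' * `pixel_embedder(size)`: resizes to `size` x `size`, standardizes,
#'   and flattens — a deterministic, training-free embedding whose
#'   information is then concentrated by PCA ([reduce_pca()]).
#' * `cnn_embedder(...)`: a compact convolutional network trained with
#'   SGD (learning rate 1e-4, momentum 0.9, batch 32, binary
#'   cross-entropy) and flip/rotation augmentation; the embedding is the
#'   penultimate dense layer. See [cnn_embedder()].
#'
#' Any object with `fit_embedder()` and `embed_images()` methods can be
#' plugged in instead (including embeddings from an externally trained
#' deep network).
#'
#' @param size resize target for the pixel embedder.
#' @return An embedder object.
#' @export
pixel_embedder <- function(size = 32) {
  structure(list(size = size, fitted = TRUE),
            class = c("pixel_embedder", "choro_embedder"))
}

#' Fit an embedding extractor on training images
#'
#' @param embedder an embedder object.
#' @param images list of [enface] objects (or numeric matrices).
#' @param labels training labels (ignored by untrained embedders).
#' @param seed RNG seed for trainable embedders.
#' @return The fitted embedder.
#' @export
fit_embedder <- function(embedder, images, labels = NULL, seed = NULL) {
  UseMethod("fit_embedder")
}

#' @export
fit_embedder.pixel_embedder <- function(embedder, images, labels = NULL,
                                        seed = NULL) {
  embedder
}

#' Embed a list of images into a feature matrix
#'
#' @inheritParams fit_embedder
#' @return Numeric matrix, one row per image, fixed column count.
#' @export
embed_images <- function(embedder, images) {
  UseMethod("embed_images")
}

as_pixel_matrix <- function(img) {
  if (inherits(img, "enface")) img$pixels else img
}

#' @export
embed_images.pixel_embedder <- function(embedder, images) {
  rows <- lapply(images, function(im) {
    m <- resize_bilinear(as_pixel_matrix(im), embedder$size)
    v <- as.numeric(m)
    (v - mean(v)) / max(sd(v), 1e-8)
  })
  E <- do.call(rbind, rows)
  colnames(E) <- paste0("px", seq_len(ncol(E)))
  E
}

#' Principal-component reduction of an embedding matrix
#'
#' Centers on the training rows and keeps `k` components (truncated to
#' the rank bound `min(k, n - 1, d)` with a warning). Held-out rows must
#' be projected with the training basis via `predict()`.
#'
#' @param E numeric embedding matrix (training rows).
#' @param k target dimension (default 100).
#' @return An object of class `choro_pca` with elements `scores`
#'   (training projection), `rotation`, `center`, `k`.
#' @export
reduce_pca <- function(E, k = 100) {
  n <- nrow(E)
  if (n < 2) abort("PCA needs at least 2 rows")
  kk <- min(k, n - 1, ncol(E))
  if (kk < k) {
    warn(sprintf("PCA dimension truncated from %d to %d (rank bound)", k, kk))
  }
  pc <- prcomp(E, center = TRUE, scale. = FALSE, rank. = kk)
  structure(
    list(scores = pc$x[, seq_len(kk), drop = FALSE],
         rotation = pc$rotation[, seq_len(kk), drop = FALSE],
         center = pc$center, k = kk),
    class = "choro_pca"
  )
}

#' @export
predict.choro_pca <- function(object, newdata, ...) {
  sweep(newdata, 2, object$center) %*% object$rotation
}
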