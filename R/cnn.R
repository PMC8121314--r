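#' Compact CNN embedding extractor
#'
#' A small two-layer convolutional network standing in for a large
#' pretrained backbone: conv(7x7, stride 4, `filters[1]` maps) -> ReLU ->
#' conv(3x3, stride 2, `filters[2]` maps) -> ReLU -> dense classifier
#' head, trained end-to-end with stochastic gradient descent (learning
#' rate 1e-4, momentum 0.9, batch size 32) on binary cross-entropy, with
#' horizontal-flip, vertical-flip and +/-15 degree rotation augmentation.
#' The embedding returned for an image is the flattened output of the
#' last convolutional layer (the "feature extraction unit"), to be
#' reduced by [reduce_pca()] downstream. Images are resized to
#' `input_size` x `input_size` and standardized per image.
#'
#' @param input_size network input side (default 64 px).
#' @param filters convolution map counts for the two layers.
#' @param hidden width of the dense head used only during training.
#' @param epochs training epochs (the clinical protocol trained for
#'   2000; the default is desk-scale).
#' @param lr,momentum,batch_size SGD settings.
#' @param augment enable flip/rotation augmentation.
#' @return An unfitted embedder of class `cnn_embedder`; fit with
#'   [fit_embedder()].
#' @export
cnn_embedder <- function(input_size = 64, filters = c(8, 16), hidden = 32,
                         epochs = 200, lr = 1e-4, momentum = 0.9,
                         batch_size = 32, augment = TRUE) {
  structure(
    list(
      input_size = input_size, filters = filters, hidden = hidden,
      epochs = epochs, lr = lr, momentum = momentum,
      batch_size = batch_size, augment = augment,
      weights = NULL, fitted = FALSE
    ),
    class = c("cnn_embedder", "choro_embedder")
  )
}

# im2col index matrix: rows = output positions, cols = within-patch
# offsets, entries = linear indices into an `side` x `side` matrix.
im2col_idx <- function(side, k, stride) {
  pos <- seq(1, side - k + 1, by = stride)
  nout <- length(pos)
  patch <- as.vector(outer(0:(k - 1), (0:(k - 1)) * side, `+`))  # r + c*side
  origin <- as.vector(outer(pos, (pos - 1) * side, `+`))
  idx <- outer(origin, patch, `+`)
  attr(idx, "nout") <- nout
  idx
}

cnn_geometry <- function(e) {
  i1 <- im2col_idx(e$input_size, 7, 4)
  o1 <- attr(i1, "nout")
  i2 <- im2col_idx(o1, 3, 2)
  o2 <- attr(i2, "nout")
  list(i1 = i1, o1 = o1, i2 = i2, o2 = o2,
       d_embed = o2^2 * e$filters[2])
}

cnn_init <- function(e, geo, seed) {
  f1 <- e$filters[1]; f2 <- e$filters[2]
  with_seed_if(seed, list(
    W1 = matrix(rnorm(49 * f1, 0, sqrt(2 / 49)), 49, f1),
    b1 = numeric(f1),
    W2 = matrix(rnorm(9 * f1 * f2, 0, sqrt(2 / (9 * f1))), 9 * f1, f2),
    b2 = numeric(f2),
    W3 = matrix(rnorm(geo$d_embed * e$hidden, 0, sqrt(2 / geo$d_embed)),
                geo$d_embed, e$hidden),
    b3 = numeric(e$hidden),
    w4 = matrix(rnorm(e$hidden, 0, sqrt(2 / e$hidden)), e$hidden, 1),
    b4 = 0
  ))
}

# forward pass for one image matrix (standardized input). Returns
# activations needed for backprop / embedding.
cnn_forward <- function(x, w, geo, f1, f2) {
  X1 <- matrix(x[geo$i1], nrow(geo$i1), 49)
  A1 <- X1 %*% w$W1 + matrix(w$b1, nrow(X1), f1, byrow = TRUE)
  A1r <- pmax(A1, 0)
  X2 <- matrix(0, nrow(geo$i2), 9 * f1)
  for (ch in seq_len(f1)) {
    X2[, (ch - 1) * 9 + 1:9] <- matrix(A1r[, ch][geo$i2], nrow(geo$i2), 9)
  }
  A2 <- X2 %*% w$W2 + matrix(w$b2, nrow(X2), f2, byrow = TRUE)
  A2r <- pmax(A2, 0)
  flat <- as.numeric(A2r)
  h <- pmax(as.numeric(flat %*% w$W3) + w$b3, 0)
  z <- sum(h * w$w4) + w$b4
  p <- 1 / (1 + exp(-z))
  list(X1 = X1, A1 = A1, A1r = A1r, X2 = X2, A2 = A2, A2r = A2r,
       flat = flat, h = h, p = p)
}

cnn_prepare_image <- function(img, size) {
  m <- resize_bilinear(as_pixel_matrix(img), size)
  (m - mean(m)) / max(sd(m), 1e-8)
}

#' @export
fit_embedder.cnn_embedder <- function(embedder, images, labels = NULL,
                                      seed = NULL) {
  if (is.null(labels)) abort("the CNN embedder needs training labels")
  y <- as.integer(choro_label_factor(labels) == "symmetric")
  geo <- cnn_geometry(embedder)
  f1 <- embedder$filters[1]; f2 <- embedder$filters[2]
  w <- cnn_init(embedder, geo, seed)
  vel <- lapply(w, function(x) x * 0)
  imgs <- lapply(images, cnn_prepare_image, size = embedder$input_size)
  n <- length(imgs)

  with_seed_if(seed, {
    for (ep in seq_len(embedder$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = embedder$batch_size)) {
        batch <- ord[start:min(start + embedder$batch_size - 1, n)]
        grad <- lapply(w, function(x) x * 0)
        for (i in batch) {
          x <- imgs[[i]]
          if (embedder$augment) {
            if (runif(1) < 0.5) x <- x[, rev(seq_len(ncol(x)))]
            if (runif(1) < 0.5) x <- x[rev(seq_len(nrow(x))), ]
            x <- rotate_nn(x, runif(1, -15, 15))
          }
          fw <- cnn_forward(x, w, geo, f1, f2)
          dz <- fw$p - y[i]
          grad$w4 <- grad$w4 + matrix(fw$h * dz, ncol = 1)
          grad$b4 <- grad$b4 + dz
          dh <- as.numeric(w$w4) * dz * (fw$h > 0)
          grad$W3 <- grad$W3 + outer(fw$flat, dh)
          grad$b3 <- grad$b3 + dh
          dflat <- as.numeric(w$W3 %*% dh)
          dA2 <- matrix(dflat, nrow(fw$A2), f2) * (fw$A2 > 0)
          grad$W2 <- grad$W2 + t(fw$X2) %*% dA2
          grad$b2 <- grad$b2 + colSums(dA2)
          dX2 <- dA2 %*% t(w$W2)
          dA1 <- matrix(0, nrow(fw$A1), f1)
          for (ch in seq_len(f1)) {
            contrib <- rowsum(as.vector(dX2[, (ch - 1) * 9 + 1:9]),
                              group = as.vector(geo$i2))
            dA1[as.integer(rownames(contrib)), ch] <-
              dA1[as.integer(rownames(contrib)), ch] + contrib
          }
          dA1 <- dA1 * (fw$A1 > 0)
          grad$W1 <- grad$W1 + t(fw$X1) %*% dA1
          grad$b1 <- grad$b1 + colSums(dA1)
        }
        for (nm in names(w)) {
          vel[[nm]] <- embedder$momentum * vel[[nm]] -
            embedder$lr * grad[[nm]] / length(batch)
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
      }
    }
  })
  embedder$weights <- w
  embedder$fitted <- TRUE
  embedder
}

#' @export
embed_images.cnn_embedder <- function(embedder, images) {
  if (!isTRUE(embedder$fitted)) abort("CNN embedder is not fitted")
  geo <- cnn_geometry(embedder)
  f1 <- embedder$filters[1]; f2 <- embedder$filters[2]
  rows <- lapply(images, function(im) {
    x <- cnn_prepare_image(im, embedder$input_size)
    cnn_forward(x, embedder$weights, geo, f1, f2)$flat
  })
  E <- do.call(rbind, rows)
  colnames(E) <- paste0("cnn", seq_len(ncol(E)))
  E
}
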