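#' @name classifier
#' @title Small convolutional patch classifier
#'
#' @description
#' A light-weight two-class CNN that separates genuine spots from background
#' structure (noise, diffuse signal, bright immobile blobs) on small ROIs:
#' two 3x3 convolutional layers (16 and 32 channels, ReLU) followed by 2x2
#' max pooling and two fully-connected layers (64 units ReLU, 2-way
#' softmax). Training uses binary cross-entropy and RMSprop; patches are
#' augmented with the three right-angle rotations and horizontal/vertical
#' flips (x6). The network is intentionally tiny so a few hundred annotated
#' ROIs suffice for training.
#'
#' Patches are handled as rows of a matrix in column-major pixel order
#' (`as.vector` of the `roi_px x roi_px` matrix) and are min-max normalized
#' per patch before entering the network, which removes dependence on
#' absolute intensity.
NULL

# ---- geometry helpers ------------------------------------------------------

# rotate an r x r patch (as column-major vector indices) by 90 degrees CCW:
# out[i, j] = in[j, r + 1 - i]
perm_rot90 <- function(r) {
  out <- matrix(0L, r, r)
  idx <- matrix(seq_len(r * r), r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) out[i, j] <- idx[j, r + 1 - i]
  as.vector(out)
}
perm_fliph <- function(r) as.vector(matrix(seq_len(r * r), r, r)[, seq(r, 1)])
perm_flipv <- function(r) as.vector(matrix(seq_len(r * r), r, r)[seq(r, 1), ])

#' Augment labeled patches with rotations and flips
#'
#' Expands each patch into 6 instances: identity, rotations by 90, 180 and
#' 270 degrees, and horizontal and vertical flips.
#'
#' @param patches matrix, one patch per row (column-major pixels).
#' @param labels integer labels, one per row.
#' @param roi_px patch edge.
#' @return List with expanded `patches` and `labels`.
#' @export
augment_patches <- function(patches, labels, roi_px) {
  r <- roi_px
  p90 <- perm_rot90(r)
  p180 <- p90[p90]
  p270 <- p180[p90]
  perms <- list(seq_len(r * r), p90, p180, p270, perm_fliph(r), perm_flipv(r))
  out <- do.call(rbind, lapply(perms, function(p) patches[, p, drop = FALSE]))
  list(patches = out, labels = rep(labels, times = length(perms)))
}

normalize_patches <- function(patches) {
  mins <- apply(patches, 1, min)
  maxs <- apply(patches, 1, max)
  span <- maxs - mins
  span[span == 0] <- 1
  (patches - mins) / span
}

# im2col index table: 9 x (s*s) linear indices into an r x r grid for a 3x3
# valid convolution with s = r - 2 output positions (column-major order).
conv_idx <- function(r) {
  s <- r - 2L
  idx <- matrix(0L, 9, s * s)
  pos <- 0L
  for (j in seq_len(s)) for (i in seq_len(s)) {     # output (i, j), col-major
    pos <- pos + 1L
    k <- 0L
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1L
      idx[k, pos] <- (j + dj - 1L) * r + (i + di)
    }
  }
  idx
}

# 2x2 max-pool groups: 4 x (p*p) linear indices into an s x s grid
pool_idx <- function(s) {
  p <- s %/% 2L
  idx <- matrix(0L, 4, p * p)
  pos <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    pos <- pos + 1L
    k <- 0L
    for (dj in 0:1) for (di in 0:1) {
      k <- k + 1L
      idx[k, pos] <- (2L * (j - 1L) + dj) * s + (2L * (i - 1L) + di) + 1L
    }
  }
  idx
}

cnn_init <- function(roi_px, c1 = 16L, c2 = 32L, fc = 64L, seed = 0L) {
  r <- as.integer(roi_px)
  s1 <- r - 2L; s2 <- s1 - 2L; p <- s2 %/% 2L
  d <- p * p * c2
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(roi_px = r, c1 = c1, c2 = c2, fc = fc,
       s1 = s1, s2 = s2, p = p, d = d,
       W1 = he(9L, c1), b1 = numeric(c1),
       W2 = he(9L * c1, c2), b2 = numeric(c2),
       W3 = he(d, fc), b3 = numeric(fc),
       W4 = he(fc, 2L), b4 = numeric(2L),
       idx1 = conv_idx(r), idx2 = conv_idx(s1), pidx = pool_idx(s2))
}

relu <- function(x) { x[x < 0] <- 0; x }

# conv1 im2col: rows ordered image-fastest, then output position
cnn_im2col1 <- function(net, X) {
  n <- nrow(X)
  s1 <- net$s1
  Xc <- X[, as.vector(net$idx1), drop = FALSE]
  dim(Xc) <- c(n, 9L, s1 * s1)
  matrix(aperm(Xc, c(1, 3, 2)), n * s1 * s1, 9L)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass on normalized patches X (n x r^2). The second convolution is
# decomposed into its 9 kernel offsets (shifted dense multiplications), which
# avoids large intermediate transposes. Returns the activations needed for
# backprop when `keep = TRUE`; `M1` may be passed in precomputed.
cnn_forward <- function(net, X, keep = FALSE, M1 = NULL) {
  n <- nrow(X)
  s1 <- net$s1; s2 <- net$s2
  c1 <- net$c1; c2 <- net$c2

  if (is.null(M1)) M1 <- cnn_im2col1(net, X)
  Z1 <- add_bias(M1 %*% net$W1, net$b1)
  A1 <- relu(Z1)

  A1a <- A1; dim(A1a) <- c(n, s1 * s1, c1)
  Z2 <- matrix(rep(net$b2, each = n * s2 * s2), n * s2 * s2, c2)
  Mk <- if (keep) vector("list", 9L) else NULL
  for (k in 1:9) {
    Ak <- A1a[, net$idx2[k, ], , drop = FALSE]
    dim(Ak) <- c(n * s2 * s2, c1)
    W2k <- net$W2[k + 9L * (seq_len(c1) - 1L), , drop = FALSE]
    Z2 <- Z2 + Ak %*% W2k
    if (keep) Mk[[k]] <- Ak
  }
  A2 <- relu(Z2)

  A2a <- A2; dim(A2a) <- c(n, s2 * s2, c2)
  P <- pmax(A2a[, net$pidx[1, ], , drop = FALSE],
            A2a[, net$pidx[2, ], , drop = FALSE],
            A2a[, net$pidx[3, ], , drop = FALSE],
            A2a[, net$pidx[4, ], , drop = FALSE])
  Fm <- matrix(P, n, net$d)

  Z3 <- add_bias(Fm %*% net$W3, net$b3)
  A3 <- relu(Z3)
  Z4 <- add_bias(A3 %*% net$W4, net$b4)
  Z4 <- Z4 - apply(Z4, 1, max)
  E <- exp(Z4)
  probs <- E / rowSums(E)
  if (!keep) return(list(probs = probs))
  list(probs = probs, M1 = M1, Z1 = Z1, Mk = Mk, Z2 = Z2,
       A2a = A2a, P = P, Fm = Fm, Z3 = Z3, A3 = A3, n = n)
}

cnn_backward <- function(net, fw, Y) {
  n <- fw$n
  s1 <- net$s1; s2 <- net$s2
  c1 <- net$c1; c2 <- net$c2

  dZ4 <- (fw$probs - Y) / n
  g <- list()
  g$W4 <- crossprod(fw$A3, dZ4); g$b4 <- colSums(dZ4)
  dZ3 <- tcrossprod(dZ4, net$W4) * (fw$Z3 > 0)
  g$W3 <- crossprod(fw$Fm, dZ3); g$b3 <- colSums(dZ3)
  dF <- tcrossprod(dZ3, net$W3)
  dP <- dF; dim(dP) <- c(n, net$p * net$p, c2)

  dA2a <- array(0, c(n, s2 * s2, c2))
  taken <- array(FALSE, dim(dP))
  for (k in 1:4) {
    slot <- fw$A2a[, net$pidx[k, ], , drop = FALSE]
    sel <- (slot == fw$P) & !taken
    dA2a[, net$pidx[k, ], ] <- dP * sel
    taken <- taken | sel
  }
  dZ2 <- matrix(dA2a, n * s2 * s2, c2) * (fw$Z2 > 0)
  g$b2 <- colSums(dZ2)
  g$W2 <- matrix(0, 9L * c1, c2)
  dA1a <- array(0, c(n, s1 * s1, c1))
  for (k in 1:9) {
    rows_k <- k + 9L * (seq_len(c1) - 1L)
    g$W2[rows_k, ] <- crossprod(fw$Mk[[k]], dZ2)
    dAk <- tcrossprod(dZ2, net$W2[rows_k, , drop = FALSE])
    dim(dAk) <- c(n, s2 * s2, c1)
    cols <- net$idx2[k, ]
    dA1a[, cols, ] <- dA1a[, cols, , drop = FALSE] + dAk
  }
  dZ1 <- matrix(dA1a, n * s1 * s1, c1) * (fw$Z1 > 0)
  g$W1 <- crossprod(fw$M1, dZ1); g$b1 <- colSums(dZ1)
  g
}

#' Train the spot/background patch classifier
#'
#' @param patches matrix of labeled ROIs, one per row (column-major pixel
#'   order), as produced by [render_training_patches()].
#' @param labels integer vector, 1 = spot, 0 = background; both classes
#'   must be present.
#' @param roi_px patch edge (pixels).
#' @param epochs training epochs (default 30).
#' @param seed RNG seed fixing initialization, shuffling and augmentation
#'   order; identical inputs and seed give identical weights.
#' @param lr,rho RMSprop learning rate and decay.
#' @param batch_size minibatch size.
#' @param augment expand the training set x6 with rotations and flips
#'   (default `TRUE`).
#' @return Object of class `spot_classifier` carrying the weights, the
#'   architecture metadata and the per-epoch training loss curve.
#' @export
train_classifier <- function(patches, labels, roi_px = 16, epochs = 30,
                             seed = 0, lr = 1e-3, rho = 0.9,
                             batch_size = 128, augment = TRUE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training requires both classes")
  if (ncol(patches) != roi_px^2)
    stop("patch size does not match roi_px")
  if (augment) {
    aug <- augment_patches(patches, labels, roi_px)
    patches <- aug$patches; labels <- aug$labels
  }
  X <- normalize_patches(patches)
  n <- nrow(X)
  Y <- cbind(1 - labels, labels)      # column 2 = spot class

  net <- cnn_init(roi_px, seed = seed)
  params <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  cache <- lapply(net[params], function(p) p * 0)
  names(cache) <- params
  eps <- 1e-8
  losses <- numeric(epochs)
  M1full <- cnn_im2col1(net, X)
  pos_off <- (seq_len(net$s1^2) - 1L) * n

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1, n)]
      M1b <- M1full[as.vector(outer(rows, pos_off, "+")), , drop = FALSE]
      fw <- cnn_forward(net, X[rows, , drop = FALSE], keep = TRUE, M1 = M1b)
      pr <- pmin(pmax(fw$probs, 1e-12), 1)
      ep_loss <- ep_loss - mean(rowSums(Y[rows, , drop = FALSE] * log(pr)))
      nb <- nb + 1
      g <- cnn_backward(net, fw, Y[rows, , drop = FALSE])
      for (pn in params) {
        cache[[pn]] <- rho * cache[[pn]] + (1 - rho) * g[[pn]]^2
        net[[pn]] <- net[[pn]] - lr * g[[pn]] / (sqrt(cache[[pn]]) + eps)
      }
    }
    losses[ep] <- ep_loss / nb
  }
  structure(c(net, list(loss_curve = losses, epochs = epochs, seed = seed,
                        n_train = n)),
            class = "spot_classifier")
}

#' @export
print.spot_classifier <- function(x, ...) {
  cat(sprintf(paste0("spot_classifier: %d x %d ROIs, conv 3x3x%d / 3x3x%d,",
                     " pool 2x2, fc %d, softmax 2\n"),
              x$roi_px, x$roi_px, x$c1, x$c2, x$fc))
  cat(sprintf("  trained %d epochs on %d instances; final loss %.4f\n",
              x$epochs, x$n_train, tail(x$loss_curve, 1)))
  invisible(x)
}

#' Classify patches
#'
#' @param model a trained [train_classifier()] model.
#' @param patches matrix, one ROI per row, matching the model's `roi_px`.
#' @return `n x 2` matrix of class probabilities (rows sum to 1); column 2
#'   is the spot probability `p_spot`.
#' @export
classify_patches <- function(model, patches) {
  if (is.vector(patches)) patches <- matrix(patches, 1)
  if (ncol(patches) != model$roi_px^2)
    stop("patch size does not match the model's roi_px")
  X <- normalize_patches(patches)
  out <- matrix(0, nrow(X), 2)
  for (start in seq(1, nrow(X), by = 512)) {
    rows <- start:min(start + 511, nrow(X))
    out[rows, ] <- cnn_forward(model, X[rows, , drop = FALSE])$probs
  }
  colnames(out) <- c("background", "spot")
  out
}

#' Save / load a classifier model
#'
#' The model is serialized as JSON with the architecture metadata embedded,
#' so a single text artifact reproduces classification exactly.
#'
#' @param model a `spot_classifier`.
#' @param path file path.
#' @return `path` (save) or the restored `spot_classifier` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(format = "vestrack-classifier-v1",
              roi_px = model$roi_px, c1 = model$c1, c2 = model$c2,
              fc = model$fc, seed = model$seed, epochs = model$epochs,
              loss_curve = model$loss_curve,
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              W3 = model$W3, b3 = model$b3, W4 = model$W4, b4 = model$b4)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  net <- cnn_init(obj$roi_px, c1 = obj$c1, c2 = obj$c2, fc = obj$fc,
                  seed = if (is.null(obj$seed)) 0 else obj$seed)
  for (pn in c("W1", "W2", "W3", "W4")) net[[pn]] <- as.matrix(obj[[pn]])
  for (pn in c("b1", "b2", "b3", "b4")) net[[pn]] <- as.numeric(obj[[pn]])
  net$loss_curve <- obj$loss_curve
  net$epochs <- obj$epochs
  net$seed <- obj$seed
  net$n_train <- NA_integer_
  class(net) <- "spot_classifier"
  net
}
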