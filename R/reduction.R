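# Large-image classification: tile the image, encode every tile with the
# frozen pretrained stack, reassemble the encoded tiles into one feature
# map, reduce each of G x G subpanes through ONE shared dense map to d_r
# nodes (equivalently a non-overlapping windowed convolution), then reduce
# the concatenated subpane outputs to the class nodes with softmax. The
# reducer's parameter count depends only on the subpane dimensions, G and
# d_r — not on the raw image size.

#' Tile an image into non-overlapping squares
#'
#' @param img H x W x C array with H, W divisible by \code{tile_size}.
#' @param tile_size tile edge in px.
#' @return class \code{tile_grid}: list(tile_size, rows, cols, coords);
#'   coords are row-major half-open (r0, r1, c0, c1), 0-based.
#' @export
tile_image <- function(img, tile_size) {
  img <- as_image_array(img)
  d <- dim(img)
  if (d[1] %% tile_size != 0 || d[2] %% tile_size != 0) {
    stop_shape("image dimensions must be divisible by tile_size")
  }
  rows <- d[1] %/% tile_size; cols <- d[2] %/% tile_size
  coords <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      coords[[length(coords) + 1L]] <-
        c(r0 = (r - 1L) * tile_size, r1 = r * tile_size,
          c0 = (cc - 1L) * tile_size, c1 = cc * tile_size)
    }
  }
  structure(list(tile_size = as.integer(tile_size), rows = rows, cols = cols,
                 coords = coords), class = "tile_grid")
}

get_tile <- function(img, coord) {
  img[(coord["r0"] + 1L):coord["r1"], (coord["c0"] + 1L):coord["c1"], ,
      drop = FALSE]
}

#' Encode tiles with a frozen stack and reassemble
#'
#' Each tile is passed independently through \code{\link{stack_encode}}
#' (per-tile zero padding, so tiles are truly independent) and the encoded
#' tiles are placed back in their grid positions.
#'
#' @param img H x W x C array.
#' @param grid a \code{\link{tile_image}} grid for it.
#' @param stages a trained \code{cae_stack}.
#' @return feature map of dim (H / 2^k, W / 2^k, F_k) for k stages.
#' @export
encode_tiles <- function(img, grid, stages) {
  img <- as_image_array(img)
  k <- length(stages)
  sc <- 2^k
  d <- dim(img)
  Fk <- if (k > 0) stages[[k]]$n_filters else d[3]
  out <- array(0, c(d[1] / sc, d[2] / sc, Fk))
  for (co in grid$coords) {
    enc <- stack_encode(get_tile(img, co), stages)
    out[(co["r0"] / sc + 1L):(co["r1"] / sc),
        (co["c0"] / sc + 1L):(co["c1"] / sc), ] <- enc
  }
  out
}

#' Configure a reduction classifier
#'
#' @param G subpane grid size (G x G subpanes share one dense map).
#' @param d_r per-subpane output dimension.
#' @param tile_size tile edge used when encoding large images.
#' @param n_classes number of class nodes.
#' @param class_names ordered class labels.
#' @return config list consumed by \code{\link{train_reduction}}.
#' @export
reduction_config <- function(G = 8L, d_r = 24L, tile_size = 64L,
                             n_classes = 3L,
                             class_names = c("TRU", "PP", "PI")) {
  list(G = as.integer(G), d_r = as.integer(d_r),
       tile_size = as.integer(tile_size), n_classes = as.integer(n_classes),
       class_names = class_names[seq_len(n_classes)])
}

# (G^2) x subpane_flat matrix of flattened subpanes, subpane row index
# fastest so array(result, c(G, G, .)) restores grid order.
subpane_matrix <- function(z, G) {
  d <- dim(z)
  if (d[1] %% G != 0 || d[2] %% G != 0) {
    stop_shape("feature-map spatial dims must be divisible by G")
  }
  sh <- d[1] %/% G; sw <- d[2] %/% G
  X <- matrix(0, G * G, sh * sw * d[3])
  for (gc in seq_len(G)) {
    for (gr in seq_len(G)) {
      X[(gc - 1L) * G + gr, ] <-
        z[((gr - 1L) * sh + 1L):(gr * sh), ((gc - 1L) * sw + 1L):(gc * sw), ]
    }
  }
  X
}

#' Shared-weight subpane reduction
#'
#' Partitions the feature map into G x G equal subpanes and maps each
#' flattened subpane through the single shared dense layer with sigmoid.
#' If the classifier carries feature standardization statistics (learned
#' from the training features, where encoding activations sit on a large
#' constant background response), each flattened subpane is standardized
#' by them first.
#'
#' @param z H' x W' x F feature map, spatial dims divisible by G.
#' @param rc a trained \code{reduction_classifier} (or any list with
#'   \code{G}, \code{W1}, \code{b1}, optionally \code{feat_mean},
#'   \code{feat_sd}).
#' @return G x G x d_r array of subpane codes.
#' @export
subpane_reduce <- function(z, rc) {
  X <- subpane_matrix(as_image_array(z), rc$G)
  if (ncol(X) != nrow(rc$W1)) stop_shape("subpane size does not match the shared dense map")
  X <- standardize_subpanes(X, rc)
  S <- sigmoid(sweep(X %*% rc$W1, 2L, rc$b1, "+"))
  array(S, c(rc$G, rc$G, ncol(rc$W1)))
}

standardize_subpanes <- function(X, rc) {
  if (!is.null(rc$feat_mean)) {
    X <- sweep(sweep(X, 2L, rc$feat_mean), 2L, rc$feat_sd, "/")
  }
  X
}

#' Full forward pass of the large-image model
#'
#' tile -> encode with the frozen stack -> shared subpane reduction ->
#' final dense -> softmax.
#'
#' @param img H x W x C array.
#' @param stages trained \code{cae_stack} (frozen).
#' @param rc trained \code{reduction_classifier}.
#' @return named probability vector over the classes (sums to 1).
#' @export
reduction_forward <- function(img, stages, rc) {
  grid <- tile_image(img, rc$tile_size)
  z <- encode_tiles(img, grid, stages)
  S <- subpane_reduce(z, rc)
  logits <- drop(as.numeric(S) %*% rc$W2) + rc$b2
  p <- drop(softmax_rows(matrix(logits, 1)))
  names(p) <- rc$class_names
  p
}

#' Train the reduction classifier on pre-encoded features
#'
#' The autoencoder stages are frozen: every training image is encoded once
#' through \code{\link{encode_tiles}} and only the shared subpane map and
#' the final dense layer are optimized (softmax cross-entropy, Adam).
#'
#' @param data a \code{labeled_dataset} of large images.
#' @param stages trained \code{cae_stack}.
#' @param rc_cfg a \code{\link{reduction_config}}.
#' @param cfg a \code{\link{train_config}}.
#' @return class \code{reduction_classifier}: the reducer weights plus the
#'   frozen \code{stages} bundled for prediction, with loss history.
#' @export
train_reduction <- function(data, stages, rc_cfg = reduction_config(),
                            cfg = train_config()) {
  tr <- dataset_subset(data, "train")
  if (length(tr$images) == 0) stop_data("no training images")
  G <- rc_cfg$G; d_r <- rc_cfg$d_r; nc <- rc_cfg$n_classes
  cn <- data$class_names %||% rc_cfg$class_names
  feats <- lapply(tr$images, function(im) {
    grid <- tile_image(im, rc_cfg$tile_size)
    subpane_matrix(encode_tiles(im, grid, stages), G)
  })
  flat_dim <- ncol(feats[[1]])
  # per-dimension standardization statistics from the training features;
  # stored on the classifier and applied at prediction time too
  all_sub <- do.call(rbind, feats)
  feat_mean <- colMeans(all_sub)
  feat_sd <- pmax(apply(all_sub, 2L, stats::sd), 1e-6)
  feats <- lapply(feats, function(X) {
    sweep(sweep(X, 2L, feat_mean), 2L, feat_sd, "/")
  })
  params <- with_seed(cfg$seed, list(
    W1 = init_uniform(c(flat_dim, d_r), flat_dim), b1 = rep(0, d_r),
    W2 = init_uniform(c(G * G * d_r, nc), G * G * d_r), b2 = rep(0, nc)))
  state <- adam_init(params)
  hist <- numeric(cfg$steps)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(length(feats), min(cfg$batch_size, length(feats)))
      acc <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
      lsum <- 0
      for (i in bi) {
        Xs <- feats[[i]]
        S <- sigmoid(sweep(Xs %*% params$W1, 2L, params$b1, "+"))
        s <- as.numeric(S)
        logits <- drop(s %*% params$W2) + params$b2
        lsum <- lsum + softmax_cross_entropy(logits, tr$labels[i])
        p <- drop(softmax_rows(matrix(logits, 1)))
        dl <- p; dl[tr$labels[i]] <- dl[tr$labels[i]] - 1
        acc$W2 <- acc$W2 + outer(s, dl)
        acc$b2 <- acc$b2 + dl
        dS <- matrix(params$W2 %*% dl, nrow(S), ncol(S)) * S * (1 - S)
        acc$W1 <- acc$W1 + crossprod(Xs, dS)
        acc$b1 <- acc$b1 + colSums(dS)
      }
      nbatch <- length(bi)
      acc <- lapply(acc, function(a) a / nbatch)
      hist[step] <- lsum / nbatch
      upd <- adam_step(params, acc, state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
  })
  structure(c(list(G = G, d_r = d_r, tile_size = rc_cfg$tile_size,
                   n_classes = nc, class_names = cn, stages = stages,
                   feat_mean = feat_mean, feat_sd = feat_sd),
              params, list(history = hist)),
            class = "reduction_classifier")
}

#' @export
print.reduction_classifier <- function(x, ...) {
  cat(sprintf("Reduction classifier: %dx%d subpanes -> %d nodes each -> %d classes\n",
              x$G, x$G, x$d_r, x$n_classes))
  cat(sprintf("  shared dense %d -> %d; final %d -> %d; tiles %d px; %d frozen AE stage(s)\n",
              nrow(x$W1), x$d_r, nrow(x$W2), x$n_classes, x$tile_size,
              length(x$stages)))
  invisible(x)
}

#' @export
predict.reduction_classifier <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  imgs <- if (is.list(newdata) && !is.array(newdata)) newdata else list(newdata)
  P <- t(vapply(imgs, function(im) {
    reduction_forward(im, object$stages, object)
  }, numeric(object$n_classes)))
  colnames(P) <- object$class_names
  if (type == "prob") { if (length(imgs) == 1L) drop(P) else P }
  else object$class_names[apply(P, 1L, which.max)]
}

#' Confusion matrix of a reduction classifier on a test split
#'
#' @param rc trained \code{reduction_classifier}.
#' @param data a \code{labeled_dataset}.
#' @return a \code{confusion_matrix}.
#' @export
evaluate_reduction <- function(rc, data) {
  te <- dataset_subset(data, "test")
  if (length(te$images) == 0) stop_data("empty test split")
  nc <- rc$n_classes
  cn <- rc$class_names
  counts <- matrix(0L, nc, nc, dimnames = list(true = cn, predicted = cn))
  for (i in seq_along(te$images)) {
    p <- reduction_forward(te$images[[i]], rc$stages, rc)
    counts[te$labels[i], which.max(p)] <- counts[te$labels[i], which.max(p)] + 1L
  }
  new_confusion_matrix(counts)
}
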