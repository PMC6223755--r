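# Reconstruction independent subspace analysis (RISA): a two-layer network
# whose first layer is a learned linear filter bank C (k filters over
# n-dimensional flattened patches) and whose second layer is a fixed binary
# group pooling H followed by a square-root of the group's summed squared
# responses:
#
#   p_i(x; C, H) = sqrt( sum_m H_im (sum_j C_mj x_j)^2 )
#
# Training minimizes a linear reconstruction term plus a lambda-weighted sum
# of the pooled features, which pushes filters inside one group to share
# invariances (in practice filters pair up). The reconstruction term is
# implemented as ||C^T C x - x||^2, the standard linear-autoencoder form for
# a k x n filter matrix.

#' Fixed binary group-pooling matrix
#'
#' Consecutive non-overlapping groups: g = k / group_size rows, each row
#' selecting \code{group_size} consecutive filters, each filter in exactly
#' one group.
#'
#' @param k number of filters.
#' @param group_size filters per group (must divide k).
#' @return g x k binary matrix.
#' @examples
#' make_pooling_matrix(4, 2)
#' @export
make_pooling_matrix <- function(k, group_size) {
  if (k %% group_size != 0) {
    stop_config("k must be divisible by group_size")
  }
  g <- k %/% group_size
  H <- matrix(0, g, k)
  for (i in seq_len(g)) {
    H[i, ((i - 1L) * group_size + 1L):(i * group_size)] <- 1
  }
  H
}

new_risa_model <- function(C, H, lambda, group_size, patch_size = NULL,
                           in_channels = NULL) {
  structure(list(C = C, H = H, lambda = lambda,
                 group_size = as.integer(group_size),
                 patch_size = patch_size, in_channels = in_channels),
            class = "risa_model")
}

#' @export
print.risa_model <- function(x, ...) {
  cat(sprintf("RISA model: %d filters over %d-dim patches, %d groups of %d, lambda = %.3g\n",
              nrow(x$C), ncol(x$C), nrow(x$H), x$group_size, x$lambda))
  h <- attr(x, "history")
  if (!is.null(h)) {
    cat(sprintf("  trained %d steps; objective %.4g -> %.4g\n",
                length(h), h[1], h[length(h)]))
  }
  invisible(x)
}

as_patch_vector <- function(x) {
  if (is.array(x) || is.matrix(x)) as.numeric(x) else x
}

#' RISA second-layer output for one patch
#'
#' Exact evaluation of p_i = sqrt(sum_m H_im (C x)_m^2); nonnegative and
#' positively homogeneous (p(a x) = |a| p(x)).
#'
#' @param x flattened patch of length n (arrays are flattened column-major).
#' @param model a \code{risa_model}.
#' @return numeric vector of g pooled features.
#' @export
risa_forward <- function(x, model) {
  x <- as_patch_vector(x)
  if (length(x) != ncol(model$C)) {
    stop_shape("patch length does not match the filter matrix")
  }
  y <- drop(model$C %*% x)
  sqrt(drop(model$H %*% y^2))
}

#' RISA training objective on a batch
#'
#' sum_t [ (1/N) ||C^T C x_t - x_t||^2 + lambda sum_i p_i(x_t) ] with N the
#' batch size.
#'
#' @param batch list of patches, or an n x T matrix of column patches.
#' @param model a \code{risa_model}.
#' @return scalar objective.
#' @export
risa_objective <- function(batch, model) {
  X <- batch_matrix(batch, ncol(model$C))
  N <- ncol(X)
  Y <- model$C %*% X
  E <- crossprod(model$C, Y) - X
  P <- sqrt(model$H %*% Y^2)
  sum(E * E) / N + model$lambda * sum(P)
}

batch_matrix <- function(batch, n) {
  X <- if (is.matrix(batch)) batch
  else if (is.list(batch) && length(batch) > 0) {
    vapply(batch, as_patch_vector, numeric(n))
  } else stop_data("empty batch")
  if (!is.matrix(X)) X <- matrix(X, n)
  if (nrow(X) != n) stop_shape("patch length does not match the filter matrix")
  if (ncol(X) == 0) stop_data("empty batch")
  X
}

# Objective value and gradient wrt C on a batch matrix X (n x T).
risa_grad <- function(C, H, lambda, X) {
  N <- ncol(X)
  Y <- C %*% X                       # k x T filter responses
  E <- crossprod(C, Y) - X           # n x T reconstruction error
  P <- sqrt(H %*% Y^2)               # g x T pooled features
  obj <- sum(E * E) / N + lambda * sum(P)
  # d/dC of sum ||C^T C x - x||^2 = 2 (Y E^T + (C E) X^T)
  g <- (2 / N) * (Y %*% t(E) + (C %*% E) %*% t(X))
  if (lambda > 0) {
    Pf <- crossprod(H, P)            # k x T: each filter's own group norm
    g <- g + lambda * ((Y / pmax(Pf, 1e-12)) %*% t(X))
  }
  list(obj = obj, grad = g)
}

#' Train a RISA model
#'
#' Adam minimization of \code{\link{risa_objective}} over the filter matrix
#' C; the pooling matrix H is fixed throughout.
#'
#' @param data list of fixed-size patches (arrays or vectors) or an n x T
#'   matrix.
#' @param k number of filters.
#' @param group_size filters per pooling group (default 2: paired filters).
#' @param lambda pooled-feature penalty weight.
#' @param cfg a \code{\link{train_config}} (its \code{lambda_s} is ignored;
#'   \code{lambda} is the RISA weight).
#' @param patch_size,in_channels optional patch geometry, recorded so the
#'   model can be applied convolutionally to images.
#' @return a \code{risa_model} with per-step objective history attached.
#' @export
train_risa <- function(data, k, group_size = 2L, lambda = 0.1,
                       cfg = train_config(), patch_size = NULL,
                       in_channels = NULL) {
  if (is.list(data) && length(data) == 0) stop_data("no training patches")
  if (is.list(data) && is.null(patch_size) && is.array(data[[1]])) {
    d <- dim(data[[1]])
    patch_size <- d[1]
    in_channels <- if (length(d) >= 3) d[3] else 1L
  }
  n <- if (is.matrix(data)) nrow(data) else length(as_patch_vector(data[[1]]))
  X_all <- batch_matrix(data, n)
  H <- make_pooling_matrix(k, group_size)
  C <- with_seed(cfg$seed, init_uniform(c(k, n), n))
  params <- list(C = C)
  state <- adam_init(params)
  hist <- numeric(cfg$steps)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(ncol(X_all), min(cfg$batch_size, ncol(X_all)))
      gr <- risa_grad(params$C, H, lambda, X_all[, bi, drop = FALSE])
      hist[step] <- gr$obj
      upd <- adam_step(params, list(C = gr$grad), state,
                       lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
  })
  model <- new_risa_model(params$C, H, lambda, group_size, patch_size,
                          in_channels)
  attr(model, "history") <- hist
  model
}

#' Apply a RISA model convolutionally to an image
#'
#' Slides the model's patch window over the image with stride 1 and
#' same-style zero padding (the same coverage as a convolution layer) and
#' computes the g pooled features at every position.
#'
#' @param img H x W x C array; the model must carry \code{patch_size} and
#'   \code{in_channels}.
#' @param model a \code{risa_model}.
#' @return H x W x g feature map.
#' @export
risa_forward_conv <- function(img, model) {
  if (is.null(model$patch_size)) {
    stop_config("model has no patch geometry; train with patch arrays")
  }
  img <- as_image_array(img)
  d <- dim(img)
  if (d[3] != model$in_channels) stop_shape("channel count does not match model")
  cols <- im2col(img, model$patch_size)    # (H*W) x n
  Y <- cols %*% t(model$C)                 # (H*W) x k
  P <- sqrt(Y^2 %*% t(model$H))            # (H*W) x g
  array(P, c(d[1], d[2], nrow(model$H)))
}

#' @export
predict.risa_model <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L &&
      !is.null(object$patch_size) &&
      !identical(dim(newdata)[1], object$patch_size)) {
    risa_forward_conv(newdata, object)
  } else {
    risa_forward(newdata, object)
  }
}

#' @export
plot.risa_model <- function(x, ...) {
  h <- attr(x, "history")
  if (is.null(h)) stop_data("model has no training history")
  graphics::plot(h, type = "l", xlab = "step", ylab = "objective", ...)
  invisible(x)
}
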