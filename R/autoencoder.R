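# Single-stage convolutional autoencoder with an information-entropy
# sparsity penalty on the encoding layer, and greedy layer-wise stacking.
#
# One stage: same-padded convolution -> sigmoid -> 2x2 max pool (encode);
# unpool by copying each value into its 2x2 block -> same-padded
# convolution with filters of the same size -> sigmoid (decode).
# The training loss is L = R + lambda_s * S, where R is the summed squared
# reconstruction error over all input nodes and S is the information
# entropy of the encoding activations, normalized per spatial position
# across filters (natural log; 0 * log 0 := 0).

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size images per step.
#' @param steps optimization steps (>= 1).
#' @param lambda_s sparsity-penalty weight (>= 0), in units of nats of
#'   encoding entropy per unit squared reconstruction error.
#' @param seed integer seed controlling init and batch sampling.
#' @return class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8L,
                         steps = 200L, lambda_s = 1e-3, seed = 1L) {
  if (steps < 1) stop_config("steps must be >= 1")
  if (lambda_s < 0) stop_config("lambda_s must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lambda_s = lambda_s,
                 seed = as.integer(seed), optimizer = "adam"),
            class = "train_config")
}

#' Construct an (untrained) autoencoder stage
#'
#' Weights are fan-in scaled uniform, drawn from the given seed.
#'
#' @param filter_size convolution filter edge f.
#' @param n_filters number of encoding filters F.
#' @param in_channels input channels.
#' @param seed integer seed for initialization.
#' @return class \code{cae_stage}.
#' @export
cae_stage <- function(filter_size, n_filters, in_channels, seed = 1L) {
  f <- as.integer(filter_size); nf <- as.integer(n_filters)
  ci <- as.integer(in_channels)
  with_seed(seed, structure(list(
    filter_size = f, n_filters = nf, in_channels = ci, pool = 2L,
    encode_filters = init_uniform(c(f, f, ci, nf), f * f * ci),
    encode_bias = rep(0, nf),
    decode_filters = init_uniform(c(f, f, nf, ci), f * f * nf),
    decode_bias = rep(0, ci)
  ), class = "cae_stage"))
}

#' @export
print.cae_stage <- function(x, ...) {
  cat(sprintf("Convolutional AE stage: %dx%d filters, %d -> %d channels, 2x2 max pool\n",
              x$filter_size, x$filter_size, x$in_channels, x$n_filters))
  h <- attr(x, "history")
  if (!is.null(h)) {
    cat(sprintf("  trained %d steps; final L = %.4g (R = %.4g, S = %.4g)\n",
                nrow(h), h$L[nrow(h)], h$R[nrow(h)], h$S[nrow(h)]))
  }
  invisible(x)
}

#' Encode one stage
#'
#' Same-padded convolution, sigmoid, then 2x2 max pooling; output spatial
#' dimensions are exactly half the input's and all activations lie in (0,1).
#'
#' @param x H x W x C array with even H and W.
#' @param stage a \code{cae_stage}.
#' @return H/2 x W/2 x F feature map.
#' @export
encode_stage <- function(x, stage) {
  x <- as_image_array(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop_shape("spatial dimensions must be even to encode (2x2 pooling)")
  }
  if (d[3] != stage$in_channels) stop_shape("channel count does not match stage")
  h <- sigmoid(conv_same(x, stage$encode_filters, stage$encode_bias))
  maxpool2(h)$values
}

#' Decode one stage
#'
#' Copies each encoding value into a 2x2 block (unpooling without switches),
#' applies a same-padded deconvolution with filters of the same size, then
#' sigmoid; output spatial dimensions are exactly double the input's.
#'
#' @param z H' x W' x F feature map.
#' @param stage a \code{cae_stage}.
#' @return 2H' x 2W' x C reconstruction in (0,1).
#' @export
decode_stage <- function(z, stage) {
  z <- as_image_array(z)
  if (dim(z)[3] != stage$n_filters) stop_shape("feature channels do not match stage")
  u <- unpool2(z)
  sigmoid(conv_same(u, stage$decode_filters, stage$decode_bias))
}

#' Reconstruction error (summed squared difference)
#'
#' @param x_in,x_out arrays of identical shape.
#' @return sum over all nodes of (x_out - x_in)^2.
#' @export
reconstruction_loss <- function(x_in, x_out) {
  if (!identical(dim(as_image_array(x_in)), dim(as_image_array(x_out)))) {
    stop_shape("input and output shapes differ")
  }
  sum((x_out - x_in)^2)
}

#' Entropy sparsity penalty of an encoding
#'
#' At each spatial position the F filter activations are normalized to a
#' distribution r over filters; the penalty is the summed information
#' entropy -sum r log r (natural log) over positions. Positions with zero
#' total activation contribute zero.
#'
#' @param z nonnegative H' x W' x F feature map.
#' @return penalty in nats (>= 0).
#' @export
sparsity_entropy <- function(z) {
  z <- as_image_array(z)
  if (any(z < 0)) stop_domain("encoding activations must be nonnegative")
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  tot <- rowSums(zm)
  ok <- tot > 0
  if (!any(ok)) return(0)
  r <- zm[ok, , drop = FALSE] / tot[ok]
  lr <- log(r)
  lr[r == 0] <- 0     # 0 * log 0 := 0
  sum(-r * lr)
}

#' Combined sparse-autoencoder loss
#'
#' @param x_in input array; \code{x_out} its reconstruction; \code{z} the
#'   encoding feature map; \code{lambda_s} the sparsity weight (>= 0).
#' @param x_out,z,lambda_s see above.
#' @return class \code{loss_breakdown}: list(R, S, lambda_s, L, N, M).
#' @export
total_loss <- function(x_in, x_out, z, lambda_s) {
  if (lambda_s < 0) stop_config("lambda_s must be >= 0")
  R <- reconstruction_loss(x_in, x_out)
  S <- sparsity_entropy(z)
  structure(list(R = R, S = S, lambda_s = lambda_s, L = R + lambda_s * S,
                 N = length(x_in), M = length(z)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("L = %.6g  (R = %.6g  +  lambda_s %.3g * S = %.6g nats; N = %d, M = %d)\n",
              x$L, x$R, x$lambda_s, x$S, x$N, x$M))
  invisible(x)
}

# Gradient of the per-position entropy penalty wrt the encoding values.
entropy_grad <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  tot <- rowSums(zm)
  g <- matrix(0, nrow(zm), ncol(zm))
  ok <- tot > 0
  if (any(ok)) {
    r <- zm[ok, , drop = FALSE] / tot[ok]
    r <- pmax(r, 1e-12)
    lr <- log(r)
    S_pos <- -rowSums(r * lr)
    g[ok, ] <- -(lr + S_pos) / tot[ok]
  }
  array(g, d)
}

# One forward+backward pass of a stage on one image. Returns loss parts and
# gradients for the four parameter arrays.
stage_grad <- function(x, st, lambda_s) {
  f <- st$filter_size
  cols_e <- im2col(x, f)
  d <- dim(x)
  a <- sweep(cols_e %*% matrix(st$encode_filters, ncol = st$n_filters),
             2L, st$encode_bias, "+")
  h <- array(sigmoid(a), c(d[1], d[2], st$n_filters))
  pl <- maxpool2(h)
  z <- pl$values
  u <- unpool2(z)
  cols_d <- im2col(u, f)
  dlog <- sweep(cols_d %*% matrix(st$decode_filters, ncol = st$in_channels),
                2L, st$decode_bias, "+")
  y <- array(sigmoid(dlog), d)

  R <- sum((y - x)^2)
  S <- sparsity_entropy(z)

  dy <- 2 * (y - x) * y * (1 - y)
  bd <- conv_same_bwd(u, st$decode_filters, dy, need_dx = TRUE, cols = cols_d)
  dz <- unpool2_bwd(bd$dx)
  if (lambda_s > 0) dz <- dz + lambda_s * entropy_grad(z)
  dh <- maxpool2_bwd(dz, pl$switch)
  da <- dh * h * (1 - h)
  be <- conv_same_bwd(x, st$encode_filters, da, need_dx = FALSE, cols = cols_e)

  list(R = R, S = S,
       grads = list(encode_filters = be$dw, encode_bias = be$db,
                    decode_filters = bd$dw, decode_bias = bd$db))
}

extract_images <- function(data, which = "train") {
  if (inherits(data, "labeled_dataset")) dataset_subset(data, which)$images
  else if (is.list(data)) data
  else stop_data("expected a labeled_dataset or a list of images")
}

#' Train one autoencoder stage
#'
#' Minimizes L = R + lambda_s * S by Adam over minibatches. Deterministic
#' for a fixed seed (initialization and batch order both come from the
#' config seed).
#'
#' @param data a \code{labeled_dataset} (its train split is used) or a
#'   plain list of H x W x C arrays.
#' @param stage_cfg list(filter_size, n_filters).
#' @param cfg a \code{\link{train_config}}.
#' @return the trained \code{cae_stage}, with a per-step data frame of
#'   mean L, R, S attached as attribute \code{"history"}.
#' @export
train_stage <- function(data, stage_cfg, cfg = train_config()) {
  imgs <- extract_images(data)
  if (length(imgs) == 0) stop_data("no training images supplied")
  d1 <- dim(as_image_array(imgs[[1]]))
  if (d1[1] %% 2L != 0L || d1[2] %% 2L != 0L) {
    stop_shape("image spatial dimensions must be divisible by 2")
  }
  st <- cae_stage(stage_cfg$filter_size, stage_cfg$n_filters, d1[3],
                  seed = cfg$seed)
  params <- st[c("encode_filters", "encode_bias",
                 "decode_filters", "decode_bias")]
  state <- adam_init(params)
  hist <- matrix(NA_real_, cfg$steps, 3,
                 dimnames = list(NULL, c("L", "R", "S")))
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(length(imgs), min(cfg$batch_size, length(imgs)))
      acc <- NULL; Rm <- 0; Sm <- 0
      for (i in bi) {
        st[names(params)] <- params
        g <- stage_grad(as_image_array(imgs[[i]]), st, cfg$lambda_s)
        Rm <- Rm + g$R; Sm <- Sm + g$S
        if (is.null(acc)) acc <- g$grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g$grads[[nm]]
      }
      nb <- length(bi)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
      upd <- adam_step(params, acc, state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
      hist[step, ] <- c((Rm + cfg$lambda_s * Sm) / nb, Rm / nb, Sm / nb)
    }
  })
  st[names(params)] <- params
  attr(st, "history") <- as.data.frame(hist)
  st
}

#' Greedy layer-wise training of a stack of stages
#'
#' Trains stage 1 on the raw images, freezes it, encodes the data, trains
#' stage 2 on the encodings, and so on. Earlier stages are never revisited.
#'
#' @param data images as in \code{\link{train_stage}}.
#' @param stage_cfgs list of list(filter_size, n_filters), one per stage.
#' @param cfg a \code{\link{train_config}}; stage k trains with seed
#'   \code{cfg$seed + k - 1}.
#' @return class \code{cae_stack}: list of trained \code{cae_stage}s.
#' @export
train_stack <- function(data, stage_cfgs, cfg = train_config()) {
  if (length(stage_cfgs) < 1) stop_config("need at least one stage config")
  cur <- lapply(extract_images(data), as_image_array)
  if (length(cur) == 0) stop_data("no training images supplied")
  stages <- vector("list", length(stage_cfgs))
  for (k in seq_along(stage_cfgs)) {
    d <- dim(cur[[1]])
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
      stop_shape(sprintf("spatial dims must be divisible by 2^%d to train %d stages",
                         length(stage_cfgs), length(stage_cfgs)))
    }
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k - 1L
    stages[[k]] <- train_stage(cur, stage_cfgs[[k]], cfg_k)
    if (k < length(stage_cfgs)) {
      cur <- lapply(cur, encode_stage, stage = stages[[k]])
    }
  }
  structure(stages, class = "cae_stack")
}

#' Encode through a stack of frozen stages
#'
#' @param x H x W x C array with spatial dims divisible by 2^(number of
#'   stages). An empty stage list returns \code{x} unchanged.
#' @param stages a \code{cae_stack} or plain list of \code{cae_stage}s.
#' @return feature map of spatial size H/2^k.
#' @export
stack_encode <- function(x, stages) {
  x <- as_image_array(x)
  for (st in stages) x <- encode_stage(x, st)
  x
}

#' @export
print.cae_stack <- function(x, ...) {
  cat("Greedy-trained autoencoder stack,", length(x), "stage(s):\n")
  for (k in seq_along(x)) {
    cat(sprintf("  [%d] ", k)); print(x[[k]])
  }
  invisible(x)
}

#' @export
predict.cae_stack <- function(object, newdata, ...) {
  stack_encode(newdata, object)
}

#' @export
plot.cae_stack <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x)))
  on.exit(graphics::par(op))
  for (k in seq_along(x)) {
    h <- attr(x[[k]], "history")
    graphics::plot(h$L, type = "l", xlab = "step", ylab = "loss",
                   main = paste("stage", k), ...)
    graphics::lines(h$R, lty = 2)
  }
  invisible(x)
}

#' Reconstruct an image through one stage
#'
#' @param x input array; \code{stage} a \code{cae_stage}.
#' @param stage the stage.
#' @return decoded reconstruction of \code{x}'s shape.
#' @export
reconstruct <- function(x, stage) {
  decode_stage(encode_stage(x, stage), stage)
}
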