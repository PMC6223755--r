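# Low-level array operations shared by every network in the package.
# Images and feature maps are plain numeric arrays with dim c(H, W, channels),
# row index first (row-major raster, origin top-left, 0-based in the docs,
# 1-based in R code). Convolution weights are arrays c(f, f, in_ch, out_ch).

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores
#' the caller's RNG state afterwards, so every seeded operation in the
#' package is a pure function of its arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Typed conditions: every precondition failure carries a condition class so
# callers (and the CLI exit-code mapping) can react without string matching.
pathae_stop <- function(kind, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("pathae_", kind, "_error"), "pathae_error",
              "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_size   <- function(msg) pathae_stop("size", msg)
stop_shape  <- function(msg) pathae_stop("shape", msg)
stop_data   <- function(msg) pathae_stop("data", msg)
stop_config <- function(msg) pathae_stop("config", msg)
stop_index  <- function(msg) pathae_stop("index", msg)
stop_domain <- function(msg) pathae_stop("domain", msg)

as_image_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_shape("expected an H x W x C numeric array")
  }
  x
}

sigmoid <- function(x) {
  # numerically stable two-sided logistic
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# --- same-padded convolution via im2col ------------------------------------

pad_offsets <- function(f) {
  top <- (f - 1L) %/% 2L           # asymmetric for even f: extra pad at end
  c(top = top, bottom = f - 1L - top)
}

im2col <- function(x, f) {
  x <- as_image_array(x)
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  po <- pad_offsets(f)
  xp <- array(0, c(H + f - 1L, W + f - 1L, C))
  xp[po["top"] + seq_len(H), po["top"] + seq_len(W), ] <- x
  cols <- matrix(0, H * W, f * f * C)
  idx <- 1L
  for (c in seq_len(C)) {
    for (dj in seq_len(f)) {
      for (di in seq_len(f)) {
        cols[, idx] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), c]
        idx <- idx + 1L
      }
    }
  }
  cols
}

col2im <- function(dcols, H, W, C, f) {
  po <- pad_offsets(f)
  dp <- array(0, c(H + f - 1L, W + f - 1L, C))
  idx <- 1L
  for (c in seq_len(C)) {
    for (dj in seq_len(f)) {
      for (di in seq_len(f)) {
        dp[di:(di + H - 1L), dj:(dj + W - 1L), c] <-
          dp[di:(di + H - 1L), dj:(dj + W - 1L), c] + matrix(dcols[, idx], H, W)
        idx <- idx + 1L
      }
    }
  }
  dp[po["top"] + seq_len(H), po["top"] + seq_len(W), , drop = FALSE]
}

#' Same-padded 2-D convolution
#'
#' Zero-padded ("same") convolution of an H x W x C array with filters
#' \code{w} of dim c(f, f, C, F); output is H x W x F.
#'
#' @param x input array H x W x C.
#' @param w filter array c(f, f, C, F).
#' @param b bias vector of length F.
#' @return array H x W x F of pre-activation responses.
#' @keywords internal
conv_same <- function(x, w, b = NULL) {
  x <- as_image_array(x)
  d <- dim(x); dw <- dim(w)
  if (d[3L] != dw[3L]) stop_shape("input channels do not match filter channels")
  f <- dw[1L]; nf <- dw[4L]
  cols <- im2col(x, f)
  out <- cols %*% matrix(w, f * f * dw[3L], nf)
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  array(out, c(d[1L], d[2L], nf))
}

# Backward pass of conv_same. dout: H x W x F gradient. Returns gradients for
# weights, bias, and (optionally) the input.
conv_same_bwd <- function(x, w, dout, need_dx = TRUE, cols = NULL) {
  x <- as_image_array(x)
  d <- dim(x); dw <- dim(w); f <- dw[1L]; nf <- dw[4L]
  if (is.null(cols)) cols <- im2col(x, f)
  dout_mat <- matrix(dout, d[1L] * d[2L], nf)
  dwm <- crossprod(cols, dout_mat)
  out <- list(
    dw = array(dwm, dw),
    db = colSums(dout_mat)
  )
  if (need_dx) {
    dcols <- dout_mat %*% t(matrix(w, f * f * dw[3L], nf))
    out$dx <- col2im(dcols, d[1L], d[2L], d[3L], f)
  }
  out
}

# --- 2x2 max pooling / unpooling -------------------------------------------

# Returns pooled values plus the per-block argmax switch (1..4, fixed
# row-major tie order) used only by backprop; the decode path unpools by
# copying, not by switches.
maxpool2 <- function(x) {
  x <- as_image_array(x)
  d <- dim(x)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop_shape("spatial dimensions must be divisible by 2 for 2x2 max pooling")
  }
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  c1 <- x[ro, co, , drop = FALSE]           # (r0, c0)
  c2 <- x[ro, co + 1L, , drop = FALSE]      # (r0, c1)
  c3 <- x[ro + 1L, co, , drop = FALSE]      # (r1, c0)
  c4 <- x[ro + 1L, co + 1L, , drop = FALSE] # (r1, c1)
  z <- pmax(c1, c2, c3, c4)
  sw <- array(4L, dim(z))
  sw[c3 == z] <- 3L
  sw[c2 == z] <- 2L
  sw[c1 == z] <- 1L
  list(values = z, switch = sw)
}

maxpool2_bwd <- function(dz, sw) {
  dd <- dim(dz)
  H <- dd[1L] * 2L; W <- dd[2L] * 2L
  dh <- array(0, c(H, W, dd[3L]))
  ro <- seq(1L, H, 2L); co <- seq(1L, W, 2L)
  dh[ro, co, ]           <- dz * (sw == 1L)
  dh[ro, co + 1L, ]      <- dz * (sw == 2L)
  dh[ro + 1L, co, ]      <- dz * (sw == 3L)
  dh[ro + 1L, co + 1L, ] <- dz * (sw == 4L)
  dh
}

# Unpooling copies each encoding value into its 2x2 block (no switches).
unpool2 <- function(z) {
  z <- as_image_array(z)
  d <- dim(z)
  u <- array(0, c(d[1L] * 2L, d[2L] * 2L, d[3L]))
  ro <- seq(1L, d[1L] * 2L, 2L); co <- seq(1L, d[2L] * 2L, 2L)
  u[ro, co, ] <- z; u[ro, co + 1L, ] <- z
  u[ro + 1L, co, ] <- z; u[ro + 1L, co + 1L, ] <- z
  u
}

unpool2_bwd <- function(du) {
  d <- dim(du)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  du[ro, co, , drop = FALSE] + du[ro, co + 1L, , drop = FALSE] +
    du[ro + 1L, co, , drop = FALSE] + du[ro + 1L, co + 1L, , drop = FALSE]
}

# --- Adam ------------------------------------------------------------------

# params/grads are flat named lists of numeric arrays.
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Fan-in scaled uniform initialization, seeded by the caller's stream.
init_uniform <- function(dims, fan_in) {
  r <- sqrt(3 / fan_in)
  array(stats::runif(prod(dims), -r, r), dims)
}

# Row-wise softmax with the usual max-shift stabilization.
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}
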