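# Independent nested-loop oracles. Deliberately naive: plain loops over
# pixels and filters, no shared code with the package's vectorized paths.

naive_conv_same <- function(x, w, b) {
  d <- dim(x); dw <- dim(w); f <- dw[1]
  po <- (f - 1) %/% 2
  out <- array(0, c(d[1], d[2], dw[4]))
  for (k in seq_len(dw[4])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        s <- b[k]
        for (c in seq_len(d[3])) {
          for (di in seq_len(f)) {
            for (dj in seq_len(f)) {
              ii <- i + di - 1 - po; jj <- j + dj - 1 - po
              if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
                s <- s + x[ii, jj, c] * w[di, dj, c, k]
              }
            }
          }
        }
        out[i, j, k] <- s
      }
    }
  }
  out
}

naive_pool2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3])) {
    for (i in seq_len(d[1] / 2)) {
      for (j in seq_len(d[2] / 2)) {
        out[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
      }
    }
  }
  out
}

naive_unpool2 <- function(z) {
  d <- dim(z)
  out <- array(0, c(d[1] * 2, d[2] * 2, d[3]))
  for (c in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        out[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c] <- z[i, j, c]
      }
    }
  }
  out
}

naive_sigmoid <- function(x) 1 / (1 + exp(-x))

naive_encode <- function(x, st) {
  naive_pool2(naive_sigmoid(naive_conv_same(x, st$encode_filters,
                                            st$encode_bias)))
}

naive_decode <- function(z, st) {
  naive_sigmoid(naive_conv_same(naive_unpool2(z), st$decode_filters,
                                st$decode_bias))
}

naive_entropy <- function(z) {
  d <- dim(z)
  total <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      t <- sum(z[i, j, ])
      if (t > 0) {
        for (k in seq_len(d[3])) {
          r <- z[i, j, k] / t
          if (r > 0) total <- total - r * log(r)
        }
      }
    }
  }
  total
}

naive_risa_forward <- function(x, C, H) {
  g <- nrow(H); k <- nrow(C)
  p <- numeric(g)
  for (i in seq_len(g)) {
    s <- 0
    for (m in seq_len(k)) {
      resp <- sum(C[m, ] * x)
      s <- s + H[i, m] * resp^2
    }
    p[i] <- sqrt(s)
  }
  p
}

naive_risa_objective <- function(X, C, H, lambda) {
  N <- ncol(X)
  total <- 0
  for (t in seq_len(N)) {
    x <- X[, t]
    rec <- as.numeric(t(C) %*% (C %*% x))
    total <- total + sum((rec - x)^2) / N
    total <- total + lambda * sum(naive_risa_forward(x, C, H))
  }
  total
}

# small deterministic fixtures
fixture_image <- function(H = 6, W = 6, C = 3, seed = 42) {
  pathae:::with_seed(seed, array(stats::runif(H * W * C), c(H, W, C)))
}

fixture_stage <- function(f = 3, nf = 4, ci = 3, seed = 5) {
  cae_stage(f, nf, ci, seed = seed)
}

tiny_labeled_dataset <- function(n_per_class = 6, size = 32, seed = 3) {
  generate_dataset(context_class_specs(), n_per_class = n_per_class,
                   size = size, seed = seed,
                   bank = make_motif_bank(6, 4, seed = seed))
}

# two hue-separable classes: motifs become much darker vs much lighter
hue_dataset <- function(n_per_class = 15, size = 16, seed = 4) {
  b1 <- make_motif_bank(6, 2, seed = seed)
  b2 <- make_motif_bank(6, 2, seed = seed)
  for (i in seq_along(b1$motifs)) {
    b1$motifs[[i]]$color <- c(0.05, 0.05, 0.3)   # dark blue ink
    b2$motifs[[i]]$color <- c(0.25, 0.75, 0.25)  # green ink
  }
  s1 <- class_spec(1L, "dark", placement = "uniform", density = 2.5e-2)
  s2 <- class_spec(2L, "green", placement = "uniform", density = 2.5e-2)
  d1 <- generate_dataset(list(s1, s1), n_per_class, size, seed = seed,
                         bank = b1)
  d2 <- generate_dataset(list(s2, s2), n_per_class, size, seed = seed + 1L,
                         bank = b2)
  keep1 <- which(d1$labels == 1L)
  structure(list(
    images = c(d1$images[keep1], d2$images[which(d2$labels == 1L)]),
    labels = c(rep(1L, length(keep1)), rep(2L, length(keep1))),
    class_names = c("dark", "green"),
    split = c(d1$split[keep1], d2$split[which(d2$labels == 1L)]),
    seed = seed), class = "labeled_dataset")
}
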