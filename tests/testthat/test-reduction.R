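# Tiling, tiled encoding, shared subpane reduction, and the frozen-stack
# training contract.

small_stack <- function(seed = 1) {
  imgs <- lapply(1:6, function(i) fixture_image(16, 16, 3, seed = i))
  train_stack(imgs, list(list(filter_size = 3, n_filters = 4)),
              train_config(steps = 8, batch_size = 3, seed = seed))
}

test_that("tiling is exact, row-major and conserving", {
  img <- fixture_image(64, 64, 3)
  grid <- tile_image(img, 16)
  expect_equal(grid$rows * grid$cols, 16)
  expect_length(grid$coords, 16)
  expect_equal(grid$coords[[1]], c(r0 = 0, r1 = 16, c0 = 0, c1 = 16))
  expect_equal(grid$coords[[2]], c(r0 = 0, r1 = 16, c0 = 16, c1 = 32))
  # identity tiling
  g1 <- tile_image(img, 64)
  expect_length(g1$coords, 1)
  expect_equal(g1$coords[[1]], c(r0 = 0, r1 = 64, c0 = 0, c1 = 64))
  # pixel multiset conservation
  pixels <- sort(unlist(lapply(grid$coords, function(co) {
    pathae:::get_tile(img, co)
  })))
  expect_equal(pixels, sort(as.numeric(img)))
  expect_error(tile_image(img, 24), class = "pathae_shape_error")
})

test_that("tiled encoding reassembles tiles and degenerates to stack_encode", {
  stack <- small_stack()
  img <- fixture_image(32, 32, 3, seed = 20)
  g1 <- tile_image(img, 32)
  expect_equal(encode_tiles(img, g1, stack), stack_encode(img, stack),
               tolerance = 1e-12)
  z <- encode_tiles(img, tile_image(img, 16), stack)
  expect_equal(dim(z), c(16, 16, 4))
  # away from tile seams the per-tile and whole-image encodings agree:
  # zero-padding effects are confined to the seam neighbourhood
  zw <- stack_encode(img, stack)
  interior <- c(1:6, 11:16)   # encoded seam at rows/cols 8|9, f/2 slop
  expect_equal(z[interior, interior, ], zw[interior, interior, ],
               tolerance = 1e-6)
})

test_that("subpane reduction is shared, equivariant, and matches a hand loop", {
  z <- pathae:::with_seed(31, array(stats::runif(8 * 8 * 3), c(8, 8, 3)))
  rc <- list(G = 4L, W1 = pathae:::with_seed(32, matrix(stats::rnorm(12 * 5), 12, 5)),
             b1 = seq(0.1, 0.5, 0.1))
  S <- subpane_reduce(z, rc)
  expect_equal(dim(S), c(4, 4, 5))
  # hand loop for one subpane (grid row 2, col 3): rows 3:4, cols 5:6
  sub <- z[3:4, 5:6, ]
  manual <- 1 / (1 + exp(-(as.numeric(sub) %*% rc$W1 + rc$b1)))
  expect_equal(S[2, 3, ], as.numeric(manual), tolerance = 1e-6)
  # permuting two subpanes permutes the outputs and changes nothing else
  z2 <- z
  z2[1:2, 1:2, ] <- z[3:4, 5:6, ]
  z2[3:4, 5:6, ] <- z[1:2, 1:2, ]
  S2 <- subpane_reduce(z2, rc)
  expect_equal(S2[1, 1, ], S[2, 3, ], tolerance = 1e-12)
  expect_equal(S2[2, 3, ], S[1, 1, ], tolerance = 1e-12)
  S2[1, 1, ] <- S[1, 1, ]; S2[2, 3, ] <- S[2, 3, ]
  expect_equal(S2, S, tolerance = 1e-12)
  expect_error(subpane_reduce(array(0, c(6, 6, 3)), rc),
               class = "pathae_shape_error")
})

test_that("subpane reduction equals a stride-G window-G convolution", {
  z <- pathae:::with_seed(33, array(stats::runif(8 * 8 * 2), c(8, 8, 2)))
  rc <- list(G = 4L, W1 = pathae:::with_seed(34, matrix(stats::rnorm(8 * 3), 8, 3)),
             b1 = c(-0.2, 0, 0.2))
  S <- subpane_reduce(z, rc)
  # direct non-overlapping windowed convolution: weight tensor w[di,dj,c,k]
  # from the flattened-subpane weight rows (di fastest, then dj, then c)
  w <- array(rc$W1, c(2, 2, 2, 3))
  conv <- array(0, c(4, 4, 3))
  for (k in 1:3) {
    for (i in 1:4) {
      for (j in 1:4) {
        acc <- rc$b1[k]
        for (c in 1:2) {
          for (di in 1:2) {
            for (dj in 1:2) {
              acc <- acc + z[2 * (i - 1) + di, 2 * (j - 1) + dj, c] *
                w[di, dj, c, k]
            }
          }
        }
        conv[i, j, k] <- 1 / (1 + exp(-acc))
      }
    }
  }
  expect_equal(S, conv, tolerance = 1e-6)
})

test_that("full forward gives probabilities; zeroed final layer is uniform; deterministic", {
  stack <- small_stack()
  ds <- tiny_labeled_dataset(n_per_class = 5, size = 32)
  rc <- train_reduction(ds, stack,
                        reduction_config(G = 4, d_r = 6, tile_size = 16,
                                         n_classes = 3,
                                         class_names = ds$class_names),
                        train_config(steps = 10, batch_size = 4, seed = 6))
  p <- reduction_forward(ds$images[[1]], stack, rc)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_identical(p, reduction_forward(ds$images[[1]], stack, rc))
  rc0 <- rc; rc0$W2[] <- 0; rc0$b2[] <- 0
  expect_equal(as.numeric(reduction_forward(ds$images[[1]], stack, rc0)),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("reduction training never touches the autoencoder stages", {
  stack <- small_stack()
  before <- lapply(stack, function(s) s[c("encode_filters", "encode_bias",
                                          "decode_filters", "decode_bias")])
  ds <- tiny_labeled_dataset(n_per_class = 5, size = 32)
  rc <- train_reduction(ds, stack,
                        reduction_config(G = 4, d_r = 6, tile_size = 16,
                                         n_classes = 3),
                        train_config(steps = 10, batch_size = 4, seed = 6))
  after <- lapply(stack, function(s) s[c("encode_filters", "encode_bias",
                                         "decode_filters", "decode_bias")])
  expect_identical(before, after)
  expect_identical(lapply(rc$stages, `[[`, "encode_filters"),
                   lapply(stack, `[[`, "encode_filters"))
})

test_that("the shared reducer's parameter count is input-size invariant for fixed subpane dims", {
  stack <- small_stack()
  ds32 <- tiny_labeled_dataset(n_per_class = 5, size = 32)
  ds64 <- tiny_labeled_dataset(n_per_class = 5, size = 64)
  # G chosen so encoded subpanes are 4x4xF at both sizes
  rc_a <- train_reduction(ds32, stack,
                          reduction_config(G = 4, d_r = 6, tile_size = 16),
                          train_config(steps = 3, batch_size = 4, seed = 1))
  rc_b <- train_reduction(ds64, stack,
                          reduction_config(G = 8, d_r = 6, tile_size = 16),
                          train_config(steps = 3, batch_size = 4, seed = 1))
  expect_identical(dim(rc_a$W1), dim(rc_b$W1))
  expect_identical(length(rc_a$b1), length(rc_b$b1))
})
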