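# Encoder/decoder geometry, the sparse loss, and greedy stacked training.

test_that("encode halves and decode doubles the spatial dimensions", {
  st <- fixture_stage(f = 3, nf = 16, ci = 3)
  x <- fixture_image(64, 64, 3)
  z <- encode_stage(x, st)
  expect_equal(dim(z), c(32, 32, 16))
  expect_true(all(z > 0 & z < 1))
  y <- decode_stage(z, st)
  expect_equal(dim(y), dim(x))
  odd <- fixture_image(7, 8, 3)
  expect_error(encode_stage(odd, st), class = "pathae_shape_error")
})

test_that("zero weights give the sigmoid closed form everywhere", {
  st <- fixture_stage(f = 3, nf = 4, ci = 3)
  st$encode_filters[] <- 0; st$encode_bias[] <- 0
  st$decode_filters[] <- 0; st$decode_bias[] <- 0
  x <- fixture_image(8, 8, 3)
  expect_true(all(encode_stage(x, st) == 0.5))
  expect_true(all(decode_stage(encode_stage(x, st), st) == 0.5))
})

test_that("unpooling copies each value into its 2x2 block", {
  z <- array(c(0.3, 0.9), c(1, 1, 2))
  u <- pathae:::unpool2(z)
  expect_equal(u[, , 1], matrix(0.3, 2, 2))
  expect_equal(u[, , 2], matrix(0.9, 2, 2))
})

test_that("encode and decode match the nested-loop oracles", {
  for (f in c(3, 4, 5)) {
    st <- fixture_stage(f = f, nf = 3, ci = 2, seed = f)
    x <- fixture_image(8, 8, 2, seed = f + 10)
    expect_equal(encode_stage(x, st), naive_encode(x, st), tolerance = 1e-6)
    z <- encode_stage(x, st)
    expect_equal(decode_stage(z, st), naive_decode(z, st), tolerance = 1e-6)
  }
})

test_that("reconstruction loss is the summed squared difference", {
  x0 <- array(0, c(8, 8, 3)); x1 <- array(1, c(8, 8, 3))
  expect_equal(reconstruction_loss(x0, x0), 0)
  expect_equal(reconstruction_loss(x0, x1), 192)
  expect_error(reconstruction_loss(x0, array(0, c(4, 4, 3))),
               class = "pathae_shape_error")
})

test_that("sparsity entropy hits its closed-form extremes", {
  uni <- array(1, c(1, 1, 8))
  expect_equal(sparsity_entropy(uni), log(8), tolerance = 1e-12)
  onehot <- array(0, c(1, 1, 8)); onehot[1, 1, 3] <- 2.5
  expect_equal(sparsity_entropy(onehot), 0)
  z <- array(c(2, 1, 1), c(1, 1, 3))
  expect_equal(sparsity_entropy(z),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-9)
  expect_equal(sparsity_entropy(array(0, c(2, 2, 4))), 0)
  neg <- array(-1, c(1, 1, 2))
  expect_error(sparsity_entropy(neg), class = "pathae_domain_error")
})

test_that("sparsity entropy matches the nested-loop oracle and its bounds", {
  for (seed in 1:5) {
    z <- pathae:::with_seed(seed, array(stats::runif(4 * 4 * 6), c(4, 4, 6)))
    s <- sparsity_entropy(z)
    expect_equal(s, naive_entropy(z), tolerance = 1e-9)
    expect_gte(s, 0)
    expect_lte(s, 16 * log(6) + 1e-12)
  }
})

test_that("total loss composes R and S with the weight", {
  fx <- tiny_fixture()
  st <- fixture_stage(f = 3, nf = 4, ci = 3)
  z <- encode_stage(fx$input, st)
  y <- decode_stage(z, st)
  lb <- total_loss(fx$input, y, z, lambda_s = 0.1)
  expect_equal(lb$L, lb$R + 0.1 * lb$S, tolerance = 1e-9)
  expect_equal(lb$R, reconstruction_loss(fx$input, y))
  expect_equal(lb$S, naive_entropy(z), tolerance = 1e-9)
  expect_equal(lb$N, 192)
  lb0 <- total_loss(fx$input, y, z, lambda_s = 0)
  expect_identical(lb0$L, lb0$R)
  # arithmetic contract on plain numbers
  lb2 <- total_loss(array(0, c(2, 2, 1)), array(1, c(2, 2, 1)),
                    array(1, c(1, 1, 2)), 0.1)
  expect_equal(lb2$L, 4 + 0.1 * log(2))
})

test_that("stage training reduces the loss and is seed-deterministic", {
  imgs <- lapply(1:12, function(i) fixture_image(16, 16, 3, seed = i))
  cfg <- train_config(steps = 30, batch_size = 4, lambda_s = 1e-3, seed = 2)
  st <- train_stage(imgs, list(filter_size = 3, n_filters = 6), cfg)
  h <- attr(st, "history")
  expect_lt(mean(h$L[26:30]), mean(h$L[1:5]))
  st2 <- train_stage(imgs, list(filter_size = 3, n_filters = 6), cfg)
  expect_identical(attr(st, "history"), attr(st2, "history"))
  expect_identical(st$encode_filters, st2$encode_filters)
  expect_error(train_stage(list(), list(filter_size = 3, n_filters = 6), cfg),
               class = "pathae_data_error")
})

test_that("greedy stacking freezes earlier stages and composes encodes", {
  imgs <- lapply(1:8, function(i) fixture_image(16, 16, 3, seed = i))
  cfgs <- list(list(filter_size = 3, n_filters = 4),
               list(filter_size = 3, n_filters = 6))
  cfg <- train_config(steps = 15, batch_size = 4, seed = 5)
  stack <- train_stack(imgs, cfgs, cfg)
  # stage 1 of the stack is bit-identical to stage 1 trained alone: later
  # stages never touched it
  alone <- train_stage(imgs, cfgs[[1]], cfg)
  expect_identical(stack[[1]]$encode_filters, alone$encode_filters)
  expect_identical(stack[[1]]$decode_filters, alone$decode_filters)
  x <- fixture_image(16, 16, 3, seed = 99)
  expect_equal(stack_encode(x, stack),
               encode_stage(encode_stage(x, stack[[1]]), stack[[2]]),
               tolerance = 1e-12)
  expect_equal(dim(stack_encode(x, stack)), c(4, 4, 6))
  expect_identical(stack_encode(x, list()), x)
  odd <- fixture_image(10, 10, 3)   # second stage sees odd 5x5 input
  expect_error(stack_encode(odd, stack), class = "pathae_shape_error")
})

test_that("predict on a stack equals stack_encode", {
  imgs <- lapply(1:6, function(i) fixture_image(8, 8, 3, seed = i))
  stack <- train_stack(imgs, list(list(filter_size = 3, n_filters = 4)),
                       train_config(steps = 5, batch_size = 3, seed = 1))
  x <- fixture_image(8, 8, 3, seed = 50)
  expect_identical(predict(stack, x), stack_encode(x, stack))
})
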