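# The generator's contracts: deterministic seeded banks and renders,
# balanced stratified datasets, and the design property that classes share
# local appearance while differing in motif dispersion.

test_that("motif bank obeys its shape, range and determinism contracts", {
  bank <- make_motif_bank(8, 4, seed = 1)
  expect_length(bank$motifs, 4)
  for (mo in bank$motifs) {
    expect_equal(dim(mo$mask), c(8, 8))
    expect_true(all(mo$mask >= 0 & mo$mask <= 1))
  }
  kinds <- vapply(bank$motifs, `[[`, "", "kind")
  expect_true("stripe" %in% kinds)
  expect_true("ring" %in% kinds)
  expect_identical(bank, make_motif_bank(8, 4, seed = 1))
  bank2 <- make_motif_bank(8, 4, seed = 2)
  expect_false(identical(bank$motifs, bank2$motifs))
  expect_error(make_motif_bank(3, 4), class = "pathae_size_error")
})

test_that("rendered class images are in range, seeded, and near-background at vanishing density", {
  bank <- make_motif_bank(8, 4, seed = 1)
  spec <- class_spec(1L, placement = "uniform")
  img <- render_class_image(spec, bank, 64, seed = 9)
  expect_equal(dim(img), c(64, 64, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, render_class_image(spec, bank, 64, seed = 9))
  expect_error(render_class_image(spec, bank, 10, seed = 1),
               class = "pathae_size_error")
  # vanishing density: deviation from the pure background stays below the
  # motif amplitude
  tiny <- class_spec(1L, placement = "uniform", density = 1e-9)
  img0 <- render_class_image(tiny, bank, 64, seed = 9)
  expect_equal(nrow(attr(img0, "placements")), 0)
  bg_dev <- max(abs(sweep(img0, 3, c(0.92, 0.78, 0.82))))
  expect_lt(bg_dev, max(vapply(bank$motifs, function(m) max(m$mask), 1)))
})

test_that("placement classes are locally alike but differ in motif dispersion", {
  specs <- context_class_specs()
  bank <- make_motif_bank(12, 4, seed = 11)
  render2 <- function(spec, seeds) {
    lapply(seeds, function(s) render_class_image(spec, bank, 256, seed = s))
  }
  u <- render2(specs[[1]], c(101, 102))
  cl <- render2(specs[[2]], c(201, 202))
  g <- render2(specs[[3]], c(301, 302))
  # 8x8 patch mean intensities pooled per class: the local appearance of
  # uniform and graded renders is statistically indistinguishable
  patch_means <- function(im, n = 100, seed = 3) {
    pathae:::with_seed(seed, {
      grid <- expand.grid(r = seq(1, 249, by = 8), c = seq(1, 249, by = 8))
      grid <- grid[sample(nrow(grid), n), ]
      vapply(seq_len(n), function(i) {
        mean(im[grid$r[i]:(grid$r[i] + 7), grid$c[i]:(grid$c[i] + 7), ])
      }, numeric(1))
    })
  }
  ks <- stats::ks.test(unlist(lapply(u, patch_means)),
                       unlist(lapply(g, patch_means)))
  expect_gt(ks$p.value, 0.01)
  # whole-image motif-position dispersion (quadrat variance/mean) separates
  # the placements
  qidx <- function(im) {
    p <- attr(im, "placements")
    qq <- table(factor(pmin(3, p$row %/% 64), levels = 0:3),
                factor(pmin(3, p$col %/% 64), levels = 0:3))
    stats::var(as.vector(qq)) / mean(qq)
  }
  expect_gt(min(vapply(cl, qidx, 1)), max(vapply(u, qidx, 1)))
  expect_gt(min(vapply(g, qidx, 1)), max(vapply(u, qidx, 1)))
})

test_that("generate_dataset is balanced, stratified 80/20 and deterministic", {
  specs <- context_class_specs()
  ds <- generate_dataset(specs, n_per_class = 10, size = 64, seed = 7)
  expect_length(ds$images, 30)
  expect_equal(sum(ds$split == "train"), 24)
  expect_equal(sum(ds$split == "test"), 6)
  expect_equal(as.vector(table(ds$labels[ds$split == "train"])), c(8, 8, 8))
  expect_equal(as.vector(table(ds$labels[ds$split == "test"])), c(2, 2, 2))
  expect_equal(as.vector(table(ds$labels)), rep(10, 3))
  ds2 <- generate_dataset(specs, n_per_class = 10, size = 64, seed = 7)
  expect_identical(ds$images, ds2$images)
  expect_error(generate_dataset(specs, n_per_class = 4, size = 64, seed = 1),
               class = "pathae_data_error")
  expect_error(generate_dataset(specs[1], n_per_class = 10, size = 64),
               class = "pathae_config_error")
})

test_that("tiny fixture pair is fixed, distinct, and hand-summable", {
  fx <- tiny_fixture()
  expect_equal(dim(fx$input), c(8, 8, 3))
  expect_equal(dim(fx$target), c(8, 8, 3))
  expect_false(identical(fx$input, fx$target))
  expect_identical(fx, tiny_fixture())
  expect_equal(reconstruction_loss(fx$input, fx$input), 0)
  # independent scalar loop over all 192 entries
  acc <- 0
  for (ch in 1:3) {
    for (j in 1:8) {
      for (i in 1:8) {
        acc <- acc + (fx$target[i, j, ch] - fx$input[i, j, ch])^2
      }
    }
  }
  expect_equal(reconstruction_loss(fx$input, fx$target), acc, tolerance = 1e-12)
})

test_that("datasets round-trip through the PNG directory format", {
  ds <- tiny_labeled_dataset(n_per_class = 5, size = 16)
  out <- tempfile("ds")
  write_dataset_png(ds, out)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  expect_true(file.exists(file.path(out, "dataset.json")))
  back <- load_dataset_dir(out)
  expect_equal(length(back$images), length(ds$images))
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$split, ds$split)
  # 8-bit quantization only
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 1 / 255)
  unlink(out, recursive = TRUE)
})
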