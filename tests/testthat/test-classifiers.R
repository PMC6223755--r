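# Softmax heads, the three variants, and confusion-matrix evaluation.

test_that("softmax cross-entropy: uniform, limit and direct evaluation", {
  expect_equal(softmax_cross_entropy(c(0, 0, 0), 1), log(3), tolerance = 1e-12)
  expect_lt(softmax_cross_entropy(c(40, 0, 0), 1), 1e-6)
  expect_equal(softmax_cross_entropy(c(1, 2, 3), 3),
               -log(exp(3) / (exp(1) + exp(2) + exp(3))), tolerance = 1e-9)
  expect_equal(softmax_cross_entropy(c(1, 2, 3), 3), 0.40761, tolerance = 1e-5)
  # stability at large logits
  expect_true(is.finite(softmax_cross_entropy(c(1e4, 0), 2)))
  expect_error(softmax_cross_entropy(c(1, 2, 3), 4),
               class = "pathae_index_error")
  expect_error(softmax_cross_entropy(c(1), 1), class = "pathae_config_error")
})

test_that("variants produce normalized probabilities and respect required inputs", {
  expect_error(build_variant("ae", NULL, list(input_size = 16)),
               class = "pathae_config_error")
  expect_error(build_variant("risa", NULL, list(input_size = 16)),
               class = "pathae_config_error")
  ds <- hue_dataset(n_per_class = 10, size = 16)
  mdl <- build_variant("direct", head_cfg = list(
    input_size = 16, n_classes = 2, class_names = ds$class_names,
    filter_size = 3))
  mdl <- train_classifier(mdl, ds, train_config(steps = 10, batch_size = 4,
                                                seed = 1))
  p <- predict(mdl, ds$images[[1]], type = "prob")
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
})

test_that("frozen AE extractor is bit-identical after head training; risa head dims", {
  ds <- hue_dataset(n_per_class = 10, size = 16)
  stack <- train_stack(dataset_subset(ds, "train")$images,
                       list(list(filter_size = 3, n_filters = 4)),
                       train_config(steps = 10, batch_size = 4, seed = 2))
  before <- list(stack[[1]]$encode_filters, stack[[1]]$decode_filters)
  mdl <- build_variant("ae", stack, list(input_size = 16, n_classes = 2,
                                         class_names = ds$class_names))
  mdl <- train_classifier(mdl, ds, train_config(steps = 15, batch_size = 4,
                                                seed = 3))
  expect_identical(list(mdl$extractor[[1]]$encode_filters,
                        mdl$extractor[[1]]$decode_filters), before)
  expect_identical(list(stack[[1]]$encode_filters,
                        stack[[1]]$decode_filters), before)
  # risa variant head input dim = groups x spatial positions
  patches <- sample_patches(ds$images, 100, 3, seed = 1)
  rm <- train_risa(patches, k = 8, group_size = 2, lambda = 0.1,
                   cfg = train_config(steps = 10, batch_size = 32, seed = 1))
  mr <- build_variant("risa", rm, list(input_size = 16, n_classes = 2))
  expect_equal(mr$feature_dim, 4 * 16 * 16)
})

test_that("hue-separable classes are learned; shuffled labels stay near chance", {
  ds <- hue_dataset(n_per_class = 15, size = 16)
  mdl <- build_variant("direct", head_cfg = list(
    input_size = 16, n_classes = 2, class_names = ds$class_names,
    filter_size = 3))
  mdl <- train_classifier(mdl, ds, train_config(steps = 300, batch_size = 8,
                                                learning_rate = 3e-3,
                                                seed = 4))
  h <- attr(mdl, "history")
  expect_lt(h[length(h)], h[1])
  cm <- evaluate_confusion(mdl, ds)
  expect_gte(cm$accuracy, 95)
  # label shuffle: no better than chance beyond noise
  ds_sh <- ds
  ds_sh$labels <- pathae:::with_seed(9, sample(ds$labels))
  mdl_sh <- build_variant("direct", head_cfg = list(
    input_size = 16, n_classes = 2, class_names = ds$class_names,
    filter_size = 3))
  mdl_sh <- train_classifier(mdl_sh, ds_sh,
                             train_config(steps = 300, batch_size = 8,
                                          learning_rate = 3e-3, seed = 4))
  cm_sh <- evaluate_confusion(mdl_sh, ds_sh)
  expect_lte(abs(cm_sh$accuracy - 50), 35)
  expect_error(train_classifier(mdl, structure(list(
    images = ds$images[1:3], labels = rep(1L, 3), class_names = "a",
    split = rep("train", 3)), class = "labeled_dataset")),
    class = "pathae_data_error")
})

test_that("confusion matrices count, conserve and score correctly", {
  ds <- tiny_labeled_dataset(n_per_class = 5, size = 16)
  # stub predictors via a minimal S3 class
  stub <- function(fun) {
    structure(list(n_classes = 3, class_names = ds$class_names, fun = fun),
              class = "stub_cls")
  }
  registerS3method("predict", "stub_cls",
                   function(object, newdata, type = "prob", ...) {
                     object$fun(newdata)
                   }, envir = globalenv())
  te <- which(ds$split == "test")
  # perfect predictor: look the label up
  lookup <- ds$labels[te]
  i <- 0
  perfect <- stub(function(img) {
    i <<- i + 1
    p <- c(0.01, 0.01, 0.01); p[lookup[i]] <- 0.97; p
  })
  cm <- evaluate_confusion(perfect, ds)
  expect_equal(diag(cm$counts), setNames(c(1, 1, 1), ds$class_names))
  expect_equal(cm$accuracy, 100)
  # constant predictor: everything lands in column 1
  const <- stub(function(img) c(1, 0, 0))
  cm0 <- evaluate_confusion(const, ds)
  expect_equal(cm0$counts[, 1], cm0$totals)
  expect_equal(sum(cm0$counts[, 2:3]), 0)
  expect_equal(cm0$accuracy, 100 * sum(ds$labels[te] == 1) / length(te))
  # conservation and internal consistency
  expect_equal(sum(cm0$counts), length(te))
  expect_equal(cm0$accuracy, 100 * sum(diag(cm0$counts)) / sum(cm0$counts),
               tolerance = 1e-9)
  # TSV report layout
  path <- tempfile(fileext = ".tsv")
  write_confusion_tsv(cm0, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$Total[4], length(te))
  unlink(path)
})
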