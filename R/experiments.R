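# Canned experiments: the context-size study (the package's central claim
# that classes defined by motif placement need large spatial context) and a
# qualitative variant-comparison report.

#' Random square crops of every image in a dataset
#'
#' One seeded crop per image; labels and split are inherited, so the crop
#' dataset probes the same classification task at reduced spatial context.
#'
#' @param ds a \code{labeled_dataset}.
#' @param size crop edge in px (<= image edge).
#' @param seed integer seed.
#' @return a \code{labeled_dataset} of size x size images.
#' @export
crop_dataset <- function(ds, size, seed = 1L) {
  full <- dim(as_image_array(ds$images[[1]]))[1]
  if (size > full) stop_size("crop size exceeds image size")
  n <- length(ds$images)
  offs <- with_seed(seed,
    matrix(sample.int(full - size + 1L, 2L * n, replace = TRUE), n, 2L))
  out <- ds
  out$images <- lapply(seq_len(n), function(i) {
    im <- as_image_array(ds$images[[i]])
    im[offs[i, 1]:(offs[i, 1] + size - 1L),
       offs[i, 2]:(offs[i, 2] + size - 1L), , drop = FALSE]
  })
  out
}

# Seeded 64-px training crops for stack pretraining (2 per train image).
pretrain_crops <- function(ds, crop = 64L, per_image = 2L, seed = 1L) {
  tr <- dataset_subset(ds, "train")
  full <- dim(as_image_array(tr$images[[1]]))[1]
  with_seed(seed, lapply(seq_len(per_image * length(tr$images)), function(i) {
    im <- as_image_array(tr$images[[((i - 1L) %% length(tr$images)) + 1L]])
    r0 <- sample.int(full - crop + 1L, 1L)
    c0 <- sample.int(full - crop + 1L, 1L)
    im[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
  }))
}

default_stage_cfgs <- function() {
  list(list(filter_size = 7L, n_filters = 16L),
       list(filter_size = 5L, n_filters = 24L),
       list(filter_size = 3L, n_filters = 32L))
}

#' Context-size experiment
#'
#' The scaled-down study of how much spatial context the classifier needs:
#' three synthetic classes share one motif bank and motif mix and differ
#' only in placement (uniform / clustered / graded). A three-stage sparse
#' autoencoder stack is pretrained greedily on 64 px crops of the training
#' split, frozen, and reduction classifiers are trained on the encoded
#' images at full size and on random crops at the requested context sizes.
#' The subpane grid scales with the input (G = encoded edge / 4) so the
#' reducer's subpane dimensions — and with them its parameter count — stay
#' fixed across context sizes.
#'
#' @param seed master seed; every stage of the experiment derives from it.
#' @param n_per_class images per class (default 80).
#' @param full_size full-image edge in px (default 256).
#' @param crop_sizes smaller context sizes to probe (default c(32, 128)).
#' @param stack_steps,reduce_steps Adam steps for pretraining / reduction.
#' @param density shared motif density per px^2.
#' @return class \code{context_experiment}: list with \code{accuracy}
#'   (named vector, percent, ordered by context size), \code{confusions},
#'   \code{stack}, \code{sizes}.
#' @export
context_size_experiment <- function(seed = 1L, n_per_class = 80L,
                                    full_size = 256L,
                                    crop_sizes = c(32L, 128L),
                                    stack_steps = 120L,
                                    reduce_steps = 800L,
                                    density = 1.1e-3) {
  seed <- as.integer(seed)
  specs <- context_class_specs(density)
  bank <- make_motif_bank(12L, 4L, seed = seed + 100L)
  ds <- generate_dataset(specs, n_per_class = n_per_class, size = full_size,
                         seed = seed, bank = bank)
  stack <- train_stack(
    pretrain_crops(ds, seed = seed + 9L),
    default_stage_cfgs(),
    train_config(steps = stack_steps, batch_size = 8L, lambda_s = 1e-3,
                 seed = seed + 10L))
  sizes <- sort(unique(c(crop_sizes, full_size)))
  acc <- numeric(length(sizes))
  confs <- vector("list", length(sizes))
  names(acc) <- names(confs) <- paste0(sizes, "px")
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    dsx <- if (sz == full_size) ds else crop_dataset(ds, sz, seed + 6L + si)
    rc <- train_reduction(dsx, stack,
      reduction_config(G = max(1L, sz %/% 32L), d_r = 24L,
                       tile_size = min(64L, sz), n_classes = 3L,
                       class_names = ds$class_names),
      train_config(steps = reduce_steps, batch_size = 16L,
                   learning_rate = 3e-3, seed = seed + 20L))
    confs[[si]] <- evaluate_reduction(rc, dsx)
    acc[si] <- confs[[si]]$accuracy
  }
  structure(list(accuracy = acc, confusions = confs, stack = stack,
                 sizes = sizes, seed = seed),
            class = "context_experiment")
}

#' @export
print.context_experiment <- function(x, ...) {
  cat("Context-size experiment (placement-only classes):\n")
  for (i in seq_along(x$sizes)) {
    cat(sprintf("  %4d px context: accuracy %.1f %%\n",
                x$sizes[i], x$accuracy[i]))
  }
  invisible(x)
}

#' Compare the three classifier variants across filter sizes
#'
#' Qualitative report of the variant x filter-size x input-size grid on
#' synthetic data: trains a direct classifier, an autoencoder-pretrained
#' classifier and a RISA-pretrained classifier at each filter size and
#' reports test accuracies.
#'
#' @param data a \code{labeled_dataset} of small images (e.g. 32 or 64 px).
#' @param filter_sizes convolution filter edges to try (default 3, 4, 5).
#' @param cfg a \code{\link{train_config}} for the supervised phase.
#' @param pre_cfg a \code{\link{train_config}} for pretraining.
#' @return data.frame (input_size, filter_size, variant, accuracy).
#' @export
compare_variants <- function(data, filter_sizes = c(3L, 4L, 5L),
                             cfg = train_config(steps = 150L),
                             pre_cfg = train_config(steps = 80L)) {
  input_size <- dim(as_image_array(data$images[[1]]))[1]
  nc <- length(data$class_names)
  tr <- dataset_subset(data, "train")
  rows <- list()
  for (f in filter_sizes) {
    stack <- train_stack(tr$images,
                         list(list(filter_size = f, n_filters = 16L)),
                         pre_cfg)
    patches <- sample_patches(tr$images, n = 400L, p = f, seed = pre_cfg$seed)
    risa <- train_risa(patches, k = 16L, group_size = 2L, lambda = 0.1,
                       cfg = pre_cfg)
    for (variant in c("direct", "ae", "risa")) {
      pre <- switch(variant, direct = NULL, ae = stack, risa = risa)
      mdl <- build_variant(variant, pre,
                           list(input_size = input_size, n_classes = nc,
                                class_names = data$class_names,
                                filter_size = f))
      mdl <- train_classifier(mdl, data, cfg)
      cm <- evaluate_confusion(mdl, data)
      rows[[length(rows) + 1L]] <- data.frame(
        input_size = input_size, filter_size = f, variant = variant,
        accuracy = cm$accuracy)
    }
  }
  do.call(rbind, rows)
}

#' Feature-recovery experiment: can top-k averaging recover a planted motif?
#'
#' Renders images dominated by the bank's first (stripe) motif, trains one
#' sparse autoencoder stage, samples patches, ranks them by each central
#' encoding node (filter x position), averages the top \code{k} patches per
#' node, and returns the best Pearson correlation between an averaged
#' image's ink intensity (1 - mean channel) and the planted motif's stamp
#' mask — the node that most clearly demonstrates the learned feature.
#'
#' @param seed master seed.
#' @param n_images number of 64 px training images.
#' @param n_patches patches sampled for the ranking (12 px).
#' @param k top patches averaged per node.
#' @param steps pretraining steps.
#' @return list(correlation, node, average, motif, stage).
#' @export
motif_recovery_experiment <- function(seed = 1L, n_images = 20L,
                                      n_patches = 8000L, k = 100L,
                                      steps = 120L) {
  seed <- as.integer(seed)
  bank <- make_motif_bank(10L, 4L, seed = seed + 3L)
  spec <- class_spec(1L, "dense", placement = "uniform", density = 3e-3,
                     motif_mix = c(0.94, 0.02, 0.02, 0.02))
  imgs <- with_seed(seed, lapply(seq_len(n_images), function(i) {
    render_class_image(spec, bank, 64L, seed = 300L + i)
  }))
  stage <- train_stage(imgs, list(filter_size = 7L, n_filters = 12L),
                       train_config(steps = steps, batch_size = 8L,
                                    lambda_s = 1e-3, seed = seed + 4L))
  patches <- sample_patches(imgs, n = n_patches, p = 12L, seed = seed + 5L)
  # encode each patch once; scan the 2x2 central nodes of the 6x6 encoding
  Z <- lapply(patches, function(pt) encode_stage(pt, stage)[3:4, 3:4, ])
  motif <- bank$motifs[[1]]$mask
  best <- list(correlation = -Inf)
  for (rr in 1:2) {
    for (cc in 1:2) {
      for (f in seq_len(stage$n_filters)) {
        s <- vapply(Z, function(z) z[rr, cc, f], numeric(1))
        top <- order(-s, seq_along(s))[seq_len(k)]
        avg <- Reduce(`+`, patches[top]) / k
        ink <- 1 - apply(avg, c(1, 2), mean)
        cc_val <- stats::cor(as.vector(ink[2:11, 2:11]), as.vector(motif))
        if (cc_val > best$correlation) {
          best <- list(correlation = cc_val,
                       node = c(filter = f, row = rr + 2L, col = cc + 2L),
                       average = avg, motif = motif, stage = stage)
        }
      }
    }
  }
  best
}

#' Sparsity-penalty contrast experiment
#'
#' Trains the same single-stage architecture twice from the same seed on
#' the same images — once with lambda_s = 0 and once with a large
#' lambda_s — and returns both runs' final encoding entropies.
#'
#' @param seed master seed.
#' @param lambda_large the penalized run's weight.
#' @param n_images,size,steps study size.
#' @return list(S_unpenalized, S_penalized, history_0, history_pen).
#' @export
sparsity_contrast_experiment <- function(seed = 1L, lambda_large = 0.05,
                                         n_images = 50L, size = 32L,
                                         steps = 200L) {
  seed <- as.integer(seed)
  specs <- context_class_specs()
  bank <- make_motif_bank(12L, 4L, seed = seed + 100L)
  imgs <- with_seed(seed, lapply(seq_len(n_images), function(i) {
    render_class_image(specs[[1L + (i %% 3L)]], bank, size,
                       seed = 1000L + i)
  }))
  cfg0 <- train_config(steps = steps, batch_size = 8L, lambda_s = 0,
                       seed = seed + 1L)
  cfgp <- cfg0; cfgp$lambda_s <- lambda_large
  scfg <- list(filter_size = 5L, n_filters = 16L)
  st0 <- train_stage(imgs, scfg, cfg0)
  stp <- train_stage(imgs, scfg, cfgp)
  h0 <- attr(st0, "history"); hp <- attr(stp, "history")
  list(S_unpenalized = h0$S[nrow(h0)], S_penalized = hp$S[nrow(hp)],
       history_0 = h0, history_pen = hp)
}

#' Reconstruction-training experiment
#'
#' Trains one stage on synthetic images and measures the mean per-image
#' reconstruction error R on held-out images, for the trained stage and
#' for the same architecture at its (seeded) initialization.
#'
#' @param seed master seed.
#' @param n_train,n_heldout,size,steps study size.
#' @return list(R_init, R_trained, ratio).
#' @export
reconstruction_ratio_experiment <- function(seed = 1L, n_train = 50L,
                                            n_heldout = 10L, size = 32L,
                                            steps = 200L) {
  seed <- as.integer(seed)
  specs <- context_class_specs()
  bank <- make_motif_bank(12L, 4L, seed = seed + 100L)
  imgs <- with_seed(seed, lapply(seq_len(n_train + n_heldout), function(i) {
    render_class_image(specs[[1L + (i %% 3L)]], bank, size,
                       seed = 2000L + i)
  }))
  held <- imgs[seq_len(n_heldout) + n_train]
  cfg <- train_config(steps = steps, batch_size = 8L, lambda_s = 1e-3,
                      seed = seed + 1L)
  trained <- train_stage(imgs[seq_len(n_train)],
                         list(filter_size = 5L, n_filters = 16L), cfg)
  init <- cae_stage(5L, 16L, 3L, seed = cfg$seed)
  mean_R <- function(st) {
    mean(vapply(held, function(x) {
      reconstruction_loss(x, reconstruct(x, st))
    }, numeric(1)))
  }
  R_init <- mean_R(init); R_trained <- mean_R(trained)
  list(R_init = R_init, R_trained = R_trained, ratio = R_trained / R_init)
}
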