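# The three classifier variants:
#   direct — convolution+pool blocks trained jointly with a softmax head;
#   ae     — a frozen greedy-pretrained autoencoder stack feeding the head;
#   risa   — a frozen RISA layer applied convolutionally feeding the head.
# All heads are linear maps to class logits trained with softmax
# cross-entropy under Adam. Pretrained extractors stay frozen during head
# training unless fine_tune = TRUE (autoencoder variant only).

#' Numerically stable softmax cross-entropy
#'
#' @param logits numeric vector of class scores (>= 2 classes).
#' @param true_class 1-based index of the true class.
#' @return -log p_true with p = softmax(logits); nonnegative.
#' @examples
#' softmax_cross_entropy(c(0, 0, 0), 1)  # log(3)
#' @export
softmax_cross_entropy <- function(logits, true_class) {
  if (length(logits) < 2) stop_config("need at least 2 classes")
  if (true_class < 1 || true_class > length(logits) ||
      true_class != round(true_class)) {
    stop_index("true_class out of range")
  }
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[true_class]
}

default_block_filters <- c(8L, 16L, 24L, 32L)

#' Build a classifier variant
#'
#' \code{direct}: conv+sigmoid+pool blocks (two for 64 px inputs, one more
#' per doubling, one fewer per halving, minimum one) trained jointly with
#' the head. \code{ae}: a trained \code{cae_stack} as frozen feature
#' extractor. \code{risa}: a trained \code{risa_model} applied
#' convolutionally as frozen extractor (head input dimension = groups x
#' spatial positions).
#'
#' @param kind "direct", "ae" or "risa".
#' @param pretrained the pretrained extractor (required for ae/risa).
#' @param head_cfg list with \code{input_size}, \code{n_classes},
#'   optionally \code{class_names}, \code{filter_size} (direct, default 5)
#'   and \code{fine_tune} (ae only, default FALSE).
#' @return class \code{pathae_classifier} (weights are seeded at training
#'   time).
#' @export
build_variant <- function(kind = c("direct", "ae", "risa"),
                          pretrained = NULL, head_cfg = list()) {
  kind <- match.arg(kind)
  input_size <- head_cfg$input_size %||% 64L
  n_classes <- head_cfg$n_classes %||% 3L
  class_names <- head_cfg$class_names %||% c("TRU", "PP", "PI")[seq_len(n_classes)]
  if (kind != "direct" && is.null(pretrained)) {
    stop_config(sprintf("variant '%s' requires a pretrained extractor", kind))
  }
  model <- list(kind = kind, input_size = as.integer(input_size),
                n_classes = as.integer(n_classes), class_names = class_names,
                fine_tune = isTRUE(head_cfg$fine_tune))
  if (kind == "direct") {
    nb <- max(1L, 2L + as.integer(round(log2(input_size / 64))))
    model$filter_size <- as.integer(head_cfg$filter_size %||% 5L)
    model$block_filters <- default_block_filters[seq_len(min(nb, 4L))]
    model$feature_dim <- as.integer(
      (input_size / 2^length(model$block_filters))^2 *
        model$block_filters[length(model$block_filters)])
    model$blocks <- NULL       # seeded at train time
  } else if (kind == "ae") {
    if (!inherits(pretrained, "cae_stack")) {
      stop_config("'ae' variant needs a cae_stack")
    }
    model$extractor <- pretrained
    fdim <- (input_size / 2^length(pretrained))^2 *
      pretrained[[length(pretrained)]]$n_filters
    model$feature_dim <- as.integer(fdim)
  } else {
    if (!inherits(pretrained, "risa_model")) {
      stop_config("'risa' variant needs a risa_model")
    }
    if (model$fine_tune) stop_config("fine_tune is only supported for the 'ae' variant")
    model$extractor <- pretrained
    model$feature_dim <- as.integer(input_size^2 * nrow(pretrained$H))
  }
  model$head <- list(W = matrix(0, model$feature_dim, n_classes),
                     b = rep(0, n_classes))
  structure(model, class = "pathae_classifier")
}

#' @export
print.pathae_classifier <- function(x, ...) {
  cat(sprintf("Classifier variant '%s': %d px input, %d features -> %d classes (%s)\n",
              x$kind, x$input_size, x$feature_dim, x$n_classes,
              paste(x$class_names, collapse = ", ")))
  h <- attr(x, "history")
  if (!is.null(h)) {
    cat(sprintf("  trained %d steps; loss %.4g -> %.4g\n",
                length(h), h[1], h[length(h)]))
  }
  invisible(x)
}

# Frozen-extractor feature vector for one image.
extract_features <- function(model, img) {
  img <- as_image_array(img)
  if (model$kind == "ae") as.numeric(stack_encode(img, model$extractor))
  else if (model$kind == "risa") as.numeric(risa_forward_conv(img, model$extractor))
  else stop_config("direct variant has no frozen extractor")
}

# Direct-variant forward with caches for backprop.
direct_forward <- function(model, img) {
  caches <- vector("list", length(model$blocks))
  x <- as_image_array(img)
  for (k in seq_along(model$blocks)) {
    blk <- model$blocks[[k]]
    f <- dim(blk$w)[1]
    cols <- im2col(x, f)
    d <- dim(x)
    a <- sweep(cols %*% matrix(blk$w, ncol = dim(blk$w)[4]), 2L, blk$b, "+")
    h <- array(sigmoid(a), c(d[1], d[2], dim(blk$w)[4]))
    pl <- maxpool2(h)
    caches[[k]] <- list(x = x, cols = cols, h = h, sw = pl$switch)
    x <- pl$values
  }
  list(flat = as.numeric(x), caches = caches, out_dim = dim(x))
}

init_direct_blocks <- function(model, in_channels, seed) {
  f <- model$filter_size
  blocks <- vector("list", length(model$block_filters))
  with_seed(seed, {
    ci <- in_channels
    for (k in seq_along(blocks)) {
      nf <- model$block_filters[k]
      blocks[[k]] <- list(w = init_uniform(c(f, f, ci, nf), f * f * ci),
                          b = rep(0, nf))
      ci <- nf
    }
  })
  blocks
}

head_logits <- function(head, X) {
  sweep(X %*% head$W, 2L, head$b, "+")
}

#' Train a classifier variant
#'
#' Adam on softmax cross-entropy over the dataset's train split. For the
#' pretrained variants the extractor features are computed once and the
#' extractor weights are untouched (frozen); with \code{fine_tune = TRUE}
#' the autoencoder encoding weights are updated jointly with the head.
#'
#' @param model a \code{\link{build_variant}} model.
#' @param data a \code{labeled_dataset} with >= 2 classes present.
#' @param cfg a \code{\link{train_config}}.
#' @return the trained model with per-step mean loss history attached.
#' @export
train_classifier <- function(model, data, cfg = train_config()) {
  tr <- dataset_subset(data, "train")
  if (length(tr$images) == 0) stop_data("no training images")
  if (length(unique(tr$labels)) < 2) stop_data("need >= 2 classes in the training data")
  model$class_names <- data$class_names %||% model$class_names
  nc <- model$n_classes
  if (max(tr$labels) > nc) stop_data("labels exceed the configured class count")

  if (model$kind == "direct") {
    model <- train_direct(model, tr, cfg)
  } else if (model$kind == "ae" && model$fine_tune) {
    model <- train_ae_finetune(model, tr, cfg)
  } else {
    X <- t(vapply(tr$images, function(im) extract_features(model, im),
                  numeric(model$feature_dim)))
    model <- train_head_only(model, X, tr$labels, cfg)
  }
  model
}

train_head_only <- function(model, X, labels, cfg) {
  nc <- model$n_classes
  params <- with_seed(cfg$seed, list(
    W = init_uniform(c(ncol(X), nc), ncol(X)), b = rep(0, nc)))
  state <- adam_init(params)
  hist <- numeric(cfg$steps)
  onehot <- diag(nc)[labels, , drop = FALSE]
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(nrow(X), min(cfg$batch_size, nrow(X)))
      Xb <- X[bi, , drop = FALSE]
      logits <- head_logits(params, Xb)
      p <- softmax_rows(logits)
      hist[step] <- mean(vapply(seq_along(bi), function(i) {
        softmax_cross_entropy(logits[i, ], labels[bi[i]])
      }, numeric(1)))
      dl <- (p - onehot[bi, , drop = FALSE]) / length(bi)
      upd <- adam_step(params,
                       list(W = crossprod(Xb, dl), b = colSums(dl)),
                       state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
  })
  model$head <- params
  attr(model, "history") <- hist
  model
}

train_direct <- function(model, tr, cfg) {
  in_ch <- dim(as_image_array(tr$images[[1]]))[3]
  model$blocks <- init_direct_blocks(model, in_ch, cfg$seed)
  nc <- model$n_classes
  params <- list()
  for (k in seq_along(model$blocks)) {
    params[[paste0("w", k)]] <- model$blocks[[k]]$w
    params[[paste0("b", k)]] <- model$blocks[[k]]$b
  }
  params$W <- with_seed(cfg$seed + 2L,
                        init_uniform(c(model$feature_dim, nc),
                                     model$feature_dim))
  params$bh <- rep(0, nc)
  state <- adam_init(params)
  hist <- numeric(cfg$steps)
  nb_blocks <- length(model$blocks)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(length(tr$images),
                       min(cfg$batch_size, length(tr$images)))
      acc <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
      lsum <- 0
      for (i in bi) {
        for (k in seq_len(nb_blocks)) {
          model$blocks[[k]]$w <- params[[paste0("w", k)]]
          model$blocks[[k]]$b <- params[[paste0("b", k)]]
        }
        fw <- direct_forward(model, tr$images[[i]])
        logits <- drop(fw$flat %*% params$W) + params$bh
        lsum <- lsum + softmax_cross_entropy(logits, tr$labels[i])
        p <- drop(softmax_rows(matrix(logits, 1)))
        dl <- p; dl[tr$labels[i]] <- dl[tr$labels[i]] - 1
        acc$W <- acc$W + outer(fw$flat, dl)
        acc$bh <- acc$bh + dl
        dz <- array(drop(params$W %*% dl), fw$out_dim)
        for (k in rev(seq_len(nb_blocks))) {
          ca <- fw$caches[[k]]
          dh <- maxpool2_bwd(dz, ca$sw)
          da <- dh * ca$h * (1 - ca$h)
          bwd <- conv_same_bwd(ca$x, params[[paste0("w", k)]], da,
                               need_dx = (k > 1L), cols = ca$cols)
          acc[[paste0("w", k)]] <- acc[[paste0("w", k)]] + bwd$dw
          acc[[paste0("b", k)]] <- acc[[paste0("b", k)]] + bwd$db
          if (k > 1L) dz <- bwd$dx
        }
      }
      nbatch <- length(bi)
      acc <- lapply(acc, function(a) a / nbatch)
      hist[step] <- lsum / nbatch
      upd <- adam_step(params, acc, state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
  })
  for (k in seq_len(nb_blocks)) {
    model$blocks[[k]]$w <- params[[paste0("w", k)]]
    model$blocks[[k]]$b <- params[[paste0("b", k)]]
  }
  model$head <- list(W = params$W, b = params$bh)
  attr(model, "history") <- hist
  model
}

# Joint training of stack encoding weights and head (fine_tune = TRUE).
train_ae_finetune <- function(model, tr, cfg) {
  stages <- model$extractor
  nc <- model$n_classes
  params <- list()
  for (k in seq_along(stages)) {
    params[[paste0("w", k)]] <- stages[[k]]$encode_filters
    params[[paste0("b", k)]] <- stages[[k]]$encode_bias
  }
  params$W <- with_seed(cfg$seed + 2L,
                        init_uniform(c(model$feature_dim, nc),
                                     model$feature_dim))
  params$bh <- rep(0, nc)
  state <- adam_init(params)
  hist <- numeric(cfg$steps)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      bi <- sample.int(length(tr$images),
                       min(cfg$batch_size, length(tr$images)))
      acc <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
      lsum <- 0
      for (i in bi) {
        x <- as_image_array(tr$images[[i]])
        caches <- vector("list", length(stages))
        for (k in seq_along(stages)) {
          f <- stages[[k]]$filter_size
          cols <- im2col(x, f)
          d <- dim(x)
          a <- sweep(cols %*% matrix(params[[paste0("w", k)]],
                                     ncol = stages[[k]]$n_filters),
                     2L, params[[paste0("b", k)]], "+")
          h <- array(sigmoid(a), c(d[1], d[2], stages[[k]]$n_filters))
          pl <- maxpool2(h)
          caches[[k]] <- list(x = x, cols = cols, h = h, sw = pl$switch)
          x <- pl$values
        }
        flat <- as.numeric(x)
        logits <- drop(flat %*% params$W) + params$bh
        lsum <- lsum + softmax_cross_entropy(logits, tr$labels[i])
        p <- drop(softmax_rows(matrix(logits, 1)))
        dl <- p; dl[tr$labels[i]] <- dl[tr$labels[i]] - 1
        acc$W <- acc$W + outer(flat, dl)
        acc$bh <- acc$bh + dl
        dz <- array(drop(params$W %*% dl), dim(x))
        for (k in rev(seq_along(stages))) {
          ca <- caches[[k]]
          dh <- maxpool2_bwd(dz, ca$sw)
          da <- dh * ca$h * (1 - ca$h)
          bwd <- conv_same_bwd(ca$x, params[[paste0("w", k)]], da,
                               need_dx = (k > 1L), cols = ca$cols)
          acc[[paste0("w", k)]] <- acc[[paste0("w", k)]] + bwd$dw
          acc[[paste0("b", k)]] <- acc[[paste0("b", k)]] + bwd$db
          if (k > 1L) dz <- bwd$dx
        }
      }
      nbatch <- length(bi)
      acc <- lapply(acc, function(a) a / nbatch)
      hist[step] <- lsum / nbatch
      upd <- adam_step(params, acc, state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
  })
  for (k in seq_along(stages)) {
    stages[[k]]$encode_filters <- params[[paste0("w", k)]]
    stages[[k]]$encode_bias <- params[[paste0("b", k)]]
  }
  model$extractor <- stages
  model$head <- list(W = params$W, b = params$bh)
  attr(model, "history") <- hist
  model
}

#' Class probabilities / labels from a trained classifier
#'
#' @param object a trained \code{pathae_classifier}.
#' @param newdata one H x W x C image or a list of them.
#' @param type "prob" for a probability vector (or matrix), "class" for
#'   predicted labels (argmax; ties to the lowest class index).
#' @param ... unused.
#' @export
predict.pathae_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  imgs <- if (is.list(newdata) && !is.array(newdata)) newdata else list(newdata)
  P <- t(vapply(imgs, function(im) {
    flat <- if (object$kind == "direct") direct_forward(object, im)$flat
            else extract_features(object, im)
    drop(softmax_rows(matrix(drop(flat %*% object$head$W) + object$head$b, 1)))
  }, numeric(object$n_classes)))
  colnames(P) <- object$class_names
  if (type == "prob") {
    if (length(imgs) == 1L) drop(P) else P
  } else {
    object$class_names[apply(P, 1L, which.max)]
  }
}

#' Confusion matrix on the test split
#'
#' Argmax prediction per test image (ties to the lowest class index);
#' counts with rows = true class, columns = predicted class.
#'
#' @param model a trained \code{pathae_classifier} (or any object with a
#'   \code{predict} method returning probabilities).
#' @param data a \code{labeled_dataset} with a nonempty test split.
#' @return class \code{confusion_matrix}: list(counts, totals, accuracy
#'   in percent).
#' @export
evaluate_confusion <- function(model, data) {
  te <- dataset_subset(data, "test")
  if (length(te$images) == 0) stop_data("empty test split")
  nc <- model$n_classes
  cn <- model$class_names
  counts <- matrix(0L, nc, nc, dimnames = list(true = cn, predicted = cn))
  for (i in seq_along(te$images)) {
    p <- predict(model, te$images[[i]], type = "prob")
    counts[te$labels[i], which.max(p)] <- counts[te$labels[i], which.max(p)] + 1L
  }
  new_confusion_matrix(counts)
}

new_confusion_matrix <- function(counts) {
  structure(list(counts = counts, totals = rowSums(counts),
                 accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cn <- colnames(x$counts)
  cat("Diagnosis  |", formatC(cn, width = 6), "| Total  Accuracy (%)\n")
  for (i in seq_len(nrow(x$counts))) {
    acc_i <- if (x$totals[i] > 0) 100 * x$counts[i, i] / x$totals[i] else NA
    cat(formatC(rownames(x$counts)[i], width = 10), "|",
        formatC(x$counts[i, ], width = 6), "|",
        formatC(x$totals[i], width = 5),
        formatC(acc_i, format = "f", digits = 1, width = 9), "\n")
  }
  cat(formatC("Total", width = 10), "|",
      formatC(colSums(x$counts), width = 6), "|",
      formatC(sum(x$counts), width = 5),
      formatC(x$accuracy, format = "f", digits = 1, width = 9), "\n")
  invisible(x)
}

#' Write a confusion matrix as TSV
#'
#' Rows = true classes, prediction columns, then Total and per-row accuracy
#' percent; a final Total row.
#'
#' @param cm a \code{confusion_matrix}.
#' @param path output file.
#' @export
write_confusion_tsv <- function(cm, path) {
  df <- as.data.frame.matrix(cm$counts)
  df$Total <- cm$totals
  df$Accuracy <- ifelse(cm$totals > 0,
                        round(100 * diag(cm$counts) / cm$totals, 1), NA)
  df <- rbind(df, c(as.list(colSums(cm$counts)), Total = sum(cm$counts),
                    Accuracy = round(cm$accuracy, 1)))
  rownames(df)[nrow(df)] <- "Total"
  utils::write.table(cbind(Subtype = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
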