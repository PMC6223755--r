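# Synthetic labeled textures: every class draws its local motifs from one
# shared bank (so cell-scale appearance carries no class signal) and differs
# only in the spatial point process placing the motifs. This emulates tissue
# subtypes whose local cell structures look alike while their cellular
# distribution over the tissue differs, which is exactly the regime where
# classification needs spatial context.

EOSIN_BG <- c(0.92, 0.78, 0.82)   # pinkish background base color
BG_NOISE_AMP <- 0.05              # low-amplitude smoothed background noise

#' Build a bank of local motif stamps
#'
#' Generates \code{n_motifs} square stamps of edge \code{m}: Gaussian
#' cell-blobs, oriented stripe patterns, concentric ring/target patterns and
#' bar crosses, each with a dark nuclear-like color. At least one stripe and
#' one ring motif are always present. The bank is a pure function of its
#' arguments: the same seed reproduces it bit for bit.
#'
#' @param m stamp edge length in pixels (>= 4).
#' @param n_motifs number of stamps (>= 2).
#' @param seed integer seed.
#' @return an object of class \code{motif_bank}: list with \code{motifs}
#'   (each a list of \code{mask} m x m in [0,1], \code{color} RGB,
#'   \code{kind}), \code{m}, \code{seed}.
#' @examples
#' bank <- make_motif_bank(8, 4, seed = 1)
#' length(bank$motifs)
#' @export
make_motif_bank <- function(m, n_motifs, seed = 1L) {
  if (m < 4) stop_size("motif edge length m must be >= 4")
  if (n_motifs < 2) stop_config("need at least 2 motifs")
  kinds <- rep(c("stripe", "ring", "blob", "cross"), length.out = n_motifs)
  ctr <- (m + 1) / 2
  gx <- matrix(rep(seq_len(m) - ctr, each = m), m, m)   # column offsets
  gy <- matrix(rep(seq_len(m) - ctr, times = m), m, m)  # row offsets
  r2 <- gx^2 + gy^2
  envelope <- exp(-r2 / (2 * (0.42 * m)^2))
  motifs <- with_seed(seed, lapply(seq_len(n_motifs), function(i) {
    kind <- kinds[i]
    mask <- switch(kind,
      blob = exp(-r2 / (2 * (0.22 * m * stats::runif(1, 0.8, 1.2))^2)),
      stripe = {
        th <- stats::runif(1, 0, pi)
        wl <- stats::runif(1, 0.55, 0.75) * m
        (0.5 + 0.5 * cos(2 * pi * (cos(th) * gx + sin(th) * gy) / wl)) *
          envelope
      },
      ring = {
        wl <- stats::runif(1, 0.5, 0.7) * m
        (0.5 + 0.5 * cos(2 * pi * sqrt(r2) / wl)) * envelope
      },
      cross = {
        wb <- stats::runif(1, 0.08, 0.16) * m
        pmax(exp(-gx^2 / (2 * wb^2)), exp(-gy^2 / (2 * wb^2))) * envelope
      })
    mask <- mask / max(mask)
    # dark purplish nuclear tones, jittered per motif
    color <- pmin(1, pmax(0, c(0.30, 0.18, 0.45) + stats::runif(3, -0.08, 0.08)))
    list(mask = mask, color = color, kind = kind)
  }))
  structure(list(motifs = motifs, m = as.integer(m), seed = as.integer(seed)),
            class = "motif_bank")
}

#' @export
print.motif_bank <- function(x, ...) {
  cat("Motif bank:", length(x$motifs), "stamps of", x$m, "x", x$m, "px (",
      paste(vapply(x$motifs, `[[`, "", "kind"), collapse = ", "), ")\n")
  invisible(x)
}

#' Specify a synthetic class
#'
#' A class is a placement point process plus a mixing distribution over the
#' motif bank. Classes meant to be distinguishable only by context share
#' \code{motif_mix} and differ in \code{placement}.
#'
#' @param class_id integer label index (1-based).
#' @param name class label string.
#' @param placement one of \code{"uniform"} (homogeneous Poisson),
#'   \code{"clustered"} (Neyman-Scott parent-offspring) or \code{"graded"}
#'   (linear-gradient inhomogeneous Poisson, sampled by thinning).
#' @param density expected motif instances per pixel^2 (> 0).
#' @param cluster_radius Gaussian offspring spread in px (clustered only).
#' @param cluster_size mean offspring per parent (clustered only).
#' @param direction gradient direction in radians (graded only).
#' @param motif_mix probability vector over the bank's motifs (sums to 1).
#' @param color_jitter scale of per-instance hue/intensity noise.
#' @return an object of class \code{class_spec}.
#' @export
class_spec <- function(class_id, name = paste0("class", class_id),
                       placement = c("uniform", "clustered", "graded"),
                       density = 1.1e-3, cluster_radius = 10, cluster_size = 9,
                       direction = 0, motif_mix = NULL, color_jitter = 0.05) {
  placement <- match.arg(placement)
  if (density <= 0) stop_config("density must be > 0")
  if (!is.null(motif_mix)) {
    if (abs(sum(motif_mix) - 1) > 1e-9) {
      stop_config("motif_mix must sum to 1")
    }
  }
  structure(list(class_id = as.integer(class_id), name = name,
                 placement = placement, density = density,
                 cluster_radius = cluster_radius, cluster_size = cluster_size,
                 direction = direction, motif_mix = motif_mix,
                 color_jitter = color_jitter),
            class = "class_spec")
}

# Smoothed background noise: coarse Gaussian grid, bilinear upsampling.
smooth_noise <- function(size, amp, cell = 8L) {
  n <- size %/% cell + 2L
  coarse <- matrix(stats::rnorm(n * n), n, n)
  pos <- (seq_len(size) - 1) / cell + 1
  i0 <- pmin(floor(pos), n - 1L); fr <- pos - i0
  a <- coarse[i0, i0, drop = FALSE]; b <- coarse[i0 + 1L, i0, drop = FALSE]
  cc <- coarse[i0, i0 + 1L, drop = FALSE]; d <- coarse[i0 + 1L, i0 + 1L, drop = FALSE]
  w1 <- matrix(1 - fr, size, size); w2 <- matrix(fr, size, size)
  h1 <- matrix(1 - fr, size, size, byrow = TRUE)
  h2 <- matrix(fr, size, size, byrow = TRUE)
  out <- (a * w1 + b * w2) * h1 + (cc * w1 + d * w2) * h2
  out * amp
}

# Sample motif center coordinates (rows/cols, 0-based continuous) for a spec.
sample_placements <- function(spec, size) {
  area <- size * size
  if (spec$placement == "uniform") {
    n <- stats::rpois(1, spec$density * area)
    cbind(row = stats::runif(n, 0, size), col = stats::runif(n, 0, size))
  } else if (spec$placement == "clustered") {
    npar <- stats::rpois(1, spec$density * area / spec$cluster_size)
    pts <- NULL
    if (npar > 0) {
      pr <- stats::runif(npar, 0, size); pc <- stats::runif(npar, 0, size)
      for (i in seq_len(npar)) {
        k <- stats::rpois(1, spec$cluster_size)
        if (k > 0) {
          pts <- rbind(pts, cbind(
            row = pr[i] + stats::rnorm(k, 0, spec$cluster_radius),
            col = pc[i] + stats::rnorm(k, 0, spec$cluster_radius)))
        }
      }
    }
    if (is.null(pts)) pts <- cbind(row = numeric(0), col = numeric(0))
    keep <- pts[, 1] >= 0 & pts[, 1] < size & pts[, 2] >= 0 & pts[, 2] < size
    pts[keep, , drop = FALSE]
  } else { # graded: intensity 2*density*t along the direction, by thinning
    ncand <- stats::rpois(1, 2 * spec$density * area)
    rr <- stats::runif(ncand, 0, size); cc <- stats::runif(ncand, 0, size)
    tpar <- (cos(spec$direction) * cc + sin(spec$direction) * rr) / size
    tpar <- pmin(1, pmax(0, tpar))
    keep <- stats::runif(ncand) < tpar
    cbind(row = rr[keep], col = cc[keep])
  }
}

#' Render one labeled class image
#'
#' Samples motif positions from the class's point process, draws motif
#' indices from the class's mix, and alpha-composites the stamps onto a
#' noisy eosin-pink background. Overlapping stamps combine by per-pixel
#' maximum of their premultiplied contributions, so composition order never
#' matters and values never wrap. The sampled motif centers are attached as
#' the \code{"placements"} attribute for spatial-statistics checks.
#'
#' @param spec a \code{\link{class_spec}}.
#' @param bank a \code{\link{make_motif_bank}} bank.
#' @param size image edge length in px (>= 2 * bank$m).
#' @param seed integer seed.
#' @return size x size x 3 numeric array in [0,1].
#' @export
render_class_image <- function(spec, bank, size, seed = 1L) {
  if (size < 2 * bank$m) stop_size("image size must be at least twice the motif size")
  m <- bank$m
  mix <- spec$motif_mix %||% rep(1 / length(bank$motifs), length(bank$motifs))
  if (length(mix) != length(bank$motifs)) {
    stop_config("motif_mix length must equal the number of motifs in the bank")
  }
  with_seed(seed, {
    bg <- array(rep(EOSIN_BG, each = size * size), c(size, size, 3))
    nz <- smooth_noise(size, BG_NOISE_AMP)
    for (ch in 1:3) bg[, , ch] <- bg[, , ch] + nz
    pts <- sample_placements(spec, size)
    alpha <- matrix(0, size, size)
    layer <- array(0, c(size, size, 3))
    if (nrow(pts) > 0) {
      midx <- sample.int(length(bank$motifs), nrow(pts), replace = TRUE,
                         prob = mix)
      half <- m %/% 2L
      for (i in seq_len(nrow(pts))) {
        mo <- bank$motifs[[midx[i]]]
        r0 <- round(pts[i, 1]) - half; c0 <- round(pts[i, 2]) - half
        rs <- max(1L, r0 + 1L):min(size, r0 + m)
        cs <- max(1L, c0 + 1L):min(size, c0 + m)
        if (length(rs) < 1L || length(cs) < 1L) next
        mrs <- rs - r0; mcs <- cs - c0
        gain <- max(0, 1 + stats::rnorm(1, 0, spec$color_jitter))
        col_i <- pmin(1, pmax(0, mo$color *
          (1 + stats::rnorm(3, 0, spec$color_jitter))))
        sub <- pmin(1, mo$mask[mrs, mcs, drop = FALSE] * gain)
        alpha[rs, cs] <- pmax(alpha[rs, cs], sub)
        for (ch in 1:3) {
          layer[rs, cs, ch] <- pmax(layer[rs, cs, ch], sub * col_i[ch])
        }
      }
    } else {
      midx <- integer(0)
    }
    img <- bg
    for (ch in 1:3) img[, , ch] <- (1 - alpha) * bg[, , ch] + layer[, , ch]
    img[img > 1] <- 1
    img[img < 0] <- 0
    attr(img, "placements") <- data.frame(
      row = if (nrow(pts)) pts[, 1] else numeric(0),
      col = if (nrow(pts)) pts[, 2] else numeric(0),
      motif = midx)
    img
  })
}

#' Generate a balanced labeled dataset
#'
#' Renders \code{n_per_class} images per class spec and makes a stratified
#' 80/20 train/test split. Deterministic for a fixed seed.
#'
#' @param specs list of \code{\link{class_spec}} objects (>= 2).
#' @param n_per_class images per class (>= 5).
#' @param size image edge length in px.
#' @param seed integer seed.
#' @param bank optional shared \code{motif_bank}; built from \code{seed} if
#'   missing.
#' @return class \code{labeled_dataset}: list with \code{images},
#'   \code{labels} (integer, 1-based), \code{class_names}, \code{split}
#'   ("train"/"test"), \code{seed}.
#' @export
generate_dataset <- function(specs, n_per_class, size, seed = 1L,
                             bank = NULL) {
  if (length(specs) < 2) stop_config("need at least 2 class specs")
  if (n_per_class < 5) stop_data("n_per_class must be >= 5")
  if (is.null(bank)) bank <- make_motif_bank(12L, 4L, seed = seed)
  n_test <- max(1L, round(0.2 * n_per_class))
  images <- list(); labels <- integer(0); split <- character(0)
  sub_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(specs) * n_per_class),
           length(specs), n_per_class))
  for (ci in seq_along(specs)) {
    for (k in seq_len(n_per_class)) {
      images[[length(images) + 1L]] <-
        render_class_image(specs[[ci]], bank, size, seed = sub_seeds[ci, k])
      labels <- c(labels, ci)
      split <- c(split, if (k > n_per_class - n_test) "test" else "train")
    }
  }
  structure(list(images = images, labels = labels,
                 class_names = vapply(specs, `[[`, "", "name"),
                 split = split, seed = as.integer(seed), bank = bank,
                 specs = specs),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled synthetic dataset:", length(x$images), "images of",
      paste(dim(x$images[[1]])[1:2], collapse = "x"), "px\n")
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("  split:", sum(x$split == "train"), "train /",
      sum(x$split == "test"), "test\n")
  invisible(x)
}

# Convenience subsets used throughout training code.
dataset_subset <- function(ds, which = c("train", "test")) {
  which <- match.arg(which)
  keep <- ds$split == which
  list(images = ds$images[keep], labels = ds$labels[keep])
}

#' Three canonical context classes
#'
#' The standard experiment: three classes sharing one motif mix, differing
#' only in placement (uniform / clustered / graded). Local patches are then
#' class-uninformative while whole-image motif dispersion separates the
#' classes.
#'
#' @param density motifs per px^2 shared by all classes.
#' @return list of three \code{class_spec}s named uniform/clustered/graded.
#' @export
context_class_specs <- function(density = 1.1e-3) {
  mix <- c(0.4, 0.3, 0.2, 0.1)
  list(
    class_spec(1L, "uniform",   placement = "uniform",   density = density,
               motif_mix = mix),
    class_spec(2L, "clustered", placement = "clustered", density = density,
               cluster_radius = 10, cluster_size = 9, motif_mix = mix),
    class_spec(3L, "graded",    placement = "graded",    density = density,
               direction = 0, motif_mix = mix)
  )
}

#' Fixed tiny fixture pair for exact-value loss tests
#'
#' Returns a deterministic, formula-enumerable 8 x 8 x 3 input and a
#' distinct 8 x 8 x 3 target, for hand-checkable loss arithmetic.
#'
#' @return list(input, target), both 8 x 8 x 3 in [0,1].
#' @export
tiny_fixture <- function() {
  idx <- expand.grid(r = 0:7, c = 0:7, ch = 0:2)
  input <- array(((idx$r + idx$c + idx$ch) %% 5) / 5, c(8, 8, 3))
  target <- array(((idx$r * idx$c + 2 * idx$ch) %% 7) / 7, c(8, 8, 3))
  list(input = input, target = target)
}

#' Write a dataset to disk as PNGs with a manifest
#'
#' Writes \code{<out>/<class>/<idx>.png}, a \code{manifest.tsv} (path,
#' label, split) and a JSON sidecar recording the generating specs and seed.
#'
#' @param ds a \code{labeled_dataset}.
#' @param out output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_dataset_png <- function(ds, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(ds$images))
  counter <- integer(length(ds$class_names))
  for (i in seq_along(ds$images)) {
    cls <- ds$class_names[ds$labels[i]]
    dir.create(file.path(out, cls), showWarnings = FALSE)
    counter[ds$labels[i]] <- counter[ds$labels[i]] + 1L
    rel <- file.path(cls, sprintf("%04d.png", counter[ds$labels[i]]))
    png::writePNG(ds$images[[i]], file.path(out, rel))
    rows[[i]] <- data.frame(path = rel, label = cls, split = ds$split[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sidecar <- list(seed = ds$seed,
                  classes = lapply(ds$specs, function(s) unclass(s)),
                  motif_bank = list(m = ds$bank$m, seed = ds$bank$seed,
                                    n_motifs = length(ds$bank$motifs)))
  jsonlite::write_json(sidecar, file.path(out, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
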