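# Filter-understanding tools: random patch sampling, ranking patches by one
# encoding node and averaging the top k (the "what does this node like"
# image), and per-filter response heat maps with reconstruction panels.

#' Sample random patches from a set of images
#'
#' Patch positions (and source images) are uniform draws from one seeded
#' stream, so the patch set is reproducible.
#'
#' @param images list of H x W x C arrays, each at least p in both dims.
#' @param n number of patches (0 allowed).
#' @param p patch edge in px.
#' @param seed integer seed.
#' @return list of n p x p x C arrays.
#' @export
sample_patches <- function(images, n, p, seed = 1L) {
  if (length(images) == 0) stop_data("no images to sample from")
  dims <- lapply(images, function(im) dim(as_image_array(im)))
  if (any(vapply(dims, function(d) d[1] < p || d[2] < p, logical(1)))) {
    stop_size("every image must be at least p in both dimensions")
  }
  if (n == 0) return(list())
  with_seed(seed, {
    ii <- sample.int(length(images), n, replace = TRUE)
    lapply(seq_len(n), function(j) {
      im <- as_image_array(images[[ii[j]]])
      d <- dim(im)
      r0 <- sample.int(d[1] - p + 1L, 1L)
      c0 <- sample.int(d[2] - p + 1L, 1L)
      im[r0:(r0 + p - 1L), c0:(c0 + p - 1L), , drop = FALSE]
    })
  })
}

# Activation score of one encoding node for a patch: the value at a fixed
# (filter, row, col) coordinate, or the spatial max for that filter when no
# position is given.
node_score <- function(patch, stages, node) {
  z <- stack_encode(patch, stages)
  d <- dim(z)
  filt <- node$filter %||% stop_index("node$filter is required")
  if (filt < 1 || filt > d[3]) stop_index("node filter index out of range")
  if (is.null(node$row)) {
    max(z[, , filt])
  } else {
    if (node$row < 1 || node$row > d[1] || node$col < 1 || node$col > d[2]) {
      stop_index("node position out of range")
    }
    z[node$row, node$col, filt]
  }
}

#' Rank patches by one encoding node
#'
#' @param patches list of equal-size patches.
#' @param stages a trained \code{cae_stack}.
#' @param node list(filter, row = NULL, col = NULL); without a position the
#'   filter's spatial maximum is used.
#' @return class \code{patch_ranking}: list(scores, order) with order
#'   sorting scores descending, ties broken by lower index.
#' @export
patch_ranking <- function(patches, stages, node) {
  if (length(patches) == 0) stop_data("no patches")
  scores <- vapply(patches, node_score, numeric(1),
                   stages = stages, node = node)
  structure(list(scores = scores,
                 order = order(-scores, seq_along(scores))),
            class = "patch_ranking")
}

#' Average of the top-k patches for one encoding node
#'
#' Ranks the patches by the chosen node's activation and returns the
#' pixelwise mean of the k strongest — an image of the pattern that drives
#' that node.
#'
#' @param patches list of p x p x C patches.
#' @param stages a trained \code{cae_stack}.
#' @param node list(filter, row = NULL, col = NULL).
#' @param k how many top patches to average (<= length(patches)).
#' @return p x p x C array in [0,1].
#' @export
top_k_feature_image <- function(patches, stages, node, k = 100L) {
  if (k < 1 || k > length(patches)) {
    stop_index("k must be between 1 and the number of patches")
  }
  rk <- patch_ranking(patches, stages, node)
  top <- rk$order[seq_len(k)]
  acc <- array(0, dim(as_image_array(patches[[top[1]]])))
  for (i in top) acc <- acc + as_image_array(patches[[i]])
  acc / k
}

# Signed-intensity red-to-blue colormap (low = red, high = blue).
heat_rgb <- function(m) {
  rng <- range(m)
  t <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0 + 0.5
  out <- array(0, c(dim(m), 3))
  out[, , 1] <- 1 - t
  out[, , 2] <- 0.15 * (1 - abs(2 * t - 1))
  out[, , 3] <- t
  out
}

#' Per-filter response maps and reconstruction panel
#'
#' Encodes the image through one stage and returns each filter's activation
#' map (half the input resolution after pooling) plus the stage's
#' reconstruction. When \code{out_dir} is given, writes one red-to-blue
#' heat-map PNG per filter and an input/reconstruction side-by-side PNG.
#'
#' @param img H x W x C array.
#' @param stage a trained \code{cae_stage}.
#' @param out_dir optional output directory for PNGs.
#' @return invisibly, list(maps = H/2 x W/2 x F activations,
#'   reconstruction = H x W x C array, files = written paths).
#' @export
response_maps <- function(img, stage, out_dir = NULL) {
  img <- as_image_array(img)
  z <- encode_stage(img, stage)
  rec <- decode_stage(z, stage)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (fidx in seq_len(dim(z)[3])) {
      fp <- file.path(out_dir, sprintf("filter_%02d.png", fidx))
      png::writePNG(heat_rgb(z[, , fidx]), fp)
      files <- c(files, fp)
    }
    panel <- array(0, c(dim(img)[1], 2L * dim(img)[2] + 4L, 3L))
    panel[, seq_len(dim(img)[2]), ] <- img
    panel[, (dim(img)[2] + 5L):(2L * dim(img)[2] + 4L), ] <- rec
    fp <- file.path(out_dir, "reconstruction.png")
    png::writePNG(panel, fp)
    files <- c(files, fp)
  }
  invisible(list(maps = z, reconstruction = rec, files = files))
}
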