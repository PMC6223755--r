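# Checkpoints, run configuration and raster I/O.
#
# A checkpoint is one hierarchical container with groups stage{k}/...,
# risa/..., reduction/... plus meta (version, configs, seeds), serialized
# as a single RDS file: the round trip is bitwise lossless and the version
# field is checked on load.

CHECKPOINT_VERSION <- 1L

#' Save a model bundle as a checkpoint
#'
#' @param bundle named list of models — any of \code{stack}
#'   (\code{cae_stack}), \code{risa} (\code{risa_model}),
#'   \code{reduction} (\code{reduction_classifier}), \code{classifier}
#'   (\code{pathae_classifier}) — plus anything else worth keeping.
#' @param path output file.
#' @param meta optional list recorded under \code{meta} (configs, seeds).
#' @return invisibly, \code{path}.
#' @export
save_checkpoint <- function(bundle, path, meta = list()) {
  obj <- list(format = "pathae-checkpoint", version = CHECKPOINT_VERSION,
              meta = c(meta, list(created = format(Sys.time(), "%Y-%m-%d"),
                                  package_version = "0.1.0")),
              groups = bundle)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path checkpoint file written by \code{\link{save_checkpoint}}.
#' @return the model bundle (named list), with the checkpoint meta attached
#'   as attribute \code{"meta"}.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such checkpoint: ", path))
  obj <- tryCatch(readRDS(path), error = function(e) {
    pathae_stop("corrupt", paste0("corrupt or truncated checkpoint: ", path))
  })
  if (!is.list(obj) || !identical(obj$format, "pathae-checkpoint")) {
    pathae_stop("corrupt", paste0("not a pathae checkpoint: ", path))
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    pathae_stop("version",
                sprintf("checkpoint version %s does not match supported version %d",
                        as.character(obj$version), CHECKPOINT_VERSION))
  }
  bundle <- obj$groups
  attr(bundle, "meta") <- obj$meta
  bundle
}

# --- run configuration ------------------------------------------------------

run_config_defaults <- function() {
  list(seed = 1L, learning_rate = 1e-3, batch_size = 8L, steps = 200L,
       lambda_s = 1e-3, variant = "ae", input_size = 64L, filter_size = 5L,
       n_classes = 3L, density = 1.1e-3, out = ".", ckpt = NULL, data = NULL)
}

#' Load a run configuration file
#'
#' YAML file; missing keys are filled with documented defaults, unknown
#' keys are rejected by name, and basic constraints are checked.
#'
#' @param path YAML file.
#' @return class \code{run_config} (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such config file: ", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    pathae_stop("config", paste0("cannot parse config: ", conditionMessage(e)))
  })
  if (is.null(raw)) raw <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (cfg$steps < 1) stop_config("steps must be >= 1")
  if (cfg$lambda_s < 0) stop_config("lambda_s must be >= 0")
  if (!cfg$variant %in% c("direct", "ae", "risa")) {
    stop_config("variant must be one of direct, ae, risa")
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' \code{load_config(save_config(cfg, path))} restores the configuration.
#'
#' @param cfg a \code{run_config} or plain list of known keys.
#' @param path output YAML path.
#' @return invisibly, \code{path}.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

# FNV-1a hash of the serialized configuration, for run logs.
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# --- raster I/O -------------------------------------------------------------

#' Read an RGB raster image
#'
#' PNG (and TIFF, when the tiff package is installed) 8-bit images,
#' normalized to [0,1]; grayscale is replicated to 3 channels and any alpha
#' channel is dropped.
#'
#' @param path image file.
#' @return H x W x 3 array in [0,1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such image: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_config("reading TIFF requires the tiff package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  img
}

#' Load a dataset directory written by \code{\link{write_dataset_png}}
#'
#' @param dir directory containing \code{manifest.tsv} and the class
#'   subdirectories of PNGs.
#' @return a \code{labeled_dataset}.
#' @export
load_dataset_dir <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop_data(paste0("no manifest.tsv under ", dir))
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  class_names <- unique(manifest$label)
  structure(list(
    images = lapply(manifest$path, function(p) read_image(file.path(dir, p))),
    labels = match(manifest$label, class_names),
    class_names = class_names,
    split = manifest$split,
    seed = NA_integer_), class = "labeled_dataset")
}
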