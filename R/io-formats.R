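#' Read an IDX image/label file pair
#'
#' Parses the big-endian IDX container used by the classic digit benchmarks
#' (magic `0x00 0x00 <type> <ndim>`, then `ndim` 32-bit dimensions, then the
#' data).  Only the unsigned-byte payload type (`0x08`) of that dialect is
#' supported; pixel bytes are scaled to `[0, 1]`.
#'
#' @param path_images path to the image file (ndim 3: n x H x W).
#' @param path_labels path to the label file (ndim 1).
#' @return an `image_dataset`: list with `images` (array n x H x W in
#'   `[0, 1]`), `labels` (integer, contiguous from 0) and `class_names`
#'   (`NULL` for IDX input).
#' @export
read_idx <- function(path_images, path_labels) {
  imgs <- read_idx_array(path_images, expected_ndim = 3L)
  labs <- read_idx_array(path_labels, expected_ndim = 1L)
  if (dim(imgs)[1] != length(labs)) {
    stop(sprintf("IDX consistency error: %d images but %d labels",
                 dim(imgs)[1], length(labs)), call. = FALSE)
  }
  new_image_dataset(imgs / 255, as.integer(labs))
}

read_idx_array <- function(path, expected_ndim) {
  if (!file.exists(path)) {
    stop(sprintf("IDX file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L) {
    stop("IDX format error: bad magic bytes", call. = FALSE)
  }
  type_code <- magic[3]
  ndim <- magic[4]
  if (type_code != 0x08) {
    stop(sprintf("IDX format error: unsupported type code 0x%02x", type_code),
         call. = FALSE)
  }
  if (ndim != expected_ndim) {
    stop(sprintf("IDX format error: expected %d dimensions, found %d",
                 expected_ndim, ndim), call. = FALSE)
  }
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims <= 0L)) {
    stop("IDX format error: truncated or invalid dimension header",
         call. = FALSE)
  }
  n_vals <- prod(dims)
  raw_vals <- readBin(con, "integer", n = n_vals, size = 1L, signed = FALSE)
  if (length(raw_vals) < n_vals) {
    stop("IDX format error: truncated data section", call. = FALSE)
  }
  if (ndim == 1L) {
    return(raw_vals)
  }
  # IDX stores row-major (last index fastest); map to an R array with the
  # sample index first.
  arr <- array(raw_vals, dim = rev(dims))      # (W, H, n) column-major
  aperm(arr, rev(seq_len(ndim)))               # (n, H, W)
}

#' Write an IDX image/label file pair
#'
#' Inverse of [read_idx()]; used to build small fixtures and to export
#' synthetic tasks in the benchmark's native container.  Values are clipped
#' to `[0, 1]` and stored as unsigned bytes.
#'
#' @param images array n x H x W with values in `[0, 1]`.
#' @param labels integer vector of length n.
#' @param path_images,path_labels output paths.
#' @return `invisible(NULL)`.
#' @export
write_idx <- function(images, labels, path_images, path_labels) {
  stopifnot(length(dim(images)) == 3L, dim(images)[1] == length(labels))
  bytes <- as.integer(round(pmin(1, pmax(0, images)) * 255))
  con <- file(path_images, "wb")
  writeBin(as.raw(c(0L, 0L, 0x08, 3L)), con)
  writeBin(as.integer(dim(images)), con, size = 4L, endian = "big")
  # back to row-major byte order
  writeBin(as.raw(aperm(array(bytes, dim(images)), c(3L, 2L, 1L))), con)
  close(con)
  con <- file(path_labels, "wb")
  writeBin(as.raw(c(0L, 0L, 0x08, 1L)), con)
  writeBin(length(labels), con, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  close(con)
  invisible(NULL)
}

new_image_dataset <- function(images, labels, class_names = NULL) {
  stopifnot(length(dim(images)) == 3L, dim(images)[1] == length(labels))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset> %d images %dx%d, %d classes\n",
              d[1], d[2], d[3], length(unique(x$labels))))
  invisible(x)
}

#' Read an image-folder dataset (alphabet/character layout)
#'
#' Every leaf directory that contains PNG files becomes one class, in sorted
#' path order, with contiguous ids from 0.  Images are converted to a single
#' channel, resized to `image_size` by area resampling, and oriented so the
#' strokes (foreground) are the high-valued pixels: if the image border is
#' brighter than the interior the image is inverted.
#'
#' @param root dataset root directory.
#' @param image_size output side length in pixels.
#' @return an `image_dataset` with `class_names` set to the leaf paths.
#' @export
read_image_folder <- function(root, image_size = 28L) {
  image_size <- check_count(image_size, "image_size")
  if (!dir.exists(root)) {
    stop(sprintf("image folder not found: %s", root), call. = FALSE)
  }
  files <- list.files(root, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("image folder format error: no PNG files under %s", root),
         call. = FALSE)
  }
  leaves <- sort(unique(dirname(files)))
  images <- array(0, dim = c(length(files), image_size, image_size))
  labels <- integer(length(files))
  idx <- 1L
  for (li in seq_along(leaves)) {
    for (f in sort(files[dirname(files) == leaves[li]])) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) {
        img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                     c(1L, 2L), mean)
      }
      border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
      if (mean(border) > mean(img)) img <- 1 - img  # foreground high
      images[idx, , ] <- resample_area(img, image_size)
      labels[idx] <- li - 1L
      idx <- idx + 1L
    }
  }
  rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root), "/?"),
             "", leaves)
  new_image_dataset(images, labels, class_names = rel)
}

# Area-overlap resampling of a single matrix to size out x out.  Each output
# pixel is the average of the input over its footprint, with fractional
# overlap weights; exact area-mean pooling when sizes divide.
resample_area <- function(img, out_size) {
  l_r <- overlap_weights(nrow(img), out_size)
  l_c <- overlap_weights(ncol(img), out_size)
  l_r %*% img %*% t(l_c)
}

overlap_weights <- function(n_in, n_out) {
  # weight[o, i] = |[ (o-1), o ) * n_in/n_out  intersect  [ (i-1), i ) | * n_out/n_in
  lo <- (seq_len(n_out) - 1) * n_in / n_out
  hi <- seq_len(n_out) * n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    i0 <- floor(lo[o]) + 1
    i1 <- ceiling(hi[o])
    for (i in i0:min(i1, n_in)) {
      ov <- min(hi[o], i) - max(lo[o], i - 1)
      if (ov > 0) w[o, i] <- ov
    }
  }
  w / (n_in / n_out)
}

#' Downsample images by area-mean pooling
#'
#' Reduces each image to `out_size` x `out_size` by averaging over the area
#' each output pixel covers (exact block means when the sizes divide, e.g.
#' 28 to 14; fractional-overlap weights otherwise, e.g. the 28-to-10
#' reduction used for the digit benchmark).  Values stay in `[0, 1]` and a
#' constant image stays constant.
#'
#' @param images array n x H x W, or a single H x W matrix.
#' @param out_size output side length; must not exceed the input size.
#' @return same structure as the input, resized.
#' @export
downsample <- function(images, out_size) {
  out_size <- check_count(out_size, "out_size")
  single <- is.matrix(images)
  if (single) images <- array(images, dim = c(1L, dim(images)))
  d <- dim(images)
  if (out_size > d[2] || out_size > d[3]) {
    stop("`out_size` must not exceed the input image size", call. = FALSE)
  }
  l_r <- overlap_weights(d[2], out_size)
  l_c <- overlap_weights(d[3], out_size)
  out <- array(0, dim = c(d[1], out_size, out_size))
  for (i in seq_len(d[1])) {
    out[i, , ] <- l_r %*% images[i, , ] %*% t(l_c)
  }
  if (single) out[1, , ] else out
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_FORMAT <- "neuromod-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Versioned container holding a model-kind tag and every array of model
#' state (including non-gradient state such as traces and activity factors).
#' Serialization is uncompressed so that save -> load -> save round-trips
#' byte-identically.
#'
#' @param object any package model object (ModNet state, plastic readout,
#'   few-shot model, ...).
#' @param path output file.
#' @param kind model kind tag; defaults to the object's class.
#' @param seed optional RNG seed to record.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, kind = class(object)[1],
                            seed = NULL) {
  payload <- list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
                  kind = kind, seed = seed, state = object)
  saveRDS(payload, path, compress = FALSE, version = 3L)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return the stored object, with attributes `kind` and `seed` available in
#'   the returned list's wrapper: a list with `state`, `kind`, `seed`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  }
  payload <- readRDS(path)
  if (!identical(payload$format, CHECKPOINT_FORMAT)) {
    stop("not a neuromod checkpoint", call. = FALSE)
  }
  if (payload$version > CHECKPOINT_VERSION) {
    stop(sprintf("checkpoint version %d is newer than supported (%d)",
                 payload$version, CHECKPOINT_VERSION), call. = FALSE)
  }
  payload[c("state", "kind", "seed")]
}
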