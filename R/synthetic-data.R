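#' Generate a multi-class Gaussian vector task
#'
#' Draws `n_classes` class means in a simplex-like arrangement (mutually
#' equidistant directions, pairwise distance equal to `separation`) and
#' samples isotropic Gaussian observations around them.  With
#' `separation = 0` the labels carry no signal; with separation well above
#' `noise_sd` the task is almost perfectly separable, emulating the easy
#' regime of the digit benchmarks the shallow modulatory network is meant
#' for.
#'
#' @param n_classes number of classes (>= 2).
#' @param dims feature dimensionality.
#' @param n_per_class samples drawn per class.
#' @param separation pairwise Euclidean distance between class means (>= 0).
#' @param noise_sd standard deviation of the isotropic noise (> 0).
#' @param seed integer seed; the same seed reproduces the task bit for bit.
#' @return an object of class `vector_task` with fields `features`
#'   (matrix, samples x dims), `labels` (integer class ids in `0:(C-1)`),
#'   `class_means` (C x dims), `noise_sd` and `separation`.
#' @examples
#' task <- make_vector_task(3, 10, 20, separation = 4, noise_sd = 1, seed = 1)
#' table(task$labels)
#' @export
make_vector_task <- function(n_classes, dims, n_per_class,
                             separation = 4, noise_sd = 1, seed = 1) {
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  dims <- check_count(dims, "dims", min = 1L)
  n_per_class <- check_count(n_per_class, "n_per_class", min = 1L)
  separation <- check_scalar(separation, "separation", min = 0)
  noise_sd <- check_scalar(noise_sd, "noise_sd", min = 0, strict = TRUE)

  with_seed(seed, {
    # Orthonormal directions scaled by separation/sqrt(2) are mutually
    # equidistant at exactly `separation` (vertices of a regular simplex up
    # to translation).  When dims < n_classes fall back to random unit
    # directions, which are approximately equidistant in high dimension.
    if (dims >= n_classes) {
      g <- matrix(rnorm(dims * n_classes), dims, n_classes)
      q <- qr.Q(qr(g))[, seq_len(n_classes), drop = FALSE]
      means <- t(q) * separation / sqrt(2)
    } else {
      g <- matrix(rnorm(n_classes * dims), n_classes, dims)
      means <- g / sqrt(rowSums(g^2)) * separation / sqrt(2)
    }
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    n <- length(labels)
    feats <- means[labels + 1L, , drop = FALSE] +
      matrix(rnorm(n * dims, sd = noise_sd), n, dims)
    structure(
      list(features = feats, labels = labels, class_means = means,
           noise_sd = noise_sd, separation = separation),
      class = "vector_task"
    )
  })
}

#' @export
print.vector_task <- function(x, ...) {
  cat(sprintf(
    "<vector_task> %d samples, %d dims, %d classes, separation %.3g, noise sd %.3g\n",
    nrow(x$features), ncol(x$features), nrow(x$class_means),
    x$separation, x$noise_sd))
  invisible(x)
}

#' Draw a fresh sample set from an existing vector task
#'
#' Generates new observations from the same class means and noise level —
#' a held-out test set for the task's distribution.
#'
#' @param task a `vector_task`.
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @return a `vector_task` sharing the parent's `class_means`.
#' @export
sample_vector_task <- function(task, n_per_class, seed = 1) {
  stopifnot(inherits(task, "vector_task"))
  n_per_class <- check_count(n_per_class, "n_per_class")
  with_seed(seed, {
    n_classes <- nrow(task$class_means)
    dims <- ncol(task$class_means)
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    n <- length(labels)
    feats <- task$class_means[labels + 1L, , drop = FALSE] +
      matrix(rnorm(n * dims, sd = task$noise_sd), n, dims)
    structure(
      list(features = feats, labels = labels,
           class_means = task$class_means,
           noise_sd = task$noise_sd, separation = task$separation),
      class = "vector_task"
    )
  })
}

#' Nearest-class-mean classification accuracy
#'
#' Classifies each row of `features` to the closest class mean and returns
#' the accuracy.  Used as the simple Bayes-like reference for
#' [make_vector_task()] tasks.
#'
#' @param task a `vector_task`.
#' @param features,labels optional held-out data; defaults to the task's own.
#' @return accuracy in `[0, 1]`.
#' @export
nearest_mean_accuracy <- function(task, features = task$features,
                                  labels = task$labels) {
  stopifnot(inherits(task, "vector_task"))
  m <- task$class_means
  # squared distances via ||x||^2 - 2 x.m + ||m||^2; the ||x||^2 term is
  # constant per row and can be dropped.
  d <- -2 * features %*% t(m)
  d <- sweep(d, 2L, rowSums(m^2), "+")
  pred <- max.col(-d, ties.method = "first") - 1L
  mean(pred == labels)
}

# ---- procedural glyphs ------------------------------------------------------

# Points along a quadratic Bezier with control points p0, p1, p2 (each length-2).
bezier_points <- function(p0, p1, p2, n = 40L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

# Rasterize a set of stroke polylines (unit-square coordinates) onto an
# image_size x image_size grid with a soft-edged pen of radius `thickness`.
render_strokes <- function(strokes, image_size, thickness,
                           rotation = 0, translation = c(0, 0)) {
  pts <- do.call(rbind, strokes)
  if (rotation != 0) {
    cs <- cos(rotation); sn <- sin(rotation)
    centered <- sweep(pts, 2L, c(0.5, 0.5))
    pts <- cbind(centered[, 1] * cs - centered[, 2] * sn,
                 centered[, 1] * sn + centered[, 2] * cs)
    pts <- sweep(pts, 2L, c(0.5, 0.5), "+")
  }
  pts <- sweep(pts, 2L, translation, "+")
  centers <- (seq_len(image_size) - 0.5) / image_size
  # squared distance from every pixel centre to every stroke point
  dx2 <- outer(centers, pts[, 1], "-")^2  # image_size x npts (x = columns)
  dy2 <- outer(centers, pts[, 2], "-")^2  # (y = rows)
  img <- matrix(0, image_size, image_size)
  edge <- 0.75 / image_size  # antialiasing band of ~0.75 px
  for (col in seq_len(image_size)) {
    d2 <- sweep(dy2, 2L, dx2[col, ], "+")
    d <- sqrt(do.call(pmin, as.data.frame(d2)))
    img[, col] <- pmin(1, pmax(0, 1 - (d - thickness) / edge))
  }
  img
}

#' Generate a bank of procedural glyph classes
#'
#' Emulates the class/sample structure of handwritten-character corpora such
#' as Omniglot (many classes, a handful of samples each) without any
#' download.  Each class is a prototype of 2-5 random quadratic strokes;
#' samples are jittered variants of the prototype (rotation up to 10
#' degrees, translation up to 2 px, and up to 1% per-pixel flips).
#'
#' @param n_classes number of glyph classes (>= 5 so 5-way episodes exist).
#' @param samples_per_class jittered samples rendered per class (default 20,
#'   the per-class count of the handwritten-character benchmark emulated).
#' @param image_size side of the square single-channel images (default 28).
#' @param seed integer seed; reproducible bit for bit.
#' @return an object of class `glyph_bank` with fields `images` (array
#'   n x H x W, values in `[0, 1]`), `labels` (integer ids in `0:(C-1)`),
#'   `n_classes`, `samples_per_class`, `image_size`, and `renderer_params`
#'   (per-class stroke definitions).
#' @examples
#' bank <- make_glyph_bank(5, samples_per_class = 2, image_size = 28, seed = 1)
#' dim(bank$images)
#' @export
make_glyph_bank <- function(n_classes, samples_per_class = 20L,
                            image_size = 28L, seed = 1) {
  n_classes <- check_count(n_classes, "n_classes", min = 5L)
  samples_per_class <- check_count(samples_per_class, "samples_per_class")
  image_size <- check_count(image_size, "image_size", min = 1L)
  if (image_size < 8L) {
    stop("`image_size` must be at least 8 pixels", call. = FALSE)
  }

  with_seed(seed, {
    params <- vector("list", n_classes)
    n_total <- n_classes * samples_per_class
    images <- array(0, dim = c(n_total, image_size, image_size))
    labels <- integer(n_total)
    idx <- 1L
    for (cls in seq_len(n_classes)) {
      n_strokes <- sample(2:5, 1L)
      strokes <- replicate(n_strokes, {
        p <- matrix(runif(6, 0.12, 0.88), 3, 2)
        bezier_points(p[1, ], p[2, ], p[3, ])
      }, simplify = FALSE)
      thickness <- runif(1, 0.035, 0.06)
      params[[cls]] <- list(n_strokes = n_strokes, strokes = strokes,
                            thickness = thickness)
      for (s in seq_len(samples_per_class)) {
        if (s == 1L) {
          rot <- 0; tr <- c(0, 0)  # first sample is the clean prototype
        } else {
          rot <- runif(1, -10, 10) * pi / 180
          tr <- runif(2, -2, 2) / image_size
        }
        img <- render_strokes(strokes, image_size, thickness, rot, tr)
        if (s > 1L) {
          flip <- matrix(rbinom(image_size^2, 1L, 0.01) == 1L,
                         image_size, image_size)
          img[flip] <- 1 - img[flip]
        }
        images[idx, , ] <- img
        labels[idx] <- cls - 1L
        idx <- idx + 1L
      }
    }
    structure(
      list(images = images, labels = labels, n_classes = n_classes,
           samples_per_class = samples_per_class, image_size = image_size,
           renderer_params = params),
      class = "glyph_bank"
    )
  })
}

#' @export
print.glyph_bank <- function(x, ...) {
  cat(sprintf("<glyph_bank> %d classes x %d samples, %dx%d images\n",
              x$n_classes, x$samples_per_class, x$image_size, x$image_size))
  invisible(x)
}

#' Write a vector task as delimited text
#'
#' Tab-separated file with the label in the first column and the features in
#' the remaining columns; a `# class_means` comment block records the
#' generating means.
#'
#' @param task a `vector_task`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vector_task <- function(task, path) {
  stopifnot(inherits(task, "vector_task"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vector_task noise_sd=%.17g separation=%.17g",
                     task$noise_sd, task$separation), con)
  writeLines(paste0("# mean\t", apply(task$class_means, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })), con)
  df <- cbind(task$labels, task$features)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a vector task written by [write_vector_task()]
#' @param path file path.
#' @return a `vector_task`.
#' @export
read_vector_task <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- strsplit(sub("^# vector_task ", "", hdr[1]), " ")[[1]]
  meta <- setNames(
    as.numeric(sub("^[a-z_]+=", "", meta)),
    sub("=.*$", "", meta)
  )
  mean_lines <- sub("^# mean\t", "", hdr[startsWith(hdr, "# mean\t")])
  means <- do.call(rbind, lapply(strsplit(mean_lines, "\t"), as.numeric))
  body <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  structure(
    list(features = as.matrix(body[, -1, drop = FALSE]),
         labels = as.integer(body[[1]]),
         class_means = means,
         noise_sd = unname(meta[["noise_sd"]]),
         separation = unname(meta[["separation"]])),
    class = "vector_task"
  )
}

#' Export a glyph bank as an image-folder tree
#'
#' Writes PNG files in the alphabet/character layout consumed by
#' [read_image_folder()]: classes are grouped into pseudo-alphabets of up to
#' 20 characters, one leaf folder per class, one greyscale PNG per sample.
#'
#' @param bank a `glyph_bank`.
#' @param root output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_glyph_folder <- function(bank, root) {
  stopifnot(inherits(bank, "glyph_bank"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (cls in seq_len(bank$n_classes) - 1L) {
    alphabet <- sprintf("alphabet%03d", cls %/% 20L)
    leaf <- file.path(root, alphabet, sprintf("character%04d", cls))
    dir.create(leaf, recursive = TRUE, showWarnings = FALSE)
    rows <- which(bank$labels == cls)
    for (k in seq_along(rows)) {
      img <- bank$images[rows[k], , ]
      png::writePNG(img, file.path(leaf, sprintf("sample%03d.png", k)))
    }
  }
  invisible(root)
}
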