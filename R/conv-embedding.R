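#' Convolutional embedding configuration
#'
#' The standard few-shot baseline embedding: a stack of modules, each a 3x3
#' same-padding convolution followed by batch normalization (batch
#' statistics, no learnable affine), ReLU, and 2x2 max pooling.  With the
#' default four modules a 28x28 input reduces to a 1x1 feature map, i.e. a
#' `filters`-length feature vector.
#'
#' @param n_modules number of conv modules (default 4).
#' @param filters filters per convolution (default 64).
#' @param input_size input image side (default 28).
#' @param in_channels input channels (default 1).
#' @return a `conv_config`.
#' @export
conv_config <- function(n_modules = 4L, filters = 64L, input_size = 28L,
                        in_channels = 1L) {
  n_modules <- check_count(n_modules, "n_modules")
  filters <- check_count(filters, "filters")
  input_size <- check_count(input_size, "input_size")
  sz <- input_size
  for (m in seq_len(n_modules)) sz <- sz %/% 2L
  if (sz < 1L) {
    stop("input too small: the pooled feature map vanishes", call. = FALSE)
  }
  structure(list(n_modules = n_modules, filters = filters,
                 input_size = input_size, in_channels = in_channels,
                 out_size = sz),
            class = "conv_config")
}

# Spatial side length after module m.
conv_sizes <- function(config) {
  sz <- config$input_size
  sizes <- integer(config$n_modules + 1L)
  sizes[1] <- sz
  for (m in seq_len(config$n_modules)) {
    sizes[m + 1L] <- sizes[m] %/% 2L
  }
  sizes
}

#' Initialize convolution weights
#'
#' Kaiming-uniform weights (`U(-sqrt(6/fan_in), +sqrt(6/fan_in))`) and zero
#' biases for each module.
#'
#' @param config a [conv_config()].
#' @param seed integer seed.
#' @return list of modules, each with `W` ((9*C_in) x filters) and `b`.
#' @export
conv_init <- function(config, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(config$n_modules), function(m) {
      c_in <- if (m == 1L) config$in_channels else config$filters
      fan_in <- 9L * c_in
      lim <- sqrt(6 / fan_in)
      list(W = matrix(runif(fan_in * config$filters, -lim, lim),
                      fan_in, config$filters),
           b = numeric(config$filters))
    })
  })
}

# Forward pass through all modules.  `X` is (H*W*C) x B.  Returns the
# feature matrix (filters x B, from the 1x1 map when out_size == 1) and the
# caches needed for the backward pass.
conv_forward <- function(params, X, config) {
  sizes <- conv_sizes(config)
  caches <- vector("list", config$n_modules)
  cur <- X
  for (m in seq_len(config$n_modules)) {
    h <- sizes[m]
    c_in <- if (m == 1L) config$in_channels else config$filters
    cv <- cpp_conv3x3_forward(cur, params[[m]]$W, params[[m]]$b, h, h, c_in)
    bn <- cpp_bn_relu_forward(cv$out, config$filters, 1e-5)
    pl <- cpp_maxpool2_forward(bn$out, h, h, config$filters)
    caches[[m]] <- list(cols = cv$cols, ynorm = bn$ynorm,
                        invstd = bn$invstd, idx = pl$idx,
                        in_rows = nrow(bn$out), h = h, c_in = c_in)
    cur <- pl$out
  }
  list(features = cur, caches = caches)
}

# Backward pass: dFeat is (out_rows x B); returns per-module gradients and
# (optionally) the gradient w.r.t. the input.
conv_backward <- function(params, caches, dFeat, config, need_dx = FALSE) {
  grads <- vector("list", config$n_modules)
  cur <- dFeat
  for (m in rev(seq_len(config$n_modules))) {
    ca <- caches[[m]]
    d_bn <- cpp_maxpool2_backward(cur, ca$idx, ca$in_rows)
    d_cv <- cpp_bn_relu_backward(d_bn, ca$ynorm, ca$invstd, config$filters)
    bk <- cpp_conv3x3_backward(d_cv, ca$cols, params[[m]]$W,
                               ca$h, ca$h, ca$c_in, config$filters)
    grads[[m]] <- list(W = bk$dW, b = bk$db)
    if (m > 1L || need_dx) cur <- bk$dX
  }
  list(grads = grads, dX = if (need_dx) cur)
}

# Flatten an image array (n x H x W) to the (H*W) x n activation layout.
images_to_batch <- function(images) {
  d <- dim(images)
  t(matrix(images, d[1], d[2] * d[3]))
}
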