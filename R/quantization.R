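#' Fixed-point format descriptor
#'
#' Signed fixed-point with `total_bits` bits of which `frac_bits` are
#' fractional (the default Q6.10: 16 bits, 6-bit signed integer part
#' including the sign, 10-bit fraction; representable range
#' about [-32, 32 - 2^-10] in steps of 2^-10).  Multiply-accumulate is
#' carried in `accumulator_bits`-bit partial sums which are then rounded
#' back to the storage format.  Rounding is to nearest, ties away from
#' zero; out-of-range values saturate.
#'
#' @param total_bits storage width (default 16).
#' @param frac_bits fractional bits (default 10).
#' @param accumulator_bits accumulator width (default 32).
#' @return a `qformat`.
#' @export
qformat <- function(total_bits = 16L, frac_bits = 10L,
                    accumulator_bits = 32L) {
  total_bits <- check_count(total_bits, "total_bits", min = 2L)
  frac_bits <- check_count(frac_bits, "frac_bits", min = 0L)
  if (frac_bits >= total_bits) {
    stop("`frac_bits` must be smaller than `total_bits`", call. = FALSE)
  }
  structure(list(
    total_bits = total_bits, frac_bits = frac_bits,
    int_bits = total_bits - frac_bits,
    accumulator_bits = check_count(accumulator_bits, "accumulator_bits"),
    scale = 2^frac_bits,
    q_min = -2^(total_bits - 1L), q_max = 2^(total_bits - 1L) - 1
  ), class = "qformat")
}

#' @export
print.qformat <- function(x, ...) {
  cat(sprintf("<qformat> Q%d.%d (%d bits, %d-bit accumulator), range [%g, %g]\n",
              x$int_bits, x$frac_bits, x$total_bits, x$accumulator_bits,
              x$q_min / x$scale, x$q_max / x$scale))
  invisible(x)
}

# Round to nearest integer, ties away from zero (R's round() rounds ties
# to even, which is not the fixed-point convention emulated here).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert real values to their fixed-point integer representation
#' @param x numeric.
#' @param fmt a [qformat()].
#' @return integer-valued numeric (exact within the accumulator width).
#' @export
to_fixed <- function(x, fmt) {
  pmin(pmax(round_half_away(x * fmt$scale), fmt$q_min), fmt$q_max)
}

#' Quantize real values to a fixed-point grid
#'
#' `round(x * 2^frac) / 2^frac`, saturated to the representable range.
#' Idempotent; the round-trip error for in-range values is at most half a
#' step (`2^-(frac_bits+1)`).
#'
#' @inheritParams to_fixed
#' @return numeric on the fixed-point grid.
#' @export
quantize <- function(x, fmt) {
  to_fixed(x, fmt) / fmt$scale
}

#' Piecewise-linear tanh approximation
#'
#' Four-segment odd function:
#' 1 for `|x| >= 3`; `0.06|x| + 0.815` for `1.5 <= |x| < 3`;
#' `0.443|x| + 0.24` for `0.5 <= |x| < 1.5`; `0.924|x|` otherwise — negated
#' for negative `x`.  Maximum deviation from tanh is below 0.09 on
#' `[-4, 4]`.
#'
#' @param x numeric.
#' @return the approximation, in `[-1, 1]`.
#' @export
pla_tanh <- function(x) {
  a <- abs(x)
  y <- ifelse(a >= 3, 1,
              ifelse(a >= 1.5, 0.06 * a + 0.815,
                     ifelse(a >= 0.5, 0.443 * a + 0.24, 0.924 * a)))
  sign(x) * y
}

# Logistic sigmoid computed through the PLA tanh identity
# sigmoid(x) = (1 + tanh(x/2)) / 2, as used on the quantized path.
pla_sigmoid <- function(x) (1 + pla_tanh(x / 2)) / 2

#' Fixed-point matrix-vector product
#'
#' Multiplies fixed-point representations of `W` and `x` in integer
#' arithmetic, accumulates in the (wider) accumulator width with
#' saturation, and rounds the result back to the storage format.
#'
#' @param W weight matrix (real values; quantized internally).
#' @param x input vector or matrix of columns (real values; quantized
#'   internally).
#' @param fmt a [qformat()].
#' @return the product on the fixed-point grid (real values).
#' @export
quantized_matmul <- function(W, x, fmt) {
  qw <- to_fixed(W, fmt)
  qx <- to_fixed(x, fmt)
  if (fmt$accumulator_bits <= 53L) {
    # integer partial sums are exact in doubles up to 2^53
    acc <- qw %*% qx
    acc_max <- 2^(fmt$accumulator_bits - 1L) - 1
    acc <- pmin(pmax(acc, -acc_max - 1), acc_max)
    out <- acc / fmt$scale^2
  } else {
    # accumulators wider than a double's exact-integer range: accumulate
    # the dequantized products in floating point (no saturation)
    out <- (qw / fmt$scale) %*% (qx / fmt$scale)
  }
  quantize(out, fmt)
}

#' Fixed-point inference for a trained ModNet
#'
#' Runs the forward pass with weights and activations on the fixed-point
#' grid: integer matrix products with wide accumulation, sigmoid
#' activations computed through the piecewise-linear tanh, and per-layer
#' outputs rounded back to the storage format.  The output layer can be
#' kept in floating point (`keep_output_float = TRUE`), the configuration
#' that preserves full-precision accuracy.
#'
#' @param state a trained `modnet_state`.
#' @param dataset features/labels (types as in [modnet_train()]).
#' @param fmt a [qformat()].
#' @param keep_output_float leave the output layer unquantized (default
#'   `TRUE`).
#' @return list with `accuracy`, `predictions`, and
#'   `weight_quantization_error` (mean relative quantization error of the
#'   weight vectors, per layer).
#' @export
quantized_inference <- function(state, dataset, fmt,
                                keep_output_float = TRUE) {
  stopifnot(inherits(fmt, "qformat"))
  data <- as_feature_data(dataset)
  layers <- list(W_proj = state$W_proj, W = state$W)
  qerr <- vapply(layers, function(W) {
    qe <- quantize(W, fmt) - W
    sqrt(sum(qe^2)) / max(sqrt(sum(W^2)), .Machine$double.eps)
  }, numeric(1))
  if (all(quantize(state$W, fmt) == 0) && any(state$W != 0)) {
    stop("format too narrow: all output weights quantize to zero",
         call. = FALSE)
  }

  X <- t(data$features)                          # n_in x n
  pre_h <- quantized_matmul(state$W_proj, quantize(X, fmt), fmt)
  hidden <- quantize(pla_sigmoid(pre_h), fmt)
  if (keep_output_float) {
    out <- sigmoid(state$W %*% hidden)
  } else {
    pre_o <- quantized_matmul(state$W, hidden, fmt)
    out <- quantize(pla_sigmoid(pre_o), fmt)
  }
  pred <- max.col(t(out), ties.method = "first") - 1L
  list(accuracy = mean(pred == data$labels), predictions = pred,
       weight_quantization_error = qerr)
}

#' Accuracy across storage bit widths
#'
#' Evaluates [quantized_inference()] for each total bit width in
#' `bit_list`, holding the integer part at 6 bits (so the fractional
#' precision grows with the width) and keeping the output layer in
#' floating point.
#'
#' @param state a trained `modnet_state`.
#' @param dataset features/labels.
#' @param bit_list integer vector of storage widths (> 6).
#' @param int_bits integer bits to hold fixed (default 6).
#' @return data frame with `bits`, `frac_bits`, `accuracy`.
#' @export
precision_sweep <- function(state, dataset, bit_list = c(8L, 10L, 12L, 14L, 16L),
                            int_bits = 6L) {
  if (length(bit_list) == 0L || any(bit_list <= int_bits)) {
    stop(sprintf("every bit width must exceed int_bits = %d", int_bits),
         call. = FALSE)
  }
  rows <- lapply(sort(as.integer(bit_list)), function(b) {
    fmt <- qformat(total_bits = b, frac_bits = b - int_bits)
    res <- quantized_inference(state, dataset, fmt,
                               keep_output_float = TRUE)
    data.frame(bits = b, frac_bits = b - int_bits,
               accuracy = res$accuracy)
  })
  do.call(rbind, rows)
}
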