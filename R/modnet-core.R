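#' ModNet configuration
#'
#' Hyperparameters of the shallow modulatory network: a fixed random
#' projection lifts the input into a high-dimensional hidden layer (the
#' Kenyon-cell expansion), the hidden-to-output weights are trained by an
#' adaptive Hebbian rule, and a modulatory layer fed with the output error
#' gates the magnitude of every weight update (the dopaminergic gate on the
#' mushroom-body output synapses).
#'
#' The per-synapse update is
#' `dw_ij = sigmoid(M_i / n_scale) * delta_ij` with plasticity term
#' `delta_ij = eta_ij * (beta1*x_i*x_j + beta2*(x_j - x_i) + beta3)`,
#' where `x_j` is the hidden (presynaptic) and `x_i` the output
#' (postsynaptic) activation, `M_i` the modulatory activation, and `eta_ij`
#' an adaptive learning rate driven by the output error (see
#' [adapt_learning_rate()]).
#'
#' @param n_in,n_out input and output layer sizes.
#' @param n_hidden hidden layer size (default 1000).
#' @param beta1,beta2,beta3 correlation, difference and bias coefficients of
#'   the plasticity term (defaults 0.1, 0.2, 0.001).
#' @param eta_in initial/adaptive learning-rate scale, in `[0.001, 0.01]`
#'   (default 0.01).
#' @param n_scale global divisor applied to the modulatory activation before
#'   the sigmoid magnitude gate; flattens the gate's dynamic range
#'   (default 10).
#' @param mod_scale tunable magnitude of the modulatory-weight update.
#' @param mod_eta_in learning-rate scale of the modulatory weights
#'   (default 0.001, the low end of the adaptive-rate range, so the
#'   modulatory weights evolve slowly relative to the standard weights).
#' @param eta_clip bound on the magnitude of the adaptive rate (default
#'   `10 * eta_in`); the divisive rate rule is singular near zero error or
#'   activation and is clipped here.
#' @param projection_density fraction of nonzero entries in the fixed random
#'   projection (1 = dense).
#' @param epochs training epochs (default 2).
#' @param rate_form functional form of the adaptive rate: `"inverse"`
#'   (`eta_in / (e_i * x_i)`, both error and activation divisive; the
#'   default) or `"ratio"` (`eta_in * e_i / x_i`).
#' @param polarity polarity rule for the adaptive rate: `"error"` (default)
#'   keeps the sign inherited from the error term; `"diff_weight"`
#'   replaces it with `sign(x_j - x_i) * sign(w_ij)` per synapse.  The
#'   latter reading destabilizes learning (see the methods vignette) and is
#'   kept only for comparison.
#' @param seed seed for weight initialization.
#' @return a `modnet_config` list.
#' @export
modnet_config <- function(n_in, n_out, n_hidden = 1000L,
                          beta1 = 0.1, beta2 = 0.2, beta3 = 0.001,
                          eta_in = 0.01, n_scale = 10, mod_scale = 1,
                          mod_eta_in = 0.001, eta_clip = 10 * eta_in,
                          projection_density = 1, epochs = 2L,
                          rate_form = c("inverse", "ratio"),
                          polarity = c("error", "diff_weight"),
                          seed = 1L) {
  cfg <- list(
    n_in = check_count(n_in, "n_in"),
    n_out = check_count(n_out, "n_out"),
    n_hidden = check_count(n_hidden, "n_hidden"),
    beta1 = check_scalar(beta1, "beta1"),
    beta2 = check_scalar(beta2, "beta2"),
    beta3 = check_scalar(beta3, "beta3"),
    eta_in = check_scalar(eta_in, "eta_in", min = 0, strict = TRUE),
    n_scale = check_scalar(n_scale, "n_scale", min = 0, strict = TRUE),
    mod_scale = check_scalar(mod_scale, "mod_scale", min = 0, strict = TRUE),
    mod_eta_in = check_scalar(mod_eta_in, "mod_eta_in", min = 0, strict = TRUE),
    eta_clip = check_scalar(eta_clip, "eta_clip", min = 0, strict = TRUE),
    projection_density = check_scalar(projection_density,
                                      "projection_density", min = 0,
                                      strict = TRUE),
    epochs = check_count(epochs, "epochs"),
    rate_form = match.arg(rate_form),
    polarity = match.arg(polarity),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$projection_density > 1) stop("`projection_density` must be <= 1",
                                       call. = FALSE)
  if (cfg$n_hidden < cfg$n_out) stop("`n_hidden` must be >= `n_out`",
                                     call. = FALSE)
  structure(cfg, class = "modnet_config")
}

#' Initialize ModNet state
#'
#' The input-to-hidden projection is fixed sparse random (uniform on
#' `[-1, 1]`, density `projection_density`) and is never trained; the
#' hidden-to-output and modulatory weights start uniform on `[-0.1, 0.1]`;
#' the adaptive rates start at their initial scales.
#'
#' @param config a [modnet_config()].
#' @return a `modnet_state` with fields `W_proj`, `W`, `W_mod`, `eta`,
#'   `mod_eta`, and `config`.
#' @export
modnet_init <- function(config) {
  stopifnot(inherits(config, "modnet_config"))
  with_seed(config$seed, {
    W_proj <- matrix(runif(config$n_hidden * config$n_in, -1, 1),
                     config$n_hidden, config$n_in)
    if (config$projection_density < 1) {
      mask <- matrix(runif(length(W_proj)) < config$projection_density,
                     nrow(W_proj), ncol(W_proj))
      W_proj <- W_proj * mask
    }
    W <- matrix(runif(config$n_out * config$n_hidden, -0.1, 0.1),
                config$n_out, config$n_hidden)
    W_mod <- matrix(runif(config$n_out * config$n_out, -0.1, 0.1),
                    config$n_out, config$n_out)
    structure(
      list(W_proj = W_proj, W = W, W_mod = W_mod,
           eta = matrix(config$eta_in, config$n_out, config$n_hidden),
           mod_eta = matrix(config$mod_eta_in, config$n_out, config$n_out),
           config = config),
      class = "modnet_state"
    )
  })
}

#' @export
print.modnet_state <- function(x, ...) {
  cat(sprintf("<modnet_state> %d -> %d -> %d\n", x$config$n_in,
              x$config$n_hidden, x$config$n_out))
  invisible(x)
}

#' ModNet forward pass
#'
#' `hidden = sigmoid(W_proj %*% input)`;
#' `output_i = sigmoid(sum_j w_ij * hidden_j)`.
#'
#' @param state a `modnet_state`.
#' @param input numeric vector of length `n_in`.
#' @return list with `hidden` and `output`, both in `(0, 1)`.
#' @export
modnet_forward <- function(state, input) {
  if (length(input) != state$config$n_in) {
    stop(sprintf("input length %d != n_in %d", length(input),
                 state$config$n_in), call. = FALSE)
  }
  hidden <- sigmoid(drop(state$W_proj %*% input))
  output <- sigmoid(drop(state$W %*% hidden))
  list(hidden = hidden, output = output)
}

#' Modulatory activation
#'
#' `M_i = sum_j w'_ij e_j`: the modulatory layer reads the output error
#' (one-hot label minus output activation) through the modulatory weights.
#' Unbounded real values.
#'
#' @param state a `modnet_state`.
#' @param error numeric vector of length `n_out`.
#' @return numeric vector `M` of length `n_out`.
#' @export
modulatory_activation <- function(state, error) {
  drop(state$W_mod %*% error)
}

#' Plasticity (direction) term of the weight update
#'
#' `delta_ij = eta_ij * (beta1*x_i*x_j + beta2*(x_j - x_i) + beta3)` with
#' `x_i` the output (postsynaptic) and `x_j` the hidden (presynaptic)
#' activation; the constant `beta3` lets a synapse change even with no pre-
#' or postsynaptic activity.
#'
#' @param state a `modnet_state` (its `eta` supplies `eta_ij`).
#' @param hidden hidden activations (length `n_hidden`).
#' @param output output activations (length `n_out`).
#' @param config a [modnet_config()].
#' @return matrix `n_out x n_hidden`.
#' @export
plasticity_term <- function(state, hidden, output, config = state$config) {
  hebb <- config$beta1 * outer(output, hidden) +
    config$beta2 * outer(-output, hidden, "+") + config$beta3
  state$eta * hebb
}

#' Adapt the learning rates from the output error
#'
#' The standard-path rate is error-driven with the output activation as a
#' divisive factor: `eta_i = eta_in * e_i / x_i` (form `"ratio"`), or the
#' fully divisive `eta_in / (e_i * x_i)` (form `"inverse"`).  When `e_i` or
#' `x_i` is 0 the rate is reset to `eta_in`; magnitudes are clipped to
#' `eta_clip` since the quotient is singular near zero.  Under the
#' `"diff_weight"` polarity rule the sign is replaced by
#' `sign(x_j - x_i) * sign(w_ij)` per synapse (with `sign(0) = +1`).  The
#' modulatory-path rates use the same quotient with the error and
#' activation exchanged, signed by the error.
#'
#' @param state a `modnet_state`.
#' @param error output error vector.
#' @param output output activation vector.
#' @param config a [modnet_config()].
#' @param hidden hidden activation vector; needed only for the
#'   `"diff_weight"` polarity rule.
#' @return the state with `eta` and `mod_eta` updated.
#' @export
adapt_learning_rate <- function(state, error, output, config = state$config,
                                hidden = NULL) {
  base <- eta_base_rate(error, output, config)
  if (config$polarity == "diff_weight") {
    if (is.null(hidden)) {
      stop("`hidden` is required for the diff_weight polarity rule",
           call. = FALSE)
    }
    polar <- sign1(outer(-output, hidden, "+")) * sign1(state$W)
    state$eta <- abs(base) * polar
  } else {
    state$eta <- matrix(base, config$n_out, config$n_hidden)
  }
  # modulatory path: error and activation exchange roles, signed by error
  mod_base <- eta_base_rate(output, error, config)
  state$mod_eta <- matrix(sign(error) * abs(mod_base),
                          config$n_out, config$n_out)
  state
}

# Per-output-neuron adaptive rate before polarity adjustment.
eta_base_rate <- function(e, x, config) {
  zero <- (e == 0) | (x == 0)
  r <- if (config$rate_form == "ratio") {
    config$eta_in * e / x
  } else {
    config$eta_in / (e * x)
  }
  r[zero] <- config$eta_in
  pmin(pmax(r, -config$eta_clip), config$eta_clip)
}

#' Update the standard (hidden-to-output) weights
#'
#' `dw_ij = sigmoid(M_i / n_scale) * delta_ij`, applied additively; the
#' sigmoid of the (scaled) modulatory activation is the magnitude gate, the
#' plasticity term carries the direction.
#'
#' @param state a `modnet_state` whose `eta` is current.
#' @param hidden,output activations from [modnet_forward()].
#' @param error output error vector.
#' @param config a [modnet_config()].
#' @return the state with `W` updated.
#' @export
update_standard_weights <- function(state, hidden, output, error,
                                    config = state$config) {
  dW <- standard_weight_delta(state, hidden, output, error, config)
  if (!all(is.finite(dW))) {
    stop(sprintf(
      "non-finite weight update (max |eta| = %g, max |M| = %g)",
      max(abs(state$eta)),
      max(abs(modulatory_activation(state, error)))), call. = FALSE)
  }
  state$W <- state$W + dW
  state
}

# The pending update dW without applying it (shared with the attention path).
standard_weight_delta <- function(state, hidden, output, error,
                                  config = state$config) {
  m_gate <- sigmoid(modulatory_activation(state, error) / config$n_scale)
  delta <- plasticity_term(state, hidden, output, config)
  m_gate * delta  # recycles by row: gate_i applied across row i
}

#' Update the modulatory weights
#'
#' `dw'_ij = eta'_ij * mod_scale` with the sign of `eta'_ij` directly
#' correlated with the error and its magnitude scaled by the output
#' activation: `eta'_ij = mod_eta_in * e_i * x_i` (zero error leaves the
#' weights untouched; as learning saturates and errors vanish, the
#' modulatory weights — and with them the modulatory activations —
#' stabilize).
#'
#' @param state a `modnet_state`.
#' @param error output error vector.
#' @param output output activation vector.
#' @param config a [modnet_config()].
#' @return the state with `W_mod` updated.
#' @export
update_modulatory_weights <- function(state, error, output,
                                      config = state$config) {
  eta_mod <- config$mod_eta_in * error * output
  state$W_mod <- state$W_mod + eta_mod * config$mod_scale
  state
}

# Coerce the accepted dataset types to a plain features/labels pair.
as_feature_data <- function(dataset) {
  if (inherits(dataset, "vector_task")) {
    list(features = dataset$features, labels = dataset$labels)
  } else if (inherits(dataset, "image_dataset")) {
    d <- dim(dataset$images)
    list(features = matrix(dataset$images, d[1], d[2] * d[3]),
         labels = dataset$labels)
  } else if (is.list(dataset) && !is.null(dataset$features)) {
    list(features = as.matrix(dataset$features),
         labels = as.integer(dataset$labels))
  } else {
    stop("unsupported dataset type", call. = FALSE)
  }
}

#' Train ModNet online
#'
#' One sample at a time (batch size 1): forward pass, output error against
#' the one-hot label, modulatory activation, adaptive-rate update, gated
#' Hebbian weight update, modulatory-weight update.  Every 100 samples the
#' history records the running training accuracy and the mean absolute
#' modulatory activation; when attention is enabled it also records region
#' activity and the pruned-connection fraction.
#'
#' @param state a `modnet_state` from [modnet_init()].
#' @param dataset a `vector_task`, `image_dataset`, or list with `features`
#'   and `labels` (labels in `0:(n_out-1)`).
#' @param config a [modnet_config()]; defaults to the state's.
#' @param attention optional [attention_spec()] enabling region-based
#'   attention with activity pruning.
#' @return list with `state` (trained) and `history` (data frame: one row
#'   per 100 samples with `samples`, `epoch`, `accuracy`, `mean_abs_M`, and,
#'   with attention, `pruned_fraction` and `zero_fraction`).
#' @export
modnet_train <- function(state, dataset, config = state$config,
                         attention = NULL) {
  data <- as_feature_data(dataset)
  n <- nrow(data$features)
  if (any(data$labels < 0L | data$labels >= config$n_out)) {
    stop("labels must lie in [0, n_out)", call. = FALSE)
  }
  att <- if (!is.null(attention)) {
    init_attention_state(attention, state$config$n_hidden)
  }
  if (!is.null(att) && att$spec$sparse_init > 0) {
    # sparse start: a seeded fraction of hidden-to-output weights begins at
    # zero; such weights may regrow in active regions
    zero_idx <- with_seed(att$spec$seed + 1L, {
      sample(length(state$W), round(att$spec$sparse_init * length(state$W)))
    })
    state$W[zero_idx] <- 0
  }
  window <- if (is.null(att)) 100L else att$spec$eval_period

  hist_rows <- list()
  correct <- 0L; abs_m <- 0; seen_in_window <- 0L; total_seen <- 0L
  # The fixed projection lets the hidden code be precomputed in one GEMM.
  hidden_all <- sigmoid(tcrossprod(data$features, state$W_proj))
  for (ep in seq_len(config$epochs)) {
    # online learning needs an interleaved class order; the presentation
    # order is a seeded per-epoch permutation
    ord <- with_seed(config$seed * 1000L + ep, sample.int(n))
    for (s in ord) {
      h <- hidden_all[s, ]
      a <- sigmoid(drop(state$W %*% h))
      y <- data$labels[s]
      e <- -a; e[y + 1L] <- e[y + 1L] + 1
      m <- modulatory_activation(state, e)
      state <- adapt_learning_rate(state, e, a, config, hidden = h)
      dW <- standard_weight_delta(state, h, a, e, config)
      if (is.null(att)) {
        state$W <- state$W + dW
      } else {
        res <- apply_attended_update(state$W, dW, att)
        state$W <- res$W; att <- res$att
        att <- accumulate_region_activity(att, h)
      }
      state <- update_modulatory_weights(state, e, a, config)

      correct <- correct + (which.max(a) - 1L == y)
      abs_m <- abs_m + mean(abs(m))
      seen_in_window <- seen_in_window + 1L
      total_seen <- total_seen + 1L
      if (seen_in_window == window) {
        if (!is.null(att)) att <- evaluate_regions(att)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          samples = total_seen, epoch = ep,
          accuracy = correct / seen_in_window,
          mean_abs_M = abs_m / seen_in_window,
          pruned_fraction = if (is.null(att)) NA_real_ else
            mean(att$pruned),
          zero_fraction = if (is.null(att)) NA_real_ else
            mean(state$W == 0)
        )
        correct <- 0L; abs_m <- 0; seen_in_window <- 0L
      }
    }
  }
  history <- do.call(rbind, hist_rows)
  if (!is.null(att)) {
    attr(state, "attention") <- att
  }
  list(state = state, history = history)
}

#' Predict labels with a trained ModNet
#' @param state a trained `modnet_state`.
#' @param dataset features (same types as [modnet_train()]).
#' @return integer labels in `0:(n_out-1)`.
#' @export
modnet_predict <- function(state, dataset) {
  data <- as_feature_data(dataset)
  hidden <- sigmoid(tcrossprod(data$features, state$W_proj))
  out <- hidden %*% t(state$W)
  max.col(out, ties.method = "first") - 1L
}

#' Test accuracy of a trained ModNet
#' @inheritParams modnet_predict
#' @return accuracy in `[0, 1]`.
#' @export
modnet_accuracy <- function(state, dataset) {
  data <- as_feature_data(dataset)
  mean(modnet_predict(state, dataset) == data$labels)
}

#' Export a training history as delimited text
#' @param history the history data frame from [modnet_train()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
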