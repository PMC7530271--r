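# Naive per-synapse loop oracles for the vectorized learning rules, plus
# lazily cached shared fixtures.  The oracles mirror the rule definitions
# element by element and stay independent of the vectorized code paths.

ns <- asNamespace("neuromod")

# -- loop oracles -------------------------------------------------------------

oracle_modulatory_activation <- function(W_mod, e) {
  m <- numeric(nrow(W_mod))
  for (i in seq_len(nrow(W_mod))) {
    for (j in seq_len(ncol(W_mod))) m[i] <- m[i] + W_mod[i, j] * e[j]
  }
  m
}

oracle_plasticity_term <- function(eta, hidden, output, cfg) {
  d <- matrix(0, length(output), length(hidden))
  for (i in seq_along(output)) {
    for (j in seq_along(hidden)) {
      d[i, j] <- eta[i, j] * (cfg$beta1 * output[i] * hidden[j] +
                                cfg$beta2 * (hidden[j] - output[i]) +
                                cfg$beta3)
    }
  }
  d
}

oracle_eta <- function(e, x, cfg) {
  eta <- matrix(0, length(e), 1)
  for (i in seq_along(e)) {
    if (e[i] == 0 || x[i] == 0) {
      r <- cfg$eta_in
    } else if (cfg$rate_form == "inverse") {
      r <- cfg$eta_in / (e[i] * x[i])
    } else {
      r <- cfg$eta_in * e[i] / x[i]
    }
    eta[i, 1] <- max(min(r, cfg$eta_clip), -cfg$eta_clip)
  }
  eta
}

oracle_standard_update <- function(W, W_mod, eta_mat, hidden, output, e, cfg) {
  m <- oracle_modulatory_activation(W_mod, e)
  dW <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) {
    gate <- 1 / (1 + exp(-m[i] / cfg$n_scale))
    for (j in seq_len(ncol(W))) {
      delta_ij <- eta_mat[i, j] * (cfg$beta1 * output[i] * hidden[j] +
                                     cfg$beta2 * (hidden[j] - output[i]) +
                                     cfg$beta3)
      dW[i, j] <- gate * delta_ij
    }
  }
  dW
}

oracle_modulatory_update <- function(W_mod, e, output, cfg) {
  for (i in seq_len(nrow(W_mod))) {
    d <- cfg$mod_eta_in * e[i] * output[i] * cfg$mod_scale
    for (j in seq_len(ncol(W_mod))) W_mod[i, j] <- W_mod[i, j] + d
  }
  W_mod
}

oracle_activity_factor <- function(acts_by_region) {
  sapply(acts_by_region, function(a) {
    mx <- 0
    for (v in a) if (v > mx) mx <- v
    if (mx == 0) return(0)
    s <- 0
    for (v in a) s <- s + v
    (s / length(a)) / mx
  })
}

oracle_covariance_update <- function(W, pre, post, cfg) {
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      W[i, j] <- W[i, j] +
        cfg$cov_eta * (pre[j] - cfg$s1) * (post[i] - cfg$s2) * W[i, j]
    }
  }
  W
}

oracle_trace_update <- function(Mod, x_in, x_out, alpha) {
  for (i in seq_len(nrow(Mod))) {
    for (j in seq_len(ncol(Mod))) {
      Mod[i, j] <- Mod[i, j] +
        alpha * x_out[i] * (x_in[j] - x_out[i] * Mod[i, j])
    }
  }
  Mod
}

# Direct (non-im2col) 3x3 same-padding convolution for one image.
oracle_conv3x3 <- function(img, kernels, bias) {
  H <- nrow(img); W <- ncol(img); F <- length(bias)
  out <- array(0, dim = c(H, W, F))
  for (f in seq_len(F)) {
    k <- kernels[[f]]  # 3x3
    for (h in seq_len(H)) {
      for (w in seq_len(W)) {
        s <- bias[f]
        for (dh in -1:1) {
          for (dw in -1:1) {
            hh <- h + dh; ww <- w + dw
            if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
              s <- s + img[hh, ww] * k[dh + 2, dw + 2]
            }
          }
        }
        out[h, w, f] <- s
      }
    }
  }
  out
}

# -- cached fixtures ----------------------------------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

sep_task <- function() {
  fixture("sep_task", function() {
    make_vector_task(10, 100, 200, separation = 6, noise_sd = 1, seed = 1)
  })
}

sep_test <- function() {
  fixture("sep_test", function() sample_vector_task(sep_task(), 50, 1001))
}

small_bank <- function() {
  fixture("small_bank", function() make_glyph_bank(40, 20, 28, seed = 3))
}

trained_modnet <- function() {
  fixture("trained_modnet", function() {
    cfg <- modnet_config(100, 10, seed = 1)
    modnet_train(modnet_init(cfg), sep_task())
  })
}
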