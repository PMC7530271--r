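#' Create a plastic readout layer
#'
#' The modulatory-trace readout: every connection has a trainable fixed
#' weight `w_ij`, a trainable plasticity coefficient `delta_ij`, and an
#' episodic trace `Mod_ij`; the effective weight is
#' `W_tot = w_ij + delta_ij * Mod_ij`.  A single global trainable rate
#' `gamma` scales the trace's modulatory context term.  `w` and `delta`
#' persist across episodes (they are optimized by backpropagation through
#' the unrolled episode); the trace is reset to zero at the start of every
#' episode and accumulates input/output co-activations during it.
#'
#' @param n_out number of output units (the N of an N-way task).
#' @param n_in number of input features.
#' @param delta_init initial plasticity coefficient (default 0.01).
#' @param gamma_init initial trace rate (default 0.02).
#' @param w_scale half-width of the uniform `w` initialization (default
#'   0.05).  The fixed component starts near zero: at the start of an
#'   episode the logits are dominated by whatever `w` encodes, and since
#'   the class-to-unit assignment is a fresh permutation every episode, a
#'   large fixed component is pure noise for the query.
#' @param seed seed for the `w` initialization.
#' @return a `plastic_readout` with fields `w`, `delta`, `gamma`, `Mod`.
#' @export
plastic_readout <- function(n_out, n_in, delta_init = 0.01,
                            gamma_init = 0.02, w_scale = 0.05, seed = 1L) {
  n_out <- check_count(n_out, "n_out")
  n_in <- check_count(n_in, "n_in")
  lim <- check_scalar(w_scale, "w_scale", min = 0)
  with_seed(seed, {
    structure(list(
      w = matrix(runif(n_out * n_in, -lim, lim), n_out, n_in),
      delta = matrix(delta_init, n_out, n_in),
      gamma = gamma_init,
      Mod = matrix(0, n_out, n_in)
    ), class = "plastic_readout")
  })
}

#' @export
print.plastic_readout <- function(x, ...) {
  cat(sprintf("<plastic_readout> %d x %d, gamma = %.4g, |Mod| max = %.4g\n",
              nrow(x$w), ncol(x$w), x$gamma, max(abs(x$Mod))))
  invisible(x)
}

#' Effective weight of the plastic readout
#'
#' `W_tot = w + delta * Mod` (elementwise).
#' @param readout a [plastic_readout()].
#' @return matrix `n_out x n_in`.
#' @export
effective_weight <- function(readout) {
  readout$w + readout$delta * readout$Mod
}

#' Plastic readout forward pass
#'
#' Softmax over `W_tot %*% x_in`.  During support presentations the one-hot
#' label guides the output: a clamp bonus is added to the labelled unit's
#' logit before the softmax, so the post-clamp output is (nearly) the
#' one-hot label and the trace binds features to the correct unit.
#'
#' @param readout a [plastic_readout()].
#' @param x_in input feature vector.
#' @param label optional 0-based class label to clamp.
#' @param clamp_bonus logit bonus for the labelled unit (default 10).
#' @return output probability vector (sums to 1).
#' @export
plastic_forward <- function(readout, x_in, label = NULL, clamp_bonus = 10) {
  z <- drop(effective_weight(readout) %*% x_in)
  if (!is.null(label)) z[label + 1L] <- z[label + 1L] + clamp_bonus
  softmax(z)
}

#' Modulatory context rate alpha
#'
#' `alpha = gamma * sigmoid(sum(x_out) / n)` with `n` the number of output
#' units: one scalar per time step, shared by every connection; always in
#' `(0, gamma)`.
#'
#' @param x_out output activation vector.
#' @param gamma the trace-rate scale.
#' @return scalar alpha.
#' @export
trace_alpha <- function(x_out, gamma) {
  gamma * sigmoid(sum(x_out) / length(x_out))
}

#' Update the episodic trace
#'
#' `Mod_ij <- Mod_ij + alpha * x_out_i * (x_in_j - x_out_i * Mod_ij)`: an
#' Oja-like accumulation of input/output co-activations, gated by the
#' modulatory context `alpha`.  For constant inputs the fixed point is
#' `Mod* = x_in / x_out`.
#'
#' @param readout a [plastic_readout()].
#' @param x_in input feature vector (presynaptic).
#' @param x_out output activation vector (postsynaptic, post-clamp).
#' @return the readout with `Mod` updated.
#' @export
trace_update <- function(readout, x_in, x_out) {
  a <- trace_alpha(x_out, readout$gamma)
  readout$Mod <- readout$Mod +
    a * (outer(x_out, x_in) - x_out^2 * readout$Mod)
  readout
}

#' Reset the episodic trace
#'
#' Sets `Mod` to exactly zero; `w`, `delta` and `gamma` are untouched.
#' Idempotent.
#'
#' @param readout a [plastic_readout()].
#' @return the readout with a zero trace.
#' @export
reset_trace <- function(readout) {
  readout$Mod[] <- 0
  readout
}

# ---- unrolled-episode forward/backward (hand-rolled BPTT) ------------------
#
# Batched over B independent episodes.  x_steps is a list of T input
# matrices (n_in x B); labels is a list of T integer vectors (0-based) or
# NULL entries (no clamp).  The trace is updated after every step except
# the last (the query).  The loss is the mean cross-entropy of the final
# step's output against `target`.

readout_episode_forward <- function(readout, x_steps, labels, target,
                                    clamp_bonus = 10) {
  n_out <- nrow(readout$w); n_in <- ncol(readout$w)
  T_steps <- length(x_steps); B <- ncol(x_steps[[1]])
  Mod <- array(0, dim = c(n_out, n_in, B))
  cache <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    X <- x_steps[[t]]
    z <- readout$w %*% X
    for (b in seq_len(B)) {
      z[, b] <- z[, b] + (readout$delta * Mod[, , b]) %*% X[, b]
    }
    if (!is.null(labels[[t]])) {
      z[cbind(labels[[t]] + 1L, seq_len(B))] <-
        z[cbind(labels[[t]] + 1L, seq_len(B))] + clamp_bonus
    }
    x_out <- softmax_cols(z)
    u <- colSums(x_out) / n_out
    alpha <- readout$gamma * sigmoid(u)
    cache[[t]] <- list(X = X, Mod_prev = Mod, x_out = x_out,
                       u = u, alpha = alpha)
    if (t < T_steps) {
      for (b in seq_len(B)) {
        xo <- x_out[, b]
        Mod[, , b] <- Mod[, , b] +
          alpha[b] * (outer(xo, X[, b]) - xo^2 * Mod[, , b])
      }
    }
  }
  probs <- cache[[T_steps]]$x_out
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(target + 1L, seq_len(B))] + eps))
  pred <- max.col(t(probs), ties.method = "first") - 1L
  list(loss = loss, probs = probs, pred = pred, correct = pred == target,
       cache = cache, Mod_final = Mod)
}

readout_episode_backward <- function(readout, fwd, target,
                                     need_dx = TRUE) {
  cache <- fwd$cache
  T_steps <- length(cache)
  B <- ncol(cache[[1]]$X)
  n_out <- nrow(readout$w); n_in <- ncol(readout$w)
  dw <- matrix(0, n_out, n_in)
  ddelta <- matrix(0, n_out, n_in)
  dgamma <- 0
  dX <- if (need_dx) lapply(cache, function(ca) matrix(0, n_in, B))
  G <- array(0, dim = c(n_out, n_in, B))  # dL/dMod_t, running

  for (t in rev(seq_len(T_steps))) {
    ca <- cache[[t]]
    dx_out <- matrix(0, n_out, B)
    if (t < T_steps) {
      # back through the trace update performed at step t
      for (b in seq_len(B)) {
        g <- G[, , b]
        xo <- ca$x_out[, b]; xb <- ca$X[, b]; mp <- ca$Mod_prev[, , b]
        a <- ca$alpha[b]
        upd <- outer(xo, xb) - xo^2 * mp     # d Mod_t / d alpha
        dalpha <- sum(g * upd)
        dx_out[, b] <- dx_out[, b] +
          a * rowSums(g * (matrix(xb, n_out, n_in, byrow = TRUE) -
                             2 * xo * mp))
        if (need_dx) {
          dX[[t]][, b] <- dX[[t]][, b] + a * drop(crossprod(g, xo))
        }
        G[, , b] <- g * (1 - a * xo^2)        # into Mod_{t-1} (via update)
        sig_u <- sigmoid(ca$u[b])
        dgamma <- dgamma + dalpha * sig_u
        du <- dalpha * readout$gamma * sig_u * (1 - sig_u)
        dx_out[, b] <- dx_out[, b] + du / n_out
      }
    } else {
      # cross-entropy + softmax at the query step
      dz <- fwd$probs
      dz[cbind(target + 1L, seq_len(B))] <-
        dz[cbind(target + 1L, seq_len(B))] - 1
      dz <- dz / B
    }
    if (t < T_steps) {
      # softmax Jacobian: dz = x_out * (dx_out - sum(dx_out * x_out))
      s <- colSums(dx_out * ca$x_out)
      dz <- ca$x_out * sweep(dx_out, 2L, s, "-")
    }
    # through z_t = (w + delta . Mod_{t-1}) X_t
    dw <- dw + tcrossprod(dz, ca$X)
    for (b in seq_len(B)) {
      outer_zb <- outer(dz[, b], ca$X[, b])
      ddelta <- ddelta + outer_zb * ca$Mod_prev[, , b]
      G[, , b] <- G[, , b] + readout$delta * outer_zb
      if (need_dx) {
        dX[[t]][, b] <- dX[[t]][, b] +
          drop(crossprod(readout$w + readout$delta * ca$Mod_prev[, , b],
                         dz[, b]))
      }
    }
  }
  list(dw = dw, ddelta = ddelta, dgamma = dgamma, dX = dX)
}
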