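#' Region-based attention specification
#'
#' The hidden layer is divided into contiguous equal regions whose mean
#' activity (relative to the most active neuron in the region) is evaluated
#' periodically.  Active regions have their weight updates scaled by the
#' activity factor; regions below the activity threshold are inhibited and
#' their weights decay toward zero, where they are clamped and counted as
#' pruned.
#'
#' @param n_regions number of contiguous regions (default 10).
#' @param eval_period samples between activity evaluations (default 100).
#' @param activity_threshold the activity factor below which a region is
#'   inhibited (default 0.1).
#' @param alpha_init initial fraction of regions marked active, in
#'   `(0, 1]`; the rest start inhibited and can only re-activate at the
#'   first evaluation (default 1).
#' @param sign `"boost"` scales the applied update by `+A_k` (the reading
#'   consistent with the attention mechanism boosting active regions);
#'   `"literal"` applies the update with a minus sign, `w - A_k dw`.
#' @param sparse_init fraction of hidden-to-output weights zeroed at
#'   initialization (0 = dense start); zeroed weights may regrow in active
#'   regions.
#' @param seed seed for the initial active-region draw.
#' @return an `attention_spec`.
#' @export
attention_spec <- function(n_regions = 10L, eval_period = 100L,
                           activity_threshold = 0.1, alpha_init = 1,
                           sign = c("boost", "literal"), sparse_init = 0,
                           seed = 1L) {
  structure(list(
    n_regions = check_count(n_regions, "n_regions"),
    eval_period = check_count(eval_period, "eval_period"),
    activity_threshold = check_scalar(activity_threshold,
                                      "activity_threshold", min = 0),
    alpha_init = check_scalar(alpha_init, "alpha_init", min = 0,
                              strict = TRUE),
    sign = match.arg(sign),
    sparse_init = check_scalar(sparse_init, "sparse_init", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "attention_spec")
}

# Contiguous equal-block region index for n neurons.
region_index <- function(n, n_regions) {
  sizes <- rep(n %/% n_regions, n_regions)
  extra <- n %% n_regions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep.int(seq_len(n_regions), sizes)
}

init_attention_state <- function(spec, n_hidden) {
  stopifnot(inherits(spec, "attention_spec"))
  region <- region_index(n_hidden, spec$n_regions)
  n_active <- max(1L, ceiling(spec$alpha_init * spec$n_regions))
  active <- with_seed(spec$seed, {
    idx <- sample(spec$n_regions, min(n_active, spec$n_regions))
    seq_len(spec$n_regions) %in% idx
  })
  list(spec = spec, region = region,
       A = as.numeric(active),          # pre-evaluation surrogate activity
       active = active,
       acc = numeric(n_hidden), count = 0L,
       pruned = NULL)                   # allocated on first update
}

#' Activity factor of neuron regions
#'
#' `A_k = mean(a_ik) / a_max`: the mean activation of the region's neurons
#' normalized by the most active neuron in the region (`A_k = 0` for an
#' all-zero region).
#'
#' @param activations_by_region a list of numeric activation vectors, one
#'   per region.
#' @return numeric vector of activity factors in `[0, 1]`.
#' @export
activity_factor <- function(activations_by_region) {
  vapply(activations_by_region, function(a) {
    if (length(a) == 0L) stop("empty region", call. = FALSE)
    a_max <- max(a)
    if (a_max == 0) 0 else mean(a) / a_max
  }, numeric(1))
}

accumulate_region_activity <- function(att, hidden) {
  att$acc <- att$acc + hidden
  att$count <- att$count + 1L
  att
}

evaluate_regions <- function(att) {
  if (att$count > 0L) {
    mean_act <- att$acc / att$count
    att$A <- activity_factor(split(mean_act, att$region))
    att$active <- att$A >= att$spec$activity_threshold
    att$acc[] <- 0
    att$count <- 0L
  }
  att
}

#' Scale pending updates by region activity
#'
#' In regions whose activity factor is at or above the threshold, the
#' pending learning-rule update for the region's neurons is scaled by
#' `A_k` (boosting the more active regions); the scaling never flips an
#' update's sign.  Connections already pruned stay at exactly 0.
#'
#' @param W weight matrix (`n_out x n_hidden`), columns grouped by hidden
#'   neuron.
#' @param pending pending update matrix, same shape.
#' @param region integer region index per hidden neuron (column).
#' @param A activity factor per region.
#' @param active logical; which regions are active.
#' @param pruned optional logical matrix of pruned connections.
#' @param sign `"boost"` or `"literal"` (see [attention_spec()]).
#' @return the updated weight matrix.
#' @export
attention_update <- function(W, pending, region, A, active,
                             pruned = NULL, sign = "boost") {
  scale <- A[region] * active[region]
  scaled <- sweep(pending, 2L, scale, "*")
  W_new <- if (sign == "boost") W + scaled else W - scaled
  if (!is.null(pruned)) W_new[pruned] <- 0
  W_new
}

#' Inhibit the weights of a low-activity region
#'
#' Weights in inhibited regions decay toward zero by `|A_k * dw|` each
#' step: positive weights decrease, negative weights increase, and a weight
#' that crosses zero is clamped to exactly 0 and marked pruned.  A zero
#' weight stays zero.
#'
#' @param W weight matrix, columns restricted to the region's neurons (or
#'   the full matrix with `cols` given).
#' @param pending pending update matrix, same shape as `W`.
#' @param A_k the region's activity factor.
#' @param pruned logical matrix of already-pruned connections (same shape);
#'   updated and returned.
#' @return list with `W` (decayed, clamped) and `pruned` (updated mask).
#' @export
inhibit_region <- function(W, pending, A_k, pruned = NULL) {
  if (is.null(pruned)) pruned <- matrix(FALSE, nrow(W), ncol(W))
  step <- abs(A_k * pending)
  W_new <- ifelse(W > 0, pmax(0, W - step),
                  ifelse(W < 0, pmin(0, W + step), 0))
  W_new <- matrix(W_new, nrow(W), ncol(W))
  W_new[pruned] <- 0
  pruned_now <- pruned | (W_new == 0)
  list(W = W_new, pruned = pruned_now)
}

# One attended online update: boost active regions, inhibit the rest.
apply_attended_update <- function(W, dW, att) {
  if (is.null(att$pruned)) att$pruned <- matrix(FALSE, nrow(W), ncol(W))
  active_cols <- att$active[att$region]
  W_new <- attention_update(W, dW, att$region, att$A, att$active,
                            pruned = att$pruned, sign = att$spec$sign)
  if (any(!active_cols)) {
    cols <- which(!active_cols)
    step_scale <- att$A[att$region][cols]
    res <- inhibit_region(W[, cols, drop = FALSE],
                          sweep(dW[, cols, drop = FALSE], 2L, step_scale,
                                "*"),
                          A_k = 1,  # A_k already folded in per column
                          pruned = att$pruned[, cols, drop = FALSE])
    W_new[, cols] <- res$W
    att$pruned[, cols] <- res$pruned
  }
  list(W = W_new, att = att)
}

#' Slow covariance update for within-network local connections
#'
#' `dw_ij = eta' * (x_pre_j - s1) * (x_post_i - s2) * w_ij`: a
#' multiplicative covariance rule (a zero weight stays zero) intended to run
#' on a slower timescale than the modulatory rule, applied every `n_slow`
#' samples to the hidden1-to-hidden2 connections using window-mean
#' activations.
#'
#' @param W_local local weight matrix (`n_post x n_pre`).
#' @param pre_acts presynaptic activations (length `n_pre`).
#' @param post_acts postsynaptic activations (length `n_post`).
#' @param config list with `cov_eta`, `s1`, `s2` (see
#'   [compartment_config()]).
#' @return the updated weight matrix.
#' @export
covariance_update <- function(W_local, pre_acts, post_acts, config) {
  dW <- config$cov_eta * outer(post_acts - config$s2,
                               pre_acts - config$s1) * W_local
  W_local + dW
}

#' Gate low-activity compartments
#'
#' A compartment whose net activity factor stays below the gating threshold
#' for two consecutive evaluations is masked: its outputs are forced to 0
#' and its updates are skipped.  Gating an already-masked compartment is a
#' no-op (idempotent).
#'
#' @param activity net activity factor per compartment (mean activity
#'   factor of its neuron population).
#' @param gate_state list with `consec_low` (integer per compartment) and
#'   `gated` (logical per compartment); pass `NULL` to start fresh.
#' @param threshold gating threshold.
#' @return updated gate state (`consec_low`, `gated`).
#' @export
gate_compartments <- function(activity, gate_state = NULL, threshold = 0.1) {
  k <- length(activity)
  if (is.null(gate_state)) {
    gate_state <- list(consec_low = integer(k), gated = logical(k))
  }
  low <- activity < threshold
  gate_state$consec_low <- ifelse(low, gate_state$consec_low + 1L, 0L)
  gate_state$gated <- gate_state$gated | (gate_state$consec_low >= 2L)
  if (all(gate_state$gated)) {
    stop("all compartments gated: degenerate network", call. = FALSE)
  }
  gate_state
}

# ---- compartmentalized network ---------------------------------------------

#' Configuration of the compartmentalized two-hidden-layer network
#'
#' Adds a second hidden layer to ModNet.  Both hidden layers are split into
#' compartments that learn, compete, and can be gated off; the
#' hidden1-to-hidden2 connections are block-diagonal-dominant and trained by
#' the slow covariance rule; the hidden2-to-output weights are trained by
#' the modulatory rule with per-compartment attention.  The hidden2 drive
#' is computed from the hidden1 deviation from the covariance threshold
#' (`W_cov %*% (h1 - s1)`), the same baseline the covariance rule measures
#' correlations against, so the local code carries pattern rather than
#' baseline activity.
#'
#' @param n_in,n_out input and output sizes.
#' @param n_hidden1,n_hidden2 hidden layer sizes (defaults 1000, 1000).
#' @param n_compartments compartments per hidden layer (default 10).
#' @param s1,s2 covariance thresholds for pre and post activations
#'   (defaults 0.5).
#' @param cov_eta covariance learning rate (default 0.01).
#' @param n_slow samples between covariance updates (default 100).
#' @param gating_threshold compartments below this net activity for two
#'   consecutive evaluations are gated off (default 0.1).
#' @param within_frac fraction of hidden1-to-hidden2 connections that are
#'   within-compartment (default 0.8).
#' @param modnet a [modnet_config()] for the modulatory readout path; its
#'   `n_in`/`n_hidden`/`n_out` are overridden to match.
#' @param attention an [attention_spec()] used per compartment; its
#'   `n_regions` is overridden to `n_compartments`.
#' @param seed initialization seed.
#' @return a `compartment_config`.
#' @export
compartment_config <- function(n_in, n_out, n_hidden1 = 1000L,
                               n_hidden2 = 1000L, n_compartments = 10L,
                               s1 = 0.5, s2 = 0.5, cov_eta = 0.01,
                               n_slow = 100L, gating_threshold = 0.1,
                               within_frac = 0.8,
                               modnet = NULL, attention = NULL,
                               seed = 1L) {
  n_in <- check_count(n_in, "n_in"); n_out <- check_count(n_out, "n_out")
  n_hidden1 <- check_count(n_hidden1, "n_hidden1")
  n_hidden2 <- check_count(n_hidden2, "n_hidden2")
  n_compartments <- check_count(n_compartments, "n_compartments")
  modnet <- modnet %||% modnet_config(n_in, n_out, n_hidden = n_hidden2,
                                      seed = seed)
  modnet$n_in <- n_in; modnet$n_hidden <- n_hidden2; modnet$n_out <- n_out
  attention <- attention %||% attention_spec(seed = seed)
  attention$n_regions <- n_compartments
  structure(list(
    n_in = n_in, n_out = n_out, n_hidden1 = n_hidden1,
    n_hidden2 = n_hidden2, n_compartments = n_compartments,
    s1 = check_scalar(s1, "s1"), s2 = check_scalar(s2, "s2"),
    cov_eta = check_scalar(cov_eta, "cov_eta", min = 0),
    n_slow = check_count(n_slow, "n_slow"),
    gating_threshold = check_scalar(gating_threshold, "gating_threshold",
                                    min = 0),
    within_frac = check_scalar(within_frac, "within_frac", min = 0),
    modnet = modnet, attention = attention,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "compartment_config")
}

#' Initialize the compartmentalized network
#' @param config a [compartment_config()].
#' @return a `compartment_state` with the fixed projection `W_proj`, the
#'   block-dominant local weights `W_cov` (hidden1 to hidden2), the readout
#'   `W`/`W_mod`/rates from the modulatory path, compartment indices, and
#'   gate state per hidden layer.
#' @export
compartment_init <- function(config) {
  stopifnot(inherits(config, "compartment_config"))
  base <- modnet_init(config$modnet)
  with_seed(config$seed + 1L, {
    W_proj <- matrix(runif(config$n_hidden1 * config$n_in, -1, 1),
                     config$n_hidden1, config$n_in)
    comp1 <- region_index(config$n_hidden1, config$n_compartments)
    comp2 <- region_index(config$n_hidden2, config$n_compartments)
    # Block-diagonal-dominant wiring: keep all within-compartment pairs and
    # only enough cross-compartment pairs that `within_frac` of connections
    # are within-compartment.
    within <- outer(comp2, comp1, "==")
    p_within <- mean(within)
    p_cross <- p_within * (1 - config$within_frac) /
      (config$within_frac * (1 - p_within))
    keep <- within | (matrix(runif(length(within)), nrow(within)) <
                        min(1, p_cross))
    # scale so the hidden2 pre-activations have usable spread (sd ~ 2)
    # through the sigmoid despite the sparse fan-in
    fan_in <- mean(keep) * config$n_hidden1
    a <- 4 * sqrt(3) / sqrt(fan_in)
    W_cov <- matrix(runif(config$n_hidden2 * config$n_hidden1, -a, a),
                    config$n_hidden2, config$n_hidden1) * keep
    structure(list(
      W_proj = W_proj, W_cov = W_cov,
      W = base$W, W_mod = base$W_mod, eta = base$eta,
      mod_eta = base$mod_eta,
      comp1 = comp1, comp2 = comp2,
      gate1 = list(consec_low = integer(config$n_compartments),
                   gated = logical(config$n_compartments)),
      gate2 = list(consec_low = integer(config$n_compartments),
                   gated = logical(config$n_compartments)),
      config = config
    ), class = "compartment_state")
  })
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("<compartment_state> %d -> %d -> %d -> %d (%d compartments)\n",
              x$config$n_in, x$config$n_hidden1, x$config$n_hidden2,
              x$config$n_out, x$config$n_compartments))
  invisible(x)
}

compartment_forward <- function(state, input) {
  h1 <- sigmoid(drop(state$W_proj %*% input))
  h1[state$gate1$gated[state$comp1]] <- 0
  h2 <- sigmoid(drop(state$W_cov %*% (h1 - state$config$s1)))
  h2[state$gate2$gated[state$comp2]] <- 0
  out <- sigmoid(drop(state$W %*% h2))
  list(h1 = h1, h2 = h2, output = out)
}

#' Train the compartmentalized network
#'
#' Online modulatory learning on the hidden2-to-output weights with
#' per-compartment attention and inhibition, the slow covariance rule on
#' the hidden1-to-hidden2 weights every `n_slow` samples (using window-mean
#' activations), and activity gating of whole compartments.
#'
#' @param state a `compartment_state`.
#' @param dataset as in [modnet_train()].
#' @param epochs training epochs (defaults to the modulatory config's).
#' @return list with `state` and `history` (per-evaluation rows: running
#'   accuracy, mean |M|, per-layer compartment activity, pruned and gated
#'   fractions).
#' @export
compartment_train <- function(state, dataset,
                              epochs = state$config$modnet$epochs) {
  cfg <- state$config
  mn <- cfg$modnet
  data <- as_feature_data(dataset)
  n <- nrow(data$features)
  period <- cfg$attention$eval_period
  thr <- cfg$attention$activity_threshold

  pruned_w <- matrix(FALSE, mn$n_out, mn$n_hidden)
  pruned_cov <- matrix(FALSE, cfg$n_hidden2, cfg$n_hidden1)
  A2 <- rep(1, cfg$n_compartments)     # pre-evaluation surrogate
  active2 <- rep(TRUE, cfg$n_compartments)
  acc1 <- numeric(cfg$n_hidden1); acc2 <- numeric(cfg$n_hidden2)
  cov_pre <- numeric(cfg$n_hidden1); cov_post <- numeric(cfg$n_hidden2)
  count <- 0L; cov_count <- 0L
  correct <- 0L; abs_m <- 0; total <- 0L
  hist_rows <- list()

  h1_all <- sigmoid(tcrossprod(data$features, state$W_proj))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cfg$seed * 1000L + ep, sample.int(n))
    for (s in ord) {
      h1 <- h1_all[s, ]
      h1[state$gate1$gated[state$comp1]] <- 0
      h2 <- sigmoid(drop(state$W_cov %*% (h1 - cfg$s1)))
      h2[state$gate2$gated[state$comp2]] <- 0
      a <- sigmoid(drop(state$W %*% h2))
      y <- data$labels[s]
      e <- -a; e[y + 1L] <- e[y + 1L] + 1
      m <- modulatory_activation(state, e)

      mini <- state[c("W", "W_mod", "eta", "mod_eta")]
      class(mini) <- "modnet_state"
      mini <- adapt_learning_rate(mini, e, a, mn, hidden = h2)
      dW <- standard_weight_delta(mini, h2, a, e, mn)
      dW[, state$gate2$gated[state$comp2]] <- 0
      att_like <- list(spec = cfg$attention, region = state$comp2,
                       A = A2, active = active2, pruned = pruned_w)
      res <- apply_attended_update(state$W, dW, att_like)
      state$W <- res$W; pruned_w <- res$att$pruned
      state$eta <- mini$eta
      mini$W <- state$W
      mini <- update_modulatory_weights(mini, e, a, mn)
      state$W_mod <- mini$W_mod; state$mod_eta <- mini$mod_eta

      acc1 <- acc1 + h1; acc2 <- acc2 + h2
      cov_pre <- cov_pre + h1; cov_post <- cov_post + h2
      count <- count + 1L; cov_count <- cov_count + 1L
      correct <- correct + (which.max(a) - 1L == y)
      abs_m <- abs_m + mean(abs(m))
      total <- total + 1L

      if (cov_count == cfg$n_slow) {
        pre_bar <- cov_pre / cov_count; post_bar <- cov_post / cov_count
        W_cov_new <- covariance_update(state$W_cov, pre_bar, post_bar, cfg)
        upd_ok <- !(state$gate2$gated[state$comp2])
        state$W_cov[upd_ok, ] <- W_cov_new[upd_ok, ]
        state$W_cov[pruned_cov] <- 0
        cov_pre[] <- 0; cov_post[] <- 0; cov_count <- 0L
      }

      if (count == period) {
        mean1 <- acc1 / count; mean2 <- acc2 / count
        A1 <- activity_factor(split(mean1, state$comp1))
        A2 <- activity_factor(split(mean2, state$comp2))
        active2 <- A2 >= thr
        # inhibit hidden1->hidden2 weights of low-activity compartments
        low2 <- which(!active2 & !state$gate2$gated)
        for (k in low2) {
          rows <- state$comp2 == k
          r <- inhibit_region(state$W_cov[rows, , drop = FALSE],
                              state$W_cov[rows, , drop = FALSE],
                              A_k = A2[k],
                              pruned = pruned_cov[rows, , drop = FALSE])
          state$W_cov[rows, ] <- r$W
          pruned_cov[rows, ] <- r$pruned
        }
        low1 <- which(A1 < thr & !state$gate1$gated)
        for (k in low1) {
          cols <- state$comp1 == k
          r <- inhibit_region(state$W_cov[, cols, drop = FALSE],
                              state$W_cov[, cols, drop = FALSE],
                              A_k = A1[k],
                              pruned = pruned_cov[, cols, drop = FALSE])
          state$W_cov[, cols] <- r$W
          pruned_cov[, cols] <- r$pruned
        }
        state$gate1 <- gate_compartments(A1, state$gate1,
                                         cfg$gating_threshold)
        state$gate2 <- gate_compartments(A2, state$gate2,
                                         cfg$gating_threshold)
        n_conn <- length(pruned_w) + length(pruned_cov)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          samples = total, epoch = ep,
          accuracy = correct / count, mean_abs_M = abs_m / count,
          pruned_fraction = (sum(pruned_w) + sum(pruned_cov)) / n_conn,
          gated1 = mean(state$gate1$gated),
          gated2 = mean(state$gate2$gated),
          mean_A2 = mean(A2)
        )
        acc1[] <- 0; acc2[] <- 0; count <- 0L; correct <- 0L; abs_m <- 0
      }
    }
  }
  state$pruned_w <- pruned_w
  state$pruned_cov <- pruned_cov
  list(state = state, history = do.call(rbind, hist_rows))
}

#' Predict with a trained compartmentalized network
#' @param state a trained `compartment_state`.
#' @param dataset features (types as in [modnet_train()]).
#' @return integer labels.
#' @export
compartment_predict <- function(state, dataset) {
  data <- as_feature_data(dataset)
  h1 <- sigmoid(tcrossprod(data$features, state$W_proj))
  h1[, state$gate1$gated[state$comp1]] <- 0
  h2 <- sigmoid(tcrossprod(h1 - state$config$s1, state$W_cov))
  h2[, state$gate2$gated[state$comp2]] <- 0
  out <- tcrossprod(h2, state$W)
  max.col(out, ties.method = "first") - 1L
}

#' @rdname compartment_predict
#' @return for `compartment_accuracy`, accuracy in `[0, 1]`.
#' @export
compartment_accuracy <- function(state, dataset) {
  data <- as_feature_data(dataset)
  mean(compartment_predict(state, dataset) == data$labels)
}
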