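#' Count trainable parameters of the embedding plus plastic readout
#'
#' Accounting: convolution weights and biases are trainable; batch
#' normalization carries no learnable affine parameters; the readout is
#' bias-free with per-connection fixed weights `w` and plasticity
#' coefficients `delta`, plus one global trace rate `gamma`.  For the
#' standard four-module, 64-filter embedding with a 5-way readout this
#' gives 640 + 3*36,928 + 320 + 320 + 1 = 112,065.
#'
#' @param conv a [conv_config()].
#' @param n_way number of output units of the readout.
#' @return integer parameter count.
#' @export
count_parameters <- function(conv, n_way) {
  stopifnot(inherits(conv, "conv_config"))
  n_way <- check_count(n_way, "n_way")
  total <- 0L
  for (m in seq_len(conv$n_modules)) {
    c_in <- if (m == 1L) conv$in_channels else conv$filters
    total <- total + 9L * c_in * conv$filters + conv$filters
  }
  n_feat <- conv$filters * conv$out_size^2
  as.integer(total + 2L * n_way * n_feat + 1L)
}

#' Few-shot model: conv embedding + plastic readout
#'
#' @param conv a [conv_config()].
#' @param n_way number of classes per episode.
#' @param seed initialization seed.
#' @param delta_init,gamma_init readout initial values (defaults 0.01, 0.02).
#' @return a `fewshot_model` with `conv_params`, `readout`, `conv`, `n_way`.
#' @export
fewshot_model <- function(conv, n_way = 5L, seed = 1L,
                          delta_init = 0.01, gamma_init = 0.02) {
  stopifnot(inherits(conv, "conv_config"))
  n_feat <- conv$filters * conv$out_size^2
  structure(list(
    conv = conv, n_way = check_count(n_way, "n_way"),
    conv_params = conv_init(conv, seed = seed),
    readout = plastic_readout(n_way, n_feat, delta_init = delta_init,
                              gamma_init = gamma_init, seed = seed + 1L)
  ), class = "fewshot_model")
}

#' @export
print.fewshot_model <- function(x, ...) {
  cat(sprintf("<fewshot_model> %d-way, %d conv modules x %d filters, %s parameters\n",
              x$n_way, x$conv$n_modules, x$conv$filters,
              format(count_parameters(x$conv, x$n_way), big.mark = ",")))
  invisible(x)
}

# Rotate a matrix by k*90 degrees (counterclockwise).
rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

#' Sample one N-way K-shot episode
#'
#' Picks N classes from `split` without replacement, K support samples per
#' class plus one disjoint query sample from one of the N classes, permutes
#' the class labels to `0:(N-1)`, and applies a per-class rotation drawn
#' from 0/90/180/270 degrees (rotated variants act as distinct classes).
#' The support presentation order is shuffled.
#'
#' @param bank a `glyph_bank` or `image_dataset`.
#' @param split integer vector of class ids to sample from.
#' @param N,K ways and shots.
#' @param seed optional seed (omit to use the ambient RNG stream).
#' @return an `episode`: `support_images` (array N*K x H x W),
#'   `support_labels` (0-based), `query_image`, `query_label`, `classes`
#'   (the original class ids in permuted-label order), `rotations`.
#' @export
sample_episode <- function(bank, split, N = 5L, K = 1L, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, sample_episode(bank, split, N, K, seed = NULL)))
  }
  N <- check_count(N, "N"); K <- check_count(K, "K")
  labels <- bank$labels
  split <- intersect(as.integer(split), unique(labels))
  counts <- table(labels[labels %in% split])
  eligible <- as.integer(names(counts))[counts >= K + 1L]
  if (length(eligible) < N) {
    stop(sprintf("need %d classes with >= %d samples; only %d available",
                 N, K + 1L, length(eligible)), call. = FALSE)
  }
  classes <- sample(eligible, N)
  rotations <- sample(0:3, N, replace = TRUE)
  H <- dim(bank$images)[2]
  support_images <- array(0, dim = c(N * K, H, H))
  support_labels <- integer(N * K)
  idx <- 1L
  query_class <- sample.int(N, 1L)
  query_image <- NULL; query_label <- NA_integer_
  for (ci in seq_len(N)) {
    pool <- which(labels == classes[ci])
    take <- sample(pool, K + (ci == query_class))
    for (k in seq_len(K)) {
      support_images[idx, , ] <- rot90k(bank$images[take[k], , ],
                                        rotations[ci])
      support_labels[idx] <- ci - 1L
      idx <- idx + 1L
    }
    if (ci == query_class) {
      query_image <- rot90k(bank$images[take[K + 1L], , ], rotations[ci])
      query_label <- ci - 1L
    }
  }
  ord <- sample.int(N * K)
  structure(list(
    support_images = support_images[ord, , , drop = FALSE],
    support_labels = support_labels[ord],
    query_image = query_image, query_label = query_label,
    classes = classes, rotations = rotations
  ), class = "episode")
}

# Assemble step-wise conv inputs for a list of episodes (all same N*K).
episode_steps <- function(episodes) {
  B <- length(episodes)
  n_sup <- dim(episodes[[1]]$support_images)[1]
  H <- dim(episodes[[1]]$support_images)[2]
  T_steps <- n_sup + 1L
  x_imgs <- vector("list", T_steps)
  labels <- vector("list", T_steps)
  for (t in seq_len(n_sup)) {
    m <- matrix(0, H * H, B)
    lab <- integer(B)
    for (b in seq_len(B)) {
      m[, b] <- as.vector(episodes[[b]]$support_images[t, , ])
      lab[b] <- episodes[[b]]$support_labels[t]
    }
    x_imgs[[t]] <- m; labels[[t]] <- lab
  }
  mq <- matrix(0, H * H, B)
  for (b in seq_len(B)) mq[, b] <- as.vector(episodes[[b]]$query_image)
  x_imgs[[T_steps]] <- mq; labels[T_steps] <- list(NULL)
  target <- vapply(episodes, function(e) e$query_label, integer(1))
  list(x_imgs = x_imgs, labels = labels, target = target)
}

# Forward a batch of episodes through conv + readout.  Returns loss,
# correctness, and (if backward) all parameter gradients.  `conv_grads =
# FALSE` skips the backward pass through the embedding (readout-only
# training with a frozen embedding).
fewshot_batch_pass <- function(model, episodes, clamp_bonus = 10,
                               backward = FALSE, conv_grads = TRUE) {
  st <- episode_steps(episodes)
  T_steps <- length(st$x_imgs)
  feats <- vector("list", T_steps)
  caches <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    fw <- conv_forward(model$conv_params, st$x_imgs[[t]], model$conv)
    feats[[t]] <- fw$features
    if (backward && conv_grads) caches[[t]] <- fw$caches
  }
  fwd <- readout_episode_forward(model$readout, feats, st$labels,
                                 st$target, clamp_bonus)
  out <- list(loss = fwd$loss, correct = fwd$correct, pred = fwd$pred)
  if (backward) {
    bk <- readout_episode_backward(model$readout, fwd, st$target,
                                   need_dx = conv_grads)
    cg <- NULL
    if (conv_grads) {
      for (t in seq_len(T_steps)) {
        g <- conv_backward(model$conv_params, caches[[t]], bk$dX[[t]],
                           model$conv)$grads
        if (is.null(cg)) {
          cg <- g
        } else {
          for (m in seq_along(g)) {
            cg[[m]]$W <- cg[[m]]$W + g[[m]]$W
            cg[[m]]$b <- cg[[m]]$b + g[[m]]$b
          }
        }
      }
    }
    out$grads <- list(conv = cg, w = bk$dw, delta = bk$ddelta,
                      gamma = bk$dgamma)
  }
  out
}

#' Run a single episode
#'
#' Resets the trace, presents the support samples sequentially with label
#' clamping and trace updates, then the unclamped query.  With
#' `train = TRUE` the gradients through the whole unrolled episode update
#' the convolution weights, `w`, `delta` and `gamma` by one SGD step.
#'
#' @param model a [fewshot_model()].
#' @param episode an [sample_episode()] result.
#' @param train apply a gradient step (default `FALSE`).
#' @param lr learning rate for the step when `train = TRUE`.
#' @param clamp_bonus support label clamp bonus.
#' @return list with `loss`, `correct`, and (if `train`) the updated
#'   `model`.
#' @export
run_episode <- function(model, episode, train = FALSE, lr = 3e-5,
                        clamp_bonus = 10) {
  res <- fewshot_batch_pass(model, list(episode), clamp_bonus,
                            backward = train)
  out <- list(loss = res$loss, correct = res$correct[1])
  if (train) {
    g <- res$grads
    for (m in seq_along(model$conv_params)) {
      model$conv_params[[m]]$W <- model$conv_params[[m]]$W - lr * g$conv[[m]]$W
      model$conv_params[[m]]$b <- model$conv_params[[m]]$b - lr * g$conv[[m]]$b
    }
    model$readout$w <- model$readout$w - lr * g$w
    model$readout$delta <- model$readout$delta - lr * g$delta
    model$readout$gamma <- model$readout$gamma - lr * g$gamma
    out$model <- model
  }
  out
}

#' Episodic training plan
#'
#' Defaults follow the full-scale protocol (Adam, initial rate 3e-5
#' multiplied by 2/3 every 100,000 episodes, 500,000 episodes, evaluation
#' on 200 episodes of held-out classes).  For desk-scale runs see
#' [scaled_fewshot_plan()].
#'
#' @param n_way,k_shot episode shape (defaults 5-way 1-shot).
#' @param episodes total training episodes.
#' @param meta_batch episodes per optimization step (gradients are averaged
#'   over the batch; the episode count always refers to episodes, not
#'   steps).
#' @param lr initial Adam learning rate.
#' @param lr_decay_every episode interval of the learning-rate decay.
#' @param lr_decay_factor multiplicative decay (default 2/3).
#' @param eval_episodes evaluation episodes on the held-out classes.
#' @param clamp_bonus support label clamp bonus.
#' @param seed training seed.
#' @return a `fewshot_plan`.
#' @export
fewshot_plan <- function(n_way = 5L, k_shot = 1L, episodes = 500000L,
                         meta_batch = 1L, lr = 3e-5,
                         lr_decay_every = 100000L, lr_decay_factor = 2 / 3,
                         eval_episodes = 200L, clamp_bonus = 10,
                         seed = 1L) {
  structure(list(
    n_way = check_count(n_way, "n_way"),
    k_shot = check_count(k_shot, "k_shot"),
    episodes = check_count(episodes, "episodes", min = 0L),
    meta_batch = check_count(meta_batch, "meta_batch"),
    lr = check_scalar(lr, "lr", min = 0, strict = TRUE),
    lr_decay_every = check_count(lr_decay_every, "lr_decay_every"),
    lr_decay_factor = check_scalar(lr_decay_factor, "lr_decay_factor",
                                   min = 0, strict = TRUE),
    eval_episodes = check_count(eval_episodes, "eval_episodes"),
    clamp_bonus = check_scalar(clamp_bonus, "clamp_bonus"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "fewshot_plan")
}

#' Desk-scale episodic training plan
#'
#' A scaled-down protocol sized for a synthetic glyph bank: 20,000 episodes
#' in meta-batches of 5 with a proportionally faster Adam rate (3e-3,
#' decayed by 2/3 every 4,000 episodes, mirroring the full protocol's five
#' decay milestones), paired with a 16-filter embedding.
#'
#' @param episodes,meta_batch,lr,lr_decay_every,seed overrides.
#' @inheritParams fewshot_plan
#' @return a `fewshot_plan`.
#' @export
scaled_fewshot_plan <- function(episodes = 20000L, meta_batch = 5L,
                                lr = 3e-3, lr_decay_every = 4000L,
                                eval_episodes = 200L, seed = 1L) {
  fewshot_plan(episodes = episodes, meta_batch = meta_batch, lr = lr,
               lr_decay_every = lr_decay_every,
               eval_episodes = eval_episodes, seed = seed)
}

#' Learning rate at a given episode under the plan's schedule
#' @param plan a [fewshot_plan()].
#' @param episode 1-based episode index.
#' @return the decayed learning rate.
#' @export
plan_lr <- function(plan, episode) {
  plan$lr * plan$lr_decay_factor^((episode - 1) %/% plan$lr_decay_every)
}

adam_new <- function(shapes) {
  lapply(shapes, function(s) list(m = s * 0, v = s * 0))
}

adam_step <- function(param, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train and evaluate the few-shot model episodically
#'
#' Samples episodes from the training classes, optimizes the convolutional
#' embedding and the plastic readout with Adam through the unrolled
#' episodes, then evaluates on episodes drawn from the held-out classes.
#' The mean query loss is recorded every 100 episodes (the loss-history
#' construction used to monitor episodic training).
#'
#' @param bank a `glyph_bank` or `image_dataset`.
#' @param plan a [fewshot_plan()].
#' @param conv a [conv_config()]; defaults to a 16-filter embedding sized
#'   to the bank's images.
#' @param train_classes,test_classes integer class-id splits; default to a
#'   ~94%/6% split of the bank's classes (training and test classes are
#'   disjoint).
#' @param train_conv set `FALSE` to freeze the embedding at its random
#'   initialization and train only the plastic readout.
#' @return list with `model`, `history` (data frame: `episode`,
#'   `mean_loss`, `lr`), and `eval` (list: `accuracy`, `ci_low`, `ci_high`,
#'   `n`).
#' @export
train_fewshot <- function(bank, plan = scaled_fewshot_plan(), conv = NULL,
                          train_classes = NULL, test_classes = NULL,
                          train_conv = TRUE) {
  all_classes <- sort(unique(bank$labels))
  if (is.null(train_classes) || is.null(test_classes)) {
    n_train <- max(plan$n_way, floor(0.94 * length(all_classes)))
    train_classes <- train_classes %||% all_classes[seq_len(n_train)]
    test_classes <- test_classes %||% setdiff(all_classes, train_classes)
  }
  stopifnot(length(intersect(train_classes, test_classes)) == 0L)
  H <- dim(bank$images)[2]
  conv <- conv %||% conv_config(filters = 16L, input_size = H)

  with_seed(plan$seed, {
    model <- fewshot_model(conv, n_way = plan$n_way,
                           seed = sample.int(.Machine$integer.max, 1L))
    opt <- list(
      conv = lapply(model$conv_params,
                    function(p) list(W = adam_new(list(p$W))[[1]],
                                     b = adam_new(list(p$b))[[1]])),
      w = adam_new(list(model$readout$w))[[1]],
      delta = adam_new(list(model$readout$delta))[[1]],
      gamma = adam_new(list(model$readout$gamma))[[1]]
    )
    hist_rows <- list()
    loss_acc <- 0; loss_n <- 0L
    done <- 0L; step <- 0L
    while (done < plan$episodes) {
      b_sz <- min(plan$meta_batch, plan$episodes - done)
      eps_list <- lapply(seq_len(b_sz), function(i) {
        sample_episode(bank, train_classes, plan$n_way, plan$k_shot)
      })
      res <- fewshot_batch_pass(model, eps_list, plan$clamp_bonus,
                                backward = TRUE, conv_grads = train_conv)
      step <- step + 1L
      lr <- plan_lr(plan, done + 1L)
      g <- res$grads
      if (train_conv) for (m in seq_along(model$conv_params)) {
        up <- adam_step(model$conv_params[[m]]$W, g$conv[[m]]$W,
                        opt$conv[[m]]$W, lr, step)
        model$conv_params[[m]]$W <- up$param; opt$conv[[m]]$W <- up$state
        up <- adam_step(model$conv_params[[m]]$b, g$conv[[m]]$b,
                        opt$conv[[m]]$b, lr, step)
        model$conv_params[[m]]$b <- up$param; opt$conv[[m]]$b <- up$state
      }
      up <- adam_step(model$readout$w, g$w, opt$w, lr, step)
      model$readout$w <- up$param; opt$w <- up$state
      up <- adam_step(model$readout$delta, g$delta, opt$delta, lr, step)
      model$readout$delta <- up$param; opt$delta <- up$state
      up <- adam_step(model$readout$gamma, g$gamma, opt$gamma, lr, step)
      model$readout$gamma <- up$param; opt$gamma <- up$state

      done <- done + b_sz
      loss_acc <- loss_acc + res$loss * b_sz; loss_n <- loss_n + b_sz
      if (loss_n >= 100L) {
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          episode = done, mean_loss = loss_acc / loss_n,
          lr = lr)
        loss_acc <- 0; loss_n <- 0L
      }
    }
    eval <- evaluate_fewshot(model, bank, test_classes,
                             episodes = plan$eval_episodes,
                             N = plan$n_way, K = plan$k_shot,
                             clamp_bonus = plan$clamp_bonus)
    list(model = model, history = do.call(rbind, hist_rows), eval = eval,
         train_classes = train_classes, test_classes = test_classes)
  })
}

#' Evaluate a few-shot model on held-out classes
#'
#' @param model a [fewshot_model()].
#' @param bank image bank.
#' @param classes class ids to sample evaluation episodes from.
#' @param episodes number of evaluation episodes.
#' @param N,K episode shape.
#' @param seed optional seed (defaults to the ambient RNG stream).
#' @param clamp_bonus support clamp bonus.
#' @param delta_zero ablation: evaluate with the plasticity coefficients
#'   forced to zero (the trace then has no effect and accuracy falls to
#'   chance).
#' @return list with `accuracy`, binomial 95% `ci_low`/`ci_high`, `n`.
#' @export
evaluate_fewshot <- function(model, bank, classes, episodes = 200L,
                             N = 5L, K = 1L, seed = NULL, clamp_bonus = 10,
                             delta_zero = FALSE) {
  if (!is.null(seed)) {
    return(with_seed(seed, evaluate_fewshot(model, bank, classes, episodes,
                                            N, K, seed = NULL, clamp_bonus,
                                            delta_zero)))
  }
  if (delta_zero) model$readout$delta[] <- 0
  correct <- logical(0)
  done <- 0L
  while (done < episodes) {
    b_sz <- min(50L, episodes - done)
    eps_list <- lapply(seq_len(b_sz), function(i) {
      sample_episode(bank, classes, N, K)
    })
    res <- fewshot_batch_pass(model, eps_list, clamp_bonus,
                              backward = FALSE)
    correct <- c(correct, res$correct)
    done <- done + b_sz
  }
  p <- mean(correct); n <- length(correct)
  half <- 1.96 * sqrt(p * (1 - p) / n)
  list(accuracy = p, ci_low = max(0, p - half), ci_high = min(1, p + half),
       n = n)
}

#' Milestone summary of an episodic loss history
#'
#' Splits the per-100-episode loss records into evenly spaced milestone
#' blocks, reports the median loss per block and its moving average — the
#' construction used to visualize whether the median episodic loss
#' decreases as training proceeds.
#'
#' @param history the `history` data frame from [train_fewshot()].
#' @param n_blocks number of milestone blocks (default 5).
#' @return data frame with `block`, `median_loss`, `moving_average`.
#' @export
loss_milestone_summary <- function(history, n_blocks = 5L) {
  blocks <- cut(seq_len(nrow(history)), breaks = n_blocks, labels = FALSE)
  med <- vapply(seq_len(n_blocks), function(b) {
    median(history$mean_loss[blocks == b])
  }, numeric(1))
  ma <- cumsum(med) / seq_along(med)
  data.frame(block = seq_len(n_blocks), median_loss = med,
             moving_average = ma)
}
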