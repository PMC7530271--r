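test_that("parameter accounting reproduces the documented totals", {
  expect_identical(count_parameters(conv_config(), n_way = 5L), 112065L)
  # decomposition: 640 + 3 * 36928 + (320 + 320 + 1)
  expect_identical(count_parameters(conv_config(), 5L),
                   640L + 3L * 36928L + 641L)
  # readout alone at N = 5 with 64 features: 320 w + 320 delta + 1 gamma
  expect_identical(count_parameters(conv_config(), 5L) -
                     (640L + 3L * 36928L), 641L)
  # degenerate 1-way readout
  expect_identical(count_parameters(conv_config(), 1L) -
                     (640L + 3L * 36928L), 129L)
  # programmatic oracle: count the actual arrays of an instantiated model
  m <- fewshot_model(conv_config(filters = 8L), n_way = 3L, seed = 1)
  n_actual <- sum(vapply(m$conv_params,
                         function(p) length(p$W) + length(p$b), numeric(1))) +
    length(m$readout$w) + length(m$readout$delta) + 1L
  expect_identical(count_parameters(m$conv, 3L), as.integer(n_actual))
})

test_that("episode sampling honours the N-way K-shot contract", {
  bank <- small_bank()
  ep <- sample_episode(bank, 0:39, 5, 1, seed = 4)
  expect_equal(dim(ep$support_images), c(5L, 28L, 28L))
  expect_setequal(ep$support_labels, 0:4)
  expect_true(ep$query_label %in% ep$support_labels)
  expect_identical(sample_episode(bank, 0:39, 5, 1, seed = 4), ep)
  ep2 <- sample_episode(bank, 0:39, 3, 2, seed = 5)
  expect_equal(dim(ep2$support_images)[1], 6L)
  expect_equal(as.vector(table(ep2$support_labels)), rep(2L, 3))
  expect_error(sample_episode(bank, 0:2, 5, 1, seed = 1), "classes")
  expect_error(sample_episode(bank, 0:39, 5, 30, seed = 1), "classes")
})

test_that("the query sample never appears in the support set", {
  bank <- small_bank()
  for (s in 1:25) {
    ep <- sample_episode(bank, 0:39, 5, 2, seed = s)
    sup <- matrix(ep$support_images, dim(ep$support_images)[1], 28 * 28)
    q <- as.vector(ep$query_image)
    expect_false(any(apply(sup, 1, function(r) all(r == q))))
  }
})

test_that("episodes drawn from a split never leak other classes", {
  bank <- small_bank()
  for (s in 1:25) {
    ep <- sample_episode(bank, 30:39, 5, 1, seed = s)
    expect_true(all(ep$classes %in% 30:39))
  }
})

test_that("an untrained model answers at chance and handles blank input", {
  bank <- small_bank()
  model <- fewshot_model(conv_config(filters = 8L), 5, seed = 3)
  ev <- evaluate_fewshot(model, bank, 0:39, episodes = 150, seed = 11)
  expect_gt(ev$accuracy, 0.05)
  expect_lt(ev$accuracy, 0.40)
  expect_true(ev$ci_low <= ev$accuracy && ev$accuracy <= ev$ci_high)
  blank <- sample_episode(bank, 0:39, 5, 1, seed = 1)
  blank$support_images[] <- 0; blank$query_image[] <- 0
  out <- run_episode(model, blank)
  expect_true(is.finite(out$loss))
})

test_that("accuracy is invariant to the episode's label permutation", {
  bank <- small_bank()
  model <- fewshot_model(conv_config(filters = 8L), 5, seed = 3)
  # the symmetry the episodic protocol relies on: with unit-exchangeable
  # readout parameters (w rows equal, delta constant) relabelling the
  # episode cannot change the loss or the query's correctness
  model$readout$w[] <- 0
  ep <- sample_episode(bank, 0:39, 5, 1, seed = 21)
  base <- ns$fewshot_batch_pass(model, list(ep))
  # relabel: apply a permutation to the labels (same images)
  perm <- c(2L, 0L, 4L, 1L, 3L)
  ep2 <- ep
  ep2$support_labels <- perm[ep$support_labels + 1L]
  ep2$query_label <- perm[ep$query_label + 1L]
  relab <- ns$fewshot_batch_pass(model, list(ep2))
  expect_equal(relab$loss, base$loss, tolerance = 1e-10)
  expect_equal(relab$correct, base$correct)
})

test_that("run_episode with train = TRUE moves every parameter group", {
  bank <- small_bank()
  model <- fewshot_model(conv_config(filters = 8L), 5, seed = 3)
  ep <- sample_episode(bank, 0:39, 5, 1, seed = 2)
  out <- run_episode(model, ep, train = TRUE, lr = 1e-3)
  expect_false(identical(out$model$readout$w, model$readout$w))
  expect_false(identical(out$model$readout$delta, model$readout$delta))
  expect_false(identical(out$model$conv_params[[1]]$W,
                         model$conv_params[[1]]$W))
  expect_false(out$model$readout$gamma == model$readout$gamma)
})

test_that("the learning-rate schedule decays at exact episode milestones", {
  plan <- fewshot_plan()
  expect_equal(plan_lr(plan, 1), 3e-5)
  expect_equal(plan_lr(plan, 100000), 3e-5)
  expect_equal(plan_lr(plan, 100001), 3e-5 * 2 / 3)
  expect_equal(plan_lr(plan, 250000), 3e-5 * (2 / 3)^2)
  expect_equal(plan_lr(plan, 500000), 3e-5 * (2 / 3)^4)
})

test_that("a short episodic run trains, logs losses, and summarizes milestones", {
  bank <- small_bank()
  plan <- scaled_fewshot_plan(episodes = 600, eval_episodes = 50, seed = 1)
  res <- train_fewshot(bank, plan, conv = conv_config(filters = 8L),
                       train_classes = 0:29, test_classes = 30:39)
  expect_named(res$history, c("episode", "mean_loss", "lr"))
  expect_equal(nrow(res$history), 6L)
  expect_true(all(is.finite(res$history$mean_loss)))
  ms <- loss_milestone_summary(res$history, n_blocks = 3L)
  expect_equal(nrow(ms), 3L)
  expect_equal(ms$moving_average[1], ms$median_loss[1])
  expect_length(intersect(res$train_classes, res$test_classes), 0)
})

test_that("a frozen random embedding still supports above-chance binding", {
  bank <- small_bank()
  plan <- scaled_fewshot_plan(episodes = 4000, eval_episodes = 200, seed = 1)
  res <- train_fewshot(bank, plan, conv = conv_config(filters = 64L),
                       train_classes = 0:29, test_classes = 30:39,
                       train_conv = FALSE)
  expect_gt(res$eval$accuracy, 0.27)  # > 2.5 binomial SDs above chance
})
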