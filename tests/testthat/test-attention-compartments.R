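test_that("activity factor normalizes mean by the regional maximum", {
  expect_equal(activity_factor(list(rep(0.7, 5))), 1)
  expect_equal(activity_factor(list(c(0.2, 0.4, 0.8, 0.6))), 0.5 / 0.8)
  expect_equal(activity_factor(list(rep(0, 4))), 0)
  expect_error(activity_factor(list(numeric(0))), "empty region")
  acts <- list(runif(7), runif(3), runif(5))
  expect_equal(activity_factor(acts), oracle_activity_factor(acts),
               tolerance = 1e-12)
})

test_that("attention scales updates by region activity without sign flips", {
  region <- rep(1:2, each = 3)
  W <- matrix(0, 2, 6)
  dW <- matrix(rnorm(12), 2, 6)
  # A_k = 0: no update at all for that region
  W1 <- attention_update(W, dW, region, A = c(0, 1), active = c(TRUE, TRUE))
  expect_equal(W1[, 1:3], matrix(0, 2, 3))
  expect_equal(W1[, 4:6], dW[, 4:6])
  # identical pending updates scale 2:1 for activities 1 vs 0.5
  same <- matrix(rnorm(6), 2, 3)
  W2 <- attention_update(W, cbind(same, same), region, A = c(1, 0.5),
                         active = c(TRUE, TRUE))
  expect_equal(W2[, 1:3], 2 * W2[, 4:6], tolerance = 1e-12)
  # scaling never flips the update's sign
  pend <- cbind(same, same)
  expect_true(all(sign(W2[W2 != 0]) == sign(pend[W2 != 0])))
})

test_that("inhibition decays weights monotonically to an exact, sticky zero", {
  W <- matrix(c(0.3, -0.2, 0, 0.05), 2, 2)
  pending <- matrix(0.04, 2, 2)
  pruned <- NULL
  prev <- W
  for (i in 1:20) {
    r <- inhibit_region(prev, pending, A_k = 0.5, pruned = pruned)
    expect_true(all(r$W[prev > 0] <= prev[prev > 0]))
    expect_true(all(r$W[prev < 0] >= prev[prev < 0]))
    expect_true(all(sign(r$W) == sign(prev) | r$W == 0))
    prev <- r$W; pruned <- r$pruned
  }
  expect_equal(prev, matrix(0, 2, 2))      # fully pruned in bounded steps
  expect_true(all(pruned))
  # zero weights stay zero
  r0 <- inhibit_region(matrix(0, 2, 2), pending, A_k = 0.9)
  expect_equal(r0$W, matrix(0, 2, 2))
})

test_that("a persistently silent region is detected and fully pruned", {
  # region 1's hidden neurons are driven hard negative: near-zero activity
  task <- make_vector_task(10, 100, 100, separation = 6, noise_sd = 0.5,
                           seed = 2)
  task$features <- abs(task$features)
  cfg <- modnet_config(100, 10, seed = 1)
  st <- modnet_init(cfg)
  region <- ns$region_index(cfg$n_hidden, 10)
  st$W_proj[region == 1, ] <- -abs(st$W_proj[region == 1, ]) * 5
  res <- modnet_train(st, task, attention = attention_spec(seed = 1))
  att <- attr(res$state, "attention")
  expect_lt(att$A[1], 0.1)                      # inhibited
  expect_true(all(att$active[-1]))              # healthy regions untouched
  expect_false(is.unsorted(res$history$pruned_fraction))
  expect_gt(mean(att$pruned[, region == 1]), 0) # pruning under way
  # bounded continuation: repeated inhibition empties the region entirely
  Wr <- res$state$W[, region == 1, drop = FALSE]
  pr <- att$pruned[, region == 1, drop = FALSE]
  for (i in 1:5000) {
    if (all(Wr == 0)) break
    r <- inhibit_region(Wr, matrix(1e-2, nrow(Wr), ncol(Wr)),
                        A_k = att$A[1], pruned = pr)
    Wr <- r$W; pr <- r$pruned
  }
  expect_equal(mean(pr), 1)
})

test_that("covariance rule is multiplicative with thresholded correlations", {
  cfg <- list(cov_eta = 0.01, s1 = 0.5, s2 = 0.5)
  W <- matrix(0.2, 1, 1)
  expect_equal(covariance_update(W, pre_acts = 0.5, post_acts = 0.9, cfg), W)
  expect_equal(covariance_update(W, 1, 1, cfg) - W,
               matrix(0.01 * 0.5 * 0.5 * 0.2, 1, 1), tolerance = 1e-15)
  expect_equal(covariance_update(matrix(0, 3, 3), runif(3), runif(3), cfg),
               matrix(0, 3, 3))
  # loop oracle on a random case
  W2 <- matrix(rnorm(12), 3, 4)
  pre <- runif(4); post <- runif(3)
  expect_lt(max(abs(covariance_update(W2, pre, post, cfg) -
                      oracle_covariance_update(W2, pre, post, cfg))), 1e-12)
})

test_that("compartment gating requires two consecutive low evaluations", {
  gs <- gate_compartments(c(0.02, 0.8, 0.9), NULL, threshold = 0.1)
  expect_equal(gs$gated, c(FALSE, FALSE, FALSE))   # one strike only
  gs <- gate_compartments(c(0.02, 0.8, 0.9), gs, threshold = 0.1)
  expect_equal(gs$gated, c(TRUE, FALSE, FALSE))    # second strike gates
  # equal healthy activity gates nothing; gating is idempotent
  gs2 <- gate_compartments(rep(0.5, 3), NULL, threshold = 0.1)
  expect_false(any(gs2$gated))
  gs3 <- gate_compartments(c(0.02, 0.8, 0.9), gs, threshold = 0.1)
  expect_equal(gs3$gated, gs$gated)
  # an intervening healthy evaluation resets the counter
  gs4 <- gate_compartments(c(0.5, 0.05, 0.5), NULL)
  gs4 <- gate_compartments(c(0.5, 0.5, 0.5), gs4)
  gs4 <- gate_compartments(c(0.5, 0.05, 0.5), gs4)
  expect_false(any(gs4$gated))
  bad <- list(consec_low = rep(5L, 2), gated = c(TRUE, FALSE))
  expect_error(gate_compartments(c(0.01, 0.01), bad), "degenerate")
})

test_that("pruned fraction grows monotonically and is init-insensitive", {
  task <- sep_task()
  cfg <- modnet_config(100, 10, seed = 1)
  finals <- sapply(c(0, 0.5), function(sp) {
    att <- attention_spec(activity_threshold = 0.75, sparse_init = sp,
                          seed = 1)
    res <- modnet_train(modnet_init(cfg), task, attention = att)
    expect_false(is.unsorted(res$history$pruned_fraction))
    tail(res$history$zero_fraction, 1)
  })
  # dense and half-sparse starts converge to nearby final sparsity
  expect_lt(abs(finals[1] - finals[2]), 0.15)
})

test_that("attention at the default threshold keeps accuracy near baseline", {
  base <- trained_modnet()
  cfg <- modnet_config(100, 10, seed = 1)
  att <- modnet_train(modnet_init(cfg), sep_task(),
                      attention = attention_spec(seed = 1))
  expect_gte(modnet_accuracy(att$state, sep_test()),
             modnet_accuracy(base$state, sep_test()) - 0.05)
})

test_that("the compartmentalized network learns and prunes more than attention-only", {
  task <- sep_task()
  test <- sep_test()
  pr_att <- numeric(2); pr_comp <- numeric(2)
  for (s in 1:2) {
    att <- attention_spec(activity_threshold = 0.75, seed = s)
    mres <- modnet_train(modnet_init(modnet_config(100, 10, n_hidden = 300,
                                                   seed = s)),
                         task, attention = att)
    pr_att[s] <- tail(mres$history$pruned_fraction, 1)
    ccfg <- compartment_config(100, 10, n_hidden1 = 300, n_hidden2 = 300,
                               attention = att, seed = s)
    cres <- compartment_train(compartment_init(ccfg), task)
    expect_false(is.unsorted(cres$history$pruned_fraction))
    pr_comp[s] <- tail(cres$history$pruned_fraction, 1)
  }
  expect_true(all(pr_comp >= pr_att))
  # at the default (non-aggressive) threshold the deep variant still learns
  ccfg <- compartment_config(100, 10, n_hidden1 = 300, n_hidden2 = 300,
                             seed = 1)
  cres <- compartment_train(compartment_init(ccfg), task)
  expect_gt(compartment_accuracy(cres$state, test), 0.5)
})

test_that("history records per-evaluation compartment activity", {
  ccfg <- compartment_config(20, 4, n_hidden1 = 40, n_hidden2 = 40,
                             n_compartments = 4, seed = 2)
  task <- make_vector_task(4, 20, 60, separation = 5, noise_sd = 1, seed = 4)
  cres <- compartment_train(compartment_init(ccfg), task, epochs = 1)
  expect_named(cres$history,
               c("samples", "epoch", "accuracy", "mean_abs_M",
                 "pruned_fraction", "gated1", "gated2", "mean_A2"))
  expect_true(all(cres$history$mean_A2 >= 0 & cres$history$mean_A2 <= 1))
})
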