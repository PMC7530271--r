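tiny_state <- function(seed = 1, n_in = 6, n_hidden = 6, n_out = 4, ...) {
  cfg <- modnet_config(n_in, n_out, n_hidden = n_hidden, seed = seed, ...)
  modnet_init(cfg)
}

test_that("forward pass matches the sigmoid-of-dot-product definition", {
  st <- tiny_state()
  st$W[] <- 0
  fw <- modnet_forward(st, rep(0.3, 6))
  expect_equal(fw$output, rep(0.5, 4))

  st1 <- tiny_state(n_in = 2, n_hidden = 2, n_out = 1)
  st1$W[1, ] <- c(0.5, 0.25)
  h <- c(1, 2)
  # bypass the projection: check the output stage on known hidden values
  out <- 1 / (1 + exp(-(st1$W %*% h)))
  expect_equal(out[1], 1 / (1 + exp(-1)), tolerance = 1e-10)

  fw2 <- modnet_forward(st, runif(6, -3, 3))
  expect_true(all(fw2$hidden > 0 & fw2$hidden < 1))
  expect_true(all(fw2$output > 0 & fw2$output < 1))
  expect_error(modnet_forward(st, rep(0, 5)), "n_in")
})

test_that("modulatory activation is the loop-oracle matrix product", {
  st <- tiny_state()
  expect_equal(modulatory_activation(st, rep(0, 4)), rep(0, 4))
  st$W_mod <- diag(4)
  expect_equal(modulatory_activation(st, c(1, -0.2, 0, 0.5)),
               c(1, -0.2, 0, 0.5))
  st$W_mod <- matrix(rnorm(16), 4, 4)
  e <- rnorm(4)
  expect_equal(modulatory_activation(st, e),
               oracle_modulatory_activation(st$W_mod, e), tolerance = 1e-12)
})

test_that("plasticity term combines correlation, difference, and bias terms", {
  st <- tiny_state(n_in = 2, n_hidden = 2, n_out = 1)
  cfg <- st$config
  # no activity: only the bias survives
  d0 <- plasticity_term(st, c(0, 0), 0, cfg)
  expect_equal(d0, st$eta * cfg$beta3, ignore_attr = TRUE)
  # hand evaluation at eta = 0.001, x_i = 0.8, x_j = 0.5
  st$eta[] <- 0.001
  d <- plasticity_term(st, c(0.5, 0.5), 0.8, cfg)
  expect_equal(d[1, 1], 0.001 * (0.1 * 0.8 * 0.5 + 0.2 * (0.5 - 0.8) + 0.001),
               tolerance = 1e-15)
  expect_equal(d[1, 1], -1.9e-5, tolerance = 1e-12)
  # correlation-only limit: sign(delta) == sign(eta * x_i * x_j)
  cfg2 <- st$config; cfg2$beta2 <- 0; cfg2$beta3 <- 0
  st$eta <- matrix(rnorm(2), 1, 2)
  h <- runif(2); o <- runif(1)
  d2 <- plasticity_term(st, h, o, cfg2)
  expect_equal(sign(d2), sign(st$eta * o * rbind(h)), ignore_attr = TRUE)
})

test_that("adaptive rate: divisive form, zero special case, clipping", {
  st <- tiny_state()
  cfg <- st$config
  # e_i = 0 resets the whole row to eta_in
  st2 <- adapt_learning_rate(st, error = rep(0, 4), output = runif(4), cfg)
  expect_true(all(st2$eta == cfg$eta_in))
  # tiny product clips at eta_clip instead of exploding
  st3 <- adapt_learning_rate(st, error = c(1e-9, 1, 1, 1) * 1e-0,
                             output = c(1e-0, 0.5, 0.5, 0.5), cfg)
  expect_equal(abs(st3$eta[1, 1]), cfg$eta_clip)
  # |eta| = eta_in / (e x) before polarity: 0.001/(0.5*0.4) = 0.005
  cfg4 <- modnet_config(6, 4, n_hidden = 6, eta_in = 0.001)
  st4 <- modnet_init(cfg4)
  st4 <- adapt_learning_rate(st4, error = c(0.5, 0, 0, 0),
                             output = c(0.4, 0.5, 0.5, 0.5), cfg4)
  expect_equal(abs(st4$eta[1, 1]), 0.005, tolerance = 1e-12)
})

test_that("standard weight update is the sigmoid-gated plasticity term", {
  st <- tiny_state()
  cfg <- st$config
  h <- runif(6); o <- runif(4)
  # zero modulatory weights make M = 0: gate is exactly 0.5
  st$W_mod[] <- 0
  delta <- plasticity_term(st, h, o, cfg)
  st2 <- update_standard_weights(st, h, o, error = runif(4), cfg)
  expect_equal(st2$W - st$W, 0.5 * delta, tolerance = 1e-12)
  # zero plasticity leaves the weights untouched
  st$eta[] <- 0
  cfg0 <- cfg; cfg0$beta3 <- 0
  st3 <- update_standard_weights(st, h, o, error = runif(4), cfg0)
  expect_equal(st3$W, st$W)
})

test_that("modulatory weight update: zero error is a no-op, sign follows error", {
  st <- tiny_state()
  cfg <- st$config
  o <- runif(4)
  st2 <- update_modulatory_weights(st, error = rep(0, 4), output = o, cfg)
  expect_identical(st2$W_mod, st$W_mod)
  e <- c(0.8, -0.3, 0.1, -0.9)
  st3 <- update_modulatory_weights(st, e, o, cfg)
  dmod <- st3$W_mod - st$W_mod
  expect_equal(sign(dmod), matrix(sign(e), 4, 4), ignore_attr = TRUE)
  # magnitude equals |eta'| * scale exactly on a 2x2 case
  cfg2 <- modnet_config(2, 2, n_hidden = 2, mod_eta_in = 0.004,
                        mod_scale = 2.5)
  st4 <- modnet_init(cfg2)
  st5 <- update_modulatory_weights(st4, c(0.5, -0.2), c(0.6, 0.3), cfg2)
  expect_equal(abs(st5$W_mod - st4$W_mod),
               matrix(abs(c(0.004 * 0.5 * 0.6, 0.004 * 0.2 * 0.3)) * 2.5,
                      2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("vectorized per-sample update equals the per-synapse loop oracle", {
  for (case in 1:20) {
    st <- tiny_state(seed = case, n_in = 4, n_hidden = 6, n_out = 3)
    cfg <- st$config
    x <- runif(4, -2, 2)
    fw <- modnet_forward(st, x)
    y <- case %% 3
    e <- -fw$output; e[y + 1] <- e[y + 1] + 1
    st <- adapt_learning_rate(st, e, fw$output, cfg, hidden = fw$hidden)
    expect_equal(matrix(oracle_eta(e, fw$output, cfg), 3, 6), st$eta,
                 tolerance = 1e-12, ignore_attr = TRUE)
    dW_vec <- ns$standard_weight_delta(st, fw$hidden, fw$output, e, cfg)
    dW_loop <- oracle_standard_update(st$W, st$W_mod, st$eta, fw$hidden,
                                      fw$output, e, cfg)
    expect_lt(max(abs(dW_vec - dW_loop)), 1e-10)
    st2 <- update_modulatory_weights(st, e, fw$output, cfg)
    expect_lt(max(abs(st2$W_mod -
                        oracle_modulatory_update(st$W_mod, e, fw$output,
                                                 cfg))), 1e-10)
  }
})

test_that("training learns the separable task and leaves the projection fixed", {
  res <- trained_modnet()
  expect_gt(modnet_accuracy(res$state, sep_test()), 0.85)
  cfg <- modnet_config(100, 10, seed = 1)
  expect_identical(res$state$W_proj, modnet_init(cfg)$W_proj)
  # history schema: one row per 100 samples
  expect_named(res$history,
               c("samples", "epoch", "accuracy", "mean_abs_M",
                 "pruned_fraction", "zero_fraction"))
  expect_equal(res$history$samples, seq(100, 4000, by = 100))
  expect_error(modnet_train(modnet_init(cfg),
                            list(features = matrix(0, 2, 100),
                                 labels = c(0L, 10L))),
               "labels")
})

test_that("zero-separation training stays at chance", {
  task <- make_vector_task(10, 100, 100, separation = 0, noise_sd = 1,
                           seed = 2)
  cfg <- modnet_config(100, 10, seed = 2)
  res <- modnet_train(modnet_init(cfg), task)
  held <- sample_vector_task(task, 50, seed = 3)
  expect_lt(modnet_accuracy(res$state, held), 0.2)
})

test_that("modulatory activation is strongest early in training", {
  res <- trained_modnet()
  m <- res$history$mean_abs_M
  q <- length(m) %/% 4
  expect_gte(m[1], mean(tail(m, q)))
})

test_that("all state stays finite under a long random-input stress run", {
  st <- tiny_state(seed = 9, n_in = 4, n_hidden = 6, n_out = 3)
  cfg <- st$config
  xs <- ns$with_seed(99, matrix(runif(10000 * 4, -5, 5), 10000, 4))
  ys <- ns$with_seed(98, sample(0:2, 10000, replace = TRUE))
  for (s in seq_len(10000)) {
    fw <- modnet_forward(st, xs[s, ])
    e <- -fw$output; e[ys[s] + 1] <- e[ys[s] + 1] + 1
    st <- adapt_learning_rate(st, e, fw$output, cfg, hidden = fw$hidden)
    st <- update_standard_weights(st, fw$hidden, fw$output, e, cfg)
    st <- update_modulatory_weights(st, e, fw$output, cfg)
  }
  expect_true(all(is.finite(st$W)))
  expect_true(all(is.finite(st$W_mod)))
  expect_true(all(is.finite(st$eta)))
  expect_true(all(abs(st$eta) <= cfg$eta_clip))
})

test_that("a larger hidden expansion never hurts on the separable task", {
  acc <- sapply(c(100L, 2500L), function(nh) {
    mean(sapply(1:5, function(s) {
      task <- make_vector_task(10, 100, 100, separation = 6, noise_sd = 1,
                               seed = s)
      cfg <- modnet_config(100, 10, n_hidden = nh, seed = s)
      res <- modnet_train(modnet_init(cfg), task)
      modnet_accuracy(res$state, sample_vector_task(task, 30, s + 500))
    }))
  })
  expect_gte(acc[2], acc[1])
})
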