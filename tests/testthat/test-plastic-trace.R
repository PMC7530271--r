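test_that("effective weight is w + delta * Mod elementwise", {
  ro <- plastic_readout(2, 3, seed = 1)
  expect_equal(effective_weight(ro), ro$w)          # Mod starts at 0
  ro$delta[] <- 0; ro$Mod[] <- rnorm(6)
  expect_equal(effective_weight(ro), ro$w)          # plasticity disabled
  ro$w[] <- 1; ro$delta[] <- 0.5; ro$Mod[] <- 2
  expect_equal(effective_weight(ro), matrix(2, 2, 3))
})

test_that("forward pass is a softmax with optional label clamping", {
  ro <- plastic_readout(5, 4, seed = 2)
  out0 <- plastic_forward(ro, rep(0, 4))
  expect_equal(out0, rep(0.2, 5), tolerance = 1e-12)  # zero input: uniform
  x <- runif(4)
  out_clamp <- plastic_forward(ro, x, label = 3L, clamp_bonus = 50)
  expect_gt(out_clamp[4], 0.999)                      # clamp dominates
  for (i in 1:5) {
    out <- plastic_forward(ro, runif(4, -2, 2), label = sample(0:4, 1))
    expect_equal(sum(out), 1, tolerance = 1e-12)
  }
})

test_that("the context rate alpha is gamma times a squashed output sum", {
  expect_equal(trace_alpha(rep(0, 5), 0.02), 0.01)
  probs <- rep(0.2, 5)  # softmax output: sums to 1, n = 5
  expect_equal(trace_alpha(probs, 0.02), 0.02 / (1 + exp(-0.2)),
               tolerance = 1e-12)
  for (i in 1:10) {
    a <- trace_alpha(runif(5), 0.02)
    expect_gt(a, 0); expect_lt(a, 0.02)
  }
})

test_that("repeated trace updates converge to the x_in/x_out fixed point", {
  ro <- plastic_readout(1, 1, gamma_init = 0.02, seed = 1)
  ro <- reset_trace(ro)
  for (i in 1:5000) ro <- trace_update(ro, 0.6, 0.5)
  expect_lt(abs(ro$Mod[1, 1] - 1.2), 1e-3)
  # zero output leaves the trace unchanged
  ro2 <- reset_trace(plastic_readout(2, 2, seed = 2))
  ro2$Mod[] <- rnorm(4)
  before <- ro2$Mod
  ro2 <- trace_update(ro2, runif(2), c(0, 0))
  expect_equal(ro2$Mod, before)
})

test_that("vectorized trace update equals the per-connection loop oracle", {
  for (case in 1:10) {
    set.seed(case)
    ro <- plastic_readout(3, 4, gamma_init = 0.05, seed = case)
    ro$Mod[] <- rnorm(12)
    x_in <- runif(4); x_out <- runif(3)
    a <- trace_alpha(x_out, ro$gamma)
    upd <- trace_update(ro, x_in, x_out)
    expect_lt(max(abs(upd$Mod -
                        oracle_trace_update(ro$Mod, x_in, x_out, a))),
              1e-12)
  }
})

test_that("trace reset zeroes Mod exactly, idempotently, and nothing else", {
  ro <- plastic_readout(3, 4, seed = 5)
  ro$Mod[] <- rnorm(12)
  keep <- ro[c("w", "delta", "gamma")]
  r1 <- reset_trace(ro)
  expect_identical(r1$Mod, matrix(0, 3, 4))
  expect_identical(r1[c("w", "delta", "gamma")], keep)
  expect_identical(reset_trace(r1), r1)
})

test_that("the trace stays bounded over a long random stress run", {
  ro <- plastic_readout(4, 6, gamma_init = 0.02, seed = 7)
  ro <- reset_trace(ro)
  xs <- ns$with_seed(1, matrix(runif(10000 * 6), 10000, 6))
  os <- ns$with_seed(2, matrix(runif(10000 * 4), 10000, 4))
  worst <- 0
  for (s in 1:10000) {
    ro <- trace_update(ro, xs[s, ], os[s, ])
    worst <- max(worst, max(abs(ro$Mod)))
  }
  expect_lt(worst, 10 * max(xs))
})

test_that("one clamped presentation binds a pattern to its label", {
  correct <- logical(100)
  for (trial in 1:100) {
    set.seed(trial)
    n_in <- 12; N <- 5
    ro <- plastic_readout(N, n_in, delta_init = 1, gamma_init = 1,
                          w_scale = 0, seed = trial)
    pats <- matrix(rnorm(n_in * N), n_in, N)   # centred random patterns
    ro <- reset_trace(ro)
    cl <- sample(0:(N - 1), 1)
    xo <- plastic_forward(ro, pats[, cl + 1], label = cl, clamp_bonus = 20)
    ro <- trace_update(ro, pats[, cl + 1], xo)
    pred <- which.max(plastic_forward(ro, pats[, cl + 1])) - 1L
    correct[trial] <- pred == cl
  }
  expect_gt(mean(correct), 1 / 5)
})

test_that("autodiff through the unrolled episode matches finite differences", {
  set.seed(42)
  n_out <- 3; n_in <- 4; B <- 2; T_steps <- 4
  ro <- plastic_readout(n_out, n_in, w_scale = 0.3, seed = 5)
  x_steps <- lapply(1:T_steps, function(t) matrix(runif(n_in * B), n_in, B))
  labels <- list(c(0L, 1L), c(1L, 2L), c(2L, 0L), NULL)
  target <- c(2L, 1L)
  loss_of <- function(r, xs = x_steps) {
    ns$readout_episode_forward(r, xs, labels, target, clamp_bonus = 3)$loss
  }
  fwd <- ns$readout_episode_forward(ro, x_steps, labels, target,
                                    clamp_bonus = 3)
  bk <- ns$readout_episode_backward(ro, fwd, target, need_dx = TRUE)
  h <- 1e-6
  for (pn in c("w", "delta")) {
    idx <- sample(length(ro[[pn]]), 6)
    num <- sapply(idx, function(i) {
      r2 <- ro; r2[[pn]][i] <- r2[[pn]][i] + h
      r3 <- ro; r3[[pn]][i] <- r3[[pn]][i] - h
      (loss_of(r2) - loss_of(r3)) / (2 * h)
    })
    ana <- if (pn == "w") bk$dw[idx] else bk$ddelta[idx]
    expect_lt(max(abs(num - ana) / (abs(num) + 1e-6)), 1e-4)
  }
  r2 <- ro; r2$gamma <- ro$gamma + h
  r3 <- ro; r3$gamma <- ro$gamma - h
  numg <- (loss_of(r2) - loss_of(r3)) / (2 * h)
  expect_lt(abs(numg - bk$dgamma) / (abs(numg) + 1e-6), 1e-4)
  for (t in c(1L, T_steps)) {
    idx <- sample(length(x_steps[[t]]), 4)
    num <- sapply(idx, function(i) {
      xs2 <- x_steps; xs2[[t]][i] <- xs2[[t]][i] + h
      xs3 <- x_steps; xs3[[t]][i] <- xs3[[t]][i] - h
      (loss_of(ro, xs2) - loss_of(ro, xs3)) / (2 * h)
    })
    expect_lt(max(abs(num - bk$dX[[t]][idx]) / (abs(num) + 1e-6)), 1e-3)
  }
})
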