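# SGD step, training loops, and the early-break rule.

test_that("sgd_step applies theta - alpha * grad across structures", {
  expect_equal(sgd_step(2, 1, 0.5), 1.5)
  th <- list(W = matrix(1:4, 2), b = c(1, 2))
  expect_equal(sgd_step(th, th, 0), th)
  two <- sgd_step(sgd_step(5, 2, 0.3), 2, 0.3)
  expect_equal(two, 5 - 2 * 0.3 * 2)
  g <- list(W = matrix(0.5, 2, 2), b = c(0.1, 0.1))
  out <- sgd_step(th, g, 1)
  expect_equal(out$W, th$W - 0.5)
  expect_error(sgd_step(th, list(W = matrix(1, 3, 3)), 0.1), "mismatch")
})

test_that("sgd_train is seeded, decreases a smooth objective, no break", {
  p <- random_cae(3, 2, seed = 1)
  X <- matrix(runif(60, -0.4, 0.4), 20, 3)
  cfg <- fsgd_config(n = 15, alpha = 0.3, epsilon = 1e-9, K = 1,
                     seed = 42)
  f1 <- sgd_train(p, X, cfg)
  f2 <- sgd_train(p, X, cfg)
  expect_identical(f1$model$W_enc, f2$model$W_enc)
  expect_identical(f1$history$losses, f2$history$losses)
  expect_equal(f1$history$break_epoch, 15L)
  expect_false(f1$history$broke_early)
  # epsilon tiny, yet sgd_train never breaks: full budget always runs
  expect_length(f1$history$losses, 15L)
  # overall descent on a smooth problem
  expect_lt(mean(tail(f1$history$losses, 3)),
            mean(head(f1$history$losses, 3)))
  expect_error(sgd_train(p, X[0, , drop = FALSE], cfg), "empty")
})

test_that("one epoch on one sample performs exactly one step", {
  p <- random_cae(2, 1, seed = 3)
  x <- matrix(c(0.2, -0.3), 1)
  cfg <- fsgd_config(n = 1, alpha = 0.25, epsilon = 1e-9, K = 1,
                     seed = 7)
  fit <- sgd_train(p, x, cfg, loss_config(0))
  g <- gradients(x, x, p, loss_config(0))
  expect_equal(fit$model$W_enc, p$W_enc - 0.25 * g$W_enc)
  expect_equal(fit$model$b_dec, p$b_dec - 0.25 * g$b_dec)
})

test_that("break rule traces match the published counter semantics", {
  # loss first at/below epsilon at epoch 80, stays below, K = 100: the
  # crossing epoch counts, so the counter reaches K at epoch 179 (the
  # reference trace rounds this to "epoch 180" as 80 + 100)
  losses <- c(seq(1, 0.004, length.out = 79), rep(0.002, 400))
  br <- fsgd_break_epoch(losses, epsilon = 0.003, K = 100)
  expect_equal(br$break_epoch, 179L)
  expect_true(br$broke_early)
  # fine-tuning trace: at epsilon from epoch 52, window 10 (52 + 10
  # reported as "epoch 62"; counter-exact break is 61)
  losses2 <- c(seq(1, 0.0021, length.out = 51), rep(0.0015, 100))
  br2 <- fsgd_break_epoch(losses2, epsilon = 0.002, K = 10)
  expect_equal(br2$break_epoch, 61L)
  # counter resets on an epoch above epsilon
  losses3 <- c(0.001, 0.001, 0.5, 0.001, 0.001, 0.001)
  expect_equal(fsgd_break_epoch(losses3, 0.003, 3)$break_epoch, 6L)
  expect_equal(fsgd_break_epoch(losses3, 0.003, 3,
                                reset = FALSE)$break_epoch, 4L)
  # never attained -> no break
  expect_false(fsgd_break_epoch(rep(1, 10), 0.003, 2)$broke_early)
})

test_that("fsgd_train breaks per rule and matches sgd_train prefix", {
  p <- random_cae(3, 2, seed = 5)
  X <- matrix(runif(90, -0.4, 0.4), 30, 3)
  # epsilon far above any loss: immediate qualification, K epochs run
  hi <- fsgd_config(n = 50, alpha = 0.1, epsilon = 1e6, K = 3, seed = 9)
  fhi <- fsgd_train(p, X, hi)
  expect_equal(fhi$history$break_epoch, 3L)
  expect_true(fhi$history$broke_early)
  # epsilon below attainable: full budget, no break
  lo <- fsgd_config(n = 12, alpha = 0.1, epsilon = 1e-12, K = 2,
                    seed = 9)
  flo <- fsgd_train(p, X, lo)
  expect_false(flo$history$broke_early)
  expect_equal(flo$history$break_epoch, 12L)
  # prefix equivalence: identical seeds -> bit-identical trajectories
  cfg_s <- fsgd_config(n = 12, alpha = 0.1, epsilon = 1e-12, K = 2,
                       seed = 9)
  fs <- sgd_train(p, X, cfg_s)
  expect_identical(flo$history$losses, fs$history$losses)
  expect_identical(flo$model$W_enc, fs$model$W_enc)
  expect_identical(flo$model$b_dec, fs$model$b_dec)
})

test_that("fsgd break bookkeeping is consistent with its own history", {
  p <- random_cae(3, 2, seed = 6, act = det_act())
  X <- matrix(runif(30, -0.1, 0.1), 10, 3)
  cfg <- fsgd_config(n = 200, alpha = 0.5, epsilon = 0.01, K = 5,
                     seed = 3)
  fit <- fsgd_train(p, X, cfg, loss_config(0))
  h <- fit$history
  expect_lte(h$break_epoch, cfg$n)
  expect_length(h$losses, h$break_epoch)
  if (h$broke_early) {
    expect_true(all(tail(h$losses, cfg$K) <= cfg$epsilon))
    br <- fsgd_break_epoch(h$losses, cfg$epsilon, cfg$K)
    expect_equal(br$break_epoch, h$break_epoch)
  }
})

test_that("noisy training with the same seed is still deterministic", {
  act <- activation_config(sigma = 0.1, train_mode = TRUE)
  p <- random_cae(3, 2, seed = 2, act = act)
  X <- matrix(runif(30, -0.4, 0.4), 10, 3)
  cfg <- fsgd_config(n = 5, alpha = 0.2, epsilon = 1e-9, K = 1,
                     seed = 77)
  f1 <- sgd_train(p, X, cfg)
  f2 <- sgd_train(p, X, cfg)
  expect_identical(f1$model$W_dec, f2$model$W_dec)
  f3 <- sgd_train(p, X, fsgd_config(n = 5, alpha = 0.2, epsilon = 1e-9,
                                    K = 1, seed = 78))
  expect_false(identical(f1$model$W_dec, f3$model$W_dec))
})

test_that("holdout monitoring trains on the remainder only", {
  p <- random_cae(3, 2, seed = 8)
  X <- matrix(runif(120, -0.4, 0.4), 40, 3)
  cfg <- fsgd_config(n = 6, alpha = 0.2, epsilon = 1e-9, K = 1,
                     seed = 5, monitor = "holdout", holdout_frac = 0.25)
  fit <- fsgd_train(p, X, cfg)
  expect_length(fit$history$losses, 6L)
  expect_true(all(is.finite(fit$history$losses)))
})

test_that("epsilon proposal returns a plausible positive threshold", {
  p <- random_cae(3, 2, seed = 4)
  X <- matrix(runif(150, -0.4, 0.4), 50, 3)
  eps <- propose_epsilon(p, X, fsgd_config(n = 20, alpha = 0.2,
                                           epsilon = 1, K = 1, seed = 1))
  expect_gt(eps, 0)
  fit <- sgd_train(p, X, fsgd_config(n = 20, alpha = 0.2, epsilon = 1,
                                     K = 1, seed = 1))
  expect_lt(eps, max(fit$history$losses) * 2)
})

test_that("history serialises to delimited text and back", {
  h <- train_history(c(0.5, 0.1, 0.05), 3L, TRUE, 10L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_history(h, path)
  h2 <- read_history(path)
  expect_identical(h2$losses, h$losses)
  expect_identical(h2$break_epoch, h$break_epoch)
  expect_identical(h2$broke_early, h$broke_early)
})
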