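# Activation, autoencoder forward passes, losses and analytic gradients.

test_that("improved sigmoid matches closed forms and rejects bad input", {
  expect_identical(improved_sigmoid(0, det_act()), 0)
  expect_equal(improved_sigmoid(log(3), det_act(k = 2)), 0.5)
  # saturation: within 1e-12 of the supremum at a = 40
  expect_lt(0.5 - improved_sigmoid(40, det_act()), 1e-12)
  expect_error(improved_sigmoid(NaN, det_act()), "non-finite")
  expect_error(improved_sigmoid(Inf, det_act()), "non-finite")
  expect_error(activation_config(k = 0), "k > 0")
})

test_that("activation range, symmetry and Taylor agreement hold", {
  set.seed(1)
  for (rep in 1:20) {
    k <- runif(1, 0.5, 3); c <- runif(1, 0.5, 3)
    a <- runif(50, -60, 60)
    act <- det_act(k, c)
    f <- improved_sigmoid(a, act)
    # mathematically strict; at saturation the bound closes in doubles
    expect_true(all(abs(f) <= 0.5 * k))
    amod <- runif(50, -8, 8)
    fm <- improved_sigmoid(amod, act)
    expect_true(all(abs(fm) < 0.5 * k))
    expect_identical(improved_sigmoid(-a, act), -f)
  }
  a <- seq(-0.1, 0.1, length.out = 201)
  expect_lt(max(abs(improved_sigmoid(a, det_act()) -
                    taylor_reference(a, det_act(), 5L))), 1e-6)
  # remainder shrinks with order near 0
  expect_equal(taylor_reference(0, det_act(3, 2), 5L), 0)
  expect_equal(taylor_reference(0.2, det_act(3, 2), 1L), 0.3)
  expect_error(taylor_reference(0.1, det_act(), order = 2L), "order")
})

test_that("noisy preactivation is exact without noise, calibrated with", {
  act <- activation_config(sigma = 0, train_mode = TRUE)
  expect_equal(noisy_preactivation(diag(2), c(1, 2), c(0, 0), act),
               c(1, 2))
  W <- matrix(rnorm(6), 2, 3); x <- rnorm(3); b <- rnorm(2)
  expect_equal(noisy_preactivation(W, x, b, act), drop(W %*% x) + b)
  expect_error(noisy_preactivation(W, rnorm(4), b, act), "shape")
  # law of large numbers on the Gaussian unit at W x + b = 0
  nact <- activation_config(sigma = 1, train_mode = TRUE)
  set.seed(99)
  draws <- replicate(1e5, 0)  # preallocate shape
  draws <- vapply(seq_len(1e5), function(i)
    noisy_preactivation(matrix(0, 1, 1), 0, 0, nact), numeric(1))
  expect_lt(abs(mean(draws)), 3 * 10^-2.5)
  expect_lt(abs(sd(draws) - 1), 0.01)
  # eval mode: sigma inactive
  eact <- activation_config(sigma = 1, train_mode = FALSE)
  expect_equal(noisy_preactivation(W, x, b, eact), drop(W %*% x) + b)
})

test_that("encode/decode honour shapes and degenerate weights", {
  p <- cae_params(matrix(0, 2, 3), c(0, 0), matrix(0, 3, 2), c(0, 0, 0),
                  det_act())
  expect_equal(encode(c(1, 2, 3), p), c(0, 0))
  expect_equal(decode(c(0.3, -0.2), p), c(0, 0, 0))
  q <- random_cae(4, 2, seed = 5)
  expect_length(encode(rnorm(4), q), 2L)
  expect_length(decode(rnorm(2), q), 4L)
  expect_error(encode(rnorm(3), q), "shape")
  expect_error(cae_params(matrix(0, 2, 3), c(0, 0), matrix(0, 4, 2),
                          numeric(4), det_act()), "shapes")
})

test_that("sample and batch losses follow the decayed square error", {
  p <- cae_params(matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2), c(0, 0),
                  det_act())
  # zero net reconstructs 0 exactly -> zero loss against zero target
  expect_equal(sample_loss(c(0.2, -0.1), c(0, 0), p), 0)
  # hand value: output [0,0] vs target [1,0] -> 1/2
  expect_equal(sample_loss(c(0, 0), c(1, 0), p), 0.5)
  q <- random_cae(3, 2, seed = 2)
  X <- matrix(runif(12, -0.4, 0.4), 4, 3)
  per <- vapply(1:4, function(i) sample_loss(X[i, ], X[i, ], q),
                numeric(1))
  expect_true(all(per >= 0))
  expect_equal(total_loss(X, X, q, loss_config(0)), mean(per))
  # decay term: lambda=2, four unit weights, zero data loss -> 4
  z <- cae_params(matrix(1, 1, 2), 0, matrix(1, 2, 1), c(0, 0),
                  det_act())
  yz <- net_forward(z, matrix(c(0.1, 0.2), 1))
  expect_equal(total_loss(matrix(c(0.1, 0.2), 1), yz, z,
                          loss_config(2)), 4)
  # monotone in lambda
  l <- vapply(c(0, 0.1, 1), function(lam)
    total_loss(X, X, q, loss_config(lam)), numeric(1))
  expect_true(all(diff(l) > 0))
  expect_error(total_loss(X[0, , drop = FALSE], X[0, , drop = FALSE],
                          q), "empty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  for (rep in 1:20) {
    vis <- sample(2:5, 1); hid <- sample(1:4, 1)
    k <- runif(1, 0.5, 2); c <- runif(1, 0.5, 2)
    p <- random_cae(vis, hid, seed = rep, act = det_act(k, c))
    X <- matrix(runif(3 * vis, -0.4, 0.4), 3, vis)
    lc <- loss_config(runif(1, 0, 1e-2))
    g <- gradients(X, X, p, lc)
    fd <- fd_gradients(X, X, p, lc)
    for (f in c("W_enc", "b_enc", "W_dec", "b_dec"))
      expect_lt(max_rel_err(g[[f]], fd[[f]]), 1e-5)
  }
})

test_that("decay part of the weight gradient is exactly lambda * W", {
  p <- random_cae(3, 2, seed = 4)
  X <- matrix(runif(9, -0.3, 0.3), 3, 3)
  g0 <- gradients(X, X, p, loss_config(0))
  g1 <- gradients(X, X, p, loss_config(0.37))
  expect_equal(g1$W_enc - g0$W_enc, 0.37 * p$W_enc)
  expect_equal(g1$W_dec - g0$W_dec, 0.37 * p$W_dec)
  expect_equal(g1$b_enc, g0$b_enc)  # biases excluded from decay
})

test_that("gradient norm vanishes at a fitted minimum", {
  # a 1-1-1 autoencoder fit to a single point it can represent exactly
  p <- cae_params(matrix(2, 1, 1), 0.3, matrix(1.5, 1, 1), -0.2,
                  det_act())
  y <- net_forward(p, matrix(0.25, 1, 1))
  g <- gradients(matrix(0.25, 1, 1), y, p, loss_config(0))
  expect_lt(max(abs(unlist(g[c("W_enc", "b_enc", "W_dec", "b_dec")]))),
            1e-6)
})

test_that("initialisation is seeded, bounded and fan-scaled", {
  p1 <- init_cae_params(6, 3, det_act(), seed = 10)
  p2 <- init_cae_params(6, 3, det_act(), seed = 10)
  p3 <- init_cae_params(6, 3, det_act(), seed = 11)
  expect_identical(p1$W_enc, p2$W_enc)
  expect_false(identical(p1$W_enc, p3$W_enc))
  r <- sqrt(6 / (6 + 3))
  expect_true(all(abs(p1$W_enc) < r) && all(abs(p1$W_dec) < r))
  expect_true(all(p1$b_enc == 0) && all(p1$b_dec == 0))
  expect_error(init_cae_params(0, 3), "visible")
})

test_that("plain-sigmoid mode reproduces a basic autoencoder bitwise", {
  act <- activation_config(k = 1, c = 1, sigma = 0, plain = TRUE)
  p <- init_cae_params(4, 2, act, seed = 3)
  x <- runif(4)
  # independent reference: standard logistic autoencoder
  sig <- function(a) 1 / (1 + exp(-a))
  h_ref <- sig(drop(p$W_enc %*% x) + p$b_enc)
  y_ref <- sig(drop(p$W_dec %*% h_ref) + p$b_dec)
  expect_identical(encode(x, p), h_ref)
  expect_identical(decode(h_ref, p), y_ref)
  expect_identical(drop(net_forward(p, matrix(x, 1))), y_ref)
})

test_that("target mapping round-trips to machine precision", {
  y <- matrix(runif(20), 4, 5)
  for (k in c(1, 1.2, 2))
    expect_equal(net_to_target(target_to_net(y, k), k), y,
                 tolerance = 1e-15)
})
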