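# Stacked-autoencoder classifier: pretraining, fine-tuning, prediction.

tiny_spec <- function(...) {
  dbn_spec(layer_sizes = c(6L, 4L, 6L, 3L, 6L, 3L),
           epochs = 40L, batch_size = 8L,
           pretrain = fsgd_config(n = 10L, alpha = 0.1, epsilon = 1e-6,
                                  K = 2L),
           ...)
}

# well-separated 3-class features in 6 dimensions
tiny_classes <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(4, 0, 0, 1, -1, 0), c(0, 4, 0, -1, 1, 0),
                   c(0, 0, 4, 0, -1, 1))
  X <- do.call(rbind, lapply(1:3, function(cl)
    sweep(matrix(rnorm(n_per * 6, sd = 0.25), n_per, 6), 2L,
          centers[cl, ], `+`)))
  list(X = X, y = factor(rep(c("run", "sit", "walk"), each = n_per)))
}

test_that("pretraining improves reconstruction and is seeded", {
  d <- tiny_classes()
  spec <- tiny_spec()
  stack <- pretrain_stack(d$X, spec, seed = 5)
  stack2 <- pretrain_stack(d$X, spec, seed = 5)
  expect_identical(stack$cae1$W_enc, stack2$cae1$W_enc)
  expect_identical(stack$cae2$W_dec, stack2$cae2$W_dec)
  # post-training loss beats the loss at initialisation
  Xn <- caehar:::apply_norm_map(d$X, stack$norm, spec$act$k)
  init <- pretrain_stack(d$X, dbn_spec(layer_sizes = spec$layer_sizes,
                                       pretrain = NULL), seed = 5)
  expect_lt(total_loss(Xn, Xn, stack$cae1, spec$lc),
            total_loss(Xn, Xn, init$cae1, spec$lc))
  expect_error(pretrain_stack(d$X[, 1:5], spec), "width")
})

test_that("skipping pretraining leaves the stack at initialisation", {
  d <- tiny_classes()
  spec0 <- dbn_spec(layer_sizes = c(6L, 4L, 6L, 3L, 6L, 3L),
                    pretrain = NULL)
  stack <- pretrain_stack(d$X, spec0, seed = 9)
  ref <- init_cae_params(6, 4, spec0$act,
                         seed = caehar:::derive_seed(9, "init-cae1"))
  expect_identical(stack$cae1$W_enc, ref$W_enc)
  expect_null(stack$history_cae1)
})

test_that("fine-tuned model separates linearly separable classes", {
  d <- tiny_classes()
  model <- train_dbn(d$X, d$y, tiny_spec(), seed = 3)
  pred <- predict(model, d$X)
  expect_equal(mean(pred$labels == d$y), 1)
  # sanity oracle: multinomial logistic fit (via two glms) also separates
  z <- as.integer(d$y == "run")
  fit <- suppressWarnings(glm(z ~ d$X, family = binomial()))
  expect_equal(mean((fitted(fit) > 0.5) == (z == 1)), 1)
})

test_that("prediction is deterministic with exclusive argmax labels", {
  d <- tiny_classes()
  model <- train_dbn(d$X, d$y, tiny_spec(), seed = 7)
  p1 <- predict(model, d$X)
  p2 <- predict(model, d$X)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$scores, p2$scores)
  expect_true(all(p1$labels %in% levels(d$y)))
  expect_equal(dim(p1$scores), c(nrow(d$X), 3L))
  expect_error(predict(model, d$X[, 1:4]), "width")
})

test_that("training is reproducible per seed and sensitive to it", {
  d <- tiny_classes()
  m1 <- train_dbn(d$X, d$y, tiny_spec(), seed = 11)
  m2 <- train_dbn(d$X, d$y, tiny_spec(), seed = 11)
  m3 <- train_dbn(d$X, d$y, tiny_spec(), seed = 12)
  expect_identical(m1$net$layers[[5]]$W, m2$net$layers[[5]]$W)
  expect_identical(m1$history$losses, m2$history$losses)
  expect_false(identical(m1$net$layers[[5]]$W, m3$net$layers[[5]]$W))
})

test_that("zero dropout and momentum reduce to plain batched backprop", {
  d <- tiny_classes(n_per = 8)
  spec <- tiny_spec(dropout_rate = 0, momentum = 0,
                    act = activation_config(sigma = 0))
  spec$epochs <- 3L
  spec$batch_size <- 1000L  # single full batch: order-free updates
  stack <- pretrain_stack(d$X, spec, seed = 2)
  model <- finetune(stack, d$X, d$y, spec, seed = 2)
  # R reference: three full-batch gradient steps on the same stack
  Xn <- caehar:::apply_norm_map(d$X, stack$norm, spec$act$k)
  Y01 <- matrix(0, nrow(Xn), 3)
  Y01[cbind(seq_len(nrow(Xn)), as.integer(d$y))] <- 1
  Yn <- target_to_net(Y01, spec$act$k)
  bp <- init_cae_net(c(6L, 3L), spec$act,
                     seed = caehar:::derive_seed(2, "init-bp"))
  net <- structure(list(layers = c(as_cae_net(stack$cae1)$layers,
                                   as_cae_net(stack$cae2)$layers,
                                   bp$layers), act = spec$act),
                   class = "cae_net")
  for (i in 1:3) {
    g <- gradients(Xn, Yn, net, spec$lc)
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$W <- net$layers[[l]]$W - spec$learning_rate * g$W[[l]]
      net$layers[[l]]$b <- net$layers[[l]]$b - spec$learning_rate * g$b[[l]]
    }
  }
  expect_equal(model$net$layers[[1]]$W, net$layers[[1]]$W,
               tolerance = 1e-12)
  expect_equal(model$net$layers[[5]]$b, net$layers[[5]]$b,
               tolerance = 1e-12)
})

test_that("fine-tuning honours the early-break rule", {
  d <- tiny_classes()
  spec <- tiny_spec(finetune_epsilon = 1e9, finetune_K = 4L)
  model <- train_dbn(d$X, d$y, spec, seed = 4)
  expect_equal(model$history$break_epoch, 4L)
  expect_true(model$history$broke_early)
  spec2 <- tiny_spec(finetune_epsilon = 1e-12, finetune_K = 2L)
  model2 <- train_dbn(d$X, d$y, spec2, seed = 4)
  expect_false(model2$history$broke_early)
  expect_equal(model2$history$break_epoch, spec2$epochs)
})

test_that("pretraining never hurts the final training loss (median)", {
  # the stated comparison runs on the synthetic activity task
  ds <- small_har()
  feats <- extract_feature_matrix(ds$segments)
  Z <- project(feats, fit_pca(feats))
  final_loss <- function(pre, seed) {
    spec <- dbn_spec(layer_sizes = c(42L, 10L, 42L, 8L, 42L, 6L),
                     epochs = 40L, batch_size = 16L)
    if (!pre) spec$pretrain <- NULL
    m <- train_dbn(Z, ds$labels, spec, seed = seed)
    tail(m$history$losses, 1)
  }
  with_pre <- vapply(1:5, function(s) final_loss(TRUE, s), numeric(1))
  without <- vapply(1:5, function(s) final_loss(FALSE, s), numeric(1))
  expect_lte(median(with_pre), median(without))
})

test_that("label handling rejects mismatches and codes one-of-N", {
  d <- tiny_classes()
  spec <- tiny_spec()
  stack <- pretrain_stack(d$X, spec, seed = 1)
  expect_error(finetune(stack, d$X, d$y[-1], spec), "one label")
  y4 <- factor(rep(c("a", "b", "c", "d"), length.out = nrow(d$X)))
  expect_error(finetune(stack, d$X, y4, spec), "classes")
  model <- finetune(stack, d$X, d$y, spec, seed = 1)
  expect_identical(model$codebook, levels(d$y))
})
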