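#' Deep-belief-network specification
#'
#' Architecture and training hyperparameters of the activity classifier:
#' two stacked continuous autoencoders (42-10-42 and 42-8-42 by default)
#' topped by a supervised backpropagation output layer of 19 units, i.e.
#' the physical layer chain 42-10-42-8-42-19.  Fine-tuning uses batched
#' backprop with momentum and inverted dropout on the hidden layers and
#' stops early once the epoch-mean loss stays at or below
#' `finetune_epsilon` for `finetune_K` consecutive epochs.
#'
#' Defaults follow small-scale pilot experience: learning rate 0.6 and
#' 100 fine-tuning epochs (a larger rate oscillates, a smaller one
#' converges too slowly within the budget), momentum 0.06 (kept small
#' because the Gaussian stochastic units already perturb the gradient),
#' dropout 0.1, early-break threshold 0.002 sustained for 10 epochs.
#' The classifier's activation uses steepness `c = 4`, which gives the
#' six-layer stack unit gain at the origin; with `c = 1` the end-to-end
#' gain is \eqn{0.25^5} and backprop at the stated learning rate stalls
#' (see the methods vignette).
#'
#' @param layer_sizes Unit counts of the physical layers, input first
#'   (default `c(42, 10, 42, 8, 42, 19)`); the first entry must match the
#'   feature dimension and the last the number of classes.
#' @param learning_rate Fine-tuning learning rate (default 0.6).
#' @param momentum Velocity coefficient (default 0.06).
#' @param dropout_rate Hidden-unit dropout probability in `[0, 1)`
#'   (default 0.1), applied during fine-tuning only.
#' @param epochs Fine-tuning epoch budget (default 100).
#' @param batch_size Fine-tuning mini-batch size (default 64).
#' @param finetune_epsilon,finetune_K Early-break threshold and window for
#'   fine-tuning (defaults 0.002 and 10).
#' @param pretrain An [fsgd_config()] for the per-sample unsupervised
#'   pretraining of each autoencoder, or `NULL` to skip pretraining and
#'   fine-tune from random initialisation.
#' @param act An [activation_config()] shared by all layers.
#' @param lc A [loss_config()] (weight decay).
#' @return An object of class `dbn_spec`.
#' @export
dbn_spec <- function(layer_sizes = c(42L, 10L, 42L, 8L, 42L, 19L),
                     learning_rate = 0.6, momentum = 0.06,
                     dropout_rate = 0.1, epochs = 100L, batch_size = 64L,
                     finetune_epsilon = 0.002, finetune_K = 10L,
                     pretrain = fsgd_config(n = 30L, alpha = 0.1,
                                            epsilon = 5e-4, K = 5L),
                     act = activation_config(c = 4), lc = loss_config()) {
  stopifnot(length(layer_sizes) == 6L, all(layer_sizes >= 1),
            layer_sizes[1] == layer_sizes[3],
            layer_sizes[3] == layer_sizes[5],
            learning_rate > 0, momentum >= 0, momentum < 1,
            dropout_rate >= 0, dropout_rate < 1,
            epochs >= 1, batch_size >= 1,
            finetune_epsilon > 0, finetune_K >= 1,
            is.null(pretrain) || inherits(pretrain, "fsgd_config"),
            inherits(act, "activation_config"),
            inherits(lc, "loss_config"))
  structure(list(layer_sizes = as.integer(layer_sizes),
                 learning_rate = learning_rate, momentum = momentum,
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 finetune_epsilon = finetune_epsilon,
                 finetune_K = as.integer(finetune_K),
                 pretrain = pretrain, act = act, lc = lc),
            class = "dbn_spec")
}

# Min-max normalisation map from training features to [0,1], then to
# network coordinates k*(x - 0.5).  Constant columns get unit scale.
fit_norm_map <- function(features) {
  mins <- apply(features, 2L, min)
  rngs <- apply(features, 2L, max) - mins
  rngs[rngs == 0] <- 1
  list(mins = mins, ranges = rngs)
}

apply_norm_map <- function(features, norm, k) {
  z <- sweep(sweep(as.matrix(features), 2L, norm$mins), 2L, norm$ranges,
             `/`)
  target_to_net(z, k)
}

#' Greedy layer-wise pretraining of the autoencoder stack
#'
#' Trains the first autoencoder on the (normalised) input features with
#' target = input, then trains the second autoencoder on the first one's
#' reconstruction-layer activations, each with [fsgd_train()].  The
#' normalisation map fitted here is carried along for fine-tuning.
#'
#' @param features Numeric feature matrix, segments in rows; the width
#'   must equal `spec$layer_sizes[1]`.
#' @param spec A [dbn_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `cae_stack`: list with `cae1`, `cae2`
#'   ([cae_params()]), `norm`, and the two pretraining histories.
#' @export
pretrain_stack <- function(features, spec = dbn_spec(), seed = NULL) {
  stopifnot(inherits(spec, "dbn_spec"))
  features <- as.matrix(features)
  if (ncol(features) != spec$layer_sizes[1])
    stop("feature width does not match the input layer", call. = FALSE)
  norm <- fit_norm_map(features)
  X <- apply_norm_map(features, norm, spec$act$k)
  ls <- spec$layer_sizes
  cae1 <- init_cae_params(ls[1], ls[2], spec$act,
                          seed = derive_seed(seed, "init-cae1"))
  cae2 <- init_cae_params(ls[3], ls[4], spec$act,
                          seed = derive_seed(seed, "init-cae2"))
  h1 <- h2 <- NULL
  if (!is.null(spec$pretrain)) {
    cfg1 <- spec$pretrain; cfg1$seed <- derive_seed(seed, "pretrain-cae1")
    fit1 <- fsgd_train(cae1, X, cfg1, spec$lc)
    cae1 <- fit1$model; h1 <- fit1$history
    H1 <- net_forward(cae1, X)  # reconstruction-layer activations
    cfg2 <- spec$pretrain; cfg2$seed <- derive_seed(seed, "pretrain-cae2")
    fit2 <- fsgd_train(cae2, H1, cfg2, spec$lc)
    cae2 <- fit2$model; h2 <- fit2$history
  }
  structure(list(cae1 = cae1, cae2 = cae2, norm = norm,
                 history_cae1 = h1, history_cae2 = h2),
            class = "cae_stack")
}

#' Supervised fine-tuning of the full network
#'
#' Stacks the two pretrained autoencoders and a randomly initialised
#' output layer into one network and trains it end to end by batched
#' backpropagation on one-hot class targets with momentum
#' (\eqn{v \leftarrow \mu v - \alpha g}, \eqn{\theta \leftarrow \theta +
#' v}), inverted dropout on the hidden layers, and the early-break rule
#' (`finetune_epsilon`, `finetune_K`).
#'
#' @param stack A `cae_stack` from [pretrain_stack()].
#' @param features Feature matrix used for pretraining (same width).
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param spec A [dbn_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `dbn_model` with the trained network, label
#'   codebook, normalisation map and training history.
#' @export
finetune <- function(stack, features, labels, spec = dbn_spec(),
                     seed = NULL) {
  stopifnot(inherits(stack, "cae_stack"), inherits(spec, "dbn_spec"))
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) != length(labels))
    stop("one label per feature row is required", call. = FALSE)
  if (any(is.na(labels))) stop("unknown (NA) label", call. = FALSE)
  n_class <- spec$layer_sizes[length(spec$layer_sizes)]
  if (nlevels(labels) > n_class)
    stop(sprintf("more classes (%d) than output units (%d)",
                 nlevels(labels), n_class), call. = FALSE)
  codebook <- levels(labels)
  X <- apply_norm_map(features, stack$norm, spec$act$k)
  # one-of-N coding on [0,1], mapped into network coordinates
  Y01 <- matrix(0, nrow(X), n_class)
  Y01[cbind(seq_len(nrow(X)), as.integer(labels))] <- 1
  Y <- target_to_net(Y01, spec$act$k)
  ls <- spec$layer_sizes
  bp <- init_cae_net(c(ls[5], ls[6]), spec$act,
                     seed = derive_seed(seed, "init-bp"))
  net <- structure(list(layers = c(as_cae_net(stack$cae1)$layers,
                                   as_cae_net(stack$cae2)$layers,
                                   bp$layers),
                        act = spec$act),
                   class = "cae_net")
  res <- with_seed(derive_seed(seed, "finetune"),
    cpp_batch_train(net_layer_W(net), net_layer_b(net), X, Y,
                    spec$act$k, spec$act$c, spec$act$sigma,
                    spec$lc$lambda_decay, spec$epochs,
                    spec$learning_rate, spec$momentum, spec$dropout_rate,
                    spec$batch_size, spec$finetune_epsilon,
                    spec$finetune_K, TRUE, TRUE))
  net <- net_with_params(net, res$W, res$b)
  structure(list(net = net, codebook = codebook, norm = stack$norm,
                 spec = spec,
                 history = train_history(res$losses, res$break_epoch,
                                         res$broke_early, spec$epochs,
                                         seed)),
            class = "dbn_model")
}

#' Pretrain and fine-tune in one call
#'
#' @inheritParams finetune
#' @return A `dbn_model` (its `stack` element keeps the pretraining
#'   histories).
#' @export
train_dbn <- function(features, labels, spec = dbn_spec(), seed = NULL) {
  stack <- pretrain_stack(features, spec, seed = seed)
  model <- finetune(stack, features, labels, spec, seed = seed)
  model$stack_history <- list(cae1 = stack$history_cae1,
                              cae2 = stack$history_cae2)
  model
}

#' @export
print.dbn_model <- function(x, ...) {
  sizes <- c(ncol(x$net$layers[[1]]$W),
             vapply(x$net$layers, function(l) length(l$b), integer(1)))
  cat(sprintf("dbn_model: layers %s, %d classes, trained %d epochs%s\n",
              paste(sizes, collapse = "-"), length(x$codebook),
              x$history$break_epoch,
              if (x$history$broke_early) " (broke early)" else ""))
  invisible(x)
}

#' Predict activity classes
#'
#' Deterministic forward pass (noise and dropout off); the predicted
#' class is the argmax over the output units, ties broken towards the
#' lowest class index.
#'
#' @param object A `dbn_model`.
#' @param features Feature matrix with the model's input width.
#' @param ... Unused.
#' @return List with `labels` (factor over the model's codebook) and the
#'   `scores` matrix (one column per class, network coordinates).
#' @export
predict.dbn_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(object$net$layers[[1]]$W))
    stop("feature width does not match the model", call. = FALSE)
  X <- apply_norm_map(features, object$norm, object$spec$act$k)
  scores <- net_forward(object$net, X)
  idx <- max.col(scores[, seq_along(object$codebook), drop = FALSE],
                 ties.method = "first")
  list(labels = factor(object$codebook[idx], levels = object$codebook),
       scores = scores)
}
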