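#' Continuous-autoencoder parameters
#'
#' A single continuous autoencoder: an encoder layer mapping visible units
#' to hidden units and a decoder layer mapping back, both using the
#' stochastic improved-sigmoid activation.  Because the activation's range
#' is \eqn{(-0.5k, 0.5k)}, training targets given on a \eqn{[0, 1]} scale
#' are mapped affinely into network coordinates (see [target_to_net()]).
#'
#' @param W_enc Encoder weight matrix (hidden x visible).
#' @param b_enc Encoder bias vector (hidden).
#' @param W_dec Decoder weight matrix (visible x hidden).
#' @param b_dec Decoder bias vector (visible).
#' @param act An [activation_config()].
#' @return An object of class `cae_params`.
#' @export
cae_params <- function(W_enc, b_enc, W_dec, b_dec,
                       act = activation_config()) {
  W_enc <- as.matrix(W_enc); W_dec <- as.matrix(W_dec)
  b_enc <- as.numeric(b_enc); b_dec <- as.numeric(b_dec)
  stopifnot(inherits(act, "activation_config"))
  if (nrow(W_enc) != length(b_enc) || nrow(W_dec) != length(b_dec) ||
      ncol(W_enc) != nrow(W_dec) || ncol(W_dec) != nrow(W_enc))
    stop("inconsistent encoder/decoder shapes", call. = FALSE)
  if (!all(is.finite(W_enc)) || !all(is.finite(W_dec)) ||
      !all(is.finite(b_enc)) || !all(is.finite(b_dec)))
    stop("non-finite parameter entries", call. = FALSE)
  structure(list(W_enc = W_enc, b_enc = b_enc,
                 W_dec = W_dec, b_dec = b_dec, act = act),
            class = "cae_params")
}

#' Random initialisation of a continuous autoencoder
#'
#' Weights are drawn uniformly on \eqn{(-r, r)} with
#' \eqn{r = \sqrt{6/(visible + hidden)}} (the usual fan-based range for
#' sigmoid units); biases start at zero.
#'
#' @param visible Number of visible units (>= 1).
#' @param hidden Number of hidden units (>= 1).
#' @param act An [activation_config()].
#' @param seed Optional integer seed; the same seed reproduces the same
#'   parameters without disturbing the caller's RNG stream.
#' @return A [cae_params()] object.
#' @export
init_cae_params <- function(visible, hidden, act = activation_config(),
                            seed = NULL) {
  stopifnot(visible >= 1, hidden >= 1)
  net <- init_cae_net(c(visible, hidden, visible), act, seed = seed)
  as_cae_params(net)
}

#' Multi-layer continuous-autoencoder network
#'
#' A stack of affine-plus-activation layers sharing one activation
#' configuration.  A two-layer network is a single autoencoder
#' ([cae_params()] is the two-layer special case); deeper stacks (e.g.
#' 3-16-2-16-3 for the swiss-roll demo) are trained the same way.
#'
#' @param layer_sizes Integer vector of unit counts, input first (length
#'   >= 2).
#' @param act An [activation_config()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return An object of class `cae_net` with elements `layers` (list of
#'   `W`, `b`) and `act`.
#' @export
init_cae_net <- function(layer_sizes, act = activation_config(),
                         seed = NULL) {
  stopifnot(is.numeric(layer_sizes), length(layer_sizes) >= 2,
            all(layer_sizes >= 1), inherits(act, "activation_config"))
  layer_sizes <- as.integer(layer_sizes)
  with_seed(seed, {
    layers <- vector("list", length(layer_sizes) - 1L)
    for (l in seq_along(layers)) {
      n_in <- layer_sizes[l]
      n_out <- layer_sizes[l + 1L]
      r <- sqrt(6 / (n_in + n_out))
      layers[[l]] <- list(
        W = matrix(runif(n_out * n_in, -r, r), n_out, n_in),
        b = numeric(n_out))
    }
    structure(list(layers = layers, act = act), class = "cae_net")
  })
}

#' @rdname cae_params
#' @param net A two-layer `cae_net`.
#' @export
as_cae_params <- function(net) {
  stopifnot(inherits(net, "cae_net"), length(net$layers) == 2L)
  cae_params(net$layers[[1L]]$W, net$layers[[1L]]$b,
             net$layers[[2L]]$W, net$layers[[2L]]$b, net$act)
}

#' @rdname init_cae_net
#' @param p A [cae_params()] object.
#' @export
as_cae_net <- function(p) {
  if (inherits(p, "cae_net")) return(p)
  stopifnot(inherits(p, "cae_params"))
  structure(list(layers = list(list(W = p$W_enc, b = p$b_enc),
                               list(W = p$W_dec, b = p$b_dec)),
                 act = p$act),
            class = "cae_net")
}

net_layer_W <- function(net) lapply(net$layers, `[[`, "W")
net_layer_b <- function(net) lapply(net$layers, `[[`, "b")

net_with_params <- function(net, Ws, bs) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- Ws[[l]]
    net$layers[[l]]$b <- as.numeric(bs[[l]])
  }
  net
}

#' Encode / decode one sample
#'
#' `encode()` applies the activation to the noisy encoder pre-activation;
#' `decode()` does the same with the decoder layer.  Both are deterministic
#' when `sigma = 0` or when the activation is not in training mode.
#'
#' @param x Visible-layer input vector.
#' @param h Hidden-layer vector.
#' @param p A [cae_params()] object.
#' @return Numeric vector (hidden-sized for `encode`, visible-sized for
#'   `decode`).
#' @export
encode <- function(x, p) {
  stopifnot(inherits(p, "cae_params"))
  improved_sigmoid(noisy_preactivation(p$W_enc, x, p$b_enc, p$act), p$act)
}

#' @rdname encode
#' @export
decode <- function(h, p) {
  stopifnot(inherits(p, "cae_params"))
  improved_sigmoid(noisy_preactivation(p$W_dec, h, p$b_dec, p$act), p$act)
}

#' Deterministic forward pass through a network
#'
#' Runs every row of `X` through the stack with noise off (and, by
#' default, ignoring training mode).
#'
#' @param net A `cae_net` (or [cae_params()], converted automatically).
#' @param X Numeric matrix, samples in rows.
#' @return Matrix of outputs, samples in rows.
#' @export
net_forward <- function(net, X) {
  net <- as_cae_net(net)
  X <- as.matrix(X)
  if (ncol(X) != ncol(net$layers[[1L]]$W))
    stop("input width does not match the network", call. = FALSE)
  H <- X
  for (lay in net$layers) {
    A <- H %*% t(lay$W) + matrix(lay$b, nrow(H), length(lay$b),
                                 byrow = TRUE)
    H <- improved_sigmoid(A, net$act)
  }
  H
}

#' Loss configuration
#'
#' @param lambda_decay Weight-decay coefficient \eqn{\lambda \ge 0}
#'   multiplying half the sum of squared weight-matrix entries (biases are
#'   excluded from the decay term).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_decay = 1e-4) {
  stopifnot(is.numeric(lambda_decay), length(lambda_decay) == 1L,
            is.finite(lambda_decay), lambda_decay >= 0)
  structure(list(lambda_decay = lambda_decay), class = "loss_config")
}

#' Square-error loss of a single sample
#'
#' \eqn{\frac{1}{2}\lVert h_{W,b}(x) - y\rVert^2} with noise off, where
#' \eqn{h_{W,b}} is the deterministic encode-decode reconstruction.
#'
#' @param x Input vector (visible size).
#' @param y Target vector (visible size), in network coordinates.
#' @param p A [cae_params()] or `cae_net`.
#' @return Non-negative scalar.
#' @export
sample_loss <- function(x, y, p) {
  net <- as_cae_net(p)
  y <- as.numeric(y)
  out_dim <- length(net$layers[[length(net$layers)]]$b)
  if (length(y) != out_dim)
    stop("target length does not match the output layer", call. = FALSE)
  yhat <- drop(net_forward(net, matrix(x, nrow = 1L)))
  0.5 * sum((yhat - y)^2)
}

#' Batch loss with weight decay
#'
#' Mean of the per-sample square-error losses plus
#' \eqn{\frac{\lambda}{2}\sum W^2} over all weight-matrix entries (biases
#' excluded).
#'
#' @param X Input matrix, samples in rows.
#' @param Y Target matrix, samples in rows (network coordinates).
#' @param p A [cae_params()] or `cae_net`.
#' @param lc A [loss_config()].
#' @return Non-negative scalar.
#' @export
total_loss <- function(X, Y, p, lc = loss_config()) {
  stopifnot(inherits(lc, "loss_config"))
  net <- as_cae_net(p)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 1L) stop("empty batch", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y row mismatch", call. = FALSE)
  Yhat <- net_forward(net, X)
  if (ncol(Yhat) != ncol(Y))
    stop("target width does not match the output layer", call. = FALSE)
  data_loss <- mean(0.5 * rowSums((Yhat - Y)^2))
  decay <- 0.5 * lc$lambda_decay *
    sum(vapply(net$layers, function(l) sum(l$W^2), numeric(1)))
  data_loss + decay
}

#' Analytic gradients of the batch loss
#'
#' Exact backpropagated gradient of [total_loss()] with respect to every
#' weight matrix and bias vector.  The activation derivative is evaluated
#' through the logistic factor \eqn{s = 1/(1+e^{-ca})} as
#' \eqn{f'(a) = k c s (1-s)}.  When the activation is in training mode
#' with \eqn{\sigma > 0}, the noise drawn on the forward pass is reused on
#' the backward pass (no gradient flows through \eqn{\sigma}).
#'
#' @param X Input matrix, samples in rows.
#' @param Y Target matrix, samples in rows.
#' @param p A [cae_params()] or `cae_net`.
#' @param lc A [loss_config()].
#' @return For `cae_params` input, a list with `W_enc`, `b_enc`, `W_dec`,
#'   `b_dec` and the evaluated `loss`; for `cae_net` input, a list with
#'   per-layer `W`/`b` gradients and `loss`.
#' @export
gradients <- function(X, Y, p, lc = loss_config()) {
  stopifnot(inherits(lc, "loss_config"))
  net <- as_cae_net(p)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 1L) stop("empty batch", call. = FALSE)
  if (ncol(X) != ncol(net$layers[[1L]]$W))
    stop("input width does not match the network", call. = FALSE)
  g <- cpp_net_gradients(net_layer_W(net), net_layer_b(net), X, Y,
                         net$act$k, net$act$c, net$act$sigma,
                         lc$lambda_decay,
                         isTRUE(net$act$train_mode) && net$act$sigma > 0)
  if (inherits(p, "cae_params")) {
    list(W_enc = g$W[[1L]], b_enc = drop(g$b[[1L]]),
         W_dec = g$W[[2L]], b_dec = drop(g$b[[2L]]), loss = g$loss)
  } else {
    list(W = g$W, b = lapply(g$b, drop), loss = g$loss)
  }
}

#' Affine mapping between data and network coordinates
#'
#' The activation's output range is \eqn{(-0.5k, 0.5k)}, so training
#' targets on a \eqn{[0, 1]} scale are mapped to network coordinates by
#' \eqn{k (y - 0.5)} and back by \eqn{h/k + 0.5}.  The two maps compose
#' to the identity (to machine precision for non-dyadic gains).
#'
#' @param y,h Numeric vector or matrix.
#' @param k Gain parameter of the activation.
#' @return Numeric object of the same shape.
#' @export
target_to_net <- function(y, k = 1) k * (y - 0.5)

#' @rdname target_to_net
#' @export
net_to_target <- function(h, k = 1) h / k + 0.5
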