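#' Activation configuration for continuous-autoencoder units
#'
#' Bundles the parameters of the gain- and steepness-controlled sigmoid
#' activation together with the standard deviation of the additive Gaussian
#' stochastic unit.  The activation is
#' \deqn{f(a) = k \left(\frac{1}{1 + e^{-c a}} - 0.5\right),}
#' a zero-centred sigmoid with range \eqn{(-0.5k, 0.5k)}.  During training
#' each pre-activation additionally receives \eqn{\sigma \cdot N(0,1)}
#' noise; with `sigma = 0` (or outside training) the unit is deterministic.
#'
#' @param k Gain control parameter (> 0); scales the output range to
#'   \eqn{(-0.5k, 0.5k)}.
#' @param c Exponential (steepness) control parameter (> 0); widens or
#'   narrows the quasi-linear region around zero.
#' @param sigma Standard deviation of the additive Gaussian unit (>= 0).
#' @param train_mode Logical; noise is active only when `TRUE`.
#' @param plain Logical; when `TRUE` the activation falls back to the plain
#'   logistic sigmoid \eqn{1/(1+e^{-a})} (ignoring `k` and `c`), recovering
#'   a basic autoencoder for reference comparisons.
#' @return An object of class `activation_config`.
#' @examples
#' act <- activation_config(k = 1, c = 1, sigma = 0)
#' improved_sigmoid(0, act)
#' @export
activation_config <- function(k = 1, c = 1, sigma = 0.1, train_mode = FALSE,
                              plain = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(c), length(c) == 1L, is.finite(c), c > 0,
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            sigma >= 0,
            is.logical(train_mode), length(train_mode) == 1L,
            is.logical(plain), length(plain) == 1L)
  structure(list(k = k, c = c, sigma = sigma, train_mode = train_mode,
                 plain = plain),
            class = "activation_config")
}

#' Gain- and steepness-controlled sigmoid activation
#'
#' Computes \eqn{f(a) = k(1/(1+e^{-c a}) - 0.5)} elementwise.  The output
#' lies strictly inside \eqn{(-0.5k, 0.5k)} for all finite inputs and is an
#' odd function of `a`.
#'
#' @param a Numeric scalar, vector or matrix of pre-activations (finite).
#' @param act An [activation_config()].
#' @return Numeric object of the same shape as `a`.
#' @export
improved_sigmoid <- function(a, act = activation_config()) {
  stopifnot(inherits(act, "activation_config"), is.numeric(a))
  if (!all(is.finite(a))) stop("non-finite pre-activation", call. = FALSE)
  if (isTRUE(act$plain)) return(1 / (1 + exp(-a)))
  # algebraically k*(1/(1+exp(-c*a)) - 0.5); the tanh form is bit-exactly
  # odd in a, which the spec-level symmetry property relies on
  act$k * 0.5 * tanh(0.5 * act$c * a)
}

# Derivative of the activation wrt its pre-activation, via the standard
# logistic factor s = 1/(1+exp(-c*a)):  f'(a) = k*c*s*(1-s).
improved_sigmoid_grad <- function(a, act) {
  if (isTRUE(act$plain)) {
    s <- 1 / (1 + exp(-a))
    return(s * (1 - s))
  }
  s <- 1 / (1 + exp(-act$c * a))
  act$k * act$c * s * (1 - s)
}

#' Truncated Taylor series of the activation at zero
#'
#' Odd-order Maclaurin polynomial of the activation,
#' \eqn{k[ca/4 - (ca)^3/48 + (ca)^5/480]}, truncated at `order`.  Serves as
#' an independent closed-form oracle for [improved_sigmoid()] near zero,
#' where the activation is quasi-linear.
#'
#' @param a Numeric scalar or vector.
#' @param act An [activation_config()] (noise is ignored).
#' @param order Truncation order; one of 1, 3, 5.
#' @return Numeric of the same shape as `a`.
#' @export
taylor_reference <- function(a, act = activation_config(), order = 5L) {
  stopifnot(inherits(act, "activation_config"), is.numeric(a),
            all(is.finite(a)))
  if (!order %in% c(1L, 3L, 5L))
    stop("order must be one of 1, 3, 5", call. = FALSE)
  x <- act$c * a
  out <- x / 4
  if (order >= 3L) out <- out - x^3 / 48
  if (order >= 5L) out <- out + x^5 / 480
  act$k * out
}

#' Pre-activation with additive Gaussian stochastic units
#'
#' Computes \eqn{W x + b + \sigma z} with \eqn{z \sim N(0, I)} drawn
#' independently per unit when the configuration is in training mode;
#' otherwise returns \eqn{W x + b} exactly.  Draws come from R's RNG
#' stream, so results are reproducible via [set.seed()].
#'
#' @param W Weight matrix (units x inputs).
#' @param x Input vector.
#' @param b Bias vector (length = units).
#' @param act An [activation_config()].
#' @return Numeric vector of pre-activations.
#' @export
noisy_preactivation <- function(W, x, b, act = activation_config()) {
  stopifnot(inherits(act, "activation_config"))
  W <- as.matrix(W)
  x <- as.numeric(x)
  b <- as.numeric(b)
  if (ncol(W) != length(x) || nrow(W) != length(b))
    stop("shape mismatch between W, x and b", call. = FALSE)
  a <- drop(W %*% x) + b
  if (isTRUE(act$train_mode) && act$sigma > 0)
    a <- a + act$sigma * rnorm(length(a))
  a
}
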