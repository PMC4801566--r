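#' Configuration for (fast) stochastic gradient descent
#'
#' Controls the per-sample SGD training loop and its early-break rule:
#' training stops once the monitored loss has stayed at or below `epsilon`
#' for `K` consecutive epochs ("fast SGD").  With the break rule disabled
#' the loop always runs the full `n` epochs.
#'
#' @param n Maximum number of iteration epochs (>= 1).
#' @param alpha Learning rate (> 0).
#' @param epsilon Minimum-loss constant, the convergence criterion (> 0).
#' @param K Break window: number of qualifying consecutive epochs (1 <= K
#'   <= n).
#' @param seed Optional integer seed controlling sample order and noise
#'   draws.
#' @param monitor `"train"` monitors the epoch-mean training loss (the
#'   mean of the per-sample losses observed during the pass, plus the
#'   weight-decay term); `"holdout"` monitors the deterministic loss on a
#'   held-out fraction of the data.
#' @param holdout_frac Fraction of samples held out when `monitor =
#'   "holdout"`.
#' @param reset_counter If `TRUE` (default) the consecutive-epoch counter
#'   resets whenever an epoch exceeds `epsilon`; `FALSE` counts
#'   qualifying epochs cumulatively.
#' @return An object of class `fsgd_config`.
#' @export
fsgd_config <- function(n = 1000L, alpha = 0.1, epsilon = 0.003, K = 100L,
                        seed = NULL, monitor = c("train", "holdout"),
                        holdout_frac = 0.1, reset_counter = TRUE) {
  monitor <- match.arg(monitor)
  stopifnot(n >= 1, alpha > 0, epsilon > 0, K >= 1, K <= n,
            holdout_frac > 0, holdout_frac < 1,
            is.logical(reset_counter), length(reset_counter) == 1L)
  structure(list(n = as.integer(n), alpha = alpha, epsilon = epsilon,
                 K = as.integer(K), seed = seed, monitor = monitor,
                 holdout_frac = holdout_frac,
                 reset_counter = reset_counter),
            class = "fsgd_config")
}

#' One gradient-descent update
#'
#' \eqn{\theta' = \theta - \alpha \, g}, applied elementwise.  Works on
#' numeric vectors/matrices and recursively on (nested) lists of them, so
#' a whole parameter structure can be stepped at once.
#'
#' @param theta Parameter structure.
#' @param grad Gradient structure of identical shape.
#' @param alpha Learning rate.
#' @return Updated structure of the same shape as `theta`.
#' @export
sgd_step <- function(theta, grad, alpha) {
  if (is.list(theta)) {
    if (!is.list(grad) || length(grad) != length(theta))
      stop("parameter/gradient structure mismatch", call. = FALSE)
    return(mapply(sgd_step, theta, grad,
                  MoreArgs = list(alpha = alpha), SIMPLIFY = FALSE))
  }
  if (!is.numeric(theta) || !is.numeric(grad) ||
      length(theta) != length(grad))
    stop("parameter/gradient shape mismatch", call. = FALSE)
  theta - alpha * grad
}

#' Training history
#'
#' Per-epoch monitored losses plus the break bookkeeping of a training
#' run; sufficient to replay and compare runs.
#'
#' @param losses Numeric vector of per-epoch monitored losses.
#' @param break_epoch Epoch at which the loop ended.
#' @param broke_early Logical; `TRUE` if the break rule fired before the
#'   epoch budget.
#' @param n Epoch budget of the run.
#' @param seed Seed used (may be `NULL`).
#' @return An object of class `train_history`.
#' @export
train_history <- function(losses, break_epoch, broke_early, n,
                          seed = NULL) {
  stopifnot(length(losses) == break_epoch,
            !broke_early || break_epoch < n)
  structure(list(losses = as.numeric(losses),
                 break_epoch = as.integer(break_epoch),
                 broke_early = isTRUE(broke_early),
                 n = as.integer(n), seed = seed),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("train_history: %d epochs (budget %d)%s, final loss %.6g\n",
              x$break_epoch, x$n,
              if (x$broke_early) ", broke early" else "",
              x$losses[length(x$losses)]))
  invisible(x)
}

#' Early-break rule over a loss sequence
#'
#' Pure form of the fast-SGD break rule: a counter increments on every
#' epoch whose loss is at most `epsilon` (resetting on a miss unless
#' `reset = FALSE`) and the loop breaks once the counter reaches `K`.
#' Useful as an oracle for checking recorded histories.
#'
#' @param losses Numeric vector of per-epoch losses.
#' @param epsilon Loss threshold.
#' @param K Required count of qualifying epochs.
#' @param reset Whether the counter resets on a miss.
#' @return List with `break_epoch` (`NA` if the rule never fires) and
#'   `broke_early`.
#' @export
fsgd_break_epoch <- function(losses, epsilon, K, reset = TRUE) {
  counter <- 0L
  for (ep in seq_along(losses)) {
    if (losses[ep] <= epsilon) counter <- counter + 1L
    else if (reset) counter <- 0L
    if (counter >= K)
      return(list(break_epoch = ep, broke_early = TRUE))
  }
  list(break_epoch = NA_integer_, broke_early = FALSE)
}

as_xy <- function(data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$X)) {
    X <- as.matrix(data$X)
    Y <- if (is.null(data$Y)) X else as.matrix(data$Y)
  } else {
    X <- as.matrix(data)
    Y <- X
  }
  if (nrow(X) < 1L) stop("empty training data", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X/Y row mismatch", call. = FALSE)
  list(X = X, Y = Y)
}

run_sgd <- function(model, data, cfg, lc, use_break) {
  stopifnot(inherits(cfg, "fsgd_config"), inherits(lc, "loss_config"))
  net <- as_cae_net(model)
  d <- as_xy(data)
  with_seed(cfg$seed, {
    if (cfg$monitor == "holdout") {
      n_hold <- max(1L, floor(cfg$holdout_frac * nrow(d$X)))
      if (n_hold >= nrow(d$X))
        stop("holdout fraction leaves no training data", call. = FALSE)
      hold <- sort(sample.int(nrow(d$X), n_hold))
      Xmon <- d$X[hold, , drop = FALSE]
      Ymon <- d$Y[hold, , drop = FALSE]
      Xtr <- d$X[-hold, , drop = FALSE]
      Ytr <- d$Y[-hold, , drop = FALSE]
    } else {
      Xtr <- d$X; Ytr <- d$Y
      Xmon <- matrix(0, 0L, ncol(d$X)); Ymon <- matrix(0, 0L, ncol(d$Y))
    }
    res <- cpp_sgd_train(net_layer_W(net), net_layer_b(net), Xtr, Ytr,
                         net$act$k, net$act$c, net$act$sigma,
                         lc$lambda_decay, cfg$n, cfg$alpha, cfg$epsilon,
                         cfg$K, use_break, cfg$reset_counter, Xmon, Ymon)
    out_net <- net_with_params(net, res$W, res$b)
    model_out <- if (inherits(model, "cae_params")) as_cae_params(out_net)
                 else out_net
    list(model = model_out,
         history = train_history(res$losses, res$break_epoch,
                                 res$broke_early, cfg$n, cfg$seed))
  })
}

#' Per-sample stochastic gradient descent
#'
#' For each of `cfg$n` epochs, visits the samples in a fresh seeded random
#' order and performs one [sgd_step()] per sample using the single-sample
#' gradient of the decayed square-error loss.  `sgd_train()` always runs
#' the full epoch budget; [fsgd_train()] additionally applies the
#' early-break rule and is otherwise identical, so with the same seed the
#' two produce bit-identical parameters and losses up to the break epoch.
#'
#' @param model A [cae_params()] or `cae_net`.
#' @param data A matrix of inputs (autoencoding: targets = inputs) or a
#'   list with elements `X` and `Y`, samples in rows, in network
#'   coordinates.
#' @param cfg An [fsgd_config()]; `epsilon`/`K` are ignored by
#'   `sgd_train()`.
#' @param lc A [loss_config()].
#' @return List with the trained `model` (same class as the input) and a
#'   [train_history()].
#' @export
sgd_train <- function(model, data, cfg = fsgd_config(),
                      lc = loss_config()) {
  run_sgd(model, data, cfg, lc, use_break = FALSE)
}

#' @rdname sgd_train
#' @export
fsgd_train <- function(model, data, cfg = fsgd_config(),
                       lc = loss_config()) {
  run_sgd(model, data, cfg, lc, use_break = TRUE)
}

#' Propose a break threshold from a pilot run
#'
#' A-posteriori selection of the minimum-loss constant: train briefly on a
#' small subsample, then propose `epsilon` as a quantile of the
#' late-epoch losses.
#'
#' @param model,data,cfg,lc As in [sgd_train()].
#' @param subsample_frac Fraction of samples used for the pilot run.
#' @param tail_frac Final fraction of epochs whose losses are summarised.
#' @param prob Quantile of those losses returned as the proposal.
#' @return A positive scalar threshold.
#' @export
propose_epsilon <- function(model, data, cfg = fsgd_config(n = 50L),
                            lc = loss_config(), subsample_frac = 0.2,
                            tail_frac = 0.25, prob = 0.5) {
  stopifnot(subsample_frac > 0, subsample_frac <= 1,
            tail_frac > 0, tail_frac <= 1, prob >= 0, prob <= 1)
  d <- as_xy(data)
  with_seed(derive_seed(cfg$seed, "epsilon-pilot"), {
    n_sub <- max(2L, ceiling(subsample_frac * nrow(d$X)))
    keep <- sample.int(nrow(d$X), min(n_sub, nrow(d$X)))
    pilot <- list(X = d$X[keep, , drop = FALSE],
                  Y = d$Y[keep, , drop = FALSE])
    fit <- sgd_train(model, pilot, cfg, lc)
    losses <- fit$history$losses
    tail_n <- max(1L, ceiling(tail_frac * length(losses)))
    as.numeric(quantile(losses[seq.int(length(losses) - tail_n + 1L,
                                       length(losses))], prob))
  })
}

#' Write / read a training history as delimited text
#'
#' Two-column tab-separated table (`epoch`, `loss`) with the break
#' metadata in `#`-prefixed header lines.
#'
#' @param history A [train_history()].
#' @param path File path.
#' @return `write_history()` returns `path` invisibly; `read_history()`
#'   returns a [train_history()].
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "train_history"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n=%d break_epoch=%d broke_early=%d",
                       history$n, history$break_epoch,
                       as.integer(history$broke_early)),
               "epoch\tloss",
               sprintf("%d\t%.17g", seq_along(history$losses),
                       history$losses)), con)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# ", "", lines[1L]), " ")[[1L]]
  kv <- vapply(strsplit(meta, "="), `[`, character(1), 2L)
  tab <- read.table(text = lines[-(1:2)], sep = "\t",
                    col.names = c("epoch", "loss"))
  train_history(tab$loss, as.integer(kv[2L]), as.integer(kv[3L]) == 1L,
                as.integer(kv[1L]))
}
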