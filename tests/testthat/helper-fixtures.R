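# Shared fixtures: tiny random networks, finite-difference oracles, and a
# small synthetic activity dataset reused across test files.

det_act <- function(k = 1, c = 1) {
  activation_config(k = k, c = c, sigma = 0, train_mode = FALSE)
}

random_cae <- function(visible, hidden, seed, act = det_act()) {
  init_cae_params(visible, hidden, act, seed = seed)
}

# Central finite differences of total_loss over every parameter entry.
fd_gradients <- function(X, Y, p, lc, step = 1e-5) {
  fields <- c("W_enc", "b_enc", "W_dec", "b_dec")
  out <- list()
  for (f in fields) {
    th <- p[[f]]
    g <- th
    for (i in seq_along(th)) {
      up <- p; up[[f]][i] <- th[i] + step
      dn <- p; dn[[f]][i] <- th[i] - step
      g[i] <- (total_loss(X, Y, up, lc) - total_loss(X, Y, dn, lc)) /
        (2 * step)
    }
    out[[f]] <- g
  }
  out
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# A small, well-separated activity dataset (6 activities, 2 subjects,
# 4 segments per pair) shared by the slower pipeline tests.
small_har <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_har_dataset(har_gen_config(
        n_activities = 6, n_subjects = 2, segments_per_pair = 4,
        seed = 11))
    cache
  }
})

# Direct O(N^2) evaluation of the DFT magnitudes, independent of fft().
dft_oracle <- function(s) {
  N <- length(s)
  n <- seq_len(N) - 1
  vapply(seq_len(N) - 1, function(k)
    Mod(sum(s * exp(-2i * pi * k * n / N))), numeric(1))
}
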