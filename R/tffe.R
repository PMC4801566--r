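#' Standard 45-channel metadata
#'
#' The canonical column layout of a segment: position-major over the five
#' body positions (torso `T`, right arm `RA`, left arm `LA`, right leg
#' `RL`, left leg `LL`), then sensor (`acc`, `gyro`, `mag`), then axis
#' (`x`, `y`, `z`) -- 45 channels in total.
#'
#' @return A data frame with columns `position`, `sensor`, `axis` and
#'   `channel` (a unique `position_sensor_axis` id), one row per channel.
#' @export
channel_metadata <- function() {
  positions <- c("T", "RA", "LA", "RL", "LL")
  sensors <- c("acc", "gyro", "mag")
  axes <- c("x", "y", "z")
  meta <- expand.grid(axis = axes, sensor = sensors, position = positions,
                      stringsAsFactors = FALSE)[, 3:1]
  meta$channel <- paste(meta$position, meta$sensor, meta$axis, sep = "_")
  rownames(meta) <- NULL
  meta
}

# Physical full-scale range of each sensor type, in its native unit
# (acc: g, gyro: deg/s, mag: microtesla).
sensor_range <- function(sensor) {
  c(acc = 5, gyro = 1200, mag = 75)[[sensor]]
}

#' One windowed sensor segment
#'
#' A 5-second window of multi-channel signal sampled at 25 Hz: 125 time
#' samples (rows) by one column per channel (45 in the standard layout),
#' with optional activity label and subject id.
#'
#' @param data Numeric matrix, 125 rows, one column per channel.
#' @param label Activity label (e.g. `"a01"`) or `NA`.
#' @param subject Subject id (1-8) or `NA`.
#' @param channel_meta Channel metadata data frame; defaults to the
#'   standard 45-channel layout of [channel_metadata()].
#' @return An object of class `sensor_segment`.
#' @export
sensor_segment <- function(data, label = NA_character_,
                           subject = NA_integer_,
                           channel_meta = channel_metadata()) {
  data <- as.matrix(data)
  if (nrow(data) != 125L)
    stop("a segment must have exactly 125 rows (5 s at 25 Hz)",
         call. = FALSE)
  if (ncol(data) != nrow(channel_meta))
    stop("segment columns do not match channel metadata", call. = FALSE)
  if (anyDuplicated(channel_meta$channel))
    stop("duplicate channel ids in metadata", call. = FALSE)
  if (!all(is.finite(data)))
    stop("non-finite values in segment data", call. = FALSE)
  colnames(data) <- channel_meta$channel
  structure(list(data = data, label = label,
                 subject = as.integer(subject),
                 channel_meta = channel_meta),
            class = "sensor_segment")
}

#' @export
print.sensor_segment <- function(x, ...) {
  cat(sprintf("sensor_segment: 125 x %d, label=%s, subject=%s\n",
              ncol(x$data), x$label, x$subject))
  invisible(x)
}

#' Time-domain channel features
#'
#' Per-channel scalar summaries with population (1/N) moment conventions
#' throughout: the arithmetic mean, the mean absolute deviation about the
#' mean, the skewness (third central moment over \eqn{\sigma^3}; defined
#' as 0 for a constant channel), and the Pearson correlation with a
#' partner channel.
#'
#' @param s,s_i,s_j Numeric channel sequences of equal length (>= 1).
#' @return A scalar.
#' @name time-features
NULL

#' @rdname time-features
#' @export
mean_feature <- function(s) {
  if (length(s) < 1L) stop("empty channel", call. = FALSE)
  mean(s)
}

#' @rdname time-features
#' @export
mad_feature <- function(s) {
  if (length(s) < 1L) stop("empty channel", call. = FALSE)
  mean(abs(s - mean(s)))
}

#' @rdname time-features
#' @export
skewness_feature <- function(s) {
  if (length(s) < 1L) stop("empty channel", call. = FALSE)
  mu <- mean(s)
  sigma2 <- mean((s - mu)^2)
  if (sigma2 == 0) return(0)
  mean((s - mu)^3) / sigma2^1.5
}

#' @rdname time-features
#' @export
corr_feature <- function(s_i, s_j) {
  if (length(s_i) != length(s_j)) stop("length mismatch", call. = FALSE)
  di <- s_i - mean(s_i)
  dj <- s_j - mean(s_j)
  den <- sqrt(sum(di^2) * sum(dj^2))
  if (den == 0) {
    warning("constant channel in correlation; returning 0",
            call. = FALSE)
    return(0)
  }
  sum(di * dj) / den
}

#' Discrete Fourier magnitudes of a channel
#'
#' Magnitudes \eqn{|X(k)|} of the length-125 DFT
#' \eqn{X(k) = \sum_n s_n e^{-j 2\pi k n / N}}.
#'
#' @param s Numeric sequence of exactly 125 samples.
#' @return Numeric vector of 125 magnitudes (index 1 is the DC bin).
#' @export
fft_magnitudes <- function(s) {
  if (length(s) != 125L)
    stop("expected a 125-sample channel", call. = FALSE)
  Mod(fft(s))
}

#' Real cepstrum of a channel
#'
#' Inverse DFT of the log magnitude spectrum,
#' \eqn{C(n) = \mathrm{IDFT}\{\log(|X(k)| + \delta)\}} with the small
#' floor \eqn{\delta = 10^{-12} \max_k |X(k)|} guarding empty bins.  The
#' real part is returned; an all-zero signal yields an all-zero cepstrum
#' with a warning.
#'
#' @param s Numeric sequence of exactly 125 samples.
#' @return Numeric vector of 125 cepstrum coefficients.
#' @export
cepstrum <- function(s) {
  if (length(s) != 125L)
    stop("expected a 125-sample channel", call. = FALSE)
  mag <- Mod(fft(s))
  mx <- max(mag)
  if (mx == 0) {
    warning("all-zero signal; cepstrum is all zeros", call. = FALSE)
    return(numeric(125L))
  }
  Re(fft(log(mag + 1e-12 * mx), inverse = TRUE)) / 125
}

#' Largest spectral peaks
#'
#' The `k` largest values over the one-sided spectrum (bins
#' \eqn{1 \ldots \lfloor N/2 \rfloor}, DC excluded), sorted descending;
#' ties break towards the lower bin index.
#'
#' @param v Magnitude (or cepstrum) sequence, DC first.
#' @param k Number of peaks (default 5).
#' @return Numeric vector of length `k`, non-increasing.
#' @export
top_k_peaks <- function(v, k = 5L) {
  usable <- v[seq.int(2L, floor(length(v) / 2) + 1L)]
  if (k > length(usable))
    stop("k exceeds the number of usable bins", call. = FALSE)
  usable[order(-usable, seq_along(usable))][seq_len(k)]
}

#' Names of the 14 per-channel features, in output order
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("mean", "mad", "skewness", "corr",
    paste0("fft_peak", 1:5), paste0("cep_peak", 1:5))
}

# Partner channel for the inter-axis correlation: cyclic pairing within
# each (position, sensor) triad -- x with y, y with z, z with x -- so every
# channel contributes exactly one correlation value.
corr_partner <- function(channel_meta) {
  nxt <- c(x = "y", y = "z", z = "x")
  key <- paste(channel_meta$position, channel_meta$sensor,
               nxt[channel_meta$axis], sep = "_")
  match(key, channel_meta$channel)
}

#' Time- and frequency-domain feature extraction
#'
#' Extracts, for each channel, 4 time-domain features (mean, mean
#' absolute deviation, skewness, inter-axis correlation) and 10
#' frequency-domain features (the five largest FFT magnitudes and the
#' five largest cepstrum values over the one-sided spectrum), i.e. 14 per
#' channel and \eqn{14 \times 45 = 630} per standard segment, reducing a
#' \eqn{125 \times 45 = 5625}-value window to 630 numbers.
#'
#' The output is ordered feature-major: all channels' means first, then
#' all channels' MADs, and so on, with names `feature:channel`.
#' Degenerate channels (constant or all-zero) contribute 0 for the
#' affected features and raise a single summarising warning.
#'
#' @param seg A [sensor_segment()].
#' @return Named numeric vector of length `14 * n_channels` (630 for the
#'   standard 45-channel layout).
#' @export
extract_features <- function(seg) {
  stopifnot(inherits(seg, "sensor_segment"))
  X <- seg$data
  nc <- ncol(X)
  partner <- corr_partner(seg$channel_meta)
  feats <- matrix(0, nrow = 14L, ncol = nc)
  degenerate <- 0L
  for (ch in seq_len(nc)) {
    s <- X[, ch]
    feats[1L, ch] <- mean_feature(s)
    feats[2L, ch] <- mad_feature(s)
    feats[3L, ch] <- skewness_feature(s)
    j <- partner[ch]
    cf <- withCallingHandlers(
      corr_feature(s, X[, j]),
      warning = function(w) {
        degenerate <<- degenerate + 1L
        invokeRestart("muffleWarning")
      })
    feats[4L, ch] <- cf
    mag <- fft_magnitudes(s)
    feats[5:9, ch] <- top_k_peaks(mag, 5L)
    cep <- withCallingHandlers(
      cepstrum(s),
      warning = function(w) {
        degenerate <<- degenerate + 1L
        invokeRestart("muffleWarning")
      })
    feats[10:14, ch] <- top_k_peaks(cep, 5L)
  }
  if (degenerate > 0L)
    warning(sprintf("%d degenerate channel feature(s) set to 0",
                    degenerate), call. = FALSE)
  out <- as.numeric(t(feats))
  names(out) <- paste(rep(feature_names(), each = nc),
                      seg$channel_meta$channel, sep = ":")
  out
}

#' Feature matrix for a list of segments
#'
#' @param segments List of [sensor_segment()] objects with identical
#'   channel layouts.
#' @return Numeric matrix, one row per segment, `14 * n_channels`
#'   columns.
#' @export
extract_feature_matrix <- function(segments) {
  stopifnot(length(segments) >= 1L)
  rows <- lapply(segments, extract_features)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
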