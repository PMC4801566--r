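#' Swiss-roll point cloud
#'
#' Generates the classic 2-D manifold embedded in 3-D used as a nonlinear
#' reconstruction benchmark: \eqn{(t \cos t, \, height, \, t \sin t)} with
#' the roll parameter \eqn{t} uniform on \eqn{[1.5\pi, 4.5\pi]} and the
#' height uniform, plus optional isotropic Gaussian jitter.  Each
#' coordinate is min-max normalised to \eqn{[0, 1]}.
#'
#' @param n_points Number of points (default 2000).
#' @param noise_sd Standard deviation of additive jitter before
#'   normalisation (default 0).
#' @param seed Optional integer seed.
#' @return A `swiss_roll_config` (constructor) / an `n x 3` matrix with
#'   every column spanning exactly `[0, 1]` (generator).
#' @export
swiss_roll_config <- function(n_points = 2000L, noise_sd = 0, seed = 1L) {
  stopifnot(n_points >= 1, noise_sd >= 0)
  structure(list(n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = seed),
            class = "swiss_roll_config")
}

#' @rdname swiss_roll_config
#' @param cfg A `swiss_roll_config`.
#' @export
make_swiss_roll <- function(cfg = swiss_roll_config()) {
  stopifnot(inherits(cfg, "swiss_roll_config"))
  with_seed(cfg$seed, {
    t <- runif(cfg$n_points, 1.5 * pi, 4.5 * pi)
    height <- runif(cfg$n_points, 0, 10)
    X <- cbind(t * cos(t), height, t * sin(t))
    if (cfg$noise_sd > 0)
      X <- X + matrix(rnorm(length(X), sd = cfg$noise_sd), nrow(X))
    if (cfg$n_points > 1L) {
      mins <- apply(X, 2L, min)
      rngs <- apply(X, 2L, max) - mins
      rngs[rngs == 0] <- 1
      X <- sweep(sweep(X, 2L, mins), 2L, rngs, `/`)
    }
    colnames(X) <- c("x", "y", "z")
    X
  })
}

#' Per-activity signal templates
#'
#' The documented constants driving the synthetic activity generator: per
#' activity, a fundamental frequency `freq_hz` and the offset (`o1`,
#' `o2`) and amplitude (`g1`, `g2`) coefficients that mix the two fixed
#' cross-channel patterns.  Shipped as a plain CSV so the stated world is
#' inspectable and editable.
#'
#' @return Data frame with one row per activity.
#' @export
har_templates <- function() {
  path <- system.file("extdata", "activity_templates.csv",
                      package = "caehar")
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}

#' Configuration of the synthetic activity dataset
#'
#' Emulates the structure of a body-worn multi-sensor recording campaign:
#' `n_activities` activities, each performed by `n_subjects` subjects for
#' `segments_per_pair` 5-second segments of 125 samples x 45 channels at
#' 25 Hz (defaults: 19 x 8 x 60 = 9120 segments).  Each channel is a
#' quasi-periodic sinusoid at the activity's template frequency with an
#' activity-specific offset, per-subject amplitude jitter, random phase
#' and Gaussian noise, clamped to the physical sensor ranges
#' (accelerometer +/-5 g, gyroscope +/-1200 deg/s, magnetometer
#' +/-75 uT).  Cross-channel offset and amplitude profiles are linear
#' combinations of three fixed patterns, so the channel-axis structure is
#' low-rank by construction.
#'
#' @param n_activities Number of activity classes (default 19).
#' @param n_subjects Number of subjects (default 8).
#' @param segments_per_pair Segments per activity-subject pair (default
#'   60).
#' @param subject_jitter_sd Standard deviation of the per-subject
#'   amplitude factor around 1 (default 0.1).
#' @param templates Template table as from [har_templates()].
#' @param seed Integer seed.
#' @return A `har_gen_config`.
#' @export
har_gen_config <- function(n_activities = 19L, n_subjects = 8L,
                           segments_per_pair = 60L,
                           subject_jitter_sd = 0.1,
                           templates = har_templates(), seed = 1L) {
  stopifnot(n_activities >= 1, n_activities <= nrow(templates),
            n_subjects >= 1, segments_per_pair >= 1,
            subject_jitter_sd >= 0)
  if (any(templates$freq_hz >= 12.5))
    stop("template frequency at or above Nyquist (12.5 Hz)",
         call. = FALSE)
  structure(list(n_activities = as.integer(n_activities),
                 n_subjects = as.integer(n_subjects),
                 segments_per_pair = as.integer(segments_per_pair),
                 samples = 125L, channels = 45L, rate = 25,
                 subject_jitter_sd = subject_jitter_sd,
                 templates = templates, seed = seed),
            class = "har_gen_config")
}

# Fixed cross-channel patterns and per-sensor scales (offset amplitude,
# oscillation amplitude, noise sd -- in g, deg/s, uT respectively).
har_channel_model <- function(meta) {
  idx <- seq_len(nrow(meta)) - 1L
  list(u1 = rep(1, nrow(meta)),
       u2 = cos(2 * pi * idx / nrow(meta)),
       off_scale = c(acc = 0.8, gyro = 100, mag = 25)[meta$sensor],
       amp_scale = c(acc = 1.0, gyro = 200, mag = 10)[meta$sensor],
       noise_sd = c(acc = 0.05, gyro = 5, mag = 0.5)[meta$sensor],
       range = c(acc = 5, gyro = 1200, mag = 75)[meta$sensor])
}

#' Generate a synthetic activity dataset
#'
#' @param cfg A [har_gen_config()].
#' @return An object of class `har_dataset`: a list with `segments` (list
#'   of [sensor_segment()]), `labels` (factor of activity ids), `subjects`
#'   (integer vector) and the generating `config`.
#' @export
make_har_dataset <- function(cfg = har_gen_config()) {
  stopifnot(inherits(cfg, "har_gen_config"))
  meta <- channel_metadata()
  chm <- har_channel_model(meta)
  tpl <- cfg$templates
  n_seg <- cfg$n_activities * cfg$n_subjects * cfg$segments_per_pair
  with_seed(cfg$seed, {
    jitter <- pmax(0.5, 1 + cfg$subject_jitter_sd * rnorm(cfg$n_subjects))
    segments <- vector("list", n_seg)
    labels <- character(n_seg)
    subjects <- integer(n_seg)
    tstep <- (seq_len(cfg$samples) - 1L) / cfg$rate
    i <- 0L
    for (a in seq_len(cfg$n_activities)) {
      offset <- chm$off_scale * (tpl$o1[a] * chm$u1 + tpl$o2[a] * chm$u2)
      amp <- chm$amp_scale * (tpl$g1[a] * chm$u1 + tpl$g2[a] * chm$u2)
      omega <- 2 * pi * tpl$freq_hz[a]
      for (subj in seq_len(cfg$n_subjects)) {
        for (k in seq_len(cfg$segments_per_pair)) {
          phase <- runif(cfg$channels, 0, 2 * pi)
          S <- sin(outer(omega * tstep, phase, `+`))
          X <- sweep(S, 2L, amp * jitter[subj], `*`)
          X <- sweep(X, 2L, offset, `+`)
          X <- X + matrix(rnorm(cfg$samples * cfg$channels),
                          cfg$samples) *
            matrix(chm$noise_sd, cfg$samples, cfg$channels, byrow = TRUE)
          lim <- matrix(chm$range, cfg$samples, cfg$channels,
                        byrow = TRUE)
          X <- pmin(pmax(X, -lim), lim)
          i <- i + 1L
          labels[i] <- tpl$activity[a]
          subjects[i] <- subj
          segments[[i]] <- sensor_segment(X, label = tpl$activity[a],
                                          subject = subj)
        }
      }
    }
    structure(list(segments = segments,
                   labels = factor(labels,
                                   levels = tpl$activity[
                                     seq_len(cfg$n_activities)]),
                   subjects = subjects, config = cfg),
              class = "har_dataset")
  })
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf("har_dataset: %d segments, %d activities, %d subjects\n",
              length(x$segments), nlevels(x$labels),
              length(unique(x$subjects))))
  invisible(x)
}

#' Write a dataset as a plain-text segment directory tree
#'
#' Lays out segments as `a<ii>/p<j>/s<kk>.txt` under `root`, each file
#' holding 125 lines of 45 comma-separated values (position-major
#' channel order).  Values are written with 17 significant digits so the
#' tree round-trips bit-exactly through [read_segment_dir()].
#'
#' @param dataset A `har_dataset`.
#' @param root Writable output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_dsa_layout <- function(dataset, root) {
  stopifnot(inherits(dataset, "har_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counters <- new.env(parent = emptyenv())
  for (i in seq_along(dataset$segments)) {
    seg <- dataset$segments[[i]]
    a <- as.integer(dataset$labels[i])
    subj <- dataset$subjects[i]
    key <- sprintf("a%02d_p%d", a, subj)
    k <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
    counters[[key]] <- k
    dir <- file.path(root, sprintf("a%02d", a), sprintf("p%d", subj))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    lines <- apply(seg$data, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, file.path(dir, sprintf("s%02d.txt", k)))
  }
  invisible(root)
}
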