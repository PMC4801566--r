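#' Read a plain-text segment directory tree
#'
#' Parses the `a<ii>/p<j>/s<kk>.txt` layout written by
#' [write_dsa_layout()]: one file per 5-second segment, 125 lines of 45
#' comma-separated values.  Activity labels and subject ids come from the
#' directory names.  Malformed files are rejected with the offending file
#' (and line) named.
#'
#' @param root Directory containing `a01`, `a02`, ... subdirectories.
#' @return A `har_dataset`.
#' @export
read_segment_dir <- function(root) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root),
                              call. = FALSE)
  adirs <- sort(list.files(root, pattern = "^a[0-9]{2}$"))
  segments <- list(); labels <- character(0); subjects <- integer(0)
  for (a in adirs) {
    pdirs <- sort(list.files(file.path(root, a), pattern = "^p[0-9]+$"))
    for (p in pdirs) {
      subj <- as.integer(sub("^p", "", p))
      files <- sort(list.files(file.path(root, a, p),
                               pattern = "^s[0-9]+\\.txt$"))
      for (f in files) {
        path <- file.path(root, a, p, f)
        lines <- readLines(path)
        if (length(lines) != 125L)
          stop(sprintf("%s: expected 125 lines, found %d", path,
                       length(lines)), call. = FALSE)
        vals <- strsplit(lines, ",", fixed = TRUE)
        bad <- which(lengths(vals) != 45L)
        if (length(bad) > 0L)
          stop(sprintf("%s: line %d has %d values (expected 45)", path,
                       bad[1L], lengths(vals)[bad[1L]]), call. = FALSE)
        X <- matrix(as.numeric(unlist(vals)), nrow = 125L, byrow = TRUE)
        if (anyNA(X))
          stop(sprintf("%s: non-numeric value", path), call. = FALSE)
        segments[[length(segments) + 1L]] <-
          sensor_segment(X, label = a, subject = subj)
        labels <- c(labels, a)
        subjects <- c(subjects, subj)
      }
    }
  }
  if (length(segments) == 0L)
    warning(sprintf("no segments found under %s", root), call. = FALSE)
  message(sprintf("read %d segments (%d activities, %d subjects) from %s",
                  length(segments), length(unique(labels)),
                  length(unique(subjects)), root))
  structure(list(segments = segments,
                 labels = factor(labels, levels = unique(labels)),
                 subjects = subjects, config = NULL),
            class = "har_dataset")
}

#' Write / read a feature matrix as TSV
#'
#' Tab-separated text with a header row of feature names
#' (`feature:channel` ids where available).  Values carry 17 significant
#' digits and round-trip exactly.
#'
#' @param features Numeric matrix, one segment per row.
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the matrix.
#' @export
write_features <- function(features, path) {
  features <- as.matrix(features)
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(features)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cn, collapse = "\t"), con)
  writeLines(apply(features, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(tab)
}

# ---- checkpoint serialization -------------------------------------------
# Numerics are stored as %.17g strings inside JSON so that a save -> load
# round trip is bit-exact (plain JSON numbers lose precision).

num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

mat_out <- function(M) list(dim = dim(M), data = num_out(M))
mat_in <- function(o) matrix(num_in(o$data), o$dim[1L], o$dim[2L])

act_out <- function(a) list(k = num_out(a$k), c = num_out(a$c),
                            sigma = num_out(a$sigma),
                            train_mode = a$train_mode, plain = a$plain)
act_in <- function(o) activation_config(num_in(o$k), num_in(o$c),
                                        num_in(o$sigma),
                                        isTRUE(o$train_mode),
                                        isTRUE(o$plain))

net_out <- function(net) {
  list(act = act_out(net$act),
       layers = lapply(net$layers, function(l)
         list(W = mat_out(l$W), b = num_out(l$b))))
}
net_in <- function(o) {
  structure(list(layers = lapply(o$layers, function(l)
    list(W = mat_in(l$W), b = num_in(l$b))),
    act = act_in(o$act)), class = "cae_net")
}

#' Save / load a model checkpoint
#'
#' One self-describing JSON archive holding every weight matrix and bias
#' vector, the activation and loss configuration, the input
#' normalisation map and (for classifiers) the label codebook.  The
#' round trip `load_checkpoint(save_checkpoint(m))` is bit-exact.
#'
#' @param model A `cae_net`, [cae_params()] or `dbn_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- if (inherits(model, "dbn_model")) {
    list(type = "dbn_model",
         net = net_out(model$net),
         codebook = model$codebook,
         norm = list(mins = num_out(model$norm$mins),
                     ranges = num_out(model$norm$ranges)),
         lambda_decay = num_out(model$spec$lc$lambda_decay),
         layer_sizes = model$spec$layer_sizes)
  } else if (inherits(model, "cae_params")) {
    list(type = "cae_params", net = net_out(as_cae_net(model)))
  } else if (inherits(model, "cae_net")) {
    list(type = "cae_net", net = net_out(model))
  } else stop("unsupported model class", call. = FALSE)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  o <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  net <- net_in(o$net)
  switch(o$type,
    cae_net = net,
    cae_params = as_cae_params(net),
    dbn_model = {
      ls <- as.integer(unlist(o$layer_sizes))
      spec <- dbn_spec(layer_sizes = ls, act = net$act,
                       lc = loss_config(num_in(o$lambda_decay)))
      structure(list(net = net,
                     codebook = unlist(o$codebook),
                     norm = list(mins = num_in(unlist(o$norm$mins)),
                                 ranges = num_in(unlist(o$norm$ranges))),
                     spec = spec, history = NULL),
                class = "dbn_model")
    },
    stop("unknown checkpoint type", call. = FALSE))
}
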