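#' Write / read recordings in a portable binary + JSON-sidecar format
#'
#' Arrays are stored as little-endian IEEE-754 doubles in `<path>.bin`
#' (column-major, i.e. the first array index varies fastest) with all
#' metadata — dimensions, sampling rate, channel labels, codebook,
#' epoch layout — in `<path>.json`.  The format is deliberately trivial so
#' that any analysis environment can read it with two lines of code.
#'
#' @param x An [epoch_array][simulate_epochs] or
#'   [continuous_recording][simulate_continuous].
#' @param path Output path without extension; `.json` and `.bin` are added.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  meta <- list(format = "zpbci-recording", version = 1L,
               kind = class(x)[1],
               dim = dim(x$values), fs = x$fs,
               channel_labels = x$channel_labels,
               dtype = "float64", byte_order = "little",
               data_file = paste0(basename(path), ".bin"))
  if (!is.null(x$codebook))
    meta$codebook <- list(frequencies = x$codebook$frequencies,
                          phases = x$codebook$phases,
                          name = x$codebook$name)
  for (f in c("stim_onset_s", "stim_s", "rest_s", "latency_s"))
    if (!is.null(x[[f]])) meta[[f]] <- x[[f]]
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @return `read_recording()` returns the stored `epoch_array` or
#'   `continuous_recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "zpbci-recording"))
    stop("not a zpbci recording: ", path)
  bin <- file.path(dirname(path), meta$data_file)
  n <- prod(meta$dim)
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8L, endian = "little")
  if (length(vals) != n) stop("truncated data file: ", bin)
  dim(vals) <- meta$dim
  if (length(meta$dim) == 2 &&
      length(meta$channel_labels) == meta$dim[1])
    dimnames(vals) <- list(meta$channel_labels, NULL)
  cb <- if (!is.null(meta$codebook))
    new_codebook(meta$codebook$frequencies, meta$codebook$phases,
                 meta$codebook$name)
  out <- list(values = vals, fs = meta$fs,
              channel_labels = meta$channel_labels, codebook = cb)
  for (f in c("stim_onset_s", "stim_s", "rest_s", "latency_s"))
    if (!is.null(meta[[f]])) out[[f]] <- meta[[f]]
  structure(out, class = meta$kind)
}

#' Save / load a trained classifier as JSON
#'
#' Weights, running statistics and configuration are serialized to a single
#' (large) JSON file in full double precision.
#'
#' @param model A [build_model()] / [train_cnn()] object.
#' @param path Output file path.
#' @return `path` invisibly; `read_model()` returns the `zp_cnn`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "zp_cnn"))
  payload <- list(format = "zpbci-model", version = 1L,
                  cfg = unclass(model$cfg),
                  weights = lapply(model$weights, function(w)
                    list(dim = dim(w) %||% length(w), data = as.numeric(w))),
                  running = model$running,
                  loss_trace = model$loss_trace,
                  trained = model$trained)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "zpbci-model")) stop("not a zpbci model: ", path)
  cfg <- structure(p$cfg, class = "model_config")
  w <- lapply(p$weights, function(el) {
    if (length(el$dim) == 2) matrix(el$data, el$dim[1], el$dim[2])
    else as.numeric(el$data)
  })
  structure(list(cfg = cfg, weights = w,
                 running = lapply(p$running, as.numeric),
                 loss_trace = p$loss_trace, trained = isTRUE(p$trained)),
            class = "zp_cnn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
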