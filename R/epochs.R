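#' Epoched multichannel EEG container
#'
#' `epoch_set()` bundles a trials x channels x samples array of epoched EEG
#' (microvolts) with its per-trial class labels, time axis, sampling rate,
#' channel montage and block membership. It is the currency passed between
#' every stage of the pipeline: the synthetic generator produces it, the
#' preprocessing stages transform it, and the decoders consume it.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param labels character or factor of length `n_trials`, trial class,
#'   conventionally `"standard"` and `"deviant"`.
#' @param times numeric vector of length `n_samples`, seconds relative to
#'   stimulus onset, strictly increasing with spacing `1/sfreq`.
#' @param sfreq sampling frequency in Hz.
#' @param channels character vector of channel names, length `n_channels`.
#' @param block_id integer vector of length `n_trials`, recording-block index
#'   of each trial. Defaults to all 1.
#' @param meta optional named list of free-form provenance (subject id,
#'   session day, processing log).
#'
#' @return An object of class `epoch_set`: a list with elements `data`,
#'   `labels` (factor), `times`, `sfreq`, `channels`, `block_id`, `meta`.
#' @export
epoch_set <- function(data, labels, times, sfreq, channels,
                      block_id = NULL, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  n_trials <- dim(data)[1L]
  if (is.null(block_id)) block_id <- rep(1L, n_trials)
  e <- structure(
    list(data = data,
         labels = factor(as.character(labels)),
         times = as.numeric(times),
         sfreq = as.numeric(sfreq),
         channels = as.character(channels),
         block_id = as.integer(block_id),
         meta = meta),
    class = "epoch_set")
  validate_epoch_set(e)
  e
}

#' @rdname epoch_set
#' @param e an `epoch_set`.
#' @export
validate_epoch_set <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  d <- dim(e$data)
  if (length(e$labels) != d[1L])
    stop("labels length (", length(e$labels), ") != number of trials (", d[1L], ")")
  if (length(e$channels) != d[2L])
    stop("channels length (", length(e$channels), ") != number of channels (", d[2L], ")")
  if (length(e$times) != d[3L])
    stop("times length (", length(e$times), ") != number of samples (", d[3L], ")")
  if (length(e$block_id) != d[1L])
    stop("block_id length != number of trials")
  if (e$sfreq <= 0) stop("sfreq must be positive")
  if (d[3L] >= 2L) {
    dt <- diff(e$times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(abs(dt - 1 / e$sfreq)) > 1e-6 / e$sfreq)
      stop("time-axis spacing is inconsistent with sfreq")
  }
  invisible(e)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$sfreq, " Hz\n", sep = "")
  cat("  time: [", format(min(x$times), digits = 4), ", ",
      format(max(x$times), digits = 4), "] s\n", sep = "")
  cat("  classes:", paste(sprintf("%s=%d", levels(x$labels),
                                  tabulate(x$labels)), collapse = ", "), "\n")
  cat("  blocks:", paste(sort(unique(x$block_id)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param e an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(e) dim(e$data)[1L]

#' Subset trials of an epoch set
#'
#' @param x an `epoch_set`.
#' @param i trial indices (integer or logical).
#' @param ... unused.
#' @return an `epoch_set` containing the selected trials, in the order given.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  x$data <- x$data[i, , , drop = FALSE]
  x$labels <- factor(x$labels[i])
  x$block_id <- x$block_id[i]
  validate_epoch_set(x)
  x
}

#' Concatenate recording blocks into a superblock
#'
#' Stacks the trials of several blocks, in the order given, into a single
#' epoch set ("superblock"). Concatenating all blocks of a session raises the
#' trial count available for classifier training and averages over
#' within-session variability. Block membership is preserved per trial in
#' `block_id`.
#'
#' @param blocks list of `epoch_set` objects sharing montage, sampling rate
#'   and time axis.
#' @return a single `epoch_set`; trial count is the sum over blocks.
#' @export
concatenate_superblock <- function(blocks) {
  if (inherits(blocks, "epoch_set")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L)
  lapply(blocks, validate_epoch_set)
  ref <- blocks[[1L]]
  for (b in blocks[-1L]) {
    if (!identical(b$channels, ref$channels))
      stop("montage mismatch between blocks")
    if (length(b$times) != length(ref$times) ||
        max(abs(b$times - ref$times)) > 1e-9)
      stop("time-axis mismatch between blocks")
    if (b$sfreq != ref$sfreq) stop("sfreq mismatch between blocks")
  }
  dat <- do.call(abind3, lapply(blocks, `[[`, "data"))
  epoch_set(
    data = dat,
    labels = unlist(lapply(blocks, function(b) as.character(b$labels))),
    times = ref$times, sfreq = ref$sfreq, channels = ref$channels,
    block_id = unlist(lapply(blocks, `[[`, "block_id")),
    meta = ref$meta)
}

# bind 3-D arrays along the first (trial) dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  n <- sum(vapply(xs, function(x) dim(x)[1L], integer(1)))
  out <- array(NA_real_, c(n, d[2L], d[3L]))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1L]
    out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

#' Write / read the on-disk epoch container
#'
#' The container is a directory holding `data.bin`, the epoch array as raw
#' little-endian float64 with sample index varying fastest (trial-major C
#' order: trial, then channel, then sample), and `meta.json`, a sidecar with
#' dimensions, labels, time axis, sampling rate, channel names, block ids and
#' free-form metadata. Both halves are plain and documented so other tools
#' can consume them.
#'
#' @param e an `epoch_set`.
#' @param path directory to create/read.
#' @return `write_epoch_set()` returns `path` invisibly; `read_epoch_set()`
#'   returns the reconstructed `epoch_set`, byte-identical data included.
#' @export
write_epoch_set <- function(e, path) {
  validate_epoch_set(e)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(e$data)
  # aperm so that sample varies fastest in the stream
  flat <- as.numeric(aperm(e$data, c(3L, 2L, 1L)))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 8L, endian = "little")
  side <- list(
    format = "erpmvpa-epochs-v1",
    dims = list(trials = d[1L], channels = d[2L], samples = d[3L]),
    dtype = "float64", byte_order = "little",
    order = "trial-major; sample fastest",
    labels = as.character(e$labels),
    times = e$times, sfreq = e$sfreq,
    channels = e$channels, block_id = e$block_id,
    meta = e$meta)
  jsonlite::write_json(side, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  side <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(side$format, "erpmvpa-epochs-v1"))
    stop("not an erpmvpa epoch container: ", path)
  d <- c(side$dims$trials, side$dims$channels, side$dims$samples)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  dat <- aperm(array(flat, dim = rev(d)), c(3L, 2L, 1L))
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  epoch_set(dat, side$labels, side$times, side$sfreq, side$channels,
            side$block_id, meta = as.list(meta))
}
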