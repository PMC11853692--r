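#' Preprocessing parameters
#'
#' Defaults follow common offline ERP conditioning for oddball recordings:
#' 0.1-30 Hz zero-phase Butterworth band-pass of order 4, 60 Hz notch,
#' +/-75 uV artifact threshold, -100..0 ms baseline, average-mastoid
#' reference.
#'
#' @param band `(low, high)` band-pass edges in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective roll-off is twice this order at zero phase).
#' @param notch notch frequency in Hz, or `NULL` to skip.
#' @param reject_threshold absolute amplitude threshold in microvolts.
#' @param baseline_window `(start, end)` seconds for baseline correction.
#' @param reference character pair of mastoid channel names, or `"none"`.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.1, 30), filter_order = 4L,
                              notch = 60, reject_threshold = 75,
                              baseline_window = c(-0.100, 0),
                              reference = "none") {
  stopifnot(band[1L] >= 0, band[1L] < band[2L], filter_order >= 1L,
            reject_threshold > 0, baseline_window[1L] < baseline_window[2L])
  structure(list(band = band, filter_order = as.integer(filter_order),
                 notch = notch, reject_threshold = reject_threshold,
                 baseline_window = baseline_window, reference = reference),
            class = "preprocess_config")
}

# zero-phase filter one vector with reflection padding against edge
# transients; pad length is capped at len - 1
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  signal::filtfilt(filt, xp)[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth band-pass and notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the
#' configured order per channel, followed by a zero-phase 2nd-order
#' Butterworth band-stop of +/-2 Hz around the notch frequency. Edge
#' transients are tamed by odd-symmetric reflection padding. Accepts either
#' continuous data (channels x samples matrix) or an `epoch_set`; filtering
#' continuous data before epoching is preferable because the 0.1 Hz
#' high-pass settles over seconds.
#'
#' @param x `epoch_set` or a channels x samples numeric matrix.
#' @param cfg a [preprocess_config()].
#' @param sfreq sampling rate in Hz; taken from `x` when it is an
#'   `epoch_set`.
#' @return filtered object of the same shape and class.
#' @export
bandpass_notch_filter <- function(x, cfg = preprocess_config(), sfreq = NULL) {
  if (inherits(x, "epoch_set")) {
    sfreq <- x$sfreq
    min_len <- dim(x$data)[3L]
  } else {
    stopifnot(is.matrix(x), !is.null(sfreq))
    min_len <- ncol(x)
  }
  nyq <- sfreq / 2
  if (cfg$band[2L] >= nyq)
    stop("band-pass upper edge must be below Nyquist (", nyq, " Hz)")
  if (!is.null(cfg$notch) && cfg$notch >= nyq)
    stop("notch frequency must be below Nyquist (", nyq, " Hz)")
  # IIR edge effects make very short segments meaningless
  if (min_len < max(3L * cfg$filter_order, 9L))
    stop("segment too short (", min_len, " samples) for an order-",
         cfg$filter_order, " zero-phase filter")
  low <- cfg$band[1L] / nyq
  bp <- if (low > 0)
    signal::butter(cfg$filter_order, c(low, cfg$band[2L] / nyq), type = "pass")
  else
    signal::butter(cfg$filter_order, cfg$band[2L] / nyq, type = "low")
  ns <- if (!is.null(cfg$notch))
    signal::butter(2L, c(cfg$notch - 2, cfg$notch + 2) / nyq, type = "stop")
  else NULL
  pad <- min(min_len - 1L, as.integer(3 * sfreq))
  fun <- function(v) {
    v <- filtfilt_padded(bp, v, pad)
    if (!is.null(ns)) v <- filtfilt_padded(ns, v, pad)
    v
  }
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    for (i in seq_len(d[1L]))
      for (j in seq_len(d[2L]))
        x$data[i, j, ] <- fun(x$data[i, j, ])
    x$meta$filtered <- sprintf("butterworth %g-%g Hz order %d, notch %s Hz",
                               cfg$band[1L], cfg$band[2L], cfg$filter_order,
                               if (is.null(cfg$notch)) "none" else cfg$notch)
    x
  } else {
    t(apply(x, 1L, fun))
  }
}

#' Re-reference to the average of the mastoids
#'
#' Subtracts the sample-wise mean of the two mastoid channels from every
#' channel, then drops the mastoids from the montage.
#'
#' @param e an `epoch_set` containing both mastoid channels.
#' @param mastoids character pair of channel names, e.g. `c("M1", "M2")`.
#' @return re-referenced `epoch_set` without the mastoid channels.
#' @export
rereference <- function(e, mastoids) {
  validate_epoch_set(e)
  stopifnot(length(mastoids) == 2L)
  idx <- match(mastoids, e$channels)
  if (anyNA(idx))
    stop("mastoid channel(s) not in montage: ",
         paste(mastoids[is.na(idx)], collapse = ", "))
  ref <- (e$data[, idx[1L], , drop = FALSE] +
          e$data[, idx[2L], , drop = FALSE]) / 2
  keep <- setdiff(seq_along(e$channels), idx)
  dat <- e$data[, keep, , drop = FALSE]
  dat <- dat - ref[, rep(1L, length(keep)), , drop = FALSE]
  e$data <- dat
  e$channels <- e$channels[keep]
  e$meta$reference <- paste("average of", paste(mastoids, collapse = "/"))
  validate_epoch_set(e)
  e
}

#' Baseline-correct each epoch
#'
#' Per trial and channel, subtracts the mean over the baseline window from
#' the entire epoch, so the baseline interval has mean zero afterwards.
#'
#' @param e an `epoch_set`.
#' @param window `(start, end)` seconds; must contain at least one sample and
#'   lie within the epoch support.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(e, window = c(-0.100, 0)) {
  validate_epoch_set(e)
  sel <- which(e$times >= window[1L] & e$times < window[2L])
  if (length(sel) == 0L)
    stop("baseline window [", window[1L], ", ", window[2L],
         ") s contains no samples")
  bl <- apply(e$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  e$data <- e$data - as.vector(bl)  # recycles over the sample dimension
  e$meta$baseline <- window
  e
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Removes every trial in which any channel at any sample exceeds the
#' threshold in absolute value (e.g. residual muscle or movement artifacts),
#' keeping labels and block ids consistent.
#'
#' @param e an `epoch_set`.
#' @param threshold absolute amplitude threshold in microvolts (default 75).
#' @return list with `epochs` (the retained trials) and `rejected` (integer
#'   indices of removed trials, relative to the input).
#' @export
reject_artifacts <- function(e, threshold = 75) {
  validate_epoch_set(e)
  stopifnot(threshold > 0)
  mx <- apply(abs(e$data), 1L, max)
  rejected <- which(mx > threshold)
  if (length(rejected) == n_trials(e))
    stop("all ", n_trials(e), " trials exceed +/-", threshold,
         " uV; nothing left to analyze")
  out <- if (length(rejected)) e[-rejected] else e
  out$meta$rejected_trials <- length(rejected)
  out$meta$reject_threshold <- threshold
  list(epochs = out, rejected = rejected)
}

#' Undersample the majority class to balance an oddball design
#'
#' Oddball designs are unbalanced by construction; classifier training uses
#' undersampling: majority-class trials are randomly removed without
#' replacement until both classes have the minority count. Performed once on
#' the assembled superblock, before any cross-validation split.
#'
#' @param e an `epoch_set` with both classes present.
#' @param seed integer seed for the random draw.
#' @return balanced `epoch_set` (trials keep their original relative order).
#' @export
undersample_balance <- function(e, seed = 1L) {
  validate_epoch_set(e)
  counts <- table(e$labels)
  if (length(counts) < 2L || any(counts == 0L))
    stop("both classes must be present to balance; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(e$labels == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  out <- e[sort(keep)]
  out$meta$undersampled_from <- as.list(counts)
  out
}

#' Cut continuous data into stimulus-locked epochs
#'
#' @param data channels x samples numeric matrix of continuous EEG.
#' @param events data frame with columns `sample` (1-based stimulus onset
#'   sample) and `label` (trial class).
#' @param sfreq sampling rate in Hz.
#' @param channels channel names, one per row of `data`.
#' @param window `(start, end)` seconds around each onset; samples span
#'   `[start, end)` half-open on the right.
#' @return an `epoch_set`; events whose window falls outside the recording
#'   are dropped with a warning.
#' @export
epoch_continuous <- function(data, events, sfreq, channels,
                             window = c(-0.100, 0.600)) {
  stopifnot(is.matrix(data), nrow(data) == length(channels),
            all(c("sample", "label") %in% names(events)))
  n_t <- floor(diff(window) * sfreq)
  offs <- round(window[1L] * sfreq)
  rel <- offs + seq_len(n_t) - 1L
  ok <- events$sample + min(rel) >= 1L &
        events$sample + max(rel) <= ncol(data)
  if (!all(ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0L) stop("no events with a complete epoch window")
  arr <- array(NA_real_, c(nrow(events), length(channels), n_t))
  for (i in seq_len(nrow(events)))
    arr[i, , ] <- data[, events$sample[i] + rel, drop = FALSE]
  times <- window[1L] + (seq_len(n_t) - 1L) / sfreq
  epoch_set(arr, events$label, times, sfreq, channels)
}

#' Run the full conditioning chain on one or more raw blocks
#'
#' Fixed stage order: filter, re-reference, baseline-correct, reject
#' artifacts, concatenate into a superblock, undersample. Each stage logs
#' its trial counts into the provenance trail (`meta$pipeline_log`). Stages
#' not configured (e.g. `reference = "none"`) are skipped but still logged.
#'
#' @param blocks list of `epoch_set` objects (or a single one).
#' @param cfg a [preprocess_config()].
#' @param filter logical; apply the band-pass/notch to each epoch (set to
#'   `FALSE` when epochs were cut from already-filtered continuous data or
#'   are synthetic).
#' @param balance logical; apply undersampling at the end.
#' @param seed seed for the undersampling draw.
#' @return a single preprocessed, balanced `epoch_set` with
#'   `meta$pipeline_log` describing every stage.
#' @export
preprocess_pipeline <- function(blocks, cfg = preprocess_config(),
                                filter = FALSE, balance = TRUE, seed = 1L) {
  if (inherits(blocks, "epoch_set")) blocks <- list(blocks)
  log <- character(0)
  blocks <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (filter) b <- bandpass_notch_filter(b, cfg)
    if (!identical(cfg$reference, "none")) b <- rereference(b, cfg$reference)
    b <- baseline_correct(b, cfg$baseline_window)
    r <- reject_artifacts(b, cfg$reject_threshold)
    log <<- c(log, sprintf("block %d: %d trials in, %d rejected (+/-%g uV)",
                           i, n_trials(b), length(r$rejected),
                           cfg$reject_threshold))
    r$epochs
  })
  e <- concatenate_superblock(blocks)
  log <- c(log, sprintf("superblock: %d trials (%s)", n_trials(e),
                        paste(sprintf("%s=%d", levels(e$labels),
                                      tabulate(e$labels)), collapse = ", ")))
  if (balance) {
    e <- undersample_balance(e, seed = seed)
    log <- c(log, sprintf("undersampled to %d trials (%s)", n_trials(e),
                          paste(sprintf("%s=%d", levels(e$labels),
                                        tabulate(e$labels)), collapse = ", ")))
  }
  e$meta$pipeline_log <- log
  e
}
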