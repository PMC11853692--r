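# Minimal BrainVision (vhdr/vmrk/data) reader.
#
# The header and marker files are INI-style text; the data file is either
# ASCII (multiplexed or vectorized) or binary multiplexed IEEE float32 /
# int16. Per-channel resolution is applied so values come out in the
# channel unit (conventionally microvolts).

parse_vhdr_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[sec]][trimws(key)] <- trimws(val)
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the text header (`.vhdr`), the marker file it names (stimulus
#' markers become events), and the data file in ASCII (multiplexed or
#' vectorized) or binary multiplexed `IEEE_FLOAT_32` / `INT_16` layout.
#' Channel resolutions are applied, so amplitudes are in the recorded unit
#' (microvolts by convention).
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return list with `data` (channels x samples matrix), `sfreq` (Hz),
#'   `channels`, and `events` (data frame: `type`, `code`, `sample`,
#'   1-based).
#' @export
read_brainvision <- function(vhdr) {
  hdr <- parse_vhdr_sections(readLines(vhdr, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr)
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  fmt <- toupper(ci[["DataFormat"]])
  orient <- toupper(if (is.null(ci[["DataOrientation"]])) "MULTIPLEXED"
                    else ci[["DataOrientation"]])
  chan_info <- hdr[["Channel Infos"]]
  parts <- strsplit(unname(chan_info[sprintf("Ch%d", seq_len(n_ch))]), ",")
  channels <- vapply(parts, `[`, character(1), 1L)
  resolution <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1,
    numeric(1))
  dir <- dirname(vhdr)
  data_path <- file.path(dir, ci[["DataFile"]])
  if (fmt == "ASCII") {
    txt <- readLines(data_path, warn = FALSE)
    skip <- hdr[["ASCII Infos"]][["SkipLines"]]
    if (!is.null(skip) && as.integer(skip) > 0L)
      txt <- txt[-seq_len(as.integer(skip))]
    rows <- lapply(strsplit(trimws(txt), "[[:space:]]+"), function(r) {
      cols <- hdr[["ASCII Infos"]][["SkipColumns"]]
      if (!is.null(cols) && as.integer(cols) > 0L)
        r <- r[-seq_len(as.integer(cols))]
      as.numeric(gsub(",", ".", r, fixed = TRUE))
    })
    m <- do.call(rbind, rows)
    dat <- if (orient == "VECTORIZED") m else t(m)
  } else if (fmt == "BINARY") {
    bfmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]])
    sz <- file.info(data_path)$size
    con <- file(data_path, "rb")
    on.exit(close(con))
    raw_vals <- if (bfmt == "IEEE_FLOAT_32")
      readBin(con, "double", n = sz / 4, size = 4L, endian = "little")
    else if (bfmt == "INT_16")
      readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
              endian = "little")
    else stop("unsupported BinaryFormat: ", bfmt)
    if (orient != "MULTIPLEXED")
      stop("only MULTIPLEXED binary orientation is supported")
    dat <- matrix(raw_vals, nrow = n_ch)
  } else stop("unsupported DataFormat: ", fmt)
  dat <- dat * resolution
  rownames(dat) <- channels
  events <- data.frame(type = character(0), code = character(0),
                       sample = integer(0))
  mf <- ci[["MarkerFile"]]
  if (!is.null(mf) && file.exists(file.path(dir, mf))) {
    mk <- parse_vhdr_sections(readLines(file.path(dir, mf),
                                        warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      p <- strsplit(unname(mk), ",")
      events <- data.frame(
        type = vapply(p, `[`, character(1), 1L),
        code = vapply(p, `[`, character(1), 2L),
        sample = as.integer(vapply(p, `[`, character(1), 3L)))
    }
  }
  list(data = dat, sfreq = sfreq, channels = channels, events = events)
}

#' Epoch a BrainVision recording with an event-code mapping
#'
#' @param vhdr path to the `.vhdr` header.
#' @param code_map named character vector mapping marker codes (the second
#'   marker field, e.g. `"S  1"`) to class labels, e.g.
#'   `c("S  1" = "standard", "S  2" = "deviant")`.
#' @param window epoch window `(start, end)` seconds around each marker.
#' @return an `epoch_set` of the matched events.
#' @export
read_brainvision_epochs <- function(vhdr, code_map,
                                    window = c(-0.100, 0.600)) {
  rec <- read_brainvision(vhdr)
  ev <- rec$events[rec$events$code %in% names(code_map), , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("no events matched the code map (codes present: ",
         paste(unique(rec$events$code), collapse = ", "), ")")
  ev$label <- unname(code_map[ev$code])
  epoch_continuous(rec$data, ev, rec$sfreq, rec$channels, window)
}
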