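#' Default 11-channel 10/20 montage
#'
#' The reduced frontocentral/parietal/temporal montage usable at the bedside:
#' F3, Fz, F4, C3, Cz, C4, P3, Pz, P4, T7, T8.
#'
#' @return character vector of channel names.
#' @export
default_montage <- function() {
  c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4", "T7", "T8")
}

#' Specify an ERP difference component
#'
#' Describes one deviant-minus-standard difference component as a smooth
#' Gaussian bump in time spread over the montage by a per-channel topography
#' weight. The bump is `amplitude * exp(-(t - peak)^2 / (2 s^2))` with
#' `s = width / 2.355`, i.e. `width` is the full width at half maximum, and
#' is truncated to zero outside `peak +/- 3 s`.
#'
#' @param name component label, e.g. `"MMN"` or `"P3a"`.
#' @param peak_latency peak time in seconds post-stimulus.
#' @param width FWHM in seconds; must be > 0.
#' @param amplitude signed peak amplitude in microvolts (negative for MMN,
#'   positive for P3a).
#' @param topography numeric vector of per-channel weights in `[0, 1]`, one
#'   per montage channel (optionally named by channel); at least one weight
#'   must be positive.
#' @return object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency, width, amplitude, topography) {
  stopifnot(width > 0, is.numeric(topography), length(topography) >= 1L)
  if (any(topography < 0 | topography > 1))
    stop("topography weights must lie in [0, 1]")
  if (!any(topography > 0))
    stop("at least one topography weight must be > 0")
  structure(list(name = name, peak_latency = peak_latency, width = width,
                 amplitude = amplitude, topography = topography),
            class = "component_spec")
}

# temporal support of the truncated bump, seconds
component_support <- function(comp) {
  s <- comp$width / 2.355
  c(comp$peak_latency - 3 * s, comp$peak_latency + 3 * s)
}

# evaluate the bump (without topography) on a time axis
component_waveform <- function(comp, times) {
  s <- comp$width / 2.355
  w <- comp$amplitude * exp(-(times - comp$peak_latency)^2 / (2 * s^2))
  w[abs(times - comp$peak_latency) > 3 * s] <- 0
  w
}

#' Default MMN + P3a component pair
#'
#' Frontocentral MMN (peak 190 ms, FWHM 80 ms, -3 uV) and P3a (peak 300 ms,
#' FWHM 100 ms, +4 uV) with topography 1.0 at Fz/Cz, 0.7 at F3/F4/C3/C4,
#' 0.4 at P3/Pz/P4 and 0.2 at T7/T8 — the frontocentral gradient typical of
#' auditory oddball difference waves.
#'
#' @param montage channel-name vector; weights are assigned by name, unknown
#'   channels get weight 0.
#' @return list of two `component_spec` objects.
#' @export
default_components <- function(montage = default_montage()) {
  w <- c(F3 = 0.7, Fz = 1.0, F4 = 0.7, C3 = 0.7, Cz = 1.0, C4 = 0.7,
         P3 = 0.4, Pz = 0.4, P4 = 0.4, T7 = 0.2, T8 = 0.2)
  topo <- ifelse(montage %in% names(w), w[montage], 0)
  names(topo) <- montage
  list(
    component_spec("MMN", peak_latency = 0.190, width = 0.080,
                   amplitude = -3, topography = topo),
    component_spec("P3a", peak_latency = 0.300, width = 0.100,
                   amplitude = 4, topography = topo))
}

#' Block-level gain profile
#'
#' One nonnegative multiplier per recording block, applied to every
#' difference component in that block. A constant profile emulates a stable
#' responder; a profile that rises and falls emulates the waxing and waning
#' of the MMN observed over hours in some comatose patients.
#'
#' @param per_block_gain numeric vector of nonnegative multipliers.
#' @param description free label, e.g. `"constant"`, `"sinusoidal"`,
#'   `"custom"`.
#' @return object of class `gain_profile`.
#' @export
gain_profile <- function(per_block_gain, description = "custom") {
  stopifnot(is.numeric(per_block_gain), all(per_block_gain >= 0))
  structure(list(per_block_gain = as.numeric(per_block_gain),
                 description = description),
            class = "gain_profile")
}

#' Full parameterization of a synthetic oddball session
#'
#' @param n_blocks number of recording blocks.
#' @param trials_per_block trials per block.
#' @param p_deviant deviant probability per trial, in (0, 0.5] (the
#'   no-consecutive-deviants constraint caps it at one deviant every other
#'   trial); 0.5 yields a strictly alternating balanced design.
#' @param sfreq sampling rate, Hz.
#' @param epoch_window `(start, end)` seconds around stimulus onset; samples
#'   span `[start, end)` half-open on the right at `1/sfreq` spacing.
#' @param montage ordered channel names.
#' @param components list of [component_spec()] applied to deviant trials
#'   only (they define the deviant-minus-standard difference).
#' @param noise_white_sd white-noise standard deviation, microvolts.
#' @param noise_pink_scale 1/f background standard deviation, microvolts.
#' @param trial_amplitude_jitter_sd multiplicative per-trial gain jitter:
#'   each deviant trial's components are scaled by
#'   `max(0, 1 + N(0, jitter_sd))` on top of the block gain.
#' @param gain [gain_profile()] with one entry per block.
#' @param seed integer seed; the full session is reproducible from the
#'   config alone.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_blocks = 1L,
                              trials_per_block = 400L,
                              p_deviant = 0.15,
                              sfreq = 512,
                              epoch_window = c(-0.100, 0.600),
                              montage = default_montage(),
                              components = default_components(montage),
                              noise_white_sd = 10,
                              noise_pink_scale = 5,
                              trial_amplitude_jitter_sd = 0.1,
                              gain = gain_profile(rep(1, n_blocks), "constant"),
                              seed = 1L) {
  stopifnot(n_blocks >= 1L, trials_per_block >= 2L,
            p_deviant > 0, p_deviant <= 0.5,
            sfreq > 0, epoch_window[1L] < 0, epoch_window[2L] > 0,
            noise_white_sd >= 0, noise_pink_scale >= 0,
            trial_amplitude_jitter_sd >= 0)
  if (inherits(components, "component_spec")) components <- list(components)
  if (length(gain$per_block_gain) != n_blocks)
    stop("gain profile length (", length(gain$per_block_gain),
         ") must equal n_blocks (", n_blocks, ")")
  for (comp in components) {
    if (length(comp$topography) != length(montage))
      stop("component '", comp$name, "': topography needs one weight per channel")
    sup <- component_support(comp)
    if (sup[1L] < 0 || sup[2L] > epoch_window[2L])
      stop("component '", comp$name, "' support [",
           format(sup[1L], digits = 3), ", ", format(sup[2L], digits = 3),
           "] s exceeds the post-stimulus window [0, ",
           epoch_window[2L], "] s")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 p_deviant = p_deviant, sfreq = sfreq,
                 epoch_window = epoch_window, montage = montage,
                 components = components,
                 noise_white_sd = noise_white_sd,
                 noise_pink_scale = noise_pink_scale,
                 trial_amplitude_jitter_sd = trial_amplitude_jitter_sd,
                 gain = gain, seed = as.integer(seed)),
            class = "simulation_config")
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Draw an oddball trial sequence
#'
#' Standard/deviant labels with a long-run deviant fraction of `p_deviant`
#' and no two consecutive deviants (the usual oddball convention: a deviant
#' is always followed by at least one standard). The sequence is drawn
#' sequentially; after a deviant the next trial is forced to be a standard,
#' and the per-draw deviant probability is set to `p / (1 - p)` so the
#' stationary deviant rate equals `p_deviant`.
#'
#' @param n_trials number of trials (>= 2).
#' @param p_deviant target deviant fraction, in (0, 0.5]; 0.5 gives strict
#'   alternation, values above 0.5 cannot honor the constraint and error.
#' @param seed integer seed.
#' @return factor of length `n_trials` with levels `standard`, `deviant`.
#' @export
generate_trial_sequence <- function(n_trials, p_deviant, seed = 1L) {
  stopifnot(n_trials >= 2L)
  if (p_deviant <= 0 || p_deviant > 0.5)
    stop("p_deviant must lie in (0, 0.5]: with no two consecutive deviants, ",
         "at most every other trial can be a deviant")
  q <- p_deviant / (1 - p_deviant)  # per-draw rate, q/(1+q) = p
  with_seed(seed, {
    u <- stats::runif(n_trials)
    lab <- character(n_trials)
    prev_dev <- FALSE
    for (i in seq_len(n_trials)) {
      if (!prev_dev && u[i] < q) {
        lab[i] <- "deviant"; prev_dev <- TRUE
      } else {
        lab[i] <- "standard"; prev_dev <- FALSE
      }
    }
    factor(lab, levels = c("standard", "deviant"))
  })
}

# 1/f ("pink") noise, one trial x channel at a time is too slow; generate a
# whole n_samples x n_series matrix per call via FFT shaping. The amplitude
# profile is 1/sqrt(f) (zero at DC), scaled analytically so each series has
# expected standard deviation `scale`.
pink_noise_matrix <- function(n_samples, n_series, sfreq, scale) {
  if (scale <= 0 || n_samples < 4L)
    return(matrix(0, n_samples, n_series))
  k <- 0:(n_samples - 1L)
  f <- pmin(k, n_samples - k) * sfreq / n_samples
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  # for white input with unit variance, Var(out) = mean(shape^2)
  shape <- shape / sqrt(mean(shape^2))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  out <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n_samples
  out * scale
}

# simulate a single block; assumes the RNG stream is already positioned
simulate_block_data <- function(cfg, labels, block_gain, times) {
  n <- length(labels)
  n_ch <- length(cfg$montage)
  n_t <- length(times)
  dat <- array(0, c(n, n_ch, n_t))
  if (cfg$noise_pink_scale > 0) {
    pink <- pink_noise_matrix(n_t, n * n_ch, cfg$sfreq, cfg$noise_pink_scale)
    dat <- dat + aperm(array(pink, c(n_t, n, n_ch)), c(2L, 3L, 1L))
  }
  if (cfg$noise_white_sd > 0)
    dat <- dat + array(stats::rnorm(n * n_ch * n_t, sd = cfg$noise_white_sd),
                       c(n, n_ch, n_t))
  dev_idx <- which(labels == "deviant")
  if (length(dev_idx) > 0L && block_gain > 0 &&
      length(cfg$components) > 0L) {
    jit <- if (cfg$trial_amplitude_jitter_sd > 0)
      pmax(0, 1 + stats::rnorm(length(dev_idx),
                               sd = cfg$trial_amplitude_jitter_sd))
    else rep(1, length(dev_idx))
    # channels x samples template summed over components
    template <- matrix(0, n_ch, n_t)
    for (comp in cfg$components)
      template <- template + outer(as.numeric(comp$topography),
                                   component_waveform(comp, times))
    for (j in seq_along(dev_idx))
      dat[dev_idx[j], , ] <- dat[dev_idx[j], , ] +
        template * (block_gain * jit[j])
  }
  dat
}

#' Generate a synthetic oddball session, block by block
#'
#' Each block draws its own trial sequence and noise from a seed derived
#' deterministically from `config$seed` and the block index, so a session is
#' reproducible block-wise and [generate_epochs()] (the concatenation of all
#' blocks) is byte-identical to concatenating this function's output.
#' Deviant trials carry every configured difference component scaled by its
#' topography, the block gain and the per-trial jitter; standards are noise
#' only, and the pre-stimulus interval contains noise only by construction
#' (component support is confined to the post-stimulus window).
#'
#' @param config a [simulation_config()].
#' @return list of per-block `epoch_set` objects, length `n_blocks`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_t <- floor(diff(config$epoch_window) * config$sfreq)
  times <- config$epoch_window[1L] + (seq_len(n_t) - 1L) / config$sfreq
  lapply(seq_len(config$n_blocks), function(b) {
    bseed <- (as.numeric(config$seed) + 104729 * b) %% 2147483647
    labels <- generate_trial_sequence(config$trials_per_block,
                                      config$p_deviant, seed = bseed)
    dat <- with_seed(bseed + 1, {
      simulate_block_data(config, labels,
                          config$gain$per_block_gain[b], times)
    })
    epoch_set(dat, labels, times, config$sfreq, config$montage,
              block_id = rep(b, config$trials_per_block),
              meta = list(generator = "erpmvpa-synthetic",
                          block = b, seed = config$seed,
                          block_gain = config$gain$per_block_gain[b]))
  })
}

#' @rdname generate_session
#' @return `generate_epochs()` returns the session concatenated into one
#'   `epoch_set` (trials in block order).
#' @export
generate_epochs <- function(config) {
  concatenate_superblock(generate_session(config))
}

#' Read a simulation config from JSON or YAML
#'
#' The file mirrors [simulation_config()] field names; `components` is a list
#' of records with `name`, `peak_latency`, `width`, `amplitude`, `topography`
#' and `gain` is either a numeric vector or a record with `per_block_gain`
#' and `description`. Omitted fields keep their defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- read_config_file(path)
  args <- raw[intersect(names(raw), names(formals(simulation_config)))]
  if (!is.null(args$epoch_window)) args$epoch_window <- as.numeric(args$epoch_window)
  if (!is.null(args$montage)) args$montage <- as.character(args$montage)
  if (!is.null(args$components)) {
    comps <- args$components
    if (is.data.frame(comps))   # jsonlite simplifies record lists to this
      comps <- lapply(seq_len(nrow(comps)), function(i) as.list(comps[i, ]))
    args$components <- lapply(comps, function(cmp)
      component_spec(cmp$name, cmp$peak_latency, cmp$width, cmp$amplitude,
                     as.numeric(unlist(cmp$topography))))
  }
  if (!is.null(args$gain)) {
    g <- args$gain
    args$gain <- if (is.list(g) && !is.null(g$per_block_gain))
      gain_profile(as.numeric(unlist(g$per_block_gain)),
                   if (is.null(g$description)) "custom" else g$description)
    else gain_profile(as.numeric(unlist(g)))
  }
  do.call(simulation_config, args)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}
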