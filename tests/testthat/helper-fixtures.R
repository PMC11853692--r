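# Shared fixtures and independent oracles for the test suite.

# Exhaustive pairwise-count AUC: probability a positive beats a negative,
# ties counted one half. Deliberately naive; the reference the fast
# rank-based implementation is checked against.
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Balanced two-class epochs with an MMN-like component only (optionally
# silenced), small enough for fast decoding tests.
signal_config <- function(trials = 120, amplitude = -3, white_sd = 8,
                          pink = 3, jitter = 0.1, seed = 1,
                          n_blocks = 1, gain = NULL) {
  comps <- list(component_spec("MMN", 0.190, 0.080, amplitude,
                               mmn_topo()))
  if (is.null(gain)) gain <- gain_profile(rep(1, n_blocks), "constant")
  simulation_config(n_blocks = n_blocks, trials_per_block = trials,
                    p_deviant = 0.5, components = comps,
                    noise_white_sd = white_sd, noise_pink_scale = pink,
                    trial_amplitude_jitter_sd = jitter,
                    gain = gain, seed = seed)
}

mmn_topo <- function() {
  topo <- c(F3 = 0.7, Fz = 1.0, F4 = 0.7, C3 = 0.7, Cz = 1.0, C4 = 0.7,
            P3 = 0.4, Pz = 0.4, P4 = 0.4, T7 = 0.2, T8 = 0.2)
  topo[default_montage()]
}

# fast decoding configuration for unit tests
fast_cfg <- function(...) {
  args <- list(c_grid = 1, n_repetitions = 2, group_size = 2,
               time_decim = 16, seed = 7)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(decoding_config, args)
}

# minimal hand-built epoch_set
toy_epochs <- function(data, labels, sfreq = 100,
                       channels = paste0("ch", seq_len(dim(data)[2]))) {
  n_t <- dim(data)[3]
  epoch_set(data, labels, times = (seq_len(n_t) - 1) / sfreq - 0.02,
            sfreq = sfreq, channels = channels)
}
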