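test_that("trial sequences honor the deviant rate and oddball constraint", {
  lab <- generate_trial_sequence(1000, 0.15, seed = 11)
  n_dev <- sum(lab == "deviant")
  # binomial 99% interval at n=1000, p=0.15 (the sequential scheme has
  # smaller variance than i.i.d. draws, so this interval is conservative)
  expect_gte(n_dev, qbinom(0.005, 1000, 0.15))
  expect_lte(n_dev, qbinom(0.995, 1000, 0.15))
  # no two consecutive deviants
  expect_false(any(lab[-1] == "deviant" & lab[-1000] == "deviant"))
  # determinism
  expect_identical(lab, generate_trial_sequence(1000, 0.15, seed = 11))
  expect_false(identical(lab, generate_trial_sequence(1000, 0.15, seed = 12)))
  # p -> 0 limit: vanishing deviant rate
  expect_true(all(generate_trial_sequence(10, 1e-9, seed = 1) == "standard"))
  # constraint makes p > 0.5 impossible
  expect_error(generate_trial_sequence(100, 0.6), "0.5")
  # strict alternation at the cap
  lab5 <- generate_trial_sequence(10, 0.5, seed = 1)
  expect_equal(sum(lab5 == "deviant"), 5)
})

test_that("long-run deviant fraction matches p_deviant", {
  lab <- generate_trial_sequence(20000, 0.15, seed = 3)
  expect_lt(abs(mean(lab == "deviant") - 0.15), 0.01)
})

test_that("noiseless construction reproduces component amplitude exactly", {
  cfg <- signal_config(trials = 10, amplitude = -3, white_sd = 0, pink = 0,
                       jitter = 0, seed = 5)
  e <- generate_epochs(cfg)
  dev <- which(e$labels == "deviant")[1]
  std <- which(e$labels == "standard")[1]
  fz <- match("Fz", e$channels)
  peak_i <- which.min(abs(e$times - 0.190))
  # the sample grid does not land exactly on the nominal peak; compare to
  # the analytic template at the nearest sample
  s <- 0.080 / 2.355
  expected <- -3 * exp(-(e$times[peak_i] - 0.190)^2 / (2 * s^2))
  expect_equal(e$data[dev, fz, peak_i] - e$data[std, fz, peak_i], expected,
               tolerance = 1e-10)
  # standards carry no component at all
  expect_equal(max(abs(e$data[std, , ])), 0)
  # pre-stimulus is clean in deviants too (post-stimulus component support)
  expect_equal(max(abs(e$data[dev, , e$times < 0])), 0)
})

test_that("components whose support leaves the window are rejected", {
  expect_error(
    signal_config(trials = 10)$components, NA)
  expect_error(
    simulation_config(components = list(
      component_spec("early", peak_latency = 0.02, width = 0.08,
                     amplitude = -3, topography = mmn_topo()))),
    "support")
  expect_error(
    simulation_config(components = list(
      component_spec("late", peak_latency = 0.59, width = 0.08,
                     amplitude = 2, topography = mmn_topo()))),
    "support")
})

test_that("grand-average difference recovers the injected amplitude", {
  cfg <- signal_config(trials = 2000, amplitude = -3, white_sd = 10,
                       pink = 0, jitter = 0, seed = 9)
  e <- generate_epochs(cfg)
  fz <- match("Fz", e$channels)
  peak_i <- which.min(abs(e$times - 0.190))
  n_dev <- sum(e$labels == "deviant")
  n_std <- sum(e$labels == "standard")
  d <- mean(e$data[e$labels == "deviant", fz, peak_i]) -
    mean(e$data[e$labels == "standard", fz, peak_i])
  # oracle: standard error of a difference of independent means
  se <- 10 * sqrt(1 / n_dev + 1 / n_std)
  expect_lt(abs(d - (-3)), 3 * se)
})

test_that("simulation is deterministic and blocks concatenate consistently", {
  cfg <- signal_config(trials = 20, n_blocks = 3, seed = 21)
  e1 <- generate_epochs(cfg)
  e2 <- generate_epochs(cfg)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$labels, e2$labels)
  session <- generate_session(cfg)
  expect_length(session, 3)
  expect_equal(n_trials(concatenate_superblock(session)), 60)
  expect_identical(concatenate_superblock(session)$data, e1$data)
  expect_equal(e1$block_id, rep(1:3, each = 20))
})

test_that("gain profile scales the per-block class difference", {
  # blocks with gain 0 carry no decodable difference, gain-2 blocks twice
  # the gain-1 difference (linearity, noiseless)
  cfg <- signal_config(trials = 30, white_sd = 0, pink = 0, jitter = 0,
                       n_blocks = 3, gain = gain_profile(c(1, 0, 2)),
                       seed = 2)
  ses <- generate_session(cfg)
  fz <- match("Fz", default_montage())
  peak_i <- which.min(abs(ses[[1]]$times - 0.190))
  diff_of <- function(e)
    mean(e$data[e$labels == "deviant", fz, peak_i]) -
      mean(e$data[e$labels == "standard", fz, peak_i])
  expect_equal(diff_of(ses[[2]]), 0)
  expect_equal(diff_of(ses[[3]]), 2 * diff_of(ses[[1]]), tolerance = 1e-12)
  s <- 0.080 / 2.355
  expect_equal(diff_of(ses[[1]]),
               -3 * exp(-(ses[[1]]$times[peak_i] - 0.190)^2 / (2 * s^2)),
               tolerance = 1e-12)
})

test_that("per-block mean difference tracks a sinusoidal gain profile", {
  g <- 1 + sin(2 * pi * (0:7) / 4) / 2      # period 4 blocks over 8 blocks
  cfg <- signal_config(trials = 600, white_sd = 4, pink = 0, jitter = 0,
                       n_blocks = 8, gain = gain_profile(g, "sinusoidal"),
                       seed = 31)
  ses <- generate_session(cfg)
  fz <- match("Fz", default_montage())
  peak_i <- which.min(abs(ses[[1]]$times - 0.190))
  est <- vapply(ses, function(e)
    mean(e$data[e$labels == "deviant", fz, peak_i]) -
      mean(e$data[e$labels == "standard", fz, peak_i]), numeric(1))
  # oracle: injected per-block amplitude is -3 * gain; estimates should
  # correlate strongly with it at this trial count
  expect_gt(cor(est, -3 * g), 0.9)
})

test_that("pink-only background has a 1/f-like (negative) spectral slope", {
  cfg <- signal_config(trials = 60, amplitude = -3, white_sd = 0, pink = 5,
                       jitter = 0, seed = 13)
  e <- generate_epochs(cfg)
  pre <- e$data[, , e$times < 0]
  n <- dim(pre)[3]
  pw <- 0
  for (i in seq_len(dim(pre)[1]))
    for (j in seq_len(dim(pre)[2]))
      pw <- pw + Mod(fft(pre[i, j, ]))^2
  f <- (seq_len(n) - 1) / n * e$sfreq
  sel <- which(f > 0 & f <= e$sfreq / 2)
  fit <- lm(log(pw[sel]) ~ log(f[sel]))
  expect_lt(coef(fit)[2], -0.5)
  # and the pink scale sets the sd approximately
  expect_lt(abs(sd(as.vector(pre)) - 5) / 5, 0.15)
})

test_that("simulation configs round-trip through JSON", {
  cfg <- signal_config(trials = 24, seed = 8)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_blocks = cfg$n_blocks, trials_per_block = cfg$trials_per_block,
         p_deviant = cfg$p_deviant,
         components = lapply(cfg$components, unclass),
         noise_white_sd = cfg$noise_white_sd,
         noise_pink_scale = cfg$noise_pink_scale,
         trial_amplitude_jitter_sd = cfg$trial_amplitude_jitter_sd,
         gain = cfg$gain$per_block_gain, seed = cfg$seed),
    path, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_simulation_config(path)
  expect_identical(generate_epochs(cfg2)$data, generate_epochs(cfg)$data)
})
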