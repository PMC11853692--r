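#' ROC AUC from two score sets
#'
#' The probability that a randomly drawn positive-class score exceeds a
#' randomly drawn negative-class score, ties counted one half — the
#' normalized Mann-Whitney rank-sum statistic, equal to the area under the
#' ROC curve. 0.5 is chance, 1 is perfect separation, 0 is perfect
#' anti-separation.
#'
#' @param scores_positive,scores_negative numeric decision values for the
#'   positive (deviant) and negative (standard) class; both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_positive, scores_negative) {
  np <- length(scores_positive); nn <- length(scores_negative)
  if (np == 0L || nn == 0L)
    stop("both score sets must be non-empty")
  r <- rank(c(scores_positive, scores_negative))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# contiguous runs where x is TRUE; returns start/end indices
find_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Cluster-based permutation test of a decoding curve
#'
#' Single-subject (level-1) inference: the observed time-resolved AUC curve
#' is computed once; for each permutation the class labels are shuffled and
#' the complete decoding analysis is repeated with the identical
#' cross-validation schedule (same seed), so label exchange is the only
#' difference. The point-wise cluster-forming threshold is the
#' `1 - alpha` permutation quantile per time point; clusters are maximal
#' contiguous supra-threshold runs scored by their mass `sum(AUC - 0.5)`
#' (or their length with `cluster_stat = "size"`); the null distribution is
#' the maximum cluster statistic of each permutation curve against the same
#' thresholds; and each observed cluster gets
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param e a balanced two-class `epoch_set`.
#' @param cfg a [decoding_config()].
#' @param n_permutations label shuffles (>= 20; default 100).
#' @param alpha significance level (default 0.05); must satisfy
#'   `alpha >= 1 / (n_permutations + 1)`.
#' @param seed seed for the label shuffles (the decoding schedule itself is
#'   governed by `cfg$seed`).
#' @param cluster_stat `"mass"` (summed AUC - 0.5) or `"size"` (run length).
#' @param observed optionally, a precomputed `decoding_curve` for `e` under
#'   `cfg` (skips recomputing the observed curve).
#' @return a `cluster_test`: data frame `clusters` (start/end time, statistic,
#'   p value), `threshold` per time point, logical `significant_mask` (TRUE
#'   exactly inside clusters with `p <= alpha`), the `observed` curve,
#'   `null_max_stat`, `n_permutations` and `alpha`.
#' @export
permutation_cluster_test <- function(e, cfg = decoding_config(),
                                     n_permutations = 100L, alpha = 0.05,
                                     seed = 1L, cluster_stat = c("mass", "size"),
                                     observed = NULL) {
  cluster_stat <- match.arg(cluster_stat)
  if (n_permutations < 20L)
    stop("n_permutations must be at least 20")
  if (alpha < 1 / (n_permutations + 1))
    stop("alpha = ", alpha, " is unattainable with ", n_permutations,
         " permutations; need alpha >= 1/(n+1) = ",
         signif(1 / (n_permutations + 1), 3))
  if (is.null(observed)) observed <- decode_time_resolved(e, cfg)
  stopifnot(inherits(observed, "decoding_curve"))
  ntp <- length(observed$times)
  n <- n_trials(e)
  perm_auc <- matrix(NA_real_, n_permutations, ntp)
  for (p in seq_len(n_permutations)) {
    e_p <- e
    e_p$labels <- with_seed(seed + 7L * p, e$labels[sample(n)])
    perm_auc[p, ] <- suppressWarnings(decode_time_resolved(e_p, cfg)$auc)
  }
  # the observed curve enters the threshold-forming distribution as the
  # identity permutation; leaving it out makes the test anti-conservative
  # at small permutation counts (null curves are compared against their own
  # quantile, the observed curve against an independent one)
  threshold <- apply(rbind(observed$auc, perm_auc), 2L, stats::quantile,
                     probs = 1 - alpha, names = FALSE)
  stat_of <- function(curve, runs) {
    if (nrow(runs) == 0L) return(numeric(0))
    vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      if (cluster_stat == "mass") sum(curve[idx] - 0.5) else length(idx)
    }, numeric(1))
  }
  obs_runs <- find_runs(observed$auc > threshold)
  obs_stats <- stat_of(observed$auc, obs_runs)
  null_max <- vapply(seq_len(n_permutations), function(p) {
    runs <- find_runs(perm_auc[p, ] > threshold)
    s <- stat_of(perm_auc[p, ], runs)
    if (length(s) == 0L) 0 else max(s)
  }, numeric(1))
  p_values <- vapply(obs_stats, function(s)
    (1 + sum(null_max >= s)) / (n_permutations + 1), numeric(1))
  mask <- rep(FALSE, ntp)
  if (nrow(obs_runs) > 0L) {
    clusters <- data.frame(
      start_time = observed$times[obs_runs$start],
      end_time = observed$times[obs_runs$end],
      statistic = obs_stats,
      p_value = p_values)
    for (i in which(p_values <= alpha))
      mask[obs_runs$start[i]:obs_runs$end[i]] <- TRUE
  } else {
    clusters <- data.frame(start_time = numeric(0), end_time = numeric(0),
                           statistic = numeric(0), p_value = numeric(0))
  }
  structure(list(clusters = clusters, threshold = threshold,
                 significant_mask = mask, observed = observed,
                 null_max_stat = null_max,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, cluster_stat = cluster_stat),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", nrow(x$clusters), " cluster(s), ",
      sum(x$clusters$p_value <= x$alpha), " significant at alpha = ",
      x$alpha, " (", x$n_permutations, " permutations)\n", sep = "")
  if (nrow(x$clusters) > 0L) print(x$clusters)
  invisible(x)
}

#' Default component search windows
#'
#' MMN: 80-230 ms with a 50 ms peak-centered averaging window; P3a:
#' 250-350 ms with a 100 ms averaging window.
#'
#' @param component `"MMN"` or `"P3a"`.
#' @return list with `search` (start, end, seconds), `mean_width` (seconds)
#'   and `polarity` (-1 for a negative-going peak, +1 positive).
#' @export
component_window <- function(component = c("MMN", "P3a")) {
  component <- match.arg(component)
  if (component == "MMN")
    list(search = c(0.080, 0.230), mean_width = 0.050, polarity = -1)
  else
    list(search = c(0.250, 0.350), mean_width = 0.100, polarity = 1)
}

#' Extract a difference-wave component amplitude
#'
#' Computes the deviant-minus-standard difference wave averaged over a
#' channel set, finds the component peak inside its search window (most
#' negative point for the MMN, most positive for the P3a), and averages the
#' difference wave over a peak-centered window (50 ms for MMN, 100 ms for
#' P3a), clipped to the search window.
#'
#' @param e an `epoch_set` with both classes present.
#' @param component `"MMN"` or `"P3a"` (sets the default windows/polarity).
#' @param channels channel names to average over; default Fz and Cz.
#' @param window optional override of the search window `(start, end)` s.
#' @param mean_width optional override of the averaging width, seconds.
#' @param curve optional `decoding_curve`; when given, the maximum AUC
#'   within the search window is reported alongside.
#' @return an `amplitude_summary`: component name, search window, `peak_latency`
#'   (s), `peak_amplitude` and `mean_amplitude` (uV), `max_auc` (or NA),
#'   channel set.
#' @export
extract_component_amplitude <- function(e, component = c("MMN", "P3a"),
                                        channels = c("Fz", "Cz"),
                                        window = NULL, mean_width = NULL,
                                        curve = NULL) {
  validate_epoch_set(e)
  cw <- component_window(match.arg(component))
  if (!is.null(window)) cw$search <- window
  if (!is.null(mean_width)) cw$mean_width <- mean_width
  if (cw$search[1L] < min(e$times) - 1e-9 ||
      cw$search[2L] > max(e$times) + 1e-9)
    stop("search window [", cw$search[1L], ", ", cw$search[2L],
         "] s lies outside the epoch support")
  idx_ch <- match(channels, e$channels)
  if (anyNA(idx_ch))
    stop("channel(s) not in montage: ",
         paste(channels[is.na(idx_ch)], collapse = ", "))
  if (!all(c("standard", "deviant") %in% levels(e$labels)) ||
      any(tabulate(e$labels)[match(c("standard", "deviant"),
                                   levels(e$labels))] == 0L))
    stop("both standard and deviant trials are required")
  dev <- apply(e$data[e$labels == "deviant", idx_ch, , drop = FALSE],
               3L, mean)
  std <- apply(e$data[e$labels == "standard", idx_ch, , drop = FALSE],
               3L, mean)
  diffw <- dev - std
  sel <- which(e$times >= cw$search[1L] & e$times <= cw$search[2L])
  peak_i <- sel[if (cw$polarity < 0) which.min(diffw[sel])
                else which.max(diffw[sel])]
  peak_t <- e$times[peak_i]
  half <- cw$mean_width / 2
  lo <- max(peak_t - half, cw$search[1L])
  hi <- min(peak_t + half, cw$search[2L])
  msel <- which(e$times >= lo & e$times <= hi)
  max_auc <- NA_real_
  if (!is.null(curve)) {
    csel <- which(curve$times >= cw$search[1L] & curve$times <= cw$search[2L])
    if (length(csel)) max_auc <- max(curve$auc[csel])
  }
  structure(list(component = match.arg(component),
                 search_window = cw$search,
                 peak_latency = peak_t,
                 peak_amplitude = diffw[peak_i],
                 mean_amplitude = mean(diffw[msel]),
                 max_auc = max_auc,
                 channels = channels,
                 difference_wave = diffw,
                 times = e$times),
            class = "amplitude_summary")
}

#' @export
print.amplitude_summary <- function(x, ...) {
  cat("<amplitude_summary> ", x$component, ": peak ",
      format(x$peak_amplitude, digits = 3), " uV at ",
      round(x$peak_latency * 1000), " ms; mean ",
      format(x$mean_amplitude, digits = 3), " uV over peak window",
      if (!is.na(x$max_auc)) paste0("; max AUC ",
                                    format(x$max_auc, digits = 3)), "\n",
      sep = "")
  invisible(x)
}

#' Correlate component amplitude with peak decoding across subjects
#'
#' Pearson correlation (with its two-sided test) between per-subject
#' component mean amplitudes and per-subject maximum AUC within the
#' component's latency window. For a negative-going component such as the
#' MMN, stronger (more negative) amplitudes with better decoding yield a
#' negative r.
#'
#' @param amplitudes per-subject component mean amplitudes (uV), or a list
#'   of `amplitude_summary` objects carrying `max_auc`.
#' @param max_aucs per-subject maximum AUC within the component window
#'   (ignored when `amplitudes` is a list of summaries).
#' @return list with `r`, `p_value`, `df`, `n`.
#' @export
correlate_auc_amplitude <- function(amplitudes, max_aucs = NULL) {
  if (is.list(amplitudes) && inherits(amplitudes[[1L]], "amplitude_summary")) {
    max_aucs <- vapply(amplitudes, `[[`, numeric(1), "max_auc")
    amplitudes <- vapply(amplitudes, `[[`, numeric(1), "mean_amplitude")
  }
  stopifnot(length(amplitudes) == length(max_aucs))
  if (length(amplitudes) < 3L)
    stop("need at least 3 subjects")
  if (stats::sd(amplitudes) == 0 || stats::sd(max_aucs) == 0)
    stop("zero variance in amplitudes or AUCs; correlation undefined")
  ct <- stats::cor.test(amplitudes, max_aucs, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(amplitudes))
}
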