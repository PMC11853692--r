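#' Decoding configuration
#'
#' Parameters of the time-resolved MVPA procedure: a linear max-margin (SVM)
#' classifier on channels-as-features at each time point, scored by ROC AUC,
#' inside repeated stratified cross-validation with nested z-scoring and
#' pseudo-trial averaging.
#'
#' @param c_grid SVM regularization (cost) candidates; the default spans
#'   0.01-100 in 7 log-spaced steps. With more than one value, C is chosen
#'   per training fold by inner cross-validation (see `n_inner_folds`).
#' @param n_folds outer folds (default 5).
#' @param n_repetitions repetitions of the whole fold loop with fresh fold
#'   and group draws (default 10); the reported dispersion is the sd across
#'   the `n_folds * n_repetitions` AUC estimates.
#' @param group_size pseudo-trial averaging count `k`: within each fold
#'   partition, trials of a class are randomly split into groups of `k` and
#'   replaced by group means (5 for superblocks, 2 for single blocks).
#' @param metric performance metric; only `"AUC"` is implemented.
#' @param seed seed for fold assignment, grouping and C selection; two calls
#'   with the same seed use the identical cross-validation schedule.
#' @param time_decim keep every `time_decim`-th time point (1 = all).
#' @param n_inner_folds folds of the inner C-selection CV (default 3).
#' @param c_select_points number of evenly spaced time points the inner CV
#'   averages over when scoring each C candidate (default 12).
#' @param engine `"dualcd"` (default), the package's compiled dual
#'   coordinate-descent linear SVM, or `"libsvm"` (via e1071) — the two
#'   solve the same max-margin problem (bias handling differs slightly) and
#'   are cross-checked against each other in the test suite; `"dualcd"` is
#'   orders of magnitude faster in the per-time-point hot loop.
#' @return object of class `decoding_config`.
#' @export
decoding_config <- function(c_grid = c(0.01, 0.0464, 0.215, 1, 4.64, 21.5, 100),
                            n_folds = 5L, n_repetitions = 10L,
                            group_size = 5L, metric = "AUC", seed = 1L,
                            time_decim = 1L, n_inner_folds = 3L,
                            c_select_points = 12L,
                            engine = c("dualcd", "libsvm")) {
  stopifnot(length(c_grid) >= 1L, all(c_grid > 0), n_folds >= 2L,
            n_repetitions >= 1L, group_size >= 1L, time_decim >= 1L,
            n_inner_folds >= 2L)
  if (!identical(metric, "AUC")) stop("only the AUC metric is implemented")
  structure(list(c_grid = sort(c_grid), n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 group_size = as.integer(group_size), metric = metric,
                 seed = as.integer(seed), time_decim = as.integer(time_decim),
                 n_inner_folds = as.integer(n_inner_folds),
                 c_select_points = as.integer(c_select_points),
                 engine = match.arg(engine)),
            class = "decoding_config")
}

# positive class for scoring: "deviant" when present, else the last level
positive_class <- function(y) {
  lv <- levels(y)
  if ("deviant" %in% lv) "deviant" else lv[length(lv)]
}

# per-class trial index sets, ordered by first occurrence so the RNG
# schedule is invariant under a renaming of the two classes (this is what
# makes the label-flip antisymmetry of the AUC exact)
class_sets <- function(y, within = NULL) {
  sets <- lapply(levels(y), function(cl) which(y == cl))
  if (!is.null(within))
    sets <- lapply(sets, function(s) s[s %in% within])
  sets[order(vapply(sets, function(s)
    if (length(s)) min(s) else Inf, numeric(1)))]
}

# stratified fold assignment: per class, shuffle and deal round-robin
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (idx in class_sets(y)) {
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                   length(idx))
  }
  folds
}

# random partition of idx into floor(n/k) groups of exactly k; remainder
# trials are dropped
group_partition <- function(idx, k) {
  n_g <- length(idx) %/% k
  if (n_g < 1L) stop("fewer than k = ", k, " trials to form one pseudo-trial")
  shuffled <- idx[sample.int(length(idx))]
  lapply(seq_len(n_g), function(g) shuffled[(g - 1L) * k + seq_len(k)])
}

# G x n averaging matrix from a list of per-class group index lists
grouping_matrix <- function(groups, n) {
  m <- matrix(0, length(groups), n)
  for (g in seq_along(groups)) m[g, groups[[g]]] <- 1 / length(groups[[g]])
  m
}

#' Z-score with training statistics only
#'
#' Computes per-feature mean and sample standard deviation (n - 1) on the
#' training matrix, standardizes it, and applies the same statistics to the
#' test matrix — the nested normalization that keeps test data out of every
#' training computation. Features with zero training variance are centered
#' but left unscaled, with a warning.
#'
#' @param train,test numeric matrices, observations x features; `test` may
#'   be `NULL`.
#' @return list with `train`, `test`, and `stats` (a list of `mean` and `sd`
#'   vectors; zero-variance features report their sd as stored, scaling
#'   used 1). The `stats` element round-trips through [zscore_apply()].
#' @export
zscore_train_apply <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  zero <- !is.finite(sdv) | sdv <= 0
  if (any(zero))
    warning(sum(zero), " feature(s) with zero training variance: ",
            "centered but not scaled")
  scale_used <- ifelse(zero, 1, sdv)
  st <- list(mean = mu, sd = sdv, scale = scale_used)
  list(train = zscore_apply(train, st),
       test = if (is.null(test)) NULL else zscore_apply(test, st),
       stats = st)
}

#' @rdname zscore_train_apply
#' @param x matrix to transform.
#' @param stats a `stats` element from [zscore_train_apply()].
#' @export
zscore_apply <- function(x, stats) {
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$scale, "/")
}

#' Replace trials by randomized within-class group means
#'
#' Pseudo-trial (sample) averaging: within each class, trials are randomly
#' partitioned into groups of exactly `k` (remainder dropped) and each group
#' is replaced by its mean, raising the signal-to-noise ratio of the
#' resulting observations at the cost of their number.
#'
#' @param x an `epoch_set`, or a numeric matrix (trials x features).
#' @param labels class labels (required for a matrix input).
#' @param k group size; every class must have at least `k` trials.
#' @param seed integer seed for the random partition.
#' @return an object of the same kind as `x` containing
#'   `sum(floor(n_class / k))` pseudo-trials with their class labels (for an
#'   `epoch_set`, `block_id` is dropped to 1 since pseudo-trials may span
#'   blocks).
#' @export
average_samples <- function(x, labels = NULL, k, seed = 1L) {
  if (inherits(x, "epoch_set")) {
    e <- x
    d <- dim(e$data)
    res <- average_samples(matrix(e$data, d[1L], d[2L] * d[3L]),
                           e$labels, k, seed)
    return(epoch_set(array(res$x, c(nrow(res$x), d[2L], d[3L])),
                     res$labels, e$times, e$sfreq, e$channels,
                     meta = c(e$meta, list(averaged_k = k))))
  }
  stopifnot(is.matrix(x), !is.null(labels), k >= 1L)
  y <- factor(labels)
  groups <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop("class '", cl, "' has ", length(idx), " trials, fewer than k = ", k)
      group_partition(idx, k)
    }), recursive = FALSE)
  })
  M <- grouping_matrix(groups, nrow(x))
  ylab <- vapply(groups, function(g) as.character(y[g[1L]]), character(1))
  list(x = M %*% x, labels = factor(ylab, levels = levels(y)))
}

# fit a linear SVM and return a scoring rule oriented so that larger scores
# favor `pos`; degenerate fits (constant features) fall back to zero scores
fit_linear_svm <- function(x, y, C, pos, engine = "dualcd") {
  if (engine == "dualcd") {
    yy <- ifelse(y == pos, 1, -1)
    wb <- .svm_dualcd(x, yy, C)
    p <- ncol(x)
    return(list(w = wb[seq_len(p)], b = wb[p + 1L]))
  }
  m <- tryCatch(e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE),
                error = function(err) NULL)
  if (is.null(m)) return(list(w = rep(0, ncol(x)), b = 0))
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  if (!identical(m$levels[m$labels[1L]], pos)) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

# AUC of each column of a score matrix (rows = observations)
auc_columns <- function(S, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  apply(S, 2L, function(s)
    (sum(rank(s)[is_pos]) - np * (np + 1) / 2) / (np * nn))
}

# Per-fold preparation: group-average then standardize with train statistics.
# X2 is trials x (channels*times) with channels varying fastest per time.
# Consumes RNG (grouping draws). Returns z-scored pseudo-trial matrices.
prep_fold <- function(X2, y, train, test, k) {
  gr_tr <- unlist(lapply(class_sets(y, train), group_partition, k = k),
                  recursive = FALSE)
  gr_te <- unlist(lapply(class_sets(y, test), group_partition, k = k),
                  recursive = FALSE)
  Xt <- X2[train, , drop = FALSE]
  mu <- colMeans(Xt)
  sdv <- sqrt(pmax(colSums(Xt * Xt) - length(train) * mu^2, 0) /
                (length(train) - 1L))
  zero <- !is.finite(sdv) | sdv <= 1e-12 * pmax(abs(mu), 1)
  sc <- ifelse(zero, 1, sdv)
  Gtr <- grouping_matrix(gr_tr, nrow(X2)) %*% X2
  Gte <- grouping_matrix(gr_te, nrow(X2)) %*% X2
  Gtr <- sweep(sweep(Gtr, 2L, mu), 2L, sc, "/")
  Gte <- sweep(sweep(Gte, 2L, mu), 2L, sc, "/")
  lab <- function(gr) factor(vapply(gr, function(g) as.character(y[g[1L]]),
                                    character(1)), levels = levels(y))
  list(train = Gtr, ytr = lab(gr_tr), test = Gte, yte = lab(gr_te),
       mu = mu, sd = sdv, n_zero_var = sum(zero))
}

# inner-CV C selection on the training trials of one outer fold; consumes
# RNG. Scores each C by mean AUC over inner folds and a decimated set of
# time points, returning the maximizing C (ties -> smallest).
select_cost <- function(X2, y, train, cfg, col_of_time, ntp) {
  if (length(cfg$c_grid) == 1L) return(cfg$c_grid)
  ytr <- droplevels(y[train])
  pos <- positive_class(y)
  tp_eval <- unique(round(seq(1L, ntp,
                              length.out = min(cfg$c_select_points, ntp))))
  inner_folds <- stratified_folds(ytr, cfg$n_inner_folds)
  score <- numeric(length(cfg$c_grid))
  for (f in seq_len(cfg$n_inner_folds)) {
    itr <- train[inner_folds != f]
    ite <- train[inner_folds == f]
    if (length(unique(y[ite])) < 2L || length(unique(y[itr])) < 2L) next
    k_in <- min(cfg$group_size,
                min(table(y[itr])), min(table(y[ite])))
    pr <- prep_fold(X2, y, itr, ite, k_in)
    is_pos <- pr$yte == pos
    for (ci in seq_along(cfg$c_grid)) {
      a <- vapply(tp_eval, function(ti) {
        cols <- col_of_time(ti)
        fit <- fit_linear_svm(pr$train[, cols, drop = FALSE], pr$ytr,
                              cfg$c_grid[ci], pos, cfg$engine)
        s <- pr$test[, cols, drop = FALSE] %*% fit$w + fit$b
        auc_columns(s, is_pos)
      }, numeric(1))
      score[ci] <- score[ci] + mean(a)
    }
  }
  cfg$c_grid[which.max(score)]
}

# shared engine behind the time-resolved curve and the temporal
# generalization matrix; mode "diag" scores only at the training time,
# mode "tgm" scores every training-time classifier at every test time.
decode_engine <- function(e, cfg, mode = c("diag", "tgm"),
                          return_details = FALSE) {
  mode <- match.arg(mode)
  validate_epoch_set(e)
  y <- droplevels(e$labels)
  if (nlevels(y) != 2L)
    stop("decoding needs exactly two classes; got ", nlevels(y))
  counts <- table(y)
  if (any(counts < 2L * cfg$group_size))
    stop("each class needs at least 2*k = ", 2L * cfg$group_size,
         " trials; got ", paste(counts, collapse = ", "))
  if (counts[1L] != counts[2L])
    warning("classes are unbalanced (", paste(counts, collapse = " vs "),
            "); consider undersample_balance()")
  if (any(counts < cfg$n_folds))
    stop("each class needs at least n_folds = ", cfg$n_folds, " trials")
  if (min(counts) %/% cfg$n_folds < cfg$group_size)
    stop("a test fold would hold fewer than k = ", cfg$group_size,
         " trials per class (", min(counts), " trials / ", cfg$n_folds,
         " folds); reduce group_size or n_folds")
  d <- dim(e$data)
  n <- d[1L]; n_ch <- d[2L]; n_t <- d[3L]
  tsel <- seq(1L, n_t, by = cfg$time_decim)
  ntp <- length(tsel)
  # keep only the decimated time points' feature columns
  X2 <- matrix(e$data, n, n_ch * n_t)
  X2 <- X2[, rep((tsel - 1L) * n_ch, each = n_ch) + seq_len(n_ch),
           drop = FALSE]
  col_of_time <- function(ti) (ti - 1L) * n_ch + seq_len(n_ch)
  pos <- positive_class(y)
  n_est <- cfg$n_folds * cfg$n_repetitions
  auc_est <- if (mode == "diag") matrix(NA_real_, n_est, ntp)
  tgm_sum <- if (mode == "tgm") matrix(0, ntp, ntp)
  details <- if (return_details) vector("list", n_est)
  zero_var_total <- 0L
  est <- 0L
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_repetitions)) {
      folds <- stratified_folds(y, cfg$n_folds)
      for (f in seq_len(cfg$n_folds)) {
        est <- est + 1L
        train <- which(folds != f)
        test <- which(folds == f)
        pr <- prep_fold(X2, y, train, test, cfg$group_size)
        zero_var_total <- zero_var_total + pr$n_zero_var
        C <- select_cost(X2, y, train, cfg, col_of_time, ntp)
        is_pos <- pr$yte == pos
        if (mode == "diag") {
          for (ti in seq_len(ntp)) {
            cols <- col_of_time(ti)
            fit <- fit_linear_svm(pr$train[, cols, drop = FALSE], pr$ytr,
                                  C, pos, cfg$engine)
            s <- pr$test[, cols, drop = FALSE] %*% fit$w + fit$b
            auc_est[est, ti] <- auc_columns(s, is_pos)
          }
        } else {
          W <- matrix(0, n_ch, ntp); b <- numeric(ntp)
          for (ti in seq_len(ntp)) {
            cols <- col_of_time(ti)
            fit <- fit_linear_svm(pr$train[, cols, drop = FALSE], pr$ytr,
                                  C, pos, cfg$engine)
            W[, ti] <- fit$w; b[ti] <- fit$b
          }
          g <- nrow(pr$test)
          # scores of every train-time classifier at every test time
          for (tj in seq_len(ntp)) {
            S <- pr$test[, col_of_time(tj), drop = FALSE] %*% W +
              matrix(b, g, ntp, byrow = TRUE)
            tgm_sum[, tj] <- tgm_sum[, tj] + auc_columns(S, is_pos)
          }
        }
        if (return_details)
          details[[est]] <- list(repetition = r, fold = f, train = train,
                                 test = test, cost = C, mean = pr$mu,
                                 sd = pr$sd)
      }
    }
  })
  if (zero_var_total > 0L)
    warning(zero_var_total,
            " zero-variance training feature(s) centered but not scaled")
  times <- e$times[tsel]
  n_pseudo <- floor(min(counts) * (cfg$n_folds - 1) / cfg$n_folds /
                      cfg$group_size)
  if (mode == "diag") {
    structure(list(times = times,
                   auc = colMeans(auc_est),
                   dispersion = apply(auc_est, 2L, stats::sd),
                   estimates = auc_est,
                   n_effective_trials = n_pseudo,
                   config = cfg, details = details),
              class = "decoding_curve")
  } else {
    structure(list(train_times = times, test_times = times,
                   auc = tgm_sum / n_est, config = cfg, details = details),
              class = "temporal_generalization")
  }
}

#' Time-resolved decoding of standard vs deviant responses
#'
#' At every time point, the channels form the feature vector and a linear
#' SVM is trained to discriminate the two trial classes, inside `n_folds`
#' stratified cross-validation repeated `n_repetitions` times. Within each
#' training fold, features are z-scored with training statistics, trials are
#' replaced by randomized within-class group means (test trials grouped
#' independently with the same training statistics applied), and the SVM
#' cost is chosen by inner cross-validation over `c_grid`. Held-out
#' pseudo-trials are scored by ROC AUC.
#'
#' @param e a balanced two-class `epoch_set`.
#' @param cfg a [decoding_config()].
#' @param return_details keep per-fold provenance (train/test indices,
#'   chosen cost, training statistics) for auditing fold hygiene.
#' @return a `decoding_curve`: `times`, mean `auc` per time point,
#'   `dispersion` (sd across the fold-by-repetition estimates), the raw
#'   `estimates` matrix, `n_effective_trials` (per-class pseudo-trials in a
#'   training fold) and the config echo.
#' @export
decode_time_resolved <- function(e, cfg = decoding_config(),
                                 return_details = FALSE) {
  decode_engine(e, cfg, mode = "diag", return_details = return_details)
}

#' Temporal generalization matrix
#'
#' Trains the per-time-point classifiers exactly as
#' [decode_time_resolved()] (same folds, groups and cost selection for the
#' same seed) and evaluates each on every other time point of the held-out
#' pseudo-trials, yielding a train-time x test-time AUC grid whose diagonal
#' reproduces the time-resolved curve. Off-diagonal structure indicates
#' representations shared or reactivated across latencies.
#'
#' @inheritParams decode_time_resolved
#' @return a `temporal_generalization`: `train_times`, `test_times`, and the
#'   mean AUC matrix (train time in rows, test time in columns).
#' @export
decode_temporal_generalization <- function(e, cfg = decoding_config(),
                                           return_details = FALSE) {
  decode_engine(e, cfg, mode = "tgm", return_details = return_details)
}

#' @export
print.decoding_curve <- function(x, ...) {
  i <- which.max(x$auc)
  cat("<decoding_curve> ", length(x$times), " time points, peak AUC ",
      format(x$auc[i], digits = 3), " at ",
      round(x$times[i] * 1000), " ms\n", sep = "")
  invisible(x)
}

#' @export
print.temporal_generalization <- function(x, ...) {
  cat("<temporal_generalization> ", length(x$train_times), " x ",
      length(x$test_times), " AUC grid, max ",
      format(max(x$auc), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Default searchlight windows
#'
#' The baseline (-100..0 ms) plus ten 50 ms bins from 50 to 550 ms.
#'
#' @return list of `(start, end)` pairs in seconds.
#' @export
searchlight_windows <- function() {
  c(list(c(-0.100, 0)),
    lapply(seq(0.050, 0.500, by = 0.050), function(s) c(s, s + 0.050)))
}

# repeated-CV AUC for an arbitrary feature matrix (one searchlight cell)
cv_auc_features <- function(FX, y, cfg) {
  pos <- positive_class(y)
  aucs <- numeric(0)
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_repetitions)) {
      folds <- stratified_folds(y, cfg$n_folds)
      for (f in seq_len(cfg$n_folds)) {
        train <- which(folds != f); test <- which(folds == f)
        pr <- prep_fold(FX, y, train, test, cfg$group_size)
        C <- if (length(cfg$c_grid) == 1L) cfg$c_grid else 1
        fit <- fit_linear_svm(pr$train, pr$ytr, C, pos, cfg$engine)
        s <- pr$test %*% fit$w + fit$b
        aucs <- c(aucs, auc_columns(s, pr$yte == pos))
      }
    }
  })
  mean(aucs)
}

#' Channel-by-window searchlight decoding
#'
#' Repeats the cross-validated classification with the feature set restricted
#' to a single channel's samples within one time window, for every channel
#' and window, mapping where in space and time the discriminative
#' information lies. The cost parameter is fixed at 1 per cell (the grids'
#' inner selection would be prohibitively slow and single-channel fits are
#' insensitive to it); folds are shared across cells through the seed.
#'
#' @param e a balanced two-class `epoch_set`.
#' @param cfg a [decoding_config()].
#' @param windows list of `(start, end)` second pairs; default
#'   [searchlight_windows()]. Windows are half-open `[start, end)` and must
#'   be non-overlapping, ordered and inside the epoch support.
#' @return a `searchlight_map`: `channels`, `windows`, and an AUC matrix
#'   (channels x windows).
#' @export
searchlight_channels <- function(e, cfg = decoding_config(),
                                 windows = searchlight_windows()) {
  validate_epoch_set(e)
  starts <- vapply(windows, `[`, numeric(1), 1L)
  ends <- vapply(windows, `[`, numeric(1), 2L)
  if (is.unsorted(starts) || any(starts[-1L] < ends[-length(ends)]))
    stop("windows must be ordered and non-overlapping")
  if (min(starts) < min(e$times) - 1e-9 ||
      max(ends) > max(e$times) + 1 / e$sfreq + 1e-9)
    stop("searchlight windows exceed the epoch support")
  y <- droplevels(e$labels)
  n_ch <- length(e$channels)
  res <- matrix(NA_real_, n_ch, length(windows),
                dimnames = list(e$channels, NULL))
  for (wi in seq_along(windows)) {
    sel <- which(e$times >= starts[wi] & e$times < ends[wi])
    for (ch in seq_len(n_ch)) {
      FX <- matrix(e$data[, ch, sel], nrow = n_trials(e))
      res[ch, wi] <- cv_auc_features(FX, y, cfg)
    }
  }
  structure(list(channels = e$channels, windows = windows, auc = res,
                 config = cfg),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  best <- arrayInd(which.max(x$auc), dim(x$auc))
  w <- x$windows[[best[2L]]]
  cat("<searchlight_map> ", nrow(x$auc), " channels x ", ncol(x$auc),
      " windows; max AUC ", format(max(x$auc), digits = 3), " at ",
      x$channels[best[1L]], " in [", w[1L] * 1000, ", ", w[2L] * 1000,
      ") ms\n", sep = "")
  invisible(x)
}

#' Pool subject-level averaged ERPs for group analyses
#'
#' Reduces each subject's epochs to at most `n_erps` averaged responses per
#' class (random within-class partitions, remainder spread as evenly as the
#' trial count allows) and stacks them across subjects, so that group-level
#' searchlight or decoding runs on subject-level ERPs as observations
#' rather than single trials.
#'
#' @param subjects list of `epoch_set` objects sharing montage and time axis.
#' @param n_erps maximum averaged responses per class per subject (default 5).
#' @param seed integer seed for the within-subject partitions.
#' @return a single `epoch_set` of pooled averaged ERPs; `block_id` holds
#'   the subject index.
#' @export
pool_subject_erps <- function(subjects, n_erps = 5L, seed = 1L) {
  if (inherits(subjects, "epoch_set")) subjects <- list(subjects)
  pooled <- lapply(seq_along(subjects), function(si) {
    e <- subjects[[si]]
    counts <- table(droplevels(e$labels))
    k <- max(1L, floor(min(counts) / n_erps))
    avg <- average_samples(e, k = k, seed = seed + si)
    # cap at n_erps per class
    keep <- unlist(lapply(levels(avg$labels), function(cl)
      utils::head(which(avg$labels == cl), n_erps)))
    out <- avg[sort(keep)]
    out$block_id <- rep(si, n_trials(out))
    out
  })
  concatenate_superblock(pooled)
}

#' Keep a subset of channels
#'
#' @param e an `epoch_set`.
#' @param channels channel names to retain (order as given).
#' @return `epoch_set` restricted to those channels.
#' @export
select_channels <- function(e, channels) {
  idx <- match(channels, e$channels)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  e$data <- e$data[, idx, , drop = FALSE]
  e$channels <- e$channels[idx]
  validate_epoch_set(e)
  e
}

#' Compare peak decoding between a full montage and a channel subset
#'
#' For each subject, runs the time-resolved decoding once with the full
#' montage and once restricted to the subset, takes the maximum AUC over
#' time in each, and compares the paired maxima with a paired-samples
#' t-test. Used to check that a reduced bedside montage preserves the
#' discriminative information of a dense one.
#'
#' @param subjects list of `epoch_set` objects, one per subject, all
#'   containing the subset channels.
#' @param channels character vector, the reduced montage (non-empty, subset
#'   of every subject's montage).
#' @param cfg a [decoding_config()].
#' @return list with `t`, `df`, `p_value`, and a data frame `per_subject`
#'   of the paired maxima (`max_auc_full`, `max_auc_subset`).
#' @export
compare_montages <- function(subjects, channels, cfg = decoding_config()) {
  if (inherits(subjects, "epoch_set")) subjects <- list(subjects)
  if (length(channels) == 0L) stop("channel subset must be non-empty")
  maxima <- t(vapply(subjects, function(e) {
    full <- max(decode_time_resolved(e, cfg)$auc)
    sub <- max(decode_time_resolved(select_channels(e, channels), cfg)$auc)
    c(full = full, subset = sub)
  }, numeric(2)))
  per_subject <- data.frame(max_auc_full = maxima[, "full"],
                            max_auc_subset = maxima[, "subset"])
  diffs <- per_subject$max_auc_full - per_subject$max_auc_subset
  if (length(subjects) >= 2L && stats::sd(diffs) > 0) {
    tt <- stats::t.test(per_subject$max_auc_full, per_subject$max_auc_subset,
                        paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, per_subject = per_subject)
  } else {
    list(t = 0, df = length(subjects) - 1L,
         p_value = 1, per_subject = per_subject)
  }
}
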