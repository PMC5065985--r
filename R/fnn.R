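# ISI labeling of sliding windows and the three-layer tanh feed-forward
# classifier that probes stimulus-related network-topology dynamics.

#' Feed-forward network configuration
#'
#' The classifier is a fully connected three-layer network (inputs -> 8
#' hidden tanh units -> one tanh output unit per class) trained by
#' back-propagation on squared error with one-hot targets at +/- 1;
#' prediction is the arg-max output unit.
#'
#' @param n_hidden Hidden units.
#' @param train_fraction Fraction of windows in the training split.
#' @param n_repetitions Random split/train/test repetitions to average over.
#' @param learning_rate,momentum,epochs Back-propagation hyperparameters
#'   (full-batch gradient descent with momentum).
#' @param patience Epochs without loss improvement before early stop.
#' @param seed Integer seed controlling splits and weight initialization.
#' @return An `fnn_config` list.
#' @export
fnn_config <- function(n_hidden = 8L, train_fraction = 0.75,
                       n_repetitions = 100L, learning_rate = 0.1,
                       momentum = 0.9, epochs = 800L, patience = 100L,
                       seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  stopifnot_scalar_count(n_hidden, "n_hidden")
  stopifnot_scalar_count(n_repetitions, "n_repetitions")
  stopifnot_scalar_count(epochs, "epochs")
  structure(list(n_hidden = as.integer(n_hidden),
                 train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "fnn_config")
}

#' Label sliding windows by inter-stimulus interval
#'
#' ISI k spans `[onset_k, onset_(k+1))`; the last ISI extends to the segment
#' end. Each window receives the class of the ISI containing its *onset*
#' time. Windows starting before the first stimulus are assigned class 1 with
#' a warning.
#'
#' @param schedule A [gen_stimulus_schedule()] result.
#' @param n_windows Number of sliding windows.
#' @param window_step_ms Window step in milliseconds (default 100).
#' @param window_onsets Optional explicit window onset times in seconds
#'   (overrides the regular grid).
#' @return Integer vector of class labels `1..n_events`.
#' @export
label_windows <- function(schedule, n_windows, window_step_ms = 100,
                          window_onsets = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  onsets <- window_onsets %||% ((seq_len(n_windows) - 1L) * window_step_ms / 1000)
  # small epsilon so a window starting at a stimulus time joins the new ISI
  # even under floating-point jitter of the onset grids
  lab <- findInterval(onsets + 1e-9, schedule$onsets)
  if (any(lab == 0L)) {
    warning("window onset(s) before the first stimulus; assigned to ISI 1")
    lab[lab == 0L] <- 1L
  }
  pmin(lab, schedule$n_events)
}

#' Bundle features and labels for classification
#'
#' @param features Windows x nodes numeric matrix (rows = sliding windows;
#'   with the default geometry, 81 x 58 for the nodes of one frequency).
#' @param labels Integer class per window (see [label_windows()]).
#' @param foi Frequency of interest the features belong to (metadata).
#' @param metric Metric name the features were taken from (metadata).
#' @return A `labeled_window_set`.
#' @export
labeled_window_set <- function(features, labels, foi = NA_real_,
                               metric = NA_character_) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("one label per feature row required", call. = FALSE)
  }
  if (any(labels < 1L)) stop("labels must be positive integers", call. = FALSE)
  structure(list(features = features, labels = labels,
                 n_classes = max(labels), foi = foi, metric = metric),
            class = "labeled_window_set")
}

# one backprop fit; X standardized, y in 1..K; returns weights
fit_fnn <- function(X, y, K, cfg) {
  n <- nrow(X); d <- ncol(X); h <- cfg$n_hidden
  Tm <- matrix(-1, n, K)
  Tm[cbind(seq_len(n), y)] <- 1
  W1 <- matrix(runif(d * h, -1, 1) / sqrt(d), d, h)
  b1 <- numeric(h)
  W2 <- matrix(runif(h * K, -1, 1) / sqrt(h), h, K)
  b2 <- numeric(K)
  vW1 <- 0 * W1; vb1 <- 0 * b1; vW2 <- 0 * W2; vb2 <- 0 * b2
  best_loss <- Inf; stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    H <- tanh(sweep(X %*% W1, 2L, b1, `+`))
    O <- tanh(sweep(H %*% W2, 2L, b2, `+`))
    E <- O - Tm
    loss <- mean(E^2)
    if (loss < best_loss - 1e-6) {
      best_loss <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
    dO <- (2 / (n * K)) * E * (1 - O^2)
    dH <- (dO %*% t(W2)) * (1 - H^2)
    vW2 <- cfg$momentum * vW2 - cfg$learning_rate * crossprod(H, dO)
    vb2 <- cfg$momentum * vb2 - cfg$learning_rate * colSums(dO)
    vW1 <- cfg$momentum * vW1 - cfg$learning_rate * crossprod(X, dH)
    vb1 <- cfg$momentum * vb1 - cfg$learning_rate * colSums(dH)
    W2 <- W2 + vW2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predict_fnn <- function(fit, X) {
  H <- tanh(sweep(X %*% fit$W1, 2L, fit$b1, `+`))
  O <- tanh(sweep(H %*% fit$W2, 2L, fit$b2, `+`))
  max.col(O, ties.method = "first")
}

#' Train and evaluate the FNN classifier over random splits
#'
#' Each repetition draws a random (unstratified) train/test split -- 61/20
#' for the default 81 windows at 75% training fraction -- standardizes each
#' feature per node on the training split, trains the tanh network by
#' back-propagation, and scores the percentage of correctly classified test
#' windows. Splits leaving a class unseen in training are re-drawn (logged).
#'
#' @param data A [labeled_window_set()].
#' @param cfg An [fnn_config()].
#' @return A `classification_result`: `ca_per_repetition` (percent),
#'   `ca_mean`, `ca_sd`, `split_sizes`, `n_redraws`, plus the metadata of
#'   `data`.
#' @export
train_and_evaluate <- function(data, cfg = fnn_config()) {
  stopifnot(inherits(data, "labeled_window_set"))
  X <- data$features
  y <- data$labels
  n <- nrow(X)
  K <- data$n_classes
  n_train <- as.integer(round(cfg$train_fraction * n))
  if (n_train < K || n_train >= n) stop("split leaves no room for train or test",
                                        call. = FALSE)
  n_redraws <- 0L
  ca <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_repetitions), function(rep) {
      for (try in 1:100) {
        tr <- sample.int(n, n_train)
        if (length(unique(y[tr])) == K) break
        n_redraws <<- n_redraws + 1L
      }
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2L, sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
      fit <- fit_fnn(Z[tr, , drop = FALSE], y[tr], K, cfg)
      pred <- predict_fnn(fit, Z[-tr, , drop = FALSE])
      100 * mean(pred == y[-tr])
    }, numeric(1))
  })
  structure(list(ca_per_repetition = ca, ca_mean = mean(ca), ca_sd = sd(ca),
                 split_sizes = c(train = n_train, test = as.integer(n - n_train)),
                 n_redraws = n_redraws, foi = data$foi, metric = data$metric,
                 n_classes = K),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> CA %.1f%% (SD %.1f) over %d repetitions, split %d/%d\n",
              x$ca_mean, x$ca_sd, length(x$ca_per_repetition),
              x$split_sizes["train"], x$split_sizes["test"]))
  invisible(x)
}

#' Stimulus-related NTD classification across metrics and frequencies
#'
#' For every metric dynamics matrix and every frequency of interest, takes
#' the 58-node (one electrode per row) block of that frequency, transposes it
#' to windows x nodes, labels windows by ISI, and runs [train_and_evaluate()].
#'
#' @param dynamics Named list of [metric_dynamics()] matrices (e.g. from
#'   [metric_dynamics_set()]).
#' @param schedule A [gen_stimulus_schedule()] result.
#' @param nodes The [hfn_nodes()] table (defines the per-frequency blocks).
#' @param cfg An [fnn_config()].
#' @param window_step_ms Window step used to label window onsets.
#' @return Data frame with one row per (metric, foi): `ca_mean`, `ca_sd`,
#'   `n_repetitions`; the individual results are in the
#'   `results` attribute.
#' @export
run_stimulus_ntd <- function(dynamics, schedule, nodes, cfg = fnn_config(),
                             window_step_ms = 100) {
  stopifnot(is.list(dynamics))
  fois <- unique(nodes$foi)
  rows <- list()
  results <- list()
  for (mt in names(dynamics)) {
    m <- dynamics[[mt]]
    labels <- label_windows(schedule, ncol(m), window_step_ms)
    for (f in fois) {
      block <- which(nodes$foi == f)
      if (length(block) == 0L) {
        warning("no nodes at FOI ", f, "; skipped")
        next
      }
      feats <- t(m[block, , drop = FALSE])
      feats[!is.finite(feats)] <- 0
      lws <- labeled_window_set(feats, labels, foi = f, metric = mt)
      res <- train_and_evaluate(lws, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mt, foi_hz = f, ca_mean = res$ca_mean, ca_sd = res$ca_sd,
        n_repetitions = length(res$ca_per_repetition))
      results[[paste(mt, f, sep = "@")]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
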