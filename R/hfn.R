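# Hyper-frequency networks: electrode x frequency nodes, ICI adjacency,
# surrogate-based significance, fixed-threshold sparsification.

#' Node table of a hyper-frequency network
#'
#' Nodes are (electrode, frequency) combinations in frequency-major order:
#' index `(foi_block - 1) * n_channels + electrode_rank`, so within-frequency
#' blocks lie along the block diagonal of the adjacency. The default geometry
#' (58 channels, frequencies of interest 2--20 Hz in 2-Hz steps) gives 580
#' nodes.
#'
#' @param labels Channel labels.
#' @param fois Frequencies of interest in Hz.
#' @return Data frame with columns `index`, `electrode`, `foi`.
#' @export
hfn_nodes <- function(labels, fois = seq(2, 20, by = 2)) {
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  data.frame(index = seq_len(length(labels) * length(fois)),
             electrode = rep(labels, times = length(fois)),
             foi = rep(fois, each = length(labels)))
}

#' All unordered node pairs of an HFN as a coupling pair table
#'
#' Self-pairs (same electrode, same frequency) are excluded; same-electrode
#' cross-frequency pairs are included, which is what lets an HFN capture
#' coupling within as well as between recording sites.
#'
#' @param nodes A [hfn_nodes()] table.
#' @return Data frame with `channel_i`, `freq_i`, `channel_j`, `freq_j` and
#'   node indices `node_i` < `node_j`, suitable for
#'   [sliding_window_coupling()].
#' @export
hfn_pairs <- function(nodes) {
  idx <- utils::combn(nodes$index, 2L)
  data.frame(channel_i = nodes$electrode[idx[1L, ]],
             freq_i = nodes$foi[idx[1L, ]],
             channel_j = nodes$electrode[idx[2L, ]],
             freq_j = nodes$foi[idx[2L, ]],
             node_i = idx[1L, ], node_j = idx[2L, ])
}

new_hfn_graph <- function(adjacency, nodes, threshold = NA_real_,
                          window_index = NA_integer_) {
  diag(adjacency) <- 0
  n <- nrow(adjacency)
  structure(list(adjacency = adjacency, nodes = nodes, threshold = threshold,
                 window_index = window_index,
                 cost = sum(adjacency != 0) / (n * (n - 1))),
            class = "hfn_graph")
}

#' @export
print.hfn_graph <- function(x, ...) {
  cat(sprintf("<hfn_graph> %d nodes, cost %.3f%s%s\n",
              nrow(x$adjacency), x$cost,
              if (!is.na(x$threshold)) sprintf(", threshold %g", x$threshold) else "",
              if (!is.na(x$window_index)) sprintf(", window %d", x$window_index) else ""))
  invisible(x)
}

#' Assemble one windowed HFN from coupling results
#'
#' Entry (i, j) of the adjacency is the ICI from node i to node j in the
#' requested window. The coupling object must cover every unordered node pair
#' (use [hfn_pairs()]); the reverse direction comes from the mirrored index.
#'
#' @param coupling A [sliding_window_coupling()] result over [hfn_pairs()].
#' @param window_index Window number (1-based).
#' @param nodes The [hfn_nodes()] table the pairs were generated from.
#' @return An `hfn_graph` with fields `adjacency`, `nodes`, `threshold`
#'   (NA until [apply_threshold()]), `window_index`, `cost`.
#' @export
build_hfn <- function(coupling, window_index, nodes) {
  stopifnot(inherits(coupling, "coupling_windows"))
  w <- stopifnot_scalar_count(window_index, "window_index")
  if (w > coupling$n_windows) stop("window_index out of range", call. = FALSE)
  p <- coupling$pairs
  if (is.null(p$node_i) || is.null(p$node_j)) {
    stop("coupling pairs lack node indices; build them with hfn_pairs()",
         call. = FALSE)
  }
  N <- nrow(nodes)
  expected <- N * (N - 1) / 2
  if (nrow(p) != expected) {
    stop("coupling must cover all ", expected, " unordered node pairs",
         call. = FALSE)
  }
  A <- matrix(0, N, N)
  A[cbind(p$node_i, p$node_j)] <- coupling$ici[, w]
  A[cbind(p$node_j, p$node_i)] <- coupling$ici_rev[, w]
  new_hfn_graph(A, nodes, window_index = w)
}

#' Sparsify an HFN at a fixed connectivity threshold
#'
#' Entries less than or equal to the threshold are zeroed; surviving entries
#' keep their weights (the graph stays weighted, not binarized). The default
#' 0.26 sits above surrogate-derived significance levels and yields sparse
#' (~20% cost) networks in the intended operating range.
#'
#' @param g An `hfn_graph`.
#' @param threshold Connectivity threshold (weights must exceed it to survive).
#' @return The thresholded `hfn_graph` with `cost` recomputed.
#' @export
apply_threshold <- function(g, threshold = 0.26) {
  stopifnot(inherits(g, "hfn_graph"))
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  A <- g$adjacency
  A[A <= threshold] <- 0
  out <- new_hfn_graph(A, g$nodes, threshold = threshold,
                       window_index = g$window_index)
  out
}

#' Build the full windowed HFN sequence
#'
#' Convenience wrapper: one (optionally thresholded) graph per sliding window.
#'
#' @inheritParams build_hfn
#' @param threshold Threshold passed to [apply_threshold()]; `NULL` skips
#'   thresholding.
#' @return List of `hfn_graph` objects, one per window.
#' @export
hfn_series <- function(coupling, nodes, threshold = 0.26) {
  lapply(seq_len(coupling$n_windows), function(w) {
    g <- build_hfn(coupling, w, nodes)
    if (!is.null(threshold)) g <- apply_threshold(g, threshold)
    g
  })
}

#' Surrogate recordings destroying phase coupling
#'
#' `time-shuffle` randomly permutes the samples of each channel (preserving
#' the value multiset); `phase-shuffle` Fourier-transforms each channel, uses
#' the original phase values in random order, and inverse-transforms, so the
#' amplitude spectrum (hence the power spectrum) is preserved exactly while
#' the time course is destroyed.
#'
#' @param rec A [segmented_recording()].
#' @param method `"time-shuffle"` or `"phase-shuffle"`.
#' @param seed Optional integer seed.
#' @return A [segmented_recording()] of identical geometry.
#' @export
make_surrogates <- function(rec, method = c("phase-shuffle", "time-shuffle"),
                            seed = NULL) {
  stopifnot(inherits(rec, "segmented_recording"))
  method <- match.arg(method)
  n <- ncol(rec$data)
  data <- with_seed(seed, {
    t(apply(rec$data, 1L, function(x) {
      if (method == "time-shuffle") return(x[sample.int(n)])
      z <- fft(x)
      amp <- Mod(z)
      ph <- Arg(z)
      # permute phases over the positive-frequency bins, then enforce the
      # conjugate symmetry a real signal requires (DC/Nyquist phases kept)
      half <- if (n %% 2L == 0L) n %/% 2L - 1L else (n - 1L) %/% 2L
      pos <- 2L:(half + 1L)
      new_ph <- ph
      new_ph[pos] <- ph[pos][sample.int(half)]
      new_ph[n + 2L - pos] <- -new_ph[pos]
      Re(fft(amp * exp(1i * new_ph), inverse = TRUE)) / n
    }))
  })
  dimnames(data) <- dimnames(rec$data)
  segmented_recording(data, rec$fs, rec$labels, schedule = rec$schedule)
}

#' Surrogate-based critical coupling value
#'
#' Pools windowed ICI values from coupling analyses of surrogate recordings,
#' bootstraps their mean (`n_boot` resamples), and reports the critical value
#' as the bootstrap mean plus the one-sided percentile confidence margin at
#' `alpha` -- i.e. the `1 - alpha` percentile of the bootstrap-mean
#' distribution. Couplings above this value are unlikely to arise from
#' phase-scrambled data.
#'
#' @param rec A [segmented_recording()].
#' @param method Surrogate scheme, see [make_surrogates()].
#' @param n_boot Bootstrap resamples (>= 100).
#' @param alpha One-sided significance level.
#' @param seed Optional integer seed.
#' @param n_surrogates Number of surrogate recordings to pool.
#' @param fois Frequencies of interest for the coupling analysis.
#' @param pairs Optional pair table (default: all HFN pairs over `fois`).
#' @param window_ms,step_ms Sliding-window parameters.
#' @param params Optional [morlet_params()] (default: FOI grid).
#' @return A `surrogate_null`: list with `method`, `n_boot`, `alpha`,
#'   `critical_value`, `boot_means`, `values`, `degenerate` flag.
#' @export
surrogate_critical_value <- function(rec, method = c("phase-shuffle", "time-shuffle"),
                                     n_boot = 1000, alpha = 1e-4, seed = NULL,
                                     n_surrogates = 10,
                                     fois = seq(2, 20, by = 2), pairs = NULL,
                                     window_ms = 2000, step_ms = 100,
                                     params = NULL) {
  method <- match.arg(method)
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  params <- params %||% morlet_params(freqs = fois)
  if (is.null(pairs)) pairs <- hfn_pairs(hfn_nodes(rec$labels, fois))
  with_seed(seed, {
    vals <- unlist(lapply(seq_len(n_surrogates), function(s) {
      sur <- make_surrogates(rec, method, seed = NULL)
      cw <- sliding_window_coupling(extract_phases(sur, params), pairs,
                                    window_ms = window_ms, step_ms = step_ms)
      c(cw$ici, cw$ici_rev)
    }))
    boot_means <- vapply(seq_len(n_boot), function(b) {
      mean(vals[sample.int(length(vals), replace = TRUE)])
    }, numeric(1))
  })
  degenerate <- stats::var(vals) == 0
  if (degenerate) warning("surrogate coupling values are constant")
  structure(list(method = method, n_boot = as.integer(n_boot), alpha = alpha,
                 critical_value = unname(quantile(boot_means, 1 - alpha)),
                 boot_means = boot_means, values = vals,
                 degenerate = degenerate),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %s, %d bootstrap resamples, alpha %g: critical %.4f\n",
              x$method, x$n_boot, x$alpha, x$critical_value))
  invisible(x)
}

#' Export an HFN adjacency
#'
#' Writes the dense adjacency as TSV, an edge list (src, dst, weight), the
#' node table, and optionally GraphML via igraph.
#'
#' @param g An `hfn_graph`.
#' @param prefix Path prefix; files `<prefix>.adj.tsv`, `<prefix>.edges.tsv`,
#'   `<prefix>.nodes.tsv`, and `<prefix>.graphml` are produced.
#' @param graphml Also write GraphML?
#' @return Invisibly, the vector of files written.
#' @export
write_hfn <- function(g, prefix, graphml = FALSE) {
  stopifnot(inherits(g, "hfn_graph"))
  files <- paste0(prefix, c(".adj.tsv", ".edges.tsv", ".nodes.tsv"))
  write.table(g$adjacency, files[1L], sep = "\t", row.names = FALSE,
              col.names = FALSE)
  nz <- which(g$adjacency != 0, arr.ind = TRUE)
  write.table(data.frame(src = nz[, 1L], dst = nz[, 2L],
                         weight = g$adjacency[nz]),
              files[2L], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(g$nodes, files[3L], sep = "\t", row.names = FALSE, quote = FALSE)
  if (graphml) {
    gml <- paste0(prefix, ".graphml")
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "directed",
                                              weighted = TRUE)
    igraph::write_graph(ig, gml, format = "graphml")
    files <- c(files, gml)
  }
  invisible(files)
}
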