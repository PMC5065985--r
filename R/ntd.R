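# Network topology dynamics: metric matrices over sliding windows, temporal
# and nodal similarity, modularity-based dynamic states and nodal communities.

node_metric <- function(g, metric) {
  A <- as_adjacency(g)
  switch(metric,
         s_in = colSums(A),
         s_out = rowSums(A),
         cc = clustering_wd(A),
         cpl = shortest_path_metrics(A)$cpl_i,
         eloc = local_efficiency(A),
         eglob = shortest_path_metrics(A)$eglob_i,
         stop("unknown metric `", metric, "`", call. = FALSE))
}

#' Nodes x windows matrix of one nodal graph metric
#'
#' Column w holds the chosen metric for every node of the window-w HFN; with
#' the default geometry (580 nodes, 81 windows) this is the 580 x 81 substrate
#' of all dynamics analyses.
#'
#' @param graphs List of `hfn_graph` objects sharing one node set (see
#'   [hfn_series()]).
#' @param metric One of `"s_in"`, `"s_out"`, `"cc"`, `"cpl"`, `"eloc"`,
#'   `"eglob"`.
#' @return A `metric_dynamics` matrix (nodes x windows) with attribute
#'   `metric`.
#' @export
metric_dynamics <- function(graphs, metric = c("s_in", "s_out", "cc", "cpl",
                                               "eloc", "eglob")) {
  metric <- match.arg(metric)
  ns <- vapply(graphs, function(g) nrow(as_adjacency(g)), integer(1))
  if (length(unique(ns)) != 1L) stop("all graphs must share one node set",
                                     call. = FALSE)
  m <- vapply(graphs, node_metric, numeric(ns[1L]), metric = metric)
  structure(m, metric = metric, class = c("metric_dynamics", "matrix", "array"))
}

#' All six metric dynamics matrices in one pass
#'
#' Computes the per-window nodal metrics once and splits them into one
#' [metric_dynamics()] matrix per metric.
#'
#' @param graphs List of `hfn_graph` objects sharing one node set.
#' @return Named list of six `metric_dynamics` matrices.
#' @export
metric_dynamics_set <- function(graphs) {
  per_window <- lapply(graphs, nodal_metrics)
  metrics <- c("s_in", "s_out", "cc", "cpl", "eloc", "eglob")
  out <- lapply(metrics, function(mt) {
    m <- vapply(per_window, `[[`, numeric(nrow(per_window[[1L]])), mt)
    structure(m, metric = mt, class = c("metric_dynamics", "matrix", "array"))
  })
  names(out) <- metrics
  out
}

pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Means and variability of a metric dynamics matrix
#'
#' Reports the grand mean (identical whichever axis is averaged first), the
#' mean across windows of the per-window SD across nodes, and the mean across
#' nodes of the per-node SD across time. Population SDs are used.
#'
#' @param m A [metric_dynamics()] matrix.
#' @return List with `grand_mean`, `sd_across_nodes`, `sd_across_time`.
#' @export
summarize_dynamics <- function(m) {
  list(grand_mean = mean(m[is.finite(m)]),
       sd_across_nodes = mean(apply(m, 2L, pop_sd)),
       sd_across_time = mean(apply(m, 1L, pop_sd)))
}

#' Temporal or nodal similarity matrix
#'
#' Pearson correlations between columns (temporal axis: windows x windows,
#' each window represented by its node vector) or rows (nodal axis: nodes x
#' nodes, each node by its time course). Zero-variance elements yield
#' undefined correlations; they are flagged in the `excluded` attribute,
#' warned about, and skipped by the modularity step.
#'
#' @param m A [metric_dynamics()] matrix.
#' @param axis `"temporal"` or `"nodal"`.
#' @return A `similarity_matrix`: square symmetric matrix with unit diagonal
#'   and attributes `axis` and `excluded`.
#' @export
similarity <- function(m, axis = c("temporal", "nodal")) {
  axis <- match.arg(axis)
  x <- if (axis == "temporal") unclass(m) else t(unclass(m))
  if (ncol(x) < 2L) stop("need >= 2 elements on the chosen axis", call. = FALSE)
  degen <- apply(x, 2L, function(col) pop_sd(col) == 0 || !all(is.finite(col)))
  if (any(degen)) {
    warning(sum(degen), " zero-variance element(s); correlations flagged undefined")
  }
  s <- suppressWarnings(cor(x))
  diag(s) <- 1
  structure(s, axis = axis, excluded = degen,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Weighted modularity of a partition
#'
#' `Q = (1/l) * sum_ij (w_ij - k_i k_j / l) * delta(m_i, m_j)` with `l` the
#' total edge weight, `k` the node strengths, and the diagonal zeroed first.
#' Q is 0 when all elements share one module and approaches 1 for strongly
#' separated modules.
#'
#' @param w Square symmetric nonnegative weight matrix.
#' @param membership Integer module id per element.
#' @return The modularity value.
#' @export
modularity_q <- function(w, membership) {
  w <- as.matrix(unclass(w))
  diag(w) <- 0
  if (any(w < 0)) stop("`w` must be nonnegative for Q; clip first", call. = FALSE)
  l <- sum(w)
  if (l == 0) return(0)
  q <- 0
  for (mod in unique(membership[!is.na(membership)])) {
    idx <- which(membership == mod)
    # strength sum taken directly over the rows so that the single-module
    # partition yields exactly sum(w)/l - 1 == 0
    q <- q + sum(w[idx, idx]) / l - (sum(w[idx, , drop = FALSE]) / l)^2
  }
  q
}

# Generic Louvain on a symmetric modularity matrix B: maximizes
# sum_ij B_ij delta(m_i, m_j) by greedy local moves + aggregation.
louvain_on_b <- function(B, seed = NULL, n_restarts = 10) {
  n <- nrow(B)
  run_once <- function() {
    membership <- seq_len(n)
    Bcur <- B
    repeat {
      m <- local_moves(Bcur)
      if (length(unique(m)) == nrow(Bcur)) break
      m <- match(m, unique(m))
      membership <- m[membership]
      Bcur <- rowsum(t(rowsum(Bcur, m)), m)
      if (nrow(Bcur) == 1L) break
    }
    membership
  }
  local_moves <- function(Bc) {
    nn <- nrow(Bc)
    m <- seq_len(nn)
    repeat {
      improved <- FALSE
      for (i in sample.int(nn)) {
        conn <- tapply(Bc[i, ], m, sum)
        conn[as.character(m[i])] <- conn[as.character(m[i])] - Bc[i, i]
        gain <- 2 * conn - 2 * conn[as.character(m[i])]
        best <- names(gain)[which.max(gain)]
        if (gain[best] > 1e-12 && best != as.character(m[i])) {
          m[i] <- as.integer(best)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    m
  }
  score <- function(m) sum(B[outer(m, m, `==`)])
  with_seed(seed, {
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(max(1L, n_restarts))) {
      m <- run_once()
      qq <- score(m)
      if (qq > best_q) {
        best_q <- qq
        best <- m
      }
    }
    list(membership = match(best, unique(best)), score = best_q)
  })
}

new_partition <- function(assignment, q, axis) {
  counts <- table(assignment, useNA = "no")
  structure(list(assignment = assignment, q = q,
                 n_modules = length(counts),
                 element_counts = as.integer(counts),
                 axis = axis),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %s axis: %d modules (Q = %.4f), sizes %s\n",
              x$axis, x$n_modules, x$q,
              paste(x$element_counts, collapse = "/")))
  invisible(x)
}

#' Modularity partition of a (nonnegative) similarity matrix
#'
#' Dynamic-state detection on the temporal similarity matrix: negative
#' correlations are clipped to zero (with a message), the diagonal is zeroed,
#' and a Louvain optimization of the Newman weighted modularity assigns each
#' element to a module. `q` is evaluated exactly on the returned assignment.
#'
#' @param s A [similarity()] matrix (temporal axis) or any symmetric matrix.
#' @param seed Seed for the Louvain restarts (fixed default for determinism).
#' @param n_restarts Independent Louvain restarts; the best-Q run is kept.
#' @return A `partition_result`: `assignment`, `q`, `n_modules`,
#'   `element_counts`, `axis`.
#' @export
modularity_partition <- function(s, seed = 1L, n_restarts = 10) {
  w <- as.matrix(unclass(s))
  axis <- attr(s, "axis") %||% "temporal"
  excluded <- attr(s, "excluded") %||% rep(FALSE, nrow(w))
  keep <- which(!excluded)
  wk <- w[keep, keep, drop = FALSE]
  n_neg <- sum(wk < 0)
  if (n_neg > 0) message(n_neg, " negative entries clipped to 0 for modularity")
  wk[wk < 0] <- 0
  diag(wk) <- 0
  l <- sum(wk)
  if (l == 0) {
    assignment <- rep(NA_integer_, nrow(w))
    assignment[keep] <- 1L
    return(new_partition(assignment, 0, axis))
  }
  k <- rowSums(wk)
  B <- wk / l - tcrossprod(k) / l^2
  if (max(abs(B)) < 1e-14) {         # e.g. all-equal similarity: Q == 0 for
    assignment <- rep(NA_integer_, nrow(w))  # every partition; one module
    assignment[keep] <- 1L
    warning("degenerate similarity structure; single module with Q = 0")
    return(new_partition(assignment, 0, axis))
  }
  fit <- louvain_on_b(B, seed = seed, n_restarts = n_restarts)
  assignment <- rep(NA_integer_, nrow(w))
  assignment[keep] <- fit$membership
  new_partition(assignment, modularity_q(wk, fit$membership), axis)
}

#' Signed Louvain partition of a similarity matrix
#'
#' Community detection for matrices with positive *and* negative entries
#' (nodal similarity): positive weights reward co-assignment and negative
#' weights penalize it, using the asymmetric signed modularity
#' `Q* = Q+ - (v- / (v+ + v-)) Q-`. The reported `q` is this signed value;
#' `q_positive` additionally gives the plain weighted modularity of the
#' positive part.
#'
#' @inheritParams modularity_partition
#' @param s A [similarity()] matrix with entries in `[-1, 1]`.
#' @return A `partition_result` with extra field `q_positive`.
#' @export
louvain_signed_partition <- function(s, seed = 1L, n_restarts = 10) {
  w <- as.matrix(unclass(s))
  axis <- attr(s, "axis") %||% "nodal"
  excluded <- attr(s, "excluded") %||% rep(FALSE, nrow(w))
  keep <- which(!excluded)
  wk <- w[keep, keep, drop = FALSE]
  diag(wk) <- 0
  wp <- pmax(wk, 0)
  wn <- pmax(-wk, 0)
  vp <- sum(wp)
  vn <- sum(wn)
  if (vp == 0 && vn == 0) {
    assignment <- rep(NA_integer_, nrow(w))
    assignment[keep] <- 1L
    p <- new_partition(assignment, 0, axis)
    p$q_positive <- 0
    return(p)
  }
  Bp <- if (vp > 0) wp / vp - tcrossprod(rowSums(wp)) / vp^2 else 0 * wk
  Bn <- if (vn > 0) wn / vn - tcrossprod(rowSums(wn)) / vn^2 else 0 * wk
  B <- Bp - (vn / (vp + vn)) * Bn
  fit <- louvain_on_b(B, seed = seed, n_restarts = n_restarts)
  assignment <- rep(NA_integer_, nrow(w))
  assignment[keep] <- fit$membership
  qp <- modularity_q(wp, fit$membership)
  qn <- modularity_q(wn, fit$membership)
  p <- new_partition(assignment, qp - (vn / (vp + vn)) * qn, axis)
  p$q_positive <- qp
  p
}

#' Counts and extremes of dynamic states or nodal communities
#'
#' Temporal axis: number of dynamic states and the minimal/maximal state
#' duration, both as total windows per state and as contiguous runs (the two
#' coincide when states form contiguous diagonal blocks). Nodal axis: number
#' of communities and the minimal/maximal community size.
#'
#' @param p A `partition_result`.
#' @param axis Override of `p$axis`.
#' @param step_s Window step in seconds used to convert durations (default
#'   0.1 s); reported alongside the window counts.
#' @return List of summary statistics.
#' @export
state_statistics <- function(p, axis = NULL, step_s = 0.1) {
  stopifnot(inherits(p, "partition_result"))
  axis <- axis %||% p$axis
  counts <- p$element_counts
  out <- list(axis = axis, n_modules = p$n_modules,
              min_size = min(counts), max_size = max(counts), q = p$q)
  if (axis == "temporal") {
    runs <- rle(p$assignment[!is.na(p$assignment)])$lengths
    out$min_run <- min(runs)
    out$max_run <- max(runs)
    out$min_duration_s <- out$min_size * step_s
    out$max_duration_s <- out$max_size * step_s
  }
  out
}

#' Null modularity distribution for a similarity matrix
#'
#' Shuffles the off-diagonal values (preserving symmetry, diagonal, and the
#' value multiset) `n` times, re-runs the same partitioning (unsigned for the
#' temporal axis, signed Louvain for the nodal axis), and reports the null Q
#' distribution and an empirical p value for the observed Q.
#'
#' @param s A [similarity()] matrix.
#' @param n Number of null matrices.
#' @param seed Optional integer seed.
#' @param n_restarts Louvain restarts per partition (smaller than the default
#'   to keep the null affordable).
#' @return List with `q_observed`, `q_null` (length `n`), `p_value`,
#'   `observed` partition.
#' @export
modularity_null <- function(s, n = 100, seed = NULL, n_restarts = 3) {
  stopifnot_scalar_count(n, "n")
  axis <- attr(s, "axis") %||% "temporal"
  part_fun <- if (axis == "nodal") louvain_signed_partition else modularity_partition
  observed <- part_fun(s, n_restarts = n_restarts)
  w <- as.matrix(unclass(s))
  nn <- nrow(w)
  ut <- which(upper.tri(w))
  q_null <- with_seed(seed, {
    vapply(seq_len(n), function(b) {
      v <- w[ut][sample.int(length(ut))]
      r <- matrix(0, nn, nn)
      r[ut] <- v
      r <- r + t(r)
      diag(r) <- diag(w)
      rs <- structure(r, axis = axis, excluded = rep(FALSE, nn),
                      class = c("similarity_matrix", "matrix", "array"))
      suppressMessages(part_fun(rs, n_restarts = n_restarts)$q)
    }, numeric(1))
  })
  list(q_observed = observed$q, q_null = q_null,
       p_value = (1 + sum(q_null >= observed$q)) / (n + 1),
       observed = observed)
}
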