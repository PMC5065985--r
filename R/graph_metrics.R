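# Weighted directed nodal graph metrics, lattice/random reference graphs,
# and small-world coefficients.

as_adjacency <- function(g) {
  if (inherits(g, "hfn_graph")) g$adjacency
  else if (is.matrix(g)) {
    if (nrow(g) != ncol(g)) stop("adjacency must be square", call. = FALSE)
    g
  } else stop("expected an `hfn_graph` or a square matrix", call. = FALSE)
}

check_weights <- function(A) {
  if (any(A < 0)) stop("weights must be nonnegative", call. = FALSE)
  A
}

#' Node strengths (weighted degrees)
#'
#' @param g An `hfn_graph` or adjacency matrix (nonnegative weights).
#' @return Data frame with per-node `s_in` (column sums) and `s_out`
#'   (row sums).
#' @export
strengths <- function(g) {
  A <- check_weights(as_adjacency(g))
  data.frame(s_in = colSums(A), s_out = rowSums(A))
}

#' Weighted directed clustering coefficient (Fagiolo)
#'
#' The number of weighted directed triangles around node i is
#' `t_i = diag((W^(1/3) + t(W^(1/3)))^3) / 2`, normalized by the number of
#' possible triangles `(k_in + k_out)(k_in + k_out - 1) - 2 * sum_j a_ij a_ji`.
#' Nodes with an undefined denominator (isolated or degree-1) get 0.
#'
#' @param g An `hfn_graph` or adjacency matrix; weights should lie in `[0, 1]`
#'   (set `rescale = TRUE` to divide by the maximum first).
#' @param rescale Rescale weights to `[0, 1]` by the maximum weight?
#' @return Numeric vector of per-node clustering coefficients in `[0, 1]`.
#' @export
clustering_wd <- function(g, rescale = FALSE) {
  A <- check_weights(as_adjacency(g))
  diag(A) <- 0
  if (rescale && max(A) > 0) A <- A / max(A)
  if (max(A) > 1 + 1e-12) {
    stop("weights must be in [0, 1]; use `rescale = TRUE`", call. = FALSE)
  }
  W3 <- A^(1 / 3)
  S <- W3 + t(W3)
  t_i <- diag(S %*% S %*% S) / 2
  a <- (A > 0) + 0
  ktot <- rowSums(a) + colSums(a)
  recip <- diag(a %*% a)
  denom <- ktot * (ktot - 1) - 2 * recip
  cc <- ifelse(denom > 0, t_i / denom, 0)
  unname(cc)
}

# directed shortest-path distance matrix on lengths 1/weight
distance_matrix <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed",
                                            weighted = TRUE, diag = FALSE)
  w <- igraph::E(ig)$weight
  d <- igraph::distances(ig, mode = "out",
                         weights = if (length(w)) 1 / w else NULL)
  dimnames(d) <- NULL
  d
}

#' Characteristic path length and global efficiency per node
#'
#' Edge lengths are inverse weights; distances are directed shortest paths.
#' `cpl_i` is the mean distance from node i to the *reachable* other nodes
#' (the number of unreachable pairs is reported); `eglob_i` is the mean
#' inverse distance to all other nodes, with unreachable pairs contributing 0
#' (the inverse of infinity).
#'
#' @param g An `hfn_graph` or adjacency matrix (nonnegative weights).
#' @return List with vectors `cpl_i`, `eglob_i`, scalars `cpl`, `eglob`
#'   (node means, `NA` removed for cpl), and `n_unreachable_pairs`.
#' @export
shortest_path_metrics <- function(g) {
  A <- check_weights(as_adjacency(g))
  diag(A) <- 0
  n <- nrow(A)
  d <- distance_matrix(A)
  diag(d) <- Inf                      # exclude self-pairs from both means
  fin <- is.finite(d)
  cpl_i <- vapply(seq_len(n), function(i) {
    di <- d[i, fin[i, ]]
    if (length(di) == 0L) NA_real_ else mean(di)
  }, numeric(1))
  inv <- ifelse(fin, 1 / d, 0)
  eglob_i <- rowSums(inv) / (n - 1)
  list(cpl_i = cpl_i, eglob_i = eglob_i,
       cpl = mean(cpl_i, na.rm = TRUE), eglob = mean(eglob_i),
       n_unreachable_pairs = sum(!fin) - n)   # diagonal excluded
}

# Floyd-Warshall on a small length matrix (Inf = no edge), diag 0
floyd_warshall <- function(len) {
  d <- len
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

#' Weighted local efficiency per node
#'
#' For node i with out-neighborhood `N_i = {j : w_ij > 0}` of size `k_i`,
#' `eloc_i = sum_{j != h in N_i} (w_ij * w_ih / d_jh(N_i))^(1/3) /
#' (k_i (k_i - 1))`, where `d_jh(N_i)` is the directed shortest-path distance
#' inside the neighborhood subgraph (inverse-weight lengths); unreachable
#' neighbor pairs contribute 0, and nodes with fewer than two neighbors get 0.
#'
#' @param g An `hfn_graph` or adjacency matrix with weights in `[0, 1]`.
#' @return Numeric vector of per-node local efficiencies.
#' @export
local_efficiency <- function(g) {
  A <- check_weights(as_adjacency(g))
  diag(A) <- 0
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- A[nb, nb, drop = FALSE]
    len <- ifelse(sub > 0, 1 / sub, Inf)
    d <- floyd_warshall(len)
    inv <- ifelse(is.finite(d), 1 / d, 0)
    diag(inv) <- 0
    wij <- A[i, nb]
    num <- sum((outer(wij, wij) * inv)^(1 / 3) * (inv > 0))
    num / (k * (k - 1))
  }, numeric(1))
}

#' Graph-level metric summary
#'
#' Mean clustering, characteristic path length, and local/global efficiency of
#' one graph, or the across-realization average for a list of graphs (as used
#' for reference networks).
#'
#' @param g An `hfn_graph`, adjacency matrix, or list of either.
#' @return List with scalars `cc`, `cpl`, `eloc`, `eglob`.
#' @export
graph_metric_summary <- function(g) {
  if (is.list(g) && !inherits(g, "hfn_graph")) {
    ms <- lapply(g, graph_metric_summary)
    return(list(cc = mean(vapply(ms, `[[`, numeric(1), "cc")),
                cpl = mean(vapply(ms, `[[`, numeric(1), "cpl")),
                eloc = mean(vapply(ms, `[[`, numeric(1), "eloc")),
                eglob = mean(vapply(ms, `[[`, numeric(1), "eglob"))))
  }
  A <- as_adjacency(g)
  sp <- shortest_path_metrics(A)
  list(cc = mean(clustering_wd(A)), cpl = sp$cpl,
       eloc = mean(local_efficiency(A)), eglob = sp$eglob)
}

off_diagonal_indices <- function(n) which(row(diag(n)) != col(diag(n)))

#' Random reference graphs
#'
#' Reassigns the edges of the input (with their weights) to uniformly random
#' off-diagonal positions without collision, preserving node count, edge
#' count, and the weight multiset exactly. The degree sequence is *not*
#' preserved (plain edge repositioning); Maslov-Sneppen degree-preserving
#' rewiring is available via `preserve_degrees = TRUE`.
#'
#' @param g An `hfn_graph` or adjacency matrix.
#' @param n_realizations Number of independent randomizations.
#' @param seed Optional integer seed.
#' @param preserve_degrees Use degree-preserving double-edge swaps instead.
#' @return List of adjacency matrices (length `n_realizations`).
#' @export
random_reference <- function(g, n_realizations = 10, seed = NULL,
                             preserve_degrees = FALSE) {
  A <- as_adjacency(g)
  diag(A) <- 0
  n <- nrow(A)
  off <- off_diagonal_indices(n)
  nz <- off[A[off] != 0]
  vals <- A[nz]
  with_seed(seed, {
    lapply(seq_len(n_realizations), function(r) {
      B <- matrix(0, n, n)
      if (length(vals)) {
        if (preserve_degrees) {
          B <- A
          ne <- length(nz)
          for (it in seq_len(10L * ne)) {
            e <- which(B != 0, arr.ind = TRUE)
            if (nrow(e) < 2L) break
            picks <- sample.int(nrow(e), 2L)
            a <- e[picks[1L], ]; b <- e[picks[2L], ]
            # swap targets: (a1->b2), (b1->a2)
            if (a[1L] == b[2L] || b[1L] == a[2L]) next
            if (B[a[1L], b[2L]] != 0 || B[b[1L], a[2L]] != 0) next
            w1 <- B[a[1L], a[2L]]; w2 <- B[b[1L], b[2L]]
            B[a[1L], a[2L]] <- 0; B[b[1L], b[2L]] <- 0
            B[a[1L], b[2L]] <- w1; B[b[1L], a[2L]] <- w2
          }
        } else {
          pos <- sample(off, length(vals))
          B[pos] <- vals
        }
      }
      B
    })
  })
}

#' Lattice reference graphs
#'
#' Starts from a random edge permutation, then pushes weight toward the main
#' diagonal: each column is split at the diagonal element and both parts are
#' sorted so the largest weights lie closest to the diagonal, giving a
#' ring/lattice-like topology with nearest-neighbor connectivity. Node count,
#' edge count, and the weight multiset are preserved exactly. Ties are broken
#' by a stable sort for determinism.
#'
#' @inheritParams random_reference
#' @return List of adjacency matrices (length `n_realizations`).
#' @export
lattice_reference <- function(g, n_realizations = 10, seed = NULL) {
  A <- as_adjacency(g)
  diag(A) <- 0
  n <- nrow(A)
  off <- off_diagonal_indices(n)
  with_seed(seed, {
    lapply(seq_len(n_realizations), function(r) {
      B <- matrix(0, n, n)
      B[off] <- A[off][sample.int(length(off))]
      for (j in seq_len(n)) {
        if (j > 1L) {
          up <- B[seq_len(j - 1L), j]
          B[seq_len(j - 1L), j] <- sort(up, method = "radix")  # largest at j-1
        }
        if (j < n) {
          lo <- B[(j + 1L):n, j]
          B[(j + 1L):n, j] <- sort(lo, decreasing = TRUE,
                                   method = "radix")           # largest at j+1
        }
      }
      B
    })
  })
}

#' Small-world coefficients against random and lattice references
#'
#' `gamma = CC / CC_rand`, `lambda = CPL / CPL_rand`, `sigma = gamma /
#' lambda`; `omega = CPL_rand / CPL - CC / CC_latt`. The efficiency variants
#' use `sigmaE = (E_loc / E_loc_rand) / (E_glob_rand / E_glob)` and
#' `omegaE = E_glob / E_glob_rand - E_loc / E_loc_latt`. `sigma > 1` and
#' `omega` near 0 indicate small-world organization; `omega > 0` leans random,
#' `omega < 0` leans lattice-like.
#'
#' @param real Graph (or [graph_metric_summary()] result) of interest.
#' @param rand,latt Reference graphs: a graph, a list of realizations, or a
#'   precomputed [graph_metric_summary()].
#' @return List with `gamma`, `lambda`, `sigma`, `omega`, `gammaE`,
#'   `lambdaE`, `sigmaE`, `omegaE` plus the three metric summaries. Undefined
#'   ratios (zero denominators) are `NA` with a warning.
#' @export
small_world_coefficients <- function(real, rand, latt) {
  summ <- function(x) {
    if (is.list(x) && all(c("cc", "cpl", "eloc", "eglob") %in% names(x))) x
    else graph_metric_summary(x)
  }
  re <- summ(real); ra <- summ(rand); la <- summ(latt)
  safe_div <- function(a, b) {
    if (!is.finite(b) || b == 0) {
      warning("undefined small-world ratio (zero or non-finite denominator)")
      return(NA_real_)
    }
    a / b
  }
  gamma <- safe_div(re$cc, ra$cc)
  lambda <- safe_div(re$cpl, ra$cpl)
  gammaE <- safe_div(re$eloc, ra$eloc)
  lambdaE <- safe_div(ra$eglob, re$eglob)
  list(gamma = gamma, lambda = lambda,
       sigma = safe_div(gamma, lambda),
       omega = safe_div(ra$cpl, re$cpl) - safe_div(re$cc, la$cc),
       gammaE = gammaE, lambdaE = lambdaE,
       sigmaE = safe_div(gammaE, lambdaE),
       omegaE = safe_div(re$eglob, ra$eglob) - safe_div(re$eloc, la$eloc),
       real = re, rand = ra, latt = la)
}

#' All nodal metrics of one graph
#'
#' @param g An `hfn_graph` or adjacency matrix.
#' @return Data frame with per-node `s_in`, `s_out`, `cc`, `cpl`, `eloc`,
#'   `eglob`.
#' @export
nodal_metrics <- function(g) {
  A <- as_adjacency(g)
  st <- strengths(A)
  sp <- shortest_path_metrics(A)
  data.frame(s_in = st$s_in, s_out = st$s_out, cc = clustering_wd(A),
             cpl = sp$cpl_i, eloc = local_efficiency(A), eglob = sp$eglob_i)
}
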