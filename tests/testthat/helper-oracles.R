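# Independent brute-force oracles and fixture builders. Everything here is
# written as plain double loops over definitions, deliberately not sharing
# code with the package implementations it checks.

random_digraph <- function(n, density = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A[A > density] <- 0
  diag(A) <- 0
  A
}

oracle_strengths <- function(A) {
  n <- nrow(A)
  s_in <- numeric(n); s_out <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    s_out[i] <- s_out[i] + A[i, j]
    s_in[i] <- s_in[i] + A[j, i]
  }
  list(s_in = s_in, s_out = s_out)
}

# Fagiolo weighted directed clustering, summed term by term
oracle_clustering <- function(A) {
  n <- nrow(A)
  W <- A^(1 / 3)
  a <- (A > 0) + 0
  cc <- numeric(n)
  for (i in 1:n) {
    t_i <- 0
    for (j in 1:n) for (h in 1:n) {
      t_i <- t_i + (W[i, j] + W[j, i]) * (W[i, h] + W[h, i]) * (W[j, h] + W[h, j])
    }
    t_i <- t_i / 2
    ktot <- sum(a[i, ]) + sum(a[, i])
    recip <- sum(a[i, ] * a[, i])
    denom <- ktot * (ktot - 1) - 2 * recip
    cc[i] <- if (denom > 0) t_i / denom else 0
  }
  cc
}

# all-pairs shortest paths on inverse-weight lengths, plain Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j && A[i, j] > 0) d[i, j] <- 1 / A[i, j]
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_cpl_eglob <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  cpl_i <- numeric(n); eglob_i <- numeric(n)
  for (i in 1:n) {
    ds <- d[i, -i]
    reach <- ds[is.finite(ds)]
    cpl_i[i] <- if (length(reach)) mean(reach) else NA_real_
    eglob_i[i] <- sum(ifelse(is.finite(ds), 1 / ds, 0)) / (n - 1)
  }
  list(cpl_i = cpl_i, eglob_i = eglob_i)
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- oracle_distances(A[nb, nb, drop = FALSE])
    acc <- 0
    for (j in seq_len(k)) for (h in seq_len(k)) {
      if (j == h || !is.finite(d[j, h]) || d[j, h] == 0) next
      acc <- acc + (A[i, nb[j]] * A[i, nb[h]] / d[j, h])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# double-loop weighted modularity (Eq form: (1/l) sum_ij (w - k k'/l) delta)
oracle_modularity <- function(W, m) {
  W <- as.matrix(W)
  diag(W) <- 0
  l <- sum(W)
  if (l == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
    if (m[i] == m[j]) q <- q + (W[i, j] - k[i] * k[j] / l) / l
  }
  q
}

# directed Watts-Strogatz-style ring: each node -> k/2 neighbors on each
# side, each edge rewired to a random target with probability p
ws_ring <- function(n = 100, k = 6, p = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in 1:n) for (s in 1:(k / 2)) {
    for (j in c((i + s - 1) %% n + 1, (i - s - 1) %% n + 1)) {
      A[i, j] <- 1
    }
  }
  edges <- which(A > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    if (runif(1) < p) {
      i <- edges[e, 1]
      free <- setdiff(which(A[i, ] == 0), i)
      if (length(free)) {
        A[i, edges[e, 2]] <- 0
        A[i, free[sample.int(length(free), 1)]] <- 1
      }
    }
  }
  A
}

# hand-built phase tensor: `mats` is a list (one per frequency) of
# channels x time matrices of phases
fake_phase_tensor <- function(mats, freqs, fs_phase = 50, labels = NULL) {
  C <- nrow(mats[[1]])
  nt <- ncol(mats[[1]])
  labels <- labels %||% paste0("Ch", seq_len(C))
  arr <- array(NA_real_, c(C, length(freqs), nt), dimnames = list(labels, NULL, NULL))
  for (k in seq_along(freqs)) arr[, k, ] <- mats[[k]]
  structure(arr, freqs = freqs, fs_phase = fs_phase,
            valid = matrix(TRUE, length(freqs), nt),
            class = "phase_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted block-correlation similarity matrix with light symmetric noise
planted_blocks <- function(sizes, within = 0.9, between = 0, noise = 0.05,
                           seed = 1, axis = "temporal") {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  s <- matrix(between, n, n)
  for (b in seq_along(sizes)) s[lab == b, lab == b] <- within
  e <- matrix(runif(n * n, -noise, noise), n, n)
  s <- s + (e + t(e)) / 2
  diag(s) <- 1
  structure(s, axis = axis, excluded = rep(FALSE, n),
            class = c("similarity_matrix", "matrix", "array"),
            truth = lab)
}

co_membership <- function(m) outer(m, m, `==`)

wrap_vals <- function(x) {
  y <- x %% (2 * pi)
  y - 2 * pi * (y > pi)
}

unwrap_vals <- function(x) cumsum(c(x[1], wrap_vals(diff(x))))

# unwrapped instantaneous phase of a (nearly) monochromatic signal via the
# analytic signal (FFT Hilbert transform)
unwrap_phase_series <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  an <- fft(fft(x) * h, inverse = TRUE) / n
  ph <- Arg(an)
  cumsum(c(ph[1], wrap_vals(diff(ph))))
}
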