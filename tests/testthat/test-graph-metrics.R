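test_that("strengths: single edge, conservation, oracle equality", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 0.5
  s <- strengths(A)
  expect_equal(s$s_out, c(0.5, 0, 0))
  expect_equal(s$s_in, c(0, 0.5, 0))
  for (seed in 1:5) {
    B <- random_digraph(10, 0.5, seed)
    so <- strengths(B)
    or <- oracle_strengths(B)
    expect_equal(so$s_in, or$s_in)
    expect_equal(so$s_out, or$s_out)
    expect_equal(sum(so$s_in), sum(so$s_out))
    expect_equal(sum(so$s_in), sum(B))
  }
})

test_that("Fagiolo clustering: complete triad = 1, path = 0, oracle equality", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_wd(K3), rep(1, 3))
  path <- matrix(0, 4, 4)
  path[cbind(1:3, 2:4)] <- 0.7
  expect_equal(clustering_wd(path), rep(0, 4))
  for (seed in 1:20) {
    A <- random_digraph(8, 0.5, seed + 100)
    expect_equal(clustering_wd(A), oracle_clustering(A), tolerance = 1e-12)
  }
})

test_that("path metrics: directed cycle enumeration, completeness, disconnection", {
  C4 <- matrix(0, 4, 4)
  C4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  sp <- shortest_path_metrics(C4)
  expect_equal(sp$cpl_i, rep((1 + 2 + 3) / 3, 4))
  expect_equal(sp$eglob_i, rep((1 + 1 / 2 + 1 / 3) / 3, 4))

  K5 <- matrix(1, 5, 5) - diag(5)
  spk <- shortest_path_metrics(K5)
  expect_equal(spk$cpl, 1)
  expect_equal(spk$eglob, 1)

  # unreachable pairs contribute 0 to eglob and are dropped from cpl
  D <- matrix(0, 3, 3)
  D[1, 2] <- 1
  spd <- shortest_path_metrics(D)
  expect_equal(spd$eglob_i, c(1 / 2, 0, 0))
  expect_equal(spd$cpl_i[1], 1)
  expect_true(is.na(spd$cpl_i[3]))
  expect_equal(spd$n_unreachable_pairs, 5)
})

test_that("local efficiency: unit triad = 1, star center = 0, oracle equality", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(local_efficiency(K3), rep(1, 3))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  expect_equal(local_efficiency(star)[1], 0)
  for (seed in 1:12) {
    A <- random_digraph(7, 0.5, seed + 200)
    expect_equal(local_efficiency(A), oracle_eloc(A), tolerance = 1e-12)
  }
})

test_that("reference graphs preserve nodes, edges, and the weight multiset", {
  set.seed(30)
  A <- random_digraph(20, 0.25, 31)
  for (ref in list(random_reference(A, 3, seed = 1),
                   lattice_reference(A, 3, seed = 1))) {
    for (B in ref) {
      expect_equal(dim(B), dim(A))
      expect_equal(sum(B != 0), sum(A != 0))
      expect_equal(sort(B[B != 0]), sort(A[A != 0]))
      expect_true(all(diag(B) == 0))
    }
  }
  # lattice concentrates weight near the diagonal
  latt <- lattice_reference(A, 5, seed = 2)
  bw <- function(M) {
    idx <- which(M != 0, arr.ind = TRUE)
    sum(abs(idx[, 1] - idx[, 2]) * M[idx]) / sum(M)
  }
  expect_lt(mean(vapply(latt, bw, numeric(1))), bw(A))
  # randomizing a lattice lowers clustering
  L <- latt[[1]]
  R <- random_reference(L, 5, seed = 3)
  expect_gt(mean(clustering_wd(L)), mean(vapply(R, function(M)
    mean(clustering_wd(M)), numeric(1))))
  # degenerate graphs
  expect_equal(lattice_reference(matrix(0, 3, 3), 1, seed = 1)[[1]],
               matrix(0, 3, 3))
  single <- matrix(0, 4, 4)
  single[2, 3] <- 0.8
  expect_equal(sum(random_reference(single, 1, seed = 1)[[1]] != 0), 1)
})

test_that("small-world coefficients: identity gives sigma 1 / omega 0; ring is small-world", {
  A <- random_digraph(12, 0.4, 40)
  m <- graph_metric_summary(A)
  sw <- small_world_coefficients(m, m, m)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$omega, 0)
  expect_equal(sw$sigmaE, 1)
  expect_equal(sw$omegaE, 0)

  W <- ws_ring(100, 6, 0.1, seed = 41)
  rand <- random_reference(W, 5, seed = 42)
  latt <- lattice_reference(W, 5, seed = 43)
  sw2 <- small_world_coefficients(W, rand, latt)
  expect_gt(sw2$sigma, 1)
  expect_gt(sw2$omega, -1)
  expect_lt(sw2$omega, 1)

  degen <- matrix(0, 4, 4)
  w <- capture_warnings(swd <- small_world_coefficients(degen, degen, degen))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(swd$sigma))
})

test_that("igraph cross-checks the inverse-weight directed distances", {
  for (seed in 1:4) {
    A <- random_digraph(9, 0.4, seed + 300)
    d_or <- oracle_distances(A)
    sp <- shortest_path_metrics(A)
    oc <- oracle_cpl_eglob(A)
    expect_equal(sp$cpl_i, oc$cpl_i, tolerance = 1e-12)
    expect_equal(sp$eglob_i, oc$eglob_i, tolerance = 1e-12)
    expect_true(all(is.finite(d_or[d_or != Inf])))
  }
})
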