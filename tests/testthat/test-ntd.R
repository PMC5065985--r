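toy_graphs <- function(n_windows = 5, n = 4, seed = 50) {
  set.seed(seed)
  nodes <- hfn_nodes(paste0("E", 1:(n / 2)), c(2, 4))
  lapply(seq_len(n_windows), function(w) {
    A <- random_digraph(n, 0.6, seed + w)
    hfnet:::new_hfn_graph(A, nodes, window_index = w)
  })
}

test_that("metric dynamics columns equal direct per-window metric calls", {
  gs <- toy_graphs()
  for (mt in c("s_in", "s_out", "cc", "cpl", "eloc", "eglob")) {
    m <- metric_dynamics(gs, mt)
    expect_equal(dim(m), c(4, 5))
    for (w in c(1, 3, 5)) {
      expect_equal(unname(m[, w]), unname(nodal_metrics(gs[[w]])[[mt]]))
    }
  }
  same <- rep(gs[1], 4)
  msame <- metric_dynamics(same, "s_out")
  expect_true(all(msame == msame[, 1]))
  set <- metric_dynamics_set(gs)
  expect_named(set, c("s_in", "s_out", "cc", "cpl", "eloc", "eglob"))
  expect_equal(unclass(set$cc), unclass(metric_dynamics(gs, "cc")),
               ignore_attr = TRUE)
})

test_that("dynamics summaries: grand mean is order-invariant, SDs behave", {
  set.seed(51)
  m <- matrix(rnorm(60), 6, 10)
  s <- summarize_dynamics(m)
  expect_equal(s$grand_mean, mean(colMeans(m)))
  expect_equal(s$grand_mean, mean(rowMeans(m)))
  expect_equal(summarize_dynamics(matrix(3, 5, 5))$sd_across_nodes, 0)
  checker <- outer(1:6, 1:8, function(i, j) (-1)^(i + j))
  sc <- summarize_dynamics(checker)
  expect_equal(sc$sd_across_nodes, 1)            # population SD
  expect_equal(sc$sd_across_time, 1)
})

test_that("similarity matrices: shape, symmetry, duplicates, degenerate rows", {
  set.seed(52)
  m <- structure(matrix(rnorm(80), 8, 10), class = c("metric_dynamics", "matrix", "array"))
  st <- similarity(m, "temporal")
  expect_equal(dim(st), c(10, 10))
  sn <- similarity(m, "nodal")
  expect_equal(dim(sn), c(8, 8))
  expect_equal(unclass(st), t(unclass(st)), tolerance = 1e-12)
  expect_true(all(diag(st) == 1))

  m2 <- m
  m2[, 5] <- m2[, 2]
  st2 <- similarity(m2, "temporal")
  expect_equal(st2[2, 5], 1)

  m3 <- m
  m3[3, ] <- 2                                    # constant node
  expect_warning(sn3 <- similarity(m3, "nodal"), "zero-variance")
  expect_true(attr(sn3, "excluded")[3])
  p <- suppressMessages(modularity_partition(structure(abs(unclass(sn3)),
    axis = "nodal", excluded = attr(sn3, "excluded"),
    class = class(sn3))))
  expect_true(is.na(p$assignment[3]))
})

test_that("modularity Q: single module zero, two cliques 0.5, double-loop oracle", {
  set.seed(53)
  W <- abs(matrix(rnorm(49), 7, 7))
  W <- (W + t(W)) / 2
  expect_identical(modularity_q(W, rep(1L, 7)), 0)

  cliques <- matrix(0, 8, 8)
  cliques[1:4, 1:4] <- 1
  cliques[5:8, 5:8] <- 1
  diag(cliques) <- 0
  expect_equal(modularity_q(cliques, rep(1:2, each = 4)), 0.5)

  for (r in 1:10) {
    W2 <- abs(matrix(rnorm(100), 10, 10))
    W2 <- (W2 + t(W2)) / 2
    memb <- sample(1:3, 10, replace = TRUE)
    expect_equal(modularity_q(W2, memb), oracle_modularity(W2, memb),
                 tolerance = 1e-12)
  }
})

test_that("planted blocks are recovered exactly; labels are permutation-invariant", {
  s <- planted_blocks(c(30, 30, 30), seed = 60)
  p <- suppressMessages(modularity_partition(s))
  expect_equal(p$n_modules, 3)
  expect_equal(co_membership(p$assignment), co_membership(attr(s, "truth")))
  expect_gt(p$q, 0.3)

  # relabeling elements permutes the partition consistently
  perm <- sample(90)
  sp <- structure(unclass(s)[perm, perm], axis = "temporal",
                  excluded = rep(FALSE, 90), class = class(s))
  pp <- suppressMessages(modularity_partition(sp))
  expect_equal(co_membership(pp$assignment), co_membership(attr(s, "truth")[perm]))

  # degenerate all-equal matrix: every partition has Q = 0; one module returned
  eq <- structure(matrix(1, 10, 10), axis = "temporal",
                  excluded = rep(FALSE, 10),
                  class = c("similarity_matrix", "matrix", "array"))
  pd <- modularity_partition(eq)
  expect_equal(pd$n_modules, 1)
  expect_identical(pd$q, 0)
})

test_that("signed Louvain: anticorrelated blocks, agreement on positive matrices", {
  n <- 40
  lab <- rep(1:2, each = n / 2)
  s <- outer(lab, lab, function(a, b) ifelse(a == b, 0.8, -0.8))
  diag(s) <- 1
  s <- structure(s, axis = "nodal", excluded = rep(FALSE, n),
                 class = c("similarity_matrix", "matrix", "array"))
  p <- louvain_signed_partition(s)
  expect_equal(p$n_modules, 2)
  expect_equal(co_membership(p$assignment), co_membership(lab))
  expect_gt(p$q, 0)

  pos <- planted_blocks(c(20, 20), within = 0.8, between = 0.05, seed = 61)
  a <- suppressMessages(modularity_partition(pos))
  b <- louvain_signed_partition(pos)
  expect_equal(co_membership(a$assignment), co_membership(b$assignment))

  iden <- structure(diag(12), axis = "nodal", excluded = rep(FALSE, 12),
                    class = c("similarity_matrix", "matrix", "array"))
  pi0 <- louvain_signed_partition(iden)
  expect_equal(pi0$n_modules, 1)
  expect_equal(pi0$q, 0)
})

test_that("state statistics report counts, extremes, and contiguous runs", {
  p <- hfnet:::new_partition(rep(1:3, each = 27), 0.4, "temporal")
  st <- state_statistics(p)
  expect_equal(st$n_modules, 3)
  expect_equal(st$min_size, 27)
  expect_equal(st$max_size, 27)
  expect_equal(st$min_run, 27)
  expect_equal(st$max_duration_s, 2.7)

  pn <- hfnet:::new_partition(rep(1:3, times = c(150, 200, 230)), 0.2, "nodal")
  sn <- state_statistics(pn)
  expect_equal(sn$min_size, 150)
  expect_equal(sn$max_size, 230)
})

test_that("null modularity separates planted structure from shuffled matrices", {
  s <- planted_blocks(c(20, 20, 20), seed = 62)
  nl <- modularity_null(s, n = 40, seed = 63)
  expect_gt(nl$q_observed, quantile(nl$q_null, 0.99))
  expect_lt(nl$p_value, 0.05)

  set.seed(64)
  r <- matrix(runif(900, 0, 0.2), 30, 30)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  rnd <- structure(r, axis = "temporal", excluded = rep(FALSE, 30),
                   class = c("similarity_matrix", "matrix", "array"))
  nl2 <- modularity_null(rnd, n = 30, seed = 65)
  expect_gt(nl2$p_value, 0.05)

  n1 <- modularity_null(s, n = 1, seed = 66)
  expect_length(n1$q_null, 1)
})

test_that("planted state counts K in {2, 4} are recovered across seeds", {
  for (K in c(2L, 4L)) {
    hits <- 0L
    for (seed in 1:10) {
      s <- planted_blocks(rep(24, K), within = 0.8, noise = 0.1, seed = 700 + seed)
      p <- suppressMessages(modularity_partition(s))
      hits <- hits + (p$n_modules == K)
    }
    expect_gte(hits, 9L)
  }
})
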