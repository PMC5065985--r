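test_that("node table is frequency-major and round-trips index <-> (electrode, foi)", {
  labels <- paste0("E", 1:58)
  nodes <- hfn_nodes(labels)
  expect_equal(nrow(nodes), 580)                 # 58 electrodes x 10 FOIs
  expect_equal(nodes$index, seq_len(580))
  for (i in c(1, 59, 580, 307)) {
    blk <- (i - 1) %/% 58
    expect_equal(nodes$electrode[i], labels[(i - 1) %% 58 + 1])
    expect_equal(nodes$foi[i], seq(2, 20, 2)[blk + 1])
  }
  small <- hfn_nodes(c("A", "B"), c(2, 4))
  expect_equal(nrow(hfn_pairs(small)), 6)        # 4 nodes -> 6 unordered pairs
})

make_toy_coupling <- function(labels = c("A", "B"), fois = c(10, 20)) {
  fs <- 250
  tt <- (0:2499) / fs
  lagged <- function(lag, f) cos(2 * pi * f * tt - lag)
  rec <- segmented_recording(rbind(cos(2 * pi * 10 * tt) + cos(2 * pi * 20 * tt),
                                   lagged(pi / 8, 10) + lagged(pi / 6, 20)),
                             fs, labels)
  ph <- extract_phases(rec, morlet_params(freqs = fois))
  nodes <- hfn_nodes(labels, fois)
  list(nodes = nodes,
       cw = sliding_window_coupling(ph, hfn_pairs(nodes)))
}

test_that("HFN assembly: zero diagonal, directed ICI entries, locked pair = 1", {
  toy <- make_toy_coupling()
  g <- build_hfn(toy$cw, 40, toy$nodes)
  A <- g$adjacency
  expect_equal(dim(A), c(4, 4))
  expect_true(all(diag(A) == 0))
  # A leads B by pi/8 at 10 Hz: node 1 (A@10) -> node 2 (B@10) fully locked
  expect_equal(A[1, 2], 1, tolerance = 1e-9)
  expect_lt(A[2, 1], 1e-9)
  expect_equal(g$cost, sum(A != 0) / 12)
  expect_error(build_hfn(toy$cw, 99, toy$nodes), "out of range")
  bad <- toy$cw
  bad$pairs <- bad$pairs[-1, ]
  expect_error(build_hfn(bad, 1, toy$nodes), "unordered")
})

test_that("thresholding keeps weights, is idempotent, cost monotone", {
  set.seed(8)
  A <- matrix(runif(100), 10, 10)
  diag(A) <- 0
  g <- hfnet:::new_hfn_graph(A, hfn_nodes(paste0("E", 1:5), c(2, 4)))
  t0 <- apply_threshold(g, 0)
  expect_equal(t0$cost, 1)                       # all-positive off-diagonal
  t1 <- apply_threshold(g, 1)
  expect_equal(t1$cost, 0)
  tm <- apply_threshold(g, 0.4)
  expect_true(all(tm$adjacency[tm$adjacency != 0] > 0.4))
  expect_equal(apply_threshold(tm, 0.4)$adjacency, tm$adjacency)
  costs <- vapply(c(0, 0.2, 0.5, 0.8), function(th) apply_threshold(g, th)$cost,
                  numeric(1))
  expect_true(all(diff(costs) <= 0))
  # surviving weights unchanged
  expect_equal(tm$adjacency[tm$adjacency != 0],
               A[A > 0.4])
})

test_that("time-shuffle preserves sample multisets; phase-shuffle the spectrum", {
  rec <- gen_coupled_oscillators(list(oscillator_spec("A", 9, snr = 2),
                                      oscillator_spec("B", 5, snr = 2)),
                                 duration = 4, seed = 10)
  ts <- make_surrogates(rec, "time-shuffle", seed = 1)
  expect_equal(sort(ts$data["A", ]), sort(rec$data["A", ]))
  expect_false(identical(ts$data["A", ], rec$data["A", ]))

  ps <- make_surrogates(rec, "phase-shuffle", seed = 1)
  for (ch in c("A", "B")) {
    a0 <- Mod(fft(rec$data[ch, ]))
    a1 <- Mod(fft(ps$data[ch, ]))
    expect_lt(max(abs(a1 - a0) / (a0 + 1e-12)), 1e-9)
    # Parseval: total power preserved
    expect_equal(sum(ps$data[ch, ]^2), sum(rec$data[ch, ]^2), tolerance = 1e-9)
  }
  expect_false(identical(ps$data["A", ], rec$data["A", ]))
})

test_that("surrogates of a locked pair destroy windowed coupling", {
  tt <- (0:2499) / 250
  rec <- segmented_recording(rbind(cos(2 * pi * 10 * tt),
                                   cos(2 * pi * 10 * tt - pi / 8)),
                             250, c("A", "B"))
  prs <- data.frame(channel_i = "A", freq_i = 10, channel_j = "B", freq_j = 10)
  p <- morlet_params(freqs = 10)
  orig <- mean(sliding_window_coupling(extract_phases(rec, p), prs)$ici)
  sur <- make_surrogates(rec, "phase-shuffle", seed = 2)
  surr <- mean(sliding_window_coupling(extract_phases(sur, p), prs)$ici)
  expect_gt(orig, 0.99)
  expect_lt(surr, 0.3)
})

test_that("bootstrap critical value: alpha = 0.5 recovers the mean, stable in n_boot", {
  set.seed(12)
  rec <- segmented_recording(matrix(rnorm(3 * 1250), 3), 250,
                             c("A", "B", "C"))
  sn <- surrogate_critical_value(rec, "time-shuffle", n_boot = 400, alpha = 0.5,
                                 seed = 3, n_surrogates = 2, fois = c(6, 10))
  expect_lt(abs(sn$critical_value - mean(sn$boot_means)), 0.002)
  sn2 <- surrogate_critical_value(rec, "time-shuffle", n_boot = 800, alpha = 0.5,
                                  seed = 4, n_surrogates = 2, fois = c(6, 10))
  expect_lt(abs(sn$critical_value - sn2$critical_value), 0.01)
  expect_error(surrogate_critical_value(rec, n_boot = 50), ">= 100")
})
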