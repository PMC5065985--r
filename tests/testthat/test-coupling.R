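grid_t <- function(nt = 500, fs = 50) (0:(nt - 1)) / fs

test_that("generalized phase difference: identity, constant offsets, 2:1 ratio", {
  nt <- 200
  phiA <- wrap_vals(2 * pi * 2 * grid_t(nt))
  phiB <- wrap_vals(2 * pi * 4 * grid_t(nt))
  pt <- fake_phase_tensor(list(rbind(phiA, phiA * 0), rbind(phiA * 0, phiB)),
                          freqs = c(2, 4))
  # identical series, 1:1
  same <- fake_phase_tensor(list(rbind(phiA, phiA)), freqs = 2)
  d0 <- generalized_phase_difference(same, list("Ch1", 2, "Ch2", 2))
  expect_true(all(d0$values == 0))
  expect_equal(unname(d0$ratio), c(1, 1))

  # constant offset -pi/8
  off <- fake_phase_tensor(list(rbind(numeric(nt), rep(pi / 8, nt))), freqs = 2)
  dd <- generalized_phase_difference(off, list("Ch1", 2, "Ch2", 2))
  expect_true(all(abs(dd$values + pi / 8) < 1e-12))

  # 2 Hz vs 4 Hz: ratio (2, 1), analytic zero
  d21 <- generalized_phase_difference(pt, list("Ch1", 2, "Ch2", 4))
  expect_equal(unname(d21$ratio), c(2, 1))
  expect_true(all(abs(d21$values) < 1e-9))
  expect_error(generalized_phase_difference(pt, list("Ch1", 2, "Ch2", 4),
                                            ratio = c(1, 1)), "ratio")
})

test_that("PSI: stable angles give 1, dispersed angles give 0", {
  expect_equal(psi(rep(pi, 100)), 1)             # anti-phase still locks
  K <- 40
  expect_lt(psi(2 * pi * (0:(K - 1)) / K), 1e-12)
  # iid uniform phases, window 100: E[PSI] ~ sqrt(pi)/2/sqrt(100)
  set.seed(1)
  reps <- matrix(runif(1e4 * 100, -pi, pi), 1e4)
  m <- mean(Mod(rowMeans(exp(1i * reps))))
  expect_lt(abs(m - sqrt(pi) / 2 / 10), 0.005)
})

test_that("ternary coding uses open intervals at 0 and +/- pi/4", {
  v <- c(pi / 8, -pi / 8, pi / 2, 0, pi / 4, -pi / 4, 0.01, -0.01)
  expect_identical(ternary_code(v)$codes, c(1L, -1L, 0L, 0L, 0L, 0L, 1L, -1L))
})

test_that("cleaning drops sub-period runs and is monotone in ACI", {
  fsP <- 50
  f0 <- 5                                        # period 0.2 s = 10 samples
  code <- c(rep(0L, 10), rep(1L, 5), rep(0L, 10), rep(-1L, 20), rep(0L, 5))
  cl <- clean_code(code, period = 1 / f0, fs_phase = fsP)
  expect_identical(cl$codes[11:15], rep(0L, 5))   # 0.1 s < 0.2 s: dropped
  expect_identical(cl$codes[26:45], rep(-1L, 20)) # 0.4 s >= 0.2 s: kept
  z <- clean_code(rep(0L, 30), period = 0.2, fs_phase = fsP)
  expect_identical(z$codes, rep(0L, 30))
  expect_warning(clean_code(code, period = 0.01, fs_phase = fsP), "no-op")

  set.seed(2)
  for (r in 1:20) {
    raw <- sample(c(-1L, 0L, 1L), 200, replace = TRUE)
    cl <- clean_code(raw, period = 0.1, fs_phase = fsP)$codes
    expect_lte(mean(cl != 0), mean(raw != 0))    # cleaned ACI <= raw ACI
    expect_true(all(cl[raw == 0L] == 0L))
  }
})

test_that("coupling indices match hand values, limits, and a counting oracle", {
  expect_equal(coupling_indices(rep(1L, 100)),
               list(pci = 1, nci = 0, aci = 1, ici = 1))
  allneg <- coupling_indices(rep(-1L, 100))
  expect_equal(allneg$ici, 0)
  expect_equal((allneg$pci + allneg$aci) / (2 * allneg$aci), 0.5)

  hand <- coupling_indices(c(rep(1L, 4), rep(-1L, 2), rep(0L, 4)))
  expect_equal(hand$pci, 0.4)
  expect_equal(hand$nci, 0.2)
  expect_equal(hand$aci, 0.6)
  expect_equal(hand$ici, (1.0 / 1.2) * 0.4)

  set.seed(4)
  for (r in 1:25) {
    v <- sample(c(-1L, 0L, 1L), 60, replace = TRUE)
    ci <- coupling_indices(v)
    np <- 0; nn <- 0
    for (x in v) {
      if (x == 1L) np <- np + 1
      if (x == -1L) nn <- nn + 1
    }
    expect_equal(ci$pci, np / 60)
    expect_equal(ci$nci, nn / 60)
    expect_equal(ci$aci, (np + nn) / 60)
    expect_true(all(unlist(ci) >= 0 & unlist(ci) <= 1))
  }
})

test_that("direction antisymmetry: negating dphi swaps PCI and NCI", {
  set.seed(5)
  dphi <- runif(300, -pi, pi)
  a <- coupling_indices(ternary_code(dphi)$codes)
  b <- coupling_indices(ternary_code(-dphi)$codes)
  expect_equal(a$pci, b$nci)
  expect_equal(a$nci, b$pci)
  expect_equal(a$aci, b$aci)
  expect_equal(psi(dphi), psi(-dphi))
})

test_that("sliding windows: count, stationarity, and standalone-op equivalence", {
  fs <- 250
  tt <- (0:2499) / fs
  rec <- segmented_recording(rbind(cos(2 * pi * 10 * tt),
                                   cos(2 * pi * 10 * tt - pi / 8)),
                             fs, c("A", "B"))
  ph <- extract_phases(rec, morlet_params(freqs = 10))
  prs <- data.frame(channel_i = "A", freq_i = 10, channel_j = "B", freq_j = 10)
  cw <- sliding_window_coupling(ph, prs)
  expect_equal(cw$n_windows, 81)
  expect_true(all(abs(cw$ici - 1) < 1e-12))       # stationary lock, A leads
  expect_true(all(abs(cw$psi - 1) < 1e-4))
  expect_lt(max(abs(cw$ici_rev)), 1e-12)
  expect_error(sliding_window_coupling(ph, prs, window_ms = 60000), "longer")

  # sliding pipeline equals composing the standalone operations
  set.seed(6)
  nt <- 300
  p1 <- wrap_vals(cumsum(rnorm(nt, 0.3, 0.4)))
  p2 <- wrap_vals(cumsum(rnorm(nt, 0.25, 0.4)))
  pt <- fake_phase_tensor(list(rbind(p1, p2)), freqs = 6)
  cw2 <- sliding_window_coupling(pt, data.frame(channel_i = "Ch1", freq_i = 6,
                                                channel_j = "Ch2", freq_j = 6))
  d <- generalized_phase_difference(pt, list("Ch1", 6, "Ch2", 6))
  cl <- clean_code(ternary_code(d), period = 1 / 6, fs_phase = 50)
  for (w in c(1, 17, 41)) {
    win <- cw2$window_start_idx[w] + 0:99
    ref <- coupling_indices(cl, win)
    expect_equal(cw2$pci[1, w], ref$pci, tolerance = 1e-12)
    expect_equal(cw2$nci[1, w], ref$nci, tolerance = 1e-12)
    expect_equal(cw2$ici[1, w], ref$ici, tolerance = 1e-12)
    expect_equal(cw2$psi[1, w], psi(d, win), tolerance = 1e-12)
  }
})

test_that("coupling switched on mid-segment raises late-window ICI", {
  set.seed(7)
  nt <- 500                                      # 10 s at 50 Hz
  drift <- wrap_vals(cumsum(rnorm(nt, 0.6, 0.3)))
  locked <- rep(pi / 8, nt)
  dphi <- c(drift[1:250], locked[251:500])
  pt <- fake_phase_tensor(list(rbind(dphi, numeric(nt))), freqs = 5)
  cw <- sliding_window_coupling(pt, data.frame(channel_i = "Ch1", freq_i = 5,
                                               channel_j = "Ch2", freq_j = 5))
  early <- mean(cw$ici[1, 1:25])
  late <- mean(cw$ici[1, 55:81])
  expect_gt(late, early + 0.5)
})

test_that("long-format export mirrors both directions", {
  pt <- fake_phase_tensor(list(rbind(rep(pi / 16, 120), numeric(120))), freqs = 4)
  cw <- sliding_window_coupling(pt, data.frame(channel_i = "Ch1", freq_i = 4,
                                               channel_j = "Ch2", freq_j = 4),
                                window_ms = 1000, step_ms = 500)
  tab <- as.data.frame(cw)
  expect_equal(nrow(tab), 2 * cw$n_windows)
  fwd <- tab[tab$src_channel == "Ch1", ]
  rev <- tab[tab$src_channel == "Ch2", ]
  expect_equal(fwd$pci, rev$nci)
  expect_equal(fwd$aci, rev$aci)
  expect_equal(fwd$psi, rev$psi)
})
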