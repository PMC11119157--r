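test_that("Pearson connectivity reproduces the analytic endpoints", {
  set.seed(31)
  x <- rnorm(100)
  seg <- eeg_trial(rbind(x, 2 * x, -x), fs = 50, label = "positive")
  M <- pearson_matrix(seg)
  expect_equal(M[1, 2], 1)        # scaled copy -> +1
  expect_equal(M[1, 3], -1)       # negated copy -> -1
  expect_equal(diag(M), rep(1, 3), ignore_attr = TRUE)

  # hand evaluation of covariance / (sd_x sd_y) on four points
  xv <- c(1, 2, 3, 4); yv <- c(1, 2, 4, 8)
  r_hand <- mean((xv - mean(xv)) * (yv - mean(yv))) /
    (sqrt(mean((xv - mean(xv))^2)) * sqrt(mean((yv - mean(yv))^2)))
  seg2 <- eeg_trial(rbind(xv, yv), fs = 4, label = "positive")
  expect_equal(pearson_matrix(seg2)[1, 2], r_hand)
})

test_that("zero-variance channels give zero correlations with a warning", {
  seg <- eeg_trial(rbind(rnorm(50), rep(1, 50)), fs = 50,
                   label = "positive", channels = c("good", "flat"))
  expect_warning(M <- pearson_matrix(seg), "flat")
  expect_identical(M["good", "flat"], 0)
  expect_identical(M["flat", "flat"], 1)
})

test_that("coherence is 1 for identical channels and single Welch segments", {
  set.seed(32)
  fs <- 64
  x <- rnorm(4 * fs)
  seg <- eeg_trial(rbind(x, x), fs = fs, label = "positive")
  M <- coherence_matrix(seg, conn_spec("Coh", band = c(4, 30)))
  expect_equal(M[1, 2], 1, tolerance = 1e-10)

  # one Welch segment: |S_ab|^2 = S_aa S_bb for any two signals
  y <- rnorm(4 * fs)
  seg2 <- eeg_trial(rbind(x, y), fs = fs, label = "positive")
  M1 <- coherence_matrix(seg2, conn_spec("Coh", band = c(4, 30),
                                         welch_seg_s = 4))
  expect_equal(M1[1, 2], 1, tolerance = 1e-10)
})

test_that("coherence matches an independent periodogram-averaging oracle", {
  set.seed(33)
  fs <- 128
  tt <- (0:(8 * fs - 1)) / fs
  base <- sin(2 * pi * 10 * tt)
  x <- base + rnorm(length(tt), sd = sqrt(0.5) / sqrt(10))  # SNR 10
  y <- base + rnorm(length(tt), sd = sqrt(0.5) / sqrt(10))
  seg <- eeg_trial(rbind(x, y), fs = fs, label = "positive")
  spec <- conn_spec("Coh", band = c(4, 45))
  M <- coherence_matrix(seg, spec)
  ref <- naive_welch_coherence(x, y, fs, spec$welch_seg_s,
                               spec$welch_overlap, spec$band)
  expect_equal(M[1, 2], ref, tolerance = 0.05)
  expect_error(coherence_matrix(seg, conn_spec("Coh", band = c(0.01, 0.2))),
               "frequency bins")
})

test_that("phase locking value hits its analytic endpoints", {
  fs <- 128
  tt <- (0:(10 * fs - 1)) / fs
  seg <- eeg_trial(rbind(sin(2 * pi * 10 * tt),
                         sin(2 * pi * 10 * tt + 0.5)),
                   fs = fs, label = "positive")
  M <- plv_matrix(seg, conn_spec("PLV", band = c(4, 45)))
  expect_equal(M[1, 2], 1, tolerance = 1e-3)   # constant offset -> 1
  expect_equal(diag(M), rep(1, 2), ignore_attr = TRUE)

  # phase differences alternating 0 / pi in equal counts cancel exactly
  phi <- rbind(rep(0, 100), rep(c(0, pi), 50))
  expect_equal(emognn:::plv_from_phases(phi)[1, 2], 0)

  # uniform random phase differences: E|mean phasor| ~ sqrt(pi / (4 n))
  set.seed(34)
  phi2 <- rbind(runif(1e5, -pi, pi), rep(0, 1e5))
  expect_lte(emognn:::plv_from_phases(phi2)[1, 2], 0.02)
})

test_that("phase lag index hits its analytic endpoints", {
  fs <- 128
  tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * tt)
  seg_same <- eeg_trial(rbind(x, x), fs = fs, label = "positive")
  spec <- conn_spec("PLI", band = c(4, 45))
  expect_equal(pli_matrix(seg_same, spec)[1, 2], 0, tolerance = 1e-6)

  seg_lag <- eeg_trial(rbind(x, sin(2 * pi * 10 * tt + pi / 2)),
                       fs = fs, label = "positive")
  M <- pli_matrix(seg_lag, spec)
  expect_equal(M[1, 2], 1, tolerance = 1e-3)
  expect_equal(diag(M), rep(0, 2), ignore_attr = TRUE)

  # alternating +pi/2 / -pi/2 lags cancel by sign symmetry
  phi <- rbind(rep(c(pi / 2, -pi / 2), 50), rep(0, 100))
  expect_equal(emognn:::pli_from_phases(phi)[1, 2], 0)
})

test_that("phase methods reject segments too short for edge trimming", {
  seg <- eeg_trial(matrix(rnorm(2 * 64), 2), fs = 32, label = "positive",
                   trial_id = "tiny")
  expect_error(plv_matrix(seg, conn_spec("PLV", band = c(4, 14))), "tiny")
})

test_that("connectivity matrices are symmetric, bounded and
           permutation-equivariant", {
  set.seed(35)
  fs <- 64
  C <- 5
  dat <- matrix(rnorm(C * 6 * fs), C)
  dat[2, ] <- dat[1, ] * 0.7 + dat[2, ] * 0.5   # some dependence
  seg <- eeg_trial(dat, fs = fs, label = "positive")
  specs <- list(conn_spec("Cor"), conn_spec("Coh", band = c(4, 28)),
                conn_spec("PLV", band = c(4, 28)),
                conn_spec("PLI", band = c(4, 28)))
  for (spec in specs) {
    M <- connectivity_matrix(seg, spec)
    expect_lt(max(abs(M - t(M))), 1e-10)
    if (spec$method == "Cor") {
      expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
    } else {
      expect_true(all(M >= -1e-12 & M <= 1 + 1e-12))
    }
    for (rep in 1:3) {
      p <- sample(C)
      segp <- eeg_trial(dat[p, ], fs = fs, label = "positive",
                        channels = seg$channels[p])
      Mp <- connectivity_matrix(segp, spec)
      expect_equal(unname(Mp), unname(M[p, p]), tolerance = 1e-10)
    }
  }
})

test_that("PLV dominates PLI for zero-lag-coupled signal pairs", {
  # sign(sin) discards the magnitude of phase concentration: for phase
  # differences symmetric about zero (shared zero-lag source plus noise)
  # the signs cancel while the phasor mean stays large.  (For independent
  # signals the two indices are both near zero and either may fluctuate
  # above the other, so no ordering holds there.)
  set.seed(36)
  fs <- 64
  spec <- conn_spec("PLV", band = c(4, 28))
  for (i in 1:100) {
    s <- rnorm(6 * fs)
    seg <- eeg_trial(rbind(s + 0.5 * rnorm(length(s)),
                           s + 0.5 * rnorm(length(s))),
                     fs = fs, label = "positive")
    phi <- emognn:::instantaneous_phases(seg, spec)
    plv <- emognn:::plv_from_phases(phi)[1, 2]
    pli <- emognn:::pli_from_phases(phi)[1, 2]
    expect_gt(plv, pli)
  }
})
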