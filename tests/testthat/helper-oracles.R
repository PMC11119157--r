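# Independent brute-force reference implementations and small fixture
# builders used across the suite.  These deliberately use naive loops and a
# different code organization from the package internals.

naive_conv <- function(x, k) {
  L <- length(x) - length(k) + 1L
  vapply(seq_len(L), function(i)
    sum(x[i:(i + length(k) - 1L)] * k), 0)
}

# conv -> square -> average pool -> log, one kernel, by explicit loops
naive_power_features <- function(x, k, pool_len, pool_stride, eps) {
  u <- naive_conv(x, k)^2
  F_n <- (length(u) - pool_len) %/% pool_stride + 1L
  vapply(seq_len(F_n), function(f) {
    s <- (f - 1L) * pool_stride + 1L
    log(mean(u[s:(s + pool_len - 1L)]) + eps)
  }, 0)
}

naive_normalize <- function(A) {
  C <- nrow(A)
  d <- numeric(C)
  for (a in seq_len(C)) d[a] <- sum(A[a, ])
  out <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C))
    out[a, b] <- A[a, b] / sqrt(d[a] * d[b])
  out
}

naive_gcn <- function(A, Z, W) {
  C <- nrow(A); Fi <- ncol(Z); Fo <- ncol(W)
  AZ <- matrix(0, C, Fi)
  for (a in seq_len(C)) for (j in seq_len(Fi))
    AZ[a, j] <- sum(A[a, ] * Z[, j])
  out <- matrix(0, C, Fo)
  for (a in seq_len(C)) for (o in seq_len(Fo))
    out[a, o] <- max(0, sum(AZ[a, ] * W[, o]))
  out
}

# Straight-line reference for the full two-stage branch (class-specific
# first layers, logistic pair attention, shared second layer).
naive_branch <- function(Z, N1, N2, bp) {
  sig <- function(x) 1 / (1 + exp(-x))
  Z1 <- naive_gcn(N1, Z, bp$W_l1)
  Z2 <- naive_gcn(N2, Z, bp$W_l2)
  C <- nrow(Z)
  h <- ncol(Z1)
  score <- function(Zl, P) {
    S <- matrix(0, C, C)
    for (a in seq_len(C)) for (b in seq_len(C))
      S[a, b] <- sig(sum(c(Zl[a, ], Zl[b, ]) * P))
    S
  }
  asc <- score(Z1, bp$P_l1) + score(Z2, bp$P_l2)
  list(Zb_l1 = naive_gcn(asc * N1, Z1, bp$W_as),
       Zb_l2 = naive_gcn(asc * N2, Z2, bp$W_as),
       ascore = asc)
}

# Welch magnitude-squared coherence by independent periodogram averaging.
naive_welch_coherence <- function(x, y, fs, seg_s, overlap, band) {
  n <- round(seg_s * fs)
  step <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  Sxx <- Syy <- numeric(n %/% 2 + 1)
  Sxy <- complex(n %/% 2 + 1)
  for (s in starts) {
    xs <- x[s:(s + n - 1L)]; ys <- y[s:(s + n - 1L)]
    fx <- fft((xs - mean(xs)) * w)[1:(n %/% 2 + 1)]
    fy <- fft((ys - mean(ys)) * w)[1:(n %/% 2 + 1)]
    Sxx <- Sxx + Mod(fx)^2
    Syy <- Syy + Mod(fy)^2
    Sxy <- Sxy + fx * Conj(fy)
  }
  freq <- (0:(n %/% 2)) * fs / n
  sel <- freq >= band[1] & freq <= band[2]
  mean(Mod(Sxy[sel])^2 / (Sxx[sel] * Syy[sel]))
}

# A C-channel segment of sinusoids with per-channel frequency/phase plus
# optional white noise.
make_tone_segment <- function(fs, dur_s, freqs, phases = NULL,
                              noise_sd = 0, label = "positive",
                              trial_id = "tone") {
  C <- length(freqs)
  if (is.null(phases)) phases <- numeric(C)
  tt <- (seq_len(round(dur_s * fs)) - 1) / fs
  dat <- t(vapply(seq_len(C), function(c)
    sin(2 * pi * freqs[c] * tt + phases[c]) +
      if (noise_sd > 0) rnorm(length(tt), sd = noise_sd) else 0,
    numeric(length(tt))))
  eeg_trial(dat, fs = fs, label = label, trial_id = trial_id)
}

# Random labelled trials for fold-plan / IO tests.
make_random_trials <- function(n_per_class, C = 4, fs = 32, dur_s = 2,
                               labels = c("positive", "negative")) {
  k <- 0
  out <- list()
  for (l in labels) for (i in seq_len(n_per_class)) {
    k <- k + 1
    out[[k]] <- eeg_trial(matrix(rnorm(C * round(dur_s * fs)), C),
                          fs = fs, label = l,
                          trial_id = sprintf("%s%02d", substr(l, 1, 1), i))
  }
  out
}

# Small strongly separable synthetic dataset for CV/e2e unit tests.
tiny_sim_dataset <- function(trials_per_class = 6, seed = 11) {
  simulate_eeg_dataset(sim_config(
    n_channels = 6, fs = 32, duration_s = 8,
    trials_per_class = trials_per_class, f0 = 8,
    coupled_l1 = 1:3, coupled_l2 = 4:6,
    coupling_amp = 1, noise_amp = 0.2, seed = seed))
}

# Tiny model config matched to tiny_sim_dataset segments (fs 32, T 128).
tiny_model_config <- function(...) {
  emognn_config(fs = 32, variants = "PLV", band = c(4, 14),
                h1 = 8, h2 = 4, ...)
}

tiny_control <- function(...) {
  args <- list(...)
  defaults <- list(learning_rate = 3e-3, batch_size = 16L,
                   max_epochs = 6L, patience = 2L, fine_tune_epochs = 2L,
                   lambda = 1e-4, seed = 5L)
  defaults[names(args)] <- args
  defaults$patience <- min(defaults$patience, defaults$max_epochs - 1L)
  do.call(emognn_control, defaults)
}
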