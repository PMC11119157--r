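test_that("kernel lengths follow the half-power-of-two sampling-rate rule", {
  expect_identical(kernel_lengths(encoder_config(128)), c(64L, 32L, 16L))
  expect_identical(kernel_lengths(encoder_config(256)), c(128L, 64L, 32L))
  # 0.5^3 * 100 = 12.5 rounds half away from zero -> 13
  expect_identical(kernel_lengths(encoder_config(100)), c(50L, 25L, 13L))
  expect_error(encoder_config(3), "kernel length")
})

test_that("power features have closed forms on degenerate inputs", {
  cfg <- encoder_config(32, pool_len = 8, pool_stride = 8)
  set.seed(51)
  params <- emognn:::init_encoder_params(cfg, 64)
  # all-zero input: every feature equals log(log_floor)
  Z0 <- encode_channel(numeric(64), cfg, params)
  expect_true(all(vapply(Z0, function(m)
    max(abs(m - log(cfg$log_floor))), 0) < 1e-12))

  # unit kernel of length 1, constant input, pool over everything
  cfg1 <- encoder_config(32, n_scales = 1, kernels_per_scale = 1,
                         pool_len = 64, pool_stride = 64, kernel_len = 1)
  p1 <- list(kernels = list(matrix(1, 1, 1)), q = list(0.3))
  Zc <- encode_channel(rep(3, 64), cfg1, p1)
  expect_equal(as.numeric(Zc[[1]]), log(9 + cfg1$log_floor))
})

test_that("encode_channel matches the naive sliding-dot-product oracle", {
  set.seed(52)
  cfg <- encoder_config(32, pool_len = 8, pool_stride = 8)
  for (i in 1:30) {
    params <- emognn:::init_encoder_params(cfg, 96)
    x <- rnorm(96)
    Z <- encode_channel(x, cfg, params)
    r <- sample(3, 1); k <- sample(9, 1)
    ref <- naive_power_features(x, params$kernels[[r]][, k],
                                cfg$pool_len, cfg$pool_stride,
                                cfg$log_floor)
    expect_equal(as.numeric(Z[[r]][k, ]), ref, tolerance = 1e-6)
  }
})

test_that("kernel attention softmax behaves as a scalar-projection gate", {
  Z <- matrix(rep(1:5, each = 9), 9, 5)       # all rows identical
  att <- kernel_attention(Z, q = c(1, 0, 0, 2, 0))
  expect_equal(att$weights, rep(1 / 9, 9))
  expect_equal(att$weighted, Z / 9)
  expect_equal(sum(att$weights), 1)

  # q orthogonal to every row -> all projections zero, uniform weights
  Zo <- matrix(c(1, -1), 2, 2)
  atto <- kernel_attention(rbind(c(1, 1), c(2, 2)), q = c(1, -1))
  expect_equal(atto$scores, c(0, 0))
  expect_equal(atto$weights, c(0.5, 0.5))

  # K = 2 with projections (1, 0): softmax gives (e/(e+1), 1/(e+1))
  Zp <- rbind(c(1, 0), c(0, 0))
  attp <- kernel_attention(Zp, q = c(1, 0))
  expect_equal(attp$weights, c(exp(1), 1) / (exp(1) + 1))
  expect_error(kernel_attention(Zp, q = c(0, 0)), "zero")
})

test_that("segment encoding shares parameters across channels", {
  set.seed(53)
  cfg <- encoder_config(32, pool_len = 8, pool_stride = 8)
  params <- emognn:::init_encoder_params(cfg, 128)
  x <- rnorm(128)
  nf <- encode_segment(rbind(x, x, rnorm(128)), cfg, params)
  expect_identical(nf$Z[1, ], nf$Z[2, ])
  expect_false(isTRUE(all.equal(nf$Z[1, ], nf$Z[3, ])))
  expect_identical(ncol(nf$Z), nf$sk)
  expect_identical(nf$sk, 9L * sum(nf$F_r))

  # with attention off the rows are plain concatenated features
  nf0 <- encode_segment(rbind(x, x), cfg, params, attention = FALSE)
  ref <- unlist(lapply(encode_channel(x, cfg, params), function(m)
    as.vector(m)))
  expect_equal(unname(nf0$Z[1, ]), ref)
})

test_that("feature lengths follow the valid-convolution pooling formula", {
  cfg <- encoder_config(128)  # pool 32/32
  F_r <- emognn:::encoder_feature_lengths(cfg, 512L)
  S <- kernel_lengths(cfg)
  expect_identical(F_r, as.integer((512 - S + 1 - 32) %/% 32 + 1))
  expect_identical(emognn:::encoder_width(cfg, 512L), 9L * sum(F_r))
  expect_error(emognn:::encoder_feature_lengths(cfg, 80L), "too short")
})

test_that("attention weights normalize and outputs stay finite", {
  set.seed(54)
  cfg <- encoder_config(32, pool_len = 8, pool_stride = 8)
  params <- emognn:::init_encoder_params(cfg, 96)
  for (i in 1:20) {
    x <- matrix(rnorm(3 * 96) * 10^runif(1, -3, 3), 3)
    fwd <- emognn:::encoder_forward(x, cfg, params, keep_cache = TRUE)
    expect_true(all(is.finite(fwd$Z)))
    for (cc in fwd$cache)
      expect_equal(rowSums(cc$W), rep(1, 3), tolerance = 1e-6)
  }
  # scaling the input by alpha shifts pre-attention features by 2 log alpha
  x <- matrix(rnorm(2 * 96), 2)
  cfg_exact <- encoder_config(32, pool_len = 8, pool_stride = 8,
                              log_floor = 1e-300)
  f1 <- emognn:::encoder_forward(x, cfg_exact, params, keep_cache = TRUE)
  f2 <- emognn:::encoder_forward(3 * x, cfg_exact, params,
                                 keep_cache = TRUE)
  for (r in 1:3)
    expect_equal(f2$cache[[r]]$G, f1$cache[[r]]$G + 2 * log(3),
                 tolerance = 1e-9)
})

test_that("encoder analytic gradients match finite differences", {
  set.seed(55)
  C <- 2; T_len <- 64
  cfg <- emognn_config(32, variants = "PLV", h1 = 4, h2 = 3,
                       pool_len = 8, pool_stride = 8)
  params <- emognn:::init_model_params(cfg, C, T_len)
  A <- matrix(c(1, 0.4, 0.4, 1), 2)
  an <- list(PLV = list(normalize_adjacency(A), normalize_adjacency(A)))
  x <- matrix(rnorm(C * T_len), C)
  y <- 2L
  theta <- unlist(params, use.names = FALSE)
  fw <- emognn:::forward_segment(params, x, an, cfg, keep_cache = TRUE)
  g <- unlist(emognn:::backward_segment(params, fw$cache, y, cfg),
              use.names = FALSE)
  loss_fn <- function(th) {
    p <- utils::relist(th, params)
    model_loss(y, emognn:::forward_segment(p, x, an, cfg)$logits)
  }
  n_enc <- length(unlist(params$encoder))
  idx <- c(sample(n_enc, 40), n_enc + sample(length(theta) - n_enc, 60))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps; up <- loss_fn(tp)
    tp[i] <- tp[i] - 2 * eps
    (up - loss_fn(tp)) / (2 * eps)
  }, 0)
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-6)
  expect_lt(max(rel), 1e-4)
})
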