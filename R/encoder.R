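# Node-feature encoder: parallel multi-scale 1D temporal convolutions whose
# squared, average-pooled, log-transformed outputs give per-channel power
# features, modulated by a per-scale kernel-attention softmax.  All kernels
# and projection vectors are shared across channels.

#' Encoder configuration
#'
#' Kernel lengths follow the sampling rate: scale r uses kernels of
#' `round(0.5^r * fs)` samples, giving half-, quarter- and eighth-second
#' filters by default.  Each scale holds `kernels_per_scale` learned filters
#' of that one length.
#'
#' @param fs sampling rate in Hz.
#' @param n_scales number of temporal scales (default 3).
#' @param kernels_per_scale number of learned filters per scale (default 9).
#' @param pool_len,pool_stride average-pooling window and stride in samples;
#'   default `round(fs/4)` for both (non-overlapping quarter-second power
#'   bins).
#' @param log_floor additive floor inside the logarithm, for numerical
#'   stability on silent inputs.
#' @param kernel_len optional explicit kernel lengths (one per scale),
#'   overriding the sampling-rate rule; mainly for toy examples.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(fs, n_scales = 3L, kernels_per_scale = 9L,
                           pool_len = NULL, pool_stride = NULL,
                           log_floor = 1e-6, kernel_len = NULL) {
  stopifnot(fs > 0, n_scales >= 1, kernels_per_scale >= 1, log_floor > 0)
  if (is.null(pool_len)) pool_len <- round_half_up(fs / 4)
  if (is.null(pool_stride)) pool_stride <- pool_len
  stopifnot(pool_len >= 1, pool_stride >= 1)
  cfg <- structure(
    list(fs = fs, n_scales = as.integer(n_scales),
         kernels_per_scale = as.integer(kernels_per_scale),
         pool_len = as.integer(pool_len),
         pool_stride = as.integer(pool_stride),
         log_floor = log_floor, kernel_len = kernel_len),
    class = "encoder_config")
  if (any(kernel_lengths(cfg) < 1))
    stop("kernel length rounds below 1 sample at the finest scale; ",
         "increase fs")
  cfg
}

#' Kernel lengths per temporal scale
#'
#' @param cfg an [encoder_config()].
#' @return Integer vector of kernel lengths in samples, one per scale:
#'   `round(0.5^r * fs)` (half away from zero), e.g. `c(64, 32, 16)` at
#'   128 Hz.
#' @export
kernel_lengths <- function(cfg) {
  if (!is.null(cfg$kernel_len)) return(as.integer(cfg$kernel_len))
  as.integer(round_half_up(0.5^seq_len(cfg$n_scales) * cfg$fs))
}

# Pooled feature length per scale for input length T, with validation.
encoder_feature_lengths <- function(cfg, T_len) {
  S <- kernel_lengths(cfg)
  L <- T_len - S + 1L
  if (any(L < 1L))
    stop(sprintf("input too short for convolution: need T >= %d samples",
                 max(S)))
  F_r <- (L - cfg$pool_len) %/% cfg$pool_stride + 1L
  if (any(F_r < 1L))
    stop(sprintf("input too short for pooling: need T >= %d samples",
                 max(S) + cfg$pool_len - 1L))
  as.integer(F_r)
}

# Total per-channel feature width SK = K * sum(F_r).
encoder_width <- function(cfg, T_len) {
  cfg$kernels_per_scale * sum(encoder_feature_lengths(cfg, T_len))
}

# Random encoder parameters (caller controls the RNG state).
init_encoder_params <- function(cfg, T_len, attention = TRUE) {
  S <- kernel_lengths(cfg)
  F_r <- encoder_feature_lengths(cfg, T_len)
  K <- cfg$kernels_per_scale
  kernels <- lapply(S, function(s)
    matrix(stats::rnorm(s * K, sd = sqrt(2 / s)), s, K))
  if (attention)
    list(kernels = kernels,
         q = lapply(F_r, function(f) stats::rnorm(f, sd = 0.1)))
  else list(kernels = kernels)
}

# im2col index cache: matrix of indices such that x[idx] is the L x S
# sliding-window matrix.
.idx_cache <- new.env(parent = emptyenv())
conv_index <- function(T_len, S) {
  key <- paste0(T_len, "_", S)
  idx <- .idx_cache[[key]]
  if (is.null(idx)) {
    L <- T_len - S + 1L
    idx <- outer(seq_len(L), 0L:(S - 1L), `+`)
    .idx_cache[[key]] <- idx
  }
  idx
}

# Stacked-channel im2col indices into a C x T matrix (column-major): block c
# holds rows (c-1)*L + 1..L, so data[idx_big] is the (C*L) x S matrix of all
# channels' sliding windows.
conv_index_stacked <- function(C, T_len, S) {
  key <- paste0("s", C, "_", T_len, "_", S)
  idx <- .idx_cache[[key]]
  if (is.null(idx)) {
    base <- (conv_index(T_len, S) - 1L) * C
    L <- nrow(base)
    idx <- base[rep(seq_len(L), times = C), , drop = FALSE] +
      rep(seq_len(C), each = L)
    dim(idx) <- NULL   # plain vector: avoids matrix-index dispatch
    .idx_cache[[key]] <- idx
  }
  idx
}

pool_matrix_cache <- new.env(parent = emptyenv())
pool_matrix <- function(L, len, stride) {
  key <- paste(L, len, stride, sep = "_")
  P <- pool_matrix_cache[[key]]
  if (is.null(P)) {
    F_r <- (L - len) %/% stride + 1L
    P <- matrix(0, F_r, L)
    for (f in seq_len(F_r))
      P[f, ((f - 1L) * stride + 1L):((f - 1L) * stride + len)] <- 1 / len
    pool_matrix_cache[[key]] <- P
  }
  P
}

#' Encode one channel into per-scale power features
#'
#' For each scale and kernel: valid (no padding) 1D convolution, element-wise
#' square, average pooling, then `log(. + log_floor)`.  This is the
#' pre-attention representation; see [kernel_attention()].
#'
#' @param x numeric vector, one channel's samples.
#' @param cfg an [encoder_config()].
#' @param params encoder parameters (element `kernels`: one
#'   length-by-K matrix per scale).
#' @return A list with one K x F_r feature matrix per scale (rows = kernels).
#' @export
encode_channel <- function(x, cfg, params) {
  T_len <- length(x)
  S <- kernel_lengths(cfg)
  F_r <- encoder_feature_lengths(cfg, T_len)
  lapply(seq_along(S), function(r) {
    Xc <- matrix(x[conv_index(T_len, S[r])], ncol = S[r])
    U <- Xc %*% params$kernels[[r]]          # L x K
    P <- pool_matrix(nrow(U), cfg$pool_len, cfg$pool_stride)
    t(log(P %*% U^2 + cfg$log_floor))        # K x F_r
  })
}

#' Kernel attention over one scale's feature matrix
#'
#' Each kernel's feature row is scored by its normalized scalar projection
#' onto a trained direction `q`; a softmax over the K scores gives the
#' weights that rescale the rows.
#'
#' @param Z K x F feature matrix (one channel, one scale).
#' @param q projection vector of length F; must be nonzero.
#' @return List with `scores` (length-K projections), `weights` (softmax,
#'   sums to 1) and `weighted` (the rescaled K x F matrix).
#' @export
kernel_attention <- function(Z, q) {
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("attention projection vector is zero")
  scores <- as.numeric(Z %*% (q / nq))
  w <- softmax(scores)
  list(scores = scores, weights = w, weighted = Z * w)
}

# Pooling bookkeeping for the stacked (C*L) x K representation.  For the
# common stride == len case pooling is a grouped block mean (rowsum); the
# general case falls back to a per-channel pooling-matrix multiply.
pool_plan <- function(C, L, F_r, len, stride) {
  key <- paste("plan", C, L, F_r, len, stride, sep = "_")
  pl <- pool_matrix_cache[[key]]
  if (is.null(pl)) {
    if (stride == len) {
      keep <- as.vector(outer(seq_len(F_r * len), (seq_len(C) - 1L) * L,
                              `+`))
      grp <- rep(seq_len(C * F_r), each = len)
      pl <- list(block = TRUE, keep = keep, grp = grp, len = len)
    } else {
      pl <- list(block = FALSE, P = pool_matrix(L, len, stride))
    }
    pool_matrix_cache[[key]] <- pl
  }
  pl
}

pool_stacked <- function(V, C, L, F_r, pl) {
  if (pl$block) {
    K <- ncol(V)
    # rows of V[keep, ] come in contiguous runs of len per pooled bin
    matrix(.colSums(matrix(V[pl$keep, , drop = FALSE], nrow = pl$len),
                    pl$len, C * F_r * K) / pl$len,
           nrow = C * F_r, ncol = K)
  } else {
    M <- matrix(0, C * F_r, ncol(V))
    for (c in seq_len(C))
      M[((c - 1L) * F_r + 1L):(c * F_r), ] <-
        pl$P %*% V[((c - 1L) * L + 1L):(c * L), , drop = FALSE]
    M
  }
}

unpool_stacked <- function(dM, C, L, F_r, pl) {
  K <- ncol(dM)
  dV <- matrix(0, C * L, K)
  if (pl$block) {
    dV[pl$keep, ] <- dM[pl$grp, , drop = FALSE] / pl$len
  } else {
    tP <- t(pl$P)
    for (c in seq_len(C))
      dV[((c - 1L) * L + 1L):(c * L), ] <-
        tP %*% dM[((c - 1L) * F_r + 1L):(c * F_r), , drop = FALSE]
  }
  dV
}

# Reshape the stacked (C*F) x K feature matrix into the flattened C x (K*F)
# block (kernel index fastest within each feature), and back.
stack_to_rows <- function(G, C, F_r, K) {
  arr <- array(G, dim = c(F_r, C, K))
  t(matrix(aperm(arr, c(3L, 1L, 2L)), K * F_r, C))
}

rows_to_stack <- function(B, C, F_r, K) {
  arr <- array(t(B), dim = c(K, F_r, C))
  matrix(aperm(arr, c(2L, 3L, 1L)), C * F_r, K)
}

# Sliding-window (im2col) matrices for all scales; depends on the data
# only, so training precomputes this once per segment and reuses it across
# epochs.
encoder_precompute <- function(data, cfg) {
  C <- nrow(data); T_len <- ncol(data)
  lapply(kernel_lengths(cfg), function(s)
    matrix(data[conv_index_stacked(C, T_len, s)],
           nrow = C * (T_len - s + 1L), ncol = s))
}

# Full encoder forward for a C x T matrix, with cache for backprop.
# Flattening order per channel: scales in order, kernel index fastest.
encoder_forward <- function(data, cfg, params, attention = TRUE,
                            keep_cache = FALSE, xbig = NULL) {
  C <- nrow(data); T_len <- ncol(data)
  S <- kernel_lengths(cfg)
  F_r <- encoder_feature_lengths(cfg, T_len)
  K <- cfg$kernels_per_scale
  blocks <- vector("list", length(S))
  cache <- if (keep_cache) vector("list", length(S))
  for (r in seq_along(S)) {
    L <- T_len - S[r] + 1L
    Xbig <- if (!is.null(xbig)) xbig[[r]] else
      matrix(data[conv_index_stacked(C, T_len, S[r])],
             nrow = C * L, ncol = S[r])
    U <- Xbig %*% params$kernels[[r]]       # (C*L) x K
    pl <- pool_plan(C, L, F_r[r], cfg$pool_len, cfg$pool_stride)
    M <- pool_stacked(U * U, C, L, F_r[r], pl)
    G <- log(M + cfg$log_floor)             # (C*F_r) x K
    if (attention) {
      q <- params$q[[r]]
      nq <- sqrt(sum(q^2))
      if (nq == 0) stop("attention projection vector is zero")
      qhat <- q / nq
      Gq <- G * rep(qhat, times = C)
      # rows come in contiguous runs of F_r per channel
      scores <- matrix(.colSums(matrix(Gq, nrow = F_r[r]),
                                F_r[r], C * K), C, K)
      E <- exp(scores - apply(scores, 1L, max))
      W <- E / rowSums(E)
      blocks[[r]] <- stack_to_rows(G * W[rep(seq_len(C), each = F_r[r]), ,
                                         drop = FALSE],
                                   C, F_r[r], K)
    } else {
      W <- NULL; qhat <- NULL; nq <- NULL
      blocks[[r]] <- stack_to_rows(G, C, F_r[r], K)
    }
    if (keep_cache)
      cache[[r]] <- list(Xbig = Xbig, U = U, M = M, G = G, W = W,
                         qhat = qhat, nq = nq, pl = pl, L = L, F = F_r[r])
  }
  Z <- do.call(cbind, blocks)
  rownames(Z) <- rownames(data)
  list(Z = Z, F_r = F_r, cache = cache)
}

# Backward pass: dZ is C x SK; returns gradients for kernels and q.
encoder_backward <- function(dZ, cache, cfg, params, attention = TRUE) {
  C <- nrow(dZ)
  K <- cfg$kernels_per_scale
  g_kernels <- vector("list", length(cache))
  g_q <- if (attention) vector("list", length(cache))
  col0 <- 0L
  for (r in seq_along(cache)) {
    cc <- cache[[r]]
    F_r <- cc$F; L <- cc$L
    chan <- rep(seq_len(C), each = F_r)
    dZp <- rows_to_stack(dZ[, col0 + seq_len(K * F_r), drop = FALSE],
                         C, F_r, K)          # (C*F) x K, pre-reweighting
    if (attention) {
      Wbig <- cc$W[chan, , drop = FALSE]
      dwv <- dZp * cc$G
      dw <- matrix(.colSums(matrix(dwv, nrow = F_r), F_r, C * K), C, K)
      dG <- dZp * Wbig
      wdw <- rowSums(cc$W * dw)
      dQ <- cc$W * (dw - wdw)                               # C x K
      dQbig <- dQ[chan, , drop = FALSE]
      # dqhat[f] = sum_{c,k} G[(c,f),k] * dQ[c,k]
      dqhat <- .rowSums(matrix(rowSums(cc$G * dQbig), F_r, C), F_r, C)
      dG <- dG + dQbig * rep(cc$qhat, times = C)
      g_q[[r]] <- (dqhat - cc$qhat * sum(cc$qhat * dqhat)) / cc$nq
    } else {
      dG <- dZp
    }
    dM <- dG / (cc$M + cfg$log_floor)
    dV <- unpool_stacked(dM, C, L, F_r, cc$pl)
    dU <- 2 * cc$U * dV
    g_kernels[[r]] <- crossprod(cc$Xbig, dU)
    col0 <- col0 + K * F_r
  }
  if (attention) list(kernels = g_kernels, q = g_q)
  else list(kernels = g_kernels)
}

#' Encode a segment into graph node features
#'
#' Applies the shared multi-scale encoder to every channel and concatenates
#' the (attention-weighted) per-scale feature blocks into one row per
#' channel.
#'
#' @param segment an [eeg_trial()]/segment, or a plain C x T matrix.
#' @param cfg an [encoder_config()].
#' @param params encoder parameters (`kernels`, and `q` when `attention`).
#' @param attention apply kernel attention (default `TRUE`); when `FALSE`
#'   the unweighted features are concatenated unchanged.
#' @return A list with `Z` (C x SK node-feature matrix), `F_r` (per-scale
#'   feature lengths) and `sk` (total width).
#' @export
encode_segment <- function(segment, cfg, params, attention = TRUE) {
  data <- if (inherits(segment, "eeg_trial")) segment$data else
    as.matrix(segment)
  out <- encoder_forward(data, cfg, params, attention = attention)
  list(Z = out$Z, F_r = out$F_r, sk = ncol(out$Z))
}
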