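# Full model: encoder -> per-variant two-stage GCN -> fusion classifier,
# trained by backpropagation with Adam.  Parameters live in a nested list
# mirrored by a flat vector for the optimizer.

#' Model architecture configuration
#'
#' @param fs sampling rate of the segments the model will see (Hz).
#' @param labels the two class labels, positive class first; `NULL` to take
#'   the sorted unique labels of the training data at fit time.
#' @param variants connectivity variants to fuse, a non-empty subset of
#'   `c("Cor", "Coh", "PLV", "PLI")`; each variant gets its own
#'   task-adjacency pair and graph branch.
#' @param band frequency band (Hz) for the spectral/phase variants.
#' @param welch_seg_s,welch_overlap Welch settings for the coherence
#'   variant.
#' @param h1,h2 hidden sizes of the per-variant and fusion MLPs.
#' @param kernel_attention,adjacency_attention attention toggles (ablation
#'   switches); disabling removes the corresponding parameters.
#' @param cnn_block when `FALSE`, raw segment samples are used as node
#'   features instead of the temporal-convolution encoding.
#' @param gcn_block when `FALSE`, node features are flattened straight into
#'   the fusion MLP, bypassing the graph stage (no adjacency needed).
#' @param pool_len,pool_stride,log_floor encoder options, see
#'   [encoder_config()].
#' @return A list of class `emognn_config`.
#' @export
emognn_config <- function(fs, labels = NULL,
                          variants = c("Cor", "Coh", "PLV", "PLI"),
                          band = c(4, 45), welch_seg_s = 1,
                          welch_overlap = 0.5, h1 = 64L, h2 = 16L,
                          kernel_attention = TRUE,
                          adjacency_attention = TRUE,
                          cnn_block = TRUE, gcn_block = TRUE,
                          pool_len = NULL, pool_stride = NULL,
                          log_floor = 1e-6) {
  variants <- if (length(variants))
    unique(match.arg(variants, c("Cor", "Coh", "PLV", "PLI"),
                     several.ok = TRUE)) else character()
  if (gcn_block && !length(variants))
    stop("variant subset must be non-empty unless the GCN block is disabled")
  if (!is.null(labels) && length(labels) != 2L)
    stop("`labels` must give exactly two class labels")
  structure(list(
    fs = fs, labels = labels, variants = variants,
    conn = stats::setNames(lapply(variants, function(v)
      conn_spec(v, band = band, welch_seg_s = welch_seg_s,
                welch_overlap = welch_overlap)), variants),
    encoder = if (cnn_block)
      encoder_config(fs, pool_len = pool_len, pool_stride = pool_stride,
                     log_floor = log_floor),
    h1 = as.integer(h1), h2 = as.integer(h2),
    kernel_attention = kernel_attention,
    adjacency_attention = adjacency_attention,
    cnn_block = cnn_block, gcn_block = gcn_block),
    class = "emognn_config")
}

#' Optimization settings
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size in segments.
#' @param max_epochs epoch cap for one training run.
#' @param patience early stopping: training halts once the validation loss
#'   has failed to improve for more than `patience` consecutive epochs
#'   (`patience = 0` stops at the first non-improvement).
#' @param fine_tune_epochs epochs of continued training on the pooled
#'   training + validation data after inner-loop model selection.
#' @param lambda squared-L2 regularization weight (weights only, not
#'   biases).
#' @param seed master seed driving weight initialization, batch order and
#'   fold shuffling.
#' @return A list of class `emognn_control`.
#' @export
emognn_control <- function(learning_rate = 1e-3, batch_size = 64L,
                           max_epochs = 6L, patience = 2L,
                           fine_tune_epochs = 3L, lambda = 1e-4,
                           seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, patience < max_epochs, fine_tune_epochs >= 0,
            lambda >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 lambda = lambda, seed = as.integer(seed)),
            class = "emognn_control")
}

# TRUE for weight entries, FALSE for biases; mirrors the parameter nesting.
weight_flags <- function(x, name = "") {
  if (is.list(x)) {
    nms <- names(x) %||% rep("", length(x))
    out <- lapply(seq_along(x), function(i)
      weight_flags(x[[i]], if (nzchar(nms[i])) nms[i] else name))
    names(out) <- names(x)
    out
  } else {
    rep(!(name %in% c("b1", "b2")), length(x))
  }
}

# Feature width of the node representation.
model_sk <- function(config, T_len) {
  if (config$cnn_block) encoder_width(config$encoder, T_len) else T_len
}

# Random initialization of all trainable tensors (caller seeds the RNG).
init_model_params <- function(config, C, T_len) {
  sk <- model_sk(config, T_len)
  if (config$gcn_block && sk %% 4L != 0L)
    stop(sprintf("node-feature width SK = %d must be divisible by 4", sk))
  p <- list()
  if (config$cnn_block)
    p$encoder <- init_encoder_params(config$encoder, T_len,
                                     attention = config$kernel_attention)
  if (config$gcn_block) {
    h <- sk %/% 2L; q4 <- sk %/% 4L
    mk <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    p$branches <- stats::setNames(lapply(config$variants, function(v) {
      b <- list(W_l1 = mk(sk, h, sqrt(2 / sk)),
                W_l2 = mk(sk, h, sqrt(2 / sk)),
                W_as = mk(h, q4, sqrt(2 / h)))
      if (config$adjacency_attention) {
        b$P_l1 <- stats::rnorm(sk, sd = 0.01)
        b$P_l2 <- stats::rnorm(sk, sd = 0.01)
      }
      b
    }), config$variants)
    p$mlp1 <- stats::setNames(lapply(config$variants, function(v)
      list(W1 = mk(config$h1, C * h, sqrt(2 / (C * h))),
           b1 = numeric(config$h1),
           W2 = mk(2L, config$h1, sqrt(2 / config$h1)),
           b2 = numeric(2L))), config$variants)
    in2 <- 2L * length(config$variants)
  } else {
    in2 <- C * sk
  }
  p$mlp2 <- list(W1 = matrix(stats::rnorm(config$h2 * in2,
                                          sd = sqrt(2 / in2)),
                             config$h2, in2),
                 b1 = numeric(config$h2),
                 W2 = matrix(stats::rnorm(2L * config$h2,
                                          sd = sqrt(2 / config$h2)),
                             2L, config$h2),
                 b2 = numeric(2L))
  p
}

# Forward pass for one C x T data matrix.  adj_norms: per variant, a list
# of the two normalized adjacencies (NULL when the GCN block is off).
forward_segment <- function(params, data, adj_norms, config,
                            keep_cache = FALSE, xbig = NULL) {
  if (config$cnn_block) {
    enc <- encoder_forward(data, config$encoder, params$encoder,
                           attention = config$kernel_attention,
                           keep_cache = keep_cache, xbig = xbig)
    Z <- enc$Z
  } else {
    enc <- NULL
    Z <- data
  }
  if (config$gcn_block) {
    V <- length(config$variants)
    branches <- vector("list", V)
    mlp1s <- vector("list", V)
    svec <- numeric(2L * V)
    for (v in seq_len(V)) {
      nm <- config$variants[v]
      br <- branch_forward_full(Z, adj_norms[[nm]][[1]],
                                adj_norms[[nm]][[2]],
                                params$branches[[nm]],
                                attention = config$adjacency_attention)
      f <- c(as.vector(br$Zb_l1), as.vector(br$Zb_l2))
      m1 <- mlp_forward(f, params$mlp1[[nm]])
      s <- softmax(m1$out)
      svec[(2L * v - 1L):(2L * v)] <- s
      branches[[v]] <- br
      mlp1s[[v]] <- c(m1, list(f = f, s = s))
    }
  } else {
    branches <- NULL; mlp1s <- NULL
    svec <- as.vector(Z)
  }
  m2 <- mlp_forward(svec, params$mlp2)
  out <- list(logits = m2$out)
  if (keep_cache)
    out$cache <- list(enc = enc, Z = Z, branches = branches, mlp1s = mlp1s,
                      svec = svec, m2 = m2)
  out
}

# Backward pass for one segment; returns gradients mirroring the parameter
# structure.  y is the true class index (1 or 2).
backward_segment <- function(params, cache, y, config) {
  g <- list()
  p_out <- softmax(cache$m2$out)
  dz <- p_out
  dz[y] <- dz[y] - 1
  m2 <- cache$m2
  dh <- as.numeric(crossprod(params$mlp2$W2, dz)) * (m2$a1 > 0)
  g$mlp2 <- list(W1 = outer(dh, cache$svec), b1 = dh,
                 W2 = outer(dz, m2$h), b2 = dz)
  dsvec <- as.numeric(crossprod(params$mlp2$W1, dh))
  if (config$gcn_block) {
    C <- nrow(cache$Z)
    q4 <- ncol(cache$Z) %/% 4L
    dZ <- matrix(0, C, ncol(cache$Z))
    g$branches <- vector("list", length(config$variants))
    g$mlp1 <- vector("list", length(config$variants))
    names(g$branches) <- names(g$mlp1) <- config$variants
    for (v in seq_along(config$variants)) {
      nm <- config$variants[v]
      m1 <- cache$mlp1s[[v]]
      s <- m1$s
      ds <- dsvec[(2L * v - 1L):(2L * v)]
      do <- s * (ds - sum(ds * s))
      dh1 <- as.numeric(crossprod(params$mlp1[[nm]]$W2, do)) * (m1$a1 > 0)
      g$mlp1[[nm]] <- list(W1 = outer(dh1, m1$f), b1 = dh1,
                           W2 = outer(do, m1$h), b2 = do)
      df <- as.numeric(crossprod(params$mlp1[[nm]]$W1, dh1))
      dZb1 <- matrix(df[seq_len(C * q4)], C, q4)
      dZb2 <- matrix(df[C * q4 + seq_len(C * q4)], C, q4)
      bb <- branch_backward(dZb1, dZb2, cache$branches[[v]]$cache,
                            params$branches[[nm]],
                            attention = config$adjacency_attention)
      gb <- list(W_l1 = bb$W_l1, W_l2 = bb$W_l2, W_as = bb$W_as)
      if (config$adjacency_attention) {
        gb$P_l1 <- as.numeric(bb$P_l1)
        gb$P_l2 <- as.numeric(bb$P_l2)
      }
      g$branches[[nm]] <- gb
      dZ <- dZ + bb$dZ
    }
  } else {
    dZ <- matrix(dsvec, nrow(cache$Z), ncol(cache$Z))
  }
  if (config$cnn_block)
    g$encoder <- encoder_backward(dZ, cache$enc$cache, config$encoder,
                                  params$encoder,
                                  attention = config$kernel_attention)
  # order fields to mirror init_model_params
  ord <- intersect(c("encoder", "branches", "mlp1", "mlp2"), names(g))
  g[ord]
}

# Per-segment backward pass that defers the large weight-gradient matrix
# products to batch level: returns the small gradients (encoder, projection
# vectors, biases) plus the per-segment factor matrices whose stacked
# cross-products give the big weight gradients.  Standard path only
# (cnn_block and gcn_block enabled).
backward_segment_stacks <- function(params, cache, y, config) {
  p_out <- softmax(cache$m2$out)
  dz <- p_out
  dz[y] <- dz[y] - 1
  m2 <- cache$m2
  dh <- as.numeric(crossprod(params$mlp2$W2, dz)) * (m2$a1 > 0)
  dsvec <- as.numeric(crossprod(params$mlp2$W1, dh))
  C <- nrow(cache$Z)
  q4 <- ncol(cache$Z) %/% 4L
  dZ <- matrix(0, C, ncol(cache$Z))
  V <- length(config$variants)
  vs <- vector("list", V)
  names(vs) <- config$variants
  for (v in seq_along(config$variants)) {
    nm <- config$variants[v]
    m1 <- cache$mlp1s[[v]]
    s <- m1$s
    ds <- dsvec[(2L * v - 1L):(2L * v)]
    do <- s * (ds - sum(ds * s))
    dh1 <- as.numeric(crossprod(params$mlp1[[nm]]$W2, do)) * (m1$a1 > 0)
    df <- as.numeric(crossprod(params$mlp1[[nm]]$W1, dh1))
    dZb1 <- matrix(df[seq_len(C * q4)], C, q4)
    dZb2 <- matrix(df[C * q4 + seq_len(C * q4)], C, q4)
    core <- branch_backward_core(dZb1, dZb2, cache$branches[[v]]$cache,
                                 params$branches[[nm]],
                                 attention = config$adjacency_attention)
    dZ <- dZ + core$dZ
    vs[[nm]] <- list(dP1 = core$dP1, dP2 = core$dP2,
                     dA2rb = rbind(core$dA2_1, core$dA2_2),
                     Mrb = rbind(cache$branches[[v]]$cache$M1,
                                 cache$branches[[v]]$cache$M2),
                     P_l1 = core$P_l1, P_l2 = core$P_l2,
                     f = m1$f, dh1 = dh1, h1h = m1$h, do = do)
  }
  enc <- encoder_backward(dZ, cache$enc$cache, config$encoder,
                          params$encoder,
                          attention = config$kernel_attention)
  list(enc = enc, Z = cache$Z, vs = vs,
       svec = cache$svec, dz = dz, dh = dh, m2h = m2$h)
}

# Combine a batch of backward_segment_stacks results into one full gradient
# structure (summed over the batch), using stacked matrix products.
assemble_batch_grads <- function(params, config, store) {
  B <- length(store)
  g <- list()
  g$encoder <- Reduce(add_grads, lapply(store, `[[`, "enc"))
  Zstack <- do.call(rbind, lapply(store, `[[`, "Z"))
  g$branches <- vector("list", length(config$variants))
  g$mlp1 <- vector("list", length(config$variants))
  names(g$branches) <- names(g$mlp1) <- config$variants
  for (nm in config$variants) {
    vs <- lapply(store, function(s) s$vs[[nm]])
    gb <- list(
      W_l1 = crossprod(Zstack, do.call(rbind, lapply(vs, `[[`, "dP1"))),
      W_l2 = crossprod(Zstack, do.call(rbind, lapply(vs, `[[`, "dP2"))),
      W_as = crossprod(do.call(rbind, lapply(vs, `[[`, "Mrb")),
                       do.call(rbind, lapply(vs, `[[`, "dA2rb"))))
    if (config$adjacency_attention) {
      gb$P_l1 <- Reduce(`+`, lapply(vs, `[[`, "P_l1"))
      gb$P_l2 <- Reduce(`+`, lapply(vs, `[[`, "P_l2"))
    }
    g$branches[[nm]] <- gb
    DH1 <- do.call(rbind, lapply(vs, `[[`, "dh1"))     # B x h1
    DO <- do.call(rbind, lapply(vs, `[[`, "do"))       # B x 2
    g$mlp1[[nm]] <- list(
      W1 = crossprod(DH1, do.call(rbind, lapply(vs, `[[`, "f"))),
      b1 = colSums(DH1),
      W2 = crossprod(DO, do.call(rbind, lapply(vs, `[[`, "h1h"))),
      b2 = colSums(DO))
  }
  DH <- do.call(rbind, lapply(store, `[[`, "dh"))      # B x h2
  DZ <- do.call(rbind, lapply(store, `[[`, "dz"))      # B x 2
  g$mlp2 <- list(
    W1 = crossprod(DH, do.call(rbind, lapply(store, `[[`, "svec"))),
    b1 = colSums(DH),
    W2 = crossprod(DZ, do.call(rbind, lapply(store, `[[`, "m2h"))),
    b2 = colSums(DZ))
  ord <- intersect(c("encoder", "branches", "mlp1", "mlp2"), names(g))
  g[ord]
}

# Fast counterpart of utils::relist for the nested parameter list: refills
# the skeleton's leaves from a flat vector in unlist order.
fast_relist <- function(theta, skel) {
  pos <- 0L
  rec <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- rec(x[[i]])
      return(x)
    }
    n <- length(x)
    v <- theta[pos + seq_len(n)]
    pos <<- pos + n
    dim(v) <- dim(x)
    v
  }
  rec(skel)
}

add_grads <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (i in seq_along(b))
      a[[i]] <- add_grads(if (i <= length(a)) a[[i]] else NULL, b[[i]])
    a
  } else a + b
}

# Mean logits / loss / accuracy over a list of data matrices (no caching).
evaluate_segments <- function(params, xs, ys, adj_norms, config, lambda,
                              theta = NULL, wmask = NULL, xbl = NULL) {
  logits <- t(vapply(seq_along(xs), function(i)
    forward_segment(params, xs[[i]], adj_norms, config,
                    xbig = xbl[[i]])$logits, numeric(2L)))
  ce <- model_loss(ys, logits)
  pen <- if (!is.null(theta) && lambda > 0)
    lambda * sum(theta[wmask]^2) else 0
  pred <- max.col(logits, ties.method = "first")
  list(logits = logits, loss = ce + pen, acc = mean(pred == ys))
}

# Core Adam training loop.  xs/ys: training data matrices and class
# indices; val_xs/val_ys optional validation set driving early stopping and
# best-epoch selection.  `init` continues from existing parameters.
fit_core <- function(xs, ys, adj_norms, config, control,
                     val_xs = NULL, val_ys = NULL, init = NULL,
                     n_epochs = NULL, early_stop = TRUE) {
  n <- length(xs)
  params <- init %||% init_model_params(config, nrow(xs[[1]]),
                                        ncol(xs[[1]]))
  xbl <- if (config$cnn_block)
    lapply(xs, encoder_precompute, cfg = config$encoder)
  val_xbl <- if (config$cnn_block && !is.null(val_xs))
    lapply(val_xs, encoder_precompute, cfg = config$encoder)
  theta <- unlist(params, use.names = FALSE)
  wmask <- unlist(weight_flags(params), use.names = FALSE)
  skel <- params
  m_t <- numeric(length(theta)); v_t <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lambda <- control$lambda
  n_epochs <- n_epochs %||% control$max_epochs
  history <- vector("list", n_epochs)
  best <- list(acc = -Inf, acc_loss = Inf, loss = Inf, params = params,
               epoch = 0L)
  wait <- 0L
  has_val <- !is.null(val_xs) && length(val_xs) > 0
  epochs_run <- 0L
  for (epoch in seq_len(n_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    use_batched <- config$cnn_block && config$gcn_block
    for (b0 in seq.int(1L, n, by = control$batch_size)) {
      idx <- ord[b0:min(b0 + control$batch_size - 1L, n)]
      bl <- 0
      if (use_batched) {
        store <- vector("list", length(idx))
        for (j in seq_along(idx)) {
          i <- idx[j]
          fw <- forward_segment(params, xs[[i]], adj_norms, config,
                                keep_cache = TRUE, xbig = xbl[[i]])
          bl <- bl + model_loss(ys[i], fw$logits)
          store[[j]] <- backward_segment_stacks(params, fw$cache, ys[i],
                                                config)
        }
        acc_g <- assemble_batch_grads(params, config, store)
      } else {
        acc_g <- NULL
        for (i in idx) {
          fw <- forward_segment(params, xs[[i]], adj_norms, config,
                                keep_cache = TRUE, xbig = xbl[[i]])
          bl <- bl + model_loss(ys[i], fw$logits)
          acc_g <- add_grads(acc_g, backward_segment(params, fw$cache,
                                                     ys[i], config))
        }
      }
      gvec <- unlist(acc_g, use.names = FALSE) / length(idx)
      if (lambda > 0) gvec <- gvec + 2 * lambda * theta * wmask
      if (!all(is.finite(gvec)) || !is.finite(bl))
        stop(sprintf("training diverged (non-finite loss/gradient) at epoch %d",
                     epoch))
      step <- step + 1L
      m_t <- beta1 * m_t + (1 - beta1) * gvec
      v_t <- beta2 * v_t + (1 - beta2) * gvec^2
      mhat <- m_t / (1 - beta1^step)
      vhat <- v_t / (1 - beta2^step)
      theta <- theta - control$learning_rate * mhat / (sqrt(vhat) + eps)
      params <- fast_relist(theta, skel)
      ep_loss <- ep_loss + bl
    }
    train_loss <- ep_loss / n + if (lambda > 0)
      lambda * sum(theta[wmask]^2) else 0
    epochs_run <- epoch
    if (has_val) {
      ev <- evaluate_segments(params, val_xs, val_ys, adj_norms, config,
                              lambda, theta, wmask, xbl = val_xbl)
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = train_loss,
                                     val_loss = ev$loss, val_acc = ev$acc)
      if (ev$acc > best$acc ||
          (ev$acc == best$acc && ev$loss < best$acc_loss)) {
        best$acc <- ev$acc; best$acc_loss <- ev$loss
        best$params <- params; best$epoch <- epoch
      }
      if (ev$loss < best$loss - 1e-12) {
        best$loss <- ev$loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (early_stop && wait > control$patience) break
      }
    } else {
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = train_loss,
                                     val_loss = NA_real_,
                                     val_acc = NA_real_)
      best$params <- params; best$epoch <- epoch
    }
  }
  list(params = best$params, final_params = params,
       history = do.call(rbind, history[!vapply(history, is.null,
                                                logical(1))]),
       best_epoch = best$epoch,
       val_acc = if (has_val) best$acc else NA_real_,
       val_loss = if (has_val) best$acc_loss else NA_real_,
       epochs_run = epochs_run)
}

seg_data <- function(s) if (inherits(s, "eeg_trial")) s$data else
  as.matrix(s)
seg_labels <- function(segs) vapply(segs, function(s) s$label, "")

adj_norm_list <- function(adjacency, config) {
  if (!config$gcn_block) return(NULL)
  if (inherits(adjacency, "task_adjacency"))
    adjacency <- stats::setNames(list(adjacency), adjacency$method)
  missing <- setdiff(config$variants, names(adjacency))
  if (length(missing))
    stop("no task adjacency supplied for variant(s): ",
         paste(missing, collapse = ", "))
  stats::setNames(lapply(config$variants, function(v)
    adjacency[[v]]$norm), config$variants)
}

#' Fit the EEG graph-attention classifier
#'
#' Trains the full model -- multi-scale temporal-convolution node encoding
#' with kernel attention, per-variant two-stage graph convolution over the
#' class-conditioned adjacency pair with adjacency attention, and the fused
#' MLP classifier -- on a set of labelled segments, by Adam on the
#' cross-entropy + squared-L2 objective.
#'
#' Task adjacencies are estimated from the *training* segments only (or can
#' be supplied precomputed); validation segments drive early stopping and
#' best-epoch selection.
#'
#' @param x list of labelled training segments (see [segment_trial()]).
#' @param config an [emognn_config()]; its `fs` must match the data.
#' @param control an [emognn_control()].
#' @param adjacency optional named list of [build_task_adjacency()] results,
#'   one per variant; built from `x` when `NULL`.
#' @param validation optional list of labelled segments for early stopping.
#' @return An object of class `emognn` with elements `params`, `config`,
#'   `control`, `adjacency`, `labels`, `history`, `val_acc`, `n_params`.
#' @seealso [predict.emognn()], [emognn_cv()]
#' @export
emognn <- function(x, config, control = emognn_control(),
                   adjacency = NULL, validation = NULL) {
  stopifnot(inherits(config, "emognn_config"),
            inherits(control, "emognn_control"))
  labels <- config$labels %||% sort(unique(seg_labels(x)))
  ys <- match(seg_labels(x), labels)
  if (anyNA(ys)) stop("segment labels outside the configured label set")
  if (config$gcn_block && is.null(adjacency))
    adjacency <- stats::setNames(lapply(config$variants, function(v)
      build_task_adjacency(x, config$conn[[v]], labels = labels)),
      config$variants)
  an <- adj_norm_list(adjacency, config)
  xs <- lapply(x, seg_data)
  val_xs <- if (!is.null(validation)) lapply(validation, seg_data)
  val_ys <- if (!is.null(validation)) match(seg_labels(validation), labels)
  fit <- with_seed(control$seed,
                   fit_core(xs, ys, an, config, control,
                            val_xs = val_xs, val_ys = val_ys))
  structure(list(params = fit$params, config = config, control = control,
                 adjacency = adjacency, labels = labels,
                 history = fit$history, best_epoch = fit$best_epoch,
                 epochs_run = fit$epochs_run, val_acc = fit$val_acc,
                 val_loss = fit$val_loss,
                 n_params = length(unlist(fit$params, use.names = FALSE)),
                 C = nrow(xs[[1]]), T_len = ncol(xs[[1]]),
                 sk = model_sk(config, ncol(xs[[1]]))),
            class = "emognn")
}

#' Predict classes or probabilities for new segments
#'
#' @param object a fitted [emognn()] model.
#' @param newdata list of segments (or C x T matrices).
#' @param type `"class"` (default), `"prob"` or `"logits"`.
#' @param ... unused.
#' @return A character vector of labels, or an n x 2 matrix (columns named
#'   by the class labels).
#' @export
predict.emognn <- function(object, newdata,
                           type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  an <- adj_norm_list(object$adjacency, object$config)
  logits <- t(vapply(newdata, function(s)
    forward_segment(object$params, seg_data(s), an,
                    object$config)$logits, numeric(2L)))
  colnames(logits) <- object$labels
  if (type == "logits") return(logits)
  probs <- exp(log_softmax_rows(logits))
  if (type == "prob") return(probs)
  object$labels[max.col(probs, ties.method = "first")]
}

#' @export
print.emognn <- function(x, ...) {
  cat("EEG graph-attention classifier\n")
  cat(sprintf("  classes: %s (positive) vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %d channels, %d samples/segment, node width SK = %d\n",
              x$C, x$T_len, x$sk))
  cat(sprintf("  variants: %s\n",
              if (x$config$gcn_block)
                paste(x$config$variants, collapse = ", ") else
                "(GCN block disabled)"))
  cat(sprintf("  %d trainable parameters; trained %d epochs (best %d)\n",
              x$n_params, x$epochs_run, x$best_epoch))
  if (!is.na(x$val_acc))
    cat(sprintf("  validation accuracy %.3f\n", x$val_acc))
  invisible(x)
}

#' @export
summary.emognn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.emognn <- function(object, ...) unlist(object$params)

#' @export
plot.emognn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = ylim, ...)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", legend = c("training", "validation"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param x a fitted `emognn` model or a nested parameter list.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(x) {
  p <- if (inherits(x, "emognn")) x$params else x
  length(unlist(p, use.names = FALSE))
}
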