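# Two-stage graph propagation over the pair of class-conditioned graphs:
# class-specific first GCN layers, adjacency attention fusing the two class
# graphs, and a shared second GCN layer.

#' One graph convolution layer
#'
#' Computes `relu(A %*% Z %*% W)`: each node's features are mixed with its
#' graph neighbors' (weighted by the normalized adjacency) and projected.
#'
#' @param A C x C (normalized) adjacency.
#' @param Z C x F_in node features.
#' @param W F_in x F_out weight matrix.
#' @return C x F_out matrix.
#' @export
gcn_layer <- function(A, Z, W) {
  A <- as.matrix(A); Z <- as.matrix(Z); W <- as.matrix(W)
  if (ncol(A) != nrow(Z) || ncol(Z) != nrow(W))
    stop(sprintf(
      "dimension mismatch: A is %dx%d, Z is %dx%d, W is %dx%d",
      nrow(A), ncol(A), nrow(Z), ncol(Z), nrow(W), ncol(W)))
  relu(A %*% Z %*% W)
}

#' All ordered pairwise concatenations of node features
#'
#' @param Z C x F node-feature matrix.
#' @return A C x C x 2F array whose (a, b, ) slice is `c(Z[a, ], Z[b, ])`.
#' @export
pairwise_concat <- function(Z) {
  Z <- as.matrix(Z)
  C <- nrow(Z); F_d <- ncol(Z)
  arr <- array(0, dim = c(C, C, 2L * F_d))
  for (a in seq_len(C)) for (b in seq_len(C))
    arr[a, b, ] <- c(Z[a, ], Z[b, ])
  arr
}

#' Adjacency attention scores from the two class branches
#'
#' Each class branch scores every channel pair by a logistic-squashed linear
#' function of the concatenated pair features,
#' `score_l[a, b] = logistic(c(Z_l[a, ], Z_l[b, ]) %*% P_l)`, and the final
#' gate is the sum of the two class scores (entries in (0, 2); exactly 1
#' everywhere when both projection vectors are zero).
#'
#' @param Z_l1,Z_l2 C x h first-layer outputs of the two class branches.
#' @param P_l1,P_l2 projection vectors of length 2h.
#' @return List with `score_l1`, `score_l2` (C x C in (0, 1)) and `ascore`
#'   (their sum).
#' @export
adjacency_attention <- function(Z_l1, Z_l2, P_l1, P_l2) {
  score_one <- function(Z, P) {
    h <- ncol(Z)
    stopifnot(length(P) == 2L * h)
    u <- as.numeric(Z %*% P[seq_len(h)])
    v <- as.numeric(Z %*% P[(h + 1L):(2L * h)])
    logistic(outer(u, v, `+`))
  }
  s1 <- score_one(as.matrix(Z_l1), P_l1)
  s2 <- score_one(as.matrix(Z_l2), P_l2)
  list(score_l1 = s1, score_l2 = s2, ascore = s1 + s2)
}

# Full branch forward with cache for backprop.  adjs = ascore * A_norm
# (element-wise), with no re-normalization.
branch_forward_full <- function(Z, norm_l1, norm_l2, bp,
                                attention = TRUE) {
  A1_1 <- norm_l1 %*% (Z %*% bp$W_l1)
  A1_2 <- norm_l2 %*% (Z %*% bp$W_l2)
  Z1 <- relu(A1_1)
  Z2 <- relu(A1_2)
  if (attention) {
    att <- adjacency_attention(Z1, Z2, bp$P_l1, bp$P_l2)
    adjs1 <- att$ascore * norm_l1
    adjs2 <- att$ascore * norm_l2
  } else {
    att <- NULL
    adjs1 <- norm_l1
    adjs2 <- norm_l2
  }
  M1 <- adjs1 %*% Z1
  M2 <- adjs2 %*% Z2
  A2_1 <- M1 %*% bp$W_as
  A2_2 <- M2 %*% bp$W_as
  list(Zb_l1 = relu(A2_1), Zb_l2 = relu(A2_2),
       cache = list(Z = Z, A1_1 = A1_1, A1_2 = A1_2,
                    Z1 = Z1, Z2 = Z2, att = att, adjs1 = adjs1,
                    adjs2 = adjs2, M1 = M1, M2 = M2,
                    A2_1 = A2_1, A2_2 = A2_2,
                    norm_l1 = norm_l1, norm_l2 = norm_l2))
}

# Shared part of the branch backward pass: everything except the large
# weight-gradient matrix products.  Returns the pre-projection gradients
# dP_l (with dW_l = Z^T dP_l) and dA2 blocks (with dW_as = M^T dA2),
# plus the projection-vector gradients and dZ.
branch_backward_core <- function(dZb1, dZb2, cache, bp, attention = TRUE) {
  cc <- cache
  dA2_1 <- dZb1 * (cc$A2_1 > 0)
  dA2_2 <- dZb2 * (cc$A2_2 > 0)
  dM1 <- tcrossprod(dA2_1, bp$W_as)
  dM2 <- tcrossprod(dA2_2, bp$W_as)
  dadjs1 <- tcrossprod(dM1, cc$Z1)
  dadjs2 <- tcrossprod(dM2, cc$Z2)
  dZ1 <- crossprod(cc$adjs1, dM1)
  dZ2 <- crossprod(cc$adjs2, dM2)
  g_P1 <- g_P2 <- NULL
  if (attention) {
    dascore <- dadjs1 * cc$norm_l1 + dadjs2 * cc$norm_l2
    h <- ncol(cc$Z1)
    back_att <- function(score, Z, P) {
      dO <- dascore * score * (1 - score)
      du <- rowSums(dO)
      dv <- colSums(dO)
      list(gP = c(crossprod(Z, du), crossprod(Z, dv)),
           dZ = outer(du, P[seq_len(h)]) + outer(dv, P[(h + 1L):(2L * h)]))
    }
    b1 <- back_att(cc$att$score_l1, cc$Z1, bp$P_l1)
    b2 <- back_att(cc$att$score_l2, cc$Z2, bp$P_l2)
    g_P1 <- b1$gP; g_P2 <- b2$gP
    dZ1 <- dZ1 + b1$dZ
    dZ2 <- dZ2 + b2$dZ
  }
  dA1_1 <- dZ1 * (cc$A1_1 > 0)
  dA1_2 <- dZ2 * (cc$A1_2 > 0)
  dP1 <- crossprod(cc$norm_l1, dA1_1)      # dW_l1 = Z^T dP1
  dP2 <- crossprod(cc$norm_l2, dA1_2)
  dZ <- tcrossprod(dP1, bp$W_l1) + tcrossprod(dP2, bp$W_l2)
  list(dP1 = dP1, dP2 = dP2, dA2_1 = dA2_1, dA2_2 = dA2_2,
       P_l1 = g_P1, P_l2 = g_P2, dZ = dZ)
}

# Backward through one branch with fully materialized weight gradients.
branch_backward <- function(dZb1, dZb2, cache, bp, attention = TRUE) {
  core <- branch_backward_core(dZb1, dZb2, cache, bp, attention)
  cc <- cache
  list(W_l1 = crossprod(cc$Z, core$dP1),
       W_l2 = crossprod(cc$Z, core$dP2),
       W_as = crossprod(cc$M1, core$dA2_1) + crossprod(cc$M2, core$dA2_2),
       P_l1 = core$P_l1, P_l2 = core$P_l2, dZ = core$dZ)
}

#' Two-stage graph aggregation over one task-adjacency pair
#'
#' First-stage GCN layers propagate the node features through each class's
#' normalized graph separately (`W_l1`, `W_l2`); adjacency attention built
#' from the two first-stage outputs gates both graphs element-wise; a shared
#' second-stage layer (`W_as`) produces the C x SK/4 branch outputs.
#'
#' @param node_features C x SK matrix (see [encode_segment()]).
#' @param task_adj a [build_task_adjacency()] result.
#' @param params branch parameters: `W_l1`, `W_l2` (SK x SK/2), `W_as`
#'   (SK/2 x SK/4) and, when `attention`, `P_l1`, `P_l2` (length SK).
#' @param attention apply adjacency attention (default `TRUE`); when
#'   `FALSE` the normalized adjacencies are used unmodulated.
#' @return List with `Zb_l1`, `Zb_l2` (C x SK/4), the modulated adjacencies
#'   `adjs_l1`, `adjs_l2`, and the attention `ascore` (or `NULL`).
#' @export
branch_forward <- function(node_features, task_adj, params,
                           attention = TRUE) {
  Z <- if (is.list(node_features)) node_features$Z else
    as.matrix(node_features)
  out <- branch_forward_full(Z, task_adj$norm[[1]], task_adj$norm[[2]],
                             params, attention = attention)
  list(Zb_l1 = out$Zb_l1, Zb_l2 = out$Zb_l2,
       adjs_l1 = out$cache$adjs1, adjs_l2 = out$cache$adjs2,
       ascore = if (attention) out$cache$att$ascore)
}
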