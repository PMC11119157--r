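# Fusion of per-variant graph features and the final classifier.

mlp_forward <- function(x, m) {
  a1 <- as.numeric(m$W1 %*% x + m$b1)
  h <- relu(a1)
  list(a1 = a1, h = h, out = as.numeric(m$W2 %*% h + m$b2))
}

#' Fuse per-variant graph features and classify
#'
#' For each connectivity variant, the two class-branch outputs are
#' concatenated and flattened into a vector of length C*SK/2, passed through
#' that variant's first-stage MLP, and softmaxed into a two-class score
#' pair.  The score pairs of all variants are concatenated and passed
#' through the shared second-stage MLP, yielding the final two-class logits.
#'
#' @param branch_outputs named list, one element per variant, each a list
#'   with C x SK/4 matrices `Zb_l1` and `Zb_l2` (see [branch_forward()]).
#' @param params list with `mlp1` (per-variant `W1`, `b1`, `W2`, `b2`) and
#'   `mlp2` (shared `W1`, `b1`, `W2`, `b2`).
#' @return List with `logits` (length 2), `variant_scores` (2 x V softmaxed
#'   first-stage outputs) and `fused` (the concatenated MLP2 input).
#' @export
fuse_and_classify <- function(branch_outputs, params) {
  if (!length(branch_outputs)) stop("variant set is empty")
  V <- length(branch_outputs)
  scores <- matrix(0, 2L, V,
                   dimnames = list(NULL, names(branch_outputs)))
  for (v in seq_len(V)) {
    bo <- branch_outputs[[v]]
    f <- c(as.vector(bo$Zb_l1), as.vector(bo$Zb_l2))
    o <- mlp_forward(f, params$mlp1[[v]])$out
    scores[, v] <- softmax(o)
  }
  fused <- as.vector(scores)
  list(logits = mlp_forward(fused, params$mlp2)$out,
       variant_scores = scores, fused = fused)
}

log_softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  Z - m - log(rowSums(exp(Z - m)))
}

#' Training loss: cross-entropy plus squared-L2 regularization
#'
#' Mean cross-entropy of the softmaxed logits against the true labels, plus
#' `lambda` times the sum of squared weight parameters (biases excluded when
#' a full parameter structure is given).
#'
#' @param true integer class indices (1 or 2), or a factor/character vector
#'   whose sorted unique values define the two classes.
#' @param logits n x 2 matrix of logits (or a length-2 vector for n = 1).
#' @param lambda regularization weight, `>= 0`.
#' @param params parameters to penalize: a numeric vector (all entries
#'   penalized), or a full nested model parameter list (weights only).
#' @return Scalar loss.
#' @export
model_loss <- function(true, logits, lambda = 0, params = NULL) {
  stopifnot(lambda >= 0)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (!is.numeric(true)) true <- as.integer(factor(true))
  stopifnot(all(true %in% c(1L, 2L)), length(true) == nrow(logits),
            all(is.finite(logits)))
  ls <- log_softmax_rows(logits)
  ce <- -mean(ls[cbind(seq_along(true), true)])
  pen <- 0
  if (lambda > 0 && !is.null(params)) {
    w <- if (is.numeric(params)) params else {
      th <- unlist(params, use.names = FALSE)
      th[unlist(weight_flags(params), use.names = FALSE)]
    }
    pen <- lambda * sum(w^2)
  }
  ce + pen
}
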