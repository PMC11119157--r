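test_that("gcn_layer propagates and rectifies", {
  Z <- matrix(c(0.5, 1, 2, 0.1, 3, 0.7), 2)
  expect_equal(gcn_layer(diag(2), Z, diag(3)), Z)
  z <- matrix(c(1, -2), 1)
  W <- matrix(c(1, 1, -1, 2), 2)
  expect_equal(gcn_layer(matrix(1), z, W),
               matrix(pmax(0, as.numeric(z %*% W)), 1))
  set.seed(61)
  for (i in 1:100) {
    C <- sample(2:5, 1); Fi <- sample(2:6, 1); Fo <- sample(2:6, 1)
    A <- matrix(runif(C * C), C); A <- (A + t(A)) / 2
    Z <- matrix(rnorm(C * Fi), C)
    W <- matrix(rnorm(Fi * Fo), Fi)
    expect_equal(gcn_layer(A, Z, W), naive_gcn(A, Z, W),
                 tolerance = 1e-7)
  }
  expect_error(gcn_layer(diag(2), matrix(0, 3, 2), diag(2)),
               "dimension mismatch.*2x2.*3x2")
})

test_that("pairwise concatenation lays out ordered node pairs", {
  z <- matrix(c(1, 2, 3), 1)
  pc1 <- pairwise_concat(z)
  expect_identical(dim(pc1), c(1L, 1L, 6L))
  expect_equal(pc1[1, 1, ], c(1, 2, 3, 1, 2, 3))
  set.seed(62)
  Z <- matrix(rnorm(12), 3)
  pc <- pairwise_concat(Z)
  for (a in 1:3) for (b in 1:3) {
    expect_equal(pc[a, b, ], c(Z[a, ], Z[b, ]))
    expect_equal(pc[a, b, 1:4], pc[a, 1, 1:4])  # first half fixed by a
  }
})

test_that("adjacency attention is a summed logistic pair gate", {
  set.seed(63)
  Z1 <- matrix(rnorm(8), 2); Z2 <- matrix(rnorm(8), 2)
  # zero projections: every score 0.5, total gate exactly 1
  att0 <- adjacency_attention(Z1, Z2, rep(0, 8), rep(0, 8))
  expect_equal(att0$ascore, matrix(1, 2, 2))
  # duplicated branch doubles the score
  P <- rnorm(8)
  attd <- adjacency_attention(Z1, Z1, P, P)
  expect_equal(attd$ascore, 2 * attd$score_l1)
  # hand-computed logistic oracle
  att <- adjacency_attention(Z1, Z2, P, rnorm(8))
  sig <- function(x) 1 / (1 + exp(-x))
  for (a in 1:2) for (b in 1:2)
    expect_equal(att$score_l1[a, b],
                 sig(sum(c(Z1[a, ], Z1[b, ]) * P)))
  expect_true(all(att$ascore > 0 & att$ascore < 2))
})

test_that("branch_forward matches a straight-line oracle and keeps shapes", {
  set.seed(64)
  C <- 3; sk <- 8
  mkA <- function() {
    A <- matrix(runif(C * C), C); A <- (A + t(A)) / 2; diag(A) <- 1
    A
  }
  ta <- list(norm = list(normalize_adjacency(mkA()),
                         normalize_adjacency(mkA())))
  for (i in 1:30) {
    bp <- list(W_l1 = matrix(rnorm(sk * sk / 2), sk),
               W_l2 = matrix(rnorm(sk * sk / 2), sk),
               W_as = matrix(rnorm(sk / 2 * sk / 4), sk / 2),
               P_l1 = rnorm(sk), P_l2 = rnorm(sk))
    Z <- matrix(rnorm(C * sk), C)
    out <- branch_forward(Z, ta, bp)
    ref <- naive_branch(Z, ta$norm[[1]], ta$norm[[2]], bp)
    expect_equal(out$Zb_l1, ref$Zb_l1, tolerance = 1e-7)
    expect_equal(out$Zb_l2, ref$Zb_l2, tolerance = 1e-7)
    expect_equal(out$ascore, ref$ascore, tolerance = 1e-7)
    expect_identical(dim(out$Zb_l1), c(3L, 2L))
    expect_identical(dim(out$Zb_l2), c(3L, 2L))
    expect_true(all(out$ascore > 0 & out$ascore < 2))
    expect_true(all(abs(out$adjs_l1) <= 2 * max(ta$norm[[1]]) + 1e-12))
  }
})

test_that("disabling adjacency attention leaves the graphs unmodulated", {
  set.seed(65)
  C <- 3; sk <- 8
  A <- matrix(runif(C * C), C); A <- (A + t(A)) / 2; diag(A) <- 1
  ta <- list(norm = list(normalize_adjacency(A), normalize_adjacency(A)))
  bp <- list(W_l1 = matrix(rnorm(sk * sk / 2), sk),
             W_l2 = matrix(rnorm(sk * sk / 2), sk),
             W_as = matrix(rnorm(sk / 2 * sk / 4), sk / 2),
             P_l1 = rep(0, sk), P_l2 = rep(0, sk))
  Z <- matrix(rnorm(C * sk), C)
  off <- branch_forward(Z, ta, bp, attention = FALSE)
  expect_equal(off$adjs_l1, ta$norm[[1]])
  expect_null(off$ascore)
  # zero projection vectors give ascore == 1, i.e. the same unmodulated
  # adjacencies through the attention path
  on0 <- branch_forward(Z, ta, bp, attention = TRUE)
  expect_equal(on0$adjs_l1, ta$norm[[1]])
  expect_equal(on0$Zb_l1, off$Zb_l1)
})

test_that("identity graphs mix no information across channels", {
  set.seed(66)
  C <- 4; sk <- 16
  ta <- list(norm = list(diag(C), diag(C)))
  bp <- list(W_l1 = matrix(rnorm(sk * sk / 2), sk),
             W_l2 = matrix(rnorm(sk * sk / 2), sk),
             W_as = matrix(rnorm(sk / 2 * sk / 4), sk / 2),
             P_l1 = rep(0, sk), P_l2 = rep(0, sk))
  Z <- matrix(rnorm(C * sk), C)
  base <- branch_forward(Z, ta, bp)
  Z2 <- Z
  Z2[3, ] <- rnorm(sk)                     # perturb one channel only
  out <- branch_forward(Z2, ta, bp)
  expect_equal(out$Zb_l1[-3, ], base$Zb_l1[-3, ])
  expect_false(isTRUE(all.equal(out$Zb_l1[3, ], base$Zb_l1[3, ])))
})

test_that("branch_forward is channel-permutation equivariant", {
  set.seed(67)
  C <- 5; sk <- 8
  mkA <- function() {
    A <- matrix(runif(C * C), C); A <- (A + t(A)) / 2; diag(A) <- 1
    normalize_adjacency(A)
  }
  N1 <- mkA(); N2 <- mkA()
  bp <- list(W_l1 = matrix(rnorm(sk * sk / 2), sk),
             W_l2 = matrix(rnorm(sk * sk / 2), sk),
             W_as = matrix(rnorm(sk / 2 * sk / 4), sk / 2),
             P_l1 = rnorm(sk), P_l2 = rnorm(sk))
  Z <- matrix(rnorm(C * sk), C)
  base <- branch_forward(Z, list(norm = list(N1, N2)), bp)
  for (i in 1:5) {
    p <- sample(C)
    out <- branch_forward(Z[p, ], list(norm = list(N1[p, p], N2[p, p])), bp)
    expect_equal(out$Zb_l1, base$Zb_l1[p, ], tolerance = 1e-10)
    expect_equal(out$Zb_l2, base$Zb_l2[p, ], tolerance = 1e-10)
  }
})
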