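test_that("attention weights are a probability distribution over tokens", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(2:6, 1); dh <- sample(1:8, 1)
    att <- attention_head(rnorm(dh), matrix(rnorm(m * dh), m, dh),
                          matrix(rnorm(m * dh), m, dh))
    expect_true(all(att$weights >= 0))
    expect_equal(sum(att$weights), 1, tolerance = 1e-12)
  }
})

test_that("softmax reduces to uniform for identical keys and matches the closed form", {
  K <- matrix(rep(c(1, -2, 0.5), 4), 4, 3, byrow = TRUE)
  att <- attention_head(c(0.3, -0.1, 0.9), K, matrix(rnorm(12), 4, 3))
  expect_equal(att$weights, rep(0.25, 4), tolerance = 1e-14)

  # two tokens with scaled scores (10, 0): weight e^10 / (e^10 + 1)
  att2 <- attention_head(1, matrix(c(10, 0), 2, 1), matrix(c(1, 2), 2, 1))
  expect_equal(att2$weights[1], exp(10) / (exp(10) + 1), tolerance = 1e-12)
  expect_gt(att2$weights[1], 0.9999)

  # adding a constant to every pre-softmax score leaves weights unchanged
  att3 <- attention_head(1, matrix(c(10, 0) + 7, 2, 1), matrix(c(1, 2), 2, 1))
  expect_equal(att3$weights, att2$weights, tolerance = 1e-12)
})

test_that("key projection obeys the relu/dropout contract", {
  d <- 6
  tokens <- matrix(abs(rnorm(4 * d)), 4, d)
  K <- project_keys(tokens, diag(d), mode = "eval")$K
  expect_equal(K, tokens)  # relu is the identity on nonnegative input

  tokens[2, ] <- 0
  K2 <- project_keys(tokens, matrix(rnorm(d * d), d, d), mode = "eval")$K
  expect_true(all(K2[2, ] == 0))

  W <- matrix(rnorm(d * d), d, d)
  a <- project_keys(tokens, W, 0.4, mode = "eval")$K
  b <- project_keys(tokens, W, 0.4, mode = "eval")$K
  expect_identical(a, b)
  expect_error(project_keys(matrix(NaN, 2, d), W), "nonfinite")
})

test_that("head splitting is exact and validated", {
  x <- matrix(rnorm(3 * 8), 3, 8)
  blocks <- split_heads(x, 2)
  expect_length(blocks, 2)
  expect_identical(ncol(blocks[[1]]), 4L)
  expect_identical(do.call(cbind, blocks), x)
  expect_identical(split_heads(x, 1)[[1]], x)
  expect_error(split_heads(matrix(0, 2, 10), 4), "not divisible")
})

test_that("H = 1 fusion equals the single-head computation exactly", {
  d <- 8; m <- 4; n <- 5
  params <- fusion_params(d, H = 1, dropout_rate = 0, seed = 3)
  B <- array(rnorm(n * m * d), c(n, m, d))
  bundle <- stack_representations(list(clinical = matrix(B[, 1, ], n, d),
                                       mRNA = matrix(B[, 2, ], n, d),
                                       miRNA = matrix(B[, 3, ], n, d),
                                       CNV = matrix(B[, 4, ], n, d)))
  fused <- multihead_fuse(bundle, params, mode = "eval")
  for (p in 1:n) {
    toks <- matrix(unclass(bundle)[p, , ], m, d)
    K <- project_keys(toks, params$W, mode = "eval")$K
    att <- attention_head(params$q, K, toks)
    expect_identical(fused$M[p, ], att$output)
    expect_identical(as.vector(fused$weights[p, 1, ]), att$weights)
  }
  # eval-mode repetition is bit-identical
  expect_identical(multihead_fuse(bundle, params, mode = "eval")$Y, fused$Y)
})

test_that("toy d=4 H=2 fusion matches a hand-executed forward pass", {
  # All parameters and tokens fixed by hand; the oracle below recomputes the
  # pipeline with scalar arithmetic, independently of the package internals.
  d <- 4; H <- 2; m <- 2
  W <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                0, 0, 1, 0,
                0, 0, 0, 1), 4, 4)  # identity keeps keys equal to tokens
  q <- c(0.5, -0.25, 1, 0.75)
  w_last <- c(1, 2, -1, 0.5)
  t1 <- c(0.2, 0.4, 0.1, 0.3)
  t2 <- c(0.9, 0.1, 0.5, 0.7)
  params <- fusion_params(d, H, dropout_rate = 0, seed = 1)
  params$W <- W; params$q <- q; params$w_last <- w_last
  bundle <- stack_representations(list(mRNA = matrix(t1, 1), miRNA = matrix(t2, 1)))
  out <- multihead_fuse(bundle, params, mode = "eval")

  # oracle: keys = tokens (identity W, nonnegative tokens)
  sc <- function(tok, qh) sum(tok * qh) / sqrt(2)
  # head 1 uses dims 1:2, head 2 dims 3:4
  s1 <- c(sc(t1[1:2], q[1:2]), sc(t2[1:2], q[1:2]))
  s2 <- c(sc(t1[3:4], q[3:4]), sc(t2[3:4], q[3:4]))
  a1 <- exp(s1) / sum(exp(s1))
  a2 <- exp(s2) / sum(exp(s2))
  head1 <- a1[1] * t1[1:2] + a1[2] * t2[1:2]
  head2 <- a2[1] * t1[3:4] + a2[2] * t2[3:4]
  M <- c(head1, head2)
  Y <- sum(M * w_last)

  expect_equal(as.vector(out$weights[1, 1, ]), a1, tolerance = 1e-12)
  expect_equal(as.vector(out$weights[1, 2, ]), a2, tolerance = 1e-12)
  expect_equal(out$M[1, ], M, tolerance = 1e-12)
  expect_equal(out$Y, Y, tolerance = 1e-12)
})

test_that("fusion is equivariant to permuting the modality tokens", {
  d <- 8; m <- 4; n <- 6
  params <- fusion_params(d, H = 2, dropout_rate = 0, seed = 5)
  B <- array(rnorm(n * m * d), c(n, m, d))
  perm <- c(3, 1, 4, 2)
  Bp <- B[, perm, ]
  class(B) <- "representation_bundle"; attr(B, "modality_order") <- letters[1:4]
  class(Bp) <- "representation_bundle"; attr(Bp, "modality_order") <- letters[perm]
  f1 <- multihead_fuse(B, params, mode = "eval")
  f2 <- multihead_fuse(Bp, params, mode = "eval")
  expect_equal(f2$weights, f1$weights[, , perm, drop = FALSE], tolerance = 1e-12)
  expect_equal(f2$M, f1$M, tolerance = 1e-12)
})

test_that("the vectorized training path agrees with the reference fusion", {
  d <- 12; n <- 7
  params <- fusion_params(d, H = 3, dropout_rate = 0, seed = 8)
  reps <- list(clinical = matrix(rnorm(n * d), n, d),
               mRNA = matrix(rnorm(n * d), n, d),
               miRNA = matrix(rnorm(n * d), n, d),
               CNV = matrix(rnorm(n * d), n, d))
  bundle <- stack_representations(reps)
  ref <- multihead_fuse(bundle, params, mode = "eval")
  fast <- privsurv:::fuse_forward(bundle, params, mode = "eval")
  expect_equal(fast$M, ref$M, tolerance = 1e-12)
  expect_equal(fast$A, ref$weights, tolerance = 1e-12)
})

test_that("gradients flow to W and q and match finite differences", {
  d <- 6; n <- 4
  params <- fusion_params(d, H = 2, dropout_rate = 0, seed = 2)
  reps <- list(mRNA = matrix(rnorm(n * d), n, d),
               miRNA = matrix(rnorm(n * d), n, d),
               CNV = matrix(rnorm(n * d), n, d))
  bundle <- stack_representations(reps)
  v <- rnorm(d)
  loss_fn <- function(p) {
    fw <- privsurv:::fuse_forward(bundle, p, mode = "eval")
    mean(fw$M %*% v)
  }
  fw <- privsurv:::fuse_forward(bundle, params, mode = "eval")
  d_F <- matrix(v, n, d, byrow = TRUE)  # per-sample grad of per-patient loss
  bk <- privsurv:::fuse_backward(fw, params, d_F)
  expect_true(any(bk$g_W != 0) && any(bk$g_q != 0))
  eps <- 1e-6
  for (probe in list(c(2, 3), c(5, 1))) {
    p2 <- params; p2$W[probe[1], probe[2]] <- p2$W[probe[1], probe[2]] + eps
    num <- (loss_fn(p2) - loss_fn(params)) / eps
    expect_equal(bk$g_W[probe[1], probe[2]], num, tolerance = 1e-4)
  }
  p3 <- params; p3$q[4] <- p3$q[4] + eps
  expect_equal(bk$g_q[4], (loss_fn(p3) - loss_fn(params)) / eps, tolerance = 1e-4)
})

test_that("attention weights export as a tidy table", {
  params <- fusion_params(8, H = 2, dropout_rate = 0, seed = 1)
  reps <- list(clinical = matrix(rnorm(24), 3, 8), mRNA = matrix(rnorm(24), 3, 8))
  out <- multihead_fuse(stack_representations(reps), params, mode = "eval")
  tab <- attention_weights_table(out$weights, patient_ids = c("a", "b", "c"),
                                 modalities = c("clinical", "mRNA"))
  expect_identical(nrow(tab), 3L * 2L * 2L)
  sums <- tapply(tab$weight, list(tab$patient_id, tab$head), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
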