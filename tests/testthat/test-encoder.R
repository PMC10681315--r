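# Encoder forward pass: closed-form examples, invariants, and equivalence
# with the scalar-loop reference on small instances.

rand_instance <- function(seed, b = 5L, t_ = 4L, c_ = 4L, L = 2L) {
  set.seed(seed)
  net <- rand_small_dsmn(seed)
  net$R <- matrix(rbinom(nrow(net$S) * t_, 1L, 0.4), nrow(net$S), t_)
  mode(net$R) <- "integer"
  incid <- build_branch_incidences(net)
  branches <- names(which(incid$enabled))
  params <- init_params(nrow(net$S), t_, c_, seed = seed)
  for (nm in names(params)) {
    if (grepl("^B|^b", nm)) {
      params[[nm]] <- matrix(rnorm(length(params[[nm]]), 0, 0.2),
                             nrow(params[[nm]]), ncol(params[[nm]]))
    }
  }
  list(params = params, data = encoder_data(incid, net$R, branches),
       cfg = list(L = L, branches = branches, conv = FALSE, masked = FALSE))
}

test_that("self-gating unit computes X * sigmoid(XP + B)", {
  X <- matrix(c(2, -2), 1, 2)
  expect_equal(self_gate(X, matrix(0, 2, 2), c(0, 0)), matrix(c(1, -1), 1, 2))
  expect_equal(self_gate(matrix(0, 3, 2), matrix(rnorm(4), 2, 2), rnorm(2)),
               matrix(0, 3, 2))
  set.seed(5)
  X <- matrix(rnorm(12), 3, 4); P <- matrix(rnorm(16), 4, 4); B <- rnorm(4)
  want <- X
  for (i in 1:3) for (j in 1:4) {
    want[i, j] <- X[i, j] * ssigmoid(sum(X[i, ] * P[, j]) + B[j])
  }
  expect_equal(self_gate(X, P, B), want, tolerance = 1e-10)
})

test_that("attention layer closed forms: zero degree and 1x1 instance", {
  # isolated drug: zero row in, zero row out
  out <- hypergraph_attention_layer(matrix(0, 1, 1), 0, matrix(c(3, 1), 1, 2),
                                    diag(2), c(0, 0))
  expect_equal(out, matrix(0, 1, 2))
  # b = 1 with weight 2: softmax of 1x1 is 1, relu passthrough, /2
  out2 <- hypergraph_attention_layer(matrix(2, 1, 1), 2, matrix(c(3, 0), 1, 2),
                                     diag(2), c(0, 0))
  expect_equal(out2, matrix(c(1.5, 0), 1, 2))
})

test_that("branch forward averages layers and handles an empty incidence", {
  D0 <- matrix(c(3, 0), 1, 2)
  bf <- branch_forward(matrix(2, 1, 1), 2, D0, matrix(0, 2, 2), c(0, 0),
                       diag(2), c(0, 0), L = 1L)
  # gate halves D0 (sigmoid(0) = 0.5); layer 1 = relu(1.5,0)/2
  expect_equal(bf$layers[[1]], matrix(c(1.5, 0), 1, 2))
  expect_equal(bf$layers[[2]], matrix(c(0.75, 0), 1, 2))
  expect_equal(bf$mean, (bf$layers[[1]] + bf$layers[[2]]) / 2)

  # all-zero incidence: propagated layers vanish, mean = D0x / (L+1)
  set.seed(3)
  D0 <- matrix(rnorm(8), 4, 2)
  bf0 <- branch_forward(matrix(0, 4, 4), rep(0, 4), D0,
                        matrix(rnorm(4), 2, 2), rnorm(2),
                        matrix(rnorm(4), 2, 2), rnorm(2), L = 2L)
  expect_equal(bf0$mean, bf0$layers[[1]] / 3)
})

test_that("branch attention is a proper softmax over branches", {
  set.seed(8)
  Dx <- matrix(rnorm(12), 3, 4)
  same <- list(j = Dx, p = Dx, i = Dx, u = Dx)
  res <- branch_attention(same, rnorm(4), matrix(rnorm(16), 4, 4))
  expect_equal(unname(res$omega), matrix(0.25, 3, 4))
  expect_equal(res$Ds, Dx)
  # a = 0 gives uniform weights regardless of the embeddings
  diff <- list(j = Dx, p = -Dx)
  res2 <- branch_attention(diff, rep(0, 4), matrix(rnorm(16), 4, 4))
  expect_equal(unname(res2$omega), matrix(0.5, 3, 2))
  expect_equal(rowSums(res2$omega), rep(1, 3))
  expect_error(branch_attention(list(), rep(0, 4), diag(4)), "disabled")
})

test_that("pair scores are inner products with index validation", {
  D <- rbind(c(1, 0), c(0, 1))
  M <- rbind(c(1, 0), c(0.6, 0.8))
  expect_equal(score_pairs(D, M, cbind(1L, 1L)), 1)
  expect_equal(score_pairs(D, M, cbind(2L, 1L)), 0)
  expect_equal(score_pairs(D, M, cbind(c(1L, 2L), c(2L, 2L))), c(0.6, 0.8))
  expect_error(score_pairs(D, M, cbind(3L, 1L)), "out of range")
})

test_that("encoder output matches the scalar-loop reference", {
  for (seed in c(21L, 22L, 23L)) {
    inst <- rand_instance(seed)
    got <- encoder_forward(inst$params, inst$data, inst$cfg)
    want <- ref_encoder_forward(inst$params, inst$data, inst$cfg)
    expect_equal(got$D, want$D, tolerance = 1e-8)
    expect_equal(got$M, want$M, tolerance = 1e-8)
    expect_equal(unname(got$omega), unname(want$omega), tolerance = 1e-8)
    expect_equal(rowSums(got$omega), rep(1, nrow(got$D)), tolerance = 1e-9)
  }
})

test_that("tape forward agrees with the plain forward", {
  inst <- rand_instance(33L)
  plain <- encoder_forward(inst$params, inst$data, inst$cfg)
  tape <- ad_tape()
  pt <- inst$params
  for (nm in names(pt)) pt[[nm]] <- ad_param(tape, inst$params[[nm]])
  taped <- encoder_forward(pt, inst$data, inst$cfg, ops_ad(tape))
  expect_equal(ad_value(taped$D), plain$D, tolerance = 1e-12)
  expect_equal(ad_value(taped$M), plain$M, tolerance = 1e-12)
})

test_that("zero embeddings with zero biases are a fixed point", {
  inst <- rand_instance(44L)
  p <- inst$params
  p$D0[] <- 0; p$M0[] <- 0
  for (nm in names(p)) if (grepl("^B|^b", nm)) p[[nm]][] <- 0
  out <- encoder_forward(p, inst$data, inst$cfg)
  expect_equal(out$D, matrix(0, nrow(out$D), ncol(out$D)))
  expect_equal(out$M, matrix(0, nrow(out$M), ncol(out$M)))
})

test_that("outputs stay finite for large random inputs", {
  inst <- rand_instance(55L)
  p <- inst$params
  set.seed(1)
  p$D0 <- matrix(runif(length(p$D0), -10, 10), nrow(p$D0))
  p$M0 <- matrix(runif(length(p$M0), -10, 10), nrow(p$M0))
  out <- encoder_forward(p, inst$data, inst$cfg)
  expect_true(all(is.finite(out$D)))
  expect_true(all(is.finite(out$M)))
})
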