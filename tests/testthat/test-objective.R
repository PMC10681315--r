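# Training objective: triple sampling, BPR, SSL readout/corruption, total
# loss composition, and descent on a small planted network.

test_that("triple sampling respects observed/unobserved structure", {
  R <- matrix(0L, 3, 4)
  R[1, 1] <- R[2, 2] <- R[2, 3] <- R[3, 4] <- 1L
  tr <- sample_triples(R, 200L, seed = 3L)
  expect_equal(nrow(tr), 200L)
  expect_true(all(R[tr[, c(1, 2)]] == 1L))
  expect_true(all(R[tr[, c(1, 3)]] == 0L))
  expect_equal(nrow(sample_triples(R, 0L, seed = 1L)), 0L)
  expect_identical(sample_triples(R, 50L, seed = 9L),
                   sample_triples(R, 50L, seed = 9L))

  # drug with a single non-edge always gets that negative
  R2 <- matrix(1L, 2, 3); R2[1, 3] <- 0L; R2[2, 1] <- 0L
  tr2 <- sample_triples(R2, 100L, seed = 4L)
  expect_true(all(tr2[tr2[, 1] == 1L, 3] == 3L))
  expect_true(all(tr2[tr2[, 1] == 2L, 3] == 1L))
})

test_that("negative draws are uniform over each drug's unobserved entities", {
  R <- matrix(0L, 2, 6)
  R[1, 1] <- R[2, 2] <- 1L  # drug 1 has 5 eligible negatives
  tr <- sample_triples(R, 2e4L, seed = 12L)
  j1 <- tr[tr[, 1] == 1L, 3]
  n <- length(j1)
  p <- 1 / 5
  for (e in 2:6) {
    freq <- mean(j1 == e)
    expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("BPR closed forms: tie gives ln 2, margin drives loss to zero", {
  D <- matrix(c(1, 0), 1, 2)
  M <- rbind(c(0.5, 0), c(0.5, 0))      # tied scores
  expect_equal(bpr_loss(D, M, cbind(1L, 1L, 2L), delta = 0), log(2),
               tolerance = 1e-9)
  M2 <- rbind(c(100, 0), c(-100, 0))    # huge margin
  expect_lt(bpr_loss(D, M2, cbind(1L, 1L, 2L), delta = 0), 1e-8)
  # monotone decreasing in the margin
  margins <- seq(-2, 2, by = 0.5)
  losses <- vapply(margins, function(m) {
    bpr_loss(D, rbind(c(m, 0), c(0, 0)), cbind(1L, 1L, 2L), delta = 0)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))

  # scalar-loop reference on a hand-set instance, with regularizer
  set.seed(6)
  D <- matrix(rnorm(8), 4, 2); M <- matrix(rnorm(6), 3, 2)
  tr <- cbind(c(1L, 2L, 4L), c(1L, 3L, 2L), c(2L, 1L, 3L))
  params <- list(W = matrix(rnorm(4), 2, 2))
  expect_equal(bpr_loss(D, M, tr, params = params, delta = 0.01),
               ref_bpr(D, M, tr, delta = 0.01, params = params),
               tolerance = 1e-10)
})

test_that("sub-hypergraph readout keeps weights and counts nonzero members", {
  r <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(subhypergraph_readout(r, rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 0)))[1, ],
               (r[1, ] + r[2, ]) / 2)
  expect_equal(subhypergraph_readout(r, rbind(c(2, 0, 1), c(0, 0, 0), c(0, 0, 0)))[1, ],
               (2 * r[1, ] + r[3, ]) / 2)
  # empty row yields the zero vector
  expect_equal(subhypergraph_readout(r, matrix(0, 3, 3))[2, ], c(0, 0))
  set.seed(2)
  I_x <- matrix(rpois(16, 1), 4, 4)
  D <- matrix(rnorm(12), 4, 3)
  expect_equal(subhypergraph_readout(D, I_x), ref_readout(D, I_x),
               tolerance = 1e-10)
})

test_that("corruption permutes without changing the entry multiset", {
  expect_equal(corrupt(matrix(7, 1, 1), seed = 5L), matrix(7, 1, 1))
  set.seed(10)
  S <- matrix(rnorm(20), 4, 5)
  St <- corrupt(S, seed = 2L)
  expect_equal(sort(as.vector(St)), sort(as.vector(S)))
  expect_identical(corrupt(S, seed = 2L), St)
})

test_that("SSL loss: exact ties give 2 ln 2 per drug per branch", {
  b <- 4L; c_ <- 3L
  D <- matrix(1, b, c_)           # identical drugs
  I_x <- matrix(1, b, b)          # everyone in every hyperedge
  params <- list(Psg_j = matrix(0, c_, c_), bsg_j = matrix(0, 1, c_))
  # constant embeddings + zero gates -> summaries all equal, corruption a no-op
  got <- ssl_loss(D, params, list(j = I_x), seed = 3L)
  expect_equal(got, b * 2 * log(2), tolerance = 1e-9)
  expect_gt(got, 0)
})

test_that("SSL loss matches the scalar reference and is always positive", {
  set.seed(14)
  b <- 4L; c_ <- 5L
  D <- matrix(rnorm(b * c_), b, c_)
  I_list <- list(j = matrix(rpois(16, 1), 4, 4), p = matrix(rpois(16, 2), 4, 4))
  params <- init_params(b, 3L, c_, seed = 2L)
  got <- ssl_loss(D, params, I_list, seed = 77L)
  want <- ref_ssl(D, params, I_list, seed = 77L)
  expect_equal(got, want, tolerance = 1e-8)
  expect_gt(got, 0)
})

test_that("total loss composes linearly in lambda", {
  expect_equal(total_loss(1.5, 10, 0), 1.5)
  expect_equal(total_loss(0, 3, 1), 3)
  l1 <- total_loss(2, 4, 0.2); l2 <- total_loss(2, 4, 0.4)
  expect_equal(l2 - l1, 0.2 * 4)
})

test_that("training descends and the no-SSL variant drops the auxiliary term", {
  net <- small_planted(seed = 6L)
  ctl <- hgdrug_control(dim = 8L, epochs = 30L, batch = 2000L)
  fit <- hgdrug(net, control = ctl, seed = 4L)
  tr <- fit$loss_trace
  expect_lt(tr$loss_total[nrow(tr)], tr$loss_total[1L])
  expect_true(all(is.finite(tr$loss_total)))

  fit0 <- hgdrug(net, control = hgdrug_control(dim = 8L, epochs = 5L,
                                               ablation = "no_ssl"), seed = 4L)
  expect_true(all(fit0$loss_trace$loss_ssl == 0))
})

test_that("ablation variants select the intended branches", {
  net <- small_planted(seed = 7L)
  ctl <- function(ab) hgdrug_control(dim = 6L, epochs = 2L, ablation = ab)
  expect_equal(hgdrug(net, control = ctl("frag_only"), seed = 1L)$branches,
               c("j", "p"))
  expect_equal(hgdrug(net, control = ctl("mol_only"), seed = 1L)$branches,
               c("i", "u"))
  f0 <- hgdrug(net, control = ctl("no_hyper"), seed = 1L)
  expect_equal(f0$branches, character(0))
  expect_null(f0$omega)
  fc <- hgdrug(net, control = ctl("conv"), seed = 1L)
  expect_equal(fc$branches, c("j", "p", "i", "u"))
})
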