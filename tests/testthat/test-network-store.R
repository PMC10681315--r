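# Edge-list IO, network assembly, and cross-validation folds.

test_that("edge lists are deduplicated and malformed lines are located", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("d1\te1", "d1\te1", "# comment", "d2\te2"), p)
  e <- read_edge_list(p)
  expect_equal(nrow(e), 2L)
  expect_equal(e$src, c("d1", "d2"))

  writeLines(character(0), p)
  expect_equal(nrow(read_edge_list(p)), 0L)

  writeLines(c("d1\te1", "oops"), p)
  expect_error(read_edge_list(p), "line 2")
})

test_that("assembly builds the expected matrices on a toy 4-drug network", {
  # hand-built: drugs a-b-c chain of DDIs, d isolated but in fragmentation
  task <- data.frame(src = c("a", "b"), dst = c("b", "c"))
  frag <- structure(list(
    fragments = data.frame(fragment_id = 1:2,
                           canonical_smiles = c("f1", "f2"),
                           divisible = c(TRUE, FALSE)),
    dfi = data.frame(drug_id = c("a", "b", "c", "d"),
                     fragment_id = c(1L, 1L, 2L, 2L)),
    ffi = data.frame(parent_id = 1L, child_id = 2L),
    drug_ids = c("a", "b", "c", "d")), class = "fragmentation")
  net <- assemble_dsmn(task, "DDI", fragmentation = frag)
  expect_equal(net$registries$drug, c("a", "b", "c", "d"))
  S_want <- matrix(0L, 4, 4)
  S_want[1, 2] <- S_want[2, 1] <- S_want[2, 3] <- S_want[3, 2] <- 1L
  expect_equal(unname(net$S), S_want)
  expect_identical(net$R, net$S)
  Y_want <- matrix(0L, 4, 2)
  Y_want[1, 1] <- Y_want[2, 1] <- Y_want[3, 2] <- Y_want[4, 2] <- 1L
  expect_equal(unname(net$Y), Y_want)
  expect_equal(unname(net$Z), matrix(c(0L, 0L, 1L, 0L), 2, 2))

  # drug in the task but not in the fragmentation -> zero Y row + warning
  task2 <- data.frame(src = "q", dst = "b")
  expect_warning(net2 <- assemble_dsmn(rbind(task, task2), "DDI",
                                       fragmentation = frag), "zero")
  expect_equal(sum(net2$Y[match("q", net2$registries$drug), ]), 0L)
})

test_that("bipartite task with a drug-drug side network fills W and S", {
  task <- data.frame(src = c("a", "a", "b"), dst = c("t1", "t2", "t1"))
  side <- list(ddi = data.frame(src = "a", dst = "b"))
  net <- assemble_dsmn(task, "DTI", side_edges = side)
  expect_equal(dim(net$W), c(2L, 2L))
  expect_equal(sum(net$W), 3L)
  expect_identical(net$R, net$W)
  expect_equal(unname(net$S), matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(assemble_dsmn(task, "DTI", side_edges = side, drugs = "a"),
               "unknown drug")
})

test_that("folds partition the positives with balanced sizes and clean negatives", {
  net <- small_planted(seed = 2L)
  folds <- make_folds(net, k = 5L, seed = 7L)
  pos <- hgdrug:::.positive_pairs(net)
  key <- function(m) paste(m[, 1L], m[, 2L])
  test_sets <- lapply(folds, function(f) key(f$test))
  # disjoint and exhaustive
  expect_equal(sort(unlist(test_sets)), sort(key(pos)))
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  sizes <- lengths(test_sets)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    expect_equal(nrow(f$test_neg), nrow(f$test))
    # negatives never collide with any positive edge
    expect_equal(sum(net$R[f$test_neg]), 0L)
    # per-fold training view contains no held-out positive
    v <- train_view(net, f)
    expect_equal(sum(v$R[f$test]), 0L)
    expect_equal(sum(v$R) + nrow(f$test), sum(net$R))
  }
  # reproducible under the seed
  folds2 <- make_folds(net, k = 5L, seed = 7L)
  expect_identical(folds, folds2)
  expect_error(make_folds(net, k = 10000L, seed = 1L), "exceeds")
})

test_that("drug-drug task folds remove both edge orientations from the view", {
  task <- data.frame(src = c("a", "b", "c", "d", "a", "e"),
                     dst = c("b", "c", "d", "e", "c", "b"))
  net <- assemble_dsmn(task, "DDI")
  folds <- make_folds(net, k = 3L, seed = 1L)
  for (f in folds) {
    v <- train_view(net, f)
    expect_true(isSymmetric(unname(v$R)))
    expect_equal(sum(v$R[f$test]), 0L)
    expect_equal(sum(v$R[f$test[, c(2, 1), drop = FALSE]]), 0L)
  }
})
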