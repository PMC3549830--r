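# Metastability-maximizing lumping: aggregation, annealing, exhaustive oracle.

test_that("lumped counts conserve totals and honor limit cases", {
  set.seed(40)
  C <- matrix(rpois(64, 4), 8, 8)
  expect_equal(lump_counts(C, 1:8, 8), C, ignore_attr = TRUE)
  expect_equal(as.numeric(lump_counts(C, rep(1, 8), 1)), sum(C))
  for (rep in 1:10) {
    L <- sample(2:4, 1)
    z <- c(seq_len(L), sample.int(L, 8 - L, replace = TRUE))[sample(8)]
    M <- lump_counts(C, z, L)
    expect_equal(sum(M), sum(C))
    expect_equal(dim(M), c(L, L))
  }
  expect_error(lump_counts(C, rep(1, 8), 2), "at least one microstate")
  expect_error(lump_counts(C, c(1:7, 9), 8), "into 1..L")
})

test_that("lumped metastability agrees with the transition-matrix route", {
  set.seed(41)
  C <- random_count_matrix(7)
  for (rep in 1:10) {
    L <- sample(2:4, 1)
    z <- c(seq_len(L), sample.int(L, 7 - L, replace = TRUE))[sample(7)]
    direct <- lumped_metastability(C, z, L)
    via_model <- metastability(transition_matrix(lump_counts(C, z, L)))
    expect_equal(direct, via_model, tolerance = 1e-14)
  }
})

test_that("exhaustive enumeration visits exactly the Stirling count", {
  C3 <- random_count_matrix(3)
  r <- exhaustive_lump(C3, 2)
  expect_equal(r$n_evaluated, 3)  # S(3,2) = 3
  C5 <- random_count_matrix(5)
  expect_equal(exhaustive_lump(C5, 3)$n_evaluated, 25)  # S(5,3) = 25
  expect_error(exhaustive_lump(matrix(1, 20, 20), 8), "exceeds 1e6")
})

test_that("block-diagonal counts are lumped along their blocks", {
  A <- matrix(c(50, 10, 10, 50), 2, 2)
  C <- rbind(cbind(A, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), A))
  r <- exhaustive_lump(C, 2)
  expect_equal(r$assignment, c(1, 1, 2, 2))
  expect_equal(r$Q, 2)  # zero off-block flux: both macrostates absorbing
})

test_that("the exhaustive optimum dominates random assignments", {
  set.seed(42)
  C <- matrix(rpois(36, 6), 6, 6)
  opt <- exhaustive_lump(C, 3)
  for (rep in 1:1000) {
    z <- c(1:3, sample.int(3, 3, replace = TRUE))[sample(6)]
    expect_gte(opt$Q + 1e-12, lumped_metastability(C, z, 3))
  }
})

test_that("annealing limit cases are forced by the constraints", {
  set.seed(43)
  C <- random_count_matrix(5)
  # L = K: every macrostate holds exactly one microstate
  r <- anneal_lump(C, 5, steps = 200, restarts = 2, seed = 1)
  expect_setequal(r$assignment, 1:5)
  expect_equal(r$Q, metastability(transition_matrix(C)), tolerance = 1e-12)
  # L = 1: single absorbing macrostate
  expect_equal(anneal_lump(C, 1, seed = 1)$Q, 1)
  expect_error(anneal_lump(C, 6), "exceed")
})

test_that("annealing recovers the planted 2-block structure at K = 8", {
  set.seed(44)
  block <- function() {
    B <- matrix(rpois(16, 2), 4, 4); diag(B) <- diag(B) + 40; B
  }
  C <- rbind(cbind(block(), matrix(rpois(16, 0.5), 4, 4)),
             cbind(matrix(rpois(16, 0.5), 4, 4), block()))
  truth <- exhaustive_lump(C, 2)
  ann <- anneal_lump(C, 2, steps = 5000, restarts = 10, seed = 7)
  expect_equal(ann$Q, truth$Q, tolerance = 1e-12)
  expect_true(same_partition(ann$assignment, truth$assignment))
  expect_true(same_partition(truth$assignment, rep(1:2, each = 4)))
})

test_that("annealer bookkeeping stays consistent with the direct objective", {
  set.seed(45)
  for (rep in 1:5) {
    C <- matrix(rpois(49, 5), 7, 7)
    r <- anneal_lump(C, 3, steps = 1000, restarts = 3, seed = rep)
    # no empty macrostates, ever
    expect_setequal(unique(r$assignment), 1:3)
    # incremental Q equals the from-scratch lump -> normalize -> trace route
    expect_equal(r$Q, lumped_metastability(C, r$assignment, 3), tolerance = 1e-10)
    # reported Q is the best over restarts
    expect_equal(r$Q, max(r$trace), tolerance = 1e-12)
    # determinism under the seed
    r2 <- anneal_lump(C, 3, steps = 1000, restarts = 3, seed = rep)
    expect_identical(r$assignment, r2$assignment)
  }
})

test_that("annealing with the default budget matches the oracle on random instances", {
  set.seed(46)
  hits <- 0
  n_inst <- 8
  for (inst in seq_len(n_inst)) {
    K <- sample(5:8, 1); L <- sample(2:3, 1)
    C <- random_count_matrix(K, diag_boost = 30)
    opt <- exhaustive_lump(C, L)
    ann <- anneal_lump(C, L, steps = 5000, restarts = 10, seed = inst)
    expect_lte(ann$Q, opt$Q + 1e-12)
    expect_gte(ann$Q, opt$Q * 0.99)   # always within 1% of optimal
    if (abs(ann$Q - opt$Q) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, n_inst - 1)
})
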