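# k-center / k-medoid splitting and the product (combination) scheme.

test_that("k-center limit cases behave as forced by the definition", {
  tr <- random_trajectory(8, 4, 6, seed = 20)
  metric <- solvent_signature_metric(2)

  all_own <- k_center(tr, K = 8, metric, seed = 1)
  expect_equal(all_own$radius, 0)
  expect_setequal(all_own$center_indices, 1:8)

  one <- k_center(tr, K = 1, metric, seed = 3)
  fl_d <- pairwise_distances(tr, metric)
  expect_equal(one$radius, max(fl_d[one$center_indices[1], ]))
  expect_error(k_center(tr, K = 9, metric), "1 <= K <= N")

  # every center belongs to its own cluster; nearest-center assignment
  cl <- k_center(tr, K = 3, metric, seed = 5)
  for (k in 1:3) expect_equal(cl$labels[cl$center_indices[k]], k)
  D <- fl_d[, cl$center_indices]
  expect_true(all(D[cbind(1:8, cl$labels)] <= apply(D, 1, min) + 1e-12))
  expect_lte(cl$n_metric_evals, 3 * 8)
})

test_that("greedy k-center is within twice the brute-force optimum", {
  set.seed(77)
  for (inst in 1:15) {
    N <- sample(8:14, 1)
    K <- sample(2:4, 1)
    tr <- random_trajectory(N, 4, 6, seed = 1000 + inst)
    metric <- if (inst %% 2) solvent_signature_metric(2) else solute_rmsd_metric()
    D <- pairwise_distances(tr, metric)
    greedy <- k_center(tr, K, metric, seed = inst)
    opt <- kcenter_brute_force_radius(D, K)
    expect_lte(greedy$radius, 2 * opt + 1e-12)
  }
})

test_that("clustering is deterministic under a fixed seed", {
  tr <- random_trajectory(20, 4, 8, seed = 44)
  metric <- solvent_signature_metric(1.5)
  a <- k_center(tr, 4, metric, seed = 9)
  b <- k_center(tr, 4, metric, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$center_indices, b$center_indices)
  c <- k_center(tr, 4, metric, seed = 10)
  expect_false(identical(a$center_indices, c$center_indices))
})

test_that("k-medoid refines k-center with a non-increasing objective", {
  # two tight, well-separated solvent clouds
  set.seed(55)
  mk <- function(center, t) {
    configuration(matrix(0, 3, 3),
                  matrix(rnorm(30, sd = 0.05), 10, 3) +
                    matrix(center, 10, 3, byrow = TRUE), frame_index = t)
  }
  frames <- c(lapply(1:6, function(t) mk(c(0, 0, 0), t)),
              lapply(7:12, function(t) mk(c(20, 0, 0), t)))
  tr <- trajectory(frames, trajectory_id = "two_groups")
  cl <- k_medoid(tr, 2, solvent_signature_metric(3), seed = 2)
  expect_true(same_partition(cl$labels, rep(1:2, each = 6)))
  trace <- attr(cl, "objective_trace")
  expect_true(all(diff(trace) <= 1e-12))

  # brute-force objective bound on small random instances
  for (inst in 1:5) {
    trr <- random_trajectory(9, 3, 6, seed = 300 + inst)
    metric <- solvent_signature_metric(2)
    D <- pairwise_distances(trr, metric)
    km <- k_medoid(trr, 2, metric, seed = inst)
    obj <- sum(D[cbind(1:9, km$center_indices[km$labels])])
    opt <- kmedoid_brute_force_objective(D, 2)
    expect_gte(obj, opt - 1e-12)
    expect_lte(obj, 1.5 * opt + 1e-12)
  }
})

test_that("product splitting reduces to single-metric clustering at K2=1 / K1=1", {
  tr <- random_trajectory(30, 4, 8, seed = 8)
  sm <- solute_rmsd_metric(); vm <- solvent_signature_metric(2)

  ps <- product_split(tr, K = 4, K1 = 4, K2 = 1, sm, vm, seed = 6)
  solo <- k_center(tr, 4, sm, seed = as.integer(6) * 2L + 1L)
  expect_identical(ps$labels, solo$labels)

  pv <- product_split(tr, K = 4, K1 = 1, K2 = 4, sm, vm, seed = 6)
  solv <- k_center(tr, 4, vm, seed = as.integer(6) * 2L + 2L)
  expect_identical(pv$labels, solv$labels)
  expect_error(product_split(tr, K = 9, K1 = 2, K2 = 2, sm, vm), "K1 \\* K2")
})

test_that("occupied product states are exactly the observed label pairs", {
  # frames engineered so solute shape and solvent position vary independently
  set.seed(23)
  shapes <- list(cbind(c(0, 1, 0), c(0, 0, 1.5), 0),   # small triangle
                 cbind(c(0, 4, 0), c(0, 0, 6), 0))     # large triangle
  clouds <- list(c(0, 0, 0), c(30, 0, 0))
  frames <- list(); truth <- list()
  t <- 0
  for (rep in 1:5) for (i in 1:2) for (j in 1:2) {
    t <- t + 1
    frames[[t]] <- configuration(
      shapes[[i]] + matrix(rnorm(9, sd = 0.01), 3, 3),
      matrix(rnorm(18, sd = 0.3), 6, 3) + matrix(clouds[[j]], 6, 3, byrow = TRUE),
      frame_index = t)
    truth[[t]] <- c(i, j)
  }
  tr <- trajectory(frames, trajectory_id = "grid")
  ps <- product_split(tr, K = 4, K1 = 2, K2 = 2,
                      solute_rmsd_metric(), solvent_signature_metric(3), seed = 2)
  expect_equal(ps$K, 4)
  truth_pair <- vapply(truth, function(x) paste(x, collapse = "-"), character(1))
  # microstate partition == partition by (solute, solvent) truth pair
  expect_true(same_partition(ps$labels, as.integer(factor(truth_pair))))
  # product consistency before merging: same state iff both labels equal
  td <- tidy(ps)
  key <- paste(td$solute_label, td$solvent_label)
  expect_true(same_partition(td$label, as.integer(factor(key, unique(key)))))
  expect_lte(ps$split_metric_evals, (2 + 2) * 20)
})

test_that("merging smallest states follows the stated rule step by step", {
  tr <- random_trajectory(40, 4, 8, seed = 99)
  sm <- solute_rmsd_metric(); vm <- solvent_signature_metric(2)
  ps <- product_split(tr, K = 6, K1 = 3, K2 = 3, sm, vm, seed = 11)
  expect_equal(ps$K, 6)

  # rebuild the pre-merge occupied states and replay the rule independently
  pre <- solvmsm:::product_split_once(solvmsm:::flatten_frames(tr), 6, 3, 3,
                                      sm, vm, 11, "global")
  st <- pre$states
  D1 <- pairwise_distances(tr, sm); D2 <- pairwise_distances(tr, vm)
  d_sol <- D1[st$solute_center_frame, st$solute_center_frame]
  d_solv <- D2[st$solvent_center_frame, st$solvent_center_frame]
  comb <- d_sol / max(d_sol) + d_solv / max(d_solv)
  replay <- simulate_merge_rule(st$population, comb, 6)
  merged_labels <- replay$owner[pre$labels]
  expect_length(unique(merged_labels), 6)
  # the package's merged partition equals the independent replay
  expect_true(same_partition(ps$labels, merged_labels))

  # occupied == K is the identity
  same <- merge_smallest_states(ps, 6)
  expect_identical(same$labels, ps$labels)
  # occupied = K+1 -> exactly one merge
  ps7 <- solvmsm:::product_split_once(solvmsm:::flatten_frames(tr), 6, 3, 3,
                                      sm, vm, 11, "global")
  if (nrow(ps7$states) >= 7) {
    m6 <- merge_smallest_states(ps7, nrow(ps7$states) - 1L)
    expect_equal(length(m6$merges), 1)
  }
  expect_error(merge_smallest_states(ps, 7), "fewer occupied")
})

test_that("nested mode clusters solvent within each solute cluster", {
  tr <- random_trajectory(24, 4, 8, seed = 13)
  ps <- product_split(tr, K = 4, K1 = 2, K2 = 2, solute_rmsd_metric(),
                      solvent_signature_metric(2), seed = 3, mode = "nested")
  expect_equal(ps$K, 4)
  expect_equal(sort(unique(ps$labels)), 1:4)
  expect_identical(ps$mode, "nested")
})
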