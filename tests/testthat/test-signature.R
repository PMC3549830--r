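# Gaussian kernel, solvent signatures, water number, PCA.

test_that("gaussian kernel matches its closed form", {
  expect_equal(gaussian_kernel(c(0, 0, 0), c(0, 0, 0), sigma = 1.7), 1)
  s <- 0.8
  expect_equal(gaussian_kernel(c(0, 0, 0), c(s * sqrt(2), 0, 0), sigma = s),
               exp(-1))
  expect_error(gaussian_kernel(c(0, 0, 0), c(1, 0, 0), sigma = 0), "sigma")
  expect_error(gaussian_kernel(c(0, 0, 0), c(1, 0, 0), sigma = -2), "sigma")
})

test_that("normalized kernel integrates to 1 (radial quadrature oracle)", {
  for (s in c(0.3, 1, 2.5)) {
    # independent oracle: 4 pi int r^2 g(r) dr over [0, 12 sigma]
    g <- function(r) (2 * pi * s^2)^(-1.5) * exp(-r^2 / (2 * s^2)) * 4 * pi * r^2
    total <- stats::integrate(g, 0, 12 * s, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
    expect_equal(gaussian_kernel(c(1, 2, 3), c(1, 2, 3), s, normalized = TRUE),
                 (2 * pi * s^2)^(-1.5))
  }
})

test_that("point signature sums kernels and is permutation invariant", {
  expect_identical(point_signature(c(0, 0, 0), matrix(numeric(0), 0, 3), 1), 0)
  x <- c(1, -2, 0.5)
  expect_equal(point_signature(x, rbind(x, x), sigma = 2), 2)
  set.seed(31)
  Y <- matrix(rnorm(60), 20, 3)
  for (rep in 1:5) {
    perm <- sample(20)
    expect_identical(point_signature(x, Y, 1.3),
                     point_signature(x, Y[perm, ], 1.3))
  }
})

test_that("signature vectors obey continuity and locality bounds", {
  set.seed(7)
  conf <- random_configuration(m = 6, n = 25, scale = 4)
  s <- 1.5
  v <- signature_vector(conf, s)
  expect_length(v, 6)
  expect_equal(as.numeric(v[1]), point_signature(conf$solute[1, ], conf$solvent, s))
  # m = 1 reduces to point_signature
  c1 <- configuration(conf$solute[1, , drop = FALSE], conf$solvent)
  expect_equal(as.numeric(signature_vector(c1, s)),
               point_signature(conf$solute[1, ], conf$solvent, s))

  # locality: far solvent contributes < n exp(-50) per entry
  far <- configuration(matrix(0, 2, 3), matrix(100 + rnorm(30), 10, 3))
  expect_lt(max(signature_vector(far, 1)), 10 * exp(-50))

  # continuity: perturbing one solvent point by delta <= sigma/10 moves each
  # entry by at most (delta/sigma) exp(-1/2) (1 + 1e-2), the kernel's maximal
  # gradient bound
  for (rep in 1:20) {
    delta <- runif(1, 0, s / 10)
    Y2 <- conf$solvent
    i <- sample(nrow(Y2), 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    Y2[i, ] <- Y2[i, ] + delta * dir
    v2 <- signature_vector(configuration(conf$solute, Y2), s)
    expect_lte(max(abs(v2 - v)), (delta / s) * exp(-0.5) * (1 + 1e-2) + 1e-12)
  }
})

test_that("signatures across a trajectory form a tidy table", {
  tr <- random_trajectory(6, 3, 10, seed = 4)
  sig <- compute_signatures(tr, sigma = 2)
  expect_s3_class(sig, "solvent_signatures")
  expect_named(sig, c("trajectory_id", "frame_index", "f1", "f2", "f3"))
  expect_equal(nrow(sig), 6)
  expect_equal(attr(sig, "sigma"), 2)
  expect_equal(as.numeric(attr(sig, "matrix")[4, ]),
               as.numeric(signature_vector(tr$frames[[4]], 2)))
})

test_that("water number reproduces interior, boundary and Monte-Carlo values", {
  reg <- cylinder_region(c(0, 0, -3), c(0, 0, 3), radius = 2)
  # single molecule at the center, sigma = radius/20
  wc <- water_number(configuration(matrix(0, 1, 3), matrix(0, 1, 3)),
                     reg, sigma = 2 / 20)
  expect_equal(wc, 1, tolerance = 1e-6)
  # molecule exactly on a flat face, on the axis: 1/2 in the small-sigma limit
  wf <- water_number(configuration(matrix(0, 1, 3), matrix(c(0, 0, 3), 1, 3)),
                     reg, sigma = 0.01)
  expect_equal(wf, 0.5, tolerance = 1e-6)
  # molecule on the curved boundary, small sigma: also ~1/2
  wr <- water_number(configuration(matrix(0, 1, 3), matrix(c(2, 0, 0), 1, 3)),
                     reg, sigma = 0.005)
  expect_equal(wr, 0.5, tolerance = 1e-2)

  # Monte-Carlo volume-integral oracle within 3 standard errors
  set.seed(99)
  Y <- rbind(matrix(rnorm(15, sd = 1.5), 5, 3),
             matrix(c(5, 5, 5, -4, 0, 6), 2, 3, byrow = TRUE))
  for (s in c(0.5, 1)) {
    exact <- water_number(configuration(matrix(0, 1, 3), Y), reg, s)
    mc <- water_number_mc(Y, reg, s, n_samples = 2e5)
    expect_lt(abs(exact - mc$estimate), 3 * mc$se)
    expect_gte(exact, 0)
    expect_lte(exact, nrow(Y))
  }
  expect_error(cylinder_region(c(0, 0, 0), c(0, 0, 0), 1), "degenerate")
  expect_error(cylinder_region(c(0, 0, 0), c(0, 0, 1), -1), "degenerate")
})

test_that("water number approaches the interior count as sigma -> 0", {
  reg <- cylinder_region(c(0, 0, 0), c(0, 0, 10), radius = 3)
  sigma <- 0.2
  # 4 interior, 3 exterior, all > 6 sigma from the boundary
  Y <- rbind(c(0, 0, 5), c(1, 1, 3), c(-1.5, 0, 7), c(0, 1.5, 2),
             c(0, 0, 14), c(8, 0, 5), c(0, -7, -2))
  wn <- water_number(configuration(matrix(0, 1, 3), Y), reg, sigma)
  expect_equal(wn, 4, tolerance = 1e-6)
})

test_that("PCA of signatures matches an eigendecomposition oracle", {
  set.seed(12)
  tr <- random_trajectory(30, 5, 12, seed = 12)
  sig <- compute_signatures(tr, sigma = 2)
  M <- attr(sig, "matrix")
  pca <- pca_signatures(sig, n_components = 5)
  # oracle: eigenvalues of the sample covariance
  ev <- sort(eigen(stats::cov(M), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(pca$explained_variance, ev[1:5], tolerance = 1e-10)
  # orthonormal components
  G <- pca$components %*% t(pca$components)
  expect_equal(G, diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  # full-rank projection reconstructs centered data
  P <- as.matrix(pca$projections[paste0("PC", 1:5)])
  rec <- P %*% pca$components
  expect_equal(rec, scale(M, center = TRUE, scale = FALSE),
               tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic sign convention
  for (j in 1:5) {
    expect_gt(pca$components[j, which.max(abs(pca$components[j, ]))], 0)
  }

  # data on a line: first component explains everything
  base <- rnorm(4)
  lineM <- outer(seq(0, 1, length.out = 10), base) +
    matrix(rnorm(40, sd = 1e-12), 10, 4)
  p1 <- pca_signatures(lineM, 2)
  expect_gt(p1$explained_variance_ratio[1], 1 - 1e-10)
  expect_error(pca_signatures(lineM, 7), "n_components")
})

test_that("every signature-derived quantity is invariant under solvent permutation", {
  set.seed(8)
  tr <- random_trajectory(5, 4, 15, seed = 8)
  sig1 <- compute_signatures(tr, sigma = 1.2)
  permuted <- trajectory(lapply(tr$frames, function(f) {
    configuration(f$solute, f$solvent[sample(nrow(f$solvent)), ],
                  frame_index = f$frame_index)
  }), trajectory_id = tr$trajectory_id)
  sig2 <- compute_signatures(permuted, sigma = 1.2)
  expect_identical(attr(sig1, "matrix"), attr(sig2, "matrix"))
  reg <- cylinder_region(c(0, 0, -4), c(0, 0, 4), 3)
  expect_identical(water_number_series(tr, reg, 0.8)$water_number,
                   water_number_series(permuted, reg, 0.8)$water_number)
})
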