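# Shared fixtures and independent oracles for the test suite.

# random configuration with m solute atoms and n solvent molecules
random_configuration <- function(m = 4, n = 8, scale = 5, frame_index = 1) {
  configuration(matrix(stats::rnorm(3 * m, sd = scale), m, 3),
                matrix(stats::rnorm(3 * n, sd = scale), n, 3),
                frame_index = frame_index)
}

random_trajectory <- function(n_frames = 5, m = 4, n = 8, seed = 1, scale = 5) {
  set.seed(seed)
  trajectory(lapply(seq_len(n_frames), function(t) {
    random_configuration(m, n, scale, frame_index = t)
  }), lag_time = 1, trajectory_id = paste0("rand", seed))
}

# rotation matrix from an axis-angle vector (Rodrigues)
rotation_from_axis_angle <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * Kx %*% Kx
}

random_rotation <- function() {
  rotation_from_axis_angle(stats::rnorm(3) * stats::runif(1, 0, pi))
}

# independent RMSD oracle: numerical minimization over rotations (axis-angle
# parameterization, centered point sets, many random starts)
rmsd_oracle <- function(A, B, n_starts = 24) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(v) {
    R <- rotation_from_axis_angle(v)
    sqrt(sum((Ac - Bc %*% t(R))^2) / nrow(A))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    v0 <- if (s == 1) c(0, 0, 0) else stats::rnorm(3) * stats::runif(1, 0, pi)
    r <- stats::optim(v0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# brute-force k-center oracle: optimal covering radius over all center
# subsets, given a full distance matrix
kcenter_brute_force_radius <- function(D, K) {
  N <- nrow(D)
  best <- Inf
  for (centers in utils::combn(N, K, simplify = FALSE)) {
    r <- max(apply(D[, centers, drop = FALSE], 1, min))
    best <- min(best, r)
  }
  best
}

# brute-force k-medoid oracle: optimal sum of distances to medoids
kmedoid_brute_force_objective <- function(D, K) {
  N <- nrow(D)
  best <- Inf
  for (medoids in utils::combn(N, K, simplify = FALSE)) {
    obj <- sum(apply(D[, medoids, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# Monte-Carlo oracle for the water number: uniform sampling of the cylinder
# volume, returning the estimate and its standard error
water_number_mc <- function(Y, region, sigma, n_samples = 2e5) {
  u <- (region$axis_end - region$axis_start) / region$height
  # orthonormal frame for the cylinder cross-section
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  z <- stats::runif(n_samples, 0, region$height)
  r <- region$radius * sqrt(stats::runif(n_samples))
  th <- stats::runif(n_samples, 0, 2 * pi)
  pts <- region$axis_start[col(matrix(0, n_samples, 3))] +
    outer(z, u) + outer(r * cos(th), e1) + outer(r * sin(th), e2)
  dens <- rep(0, n_samples)
  for (i in seq_len(nrow(Y))) {
    d2 <- rowSums(sweep(pts, 2, Y[i, ])^2)
    dens <- dens + exp(-d2 / (2 * sigma^2))
  }
  dens <- dens * (2 * pi * sigma^2)^(-1.5)
  vol <- pi * region$radius^2 * region$height
  list(estimate = vol * mean(dens),
       se = vol * stats::sd(dens) / sqrt(n_samples))
}

# random metastable count matrix: diagonal-dominant with block structure
random_count_matrix <- function(K, diag_boost = 50) {
  C <- matrix(stats::rpois(K * K, 3), K, K)
  diag(C) <- diag(C) + stats::rpois(K, diag_boost)
  C
}

# independent simulator of the smallest-state merging rule, working from a
# population vector and a combined state-distance matrix
simulate_merge_rule <- function(pop, comb, K) {
  ns <- length(pop)
  alive <- rep(TRUE, ns)
  owner <- seq_len(ns)
  while (sum(alive) > K) {
    al <- which(alive)
    sm <- al[order(pop[al], al)][1]
    cand <- setdiff(al, sm)
    dest <- cand[order(comb[sm, cand], cand)][1]
    pop[dest] <- pop[dest] + pop[sm]
    alive[sm] <- FALSE
    owner[owner == sm] <- dest
  }
  list(owner = owner, pop = pop, alive = alive)
}

# partition-equality helper: two label vectors describe the same partition
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
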