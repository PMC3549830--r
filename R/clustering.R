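# Geometric splitting of configurations into microstates: greedy k-center
# (Gonzalez farthest-point, a 2-approximation), k-medoid refinement, and the
# combination scheme crossing K1 solute clusters with K2 solvent clusters.

new_clustering <- function(labels, centers, radius, metric, K, seed, info,
                           n_metric_evals) {
  structure(list(
    labels = as.integer(labels), center_indices = as.integer(centers),
    radius = radius, metric = metric, K = as.integer(K), seed = seed,
    info = info, n_metric_evals = n_metric_evals
  ), class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> K = %d over %d frames, radius = %.4g (%s metric)\n",
              x$K, length(x$labels), x$radius, x$metric$kind))
  invisible(x)
}

#' @rdname k_center
#' @param x a `clustering` object.
#' @param ... unused.
#' @method tidy clustering
#' @export
tidy.clustering <- function(x, ...) {
  dplyr::mutate(x$info, label = x$labels)
}

#' @rdname k_center
#' @method glance clustering
#' @export
glance.clustering <- function(x, ...) {
  tibble::tibble(K = x$K, n = length(x$labels), radius = x$radius,
                 metric = x$metric$kind, n_metric_evals = x$n_metric_evals,
                 seed = x$seed)
}

# run expr under a temporary RNG seed, restoring global RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# core greedy k-center on a prepared metric; returns labels/centers/radius
k_center_core <- function(pm, N, K, seed) {
  first <- with_local_seed(seed, sample.int(N, 1L))
  centers <- integer(K)
  centers[1L] <- first
  dmin <- pm$dist_one_to_many(first, seq_len(N))
  labels <- rep(1L, N)
  k <- 1L
  while (k < K) {
    k <- k + 1L
    nxt <- which.max(dmin)   # farthest frame; ties -> lowest index
    centers[k] <- nxt
    d <- pm$dist_one_to_many(nxt, seq_len(N))
    closer <- d < dmin       # strict: ties keep the earlier (lower-id) center
    labels[closer] <- k
    dmin[closer] <- d[closer]
    labels[nxt] <- k
    dmin[nxt] <- 0
  }
  list(labels = labels, centers = centers, radius = max(dmin))
}

#' k-center clustering of trajectory frames
#'
#' Greedy farthest-point (Gonzalez) k-center under a configuration metric:
#' the first center is a seeded-random frame; each subsequent center is the
#' frame farthest from all existing centers; every frame is assigned to its
#' nearest center (ties to the earlier center). Uses at most `K * N` metric
#' evaluations and returns a covering radius at most twice the optimal
#' k-center radius.
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param K number of clusters, `1 <= K <= N`.
#' @param metric a [solute_rmsd_metric()] or [solvent_signature_metric()].
#' @param seed integer RNG seed (choice of first center).
#' @return Object of class `clustering` with fields `labels` (1..K per
#'   frame), `center_indices`, `radius`, `n_metric_evals`; [tidy()] gives the
#'   per-frame label table, [glance()] a one-row summary.
#' @examples
#' tr <- simulate_two_basin(two_basin_params(seed = 1), n_frames = 50)
#' cl <- k_center(tr, K = 2, solvent_signature_metric(1), seed = 7)
#' glance(cl)
#' @export
k_center <- function(trajs, K, metric, seed = 1L) {
  fl <- flatten_frames(trajs)
  N <- length(fl$frames)
  K <- as.integer(K)
  if (K < 1L || K > N) stop("K must satisfy 1 <= K <= N (N = ", N, ")", call. = FALSE)
  pm <- prepare_metric(metric, fl)
  res <- k_center_core(pm, N, K, seed)
  new_clustering(res$labels, res$centers, res$radius, metric, K, seed,
                 fl$info, pm$n_evals)
}

#' k-medoid clustering of trajectory frames
#'
#' Alternating assignment / medoid-update refinement started from the seeded
#' k-center solution. The objective (sum of frame-to-medoid distances) is
#' non-increasing across iterations; stops at a fixed point or `max_iter`.
#'
#' @inheritParams k_center
#' @param max_iter maximum refinement sweeps.
#' @return A `clustering` object; the attribute `objective_trace` records the
#'   objective after each sweep.
#' @export
k_medoid <- function(trajs, K, metric, seed = 1L, max_iter = 20L) {
  fl <- flatten_frames(trajs)
  N <- length(fl$frames)
  K <- as.integer(K)
  if (K < 1L || K > N) stop("K must satisfy 1 <= K <= N (N = ", N, ")", call. = FALSE)
  pm <- prepare_metric(metric, fl)
  init <- k_center_core(pm, N, K, seed)
  medoids <- init$centers
  trace <- numeric(0)
  labels <- init$labels
  for (it in seq_len(max_iter)) {
    D <- vapply(medoids, function(c) pm$dist_one_to_many(c, seq_len(N)),
                numeric(N))                     # N x K
    labels <- max.col(-D, ties.method = "first")
    obj <- sum(D[cbind(seq_len(N), labels)])
    new_medoids <- medoids
    for (k in seq_len(K)) {
      members <- which(labels == k)
      if (!length(members)) next
      within <- vapply(members, function(i) sum(pm$dist_one_to_many(i, members)),
                       numeric(1))
      new_medoids[k] <- members[which.min(within)]
    }
    trace <- c(trace, obj)
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  D <- vapply(medoids, function(c) pm$dist_one_to_many(c, seq_len(N)), numeric(N))
  labels <- max.col(-D, ties.method = "first")
  radius <- max(D[cbind(seq_len(N), labels)])
  out <- new_clustering(labels, medoids, radius, metric, K, seed, fl$info, pm$n_evals)
  attr(out, "objective_trace") <- trace
  out
}

#' Combination (product) splitting with solute and solvent clusters
#'
#' Clusters all frames twice -- into `K1` solute clusters under the solute
#' metric and `K2` solvent clusters under the solvent metric -- and defines a
#' microstate as an occupied (solute cluster, solvent cluster) pair: two
#' frames share a microstate iff they share both cluster assignments. If
#' fewer than `K` product states are occupied, `K1` and `K2` are incremented
#' (up to 5 times) and the split repeated; occupied states beyond `K` are
#' then reduced to exactly `K` by [merge_smallest_states()]. The traditional
#' solute-only model is the special case `K2 = 1`, the solvent-only model
#' `K1 = 1`. With `K1 = K2 = ceiling(sqrt(K))` (the default) the split stage
#' costs O(sqrt(K) N) metric evaluations rather than O(K N).
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param K target number of microstates.
#' @param K1,K2 solute / solvent cluster counts (`K1 * K2 >= K`); default
#'   `ceiling(sqrt(K))` each.
#' @param solute_metric,solvent_metric the two [solute_rmsd_metric()] /
#'   [solvent_signature_metric()] distance functions.
#' @param seed master seed; the two k-center runs use seeds derived from it.
#' @param mode `"global"` (independent global solvent clustering, default) or
#'   `"nested"` (solvent clustered separately within each solute cluster).
#' @return Object of class `product_clustering`: per-frame `labels` (1..K),
#'   the two stage clusterings, a `states` tibble mapping microstates to
#'   (solute, solvent) cluster pairs, and metric-evaluation counters
#'   (`split_metric_evals` covers the two clustering runs only).
#' @export
product_split <- function(trajs, K, K1 = NULL, K2 = NULL,
                          solute_metric = solute_rmsd_metric(),
                          solvent_metric, seed = 1L,
                          mode = c("global", "nested")) {
  mode <- match.arg(mode)
  fl <- flatten_frames(trajs)
  N <- length(fl$frames)
  K <- as.integer(K)
  if (K < 1L || K > N) stop("K must satisfy 1 <= K <= N", call. = FALSE)
  K1 <- as.integer(K1 %||% ceiling(sqrt(K)))
  K2 <- as.integer(K2 %||% ceiling(sqrt(K)))
  if (K1 * K2 < K) stop("K1 * K2 must be at least K", call. = FALSE)

  for (attempt in 0:5) {
    k1 <- min(K1 + attempt, N); k2 <- min(K2 + attempt, N)
    res <- product_split_once(fl, K, k1, k2, solute_metric, solvent_metric,
                              seed, mode)
    if (nrow(res$states) >= K) {
      if (attempt > 0) {
        message(sprintf("product_split: increased cluster counts to K1 = %d, K2 = %d to reach %d occupied states",
                        k1, k2, nrow(res$states)))
      }
      return(merge_smallest_states(res, K))
    }
  }
  stop(sprintf("product_split: only %d occupied product states after 5 increments (need K = %d)",
               nrow(res$states), K), call. = FALSE)
}

product_split_once <- function(fl, K, K1, K2, solute_metric, solvent_metric,
                               seed, mode) {
  N <- length(fl$frames)
  seed1 <- as.integer(seed) * 2L + 1L
  seed2 <- as.integer(seed) * 2L + 2L
  pm1 <- prepare_metric(solute_metric, fl)
  r1 <- k_center_core(pm1, N, K1, seed1)
  sol_cl <- new_clustering(r1$labels, r1$centers, r1$radius, solute_metric,
                           K1, seed1, fl$info, pm1$n_evals)
  pm2 <- prepare_metric(solvent_metric, fl)
  if (mode == "global") {
    r2 <- k_center_core(pm2, N, K2, seed2)
    solv_labels <- r2$labels
    solv_center_of <- function(lab) r2$centers[lab]
    solv_evals <- pm2$n_evals
    solv_cl <- new_clustering(r2$labels, r2$centers, r2$radius, solvent_metric,
                              K2, seed2, fl$info, pm2$n_evals)
  } else {
    # nested: K2 solvent clusters within each solute cluster
    solv_labels <- integer(N)
    centers_by_group <- vector("list", K1)
    for (g in seq_len(K1)) {
      members <- which(r1$labels == g)
      kg <- min(K2, length(members))
      rg <- k_center_subset(pm2, members, kg, seed2 + g)
      solv_labels[members] <- rg$labels
      centers_by_group[[g]] <- rg$centers
    }
    solv_center_of <- NULL
    solv_evals <- pm2$n_evals
    solv_cl <- structure(list(labels = solv_labels, mode = "nested",
                              centers_by_group = centers_by_group,
                              metric = solvent_metric, K = K2),
                         class = "nested_solvent_clustering")
  }
  # occupied product states in (solute, solvent) lexicographic order
  key <- (r1$labels - 1L) * max(solv_labels, K2) + solv_labels
  occ <- sort(unique(key))
  micro <- match(key, occ)
  kk <- max(solv_labels, K2)
  st_sol <- ((occ - 1L) %/% kk) + 1L
  st_solv <- ((occ - 1L) %% kk) + 1L
  pop <- tabulate(micro, nbins = length(occ))
  # representative center frames per state
  sol_center_frame <- r1$centers[st_sol]
  solv_center_frame <- integer(length(occ))
  for (s in seq_along(occ)) {
    if (mode == "global") {
      solv_center_frame[s] <- solv_center_of(st_solv[s])
    } else {
      solv_center_frame[s] <- centers_by_group[[st_sol[s]]][st_solv[s]]
    }
  }
  states <- tibble::tibble(
    state = seq_along(occ), solute_label = st_sol, solvent_label = st_solv,
    population = pop, solute_center_frame = sol_center_frame,
    solvent_center_frame = solv_center_frame
  )
  structure(list(
    labels = micro, states = states, solute = sol_cl, solvent = solv_cl,
    K = length(occ), K1 = K1, K2 = K2, seed = seed, mode = mode,
    info = fl$info,
    split_metric_evals = pm1$n_evals + solv_evals,
    solute_metric = solute_metric, solvent_metric = solvent_metric,
    fl = fl, merges = list()
  ), class = "product_clustering")
}

# greedy k-center over a subset of frame indices (labels 1..K within subset)
k_center_subset <- function(pm, members, K, seed) {
  n <- length(members)
  first <- with_local_seed(seed, sample.int(n, 1L))
  centers <- integer(K); centers[1L] <- members[first]
  dmin <- pm$dist_one_to_many(members[first], members)
  labels <- rep(1L, n)
  k <- 1L
  while (k < K) {
    k <- k + 1L
    nxt <- which.max(dmin)
    centers[k] <- members[nxt]
    d <- pm$dist_one_to_many(members[nxt], members)
    closer <- d < dmin
    labels[closer] <- k
    dmin[closer] <- d[closer]
    labels[nxt] <- k; dmin[nxt] <- 0
  }
  list(labels = labels, centers = centers, radius = max(dmin))
}

#' @export
print.product_clustering <- function(x, ...) {
  cat(sprintf("<product_clustering> K = %d microstates from K1 = %d solute x K2 = %d solvent clusters (%s mode), %d frames\n",
              x$K, x$K1, x$K2, x$mode, length(x$labels)))
  invisible(x)
}

#' @rdname product_split
#' @param x a `product_clustering`.
#' @param ... unused.
#' @method tidy product_clustering
#' @export
tidy.product_clustering <- function(x, ...) {
  dplyr::mutate(x$info, label = x$labels,
                solute_label = x$solute$labels, solvent_label = x$solvent$labels)
}

#' @rdname product_split
#' @method glance product_clustering
#' @export
glance.product_clustering <- function(x, ...) {
  tibble::tibble(K = x$K, K1 = x$K1, K2 = x$K2, n = length(x$labels),
                 mode = x$mode, split_metric_evals = x$split_metric_evals,
                 n_merges = length(x$merges), seed = x$seed)
}

#' Merge the smallest product states down to K microstates
#'
#' Repeatedly takes the occupied state with the smallest population (ties to
#' the lower state id) and merges it into the state minimizing the combined
#' center distance `d_solute / D_solute + d_solvent / D_solvent`, where each
#' `D` is the diameter of the respective set of cluster centers (a zero
#' diameter drops that term). The absorbing state keeps its center pair.
#' After any merge, states are relabeled densely 1..K in decreasing
#' population order.
#'
#' @param pc a `product_clustering` from [product_split()].
#' @param K target state count (`<=` current occupied states).
#' @return The reduced `product_clustering` with exactly `K` states.
#' @export
merge_smallest_states <- function(pc, K) {
  stopifnot(inherits(pc, "product_clustering"))
  K <- as.integer(K)
  S <- nrow(pc$states)
  if (S < K) stop("fewer occupied states (", S, ") than K = ", K, call. = FALSE)
  if (S == K) return(pc)

  pm1 <- prepare_metric(pc$solute_metric, pc$fl)
  pm2 <- prepare_metric(pc$solvent_metric, pc$fl)
  st <- pc$states
  ns <- nrow(st)
  d_sol <- matrix(0, ns, ns); d_solv <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    d_sol[i, ] <- pm1$dist_one_to_many(st$solute_center_frame[i], st$solute_center_frame)
    d_solv[i, ] <- pm2$dist_one_to_many(st$solvent_center_frame[i], st$solvent_center_frame)
  }
  D1 <- max(d_sol); D2 <- max(d_solv)
  comb <- (if (D1 > 0) d_sol / D1 else d_sol * 0) +
          (if (D2 > 0) d_solv / D2 else d_solv * 0)

  alive <- rep(TRUE, ns)
  pop <- st$population
  owner <- seq_len(ns)          # original state -> absorbing alive state
  merges <- pc$merges
  while (sum(alive) > K) {
    al <- which(alive)
    sm <- al[order(pop[al], al)][1L]          # smallest population, ties low id
    cand <- setdiff(al, sm)
    dest <- cand[order(comb[sm, cand], cand)][1L]
    pop[dest] <- pop[dest] + pop[sm]
    alive[sm] <- FALSE
    owner[owner == sm] <- dest
    merges[[length(merges) + 1L]] <- list(from = sm, into = dest)
  }
  al <- which(alive)
  # dense relabel in decreasing population order (ties by state id)
  ord <- al[order(-pop[al], al)]
  newid <- integer(ns)
  newid[ord] <- seq_along(ord)
  labels <- newid[owner[pc$labels]]
  states <- st[ord, ]
  states$state <- seq_len(K)
  states$population <- pop[ord]
  out <- pc
  out$labels <- labels
  out$states <- states
  out$K <- K
  out$merges <- merges
  out
}
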