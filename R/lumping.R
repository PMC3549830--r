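# Lumping microstates into macrostates by maximizing metastability.
#
# The objective for a candidate assignment is computed from the aggregated
# macrostate count matrix: lump the micro counts, column-normalize, take the
# trace. Simulated annealing proposes single-microstate reassignments with
# temperature 1/step; an exhaustive set-partition enumerator serves as the
# exact optimum for small problems.

#' Aggregate a micro count matrix under a lumping assignment
#'
#' `macro_counts[a, b] = sum over micro i in a, j in b of counts[i, j]`;
#' total counts are conserved.
#'
#' @param counts `K x K` micro count matrix (column-source convention).
#' @param assignment integer vector length K mapping microstate -> macrostate
#'   in 1..L; every macrostate must be non-empty.
#' @param L number of macrostates.
#' @return `L x L` count matrix.
#' @export
lump_counts <- function(counts, assignment, L) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  assignment <- as.integer(assignment)
  L <- as.integer(L)
  if (length(assignment) != K || any(assignment < 1L | assignment > L)) {
    stop("assignment must map all ", K, " microstates into 1..L", call. = FALSE)
  }
  if (length(unique(assignment)) != L) {
    stop("every macrostate must contain at least one microstate", call. = FALSE)
  }
  Z <- matrix(0, K, L)
  Z[cbind(seq_len(K), assignment)] <- 1
  t(Z) %*% counts %*% Z
}

# metastability of an assignment straight from macro counts (self-loop
# convention for zero columns, matching transition_matrix())
macro_Q <- function(M) {
  tot <- colSums(M)
  d <- diag(as.matrix(M))
  sum(ifelse(tot > 0, d / tot, 1))
}

#' Metastability of a lumping assignment
#'
#' Convenience: [lump_counts()] then column-normalize and take the trace.
#'
#' @inheritParams lump_counts
#' @return Scalar Q of the lumped model.
#' @export
lumped_metastability <- function(counts, assignment, L) {
  macro_Q(lump_counts(counts, assignment, L))
}

new_lumping_result <- function(assignment, Q, trace, seed, method, extra = list()) {
  structure(c(list(assignment = as.integer(assignment), Q = Q, L = max(assignment),
                   trace = trace, seed = seed, method = method), extra),
            class = "lumping_result")
}

#' @export
print.lumping_result <- function(x, ...) {
  cat(sprintf("<lumping_result> %d microstates -> %d macrostates, Q = %.4f (Q/L = %.4f) [%s]\n",
              length(x$assignment), x$L, x$Q, x$Q / x$L, x$method))
  invisible(x)
}

#' @rdname anneal_lump
#' @param x a `lumping_result`.
#' @param ... unused.
#' @method tidy lumping_result
#' @export
tidy.lumping_result <- function(x, ...) {
  tibble::tibble(microstate = seq_along(x$assignment), macrostate = x$assignment)
}

#' @rdname anneal_lump
#' @method glance lumping_result
#' @export
glance.lumping_result <- function(x, ...) {
  tibble::tibble(K = length(x$assignment), L = x$L, Q = x$Q,
                 Q_normalized = x$Q / x$L, method = x$method,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Lump microstates into macrostates by simulated annealing
#'
#' Maximizes the metastability Q of the lumped model. Each restart draws a
#' uniform random assignment (redrawn until all L macrostates are occupied),
#' then performs `steps` moves: a microstate is picked uniformly at random
#' and proposed a uniform random macrostate; the move is rejected outright if
#' it would empty a macrostate; otherwise it is accepted when `Q' >= Q`, and
#' with probability `exp((Q' - Q) / temp)` when downhill, with temperature
#' `temp = 1 / step` (reset each restart). The best assignment sampled in any
#' restart is returned.
#'
#' @param counts `K x K` micro transition count matrix.
#' @param L target number of macrostates (`<= K`).
#' @param steps annealing steps per restart (default 10000).
#' @param restarts independent restarts (default 100).
#' @param seed integer master seed; restarts use derived streams.
#' @return Object of class `lumping_result`: `assignment` (1..L per
#'   microstate), `Q`, per-restart best-Q `trace`, and canonical relabeling
#'   by smallest contained microstate.
#' @examples
#' C <- rbind(c(90, 5, 3, 1), c(5, 90, 1, 3), c(3, 1, 90, 5), c(1, 3, 5, 90))
#' anneal_lump(C, L = 2, steps = 500, restarts = 5, seed = 1)
#' @export
anneal_lump <- function(counts, L, steps = 10000L, restarts = 100L, seed = 1L) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  L <- as.integer(L)
  if (L > K) stop("L must not exceed the number of microstates K", call. = FALSE)
  if (L < 1L) stop("L must be positive", call. = FALSE)
  if (L == 1L) {
    return(new_lumping_result(rep(1L, K), macro_Q(lump_counts(counts, rep(1L, K), 1L)),
                              trace = NULL, seed = seed, method = "anneal"))
  }
  steps <- as.integer(steps); restarts <- as.integer(restarts)
  best_Q <- -Inf; best_z <- NULL
  trace <- numeric(restarts)
  for (r in seq_len(restarts)) {
    res <- with_local_seed(as.integer(seed) + r, anneal_once(counts, K, L, steps))
    trace[r] <- res$Q
    if (res$Q > best_Q) { best_Q <- res$Q; best_z <- res$z }
  }
  z <- canonical_assignment(best_z)
  new_lumping_result(z, best_Q, trace, seed, "anneal")
}

anneal_once <- function(counts, K, L, steps) {
  # initial assignment: uniform over all maps, rejection until surjective
  repeat {
    z <- sample.int(L, K, replace = TRUE)
    if (length(unique(z)) == L) break
  }
  sizes <- tabulate(z, L)
  Z <- matrix(0, K, L); Z[cbind(seq_len(K), z)] <- 1
  M <- t(Z) %*% counts %*% Z
  Q <- macro_Q(M)
  best_Q <- Q; best_z <- z
  for (s in seq_len(steps)) {
    i <- sample.int(K, 1L)
    b <- sample.int(L, 1L)
    a <- z[i]
    if (b == a) next
    if (sizes[a] == 1L) next        # would empty macrostate a: reject
    # incremental macro-count update for moving micro i from a to b
    r_vec <- as.numeric(counts[i, ] %*% Z)      # row i aggregated by macro
    c_vec <- as.numeric(crossprod(Z, counts[, i]))
    cii <- counts[i, i]
    M2 <- M
    M2[a, ] <- M2[a, ] - r_vec; M2[b, ] <- M2[b, ] + r_vec
    M2[, a] <- M2[, a] - c_vec; M2[, b] <- M2[, b] + c_vec
    M2[a, a] <- M2[a, a] + cii
    M2[b, a] <- M2[b, a] - cii
    M2[a, b] <- M2[a, b] - cii
    M2[b, b] <- M2[b, b] + cii
    Q2 <- macro_Q(M2)
    accept <- if (Q2 >= Q) TRUE else stats::runif(1) < exp((Q2 - Q) * s)
    if (accept) {
      M <- M2; Q <- Q2
      sizes[a] <- sizes[a] - 1L; sizes[b] <- sizes[b] + 1L
      Z[i, a] <- 0; Z[i, b] <- 1
      z[i] <- b
      if (Q > best_Q) { best_Q <- Q; best_z <- z }
    }
  }
  list(Q = best_Q, z = best_z)
}

# relabel macrostates by order of smallest contained microstate
canonical_assignment <- function(z) {
  first_seen <- unique(z)
  match(z, first_seen)
}

#' Exhaustive optimal lumping (oracle for small problems)
#'
#' Enumerates every partition of the K microstates into exactly L non-empty
#' macrostates (restricted growth strings; S(K, L) partitions) and returns
#' the metastability-maximizing one. Refuses when the Stirling search space
#' exceeds 1e6. Ties are broken toward the lexicographically smallest
#' canonical assignment.
#'
#' @inheritParams anneal_lump
#' @return A `lumping_result` with `method = "exhaustive"`.
#' @export
exhaustive_lump <- function(counts, L) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  L <- as.integer(L)
  if (L > K || L < 1L) stop("require 1 <= L <= K", call. = FALSE)
  n_part <- stirling2(K, L)
  if (n_part > 1e6) {
    stop(sprintf("exhaustive search space S(%d, %d) = %s exceeds 1e6",
                 K, L, format(n_part, big.mark = ",")), call. = FALSE)
  }
  best_Q <- -Inf; best_z <- NULL; n_seen <- 0L
  enumerate_partitions(K, L, function(z) {
    n_seen <<- n_seen + 1L
    Q <- macro_Q(lump_counts(counts, z, L))
    if (Q > best_Q + 1e-15 ||
        (abs(Q - best_Q) <= 1e-15 && !is.null(best_z) &&
         lex_less(z, best_z))) {
      best_Q <<- Q; best_z <<- z
    }
  })
  new_lumping_result(best_z, best_Q, trace = NULL, seed = NULL,
                     method = "exhaustive", extra = list(n_evaluated = n_seen))
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

stirling2 <- function(n, k) {
  S <- matrix(0, n + 1, k + 1)
  S[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
    }
  }
  S[n + 1, k + 1]
}

# enumerate set partitions of 1..K into exactly L blocks as canonical
# (restricted-growth) assignments; calls fn(z) for each
enumerate_partitions <- function(K, L, fn) {
  z <- integer(K)
  recurse <- function(i, maxlab) {
    if (i > K) {
      if (maxlab == L) fn(z)
      return(invisible(NULL))
    }
    # prune: the remaining K - i positions can introduce at most K - i new labels
    for (lab in seq_len(min(maxlab + 1L, L))) {
      z[i] <<- lab
      new_max <- max(maxlab, lab)
      if (new_max + (K - i) >= L) recurse(i + 1L, new_max)
    }
  }
  recurse(1L, 0L)
  invisible(NULL)
}

#' Serialize a lumping result to JSON
#'
#' @param result a `lumping_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lumping_json <- function(result, path) {
  jsonlite::write_json(
    list(assignment = result$assignment, Q = result$Q, L = result$L,
         method = result$method, seed = result$seed,
         restart_best_Q = result$trace),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
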