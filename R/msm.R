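# Transition counting, column-stochastic transition matrices, population
# propagation, and metastability.
#
# Orientation note: T is COLUMN-stochastic here -- entry T[i, j] is the
# probability of moving j -> i, and populations evolve as P(n tau) =
# T(tau)^n P(0). Many MSM codes use the row-stochastic transpose.

#' Label sequences from clusterings or vectors
#'
#' Bundles per-trajectory integer label sequences so that transition counting
#' never crosses a trajectory boundary. [tidy()] on a clustering object
#' yields a table convertible with [label_sequences()].
#'
#' @param labels either a `clustering`/`product_clustering` object, a tibble
#'   with `trajectory_id` and `label` columns (frame order preserved), or a
#'   plain integer vector (one trajectory).
#' @return List of integer vectors, one per trajectory, class
#'   `label_sequences`.
#' @export
label_sequences <- function(labels) {
  if (inherits(labels, "clustering") || inherits(labels, "product_clustering")) {
    labels <- tidy(labels)
  }
  seqs <- if (is.data.frame(labels)) {
    unname(split(as.integer(labels$label), factor(labels$trajectory_id,
                                                  levels = unique(labels$trajectory_id))))
  } else if (is.numeric(labels)) {
    list(as.integer(labels))
  } else if (is.list(labels)) {
    lapply(labels, as.integer)
  } else {
    stop("cannot interpret labels as label sequences", call. = FALSE)
  }
  structure(seqs, class = "label_sequences")
}

#' Count microstate transitions at a frame lag
#'
#' Sliding-window counting with stride 1: within each trajectory, every pair
#' of frames `(t, t + lag_frames)` increments `counts[to, from]` -- columns
#' index the source state, matching the column-stochastic convention. No
#' pairs are counted across trajectory boundaries.
#'
#' @param seqs labels in any form accepted by [label_sequences()].
#' @param K number of states (labels must lie in 1..K).
#' @param lag_frames positive integer lag in frames.
#' @return `K x K` integer count matrix (`counts[i, j]` = observed j -> i).
#' @examples
#' count_transitions(c(1, 1, 2, 2), K = 2, lag_frames = 1)
#' @export
count_transitions <- function(seqs, K, lag_frames = 1L) {
  seqs <- label_sequences(seqs)
  K <- as.integer(K); lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("lag_frames must be a positive integer", call. = FALSE)
  C <- matrix(0L, K, K)
  for (s in seqs) {
    if (any(s < 1L | s > K)) {
      stop("labels out of range 1..K (K = ", K, ")", call. = FALSE)
    }
    len <- length(s)
    if (len <= lag_frames) next
    from <- s[seq_len(len - lag_frames)]
    to <- s[(lag_frames + 1L):len]
    tab <- table(factor(to, levels = seq_len(K)), factor(from, levels = seq_len(K)))
    C <- C + matrix(as.integer(tab), K, K)
  }
  C
}

#' Column-stochastic transition matrix from counts
#'
#' Normalizes each column of the count matrix to sum to 1. A state with no
#' outgoing observations (zero column) gets a self-loop column with a
#' warning; such states contribute 1 to the metastability and are flagged in
#' the result.
#'
#' @param counts non-negative `K x K` count matrix (`counts[i, j]` = j -> i).
#' @param lag_time lag time carried as metadata.
#' @return Object of class `transition_model`: `counts`, `T`
#'   (column-stochastic), `lag_time`, `populations` (column totals),
#'   `empty_states`.
#' @export
transition_matrix <- function(counts, lag_time = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  K <- nrow(counts)
  tot <- colSums(counts)
  empty <- which(tot == 0)
  Tm <- counts
  for (j in seq_len(K)) {
    if (tot[j] > 0) {
      Tm[, j] <- counts[, j] / tot[j]
    } else {
      Tm[, j] <- 0; Tm[j, j] <- 1
    }
  }
  if (length(empty)) {
    warning("states with no outgoing transitions given self-loop columns: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, T = Tm, lag_time = lag_time,
                 populations = tot, empty_states = empty, K = K),
            class = "transition_model")
}

#' Build a transition model directly from labels
#'
#' Convenience wrapper: [count_transitions()] then [transition_matrix()].
#'
#' @inheritParams count_transitions
#' @param lag_time physical lag (defaults to `lag_frames`).
#' @return A `transition_model`.
#' @export
estimate_msm <- function(seqs, K, lag_frames = 1L, lag_time = lag_frames) {
  transition_matrix(count_transitions(seqs, K, lag_frames), lag_time = lag_time)
}

#' @export
print.transition_model <- function(x, ...) {
  q <- metastability(x)
  cat(sprintf("<transition_model> K = %d states, lag = %g, Q = %.4f (Q/K = %.4f)\n",
              x$K, x$lag_time, q, q / x$K))
  invisible(x)
}

#' @rdname transition_matrix
#' @param x a `transition_model`.
#' @param ... unused.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  K <- x$K
  tibble::tibble(
    from = rep(seq_len(K), each = K),
    to = rep.int(seq_len(K), K),
    count = as.vector(x$counts),          # column-major: to varies fastest
    probability = as.vector(x$T)
  )
}

#' @rdname transition_matrix
#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  q <- metastability(x)
  tibble::tibble(K = x$K, lag_time = x$lag_time, total_counts = sum(x$counts),
                 Q = q, Q_normalized = q / x$K,
                 n_empty_states = length(x$empty_states))
}

#' Propagate a population vector through the model
#'
#' Computes `T^n P0` by repeated application; the result remains a
#' probability distribution.
#'
#' @param model a `transition_model`.
#' @param P0 initial probability vector over the K states (sums to 1).
#' @param n non-negative number of lag steps.
#' @return Probability vector after `n` steps.
#' @export
propagate <- function(model, P0, n) {
  stopifnot(inherits(model, "transition_model"))
  P0 <- as.numeric(P0)
  if (length(P0) != model$K || any(P0 < -1e-12) ||
      abs(sum(P0) - 1) > 1e-8) {
    stop("P0 must be a probability distribution over K states", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative", call. = FALSE)
  P <- P0
  for (i in seq_len(n)) P <- as.numeric(model$T %*% P)
  P
}

#' Metastability of a transition model
#'
#' The trace `Q = sum_i T_ii` of the column-stochastic transition matrix:
#' the expected number of states whose trajectories stay put over one lag
#' time. `Q` lies in `[0, K]`; the normalized value `Q / K` lies in `[0, 1]`
#' and equals `1/K` in expectation for dynamics-blind uniform random state
#' assignments.
#'
#' @param model a `transition_model` (or a bare column-stochastic matrix).
#' @param normalized return `Q / K` instead of `Q`.
#' @return Scalar metastability.
#' @export
metastability <- function(model, normalized = FALSE) {
  Tm <- if (inherits(model, "transition_model")) model$T else as.matrix(model)
  q <- sum(diag(Tm))
  if (normalized) q / nrow(Tm) else q
}

#' Serialize a transition model to JSON
#'
#' @param model a `transition_model`.
#' @param path output path.
#' @param state_provenance optional tibble describing each state (e.g. the
#'   solute/solvent cluster pair it came from).
#' @return `path`, invisibly.
#' @export
write_msm_json <- function(model, path, state_provenance = NULL) {
  obj <- list(K = model$K, lag_time = model$lag_time,
              counts = model$counts, transition_matrix = model$T,
              populations = model$populations,
              metastability = metastability(model),
              empty_states = model$empty_states)
  if (!is.null(state_provenance)) obj$state_provenance <- state_provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
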