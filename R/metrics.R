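# Configuration distances: Kabsch-aligned solute RMSD and Euclidean distance
# between solvent signatures.

#' Minimum RMSD after optimal rigid-body superposition
#'
#' Root-mean-square deviation between two point sets after the proper
#' rotation and translation minimizing it (Kabsch algorithm via SVD;
#' reflections excluded by forcing det(R) = +1). Degenerate sets (m < 3 or
#' collinear points) are handled by the same SVD construction, which reduces
#' to the optimal translation-only alignment when no rotation is determined.
#'
#' @param A,B numeric `m x 3` matrices with equal `m >= 1`.
#' @return Non-negative scalar RMSD.
#' @examples
#' A <- matrix(rnorm(15), 5, 3)
#' kabsch_rmsd(A, A)                        # 0
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as_coord_matrix(A, "A"); B <- as_coord_matrix(B, "B")
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows", call. = FALSE)
  m <- nrow(A)
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  H <- crossprod(Bc, Ac)              # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- Ac - Bc %*% t(R)
  sqrt(sum(diff^2) / m)
}

#' Euclidean distance between two signature vectors
#'
#' Signatures computed at different kernel widths live on different scales
#' and are rejected as incomparable.
#'
#' @param a,b numeric signature vectors of equal length (as returned by
#'   [signature_vector()], carrying a `sigma` attribute).
#' @return Non-negative scalar.
#' @export
signature_distance <- function(a, b) {
  sa <- attr(a, "sigma"); sb <- attr(b, "sigma")
  if (!is.null(sa) && !is.null(sb) && !isTRUE(all.equal(sa, sb))) {
    stop("signatures computed at different sigma are incomparable", call. = FALSE)
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("signature vectors must have equal length", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Distance functions over configurations
#'
#' Constructors for the two metrics used in the split step: solute RMSD after
#' Kabsch alignment, and Euclidean distance between solvent signatures at a
#' given kernel width.
#'
#' @param sigma kernel width for the solvent-signature metric.
#' @return Object of class `distance_function`.
#' @export
solute_rmsd_metric <- function() {
  structure(list(kind = "solute_rmsd"), class = "distance_function")
}

#' @rdname solute_rmsd_metric
#' @export
solvent_signature_metric <- function(sigma) {
  check_sigma(sigma)
  structure(list(kind = "solvent_signature", sigma = sigma),
            class = "distance_function")
}

#' @export
print.distance_function <- function(x, ...) {
  cat(sprintf("<distance_function: %s%s>\n", x$kind,
              if (x$kind == "solvent_signature") sprintf(" (sigma = %g)", x$sigma) else ""))
  invisible(x)
}

# Prepare a metric for repeated evaluation over a flattened frame set.
# Returns an environment with dist(i, j) and an evaluation counter; the
# solvent metric precomputes the signature matrix once (O(Nmn)) so each
# evaluation is O(m).
prepare_metric <- function(metric, fl) {
  stopifnot(inherits(metric, "distance_function"))
  env <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  if (metric$kind == "solute_rmsd") {
    coords <- lapply(fl$frames, function(f) f$solute)
    env$dist <- function(i, j) {
      env$n_evals <- env$n_evals + 1L
      kabsch_rmsd(coords[[i]], coords[[j]])
    }
    env$dist_one_to_many <- function(i, js) {
      env$n_evals <- env$n_evals + length(js)
      vapply(js, function(j) kabsch_rmsd(coords[[i]], coords[[j]]), numeric(1))
    }
  } else {
    S <- t(vapply(fl$frames, function(f) {
      as.numeric(signature_vector(f, metric$sigma, box = fl$box))
    }, numeric(nrow(fl$frames[[1]]$solute))))
    if (length(fl$frames) == 1L) S <- matrix(S, nrow = 1L)
    env$dist <- function(i, j) {
      env$n_evals <- env$n_evals + 1L
      sqrt(sum((S[i, ] - S[j, ])^2))
    }
    env$dist_one_to_many <- function(i, js) {
      env$n_evals <- env$n_evals + length(js)
      d <- sweep(S[js, , drop = FALSE], 2L, S[i, ])
      sqrt(rowSums(d * d))
    }
    env$signatures <- S
  }
  env
}

#' Pairwise distance matrix between all frames
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param metric a [solute_rmsd_metric()] or [solvent_signature_metric()].
#' @return Symmetric `N x N` matrix with zero diagonal.
#' @examples
#' tr <- simulate_two_basin(two_basin_params(seed = 1), n_frames = 10)
#' D <- pairwise_distances(tr, solvent_signature_metric(sigma = 1))
#' @export
pairwise_distances <- function(trajs, metric) {
  fl <- flatten_frames(trajs)
  pm <- prepare_metric(metric, fl)
  N <- length(fl$frames)
  D <- matrix(0, N, N)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      d <- pm$dist_one_to_many(i, (i + 1L):N)
      D[i, (i + 1L):N] <- d
      D[(i + 1L):N, i] <- d
    }
  }
  D
}
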