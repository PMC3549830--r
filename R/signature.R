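# Gaussian solvent signatures, the water-number observable, and PCA of
# signatures.
#
# The signature of solute atom x against the solvent point set Y is
#   f(x, Y) = sum_i K(x, y_i),  K(x, y) = exp(-||x - y||^2 / (2 sigma^2)),
# a permutation-invariant, continuous, local summary of the solvent density
# at x. The water number integrates the *normalized* kernel density over a
# cylindrical region V, giving a continuous surrogate for the count of
# solvent molecules inside V.

#' Gaussian kernel between two points
#'
#' Unnormalized: `exp(-||x - y||^2 / (2 sigma^2))`, in (0, 1].
#' Normalized: the same times `(2 pi sigma^2)^(-3/2)`, so the kernel
#' integrates to 1 over R^3 and tends to a Dirac delta as `sigma -> 0`.
#'
#' @param x,y numeric length-3 points.
#' @param sigma positive kernel width, in coordinate units.
#' @param normalized use the density-normalized kernel (default `FALSE`).
#' @return Non-negative scalar.
#' @examples
#' gaussian_kernel(c(0, 0, 0), c(0, 0, 0), sigma = 1)       # 1
#' gaussian_kernel(c(0, 0, 0), c(sqrt(2), 0, 0), sigma = 1) # exp(-1)
#' @export
gaussian_kernel <- function(x, y, sigma, normalized = FALSE) {
  check_sigma(sigma)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != 3L || length(y) != 3L || any(!is.finite(c(x, y)))) {
    stop("x and y must be finite length-3 vectors", call. = FALSE)
  }
  d2 <- sum((x - y)^2)
  k <- exp(-d2 / (2 * sigma^2))
  if (normalized) k <- k * (2 * pi * sigma^2)^(-1.5)
  k
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive finite scalar", call. = FALSE)
  }
  invisible(sigma)
}

# squared distances from one point to the rows of Y, minimum-image if box given
sqdist_point_rows <- function(x, Y, box = NULL) {
  if (nrow(Y) == 0L) return(numeric(0))
  d <- sweep(Y, 2L, x)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  rowSums(d * d)
}

#' Signature of a single solute point against the solvent
#'
#' `f(x, Y) = sum_i K(x, y_i)`: the Gaussian-kernel mass of all solvent
#' molecules seen from `x`. Invariant under permutation of the rows of `Y`;
#' an empty `Y` gives 0.
#'
#' @param x numeric length-3 solute point.
#' @param Y numeric `n x 3` solvent matrix (may have 0 rows).
#' @param sigma positive kernel width.
#' @param normalized use the normalized kernel (density units).
#' @param box optional periodic box (minimum-image distances).
#' @return Non-negative scalar.
#' @export
point_signature <- function(x, Y, sigma, normalized = FALSE, box = NULL) {
  check_sigma(sigma)
  Y <- as_coord_matrix(Y, "solvent", allow_empty = TRUE)
  # sorted summation: bit-identical results under any solvent permutation
  s <- sum(sort(exp(-sqdist_point_rows(as.numeric(x), Y, box) / (2 * sigma^2))))
  if (normalized) s <- s * (2 * pi * sigma^2)^(-1.5)
  s
}

#' Signature vector of a configuration
#'
#' The length-`m` vector `{f(x_1, Y), ..., f(x_m, Y)}` of per-solute-atom
#' solvent signatures; costs O(mn) kernel evaluations.
#'
#' @param conf a [configuration()].
#' @param sigma positive kernel width.
#' @param box optional periodic box.
#' @return Numeric vector of length `m` with attribute `sigma`.
#' @export
signature_vector <- function(conf, sigma, box = NULL) {
  stopifnot(inherits(conf, "configuration"))
  check_sigma(sigma)
  X <- conf$solute; Y <- conf$solvent
  v <- if (nrow(Y) == 0L) {
    numeric(nrow(X))
  } else {
    # m x n squared-distance matrix, vectorized
    if (is.null(box)) {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
      d2[d2 < 0] <- 0
      E <- exp(-d2 / (2 * sigma^2))
      # per-atom sorted summation keeps entries bit-identical under solvent
      # permutation (plain rowSums would depend on addition order)
      apply(E, 1L, function(r) sum(sort(r)))
    } else {
      vapply(seq_len(nrow(X)), function(i) {
        sum(sort(exp(-sqdist_point_rows(X[i, ], Y, box) / (2 * sigma^2))))
      }, numeric(1))
    }
  }
  structure(v, sigma = sigma)
}

#' Signatures of every frame in one or more trajectories
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param sigma positive kernel width.
#' @return A tibble of class `solvent_signatures`: `trajectory_id`,
#'   `frame_index`, then columns `f1..fm`. Attributes `sigma` and `matrix`
#'   (the raw `N x m` signature matrix) are attached for downstream use.
#' @examples
#' tr <- simulate_two_basin(two_basin_params(seed = 1), n_frames = 20)
#' sig <- compute_signatures(tr, sigma = 1)
#' @export
compute_signatures <- function(trajs, sigma) {
  check_sigma(sigma)
  fl <- flatten_frames(trajs)
  S <- t(vapply(fl$frames, function(f) {
    as.numeric(signature_vector(f, sigma, box = fl$box))
  }, numeric(nrow(fl$frames[[1]]$solute))))
  if (nrow(fl$info) == 1L) S <- matrix(S, nrow = 1L)
  colnames(S) <- paste0("f", seq_len(ncol(S)))
  out <- dplyr::bind_cols(fl$info, tibble::as_tibble(S))
  attr(out, "sigma") <- sigma
  attr(out, "matrix") <- S
  class(out) <- c("solvent_signatures", class(out))
  out
}

signature_matrix_of <- function(sig) {
  stopifnot(inherits(sig, "solvent_signatures"))
  M <- attr(sig, "matrix")
  if (is.null(M)) {
    M <- as.matrix(sig[grep("^f[0-9]+$", names(sig))])
  }
  M
}

#' Cylindrical integration region
#'
#' The region `V` over which the water number is integrated: the cylinder of
#' radius `radius` whose axis runs from `axis_start` to `axis_end`.
#'
#' @param axis_start,axis_end numeric length-3 endpoints of the axis
#'   (distinct).
#' @param radius positive cylinder radius.
#' @return Object of class `cylinder_region`.
#' @export
cylinder_region <- function(axis_start, axis_end, radius) {
  axis_start <- as.numeric(axis_start); axis_end <- as.numeric(axis_end)
  if (length(axis_start) != 3L || length(axis_end) != 3L ||
      any(!is.finite(c(axis_start, axis_end)))) {
    stop("axis endpoints must be finite length-3 vectors", call. = FALSE)
  }
  h <- sqrt(sum((axis_end - axis_start)^2))
  if (h <= 0) stop("degenerate cylinder: axis endpoints coincide", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop("degenerate cylinder: radius must be positive", call. = FALSE)
  }
  structure(list(axis_start = axis_start, axis_end = axis_end,
                 radius = radius, height = h),
            class = "cylinder_region")
}

# exponentially scaled modified Bessel I0(x) e^{-x}; base besselI underflows
# for very large x, where the asymptotic series applies
i0_scaled <- function(x) {
  small <- x < 1e5
  out <- numeric(length(x))
  out[small] <- besselI(x[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- (1 + 1 / (8 * xl) + 9 / (128 * xl^2)) / sqrt(2 * pi * xl)
  }
  out
}

# mass of an isotropic 2-D Gaussian (sd sigma) centered at radial offset rho,
# inside the disk of radius r about the origin: 1 - MarcumQ1(rho/s, r/s).
# Quadrature over the Rice density, written with the exponentially scaled
# Bessel I0 for numerical stability at small sigma.
disk_gaussian_mass <- function(rho, r, sigma) {
  if (rho / sigma > r / sigma + 9) return(0)       # entire disk > 9 sd away
  lo <- max(0, rho - 9 * sigma)
  hi <- min(r, rho + 9 * sigma)
  if (hi <= lo) {
    # offset point far inside: if rho + 9 sigma < r the disk holds ~all mass
    return(if (rho + 9 * sigma < r) 1 else 0)
  }
  f <- function(t) {
    (t / sigma^2) * exp(-(t - rho)^2 / (2 * sigma^2)) *
      i0_scaled(t * rho / sigma^2)
  }
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-10,
                          subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' Water number inside a cylindrical region
#'
#' Integrates the normalized-kernel solvent density over the cylinder `V`:
#' `sum_i integral_V K(x, y_i) dx`. Because the normalized 3-D Gaussian is
#' separable, each molecule contributes an axial factor (1-D Gaussian mass
#' between the two faces, a difference of error functions) times a radial
#' factor (2-D Gaussian mass in the disk, by quadrature). The value lies in
#' `[0, n]`, is continuous in every coordinate, and tends to the integer
#' count of molecules inside `V` as `sigma -> 0`; a molecule exactly on a
#' flat face contributes 1/2 in that limit.
#'
#' @param conf a [configuration()] (only the solvent is used) or an `n x 3`
#'   solvent matrix.
#' @param region a [cylinder_region()].
#' @param sigma positive kernel width (same units as the coordinates).
#' @return Non-negative scalar in `[0, n]`.
#' @export
water_number <- function(conf, region, sigma) {
  check_sigma(sigma)
  if (!inherits(region, "cylinder_region")) {
    stop("region must be a cylinder_region()", call. = FALSE)
  }
  Y <- if (inherits(conf, "configuration")) conf$solvent else
    as_coord_matrix(conf, "solvent", allow_empty = TRUE)
  if (nrow(Y) == 0L) return(0)
  u <- (region$axis_end - region$axis_start) / region$height
  rel <- sweep(Y, 2L, region$axis_start)
  a <- as.numeric(rel %*% u)                      # axial coordinate in [0, h]
  rho <- sqrt(pmax(rowSums(rel^2) - a^2, 0))      # radial offset from axis
  axial <- stats::pnorm((region$height - a) / sigma) - stats::pnorm(-a / sigma)
  radial <- vapply(rho, disk_gaussian_mass, numeric(1),
                   r = region$radius, sigma = sigma)
  sum(sort(axial * radial))   # order-canonical: permutation invariant bitwise
}

#' Water number along a trajectory
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param region a [cylinder_region()].
#' @param sigma positive kernel width.
#' @return Tibble: `trajectory_id`, `frame_index`, `water_number`.
#' @export
water_number_series <- function(trajs, region, sigma) {
  fl <- flatten_frames(trajs)
  wn <- vapply(fl$frames, water_number, numeric(1), region = region, sigma = sigma)
  dplyr::mutate(fl$info, water_number = wn)
}

#' Principal component analysis of solvent signatures
#'
#' Mean-centered (unscaled) PCA of the `N x m` signature matrix. Component
#' signs are fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param signatures a `solvent_signatures` tibble from [compute_signatures()],
#'   or a plain numeric matrix with frames as rows.
#' @param n_components number of components to keep (`<= m`).
#' @return Object of class `signature_pca`: list with `components`
#'   (`n_components x m`, orthonormal rows), `projections` (tibble of frame
#'   ids and `PC1..`), `explained_variance`, and `explained_variance_ratio`.
#' @export
pca_signatures <- function(signatures, n_components = 2L) {
  if (inherits(signatures, "solvent_signatures")) {
    M <- signature_matrix_of(signatures)
    info <- signatures[c("trajectory_id", "frame_index")]
  } else {
    M <- as.matrix(signatures)
    info <- tibble::tibble(trajectory_id = "traj", frame_index = seq_len(nrow(M)))
  }
  if (nrow(M) < 2L) stop("PCA needs at least 2 signatures", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > ncol(M)) {
    stop("n_components must be between 1 and m", call. = FALSE)
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  proj <- scale(M, center = pc$center, scale = FALSE) %*% rot
  colnames(proj) <- paste0("PC", seq_len(k))
  ev <- pc$sdev^2
  structure(list(
    components = t(rot),
    projections = dplyr::bind_cols(info, tibble::as_tibble(proj)),
    explained_variance = ev[seq_len(k)],
    explained_variance_ratio = ev[seq_len(k)] / sum(ev),
    center = pc$center,
    sigma = attr(signatures, "sigma")
  ), class = "signature_pca")
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf("<signature_pca> %d components over %d signature dimensions\n",
              nrow(x$components), ncol(x$components)))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_signatures
#' @param x a `signature_pca` object.
#' @param ... unused.
#' @method tidy signature_pca
#' @export
tidy.signature_pca <- function(x, ...) x$projections

#' @rdname pca_signatures
#' @method glance signature_pca
#' @export
glance.signature_pca <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    m = ncol(x$components),
    total_explained_ratio = sum(x$explained_variance_ratio)
  )
}

#' Write signatures to TSV
#'
#' @param signatures `solvent_signatures` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(signatures, path) {
  utils::write.table(as.data.frame(signatures), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
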