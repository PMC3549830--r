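# Synthetic trajectory generators with known metastable structure.
#
# Two stand-ins for the systems the method targets: a single-file
# channel-filling lattice model (nanopore hydration: sharp empty/full
# transitions, molecules entering and leaving only at the channel ends) and
# a two-basin solute-plus-solvent model (a small solute hopping between two
# conformations, each with its own mean solvent arrangement).

#' Parameters of the single-file channel model
#'
#' The channel holds `n_sites` lattice sites along its axis. Occupancy is
#' always a contiguous block of filled sites anchored at the left or right
#' end (or empty, or full): molecules enter and leave only at the channel
#' ends, so a left-filling chain cannot become right-filling without passing
#' through empty or full. Per frame, an empty channel starts filling from
#' either end with probability `p_enter` each; a partial block grows by one
#' site (probability `p_enter`) or shrinks by one (probability `p_exit`); a
#' full channel starts emptying from either end with probability `p_exit`
#' each.
#'
#' @param n_sites sites along the channel axis (default 6).
#' @param p_enter per-frame entry probability at an available end.
#' @param p_exit per-frame exit probability at an available end.
#' @param site_spacing distance between adjacent sites (length units).
#' @param tube_radius radius of the solute tube wall.
#' @param n_bath bath waters placed outside the tube (re-drawn each frame).
#' @param init initial occupancy: `"empty"`, `"full"`, or a chain state id.
#' @param seed integer RNG seed.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(n_sites = 6L, p_enter = 0.02, p_exit = 0.02,
                           site_spacing = 1, tube_radius = 1, n_bath = 30L,
                           init = "empty", seed = 1L) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 2L, site_spacing > 0, tube_radius > 0, n_bath >= 0L)
  if (p_enter < 0 || p_exit < 0 || 2 * p_enter > 1 || 2 * p_exit > 1 ||
      p_enter + p_exit > 1) {
    stop("need p_enter, p_exit >= 0 with 2*p_enter <= 1, 2*p_exit <= 1 and p_enter + p_exit <= 1",
         call. = FALSE)
  }
  structure(list(n_sites = n_sites, p_enter = p_enter, p_exit = p_exit,
                 site_spacing = site_spacing, tube_radius = tube_radius,
                 n_bath = as.integer(n_bath), init = init,
                 seed = as.integer(seed)),
            class = "channel_params")
}

#' Chain states and analytic transition matrix of the channel model
#'
#' The occupancy chain has `2 n_sites` states arranged in a ring:
#' empty, left-filled 1..n-1, full, right-filled n-1..1. Returns the exact
#' column-stochastic single-frame transition matrix together with a state
#' table (occupancy count, filling side, and the 4-way category
#' empty/full/left/right used for coarse models).
#'
#' @param params a [channel_params()].
#' @return List with `T` (column-stochastic `2n x 2n`), `states` tibble
#'   (`state`, `label`, `side`, `occupancy`, `category`), and `n_states`.
#' @export
channel_chain <- function(params) {
  stopifnot(inherits(params, "channel_params"))
  n <- params$n_sites
  pe <- params$p_enter; px <- params$p_exit
  # state ids: 1 = empty; 1+k = left-k (k = 1..n-1); n+k = right-k; 2n = full
  S <- 2L * n
  id_empty <- 1L; id_full <- 2L * n
  id_left <- function(k) 1L + k
  id_right <- function(k) n + k
  lab <- character(S); side <- character(S); occ <- integer(S)
  lab[id_empty] <- "empty"; side[id_empty] <- "none"; occ[id_empty] <- 0L
  lab[id_full] <- "full"; side[id_full] <- "both"; occ[id_full] <- n
  for (k in seq_len(n - 1L)) {
    lab[id_left(k)] <- paste0("L", k); side[id_left(k)] <- "left"
    occ[id_left(k)] <- k
    lab[id_right(k)] <- paste0("R", k); side[id_right(k)] <- "right"
    occ[id_right(k)] <- k
  }
  Tm <- matrix(0, S, S)
  add <- function(from, to, p) Tm[to, from] <<- Tm[to, from] + p
  add(id_empty, id_left(1L), pe)
  add(id_empty, id_right(1L), pe)
  add(id_empty, id_empty, 1 - 2 * pe)
  add(id_full, if (n > 1L) id_left(n - 1L) else id_empty, px)
  add(id_full, if (n > 1L) id_right(n - 1L) else id_empty, px)
  add(id_full, id_full, 1 - 2 * px)
  for (k in seq_len(n - 1L)) {
    up_l <- if (k + 1L == n) id_full else id_left(k + 1L)
    dn_l <- if (k == 1L) id_empty else id_left(k - 1L)
    add(id_left(k), up_l, pe); add(id_left(k), dn_l, px)
    add(id_left(k), id_left(k), 1 - pe - px)
    up_r <- if (k + 1L == n) id_full else id_right(k + 1L)
    dn_r <- if (k == 1L) id_empty else id_right(k - 1L)
    add(id_right(k), up_r, pe); add(id_right(k), dn_r, px)
    add(id_right(k), id_right(k), 1 - pe - px)
  }
  category <- ifelse(lab == "empty", "empty",
              ifelse(lab == "full", "full",
              ifelse(side == "left", "left", "right")))
  list(T = Tm,
       states = tibble::tibble(state = seq_len(S), label = lab, side = side,
                               occupancy = occ, category = category),
       n_states = S)
}

# site z-coordinates, centered on the origin
channel_site_z <- function(params) {
  n <- params$n_sites
  (seq_len(n) - (n + 1) / 2) * params$site_spacing
}

#' Cylindrical region spanned by the channel sites
#'
#' The integration region whose flat faces pass exactly through the first and
#' last site positions, so that in a full channel the two end molecules sit
#' on the boundary and each contributes about 1/2 to the water number.
#'
#' @param params a [channel_params()].
#' @return A [cylinder_region()] along the channel axis at the tube radius.
#' @export
channel_region <- function(params) {
  z <- channel_site_z(params)
  cylinder_region(c(0, 0, z[1L]), c(0, 0, z[length(z)]), params$tube_radius)
}

occupied_sites <- function(state, n) {
  if (state == 1L) return(integer(0))
  if (state == 2L * n) return(seq_len(n))
  if (state <= n) return(seq_len(state - 1L))            # left-k, k = state - 1
  k <- state - n                                          # right-k
  (n - k + 1L):n
}

#' Simulate the channel-filling model
#'
#' Evolves the occupancy chain of [channel_chain()] for `n_frames` steps and
#' renders each occupancy as a [configuration()]: the solute is a fixed tube
#' of 8-atom carbon rings (one ring per site); the solvent comprises one
#' water at each occupied site plus the remaining waters placed in a bath
#' shell outside the tube, re-drawn every frame. The total solvent count
#' `n_sites + n_bath` is constant. The hidden chain state of every frame is
#' attached as `attr(, "hidden_states")`, with the state table as
#' `attr(, "state_table")`.
#'
#' @param params a [channel_params()].
#' @param n_frames number of frames.
#' @param lag_time frame interval metadata.
#' @return A [trajectory()] with ground-truth attributes.
#' @examples
#' tr <- simulate_channel(channel_params(seed = 42), n_frames = 100)
#' table(attr(tr, "hidden_states"))
#' @export
simulate_channel <- function(params, n_frames, lag_time = 1) {
  stopifnot(inherits(params, "channel_params"))
  chain <- channel_chain(params)
  n <- params$n_sites
  z <- channel_site_z(params)
  # solute: ring of 8 atoms at each site
  ring_angles <- seq(0, 2 * pi, length.out = 9L)[-9L]
  solute <- do.call(rbind, lapply(z, function(zz) {
    cbind(params$tube_radius * cos(ring_angles),
          params$tube_radius * sin(ring_angles), zz)
  }))
  half_extent <- sqrt(max(z)^2 + params$tube_radius^2)
  r_in <- half_extent + 2 * params$site_spacing
  r_out <- r_in + 3 * params$site_spacing
  init_state <- if (identical(params$init, "empty")) 1L
    else if (identical(params$init, "full")) 2L * n
    else as.integer(params$init)
  n_solvent <- n + params$n_bath

  with_local_seed(params$seed, {
    states <- integer(n_frames)
    s <- init_state
    for (t in seq_len(n_frames)) {
      states[t] <- s
      s <- sample.int(chain$n_states, 1L, prob = chain$T[, s])
    }
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      occ <- occupied_sites(states[t], n)
      tube_waters <- if (length(occ)) {
        cbind(0, 0, z[occ])
      } else {
        matrix(numeric(0), 0L, 3L)
      }
      n_out <- n_solvent - length(occ)
      # uniform in the spherical shell [r_in, r_out]
      u <- matrix(stats::rnorm(3L * n_out), n_out, 3L)
      u <- u / sqrt(rowSums(u^2))
      rr <- (stats::runif(n_out) * (r_out^3 - r_in^3) + r_in^3)^(1 / 3)
      bath <- u * rr
      frames[[t]] <- configuration(solute, rbind(tube_waters, bath),
                                   frame_index = t)
    }
    tr <- trajectory(frames, lag_time = lag_time, trajectory_id = "channel")
    attr(tr, "hidden_states") <- states
    attr(tr, "state_table") <- chain$states
    tr
  })
}

#' Parameters of the two-basin solute-plus-solvent model
#'
#' A hidden basin label follows a symmetric 2-state Markov chain with
#' per-frame switch probability `hop_probability`. The solute is the current
#' basin's reference structure plus isotropic Gaussian noise; the solvent is
#' a fixed base cloud displaced by a basin-dependent mean shift (basin 1
#' gets `-solvent_shift / 2`, basin 2 `+solvent_shift / 2`) plus isotropic
#' noise. The ratio `|solvent_shift| / solvent_noise` controls how separable
#' the basins are from the solvent alone.
#'
#' @param basin_centers list of two `m x 3` reference solute structures;
#'   default: a 10-atom extended chain vs the same chain bent by 90 degrees.
#' @param hop_probability per-frame basin switch probability, in (0, 0.5).
#' @param solute_noise sd of solute coordinate noise.
#' @param n_solvent number of solvent molecules.
#' @param solvent_shift length-3 mean solvent displacement between basins.
#' @param solvent_noise sd of solvent coordinate noise.
#' @param cloud_radius radius of the base solvent cloud.
#' @param seed integer RNG seed.
#' @return Object of class `two_basin_params`.
#' @export
two_basin_params <- function(basin_centers = NULL, hop_probability = 0.02,
                             solute_noise = 0.1, n_solvent = 40L,
                             solvent_shift = c(5, 0, 0), solvent_noise = 1,
                             cloud_radius = 6, seed = 1L) {
  if (is.null(basin_centers)) {
    m <- 10L
    straight <- cbind((seq_len(m) - (m + 1) / 2) * 1.5, 0, 0)
    half <- m %/% 2L
    bent <- straight
    # fold the second half upward by 90 degrees about the chain midpoint
    pivot <- straight[half, ]
    for (i in (half + 1L):m) {
      d <- straight[i, ] - pivot
      bent[i, ] <- pivot + c(0, d[1], d[3])
    }
    basin_centers <- list(straight, bent)
  }
  stopifnot(length(basin_centers) == 2L)
  if (!(hop_probability > 0 && hop_probability < 0.5)) {
    stop("hop_probability must lie in (0, 0.5)", call. = FALSE)
  }
  stopifnot(solute_noise >= 0, solvent_noise >= 0, n_solvent >= 1L,
            cloud_radius > 0, length(solvent_shift) == 3L)
  structure(list(basin_centers = lapply(basin_centers, as_coord_matrix, what = "basin"),
                 hop_probability = hop_probability, solute_noise = solute_noise,
                 n_solvent = as.integer(n_solvent),
                 solvent_shift = as.numeric(solvent_shift),
                 solvent_noise = solvent_noise, cloud_radius = cloud_radius,
                 seed = as.integer(seed)),
            class = "two_basin_params")
}

#' Simulate the two-basin model
#'
#' @param params a [two_basin_params()].
#' @param n_frames number of frames.
#' @param lag_time frame interval metadata.
#' @return A [trajectory()]; hidden basin labels (1 or 2) are attached as
#'   `attr(, "hidden_states")`.
#' @examples
#' tr <- simulate_two_basin(two_basin_params(seed = 3), n_frames = 200)
#' mean(attr(tr, "hidden_states") == 1)
#' @export
simulate_two_basin <- function(params, n_frames, lag_time = 1) {
  stopifnot(inherits(params, "two_basin_params"))
  m <- nrow(params$basin_centers[[1L]])
  n <- params$n_solvent
  with_local_seed(params$seed, {
    # fixed base cloud, uniform in a sphere
    u <- matrix(stats::rnorm(3L * n), n, 3L)
    u <- u / sqrt(rowSums(u^2))
    base_cloud <- u * (stats::runif(n)^(1 / 3) * params$cloud_radius)

    basins <- integer(n_frames)
    basins[1L] <- sample(1:2, 1L)
    hops <- stats::runif(n_frames - 1L) < params$hop_probability
    for (t in seq_len(n_frames - 1L)) {
      basins[t + 1L] <- if (hops[t]) 3L - basins[t] else basins[t]
    }
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      b <- basins[t]
      solute <- params$basin_centers[[b]] +
        matrix(stats::rnorm(3L * m, sd = params$solute_noise), m, 3L)
      shift <- params$solvent_shift * (if (b == 1L) -0.5 else 0.5)
      solvent <- sweep(base_cloud, 2L, -shift) +
        matrix(stats::rnorm(3L * n, sd = params$solvent_noise), n, 3L)
      frames[[t]] <- configuration(solute, solvent, frame_index = t)
    }
    tr <- trajectory(frames, lag_time = lag_time, trajectory_id = "two_basin")
    attr(tr, "hidden_states") <- basins
    tr
  })
}

#' Write ground-truth hidden states to TSV
#'
#' @param traj a trajectory from [simulate_channel()] or
#'   [simulate_two_basin()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(traj, path) {
  hs <- attr(traj, "hidden_states")
  if (is.null(hs)) stop("trajectory carries no hidden states", call. = FALSE)
  utils::write.table(
    data.frame(frame_index = seq_along(hs), hidden_state = hs),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Agreement between cluster labels and hidden ground truth (2 states)
#'
#' Fraction of frames on which a 2-way clustering matches the hidden basin
#' labels, maximized over the two possible relabelings.
#'
#' @param labels integer cluster labels (values 1, 2).
#' @param truth integer hidden labels (values 1, 2).
#' @return Agreement fraction in [0.5, 1].
#' @export
label_agreement <- function(labels, truth) {
  labels <- as.integer(labels); truth <- as.integer(truth)
  stopifnot(length(labels) == length(truth))
  a <- mean(labels == truth)
  max(a, 1 - a)
}
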