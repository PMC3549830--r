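# End-to-end pipeline: read/simulate -> signatures -> split -> count ->
# transition matrix -> (optional) lump, with a reproducible run manifest.

#' Configuration for an end-to-end MSM run
#'
#' Validates all stage parameters before any computation. Three model types
#' are supported: `"solute"` (RMSD metric only, `K2 = 1`), `"solvent"`
#' (signature metric only, `K1 = 1`), and `"combined"` (product clustering
#' with `K1 * K2 >= K`).
#'
#' @param model `"solute"`, `"solvent"` or `"combined"`.
#' @param K number of microstates.
#' @param sigma kernel width for the solvent signature (required unless
#'   `model = "solute"`).
#' @param K1,K2 solute/solvent cluster counts for the combined model;
#'   defaults `ceiling(sqrt(K))`. Forced to `(K, 1)` for the solute model and
#'   `(1, K)` for the solvent model.
#' @param L number of macrostates for lumping; `NULL` skips the lump step.
#' @param lag_frames integer transition-counting lag.
#' @param steps,restarts simulated-annealing budget.
#' @param seed master seed for every stochastic stage.
#' @param mode product-clustering mode (`"global"` or `"nested"`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = c("combined", "solute", "solvent"),
                       K, sigma = NULL, K1 = NULL, K2 = NULL, L = NULL,
                       lag_frames = 1L, steps = 10000L, restarts = 100L,
                       seed = 1L, mode = c("global", "nested")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  K <- as.integer(K)
  if (K < 1L) stop("K must be positive", call. = FALSE)
  if (model == "solute") {
    K1 <- K; K2 <- 1L
  } else if (model == "solvent") {
    K1 <- 1L; K2 <- K
  } else {
    K1 <- as.integer(K1 %||% ceiling(sqrt(K)))
    K2 <- as.integer(K2 %||% ceiling(sqrt(K)))
    if (K1 * K2 < K) stop("K1 * K2 < K: infeasible combination model", call. = FALSE)
  }
  if (model != "solute") check_sigma(sigma)
  if (!is.null(L)) {
    L <- as.integer(L)
    if (L < 1L || L > K) stop("L must lie in 1..K", call. = FALSE)
  }
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("lag_frames must be positive", call. = FALSE)
  structure(list(model = model, K = K, K1 = K1, K2 = K2, L = L,
                 sigma = sigma, lag_frames = lag_frames,
                 steps = as.integer(steps), restarts = as.integer(restarts),
                 seed = as.integer(seed), mode = mode),
            class = "run_config")
}

#' Run the full split/count/lump pipeline on trajectories
#'
#' Executes the model selected in the [run_config()]: geometric splitting
#' into `K` microstates (solute RMSD, solvent signatures, or their product),
#' transition counting at the configured lag, column-stochastic transition
#' matrix estimation, and -- when `L` is set -- metastability-maximizing
#' lumping into `L` macrostates. Reports normalized metastability for the
#' split (`Q/K`) and lumped (`Q/L`) models next to the `1/K` (`1/L`) random
#' baselines, and a manifest recording every parameter and seed.
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, label tables (TSV),
#'   models (JSON) and the manifest (JSON) are written there.
#' @return Object of class `msm_run`: `clustering`, `micro_model`,
#'   `lumping`, `macro_model` (when lumped), `manifest`.
#' @examples
#' tr <- simulate_two_basin(two_basin_params(seed = 5), n_frames = 300)
#' run <- run_pipeline(tr, run_config("solvent", K = 4, sigma = 2, L = 2,
#'                                    steps = 500, restarts = 5, seed = 5))
#' glance(run)
#' @export
run_pipeline <- function(trajs, config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  trajs <- as_traj_list(trajs)
  N <- n_frames(trajs)
  if (config$K > N) stop("K exceeds the number of frames", call. = FALSE)

  solvent_metric <- if (config$model != "solute") {
    solvent_signature_metric(config$sigma)
  }
  cl <- switch(config$model,
    solute = k_center(trajs, config$K, solute_rmsd_metric(), seed = config$seed),
    solvent = k_center(trajs, config$K, solvent_metric, seed = config$seed),
    combined = product_split(trajs, config$K, config$K1, config$K2,
                             solute_rmsd_metric(), solvent_metric,
                             seed = config$seed, mode = config$mode)
  )
  micro <- estimate_msm(cl, config$K, lag_frames = config$lag_frames,
                        lag_time = config$lag_frames * trajs[[1]]$lag_time)
  lump <- NULL; macro <- NULL
  if (!is.null(config$L)) {
    lump <- anneal_lump(micro$counts, config$L, steps = config$steps,
                        restarts = config$restarts, seed = config$seed)
    macro <- transition_matrix(
      lump_counts(micro$counts, lump$assignment, config$L),
      lag_time = micro$lag_time)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("solvmsm")),
    model = config$model, K = config$K,
    K1 = if (inherits(cl, "product_clustering")) cl$K1 else config$K1,
    K2 = if (inherits(cl, "product_clustering")) cl$K2 else config$K2,
    L = config$L, sigma = config$sigma, lag_frames = config$lag_frames,
    anneal_steps = config$steps, anneal_restarts = config$restarts,
    seed = config$seed, mode = config$mode, n_frames = N,
    n_trajectories = length(trajs),
    trajectory_ids = vapply(trajs, function(t) t$trajectory_id, character(1)),
    split_metric_evals = if (inherits(cl, "product_clustering"))
      cl$split_metric_evals else cl$n_metric_evals,
    Q_split = metastability(micro), Q_split_normalized = metastability(micro) / config$K,
    random_baseline_split = 1 / config$K,
    Q_lumped = if (!is.null(macro)) metastability(macro),
    Q_lumped_normalized = if (!is.null(macro)) metastability(macro) / config$L,
    random_baseline_lumped = if (!is.null(config$L)) 1 / config$L
  )
  run <- structure(list(clustering = cl, micro_model = micro, lumping = lump,
                        macro_model = macro, manifest = manifest,
                        config = config),
                   class = "msm_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(tidy(run$clustering)),
                     file.path(output_dir, "microstate_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_msm_json(run$micro_model, file.path(output_dir, "micro_model.json"),
                 state_provenance = if (inherits(run$clustering, "product_clustering"))
                   run$clustering$states)
  if (!is.null(run$lumping)) {
    write_lumping_json(run$lumping, file.path(output_dir, "lumping.json"))
    write_msm_json(run$macro_model, file.path(output_dir, "macro_model.json"))
  }
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(output_dir)
}

#' @export
print.msm_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<msm_run> %s model: K = %d microstates, Q/K = %.4f (baseline %.4f)\n",
              m$model, m$K, m$Q_split_normalized, m$random_baseline_split))
  if (!is.null(m$Q_lumped)) {
    cat(sprintf("  lumped to L = %d macrostates, Q/L = %.4f (baseline %.4f)\n",
                m$L, m$Q_lumped_normalized, m$random_baseline_lumped))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `msm_run`.
#' @param ... unused.
#' @method tidy msm_run
#' @export
tidy.msm_run <- function(x, ...) {
  out <- tidy(x$clustering)
  if (!is.null(x$lumping)) {
    out$macrostate <- x$lumping$assignment[out$label]
  }
  out
}

#' @rdname run_pipeline
#' @method glance msm_run
#' @export
glance.msm_run <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    model = m$model, K = m$K, K1 = m$K1, K2 = m$K2,
    L = m$L %||% NA_integer_,
    Q_split = m$Q_split, Q_split_normalized = m$Q_split_normalized,
    Q_lumped = m$Q_lumped %||% NA_real_,
    Q_lumped_normalized = m$Q_lumped_normalized %||% NA_real_,
    split_metric_evals = m$split_metric_evals,
    n_frames = m$n_frames, seed = m$seed
  )
}
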