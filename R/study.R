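# End-to-end study runs: train unit simulators + assembly on a generated
# data bundle, roll out on held-out networks, and report the range-normalized
# error and interface diagnostics.

#' Train the full surrogate pipeline on a generated data bundle
#'
#' Trains the pipe and bifurcation simulators on their unit datasets, builds
#' the assembly dataset from the training networks' intermediate predictions
#' and trains the assembly model (one model per requested \code{alpha}).
#' Networks are split (seeded) into training and held-out sets.
#'
#' @param data output of \code{\link{generate_transport_data}}.
#' @param seed root seed for this pipeline run (splits, initialization,
#'   batching).
#' @param epochs training epochs for simulators and assembly.
#' @param loss_mode simulator loss mode.
#' @param alphas assembly penalty strengths to train (one model each).
#' @param holdout_fraction fraction of networks held out for evaluation.
#' @return list with \code{simulators}, \code{assemblies} (named by alpha),
#'   \code{train_nets}, \code{eval_nets} and the configs used.
#' @export
train_pipeline <- function(data, seed = 1, epochs = 50L,
                           loss_mode = "mse+pde", alphas = 10,
                           holdout_fraction = 0.25) {
  n_nets <- length(data$networks)
  eval_nets <- with_seed(seed, {
    sort(sample.int(n_nets, max(1L, round(holdout_fraction * n_nets))))
  })
  train_nets <- setdiff(seq_len(n_nets), eval_nets)
  cfg <- training_config(epochs = epochs, seed = seed, loss_mode = loss_mode)
  simulators <- lapply(data$datasets, function(ds) {
    # keep only samples from training networks
    keep <- which(vapply(ds$index$geo, function(gi) {
      ds$geos[[gi]]$net %in% train_nets
    }, TRUE))
    test_idx <- with_seed(seed + 1L,
                          sort(sample(keep, round(0.25 * length(keep)))))
    train_simulator(ds, cfg, train_idx = setdiff(keep, test_idx),
                    test_idx = test_idx)
  })
  adata <- build_assembly_dataset(data, simulators, net_idx = train_nets)
  assemblies <- lapply(alphas, function(a) {
    train_assembly(adata, cfg, alpha = a)
  })
  names(assemblies) <- as.character(alphas)
  list(simulators = simulators, assemblies = assemblies,
       train_nets = train_nets, eval_nets = eval_nets, config = cfg)
}

#' Evaluate a trained pipeline on held-out networks
#'
#' Rolls out the simulators + assembly on each held-out network for a subset
#' of boundary values, against reference-solver trajectories.
#'
#' @param pipeline output of \code{\link{train_pipeline}}.
#' @param data the data bundle the pipeline was trained on.
#' @param alpha which trained assembly to use (name in
#'   \code{pipeline$assemblies}); \code{NA} evaluates without assembly.
#' @param n_bc number of boundary values per network (evenly spread over the
#'   sweep).
#' @param n_steps rollout length (default: the bundle's trajectory length).
#' @return list with \code{mre} (mean over rollouts of the per-step MRE),
#'   \code{per_rollout}, and mean interface gaps before/after assembly.
#' @export
evaluate_pipeline <- function(pipeline, data, alpha = "10", n_bc = 2L,
                              n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- data$manifest$n_steps
  asm <- if (is.na(alpha)) NULL else pipeline$assemblies[[as.character(alpha)]]
  bcs <- data$c_in_values[unique(round(seq(1, length(data$c_in_values),
                                           length.out = n_bc)))]
  rows <- list()
  for (ni in pipeline$eval_nets) {
    for (ci in bcs) {
      ev <- evaluate_network_rollout(pipeline$simulators, asm, data, ni, ci,
                                     n_steps)
      gp <- ev$gaps
      rows[[length(rows) + 1L]] <- data.frame(
        net = ni, c_in = ci, mre = ev$mean,
        gap_pre = mean(gp[, "pre"], na.rm = TRUE),
        gap_post = mean(gp[, "post"], na.rm = TRUE))
    }
  }
  per <- do.call(rbind, rows)
  list(mre = mean(per$mre), per_rollout = per,
       gap_pre = mean(per$gap_pre), gap_post = mean(per$gap_post))
}
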