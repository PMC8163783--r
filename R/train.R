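# Dataset construction from solver trajectories, simulator training with the
# physics-informed loss, cross-validation, and the error metrics.

#' Training configuration
#'
#' @param epochs training epochs.
#' @param lr,lr_min initial and final learning rate of the decade step decay
#'   (drops by 10x at evenly spaced milestones spanning the range).
#' @param batch_size samples per within-geometry batch.
#' @param seed root seed for splitting, initialization and batching.
#' @param loss_mode \code{"mse+pde"} (MSE plus PDE-residual terms) or
#'   \code{"mse"}.
#' @param noise_sd standard deviation of the Gaussian perturbation added to
#'   input concentrations (normalized units) during training; optional
#'   robustness augmentation for autoregressive rollouts.
#' @param test_fraction held-out fraction for the train/test split.
#' @param pde_weight multiplier on the PDE-residual terms (1 as printed in
#'   the governing loss; 0 reduces the \code{"mse+pde"} mode to plain MSE).
#' @export
training_config <- function(epochs = 50L, lr = 1e-3, lr_min = 1e-6,
                            batch_size = 50L, seed = 1L,
                            loss_mode = c("mse+pde", "mse"),
                            noise_sd = 0, test_fraction = 0.25,
                            pde_weight = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1,
            test_fraction >= 0, test_fraction < 1, pde_weight >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_min = lr_min,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_mode = loss_mode, noise_sd = noise_sd,
                 test_fraction = test_fraction, pde_weight = pde_weight),
            class = "training_config")
}

new_transport_dataset <- function(kind, geos, blocks, params, manifest) {
  idx <- do.call(rbind, lapply(seq_along(geos), function(i) {
    data.frame(geo = i, col = seq_len(ncol(blocks[[i]]$prev)))
  }))
  structure(list(kind = kind, geos = geos, blocks = blocks, params = params,
                 manifest = manifest, index = idx),
            class = "transport_dataset")
}

#' @export
print.transport_dataset <- function(x, ...) {
  cat("Transport dataset (", x$kind, "): ", length(x$geos), " geometries, ",
      nrow(x$index), " samples\n", sep = "")
  invisible(x)
}

# indices of the sampled consecutive-state pairs
pick_pairs <- function(n_steps, pairs_per_trajectory) {
  if (is.null(pairs_per_trajectory)) return(seq_len(n_steps))
  unique(round(seq(1, n_steps, length.out = pairs_per_trajectory)))
}

#' Build a one-step training dataset from solver trajectories
#'
#' One sample per (selected) consecutive state pair per trajectory, with
#' concentrations normalized by each trajectory's inlet concentration. The
#' manifest records the generation choices.
#'
#' @param trajectories list of \code{list(graph =, trajectory =, c_in =)}
#'   entries, all of the same unit kind.
#' @param unit_kind \code{"pipe"} or \code{"bifurcation"}.
#' @param params \code{simulation_params} used to produce the trajectories.
#' @param pairs_per_trajectory number of consecutive-state pairs kept per
#'   trajectory (evenly spread; \code{NULL} keeps all pairs).
#' @return a \code{"transport_dataset"}.
#' @export
build_dataset <- function(trajectories, unit_kind, params,
                          pairs_per_trajectory = NULL) {
  keep <- vapply(trajectories, function(tr) {
    ok <- length(tr$trajectory$times) >= 2L
    if (!ok) warning("skipping a trajectory with fewer than 2 states")
    ok
  }, TRUE)
  trajectories <- trajectories[keep]
  if (!length(trajectories)) stop("no usable trajectories")
  geos <- list(); blocks <- list()
  gkey <- character(0)
  for (tr in trajectories) {
    g <- tr$graph
    key <- sprintf("%d:%.17g:%.17g", g$n, sum(g$pos), sum(g$pos^2))
    gi <- match(key, gkey)
    if (is.na(gi)) {
      gkey <- c(gkey, key)
      gi <- length(gkey)
      geos[[gi]] <- list(g = g, geo = gnn_geometry(g, params))
      blocks[[gi]] <- list(prev = NULL, nxt = NULL, c_in = numeric(0))
    }
    T <- length(tr$trajectory$times)
    ks <- pick_pairs(T - 1L, pairs_per_trajectory)
    cs <- tr$c_in %||% params$c_in
    st <- rbind(tr$trajectory$c0, tr$trajectory$c_plus) / cs
    blocks[[gi]]$prev <- cbind(blocks[[gi]]$prev, st[, ks, drop = FALSE])
    blocks[[gi]]$nxt <- cbind(blocks[[gi]]$nxt, st[, ks + 1L, drop = FALSE])
    blocks[[gi]]$c_in <- c(blocks[[gi]]$c_in, rep(cs, length(ks)))
  }
  new_transport_dataset(unit_kind, geos, blocks, params,
                        manifest = list(
                          n_trajectories = length(trajectories),
                          pairs_per_trajectory = pairs_per_trajectory))
}

# imposed-node row indices for a column-major (node, sample) stacking
imposed_rows <- function(geo, k) {
  if (!length(geo$imposed)) return(integer(0))
  as.vector(outer(geo$imposed, (seq_len(k) - 1L) * geo$n, `+`))
}

# precompute the full feature matrices of a geometry (all sample columns);
# valid whenever no input noise is injected
sim_features_all <- function(entry, block, params) {
  n <- entry$geo$n
  S <- ncol(block$prev)
  geo_features(entry$geo, entry$g, params,
               block$prev[seq_len(n), , drop = FALSE],
               block$prev[n + seq_len(n), , drop = FALSE],
               cin = block$c_in)
}

# forward + loss + gradient on one within-geometry batch of samples
sim_batch <- function(model, entry, block, cols, params, loss_mode,
                      noise_sd = 0, grad = TRUE, pde_weight = 1,
                      feats = NULL) {
  g <- entry$g; geo <- entry$geo
  n <- geo$n; k <- length(cols)
  prev <- block$prev[, cols, drop = FALSE]
  if (noise_sd > 0) {
    prev <- prev + rnorm(length(prev), 0, noise_sd)
  }
  C0 <- prev[seq_len(n), , drop = FALSE]
  Cp <- prev[n + seq_len(n), , drop = FALSE]
  cin <- block$c_in[cols]
  if (is.null(feats) || noise_sd > 0) {
    ft <- geo_features(geo, g, params, C0, Cp, cin = cin)
  } else {
    rows <- as.vector(outer(seq_len(n), (cols - 1L) * n, `+`))
    ft <- list(X = feats$X[rows, , drop = FALSE],
               E = feats$E[rows, , drop = FALSE])
  }
  fwd <- sim_forward(model, ft$X, ft$E, keep_cache = grad)
  pred <- fwd$pred
  if (isTRUE(model$delta)) {
    pred <- pred + cbind(as.vector(C0), as.vector(Cp))
  }
  lam <- params$lambda_in
  imp <- imposed_rows(geo, k)
  if (length(imp)) { pred[imp, 1L] <- 1; pred[imp, 2L] <- lam }
  impo <- if (length(geo$imposed_out)) {
    as.vector(outer(geo$imposed_out, (seq_len(k) - 1L) * n, `+`))
  } else integer(0)
  if (length(impo)) {
    pred[impo, 1L] <- rep(params$c_out / cin, each = length(geo$imposed_out))
  }
  nxt <- block$nxt[, cols, drop = FALSE]
  targ <- cbind(as.vector(nxt[seq_len(n), , drop = FALSE]),
                as.vector(nxt[n + seq_len(n), , drop = FALSE]))
  err <- pred - targ
  loss <- sum(err^2) / (n * k)
  dPred <- if (grad) 2 * err / (n * k) else NULL
  if (loss_mode == "mse+pde") {
    predstack <- rbind(matrix(pred[, 1L], n, k), matrix(pred[, 2L], n, k))
    R <- as.matrix(geo$P %*% predstack - prev / params$dt)
    if (length(geo$res_mask)) R[geo$res_mask, ] <- 0
    loss <- loss + pde_weight * sum(R^2) / (n * k)
    if (grad) {
      dR <- as.matrix(geo$Pt %*% R) * (2 * pde_weight / (n * k))
      dPred[, 1L] <- dPred[, 1L] + as.vector(dR[seq_len(n), , drop = FALSE])
      dPred[, 2L] <- dPred[, 2L] + as.vector(dR[n + seq_len(n), , drop = FALSE])
    }
  }
  if (!grad) return(list(loss = loss, pred = pred, targ = targ))
  if (length(imp)) { dPred[imp, 1L] <- 0; dPred[imp, 2L] <- 0 }
  if (length(impo)) dPred[impo, 1L] <- 0
  list(loss = loss, grads = sim_backward(model, fwd, dPred))
}

split_chunks <- function(x, size) {
  if (!length(x)) return(list())
  split(x, ceiling(seq_along(x) / size))
}

#' Train a unit simulator
#'
#' Adam optimization of the GN-block simulator under the physics-informed
#' loss (or plain MSE), with a decade step learning-rate decay, a seeded
#' train/test split, and per-epoch loss logging. Fully deterministic for a
#' given configuration.
#'
#' @param dataset a \code{transport_dataset}.
#' @param config a \code{training_config}.
#' @param model optionally a pre-initialized or pre-trained
#'   \code{gnn_simulator} to continue from.
#' @param train_idx,test_idx optional explicit sample row numbers of
#'   \code{dataset$index} (used by \code{\link{cross_validate}}); defaults to
#'   a seeded random split.
#' @return a trained \code{gnn_simulator} with a \code{log} data.frame.
#' @export
train_simulator <- function(dataset, config = training_config(),
                            model = NULL, train_idx = NULL, test_idx = NULL) {
  stopifnot(inherits(dataset, "transport_dataset"))
  ns <- nrow(dataset$index)
  if (ns == 0L) stop("empty dataset")
  with_seed(config$seed, {
    if (is.null(train_idx)) {
      test_idx <- sort(sample.int(ns, round(config$test_fraction * ns)))
      train_idx <- setdiff(seq_len(ns), test_idx)
    }
    if (is.null(model)) {
      model <- simulator_model(dataset$kind, seed = sample.int(1e8, 1))
    }
    opt <- adam_init(model$params)
    params <- dataset$params
    cols_of <- function(idx) split(dataset$index$col[idx], dataset$index$geo[idx])
    train_cols <- cols_of(train_idx)
    test_cols <- cols_of(test_idx)
    feats <- if (config$noise_sd == 0) {
      lapply(seq_along(dataset$geos), function(i) {
        sim_features_all(dataset$geos[[i]], dataset$blocks[[i]], params)
      })
    }
    feats_of <- function(gi) if (is.null(feats)) NULL else feats[[gi]]
    log <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(ep, config$epochs, config$lr, config$lr_min)
      batches <- list()
      for (gi in names(train_cols)) {
        gc0 <- train_cols[[gi]]
        gc0 <- gc0[sample.int(length(gc0))]
        for (ch in split_chunks(gc0, config$batch_size)) {
          batches[[length(batches) + 1L]] <- list(gi = as.integer(gi), cols = ch)
        }
      }
      if (length(batches) > 1L) batches <- batches[sample.int(length(batches))]
      tr_loss <- 0; tr_n <- 0L
      for (b in batches) {
        out <- sim_batch(model, dataset$geos[[b$gi]], dataset$blocks[[b$gi]],
                         b$cols, params, config$loss_mode, config$noise_sd,
                         pde_weight = config$pde_weight %||% 1,
                         feats = feats_of(b$gi))
        if (!is.finite(out$loss)) {
          stop("non-finite training loss at epoch ", ep)
        }
        st <- adam_step(model$params, out$grads, opt, lr)
        model$params <- st$params; opt <- st$state
        tr_loss <- tr_loss + out$loss * length(b$cols)
        tr_n <- tr_n + length(b$cols)
      }
      te_loss <- 0; te_n <- 0L
      for (gi in names(test_cols)) {
        out <- sim_batch(model, dataset$geos[[as.integer(gi)]],
                         dataset$blocks[[as.integer(gi)]],
                         test_cols[[gi]], params, config$loss_mode,
                         noise_sd = 0, grad = FALSE,
                         pde_weight = config$pde_weight %||% 1,
                         feats = feats_of(as.integer(gi)))
        te_loss <- te_loss + out$loss * length(test_cols[[gi]])
        te_n <- te_n + length(test_cols[[gi]])
      }
      log[[ep]] <- data.frame(epoch = ep, lr = lr,
                              train_loss = tr_loss / max(tr_n, 1L),
                              test_loss = te_loss / max(te_n, 1L))
    }
    model$log <- rbind(model$log, do.call(rbind, log))
    model$config <- utils::modifyList(model$config, unclass(config))
    model$train_idx <- train_idx
    model$test_idx <- test_idx
    model
  })
}

#' Per-sample relative error of one-step predictions
#'
#' For each selected sample, the root-mean-square nodal error of the
#' predicted (c0, c+) fields over the ground-truth range (the MRE, in
#' percent).
#'
#' @param model a trained \code{gnn_simulator}.
#' @param dataset a \code{transport_dataset}.
#' @param idx sample row numbers (default: all).
#' @return numeric vector of MRE values, percent.
#' @export
evaluate_mre <- function(model, dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(dataset$index))
  params <- dataset$params
  out <- numeric(0)
  for (gi in unique(dataset$index$geo[idx])) {
    cols <- dataset$index$col[idx][dataset$index$geo[idx] == gi]
    res <- sim_batch(model, dataset$geos[[gi]], dataset$blocks[[gi]], cols,
                     params, "mse", noise_sd = 0, grad = FALSE)
    n <- dataset$geos[[gi]]$geo$n
    for (ci in seq_along(cols)) {
      rows <- (ci - 1L) * n + seq_len(n)
      p <- c(res$pred[rows, 1L], res$pred[rows, 2L])
      t <- c(res$targ[rows, 1L], res$targ[rows, 2L])
      out <- c(out, mre(p, t))
    }
  }
  out
}

#' k-fold cross-validation of a unit simulator
#'
#' Deterministic fold assignment given the configuration seed; each fold is
#' held out once, the simulator is trained on the remainder, and the fold's
#' mean one-step MRE is recorded.
#'
#' @param dataset a \code{transport_dataset}.
#' @param config a \code{training_config}.
#' @param k_folds number of folds (>= 2).
#' @return list with \code{fold_mre}, \code{mean_mre} and \code{sd_mre}.
#' @export
cross_validate <- function(dataset, config = training_config(), k_folds = 4L) {
  stopifnot(k_folds >= 2L)
  ns <- nrow(dataset$index)
  fold <- with_seed(config$seed, sample(rep_len(seq_len(k_folds), ns)))
  if (min(table(fold)) == 0L) stop("a fold has no test samples")
  fold_mre <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- which(fold == f)
    trn <- which(fold != f)
    m <- train_simulator(dataset, config, train_idx = trn, test_idx = te)
    fold_mre[f] <- mean(evaluate_mre(m, dataset, te))
  }
  list(fold_mre = fold_mre, mean_mre = mean(fold_mre), sd_mre = sd(fold_mre),
       fold_sizes = as.integer(table(fold)))
}

#' Fine-tune a trained simulator on a new dataset
#'
#' Continues training from the given model's weights; the appended log rows
#' carry the new run's epochs. With \code{epochs = 0} the weights are
#' returned unchanged.
#'
#' @param model a trained \code{gnn_simulator}.
#' @param new_dataset a \code{transport_dataset} of the same unit kind.
#' @param config a \code{training_config}.
#' @export
fine_tune <- function(model, new_dataset, config = training_config()) {
  if (model$kind != new_dataset$kind) {
    stop("architecture mismatch: model kind '", model$kind,
         "' vs dataset kind '", new_dataset$kind, "'")
  }
  if (config$epochs == 0L) return(model)
  train_simulator(new_dataset, config, model = model)
}

#' Root-mean-square nodal error (MAE)
#'
#' The field's customary "MAE" for nodal concentration fields: the square
#' root of the mean squared nodal difference (a root-mean-square, despite
#' the name).
#'
#' @param pred,truth numeric vectors of equal length.
#' @return scalar error in concentration units.
#' @export
mae <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop("pred and truth must be non-empty and of equal length")
  }
  sqrt(mean((pred - truth)^2))
}

#' Mean relative error (MRE)
#'
#' \code{mae(pred, truth)} normalized by the ground-truth nodal range and
#' expressed in percent.
#'
#' @param pred,truth numeric vectors of equal length.
#' @return scalar error, percent.
#' @export
mre <- function(pred, truth) {
  rng <- max(truth) - min(truth)
  if (rng <= 0) stop("ground-truth range is zero; MRE undefined")
  mae(pred, truth) / rng * 100
}

#' Save / load a model checkpoint
#'
#' Serializes the model (configuration, weights, training log) to an RDS
#' file.
#'
#' @param model a \code{gnn_simulator} or \code{gnn_assembly}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
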