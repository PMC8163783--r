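# Graph-network simulators for pipe and bifurcation units.
#
# Architecture (encode-process-decode): nodal input features (coordinates,
# simulation-parameter vector, current concentrations) pass through L GN
# blocks; each block aggregates the analytic edge features (concentration
# gradient along the edge and edge length) over a node's incident edges,
# concatenates the aggregate with the node's current embedding and applies a
# shared node MLP (two hidden ReLU layers of width 32). A decoder MLP (three
# hidden ReLU layers of width 32, linear output) maps the final embedding to
# the two concentrations at the next time step.

SIM_N_FEAT <- 11L  # 3 coords + 6 parameters + 2 concentrations
SIM_N_EDGE <- 3L   # mean gradient of c0, of c+, mean edge length

#' Analytic edge features
#'
#' For an edge between nodes at \code{pos_i}, \code{pos_j} carrying scalar
#' values \code{c_i}, \code{c_j}: the concentration gradient along the edge
#' and the edge length, \code{[(c_j - c_i)/d, d]} with
#' \code{d = ||pos_j - pos_i||}.
#'
#' @param pos_i,pos_j 3-vectors.
#' @param c_i,c_j scalars.
#' @return numeric length-2 vector.
#' @export
edge_features <- function(pos_i, pos_j, c_i, c_j) {
  d <- sqrt(sum((pos_j - pos_i)^2))
  if (d == 0) stop("coincident edge endpoints: edge length is zero")
  c((c_j - c_i) / d, d)
}

# per-geometry cache: normalization, mean-aggregation operator, residual
# operator for the physics loss, imposed-node bookkeeping
gnn_geometry <- function(g, params) {
  center <- colMeans(g$pos)
  scale <- mean(g$sections$radius)
  coords_n <- sweep(g$pos, 2, center) / scale
  e <- g$edges
  d_n <- sqrt(rowSums((coords_n[e[, 2], , drop = FALSE] -
                       coords_n[e[, 1], , drop = FALSE])^2))
  i <- c(e[, 1], e[, 2]); j <- c(e[, 2], e[, 1])
  deg <- tabulate(i, nbins = g$n)
  Mg <- sparseMatrix(i = i, j = j, x = 1 / (deg[i] * c(d_n, d_n)),
                     dims = c(g$n, g$n))
  gi <- as.numeric(Matrix::rowSums(Mg))
  dbar <- as.numeric(sparseMatrix(i = i, j = rep(1L, length(i)),
                                  x = c(d_n, d_n) / deg[i],
                                  dims = c(g$n, 1L)))
  v <- compute_velocity(g, params)
  ops <- transport_operators(g, params, v)
  kp <- params$k_plus; kpp <- params$kp_plus
  N <- g$n
  I <- Diagonal(N)
  A <- rbind(cbind(params$D * ops$L - kp * I, kpp * I),
             cbind(kp * I, -ops$Adv - kpp * I))
  P <- Diagonal(2L * N) / params$dt - A
  imposed <- which(g$role == "inlet" & is.na(g$iface))
  imposed_out <- if (!is.null(params$c_out)) {
    which(g$role == "outlet" & is.na(g$iface))
  } else integer(0)
  u_node <- v$u_sec[g$sec]
  # rows whose ground truth does not obey the unit-local discrete PDE: nodes
  # under a boundary condition and end sections whose network stencil is cut
  # by the unit boundary; excluded from the residual term of the training loss
  bnd <- which(g$role != "interior")
  res_mask <- c(bnd, N + bnd)
  list(coords_n = coords_n, scale = scale, Mg = Mg, gi = gi, dbar = dbar,
       P = P, Pt = Matrix::t(P), imposed = imposed,
       imposed_out = imposed_out, res_mask = res_mask, u_node = u_node,
       v = v, n = g$n)
}

# features for a batch of states: C0n, Cpn are n x k matrices (normalized);
# cin: the raw inlet concentration of each sample (scalar or per column)
geo_features <- function(geo, g, params, C0n, Cpn, cin = params$c_in) {
  n <- geo$n; k <- ncol(C0n)
  idx <- rep(seq_len(n), k)
  E1 <- as.matrix(geo$Mg %*% C0n - geo$gi * C0n)
  E2 <- as.matrix(geo$Mg %*% Cpn - geo$gi * Cpn)
  cinv <- if (length(cin) == 1L) rep(cin, n * k) else rep(cin, each = n)
  X <- cbind(geo$coords_n[idx, , drop = FALSE],
             params$D, params$k_plus, params$kp_plus,
             geo$u_node[idx], cinv, g$r_frac[idx],
             as.vector(C0n), as.vector(Cpn))
  E <- cbind(as.vector(E1), as.vector(E2), geo$dbar[idx])
  list(X = X, E = E)
}

#' Construct an untrained unit simulator
#'
#' @param kind \code{"pipe"} or \code{"bifurcation"}.
#' @param L number of GN-block steps (message-passing hops).
#' @param width hidden-layer width.
#' @param seed integer seed for weight initialization.
#' @param zero_decoder zero-initialize the decoder output layer.
#' @param delta decoder output is the per-step concentration increment added
#'   to the input state (default); \code{FALSE} predicts the next-step field
#'   directly.
#' @return an object of class \code{"gnn_simulator"}.
#' @export
simulator_model <- function(kind = c("pipe", "bifurcation"), L = 3L,
                            width = 32L, seed = 1, zero_decoder = TRUE,
                            delta = TRUE) {
  kind <- match.arg(kind)
  with_seed(seed, {
    blocks <- lapply(seq_len(L), function(l) {
      d_in <- (if (l == 1L) SIM_N_FEAT else width) + SIM_N_EDGE
      mlp_init(c(d_in, width, width, width))
    })
    dec <- mlp_init(c(width, width, width, width, 2L), zero_last = zero_decoder)
    structure(list(kind = kind, L = L, width = width, delta = delta,
                   params = list(blocks = blocks, dec = dec),
                   config = list(seed = seed), log = NULL),
              class = "gnn_simulator")
  })
}

#' One GN-block update
#'
#' Aggregates the analytic edge features over each node's incident edges
#' (mean reducer), concatenates the aggregate with the node's embedding and
#' applies the block's node MLP.
#'
#' @param block a block parameter list (as in
#'   \code{simulator_model()$params$blocks[[l]]}).
#' @param g a \code{template_graph}.
#' @param h current per-node embeddings (nodes x d matrix).
#' @param c0,c_plus per-node scalar fields used by the edge function.
#' @return updated embeddings.
#' @export
gn_block_forward <- function(block, g, h, c0, c_plus = NULL) {
  e <- g$edges
  d <- sqrt(rowSums((g$pos[e[, 2], , drop = FALSE] -
                     g$pos[e[, 1], , drop = FALSE])^2))
  if (any(d == 0)) stop("coincident edge endpoints: edge length is zero")
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = g$n)
  if (any(deg == 0)) warning("isolated node(s): aggregated edge features set to zero")
  agg <- function(vals) {
    x <- numeric(g$n)
    inc <- c(e[, 1], e[, 2])
    for (r in seq_along(inc)) x[inc[r]] <- x[inc[r]] + vals[r]
    x / pmax(deg, 1L)
  }
  g1 <- agg(c((c0[e[, 2]] - c0[e[, 1]]) / d, (c0[e[, 1]] - c0[e[, 2]]) / d))
  E <- cbind(g1, if (is.null(c_plus)) NULL else
    agg(c((c_plus[e[, 2]] - c_plus[e[, 1]]) / d,
          (c_plus[e[, 1]] - c_plus[e[, 2]]) / d)),
    agg(c(d, d)))
  mlp_forward(block, cbind(h, E))$out
}

# full batched forward pass (compiled core); the activation cache lives on
# the C++ side between the forward and backward calls
sim_forward <- function(model, X, E, keep_cache = TRUE) {
  out <- .sim_fwd_cpp(model$params$blocks, model$params$dec, X, E, keep_cache)
  list(pred = out$pred, cache = out$cache)
}

sim_backward <- function(model, fwd, dPred) {
  .sim_bwd_cpp(model$params$blocks, model$params$dec, fwd$cache, dPred,
               SIM_N_EDGE)
}

#' One simulator step
#'
#' Predicts the concentrations at \code{t + dt} from the current state.
#' Features are normalized per geometry (coordinates centered on the unit
#' centroid and scaled by its mean section radius, concentrations scaled by
#' the inlet concentration); the network inlet Dirichlet values are
#' re-imposed on the output.
#'
#' @param model a trained \code{gnn_simulator} (or
#'   \code{\link{solver_surrogate}}).
#' @param g the unit \code{template_graph}.
#' @param state current \code{concentration_state}.
#' @param params \code{simulation_params}.
#' @param geo optional precomputed geometry cache (internal reuse).
#' @return the predicted \code{concentration_state} at \code{state$time + dt}.
#' @export
simulator_step <- function(model, g, state, params, geo = NULL) {
  UseMethod("simulator_step")
}

#' @export
simulator_step.gnn_simulator <- function(model, g, state, params, geo = NULL) {
  if (is.null(geo)) geo <- gnn_geometry(g, params)
  cs <- params$c_in
  ft <- geo_features(geo, g, params, cbind(state$c0 / cs),
                     cbind(state$c_plus / cs))
  pred <- sim_forward(model, ft$X, ft$E)$pred
  if (isTRUE(model$delta)) {
    pred <- pred + cbind(state$c0 / cs, state$c_plus / cs)
  }
  if (any(!is.finite(pred))) {
    stop("numerical error: non-finite simulator prediction (max |input| = ",
         max(abs(ft$X)), ")")
  }
  c0 <- pred[, 1] * cs
  cp <- pred[, 2] * cs
  if (length(geo$imposed)) {
    c0[geo$imposed] <- params$c_in
    cp[geo$imposed] <- params$lambda_in * params$c_in
  }
  if (length(geo$imposed_out)) c0[geo$imposed_out] <- params$c_out
  concentration_state(c0, cp, time = state$time + params$dt)
}

#' Reference-solver step wrapped as a surrogate
#'
#' A "perfect surrogate" whose step is the reference solver's step; useful
#' for validating rollout plumbing.
#'
#' @param g a \code{template_graph}.
#' @param params \code{simulation_params}.
#' @export
solver_surrogate <- function(g, params) {
  v <- compute_velocity(g, params)
  structure(list(sys = build_transport_system(g, params, v, "implicit")),
            class = c("solver_surrogate"))
}

#' @export
simulator_step.solver_surrogate <- function(model, g, state, params,
                                            geo = NULL) {
  x <- step_system(model$sys, state_to_vec(state, 2L))
  n <- g$n
  concentration_state(x[seq_len(n)], x[n + seq_len(n)],
                      time = state$time + params$dt)
}

#' Autoregressive rollout of a simulator
#'
#' Each step's prediction becomes the next step's input; inlet Dirichlet
#' values are re-imposed every step.
#'
#' @inheritParams simulator_step
#' @param init initial \code{concentration_state}.
#' @param n_steps number of steps.
#' @return a \code{transport_trajectory} of length \code{n_steps + 1}.
#' @export
rollout <- function(model, g, init, params, n_steps, geo = NULL) {
  if (is.null(geo) && inherits(model, "gnn_simulator")) {
    geo <- gnn_geometry(g, params)
  }
  n <- g$n
  C0 <- matrix(0, n, n_steps + 1L); Cp <- matrix(0, n, n_steps + 1L)
  st <- init
  C0[, 1L] <- st$c0; Cp[, 1L] <- st$c_plus
  for (k in seq_len(n_steps)) {
    st <- simulator_step(model, g, st, params, geo = geo)
    cap <- 1e6 * max(params$c_in, 1)
    if (max(abs(st$c0), abs(st$c_plus)) > cap) {
      stop("rollout diverged at step ", k)
    }
    C0[, k + 1L] <- st$c0; Cp[, k + 1L] <- st$c_plus
  }
  structure(list(c0 = C0, c_plus = Cp, c_minus = NULL,
                 times = init$time + params$dt * (0:n_steps),
                 method = class(model)[1L]),
            class = "transport_trajectory")
}

#' Physics-informed simulator loss
#'
#' Mean squared prediction error plus the mean squared residuals of the two
#' governing equations evaluated at the prediction: the time derivative is
#' \code{(pred - prev)/dt}; the Laplacian and the upwind advective gradient
#' are the reference solver's discrete operators. With
#' \code{include_residual = FALSE} the loss reduces to the plain MSE.
#'
#' @param pred,truth,prev \code{concentration_state}s at t+dt (prediction,
#'   ground truth) and t.
#' @param g the \code{template_graph}.
#' @param params \code{simulation_params}.
#' @param v a \code{velocity_field}; required for the residual terms.
#' @param include_residual include the PDE-residual terms.
#' @return scalar loss.
#' @export
simulator_loss <- function(pred, truth, prev, g, params, v = NULL,
                           include_residual = TRUE) {
  mse <- mean((pred$c0 - truth$c0)^2 + (pred$c_plus - truth$c_plus)^2)
  if (!include_residual) return(mse)
  if (is.null(v)) stop("a velocity field is required for the residual terms")
  ops <- transport_operators(g, params, v)
  kp <- params$k_plus; kpp <- params$kp_plus
  r0 <- (pred$c0 - prev$c0) / params$dt -
    (params$D * as.numeric(ops$L %*% pred$c0) - kp * pred$c0 +
       kpp * pred$c_plus)
  rp <- (pred$c_plus - prev$c_plus) / params$dt +
    as.numeric(ops$Adv %*% pred$c_plus) - kp * pred$c0 + kpp * pred$c_plus
  mse + mean(r0^2) + mean(rp^2)
}

#' @export
print.gnn_simulator <- function(x, ...) {
  cat("GNN ", x$kind, " simulator: ", x$L, " GN blocks + MLP decoder (width ",
      x$width, ")\n", sep = "")
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat("  trained ", nrow(x$log), " epochs; final train/test loss ",
        format(last$train_loss, digits = 4), " / ",
        format(last$test_loss, digits = 4), "\n", sep = "")
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.gnn_simulator <- function(object, ...) {
  print(object)
  npar <- sum(unlist(tree_map(function(x) length(x), object$params)))
  cat("  parameters:", npar, "\n")
  if (!is.null(object$config$loss_mode)) {
    cat("  loss mode:", object$config$loss_mode, "\n")
  }
  invisible(object)
}

#' Predict method: one step or a rollout
#'
#' @param object a \code{gnn_simulator}.
#' @param g a \code{template_graph}.
#' @param state a \code{concentration_state}.
#' @param params \code{simulation_params}.
#' @param n_steps 1 for a single step, larger for an autoregressive rollout.
#' @param ... unused.
#' @export
predict.gnn_simulator <- function(object, g, state, params, n_steps = 1, ...) {
  if (n_steps == 1) simulator_step(object, g, state, params)
  else rollout(object, g, state, params, n_steps)
}

#' Training-curve plot
#'
#' @param x a trained \code{gnn_simulator}.
#' @param ... passed to \code{matplot}.
#' @export
plot.gnn_simulator <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$test_loss),
                    type = "l", lty = 1:2, col = c("black", "red"), log = "y",
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "test"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
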