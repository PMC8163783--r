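# Synthetic study-data pipeline: seeded morphologies, network-level solver
# trajectories, and unit-level one-step datasets extracted by restriction.

#' Generate a set of synthetic neurite networks
#'
#' Each network is a seeded synthetic morphology (1-3 bifurcations in
#' round-robin), decomposed into units, with its stitched network graph.
#'
#' @param n number of networks.
#' @param seed root seed.
#' @param morph named list of overrides for
#'   \code{\link{generate_morphology}}.
#' @param max_pipe_sections pipe-splitting threshold passed to
#'   \code{\link{decompose_morphology}} (default 8, so long branches yield
#'   pipe-pipe interfaces).
#' @return list of networks: \code{morphology}, \code{sg}, \code{graph}
#'   (stitched \code{template_graph}), \code{map} (unit node map).
#' @export
generate_networks <- function(n, seed = 1, morph = list(),
                              max_pipe_sections = 8L) {
  lapply(seq_len(n), function(i) {
    args <- utils::modifyList(list(
      n_bifurcations = 1L + (i - 1L) %% 3L,
      branch_length_range = c(8, 14),
      radius_root = 1.0, taper_ratio = 0.85, sampling_spacing = 1.0,
      seed = (seed * 1009L + i * 7919L) %% 2147483647L), morph)
    m <- do.call(generate_morphology, args)
    sg <- decompose_morphology(m, max_pipe_sections = max_pipe_sections)
    g <- build_network_graph(sg)
    list(morphology = m, sg = sg, graph = g, map = attr(g, "unit_node_map"))
  })
}

# solve a network for each boundary value and keep the sampled state pairs;
# trajectories start from the steady state of the reference boundary value
# (c_ref) and relax toward the steady state of the new value.
solve_network_pairs <- function(net, params, c_in_values, n_steps, pair_steps,
                                c_ref = 1.0) {
  g <- net$graph
  v <- compute_velocity(g, params)
  sys <- build_transport_system(g, params, v, "implicit")
  init <- steady_state_solve(g, simulation_params_set(params, c_in = c_ref), v)
  init$time <- 0
  lapply(c_in_values, function(ci) {
    pr <- simulation_params_set(params, c_in = ci)
    sysi <- sys
    sysi$bc <- transport_bc(g, pr)
    tr <- solve_transport(g, pr, v, init = init, n_steps = n_steps,
                          system = sysi)
    st <- rbind(tr$c0, tr$c_plus)
    list(prev = st[, pair_steps, drop = FALSE],
         nxt = st[, pair_steps + 1L, drop = FALSE], c_in = ci)
  })
}

# tweak selected fields of a simulation_params object
simulation_params_set <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  params
}

#' Generate the full scaled study dataset
#'
#' Seeded synthetic networks are solved with the reference transport solver
#' for a sweep of inlet boundary concentrations; unit-level one-step samples
#' are extracted by restricting the network states to each pipe and
#' bifurcation unit. The manifest records every generation choice.
#'
#' @param n_networks number of synthetic morphologies.
#' @param n_boundary number of inlet boundary concentration values (evenly
#'   spaced over \code{c_in_range}).
#' @param n_steps solver steps per trajectory (of length \code{params$dt}).
#' @param pairs_per_trajectory consecutive-state pairs kept per trajectory.
#' @param n_geometries unit geometries kept per unit kind (sampled over the
#'   network pool, seeded).
#' @param seed root seed.
#' @param params \code{simulation_params}.
#' @param morph morphology-generator overrides.
#' @param c_in_range range of the boundary concentration sweep, mol/um^3.
#' @param c_ref reference boundary value whose steady state initializes each
#'   trajectory (the trajectories capture the relaxation after a boundary
#'   switch from \code{c_ref} to each sweep value).
#' @param max_pipe_sections see \code{\link{generate_networks}}.
#' @return list with \code{networks} (each carrying its solved state pairs in
#'   \code{$pairs}), \code{datasets} (\code{pipe}, \code{bifurcation}
#'   \code{transport_dataset}s), \code{params} and \code{manifest}.
#' @export
generate_transport_data <- function(n_networks = 30L, n_boundary = 20L,
                                    n_steps = 50L, pairs_per_trajectory = 3L,
                                    n_geometries = 30L, seed = 1L,
                                    params = simulation_params(c_out = 0),
                                    morph = list(),
                                    c_in_range = c(0.5, 1.5),
                                    c_ref = 1.0,
                                    max_pipe_sections = 8L) {
  networks <- generate_networks(n_networks, seed, morph, max_pipe_sections)
  c_in_values <- seq(c_in_range[1], c_in_range[2], length.out = n_boundary)
  pair_steps <- pick_pairs(n_steps, pairs_per_trajectory)
  for (i in seq_along(networks)) {
    networks[[i]]$pairs <- solve_network_pairs(networks[[i]], params,
                                               c_in_values, n_steps,
                                               pair_steps, c_ref)
  }
  datasets <- lapply(c(pipe = "pipe", bifurcation = "bifurcation"), function(kd) {
    pool <- do.call(rbind, lapply(seq_along(networks), function(i) {
      us <- which(vapply(networks[[i]]$sg$units, `[[`, "", "kind") == kd)
      if (length(us)) data.frame(net = i, unit = us) else NULL
    }))
    if (is.null(pool) || nrow(pool) == 0L) return(NULL)
    keep <- if (nrow(pool) > n_geometries) {
      with_seed(seed + 17L, sort(sample.int(nrow(pool), n_geometries)))
    } else seq_len(nrow(pool))
    pool <- pool[keep, , drop = FALSE]
    geos <- list(); blocks <- list()
    for (r in seq_len(nrow(pool))) {
      net <- networks[[pool$net[r]]]
      u <- pool$unit[r]
      g <- build_unit_graph(net$sg$units[[u]])
      nm <- net$map[[u]]
      N <- net$graph$n
      rows <- c(nm, N + nm)
      prev <- NULL; nxt <- NULL; cins <- numeric(0)
      for (pb in net$pairs) {
        prev <- cbind(prev, pb$prev[rows, , drop = FALSE] / pb$c_in)
        nxt <- cbind(nxt, pb$nxt[rows, , drop = FALSE] / pb$c_in)
        cins <- c(cins, rep(pb$c_in, ncol(pb$prev)))
      }
      geos[[r]] <- list(g = g, geo = gnn_geometry(g, params),
                        net = pool$net[r], unit = u)
      blocks[[r]] <- list(prev = prev, nxt = nxt, c_in = cins)
    }
    new_transport_dataset(kd, geos, blocks, params,
                          manifest = list(seed = seed, n_networks = n_networks,
                                          n_boundary = n_boundary,
                                          n_steps = n_steps,
                                          pair_steps = pair_steps,
                                          n_geometries = nrow(pool)))
  })
  list(networks = networks, datasets = datasets, params = params,
       c_in_values = c_in_values, pair_steps = pair_steps,
       manifest = list(seed = seed, n_networks = n_networks,
                       n_boundary = n_boundary, n_steps = n_steps,
                       pairs_per_trajectory = pairs_per_trajectory,
                       n_geometries = n_geometries, c_in_range = c_in_range,
                       c_ref = c_ref, morph = morph,
                       max_pipe_sections = max_pipe_sections))
}

#' Build the assembly training dataset
#'
#' For every sampled network state pair, each (frozen) unit simulator takes
#' one step from the ground-truth state at t_k; the per-interface inputs
#' (interface + adjacent sections from both sides) and ground-truth targets
#' at t_{k+1} are collected, grouped by interface kind.
#'
#' @param data output of \code{\link{generate_transport_data}}.
#' @param simulators named list with trained \code{pipe} and
#'   \code{bifurcation} simulators.
#' @param net_idx which networks to use (default: all).
#' @return an object of class \code{"assembly_dataset"}.
#' @export
build_assembly_dataset <- function(data, simulators, net_idx = NULL) {
  if (is.null(net_idx)) net_idx <- seq_along(data$networks)
  params <- data$params
  acc <- setNames(lapply(ASM_KINDS, function(k) list()), ASM_KINDS)
  for (i in net_idx) {
    net <- data$networks[[i]]
    sg <- net$sg
    if (!length(sg$interfaces)) next
    unit_graphs <- lapply(sg$units, build_unit_graph)
    ispec <- interface_spec(sg, unit_graphs)
    N <- net$graph$n
    # batched one-step predictions per unit over all (boundary, pair) columns
    preds <- lapply(seq_along(sg$units), function(u) {
      g <- unit_graphs[[u]]
      geo <- gnn_geometry(g, params)
      nm <- net$map[[u]]
      C0 <- NULL; Cp <- NULL; cins <- numeric(0)
      for (pb in net$pairs) {
        C0 <- cbind(C0, pb$prev[nm, , drop = FALSE] / pb$c_in)
        Cp <- cbind(Cp, pb$prev[N + nm, , drop = FALSE] / pb$c_in)
        cins <- c(cins, rep(pb$c_in, ncol(pb$prev)))
      }
      ft <- geo_features(geo, g, params, C0, Cp, cin = cins)
      pr <- sim_forward(simulators[[g$kind]], ft$X, ft$E)$pred
      if (isTRUE(simulators[[g$kind]]$delta)) {
        pr <- pr + cbind(as.vector(C0), as.vector(Cp))
      }
      k <- ncol(C0)
      imp <- imposed_rows(geo, k)
      if (length(imp)) {
        pr[imp, 1L] <- 1; pr[imp, 2L] <- params$lambda_in
      }
      if (length(geo$imposed_out)) {
        impo <- as.vector(outer(geo$imposed_out, (seq_len(k) - 1L) * g$n, `+`))
        pr[impo, 1L] <- rep(params$c_out / cins, each = length(geo$imposed_out))
      }
      list(P0 = matrix(pr[, 1L], g$n, k), Pp = matrix(pr[, 2L], g$n, k))
    })
    truth <- lapply(seq_along(sg$units), function(u) {
      nm <- net$map[[u]]
      T0 <- NULL; Tp <- NULL
      for (pb in net$pairs) {
        T0 <- cbind(T0, pb$nxt[nm, , drop = FALSE] / pb$c_in)
        Tp <- cbind(Tp, pb$nxt[N + nm, , drop = FALSE] / pb$c_in)
      }
      list(T0 = T0, Tp = Tp)
    })
    ncols <- ncol(preds[[1L]]$P0)
    for (sp in ispec) {
      pa <- preds[[sp$a]]; pb_ <- preds[[sp$b]]
      X <- rbind(pa$P0[sp$a_if, ], pa$Pp[sp$a_if, ],
                 pa$P0[sp$a_adj, ], pa$Pp[sp$a_adj, ],
                 pb_$P0[sp$b_if, ], pb_$Pp[sp$b_if, ],
                 pb_$P0[sp$b_adj, ], pb_$Pp[sp$b_adj, ])
      ta <- truth[[sp$a]]; tb <- truth[[sp$b]]
      T_if <- rbind(ta$T0[sp$a_if, ], ta$Tp[sp$a_if, ])
      T_a1 <- rbind(ta$T0[sp$a_adj, ], ta$Tp[sp$a_adj, ])
      T_a2 <- rbind(tb$T0[sp$b_adj, ], tb$Tp[sp$b_adj, ])
      # constant (assembly-independent) part of the pairwise MSE
      oth_a <- setdiff(seq_len(nrow(pa$P0)), c(sp$a_if, sp$a_adj))
      oth_b <- setdiff(seq_len(nrow(pb_$P0)), c(sp$b_if, sp$b_adj))
      const <- colSums((pa$P0[oth_a, , drop = FALSE] - ta$T0[oth_a, , drop = FALSE])^2) +
        colSums((pa$Pp[oth_a, , drop = FALSE] - ta$Tp[oth_a, , drop = FALSE])^2) +
        colSums((pb_$P0[oth_b, , drop = FALSE] - tb$T0[oth_b, , drop = FALSE])^2) +
        colSums((pb_$Pp[oth_b, , drop = FALSE] - tb$Tp[oth_b, , drop = FALSE])^2)
      acc[[sp$kind]][[length(acc[[sp$kind]]) + 1L]] <-
        list(X = t(X), T_if = t(T_if), T_a1 = t(T_a1), T_a2 = t(T_a2),
             const = const, n_pair = rep(sp$n_pair, ncols))
    }
  }
  kinds <- lapply(acc, function(lst) {
    if (!length(lst)) return(NULL)
    list(X = do.call(rbind, lapply(lst, `[[`, "X")),
         T_if = do.call(rbind, lapply(lst, `[[`, "T_if")),
         T_a1 = do.call(rbind, lapply(lst, `[[`, "T_a1")),
         T_a2 = do.call(rbind, lapply(lst, `[[`, "T_a2")),
         const = unlist(lapply(lst, `[[`, "const")),
         n_pair = unlist(lapply(lst, `[[`, "n_pair")))
  })
  structure(list(kinds = kinds, params = params,
                 manifest = list(net_idx = net_idx)),
            class = "assembly_dataset")
}

# loss and gradient for a batch of assembly rows of one kind
asm_batch <- function(comp, blk, rows, alpha, grad = TRUE) {
  X <- blk$X[rows, , drop = FALSE]
  fw <- mlp_forward(comp, X)
  out <- X + fw$out
  half <- 2L * IFACE_NN
  i1 <- seq_len(half); i2 <- half + i1; i3 <- 2L * half + i1; i4 <- 3L * half + i1
  s1i <- out[, i1, drop = FALSE]; s1a <- out[, i2, drop = FALSE]
  s2i <- out[, i3, drop = FALSE]; s2a <- out[, i4, drop = FALSE]
  resv <- (s1i + s2i) / 2
  R <- length(rows)
  np <- blk$n_pair[rows]
  e_if <- resv - blk$T_if[rows, , drop = FALSE]
  e_a1 <- s1a - blk$T_a1[rows, , drop = FALSE]
  e_a2 <- s2a - blk$T_a2[rows, , drop = FALSE]
  gap <- s1i - s2i
  mse_row <- (rowSums(e_if^2) + rowSums(e_a1^2) + rowSums(e_a2^2) +
                blk$const[rows]) / np
  pen_row <- alpha * rowSums(gap^2) / IFACE_NN
  loss <- mean(mse_row + pen_row)
  if (!grad) return(list(loss = loss, gap = mean(abs(gap))))
  dOut <- matrix(0, R, ncol(out))
  w <- 2 / (np * R)
  dres <- e_if * w
  dgap <- gap * (2 * alpha / (IFACE_NN * R))
  dOut[, i1] <- dres / 2 + dgap
  dOut[, i3] <- dres / 2 - dgap
  dOut[, i2] <- e_a1 * w
  dOut[, i4] <- e_a2 * w
  list(loss = loss, grads = mlp_backward(comp, fw, dOut)$grads)
}

#' Train the assembly model
#'
#' Adam optimization of the three component MLPs under the
#' interface-penalized loss, with a seeded 75/25 row split and per-epoch
#' logging. \code{alpha = 0} trains the pure-MSE ablation.
#'
#' @param adata an \code{assembly_dataset}.
#' @param config a \code{training_config}.
#' @param alpha penalty strength (default 10).
#' @param model optional pre-initialized \code{gnn_assembly}.
#' @return a trained \code{gnn_assembly}.
#' @export
train_assembly <- function(adata, config = training_config(), alpha = 10,
                           model = NULL) {
  with_seed(config$seed, {
    if (is.null(model)) {
      model <- assembly_model(alpha = max(alpha, .Machine$double.eps),
                              seed = sample.int(1e8, 1))
    }
    model$alpha <- alpha
    kinds <- names(which(!vapply(adata$kinds, is.null, TRUE)))
    splits <- lapply(kinds, function(k) {
      R <- nrow(adata$kinds[[k]]$X)
      te <- sort(sample.int(R, round(config$test_fraction * R)))
      list(train = setdiff(seq_len(R), te), test = te)
    })
    names(splits) <- kinds
    opt <- setNames(lapply(kinds, function(k) adam_init(model$components[[k]])),
                    kinds)
    log <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(ep, config$epochs, config$lr, config$lr_min)
      tr_loss <- 0; tr_n <- 0L
      for (k in kinds) {
        trn <- splits[[k]]$train
        trn <- trn[sample.int(length(trn))]
        for (ch in split_chunks(trn, max(config$batch_size, 256L))) {
          out <- asm_batch(model$components[[k]], adata$kinds[[k]], ch, alpha)
          st <- adam_step(model$components[[k]], out$grads, opt[[k]], lr)
          model$components[[k]] <- st$params; opt[[k]] <- st$state
          tr_loss <- tr_loss + out$loss * length(ch); tr_n <- tr_n + length(ch)
        }
      }
      te_loss <- 0; te_n <- 0L
      for (k in kinds) {
        te <- splits[[k]]$test
        if (!length(te)) next
        out <- asm_batch(model$components[[k]], adata$kinds[[k]], te, alpha,
                         grad = FALSE)
        te_loss <- te_loss + out$loss * length(te); te_n <- te_n + length(te)
      }
      log[[ep]] <- data.frame(epoch = ep, lr = lr,
                              train_loss = tr_loss / max(tr_n, 1L),
                              test_loss = te_loss / max(te_n, 1L))
    }
    model$log <- rbind(model$log, do.call(rbind, log))
    model
  })
}
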