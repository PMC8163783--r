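# Reference solver for the unidirectional motor-assisted transport model on
# template graphs. Free material (c0) diffuses; motor-bound material (c+)
# is advected along the local centerline direction with a Poiseuille radial
# profile; the two pools exchange at attachment/detachment rates k+ and k'+:
#
#   dc0/dt = D Lap c0 - k+ c0 + k'+ c+
#   dc+/dt = -div(u+ c+) + k+ c0 - k'+ c+
#
# with Dirichlet values (c, lambda*c) at the incoming end and zero-gradient
# (or Dirichlet, when an outgoing concentration is supplied) at the outgoing
# end. The discrete Laplacian is the unnormalized graph operator with edge
# weights 1/length^2 (exactly the 1D three-point stencil along the section
# axis for section-uniform fields); advection is first-order upwind along
# edges using the velocity component along each edge.

#' Simulation parameters of the transport model
#'
#' @param D diffusion coefficient of free material, um^2/s.
#' @param k_plus,k_minus filament attachment rates, 1/s.
#' @param kp_plus,kp_minus filament detachment rates, 1/s.
#' @param u_i inlet transport speed, um/s (peak of the parabolic profile).
#' @param lambda_in degree of loading at the incoming end (c+ = lambda * c);
#'   defaults to the equilibrium ratio k_plus / kp_plus.
#' @param lambda_out degree of loading at the outgoing end (bidirectional
#'   mode only).
#' @param c_in free concentration held at the incoming end, mol/um^3;
#'   \code{NULL} leaves the incoming end free (no Dirichlet row).
#' @param c_out free concentration at the outgoing end; \code{NULL} (default)
#'   selects a zero-gradient outgoing end.
#' @param dt reporting time step, s.
#' @param unidirectional drop the retrograde pool (c-, u-, k-, k'-).
#' @return an object of class \code{"simulation_params"}.
#' @export
simulation_params <- function(D = 1.0, k_plus = 1.0, k_minus = 1.0,
                              kp_plus = 0.5, kp_minus = 0.5, u_i = 0.1,
                              lambda_in = NULL, lambda_out = NULL,
                              c_in = 1.0, c_out = NULL, dt = 0.1,
                              unidirectional = TRUE) {
  stopifnot(D >= 0, k_plus >= 0, k_minus >= 0, kp_plus >= 0, kp_minus >= 0,
            dt > 0)
  if (is.null(lambda_in)) {
    lambda_in <- if (kp_plus > 0) k_plus / kp_plus else 1
  }
  if (is.null(lambda_out)) {
    lambda_out <- if (kp_minus > 0) k_minus / kp_minus else 1
  }
  structure(list(D = D, k_plus = k_plus, k_minus = k_minus,
                 kp_plus = kp_plus, kp_minus = kp_minus, u_i = u_i,
                 lambda_in = lambda_in, lambda_out = lambda_out,
                 c_in = c_in, c_out = c_out, dt = dt,
                 unidirectional = unidirectional),
            class = "simulation_params")
}

#' Concentration state
#'
#' Per-node free (\code{c0}) and motor-bound (\code{c_plus}) concentrations,
#' mol/um^3, at one time point.
#'
#' @param c0,c_plus numeric vectors, one value per graph node.
#' @param time time point, s.
#' @param c_minus retrograde pool (bidirectional mode), or \code{NULL}.
#' @export
concentration_state <- function(c0, c_plus, time = 0, c_minus = NULL) {
  stopifnot(length(c0) == length(c_plus), all(is.finite(c0)),
            all(is.finite(c_plus)))
  structure(list(c0 = c0, c_plus = c_plus, c_minus = c_minus, time = time),
            class = "concentration_state")
}

#' Spatially uniform balanced state
#'
#' The uniform state with \code{c0 = c_in} and \code{c_plus} at the
#' attachment/detachment equilibrium \code{(k+ / k'+) c0}, a stationary
#' point of the transport model (all spatial terms vanish and the reaction
#' terms balance).
#'
#' @param g a \code{template_graph}.
#' @param params \code{simulation_params}.
#' @export
uniform_balanced_state <- function(g, params) {
  c0 <- rep(params$c_in, g$n)
  concentration_state(c0, (params$k_plus / params$kp_plus) * c0)
}

#' Poiseuille velocity field on a template graph
#'
#' Each node on a cross section of radius R at radial distance r moves at
#' \code{u_sec * (1 - (r/R)^2)} along the local centerline tangent (zero at
#' the neurite wall). The section peak speed \code{u_sec} equals \code{u_i}
#' at the inlet and follows area-weighted flux conservation downstream: along
#' a run it scales with R_parent^2/R^2, and at a branch point the parent
#' volumetric flux is split over the children in proportion to their
#' cross-section areas.
#'
#' @param g a \code{template_graph}.
#' @param params \code{simulation_params} (uses \code{u_i}).
#' @return an object of class \code{"velocity_field"}: per-node velocity
#'   vectors (\code{vec}), speeds, and per-section peak speed \code{u_sec}.
#' @export
compute_velocity <- function(g, params) {
  if (!any(g$role == "inlet")) {
    stop("graph has no inlet-role nodes; cannot anchor the velocity field")
  }
  u_sec <- params$u_i * g$sections$u_rel
  speed <- u_sec[g$sec] * (1 - g$r_frac^2)
  tang <- as.matrix(g$sections[g$sec, c("tx", "ty", "tz")])
  structure(list(vec = tang * speed, speed = speed, u_sec = u_sec),
            class = "velocity_field")
}

#' Volumetric flux through each cross section
#'
#' Cross-section mean of the parabolic profile is \code{u_sec / 2}, so the
#' flux is \code{pi R^2 u_sec / 2}.
#'
#' @param g a \code{template_graph}.
#' @param v a \code{velocity_field}.
#' @export
section_flux <- function(g, v) {
  pi * g$sections$radius^2 * v$u_sec / 2
}

#' Discrete spatial operators of the transport model
#'
#' Returns the graph Laplacian \code{L} (edge weights 1/length^2, used for
#' diffusion of c0), the upwind divergence operator \code{Adv} (so that
#' \code{Adv \%*\% c} approximates div(u c)), and the full right-hand-side
#' operator \code{A} of the semi-discrete system d(c0, c+)/dt = A (c0, c+)
#' without boundary rows modified.
#'
#' @param g a \code{template_graph}.
#' @param params \code{simulation_params}.
#' @param v a \code{velocity_field} for \code{g}.
#' @export
transport_operators <- function(g, params, v) {
  N <- g$n
  e <- g$edges
  dvec <- g$pos[e[, 2], , drop = FALSE] - g$pos[e[, 1], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  w <- 1 / len^2
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  L <- sparseMatrix(i = i, j = j, x = c(w, w), dims = c(N, N))
  L <- L - Diagonal(N, x = as.numeric(Matrix::rowSums(L)))
  # upwind advective derivative u . grad c (the model's transport term; for
  # the incompressible flow the advective and conservative forms agree in the
  # continuum, and the advective form keeps uniform fields exactly invariant
  # on the graph): at node i, sum over upwind neighbours j (flow j -> i) of
  # (-s_ij)/d * (c_i - c_j), with s_ij the edge-midpoint velocity component
  # from i toward j.
  umid <- 0.5 * (v$vec[e[, 1], , drop = FALSE] + v$vec[e[, 2], , drop = FALSE])
  s <- rowSums(umid * dvec) / len      # component i -> j
  sd <- c(s, -s)                       # directed, rows (i->j) then (j->i)
  dirlen <- c(len, len)
  upw <- pmax(-sd, 0) / dirlen         # weight of upwind neighbour j
  Adv <- sparseMatrix(i = i, j = j, x = -upw, dims = c(N, N)) +
    sparseMatrix(i = i, j = i, x = upw, dims = c(N, N))
  kp <- params$k_plus; kpp <- params$kp_plus
  I <- Diagonal(N)
  A <- rbind(cbind(params$D * L - kp * I, kpp * I),
             cbind(kp * I, -Adv - kpp * I))
  if (!params$unidirectional) {
    km <- params$k_minus; kpm <- params$kp_minus
    # retrograde pool advected against the flow
    upm <- pmax(sd, 0) / dirlen
    AdvM <- sparseMatrix(i = i, j = j, x = -upm, dims = c(N, N)) +
      sparseMatrix(i = i, j = i, x = upm, dims = c(N, N))
    Z <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(N, N))
    A <- rbind(
      cbind(params$D * L - (kp + km) * I, kpp * I, kpm * I),
      cbind(kp * I, -Adv - kpp * I, Z),
      cbind(km * I, Z, -AdvM - kpm * I))
  }
  list(L = L, Adv = Adv, A = A, edge_len = len)
}

# boundary bookkeeping: Dirichlet rows and zero-gradient copy rows in the
# stacked (c0, c+[, c-]) indexing
transport_bc <- function(g, params) {
  N <- g$n
  nf <- if (params$unidirectional) 2L else 3L
  inlet <- which(g$role == "inlet")
  outlet <- which(g$role == "outlet")
  # zero-gradient partner: same template index on the neighbouring section
  partner <- function(nodes) {
    off <- c(0L, cumsum(g$sections$nn))
    vapply(nodes, function(i) {
      s <- g$sec[i]
      p <- g$sections$parent[s]
      if (p == 0L) {  # inlet-side free end: copy from the child section
        p <- which(g$sections$parent == s)[1L]
      }
      off[p] + g$ti[i]
    }, 0L)
  }
  dir_idx <- integer(0); dir_val <- numeric(0)
  zg_idx <- integer(0); zg_partner <- integer(0)
  if (!is.null(params$c_in) && length(inlet)) {
    dir_idx <- c(inlet, inlet + N)
    dir_val <- c(rep(params$c_in, length(inlet)),
                 rep(params$lambda_in * params$c_in, length(inlet)))
  }
  if (length(outlet)) {
    if (!is.null(params$c_out)) {
      dir_idx <- c(dir_idx, outlet)
      dir_val <- c(dir_val, rep(params$c_out, length(outlet)))
      zg_idx <- c(zg_idx, outlet + N)
      zg_partner <- c(zg_partner, partner(outlet) + N)
      if (nf == 3L) {
        dir_idx <- c(dir_idx, outlet + 2L * N)
        dir_val <- c(dir_val, rep(params$lambda_out * params$c_out,
                                  length(outlet)))
      }
    } else {
      for (f in seq_len(nf) - 1L) {
        zg_idx <- c(zg_idx, outlet + f * N)
        zg_partner <- c(zg_partner, partner(outlet) + f * N)
      }
    }
  }
  list(dir_idx = dir_idx, dir_val = dir_val,
       zg_idx = zg_idx, zg_partner = zg_partner, nf = nf)
}

# assemble and cache the stepping system
build_transport_system <- function(g, params, v, method = "implicit") {
  ops <- transport_operators(g, params, v)
  bc <- transport_bc(g, params)
  N <- g$n; nf <- bc$nf
  A <- ops$A
  fixed <- c(bc$dir_idx, bc$zg_idx)
  if (length(fixed)) {
    keep <- !(seq_len(nf * N) %in% fixed)
    A <- Diagonal(nf * N, x = as.numeric(keep)) %*% A
  }
  sys <- list(ops = ops, bc = bc, A = A, N = N, nf = nf, method = method,
              dt = params$dt)
  if (method == "implicit") {
    S <- Diagonal(nf * N) - params$dt * A
    if (length(bc$zg_idx)) {
      S <- S + sparseMatrix(i = bc$zg_idx, j = bc$zg_partner,
                            x = rep(-1, length(bc$zg_idx)),
                            dims = dim(S))
    }
    sys$S_lu <- Matrix::lu(S)
  } else {
    hmin <- min(ops$edge_len)
    umax <- max(abs(v$speed), 1e-12)
    dt_diff <- if (params$D > 0) hmin^2 / (2 * params$D) else Inf
    dt_stab <- 0.4 * min(dt_diff, hmin / umax,
                         0.8 / max(abs(Matrix::diag(A)), 1e-12))
    sys$nsub <- max(1L, as.integer(ceiling(params$dt / dt_stab)))
    sys$h <- params$dt / sys$nsub
  }
  sys
}

impose_bc_vec <- function(x, bc) {
  if (length(bc$dir_idx)) x[bc$dir_idx] <- bc$dir_val
  if (length(bc$zg_idx)) x[bc$zg_idx] <- x[bc$zg_partner]
  x
}

state_to_vec <- function(state, nf) {
  x <- c(state$c0, state$c_plus)
  if (nf == 3L) x <- c(x, state$c_minus %||% numeric(length(state$c0)))
  x
}

step_system <- function(sys, x) {
  bc <- sys$bc
  if (sys$method == "implicit") {
    b <- x
    if (length(bc$dir_idx)) b[bc$dir_idx] <- bc$dir_val
    if (length(bc$zg_idx)) b[bc$zg_idx] <- 0
    x <- as.numeric(Matrix::solve(sys$S_lu, b))
  } else {
    for (k in seq_len(sys$nsub)) {
      x <- x + sys$h * as.numeric(sys$A %*% x)
      x <- impose_bc_vec(x, bc)
    }
  }
  x
}

#' Solve the transport model on a template graph
#'
#' Method-of-lines integration of the motor-assisted transport model:
#' diffusion by the weighted graph Laplacian, advection by edgewise upwind
#' differences along the velocity field, linear reaction coupling between
#' the free and bound pools. Default time stepping is implicit Euler with a
#' cached sparse factorization (unconditionally stable on the stiff
#' template-graph operator); explicit Euler with automatic stable
#' substepping is available via \code{method = "explicit"}.
#'
#' @param g a \code{template_graph}.
#' @param params \code{simulation_params}.
#' @param v a \code{velocity_field}; computed from \code{params} if missing.
#' @param init initial \code{concentration_state}; zeros if \code{NULL}.
#' @param n_steps number of reporting steps of length \code{params$dt}.
#' @param method \code{"implicit"} (default) or \code{"explicit"}.
#' @param system a prebuilt stepping system (internal reuse across calls).
#' @return a \code{"transport_trajectory"}: matrices \code{c0}, \code{c_plus}
#'   (nodes x steps+1) and \code{times}.
#' @export
solve_transport <- function(g, params, v = NULL, init = NULL, n_steps = 50,
                            method = c("implicit", "explicit"),
                            system = NULL) {
  method <- match.arg(method)
  if (is.null(v)) v <- compute_velocity(g, params)
  sys <- system %||% build_transport_system(g, params, v, method)
  nf <- sys$nf; N <- sys$N
  if (is.null(init)) init <- concentration_state(numeric(N), numeric(N))
  x <- impose_bc_vec(state_to_vec(init, nf), sys$bc)
  out <- matrix(0, nf * N, n_steps + 1L)
  out[, 1L] <- x
  cap <- 1e6 * max(max(abs(x)), 1)
  for (k in seq_len(n_steps)) {
    x <- step_system(sys, x)
    if (any(!is.finite(x)) || max(abs(x)) > cap) {
      stop("stability error at step ", k,
           ": concentrations diverged; use a smaller dt or implicit stepping")
    }
    out[, k + 1L] <- x
  }
  structure(list(c0 = out[seq_len(N), , drop = FALSE],
                 c_plus = out[N + seq_len(N), , drop = FALSE],
                 c_minus = if (nf == 3L) out[2L * N + seq_len(N), , drop = FALSE],
                 times = init$time + params$dt * (0:n_steps),
                 method = method),
            class = "transport_trajectory")
}

#' Run the solver until the transport process is steady
#'
#' Steps until the max-norm relative change per unit time drops below
#' \code{tol}, i.e. \code{max|c(t+dt) - c(t)| / (dt * max|c(t+dt)|) < tol}.
#'
#' @inheritParams solve_transport
#' @param tol relative-change-per-second tolerance.
#' @param max_time cap on simulated time, s.
#' @return list with the \code{trajectory}, the stopping time
#'   \code{steady_time} and a \code{steady} flag (\code{FALSE} when
#'   \code{max_time} was reached first).
#' @export
run_to_steady_state <- function(g, params, v = NULL, init = NULL,
                                tol = 1e-4, max_time = 200,
                                method = c("implicit", "explicit")) {
  method <- match.arg(method)
  if (is.null(v)) v <- compute_velocity(g, params)
  sys <- build_transport_system(g, params, v, method)
  nf <- sys$nf; N <- sys$N
  if (is.null(init)) init <- concentration_state(numeric(N), numeric(N))
  x <- impose_bc_vec(state_to_vec(init, nf), sys$bc)
  xs <- list(x)
  t <- init$time
  steady <- FALSE
  while (t < init$time + max_time - 1e-12) {
    xn <- step_system(sys, x)
    t <- t + params$dt
    xs[[length(xs) + 1L]] <- xn
    rel <- max(abs(xn - x)) / (params$dt * max(max(abs(xn)), 1e-300))
    x <- xn
    if (rel < tol) { steady <- TRUE; break }
  }
  out <- do.call(cbind, xs)
  traj <- structure(list(c0 = out[seq_len(N), , drop = FALSE],
                         c_plus = out[N + seq_len(N), , drop = FALSE],
                         c_minus = if (nf == 3L) out[2L * N + seq_len(N), , drop = FALSE],
                         times = init$time + params$dt * (seq_along(xs) - 1L),
                         method = method),
                    class = "transport_trajectory")
  list(trajectory = traj, steady_time = t, steady = steady)
}

#' Direct steady-state solve
#'
#' Solves the stationary transport problem (spatial operator zero, boundary
#' rows imposed) as one sparse linear system.
#'
#' @inheritParams solve_transport
#' @return a \code{concentration_state} (time \code{NA}).
#' @export
steady_state_solve <- function(g, params, v = NULL) {
  if (is.null(v)) v <- compute_velocity(g, params)
  ops <- transport_operators(g, params, v)
  bc <- transport_bc(g, params)
  N <- g$n; nf <- bc$nf
  A <- ops$A
  rhs <- numeric(nf * N)
  fixed <- c(bc$dir_idx, bc$zg_idx)
  keep <- !(seq_len(nf * N) %in% fixed)
  M <- Diagonal(nf * N, x = as.numeric(keep)) %*% A
  if (length(bc$dir_idx)) {
    M <- M + sparseMatrix(i = bc$dir_idx, j = bc$dir_idx,
                          x = rep(1, length(bc$dir_idx)), dims = dim(M))
    rhs[bc$dir_idx] <- bc$dir_val
  }
  if (length(bc$zg_idx)) {
    M <- M + sparseMatrix(i = c(bc$zg_idx, bc$zg_idx),
                          j = c(bc$zg_idx, bc$zg_partner),
                          x = rep(c(1, -1), each = length(bc$zg_idx)),
                          dims = dim(M))
  }
  x <- as.numeric(Matrix::solve(M, rhs))
  concentration_state(x[seq_len(N)], x[N + seq_len(N)], time = NA,
                      c_minus = if (nf == 3L) x[2L * N + seq_len(N)])
}

#' Extract one state from a trajectory
#'
#' @param traj a \code{transport_trajectory}.
#' @param k step index (1 = initial state).
#' @export
get_state <- function(traj, k) {
  concentration_state(traj$c0[, k], traj$c_plus[, k],
                      time = traj$times[k],
                      c_minus = if (!is.null(traj$c_minus)) traj$c_minus[, k])
}

#' @export
print.transport_trajectory <- function(x, ...) {
  cat("Transport trajectory: ", nrow(x$c0), " nodes, ",
      length(x$times), " states, t = [", x$times[1], ", ",
      x$times[length(x$times)], "] s (", x$method, " stepping)\n", sep = "")
  invisible(x)
}

#' Export a trajectory's final state (or all states) as CSV
#'
#' @param traj a \code{transport_trajectory}.
#' @param g the owning \code{template_graph}.
#' @param path output path.
#' @param all write every time step (long format) instead of the last state.
#' @export
write_trajectory_csv <- function(traj, g, path, all = FALSE) {
  ks <- if (all) seq_along(traj$times) else length(traj$times)
  df <- do.call(rbind, lapply(ks, function(k) {
    data.frame(time = traj$times[k], node = seq_len(g$n),
               x = g$pos[, 1], y = g$pos[, 2], z = g$pos[, 3],
               section = g$sec, c0 = traj$c0[, k], c_plus = traj$c_plus[, k])
  }))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a trajectory along the arc length
#'
#' Draws the section-mean free and bound concentrations against each
#' section's distance from the inlet, for a set of time steps.
#'
#' @param x a \code{transport_trajectory}.
#' @param g the owning \code{template_graph}.
#' @param steps which states to draw (default 5 evenly spaced).
#' @param ... passed to \code{matplot}.
#' @export
plot.transport_trajectory <- function(x, g, steps = NULL, ...) {
  ns <- nrow(g$sections)
  ctr <- as.matrix(g$sections[, c("cx", "cy", "cz")])
  arc <- numeric(ns)
  for (s in seq_len(ns)) {
    p <- g$sections$parent[s]
    arc[s] <- if (p == 0L) 0 else arc[p] + sqrt(sum((ctr[s, ] - ctr[p, ])^2))
  }
  if (is.null(steps)) {
    steps <- unique(round(seq(1, length(x$times), length.out = 5)))
  }
  secmean <- function(v) tapply(v, g$sec, mean)
  y0 <- sapply(steps, function(k) secmean(x$c0[, k]))
  graphics::matplot(arc[order(arc)], y0[order(arc), , drop = FALSE],
                    type = "l", lty = 1,
                    xlab = "arc length from inlet (um)",
                    ylab = "section-mean c0 (mol/um^3)", ...)
  invisible(x)
}
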