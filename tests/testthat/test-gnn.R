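test_that("the analytic edge function matches its closed form", {
  expect_equal(edge_features(c(0, 0, 0), c(0, 0, 2), 1, 3), c(1.0, 2.0))
  expect_equal(edge_features(c(1, 1, 1), c(2, 1, 1), 5, 5)[1], 0)
  # antisymmetry of the gradient component, symmetry of the length
  a <- edge_features(c(0, 1, 0), c(2, 0, 2), 0.3, 0.9)
  b <- edge_features(c(2, 0, 2), c(0, 1, 0), 0.9, 0.3)
  expect_equal(a[1], -b[1])
  expect_equal(a[2], b[2])
  expect_error(edge_features(c(1, 1, 1), c(1, 1, 1), 0, 1), "zero")
})

test_that("a GN block matches a step-by-step hand evaluation on a path graph", {
  # 3-node path with hand-set weights
  g <- list(pos = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3)),
            edges = rbind(c(1L, 2L), c(2L, 3L)), n = 3L)
  class(g) <- "template_graph"
  set.seed(21)
  block <- neuriteflow:::mlp_init(c(4 + 3, 5, 5, 4))
  h <- matrix(rnorm(12), 3, 4)
  c0 <- c(1, 2, 0.5); cp <- c(0.2, 0.1, 0.4)
  out <- gn_block_forward(block, g, h, c0, cp)
  # oracle: manual aggregate -> concatenate -> MLP per node
  relu <- function(x) pmax(x, 0)
  for (i in 1:3) {
    nb <- if (i == 1) list(c(2, 1)) else if (i == 3) list(c(2, 2)) else
      list(c(1, 1), c(3, 2))
    fs <- sapply(nb, function(e) {
      d <- e[2]
      c((c0[e[1]] - c0[i]) / d, (cp[e[1]] - cp[i]) / d, d)
    })
    agg <- rowMeans(matrix(fs, nrow = 3))
    x <- c(h[i, ], agg)
    a1 <- relu(x %*% block[[1]]$W + block[[1]]$b)
    a2 <- relu(a1 %*% block[[2]]$W + block[[2]]$b)
    a3 <- a2 %*% block[[3]]$W + block[[3]]$b
    expect_equal(out[i, ], as.numeric(a3), tolerance = 1e-12)
  }
})

test_that("GN blocks are permutation-equivariant", {
  g <- fx_pipe_graph()
  set.seed(31)
  block <- neuriteflow:::mlp_init(c(6 + 3, 8, 8, 5))
  h <- matrix(rnorm(g$n * 6), g$n, 6)
  c0 <- runif(g$n); cp <- runif(g$n)
  base <- gn_block_forward(block, g, h, c0, cp)
  for (rep in seq_len(100)) {
    pm <- sample.int(g$n)
    inv <- integer(g$n); inv[pm] <- seq_len(g$n)
    g2 <- g
    g2$pos <- g$pos[pm, ]
    g2$edges <- matrix(inv[g$edges], ncol = 2)
    out <- gn_block_forward(block, g2, h[pm, ], c0[pm], cp[pm])
    expect_identical(out, base[pm, ])
  }
})

test_that("aggregated edge parts vanish when concentrations are constant", {
  g <- fx_pipe_graph()
  geo <- neuriteflow:::gnn_geometry(g, fx_params())
  ft <- neuriteflow:::geo_features(geo, g, fx_params(),
                                   matrix(1, g$n, 2), matrix(0.5, g$n, 2))
  expect_equal(max(abs(ft$E[, 1:2])), 0)
})

test_that("a zero-initialized direct decoder predicts only the boundary rows", {
  g <- fx_pipe_graph()
  params <- fx_params()
  model <- simulator_model("pipe", seed = 5, zero_decoder = TRUE,
                           delta = FALSE)
  st <- concentration_state(runif(g$n), runif(g$n))
  out <- simulator_step(model, g, st, params)
  inlet <- which(g$role == "inlet")
  expect_equal(out$c0[inlet], rep(params$c_in, length(inlet)))
  expect_equal(out$c_plus[inlet], rep(2 * params$c_in, length(inlet)))
  expect_equal(max(abs(out$c0[-inlet])), 0)
  expect_equal(max(abs(out$c_plus[-inlet])), 0)
  # shape contract
  expect_length(out$c0, g$n)
  expect_length(out$c_plus, g$n)
})

test_that("rollouts respect length and boundary contracts", {
  g <- fx_pipe_graph()
  params <- fx_params()
  model <- simulator_model("pipe", seed = 6)
  init <- uniform_balanced_state(g, params)
  tr0 <- rollout(model, g, init, params, n_steps = 0)
  expect_equal(ncol(tr0$c0), 1L)
  tr <- rollout(model, g, init, params, n_steps = 5)
  inlet <- which(g$role == "inlet")
  for (k in seq_len(6)) {
    expect_equal(tr$c0[inlet, k], rep(params$c_in, length(inlet)))
    expect_equal(tr$c_plus[inlet, k], rep(2 * params$c_in, length(inlet)))
  }
})

test_that("a perfect (solver-step) surrogate reproduces the solver trajectory", {
  g <- fx_pipe_graph()
  params <- fx_params()
  surr <- solver_surrogate(g, params)
  init <- concentration_state(numeric(g$n), numeric(g$n))
  ref <- solve_transport(g, params, init = init, n_steps = 10)
  init2 <- get_state(ref, 1)  # with boundary values imposed
  tr <- rollout(surr, g, init2, params, n_steps = 10)
  expect_equal(tr$c0, ref$c0, tolerance = 1e-12)
  expect_equal(tr$c_plus, ref$c_plus, tolerance = 1e-12)
})

test_that("the physics-informed loss vanishes at the stationary state", {
  g <- fx_pipe_graph()
  params <- fx_params()
  v <- compute_velocity(g, params)
  st <- uniform_balanced_state(g, params)
  expect_lt(simulator_loss(st, st, st, g, params, v), 1e-10)
})

test_that("disabling the residual terms reduces the loss to the MSE", {
  g <- fx_pipe_graph()
  params <- fx_params()
  set.seed(41)
  pred <- concentration_state(runif(g$n), runif(g$n))
  truth <- concentration_state(runif(g$n), runif(g$n))
  prev <- concentration_state(runif(g$n), runif(g$n))
  mse <- mean((pred$c0 - truth$c0)^2 + (pred$c_plus - truth$c_plus)^2)
  expect_equal(simulator_loss(pred, truth, prev, g, params,
                              include_residual = FALSE), mse)
})

test_that("the simulator loss matches a hand evaluation on a 4-node graph", {
  g <- list(pos = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3.5)),
            edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)), n = 4L)
  class(g) <- "template_graph"
  params <- simulation_params(dt = 0.1)
  u <- 0.2
  v <- list(vec = matrix(rep(c(0, 0, u), each = 4), 4), speed = rep(u, 4))
  pred <- concentration_state(c(1, 0.8, 0.6, 0.5), c(2, 1.5, 1.2, 1.0))
  truth <- concentration_state(c(1, 0.9, 0.55, 0.45), c(2, 1.4, 1.1, 1.0))
  prev <- concentration_state(c(1, 0.7, 0.65, 0.55), c(2, 1.6, 1.3, 0.9))
  got <- simulator_loss(pred, truth, prev, g, params, v)
  # independent term-by-term evaluation
  d <- c(1, 1, 1.5)
  lap <- function(c0) c(
    (c0[2] - c0[1]) / d[1]^2,
    (c0[1] - c0[2]) / d[1]^2 + (c0[3] - c0[2]) / d[2]^2,
    (c0[2] - c0[3]) / d[2]^2 + (c0[4] - c0[3]) / d[3]^2,
    (c0[3] - c0[4]) / d[3]^2)
  upw <- function(cp) c(0, u * (cp[2] - cp[1]) / d[1],
                        u * (cp[3] - cp[2]) / d[2],
                        u * (cp[4] - cp[3]) / d[3])
  mseterm <- mean((pred$c0 - truth$c0)^2 + (pred$c_plus - truth$c_plus)^2)
  r0 <- (pred$c0 - prev$c0) / 0.1 -
    (lap(pred$c0) - pred$c0 + 0.5 * pred$c_plus)
  rp <- (pred$c_plus - prev$c_plus) / 0.1 + upw(pred$c_plus) -
    pred$c0 + 0.5 * pred$c_plus
  expect_equal(got, mseterm + mean(r0^2) + mean(rp^2), tolerance = 1e-12)
})
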