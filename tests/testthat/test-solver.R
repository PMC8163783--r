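test_that("the Poiseuille profile is exact at the axis and the wall", {
  g <- fx_pipe_graph()
  v <- compute_velocity(g, fx_params())
  inlet_center <- which(g$role == "inlet" & g$r_frac == 0)
  expect_equal(v$speed[inlet_center], 0.1)                  # u_i at r = 0
  expect_equal(max(abs(v$speed[g$r_frac == 1])), 0)         # no-slip wall
  # interior profile: u = u_sec (1 - (r/R)^2) at r = R/2
  mid <- which(g$sec == 2L & g$r_frac == 0.5)
  expect_equal(v$speed[mid], rep(0.75 * v$u_sec[2L], 8L))
  g2 <- g; g2$role[g2$role == "inlet"] <- "interior"
  expect_error(compute_velocity(g2, fx_params()), "inlet")
})

test_that("volumetric flux is conserved through bifurcations", {
  for (s in seq_len(100)) {
    set.seed(4000 + s)
    rc <- runif(2, 0.5, 1)
    ang <- runif(1, 15, 45)
    g <- build_bifurcation_graph(fx_bif_unit(r_child = rc, angle = ang))
    v <- compute_velocity(g, fx_params())
    Q <- section_flux(g, v)
    kids <- split(seq_len(nrow(g$sections)), factor(g$sections$parent,
                                                    levels = 0:nrow(g$sections)))
    for (p in seq_len(nrow(g$sections))) {
      ch <- kids[[as.character(p)]]
      if (length(ch)) {
        expect_lt(abs(Q[p] - sum(Q[ch])) / Q[p], 1e-12)
      }
    }
  }
  # the symmetric case: children at R_parent / sqrt(2) keep the parent speed
  g <- build_bifurcation_graph(fx_bif_unit(r_child = rep(1 / sqrt(2), 2)))
  v <- compute_velocity(g, fx_params())
  expect_equal(max(v$u_sec), min(v$u_sec), tolerance = 1e-12)
})

test_that("the uniform balanced state is stationary on pipes and bifurcations", {
  params <- fx_params()  # D = 1, k+- = 1, k'+- = 0.5, u_i = 0.1, dt = 0.1
  for (g in list(fx_pipe_graph(), fx_bif_graph())) {
    st <- uniform_balanced_state(g, params)
    expect_equal(st$c_plus, 2 * st$c0)  # lambda = k+ / k'+ = 2
    for (method in c("implicit", "explicit")) {
      tr <- solve_transport(g, params, init = st, n_steps = 5, method = method)
      expect_lt(max(abs(tr$c0 - st$c0)), 1e-10)
      expect_lt(max(abs(tr$c_plus - st$c_plus)), 1e-10)
    }
  }
})

test_that("pure diffusion with closed boundaries conserves mass", {
  g <- fx_pipe_graph()
  p0 <- simulation_params(D = 1, k_plus = 0, k_minus = 0, kp_plus = 0,
                          kp_minus = 0, u_i = 0, c_in = NULL)
  v <- compute_velocity(g, p0)
  g2 <- g
  g2$role[] <- "interior"  # no Dirichlet, no outlet copy: closed domain
  set.seed(8)
  init <- concentration_state(runif(g$n), numeric(g$n))
  for (method in c("explicit", "implicit")) {
    sys <- neuriteflow:::build_transport_system(g2, p0, v, method)
    x <- neuriteflow:::state_to_vec(init, 2L)
    m0 <- sum(x)
    for (k in seq_len(1000)) x <- neuriteflow:::step_system(sys, x)
    expect_lt(abs(sum(x) - m0) / m0, 1e-10)
    expect_true(all(x > -1e-12))
  }
})

test_that("an advected pulse travels at the mean template speed", {
  p <- pipe_unit(cbind(0, 0, seq(0, 30, by = 0.5)), 1.0)
  g <- build_pipe_graph(p, section_spacing = 1)
  pr <- simulation_params(D = 0, k_plus = 0, k_minus = 0, kp_plus = 0,
                          kp_minus = 0, u_i = 0.5, c_in = NULL)
  v <- compute_velocity(g, pr)
  z <- g$pos[, 3]
  init <- concentration_state(numeric(g$n), exp(-(z - 8)^2 / 4))
  tr <- solve_transport(g, pr, v, init, n_steps = 100, method = "explicit")
  com <- function(cp) sum(z * cp) / sum(cp)
  drift <- com(tr$c_plus[, 101]) - com(tr$c_plus[, 1])
  expected <- mean(v$speed) * 10          # ubar * t
  expect_lt(abs(drift - expected) / expected, 0.05)
})

test_that("solutions self-converge under time-step refinement", {
  g <- fx_pipe_graph()
  params <- fx_params()
  pr2 <- neuriteflow:::simulation_params_set(params, dt = 0.05)
  tr1 <- solve_transport(g, params, n_steps = 100)           # T = 10 s
  tr2 <- solve_transport(g, pr2, n_steps = 200)
  err <- max(abs(tr1$c0[, 101] - tr2$c0[, 201])) / max(tr2$c0[, 201])
  expect_lt(err, 0.01)
})

test_that("the steady pipe profile converges to a 1D two-field oracle", {
  # uniform plug velocity so the template graph reduces exactly to a 1D
  # two-field system along the section chain; the oracle is an independent
  # dense-grid 1D steady solve
  params <- simulation_params(c_in = 1, c_out = 0, u_i = 0.1)
  ubar <- 0.1
  L_pipe <- 10
  oracle_1d <- function(nfine) {
    h <- L_pipe / nfine
    n <- nfine + 1L
    A <- matrix(0, 2L * n, 2L * n)
    b <- numeric(2L * n)
    for (i in 2:(n - 1L)) {
      A[i, i - 1L] <- 1 / h^2; A[i, i + 1L] <- 1 / h^2
      A[i, i] <- -2 / h^2 - 1          # D = 1, k+ = 1
      A[i, n + i] <- 0.5               # k'+
      A[n + i, n + i] <- -ubar / h - 0.5
      A[n + i, n + i - 1L] <- ubar / h
      A[n + i, i] <- 1
    }
    A[1, 1] <- 1; b[1] <- 1
    A[n, n] <- 1; b[n] <- 0
    A[n + 1L, n + 1L] <- 1; b[n + 1L] <- 2
    A[2L * n, 2L * n] <- 1; A[2L * n, 2L * n - 1L] <- -1
    x <- solve(A, b)
    list(z = seq(0, L_pipe, by = h), c0 = x[1:n], cp = x[(n + 1L):(2L * n)])
  }
  ora <- oracle_1d(2000)
  errs <- vapply(c(2, 1, 0.5), function(h) {
    p <- pipe_unit(cbind(0, 0, seq(0, L_pipe, by = 0.25)), 1.0)
    g <- build_pipe_graph(p, section_spacing = h)
    v <- compute_velocity(g, params)
    v$vec <- matrix(rep(c(0, 0, ubar), each = g$n), g$n)  # plug flow
    v$speed <- rep(ubar, g$n)
    st <- steady_state_solve(g, params, v)
    secmean <- tapply(st$c_plus, g$sec, mean)
    zsec <- g$sections$cz
    max(abs(secmean - approx(ora$z, ora$cp, zsec)$y))
  }, 0)
  expect_true(all(diff(errs) < 0))  # monotone decrease over 3 refinements
  # first-order scheme: quartering the spacing should (more than) halve the
  # error against the fine-grid oracle
  expect_lt(errs[3], errs[1] / 2)
})

test_that("concentrations stay non-negative under the stability bound", {
  g <- fx_bif_graph()
  params <- fx_params()
  set.seed(9)
  init <- concentration_state(runif(g$n), runif(g$n))
  tr <- solve_transport(g, params, init = init, n_steps = 100,
                        method = "explicit")
  expect_gt(min(tr$c0, tr$c_plus), -1e-12)
})

test_that("run_to_steady_state stops immediately at a stationary start", {
  g <- fx_pipe_graph()
  params <- fx_params()
  st <- uniform_balanced_state(g, params)
  rs <- run_to_steady_state(g, params, init = st, tol = 1e-6, max_time = 10)
  expect_true(rs$steady)
  expect_equal(rs$steady_time, params$dt)
  # tol = 0 can never be met: runs to max_time and reports not-steady
  rs0 <- run_to_steady_state(g, params, init = st, tol = 0, max_time = 1)
  expect_false(rs0$steady)
  expect_gte(rs0$steady_time, 1 - 1e-9)
})

test_that("a short pipe reaches steadiness near the direct steady solve", {
  p <- pipe_unit(cbind(0, 0, seq(0, 4, by = 0.5)), 1.0)
  g <- build_pipe_graph(p, section_spacing = 2)
  params <- simulation_params(c_in = 1, c_out = 0)
  rs <- run_to_steady_state(g, params, tol = 1e-4, max_time = 120)
  expect_true(rs$steady)
  st <- steady_state_solve(g, params)
  last <- ncol(rs$trajectory$c0)
  expect_lt(max(abs(rs$trajectory$c0[, last] - st$c0)), 0.02)
})

test_that("diverging explicit integration aborts with a stability error", {
  g <- fx_pipe_graph()
  params <- fx_params()
  v <- compute_velocity(g, params)
  sys <- neuriteflow:::build_transport_system(g, params, v, "explicit")
  sys$nsub <- 1L; sys$h <- 50  # deliberately break the stability bound
  init <- uniform_balanced_state(g, params)
  init$c0[30] <- 5
  expect_error(solve_transport(g, params, v, init, n_steps = 200,
                               method = "explicit", system = sys),
               "stability error")
})
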