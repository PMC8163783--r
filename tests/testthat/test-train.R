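test_that("the root-mean-square nodal error follows its printed form", {
  expect_equal(mae(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(mae(c(2, 3, 4), c(1, 2, 3)), 1)          # constant offset
  expect_equal(mae(c(1, 2, 3), c(1, 1, 1)), sqrt(5 / 3))
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("the relative error normalizes by the ground-truth range", {
  expect_equal(mre(c(1, 2), c(1, 2)), 0)
  expect_equal(mre(c(1.1, 3.1), c(1, 3)), 0.1 / 2 * 100)  # range 2, MAE 0.1
  expect_error(mre(c(1, 2), c(1, 1)), "range")
  # scale invariance
  set.seed(3)
  p <- runif(10); t <- runif(10)
  expect_equal(mre(p, t), mre(7 * p, 7 * t), tolerance = 1e-12)
  # independent two-line recomputation on random vectors
  expect_equal(mre(p, t), sqrt(mean((p - t)^2)) / diff(range(t)) * 100)
})

test_that("build_dataset yields one sample per consecutive state pair", {
  g <- fx_pipe_graph()
  params <- simulation_params(c_out = 0)
  tr <- solve_transport(g, params, n_steps = 10)  # 11 states
  ds <- build_dataset(list(list(graph = g, trajectory = tr, c_in = 1)),
                      "pipe", params)
  expect_equal(nrow(ds$index), 10L)
  # subsampling keeps the requested number of evenly spread pairs
  ds5 <- build_dataset(list(list(graph = g, trajectory = tr, c_in = 1)),
                       "pipe", params, pairs_per_trajectory = 5)
  expect_equal(nrow(ds5$index), 5L)
  # too-short trajectories are skipped with a warning
  tr1 <- tr; tr1$times <- tr$times[1]; tr1$c0 <- tr$c0[, 1, drop = FALSE]
  tr1$c_plus <- tr$c_plus[, 1, drop = FALSE]
  expect_warning(
    ds2 <- build_dataset(list(list(graph = g, trajectory = tr, c_in = 1),
                              list(graph = g, trajectory = tr1, c_in = 1)),
                         "pipe", params),
    "fewer than 2")
  expect_equal(nrow(ds2$index), 10L)
})

test_that("dataset generation is deterministic for a fixed manifest", {
  d1 <- generate_transport_data(n_networks = 2, n_boundary = 2, n_steps = 6,
                                pairs_per_trajectory = 2, n_geometries = 3,
                                seed = 9)
  d2 <- generate_transport_data(n_networks = 2, n_boundary = 2, n_steps = 6,
                                pairs_per_trajectory = 2, n_geometries = 3,
                                seed = 9)
  expect_identical(d1$datasets$pipe$blocks, d2$datasets$pipe$blocks)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("training is reproducible and reduces the training loss", {
  ds <- fx_small_data()$datasets$pipe
  cfg <- training_config(epochs = 3, seed = 4)
  m1 <- train_simulator(ds, cfg)
  m2 <- train_simulator(ds, cfg)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$log$train_loss, 1), m1$log$train_loss[1])
  expect_error(train_simulator(ds, training_config(epochs = 1, seed = 1,
                                                   lr = 1e300)),
               "non-finite")
})

test_that("zero pde weight reproduces the plain-MSE training dynamics", {
  ds <- fx_small_data()$datasets$pipe
  m_mse <- train_simulator(ds, training_config(epochs = 2, seed = 4,
                                               loss_mode = "mse"))
  m_w0 <- train_simulator(ds, training_config(epochs = 2, seed = 4,
                                              loss_mode = "mse+pde",
                                              pde_weight = 0))
  expect_lt(abs(m_mse$log$train_loss[1] - m_w0$log$train_loss[1]), 1e-6)
  expect_equal(m_mse$params, m_w0$params, tolerance = 1e-12)
})

test_that("cross-validation folds partition the samples evenly", {
  ds <- fx_small_data()$datasets$pipe
  cv <- cross_validate(ds, training_config(epochs = 1, seed = 4), 4)
  expect_length(cv$fold_mre, 4L)
  expect_equal(sum(cv$fold_sizes), nrow(ds$index))
  expect_lte(max(cv$fold_sizes) - min(cv$fold_sizes), 1L)
  expect_error(cross_validate(ds, training_config(epochs = 1), 1),
               "k_folds")
})

test_that("identical samples across folds give zero fold spread", {
  g <- fx_pipe_graph()
  params <- simulation_params(c_out = 0)
  tr <- solve_transport(g, params, n_steps = 1)
  trajs <- rep(list(list(graph = g, trajectory = tr, c_in = 1)), 8)
  ds <- build_dataset(trajs, "pipe", params)  # 8 identical samples
  cv <- cross_validate(ds, training_config(epochs = 0, seed = 1), 4)
  expect_equal(cv$sd_mre, 0, tolerance = 1e-12)
})

test_that("fine-tuning contracts hold", {
  ds <- fx_small_data()$datasets$pipe
  m <- train_simulator(ds, training_config(epochs = 2, seed = 4))
  m0 <- fine_tune(m, ds, training_config(epochs = 0))
  expect_identical(m0$params, m$params)
  expect_error(fine_tune(m, fx_small_data()$datasets$bifurcation,
                         training_config(epochs = 1)),
               "architecture mismatch")
  # fine-tuning on the training set must not degrade the test loss by > 1%
  m1 <- fine_tune(m, ds, training_config(epochs = 2, seed = 4, lr = 1e-4))
  expect_lt(tail(m1$log$test_loss, 1),
            tail(m$log$test_loss, 1) * 1.01)
})

test_that("model checkpoints round-trip through save/load", {
  ds <- fx_small_data()$datasets$pipe
  m <- train_simulator(ds, training_config(epochs = 1, seed = 4))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$log, m$log)
})
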