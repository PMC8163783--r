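# shared small network with interfaces, plus a truth-derived intermediate
asm_fixture <- function() {
  fx("asm_fixture", function() {
    m <- generate_morphology(1, seed = 19, branch_length_range = c(14, 16))
    sg <- decompose_morphology(m)
    net <- build_network_graph(sg)
    map <- attr(net, "unit_node_map")
    params <- simulation_params(c_out = 0)
    st <- steady_state_solve(net, params)
    units <- lapply(map, function(idx) list(c0 = st$c0[idx],
                                            c_plus = st$c_plus[idx]))
    list(sg = sg, net = net, map = map, params = params,
         gp = global_prediction(units),
         unit_graphs = lapply(sg$units, build_unit_graph))
  })
}

test_that("an identity-initialized assembly is a fixed point on consistent fields", {
  fxa <- asm_fixture()
  model <- assembly_model(seed = 2, identity_init = TRUE)
  out <- assemble_step(model, fxa$sg, fxa$gp, fxa$params,
                       unit_graphs = fxa$unit_graphs)
  for (u in seq_along(fxa$gp$units)) {
    expect_equal(out$units[[u]]$c0, fxa$gp$units[[u]]$c0, tolerance = 1e-12)
    expect_equal(out$units[[u]]$c_plus, fxa$gp$units[[u]]$c_plus,
                 tolerance = 1e-12)
  }
  expect_equal(max(attr(out, "gap_post")), 0)
})

test_that("interface kinds dispatch to the matching component", {
  fxa <- asm_fixture()
  expect_true(all(fxa$sg$adjacency$kind == "p-b"))
  expect_equal(nrow(fxa$sg$adjacency), 3L)
  ispec <- neuriteflow:::interface_spec(fxa$sg, fxa$unit_graphs)
  expect_equal(vapply(ispec, `[[`, "", "kind"), rep("p-b", 3L))
  # canonical ordering puts the pipe first in a p-b pair
  for (sp in ispec) {
    expect_equal(fxa$sg$units[[sp$a]]$kind, "pipe")
    expect_equal(fxa$sg$units[[sp$b]]$kind, "bifurcation")
  }
})

test_that("assemble_step matches an independent gather-concatenate-MLP pass", {
  fxa <- asm_fixture()
  model <- assembly_model(seed = 77, identity_init = FALSE)
  set.seed(55)
  gp <- fxa$gp
  for (u in seq_along(gp$units)) {  # perturb so the two sides disagree
    gp$units[[u]]$c0 <- gp$units[[u]]$c0 + rnorm(length(gp$units[[u]]$c0), 0, 0.05)
    gp$units[[u]]$c_plus <- gp$units[[u]]$c_plus +
      rnorm(length(gp$units[[u]]$c_plus), 0, 0.05)
  }
  out <- assemble_step(model, fxa$sg, gp, fxa$params,
                       unit_graphs = fxa$unit_graphs)
  ispec <- neuriteflow:::interface_spec(fxa$sg, fxa$unit_graphs)
  relu <- function(x) pmax(x, 0)
  cs <- fxa$params$c_in
  iv <- attr(out, "interface_values")
  for (k in seq_along(ispec)) {
    sp <- ispec[[k]]
    x <- c(gp$units[[sp$a]]$c0[sp$a_if], gp$units[[sp$a]]$c_plus[sp$a_if],
           gp$units[[sp$a]]$c0[sp$a_adj], gp$units[[sp$a]]$c_plus[sp$a_adj],
           gp$units[[sp$b]]$c0[sp$b_if], gp$units[[sp$b]]$c_plus[sp$b_if],
           gp$units[[sp$b]]$c0[sp$b_adj], gp$units[[sp$b]]$c_plus[sp$b_adj]) / cs
    comp <- model$components[[sp$kind]]
    a <- x
    for (l in 1:4) {
      a <- as.numeric(a %*% comp[[l]]$W + comp[[l]]$b)
      if (l < 4) a <- relu(a)
    }
    o <- x + a
    expect_equal(iv[[k]]$s1, o[1:34] * cs, tolerance = 1e-12)
    expect_equal(iv[[k]]$s2, o[69:102] * cs, tolerance = 1e-12)
    # the resolved interface value is the mean of the two updated sides
    resv <- (o[1:34] + o[69:102]) / 2 * cs
    expect_equal(out$units[[sp$a]]$c0[sp$a_if], resv[1:17], tolerance = 1e-12)
    expect_equal(out$units[[sp$b]]$c0[sp$b_if], resv[1:17], tolerance = 1e-12)
    expect_equal(out$units[[sp$b]]$c_plus[sp$b_if], resv[18:34],
                 tolerance = 1e-12)
  }
})

test_that("assembly output does not depend on interface iteration order", {
  fxa <- asm_fixture()
  model <- assembly_model(seed = 78, identity_init = FALSE)
  ispec <- neuriteflow:::interface_spec(fxa$sg, fxa$unit_graphs)
  out1 <- assemble_step(model, fxa$sg, fxa$gp, fxa$params, ispec = ispec)
  out2 <- assemble_step(model, fxa$sg, fxa$gp, fxa$params,
                        ispec = rev(ispec))
  for (u in seq_along(out1$units)) {
    expect_equal(out1$units[[u]]$c0, out2$units[[u]]$c0, tolerance = 1e-12)
    expect_equal(out1$units[[u]]$c_plus, out2$units[[u]]$c_plus,
                 tolerance = 1e-12)
  }
})

test_that("the assembly loss is zero iff fields and interfaces agree", {
  fxa <- asm_fixture()
  expect_lt(assembly_loss(fxa$gp, fxa$gp, fxa$sg, alpha = 10,
                          unit_graphs = fxa$unit_graphs), 1e-20)
  expect_error(assembly_loss(fxa$gp, fxa$gp, fxa$sg, alpha = -1),
               "alpha")
})

test_that("a constant interface gap contributes exactly alpha * delta^2", {
  # a two-pipe network with exactly one (pipe-pipe) interface
  m <- generate_morphology(0, seed = 23, branch_length_range = c(25, 25))
  sg <- decompose_morphology(m, max_pipe_sections = 10)
  expect_length(sg$interfaces, 1L)
  unit_graphs <- lapply(sg$units, build_unit_graph)
  params <- simulation_params(c_out = 0)
  net <- build_network_graph(sg)
  st <- steady_state_solve(net, params)
  truth <- global_prediction(lapply(attr(net, "unit_node_map"), function(i) {
    list(c0 = st$c0[i], c_plus = st$c_plus[i])
  }))
  delta <- 0.07
  sp <- neuriteflow:::interface_spec(sg, unit_graphs)[[1]]
  pred <- truth  # +/- delta/2 on the two sides' c0: resolved mean = truth
  pred$units[[sp$a]]$c0[sp$a_if] <- pred$units[[sp$a]]$c0[sp$a_if] + delta / 2
  pred$units[[sp$b]]$c0[sp$b_if] <- pred$units[[sp$b]]$c0[sp$b_if] - delta / 2
  got <- assembly_loss(pred, truth, sg, alpha = 10,
                       unit_graphs = unit_graphs)
  expect_equal(got, 10 * delta^2, tolerance = 1e-12)
  # alpha = 0 removes the penalty: only the (zero) MSE remains
  expect_equal(assembly_loss(pred, truth, sg, alpha = 0,
                             unit_graphs = unit_graphs), 0,
               tolerance = 1e-20)
})

test_that("a single-pipe network rollout equals the unit rollout", {
  m <- generate_morphology(0, seed = 31)
  sg <- decompose_morphology(m)
  params <- simulation_params(c_out = 0)
  model <- simulator_model("pipe", seed = 8)
  g <- build_unit_graph(sg$units[[1]])
  net <- build_network_graph(sg)
  init <- steady_state_solve(net, params)
  init$time <- 0
  tr_net <- predict_network(list(pipe = model), NULL, sg, params, 5,
                            init = init)
  tr_unit <- rollout(model, g, init, params, 5)
  expect_equal(tr_net$c0, tr_unit$c0, tolerance = 1e-12)
  expect_equal(tr_net$c_plus, tr_unit$c_plus, tolerance = 1e-12)
})

test_that("network rollouts hold the inlet boundary at every step", {
  fxa <- asm_fixture()
  sims <- list(pipe = simulator_model("pipe", seed = 1),
               bifurcation = simulator_model("bifurcation", seed = 2))
  asm <- assembly_model(seed = 3)
  tr <- predict_network(sims, asm, fxa$sg, fxa$params, 4)
  inlet <- which(fxa$net$role == "inlet")
  for (k in 1:5) {
    expect_equal(tr$c0[inlet, k], rep(fxa$params$c_in, length(inlet)))
    expect_equal(tr$c_plus[inlet, k],
                 rep(2 * fxa$params$c_in, length(inlet)))
  }
})
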