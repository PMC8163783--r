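# Shared fixtures, built once per test run and cached.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (!exists(name, envir = .fx_env)) assign(name, maker(), envir = .fx_env)
  get(name, envir = .fx_env)
}

fx_params <- function() simulation_params()  # the study's physical parameters

fx_pipe_graph <- function() fx("pipe_graph", function() {
  build_pipe_graph(pipe_unit(cbind(0, 0, seq(0, 8, by = 0.5)), 1.0),
                   section_spacing = 2)
})

fx_bif_unit <- function(r_child = c(0.8, 0.8), angle = 30) {
  th <- angle * pi / 180
  stub <- function(dirv, r) {
    list(centers = outer(1:3, dirv), radii = rep(r, 3))
  }
  bifurcation_unit(
    branch_point = c(0, 0, 0),
    branches = list(stub(c(0, 0, -1), 1.0),
                    stub(c(sin(th), 0, cos(th)), r_child[1]),
                    stub(c(-sin(th), 0.2, cos(th)), r_child[2])),
    radius = 1.0)
}

fx_bif_graph <- function() fx("bif_graph", function() {
  build_bifurcation_graph(fx_bif_unit())
})

fx_morph <- function() fx("morph", function() generate_morphology(2, seed = 7))

fx_sg <- function() fx("sg", function() decompose_morphology(fx_morph()))

# a tiny generated data bundle for training-level tests
fx_small_data <- function() fx("small_data", function() {
  generate_transport_data(n_networks = 3, n_boundary = 3, n_steps = 12,
                          pairs_per_trajectory = 3, n_geometries = 4,
                          seed = 5)
})
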