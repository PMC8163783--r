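# neuriteflow

Graph-network surrogates for motor-assisted material transport in neurite
trees.

Neurons ferry proteins, vesicles and organelles through highly branched
neurites by a combination of free diffusion and molecular-motor transport
along cytoskeletal filaments. Simulating this with full 3D finite-element
solvers is accurate but slow for whole-neuron morphologies. `neuriteflow`
implements the surrogate-modeling alternative for researchers in
computational neuroscience and systems biology: decompose the neurite
network into simple units, learn fast graph-network simulators for each
unit type, and stitch the local predictions into a consistent network-wide
concentration field.

The transport model couples a free pool $c_0$ and a motor-bound pool $c_+$
(mol/µm³):

$$
\partial_t c_0 - D\nabla^2 c_0 = -k_+ c_0 + k_+' c_+ ,\qquad
\partial_t c_+ + \mathbf u_+\!\cdot\!\nabla c_+ = k_+ c_0 - k_+' c_+ ,
$$

with Dirichlet loading $c_0=c$, $c_+=\lambda c$ at the incoming end and a
parabolic (Poiseuille) velocity profile $u(r)=u_i(1-(r/R)^2)$ whose
volumetric flux is split area-weighted at branch points. Defaults:
$D=1.0\ \mu m^2/s$, $k_\pm=1.0\ s^{-1}$, $k_\pm'=0.5\ s^{-1}$,
$u_i=0.1\ \mu m/s$, $\Delta t=0.1\ s$.

The package provides:

* **Morphologies** — an SWC reader/writer (NeuroMorpho dialect) and a
  seeded generator of synthetic branched trees, so the whole pipeline runs
  without downloads.
* **Decomposition** — pipes and bifurcations with fixed cross-section node
  templates (17 nodes per section; 23 at branch points) and exact shared
  interfaces.
* **Reference solver** — implicit/explicit method-of-lines integration of
  the transport model on template graphs, plus a direct steady-state solve.
* **GNN simulators** — recurrent GN blocks (analytic edge features:
  concentration gradient along the edge and edge length) with an MLP
  decoder, trained by Adam under an MSE + PDE-residual loss.
* **Assembly model** — learned message passing across interfaces
  (pipe–pipe, pipe–bifurcation, bifurcation–bifurcation components) trained
  with an interface-consistency penalty (strength $\alpha=10$).
* **Metrics & orchestration** — the root-mean-square nodal error (MAE), the
  range-normalized relative error (MRE, %), k-fold cross-validation, and a
  YAML-configured experiment runner with run manifests.

## Worked example

```r
library(neuriteflow)

# a synthetic neurite with two bifurcations, decomposed into units
m  <- generate_morphology(n_bifurcations = 2, seed = 7)
sg <- decompose_morphology(m)
sg
#> Structure graph: 5 pipe(s), 2 bifurcation(s), 6 interface(s)
#>   interface kinds: p-b=6

# reference solution on the stitched network graph
params <- simulation_params(c_out = 0)   # tips act as a perfect sink
net    <- build_network_graph(sg)
steady <- steady_state_solve(net, params)
round(range(steady$c0), 3)
#> [1] 0 1

# a small end-to-end study: generate data, train, evaluate
data <- generate_transport_data(n_networks = 6, n_boundary = 6,
                                n_steps = 50, n_geometries = 8, seed = 1)
pl <- train_pipeline(data, seed = 1, epochs = 50)
ev <- evaluate_pipeline(pl, data)
round(ev$mre, 2)
#> [1] 1.59
```

The last number is the mean relative error (percent) of the trained
simulators + assembly rolled out autoregressively for 50 steps on held-out
networks, measured against the reference solver: even at this small
training size the surrogate tracks the relaxation of the concentration
field after a boundary-condition switch to under 2% of the field range.
`ev$gap_pre` / `ev$gap_post` report the mean absolute interface
discrepancy before and after each assembly pass.

A command-line front end over the same functions is installed at
`inst/cli/neuriteflow.R` (`run`, `generate`, `evaluate` subcommands), and
`run_experiment()` drives a whole configured study into a run directory
with a manifest, metrics and checkpoints.

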