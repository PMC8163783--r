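---
title: "Graph-network surrogates for motor-assisted transport in neurite trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-network surrogates for motor-assisted transport in neurite trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuriteflow)
```

## The transport model

Neurons move proteins, vesicles and organelles through their neurites by a
combination of free diffusion and motor-driven transport along cytoskeletal
filaments. `neuriteflow` models this with two coupled concentration fields on
the neurite's internal volume: a free pool $c_0$ and a motor-bound
(anterograde) pool $c_+$, in mol/$\mu m^3$:

$$
\frac{\partial c_0}{\partial t} - D\nabla^2 c_0 = -k_+ c_0 + k_+' c_+ ,
\qquad
\frac{\partial c_+}{\partial t} + \mathbf{u}_+\!\cdot\!\nabla c_+
  = k_+ c_0 - k_+' c_+ ,
$$

with $D$ the diffusivity of free material ($\mu m^2/s$), $k_+$ and $k_+'$ the
filament attachment and detachment rates (1/s), and $\mathbf{u}_+$ the
motor transport velocity. The filament system is assumed unipolar, so the
retrograde pool ($c_-$, with its rates $k_-, k_-'$) is dropped; the solver
retains it behind `unidirectional = FALSE`, untested against reference
values. At the incoming end the concentrations are held at $c_0 = c$,
$c_+ = \lambda c$, where $\lambda$ (the *degree of loading*) defaults to the
equilibrium ratio $k_+/k_+'$; at the outgoing ends either a zero-gradient
condition or a held concentration $\tilde c$ applies. Default physical
parameters are $D = 1.0\ \mu m^2/s$, $k_\pm = 1.0\ s^{-1}$,
$k_\pm' = 0.5\ s^{-1}$, $u_i = 0.1\ \mu m/s$, and a reporting time step of
$0.1\ s$.

Rather than solving a momentum equation, the velocity field is analytic: on
every circular cross section of radius $R$ the axial speed follows the
Poiseuille profile $u(r) = u_{sec}\,(1 - (r/R)^2)$ with no slip at the wall.
The section peak speed $u_{sec}$ equals $u_i$ at the network inlet and
follows area-weighted volumetric-flux conservation downstream: along a
tapering run $u_{sec} \propto R^{-2}$ holds the flux constant, and at a
branch point the parent flux is split over the children in proportion to
their cross-section areas (so two children of radius $R/\sqrt2$ each inherit
the parent's peak speed unchanged).

## Geometry: templates, pipes, bifurcations

Morphologies come from SWC files (NeuroMorpho dialect) or from the seeded
synthetic generator, which grows binary trees with geometrically tapering
radii, gently curved branches and configurable branch lengths. The tree is
decomposed into two unit types: **pipes** (unbranched runs of cross
sections) and **bifurcations** (a branch point plus three cross sections
along each incident branch). Cross sections are placed at roughly twice the
local radius apart and carry a fixed node template: 1 center node, 8 nodes
at $r = R/2$, 8 at $r = R$ (17 nodes), angularly aligned rings. The
branch-point section carries 6 extra wall nodes flanking the three
branch-junction azimuths (23 nodes); when a junction azimuth falls close to
a fixed ring angle the extra nodes are nudged to keep a minimum angular
separation of $\pi/16$, which bounds the smallest edge length and hence the
stiffness of the discrete operators. Within a section, edges connect the
center to the inner ring, rings radially and tangentially; across adjacent
sections, nodes of equal template index are linked. Section frames are
parallel-transported along the centerline so rings do not spin along curved
branches. Units sharing a section are joined by an *interface*; because both
units instantiate the same computed section, interface node positions
coincide exactly. Long pipes can be split into chunks (`max_pipe_sections`),
which produces pipe–pipe interfaces; very short internal branches produce
direct bifurcation–bifurcation interfaces.

The exact in-plane placement of the 17- and 23-node templates is a
documented package convention (counts and roles are fixed; the layout
matters only through the discrete operators built from it).

## The reference solver

The solver integrates the transport model on the template graph by the
method of lines:

* **Diffusion** uses the unnormalized graph Laplacian with edge weights
  $1/d^2$. On section-uniform fields this reduces exactly to the 1D
  three-point stencil along the section axis, which is what makes the
  straight-pipe solution converge to an independent 1D two-field
  computation under refinement. A per-node (degree) normalization was
  deliberately **not** applied: it would make the effective diffusivity
  depend on the node's ring position and would destroy both that
  consistency and exact mass conservation (the $1/d^2$ operator is
  symmetric, so closed-domain mass is conserved to round-off).
* **Advection** uses the upwind *advective* form $\mathbf u\cdot\nabla c$
  (the printed form of the governing equation): at node $i$, upwind
  neighbours $j$ contribute $(-s_{ij})_+ (c_i - c_j)/d_{ij}$, with $s_{ij}$
  the edge-midpoint velocity component along the edge. For the
  incompressible flow the advective and conservative forms agree in the
  continuum; on the collapsed graph only the advective form keeps uniform
  fields exactly invariant, which preserves the model's uniform balanced
  stationary state ($c_+ = (k_+/k_+')c_0$) to machine precision on any
  graph.
* **Time stepping** defaults to implicit Euler with a cached sparse LU
  factorization. The template graph is stiff (intra-section edges are a
  fraction of the radius long), so explicit Euler needs roughly ten
  substeps per $0.1$ s reporting step; implicit stepping is
  unconditionally stable, preserves stationarity, positivity and closed
  mass exactly, and makes one reporting step a single triangular solve.
  Explicit Euler with the stability bound
  $\Delta t \le 0.4\,\min(h^2/2D,\ h/u_{max})$ (and a Gershgorin guard)
  remains available via `method = "explicit"` and is used in tests whose
  point is the explicit scheme. A direct steady-state solve
  (`steady_state_solve()`) solves the stationary system in one sparse
  factorization.

## The learned simulators

Each unit kind has its own simulator with the same recurrent architecture:
nodal features (coordinates; the parameter vector $D, k_+, k_+', u_{sec},
c_{in}, r/R$; the current concentrations) pass through $L = 3$ GN blocks.
A block computes, for every edge, the analytic features
$[(c_j - c_i)/\lVert p_j - p_i\rVert,\ \lVert p_j - p_i\rVert]$ (for both
fields, plus the length), aggregates them per node by the mean over incident
edges, concatenates the aggregate with the node's embedding and applies a
shared node MLP (two hidden ReLU layers of width 32). The mean reducer was
chosen because it is robust to the different degrees of the 17- and 23-node
templates. A decoder MLP (three hidden ReLU layers of width 32, linear
output) maps the final embedding to the two output values per node.

Two output conventions are supported. The default decodes the **per-step
increment**, added to the input state; its output layer is zero-initialized,
so training starts exactly at the identity predictor and learns corrections.
This is the standard parameterization in learned-simulator practice and is
what makes the small per-step changes of a stiff relaxation learnable within
a modest epoch budget; decoding the absolute next-step field is retained
(`delta = FALSE`). Network-inlet Dirichlet values (and held outgoing-end
values, when present) are re-imposed on every output.

Features are normalized per geometry: coordinates are centered on the unit
centroid and scaled by its mean section radius; concentrations are scaled by
the trajectory's inlet concentration. Because the model is linear in
concentration, this normalization is exact rather than statistical.

**Physics-informed loss.** Training minimizes the mean squared prediction
error plus the mean squared residuals of the two governing equations, all
terms unweighted. The residuals use the solver's own discrete operators,
$\partial c/\partial t \approx (c^{pred} - c^{prev})/\Delta t$, and evaluate
the spatial terms at the prediction — the backward-Euler defect — so the
residual of the reference (implicit-solver) data is zero by construction.
Residual rows at nodes whose ground truth obeys a boundary condition rather
than the interior PDE (network inlets and outlets, and unit end sections
whose stencil is cut by the unit boundary) are excluded; keeping them would
penalize the model for matching the true boundary behaviour. A
`pde_weight` of 0 reduces the mode to plain MSE exactly.

**Optimization.** Adam with a decade step decay from $10^{-3}$ to $10^{-6}$
at evenly spaced milestones, 50 epochs and a seeded 75/25 train/test split
by default. Batches group samples of one geometry so the sparse aggregation
and residual operators apply to a whole batch at once; the default batch is
50 samples. Optional Gaussian input noise (`noise_sd`) is available as a
rollout-robustness augmentation but defaults to 0: the transport dynamics
are contractive toward the boundary-driven steady state, and measured
rollouts are stable without it (noise measurably degrades both one-step and
rollout accuracy here).

## The assembly model

Units predict independently, so the two owners of an interface disagree
there. The assembly model reconciles them: for every interface, the
intermediate predictions on the interface section and on the adjacent
section of each side (4 sections x 17 nodes x 2 fields = 136 values) are
concatenated and passed through a component MLP matched to the interface
kind (pipe–pipe, pipe–bifurcation, bifurcation–bifurcation; three hidden
ReLU layers of width 32). The component is residual (output = input + MLP),
so zero-initializing its output layer gives an exact identity passthrough.
The component outputs updated per-side values; the interface takes the mean
of the two updated sides (single-valued afterwards) and each side's
adjacent section takes its own update. One pass per time step is the
default; where several interfaces write to one node the updates are
averaged, which also makes the pass independent of interface iteration
order. Training minimizes, per interface pair, the mean squared nodal error
over the two units (interface counted once, at the resolved mean) plus
$\alpha$ times the mean squared discrepancy between the two sides'
interface predictions, with $\alpha = 10$; $\alpha = 0$ gives the
pure-MSE ablation.

During a network rollout every unit simulator advances one step from the
current global state, the assembly pass reconciles the interfaces, the
reconciled field feeds the next step, and the network-inlet values are
re-imposed.

## The synthetic study and what it does (not) show

No neuron reconstructions ship with the package; the whole pipeline is
exercised on seeded synthetic morphologies (1–3 bifurcations in
round-robin, branch lengths 8–14 $\mu m$, root radius 1 $\mu m$, taper
0.85 per branch order). The data protocol solves each network with the
reference solver for 20 inlet boundary concentrations evenly spaced over
0.5–1.5 mol/$\mu m^3$, with the outgoing tips held at $\tilde c = 0$ (a
perfect sink, which gives every unit a genuine steady spatial gradient).
Each trajectory starts from the steady state of the reference boundary
value $c_{ref} = 1.0$ and records 50 steps of the relaxation that follows
the switch to the new boundary value — a protocol under which every unit,
however deep in the tree, carries informative signal within a short
trajectory. Unit-level one-step training samples are extracted by
*restriction* of the network states to each unit (3 consecutive-state pairs
per trajectory, evenly spread, recorded in the dataset manifest), so
interfaces carry genuine transient values; 30 unit geometries per kind are
sampled across the networks. These sizes are the package's desk-scale study
conditions, chosen once; the builders accept larger values. The full study
(30 networks, 20 boundary values, 30 geometries per kind) is what
`scripts/acceptance.R` reruns; the test suite exercises the same checks at
a smaller stated size (12 networks, 10 boundary values, 16 geometries per
kind) with identical thresholds.

What passing tests show: the solver's analytic invariants (stationarity,
conservation, flux balance, 1D convergence) hold; the simulators learn the
one-step map of this linear, boundary-driven relaxation to a small fraction
of the field range; the assembly reduces interface discrepancy; whole
trained pipelines track held-out network trajectories within the headline
error band. What they do not show: performance on real neuron geometries
(real morphologies have varicosities, noise and radius irregularities the
generator does not emulate), on nonlinearly coupled transport models, or
against a full 3D finite-element/isogeometric reference — the graph solver
stands in for one at desk scale.

## Numerical choices and degenerate inputs

* Concentration ranges below machine precision make the range-normalized
  error (MRE) undefined; `mre()` errors on a zero range rather than
  returning infinity.
* The "MAE" metric is, as customary for this quantity, a root-mean-square
  of nodal differences; the relative error divides it by the ground-truth
  nodal range and multiplies by 100.
* Degree>3 skeleton branch points are split into cascaded degree-3
  bifurcations; a root that is itself a branch point is rejected.
* Segments too short to host their units (cross sections would be packed
  closer than 0.4 of the local radius) raise a decomposition error naming
  the location.
* All randomness (morphology growth, splits, initialization, batching)
  derives from explicit integer seeds through a private RNG stream that
  never disturbs the caller's `.Random.seed`; end-to-end reruns are
  bit-stable.

## Known limitations

* The retrograde pool is implemented but unvalidated (`unidirectional =
  FALSE`).
* The assembly updates only the interface neighbourhood (interface plus one
  adjacent section per side); errors deeper inside a unit are the
  simulator's responsibility.
* The physics-residual term is most valuable when data are scarce or noisy
  — the regime where physics-informed losses earn their keep. On this
  package's clean, densely sampled synthetic protocol both loss modes reach
  errors far below a percent of the field range, and the test suite's
  cross-validated comparison between them shows differences at seed-noise
  level with no guaranteed direction; with ground truth from a coarser or
  noisier reference the ordering would be expected to favour the
  physics-informed loss.
* Experiment runs store checkpoints as RDS; there is no cross-version
  serialization guarantee.
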