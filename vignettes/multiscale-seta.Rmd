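---
title: "A concurrent MD-FEM model of gecko seta adhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A concurrent MD-FEM model of gecko seta adhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A gecko seta is a micrometre-scale keratinous hair that branches
hierarchically into nanoscale terminal pads (spatulae), which are the
actual adhesive contact elements. `setascale` implements a concurrent
two-scale description of one seta pressed onto and pulled off a smooth,
rigid, non-polar substrate:

* the branched setal shaft is a static, linear-elastic tetrahedral finite
  element (FE) body;
* each spatula is a coarse-grained bead-spring network undergoing
  thermostatted molecular dynamics (MD) against a frozen Lennard-Jones
  substrate;
* the two descriptions overlap in one bridging domain (BD) per spatula,
  where anchor points (APs) - virtual particles pinned at bridging-domain
  FE node positions - are tethered to nearby beads by harmonic springs and
  exchange time-averaged forces and displacements.

The calculation alternates: an MD phase runs with the APs held fixed and
accumulates the time-averaged spring force on every AP over the final
portion of the trajectory; then, with the beads frozen, one static FE
solve applies those forces as Neumann loads on the bridging-domain nodes
while the driver nodes (the truncated seta top) receive the prescribed
displacement; finally the displaced bridging-domain node positions become
the AP positions for the next MD phase. One such MD+FEM pair is an
iteration; a load step is one driver displacement increment followed by a
fixed number of iterations.

### Seta geometry

The skeleton is built between the positive branches of two envelope
curves `x^2/C1^2 - y^2/C2^2 = 1` with `C1 = 0.5 D0` and `1.5 D0`,
`C2 = C1 tan(alpha)`. At each branching height
`H_i = eta^(n_levels - i) * H_sp` the horizontal segment between the
curves is divided into `2^(i-1)` equidistant intervals whose midpoints
are the branching points; tips sit at the substrate-plane midpoints of
`2^n_levels` intervals. Branch widths follow
`W_i = gamma^(n_levels + 1 - i) * R_sp`. Full-scale defaults (`H0` 22.8
um, `D0` 13.5 um, `alpha` 30 deg, `R_sp` 50 nm, `eta` 2.417, `H_sp` 0.67
um, four levels, sixteen tips) reproduce the printed total height from
the height recursion to within 0.3%. The width-scaling parameter `gamma`
is not recoverable from any printed number; the default `gamma = eta =
2.417` gives a ~4.1 um base shaft, consistent with real seta diameters,
and is exposed in the configuration - it should be treated as a model
choice, not a literature value.

The solid is the union of linearly tapering circular frusta swept along
the skeleton edges. It is meshed by voxelising on a regular grid aligned
with the top truncation plane and splitting every interior voxel into six
face-conforming tetrahedra (Kuhn subdivision). This is the simplest
reproducible construction: it is deterministic, bit-for-bit identical
across runs, translation invariant, and its volume converges to the
solid's volume as the voxel size shrinks (the mesh test checks 5% at the
default density against an independent dense-quadrature estimate of the
union volume). The portion above `H0` is removed; the nodes on the cut
plane form the driver set. The lower half (configurable fraction) of each
final branch is removed to make room for the molecular spatula; the
bottom `bd_frac` of what remains defines the bridging-domain node region.

### Material

The shaft is isotropic linear elastic, `sigma = lambda tr(eps) I + 2 mu
eps`, with `lambda = E nu / ((1+nu)(1-2nu))` and `mu = E/(2(1+nu))`.
Per run, `E` and `nu` are sampled once from independent normals
(`4.518 +/- 0.036` GPa, `0.401 +/- 0.002`); out-of-range draws are
rejected and redrawn (with these spreads that is practically never).
Independence of the two draws is the simplest reading of the reported
values; no joint distribution is stated anywhere.

### Spatula and substrate

A spatula is a jittered-lattice fill of a parametric shape - a thin pad
plate with a tapered distal tip strip and a cylindrical shaft rising from
the proximal pad end at 45 degrees (the natural inclination of the final
branches). Every bead (65228 Da at full scale, about five keratin
molecules) bonds to its 30 nearest neighbours with harmonic springs `V =
K/2 (r - b0)^2`; equilibrium lengths are the as-built distances, so a
fresh spatula is stress free. Bond constants are anisotropic, `K = k +
k_b |cos(theta)|` with `theta` the angle to the keratin fibril direction,
taken as a single global unit vector along the shaft axis (the simplest
fibre field consistent with a fibril-reinforced shaft). The full-scale
spacing preset (4.4 nm, jitter 0.18) reproduces the reference network's
bond-length statistics (shortest ~3 nm, mean ~7.3 nm).

`virtual_tensile_test()` measures `E` and `nu` of a bead network by
clamping the axial coordinate of the two end slabs at an affinely
strained position, relaxing everything else by energy minimisation
(L-BFGS with analytic gradients), and evaluating the virial stress. Two
stress estimators are provided: midpoint binning with per-bead tributary
volumes (robust for irregular shapes) and, when a lateral core margin is
requested, Irving-Kirkwood line weighting over an exact core box, which
is unbiased even for perfectly commensurate lattices and is what the
closed-form simple-cubic benchmark uses. `tune_stiffness()` matches a
target `E` by joint rescaling of `(k, k_b)` (the response is exactly
linear) and steers `nu` by a secant search on `k_b/k`. A purely
central-force harmonic network cannot reach arbitrary Poisson ratios;
with the default bonding rules the attainable `nu` along the fibril axis
spans roughly 0.2-0.45, and the search reports the best achieved value
rather than pretending convergence.

The substrate is a frozen, cavity-free square monolayer of beads on the
plane y = 0 (spacing below the LJ sigma), optionally underlaid by an
amorphous bulk. Because the monolayer plus bulk exceeds the interaction
cutoff, beads deeper than the cutoff cannot influence any force - the
package verifies this identity directly - so the bulk is off by default.
Spatula-substrate interactions are a truncated, unshifted 12-6 LJ
(epsilon 290 kJ/mol, sigma 4 nm, cutoff 12 nm = 3 sigma at full scale).
With these parameters about 2% of the contact-state attraction lies
beyond the cutoff; the cutoff retains "most" of the tail, not all of it.

### MD engine

Velocity-Verlet NVT at a 20 fs time step. Outside the bridging domain a
stochastic (canonical-sampling) velocity-rescaling thermostat with 2 ps
coupling holds 300 K; inside the bridging domain a weak Berendsen
thermostat (10 ps) dissipates the kinetic energy injected by load steps.
Langevin-type thermostats are deliberately absent: the system is a vacuum
model and implicit friction suppresses snap-in and post-detachment
oscillations. "Inside the bridging domain" means beads bonded to an AP by
default; a flag widens it to the whole spatula for strongly damped
quasi-static holds. All thermostat noise comes from a dedicated
deterministic PRNG seeded per phase, so every trajectory is exactly
reproducible. The substrate is static, so its neighbour structure is
built once per phase; for the pure-monolayer case neighbour search is a
direct lattice-index window.

### Coupling and protocol

Each AP is created at a bridging-domain FE node and greedily paired (in
ascending node order, ties to the lowest bead index) with its nearest
not-yet-paired bead within a cap of twice the mean bond length; the
pairing-time distance becomes the spring's equilibrium length, so
coupling springs start force free. Nodes that find no partner host no AP.
The MD-coupling spring constant is 0.28 nN/nm at full scale (equal to the
base bond constant); the FE-coupling penalty springs (0.08 nN/nm) anchor
the AP-hosting nodes to their positions at the start of each FEM
iteration, i.e. they restrain per-iteration increments and vanish as the
iteration converges. The solved system is `(K + K^FE) du = f_ext - K u`,
with the driver Dirichlet displacement applied in the first iteration of
each load step and the driver fully clamped in the rest.

Because the FE solve is static, physical time comes from the MD side:
`dt_ls = n_iter * n_md * dt_MD` (1.4 ns per load step at the production
schedule), and the pull-off velocity is the prescribed displacement per
load step over that duration (0.7 m/s for 1 nm).

The protocol mirrors force-microscopy practice: spatulae start at least
13 nm above the substrate (beyond the 12 nm cutoff); the driver moves
down 1 nm per load step until the summed spatula-substrate compressive
force reaches the preload target *and* every spatula is genuinely pressed
on (in contact and carrying at least a quarter of its fair share - the
reference protocol states only the total force but also demands that all
spatulae establish contact; the per-spatula floor operationalises that).
With a zero preload target the phase degenerates to "stop at first
contact". One relaxation load step without displacement follows, then the
driver reverses 1 nm per load step until every spatula has lost all
contacts. Forces are recorded at three points with a compression-positive
sign convention: the substrate reaction and the summed AP force are
averaged over the final window of the last iteration of each load step;
the driver constraint force is taken directly at the end of the load
step.

### Observables

A contact point is a (spatula bead, substrate bead) pair strictly closer
than the cutoff. A spatula counts as detached at the first load step at
which its contact count reaches zero and stays zero - transient contact
loss during tip slips does not register. Adhesion is quoted as the
magnitude of the most negative force. Two per-spatula averaging
conventions are computed: the naive one divides the seta-level minimum by
the spatula count, the per-spatula one averages each spatula's own
|F_min|; because individual minima are not simultaneous the latter is
never below the former (asserted on every analysis). Sliding velocity is
the least-squares slope of the mean pad X position against time (nm/ns =
m/s); the apparent friction coefficient is the ratio of window-averaged
|lateral| to |normal| substrate force, with windows in which the normal
force changes sign rejected.

## The miniature study system

Everything end-to-end runs on a deterministic miniature preset
(`make_mini_system()`): a 2-level seta (4 spatulae, alternating
orientations: odd-numbered tip-first, even-numbered pad-parallel), ~370
and ~500 beads per spatula, a coarse mesh (10 nm voxels), and a shortened
protocol (2 nm per load step, 2 iterations of 500 steps each, ~3 nN per
spatula preload). The miniature generator preserves every structural rule
of the full model; the following quantities are deliberately rescaled,
for reasons worth recording:

* **Bead mass 1000 Da** (vs 65228). The spatula's rigid-body response
  time scales as `sqrt(M / k_coupling)`; at full scale it is well inside
  one 140 ps iteration, but a desk-scale iteration is only 10 ps. The
  lighter bead restores the ratio so that displacement actually transmits
  through the anchor springs within an iteration.
* **MD-coupling spring 1.4 nN/nm** (vs 0.28) for the same reason: it
  keeps the AP tracking time commensurate with the shortened iterations.
* **In-BD Berendsen coupling 1 ps** (vs 10): the bridging domain must
  dissipate load-step kinetic energy on the shorter iteration timescale,
  otherwise the staggered MD-FEM loop pumps a rocking resonance of the
  spatula against the floppy final branch.
* **LJ well depth 60 kJ/mol** (vs 290): adhesion must be breakable by a
  seta whose absolute stiffness is ~100 times lower than the full-scale
  one within tens of load steps.
* **Pad-parallel shafts 65 nm longer**: rolling a spatula tip-first
  lowers its distal edge by tens of nm; the longer pad-parallel shaft
  brings both orientations to comparable approach heights so preload can
  press all four spatulae on within the shortened schedule.

What the mini runs do show, emergently: compressive rise during preload;
jump-to-contact for pad-parallel spatulae with initial contact counts far
above the tip-first ones; a single global adhesion minimum; sequential
detachment with tip-first spatulae releasing before pad-parallel ones;
a two-stage contact plateau (pad peels, tip holds) for pad-parallel
spatulae; and contacts tracking the force magnitude through the
detachment stage. What they cannot show: quantitative full-scale force
magnitudes (the -284.5 nN seta minimum, 33.2 nN per-spatula adhesion,
0.66 m/s sliding, mu = 0.55 all live at 16 spatulae x hundreds of ns and
are out of desk reach), loading-rate effects, humidity, rough or
deformable substrates.

## Numerical choices

* **Units.** Internal MD units are nm / Da / kJ/mol, whose derived time
  unit is exactly 1 ps; FEM works in nm / nN / GPa (1 GPa = 1 nN/nm^2).
  Conversions happen in one tested place (1 kJ/mol/nm = 1.6605 pN).
* **Penalty scope.** The FE-coupling springs act on the nodes that host
  anchor points. Applying them to every node of the geometric
  bridging-domain region over-restrains the FE relaxation (the penalty
  then dwarfs the branch stiffness and the per-iteration increments stall).
* **Penalty reference.** Springs re-anchor to the node positions at the
  start of every FEM iteration (increment restraint). The alternative -
  anchoring to the t = 0 positions - turns them into absolute springs
  that fight the whole pull displacement and is not what the method
  needs; it is not implemented.
* **Staggered-coupling stability.** The loop is stable when the penalty
  (per AP-hosting node) times the node count is comparable to or exceeds
  the AP spring stiffness projected on the soft structural modes, and
  when the in-BD thermostat removes the kinetic energy a load step
  injects within about one iteration. The divergence guard aborts if any
  AP moves more than ten load-step displacements in a single iteration.
* **Driver reaction sign.** The reported driver force is minus the Y
  constraint reaction, which makes all three recorded forces positive in
  compression and negative in adhesion.
* **Three-way force consistency.** Before detachment the substrate, AP,
  and driver forces agree up to the penalty drag, which scales as `k_FE *
  (eps_ls / n_iter) * n_AP`. At the production schedule that drag is a
  few nN against a 320 nN preload; at the miniature schedule (2 nm over 2
  iterations) it is not negligible, so the mini suite checks the
  consistency in a quiet static hold (a weight hung on one spatula under
  strong damping converges to AP-driver agreement within 2%) rather than
  during fast pulling. This mirrors the reference observation that the
  three curves align pre-detachment and diverge when the iteration count
  per load step is too small for the loading rate.
* **FEM solver.** Sparse supernodal Cholesky of the constrained
  penalised operator, factorised once per system and reused across all
  iterations (the constraint set is constant; only right-hand sides
  change). Quadratic (10-node) tets are available and used for the
  bending benchmark; the seta itself defaults to linear tets at a density
  validated by the cantilever test (P2 within 5% of Euler-Bernoulli, P1
  within ~12% at the stated density).
* **Detachment rule.** "Stays zero" to the end of the record, with a
  3-step confirmation horizon for truncated series; first-zero would
  misclassify transient tip slips as detachments.
* **Randomness.** One master seed derives independent streams (material,
  per-spatula jitter, initial velocities, per-iteration thermostat noise)
  through a fixed integer map; repeating any build or run with the same
  seed is bitwise identical.

## Known limitations

* The seta is linear elastic and isotropic; real setae are anisotropic
  and likely viscoelastic under fast loading.
* The substrate is rigid, atomically smooth, non-polar, and dry; no
  humidity, capillarity, roughness, or substrate deformation.
* Central-force bead networks cap the attainable Poisson's ratio; the
  tuner recovers the target Young's modulus but reports, rather than
  forces, the Poisson's ratio.
* The miniature preset trades force magnitudes for runtime; only the
  full-scale configuration (16 spatulae, 7000-step iterations, hundreds
  of ns) is expected to reproduce literature force values, and running it
  is a cluster-scale task outside the test suite.
* The mesh generator produces voxel (staircase) boundaries; smooth
  surface meshes, curved branches, and non-circular cross sections are
  not modelled.
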