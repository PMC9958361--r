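---
title: "Models and methods behind mtnetsim"
author: "mtnetsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtnetsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtnetsim)
```

## The physical model

`mtnetsim` simulates quasi-two-dimensional active networks of growing
microtubules crosslinked and slid by two-headed, plus-end-directed motors
with KIF11-like kinetics. The simulation volume is a thin slab
(Lz = 0.2 um), periodic in x and y and bounded by reflecting walls in z,
so extended networks can form while the geometry stays effectively planar.

**Filaments.** Each microtubule is an inextensible, bending-elastic chain
of equally spaced vertices, minus end first. Bending forces follow the
discrete worm-like-chain form: for interior vertex $j$ the second
difference $b_j = x_{j-1} - 2x_j + x_{j+1}$ contributes the stencil
$(-k b_j, 2 k b_j, -k b_j)$ with $k = \kappa / \ell^3$ at vertex spacing
$\ell$; the field carries zero net force and torque.

**Pair interaction.** Filaments interact through a piecewise-linear
force between each vertex and its projection onto segments of other
filaments,
$$F(d) = k\,(d - d_0),\qquad k = \begin{cases} K_r & d \le d_0\\
K_a & d_0 < d < d_0 + d_1\\ 0 & \text{otherwise,}\end{cases}$$
with $d_0 = 0.1$ um (the center-to-center spacing of bundled
microtubules), an attractive shell of width $d_1 = 0.32$ um representing
a depletion attraction induced by a crowding agent, $K_r = 50$ pN/um and
$K_a$ varied up to 1.2 pN/um. The maximal attractive work
$K_a d_1^2/2 \approx 0.061$ pN um (about 14 kT) stays well below the
repulsive barrier $K_r d_0^2 / 2 = 0.25$ pN um (about 60 kT). The force
acts along the contact normal, so it cannot resist axial sliding of
bundled filaments.

**Motors.** A motor has two heads that bind independently within a
capture radius (`r_bind`, 0.05 um) at rate `k_on`, walk toward the plus
end with the linear force-velocity law
$v = \mathrm{clamp}\!\left(v_m (1 + f_\parallel / f_s),\, 0,\, v_m\right)$
($v_m = 0.03$ um/s, $f_s = 5$ pN; no backward stepping, no super-speed
under assisting load), and unbind at `k_off_side` from the filament
lattice or `k_off_end` = 0.2/s from the plus end (5 s mean end
residence). A head that reaches the plus end stays pinned there until it
unbinds; this slow end release is what lets plus ends gather into aster
foci. Doubly bound motors act as Hookean springs (`k_link`) whose force
is distributed onto the adjacent filament vertices and whose axial
component loads the walking law. Detached motors diffuse freely
(`D_motor`).

**Growth.** All filaments nucleate at t = 0 as short seeds and elongate
at their plus ends only, at the shared, tubulin-limited rate
$v_g(t) = \alpha\,[1 - \sum_i L_i(t) / \Omega]$. The budget
$\Omega$ (total polymer length) and the seed count $N$ set the final mean
length $L = \Omega / N$; with every filament at the same length the mean
obeys $\ell(t) = (\Omega/N)(1 - e^{-\alpha N t/\Omega}) +
\ell_0 e^{-\alpha N t/\Omega}$, which the test suite checks against the
discrete update to $10^{-3}$ um. $\alpha$ defaults to the motor speed.

## Numerical scheme

Dynamics are overdamped Langevin: each vertex carries drag
$\gamma = c\, 3\pi \eta\, \ell_0$ and receives $F\gamma^{-1}\Delta t$
plus Brownian noise of variance $2 k_B T \Delta t / \gamma$ per axis.
Three ingredients keep the explicit scheme honest and stable:

1. **Inextensibility projection.** The displacement field of each chain
   is projected onto the subspace with no first-order segment extension
   (a tridiagonal Lagrange-multiplier solve along the chain). Without
   it, the arc-length re-projection alone inflates the chain's
   center-of-mass diffusion severalfold above the Einstein value and
   ratchets thermally bent chains toward the minus end; with it, the
   measured diffusion of a free filament matches $k_BT/(n\gamma)$
   (tested), and the summed drag of a 2.5 um filament matches
   slender-body theory within 20% at the calibration `drag_c = 0.2`.
2. **Arc-length reshape.** After each step (and after tip growth) the
   chain is resampled to equally spaced vertices of exact total length,
   then recentred on the centroid of the resampled points, which removes
   the second-order drift of a one-sided rebuild. A vertex is added
   whenever the spacing would exceed 1.5 `seg_len`.
3. **Displacement limiter.** Dense regions (aster cores, zipped bundles)
   stack dozens of contact and motor-link stiffnesses on single
   vertices, which no fixed explicit time step can integrate smoothly.
   Per-vertex displacements are therefore capped at 0.2 segment lengths
   per step -- a local adaptive substep that saturates transient force
   pile-ups; occurrences are counted and reported (`n_clamped`). A
   displacement beyond 25 segment lengths aborts with an
   unstable-timestep error.

Contact discovery uses vertex cell lists and a Verlet pair list (skin
0.4 um) rebuilt when any vertex has drifted more than half the skin; the
accelerated forces are bit-compared against a brute-force all-pairs
oracle in the tests. Binding draws its Bernoulli trial before the
neighbor search, so only the small fraction of heads that would bind
this step pays for a search. One seeded `mt19937_64` stream drives each
engine invocation, making runs bit-reproducible for a given seed on one
platform.

### Default parameters

Values the study protocol states are fixed in [`default_params()`]
(d0, d1, Kr, Ka range, v_m, k_off_end, motor:filament ratio 16, Lz,
box = 16 L, growth toward mean length L). The remaining numerical and
kinetic constants are package choices:

| parameter | default | rationale |
|---|---|---|
| `dt` | 0.01 s | explicit-Euler stability at the stiffness the defaults produce |
| `eta` | 1.2 Pa s | effective drag of the crowded assay medium; admits `dt` stably |
| `drag_c` | 0.2 | matches slender-body diffusion of a 2.5 um filament within 20% |
| `seg_len` | 1.0 um | resolves bending at persistence lengths >> L |
| `kappa` | 20 pN um^2 | textbook microtubule rigidity |
| `k_on` | 5 /s | fast capture within `r_bind` = 0.05 um |
| `k_off_side` | 0.05 /s | 20 s lattice residence, slower than end release x4 |
| `f_stall` | 5 pN | kinesin-scale stall force |
| `k_link` | 30 pN/um | soft enough for stable explicit integration of stacked links |
| `D_motor` | 10 um^2/s | free protein diffusion |
| `kT` | 4.11e-3 pN um | ~25 C |

Raising `eta` and `dt` together leaves every displacement scale and the
stability margin unchanged while halving the step count; motor-driven
sliding is force-limited far below stall at these drags, so transport
speeds are insensitive to the choice.

## Network descriptors

Seven scalars summarize a configuration; they are computed on the final
frame of a run (mobility from the last 200 s).

* **Nematic order S.** The box is tiled with 10 um windows (sized to
  contain one aster, so radial arrangements average to low order). Per
  window, $Q = \langle \hat u \otimes \hat u\rangle - I/2$ is built from
  the in-plane components of the minus-to-plus end-to-end vectors and
  the window order is $S_w = 2\lambda_{max}(Q)$; the factor 2 is the 2D
  rescaling that maps perfect alignment to exactly 1 while leaving
  isotropy near 0. Windows are weighted by their filament count;
  filaments are assigned by the midpoint of their end-to-end chord.
* **Crosslink taxonomy.** Each doubly bound motor is an End link if
  either head lies within 10 nm of a plus end, otherwise P/X/AP by the
  internal angle between plus-end-directed tangents with bins
  [0, 60), [60, 120], (120, 180] degrees (the boundary angles are
  assigned to X). fEnd is normalized over all links; fP, fAP, fX over
  non-end links only -- the two normalizations the descriptor set uses.
* **Mobility.** Mean over filaments of the minus-end displacement
  projected on the plus-to-minus axis over a 200 s interval, positive
  for minus-end-leading sliding; the long interval suppresses the
  diffusive contribution (tested against drift-free ensembles).
* **Largest cluster fraction.** Connected components of the
  filament-crosslink graph (via `igraph`), largest component size over N.

## State classification

Descriptor matrices from parameter sweeps are z-scored (the descriptors
mix um/s with dimensionless fractions; standardization is exposed and
documented rather than silent), projected on their first two principal
components (`stats::prcomp`; loading signs canonicalized), and clustered
with K-means, k = 4, k-means++ seeding, best of 50 restarts
(deterministic for a given seed). Clusters are then named from their
centroids over the raw descriptors, in fixed priority:

1. aster: fEnd >= 0.4 and S < 0.5;
2. parallel bundle: S >= 0.5 and fP >= 0.5;
3. extensile bundle: fAP >= 0.3, |mobility| >= 0.005 um/s,
   cluster fraction >= 0.5;
4. gliding mesh: fX >= 0.3, cluster fraction >= 0.8, S < 0.5;
5. otherwise: outlier.

The priority order resolves runs matching several signatures; two
clusters matching the same rule are both named, with a warning. The
thresholds mirror the qualitative state signatures (end-link-rich
disordered asters; ordered parallel-link bundles; sliding,
antiparallel-linked connected bundles; percolated isotropic meshes rich
in X links) and sit midway between the archetype values, so they are
insensitive to moderate descriptor noise. A leave-one-descriptor-out
robustness check reruns the whole pipeline seven times and reports label
agreement (naming still uses all seven centroid coordinates, so the
rules remain well defined when their own descriptor is left out).

## Synthetic fixtures

`make_fixture()` builds configurations whose descriptors are known by
construction: radial asters with all links within the end radius
(fEnd = 1, S near 0 when centred in one window), co-oriented bundles
split into several disconnected stacks (S = 1, fP = 1, small cluster
fraction -- the parallel-bundle state signature), alternating-polarity
bundles (S = 1, fAP = 1, chained into one cluster), isotropic meshes
with motors at geometric chord crossings (periodic minimum-image
crossing detection; filaments that cross nothing are redrawn and a
spanning set of crossings is always kept, so the mesh percolates by
construction), and motor-free random fields (exempt from the packing
check: they are orientation-statistics fixtures without interactions). Prescribed rigid sliding of the antiparallel bundle
provides an exact mobility oracle. `make_sweep()` emulates a 5 x 5
phase-grid: one deterministic geometry per archetype, with optional
Gaussian descriptor noise applied on the standardized scale (a fraction
of each descriptor's across-sweep spread -- a raw amplitude in mixed
units would swamp the um/s-scale mobility while barely touching the
fractions). These fixtures exercise the descriptor and classification
pipeline exactly; what they do not emulate is simulation output --
curved filaments, partially sorted bundles, motors in transit -- so
passing fixture tests validates the measurement code, not the dynamics.
The dynamics are validated separately (diffusion, kinetics, growth,
transport oracles, and reduced-scale phase runs).

## Reduced-scale phase protocol

Published full-scale runs (40 x 40 um, thousands of filaments, 60-80
simulated minutes) are far beyond a desk-scale budget, so the package's
end-to-end checks run the same protocols in smaller periodic boxes for
three seeds each: the short-filament aster condition (L = 2.5 um,
1.3 um/um^2, no attraction, 12 x 12 um, 30 min), the dense attractive
condition (L = 2.5 um, 5 um/um^2, Ka = 1.2 pN/um, 7 x 7 um, 30 min),
the long-filament bundle condition (L = 10 um, 2.5 um/um^2, 16 x 16 um,
60 min) and the dense long-filament condition (L = 10 um, 10 um/um^2,
8 x 8 um, 30 min). Box sizes were fixed by the single-CPU compute
budget, within the filament-count cap of the reduced protocol.

The reduction is not free of consequences, and the package reports them
rather than hiding them. Small periodic boxes hold only one or two
bundles, so motor-driven polarity sorting runs to completion instead of
being continually undone by bundle-bundle recombination -- the dense
attractive condition therefore reaches a sorted polar bundle rather
than a sustained extensile state, and antiparallel-link fractions
collapse. Dense long-filament networks over-connect (largest-cluster
fraction near 1) and, with constant-rate unbinding and no backward
stepping, opposing motors jam the mesh, so collective sliding speeds
stay an order of magnitude below the single-motor transport speed that
the cargo oracle verifies. In end-gathered asters the non-end links
that remain are predominantly parallel, so the parallel-link fraction
(normalized over non-end links only) exceeds the end-link fraction
structurally. These are properties of the model at this scale, visible
in the end-to-end checks.

## Known limitations

* No dynamic instability, shrinkage or re-nucleation: filament number is
  fixed and length only grows.
* No hydrodynamic interactions and no crowding-enhanced binding or drag
  beyond the uniform effective viscosity.
* The explicit integrator saturates (rather than resolves) force
  pile-ups beyond the displacement limiter; quasi-static core structure
  is approximate at the 0.1 um scale.
* Free motors diffuse but do not interact sterically; singly bound heads
  ride at their attachment point and may walk.
* The classifier's naming thresholds are heuristics over cluster
  centroids; clusters with genuinely mixed character are reported as
  `outlier` rather than forced into a state.

## A small worked pipeline

```{r, eval = FALSE}
p <- default_params("fig1_lowdens", Ka = 0, box = c(16, 16), T_end = 1800)
run <- run_simulation(p, seed = 1)
round(run$descriptors, 3)

sweep <- make_sweep(noise_sd = 0.05, seed = 1)
res <- classify_states(sweep, seed = 1)
table(sweep$truth, res$labels)
```
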