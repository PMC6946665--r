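---
title: "Active ring-polymer melts: model, threading analysis and observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active ring-polymer melts: model, threading analysis and observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmelt)
```

# The physical model

`ringmelt` simulates dense melts of unknotted, mutually nonconcatenated ring
polymers in which part of each ring is "hot": a consecutive arc of $N_h$
monomers is coupled to a Langevin thermostat at temperature $T_h$ while the
rest of the chain stays at $T_c < T_h$.  Because the rings cannot cross each
other, the stronger fluctuations of the hot arcs drive the system into a
topologically arrested state: rings thread one another ever more deeply, and
the threading network percolates while ordinary relaxation channels freeze
out.  The package provides all pieces needed to build such systems, run
them, and quantify both the topological state (threadings through minimal
surfaces) and the glassy dynamics (mean squared displacements, scattering
functions, ergodicity breaking).

All quantities are in reduced Lennard-Jones units,
$\epsilon = \sigma = m = k_B = 1$ and $\tau = \sigma\sqrt{m/\epsilon}$.

## Interactions

Monomers interact through three terms (see `wca_energy()`, `fene_energy()`,
`angle_energy()` and their `*_force()` companions):

* a purely repulsive, cut-and-shifted Lennard-Jones (WCA) pair potential,
  $U_{\mathrm{WCA}}(r) = \left(4[(1/r)^{12} - (1/r)^{6}] + 1\right)
  \theta(2^{1/6} - r)$;
* a FENE bond, $U_{\mathrm{FENE}}(r) = -\tfrac12 r_{\max}^2 K
  \log[1 - (r/r_{\max})^2]$ with $K = 30$ and $r_{\max} = 1.5$ (one symbol
  is used for the maximum extension throughout; a bond reaching it aborts
  the run rather than permitting a chain crossing);
* a cosine bending term $U_{\mathrm{angle}} = k_\theta(1 - \cos(\theta-\pi))$
  with $k_\theta = 1.5$, applied to every consecutive triplet along each
  ring (cyclically; after cutting, to interior triplets only).

With these constants the chains are effectively uncrossable, which is what
makes the topological state well defined and conserved.

## Parameters and defaults

`ring_params()` collects the model constants.  The defaults are the standard
operating point of this model family:

| parameter | default | units | meaning |
|---|---|---|---|
| `rho` | 0.85 | $\sigma^{-3}$ | monomer number density (fixed volume) |
| `dt` | 0.005 | $\tau$ | integration step |
| `gamma` | 2/3 | $\tau^{-1}$ | friction of both thermostats |
| `T_h`, `T_c` | 3, 1 | $\epsilon/k_B$ | hot / cold thermostat temperatures |
| `N_h` | `N/8` | monomers | hot arc length |
| `M_a` | `M` | — | number of partly active rings |
| `K`, `r_max` | 30, 1.5 | — | FENE constants |
| `k_theta` | 1.5 | $\epsilon$ | bending stiffness |

# The two-temperature Langevin engine

`md_advance()` integrates underdamped Langevin dynamics with velocity
Verlet and impulsive friction/noise (the semantics of the widely used
"langevin fix"): at each force evaluation every monomer receives
$-\gamma m \mathbf v$ plus a white-noise kick whose variance obeys the
fluctuation–dissipation relation at that monomer's *own* label temperature.
The noise is drawn from a counter-based hash stream keyed by
(seed, global step, monomer, component), so runs are bitwise reproducible
and can be continued seamlessly across calls (`step_offset`).  The kicks
are variance-matched uniform deviates; since a velocity integrates
$\sim 1/(\gamma\,\mathrm{dt}) \approx 300$ kicks per relaxation time, the
stationary velocity distribution is Maxwell–Boltzmann far below any
detectable deviation (the test suite checks this with a Kolmogorov–Smirnov
test on $\sim 10^5$ samples).

Pair forces use a Verlet neighbour list built from cell binning with a
0.3 $\sigma$ skin, rebuilt on the standard half-skin displacement
criterion.  Any correct neighbour search would do; this one makes the
desk-scale runs below practical on one CPU core.

## Measured channel temperatures are not the thermostat set points

An important physical point, documented here because it shapes what a
"thermostat fidelity" check can mean in a dense melt: the *measured*
kinetic temperature $m\langle v^2\rangle/3$ of the hot-labelled monomers is
substantially below $T_h$ in a mixed system.  Excluded-volume and bond
collisions conduct kinetic energy from hot to cold monomers at a rate
comparable to or faster than the weak friction $\gamma = 2/3\,\tau^{-1}$
re-supplies it, so a uniformly mixed melt with $T_h = 3$, $T_c = 1$
stabilises near $T^{\mathrm{kin}}_{\mathrm{hot}} \approx 1.65$ and
$T^{\mathrm{kin}}_{\mathrm{cold}} \approx 1.2$.  This is not an integrator
artifact: the all-hot and all-cold limits reproduce 3.00 and 1.00 to a few
tenths of a percent, halving `dt` leaves the mixed-system values unchanged,
the hot deficit balances the cold excess exactly, and increasing $\gamma$
moves the channels toward their set points.  The thermostat *set points*
are exactly $T_h$ and $T_c$; the nonequilibrium steady state is free to
sit between them.  `kinetic_temperatures()` reports the measured values
per channel.

# Building melts with guaranteed topology

`build_melt()` must produce a dense ($\rho = 0.85$) melt in which every
pairwise Gauss linking number is zero and every ring is unknotted — and it
must *guarantee* this by construction rather than by rejection.  The recipe:

1. **Planar double spirals.**  Each ring is laid down as a two-arm
   Archimedean spiral (out along one arm, back along the interleaved arm,
   closed by two short radial hops).  This curve is simple (never
   self-intersects) in its plane, hence unknotted, and its footprint can be
   made as small as needed — a plain circle of $N$ monomers has radius
   $Nb/2\pi$ and stops fitting the box already for $N \gtrsim 50$.
   Rings are assigned to cells of a grid of parallel planes; curves lying
   in disjoint parallel planes (or disjoint cells of one plane) are never
   linked.
2. **Enlarged construction box.**  The layout and the subsequent push-off
   happen in a box enlarged by 1.3 per edge (density lowered by 2.2), which
   keeps the in-plane strand spacing comfortable.
3. **Athermal push-off.**  Overlaps are removed with the WCA force clamped
   below a ramp of radii ($1.05\,\sigma \to 0.6\,\sigma$) plus a per-step
   displacement limiter, with the thermostats effectively off.  The ramp
   keeps early forces below the FENE restoring scale (so no bond can be
   ripped), and the athermal dynamics prevents the soft-core stages from
   letting strands diffuse through one another.  The raw clamped force at
   $0.6\,\sigma$ ($\sim 3.6\times 10^4$) is far too stiff for
   $\mathrm{dt} = 0.005$, which is why the limiter — standard limited-step
   relaxation practice — accompanies it.  Neither the clamp nor the limiter
   is ever active in production dynamics.
4. **Affine compression.**  The box is shrunk to its target size in 1.5%
   steps with short relaxations in between, under the *full* potential —
   the chains are uncrossable during compression, so the trivial topology
   of step 1 is conserved.
5. **Verification.**  All $\binom{M}{2}$ pairwise Gauss linking numbers are
   computed (exact signed solid angles per segment pair, `linking_number()`)
   and must vanish; `verify_topology()` additionally reports bond-length
   bounds and an advisory unknot screen by triangle-elimination contour
   simplification.  Verification is a hard gate: a nonzero linking number
   is a builder error, never a warning.

The builder output is *locally* relaxed: bond lengths, local packing and
segment statistics on scales of a few monomers are equilibrium-like after
the short pre-equilibration, but large-scale ring conformations are not
those of a fully equilibrated melt (that requires times of order the
diffusion time, $\sim 10^5\,\tau$ for $N = 400$, far beyond a desk run).
Consequences for test expectations are discussed below.

Hot arcs are assigned by `assign_activity()`: `M_a` rings are drawn
uniformly (seeded) and each receives one contiguous arc of `N_h` hot
monomers with a uniformly random starting position, since no particular
placement is physically distinguished.

`cut_bonds()` converts every ring into a linear cold–hot–cold triblock by
removing the single bond between the two cold monomers farthest along the
contour from the hot arc's midpoint (for an all-cold ring, the bond closing
the contour).  Monomer storage order is left untouched so trajectories
recorded across the cut remain consistent; the contour order of each open
chain is kept in `state$chain_order`.

# Minimal surfaces and threading

A threading of ring $j$ by ring $i$ is an intersection of $i$'s contour
with the minimal disc-topology surface spanned on $j$'s (fixed) contour.

`triangulate_ring()` spans an oriented centroid fan on the unwrapped
contour; `minimize_area()` evolves the interior vertices by steepest
descent on the total triangle area — the discretised overdamped
surface-tension flow — with a backtracking line search per sweep, since an
overdamped evolution fixes no step size.  Every few sweeps the mesh is
maintained: Delaunay-style edge flips, refinement of long interior edges
toward a target edge of one bond length (so no threading bond can skip a
triangle), and collapse of short interior edges.  All operations preserve
disc topology ($V - E + F = 1$) and never move boundary vertices.  The
descent stops when the relative area decrease per sweep falls below `tol`
(default $10^{-4}$).  The surface is "close to minimal" in the same
pragmatic sense as in surface-evolution software: the tests require
agreement within 1% of the exact polygon area for planar boundaries and
within 2% between independent minimizations started from different meshes.
Self-intersection of the evolving surface is not prevented; the threading
analysis is robust to it because crossings are counted with signs.

`find_piercings()` intersects every bond of the threading contour with
every triangle (vectorised Möller–Trumbore), reporting the bond index,
intersection point and crossing sign.  Grazing hits within $10^{-9}$ of a
triangle edge trigger a tiny seeded perturbation and a retry, which also
resolves crossings through shared edges without double counting.  Under
periodic boundaries the contour is first shifted into the minimum image of
the surface's centroid and all 27 box-shift images are tested with
bounding-box culling.  Correctness of this scan requires only that each
contour fit within one box length; the analysis therefore aborts only in
that case.  (At production scale rings are far smaller than the box; at
desk scale every ring spans an appreciable fraction of it, so an abort at
half the box — a natural rule for production geometry — would forbid desk
analysis altogether.  Parity and sign cancellation hold per periodic copy,
because each copy is a closed curve unlinked with the surface boundary.)

For a nonconcatenated pair the piercing count is even and the signs cancel;
`analyze_threading()` flags violations as concatenation anomalies instead
of silently dropping them.  The separation length follows the alternating
parity sum
$L_{\mathrm{sep}} = \min\bigl(\sum_{i\,\mathrm{even}} L_{t_i},
\sum_{i\,\mathrm{odd}} L_{t_i}\bigr)$,
with $L_{t_i}$ the contour length in monomers between consecutive
penetrations; arcs are measured between piercing-bond midpoints, because
the definition carries no sub-bond resolution.  Which penetration counts
as "first" is immaterial — the two parity classes swap and the minimum is
unchanged, which is precisely why the minimum is taken.  The threading
ratio is $Q = L_{\mathrm{sep}}/(N - L_{\mathrm{sep}}) \in (0, 1]$.  A pair
whose two penetrations sit on the same bond ($L_{\mathrm{sep}} < 1$) is a
graze, not a threading, and is dropped.

Threading *kinetics* operate on directed pair sets per frame: gain/loss
$\Delta n^\pm$ are set-difference cardinalities, the correlation
$\Phi(t, t_0)$ is presence-based (a pair that unthreads and re-threads
still correlates), and the survival distribution $\pi(t, t_0)$ tracks the
first unthreading, with never-unthreading pairs accumulating in the final
(censored) bin.  `threaded_neighbor_count()` divides the number of
*directed* threaded pairs by $M$; directed counting is the convention
adopted throughout (if $i$ threads $j$ and $j$ threads $i$, both count).
Clusters (`threading_clusters()`) connect two rings when at least one
threads the other with $L_{\mathrm{sep}} > L_{\mathrm{cutoff}}$, via
union–find; for active/passive mixtures the largest cluster among
passive-only clusters is reported separately.  Surfaces are recomputed
independently per frame — no warm start — so analyses are reproducible
frame by frame.

# Observables and conventions

Langevin dynamics does not conserve momentum, so every displacement-based
observable is evaluated in the **system centre-of-mass frame**: the global
COM is subtracted per frame before anything else.  A rigidly co-moving
system therefore has $g_3 \equiv 0$.

* `g3()` — squared displacement of ring COMs from a stated origin $t_0$,
  averaged over rings only (no multiple time origins: after the activity
  onset the dynamics is aging, not stationary).
* `self_isf()` — $F_s(q, t, t_0)$ of ring COMs, averaged over all
  box-compatible wavevectors in a 2%-wide shell around the requested
  magnitude (a single lattice vector would not be isotropic); the real
  part is reported.  `nonergodicity_parameter()` evaluates it at the final
  available lag.  `structure_factor()` locates $q^\*$, the maximum of
  $S(q)$ of the ring COMs (at production scale
  $q^\*\sigma \approx 0.35$).
* `ergodicity_breaking()` — relative variance across rings of the
  time-averaged squared displacement at lag $\Delta$ (trapezoidal
  discretisation at the frame spacing).  For ergodic Brownian motion of
  the 3-d COM this decays as $(4/3)(\Delta/t)/3 = (4/9)(\Delta/t)$: the
  familiar $4/3$ coefficient is the one-dimensional result, and the three
  Cartesian components average it down by 3.  The package's tests assert
  the dimension-correct form; the qualitative signature (decay $\sim
  t^{-1}$ when ergodic, $\sim t^0$ when arrested) is unaffected.
* `cold_hot_vector()` — per-ring vector from the cold block's COM to the
  hot block's COM, its mean magnitude, and the directionality correlation
  $\langle \mathbf e_d(t+\Delta)\cdot\mathbf e_{ch}(t)\rangle$ that
  quantifies the emergent "hot head drags cold tail" motion.
* `internal_distances()` — mean squared end-to-end distance of
  $s$-monomer subsegments, position-averaged within the hot block, the
  cold block, or the whole ring, with a log–log least-squares power-law
  fit ($R^2(s) \sim s^{2\nu}$) over a stated window.  The trail exponent
  $\nu_{\mathrm{trail}}$ of the arrested state is obtained this way at
  production scale.  Fit windows default to $s \in [10, 100]$ and are
  always explicit arguments, since no universal window exists; standard
  errors accompany every exponent.
* `displacement_distribution()` — 1-d COM displacement histograms and the
  excess kurtosis $\kappa = m_4/m_2^2 - 3$ (0 for Gaussian, 3 for
  Laplace), the standard diagnostic of cage-escape intermittency.
* `radius_of_gyration()`, `hot_neighbor_count()`,
  `uniform_neighbor_expectation()` — structure measures; the uniform
  closed form $(4/3)\pi c^3 M/V \approx 0.3$ at production geometry
  ($c = 3.25\,\sigma$) is the reference value for the segregation
  diagnostic.

# The synthetic-data generators

Two kinds of synthetic input exist, with different purposes:

* The **melt builder** (above) *is* the study's configuration source: all
  simulated systems — equilibrium melts, partly active melts
  ($N_h$, $M_a$), and cut-ring triblock variants — originate from it at
  the stated composition and density.
* The **observable validators** (`brownian_trajectory()`,
  `fgn_trajectory()`, `kick_trajectory()`,
  `markov_threading_series()`) generate idealized COM dynamics with known
  closed forms (Einstein slope $6D$, Gaussian ISF, $(4/9)\Delta/t$ EB,
  prescribed MSD exponents, geometric threading lifetimes).  They validate
  the estimators, not the physics: passing those tests shows the
  observables measure what they claim on processes where the answer is
  known exactly.  They do not emulate interactions, topology, aging or
  heterogeneity of real melts, so they say nothing about whether a given
  desk melt is equilibrated — that caveat appears wherever it matters.

# Desk-scale problem sizes and what they can and cannot show

The production systems behind the headline phenomenology are
$M = 1600$ rings of $N = 400$ monomers evolved for more than $10^7\,\tau$ —
months of cluster compute.  The package's own validation uses desk-scale
systems chosen to finish on one CPU core in minutes:

* thermostat and transport checks: $M = 10$, $N = 80$, $N_h = 10$,
  $1.5\times 10^5$–$5\times 10^5$ steps;
* segment-statistics checks: $M = 6$, $N = 200$, equilibrated
  $2000\,\tau$ and sampled over $400\,\tau$;
* threading analyses: $M = 27$, $N = 16$ (rings must stay below the box
  size);
* equilibrium controls and property tests: a few hundred particles each.

Two production-scale reference numbers are *not* reproducible at these
sizes, and the
package reports the faithful desk-scale values rather than adjusting
anything toward the targets: the measured hot-channel kinetic temperature
(see the thermostat section; $\approx 1.65$, not $T_h = 3$) and the
50-monomer segment radius of gyration ($\approx 3.6$–$3.8\,\sigma$ at the
desk plateau versus $3.25\,\sigma$ in a fully equilibrated large melt,
whose compact internal statistics require equilibration times far beyond a
desk run).  The corresponding acceptance checks are expected to read red;
the surrounding property suites (equilibrium limits, closed forms,
topology conservation) are the evidence that the implementation itself is
sound.  The cluster-scale exponents ($\nu_{\mathrm{trail}} = 0.57$,
superdiffusion $1.13$, arrested $t^{0.36}$, equilibrium $t^{0.8}$) are
exposed through the same `g3()`/`internal_distances()`/`fit_power_law()`
machinery, whose calibration on synthetic inputs with known exponents is
part of the test suite, so a user with cluster resources can attempt the
full-scale fits directly.

# Numerical choices and degenerate inputs

* Determinism: every stochastic element (builder, thermostat noise, arc
  placement, perturbation retries) derives from explicit integer seeds;
  identical inputs give bitwise-identical outputs, independent of
  scheduling.
* Contours are unwrapped by accumulating minimum-image bond vectors from
  each ring's first monomer; a closure defect above $10^{-6}\,\sigma$
  (a ring winding the torus, or corrupted coordinates) rejects the frame.
* Overstretched bonds ($r \ge r_{\max}$) abort integration with an error
  object carrying the last valid state.
* Grazing segment–triangle geometry perturbs and retries three times, then
  errors; exactly-degenerate triangles in a mesh error with the mesh
  attached.
* A single ring makes EB degenerate (reported 0 with a warning); an empty
  thermostat channel reports `NA`, not zero; `t0` must be a frame time.
* Wavevectors must be box-compatible; requests more than 5% from any
  lattice magnitude error out, listing the nearest available one.

# The pipeline

`read_config()`, `cmd_build()`, `cmd_run()`, `cmd_analyze()` (and the thin
command-line wrapper in `inst/cli/ringmelt.R`) chain the stages from one
YAML configuration: build and verify, run a phase schedule
(equilibrate → activity onset at $t_0 = 0$ → optional cut), and analyze.
Initial states are LAMMPS data files, trajectories are LAMMPS dump text
(XYZ also supported; both are read back), threading tables and observable
series are tab-separated text, surfaces export to OFF/PLY.  The MD5 hash
of the scientific configuration is embedded in every output and checked on
input, so mixing files from different configurations fails loudly.  All
I/O is plain text; no binary container format is required at desk scale.

# Known limitations

* Desk-scale melts are locally, not globally, equilibrated; observables on
  scales beyond $\sim 50$ monomers carry preparation bias (quantified
  above).
* The minimal-surface solver guarantees "close to minimal", not the global
  minimum — the same pragmatic guarantee the field's surface-evolution
  tools provide.
* Statistical, not trajectory-level, equivalence with any particular MD
  engine's Langevin discretisation is claimed (temperatures and transport
  coefficients match; individual trajectories cannot).
* The threading–stress correlation, shape parameters beyond $R_g$, contact
  probabilities and entanglement-length estimation are out of scope;
  $N_e \approx 28$ is treated as a literature constant where needed.
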