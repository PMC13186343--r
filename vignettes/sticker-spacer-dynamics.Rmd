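---
title: "Sticker-spacer condensate dynamics: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sticker-spacer condensate dynamics: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysticker)
```

## The model

Biomolecular condensates formed by multivalent proteins and nucleic acids
are well described by *sticker-spacer* polymers: stickers form transient,
specific crosslinks, spacers contribute excluded volume and weak,
non-specific cohesion. A defining feature of many such systems is strict
single valency -- a sticker holds at most one partner at a time -- which
purely isotropic attraction cannot reproduce: it changes cluster statistics,
produces valency-exhaustion kinetic arrest, and decouples the network
(percolation) transition from the density transition.

`polysticker` simulates linear bead chains in a periodic box under Langevin
dynamics. All quantities use the "real" unit convention: Angstrom,
femtosecond, kcal/mol, g/mol, Kelvin; the thermal energy at the default
310 K is kT = `r round(kT_kcal(310), 4)` kcal/mol. Four potential terms act:

* **Chain connectivity** -- consecutive beads joined by harmonic springs
  $E = K_b (R - R_0)^2$ with defaults $K_b = 3$ kcal mol$^{-1}$ A$^{-2}$,
  $R_0 = 10$ A. (Note the convention without the factor 1/2.)
* **Chain flexibility** -- a cosine bending term on each bead triplet,
  $E = \kappa\,(1 - \cos\theta)$ with $\theta$ the deviation from a straight
  chain (equivalently $\kappa(1 + \cos\theta_{\mathrm{interior}})$), default
  $\kappa = 2$ kcal/mol. A straight chain has zero bending energy.
* **Non-specific cohesion** -- truncated, *unshifted* Lennard-Jones between
  all non-excluded bead pairs,
  $E = 4E_{ns}[(\sigma/r)^{12} - (\sigma/r)^6]$ for $r \le R_{max}$, with
  bead diameter $\sigma = 10$ A and cutoff $R_{max} = 2.5\sigma$. Keeping
  the cited pair style's default (no energy shift) preserves fidelity to
  the published force field at the cost of a $\approx 0.016\,E_{ns}$
  discontinuity at the cutoff; the consequences for energy conservation are
  discussed below. Only directly bonded pairs (permanent 1-2 neighbours and
  currently bonded sticker pairs) are excluded from LJ; 1-3 and 1-4
  neighbours interact at full strength.
* **Specific sticker bonds** -- a shifted-harmonic well between *bonded*
  complementary stickers,
  $E(R) = \frac{E_s}{(R_0^s - R_{cut})^2}\left[(R - R_0^s)^2 - (R_{cut} - R_0^s)^2\right]$
  for $R < R_{cut}$ and $0$ beyond. The well bottom at
  $R_0^s = 1.122\,\sigma$ has depth $-E_s$ and the energy rises to exactly
  zero at $R_{cut} = R_0^s + 1.5$ A.

The two energy scales are deliberately separate: $E_s$ (specific) drives
network formation, $E_{ns}$ (non-specific) tunes cluster compaction. Both
are most naturally specified in units of kT via `default_forcefield()`.

## The hybrid bond scheme

Every `bond_attempt_every` steps (default 20) the engine runs a stochastic
create/break pass:

1. **Break pass.** Every bonded sticker pair whose minimum-image distance
   satisfies $R \ge R_{cut}$ breaks with probability $p_{off}$. A pair
   inside the well ($R < R_{cut}$) is never broken -- dissociation requires
   diffusing over the well edge.
2. **Create pass.** All candidate pairs (complementary types, both
   currently unpaired, $R \le R_{cut}$) are visited in uniformly random
   order; each is accepted with probability $p_{on}$ provided both members
   are still unpaired. This enforces strict valency 1: a bonded sticker is
   invisible to further candidates until its bond breaks.

Defaults are $p_{on} = p_{off} = 1$. The break pass runs before the create
pass within an attempt so that a break-and-instant-reform shows up as two
logged events rather than silently cancelling; the ordering is a
convention (the two passes touch disjoint pairs at $p_{on}=p_{off}=1$,
since breakable pairs are outside $R_{cut}$ and creatable pairs inside).
`p_on`/`p_off` apply per candidate pair per attempt, matching the pairwise
formulation of the scheme; at $p_{on} = 1$ this reduces to uniform random
partner choice among simultaneous competitors, which the tests verify
directly.

## Integration and the thermostat

Positions and velocities advance by a BAOAB splitting: half-kick, half
drift, an exact Ornstein-Uhlenbeck velocity update
$v \leftarrow c_1 v + c_2 \xi$ with $c_1 = e^{-\Delta t/t_{damp}}$ and
$c_2 = \sqrt{kT/m}\sqrt{1 - c_1^2}$, half drift, half-kick. When the
thermostat is off ($t_{damp} = \infty$) the scheme reduces *exactly* to
velocity Verlet, so the NVE limit is available for integrator checks. The
damping time `t_damp` plays the role of solvent viscosity: a free bead has
diffusion coefficient $D = kT\,t_{damp}/m$ (`free_diffusion_coefficient()`),
and the package's acceptance suite verifies both the value and the
$\log D$ vs $\log t_{damp}$ slope of 1.

Two deliberate numerical choices:

* The noise $\xi$ is drawn *uniform* with exactly matched first and second
  moments (zero mean, unit variance), the default of the major
  coarse-grained MD engines. Every observable used here -- equipartition,
  diffusion coefficients, Boltzmann occupancies -- depends on the noise
  only through those moments, and the stationary velocity distribution
  Gaussianizes by convolution over $\sim t_{damp}/\Delta t$ kicks.
* All randomness is *counter-based*: the thermostat and the bond engine
  hold independent seeds, and each step's draws come from a fresh SplitMix64
  stream keyed on (seed, absolute step number). Consequently a restart file
  needs no generator state, a resumed run continues the original trajectory
  bit-for-bit, and a run chunked into restart intervals is identical to an
  uninterrupted one.

Typical timesteps are 15-30 fs. An instability guard aborts with a clear
error when any bead moves more than a quarter box in one step. Energy
conservation in the NVE limit is verified on the continuous part of the
Hamiltonian (bonds + angles, $E_{ns} = 0$): the unshifted LJ truncation
injects $O(10^{-3})$ kcal/mol jumps whenever a pair crosses $R_{max}$,
which is a documented property of the published force field rather than of
the integrator. With the full force field the same check shows the drift
growing monotonically with the timestep, as expected.

Pair interactions use a Verlet list built from a cell grid (skin 3 A,
rebuilt when any bead has moved half a skin), falling back to an all-pairs
enumeration when the box is too small for spatial binning -- e.g. the
elongated two-particle box below.

## System construction

Chains are built from a repeated block template (`block_template()`,
`build_chain()`): the block pattern fixes the sticker arrangement, the
repeat count the chain length. `pack_system()` places each chain copy as a
random walk with step $R_0$, rejecting placements that bring any bead
within `min_separation` (default $\sigma$) of another chain under the
minimum image -- enough to avoid LJ overlap blowups at step 0, with
per-chain regrow attempts bounded so that infeasible densities fail
loudly. Packing is seed-reproducible. An optional `region` argument packs
chains into a sub-box, which is how the titration experiment prepares a
dense preformed droplet. Since the initial inter-chain spacing used by
external packers is not standardised, these defaults are this package's
own choice. Systems round-trip through LAMMPS-style molecular data files;
full dynamical snapshots (positions, velocities, images, pairing, step)
round-trip exactly through a versioned plain-text restart format.

## Observables

* **Energy traces** (`run_simulation()` thermo output): $E_{bond}$ sums
  permanent bonds *and* active sticker wells, so each bond formed at the
  rest distance lowers it by $E_s$; $E_{pair}$ is the LJ sum; and
  $E_{potential} = E_{bond} + E_{pair} + E_{angle}$ holds identically at
  every evaluation.
* **Sticker saturation** -- the fraction of stickers currently bonded.
* **Cluster statistics** -- one graph node per chain, one edge per active
  inter-chain sticker bond; connected components give cluster sizes
  $S_i$ with multiplicities $n_i$. With $f_i = n_i S_i / N$, the *average
  cluster occupancy* is $\mathrm{ACO} = \sum_i f_i S_i = \frac{1}{N}\sum_i n_i S_i^2$,
  normalized by $N$ to lie in $[1/N, 1]$: $1/N$ for free monomers, 1 for a
  single condensate. ACO is size-weighted -- the expected cluster size seen
  by a random *chain* -- and is monotone under cluster mergers.
* **Radius of gyration and MSD** are computed on unwrapped coordinates via
  the stored integer image flags; wrapped coordinates corrupt both. The
  MSD uses origin averaging over logarithmically spaced lags and fits
  $\mathrm{MSD} = 6Dt$ beyond $10\,t_{damp}$ to exclude the ballistic
  regime.
* **Dissociation kinetics** -- break events per fixed window (default
  $10^6$ steps), from the exact event log.
* **Radial profiles** -- sticker/spacer number density in shells about a
  cluster's centre of mass, after unwrapping the cluster into one periodic
  image by breadth-first traversal over its bond graph.

## Detailed balance of the bond scheme

Because bond formation/breakage is a discrete intervention in a continuous
dynamics, it must be checked that the hybrid scheme samples the Boltzmann
distribution. The two-particle experiment (`run_two_particle()`) places one
A and one B sticker in an elongated periodic box (default
$300 \times 15 \times 15$ A -- pseudo-one-dimensional to speed up the
diffusive search; the box volume only shifts the $K_{eq}$ prefactor) and
records the bond state at every attempt step. Classifying successive frame
pairs as UU/UB/BU/BB gives stationary occupancies
$\pi_U = N_U/(N_U + N_B)$, transition rates $P_{U\to B} = N_{UB}/N_U$,
$P_{B\to U} = N_{BU}/N_B$, and $K_{eq} = \pi_U/\pi_B$
(`transition_stats()`). Detailed balance requires the flux identity
$\pi_U P_{U\to B} = \pi_B P_{B\to U}$; under these estimators the flux
ratio reduces to $N_{UB}/N_{BU}$, and for a contiguous trajectory
$|N_{UB} - N_{BU}| \le 1$ exactly, so the identity is satisfied to $O(1/N)$
by construction -- the informative check is that $K_{eq}$ is *Boltzmann*:
$\ln K_{eq}$ linear in $E_s$.

One quantitative subtlety is worth recording. The bound state is not a
single energy level but a harmonic well of finite width, whose occupancy
integral carries an entropic factor $\propto \sqrt{kT/E_s}$. The exact
prediction is therefore
$\ln K_{eq} = \mathrm{const} - E_s/kT + \tfrac{1}{2}\ln(E_s/kT) + O(kT/E_s)$,
whose local slope is $-(1 - kT/2E_s)$: it approaches $-1$ from above as the
well deepens. Over the standard grid $E_s = 2\text{-}7\,kT$ a straight-line
fit of this curve has slope $\approx -0.88$ with $R^2 > 0.999$ -- log-linear
to high precision, as reported for this scheme, but with a fitted slope
measurably shallower than $-1$ at these well depths. The package reports
the fitted slope with its confidence interval and leaves the
interpretation explicit rather than absorbing the entropic term.

## Phase-transition titration

`phase_titration()` starts every grid point from the same preformed
cluster, runs at each $E_s$, and time-averages normalized ACO, saturation
and dissociation counts after discarding an equilibration fraction. The
phase boundary is operationalized as the $E_s$ at which the normalized ACO
crosses 0.5 (linear interpolation); "switch-like" dissolution shows up as a
sharp crossing, saturation as a shallower sigmoid, and dissociation counts
as a non-monotonic curve peaking near the boundary (many short-lived bonds
below it, Arrhenius-suppressed dissociation $\propto e^{-E_s/kT}$ above
it). Runs whose ACO still trends in the last third are flagged
non-equilibrated.

## Study conditions and desk-scale choices

The flagship clustering system is two-component and heterotypic: chains of
50 beads with 10 evenly spaced stickers (block `A spacer spacer spacer
spacer` repeated 10 times, and likewise with B), A binding B only, at
$E_s = 6\,kT$, $E_{ns} = 0.3\,kT$, 310 K, with 400 chains in an 800 A box.
Full equilibration of that system takes tens of millions of steps. The
package's test suite exercises the same physics at sizes a single desk CPU
covers in minutes, chosen once, on physical grounds:

* Detailed balance: 5-6 values of $E_s \in [2, 7]\,kT$ with $10^6$ sampled
  frames each ($2\times 10^7$ steps per value).
* Diffusion: 48 independent free beads, $\Delta t = 10$ fs, six damping
  times 100-3200 fs, $3\times 10^5$ steps per damping value.
* Clustering/titration stand-in: 40 chains (20 + 20) of the flagship
  architecture, condensed in a 200 A box, $\Delta t = 30$ fs,
  $t_{damp} = 2000$ fs. The reduced box raises concentration to keep
  diffusive encounter times inside desk scale (the same small-volume
  strategy used to avoid kinetic arrest in the flagship protocol), and the
  larger damping time -- which affects kinetics only, not equilibrium --
  accelerates diffusion four-fold. (At this density the condensate is
  system-spanning, which is fine for saturation equilibria but not for a
  droplet-dissolution experiment.) The titration therefore uses a droplet
  prepared directly in the chain-count-proportional 371 A box by packing
  all 40 chains into a central 150 A region and bonding them up briefly at
  high $E_s$, so dissolution is probed at the flagship's own overall
  concentration. `rebox_state()` is available for moving non-spanning
  configurations between boxes. Saturation equilibria and the location of the ACO transition
  are equilibrium properties and survive these kinetic accelerations;
  absolute rates and coarsening pathways do not, and nothing desk-scale is
  claimed about them.

What passing these tests shows -- and what it does not. The generator
emulates the constitutive physics (valency-limited bonding, separate
specific/non-specific energy scales, Langevin kinetics) and validates the
estimators against closed forms and brute-force oracles. It does not
emulate sequence heterogeneity, chemically detailed interactions, or
hydrodynamics; quantitative plateau values (e.g. the saturation level of
the 400-chain system) depend on box size and stoichiometry and are only
reproduced at the original scale.

## Known limitations

* Single-process engine; no spatial decomposition or enhanced-sampling
  (metadynamics) machinery.
* Linear chains only -- no branched or ring topologies.
* The unshifted LJ cutoff discontinuity slightly degrades NVE conservation
  (documented above); it is kept for force-field fidelity.
* Electrostatics and tabulated potentials are out of scope.
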