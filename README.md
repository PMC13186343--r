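# polysticker

Coarse-grained Langevin dynamics of **sticker–spacer polymers** with
reversible, strictly single-valent sticker bonds — the minimal physics of
biomolecular condensates in which specific crosslinks (stickers) drive a
percolation-coupled phase transition while weak non-specific cohesion
(spacers) tunes cluster compaction.

It is aimed at condensate modellers who need what isotropic-attraction MD
cannot give them: explicit bookkeeping of bonding valency. Each sticker
holds at most one partner; bonds form with probability `p_on` when two
complementary stickers come within a cutoff and break with probability
`p_off` only once they have diffused beyond it.

## Model

Chains are linear bead polymers (bead diameter σ = 10 Å, mass 100 g/mol)
built from a repeated sticker/spacer block. Four energy terms
(kcal/mol, Å, fs, K — "real" units):

| term | form | defaults |
|---|---|---|
| chain bonds | E = K_b (R − R₀)² | K_b = 3, R₀ = 10 Å |
| bending | E = κ (1 − cos θ), θ = deviation from straight | κ = 2 |
| non-specific | E = 4 E_ns[(σ/r)¹² − (σ/r)⁶], truncated at R_max | E_ns = 0.3 kT, R_max = 2.5 σ |
| specific bond | E = E_s/(R₀ˢ−R_cut)² [(R−R₀ˢ)² − (R_cut−R₀ˢ)²] for R < R_cut | E_s = 6 kT, R₀ˢ = 1.122 σ, R_cut = R₀ˢ + 1.5 Å |

The specific well has depth −E_s at R₀ˢ and rises to exactly 0 at R_cut.
Integration is BAOAB Langevin (velocity-Verlet in the NVE limit) with bond
create/break attempts every 20 steps. All randomness is counter-based, so
identical seeds give bit-identical trajectories and restart files resume a
run exactly.

Analysis includes energy traces, sticker saturation, radius of gyration,
MSD/diffusion, dissociation kinetics, radial density profiles, and
graph-based cluster statistics summarized by the **average cluster
occupancy**: with n_i clusters of S_i chains out of N,
`ACO = Σ f_i S_i = (1/N) Σ n_i S_i²`, `f_i = n_i S_i/N`; normalized by N it
runs from 1/N (dispersed) to 1 (one condensate).

## Worked example

Forty two-component chains (10 stickers + 40 spacers each, A binds B only)
clustering in a periodic box:

```r
library(polysticker)

chA  <- build_chain(block_template(c("A", rep("spacer", 4)), 10))
chB  <- build_chain(block_template(c("B", rep("spacer", 4)), 10))
rule <- complementarity_rule(list(c("A", "B")))
sys  <- pack_system(list(list(chA, 20), list(chB, 20)),
                    box = 200, rule, seed = 1)
sys$state$vel <- init_velocities(nrow(sys$state$pos), T = 310, seed = 2)

p   <- default_forcefield(Es_kT = 6, Ens_kT = 0.3)   # kT at 310 K
cfg <- simulation_config(n_steps = 2e5, dt = 30, t_damp = 2000,
                         thermo_every = 5e4, seed_thermostat = 3,
                         seed_bonds = 4)
run <- run_simulation(sys$state, sys$topology, p, cfg)
tail(run$thermo[, c("step", "E_bond", "E_pair", "saturation")], 3)
sticker_saturation(run$state, sys$topology)
cluster_stats(run$state, sys$topology)$aco_norm
```

```
    step   E_bond    E_pair saturation
3 100000 131.8885 -415.5686      0.715
4 150000 124.7213 -438.4173      0.705
5 200000 106.5865 -438.0960      0.720
[1] 0.72
[1] 1
```

Bond formation drives `E_bond` down by ≈ E_s per sticker pair (the residual
positive value is thermal stretching of the 1960 permanent springs),
`E_pair` follows as spacer cohesion compacts the growing clusters,
saturation plateaus at 0.72, and a normalized ACO of 1 says every chain has
joined a single percolated condensate. The detailed-balance experiment
behind the bond scheme:

```r
db <- detailed_balance_report(2:7, n_frames = 1e6, seed = 1)
c(db$fit$slope, db$fit$r_squared)   # log K_eq linear in Es
#> [1] -0.780  0.943
```

(10⁶ frames per E_s for a quick look; the 10⁷-frame protocol used by
`scripts/acceptance.R` tightens the regression to R² ≈ 0.997.)

A command-line interface (`exec/polysticker`) exposes the same pipeline as
`build`, `run`, `analyze`, `validate-db` and `titrate` subcommands driven
by a YAML config; every invocation writes a `manifest.json` (config, seeds,
package version) from which the run can be reproduced.

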