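---
title: "Rescoring protein-peptide docking decoys by restrained-MD interaction energy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring protein-peptide docking decoys by restrained-MD interaction energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscore)
```

## The problem

Coarse-grained peptide docking (CABS-dock and its relatives) explores binding
poses over a whole receptor surface and typically returns on the order of a
thousand candidate models per complex, grouped into simulation replicas. The
coarse-grained energy that drove the search is deliberately smooth, so it
ranks those candidates poorly: near-native poses are present in the set but
rarely at the top. pepscore implements a physical rescoring protocol for this
situation: each all-atom candidate is briefly relaxed under positional
restraints, scored by its time-averaged receptor-peptide nonbonded
interaction energy, and the candidates are re-ranked by that score. The
package also implements the scheme it is meant to beat — per-replica
low-energy selection followed by k-medoids clustering — plus the evaluation
machinery (ligand RMSD against a reference structure, best-of-top-N, binned
win counts) and a synthetic decoy generator so every stage can be exercised
and tested without any external data.

## The scoring statistic

For a complex with receptor atom set $R$ and peptide atom set $P$, a
configuration is scored by

$$
E_{\mathrm{int}} \;=\; \sum_{i \in R}\sum_{j \in P}
\left[ \frac{k_e\, q_i q_j}{\varepsilon_r\, r_{ij}}
 \;+\; 4\epsilon_{ij}\!\left(\Big(\tfrac{\sigma_{ij}}{r_{ij}}\Big)^{12}
 - \Big(\tfrac{\sigma_{ij}}{r_{ij}}\Big)^{6}\right)\right]
 \, \mathbf{1}\,[\,r_{ij} \le r_c\,],
$$

with $k_e = 1389.35457644382$ kJ mol$^{-1}$ Å e$^{-2}$, Lorentz-Berthelot
combination ($\sigma_{ij}$ arithmetic, $\epsilon_{ij}$ geometric), relative
permittivity $\varepsilon_r = 1$ and cutoff $r_c = 12$ Å by default. Receptor
and peptide share no covalent bonds, so every cross pair is a full nonbonded
pair — there are no exclusions or 1-4 scalings across the interface. The sum
is accumulated in double precision in a fixed atom order, so scores are
deterministic.

Two deliberate simplifications relative to a solvated simulation package:
plain truncation at the cutoff replaces lattice-sum (PME) electrostatics, and
there is no periodic box or explicit solvent. Absolute energies are therefore
not comparable with solvated lattice-sum values; the statistic is a
*relative ranking score*, which is all the protocol needs.

Each model's reported score is the arithmetic mean of $E_{\mathrm{int}}$ over
the trailing half of its recorded trajectory frames
(`window_mean_energy(window_fraction = 0.5)`): for the full 100 ps schedule
with frames every 2 ps this is the last 25 of 50 frames, i.e. the 50-100 ps
window, discarding the early relaxation transient.

## Refinement: restrained minimization and sampling

The refinement stage serves one purpose: let side chains and local contacts
relax so the interaction energy reflects the pose rather than reconstruction
noise, while keeping the pose itself (the backbone) where the docking put it.

**Potential.** The internal potential is the nonbonded form above applied to
*all* atom pairs (intra- and inter-chain), plus a minimal covalent skeleton:
harmonic "chain-glue" bonds (force constant 418.4 kJ mol$^{-1}$ Å$^{-2}$,
equilibrium at the input geometry) along N-CA, CA-C, C-O, CA-CB and the
peptide bond C(i)-N(i+1), with any remaining side-chain atom tied to its
nearest intra-residue neighbor; nonbonded pairs within two bonds of each
other are excluded. This is an intentionally minimal substitute for a full
bonded force field: it prevents chains from dissolving under thermal noise
and avoids 1-2/1-3 clash artifacts, and nothing more. Because bond
equilibria equal the input distances, any input geometry starts at bond
equilibrium and the refinement signal comes from the nonbonded terms.

**Minimization** is steepest descent with an adaptive step (accepted steps
scale the trial displacement up by 1.2, rejected ones halve it), run for up
to 2000 accepted steps or until the trial step falls below $10^{-6}$ Å.
C-alpha atoms of both chains are *fixed* — their gradient components are
projected out — so the optimizer can only repack side chains and carbonyls.
The energy trace over accepted steps is non-increasing by construction, and
the tests assert it.

**Sampling** is BAOAB-discretized Langevin dynamics: 2 fs time step, 300 K,
friction 1 ps$^{-1}$, with every C-alpha *harmonically restrained* (not
fixed) to its post-minimization position at $k = 1000$ kJ mol$^{-1}$
nm$^{-2}$ (0.01 of that per Å$^2$; force constants are accepted in the
conventional kJ/(mol nm$^2$) units and converted internally). BAOAB was
chosen because it samples the configurational distribution of stiff harmonic
systems essentially without step-size bias at these parameters
($\omega\,\Delta t \approx 0.02$), which the equipartition test verifies
directly: the positional variance of a lone restrained atom matches
$k_B T / k$ to within a few percent. Thermal noise comes from an internal
splitmix64 stream seeded per model, so trajectories are bitwise reproducible
and independent of model processing order.

At these settings the restraints do their job: the per-frame RMS C-alpha
displacement from the restraint targets stays near
$\sqrt{3 k_B T/k} \approx 0.87$ Å (we assert $< 1.5$ Å), while individual
atoms transiently reach ~2 Å, exactly as the Maxwell tail predicts. The
quantity that matters for scoring integrity — the change in ligand RMSD
between a decoy as docked and its last refined frame — stays below 1 Å
(measured 0.3-0.7 Å across decoy sets), so refinement does not move models
between accuracy classes.

**Default schedule.** The package default is 5000 steps (10 ps) with frames
every 1000 steps (2 ps), i.e. 5 frames of which the trailing 3 are scored.
This is the desk-scale operating point used throughout the tests and the
acceptance script; `refine_config(sample_steps = 50000)` gives the full
100 ps / 50-frame schedule, which changes runtime, not code paths.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cutoff` | 12 | Å | nonbonded truncation radius |
| `dielectric` | 1 | — | relative permittivity of the Coulomb term |
| `k_restr` | 1000 | kJ mol$^{-1}$ nm$^{-2}$ | C-alpha restraint strength during sampling |
| `k_bond` | 418.4 | kJ mol$^{-1}$ Å$^{-2}$ | chain-glue bond strength |
| `minimize_steps` | 2000 | — | steepest-descent step budget |
| `dt` | 2 | fs | Langevin time step |
| `temperature` | 300 | K | thermostat target |
| `friction` | 1 | ps$^{-1}$ | Langevin coupling |
| `frame_interval` | 1000 | steps | 2 ps between recorded frames |
| `window_fraction` | 0.5 | — | trailing fraction of frames averaged into the score |
| `per_replica_keep` / `n_replicas` | 100 / 10 | — | baseline low-energy selection (1000-model pool) |
| `k` | 10 or 100 | — | baseline cluster count = reported top-scored models |

## The parameter library

`toyff` (JSON, bundled) maps each standard residue's heavy atoms to a partial
charge and a van der Waals type (six types; AMBER-like $\sigma$, $\epsilon$,
masses). Charges use a condensed-hydrogen convention — polar hydrogen charges
are folded into their heavy atom, so the amide nitrogen is neutral and each
peptide unit carries a localized C(+)/O(−) carbonyl dipole — and are
pre-scaled by $1/\sqrt{\varepsilon_{\mathrm{eff}}}$ with
$\varepsilon_{\mathrm{eff}} = 4$, the standard effective dielectric for
screened electrostatics at a solvated protein interface evaluated with a
vacuum Coulomb term. Without this screening, long-range sums over the rigid
carbonyl combs of two facing secondary-structure elements dominate the
interface energy and drown the packing signal the score is supposed to
measure. Terminal residues use the same templates as internal ones and net
neutrality is not enforced; both are documented approximations acceptable
for a relative ranking statistic. The library is a swappable file, not a
reproduction of any published force field.

## Baseline ranking

The comparison scheme mirrors the coarse-grained pipeline's own scoring:
keep the `per_replica_keep` lowest coarse-grained-energy models from each
replica (100 from each of 10 replicas by default), compute pairwise peptide
C-alpha RMSD between the selected models after superposing each onto a
common receptor frame, cluster with k-medoids ($k$ = 10 or 100), and report
the medoids as the top-scored set. k-medoids runs PAM alternation from a
seeded k-medoids++ initialization followed by the PAM swap phase (greedy
medoid/non-medoid exchanges); the swap phase is what makes small instances
reach the exhaustive-search optimum reliably (≥ 80% of seeds in the tests,
never below it). Medoids are ordered by ascending cluster-mean
coarse-grained energy — the clustering literature leaves this choice open,
and it keeps the output deterministic. The clustering metric superposes all
models onto one common receptor frame rather than per-pair, which is exactly
equivalent when decoys share a receptor (the docking-decoy case) and linear
rather than quadratic in superposition count.

## Evaluation

Ligand RMSD follows the rescoring convention: superpose the model onto the
reference using *receptor* atoms only (C-alphas by default; an all-atom fit
is available), then compute the C-alpha RMSD of the peptide without
re-fitting. Residues correspond by (chain, residue number, insertion code),
appropriate for decoys of a single complex. `best_of_top_n` is the lowest
ligand RMSD among the N top-ranked models; `bin_win_counts` compares two
methods per complex, crediting the strictly better one in the 0.5 Å
half-open bin of the winning RMSD, with exact ties counted separately. The
RMSD reported per model comes from the *last* trajectory frame, while the
score averages the trailing window; both conventions are recorded in the
ranked table.

## The synthetic benchmark

`make_toy_complex` builds a two-helix receptor bundle (backbone + CB heavy
atoms on ideal helical geometry) with an extended peptide strand in the
inter-helix groove. Three design choices make it a *usable* scoring
benchmark rather than a random structure:

- the second helix is tilted (taper 0.18 Å per Å of rise), so the groove
  narrows along its axis and a peptide sliding along it loses contact —
  without this the landscape is translation-degenerate and no score can
  prefer the native registry;
- the peptide is placed at van der Waals contact (closest-approach target
  3.5 Å) with both helices, adapted per seed;
- the peptide pose is then rigid-body optimized (deterministic pattern
  search over 6 degrees of freedom) in the interaction energy itself, so
  the reference pose is a genuine local optimum of the scoring landscape —
  the property any real native complex has and a benchmark native must have.

`generate_decoys` perturbs the peptide rigidly: a random rotation about the
peptide C-alpha centroid plus a translation whose magnitude is solved from
the target RMSD (the two contributions add exactly in quadrature about the
centroid), with rejection of poses whose closest receptor approach falls
below 2.5 Å. Target RMSDs come from a truncated-at-zero normal mixture —
unimodal `list(c(1, 6, 3))` by default, emulating sets whose docked ligand
samples the site and its vicinity; a two-component mixture such as
`list(c(0.6, 2.5, 0.7), c(0.4, 30, 1.0))` reproduces the bimodal pattern of
complexes with a competing distant binding mode. A coarse-grained
pseudo-energy is planted through a Gaussian copula on the RMSD ranks
(Pearson $2\sin(\pi\rho_s/6)$ for a target Spearman $\rho_s$), rescaled
until the realized Spearman correlation is within 0.1 of `funnel_rho`
(default 0.7, a moderate funnel typical of knowledge-based docking scores).
All randomness descends from one seed through named substreams (sequence,
poses, pseudo-energy, side-chain noise), so sets are reproducible and
adding models does not perturb existing ones.

`perturb_sidechains` emulates imperfect all-atom reconstruction: Gaussian
displacement of receptor side-chain (non-backbone) atoms only, leaving
C-alphas and the peptide untouched. Substituting the crystal receptor via
`substitute_receptor` and rescoring isolates the effect of that noise — the
package's receptor-substitution control experiment.

**What the generator does not emulate.** Decoys are rigid-peptide
perturbations: no internal peptide flexibility, no backbone reconstruction
error, no alternative side-chain rotamers, no solvent. Passing tests on this
benchmark therefore demonstrate that the protocol's machinery is correct and
that its statistics behave as designed under controlled conditions; they do
not certify accuracy on real docking decoys, whose noise sources are richer.

## Numerical choices and degenerate inputs

- Energies accumulate in double precision in a fixed receptor-major order;
  ranking ties break lexicographically by model id, making every ranking a
  reproducible total order.
- Superposition uses Kabsch via SVD with the proper-rotation sign
  correction; fewer than three points or collinear point sets are rejected
  as degenerate rather than silently fit.
- Coincident receptor-peptide atom pairs (r = 0) are an error naming the
  pair, not an infinity propagated into a mean.
- The minimizer treats a non-finite starting energy as "clashing input" and
  names the worst pair; the sampler aborts when the potential exceeds
  $10^6$ kJ/mol ("unstable integration"), which is how an oversized time
  step manifests.
- Multi-model PDB blocks, `repN` filename tokens, and a manifest TSV
  (`model_id`, `replica_id`, `cg_energy`) cover the three ways decoy sets
  arrive; alternate locations other than blank/"A" are dropped, waters and
  heteroatoms excluded, insertion codes preserved as part of the residue
  key.
- In the pipeline, one failing decoy is logged and excluded; a run aborts
  only when more than 10% of models fail, so a single pathological decoy
  cannot kill a thousand-model run.

## Problem sizes

The test suite and the acceptance script run the full protocol at desk
scale, chosen so the whole suite completes in minutes while every code path
and statistic is exercised: toy complexes of 40 + 10 residues (~244 heavy
atoms), decoy sets of 100-200 models over 10 replicas, 10 ps of restrained
sampling per model (5 frames, trailing 3 scored), and 50-seed Monte-Carlo
repetitions for the funnel-recovery and receptor-substitution success
rates. The success thresholds asserted in the acceptance tests (45/50
funnel recoveries; 60% substitution improvement) were fixed from
Monte-Carlo measurements with the generator's defaults before being frozen
into the tests.

## Known limitations

- No explicit solvent, lattice-sum electrostatics, pressure coupling, or
  constraint algorithms; the thermostat is Langevin friction. Absolute
  energies are not comparable with solvated MD engines.
- The bonded model is a minimal chain glue, not a transferable force field;
  conformational refinement beyond side-chain repacking is out of scope.
- Charged side chains carry screened net charges and no counter-ions exist;
  benchmarks therefore use neutral sequences, and scoring of highly charged
  real interfaces with `toyff` should be expected to be electrostatically
  crude.
- k-medoids at the 1000-model pool size uses the full PAM swap phase
  (seconds); far larger pools would need a sampled variant, which is not
  implemented.
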