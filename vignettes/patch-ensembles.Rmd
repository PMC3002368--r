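---
title: "Sampling side-chain ensembles for surface patches: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling side-chain ensembles for surface patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchsampler)
```

## The model

`patchsampler` treats flexible protein–protein docking as an ensemble
problem: instead of predicting *the* side-chain arrangement of a surface
region, it emits a small set of plausible arrangements and leaves the
choice to the later docking stages. The unit of sampling is a **patch** —
the residues inside a sphere grown around an interface atom until it
contains 8 or 9 *effective* residues (all types except ALA and GLY, whose
heavy-atom side chain is rigid). Eight-ish residues is the practical
ceiling: the configuration space of a patch is the product of its
per-residue rotamer counts, and the downstream clustering dominates the
cost once millions of combinations are in play.

The backbone is held fixed in its unbound conformation throughout. This is
an explicit modeling assumption, not an approximation that averages out:
when the local backbone moves by more than ~2 Å upon binding, no
side-chain resampling on the unbound backbone can reach the bound state,
and the evaluation tools in this package will show exactly that.

### Energy

The scoring function is deliberately minimal — a united-atom (heavy atoms
only) non-bonded sum of a Lennard-Jones and a Coulomb term over pairs of
one patch atom and one atom of the same protein:

$$E=\sum_{(i,j)}\min\!\Big(\epsilon_{ij}\big(\tfrac{A_{ij}}{r_{ij}^{12}}-\tfrac{B_{ij}}{r_{ij}^{6}}\big),\,2\Big)+\sum_{(i,j)}\frac{q_iq_j}{4\pi\epsilon_0\epsilon_r\,r_{ij}}$$

Three guards keep the discrete rotamer representation from blowing up the
energetics: distances are floored at 2 Å, the LJ term is capped at 2
kcal/mol per pair, and residue pairs interact only when their Cα atoms are
within 20 Å. Interactions with solvent-exposed residues (accessible area
above 50% of the residue's extended-tripeptide reference) are halved, a
crude but effective stand-in for solvent screening. The Coulomb term is
**not** capped; the 2 Å floor alone bounds it. If a patch contains two
cysteines whose SG atoms sit 1.8–2.3 Å apart with both CB–SG–SG angles in
[90°, 120°], a configurable disulfide bonus (−10 kcal/mol) is added.

Parameter choices a user may care about:

| parameter | default | meaning |
|---|---|---|
| `epsilon_r` | 1 | relative dielectric; rescales only the Coulomb term |
| `r_floor` | 2 Å | lower distance cap |
| `lj_cap` | 2 kcal/mol | per-pair LJ ceiling |
| `pair_cutoff` | 20 Å | Cα–Cα interaction cutoff |
| `exposure_threshold` | 0.5 | accessible-area ratio above which a residue counts as exposed |
| `exposure_scale` | 0.5 | scale applied to terms with exposed partners |
| `e_ss` | −10 kcal/mol | disulfide bonus |
| `kT` | 0.593 kcal/mol | mean-field temperature (298 K) |
| `damping` | 0.9 | memory coefficient of the SCMF update |
| `tol`, `max_iter` | 1e−4, 500 | SCMF convergence controls |

The 1/2 exposure scaling is stated for the "j" (partner) side of a pair;
for pairs *inside* the patch, where both atoms play both roles, we average
the two residues' factors, which keeps the energy symmetric and lets the
precomputed SCMF tables reproduce `conformation_energy` exactly. For
intra-residue pairs we exclude atoms separated by fewer than 4 bonds — the
standard non-bonded exclusion, needed because ideal-geometry rebuilding
makes 1-2/1-3 distances constant anyway.

Accessibility is computed **once, on the unbound structure** (rolling
probe 1.4 Å, Shrake-Rupley sphere sampling with 240 points per atom).
Recomputing it per candidate conformation would make the energy model
self-referential and was not considered.

### Mean-field filtering stratified by χ1

Taking the k lowest-energy combinations of a patch would cluster around
one minimum. Instead, the sampled space is stratified by the χ1 torsion:
each flexible residue's rotamers fall into the canonical wells g+ (60°),
t (180°) and g− (−60°), and every combination of per-residue wells is
visited. Two exceptions: histidine is enumerated rotamer by rotamer (its
protonation ambiguity makes its energetics unreliable, so we keep
everything), and serine/cysteine — short, hydroxyl/thiol-tipped side
chains whose χ1 matters little for patch shape — are left "free", letting
the mean field pick among their rotamers within every configuration. The
free-slot choice is made independently inside each configuration (the
alternative reading — one global choice shared by all configurations —
would couple strata for no physical reason).

Within one configuration, the admissible rotamer sets define a
**multi-copy system**: residue *i* carries all its rotamers
simultaneously, weighted by probabilities $p_i$. With precomputed tables
(rotamer vs fixed surroundings `E_bb`, intra-rotamer `E_self`, rotamer
pair `E_pair`) the effective energy of rotamer $r$ is

$$\bar E_i(r) = E^{BB}_{i,r} + E^{self}_{i,r} + \tfrac12\sum_{j\neq i}\sum_s p_j(s)\,E^{pair}_{i,r,j,s},$$

and the update reweights $p_i \propto \exp(-\bar E_i/kT)$, mixed with the
previous probabilities (damping 0.9) until the largest probability change
drops below `tol`. The free energy being minimized is
$\langle E\rangle + kT\sum p\log p$; the entropy term is printed unitless
in some formulations, but only the $kT$-scaled version makes the
one-residue minimizer the Boltzmann distribution, so that is what is
implemented (and tested against the closed form). The winning conformation
of a configuration takes each residue's most probable rotamer (ties to the
lowest index). The whole filter is deterministic — no random numbers
anywhere in it.

Two implementation notes. First, the tables are built once per patch and
subset per configuration, so the per-configuration cost is small; residues
with a single admissible rotamer in a configuration are frozen and their
field folded into a constant. Second, the table decomposition reproduces
`conformation_energy` exactly (a tested invariant), so the energies
reported for filtered conformations are the same quantity the evaluation
stage uses.

### Clustering

k-means with k = 50 runs on the flattened side-chain coordinates of the
filtered conformations. Because every conformation of a patch shares the
backbone and the exact atom correspondence, Euclidean distance in that
space is side-chain RMSD times a constant, so this *is* k-means under the
stated metric. We use Lloyd iterations with farthest-point seeding from a
user seed, converging when assignments stabilize; `stats::kmeans` was
rejected because it aborts on empty clusters (routine here, with
near-duplicate conformations) and does not offer assignment-stability
semantics. Each cluster contributes its minimum-energy member, and the
unbound conformation is appended unconditionally (never deduplicated; a
coincidence is flagged). The final ensemble therefore has at most 51
members.

## What the synthetic world does and does not test

`make_toy_case` builds an ideal extended strand (φ, ψ = −120°, 120°) of
eight flexible residues (serine, cysteine, valine, threonine, leucine,
aspartate, glutamine, methionine — small polar, branched and long types,
including the free-slot path) capped by alanines, with a parallel poly-ALA
partner strand 5 Å away so interface detection fires on every residue.
Bound side chains sit exactly on toy-library rotamers; unbound side chains
are the bound ones with χ1 flipped by 120° on every second residue and χ2
shifted by 15° — a deliberate, recoverable perturbation. Both states share
the backbone exactly. The toy force field is element-based LJ with zero
charges (`make_toy_params`), so toy energetics are shape-only.

A green pipeline test on this world establishes: geometric correctness of
building/measurement, the energy decomposition, the stratified filter, the
clustering bookkeeping, and that the ensemble recovers library-representable
bound states under χ1 perturbation with no backbone change. It does *not*
establish performance on real interfaces: real side chains have
correlated, statistically weighted rotamers; real energetics create an
energy–proximity correlation that guides the min-energy representative
choice; and real cases have backbone change. One consequence is visible in
the acceptance suite: in this energetically flat toy world the min-energy
representative of a cluster is effectively an arbitrary member, so the
clustering stage can lose up to ~0.8 Å of best-pick quality against the
filtered set, more than observed on real data. We keep that bound asserted
at its literature value and let the test report the discrepancy rather
than tuning the world to hide it.

## Numerical choices and degenerate inputs

- **Angles** live in (−180°, 180°]; χ1 bins break boundary ties toward
  g+, then t, then g− (so 0° is g+, −120° is t).
- **Radius search** for patches walks a 0.25 Å grid from 3 Å, bisecting
  to 0.01 Å when the effective-residue count jumps past 9 between steps;
  if 8–9 is unreachable the nearest count to 8.5 is taken and the patch
  is flagged degenerate (kept, not dropped).
- **Ties**: maximal-probability rotamer, minimal-energy representative and
  best pick all resolve ties to the lowest index, making every stage
  deterministic.
- **Backbone completeness** requires N, CA, C. A missing carbonyl O is
  rebuilt by ideal geometry (using the next residue's N when available)
  instead of rejecting the case; O does not anchor side-chain building,
  so this maximizes usable cases while honoring the reject rule for
  N/CA/C.
- **Proline** is carried as a single-rotamer type with a rigid approximate
  ring: free-χ rebuilding cannot close the pyrrolidine ring, and its
  conformational contribution to patch shape is minor.
- **Alternate locations** keep the highest-occupancy conformer (ties to
  altloc A); selenomethionine is rescued as methionine; other
  non-standard residues are dropped with a warning.
- **Supplementation RMSD** (the 0.6 Å rule) is computed in place on the
  shared backbone, without superposition and without symmetry-aware atom
  swapping; the same convention is used for all shared-backbone
  comparisons. Bound-vs-unbound comparisons, which involve two different
  frames, superpose the patch backbone once (least squares) and report
  that fit as the backbone-change RMSD.
- **Counts** are exact in double precision below 2^53, far beyond any
  8–9-residue patch.

## Known limitations

- The shipped rotamer library and parameter table are idealized,
  synthetic stand-ins (their file headers say so); serious applications
  should supply a statistical library and force-field-derived parameters
  in the documented text formats.
- Ring geometry (HIS, PHE, TYR, TRP, PRO) is closed approximately by
  fixed torsions; χ-defining atoms are exact, ring-closure bond lengths
  are not.
- No symmetry-aware RMSD for chemically equivalent atoms (PHE CD1/CD2,
  ASP OD1/OD2, ...): a conformation identical up to ring flip scores as
  different.
- Backbone flexibility, patch complementarity matching and docking
  scoring are out of scope here by design.
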