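---
title: "Models and methods behind foldsector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foldsector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsector)
```

foldsector links three layers of information about an oligomeric protein
fold — conformational dynamics, contact energetics and molecular
evolution — and overlays them into interface-associated sectors. This
vignette explains each model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic generators do and do not
emulate.

## Reduced representation

Everything downstream of PDB parsing is Cα-only, with coordinates in
nanometres and residues identified by (chain, author number, insertion
code). The coarsening is deliberate: it makes ensembles, encodings and
contact maps cheap enough to validate exhaustively, at the cost of all
side-chain and hydrogen-bond detail. Analyses that depend on full-atom
chemistry (explicit hydrogen-bond networks, side-chain packing,
configurational frustration) are outside what this package can express,
and conclusions about real systems should be drawn accordingly.

## Constraint-based ensembles

`build_constraints()` turns a reference structure into distance bounds:
every chain-neighbour Cα pair gets a tight bound (native distance ±5%),
every native contact within `contact_cutoff` (default 0.8 nm, the
standard Cα–Cα contact range) a looser one (±15%). A seeded random
`retain_fraction` of the non-bonded bounds is kept; dropping the rest is
a stochastic stand-in for the removal of solvent-unstable interactions
that full-atom engines decide chemically. No hydrogen-bond chemistry is
modelled — this is a documented approximation, not an oversight.

`generate_ensemble()` displaces every Cα uniformly inside a cube
(default side 0.2 nm per move; the displacement scale is configurable)
and then projects pairs onto violated bounds, processing violations in a
seeded random order each sweep to avoid directional bias, for up to 500
sweeps (`max_iter`). A trial that fails to satisfy all bounds within
1e-4 nm is rejected; if the acceptance rate over the first 200 trials
falls below 1% the constraint set is declared infeasible. Accepted
conformers are superposed back onto the reference, so ensembles are
produced in the reference frame. Same seed, same inputs — bit-identical
output.

## Essential dynamics

`ens_pca()` fits each conformer to the reference crystal conformer
(single Kabsch fit, not iterative mean-fitting — matching the rmsf
reference convention) and diagonalises the 3N × 3N covariance.
Eigenvector signs are fixed by making each mode's largest-magnitude
component positive, so results are reproducible across platforms. A
zero-variance ensemble yields all-zero eigenvalues rather than an error.

Subspace convergence uses RMSIP over the top 10 modes — the standard
essential-dynamics overlap measure; the "overlap" of ensemble subsets is
not otherwise defined operationally, and RMSIP is the conventional
choice. Note that RMSIP near 1 requires the top-k subspace to be
well-determined: an ensemble whose spectrum collapses into isotropic
noise after 3 modes cannot show high 10-mode RMSIP no matter how
converged it is. The convergence study therefore uses a planted 10-mode
decaying spectrum whose top three fractions are 0.46/0.14/0.10.

Hinge descriptors define, per conformer, the inertial long axis of two
residue sets. Tilt is the change in inter-axis angle. For bend and
twist, the reference frame (second axis, in-plane perpendicular, and
interface normal = cross product of the two reference axes) is
*transported* with the first axis by the minimal rotation taking the
reference first axis onto its current direction; twist is the in-plane
rotation of the second axis about the normal, bend its out-of-plane
deflection. The transport makes the angles measure relative deformation
rather than residual global motion left by the superposition fit.
Parallel axes leave the normal undefined; such conformers are flagged
degenerate rather than silently scored.

## Structural alphabet and coupling networks

Fragments are 4 consecutive Cα of one chain (N − 3 windows per chain,
never across chain breaks). The geometry descriptor is scale-free: the
three planar angles (1,2,3), (2,3,4), (1,2,4) plus the pseudo-torsion
(1,2,3,4), the torsion embedded as cosine/sine so that distances respect
its periodicity. Encoding assigns the nearest prototype by Euclidean
distance on descriptors, ties to the lowest letter index.

The bundled 25-letter alphabet is a deterministic grid over pseudo-bond
angles (85°–145°) and torsions (−160°–160°) covering helix-like through
extended fragments. It is a synthetic construction, not the
literature-derived prototype table fitted to X-ray fragment statistics;
`fit_alphabet()` (seeded k-means on the input ensemble's descriptors)
provides a data-driven alternative. All coupling statistics are
alphabet-agnostic.

Column couplings use the bias-corrected normalized mutual information
nMI = (I − ε)/H_joint in natural-log units, with the Miller–Madow bias
ε = (r_i − 1)(r_j − 1)/(2M) nats, clipped to [0, 1]; a constant joint
column is defined as nMI = 0. Network edges must exceed both the nMI
threshold (default 0.15) and the 2s significance level — mean + 2 sd of
the all-eligible-pairs corrected nMI distribution — and satisfy the
fragment separation rule (same-chain window starts more than 4 residues
apart; cross-chain pairs always eligible). Centrality is the leading
eigenvector of the symmetric nMI matrix, unit-normalized and
nonnegative; on a disconnected graph it is computed on the full matrix
(mass concentrates on the dominant component) with component indices
reported. Residue profiles average the centrality of the up-to-four
windows covering each residue.

## Contact frustration

The frustration index z-scores each native contact energy against `h`
decoys obtained by re-drawing both residue identities uniformly over the
20 amino acids with geometry fixed (the mutational scheme; the
configurational variant is out of scope):
index = (decoy mean − native)/decoy sd, population sd as the estimator.
The sign convention makes stabilizing contacts positive, which is the
orientation consistent with the classification thresholds: relaxed above
0.78, stressed below −1, neutral between. A zero decoy spread leaves the
index undefined; such contacts are flagged and classified neutral. The
index is invariant to shifting the energy table or scaling it by a
positive constant, and exhaustive enumeration of all 400 ordered
identity pairs (`exhaustive = TRUE`) provides the deterministic limit
that sampled runs converge to at rate ~1/sqrt(h).

The default energy model is a deterministic hydrophobicity-product
potential built from the Kyte–Doolittle scale — a synthetic stand-in
with the qualitative structure of knowledge-based contact potentials
(hydrophobic–hydrophobic favourable). Any symmetric 20 × 20 table can be
injected, and all tests of the index's mathematics are model-agnostic.

## Coevolution

Raw pair scores come from a pluggable scorer; the default is
average-product-corrected (APC) mutual information on
redundancy-weighted frequencies (weights 1/n over the ≥ 0.8-identity
neighbourhood, gaps excluded; columns over 50% gapped are dropped from
pair scoring). Negative product-corrected values are truncated at zero:
they carry no coupling evidence, and truncation keeps the raw score
nonnegative so that the scaled score S_s = S_r/mean(S_r) — whose mean is
exactly 1 by construction — preserves ranking. (Without truncation a
near-zero mean raw score can flip the sign of every scaled score.) Only
pairs separated by more than 3 positions are scored. The tier thresholds
S_s > 1.4 and S_s > 0.5 and the reported significance ratio Nseq/L are
scorer-independent; with the MI default the S_s scale runs higher than
with pseudo-likelihood scores, so tier thresholds should be read as
selectors, not calibrated probabilities. Contact-probability columns
from external services are accepted as pass-through annotation only —
they cannot be recomputed here.

## Evolutionary Trace

rvET integrates column entropy with tree hierarchy: the rooted tree
(midpoint-rooted if necessary) is cut into successively more groups by
splitting internal nodes shallowest-first; at a level with n groups the
node weight is 1/n and group weights are proportional to 1/(group size),
normalised per level. Each group contributes its members' unweighted
column entropy. A fully conserved column scores exactly 1; smaller means
more anciently conserved. The weighting scheme is one of several
consistent readings of the published form (whose summation limits are
not printable as stated); it is chosen to reproduce the defining
behaviours — conserved → 1, clade-fixed variation scoring as more
ancient than scattered variation — and is stated here prominently
because other rvET implementations weight groups differently.

## Phylogenetic statistics

Distance trees use neighbor joining (ape) on identity distances or the
Kimura correction −ln(1 − d − d²/5); saturated distances (argument
≤ 0.01) are capped with a warning rather than erroring, since NJ needs a
finite matrix. Negative NJ branch lengths are clamped to zero with the
originals recorded. Tree similarity r is the Pearson correlation of the
two trees' all-pairs tip-distance vectors over the shared (or
explicitly paired) tip set — all-pairs rather than root-distances, since
the similarity statistic indexes one distance vector per tree.
Diversity is the mean pairwise tip path distance. Clade composition
reports homeotherm:poikilotherm ratios; a clade is flagged when its
ratio leaves mean ± 2s of the *other* clades' finite ratios (population
s), with all-H clades reported as infinite and excluded from the
reference. Greedy sequence clustering is longest-first with
join-first-representative semantics, deterministic for a given input
order; order sensitivity is inherent to the greedy rule and is tested,
not hidden.

## Sectors

The overlay graph unions dynamic fragment edges — projected onto all
4 × 4 residue pairs of their windows with the nMI weight split evenly,
since no finer attribution is defined — with coevolved pairs above the
top tier, tagging edges dynamic/coevolved/both and attaching frustration
and interface classes where a native contact exists. Sectors are
communities of the coevolved subgraph found by walktrap (6-step random
walks), a deterministic method chosen over plain connected components
because a small fraction of spurious cross-sector edges must not fuse
two sectors — with components, a single bridging edge would; on disjoint
dense subgraphs walktrap reduces to components. Each sector is labelled
by the majority interface class among native interface contacts within
one contact step (configurable radius) of its residues; exact ties are
labelled "mixed", never silently resolved, and sectors touching no
interface are "unassigned".

## Synthetic generators and what passing tests mean

The generators plant known ground truth in every input class: idealized
helical multi-chain layouts with recorded interface contacts; ensembles
with an exact low-rank mode spectrum (Gaussian amplitudes along random
orthonormal internal directions, rigid-body motion projected out, plus
isotropic residual) and optional two-state fragment couplings (coherent
±0.2 nm zig-zag deformations toggling in lockstep with a copy-noise
probability); alignments evolved tip-ward along a known tree by uniform
exchange with compensatory planted column pairs (the second column
follows a fixed permutation mapping of the first with probability equal
to the coupling strength, default 0.9); coalescent or Yule trees with
planted clade label compositions.

Study problem sizes were fixed once: spectrum-recovery uses a 50-residue
chain at m = 20,000 conformers; convergence uses a 10-mode decaying
spectrum at m = 4,000 split into quarters; coevolution recovery uses
L = 60, Nseq = 400, ten planted pairs over 20 seeds on Yule trees of
depth 1.5 with substitution rate 1. The Yule choice matters and is worth
stating: a deep Kingman coalescent concentrates its history in one basal
split, which hands every variable column pair genuine shared-ancestry
mutual information — an information-theoretic confound for any MI-class
scorer, and not representative of diversified, redundancy-clustered
homolog collections. The coalescent model remains the default where deep
clade structure is the point (clade-composition studies).

What the passing tests show: the statistics are implemented exactly
(oracle equivalence, closed forms, additivity, affine invariance), and
the pipeline recovers planted signals under realistic synthetic
conditions. What they do not show: that a real tCONCOORD ensemble, a
real Pfam alignment or a real contact potential would reproduce any
particular published magnitudes — the synthetic ensembles have no solvent physics, the
synthetic alignments no substitution-model realism, and the bundled
energy table no statistical calibration. The package's claims about real
systems are structural (which quantities are computed and how), not
numerical.

## Known limitations

Cα-only energetics; no altloc handling beyond first occupancy; no mmCIF;
no maximum-likelihood phylogenetics (NJ only, by design — its exactness
on additive matrices is what makes small-case oracles possible); the
external pseudo-likelihood coevolution service and its contact
calibration are not reproduced, only interfaced.
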