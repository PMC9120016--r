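# foldsector

Integrated analysis of protein conformational dynamics and molecular
evolution for oligomeric folds, built for the kind of question raised by
ring-forming assemblies such as the CaMKII holoenzyme hub: which parts of
a fold are dynamically coupled, which contacts are energetically cheap or
expensive to maintain, which residue pairs coevolve, and how those three
layers overlap into interface-associated *sectors*.

## Who it is for

Structural bioinformaticians who have (or can simulate) a multi-conformer
Cα ensemble of an oligomer, an aligned set of homologous sequences, and a
phylogeny, and who want a reproducible, scriptable path from those inputs
to coupling networks, frustration maps, evolutionary-trace profiles, tree
statistics and a sector partition — with seeded synthetic generators so
every step can be validated against planted ground truth without
downloading anything.

## The statistics at its core

- **Constraint ensembles.** Conformers are generated from a reference
  structure by random Cα displacement inside a cube, followed by iterative
  projection onto distance bounds (tight ±5% bounds for chain neighbours,
  ±15% for native contacts, with a stochastic retain fraction emulating
  unstable-bond removal), up to 500 correction sweeps.
- **Essential dynamics.** PCA of the Cα covariance; the eigenvalue
  fraction per mode measures how much motion it carries. Convergence is
  assessed by RMSIP, the root-mean-square inner product of the top-k mode
  subspaces of disjoint ensemble subsets.
- **Dynamic coupling networks.** Conformers are encoded as strings over a
  structural alphabet of 4-residue fragment prototypes; column pairs are
  scored with bias-corrected normalized mutual information,

      nMI(Ci; Cj) = (I(Ci; Cj) − ε(Ci; Cj)) / H(Ci, Cj),

  with ε the Miller–Madow finite-size term (ri−1)(rj−1)/(2M) nats. Edges
  pass an nMI threshold (default 0.15), a fragment-separation filter
  (default > 4 residues) and a 2s significance cut; node importance is the
  leading eigenvector of the coupling matrix (E·M = λE).
- **Contact frustration.** Each native contact's pair energy is z-scored
  against decoys with randomized residue identities:
  ΔEfr = (mean(E_decoy) − E_native)/sd(E_decoy); contacts above 0.78 are
  "relaxed" (minimally frustrated), below −1 "stressed".
- **Coevolution.** A pluggable raw score S_r per column pair (default:
  APC-corrected, redundancy-weighted mutual information, separation > 3)
  is scaled as S_s = S_r / mean(S_r); tiers S_s > 1.4 (top) and
  S_s > 0.5 (mapped) select pairs for structural mapping, with the
  significance ratio Nseq/L reported.
- **Evolutionary Trace.** rvET_i = 1 + Σ_n w_node(n) Σ_g w_group(g) s_i(g)
  over tree partition levels n = 1..Ntips−1, with s_i the natural-log
  column entropy; a fully conserved column scores exactly 1.
- **Phylogenetic statistics.** Neighbor-joining trees from identity or
  Kimura-corrected distances; tree similarity r = Pearson correlation of
  paired tip-distance vectors; clade diversity as mean pairwise tip
  distance; homeotherm:poikilotherm clade ratios flagged when outside
  mean ± 2s of the other clades.
- **Sectors.** Residue-level union of dynamic and coevolved edges,
  partitioned into communities and labelled by the majority interface
  class (vertical dimer, lateral dimer, kinase–hub) of nearby native
  contacts, with per-sector frustration composition.

## Worked example

```r
library(foldsector)

s   <- synth_structure(12, "tetramer")          # 4 chains, 2 interfaces
gt  <- attr(s, "groundtruth")
cm  <- contacts(s, interface_roles = gt$interface_roles)
cs  <- build_constraints(s, retain_fraction = 1, seed = 1)
e   <- generate_ensemble(s, cs, m = 200, seed = 2)

ens_pca(e)
#> <fold_pca> 200 conformers, leading fractions: 0.031, 0.03, 0.028

frustration_summary(frustration(cm, h = 400, seed = 3))
#> # A tibble: 3 × 6
#>   interface_class relaxed neutral stressed     n stressed_fraction
#>   <chr>             <int>   <int>    <int> <int>             <dbl>
#> 1 intra                 7      44       17    68             0.25
#> 2 lat_dim               4      14        8    26             0.308
#> 3 vert_dim              7      12        3    22             0.136
```

A diffuse constraint ensemble has a flat mode spectrum (leading fractions
~0.03 each: no planted collective motion); under the hydropathy-based
default energy model the vertical-dimer interface of this fixture carries
a lower stressed fraction than the lateral one. The planted-signal
generators show the recovery side:

```r
st  <- synth_tree(n_tips = 400, seed = 7, model = "yule")
msa <- synth_msa(st$tree, L = 60, rate = 1,
                 coupled_cols = list(c(5L, 20L)), strength = 0.9, seed = 7)
head(tidy(coevolve(msa)), 2)
#> # A tibble: 2 × 5
#>       i     j   s_r   s_s tier
#>   <int> <int> <dbl> <dbl> <chr>
#> 1     5    20 1.30  70.1  top
#> 2    17    40 0.181  9.77 top
```

The planted covarying pair (5, 20) tops the scaled-score ranking by a
factor of ~7. `run_pipeline(pipeline_config())` chains every stage on the
synthetic study system and writes per-stage tables plus a manifest.

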