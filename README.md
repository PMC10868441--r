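# idpens

Quantitative analysis of weighted conformer ensembles of intrinsically
disordered proteins (IDPs) and regions (IDRs), for structural biologists who
model such systems from NMR, EPR, SAXS/SANS or single-molecule restraints and
need to compare, profile and visualize the resulting ensembles.

An ensemble is C atomistic conformers of one chain plus a normalized weight
vector w (w_c ≥ 0, Σ w_c = 1). The package implements:

- **Conformer-space similarity.** The distance root-mean-square deviation
  between conformers c1, c2 of an N-residue chain,

      D(c1,c2) = sqrt( (2 / (N(N-1))) Σ_{i<j} (r_ij,c1 − r_ij,c2)² ),

  is a superposition-free metric (invariant under rigid motion and
  reflection). Ensembles are compared through the weighted mean square
  conformer-space distance Δ_kl = Σ Σ w_k w_l D², and the single-valued
  similarity **s_kl = sqrt(Δ_kk Δ_ll) / Δ_kl** ∈ [0, 1] (0 for two distinct
  single conformers, 1 for identical ensembles). The Shannon entropy
  −Σ w log₁₀ w scores ensemble parsimony.
- **Site-specific order and flexibility.** From Cα–Cα bond vectors, the
  site-pair correlation K_ij = 1 − √2·σ_ij (σ²_ij the weighted variance of
  cos θ_ij) and the order parameter o_i = (1/N_v) Σ_j K_ij; from backbone
  dihedrals, the circular resultants R(φ_i), R(ψ_i) and the flexibility
  f_i = 1 − R(φ_i)/2 − R(ψ_i)/2, with random-coil reference bands.
- **Flory random-coil deviations.** Section RMS end-to-end distances
  r_ee(i,j), the scaling-law fit r_ee = b₀ ΔN^ν, and the proximity (P),
  compactness (C) and section-deviation (S) matrices that expose
  heterogeneous local compaction/expansion.
- **Domain partitioning.** Iterative detection of folded domains as low
  square blocks of an AlphaFold PAE matrix (threshold 10.58 Å, minimum
  domain 25 residues), or ordered runs of a per-residue disorder track, with
  F / Sf / Mf / D protein classification and threshold-sensitivity sweeps.
- **Shape visualization.** Inertia-tensor principal-axes superposition of
  disordered conformers, weighted pseudo-electron density on a grid
  (CCP4/MRC export, 99.9 % isolevel) and Debye-screened electrostatic
  surface coloring.
- **Chain generator.** Monte-Carlo backbone ensembles from residue-class
  (Gly/Pro/Thr/general) Ramachandran basin mixtures with optional Cα
  excluded volume and distance-restraint rejection sampling, plus synthetic
  PAE matrices with planted domains.

## Worked example

```r
library(idpens)

# two ensembles of the same 60-residue QGSY-rich chain:
# unrestrained vs restrained to a 15 A contact between residues 10 and 40
seq60 <- coil_reference_sequence(60)
free  <- generate_ensemble(seq60, 100, seed = 1, label = "free")
rs <- list(list(i = 10, j = 40, r = seq(8, 30, 0.5),
                p = dnorm(seq(8, 30, 0.5), 15, 2), acceptance_fraction = 0.5))
bound <- generate_ensemble(seq60, 100, seed = 2, restraints = rs,
                           label = "restrained")

similarity_matrix(list(free, bound))[1:2, 1:2]
#>             free restrained
#> free       1.000      0.702
#> restrained 0.702      1.000

fit_flory(section_ree(ca_trace(free)))
#> Flory fit over 1770 sections: b0 = 5.3887 A, nu = 0.5696 (rss 1304)

order_parameter(free)
#> order profile: 59 sites, mean o = 0.2185 (sd 0.0052)

pae <- synthetic_pae(300, list(c(30, 120), c(160, 280)), seed = 3)
partition_pae(pae)
#> domain partition (N = 300): class Mf
#>   domain 30-120
#>   domain 160-280
```

The similarity 0.702 says the restrained ensemble occupies a measurably
different region of conformer space than the free coil while still
overlapping it broadly. The fitted exponent ν ≈ 0.57 of the short free
chain sits between the θ-solvent (0.5) and good-solvent (0.588) limits, as
expected for a short self-intersecting Ramachandran coil; the mean site
order ≈ 0.22 is close to the random-coil baseline; and the two planted PAE
blocks are recovered exactly, classifying the synthetic protein as Mf
(multiple folded domains with IDR linkers).

A thin command-line wrapper over the same functions is installed at
`inst/cli/idpens-cli.R` (subcommands `similarity`, `profile`, `coil`,
`partition`, `shape`, `generate`).

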