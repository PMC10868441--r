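---
title: "Methods: ensemble analysis of disordered proteins with idpens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble analysis of disordered proteins with idpens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpens)
```

Intrinsically disordered proteins (IDPs) and regions (IDRs) are described by
conformational ensembles: a set of C atomistic conformers with statistical
weights $w_c \ge 0$, $\sum_c w_c = 1$. This vignette documents the models
implemented in idpens, the assumptions behind them, the defaults and their
units, and what the synthetic chain generator does and does not emulate.

## Conformer space and the similarity measure

For an $N$-residue chain reduced to its C$\alpha$ trace, the distance
root-mean-square deviation between two conformers,
$$ D_{c_1 c_2} = \sqrt{\frac{2}{N(N-1)} \sum_{i<j}
   \left(r_{ij,c_1} - r_{ij,c_2}\right)^2 }, $$
depends only on internal distances, so no superposition is needed and the
value is invariant under rigid motion and reflection of either conformer.
$D$ is the Euclidean norm of the difference of the scaled internal-distance
vectors $u_c = d_c / \sqrt{N(N-1)/2}$, hence a metric: every conformer is a
point $u_c$ in an abstract Euclidean "conformer space". This embedding is
used only as a *test oracle*; the implementation works directly on the
pooled distance matrix.

Ensembles $k, l$ are compared through the weighted mean square distance
$$ \Delta_{kl} = \sum_{c_k} \sum_{c_l} w_{k,c_k} w_{l,c_l} D^2_{c_k c_l}, $$
which includes self-pairs for $k = l$ (they contribute zero), and the
dimensionless similarity
$$ s_{kl} = \frac{\sqrt{\Delta_{kk}\,\Delta_{ll}}}{\Delta_{kl}}. $$
The geometric-mean numerator is the only reading that is dimensionless and
gives $s = 1$ for identical ensembles. Because
$\Delta_{kl} = \tfrac12\Delta_{kk} + \tfrac12\Delta_{ll} +
\lVert\mu_k-\mu_l\rVert^2$ (with $\mu$ the weighted mean embedded point),
the AM–GM inequality guarantees $0 \le s \le 1$; the degenerate case
$\Delta_{kl} = 0$ can only occur for identical weighted point sets and
returns $s = 1$ by continuity. Ensembles of unequal residue count are
rejected rather than silently aligned; subsetting to a common residue range
is an explicit user action.

The Shannon entropy of the weights is defined with the decadic logarithm,
$-\sum_c w_c \log_{10} w_c$, so that a uniform 10-conformer ensemble scores
exactly 1.

## Site-specific order and flexibility

**Order.** For bond vectors $\mathbf r_{i,i+1}$ between consecutive
C$\alpha$ atoms, the weighted variance $\sigma^2_{ij}$ of $\cos\theta_{ij}$
over conformers measures the orientational correlation of sites $i$ and
$j$. The site-pair correlation is $K_{ij} = 1 - \sqrt{2}\,\sigma_{ij}$,
clipped to $[0, 1]$. The $\sqrt2$ factor is fixed by the two endpoint
conditions: $\sigma^2 \to \tfrac12$ for uniformly distributed
$\theta_{ij}$ must give $K \to 0$, and $\sigma = 0$ for a rigid pair must
give $K = 1$. (A rendering with $1 - 2\sigma_{ij}$ would give $K = -0.41$,
not 0, at the uniform endpoint.) Values below zero — possible for bimodal
$\cos\theta$ distributions where $\sigma^2 > \tfrac12$ — are clipped to 0.
The site order parameter is the row mean over all $N_v = N - 1$ bond
vectors, including $j = i$:
$$ o_i = \frac{1}{N_v} \sum_j K_{ij}. $$
Bond vectors, not residues, are the objects of these equations, so the
normalization uses $N_v$. For mutually independent isotropic bond vectors,
$\mathrm{var}(\cos\theta) = \tfrac13$ and the off-diagonal baseline is
$K = 1-\sqrt{2/3} \approx 0.18$; a real random coil adds near-diagonal
correlation from local chain stiffness, which is why an unrestrained
Ramachandran coil shows a mean $o_i$ near 0.19 rather than 0.18. The
variance is computed in two passes (mean first, then squared deviations)
because the one-pass $E[x^2]-E[x]^2$ form loses the rigid-ensemble endpoint
$K = 1$ to cancellation.

**Flexibility.** The circular resultant length of a dihedral over the
ensemble, $R = |\sum_c w_c e^{i\alpha_c}|$, is 1 for identical angles and
0 in the uniform limit. The flexibility
$f_i = 1 - \tfrac12 R(\phi_i) - \tfrac12 R(\psi_i)$ therefore runs from 0
(rigid) to 1 (uniform). Undefined dihedrals (chain termini, chain breaks)
are excluded per site with weight renormalization; at sites where only one
of the two dihedrals exists, $f$ is computed from the defined resultant
alone and flagged `partial`, rather than propagating missingness.

**Reference bands.** Random-coil expectations for $o$ and $f$ are
regenerated from a seeded unrestrained generator ensemble
(`random_coil_reference()`), not hard-coded, because they depend on the
Ramachandran library in use. Bands are mean ± 1.96 sd per flexibility
class (Gly, Pro, Thr, other) for $f$ and global for $o$.

## Deviation from Flory random-coil scaling

Section end-to-end distances
$r_{ee}(i,j) = \sqrt{\sum_c w_c\, r^2_{ij,c}}$ are fitted with the Flory
law $r_{ee} = b_0\,\Delta N^{\nu}$ ($\Delta N = j - i$), minimizing the
*linear-space, unweighted* sum of squares over all sections — matching the
convention that every section counts equally and $b_0$ (the Kuhn length,
Å) is shared along the chain. $\nu$ is constrained to $[0.1, 1]$; for
fixed $\nu$, $b_0$ has a closed-form least-squares solution, so the fit
reduces to a robust one-dimensional minimization (tolerance $10^{-10}$).
An exact synthetic law is recovered to $10^{-6}$. Reference exponents:
$\nu = \tfrac13$ (poor solvent), $\tfrac12$ ($\theta$ solvent), 0.588
(good solvent); finite-length chains with local stiffness fit slightly
above their asymptotic exponent.

Deviations are displayed as the proximity matrix
$P_{ij} = (r_{ee}(i,j) - b_0\Delta N^\nu)/(b_0\Delta N^\nu)$, the
section-deviation matrix $S_{ij} = r_{ee}(i,j) - \bar r_{ee}(\Delta N)$
(with $\bar r_{ee}$ the arithmetic mean over equal-length sections — by
construction each antidiagonal of $S$ has zero mean), and the analogous
compactness matrix built from ensemble-RMS section gyration radii with its
own $(b_{0g}, \nu_g)$ fit. Section gyration radii use C$\alpha$ atoms with
equal masses and are combined across conformers as a weighted RMS,
mirroring the $r_{ee}$ definition; the prefix-sum identity
$R_g^2 = \langle|r|^2\rangle - |\langle r\rangle|^2$ keeps the cost at
$O(N^2)$ per conformer.

## Domain partitioning and protein classes

The PAE-based algorithm operates on the symmetrized matrix
$M \leftarrow (M + M^T)/2$, capped at 31.75 Å:

1. binarize: $B_{ij} = [M_{ij} < t_\mathrm{domain}]$ with the default
   $t_\mathrm{domain} = 10.58$ Å (one third of the cap);
2. per residue, the run length $e_i$ = largest $\Delta N$ with
   $B_{ij} = 1$ for all $j = i{+}1 \dots i{+}\Delta N$ (truncated at the
   chain end); $e$ is smoothed with a centered moving average of width 5
   that shrinks at the termini, rounded half-away-from-zero;
3. while $\max e \ge$ the minimum domain size (25 residues): seed the
   domain $(i_{\max}, i_{\max} + e_{\max})$ (lowest index wins ties),
   refine by growing the interval outward while the mean PAE of the
   adjacent residue to the current members is below $t_\mathrm{domain}$
   (contiguous growth only, so domains remain intervals), then zero $e$
   over the members and mask their rows/columns in $M$ with $10^6$;
4. merge domains separated by a linker of fewer than 3 residues.

A seed interval that would overlap a previously accepted domain is
truncated at the first assigned residue (and discarded if it falls below
the minimum size); this guard keeps partitions disjoint and the loop
finite, a case the bare run-length construction does not exclude.

Classes: **D** (no domain), **Mf** (≥ 2 domains), **Sf** (single domain
with a terminal segment of ≥ 10 residues), else **F**. The
one-dimensional track variant classifies residues ordered by a *strict*
threshold rule (eSpritz style: score < 0.15, the midpoint of the
0.14–0.16 sensitivity range; CheZOD style: score > 8 with
`ordered_when = "above"`), takes ordered runs of ≥ 25 residues as domains
and merges across sub-3-residue linkers. `sweep_threshold()` re-partitions
over a grid (default 8.58–12.58 Å in 0.1 Å steps for PAE) and reports the
class fraction across the sweep as a sensitivity summary. The scalar
disorder parameter `mean_pae_disorder()` averages PAE over pairs with
$|i-j| \ge 10$, because the near-diagonal PAE is low even in IDPs.

## Shape superposition, density and surface potential

Each conformer's inertia tensor
$I = \sum_a m_a (|r_a|^2\mathbf 1 - r_a r_a^T)$ (about the center of
mass) is diagonalized; coordinates are rotated into the principal axes
with eigenvalues ordered $I_x \le I_y \le I_z$ and the rotation forced to
determinant +1 so chirality is never inverted. If the first atom of the
N-terminal residue ends up at larger $x$ *or* $z$ than the last atom of
the C-terminal residue, one of the three proper π-rotations about a
principal axis is applied; among them the one minimizing $x_N + z_N$ is
chosen, with ties broken toward the rotation about $y$. The trigger and
tie-break are conventions of this package — only "N-terminus at low $x$
and $z$" is fixed by the method's intent — and are stated here because a
different convention changes individual orientations (never the density's
shape statistics).

The pseudo-electron density places an isotropic Gaussian per atom,
amplitude = electron count, $\sigma = 1.0$ Å for heavy atoms and 0.7 Å
for hydrogens, on a regular grid (default spacing 1 Å, padding 5 Å),
summed per conformer and combined with the ensemble weights. This
deliberately simple kernel model is adequate because the isosurface is a
semiquantitative visualization, not a scattering model. Values are stored
as electrons per voxel, so a single carbon integrates to ≈ 6. The
isolevel is the largest $\tau$ whose superlevel set holds ≥ 99.9 % of the
total (the default fraction). Maps export as minimal mode-2 CCP4/MRC
files (written directly, as no installed R package provides an MRC
writer).

Surface electrostatics uses Henderson–Hasselbalch fractional charges with
the standard side-chain pK$_a$ values Asp 3.65, Glu 4.25, His 6.08,
Lys 10.53, Arg 12.48 at default pH 7.0: carboxylates at the O-pair
midpoint, Lys at NZ, Arg at the NH1/NH2 midpoint, His at the ND1/NE2
midpoint, and phosphorylated Ser/Thr/Tyr (SEP/TPO/PTR) as −2 at the
midpoint of the terminal phosphate oxygens. Terminal backbone charges are
excluded by default. The potential at each isosurface vertex is the
Debye–Hückel sum $\sum_q q\, e^{-d/\lambda_D}/d$ with
$\lambda_D = 0.304/\sqrt{I\,[\mathrm{M}]}$ nm (7.85 Å at the default
150 mM); the $1/d$ Coulomb factor is the physically standard screened
kernel and is included even though a bare exponential would also serve
the coloring purpose. Missing side-chain atoms skip that charge with a
warning rather than failing the whole surface.

## The chain generator: what it emulates and what it does not

`generate_ensemble()` draws per-residue $(\phi, \psi)$ from a
residue-class library and builds the chain with ideal trans-peptide
geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, $\omega = 180°$),
yielding the canonical 3.80 Å consecutive C$\alpha$ spacing. The library
(`default_ramachandran_library()`) is a compact basin-mixture
reconstruction of random-coil Ramachandran statistics: the general class
mixes β, PPII, α$_R$ and a small α$_L$ basin; Pro is pinned near
$\phi = -65°$ with a PPII-dominated ψ; Thr is restricted to Ramachandran
quadrants II/III; Gly adds mirrored positive-φ basins. Basin weights were
set, once, so that an unrestrained coil reproduces the published
random-coil flexibility ordering and ranges per class (Gly ≈ 0.72 >
other ≈ 0.41 > Thr ≈ 0.34 > Pro ≈ 0.26) and the random-coil mean site
order ≈ 0.19; exact reproduction of any particular published
Ramachandran density is out of scope, so class means agree approximately,
not digit-for-digit.

Options: C$\alpha$-only excluded volume (reject conformers with any
$|i-j| \ge 3$ pair closer than 4.0 Å — full-atom clash checking is out of
scope), and distance-restraint rejection sampling: a conformer is kept
with probability $\min(1, p(r)/(\max p \cdot a))$, where $p$ is the
restraint histogram (linearly interpolated) at the conformer's
C$\alpha$–C$\alpha$ distance and $a$ a configured acceptance fraction.
Rejection restarts the whole conformer — simple and unbiased, at the cost
of efficiency, which is acceptable at fixture scale; segment-wise
resampling of a production modeling tool is not reproduced. The default
test chain (`coil_reference_sequence()`) is a fixed deterministic
QGSY-rich 267-residue repeat emulating the composition of a prion-like
low-complexity domain, covering all four flexibility classes.

What the generator does **not** emulate: side chains (so ensembles carry
no intrinsic charges), cis-proline ($\omega$ fixed trans), bond-length/
angle variability, solvent or sequence-specific compaction, and
experimental restraint noise. Passing tests on generator ensembles
therefore demonstrate the correctness of the estimators and the internal
consistency of the statistics — not that any particular experimental
ensemble is a random coil.

`synthetic_pae()` plants square low-PAE blocks (4 Å within, 22 Å
elsewhere, 1 Å noise) with a linear near-diagonal ramp of half-width 10
residues that mimics the short-range PAE suppression seen even in IDPs,
then symmetrizes and clips to [0, 31.75] Å. Blocks of 30–120 residues
separated by ≥ 12-residue linkers are recovered exactly by the partition
algorithm in the seeded test family.

## Numerical choices and degenerate inputs

- Weights are renormalized on load; all-zero or negative weights are
  errors. After any read, $|\sum w - 1| < 10^{-12}$.
- Pooled DRMSD matrices are computed in double precision via a Gram-matrix
  identity, with the tiny negative round-off of squared distances clamped
  at 0.
- Dihedrals spanning a peptide-bond break (C–N distance > 2.5 Å) are NA
  per conformer, with a warning.
- Near-degenerate inertia spectra (relative gap < $10^{-6}$) warn that
  the PAS orientation is unstable; the transform is still returned.
- The Flory fit requires ≥ 10 sections and errors with diagnostics if the
  profiled $b_0$ is non-positive.
- Alternate-location atoms other than blank/'A' are dropped with a
  warning; hydrogens are kept where present (they matter for masses and
  densities); HETATM records are flagged and excluded from C$\alpha$
  traces, dihedrals and (by default) inertia/density computations.
- Conformer weights have no standard field in the PDB format, so they
  live in a plain-text sidecar file (one weight per model, `#` comments);
  uniform weights are assumed when absent.

## Problem sizes used by the test suite

The statistical checks run at deliberately modest scale, chosen as the
smallest sizes at which the tested quantities are stable: the random-coil
baseline uses a 267-residue chain with C = 1000 conformers (the chain
length of the published coil reference; the mean order parameter is
stable to ±0.001 across seeds at this C), flexibility-class comparisons
use C ≥ 120, planted-domain recovery uses 50 seeded matrices at N = 520,
and conformer-space property checks use 100 random ensemble pairs at
N = 8. `scripts/acceptance.R` regenerates the headline numbers at the
same scales from a user-supplied seed.

## Known limitations

- The similarity $s_{kl}$ compares ensembles of the *same* chain only;
  no alignment or truncation is attempted for mismatched constructs.
- The Ramachandran library is a four-class approximation; residue types
  within the "other" class share one basin mixture.
- The PAE partition assumes folded domains are contiguous intervals;
  non-contiguous domain accretion is deliberately not allowed because
  merging and classification require intervals.
- The electrostatic surface model is screened point charges on a kernel
  density isosurface — a coloring aid, not a Poisson–Boltzmann solution.
- Remote-database conveniences (fetching deposited ensembles or PAE
  matrices) are not bundled; all operations accept local files.
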