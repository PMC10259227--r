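---
title: "Energy-grid and propensity-based prediction of protein-protein interaction sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-grid and propensity-based prediction of protein-protein interaction sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppisite)
```

## The model

`ppisite` treats interaction-site prediction as a two-phase procedure.

**Demarcation (ground truth).** Given an experimentally determined
complex, two heavy atoms on different chains are an atomic contact pair
(ACP) when

$$d(a,b) \;<\; r_a + r_b + t, \qquad t = 1.0\ \text{Å},$$

with $r$ the Bondi van der Waals radius of the element. The comparison is
strict, and the ACP set of a chain pair is the interaction interface
(PPII); the unique atoms one chain contributes form its interacting patch
(PPIP). Interfaces with fewer than 20 ACPs are treated as crystal noise
and dropped. These demarcated patches are the reference that predictions
are scored against — there is no hand labeling anywhere.

**Parametric scores.** Three per-residue scales are used:

* **RIP** — residue interface propensity, estimated from training
  interfaces as a pseudocount-smoothed frequency ratio
  $\mathrm{RIP}(r) = \hat f_\text{interface}(r) / \hat f_\text{reference}(r)$,
  where a residue counts once per interface however many of its atoms
  interact, and the reference is the full residue composition of the
  training chains. Values above 1 mark residue types enriched at
  interfaces. Any user table can be substituted from a TSV.
* **Hydrophobicity** $\varphi$ — the Hessa et al. (2005) biological scale
  (apparent free energy of membrane insertion, kcal/mol).
* **Solvation** $\Delta G$ — the Wimley–White (1996) interfacial scale
  (water → membrane interface transfer free energy, kcal/mol); charged
  forms for Asp/Glu/Arg/Lys, neutral His.

Each residue score is decomposed to a per-atom score by dividing by the
number of heavy atoms the residue normally has *excluding the
peptide-bond atoms N, C and O* (glycine has 1, tryptophan 11; CA counts).
That decomposition makes a patch score a simple linear sum over its atoms,

$$S_\text{patch} = \sum_{a \in \text{patch}} \frac{S(\mathrm{res}(a))}{n_\mathrm{atoms}(\mathrm{res}(a))},$$

which is additive over disjoint patches and exactly reconstructs a
residue's score when all its counted atoms are present. The same
construction scores grid points (through their neighboring atoms) and
candidate sites (through their occluded atoms).

**Energy grid.** The unbound chain is boxed with 4.5 Å padding and
discretized at 0.9 Å. Each grid point hosts a methyl (−CH3) probe whose
van der Waals interaction with the protein is a 12-6 Lennard-Jones sum
with Lorentz–Berthelot combination,

$$E_k = \sum_i \varepsilon_{ij}\left[\left(\tfrac{r_{\min,ij}}{r_{ik}}\right)^{12} - 2\left(\tfrac{r_{\min,ij}}{r_{ik}}\right)^{6}\right],$$

truncated at 8 Å and clamped at $+10^3$ kcal/mol inside atomic cores (so
interior points are never "favorable" and prediction is implicitly
restricted to the surface). The parameter table shipped with the package
uses united-atom-style values — protein heavy atoms as extended atoms with
implicit hydrogens (C: ε 0.150 kcal/mol, r_min/2 2.00 Å; probe CH3: ε
0.175, 2.10) — because crystal structures rarely resolve hydrogens and the
package ignores them throughout. The table is a plain TSV and fully
swappable. Points with $E_k$ below a negative threshold are retained.

**Sites.** Retained points are clustered by single-linkage connected
components at $0.9\sqrt{3} + 10^{-9}$ Å, the 26-neighbor connectivity of
the cubic lattice; when more than 15 components form, the 15 largest are
kept (ties: lower total energy, then lowest grid index — every tie-break
is deterministic). The cluster cap is read as an upper bound: nothing
forces exactly 15 clusters out of an arbitrary point set. Each cluster
maps to the protein atoms within the probe-contact radius of any member
point; those atoms carry the cluster's three cumulative scores. Sites are
ranked by

$$z(\textstyle\sum_k P_k) + z(|\textstyle\sum_k E_k|),$$

the standardized cumulative overall propensity plus standardized energy
magnitude, where the overall propensity of a point is the equal-weighted
sum of its three per-scale z-scores (weights configurable). At most 10
sites are reported.

**Training scan.** Candidate-site cumulative scores are pooled over the
training chains and all candidate thresholds, IQR-filtered
($k = 1.5$, quartiles by linear interpolation, one pass) and cut into
domains of Scott's-rule width $3.49\, s\, n^{-1/3}$ spanning
$[\min, \max]$; bins are half-open with the last bin closed. For every
parameter pair (RIP×φ, RIP×ΔG, φ×ΔG), domain combination and threshold,
candidate sites are compared with the actual patch through

$$Ƭ = \frac{2pc}{p + c}, \qquad p = \frac{|P \cap A|}{|P|},\quad c = \frac{|P \cap A|}{|A|},$$

and the bins of sites reaching $Ƭ \ge 0.25$ are accumulated. The energy
threshold retained is the one maximizing the number of training chains
with an accepted site (ties go to the least stringent threshold). At
prediction time a cluster survives when at least one parameter pair places
both of its scores in accepted bins.

## Evaluation

A predicted chain is *correct* when any reported site reaches
$Ƭ \ge 0.25$ (the boundary is inclusive). Dataset evaluation reports the
fraction of correct chains plus the mean coverage of the best site among
the top-1 and top-2 ranks — the same quantities `scripts/acceptance.R`
writes. $Ƭ$ is computed at the atom level, since interfaces are atom sets
throughout; the harmonic mean is the canonical precision/coverage
combiner, and a `min(p, c)` variant is available. Note the ordering
$\min(p,c) \le Ƭ \le \max(p,c)$: the harmonic mean can never fall below
the worse of the two rates.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `tolerance` | 1.0 | Å | ACP cutoff beyond the vdW radius sum |
| `min_acps` | 20 | – | minimum contacts per retained interface |
| `spacing` | 0.9 | Å | grid resolution |
| `padding` | 4.5 | Å | grid box margin (≈ probe minimum distance) |
| `energy_thresholds` | −0.5 … −3.0 | kcal/mol | candidate retention thresholds for the scan |
| `site_radius` | 5.0 | Å | probe-contact radius mapping points to atoms |
| `linkage_cutoff` | 0.9·√3 | Å | single-linkage clustering distance |
| `max_clusters` | 15 | – | cluster cap |
| `max_sites` | 10 | – | predicted sites per chain |
| `tau_min` | 0.25 | – | correctness threshold on Ƭ |

**Why `site_radius` is 5.0 Å and not 1.6 Å.** The natural first choice for
"atoms occluded by a grid point" is a small center-to-center radius such
as 1.6 Å, and the low-level operations (`grid_point_propensity()`,
`site_atoms()`) default to exactly that. But a grid point that is
*energetically favorable* necessarily floats near the Lennard-Jones
minimum, about 4.1 Å from the nearest carbon center; a 1.6 Å
center-to-center ball around it is always empty, which would leave every
retained point scoreless and every site atomless. The pipeline therefore
measures occlusion at the probe-contact scale: an atom is occluded when
the favorable probe position sits within ≈ r_min (4.1 Å) plus ~1 Å of it.
That reading keeps the literal small-radius semantics available at the
operation level while making the method as a whole well-posed.

## The synthetic-complex generator

Real training corpora for this method are thousands of PDB complexes;
everything here must instead be testable from code. The generator builds
two chains of idealized residues — carbon spheres at 1.5 Å covalent-like
spacing on a 4 Å lattice, heavy-atom counts taken from the real
residue-topology table — facing each other across a 3.5 Å gap. The
residues of a central contact zone expose a flat contact layer of up to 3
atoms in the contact plane; everything else is recessed by 4.5 Å, so the
facing contact layers are exactly the atoms the ACP rule recovers and the
ground-truth patch is a multi-atom contact layer, as in a real interface.
Coordinates get ±0.15 Å jitter from an explicitly seeded generator (no
global RNG state leaks), making fixtures byte-identical per seed. Default
study conditions: 40 residues per chain, a 25-residue contact zone
(≈ 250 ACPs, comfortably past the 20-ACP filter), uniform residue
composition; `make_scored_fixture()` additionally steers the contact-zone
composition by deterministic greedy replacement until the patch score
lands in a requested domain bin.

What the generator does *not* emulate: real backbone connectivity,
side-chain rotamers, secondary structure, curved interfaces,
crystal-packing contacts, or composition bias at interfaces. Passing
end-to-end tests therefore demonstrates that the machinery — demarcation,
scoring, grid energetics, clustering, the domain scan, ranking and
evaluation — is correct and internally consistent on geometrically honest
inputs; it does not certify predictive accuracy on real structures, which
depends on training data this package deliberately does not ship.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation between order statistics (R's type
  7); no convention was externally fixed, so the most common one is used.
* Scott bins: the bin count is `ceiling(range / width)` with a 1e-9 guard
  against floating-point shortfall; the final bin absorbs the maximum.
* Z-standardization with zero spread returns 0 (a constant column carries
  no ranking information rather than NaN).
* Clustering ties and ranking ties break by size, then total energy, then
  lowest grid linear index — full determinism is a tested contract
  (byte-identical JSON/TSV across runs).
* Energies at r → 0 are clamped at +10³ kcal/mol (with an r² floor of
  10⁻⁴ Ų); beyond the 8 Å cutoff contributions are exactly zero.
* Chains with no favorable grid point yield an empty prediction with a
  warning, not an error; an empty actual patch is an error (Ƭ undefined).
* If the learned domains reject every candidate cluster of a chain,
  prediction falls back to the unfiltered ranking with a warning — the
  domain filter acts as a soft prior rather than a hard gate, so a chain
  is never left siteless merely because its scores drift outside the
  training range.

## Design decisions that were genuinely open

* **Domain distributions.** The score domains could be built from the
  distributions of *actual patch* cumulative scores or of *candidate
  site* cumulative scores. Domain membership is tested on candidate
  sites, and at the package's test scale candidate sites contain roughly
  three times more atoms than the constructed patches, so patch-derived
  bins would contain no site score and the scan would learn nothing.
  `train_ranges()` therefore bins candidate-site scores;
  `scan_domains()` accepts any externally built domain sets, so the
  patch-derived variant remains one call away.
* **Cumulative vs per-atom domain filtering.** Candidate sites are
  filtered on their cumulative scores (the same construction as patch
  scores), not per atom; per-atom filtering would decouple the filter
  from the distributions the domains were built on.
* **One global energy threshold** is learned rather than one per
  parameter pair; the per-pair accounting is kept in the scan statistics,
  so a per-pair variant needs only a different reduction.
* **Peptide-bond atoms** are read as backbone N, C, O — the three atoms
  of the amide linkage; CA is counted with the side chain.
* **A–B vs B–A contacts** count as one unordered pair.

## Limitations

* The RIP table is derived from whatever training interfaces are
  supplied; with few training complexes it is noisy, and no
  surface-area-weighted reference is used (a SASA-based reference would
  add a dependency without changing the machinery).
* The methyl probe is a single sphere: no electrostatics, hydrogen-bond
  probes, or probe orientation.
* Interfaces are demarcated between chain pairs only; no symmetry mates,
  no assemblies, no crystal-contact filtering.
* Scoring treats only the 20 standard residues; mapped modified residues
  (e.g. MSE → MET) are scored, unmapped ones contribute geometry and
  energy but no propensity.

## Problem sizes used by the tests

The end-to-end suite trains on 10 and evaluates on 10 synthetic complexes
of 40 residues per chain (about 200 heavy atoms, a 37×33×32 grid at
0.9 Å); a full train-plus-evaluate cycle runs in well under a minute on
one CPU, and the complete test suite in under two minutes. Oracle
comparisons (brute-force contact search, double-loop energy sums,
independent single-linkage clustering) run on smaller random systems where
the naive algorithms are exact and fast.
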