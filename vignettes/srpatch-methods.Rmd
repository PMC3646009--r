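---
title: "Methods: surface conservation patches and essential dynamics of spectrin-repeat models"
author: "srpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface conservation patches and essential dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpatch)
```

# The problem

Spectrin repeats (SRs) are ~106-residue three-helix antiparallel coiled-coil
bundles, strung in tandem to form the rod domains of spectrin-family
proteins such as the nuclear-envelope nesprins. For proteins with dozens of
repeats and no experimental structures, homology models are the only
structural handle, and two questions dominate: *which parts of each repeat
surface are candidate protein-interaction sites*, and *how trustworthy is
each model*. `srpatch` implements the analysis layer that answers both, plus
the essential-dynamics toolkit used to characterise SR flexibility in
coordinate ensembles, and a synthetic-data module that makes the entire
pipeline testable without any external structure.

# Surface mapping: SASA, burial and the Ala-Xxx-Ala reference

Solvent-accessible surface area is computed with a Shrake–Rupley quadrature:
each atom's accessible area is the fraction of test points on its
solvent-expanded sphere (van der Waals radius + probe, probe 1.4 Å) not
occluded by any neighbouring expanded sphere, times the sphere area.

Numerical choices that matter:

* **Deterministic quadrature.** Test points come from a generalized-spiral
  (Fibonacci) construction, not random sampling, so areas are exactly
  reproducible without a seed. At the default 960 points the isolated-sphere
  error is below 1% of the analytic area $4\pi(r+p)^2$.
* **Molecule-fixed frame.** A fixed lab-frame point grid makes areas depend
  on the molecule's orientation by up to one point-weight per atom. The grid
  is therefore expressed in a canonical frame built from the principal axes
  of the atom cloud (signs anchored to the first atoms), so areas are
  invariant under rigid motion of the input to floating-point precision.
* **Radii.** A single heavy-atom table: carbonyl C 1.70, aliphatic C (CA,
  CB, side-chain) 1.87, N 1.55, O 1.52, S 1.80 Å; configurable via
  `sasaParams()`. Hydrogens are never modelled.

Relative SASA divides a residue's in-protein area by its area in an
extended (φ = −139°, ψ = +135°) Ala-Xxx-Ala tripeptide built by the same
internal-coordinate machinery and measured by the same engine. Keeping the
numerator and denominator inside one engine and one atom representation is
deliberate: published tripeptide tables assume full side chains and a
particular radius set, and mixing conventions shifts the burial boundary
unpredictably. A residue is **buried** when relative SASA ≤ 20% and
**exposed** above 20%; the source rule states strict inequalities on both
sides, so the boundary value itself is a convention — we classify exactly
20% as buried, and the cutoff is a parameter.

# Conservation patches (pbs)

Conservation grades are ConSurf-style integers 1–9 (9 = most conserved),
consumed as input, never computed. A residue is **conserved** when its grade
is ≥ 7. (The source describes the threshold both as "≥ 7" and, in one
methods sentence, as "> 7"; the explicit definition ≥ 7 is followed, and the
threshold is configurable.)

The neighbour relation is the Cα contact map

$$\mathrm{Contact}(i,j) = 1 \iff |i-j| > 1 \text{ and } d_{C\alpha}(i,j) \le 10\,\text{Å},$$

inclusive at the boundary (the formula's reading; the strict "< 10 Å"
variant is available via `inclusive = FALSE`). Sequence neighbours never
count, even when spatially close — this is preserved exactly as stated.

A **pbs centre** is a conserved, exposed residue with *more than five*
conserved, exposed neighbours under this relation. Both qualifications are
applied to neighbours as well as centres (the stricter and explicit
wording). Centres are counted per repeat, and maximal runs of adjacent
repeats each holding more than five centres are flagged as candidate
interaction regions. `findPbs()` is intentionally a direct transcription of
the rule; its only non-trivial property — agreement with an exhaustive
$O(n^2)$ recount — is asserted over random instances in the test suite.

# Secondary structure and model-quality gates

Backbone hydrogen bonds use the Kabsch–Sander electrostatic model,
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bond iff $E < -0.5$, with the amide H reconstructed 1 Å from N
opposing the preceding C=O direction (model inputs lack hydrogens; proline
donates nothing). n-turn patterns (i→i+3/4/5) yield 3₁₀/α/π helices with
the canonical precedence H > G > I; strand detection is a minimal
two-bridge ladder rule, adequate because SR structures are helical — sheet
accuracy is not a contract of this package. **Helical content** counts
H + G + I; π-helices are explicitly part of SR linker behaviour, which is
why they are included (the set is configurable).

Two gates triage models:

* **Helicity gate.** A model is sent to refinement when its helical content
  falls below (1 − 0.10) × 0.82 = 73.8%, i.e. "within 10%" of the 82%
  template average is read *relatively*. The alternative
  percentage-point reading (cut at 72%) is inconsistent with the published
  outlier set — repeats at 73% helicity are refined while a remodelled
  repeat at 80% passes — and that consistency check is frozen in the test
  suite. Both readings are selectable.
* **Z-score bands.** Externally computed knowledge-based Z-scores are banded
  at the two control-distribution centres: ≤ −5.3 very reliable (canonical
  SR template centre), ≥ −3.0 less reliable (three-helix-bundle decoy
  centre), reliable in between. The bands partition the real line; "centred"
  is read as the arithmetic mean, with a histogram-mode option (bin width
  0.5) since the original distributions were read off plots. The package
  never computes the underlying potential — constructing the decoy set
  requires a comparative-modelling pipeline that is out of scope here.

# Essential dynamics

Ensembles are Cα coordinate sets (read from multi-MODEL PDB; native MD
formats are out of scope). Frames are superposed by Kabsch SVD
superposition onto an iterated mean structure (two passes, Cα-only,
mass-unweighted — the conventional choice, and alternatives shift results
well within the tolerances asserted). Then:

* **RMSF** per residue, $\sqrt{\langle|r_i - \langle r_i\rangle|^2\rangle}$
  (frame-count denominator $n$, not $n-1$).
* **Covariance PCA**: eigen-decomposition of the 3N×3N Cα covariance;
  eigenvalues (Å²) descending; rank deficiency simply yields zero tail
  eigenvalues.
* **Subspace overlap**: the average square projection of the first k = 10
  eigenvectors of one decomposition onto the first k of another,
  $\frac{1}{k}\sum_{ij}(a_i \cdot b_j)^2$ — 1 for identical essential
  subspaces (order- and sign-invariant), ≈ k/3N for unrelated ones.
* **Correlated motions**: normalised displacement covariance
  $C_{ij}$; pairs with $|C_{ij}| > 0.8$ and $|i-j| > 1$ are reported, the
  absolute value so anti-phase pairs are kept, with the signed value in the
  output.
* **Porcupine export**: a two-MODEL PDB (mean, mean + scale × eigenvector)
  so any viewer can draw per-Cα arrows for a mode.

# The synthetic-data module

The generator produces the three kinds of input the analysis assumes, at
the study conditions used throughout the tests:

* **Bundles** (`buildBundle`): helices of 16/18/16 residues built by
  internal-coordinate (NeRF) extension at ideal α torsions (φ = −57°,
  ψ = −47°), packed rigidly and antiparallel on an equilateral triangle of
  side 10 Å; 4-residue loops. Helices are placed rigidly rather than grown
  through loop dihedrals because pure dihedral extension cannot guarantee
  the stated axis separation — the packing *is* the specification, so the
  loops adapt instead: their Cα trace follows a Bezier arc whose length is
  matched to (n+1) × 3.8 Å, with approximate backbone atoms threaded
  through it (standard bond lengths to the adjacent Cα, carbonyl O
  perpendicular to the chain). Clashes trigger up to ten deterministic
  retries with a widened arc. Side chains are truncated at Cβ (Gly has
  none); the sequence is a fixed helix pattern with Gly/Ser loops.
* **Grade tables** (`plantConservation`): a cluster of grade ≥ 7 residues
  planted on *exposed* residues within 10 Å of an exposed centre, over a
  uniform background of grades ≤ 6; seeded and reproducible.
* **Ensembles** (`buildEnsemble`): reference + sinusoidal excursions along
  orthonormal 3N modes + isotropic Gaussian noise per coordinate.
  `randomInternalModes()` supplies planted modes orthogonal to the six
  rigid-body modes — necessary for exact recovery claims, because
  superposition removes the rigid components of any planted motion (the
  hinge mode from `makeHingeMode()` deliberately keeps them, as a physical
  bending motion does).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: side-chain packing (the Cβ-truncated bundle is far
more solvent-exposed than a real SR, so burial fractions are much lower
than the one-third of conserved residues seen in real repeats), sequence-
dependent conservation structure, anharmonic or multi-basin dynamics, and
experimental artefacts (missing residues, altloc disorder beyond what the
reader resolves, B-factor noise).

# Problem sizes and tolerances

The test suite and the acceptance script run on the 58-residue default
bundle; SASA uses 960 quadrature points where the quadrature itself is
under test and 240 elsewhere (classifications are stable well below that);
ensembles use 300–3000 frames, with 2000 frames for the closed-form RMSF
(±5%) and planted-mode recovery (|dot| > 0.95) checks; the brute-force pbs
equivalence runs 100 random instances up to n = 200; planted-cluster
recovery uses 100 seeds. These sizes make the whole suite run in a few
minutes on one CPU while leaving every tolerance comfortably non-trivial.

# Known limitations

* Absolute SASA values are not comparable to coarse-grained engines (e.g.
  POPS) or to full-side-chain calculations; the buried/exposed
  classification against the package's own reference is the contract.
* The secondary-structure assigner covers H/G/I/E/T/C only — no bends,
  chirality or disulfide annotation, and strand detection is minimal.
* `templateHelicalContent()` needs either network access to RCSB or a local
  directory of the template entries; it is the one function whose benchmark
  (the 82% template average, reproduced to ±3 points) cannot be computed
  from synthetic data.
* Multi-chain inputs are analysed per chain; chain concatenation is not
  implemented because SR models are single-chain.
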