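# srpatch

Structural analysis of spectrin-repeat (SR) models: surface conservation
patches, model-quality gates, and essential dynamics.

Spectrin repeats are ~106-residue antiparallel three-helix bundles strung in
tandem through spectrin-family rod domains (spectrins, α-actinins, utrophin,
dystrophin, and the nuclear-envelope nesprins implicated in Emery–Dreifuss
muscular dystrophy). When a rod holds dozens of repeats and no experimental
structures exist, homology models carry the structural analysis — and the
two questions this package answers are *where on each repeat surface a
protein-interaction site is likely to sit* and *how much each model should
be trusted*.

## What it computes

**Putative binding sites (pbs).** Per-residue solvent accessibility from a
deterministic Shrake–Rupley engine; a residue is *buried* when its SASA in
the protein is ≤ 20% of its SASA in an extended Ala-Xxx-Ala tripeptide,
*exposed* above. With ConSurf-style conservation grades (1–9, conserved
means grade ≥ 7) and the Cα contact relation

    Contact(i,j) = 1  iff  |i−j| > 1  and  d(i,j) ≤ 10 Å

a **pbs centre** is a conserved, exposed residue with more than five
conserved, exposed neighbours. Centres are counted per repeat and contiguous
repeats with more than five centres are flagged as candidate interaction
regions.

**Model quality.** Kabsch–Sander secondary structure (H/G/I/E/T/C from the
electrostatic hydrogen-bond model, bond iff E < −0.5 kcal/mol); models whose
helical content falls below 0.9 × 82% (the SR template average) are gated
for refinement; externally computed knowledge-based Z-scores are banded at
−5.3 (very reliable) and −3.0 (less reliable).

**Essential dynamics.** Kabsch superposition, per-residue RMSF, Cα
covariance PCA, the average square projection of the first 10 eigenvectors
of one ensemble onto another (1 = identical essential subspaces), correlated
motions (|C_ij| > 0.8), and porcupine-style mode export.

**Synthetic data.** An internal-coordinate generator builds idealized
three-helix bundles, plants conserved surface clusters into grade tables,
and synthesizes ensembles with planted collective modes — so every stage of
the pipeline is testable offline and end to end.

## Worked example

```r
library(srpatch)

s <- buildBundle(bundleSpec())        # 16/18/16-residue helices, 4-residue loops
s
#> SRStructure: 1 chain(s), 58 residue(s), 286 atom(s)
#>   title: synthetic three-helix bundle (16/18/16)

sasa <- computeSasa(s)                # probe 1.4 Å, 960 points
g    <- plantConservation(s, sasa, seed = 17)   # planted surface cluster
res  <- analyzeRepeats(s, g)
res$reports
#>   repeat_id helical_content gate zscore reliability percent_conserved
#> 1       SR1       0.7586207 pass     NA        <NA>         0.4137931
#>   conserved_buried conserved_exposed pbs_count
#> 1                0                 1        22

head(res$centres, 3)
#>   seq_index author_number aa neighbour_count
#> 1         4             5  Q              11
#> 2         5             6  S              12
#> 3         7             8  D               9
```

Reading the output: the bundle assigns 75.9% helical content (44 of 58
residues in α-helix, the loops fraying the termini), which passes the
refinement gate (cut-off 73.8%); 41% of residues carry a planted grade ≥ 7,
all of them exposed on this Cβ-truncated synthetic surface; 22 residues
qualify as pbs centres, each listed with its author numbering and its count
of conserved, exposed neighbours within 10 Å.

A thin command-line wrapper over the same functions ships in
`inst/scripts/srpatch.R`:

```sh
Rscript inst/scripts/srpatch.R analyze --pdb model.pdb --grades g.tsv --out report.json
```

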