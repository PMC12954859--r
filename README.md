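# LigandForge

Restraint dictionaries for the ligands and small molecules found in
macromolecular crystal structures.

Refinement programs restrain every bond, angle, torsion, chiral centre
and planar group of a ligand toward an ideal value with an estimated
standard deviation (e.s.d.). The Protein Data Bank's Chemical Component
Dictionary describes a component's atoms, bonds and coordinates but
carries no restraints, so every novel ligand needs a dictionary built
for it — and a way to tell whether the geometry behind that dictionary
is any good. LigandForge implements that workflow for structural
biologists and methods developers:

- **read/write** chemical-component CIF and MDL SDF descriptions, and
  Monomer-Library-style restraint CIFs;
- **filter** components the pipeline should not touch (obsolete
  entries, single atoms, metal-containing species, standard residues,
  curated skip lists);
- **perceive** the molecular graph: rings, aromaticity, hybridization,
  acidic protons (protonation variants), polymer termini;
- **generate** a complete restraint dictionary from a 3D geometry,
  including hydrogen-positioning restraints for riding-hydrogen
  refinement;
- **validate** geometries against a reference table of ideal values
  with the maximum-Z-score scheme;
- **verify** dictionaries by a restraint-driven minimization round
  trip.

## The validation scheme

For each bond and angle with a reference entry (ideal value and
standard deviation σ, a stand-in for CSD/Mogul statistics), the
Z-score is

    Z = |observed − ideal| / σ

and the whole geometry is classified by its maximum |Z|:

| max \|Z\| | designation  |
|-----------|--------------|
| < 2       | awesome      |
| < 4       | superior     |
| < 6       | satisfactory |
| ≥ 6       | fail         |

Two refinement-practice wrinkles are applied. First, reference σ
values derived from one or two observations can be tiny or exactly
zero; ad hoc floors of 0.005 Å (bonds) and 0.75° (angles) are
substituted, and a geometry that only passes with floored values is
designated *satisfactory (reasonable std)* regardless of its Z-score.
Second, restraint e.s.d. values written to the dictionary are **twice**
the (floored) reference σ — raw small-molecule σ values are too tight
for macromolecular refinement. Amino-acid-like components are
validated on their side chain only (backbone ideals come from the
polymer libraries) and have the polymerization atoms H2/OXT/HXT
trimmed from the emitted dictionary. For acids, both the deprotonated
*in situ* state expected inside a protein and the protonated *in
notitia* state recorded in the database get dictionaries; the in
notitia state is only validated once the in situ state passes.

The round-trip check minimizes the source geometry under its own
dictionary — harmonic residuals per restraint plus a repulsive-only
nonbonded term — and reports the Kabsch-superposed RMSD between start
and final coordinates: a self-consistent dictionary reproduces its own
geometry.

## Worked example

```r
library(LigandForge)

cc   <- makeComponent("acetic_acid")          # 8-atom toy acid fixture
g    <- assignHybridization(buildGraph(cc), cc)
m    <- measureGeometry(cc, g)
dict <- buildDictionary(cc, m, graph = g)
dict
#> RestraintDictionary ACH [in_situ]: 7 bonds, 10 angles, 4 torsions,
#>   0 chiral, 4 plane atoms
#>   provenance: measured geometry

tab <- makeReferenceTable(dict, g)            # self-consistent table
validateGeometry(m, g, tab)
#> ZscoreReport ACH [in_situ]: awesome
#>   max|Z| = 0.000, rmsZ(bonds) = 0.000, rmsZ(angles) = 0.000, unmatched = 0

roundtripCheck(dict, cc)
#> MinimizationResult: rmsd to start 0.0000 A, 1 iterations,
#>   |grad| 0.00e+00, converged

enumerateProtonationVariants(cc)[[1]]
#> ProtonationVariant ACH [in_situ]: 1 proton(s) removed, dQ -1
```

A geometry identical to its reference ideals scores `max|Z| = 0`
("awesome"), its dictionary minimizes back onto itself (RMSD 0), and
the acid enumerates a deprotonated in situ variant with net charge −1.
A real outlier looks different: a P–O bond observed at 1.681 Å against
a reference of 1.623 ± 0.009 Å gives

```r
zscore(1.681, 1.623, 0.009)
#> [1] 6.444444
```

which exceeds 6 and fails validation.

A thin command-line front end is provided in `exec/forge`
(`forge generate | validate | minimize | pipeline | fixtures |
config`); `forge validate` exits 2 on a failing classification.

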