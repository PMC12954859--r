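---
title: "Generating and validating ligand restraint dictionaries"
author: "LigandForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and validating ligand restraint dictionaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LigandForge)
```

## The problem

Macromolecular refinement treats ligand geometry as prior knowledge: a
restraint dictionary assigns each bond, valence angle, torsion, chiral
centre and planar group an ideal value and an e.s.d., and the refinement
target penalizes deviations from them. The public component dictionary
describes a ligand's atoms, bonds and coordinates but not its
restraints, and deposited coordinates are not necessarily ideal
geometries. This package implements the machinery around that gap: it
turns a component description plus a trusted 3D geometry into a complete
dictionary, scores candidate geometries against reference bond/angle
statistics, and verifies that a dictionary reproduces the geometry it
was derived from.

The geometry itself is an input, not a computation: quantum-chemistry
optimizations (or any other provider) supply candidate coordinate sets,
and the pipeline consumes them in preference order, accepting the first
that validates. This keeps heavy external engines out of the package
while preserving the cascade logic.

## Validation model

For every bond and angle the package derives a type key — per-atom
tokens of element, hybridization and ring/aromatic membership, joined in
a canonical order so the key is invariant to tuple direction. The key is
looked up in a `ReferenceTable` of `(ideal, sd, n_obs)` rows, a
delimited-text stand-in for fragment statistics from a small-molecule
database. The Z-score of a term is $|x_{obs} - x_{ideal}|/\sigma$, and
the geometry is classified by its maximum $|Z|$: strictly below 2, 4, 6
gives *awesome*, *superior*, *satisfactory*; anything else fails. The
root-mean-square Z over bonds and over angles is reported alongside, as
validation reports conventionally do.

Two deficiencies of reference statistics are handled explicitly:

* **Sparse types.** A type observed once can carry $\sigma = 0$, which
  makes the Z-score undefined. Scoring is therefore two-pass: pass 1
  uses raw $\sigma$ (zero-$\sigma$ terms count as unmatched); only when
  pass 1 fails, or zero-$\sigma$ terms were present, is pass 2 run with
  floors $\sigma \ge 0.005$ Å (bonds) and $\sigma \ge 0.75°$ (angles).
  A pass-2 verdict that is not a failure is downgraded to *satisfactory
  (reasonable std)* regardless of the Z-score; a geometry that passes
  on raw $\sigma$ can never earn that flag.
* **Unknown types.** Terms with no reference entry do not fail
  validation; they are counted (`nUnmatched`) and reported, keeping the
  verdict honest without punishing novel chemistry.

Classification uses bonds and angles only. Torsions, rings, planes and
chirality are restrained but not Z-scored: refinement practice judges
model quality by bond/angle deviations, and torsion statistics are
multimodal in ways a single (ideal, σ) pair cannot represent.

Exact threshold values sit on the *worse* side: $\max|Z| = 6.000$
fails. The bands are configuration (`ValidationConfig`), but the
defaults are the scheme's published constants and tests pin them.

## Restraint generation

Ideal values are the measured internal coordinates of the accepted
geometry. E.s.d. values come from the reference table where a term's
type matches: the restraint e.s.d. is `multiplier × max(sd, floor)`
with multiplier 2 — doubling raw small-molecule σ values is the
established refinement convention, and flooring first means the floors
describe the σ scale, not the doubled scale. Types absent from the
table fall back to conventional Monomer-Library magnitudes (bond
0.02 Å, angle 1.5°, plane 0.02 Å, torsion 30/20/10° by period), all
exposed in `EsdPolicy`.

Torsion restraints follow hybridization of the central bond: sp3–sp3
threefold, sp2–sp2 twofold with the ideal snapped to 0/180°, sp2–sp3
sixfold, non-aromatic ring bonds period 1 at the measured value;
aromatic-ring internal bonds carry no torsion (planes cover them) and
bonds with an sp end none at all (the dihedral is degenerate near
collinearity). One representative torsion is emitted per eligible
central bond, reference atoms chosen by heaviest-element-then-name
priority for determinism. The format also accepts discrete-ideal
torsions (period 0 with a list of allowed values, serialized as
multiple rows sharing a torsion id) for minima that are not evenly
spaced; the generator never produces them, but the energy model and
serialization honor them.

Hydrogens get special care because riding-hydrogen refinement positions
each H from its parent's restraints: generation fails unless every
hydrogen has a bond restraint, an angle restraint and — whenever a
non-degenerate four-atom path exists — a positioning torsion. "Exists"
means the central bond of the path is itself torsion-eligible; a methyl
next to a nitrile has no such path and is accepted as-is.

Hybridization itself is deliberately simple: triple bond or cumulated
double bonds → sp; aromatic or one double bond → sp2; otherwise sp3 —
with one guard: an atom with four σ-neighbours (phosphate P, sulfone
S) is tetrahedral regardless of its formal double bonds. Aromaticity
trusts explicit aromatic bond flags and additionally marks 6-rings of
alternating single/double bonds; no Hückel counting. Ring perception is
a smallest-set-of-smallest-rings construction (shortest cycle through
each edge, reduced to a GF(2)-independent basis, ties broken by sorted
atom names) — deterministic by construction.

Chirality restraints store the sign of the signed volume of the three
highest-priority heavy neighbours about each sp3 centre; volumes within
±0.1 Å³ of zero are "both". Planes group each aromatic ring with its
first-shell substituents, and each non-ring sp2 centre with its
neighbours; groups sharing ≥ 3 atoms merge, groups under 4 atoms drop.

## Protonation variants and polymer termini

Databases typically record acids protonated; inside a protein they are
usually not. The package enumerates at most two states: the unchanged
*in notitia* record and an *in situ* state with acidic protons removed
and the bearing oxygens' charges decremented. The acidic-proton pattern
is the minimal chemically standard set — H on O single-bonded to a
carbonyl-bearing C, to S with two S=O, or to P with one P=O. Alcohols
and basic sites (e.g. histidine-like imidazoles) do not generate
variants; protonation of basic centres is curated work outside this
scope. The in notitia geometry is only validated after the in situ
geometry passes — if the physiological form cannot be restrained there
is no point shipping the database form. When only one geometry is
supplied, the in situ variant reuses it with the protons deleted; this
is logged as approximate, and callers with per-variant optimized
geometries supply them through the candidate-geometry interface.

Amino-acid components keep their neutral termini during measurement
(that is how the source geometries are computed) but the emitted
dictionary drops H2, OXT and HXT so the restraints suit the in-chain
form, and validation is side-chain-only: backbone ideals are the
polymer library's business. The backbone/side-chain partition is the
atom-name set {N, CA, C, O, OXT, H, H2, HA, HXT}, configurable because
nonstandard residues may deviate.

## Minimization model

The round-trip verifier minimizes coordinates under the energy

$$E = \sum_k w_k \sum_{t \in k} \left( \frac{\Delta_t}{\sigma_t} \right)^2 + E_{rep}$$

with wrap-aware periodic torsion residuals (nearest symmetry copy, or
nearest discrete ideal), a one-sided chirality term, a best-fit-plane
deviation term, and a repulsive-only nonbonded term: a quadratic
penalty $(c_{ij} - d_{ij})^2$ for pairs at least four bonds apart
closer than $c_{ij} = 0.8\,(r_i + r_j)$ in van der Waals radii, with
hydrogen at the reduced radius (1.0 Å) conventional in restraint
minimizers so ordinary 1-5 H···X contacts are unpenalized. Gradients
are analytic throughout; the plane gradient holds the fitted plane
fixed, which the envelope theorem makes exact because the weighted
best-fit plane minimizes the very sum being differentiated. The
chirality term is flat-bottomed: it penalizes a signed volume only on
the wrong side of ±0.5 Å³, so any correctly-handed tetrahedral centre
feels no force. A strictly harmonic pull toward a fixed target volume
would contradict the dictionary's own self-consistency requirement
(the restraint stores a sign, not a magnitude) — mirror images are
still strongly penalized, which is the restraint's job.

Descent is L-BFGS-B on the flattened coordinates (default: gradient
tolerance 10⁻⁴ per Å, 2000 iterations), deterministic for identical
inputs. Degenerate inputs (overlapping atoms within 0.1 Å, non-finite
starting energy) are rejected up front. Superposition RMSD uses the
Kabsch algorithm with the proper-rotation (no reflection) constraint.

Units are Å and degrees at every interface; trigonometric internals
use radians. Torsions live in (−180°, 180°] and all torsion
comparisons are modulo 360 with wrap-aware distances.

## The fixture generator

Every test runs on synthetic components: alkane chains, benzene, the
acetic acid / acetate pair, an alanine-like amino acid with a chiral
CA and full termini, and a methyl-phosphate-like diester with two
acidic protons. Geometry constants are conventional textbook values
(C–C 1.53 Å, aromatic C–C 1.39 Å, C–H 1.09 Å, tetrahedral 109.47°, …),
hard-coded and documented in the module; they are construction
constants, not empirical claims. `perturbComponent` adds seeded
Gaussian coordinate noise; `makeReferenceTable` builds a reference
table *from* a dictionary, so bias `b` with σ `s` provably induces
max|Z| = b/s — the tests' constructed-Z lever.

What the fixtures do **not** emulate is worth stating: real reference
statistics are noisy, multimodal and incomplete; real ligand
geometries carry strain, crystal-field distortion and tautomeric
ambiguity; real components reach hundreds of atoms. Passing tests
demonstrate that the machinery — typing, scoring, flooring,
classification, generation, serialization, minimization — behaves
exactly as specified on controlled inputs, not that any particular
external geometry source is accurate. Problem sizes throughout the
suite (≤ 14 atoms, ≤ 5 fixtures per property) keep the full run in the
tens of seconds while exercising every code path; the machinery itself
is size-agnostic.

## Design choices that were genuinely open

* **Filter element set.** The excluded-"metal" complement is the
  allowed set {H, D, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}; noble
  gases and all metals trigger exclusion. Halogens, Se and Si stay
  because organics containing them are routinely restrainable.
* **Skip list as input.** Entries previously validated elsewhere are
  skipped by id via `FilterPolicy`; no attempt is made to recompute a
  prior pipeline's acceptance decisions.
* **One torsion per bond.** The redundancy-adjustment policy is: one
  representative torsion per eligible central bond plus whatever
  hydrogen-positioning torsions completeness demands. Emitting all
  torsions would multiply correlated restraints without adding
  information.
* **Floor-then-double.** Floors replace deficient σ values *before*
  the 2× e.s.d. multiplier, because the floors are statements about
  plausible σ, and the doubling is a statement about refinement use.
* **Unmatched terms don't fail.** See above; the count is surfaced
  instead.
* **Candidate geometries are data.** The provider interface is a list
  of labelled coordinate sets; the package ships only the
  identity/fixture provider.

## Known limitations

Metals and metal clusters are out of scope by design, as are link
records between residues, rotamer-derived torsion sets, ring-pucker
validation, tautomer and basic-site protonation enumeration, and
force-field (e.g. GAFF-style) parameter generation. SMILES strings are
carried as metadata only. The type-key granularity is coarser than
real fragment-environment typing; with sparse hand-written tables this
under-merges rather than over-merges, which is the safe direction for
validation.
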