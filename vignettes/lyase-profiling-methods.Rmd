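---
title: "Methods: charged-residue, salt-bridge and motif profiling of MIO ammonia-lyases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charged-residue, salt-bridge and motif profiling of MIO ammonia-lyases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyaseprofile)
```

## The scientific question

Aromatic amino acid ammonia-lyases (phenylalanine, histidine and tyrosine
ammonia-lyases — PAL, HAL, TAL) are MIO-dependent homotetramers.  Within
this family, enzymes that tolerate heat and strongly basic pH differ from
their mesophilic relatives in ways that are visible from sequence and
structure alone: thermotolerant members carry unusually dense salt-bridge
networks, sometimes candidate disulfide bridges, and alkalophilic members
a marked excess of acidic over basic residues, concentrated on the solvent
face.  `lyaseprofile` computes exactly these comparative descriptors —
nothing kinetic, nothing spectroscopic — so that a new family member can be
placed next to the characterised ones on one comparable footing.

The package computes, per enzyme:

* **Composition descriptors** (per chain): length, Cys count,
  Asp/Glu/Lys/Arg percentages, and the *acid excess*
  $(\#\mathrm{Asp} + \#\mathrm{Glu}) - (\#\mathrm{Lys} + \#\mathrm{Arg})$.
  Positive acid excess is the compositional signature of alkali-adapted
  enzymes.
* **Family call** by the selectivity dyad: the two residues aligned to
  Ser83–His84 of *P. putida* HAL discriminate substrate specificity —
  FL marks PALs, SH HALs, HL/HQ TALs — and the MIO-forming Ala-Ser-Gly
  tripeptide is located by alignment anchoring.
* **Salt-bridge statistics** on the biological tetramer: ion pairs under a
  side-chain oxygen–nitrogen distance criterion, with the count-once
  participation percentage.
* **Disulfide candidates**: Cys–Cys pairs under a sulfur–sulfur distance
  criterion, classified intra- vs inter-subunit.
* A **surface-charge proxy** built on solvent-accessible surface areas.

## Operational definitions and their parameters

**Salt bridge.** An acidic residue (Asp: OD1/OD2; Glu: OE1/OE2) and a basic
residue (Lys: NZ; Arg: NE/NH1/NH2) with *any* O–N atom distance within
**3.2 Å (inclusive)**.  The unit counted is the residue *pair*: multiple
atomic contacts between the same two residues count once.  For the
participation percentage ("AA in SB %"), each residue of the whole
assembly counts once no matter how many bridges it joins.  Histidine
nitrogens (ND1/NE2) and the terminal carboxylate/amine are excluded by
default — the comparative tables this reproduces tabulate Lys/Arg only —
but `include_his` and `include_termini` exist because other tools'
selections differ, and reproducing a published count can require matching
the original selection.  Hydrogens never enter any distance computation.

**Disulfide candidate.** Two cysteines with SG–SG distance strictly below
**6 Å** — an upper bound for "could form a bridge after local
rearrangement", not a bonded-geometry criterion (bonded S–S is ~2.05 Å).
When SG is missing from a deposited side chain the CB–CB distance is used
and the pair flagged.

**Assembly before statistics.** These enzymes function as homotetramers and
the bridge statistics are defined on the tetramer, not the crystal
asymmetric unit.  `apply_assembly()` expands deposited transforms
(`REMARK 350` / mmCIF assembly categories) with deterministic chain
renaming (`A` under operators 1–4 becomes `A1`–`A4`).  There is no silent
fallback: analysing an asymmetric unit requires the explicit
`use_asymmetric_unit` flag, because a tetramer statistic computed on a
monomer would be silently wrong by roughly a factor of four.

**Alignment.** Global (end-to-end) affine-gap alignment, BLOSUM62, gap
open 10, extension 0.5 per residue (EMBOSS-style defaults; the penalties
are configurable and the matrix name validated).  Percent identity is
matches over alignment columns.  Scores follow the convention that a gap
of length $L$ costs $\text{open} + L\cdot\text{extend}$.

**Motif anchoring.** ASG is a common tripeptide, so the MIO site is never
taken from a leftmost scan: the query position *aligned to the annotated
reference MIO start* is reported, and only if the query tripeptide there is
ASG.  The family call reads the dyad letters at the query positions aligned
to the anchor dyad; anchoring below 15% identity (beneath the twilight
zone, configurable) or a missing anchored ASG yields `non-MIO`.

**SASA.** Shrake–Rupley point sampling on a deterministic golden-section
sphere lattice, 960 points per atom, probe 1.4 Å, Bondi van der Waals
radii.  No randomness: results are exactly reproducible and
rotation-invariant to well under 0.5%.  An isolated atom reproduces the
closed-form sphere area to machine precision at this lattice density.

**Surface-charge proxy.** The descriptor
$(\text{basic} - \text{acidic}) / (\text{basic} + \text{acidic})$
over the exposed (per-residue SASA > 5 Å²) areas of Asp/Glu vs Lys/Arg.
This is deliberately *not* a Poisson–Boltzmann potential — continuum
electrostatics is out of scope — and every output labels it
"exposure-weighted proxy".  It supports ordering claims ("this variant is
more acid-faced than that one"), which is all the qualitative
surface-potential comparisons it stands in for support either; it is
property-tested on constructed pairs only, never asserted against rendered
figures.

## The synthetic-data generator

Every stage is testable offline because the generator builds structures
whose ground truth is *certified*, not merely intended.  Residues sit on a
12 Å lattice (chains stacked in y, residues along x) with minimal atom sets
(N, CA, C, O, CB plus the criterion atoms OD1/OE1, NZ/NH1, SG).  Each
planted feature — ion pair inside the cutoff, decoy pair just outside it,
disulfide pair — occupies its own block of three lattice columns, which
keeps any two features tens of Ångströms apart, and the planted/decoy
distance ranges must keep a ≥ 0.05 Å margin around the 3.2 Å boundary so
no feature is ambiguous.  After construction an internal all-pairs
brute-force scan verifies that the planted features are the *only* ones
inside any criterion; the test suite re-verifies this with its own,
independently written brute force.  Output is byte-deterministic per seed.

What the toys do **not** emulate: real packing density, rotamer geometry,
backbone connectivity, crystallographic disorder, or the correlated
residue placement of folded proteins.  Passing the planted-recovery
batteries therefore demonstrates the *detection logic* (criteria,
counting rules, spatial indexing) is correct, not that any biological
conclusion follows; the published-structure checks, which need the
deposited PDB entries, are the bridge to real data and are wired to run
whenever those files are supplied.

Sequence generation matches a target composition within one count per
targeted letter (counts are imposed by construction, plants by swapping),
and rejection-samples until each planted motif occurs exactly at its
planted position and nowhere else.

The packaged anchor set (`lyase_anchors()`) is synthetic for the same
reason: generated scaffolds with planted ASG at position 152 and planted
FL/SH/HQ dyads at positions 83–84, mirroring the real numbering.  The
file names and annotations say "synthetic"; for real analyses the curated
reference sequences (the *P. putida* HAL and characterised PAL/TAL
accessions) should be substituted via the `fasta`/`annotation` arguments.

## Numerical and design choices

* **Residue numbering** is taken verbatim from the file (author
  numbering); sequence positions are 1-based throughout, so a motif
  reported at 152 means residues 152–154 in the author numbering of the
  query.
* **Alternate locations**: the highest-occupancy conformer wins, ties
  broken by alphabetical alt-loc id — deterministic and standard.
* **Non-standard residues**: selenomethionine maps to M; anything else
  becomes `X`, counts toward chain length, and is excluded from all
  charged-residue statistics.  Waters and non-amino-acid heteroatoms are
  stripped before analysis (whether the original comparisons stripped them
  is unstated; this is this package's choice, recorded in provenance).
* **Cutoff inclusivity**: ion pairs ≤ 3.2 Å ("within"), disulfides
  < 6 Å — read literally from the criteria's wording and pinned by
  boundary tests at exactly 3.2 and exactly 6.0.
* **Printed-table reconstruction**: `acid_excess_from_percentages()`
  inverts 1-decimal rounding as
  $\mathrm{round}(L\,(a+g-k-r)/100)$ with halves away from zero.  Two rows
  of the published family comparison (the *P. crispum* PAL and
  *R. sphaeroides* TAL rows) do not reconstruct under the stated
  definition (2 vs printed 12; −1 vs printed 0) — possibly His or terminal
  charges were counted, or a misprint.  The package implements the stated
  definition and documents the discrepancy rather than fitting it; those
  two rows are excluded from the reconstruction checks and the exclusion
  is itself asserted in the suite.
* **Determinism**: pair lists are sorted by (chain, residue number),
  reports are byte-identical across reruns, and every report row embeds
  the configuration, its hash, input checksums and the package version.
* **Spatial indexing**: detection uses a uniform grid with cell size equal
  to the cutoff (27-cell neighbourhoods), asserted exactly equal to the
  all-pairs scan on every synthetic instance tested.

## Problem sizes used in the checks

The verification batteries run at sizes chosen to exercise every code path
while staying desk-scale: 50 generator seeds for detection/recovery
(multimers of 1–4 chains × 36–60 residues), 40–100 random short pairs
(length ≤ 12) for the alignment-vs-oracle comparison, 25 end-to-end panel
entries, SASA lattices of 960 points (240 where only ordering matters).
The published-tetramer checks (1GKM, 3CZO, 1W27, 2O7E) run on ~2,000-residue
assemblies when the PDB files are supplied.

## Known limitations

* The real accession-based checks (UniProt Q1AV79/P21310 sequences; the
  four deposited tetramers) require files this package does not
  redistribute; the corresponding suite blocks fail until they are placed
  under `inst/extdata/` as documented in the test file.
* The alkalophilic enzyme's own published bridge statistics (285 bridges,
  23.1% participation) and its three candidate disulfides were computed on
  an undeposited homology model; they ship as published reference values
  (`published_lyase_panel()`) and are never recomputed.
* Reproducing printed counts from other tools can depend on their atom
  selections (His, termini, assembly choice); the sensitivity flags exist
  for exactly that comparison, and provenance records which selection was
  used.
* No pKa prediction, no hydrogen-bond networks, no energies, no continuum
  electrostatics, no multi-model NMR handling (first model only), no
  ligand chemistry.
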