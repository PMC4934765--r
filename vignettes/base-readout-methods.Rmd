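---
title: "Discovering base-readout motifs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering base-readout motifs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basereadout)
```

## The problem

Sequence-specific DNA-binding proteins read part of their target sequence
"directly": individual amino-acid side chains form hydrogen bonds and van
der Waals contacts with the functional groups that each base exposes in the
grooves of the double helix.  The classical examples are the bidentate
hydrogen bonds of asparagine/glutamine amides with the Hoogsteen edge of
adenine and of the arginine guanidinium group with the Hoogsteen edge of
guanine.  `basereadout` implements a statistical/energetic screen for such
motifs: it extracts every interacting amino acid-nucleotide pair from a set
of protein-DNA complex structures, asks which geometrical arrangements
recur across unrelated proteins, scores each arrangement with a
molecular-mechanics interaction energy in several dielectric environments,
and grades every (amino acid, base, edge) combination against four criteria
of specificity.

## Pipeline stages and their parameters

### Structure ingestion

Structures are parsed from PDB text (`parse_structure()`), and kept only if
solved by X-ray crystallography to a resolution strictly better than 2.5 A
with an R-factor of at most 0.25 (`filter_structures()`).  Structures
missing either metadatum are excluded with a warning; that is a
conservative choice, since the source records do not say how such entries
should be treated.  A usable structure must contain a double-stranded DNA
region of at least 4 consecutive Watson-Crick pairs
(`detect_duplexes()`); pairing is decided by a purine N1 to pyrimidine N3
distance under 3.5 A between complementary residues on locally antiparallel
strands, the minimal standard test.  Identical protein chains
(homomultimers) collapse to the alphabetically first chain and each
distinct chain becomes an independent analysis entry (`make_entries()`).

### Contact extraction

An amino acid and a nucleotide form a *contact dimer* when any of the
residue's three reference atoms (its characteristic side-chain atoms; a
packaged, editable table) lies within 1.0 A plus the sum of the van der
Waals radii of any DNA heavy atom (`find_contacts()`).  Nucleotides at a
strand's 5' end lack the phosphate group and are discarded.  A dimer is
*base-directed* when any amino-acid atom -- all atoms this time, not just
the reference atoms -- satisfies the same rule against a base-moiety atom
(`flag_base_directed()`).  Base-directed dimers are duplicated and stripped
to the bare base (`strip_to_base()`) so the energetic contribution of the
sugar-phosphate backbone can be isolated.

### Redundancy treatment

Entries from homologous proteins would otherwise dominate the statistics.
All protein pairs are globally aligned (Needleman-Wunsch under BLOSUM62,
affine gaps with opening 10 and extension 0.5 -- the defaults of the
classic `needle` program; identity is identical positions over full
alignment length including gap columns).  `cull_by_identity()` then keeps,
scanning entries in alphanumeric order, only entries below the chosen
pairwise identity level (30/90/95/100 %).  The greedy keep-first reading is
one of several consistent with a "complement of merged homolog lists"
description; it guarantees by construction that every kept pair satisfies
the bound, which is the property the tests check.

### Geometry: common frame and clustering

All dimers of one amino-acid x base type are superposed onto a packaged
ideal base template by least-squares fitting of the base heavy atoms
(proper rotation only), carrying the side chain along rigidly
(`build_distribution()`).  `greedy_cluster()` then repeatedly finds the
pose with the most neighbours within 1.5 A reference-atom RMSD (computed
*without* re-superposition, since all poses share the base frame), removes
it with its neighbours as a cluster, and stops after 6 clusters or when the
next cluster would be smaller than `min_size`.  The sparse-population
cut-off is not quantified in the source description; the default of 4
members is this package's choice and is exposed as a parameter.  Ties in
neighbour count break toward the lowest pose index for determinism.

### System preparation

Scored species are chemically complete small molecules:

* amino acids in the *C-alpha representation*: backbone amide and carbonyl
  groups removed, C-alpha capped as a methyl group; proline keeps its ring
  as a neutral tetrahydropyrrole and glycine becomes methane;
* full 2'-deoxyribonucleoside 5'-monophosphates (dNMPs), whose phosphate is
  completed by the bridging O3' oxygen placed 1.610 A from the phosphorus,
  perpendicular to the OP1/OP2/O5' plane on the phosphorus side of that
  plane (the side choice completes a tetrahedron; the alternative sign
  would fold the oxygen back through the plane), plus a single capping
  hydrogen on that oxygen;
* stripped bases protonated at N9 (purines) or N1 (pyrimidines).

Hydrogens are added from ideal template geometries by superposing each
parent atom's local frame; histidine is protonated on N-epsilon, guanine
carries its N1 imino hydrogen (never N3), and G/C are keto, A/T amino
tautomers.  Total monomer charges are exactly +1 e (Arg, Lys), -1 e (Asp,
Glu, dNMPs) or 0 e (everything else), enforced by splitting the residual
charge symmetrically over the specially added hydrogens.

### The packaged parameter set

No external force-field files are read; the package ships its own compact
parameter set in the Amber functional form, generated reproducibly by the
scripts under `data-raw/`:

* *Geometry and bond graphs* come from the PDB Chemical Component
  Dictionary ideal coordinates.
* *Partial charges* use a bond-increment scheme: every bond moves a fixed
  increment of charge from the less to the more electronegative atom (e.g.
  0.42 e along N-H, 0.46 e along O-H, 0.60 e along C=O; pyridine-type ring
  nitrogens draw a full ring increment while substituted ring nitrogens are
  treated as saturated), formal charges are added on top, and chemically
  equivalent atoms are averaged.  The increments were calibrated so that
  hydrogen-bonding groups carry polar magnitudes comparable to published
  protein/nucleic-acid force fields (amide H about +0.42 e, carbonyl O
  about -0.55 e, ring N about -0.6 e); with them a canonical
  asparagine-adenine bidentate dimer scores about -26 kJ/mol in vacuum,
  in the range expected for that motif.  Totals are integral by
  construction.
* *Lennard-Jones* constants are the standard published Amber94 atom-class
  values (combination rules: arithmetic sigma, geometric epsilon); 1-4
  pairs are scaled by 1/1.2 (Coulomb) and 1/2 (Lennard-Jones); there is no
  cutoff.
* *Bonded terms* are harmonic bonds and angles with equilibrium values
  taken from the ideal template geometry and generic force constants
  (350000 kJ/mol/nm^2 for X-H bonds, 250000 otherwise; 418.4 kJ/mol/rad^2
  for angles).  Because heavy atoms are frozen during minimisation and
  intramolecular terms cancel in the supermolecular difference, the results
  are insensitive to these constants.  Periodic torsions are assigned only
  to hydrogen rotors: a strong 2-fold planar term (25 kJ/mol) keeps
  hydrogens on sp2 nitrogens (amides, guanidinium, ring N-H, base amino
  groups) in plane, and a weak 3-fold term (1.5 kJ/mol) restrains sp3
  rotors.  Without the planar terms a minimiser could rotate any amide
  hydrogen toward any nearby acceptor, which real amides cannot do.
* *Generalized-Born parameters* are the standard HCT/mbondi intrinsic
  radii and screening factors with a 0.09 A offset.
* *Motif templates* (the canonical Asn/Gln-adenine and Arg-guanine
  Hoogsteen arrangements plus a generic single-hydrogen-bond serine pose)
  are first docked geometrically against the ideal base and then refined
  to the packaged force field's own rigid-body energy optimum, so that a
  planted pose sits at a smooth minimum rather than on a repulsive wall.

### Energetics

`potential_energy()` evaluates the Amber-form terms with the electrostatic
constant 138.935485 kJ mol^-1 nm e^-2.  In media with relative permittivity
4, 16 or 80 the Hawkins-Cramer-Truhlar generalized-Born polar term (solute
dielectric 1, the permittivity entering only as the solvent dielectric --
the vacuum Coulomb term is never scaled) and an ACE-type nonpolar term
proportional to an analytic per-atom surface-area estimate (surface tension
2.05 kJ/mol/nm^2) are added.  `minimize_hydrogens()` relaxes hydrogen
positions by Polak-Ribiere conjugate gradients with heavy atoms frozen
bit-identically, stopping at a maximum force of 10 kJ/mol/nm or 400
iterations (both unstated in the source protocol and exposed as
parameters).  `interaction_energy()` implements the supermolecular
protocol: relax the dimer's hydrogens, single-point the dimer, split it,
single-point each monomer in the dimer conformation, relax each monomer
alone, and combine with the monomer deformation energies; algebraically the
result equals dimer energy minus the self-relaxed monomer energies, and
both routes are computed and compared in the tests.

### Specificity

For each distribution a Freedman-Diaconis histogram (bin width
`2 IQR n^(-1/3)`, midpoint-interpolated quartiles; a constant sample falls
back to a single bin and a zero-IQR sample to the Sturges bin count) is
overlaid with the histogram of the cluster with the lowest mean energy on
the same bin boundaries (`build_profile()`).  `classify_edge()` assigns
each dimer the base edge holding the plurality of its base-side contact
atoms (packaged edge atom sets; the shared C6/C4 substituent breaks ties
toward the Hoogsteen set for purines and Watson-Crick for pyrimidines),
`phosphate` for backbone-only contacts, and `stacking` when the base is
contacted without any donor-acceptor pair within 3.5 A and the contact
centroid sits at least 2.5 A out of the base plane.  The four criteria are
then, per medium (`evaluate_specificity()`):

1. the arrangement must lie within a geometrical cluster;
2. that cluster must be attractive (mean below zero) and the most
   stabilising cluster of its distribution;
3. little else may populate the cluster's energy span: the overlap
   fraction (non-cluster dimers inside the span over them plus the cluster
   size) must not exceed 0.3;
4. the cluster mean must be lower, signed, than the energy of *any*
   contact of the same amino acid with any other base at the same edge --
   by at least 4 kJ/mol for a *strong* verdict, by any margin for an
   *ambiguous* one.

The overlap threshold, margin, and the minimum-over-rivals comparison
statistic are operational constants for the qualitative "little to no other
contacts" and "lower than any" requirements; all are configurable, and a
robust alternative to the minimum (a low percentile) can be substituted by
the user on the tidy `dimer_table`.

## The synthetic-data module

Because no structure archive is bundled, every stage is exercised on
synthetic fixtures with known ground truth:

* `build_bdna_duplex()` places a packaged fiber-style nucleotide template
  (bases pinned analytically in the standard base-pair reference frame,
  backbone closed torsionally) with a twist of 36 degrees and rise of
  3.38 A per step; 5'-terminal residues lack their phosphate;
* `generate_complex_fixture()` writes a legal PDB document with REMARK 2/3
  metadata, the duplex, side chains planted in packaged motif geometries
  perturbed by rigid-body Gaussian noise, background side chains in random
  non-repeating orientations in contact with randomly chosen bases, and
  far-away stub residues giving each protein chain a distinct sequence;
* `generate_pose_distribution()` emits reference-atom pose sets with
  planted dense groups and isolated background poses;
* `generate_homolog_family()` mutates a protein sequence to prescribed
  global-alignment identities under a substitution-only model.

Default study conditions used by the end-to-end suites: planted-pose noise
0.15 A (the rigid-body component of coordinate uncertainty at ~2 A
resolution), background poses anchored 3.4-4.2 A from a base atom, about
one planted copy and two background poses per fixture, and fixture DNA
sequences that vary the planted base's neighbours.  The neighbour variety
matters: a side chain hydrogen-bonding one base also touches the stacked
neighbours, and if every fixture used the same sequence those incidental
contacts would accumulate into a spurious conserved cluster on the
neighbouring base -- an artefact that the sequence diversity of real
structure archives suppresses automatically.

What the fixtures do *not* emulate: real protein folds and backbone
context, water-mediated contacts, DNA deformation, crystallographic noise
beyond rigid pose perturbation, and the long tail of interface geometries
present in real archives.  A passing end-to-end suite therefore shows that
the machinery recovers what was planted under realistic geometric and
energetic conditions, not that any particular biological motif inventory is
reproduced; the headline dataset counts of the original study depend on a
specific archive snapshot and are out of scope here.

## Numerical choices and degenerate inputs

* Superposition uses the SVD construction with a determinant guard (never
  a reflection) and rejects collinear point sets.
* The O3' construction rejects a phosphorus within 1e-6 A of the oxygen
  plane.
* Pose-noise perturbation refits the exact internal geometry rigidly onto
  the noisy cloud, so chemistry is never distorted.
* The conjugate-gradient line search backtracks with an Armijo condition;
  a non-finite energy aborts with the step number.
* Energy gradients are analytic-free: central differences at 2e-6 nm on
  the moving (hydrogen) coordinates only, which is robust for every term
  including the generalized-Born radii, and fast in compiled code.
* Histogram binning treats the right edge of the last bin as closed.
* Background-pose packing and homolog-family generation abort after a
  bounded number of rejection-sampling retries.

## Problem sizes in the shipped suites

The test and acceptance suites run at desk scale: nine-fixture end-to-end
studies (one planted motif each, two media), 100-spec clustering sweeps,
50-system brute-force energy comparisons up to 200 atoms, and 200
random alignment pairs up to length 8.  These sizes were chosen to give
each statistical claim enough replication while keeping a full run in the
minutes range on a single core.

## Known limitations

* The charge set, while calibrated to canonical H-bond energetics, is a
  bond-increment model; absolute interaction energies should be read as
  model energies, not transferable Amber energies.
* Only substitution mutations are modelled in homolog families, so very
  low identity targets (< 5 %) are rejected.
* Edge classification is heuristic for contacts spanning two edges; the
  plurality rule with fixed tie-breaks keeps it deterministic.
* The pipeline scores the stripped-base or the full-dNMP dimer set; mixed
  analyses should run the pipeline twice and compare tables.
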