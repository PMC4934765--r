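# basereadout

Energetic and geometric discovery of sequence-specific DNA base-readout
motifs from structures of protein–DNA complexes.

## The scientific problem

Some amino-acid side chains can tell DNA bases apart by the pattern of
hydrogen-bond donors and acceptors each base exposes in the grooves of the
double helix — the classical *direct readout*, e.g. the bidentate hydrogen
bond of an asparagine amide with the N7/N6 Hoogsteen edge of adenine.
`basereadout` implements a screen for such motifs that couples the two
signatures a genuine readout motif must show at once: geometric
conservation across unrelated proteins and distinctive energetic
favourability.

The pipeline, for a set of protein–DNA complex structures:

1. filters structures (resolution < 2.5 Å, R-factor ≤ 0.25, a duplex of
   ≥ 4 bp) and splits them into single-protein-chain entries, collapsing
   identical chains;
2. extracts every interacting amino acid–dNMP dimer with a van der Waals
   distance criterion (contact when *d* < r₁ + r₂ + 1.0 Å against the
   residue's reference atoms), discards 5′-terminal nucleotides, flags
   base-directed dimers and builds a backbone-stripped duplicate set;
3. optionally removes homologous entries (Needleman–Wunsch/BLOSUM62
   pairwise identity culling at 30/90/95/100 %);
4. superposes all dimers of one amino-acid × base type into a common base
   frame and finds recurrent side-chain poses by greedy clustering
   (neighbour RMSD over the three reference atoms < 1.5 Å, at most 6
   clusters);
5. scores every dimer with a supermolecular molecular-mechanics
   interaction energy
   E_int = E(dimer) − E(monA) − E(monB) + D_A + D_B,
   where hydrogens are relaxed by conjugate gradients with frozen heavy
   atoms and D_X are the monomer deformation energies — in vacuum and in
   generalized-Born (HCT) implicit solvent at ε = 4, 16 or 80;
6. builds Freedman–Diaconis interaction-energy profiles overlaying the
   lowest-lying cluster on the full distribution, classifies the contacted
   base edge (Hoogsteen / Watson–Crick / sugar / phosphate / stacking),
   and grades every (amino acid, base, edge, medium) combination against
   four criteria of specificity (in a cluster; attractive and lowest;
   little else in its energy span; lower than any contact with any other
   base at that edge).

A first-class synthetic-data module generates PDB fixtures with an
idealized B-DNA duplex, planted canonical motifs with controlled pose
noise, random background poses and controlled-identity sequence families,
so the whole pipeline is testable without downloading any structures.

## Worked example

```r
library(basereadout)

spec <- fixture_spec("GCGAGCGC",
  planted_motifs = list(list(motif = "asn_ade_hoogsteen", position = 4, sd = 0)),
  seed = 1)
pdb   <- generate_complex_fixture(spec)
rec   <- parse_structure(pdb, id = "demo")
rec
#> <structure_record> demo: 3 chain(s), 357 atoms; resolution 2 A, R-factor 0.2

entry <- make_entries(rec)
dimer <- Filter(function(d) d$nuc_type == "DA",
                find_contacts(rec, entry[1, ]))[[1]]
flag_base_directed(dimer)
#> <contact_dimer> demo A:ASN1 - X:DA4 [base-directed]
classify_edge(dimer)
#> [1] "hoogsteen"

system <- prepare_dimer(strip_to_base(dimer))
system
#> <prepared_system> 27 atoms (12 H), 27 bonds, total charge +0.000 e
interaction_energy(system, medium(4))[, 1:4]
#>    e_int e_dimer_opt e_a_dimerconf e_b_dimerconf
#> 1 -15.51     -518.46       -247.24       -255.31
```

The planted asparagine–adenine bidentate dimer is recovered as a
base-directed Hoogsteen-edge contact, and its interaction energy in a
dielectric of 4 is −15.5 kJ/mol — attractive, and far below what random
contact poses reach (the components show the dimer and monomer
single-point energies and the ~0.2 kJ/mol hydrogen-relaxation deformation
terms).  `run_readout_pipeline()` chains all stages over many structures
and returns tidy `dimer_table` and `verdicts` tibbles; `autoplot()` draws
the energy-profile overlays and `tidy()`/`glance()` summarise fitted
studies.

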