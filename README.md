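# pairdex

Detection, protonation typing and canonical naming of nucleobase
homo-pairs in small-molecule crystal structures.

## What it does, and for whom

Crystals of free nucleobases (adenine, guanine, hypoxanthine, thymine,
uracil, cytosine) and their N1/N9 derivatives are full of base pairs —
planar dimers held by two or more hydrogen bonds across the Watson–Crick
(W), Hoogsteen (H) and Sugar (S) edges.  Because small-molecule structures
resolve hydrogen atoms, they reveal protonation states and hydrogen-bond
geometry far more precisely than nucleic-acid crystallography.  pairdex is
for structural chemists and RNA bioinformaticians who want to find, type
and count such pairs reproducibly:

* **recognition** of nucleobase moieties by element-coloured subgraph
  matching, with the survey's exclusion rules (substituents only at the
  glycosidic nitrogen, no metal coordination);
* **detection** of pairs under explicit criteria: donor⋯acceptor within
  the Bondi van der Waals sum + 1 Å, the D⋯A vector within 45° of both
  ring planes, D–H⋯A ≥ 120° when hydrogen is modelled, at least two bonds;
* **protonation and charge**: pattern strings such as `1H 3 7 9R`
  (N1-protonated N9-derivative of a purine), with formal charge = observed
  ring N–H minus the neutral reference (`1H 3 7 9H` adenine is +1,
  `1 3H` thymine is −1), and honest `R?` / `No R?` labels when hydrogens
  were not determined;
* **naming**: canonical atom-level names, `AA_fWH_(16)(67)` = two adenines,
  second base flipped, W edge against H edge, bonds N1⋯N6 and N6⋯N7; the
  orientation letter maps to Leontis–Westhof strand orientation (`f` ↔
  *cis*, `m` ↔ *trans*);
* **crystallography**: small-molecule CIF (cell, symmetry operators,
  disorder, explicit bond tables) and PDB input, whole-molecule symmetry
  expansion and duplicate collapse;
* **survey statistics**: refcode-family deduplicated frequencies,
  protonation cross-tabs, category percentages and hydrogen-bond geometry
  summaries, plus a bundled transcription of the published per-type count
  tables;
* **synthetic fixtures**: an idealized-geometry builder that realizes all
  47 catalogued homo-pair types for ground-truth testing.

## Worked example

```r
library(pairdex)

s  <- build_pair("AA_fWH_(16)(67)")   # idealized N9-methyladenine dimer
pr <- detect_pairs(s)[[1]]
pr
#> <base_pair> AA_fWH_(16)(67)  (2 H-bonds, interplanar 0.0 deg, C1'...C1' 11.51 A)

pair_geometry(pr)$bonds
#>   n1 n2   class d_a   d_h      h_a      dha
#> 1  1  6 N-H...N 2.9 1.009 1.901009 170.0111
#> 2  6  7 N-H...N 2.9 1.009 2.053128 140.0581
```

The pair was rebuilt, re-detected and renamed to exactly the catalogue
name; both N–H⋯N bonds sit at the 2.9 Å target with neutron-normalized
hydrogen positions (D–H 1.009 Å) and donor angles well above the 120°
floor.  Survey arithmetic runs the same way from the bundled tables:

```r
tab <- tabulate_frequencies(printed_table_records(printed_tables())$records)
tab$totals["A"]                                    # 325 adenine pairs
percentage(tab, "UU_fWH_(34)(45)", "substituted")  # 51.72414 (the Calcutta pair)
```

A thin command line lives in `inst/cli/pairdex`
(`pairdex scan <files.cif>`, `pairdex bases`, `pairdex name`,
`pairdex fixtures`, `pairdex report`).

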