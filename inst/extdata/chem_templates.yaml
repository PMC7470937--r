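# Chemical knowledge shared by every pairdex module.
#
# Canonical interaction numbering: a digit in a pair name such as AA_(16)(67)
# refers to the "interaction atom" at that ring position -- the exocyclic
# heteroatom (amino N / carbonyl O) or methyl carbon when one is attached
# there, otherwise the ring atom itself.  Ring atoms are addressed by their
# position number ("1".."9"), exocyclic atoms by the position they hang off
# plus an "x" suffix ("6x" = adenine N6 amino, "2x" = guanine N2, ...).
#
# Edge membership (W = Watson-Crick, H = Hoogsteen, S = Sugar) is fixed by the
# full catalogue of observed pair names: purine C8 sits on both H and S,
# pyrimidine C6 on S.
bases:
  A:
    full_name: adenine
    kind: purine
    glycosidic: 9
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
      "7": "N"
      "8": C
      "9": "N"
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
      - ["4", "9"]
      - ["9", "8"]
      - ["8", "7"]
      - ["7", "5"]
    exocyclic:
      - {id: "6x", pos: "6", element: "N", kind: amino, label: N6}
    ch_positions: ["2", "8"]
    edges:
      W: [1, 2, 6]
      H: [6, 7, 8]
      S: [2, 3, 8, 9]
    neutral_nh:
      R: []
      free: [9]
  G:
    full_name: guanine
    kind: purine
    glycosidic: 9
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
      "7": "N"
      "8": C
      "9": "N"
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
      - ["4", "9"]
      - ["9", "8"]
      - ["8", "7"]
      - ["7", "5"]
    exocyclic:
      - {id: "2x", pos: "2", element: "N", kind: amino, label: N2}
      - {id: "6x", pos: "6", element: O, kind: carbonyl, label: O6}
    ch_positions: ["8"]
    edges:
      W: [1, 2, 6]
      H: [6, 7, 8]
      S: [2, 3, 8, 9]
    neutral_nh:
      R: [1]
      free: [1, 9]
  Hx:
    full_name: hypoxanthine
    kind: purine
    glycosidic: 9
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
      "7": "N"
      "8": C
      "9": "N"
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
      - ["4", "9"]
      - ["9", "8"]
      - ["8", "7"]
      - ["7", "5"]
    exocyclic:
      - {id: "6x", pos: "6", element: O, kind: carbonyl, label: O6}
    ch_positions: ["2", "8"]
    edges:
      W: [1, 2, 6]
      H: [6, 7, 8]
      S: [2, 3, 8, 9]
    neutral_nh:
      R: [1]
      free: [1, 9]
  T:
    full_name: thymine
    kind: pyrimidine
    glycosidic: 1
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
    exocyclic:
      - {id: "2x", pos: "2", element: O, kind: carbonyl, label: O2}
      - {id: "4x", pos: "4", element: O, kind: carbonyl, label: O4}
      - {id: "5x", pos: "5", element: C, kind: methyl, label: C7}
    ch_positions: ["6"]
    edges:
      W: [2, 3, 4]
      H: [4, 5]
      S: [1, 2, 6]
    neutral_nh:
      R: [3]
      free: [1, 3]
  U:
    full_name: uracil
    kind: pyrimidine
    glycosidic: 1
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
    exocyclic:
      - {id: "2x", pos: "2", element: O, kind: carbonyl, label: O2}
      - {id: "4x", pos: "4", element: O, kind: carbonyl, label: O4}
    ch_positions: ["5", "6"]
    edges:
      W: [2, 3, 4]
      H: [4, 5]
      S: [1, 2, 6]
    neutral_nh:
      R: [3]
      free: [1, 3]
  C:
    full_name: cytosine
    kind: pyrimidine
    glycosidic: 1
    ring:
      "1": "N"
      "2": C
      "3": "N"
      "4": C
      "5": C
      "6": C
    ring_bonds:
      - ["1", "2"]
      - ["2", "3"]
      - ["3", "4"]
      - ["4", "5"]
      - ["5", "6"]
      - ["6", "1"]
    exocyclic:
      - {id: "2x", pos: "2", element: O, kind: carbonyl, label: O2}
      - {id: "4x", pos: "4", element: "N", kind: amino, label: N4}
    ch_positions: ["5", "6"]
    edges:
      W: [2, 3, 4]
      H: [4, 5]
      S: [1, 2, 6]
    neutral_nh:
      R: []
      free: [1]

params:
  da_margin: 1.0          # D...A accepted within vdW(D)+vdW(A)+da_margin  [Angstrom]
  plane_angle_max: 45.0   # max angle between D...A vector and either base plane [deg]
  dha_min: 120.0          # min D-H...A angle when H is modelled [deg]
  covalent_tolerance: 0.4 # bond inference slack on covalent radius sums [Angstrom]
  min_hbonds: 2           # hydrogen bonds required to call a base pair
  contact_radius: 6.0     # symmetry-expansion envelope [Angstrom]
  # Bondi van der Waals radii [Angstrom]
  vdw_radii:
    H: 1.20
    C: 1.70
    "N": 1.55
    O: 1.52
    F: 1.47
    P: 1.80
    S: 1.80
    Cl: 1.75
    Br: 1.85
    I: 1.98
  # Covalent radii for bond inference [Angstrom]
  covalent_radii:
    H: 0.31
    B: 0.84
    C: 0.76
    "N": 0.71
    O: 0.66
    F: 0.57
    Na: 1.66
    Mg: 1.41
    Si: 1.11
    P: 1.07
    S: 1.05
    Cl: 1.02
    K: 2.03
    Ca: 1.76
    Mn: 1.39
    Fe: 1.32
    Co: 1.26
    Ni: 1.24
    Cu: 1.32
    Zn: 1.22
    Br: 1.20
    Ru: 1.46
    Pd: 1.39
    Ag: 1.45
    Cd: 1.44
    I: 1.39
    Pt: 1.36
    Au: 1.36
    Hg: 1.32
    Pb: 1.46
  # Averaged D-H bond lengths from neutron diffraction, used to normalize
  # X-ray hydrogen positions [Angstrom]
  neutron_dh:
    C: 1.083
    "N": 1.009
    O: 0.983
  # Elements allowed to bond a nucleobase atom without triggering the
  # organometallic exclusion
  nonmetals: [H, C, "N", O, P, S, F, Cl, Br, I]
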