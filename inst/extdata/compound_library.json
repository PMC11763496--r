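[
  {
    "name": "gulypyrone B",
    "nominal_mass": 210,
    "formula": "C11H14O4",
    "source_taxon": "Diaporthe gulyae",
    "reference": "Andolfi et al., J. Nat. Prod. 2015",
    "note": "one of four Diaporthe compounds reported at nominal mass 210; only the named compound is carried, the mass ambiguity is noted here",
    "decoy": false
  },
  {
    "name": "gulypyrone A",
    "nominal_mass": 212,
    "formula": "C11H16O4",
    "source_taxon": "Diaporthe gulyae",
    "reference": "Andolfi et al., J. Nat. Prod. 2015",
    "decoy": false
  },
  {
    "name": "nectriapyrone",
    "nominal_mass": 194,
    "formula": "C11H14O3",
    "source_taxon": "Diaporthe angelicae (Phomopsis foeniculi)",
    "reference": "Evidente et al., J. Agric. Food Chem. 2011",
    "decoy": false
  },
  {
    "name": "multiplolide A",
    "nominal_mass": 214,
    "formula": "C10H14O5",
    "source_taxon": "Diaporthe sp. JC-J7",
    "reference": "Hu et al., Nat. Prod. Res. 2020",
    "decoy": false
  },
  {
    "name": "diaporol R",
    "nominal_mass": 236,
    "formula": "C15H24O2",
    "source_taxon": "Diaporthe sp. (Rhizophora stylosa)",
    "reference": "Zhang et al., Tetrahedron 2014",
    "decoy": false
  },
  {
    "name": "diaporol S / 3beta-hydroxyconfertifolin",
    "nominal_mass": 250,
    "formula": "C15H22O3",
    "source_taxon": "Diaporthe sp. (Rhizophora stylosa)",
    "reference": "Zhang et al., Tetrahedron 2014",
    "note": "stereoisomer pair sharing nominal mass 250",
    "decoy": false
  },
  {
    "name": "4-ethyltetrahydro-3-methyl-5-propyl-2,3-furandiol",
    "nominal_mass": 188,
    "formula": "C10H20O3",
    "source_taxon": "Diaporthe sp. XZ-07",
    "reference": "Cao et al., Nat. Prod. Res. 2021",
    "decoy": false
  },
  {
    "name": "dihydro-5-[5-(1-hydroxyethyl)furan-2-yl]-2(3H)-furanone",
    "nominal_mass": 196,
    "formula": "C10H12O4",
    "source_taxon": "Diaporthe sp. XZ-07",
    "reference": "Cao et al., Nat. Prod. Res. 2021",
    "decoy": false
  },
  {
    "name": "diaporthelactone",
    "nominal_mass": 206,
    "formula": "C11H10O4",
    "source_taxon": "Diaporthe sp. HLY2",
    "reference": "Lin et al., J. Chem. Res. 2005",
    "decoy": false
  },
  {
    "name": "diaportheone A",
    "nominal_mass": 218,
    "formula": "C12H10O4",
    "source_taxon": "Diaporthe sp. P133",
    "reference": "Bungihan et al., J. Nat. Med. 2011",
    "decoy": false
  },
  {
    "name": "phomolide G",
    "nominal_mass": 244,
    "source_taxon": "Diaporthe terebinthifolii GG3F6",
    "reference": "Santos et al., 2016",
    "note": "molecular formula pending literature verification",
    "decoy": false
  },
  {
    "name": "phomolide C",
    "nominal_mass": 342,
    "source_taxon": "Diaporthe sp. 1308-05",
    "reference": "Yang et al., 2010",
    "note": "molecular formula pending literature verification",
    "decoy": false
  },
  {
    "name": "volemolide",
    "nominal_mass": 346,
    "source_taxon": "Diaporthe sp. LG23",
    "reference": "Li et al., 2015",
    "note": "molecular formula pending literature verification",
    "decoy": false
  },
  {
    "name": "decoy-400",
    "nominal_mass": 400,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-403",
    "nominal_mass": 403,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-420",
    "nominal_mass": 420,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-423",
    "nominal_mass": 423,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-435",
    "nominal_mass": 435,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-440",
    "nominal_mass": 440,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-444",
    "nominal_mass": 444,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-450",
    "nominal_mass": 450,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-455",
    "nominal_mass": 455,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-460",
    "nominal_mass": 460,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-464",
    "nominal_mass": 464,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-480",
    "nominal_mass": 480,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-485",
    "nominal_mass": 485,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-520",
    "nominal_mass": 520,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-525",
    "nominal_mass": 525,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-550",
    "nominal_mass": 550,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-560",
    "nominal_mass": 560,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-565",
    "nominal_mass": 565,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-600",
    "nominal_mass": 600,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-620",
    "nominal_mass": 620,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-650",
    "nominal_mass": 650,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  },
  {
    "name": "decoy-660",
    "nominal_mass": 660,
    "source_taxon": "synthetic decoy",
    "reference": "synthetic record at a mass absent from the study's ion sets",
    "decoy": true
  }
]
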