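# inchikit

Layered canonical chemical-structure identifiers and their 27-character
hashed keys, implemented in R.

Registry numbers and names cannot tell two databases whether they hold
the same compound; a *structure-based* identifier can, but only if every
reasonable drawing of one substance — resonance forms, tautomers,
protonation states, isotopologues, metal-bonding conventions — collapses
to one string. `inchikit` is for cheminformaticians and tool builders who
want that normalization-plus-canonicalization pipeline as an inspectable,
tested R package: molfile/SD input, a neutral tautomer-merged *core
parent structure*, canonical atom numbers, layer-by-layer serialization,
and a fixed-length hashed key for indexing and web search.

## What it computes

For an input structure the pipeline produces

```
InChI=1S/<formula>/c<connections>/h<hydrogens>[/q±n][/p±n]
        [/b.../t.../m0|1/s1][/i...][/f...][/r...]
```

* **Normalization** — drawing corrections, salt and metal disconnection,
  kekulization, and proton transfer until the parent is neutral; mobile
  hydrogens are detected from donor/acceptor patterns `M=Q–ZH`
  (M, Z ∈ {N, O, S, Se, Te}) merged across conjugated systems and stored
  as groups, never positions.
* **Canonical numbering** — atoms colored by (element, connectivity),
  then the exact lexicographic minimum of the flattened connection-table
  code over all consistent numberings, refined stage by stage with the
  hydrogen list, the mobile-group list and the isotopic weights
  `nH1 + 32(nH2 + 32(nH3 + 32·shift))`. The surviving numberings form the
  automorphism group used for equivalence classes and stereo.
* **Stereo perception** — tetrahedral parities as signs of oriented
  tetrahedron volumes (2D wedges lifted 45°, or 3D coordinates),
  double-bond cis/trans from geometry (never inside rings smaller than
  8), canonical parity lists minimized over the automorphism group, and
  enantiomer selection against the mirror image (`/m`, `/s`).
* **Hashed key** — `AAAAAAAAAAAAAA-BBBBBBBBFV-P`: SHA-256 of the skeleton
  part truncated to 65 bits (14 base-26 letters), SHA-256 of the advanced
  layers truncated to 37 bits (8 letters), a standardness flag, version
  letter `A`, and a protonation flag letter.

## Worked example

```r
library(inchikit)

txt <- generate_fixture("guanine")   # a V2000 molfile, built in code
id  <- inchi(txt)
id$text
#> InChI=1S/C5H5N5O/c6-5-9-3-2(4(11)10-5)7-1-8-3/h1H,(H4,6,7,8,9,10,11)
make_key(id)$text
#> JZRNFSCGLQBXZY-PFSKNNIHSA-N
```

Reading the string: carbons are atoms 1–5, nitrogens 6–10, oxygen 11
(canonical numbers follow the formula's element order); `/c` walks the
purine skeleton; `/h` says atom 1 carries one immobile hydrogen while
four tautomeric hydrogens are shared by atoms 6–11. Because those four
hydrogens are mobile, every guanine tautomer yields this same string and
key. Asking for the fixed-hydrogen layer pins the drawn tautomer instead:

```r
inchi(txt, inchi_options(fixed_h = TRUE))$text
#> InChI=1/C5H5N5O/c6-5-9-3-2(4(11)10-5)7-1-8-3/h1H,(H4,6,7,8,9,10,11)/f/h8,10H,6H2
```

Stereochemistry, for one tartaric acid enantiomer drawn with wedges:

```r
inchi(fixture_molecule("tartaric-1"))$text
#> InChI=1S/C4H6O6/c5-1(3(7)8)2(6)4(9)10/h1-2,5-6H,(H,7,8)(H,9,10)/t1-,2-/m1/s1
```

A command-line wrapper is installed as `exec/inchikit`
(`inchikit ident file.sdf --FixedH`, `inchikit key`, `inchikit trace`,
`inchikit fixtures <dir>`).

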