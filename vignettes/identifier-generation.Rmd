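---
title: "How inchikit builds layered identifiers and hashed keys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How inchikit builds layered identifiers and hashed keys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inchikit)
```

## The model

`inchikit` assigns a chemical structure a layered, canonical line
notation and a 27-character hashed key. The central object is the *core
parent structure*: a neutral, tautomer-merged, metal-disconnected,
stereo-free and isotope-free archetype shared by a family of input
drawings. A molecule is modelled as a colored multigraph of skeletal
atoms; bonds are plain links (orders matter only during normalization,
never in the identifier), terminal hydrogens are per-atom counts in four
isotope classes (plain H, labelled protium, deuterium, tritium), and
formal charges are bookkeeping quantities that the normalized identifier
only retains as a per-component net charge.

The identifier describes the input as the parent plus deviations, one
layer per aspect: Hill formula, skeletal connections `/c`, hydrogens
`/h` (immobile positions, then mobile groups), net charge `/q`, protons
added or removed `/p`, double-bond and tetrahedral stereo `/b /t /m /s`,
isotopes `/i`, drawn tautomer-hydrogen positions `/f`, and reconnected
metal bonds `/r`. Mesomeric drawings, tautomers and protonation states of
one substance therefore share their standard layers by construction.

## Normalization

Normalization applies, in order: a fixed repertoire of drawing
corrections (charge moved off hydrogens, 1,3 charge-separated patterns
neutralized, oxoanion charges moved to terminal oxygens, carbocation plus
amine fused to an iminium bond, and adjacent opposite charges annihilated
into a higher standard valence, which normalizes charge-separated nitro
groups); disconnection of simple metal–halide salts (the halide takes a
negative charge, the metal a positive one; `H4N–X` splits into ammonia
and `HX`); disconnection of every remaining bond to a metal, with charges
transferred to the metal where a standard valence permits and the
original bonding kept for `/r`; kekulization of aromatic input bonds by a
matching search plus cancellation of adjacent doublet radicals; and
proton normalization toward zero net charge.

Proton removal first takes protons from positively charged N/P/O/S/Se/Te
bearing hydrogens, then rearranges alternating single/double bond paths
to expose concealed protons (a hydrogen-bearing heteroatom donates along
a path ending at the charged atom, or at a double-bonded chalcogen
receiver that is then deprotonated). Proton addition neutralizes acid
anions. Two additions go beyond the patterns usually quoted for this
step: bare halide/chalcogenide anions, and oxoacid anions whose central
atom carries a double-bonded terminal chalcogen (phosphates, sulfonates).
Both are required to reproduce the expected identifiers for chloride and
for triphosphates, and are best understood as part of the same
neutralization principle.

Mobile hydrogens are detected from donor/acceptor patterns `M=Q–ZH`
(M, Z one of N(III), O(II), S(II), Se(II), Te(II); Q one of C, N, S, P,
Sb, As, Se, Te, Br, Cl, I; the hydrogen may be a shared negative charge
instead). The `=` bond may be a true double bond, a bond already marked
tautomeric, or a single bond that an alternating-bond rearrangement of
the conjugated system could make double; the rearrangement test lets
current group members release or absorb one hydrogen, which is what
merges, say, the six heteroatoms of guanine into one group of four shared
hydrogens. Overlapping matches are unioned; members lose their hydrogens
and shared negative charges to the group. Groups holding only negative
charges are dropped from the identifier. Positive charges on N/P moving
along alternating paths mark those bonds changeable, which excludes them
from double-bond stereo.

## Canonical numbering

Atoms are first colored by (element precedence, number of connections),
element precedence being carbon, then other elements alphabetically,
then bridging hydrogen; colors are kept in cumulative form (each color
equals the number of atoms with that or a smaller color). The canonical
numbering minimizes the flattened connection-table code — one segment
per color holding the color and its ascending smaller-colored neighbors
— and then, among code minimizers, successively minimizes the immobile
hydrogen list, the mobile-group list, the isotopic weight list
(`iso_weight = nH1 + 32(nH2 + 32(nH3 + 32·shift))`, shift incremented
when non-negative so that zero is reserved for unlabelled atoms, and a
large sentinel for unlabelled atoms so labels attract small numbers),
and, for the fixed-hydrogen layers, the drawn hydrogen counts and drawn
isotopic weights. Each stage's optimal numberings are a subset of the
previous stage's, and the surviving set at each stage is exactly the
automorphism group of everything minimized so far, which later feeds the
stereo minimization and the printed equivalence classes.

Two design points deserve explanation because the design was genuinely
open:

* **The minimum is exact.** Equitable-partition refinement with
  individualization (the classical approach, exposed as
  `refine_equitable()`/`individualize()` and used by `stage_trace()` for
  the worked-example view) reaches a canonical labelling, but the
  ordering imposed by refinement does not always contain the
  lexicographically smallest code: an eight-atom S/N chain is enough to
  make them differ. `inchikit` defines canonicality as the exact minimum
  over all numberings consistent with the initial invariant and computes
  it with a branch-and-bound search (compiled code): colors are assigned
  in invariant-block order, partial codes prune the tree, and structural
  twins (atoms with identical neighborhoods) are descended once and
  restored afterwards by closing the minimizer set under twin
  transpositions. This keeps the result identical to an exhaustive
  enumeration while staying fast for chemical graphs. For the same
  reason, re-seeding the search with equivalence-class colors (a
  classical efficiency device) is omitted: it can reorder interleaved
  orbits and would change the result away from the exact minimum.
* **Mobile groups join as comparison lists, not pseudoatoms.** Groups
  enter the minimization as sorted member-color lists plus hydrogen and
  charge counts. This has the same discriminating power as attaching
  directed pseudo-edges, without touching the real connection table.

A configurable node budget (2e7 nodes) guards against pathological
symmetric inputs; exceeding it raises an error rather than returning a
silently wrong numbering.

## Stereochemistry

Tetrahedral candidates are 4-coordinate C/Si/Ge, charged 4-coordinate N,
P/As with three or four single bonds (phosphines stay stereogenic even
with a hydrogen), and S/Se with three connections and one double-bonded
terminal chalcogen (the lone pair is the fourth apex, ranked below
hydrogen). Centers with two hydrogens of one class are skipped, as are
N/S/Se centers with a terminal H neighbor or two `-XH` terminal
neighbors. Neutral 3-coordinate nitrogen is never treated as stereogenic
(pyramidal inversion); this is a simplification relative to bridgehead
special cases. In 2D, all bonds are normalized to unit length and wedge
wide-ends lifted (up) or lowered (down) by 45°; by default only wedges
whose narrow end sits at the evaluated center act on it, while the
two-atom interpretation is available as an option. In 3D, coordinates are
used directly and up/down wedges ignored; wavy bonds always force
"unknown". Parity is the sign of the oriented tetrahedron volume viewed
from the lowest-ranked apex; a single missing apex (implicit hydrogen or
lone pair) is reconstructed antipodally; degenerate geometry (volume
below 1e-6 of unit scale) leaves the parity undefined with a warning.

Double bonds and three-bond cumulenes between C/N atoms are candidates
when rigid: tautomeric and charge-changeable bonds are excluded, as are
double bonds in rings of fewer than 8 atoms. Parity compares the sides of
the higher-numbered single-bond neighbor at each end (same side: `-`).
Allenes (two cumulated double bonds) are tetrahedral-class elements whose
apices are the four end substituents; in 2D their configuration must be
wedged at one allene end.

Parities are evaluated under every numbering that survived the
constitution stages, and the mapping minimizing (double-bond list, allene
list, tetrahedral list; parity order `-` < `+` < `?` < `u`) is kept.
Elements whose parity an automorphism can flip in isolation are removed
as pseudo-stereogenic (at most two at a time, iterated). The mirror image
is then processed identically; the smaller record wins, `/m` records
whether inversion was chosen, and `/s1` marks absolute stereochemistry.
Relative and racemic interpretations drop `/m` and print `/s2`/`/s3`
(the racemic value extrapolates the flag sequence; only the absolute and
relative values are fixed by convention). If inversion changes nothing
the structure is achiral and no `/m`/`/s` appear. Undefined and unknown
parities both print as `?` unless the dedicated option distinguishes
them, and stereo layers are omitted entirely when no defined parity
exists (unless always-show is requested).

## Serialization and the hashed key

Within each component, `/c` is a depth-first walk from the
smallest-numbered terminal atom, always descending to the smallest
unvisited neighbor; ring closures are emitted where first met; at each
atom, branch subtrees are parenthesized together (shortest first, ties by
smaller head number) and the longest continues the chain. This traversal
reproduces the reference connection strings for every conformance
fixture. Components are ordered by a frozen tuple — carbon-containing
first, more atoms first, then ascending formula and payload strings —
and identical components collapse to a formula multiplier (`2CH4`) with
`n*payload` abbreviations in the other layers. `/q` is per-component,
`/p` is the total proton count. The hydrogen-range syntax uses maximal
runs (`1-2,5-6H`); mobile groups sort by hydrogen count, then members.

The key hashes two parts of the identifier with SHA-256: the skeleton
part (formula, `/c`, `/h`) truncated to 65 bits becomes the 14-letter
first block, everything after the protonation layer truncated to 37 bits
becomes the 8-letter second block (base-26, `A` = 0, zero-padded), and
`/p` itself is not hashed but mapped to the final flag letter (`N`
neutral, `O`..`Z` for +1..+12, `M`..`B` for −1..−12, `A` beyond; the
positive/negative letter ranges reconstruct a convention whose table is
not printed in full anywhere, and are fixed by the neutral letter, the
single-character-difference property and the ±12 breakdown). Birthday
arithmetic on those widths gives the collision figures the package
reports: a 1.3% chance of a first-block collision among 10^9 compounds
and expected first collisions near `sqrt(2^65)` ≈ 6.1e9 skeletons and
`sqrt(2^37)` ≈ 3.7e5 isomers per skeleton.

## What the random generator emulates

`random_molecule()` drives the property suites: connected skeletons of
up to 12 atoms over C/N/O/S/Cl grown as random trees with occasional ring
closures, double/triple bonds placed only where standard valences permit,
at most one charged site (a protonated nitrogen or an alkoxide-like
oxygen), and occasional isotopic labels. It deliberately emulates small
organic structures with a single, unambiguous protonation event; it does
not emulate polyions with competing deprotonation sites (where the
reference rule set needs its full ambiguity resolution), organometallics,
or macrocycles. Passing the permutation-invariance and oracle suites
therefore demonstrates correctness of canonicalization, serialization and
hashing on ordinary covalent chemistry, not coverage of the full
normalization rule inventory.

Problem sizes used by the shipped suites: the exhaustive-oracle check
compares 500 random components of at most 8 atoms against an all-`n!`
enumeration; input-order invariance is verified on 1000 random molecules
under 20 random atom permutations each; rotation invariance uses 100
random proper rotations. These sizes give the brute-force oracle exact
coverage while keeping the whole suite in the minutes range.

## Known limitations

* Hard proton *addition* along alternating paths is not implemented;
  simple addition plus the oxoacid-anion rule covers common acids.
* The `/f` layer carries its own formula, hydrogen, charge and isotope
  sublayers but not a recomputed stereo sublayer, and no transposition
  map is emitted when the fixed-H numbering departs from the mobile-H
  numbering.
* Extended stereo (atropisomers, square-planar or octahedral metal
  centers) is out of scope, as is any auxiliary-information output or
  back-conversion from an identifier to a structure.
* Exact agreement with the reference numbering is asserted on the
  conformance fixtures; for structures where the refinement-ordered
  labelling of the reference differs from the exact code minimum (rare,
  but real), this package prints the exact minimum.

## A worked example

```{r example}
txt <- generate_fixture("guanine")
id <- inchi(txt, inchi_options(fixed_h = TRUE))
id$text
make_key(id)$text
```

The `/h` layer shows one immobile hydrogen on atom 1 and four hydrogens
shared by the six heteroatoms; the `/f` layer pins them to the drawn
9H-tautomer.
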