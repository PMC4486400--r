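Package: inchikit
Title: Layered Canonical Chemical Identifiers and Hashed Compact Keys
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Generates layered, canonical line-notation identifiers for
    chemical structures read from V2000 molfiles or SD files, together with
    their 27-character hashed compact keys. Input structures are normalized
    to a neutral, tautomer-merged, metal-disconnected core parent structure;
    atoms are numbered by a staged McKay-style canonical labelling
    (equitable partition refinement with individualization and automorphism
    detection); tetrahedral, double-bond and allene stereo parities are
    perceived from 2D wedge marks or 3D coordinates and canonicalized; and
    the result is serialized layer by layer (formula, connections,
    hydrogens, charge, protonation, stereo, isotopes, fixed hydrogens,
    reconnected metals). Compact keys are derived from truncated SHA-256
    hashes in a base-26 alphabet, with birthday-bound collision analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    openssl,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
NeedsCompilation: yes
Config/testthat/edition: 3
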