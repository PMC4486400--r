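# Molecular data model, molfile round trips, valence schema, formulas.

test_that("molfile reading maps fields and folds terminal hydrogens", {
  txt <- generate_fixture("2-chlorobutane")
  m <- read_molfile(txt)
  expect_equal(n_atoms(m), 5L)
  expect_equal(nrow(m$bonds), 4L)
  expect_equal(sort(m$atoms$element), c("C", "C", "C", "C", "Cl"))

  # single-atom methane
  mm <- read_molfile(generate_fixture("methane"))
  expect_equal(n_atoms(mm), 1L)
  expect_equal(nrow(mm$bonds), 0L)

  # charge via M CHG
  cl <- read_molfile(generate_fixture("chloride-anion"))
  expect_equal(cl$atoms$charge, -1L)
  expect_match(generate_fixture("chloride-anion"), "M  CHG", fixed = TRUE)

  # V3000 rejected, malformed counts rejected
  bad <- c("", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000")
  expect_error(read_molfile(bad), "V3000")
  expect_error(read_molfile(c("", "", "", "ABC")), "counts")
})

test_that("molfile writing round-trips every fixture molecule", {
  for (nm in fixture_names()) {
    m <- fixture_molecule(nm)
    m2 <- read_molfile(write_molfile(m))
    expect_equal(m2$atoms[, c("element", "charge", "radical", "mass",
                              "nH", "nH1", "nH2", "nH3")],
                 m$atoms[, c("element", "charge", "radical", "mass",
                             "nH", "nH1", "nH2", "nH3")],
                 info = nm)
    key <- function(b) paste(sort(paste(pmin(b$a, b$b), pmax(b$a, b$b),
                                        b$order)), collapse = "|")
    expect_equal(key(m2$bonds), key(m$bonds), info = nm)
  }
})

test_that("D and T atom symbols become isotopic hydrogen counts", {
  txt <- c("", "", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    0.0000    0.0000 D   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "M  END")
  m <- read_molfile(txt)
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$atoms$nH2, 1L)
})

test_that("implicit hydrogens reach the nearest higher standard valence", {
  m <- molecule(data.frame(element = c("C", "C")), data.frame(a = 1, b = 2))
  m <- add_implicit_hydrogens(m)
  expect_equal(m$atoms$nH, c(3L, 3L))

  # neutral N with bond-order sum 3 is not raised to the pentavalent state
  m <- molecule(data.frame(element = c("N", "C"), nH = c(1L, 3L)),
                data.frame(a = 1, b = 2, order = 2))
  expect_equal(add_implicit_hydrogens(m)$atoms$nH, c(1L, 3L))

  # neutral S with sum 3 is not raised to the tetravalent state
  m <- molecule(data.frame(element = c("S", "C"), nH = c(1L, 3L)),
                data.frame(a = 1, b = 2))
  expect_equal(add_implicit_hydrogens(m)$atoms$nH[1], 1L)

  # isolated sodium receives one hydrogen; iron receives none
  expect_equal(add_implicit_hydrogens(
    molecule(data.frame(element = "Na")))$atoms$nH, 1L)
  expect_equal(add_implicit_hydrogens(
    molecule(data.frame(element = "Fe")))$atoms$nH, 0L)

  # charge outside the schema: no hydrogens added
  expect_equal(add_implicit_hydrogens(
    molecule(data.frame(element = "Cl", charge = -1L)))$atoms$nH, 0L)

  # doublet radical reserves one valence
  expect_equal(add_implicit_hydrogens(
    molecule(data.frame(element = "C", radical = "doublet")))$atoms$nH, 3L)
})

test_that("Hill formulas follow carbon-hydrogen-alphabetical order", {
  cl <- add_implicit_hydrogens(fixture_molecule("methane"))
  expect_equal(hill_formula(cl), "CH4")
  # carbon-free: alphabetical with H in place
  m <- molecule(data.frame(element = "Cl", nH = 1L))
  expect_equal(hill_formula(m), "ClH")
  m <- molecule(data.frame(element = c("N", "O"), nH = c(2L, 1L)),
                data.frame(a = 1, b = 2))
  expect_equal(hill_formula(m), "H3NO")
  # count of one omits the digit; multi-element
  g <- fixture_molecule("guanine")
  expect_equal(hill_formula(g), "C5H5N5O")
})

test_that("formula and implicit-H total are invariant under atom order", {
  for (nm in c("guanine", "tartaric-1", "mobile-charge-a")) {
    m <- fixture_molecule(nm)
    f0 <- hill_formula(add_implicit_hydrogens(m))
    set.seed(11)
    for (r in 1:100) {
      mp <- permuted(m, sample(n_atoms(m)))
      expect_identical(hill_formula(add_implicit_hydrogens(mp)), f0)
    }
  }
})

test_that("connected components partition the bond graph", {
  expect_equal(length(unique(connected_components(
    normalize_structure(add_implicit_hydrogens(
      fixture_molecule("sodium-chloride")))$parent))), 2L)
  eth <- molecule(data.frame(element = c("C", "C"), nH = c(3L, 3L)),
                  data.frame(a = 1, b = 2))
  expect_equal(unique(connected_components(eth)), 1L)
  expect_equal(length(connected_components(
    molecule(data.frame(element = character(0))))), 0L)
})

test_that("multi-record SD files split on the record separator", {
  sdf <- paste0(generate_fixture("methane"), "$$$$\n",
                generate_fixture("chloride-anion"), "$$$$\n")
  recs <- read_sdf(sdf)
  expect_length(recs, 2L)
  expect_equal(recs[[2]]$atoms$element, "Cl")
})
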