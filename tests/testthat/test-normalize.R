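# Normalization: drawing fixes, disconnection, kekulization, protons,
# mobile hydrogen and mobile charge.

test_that("charge-separated drawings collapse to the neutral form", {
  a <- inchi(fixture_molecule("formamide"))$text
  b <- inchi(fixture_molecule("formamide-mesomer"))$text
  expect_identical(a, b)
  a <- inchi(fixture_molecule("nitromethane"))$text
  b <- inchi(fixture_molecule("nitromethane-mesomer"))$text
  expect_identical(a, b)
  # no matching pattern: methane unchanged
  m <- add_implicit_hydrogens(fixture_molecule("methane"))
  expect_identical(fix_drawing(m)$atoms, m$atoms)
})

test_that("salt disconnection splits metal halides and H4N-X", {
  nacl <- add_implicit_hydrogens(fixture_molecule("sodium-chloride"))
  d <- disconnect_salts(fix_drawing(nacl))
  expect_equal(nrow(d$bonds), 0L)
  expect_equal(sort(d$atoms$charge), c(-1L, 1L))

  nh4 <- add_implicit_hydrogens(fixture_molecule("ammonium-chloride"))
  d <- disconnect_salts(fix_drawing(nh4))
  expect_equal(nrow(d$bonds), 0L)
  expect_equal(d$atoms$charge, c(0L, 0L))
  expect_equal(inchikit:::total_H(d), c(3L, 1L))

  # sodium nitrate is not a simple salt; general metal disconnection
  # applies instead
  nan3 <- molecule(data.frame(element = c("Na", "O", "N", "O", "O")),
                   data.frame(a = c(1, 2, 3, 3), b = c(2, 3, 4, 5),
                              order = c(1, 1, 2, 2)))
  s <- disconnect_salts(fix_drawing(add_implicit_hydrogens(nan3)))
  expect_equal(nrow(s$bonds), 4L)  # untouched by the salt rule
  dm <- disconnect_metals(s)
  expect_equal(nrow(dm$disconnected$bonds), 3L)
  expect_equal(sum(dm$disconnected$atoms$charge), 0L)
  expect_equal(nrow(dm$reconnected$bonds), 4L)
})

test_that("metal disconnection removes every metal bond, keeps a copy", {
  fe <- molecule(data.frame(element = c("Fe", "C", "C"), nH = c(0, 3, 3)),
                 data.frame(a = c(1, 1), b = c(2, 3)))
  dm <- disconnect_metals(fe)
  expect_equal(nrow(dm$disconnected$bonds), 0L)
  expect_equal(nrow(dm$reconnected$bonds), 2L)
  # metal-free molecule passes through
  eth <- molecule(data.frame(element = c("C", "C"), nH = c(3, 3)),
                  data.frame(a = 1, b = 2))
  dm <- disconnect_metals(eth)
  expect_identical(dm$disconnected$bonds, eth$bonds)
})

test_that("aromatic input bonds are kekulized; radicals cancel", {
  benz <- molecule(data.frame(element = rep("C", 6), nH = rep(1L, 6)),
                   data.frame(a = 1:6, b = c(2:6, 1), order = 4L))
  k <- resolve_radicals_and_kekulize(benz)
  expect_setequal(unique(k$bonds$order), c(1L, 2L))
  expect_equal(sum(k$bonds$order == 2L), 3L)

  pyrrole <- molecule(
    data.frame(element = c("N", "C", "C", "C", "C"),
               nH = c(1L, 1L, 1L, 1L, 1L)),
    data.frame(a = 1:5, b = c(2:5, 1), order = 4L))
  k <- resolve_radicals_and_kekulize(pyrrole)
  expect_equal(sum(k$bonds$order == 2L), 2L)
  ndbl <- sum(k$bonds$order[k$bonds$a == 1L | k$bonds$b == 1L] == 2L)
  expect_equal(ndbl, 0L)  # the NH contributes the lone pair

  # odd unkekulizable system errors
  cp <- molecule(data.frame(element = rep("C", 5), nH = rep(1L, 5)),
                 data.frame(a = 1:5, b = c(2:5, 1), order = 4L))
  expect_error(resolve_radicals_and_kekulize(cp), "kekulize")

  rad <- molecule(data.frame(element = c("C", "C"), nH = c(2L, 2L),
                             radical = c("doublet", "doublet")),
                  data.frame(a = 1, b = 2))
  k <- resolve_radicals_and_kekulize(rad)
  expect_equal(k$bonds$order, 2L)
  expect_equal(unique(k$atoms$radical), "none")
})

test_that("proton normalization neutralizes and books the proton count", {
  r <- normalize_protons(molecule(data.frame(element = "Cl",
                                             charge = -1L)))
  expect_equal(r$p, -1L)
  expect_equal(r$parent$atoms$nH, 1L)
  expect_equal(r$parent$atoms$charge, 0L)

  r <- normalize_protons(molecule(data.frame(element = "H", charge = 1L)))
  expect_equal(r$p, 1L)
  expect_equal(n_atoms(r$parent), 0L)

  # ammonium cation: simple removal from the charged nitrogen
  r <- normalize_protons(molecule(data.frame(element = "N", charge = 1L,
                                             nH = 4L)))
  expect_equal(r$p, 1L)
  expect_equal(r$parent$atoms$nH, 3L)
})

test_that("charge bookkeeping: input charge equals q plus protons", {
  for (nm in c("chloride-anion", "proton", "lysine-zwitterion",
               "lysine-cation", "mobile-charge-a", "atp-32P-monoanion")) {
    m <- add_implicit_hydrogens(fixture_molecule(nm))
    input_q <- sum(m$atoms$charge)
    id <- inchi(m)
    expect_equal(id$q + id$p, input_q, info = nm)
  }
  for (s in 1:200) {
    m <- add_implicit_hydrogens(random_molecule(s))
    id <- inchi(m)
    expect_equal(id$q + id$p, sum(m$atoms$charge), info = paste("seed", s))
  }
})

test_that("mobile hydrogen groups match the tautomerism patterns", {
  g <- normalize_structure(add_implicit_hydrogens(
    fixture_molecule("guanine")))
  expect_length(g$groups, 1L)
  expect_equal(g$groups[[1]]$nH, 4L)
  expect_length(g$groups[[1]]$members, 6L)

  eth <- molecule(data.frame(element = c("C", "C"), nH = c(3L, 3L)),
                  data.frame(a = 1, b = 2))
  expect_length(detect_mobile_H(eth)$groups, 0L)

  u <- normalize_structure(add_implicit_hydrogens(fixture_molecule("urea")))
  expect_length(u$groups, 1L)
  expect_equal(u$groups[[1]]$nH, 4L)
  expect_length(u$groups[[1]]$members, 3L)
})

test_that("normalizing an already-normalized parent changes nothing", {
  for (nm in c("guanine", "tartaric-1", "urea", "mobile-charge-a")) {
    p1 <- normalize_structure(add_implicit_hydrogens(fixture_molecule(nm)))
    p2 <- normalize_structure(p1$parent)
    expect_identical(p2$parent$atoms[, c("element", "charge", "nH", "nH1",
                                         "nH2", "nH3")],
                     p1$parent$atoms[, c("element", "charge", "nH", "nH1",
                                        "nH2", "nH3")], info = nm)
    expect_equal(p2$p, 0L, info = nm)
  }
})

test_that("mobile positive charge marks changeable bonds", {
  a <- normalize_structure(add_implicit_hydrogens(
    fixture_molecule("mobile-charge-a")))
  expect_gt(length(a$changeable_bonds), 0L)
  eth <- molecule(data.frame(element = c("C", "C"), nH = c(3L, 3L)),
                  data.frame(a = 1, b = 2))
  expect_length(detect_mobile_charge(eth), 0L)
})
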