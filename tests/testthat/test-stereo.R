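# Stereo perception and canonicalization: tetrahedral parities from
# wedges and 3D coordinates, double-bond geometry, enantiomer selection,
# ring-size rules and wedge conventions.

test_that("tartaric acid drawings give the printed stereo layers", {
  expect_identical(
    ident_text(fixture_molecule("tartaric-1")),
    "InChI=1S/C4H6O6/c5-1(3(7)8)2(6)4(9)10/h1-2,5-6H,(H,7,8)(H,9,10)/t1-,2-/m1/s1")
  expect_identical(
    ident_text(fixture_molecule("tartaric-2")),
    "InChI=1S/C4H6O6/c5-1(3(7)8)2(6)4(9)10/h1-2,5-6H,(H,7,8)(H,9,10)/t1-,2-/m0/s1")
  # the meso diastereomer differs in /t and is inversion-invariant
  meso <- ident_text(fixture_molecule("tartaric-meso"))
  expect_match(meso, "/t1-,2\\+$")
  expect_false(grepl("/m", meso))
})

test_that("relative stereochemistry drops /m and equates enantiomers", {
  r1 <- ident_text(fixture_molecule("tartaric-1"), inchi_options(srel = TRUE))
  r2 <- ident_text(fixture_molecule("tartaric-2"), inchi_options(srel = TRUE))
  expect_identical(r1, r2)
  expect_match(r1, "/t1-,2-/s2$")
  expect_true(startsWith(r1, "InChI=1/"))
  # racemic mode
  rc <- ident_text(fixture_molecule("tartaric-1"), inchi_options(srac = TRUE))
  expect_match(rc, "/t1-,2-/s3$")
})

test_that("molecules without stereo elements have no stereo layers", {
  for (nm in c("guanine", "methane", "urea"))
    expect_false(grepl("/[bt]", sub("^.*?/h", "", ident_text(
      fixture_molecule(nm)))), info = nm)
})

test_that("mirror-image 3D coordinates flip only the enantiomer flag", {
  t1 <- ident_text(chiral_3d(FALSE))
  t2 <- ident_text(chiral_3d(TRUE))
  expect_false(identical(t1, t2))
  expect_identical(gsub("/m[01]", "/m", t1), gsub("/m[01]", "/m", t2))
  expect_match(t1, "/t1[+-]/m[01]/s1")
})

test_that("proper rotations leave every parity unchanged", {
  ref <- ident_text(chiral_3d(FALSE))
  set.seed(31)
  for (r in 1:100) {
    m <- rotate3d(chiral_3d(FALSE), random_rotation())
    expect_identical(ident_text(m), ref)
  }
})

test_that("the small-ring double bond boundary sits exactly at 8", {
  expect_false(grepl("/b", ident_text(fixture_molecule("cyclohexene"))))
  expect_false(grepl("/b", ident_text(fixture_molecule("cycloheptene"))))
  expect_match(ident_text(fixture_molecule("cyclooctene")), "/b2-1-")
  expect_match(ident_text(fixture_molecule("cyclononene")), "/b2-1-")
})

test_that("geometric, anti-geometric and unspecified alkenes differ", {
  z <- ident_text(fixture_molecule("but-2-ene-Z"))
  e <- ident_text(fixture_molecule("but-2-ene-E"))
  u <- ident_text(fixture_molecule("but-2-ene"))
  expect_match(z, "/b4-3-$")
  expect_match(e, "/b4-3\\+$")
  expect_false(grepl("/b", u))
  expect_identical(unique(substr(c(z, e, u), 1, 30)),
                   substr(z, 1, 30))
})

test_that("wedge conventions decide which atom a wedge affects", {
  # narrow end at the stereocenter: perceived under both conventions
  t_def <- ident_text(butanol_wedge(from = 2))
  expect_match(t_def, "/t4-/m[01]/s1")
  t_np <- ident_text(butanol_wedge(from = 2), inchi_options(newpsoff = TRUE))
  expect_match(t_np, "/t4-/m[01]/s1")
  # narrow end at the far atom: invisible by default, perceived under
  # the two-atom convention
  expect_false(grepl("/t", ident_text(butanol_wedge(from = 5))))
  expect_match(ident_text(butanol_wedge(from = 5),
                          inchi_options(newpsoff = TRUE)), "/t4")
})

test_that("wavy bonds force unknown parity; SUU/SLUUD control display", {
  m <- butanol_wedge(from = 2, wedge = "either")
  expect_false(grepl("/t", ident_text(m)))
  suu <- ident_text(m, inchi_options(suu = TRUE))
  expect_match(suu, "/t4\\?$")
  expect_true(startsWith(suu, "InChI=1/"))
  expect_match(ident_text(m, inchi_options(suu = TRUE, sluud = TRUE)),
               "/t4u$")
})

test_that("stereo perception ignores input stereo under SNon", {
  s <- ident_text(fixture_molecule("tartaric-1"), inchi_options(s_non = TRUE))
  expect_false(grepl("/[tms]", sub("^.*?/h", "", s)))
  expect_true(startsWith(s, "InChI=1S/"))
})

test_that("chiral-flag mode maps the flag to absolute or relative", {
  m1 <- fixture_molecule("tartaric-1")
  m1$chiral <- TRUE
  expect_match(ident_text(m1, inchi_options(sucf = TRUE)), "/m1/s1$")
  m0 <- fixture_molecule("tartaric-1")
  m0$chiral <- FALSE
  expect_match(ident_text(m0, inchi_options(sucf = TRUE)), "/s2$")
})

test_that("four identical hydrogens or duplicate branches kill a center", {
  expect_false(grepl("/t", ident_text(fixture_molecule("methane"),
                                      inchi_options(suu = TRUE))))
  # isopropyl center: two methyls in one orbit, swap flips only it
  iso <- molecule(
    data.frame(element = c("C", "C", "C", "O"),
               x = c(0, -1, 1, 0), y = c(0, 0.6, 0.6, -1),
               nH = c(1L, 3L, 3L, 1L)),
    data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = 1L,
               wedge = c("up", "none", "none"), from = 1L))
  expect_false(grepl("/t", ident_text(iso)))
})
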