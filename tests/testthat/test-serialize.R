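# Serialization: connection traversal, hydrogen sublayers, charge and
# protonation, component ordering, layer grammar.

test_that("connection layers reproduce the reference traversals", {
  cases <- c(
    guanine = "6-5-9-3-2(4(11)10-5)7-1-8-3",
    `tartaric-1` = "5-1(3(7)8)2(6)4(9)10",
    `mobile-charge-a` = "1-8(2)5-6(10)7-9(3)4",
    urea = "2-1(3)4",
    `2-chlorobutane` = "1-3-4(2)5")
  for (nm in names(cases)) {
    parsed <- parse_identifier(ident_text(fixture_molecule(nm)))
    expect_identical(layer_value(parsed, "c"), unname(cases[nm]), info = nm)
  }
  # single atoms have no connection layer
  expect_false(grepl("/c", ident_text(fixture_molecule("methane")),
                     fixed = TRUE))
})

test_that("hydrogen sublayers use maximal runs and sorted mobile groups", {
  p <- parse_identifier(ident_text(fixture_molecule("tartaric-1")))
  expect_identical(layer_value(p, "h"), "1-2,5-6H,(H,7,8)(H,9,10)")
  p <- parse_identifier(ident_text(fixture_molecule("atp-32P-monoanion")))
  expect_identical(layer_value(p, "h"),
                   "2-7,16-17H,1H2,(H,21,22)(H,23,24)(H2,11,13,14)(H2,18,19,20)")
  expect_identical(layer_value(parse_identifier(
    ident_text(fixture_molecule("methane"))), "h"), "1H4")
})

test_that("charge and protonation sublayers carry signed values", {
  p <- parse_identifier(ident_text(fixture_molecule("chloride-anion")))
  expect_identical(layer_value(p, "p"), "-1")
  expect_true(is.na(layer_value(p, "q")))
  p <- parse_identifier(ident_text(fixture_molecule("mobile-charge-a")))
  expect_identical(layer_value(p, "p"), "+1")
  p <- parse_identifier(ident_text(fixture_molecule("urea")))
  expect_true(is.na(layer_value(p, "q")))
  expect_true(is.na(layer_value(p, "p")))
})

test_that("components are ordered deterministically with separators", {
  t1 <- ident_text(fixture_molecule("ammonium-chloride"))
  expect_identical(t1, "InChI=1S/ClH.H3N/h1H;1H3")
  # reversed input order gives the identical string
  m <- fixture_molecule("ammonium-chloride")
  mp <- permuted(m, c(2L, 1L))
  expect_identical(ident_text(mp), t1)
  expect_identical(ident_text(fixture_molecule("sodium-chloride")),
                   "InChI=1S/ClH.Na/h1H;/q;+1/p-1")
  # two identical components aggregate with a multiplier
  two <- molecule(data.frame(element = c("C", "C")), NULL)
  expect_identical(ident_text(two), "InChI=1S/2CH4/h2*1H4")
})

test_that("emitted strings parse back into their layer map", {
  for (nm in c("guanine", "tartaric-1", "sodium-chloride", "urea-d2",
               "atp-32P-monoanion", "mobile-charge-c")) {
    for (fh in c(FALSE, TRUE)) {
      txt <- ident_text(fixture_molecule(nm), inchi_options(fixed_h = fh))
      p <- parse_identifier(txt)
      expect_identical(p$standard, !fh, info = nm)
      body <- sub("^InChI=1S?/", "", txt)
      rebuilt <- paste(ifelse(p$layers$tag == "", p$layers$payload,
                              paste0(p$layers$tag, p$layers$payload)),
                       collapse = "/")
      expect_identical(rebuilt, body, info = nm)
    }
  }
})

test_that("serialization is byte-identical across repeated runs", {
  for (nm in c("guanine", "atp-32P-monoanion")) {
    a <- ident_text(fixture_molecule(nm))
    b <- ident_text(read_molfile(generate_fixture(nm)))
    expect_identical(a, b, info = nm)
  }
})

test_that("option classes control the standard prefix exactly", {
  m <- fixture_molecule("tartaric-1")
  # perception options retain standardness
  expect_true(startsWith(ident_text(m, inchi_options(s_non = TRUE)),
                         "InChI=1S/"))
  expect_true(startsWith(ident_text(m, inchi_options(newpsoff = TRUE)),
                         "InChI=1S/"))
  expect_true(startsWith(ident_text(m, inchi_options(do_not_add_h = TRUE)),
                         "InChI=1S/"))
  # interpretation/creation options drop it, even with no stereo present
  for (o in list(inchi_options(srel = TRUE), inchi_options(srac = TRUE),
                 inchi_options(sucf = TRUE), inchi_options(suu = TRUE),
                 inchi_options(sluud = TRUE), inchi_options(rec_met = TRUE),
                 inchi_options(fixed_h = TRUE))) {
    expect_true(startsWith(ident_text(fixture_molecule("methane"), o),
                           "InChI=1/"))
  }
})

test_that("the reconnected layer appears only for metal disconnection", {
  fe <- molecule(data.frame(element = c("Fe", "C", "C"), nH = c(0, 3, 3)),
                 data.frame(a = c(1, 1), b = c(2, 3)))
  t_fe <- ident_text(fe, inchi_options(rec_met = TRUE))
  expect_match(t_fe, "/rC2H6Fe/")
  # a disconnected simple salt cannot be reconnected this way
  t_nacl <- ident_text(fixture_molecule("sodium-chloride"),
                       inchi_options(rec_met = TRUE))
  expect_false(grepl("/r", t_nacl, fixed = TRUE))
  expect_true(startsWith(t_nacl, "InChI=1/"))
})
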