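# Hashed compact key: identifier splitting, truncation widths, base-26
# encoding, flags, and collision analytics.

test_that("identifiers split into skeleton, protonation and the rest", {
  s <- split_identifier(ident_text(fixture_molecule("tartaric-1")))
  expect_identical(s$part3, "/t1-,2-/m1/s1")
  expect_identical(s$part2, "")
  expect_true(s$standard)
  s <- split_identifier("InChI=1S/ClH/h1H/p-1")
  expect_identical(s$part1, "ClH/h1H")
  expect_identical(s$part2, "/p-1")
  expect_identical(s$part3, "")
  s <- split_identifier("InChI=1S/CH4/h1H4")
  expect_identical(s$part2, "")
  expect_identical(s$part3, "")
  s <- split_identifier("InChI=1S/p+1")
  expect_identical(s$part1, "")
  expect_identical(s$part2, "/p+1")
  expect_error(split_identifier("FOO=1/CH4"), "prefix")
})

test_that("hash truncation keeps the stated number of leading bits", {
  h65 <- hash_truncate("abc", 65L)
  h37 <- hash_truncate("abc", 37L)
  expect_lte(block_bitlength(h65), 65L)
  expect_lte(block_bitlength(h37), 37L)
  # identical input, identical truncation
  expect_identical(hash_truncate("", 37L), hash_truncate("", 37L))
  # avalanche: distinct single-character changes never collide in a
  # small sample
  set.seed(5)
  base <- "C10H16N5O13P3/c1-2-3/h1H"
  muts <- character(0)
  for (i in 1:300) {
    pos <- sample(nchar(base), 1)
    ch <- sample(c(LETTERS, letters, as.character(0:9)), 1)
    muts <- c(muts, paste0(substr(base, 1, pos - 1), ch,
                           substr(base, pos + 1, nchar(base))))
  }
  muts <- unique(muts)
  hashes <- vapply(muts, function(s)
    base26_encode(hash_truncate(s, 65L), 14L), "")
  expect_equal(anyDuplicated(hashes), 0L)
})

test_that("base-26 encoding is positional, padded and bijective", {
  expect_identical(base26_encode(0L, 14L), "AAAAAAAAAAAAAA")
  expect_identical(base26_encode(25L, 8L), "AAAAAAAZ")
  expect_identical(base26_encode(26L, 8L), "AAAAAABA")
  expect_error(base26_encode(26L, 1L), "range")
  bn_value <- function(v) sum(v * 32768^(seq_along(v) - 1))
  set.seed(8)
  for (i in 1:500) {
    v <- sample.int(2^31 - 1L, 1L)
    expect_equal(bn_value(base26_decode(base26_encode(v, 14L))), v)
  }
})

test_that("proton flags map the protonation count to single letters", {
  expect_identical(proton_flag(0L), "N")
  expect_identical(proton_flag(1L), "O")
  expect_identical(proton_flag(12L), "Z")
  expect_identical(proton_flag(-1L), "M")
  expect_identical(proton_flag(-12L), "B")
  expect_identical(proton_flag(13L), "A")
  expect_identical(proton_flag(-13L), "A")
})

test_that("keys have the fixed 27-character two-block layout", {
  for (nm in c("methane", "guanine", "tartaric-1", "chloride-anion")) {
    k <- make_key(inchi(fixture_molecule(nm)))
    expect_equal(nchar(k$text), 27L, info = nm)
    expect_match(k$text, "^[A-Z]{14}-[A-Z]{8}[SN]A-[A-Z]$", info = nm)
    expect_lte(block_bitlength(base26_decode(k$block1)), 65L)
    expect_lte(block_bitlength(base26_decode(k$block2)), 37L)
  }
  # standardness flag follows the identifier
  k <- make_key(inchi(fixture_molecule("guanine"),
                      inchi_options(fixed_h = TRUE)))
  expect_identical(k$flag_std, "N")
})

test_that("key blocks separate skeleton from advanced layers", {
  k1 <- make_key(inchi(fixture_molecule("tartaric-1")))
  k2 <- make_key(inchi(fixture_molecule("tartaric-2")))
  km <- make_key(inchi(fixture_molecule("tartaric-meso")))
  expect_identical(k1$block1, k2$block1)
  expect_identical(k1$block1, km$block1)
  expect_false(identical(k1$block2, k2$block2))
  expect_false(identical(k1$block2, km$block2))
  # isotopic substitution moves only the second block
  ku <- make_key(inchi(fixture_molecule("urea")))
  kd <- make_key(inchi(fixture_molecule("urea-d2")))
  expect_identical(ku$block1, kd$block1)
  expect_false(identical(ku$block2, kd$block2))
  # stereo-less, isotope-less molecules share the empty-part3 block
  kb <- make_key(inchi(fixture_molecule("methane")))
  kc <- make_key(inchi(fixture_molecule("urea")))
  expect_identical(kb$block2, kc$block2)
})

test_that("collision analytics reproduce the birthday-bound figures", {
  expect_equal(round(100 * collision_estimate(1e9, 65L), 1), 1.3)
  expect_equal(signif(100 * collision_estimate(1e8, 65L), 2), 0.014)
  expect_equal(collision_estimate(1, 65L), 0)
  expect_equal(signif(expected_first_collision(65L), 2), 6.1e9)
  expect_equal(signif(expected_first_collision(37L), 2), 3.7e5)
})
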