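# Canonical numbering: initial colors, refinement, individualization,
# connection-table codes, the staged search against the brute-force
# oracle, and isotopic weights.

test_that("initial colors follow element precedence then connectivity", {
  m <- add_implicit_hydrogens(fixture_molecule("2-chlorobutane"))
  expect_equal(initial_colors(m), c(2L, 3L, 4L, 5L, 2L))
  benz <- molecule(data.frame(element = rep("C", 6), nH = 1L),
                   data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1)))
  expect_equal(initial_colors(benz), rep(6L, 6))
  expect_equal(initial_colors(molecule(data.frame(element = "C"))), 1L)
})

test_that("equitable refinement reproduces the worked example", {
  m <- add_implicit_hydrogens(fixture_molecule("2-chlorobutane"))
  adj <- inchikit:::adjacency(m)
  expect_equal(refine_equitable(adj, initial_colors(m)),
               c(1L, 3L, 4L, 5L, 2L))
  # benzene stays a single cell
  benz <- molecule(data.frame(element = rep("C", 6), nH = 1L),
                   data.frame(a = 1:6, b = c(2:6, 1)))
  expect_equal(refine_equitable(inchikit:::adjacency(benz),
                                initial_colors(benz)), rep(6L, 6))
  # path of three: endpoints one cell, middle its own
  p3 <- molecule(data.frame(element = rep("C", 3)),
                 data.frame(a = c(1, 2), b = c(2, 3)))
  r <- refine_equitable(inchikit:::adjacency(p3), initial_colors(p3))
  expect_equal(r, c(2L, 3L, 2L))
})

test_that("individualization reduces the smallest duplicated color", {
  branches <- individualize(c(1L, 2L, 5L, 5L, 5L, 7L, 7L))
  expect_length(branches, 3L)
  expect_equal(branches[[1]], c(1L, 2L, 3L, 5L, 5L, 7L, 7L))
  expect_equal(branches[[2]], c(1L, 2L, 5L, 3L, 5L, 7L, 7L))
  expect_length(individualize(c(2L, 2L)), 2L)
  expect_error(individualize(c(1L, 2L)), "discrete")
})

test_that("connection-table codes list smaller-colored neighbors", {
  m <- add_implicit_hydrogens(fixture_molecule("2-chlorobutane"))
  tr <- stage_trace(m)
  expect_equal(tr$code, c(1L, 2L, 3L, 1L, 4L, 2L, 3L, 5L, 4L))
  expect_equal(connection_table_code(list(integer(0)), 1L), 1L)
  two <- molecule(data.frame(element = c("C", "C")),
                  data.frame(a = 1, b = 2))
  expect_equal(connection_table_code(inchikit:::adjacency(two), c(1L, 2L)),
               c(1L, 2L, 1L))
  expect_error(connection_table_code(inchikit:::adjacency(two), c(1L, 1L)),
               "discrete")
})

test_that("canonical search equals the exhaustive oracle on benchmarks", {
  # benzene: one equivalence class of 6
  benz <- molecule(data.frame(element = rep("C", 6), nH = 1L),
                   data.frame(a = 1:6, b = c(2:6, 1)))
  cres <- canonicalize(benz)
  bo <- oracle_canonical(benz)
  expect_equal(as.integer(cres$A$code), as.integer(bo$code))
  expect_equal(unique(cres$A$orbits), 1L)

  # neopentane skeleton: four methyl carbons in one class
  neo <- molecule(data.frame(element = rep("C", 5),
                             nH = c(0L, 3L, 3L, 3L, 3L)),
                  data.frame(a = rep(1, 4), b = 2:5))
  cres <- canonicalize(neo)
  bo <- oracle_canonical(neo)
  expect_equal(as.integer(cres$A$code), as.integer(bo$code))
  expect_equal(sum(cres$A$orbits == min(cres$A$orbits[-1])), 4L)

  # 2-chlorobutane: all classes singletons
  m <- add_implicit_hydrogens(fixture_molecule("2-chlorobutane"))
  cres <- canonicalize(m)
  expect_equal(sort(cres$B$orbits), 1:5)
})

test_that("hydrogen counts break remaining ties at the second stage", {
  # propene: the CH2 end takes the smaller number than the CH3 end
  pr <- molecule(data.frame(element = rep("C", 3), nH = c(2L, 1L, 3L)),
                 data.frame(a = c(1, 2), b = c(2, 3), order = c(2, 1)))
  cres <- canonicalize(pr)
  bo <- oracle_canonical(pr, use_h = TRUE)
  expect_equal(as.integer(cres$B$nu), as.integer(bo$numbering))
  # ethane: both carbons stay equivalent
  eth <- molecule(data.frame(element = c("C", "C"), nH = c(3L, 3L)),
                  data.frame(a = 1, b = 2))
  cres <- canonicalize(eth)
  expect_equal(cres$B$orbits, c(1L, 1L))
})

test_that("random components match brute-force minima and orbits", {
  set.seed(99)
  checked <- 0L
  s <- 0L
  while (checked < 120L) {
    s <- s + 1L
    m <- add_implicit_hydrogens(random_molecule(s, n_atoms = 3L + (s %% 6L)))
    for (sub in normalized_components(m)) {
      if (n_atoms(sub) < 2L || n_atoms(sub) > 8L) next
      cres <- canonicalize(sub)
      bo <- oracle_canonical(sub)
      expect_equal(as.integer(cres$A$code), as.integer(bo$code),
                   info = paste("seed", s))
      expect_equal(as.integer(cres$A$orbits), as.integer(bo$orbits),
                   info = paste("seed", s))
      boH <- oracle_canonical(sub, use_h = TRUE)
      expect_equal(as.integer(cres$B$orbits), as.integer(boH$orbits),
                   info = paste("seed", s))
      checked <- checked + 1L
    }
  }
})

test_that("each stage's optimal numberings are a subset of the last", {
  key <- function(nu) paste(nu, collapse = ",")
  for (s in 301:340) {
    m <- add_implicit_hydrogens(random_molecule(s))
    for (sub in normalized_components(m)) {
      if (n_atoms(sub) < 2L) next
      cres <- canonicalize(sub)
      stages <- list(cres$A, cres$B, cres$mob, cres$iso)
      for (k in 2:4) {
        prev <- vapply(stages[[k - 1]]$nus, key, "")
        cur <- vapply(stages[[k]]$nus, key, "")
        expect_true(all(cur %in% prev), info = paste("seed", s, "stage", k))
        expect_lte(length(cur), length(prev))
      }
    }
  }
})

test_that("isotopic weights follow the nested base-32 formula", {
  # direct re-evaluation over the full small grid
  for (nH1 in 0:3) for (nH2 in 0:3) for (nH3 in 0:3) for (shift in 0:3) {
    horner <- nH1 + 32 * (nH2 + 32 * (nH3 + 32 * shift))
    expect_identical(horner,
                     nH1 + 32 * nH2 + 32^2 * nH3 + 32^3 * shift)
  }
  # one attached deuterium on a non-isotopic atom
  m <- molecule(data.frame(element = "C", nH2 = 1L))
  expect_equal(iso_weights(m), 32)
  # 13C with no hydrogens: shift 1 incremented to 2
  m <- molecule(data.frame(element = "C", mass = 13L))
  expect_equal(iso_weights(m), 2 * 32^3)
  # isotope below the rounded mass keeps its negative shift
  m <- molecule(data.frame(element = "C", mass = 11L))
  expect_equal(iso_weights(m), -32^3)
  # fully non-isotopic atoms take the sentinel
  m <- molecule(data.frame(element = "C", nH = 4L))
  expect_gt(iso_weights(m), 32^4)
  # labelled atoms take the smallest canonical numbers
  m2 <- molecule(data.frame(element = c("C", "C"), nH = c(3L, 3L),
                            mass = c(NA, 13L)),
                 data.frame(a = 1, b = 2))
  cres <- canonicalize(m2)
  expect_equal(cres$iso$nu, c(2L, 1L))
})

test_that("exchangeable isotopic hydrogens stay out of atom iso lists", {
  id <- inchi(fixture_molecule("urea-d2"), inchi_options(fixed_h = TRUE))
  expect_identical(
    id$text,
    "InChI=1/CH4N2O/c2-1(3)4/h(H4,2,3,4)/i/hD2/f/h2-3H2/i2D2")
})
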