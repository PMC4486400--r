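# Programmatic fixtures: reference molecules built in code (returned as
# molecule objects or molfile text), and a seeded random molecule
# generator for property-based testing.

fixture_builders <- local({
  b <- list()

  b[["methane"]] <- function() {
    molecule(data.frame(element = "C"))
  }

  b[["2-chlorobutane"]] <- function() {
    # atom order: CH3, CH2, CH(Cl), Cl, CH3
    atoms <- data.frame(
      element = c("C", "C", "C", "Cl", "C"),
      x = c(0, 1, 2, 2, 3), y = c(0, 0.6, 0, -1.1, 0.6))
    bonds <- data.frame(a = c(1, 2, 3, 3), b = c(2, 3, 4, 5))
    molecule(atoms, bonds)
  }

  b[["guanine"]] <- function() {
    # 2-amino-9H-purin-6(1H)-one; atom order:
    # 1 C2, 2 C4, 3 C5, 4 C6, 5 C8, 6 N1, 7 N3, 8 N7, 9 N9, 10 N(amino),
    # 11 O6
    atoms <- data.frame(
      element = c("C", "C", "C", "C", "C", "N", "N", "N", "N", "N", "O"),
      nH = c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 2L, 0L))
    bonds <- data.frame(
      a =     c(6, 1, 7, 2, 3, 4, 4, 1, 2, 3, 8, 5),
      b =     c(1, 7, 2, 3, 4, 6, 11, 10, 9, 8, 5, 9),
      order = c(1, 2, 1, 2, 1, 1, 2, 1, 1, 1, 2, 1))
    molecule(atoms, bonds)
  }

  tartaric <- function(wedge1, wedge2) {
    # 1 C(alpha, carries O5), 2 C(alpha, carries O6), 3/4 carboxyl C,
    # 5/6 hydroxyl O, 7/9 carbonyl O, 8/10 acid O
    atoms <- data.frame(
      element = c("C", "C", "C", "C", "O", "O", "O", "O", "O", "O"),
      x = c(0, 1, -1, 2, 0, 1, -1, -2, 2, 3),
      y = c(0, 0.5, 0.5, 0, -1, 1.5, 1.5, 0, -1, 0.5),
      nH = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L))
    bonds <- data.frame(
      a = c(1, 1, 1, 2, 2, 3, 3, 4, 4),
      b = c(2, 3, 5, 4, 6, 7, 8, 9, 10),
      order = c(1, 1, 1, 1, 1, 2, 1, 2, 1),
      wedge = c("none", "none", wedge1, "none", wedge2,
                "none", "none", "none", "none"),
      from = c(1, 1, 1, 2, 2, 3, 3, 4, 4))
    molecule(atoms, bonds)
  }
  b[["tartaric-1"]] <- function() tartaric("up", "up")
  b[["tartaric-2"]] <- function() tartaric("down", "down")
  b[["tartaric-meso"]] <- function() tartaric("up", "down")

  b[["formamide"]] <- function() {
    molecule(data.frame(element = c("C", "N", "O"), nH = c(1L, 2L, 0L)),
             data.frame(a = c(1, 1), b = c(2, 3), order = c(1, 2)))
  }
  b[["formamide-mesomer"]] <- function() {
    molecule(data.frame(element = c("C", "N", "O"), nH = c(1L, 2L, 0L),
                        charge = c(0L, 1L, -1L)),
             data.frame(a = c(1, 1), b = c(2, 3), order = c(2, 1)))
  }

  b[["nitromethane"]] <- function() {
    molecule(data.frame(element = c("C", "N", "O", "O"),
                        nH = c(3L, 0L, 0L, 0L),
                        charge = c(0L, 1L, 0L, -1L)),
             data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 2, 1)))
  }
  b[["nitromethane-mesomer"]] <- function() {
    molecule(data.frame(element = c("C", "N", "O", "O"),
                        nH = c(3L, 0L, 0L, 0L),
                        charge = c(0L, 1L, -1L, 0L)),
             data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 1, 2)))
  }

  b[["urea"]] <- function() {
    molecule(data.frame(element = c("C", "N", "N", "O"),
                        nH = c(0L, 2L, 2L, 0L)),
             data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = c(1, 1, 2)))
  }
  b[["urea-d2"]] <- function() {
    molecule(data.frame(element = c("C", "N", "N", "O"),
                        nH = c(0L, 0L, 2L, 0L),
                        nH2 = c(0L, 2L, 0L, 0L)),
             data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = c(1, 1, 2)))
  }

  b[["chloride-anion"]] <- function() {
    molecule(data.frame(element = "Cl", charge = -1L))
  }
  b[["proton"]] <- function() {
    molecule(data.frame(element = "H", charge = 1L))
  }
  b[["ammonium-chloride"]] <- function() {
    molecule(data.frame(element = c("N", "Cl"), nH = c(4L, 0L)),
             data.frame(a = 1, b = 2))
  }
  b[["sodium-chloride"]] <- function() {
    molecule(data.frame(element = c("Na", "Cl")),
             data.frame(a = 1, b = 2))
  }

  butene <- function(geom) {
    # 1, 2 methyls; 3, 4 sp2 carbons
    y2 <- switch(geom, Z = 0.87, E = -0.87, none = 0)
    x <- switch(geom, none = c(0, 0, 0, 0), c(-0.5, 1.5, 0, 1))
    y <- switch(geom, none = c(0, 0, 0, 0), c(0.87, y2, 0, 0))
    atoms <- data.frame(element = c("C", "C", "C", "C"),
                        x = x, y = y,
                        nH = c(3L, 3L, 1L, 1L))
    bonds <- data.frame(a = c(1, 3, 4), b = c(3, 4, 2),
                        order = c(1, 2, 1))
    molecule(atoms, bonds)
  }
  b[["but-2-ene-Z"]] <- function() butene("Z")
  b[["but-2-ene-E"]] <- function() butene("E")
  b[["but-2-ene"]] <- function() butene("none")

  cycloalkene <- function(n) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    atoms <- data.frame(element = rep("C", n),
                        x = cos(th), y = sin(th),
                        nH = c(1L, 1L, rep(2L, n - 2L)))
    bonds <- data.frame(a = seq_len(n), b = c(seq_len(n)[-1], 1L),
                        order = c(2L, rep(1L, n - 1L)))
    molecule(atoms, bonds)
  }
  for (nn in 6:9)
    b[[paste0("cyclo", c("hexene", "heptene", "octene", "nonene")[nn - 5])]] <-
      local({ n0 <- nn; function() cycloalkene(n0) })

  # hypothetical mobile-charge structures; atom order:
  # 1-4 methyl C, 5 CH, 6 C, 7 N, 8 N(+ in a), 9 N, 10 O
  mobile_charge <- function(variant) {
    nH <- c(3L, 3L, 3L, 3L, 1L, 0L, 0L, 0L, 0L, 0L)
    charge <- rep(0L, 10)
    if (variant == "a") {
      charge[8] <- 1L
      nH[10] <- 1L
      bonds <- data.frame(
        a =     c(1, 2, 8, 5, 6, 6, 7, 9, 9),
        b =     c(8, 8, 5, 6, 10, 7, 9, 3, 4),
        order = c(1, 1, 2, 1, 1, 2, 1, 1, 1))
    } else if (variant == "b") {
      charge[9] <- 1L
      nH[10] <- 1L
      bonds <- data.frame(
        a =     c(1, 2, 8, 5, 6, 6, 7, 9, 9),
        b =     c(8, 8, 5, 6, 10, 7, 9, 3, 4),
        order = c(1, 1, 1, 2, 1, 1, 2, 1, 1))
    } else {
      charge[8] <- 1L
      nH[7] <- 1L
      bonds <- data.frame(
        a =     c(1, 2, 8, 5, 6, 6, 7, 9, 9),
        b =     c(8, 8, 5, 6, 10, 7, 9, 3, 4),
        order = c(1, 1, 2, 1, 2, 1, 1, 1, 1))
    }
    molecule(data.frame(element = c(rep("C", 6), "N", "N", "N", "O"),
                        nH = nH, charge = charge), bonds)
  }
  b[["mobile-charge-a"]] <- function() mobile_charge("a")
  b[["mobile-charge-b"]] <- function() mobile_charge("b")
  b[["mobile-charge-c"]] <- function() mobile_charge("c")

  lysine <- function(state) {
    # 1 carboxyl C, 2 alpha C, 3-6 chain C, 7 alpha N, 8 side N,
    # 9 carbonyl O, 10 acid O
    nH <- c(0L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 0L, 1L)
    charge <- rep(0L, 10)
    if (state == "zwitterion") {
      nH[7] <- 3L; charge[7] <- 1L
      nH[10] <- 0L; charge[10] <- -1L
    } else if (state == "cation") {
      nH[7] <- 3L; charge[7] <- 1L
    }
    molecule(data.frame(element = c(rep("C", 6), "N", "N", "O", "O"),
                        nH = nH, charge = charge),
             data.frame(a = c(1, 2, 3, 4, 5, 2, 6, 1, 1),
                        b = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
                        order = c(1, 1, 1, 1, 1, 1, 1, 2, 1)))
  }
  b[["lysine"]] <- function() lysine("neutral")
  b[["lysine-zwitterion"]] <- function() lysine("zwitterion")
  b[["lysine-cation"]] <- function() lysine("cation")

  b[["atp-32P-monoanion"]] <- function() {
    # adenosine 5'-triphosphate, gamma-32P, one terminal O(-); no stereo
    # atoms 1-10 C: C2,C4,C5,C6,C8 (adenine), C1',C2',C3',C4',C5'
    # atoms 11-15 N: amino, N1, N3, N7, N9
    # atoms 16-28 O: O2',O3',O4',O5', Oa=,OaH,Oab, Ob=,ObH,Obg, Og=,OgH,Og-
    # atoms 29-31 P: Pa, Pb, Pg (Pg mass 32)
    el <- c(rep("C", 10), rep("N", 5), rep("O", 13), rep("P", 3))
    nH <- rep(0L, 31)
    nH[c(1, 5, 6, 7, 8, 9)] <- 1L   # C2, C8, C1'-C4'
    nH[10] <- 2L                    # C5'
    nH[11] <- 2L                    # amino N
    nH[c(16, 17)] <- 1L             # O2'H, O3'H
    nH[c(21, 24, 27)] <- 1L         # OaH, ObH, OgH
    charge <- rep(0L, 31)
    charge[28] <- -1L               # terminal gamma O(-)
    mass <- rep(NA_integer_, 31)
    mass[31] <- 32L
    e <- rbind(
      c(12, 1, 1), c(1, 13, 2), c(13, 2, 1), c(2, 3, 2), c(3, 4, 1),
      c(4, 12, 2), c(4, 11, 1), c(3, 14, 1), c(14, 5, 2), c(5, 15, 1),
      c(15, 2, 1), c(15, 6, 1),
      c(6, 7, 1), c(7, 8, 1), c(8, 9, 1), c(9, 18, 1), c(18, 6, 1),
      c(7, 16, 1), c(8, 17, 1), c(9, 10, 1), c(10, 19, 1),
      c(19, 29, 1), c(29, 20, 2), c(29, 21, 1), c(29, 22, 1),
      c(22, 30, 1), c(30, 23, 2), c(30, 24, 1), c(30, 25, 1),
      c(25, 31, 1), c(31, 26, 2), c(31, 27, 1), c(31, 28, 1))
    molecule(data.frame(element = el, nH = nH, charge = charge,
                        mass = mass),
             data.frame(a = e[, 1], b = e[, 2], order = e[, 3]))
  }

  b
})

#' Names of available fixtures
#' @return character vector of registry names.
#' @export
fixture_names <- function() sort(names(fixture_builders))

#' Build a fixture molecule
#'
#' @param name registry name (see [fixture_names()]).
#' @return an `inchikit_mol`.
#' @export
fixture_molecule <- function(name) {
  f <- fixture_builders[[name]]
  if (is.null(f))
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  f()
}

#' Generate a fixture molfile
#'
#' @param name registry name.
#' @return molfile text.
#' @export
generate_fixture <- function(name) {
  write_molfile(fixture_molecule(name), title = name)
}

#' Seeded random small molecule
#'
#' Connected random skeleton over C/N/O/S/Cl with occasional double and
#' triple bonds, a single charge site, and isotopic labels, all within the
#' standard valence schema. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_atoms number of skeletal atoms (1-12).
#' @param charges allow a charged site.
#' @param isotopes allow isotopic labels.
#' @return an `inchikit_mol` (implicit hydrogens not yet added).
#' @export
random_molecule <- function(seed, n_atoms = NULL, charges = TRUE,
                            isotopes = TRUE) {
  set.seed(seed)
  if (is.null(n_atoms)) n_atoms <- sample(3:10, 1)
  stopifnot(n_atoms >= 1L, n_atoms <= 12L)
  n <- n_atoms
  a <- integer(0); bb <- integer(0)
  deg <- integer(n)
  if (n > 1L) for (i in 2:n) {
    cand <- which(deg[seq_len(i - 1L)] < 4L)
    p <- cand[sample.int(length(cand), 1L)]
    a <- c(a, p); bb <- c(bb, i)
    deg[p] <- deg[p] + 1L; deg[i] <- deg[i] + 1L
  }
  # occasional ring closure
  if (n >= 5L && runif(1) < 0.4) {
    free <- which(deg < 3L)
    if (length(free) >= 2L) {
      pr <- sample(free, 2L)
      u <- min(pr); v <- max(pr)
      if (!any((a == u & bb == v))) {
        a <- c(a, u); bb <- c(bb, v)
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      }
    }
  }
  caps <- c(C = 4L, N = 3L, O = 2L, S = 2L, Cl = 1L)
  el <- sample(names(caps), n, replace = TRUE,
               prob = c(0.55, 0.18, 0.15, 0.06, 0.06))
  for (i in seq_len(n)) if (deg[i] > caps[[el[i]]]) el[i] <- "C"
  free <- vapply(seq_len(n), function(i) caps[[el[i]]] - deg[i], 0L)
  ord <- rep(1L, length(a))
  for (k in seq_along(a)) {
    if (free[a[k]] >= 1L && free[bb[k]] >= 1L && runif(1) < 0.25) {
      ord[k] <- 2L
      free[a[k]] <- free[a[k]] - 1L
      free[bb[k]] <- free[bb[k]] - 1L
      if (free[a[k]] >= 1L && free[bb[k]] >= 1L && runif(1) < 0.15 &&
          el[a[k]] == "C" && el[bb[k]] == "C") {
        ord[k] <- 3L
        free[a[k]] <- free[a[k]] - 1L
        free[bb[k]] <- free[bb[k]] - 1L
      }
    }
  }
  charge <- rep(0L, n)
  if (charges && runif(1) < 0.2) {
    i <- sample.int(n, 1L)
    if (el[i] == "N") charge[i] <- 1L
    if (el[i] == "O" && free[i] > 0L) charge[i] <- -1L
  }
  mass <- rep(NA_integer_, n)
  nH2 <- rep(0L, n)
  if (isotopes) {
    if (runif(1) < 0.25) {
      i <- sample.int(n, 1L)
      mass[i] <- rounded_mass(el[i]) + 1L
    }
    if (runif(1) < 0.15) {
      i <- sample.int(n, 1L)
      if (free[i] > 0L && el[i] != "Cl") nH2[i] <- 1L
    }
  }
  molecule(data.frame(element = el, charge = charge, mass = mass,
                      nH2 = nH2),
           if (length(a)) data.frame(a = a, b = bb, order = ord) else NULL)
}

#' Canonicalization trace of the hydrogenless stage
#'
#' Reports the initial colors, the refined equitable colors, the final
#' canonical colors and the minimal connection-table code, mirroring the
#' staged worked example.
#'
#' @param m molecule (normalized or plain skeleton).
#' @return list with `initial`, `refined`, `final`, `code`.
#' @export
stage_trace <- function(m) {
  init <- initial_colors(m)
  adj <- adjacency(m)
  refined <- refine_equitable(adj, init)
  res <- canonical_search_raw(adj, init)
  list(initial = init, refined = refined, final = res$nus[[1]],
       code = res$code)
}
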