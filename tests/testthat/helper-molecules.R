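# Shared helpers: small molecule builders, adjacency matrices, the
# brute-force oracle wrapper, and 3D geometry utilities.

adj_matrix <- function(m) {
  n <- n_atoms(m)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(m$bonds))) {
    A[m$bonds$a[k], m$bonds$b[k]] <- 1L
    A[m$bonds$b[k], m$bonds$a[k]] <- 1L
  }
  A
}

# brute-force canonical minimum of one normalized connected component
oracle_canonical <- function(sub, use_h = FALSE) {
  er <- inchikit:::element_rank(sub$atoms$element)
  brute_canonical(adj_matrix(sub), as.integer(er),
                  as.integer(inchikit:::total_H(sub)), use_h)
}

normalized_components <- function(m) {
  norm <- normalize_structure(m)
  cc <- connected_components(norm$parent)
  lapply(unique(cc), function(ci)
    inchikit:::sub_molecule(norm$parent, which(cc == ci)))
}

permuted <- function(m, perm) inchikit:::permute_molecule(m, perm)

# one-stereocenter 3D molecule: C bonded to F, Cl, Br at tetrahedral
# positions (implicit H takes the remaining apex)
chiral_3d <- function(flip = FALSE) {
  z <- if (flip) -1 else 1
  molecule(
    data.frame(element = c("C", "F", "Cl", "Br"),
               x = c(0, 1, -1, -1), y = c(0, 1, 1, -1),
               z = c(0, z, -z, z), nH = c(1L, 0L, 0L, 0L)),
    data.frame(a = c(1, 1, 1), b = c(2, 3, 4)))
}

rotate3d <- function(m, R) {
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m$atoms$x <- xyz[, 1]
  m$atoms$y <- xyz[, 2]
  m$atoms$z <- xyz[, 3]
  m
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

mirror3d <- function(m) {
  m$atoms$z <- -m$atoms$z
  m
}

# butan-2-ol with a configurable wedge (for convention tests)
butanol_wedge <- function(from, wedge = "up") {
  molecule(
    data.frame(element = c("C", "C", "C", "C", "O"),
               x = c(0, 1, 2, 3, 1), y = c(0, 0.6, 0, 0.6, 1.6),
               nH = c(3L, 1L, 2L, 3L, 1L)),
    data.frame(a = c(1, 2, 3, 2), b = c(2, 3, 4, 5), order = 1L,
               wedge = c("none", "none", "none", wedge),
               from = c(1L, 2L, 3L, from)))
}

# 9H-guanine redrawn as the 7H tautomer
guanine_7H <- function() {
  gt <- fixture_molecule("guanine")
  gt$atoms$nH[8] <- 1L
  gt$atoms$nH[9] <- 0L
  gt$bonds$order[gt$bonds$a == 8 & gt$bonds$b == 5] <- 1L
  gt$bonds$order[gt$bonds$a == 5 & gt$bonds$b == 9] <- 2L
  gt
}

ident_text <- function(x, ...) inchi(x, ...)$text
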