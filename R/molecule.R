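# Internal molecular data model: a colored multigraph of skeletal atoms with
# per-atom terminal-hydrogen counts, charges, isotopes, radicals and
# coordinates.
#
# Hydrogen bookkeeping distinguishes four classes per atom:
#   nH  - hydrogens of natural isotopic composition (plain H)
#   nH1 - explicitly labelled protium (1H), treated as an isotopic label
#   nH2 - deuterium
#   nH3 - tritium

RADICAL_LEVELS <- c("none", "singlet", "doublet", "triplet")

#' Construct a molecule
#'
#' @param atoms data frame with columns `element` (symbol), and optionally
#'   `charge`, `radical`, `mass` (mass number, `NA` = natural), `nH`, `nH1`,
#'   `nH2`, `nH3`, `x`, `y`, `z`. Missing columns are filled with defaults.
#' @param bonds data frame with columns `a`, `b` (1-based atom indices) and
#'   optionally `order` (1, 2, 3; 4 marks an aromatic input bond pending
#'   kekulization), `wedge` (`"none"`, `"up"`, `"down"`, `"either"`) and
#'   `from` (atom index at the narrow end of the wedge).
#' @param chiral logical; molfile chiral flag.
#' @return an object of class `inchikit_mol`.
#' @export
molecule <- function(atoms, bonds = NULL, chiral = FALSE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot("element" %in% names(atoms))
  n <- nrow(atoms)
  fill <- function(col, default) {
    if (is.null(atoms[[col]])) rep(default, n) else atoms[[col]]
  }
  atoms <- data.frame(
    element = as.character(atoms$element),
    charge = as.integer(fill("charge", 0L)),
    radical = as.character(fill("radical", "none")),
    mass = as.integer(fill("mass", NA_integer_)),
    nH = as.integer(fill("nH", 0L)),
    nH1 = as.integer(fill("nH1", 0L)),
    nH2 = as.integer(fill("nH2", 0L)),
    nH3 = as.integer(fill("nH3", 0L)),
    x = as.numeric(fill("x", 0)),
    y = as.numeric(fill("y", 0)),
    z = as.numeric(fill("z", 0)),
    stringsAsFactors = FALSE
  )
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0),
                        wedge = character(0), from = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    nb <- nrow(bonds)
    bfill <- function(col, default) {
      if (is.null(bonds[[col]])) rep(default, nb) else bonds[[col]]
    }
    bonds <- data.frame(
      a = as.integer(bonds$a), b = as.integer(bonds$b),
      order = as.integer(bfill("order", 1L)),
      wedge = as.character(bfill("wedge", "none")),
      from = as.integer(if (is.null(bonds[["from"]])) bonds$a
                        else bonds$from),
      stringsAsFactors = FALSE
    )
  }
  m <- structure(list(atoms = atoms, bonds = bonds, chiral = isTRUE(chiral)),
                 class = "inchikit_mol")
  validate_molecule(m)
  m
}

validate_molecule <- function(m) {
  n <- nrow(m$atoms)
  b <- m$bonds
  if (nrow(b)) {
    if (any(b$a < 1L | b$a > n | b$b < 1L | b$b > n))
      stop("bond references a missing atom", call. = FALSE)
    if (any(b$a == b$b))
      stop("bond connects an atom to itself", call. = FALSE)
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key))
      stop("duplicate bond between one atom pair", call. = FALSE)
    if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
      stop("bond order must be 1, 2, 3 (or 4 pending kekulization)",
           call. = FALSE)
  }
  if (any(m$atoms$nH < 0L | m$atoms$nH1 < 0L |
          m$atoms$nH2 < 0L | m$atoms$nH3 < 0L))
    stop("negative hydrogen count", call. = FALSE)
  if (!all(m$atoms$radical %in% RADICAL_LEVELS))
    stop("invalid radical state", call. = FALSE)
  invisible(m)
}

#' Number of skeletal atoms
#' @param m molecule.
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

# Total terminal hydrogens (all isotope classes) per atom.
total_H <- function(m) {
  with(m$atoms, nH + nH1 + nH2 + nH3)
}

# Adjacency list over skeletal bonds; list of integer vectors.
adjacency <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a[k]]] <- c(adj[[b$a[k]]], b$b[k])
    adj[[b$b[k]]] <- c(adj[[b$b[k]]], b$a[k])
  }
  lapply(adj, sort)
}

# Sum of explicit bond orders per atom (aromatic order 4 counts 1.5 and is
# resolved before any valence-sensitive step).
bond_order_sum <- function(m) {
  n <- n_atoms(m)
  s <- numeric(n)
  b <- m$bonds
  ord <- ifelse(b$order == 4L, 1.5, b$order)
  for (k in seq_len(nrow(b))) {
    s[b$a[k]] <- s[b$a[k]] + ord[k]
    s[b$b[k]] <- s[b$b[k]] + ord[k]
  }
  s
}

#' Connected components of the bond graph
#'
#' @param m molecule.
#' @return integer vector assigning each atom a component id (1-based,
#'   numbered by smallest member atom); zero atoms give an empty vector.
#' @export
connected_components <- function(m) {
  n <- n_atoms(m)
  if (n == 0L) return(integer(0))
  adj <- adjacency(m)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Add implicit hydrogens to reach the nearest higher standard valence
#'
#' Hypovalent non-metal atoms are topped up with plain hydrogens until the
#' nearest higher standard valence for their (element, charge) is reached.
#' No hydrogen is added to reach pentavalent neutral nitrogen or tetravalent
#' neutral sulfur. Metals receive hydrogens only if they are on the fixed
#' list of hydrogen-accepting metals. Radical centres reserve one (doublet)
#' or two (singlet/triplet) valences. Element H itself never receives
#' implicit hydrogens.
#'
#' @param m molecule.
#' @return molecule with updated `nH` counts.
#' @export
add_implicit_hydrogens <- function(m) {
  bs <- bond_order_sum(m)
  hs <- total_H(m)
  for (i in seq_len(n_atoms(m))) {
    el <- m$atoms$element[i]
    if (el == "H") next
    if (is_metal(el) && !(el %in% METALS_WITH_IMPLICIT_H)) next
    vals <- standard_valences(el, m$atoms$charge[i])
    if (!length(vals)) next
    radadj <- switch(m$atoms$radical[i],
                     none = 0L, doublet = 1L, singlet = 2L, triplet = 2L)
    used <- bs[i] + hs[i] + radadj
    cand <- vals[vals >= used]
    if (!length(cand)) next
    target <- cand[[1]]
    if (el == "N" && m$atoms$charge[i] == 0L && target == 5L && used < 5)
      next
    if (el == "S" && m$atoms$charge[i] == 0L && target == 4L && used < 4)
      next
    add <- as.integer(target - used)
    if (add > 0L) m$atoms$nH[i] <- m$atoms$nH[i] + add
  }
  m
}

#' Hill-convention molecular formula
#'
#' Carbon first, then hydrogen, then all other elements alphabetically;
#' carbon-free formulas are purely alphabetical (hydrogen in its
#' alphabetical place). All terminal hydrogens (any isotope) count as H.
#'
#' @param m molecule.
#' @param which optional integer vector of atom indices restricting the
#'   formula to a component.
#' @return formula string (empty for an empty selection).
#' @export
hill_formula <- function(m, which = NULL) {
  idx <- if (is.null(which)) seq_len(n_atoms(m)) else which
  if (!length(idx)) return("")
  els <- m$atoms$element[idx]
  counts <- table(els)
  nh <- sum(total_H(m)[idx]) + sum(els == "H")
  counts <- counts[names(counts) != "H"]
  syms <- names(counts)
  out <- character(0)
  fmt <- function(s, k) if (k == 1) s else paste0(s, k)
  if ("C" %in% syms) {
    out <- c(out, fmt("C", counts[["C"]]))
    if (nh > 0) out <- c(out, fmt("H", nh))
    rest <- sort(setdiff(syms, "C"))
    for (s in rest) out <- c(out, fmt(s, counts[[s]]))
  } else {
    all_syms <- syms
    if (nh > 0) all_syms <- c(all_syms, "H")
    for (s in sort(all_syms)) {
      k <- if (s == "H") nh else counts[[s]]
      out <- c(out, fmt(s, k))
    }
  }
  paste(out, collapse = "")
}

# Extract the sub-molecule induced by atom indices `idx` (bonds inside).
# Folded-hydrogen geometry records are remapped and carried along.
sub_molecule <- function(m, idx) {
  map <- match(seq_len(n_atoms(m)), idx)
  b <- m$bonds[m$bonds$a %in% idx & m$bonds$b %in% idx, , drop = FALSE]
  b$a <- map[b$a]
  b$b <- map[b$b]
  b$from <- map[b$from]
  out <- molecule(m$atoms[idx, , drop = FALSE], b, chiral = m$chiral)
  if (!is.null(m$hfold) && nrow(m$hfold)) {
    hf <- m$hfold[m$hfold$atom %in% idx, , drop = FALSE]
    hf$atom <- map[hf$atom]
    rownames(hf) <- NULL
    out$hfold <- hf
  }
  out
}

# Reorder atoms by permutation `perm` (new index of old atom i is perm[i]).
permute_molecule <- function(m, perm) {
  inv <- order(perm)
  at <- m$atoms[inv, , drop = FALSE]
  rownames(at) <- NULL
  b <- m$bonds
  if (nrow(b)) {
    b$a <- perm[b$a]
    b$b <- perm[b$b]
    b$from <- perm[b$from]
  }
  molecule(at, b, chiral = m$chiral)
}

#' @export
print.inchikit_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds, formula %s>\n",
              n_atoms(x), nrow(x$bonds), hill_formula(x)))
  invisible(x)
}
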