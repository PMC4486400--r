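# Element reference data: the standard-valence schema, metal classification,
# and rounded average atomic masses used by the isotopic canonicalization
# stage.

# Elements considered non-metals; every other element is a metal.
NONMETALS <- c("H", "He", "B", "C", "N", "O", "F", "Ne", "Si", "P", "S",
               "Cl", "Ar", "Ge", "As", "Se", "Br", "Kr", "Te", "I", "Xe",
               "At", "Rn")

# Metals that receive implicit hydrogens to fill a standard valence.
METALS_WITH_IMPLICIT_H <- c("Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Ga",
                            "Rb", "Sr", "In", "Sn", "Sb", "Cs", "Ba", "Tl",
                            "Pb", "Bi", "Po", "Fr", "Ra")

# Standard valences by (element, formal charge). Entries absent from the
# schema leave an atom without standard valences: it then receives no
# implicit hydrogens.
.valence_spec <- list(
  H  = list(`0` = 1),
  B  = list(`-2` = 3, `-1` = 4, `0` = 3, `1` = 2, `2` = 1),
  C  = list(`-2` = 2, `-1` = 3, `0` = 4, `1` = 3, `2` = 2),
  N  = list(`-2` = 1, `-1` = 2, `0` = c(3, 5), `1` = 4, `2` = 3),
  O  = list(`-1` = 1, `0` = 2, `1` = c(3, 5), `2` = 4),
  F  = list(`0` = 1, `1` = 2, `2` = c(3, 5)),
  Si = list(`-2` = 2, `-1` = c(3, 5), `0` = 4, `1` = 3, `2` = 2),
  P  = list(`-2` = c(1, 3, 5, 7), `-1` = c(2, 4, 6), `0` = c(3, 5),
            `1` = 4, `2` = 3),
  S  = list(`-1` = c(1, 3, 5, 7), `0` = c(2, 4, 6), `1` = c(3, 5), `2` = 4),
  Cl = list(`0` = c(1, 3, 5, 7), `1` = c(2, 4, 6), `2` = c(3, 5)),
  Ge = list(`-2` = c(2, 4, 6), `-1` = c(3, 5), `0` = 4, `1` = 3),
  As = list(`-2` = c(1, 3, 5, 7), `-1` = c(2, 4, 6), `0` = c(3, 5),
            `1` = 4, `2` = 3),
  Se = list(`-1` = c(1, 3, 5, 7), `0` = c(2, 4, 6), `1` = c(3, 5), `2` = 4),
  Br = list(`0` = c(1, 3, 5, 7), `1` = c(2, 4, 6), `2` = c(3, 5)),
  Te = list(`-1` = c(1, 3, 5, 7), `0` = c(2, 4, 6), `1` = c(3, 5),
            `2` = c(2, 4)),
  I  = list(`0` = c(1, 3, 5, 7), `1` = c(2, 4, 6), `2` = c(3, 5)),
  At = list(`0` = c(1, 3, 5, 7), `1` = c(2, 4, 6), `2` = c(3, 5)),
  # metals that receive implicit H
  Li = list(`0` = 1), Na = list(`0` = 1), K = list(`0` = 1),
  Rb = list(`0` = 1), Cs = list(`0` = 1), Fr = list(`0` = 1),
  Be = list(`0` = 2, `1` = 1), Mg = list(`0` = 2, `1` = 1),
  Ca = list(`0` = 2, `1` = 1), Sr = list(`0` = 2, `1` = 1),
  Ba = list(`0` = 2, `1` = 1), Ra = list(`0` = 2, `1` = 1),
  Al = list(`-2` = c(3, 5), `-1` = 4, `0` = 3, `1` = 2, `2` = 1),
  Ga = list(`-2` = c(3, 5), `-1` = 4, `0` = 3, `2` = 1),
  In = list(`-2` = c(3, 5), `-1` = c(2, 4), `0` = 3, `2` = 1),
  Tl = list(`-2` = c(3, 5), `-1` = c(2, 4), `0` = c(1, 3)),
  Sn = list(`-2` = c(2, 4, 6), `-1` = c(3, 5), `0` = c(2, 4), `1` = 3),
  Pb = list(`-2` = c(2, 4, 6), `-1` = c(3, 5), `0` = c(2, 4), `1` = 3),
  Sb = list(`-2` = c(1, 3, 5, 7), `-1` = c(2, 4, 6), `0` = c(3, 5),
            `1` = c(2, 4), `2` = 3),
  Bi = list(`-2` = c(1, 3, 5, 7), `-1` = c(2, 4, 6), `0` = c(3, 5),
            `1` = c(2, 4), `2` = 3),
  Po = list(`-1` = c(1, 3, 5, 7), `0` = c(2, 4, 6), `1` = c(3, 5),
            `2` = c(2, 4)),
  # other metals: neutral-state valences only
  Sc = list(`0` = 3), Ti = list(`0` = c(3, 4)), V = list(`0` = c(2, 3, 4, 5)),
  Cr = list(`0` = c(2, 3, 6)), Mn = list(`0` = c(2, 3, 4, 6)),
  Fe = list(`0` = c(2, 3, 4, 6)), Co = list(`0` = c(2, 3)),
  Ni = list(`0` = c(2, 3)), Cu = list(`0` = c(1, 2)), Zn = list(`0` = 2),
  Y = list(`0` = 3), Zr = list(`0` = 4), Nb = list(`0` = c(3, 5)),
  Mo = list(`0` = c(3, 4, 5, 6)), Tc = list(`0` = 7),
  Ru = list(`0` = c(2, 3, 4, 6)), Rh = list(`0` = c(2, 3, 4)),
  Pd = list(`0` = c(2, 4)), Ag = list(`0` = 1), Cd = list(`0` = 2),
  La = list(`0` = 3), Ce = list(`0` = c(3, 4)), Pr = list(`0` = c(3, 4)),
  Nd = list(`0` = 3), Pm = list(`0` = 3), Sm = list(`0` = c(2, 3)),
  Eu = list(`0` = c(2, 3)), Gd = list(`0` = 3), Tb = list(`0` = c(3, 4)),
  Dy = list(`0` = 3), Ho = list(`0` = 3), Er = list(`0` = 3),
  Tm = list(`0` = c(2, 3)), Yb = list(`0` = c(2, 3)), Lu = list(`0` = 3),
  Hf = list(`0` = 4), Ta = list(`0` = 5), W = list(`0` = c(3, 4, 5, 6)),
  Re = list(`0` = c(2, 4, 6, 7)), Os = list(`0` = c(2, 3, 4, 6)),
  Ir = list(`0` = c(2, 3, 4, 6)), Pt = list(`0` = c(2, 4)),
  Au = list(`0` = c(1, 3)), Hg = list(`0` = c(1, 2)),
  Ac = list(`0` = 3), Th = list(`0` = c(3, 4)), Pa = list(`0` = c(3, 4, 5)),
  U = list(`0` = c(3, 4, 5, 6)), Np = list(`0` = c(3, 4, 5, 6)),
  Pu = list(`0` = c(3, 4, 5, 6)), Am = list(`0` = c(3, 4, 5, 6)),
  Cm = list(`0` = 3), Bk = list(`0` = c(3, 4)), Cf = list(`0` = 3),
  Es = list(`0` = 3), Fm = list(`0` = 3), Md = list(`0` = 3),
  No = list(`0` = 2), Lr = list(`0` = 3), Rf = list(`0` = 4),
  Db = list(`0` = 5), Sg = list(`0` = 6), Bh = list(`0` = 7),
  Hs = list(`0` = 1), Mt = list(`0` = 1), Ds = list(`0` = 1),
  Rg = list(`0` = 1), Cn = list(`0` = 1)
)

# Average atomic masses rounded to the nearest integer, indexed by symbol.
ROUNDED_MASS <- c(
  H = 1, He = 4, Li = 7, Be = 9, B = 11, C = 12, N = 14, O = 16, F = 19,
  Ne = 20, Na = 23, Mg = 24, Al = 27, Si = 28, P = 31, S = 32, Cl = 35,
  Ar = 40, K = 39, Ca = 40, Sc = 45, Ti = 48, V = 51, Cr = 52, Mn = 55,
  Fe = 56, Co = 59, Ni = 59, Cu = 64, Zn = 65, Ga = 70, Ge = 73, As = 75,
  Se = 79, Br = 80, Kr = 84, Rb = 85, Sr = 88, Y = 89, Zr = 91, Nb = 93,
  Mo = 96, Tc = 98, Ru = 101, Rh = 103, Pd = 106, Ag = 108, Cd = 112,
  In = 115, Sn = 119, Sb = 122, Te = 128, I = 127, Xe = 131, Cs = 133,
  Ba = 137, La = 139, Ce = 140, Pr = 141, Nd = 144, Pm = 145, Sm = 150,
  Eu = 152, Gd = 157, Tb = 159, Dy = 163, Ho = 165, Er = 167, Tm = 169,
  Yb = 173, Lu = 175, Hf = 178, Ta = 181, W = 184, Re = 186, Os = 190,
  Ir = 192, Pt = 195, Au = 197, Hg = 201, Tl = 204, Pb = 207, Bi = 209,
  Po = 209, At = 210, Rn = 222, Fr = 223, Ra = 226, Ac = 227, Th = 232,
  Pa = 231, U = 238, Np = 237, Pu = 244, Am = 243, Cm = 247, Bk = 247,
  Cf = 251, Es = 252, Fm = 257, Md = 258, No = 259, Lr = 262, Rf = 267,
  Db = 268, Sg = 271, Bh = 272, Hs = 270, Mt = 276, Ds = 281, Rg = 280,
  Cn = 285
)

#' Test whether element symbols denote metals
#'
#' @param element character vector of element symbols.
#' @return logical vector; `TRUE` for metals. Every element outside the
#'   fixed non-metal set is a metal.
#' @export
is_metal <- function(element) !(element %in% NONMETALS)

#' Standard valences of an element at a formal charge
#'
#' Looks up the standard valence list of the valence schema. Elements or
#' charges without an entry return an empty vector; such atoms receive no
#' implicit hydrogens.
#'
#' @param element element symbol (scalar).
#' @param charge integer formal charge (scalar).
#' @return integer vector of standard valences in ascending order (possibly
#'   empty).
#' @export
standard_valences <- function(element, charge = 0L) {
  ent <- .valence_spec[[element]]
  if (is.null(ent)) return(integer(0))
  v <- ent[[as.character(charge)]]
  if (is.null(v)) return(integer(0))
  as.integer(v)
}

# Rank used everywhere for canonical ordering of elements: carbon first,
# all other elements alphabetical, bridging hydrogen last.
element_rank <- function(element) {
  ifelse(element == "C", 1L,
         ifelse(element == "H", 1000L,
                match(element, .noncarbon_alpha) + 1L))
}

.noncarbon_alpha <- local({
  syms <- unique(c(names(.valence_spec), NONMETALS, names(ROUNDED_MASS)))
  sort(setdiff(syms, c("C", "H")))
})

rounded_mass <- function(element) {
  m <- ROUNDED_MASS[element]
  ifelse(is.na(m), 0L, as.integer(m))
}
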