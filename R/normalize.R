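# Normalization of an input structure to the core parent structure:
# drawing corrections, salt/metal disconnection, kekulization and radical
# cancellation, proton removal/addition toward a neutral parent, and
# detection of mobile-hydrogen and mobile-charge groups.

CHALCOGENS <- c("O", "S", "Se", "Te")
HALOGENS <- c("F", "Cl", "Br", "I", "At")
TAUT_END_ELEMENTS <- c("N", "O", "S", "Se", "Te")
TAUT_Q_ELEMENTS <- c("C", "N", "S", "P", "Sb", "As", "Se", "Te",
                     "Br", "Cl", "I")

bond_index <- function(m, i, j) {
  which((m$bonds$a == i & m$bonds$b == j) | (m$bonds$a == j & m$bonds$b == i))
}

# does (element, charge) admit `val` as a standard valence?
valence_ok <- function(el, chg, val) {
  val %in% standard_valences(el, chg)
}

atom_valence_used <- function(m) bond_order_sum(m) + total_H(m)

# ---- drawing corrections --------------------------------------------------

#' Apply hard-coded drawing corrections
#'
#' Runs the fixed repertoire of input corrections, each to a local
#' fixpoint, in order: moving charge from hydrogen to a heavy atom;
#' neutralizing 1,3 charge-separated patterns (+A=B-C- becomes A-B=C);
#' moving negative charge from central atoms of oxoanions to terminal
#' oxygens; moving positive charge from carbon to create an imine nitrogen;
#' annihilating adjacent opposite charges by raising the bond order to a
#' higher standard valence state (nitro groups drawn charge-separated
#' become the neutral pentavalent form). Non-matching structures pass
#' through unchanged.
#'
#' @param m molecule (implicit hydrogens resolved).
#' @return corrected molecule.
#' @export
fix_drawing <- function(m) {
  repeat {
    changed <- FALSE
    m1 <- fix_charged_hydrogen(m)
    m1 <- fix_separated_13(m1)
    m1 <- fix_oxoanion_center(m1)
    m1 <- fix_imine_cation(m1)
    m1 <- fix_adjacent_opposite(m1)
    changed <- !identical(m1[c("atoms", "bonds")], m[c("atoms", "bonds")])
    m <- m1
    if (!changed) return(m)
  }
}

# charged skeletal hydrogen bonded to a heavy atom: move the charge there
fix_charged_hydrogen <- function(m) {
  repeat {
    idx <- which(m$atoms$element == "H" & m$atoms$charge == 1L)
    hit <- FALSE
    for (i in idx) {
      nb <- adjacency(m)[[i]]
      if (length(nb) != 1L || m$atoms$element[nb] == "H") next
      k <- bond_index(m, i, nb)
      if (m$bonds$order[k] != 1L) next
      j <- nb
      m$atoms$charge[j] <- m$atoms$charge[j] + 1L
      m$atoms$nH[j] <- m$atoms$nH[j] + 1L
      keep <- setdiff(seq_len(n_atoms(m)), i)
      m <- sub_molecule(m, keep)
      hit <- TRUE
      break
    }
    if (!hit) return(m)
  }
}

# +A=B-C(-)  ->  A-B=C (both charges to zero); valences must stay standard
fix_separated_13 <- function(m) {
  repeat {
    hit <- FALSE
    pos <- which(m$atoms$charge > 0L & !is_metal(m$atoms$element))
    for (a in pos) {
      if (hit) break
      for (kb in seq_len(nrow(m$bonds))) {
        if (m$bonds$order[kb] != 2L) next
        ends <- c(m$bonds$a[kb], m$bonds$b[kb])
        if (!(a %in% ends)) next
        b <- setdiff(ends, a)
        for (cc in adjacency(m)[[b]]) {
          if (cc == a || m$atoms$charge[cc] >= 0L) next
          kc <- bond_index(m, b, cc)
          if (m$bonds$order[kc] != 1L) next
          used_a <- atom_valence_used(m)[a]
          used_c <- atom_valence_used(m)[cc]
          if (!valence_ok(m$atoms$element[a], m$atoms$charge[a] - 1L,
                          used_a - 1L)) next
          if (!valence_ok(m$atoms$element[cc], m$atoms$charge[cc] + 1L,
                          used_c + 1L)) next
          m$bonds$order[kb] <- 1L
          m$bonds$order[kc] <- 2L
          m$atoms$charge[a] <- m$atoms$charge[a] - 1L
          m$atoms$charge[cc] <- m$atoms$charge[cc] + 1L
          hit <- TRUE
          break
        }
        if (hit) break
      }
    }
    if (!hit) return(m)
  }
}

# negatively charged central atom with a doubly bonded terminal oxygen:
# move the charge out to the oxygen
fix_oxoanion_center <- function(m) {
  repeat {
    hit <- FALSE
    neg <- which(m$atoms$charge < 0L & !(m$atoms$element %in% CHALCOGENS) &
                 !is_metal(m$atoms$element))
    deg <- lengths(adjacency(m))
    for (a in neg) {
      for (o in adjacency(m)[[a]]) {
        if (m$atoms$element[o] != "O" || deg[o] != 1L ||
            m$atoms$charge[o] != 0L || total_H(m)[o] != 0L) next
        k <- bond_index(m, a, o)
        if (m$bonds$order[k] != 2L) next
        m$bonds$order[k] <- 1L
        m$atoms$charge[a] <- m$atoms$charge[a] + 1L
        m$atoms$charge[o] <- -1L
        hit <- TRUE
        break
      }
      if (hit) break
    }
    if (!hit) return(m)
  }
}

# carbocation bonded to a trivalent neutral nitrogen: form the iminium bond
fix_imine_cation <- function(m) {
  repeat {
    hit <- FALSE
    pos <- which(m$atoms$element == "C" & m$atoms$charge == 1L)
    used <- atom_valence_used(m)
    for (a in pos) {
      if (used[a] >= 4) next
      for (nb in adjacency(m)[[a]]) {
        if (m$atoms$element[nb] != "N" || m$atoms$charge[nb] != 0L) next
        if (used[nb] != 3) next
        k <- bond_index(m, a, nb)
        if (m$bonds$order[k] != 1L) next
        m$bonds$order[k] <- 2L
        m$atoms$charge[a] <- 0L
        m$atoms$charge[nb] <- 1L
        hit <- TRUE
        break
      }
      if (hit) break
    }
    if (!hit) return(m)
  }
}

# adjacent opposite charges: raise the bond order, sending the atoms to a
# higher standard valence state (covers charge-separated nitro and diazo
# drawings)
fix_adjacent_opposite <- function(m) {
  repeat {
    hit <- FALSE
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a[k]; b <- m$bonds$b[k]
      ca <- m$atoms$charge[a]; cb <- m$atoms$charge[b]
      if (ca == 0L || cb == 0L || sign(ca) == sign(cb)) next
      if (m$bonds$order[k] >= 3L) next
      if (is_metal(m$atoms$element[a]) || is_metal(m$atoms$element[b])) next
      pos <- if (ca > 0L) a else b
      neg <- if (ca > 0L) b else a
      used <- atom_valence_used(m)
      if (!valence_ok(m$atoms$element[pos], m$atoms$charge[pos] - 1L,
                      used[pos] + 1L)) next
      if (!valence_ok(m$atoms$element[neg], m$atoms$charge[neg] + 1L,
                      used[neg] + 1L)) next
      m$bonds$order[k] <- m$bonds$order[k] + 1L
      m$atoms$charge[pos] <- m$atoms$charge[pos] - 1L
      m$atoms$charge[neg] <- m$atoms$charge[neg] + 1L
      hit <- TRUE
      break
    }
    if (!hit) return(m)
  }
}

# ---- disconnection --------------------------------------------------------

#' Disconnect simple salts
#'
#' Breaks single bonds between qualifying metals (no hydrogens, used
#' valence at the lowest or second-lowest standard valence) and halogen
#' atoms of the acid; the halogen receives a single negative charge and the
#' metal charge is incremented. Structures drawn H4N-X are split into NH3
#' and HX. Other metal compounds are left for general metal disconnection.
#'
#' @param m molecule after drawing fixes.
#' @return molecule with qualifying salt bonds broken.
#' @export
disconnect_salts <- function(m) {
  repeat {
    hit <- FALSE
    used <- atom_valence_used(m)
    hs <- total_H(m)
    for (k in seq_len(nrow(m$bonds))) {
      if (m$bonds$order[k] != 1L) next
      a <- m$bonds$a[k]; b <- m$bonds$b[k]
      for (ord in list(c(a, b), c(b, a))) {
        met <- ord[1]; x <- ord[2]
        if (!is_metal(m$atoms$element[met])) next
        if (hs[met] > 0L) next
        if (!(m$atoms$element[x] %in% HALOGENS)) next
        if (m$atoms$charge[x] != 0L) next
        vals <- standard_valences(m$atoms$element[met], m$atoms$charge[met])
        if (!length(vals)) next
        ok_val <- used[met] %in% vals[seq_len(min(2L, length(vals)))]
        if (m$atoms$charge[met] > 0L) ok_val <- used[met] == vals[[1]]
        if (!ok_val) next
        m$bonds <- m$bonds[-k, , drop = FALSE]
        m$atoms$charge[x] <- -1L
        m$atoms$charge[met] <- m$atoms$charge[met] + 1L
        hit <- TRUE
        break
      }
      if (hit) break
    }
    if (!hit) break
  }
  # H4N-X -> NH3 + HX
  repeat {
    hit <- FALSE
    hs <- total_H(m)
    for (k in seq_len(nrow(m$bonds))) {
      if (m$bonds$order[k] != 1L) next
      a <- m$bonds$a[k]; b <- m$bonds$b[k]
      for (ord in list(c(a, b), c(b, a))) {
        nn <- ord[1]; x <- ord[2]
        if (m$atoms$element[nn] != "N" || m$atoms$charge[nn] != 0L) next
        if (hs[nn] != 4L || m$atoms$nH[nn] < 1L) next
        if (!(m$atoms$element[x] %in% HALOGENS) || m$atoms$charge[x] != 0L)
          next
        m$bonds <- m$bonds[-k, , drop = FALSE]
        m$atoms$nH[nn] <- m$atoms$nH[nn] - 1L
        m$atoms$nH[x] <- m$atoms$nH[x] + 1L
        hit <- TRUE
        break
      }
      if (hit) break
    }
    if (!hit) break
  }
  m
}

#' Disconnect remaining metal bonds
#'
#' Deletes every bond incident to a metal atom. Charges of disconnected
#' halogen/O/S/Se/Te/N/P/As/B partners are adjusted by transferring charge
#' to the metal where a standard valence permits. The pre-disconnection
#' bonding is returned for the reconnected layer. Adjacent-opposite-charge
#' annihilation is applied a second time to the disconnected structure.
#'
#' @param m molecule after salt disconnection.
#' @return list with `disconnected` and `reconnected` molecules.
#' @export
disconnect_metals <- function(m) {
  reconnected <- m
  adjustable <- c(HALOGENS, "O", "S", "Se", "Te", "N", "P", "As", "B")
  repeat {
    metal_bond <- which(is_metal(m$atoms$element[m$bonds$a]) |
                        is_metal(m$atoms$element[m$bonds$b]))
    if (!length(metal_bond)) break
    k <- metal_bond[[1]]
    a <- m$bonds$a[k]; b <- m$bonds$b[k]
    met <- if (is_metal(m$atoms$element[a])) a else b
    x <- setdiff(c(a, b), met)[[1]]
    ord <- m$bonds$order[k]
    m$bonds <- m$bonds[-k, , drop = FALSE]
    if (!is_metal(m$atoms$element[x]) &&
        m$atoms$element[x] %in% adjustable && m$atoms$charge[x] == 0L) {
      used <- atom_valence_used(m)[x]
      if (valence_ok(m$atoms$element[x], -1L, used + ord - 1L) || ord == 1L) {
        m$atoms$charge[x] <- -1L
        m$atoms$charge[met] <- m$atoms$charge[met] + 1L
        if (ord > 1L) {
          # remaining electrons of a multiple bond stay with the metal
          m$atoms$charge[met] <- m$atoms$charge[met] + (ord - 1L)
          m$atoms$charge[x] <- m$atoms$charge[x] - (ord - 1L)
        }
      }
    }
  }
  m <- fix_adjacent_opposite(m)
  list(disconnected = m, reconnected = reconnected)
}

# ---- kekulization and radicals --------------------------------------------

#' Resolve aromatic input bonds and cancel pairable radicals
#'
#' Bonds of input type 4 are assigned alternating single/double orders by a
#' matching search: every atom whose valence demands one more bond receives
#' exactly one double bond among its aromatic bonds. Adjacent doublet
#' radicals are cancelled into a double bond.
#'
#' @param m molecule.
#' @return molecule with orders in \{1,2,3\}.
#' @export
resolve_radicals_and_kekulize <- function(m) {
  arom <- which(m$bonds$order == 4L)
  if (length(arom)) {
    atoms_in <- sort(unique(c(m$bonds$a[arom], m$bonds$b[arom])))
    # valence demand with aromatic bonds counted single
    demand <- integer(n_atoms(m))
    bs <- bond_order_sum(m)
    bs_single <- bs - 0.5 * vapply(seq_len(n_atoms(m)), function(i)
      sum(m$bonds$order[arom][m$bonds$a[arom] == i |
                              m$bonds$b[arom] == i]) / 4 * 4, 0)
    hs <- total_H(m)
    needs <- logical(n_atoms(m))
    for (i in atoms_in) {
      ar_i <- sum(m$bonds$a[arom] == i | m$bonds$b[arom] == i)
      base <- (bs[i] - 1.5 * ar_i) + ar_i + hs[i]
      vals <- standard_valences(m$atoms$element[i], m$atoms$charge[i])
      if (!length(vals)) next
      needs[i] <- !(base %in% vals) && ((base + 1) %in% vals)
    }
    # match: every `needs` atom gets exactly one double among aromatic bonds
    sel <- rep(FALSE, length(arom))
    satisfied <- !needs
    assign_k <- function(pos) {
      if (pos > length(arom)) return(all(satisfied[atoms_in]))
      k <- arom[pos]
      a <- m$bonds$a[k]; b <- m$bonds$b[k]
      # try double
      if (!satisfied[a] && !satisfied[b]) {
        satisfied[a] <<- TRUE; satisfied[b] <<- TRUE; sel[pos] <<- TRUE
        if (assign_k(pos + 1L)) return(TRUE)
        satisfied[a] <<- FALSE; satisfied[b] <<- FALSE; sel[pos] <<- FALSE
      }
      assign_k(pos + 1L)
    }
    if (!assign_k(1L))
      stop("cannot kekulize aromatic system", call. = FALSE)
    m$bonds$order[arom] <- ifelse(sel, 2L, 1L)
  }
  # adjacent doublet radicals cancel into a double bond
  repeat {
    hit <- FALSE
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a[k]; b <- m$bonds$b[k]
      if (m$atoms$radical[a] == "doublet" && m$atoms$radical[b] == "doublet" &&
          m$bonds$order[k] < 3L) {
        m$bonds$order[k] <- m$bonds$order[k] + 1L
        m$atoms$radical[a] <- "none"
        m$atoms$radical[b] <- "none"
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  m
}

# ---- proton normalization -------------------------------------------------

# countable charge: +-1 on non-metal atoms with standard valences, not
# adjacent to another charged atom
countable_charge <- function(m) {
  adj <- adjacency(m)
  total <- 0L
  for (i in seq_len(n_atoms(m))) {
    ch <- m$atoms$charge[i]
    if (abs(ch) != 1L) next
    if (is_metal(m$atoms$element[i])) next
    if (!length(standard_valences(m$atoms$element[i], 0L))) next
    if (any(m$atoms$charge[adj[[i]]] != 0L)) next
    total <- total + ch
  }
  total
}

# remove one H (preferring plain H, then protium, deuterium, tritium);
# returns updated molecule or NULL
take_H <- function(m, i) {
  for (cls in c("nH", "nH1", "nH2", "nH3")) {
    if (m$atoms[[cls]][i] > 0L) {
      m$atoms[[cls]][i] <- m$atoms[[cls]][i] - 1L
      return(m)
    }
  }
  NULL
}

# alternating-path flip: path v0-v1=v2-...=vk with orders alternating
# starting `first_order` at (v0,v1); flips all orders along the path.
flip_path <- function(m, path) {
  for (i in seq_len(length(path) - 1L)) {
    k <- bond_index(m, path[i], path[i + 1L])
    m$bonds$order[k] <- ifelse(m$bonds$order[k] == 1L, 2L, 1L)
  }
  m
}

# find an alternating path from `from` to any atom satisfying `is_goal`,
# orders alternating starting with `start_order`; shortest first, ties by
# ascending atom index. Returns the path (atom indices) or NULL.
find_alternating_path <- function(m, from, start_order, is_goal,
                                  min_len = 2L) {
  adj <- adjacency(m)
  queue <- list(list(v = from, path = from, want = start_order))
  seen <- paste(from, start_order)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[cur$v]]) {
      if (w %in% cur$path) next
      k <- bond_index(m, cur$v, w)
      if (m$bonds$order[k] != cur$want) next
      npath <- c(cur$path, w)
      if (length(npath) >= min_len && cur$want == 2L && is_goal(w, npath))
        return(npath)
      key <- paste(w, 3L - cur$want)
      if (key %in% seen) next
      seen <- c(seen, key)
      queue[[length(queue) + 1L]] <-
        list(v = w, path = npath, want = 3L - cur$want)
    }
  }
  NULL
}

#' Normalize protons toward a neutral core parent
#'
#' Removes protons from positively charged heteroatoms (simple, then via
#' alternating-path rearrangement), removes protons from neutral
#' heteroatoms of acid fragments while the net countable charge is
#' positive, and adds protons to reduce negative charge (acid-anion
#' fragments and bare halide/chalcogenide anions). Bare protons are
#' absorbed into the proton count.
#'
#' @param m disconnected, kekulized molecule.
#' @return list with `parent` molecule and `p` (protons removed minus
#'   protons added).
#' @export
normalize_protons <- function(m) {
  removed <- 0L
  added <- 0L
  adj <- adjacency(m)
  deg <- lengths(adj)

  # bare protons
  bare <- which(m$atoms$element == "H" & m$atoms$charge == 1L & deg == 0L &
                total_H(m) == 0L)
  if (length(bare)) {
    removed <- removed + length(bare)
    m <- sub_molecule(m, setdiff(seq_len(n_atoms(m)), bare))
  }

  # 1. simple removal from charged heteroatoms
  repeat {
    hit <- FALSE
    adj <- adjacency(m)
    for (i in which(m$atoms$charge == 1L &
                    m$atoms$element %in% c("N", "P", "O", "S", "Se", "Te"))) {
      if (any(m$atoms$charge[adj[[i]]] != 0L)) next
      m2 <- take_H(m, i)
      if (is.null(m2)) next
      m <- m2
      m$atoms$charge[i] <- 0L
      removed <- removed + 1L
      hit <- TRUE
      break
    }
    if (!hit) break
  }

  # 2. hard removal: positive N/P without hydrogens, fed by an alternating
  # path from a hydrogen-bearing heteroatom
  repeat {
    if (countable_charge(m) <= 0L) break
    hs <- total_H(m)
    donors <- which(m$atoms$element %in% TAUT_END_ELEMENTS & hs > 0L &
                    m$atoms$charge == 0L)
    hit <- FALSE
    for (d in donors) {
      path <- find_alternating_path(
        m, d, 1L,
        function(w, p) m$atoms$charge[w] == 1L &&
          m$atoms$element[w] %in% c("N", "P"))
      if (is.null(path)) next
      m <- flip_path(m, path)
      m2 <- take_H(m, d)
      if (is.null(m2)) { m <- flip_path(m, path); next }
      m <- m2
      m$atoms$charge[path[length(path)]] <- 0L
      removed <- removed + 1L
      hit <- TRUE
      break
    }
    if (!hit) break
  }

  # 3. remove protons from neutral heteroatoms of acid fragments
  repeat {
    if (countable_charge(m) <= 0L) break
    site <- acid_proton_site(m)
    if (is.null(site)) break
    m2 <- take_H(m, site)
    if (is.null(m2)) break
    m <- m2
    m$atoms$charge[site] <- -1L
    removed <- removed + 1L
  }

  # 4. hard removal onto a double-bonded chalcogen receiver
  repeat {
    if (countable_charge(m) <= 0L) break
    hs <- total_H(m)
    donors <- which(m$atoms$element %in% TAUT_END_ELEMENTS & hs > 0L &
                    m$atoms$charge == 0L)
    hit <- FALSE
    for (d in donors) {
      path <- find_alternating_path(
        m, d, 1L,
        function(w, p) m$atoms$element[w] %in% CHALCOGENS &&
          m$atoms$charge[w] == 0L && total_H(m)[w] == 0L)
      if (is.null(path)) next
      m <- flip_path(m, path)
      m2 <- take_H(m, d)
      if (is.null(m2)) { m <- flip_path(m, path); next }
      m <- m2
      m$atoms$charge[path[length(path)]] <- -1L
      removed <- removed + 1L
      hit <- TRUE
      break
    }
    if (!hit) break
  }

  # 5. add protons to reduce negative charge
  repeat {
    if (countable_charge(m) >= 0L) break
    site <- anion_protonation_site(m)
    if (is.null(site)) break
    m$atoms$nH[site] <- m$atoms$nH[site] + 1L
    m$atoms$charge[site] <- m$atoms$charge[site] + 1L
    added <- added + 1L
  }

  list(parent = m, p = removed - added)
}

# neutral QH of fragments =C-QH, -Q-QH, C-ZH, =N-QH (Q chalcogen; Z = S,
# Se, Te); smallest atom index first
acid_proton_site <- function(m) {
  adj <- adjacency(m)
  hs <- total_H(m)
  bs <- bond_order_sum(m)
  for (q in which(m$atoms$element %in% CHALCOGENS & hs > 0L &
                  m$atoms$charge == 0L)) {
    for (y in adj[[q]]) {
      k <- bond_index(m, q, y)
      if (m$bonds$order[k] != 1L) next
      el <- m$atoms$element[y]
      if (el == "C" && bs[y] > lengths(adj)[y]) return(q)          # =C-QH
      if (el %in% CHALCOGENS) return(q)                            # -Q-QH
      if (el == "C" && m$atoms$element[q] %in% c("S", "Se", "Te"))
        return(q)                                                  # C-ZH
      if (el == "N" && bs[y] > lengths(adj)[y]) return(q)          # =N-QH
    }
  }
  NULL
}

# Q(-) of fragments =C-Q-, -Q-Q-, C-Z-, =N-Q-, plus bare halide or
# chalcogenide anions
anion_protonation_site <- function(m) {
  adj <- adjacency(m)
  bs <- bond_order_sum(m)
  deg <- lengths(adj)
  hs <- total_H(m)
  for (q in which(m$atoms$charge == -1L)) {
    el <- m$atoms$element[q]
    if (el %in% HALOGENS && deg[q] == 0L) return(q)
    if (el %in% CHALCOGENS && deg[q] == 0L) return(q)
    if (!(el %in% CHALCOGENS)) next
    for (y in adj[[q]]) {
      k <- bond_index(m, q, y)
      if (m$bonds$order[k] != 1L) next
      ely <- m$atoms$element[y]
      if (ely == "C" && bs[y] > deg[y] + hs[y]) return(q)
      if (ely %in% CHALCOGENS) return(q)
      if (ely == "C" && el %in% c("S", "Se", "Te")) return(q)
      if (ely == "N" && bs[y] > deg[y] + hs[y]) return(q)
      # oxoacid anions generally: the central atom carries a double bond
      # to a terminal chalcogen (phosphate, sulfonate, ...)
      for (z in adj[[y]]) {
        if (z == q) next
        kz <- bond_index(m, y, z)
        if (m$bonds$order[kz] == 2L &&
            m$atoms$element[z] %in% CHALCOGENS && deg[z] == 1L)
          return(q)
      }
    }
  }
  NULL
}

# ---- mobile hydrogen detection --------------------------------------------

taut_endpoint_ok <- function(m, i) {
  el <- m$atoms$element[i]
  if (!(el %in% TAUT_END_ELEMENTS)) return(FALSE)
  ch <- m$atoms$charge[i]
  used <- atom_valence_used(m)[i]
  if (el == "N") return((ch == 0L && used <= 3) || (ch == -1L && used <= 2))
  (ch == 0L && used <= 2) || (ch == -1L && used <= 1)
}

#' Detect mobile-hydrogen groups
#'
#' Matches the donor/acceptor tautomerism patterns M=Q-ZH (and the variant
#' with a negative charge in place of the hydrogen) where M and Z are
#' N(III), O(II), S(II), Se(II) or Te(II) and Q is one of C, N, S, P, Sb,
#' As, Se, Te, Br, Cl, I. The double bond may be a true double bond, a bond
#' already marked tautomeric, or a single bond that an alternating-bond
#' rearrangement of the conjugated system could make double. Overlapping
#' matches are merged; hydrogens and shared negative charges are tallied.
#'
#' @param m normalized parent candidate.
#' @return list with `groups` (each `members`, `nH`, `nneg`, and per-isotope
#'   exchangeable counts) and `taut_bonds` (bond indices marked tautomeric).
#' @export
detect_mobile_H <- function(m) {
  n <- n_atoms(m)
  adj <- adjacency(m)
  hs <- total_H(m)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  taut <- rep(FALSE, nrow(m$bonds))
  member <- rep(FALSE, n)

  donor_ok <- function(z) taut_endpoint_ok(m, z) &&
    (hs[z] > 0L || m$atoms$charge[z] == -1L || member[z])
  acceptor_ok <- function(mm) taut_endpoint_ok(m, mm)

  # alternating-bond rearrangement test: can atom w accept one more bond,
  # with current group members free to release or absorb one
  # hydrogen/charge? `inc` frees capacity at w (drop an H if a member, or
  # turn one of w's double bonds single and let the partner regain);
  # `regain` restores a lost bond at x (take an H if a member, or form a
  # new double along one of x's single bonds).
  can_increase <- function(w, avoid_k, visited) {
    if (member[w]) return(TRUE)
    for (x in adj[[w]]) {
      k <- bond_index(m, w, x)
      if (k == avoid_k || k %in% visited) next
      if (m$bonds$order[k] != 2L) next
      if (can_regain(x, k, c(visited, k))) return(TRUE)
    }
    FALSE
  }
  can_regain <- function(x, avoid_k, visited) {
    if (member[x]) return(TRUE)
    for (y in adj[[x]]) {
      k <- bond_index(m, x, y)
      if (k == avoid_k || k %in% visited) next
      if (m$bonds$order[k] != 1L) next
      if (can_increase(y, k, c(visited, k))) return(TRUE)
    }
    FALSE
  }
  can_be_double <- function(u, v, k) {
    can_increase(u, k, integer(0)) && can_increase(v, k, integer(0))
  }

  repeat {
    changed <- FALSE
    for (q in which(m$atoms$element %in% TAUT_Q_ELEMENTS)) {
      nbq <- adj[[q]]
      if (length(nbq) < 2L) next
      for (mm in nbq) {
        if (!acceptor_ok(mm)) next
        kmq <- bond_index(m, q, mm)
        dbl <- m$bonds$order[kmq] == 2L || taut[kmq] ||
          (m$bonds$order[kmq] == 1L && any(member) &&
           can_be_double(mm, q, kmq))
        if (!dbl) next
        for (z in nbq) {
          if (z == mm) next
          kqz <- bond_index(m, q, z)
          if (m$bonds$order[kqz] != 1L && !taut[kqz]) next
          if (!donor_ok(z)) next
          rm_ <- find(mm); rz <- find(z)
          delta <- (rm_ != rz) || !member[mm] || !member[z] ||
            !taut[kmq] || !taut[kqz]
          if (!delta) next
          if (rm_ != rz) parent[max(rm_, rz)] <- min(rm_, rz)
          member[mm] <- TRUE
          member[z] <- TRUE
          taut[kmq] <- TRUE
          taut[kqz] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  if (!any(member))
    return(list(groups = list(), taut_bonds = integer(0)))
  roots <- vapply(seq_len(n), find, 0L)
  groups <- list()
  for (r in unique(roots[member])) {
    mem <- which(roots == r & member)
    if (length(mem) < 2L) next
    nH <- sum(hs[mem])
    nneg <- sum(m$atoms$charge[mem] == -1L)
    if (nH + nneg == 0L) next
    groups[[length(groups) + 1L]] <- list(
      members = mem, nH = nH, nneg = nneg,
      exH1 = sum(m$atoms$nH1[mem]),
      exH2 = sum(m$atoms$nH2[mem]),
      exH3 = sum(m$atoms$nH3[mem]))
  }
  list(groups = groups, taut_bonds = which(taut))
}

#' Mark bonds changeable by mobile positive charge
#'
#' Positive charges on nitrogen (and phosphorus) atoms move along
#' alternating bond paths between such atoms; every bond on such a path is
#' changeable and cannot support double-bond stereochemistry.
#'
#' @param m molecule.
#' @return integer vector of changeable bond indices.
#' @export
detect_mobile_charge <- function(m) {
  changeable <- logical(nrow(m$bonds))
  pos <- which(m$atoms$element %in% c("N", "P") & m$atoms$charge == 1L)
  used <- atom_valence_used(m)
  for (p0 in pos) {
    # charge leaves through one of its double bonds; the receiving N/P
    # gains a double bond, so it must have a free valence slot. All
    # alternating paths are enumerated and their bonds marked.
    adj <- adjacency(m)
    queue <- list(list(v = p0, path = p0, want = 2L))
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[cur$v]]) {
        if (w %in% cur$path) next
        k <- bond_index(m, cur$v, w)
        if (m$bonds$order[k] != cur$want) next
        npath <- c(cur$path, w)
        goal <- cur$want == 1L && m$atoms$element[w] %in% c("N", "P") &&
          m$atoms$charge[w] == 0L && used[w] <= 3
        if (goal) {
          for (i in seq_len(length(npath) - 1L))
            changeable[bond_index(m, npath[i], npath[i + 1L])] <- TRUE
        }
        if (length(npath) <= 12L)
          queue[[length(queue) + 1L]] <-
            list(v = w, path = npath, want = 3L - cur$want)
      }
    }
  }
  which(changeable)
}

# ---- orchestrator ---------------------------------------------------------

#' Normalize an input structure to its core parent
#'
#' Applies, in order: drawing corrections, salt disconnection, metal
#' disconnection, kekulization and radical cancellation, a fixed-hydrogen
#' snapshot (the structure as drawn, for the fixed-H layer), proton
#' normalization, and mobile hydrogen/charge detection. Mobile hydrogens
#' and shared negative charges are pooled into their groups and removed
#' from the member atoms.
#'
#' @param m molecule with implicit hydrogens resolved.
#' @return a normalization result: list with `parent`, `p`, `q`, `groups`,
#'   `fixed` (drawn hydrogen counts and net charge), `original`
#'   (pre-disconnection, for the reconnected layer), `taut_bonds`,
#'   `changeable_bonds`.
#' @export
normalize_structure <- function(m) {
  hfold_keep <- m$hfold
  m <- fix_drawing(m)
  original <- m
  m <- disconnect_salts(m)
  dm <- disconnect_metals(m)
  metal_disconnected <- nrow(dm$reconnected$bonds) > nrow(dm$disconnected$bonds)
  m <- dm$disconnected
  m <- resolve_radicals_and_kekulize(m)
  fixed_snapshot <- m
  pr <- normalize_protons(m)
  m <- pr$parent
  det <- detect_mobile_H(m)
  groups <- det$groups
  # drop charge-only groups from the identifier
  emit_groups <- Filter(function(g) g$nH > 0L, groups)
  q <- sum(m$atoms$charge)
  # pool hydrogens and negative charges of emitted groups
  for (g in emit_groups) {
    for (i in g$members) {
      m$atoms$nH[i] <- 0L
      m$atoms$nH1[i] <- 0L
      m$atoms$nH2[i] <- 0L
      m$atoms$nH3[i] <- 0L
      if (m$atoms$charge[i] == -1L) m$atoms$charge[i] <- 0L
    }
  }
  changeable <- detect_mobile_charge(m)
  # fixed snapshot may have more atoms than the parent only via bare
  # protons; align by dropping charged bare hydrogens
  fx <- fixed_snapshot
  if (n_atoms(fx) != n_atoms(m)) {
    degf <- lengths(adjacency(fx))
    baref <- which(fx$atoms$element == "H" & fx$atoms$charge == 1L &
                   degf == 0L & total_H(fx) == 0L)
    fx <- sub_molecule(fx, setdiff(seq_len(n_atoms(fx)), baref))
  }
  if (!is.null(hfold_keep) && is.null(m$hfold)) {
    # carry folded-hydrogen geometry through steps that rebuilt the object;
    # indices are still valid unless atoms were removed
    if (max(c(0L, hfold_keep$atom)) <= n_atoms(m)) m$hfold <- hfold_keep
  }
  fxc <- fx$atoms[, c("nH", "nH1", "nH2", "nH3")]
  rownames(fxc) <- NULL
  list(parent = m, p = pr$p, q = q, groups = emit_groups,
       all_groups = groups,
       fixed = list(counts = fxc, charges = fx$atoms$charge,
                    charge = sum(fx$atoms$charge)),
       original = original,
       metal_disconnected = metal_disconnected,
       taut_bonds = det$taut_bonds,
       changeable_bonds = changeable)
}
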