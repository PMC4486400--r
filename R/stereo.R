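# Perception of tetrahedral, double-bond and allene/cumulene stereo
# elements from 2D wedges or 3D coordinates, and their canonicalization
# against the minimal canonical numbering (including enantiomer selection).
#
# Geometry is reduced once to orientation data that is independent of the
# numbering: a reference parity per tetrahedral element (sign of the
# oriented tetrahedron volume with apices in a fixed reference order) and
# per-substituent side signs for double bonds. Applying a canonical
# numbering then only involves the sign of a rank permutation.

# parity encoding for minimization: "-" < "+" < "?" < "u"
PARITY_ORD <- c(`-` = 1L, `+` = 2L, `?` = 3L, u = 4L)

stereo_warning <- function(...) {
  msg <- paste0(...)
  warning(msg, call. = FALSE)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(NULL)
  v / n
}

# apex vectors for a center: skeletal neighbors (wedge-adjusted in 2D),
# folded hydrogens with geometry, then implicit hydrogens / lone pair as
# the antipode of the others. Returns NULL if geometry is insufficient.
apex_vectors <- function(m, center, nbrs, hrecs, n_missing, is3d, newpsoff) {
  vs <- list()
  cx <- c(m$atoms$x[center], m$atoms$y[center], m$atoms$z[center])
  for (j in nbrs) {
    p <- c(m$atoms$x[j], m$atoms$y[j], m$atoms$z[j])
    v <- p - cx
    if (is3d) {
      v <- unit3(v)
      if (is.null(v)) return(NULL)
    } else {
      k <- bond_index(m, center, j)
      w <- m$bonds$wedge[k]
      zsign <- 0
      if (w %in% c("up", "down")) {
        s <- if (w == "up") 1 else -1
        if (m$bonds$from[k] == center) zsign <- s
        else if (newpsoff) zsign <- -s
      }
      u <- unit3(c(v[1], v[2], 0))
      if (is.null(u)) return(NULL)
      v <- if (zsign == 0) u else
        c(u[1] * cos(pi / 4), u[2] * cos(pi / 4), zsign * sin(pi / 4))
    }
    vs[[length(vs) + 1L]] <- v
  }
  if (!is.null(hrecs) && nrow(hrecs)) for (r in seq_len(nrow(hrecs))) {
    p <- c(hrecs$x[r], hrecs$y[r], hrecs$z[r])
    v <- p - cx
    if (is3d) {
      v <- unit3(v)
      if (is.null(v)) return(NULL)
    } else {
      w <- hrecs$wedge[r]
      zsign <- 0
      if (w %in% c("up", "down")) {
        s <- if (w == "up") 1 else -1
        if (hrecs$narrow_at_center[r]) zsign <- s
        else if (newpsoff) zsign <- -s
      }
      u <- unit3(c(v[1], v[2], 0))
      if (is.null(u)) return(NULL)
      v <- if (zsign == 0) u else
        c(u[1] * cos(pi / 4), u[2] * cos(pi / 4), zsign * sin(pi / 4))
    }
    vs[[length(vs) + 1L]] <- v
  }
  if (n_missing > 1L) return(NULL)
  if (n_missing == 1L) {
    s <- -Reduce(`+`, vs)
    s <- unit3(s)
    if (is.null(s)) return(NULL)
    vs[[length(vs) + 1L]] <- s
  }
  vs
}

# oriented volume sign for apices v0..v3 (list of 4 vectors): +1 if
# v1, v2, v3 appear clockwise when viewed from v0
tetra_sign <- function(vs) {
  mat <- rbind(vs[[2]] - vs[[1]], vs[[3]] - vs[[1]], vs[[4]] - vs[[1]])
  d <- det(mat)
  if (abs(d) < 1e-6) return(0)
  sign(d)
}

# rank keys for substituents: skeletal atoms rank by canonical color at
# evaluation time; hydrogen classes rank below all colors
H_RANKS <- c(nH = -4, nH1 = -3, nH2 = -2, nH3 = -1)
LONE_PAIR_RANK <- -5

#' Perceive possibly stereogenic tetrahedral centers
#'
#' Candidates are 4-coordinate C/Si/Ge/N(+)/P/As and 3-coordinate P/As
#' (lone pair as fourth apex) and S/Se bearing one double-bonded terminal
#' chalcogen. Centers with two hydrogens of one isotope class are skipped;
#' N/S/Se centers with a terminal H neighbor or two -XH(m) terminal
#' neighbors are skipped (phosphines and arsines are kept even with an H).
#' The reference parity is the sign of the oriented tetrahedron volume
#' after normalizing bond lengths and lifting wedge wide-ends by 45
#' degrees (3D coordinates are used directly and wedges ignored; wavy
#' bonds force "unknown").
#'
#' @param m component molecule (with folded-hydrogen records).
#' @param newpsoff logical; wedge interpretation convention.
#' @param isotopic logical; when `FALSE`, hydrogen isotope classes are not
#'   distinguished (a center with two hydrogens of any class is dropped).
#' @return list of records: `atom`, `ref_parity` (+1/-1), `defined`,
#'   `unknown`, `subst` (list of substituent keys in apex order).
#' @export
perceive_tetrahedral <- function(m, newpsoff = FALSE, isotopic = TRUE) {
  adj <- adjacency(m)
  deg <- lengths(adj)
  bs <- bond_order_sum(m)
  hs_all <- m$atoms[, c("nH", "nH1", "nH2", "nH3")]
  is3d <- any(abs(m$atoms$z) > 1e-9) ||
    (!is.null(m$hfold) && nrow(m$hfold) && any(abs(m$hfold$z) > 1e-9))
  out <- list()
  for (i in seq_len(n_atoms(m))) {
    el <- m$atoms$element[i]
    ch <- m$atoms$charge[i]
    nb <- adj[[i]]
    nh_classes <- as.integer(hs_all[i, ])
    nh_tot <- sum(nh_classes)
    nsub <- deg[i] + nh_tot
    has_lp <- FALSE
    single_only <- all(m$bonds$order[vapply(nb, function(j)
      bond_index(m, i, j), 0L)] == 1L) || deg[i] == 0L
    cand <- FALSE
    if (el %in% c("C", "Si", "Ge")) {
      cand <- nsub == 4L && single_only
    } else if (el == "N") {
      cand <- nsub == 4L && single_only && ch == 1L
    } else if (el %in% c("P", "As")) {
      if (nsub == 4L && single_only) cand <- TRUE
      if (nsub == 3L && single_only && ch == 0L) { cand <- TRUE; has_lp <- TRUE }
    } else if (el %in% c("S", "Se")) {
      # sulfoxide-like: three connections, one double bond to a terminal
      # chalcogen, lone pair as fourth apex
      if (deg[i] == 3L && bs[i] == 4 && nh_tot == 0L) {
        dbl <- Filter(function(j)
          m$bonds$order[bond_index(m, i, j)] == 2L, nb)
        if (length(dbl) == 1L && m$atoms$element[dbl] %in% CHALCOGENS) {
          cand <- TRUE; has_lp <- TRUE
        }
      }
      if (deg[i] == 3L && ch == 1L && nh_tot == 0L && single_only) {
        cand <- TRUE; has_lp <- TRUE
      }
    }
    if (!cand) next
    # hydrogen-multiplicity exclusions
    if (isotopic) {
      if (any(nh_classes >= 2L)) next
    } else {
      if (nh_tot >= 2L) next
    }
    # heteroatom exclusions
    if (el %in% c("N", "S", "Se") ||
        (el %in% c("P", "As") && FALSE)) {
      if (nh_tot > 0L) next
      xh <- 0L
      for (j in nb) {
        if (deg[j] == 1L && m$atoms$element[j] %in%
            c("O", "S", "Se", "Te", "N") && total_H(m)[j] > 0L)
          xh <- xh + 1L
      }
      if (xh >= 2L) next
    }
    # substituent keys in reference order: skeletal neighbors ascending,
    # then H classes, then lone pair
    subst <- as.list(nb)
    hrecs <- NULL
    if (!is.null(m$hfold) && nrow(m$hfold)) {
      hrecs <- m$hfold[m$hfold$atom == i, , drop = FALSE]
      # only hydrogens with usable geometry help; others stay implicit
      usable <- logical(nrow(hrecs))
      for (r in seq_len(nrow(hrecs))) {
        d <- c(hrecs$x[r] - m$atoms$x[i], hrecs$y[r] - m$atoms$y[i],
               hrecs$z[r] - m$atoms$z[i])
        usable[r] <- sqrt(sum(d^2)) > 1e-9
      }
      hrecs <- hrecs[usable, , drop = FALSE]
    }
    n_geom_h <- if (is.null(hrecs)) 0L else nrow(hrecs)
    if (!is.null(hrecs) && n_geom_h)
      for (r in seq_len(nrow(hrecs))) subst <- c(subst, hrecs$iso[r])
    n_missing <- (nh_tot - n_geom_h) + as.integer(has_lp)
    if (nh_tot - n_geom_h > 0L) {
      # implicit hydrogens without geometry, in class order
      left <- nh_classes
      if (!is.null(hrecs) && n_geom_h)
        for (r in seq_len(nrow(hrecs))) {
          cls <- hrecs$iso[r]
          left[match(cls, c("nH", "nH1", "nH2", "nH3"))] <-
            left[match(cls, c("nH", "nH1", "nH2", "nH3"))] - 1L
        }
      for (ci in seq_along(left)) if (left[ci] > 0L)
        for (rep_i in seq_len(left[ci]))
          subst <- c(subst, c("nH", "nH1", "nH2", "nH3")[ci])
    }
    if (has_lp) subst <- c(subst, "lp")
    # wavy bond at the center forces unknown parity
    # wavy bonds always force unknown stereochemistry, 2D or 3D
    wavy <- any(vapply(nb, function(j) {
      k <- bond_index(m, i, j)
      m$bonds$wedge[k] == "either"
    }, TRUE))
    if (!is.null(hrecs) && nrow(hrecs))
      wavy <- wavy || any(hrecs$wedge == "either")
    rec <- list(atom = i, subst = subst, ref_parity = 0,
                defined = FALSE, unknown = FALSE)
    if (wavy) {
      rec$unknown <- TRUE
      out[[length(out) + 1L]] <- rec
      next
    }
    # need at least one wedge in 2D
    any_wedge <- any(vapply(nb, function(j) {
      k <- bond_index(m, i, j)
      m$bonds$wedge[k] %in% c("up", "down") &&
        (m$bonds$from[k] == i || newpsoff)
    }, TRUE)) || (!is.null(hrecs) && nrow(hrecs) &&
                  any(hrecs$wedge %in% c("up", "down") &
                      (hrecs$narrow_at_center | newpsoff)))
    if (!is3d && !any_wedge) {
      out[[length(out) + 1L]] <- rec
      next
    }
    vs <- apex_vectors(m, i, nb, hrecs,
                       n_missing = n_missing, is3d = is3d,
                       newpsoff = newpsoff)
    if (is.null(vs) || length(vs) != 4L) {
      out[[length(out) + 1L]] <- rec
      next
    }
    sg <- tetra_sign(vs)
    if (sg == 0) {
      stereo_warning("degenerate geometry at atom ", i,
                     "; parity left undefined")
      out[[length(out) + 1L]] <- rec
      next
    }
    # centroid check: center inside the apex tetrahedron
    ctr <- Reduce(`+`, vs) / 4
    if (sqrt(sum(ctr^2)) > 0.95)
      stereo_warning("central atom ", i, " lies outside its tetrahedron")
    rec$ref_parity <- sg
    rec$defined <- TRUE
    out[[length(out) + 1L]] <- rec
  }
  out
}

# smallest ring containing bond (a, b); Inf if acyclic
ring_size_of_bond <- function(m, a, b) {
  adj <- adjacency(m)
  dist <- rep(NA_integer_, n_atoms(m))
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (v == a && w == b) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  if (is.na(dist[b])) Inf else dist[b] + 1L
}

#' Perceive possibly stereogenic double bonds and cumulenes
#'
#' Rigid double bonds (and cumulenes with three double bonds) between C/N
#' atoms are candidates; bonds in rings of fewer than 8 atoms, tautomeric
#' bonds and bonds changeable by mobile charges are not. Allenes (two
#' double bonds) become tetrahedral-class elements handled separately.
#' Geometry gives each end-substituent a side sign relative to the bond
#' axis; parity is evaluated against canonical numbers later.
#'
#' @param m component molecule.
#' @param excluded_bonds bond indices that cannot be stereogenic.
#' @return list with `bonds` (double-bond/cumulene records) and `allenes`.
#' @export
perceive_double_bonds <- function(m, excluded_bonds = integer(0)) {
  adj <- adjacency(m)
  deg <- lengths(adj)
  is3d <- any(abs(m$atoms$z) > 1e-9)
  dbl <- which(m$bonds$order == 2L)
  # cumulated systems: chains of consecutive double bonds through
  # 2-coordinate middle atoms
  in_chain <- rep(FALSE, length(dbl))
  chains <- list()
  for (ii in seq_along(dbl)) {
    if (in_chain[ii]) next
    k <- dbl[ii]
    chain_atoms <- c(m$bonds$a[k], m$bonds$b[k])
    chain_bonds <- k
    repeat {
      ext <- FALSE
      for (endpos in c(1L, length(chain_atoms))) {
        e <- chain_atoms[endpos]
        if (deg[e] == 2L) {
          ks <- which((m$bonds$a == e | m$bonds$b == e) &
                      m$bonds$order == 2L)
          ks <- setdiff(ks, chain_bonds)
          if (length(ks) == 1L) {
            nxt <- setdiff(c(m$bonds$a[ks], m$bonds$b[ks]), e)
            if (!(nxt %in% chain_atoms)) {
              chain_bonds <- c(chain_bonds, ks)
              chain_atoms <- if (endpos == 1L) c(nxt, chain_atoms)
                             else c(chain_atoms, nxt)
              ext <- TRUE
            }
          }
        }
      }
      if (!ext) break
    }
    in_chain[match(chain_bonds, dbl)] <- TRUE
    chains[[length(chains) + 1L]] <-
      list(atoms = chain_atoms, bonds = chain_bonds)
  }
  bonds_out <- list()
  allenes_out <- list()
  hs <- total_H(m)
  end_subst <- function(e, partner) {
    # single-bonded skeletal neighbors of an end atom
    Filter(function(j) {
      j != partner && m$bonds$order[bond_index(m, e, j)] == 1L
    }, adj[[e]])
  }
  side_sign_2d <- function(pa, pb, pn) {
    v <- pb - pa
    w <- pn - pa
    s <- v[1] * w[2] - v[2] * w[1]
    if (abs(s) < 1e-9) 0 else sign(s)
  }
  side_sign_3d <- function(pa, pb, pn) {
    axis <- unit3(pb - pa)
    if (is.null(axis)) return(0)
    w <- pn - pa
    w <- w - sum(w * axis) * axis
    list(vec = w)
  }
  for (ch in chains) {
    nb_dbl <- length(ch$bonds)
    if (nb_dbl == 2L) {
      # allene
      a <- ch$atoms[1]; y <- ch$atoms[2]; z <- ch$atoms[length(ch$atoms)]
      if (length(ch$atoms) != 3L) next
      allenes_out[[length(allenes_out) + 1L]] <-
        perceive_allene(m, a, y, z, is3d)
      next
    }
    if (!(nb_dbl %in% c(1L, 3L))) next
    if (any(ch$bonds %in% excluded_bonds)) next
    e1 <- ch$atoms[1]
    e2 <- ch$atoms[length(ch$atoms)]
    if (!all(m$atoms$element[c(e1, e2)] %in% c("C", "N"))) next
    if (nb_dbl == 1L) {
      rs <- ring_size_of_bond(m, e1, e2)
      if (rs < 8L) next
    }
    s1 <- end_subst(e1, ch$atoms[2])
    s2 <- end_subst(e2, ch$atoms[length(ch$atoms) - 1L])
    # an end with no skeletal single neighbor offers nothing to compare
    if (!length(s1) || !length(s2)) {
      # N ends may use the lone pair side; only =N- with one neighbor
      if (!(m$atoms$element[e1] == "N" && length(s1) == 0L && hs[e1] == 0L) &&
          !(m$atoms$element[e2] == "N" && length(s2) == 0L && hs[e2] == 0L))
        next
    }
    if (!length(s1) && hs[e1] > 0L) next
    if (!length(s2) && hs[e2] > 0L) next
    # ends with two hydrogens (no skeletal substituent) are not stereogenic
    if (!length(s1) && m$atoms$element[e1] == "C") next
    if (!length(s2) && m$atoms$element[e2] == "C") next
    pa <- c(m$atoms$x[e1], m$atoms$y[e1], m$atoms$z[e1])
    pb <- c(m$atoms$x[e2], m$atoms$y[e2], m$atoms$z[e2])
    have_geom <- sqrt(sum((pb - pa)^2)) > 1e-9 &&
      (is3d || any(abs(c(m$atoms$x, m$atoms$y)) > 1e-9))
    sides1 <- list()
    sides2 <- list()
    collinear <- FALSE
    if (have_geom) {
      for (j in s1) {
        pn <- c(m$atoms$x[j], m$atoms$y[j], m$atoms$z[j])
        if (is3d) {
          ss <- side_sign_3d(pa, pb, pn)
          sides1[[as.character(j)]] <- ss$vec
        } else {
          sides1[[as.character(j)]] <- side_sign_2d(pa, pb, pn)
          if (sides1[[as.character(j)]] == 0) collinear <- TRUE
        }
      }
      for (j in s2) {
        pn <- c(m$atoms$x[j], m$atoms$y[j], m$atoms$z[j])
        if (is3d) {
          ss <- side_sign_3d(pa, pb, pn)
          sides2[[as.character(j)]] <- ss$vec
        } else {
          sides2[[as.character(j)]] <- side_sign_2d(pb, pa, pn) * -1
          if (sides2[[as.character(j)]] == 0) collinear <- TRUE
        }
      }
    }
    if (collinear)
      stereo_warning("collinear substituents at double bond ", e1, "-", e2,
                     "; parity left undefined")
    defined <- have_geom && !collinear &&
      (length(sides1) || m$atoms$element[e1] == "N") &&
      (length(sides2) || m$atoms$element[e2] == "N")
    bonds_out[[length(bonds_out) + 1L]] <- list(
      ends = c(e1, e2), subst1 = s1, subst2 = s2,
      sides1 = sides1, sides2 = sides2, is3d = is3d,
      defined = defined && length(sides1) > 0L && length(sides2) > 0L,
      unknown = FALSE,
      kind = if (nb_dbl == 1L) "double" else "cumulene3")
  }
  list(bonds = bonds_out, allenes = allenes_out)
}

perceive_allene <- function(m, a, y, z, is3d) {
  adj <- adjacency(m)
  s1 <- Filter(function(j) j != y &&
                 m$bonds$order[bond_index(m, a, j)] == 1L, adj[[a]])
  s2 <- Filter(function(j) j != y &&
                 m$bonds$order[bond_index(m, z, j)] == 1L, adj[[z]])
  rec <- list(center = y, ends = c(a, z), subst1 = s1, subst2 = s2,
              ref_parity = 0, defined = FALSE, unknown = FALSE,
              h1 = total_H(m)[a], h2 = total_H(m)[z])
  # each end needs at most one hydrogen and at least 1 substituent in total
  if (rec$h1 > 1L || rec$h2 > 1L) return(rec)
  if (length(s1) + rec$h1 != 2L || length(s2) + rec$h2 != 2L) return(rec)
  # geometry: 3D coordinates directly, or wedges on the bonds at one end
  apex <- function(e, subs) lapply(subs, function(j) {
    p <- c(m$atoms$x[j] - m$atoms$x[e], m$atoms$y[j] - m$atoms$y[e],
           m$atoms$z[j] - m$atoms$z[e])
    k <- bond_index(m, e, j)
    if (!is3d) {
      w <- m$bonds$wedge[k]
      zs <- 0
      if (w == "up" && m$bonds$from[k] == e) zs <- 1
      if (w == "down" && m$bonds$from[k] == e) zs <- -1
      u <- unit3(c(p[1], p[2], 0))
      if (is.null(u)) return(NULL)
      if (zs == 0) u else c(u[1] * cos(pi / 4), u[2] * cos(pi / 4),
                            zs * sin(pi / 4))
    } else unit3(p)
  })
  v1 <- apex(a, s1)
  v2 <- apex(z, s2)
  if (any(vapply(c(v1, v2), is.null, TRUE))) return(rec)
  # hydrogens at an end take the in-plane position opposite the skeletal
  # substituent at that end
  if (rec$h1 == 1L) v1 <- c(v1, list(-v1[[1]] * c(1, 1, -1)))
  if (rec$h2 == 1L) v2 <- c(v2, list(-v2[[1]] * c(1, 1, -1)))
  if (!is3d) {
    wedged <- any(m$bonds$wedge[c(vapply(s1, function(j)
      bond_index(m, a, j), 0L), vapply(s2, function(j)
        bond_index(m, z, j), 0L))] %in% c("up", "down"))
    if (!wedged) return(rec)
  }
  vs <- c(v1, v2)
  if (length(vs) != 4L) return(rec)
  sg <- tetra_sign(vs)
  if (sg == 0) return(rec)
  rec$ref_parity <- sg
  rec$defined <- TRUE
  # reference substituent order: subst1 atoms, [H], subst2 atoms, [H]
  subs <- c(as.list(s1), if (rec$h1) "nH", as.list(s2), if (rec$h2) "nH")
  rec$subst <- subs
  rec
}

# permutation sign of ranks relative to reference order
perm_sign <- function(ranks) {
  n <- length(ranks)
  s <- 1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (ranks[i] > ranks[j]) s <- -s
    if (ranks[i] == ranks[j]) return(0)
  }
  s
}

subst_rank <- function(keys, nu) {
  vapply(keys, function(k) {
    if (is.character(k)) {
      if (k == "lp") LONE_PAIR_RANK else unname(H_RANKS[k])
    } else as.numeric(nu[k])
  }, 0)
}

# evaluate a tetrahedral record under a numbering: "+", "-", "?" or "u"
eval_tetra <- function(rec, nu) {
  if (rec$unknown) return("u")
  if (!rec$defined) return("?")
  ranks <- subst_rank(rec$subst, nu)
  ps <- perm_sign(ranks)
  if (ps == 0) return("?")
  if (rec$ref_parity * ps > 0) "+" else "-"
}

# evaluate a double-bond record: parity from the side signs of the
# larger-ranked single-bond neighbor at each end
eval_dbond <- function(rec, nu, m) {
  pick <- function(subs, end) {
    if (!length(subs)) return(NULL)
    subs[[which.max(nu[unlist(subs)])]]
  }
  j1 <- pick(rec$subst1, rec$ends[1])
  j2 <- pick(rec$subst2, rec$ends[2])
  if (is.null(j1) || is.null(j2)) return("?")
  if (rec$unknown) return("u")
  if (!rec$defined) return("?")
  s1 <- rec$sides1[[as.character(j1)]]
  s2 <- rec$sides2[[as.character(j2)]]
  if (rec$is3d) {
    d <- sum(s1 * s2)
    if (abs(d) < 1e-9) return("?")
    if (d > 0) "-" else "+"
  } else {
    if (s1 == 0 || s2 == 0) return("?")
    if (s1 * s2 > 0) "-" else "+"
  }
}

eval_allene <- function(rec, nu) {
  if (rec$unknown) return("u")
  if (!rec$defined) return("?")
  ranks <- subst_rank(rec$subst, nu)
  ps <- perm_sign(ranks)
  if (ps == 0) return("?")
  if (rec$ref_parity * ps > 0) "+" else "-"
}

# stereo lists for one numbering; returns list(D1, D2, D3, entries)
stereo_lists <- function(raw, nu, m, invert = FALSE) {
  flip <- function(p) {
    if (!invert) return(p)
    if (p == "+") "-" else if (p == "-") "+" else p
  }
  d1 <- list()
  for (rec in raw$bonds) {
    p <- eval_dbond(rec, nu, m)  # reflection leaves cis/trans unchanged
    cs <- sort(nu[rec$ends], decreasing = TRUE)
    d1[[length(d1) + 1L]] <- list(c1 = cs[1], c2 = cs[2], p = p,
                                  rec = rec)
  }
  if (length(d1)) {
    keys <- vapply(d1, function(e) e$c1 * 10000 + e$c2, 0)
    d1 <- d1[order(keys)]
  }
  d2 <- list()
  for (rec in raw$allenes) {
    p <- flip(eval_allene(rec, nu))
    d2[[length(d2) + 1L]] <- list(c = nu[rec$center], p = p, rec = rec)
  }
  if (length(d2)) d2 <- d2[order(vapply(d2, function(e) e$c, 0))]
  d3 <- list()
  for (rec in raw$tetra) {
    p <- flip(eval_tetra(rec, nu))
    d3[[length(d3) + 1L]] <- list(c = nu[rec$atom], p = p, rec = rec)
  }
  if (length(d3)) d3 <- d3[order(vapply(d3, function(e) e$c, 0))]
  num <- unlist(c(
    lapply(d1, function(e) c(e$c1, e$c2, PARITY_ORD[[e$p]])),
    lapply(d2, function(e) c(e$c, PARITY_ORD[[e$p]])),
    lapply(d3, function(e) c(e$c, PARITY_ORD[[e$p]]))))
  if (is.null(num)) num <- numeric(0)
  list(d1 = d1, d2 = d2, d3 = d3, key = num)
}

#' Canonical stereo parities of a component
#'
#' Evaluates all stereo elements under every numbering that attains the
#' canonical minimum, keeps the lexicographically smallest (double bonds,
#' then allenes, then tetrahedral centers; parity order "-" < "+" < "?" <
#' "u"), removes pseudo-stereogenic elements whose parities can be flipped
#' in isolation by an automorphism (when at most two such elements exist),
#' and selects between the structure and its mirror image.
#'
#' @param m component molecule.
#' @param nus list of minimal canonical numberings.
#' @param raw output of the perception functions
#'   (`list(tetra=, bonds=, allenes=)`).
#' @param mode one of "absolute", "relative", "racemic".
#' @return stereo record: `b`, `t` entry lists, `m_flag`, `s_flag`,
#'   `chiral` plus the numbering used.
#' @export
canonical_parities <- function(m, nus, raw, mode = "absolute") {
  empty <- list(b = list(), t = list(), m_flag = NA_integer_,
                s_flag = NA_integer_, chiral = FALSE)
  if (!length(raw$tetra) && !length(raw$bonds) && !length(raw$allenes))
    return(empty)
  minimize <- function(invert) {
    best <- NULL
    for (nu in nus) {
      ls <- stereo_lists(raw, nu, m, invert = invert)
      if (is.null(best) || cmp_vec_flex(ls$key, best$key) < 0L)
        best <- ls
    }
    best
  }
  # pseudo-stereo removal: drop elements whose parity differs between two
  # minimal numberings while everything else is unchanged
  repeat {
    base <- minimize(FALSE)
    removable <- integer(0)
    nel <- length(base$d1) + length(base$d2) + length(base$d3)
    if (nel && length(nus) > 1L) {
      keys <- lapply(nus, function(nu) stereo_lists(raw, nu, m)$key)
      widths <- c(vapply(base$d1, function(e) 3L, 0L),
                  vapply(base$d2, function(e) 2L, 0L),
                  vapply(base$d3, function(e) 2L, 0L))
      offs <- cumsum(c(0L, widths))
      for (el in seq_len(nel)) {
        pos <- offs[el] + widths[el]  # parity slot of element el
        for (k2 in keys) {
          if (length(k2) != length(keys[[1]])) next
          diffs <- which(keys[[1]] != k2)
          if (length(diffs) == 1L && diffs == pos) {
            removable <- c(removable, el)
            break
          }
        }
      }
      removable <- unique(removable)
    }
    if (length(removable) && length(removable) <= 2L) {
      raw <- drop_elements(raw, base, removable)
      if (!length(raw$tetra) && !length(raw$bonds) && !length(raw$allenes))
        return(empty)
      next
    }
    break
  }
  orig <- minimize(FALSE)
  inv <- minimize(TRUE)
  cc <- cmp_vec_flex(inv$key, orig$key)
  chiral <- cc != 0L
  chosen <- if (cc < 0L) inv else orig
  m_flag <- if (!chiral) NA_integer_ else if (cc < 0L) 1L else 0L
  s_flag <- if (!chiral) NA_integer_ else
    switch(mode, absolute = 1L, relative = 2L, racemic = 3L)
  if (mode %in% c("relative", "racemic") && chiral) m_flag <- NA_integer_
  list(b = chosen$d1,
       t = c(chosen$d2, chosen$d3),
       m_flag = m_flag, s_flag = s_flag, chiral = chiral)
}

# lexicographic comparison tolerating unequal lengths (shorter, equal
# prefix counts as smaller)
cmp_vec_flex <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- a[seq_len(n)] != b[seq_len(n)]
    if (any(d)) {
      i <- which.max(d)
      return(if (a[i] < b[i]) -1L else 1L)
    }
  }
  if (length(a) < length(b)) -1L else if (length(a) > length(b)) 1L else 0L
}

drop_elements <- function(raw, base, removable) {
  n1 <- length(base$d1); n2 <- length(base$d2)
  keep_b <- rep(TRUE, length(raw$bonds))
  keep_a <- rep(TRUE, length(raw$allenes))
  keep_t <- rep(TRUE, length(raw$tetra))
  for (el in removable) {
    if (el <= n1) {
      rec <- base$d1[[el]]$rec
      keep_b[vapply(raw$bonds, function(r)
        identical(r$ends, rec$ends), TRUE)] <- FALSE
    } else if (el <= n1 + n2) {
      rec <- base$d2[[el - n1]]$rec
      keep_a[vapply(raw$allenes, function(r)
        identical(r$center, rec$center), TRUE)] <- FALSE
    } else {
      rec <- base$d3[[el - n1 - n2]]$rec
      keep_t[vapply(raw$tetra, function(r)
        identical(r$atom, rec$atom), TRUE)] <- FALSE
    }
  }
  list(bonds = raw$bonds[keep_b], allenes = raw$allenes[keep_a],
       tetra = raw$tetra[keep_t])
}

#' Filter stereo output per creation options
#'
#' Default behavior drops all stereo layers when no defined parity exists;
#' SUU keeps undefined/unknown entries. SLUUD prints explicit unknowns as
#' "u" instead of "?".
#'
#' @param sr stereo record from [canonical_parities()].
#' @param suu logical; always show unknown/undefined stereo.
#' @param sluud logical; distinct letter for explicit unknowns.
#' @return adjusted stereo record (entries may be empty).
#' @export
apply_stereo_options <- function(sr, suu = FALSE, sluud = FALSE) {
  all_entries <- c(sr$b, sr$t)
  any_defined <- any(vapply(all_entries, function(e)
    e$p %in% c("+", "-"), TRUE))
  if (!any_defined && !suu)
    return(list(b = list(), t = list(), m_flag = NA_integer_,
                s_flag = NA_integer_, chiral = FALSE))
  if (!sluud) {
    sr$b <- lapply(sr$b, function(e) { if (e$p == "u") e$p <- "?"; e })
    sr$t <- lapply(sr$t, function(e) { if (e$p == "u") e$p <- "?"; e })
  }
  sr
}
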