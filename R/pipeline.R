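# Top-level pipeline: molfile/molecule -> normalization -> per-component
# canonicalization and stereo -> serialized identifier (+ hashed key).

#' Identifier generation options
#'
#' Perception options (`do_not_add_h`, `s_non`, `newpsoff`) keep the
#' standard prefix; stereo interpretation (`srel`, `srac`, `sucf`) and
#' creation options (`suu`, `sluud`, `rec_met`, `fixed_h`) make the
#' identifier non-standard.
#'
#' @param do_not_add_h skip implicit hydrogen addition.
#' @param s_non ignore all stereo input.
#' @param newpsoff wedge affects both of its atoms, not only the narrow
#'   end.
#' @param srel relative stereochemistry.
#' @param srac racemic stereochemistry.
#' @param sucf take absolute/relative from the molfile chiral flag.
#' @param suu always show unknown/undefined stereo.
#' @param sluud letter `u` for explicit unknowns.
#' @param rec_met append the reconnected-metal layer.
#' @param fixed_h append the fixed-hydrogen layer.
#' @return options object.
#' @export
inchi_options <- function(do_not_add_h = FALSE, s_non = FALSE,
                          newpsoff = FALSE, srel = FALSE, srac = FALSE,
                          sucf = FALSE, suu = FALSE, sluud = FALSE,
                          rec_met = FALSE, fixed_h = FALSE) {
  opts <- list(do_not_add_h = do_not_add_h, s_non = s_non,
               newpsoff = newpsoff, srel = srel, srac = srac, sucf = sucf,
               suu = suu, sluud = sluud, rec_met = rec_met,
               fixed_h = fixed_h)
  opts$standard <- !(srel || srac || sucf || suu || sluud || rec_met ||
                     fixed_h)
  class(opts) <- "inchikit_options"
  opts
}

#' Generate the layered identifier for a structure
#'
#' @param x molfile text, path to a molfile, or an `inchikit_mol`.
#' @param options an [inchi_options()] object.
#' @return object of class `inchikit_ident` with fields `text`,
#'   `standard`, `p`, `q`, plus per-component details.
#' @export
inchi <- function(x, options = inchi_options()) {
  m <- if (inherits(x, "inchikit_mol")) x
       else if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
         read_molfile(readLines(x))
       else read_molfile(x)
  if (!options$do_not_add_h) m <- add_implicit_hydrogens(m)
  norm <- normalize_structure(m)
  parent <- norm$parent

  comps_idx <- split(seq_len(n_atoms(parent)), connected_components(parent))
  comps <- list()
  stereo_mode <- if (options$srel) "relative"
                 else if (options$srac) "racemic"
                 else if (options$sucf) {
                   if (isTRUE(m$chiral)) "absolute" else "relative"
                 } else "absolute"
  for (ci in seq_along(comps_idx)) {
    idx <- sort(comps_idx[[ci]])
    sub <- sub_molecule(parent, idx)
    map <- match(seq_len(n_atoms(parent)), idx)
    lgroups <- list()
    for (g in norm$groups) if (all(g$members %in% idx)) {
      g$members <- map[g$members]
      lgroups[[length(lgroups) + 1L]] <- g
    }
    lfixed <- norm$fixed$counts[idx, , drop = FALSE]
    rownames(lfixed) <- NULL
    cres <- canonicalize(sub, lgroups, lfixed)
    nu <- cres$mob$nu
    adj <- adjacency(sub)

    # stereo
    sr <- list(b = list(), t = list(), m_flag = NA_integer_,
               s_flag = NA_integer_, chiral = FALSE)
    if (!options$s_non) {
      excl <- integer(0)
      for (gk in c("taut_bonds", "changeable_bonds")) {
        gb <- norm[[gk]]
        if (length(gb)) {
          pb <- parent$bonds[gb, , drop = FALSE]
          pb <- pb[pb$a %in% idx & pb$b %in% idx, , drop = FALSE]
          if (nrow(pb))
            excl <- c(excl, vapply(seq_len(nrow(pb)), function(r)
              bond_index(sub, map[pb$a[r]], map[pb$b[r]]), 0L))
        }
      }
      raw <- list(tetra = perceive_tetrahedral(sub, options$newpsoff,
                                               isotopic = FALSE))
      pd <- perceive_double_bonds(sub, excluded_bonds = unique(excl))
      raw$bonds <- pd$bonds
      raw$allenes <- pd$allenes
      sr <- canonical_parities(sub, cres$mob$nus, raw, mode = stereo_mode)
      sr <- apply_stereo_options(sr, suu = options$suu,
                                 sluud = options$sluud)
      if (options$sucf && isTRUE(m$chiral) && !sr$chiral &&
          (length(sr$t) || length(sr$b)))
        warning("Not chiral", call. = FALSE)
    }

    # component charge: residual atom charges plus pooled negatives
    qc <- sum(sub$atoms$charge) - sum(vapply(lgroups, function(g)
      g$nneg, 0L))
    hs <- total_H(sub)
    grp_H <- sum(vapply(lgroups, function(g) g$nH, 0L))

    # isotopic layer (exchangeable mobile isotopic H reported separately)
    iso_nu <- cres$iso$nu
    iso_str <- emit_iso_entries(sub, iso_nu)
    ex <- c(sum(vapply(lgroups, function(g) g$exH1, 0L)),
            sum(vapply(lgroups, function(g) g$exH2, 0L)),
            sum(vapply(lgroups, function(g) g$exH3, 0L)))
    ih_str <- emit_exchangeable(ex)

    # fixed-H layer content
    f_h <- ""
    f_q <- qc
    f_formula <- NULL
    f_i <- ""
    fcounts <- lfixed$nH + lfixed$nH1 + lfixed$nH2 + lfixed$nH3
    fixed_differs <- length(lgroups) > 0L ||
      !identical(as.integer(fcounts), as.integer(hs)) ||
      sum(norm$fixed$charges[idx]) != qc
    if (options$fixed_h && fixed_differs) {
      fnu <- cres$fix$nu
      # atoms whose drawn hydrogen count differs from the parent's
      memb <- which(fcounts > 0L & fcounts != hs)
      fh_on <- integer(n_atoms(sub))
      fh_on[memb] <- fcounts[memb]
      f_h <- emit_h(fh_on, fnu, list())
      f_q <- sum(norm$fixed$charges[idx])
      fsub <- sub
      fsub$atoms$nH <- lfixed$nH
      fsub$atoms$nH1 <- lfixed$nH1
      fsub$atoms$nH2 <- lfixed$nH2
      fsub$atoms$nH3 <- lfixed$nH3
      f_i <- emit_iso_entries(fsub, cres$fixiso$nu)
      if (identical(f_i, iso_str)) f_i <- ""
      ffml <- hill_formula(fsub)
      f_formula <- ffml
    }

    formula <- hill_formula_with_extra_H(sub, grp_H)
    comps[[length(comps) + 1L]] <- list(
      natoms = n_atoms(sub),
      formula = formula,
      c = emit_c(adj, nu),
      h = emit_h(hs, nu, lgroups),
      q = qc,
      q_str = if (qc != 0L) fmt_signed(qc) else "",
      b = emit_b(sr$b),
      t = emit_t(sr$t),
      m = sr$m_flag,
      s = sr$s_flag,
      i = iso_str,
      ih = ih_str,
      f_formula = if (is.null(f_formula)) formula else f_formula,
      f_h = f_h,
      f_q_str = if (options$fixed_h && f_q != qc) fmt_signed(f_q) else "",
      f_i = f_i,
      chiral = sr$chiral
    )
  }
  comps <- order_components(comps)

  reconnected <- NULL
  if (options$rec_met && isTRUE(norm$metal_disconnected)) {
    ropts <- options
    ropts$rec_met <- FALSE
    rid <- inchi_on_molecule_no_disconnect(norm$original, ropts)
    reconnected <- sub("^InChI=1S?/", "", rid$text)
  }

  text <- assemble(comps, p = norm$p, standard = options$standard,
                   fixed_h = options$fixed_h, reconnected = reconnected)
  structure(list(text = text, standard = options$standard, p = norm$p,
                 q = sum(vapply(comps, function(cp) cp$q, 0)),
                 components = comps, normalization = norm),
            class = "inchikit_ident")
}

# serialization of the reconnected structure: same pipeline minus the
# disconnection steps
inchi_on_molecule_no_disconnect <- function(m, options) {
  norm <- normalize_structure_no_disconnect(m)
  parent <- norm$parent
  comps_idx <- split(seq_len(n_atoms(parent)), connected_components(parent))
  comps <- list()
  for (idx in comps_idx) {
    idx <- sort(idx)
    sub <- sub_molecule(parent, idx)
    map <- match(seq_len(n_atoms(parent)), idx)
    lgroups <- list()
    for (g in norm$groups) if (all(g$members %in% idx)) {
      g$members <- map[g$members]
      lgroups[[length(lgroups) + 1L]] <- g
    }
    cres <- canonicalize(sub, lgroups)
    nu <- cres$mob$nu
    qc <- sum(sub$atoms$charge) - sum(vapply(lgroups, function(g)
      g$nneg, 0L))
    grp_H <- sum(vapply(lgroups, function(g) g$nH, 0L))
    comps[[length(comps) + 1L]] <- list(
      natoms = n_atoms(sub),
      formula = hill_formula_with_extra_H(sub, grp_H),
      c = emit_c(adjacency(sub), nu),
      h = emit_h(total_H(sub), nu, lgroups),
      q = qc,
      q_str = if (qc != 0L) fmt_signed(qc) else "",
      b = "", t = "", m = NA_integer_, s = NA_integer_,
      i = emit_iso_entries(sub, cres$iso$nu), ih = "",
      f_formula = hill_formula_with_extra_H(sub, grp_H),
      f_h = "", f_q_str = "", f_i = "", chiral = FALSE)
  }
  comps <- order_components(comps)
  list(text = assemble(comps, p = norm$p, standard = FALSE))
}

normalize_structure_no_disconnect <- function(m) {
  m <- fix_drawing(m)
  m <- resolve_radicals_and_kekulize(m)
  pr <- normalize_protons(m)
  m <- pr$parent
  det <- detect_mobile_H(m)
  emit_groups <- Filter(function(g) g$nH > 0L, det$groups)
  q <- sum(m$atoms$charge)
  for (g in emit_groups) for (i in g$members) {
    m$atoms$nH[i] <- 0L
    m$atoms$nH1[i] <- 0L
    m$atoms$nH2[i] <- 0L
    m$atoms$nH3[i] <- 0L
    if (m$atoms$charge[i] == -1L) m$atoms$charge[i] <- 0L
  }
  list(parent = m, p = pr$p, q = q, groups = emit_groups,
       taut_bonds = det$taut_bonds, changeable_bonds = integer(0))
}

# Hill formula including pooled mobile-group hydrogens
hill_formula_with_extra_H <- function(m, extra_H) {
  if (extra_H == 0L) return(hill_formula(m))
  m2 <- m
  if (n_atoms(m2)) m2$atoms$nH[1] <- m2$atoms$nH[1] + extra_H
  hill_formula(m2)
}

#' @export
print.inchikit_ident <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.inchikit_ident <- function(x, ...) x$text

as_identifier_text <- function(s) {
  if (inherits(s, "inchikit_ident")) s$text else as.character(s)
}

#' Identifier plus hashed key in one call
#'
#' @param x molfile text/path or molecule.
#' @param options an [inchi_options()] object.
#' @return list with `identifier` and `key` objects.
#' @export
inchi_with_key <- function(x, options = inchi_options()) {
  id <- inchi(x, options)
  list(identifier = id, key = make_key(id))
}
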