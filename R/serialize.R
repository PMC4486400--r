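# Layer-by-layer serialization: skeletal-connections traversal, hydrogen
# sublayers, charge/protonation, stereo, isotopic and fixed-H layers,
# multi-component ordering with multipliers, and final assembly.

# ---- skeletal connections (/c) --------------------------------------------

#' Render the skeletal-connections layer of one component
#'
#' Walks the canonical structure depth-first, starting from the
#' smallest-numbered terminal atom (or atom 1 in its absence), always
#' descending to the smallest unvisited neighbor; ring closures are
#' emitted where first encountered. At every atom all branch subtrees are
#' parenthesized together (comma-separated, shortest first, ties by
#' smaller leading number) and the longest subtree continues the chain.
#'
#' @param adj adjacency list of the component.
#' @param nu canonical numbering.
#' @return the `/c` payload string (empty for a single atom).
#' @export
emit_c <- function(adj, nu) {
  n <- length(nu)
  if (n <= 1L || !sum(lengths(adj))) return("")
  col2atom <- order(nu)
  nbc <- lapply(seq_len(n), function(c) sort(nu[adj[[col2atom[c]]]]))
  deg <- lengths(nbc)
  term <- which(deg == 1L)
  start <- if (length(term)) min(term) else 1L
  visited <- rep(FALSE, n)
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  build <- function(c) {
    visited[c] <<- TRUE
    items <- list()
    for (w in nbc[[c]]) {
      k <- ekey(c, w)
      if (!is.null(used[[k]])) next
      used[[k]] <- TRUE
      if (visited[w]) {
        items[[length(items) + 1L]] <-
          list(str = as.character(w), tokens = 1L, first = w)
      } else {
        sub <- build(w)
        items[[length(items) + 1L]] <- sub
      }
    }
    if (!length(items))
      return(list(str = as.character(c), tokens = 1L, first = c))
    keys <- vapply(items, function(it) it$tokens * 100000 + it$first, 0)
    items <- items[order(keys)]
    cont <- items[[length(items)]]
    branches <- items[-length(items)]
    s <- as.character(c)
    if (length(branches))
      s <- paste0(s, "(", paste(vapply(branches, `[[`, "", "str"),
                                collapse = ","), ")")
    s <- paste0(s, if (length(branches)) "" else "-", cont$str)
    list(str = s, tokens = 1L + sum(vapply(items, `[[`, 0L, "tokens")),
         first = c)
  }
  build(start)$str
}

# ---- hydrogens (/h) -------------------------------------------------------

format_ranges <- function(v) {
  v <- sort(unique(v))
  if (!length(v)) return("")
  runs <- split(v, cumsum(c(1L, diff(v) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r)
    else paste0(r[1], "-", r[length(r)])
  }, ""), collapse = ",")
}

#' Render the hydrogens layer of one component
#'
#' Immobile hydrogens first (`1-2,5-6H`, `3H2`, ... by ascending count),
#' then mobile groups as `(H<k>,a,b,...)` sorted by hydrogen count, then
#' member numbers.
#'
#' @param hs immobile hydrogen count per atom.
#' @param nu canonical numbering.
#' @param groups mobile groups (local atom indices).
#' @return `/h` payload string (may be empty).
#' @export
emit_h <- function(hs, nu, groups = list()) {
  parts <- character(0)
  byc <- hs[order(nu)]
  for (k in sort(unique(byc[byc > 0L]))) {
    cols <- which(byc == k)
    parts <- c(parts, paste0(format_ranges(cols), "H",
                             if (k > 1L) k else ""))
  }
  if (length(groups)) {
    gitems <- lapply(groups, function(g) {
      mem <- sort(nu[g$members])
      list(nH = g$nH, nneg = g$nneg, mem = mem)
    })
    keys <- vapply(gitems, function(g)
      paste(sprintf("%06d", c(g$nH, g$mem)), collapse = ","), "")
    gitems <- gitems[order(keys)]
    gs <- vapply(gitems, function(g) {
      paste0("(H", if (g$nH > 1L) g$nH else "",
             if (g$nneg > 0L) paste0("-", if (g$nneg > 1L) g$nneg else ""),
             ",", paste(g$mem, collapse = ","), ")")
    }, "")
    parts <- c(parts, paste(gs, collapse = ""))
  }
  paste(parts, collapse = ",")
}

# ---- charge/protonation ---------------------------------------------------

fmt_signed <- function(v) {
  if (v > 0L) paste0("+", v) else as.character(v)
}

# ---- stereo (/b /t) -------------------------------------------------------

emit_b <- function(entries) {
  if (!length(entries)) return("")
  paste(vapply(entries, function(e)
    paste0(e$c1, "-", e$c2, e$p), ""), collapse = ",")
}

emit_t <- function(entries) {
  if (!length(entries)) return("")
  entries <- entries[order(vapply(entries, function(e) e$c, 0))]
  paste(vapply(entries, function(e) paste0(e$c, e$p), ""), collapse = ",")
}

# ---- isotopes (/i) --------------------------------------------------------

#' Render isotopic layer entries for one component
#'
#' Entries `<canonical><+shift><H|D|T><count>` in ascending canonical
#' number; only atoms with a mass label or attached isotopic hydrogens
#' appear.
#'
#' @param m component molecule (atom isotope fields as to be reported).
#' @param nu canonical numbering of the isotopic stage.
#' @return `/i` payload string (may be empty).
#' @export
emit_iso_entries <- function(m, nu) {
  sh <- iso_shift_raw(m)
  ent <- character(0)
  for (c in seq_along(nu)) {
    i <- order(nu)[c]
    s <- sh[i]
    hpart <- ""
    for (cls in c("nH1", "nH2", "nH3")) {
      k <- m$atoms[[cls]][i]
      if (k > 0L)
        hpart <- paste0(hpart, switch(cls, nH1 = "H", nH2 = "D", nH3 = "T"),
                        if (k > 1L) k else "")
    }
    if (s == 0L && !nzchar(hpart)) next
    spart <- if (s != 0L) fmt_signed(s) else ""
    ent <- c(ent, paste0(c, spart, hpart))
  }
  paste(ent, collapse = ",")
}

# raw isotopic shift (mass - rounded mass), without the increment used in
# canonicalization weights: the printed layer shows the true difference
iso_shift_raw <- function(m) {
  sh <- integer(n_atoms(m))
  has <- !is.na(m$atoms$mass)
  sh[has] <- m$atoms$mass[has] - rounded_mass(m$atoms$element[has])
  sh
}

emit_exchangeable <- function(ex) {
  # ex: c(nH1, nH2, nH3)
  out <- ""
  lab <- c("H", "D", "T")
  for (i in 1:3) if (ex[i] > 0L)
    out <- paste0(out, lab[i], if (ex[i] > 1L) ex[i] else "")
  out
}

# ---- component ordering and assembly --------------------------------------

#' Order serialized components
#'
#' Components are sorted by a fixed comparison tuple: carbon-containing
#' components first, then more skeletal atoms first, then ascending
#' formula string, then ascending `/c`, `/h` and `/q` payloads.
#'
#' @param comps list of per-component layer sets.
#' @return the list reordered.
#' @export
order_components <- function(comps) {
  if (length(comps) <= 1L) return(comps)
  keys <- vapply(comps, function(cp) {
    paste(
      if (grepl("^C(?![a-z])", cp$formula, perl = TRUE)) "0" else "1",
      sprintf("%06d", 999999L - cp$natoms),
      sprintf("%-40s", cp$formula),
      sprintf("%-80s", cp$c),
      sprintf("%-80s", cp$h),
      sprintf("%-10s", as.character(cp$q)),
      sep = "|")
  }, "")
  comps[order(keys)]
}

# group consecutive identical components; returns list of (comp, count)
group_components <- function(comps) {
  out <- list()
  i <- 1L
  while (i <= length(comps)) {
    j <- i
    while (j < length(comps) &&
           identical(comps[[j + 1L]][setdiff(names(comps[[j + 1L]]),
                                             "natoms")],
                     comps[[i]][setdiff(names(comps[[i]]), "natoms")]))
      j <- j + 1L
    out[[length(out) + 1L]] <- list(comp = comps[[i]], count = j - i + 1L)
    i <- j + 1L
  }
  out
}

# join a componentized layer: "" entries stay empty; multiplied groups
# render as n*payload (only when the payload is non-empty)
join_layer <- function(grouped, field) {
  vals <- character(0)
  for (g in grouped) {
    v <- g$comp[[field]]
    if (is.null(v)) v <- ""
    if (!nzchar(v)) vals <- c(vals, rep("", g$count))
    else if (g$count > 1L) vals <- c(vals, paste0(g$count, "*", v))
    else vals <- c(vals, v)
  }
  if (all(!nzchar(vals))) return("")
  paste(vals, collapse = ";")
}

#' Assemble the identifier string
#'
#' @param comps ordered per-component layer sets.
#' @param p total protonation count.
#' @param standard logical; selects the `InChI=1S/` or `InChI=1/` prefix.
#' @param fixed_h logical; emit the fixed-H layer.
#' @param reconnected optional reconnected-layer body (everything after
#'   the prefix of a separately serialized structure).
#' @return identifier text.
#' @export
assemble <- function(comps, p = 0L, standard = TRUE, fixed_h = FALSE,
                     reconnected = NULL) {
  prefix <- if (standard) "InChI=1S" else "InChI=1"
  grouped <- group_components(comps)
  # formula with multipliers, dot-separated
  fml <- paste(vapply(grouped, function(g) {
    paste0(if (g$count > 1L) g$count else "", g$comp$formula)
  }, ""), collapse = ".")
  segs <- character(0)
  if (nzchar(fml)) segs <- c(segs, fml)
  add <- function(tag, payload) {
    if (nzchar(payload)) segs <<- c(segs, paste0(tag, payload))
    invisible()
  }
  add("c", join_layer(grouped, "c"))
  add("h", join_layer(grouped, "h"))
  qs <- join_layer(grouped, "q_str")
  add("q", qs)
  if (p != 0L) add("p", fmt_signed(p))
  add("b", join_layer(grouped, "b"))
  add("t", join_layer(grouped, "t"))
  ms <- paste(unlist(lapply(grouped, function(g)
    rep(if (is.null(g$comp$m) || is.na(g$comp$m)) "" else
      as.character(g$comp$m), g$count))), collapse = "")
  if (nzchar(ms)) segs <- c(segs, paste0("m", ms))
  svals <- unlist(lapply(grouped, function(g) g$comp$s))
  svals <- svals[!is.na(svals)]
  if (length(svals)) segs <- c(segs, paste0("s", max(svals)))
  iso <- join_layer(grouped, "i")
  exh <- join_layer(grouped, "ih")
  if (nzchar(iso) || nzchar(exh)) {
    seg <- paste0("i", iso)
    if (nzchar(exh)) seg <- paste0(seg, "/h", exh)
    segs <- c(segs, seg)
  }
  if (fixed_h) {
    fhl <- join_layer(grouped, "f_h")
    fq <- join_layer(grouped, "f_q_str")
    fi <- join_layer(grouped, "f_i")
    ffml_differs <- any(vapply(grouped, function(g)
      !identical(g$comp$f_formula, g$comp$formula), TRUE))
    if (nzchar(fhl) || nzchar(fq) || nzchar(fi) || ffml_differs) {
      seg <- "f"
      if (ffml_differs) {
        seg <- paste0(seg, paste(vapply(grouped, function(g)
          paste0(if (g$count > 1L) g$count else "", g$comp$f_formula), ""),
          collapse = "."))
      }
      if (nzchar(fhl)) seg <- paste0(seg, "/h", fhl)
      if (nzchar(fq)) seg <- paste0(seg, "/q", fq)
      if (nzchar(fi)) seg <- paste0(seg, "/i", fi)
      segs <- c(segs, seg)
    }
  }
  if (!is.null(reconnected) && nzchar(reconnected))
    segs <- c(segs, paste0("r", reconnected))
  paste0(prefix, "/", paste(segs, collapse = "/"))
}

#' Parse an identifier into its layers
#'
#' @param text identifier string.
#' @return list with `standard` and `layers`, a data frame of layer tags
#'   (empty tag for the formula) and payloads in order.
#' @export
parse_identifier <- function(text) {
  standard <- startsWith(text, "InChI=1S/")
  if (!standard && !startsWith(text, "InChI=1/"))
    stop("unrecognized identifier prefix", call. = FALSE)
  body <- sub("^InChI=1S?/", "", text)
  toks <- strsplit(body, "/", fixed = TRUE)[[1]]
  tags <- character(length(toks))
  pays <- character(length(toks))
  for (i in seq_along(toks)) {
    if (i == 1L && grepl("^[A-Z0-9.]", toks[i])) {
      tags[i] <- ""
      pays[i] <- toks[i]
    } else {
      tags[i] <- sub("^([a-z]).*$", "\\1", toks[i])
      pays[i] <- sub("^[a-z]", "", toks[i])
    }
  }
  list(standard = standard,
       layers = data.frame(tag = tags, payload = pays,
                           stringsAsFactors = FALSE))
}

#' Fetch one layer's payload from parsed layers
#'
#' @param parsed result of [parse_identifier()].
#' @param tag layer tag ("" for formula, "c", "h", ...). Only the first
#'   occurrence (the main layer) is returned.
#' @return payload string or `NA` when absent.
#' @export
layer_value <- function(parsed, tag) {
  i <- which(parsed$layers$tag == tag)
  if (!length(i)) return(NA_character_)
  parsed$layers$payload[i[1]]
}
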