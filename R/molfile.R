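# Reading and writing molfile V2000 / SD files.
#
# Explicit terminal hydrogen atoms are folded into per-atom counts on their
# skeletal neighbor when a file is read; the writer expands them again, so
# read(write(m)) reproduces the data model.

.chg_codes <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                `7` = -3L)
.wedge_codes <- c(`1` = "up", `6` = "down", `4` = "either")

num_at <- function(line, from, to) {
  s <- substr(line, from, to)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) && !grepl("^\\s*$", s))
    stop("malformed numeric field in molfile: '", s, "'", call. = FALSE)
  if (is.na(v)) 0 else v
}

#' Read a molfile (V2000)
#'
#' Parses the counts line, atom block, bond block and `M  CHG`/`M  ISO`/
#' `M  RAD` property lines. `M  CHG` and `M  RAD` supersede the atom-block
#' charge column. Wedge codes 1/6/4 map to up/down/either with the narrow
#' end at the first bond atom. Explicit terminal hydrogens (including D and
#' T symbols, converted to H with mass number 2/3) are folded into counts
#' on their neighbor; their geometry and any wedge is kept for stereo
#' perception.
#'
#' @param text molfile contents as a single string or character vector of
#'   lines.
#' @return an `inchikit_mol`.
#' @export
read_molfile <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  if (length(lines) < 4L) stop("molfile too short", call. = FALSE)
  counts <- lines[[4]]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("V3000 molfiles are not supported", call. = FALSE)
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb))
    stop("malformed counts line", call. = FALSE)
  chiral <- suppressWarnings(as.integer(substr(counts, 13, 15)))
  chiral <- !is.na(chiral) && chiral == 1L
  if (length(lines) < 4L + na + nb)
    stop("molfile truncated before end of atom/bond blocks", call. = FALSE)

  atoms <- data.frame(element = character(na), charge = 0L, radical = "none",
                      mass = NA_integer_, nH = 0L, nH1 = 0L, nH2 = 0L,
                      nH3 = 0L, x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  for (i in seq_len(na)) {
    l <- lines[[4L + i]]
    atoms$x[i] <- num_at(l, 1, 10)
    atoms$y[i] <- num_at(l, 11, 20)
    atoms$z[i] <- num_at(l, 21, 30)
    atoms$element[i] <- trimws(substr(l, 32, 34))
    cc <- suppressWarnings(as.integer(substr(l, 37, 39)))
    if (!is.na(cc) && cc > 0L) {
      if (cc == 4L) atoms$radical[i] <- "doublet"
      else if (as.character(cc) %in% names(.chg_codes))
        atoms$charge[i] <- .chg_codes[[as.character(cc)]]
    }
  }
  bonds <- data.frame(a = integer(nb), b = integer(nb),
                      order = rep(1L, nb), wedge = rep("none", nb),
                      from = integer(nb), stringsAsFactors = FALSE)
  for (k in seq_len(nb)) {
    l <- lines[[4L + na + k]]
    a <- suppressWarnings(as.integer(substr(l, 1, 3)))
    b <- suppressWarnings(as.integer(substr(l, 4, 6)))
    if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > na || b > na)
      stop("bond references a missing atom", call. = FALSE)
    typ <- suppressWarnings(as.integer(substr(l, 7, 9)))
    st <- suppressWarnings(as.integer(substr(l, 10, 12)))
    bonds$a[k] <- a
    bonds$b[k] <- b
    bonds$order[k] <- if (is.na(typ)) 1L else typ
    bonds$from[k] <- a
    if (!is.na(st) && as.character(st) %in% names(.wedge_codes))
      bonds$wedge[k] <- .wedge_codes[[as.character(st)]]
  }
  # property block
  chg_seen <- FALSE
  rad_seen <- FALSE
  for (l in lines[-seq_len(4L + na + nb)]) {
    tag <- substr(l, 1, 6)
    if (tag == "M  END") break
    if (!(tag %in% c("M  CHG", "M  ISO", "M  RAD"))) next
    nn <- as.integer(substr(l, 7, 9))
    if (tag == "M  CHG" && !chg_seen) { atoms$charge[] <- 0L; chg_seen <- TRUE }
    if (tag == "M  RAD" && !rad_seen) { atoms$radical[] <- "none"; rad_seen <- TRUE }
    for (j in seq_len(nn)) {
      off <- 10L + (j - 1L) * 8L
      ai <- as.integer(substr(l, off, off + 3L))
      vv <- as.integer(substr(l, off + 4L, off + 7L))
      if (tag == "M  CHG") atoms$charge[ai] <- vv
      if (tag == "M  ISO") atoms$mass[ai] <- vv
      if (tag == "M  RAD")
        atoms$radical[ai] <- c("none", "singlet", "doublet",
                               "triplet")[vv + 1L]
    }
  }
  # D/T pseudo-elements
  for (i in seq_len(na)) {
    if (atoms$element[i] == "D") { atoms$element[i] <- "H"; atoms$mass[i] <- 2L }
    if (atoms$element[i] == "T") { atoms$element[i] <- "H"; atoms$mass[i] <- 3L }
  }
  fold_terminal_hydrogens(
    molecule(atoms, if (nb) bonds else NULL, chiral = chiral))
}

# Fold explicit terminal H atoms into neighbor counts. Keeps a record of
# folded hydrogens (position, isotope class, wedge direction) for stereo
# perception. H atoms that are charged, radical, multiply bonded or bonded
# only to H remain skeletal.
fold_terminal_hydrogens <- function(m) {
  at <- m$atoms
  n <- nrow(at)
  adj <- adjacency(m)
  fold <- logical(n)
  recs <- list()
  for (i in seq_len(n)) {
    if (at$element[i] != "H") next
    if (at$charge[i] != 0L || at$radical[i] != "none") next
    if (length(adj[[i]]) != 1L) next
    j <- adj[[i]]
    if (at$element[j] == "H") next
    k <- which((m$bonds$a == i & m$bonds$b == j) |
               (m$bonds$a == j & m$bonds$b == i))
    if (m$bonds$order[k] != 1L) next
    fold[i] <- TRUE
    cls <- if (is.na(at$mass[i])) "nH" else switch(as.character(at$mass[i]),
                 `1` = "nH1", `2` = "nH2", `3` = "nH3", "nH")
    recs[[length(recs) + 1L]] <- data.frame(
      atom = j, iso = cls, x = at$x[i], y = at$y[i], z = at$z[i],
      wedge = m$bonds$wedge[k],
      narrow_at_center = m$bonds$from[k] == j,
      stringsAsFactors = FALSE)
  }
  if (!any(fold)) {
    m$hfold <- data.frame(atom = integer(0), iso = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0), wedge = character(0),
                          narrow_at_center = logical(0))
    return(m)
  }
  keep <- which(!fold)
  recs <- do.call(rbind, recs)
  for (r in seq_len(nrow(recs))) {
    a <- recs$atom[r]
    cls <- recs$iso[r]
    at[[cls]][a] <- at[[cls]][a] + 1L
  }
  map <- match(seq_len(n), keep)
  b <- m$bonds
  b <- b[!fold[b$a] & !fold[b$b], , drop = FALSE]
  b$a <- map[b$a]; b$b <- map[b$b]; b$from <- map[b$from]
  out <- molecule(at[keep, , drop = FALSE], b, chiral = m$chiral)
  recs$atom <- map[recs$atom]
  out$hfold <- recs
  out
}

#' Read a multi-record SD file
#'
#' @param text SDF contents (string or lines); records separated by `$$$$`.
#' @return list of `inchikit_mol`.
#' @export
read_sdf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  brk <- c(0L, which(trimws(lines) == "$$$$"), length(lines) + 1L)
  brk <- unique(brk)
  out <- list()
  for (i in seq_len(length(brk) - 1L)) {
    if (brk[i] + 1L > brk[i + 1L] - 1L) next
    chunk <- lines[(brk[i] + 1L):(brk[i + 1L] - 1L)]
    chunk <- chunk[cumsum(substr(chunk, 1, 6) == "M  END") == 0 |
                   substr(chunk, 1, 6) == "M  END"]
    if (!any(nzchar(trimws(chunk)))) next
    out[[length(out) + 1L]] <- read_molfile(chunk)
  }
  out
}

#' Write a molecule as a molfile (V2000)
#'
#' Terminal hydrogen counts are expanded to explicit H atoms (with `M  ISO`
#' lines for protium/deuterium/tritium labels) so that reading the output
#' reproduces the molecule.
#'
#' @param m molecule.
#' @param title optional title line.
#' @return molfile text (single string, LF line endings).
#' @export
write_molfile <- function(m, title = "") {
  if (any(!nzchar(m$atoms$element)))
    stop("atom without element symbol", call. = FALSE)
  at <- m$atoms
  bd <- m$bonds
  n0 <- nrow(at)
  # expand hydrogens
  extra <- list()
  for (i in seq_len(n0)) {
    for (cls in c("nH", "nH1", "nH2", "nH3")) {
      k <- at[[cls]][i]
      if (k > 0L)
        extra[[length(extra) + 1L]] <-
          data.frame(parent = i, n = k,
                     mass = switch(cls, nH = NA_integer_, nH1 = 1L,
                                   nH2 = 2L, nH3 = 3L))
    }
  }
  hx <- if (length(extra)) do.call(rbind, extra) else NULL
  nh_total <- if (is.null(hx)) 0L else sum(hx$n)
  na <- n0 + nh_total
  nb <- nrow(bd) + nh_total
  out <- c(title, "  inchikit", "",
           sprintf("%3d%3d  0  0%3d  0  0  0  0  0999 V2000",
                   na, nb, as.integer(m$chiral)))
  codes <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  atom_line <- function(x, y, z, el, chg) {
    cc <- 0L
    if (as.character(chg) %in% names(codes)) cc <- codes[[as.character(chg)]]
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            x, y, z, el, cc)
  }
  for (i in seq_len(n0))
    out <- c(out, atom_line(at$x[i], at$y[i], at$z[i], at$element[i],
                            at$charge[i]))
  hrows <- list()  # (index, parent, mass)
  idx <- n0
  if (!is.null(hx)) for (r in seq_len(nrow(hx))) {
    p <- hx$parent[r]
    for (j in seq_len(hx$n[r])) {
      idx <- idx + 1L
      out <- c(out, atom_line(at$x[p], at$y[p], at$z[p], "H", 0L))
      hrows[[length(hrows) + 1L]] <- c(idx, p, hx$mass[r])
    }
  }
  wcode <- c(up = 1L, down = 6L, either = 4L, none = 0L)
  for (k in seq_len(nrow(bd))) {
    a <- bd$a[k]; b <- bd$b[k]
    if (bd$wedge[k] != "none" && bd$from[k] == b) { tmp <- a; a <- b; b <- tmp }
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", a, b, bd$order[k],
                          wcode[[bd$wedge[k]]]))
  }
  for (h in hrows)
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", h[2], h[1], 1L, 0L))
  prop <- function(tag, atoms, values) {
    res <- character(0)
    while (length(atoms)) {
      take <- seq_len(min(8L, length(atoms)))
      res <- c(res, paste0("M  ", tag, sprintf("%3d", length(take)),
                           paste0(sprintf("%4d%4d", atoms[take],
                                          values[take]), collapse = "")))
      atoms <- atoms[-take]; values <- values[-take]
    }
    res
  }
  chg_at <- which(at$charge != 0L)
  if (length(chg_at)) out <- c(out, prop("CHG", chg_at, at$charge[chg_at]))
  iso_at <- which(!is.na(at$mass))
  iso_vals <- at$mass[iso_at]
  hiso <- Filter(function(h) !is.na(h[3]), hrows)
  if (length(hiso)) {
    iso_at <- c(iso_at, vapply(hiso, `[`, 0, 1))
    iso_vals <- c(iso_vals, vapply(hiso, `[`, 0, 3))
  }
  if (length(iso_at)) out <- c(out, prop("ISO", iso_at, iso_vals))
  rad_at <- which(at$radical != "none")
  if (length(rad_at))
    out <- c(out, prop("RAD", rad_at,
                       match(at$radical[rad_at], RADICAL_LEVELS) - 1L))
  out <- c(out, "M  END")
  paste0(paste(out, collapse = "\n"), "\n")
}
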