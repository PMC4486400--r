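# Staged canonical atom numbering by equitable-partition refinement with
# individualization: hydrogenless constitution first, then terminal
# hydrogens, then mobile-hydrogen groups, then isotopic composition, then
# fixed hydrogen positions. Each stage appends one list to minimize while
# keeping the earlier lists at their minimum, so each stage's optimal
# numberings are a subset of the previous stage's.

# Sentinel isotopic weight for fully non-isotopic atoms; exceeds any value
# the iso_weight formula can produce for chemically possible inputs, so
# isotopically labelled atoms take the smallest canonical numbers.
ISO_SENTINEL <- 2^32

# ---- colorings ------------------------------------------------------------

# Normalize per-atom integer key vectors to colors: rank keys
# lexicographically ascending; each color equals the number of atoms with
# that or a smaller color. Keys may be negative (bounded by +-1e10).
rank_to_colors <- function(keys) {
  enc <- vapply(keys, function(k)
    paste(sprintf("%011.0f", k + 1e10), collapse = ","), "")
  f <- factor(enc, levels = sort(unique(enc)))
  r <- as.integer(f)
  sizes <- tabulate(r)
  cumsum(sizes)[r]
}

#' Initial canonical colors
#'
#' Colors atoms by (element precedence, number of connections), element
#' precedence being carbon first, then other elements alphabetically, then
#' bridging hydrogen. Colors are in cumulative form: each color equals the
#' number of atoms with that or a smaller color.
#'
#' @param m molecule (normalized parent; terminal hydrogens are counts, not
#'   atoms).
#' @return integer color vector.
#' @export
initial_colors <- function(m) {
  deg <- lengths(adjacency(m))
  keys <- Map(function(e, d) c(e, d), element_rank(m$atoms$element), deg)
  rank_to_colors(keys)
}

#' Refine a coloring to the coarsest equitable partition below it
#'
#' Each atom's key is its own color followed by the ascending colors of its
#' neighbors; atoms are re-colored by lexicographic rank of the keys until a
#' fixpoint is reached.
#'
#' @param adj adjacency list.
#' @param colors integer color vector (cumulative form).
#' @return refined color vector (cumulative form, equitable).
#' @export
refine_equitable <- function(adj, colors) {
  repeat {
    keys <- lapply(seq_along(adj), function(i)
      c(colors[i], sort(colors[adj[[i]]])))
    new <- rank_to_colors(keys)
    if (identical(new, colors)) return(colors)
    colors <- new
  }
}

#' Connection-table code of a discrete coloring
#'
#' Segments in ascending color of the first atom; each segment holds the
#' first atom's color followed by the ascending colors of its
#' smaller-colored neighbors, flattened without delimiters.
#'
#' @param adj adjacency list.
#' @param nu discrete coloring (atom -> canonical number).
#' @return integer vector of length n + number of bonds.
#' @export
connection_table_code <- function(adj, nu) {
  if (anyDuplicated(nu)) stop("coloring is not discrete", call. = FALSE)
  atoms_by_color <- order(nu)
  out <- vector("list", length(nu))
  for (k in seq_along(atoms_by_color)) {
    i <- atoms_by_color[k]
    nb <- sort(nu[adj[[i]]])
    out[[k]] <- c(k, nb[nb < k])
  }
  unlist(out, use.names = FALSE)
}

# first non-equal position comparison; -1 if a < b, 0 equal, 1 if a > b.
# Only called on equal-length vectors.
cmp_vec <- function(a, b) {
  d <- a != b
  if (!any(d)) return(0L)
  i <- which.max(d)
  if (a[i] < b[i]) -1L else 1L
}

#' Individualization branches of a non-discrete equitable coloring
#'
#' Picks the smallest duplicated color; each member atom of that cell in
#' turn has its color reduced to (previous distinct color + 1).
#'
#' @param colors equitable, non-discrete coloring.
#' @return list of branch colorings (not yet re-refined), one per member of
#'   the target cell, in ascending original atom index.
#' @export
individualize <- function(colors) {
  tab <- table(colors)
  dup <- as.integer(names(tab)[tab > 1L])
  if (!length(dup)) stop("coloring is already discrete", call. = FALSE)
  target <- min(dup)
  smaller <- colors[colors < target]
  newc <- if (length(smaller)) max(smaller) + 1L else 1L
  members <- which(colors == target)
  lapply(members, function(a) { cl <- colors; cl[a] <- newc; cl })
}

# ---- search ---------------------------------------------------------------

# Exact search for the minimal connection-table code over all numberings
# consistent with the initial invariant coloring, then successive
# filtering by the auxiliary lists. The code minimization runs in
# compiled code (branch-and-bound with partial-code pruning); equitable
# refinement with individualization (above) provides the worked-trace
# view of the same minimization and is exercised by the unit tests.
canonical_search_raw <- function(adj, init_colors, aux_funs = list(),
                                 max_leaves = 200000L) {
  n <- length(init_colors)
  if (n == 0L)
    return(list(nus = list(integer(0)), tuple = numeric(0),
                code = integer(0)))
  adjm <- matrix(0L, n, n)
  for (i in seq_len(n)) adjm[i, adj[[i]]] <- 1L
  res <- lexmin_code_search(adjm, as.integer(init_colors))
  nus <- lapply(seq_len(ncol(res$numberings)), function(k)
    res$numberings[, k])
  tuple <- as.numeric(res$code)
  for (f in aux_funs) {
    flt <- filter_min_aux(nus, f)
    nus <- flt$nus
    tuple <- c(tuple, flt$value)
  }
  list(nus = nus, tuple = tuple, code = as.integer(res$code))
}

# keep the numberings minimizing aux list f, lexicographically
filter_min_aux <- function(nus, f) {
  vals <- lapply(nus, f)
  best <- NULL
  keep <- logical(length(nus))
  for (k in seq_along(vals)) {
    if (is.null(best)) {
      best <- vals[[k]]
      keep[k] <- TRUE
    } else {
      cc <- cmp_vec(vals[[k]], best)
      if (cc < 0L) {
        best <- vals[[k]]
        keep[] <- FALSE
        keep[k] <- TRUE
      } else if (cc == 0L) keep[k] <- TRUE
    }
  }
  list(nus = nus[keep], value = best)
}

# Orbit partition from the set of minimal numberings: atoms receiving the
# same color in two minimal numberings are equivalent. Returns for each
# atom the smallest canonical color in its orbit (under the first minimal
# numbering).
orbits_from_numberings <- function(nus) {
  n <- length(nus[[1]])
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ref <- order(nus[[1]])  # atom with color c under reference numbering
  for (nu in nus) {
    cur <- order(nu)
    for (cc in seq_len(n)) {
      rx <- find(ref[cc]); ry <- find(cur[cc])
      if (rx != ry) parent[max(rx, ry)] <- min(rx, ry)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  nu0 <- nus[[1]]
  cls <- integer(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    cls[members] <- min(nu0[members])
  }
  cls
}

# ---- staged canonicalization ----------------------------------------------

iso_shift <- function(m) {
  sh <- integer(n_atoms(m))
  has <- !is.na(m$atoms$mass)
  sh[has] <- m$atoms$mass[has] - rounded_mass(m$atoms$element[has])
  # increment non-negative shifts of labelled atoms; shift 0 is reserved
  # for unlabelled atoms
  sh[has & sh >= 0L] <- sh[has & sh >= 0L] + 1L
  sh
}

#' Isotopic weight of each atom
#'
#' `iso_weight = nH1 + 32 * (nH2 + 32 * (nH3 + 32 * shift))` with
#' shift = mass number minus rounded average mass (incremented when >= 0 so
#' labelled atoms never have shift 0). Atoms with no isotopic label and no
#' isotopic hydrogens get a sentinel larger than any real weight, which
#' forces labelled atoms to take the smallest canonical numbers.
#'
#' @param m molecule.
#' @return numeric vector of weights.
#' @export
iso_weights <- function(m) {
  sh <- iso_shift(m)
  w <- m$atoms$nH1 + 32 * (m$atoms$nH2 + 32 * (m$atoms$nH3 + 32 * sh))
  w[w == 0] <- ISO_SENTINEL
  w
}

# aux-list builders; each returns function(nu) -> numeric vector
aux_by_color <- function(values) {
  force(values)
  function(nu) values[order(nu)]
}

aux_mobile_groups <- function(groups) {
  force(groups)
  function(nu) {
    if (!length(groups)) return(numeric(0))
    items <- lapply(groups, function(g)
      c(length(g$members), sort(nu[g$members]), g$nH, g$nneg))
    keys <- vapply(items, function(v)
      paste(sprintf("%011.0f", v + 1e10), collapse = ","), "")
    unlist(items[order(keys)], use.names = FALSE)
  }
}

#' Staged canonical numbering of a normalized component
#'
#' Runs the refinement/individualization search once per stage, each stage
#' appending one list to the comparison tuple:
#' \describe{
#'   \item{A}{hydrogenless connection-table code}
#'   \item{B}{immobile terminal-hydrogen counts}
#'   \item{mob}{mobile-hydrogen groups (members, hydrogen and negative
#'     charge counts)}
#'   \item{iso}{isotopic weights (exchangeable isotopic hydrogens live in
#'     the groups, not on atoms, so they are excluded automatically)}
#'   \item{fix}{drawn (fixed) hydrogen counts}
#'   \item{fixiso}{isotopic weights of the drawn structure}
#' }
#' Stages that add no information reuse the previous stage's result.
#'
#' @param parent normalized component (mobile hydrogens removed from atoms).
#' @param groups list of mobile-hydrogen groups
#'   (`list(members=, nH=, nneg=)`).
#' @param fixed data frame of drawn hydrogen counts (columns `nH`, `nH1`,
#'   `nH2`, `nH3`), or `NULL` when identical to the parent's.
#' @return list of per-stage results (`nus`, `nu`, `orbits`, `code`,
#'   `tuple`).
#' @export
canonicalize <- function(parent, groups = list(), fixed = NULL) {
  adj <- adjacency(parent)
  n <- n_atoms(parent)
  hs <- total_H(parent)
  iso <- iso_weights(parent)
  if (is.null(fixed)) fixed <- parent$atoms[, c("nH", "nH1", "nH2", "nH3")]
  fh <- fixed$nH + fixed$nH1 + fixed$nH2 + fixed$nH3
  fiso_m <- parent
  fiso_m$atoms$nH <- fixed$nH
  fiso_m$atoms$nH1 <- fixed$nH1
  fiso_m$atoms$nH2 <- fixed$nH2
  fiso_m$atoms$nH3 <- fixed$nH3
  fiso <- iso_weights(fiso_m)

  init <- initial_colors(parent)
  base <- canonical_search_raw(adj, init)
  stage <- function(nus, tuple) {
    list(nus = nus, nu = if (n) nus[[1]] else integer(0),
         orbits = if (n) orbits_from_numberings(nus) else integer(0),
         code = base$code, tuple = tuple)
  }
  narrow <- function(prev, values_fun) {
    flt <- filter_min_aux(prev$nus, values_fun)
    stage(flt$nus, c(prev$tuple, flt$value))
  }
  out <- list()
  out$A <- stage(base$nus, base$tuple)
  out$B <- narrow(out$A, aux_by_color(hs))
  out$mob <- if (length(groups)) narrow(out$B, aux_mobile_groups(groups))
             else out$B
  has_iso <- any(iso != ISO_SENTINEL)
  out$iso <- if (has_iso) narrow(out$mob, aux_by_color(iso)) else out$mob
  fixed_differs <- !identical(as.integer(fh), as.integer(hs))
  out$fix <- if (fixed_differs) narrow(out$mob, aux_by_color(fh))
             else out$mob
  has_fiso <- any(fiso != ISO_SENTINEL)
  out$fixiso <- if (has_fiso) narrow(out$fix, aux_by_color(fiso))
                else out$fix
  out
}
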