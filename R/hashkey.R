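# The 27-character hashed compact key: split the identifier, hash parts
# with SHA-256, truncate to 65/37 bits, encode base-26, append flag
# characters.

# ---- small big-integer helpers (little-endian base 2^15 digit vectors) ----

BN_BASE <- 32768L

bn_zero <- function() 0L

bn_from_bits <- function(bits) {
  # bits: integer vector of 0/1, most significant first
  v <- 0L
  for (b in bits) {
    v <- bn_mul_small(v, 2L)
    v <- bn_add_small(v, b)
  }
  v
}

bn_mul_small <- function(v, k) {
  carry <- 0
  out <- integer(length(v))
  for (i in seq_along(v)) {
    t <- v[i] * k + carry
    out[i] <- t %% BN_BASE
    carry <- t %/% BN_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BN_BASE)
    carry <- carry %/% BN_BASE
  }
  while (length(out) > 1L && out[length(out)] == 0L)
    out <- out[-length(out)]
  as.integer(out)
}

bn_add_small <- function(v, k) {
  i <- 1L
  carry <- k
  out <- v
  while (carry > 0) {
    if (i > length(out)) out <- c(out, 0L)
    t <- out[i] + carry
    out[i] <- t %% BN_BASE
    carry <- t %/% BN_BASE
    i <- i + 1L
  }
  as.integer(out)
}

bn_divmod_small <- function(v, d) {
  rem <- 0
  out <- integer(length(v))
  for (i in rev(seq_along(v))) {
    t <- rem * BN_BASE + v[i]
    out[i] <- t %/% d
    rem <- t %% d
  }
  while (length(out) > 1L && out[length(out)] == 0L)
    out <- out[-length(out)]
  list(q = as.integer(out), r = as.integer(rem))
}

bn_is_zero <- function(v) all(v == 0L)

bn_bitlength <- function(v) {
  while (length(v) > 1L && v[length(v)] == 0L) v <- v[-length(v)]
  top <- v[length(v)]
  if (top == 0L) return(0L)
  nb <- 0L
  while (top > 0L) { nb <- nb + 1L; top <- top %/% 2L }
  nb + 15L * (length(v) - 1L)
}

# ---- operations -----------------------------------------------------------

#' Split an identifier string for hashing
#'
#' Part 1 is the leading substring with the formula, connectivity (`/c`)
#' and hydrogens (`/h`) sublayers; part 2 is the protonation layer (`/p`);
#' part 3 is all the rest. The prefix is stripped and the standard flag
#' memorized.
#'
#' @param s identifier string (or an object from [inchi()]).
#' @return list with `part1`, `part2`, `part3`, `standard`.
#' @export
split_identifier <- function(s) {
  s <- as_identifier_text(s)
  standard <- startsWith(s, "InChI=1S/")
  if (!standard && !startsWith(s, "InChI=1/"))
    stop("unrecognized identifier prefix", call. = FALSE)
  body <- sub("^InChI=1S?/", "", s)
  toks <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (!length(toks)) toks <- ""
  # identifiers with no formula sublayer (a bare proton) start with a
  # lowercase layer tag
  if (grepl("^[a-z]", toks[1])) toks <- c("", toks)
  tags <- c("", substr(toks[-1], 1, 1))
  part1 <- character(0)
  part2 <- character(0)
  part3 <- character(0)
  in_head <- TRUE
  for (i in seq_along(toks)) {
    tg <- tags[i]
    if (in_head && (i == 1L || tg %in% c("c", "h"))) {
      part1 <- c(part1, toks[i])
      next
    }
    in_head <- FALSE
    if (tg == "p" && !length(part3)) part2 <- c(part2, toks[i])
    else part3 <- c(part3, toks[i])
  }
  j <- function(x, lead = FALSE)
    if (!length(x)) "" else paste0(if (lead) "/" else "",
                                   paste(x, collapse = "/"))
  list(part1 = j(part1), part2 = j(part2, lead = TRUE),
       part3 = j(part3, lead = TRUE), standard = standard)
}

#' Truncated SHA-256 hash of an identifier part
#'
#' @param part character string (may be empty).
#' @param bits number of leading bits to keep (65 for the first block, 37
#'   for the second).
#' @return big-integer digit vector (see `bn_bitlength`).
#' @export
hash_truncate <- function(part, bits) {
  dg <- as.integer(openssl::sha256(charToRaw(part)))
  nbytes <- ceiling(bits / 8)
  bitvec <- integer(0)
  for (by in dg[seq_len(nbytes)])
    bitvec <- c(bitvec, as.integer(bitwAnd(bitwShiftR(by, 7:0), 1L)))
  bn_from_bits(bitvec[seq_len(bits)])
}

#' Base-26 encoding of a truncated hash
#'
#' Pure positional base-26, most significant letter first, `A` = 0 through
#' `Z` = 25, zero-padded to the block width.
#'
#' @param v big-integer digit vector (or a plain non-negative integer).
#' @param width output width (14 or 8).
#' @return uppercase letter string.
#' @export
base26_encode <- function(v, width) {
  if (length(v) == 1L && v < BN_BASE) v <- as.integer(v)
  letters_out <- character(width)
  for (i in width:1) {
    dm <- bn_divmod_small(v, 26L)
    letters_out[i] <- LETTERS[dm$r + 1L]
    v <- dm$q
  }
  if (!bn_is_zero(v))
    stop("value out of range for base-26 width ", width, call. = FALSE)
  paste(letters_out, collapse = "")
}

#' Decode a base-26 block
#'
#' @param s uppercase letter string.
#' @return big-integer digit vector.
#' @export
base26_decode <- function(s) {
  ds <- match(strsplit(s, "")[[1]], LETTERS) - 1L
  if (anyNA(ds)) stop("invalid base-26 string", call. = FALSE)
  v <- 0L
  for (d in ds) {
    v <- bn_mul_small(v, 26L)
    v <- bn_add_small(v, d)
  }
  v
}

#' Bit length of a decoded block
#' @param v big-integer digit vector from [base26_decode()].
#' @return integer number of bits.
#' @export
block_bitlength <- function(v) bn_bitlength(v)

#' Protonation flag letter
#'
#' `N` for no proton-related ionization; `O`..`Z` for +1..+12 inserted
#' protons, `M`..`B` for -1..-12, and `A` when the magnitude exceeds 12.
#'
#' @param p protonation count (the `/p` value; 0 when absent).
#' @return single uppercase letter.
#' @export
proton_flag <- function(p) {
  if (p == 0L) return("N")
  if (abs(p) > 12L) return("A")
  LETTERS[14L + p]
}

#' Generate the 27-character hashed key
#'
#' Layout `AAAAAAAAAAAAAA-BBBBBBBBFV-P`: a 14-letter block hashing the
#' skeleton part (formula/connections/hydrogens, 65 bits of SHA-256), an
#' 8-letter block hashing the remaining layers (37 bits), the
#' standardness flag (`S`/`N`), version letter `A`, and the protonation
#' flag.
#'
#' @param s identifier string or [inchi()] result.
#' @return object of class `inchikit_key`: list with `text`, `block1`,
#'   `block2`, `flag_std`, `flag_proton`.
#' @export
make_key <- function(s) {
  parts <- split_identifier(s)
  b1 <- base26_encode(hash_truncate(parts$part1, 65L), 14L)
  b2 <- base26_encode(hash_truncate(parts$part3, 37L), 8L)
  p <- 0L
  if (nzchar(parts$part2)) {
    pv <- sub("^/p", "", parts$part2)
    p <- as.integer(sub("^\\+", "", strsplit(pv, ";", fixed = TRUE)[[1]][1]))
  }
  fs <- if (parts$standard) "S" else "N"
  fp <- proton_flag(p)
  structure(list(text = paste0(b1, "-", b2, fs, "A", "-", fp),
                 block1 = b1, block2 = b2, flag_std = fs,
                 flag_version = "A", flag_proton = fp),
            class = "inchikit_key")
}

#' @export
print.inchikit_key <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.inchikit_key <- function(x, ...) x$text

#' Birthday-bound collision probability
#'
#' Probability of at least one collision among `n` random values hashed to
#' `bits` bits: `1 - exp(-n (n - 1) / 2 / 2^bits)`.
#'
#' @param n number of hashed items.
#' @param bits hash width in bits.
#' @return probability in `[0, 1]`.
#' @export
collision_estimate <- function(n, bits) {
  1 - exp(-n * (n - 1) / 2 / 2^bits)
}

#' Expected database size at the first collision
#'
#' @param bits hash width in bits.
#' @return `sqrt(2^bits)`.
#' @export
expected_first_collision <- function(bits) sqrt(2^bits)
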