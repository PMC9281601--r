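#' @useDynLib codonlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cyclic 4-ary Gray ring over all 64 trinucleotide codons: every consecutive
# pair (including position 63 -> 0) differs in exactly one nucleotide.
# Built once from the modular base-4 Gray code with digit map 0->A, 1->C,
# 2->T, 3->G and frozen here as the canonical ring.
CODON_RING <- c(
  "AAA", "AAC", "AAT", "AAG", "ACG", "ACA", "ACC", "ACT", "ATT", "ATG",
  "ATA", "ATC", "AGC", "AGT", "AGG", "AGA", "CGA", "CGC", "CGT", "CGG",
  "CAG", "CAA", "CAC", "CAT", "CCT", "CCG", "CCA", "CCC", "CTC", "CTT",
  "CTG", "CTA", "TTA", "TTC", "TTT", "TTG", "TGG", "TGA", "TGC", "TGT",
  "TAT", "TAG", "TAA", "TAC", "TCC", "TCT", "TCG", "TCA", "GCA", "GCC",
  "GCT", "GCG", "GTG", "GTA", "GTC", "GTT", "GGT", "GGG", "GGA", "GGC",
  "GAC", "GAT", "GAG", "GAA"
)

# Canonical 0-based ring position of every supported character. Placement is
# frozen so that, at offset 0, S -> ATA, Z -> ATC and V -> GAG, and the
# confusable pairs (N,M), (S,Z), (G,Q), (I,E), (0,1), (5,6), (6,7) occupy
# ring-adjacent positions (digits 0-9 sit on one consecutive run, which also
# makes 5,6,7 consecutive). "*" is the field separator; " " is the in-field
# space. Unassigned ring positions decode to NA.
CHAR_POSITIONS <- c(
  "A" = 0L, "B" = 1L, "C" = 2L, "D" = 3L, "F" = 4L, "H" = 5L, "J" = 6L,
  "K" = 7L, "L" = 8L, "O" = 9L, "S" = 10L, "Z" = 11L, "P" = 12L, "N" = 13L,
  "M" = 14L, "R" = 15L, "G" = 16L, "Q" = 17L, "T" = 18L, "U" = 19L,
  "0" = 20L, "1" = 21L, "2" = 22L, "3" = 23L, "4" = 24L, "5" = 25L,
  "6" = 26L, "7" = 27L, "8" = 28L, "9" = 29L, "W" = 30L, "I" = 31L,
  "E" = 32L, "X" = 33L, "Y" = 34L, " " = 35L, "*" = 36L, "V" = 62L
)

FIELD_SEPARATOR <- "*"

#' Build the default codon wheel
#'
#' The codon wheel maps every supported character (A-Z, 0-9, space and the
#' field separator) to one of the 64 trinucleotide codons. The 64 codons are
#' arranged on a cyclic ring in which every pair of neighbouring codons
#' differs in exactly one nucleotide, and characters that are frequently
#' confused in administrative registries (keyboard neighbours such as N/M, and
#' phonetically similar letters such as S/Z in Portuguese) are pinned to
#' neighbouring ring positions, so a confusable-character typo costs a single
#' nucleotide in the encoded sequence.
#'
#' An encryption key "spins" the wheel: the character layout is unchanged but
#' every character's codon is taken `offset` positions further along the ring.
#' Because rotation preserves ring distances, the error-tolerance design is
#' identical under every key.
#'
#' @param key Optional key text. When supplied, the wheel is rotated by
#'   [offset_from_key()]; when `NULL`, offset 0 is used.
#' @return An object of class `codon_wheel`: a list with elements `ring`
#'   (length-64 character vector of codons), `char_positions` (named integer
#'   vector of 0-based ring positions) and `offset` (integer in 0..63).
#' @examples
#' w <- build_default_wheel()
#' encode_char(w, "S") # "ATA"
#' @export
build_default_wheel <- function(key = NULL) {
  wheel <- structure(
    list(ring = CODON_RING, char_positions = CHAR_POSITIONS, offset = 0L),
    class = "codon_wheel"
  )
  if (!is.null(key)) wheel <- rotate(wheel, offset_from_key(key))
  wheel
}

#' Derive a wheel rotation offset from an encryption key
#'
#' The offset is the first 8 bytes of the SHA-256 digest of the UTF-8 key
#' bytes, read as a big-endian unsigned integer, modulo 64. Any text
#' (including the empty string) is a valid key, and the derivation is
#' deterministic so that runs can be reproduced by fixing the key.
#'
#' @param key Key text (scalar character).
#' @return Integer offset in `[0, 63]`.
#' @export
offset_from_key <- function(key) {
  stopifnot(is.character(key), length(key) == 1L, !is.na(key))
  cl_key_offset(enc2utf8(key))
}

#' Generate a random alphanumeric encryption key
#'
#' Used when no key is supplied: a fresh key is generated per run so that
#' encoded output from one run cannot be decoded in another.
#'
#' @param length Number of key characters.
#' @return A scalar character key.
#' @export
random_key <- function(length = 16L) {
  pool <- c(LETTERS, letters, 0:9)
  paste(sample(pool, length, replace = TRUE), collapse = "")
}

#' Rotate a codon wheel
#'
#' Character `c` maps to `ring[(position(c) + offset) %% 64]`; the character
#' layout itself is unchanged. The ring is cyclic, so offsets are taken
#' modulo 64 (rotating by 64 is the identity).
#'
#' @param wheel A `codon_wheel`.
#' @param offset A single integer (any value; reduced modulo 64).
#' @return The rotated `codon_wheel`.
#' @export
rotate <- function(wheel, offset) {
  stopifnot(inherits(wheel, "codon_wheel"))
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
      offset != round(offset)) {
    stop("`offset` must be a single integer", call. = FALSE)
  }
  wheel$offset <- as.integer((wheel$offset + offset) %% 64)
  wheel
}

# codon assigned to each supported character under the wheel's offset,
# named by character
wheel_codon_table <- function(wheel) {
  pos <- (wheel$char_positions + wheel$offset) %% 64L
  stats::setNames(wheel$ring[pos + 1L], names(wheel$char_positions))
}

#' Encode a single character as a codon
#'
#' @param wheel A `codon_wheel`.
#' @param char A single supported character (A-Z, 0-9, space or `*`).
#' @return A three-letter codon.
#' @export
encode_char <- function(wheel, char) {
  tab <- wheel_codon_table(wheel)
  out <- tab[char]
  if (anyNA(out)) {
    bad <- unique(char[is.na(out)])
    stop("unsupported character(s): ", paste(dQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Decode a codon back to its character
#'
#' @param wheel A `codon_wheel`.
#' @param codon A trinucleotide over A/C/G/T.
#' @return The decoded character, or `NA` if the ring position carries no
#'   character.
#' @export
decode_codon <- function(wheel, codon) {
  stopifnot(all(grepl("^[ACGT]{3}$", codon)))
  tab <- wheel_codon_table(wheel)
  rev <- stats::setNames(names(tab), tab)
  out <- rev[codon]
  unname(out)
}

#' Export a wheel as a two-column character/codon table
#'
#' @param wheel A `codon_wheel`.
#' @return A data.frame with columns `char` and `codon`, one row per
#'   supported character, in ring-position order.
#' @export
wheel_table <- function(wheel) {
  tab <- wheel_codon_table(wheel)
  ord <- order(wheel$char_positions)
  data.frame(char = names(tab)[ord], codon = unname(tab)[ord],
             stringsAsFactors = FALSE)
}

# short hex fingerprint of a key, used to refuse aligning databases encoded
# under different keys
key_fingerprint <- function(key) {
  cl_sha256_hex(enc2utf8(key))
}
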