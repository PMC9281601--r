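SPAN_COLS <- c("name_start", "name_end", "birth_date_start", "birth_date_end",
               "sex_start", "sex_end", "mother_name_start", "mother_name_end")
CANONICAL_FIELDS <- c("name", "birth_date", "sex", "mother_name")

# fingerprint of the wheel state (ring + layout + offset): two databases are
# alignable iff they were encoded under wheels with equal fingerprints
wheel_fingerprint <- function(wheel) {
  tab <- wheel_codon_table(wheel)
  cl_sha256_hex(paste(names(tab), tab, sep = ":", collapse = ";"))
}

# vectorized field -> codon string under a wheel
encode_field <- function(values, codon_tab) {
  out <- character(length(values))
  nz <- which(nzchar(values))
  if (length(nz) == 0L) return(out)
  spl <- strsplit(values[nz], "", fixed = TRUE)
  out[nz] <- vapply(spl, function(ch) {
    codons <- codon_tab[ch]
    if (anyNA(codons)) {
      stop("unsupported character(s): ",
           paste(unique(ch[is.na(codons)]), collapse = ", "), call. = FALSE)
    }
    paste(codons, collapse = "")
  }, character(1))
  out
}

#' Encode cleaned records as DNA sequences
#'
#' Serializes each record's four identification fields in the canonical order
#' (name, date of birth, sex, mother's name), one codon per character, with a
#' dedicated separator codon between consecutive fields. The separator keeps
#' field boundaries sharp in alignments and allows per-field error
#' attribution. Empty fields contribute zero character codons but keep their
#' separators, so an all-empty record encodes to exactly three separator
#' codons (9 nt).
#'
#' @param db A `clean_db` (see [clean_records()]).
#' @param wheel A `codon_wheel`, typically `build_default_wheel(key)`.
#' @return An `encoded_db`: data.frame with `record_id`, `sequence`, and
#'   0-based half-open codon-unit span columns
#'   (`name_start`, `name_end`, ..., `mother_name_end`), with attribute
#'   `key_fingerprint` identifying the wheel state used.
#' @export
encode_records <- function(db, wheel) {
  stopifnot(inherits(wheel, "codon_wheel"))
  validate_clean_db(db)
  tab <- wheel_codon_table(wheel)
  sep <- unname(tab[FIELD_SEPARATOR])
  if (nrow(db) == 0L) {
    enc <- data.frame(record_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
    for (cn in SPAN_COLS) enc[[cn]] <- integer(0)
    attr(enc, "key_fingerprint") <- wheel_fingerprint(wheel)
    class(enc) <- c("encoded_db", "data.frame")
    return(enc)
  }
  f1 <- encode_field(db$name, tab)
  f2 <- encode_field(db$birth_date, tab)
  f3 <- encode_field(db$sex, tab)
  f4 <- encode_field(db$mother_name, tab)
  n1 <- nchar(f1) %/% 3L; n2 <- nchar(f2) %/% 3L
  n3 <- nchar(f3) %/% 3L; n4 <- nchar(f4) %/% 3L
  enc <- data.frame(
    record_id = db$record_id,
    sequence = paste0(f1, sep, f2, sep, f3, sep, f4),
    name_start = 0L, name_end = n1,
    birth_date_start = n1 + 1L, birth_date_end = n1 + 1L + n2,
    sex_start = n1 + n2 + 2L, sex_end = n1 + n2 + 2L + n3,
    mother_name_start = n1 + n2 + n3 + 3L,
    mother_name_end = n1 + n2 + n3 + 3L + n4,
    stringsAsFactors = FALSE
  )
  attr(enc, "key_fingerprint") <- wheel_fingerprint(wheel)
  class(enc) <- c("encoded_db", "data.frame")
  enc
}

#' Encode a single cleaned record
#'
#' @param record A one-row `clean_db` or a list with the canonical fields.
#' @param wheel A `codon_wheel`.
#' @return A one-row `encoded_db`.
#' @export
encode_record <- function(record, wheel) {
  db <- as.data.frame(record, stringsAsFactors = FALSE)
  class(db) <- c("clean_db", "data.frame")
  encode_records(db, wheel)
}

#' Decode encoded records back to cleaned records
#'
#' Exact inverse of [encode_records()] under the same wheel (same key). A
#' wheel with a different rotation almost surely fails the separator check
#' and raises a probable-key-mismatch error.
#'
#' @param enc An `encoded_db`.
#' @param wheel A `codon_wheel`.
#' @return A `clean_db`.
#' @export
decode_records <- function(enc, wheel) {
  stopifnot(inherits(wheel, "codon_wheel"))
  tab <- wheel_codon_table(wheel)
  rev_tab <- stats::setNames(names(tab), tab)
  n <- nrow(enc)
  fields <- matrix("", nrow = n, ncol = 4L,
                   dimnames = list(NULL, CANONICAL_FIELDS))
  for (i in seq_len(n)) {
    seq <- enc$sequence[i]
    stopifnot(nchar(seq) %% 3L == 0L)
    codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
    chars <- rev_tab[codons]
    seps <- which(!is.na(chars) & chars == FIELD_SEPARATOR)
    exp_seps <- c(enc$name_end[i], enc$birth_date_end[i], enc$sex_end[i]) + 1L
    if (anyNA(chars) || !identical(as.integer(seps), as.integer(exp_seps))) {
      stop("decoding failed for record ", enc$record_id[i],
           ": probable key mismatch", call. = FALSE)
    }
    for (f in CANONICAL_FIELDS) {
      a <- enc[[paste0(f, "_start")]][i]; b <- enc[[paste0(f, "_end")]][i]
      fields[i, f] <- if (b > a) paste(chars[(a + 1L):b], collapse = "") else ""
    }
  }
  db <- data.frame(record_id = enc$record_id,
                   name = fields[, "name"],
                   birth_date = fields[, "birth_date"],
                   sex = fields[, "sex"],
                   mother_name = fields[, "mother_name"],
                   stringsAsFactors = FALSE)
  validate_clean_db(db)
  class(db) <- c("clean_db", "data.frame")
  db
}

#' Write an encoded database as FASTA plus a spans sidecar
#'
#' The FASTA holds only the record id in each header (60-column wrap), so it
#' is consumable by any external alignment backend; the per-field codon spans
#' and the key fingerprint travel in a sidecar TSV `<path>.spans.tsv`.
#'
#' @param enc An `encoded_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(enc, path) {
  if (any(grepl("[[:space:]]", enc$record_id))) {
    stop("record ids must not contain whitespace", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(enc$sequence)
  names(seqs) <- enc$record_id
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  sidecar <- paste0(path, ".spans.tsv")
  con <- file(sidecar, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# key_fingerprint\t",
                    attr(enc, "key_fingerprint") %||% ""), con)
  utils::write.table(as.data.frame(enc)[, c("record_id", SPAN_COLS)], con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an encoded database from FASTA plus its spans sidecar
#'
#' @param path FASTA path written by [write_fasta()].
#' @return An `encoded_db`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA header(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".spans.tsv")
  if (!file.exists(sidecar)) {
    stop("missing spans sidecar: ", sidecar, call. = FALSE)
  }
  first <- readLines(sidecar, n = 1L)
  fp <- sub("^# key_fingerprint\t", "", first)
  spans <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = c(record_id = "character"))
  if (length(ids) == 0L) {
    enc <- data.frame(record_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
    for (cn in SPAN_COLS) enc[[cn]] <- integer(0)
  } else {
    m <- match(ids, spans$record_id)
    if (anyNA(m)) {
      stop("spans sidecar missing record(s): ",
           paste(utils::head(ids[is.na(m)], 5L), collapse = ", "),
           call. = FALSE)
    }
    enc <- cbind(
      data.frame(record_id = ids, sequence = as.character(seqs),
                 stringsAsFactors = FALSE),
      spans[m, SPAN_COLS, drop = FALSE]
    )
    rownames(enc) <- NULL
  }
  attr(enc, "key_fingerprint") <- fp
  class(enc) <- c("encoded_db", "data.frame")
  enc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
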