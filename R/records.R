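#' Clean free-text identification fields
#'
#' Uppercases, folds diacritics to their base letters, replaces punctuation
#' (hyphens, apostrophes, and anything else outside A-Z) by a single space,
#' and collapses whitespace. Punctuation maps to space rather than being
#' deleted so that compound names keep their token boundaries. The result
#' matches `[A-Z ]*` with no leading/trailing/double spaces, and the
#' operation is total and idempotent.
#'
#' @param raw Character vector of free text (any encoding R can represent).
#' @return Character vector of cleaned text, same length as `raw`.
#' @examples
#' clean_text("José da Sílva-Melo") # "JOSE DA SILVA MELO"
#' @export
clean_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- as.character(raw)
  out[is.na(out)] <- ""
  # fold diacritics to ASCII base letters; anything still non-ASCII is
  # punctuation-ruled into a space below
  out <- stringi::stri_trans_general(out, "Latin-ASCII")
  out[is.na(out)] <- ""
  out <- toupper(out)
  out <- gsub("[^A-Z]+", " ", out)
  out <- trimws(gsub(" +", " ", out))
  out
}

#' Standardize a date to YYYYMMDD
#'
#' Parses free-text dates under a declared dialect and returns the fixed
#' eight-digit ISO form. A fixed-width digit string keeps each digit on a
#' stable codon position, so a single-digit typo costs exactly one codon in
#' the encoded sequence. Empty input (missing data) passes through as the
#' empty string.
#'
#' @param raw Character vector of date text.
#' @param dialect One of `"DMY"`, `"MDY"`, `"YMD"`, `"ISO"` (`ISO` accepts
#'   `YYYY-MM-DD` or the already-standard `YYYYMMDD`).
#' @param record_id Optional ids used in error messages for unparseable rows.
#' @return Character vector of `"YYYYMMDD"` or `""`.
#' @export
standardize_date <- function(raw, dialect = c("DMY", "MDY", "YMD", "ISO"),
                             record_id = NULL) {
  dialect <- match.arg(dialect)
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  out <- character(length(raw))
  nonempty <- which(nzchar(trimws(raw)))
  if (length(nonempty) == 0L) return(out)
  x <- trimws(raw[nonempty])
  # separator-free 8-digit input is always read as canonical YYYYMMDD (so
  # re-cleaning a standardized file is idempotent); day-first/month-first
  # compact forms are ambiguous with it and are not guessed
  fmt <- switch(dialect,
    DMY = c("%d/%m/%Y", "%d-%m-%Y", "%d.%m.%Y", "%Y%m%d"),
    MDY = c("%m/%d/%Y", "%m-%d-%Y", "%m.%d.%Y", "%Y%m%d"),
    YMD = c("%Y/%m/%d", "%Y-%m-%d", "%Y.%m.%d", "%Y%m%d"),
    ISO = c("%Y-%m-%d", "%Y%m%d")
  )
  parsed <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  for (f in fmt) {
    miss <- is.na(parsed)
    if (!any(miss)) break
    parsed[miss] <- as.Date(x[miss], format = f)
  }
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed))
    ids <- if (!is.null(record_id)) record_id[nonempty][bad] else
      paste0("row ", nonempty[bad])
    stop("unparseable date(s) under dialect ", dialect, " for: ",
         paste(utils::head(ids, 5L), collapse = ", "),
         if (length(ids) > 5L) ", ..." else "", call. = FALSE)
  }
  out[nonempty] <- format(parsed, "%Y%m%d")
  out
}

#' Standardize a sex field to M/F/U
#'
#' Recognizes common codings (`M`, `F`, `MALE`, `FEMALE`, `1`, `2`);
#' anything else, including missing, becomes `U` (unknown).
#'
#' @param raw Character vector.
#' @return Character vector over `{"M", "F", "U"}`.
#' @export
standardize_sex <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  x[is.na(x)] <- ""
  out <- rep("U", length(x))
  out[x %in% c("M", "MALE", "MASC", "MASCULINO", "1")] <- "M"
  out[x %in% c("F", "FEMALE", "FEM", "FEMININO", "2")] <- "F"
  out
}

#' Assemble a cleaned person-record database
#'
#' Applies [clean_text()], [standardize_date()] and [standardize_sex()] to
#' the four identification fields and validates record ids. This is the
#' canonical in-memory form every downstream module consumes.
#'
#' @param record_id Unique opaque id per record.
#' @param name,mother_name Free-text names.
#' @param birth_date Free-text dates (see `dialect`).
#' @param sex Free-text sex codes.
#' @param dialect Date dialect passed to [standardize_date()].
#' @return A `clean_db`: a data.frame with columns `record_id`, `name`,
#'   `birth_date`, `sex`, `mother_name`.
#' @export
clean_records <- function(record_id, name, birth_date, sex, mother_name,
                          dialect = "DMY") {
  record_id <- as.character(record_id)
  if (anyNA(record_id) || any(!nzchar(record_id))) {
    stop("record_id must be non-missing and non-empty", call. = FALSE)
  }
  dup <- unique(record_id[duplicated(record_id)])
  if (length(dup) > 0L) {
    stop("duplicate record_id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "", call. = FALSE)
  }
  db <- data.frame(
    record_id = record_id,
    name = clean_text(name),
    birth_date = standardize_date(birth_date, dialect, record_id),
    sex = standardize_sex(sex),
    mother_name = clean_text(mother_name),
    stringsAsFactors = FALSE
  )
  class(db) <- c("clean_db", "data.frame")
  db
}

#' Load and clean a delimited person-record database
#'
#' Reads a CSV/TSV file with a header, maps its columns to the four
#' identification fields plus the id column, cleans every row, and reports
#' per-column missingness.
#'
#' @param path Path to a delimited UTF-8 text file with a header row.
#' @param column_map Named list/vector mapping the canonical names
#'   (`record_id`, `name`, `birth_date`, `sex`, `mother_name`) to the file's
#'   column names, or the path of a YAML file holding that mapping. `NULL`
#'   means the file already uses the canonical names.
#' @param sep Field separator; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab` means tab, otherwise comma).
#' @param dialect Date dialect, see [standardize_date()].
#' @return A `clean_db` (see [clean_records()]) with attribute `load_report`,
#'   a named integer vector counting empty values per field.
#' @export
load_database <- function(path, column_map = NULL, sep = NULL,
                          dialect = "DMY") {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map)) {
    column_map <- yaml::read_yaml(column_map)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  canonical <- c("record_id", "name", "birth_date", "sex", "mother_name")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0L) {
      stop("unknown field(s) in column_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0L) {
    stop("mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  db <- clean_records(
    record_id = raw[[map[["record_id"]]]],
    name = raw[[map[["name"]]]],
    birth_date = raw[[map[["birth_date"]]]],
    sex = raw[[map[["sex"]]]],
    mother_name = raw[[map[["mother_name"]]]],
    dialect = dialect
  )
  report <- vapply(
    c("name", "birth_date", "sex", "mother_name"),
    function(f) {
      v <- db[[f]]
      sum(!nzchar(v) | (f == "sex" & v == "U"))
    },
    integer(1)
  )
  attr(db, "load_report") <- report
  db
}

#' Write a cleaned database to CSV
#'
#' @param db A `clean_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clean_csv <- function(db, path) {
  utils::write.csv(as.data.frame(db)[, c("record_id", "name", "birth_date",
                                         "sex", "mother_name")],
                   path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# tolerant validator used by tests and the encoder: sex may also be empty
# because the blank-field error class can empty any field
validate_clean_db <- function(db) {
  stopifnot(is.data.frame(db))
  need <- c("record_id", "name", "birth_date", "sex", "mother_name")
  if (!all(need %in% names(db))) {
    stop("clean_db must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok_name <- grepl("^$|^[A-Z]+( [A-Z]+)*$", db$name) &
    grepl("^$|^[A-Z]+( [A-Z]+)*$", db$mother_name)
  ok_date <- grepl("^$|^[0-9]{8}$", db$birth_date)
  ok_sex <- db$sex %in% c("M", "F", "U", "")
  bad <- which(!(ok_name & ok_date & ok_sex))
  if (length(bad) > 0L) {
    stop("invalid cleaned record(s): ",
         paste(utils::head(db$record_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
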