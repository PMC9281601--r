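# Character pairs commonly swapped in Brazilian administrative registries:
# keyboard neighbours and phonetically equivalent letters, plus the digit
# pairs most often switched in dates of birth. Used both by the codon wheel
# layout (ring-adjacent) and, up-weighted, by the typo injector.
CONFUSABLE_PAIRS <- list(
  c("N", "M"), c("S", "Z"), c("G", "Q"), c("I", "E"),
  c("0", "1"), c("5", "6"), c("6", "7")
)

#' Error model for the typo injector
#'
#' One corrupted record receives exactly one error type, drawn by
#' `type_weights`: random 1-3 character substitution (45%), middle-name
#' deletion (49%), deletion of one or more trailing surnames, e.g. due to
#' marriage renaming (5%), or a completely blank field (1%). These defaults
#' mirror error compositions observed in real health-related registries.
#'
#' @param corrupt_fraction Fraction of records corrupted (default 0.10).
#' @param type_weights Named weights over the four error types; must sum
#'   to 1.
#' @param substitution_count_range Possible numbers of substituted
#'   characters, drawn uniformly.
#' @param confusion_bias `NULL` for uniform replacement, or a data.frame
#'   with columns `char_a`, `char_b`, `weight`: when the original character
#'   belongs to a listed pair, the partner's sampling weight is multiplied
#'   by `weight` (all other candidates keep weight 1). The default
#'   up-weights the designated confusable pairs tenfold.
#' @return An `error_spec` list.
#' @export
error_spec <- function(corrupt_fraction = 0.10,
                       type_weights = c(char_substitution = 0.45,
                                        middle_name_deletion = 0.49,
                                        surname_deletion = 0.05,
                                        blank_field = 0.01),
                       substitution_count_range = 1:3,
                       confusion_bias = default_confusion_bias()) {
  stopifnot(corrupt_fraction >= 0, corrupt_fraction <= 1,
            abs(sum(type_weights) - 1) < 1e-8,
            setequal(names(type_weights),
                     c("char_substitution", "middle_name_deletion",
                       "surname_deletion", "blank_field")))
  if (!is.null(confusion_bias)) {
    stopifnot(is.data.frame(confusion_bias),
              all(c("char_a", "char_b", "weight") %in%
                    names(confusion_bias)))
  }
  structure(list(corrupt_fraction = corrupt_fraction,
                 type_weights = type_weights,
                 substitution_count_range = substitution_count_range,
                 confusion_bias = confusion_bias),
            class = "error_spec")
}

#' Default confusable-pair bias table
#'
#' @param weight Multiplier applied to each designated confusable pair.
#' @return data.frame with columns `char_a`, `char_b`, `weight`.
#' @export
default_confusion_bias <- function(weight = 10) {
  data.frame(char_a = vapply(CONFUSABLE_PAIRS, `[`, "", 1L),
             char_b = vapply(CONFUSABLE_PAIRS, `[`, "", 2L),
             weight = weight, stringsAsFactors = FALSE)
}

#' Load the bundled synthetic name-frequency tables
#'
#' Synthetic Brazilian-style given-name and surname lists with Zipf-like
#' frequency weights, shipped with the package. They stand in for a census
#' name list: same structure (name, sex, weight) and (surname, weight), but
#' the weights are invented.
#'
#' @return List with data.frames `given` (name, sex, weight) and `surnames`
#'   (surname, weight).
#' @export
default_name_tables <- function() {
  gp <- system.file("extdata", "synthetic_given_names.tsv",
                    package = "codonlink", mustWork = TRUE)
  sp <- system.file("extdata", "synthetic_surnames.tsv",
                    package = "codonlink", mustWork = TRUE)
  list(
    given = utils::read.table(gp, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE),
    surnames = utils::read.table(sp, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  )
}

# sample n full names: given name (by sex) + 1-3 surnames; most people carry
# two surnames (maternal + paternal), so the count distribution is skewed
sample_names <- function(n, sex, tables,
                         surname_count_probs = c(0.05, 0.60, 0.35)) {
  giv <- tables$given
  sur <- tables$surnames
  given <- character(n)
  for (sx in unique(sex)) {
    pool <- giv[giv$sex == sx, ]
    idx <- sex == sx
    given[idx] <- sample(pool$name, sum(idx), replace = TRUE,
                         prob = pool$weight)
  }
  n_sur <- sample(1:3, n, replace = TRUE, prob = surname_count_probs)
  draw <- function() sample(sur$surname, n, replace = TRUE,
                            prob = sur$weight)
  # surnames are distinct within one record: redraw collisions
  s1 <- draw()
  s2 <- draw()
  for (i in 1:20) {
    clash <- s2 == s1
    if (!any(clash)) break
    s2[clash] <- draw()[clash]
  }
  s3 <- draw()
  for (i in 1:20) {
    clash <- s3 == s1 | s3 == s2
    if (!any(clash)) break
    s3[clash] <- draw()[clash]
  }
  full <- paste(given, s1)
  full <- ifelse(n_sur >= 2, paste(full, s2), full)
  ifelse(n_sur >= 3, paste(full, s3), full)
}

#' Generate a synthetic population of cleaned person records
#'
#' Each record carries a full name (given name plus 1-3 frequency-sampled
#' surnames), a mother's full name (female given name; shares the
#' individual's last surname with probability `mother_share_prob`), a date
#' of birth uniform over `date_range`, and a sex drawn by `sex_ratio`. Fully
#' reproducible from `seed`.
#'
#' @param n Number of records.
#' @param name_tables Tables from [default_name_tables()].
#' @param date_range Length-2 `Date`-coercible vector.
#' @param sex_ratio Probability of sex `"M"`.
#' @param mother_share_prob Probability that the mother's last surname
#'   equals the individual's.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for generated record ids.
#' @return A `clean_db`.
#' @export
generate_population <- function(n, name_tables = default_name_tables(),
                                date_range = c("1940-01-01", "2010-12-31"),
                                sex_ratio = 0.5, mother_share_prob = 0.8,
                                seed = NULL, id_prefix = "R") {
  stopifnot(n >= 1)
  if (nrow(name_tables$given) == 0L || nrow(name_tables$surnames) == 0L) {
    stop("empty name tables", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sex <- ifelse(stats::runif(n) < sex_ratio, "M", "F")
  name <- sample_names(n, sex, name_tables)
  mother <- sample_names(n, rep("F", n), name_tables)
  share <- stats::runif(n) < mother_share_prob
  last <- function(x) vapply(strsplit(x, " ", fixed = TRUE),
                             function(t) t[length(t)], character(1))
  drop_last <- function(x) vapply(strsplit(x, " ", fixed = TRUE),
                                  function(t) paste(t[-length(t)],
                                                    collapse = " "),
                                  character(1))
  mother[share] <- paste(drop_last(mother[share]), last(name[share]))
  d0 <- as.Date(date_range[1]); d1 <- as.Date(date_range[2])
  dob <- format(d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                                replace = TRUE) - 1L, "%Y%m%d")
  db <- data.frame(
    record_id = sprintf("%s%07d", id_prefix, seq_len(n)),
    name = name, birth_date = dob, sex = sex, mother_name = mother,
    stringsAsFactors = FALSE
  )
  class(db) <- c("clean_db", "data.frame")
  db
}

# replacement for one character: uniform over the alphabet minus the
# original, with listed partners of the original up-weighted per the bias
# table
draw_replacement <- function(orig, alphabet, bias) {
  pool <- setdiff(alphabet, orig)
  w <- rep(1, length(pool))
  if (!is.null(bias)) {
    hit_a <- bias$char_a == orig
    hit_b <- bias$char_b == orig
    partners <- c(bias$char_b[hit_a], bias$char_a[hit_b])
    weights <- c(bias$weight[hit_a], bias$weight[hit_b])
    m <- match(partners, pool)
    ok <- !is.na(m)
    w[m[ok]] <- w[m[ok]] * weights[ok]
  }
  sample(pool, 1L, prob = w)
}

substitute_chars <- function(value, k, bias, digits) {
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  eligible <- which(chars != " ")
  if (length(eligible) == 0L) return(value)
  k <- min(k, length(eligible))
  pos <- if (length(eligible) == 1L) eligible else sample(eligible, k)
  alphabet <- if (digits) as.character(0:9) else LETTERS
  for (p in pos) chars[p] <- draw_replacement(chars[p], alphabet, bias)
  paste(chars, collapse = "")
}

#' Inject typographical errors into cleaned records
#'
#' A uniformly random `ceiling(corrupt_fraction * n)` subset of records is
#' corrupted; each corrupted record receives exactly one error type drawn by
#' the spec's weights. Character substitution picks a field among name,
#' mother's name and date of birth and substitutes 1-3 characters (digits
#' within the date), drawing replacements with confusable pairs up-weighted.
#' Middle-name deletion removes one interior name token (falling back to the
#' other name field, then to surname deletion, when no field has three
#' tokens); surname deletion drops one or more trailing tokens leaving at
#' least the given name; blank-field empties one uniformly chosen field.
#'
#' @param records A `clean_db`.
#' @param spec An [error_spec()].
#' @param seed Optional integer seed.
#' @return List with `records` (corrupted copy) and `error_log`, a
#'   data.frame with columns `record_id`, `type` (drawn), `applied`
#'   (realized, after fallbacks) and `field`.
#' @export
corrupt <- function(records, spec = error_spec(), seed = NULL) {
  stopifnot(inherits(spec, "error_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  empty_log <- data.frame(record_id = character(0), type = character(0),
                          applied = character(0), field = character(0),
                          stringsAsFactors = FALSE)
  if (spec$corrupt_fraction == 0 || n == 0L) {
    return(list(records = records, error_log = empty_log))
  }
  n_corrupt <- ceiling(spec$corrupt_fraction * n)
  if (n < 1 / spec$corrupt_fraction) {
    warning("fewer records than 1/corrupt_fraction; corrupting ", n_corrupt,
            " record(s)", call. = FALSE)
  }
  targets <- sort(sample.int(n, n_corrupt))
  types <- sample(names(spec$type_weights), n_corrupt, replace = TRUE,
                  prob = spec$type_weights)
  out <- records
  log <- vector("list", n_corrupt)
  ntok <- function(x) if (!nzchar(x)) 0L else
    length(strsplit(x, " ", fixed = TRUE)[[1]])

  apply_substitution <- function(i) {
    field <- sample(c("name", "mother_name", "birth_date"), 1L)
    if (!nzchar(out[[field]][i])) {
      field <- c("name", "mother_name", "birth_date")[
        which(nzchar(c(out$name[i], out$mother_name[i],
                       out$birth_date[i])))[1]]
      if (is.na(field)) return(NA_character_)
    }
    kr <- spec$substitution_count_range
    k <- if (length(kr) == 1L) kr else sample(kr, 1L)
    out[[field]][i] <<- substitute_chars(out[[field]][i], k,
                                         spec$confusion_bias,
                                         digits = field == "birth_date")
    field
  }
  apply_surname_deletion <- function(i) {
    field <- sample(c("name", "mother_name"), 1L)
    if (ntok(out[[field]][i]) < 2L) {
      field <- setdiff(c("name", "mother_name"), field)
      if (ntok(out[[field]][i]) < 2L) return(NA_character_)
    }
    tok <- strsplit(out[[field]][i], " ", fixed = TRUE)[[1]]
    j <- sample.int(length(tok) - 1L, 1L)
    out[[field]][i] <<- paste(tok[seq_len(length(tok) - j)], collapse = " ")
    field
  }

  for (idx in seq_along(targets)) {
    i <- targets[idx]
    type <- types[idx]
    applied <- type
    field <- NA_character_
    if (type == "char_substitution") {
      field <- apply_substitution(i)
    } else if (type == "middle_name_deletion") {
      field <- sample(c("name", "mother_name"), 1L)
      if (ntok(out[[field]][i]) < 3L) {
        field <- setdiff(c("name", "mother_name"), field)
      }
      if (ntok(out[[field]][i]) >= 3L) {
        tok <- strsplit(out[[field]][i], " ", fixed = TRUE)[[1]]
        interior <- 2:(length(tok) - 1L)
        drop <- if (length(interior) == 1L) interior else
          sample(interior, 1L)
        out[[field]][i] <- paste(tok[-drop], collapse = " ")
      } else {
        applied <- "surname_deletion"
        field <- apply_surname_deletion(i)
      }
    } else if (type == "surname_deletion") {
      field <- apply_surname_deletion(i)
      if (is.na(field)) {
        applied <- "char_substitution"
        field <- apply_substitution(i)
      }
    } else {
      field <- sample(c("name", "birth_date", "sex", "mother_name"), 1L)
      out[[field]][i] <- ""
    }
    log[[idx]] <- data.frame(record_id = records$record_id[i], type = type,
                             applied = applied, field = field,
                             stringsAsFactors = FALSE)
  }
  list(records = out, error_log = do.call(rbind, log))
}

#' Build a linkage benchmark with ground truth
#'
#' The subject database is a generated population; the query database is a
#' random sample of `n_query` subject records (re-identified and corrupted
#' per `spec`) plus, when `with_noise`, the same number of freshly generated
#' records guaranteed (by rejection on all four fields) to have no subject
#' counterpart -- unmatched noise.
#'
#' @param n_subject,n_query Database sizes (`n_query <= n_subject`).
#' @param spec An [error_spec()].
#' @param with_noise Add `n_query` unmatched noise records to the query set.
#' @param seed Integer seed.
#' @param name_tables See [default_name_tables()].
#' @return List with `query` and `subject` (`clean_db`s) and `manifest`, a
#'   list holding `pairs` (query_id, subject_id for every true match),
#'   `noise_ids`, and the corruption `error_log`.
#' @export
make_benchmark <- function(n_subject, n_query, spec = error_spec(),
                           with_noise = TRUE, seed = NULL,
                           name_tables = default_name_tables()) {
  stopifnot(n_query <= n_subject)
  if (!is.null(seed)) set.seed(seed)
  subject <- generate_population(n_subject, name_tables, id_prefix = "S")
  pick <- sort(sample.int(n_subject, n_query))
  query <- subject[pick, , drop = FALSE]
  query$record_id <- sprintf("Q%07d", seq_len(n_query))
  rownames(query) <- NULL
  class(query) <- c("clean_db", "data.frame")
  pairs <- data.frame(query_id = query$record_id,
                      subject_id = subject$record_id[pick],
                      stringsAsFactors = FALSE)
  cr <- corrupt(query, spec)
  query <- cr$records
  noise_ids <- character(0)
  if (with_noise && n_query > 0L) {
    key4 <- function(db) paste(db$name, db$birth_date, db$sex,
                               db$mother_name, sep = "|")
    subject_keys <- key4(subject)
    noise <- generate_population(n_query, name_tables, id_prefix = "N")
    for (iter in 1:20) {
      clash <- key4(noise) %in% subject_keys
      if (!any(clash)) break
      repl <- generate_population(sum(clash), name_tables, id_prefix = "N")
      noise[clash, c("name", "birth_date", "sex", "mother_name")] <-
        repl[, c("name", "birth_date", "sex", "mother_name")]
    }
    noise$record_id <- sprintf("Q%07d", n_query + seq_len(n_query))
    noise_ids <- noise$record_id
    query <- rbind(query, noise)
    class(query) <- c("clean_db", "data.frame")
  }
  list(query = query, subject = subject,
       manifest = list(pairs = pairs, noise_ids = noise_ids,
                       error_log = cr$error_log))
}

#' Build the four labeled databases of the classifier-training protocol
#'
#' Four databases (training_query, training_subject, testing_query,
#' testing_subject) of `2 * n_class` records each. Class-1 (matched) records
#' are duplicated across the query/subject of their split, with the query
#' copy corrupted at rate `class1_error_rate`; class-0 (unmatched) records
#' are unique to one database. At the default `n_class = 12500` each
#' database holds 25,000 records and 75,000 unique records exist overall.
#'
#' @param seed Integer seed.
#' @param n_class Records per class per database.
#' @param class1_error_rate Corruption rate applied to class-1 query copies.
#' @param name_tables See [default_name_tables()].
#' @return List with the four `clean_db`s, `train_pairs` / `test_pairs`
#'   (query_id, subject_id of class-1 duplicates), and `error_log` (per
#'   split).
#' @export
make_ml_datasets <- function(seed = NULL, n_class = 12500,
                             class1_error_rate = 0.15,
                             name_tables = default_name_tables()) {
  if (!is.null(seed)) set.seed(seed)
  spec <- error_spec(corrupt_fraction = class1_error_rate)
  build_split <- function(prefix) {
    shared <- generate_population(n_class, name_tables,
                                  id_prefix = paste0(prefix, "M"))
    uq <- generate_population(n_class, name_tables,
                              id_prefix = paste0(prefix, "UQ"))
    us <- generate_population(n_class, name_tables,
                              id_prefix = paste0(prefix, "US"))
    qcopy <- shared
    qcopy$record_id <- sub(paste0("^", prefix, "M"), paste0(prefix, "QM"),
                           shared$record_id)
    cr <- corrupt(qcopy, spec)
    query <- rbind(cr$records, uq)
    subject <- rbind(shared, us)
    class(query) <- class(subject) <- c("clean_db", "data.frame")
    list(query = query, subject = subject,
         pairs = data.frame(query_id = qcopy$record_id,
                            subject_id = shared$record_id,
                            stringsAsFactors = FALSE),
         error_log = cr$error_log)
  }
  tr <- build_split("T")
  te <- build_split("E")
  list(training_query = tr$query, training_subject = tr$subject,
       testing_query = te$query, testing_subject = te$subject,
       train_pairs = tr$pairs, test_pairs = te$pairs,
       error_log = list(training = tr$error_log, testing = te$error_log))
}
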