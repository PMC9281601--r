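# Scoring is fixed at match +1 / mismatch -2, affine gaps open -2 extend -2
# (a gap of length L costs 2 + 2L), approximating megablast defaults. The
# bit-score scale uses ungapped Karlin-Altschul constants for +1/-2 on
# uniform nucleotide composition; percentage-of-self normalization makes the
# absolute scale nearly irrelevant, but E-value cutoffs need a calibrated one.
KA_LAMBDA <- 1.33
KA_K <- 0.621
SW_MATCH <- 1L
SW_MISMATCH <- 2L
SW_GAP_OPEN <- 2L
SW_GAP_EXTEND <- 2L

# seeding presets: `fast` uses long exact words; `sensitive` short words with
# a higher shared-seed requirement, for queries the fast pass misses.
# max_candidates caps, per query, the number of gapped extensions, keeping
# the subjects with the strongest seed support (the same role as BLAST's
# max_target_seqs).
TASK_PRESETS <- list(
  fast = list(k = 12L, min_seed = 4L, gate = 30L, max_candidates = 64L),
  sensitive = list(k = 7L, min_seed = 6L, gate = 25L, max_candidates = 64L)
)

#' Alignment parameter set
#'
#' @param task `"fast"` (long exact seeds) or `"sensitive"` (short seeds,
#'   used to rescue queries with no fast-pass hit).
#' @param evalue_cutoff Positive E-value cutoff, or `NULL` to retrieve all
#'   hits (review mode).
#' @return An `alignment_params` list. Scoring, `max_hsps = 1` and
#'   plus-strand-only are fixed.
#' @export
alignment_params <- function(task = c("fast", "sensitive"),
                             evalue_cutoff = 1e-10) {
  task <- match.arg(task)
  if (!is.null(evalue_cutoff)) {
    stopifnot(is.numeric(evalue_cutoff), length(evalue_cutoff) == 1L,
              evalue_cutoff > 0)
  }
  structure(list(task = task, evalue_cutoff = evalue_cutoff,
                 max_hsps = 1L, strand = "plus"),
            class = "alignment_params")
}

bitscore_from_raw <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

evalue_from_raw <- function(raw, qlen, db_len) {
  KA_K * qlen * db_len * exp(-KA_LAMBDA * raw)
}

#' Index an encoded subject database
#'
#' Builds the exact k-mer postings view of the subject set used by the
#' internal aligner. A sequence of length L contributes `max(0, L - k + 1)`
#' postings; sequences shorter than the word length contribute none and are
#' flagged with a warning.
#'
#' @param subject An `encoded_db`.
#' @param k Word length (>= 4).
#' @return A `subject_index` holding the encoded set, word length, and the
#'   per-sequence posting counts (`n_postings`).
#' @export
index_subject <- function(subject, k = TASK_PRESETS$fast$k) {
  stopifnot(inherits(subject, "encoded_db"), k >= 4L)
  n_post <- cl_kmer_postings(subject$sequence, as.integer(k))
  short <- which(n_post == 0L & nchar(subject$sequence) > 0L)
  if (length(short) > 0L) {
    warning(length(short), " sequence(s) shorter than the word length ",
            "contribute no postings", call. = FALSE)
  }
  structure(list(subject = subject, k = as.integer(k),
                 n_postings = stats::setNames(n_post, subject$record_id)),
            class = "subject_index")
}

#' Align encoded queries against an indexed subject database
#'
#' Internal backend: exact k-mer seeding, ungapped diagonal screening, then
#' optimal affine-gap local alignment of surviving candidate pairs. At most
#' one HSP (the optimal local alignment) is reported per query-subject pair;
#' plus strand only; hits above the E-value cutoff are dropped. Queries and
#' subject must have been encoded under the same key (checked by
#' fingerprint).
#'
#' @param queries An `encoded_db`.
#' @param index A `subject_index` (see [index_subject()]), or an `encoded_db`
#'   which is indexed on the fly at the task's word length.
#' @param params An [alignment_params()].
#' @param query_subset Optional integer vector of query row indices to run.
#' @return A data.frame of hits with BLAST tabular columns `qseqid, sseqid,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore` plus `qcovhsp`, `qlen`, `slen` and the raw alignment `score`.
#' @export
align <- function(queries, index, params = alignment_params(),
                  query_subset = NULL) {
  stopifnot(inherits(queries, "encoded_db"),
            inherits(params, "alignment_params"))
  preset <- TASK_PRESETS[[params$task]]
  if (inherits(index, "encoded_db")) index <- index_subject(index, preset$k)
  stopifnot(inherits(index, "subject_index"))
  subject <- index$subject
  fq <- attr(queries, "key_fingerprint")
  fs <- attr(subject, "key_fingerprint")
  if (!is.null(fq) && !is.null(fs) && !identical(fq, fs)) {
    stop("query and subject databases were encoded under different keys",
         call. = FALSE)
  }
  if (is.null(query_subset)) query_subset <- seq_len(nrow(queries))
  raw <- cl_align_batch(
    queries$sequence, subject$sequence, as.integer(query_subset),
    preset$k, preset$min_seed, preset$gate, preset$max_candidates,
    SW_MATCH, SW_MISMATCH, SW_GAP_OPEN, SW_GAP_EXTEND
  )
  hits <- as.data.frame(raw, stringsAsFactors = FALSE)
  qlen <- nchar(queries$sequence)[hits$qidx]
  slen <- nchar(subject$sequence)[hits$sidx]
  db_len <- sum(nchar(subject$sequence))
  out <- data.frame(
    qseqid = queries$record_id[hits$qidx],
    sseqid = subject$record_id[hits$sidx],
    pident = ifelse(hits$length > 0, 100 * hits$matches / hits$length, 0),
    length = hits$length,
    mismatch = hits$mismatch,
    gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = evalue_from_raw(hits$score, qlen, db_len),
    bitscore = bitscore_from_raw(hits$score),
    qcovhsp = 100 * (hits$qend - hits$qstart + 1) / qlen,
    qlen = qlen, slen = slen,
    score = hits$score,
    stringsAsFactors = FALSE
  )
  if (!is.null(params$evalue_cutoff)) {
    out <- out[out$evalue <= params$evalue_cutoff, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# two-pass orchestration: all queries under `fast`; queries with zero
# surviving hits re-run under `sensitive`
align_two_pass <- function(queries, subject, evalue_cutoff = 1e-10) {
  p_fast <- alignment_params("fast", evalue_cutoff)
  hits <- align(queries, subject, p_fast)
  missed <- which(!(queries$record_id %in% hits$qseqid))
  if (length(missed) > 0L) {
    p_sens <- alignment_params("sensitive", evalue_cutoff)
    rescue <- align(queries, subject, p_sens, query_subset = missed)
    hits <- rbind(hits, rescue)
    rownames(hits) <- NULL
  }
  hits
}

#' Self-alignment bit-scores, in closed form
#'
#' A sequence aligned against itself matches end to end, so the raw score is
#' `length x match reward`; the bit-score transform is applied directly and
#' no alignment is run. Records with empty sequences have no self-score and
#' are excluded with a warning.
#'
#' @param enc An `encoded_db`.
#' @return Named numeric vector, record id -> self bit-score.
#' @export
self_scores <- function(enc) {
  len <- nchar(enc$sequence)
  empty <- which(len == 0L)
  if (length(empty) > 0L) {
    warning(length(empty), " record(s) with empty sequences excluded from ",
            "self-scores", call. = FALSE)
  }
  keep <- len > 0L
  stats::setNames(bitscore_from_raw(SW_MATCH * len[keep]),
                  enc$record_id[keep])
}

#' Normalize hit bit-scores as percentage of the self-hit
#'
#' Long sequences outscore short ones even for equally perfect matches, which
#' would penalize people with short names. Each hit's bit-score is therefore
#' expressed as a percentage of the best possible bit-score for that query --
#' the query aligned against itself -- yielding `norm_bitscore` in (0, 100]
#' with self-hits at exactly 100.
#'
#' @param hits Hit table from [align()].
#' @param selfscores Named vector from [self_scores()] covering every qseqid.
#' @return `hits` with a `norm_bitscore` column appended; hits whose query
#'   has no self-score are dropped with a warning.
#' @export
normalize_hits <- function(hits, selfscores) {
  ss <- selfscores[hits$qseqid]
  miss <- is.na(ss)
  if (any(miss)) {
    warning(sum(miss), " hit(s) dropped: query has no self-score",
            call. = FALSE)
    hits <- hits[!miss, , drop = FALSE]
    ss <- ss[!miss]
  }
  hits$norm_bitscore <- pmin(100, 100 * hits$bitscore / unname(ss))
  rownames(hits) <- NULL
  hits
}

#' Optimal local alignment of one sequence pair
#'
#' Runs the internal backend's affine-gap Smith-Waterman directly on two DNA
#' sequences (no seeding or screening) and returns the optimal local
#' alignment statistics under the package's fixed scoring.
#'
#' @param qseq,sseq DNA sequence strings over A/C/G/T.
#' @return Named integer vector: `score` (raw), `length`, `matches`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive nucleotide coordinates); all zero when no positive-scoring
#'   alignment exists.
#' @export
align_pair <- function(qseq, sseq) {
  stopifnot(is.character(qseq), is.character(sseq),
            length(qseq) == 1L, length(sseq) == 1L)
  cl_sw_pair(qseq, sseq, SW_MATCH, SW_MISMATCH, SW_GAP_OPEN, SW_GAP_EXTEND)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore",
              "qcovhsp", "qlen")

#' Write / read a tabular hit file
#'
#' 14-column TSV in BLAST `outfmt 6`-compatible order (the standard 12
#' columns extended with `qcovhsp` and `qlen`), so files produced by an
#' external `blastn` run with
#' `-outfmt "6 std qcovhsp qlen"` parse identically.
#'
#' @param hits Hit table.
#' @param path TSV path.
#' @return `path` invisibly / the hit data.frame.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          rep(NA, 12)))
  names(out) <- HIT_COLS
  out
}

#' Align with the external blastn backend
#'
#' Adapter around NCBI BLAST+ `blastn`, invoked with `-dust no -max_hsps 1
#' -strand plus` and the given task and E-value cutoff. Self bit-scores for
#' normalization are taken from blastn itself (each query against its own
#' database restricted to the self pair), so normalized scores live on
#' blastn's own bit-score scale.
#'
#' @param queries,subject `encoded_db` objects sharing one key.
#' @param task `"megablast"` or `"dc-megablast"`.
#' @param evalue_cutoff E-value cutoff, `NULL` for review mode (all hits).
#' @param blastn,makeblastdb Paths to the BLAST+ executables.
#' @return A hit table like [align()]'s (without `slen`/`score`), already
#'   normalized (`norm_bitscore` column).
#' @export
align_blastn <- function(queries, subject, task = "megablast",
                         evalue_cutoff = 1e-10, blastn = "blastn",
                         makeblastdb = "makeblastdb") {
  if (Sys.which(blastn) == "" || Sys.which(makeblastdb) == "") {
    stop("BLAST+ executables not found on PATH", call. = FALSE)
  }
  fq <- attr(queries, "key_fingerprint")
  fs <- attr(subject, "key_fingerprint")
  if (!is.null(fq) && !is.null(fs) && !identical(fq, fs)) {
    stop("query and subject databases were encoded under different keys",
         call. = FALSE)
  }
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "q.fasta"); sf <- file.path(td, "s.fasta")
  write_fasta(queries, qf); write_fasta(subject, sf)
  run_blastn <- function(query_fa, db_fa, evalue) {
    db <- paste0(db_fa, ".db")
    system2(makeblastdb, c("-in", db_fa, "-dbtype", "nucl", "-out", db),
            stdout = FALSE, stderr = FALSE)
    out <- file.path(td, paste0(basename(query_fa), ".hits"))
    args <- c("-query", query_fa, "-db", db, "-task", task,
              "-dust", "no", "-max_hsps", "1", "-strand", "plus",
              "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore qcovhsp qlen"),
              "-out", out)
    if (!is.null(evalue)) args <- c(args, "-evalue", format(evalue))
    status <- system2(blastn, args, stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("blastn failed (exit ", status, ")", call. = FALSE)
    if (file.size(out) == 0L) {
      h <- as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(HIT_COLS)), HIT_COLS))
      h$qseqid <- character(0); h$sseqid <- character(0)
      return(h)
    }
    read_hits(out)
  }
  hits <- run_blastn(qf, sf, evalue_cutoff)
  selfh <- run_blastn(qf, qf, NULL)
  selfh <- selfh[selfh$qseqid == selfh$sseqid, , drop = FALSE]
  ss <- stats::setNames(selfh$bitscore, selfh$qseqid)
  normalize_hits(hits, ss)
}
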