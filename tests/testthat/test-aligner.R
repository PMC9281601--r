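test_that("self-alignment yields the perfect hit", {
  set.seed(21)
  db <- random_clean_db(10, allow_empty = FALSE)
  enc <- encode_records(db, build_default_wheel("selfkey"))
  hits <- align(enc, enc)
  self <- hits[hits$qseqid == hits$sseqid, ]
  expect_identical(nrow(self), 10L)
  expect_true(all(self$pident == 100))
  expect_true(all(self$mismatch == 0L))
  expect_true(all(self$gapopen == 0L))
  expect_true(all(self$qcovhsp == 100))
  expect_true(all(self$qstart == 1L & self$sstart == 1L))
  expect_true(all(self$qend == self$qlen))
})

test_that("k-mer postings follow the L - k + 1 arithmetic", {
  db <- data.frame(record_id = c("a", "b", "c"),
                   name = c("ABCDEFGH", "ABCDEFGH", "AB"),
                   birth_date = "", sex = "", mother_name = "",
                   stringsAsFactors = FALSE)
  class(db) <- c("clean_db", "data.frame")
  enc <- encode_records(db, build_default_wheel())
  idx <- index_subject(enc, k = 12L)
  L <- nchar(enc$sequence)
  expect_identical(unname(idx$n_postings), pmax(0L, L - 12L + 1L))
  # identical sequences contribute identical posting counts
  expect_identical(idx$n_postings[["a"]], idx$n_postings[["b"]])
  # k longer than the shortest sequence: zero postings, with a warning
  expect_warning(idx2 <- index_subject(enc, k = 16L), "word length")
  expect_identical(idx2$n_postings[["c"]], 0L)
})

test_that("internal backend raw scores equal brute-force Smith-Waterman", {
  set.seed(22)
  nts <- c("A", "C", "G", "T")
  for (i in 1:60) {
    la <- sample(10:180, 1); lb <- sample(10:180, 1)
    a <- paste(sample(nts, la, TRUE), collapse = "")
    # half the pairs share a planted common segment so scores are non-trivial
    b <- if (i %% 2 == 0) {
      paste(sample(nts, lb, TRUE), collapse = "")
    } else {
      core <- substr(a, 1, min(la, sample(20:60, 1)))
      paste0(paste(sample(nts, sample(0:20, 1), TRUE), collapse = ""), core,
             paste(sample(nts, sample(0:20, 1), TRUE), collapse = ""))
    }
    expect_identical(align_pair(a, b)[["score"]],
                     as.integer(bios_sw_score(a, b)))
  }
  # tiny cases against the independent pure-R DP as well
  for (i in 1:25) {
    a <- paste(sample(nts, sample(5:25, 1), TRUE), collapse = "")
    b <- paste(sample(nts, sample(5:25, 1), TRUE), collapse = "")
    expect_identical(align_pair(a, b)[["score"]], as.integer(r_sw_score(a, b)))
  }
})

test_that("pipeline scores on mutated record pairs match the oracle", {
  set.seed(23)
  pop <- generate_population(60, seed = 231)
  cr <- corrupt(pop, error_spec(corrupt_fraction = 1), seed = 232)
  w <- build_default_wheel("oracle")
  qe <- encode_records(cr$records, w)
  se <- encode_records(pop, w)
  hits <- align(qe, se, alignment_params("fast", evalue_cutoff = NULL))
  own <- hits[hits$qseqid == hits$sseqid, ]
  expect_gte(nrow(own), 50L)
  for (i in seq_len(nrow(own))) {
    qs <- qe$sequence[match(own$qseqid[i], qe$record_id)]
    ss <- se$sequence[match(own$sseqid[i], se$record_id)]
    expect_identical(own$score[i], as.integer(bios_sw_score(qs, ss)))
  }
})

test_that("one HSP per pair, plus strand, deterministic output", {
  set.seed(24)
  db <- random_clean_db(40, allow_empty = FALSE)
  enc <- encode_records(db, build_default_wheel("det"))
  h1 <- align(enc, enc, alignment_params("fast", evalue_cutoff = NULL))
  h2 <- align(enc, enc, alignment_params("fast", evalue_cutoff = NULL))
  expect_identical(h1, h2)
  expect_false(any(duplicated(h1[, c("qseqid", "sseqid")])))
  expect_true(all(h1$qstart <= h1$qend & h1$sstart <= h1$send))
  expect_true(all(h1$qend <= h1$qlen))
  expect_true(all(h1$qcovhsp >= 0 & h1$qcovhsp <= 100))
})

test_that("alignment scores are symmetric for sequence pairs", {
  set.seed(25)
  nts <- c("A", "C", "G", "T")
  for (i in 1:40) {
    a <- paste(sample(nts, 60, TRUE), collapse = "")
    b <- paste(sample(nts, 60, TRUE), collapse = "")
    expect_identical(align_pair(a, b)[["score"]], align_pair(b, a)[["score"]])
  }
})

test_that("the E-value cutoff drops weak hits; review mode keeps them", {
  set.seed(26)
  pop <- generate_population(200, seed = 261)
  w <- build_default_wheel("ev")
  enc <- encode_records(pop, w)
  all_hits <- align(enc, enc, alignment_params("fast", evalue_cutoff = NULL))
  cut <- align(enc, enc, alignment_params("fast", evalue_cutoff = 1e-30))
  expect_lt(nrow(cut), nrow(all_hits))
  expect_true(all(cut$evalue <= 1e-30))
  strict_set <- paste(cut$qseqid, cut$sseqid)
  loose_set <- paste(all_hits$qseqid, all_hits$sseqid)
  expect_true(all(strict_set %in% loose_set))
})

test_that("self-scores come from the closed form and match the backend", {
  db <- data.frame(record_id = "s", name = "ABCDEFG", birth_date = "",
                   sex = "", mother_name = "", stringsAsFactors = FALSE)
  class(db) <- c("clean_db", "data.frame")
  enc <- encode_records(db, build_default_wheel())
  # 7 chars + 3 separators = 30 nt; raw self score = 30
  expect_identical(nchar(enc$sequence), 30L)
  ss <- self_scores(enc)
  expect_equal(unname(ss["s"]), (1.33 * 30 - log(0.621)) / log(2))
  hit <- align(enc, enc)
  expect_equal(hit$bitscore, unname(ss["s"]), tolerance = 1e-12)
  # longer sequence, strictly larger self-score
  db2 <- db; db2$name <- "ABCDEFGH"; class(db2) <- class(db)
  expect_gt(self_scores(encode_records(db2, build_default_wheel()))[["s"]],
            ss[["s"]])
})

test_that("normalization is percentage-of-self with self-hits at 100", {
  hits <- data.frame(qseqid = c("a", "a", "b"), sseqid = c("a", "x", "y"),
                     bitscore = c(80, 40, 60), stringsAsFactors = FALSE)
  ss <- c(a = 80, b = 120)
  nh <- normalize_hits(hits, ss)
  expect_equal(nh$norm_bitscore, c(100, 50, 50))
  # missing self-score: hit dropped with a warning
  expect_warning(
    nh2 <- normalize_hits(
      data.frame(qseqid = "z", sseqid = "y", bitscore = 10,
                 stringsAsFactors = FALSE), ss),
    "self-score")
  expect_identical(nrow(nh2), 0L)
})

test_that("normalized score is invariant to equal padding on both sides", {
  w <- build_default_wheel("pad")
  mk <- function(name, id) {
    db <- data.frame(record_id = id, name = name, birth_date = "19900101",
                     sex = "M", mother_name = "ANA SILVA",
                     stringsAsFactors = FALSE)
    class(db) <- c("clean_db", "data.frame")
    db
  }
  run <- function(qname, sname) {
    qe <- encode_records(mk(qname, "q"), w)
    se <- encode_records(mk(sname, "s"), w)
    h <- normalize_hits(align(qe, se, alignment_params("fast", NULL)),
                        self_scores(qe))
    h$norm_bitscore[h$qseqid == "q" & h$sseqid == "s"]
  }
  short <- run("JOSE SILVA", "JOSE SILVE")
  padded <- run("JOSE SILVA DOS SANTOS JUNIOR",
                "JOSE SILVE DOS SANTOS JUNIOR")
  # same single typo; normalization damps the length effect: the padded pair
  # may only look more similar, and both stay well above unrelated pairs
  expect_gte(padded, short)
  expect_lt(abs(padded - short), 10)
})

test_that("key fingerprint mismatch refuses to align", {
  db <- random_clean_db(5)
  e1 <- encode_records(db, build_default_wheel("key-a"))
  e2 <- encode_records(db, build_default_wheel("key-b"))
  expect_error(align(e1, e2), "different keys")
})

test_that("hit tables roundtrip through the 14-column TSV dialect", {
  set.seed(27)
  db <- random_clean_db(20, allow_empty = FALSE)
  enc <- encode_records(db, build_default_wheel("tsv"))
  hits <- align(enc, enc)
  path <- tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_identical(back$qseqid, hits$qseqid)
  expect_equal(back$bitscore, hits$bitscore, tolerance = 1e-6)
  expect_identical(ncol(back), 14L)
})
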