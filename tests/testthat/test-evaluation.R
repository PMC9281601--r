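mk_results <- function(query_id, subject_id, probability) {
  data.frame(query_id = query_id, subject_id = subject_id,
             probability = probability,
             decision = ifelse(is.na(subject_id), "unmatched", "matched"),
             n_candidates = 1L, stringsAsFactors = FALSE)
}

test_that("perfect linkage scores perfectly", {
  pairs <- data.frame(query_id = sprintf("q%03d", 1:100),
                      subject_id = sprintf("s%03d", 1:100),
                      stringsAsFactors = FALSE)
  noise <- sprintf("n%03d", 1:100)
  res <- rbind(
    mk_results(pairs$query_id, pairs$subject_id, runif(100, 0.9, 1)),
    mk_results(noise, NA_character_, runif(100, 0, 0.1))
  )
  m <- score_linkage(res, list(pairs = pairs, noise_ids = noise))
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(100L, 0L, 0L, 100L))
  expect_equal(c(m$precision, m$recall, m$f_score, m$accuracy),
               rep(1, 4))
  expect_equal(m$auc, 1)
})

test_that("degenerate outputs score as defined", {
  pairs <- data.frame(query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
                      stringsAsFactors = FALSE)
  manifest <- list(pairs = pairs, noise_ids = c("n1", "n2"))
  allun <- mk_results(c("q1", "q2", "n1", "n2"), NA_character_, 0)
  m <- score_linkage(allun, manifest)
  expect_equal(m$recall, 0)
  expect_identical(m$tn, 2L)
  # wrong links and linked noise are false positives
  wrong <- mk_results(c("q1", "q2", "n1", "n2"),
                      c("s2", "s2", "s1", NA), c(1, 1, 1, 0))
  m2 <- score_linkage(wrong, manifest)
  expect_identical(m2$fp, 2L)   # q1 mislinked + linked noise n1
  expect_identical(m2$tp, 1L)   # q2 correctly linked
  expect_identical(m2$fn, 0L)   # a mislinked true pair is fp, not fn
  expect_identical(m2$tn, 1L)
  # ids outside the manifest are rejected
  expect_error(
    score_linkage(mk_results("zz", NA_character_, 0), manifest),
    "not in manifest")
})

test_that("AUC: trapezoid equals brute-force concordance; random is ~0.5", {
  set.seed(71)
  concordance <- function(score, label) {
    pos <- score[label == 1L]; neg <- score[label == 0L]
    s <- 0
    for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
    s / (length(pos) * length(neg))
  }
  for (i in 1:5) {
    n <- 60
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) label[1:2] <- c(0L, 1L)
    score <- round(runif(n), 2) + label * runif(1, 0, 0.3)
    roc <- codonlink:::roc_points(score, label)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(codonlink:::trapezoid_auc(roc),
                 concordance(score, label), tolerance = 1e-9)
  }
  # random probabilities at n = 2000: AUC ~ 0.5
  pairs <- data.frame(query_id = sprintf("q%d", 1:1000),
                      subject_id = sprintf("s%d", 1:1000),
                      stringsAsFactors = FALSE)
  noise <- sprintf("n%d", 1:1000)
  res <- rbind(mk_results(pairs$query_id, pairs$subject_id, runif(1000)),
               mk_results(noise, NA_character_, runif(1000)))
  m <- score_linkage(res, list(pairs = pairs, noise_ids = noise))
  expect_lt(abs(m$auc - 0.5), 0.05)
  # metrics invariant under row permutation
  perm <- res[sample.int(nrow(res)), ]
  expect_equal(score_linkage(perm, list(pairs = pairs, noise_ids = noise)),
               m)
})

test_that("per-field error profile matches the simulator's error log", {
  models <- protocol_fixture()
  bm <- make_benchmark(400, 80, seed = 72)
  w <- build_default_wheel("prof")
  res <- link(encode_records(bm$query, w), encode_records(bm$subject, w),
              models$rf)
  prof <- per_field_error_profile(res, bm$manifest, bm$query, bm$subject)
  # cross-check against the manifest's log restricted to linked true pairs
  truth <- stats::setNames(bm$manifest$pairs$subject_id,
                           bm$manifest$pairs$query_id)
  linked_ok <- res$query_id[which(!is.na(res$subject_id) &
    res$query_id %in% names(truth) &
    res$subject_id == unname(truth[res$query_id]))]
  log <- bm$manifest$error_log
  log <- log[log$record_id %in% linked_ok, ]
  expected <- table(factor(log$field, levels = c("name", "birth_date",
                                                 "sex", "mother_name")))
  expect_identical(unname(prof[c("name", "birth_date", "sex",
                                 "mother_name")]),
                   as.integer(expected))
  expect_identical(unname(prof[["any_field"]]), nrow(log))
  expect_identical(unname(prof[["n_pairs"]]), length(linked_ok))
})

test_that("zero corruption yields an all-zero error profile", {
  models <- protocol_fixture()
  bm <- make_benchmark(200, 40, spec = error_spec(corrupt_fraction = 0),
                       seed = 73)
  w <- build_default_wheel("prof0")
  res <- link(encode_records(bm$query, w), encode_records(bm$subject, w),
              models$rf)
  prof <- per_field_error_profile(res, bm$manifest, bm$query, bm$subject)
  expect_identical(unname(prof[c("name", "birth_date", "sex",
                                 "mother_name", "any_field")]),
                   rep(0L, 5))
})

test_that("substitution networks tally positional swaps in mismatch-only fields", {
  pairs <- data.frame(query_id = "q1", subject_id = "s1",
                      stringsAsFactors = FALSE)
  manifest <- list(pairs = pairs, noise_ids = character(0))
  res <- mk_results("q1", "s1", 1)
  qdb <- data.frame(record_id = "q1", name = "LUIZ", birth_date = "19900101",
                    sex = "M", mother_name = "ANA", stringsAsFactors = FALSE)
  sdb <- data.frame(record_id = "s1", name = "LUIS", birth_date = "19900101",
                    sex = "M", mother_name = "ANA SILVA",
                    stringsAsFactors = FALSE)
  net <- substitution_network(res, manifest, qdb, sdb)
  # one S/Z swap; the unequal-length mother field is excluded
  expect_identical(net$letters$char_a, "S")
  expect_identical(net$letters$char_b, "Z")
  expect_identical(net$letters$count, 1L)
  expect_equal(net$letters$frequency, 100 / 4)
  expect_identical(nrow(net$digits), 0L)
})

test_that("a concentrated confusion bias surfaces as the top letter edge", {
  models <- protocol_fixture()
  set.seed(74)
  subject <- generate_population(400, seed = 741, id_prefix = "S")
  query <- subject
  query$record_id <- sprintf("Q%05d", seq_len(nrow(query)))
  class(query) <- c("clean_db", "data.frame")
  spec <- error_spec(corrupt_fraction = 1,
                     type_weights = c(char_substitution = 1,
                                      middle_name_deletion = 0,
                                      surname_deletion = 0, blank_field = 0),
                     confusion_bias = data.frame(char_a = "N", char_b = "M",
                                                 weight = 1000))
  cr <- corrupt(query, spec, seed = 742)
  manifest <- list(pairs = data.frame(query_id = query$record_id,
                                      subject_id = subject$record_id,
                                      stringsAsFactors = FALSE),
                   noise_ids = character(0))
  w <- build_default_wheel("net")
  res <- link(encode_records(cr$records, w), encode_records(subject, w),
              models$rf)
  net <- substitution_network(res, manifest, cr$records, subject)
  expect_gt(nrow(net$letters), 1L)
  expect_identical(paste(net$letters$char_a[1], net$letters$char_b[1]),
                   "M N")
  expect_true(all(net$letters$frequency >= 0))
  expect_lte(sum(net$letters$frequency), 100 + 1e-9)
})
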