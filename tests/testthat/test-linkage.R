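toy_features <- function(n, class1) {
  # linearly separable toy geometry: strong hits vs weak hits
  data.frame(
    norm_bitscore = if (class1) runif(n, 90, 100) else runif(n, 10, 40),
    mismatch = if (class1) rpois(n, 1) else rpois(n, 12),
    gapopen = if (class1) rbinom(n, 1, 0.2) else rbinom(n, 4, 0.5),
    qcovhsp = if (class1) runif(n, 95, 100) else runif(n, 10, 60),
    sstart = if (class1) rep(1, n) else sample(5:60, n, TRUE),
    qstart = if (class1) rep(1, n) else sample(5:60, n, TRUE)
  )
}

test_that("self-hits map to the canonical feature vector", {
  set.seed(31)
  db <- random_clean_db(5, allow_empty = FALSE)
  enc <- encode_records(db, build_default_wheel("feat"))
  hits <- normalize_hits(align(enc, enc), self_scores(enc))
  self <- hits[hits$qseqid == hits$sseqid, ]
  f <- extract_features(self)
  expect_identical(names(f), c("norm_bitscore", "mismatch", "gapopen",
                               "qcovhsp", "sstart", "qstart"))
  for (i in seq_len(nrow(f))) {
    expect_equal(unlist(f[i, ]),
                 c(norm_bitscore = 100, mismatch = 0, gapopen = 0,
                   qcovhsp = 100, sstart = 1, qstart = 1))
  }
})

test_that("both models separate linearly separable toy data perfectly", {
  set.seed(32)
  feats <- rbind(toy_features(200, TRUE), toy_features(200, FALSE))
  labels <- rep(c(1L, 0L), each = 200)
  models <- train_models(feats, labels, seed = 1)
  expect_equal(models$report$rf[["accuracy"]], 1)
  expect_equal(models$report$lr[["accuracy"]], 1)
  expect_error(train_models(toy_features(50, TRUE), rep(1L, 50)),
               "both classes")
})

test_that("training on permuted labels collapses accuracy to chance", {
  set.seed(33)
  feats <- rbind(toy_features(1000, TRUE), toy_features(1000, FALSE))
  labels <- sample(rep(c(1L, 0L), each = 1000))  # permuted: labels x features independent
  models <- train_models(feats, labels, seed = 2)
  test_feats <- rbind(toy_features(1000, TRUE), toy_features(1000, FALSE))
  test_labels <- rep(c(1L, 0L), each = 1000)
  acc <- mean(classify(models$rf, test_feats)$class == test_labels)
  expect_gt(acc, 0.5 - 0.03)
  expect_lt(acc, 0.5 + 0.03)
})

test_that("classification is a proper probability with enforced schema", {
  set.seed(34)
  models <- protocol_fixture()
  f <- toy_features(50, TRUE)
  out <- classify(models$rf, f)
  expect_true(all(out$probability >= 0 & out$probability <= 1))
  expect_identical(out$class, as.integer(out$probability >= 0.5))
  expect_error(classify(models$rf, f[, 1:5]), "feature columns")
  bad <- f; names(bad)[1] <- "bitscore"
  expect_error(classify(models$rf, bad), "feature columns")
})

test_that("protocol-trained models recognize perfect and null features", {
  models <- protocol_fixture()
  self_feat <- data.frame(norm_bitscore = 100, mismatch = 0, gapopen = 0,
                          qcovhsp = 100, sstart = 1, qstart = 1)
  null_feat <- data.frame(norm_bitscore = 0, mismatch = 0, gapopen = 0,
                          qcovhsp = 0, sstart = 0, qstart = 0)
  expect_identical(classify(models$rf, self_feat)$class, 1L)
  expect_identical(classify(models$lr, self_feat)$class, 1L)
  expect_identical(classify(models$rf, null_feat)$class, 0L)
  expect_identical(classify(models$lr, null_feat)$class, 0L)
  # out-of-sample accuracy on the protocol's testing split is near-perfect
  expect_gte(models$test_report$rf[["accuracy"]], 0.97)
})

test_that("higher mismatch never raises the LR match probability", {
  models <- protocol_fixture()
  base <- data.frame(norm_bitscore = 85, mismatch = 0:15, gapopen = 1,
                     qcovhsp = 90, sstart = 1, qstart = 1)
  p <- classify(models$lr, base)$probability
  expect_true(all(diff(p) <= 1e-12))
})

test_that("linking identical databases matches every record to its copy", {
  set.seed(35)
  models <- protocol_fixture()
  pop <- generate_population(10, seed = 351)
  w <- build_default_wheel("ident")
  qdb <- pop
  qdb$record_id <- sprintf("Q%02d", 1:10)
  class(qdb) <- c("clean_db", "data.frame")
  res <- link(encode_records(qdb, w), encode_records(pop, w), models$rf)
  expect_identical(nrow(res), 10L)
  expect_true(all(res$decision == "matched"))
  expect_identical(res$subject_id, pop$record_id)
  expect_true(all(res$probability >= 0.5))
})

test_that("noise queries absent from the subject stay unmatched", {
  models <- protocol_fixture()
  bm <- make_benchmark(300, 30, spec = error_spec(corrupt_fraction = 0),
                       with_noise = TRUE, seed = 36)
  w <- build_default_wheel("noise")
  res <- link(encode_records(bm$query, w), encode_records(bm$subject, w),
              models$rf)
  noise <- res[res$query_id %in% bm$manifest$noise_ids, ]
  expect_identical(nrow(noise), 30L)
  expect_true(all(noise$decision == "unmatched"))
  # one decision per query, never more than one linked subject
  expect_identical(anyDuplicated(res$query_id), 0L)
})

test_that("exact-duplicate pair features are invariant under the encoding key", {
  set.seed(37)
  pop <- generate_population(80, seed = 371)
  qdb <- pop
  qdb$record_id <- sprintf("Q%04d", seq_len(nrow(pop)))
  class(qdb) <- c("clean_db", "data.frame")
  run <- function(key) {
    w <- build_default_wheel(key)
    qe <- encode_records(qdb, w)
    se <- encode_records(pop, w)
    h <- normalize_hits(align(qe, se), self_scores(qe))
    h <- h[h$sseqid == pop$record_id[match(h$qseqid, qdb$record_id)], ]
    h <- h[order(h$qseqid), ]
    rownames(h) <- NULL
    cbind(h["qseqid"], extract_features(h))
  }
  expect_equal(run("key-one"), run("completely different key"))
})

test_that("linkage decisions are stable across encoding keys", {
  models <- protocol_fixture()
  bm <- make_benchmark(500, 100, seed = 372, with_noise = TRUE)
  decide <- function(key) {
    w <- build_default_wheel(key)
    res <- link(encode_records(bm$query, w), encode_records(bm$subject, w),
                models$rf)
    res[order(res$query_id), c("query_id", "subject_id", "decision")]
  }
  d1 <- decide("alpha-key")
  d2 <- decide("beta-key")
  agree <- mean(d1$decision == d2$decision &
                  (is.na(d1$subject_id) == is.na(d2$subject_id)) &
                  (is.na(d1$subject_id) | d1$subject_id == d2$subject_id),
                na.rm = TRUE)
  expect_gte(agree, 0.98)
})

test_that("linkage decisions are reproducible and serializable", {
  models <- protocol_fixture()
  bm <- make_benchmark(200, 20, seed = 38)
  w <- build_default_wheel("repro")
  qe <- encode_records(bm$query, w); se <- encode_records(bm$subject, w)
  r1 <- link(qe, se, models$rf)
  r2 <- link(qe, se, models$rf)
  expect_identical(r1, r2)
  path <- tempfile(fileext = ".rds")
  save_model(models$rf, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  r3 <- link(qe, se, m2)
  expect_identical(as.data.frame(r1), as.data.frame(r3))
})
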