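# ranger is imported (not just ::-called) so that its predict() S3 method is
# registered even when a model is deserialized before any training happens
#' @importFrom ranger ranger
NULL

FEATURE_NAMES <- c("norm_bitscore", "mismatch", "gapopen", "qcovhsp",
                   "sstart", "qstart")

#' Extract the six classifier features from normalized hits
#'
#' The match classifier sees exactly six alignment-derived features, in this
#' order: normalized bit-score (% of the query's self-hit), mismatch count,
#' gap-opening count, query coverage by the HSP (%), subject start and query
#' start (1-based). A self-hit maps to `(100, 0, 0, 100, 1, 1)`.
#'
#' @param hits Normalized hit table (see [normalize_hits()]).
#' @return data.frame with the six feature columns in canonical order.
#' @export
extract_features <- function(hits) {
  stopifnot("norm_bitscore" %in% names(hits))
  out <- hits[, FEATURE_NAMES, drop = FALSE]
  rownames(out) <- NULL
  out
}

new_match_model <- function(algorithm, fit, threshold, fingerprint) {
  structure(list(algorithm = algorithm, fit = fit, threshold = threshold,
                 feature_names = FEATURE_NAMES, fingerprint = fingerprint),
            class = "match_model")
}

#' Train the match/non-match classifiers
#'
#' Fits the two reference models on labeled feature vectors: a random forest
#' (75 trees) and a logistic regression with library defaults. Features are
#' key-invariant -- alignment scores depend only on codon distances, which
#' wheel rotation preserves -- so a model trained under one key is valid
#' under any other.
#'
#' @param features data.frame with the six canonical feature columns.
#' @param labels Vector of 0/1 class labels (1 = match); both classes must
#'   be present.
#' @param seed Integer seed for the forest's bootstrap.
#' @param threshold Decision threshold on the match probability.
#' @return List with `rf` and `lr` (`match_model` objects) and `report`
#'   (held-in training accuracy and per-class recall for each model).
#' @export
train_models <- function(features, labels, seed = 1L, threshold = 0.5) {
  stopifnot(identical(names(features), FEATURE_NAMES))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  set.seed(seed)
  y <- factor(labels, levels = c(0L, 1L))
  rf_fit <- ranger::ranger(
    x = features, y = y, num.trees = 75L, probability = TRUE,
    num.threads = 1L, seed = seed
  )
  # quasi-separation warnings are expected: alignment features separate the
  # classes almost perfectly on simulated data
  lr_fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(),
               data = cbind(features, y = labels))
  )
  fingerprint <- list(
    seed = seed,
    data_hash = cl_sha256_hex(paste(
      nrow(features), sum(labels),
      signif(sum(features$norm_bitscore), 12), sep = ":"))
  )
  rf <- new_match_model("random_forest", rf_fit, threshold, fingerprint)
  lr <- new_match_model("logistic_regression", lr_fit, threshold, fingerprint)
  report <- lapply(list(rf = rf, lr = lr), function(m) {
    cls <- classify(m, features)$class
    c(accuracy = mean(cls == labels),
      recall_class1 = mean(cls[labels == 1L] == 1L),
      recall_class0 = mean(cls[labels == 0L] == 0L))
  })
  list(rf = rf, lr = lr, report = report)
}

#' Score feature vectors with a fitted match model
#'
#' @param model A `match_model`.
#' @param features data.frame with the six canonical feature columns (order
#'   enforced).
#' @return List with `probability` (match probability in `[0, 1]`) and
#'   `class` (1 iff probability >= the model's threshold).
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "match_model"))
  if (!identical(names(features), model$feature_names)) {
    stop("feature columns must be exactly (",
         paste(model$feature_names, collapse = ", "), ") in order",
         call. = FALSE)
  }
  if (nrow(features) == 0L) {
    return(list(probability = numeric(0), class = integer(0)))
  }
  prob <- if (model$algorithm == "random_forest") {
    unname(stats::predict(model$fit, data = features,
                          num.threads = 1L)$predictions[, "1"])
  } else {
    unname(stats::predict(model$fit, features, type = "response"))
  }
  list(probability = prob, class = as.integer(prob >= model$threshold))
}

# align + normalize + label hits of a labeled query/subject split; used to
# build classifier training data. Review mode (no E-value cutoff) so weak
# non-match candidates populate class 0.
labeled_features <- function(query_enc, subject_enc, pairs,
                             evalue_cutoff = NULL) {
  hits <- align_two_pass(query_enc, subject_enc, evalue_cutoff)
  hits <- normalize_hits(hits, self_scores(query_enc))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  truth <- paste(pairs$query_id, pairs$subject_id, sep = "\r")
  list(features = extract_features(hits),
       labels = as.integer(key %in% truth),
       hits = hits)
}

#' Train classifiers on the simulated protocol
#'
#' Runs the full simulator protocol ([make_ml_datasets()]): generates the
#' labeled training split, aligns query against subject in review mode,
#' labels hits from the ground-truth manifest, and fits both models. The
#' testing split is aligned and scored for an out-of-sample report.
#'
#' @param seed Integer seed for simulation and training.
#' @param n_class Records per class per database (see [make_ml_datasets()]).
#' @param key Encryption key used for the protocol run (any text; features
#'   are key-invariant).
#' @return As [train_models()], plus `test_report` with out-of-sample
#'   accuracy for both models.
#' @export
train_protocol_models <- function(seed = 1L, n_class = 12500,
                                  key = "protocol") {
  ml <- make_ml_datasets(seed = seed, n_class = n_class)
  wheel <- build_default_wheel(key)
  tq <- encode_records(ml$training_query, wheel)
  ts <- encode_records(ml$training_subject, wheel)
  train <- labeled_features(tq, ts, ml$train_pairs)
  models <- train_models(train$features, train$labels, seed = seed)
  eq <- encode_records(ml$testing_query, wheel)
  es <- encode_records(ml$testing_subject, wheel)
  test <- labeled_features(eq, es, ml$test_pairs)
  models$test_report <- lapply(models[c("rf", "lr")], function(m) {
    cls <- classify(m, test$features)$class
    c(accuracy = mean(cls == test$labels),
      recall_class1 = mean(cls[test$labels == 1L] == 1L),
      recall_class0 = mean(cls[test$labels == 0L] == 0L))
  })
  models
}

#' Link two encoded databases
#'
#' Aligns every query against the subject database (fast pass, then a
#' sensitive rescue pass for queries with no surviving hit), normalizes
#' scores, classifies every candidate hit, and emits one decision per query:
#' among class-1 candidates the one with the highest normalized bit-score
#' wins (ties: lower mismatch count, then lexicographically smaller subject
#' id); queries with no class-1 candidate are unmatched.
#'
#' @param query_enc,subject_enc `encoded_db` objects sharing one key.
#' @param model A fitted `match_model`.
#' @param evalue_cutoff E-value cutoff for the candidate search (`NULL`
#'   retrieves all hits).
#' @return A `linkage_result` data.frame, one row per query: `query_id`,
#'   `subject_id` (`NA` when unmatched), `probability` (match probability of
#'   the linked candidate, or the best candidate's probability when
#'   unmatched, 0 with no candidates), `decision`, `n_candidates`. Attribute
#'   `provenance` records backend and model fingerprint.
#' @export
link <- function(query_enc, subject_enc, model,
                 evalue_cutoff = 1e-10) {
  stopifnot(inherits(model, "match_model"))
  hits <- align_two_pass(query_enc, subject_enc, evalue_cutoff)
  hits <- normalize_hits(hits, self_scores(query_enc))
  scored <- classify(model, extract_features(hits))
  hits$probability <- scored$probability
  hits$class <- scored$class
  res <- data.frame(query_id = query_enc$record_id,
                    subject_id = NA_character_,
                    probability = 0, decision = "unmatched",
                    n_candidates = 0L, stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    split_idx <- split(seq_len(nrow(hits)), hits$qseqid)
    m <- match(names(split_idx), res$query_id)
    for (g in seq_along(split_idx)) {
      rows <- split_idx[[g]]
      i <- m[g]
      res$n_candidates[i] <- length(rows)
      res$probability[i] <- max(hits$probability[rows])
      pos <- rows[hits$class[rows] == 1L]
      if (length(pos) > 0L) {
        ord <- order(-hits$norm_bitscore[pos], hits$mismatch[pos],
                     hits$sseqid[pos])
        best <- pos[ord[1L]]
        res$subject_id[i] <- hits$sseqid[best]
        res$probability[i] <- hits$probability[best]
        res$decision[i] <- "matched"
      }
    }
  }
  attr(res, "provenance") <- list(
    backend = "internal", model = model$algorithm,
    fingerprint = model$fingerprint,
    evalue_cutoff = evalue_cutoff
  )
  class(res) <- c("linkage_result", "data.frame")
  res
}

#' Clean-to-linked convenience wrapper
#'
#' Encodes two cleaned databases under one key and runs [link()].
#'
#' @param query_db,subject_db `clean_db` objects.
#' @param model A fitted `match_model`.
#' @param key Encryption key; a random key is generated (and reported via
#'   message) when `NULL`.
#' @param ... Passed to [link()].
#' @return A `linkage_result`.
#' @export
link_databases <- function(query_db, subject_db, model, key = NULL, ...) {
  if (is.null(key)) {
    key <- random_key()
    message("generated run key: ", key)
  }
  wheel <- build_default_wheel(key)
  link(encode_records(query_db, wheel), encode_records(subject_db, wheel),
       model, ...)
}

#' Save / load a fitted match model
#'
#' The model file is a versioned R serialization; a JSON sidecar
#' (`<path>.json`) carries the algorithm, feature schema and training
#' fingerprint for audit.
#'
#' @param model A `match_model`.
#' @param path Output path.
#' @return `path` invisibly / the `match_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "match_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  meta <- list(format_version = 1L, algorithm = model$algorithm,
               feature_names = model$feature_names,
               threshold = model$threshold,
               fingerprint = model$fingerprint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$model, "match_model")) {
    stop("not a codonlink model file: ", path, call. = FALSE)
  }
  if (!identical(obj$model$feature_names, FEATURE_NAMES)) {
    stop("model feature schema does not match this package version",
         call. = FALSE)
  }
  obj$model
}
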