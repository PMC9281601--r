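#' Score linkage results against a ground-truth manifest
#'
#' A correctly linked true pair counts as a true positive; a query linked to
#' the wrong subject, or a linked noise record, as a false positive; an
#' unmatched true-pair query as a false negative; an unmatched noise record
#' as a true negative. The ROC sweeps the per-query match probability as the
#' score separating true-pair queries from noise queries; AUC is the
#' trapezoid area.
#'
#' @param results A `linkage_result` (see [link()]).
#' @param manifest Ground-truth manifest with `pairs` (query_id,
#'   subject_id) and `noise_ids` (see [make_benchmark()]).
#' @return A `linkage_metrics` list: counts `tp`, `fp`, `fn`, `tn`;
#'   `precision`, `recall`, `f_score`, `accuracy`; `auc` and the `roc`
#'   data.frame (fpr, tpr, threshold).
#' @export
score_linkage <- function(results, manifest) {
  universe <- c(manifest$pairs$query_id, manifest$noise_ids)
  outside <- setdiff(results$query_id, universe)
  if (length(outside) > 0L) {
    stop("query id(s) not in manifest: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  truth <- stats::setNames(manifest$pairs$subject_id,
                           manifest$pairs$query_id)
  is_pair <- results$query_id %in% manifest$pairs$query_id
  linked <- !is.na(results$subject_id)
  correct <- linked & is_pair &
    results$subject_id == unname(truth[results$query_id])
  correct[is.na(correct)] <- FALSE
  tp <- sum(correct)
  fp <- sum(linked & !correct)
  fn <- sum(!linked & is_pair)
  tn <- sum(!linked & !is_pair)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) &&
                 precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- (tp + tn) / nrow(results)
  roc <- roc_points(results$probability, as.integer(is_pair))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f_score = f_score,
                 accuracy = accuracy, auc = trapezoid_auc(roc), roc = roc),
            class = "linkage_metrics")
}

# ROC curve over score thresholds; one point per distinct score, plus the
# (0,0) and (1,1) anchors; monotone non-decreasing by construction
roc_points <- function(score, label) {
  stopifnot(length(score) == length(label))
  if (length(score) == 0L || length(unique(label)) < 2L) {
    return(data.frame(fpr = c(0, 1), tpr = c(0, 1),
                      threshold = c(Inf, -Inf)))
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pos <- sum(label == 1L)
  neg <- sum(label == 0L)
  tpr <- vapply(thr, function(t) sum(score >= t & label == 1L) / pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & label == 0L) / neg,
                numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = thr)
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) }
  n <- length(x)
  if (x[n] < 1) { x <- c(x, 1); y <- c(y, y[n]) }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# correctly linked true pairs with both cleaned records side by side
linked_true_pairs <- function(results, manifest, query_db, subject_db) {
  truth <- stats::setNames(manifest$pairs$subject_id,
                           manifest$pairs$query_id)
  ok <- !is.na(results$subject_id) &
    results$query_id %in% names(truth) &
    results$subject_id == unname(truth[results$query_id])
  ok[is.na(ok)] <- FALSE
  qi <- match(results$query_id[ok], query_db$record_id)
  si <- match(results$subject_id[ok], subject_db$record_id)
  list(query = query_db[qi, , drop = FALSE],
       subject = subject_db[si, , drop = FALSE])
}

#' Per-field error profile of linked true pairs
#'
#' For every correctly linked true pair, compares the cleaned field values
#' on both sides and counts, per identification field, how many pairs
#' differ -- the per-variable error landscape of the linked records.
#'
#' @param results A `linkage_result`.
#' @param manifest Ground-truth manifest.
#' @param query_db,subject_db The cleaned databases the linkage ran on.
#' @return Named integer vector with one count per field plus
#'   `any_field` (pairs with at least one differing field) and `n_pairs`
#'   (linked true pairs compared).
#' @export
per_field_error_profile <- function(results, manifest, query_db,
                                    subject_db) {
  p <- linked_true_pairs(results, manifest, query_db, subject_db)
  diffs <- vapply(CANONICAL_FIELDS,
                  function(f) p$query[[f]] != p$subject[[f]],
                  logical(nrow(p$query)))
  if (nrow(p$query) == 1L) diffs <- matrix(diffs, nrow = 1L,
                                           dimnames = list(NULL,
                                                           CANONICAL_FIELDS))
  counts <- if (nrow(p$query) == 0L) {
    stats::setNames(integer(length(CANONICAL_FIELDS)), CANONICAL_FIELDS)
  } else as.integer(colSums(diffs))
  out <- c(counts, if (nrow(p$query) == 0L) 0L else
    as.integer(sum(rowSums(diffs) > 0L)), nrow(p$query))
  stats::setNames(out, c(CANONICAL_FIELDS, "any_field", "n_pairs"))
}

#' Character substitution networks from linked true pairs
#'
#' For every correctly linked true pair and every field where the two
#' cleaned values have equal length but differ (the mismatch-only regime --
#' unequal lengths imply indels and are excluded), position-wise character
#' swaps are tallied. Letter swaps (name fields and sex) and digit swaps
#' (date of birth) are reported separately; edge frequencies are percentages
#' of all compared character positions in the included fields of that
#' class.
#'
#' @inheritParams per_field_error_profile
#' @return List of two data.frames, `letters` and `digits`, each with
#'   columns `char_a`, `char_b` (unordered pair, `char_a` < `char_b`),
#'   `count` and `frequency` (%), sorted by decreasing count, plus
#'   attribute `compared` (total positions compared).
#' @export
substitution_network <- function(results, manifest, query_db, subject_db) {
  p <- linked_true_pairs(results, manifest, query_db, subject_db)
  tally <- function(fields) {
    swaps <- list()
    compared <- 0L
    for (f in fields) {
      a <- p$query[[f]]; b <- p$subject[[f]]
      keep <- which(nchar(a) == nchar(b) & a != b & nzchar(a))
      for (i in keep) {
        ca <- strsplit(a[i], "", fixed = TRUE)[[1]]
        cb <- strsplit(b[i], "", fixed = TRUE)[[1]]
        ok <- ca != " " & cb != " "
        compared <- compared + sum(ok)
        mm <- which(ok & ca != cb)
        if (length(mm) > 0L) {
          swaps[[length(swaps) + 1L]] <-
            data.frame(char_a = pmin(ca[mm], cb[mm]),
                       char_b = pmax(ca[mm], cb[mm]),
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(swaps) == 0L) {
      out <- data.frame(char_a = character(0), char_b = character(0),
                        count = integer(0), frequency = numeric(0),
                        stringsAsFactors = FALSE)
    } else {
      all_sw <- do.call(rbind, swaps)
      agg <- stats::aggregate(list(count = rep(1L, nrow(all_sw))),
                              all_sw, sum)
      agg <- agg[order(-agg$count, agg$char_a, agg$char_b), , drop = FALSE]
      rownames(agg) <- NULL
      agg$frequency <- 100 * agg$count / compared
      out <- agg
    }
    attr(out, "compared") <- compared
    out
  }
  list(letters = tally(c("name", "mother_name", "sex")),
       digits = tally("birth_date"))
}

#' Export the no-cutoff candidate-pair review table
#'
#' Runs the linkage alignment in review mode (no E-value cutoff, all hits
#' retained), scores every candidate pair with the model, and returns the
#' full table for human review -- query id, subject id, match probability
#' and the six classifier features, sorted by query then descending
#' probability.
#'
#' @param query_enc,subject_enc `encoded_db` objects sharing one key.
#' @param model A fitted `match_model`.
#' @return data.frame of candidate pairs.
#' @export
export_candidates <- function(query_enc, subject_enc, model) {
  hits <- align_two_pass(query_enc, subject_enc, evalue_cutoff = NULL)
  hits <- normalize_hits(hits, self_scores(query_enc))
  feats <- extract_features(hits)
  prob <- classify(model, feats)$probability
  out <- cbind(data.frame(query_id = hits$qseqid,
                          subject_id = hits$sseqid,
                          probability = prob, stringsAsFactors = FALSE),
               feats)
  out <- out[order(out$query_id, -out$probability), , drop = FALSE]
  rownames(out) <- NULL
  out
}
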