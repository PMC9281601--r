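#' Deduplicate an encoded database by greedy centroid clustering
#'
#' Records are visited in order of decreasing sequence length (ties broken
#' by record id); each record joins the first existing centroid, in centroid
#' creation order, whose alignment reaches both the identity and the
#' coverage thresholds, and otherwise founds a new centroid. First-fit
#' assignment makes the procedure deterministic and near-linear when
#' duplicates are rare. Exact duplicates always cluster at any threshold.
#'
#' @param enc An `encoded_db` (one key).
#' @param identity_threshold Minimum percent identity to a centroid
#'   (50-100). The default 97 lets a single-character typo in a typical full
#'   record (75+ nt) still cluster.
#' @param coverage_threshold Minimum query coverage (%) of the member
#'   candidate by the alignment.
#' @return A data.frame of cluster assignments: `record_id`, `centroid_id`,
#'   `identity_to_centroid`, `is_centroid`; attribute `duplicates` lists the
#'   non-centroid members.
#' @export
dedup_cluster <- function(enc, identity_threshold = 97,
                          coverage_threshold = 90) {
  stopifnot(inherits(enc, "encoded_db"),
            identity_threshold >= 50, identity_threshold <= 100,
            coverage_threshold >= 0, coverage_threshold <= 100)
  n <- nrow(enc)
  out <- data.frame(record_id = character(0), centroid_id = character(0),
                    identity_to_centroid = numeric(0),
                    is_centroid = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(out, "duplicates") <- character(0)
    return(out)
  }
  ord <- order(-nchar(enc$sequence), enc$record_id)
  ids <- enc$record_id[ord]
  seqs <- enc$sequence[ord]
  centroid_seq <- character(0)
  centroid_id <- character(0)
  assign_to <- character(n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(centroid_id)) {
      a <- cl_sw_pair(seqs[i], centroid_seq[ci], SW_MATCH, SW_MISMATCH,
                      SW_GAP_OPEN, SW_GAP_EXTEND)
      if (a[["length"]] == 0L) next
      pident <- 100 * a[["matches"]] / a[["length"]]
      qcov <- 100 * (a[["qend"]] - a[["qstart"]] + 1) / nchar(seqs[i])
      if (pident >= identity_threshold && qcov >= coverage_threshold) {
        assign_to[i] <- centroid_id[ci]
        identity[i] <- pident
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_id <- c(centroid_id, ids[i])
      centroid_seq <- c(centroid_seq, seqs[i])
      assign_to[i] <- ids[i]
      identity[i] <- 100
    }
  }
  out <- data.frame(record_id = ids, centroid_id = assign_to,
                    identity_to_centroid = identity,
                    is_centroid = ids == assign_to,
                    stringsAsFactors = FALSE)
  attr(out, "duplicates") <- out$record_id[!out$is_centroid]
  out
}

#' Deduplicate a cleaned database
#'
#' Convenience wrapper: encodes under a throwaway key, clusters with
#' [dedup_cluster()], and returns the centroid records only, plus the
#' cluster table.
#'
#' @param db A `clean_db`.
#' @param identity_threshold,coverage_threshold See [dedup_cluster()].
#' @return List with `unique` (centroid-only `clean_db`) and `clusters`.
#' @export
dedup_records <- function(db, identity_threshold = 97,
                          coverage_threshold = 90) {
  wheel <- build_default_wheel(random_key())
  clusters <- dedup_cluster(encode_records(db, wheel), identity_threshold,
                            coverage_threshold)
  keep <- db[db$record_id %in% clusters$record_id[clusters$is_centroid], ,
             drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("clean_db", "data.frame")
  list(unique = keep, clusters = clusters)
}
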