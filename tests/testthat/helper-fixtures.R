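# Independent pure-R affine-gap local alignment score (quadratic DP, no
# shared code with the C++ backend). Gap of length L costs open + L * ext.
r_sw_score <- function(a, b, match = 1, mismatch = -2, open = 2, ext = 2) {
  qa <- strsplit(a, "")[[1]]
  qb <- strsplit(b, "")[[1]]
  m <- length(qa); n <- length(qb)
  if (m == 0 || n == 0) return(0)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- if (qa[i - 1] == qb[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Biostrings exact Smith-Waterman, used as the brute-force oracle for the
# internal backend on larger batches
bios_sw_score <- local({
  mat <- NULL
  function(a, b) {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE)
    }
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 2))
  }
})

# random already-clean records with gibberish fields (harsher than the
# population generator: arbitrary token lengths, occasional empties)
random_clean_db <- function(n, allow_empty = TRUE) {
  rand_name <- function() {
    k <- sample(1:4, 1)
    paste(replicate(k, paste(sample(LETTERS, sample(2:9, 1), TRUE),
                             collapse = "")), collapse = " ")
  }
  maybe <- function(x) if (allow_empty && runif(1) < 0.1) "" else x
  db <- data.frame(
    record_id = sprintf("X%05d", seq_len(n)),
    name = vapply(seq_len(n), function(i) maybe(rand_name()), ""),
    birth_date = vapply(seq_len(n), function(i)
      maybe(format(as.Date("1950-01-01") + sample.int(20000, 1), "%Y%m%d")),
      ""),
    sex = sample(c("M", "F", "U", ""), n, TRUE),
    mother_name = vapply(seq_len(n), function(i) maybe(rand_name()), ""),
    stringsAsFactors = FALSE
  )
  class(db) <- c("clean_db", "data.frame")
  db
}

# one small protocol-trained model pair shared across test files (training
# is the slow part; cache per session)
protocol_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_protocol_models(seed = 42, n_class = 300,
                                      key = "fixture")
    }
    cache
  }
})

hamming3 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
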