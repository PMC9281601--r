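# codonlink

DNA-encoded probabilistic record linkage for administrative person
registries.

Health and administrative databases often need to be linked without a shared
unique key, using error-prone identification fields: the person's full name,
date of birth, sex, and mother's full name. `codonlink` turns this into a
sequence-comparison problem. Each record is encoded into a DNA sequence with
a **codon wheel** — a cyclic arrangement of the 64 codons in which
neighbouring codons differ by one nucleotide and frequently confused
characters (keyboard neighbours like N/M, phonetic pairs like S/Z, digit
swaps like 0/1) sit on adjacent positions, so a typical typo costs a single
nucleotide. Databases are then compared with a seeded local aligner
(Smith–Waterman with affine gaps; match +1, mismatch −2, gap open/extend
−2), each hit's bit-score is normalized as a **percentage of the query's
self-hit** (removing the length bias that penalizes short names), and a
classifier — random forest (75 trees) or logistic regression — trained on
simulator-generated labeled pairs decides match vs non-match from six
alignment features:

```
(norm_bitscore, mismatch, gapopen, qcovhsp, sstart, qstart)
```

An encryption key "spins" the wheel (SHA-256 → rotation offset) without
moving the characters, so encoded files from one run cannot be decoded in
another, while alignment behaviour is unchanged.

The package also provides:

* a synthetic person-record simulator with a realistic typo-injection error
  model (45% 1–3-character substitutions, 49% middle-name deletions, 5%
  surname deletions, 1% blank fields; 10% of records corrupted by default)
  and complete ground-truth manifests;
* greedy centroid deduplication of a single database (identity ≥ 97%,
  coverage ≥ 90% by default);
* evaluation utilities: precision/recall/F-score/accuracy, ROC/AUC,
  per-field error profiles and character substitution networks;
* an adapter for NCBI BLAST+ `blastn` as an interchangeable alignment
  backend, and a CLI (`inst/cli/codonlink`) with `clean`, `encode`,
  `simulate`, `train`, `link`, `dedup` and `evaluate` subcommands.

## Worked example

```r
library(codonlink)

# a simulated study: 10,000-person subject registry; 1,000 of them re-appear
# as queries with 10% corrupted fields, plus 1,000 unrelated noise records
bm <- make_benchmark(n_subject = 10000, n_query = 1000, seed = 5)

# train the match classifier on the simulated four-database protocol
models <- train_protocol_models(seed = 1, n_class = 2500)

# encode both databases under one run key and link
wheel <- build_default_wheel("my-run-key")
res <- link(encode_records(bm$query, wheel),
            encode_records(bm$subject, wheel), models$rf)
head(res, 3)
#>   query_id subject_id probability decision n_candidates
#> 1 Q0000001   S0000024   0.9813604  matched           56
#> 2 Q0000002   S0000029   0.9806639  matched           50
#> 3 Q0000003   S0000031   0.9813604  matched           56

m <- score_linkage(res, bm$manifest)
round(c(precision = m$precision, recall = m$recall,
        f_score = m$f_score, auc = m$auc), 4)
#> precision    recall   f_score       auc
#>    0.9980    0.9990    0.9985    1.0000
```

Every query receives one decision: the linked subject id (or `NA`), the
classifier's match probability, and the number of candidate alignments
considered. `score_linkage()` compares decisions against the simulator's
ground-truth manifest: here 999 of the 1,000 true pairs are recovered
(recall 0.999) with two false positives (precision 0.998), and the
probability score separates true-pair queries from noise essentially
perfectly (AUC ≈ 1).

Field-level error forensics on the linked pairs:

```r
per_field_error_profile(res, bm$manifest, bm$query, bm$subject)
#>        name  birth_date         sex mother_name   any_field     n_pairs
#>          49          18           0          32          99         999
substitution_network(res, bm$manifest, bm$query, bm$subject)$digits[1:2, ]
#>   char_a char_b count frequency
#> 1      0      1     8  5.555556
#> 2      6      7     5  3.472222
```

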