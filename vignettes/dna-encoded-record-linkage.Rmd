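---
title: "DNA-encoded probabilistic record linkage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-encoded probabilistic record linkage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonlink)
```

## The problem

Epidemiological research routinely needs to decide whether a record in one
administrative database (say, a notifiable-disease registry) and a record in
another (say, a mortality registry) refer to the same person, in the absence
of a shared unique key. Identification fields — full name, date of birth,
sex, mother's full name — carry typos, missing tokens and spelling variants,
so exact joins miss many true links, and pairwise fuzzy comparison of large
databases is computationally prohibitive.

`codonlink` approaches this as a sequence-comparison problem. Each record's
four identification fields are serialized into a DNA sequence, one codon per
character; two databases are then compared with a fast seeded local aligner
of the kind used for nucleotide search, and candidate pairs are classified as
match / non-match by a model trained on simulated labeled data. Sequence
alignment tolerates substitutions and indels natively, which is exactly the
error structure of administrative records.

## The codon wheel

The encoding table is a *codon wheel*: the 64 trinucleotide codons are
arranged on a cyclic ring in which every pair of neighbouring codons differs
in exactly one nucleotide (a cyclic 4-ary Gray sequence), and each supported
character (A–Z, 0–9, space, field separator) is pinned to a ring position.
Characters that are frequently interchanged in registries — keyboard
neighbours (N/M), letters with shared phonetics in Brazilian Portuguese
(S/Z, G/Q, I/E), and the digit pairs most often switched in dates (0/1, 5/6,
6/7) — are placed on *adjacent* ring positions. A confusable-character typo
therefore costs a single nucleotide mismatch instead of up to three,
mirroring how genetic-code degeneracy makes some mutations silent. At the
default rotation the wheel assigns S → ATA, Z → ATC and V → GAG, so
`LUIZ`/`LUIS` differ by one nucleotide while `LUIZ`/`LUIV` differ by two or
three.

Privacy is handled by *spinning* the wheel: an arbitrary text key is hashed
(SHA-256, first 8 bytes big-endian, mod 64) to a rotation offset, and every
character's codon is taken that many positions further along the ring. The
character layout never moves, and because the ring is a Gray cycle, ring
neighbours remain at Hamming distance 1 under every rotation — the
error-tolerance design is key-independent. A fresh random key is generated
per run when none is given; results are reproducible by fixing the key. One
caveat discovered in implementation and worth stating precisely: only
*adjacent* distances are preserved by rotation. The Hamming distance between
codons further apart on the ring varies with the offset, so alignment
features of non-identical record pairs can jitter slightly across keys;
linkage *decisions* are empirically stable (the suite checks ≥ 98%
agreement across keys), and features of exact-duplicate pairs are exactly
invariant. This encoding is an obfuscation layer, not cryptography: with the
key the decoding is unique, without it 64 candidate decodings exist.

The published partial table (three pinned codons, seven adjacency pairs)
does not determine a full layout; the layout shipped here is one valid
completion, frozen as a package constant. Digits 0–9 occupy one consecutive
run, which yields the 0/1 adjacency and makes 5, 6, 7 consecutive.

## Encoding records

Fields are encoded in a canonical order — name, date of birth, sex, mother's
name — with one dedicated separator codon between consecutive fields. The
separator keeps field boundaries sharp in alignments and allows errors in
linked pairs to be attributed to fields afterwards. Empty fields are encoded
as zero codons (never imputed), so a blank field survives the pipeline and
simply contributes nothing to the alignment; an all-empty record is exactly
three separator codons. Dates are normalized to fixed-width `YYYYMMDD` so a
single-digit typo costs exactly one codon, and punctuation in names is
mapped to a space (not deleted) so compound names keep their token
boundaries — token-deletion errors then align cleanly as gaps. Name
particles (DA/DE/DOS) are kept: nothing in the error model suggests removing
them, and they carry alignment signal.

## Alignment and score normalization

The internal aligner is a classic seed-and-extend design: exact k-mer
seeding against an indexed subject database, screening of candidate pairs by
the best ungapped diagonal score, then optimal affine-gap Smith–Waterman
(with traceback) on survivors. Scoring is fixed at match +1, mismatch −2,
gap open −2, gap extend −2 (a gap of length L costs 2 + 2L), a megablast-like
regime. Two presets are orchestrated in two passes: `fast` (word length 12)
for all queries, then `sensitive` (word length 7, higher seed-count
requirement) only for queries with no surviving fast-pass hit. Per query, at
most `max_candidates = 64` subjects (ranked by seed support) undergo gapped
extension — the same pragmatic role as BLAST's `max_target_seqs`; the true
counterpart essentially always ranks first by shared k-mers, and the cap
bounds worst-case cost when many subjects share a common surname token. One
HSP — the optimal local alignment — is reported per pair, plus strand only.
Ties among equal-scoring alignments are resolved deterministically by the
smallest (query end, subject end) cell and a fixed traceback preference
(diagonal over vertical over horizontal).

Bit-scores use ungapped Karlin–Altschul constants for +1/−2 on uniform
composition (λ = 1.33, K = 0.621); E = K·m·n·e^(−λS) with n the total
subject length, cutoff 1e−10 by default, and a no-cutoff review mode that
retrieves every candidate pair for human inspection. Gapped alignments
technically call for slightly different constants; since scores are
normalized (below) before classification, the absolute scale only matters
for the cutoff, where the ungapped values are conservative enough in
practice.

Longer sequences reach higher scores than short ones even for equally
perfect matches, which would penalize people with short names. Every hit's
bit-score is therefore expressed as a **percentage of the query's self-hit**
— the query aligned against itself, whose raw score is simply its length, so
no alignment needs to be run. Self-hits normalize to exactly 100. E-values
are carried raw: "percent of best possible E-value" is not well defined (the
best value approaches zero), so only the bit-score is normalized.

An adapter for NCBI BLAST+ `blastn` (invoked with `-dust no -max_hsps 1
-strand plus` and the chosen task/E-value) provides an interchangeable
external backend; its self-scores for normalization are taken from blastn
itself so normalized scores stay on one scale. The test suite checks that
both backends produce the same linked pairs after classification.

## Match classification

Each candidate hit is summarized by six features, in a fixed order:
normalized bit-score, mismatch count, gap-opening count, query coverage by
the HSP, subject start, query start. Two models are provided: a random
forest (75 trees; implemented with `ranger`, whose classification split
criterion is Gini impurity — the entropy criterion of some other libraries
is not available in mainstream R forests, and at these sample sizes the two
are practically indistinguishable) and a logistic regression with library
defaults. The forest is the default shipped model; the logistic model is
kept for comparability and for its monotone, inspectable behaviour (the
suite checks that increasing the mismatch count never raises its match
probability).

Training data come from the simulator's four-database protocol: matched
(class 1) records duplicated across a query/subject pair of databases with
the query copy corrupted at a 15% rate, unmatched (class 0) records unique
to one database; 12,500 of each class per database, 75,000 unique records
overall. Hits between the training query and subject databases are labeled
by the known ground truth and fed to both models; the held-out testing split
provides an out-of-sample report. Training alignment runs in review mode
(no E-value cutoff) so weak candidate pairs populate class 0.

Per query, every candidate is classified; among class-1 candidates the
highest normalized bit-score wins, with ties broken by lower mismatch count
and then lexicographic subject id. Queries with no class-1 candidate are
unmatched. The decision threshold is 0.5 and configurable, there being no
canonical value.

## The simulator

`generate_population()` emulates a civil registry: given names sampled by
sex from a bundled synthetic frequency table, 1–3 surnames
(probabilities 0.05/0.60/0.35 — most people carry a maternal and a paternal
surname), a mother's name sharing the individual's last surname with
probability 0.8 (marriage renaming), dates of birth uniform over 1940–2010,
and a configurable sex ratio. The name tables are *synthetic* stand-ins for
a census list: same structure, invented Zipf-like weights; they produce
realistic collision behaviour (common full names do recur) but not the true
diversity of a 300M-person registry, so desk-scale results here overstate
name-collision rates relative to census-scale data.

`corrupt()` injects the error model: a uniformly random
⌈corrupt_fraction · n⌉ subset of records (default 10%) receives exactly one
error each, drawn as 45% character substitution (1–3 characters, in the
name, mother's name or date of birth; replacements up-weight the designated
confusable pairs tenfold), 49% middle-name deletion, 5% deletion of one or
more trailing surnames, 1% a completely blank field. Middle-name deletion
needs a ≥ 3-token name; the injector falls back to the other name field and
then to surname deletion, and logs both the drawn and the applied type. The
surname-count distribution keeps that fallback below ~0.3%, so the realized
composition stays within 3 binomial standard errors of 45/49/5/1 at
n = 10,000. Benchmarks add an equal number of freshly generated *noise*
records, rejected against exact four-field collisions with the subject
database, and emit a complete ground-truth manifest (true pairs, noise ids,
error log).

## Deduplication

Within one database, duplicates are found by greedy centroid clustering:
records in decreasing sequence-length order (ties by id) either join the
first existing centroid reaching both thresholds — percent identity ≥ 97 and
query coverage ≥ 90 by default — or found a new centroid. First-fit keeps
the procedure deterministic and near-linear when duplicates are rare. The
defaults are chosen so a single-character typo in a typical full record
(≥ 25 characters, hence ≥ 75 nt plus separators) still clusters
(identity ≈ 96–99%), while records sharing only a surname token do not; the
original tool's threshold is not published, so both knobs are exposed.

## Evaluation

`score_linkage()` compares decisions with the manifest: a correctly linked
true pair is a true positive; linking the wrong subject, or linking a noise
record, a false positive; an unmatched true pair a false negative; an
unmatched noise record a true negative. The ROC sweeps the per-query match
probability as a score separating true-pair queries from noise queries; AUC
is computed by trapezoid and cross-checked in the tests against a
brute-force concordance count. `per_field_error_profile()` and
`substitution_network()` reproduce the error-profiling analyses on linked
true pairs: the former counts differing records per field; the latter
tallies position-wise character swaps in field pairs of *equal length* that
differ (mismatch-only — unequal lengths imply indels and are excluded),
reporting letters and digits separately as percentages of all compared
character positions. That denominator is a package choice; the reference
analyses do not state theirs, so absolute swap rates are comparable only
within runs of this package.

## Problem sizes and numerical choices

The simulation protocol is run at its stated sizes where it is cheap:
dataset construction (4 × 25,000 records), error-composition and
corruption-rate checks (n = 10,000). Alignment-heavy stages use scaled runs
chosen for single-CPU convenience: classifier training on a protocol run
with 2,500 records per class per database (10,000 alignment queries in
total), and the end-to-end benchmark at 1,000 corrupted queries plus 1,000
noise records against 10,000 subjects. At these sizes the out-of-sample
classifier accuracy and the benchmark F-score are already at or above
99.7%, and enlarging the training run further did not change decisions in
our runs.

Other fixed choices: seeding word lengths 12 (fast) and 7 (sensitive) with
minimum seed counts 4 and 6 and ungapped screening thresholds 30 and 25 (a
true match always retains a long exact diagonal segment — at minimum the
date-of-birth/sex block plus separators — while unrelated records sharing a
single common token rarely do); E-value cutoff 1e−10; decision threshold
0.5; dedup identity 97% and coverage 90%; mother-surname sharing 0.8 and
confusable up-weighting ×10 in the simulator (the phenomena are documented,
their rates are not, so these are package defaults exposed as parameters).

## Known limitations

* The synthetic name tables are small; full-name collisions between
  distinct simulated people are more common than in census-scale data. The
  classifier handles these (they dominate its class-0 training examples),
  but absolute false-positive rates on simulated data should not be read as
  real-data estimates.
* Passing the simulated benchmarks shows the pipeline recovers the *modeled*
  error processes (substitutions, token deletions, blank fields, noise
  records). Real registries also contain swapped fields, nicknames,
  hyphenation variants and transliteration effects that the simulator does
  not emulate.
* The encryption layer is deliberately weak (64 possible rotations); it
  protects against casual reading of intermediate files, nothing more.
* Minus-strand search, multi-HSP chaining and translated comparisons are
  out of scope; record sequences are short and plus-strand by construction.
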