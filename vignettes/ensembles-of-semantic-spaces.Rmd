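---
title: "Ensembles of semantic spaces: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of semantic spaces: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical free text is dense with undefined abbreviations and local synonyms:
the same clinical concept surfaces as `ekg`, `elektrokardiogram`, or a local
shorthand, and lexical resources with this coverage largely do not exist for
smaller languages. `synsemble` extracts candidate synonyms and
abbreviation–expansion pairs directly from corpora, using the distributional
hypothesis: terms that occur with similar sets of neighbors tend to have
similar meanings. Synonymy is the canonical *paradigmatic* relation — two
interchangeable forms share neighbors without needing to co-occur — which is
what sliding-window distributional models capture.

No single model configuration captures the phenomenon best. The package's
central idea is therefore the *ensemble of semantic spaces*: query several
spaces — built with different models (bag-of-words vs order-aware),
different context-window sizes, with and without stop words, and from
corpora of different genres — and combine their ranked outputs.

## Models

**Random Indexing (RI).** Every term-as-context receives a static sparse
ternary *index vector* of dimensionality `d = 1000` with 8 non-zero elements
(four `+1`, four `−1`) at pseudo-random positions; distinct terms' index
vectors are near-orthogonal with overwhelming probability. A term's *context
vector* is accumulated by adding, for every occurrence, the index vectors of
its in-window neighbors, weighted by distance: a neighbor at distance
$dist$ contributes with weight $2^{1-dist}$, so immediate neighbors count
fully and the weight halves per step. RI is an incremental random-projection
compression of the (positional) co-occurrence matrix; `d` and the non-zero
count trade fidelity against memory and are kept at the conventional
1000 / 8.

**Random Permutation (RP).** Identical accumulation, but instead of distance
weighting, the neighbor's index vector is circularly rotated by its signed
offset (−1 for the word just left of the target, +2 for the second word
right, ...). Rotation is an orthogonal change of coordinates, so each
relative position effectively gets its own near-orthogonal copy of the
index vector: two terms end up close only when they share neighbors *in the
same relative positions*. RP therefore encodes word order and tends to
return more tightly substitutable terms than RI; their top-10 lists overlap
only partially, which is exactly why combining them helps.

Determinism: index vectors are derived from a 32-bit FNV-1a hash of the term
mixed with a user seed, expanded through a small tempered linear-congruential
stream, all in exact double arithmetic. A space is thus reproducible from
`(corpus, seed)` alone, independent of platform and of the order in which
terms are encountered. Context vectors are stored dense (`d` is small);
index vectors sparse.

Window conventions: a *segment* (sentence or document, one per input line)
is a hard context boundary — windows never cross it. Distances and offsets
are counted on the processed token stream, i.e. *after* stop-word removal
when it is enabled; a removed stop word does not hold a position open. RI
spaces are conventionally trained on stop-word-filtered corpora (ubiquitous
function words carry little lexical meaning), while RP spaces are trained
both with and without stop words, since function words do carry syntactic
signal that order encoding can exploit. The wide-window RI space (10+10)
uses the same distance weighting as the narrow ones.

## Combination strategies

All strategies consume per-space cosine score maps for one query and emit a
single ranked list (ties always broken lexicographically, so every output is
deterministic):

* **Subset re-ranking** (`combine_subset`): candidates are one space's top-30
  pool, ordered by the other space's cosine. Both published directions (rank
  with RI inside an RP pool, and vice versa) come from the argument order.
  If fewer than 10 candidates survive the pool filter the shorter list is
  returned rather than padded.
* **SUM / AVG** (`combine_scores`): cosine scores summed across spaces
  (absent term = 0), or summed and divided by the number of spaces
  containing the term (mitigating vocabulary differences between corpora).
  With `normalize = TRUE`, scores are first replaced by 0-based ranks and
  the combined list sorts ascending, zero best. A term absent from a space
  receives the penalty rank `horizon` (default: union-vocabulary size) —
  absence must never be an advantage under ascending sort. The choice of a
  maximal penalty is deliberately conservative and is one plausible reading
  of why rank-normalized combinations underperform score-based ones.
* **Two-step** (`combine_two_step`): each corpus' pair is combined over raw
  scores first, the two combined lists are rank-normalized, then combined
  across corpora with SUM or AVG over ranks (AVG divides by the number of
  all four source spaces containing the term).

Score-based SUM/AVG are computed over the full union vocabulary (exact
rather than truncated at a retrieval horizon); a horizon is configurable for
speed on very large vocabularies.

## Post-filtering

Candidate lists can be filtered with task-specific rules, in two modes. The
*fixed* mode scans up to 100 candidates in rank order, keeps rule-accepted
ones until 10 are found, and refills any remaining slots with the
highest-ranked rejected candidates — output length is always 10, so recall
cannot drop when the gold term is accepted within the scan. The *dynamic*
mode returns the accepted candidates only (1–10; if none is accepted, the
single top-ranked candidate), trading a little recall for precision. The
100-candidate scan is applied in both modes.

Abbreviation–expansion validity is structural: the abbreviation must have at
most 4 letters, the expansion at least 5, the abbreviation's letters must
occur in the expansion in order, and both must share the initial letter.
Lengths count letters only, as digits and punctuation are stripped upstream.
Synonym filtering uses cosine/rank cut-off profiles (`clinical`,
`medical`, and `combined` for four-space summed cosines with maximum 4);
ranks in the clauses are 0-based, so a `rank < 9` clause admits ranks 0–8.

## Evaluation framework

Reference standards are tab-separated tuples; synonym tuples query in both
directions, abbreviation tuples in the direction of the task. Multiword
terms are removed (the spaces model unigrams), and tuples can be restricted
to terms occurring at least 50 times in every corpus involved — rare terms
lack the distributional evidence for stable vectors. Tuples are split (by
tuple, not by query) into development and evaluation halves.

*Recall@10* micro-averages over (query, gold) pairs: the proportion of
expected terms found among ten suggestions. Out-of-vocabulary queries count
as misses. *Weighted precision* scores a true positive at 0-based rank $i$
among $j$ suggestions as $j - i$, normalized by the maximum attainable
score; $j$ is 10 in fixed mode and the returned length under a dynamic
cut-off. The package reports the mean over queries. Paired systems are
compared with the exact binomial two-sided sign test over discordant
queries (a query "succeeds" if any of its gold terms is found; configurable
to all-hits). A sweep utility re-filters the reference standard at
thresholds 1–100 and reports recall and query counts per threshold.

## The synthetic generator

Real clinical corpora cannot be redistributed, so the package generates its
own study conditions. Two corpora share a vocabulary (~1800 background
pseudo-words with Zipf-distributed frequencies, assigned to 10 topics) and a
set of planted lexemes: 20 synonym lexemes with two full-word surface forms
and 10 abbreviation lexemes whose short form is an ordered letter
subsequence of the expansion sharing its initial (≤4 vs ≥5 letters, by
construction). Segments of 10 tokens are drawn from a per-corpus topic
mixture; each lexeme occurrence is spliced in as a 5-token window whose
context positions are dominated (80%) by the *collocate set* of the
lexeme's topical cluster.

Three design choices matter:

* **Topic-mixture with collocate windows, not n-gram templates**: the method
  under test relies on shared-neighbor structure; collocate windows create
  it directly and measurably.
* **Shared cluster collocates**: all lexemes homed in a topic share one
  collocate set, so the expected contexts of a planted form and its
  cluster's other members are identical, and ordering within a cluster is
  driven by sampling noise. The gold term is *usually* but not always the
  nearest neighbor — reproducing the central difficulty of real corpora,
  where distributional similarity cannot fully separate synonymy from close
  topical relatedness, and giving the post-filter real decoys to remove.
* **Deterministic occurrence scheduling**: per corpus, the dispreferred
  surface form of each lexeme receives exactly the frequency floor
  (default 60 occurrences) and the preferred form `skew/(1−skew)` times as
  many (genre skew 0.8), so every reference term meets the floor in both
  corpora by construction rather than by rejection sampling. Corpus A
  prefers first forms (for abbreviation lexemes, the short form —
  telegraphic clinical style); corpus B the expansions (journal style).
  A `freq_spread` parameter scales the schedule across lexemes when varied
  frequencies are wanted, e.g. for threshold sweeps.

What the generator does **not** emulate: morphology and spelling variation,
word ambiguity (each surface form realizes one lexeme), multiword terms,
parenthetical abbreviation definitions, and the long-tail sparsity of real
clinical language. Passing the end-to-end tests therefore shows that the
pipeline recovers planted paradigmatic structure under genre skew and
realistic confusability — it does not certify recall levels on real text,
which are far lower (a few tenths at best on clinical corpora).

## Numerical and degenerate-input choices

* Cosine with a zero vector (a term never seen with in-window neighbors) is
  defined as 0, not NaN: such terms are maximally dissimilar to everything.
* All ties — equal cosines, equal combined ranks — break lexicographically
  in the C locale.
* Out-of-vocabulary queries raise a typed condition (`synsemble_oov`);
  evaluation code catches it and counts the query's gold terms as misses.
* Space files round-trip bit-exactly (`%.17g`); loading verifies a version
  header, the vocabulary count, and per-row element counts.
* The exact sign test with no discordant pairs returns p = 1.

## Problem sizes

The test suite trains spaces of `d` 40–300 on corpora of a few hundred
tokens for the oracle comparisons, and the end-to-end checks use five seeded
bundles at the study scale: ~295k tokens per corpus, ~2050 term
vocabulary, `d = 1000`, window 2+2, 20 synonym + 10 abbreviation pairs at a
frequency floor of 60. One bundle trains its four spaces in a few seconds;
the full suite and the acceptance script each complete in a few minutes on
one CPU.

## Known limitations

* Spaces are additive, so corpora can be merged by retraining on
  concatenation, but there is no true online update API.
* Vector-level fusion of spaces (adding context vectors across models) is
  out of scope; ensembles operate on ranked outputs only.
* No approximate nearest-neighbor index: retrieval is a full scan, which is
  the right trade-off at these vocabulary sizes but not for millions of
  types.
* The shipped synonym cut-off profiles encode thresholds tuned on clinical
  and medical development data; on other corpora they are starting points,
  and `synonym_rule(clauses = ...)` accepts custom clauses.
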