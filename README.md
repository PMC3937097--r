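# synsemble

Ensembles of Random Indexing and Random Permutation semantic spaces for
extracting **synonyms** and **abbreviation–expansion pairs** from free-text
medical corpora.

Clinical notes are full of undefined abbreviations and local synonyms, and
for most languages no lexical resource covers them. `synsemble` finds
candidate term pairs distributionally: terms that occur with similar sets of
neighbors tend to mean similar things (a *paradigmatic* relation — the terms
need never co-occur themselves). Because no single model configuration
captures this best, the package queries several semantic spaces — different
models, context-window sizes, stop-word handling, and corpora — and combines
their ranked outputs into one candidate list.

## The models and measures

**Random Indexing (RI)** assigns every term a static sparse ternary index
vector (d = 1000, four +1s and four −1s at hash-determined positions; index
vectors of distinct terms are near-orthogonal). A term's context vector is
the sum, over all its occurrences, of its in-window neighbors' index
vectors, weighted by distance:

    weight(dist) = 2^(1 − dist)

**Random Permutation (RP)** replaces the distance weighting with a circular
rotation of the neighbor's index vector by its signed offset, so two terms
are close only if they share neighbors *in the same relative positions* —
an order-aware variant that retrieves different candidates than RI.

Spaces are combined per query by **subset re-ranking** (order one space's
top-30 pool by the other space's cosine), **score summing/averaging**
(optionally rank-normalized), or **two-step** combination across corpora
(combine each corpus' pair, rank-normalize, combine the combinations).
Candidate lists can then be **post-filtered**: abbreviation–expansion
candidates must satisfy length bounds (≤4 vs ≥5 letters) and an
ordered-letter-subsequence test with identical initials; synonym candidates
pass cosine/rank cut-off profiles. Evaluation uses **recall@10** over a
reference standard, **rank-weighted precision**

    P_w = Σ_{i ∈ true positives} (j − i) / Σ_{i=0}^{j−1} (j − i)

(0-based rank i among j suggestions), and the exact binomial sign test for
paired comparisons.

Since clinical corpora cannot be redistributed, the package ships a
synthetic-corpus generator that plants synonym and abbreviation pairs in two
genre-skewed topic-mixture corpora, with guaranteed frequency floors and
realistic near-neighbor decoys, so the entire pipeline is testable end to
end.

## Worked example

```r
library(synsemble)

# Two genre-distinct corpora with planted synonym and abbreviation pairs
bundle <- generate_bundle(synth_config(seed = 7, vocab_size = 600,
                                       n_topics = 6, n_synonym_pairs = 6,
                                       n_abbrev_pairs = 4,
                                       segments_per_corpus = 4000,
                                       min_pair_frequency = 40))
#> <synthetic bundle seed=7> corpora 50000/50000 tokens, 6 synonym pairs, 4 abbreviation pairs

# One RI and one RP space per corpus (window 2+2, d = 1000)
cfg <- index_config(seed = 7)
spaces <- list(train_ri(bundle$corpus_a, window_spec(2), cfg),
               train_rp(bundle$corpus_a, window_spec(2), cfg),
               train_ri(bundle$corpus_b, window_spec(2), cfg),
               train_rp(bundle$corpus_b, window_spec(2), cfg))

# A planted abbreviation and its expansion
bundle$ref_abbr$tuples[[1]]
#> [1] "evhl"     "evubhnyl"

# Query the four-space SUM ensemble for the abbreviation
q <- bundle$ref_abbr$tuples[[1]][1]
hits <- ensemble_query(spaces, q, ensemble_config("SCORE_SUM", out_k = 100))
print(hits, n = 5)
#> <candidates for 'evhl'> summed_cosine [SCORE_SUM], 100 terms
#>       term    score rank
#>  xlamambfn 3.810079    0
#>   evubhnyl 3.783960    1
#>      zvenc 3.719286    2
#>     tpbjup 3.227903    3
#>      blcyd 3.215733    4

# Structural post-filtering promotes valid expansions
filtered <- refill_top10(hits, filter_abbrev(q, "abbr2exp"))
print(filtered, n = 5)
#> <candidates for 'evhl'> summed_cosine [SCORE_SUM | filtered:refill], 10 terms
#>       term    score rank original_rank accepted
#>   evubhnyl 3.783960    0             1     TRUE
#>  xlamambfn 3.810079    1             0    FALSE
#>      zvenc 3.719286    2             2    FALSE
#>     tpbjup 3.227903    3             3    FALSE
#>      blcyd 3.215733    4             4    FALSE

# Evaluate the synonym task end to end
outputs <- batch_query(function(q) ensemble_query(
  spaces, q, ensemble_config("SCORE_SUM", out_k = 10)), bundle$ref_syn)
evaluate_outputs(outputs, bundle$ref_syn, k = 10)
#> <evaluation> 12 queries | recall@10 = 1.000 | weighted precision = 0.168
```

Reading the output: the topical decoy `xlamambfn` narrowly outranks the true
expansion `evubhnyl` on raw summed cosine; the subsequence/length filter
rejects it (wrong letters) and promotes the expansion to rank 0, with the
rejected decoys refilling the remaining slots. The per-query weighted
precision of a list whose only gold term sits at rank 0 is 10/55 ≈ 0.18,
which is why mean weighted precision is low even at perfect recall — each
query has just one expected term.

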