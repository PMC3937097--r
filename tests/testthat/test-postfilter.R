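test_that("the ordered-subsequence test requires order and identical initials", {
  expect_true(ordered_subsequence_same_initial("ekg", "elektrokardiogram"))
  expect_false(ordered_subsequence_same_initial("kg", "elektrokardiogram"))
  expect_false(ordered_subsequence_same_initial("vzv", "varicella"))
  expect_true(ordered_subsequence_same_initial("E.K.G.", "Elektrokardiogram"))
  expect_error(ordered_subsequence_same_initial("", "abc"), "letter")
  expect_error(ordered_subsequence_same_initial("a", "..."), "letter")
})

test_that("abbreviation validity rules enforce length bounds and subsequence structure", {
  # expansion query -> short-form candidates (candidate must have < 5 letters)
  expect_true(accept_exp_to_abbr("elektrokardiogram", "ekg"))
  expect_false(accept_exp_to_abbr("elektrokardiogram", "elektro"))  # 7 letters
  expect_false(accept_exp_to_abbr("elektrokardiogram", "gke"))      # order violated
  expect_true(accept_exp_to_abbr("elektrokardiogram", "ekgm"))      # boundary: 4 letters
  expect_false(accept_exp_to_abbr("elektrokardiogram", "ekgra"))    # boundary: 5 letters

  # abbreviation query -> expansion candidates (candidate must have > 4 letters)
  expect_true(accept_abbr_to_exp("ekg", "elektrokardiogram"))
  expect_false(accept_abbr_to_exp("ekg", "ekge"))                   # 4 letters
  expect_true(accept_abbr_to_exp("ekg", "eekgg"))                   # boundary: 5 letters
  expect_false(accept_abbr_to_exp("ekg", "kardiogram"))             # initials differ
  expect_error(abbrev_rule(5, 5), "below")
})

test_that("synonym cut-off profiles implement their cosine/rank clauses", {
  clin <- synonym_rule("clinical")
  expect_true(accept_synonym(0.45, 8, clin))
  expect_false(accept_synonym(0.45, 9, clin))
  expect_true(accept_synonym(0.60, 50, clin))
  expect_false(accept_synonym(0.59, 9, clin))

  med <- synonym_rule("medical")
  expect_true(accept_synonym(0.50, 99, med))
  expect_false(accept_synonym(0.49, 0, med))

  comb <- synonym_rule("combined")
  expect_true(accept_synonym(1.90, 99, comb))
  expect_true(accept_synonym(1.85, 4, comb))
  expect_false(accept_synonym(1.85, 6, comb))
  expect_true(accept_synonym(1.76, 2, comb))
  expect_false(accept_synonym(1.76, 3, comb))
  expect_false(accept_synonym(1.74, 0, comb))

  custom <- synonym_rule(clauses = data.frame(cos = 0.9, max_rank = 2))
  expect_true(accept_synonym(0.95, 1, custom))
  expect_false(accept_synonym(0.95, 2, custom))
  expect_error(accept_synonym(0.5, -1, clin), "rank")
})

test_that("greedy subsequence matches an independent regex oracle on random pairs", {
  set.seed(12)
  alphabet <- letters[1:6]  # small alphabet: frequent true subsequences
  for (i in 1:2000) {
    short <- paste(sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = "")
    long <- paste(sample(alphabet, sample(4:10, 1), replace = TRUE), collapse = "")
    expect_identical(ordered_subsequence_same_initial(short, long),
                     subseq_regex_oracle(short, long))
  }
})

test_that("fixed-mode filtering collects accepted candidates and refills with best rejected", {
  stream <- numbered_stream(100)
  hits <- c("t006", "t041", "t091")  # original ranks 5, 40, 90
  accept <- function(term, score, rank) term %in% hits
  out <- refill_top10(stream, accept)
  expect_equal(nrow(out$candidates), 10L)
  expect_equal(candidate_terms(out)[1:3], hits)
  # pads are the highest-ranked rejected candidates (ranks 0,1,2,3,4,6,7)
  expect_equal(candidate_terms(out)[4:10],
               c("t001", "t002", "t003", "t004", "t005", "t007", "t008"))
  expect_equal(out$candidates$accepted, c(rep(TRUE, 3), rep(FALSE, 7)))

  all_ok <- refill_top10(stream, function(...) TRUE)
  expect_equal(candidate_terms(all_ok), sprintf("t%03d", 1:10))

  none <- refill_top10(stream, function(...) FALSE)
  expect_equal(candidate_terms(none), sprintf("t%03d", 1:10))
  expect_false(any(none$candidates$accepted))

  # candidates beyond the scan limit are never consulted
  far <- candidate_list("q", stats::setNames(seq(1, 0.01, length.out = 150),
                                             sprintf("t%03d", 1:150)))
  out_far <- refill_top10(far, function(term, ...) term == "t150")
  expect_false("t150" %in% candidate_terms(out_far))
})

test_that("dynamic cut-off returns one to max_k accepted candidates", {
  stream <- numbered_stream(100)
  two <- dynamic_cutoff(stream, function(term, ...) term %in% c("t010", "t050"))
  expect_equal(candidate_terms(two), c("t010", "t050"))

  none <- dynamic_cutoff(stream, function(...) FALSE)
  expect_equal(candidate_terms(none), "t001")  # fall back to the rank-0 term

  many <- dynamic_cutoff(stream, function(...) TRUE)
  expect_equal(candidate_terms(many), sprintf("t%03d", 1:10))
})

test_that("filtering never hurts recall when the gold term is accepted within the scan", {
  stream <- numbered_stream(100)
  set.seed(5)
  for (i in 1:20) {
    gold <- sprintf("t%03d", sample(100, 1))
    decoys <- sprintf("t%03d", sample(100, 5))
    accept <- function(term, ...) term %in% c(gold, decoys)
    filtered <- candidate_terms(refill_top10(stream, accept))
    unfiltered <- utils::head(candidate_terms(stream), 10)
    expect_true(gold %in% filtered || !(gold %in% unfiltered))
    # dynamic output is a subset of the refill output's accepted prefix
    dyn <- dynamic_cutoff(stream, accept)
    acc_prefix <- candidate_terms(refill_top10(stream, accept))[
      refill_top10(stream, accept)$candidates$accepted]
    expect_true(all(candidate_terms(dyn) %in% acc_prefix))
  }
})

test_that("filter predicates wire queries to the right rule direction", {
  f1 <- filter_abbrev("ekg", "abbr2exp")
  expect_true(f1("elektrokardiogram", 0.5, 0))
  expect_false(f1("ekge", 0.5, 0))
  f2 <- filter_abbrev("elektrokardiogram", "exp2abbr")
  expect_true(f2("ekg", 0.5, 0))
  expect_false(f2("elektro", 0.5, 0))
  f3 <- filter_synonym(synonym_rule("medical"))
  expect_true(f3("term", 0.51, 9))
  expect_false(f3("term", 0.49, 0))
})
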