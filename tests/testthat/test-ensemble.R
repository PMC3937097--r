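# Fixed score maps used for the hand-computed combination cases: two spaces
# per corpus (RI/RP from "clinical" A and "medical" B), query already excluded.
map_a1 <- c(x = 0.9, y = 0.5, z = 0.3)
map_a2 <- c(x = 0.2, y = 0.7, w = 0.6)
map_b1 <- c(y = 0.8, z = 0.6, v = 0.4)
map_b2 <- c(x = 0.1, v = 0.9)
four <- list(map_a1, map_a2, map_b1, map_b2)

test_that("rank normalization assigns 0-based ranks, clamps at the horizon, and preserves order", {
  r <- rank_normalize(c(x = 0.9, y = 0.5))
  expect_equal(r, c(x = 0, y = 1))
  r2 <- rank_normalize(c(a = 0.9, b = 0.8, c = 0.7, d = 0.6), horizon = 2)
  expect_equal(unname(r2), c(0, 1, 2, 2))
  cl <- candidate_list("q", c(a = 0.3, b = 0.8))
  expect_equal(rank_normalize(cl), c(b = 0, a = 1))
})

test_that("score summing and averaging match hand-computed outputs", {
  two <- list(c(x = 0.9, y = 0.5), c(x = 0.2, y = 0.7))
  got <- combine_scores(two, "SUM")
  expect_equal(candidate_terms(got), c("y", "x"))
  expect_equal(got$candidates$score, c(1.2, 1.1))

  three <- list(c(x = 0.9, y = 0.5, z = 0.8), c(x = 0.2, y = 0.7))
  avg <- combine_scores(three, "AVG")
  expect_equal(candidate_terms(avg)[1], "z")          # 0.8/1 beats x: 1.1/2
  expect_equal(avg$candidates$score[avg$candidates$term == "x"], 0.55)

  expect_error(combine_scores(list(c(x = 1))), "two score maps")
})

test_that("four-space single-step strategies reproduce hand-worked rankings", {
  sum4 <- combine_scores(four, "SUM")
  expect_equal(candidate_terms(sum4), c("y", "v", "x", "z", "w"))
  expect_equal(sum4$candidates$score, c(2.0, 1.3, 1.2, 0.9, 0.6))

  avg4 <- combine_scores(four, "AVG")
  expect_equal(candidate_terms(avg4), c("y", "v", "w", "z", "x"))

  # normalized: per-map ranks with penalty 5 (union size), ascending sums
  sum4n <- combine_scores(four, "SUM", normalize = TRUE)
  expect_equal(candidate_terms(sum4n), c("y", "x", "v", "z", "w"))
  expect_equal(sum4n$candidates$score, c(6, 8, 12, 13, 16))

  avg4n <- combine_scores(four, "AVG", normalize = TRUE)
  expect_equal(candidate_terms(avg4n), c("y", "x", "v", "z", "w"))
  expect_equal(avg4n$candidates$score, c(2, 8 / 3, 6, 6.5, 16))
})

test_that("normalized summing breaks rank ties lexicographically", {
  m1 <- c(x = 0.9, y = 0.6, z = 0.3)  # order x, y, z
  m2 <- c(y = 0.9, x = 0.6, z = 0.3)  # order y, x, z
  got <- combine_scores(list(m1, m2), "SUM", normalize = TRUE)
  expect_equal(got$candidates$score, c(1, 1, 4))
  expect_equal(candidate_terms(got), c("x", "y", "z"))
})

test_that("subset re-ranking filters by one space's pool and orders by the other", {
  ri <- toy_space(c(a = 0.9, b = 0.8, c = 0.7, d = 0.6, e = 0.5))
  rp <- toy_space(c(c = 0.95, e = 0.85, a = 0.75, f = 0.65))
  got <- combine_subset(ri, rp, "q", out_k = 10, pool_k = 3)
  expect_equal(candidate_terms(got), c("a", "c", "e"))
  rev_dir <- combine_subset(rp, ri, "q", out_k = 10, pool_k = 3)
  expect_equal(candidate_terms(rev_dir), c("c", "a"))  # b OOV in rp: dropped

  same <- combine_subset(ri, ri, "q", out_k = 3, pool_k = 5)
  expect_equal(candidate_terms(same), c("a", "b", "c"))

  # pool disjoint from the ranking space's vocabulary -> empty list
  rp_only <- toy_space(c(f = 0.9, g = 0.8))
  ri_q <- toy_space(c(a = 0.9))
  expect_equal(nrow(combine_subset(ri_q, rp_only, "q", out_k = 2,
                                   pool_k = 2)$candidates), 0L)

  expect_error(combine_subset(ri, rp, "zzz"), class = "synsemble_oov")
})

test_that("two-step combinations follow the rank-then-combine scheme", {
  pair_a <- list(map_a1, map_a2)
  pair_b <- list(map_b1, map_b2)

  ss <- combine_two_step(pair_a, pair_b, "SUM", "SUM")
  expect_equal(candidate_terms(ss), c("y", "x", "v", "z", "w"))
  expect_equal(ss$candidates$score, c(1, 4, 5, 5, 7))

  sa <- combine_two_step(pair_a, pair_b, "SUM", "AVG")
  expect_equal(candidate_terms(sa), c("y", "x", "v", "z", "w"))
  expect_equal(sa$candidates$score, c(1 / 3, 4 / 3, 2.5, 2.5, 7))

  as <- combine_two_step(pair_a, pair_b, "AVG", "SUM")
  expect_equal(candidate_terms(as), c("y", "w", "x", "z", "v"))
  expect_equal(as$candidates$score, c(1, 5, 5, 5, 6))

  aa <- combine_two_step(pair_a, pair_b, "AVG", "AVG")
  expect_equal(candidate_terms(aa), c("y", "x", "z", "v", "w"))

  # identical pairs on both sides: SUM->SUM preserves the single-pair order
  single <- combine_scores(pair_a, "SUM")
  both <- combine_two_step(pair_a, pair_a, "SUM", "SUM")
  expect_equal(candidate_terms(both), candidate_terms(single))

  # a term seen in only one corpus takes the penalty from the other
  pa <- list(c(only_a = 0.99, shared = 0.5), c(shared = 0.5))
  pb <- list(c(shared = 0.9), c(shared = 0.8))
  pen <- combine_two_step(pa, pb, "SUM", "SUM")
  expect_equal(candidate_terms(pen)[1], "shared")
})

test_that("AVG and SUM agree in ordering whenever every term occurs in every space", {
  set.seed(99)
  for (i in 1:1000) {
    terms <- paste0("t", 1:5)
    maps <- lapply(1:4, function(j) stats::setNames(round(runif(5), 3), terms))
    s <- candidate_terms(combine_scores(maps, "SUM", out_k = 5))
    a <- candidate_terms(combine_scores(maps, "AVG", out_k = 5))
    expect_identical(a, s)
    aa <- candidate_terms(combine_two_step(maps[1:2], maps[3:4], "AVG", "AVG"))
    as_ <- candidate_terms(combine_two_step(maps[1:2], maps[3:4], "AVG", "SUM"))
    expect_identical(aa, as_)
  }
})

test_that("combination output is invariant to map insertion order", {
  got1 <- candidate_terms(combine_scores(four, "SUM", normalize = TRUE))
  got2 <- candidate_terms(combine_scores(rev(four), "SUM", normalize = TRUE))
  expect_identical(got1, got2)
  got3 <- candidate_terms(combine_scores(lapply(four, function(m) m[sample(length(m))]),
                                         "SUM", normalize = TRUE))
  expect_identical(got1, got3)
})

test_that("ensemble_query dispatches strategies over spaces", {
  ri <- toy_space(c(a = 0.9, b = 0.8, c = 0.7))
  rp <- toy_space(c(a = 0.5, b = 0.85, c = 0.1))
  sum_cfg <- ensemble_config("SCORE_SUM", out_k = 3)
  got <- ensemble_query(list(ri, rp), "q", sum_cfg)
  expect_equal(candidate_terms(got)[1], "b")  # 1.65 beats a: 1.4
  sub <- ensemble_query(list(ri, rp), "q",
                        ensemble_config("SUBSET_RANK_IN_POOL", pool_k = 2, out_k = 2))
  expect_equal(candidate_terms(sub), c("a", "b"))
  two <- ensemble_query(list(list(ri, rp), list(ri, rp)), "q",
                        ensemble_config("TWO_STEP"))
  expect_s3_class(two, "candidate_list")
  expect_error(ensemble_query(list(ri, rp), "zzz", sum_cfg),
               class = "synsemble_oov")
})
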