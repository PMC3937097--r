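test_that("reference standards parse TSV, drop multiword terms, and derive queries per task", {
  f <- withr::local_tempfile(lines = c(
    "vzv\tvaricella\tvattkoppor",
    "x\thjärt infarkt",
    "EKG\telektrokardiogram"
  ))
  abbr <- load_reference_standard(f, "abbr2exp")
  expect_length(abbr$tuples, 2L)  # the multiword tuple collapses below 2 terms
  q <- ref_queries(abbr)
  expect_equal(q$vzv, c("varicella", "vattkoppor"))
  expect_equal(q$ekg, "elektrokardiogram")  # lowercased

  rev_q <- ref_queries(as_task(abbr, "exp2abbr"))
  expect_equal(rev_q$varicella, "vzv")
  expect_equal(rev_q$elektrokardiogram, "ekg")

  fs <- withr::local_tempfile(lines = "a\tb")
  syn <- load_reference_standard(fs, "syn")
  qs <- ref_queries(syn)
  expect_equal(qs$a, "b")  # synonym pairs query both ways
  expect_equal(qs$b, "a")

  fbad <- withr::local_tempfile(lines = c("a\tb", "lonely"))
  expect_error(load_reference_standard(fbad, "syn"), "line 2")
})

test_that("reference standards round-trip through TSV", {
  ref <- reference_standard(list(c("aa", "bb"), c("cc", "dd", "ee")), "syn")
  f <- withr::local_tempfile()
  write_reference_standard(ref, f)
  back <- load_reference_standard(f, "syn")
  expect_equal(back$tuples, ref$tuples)
})

test_that("dev/eval splitting partitions tuples evenly and deterministically", {
  ref <- reference_standard(lapply(1:7, function(i) c(paste0("a", i), paste0("b", i))),
                            "syn")
  sp <- split_dev_eval(ref, seed = 4)
  expect_equal(length(sp$dev$tuples), 4L)
  expect_equal(length(sp$eval$tuples), 3L)
  expect_length(intersect(vapply(sp$dev$tuples, paste, "", collapse = "|"),
                          vapply(sp$eval$tuples, paste, "", collapse = "|")), 0L)
  sp2 <- split_dev_eval(ref, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp$dev$tuples, split_dev_eval(ref, seed = 5)$dev$tuples))
})

test_that("frequency filtering requires every term to meet the floor in every table", {
  ref <- reference_standard(list(c("a", "b"), c("c", "d")), "syn")
  t1 <- c(a = 50, b = 49, c = 80, d = 60)
  expect_length(filter_by_frequency(ref, t1, 50)$tuples, 1L)
  t2 <- c(a = 50, b = 50, c = 80, d = 10)
  both <- filter_by_frequency(ref, list(c(a = 50, b = 50, c = 80, d = 60), t2), 50)
  expect_equal(both$tuples, list(c("a", "b")))  # (c,d) fails the second table
  all_kept <- filter_by_frequency(ref, t1, 1)
  expect_length(all_kept$tuples, 2L)
  # adding a table never increases survivors
  for (th in c(1, 30, 50)) {
    n1 <- length(filter_by_frequency(ref, t1, th)$tuples)
    n2 <- length(filter_by_frequency(ref, list(t1, t2), th)$tuples)
    expect_lte(n2, n1)
  }
})

test_that("recall@k micro-averages over (query, gold) pairs", {
  ref <- reference_standard(list(c("q1", "g1"), c("q2", "g2a", "g2b")), "abbr2exp")
  outs <- list(q1 = c("g1", "x"), q2 = c("g2a", "y"))
  expect_equal(recall_at_k(outs, ref, k = 10), 2 / 3)
  expect_equal(recall_at_k(list(q1 = character(0), q2 = character(0)), ref), 0)
  expect_equal(recall_at_k(list(q1 = "g1", q2 = c("g2a", "g2b")), ref), 1)
  # monotone non-decreasing in k
  outs2 <- list(q1 = c("x", "y", "g1"), q2 = c("g2b", "z", "w", "g2a"))
  r <- vapply(1:5, function(k) recall_at_k(outs2, ref, k = k), numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("weighted precision matches direct evaluation of the scoring formula", {
  ten <- paste0("c", 1:10)
  expect_equal(weighted_precision(ten, gold = ten, j = 10), 1)
  expect_equal(weighted_precision(ten, gold = "c1", j = 10), 10 / 55)
  expect_equal(weighted_precision(ten, gold = c("c1", "c10"), j = 10), 11 / 55)
  expect_equal(weighted_precision(ten, gold = "none", j = 10), 0)
  # dynamic mode: j equals the returned length
  expect_equal(weighted_precision(c("g", "x"), gold = "g", j = 2), 2 / 3)
  # lists longer than j are truncated
  expect_equal(weighted_precision(c(paste0("x", 1:10), "g"), gold = "g", j = 10), 0)
})

test_that("weighted precision is within [0,1] and improves as hits move up", {
  set.seed(13)
  terms <- paste0("c", 1:10)
  for (i in 1:50) {
    hits <- sort(sample(0:9, sample(1:5, 1)))
    gold <- terms[hits + 1]
    p <- weighted_precision(terms, gold, j = 10)
    expect_gte(p, 0); expect_lte(p, 1)
    if (hits[1] >= 1) {
      better_gold <- terms[hits]  # every hit one rank higher
      expect_gte(weighted_precision(terms, better_gold, j = 10), p)
    }
  }
})

test_that("the exact sign test matches closed form and brute-force enumeration", {
  a <- c(rep(TRUE, 8), rep(FALSE, 4))
  b <- c(rep(FALSE, 8), rep(FALSE, 4))
  expect_equal(sign_test_exact(a, b), 0.0078125)  # 2 * (1/2)^8

  expect_equal(sign_test_exact(c(TRUE, FALSE), c(FALSE, TRUE)), 1)  # equal wins
  expect_equal(sign_test_exact(logical(3), logical(3)), 1)          # no discordance
  expect_error(sign_test_exact(TRUE, c(TRUE, FALSE)), "length")

  set.seed(17)
  for (i in 1:200) {
    n_pairs <- sample(1:20, 1)
    a <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
    b <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
    disc <- a != b
    expect_equal(sign_test_exact(a, b),
                 sign_test_enum(sum(disc), sum(a & disc)))
  }
})

test_that("evaluation reports aggregate recall and mean weighted precision", {
  ref <- reference_standard(list(c("q1", "g1"), c("q2", "g2")), "abbr2exp")
  outs <- list(q1 = c("g1", paste0("x", 1:9)), q2 = paste0("y", 1:10))
  rep_ <- evaluate_outputs(outs, ref, k = 10)
  expect_equal(rep_$recall_at_k, 0.5)
  expect_equal(rep_$mean_weighted_precision, mean(c(10 / 55, 0)))
  expect_equal(rep_$n_queries, 2L)

  dyn <- evaluate_outputs(list(q1 = "g1", q2 = "z"), ref, k = 10, dynamic = TRUE)
  expect_equal(dyn$per_query$weighted_precision, c(1, 0))

  f <- withr::local_tempfile(fileext = ".json")
  s <- write_eval_report(rep_, json_path = f, label = "demo")
  expect_equal(jsonlite::read_json(f, simplifyVector = TRUE)$summary$recall, 0.5)
  expect_equal(s$n_queries, 2L)
})

test_that("frequency sweeps report shrinking reference sets as the threshold rises", {
  ref <- reference_standard(list(c("a", "b"), c("c", "d")), "syn")
  tabs <- list(c(a = 100, b = 100, c = 10, d = 100))
  outs <- list(a = "b", b = "a", c = "x", d = "y")
  sw <- frequency_sweep(outs, ref, tabs, thresholds = c(1, 50))
  expect_equal(sw$n_tuples, c(2L, 1L))
  expect_equal(sw$recall, c(0.5, 1))
  expect_true(all(diff(sw$n_queries) <= 0))
})
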