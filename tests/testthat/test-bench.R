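test_that("matching honors the inclusive 500 bp window", {
  truth <- make_sv(1000L, caller = "T")
  hit <- match_to_truth(make_sv(1400L), truth, "DEL")
  expect_equal(c(hit$tp, hit$fp, hit$fn), c(1L, 0L, 0L))
  exact <- match_to_truth(make_sv(1500L), truth, "DEL")
  expect_equal(exact$tp, 1L)
  miss <- match_to_truth(make_sv(1501L), truth, "DEL")
  expect_equal(c(miss$tp, miss$fp, miss$fn), c(0L, 1L, 1L))
})

test_that("assignment is one-to-one: extra nearby calls become FPs", {
  truth <- make_sv(1000L, caller = "T")
  conf <- match_to_truth(make_sv(c(900L, 1100L)), truth, "DEL")
  expect_equal(c(conf$tp, conf$fp, conf$fn), c(1L, 1L, 0L))
  pairs <- attr(conf, "pairs")
  expect_equal(pairs$distance, 100L)  # nearest call wins
})

test_that("matching requires same contig and same type", {
  truth <- make_sv(1000L, caller = "T")
  other_contig <- match_to_truth(make_sv(1000L, contig = "chr2"), truth, "DEL")
  expect_equal(other_contig$tp, 0L)
  expect_error(
    match_to_truth(make_sv(1000L, svtype = "INS"), truth, "DEL"),
    "one type"
  )
})

test_that("empty call sets score zero without erroring", {
  truth <- make_sv(c(1000L, 5000L), caller = "T")
  conf <- match_to_truth(make_sv(integer()), truth, "DEL")
  expect_equal(c(conf$tp, conf$fp, conf$fn), c(0L, 0L, 2L))
  m <- compute_metrics(tibble::as_tibble(conf))
  expect_equal(c(m$precision, m$recall, m$f1), c(0, 0, 0))
})

test_that("precision, recall and F1 reproduce a published single-caller row", {
  # Verified against a published HG002 DEL evaluation (total 3935 calls).
  m <- compute_metrics(tibble::tibble(tp = 2996, fp = 939, fn = 2468))
  expect_equal(round_half_up(m$precision, 2), 0.76)
  expect_equal(round_half_up(m$recall, 2), 0.55)
  expect_equal(round_half_up(m$f1, 2), 0.64)

  sym <- compute_metrics(tibble::tibble(tp = 5, fp = 5, fn = 5))
  expect_equal(c(sym$precision, sym$recall, sym$f1), c(0.5, 0.5, 0.5))
  expect_error(compute_metrics(tibble::tibble(tp = -1, fp = 0, fn = 0)),
               "non-negative")
})

test_that("micro averaging matches the published four-dataset combination", {
  counts <- tibble::tibble(
    callset = "DRAGEN", svtype = "DEL",
    tp = c(3425, 4790, 4896, 5775),
    fp = c(1362, 1613, 999, 1122),
    fn = c(2039, 3739, 3798, 4390)
  )
  cmb <- combine_micro(counts)
  expect_equal(round_half_up(cmb$recall, 2), 0.57)
  expect_equal(round_half_up(cmb$precision, 2), 0.79)
  expect_equal(round_half_up(cmb$f1, 2), 0.66)
  expect_equal(cmb$tp, 18886)
})

test_that("micro average is scale-invariant and bounded by per-dataset metrics", {
  one <- tibble::tibble(callset = "x", svtype = "DEL", tp = 40, fp = 10, fn = 50)
  expect_equal(
    combine_micro(one)[, c("precision", "recall", "f1")],
    compute_metrics(one)[, c("precision", "recall", "f1")]
  )
  expect_equal(
    combine_micro(dplyr::bind_rows(one, one))[, c("precision", "recall", "f1")],
    combine_micro(one)[, c("precision", "recall", "f1")]
  )

  withr::with_seed(99, {
    for (i in 1:20) {
      counts <- tibble::tibble(
        callset = "x", svtype = "DEL",
        tp = sample(0:100, 4), fp = sample(0:100, 4), fn = sample(1:100, 4)
      )
      per <- compute_metrics(counts)
      cmb <- combine_micro(counts)
      expect_gte(cmb$recall, min(per$recall))
      expect_lte(cmb$recall, max(per$recall))
      expect_gte(cmb$precision, min(per$precision))
      expect_lte(cmb$precision, max(per$precision))
    }
  })
  expect_error(combine_micro(tibble::tibble(tp = integer(), fp = integer(),
                                            fn = integer())), "at least one")
})

test_that("greedy TP is bounded by maximum matching and exact when truth is spaced", {
  for (i in 1:100) {
    withr::with_seed(3000 + i, {
      n_truth <- sample(1:20, 1)
      n_test <- sample(1:20, 1)
      truth_pos <- sample(1:4000, n_truth)
      test_pos <- sample(1:4000, n_test)
    })
    conf <- match_to_truth(make_sv(test_pos), make_sv(truth_pos, caller = "T"),
                           "DEL")
    expect_lte(conf$tp, max_matching_tp(truth_pos, test_pos))
  }
  for (i in 1:50) {
    withr::with_seed(4000 + i, {
      n_truth <- sample(1:15, 1)
      truth_pos <- cumsum(sample(1001:3000, n_truth, replace = TRUE))
      n_test <- sample(1:20, 1)
      test_pos <- sample(1:max(truth_pos + 1000), n_test)
    })
    conf <- match_to_truth(make_sv(test_pos), make_sv(truth_pos, caller = "T"),
                           "DEL")
    expect_equal(conf$tp, max_matching_tp(truth_pos, test_pos))
  }
})

test_that("the matching window is symmetric on spacing-separated instances", {
  withr::with_seed(6, {
    truth_pos <- cumsum(sample(1001:2000, 30, replace = TRUE))
    keep <- runif(30) < 0.6
    test_pos <- truth_pos[keep] + sample(-400:400, sum(keep), replace = TRUE)
  })
  a <- match_to_truth(make_sv(test_pos), make_sv(truth_pos, caller = "T"), "DEL")
  b <- match_to_truth(make_sv(truth_pos), make_sv(test_pos, caller = "T"), "DEL")
  expect_equal(a$tp, b$tp)
})

test_that("benchmark objects tidy, glance and plot", {
  truth <- dplyr::bind_rows(
    make_sv(c(1000L, 5000L, 9000L), caller = "T"),
    make_sv(c(20000L, 30000L), caller = "T", svtype = "INS")
  )
  callsets <- list(
    good = dplyr::bind_rows(make_sv(c(1004L, 5100L)),
                            make_sv(20000L, svtype = "INS")),
    noisy = make_sv(c(1000L, 99000L))
  )
  bench <- benchmark_callsets(callsets, truth, dataset = "d1")
  td <- tidy(bench)
  expect_equal(nrow(td), 4)  # 2 callsets x 2 svtypes
  expect_equal(td$tp[td$callset == "good" & td$svtype == "DEL"], 2L)
  expect_equal(td$fn[td$callset == "good" & td$svtype == "INS"], 1L)
  gl <- glance(bench)
  expect_equal(nrow(gl), 4)
  expect_s3_class(autoplot(bench), "ggplot")
  # conservation invariants
  expect_equal(bench$counts$tp + bench$counts$fp, bench$counts$total)
})

test_that("evaluation reports round half up to two decimals", {
  counts <- tibble::tibble(dataset = "d1", callset = "x", svtype = "DEL",
                           tp = 5, fp = 3, fn = 3)
  rep <- evaluation_report(counts)
  expect_equal(rep$per_dataset$d1$precision_2dp, 0.63)  # 0.625 rounds up
  expect_equal(rep$per_dataset$d1$recall_2dp, 0.63)
  expect_equal(round_half_up(0.625, 2), 0.63)
  expect_equal(round_half_up(-0.625, 2), -0.63)

  out <- withr::local_tempdir()
  evaluation_report(counts, out_dir = out)
  expect_true(file.exists(file.path(out, "metrics_d1.tsv")))
  expect_true(file.exists(file.path(out, "metrics_combined.tsv")))
})
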