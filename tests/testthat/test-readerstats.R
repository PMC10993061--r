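make_responses <- function(truth, calls, confidence = NULL, reader = "r1",
                           condition = "HR") {
  n <- length(truth)
  if (is.null(confidence)) confidence <- rep("high", n)
  list(
    responses = data.frame(reader_id = reader,
                           image_id = sprintf("i%02d", seq_len(n)),
                           condition = condition, call = calls,
                           confidence = confidence, stringsAsFactors = FALSE),
    gold = data.frame(image_id = sprintf("i%02d", seq_len(n)), truth = truth,
                      stringsAsFactors = FALSE)
  )
}

P <- "neoplastic"; N <- "non_neoplastic"

test_that("confusion counts match hand enumeration", {
  d <- make_responses(rep(c(P, N), c(4, 6)),
                      c(P, P, P, N, P, N, N, N, N, N))
  cm <- confusion(d$responses, d$gold)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(3L, 1L, 1L, 5L))
  expect_identical(cm$n, 10L)
  # all-correct toy set: no errors
  d2 <- make_responses(c(P, P, N, N), c(P, P, N, N))
  cm2 <- confusion(d2$responses, d2$gold)
  expect_identical(c(cm2$fp, cm2$fn), c(0L, 0L))
  # empty stratum: zero counts, flagged
  cm3 <- confusion(d2$responses, d2$gold, stratum = "low_conf")
  expect_true(cm3$empty)
  expect_identical(cm3$tp + cm3$fp + cm3$fn + cm3$tn, 0L)
  # missing gold labels are reported by id
  bad <- d$responses
  bad$image_id[1] <- "mystery"
  expect_error(confusion(bad, d$gold), "mystery")
})

test_that("confusion counts partition across confidence strata", {
  set.seed(71)
  n <- 60
  truth <- sample(c(P, N), n, replace = TRUE)
  calls <- ifelse(runif(n) < 0.7, truth, ifelse(truth == P, N, P))
  conf <- sample(c("high", "low"), n, replace = TRUE)
  d <- make_responses(truth, calls, conf)
  all_c <- confusion(d$responses, d$gold, "all")
  hi <- confusion(d$responses, d$gold, "high_conf")
  lo <- confusion(d$responses, d$gold, "low_conf")
  for (f in c("tp", "fp", "fn", "tn")) {
    expect_identical(hi[[f]] + lo[[f]], all_c[[f]])
  }
  # order invariance
  perm <- sample(n)
  all_p <- confusion(d$responses[perm, ], d$gold)
  expect_identical(all_p[c("tp", "fp", "fn", "tn")],
                   all_c[c("tp", "fp", "fn", "tn")])
})

test_that("diagnostic metrics match brute force on all small tables", {
  # exhaustive 2x2 tables with totals <= 12
  for (tp in 0:12) for (fp in 0:(12 - tp)) for (fn in 0:(12 - tp - fp)) {
    for (tn in 0:(12 - tp - fp - fn)) {
      m <- diagnostic_metrics(list(tp = tp, fp = fp, fn = fn, tn = tn))
      tot <- tp + fp + fn + tn
      expect_equal(m$accuracy, if (tot == 0) NA_real_ else (tp + tn) / tot)
      expect_equal(m$sensitivity,
                   if (tp + fn == 0) NA_real_ else tp / (tp + fn))
      expect_equal(m$specificity,
                   if (tn + fp == 0) NA_real_ else tn / (tn + fp))
    }
  }
})

test_that("diagnostic metrics handle the worked example and edge cases", {
  m <- diagnostic_metrics(list(tp = 3, fn = 1, fp = 1, tn = 5))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  perfect <- diagnostic_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  none_pos <- diagnostic_metrics(list(tp = 0, fp = 2, fn = 0, tn = 3))
  expect_true(is.na(none_pos$sensitivity))
  expect_error(diagnostic_metrics(list(tp = -1, fp = 0, fn = 0, tn = 0)),
               "nonnegative")
})

test_that("unpaired t-test matches the hand formula and stats::t.test", {
  a <- c(0.70, 0.72, 0.74)
  b <- c(0.60, 0.62, 0.64)
  got <- unpaired_t_test(a, b)
  want <- brute_pooled_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$t, 6.123724, tolerance = 1e-6)  # pooled SD 0.02, df 4
  expect_identical(got$df, 4)
  # swap antisymmetry
  sw <- unpaired_t_test(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)
  # identical groups
  same <- unpaired_t_test(c(1, 1), c(1, 1))
  expect_identical(c(same$t, same$p), c(0, 1))
  expect_error(unpaired_t_test(c(1, 1), c(2, 2)), "undefined")
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
  # agreement with the reference implementation on random groups
  set.seed(81)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), 0.7, 0.1)
    y <- rnorm(sample(3:12, 1), 0.65, 0.12)
    ours <- unpaired_t_test(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    ours_w <- unpaired_t_test(x, y, var_equal = FALSE)
    ref_w <- stats::t.test(x, y)
    expect_equal(ours_w$t, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-10)
  }
})

test_that("equivalence sample size follows the two-proportion formula", {
  # p = 0.5, alpha 0.05 two-sided, power 0.8, limit 0.15
  expect_identical(equivalence_sample_size(0.5, 0.15), 175L)
  # monotone in the limit; quadruples when the limit halves (up to rounding)
  n_wide <- equivalence_sample_size(0.7, 0.30)
  n_narrow <- equivalence_sample_size(0.7, 0.15)
  expect_lt(n_wide, n_narrow)
  expect_lte(abs(n_narrow - 4 * n_wide), 4)
  expect_error(equivalence_sample_size(0, 0.15), "p_assumed")
  expect_error(equivalence_sample_size(0.5, 1), "limit")
})

test_that("the demo gold set carries the 78/42 class mix", {
  gold <- demo_gold_labels()
  expect_identical(nrow(gold), 120L)
  expect_identical(sum(gold$truth == P), 78L)
  expect_identical(sum(gold$truth == N), 42L)
  expect_identical(gold, demo_gold_labels())
})

test_that("identical response tables across conditions give p = 1 everywhere", {
  gold <- demo_gold_labels()
  acc <- c(r1 = 0.7, r2 = 0.72, r3 = 0.68, r4 = 0.74)
  hr <- simulate_reader_responses(gold, list(HR = acc), seed = 5)
  sr <- hr
  sr$condition <- "SR"
  rep <- reader_study_report(rbind(hr, sr), gold)
  expect_true(all(rep$tests$p == 1))
  expect_identical(rep$pooled$accuracy[rep$pooled$condition == "HR" &
                                         rep$pooled$stratum == "all"],
                   rep$pooled$accuracy[rep$pooled$condition == "SR" &
                                         rep$pooled$stratum == "all"])
})

test_that("simulated readers reproduce their nominal accuracy", {
  gold <- demo_gold_labels()
  resp <- simulate_reader_responses(
    gold, list(HR = c(r1 = 0.7, r2 = 0.7, r3 = 0.7, r4 = 0.7),
               SR = c(r1 = 0.7, r2 = 0.7, r3 = 0.7, r4 = 0.7)),
    high_conf_rate = 0.5, seed = 7)
  rep <- reader_study_report(resp, gold)
  pooled <- rep$pooled[rep$pooled$stratum == "all", ]
  n <- 4 * 120
  half <- 1.96 * sqrt(0.7 * 0.3 / n)
  expect_true(all(abs(pooled$accuracy - 0.7) < half))
  # confidence fractions near the nominal rate
  expect_true(all(abs(rep$confidence$high_conf_fraction - 0.5) < 0.1))
  # strata partition: per-reader high + low counts equal "all"
  pr <- rep$per_reader
  for (rd in unique(pr$reader_id)) {
    for (cond in c("HR", "SR")) {
      sub <- pr[pr$reader_id == rd & pr$condition == cond, ]
      expect_identical(sub$n[sub$stratum == "high_conf"] +
                         sub$n[sub$stratum == "low_conf"],
                       sub$n[sub$stratum == "all"])
    }
  }
})

test_that("single-reader studies omit t-tests with a notice", {
  gold <- demo_gold_labels()
  resp <- simulate_reader_responses(gold, list(HR = c(solo = 0.7),
                                               SR = c(solo = 0.7)), seed = 9)
  rep <- reader_study_report(resp, gold)
  expect_null(rep$tests)
  expect_match(rep$notes, "single reader")
})

test_that("reader reports write CSV and JSON outputs", {
  gold <- demo_gold_labels()
  resp <- simulate_reader_responses(gold, seed = 11)
  rep <- reader_study_report(resp, gold)
  dir <- withr::local_tempdir()
  write_reader_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("per_reader.csv", "pooled.csv",
                                               "tests.csv", "confidence.csv",
                                               "report.json")))))
  back <- utils::read.csv(file.path(dir, "pooled.csv"))
  expect_equal(nrow(back), nrow(rep$pooled))
})
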