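# Reader-study analytics: diagnostic performance of binary neoplasia calls
# against a histopathology gold standard, confidence stratification, group
# comparison across readers, and equivalence sample-size planning. The
# positive class is "neoplastic" throughout.

validate_responses <- function(responses) {
  need <- c("reader_id", "image_id", "condition", "call", "confidence")
  stop_if_not(is.data.frame(responses) && all(need %in% names(responses)),
              paste("responses must have columns:", paste(need, collapse = ", ")))
  stop_if_not(all(responses$call %in% c("neoplastic", "non_neoplastic")),
              "call must be neoplastic or non_neoplastic")
  stop_if_not(all(responses$confidence %in% c("high", "low")),
              "confidence must be high or low")
  key <- paste(responses$reader_id, responses$image_id, responses$condition)
  stop_if_not(!anyDuplicated(key),
              "one response per (reader, image, condition) is required")
  invisible(responses)
}

validate_gold <- function(gold) {
  stop_if_not(is.data.frame(gold) && all(c("image_id", "truth") %in% names(gold)),
              "gold must have columns image_id, truth")
  stop_if_not(all(gold$truth %in% c("neoplastic", "non_neoplastic")),
              "truth must be neoplastic or non_neoplastic")
  stop_if_not(!anyDuplicated(gold$image_id), "gold labels must be unique per image")
  invisible(gold)
}

#' Confusion counts of reader calls against the gold standard
#'
#' Positive class is `neoplastic`. `stratum` restricts to high- or
#' low-confidence responses; counts always sum to the number of responses in
#' the stratum. An empty stratum yields all-zero counts flagged `empty`.
#'
#' @param responses data.frame with columns `reader_id`, `image_id`,
#'   `condition`, `call`, `confidence`.
#' @param gold data.frame with columns `image_id`, `truth`.
#' @param stratum `"all"`, `"high_conf"` or `"low_conf"`.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn`, `n`, `stratum`, `empty`.
#' @export
confusion <- function(responses, gold, stratum = c("all", "high_conf", "low_conf")) {
  stratum <- match.arg(stratum)
  validate_responses(responses)
  validate_gold(gold)
  missing <- setdiff(unique(responses$image_id), gold$image_id)
  if (length(missing) > 0) {
    stop("responses reference images without gold labels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- switch(stratum, all = rep(TRUE, nrow(responses)),
                 high_conf = responses$confidence == "high",
                 low_conf = responses$confidence == "low")
  r <- responses[keep, , drop = FALSE]
  truth <- gold$truth[match(r$image_id, gold$image_id)]
  pos_call <- r$call == "neoplastic"
  pos_truth <- truth == "neoplastic"
  structure(list(tp = sum(pos_call & pos_truth),
                 fp = sum(pos_call & !pos_truth),
                 fn = sum(!pos_call & pos_truth),
                 tn = sum(!pos_call & !pos_truth),
                 n = nrow(r), stratum = stratum, empty = nrow(r) == 0L),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`. Ratios with a zero denominator are reported as `NA`
#' (absent), never coerced to 0.
#'
#' @param counts a `confusion_counts` object, or a named list/vector with
#'   `tp`, `fp`, `fn`, `tn`.
#' @return object of class `performance_summary`: list with `sensitivity`,
#'   `specificity`, `accuracy`, the four counts, `stratum`.
#' @export
diagnostic_metrics <- function(counts) {
  cl <- as.list(counts)
  for (nm in c("tp", "fp", "fn", "tn")) {
    stop_if_not(is_number(cl[[nm]]) && cl[[nm]] >= 0 && cl[[nm]] == round(cl[[nm]]),
                "counts must be nonnegative integers")
  }
  tot <- cl$tp + cl$fp + cl$fn + cl$tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = ratio(cl$tp, cl$tp + cl$fn),
    specificity = ratio(cl$tn, cl$tn + cl$fp),
    accuracy = ratio(cl$tp + cl$tn, tot),
    tp = cl$tp, fp = cl$fp, fn = cl$fn, tn = cl$tn,
    stratum = if (is.null(cl$stratum)) "all" else cl$stratum
  ), class = "performance_summary")
}

#' Two-sample unpaired t-test
#'
#' Two-sided unpaired t-test of equal means; pooled-variance (Student's) by
#' default, with `var_equal = FALSE` giving the Welch form. Degenerate inputs
#' with zero pooled variance return `p = 1` when the group means are equal and
#' raise an error otherwise.
#'
#' @param group_a,group_b numeric vectors, each of length `>= 2`.
#' @param var_equal pooled-variance Student's test if `TRUE` (default).
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(group_a, group_b, var_equal = TRUE) {
  stop_if_not(is.numeric(group_a) && length(group_a) >= 2 &&
                is.numeric(group_b) && length(group_b) >= 2,
              "each group needs at least 2 values")
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    stop("zero variance in both groups with unequal means: t is undefined",
         call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Equivalence-trial sample size for binary outcomes
#'
#' Smallest integer `n >= (z_{1-alpha/2} + z_{1-beta})^2 * 2 p (1 - p) /
#' limit^2` under the two-proportion equal-variance formulation with no
#' continuity correction. The assumed proportion enters explicitly: published
#' reader-study sample sizes computed from "sample-based variance estimates"
#' cannot be reproduced without knowing the variance actually assumed, so
#' `p_assumed` is an argument, not a hidden constant.
#'
#' @param p_assumed assumed response proportion in `(0, 1)`.
#' @param limit equivalence limit (margin) in `(0, 1)`.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @return integer sample size per group.
#' @export
equivalence_sample_size <- function(p_assumed, limit, alpha = 0.05,
                                    power = 0.8) {
  stop_if_not(is_number(p_assumed) && p_assumed > 0 && p_assumed < 1,
              "p_assumed must be in (0, 1)")
  stop_if_not(is_number(limit) && limit > 0 && limit < 1,
              "limit must be in (0, 1)")
  stop_if_not(is_number(alpha) && alpha > 0 && alpha < 1,
              "alpha must be in (0, 1)")
  stop_if_not(is_number(power) && power > 0 && power < 1,
              "power must be in (0, 1)")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(z^2 * 2 * p_assumed * (1 - p_assumed) / limit^2))
}

#' Demo gold-standard label set
#'
#' A deterministic 120-image gold set with the reference class mix of the
#' reader study: 78 neoplastic (65%) and 42 non-neoplastic (35%) images, in a
#' fixed pseudo-random order. This is a synthetic stand-in for a biopsy
#' histopathology adjudication.
#'
#' @return data.frame with columns `image_id`, `truth`.
#' @export
demo_gold_labels <- function() {
  n <- 120L
  truth <- rep(c("neoplastic", "non_neoplastic"), c(78L, 42L))
  ord <- withr::with_seed(20240404L, sample.int(n))
  data.frame(image_id = sprintf("img%03d", seq_len(n)), truth = truth[ord],
             stringsAsFactors = FALSE)
}

#' Simulate reader responses
#'
#' Draws per-reader binary calls for each image and condition: the call is
#' correct with the reader's accuracy for that condition, and confidence is
#' high with probability `high_conf_rate`. Deterministic under `seed`.
#'
#' @param gold data.frame `image_id`, `truth`.
#' @param reader_accuracy named list: per condition, numeric vector of
#'   per-reader probabilities of a correct call (names become reader ids).
#' @param high_conf_rate probability of a high-confidence response.
#' @param seed integer seed.
#' @return responses data.frame suitable for [confusion()] /
#'   [reader_study_report()].
#' @export
simulate_reader_responses <- function(gold,
                                      reader_accuracy = list(
                                        HR = c(r1 = 0.72, r2 = 0.70, r3 = 0.74,
                                               r4 = 0.64),
                                        SR = c(r1 = 0.71, r2 = 0.69, r3 = 0.73,
                                               r4 = 0.63)),
                                      high_conf_rate = 0.5, seed = 1L) {
  validate_gold(gold)
  stop_if_not(is.list(reader_accuracy) && length(reader_accuracy) >= 1,
              "reader_accuracy must be a named list of per-condition vectors")
  withr::with_seed(seed, {
    rows <- list()
    for (cond in names(reader_accuracy)) {
      acc <- reader_accuracy[[cond]]
      readers <- names(acc)
      if (is.null(readers)) readers <- sprintf("reader%02d", seq_along(acc))
      for (j in seq_along(acc)) {
        correct <- runif(nrow(gold)) < acc[j]
        call <- ifelse(correct, gold$truth,
                       ifelse(gold$truth == "neoplastic", "non_neoplastic",
                              "neoplastic"))
        conf <- ifelse(runif(nrow(gold)) < high_conf_rate, "high", "low")
        rows[[length(rows) + 1]] <- data.frame(
          reader_id = readers[j], image_id = gold$image_id, condition = cond,
          call = call, confidence = conf, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Full reader-study report
#'
#' Per-reader and pooled diagnostic performance for each condition, overall
#' and by confidence stratum; per-metric unpaired t-tests comparing the two
#' conditions across readers; and the high-confidence response fraction per
#' condition. With a single reader, t-tests are omitted with a notice.
#'
#' @param responses responses data.frame (both conditions present).
#' @param gold gold-label data.frame.
#' @param conditions length-2 character vector of condition labels to compare
#'   (default the two unique values in `responses$condition`).
#' @return list with `per_reader` (data.frame), `pooled` (data.frame),
#'   `tests` (data.frame or `NULL`), `confidence` (data.frame), `notes`
#'   (character).
#' @export
reader_study_report <- function(responses, gold, conditions = NULL) {
  validate_responses(responses)
  validate_gold(gold)
  if (is.null(conditions)) conditions <- sort(unique(responses$condition))
  stop_if_not(length(conditions) == 2L &&
                all(conditions %in% responses$condition),
              "responses must cover exactly two conditions")
  readers <- sort(unique(responses$reader_id))
  strata <- c("all", "high_conf", "low_conf")
  metr <- function(sub, stratum) diagnostic_metrics(confusion(sub, gold, stratum))
  per_reader <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(readers, function(rd) {
      sub <- responses[responses$condition == cond &
                         responses$reader_id == rd, , drop = FALSE]
      do.call(rbind, lapply(strata, function(st) {
        m <- metr(sub, st)
        data.frame(reader_id = rd, condition = cond, stratum = st,
                   n = m$tp + m$fp + m$fn + m$tn,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   accuracy = m$accuracy, tp = m$tp, fp = m$fp, fn = m$fn,
                   tn = m$tn, stringsAsFactors = FALSE)
      }))
    }))
  }))
  pooled <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- responses[responses$condition == cond, , drop = FALSE]
    do.call(rbind, lapply(strata, function(st) {
      m <- metr(sub, st)
      data.frame(condition = cond, stratum = st,
                 n = m$tp + m$fp + m$fn + m$tn,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 accuracy = m$accuracy, tp = m$tp, fp = m$fp, fn = m$fn,
                 tn = m$tn, stringsAsFactors = FALSE)
    }))
  }))
  notes <- character()
  tests <- NULL
  if (length(readers) >= 2) {
    pr_all <- per_reader[per_reader$stratum == "all", ]
    tests <- do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy"),
                                   function(m) {
      a <- pr_all[[m]][pr_all$condition == conditions[1]]
      b <- pr_all[[m]][pr_all$condition == conditions[2]]
      if (anyNA(a) || anyNA(b)) {
        return(data.frame(metric = m, t = NA_real_, df = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      tt <- tryCatch(unpaired_t_test(a, b),
                     error = function(e) list(t = NA_real_, df = NA_real_,
                                              p = NA_real_))
      data.frame(metric = m, t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  } else {
    notes <- c(notes, "single reader: between-condition t-tests omitted")
  }
  confidence <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- responses[responses$condition == cond, , drop = FALSE]
    data.frame(condition = cond, n = nrow(sub),
               high_conf_fraction = mean(sub$confidence == "high"),
               stringsAsFactors = FALSE)
  }))
  list(per_reader = per_reader, pooled = pooled, tests = tests,
       confidence = confidence, notes = notes)
}

#' Write a reader-study report to disk
#'
#' Writes the report tables as CSV plus a combined JSON file.
#'
#' @param report result of [reader_study_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reader_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_reader, file.path(dir, "per_reader.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pooled, file.path(dir, "pooled.csv"),
                   row.names = FALSE)
  if (!is.null(report$tests)) {
    utils::write.csv(report$tests, file.path(dir, "tests.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$confidence, file.path(dir, "confidence.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              na = "null", dataframe = "rows"),
             file.path(dir, "report.json"))
  invisible(dir)
}
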