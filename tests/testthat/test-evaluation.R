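# random prediction/gold fixtures over a small vocabulary
random_eval_fixture <- function(v, n, acc_target = 0.7, seed = 1) {
  set.seed(seed)
  golds <- sample(v$codes, n, replace = TRUE)
  preds <- ifelse(stats::runif(n) < acc_target, golds,
                  sample(v$codes, n, replace = TRUE))
  list(preds = preds, golds = golds)
}

# random probability rows (Dirichlet-ish) with argmax extracted
random_distributions <- function(v, n, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * v$V), n, v$V)
  p <- p / rowSums(p)
  colnames(p) <- v$codes
  p
}

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c("A00", "B00"), c("A00", "B00")), 1)
  expect_equal(accuracy(c("A00", "B00", "C00", "D00"),
                        c("A00", "B00", "C00", "X00")), 0.75)
  expect_error(accuracy("A00", c("A00", "B00")), "length")
  v <- test_vocab()
  fx <- random_eval_fixture(v, 1000, seed = 3)
  naive <- 0
  for (i in seq_len(1000)) naive <- naive + (fx$preds[i] == fx$golds[i])
  expect_equal(accuracy(fx$preds, fx$golds), naive / 1000)
})

test_that("bootstrap intervals behave on degenerate and typical inputs", {
  expect_equal(bootstrap_ci(rep(1, 50), B = 200, seed = 1), c(1, 1))
  expect_equal(bootstrap_ci(rep(0, 50), B = 200, seed = 1), c(0, 0))
  flags <- c(rep(1, 1800), rep(0, 200))
  ci1 <- bootstrap_ci(flags, B = 500, seed = 4)
  expect_identical(ci1, bootstrap_ci(flags, B = 500, seed = 4))
  expect_lt(ci1[1], 0.9); expect_gt(ci1[2], 0.9)
  # half-width on the order of the binomial standard error
  se <- sqrt(0.9 * 0.1 / 2000)
  hw <- diff(ci1) / 2
  expect_gt(hw, 1.2 * se); expect_lt(hw, 2.8 * se)
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("per-chapter tables decompose the accuracy by prevalence", {
  v <- test_vocab()
  ch1 <- v$codes[v$chapters == "I"]
  rep1 <- per_chapter_report(ch1[1:3], ch1[1:3], v)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$prevalence, 1)
  expect_equal(rep1$error_rate, 0)

  golds <- c(ch1[1], ch1[1], ch1[2])
  preds <- c(ch1[1], v$codes[50], v$codes[60])
  rep2 <- per_chapter_report(preds, golds, v)
  expect_equal(rep2$error_rate[rep2$chapter == "I"], 2 / 3)

  fx <- random_eval_fixture(v, 500, seed = 7)
  rep3 <- per_chapter_report(fx$preds, fx$golds, v)
  expect_equal(sum(rep3$prevalence), 1, tolerance = 1e-12)
  # prevalence-weighted error rates recompose the global accuracy
  expect_equal(sum(rep3$prevalence * (1 - rep3$error_rate)),
               accuracy(fx$preds, fx$golds), tolerance = 1e-12)
  # chapters never observed as gold are flagged
  expect_setequal(c(rep3$chapter, attr(rep3, "unobserved_chapters")),
                  unique(unname(v$chapters)))
})

test_that("chapter confusion of errors counts mispredictions only", {
  v <- test_vocab()
  expect_equal(dim(chapter_confusion_on_errors(v$codes[1:5], v$codes[1:5], v)),
               c(0L, 0L))
  ch1 <- v$codes[v$chapters == "I"]
  m1 <- chapter_confusion_on_errors(ch1[2], ch1[1], v)
  expect_equal(unname(m1["I", "I"]), 1L)  # in-chapter error on the diagonal
  fx <- random_eval_fixture(v, 400, acc_target = 0.6, seed = 11)
  m <- chapter_confusion_on_errors(fx$preds, fx$golds, v)
  expect_equal(sum(m), sum(fx$preds != fx$golds))
})

test_that("top-k accuracy is monotone, exact at k=V, and argmax at k=1", {
  v <- test_vocab()
  probs <- random_distributions(v, 200, seed = 5)
  set.seed(6)
  golds <- sample(v$codes, 200, replace = TRUE)
  accs <- vapply(1:5, function(k) topk_accuracy(probs, golds, v, k), 0)
  expect_true(all(diff(accs) >= 0))
  expect_equal(topk_accuracy(probs, golds, v, v$V), 1)
  preds <- v$codes[max.col(probs, ties.method = "first")]
  expect_equal(topk_accuracy(probs, golds, v, 1), accuracy(preds, golds))
  expect_error(topk_accuracy(probs, golds, v, 0), "k must be")
})

test_that("the top-2 identity with second-choice accuracy holds exactly", {
  v <- test_vocab()
  for (s in 1:3) {
    probs <- random_distributions(v, 300, seed = s)
    set.seed(s + 10)
    golds <- sample(v$codes, 300, replace = TRUE)
    preds <- v$codes[max.col(probs, ties.method = "first")]
    acc <- accuracy(preds, golds)
    sc <- second_choice_accuracy_on_errors(probs, preds, golds, v)
    expect_equal(topk_accuracy(probs, golds, v, 2),
                 acc + (1 - acc) * sc, tolerance = 1e-12)
  }
  # all-gold-at-rank-2 yields 1, no errors is flagged undefined
  p <- matrix(c(0.6, 0.4, 0, 0.6, 0.4, 0), 2, 3, byrow = TRUE)
  v3 <- build_vocabulary(c("A00", "B00", "C00"))
  colnames(p) <- v3$codes
  expect_equal(second_choice_accuracy_on_errors(
    p, c("A00", "A00"), c("B00", "B00"), v3), 1)
  expect_warning(
    out <- second_choice_accuracy_on_errors(p, c("A00", "A00"),
                                            c("A00", "A00"), v3),
    "undefined")
  expect_true(is.na(out))
})

test_that("calibration report bins confidences by correctness", {
  v <- test_vocab()
  probs <- random_distributions(v, 250, seed = 8)
  set.seed(9)
  golds <- sample(v$codes, 250, replace = TRUE)
  preds <- v$codes[max.col(probs, ties.method = "first")]
  cal <- calibration_report(probs, preds, golds, n_bins = 10)
  expect_equal(sum(cal$bins$count_correct) + sum(cal$bins$count_incorrect),
               250L)
  # a perfectly confident, always-correct model concentrates in the top bin
  pc <- diag(3)[c(1, 2), ]
  v3 <- build_vocabulary(c("A00", "B00", "C00"))
  colnames(pc) <- v3$codes
  cal2 <- calibration_report(pc, c("A00", "B00"), c("A00", "B00"), n_bins = 5)
  expect_equal(cal2$bins$count_correct[5], 2L)
  expect_equal(sum(cal2$bins$count_incorrect), 0L)
  expect_equal(cal2$mean_confidence_correct, 1)
  expect_error(calibration_report(probs, preds, golds, n_bins = 1), "n_bins")
})

test_that("baseline comparison handles rejects the dual way", {
  ores <- function(ucd, rejected = FALSE) {
    list(ucd = if (rejected) NA_character_ else ucd, rejected = rejected)
  }
  golds <- rep("A00", 4)
  # zero rejects: both accuracies coincide
  b0 <- compare_with_baseline(rep("A00", 4),
                              replicate(4, ores("A00"), simplify = FALSE),
                              golds)
  expect_equal(b0$overall_accuracy, b0$nonrejected_accuracy)
  expect_equal(b0$reject_fraction, 0)
  # 50% rejects, everything else correct: overall 0.5, nonrejected 1.0
  b1 <- compare_with_baseline(
    rep("A00", 4),
    list(ores("A00"), ores("A00"), ores(NA, TRUE), ores(NA, TRUE)), golds)
  expect_equal(b1$overall_accuracy, 0.5)
  expect_equal(b1$nonrejected_accuracy, 1)
  expect_equal(b1$reject_fraction, 0.5)
  # property: overall <= nonrejected whenever rejects exist
  set.seed(13)
  for (i in 1:20) {
    n <- 40
    rej <- stats::runif(n) < stats::runif(1, 0.05, 0.6)
    ok <- stats::runif(n) < 0.8
    res <- lapply(seq_len(n), function(j) {
      ores(if (ok[j]) "A00" else "B00", rej[j])
    })
    b <- compare_with_baseline(rep("A00", n), res, rep("A00", n))
    if (any(rej) && !is.na(b$nonrejected_accuracy) &&
        b$nonrejected_accuracy > 0) {
      expect_lte(b$overall_accuracy, b$nonrejected_accuracy)
    }
  }
  expect_error(compare_with_baseline("A00", list(), "A00"), "aligned")
})

test_that("the full evaluation report is coherent", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- tiny_trained_coder()
  test <- generate_dataset(m, 150, seed = 70)
  rep <- evaluate_coder(coder, test, v, B = 200, seed = 3)
  expect_s3_class(rep, "ucd_eval_report")
  expect_equal(rep$n, 150L)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_lte(rep$ci95[1], rep$ci95[2])
  expect_gte(rep$topk["top2"], rep$topk["top1"])
  expect_equal(unname(rep$topk["top1"]), rep$accuracy)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n, 150L)
  expect_equal(parsed$accuracy, rep$accuracy)
})
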