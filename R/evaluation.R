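#' Prediction accuracy
#'
#' Fraction of exactly matching predicted codes.
#'
#' @param preds,golds Equal-length character vectors of codes.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(preds, golds) {
  if (length(preds) != length(golds)) stop("preds and golds differ in length")
  if (length(preds) == 0) stop("empty input")
  mean(preds == golds)
}

#' Percentile bootstrap confidence interval for an accuracy
#'
#' Resamples the 0/1 correctness flags with replacement `B` times and takes
#' the percentile interval of the resampled accuracies. Deterministic under
#' `seed`.
#'
#' @param correct_flags Vector of 0/1 (or logical) correctness indicators.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(correct_flags, B = 1000L, level = 0.95, seed = 1L) {
  n <- length(correct_flags)
  if (n < 1) stop("empty input")
  if (B < 1) stop("B must be >= 1")
  flags <- as.numeric(correct_flags)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  means <- colMeans(matrix(sample(flags, n * B, replace = TRUE), n, B))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
}

#' Per-chapter prevalence and error rate
#'
#' For every chapter observed among the gold codes: its prevalence (gold
#' count / n) and the misprediction rate within the chapter. Chapters of the
#' vocabulary never observed as gold UCD are listed in the
#' `"unobserved_chapters"` attribute.
#'
#' @param preds,golds Aligned code vectors.
#' @param vocab A `ucd_vocabulary` supplying the chapter map.
#' @return data.frame with columns `chapter`, `n`, `prevalence`, `errors`,
#'   `error_rate`.
#' @export
per_chapter_report <- function(preds, golds, vocab) {
  if (length(preds) != length(golds)) stop("preds and golds differ in length")
  if (length(golds) == 0) stop("empty input")
  gch <- chapter_of(golds, vocab)
  err <- preds != golds
  tab <- tapply(err, gch, function(x) c(n = length(x), errors = sum(x)))
  chapters <- names(tab)
  n_ch <- vapply(tab, `[[`, 0, "n")
  e_ch <- vapply(tab, `[[`, 0, "errors")
  out <- data.frame(
    chapter = chapters,
    n = as.integer(n_ch),
    prevalence = n_ch / length(golds),
    errors = as.integer(e_ch),
    error_rate = e_ch / n_ch,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "unobserved_chapters") <-
    setdiff(unique(unname(vocab$chapters)), chapters)
  out
}

#' Chapter-level confusion matrix of mispredictions
#'
#' Restricted to errors: cell `(true chapter, predicted chapter)` counts
#' mispredictions. With zero errors the matrix is empty (0 x 0).
#'
#' @inheritParams per_chapter_report
#' @return Integer matrix, rows = true chapter, columns = predicted chapter.
#' @export
chapter_confusion_on_errors <- function(preds, golds, vocab) {
  if (length(preds) != length(golds)) stop("preds and golds differ in length")
  err <- which(preds != golds)
  if (length(err) == 0) return(matrix(0L, 0, 0))
  tch <- chapter_of(golds[err], vocab)
  pch <- chapter_of(preds[err], vocab)
  lev <- sort(unique(c(tch, pch)))
  as.matrix(table(factor(tch, levels = lev), factor(pch, levels = lev)))
}

# rank of the gold code in each distribution row, under the coder's
# deterministic tie-break (ties resolved toward the lower vocabulary index)
gold_rank <- function(distributions, gold_idx) {
  n <- nrow(distributions)
  pg <- distributions[(gold_idx - 1L) * n + seq_len(n)]
  higher <- rowSums(distributions > pg)
  ties_before <- rowSums(distributions == pg &
                           col(distributions) < gold_idx)
  higher + ties_before + 1L
}

#' Top-k accuracy
#'
#' Fraction of cases whose gold code is among the `k` most probable codes of
#' the model's output distribution (same tie-break as [predict_topk()]).
#'
#' @param distributions `n x V` probability matrix (rows = certificates,
#'   columns ordered like `vocab$codes`).
#' @param golds Gold codes, length n.
#' @param vocab The vocabulary.
#' @param k `1 <= k <= V`.
#' @return Fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(distributions, golds, vocab, k) {
  if (k < 1 || k > vocab$V) stop("k must be in 1..V")
  gi <- unname(vocab$index[golds])
  if (anyNA(gi)) stop("gold code(s) outside the vocabulary")
  mean(gold_rank(distributions, gi) <= k)
}

#' Second-choice accuracy on mispredicted cases
#'
#' Among the certificates the model mispredicts, the fraction whose
#' second-most-probable code is the gold code. Undefined (returns `NA` with
#' a warning) when there are no errors. Satisfies the exact identity
#' `top2 = accuracy + (1 - accuracy) * second_choice_on_errors` whenever
#' `preds` is the argmax of `distributions`.
#'
#' @inheritParams topk_accuracy
#' @param preds Argmax predictions aligned with `distributions`.
#' @return Fraction, or `NA` if there are no errors.
#' @export
second_choice_accuracy_on_errors <- function(distributions, preds, golds,
                                             vocab) {
  err <- which(preds != golds)
  if (length(err) == 0) {
    warning("no mispredicted cases: second-choice accuracy is undefined")
    return(NA_real_)
  }
  gi <- unname(vocab$index[golds[err]])
  mean(gold_rank(distributions[err, , drop = FALSE], gi) == 2L)
}

#' Confidence calibration report
#'
#' The confidence of a prediction is the probability weight of the argmax.
#' Confidences are histogrammed separately for correct and incorrect
#' predictions (the bar-plot surface of a calibration figure), with group
#' mean confidences attached.
#'
#' @inheritParams second_choice_accuracy_on_errors
#' @param n_bins Number of equal-width bins on `[0, 1]` (default 10).
#' @return List with `bins` (data.frame `bin`, `lower`, `upper`,
#'   `count_correct`, `count_incorrect`), `mean_confidence_correct`,
#'   `mean_confidence_incorrect`.
#' @export
calibration_report <- function(distributions, preds, golds, n_bins = 10L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  conf <- apply(distributions, 1, max)
  correct <- preds == golds
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(conf, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  cc <- tabulate(bin[correct], nbins = n_bins)
  ci <- tabulate(bin[!correct], nbins = n_bins)
  list(
    bins = data.frame(
      bin = seq_len(n_bins), lower = edges[-length(edges)], upper = edges[-1],
      count_correct = cc, count_incorrect = ci
    ),
    mean_confidence_correct = if (any(correct)) mean(conf[correct]) else NA_real_,
    mean_confidence_incorrect = if (any(!correct)) mean(conf[!correct]) else NA_real_
  )
}

#' Reject-aware baseline comparison
#'
#' A rule-based coder with a reject option is scored twice: overall accuracy
#' counts rejects as errors (the lower measurement), nonrejected accuracy
#' excludes them (the improved estimate). The statistical coder's accuracy
#' on the identical certificates is reported alongside.
#'
#' @param model_preds Model argmax predictions.
#' @param baseline_results List of [oracle_code()] results (same
#'   certificates, same order).
#' @param golds Gold codes.
#' @return Object of class `ucd_baseline_comparison`: list with
#'   `overall_accuracy`, `nonrejected_accuracy`, `reject_fraction`,
#'   `model_accuracy`, `n`.
#' @export
compare_with_baseline <- function(model_preds, baseline_results, golds) {
  n <- length(golds)
  if (length(model_preds) != n || length(baseline_results) != n) {
    stop("inputs are not aligned")
  }
  rej <- vapply(baseline_results, `[[`, TRUE, "rejected")
  bp <- vapply(baseline_results, `[[`, "", "ucd")
  overall <- mean(!rej & !is.na(bp) & bp == golds)
  nonrej <- if (any(!rej)) mean(bp[!rej] == golds[!rej]) else NA_real_
  structure(
    list(
      overall_accuracy = overall,
      nonrejected_accuracy = nonrej,
      reject_fraction = mean(rej),
      model_accuracy = mean(model_preds == golds),
      n = n
    ),
    class = "ucd_baseline_comparison"
  )
}

#' @export
print.ucd_baseline_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<baseline comparison, n=%d>\n",
           "  baseline overall (rejects = errors): %.4f\n",
           "  baseline on nonrejected certificates: %.4f (reject fraction %.3f)\n",
           "  model accuracy on the same set:       %.4f\n"),
    x$n, x$overall_accuracy, x$nonrejected_accuracy, x$reject_fraction,
    x$model_accuracy))
  invisible(x)
}

#' Full evaluation report for a trained coder
#'
#' Computes the complete metric surface on a labeled test set: accuracy with
#' a percentile-bootstrap 95% CI, per-chapter prevalence/error table,
#' chapter confusion of errors, top-k accuracies, second-choice accuracy on
#' errors, and the confidence calibration histogram.
#'
#' @param coder Trained `ucd_coder`.
#' @param test_certs Labeled certificates.
#' @param vocab The vocabulary.
#' @param B,level Bootstrap settings (1000 replicates, 0.95).
#' @param k Integer vector of top-k values (default `c(1, 2)`).
#' @param n_bins Calibration bins (10).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `ucd_eval_report`.
#' @export
evaluate_coder <- function(coder, test_certs, vocab, B = 1000L, level = 0.95,
                           k = c(1L, 2L), n_bins = 10L, seed = 1L) {
  golds <- vapply(test_certs, `[[`, "", "gold_ucd")
  if (anyNA(golds)) stop("test certificates must carry a gold UCD")
  distributions <- predict_proba_batch(coder, test_certs, vocab)
  preds <- vocab$codes[max.col(distributions, ties.method = "first")]
  acc <- accuracy(preds, golds)
  topk <- stats::setNames(
    vapply(k, function(kk) topk_accuracy(distributions, golds, vocab, kk), 0),
    paste0("top", k))
  sc <- if (acc < 1) {
    second_choice_accuracy_on_errors(distributions, preds, golds, vocab)
  } else NA_real_
  structure(
    list(
      n = length(golds),
      accuracy = acc,
      ci95 = bootstrap_ci(as.numeric(preds == golds), B = B, level = level,
                          seed = seed),
      per_chapter = per_chapter_report(preds, golds, vocab),
      chapter_confusion = chapter_confusion_on_errors(preds, golds, vocab),
      topk = topk,
      second_choice_on_errors = sc,
      calibration = calibration_report(distributions, preds, golds, n_bins),
      preds = preds, golds = golds
    ),
    class = "ucd_eval_report"
  )
}

#' @export
print.ucd_eval_report <- function(x, ...) {
  cat(sprintf("<ucd_eval_report> n=%d\n", x$n))
  cat(sprintf("  accuracy: %.4f (95%% CI %.4f-%.4f)\n", x$accuracy,
              x$ci95[1], x$ci95[2]))
  for (nm in names(x$topk)) cat(sprintf("  %s: %.4f\n", nm, x$topk[nm]))
  if (!is.na(x$second_choice_on_errors)) {
    cat(sprintf("  second choice on errors: %.4f\n", x$second_choice_on_errors))
  }
  cat(sprintf("  mean confidence correct/incorrect: %.3f / %.3f\n",
              x$calibration$mean_confidence_correct,
              x$calibration$mean_confidence_incorrect))
  cat(sprintf("  chapters observed: %d\n", nrow(x$per_chapter)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `ucd_eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "ucd_eval_report"))
  out <- list(
    n = report$n, accuracy = report$accuracy,
    ci95 = list(lo = report$ci95[1], hi = report$ci95[2]),
    topk = as.list(report$topk),
    second_choice_on_errors = report$second_choice_on_errors,
    per_chapter = report$per_chapter,
    chapter_confusion = if (length(report$chapter_confusion)) {
      as.data.frame.table(report$chapter_confusion,
                          responseName = "count",
                          stringsAsFactors = FALSE)
    } else list(),
    calibration = report$calibration
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
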