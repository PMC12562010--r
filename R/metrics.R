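## ---------------------------------------------------------------------------
## Confusion-matrix statistics and inference on balanced accuracy
## ---------------------------------------------------------------------------

#' Confusion matrix from predictions
#'
#' @param predicted 0/1 predicted classes (or probabilities, thresholded
#'   upstream).
#' @param labels 0/1 true labels.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_matrix <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  c(TP = sum(predicted == 1L & labels == 1L),
    FP = sum(predicted == 1L & labels == 0L),
    TN = sum(predicted == 0L & labels == 0L),
    FN = sum(predicted == 0L & labels == 1L))
}

#' Classification rates from a confusion matrix
#'
#' sens = TP/(TP+FN), spec = TN/(TN+FP), ppv = TP/(TP+FP), npv = TN/(TN+FN),
#' balanced accuracy = (sens+spec)/2. Rates with a zero denominator are
#' reported as `NA` (undefined), never coerced to 0.
#'
#' @param cm Named vector with entries `TP`, `FP`, `TN`, `FN` (all >= 0).
#' @return Named numeric vector
#'   `c(sensitivity, specificity, ppv, npv, balanced_accuracy)`.
#' @export
rates <- function(cm) {
  cm <- cm[c("TP", "FP", "TN", "FN")]
  stopifnot(all(!is.na(cm)), all(cm >= 0))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(cm[["TP"]], cm[["TP"]] + cm[["FN"]])
  spec <- div(cm[["TN"]], cm[["TN"]] + cm[["FP"]])
  c(sensitivity = sens,
    specificity = spec,
    ppv = div(cm[["TP"]], cm[["TP"]] + cm[["FP"]]),
    npv = div(cm[["TN"]], cm[["TN"]] + cm[["FN"]]),
    balanced_accuracy = (sens + spec) / 2)
}

# round half away from zero (base round() is half-to-even)
.round_half_up <- function(x) floor(x + 0.5)

#' Exact binomial test on an adjusted success count
#'
#' Tests above-chance performance: the observed success count is
#' `round(balanced_accuracy * n_test)` (half away from zero) and the p-value
#' is the one-sided upper tail `P[X >= successes]` for
#' `X ~ Binomial(n_test, 0.5)`.
#'
#' @param balanced_accuracy Value in \[0, 1\].
#' @param n_test Number of test cases (>= 1).
#' @return The p-value.
#' @export
binomial_pvalue <- function(balanced_accuracy, n_test) {
  n_test <- as.integer(n_test)
  if (is.na(n_test) || n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  stopifnot(balanced_accuracy >= 0, balanced_accuracy <= 1)
  successes <- .round_half_up(balanced_accuracy * n_test)
  stats::pbinom(successes - 1L, n_test, 0.5, lower.tail = FALSE)
}

#' Wilson score confidence interval
#'
#' @param successes Number of successes in `[0, n]` (the pipeline passes the
#'   balanced-accuracy-adjusted count `round(balanced_accuracy * n)`).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`, both in \[0, 1\] and
#'   bracketing `successes/n`.
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries the exact bound is 0 (or 1); avoid floating residue
  low <- if (successes == 0) 0 else max(0, centre - half)
  high <- if (successes == n) 1 else min(1, centre + half)
  c(low = low, high = high)
}

#' Percentile bootstrap CI for balanced accuracy
#'
#' Resamples (prediction, label) pairs with replacement and takes percentile
#' bounds of the resampled balanced accuracies. Resamples that lose a class
#' entirely (undefined balanced accuracy) are dropped.
#'
#' @param predicted 0/1 predictions.
#' @param labels 0/1 labels (both classes must be present).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer RNG seed (local to this call).
#' @param confidence Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(predicted, labels, n_boot = 1000L, seed = 1L,
                         confidence = 0.95) {
  stopifnot(length(predicted) == length(labels), n_boot >= 100L)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("balanced accuracy undefined: labels contain a single class",
         call. = FALSE)
  }
  n <- length(labels)
  stats_boot <- numeric(0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- labels[idx]
    if (length(unique(lb)) < 2L) next
    r <- rates(confusion_matrix(predicted[idx], lb))
    stats_boot <- c(stats_boot, r[["balanced_accuracy"]])
  }
  alpha <- 1 - confidence
  q <- stats::quantile(stats_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(low = q[1L], high = q[2L])
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Full evaluation report for thresholded pair predictions
#'
#' @param probabilities Predicted pathogenicity probabilities.
#' @param labels 0/1 labels.
#' @param threshold Classification threshold on the sigmoid output.
#' @param bootstrap Also compute a bootstrap CI (slower).
#' @param seed Seed for the bootstrap.
#' @return Object of class `patho_eval`: confusion matrix, rates, adjusted
#'   success count, Wilson CI, binomial p-value, and optionally the
#'   bootstrap CI.
#' @export
eval_report <- function(probabilities, labels, threshold = 0.5,
                        bootstrap = FALSE, seed = 1L) {
  if (!length(labels)) stop("empty pair list", call. = FALSE)
  predicted <- as.integer(probabilities >= threshold)
  cm <- confusion_matrix(predicted, labels)
  r <- rates(cm)
  n <- length(labels)
  ba <- r[["balanced_accuracy"]]
  successes <- .round_half_up(ba * n)
  out <- list(confusion = cm, rates = r, n_test = n,
              threshold = threshold, successes = successes,
              wilson = wilson_ci(successes, n),
              p_value = binomial_pvalue(ba, n))
  if (bootstrap) {
    out$bootstrap <- bootstrap_ci(predicted, labels, seed = seed)
  }
  class(out) <- "patho_eval"
  out
}

#' @export
print.patho_eval <- function(x, digits = 3, ...) {
  cat("Variant-disease pair evaluation (n =", x$n_test, ")\n")
  cat("  confusion: TP", x$confusion[["TP"]], " FP", x$confusion[["FP"]],
      " TN", x$confusion[["TN"]], " FN", x$confusion[["FN"]], "\n")
  r <- round(x$rates, digits)
  cat("  balanced accuracy:", r[["balanced_accuracy"]],
      " (95% Wilson CI ", round(x$wilson[["low"]], digits), "-",
      round(x$wilson[["high"]], digits), ")\n", sep = "")
  cat("  sensitivity:", r[["sensitivity"]], " specificity:",
      r[["specificity"]], " PPV:", r[["ppv"]], " NPV:", r[["npv"]], "\n")
  cat("  binomial p-value (vs 0.5):", format(x$p_value, digits = digits),
      "\n")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report A `patho_eval` object.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "patho_eval"))
  out <- list(
    confusion = as.list(report$confusion),
    balanced_accuracy = report$rates[["balanced_accuracy"]],
    sensitivity = report$rates[["sensitivity"]],
    specificity = report$rates[["specificity"]],
    ppv = report$rates[["ppv"]],
    npv = report$rates[["npv"]],
    n_test = report$n_test,
    threshold = report$threshold,
    ci_low = report$wilson[["low"]],
    ci_high = report$wilson[["high"]],
    p_value = report$p_value
  )
  if (!is.null(report$bootstrap)) {
    out$bootstrap_low <- report$bootstrap[["low"]]
    out$bootstrap_high <- report$bootstrap[["high"]]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
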