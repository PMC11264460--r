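#' Exact-match accuracy between two score vectors
#'
#' 100 x (number of correctly classified assessments) / (total assessments).
#'
#' @param pred,ref Integer score vectors of equal length.
#' @return Percent in [0, 100].
#' @export
score_accuracy <- function(pred, ref) {
  check_pair(pred, ref)
  100 * mean(pred == ref)
}

#' Mean square error between two score vectors
#'
#' @inheritParams score_accuracy
#' @return Mean of squared score differences.
#' @export
score_mse <- function(pred, ref) {
  check_pair(pred, ref)
  mean((ref - pred)^2)
}

#' Tally of absolute score differences
#'
#' Histogram of `|pred - ref|` over the possible differences 0-4; the counts
#' sum to the number of trials, and the count at 0 recovers the accuracy.
#'
#' @inheritParams score_accuracy
#' @return Tibble with columns `abs_diff` (0-4) and `n`.
#' @export
diff_tally <- function(pred, ref) {
  check_pair(pred, ref)
  d <- abs(pred - ref)
  tibble::tibble(abs_diff = 0:4,
                 n = vapply(0:4, function(k) sum(d == k), integer(1)))
}

check_pair <- function(pred, ref) {
  if (length(pred) != length(ref)) abort("pred and ref differ in length")
  if (length(pred) < 1L) abort("empty score vectors")
  invisible(NULL)
}

#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal ratings with quadratic weights
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2`, so disagreements are penalized by
#' squared category distance. The standard error is a seeded nonparametric
#' bootstrap over trials by default; the large-sample asymptotic formula
#' (Fleiss, Cohen & Everitt) is available as an alternative.
#'
#' @param r1,r2 Integer score vectors of equal length (>= 2).
#' @param categories The full ordinal category set, default `0:4`; the
#'   weight matrix is built over all of it even when some categories are
#'   unobserved.
#' @param se_method `"bootstrap"` (default) or `"asymptotic"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return Tibble with `kappa`, `se`, `n` and a logical `degenerate` flag
#'   (`TRUE`, with `kappa = NA`, when both raters use a single identical
#'   category so chance agreement is total and kappa is undefined).
#' @export
quadratic_weighted_kappa <- function(r1, r2, categories = 0:4,
                                     se_method = c("bootstrap", "asymptotic"),
                                     n_boot = 2000, seed = 1) {
  se_method <- match.arg(se_method)
  check_pair(r1, r2)
  if (length(r1) < 2L) abort("need at least 2 paired ratings")
  if (!all(r1 %in% categories) || !all(r2 %in% categories)) {
    abort("ratings outside the declared category set")
  }
  k <- qwk_stat(r1, r2, categories)
  if (is.na(k)) {
    return(tibble::tibble(kappa = NA_real_, se = NA_real_,
                          n = length(r1), degenerate = TRUE))
  }
  se <- if (se_method == "bootstrap") {
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(r1), replace = TRUE)
        qwk_stat(r1[idx], r2[idx], categories)
      }, numeric(1))
    })
    sd(boots, na.rm = TRUE)
  } else {
    qwk_asymptotic_se(r1, r2, categories)
  }
  tibble::tibble(kappa = k, se = se, n = length(r1), degenerate = FALSE)
}

qwk_weights <- function(categories) {
  k <- length(categories)
  i <- seq_len(k)
  1 - outer(i, i, function(a, b) (a - b)^2) / (k - 1)^2
}

qwk_confusion <- function(r1, r2, categories) {
  table(factor(r1, levels = categories), factor(r2, levels = categories))
}

qwk_stat <- function(r1, r2, categories) {
  O <- qwk_confusion(r1, r2, categories) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  W <- qwk_weights(categories)
  po <- sum(W * O)
  pe <- sum(W * E)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Large-sample SE for weighted kappa (Fleiss, Cohen & Everitt 1969).
qwk_asymptotic_se <- function(r1, r2, categories) {
  n <- length(r1)
  O <- qwk_confusion(r1, r2, categories) / n
  pi_ <- rowSums(O)
  pj_ <- colSums(O)
  W <- qwk_weights(categories)
  po <- sum(W * O)
  pe <- sum(W * outer(pi_, pj_))
  wbar_i <- as.vector(W %*% pj_)
  wbar_j <- as.vector(t(W) %*% pi_)
  term <- outer(wbar_i, wbar_j, `+`)
  num <- sum(O * (W * (1 - pe) - term * (1 - po))^2) -
    (po * pe - 2 * pe + po)^2
  sqrt(num / (n * (1 - pe)^4))
}

#' Prediction bias test
#'
#' One-sample t-test of the signed differences `pred - ref` against zero, to
#' detect a tendency to over- or under-predict: a negative mean difference
#' means under-prediction. Cohen's d is `mean(diff) / sd(diff)`; when the
#' differences are constant (sd = 0) d is reported as 0 with a flag.
#'
#' @inheritParams score_accuracy
#' @return Tibble with `mean_diff`, `t`, `df`, `p_value`, `cohens_d`,
#'   `degenerate`.
#' @export
bias_test <- function(pred, ref) {
  check_pair(pred, ref)
  if (length(pred) < 2L) abort("need at least 2 trials")
  d <- pred - ref
  if (sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), t = 0, df = length(d) - 1,
                          p_value = 1, cohens_d = 0, degenerate = TRUE))
  }
  tt <- t.test(d, mu = 0)
  tibble::tibble(mean_diff = mean(d),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 cohens_d = mean(d) / sd(d),
                 degenerate = FALSE)
}

#' One-way ANOVA across networks' difference scores
#'
#' Classic fixed-effects one-way ANOVA on the signed score differences,
#' grouped by network, testing whether the networks' prediction errors
#' differ in mean.
#'
#' @param diffs Data frame with numeric `diff` and a grouping column
#'   `network`.
#' @return Tibble with `F`, `df1`, `df2`, `p_value`.
#' @export
networks_anova <- function(diffs) {
  stopifnot(all(c("diff", "network") %in% names(diffs)))
  g <- factor(diffs$network)
  if (nlevels(g) < 2L) abort("need at least 2 networks")
  if (any(table(g) < 2L)) abort("each network needs at least 2 trials")
  fit <- oneway.test(diff ~ network, data = diffs, var.equal = TRUE)
  tibble::tibble(F = unname(fit$statistic),
                 df1 = unname(fit$parameter[1]),
                 df2 = unname(fit$parameter[2]),
                 p_value = fit$p.value)
}

#' Binarize ordinal scores into impaired / unimpaired
#'
#' A score of 2 or greater (moderate or higher impairment) maps to
#' `"impaired"`; 0 or 1 to `"unimpaired"`.
#'
#' @param scores Integer scores 0-4.
#' @return Factor with levels `impaired`, `unimpaired`.
#' @export
binarize <- function(scores) {
  stopifnot(all(scores %in% 0:4))
  factor(ifelse(scores >= 2, "impaired", "unimpaired"),
         levels = c("impaired", "unimpaired"))
}

#' Build a 2x2 contingency table from binarized scores
#'
#' "Positive" is impaired: TP counts trials called impaired by both
#' prediction and reference.
#'
#' @inheritParams score_accuracy
#' @return Tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
contingency_table <- function(pred, ref) {
  check_pair(pred, ref)
  bp <- binarize(pred) == "impaired"
  br <- binarize(ref) == "impaired"
  tibble::tibble(TP = sum(bp & br), FP = sum(bp & !br),
                 FN = sum(!bp & br), TN = sum(!bp & !br))
}

#' Contingency metrics: recall, precision, accuracy, F1
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Zero-denominator
#' cases are returned as `NA` with the `undefined` flag set.
#'
#' @param ct One-row data frame with counts `TP`, `FP`, `FN`, `TN` (e.g.
#'   from [contingency_table()]), or a numeric vector with those names.
#' @return Tibble with `recall`, `precision`, `accuracy`, `f1` (proportions
#'   in [0, 1]) and logical `undefined`.
#' @export
#' @examples
#' contingency_metrics(c(TP = 49, FP = 7, FN = 6, TN = 18))
contingency_metrics <- function(ct) {
  if (is.numeric(ct)) ct <- as.list(ct)
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(ct)))
  tp <- ct$TP; fp <- ct$FP; fn <- ct$FN; tn <- ct$TN
  total <- tp + fp + fn + tn
  if (total <= 0) abort("empty contingency table")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  accuracy <- (tp + tn) / total
  f1 <- if (!is.na(recall) && !is.na(precision) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(recall = recall, precision = precision,
                 accuracy = accuracy, f1 = f1,
                 undefined = anyNA(c(recall, precision, f1)))
}

#' Full agreement report for one prediction set
#'
#' Bundles the whole evaluation battery for a prediction vector against a
#' reference score vector: exact accuracy, MSE, the absolute-difference
#' tally, quadratic weighted kappa with standard error, the prediction-bias
#' t-test, and the binary impaired/unimpaired contingency metrics.
#'
#' @param predictions Data frame with integer columns `predicted` and a
#'   reference score column (default `median_score`).
#' @param ref_col Name of the reference column.
#' @param n_boot,seed Passed to [quadratic_weighted_kappa()].
#' @return Object of class `agreement_report` (a list of tibbles).
#' @export
agreement_report <- function(predictions, ref_col = "median_score",
                             n_boot = 2000, seed = 1) {
  stopifnot(all(c("predicted", ref_col) %in% names(predictions)))
  pred <- predictions$predicted
  ref <- predictions[[ref_col]]
  structure(
    list(
      n = length(pred),
      accuracy = score_accuracy(pred, ref),
      mse = score_mse(pred, ref),
      diff_tally = diff_tally(pred, ref),
      kappa = quadratic_weighted_kappa(pred, ref, n_boot = n_boot,
                                       seed = seed),
      bias = bias_test(pred, ref),
      contingency = contingency_table(pred, ref),
      metrics = contingency_metrics(contingency_table(pred, ref))
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  accuracy: %.1f%%   MSE: %.2f\n", x$accuracy, x$mse))
  cat(sprintf("  quadratic weighted kappa: %.2f +/- %.2f\n",
              x$kappa$kappa, x$kappa$se))
  cat(sprintf("  bias: mean diff %+.3f (t = %.2f, p = %.3f, d = %.3f)\n",
              x$bias$mean_diff, x$bias$t, x$bias$p_value, x$bias$cohens_d))
  m <- x$metrics
  cat(sprintf("  binary: recall %.0f%%, precision %.0f%%, accuracy %.0f%%, F1 %.2f\n",
              100 * m$recall, 100 * m$precision, 100 * m$accuracy, m$f1))
  invisible(x)
}

#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy_pct", "mse", "kappa", "kappa_se", "bias_mean_diff",
               "bias_t", "bias_p", "cohens_d", "recall", "precision",
               "binary_accuracy", "f1"),
    value = c(x$accuracy, x$mse, x$kappa$kappa, x$kappa$se,
              x$bias$mean_diff, x$bias$t, x$bias$p_value, x$bias$cohens_d,
              x$metrics$recall, x$metrics$precision, x$metrics$accuracy,
              x$metrics$f1)
  )
}

#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, mse = x$mse,
                 kappa = x$kappa$kappa, f1 = x$metrics$f1)
}
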