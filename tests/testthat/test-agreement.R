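test_that("accuracy, MSE and difference tally follow their formulas", {
  expect_equal(score_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(score_accuracy(c(1, 2), c(1, 3)), 50)
  expect_equal(score_mse(c(2), c(2)), 0)
  expect_equal(score_mse(c(0), c(2)), 4)
  expect_equal(diff_tally(rep(2, 7), rep(2, 7))$n, c(7, 0, 0, 0, 0))
  expect_equal(diff_tally(c(0, 4), c(4, 4))$n, c(1, 0, 0, 0, 1))
  expect_error(score_accuracy(1:3, 1:4), "length")
})

test_that("accuracy, MSE and tally match counting oracles on random vectors", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    pred <- sample(0:4, n, replace = TRUE)
    ref <- sample(0:4, n, replace = TRUE)
    expect_equal(score_accuracy(pred, ref),
                 100 * sum(pred == ref) / n)
    expect_equal(score_mse(pred, ref), sum((ref - pred)^2) / n)
    tal <- diff_tally(pred, ref)
    expect_equal(sum(tal$n), n)
    expect_equal(tal$n,
                 vapply(0:4, function(k) sum(abs(pred - ref) == k),
                        integer(1)))
    # invariant: accuracy equals 100 * tally[0] / n
    expect_equal(score_accuracy(pred, ref), 100 * tal$n[1] / n)
  }
})

# independent kappa oracle: explicit double loop over category pairs
qwk_oracle <- function(r1, r2, cats = 0:4) {
  k <- length(cats)
  w <- function(i, j) 1 - (i - j)^2 / (k - 1)^2
  n <- length(r1)
  po <- mean(mapply(function(a, b) w(match(a, cats), match(b, cats)),
                    r1, r2))
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pe <- pe + mean(r1 == cats[i]) * mean(r2 == cats[j]) * w(i, j)
    }
  }
  (po - pe) / (1 - pe)
}

test_that("quadratic weighted kappa is 1 for identical ratings", {
  r <- c(0, 1, 2, 3, 4, 2, 1)
  out <- quadratic_weighted_kappa(r, r, n_boot = 50, seed = 1)
  expect_equal(out$kappa, 1)
  expect_false(out$degenerate)
})

test_that("kappa equals the brute-force confusion-matrix oracle", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    r1 <- sample(0:4, n, replace = TRUE)
    r2 <- sample(0:4, n, replace = TRUE)
    expected <- qwk_oracle(r1, r2)
    got <- quadratic_weighted_kappa(r1, r2, n_boot = 2, seed = 1)
    if (!is.finite(expected)) {
      expect_true(got$degenerate)
    } else {
      expect_equal(got$kappa, expected, tolerance = 1e-12)
    }
  }
})

test_that("kappa is near zero for independent ratings", {
  set.seed(8)
  r1 <- sample(0:4, 400, replace = TRUE)
  r2 <- sample(0:4, 400, replace = TRUE)
  out <- quadratic_weighted_kappa(r1, r2, n_boot = 500, seed = 3)
  expect_lt(abs(out$kappa), 3 * out$se)
})

test_that("kappa flags the single-category degenerate case", {
  out <- quadratic_weighted_kappa(rep(2, 10), rep(2, 10), n_boot = 10)
  expect_true(out$degenerate)
  expect_true(is.na(out$kappa))
})

test_that("asymptotic kappa SE is finite and comparable to the bootstrap", {
  set.seed(12)
  r1 <- pmin(4, pmax(0, round(rnorm(200, 2, 1))))
  r2 <- pmin(4, pmax(0, round(r1 + rnorm(200, 0, 0.8))))
  boot <- quadratic_weighted_kappa(r1, r2, n_boot = 2000, seed = 4)
  asym <- quadratic_weighted_kappa(r1, r2, se_method = "asymptotic")
  expect_equal(asym$kappa, boot$kappa)
  expect_gt(asym$se, 0)
  expect_lt(abs(asym$se - boot$se) / boot$se, 0.5)
})

test_that("bias test matches its formula and handles degeneracy", {
  out <- bias_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(out$degenerate)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$cohens_d, 0)

  # diffs (-1,-1,-1,0): d and t by hand
  d <- c(-1, -1, -1, 0)
  out2 <- bias_test(c(0, 1, 2, 4), c(1, 2, 3, 4))
  expect_equal(out2$mean_diff, mean(d))
  expect_equal(out2$cohens_d, mean(d) / sd(d))
  expect_equal(out2$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_lt(out2$mean_diff, 0) # under-prediction is negative
})

test_that("one-way ANOVA across networks matches a hand-worked example", {
  d <- tibble::tibble(
    diff = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    network = rep(c("a", "b", "c"), each = 3)
  )
  out <- networks_anova(d)
  # grand mean 3; SSB = 6 on 2 df, SSW = 6 on 6 df -> F = 3
  expect_equal(out$F, 3)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 6)
  expect_equal(out$p_value, stats::pf(3, 2, 6, lower.tail = FALSE))

  same <- tibble::tibble(diff = rep(c(1, 2, 3), 2),
                         network = rep(c("a", "b"), each = 3))
  expect_equal(networks_anova(same)$F, 0)
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(55)
  reject <- mean(replicate(200, {
    d <- tibble::tibble(diff = rnorm(80),
                        network = rep(c("a", "b", "c", "d"), each = 20))
    networks_anova(d)$p_value < 0.05
  }))
  expect_gt(reject, 0.005)
  expect_lt(reject, 0.125)
})

test_that("binarization uses the score >= 2 boundary", {
  expect_equal(as.character(binarize(c(0, 1, 2, 3, 4))),
               c("unimpaired", "unimpaired", "impaired", "impaired",
                 "impaired"))
})

test_that("contingency metrics reproduce hand-checkable tables", {
  m <- contingency_metrics(c(TP = 10, FP = 0, FN = 0, TN = 0))
  expect_equal(unlist(m[c("recall", "precision", "accuracy", "f1")]),
               c(recall = 1, precision = 1, accuracy = 1, f1 = 1))

  z <- contingency_metrics(c(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(z$recall, 0)
  expect_true(is.na(z$precision))
  expect_equal(z$accuracy, 0.5)
  expect_true(z$undefined)
})

test_that("contingency metrics agree with recomputation from raw vectors", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    pred <- sample(0:4, n, replace = TRUE)
    ref <- sample(0:4, n, replace = TRUE)
    ct <- contingency_table(pred, ref)
    m <- contingency_metrics(ct)
    bp <- pred >= 2
    br <- ref >= 2
    expect_equal(ct$TP + ct$FP + ct$FN + ct$TN, n)
    if (sum(br) > 0) expect_equal(m$recall, sum(bp & br) / sum(br))
    if (sum(bp) > 0) expect_equal(m$precision, sum(bp & br) / sum(bp))
    expect_equal(m$accuracy, mean(bp == br))
  }
})

test_that("agreement_report bundles the battery coherently", {
  set.seed(17)
  ref <- sample(0:4, 120, replace = TRUE)
  pred <- pmin(4, pmax(0, ref + sample(c(-1, 0, 0, 1), 120, replace = TRUE)))
  rep_ <- agreement_report(tibble::tibble(predicted = pred,
                                          median_score = ref),
                           n_boot = 200, seed = 2)
  expect_equal(rep_$accuracy, 100 * rep_$diff_tally$n[1] / rep_$n)
  expect_lte(rep_$kappa$kappa, 1)
  td <- tidy(rep_)
  expect_true(all(c("accuracy_pct", "kappa", "f1") %in% td$metric))
})
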