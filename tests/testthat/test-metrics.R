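# Concordance metrics against from-definition oracles.

test_that("precision/recall/F1 match a brute-force count oracle on random matrices", {
  set.seed(42)
  for (rep in 1:30) {
    cm <- matrix(rpois(25, 4), 5, 5)
    for (g in 1:5) {
      got <- suppressWarnings(precision_recall_f1(cm, g))
      tp <- cm[g, g]
      fp <- 0; fn <- 0
      for (i in 1:5) for (j in 1:5) {
        if (j == g && i != g) fp <- fp + cm[i, j]
        if (i == g && j != g) fn <- fn + cm[i, j]
      }
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(as.numeric(got), c(prec, rec, f1), tolerance = 1e-12)
    }
  }
})

test_that("diagonal confusion matrix gives perfect per-grade scores", {
  cm <- diag(c(3, 5, 2, 7, 1))
  for (g in 1:5) {
    expect_equal(as.numeric(precision_recall_f1(cm, g)), c(1, 1, 1))
  }
})

test_that("a grade absent from predictions yields 0 precision with a flag", {
  cm <- confusion_matrix(c(1, 2, 2, 3), c(1, 3, 3, 3))
  expect_warning(res <- precision_recall_f1(cm, 2), "empty denominator")
  expect_equal(res[["precision"]], 0)
  expect_true(attr(res, "flag"))
})

test_that("quadratic kappa matches a from-definition double-loop oracle", {
  kappa_oracle <- function(cm) {
    k <- nrow(cm); n <- sum(cm)
    num <- 0; den <- 0
    for (i in 1:k) for (j in 1:k) {
      w <- (i - j)^2 / (k - 1)^2
      e <- sum(cm[i, ]) * sum(cm[, j]) / n
      num <- num + w * cm[i, j]
      den <- den + w * e
    }
    1 - num / den
  }
  toy <- matrix(c(5, 2, 0, 1, 7, 3, 0, 2, 6), 3, 3, byrow = TRUE)
  expect_equal(quadratic_kappa(toy), kappa_oracle(toy), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:50) {
    cm <- matrix(rpois(25, 3), 5, 5)
    if (sum(cm) == 0) next
    expect_equal(quadratic_kappa(cm), kappa_oracle(cm), tolerance = 1e-12)
  }
})

test_that("quadratic kappa has its textbook fixed points and bounds", {
  expect_equal(quadratic_kappa(diag(c(4, 6, 2, 9, 3))), 1)
  # observed = outer product of marginals -> chance agreement, kappa 0
  r <- c(10, 20, 30); s <- c(15, 25, 20)
  O <- outer(r, s) / sum(r)
  expect_equal(quadratic_kappa(O), 0, tolerance = 1e-12)
  # symmetric matrix: transposition invariance; range check on random input
  set.seed(1)
  for (rep in 1:20) {
    cm <- matrix(rpois(25, 3), 5, 5)
    cm_s <- cm + t(cm)
    expect_equal(quadratic_kappa(cm_s), quadratic_kappa(t(cm_s)),
                 tolerance = 1e-12)
    if (sum(cm) > 0) {
      k <- quadratic_kappa(cm)
      expect_gte(k, -1); expect_lte(k, 1)
    }
  }
  expect_equal(quadratic_kappa(matrix(c(7, 0, 0, 0), 2, 2)), 1)
  expect_error(quadratic_kappa(matrix(c(0, 7, 0, 0), 2, 2)), "degenerate")
})

test_that("accuracy always equals trace over total of the confusion matrix", {
  set.seed(5)
  for (rep in 1:20) {
    ref <- sample(1:5, 40, replace = TRUE)
    cmp <- sample(1:5, 40, replace = TRUE)
    cm <- confusion_matrix(ref, cmp)
    expect_equal(sum(diag(cm)) / sum(cm), mean(ref == cmp))
  }
})

test_that("bootstrap interval is seeded, degenerate on constants, and widens with level", {
  df <- data.frame(x = c(rep(1, 5), rep(0, 5)))
  const <- bootstrap_ci(df, function(d) 1, n_boot = 100, seed = 3)
  expect_equal(unname(const[1]), unname(const[2]))
  ci_a <- bootstrap_ci(df, function(d) mean(d$x), n_boot = 500, seed = 9)
  ci_b <- bootstrap_ci(df, function(d) mean(d$x), n_boot = 500, seed = 9)
  expect_identical(ci_a, ci_b)
  widths <- sapply(c(0.90, 0.95, 0.99), function(lv) {
    ci <- bootstrap_ci(df, function(d) mean(d$x), n_boot = 500,
                       level = lv, seed = 11)
    ci[2] - ci[1]
  })
  expect_true(all(diff(widths) >= 0))
})

test_that("bootstrap interval contains the point estimate in almost all seeded trials", {
  set.seed(20)
  hits <- 0L
  n_trials <- 200
  for (t in seq_len(n_trials)) {
    df <- data.frame(x = rnorm(25))
    ci <- bootstrap_ci(df, function(d) mean(d$x), n_boot = 300, seed = t)
    pt <- attr(ci, "point")
    if (pt >= ci[1] && pt <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.99)
})

test_that("bootstrap redraws resamples on which the statistic is undefined", {
  df <- data.frame(x = c(1, 1, 1, 2))
  stat <- function(d) {
    if (all(d$x == 1)) stop("undefined")
    mean(d$x)
  }
  ci <- bootstrap_ci(df, stat, n_boot = 50, seed = 2)
  expect_true(all(is.finite(ci)))
  expect_gte(attr(ci, "n_redrawn"), 1L)
})

test_that("upgrading/downgrading rates follow the clinical direction convention", {
  all_eq <- upgrade_downgrade(c(1, 3, 5), c(1, 3, 5))
  expect_equal(all_eq$upgrade_rate, 0)
  expect_equal(all_eq$downgrade_rate, 0)
  # reference 2 vs compared {1,3,2,2}: one under-call, one over-call
  ud <- upgrade_downgrade(c(2, 2, 2, 2), c(1, 3, 2, 2))
  expect_equal(ud$upgrade_rate, 0.25)
  expect_equal(ud$downgrade_rate, 0.25)
  expect_equal(ud$concordance_rate, 0.5)
  # rates recomputed from the shift matrix agree with the direct computation
  set.seed(8)
  ref <- sample(1:5, 60, replace = TRUE)
  cmp <- sample(1:5, 60, replace = TRUE)
  ud <- upgrade_downgrade(ref, cmp)
  sm <- ud$shift_matrix
  up_from_sm <- sum(sm[lower.tri(sm)]) / sum(sm)   # compared < reference
  down_from_sm <- sum(sm[upper.tri(sm)]) / sum(sm)
  expect_equal(ud$upgrade_rate, up_from_sm)
  expect_equal(ud$downgrade_rate, down_from_sm)
  expect_equal(ud$upgrade_rate + ud$downgrade_rate + ud$concordance_rate, 1,
               tolerance = 1e-9)
})

test_that("chi-square matches the textbook sum and degenerates on exact independence", {
  set.seed(13)
  for (rep in 1:30) {
    tab <- matrix(rpois(12, 8) + 1, 3, 4)
    res <- contingency_test(tab, method = "chi2")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  }
  indep <- outer(c(10, 20), c(30, 70)) / 100 * 10   # exact outer product
  res <- contingency_test(indep, method = "chi2")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
})

test_that("auto mode switches to Fisher when expected counts are small", {
  tab <- matrix(c(1, 9, 2, 3), 2, 2)   # min expected count 2 < 5
  res <- contingency_test(tab, method = "auto")
  expect_equal(res$method, "fisher")
  expect_equal(res$p.value, fisher.test(tab)$p.value)
  big <- matrix(c(30, 40, 50, 60), 2, 2)
  expect_equal(contingency_test(big, method = "auto")$method, "chi2")
})

test_that("zero-margin rows are dropped with a warning", {
  tab <- rbind(c(10, 20), c(0, 0), c(30, 5))
  expect_warning(res <- contingency_test(tab, method = "chi2"), "zero-margin")
  expect_equal(res$statistic,
               contingency_test(tab[c(1, 3), ], method = "chi2")$statistic)
})

test_that("rank AUC equals the all-pairs brute-force count", {
  auc_brute <- function(score, positive) {
    pos <- score[positive]; neg <- score[!positive]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- 50
    probs <- matrix(rexp(5 * n), n, 5)
    probs <- probs / rowSums(probs)
    ref <- sample(1:5, n, replace = TRUE)
    got <- grouped_auc(probs, ref)
    for (split in names(got)) {
      neg <- switch(split, low = 1, medium = 1:2, high = 1:3)
      pos_cls <- setdiff(1:5, neg)
      score <- rowSums(probs[, pos_cls, drop = FALSE])
      want <- auc_brute(score, ref %in% pos_cls)
      expect_equal(unname(got[[split]]), want, tolerance = 1e-9)
    }
  }
})

test_that("grouped AUC is 1 under perfect separation and ~0.5 under shuffled labels", {
  ref <- c(rep(1, 10), rep(4, 10))
  probs <- matrix(0, 20, 5)
  probs[1:10, 1] <- 1
  probs[11:20, 4] <- 1
  expect_equal(unname(grouped_auc(probs, ref)), c(1, 1, 1))
  # shuffled labels: AUC within 3 SE of 0.5 at n = 2000
  set.seed(77)
  n <- 2000
  probs <- matrix(rexp(5 * n), n, 5); probs <- probs / rowSums(probs)
  ref <- sample(1:5, n, replace = TRUE)
  a <- grouped_auc(probs, ref)
  for (split in names(a)) {
    neg <- switch(split, low = 1, medium = 1:2, high = 1:3)
    n1 <- sum(ref %in% setdiff(1:5, neg)); n0 <- n - n1
    se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
    expect_lt(abs(a[[split]] - 0.5), 3 * se)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  probs <- matrix(rexp(5 * 80), 80, 5); probs <- probs / rowSums(probs)
  ref <- sample(1:5, 80, replace = TRUE)
  got <- grouped_auc(probs, ref)
  score <- rowSums(probs[, 2:5])
  roc <- pROC::roc(response = factor(ref > 1, c(FALSE, TRUE)),
                   predictor = score, direction = "<", quiet = TRUE)
  expect_equal(unname(got[["low"]]), as.numeric(pROC::auc(roc)),
               tolerance = 1e-12)
})

test_that("concordance report is internally consistent", {
  set.seed(17)
  ref <- sample(1:5, 50, replace = TRUE)
  cmp <- pmin(5, pmax(1, ref + sample(-1:1, 50, replace = TRUE)))
  rep_ <- suppressWarnings(concordance_report(ref, cmp, n_boot = 100, seed = 4))
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion))
  expect_equal(rep_$upgrade_rate + rep_$downgrade_rate + rep_$concordance_rate,
               1, tolerance = 1e-9)
  expect_equal(rep_$kappa, quadratic_kappa(rep_$confusion))
  expect_output(print(rep_), "quadratic kappa")
})
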