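# Concordance evaluation: accuracy, quadratic-weighted kappa, per-grade
# precision/recall/F1 with bootstrap CIs, upgrading/downgrading decomposition,
# contingency-table tests and grouped ROC/AUC.

#' Build a 5x5 (or KxK) confusion matrix
#'
#' Rows index the reference grade (surgical pathology, GG-RP) and columns the
#' compared grade (biopsy GG-NB or model GG-Pre).
#'
#' @param reference integer grades 1..K.
#' @param compared integer grades 1..K.
#' @param k number of grade categories (default 5).
#' @return integer KxK matrix of counts.
#' @export
confusion_matrix <- function(reference, compared, k = 5L) {
  stop_if_not(length(reference) == length(compared),
              "reference and compared must have equal length")
  stop_if_not(all(reference %in% seq_len(k)) && all(compared %in% seq_len(k)),
              "grades must lie in 1..%d", k)
  cm <- table(factor(reference, levels = seq_len(k)),
              factor(compared, levels = seq_len(k)))
  m <- matrix(as.integer(cm), k, k,
              dimnames = list(reference = seq_len(k), compared = seq_len(k)))
  m
}

#' One-vs-rest precision, recall and F1 for a grade
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean, all
#' computed from a confusion matrix whose rows are the reference grade. An
#' empty denominator yields 0 with attribute `flag = TRUE` and a warning.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param grade grade category (column/row index).
#' @return named numeric vector (precision, recall, f1); attribute `flag` is
#'   TRUE when any denominator was empty.
#' @export
precision_recall_f1 <- function(cm, grade) {
  stop_if_not(grade >= 1 && grade <= nrow(cm), "grade out of range")
  tp <- cm[grade, grade]
  fp <- sum(cm[, grade]) - tp
  fn <- sum(cm[grade, ]) - tp
  flag <- FALSE
  div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("empty denominator for %s at grade %d; reporting 0",
                      what, grade), call. = FALSE)
      flag <<- TRUE
      0
    } else num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    if (!flag) { } # both defined but zero: F1 is 0 without a flag
    0
  } else 2 * precision * recall / (precision + recall)
  structure(c(precision = precision, recall = recall, f1 = f1), flag = flag)
}

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected agreement with weights `w_ij = (i-j)^2 / (K-1)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` is the observed matrix
#' and `E` the outer product of its marginals (scaled to the total).
#'
#' @param cm square confusion matrix of counts.
#' @return kappa in \[-1, 1\]. A matrix with all mass in one diagonal cell
#'   returns 1; all mass in one off-diagonal cell is an error (kappa
#'   undefined: no marginal variance).
#' @export
quadratic_kappa <- function(cm) {
  k <- nrow(cm)
  stop_if_not(k == ncol(cm), "confusion matrix must be square")
  n <- sum(cm)
  stop_if_not(n >= 1, "confusion matrix must contain at least one count")
  i <- matrix(seq_len(k), k, k)
  w <- (i - t(i))^2 / (k - 1)^2
  E <- outer(rowSums(cm), colSums(cm)) / n
  if (any(cm == n)) {
    # zero-variance marginals: all mass in one cell
    if (sum(diag(cm)) == n) return(1)
    stop("kappa undefined: degenerate marginals with off-diagonal mass",
         call. = FALSE)
  }
  denom <- sum(w * E)
  if (denom == 0) return(1)   # all mass on the diagonal of one category pair
  1 - sum(w * cm) / denom
}

#' Percentile bootstrap confidence interval at the patient level
#'
#' Resamples patients (rows) with replacement and returns the percentile
#' interval of `statistic` over `n_boot` resamples. A resample on which the
#' statistic is undefined (errors or returns NA) is redrawn; the number of
#' redraws is recorded in attribute `n_redrawn`.
#'
#' @param data data.frame (or matrix) with one row per patient.
#' @param statistic function of a data subset returning a scalar.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric `c(lo, hi)` with attributes `point` and `n_redrawn`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  n <- nrow(data)
  stop_if_not(!is.null(n) && n >= 2, "need at least 2 patients")
  point <- statistic(data)
  stats_b <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
        if (length(val) == 1 && is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 50L * n_boot)
          stop("statistic undefined on almost every resample", call. = FALSE)
      }
      stats_b[b] <- val
    }
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_b, c(alpha, 1 - alpha), type = 7))
  structure(ci, point = point, n_redrawn = n_redrawn)
}

#' Upgrading/downgrading decomposition
#'
#' In clinical usage "upgrading" means the reference (surgical) grade exceeds
#' the compared (biopsy or predicted) grade — the earlier assessment
#' under-called the tumor; "downgrading" is the reverse.
#'
#' @param reference integer grades 1..5 (GG-RP).
#' @param compared integer grades 1..5 (GG-NB or GG-Pre).
#' @return list with `upgrade_rate`, `downgrade_rate`, `concordance_rate`
#'   (summing to 1) and `shift_matrix`, the 5x5 reference-by-compared count
#'   matrix.
#' @export
upgrade_downgrade <- function(reference, compared) {
  stop_if_not(all(reference %in% 1:5) && all(compared %in% 1:5),
              "grades must lie in 1..5")
  n <- length(reference)
  list(
    upgrade_rate = sum(compared < reference) / n,
    downgrade_rate = sum(compared > reference) / n,
    concordance_rate = sum(compared == reference) / n,
    shift_matrix = confusion_matrix(reference, compared)
  )
}

#' Contingency-table test (Pearson chi-square or Fisher)
#'
#' Pearson chi-square without continuity correction by default; `"auto"`
#' switches to Fisher's exact test when any expected count falls below 5.
#' Fisher on tables larger than 2x2 uses a seeded Monte-Carlo p-value when
#' exact enumeration fails. Rows or columns with zero margin are dropped
#' with a warning.
#'
#' @param table matrix of nonnegative integer counts, at least 2x2.
#' @param method `"chi2"`, `"fisher"` or `"auto"`.
#' @param seed seed for the Monte-Carlo Fisher fallback.
#' @return list with `statistic` (NA for Fisher), `p.value`, `method` and
#'   `expected` (chi-square only).
#' @export
contingency_test <- function(table, method = c("chi2", "fisher", "auto"),
                             seed = 1L) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stop_if_not(all(table >= 0) && all(table == round(table)),
              "counts must be nonnegative integers")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    table <- table[!zr, !zc, drop = FALSE]
  }
  stop_if_not(nrow(table) >= 2 && ncol(table) >= 2,
              "need at least a 2x2 table after dropping empty margins")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "chi2") {
    res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(res$statistic), p.value = res$p.value,
         method = "chi2", expected = expected)
  } else {
    res <- tryCatch(
      stats::fisher.test(table),
      error = function(e) with_seed(seed,
        stats::fisher.test(table, simulate.p.value = TRUE, B = 1e5)))
    list(statistic = NA_real_, p.value = res$p.value, method = "fisher",
         expected = expected)
  }
}

# midrank-based AUC (Mann-Whitney); ties get midranks.
.rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grouped one-vs-rest ROC AUC over grade splits
#'
#' For each split the binary score is the summed class probability on the
#' positive side: low grade (1 vs 2-5), medium (1-2 vs 3-5), high
#' (1-3 vs 4-5). AUC is the Mann-Whitney rank statistic with midranks for
#' ties. A split with a single class present is reported as NA.
#'
#' @param probs n x 5 matrix of per-patient class probabilities.
#' @param reference integer grades 1..5.
#' @return named numeric vector `c(low, medium, high)`.
#' @export
grouped_auc <- function(probs, reference) {
  probs <- as.matrix(probs)
  stop_if_not(ncol(probs) == 5, "probs must have 5 columns")
  stop_if_not(nrow(probs) == length(reference),
              "probs rows must match reference length")
  splits <- list(low = 1L, medium = 1:2, high = 1:3)
  out <- vapply(splits, function(neg) {
    pos <- setdiff(1:5, neg)
    score <- rowSums(probs[, pos, drop = FALSE])
    positive <- reference %in% pos
    .rank_auc(score, positive)
  }, 0)
  out
}

#' Full concordance report between reference and compared grades
#'
#' Aggregates overall accuracy, quadratic-weighted kappa, per-grade
#' precision/recall/F1 (each with a patient-level percentile bootstrap CI),
#' the upgrading/downgrading decomposition and, when probabilities are
#' supplied, grouped AUCs.
#'
#' @param reference integer grades 1..5 (GG-RP).
#' @param compared integer grades 1..5 (GG-NB or GG-Pre).
#' @param probs optional n x 5 probability matrix for grouped AUC.
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `concordance_report`.
#' @export
concordance_report <- function(reference, compared, probs = NULL,
                               n_boot = 1000, level = 0.95, seed = 1L) {
  df <- data.frame(reference = reference, compared = compared)
  cm <- confusion_matrix(reference, compared)
  acc <- sum(diag(cm)) / sum(cm)
  acc_ci <- bootstrap_ci(df, function(d) mean(d$reference == d$compared),
                         n_boot, level, derive_seed(seed, 1))
  kap <- quadratic_kappa(cm)
  kap_ci <- bootstrap_ci(df, function(d)
    quadratic_kappa(confusion_matrix(d$reference, d$compared)),
    n_boot, level, derive_seed(seed, 2))
  per_grade <- lapply(1:5, function(g) {
    prf <- suppressWarnings(precision_recall_f1(cm, g))
    ci <- suppressWarnings(bootstrap_ci(df, function(d)
      precision_recall_f1(confusion_matrix(d$reference, d$compared), g)[["f1"]],
      n_boot, level, derive_seed(seed, 2 + g)))
    c(prf, f1_lo = ci[[1]], f1_hi = ci[[2]])
  })
  ud <- upgrade_downgrade(reference, compared)
  aucs <- if (!is.null(probs)) grouped_auc(probs, reference) else NULL
  structure(list(
    confusion = cm,
    accuracy = acc, accuracy_ci = as.numeric(acc_ci),
    kappa = kap, kappa_ci = as.numeric(kap_ci),
    per_grade = do.call(rbind, per_grade),
    upgrade_rate = ud$upgrade_rate,
    downgrade_rate = ud$downgrade_rate,
    concordance_rate = ud$concordance_rate,
    shift_matrix = ud$shift_matrix,
    auc = aucs,
    n = length(reference), n_boot = n_boot, level = level
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, digits = 3, ...) {
  cat(sprintf("Concordance report (n = %d)\n", x$n))
  cat(sprintf("  accuracy: %.*f  [%.*f, %.*f]\n", digits, x$accuracy,
              digits, x$accuracy_ci[1], digits, x$accuracy_ci[2]))
  cat(sprintf("  quadratic kappa: %.*f  [%.*f, %.*f]\n", digits, x$kappa,
              digits, x$kappa_ci[1], digits, x$kappa_ci[2]))
  cat(sprintf("  upgrading: %.1f%%   downgrading: %.1f%%   concordant: %.1f%%\n",
              100 * x$upgrade_rate, 100 * x$downgrade_rate,
              100 * x$concordance_rate))
  cat("  per-grade precision/recall/F1:\n")
  pg <- round(x$per_grade, digits)
  rownames(pg) <- paste0("  GG", 1:5)
  print(pg)
  if (!is.null(x$auc)) {
    cat("  grouped AUC: ",
        paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  print(object, ...)
  cat("  confusion matrix (rows = reference GG-RP):\n")
  print(object$confusion)
  invisible(object)
}
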