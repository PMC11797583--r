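# Diagnostic accuracy of an integer risk score against a binary gold
# standard. Positivity convention throughout: score >= cutoff is
# test-positive. Confidence intervals: Wilson score for proportions, Simel
# log-transform for likelihood ratios, Hanley-McNeil for the AUC.

AUC_BANDS <- c("not_useful", "poor", "sufficient", "good", "very_good", "excellent")

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (length(scores) == 0L) stop("no observations", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must not contain missing values", call. = FALSE)
  }
  if (!any(labels)) stop("no positive (dysglycemic) labels present", call. = FALSE)
  if (all(labels)) stop("no negative (non-dysglycemic) labels present", call. = FALSE)
  labels
}

#' Confusion table of a score cutoff against the gold standard
#'
#' Dichotomizes scores at `score >= cutoff` and cross-tabulates against the
#' binary outcome.
#'
#' @param scores numeric vector of risk-score totals.
#' @param labels logical vector; `TRUE` = gold-standard positive (dysglycemic).
#' @param cutoff positivity threshold (score >= cutoff is test-positive).
#' @return An object of class `dr_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn` and the cutoff.
#' @examples
#' confusion_at_cutoff(c(10, 13, 14, 9), c(FALSE, TRUE, TRUE, FALSE), 13)
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- check_scores_labels(scores, labels)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  pos <- scores >= cutoff
  structure(list(
    tp = sum(pos & labels), fp = sum(pos & !labels),
    fn = sum(!pos & labels), tn = sum(!pos & !labels),
    cutoff = cutoff
  ), class = "dr_confusion")
}

#' @export
print.dr_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              outcome = c("dysglycemic", "non-dysglycemic")))
  cat("Cutoff >=", x$cutoff, "\n")
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return Numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Sensitivity, specificity and predictive values with Wilson intervals
#'
#' Computes Se = tp/(tp+fn), Sp = tn/(tn+fp), PPV = tp/(tp+fp),
#' NPV = tn/(tn+fn) from a confusion table, each with a Wilson score interval
#' at level `1 - alpha`. A metric whose denominator is zero is returned as
#' `NA` and flagged in the `undefined` column rather than propagating NaN.
#'
#' @param table a [confusion_at_cutoff()] object.
#' @param alpha significance level (default 0.05 for 95% intervals).
#' @return data.frame with one row per metric: `metric`, `estimate`, `lower`,
#'   `upper`, `undefined`.
#' @export
diagnostic_metrics <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "dr_confusion"), alpha > 0, alpha < 1)
  defs <- list(se = c(table$tp, table$tp + table$fn),
               sp = c(table$tn, table$tn + table$fp),
               ppv = c(table$tp, table$tp + table$fp),
               npv = c(table$tn, table$tn + table$fn))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0L) {
      data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, undefined = TRUE)
    } else {
      ci <- wilson_ci(x, n, conf = 1 - alpha)
      data.frame(metric = m, estimate = ci[["estimate"]],
                 lower = ci[["lower"]], upper = ci[["upper"]],
                 undefined = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Likelihood ratios of a confusion table with log-method intervals
#'
#' LR+ = Se/(1-Sp), LR- = (1-Se)/Sp, with `1 - alpha` confidence intervals on
#' the log scale (Simel et al.). When the table is perfectly specific
#' (fp = 0), LR+ is reported as infinite with a one-sided interval whose lower
#' bound uses a 0.5 continuity correction.
#'
#' @inheritParams diagnostic_metrics
#' @return List with `lr_pos` and `lr_neg`, each `c(estimate, lower, upper)`.
#' @examples
#' tab <- confusion_at_cutoff(c(10, 13, 14, 9, 12), c(F, T, T, F, F), 13)
#' likelihood_ratios(tab)
#' @export
likelihood_ratios <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "dr_confusion"), alpha > 0, alpha < 1)
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n1 <- tp + fn; n0 <- fp + tn
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes are required for likelihood ratios", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  lr_ci <- function(a, b, n_a, n_b) {
    # LR = (a/n_a) / (b/n_b); log-scale SE sqrt(1/a - 1/n_a + 1/b - 1/n_b)
    lr <- (a / n_a) / (b / n_b)
    se <- sqrt(1 / a - 1 / n_a + 1 / b - 1 / n_b)
    c(estimate = lr, lower = exp(log(lr) - z * se), upper = exp(log(lr) + z * se))
  }
  lr_pos <- if (fp == 0L) {
    low <- lr_ci(tp, 0.5, n1, n0)[["lower"]]
    c(estimate = Inf, lower = low, upper = Inf)
  } else if (tp == 0L) {
    c(estimate = 0, lower = 0, upper = lr_ci(0.5, fp, n1, n0)[["upper"]])
  } else {
    lr_ci(tp, fp, n1, n0)
  }
  lr_neg <- if (tn == 0L) {
    stop("specificity is zero; LR- undefined", call. = FALSE)
  } else if (fn == 0L) {
    c(estimate = 0, lower = 0, upper = lr_ci(0.5, tn, n1, n0)[["upper"]])
  } else {
    lr_ci(fn, tn, n1, n0)
  }
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Empirical ROC curve of an integer score
#'
#' Sweeps the positivity threshold over all distinct observed scores plus a
#' `+Inf` sentinel (descending), computing one (FPR, TPR) point per threshold
#' via [confusion_at_cutoff()] semantics. The curve runs from (0, 0) to
#' (1, 1) and is monotone non-decreasing in both coordinates.
#'
#' @inheritParams confusion_at_cutoff
#' @return An object of class `dr_roc`: data.frame `(threshold, tpr, fpr)`
#'   with attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  s <- scores
  l <- labels
  tpr <- vapply(thr, function(t) if (t == Inf) 0 else sum(l[s >= t]) / n_pos, 0)
  fpr <- vapply(thr, function(t) if (t == Inf) 0 else sum(!l[s >= t]) / n_neg, 0)
  structure(
    data.frame(threshold = thr, tpr = tpr, fpr = fpr),
    n_pos = n_pos, n_neg = n_neg,
    class = c("dr_roc", "data.frame")
  )
}

#' @export
plot.dr_roc <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    plot(c(0, 1), c(0, 1), type = "n", xlab = "1 - specificity",
         ylab = "Sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  }
  graphics::lines(x$fpr, x$tpr, col = col, lwd = 2)
  invisible(x)
}

auc_band <- function(auc) {
  # bands closed on the left: [0.9, 1] excellent ... [0.5, 0.6) poor, < 0.5 not useful
  idx <- findInterval(auc, c(0.5, 0.6, 0.7, 0.8, 0.9)) + 1L
  factor(AUC_BANDS[idx], levels = AUC_BANDS)
}

#' Area under the ROC curve with Hanley-McNeil interval
#'
#' Trapezoidal area under the empirical curve; numerically identical to the
#' pairwise-comparison statistic P(case score > control score) +
#' 0.5 P(tie). The standard error is Hanley & McNeil's, and the area is
#' banded per the conventional scheme (0.9--1.0 excellent, 0.8--0.9 very
#' good, 0.7--0.8 good, 0.6--0.7 sufficient, 0.5--0.6 poor, <0.5 not useful;
#' bands closed on the left).
#'
#' @param roc a [roc_curve()] object, or raw scores (with `labels`).
#' @param labels optional; when `roc` is a numeric score vector, the logical
#'   gold-standard labels.
#' @param alpha significance level for the `1 - alpha` interval.
#' @return An object of class `dr_auc`: list with `auc`, `se`, `lower`,
#'   `upper`, `band`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(roc, labels = NULL, alpha = 0.05) {
  if (!inherits(roc, "dr_roc")) roc <- roc_curve(roc, labels)
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]; y <- roc$tpr[ord]
  a <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  n1 <- attr(roc, "n_pos"); n0 <- attr(roc, "n_neg")
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    auc = a, se = se,
    lower = max(0, a - z * se), upper = min(1, a + z * se),
    band = auc_band(a), n_pos = n1, n_neg = n0, conf = 1 - alpha
  ), class = "dr_auc")
}

#' @export
print.dr_auc <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (%.0f%% CI %.*f-%.*f), %s\n", digits, x$auc,
              100 * x$conf, digits, x$lower, digits, x$upper,
              as.character(x$band)))
  invisible(x)
}

#' Full accuracy report across integer cutoffs
#'
#' One row per cutoff with the confusion counts, Se/Sp/PPV/NPV (Wilson
#' intervals), LR+/LR- (log-method intervals) and the Youden index
#' `se + sp - 1`; the scale's AUC is attached as an attribute (it does not
#' depend on the cutoff).
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs integer cutoffs to sweep (default 11--16).
#' @param alpha significance level.
#' @return data.frame of class `dr_accuracy`, attribute `auc` a [roc_auc()]
#'   object.
#' @export
accuracy_table <- function(scores, labels, cutoffs = 11:16, alpha = 0.05) {
  labels <- check_scores_labels(scores, labels)
  rows <- lapply(cutoffs, function(k) {
    tab <- confusion_at_cutoff(scores, labels, k)
    m <- diagnostic_metrics(tab, alpha)
    lr <- likelihood_ratios(tab, alpha)
    est <- stats::setNames(m$estimate, m$metric)
    lo <- stats::setNames(m$lower, m$metric)
    hi <- stats::setNames(m$upper, m$metric)
    data.frame(
      cutoff = k, tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
      se = est[["se"]], se_lo = lo[["se"]], se_hi = hi[["se"]],
      sp = est[["sp"]], sp_lo = lo[["sp"]], sp_hi = hi[["sp"]],
      ppv = est[["ppv"]], ppv_lo = lo[["ppv"]], ppv_hi = hi[["ppv"]],
      npv = est[["npv"]], npv_lo = lo[["npv"]], npv_hi = hi[["npv"]],
      lr_pos = lr$lr_pos[["estimate"]], lr_pos_lo = lr$lr_pos[["lower"]],
      lr_pos_hi = lr$lr_pos[["upper"]],
      lr_neg = lr$lr_neg[["estimate"]], lr_neg_lo = lr$lr_neg[["lower"]],
      lr_neg_hi = lr$lr_neg[["upper"]],
      youden = est[["se"]] + est[["sp"]] - 1
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "auc") <- roc_auc(roc_curve(scores, labels), alpha = alpha)
  class(out) <- c("dr_accuracy", "data.frame")
  out
}

#' Optimal screening cutoff
#'
#' `"youden"` maximizes Se + Sp - 1 over all integer cutoffs in the observed
#' score range; `"lr_constrained"` restricts candidates to cutoffs that are
#' clinically useful by the likelihood-ratio convention (LR+ > 2 and
#' LR- < 0.5) before maximizing the Youden index, falling back to the plain
#' Youden rule (with a warning and `fallback = TRUE`) when no cutoff
#' qualifies. Ties are broken toward the lower cutoff, favouring sensitivity
#' in a screening setting.
#'
#' @inheritParams confusion_at_cutoff
#' @param method `"youden"` or `"lr_constrained"`.
#' @param alpha significance level for the per-cutoff report.
#' @return An object of class `dr_cutoff`: list with `cutoff`, `method`,
#'   `fallback`, `report` (the [accuracy_table()] row at the chosen cutoff)
#'   and `auc`.
#' @export
optimal_cutoff <- function(scores, labels, method = c("youden", "lr_constrained"),
                           alpha = 0.05) {
  method <- match.arg(method)
  labels <- check_scores_labels(scores, labels)
  if (length(unique(scores)) < 2L) {
    stop("all scores are identical; no cutoff can discriminate", call. = FALSE)
  }
  cand <- seq(floor(min(scores)) + 1L, ceiling(max(scores)))
  tab <- accuracy_table(scores, labels, cutoffs = cand, alpha = alpha)
  fallback <- FALSE
  pool <- tab
  if (method == "lr_constrained") {
    ok <- !is.na(tab$lr_pos) & tab$lr_pos > 2 & !is.na(tab$lr_neg) & tab$lr_neg < 0.5
    if (!any(ok)) {
      warning("no cutoff satisfies LR+ > 2 and LR- < 0.5; ",
              "falling back to the Youden rule", call. = FALSE)
      fallback <- TRUE
    } else {
      pool <- tab[ok, , drop = FALSE]
    }
  }
  best <- pool[which.max(pool$youden), , drop = FALSE]  # which.max -> first = lowest cutoff
  structure(list(
    cutoff = best$cutoff, method = method, fallback = fallback,
    report = best, auc = attr(tab, "auc")
  ), class = "dr_cutoff")
}

#' @export
print.dr_cutoff <- function(x, ...) {
  cat(sprintf("Optimal cutoff >= %d (%s%s): Se %.1f%%, Sp %.1f%%, Youden %.3f\n",
              x$cutoff, x$method, if (x$fallback) ", youden fallback" else "",
              100 * x$report$se, 100 * x$report$sp, x$report$youden))
  print(x$auc)
  invisible(x)
}
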