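# Confusion tables, accuracy metrics, likelihood ratios, ROC/AUC and
# optimal-cutoff selection.

test_that("confusion tables count the score >= cutoff convention", {
  tab <- confusion_at_cutoff(c(10, 13, 14, 9), c(FALSE, TRUE, TRUE, FALSE), 13)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(2L, 0L, 0L, 2L))
  # a score exactly at the cutoff is test-positive
  tab2 <- confusion_at_cutoff(c(13, 13), c(TRUE, FALSE), 13)
  expect_equal(c(tab2$tp, tab2$fp, tab2$fn, tab2$tn), c(1L, 1L, 0L, 0L))
})

test_that("confusion counts equal an exhaustive per-element loop", {
  set.seed(20)
  for (rep in 1:5) {
    scores <- sample(0:26, 20, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(labels) || all(labels)) next
    k <- sample(5:20, 1)
    tab <- confusion_at_cutoff(scores, labels, k)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(scores)) {
      pos <- scores[i] >= k
      if (pos && labels[i]) tp <- tp + 1L
      if (pos && !labels[i]) fp <- fp + 1L
      if (!pos && labels[i]) fn <- fn + 1L
      if (!pos && !labels[i]) tn <- tn + 1L
    }
    expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(tp, fp, fn, tn))
    expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 20L)
  }
})

test_that("degenerate label sets are rejected with the class named", {
  expect_error(confusion_at_cutoff(integer(0), logical(0), 13), "no observations")
  expect_error(confusion_at_cutoff(1:3, c(TRUE, TRUE, TRUE), 2), "negative")
  expect_error(confusion_at_cutoff(1:3, c(FALSE, FALSE, FALSE), 2), "positive")
})

test_that("metrics reproduce the reconstructed 2x2 of a published cutoff row", {
  # tp/fn/tn/fp reconstructed from Se 63.6 / Sp 84.3 with 1289 dysglycemic
  # and 2448 non-dysglycemic participants
  tab <- structure(list(tp = 820, fp = 384, fn = 469, tn = 2064, cutoff = 13),
                   class = "dr_confusion")
  m <- diagnostic_metrics(tab)
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["se"]], 0.636, tolerance = 0.001 / 0.636)
  expect_equal(est[["sp"]], 0.843, tolerance = 0.001 / 0.843)
  expect_equal(est[["ppv"]], 820 / 1204)
  expect_equal(est[["npv"]], 2064 / 2533)
  # Wilson interval for Se is near the printed 61.1-66.1
  se_row <- m[m$metric == "se", ]
  expect_equal(se_row$lower, 0.610, tolerance = 0.005)
  expect_equal(se_row$upper, 0.662, tolerance = 0.005)
})

test_that("Wilson intervals agree with the score-test oracle", {
  cases <- list(c(8, 10), c(50, 100), c(820, 1289), c(0, 20), c(20, 20))
  for (cs in cases) {
    ours <- wilson_ci(cs[1], cs[2])
    if (cs[1] %in% c(0, cs[2])) {
      # closed-form endpoints at the boundary
      expect_true(ours[["lower"]] >= 0 && ours[["upper"]] <= 1)
      next
    }
    oracle <- stats::prop.test(cs[1], cs[2], correct = FALSE)$conf.int
    expect_equal(unname(ours[["lower"]]), oracle[1], tolerance = 1e-10)
    expect_equal(unname(ours[["upper"]]), oracle[2], tolerance = 1e-10)
  }
})

test_that("a perfect table yields unit metrics; zero denominators are flagged", {
  perfect <- confusion_at_cutoff(c(rep(20, 50), rep(5, 50)),
                                 rep(c(TRUE, FALSE), each = 50), 13)
  m <- diagnostic_metrics(perfect)
  expect_equal(m$estimate, rep(1, 4))
  # cutoff below every score: nobody tests negative, NPV undefined
  allpos <- confusion_at_cutoff(c(5, 6, 7), c(TRUE, FALSE, TRUE), 0)
  m2 <- diagnostic_metrics(allpos)
  expect_true(m2$undefined[m2$metric == "npv"])
  expect_true(is.na(m2$estimate[m2$metric == "npv"]))
  expect_false(anyNA(m2$estimate[m2$metric != "npv"]))
})

test_that("likelihood ratios match their defining identities", {
  set.seed(31)
  scores <- sample(0:26, 400, replace = TRUE)
  labels <- runif(400) < plogis((scores - 12) / 4)
  for (k in c(8, 11, 13, 16)) {
    tab <- confusion_at_cutoff(scores, labels, k)
    m <- diagnostic_metrics(tab)
    est <- setNames(m$estimate, m$metric)
    lr <- likelihood_ratios(tab)
    expect_equal(lr$lr_pos[["estimate"]] * (1 - est[["sp"]]), est[["se"]],
                 tolerance = 1e-12)
    expect_equal(lr$lr_neg[["estimate"]] * est[["sp"]], 1 - est[["se"]],
                 tolerance = 1e-12)
    expect_true(lr$lr_pos[["lower"]] < lr$lr_pos[["estimate"]])
    expect_true(lr$lr_pos[["upper"]] > lr$lr_pos[["estimate"]])
  }
  # an uninformative test has both ratios equal to 1
  se_sp_half <- structure(list(tp = 25, fp = 25, fn = 25, tn = 25, cutoff = 1),
                          class = "dr_confusion")
  lr <- likelihood_ratios(se_sp_half)
  expect_equal(lr$lr_pos[["estimate"]], 1)
  expect_equal(lr$lr_neg[["estimate"]], 1)
})

test_that("perfect specificity reports an infinite LR+ with one-sided CI", {
  tab <- structure(list(tp = 10, fp = 0, fn = 5, tn = 20, cutoff = 13),
                   class = "dr_confusion")
  lr <- likelihood_ratios(tab)
  expect_identical(lr$lr_pos[["estimate"]], Inf)
  expect_identical(lr$lr_pos[["upper"]], Inf)
  expect_true(is.finite(lr$lr_pos[["lower"]]) && lr$lr_pos[["lower"]] > 0)
})

test_that("the ROC curve has the sentinel endpoints and is monotone", {
  set.seed(8)
  scores <- sample(0:26, 300, replace = TRUE)
  labels <- runif(300) < plogis((scores - 13) / 3)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(nrow(roc), length(unique(scores)) + 1L)
})

test_that("AUC handles the canonical worked examples", {
  # perfect separation
  a <- roc_auc(c(rep(20, 10), rep(5, 10)), rep(c(TRUE, FALSE), each = 10))
  expect_equal(a$auc, 1.0)
  expect_equal(as.character(a$band), "excellent")
  # fully ordered scores
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  # one discordant pair out of four
  expect_equal(roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 0.75)
})

test_that("labels independent of scores give a chance-level AUC", {
  set.seed(14)
  scores <- sample(0:26, 1e4, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), 1e4, replace = TRUE)
  expect_equal(roc_auc(scores, labels)$auc, 0.5, tolerance = 0.02 / 0.5)
})

test_that("trapezoid AUC equals the pairwise statistic and the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(0:26, n, replace = TRUE)
    labels <- runif(n) < plogis((scores - sample(8:16, 1)) / 3)
    if (!any(labels) || all(labels)) next
    a <- roc_auc(scores, labels)$auc
    expect_equal(a, pairwise_auc(scores, labels), tolerance = 1e-12)
    oracle <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                             predictor = scores,
                                             quiet = TRUE, direction = "<")))
    expect_equal(a, oracle, tolerance = 1e-10)
  }
})

test_that("AUC bands are closed on the left", {
  bands <- vapply(c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55, 0.5, 0.45),
                  function(a) as.character(cubdrisc:::auc_band(a)), "")
  expect_equal(bands, c("excellent", "excellent", "very_good", "very_good",
                        "good", "good", "sufficient", "sufficient",
                        "poor", "poor", "not_useful"))
  expect_equal(as.character(roc_auc(c(1, 3, 2, 4),
                                    c(FALSE, FALSE, TRUE, TRUE))$band), "good")
})

test_that("metrics are invariant to record order", {
  set.seed(23)
  scores <- sample(0:26, 500, replace = TRUE)
  labels <- runif(500) < plogis((scores - 12) / 4)
  perm <- sample(500)
  t1 <- accuracy_table(scores, labels)
  t2 <- accuracy_table(scores[perm], labels[perm])
  a1 <- attr(t1, "auc"); a2 <- attr(t2, "auc")
  attr(t1, "auc") <- attr(t2, "auc") <- NULL
  expect_equal(t1, t2)
  expect_equal(a1$auc, a2$auc)
})

test_that("the Youden cutoff dominates every other integer cutoff", {
  set.seed(77)
  for (rep in 1:5) {
    scores <- sample(0:26, 400, replace = TRUE)
    labels <- runif(400) < plogis((scores - sample(10:15, 1)) / 3)
    if (!any(labels) || all(labels)) next
    opt <- optimal_cutoff(scores, labels, method = "youden")
    cand <- seq(min(scores) + 1L, max(scores))
    js <- vapply(cand, function(k) {
      tab <- confusion_at_cutoff(scores, labels, k)
      m <- diagnostic_metrics(tab)
      sum(m$estimate[m$metric %in% c("se", "sp")]) - 1
    }, 0)
    expect_true(all(opt$report$youden >= js - 1e-12))
    # ties break toward the lower cutoff
    expect_equal(opt$cutoff, cand[which.max(js)])
  }
})

test_that("perfectly separated classes recover the separating score", {
  scores <- c(rep(13, 30), rep(10, 30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(optimal_cutoff(scores, labels)$cutoff, 11L)
  # scores strictly above/below 13 with cases at 13+
  scores2 <- c(rep(c(13, 14, 15), 10), rep(c(10, 11, 12), 10))
  labels2 <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(optimal_cutoff(scores2, labels2)$cutoff, 13L)
})

test_that("the LR-constrained rule restricts to clinically useful cutoffs", {
  set.seed(55)
  scores <- sample(0:26, 2000, replace = TRUE)
  labels <- runif(2000) < plogis((scores - 13) / 2.5)
  opt <- optimal_cutoff(scores, labels, method = "lr_constrained")
  expect_false(opt$fallback)
  expect_true(opt$report$lr_pos > 2)
  expect_true(opt$report$lr_neg < 0.5)
  # a hopeless test triggers the Youden fallback with a warning
  set.seed(56)
  noise <- sample(0:26, 300, replace = TRUE)
  ylab <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  expect_warning(opt2 <- optimal_cutoff(noise, ylab, method = "lr_constrained"),
                 "falling back")
  expect_true(opt2$fallback)
})

test_that("identical scores admit no cutoff", {
  expect_error(optimal_cutoff(rep(12, 40), rep(c(TRUE, FALSE), 20)),
               "identical")
})
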