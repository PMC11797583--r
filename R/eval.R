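# Central evaluation object: scores every scale, classifies the OGTT gold
# standard, and assembles accuracy, concordance, ROC and optimal-cutoff
# results, overall and per group.

#' Evaluate diabetes risk scales against the OGTT gold standard
#'
#' The package's central fitting function. Scores every requested scale on
#' all records, classifies each complete OGTT pair into the five glycemic
#' states, takes dysglycemia (any non-normal state) as the binary gold
#' standard, and computes for each scale: the accuracy table across the
#' requested cutoffs (Se/Sp/PPV/NPV with Wilson intervals, likelihood ratios
#' with log-method intervals), the ROC curve with trapezoidal AUC and
#' Hanley-McNeil interval, and the optimal cutoff under both the Youden and
#' the likelihood-ratio-constrained rule. Cross-scale agreement against the
#' reference scale is quantified by Cohen's kappa at each cutoff. With
#' `by = "sex"` (or any grouping column) the accuracy/AUC/cutoff analyses are
#' rerun within each group.
#'
#' Records lacking either OGTT value are still scored but excluded from all
#' evaluation statistics; their count is reported in the object.
#'
#' @param data participant data.frame (see [read_participants()]).
#' @param scales character vector of scale names to evaluate.
#' @param cutoffs integer cutoffs to sweep (default 11--16).
#' @param reference scale used as concordance reference; must be in
#'   `scales`.
#' @param alpha significance level for all intervals.
#' @param by optional name of a grouping column (e.g. `"sex"`).
#' @param thresholds a [glucose_thresholds()] object.
#' @return An object of class `dr_eval`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 800, seed = 7))
#' ev <- dr_eval(coh)
#' ev
#' @export
dr_eval <- function(data, scales = c("FINDRISC", "LA_FINDRISC", "CUBDRISC"),
                    cutoffs = 11:16, reference = "FINDRISC", alpha = 0.05,
                    by = NULL, thresholds = glucose_thresholds()) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (!reference %in% scales) {
    stop("reference scale '", reference, "' must be among the evaluated scales",
         call. = FALSE)
  }
  if (any(cutoffs < 0 | cutoffs > 26)) {
    stop("cutoffs must lie within [0, 26]", call. = FALSE)
  }
  if (!is.null(by) && !by %in% names(data)) {
    stop("grouping column '", by, "' not found", call. = FALSE)
  }

  scores <- lapply(scales, function(nm) dr_score(data, dr_scale(nm)))
  names(scores) <- scales

  has_ogtt <- !is.na(data$fpg_mmol) & !is.na(data$g2h_mmol)
  n_excluded <- sum(!has_ogtt)
  if (!any(has_ogtt)) {
    stop("no records carry a complete OGTT glucose pair", call. = FALSE)
  }
  status <- factor(rep(NA_character_, nrow(data)), levels = GLYCEMIC_STATES)
  status[has_ogtt] <- classify_ogtt(data$fpg_mmol[has_ogtt],
                                    data$g2h_mmol[has_ogtt], thresholds)
  outcome <- dysglycemia(as.character(status[has_ogtt]))

  groups <- list(overall = rep(TRUE, sum(has_ogtt)))
  if (!is.null(by)) {
    gvals <- data[[by]][has_ogtt]
    for (g in sort(unique(as.character(gvals)))) {
      groups[[paste0(by, "=", g)]] <- gvals == g
    }
  }

  accuracy <- list(); aucs <- list(); rocs <- list(); optimal <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    for (sc in scales) {
      s <- scores[[sc]][has_ogtt][idx]
      y <- outcome[idx]
      tab <- accuracy_table(s, y, cutoffs = cutoffs, alpha = alpha)
      aucs[[paste(gname, sc, sep = ".")]] <- attr(tab, "auc")
      tab <- cbind(group = gname, scale = sc, tab)
      accuracy[[length(accuracy) + 1L]] <- tab
      if (gname == "overall") rocs[[sc]] <- roc_curve(s, y)
      for (m in c("youden", "lr_constrained")) {
        optimal[[paste(gname, sc, m, sep = ".")]] <-
          suppressWarnings(optimal_cutoff(s, y, method = m, alpha = alpha))
      }
    }
  }
  accuracy <- do.call(rbind, accuracy)
  rownames(accuracy) <- NULL

  concordance <- concordance_sweep(
    lapply(scores, function(s) s[has_ogtt]),
    reference = reference, cutoffs = cutoffs
  )

  structure(list(
    scores = scores, status = status, has_ogtt = has_ogtt,
    outcome = outcome, accuracy = accuracy, concordance = concordance,
    auc = aucs, roc = rocs, optimal = optimal,
    n = nrow(data), n_evaluated = sum(has_ogtt), n_excluded = n_excluded,
    scales = scales, cutoffs = cutoffs, reference = reference,
    alpha = alpha, by = by, call = match.call()
  ), class = "dr_eval")
}

#' @export
print.dr_eval <- function(x, ...) {
  cat("Diabetes risk scale evaluation\n")
  cat(sprintf("  records: %d (%d evaluated, %d without complete OGTT)\n",
              x$n, x$n_evaluated, x$n_excluded))
  prev <- mean(x$outcome)
  cat(sprintf("  dysglycemia prevalence: %.1f%%\n", 100 * prev))
  cat("  optimal cutoffs (Youden | LR-constrained), overall:\n")
  for (sc in x$scales) {
    y <- x$optimal[[paste("overall", sc, "youden", sep = ".")]]
    l <- x$optimal[[paste("overall", sc, "lr_constrained", sep = ".")]]
    a <- x$auc[[paste("overall", sc, sep = ".")]]
    cat(sprintf("    %-12s >=%d | >=%d%s   AUC %.3f (%s)\n", sc,
                y$cutoff, l$cutoff, if (l$fallback) "*" else "",
                a$auc, as.character(a$band)))
  }
  if (any(vapply(x$optimal, function(o) o$fallback, TRUE))) {
    cat("    (* no cutoff met LR+ > 2 and LR- < 0.5; Youden fallback)\n")
  }
  invisible(x)
}

#' @export
summary.dr_eval <- function(object, ...) {
  structure(list(eval = object), class = "summary.dr_eval")
}

#' @export
print.summary.dr_eval <- function(x, ...) {
  ev <- x$eval
  print(ev)
  cat("\nAccuracy by cutoff (overall):\n")
  tab <- ev$accuracy[ev$accuracy$group == "overall",
                     c("scale", "cutoff", "se", "sp", "ppv", "npv",
                       "lr_pos", "lr_neg", "youden")]
  tab$se <- round(100 * tab$se, 1); tab$sp <- round(100 * tab$sp, 1)
  tab$ppv <- round(100 * tab$ppv, 1); tab$npv <- round(100 * tab$npv, 1)
  tab$lr_pos <- round(tab$lr_pos, 1); tab$lr_neg <- round(tab$lr_neg, 2)
  tab$youden <- round(tab$youden, 3)
  print(tab, row.names = FALSE)
  cat("\nConcordance with", ev$reference, "(Cohen's kappa):\n")
  ktab <- ev$concordance
  ktab$kappa <- round(ktab$kappa, 3)
  ktab$standard_error <- round(ktab$standard_error, 3)
  print(ktab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dr_eval <- function(x, group = "overall", ...) {
  cols <- c("steelblue", "firebrick", "darkgreen")
  first <- TRUE
  for (i in seq_along(x$scales)) {
    sc <- x$scales[i]
    roc <- x$roc[[sc]]
    if (is.null(roc)) next
    plot(roc, add = !first, col = cols[(i - 1L) %% length(cols) + 1L],
         main = "ROC curves", ...)
    first <- FALSE
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", x$scales,
                                    vapply(x$scales, function(sc)
                                      x$auc[[paste("overall", sc, sep = ".")]]$auc, 0)),
                   col = cols[seq_along(x$scales)], lwd = 2, bty = "n")
  invisible(x)
}
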