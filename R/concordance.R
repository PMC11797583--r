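# Chance-corrected agreement between dichotomized scales: Cohen's kappa with
# the Fleiss-Cohen-Everitt large-sample standard error for reporting, the
# null-hypothesis SE for the significance test, and Landis-Koch strength
# bands.

KAPPA_STRENGTH <- c("poor", "slight", "acceptable", "moderate",
                    "considerable", "almost_perfect")

# Round half up at 2 decimals before banding, matching 2-dp kappa reporting;
# values in (0, 0.005) therefore band as "poor" boundary-consistently with
# kappa printed as 0.00, and 0.005 as "slight" (prints 0.01).
kappa_strength <- function(kappa) {
  stopifnot(all(abs(kappa) <= 1 + 1e-12))
  k2 <- floor(kappa * 100 + 0.5) / 100
  idx <- findInterval(k2, c(0.005, 0.205, 0.405, 0.605, 0.805)) + 1L
  factor(KAPPA_STRENGTH[idx], levels = KAPPA_STRENGTH)
}

#' Cohen's kappa between two binary classifications
#'
#' Computes the chance-corrected agreement kappa = (p_o - p_e)/(1 - p_e),
#' where p_o is the observed agreement and p_e the agreement expected from
#' the marginals. Two standard errors are reported: the Fleiss-Cohen-Everitt
#' large-sample SE (`se`, the one quoted alongside kappa in agreement
#' tables) and the null-hypothesis SE (`se0`), from which a two-sided normal
#' p-value for H0: kappa = 0 is derived. Strength is interpreted on the
#' Landis-Koch scale: <=0.00 poor, 0.01--0.20 slight, 0.21--0.40 acceptable,
#' 0.41--0.60 moderate, 0.61--0.80 considerable, 0.81--1.00 almost perfect.
#'
#' @param a,b logical (or coercible) vectors of equal length >= 2.
#' @return An object of class `dr_kappa`: list with `kappa`, `se`, `se0`,
#'   `p_value`, `strength`, `p_o`, `p_e`, `n`, `table` and `undefined`
#'   (`TRUE` when both raters are constant so p_e = 1 and kappa has no
#'   defined value).
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
cohen_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)

  lv <- c(FALSE, TRUE)
  tab <- table(factor(a, lv), factor(b, lv)) / n
  p_o <- sum(diag(tab))
  rm_ <- rowSums(tab); cm_ <- colSums(tab)
  p_e <- sum(rm_ * cm_)

  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(structure(list(
      kappa = NA_real_, se = NA_real_, se0 = NA_real_, p_value = NA_real_,
      strength = factor(NA, levels = KAPPA_STRENGTH), p_o = p_o, p_e = p_e,
      n = n, table = tab * n, undefined = TRUE
    ), class = "dr_kappa"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt large-sample SE
  k <- nrow(tab)
  termA <- 0
  for (i in seq_len(k)) {
    termA <- termA + tab[i, i] * (1 - (rm_[i] + cm_[i]) * (1 - kappa))^2
  }
  termB <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) termB <- termB + tab[i, j] * (cm_[i] + rm_[j])^2
  }
  termB <- termB * (1 - kappa)^2
  termC <- (kappa - p_e * (1 - kappa))^2
  var_k <- (termA + termB - termC) / ((1 - p_e)^2 * n)
  se <- sqrt(max(0, var_k))

  # SE under H0: kappa = 0
  var0 <- (p_e + p_e^2 - sum(rm_ * cm_ * (rm_ + cm_))) / ((1 - p_e)^2 * n)
  se0 <- sqrt(max(0, var0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))

  structure(list(
    kappa = unname(kappa), se = unname(se), se0 = unname(se0),
    p_value = unname(p_value), strength = kappa_strength(kappa),
    p_o = unname(p_o), p_e = unname(p_e), n = n, table = tab * n,
    undefined = FALSE
  ), class = "dr_kappa")
}

#' @export
print.dr_kappa <- function(x, ...) {
  if (x$undefined) {
    cat("Cohen's kappa: undefined (both classifications constant)\n")
  } else {
    cat(sprintf("Cohen's kappa %.3f (SE %.3f, p %s), %s\n",
                x$kappa, x$se,
                format.pval(x$p_value, digits = 3, eps = 1e-4),
                as.character(x$strength)))
  }
  invisible(x)
}

#' Kappa concordance sweep between a reference scale and the others
#'
#' For each cutoff and each non-reference scale, computes Cohen's kappa
#' between the dichotomizations `reference >= cutoff` and `scale >= cutoff`
#' on the same records, reproducing the shape of a per-cutoff agreement
#' table.
#'
#' @param scores_by_scale named list of integer score vectors, all on
#'   identical record sets.
#' @param reference name of the reference (gold-standard) scale; must be an
#'   element of `names(scores_by_scale)`.
#' @param cutoffs integer cutoffs within 0--26.
#' @return data.frame with columns `cutoff`, `scale`, `kappa`,
#'   `standard_error`, `p_value`, `strength`.
#' @export
concordance_sweep <- function(scores_by_scale, reference = "FINDRISC",
                              cutoffs = 11:16) {
  stopifnot(is.list(scores_by_scale), length(scores_by_scale) >= 2L)
  if (!reference %in% names(scores_by_scale)) {
    stop("reference scale '", reference, "' not among the scored scales",
         call. = FALSE)
  }
  if (any(cutoffs < 0 | cutoffs > 26)) {
    stop("cutoffs must lie within [0, 26]", call. = FALSE)
  }
  lens <- lengths(scores_by_scale)
  if (length(unique(lens)) != 1L) {
    stop("all scales must be scored on the same records", call. = FALSE)
  }
  ref <- scores_by_scale[[reference]]
  others <- setdiff(names(scores_by_scale), reference)
  rows <- list()
  for (k in cutoffs) {
    for (sc in others) {
      kp <- cohen_kappa(ref >= k, scores_by_scale[[sc]] >= k)
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = k, scale = sc, kappa = kp$kappa, standard_error = kp$se,
        p_value = kp$p_value, strength = as.character(kp$strength)
      )
    }
  }
  do.call(rbind, rows)
}
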