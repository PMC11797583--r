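# OGTT-based glycemic classification. Canonical unit is mmol/L; values on a
# threshold belong to the higher category (all lower-bound inequalities are
# ">=" in the diagnostic criteria).

GLYCEMIC_STATES <- c("normal", "AFG", "AGT", "AFG_AGT", "DM2")

#' Diagnostic glucose thresholds
#'
#' Defaults are the 2012 Cuban / ALAD / ADA oral-glucose-tolerance-test
#' criteria: altered fasting glucose from 5.6 mmol/L (100 mg/dL), diabetes
#' from 7.0 mmol/L (126 mg/dL) fasting; altered tolerance from 7.8 mmol/L
#' (140 mg/dL), diabetes from 11.1 mmol/L (200 mg/dL) at 2 hours.
#'
#' @param fpg_lower,fpg_dm fasting thresholds (mmol/L).
#' @param g2h_lower,g2h_dm 2-hour post-load thresholds (mmol/L).
#' @return An object of class `glucose_thresholds`.
#' @export
glucose_thresholds <- function(fpg_lower = 5.6, fpg_dm = 7.0,
                               g2h_lower = 7.8, g2h_dm = 11.1) {
  th <- list(fpg_lower = fpg_lower, fpg_dm = fpg_dm,
             g2h_lower = g2h_lower, g2h_dm = g2h_dm)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1L && x > 0, TRUE))) {
    stop("thresholds must be positive scalars", call. = FALSE)
  }
  if (fpg_lower >= fpg_dm || g2h_lower >= g2h_dm) {
    stop("lower thresholds must be below the diabetes thresholds", call. = FALSE)
  }
  structure(th, class = "glucose_thresholds")
}

#' @rdname glucose_thresholds
#' @param json a JSON string or file path with any subset of the four
#'   threshold fields; unspecified fields keep their defaults.
#' @export
thresholds_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  do.call(glucose_thresholds, utils::modifyList(
    list(fpg_lower = 5.6, fpg_dm = 7.0, g2h_lower = 7.8, g2h_dm = 11.1),
    doc[names(doc) %in% c("fpg_lower", "fpg_dm", "g2h_lower", "g2h_dm")]
  ))
}

#' Classify an OGTT glucose pair into the five glycemic states
#'
#' Partition of the (fasting, 2-hour) plane: `DM2` if fasting >= 7.0 or
#' 2-hour >= 11.1 mmol/L; otherwise `AFG_AGT` if both the fasting and the
#' 2-hour value sit in their impaired bands, `AFG` if only fasting is
#' impaired, `AGT` if only the 2-hour value is, else `normal`. The states are
#' mutually exclusive and exhaustive over valid pairs; boundary values fall in
#' the higher state.
#'
#' @param fpg fasting plasma glucose, mmol/L.
#' @param g2h 2-hour post-load plasma glucose, mmol/L.
#' @param thresholds a [glucose_thresholds()] object.
#' @return Factor with levels `normal, AFG, AGT, AFG_AGT, DM2`.
#' @examples
#' classify_ogtt(c(6.0, 5.0, 6.5, 7.2), c(7.0, 8.5, 9.0, 6.0))
#' @export
classify_ogtt <- function(fpg, g2h, thresholds = glucose_thresholds()) {
  stopifnot(inherits(thresholds, "glucose_thresholds"))
  fpg <- as.numeric(fpg)
  g2h <- as.numeric(g2h)
  if (length(fpg) != length(g2h)) {
    stop("fasting and 2-hour glucose vectors must have equal length", call. = FALSE)
  }
  if (anyNA(fpg) || anyNA(g2h)) {
    stop("both OGTT values are required for classification; ",
         "no single-measure fallback is applied", call. = FALSE)
  }
  if (any(fpg <= 0 | fpg >= 50 | g2h <= 0 | g2h >= 50)) {
    stop("glucose values must lie in (0, 50) mmol/L", call. = FALSE)
  }
  fpg_imp <- fpg >= thresholds$fpg_lower
  g2h_imp <- g2h >= thresholds$g2h_lower
  state <- ifelse(fpg >= thresholds$fpg_dm | g2h >= thresholds$g2h_dm, "DM2",
           ifelse(fpg_imp & g2h_imp, "AFG_AGT",
           ifelse(fpg_imp, "AFG",
           ifelse(g2h_imp, "AGT", "normal"))))
  factor(state, levels = GLYCEMIC_STATES)
}

#' Derived binary outcomes from a glycemic state
#'
#' `dysglycemia()` is `TRUE` for any state other than `normal` (prediabetes or
#' previously undiagnosed diabetes); `prediabetes_flag()` is `TRUE` only for
#' the prediabetic states `AFG`, `AGT` and `AFG_AGT` (diabetes is not
#' prediabetes).
#'
#' @param state factor or character vector of glycemic states.
#' @return Logical vector.
#' @export
dysglycemia <- function(state) {
  state <- as.character(state)
  if (!all(state %in% GLYCEMIC_STATES)) {
    stop("invalid glycemic state(s)", call. = FALSE)
  }
  state != "normal"
}

#' @rdname dysglycemia
#' @export
prediabetes_flag <- function(state) {
  state <- as.character(state)
  if (!all(state %in% GLYCEMIC_STATES)) {
    stop("invalid glycemic state(s)", call. = FALSE)
  }
  state %in% c("AFG", "AGT", "AFG_AGT")
}

#' Convert glucose from mg/dL to mmol/L
#'
#' Uses the conventional divisor 18.0, under which the usual printed pairs map
#' within rounding (100 -> 5.56, 126 -> 7.0, 140 -> 7.78, 200 -> 11.1).
#'
#' @param value glucose in mg/dL, positive.
#' @return Glucose in mmol/L.
#' @export
mgdl_to_mmol <- function(value) {
  value <- as.numeric(value)
  if (anyNA(value) || any(value <= 0)) {
    stop("glucose in mg/dL must be positive", call. = FALSE)
  }
  value / 18.0
}
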