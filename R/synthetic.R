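# Seeded synthetic screening cohorts. The defaults emulate the marginal
# structure of a risk-factor-enriched adult screening population: 58.7%
# women; age bands <45 / 45-54 / 55-64 / >=65 at 34.7/19.9/19.3/26.1%; BMI
# bands normal/overweight/obese at 46.5/35.9/17.6%; item prevalences
# (activity 53.3%, daily fruit/veg 17.4%, antihypertensives 47.5%, prior
# high glucose 35.5%, first-degree family history 29.9%); outcome mix
# normal/AFG/AGT/AFG+AGT/DM2 = 65.5/21.4/3.5/3.2/6.4%. Items are drawn
# independently except waist | (sex, BMI band) and outcome | score.

#' Configuration of a synthetic screening cohort
#'
#' Bundles the marginal targets and coupling parameters of
#' [generate_cohort()]. Probability vectors must sum to 1. `link_slope` is
#' the per-point log-odds increment of the cumulative-logit link that couples
#' the latent glycemic state to the FINDRISC total; intercepts are calibrated
#' at generation time so the marginal state frequencies match
#' `outcome_probs`.
#'
#' @param n number of records.
#' @param seed integer seed making generation deterministic.
#' @param sex_p_woman probability of female sex.
#' @param age_band_probs probabilities of age bands 20--44, 45--54, 55--64,
#'   65--89.
#' @param bmi_band_probs probabilities of BMI bands <25, 25--30, >30 kg/m2.
#' @param item_prevalences named list: `activity`, `fruit_veg`, `htn_meds`,
#'   `high_glucose_history`, `fh_first_degree`, `fh_second_degree`.
#' @param outcome_probs named 5-vector over
#'   `normal, AFG, AGT, AFG_AGT, DM2`.
#' @param link_slope non-negative per-point log-odds increment; 0 decouples
#'   the outcome from the score. The default 0.22 was fixed once by a
#'   calibration experiment so the FINDRISC-vs-dysglycemia AUC of a default
#'   cohort lands near 0.75, the qualitative regime of a risk-factor-enriched
#'   screening population.
#' @param wc_location per-sex waist-circumference location (cm) by BMI band;
#'   waists are log-normal around these with `wc_sdlog`.
#' @param wc_sdlog log-scale SD of the waist draw.
#' @param require_risk_factor if `TRUE`, rejection-sample so every record
#'   satisfies at least one screening eligibility criterion. Off by default:
#'   the default marginals already describe a risk-factor-enriched
#'   population, and re-filtering would distort them.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 3737, seed = 1L,
                          sex_p_woman = 0.587,
                          age_band_probs = c(0.347, 0.199, 0.193, 0.261),
                          bmi_band_probs = c(0.465, 0.359, 0.176),
                          item_prevalences = list(
                            activity = 0.533, fruit_veg = 0.174,
                            htn_meds = 0.475, high_glucose_history = 0.355,
                            fh_first_degree = 0.299, fh_second_degree = 0.15),
                          outcome_probs = c(normal = 0.655, AFG = 0.214,
                                            AGT = 0.035, AFG_AGT = 0.032,
                                            DM2 = 0.064),
                          link_slope = 0.22,
                          wc_location = list(M = c(84, 94, 105),
                                             W = c(78, 88, 100)),
                          wc_sdlog = 0.07,
                          require_risk_factor = FALSE) {
  stopifnot(n >= 1, length(age_band_probs) == 4L, length(bmi_band_probs) == 3L,
            length(outcome_probs) == 5L, link_slope >= 0,
            sex_p_woman >= 0, sex_p_woman <= 1)
  for (v in list(age_band_probs, bmi_band_probs, outcome_probs)) {
    if (abs(sum(v) - 1) > 1e-9) {
      stop("probability vector does not sum to 1: ",
           paste(v, collapse = "/"), call. = FALSE)
    }
    if (any(v < 0)) stop("negative probabilities", call. = FALSE)
  }
  fh_none <- 1 - item_prevalences$fh_first_degree - item_prevalences$fh_second_degree
  if (fh_none < 0) stop("family-history prevalences exceed 1", call. = FALSE)
  structure(list(
    n = as.integer(n), seed = as.integer(seed), sex_p_woman = sex_p_woman,
    age_band_probs = age_band_probs, bmi_band_probs = bmi_band_probs,
    item_prevalences = item_prevalences,
    outcome_probs = stats::setNames(as.numeric(outcome_probs), GLYCEMIC_STATES),
    link_slope = link_slope, wc_location = wc_location, wc_sdlog = wc_sdlog,
    require_risk_factor = require_risk_factor
  ), class = "cohort_config")
}

# truncated draws via inverse-CDF
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# raw covariate draw, without outcome coupling
draw_covariates <- function(config, n) {
  AGE_BANDS <- list(c(20, 45), c(45, 55), c(55, 65), c(65, 90))
  BMI_BANDS <- list(c(16.5, 25 - 1e-6), c(25, 30), c(30 + 1e-6, 45))
  BMI_MEANLOG <- log(c(22.5, 27.2, 33))

  sex <- ifelse(stats::runif(n) < config$sex_p_woman, "W", "M")
  age_band <- sample.int(4L, n, replace = TRUE, prob = config$age_band_probs)
  age_lims <- do.call(rbind, AGE_BANDS)[age_band, , drop = FALSE]
  age <- as.integer(floor(stats::runif(n, age_lims[, 1], age_lims[, 2])))

  bmi_band <- sample.int(3L, n, replace = TRUE, prob = config$bmi_band_probs)
  bmi <- numeric(n)
  for (b in 1:3) {
    idx <- bmi_band == b
    if (any(idx)) {
      bmi[idx] <- rtrunc_lnorm(sum(idx), BMI_MEANLOG[b], 0.1,
                               BMI_BANDS[[b]][1], BMI_BANDS[[b]][2])
    }
  }
  wc <- numeric(n)
  for (s in c("M", "W")) {
    idx <- sex == s
    if (any(idx)) {
      loc <- config$wc_location[[s]][bmi_band[idx]]
      wc[idx] <- stats::rlnorm(sum(idx), log(loc), config$wc_sdlog)
    }
  }
  ip <- config$item_prevalences
  fh_p <- c(none = 1 - ip$fh_first_degree - ip$fh_second_degree,
            second_degree = ip$fh_second_degree,
            first_degree = ip$fh_first_degree)
  data.frame(
    age = age, sex = sex, bmi = bmi, waist_cm = wc,
    physical_activity = stats::runif(n) < ip$activity,
    daily_fruit_veg = stats::runif(n) < ip$fruit_veg,
    antihypertensive_meds = stats::runif(n) < ip$htn_meds,
    history_high_glucose = stats::runif(n) < ip$high_glucose_history,
    family_history = sample(names(fh_p), n, replace = TRUE, prob = fh_p)
  )
}

# calibrate cumulative-logit intercepts so mean over records of
# plogis(eta + theta_k) hits each tail target
calibrate_link <- function(eta, tail_targets) {
  vapply(tail_targets, function(q) {
    if (q <= 0 || q >= 1) {
      stop("infeasible outcome calibration: cumulative tail target ", q,
           " outside (0, 1); adjust outcome_probs", call. = FALSE)
    }
    f <- function(th) mean(stats::plogis(eta + th)) - q
    stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  }, 0)
}

# state-conditional glucose boxes; eps keeps draws strictly inside open ends
draw_glucose <- function(state, th) {
  n <- length(state)
  eps <- 1e-6
  fpg <- numeric(n); g2h <- numeric(n)
  boxes <- list(
    normal  = list(fpg = c(5.0, 0.40, 3.2, th$fpg_lower - eps),
                   g2h = c(5.8, 1.00, 2.8, th$g2h_lower - eps)),
    AFG     = list(fpg = c(6.0, 0.35, th$fpg_lower, th$fpg_dm - eps),
                   g2h = c(6.5, 0.90, 2.8, th$g2h_lower - eps)),
    AGT     = list(fpg = c(5.2, 0.30, 3.2, th$fpg_lower - eps),
                   g2h = c(8.8, 0.80, th$g2h_lower, th$g2h_dm - eps)),
    AFG_AGT = list(fpg = c(6.2, 0.35, th$fpg_lower, th$fpg_dm - eps),
                   g2h = c(9.0, 0.80, th$g2h_lower, th$g2h_dm - eps)),
    DM2     = list(fpg = c(8.2, 1.20, th$fpg_dm, 20),
                   g2h = c(13.5, 2.00, th$g2h_dm, 30))
  )
  for (st in names(boxes)) {
    idx <- state == st
    m <- sum(idx)
    if (m == 0L) next
    bx <- boxes[[st]]
    fpg[idx] <- rtrunc_norm(m, bx$fpg[1], bx$fpg[2], bx$fpg[3], bx$fpg[4])
    g2h[idx] <- rtrunc_norm(m, bx$g2h[1], bx$g2h[2], bx$g2h[3], bx$g2h[4])
  }
  # diabetes presents with either measure elevated: keep a share with only
  # one of the two above its threshold
  dm <- which(state == "DM2")
  if (length(dm)) {
    u <- stats::runif(length(dm))
    only_fasting <- dm[u < 0.2]
    only_2h <- dm[u >= 0.2 & u < 0.4]
    if (length(only_fasting)) {
      g2h[only_fasting] <- rtrunc_norm(length(only_fasting), 9.0, 1.5,
                                       5.0, th$g2h_dm - eps)
    }
    if (length(only_2h)) {
      fpg[only_2h] <- rtrunc_norm(length(only_2h), 6.2, 0.5,
                                  4.5, th$fpg_dm - eps)
    }
  }
  list(fpg = fpg, g2h = g2h)
}

#' Generate a synthetic screening cohort
#'
#' Draws `config$n` participant records with the configured marginal
#' structure, couples a latent glycemic state to each record's FINDRISC total
#' through a cumulative-logit link (intercepts calibrated so marginal state
#' frequencies match `outcome_probs` in expectation), and draws an OGTT
#' glucose pair from state-conditional truncated normal distributions that
#' respect the diagnostic thresholds, so [classify_ogtt()] reproduces the
#' latent state exactly on every record.
#'
#' @param config a [cohort_config()].
#' @param thresholds a [glucose_thresholds()] object used for the glucose
#'   boxes.
#' @return data.frame of class `dr_cohort`: participant columns plus
#'   `fpg_mmol`, `g2h_mmol` and the truth column `latent_state`. Attributes:
#'   `config`, `seed`, and `link` (slope, calibrated intercepts and the score
#'   centering used), enabling oracle computations on the generative model.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 500, seed = 42))
#' table(coh$latent_state)
#' @export
generate_cohort <- function(config = cohort_config(),
                            thresholds = glucose_thresholds()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n

  cov <- draw_covariates(config, n)
  if (config$require_risk_factor) {
    keep <- screening_eligibility(cov)$eligible
    cov <- cov[keep, , drop = FALSE]
    guard <- 0L
    while (nrow(cov) < n) {
      extra <- draw_covariates(config, n)
      keep <- screening_eligibility(extra)$eligible
      cov <- rbind(cov, extra[keep, , drop = FALSE])
      guard <- guard + 1L
      if (guard > 1000L) {
        stop("eligibility rejection sampling failed to reach n; ",
             "marginals leave too few eligible records", call. = FALSE)
      }
    }
    cov <- cov[seq_len(n), , drop = FALSE]
  }
  rownames(cov) <- NULL

  score <- dr_score(cov, dr_scale("FINDRISC"))
  centre <- mean(score)
  eta <- config$link_slope * (score - centre)
  p <- config$outcome_probs
  tail_targets <- rev(cumsum(rev(p)))[-1]  # P(state >= AFG), ..., P(DM2)
  thetas <- calibrate_link(eta, tail_targets)
  tails <- vapply(thetas, function(th) stats::plogis(eta + th),
                  numeric(n))                       # n x 4, ordered columns
  if (n == 1L) tails <- matrix(tails, nrow = 1L)
  u <- stats::runif(n)
  state_idx <- 1L + rowSums(u < tails)
  state <- factor(GLYCEMIC_STATES[state_idx], levels = GLYCEMIC_STATES)

  glu <- draw_glucose(as.character(state), thresholds)

  out <- data.frame(id = sprintf("S%06d", seq_len(n)), cov,
                    fpg_mmol = glu$fpg, g2h_mmol = glu$g2h,
                    latent_state = state)
  realized <- classify_ogtt(out$fpg_mmol, out$g2h_mmol, thresholds)
  if (!all(realized == out$latent_state)) {
    stop("internal error: glucose draw violated a threshold box", call. = FALSE)
  }
  structure(out, config = config, seed = config$seed,
            link = list(slope = config$link_slope, thetas = unname(thetas),
                        centre = centre),
            class = c("dr_cohort", "data.frame"))
}

#' Write a synthetic cohort as CSV with run metadata
#'
#' Writes the participant CSV dialect plus the `latent_state` truth column,
#' and a sidecar `<path>.meta.json` recording the seed and configuration.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "dr_cohort"))
  write_participants(as.data.frame(cohort), path)
  cfg <- attr(cohort, "config")
  meta <- list(seed = cfg$seed, n = cfg$n,
               config = unclass(cfg), link = attr(cohort, "link"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Screening eligibility by diabetes risk factors
#'
#' A record is eligible when at least one criterion holds: age >= 45 years;
#' BMI >= 25 kg/m2; any family history of diabetes; waist circumference
#' >= 80 cm (women) / >= 90 cm (men); hypertension or antihypertensive
#' treatment; sedentary lifestyle (no regular physical activity). Optional
#' extended columns add criteria when present: `triglycerides_mmol >= 1.7`,
#' `hdl_mmol < 1.03`, and logical flags `gestational_diabetes`, `macrosomia`,
#' `ascvd`, `low_birth_weight`, `pcos`, `acanthosis_nigricans`. Absent
#' extended columns simply cannot trigger their criteria.
#'
#' @param data data.frame of participant records.
#' @return List with `eligible` (logical vector) and `reasons` (list of
#'   character vectors naming each satisfied criterion).
#' @examples
#' screening_eligibility(data.frame(age = 50, sex = "M", bmi = 23,
#'   waist_cm = 85, physical_activity = TRUE, daily_fruit_veg = TRUE,
#'   antihypertensive_meds = FALSE, history_high_glucose = FALSE,
#'   family_history = "none"))
#' @export
screening_eligibility <- function(data) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  sex <- normalize_sex(data$sex)
  bmi <- resolve_bmi(data)
  crit <- list(
    "age>=45" = data$age >= 45,
    "BMI>=25" = bmi >= 25,
    "family_history" = normalize_fh(data$family_history) != "none",
    "waist" = ifelse(sex == "W", data$waist_cm >= 80, data$waist_cm >= 90),
    "hypertension" = as_flag(data$antihypertensive_meds, "antihypertensive_meds"),
    "sedentary" = !as_flag(data$physical_activity, "physical_activity")
  )
  ext <- list(
    "triglycerides>=1.7" = if ("triglycerides_mmol" %in% names(data))
      data$triglycerides_mmol >= 1.7,
    "HDL<1.03" = if ("hdl_mmol" %in% names(data)) data$hdl_mmol < 1.03,
    "gestational_diabetes" = if ("gestational_diabetes" %in% names(data))
      as_flag(data$gestational_diabetes, "gestational_diabetes"),
    "macrosomia" = if ("macrosomia" %in% names(data))
      as_flag(data$macrosomia, "macrosomia"),
    "ASCVD" = if ("ascvd" %in% names(data)) as_flag(data$ascvd, "ascvd"),
    "low_birth_weight" = if ("low_birth_weight" %in% names(data))
      as_flag(data$low_birth_weight, "low_birth_weight"),
    "PCOS" = if ("pcos" %in% names(data)) as_flag(data$pcos, "pcos"),
    "acanthosis_nigricans" = if ("acanthosis_nigricans" %in% names(data))
      as_flag(data$acanthosis_nigricans, "acanthosis_nigricans")
  )
  crit <- c(crit, Filter(Negate(is.null), ext))
  mat <- vapply(crit, function(x) {
    x[is.na(x)] <- FALSE
    x
  }, logical(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(crit)))
  eligible <- rowSums(mat) > 0
  reasons <- lapply(seq_len(n), function(i) names(crit)[mat[i, ]])
  list(eligible = unname(eligible), reasons = reasons)
}

#' Screening cohort flow arithmetic
#'
#' Computes the analyzed sample size from the interview-to-analysis flow:
#' interviewed minus persons without any risk factor, minus known diabetes,
#' minus those not examined. Every intermediate stage must stay
#' non-negative.
#'
#' @param interviewed,no_risk_factor,known_diabetes,not_examined non-negative
#'   counts.
#' @return Integer analyzed count, with attribute `stages` (the intermediate
#'   counts).
#' @examples
#' cohort_flow(9056, 905, 505, 3909)
#' @export
cohort_flow <- function(interviewed, no_risk_factor = 0, known_diabetes = 0,
                        not_examined = 0) {
  counts <- c(interviewed, no_risk_factor, known_diabetes, not_examined)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  at_risk <- interviewed - no_risk_factor
  eligible <- at_risk - known_diabetes
  analyzed <- eligible - not_examined
  if (at_risk < 0 || eligible < 0 || analyzed < 0) {
    stop("cohort flow produced a negative intermediate count", call. = FALSE)
  }
  structure(as.integer(analyzed),
            stages = c(at_risk = as.integer(at_risk),
                       eligible = as.integer(eligible),
                       analyzed = as.integer(analyzed)))
}
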