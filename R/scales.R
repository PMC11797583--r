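# Scoring tables for the FINDRISC questionnaire and its Latin-American and
# Cuban waist-circumference variants. All three scales share the same eight
# items and point weights; only the waist bands differ.

SCALE_NAMES <- c("FINDRISC", "LA_FINDRISC", "CUBDRISC")

FH_LEVELS <- c("none", "second_degree", "first_degree")

RISK_CATEGORIES <- c("low", "slightly_elevated", "moderate", "high", "very_high")

# Items a record must carry to be scorable. `waist` reads column waist_cm;
# `bmi` may be derived from height_m/weight_kg.
SCORE_ITEMS <- c("age", "bmi", "waist", "physical_activity", "daily_fruit_veg",
                 "antihypertensive_meds", "history_high_glucose", "family_history")

# A band list is a data.frame(lower, upper, points); NA means an open end and
# a value belongs to the FIRST band with lower <= x <= upper. Adjacent closed
# bands sharing a boundary are disambiguated by order (e.g. BMI 30 falls in
# [25, 30] -> 1 point, not (30, Inf) -> 3 points).
band_table <- function(...) {
  rows <- list(...)
  out <- data.frame(
    lower = vapply(rows, function(r) if (is.null(r[[1]])) NA_real_ else as.numeric(r[[1]]), 0),
    upper = vapply(rows, function(r) if (is.null(r[[2]])) NA_real_ else as.numeric(r[[2]]), 0),
    points = vapply(rows, function(r) as.integer(r[[3]]), 0L)
  )
  if (any(out$points < 0)) stop("band points must be non-negative", call. = FALSE)
  out
}

band_points <- function(bands, x) {
  pts <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$lower[i]
    hi <- bands$upper[i]
    hit <- is.na(pts) & !is.na(x) &
      (is.na(lo) | x >= lo) & (is.na(hi) | x <= hi)
    pts[hit] <- bands$points[i]
  }
  pts
}

wc_bands <- function(name) {
  switch(name,
    FINDRISC = list(
      M = band_table(list(94, 102, 3), list(102, NULL, 4), list(NULL, NULL, 0)),
      W = band_table(list(80, 88, 3), list(88, NULL, 4), list(NULL, NULL, 0))
    ),
    LA_FINDRISC = list(
      M = band_table(list(94, NULL, 4), list(NULL, NULL, 0)),
      W = band_table(list(90, NULL, 4), list(NULL, NULL, 0))
    ),
    CUBDRISC = list(
      M = band_table(list(90, NULL, 4), list(NULL, NULL, 0)),
      W = band_table(list(80, NULL, 4), list(NULL, NULL, 0))
    )
  )
}

#' Build a diabetes risk scale definition
#'
#' Constructs the complete scoring table for one of the three questionnaire
#' scales. All three share the age, body-mass-index and fixed-item weights and
#' differ only in the sex-specific waist-circumference bands:
#' \describe{
#'   \item{FINDRISC}{men <94 cm: 0, 94--102: 3, >102: 4; women <80: 0,
#'     80--88: 3, >88: 4}
#'   \item{LA_FINDRISC}{men >=94 cm: 4; women >=90 cm: 4 (else 0)}
#'   \item{CUBDRISC}{men >=90 cm: 4; women >=80 cm: 4 (else 0)}
#' }
#' Age scores 0/2/3/4 points for <45 / 45--54 / 55--64 / >=65 years; BMI
#' scores 0/1/3 for <25 / 25--30 / >30 kg/m2; inactivity 2; not eating fruit
#' or vegetables daily 1; antihypertensive medication 2; a prior high-glucose
#' episode 5; family history of diabetes 3 (second degree, including a wife's
#' gestational diabetes) or 5 (first degree). Every scale totals 0--26.
#'
#' @param name one of `"FINDRISC"`, `"LA_FINDRISC"`, `"CUBDRISC"`.
#' @return An object of class `dr_scale`: the banded scoring table.
#' @examples
#' sc <- dr_scale("CUBDRISC")
#' max_score(sc)
#' @export
dr_scale <- function(name = c("FINDRISC", "LA_FINDRISC", "CUBDRISC")) {
  if (length(name) != 1L || !name %in% SCALE_NAMES) {
    stop("unknown scale '", paste(name, collapse = ","),
         "'; must be one of: ", paste(SCALE_NAMES, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    name = name,
    age_bands = band_table(list(NULL, 44, 0), list(45, 54, 2),
                           list(55, 64, 3), list(65, NULL, 4)),
    bmi_bands = band_table(list(25, 30, 1), list(30, NULL, 3),
                           list(NULL, NULL, 0)),
    wc_bands_by_sex = wc_bands(name),
    fixed_item_points = list(
      physical_activity     = c(yes = 0L, no = 2L),
      daily_fruit_veg       = c(yes = 0L, no = 1L),
      antihypertensive_meds = c(no = 0L, yes = 2L),
      history_high_glucose  = c(no = 0L, yes = 5L),
      family_history        = c(none = 0L, second_degree = 3L, first_degree = 5L)
    )
  ), class = "dr_scale")
}

#' @export
print.dr_scale <- function(x, ...) {
  cat("Diabetes risk scale:", x$name, "(maximum", max_score(x), "points)\n")
  cat("Waist-circumference bands:\n")
  for (s in names(x$wc_bands_by_sex)) {
    b <- x$wc_bands_by_sex[[s]]
    lab <- apply(b, 1L, function(r) {
      lo <- r[["lower"]]; hi <- r[["upper"]]
      rng <- if (is.na(lo) && is.na(hi)) "otherwise"
             else if (is.na(lo)) paste0("<=", hi)
             else if (is.na(hi)) paste0(">=", lo)
             else paste0(lo, "-", hi)
      paste0(rng, " cm: ", r[["points"]], "p")
    })
    cat("  ", s, ": ", paste(lab, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Maximum attainable total score of a scale
#'
#' Sums the maximal band points over the eight questionnaire items (taking the
#' per-sex maximum for the waist item). All three built-in scales reach 26.
#'
#' @param scale a [dr_scale()] object.
#' @return Integer maximum total.
#' @export
max_score <- function(scale) {
  stopifnot(inherits(scale, "dr_scale"))
  tot <- 0L
  if (!is.null(scale$age_bands)) tot <- tot + max(scale$age_bands$points)
  if (!is.null(scale$bmi_bands)) tot <- tot + max(scale$bmi_bands$points)
  if (!is.null(scale$wc_bands_by_sex)) {
    tot <- tot + max(vapply(scale$wc_bands_by_sex,
                            function(b) max(b$points), 0L))
  }
  tot + sum(vapply(scale$fixed_item_points, max, 0L))
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("M", "MAN", "MALE"), "M",
         ifelse(s %in% c("W", "F", "WOMAN", "FEMALE"), "W", NA_character_))
  if (anyNA(out[!is.na(sex)])) {
    bad <- unique(s[is.na(out) & !is.na(sex)])
    stop("unrecognized sex code(s): ", paste(bad, collapse = ", "),
         " (expected M/W)", call. = FALSE)
  }
  out
}

normalize_fh <- function(fh) {
  f <- tolower(trimws(as.character(fh)))
  if (!all(f[!is.na(fh)] %in% FH_LEVELS)) {
    bad <- unique(f[!f %in% FH_LEVELS & !is.na(fh)])
    stop("unrecognized family_history level(s): ", paste(bad, collapse = ", "),
         " (expected none/second_degree/first_degree)", call. = FALSE)
  }
  f
}

as_flag <- function(x, item) {
  if (is.logical(x)) return(x)
  v <- trimws(as.character(x))
  out <- ifelse(v %in% c("1", "TRUE", "true", "yes"), TRUE,
         ifelse(v %in% c("0", "FALSE", "false", "no"), FALSE, NA))
  if (anyNA(out[!is.na(x)])) {
    stop("item '", item, "' has values not codable as 0/1", call. = FALSE)
  }
  out
}

# Resolve BMI: an explicit bmi column wins; otherwise derive weight/height^2.
resolve_bmi <- function(data) {
  bmi <- if ("bmi" %in% names(data)) as.numeric(data$bmi) else rep(NA_real_, nrow(data))
  if (all(c("height_m", "weight_kg") %in% names(data))) {
    derived <- as.numeric(data$weight_kg) / as.numeric(data$height_m)^2
    bmi <- ifelse(is.na(bmi), derived, bmi)
  }
  bmi
}

check_scorable <- function(data) {
  cols <- c(age = "age", waist = "waist_cm",
            physical_activity = "physical_activity",
            daily_fruit_veg = "daily_fruit_veg",
            antihypertensive_meds = "antihypertensive_meds",
            history_high_glucose = "history_high_glucose",
            family_history = "family_history", sex = "sex")
  for (item in names(cols)) {
    col <- cols[[item]]
    if (!col %in% names(data)) {
      stop("missing questionnaire item '", item, "' (column '", col, "')",
           call. = FALSE)
    }
    if (anyNA(data[[col]])) {
      stop("questionnaire item '", item, "' has missing values in ",
           sum(is.na(data[[col]])), " record(s); no imputation is performed",
           call. = FALSE)
    }
  }
  bmi <- resolve_bmi(data)
  if (anyNA(bmi)) {
    stop("questionnaire item 'bmi' has missing values in ", sum(is.na(bmi)),
         " record(s) and height_m/weight_kg are not both available",
         call. = FALSE)
  }
  if (any(data$age < 19)) stop("age must be >= 19 years", call. = FALSE)
  if (any(bmi <= 0) || any(data$waist_cm <= 0)) {
    stop("bmi and waist_cm must be positive", call. = FALSE)
  }
  invisible(bmi)
}

#' Score participants on a diabetes risk scale
#'
#' Applies the eight-item scoring table of a scale to every row of a
#' participant table. All items must be present and non-missing; records are
#' never imputed. BMI may be supplied directly (`bmi`) or via `height_m` and
#' `weight_kg`; an explicit `bmi` takes precedence.
#'
#' @param data data.frame of participant records (see [read_participants()]
#'   for the column dialect).
#' @param scale a [dr_scale()] object or a scale name.
#' @param per_item if `TRUE`, return the per-item point matrix along with the
#'   totals.
#' @return Integer vector of total scores in 0--26, or (with
#'   `per_item = TRUE`) a data.frame with one column per item plus `total`.
#' @examples
#' rec <- data.frame(age = 40, sex = "W", bmi = 22, waist_cm = 75,
#'                   physical_activity = TRUE, daily_fruit_veg = TRUE,
#'                   antihypertensive_meds = FALSE, history_high_glucose = FALSE,
#'                   family_history = "none")
#' dr_score(rec, "FINDRISC")
#' @export
dr_score <- function(data, scale, per_item = FALSE) {
  if (is.character(scale)) scale <- dr_scale(scale)
  stopifnot(inherits(scale, "dr_scale"), is.data.frame(data))
  bmi <- check_scorable(data)
  sex <- normalize_sex(data$sex)
  fh <- normalize_fh(data$family_history)

  fixed <- scale$fixed_item_points
  yn <- function(flag, map) unname(ifelse(flag, map[["yes"]], map[["no"]]))
  pts <- data.frame(
    age = band_points(scale$age_bands, as.numeric(data$age)),
    bmi = band_points(scale$bmi_bands, bmi),
    waist = NA_integer_,
    physical_activity = yn(as_flag(data$physical_activity, "physical_activity"),
                           fixed$physical_activity),
    daily_fruit_veg = yn(as_flag(data$daily_fruit_veg, "daily_fruit_veg"),
                         fixed$daily_fruit_veg),
    antihypertensive_meds = yn(as_flag(data$antihypertensive_meds, "antihypertensive_meds"),
                               fixed$antihypertensive_meds),
    history_high_glucose = yn(as_flag(data$history_high_glucose, "history_high_glucose"),
                              fixed$history_high_glucose),
    family_history = unname(fixed$family_history[fh])
  )
  wc <- as.numeric(data$waist_cm)
  for (s in c("M", "W")) {
    idx <- sex == s
    if (any(idx)) pts$waist[idx] <- band_points(scale$wc_bands_by_sex[[s]], wc[idx])
  }
  total <- as.integer(rowSums(pts))
  if (per_item) {
    pts$total <- total
    pts
  } else {
    total
  }
}

#' Ten-year diabetes risk category for a total score
#'
#' Maps total scores to the five published risk bands: <7 low (1% expected to
#' develop type 2 diabetes within 10 years), 7--11 slightly elevated (4%),
#' 12--14 moderate (17%), 15--20 high (33%), >=21 very high (50%).
#'
#' @param total integer vector of total scores in 0--26.
#' @return data.frame with columns `total`, `category` (ordered factor) and
#'   `ten_year_risk_pct`.
#' @examples
#' risk_category(c(6, 13, 21))
#' @export
risk_category <- function(total) {
  total <- as.numeric(total)
  if (anyNA(total) || any(total != floor(total)) ||
      any(total < 0) || any(total > 26)) {
    stop("total score must be an integer in [0, 26]", call. = FALSE)
  }
  idx <- findInterval(total, c(0, 7, 12, 15, 21))
  data.frame(
    total = as.integer(total),
    category = factor(RISK_CATEGORIES[idx], levels = RISK_CATEGORIES,
                      ordered = TRUE),
    ten_year_risk_pct = c(1, 4, 17, 33, 50)[idx]
  )
}

# --- JSON (de)serialization of scale definitions -----------------------------

bands_to_triples <- function(bands) {
  lapply(seq_len(nrow(bands)), function(i) {
    list(lower = if (is.na(bands$lower[i])) NULL else bands$lower[i],
         upper = if (is.na(bands$upper[i])) NULL else bands$upper[i],
         points = bands$points[i])
  })
}

triples_to_bands <- function(triples) {
  val <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) NULL else x
  do.call(band_table, lapply(triples, function(t) {
    list(val(t$lower), val(t$upper), t$points)
  }))
}

#' Serialize or restore a scale definition as JSON
#'
#' Bands are written as ordered `[lower, upper, points]` objects with `null`
#' open ends; a value belongs to the first band it matches. The JSON form lets
#' users register national questionnaire variants without touching code.
#'
#' @param scale a [dr_scale()] object.
#' @param path file to write to; if `NULL`, the JSON string is returned.
#' @return `scale_to_json`: the JSON string (invisibly when written to file).
#' @export
scale_to_json <- function(scale, path = NULL) {
  stopifnot(inherits(scale, "dr_scale"))
  doc <- list(
    name = scale$name,
    age_bands = bands_to_triples(scale$age_bands),
    bmi_bands = bands_to_triples(scale$bmi_bands),
    wc_bands_by_sex = lapply(scale$wc_bands_by_sex, bands_to_triples),
    fixed_item_points = lapply(scale$fixed_item_points, as.list)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname scale_to_json
#' @param json a JSON string or path to a JSON file written by
#'   [scale_to_json()].
#' @return `scale_from_json`: a `dr_scale` object.
#' @export
scale_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(
    name = doc$name,
    age_bands = triples_to_bands(doc$age_bands),
    bmi_bands = triples_to_bands(doc$bmi_bands),
    wc_bands_by_sex = lapply(doc$wc_bands_by_sex, triples_to_bands),
    fixed_item_points = lapply(doc$fixed_item_points,
                               function(m) unlist(lapply(m, as.integer)))
  ), class = "dr_scale")
}

# --- Participant CSV dialect -------------------------------------------------

#' Read or write participant records as CSV
#'
#' The dialect is one header row with columns named after the record fields
#' (`id, age, sex, bmi, waist_cm, physical_activity, daily_fruit_veg,
#' antihypertensive_meds, history_high_glucose, family_history, fpg_mmol,
#' g2h_mmol`), sex coded `M`/`W`, boolean items coded `1`/`0`, family history
#' as `none`/`second_degree`/`first_degree`. Glucose columns are optional
#' (records without an OGTT can still be scored).
#'
#' @param path CSV file path.
#' @return `read_participants`: a data.frame with booleans as logical and sex
#'   normalized to `M`/`W`.
#' @export
read_participants <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("no participant records in '", path, "'", call. = FALSE)
  for (col in c("physical_activity", "daily_fruit_veg",
                "antihypertensive_meds", "history_high_glucose")) {
    if (col %in% names(data)) data[[col]] <- as_flag(data[[col]], col)
  }
  if ("sex" %in% names(data)) data$sex <- normalize_sex(data$sex)
  if ("family_history" %in% names(data)) {
    data$family_history <- normalize_fh(data$family_history)
  }
  data
}

#' @rdname read_participants
#' @param data data.frame of participant records.
#' @return `write_participants`: the path, invisibly.
#' @export
write_participants <- function(data, path) {
  out <- data
  for (col in c("physical_activity", "daily_fruit_veg",
                "antihypertensive_meds", "history_high_glucose")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
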