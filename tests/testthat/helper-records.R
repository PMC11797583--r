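# Fixture builders used across test files.

# A single participant record with every item at its zero-point level;
# override any field via ...
zero_risk_record <- function(...) {
  rec <- data.frame(
    id = "r1", age = 40L, sex = "W", bmi = 22, waist_cm = 75,
    physical_activity = TRUE, daily_fruit_veg = TRUE,
    antihypertensive_meds = FALSE, history_high_glucose = FALSE,
    family_history = "none", stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# every item at its maximum-point level
max_risk_record <- function(...) {
  zero_risk_record(age = 70L, sex = "M", bmi = 32, waist_cm = 110,
                   physical_activity = FALSE, daily_fruit_veg = FALSE,
                   antihypertensive_meds = TRUE, history_high_glucose = TRUE,
                   family_history = "first_degree", ...)
}

# random scorable records (no OGTT columns)
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("r%03d", seq_len(n)),
    age = sample(19:95, n, replace = TRUE),
    sex = sample(c("M", "W"), n, replace = TRUE),
    bmi = runif(n, 17, 45),
    waist_cm = runif(n, 60, 140),
    physical_activity = sample(c(TRUE, FALSE), n, replace = TRUE),
    daily_fruit_veg = sample(c(TRUE, FALSE), n, replace = TRUE),
    antihypertensive_meds = sample(c(TRUE, FALSE), n, replace = TRUE),
    history_high_glucose = sample(c(TRUE, FALSE), n, replace = TRUE),
    family_history = sample(c("none", "second_degree", "first_degree"), n,
                            replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# brute-force pairwise AUC oracle: P(case > control) + 0.5 P(tie)
pairwise_auc <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}
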