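# Scoring tables and band lookups for the three questionnaire variants.

test_that("the three scales differ only in their waist bands", {
  f <- dr_scale("FINDRISC")
  la <- dr_scale("LA_FINDRISC")
  cu <- dr_scale("CUBDRISC")
  for (part in c("age_bands", "bmi_bands", "fixed_item_points")) {
    expect_identical(f[[part]], la[[part]])
    expect_identical(f[[part]], cu[[part]])
  }
  # FINDRISC: three-band waist scoring with a 3-point middle band
  expect_equal(f$wc_bands_by_sex$M$points, c(3L, 4L, 0L))
  expect_equal(f$wc_bands_by_sex$M$lower[1:2], c(94, 102))
  expect_equal(f$wc_bands_by_sex$W$lower[1:2], c(80, 88))
  # the variants collapse to a single 4-point threshold
  expect_equal(la$wc_bands_by_sex$M$lower[1], 94)
  expect_equal(la$wc_bands_by_sex$W$lower[1], 90)
  expect_equal(cu$wc_bands_by_sex$M$lower[1], 90)
  expect_equal(cu$wc_bands_by_sex$W$lower[1], 80)
  expect_equal(la$wc_bands_by_sex$M$points, c(4L, 0L))
  expect_error(dr_scale("NORDRISC"), "unknown scale")
})

test_that("extreme records score 0 and 26 on every scale", {
  for (nm in c("FINDRISC", "LA_FINDRISC", "CUBDRISC")) {
    expect_equal(dr_score(zero_risk_record(), nm), 0L)
    expect_equal(dr_score(max_risk_record(), nm), 26L)
    expect_equal(max_score(dr_scale(nm)), 26L)
  }
})

test_that("waist-discordant fixtures reproduce the scales' band differences", {
  man92 <- zero_risk_record(sex = "M", waist_cm = 92)
  expect_equal(dr_score(man92, "FINDRISC"), 0L)
  expect_equal(dr_score(man92, "LA_FINDRISC"), 0L)
  expect_equal(dr_score(man92, "CUBDRISC"), 4L)
  woman85 <- zero_risk_record(waist_cm = 85)
  expect_equal(dr_score(woman85, "FINDRISC"), 3L)
  expect_equal(dr_score(woman85, "LA_FINDRISC"), 0L)
  expect_equal(dr_score(woman85, "CUBDRISC"), 4L)
})

test_that("band boundaries follow the closed-band reading of the table", {
  # BMI 25 and 30 both earn 1 point; just above 30 earns 3
  for (bmi in c(25, 27.5, 30)) {
    expect_equal(dr_score(zero_risk_record(bmi = bmi), "FINDRISC"), 1L)
  }
  expect_equal(dr_score(zero_risk_record(bmi = 30.01), "FINDRISC"), 3L)
  # FINDRISC man: 94 and 102 in the 3-point band, above 102 in the 4-point
  expect_equal(dr_score(zero_risk_record(sex = "M", waist_cm = 94), "FINDRISC"), 3L)
  expect_equal(dr_score(zero_risk_record(sex = "M", waist_cm = 102), "FINDRISC"), 3L)
  expect_equal(dr_score(zero_risk_record(sex = "M", waist_cm = 102.5), "FINDRISC"), 4L)
  # age bands at 44/45/54/55/64/65
  ages <- c(44, 45, 54, 55, 64, 65)
  pts <- vapply(ages, function(a)
    dr_score(zero_risk_record(age = a), "FINDRISC"), 0L)
  expect_equal(pts, c(0L, 2L, 2L, 3L, 3L, 4L))
})

test_that("per-item points sum to the total and items add independently", {
  recs <- random_records(200)
  for (nm in c("FINDRISC", "LA_FINDRISC", "CUBDRISC")) {
    tab <- dr_score(recs, nm, per_item = TRUE)
    expect_equal(rowSums(tab[, setdiff(names(tab), "total")]), as.numeric(tab$total))
    expect_true(all(tab$total >= 0 & tab$total <= 26))
  }
})

test_that("scoring is deterministic and invariant to record order", {
  recs <- random_records(100, seed = 3)
  s1 <- dr_score(recs, "CUBDRISC")
  s2 <- dr_score(recs, "CUBDRISC")
  expect_identical(s1, s2)
  perm <- sample(nrow(recs))
  expect_identical(dr_score(recs[perm, ], "CUBDRISC"), s1[perm])
})

test_that("for men the Cuban waist band never scores below the Latin-American one", {
  recs <- random_records(500, seed = 11)
  men <- recs[recs$sex == "M", ]
  cu <- dr_score(men, "CUBDRISC", per_item = TRUE)$waist
  la <- dr_score(men, "LA_FINDRISC", per_item = TRUE)$waist
  expect_true(all(cu >= la))
})

test_that("scales agree exactly on records with concordant waist points", {
  # waists below all thresholds, or far above all of them
  low <- zero_risk_record(waist_cm = 70)
  high <- max_risk_record(waist_cm = 120)
  recs <- random_records(100, seed = 5)
  recs$waist_cm <- ifelse(recs$sex == "M", sample(c(70, 130), 100, TRUE),
                          sample(c(70, 130), 100, TRUE))
  for (d in list(low, high, recs)) {
    expect_equal(dr_score(d, "FINDRISC"), dr_score(d, "LA_FINDRISC"))
    expect_equal(dr_score(d, "FINDRISC"), dr_score(d, "CUBDRISC"))
  }
})

test_that("missing items are rejected by name, never imputed", {
  rec <- zero_risk_record()
  rec$waist_cm <- NA
  expect_error(dr_score(rec, "FINDRISC"), "waist")
  rec2 <- zero_risk_record()
  rec2$family_history <- NULL
  expect_error(dr_score(rec2, "FINDRISC"), "family_history")
  rec3 <- zero_risk_record()
  rec3$bmi <- NA
  expect_error(dr_score(rec3, "FINDRISC"), "bmi")
})

test_that("BMI is derived from height and weight only when not given directly", {
  rec <- zero_risk_record()
  rec$bmi <- NA
  rec$height_m <- 1.6
  rec$weight_kg <- 80  # derived BMI 31.25 -> 3 points
  expect_equal(dr_score(rec, "FINDRISC"), 3L)
  rec$bmi <- 22       # explicit value wins -> 0 points
  expect_equal(dr_score(rec, "FINDRISC"), 0L)
})

test_that("risk categories follow the published bands and are monotone", {
  rc <- risk_category(c(6, 13, 21))
  expect_equal(as.character(rc$category), c("low", "moderate", "very_high"))
  expect_equal(rc$ten_year_risk_pct, c(1, 17, 50))
  all_rc <- risk_category(0:26)
  expect_equal(as.character(all_rc$category[c(7, 8, 12, 13, 15, 16, 21, 22)]),
               c("low", "slightly_elevated", "slightly_elevated", "moderate",
                 "moderate", "high", "high", "very_high"))
  expect_true(all(diff(all_rc$ten_year_risk_pct) >= 0))
  expect_error(risk_category(27), "0, 26")
  expect_error(risk_category(-1), "0, 26")
})

test_that("a scale without the waist item tops out at 22", {
  sc <- dr_scale("FINDRISC")
  sc$wc_bands_by_sex <- NULL
  expect_equal(max_score(sc), 22L)
})

test_that("scale definitions survive a JSON round trip", {
  for (nm in c("FINDRISC", "LA_FINDRISC", "CUBDRISC")) {
    sc <- dr_scale(nm)
    back <- scale_from_json(scale_to_json(sc))
    recs <- random_records(50, seed = 7)
    expect_equal(back$name, nm)
    expect_equal(dr_score(recs, back), dr_score(recs, sc))
  }
  path <- tempfile(fileext = ".json")
  scale_to_json(dr_scale("CUBDRISC"), path)
  expect_equal(scale_from_json(path)$name, "CUBDRISC")
})

test_that("participant CSV dialect round-trips", {
  recs <- random_records(30, seed = 9)
  recs$fpg_mmol <- runif(30, 4, 8)
  recs$g2h_mmol <- runif(30, 4, 12)
  path <- tempfile(fileext = ".csv")
  write_participants(recs, path)
  # booleans written as 1/0
  hdr <- readLines(path, n = 2)
  expect_match(hdr[2], ",(0|1),(0|1),(0|1),(0|1),")
  back <- read_participants(path)
  expect_equal(back$physical_activity, recs$physical_activity)
  expect_equal(dr_score(back, "FINDRISC"), dr_score(recs, "FINDRISC"))
  expect_equal(back$fpg_mmol, recs$fpg_mmol, tolerance = 1e-6)
  suppressWarnings(expect_error(read_participants(tempfile()), "cannot open"))
})
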