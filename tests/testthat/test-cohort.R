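test_that("index assignment picks the oldest qualifying note with tie-breaks", {
  notes <- clinical_notes(c("n1", "n2", "n3", "n4", "n5"),
                          c("p1", "p1", "p2", "p2", "p2"),
                          c("2020-05-01", "2019-03-02",
                            "2019-07-01", "2019-02-01", "2019-02-01"),
                          rep("wearable note", 5))
  preds <- data.frame(note_id = paste0("n", 1:5),
                      hard_label = c("positive", "positive", rep("negative", 3)))
  idx <- assign_index(notes, preds)
  p1 <- idx[idx$patient_id == "p1", ]
  expect_identical(p1$group, "prediagnosis")
  expect_identical(p1$index_note_id, "n2")
  expect_identical(p1$index_date, as.Date("2019-03-02"))
  p2 <- idx[idx$patient_id == "p2", ]
  expect_identical(p2$group, "no_prediagnosis")
  expect_identical(p2$index_note_id, "n4")  # date tie n4/n5 -> smaller id
})

test_that("descendant closure handles leaves, cycles and absent concepts", {
  edges <- data.frame(parent = c("a", "a", "b", "x"),
                      child = c("b", "c", "d", "y"))
  expect_setequal(descendants("a", edges), c("a", "b", "c", "d"))
  expect_setequal(descendants("d", edges), "d")
  expect_warning(out <- descendants("zz", edges), "not in hierarchy")
  expect_identical(out, "zz")
  cyc <- data.frame(parent = c("a", "b"), child = c("b", "a"))
  expect_error(descendants("a", cyc), "cycle")
  # diamond shapes are fine
  dia <- data.frame(parent = c("a", "a", "b", "c"),
                    child = c("b", "c", "d", "d"))
  expect_setequal(descendants("a", dia), c("a", "b", "c", "d"))
})

test_that("prior-AF washout is strictly before the index date", {
  assignments <- data.frame(patient_id = c("p1", "p2", "p3"),
                            group = "prediagnosis",
                            index_note_id = c("n1", "n2", "n3"),
                            index_date = as.Date("2020-06-01"))
  conditions <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    concept_code = "313217",
    date = as.Date(c("2020-05-31", "2020-06-01", "2020-07-01")),
    setting = "ambulatory")
  out <- exclude_prior_af(assignments, conditions, "313217")
  expect_setequal(out$patient_id, c("p2", "p3"))
  # occurrences outside ambulatory/inpatient never exclude
  conditions$setting <- "other"
  out2 <- exclude_prior_af(assignments, conditions, "313217")
  expect_identical(nrow(out2), 3L)
})

test_that("the 60-day diagnosis window is inclusive at both ends", {
  assignments <- data.frame(patient_id = c("p1", "p2"),
                            group = c("prediagnosis", "no_prediagnosis"),
                            index_note_id = c("n1", "n2"),
                            index_date = as.Date("2020-01-01"))
  conditions <- data.frame(
    patient_id = c("p1", "p2"),
    concept_code = "313217",
    date = as.Date(c("2020-03-01", "2020-03-02")),  # +60 and +61 days
    setting = "inpatient")
  out <- af_diagnosis_within(assignments, conditions, "313217")
  expect_identical(out$assignments$diagnosed, c(TRUE, FALSE))
  expect_equal(out$mean_lag_days, 60)
})

test_that("cohort plumbing matches brute-force scans on a synthetic panel", {
  cfg <- generator_config(n_patients = 300, seed = 62)
  corp <- generate_notes(cfg)
  ehr <- generate_structured_ehr(cfg, corp$truth)
  lab <- corp$truth$note_labels
  preds <- data.frame(note_id = lab$note_id,
                      hard_label = ifelse(lab$label == "positive",
                                          "positive", "negative"))
  idx <- assign_index(corp$notes, preds)
  # oracle: per-patient loop over notes
  for (p in sample(idx$patient_id, 40)) {
    sub <- corp$notes[corp$notes$patient_id == p, ]
    plab <- preds$hard_label[match(sub$note_id, preds$note_id)]
    pos <- sub[plab == "positive", ]
    pick <- if (nrow(pos)) pos else sub
    pick <- pick[order(pick$note_date, pick$note_id), ][1, ]
    row <- idx[idx$patient_id == p, ]
    expect_identical(row$index_note_id, pick$note_id)
    expect_identical(row$group,
                     if (nrow(pos)) "prediagnosis" else "no_prediagnosis")
  }
  af_codes <- descendants("313217", ehr$concept_edges)
  washed <- exclude_prior_af(idx, ehr$conditions, af_codes)
  prior_oracle <- vapply(idx$patient_id, function(p) {
    cc <- ehr$conditions[ehr$conditions$patient_id == p, ]
    cc <- cc[cc$concept_code %in% af_codes &
               cc$setting %in% c("ambulatory", "inpatient"), ]
    any(as.Date(cc$date) < idx$index_date[idx$patient_id == p])
  }, logical(1))
  expect_setequal(washed$patient_id, idx$patient_id[!prior_oracle])
  dx <- af_diagnosis_within(washed, ehr$conditions, af_codes)$assignments
  for (p in sample(dx$patient_id, 40)) {
    cc <- ehr$conditions[ehr$conditions$patient_id == p, ]
    cc <- cc[cc$concept_code %in% af_codes &
               cc$setting %in% c("ambulatory", "inpatient"), ]
    d0 <- dx$index_date[dx$patient_id == p]
    want <- any(as.Date(cc$date) >= d0 & as.Date(cc$date) <= d0 + 60)
    expect_identical(dx$diagnosed[dx$patient_id == p], want, info = p)
  }
})

test_that("CHA2DS2-VASc reproduces the standard rubric", {
  expect_identical(chads_vasc_score(30, "male")$total, 0L)
  expect_identical(chads_vasc_score(80, "female", hypertension = TRUE)$total, 4L)
  expect_identical(
    chads_vasc_score(80, "female", chf = TRUE, hypertension = TRUE,
                     diabetes = TRUE, stroke = TRUE, vascular = TRUE)$total, 9L)
  s <- chads_vasc_score(70, "missing", tia = TRUE)
  expect_identical(s$total, 3L)  # 2 (TIA) + 1 (age 65-74)
  expect_true(s$sex_missing)
  # age components are mutually exclusive
  expect_identical(chads_vasc_score(75, "male")$components[["age_65_74"]], 0L)
})

test_that("record-based scoring honours the as-of date", {
  conditions <- data.frame(patient_id = "p",
                           concept_code = c("htn", "dm"),
                           date = as.Date(c("2019-01-01", "2021-01-01")))
  s <- chads_vasc_from_record("1950-06-15", "male", conditions, "2020-06-15")
  expect_identical(s$total, 2L)  # age 70 -> 1, hypertension -> 1; dm not yet
})

test_that("Welch one-tailed t matches the reference implementation", {
  set.seed(91)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    got <- welch_t_one_tailed(a, b, "a_greater")
    ref <- t.test(a, b, alternative = "greater", var.equal = FALSE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    got2 <- welch_t_one_tailed(a, b, "b_greater")
    ref2 <- t.test(a, b, alternative = "less", var.equal = FALSE)
    expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-10)
  }
  x <- rnorm(20)
  expect_equal(welch_t_one_tailed(x, x, "a_greater")$p_value, 0.5)
  expect_error(welch_t_one_tailed(1, rnorm(5)), "at least 2")
  expect_error(welch_t_one_tailed(rep(1, 5), rep(2, 6)), "zero variance")
})

test_that("one-tailed p is half the two-tailed p in the observed direction", {
  set.seed(17)
  a <- rnorm(30, 1)
  b <- rnorm(25, 0)
  got <- welch_t_one_tailed(a, b, "a_greater")
  two <- t.test(a, b)$p.value
  expect_equal(got$p_value, two / 2, tolerance = 1e-12)
})

test_that("chi-squared matches the reference and the textbook formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  got <- chi_square(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # direct formula evaluation
  expect_equal(got$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  same <- matrix(c(15, 30, 15, 30), 2)
  got2 <- chi_square(same)
  expect_equal(got2$statistic, 0)
  expect_equal(got2$p_value, 1)
  race_shape <- matrix(rpois(12, 30) + 1, nrow = 6)
  expect_identical(chi_square(race_shape)$df, 5L)
  bad <- matrix(c(0, 0, 5, 5), 2)
  expect_error(chi_square(bad), "zero expected")
})

test_that("relative risk reproduces raw and printed-percentage conventions", {
  expect_equal(relative_risk(305, 1037, 262, 16560, "printed_percent"), 18.61)
  raw <- relative_risk(305, 1037, 262, 16560, "raw")
  expect_equal(raw, (305 / 1037) / (262 / 16560), tolerance = 1e-12)
  expect_equal(round(raw, 2), 18.59)
  expect_equal(relative_risk(10, 100, 20, 200, "raw"), 1)
  expect_equal(relative_risk(30, 300, 60, 600, "raw"),
               relative_risk(10, 100, 20, 200, "raw"))
  expect_error(relative_risk(1, 10, 0, 10), "undefined")
})

test_that("printed percentages follow the half-up display convention", {
  expect_equal(pct(525, 1037), 50.63)
  expect_equal(pct(5936, 16560), 35.85)
  expect_equal(pct(305, 1037), 29.41)
  expect_equal(pct(262, 16560), 1.58)
  expect_equal(pct(53509, 56924, 0), 94)
  expect_equal(round_half_up(105 / 600, 2), 0.18)
  expect_equal(round_half_up(100 / 600, 2), 0.17)
})

test_that("comparison tables tabulate counts exactly and need both groups", {
  cfg <- generator_config(n_patients = 500, seed = 83)
  corp <- generate_notes(cfg)
  ehr <- generate_structured_ehr(cfg, corp$truth)
  lab <- corp$truth$note_labels
  preds <- data.frame(note_id = lab$note_id,
                      hard_label = ifelse(lab$label == "positive",
                                          "positive", "negative"))
  cs <- run_cohort_study(corp$notes, preds, ehr)
  tab <- cs$tables$all$table
  n1 <- cs$tables$all$group_sizes[["prediagnosis"]]
  n2 <- cs$tables$all$group_sizes[["no_prediagnosis"]]
  # partition: group sizes sum to assignments minus missing-sex exclusions
  sexes <- ehr$patients$sex[match(cs$assignments$patient_id,
                                  ehr$patients$patient_id)]
  expect_identical(n1 + n2, sum(sexes %in% c("male", "female")))
  # sex row counts equal a direct per-patient tabulation
  keep <- sexes %in% c("male", "female")
  g1 <- cs$assignments$group[keep] == "prediagnosis"
  sex_rows <- tab[tab$characteristic == "sex", ]
  expect_identical(sex_rows$group1_n[sex_rows$level == "male"],
                   sum(sexes[keep][g1] == "male"))
  expect_identical(sex_rows$group2_n[sex_rows$level == "female"],
                   sum(sexes[keep][!g1] == "female"))
  # hypertension counts equal a brute-force per-patient check at index date
  af_idx <- cs$assignments$index_date[keep]
  htn <- vapply(which(keep), function(i) {
    p <- cs$assignments$patient_id[i]
    cc <- ehr$conditions[ehr$conditions$patient_id == p &
                           ehr$conditions$concept_code == "htn", ]
    any(as.Date(cc$date) <= cs$assignments$index_date[i])
  }, logical(1))
  expect_identical(tab$group1_n[tab$characteristic == "hypertension"],
                   sum(htn[g1]))
  # categorical percentages sum to 100 within rounding
  race_rows <- tab[tab$characteristic == "race_ethnicity", ]
  expect_lt(abs(sum(race_rows$group1_value) - 100), 0.1)
  # monotonicity across stages
  expect_lte(sum(cs$tables$no_prior_af$group_sizes),
             sum(cs$tables$all$group_sizes))
  expect_lte(sum(cs$tables$diagnosed$group_sizes),
             sum(cs$tables$no_prior_af$group_sizes))
  # empty comparison group errors
  all_neg <- data.frame(note_id = lab$note_id, hard_label = "negative")
  expect_error(run_cohort_study(corp$notes, all_neg, ehr), "empty")
})
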