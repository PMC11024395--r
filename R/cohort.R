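# Retrospective cohort procedures: index-note selection, concept-hierarchy
# descendants, prior-AF washout, 60-day diagnosis windows, CHA2DS2-VASc
# scoring and the two-group characteristics tables.

# Concept code of the atrial fibrillation root in the terminology hierarchy.
AF_ROOT_CODE <- "313217"

#' Assign each patient an index note and study group
#'
#' The oldest classifier-positive note is the index note (group
#' `prediagnosis`); patients without any positive note anchor on their
#' oldest wearable note (group `no_prediagnosis`).  Date ties break to the
#' lexicographically smallest `note_id`.
#'
#' @param notes A note table (already restricted to wearable notes).
#' @param predictions Data frame with `note_id` and `hard_label`
#'   ("positive"/"negative") for every note.
#' @return Data frame with `patient_id`, `group`, `index_note_id`,
#'   `index_date`.
#' @export
assign_index <- function(notes, predictions) {
  lab <- predictions$hard_label[match(notes$note_id, predictions$note_id)]
  if (anyNA(lab)) stop("assign_index(): every note needs a prediction")
  pick_oldest <- function(df) {
    df <- df[order(df$note_date, df$note_id), , drop = FALSE]
    df[1L, ]
  }
  out <- lapply(split(seq_len(nrow(notes)), notes$patient_id), function(i) {
    sub <- notes[i, , drop = FALSE]
    pos <- sub[lab[i] == "positive", , drop = FALSE]
    if (nrow(pos) > 0L) {
      idx <- pick_oldest(pos)
      grp <- "prediagnosis"
    } else {
      idx <- pick_oldest(sub)
      grp <- "no_prediagnosis"
    }
    data.frame(patient_id = idx$patient_id, group = grp,
               index_note_id = idx$note_id, index_date = idx$note_date,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Transitive descendants of a concept code
#'
#' The concept plus everything reachable through parent-to-child edges.
#' Errors when a cycle is reachable from the concept; a concept absent from
#' the hierarchy returns itself with a warning.
#'
#' @param concept Concept code (character scalar).
#' @param hierarchy Data frame of edges with columns `parent`, `child`.
#' @return Character vector of codes (the concept first).
#' @export
descendants <- function(concept, hierarchy) {
  concept <- as.character(concept)
  parent <- as.character(hierarchy$parent)
  child <- as.character(hierarchy$child)
  if (!concept %in% c(parent, child)) {
    warning("descendants(): concept ", concept, " not in hierarchy")
    return(concept)
  }
  # depth-first search with an explicit recursion stack for cycle detection
  visited <- character(0)
  on_stack <- character(0)
  dfs <- function(node) {
    if (node %in% on_stack) {
      stop("descendants(): cycle detected in hierarchy at concept ", node)
    }
    if (node %in% visited) return(invisible(NULL))
    visited <<- c(visited, node)
    on_stack <<- c(on_stack, node)
    for (ch in child[parent == node]) dfs(ch)
    on_stack <<- setdiff(on_stack, node)
    invisible(NULL)
  }
  dfs(concept)
  visited
}

#' Exclude patients with an AF diagnosis before their index note
#'
#' Removes patients having any ambulatory or inpatient condition occurrence
#' coded with an AF concept strictly before the index date (washout).
#'
#' @param assignments Output of [assign_index()].
#' @param conditions Data frame with `patient_id`, `concept_code`, `date`,
#'   `setting`.
#' @param af_codes AF concept codes, typically `descendants("313217", ...)`.
#' @return The filtered assignments.
#' @export
exclude_prior_af <- function(assignments, conditions, af_codes) {
  conditions$date <- as_date(conditions$date)
  af <- conditions[conditions$concept_code %in% af_codes &
                     conditions$setting %in% c("ambulatory", "inpatient"), ,
                   drop = FALSE]
  idx_date <- assignments$index_date[match(af$patient_id,
                                           assignments$patient_id)]
  prior <- unique(af$patient_id[!is.na(idx_date) & af$date < idx_date])
  assignments[!assignments$patient_id %in% prior, , drop = FALSE]
}

#' AF diagnosis within a window after the index note
#'
#' Flags patients whose earliest ambulatory/inpatient AF-coded occurrence
#' falls inside `[index_date, index_date + window_days]` (both ends
#' inclusive) and reports the mean index-to-diagnosis lag among diagnosed
#' prediagnosis-group patients.
#'
#' @param assignments Assignments after [exclude_prior_af()].
#' @param conditions Condition occurrence table.
#' @param af_codes AF concept codes.
#' @param window_days Window length (default 60).
#' @return List with `assignments` (input plus `diagnosed`,
#'   `diagnosis_date`, `diagnosis_code`) and `mean_lag_days`.
#' @export
af_diagnosis_within <- function(assignments, conditions, af_codes,
                                window_days = 60) {
  conditions$date <- as_date(conditions$date)
  af <- conditions[conditions$concept_code %in% af_codes &
                     conditions$setting %in% c("ambulatory", "inpatient"), ,
                   drop = FALSE]
  assignments$diagnosed <- FALSE
  assignments$diagnosis_date <- as.Date(NA)
  assignments$diagnosis_code <- NA_character_
  by_patient <- split(af, af$patient_id)
  for (i in seq_len(nrow(assignments))) {
    sub <- by_patient[[assignments$patient_id[i]]]
    if (is.null(sub)) next
    d0 <- assignments$index_date[i]
    inside <- sub$date >= d0 & sub$date <= d0 + window_days
    if (any(inside)) {
      sub <- sub[inside, , drop = FALSE]
      first <- which.min(sub$date)
      assignments$diagnosed[i] <- TRUE
      assignments$diagnosis_date[i] <- sub$date[first]
      assignments$diagnosis_code[i] <- sub$concept_code[first]
    }
  }
  pre <- assignments$group == "prediagnosis" & assignments$diagnosed
  mean_lag <- if (any(pre)) {
    mean(as.numeric(assignments$diagnosis_date[pre] -
                      assignments$index_date[pre]))
  } else {
    NA_real_
  }
  list(assignments = assignments, mean_lag_days = mean_lag)
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Standard rubric: congestive heart failure 1, hypertension 1, age >= 75
#' years 2, diabetes 1, prior stroke/TIA/thromboembolism 2, vascular
#' disease 1, age 65-74 years 1, female sex 1; total 0-9.  The two age
#' components are mutually exclusive.  Missing sex scores 0 on the sex
#' component and raises the `sex_missing` flag.
#'
#' @param age Age in completed years.
#' @param sex `"male"`, `"female"` or `"missing"`.
#' @param chf,hypertension,diabetes,stroke,tia,vascular Logical component
#'   flags (stroke and TIA both feed the 2-point component).
#' @return List with `total`, `components` (named points vector) and
#'   `sex_missing`.
#' @export
#' @examples
#' chads_vasc_score(80, "female", hypertension = TRUE)$total # 4
chads_vasc_score <- function(age, sex, chf = FALSE, hypertension = FALSE,
                             diabetes = FALSE, stroke = FALSE, tia = FALSE,
                             vascular = FALSE) {
  stopifnot(is.numeric(age), length(age) == 1L)
  sex <- match.arg(sex, c("male", "female", "missing"))
  comp <- c(
    chf = as.integer(chf),
    hypertension = as.integer(hypertension),
    age_ge_75 = if (age >= 75) 2L else 0L,
    diabetes = as.integer(diabetes),
    stroke_tia = if (stroke || tia) 2L else 0L,
    vascular = as.integer(vascular),
    age_65_74 = if (age >= 65 && age < 75) 1L else 0L,
    female = if (sex == "female") 1L else 0L
  )
  list(total = sum(comp), components = comp, sex_missing = sex == "missing")
}

# Default mapping from characteristic names to synthetic concept codes.
default_condition_codes <- function() {
  list(chf = "chf", hypertension = "htn", diabetes = "dm",
       stroke = "stroke", tia = "tia", vascular = "vasc")
}

#' Score CHA2DS2-VASc from condition occurrences
#'
#' Component flags come from condition occurrences dated on or before
#' `as_of`; age is computed at `as_of`.
#'
#' @param birth_date,sex Patient demographics.
#' @param conditions This patient's condition occurrences (`concept_code`,
#'   `date`).
#' @param as_of Scoring date.
#' @param code_map Named list mapping components (`chf`, `hypertension`,
#'   `diabetes`, `stroke`, `tia`, `vascular`) to concept-code vectors.
#' @return As [chads_vasc_score()].
#' @export
chads_vasc_from_record <- function(birth_date, sex, conditions, as_of,
                                   code_map = default_condition_codes()) {
  as_of <- as_date(as_of)
  active <- conditions[as_date(conditions$date) <= as_of, , drop = FALSE]
  has <- function(component) {
    any(active$concept_code %in% code_map[[component]])
  }
  chads_vasc_score(age_at(birth_date, as_of), sex,
                   chf = has("chf"), hypertension = has("hypertension"),
                   diabetes = has("diabetes"), stroke = has("stroke"),
                   tia = has("tia"), vascular = has("vascular"))
}

# ---- comparison tables ----------------------------------------------------

row_categorical <- function(section, label, x1, x2, n1, n2) {
  counts <- rbind(x1, x2)
  keep <- colSums(counts) > 0  # levels absent from both groups are omitted
  counts <- counts[, keep, drop = FALSE]
  test <- chi_square(t(counts))
  data.frame(section = section, characteristic = label,
             level = colnames(counts),
             group1_n = as.integer(counts[1L, ]),
             group1_value = pct(counts[1L, ], n1),
             group2_n = as.integer(counts[2L, ]),
             group2_value = pct(counts[2L, ], n2),
             test = "chi_square", statistic = test$statistic,
             p_value = test$p_value, stringsAsFactors = FALSE,
             row.names = NULL)
}

row_binary <- function(section, label, k1, k2, n1, n2) {
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  test <- chi_square(tab)
  data.frame(section = section, characteristic = label, level = label,
             group1_n = k1, group1_value = pct(k1, n1),
             group2_n = k2, group2_value = pct(k2, n2),
             test = "chi_square", statistic = test$statistic,
             p_value = test$p_value, stringsAsFactors = FALSE)
}

row_continuous <- function(section, label, x1, x2, direction) {
  test <- welch_t_one_tailed(x1, x2, direction)
  data.frame(section = section, characteristic = label, level = "mean_sd",
             group1_n = length(x1), group1_value = mean(x1),
             group2_n = length(x2), group2_value = mean(x2),
             test = "welch_t_one_tailed", statistic = test$statistic,
             p_value = test$p_value, stringsAsFactors = FALSE)
}

#' Two-group cohort characteristics table
#'
#' Builds the characteristics table for one analysis stage:
#' \describe{
#'   \item{`all`}{every patient with an index assignment;}
#'   \item{`no_prior_af`}{after the prior-AF washout;}
#'   \item{`diagnosed`}{patients diagnosed with AF inside the window,
#'     characterized at the index diagnosis date, with AF subtype,
#'     medication and cardioversion rows added (only the first prescription
#'     or procedure within 60 days of the index diagnosis counts; drugs
#'     never prescribed are omitted).}
#' }
#' Demographics (mean age, race/ethnicity, sex), comorbidity prevalences
#' and the mean CHA2DS2-VASc score are compared between the prediagnosis
#' and no-prediagnosis groups with the configured one-tailed Welch t test
#' (continuous) or chi-squared test (categorical).  Patients missing sex
#' are excluded from the table.  P values are unadjusted.
#'
#' @param assignments Index assignments for the requested stage (for
#'   `diagnosed`, the output of [af_diagnosis_within()] restricted to
#'   diagnosed patients).
#' @param ehr A synthetic EHR bundle ([generate_structured_ehr()]) or any
#'   list with `patients`, `conditions`, `drugs`, `procedures`.
#' @param stage `"all"`, `"no_prior_af"` or `"diagnosed"`.
#' @param directions Named list mapping continuous characteristics to the
#'   one-tailed direction; defaults to the prediagnosis group being older
#'   with higher scores.
#' @param code_map Component-to-code map, as in [chads_vasc_from_record()].
#' @param window_days Medication/procedure window after the index diagnosis
#'   (default 60).
#' @return List with `table` (data frame of rows), `group_sizes`, `stage`.
#' @export
build_comparison_table <- function(assignments, ehr,
                                   stage = c("all", "no_prior_af", "diagnosed"),
                                   directions = list(age = "a_greater",
                                                     chads_vasc = "a_greater"),
                                   code_map = default_condition_codes(),
                                   window_days = 60) {
  stage <- match.arg(stage)
  patients <- ehr$patients
  conditions <- ehr$conditions
  conditions$date <- as_date(conditions$date)
  pat <- patients[match(assignments$patient_id, patients$patient_id), ]
  keep <- !is.na(pat$sex) & pat$sex %in% c("male", "female")
  assignments <- assignments[keep, , drop = FALSE]
  pat <- pat[keep, , drop = FALSE]

  g1 <- assignments$group == "prediagnosis"
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf(paste0("build_comparison_table(): a comparison group is ",
                        "empty or too small (prediagnosis %d, ",
                        "no_prediagnosis %d)"), n1, n2))
  }
  as_of <- if (stage == "diagnosed") {
    as_date(assignments$diagnosis_date)
  } else {
    as_date(assignments$index_date)
  }

  age <- age_at(pat$birth_date, as_of)
  race_levels <- c("Asian", "Black", "Hispanic", "White", "Others",
                   "Undisclosed")
  race <- factor(pat$race_ethnicity, levels = race_levels)
  cond_by_pat <- split(conditions, conditions$patient_id)
  flags <- vapply(seq_len(nrow(pat)), function(i) {
    sub <- cond_by_pat[[pat$patient_id[i]]]
    if (is.null(sub)) sub <- conditions[0, ]
    active <- sub[sub$date <= as_of[i], , drop = FALSE]
    vapply(c("chf", "hypertension", "diabetes", "vascular", "stroke", "tia"),
           function(cmp) any(active$concept_code %in% code_map[[cmp]]),
           logical(1))
  }, logical(6))
  chads <- vapply(seq_len(nrow(pat)), function(i) {
    chads_vasc_score(age[i], pat$sex[i],
                     chf = flags["chf", i],
                     hypertension = flags["hypertension", i],
                     diabetes = flags["diabetes", i],
                     stroke = flags["stroke", i], tia = flags["tia", i],
                     vascular = flags["vascular", i])$total
  }, numeric(1))

  rows <- list(
    row_continuous("demographics", "age", age[g1], age[!g1],
                   directions$age %||% "a_greater"),
    row_categorical("demographics", "race_ethnicity",
                    table(race[g1]), table(race[!g1]), n1, n2),
    row_categorical("demographics", "sex",
                    table(factor(pat$sex[g1], c("male", "female"))),
                    table(factor(pat$sex[!g1], c("male", "female"))), n1, n2),
    row_binary("comorbidities", "congestive_heart_failure",
               sum(flags["chf", g1]), sum(flags["chf", !g1]), n1, n2),
    row_binary("comorbidities", "hypertension",
               sum(flags["hypertension", g1]), sum(flags["hypertension", !g1]),
               n1, n2),
    row_binary("comorbidities", "diabetes",
               sum(flags["diabetes", g1]), sum(flags["diabetes", !g1]), n1, n2),
    row_binary("comorbidities", "vascular_disease",
               sum(flags["vascular", g1]), sum(flags["vascular", !g1]), n1, n2),
    row_continuous("scores", "chads_vasc", chads[g1], chads[!g1],
                   directions$chads_vasc %||% "a_greater")
  )

  if (stage == "diagnosed") {
    subtype <- factor(ehr$subtype_map[assignments$diagnosis_code],
                      levels = c("generic", "chronic", "paroxysmal",
                                 "persistent"))
    rows <- c(rows, list(
      row_categorical("diagnosis", "af_subtype",
                      table(subtype[g1]), table(subtype[!g1]), n1, n2)
    ))
    drugs <- ehr$drugs
    drugs$date <- as_date(drugs$date)
    med_groups <- list(anticoagulant = afwatch_lexicon("anticoagulant"),
                       rhythm_management = afwatch_lexicon("rhythm"))
    for (sec in names(med_groups)) {
      for (drug in med_groups[[sec]]$terms) {
        on_drug <- vapply(seq_len(nrow(assignments)), function(i) {
          sub <- drugs[drugs$patient_id == assignments$patient_id[i] &
                         tolower(drugs$drug_name) == drug, , drop = FALSE]
          if (nrow(sub) == 0L) return(FALSE)
          first <- min(sub$date)  # index prescription only
          first >= as_of[i] & first <= as_of[i] + window_days
        }, logical(1))
        k1 <- sum(on_drug[g1])
        k2 <- sum(on_drug[!g1])
        if (k1 + k2 == 0L) next  # drugs never prescribed are omitted
        rows <- c(rows, list(row_binary(sec, drug, k1, k2, n1, n2)))
      }
    }
    procs <- ehr$procedures
    procs$date <- as_date(procs$date)
    cardio <- vapply(seq_len(nrow(assignments)), function(i) {
      sub <- procs[procs$patient_id == assignments$patient_id[i] &
                     procs$name == "cardioversion", , drop = FALSE]
      if (nrow(sub) == 0L) return(FALSE)
      first <- min(sub$date)
      first >= as_of[i] & first <= as_of[i] + window_days
    }, logical(1))
    rows <- c(rows, list(row_binary("procedures", "cardioversion",
                                    sum(cardio[g1]), sum(cardio[!g1]),
                                    n1, n2)))
  }

  list(table = do.call(rbind, rows),
       group_sizes = c(prediagnosis = n1, no_prediagnosis = n2),
       stage = stage)
}

#' Run the full retrospective cohort study
#'
#' Chains index assignment, prior-AF washout, the diagnosis window and the
#' three stage tables, and computes the relative risk of a clinician
#' diagnosis between the two groups (printed-percentage convention).
#'
#' @param notes Wearable note table.
#' @param predictions Hard classifier labels per note.
#' @param ehr Structured EHR bundle ([generate_structured_ehr()]).
#' @param window_days Diagnosis window (default 60).
#' @param af_root AF root concept code (default "313217").
#' @return List with `assignments`, `washed` (post-washout assignments),
#'   `diagnosis` (flags + mean lag), `tables` (per stage),
#'   `relative_risk`, `diagnosis_rates`.
#' @export
run_cohort_study <- function(notes, predictions, ehr, window_days = 60,
                             af_root = AF_ROOT_CODE) {
  assignments <- assign_index(notes, predictions)
  af_codes <- descendants(af_root, ehr$concept_edges)
  washed <- exclude_prior_af(assignments, ehr$conditions, af_codes)
  diag <- af_diagnosis_within(washed, ehr$conditions, af_codes, window_days)
  da <- diag$assignments
  g1 <- da$group == "prediagnosis"
  a <- sum(da$diagnosed[g1])
  b <- sum(da$diagnosed[!g1])
  rr <- if (sum(g1) > 0 && sum(!g1) > 0 && b > 0) {
    relative_risk(a, sum(g1), b, sum(!g1), "printed_percent")
  } else {
    NA_real_
  }
  tables <- list(
    all = build_comparison_table(assignments, ehr, "all"),
    no_prior_af = build_comparison_table(washed, ehr, "no_prior_af"),
    diagnosed = build_comparison_table(da[da$diagnosed, , drop = FALSE], ehr,
                                       "diagnosed", window_days = window_days)
  )
  rate <- function(k, n) if (n > 0) pct(k, n) else NA_real_
  list(assignments = assignments, washed = washed, diagnosis = diag,
       tables = tables, relative_risk = rr,
       diagnosis_rates = c(prediagnosis = rate(a, sum(g1)),
                           no_prediagnosis = rate(b, sum(!g1))))
}
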