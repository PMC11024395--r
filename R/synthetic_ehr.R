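# Seeded synthetic-EHR generator: template-based clinical notes with known
# ground truth (wearable AF prediagnosis mentions, negated variants,
# boilerplate distractors) plus linked structured tables (patients,
# conditions with a concept hierarchy, drug exposures, procedures), so the
# whole pipeline runs end to end without any protected data.

#' Generator configuration
#'
#' Defaults emulate the study conditions of the surveillance corpus: note
#' prevalence of a true prediagnosis 0.18, an even mix over the 8 positive
#' sentence patterns, a modest share of negated variants and meditation
#' boilerplate distractors, notes dated 2019-2022.  `hard = TRUE` adds a
#' fraction of positives that evade the labeling functions (out-of-lexicon
#' surface forms or slot gaps beyond the matcher's token-gap tolerance),
#' creating irreducible label-model false negatives.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient_mean Mean notes per patient (1 + Poisson).
#' @param prevalence Probability a note carries a true prediagnosis
#'   (default 0.18, the manually labeled test-set prevalence).
#' @param pattern_mix Weights over the 8 positive templates (sum to 1).
#' @param negation_rate Fraction of negative notes that are negated-AF
#'   variants (default 0.15).
#' @param distractor_rate Fraction of negative notes that are wearable
#'   boilerplate distractors (default 0.25); remaining negatives split 2:1
#'   between wearable-without-AF and AF-without-wearable.
#' @param date_range Two dates bounding note dates.
#' @param filler_max Maximum filler tokens inserted between pattern slots
#'   (default 2; keep at or below the labeling-function gap tolerance for a
#'   canonical, fully separable corpus).
#' @param hard Add hard positives (default FALSE).
#' @param hard_fraction Fraction of positives made hard when `hard = TRUE`
#'   (default 0.3; half out-of-lexicon wording, half oversized slot gaps).
#' @param prior_af_rate_pos,prior_af_rate_neg Probability of an AF
#'   diagnosis predating the first note, for patients with / without a true
#'   prediagnosis.
#' @param diag_rate_pos,diag_rate_neg Probability of a clinician AF
#'   diagnosis within the 60-day observation window for the two groups
#'   (defaults 0.2941 and 0.0158, the published within-window rates).
#' @param diag_lag_mean Mean prediagnosis-to-diagnosis lag in days
#'   (default 4.74).
#' @param missing_race_fraction Fraction of patients with undisclosed race
#'   and ethnicity (default 0.1112, the published fraction).
#' @param seed Mandatory seed.
#' @return A list of class `afwatch_generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             notes_per_patient_mean = 2,
                             prevalence = 0.18,
                             pattern_mix = rep(1 / 8, 8),
                             negation_rate = 0.15,
                             distractor_rate = 0.25,
                             date_range = c("2019-01-01", "2022-12-31"),
                             filler_max = 2,
                             hard = FALSE,
                             hard_fraction = 0.3,
                             prior_af_rate_pos = 0.5,
                             prior_af_rate_neg = 0.13,
                             diag_rate_pos = 0.2941,
                             diag_rate_neg = 0.0158,
                             diag_lag_mean = 4.74,
                             missing_race_fraction = 0.1112,
                             seed = NULL) {
  if (is.null(seed)) stop("generator_config(): seed is mandatory")
  rates <- c(prevalence, negation_rate, distractor_rate, hard_fraction,
             prior_af_rate_pos, prior_af_rate_neg, diag_rate_pos,
             diag_rate_neg, missing_race_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("generator_config(): probabilities must lie in [0, 1]")
  }
  if (abs(sum(pattern_mix) - 1) > 1e-8 || length(pattern_mix) != 8L) {
    stop("generator_config(): pattern_mix must be 8 weights summing to 1")
  }
  structure(as.list(environment()), class = "afwatch_generator_config")
}

# surface-form pools ---------------------------------------------------------

.pos_wearables <- c("Apple Watch", "Fitbit", "Kardia", "smartwatch",
                    "smart watch", "AliveCor", "Galaxy Watch", "wearable")
.pos_af <- c("afib", "AF", "a.fib", "atrial fibrillation", "a-fib",
             "irregular heartbeat", "irregular rhythm", "atrial fib",
             "irregular pulse", "paf")
.verbs_past <- c("noted", "detected", "recorded", "showed", "observed",
                 "captured", "identified", "registered", "reported")
.verbs_notify <- c("notified", "alerted", "warned")
.verbs_receive <- c("Received", "Got", "Noticed", "Saw")
.event_nouns <- c("notification", "alert", "alarm", "warning", "reading")
.fillers <- c("the", "his", "her", "their", "a", "new", "this", "today",
              "overnight", "yesterday", "morning", "routine", "recent",
              "again", "repeatedly")

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

filler_tokens <- function(n) {
  if (n <= 0) return("")
  paste0(paste(sample(.fillers, n, replace = TRUE), collapse = " "), " ")
}

# One positive sentence realizing pattern `p` (1..8) with up to `gmax`
# filler tokens in each inter-slot gap.
realize_positive <- function(p, gmax) {
  w <- sample(.pos_wearables, 1)
  af <- sample(.pos_af, 1)
  g <- function() filler_tokens(sample.int(gmax + 1L, 1L) - 1L)
  switch(p,
    sprintf("%s in chart. Patient wears %s%s, %s mentioned with %s.",
            cap_first(af), g(), w, sample(.event_nouns, 1), af),
    sprintf("%s %swas %s %son %s%s.", cap_first(af), g(),
            sample(.verbs_past, 1), g(), g(), w),
    sprintf("%s %s%s %s%s.", cap_first(w), g(), sample(.verbs_notify, 1),
            g(), af),
    sprintf("%s %s%s showing %s%s.", sample(c("Observed", "Checked", "Saw"), 1),
            g(), w, g(), af),
    sprintf("%s %s%s from %s%s.", sample(.verbs_receive, 1), g(), af, g(), w),
    sprintf("%s %s%s from %s%s of %s.", sample(c("Got", "Received"), 1), g(),
            sample(.event_nouns, 1), g(), w, af),
    sprintf("%s %son %s %sof %s.", cap_first(sample(c("notification", "alert",
            "alarm"), 1)), g(), w, g(), af),
    sprintf("Per %s%s, patient %s%s %s.", g(), w, g(),
            sample(c("had", "has", "showed", "reported"), 1), af)
  )
}

# Concessive prefixes that place a negation trigger in front of the AF term
# without negating it.  Joined with a comma they sit inside the same
# sentence, so the sentence-scoped negation rule wrongly suppresses every
# labeling function (a classic clinical-negation scoping error); joined with
# a period they are a separate sentence and the functions fire.  The word
# n-gram representation of the two variants is identical (punctuation is not
# a token), which is what lets a trained classifier recover the suppressed
# notes and generalize beyond the rules.
.concessive_prefixes <- c("Though not symptomatic",
                          "Although without palpitations at rest",
                          "No associated chest pain",
                          "Patient not aware of symptoms")

realize_negated <- function() {
  w <- sample(.pos_wearables, 1)
  af <- sample(.pos_af, 1)
  switch(sample.int(3L, 1L),
    sprintf("%s %s no %s.", cap_first(w), sample(.verbs_past, 1), af),
    sprintf("Patient denies %s; %s readings unremarkable.", af, w),
    sprintf("Ruled out %s on %s after full review.", af, w)
  )
}

realize_wearable_only <- function() {
  w <- sample(.pos_wearables, 1)
  switch(sample.int(3L, 1L),
    sprintf("Patient checked %s daily for step counts.", w),
    sprintf("Uses a %s to track sleep and exercise.", w),
    sprintf("%s synced at visit; counseling on activity goals.", cap_first(w))
  )
}

realize_af_only <- function() {
  af <- sample(.pos_af, 1)
  switch(sample.int(2L, 1L),
    sprintf("History of %s, rate controlled on current regimen.", af),
    sprintf("ECG in clinic confirmed %s; cardiology follow up arranged.", af)
  )
}

realize_distractor <- function() {
  w <- sample(c("wearable", "smartwatch", "smart watch", "fitness tracker"), 1)
  switch(sample.int(3L, 1L),
    sprintf("We recommend the use of a %s during guided meditation sessions.",
            w),
    sprintf("Wellness handout provided: breathing exercises and %s based mindfulness programs.",
            w),
    sprintf("Patient counseled to consider a %s for general activity tracking as part of lifestyle advice.",
            w)
  )
}

.boilerplate <- c("Patient seen in clinic today.", "Vitals stable.",
                  "Plan discussed and questions answered.",
                  "Follow up in three months.",
                  "Medication list reviewed and reconciled.")

#' Generate a synthetic note corpus with ground truth
#'
#' Positive notes realize one of the 8 canonical sentence patterns with
#' sampled wearable / AF / verb surface forms and filler tokens; negative
#' notes are negated-AF variants, meditation-style boilerplate distractors,
#' wearable mentions without AF, or AF without a wearable.  Byte-identical
#' output for identical configuration (seed included).
#'
#' @param config A [generator_config()].
#' @return List with `notes` (a [clinical_notes()] table), `truth` (list
#'   holding `note_labels`, `patients` with per-patient prediagnosis /
#'   diagnosis / prior-AF dates and demographics).
#' @export
generate_notes <- function(config) {
  stopifnot(inherits(config, "afwatch_generator_config"))
  with_seed(config$seed, {
    np <- config$n_patients
    patient_id <- sprintf("P%05d", seq_len(np))
    sex <- sample(c("male", "female"), np, replace = TRUE,
                  prob = c(0.44, 0.56))
    sex[stats::runif(np) < 0.003] <- "missing"
    age0 <- pmin(pmax(round(stats::rnorm(np, 55, 16)), 23), 95)
    race_pool <- c(Asian = 0.165, Black = 0.033, Hispanic = 0.091,
                   White = 0.66, Others = 0.009)
    race <- ifelse(stats::runif(np) < config$missing_race_fraction,
                   "Undisclosed",
                   sample(names(race_pool), np, replace = TRUE,
                          prob = race_pool / sum(race_pool)))
    n_notes <- 1L + stats::rpois(np, max(config$notes_per_patient_mean - 1, 0))
    pid <- rep(patient_id, n_notes)
    n <- length(pid)
    d0 <- as_date(config$date_range[1])
    d1 <- as_date(config$date_range[2])
    note_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                                 replace = TRUE) - 1L
    # positivity: base prevalence with mild age/sex effects, intercept
    # calibrated so the marginal rate equals the configured prevalence
    page <- rep(age0, n_notes)
    psex <- rep(sex, n_notes)
    eff <- 0.25 * (page - 55) / 10 + 0.35 * (psex == "male")
    alpha <- if (config$prevalence == 0) {
      -Inf
    } else if (config$prevalence == 1) {
      Inf
    } else {
      stats::uniroot(function(a) mean(stats::plogis(a + eff)) -
                       config$prevalence, c(-20, 20))$root
    }
    positive <- stats::runif(n) < stats::plogis(alpha + eff)
    # negative subtype mix
    neg_kind <- sample(c("negated", "distractor", "wearable_only", "af_only"),
                       n, replace = TRUE,
                       prob = c(config$negation_rate, config$distractor_rate,
                                2 / 3 * (1 - config$negation_rate -
                                           config$distractor_rate),
                                1 / 3 * (1 - config$negation_rate -
                                           config$distractor_rate)))
    # hard mode: a fraction of positives carry a concessive prefix; when the
    # prefix shares the sentence (comma join, 40%) the negation rule
    # suppresses every labeling function and the note is an irreducible
    # label-model false negative
    prefixed <- config$hard & positive & stats::runif(n) < config$hard_fraction
    suppressed <- prefixed & stats::runif(n) < 0.4
    pattern <- sample.int(8L, n, replace = TRUE, prob = config$pattern_mix)
    if (any(prefixed)) {
      # the dictionary-lookup template spans two sentences and would evade
      # the prefix, so prefixed notes draw from the grammatical patterns
      p28 <- config$pattern_mix[2:8]
      pattern[prefixed] <- sample(2:8, sum(prefixed), replace = TRUE,
                                  prob = if (sum(p28) > 0) p28 else rep(1, 7))
    }
    text <- character(n)
    for (i in seq_len(n)) {
      core <- if (positive[i]) {
        realize_positive(pattern[i], config$filler_max)
      } else {
        switch(neg_kind[i],
               negated = realize_negated(),
               distractor = realize_distractor(),
               wearable_only = realize_wearable_only(),
               af_only = realize_af_only())
      }
      if (prefixed[i]) {
        core <- paste0(sample(.concessive_prefixes, 1),
                       if (suppressed[i]) ", " else ". ", core)
      }
      pre <- sample(.boilerplate, 1)
      post <- sample(.boilerplate, 1)
      text[i] <- paste(pre, core, post)
    }
    notes <- clinical_notes(sprintf("N%06d", seq_len(n)), pid, note_date, text)
    note_labels <- data.frame(
      note_id = notes$note_id,
      label = ifelse(positive, "positive", "negative"),
      hard = suppressed, stringsAsFactors = FALSE)

    # patient-level truth
    first_note <- as.Date(vapply(split(note_date, pid), min, 0),
                          origin = "1970-01-01")[patient_id]
    prediag <- rep(as.Date(NA), np)
    for (j in which(positive)) {
      k <- match(pid[j], patient_id)
      if (is.na(prediag[k]) || note_date[j] < prediag[k]) {
        prediag[k] <- note_date[j]
      }
    }
    has_pre <- !is.na(prediag)
    prior_af <- stats::runif(np) <
      ifelse(has_pre, config$prior_af_rate_pos, config$prior_af_rate_neg)
    prior_af_date <- rep(as.Date(NA), np)
    prior_af_date[prior_af] <- first_note[prior_af] -
      (30L + sample.int(1000L, sum(prior_af), replace = TRUE))
    diag <- stats::runif(np) <
      ifelse(has_pre, config$diag_rate_pos, config$diag_rate_neg)
    diag_date <- rep(as.Date(NA), np)
    # the configured diagnosis rates are within-60-day rates, so lags fall
    # inside the observation window for both groups
    lag_pos <- 1L + stats::rgeom(np, 1 / config$diag_lag_mean)
    lag_neg <- sample.int(61L, np, replace = TRUE) - 1L
    diag_date[diag & has_pre] <- prediag[diag & has_pre] +
      lag_pos[diag & has_pre]
    diag_date[diag & !has_pre] <- first_note[diag & !has_pre] +
      lag_neg[diag & !has_pre]
    birth_date <- first_note - round(age0 * 365.25) -
      sample.int(180L, np, replace = TRUE)

    truth <- list(
      note_labels = note_labels,
      patients = data.frame(
        patient_id = patient_id, birth_date = birth_date, sex = sex,
        race_ethnicity = race, first_note_date = first_note,
        prediagnosis_date = prediag, prior_af_date = prior_af_date,
        af_diagnosis_date = diag_date, stringsAsFactors = FALSE)
    )
    list(notes = notes, truth = truth)
  })
}

# concept hierarchy: AF root with two levels of descendants plus an
# unrelated decoy branch (all codes synthetic)
af_concept_edges <- function() {
  data.frame(
    parent = c("313217", "313217", "313217",
               "3132171", "3132172", "3132173",
               "195080", "195080"),
    child = c("3132171", "3132172", "3132173",
              "31321711", "31321721", "31321731",
              "1950801", "1950802"),
    stringsAsFactors = FALSE
  )
}

af_subtype_map <- function() {
  c("313217" = "generic",
    "3132171" = "paroxysmal", "31321711" = "paroxysmal",
    "3132172" = "chronic", "31321721" = "chronic",
    "3132173" = "persistent", "31321731" = "persistent")
}

#' Generate linked structured EHR tables
#'
#' Builds demographics, condition occurrences (comorbidities with onset
#' dates; AF occurrences coded at the synthetic AF root `313217` or one of
#' its generated descendants, dated per the ground truth), drug exposures
#' drawn from the anticoagulant / rhythm-management lexicons, cardioversion
#' procedures, and the rooted concept-hierarchy edge list (two levels of AF
#' descendants plus a decoy branch).
#'
#' @param config The [generator_config()] used for the notes.
#' @param truth Ground truth from [generate_notes()].
#' @return A list of class `afwatch_ehr` with `patients`, `conditions`,
#'   `drugs`, `procedures`, `concept_edges`, `subtype_map`.
#' @export
generate_structured_ehr <- function(config, truth) {
  pts <- truth$patients
  np <- nrow(pts)
  with_seed(config$seed + 1L, {
    age <- age_at(pts$birth_date, pts$first_note_date)
    cond_rate <- function(base, slope) {
      stats::plogis(base + slope * (age - 55))
    }
    draw <- function(p) stats::runif(np) < p
    comorb <- list(
      chf = draw(cond_rate(-2.9, 0.045)),
      htn = draw(cond_rate(-0.7, 0.055)),
      dm = draw(cond_rate(-3.0, 0.02)),
      stroke = draw(cond_rate(-3.6, 0.03)),
      tia = draw(cond_rate(-4.0, 0.03)),
      vasc = draw(cond_rate(-2.7, 0.04))
    )
    cond_rows <- list()
    for (code in names(comorb)) {
      has <- comorb[[code]]
      k <- sum(has)
      if (k == 0L) next
      onset <- pts$first_note_date[has] -
        sample.int(2000L, k, replace = TRUE)
      # a few late onsets exercise the as-of filtering
      late <- stats::runif(k) < 0.05
      onset[late] <- pts$first_note_date[has][late] +
        sample.int(400L, sum(late), replace = TRUE)
      cond_rows[[code]] <- data.frame(
        patient_id = pts$patient_id[has], concept_code = code, date = onset,
        setting = sample(c("ambulatory", "inpatient", "other"), k,
                         replace = TRUE, prob = c(0.7, 0.2, 0.1)),
        stringsAsFactors = FALSE)
    }
    af_codes_all <- c("313217", "3132171", "3132172", "3132173",
                      "31321711", "31321721", "31321731")
    subtype_prob <- c(0.78, 0.08, 0.08, 0.004, 0.004, 0.026, 0.026)
    af_occurrence <- function(ids, dates) {
      k <- length(ids)
      data.frame(patient_id = ids,
                 concept_code = sample(af_codes_all, k, replace = TRUE,
                                       prob = subtype_prob),
                 date = dates,
                 setting = sample(c("ambulatory", "inpatient"), k,
                                  replace = TRUE, prob = c(0.65, 0.35)),
                 stringsAsFactors = FALSE)
    }
    prior <- !is.na(pts$prior_af_date)
    if (any(prior)) {
      cond_rows$prior_af <- af_occurrence(pts$patient_id[prior],
                                          pts$prior_af_date[prior])
    }
    dx <- !is.na(pts$af_diagnosis_date)
    if (any(dx)) {
      cond_rows$af_dx <- af_occurrence(pts$patient_id[dx],
                                       pts$af_diagnosis_date[dx])
    }
    conditions <- do.call(rbind, cond_rows)
    rownames(conditions) <- NULL

    # drug exposures: mostly within 60 days of the AF diagnosis, slightly
    # more anticoagulation for prediagnosed patients; beta blockers also
    # among hypertensives without AF
    has_pre <- !is.na(pts$prediagnosis_date)
    drug_rows <- list()
    drug_probs <- list(
      apixaban = c(0.25, 0.15), rivaroxaban = c(0.10, 0.04),
      warfarin = c(0.01, 0.012), metoprolol = c(0.17, 0.17),
      carvedilol = c(0.005, 0.01), labetalol = c(0.02, 0.015),
      atenolol = c(0.01, 0.02), flecainide = c(0.055, 0.03),
      propafenone = c(0.023, 0.008), verapamil = c(0.01, 0.008),
      diltiazem = c(0.05, 0.035), amlodipine = c(0.013, 0.011),
      digoxin = c(0.01, 0.004)
    )
    for (drug in names(drug_probs)) {
      p <- ifelse(has_pre, drug_probs[[drug]][1], drug_probs[[drug]][2])
      take <- dx & (stats::runif(np) < p)
      k <- sum(take)
      if (k == 0L) next
      lag <- sample.int(75L, k, replace = TRUE) - 1L  # some beyond the window
      drug_rows[[drug]] <- data.frame(
        patient_id = pts$patient_id[take], drug_name = drug,
        date = pts$af_diagnosis_date[take] + lag, stringsAsFactors = FALSE)
    }
    bb <- comorb$htn & !dx & draw(0.15)
    if (any(bb)) {
      drug_rows$htn_bb <- data.frame(
        patient_id = pts$patient_id[bb], drug_name = "metoprolol",
        date = pts$first_note_date[bb] +
          sample.int(200L, sum(bb), replace = TRUE) - 100L,
        stringsAsFactors = FALSE)
    }
    drugs <- do.call(rbind, drug_rows)
    if (is.null(drugs)) {
      drugs <- data.frame(patient_id = character(), drug_name = character(),
                          date = as.Date(character()))
    }
    rownames(drugs) <- NULL

    cardio <- dx & draw(0.08)
    procedures <- data.frame(
      patient_id = pts$patient_id[cardio],
      name = rep("cardioversion", sum(cardio)),
      date = pts$af_diagnosis_date[cardio] +
        sample.int(60L, sum(cardio), replace = TRUE) - 1L,
      stringsAsFactors = FALSE)

    structure(list(
      patients = pts[, c("patient_id", "birth_date", "sex", "race_ethnicity")],
      conditions = conditions, drugs = drugs, procedures = procedures,
      concept_edges = af_concept_edges(), subtype_map = af_subtype_map()
    ), class = "afwatch_ehr")
  })
}

#' Write the synthetic corpus and tables to disk
#'
#' Notes as JSON lines; structured tables as CSV (`patients.csv`,
#' `conditions.csv`, `drugs.csv`, `procedures.csv`, `concept_edges.csv`).
#'
#' @param corpus Output of [generate_notes()].
#' @param ehr Output of [generate_structured_ehr()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_ehr <- function(corpus, ehr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_notes_jsonl(corpus$notes, file.path(dir, "notes.jsonl"))
  utils::write.csv(corpus$truth$note_labels,
                   file.path(dir, "note_labels.csv"), row.names = FALSE)
  for (tab in c("patients", "conditions", "drugs", "procedures",
                "concept_edges")) {
    utils::write.csv(ehr[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Sample a gold-labeled evaluation set
#'
#' Emulates manual labeling: picks `n` patients at random, one note each,
#' and attaches the ground-truth label; `split` tags the set as test or
#' development.
#'
#' @param corpus Output of [generate_notes()].
#' @param n Number of notes (default 600).
#' @param split `"test"` or `"development"`.
#' @param seed Seed.
#' @param exclude_note_ids Notes never to select (e.g. the other split).
#' @return Data frame with `note_id`, `gold_label`, `split`.
#' @export
sample_gold_set <- function(corpus, n = 600, split = "test", seed = 1L,
                            exclude_note_ids = character(0)) {
  notes <- corpus$notes[!corpus$notes$note_id %in% exclude_note_ids, ,
                        drop = FALSE]
  with_seed(seed, {
    pids <- sample(unique(notes$patient_id),
                   min(n, length(unique(notes$patient_id))))
    ids <- vapply(pids, function(p) {
      sub <- notes$note_id[notes$patient_id == p]
      if (length(sub) == 1L) sub else sample(sub, 1L)
    }, "")
    lab <- corpus$truth$note_labels
    data.frame(note_id = unname(ids),
               gold_label = lab$label[match(ids, lab$note_id)],
               split = split, stringsAsFactors = FALSE)
  })
}
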