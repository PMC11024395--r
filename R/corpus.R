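# Note/patient data model, cohort note filters, sentence segmentation with
# coarse part-of-speech tags, and the classifier token budget.

#' Construct a clinical note table
#'
#' @param note_id Unique note identifiers.
#' @param patient_id Patient identifiers.
#' @param note_date Note dates (`Date` or ISO-8601 strings).
#' @param text Free note text.
#' @return A data frame with one row per note.
#' @export
clinical_notes <- function(note_id, patient_id, note_date, text) {
  note_id <- as.character(note_id)
  if (anyDuplicated(note_id)) stop("clinical_notes(): note_id must be unique")
  note_date <- as_date(note_date)
  if (anyNA(note_date)) stop("clinical_notes(): note_date must be ISO-8601")
  df <- data.frame(note_id = note_id, patient_id = as.character(patient_id),
                   note_date = note_date, text = as.character(text),
                   stringsAsFactors = FALSE)
  class(df) <- c("afwatch_notes", class(df))
  df
}

#' Read / write a note corpus as JSON lines
#'
#' One JSON object per line with fields `note_id`, `patient_id`,
#' `note_date`, `text`.
#'
#' @param path File path.
#' @param notes For writing, a note table from [clinical_notes()].
#' @return `read_notes_jsonl()` returns a note table.
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  clinical_notes(
    vapply(recs, `[[`, "", "note_id"),
    vapply(recs, `[[`, "", "patient_id"),
    vapply(recs, `[[`, "", "note_date"),
    vapply(recs, `[[`, "", "text")
  )
}

#' @rdname read_notes_jsonl
#' @export
write_notes_jsonl <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(note_id = notes$note_id[i],
                          patient_id = notes$patient_id[i],
                          note_date = format(notes$note_date[i]),
                          text = notes$text[i]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter notes into the surveillance cohort
#'
#' Retains notes that (1) mention a wearable device, (2) belong to a patient
#' at least `min_age` completed years old on the note date (birthday
#' inclusive), and (3) are dated on or after `cutoff_date` (the first
#' consumer AF-detection feature release).  Filters are applied in that
#' order and per-filter exclusion counts are reported.  Notes whose patient
#' has no birth date are excluded with their own reason rather than
#' failing.  Filtering is idempotent.
#'
#' @param notes A note table ([clinical_notes()]).
#' @param birth_dates Data frame with `patient_id` and `birth_date`.
#' @param cutoff_date Earliest admissible note date (default "2019-01-01").
#' @param min_age Minimum age in completed years at the note date (default 22).
#' @param wearable Wearable [term_lexicon()]; default the built-in one.
#' @return A list with `notes` (retained rows) and `exclusions` (data frame
#'   of `reason`, `n`).
#' @export
filter_notes_for_cohort <- function(notes, birth_dates,
                                    cutoff_date = "2019-01-01",
                                    min_age = 22, wearable = NULL) {
  wearable <- wearable %||% afwatch_lexicon("wearable")
  cutoff_date <- as_date(cutoff_date)
  bd <- as_date(birth_dates$birth_date)[match(notes$patient_id,
                                              as.character(birth_dates$patient_id))]
  excl <- c(no_wearable_mention = 0L, missing_birth_date = 0L,
            under_min_age = 0L, before_cutoff_date = 0L)

  keep <- texts_with_terms(notes$text, wearable)
  excl["no_wearable_mention"] <- sum(!keep)

  known <- !is.na(bd)
  excl["missing_birth_date"] <- sum(keep & !known)
  keep <- keep & known

  old_enough <- rep(FALSE, nrow(notes))
  old_enough[keep] <- age_at(bd[keep], notes$note_date[keep]) >= min_age
  excl["under_min_age"] <- sum(keep & !old_enough)
  keep <- keep & old_enough

  recent <- notes$note_date >= cutoff_date
  excl["before_cutoff_date"] <- sum(keep & !recent)
  keep <- keep & recent

  list(notes = notes[keep, , drop = FALSE],
       exclusions = data.frame(reason = names(excl), n = as.integer(excl),
                               stringsAsFactors = FALSE))
}

.prepositions <- c("on", "in", "of", "from", "per", "by", "at", "with", "to",
                   "for", "via", "during", "over", "through", "off", "onto",
                   "into")
.aux_verbs <- c("is", "are", "was", "were", "be", "been", "being", "am",
                "do", "does", "did", "can", "could", "will", "would", "may",
                "might", "shall", "should")
.subject_terms <- c("patient", "patients", "pt", "pts", "he", "she", "they",
                    "man", "woman")

# Coarse tags for one sentence's word tokens.
tag_tokens <- function(tokens, action, event) {
  tag <- rep("other", length(tokens))
  tag[tokens %in% event$terms] <- "noun"
  tag[tokens %in% .subject_terms] <- "noun"
  verb <- is_action_token(tokens, action) | tokens %in% .aux_verbs
  tag[verb & tag == "other"] <- "verb"
  tag[tokens %in% .prepositions] <- "prep"
  tag
}

#' Segment a note into sentences with tagged tokens
#'
#' Deterministic rule-based segmentation: sentence boundaries at newlines
#' and at `.`, `!` or `?` followed by whitespace and an upper-case letter or
#' digit (or end of text).  Dotted medical abbreviations such as "a.fib" are
#' never split because the period is not followed by whitespace plus a
#' capital.  Each word token carries a coarse part-of-speech tag from
#' \{`noun`, `verb`, `prep`, `other`\}: prepositions from a closed list,
#' verbs from the action-term stems plus auxiliaries, nouns from the
#' event-noun and subject lists.
#'
#' @param text A single note text (or a one-row note table).
#' @param lexicons Named lexicon list from [afwatch_lexicons()] (defaults to
#'   the built-ins).
#' @return A list of sentence annotations; each is a list with `start`,
#'   `end` (1-based inclusive offsets into `text`), `text`, and `tokens`
#'   (data frame `surface`, `tag`, `start`, `end` with offsets into the full
#'   note text).
#' @export
#' @examples
#' length(segment_and_tag("Wearable notified AF. Patient asymptomatic."))
segment_and_tag <- function(text, lexicons = NULL) {
  if (is.data.frame(text)) text <- text$text[[1L]]
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  lexicons <- lexicons %||% afwatch_lexicons()
  n <- nchar(text)
  if (n == 0L) return(list())

  # boundary positions: last character of each sentence-terminating run
  bounds <- integer(0)
  punct <- gregexpr("[.!?]+", text)[[1L]]
  if (punct[1L] != -1L) {
    ends <- as.integer(punct) + attr(punct, "match.length") - 1L
    for (e in ends) {
      rest <- substr(text, e + 1L, n)
      if (grepl("^\\s*$", rest) || grepl("^\\s+[A-Z0-9]", rest)) {
        bounds <- c(bounds, e)
      }
    }
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  if (nl[1L] != -1L) bounds <- c(bounds, as.integer(nl))
  bounds <- sort(unique(c(bounds, n)))

  action <- lexicons$action
  event <- lexicons$event
  out <- list()
  sent_start <- 1L
  for (b in bounds) {
    seg <- substr(text, sent_start, b)
    # trim whitespace but keep offsets
    lead <- regmatches(seg, regexpr("^\\s*", seg))
    s0 <- sent_start + nchar(lead)
    seg_trim <- sub("\\s+$", "", sub("^\\s*", "", seg))
    if (nzchar(seg_trim)) {
      e0 <- s0 + nchar(seg_trim) - 1L
      toks <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9\\s]", seg_trim, perl = TRUE)[[1L]]
      tok_df <- if (toks[1L] == -1L) {
        data.frame(surface = character(), tag = character(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE)
      } else {
        ts <- as.integer(toks)
        te <- ts + attr(toks, "match.length") - 1L
        surf <- substring(seg_trim, ts, te)
        data.frame(surface = surf,
                   tag = tag_tokens(tolower(surf), action, event),
                   start = s0 + ts - 1L, end = s0 + te - 1L,
                   stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- list(start = s0, end = e0, text = seg_trim,
                                      tokens = tok_df)
    }
    sent_start <- b + 1L
  }
  out
}

#' Sentences containing a wearable mention
#'
#' @param annotations Output of [segment_and_tag()].
#' @param mentions Wearable mention data frame from [find_term_mentions()]
#'   (offsets into the same note text).
#' @return The subset of `annotations` whose span intersects at least one
#'   mention, in document order.
#' @export
select_candidate_sentences <- function(annotations, mentions) {
  if (length(annotations) == 0L || is.null(mentions) || nrow(mentions) == 0L) {
    return(list())
  }
  keep <- vapply(annotations, function(s) {
    any(mentions$start <= s$end & mentions$end >= s$start)
  }, logical(1))
  annotations[keep]
}

# Word/punctuation tokenization used for the input-length budget.  The
# transformer vocabulary itself is out of scope, so "subword token" is
# defined by this tokenizer and the budget is configurable.
count_tokens <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9\\s]", text, perl = TRUE)
  vapply(m, function(x) if (x[1L] == -1L) 0L else length(x), integer(1))
}

#' Trim note text to a token budget
#'
#' Truncates at the tail on a token boundary so the retained text has at
#' most `budget` tokens; shorter notes are returned unchanged.
#'
#' @param text Character vector of note texts.
#' @param budget Maximum token count (default 4096).
#' @return Character vector of trimmed texts.
#' @export
trim_to_token_budget <- function(text, budget = 4096) {
  stopifnot(budget > 0)
  vapply(text, function(tx) {
    m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9\\s]", tx, perl = TRUE)[[1L]]
    if (m[1L] == -1L || length(m) <= budget) return(tx)
    cut <- as.integer(m[budget]) + attr(m, "match.length")[budget] - 1L
    substr(tx, 1L, cut)
  }, "", USE.NAMES = FALSE)
}

#' Proportion of notes within the token budget
#'
#' Corpus-level report: the printed percentage of notes whose token count
#' fits the classifier input budget, and the count trimmed.
#'
#' @param notes A note table.
#' @param budget Token budget (default 4096).
#' @param digits Decimal digits of the printed percentage (default 0).
#' @return List with `n_within`, `n_total`, `percent_within`.
#' @export
token_budget_report <- function(notes, budget = 4096, digits = 0) {
  n <- count_tokens(notes$text)
  list(n_within = sum(n <= budget), n_total = length(n),
       percent_within = pct(sum(n <= budget), length(n), digits))
}
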