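# Labeling functions: one-sided heuristics that vote POSITIVE or abstain on
# a note.  Eight functions are defined: a dictionary lookup plus seven
# grammatical patterns over AF terms, action verbs, event nouns,
# prepositions and wearable mentions, all with negation suppression.

.negation_single <- c("no", "not", "denies", "denied", "without", "never")
.negation_bigrams <- list(c("negative", "for"), c("ruled", "out"))
.negation_resets <- c("but", "however")

#' Detect negation of an AF mention within a sentence
#'
#' True when a negation trigger ("no", "not", "denies", "without",
#' "negative for", "ruled out", "never") precedes the mention within the
#' sentence and no conjunction reset ("but", "however") intervenes between
#' the trigger and the mention.
#'
#' @param sentence A sentence annotation from [segment_and_tag()].
#' @param af_mention A mention row (offsets into the same note text as the
#'   sentence annotation).
#' @return Logical flag.
#' @export
detect_negation <- function(sentence, af_mention) {
  toks <- sentence$tokens
  if (nrow(toks) == 0L) return(FALSE)
  before <- which(toks$end < af_mention$start)
  if (length(before) == 0L) return(FALSE)
  surf <- tolower(toks$surface[before])
  neg <- FALSE
  i <- 1L
  while (i <= length(surf)) {
    w <- surf[i]
    if (w %in% .negation_resets) {
      neg <- FALSE
    } else if (w %in% .negation_single) {
      neg <- TRUE
    } else if (i < length(surf)) {
      for (bg in .negation_bigrams) {
        if (w == bg[1L] && surf[i + 1L] == bg[2L]) {
          neg <- TRUE
          i <- i + 1L
          break
        }
      }
    }
    i <- i + 1L
  }
  neg
}

# Map a character span to the indices of word tokens it overlaps.
span_token_range <- function(tokens, start, end) {
  idx <- which(tokens$start <= end & tokens$end >= start)
  if (length(idx) == 0L) return(NULL)
  c(min(idx), max(idx))
}

# Slot candidate token ranges for one sentence.  Each candidate is an
# integer pair (first token index, last token index).
lf_slot_candidates <- function(sentence, af_mentions, wearable_mentions,
                               action, event) {
  toks <- sentence$tokens
  surf <- tolower(toks$surface)
  span_list <- function(mentions) {
    if (is.null(mentions) || nrow(mentions) == 0L) return(list())
    out <- lapply(seq_len(nrow(mentions)), function(i) {
      span_token_range(toks, mentions$start[i], mentions$end[i])
    })
    out[!vapply(out, is.null, logical(1))]
  }
  single <- function(idx) lapply(idx, function(i) c(i, i))
  verb_idx <- which(toks$tag == "verb")
  event_idx <- which(surf %in% event$terms | is_action_token(surf, action))
  subj_idx <- which(surf %in% .subject_terms)
  prep_idx <- which(toks$tag == "prep")
  list(af = span_list(af_mentions),
       wearable = span_list(wearable_mentions),
       verb = single(verb_idx),
       prep = single(prep_idx),
       event = single(event_idx),
       subject = single(subj_idx))
}

# Ordered slot patterns for LF2-LF8 (LF1 is the grammar-free dictionary
# lookup handled separately).
.lf_patterns <- list(
  `2` = c("af", "verb", "prep", "wearable"),
  `3` = c("wearable", "verb", "af"),
  `4` = c("verb", "wearable", "verb", "af"),
  `5` = c("verb", "af", "prep", "wearable"),
  `6` = c("verb", "event", "prep", "wearable", "af"),
  `7` = c("event", "prep", "wearable", "af"),
  `8` = c("wearable", "subject", "verb", "af")
)

# Is there an assignment of non-overlapping candidates in slot order with at
# most `gap` word tokens between consecutive slots?  Depth-first search;
# sentences are short.
match_slot_pattern <- function(cands, gap) {
  n <- length(cands)
  rec <- function(k, prev_end) {
    if (k > n) return(TRUE)
    for (r in cands[[k]]) {
      if (prev_end < 0L || (r[1L] > prev_end && r[1L] - prev_end - 1L <= gap)) {
        if (rec(k + 1L, r[2L])) return(TRUE)
      }
    }
    FALSE
  }
  rec(1L, -1L)
}

#' Apply one labeling function to a sentence
#'
#' LF1 is a dictionary lookup and is scored at note level by
#' [assemble_vote_matrix()]; called here it votes POSITIVE when the sentence
#' itself holds an unnegated AF mention, a wearable mention and an
#' action/event term.  LF2-LF8 vote POSITIVE when the sentence realizes the
#' function's ordered slot pattern (AF term, action verb, preposition, event
#' noun, subject, wearable mention as the pattern requires) with at most
#' `gap` intervening word tokens between consecutive slots and an unnegated
#' AF mention; otherwise they abstain.
#'
#' @param lf_id Integer 1-8.
#' @param sentence A sentence annotation from [segment_and_tag()].
#' @param wearable_mentions,af_mentions Mention data frames with offsets
#'   into the note text.
#' @param lexicons Lexicon list (defaults to built-ins).
#' @param gap Maximum word tokens between consecutive pattern slots
#'   (default 5).
#' @return `"POSITIVE"` or `"ABSTAIN"`.
#' @export
lf_apply <- function(lf_id, sentence, wearable_mentions, af_mentions,
                     lexicons = NULL, gap = 5) {
  if (!lf_id %in% 1:8) stop("lf_apply(): unknown lf_id ", lf_id)
  lexicons <- lexicons %||% afwatch_lexicons()
  if (is.null(af_mentions) || nrow(af_mentions) == 0L) return("ABSTAIN")
  unneg <- af_mentions[!vapply(seq_len(nrow(af_mentions)), function(i) {
    detect_negation(sentence, af_mentions[i, ])
  }, logical(1)), , drop = FALSE]
  if (nrow(unneg) == 0L) return("ABSTAIN")
  cands <- lf_slot_candidates(sentence, unneg, wearable_mentions,
                              lexicons$action, lexicons$event)
  if (lf_id == 1L) {
    ok <- length(cands$af) > 0L && length(cands$wearable) > 0L &&
      length(cands$event) > 0L
    return(if (ok) "POSITIVE" else "ABSTAIN")
  }
  pattern <- .lf_patterns[[as.character(lf_id)]]
  if (any(vapply(cands[pattern], length, integer(1)) == 0L)) return("ABSTAIN")
  if (match_slot_pattern(cands[pattern], gap)) "POSITIVE" else "ABSTAIN"
}

# All 8 votes for one note text.  Returns an integer vector lf1..lf8 with
# 1 = POSITIVE, 0 = ABSTAIN.
apply_lfs_note <- function(text, lexicons, gap = 5) {
  votes <- integer(8L)
  ann <- segment_and_tag(text, lexicons)
  if (length(ann) == 0L) return(votes)
  has_unneg_af <- FALSE
  has_wearable <- FALSE
  has_event <- FALSE
  for (s in ann) {
    af <- find_term_mentions(s$text, lexicons$af)
    wear <- find_term_mentions(s$text, lexicons$wearable)
    if (nrow(af) > 0L) {
      af$start <- af$start + s$start - 1L
      af$end <- af$end + s$start - 1L
    }
    if (nrow(wear) > 0L) {
      wear$start <- wear$start + s$start - 1L
      wear$end <- wear$end + s$start - 1L
      has_wearable <- TRUE
    }
    surf <- tolower(s$tokens$surface)
    if (any(surf %in% lexicons$event$terms) ||
        any(is_action_token(surf, lexicons$action))) {
      has_event <- TRUE
    }
    if (nrow(af) > 0L) {
      unneg <- !vapply(seq_len(nrow(af)), function(i) {
        detect_negation(s, af[i, ])
      }, logical(1))
      if (any(unneg)) has_unneg_af <- TRUE
    }
    if (nrow(wear) > 0L && nrow(af) > 0L) {
      for (id in 2:8) {
        if (votes[id] == 0L &&
            lf_apply(id, s, wear, af, lexicons, gap) == "POSITIVE") {
          votes[id] <- 1L
        }
      }
    }
  }
  # LF1: dictionary lookup across the whole note, ignoring grammar
  if (has_unneg_af && has_wearable && has_event) votes[1L] <- 1L
  votes
}

#' Assemble the labeling-function vote matrix
#'
#' Applies all 8 labeling functions to every note.  A note-level vote is
#' POSITIVE when any sentence yields POSITIVE for that function (OR
#' aggregation); abstain is explicit as 0.  Notes lacking either an AF term
#' or a wearable term are all-abstain by construction and skip the per
#' sentence work.
#'
#' @param notes A note table ([clinical_notes()]).
#' @param lexicons Lexicon list (defaults to built-ins).
#' @param gap Maximum word tokens between consecutive pattern slots
#'   (default 5).
#' @return A data frame with `note_id` and columns `lf1`..`lf8` holding
#'   1 (POSITIVE) / 0 (ABSTAIN), rows in input order.
#' @export
assemble_vote_matrix <- function(notes, lexicons = NULL, gap = 5) {
  lexicons <- lexicons %||% afwatch_lexicons()
  n <- nrow(notes)
  votes <- matrix(0L, nrow = n, ncol = 8L,
                  dimnames = list(NULL, paste0("lf", 1:8)))
  needs_work <- texts_with_terms(notes$text, lexicons$af) &
    texts_with_terms(notes$text, lexicons$wearable)
  for (i in which(needs_work)) {
    votes[i, ] <- apply_lfs_note(notes$text[i], lexicons, gap)
  }
  cbind(data.frame(note_id = notes$note_id, stringsAsFactors = FALSE),
        as.data.frame(votes))
}

#' Per-function empirical metrics against gold labels
#'
#' Scores each labeling function as a binary predictor with abstain counted
#' as a negative prediction, so per-function accuracy is defined:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R), accuracy = (TP+TN)/n.
#'
#' @param vote_matrix Output of [assemble_vote_matrix()].
#' @param gold Data frame with `note_id` and `gold_label`
#'   ("positive"/"negative"); every gold note must be present in the matrix.
#' @return Data frame with one row per function and the four metrics.
#' @export
lf_empirical_metrics <- function(vote_matrix, gold) {
  if (nrow(gold) == 0L) stop("lf_empirical_metrics(): empty gold set")
  idx <- match(gold$note_id, vote_matrix$note_id)
  if (anyNA(idx)) stop("lf_empirical_metrics(): gold notes missing from matrix")
  truth <- gold$gold_label == "positive"
  out <- lapply(1:8, function(j) {
    pred <- vote_matrix[[paste0("lf", j)]][idx] == 1L
    m <- binary_metrics(pred, truth)
    data.frame(lf = paste0("lf", j), precision = m$precision,
               recall = m$recall, f1 = m$f1, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Confusion-matrix metrics for logical prediction/truth vectors.
binary_metrics <- function(pred, truth) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = (tp + tn) / length(truth))
}
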