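#' afwatch: weak-supervision surveillance of wearable AF prediagnoses
#'
#' End-to-end pipeline: term lexicons and gazetteer matching
#' ([afwatch_lexicon()], [find_term_mentions()]), cohort note filters and
#' sentence annotation ([filter_notes_for_cohort()], [segment_and_tag()]),
#' eight labeling functions with negation handling
#' ([assemble_vote_matrix()]), a generative label model fit by EM
#' ([fit_label_model()]), a noise-aware n-gram classifier
#' ([train_noise_aware()]), the retrospective cohort analysis
#' ([run_cohort_study()]) and a seeded synthetic-EHR generator
#' ([generate_notes()]).
#'
#' @keywords internal
"_PACKAGE"

#' Weak-label a corpus end to end
#'
#' Convenience wrapper: assembles the labeling-function vote matrix, fits
#' the generative label model and returns probabilistic plus hardened
#' labels for every note.
#'
#' @param notes A note table.
#' @param lexicons Lexicon list (defaults to built-ins).
#' @param gap Labeling-function slot-gap tolerance (default 5).
#' @param seed Seed for the label-model initialization.
#' @param threshold Hardening threshold (default 0.5).
#' @return List with `votes`, `model`, `labels` (note_id, p_positive,
#'   hard_label).
#' @export
weak_label_corpus <- function(notes, lexicons = NULL, gap = 5, seed = 1L,
                              threshold = 0.5) {
  lexicons <- lexicons %||% afwatch_lexicons()
  votes <- assemble_vote_matrix(notes, lexicons, gap)
  model <- fit_label_model(votes, seed = seed)
  labels <- harden_labels(predict_proba(model, votes), threshold)
  list(votes = votes, model = model, labels = labels)
}
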