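# Independent brute-force oracles used across the suite.  These deliberately
# re-derive expected values by enumeration or textbook formulas, never by
# calling the code paths they check.

# exhaustive-offset gazetteer: try every lexicon term at every character
# offset of the normalized text, keep longest-leftmost non-overlapping
oracle_find_mentions <- function(text, terms) {
  norm <- tolower(gsub("\\s+", " ", text))
  norm <- sub("^ ", "", sub(" $", "", norm))
  cand <- list()
  for (term in terms) {
    L <- nchar(term)
    if (L > nchar(norm)) next
    for (s in seq_len(nchar(norm) - L + 1L)) {
      if (substr(norm, s, s + L - 1L) != term) next
      pre <- if (s > 1L) substr(norm, s - 1L, s - 1L) else ""
      post <- if (s + L <= nchar(norm)) substr(norm, s + L, s + L) else ""
      first <- substr(term, 1L, 1L)
      last <- substr(term, L, L)
      ok <- TRUE
      if (grepl("[a-z0-9]", first) && grepl("[a-z0-9]", pre)) ok <- FALSE
      if (grepl("[a-z0-9]", last) && grepl("[a-z0-9]", post)) ok <- FALSE
      if (ok) cand[[length(cand) + 1L]] <- c(s, s + L - 1L)
    }
  }
  if (length(cand) == 0L) return(character(0))
  cand <- cand[order(vapply(cand, `[`, 0, 1L),
                     -vapply(cand, function(x) x[2] - x[1], 0))]
  out <- character(0)
  last_end <- -1L
  for (cc in cand) {
    if (cc[1] > last_end) {
      out <- c(out, substr(norm, cc[1], cc[2]))
      last_end <- cc[2]
    }
  }
  out
}

# positional scan: negation trigger token before the AF token position with
# no reset token in between
oracle_negated <- function(tokens, af_pos) {
  singles <- c("no", "not", "denies", "denied", "without", "never")
  resets <- c("but", "however")
  state <- FALSE
  i <- 1L
  while (i < af_pos) {
    tk <- tokens[i]
    if (tk %in% resets) state <- FALSE
    if (tk %in% singles) state <- TRUE
    if (i + 1L < af_pos) {
      if ((tk == "negative" && tokens[i + 1L] == "for") ||
          (tk == "ruled" && tokens[i + 1L] == "out")) {
        state <- TRUE
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  state
}

# closed-form posterior for the one-sided emission model, coded directly
# from Bayes' rule over an explicit vote vector
oracle_posterior <- function(votes, prior, accuracy, propensity) {
  lik <- function(y) {
    p <- if (y == 1) propensity * accuracy else propensity * (1 - accuracy)
    prod(ifelse(votes == 1, p, 1 - p))
  }
  prior * lik(1) / (prior * lik(1) + (1 - prior) * lik(0))
}

# confusion-count metrics computed with explicit loops
oracle_confusion_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = pr, recall = rc,
       f1 = if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0,
       accuracy = (tp + tn) / length(pred))
}

# CHA2DS2-VASc rubric restated as an explicit points table
oracle_chads <- function(age, sex, chf, htn, dm, stroke, tia, vasc) {
  pts <- 0L
  if (chf) pts <- pts + 1L
  if (htn) pts <- pts + 1L
  if (dm) pts <- pts + 1L
  if (vasc) pts <- pts + 1L
  if (stroke || tia) pts <- pts + 2L
  if (age >= 75) pts <- pts + 2L else if (age >= 65) pts <- pts + 1L
  if (identical(sex, "female")) pts <- pts + 1L
  pts
}

# breadth-first traversal of a parent->child edge list
oracle_bfs_descendants <- function(root, edges) {
  seen <- root
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- edges$child[edges$parent %in% frontier]
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# small corpus of hand-written notes with known per-LF expectations
lf_example_notes <- function() {
  data.frame(
    text = c("AF noted on wearable",
             "Wearable notified AF",
             "Observed wearable showing AF",
             "Received AF from wearable",
             "Got notification from wearable of AF",
             "Notified on wearable of AF",
             "Per wearable, patient had AF",
             "Apple Watch showed no afib",
             "patient exercised daily"),
    stringsAsFactors = FALSE)
}

make_notes <- function(texts, patient = NULL, dates = "2020-06-01") {
  n <- length(texts)
  clinical_notes(sprintf("n%03d", seq_len(n)),
                 patient %||% sprintf("p%03d", seq_len(n)),
                 rep_len(dates, n), texts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
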