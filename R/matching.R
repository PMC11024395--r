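# Gazetteer matching: normalization with an offset map back to the original
# string, longest-match term location on token boundaries, and the
# action-term vicinity rule used to enrich candidate notes.

# Vectorized normalization without an offset map (lowercase, collapse runs of
# whitespace to a single space, trim ends).
normalize_string <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

#' Normalize note text with an offset map
#'
#' Lowercases and collapses whitespace while recording, for every character
#' of the normalized string, its position in the original string, so matches
#' found on normalized text can be reported as spans of the source note.
#' Normalization is idempotent.
#'
#' @param text A single character string.
#' @return A list with `text` (normalized string) and `map` (integer vector:
#'   `map[i]` is the 1-based original position of normalized character `i`).
#' @export
#' @examples
#' normalize_text("Apple  Watch")$text
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) == 0L) return(list(text = "", map = integer(0)))
  chars <- strsplit(tolower(text), "", fixed = TRUE)[[1L]]
  ws <- grepl("[\\s]", chars, perl = TRUE)
  prev_ws <- c(TRUE, ws[-length(ws)])
  keep <- !ws | !prev_ws           # drop leading whitespace and repeats
  idx <- which(keep)
  out <- chars[idx]
  out[ws[idx]] <- " "
  while (length(out) > 0L && out[length(out)] == " ") {
    out <- out[-length(out)]
    idx <- idx[-length(idx)]
  }
  list(text = paste(out, collapse = ""), map = idx)
}

is_alnum_char <- function(ch) grepl("^[a-z0-9]$", ch)

# All occurrences of each (already normalized) term in a normalized string,
# restricted to token boundaries: a term edge that is alphanumeric must not
# touch an adjacent alphanumeric character.
locate_terms_norm <- function(norm, terms) {
  out <- vector("list", length(terms))
  n <- nchar(norm)
  for (k in seq_along(terms)) {
    term <- terms[[k]]
    hits <- gregexpr(term, norm, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    starts <- as.integer(hits)
    ends <- starts + nchar(term) - 1L
    ok <- rep(TRUE, length(starts))
    if (is_alnum_char(substr(term, 1L, 1L))) {
      before <- ifelse(starts > 1L,
                       substring(norm, starts - 1L, starts - 1L), "")
      ok <- ok & !grepl("[a-z0-9]", before)
    }
    last <- substr(term, nchar(term), nchar(term))
    if (is_alnum_char(last)) {
      after <- ifelse(ends < n, substring(norm, ends + 1L, ends + 1L), "")
      ok <- ok & !grepl("[a-z0-9]", after)
    }
    if (any(ok)) {
      out[[k]] <- data.frame(term = term, start = starts[ok], end = ends[ok],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Find lexicon term mentions in a note
#'
#' Locates all non-overlapping mentions of lexicon terms, resolving overlaps
#' by longest match, leftmost first ("fit bit" beats "bit").  Matching is on
#' normalized text (case- and whitespace-insensitive) and spans are reported
#' on the original string.  The result is independent of the order of terms
#' in the lexicon.
#'
#' @param text A single note text.
#' @param lexicon A [term_lexicon()].
#' @return A data frame with columns `lexicon`, `term` (normalized form),
#'   `start`, `end` (1-based inclusive character offsets into `text`),
#'   sorted by `start`.  Zero rows when nothing matches.
#' @export
#' @examples
#' find_term_mentions("Pt's Apple  Watch alerted overnight",
#'                    afwatch_lexicon("wearable"))
find_term_mentions <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "term_lexicon"))
  empty <- data.frame(lexicon = character(), term = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  nt <- normalize_text(text)
  if (!nzchar(nt$text)) return(empty)
  cand <- locate_terms_norm(nt$text, lexicon$terms)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # longest match, leftmost first; term name as a final deterministic tie-break
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$term), ]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(lexicon = lexicon$name, term = cand$term,
             start = nt$map[cand$start], end = nt$map[cand$end],
             stringsAsFactors = FALSE)
}

# Vectorized presence test: which texts contain at least one lexicon term on
# token boundaries?  Used as a fast path before per-note span work.
texts_with_terms <- function(texts, lexicon) {
  norm <- normalize_string(texts)
  hit <- rep(FALSE, length(texts))
  for (term in lexicon$terms) {
    pat <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
    first <- substr(term, 1L, 1L)
    last <- substr(term, nchar(term), nchar(term))
    if (is_alnum_char(first)) pat <- paste0("(?<![a-z0-9])", pat)
    if (is_alnum_char(last)) pat <- paste0(pat, "(?![a-z0-9])")
    hit <- hit | grepl(pat, norm, perl = TRUE)
    if (all(hit)) break
  }
  hit
}

# Matches of action terms (stem + irregular forms) on the ORIGINAL string;
# lowercasing preserves offsets so spans need no mapping.
find_action_mentions <- function(text, action = NULL) {
  action <- action %||% afwatch_lexicon("action")
  low <- tolower(text)
  pats <- c(
    paste0("\\b", action$stems, "[a-z]*"),
    paste0("\\b", action$irregular, "\\b")
  )
  res <- lapply(pats, function(p) {
    m <- gregexpr(p, low, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer())
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# Whether a token (lowercase) is an inflection of an action verb.
is_action_token <- function(tokens, action) {
  hit <- tokens %in% action$irregular
  for (s in action$stems) hit <- hit | startsWith(tokens, s)
  hit
}

#' Action term in the vicinity of a mention
#'
#' Implements the enrichment rule used to pick candidate notes: is there an
#' action term (alert, notify, ...; matched by stem, so "notified" counts)
#' close to a wearable mention?  Distance is measured in characters of the
#' original text, symmetrically: true when an action mention starts within
#' `window` characters before the mention starts, or ends within `window`
#' characters after the mention ends (mentions overlapping the span count
#' through the same rule).  Monotone in `window`.
#'
#' @param text The original note text.
#' @param mention One row of [find_term_mentions()] output (or any list with
#'   `start` and `end` offsets into `text`).
#' @param window Vicinity size in characters (default 30).
#' @param action Action [term_lexicon()]; default the built-in one.
#' @return Logical flag.
#' @export
has_action_in_vicinity <- function(text, mention, window = 30, action = NULL) {
  start <- as.integer(mention$start)
  end <- as.integer(mention$end)
  if (is.na(start) || is.na(end) || start < 1L || end < start ||
      end > nchar(text)) {
    stop("has_action_in_vicinity(): mention out of bounds")
  }
  acts <- find_action_mentions(text, action)
  if (nrow(acts) == 0L) return(FALSE)
  before <- acts$start >= start - window & acts$start < start
  after <- acts$end > end & acts$end <= end + window
  any(before | after)
}
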