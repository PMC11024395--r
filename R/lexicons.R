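#' Term lexicons
#'
#' A `term_lexicon` is a named dictionary of lowercase surface strings used
#' for gazetteer matching in clinical notes: wearable device names, terms
#' denoting atrial fibrillation, action verbs describing a device alerting a
#' patient, notification-event nouns, and the anticoagulant / rhythm
#' medication lists used by the cohort analysis.  The built-in lexicons ship
#' as YAML under `inst/extdata/lexicons` and are loaded with
#' [afwatch_lexicon()].
#'
#' @param name Short label for the lexicon.
#' @param terms Character vector of surface strings; normalized (lowercase,
#'   internal whitespace collapsed) and deduplicated on construction.
#' @param match_policy Only `"longest"` (longest match, leftmost first) is
#'   currently defined.
#' @param stems Optional character vector of verb stems; a token starting
#'   with a stem counts as a match (so "notified" matches stem "notif").
#' @param irregular Optional irregular forms matched as whole tokens.
#' @param groups Optional named list grouping terms (e.g. drug classes).
#' @return An object of class `term_lexicon`.
#' @export
term_lexicon <- function(name, terms, match_policy = "longest",
                         stems = NULL, irregular = NULL, groups = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.character(terms))
  norm <- normalize_string(terms)
  if (any(!nzchar(norm))) stop("term_lexicon(): empty term after normalization")
  norm <- unique(norm)
  structure(
    list(name = name, terms = norm, match_policy = match_policy,
         stems = stems, irregular = irregular, groups = groups),
    class = "term_lexicon"
  )
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat(sprintf("<term_lexicon '%s': %d terms>\n", x$name, length(x$terms)))
  invisible(x)
}

#' Load a built-in or user lexicon
#'
#' Built-in lexicons: `"wearable"`, `"af"`, `"action"`, `"event"`,
#' `"anticoagulant"`, `"rhythm"`.  User extension files (same YAML layout)
#' merge additively into the built-in term list.
#'
#' @param name Name of a built-in lexicon, or a path to a YAML file.
#' @param extensions Optional character vector of YAML file paths whose terms
#'   are appended to the base lexicon.
#' @return A [term_lexicon()].
#' @export
#' @examples
#' wl <- afwatch_lexicon("wearable")
#' wl$terms[1:3]
afwatch_lexicon <- function(name, extensions = NULL) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "lexicons", paste0(name, ".yaml"),
                package = "afwatch", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("afwatch_lexicon(): no lexicon named or at '%s'", name))
  }
  spec <- yaml::read_yaml(path)
  terms <- as.character(spec$terms)
  stems <- spec$stems
  irregular <- spec$irregular
  groups <- spec$groups
  for (ext in extensions) {
    e <- yaml::read_yaml(ext)
    terms <- c(terms, as.character(e$terms))
    stems <- c(stems, e$stems)
    irregular <- c(irregular, e$irregular)
  }
  term_lexicon(spec$name %||% name, terms,
               match_policy = spec$match_policy %||% "longest",
               stems = if (length(stems)) unique(as.character(stems)),
               irregular = if (length(irregular)) unique(as.character(irregular)),
               groups = groups)
}

#' Load all built-in lexicons
#'
#' @return Named list of [term_lexicon()] objects.
#' @export
afwatch_lexicons <- function() {
  nm <- c("wearable", "af", "action", "event", "anticoagulant", "rhythm")
  stats::setNames(lapply(nm, afwatch_lexicon), nm)
}
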