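#' Context lexicon for negation and family-history suppression
#'
#' The engine only reports the patient's personal history: matches inside
#' a negated clause ("no personal history of CAD") or a family-history
#' clause ("family history of ischemic heart disease") are suppressed.
#' Suppression is trigger-and-clause-scope based, in the style of classic
#' clinical negation heuristics: a trigger only acts on matches in its
#' own clause, where clauses are delimited by conjunctions and
#' punctuation ("but", "however", ";", ",").
#'
#' @param path YAML file with keys `negation_pre_triggers`,
#'   `negation_post_triggers`, `family_triggers`, `clause_boundaries`,
#'   each a non-empty list of terms. `NULL` loads the shipped defaults.
#' @return A `context_lexicon` object (named list of the four term sets).
#' @export
read_context_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("context", "context_default.yaml",
                        package = "cardiophen", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  need <- c("negation_pre_triggers", "negation_post_triggers",
            "family_triggers", "clause_boundaries")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("context lexicon is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lex <- lapply(raw[need], function(x) tolower(as.character(x)))
  if (any(vapply(lex, length, 1L) == 0L)) {
    stop("context lexicon term sets must be non-empty", call. = FALSE)
  }
  # pre-tokenized trigger phrases, compiled once at load
  lex$compiled <- lapply(lex[need], function(set) {
    Filter(function(t) length(t) > 0L, lapply(set, term_tokens))
  })
  structure(lex, class = "context_lexicon")
}

#' @rdname read_context_lexicon
#' @export
default_context_lexicon <- function() read_context_lexicon(NULL)

# token indices (1-based, inclusive) of the clause containing the
# half-open 0-based token span [start, end)
.clause_bounds <- function(norms, token_start, token_end, boundaries) {
  is_boundary <- norms %in% boundaries
  lo <- token_start + 1L                 # first token of the match, 1-based
  hi <- token_end                        # last token of the match, 1-based
  before <- which(is_boundary[seq_len(max(lo - 1L, 0L))])
  after <- which(is_boundary) ; after <- after[after > hi]
  c(if (length(before)) max(before) + 1L else 1L,
    if (length(after)) min(after) - 1L else length(norms))
}

# positions (start, end inclusive, 1-based) where any trigger phrase
# occurs; `triggers` is a term vector or a pre-tokenized list
.trigger_hits <- function(norms, triggers) {
  if (!is.list(triggers)) triggers <- lapply(triggers, term_tokens)
  hits <- NULL
  for (toks in triggers) {
    k <- length(toks)
    if (k == 0L || k > length(norms)) next
    first <- which(norms == toks[1L])
    for (i in first[first <= length(norms) - k + 1L]) {
      if (k == 1L || all(norms[(i + 1L):(i + k - 1L)] == toks[-1L])) {
        hits <- rbind(hits, c(i, i + k - 1L))
      }
    }
  }
  hits
}

# one scan per sentence shared by all matches
.context_scan <- function(tokens, lexicon) {
  comp <- lexicon$compiled
  norms <- tokens$norm
  list(norms = norms,
       pre = .trigger_hits(norms, comp$negation_pre_triggers %||%
                             lexicon$negation_pre_triggers),
       post = .trigger_hits(norms, comp$negation_post_triggers %||%
                              lexicon$negation_post_triggers),
       fam = .trigger_hits(norms, comp$family_triggers %||%
                             lexicon$family_triggers),
       boundaries = lexicon$clause_boundaries)
}

.negated_scan <- function(scan, token_start, token_end) {
  cb <- .clause_bounds(scan$norms, token_start, token_end, scan$boundaries)
  lo <- token_start + 1L; hi <- token_end
  if (!is.null(scan$pre) &&
      any(scan$pre[, 1L] >= cb[1L] & scan$pre[, 1L] < lo)) return(TRUE)
  if (!is.null(scan$post) &&
      any(scan$post[, 2L] > hi & scan$post[, 2L] <= cb[2L])) return(TRUE)
  FALSE
}

.family_scan <- function(scan, token_start, token_end) {
  cb <- .clause_bounds(scan$norms, token_start, token_end, scan$boundaries)
  lo <- token_start + 1L
  !is.null(scan$fam) &&
    any(scan$fam[, 1L] >= cb[1L] & scan$fam[, 1L] < lo)
}

#' Is a match negated?
#'
#' True iff a negation pre-trigger occurs before the match start within
#' the same clause, or a post-trigger occurs after the match end within
#' the same clause. Clause boundaries block trigger scope, so
#' "No chest pain, but known CAD" does not negate the CAD mention.
#'
#' @param tokens Token data.frame for the sentence (from [tokenize()]).
#' @param token_start,token_end 0-based half-open token span of the match.
#' @param lexicon A `context_lexicon`.
#' @return Logical flag.
#' @export
is_negated <- function(tokens, token_start, token_end, lexicon) {
  # a pre-trigger acts if it STARTS before the match start (it may
  # overlap the match: "no history of" vs a match on "history of cad")
  .negated_scan(.context_scan(tokens, lexicon), token_start, token_end)
}

#' Is a match a family-history mention?
#'
#' True iff a family trigger ("family history", "mother", ...) occurs
#' before the match start within the same clause. Clause scoping keeps
#' the patient's own findings: in "His mother had an MI; pt with HTN"
#' the hypertension mention survives.
#'
#' @inheritParams is_negated
#' @return Logical flag.
#' @export
is_family_history <- function(tokens, token_start, token_end, lexicon) {
  .family_scan(.context_scan(tokens, lexicon), token_start, token_end)
}

#' Drop negated and family-history matches
#'
#' Pure subset operation: returns exactly the matches for which both
#' [is_negated()] and [is_family_history()] are false, in input order.
#'
#' @param matches data.frame from [match_patterns()].
#' @param tokens Token data.frame of the same sentence.
#' @param lexicon A `context_lexicon`.
#' @return Filtered match data.frame.
#' @export
apply_context_filters <- function(matches, tokens, lexicon) {
  if (nrow(matches) == 0L) return(matches)
  scan <- .context_scan(tokens, lexicon)
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    s <- matches$token_start[i]; e <- matches$token_end[i]
    !.negated_scan(scan, s, e) && !.family_scan(scan, s, e)
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
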