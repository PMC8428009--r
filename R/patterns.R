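#' Parse a phrase-pattern element sequence
#'
#' A pattern's `seq` string is a space-separated list of elements:
#' a word-class name (required element), a name with a `?` suffix
#' (optional element), or `ANY*` (a gap matching zero or more tagged
#' spans of any class, never crossing the sentence). A pattern must
#' contain at least one required, non-gap element.
#'
#' @param seq Single element string, e.g. `"NUM? STENT ANY* CORONARY"`.
#' @return List of elements, each `list(kind, class, optional)` with
#'   `kind` one of `"class"`, `"gap"`.
#' @export
parse_pattern_seq <- function(seq) {
  parts <- strsplit(trimws(seq), "\\s+")[[1]]
  if (length(parts) == 0L || !nzchar(parts[1L])) {
    stop("empty pattern sequence", call. = FALSE)
  }
  elems <- lapply(parts, function(p) {
    if (p == "ANY*") return(list(kind = "gap", class = NA_character_,
                                 optional = TRUE))
    optional <- grepl("\\?$", p)
    cls <- sub("\\?$", "", p)
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", cls)) {
      stop("malformed pattern element: ", p, call. = FALSE)
    }
    list(kind = "class", class = cls, optional = optional)
  })
  required <- vapply(elems, function(e) e$kind == "class" && !e$optional,
                     logical(1))
  if (!any(required)) {
    stop("pattern needs at least one required word-class element: ", seq,
         call. = FALSE)
  }
  elems
}

#' Match phrase patterns against a tagged sentence
#'
#' Each pattern is matched independently against the word-class sequence
#' produced by [tag_word_classes()]. `ANY*` gaps are non-greedy and
#' bounded by the sentence; optional elements may be skipped. All distinct
#' placements are found and then collapsed to at most one match per
#' `(pattern_id, leftmost start)`, keeping the shortest (non-greedy) end;
#' placements of the same pattern that share an end are the same firing
#' with a leading optional element skipped and collapse to the leftmost
#' start. Matches from different patterns may overlap.
#'
#' A pattern may carry a numeric guard (`guard: num_ge_50_pct`): the
#' match is kept only if some `NUM` span it covers has value >= 50 and a
#' percent sign (either attached, as in "70%", or the next token).
#'
#' @param tagged data.frame from [tag_word_classes()].
#' @param patterns List of pattern objects, each
#'   `list(pattern_id, output_id, category, elements, guard)` with
#'   `elements` from [parse_pattern_seq()].
#' @param tokens Token data.frame for the same sentence; required when any
#'   pattern carries a guard, and used to report character spans.
#' @return data.frame with one row per surviving match: `pattern_id`,
#'   `output_id`, `category`, `span_start`, `span_end` (tagged-span
#'   indices, half-open), `token_start`, `token_end` (token indices,
#'   half-open).
#' @export
match_patterns <- function(tagged, patterns, tokens = NULL) {
  empty <- data.frame(pattern_id = character(), output_id = integer(),
                      category = character(), span_start = integer(),
                      span_end = integer(), token_start = integer(),
                      token_end = integer(), stringsAsFactors = FALSE)
  m <- nrow(tagged)
  if (m == 0L || length(patterns) == 0L) return(empty)
  cls <- tagged$word_class
  rows <- list()
  for (pat in patterns) {
    required <- vapply(Filter(function(e) e$kind == "class" && !e$optional,
                              pat$elements), `[[`, "", "class")
    if (!all(required %in% cls)) next     # cheap reject

    for (s in seq_len(m)) {
      ends <- .match_from(pat$elements, 1L, s, cls)
      ends <- ends[ends > s]
      if (length(ends) == 0L) next
      e <- min(ends)                      # non-greedy
      tok_s <- tagged$token_start[s]
      tok_e <- tagged$token_end[e - 1L]
      if (!is.null(pat$guard) && !is.na(pat$guard) &&
          !.check_guard(pat$guard, tagged, s, e - 1L, tokens)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pattern_id = pat$pattern_id, output_id = as.integer(pat$output_id),
        category = pat$category, span_start = s - 1L, span_end = e - 1L,
        token_start = tok_s, token_end = tok_e, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # one match per (pattern_id, leftmost start); rows are in ascending
  # start order per pattern with the shortest end chosen above
  out <- out[!duplicated(out[, c("pattern_id", "span_start")]), , drop = FALSE]
  # a later start reaching the same end is the same firing with a
  # leading optional skipped; keep the leftmost
  out <- out[!duplicated(out[, c("pattern_id", "span_end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# recursive matcher: possible positions (1-based, exclusive) after
# matching elements e.. starting at span position p
.match_from <- function(elements, e, p, cls) {
  if (e > length(elements)) return(p)
  el <- elements[[e]]
  n <- length(cls)
  if (el$kind == "gap") {
    res <- integer()
    for (q in p:(n + 1L)) {
      res <- c(res, .match_from(elements, e + 1L, q, cls))
    }
    return(unique(res))
  }
  res <- integer()
  if (el$optional) res <- .match_from(elements, e + 1L, p, cls)
  if (p <= n && cls[p] == el$class) {
    res <- c(res, .match_from(elements, e + 1L, p + 1L, cls))
  }
  unique(res)
}

# numeric guards, keyed by name so module files stay declarative
.check_guard <- function(guard, tagged, s, e, tokens) {
  if (guard != "num_ge_50_pct") {
    stop("unknown pattern guard: ", guard, call. = FALSE)
  }
  if (is.null(tokens)) stop("guarded patterns need the token table",
                            call. = FALSE)
  for (i in s:e) {
    if (tagged$word_class[i] != "NUM") next
    tok_i <- tagged$token_start[i] + 1L          # single-token NUM span
    norm <- tokens$norm[tok_i]
    pct <- grepl("%$", norm) ||
      (tok_i < nrow(tokens) && tokens$norm[tok_i + 1L] == "%")
    val <- suppressWarnings(as.numeric(sub("%$", "", norm)))
    if (!is.na(val) && val >= 50 && pct) return(TRUE)
  }
  FALSE
}

#' Resolve pattern matches to sentence-level outputs
#'
#' Deduplicates the categories fired in one sentence (one entry per
#' category regardless of how many patterns fired) while preserving every
#' `(pattern_id, output_id)` pair as provenance.
#'
#' @param matches data.frame from [match_patterns()] for one sentence.
#' @return list with `categories` (character vector, unique, in first-fire
#'   order) and `provenance` (the match data.frame, unchanged).
#' @export
resolve_outputs <- function(matches) {
  list(categories = unique(matches$category), provenance = matches)
}
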