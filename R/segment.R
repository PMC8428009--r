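#' Default protected abbreviations for sentence segmentation
#'
#' Clinical text is abbreviation-dense; a period that closes one of these
#' forms never ends a sentence. The list is plain data so deployments can
#' extend it (see [segment_sentences()]'s `abbreviations` argument).
#' Single capital initials ("J.") and decimal numbers are protected by
#' rule, not by list.
#'
#' @return Character vector of lower-cased protected forms.
#' @export
protected_abbreviations <- function() {
  c("mr.", "mrs.", "ms.", "dr.", "prof.", "st.", "jr.", "sr.",
    "pt.", "pts.", "vs.", "e.g.", "i.e.", "etc.", "approx.", "appt.",
    "no.", "wt.", "ht.", "fx.", "tab.", "cap.", "b.i.d.", "t.i.d.",
    "q.d.", "q.i.d.", "p.o.", "p.r.n.", "a.m.", "p.m.",
    # forms with no terminator; kept so the configured list documents the
    # full protected vocabulary in one place
    "s/p", "h/o", "c/o", "w/o", "r/o")
}

#' Segment note text into sentences
#'
#' Sentence terminators are `.`, `!`, `?` (when followed by whitespace or
#' end of text) and line breaks, so one-line section headers
#' ("History: ...") and list items each become their own sentence. A
#' period is not a terminator when it closes a protected abbreviation,
#' a single capital initial, or sits inside a decimal number.
#'
#' @param text Note text (single string; `NA` treated as empty).
#' @param abbreviations Lower-cased protected forms; defaults to
#'   [protected_abbreviations()].
#' @return data.frame with one row per sentence: `index` (0-based),
#'   `char_start`, `char_end` (0-based half-open span into `text`) and
#'   `text` (the exact substring, whitespace-trimmed via the span).
#' @examples
#' segment_sentences("History of CAD s/p MI in 2018. Denies chest pain.")
#' @export
segment_sentences <- function(text, abbreviations = protected_abbreviations()) {
  empty <- data.frame(index = integer(), char_start = integer(),
                      char_end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  n <- nchar(text)
  cand <- gregexpr("[.!?\n]", text)[[1]]
  if (cand[1L] == -1L) cand <- integer()
  breaks <- integer()
  for (pos in cand) {
    ch <- substr(text, pos, pos)
    if (ch == "\n") { breaks <- c(breaks, pos); next }
    nxt <- if (pos < n) substr(text, pos + 1L, pos + 1L) else ""
    # terminators must be followed by whitespace or end of text
    if (nzchar(nxt) && !grepl("^\\s$", nxt)) next
    if (ch == ".") {
      # the whitespace-delimited word ending at this period
      head_txt <- substr(text, 1L, pos)
      word <- sub(".*\\s", "", head_txt)
      lw <- tolower(word)
      if (lw %in% abbreviations) next
      if (grepl("^[A-Za-z]\\.$", word)) next            # single initial
      if (grepl("[0-9]\\.[0-9]", word)) next            # decimal number
    }
    breaks <- c(breaks, pos)
  }

  ends <- unique(sort(c(breaks, n)))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- empty
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (substr(text, e, e) == "\n") e <- e - 1L
    # trim by narrowing the span so substring(text, span) == sentence text
    while (s <= e && grepl("^\\s$", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    if (s > e) next
    out <- rbind(out, data.frame(
      index = nrow(out), char_start = s - 1L, char_end = e,
      text = substr(text, s, e), stringsAsFactors = FALSE))
  }
  out
}

# token pattern: numbers (decimals, percents, date-like runs), words with
# intra-token '/', '-', apostrophes (s/p, h/o, type-2, patient's), then any
# single non-space punctuation character
.token_regex <- paste0(
  "[0-9]+(?:\\.[0-9]+)?%?(?:[/-][A-Za-z0-9]+)*",
  "|[A-Za-z][A-Za-z0-9]*(?:['/-][A-Za-z0-9]+)*",
  "|[^\\sA-Za-z0-9]")

#' Tokenize one sentence
#'
#' Splits on whitespace and punctuation, keeping `/`, `-` and apostrophes
#' inside tokens ("s/p", "h/o"), `.` inside decimal numbers, and `%`
#' attached to numbers, so ">50%" yields a ">" token followed by a single
#' "50%" token. Remaining punctuation characters become one-character
#' tokens (clause boundaries like "," and ";" are needed downstream).
#'
#' @param text Sentence text (single string).
#' @return data.frame with one row per token: `surface`, `norm`
#'   (lower-cased surface), `char_start`, `char_end` (0-based half-open
#'   span into the sentence).
#' @examples
#' tokenize("The patient had 2 stents placed in his LAD in July 2018")
#' @export
tokenize <- function(text) {
  empty <- data.frame(surface = character(), norm = character(),
                      char_start = integer(), char_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(empty)
  len <- attr(m, "match.length")
  surface <- substring(text, m, m + len - 1L)
  data.frame(surface = surface, norm = tolower(surface),
             char_start = as.integer(m) - 1L,
             char_end = as.integer(m) + len - 1L,
             stringsAsFactors = FALSE)
}

# normalized token sequence of a lexicon term / trigger phrase
term_tokens <- function(term) tokenize(term)$norm
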