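# Independent brute-force oracle for phrase-pattern matching: translate
# the pattern into a regular expression over single-letter class codes
# and test every contiguous window of the tagged sequence for an exact
# parse. Canonicalization mirrors the engine's contract: per start keep
# the shortest end, then per end keep the leftmost start.
oracle_match <- function(cls, elements) {
  codes <- letters[seq_along(unique(cls))]
  names(codes) <- unique(cls)
  enc <- function(x) paste(codes[x], collapse = "")
  rx <- vapply(elements, function(el) {
    if (el$kind == "gap") return(".*")
    code <- unname(codes[el$class])
    if (is.na(code)) code <- "0"      # class absent from sentence
    if (el$optional) paste0("(", code, ")?") else code
  }, "")
  rx <- paste0("^", paste(rx, collapse = ""), "$")
  n <- length(cls)
  wins <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (grepl(rx, enc(cls[s:e]))) wins <- rbind(wins, c(s - 1L, e))
    }
  }
  if (is.null(wins)) {
    return(data.frame(span_start = integer(), span_end = integer()))
  }
  out <- data.frame(span_start = wins[, 1L], span_end = wins[, 2L])
  out <- out[order(out$span_start, out$span_end), , drop = FALSE]
  out <- out[!duplicated(out$span_start), , drop = FALSE]
  out <- out[!duplicated(out$span_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tagged-span table over an explicit class sequence (single-token spans)
fake_tagged <- function(cls) {
  data.frame(word_class = cls, token_start = seq_along(cls) - 1L,
             token_end = seq_along(cls), matched_term = NA_character_,
             stringsAsFactors = FALSE)
}

# minimal in-memory module for engine tests
tiny_module <- function(wordclasses, patterns, concept = "cad") {
  validate_module(list(meta = list(name = "tiny", version = "0"),
                       concept = concept, wordclasses = wordclasses,
                       patterns = patterns),
                  source = "<tiny>")
}

shipped <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(shipped_modules(), load_shipped_module)
      names(cache) <<- shipped_modules()
    }
    cache
  }
})

ctx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_context_lexicon()
    cache
  }
})

# categories extracted from one sentence by every shipped module
extract_all <- function(text) {
  sort(unique(unlist(lapply(shipped(), function(m)
    extract_sentence(text, m, ctx())$categories))))
}

# every (template, term) rendering for a bank entry
render_all <- function(templates, terms) {
  out <- character()
  for (tpl in templates) {
    if (grepl("{term}", tpl, fixed = TRUE)) {
      out <- c(out, vapply(terms, function(t)
        gsub("{term}", t, tpl, fixed = TRUE), ""))
    } else {
      out <- c(out, tpl)
    }
  }
  out
}
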