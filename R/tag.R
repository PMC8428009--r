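#' Tag tokens with word classes
#'
#' Greedy left-to-right longest-match tagging of normalized tokens against
#' a module lexicon. Multi-word terms match contiguous token runs; ties at
#' equal length go to the earliest-declared word class. Tokens covered by
#' no lexicon term are tagged `NUM` when they look numeric (digits,
#' decimals, optional trailing `%`) and `UNKNOWN` otherwise, so the
#' output always tiles the token sequence.
#'
#' `UNKNOWN` and `NUM` are reserved class names a module may not declare.
#'
#' @param tokens data.frame from [tokenize()].
#' @param wordclasses Named list: class name -> character vector of terms.
#'   Declaration order is the tie-break order.
#' @return data.frame with one row per tagged span: `word_class`,
#'   `token_start`, `token_end` (0-based half-open token-index span) and
#'   `matched_term` (the lexicon entry; `NA` for `UNKNOWN`/`NUM`).
#' @examples
#' tag_word_classes(tokenize("coronary heart disease"),
#'                  list(CAD = c("cad", "coronary disease",
#'                               "coronary heart disease")))
#' @export
tag_word_classes <- function(tokens, wordclasses) {
  empty <- data.frame(word_class = character(), token_start = integer(),
                      token_end = integer(), matched_term = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(tokens)
  if (n == 0L) return(empty)
  lex <- if (is.environment(wordclasses)) wordclasses
  else compile_lexicon(wordclasses)
  norms <- tokens$norm
  cls_out <- character(n); start_out <- integer(n)
  end_out <- integer(n); term_out <- character(n)
  nr <- 0L
  i <- 1L
  while (i <= n) {
    best <- NULL
    for (entry in lexicon_candidates(lex, norms[i])) {
      k <- length(entry$toks)
      if (i + k - 1L > n) next
      if (!all(norms[i:(i + k - 1L)] == entry$toks)) next
      if (is.null(best) ||
          k > length(best$toks) ||
          (k == length(best$toks) && entry$order < best$order)) {
        best <- entry
      }
    }
    nr <- nr + 1L
    if (!is.null(best)) {
      k <- length(best$toks)
      cls_out[nr] <- best$class
      start_out[nr] <- i - 1L; end_out[nr] <- i - 1L + k
      term_out[nr] <- best$term
      i <- i + k
    } else {
      cls_out[nr] <- if (grepl("^[0-9]+(\\.[0-9]+)?%?$", norms[i]))
        "NUM" else "UNKNOWN"
      start_out[nr] <- i - 1L; end_out[nr] <- i
      term_out[nr] <- NA_character_
      i <- i + 1L
    }
  }
  keep <- seq_len(nr)
  data.frame(word_class = cls_out[keep], token_start = start_out[keep],
             token_end = end_out[keep], matched_term = term_out[keep],
             stringsAsFactors = FALSE)
}

# index lexicon entries by first token for the left-to-right scan
compile_lexicon <- function(wordclasses) {
  env <- new.env(parent = emptyenv())
  order_i <- 0L
  for (cls in names(wordclasses)) {
    order_i <- order_i + 1L
    for (term in wordclasses[[cls]]) {
      toks <- term_tokens(term)
      if (length(toks) == 0L) next
      key <- toks[1L]
      entry <- list(class = cls, term = term, toks = toks, order = order_i)
      cur <- if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env) else list()
      assign(key, c(cur, list(entry)), envir = env)
    }
  }
  env
}

lexicon_candidates <- function(lex, norm) {
  if (exists(norm, envir = lex, inherits = FALSE)) get(norm, envir = lex)
  else list()
}
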