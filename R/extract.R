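#' Extract diagnostic categories from one sentence
#'
#' Composes the engine: [tokenize()] -> [tag_word_classes()] ->
#' [match_patterns()] -> [apply_context_filters()] ->
#' [resolve_outputs()]. Categories are deduplicated per sentence; every
#' surviving pattern firing is kept as provenance.
#'
#' @param text Sentence text.
#' @param module A `comorbidity_module` (or a name accepted by
#'   [load_shipped_module()]).
#' @param context A `context_lexicon`; defaults to the shipped one.
#' @param note_id,sentence_index Provenance carried into the annotation.
#' @param char_offset Character offset of the sentence within its note;
#'   provenance spans are reported note-relative.
#' @return A `sentence_annotation`: list with `note_id`,
#'   `sentence_index`, `categories` (character vector, possibly empty)
#'   and `provenance` (data.frame `pattern_id`, `output_id`, `category`,
#'   `char_start`, `char_end`).
#' @examples
#' \dontrun{
#' extract_sentence("Mrs. Smith has a history of elevated cholesterol",
#'                  "dyslipidemia")$categories
#' }
#' @export
extract_sentence <- function(text, module, context = default_context_lexicon(),
                             note_id = NA_character_, sentence_index = NA_integer_,
                             char_offset = 0L) {
  module <- load_shipped_module(module)
  tokens <- tokenize(text)
  tagged <- tag_word_classes(tokens, module$lexicon %||% module$wordclasses)
  matches <- match_patterns(tagged, module$patterns, tokens)
  matches <- apply_context_filters(matches, tokens, context)
  res <- resolve_outputs(matches)
  prov <- if (nrow(matches) == 0L) {
    data.frame(pattern_id = character(), output_id = integer(),
               category = character(), char_start = integer(),
               char_end = integer(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      pattern_id = matches$pattern_id, output_id = matches$output_id,
      category = matches$category,
      char_start = as.integer(char_offset) +
        tokens$char_start[matches$token_start + 1L],
      char_end = as.integer(char_offset) +
        tokens$char_end[matches$token_end],
      stringsAsFactors = FALSE)
  }
  structure(list(note_id = note_id, sentence_index = sentence_index,
                 categories = res$categories, provenance = prov),
            class = "sentence_annotation")
}

#' Extract a note-level annotation with one module
#'
#' Segments the note, runs [extract_sentence()] on every sentence, and
#' unions the surviving sentence categories into note-level concept and
#' subcategory flags. A note whose only diagnostic sentences are negated
#' or family-history mentions gets all-false flags and no sentence
#' annotations.
#'
#' @param note List or one-row data.frame with `note_id`, `text`, and
#'   optionally `note_type`.
#' @inheritParams extract_sentence
#' @return A `note_annotation`: list with `note_id`, `concept`,
#'   `concept_present` (flag), `subcategory_present` (named logical over
#'   the module's subcategories) and `sentence_annotations` (list of
#'   non-empty `sentence_annotation`s).
#' @export
extract_note <- function(note, module, context = default_context_lexicon()) {
  module <- load_shipped_module(module)
  note_id <- as.character(note$note_id)
  sents <- segment_sentences(if (is.na(note$text[1L])) "" else note$text[1L])
  anns <- list()
  for (i in seq_len(nrow(sents))) {
    ann <- extract_sentence(sents$text[i], module, context,
                            note_id = note_id,
                            sentence_index = sents$index[i],
                            char_offset = sents$char_start[i])
    if (length(ann$categories) > 0L) anns[[length(anns) + 1L]] <- ann
  }
  cats <- unique(unlist(lapply(anns, `[[`, "categories")))
  subs <- concept_taxonomy()[[module$concept]]
  sub_present <- stats::setNames(
    paste(module$concept, subs, sep = ".") %in% cats, subs)
  structure(list(note_id = note_id, concept = module$concept,
                 concept_present = length(cats) > 0L,
                 subcategory_present = sub_present,
                 sentence_annotations = anns),
            class = "note_annotation")
}

#' Run one or more modules over a corpus of notes
#'
#' Deterministic, order-preserving batch extraction. Notes that fail to
#' process are recorded and skipped rather than aborting the batch.
#'
#' @param notes data.frame with columns `note_id`, `text` and optionally
#'   `note_type` (see [read_notes()]).
#' @param modules `"all"` (default), a character vector of shipped module
#'   names, or a list of `comorbidity_module` objects.
#' @inheritParams extract_sentence
#' @return A `corpus_annotations` list:
#' \describe{
#'   \item{sentences}{data.frame of surviving sentence-level references:
#'     `note_id`, `sentence_index`, `category`, `concept`, `subcategory`,
#'     `pattern_id`, `output_id`, `char_start`, `char_end`.}
#'   \item{notes}{data.frame of note-level positives: `note_id`,
#'     `category`, `concept`, `subcategory` (one row per present
#'     category).}
#'   \item{universe}{character vector of all processed note ids.}
#'   \item{failures}{data.frame `note_id`, `error`.}
#' }
#' @export
extract_corpus <- function(notes, modules = "all",
                           context = default_context_lexicon()) {
  if (identical(modules, "all")) modules <- shipped_modules()
  if (!is.list(modules) || inherits(modules, "comorbidity_module")) {
    modules <- if (inherits(modules, "comorbidity_module")) list(modules)
    else lapply(modules, load_shipped_module)
  }
  if (anyDuplicated(notes$note_id)) {
    stop("note_id values must be unique within a corpus", call. = FALSE)
  }
  sent_rows <- list(); fail_rows <- list()
  for (i in seq_len(nrow(notes))) {
    note <- notes[i, , drop = FALSE]
    res <- tryCatch({
      for (mod in modules) {
        ann <- extract_note(note, mod, context)
        for (sa in ann$sentence_annotations) {
          p <- sa$provenance
          p$note_id <- ann$note_id
          p$sentence_index <- sa$sentence_index
          sent_rows[[length(sent_rows) + 1L]] <- p
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      fail_rows[[length(fail_rows) + 1L]] <- data.frame(
        note_id = as.character(note$note_id), error = res,
        stringsAsFactors = FALSE)
    }
  }
  sentences <- if (length(sent_rows) > 0L) do.call(rbind, sent_rows) else
    data.frame(pattern_id = character(), output_id = integer(),
               category = character(), char_start = integer(),
               char_end = integer(), note_id = character(),
               sentence_index = integer(), stringsAsFactors = FALSE)
  cs <- split_category(sentences$category)
  sentences <- cbind(
    sentences[, c("note_id", "sentence_index", "category")],
    cs,
    sentences[, c("pattern_id", "output_id", "char_start", "char_end")])
  rownames(sentences) <- NULL
  note_pos <- unique(sentences[, c("note_id", "category", "concept",
                                   "subcategory")])
  rownames(note_pos) <- NULL
  structure(list(sentences = sentences, notes = note_pos,
                 universe = as.character(notes$note_id),
                 failures = if (length(fail_rows) > 0L)
                   do.call(rbind, fail_rows) else
                     data.frame(note_id = character(), error = character(),
                                stringsAsFactors = FALSE)),
            class = "corpus_annotations")
}

#' @export
print.corpus_annotations <- function(x, ...) {
  cat("<corpus_annotations> ", length(x$universe), " notes, ",
      nrow(x$sentences), " sentence-level references, ",
      nrow(x$notes), " note-level positives",
      if (nrow(x$failures) > 0L) paste0(", ", nrow(x$failures), " failures"),
      "\n", sep = "")
  invisible(x)
}
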