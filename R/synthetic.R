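#' Configuration for the synthetic-note generator
#'
#' Defaults emulate the composition of a 200-note cardiovascular
#' validation corpus: a predominately outpatient / discharge-summary mix,
#' per-concept note prevalences matching the reference positive rates
#' (hypertension 0.41, dyslipidemia 0.34, diabetes 0.145, CAD 0.27,
#' stroke/TIA 0.205) spread over subcategories, one to four mentions per
#' positive note, and background rates of negated and family-history
#' phrasings that the engine must ignore.
#'
#' @param n_notes Number of notes to generate.
#' @param note_type_mix Named proportions over
#'   `c(outpatient, discharge_summary)`.
#' @param prevalence Named numeric vector: category
#'   (`concept.subcategory`) -> probability that a note is positive.
#' @param mentions_per_positive Integer range `c(min, max)`: mentions
#'   planted per positive (note, category).
#' @param negation_rate Probability that a planted mention renders as a
#'   negated phrasing (excluded from gold).
#' @param family_history_rate Probability that a note gains one
#'   family-history distractor sentence.
#' @param distractor_sentences_per_note Neutral filler sentences added to
#'   every note.
#' @param seed Mandatory integer seed; identical config + seed gives a
#'   byte-identical corpus.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_notes = 200L,
                             note_type_mix = c(outpatient = 0.7,
                                               discharge_summary = 0.3),
                             prevalence = default_prevalence(),
                             mentions_per_positive = c(1L, 4L),
                             negation_rate = 0.2,
                             family_history_rate = 0.2,
                             distractor_sentences_per_note = 3L,
                             seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  if (n_notes < 0L) stop("n_notes must be >= 0", call. = FALSE)
  if (any(prevalence < 0 | prevalence > 1) ||
      any(c(negation_rate, family_history_rate) < 0) ||
      any(c(negation_rate, family_history_rate) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  check_categories(names(prevalence))
  if (length(mentions_per_positive) != 2L ||
      mentions_per_positive[1L] < 1L ||
      mentions_per_positive[2L] < mentions_per_positive[1L]) {
    stop("mentions_per_positive must be an increasing range >= 1",
         call. = FALSE)
  }
  structure(list(n_notes = as.integer(n_notes),
                 note_type_mix = note_type_mix / sum(note_type_mix),
                 prevalence = prevalence,
                 mentions_per_positive = as.integer(mentions_per_positive),
                 negation_rate = negation_rate,
                 family_history_rate = family_history_rate,
                 distractor_sentences_per_note =
                   as.integer(distractor_sentences_per_note),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_prevalence <- function() {
  c(hypertension.present = 0.41,
    dyslipidemia.present = 0.34,
    diabetes.type1 = 0.015, diabetes.type2 = 0.05,
    diabetes.unspecified = 0.08,
    cad.unspecified = 0.10, cad.stenosis_gt50 = 0.03,
    cad.unstable_angina = 0.03, cad.mi = 0.06, cad.stemi = 0.015,
    cad.revascularization = 0.045,
    stroke_tia.ischemic = 0.06, stroke_tia.embolic = 0.03,
    stroke_tia.unspecified = 0.075, stroke_tia.tia = 0.04)
}

#' Load the synthetic-note template bank
#'
#' @param path YAML template bank; `NULL` loads the shipped bank. Every
#'   category must provide at least three positive templates.
#' @return A `template_bank` list.
#' @export
read_template_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("templates", "templates.yaml",
                        package = "cardiophen", mustWork = TRUE)
  }
  bank <- yaml::read_yaml(path)
  check_categories(names(bank$categories))
  for (cat in names(bank$categories)) {
    entry <- bank$categories[[cat]]
    if (length(entry$positive) < 3L) {
      stop("category ", cat, " has fewer than 3 positive templates",
           call. = FALSE)
    }
    slotted <- grepl("{term}", c(entry$positive, entry$negated,
                                 entry$family), fixed = TRUE)
    if (any(slotted) && length(entry$terms) == 0L) {
      stop("category ", cat, " has slotted templates but no terms",
           call. = FALSE)
    }
  }
  structure(bank, class = "template_bank")
}

# uniform draws that consume exactly one RNG variate each, so toggling a
# rate does not shift the stream
.draw_int <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1L))
.draw_one <- function(x) x[[.draw_int(1L, length(x))]]

.render <- function(template, terms) {
  if (grepl("{term}", template, fixed = TRUE)) {
    term <- .draw_one(terms)
    gsub("{term}", term, template, fixed = TRUE)
  } else {
    stats::runif(1)   # keep the stream aligned with the slotted branch
    template
  }
}

#' Generate a labeled synthetic corpus
#'
#' Notes are assembled one sentence per line from the template bank:
#' a note-type header, planted positive mentions (gold), negated and
#' family-history renderings (explicitly NOT gold), and neutral
#' distractor sentences, in shuffled order. Gold records are emitted for
#' every planted positive at sentence level (index into the final note)
#' and at note level (blank sentence index).
#'
#' @param config A `generator_config`.
#' @param bank A `template_bank`; defaults to the shipped bank.
#' @return list with `notes` (data.frame `note_id`, `text`, `note_type`)
#'   and `gold` (data.frame `note_id`, `adjudicator_id`, `concept`,
#'   `subcategory`, `sentence_index`).
#' @export
generate_corpus <- function(config, bank = read_template_bank()) {
  stopifnot(inherits(config, "generator_config"))
  no_templates <- setdiff(names(config$prevalence)[config$prevalence > 0],
                          names(bank$categories))
  if (length(no_templates) > 0L) {
    stop("prevalence requested for categories with no templates: ",
         paste(no_templates, collapse = ", "), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  cats <- names(config$prevalence)
  notes <- vector("list", config$n_notes)
  gold <- list()
  for (i in seq_len(config$n_notes)) {
    note_id <- sprintf("note%05d", i)
    note_type <- names(config$note_type_mix)[
      1L + (stats::runif(1) >= config$note_type_mix[1L])]
    sents <- character(); sent_cat <- character()
    for (cat in cats) {
      if (stats::runif(1) >= config$prevalence[[cat]]) next
      entry <- bank$categories[[cat]]
      m <- .draw_int(config$mentions_per_positive[1L],
                     config$mentions_per_positive[2L])
      for (k in seq_len(m)) {
        negate <- stats::runif(1) < config$negation_rate
        pool <- if (negate) entry$negated else entry$positive
        txt <- .render(.draw_one(pool), entry$terms)
        sents <- c(sents, txt)
        sent_cat <- c(sent_cat, if (negate) NA_character_ else cat)
      }
    }
    if (stats::runif(1) < config$family_history_rate) {
      cat <- .draw_one(cats)
      entry <- bank$categories[[cat]]
      txt <- .render(.draw_one(entry$family), entry$terms)
      sents <- c(sents, txt); sent_cat <- c(sent_cat, NA_character_)
    }
    for (k in seq_len(config$distractor_sentences_per_note)) {
      sents <- c(sents, .draw_one(bank$distractors))
      sent_cat <- c(sent_cat, NA_character_)
    }
    ord <- sample.int(length(sents))
    sents <- sents[ord]; sent_cat <- sent_cat[ord]
    # header stays first and is never gold
    sents <- c(bank$headers[[note_type]], sents)
    sent_cat <- c(NA_character_, sent_cat)
    notes[[i]] <- data.frame(note_id = note_id,
                             text = paste(sents, collapse = "\n"),
                             note_type = note_type,
                             stringsAsFactors = FALSE)
    pos <- which(!is.na(sent_cat))
    if (length(pos) > 0L) {
      cs <- split_category(sent_cat[pos])
      gold[[length(gold) + 1L]] <- data.frame(
        note_id = note_id, adjudicator_id = "generator",
        concept = cs$concept, subcategory = cs$subcategory,
        sentence_index = pos - 1L, stringsAsFactors = FALSE)
    }
  }
  gold_df <- if (length(gold) > 0L) do.call(rbind, gold) else
    data.frame(note_id = character(), adjudicator_id = character(),
               concept = character(), subcategory = character(),
               sentence_index = integer(), stringsAsFactors = FALSE)
  # add note-level rows (blank sentence index) for every positive note
  if (nrow(gold_df) > 0L) {
    note_rows <- unique(gold_df[, c("note_id", "adjudicator_id",
                                    "concept", "subcategory")])
    note_rows$sentence_index <- NA_integer_
    gold_df <- rbind(gold_df, note_rows)
    rownames(gold_df) <- NULL
  }
  list(notes = if (config$n_notes > 0L) do.call(rbind, notes) else
    data.frame(note_id = character(), text = character(),
               note_type = character(), stringsAsFactors = FALSE),
    gold = gold_df)
}

#' Plant known extraction errors into a generated corpus
#'
#' Induces an exactly known confusion structure for oracle testing:
#' false negatives are out-of-lexicon paraphrases (added to gold, missed
#' by the engine) appended to notes previously negative for the concept;
#' false positives are trigger-adjacent trap phrasings (matched by the
#' engine, excluded from gold). Each planted item lands in its own
#' previously-negative note, so per concept the note-level and
#' sentence-level confusion deltas equal the planted counts.
#'
#' @param notes,gold A corpus from [generate_corpus()].
#' @param error_spec Named list: concept -> `c(fn = ..., fp = ...)`.
#' @param seed Integer seed for choosing host notes.
#' @param bank A `template_bank`.
#' @return list with modified `notes`, `gold`, and `manifest` (data.frame
#'   `note_id`, `sentence_index`, `concept`, `subcategory`, `kind`
#'   (`"fn"`/`"fp"`)).
#' @export
plant_errors <- function(notes, gold, error_spec, seed,
                         bank = read_template_bank()) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  manifest <- list()
  for (cn in names(error_spec)) {
    spec <- error_spec[[cn]]
    n_fn <- if ("fn" %in% names(spec)) as.integer(spec[["fn"]]) else 0L
    n_fp <- if ("fp" %in% names(spec)) as.integer(spec[["fp"]]) else 0L
    if (n_fn + n_fp == 0L) next
    neg_notes <- setdiff(notes$note_id, gold$note_id[gold$concept == cn])
    if (length(neg_notes) < n_fn + n_fp) {
      stop("infeasible error spec for ", cn, ": need ", n_fn + n_fp,
           " concept-negative notes, have ", length(neg_notes),
           call. = FALSE)
    }
    hosts <- sample(neg_notes, n_fn + n_fp)
    fn_entry <- bank$fn_paraphrases[[cn]]
    fp_entry <- bank$fp_traps[[cn]]
    for (j in seq_len(n_fn + n_fp)) {
      is_fn <- j <= n_fn
      host <- hosts[j]
      txt <- if (is_fn) .draw_one(fn_entry$sentences) else
        .draw_one(fp_entry$sentences)
      row <- which(notes$note_id == host)
      idx <- nrow(segment_sentences(notes$text[row]))
      notes$text[row] <- paste(notes$text[row], txt, sep = "\n")
      sub <- if (is_fn) fn_entry$subcategory else
        split_category(fp_entry$category)$subcategory
      if (is_fn) {
        gold <- rbind(gold,
          data.frame(note_id = host, adjudicator_id = "generator",
                     concept = cn, subcategory = sub,
                     sentence_index = c(idx, NA_integer_),
                     stringsAsFactors = FALSE))
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        note_id = host, sentence_index = idx, concept = cn,
        subcategory = sub, kind = if (is_fn) "fn" else "fp",
        stringsAsFactors = FALSE)
    }
  }
  rownames(gold) <- NULL
  list(notes = notes, gold = gold,
       manifest = if (length(manifest) > 0L) do.call(rbind, manifest) else
         data.frame(note_id = character(), sentence_index = integer(),
                    concept = character(), subcategory = character(),
                    kind = character(), stringsAsFactors = FALSE))
}
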