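#' Load and validate a comorbidity module definition
#'
#' A module file is one YAML document with keys:
#' \describe{
#'   \item{meta}{`name` and `version`.}
#'   \item{concept}{one of the five concepts in [concept_taxonomy()].}
#'   \item{wordclasses}{mapping `NAME: [terms...]`; declaration order is
#'     the tie-break order for equal-length lexicon matches.}
#'   \item{patterns}{list of `{id, output, category, seq}` entries, with
#'     an optional `guard` (currently `num_ge_50_pct`); `seq` is a
#'     space-separated element string, see [parse_pattern_seq()].}
#' }
#' Validation failures (duplicate terms across word classes, dangling
#' word-class references, duplicate output ids or pattern ids, categories
#' outside the module's taxonomy, reserved class names) are collected and
#' reported together.
#'
#' @param path Path to the module YAML file.
#' @return A `comorbidity_module` object.
#' @seealso [shipped_modules()], [write_module()]
#' @export
load_module <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_module(raw, source = path)
}

#' @rdname load_module
#' @param raw Parsed module structure (as returned by `yaml::read_yaml`).
#' @param source Label used in error messages.
#' @export
validate_module <- function(raw, source = "<module>") {
  errs <- character()
  add <- function(...) errs <<- c(errs, paste0(...))

  name <- raw$meta$name
  version <- raw$meta$version
  if (is.null(name) || !nzchar(name)) add("meta.name is missing")
  if (is.null(version)) add("meta.version is missing")
  concept <- raw$concept
  if (is.null(concept) || !concept %in% concept_names()) {
    add("concept must be one of: ", paste(concept_names(), collapse = ", "))
    concept <- NA_character_
  }

  wc <- raw$wordclasses
  if (is.null(wc) || length(wc) == 0L) add("no word classes declared")
  wc <- lapply(wc, as.character)
  reserved <- intersect(names(wc), c("UNKNOWN", "NUM"))
  if (length(reserved) > 0L) {
    add("reserved word-class name declared: ",
        paste(reserved, collapse = ", "))
  }
  if (anyDuplicated(names(wc))) add("duplicate word-class names")
  empty_cls <- names(wc)[vapply(wc, length, 1L) == 0L]
  if (length(empty_cls) > 0L) {
    add("word class with no terms: ", paste(empty_cls, collapse = ", "))
  }
  # no term may appear in two word classes of the same module
  term_tab <- data.frame(
    class = rep(names(wc), vapply(wc, length, 1L)),
    term = tolower(unlist(wc, use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (nrow(term_tab) > 0L) {
    dup_terms <- unique(term_tab$term[duplicated(term_tab$term)])
    for (t in dup_terms) {
      add("term \"", t, "\" appears in multiple word classes: ",
          paste(unique(term_tab$class[term_tab$term == t]), collapse = ", "))
    }
  }

  pats_raw <- raw$patterns
  if (is.null(pats_raw) || length(pats_raw) == 0L) add("no patterns declared")
  valid_cats <- if (!is.na(concept)) {
    paste(concept, concept_taxonomy()[[concept]], sep = ".")
  } else character()
  patterns <- list()
  seen_ids <- character(); seen_outputs <- integer()
  for (p in pats_raw) {
    pid <- p$id; out_id <- p$output; cat <- p$category; seq <- p$seq
    if (is.null(pid) || !nzchar(pid)) { add("pattern with no id"); next }
    if (pid %in% seen_ids) add("duplicate pattern id: ", pid)
    seen_ids <- c(seen_ids, pid)
    if (is.null(out_id)) {
      add("pattern ", pid, " has no output id")
    } else if (as.integer(out_id) %in% seen_outputs) {
      add("duplicate output id: ", out_id, " (pattern ", pid, ")")
    } else {
      seen_outputs <- c(seen_outputs, as.integer(out_id))
    }
    if (is.null(cat) || !(cat %in% valid_cats)) {
      add("pattern ", pid, " category not in module taxonomy: ",
          if (is.null(cat)) "<missing>" else cat)
    }
    elems <- tryCatch(parse_pattern_seq(seq), error = function(e) {
      add("pattern ", pid, ": ", conditionMessage(e)); NULL
    })
    if (!is.null(elems)) {
      refs <- vapply(Filter(function(e) e$kind == "class", elems),
                     `[[`, "", "class")
      dangling <- setdiff(refs, c(names(wc), "NUM"))
      if (length(dangling) > 0L) {
        add("pattern ", pid, " references undeclared word class: ",
            paste(dangling, collapse = ", "))
      }
    }
    guard <- p$guard
    if (!is.null(guard) && !guard %in% "num_ge_50_pct") {
      add("pattern ", pid, " has unknown guard: ", guard)
    }
    patterns[[length(patterns) + 1L]] <- list(
      pattern_id = pid,
      output_id = if (is.null(out_id)) NA_integer_ else as.integer(out_id),
      category = if (is.null(cat)) NA_character_ else cat,
      seq = seq, elements = elems,
      guard = if (is.null(guard)) NA_character_ else guard)
  }

  if (length(errs) > 0L) {
    stop("invalid module (", source, "):\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(name = name, version = as.character(version),
                 concept = concept, wordclasses = wc, patterns = patterns,
                 # lexicon index precompiled once so per-sentence tagging
                 # does not re-tokenize every term
                 lexicon = compile_lexicon(wc)),
            class = "comorbidity_module")
}

#' @export
print.comorbidity_module <- function(x, ...) {
  cat("<comorbidity_module> ", x$name, " v", x$version,
      " (concept: ", x$concept, ")\n", sep = "")
  cat("  ", length(x$wordclasses), " word classes, ",
      length(x$patterns), " patterns, ",
      length(unique(vapply(x$patterns, `[[`, "", "category"))),
      " categories\n", sep = "")
  invisible(x)
}

#' Serialize a module definition back to YAML
#'
#' Writes the canonical form that [load_module()] reads; serialize ->
#' load -> serialize is idempotent.
#'
#' @param module A `comorbidity_module`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_module <- function(module, path) {
  pats <- lapply(module$patterns, function(p) {
    out <- list(id = p$pattern_id, output = p$output_id,
                category = p$category, seq = p$seq)
    if (!is.na(p$guard)) out$guard <- p$guard
    out
  })
  doc <- list(meta = list(name = module$name, version = module$version),
              concept = module$concept,
              wordclasses = module$wordclasses,
              patterns = pats)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Shipped comorbidity modules
#'
#' Five re-authored rule sets covering hypertension, dyslipidemia,
#' diabetes, coronary artery disease, and non-hemorrhagic stroke/TIA.
#' They are representative, not byte-level reproductions of any published
#' rule files: smaller, but structurally faithful (word classes, phrase
#' patterns with optional elements and gaps, numbered outputs, full
#' subcategory coverage).
#'
#' @return `shipped_modules()`: character vector of module names.
#' @export
shipped_modules <- function() {
  c("hypertension", "dyslipidemia", "diabetes", "cad", "stroke_tia")
}

#' @rdname shipped_modules
#' @param name Module name (one of `shipped_modules()`), a path to a
#'   module YAML file, or an already-loaded `comorbidity_module`.
#' @return `load_shipped_module()`: a `comorbidity_module`.
#' @export
load_shipped_module <- function(name) {
  if (inherits(name, "comorbidity_module")) return(name)
  if (file.exists(name)) return(load_module(name))
  if (!name %in% shipped_modules()) {
    stop("unknown module \"", name, "\"; available: ",
         paste(shipped_modules(), collapse = ", "), call. = FALSE)
  }
  load_module(system.file("modules", paste0(name, ".yaml"),
                          package = "cardiophen", mustWork = TRUE))
}
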