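#' Merge a dual-adjudicator gold table
#'
#' When the gold table carries two (or more) adjudicator ids, the merged
#' reference is the union of their distinct positive references, and
#' every reference not logged by all adjudicators is listed as a conflict
#' for manual resolution. A single-adjudicator (or pre-merged) table
#' passes through with no conflicts.
#'
#' @param gold Gold data.frame (see [read_gold()]).
#' @return list with `gold` (merged, one row per distinct reference) and
#'   `conflicts` (data.frame of references needing manual review).
#' @export
merge_gold <- function(gold) {
  cols <- c("note_id", "concept", "subcategory", "sentence_index")
  if (!"adjudicator_id" %in% names(gold) ||
      length(unique(gold$adjudicator_id)) <= 1L) {
    merged <- unique(gold[, cols, drop = FALSE])
    rownames(merged) <- NULL
    return(list(gold = merged,
                conflicts = merged[0, , drop = FALSE]))
  }
  adjs <- unique(as.character(gold$adjudicator_id))
  key <- do.call(paste, c(gold[cols], sep = "\r"))
  n_adj_per_key <- tapply(gold$adjudicator_id, key,
                          function(x) length(unique(x)))
  merged <- unique(gold[, cols, drop = FALSE])
  mkey <- do.call(paste, c(merged[cols], sep = "\r"))
  conflicts <- merged[n_adj_per_key[mkey] < length(adjs), , drop = FALSE]
  rownames(merged) <- NULL; rownames(conflicts) <- NULL
  list(gold = merged, conflicts = conflicts)
}

# evaluation targets: every concept, plus each subcategory of the
# multi-level concepts
.eval_targets <- function() {
  tax <- concept_taxonomy()
  rows <- lapply(names(tax), function(cn) {
    sub <- if (length(tax[[cn]]) > 1L) tax[[cn]] else character()
    data.frame(concept = cn, subcategory = c(NA_character_, sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions against an adjudicated gold standard
#'
#' The full two-level evaluation: per concept and per subcategory,
#' note-level sensitivity, specificity and PPV and sentence-level
#' sensitivity and PPV, original and (when corrections are supplied)
#' corrected, each with an exact binomial 95\% CI. Sentence-level
#' specificity is structurally NA (true negatives are not enumerable);
#' targets with zero gold and zero predicted references are emitted as
#' not estimable.
#'
#' Corrections reclassify system-found, adjudicator-missed true
#' positives (see [corrected_counts()]). A confirmed correction must
#' correspond to a counted false-positive item at the note or sentence
#' level; one matching neither is an error.
#'
#' @param gold Gold data.frame (columns `note_id`, optional
#'   `adjudicator_id`, `concept`, `subcategory`, `sentence_index` with
#'   `NA` for note-level-only rows). Multi-adjudicator tables are merged
#'   by [merge_gold()]; the conflicts are attached to the report.
#' @param predictions A `corpus_annotations` (from [extract_corpus()]) or
#'   a list with `sentences` and `notes` data.frames of the same shape.
#' @param corrections Optional corrections data.frame (columns `note_id`,
#'   `concept`, `subcategory`, `sentence_index`, `confirmed`).
#' @param universe Character vector of all note ids under evaluation;
#'   defaults to the prediction universe.
#' @return An `evaluation_report`: list with `metrics` (long-format
#'   data.frame), `counts` (confusion counts per target and level),
#'   `conflicts`, and `universe`.
#' @export
evaluate_run <- function(gold, predictions, corrections = NULL,
                         universe = NULL) {
  if (is.null(universe)) universe <- predictions$universe
  if (is.null(universe)) stop("a note universe is required", call. = FALSE)
  universe <- unique(as.character(universe))
  check_categories(paste(gold$concept, gold$subcategory, sep = "."))
  mg <- merge_gold(gold)
  gold <- mg$gold
  canon <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0L) {
      df <- as.data.frame(stats::setNames(
        rep(list(character()), length(cols)), cols))
    }
    df
  }
  pred_s <- canon(predictions$sentences,
                  c("note_id", "sentence_index", "concept", "subcategory"))
  pred_n <- canon(predictions$notes,
                  c("note_id", "concept", "subcategory"))
  if (!is.null(corrections) && nrow(corrections) > 0L) {
    check_categories(paste(corrections$concept, corrections$subcategory,
                           sep = "."))
    corrections <- corrections[as.logical(corrections$confirmed), ,
                               drop = FALSE]
  }

  targets <- .eval_targets()
  metric_rows <- list(); count_rows <- list()
  for (t in seq_len(nrow(targets))) {
    cn <- targets$concept[t]; sub <- targets$subcategory[t]
    label <- if (is.na(sub)) cn else paste(cn, sub, sep = ".")
    pick <- function(df) {
      if (is.null(df) || nrow(df) == 0L) return(df[0, , drop = FALSE])
      sel <- df$concept == cn & (is.na(sub) | df$subcategory == sub)
      df[sel, , drop = FALSE]
    }
    g <- pick(gold); ps <- pick(pred_s); pn <- pick(pred_n)
    co <- if (is.null(corrections)) NULL else pick(corrections)

    estimable <- nrow(g) > 0L || nrow(ps) > 0L || nrow(pn) > 0L

    # ---- note level ----
    g_notes <- unique(g$note_id)
    p_notes <- unique(pn$note_id)
    cc_note <- note_confusion(g_notes, p_notes, universe)
    c_note <- 0L
    if (!is.null(co) && nrow(co) > 0L) {
      fp_notes <- setdiff(p_notes, g_notes)
      c_note <- length(intersect(unique(co$note_id), fp_notes))
    }
    # ---- sentence level ----
    g_sent <- unique(g[!is.na(g$sentence_index),
                       c("note_id", "sentence_index"), drop = FALSE])
    p_sent <- unique(ps[, c("note_id", "sentence_index"), drop = FALSE])
    cc_sent <- sentence_confusion(g_sent, p_sent)
    c_sent <- 0L
    if (!is.null(co) && nrow(co) > 0L) {
      cos <- co[!is.na(co$sentence_index), , drop = FALSE]
      gk <- paste(g_sent$note_id, g_sent$sentence_index, sep = "\r")
      pk <- paste(p_sent$note_id, p_sent$sentence_index, sep = "\r")
      ck <- unique(paste(cos$note_id, cos$sentence_index, sep = "\r"))
      c_sent <- sum(ck %in% setdiff(pk, gk))
      # every confirmed correction must hit a counted FP item somewhere
      note_fp <- setdiff(p_notes, g_notes)
      unmatched <- co[!(co$note_id %in% note_fp) &
                        !(paste(co$note_id, co$sentence_index, sep = "\r")
                          %in% setdiff(pk, gk)), , drop = FALSE]
      if (nrow(unmatched) > 0L) {
        stop("correction(s) for ", label,
             " do not correspond to any predicted-only item: note ",
             paste(unique(unmatched$note_id), collapse = ", "),
             call. = FALSE)
      }
    }

    variants <- list(list(corrected = FALSE, note = cc_note, sent = cc_sent))
    if (!is.null(corrections)) {
      variants <- c(variants, list(list(
        corrected = TRUE,
        note = corrected_counts(cc_note, c_note),
        sent = corrected_counts(cc_sent, c_sent))))
    }
    for (v in variants) {
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        target = label, concept = cn, subcategory = sub,
        corrected = v$corrected,
        level = c("note", "sentence"),
        tp = c(v$note$tp, v$sent$tp), fp = c(v$note$fp, v$sent$fp),
        fn = c(v$note$fn, v$sent$fn), tn = c(v$note$tn, NA_integer_),
        stringsAsFactors = FALSE)
      mk <- function(level, metric, num, den) {
        if (!estimable || den == 0L) {
          data.frame(target = label, concept = cn, subcategory = sub,
                     level = level, metric = metric, corrected = v$corrected,
                     estimate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, numerator = num, denominator = den,
                     estimable = FALSE, stringsAsFactors = FALSE)
        } else {
          m <- metric_with_ci(num, den, metric, corrected = v$corrected)
          data.frame(target = label, concept = cn, subcategory = sub,
                     level = level, metric = metric, corrected = v$corrected,
                     estimate = m$estimate, ci_low = m$ci_low,
                     ci_high = m$ci_high, numerator = num, denominator = den,
                     estimable = TRUE, stringsAsFactors = FALSE)
        }
      }
      nn <- v$note; ss <- v$sent
      metric_rows[[length(metric_rows) + 1L]] <- rbind(
        mk("note", "sensitivity", nn$tp, nn$tp + nn$fn),
        mk("note", "specificity", nn$tn, nn$tn + nn$fp),
        mk("note", "ppv", nn$tp, nn$tp + nn$fp),
        mk("sentence", "sensitivity", ss$tp, ss$tp + ss$fn),
        # sentence-level specificity is structurally NA
        data.frame(target = label, concept = cn, subcategory = sub,
                   level = "sentence", metric = "specificity",
                   corrected = v$corrected, estimate = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   numerator = NA_integer_, denominator = NA_integer_,
                   estimable = FALSE, stringsAsFactors = FALSE),
        mk("sentence", "ppv", ss$tp, ss$tp + ss$fp))
    }
  }
  structure(list(metrics = do.call(rbind, metric_rows),
                 counts = do.call(rbind, count_rows),
                 conflicts = mg$conflicts, universe = universe),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render an evaluation report as a text table
#'
#' One block per target, Original/Corrected columns for sensitivity,
#' specificity and PPV at the note and sentence level; estimates are
#' shown as `estimate (ci_low-ci_high)` in percent, rounded half-even to
#' one decimal. Sentence-level specificity prints NA; targets that are
#' not estimable print NE.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Character vector of lines.
#' @export
format.evaluation_report <- function(x, ...) {
  m <- x$metrics
  has_corr <- any(m$corrected)
  cell <- function(target, level, metric, corrected) {
    r <- m[m$target == target & m$level == level & m$metric == metric &
             m$corrected == corrected, , drop = FALSE]
    if (nrow(r) == 0L) return("NA")
    if (!r$estimable) {
      if (level == "sentence" && metric == "specificity") return("NA")
      return("NE")
    }
    sprintf("%s (%s-%s)", format_pct(r$estimate), format_pct(r$ci_low),
            format_pct(r$ci_high))
  }
  lines <- character()
  for (target in unique(m$target)) {
    lines <- c(lines, sprintf("== %s ==", target))
    hdr <- if (has_corr)
      c("level", "sens", "sens(corr)", "spec", "spec(corr)",
        "ppv", "ppv(corr)")
    else c("level", "sens", "spec", "ppv")
    rows <- lapply(c("note", "sentence"), function(lv) {
      vals <- c(lv)
      for (metric in c("sensitivity", "specificity", "ppv")) {
        vals <- c(vals, cell(target, lv, metric, FALSE))
        if (has_corr) vals <- c(vals, cell(target, lv, metric, TRUE))
      }
      vals
    })
    tab <- rbind(hdr, do.call(rbind, rows))
    widths <- apply(nchar(tab), 2, max)
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines, paste(mapply(formatC, tab[i, ], width = widths,
                                     flag = "-"), collapse = "  "))
    }
    lines <- c(lines, "")
  }
  if (nrow(x$conflicts) > 0L) {
    lines <- c(lines, sprintf("%d unresolved adjudication conflict(s)",
                              nrow(x$conflicts)))
  }
  lines
}

#' Write an evaluation report to disk
#'
#' @param report An `evaluation_report`.
#' @param json_path Machine-readable JSON output (metrics, counts,
#'   conflicts).
#' @param text_path Optional rendered text table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, text_path = NULL) {
  jsonlite::write_json(
    list(metrics = report$metrics, counts = report$counts,
         conflicts = report$conflicts,
         universe_size = length(report$universe)),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(text_path)) {
    writeLines(format(report), text_path)
  }
  invisible(json_path)
}
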