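#' Note-level confusion counts
#'
#' Per-note tabulation against the note universe: TP if gold-positive and
#' predicted-positive, FN if gold-positive only, FP if predicted-positive
#' only, TN if neither.
#'
#' @param gold Character vector of gold-positive note ids.
#' @param predicted Character vector of predicted-positive note ids.
#' @param universe Character vector of all note ids under evaluation.
#' @return A `confusion_counts` list: `level = "note"`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
note_confusion <- function(gold, predicted, universe) {
  gold <- unique(as.character(gold)); predicted <- unique(as.character(predicted))
  universe <- unique(as.character(universe))
  stray <- setdiff(c(gold, predicted), universe)
  if (length(stray) > 0L) {
    stop("note ids outside the declared universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  g <- universe %in% gold; p <- universe %in% predicted
  structure(list(level = "note",
                 tp = sum(g & p), fp = sum(!g & p),
                 fn = sum(g & !p), tn = sum(!g & !p)),
            class = "confusion_counts")
}

#' Sentence-level confusion counts
#'
#' Unit of analysis is one positive reference `(note_id, sentence_index)`
#' for a given category; counts follow by set algebra. True negatives are
#' not enumerable at sentence level and are absent (specificity is
#' reported NA downstream).
#'
#' @param gold,predicted data.frames with columns `note_id` and
#'   `sentence_index`. Duplicate gold references collapse with a warning.
#' @return A `confusion_counts` list: `level = "sentence"`, `tp`, `fp`,
#'   `fn`, `tn = NA`.
#' @export
sentence_confusion <- function(gold, predicted) {
  gk <- paste(gold$note_id, gold$sentence_index, sep = "\r")
  pk <- unique(paste(predicted$note_id, predicted$sentence_index, sep = "\r"))
  if (anyDuplicated(gk)) {
    warning("duplicate gold sentence references collapsed", call. = FALSE)
    gk <- unique(gk)
  }
  structure(list(level = "sentence",
                 tp = sum(gk %in% pk), fp = sum(!pk %in% gk),
                 fn = sum(!gk %in% pk), tn = NA_integer_),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> level=", x$level, " tp=", x$tp, " fp=", x$fp,
      " fn=", x$fn, " tn=", if (is.na(x$tn)) "NA" else x$tn, "\n", sep = "")
  invisible(x)
}

#' Proportion metric with an exact binomial confidence interval
#'
#' Point estimate `100 * numerator / denominator` with a two-sided
#' Clopper-Pearson `(1 - alpha)` interval, in percent. Full precision is
#' retained; display rounding (half-even, one decimal) happens in
#' [format()] / report rendering only.
#'
#' @param numerator,denominator Non-negative integers,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`.
#' @param alpha Two-sided error rate (default 0.05 for a 95\% CI).
#' @param corrected Flag carried through to the result.
#' @return A `metric_result` list: `metric`, `estimate`, `ci_low`,
#'   `ci_high` (percent), `numerator`, `denominator`, `corrected`.
#' @examples
#' metric_with_ci(29, 29, "sensitivity")   # lower bound 88.1%
#' @export
metric_with_ci <- function(numerator, denominator,
                           metric = c("sensitivity", "specificity", "ppv"),
                           alpha = 0.05, corrected = FALSE) {
  metric <- match.arg(metric)
  if (denominator <= 0L) {
    stop("undefined metric: denominator is zero", call. = FALSE)
  }
  if (numerator < 0L || numerator > denominator) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  x <- numerator; n <- denominator
  lo <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1L)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1L, n - x)
  structure(list(metric = metric, estimate = 100 * x / n,
                 ci_low = 100 * lo, ci_high = 100 * hi,
                 numerator = as.integer(x), denominator = as.integer(n),
                 corrected = isTRUE(corrected)),
            class = "metric_result")
}

#' @export
format.metric_result <- function(x, ...) {
  sprintf("%s (%s-%s)", format_pct(x$estimate), format_pct(x$ci_low),
          format_pct(x$ci_high))
}

#' @export
print.metric_result <- function(x, ...) {
  cat("<metric_result> ", x$metric, if (x$corrected) " (corrected)", ": ",
      format(x), "  [", x$numerator, "/", x$denominator, "]\n", sep = "")
  invisible(x)
}

# half-even rounding to one decimal, trailing zeros dropped ("100", "88.1")
format_pct <- function(x) {
  ifelse(is.na(x), "NA", sub("\\.0$", "", sprintf("%.1f", round(x, 1))))
}

#' Apply secondary-review corrections to confusion counts
#'
#' Reclassifies system-found, adjudicator-missed true positives: with `c`
#' confirmed corrections, `tp' = tp + c`, `fp' = fp - c`, `fn` unchanged,
#' and at note level `tn` unchanged (the corrected items leave the
#' negative pool, so corrected specificity is `tn / (tn + fp - c)`).
#' Corrected sensitivity and PPV can therefore never fall below the
#' originals.
#'
#' @param counts A `confusion_counts`.
#' @param corrections Either a single non-negative integer (the number of
#'   confirmed corrections) or a data.frame with a logical `confirmed`
#'   column, in which case `c = sum(confirmed)`.
#' @return A `confusion_counts` with the reclassification applied.
#' @export
corrected_counts <- function(counts, corrections) {
  c_n <- if (is.data.frame(corrections)) sum(as.logical(corrections$confirmed))
  else as.integer(corrections)
  if (is.na(c_n) || c_n < 0L) stop("invalid correction count", call. = FALSE)
  if (c_n > counts$fp) {
    stop("inconsistent corrections: ", c_n, " confirmed but only ",
         counts$fp, " false positives counted", call. = FALSE)
  }
  counts$tp <- counts$tp + c_n
  counts$fp <- counts$fp - c_n
  counts
}

#' Cohen's kappa for two adjudicators
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o` is observed agreement and `p_e` the chance agreement implied by
#' the raters' marginals. Two identical constant labelings (agreement
#' certain by the marginals) return 1.
#'
#' @param a,b Label vectors over the same note universe (binary flags in
#'   typical use; any label alphabet works).
#' @return Numeric kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.5
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must cover the same note universe", call. = FALSE)
  }
  if (length(a) == 0L) stop("empty label vectors", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  po <- mean(a == b)
  lev <- union(a, b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), 0))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (po == 1) return(1)
    stop("kappa undefined: chance agreement is 1 with disagreement present",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Note-level kappa per concept from a dual-adjudicator gold table
#'
#' @param gold Gold data.frame (see [read_gold()]) containing exactly two
#'   `adjudicator_id` values.
#' @param universe Character vector of all adjudicated note ids.
#' @return data.frame with columns `concept` and `kappa`.
#' @export
kappa_by_concept <- function(gold, universe) {
  adjs <- sort(unique(as.character(gold$adjudicator_id)))
  if (length(adjs) != 2L) {
    stop("exactly two adjudicators required, found ", length(adjs),
         call. = FALSE)
  }
  universe <- unique(as.character(universe))
  res <- lapply(concept_names(), function(cn) {
    flags <- lapply(adjs, function(ad) {
      pos <- unique(gold$note_id[gold$adjudicator_id == ad &
                                   gold$concept == cn])
      as.integer(universe %in% pos)
    })
    data.frame(concept = cn, kappa = cohens_kappa(flags[[1L]], flags[[2L]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
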